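# Synthetic genomes with planted repeat structure.
#
# The simulator emulates exactly the structures the pipeline must
# separate: true MITE families (TIR + interior + reverse-complement TIR,
# with a per-insertion target site duplicated on both sides, copies
# dispersed at uniformly random loci and independently mutated), false
# retroelement-like families (an inverted repeat flanked by abutting
# direct repeats buried inside a cassette that is copied verbatim, so
# every copy carries identical 50-nt flanking contexts), and simple
# repeat stretches. Insertions never overlap, and every generator is
# deterministic given its seed (the seed is applied with `set.seed`).

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Family specification for the simulator
#'
#' @param family_id Unique family name.
#' @param element_len Element length in nt, 50-800.
#' @param tir_len TIR arm length in nt (`2 * tir_len < element_len`).
#' @param tsd_len TSD length in nt, 2-10.
#' @param copy_number Number of copies to plant.
#' @param mutation_rate Per-site substitution probability, at most 0.2.
#' @param kind One of `"true_mite"`, `"false_retro_like"`,
#'   `"simple_repeat"`.
#' @return A list of class `family_spec`.
#' @export
family_spec <- function(family_id, element_len, tir_len, tsd_len,
                        copy_number, mutation_rate = 0,
                        kind = c("true_mite", "false_retro_like",
                                 "simple_repeat")) {
  kind <- match.arg(kind)
  if (element_len < 50L || element_len > 800L)
    stop("element_len must lie in [50, 800]")
  if (2L * tir_len >= element_len)
    stop("need 2 * tir_len < element_len")
  if (tsd_len < 2L || tsd_len > 10L) stop("tsd_len must lie in [2, 10]")
  if (mutation_rate < 0 || mutation_rate > 0.2)
    stop("mutation_rate must lie in [0, 0.2]")
  structure(list(family_id = family_id,
                 element_len = as.integer(element_len),
                 tir_len = as.integer(tir_len),
                 tsd_len = as.integer(tsd_len),
                 copy_number = as.integer(copy_number),
                 mutation_rate = mutation_rate, kind = kind),
            class = "family_spec")
}

#' Generate a random background genome
#'
#' I.i.d. nucleotides at the given GC content, split over `n_entries`
#' entries of near-equal size.
#'
#' @param total_len Total genome length in nt.
#' @param n_entries Number of database entries.
#' @param gc GC content fraction.
#' @param seed RNG seed.
#' @return A [genome_db()] object.
#' @export
make_background <- function(total_len, n_entries = 1L, gc = 0.5,
                            seed = NULL) {
  if (total_len < n_entries) stop("total_len must be >= n_entries")
  if (!is.null(seed)) set.seed(seed)
  base <- total_len %/% n_entries
  lens <- rep(base, n_entries)
  lens[1L] <- lens[1L] + total_len - sum(lens)
  seqs <- vapply(lens, random_dna, character(1), gc = gc)
  names(seqs) <- sprintf("chr%d", seq_len(n_entries))
  genome_db(seqs)
}

#' Build a MITE family consensus
#'
#' element = TIR + random interior + reverse complement of the TIR, with
#' a TIR that is not a simple repeat (so the planted family is detectable
#' in principle).
#'
#' @param spec A [family_spec()] with `kind = "true_mite"`.
#' @param seed RNG seed.
#' @param gc GC content of TIR and interior.
#' @return The consensus sequence.
#' @export
make_mite_consensus <- function(spec, seed = NULL, gc = 0.5) {
  stopifnot(spec$kind == "true_mite")
  if (!is.null(seed)) set.seed(seed)
  repeat {
    tir <- random_dna(spec$tir_len, gc)
    if (!is_simple_arm(tir)) break
  }
  interior <- random_dna(spec$element_len - 2L * spec$tir_len, gc)
  paste0(tir, interior, reverse_complement(tir))
}

# substitution-only mutation; the first and last `exempt` nt (TIR termini)
# stay intact unless mutate_all
mutate_copy <- function(seq, rate, exempt = 5L, mutate_all = FALSE) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  lo <- if (mutate_all) 1L else exempt + 1L
  hi <- if (mutate_all) n else n - exempt
  if (hi < lo) return(seq)
  sub <- lo:hi
  hit <- sub[stats::runif(length(sub)) < rate]
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

seq_identity <- function(a, b) {
  m <- min(nchar(a), nchar(b))
  .hamming_matches_cpp(encode_seq(substr(a, 1L, m)),
                       encode_seq(substr(b, 1L, m))) / m
}

# choose distinct insertion points across entries, uniform over total
# length, respecting an edge margin and a minimum pairwise gap; returns a
# data.frame(entry, point) in genome order
choose_points <- function(db, n, min_gap, edge_margin = 60L,
                          avoid = NULL, max_tries = 200000L) {
  lens <- nchar(db$seq)
  cum <- c(0, cumsum(lens))
  if (!is.null(avoid) && nrow(avoid) > 0L) {
    avoid_e <- match(avoid$entry_id, names(db$seq))
  }
  chosen_e <- integer(0)
  chosen_p <- integer(0)
  tries <- 0L
  while (length(chosen_e) < n) {
    tries <- tries + 1L
    if (tries > max_tries) stop("insufficient room to place insertions")
    g <- floor(stats::runif(1) * db$total_length)
    e <- findInterval(g, cum, rightmost.closed = TRUE)
    p <- as.integer(g - cum[e])
    if (p < edge_margin || p > lens[e] - edge_margin) next
    samee <- chosen_e == e
    if (any(abs(chosen_p[samee] - p) < min_gap)) next
    if (!is.null(avoid) && nrow(avoid) > 0L) {
      hit <- avoid_e == e & p >= avoid$lo - edge_margin &
        p <= avoid$hi + edge_margin
      if (any(hit)) next
    }
    chosen_e <- c(chosen_e, e)
    chosen_p <- c(chosen_p, p)
  }
  o <- order(chosen_e, chosen_p)
  data.frame(entry = chosen_e[o], point = chosen_p[o])
}

# splice insertions (data.frame entry, point, seq, plus metadata columns)
# into db; returns list(db, where) with `where` giving the final 0-based
# start of every inserted sequence
splice_inserts <- function(db, ins) {
  ins <- ins[order(ins$entry, ins$point), , drop = FALSE]
  seqs <- db$seq
  where <- integer(nrow(ins))
  for (e in unique(ins$entry)) {
    rows <- which(ins$entry == e)
    s <- seqs[[e]]
    parts <- character(0)
    prev <- 0L
    shift <- 0L
    for (r in rows) {
      p <- ins$point[r]
      parts <- c(parts, substr(s, prev + 1L, p), ins$seq[r])
      where[r] <- p + shift
      shift <- shift + nchar(ins$seq[r])
      prev <- p
    }
    parts <- c(parts, substr(s, prev + 1L, nchar(s)))
    seqs[[e]] <- paste(parts, collapse = "")
  }
  list(db = genome_db(seqs), where = where, order = order(ins$entry, ins$point))
}

empty_truth_copies <- function() {
  data.frame(family_id = character(), entry_id = character(),
             start = integer(), end = integer(), strand = character(),
             identity = numeric(), flank_context_id = character(),
             tsd = character(), kind = character())
}

#' Plant a MITE family into a genome
#'
#' Inserts `copy_number` copies of the consensus at uniformly random,
#' non-overlapping loci. At each locus the `tsd_len` nt of background to
#' the right of the insertion point become the target site and are
#' duplicated on both sides of the element (true TSD semantics). Each
#' copy is mutated independently at `mutation_rate` (substitutions only;
#' the terminal 5 nt of the element and the TSD stay intact unless
#' `mutate_all`).
#'
#' @param db A [genome_db()] object.
#' @param consensus The family consensus from [make_mite_consensus()].
#' @param spec The [family_spec()].
#' @param seed RNG seed.
#' @param mutate_all Also mutate the TIR termini (default `FALSE`).
#' @param min_gap Minimum distance between insertion points (default:
#'   element length + 150).
#' @return A list with the new `db` and a `truth` data frame (one row per
#'   planted copy, final 0-based half-open element coordinates).
#' @export
plant_family <- function(db, consensus, spec, seed = NULL,
                         mutate_all = FALSE, min_gap = NULL,
                         avoid = NULL) {
  stopifnot(inherits(db, "mite_genome"), spec$kind == "true_mite")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(min_gap)) min_gap <- spec$element_len + 150L
  pts <- choose_points(db, spec$copy_number, min_gap, avoid = avoid)
  ins <- data.frame(entry = pts$entry, point = pts$point,
                    seq = character(nrow(pts)))
  copies <- character(nrow(pts))
  tsds <- character(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    s <- db$seq[[pts$entry[i]]]
    site <- substr(s, pts$point[i] + 1L, pts$point[i] + spec$tsd_len)
    copies[i] <- mutate_copy(consensus, spec$mutation_rate,
                             mutate_all = mutate_all)
    tsds[i] <- site
    # insert element + duplicated site immediately after the site
    ins$point[i] <- pts$point[i] + spec$tsd_len
    ins$seq[i] <- paste0(copies[i], site)
  }
  sp <- splice_inserts(db, ins)
  ord <- sp$order
  truth <- data.frame(
    family_id = spec$family_id,
    entry_id = db$ids[ins$entry[ord]],
    start = sp$where,
    end = sp$where + spec$element_len,
    strand = "+",
    identity = vapply(copies[ord], seq_identity, numeric(1), b = consensus,
                      USE.NAMES = FALSE),
    flank_context_id = sprintf("%s_ctx%d", spec$family_id,
                               seq_along(ord)),
    tsd = tsds[ord],
    kind = "true_mite")
  events <- data.frame(entry_id = db$ids[ins$entry], point = ins$point,
                       len = nchar(ins$seq))
  list(db = sp$db, truth = truth, events = events)
}

#' Plant a false (retroelement-like) family
#'
#' Builds a cassette of fixed left context + direct repeat + IR core +
#' direct repeat + fixed right context, and plants verbatim copies at
#' random loci. The core alone passes the IR and TSD screens, but every
#' copy carries identical flanking sequence -- the signature of an
#' internal fragment of a larger repeat rather than a mobile element.
#' The context is deep (default 400 nt per side) so that, as in a real
#' retroelement body, no window inside the element-size range can reach
#' from one edge of the repeat to the other and pick up locus-specific
#' flanks on both sides.
#'
#' @param db A [genome_db()] object.
#' @param spec A [family_spec()] with `kind = "false_retro_like"`;
#'   `element_len` refers to the IR core (TIR..TIR span).
#' @param seed RNG seed.
#' @param gc GC content of the cassette.
#' @param ctx_len Fixed context length per side in nt (default 400).
#' @param avoid Occupied intervals to stay clear of (see
#'   [plant_family()]).
#' @return A list with the new `db`, a `truth` data frame (core element
#'   coordinates) and the cassette `core` consensus.
#' @export
plant_false_family <- function(db, spec, seed = NULL, gc = 0.5,
                               ctx_len = 400L, avoid = NULL) {
  stopifnot(inherits(db, "mite_genome"), spec$kind == "false_retro_like")
  if (!is.null(seed)) set.seed(seed)
  repeat {
    tir <- random_dna(spec$tir_len, gc)
    if (!is_simple_arm(tir)) break
  }
  interior <- random_dna(spec$element_len - 2L * spec$tir_len, gc)
  core <- paste0(tir, interior, reverse_complement(tir))
  tsd <- random_dna(spec$tsd_len, gc)
  ctx_l <- random_dna(ctx_len, gc)
  ctx_r <- random_dna(ctx_len, gc)
  cassette <- paste0(ctx_l, tsd, core, tsd, ctx_r)
  pts <- choose_points(db, spec$copy_number, nchar(cassette) + 150L,
                       avoid = avoid)
  ins <- data.frame(entry = pts$entry, point = pts$point, seq = cassette)
  sp <- splice_inserts(db, ins)
  ord <- sp$order
  core_start <- sp$where + ctx_len + spec$tsd_len
  truth <- data.frame(
    family_id = spec$family_id,
    entry_id = db$ids[ins$entry[ord]],
    start = core_start,
    end = core_start + spec$element_len,
    strand = "+",
    identity = 1,
    flank_context_id = sprintf("%s_shared", spec$family_id),
    tsd = tsd,
    kind = "false_retro_like")
  events <- data.frame(entry_id = db$ids[ins$entry], point = ins$point,
                       len = nchar(ins$seq))
  list(db = sp$db, truth = truth, core = core, events = events)
}

#' Plant simple-repeat stretches
#'
#' Inserts homopolymer, `(AT)n` and `(GC)n` stretches at random loci --
#' negative material that must be rejected by the simple-arm and
#' low-complexity filters.
#'
#' @param db A [genome_db()] object.
#' @param n_stretches Number of stretches.
#' @param len_range Length range in nt (default 100-300).
#' @param seed RNG seed.
#' @return A list with the new `db` and an `intervals` data frame of the
#'   planted stretches (final 0-based half-open coordinates).
#' @export
plant_simple_repeats <- function(db, n_stretches, len_range = c(100L, 300L),
                                 seed = NULL, avoid = NULL) {
  stopifnot(inherits(db, "mite_genome"))
  if (!is.null(seed)) set.seed(seed)
  if (n_stretches == 0L) {
    return(list(db = db, intervals = data.frame(
      entry_id = character(), start = integer(), end = integer(),
      type = character()),
      events = data.frame(entry_id = character(), point = integer(),
                          len = integer())))
  }
  types <- sample(c("homopolymer", "AT", "GC"), n_stretches, replace = TRUE)
  lens <- sample(seq.int(len_range[1L], len_range[2L]), n_stretches,
                 replace = TRUE)
  seqs <- vapply(seq_len(n_stretches), function(i) {
    switch(types[i],
           homopolymer = strrep(sample(c("A", "C", "G", "T"), 1L), lens[i]),
           AT = substr(strrep("AT", ceiling(lens[i] / 2)), 1L, lens[i]),
           GC = substr(strrep("GC", ceiling(lens[i] / 2)), 1L, lens[i]))
  }, character(1))
  pts <- choose_points(db, n_stretches, max(lens) + 150L, avoid = avoid)
  ins <- data.frame(entry = pts$entry, point = pts$point, seq = seqs)
  sp <- splice_inserts(db, ins)
  ord <- sp$order
  list(db = sp$db, intervals = data.frame(
    entry_id = db$ids[ins$entry[ord]],
    start = sp$where, end = sp$where + nchar(seqs[ord]),
    type = types[ord]),
    events = data.frame(entry_id = db$ids[ins$entry], point = ins$point,
                        len = nchar(seqs)))
}

#' Default simulation scenario
#'
#' The study conditions used throughout the test suite: a 2-Mb background
#' at 43% GC over 4 entries, 8 true MITE families with copy numbers
#' between 12 and 40 and per-copy mutation up to 5%, 5 identical-flank
#' false families of 15 copies, and 10 simple-repeat stretches.
#'
#' @return A list of `true_specs`, `false_specs`, `n_simple` and
#'   background settings.
#' @export
default_simulation_specs <- function() {
  copy_numbers <- c(12L, 15L, 18L, 22L, 26L, 30L, 35L, 40L)
  element_lens <- c(120L, 450L, 260L, 90L, 340L, 180L, 600L, 150L)
  tir_lens <- c(12L, 20L, 14L, 11L, 25L, 13L, 30L, 15L)
  tsd_lens <- c(2L, 3L, 8L, 2L, 5L, 3L, 4L, 9L)
  mut <- c(0, 0.01, 0.02, 0.03, 0.05, 0.02, 0.04, 0)
  true_specs <- lapply(seq_len(8L), function(i) {
    family_spec(sprintf("mite%02d", i), element_lens[i], tir_lens[i],
                tsd_lens[i], copy_numbers[i], mut[i], "true_mite")
  })
  false_specs <- lapply(seq_len(5L), function(i) {
    family_spec(sprintf("decoy%02d", i), c(100L, 200L, 150L, 90L, 260L)[i],
                c(12L, 15L, 11L, 14L, 20L)[i], c(3L, 4L, 2L, 5L, 3L)[i],
                15L, 0, "false_retro_like")
  })
  list(true_specs = true_specs, false_specs = false_specs,
       n_simple = 10L, total_len = 2000000L, n_entries = 4L, gc = 0.43)
}

#' Simulate a genome with planted repeat structure
#'
#' Generates a background and plants all families and simple repeats.
#' Planting is sequential with non-overlap enforced through generous
#' spacing; final coordinates in the truth table refer to the returned
#' genome.
#'
#' @param specs A scenario list as returned by
#'   [default_simulation_specs()] (the default).
#' @param seed Master RNG seed; per-step seeds are derived from it.
#' @return A list of class `mite_simulation`: `db`, `truth` (copy-level
#'   data frame), `families` (per-family table with consensus sequences),
#'   `simple` (planted stretch intervals).
#' @export
simulate_genome <- function(specs = default_simulation_specs(), seed = 1L) {
  db <- make_background(specs$total_len, specs$n_entries, specs$gc,
                        seed = seed)
  truth <- empty_truth_copies()
  fam <- list()
  next_seed <- seed
  for (sp in specs$true_specs) {
    next_seed <- next_seed + 1L
    cons <- make_mite_consensus(sp, seed = next_seed, gc = specs$gc)
    next_seed <- next_seed + 1L
    res <- plant_family(db, cons, sp, seed = next_seed,
                        avoid = truth_avoid(truth))
    truth <- shift_existing(truth, res$events)
    truth <- rbind(truth, res$truth)
    db <- res$db
    fam[[sp$family_id]] <- data.frame(
      family_id = sp$family_id, kind = sp$kind, consensus = cons,
      element_len = sp$element_len, tir_len = sp$tir_len,
      tsd_len = sp$tsd_len, copy_number = sp$copy_number,
      mutation_rate = sp$mutation_rate)
  }
  for (sp in specs$false_specs) {
    next_seed <- next_seed + 1L
    res <- plant_false_family(db, sp, seed = next_seed, gc = specs$gc,
                              avoid = truth_avoid(truth))
    truth <- shift_existing(truth, res$events)
    truth <- rbind(truth, res$truth)
    db <- res$db
    fam[[sp$family_id]] <- data.frame(
      family_id = sp$family_id, kind = sp$kind, consensus = res$core,
      element_len = sp$element_len, tir_len = sp$tir_len,
      tsd_len = sp$tsd_len, copy_number = sp$copy_number,
      mutation_rate = sp$mutation_rate)
  }
  next_seed <- next_seed + 1L
  simple <- plant_simple_repeats(db, specs$n_simple, seed = next_seed,
                                 avoid = truth_avoid(truth))
  truth <- shift_existing(truth, simple$events)
  db <- simple$db
  rownames(truth) <- NULL
  structure(list(db = db, truth = truth,
                 families = do.call(rbind, c(fam, list(make.row.names = FALSE))),
                 simple = simple$intervals),
            class = "mite_simulation")
}

# occupied intervals (with the cassette context for false families) that
# later planting calls must not hit
truth_avoid <- function(truth) {
  if (nrow(truth) == 0L) return(NULL)
  pad <- ifelse(truth$kind == "false_retro_like", 62L, 12L)
  data.frame(entry_id = truth$entry_id, lo = truth$start - pad,
             hi = truth$end + pad)
}

# Shift existing truth coordinates for the insertion events of a later
# planting call (events carry insertion points in the coordinates the
# rows currently use).
shift_existing <- function(truth, events) {
  if (nrow(truth) == 0L || nrow(events) == 0L) return(truth)
  for (r in seq_len(nrow(truth))) {
    sel <- events$entry_id == truth$entry_id[r] &
      events$point <= truth$start[r]
    add <- sum(events$len[sel])
    truth$start[r] <- truth$start[r] + add
    truth$end[r] <- truth$end[r] + add
  }
  truth
}
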