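# Family evaluation: genome-wide full-length copy counting and
# flanking-sequence diversity.
#
# A genuine MITE family has many near-identical copies scattered across
# independent insertion sites, so its copies show diverse 50-nt flanking
# contexts. A repeat whose copies all carry the same flanks (an internal
# fragment of a larger element, e.g. a retroelement cassette) is a false
# family. Copy counting is seed-and-verify: exact k-mer seeds from the
# query anchor candidate loci in a precomputed genome index, and each
# locus is verified by direct (ungapped) identity over the full element.

#' Build a k-mer position index over a genome database
#'
#' @param db A [genome_db()] object.
#' @param k Seed length in nt (default 12).
#' @return A `kmer_index` object used by [count_full_length_copies()],
#'   [mask_known()] and the pipeline.
#' @export
build_kmer_index <- function(db, k = 12L) {
  stopifnot(inherits(db, "mite_genome"))
  k <- as.integer(k)
  enc <- lapply(db$seq, encode_seq)
  codes <- vector("list", length(enc))
  entry <- vector("list", length(enc))
  pos <- vector("list", length(enc))
  for (i in seq_along(enc)) {
    cd <- rolling_codes(enc[[i]], k)
    ok <- which(!is.na(cd))
    codes[[i]] <- cd[ok]
    entry[[i]] <- rep.int(i, length(ok))
    pos[[i]] <- ok - 1L  # 0-based
  }
  codes <- unlist(codes, use.names = FALSE)
  entry <- unlist(entry, use.names = FALSE)
  pos <- unlist(pos, use.names = FALSE)
  o <- order(codes)
  structure(
    list(k = k, codes = codes[o], entry = entry[o], pos = pos[o],
         enc = enc, entry_ids = db$ids,
         entry_len = vapply(enc, length, integer(1))),
    class = "kmer_index"
  )
}

# rolling k-mer codes as exact doubles (4^k <= 2^53); NA where the window
# contains N
rolling_codes <- function(enc, k) {
  n <- length(enc)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  code <- numeric(m)
  for (i in 0:(k - 1L)) {
    code <- code * 4 + pmin(enc[(1L + i):(m + i)], 3L)
  }
  ncum <- c(0L, cumsum(enc == 4L))
  code[ncum[(1L:m) + k] - ncum[1L:m] > 0L] <- NA_real_
  code
}

# indices into the sorted index matching each query code: positions
# (lo, hi] in the sorted code vector
kmer_lookup <- function(index, qcodes) {
  .lookup_range_cpp(index$codes, qcodes)
}

#' Count full-length genomic copies of an element
#'
#' Searches both strands of the whole database for near-full-length copies
#' of `element_seq` (query coverage at least `full_length_coverage_min`,
#' ungapped identity at least `copy_identity_min`). Overlapping hits at a
#' locus (more than 50% of the shorter hit shared) are collapsed to the
#' best by identity x coverage. The query's own source locus is one of the
#' hits.
#'
#' @param element_seq The element sequence (left TIR start to right TIR
#'   end inclusive).
#' @param db A [genome_db()] object.
#' @param copy_identity_min Minimum identity fraction (default 0.80).
#' @param full_length_coverage_min Minimum query coverage (default 0.90).
#' @param index Optional precomputed [build_kmer_index()]; built on the
#'   fly when `NULL`.
#' @param seed_step Spacing of seed k-mers along the query (default 4 nt).
#' @return A data frame of hits: `entry_id`, `start`, `end` (0-based
#'   half-open), `strand`, `identity`, `query_coverage`, ordered by
#'   genome position.
#' @export
count_full_length_copies <- function(element_seq, db,
                                     copy_identity_min = 0.80,
                                     full_length_coverage_min = 0.90,
                                     index = NULL, seed_step = 4L) {
  stopifnot(inherits(db, "mite_genome"))
  if (is.null(index)) index <- build_kmer_index(db)
  len <- nchar(element_seq)
  k <- index$k
  hits <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") element_seq else reverse_complement(element_seq)
    qenc <- encode_seq(q)
    qcodes <- rolling_codes(qenc, k)
    offs <- seq.int(1L, max(1L, len - k + 1L), by = seed_step)
    offs <- offs[offs <= length(qcodes)]
    offs <- offs[!is.na(qcodes[offs])]
    if (length(offs) == 0L) next
    rng <- kmer_lookup(index, qcodes[offs])
    cand_entry <- integer(0); cand_start <- integer(0)
    for (ii in seq_along(offs)) {
      if (rng$hi[ii] <= rng$lo[ii]) next
      sel <- (rng$lo[ii] + 1L):rng$hi[ii]
      cand_entry <- c(cand_entry, index$entry[sel])
      cand_start <- c(cand_start, index$pos[sel] - (offs[ii] - 1L))
    }
    if (length(cand_entry) == 0L) next
    key <- !duplicated(cand_entry * 2^31 + cand_start)
    cand_entry <- cand_entry[key]; cand_start <- cand_start[key]
    for (ii in seq_along(cand_entry)) {
      e <- cand_entry[ii]; g0 <- cand_start[ii]
      elen <- index$entry_len[e]
      c0 <- max(g0, 0L); c1 <- min(g0 + len, elen)
      ov <- c1 - c0
      if (ov < full_length_coverage_min * len) next
      qs <- qenc[(c0 - g0 + 1L):(c1 - g0)]
      gs <- index$enc[[e]][(c0 + 1L):c1]
      m <- .hamming_matches_cpp(qs, gs)
      if (m < copy_identity_min * ov) next
      hits[[length(hits) + 1L]] <- data.frame(
        entry = e, start = c0, end = c1, strand = strand,
        identity = m / ov, query_coverage = ov / len)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(entry_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      identity = numeric(), query_coverage = numeric()))
  }
  h <- do.call(rbind, hits)
  h <- h[order(h$entry, h$start, h$strand), , drop = FALSE]
  # collapse per-locus duplicates (hits overlapping > 50% of the shorter)
  cluster <- integer(nrow(h))
  cl <- 0L
  cur_entry <- -1L; cur_start <- -1L; cur_end <- -1L
  for (i in seq_len(nrow(h))) {
    same <- FALSE
    if (h$entry[i] == cur_entry) {
      ov <- min(cur_end, h$end[i]) - max(cur_start, h$start[i])
      shorter <- min(cur_end - cur_start, h$end[i] - h$start[i])
      same <- ov > 0.5 * shorter
    }
    if (same) {
      cluster[i] <- cl
      cur_start <- min(cur_start, h$start[i])
      cur_end <- max(cur_end, h$end[i])
    } else {
      cl <- cl + 1L
      cluster[i] <- cl
      cur_entry <- h$entry[i]
      cur_start <- h$start[i]
      cur_end <- h$end[i]
    }
  }
  score <- h$identity * h$query_coverage
  pick <- vapply(split(seq_len(nrow(h)), cluster), function(ix) {
    ix[order(-score[ix], h$strand[ix] != "+", h$start[ix])][1L]
  }, integer(1))
  h <- h[sort(pick), , drop = FALSE]
  data.frame(entry_id = index$entry_ids[h$entry], start = h$start,
             end = h$end, strand = h$strand, identity = h$identity,
             query_coverage = h$query_coverage, row.names = NULL)
}

#' Retrieve 50-nt flanking sequences for family hits
#'
#' For each hit the windows immediately left and right of the hit are
#' extracted in reference orientation; for minus-strand hits the two
#' windows are swapped and reverse-complemented so that flanks are always
#' element-oriented. Flanks truncated by an entry end are kept and
#' flagged.
#'
#' @param hits A data frame from [count_full_length_copies()].
#' @param db A [genome_db()] object.
#' @param flank_window Flank size in nt (default 50).
#' @return A data frame with `left`, `right`, `left_truncated`,
#'   `right_truncated` plus the hit columns.
#' @export
collect_flanks <- function(hits, db, flank_window = 50L) {
  stopifnot(inherits(db, "mite_genome"))
  n <- nrow(hits)
  left <- character(n); right <- character(n)
  lt <- logical(n); rt <- logical(n)
  for (i in seq_len(n)) {
    s <- db$seq[[hits$entry_id[i]]]
    elen <- nchar(s)
    a0 <- max(0L, hits$start[i] - flank_window)
    gl <- substr(s, a0 + 1L, hits$start[i])
    b1 <- min(elen, hits$end[i] + flank_window)
    gr <- substr(s, hits$end[i] + 1L, b1)
    gl_tr <- nchar(gl) < flank_window
    gr_tr <- nchar(gr) < flank_window
    if (hits$strand[i] == "+") {
      left[i] <- gl; right[i] <- gr; lt[i] <- gl_tr; rt[i] <- gr_tr
    } else {
      left[i] <- reverse_complement(gr)
      right[i] <- reverse_complement(gl)
      lt[i] <- gr_tr; rt[i] <- gl_tr
    }
  }
  cbind(hits, data.frame(left = left, right = right,
                         left_truncated = lt, right_truncated = rt))
}

# identity between two junction-anchored flanks over the shorter length;
# left flanks are anchored at their right (junction) end, right flanks at
# their left end
flank_identity <- function(a, b, side) {
  m <- min(nchar(a), nchar(b))
  if (m == 0L) return(0)
  if (side == "left") {
    a <- substr(a, nchar(a) - m + 1L, nchar(a))
    b <- substr(b, nchar(b) - m + 1L, nchar(b))
  } else {
    a <- substr(a, 1L, m)
    b <- substr(b, 1L, m)
  }
  .hamming_matches_cpp(encode_seq(a), encode_seq(b)) / m
}

#' Count distinct flank classes among family copies
#'
#' Considers at most `subset_max` flank pairs (the first in genome order;
#' comparing a small subset is sufficient to expose a shared context).
#' Two pairs belong to the same class when either side matches the other
#' pair's corresponding side at more than `flank_identity_max` identity
#' over the shorter length; classes are merged by single linkage. A
#' fragment buried inside a larger repeat recurs with the repeat body on
#' both sides, so a single shared side is already strong evidence that
#' two copies sit in the same context.
#'
#' @param pairs A data frame from [collect_flanks()].
#' @param subset_max Maximum number of pairs compared (default 20).
#' @param flank_identity_max Identity above which two flanks are "the
#'   same" (default 0.80, strict).
#' @return The number of distinct flank classes.
#' @export
count_distinct_flanks <- function(pairs, subset_max = 20L,
                                  flank_identity_max = 0.80) {
  if (nrow(pairs) == 0L) stop("no flank pairs to compare")
  n <- min(nrow(pairs), subset_max)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      same <- flank_identity(pairs$left[i], pairs$left[j], "left") >
        flank_identity_max ||
        flank_identity(pairs$right[i], pairs$right[j], "right") >
        flank_identity_max
      if (same) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

#' Evaluate a putative element against the whole genome
#'
#' Composes copy counting, flank retrieval and flank classing into the
#' final verdict for one putative element that already passed the IR and
#' TSD screens:
#' * `candidate` -- at least `copy_threshold` full-length copies spread
#'   over at least `flank_class_threshold` distinct flank classes;
#' * `false_family` -- enough copies but too few flank classes (the
#'   copies share their insertion context, so the repeat is an internal
#'   fragment of something larger);
#' * `below_copy_threshold` -- too few copies to call a family.
#'
#' @param element_seq The putative element sequence.
#' @param db A [genome_db()] object.
#' @param params A [pipeline_params()] object.
#' @param index Optional precomputed [build_kmer_index()] of `db`.
#' @return A list of class `candidate_evaluation` with `element_seq`,
#'   `copy_count`, `distinct_flank_count` (`NA` when the copy threshold
#'   was not met), `verdict` and the hit table.
#' @export
evaluate_candidate <- function(element_seq, db, params = pipeline_params(),
                               index = NULL) {
  hits <- count_full_length_copies(
    element_seq, db,
    copy_identity_min = params$copy_identity_min,
    full_length_coverage_min = params$full_length_coverage_min,
    index = index, seed_step = params$seed_step)
  copy_count <- nrow(hits)
  if (copy_count < params$copy_threshold) {
    ev <- list(element_seq = element_seq, copy_count = copy_count,
               distinct_flank_count = NA_integer_,
               verdict = "below_copy_threshold", hits = hits)
    return(structure(ev, class = "candidate_evaluation"))
  }
  fl <- collect_flanks(hits, db, flank_window = params$flank_window)
  nf <- count_distinct_flanks(fl, subset_max = params$subset_max,
                              flank_identity_max = params$flank_identity_max)
  verdict <- if (nf >= params$flank_class_threshold) "candidate" else
    "false_family"
  structure(
    list(element_seq = element_seq, copy_count = copy_count,
         distinct_flank_count = nf, verdict = verdict, hits = fl),
    class = "candidate_evaluation"
  )
}

#' @export
print.candidate_evaluation <- function(x, ...) {
  cat(sprintf("candidate_evaluation: %d nt, %d copies, %s flank classes -> %s\n",
              nchar(x$element_seq), x$copy_count,
              ifelse(is.na(x$distinct_flank_count), "-",
                     x$distinct_flank_count), x$verdict))
  invisible(x)
}
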