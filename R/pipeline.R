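# Pipeline orchestration.
#
# Slices are processed in database order. Each slice is hard-masked with
# the filter database (everything already deposited), cleaned of
# low-complexity sequence, scanned for TIR pairs, screened for TSDs, and
# surviving putative elements are evaluated genome-wide. One exemplar per
# family is deposited; later copies of the family are removed by masking
# or, within the same slice, by the redundancy check. Discovery may stop
# early after the fraction of the database given by the sampling model;
# copy counting always sees the whole database.

#' Pipeline parameter set
#'
#' @param scan A [scan_params()] object (element size range, arm length,
#'   identity, seed length).
#' @param tsd_min,tsd_max TSD length bounds in nt (defaults 2 and 10).
#' @param flank_probe Flank window used for the TSD search, nt (default 10).
#' @param tir_terminal Terminal TIR length used by the TSD fallback,
#'   nt (default 5).
#' @param flank_window Flank length retrieved per copy for the diversity
#'   test, nt (default 50).
#' @param copy_threshold Minimum full-length copies for a family
#'   (default 10).
#' @param flank_class_threshold Minimum distinct flank classes for a true
#'   family (default 3).
#' @param copy_identity_min Identity for counted copies (default 0.80).
#' @param full_length_coverage_min Query coverage for counted copies
#'   (default 0.90).
#' @param subset_max Flank pairs compared per family (default 20).
#' @param flank_identity_max Identity above which two flanks are the same
#'   context (default 0.80).
#' @param max_slice_size Slice size in nt (default 100000).
#' @param overlap Slice overlap in nt; defaults to
#'   `max_element_len + 2 * flank_window` so no element plus its flank
#'   context straddles two slices undetected.
#' @param p_miss Early-stop probability of missing a family with exactly
#'   `copy_threshold` copies, or `NULL` to scan everything.
#' @param redundancy_identity,redundancy_coverage Thresholds for
#'   [is_redundant()] (defaults 0.80 and 0.80).
#' @param low_complexity_window,entropy_threshold Parameters of
#'   [mask_low_complexity()].
#' @param seed_k Index k-mer size for copy counting (default 12).
#' @param seed_step Seed spacing along queries (default 4).
#' @param tsd_anywhere Accept a TSD anywhere within the two 10-nt flank
#'   windows instead of requiring it to abut the junctions exactly
#'   (default `TRUE`). Local arm alignment can over- or under-shoot the
#'   true element boundary by a base or two when flanking sequence
#'   happens to extend the inverted repeat, and a strictly abutting
#'   search would then miss the genuine TSD sitting a few nt from the
#'   detected junction.
#' @param workers Worker count; evaluation order and deposits are
#'   serialized in discovery order, so results are identical for any
#'   value.
#' @param rng_seed Seed recorded with the run (the pipeline itself is
#'   deterministic).
#' @return A list of class `pipeline_params`.
#' @export
pipeline_params <- function(scan = scan_params(),
                            tsd_min = 2L, tsd_max = 10L,
                            flank_probe = 10L, tir_terminal = 5L,
                            flank_window = 50L,
                            copy_threshold = 10L,
                            flank_class_threshold = 3L,
                            copy_identity_min = 0.80,
                            full_length_coverage_min = 0.90,
                            subset_max = 20L,
                            flank_identity_max = 0.80,
                            max_slice_size = 100000L,
                            overlap = NULL,
                            p_miss = NULL,
                            redundancy_identity = 0.80,
                            redundancy_coverage = 0.80,
                            low_complexity_window = 64L,
                            entropy_threshold = 1.0,
                            seed_k = 12L, seed_step = 4L,
                            tsd_anywhere = TRUE,
                            workers = 1L, rng_seed = 1L) {
  if (tsd_min < 2L || tsd_max > 10L || tsd_min > tsd_max)
    stop("need 2 <= tsd_min <= tsd_max <= 10")
  if (!is.null(p_miss) && (p_miss <= 0 || p_miss >= 1))
    stop("p_miss must lie strictly between 0 and 1")
  if (is.null(overlap)) overlap <- scan$max_element_len + 2L * flank_window
  p <- list(scan = scan, tsd_min = as.integer(tsd_min),
            tsd_max = as.integer(tsd_max),
            flank_probe = as.integer(flank_probe),
            tir_terminal = as.integer(tir_terminal),
            flank_window = as.integer(flank_window),
            copy_threshold = as.integer(copy_threshold),
            flank_class_threshold = as.integer(flank_class_threshold),
            copy_identity_min = copy_identity_min,
            full_length_coverage_min = full_length_coverage_min,
            subset_max = as.integer(subset_max),
            flank_identity_max = flank_identity_max,
            max_slice_size = as.integer(max_slice_size),
            overlap = as.integer(overlap), p_miss = p_miss,
            redundancy_identity = redundancy_identity,
            redundancy_coverage = redundancy_coverage,
            low_complexity_window = as.integer(low_complexity_window),
            entropy_threshold = entropy_threshold,
            seed_k = as.integer(seed_k), seed_step = as.integer(seed_step),
            tsd_anywhere = isTRUE(tsd_anywhere),
            workers = as.integer(workers), rng_seed = as.integer(rng_seed))
  if (p$overlap >= p$max_slice_size) stop("overlap must be < max_slice_size")
  structure(p, class = "pipeline_params")
}

#' Database fraction needed to catch an N-copy family
#'
#' Under uniform random placement of `n_copies` copies, the probability
#' that none lies in the first fraction X of the database is
#' `(1 - X)^N`; the fraction to scan so that the family is missed with
#' probability `p_miss` is therefore `X = 1 - p_miss^(1/N)`.
#'
#' @param p_miss Acceptable probability of missing the family (0, 1].
#' @param n_copies Family copy number (>= 1).
#' @return The fraction X of the database to scan.
#' @export
coverage_fraction <- function(p_miss, n_copies) {
  if (p_miss <= 0 || p_miss > 1) stop("p_miss must be in (0, 1]")
  if (n_copies < 1) stop("n_copies must be >= 1")
  1 - p_miss^(1 / n_copies)
}

#' Probability of missing an N-copy family in a scanned prefix
#'
#' Exact inverse of [coverage_fraction()]: `(1 - x)^N`.
#'
#' @param x Fraction of the database scanned, in [0, 1].
#' @param n_copies Family copy number (>= 1).
#' @return The miss probability.
#' @export
miss_probability <- function(x, n_copies) {
  if (x < 0 || x > 1) stop("x must be in [0, 1]")
  if (n_copies < 1) stop("n_copies must be >= 1")
  (1 - x)^n_copies
}

#' Early-stop point for discovery scanning
#'
#' The fraction of the database after which TIR/TSD discovery halts. Only
#' discovery is truncated: copy counting and flank retrieval always use
#' the whole database, so copy-threshold semantics do not drift with
#' `p_miss`.
#'
#' @param params A [pipeline_params()] object.
#' @return A fraction in (0, 1]; 1.0 when `p_miss` is unset.
#' @export
discovery_stop_point <- function(params) {
  if (is.null(params$p_miss)) return(1.0)
  coverage_fraction(params$p_miss, params$copy_threshold)
}

#' Mask regions of a slice matching the filter database
#'
#' Every region of the slice matching a deposited sequence at the copy
#' -counting thresholds is hard-masked, so already-known families cannot
#' re-enter discovery.
#'
#' @param slice A [genome_slice()].
#' @param filter_seqs Character vector of deposited sequences (may be
#'   empty).
#' @param params A [pipeline_params()] object.
#' @return The masked slice.
#' @export
mask_known <- function(slice, filter_seqs, params = pipeline_params()) {
  if (length(filter_seqs) == 0L) return(slice)
  sdb <- genome_db(stats::setNames(slice$residues, "slice"))
  idx <- build_kmer_index(sdb, params$seed_k)
  ivs <- list()
  for (rec in filter_seqs) {
    hits <- count_full_length_copies(
      rec, sdb, copy_identity_min = params$copy_identity_min,
      full_length_coverage_min = params$full_length_coverage_min,
      index = idx, seed_step = params$seed_step)
    for (i in seq_len(nrow(hits))) {
      ivs[[length(ivs) + 1L]] <- c(hits$start[i], hits$end[i])
    }
  }
  hard_mask(slice, ivs)
}

#' Is an element already represented in a deposit database?
#'
#' `TRUE` when the element matches an existing record at or above
#' `redundancy_identity` identity over at least `redundancy_coverage` of
#' the shorter of the two sequences. The comparison is ungapped (like
#' every similarity measure in this package): shared 12-mers between the
#' element and a record vote for a relative offset, and the best offsets
#' are verified by direct identity over the implied overlap, on both
#' strands.
#'
#' @param element_seq The element sequence.
#' @param output_seqs Character vector of deposited records.
#' @param identity_min,coverage_min Thresholds (defaults 0.80, 0.80).
#' @return Logical.
#' @export
is_redundant <- function(element_seq, output_seqs,
                         identity_min = 0.80, coverage_min = 0.80) {
  if (length(output_seqs) == 0L) return(FALSE)
  k <- 12L
  for (rec in output_seqs) {
    renc <- encode_seq(rec)
    rcodes <- rolling_codes(renc, k)
    rord <- order(rcodes, na.last = NA)
    rsort <- rcodes[rord]
    for (q in c(element_seq, reverse_complement(element_seq))) {
      qenc <- encode_seq(q)
      qcodes <- rolling_codes(qenc, k)
      qpos <- which(!is.na(qcodes))
      if (length(qpos) == 0L) next
      rng <- .lookup_range_cpp(rsort, qcodes[qpos])
      offs <- integer(0)
      for (ii in seq_along(qpos)) {
        if (rng$hi[ii] <= rng$lo[ii]) next
        offs <- c(offs, rord[(rng$lo[ii] + 1L):rng$hi[ii]] - qpos[ii])
      }
      if (length(offs) == 0L) next
      tab <- sort(table(offs), decreasing = TRUE)
      shorter <- min(nchar(q), nchar(rec))
      for (d in as.integer(names(tab))[seq_len(min(3L, length(tab)))] ) {
        # query position i aligns to record position i + d (1-based)
        i0 <- max(1L, 1L - d)
        i1 <- min(nchar(q), nchar(rec) - d)
        ov <- i1 - i0 + 1L
        if (ov < coverage_min * shorter) next
        m <- .hamming_matches_cpp(qenc[i0:i1], renc[(i0 + d):(i1 + d)])
        if (m >= identity_min * ov) return(TRUE)
      }
    }
  }
  FALSE
}

pad_flank <- function(entry_seq, from, to, width) {
  # [from, to) 0-based, clipped at entry bounds, N-padded back to width
  n <- nchar(entry_seq)
  a <- max(0L, from); b <- min(n, to)
  s <- if (b > a) substr(entry_seq, a + 1L, b) else ""
  left_pad <- a - from
  right_pad <- to - b
  paste0(strrep("N", left_pad), s, strrep("N", right_pad))
}

#' Run the MITE discovery pipeline
#'
#' Processes a genome database end to end and writes `candidates.fasta`
#' (one exemplar per family, with copy count, TSD, TIR length and source
#' locus in the header), `false.fasta` (families disqualified by shared
#' flanks), `filter.fasta` (everything deposited, used for masking),
#' `report.tsv` (progress at each deposit) and `run.log` to `out_dir`.
#' The run is deterministic given the genome and parameters.
#'
#' @param genome A FASTA path or a [genome_db()] object.
#' @param out_dir Output directory (created if needed).
#' @param params A [pipeline_params()] object.
#' @param quiet Suppress console progress (default `TRUE`).
#' @return A list of class `mite_scan_result`: `candidates`, `false`,
#'   `report` (data frames), `n_slices`, `stop_fraction`, `paths`.
#' @export
mite_scan <- function(genome, out_dir, params = pipeline_params(),
                      quiet = TRUE) {
  db <- if (inherits(genome, "mite_genome")) genome else read_fasta(genome)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    cat(line, "\n", file = log_path, sep = "", append = TRUE)
    if (!quiet) message(line)
  }
  cat("", file = log_path)

  slices <- slice_entries(db, params$max_slice_size, params$overlap)
  index <- build_kmer_index(db, params$seed_k)
  total <- db$total_length
  entry_cum <- stats::setNames(
    c(0, cumsum(nchar(db$seq)))[seq_along(db$ids)], db$ids)
  stop_fraction <- discovery_stop_point(params)
  stop_nt <- ceiling(stop_fraction * total)
  logf("mitescan: %d entries, %d nt, %d slices, discovery over %.1f%% of database",
       length(db$ids), total, length(slices), 100 * stop_fraction)

  records <- list()   # each: list(name, label, seq, header)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  progress <- list()
  n_cand <- 0L; n_false <- 0L
  t0 <- Sys.time()
  last_fraction <- 0

  filter_seqs <- function() vapply(records, `[[`, character(1), "seq")

  # exact k-mer codes (both strands) over deposited records, kept per
  # label; an element sharing no code with a set cannot be a
  # near-duplicate of any record in it, so the alignment-based redundancy
  # check can be skipped
  dep_codes <- list(candidate = numeric(0), false_family = numeric(0))
  add_dep_codes <- function(label, seq) {
    cd <- c(rolling_codes(encode_seq(seq), params$seed_k),
            rolling_codes(encode_seq(reverse_complement(seq)),
                          params$seed_k))
    dep_codes[[label]] <<- sort(unique(c(dep_codes[[label]],
                                         cd[!is.na(cd)])))
  }
  redundant_in <- function(element, label) {
    set <- dep_codes[[label]]
    if (length(set) == 0L) return(FALSE)
    cd <- rolling_codes(encode_seq(element), params$seed_k)
    cd <- cd[!is.na(cd)]
    if (length(cd) == 0L) return(FALSE)
    rng <- .lookup_range_cpp(set, cd)
    if (!any(rng$hi > rng$lo)) return(FALSE)
    labs <- vapply(records, `[[`, character(1), "label")
    is_redundant(element,
                 vapply(records, `[[`, character(1), "seq")[labs == label],
                 params$redundancy_identity, params$redundancy_coverage)
  }

  flush_outputs <- function() {
    labs <- vapply(records, `[[`, character(1), "label")
    hdr <- vapply(records, `[[`, character(1), "header")
    seqs <- vapply(records, `[[`, character(1), "seq")
    lab_hdr <- if (length(hdr)) paste0(hdr, " label=", labs) else character(0)
    write_fasta(stats::setNames(seqs[labs == "candidate"],
                                hdr[labs == "candidate"]),
                file.path(out_dir, "candidates.fasta"))
    write_fasta(stats::setNames(seqs[labs == "false_family"],
                                hdr[labs == "false_family"]),
                file.path(out_dir, "false.fasta"))
    write_fasta(stats::setNames(seqs, lab_hdr),
                file.path(out_dir, "filter.fasta"))
    write_report(progress_df(progress), file.path(out_dir, "report.tsv"))
  }

  for (sl in slices) {
    g_abs <- entry_cum[[sl$parent_id]] + sl$parent_offset
    if (g_abs >= stop_nt) break
    scan_len <- nchar(sl$residues)
    if (g_abs + scan_len > stop_nt) {
      sl$residues <- substr(sl$residues, 1L, stop_nt - g_abs)
    }
    if (nchar(sl$residues) < params$scan$min_element_len) next
    masked <- mask_known(sl, filter_seqs(), params)
    masked$residues <- mask_low_complexity(
      masked$residues, params$low_complexity_window,
      params$entropy_threshold)
    pairs <- find_inverted_repeats(masked, params$scan)
    if (nrow(pairs) == 0L) next
    # strongest signature first: the clean TIR pair at a locus deposits
    # before weaker overlapping artifacts, which the redundancy check
    # then suppresses
    arm_score <- round(pairs$arm_len * pairs$arm_identity) -
      params$scan$mismatch_penalty *
      (pairs$arm_len - round(pairs$arm_len * pairs$arm_identity))
    pairs <- pairs[order(-arm_score, pairs$left_start, pairs$right_end), ,
                   drop = FALSE]
    entry_seq <- db$seq[[sl$parent_id]]

    for (i in seq_len(nrow(pairs))) {
      gstart <- sl$parent_offset + pairs$left_start[i]
      gend <- sl$parent_offset + pairs$right_end[i]
      key <- sprintf("%s:%d-%d", sl$parent_id, gstart, gend)
      if (!is.null(seen[[key]])) next
      assign(key, TRUE, envir = seen)

      lf <- pad_flank(entry_seq, gstart - params$flank_probe, gstart,
                      params$flank_probe)
      rf <- pad_flank(entry_seq, gend, gend + params$flank_probe,
                      params$flank_probe)
      head5 <- substr(entry_seq, gstart + 1L, gstart + params$tir_terminal)
      tail5 <- substr(entry_seq, gend - params$tir_terminal + 1L, gend)
      tsd <- find_tsd_with_fallback(lf, rf, head5, tail5,
                                    params$tsd_min, params$tsd_max,
                                    anywhere = params$tsd_anywhere)
      if (is.null(tsd)) next
      element <- substr(entry_seq, gstart + 1L, gend)

      # a sequence already represented in the output is not deposited
      # again (the genome-wide mask removes most later copies; this
      # catches copies inside the slice where the family was first found)
      if (redundant_in(element, "candidate")) next

      ev <- evaluate_candidate(element, db, params, index)
      if (ev$verdict == "below_copy_threshold") next
      if (ev$verdict == "false_family" &&
          redundant_in(element, "false_family")) next

      if (ev$verdict == "candidate") {
        n_cand <- n_cand + 1L
        name <- sprintf("MD_%d", n_cand)
      } else {
        n_false <- n_false + 1L
        name <- sprintf("MDF_%d", n_false)
      }
      header <- sprintf(
        "%s len=%d tir=%d tsd=%s copies=%d flank_classes=%d locus=%s:%d-%d",
        name, nchar(element), pairs$arm_len[i], tsd$sequence,
        ev$copy_count, ev$distinct_flank_count,
        sl$parent_id, gstart + 1L, gend)
      records[[length(records) + 1L]] <- list(
        name = name, label = ev$verdict, seq = element, header = header)
      add_dep_codes(ev$verdict, element)
      elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
      fraction <- min(1, (entry_cum[[sl$parent_id]] + gend) / total)
      fraction <- max(fraction, last_fraction)
      last_fraction <- fraction
      progress[[length(progress) + 1L]] <- data.frame(
        fraction_processed = fraction, n_candidates = n_cand,
        n_false = n_false, elapsed_s = elapsed,
        rate_per_hour = if (elapsed > 0) fraction / elapsed * 3600 else NA_real_,
        predicted_remaining_s = if (fraction > 0)
          elapsed * (1 - fraction) / fraction else NA_real_)
      logf("deposit %s (%s): %d nt, %d copies, %s flank classes at %s:%d-%d",
           name, ev$verdict, nchar(element), ev$copy_count,
           ev$distinct_flank_count, sl$parent_id, gstart + 1L, gend)
      flush_outputs()
    }
    writeLines(as.character(sl$slice_index), file.path(out_dir, "state.txt"))
  }
  flush_outputs()
  logf("done: %d candidates, %d false families", n_cand, n_false)

  labs <- vapply(records, `[[`, character(1), "label")
  result <- list(
    candidates = records_df(records[labs == "candidate"]),
    false = records_df(records[labs == "false_family"]),
    report = progress_df(progress),
    n_slices = length(slices),
    stop_fraction = stop_fraction,
    paths = list(
      candidates = file.path(out_dir, "candidates.fasta"),
      false = file.path(out_dir, "false.fasta"),
      filter = file.path(out_dir, "filter.fasta"),
      report = file.path(out_dir, "report.tsv"),
      log = log_path))
  structure(result, class = "mite_scan_result")
}

records_df <- function(records) {
  if (length(records) == 0L) {
    return(data.frame(name = character(), header = character(),
                      seq = character()))
  }
  data.frame(name = vapply(records, `[[`, character(1), "name"),
             header = vapply(records, `[[`, character(1), "header"),
             seq = vapply(records, `[[`, character(1), "seq"))
}

progress_df <- function(progress) {
  if (length(progress) == 0L) {
    return(data.frame(fraction_processed = numeric(),
                      n_candidates = integer(), n_false = integer(),
                      elapsed_s = numeric(), rate_per_hour = numeric(),
                      predicted_remaining_s = numeric()))
  }
  do.call(rbind, progress)
}

#' @export
print.mite_scan_result <- function(x, ...) {
  cat(sprintf("mite_scan_result: %d candidate families, %d false families\n",
              nrow(x$candidates), nrow(x$false)))
  cat(sprintf("  discovery over %.1f%% of the database, %d slices\n",
              100 * x$stop_fraction, x$n_slices))
  invisible(x)
}

#' Write a progress report
#'
#' Tab-separated, one row per deposit, with the processed fraction, the
#' running candidate and false counts, elapsed time, the cumulative
#' processing rate and the predicted remaining time (cumulative-average
#' estimator).
#'
#' @param records A data frame of progress records (may be empty).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(records, path) {
  cols <- c("fraction_processed", "n_candidates", "n_false", "elapsed_s",
            "rate_per_hour", "predicted_remaining_s")
  if (nrow(records) == 0L) {
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  utils::write.table(records[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
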