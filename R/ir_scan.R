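# Terminal-inverted-repeat detection.
#
# An IR pair is an ungapped alignment of a left arm against the reverse
# complement of a right arm within the same window of genome. All arm
# placements pairing position p with position q live on the anti-diagonal
# c = p + q, which makes exhaustive enumeration (the test oracle) and
# seeded scanning directly comparable.

#' Scan parameter set
#'
#' Parameters controlling inverted-repeat detection. `sensitivity` maps to
#' the exact-match seed length used to anchor arm alignments: shorter seeds
#' find more diverged arms at higher cost (`"high"` = 6 nt, `"medium"` =
#' 8 nt, `"low"` = 10 nt). An explicit `seed_len` overrides the mapping.
#' Every reported arm must contain at least one exact match run of
#' `seed_len`, which is part of the acceptance contract (and what makes
#' seeded scanning exhaustive).
#'
#' @param min_element_len Minimum element length in nt (default 50).
#' @param max_element_len Maximum element length in nt (default 800).
#' @param min_arm_len Minimum TIR arm length in nt (default 10).
#' @param min_arm_identity Minimum arm identity fraction (default 0.80).
#' @param seed_len Exact seed length in nt (default from `sensitivity`).
#' @param mismatch_penalty Scoring penalty per mismatch relative to a
#'   match score of 1 (default 3). Among overlapping acceptable windows
#'   on an anti-diagonal the score-maximal one is reported, which stops
#'   arms at the TIR boundary instead of letting a clean arm drift into
#'   flanking sequence on its banked identity budget.
#' @param sensitivity One of `"low"`, `"medium"`, `"high"`.
#' @return A list of class `scan_params`.
#' @export
scan_params <- function(min_element_len = 50L, max_element_len = 800L,
                        min_arm_len = 10L, min_arm_identity = 0.80,
                        seed_len = NULL, mismatch_penalty = 3L,
                        sensitivity = c("medium", "low", "high")) {
  sensitivity <- match.arg(sensitivity)
  if (is.null(seed_len)) {
    seed_len <- c(low = 10L, medium = 8L, high = 6L)[[sensitivity]]
  }
  p <- list(min_element_len = as.integer(min_element_len),
            max_element_len = as.integer(max_element_len),
            min_arm_len = as.integer(min_arm_len),
            min_arm_identity = as.numeric(min_arm_identity),
            seed_len = as.integer(seed_len),
            mismatch_penalty = as.integer(mismatch_penalty),
            sensitivity = sensitivity)
  if (p$min_element_len <= 0L || p$min_element_len >= p$max_element_len)
    stop("need 0 < min_element_len < max_element_len")
  if (2L * p$min_arm_len > p$min_element_len)
    stop("need 2 * min_arm_len <= min_element_len")
  if (p$min_arm_identity <= 0 || p$min_arm_identity > 1)
    stop("min_arm_identity must be in (0, 1]")
  if (p$seed_len < 4L || p$seed_len > 10L)
    stop("seed_len must be between 4 and 10")
  if (p$seed_len > p$min_arm_len)
    stop("seed_len must not exceed min_arm_len")
  if (p$mismatch_penalty < 1L)
    stop("mismatch_penalty must be >= 1")
  structure(p, class = "scan_params")
}

empty_ir <- function() {
  data.frame(left_start = integer(), left_end = integer(),
             right_start = integer(), right_end = integer(),
             arm_len = integer(), arm_identity = numeric())
}

slice_residues <- function(slice) {
  if (inherits(slice, "genome_slice")) slice$residues else as.character(slice)
}

#' Find candidate terminal-inverted-repeat pairs
#'
#' Detects all accepted arm pairs in a slice by exact-seed anchoring
#' against the reverse complement followed by maximal window selection on
#' each anti-diagonal, then removes arms that are simple repeats
#' ([is_simple_arm()]). Coordinates are 0-based half-open within the
#' slice; rows are ordered by `(left_start, right_end)`.
#'
#' @param slice A [genome_slice()] or a plain nucleotide string.
#' @param params A [scan_params()] object.
#' @return A data frame with columns `left_start`, `left_end`,
#'   `right_start`, `right_end`, `arm_len`, `arm_identity`.
#' @export
find_inverted_repeats <- function(slice, params = scan_params()) {
  seq <- slice_residues(slice)
  if (nchar(seq) < params$min_element_len) return(empty_ir())
  codes <- encode_seq(seq)
  hits <- .ir_scan_cpp(codes, params$min_element_len, params$max_element_len,
                       params$min_arm_len, params$min_arm_identity,
                       params$seed_len, params$mismatch_penalty)
  finalize_ir(hits, seq)
}

# shared tail of both IR engines: simple-arm filter + canonical ordering
finalize_ir <- function(hits, seq) {
  if (nrow(hits) == 0L) return(empty_ir())
  left <- substr(rep(seq, nrow(hits)), hits$left_start + 1L, hits$left_end)
  right <- substr(rep(seq, nrow(hits)), hits$right_start + 1L, hits$right_end)
  keep <- !vapply(left, is_simple_arm, logical(1), USE.NAMES = FALSE) &
    !vapply(right, is_simple_arm, logical(1), USE.NAMES = FALSE)
  hits <- hits[keep, , drop = FALSE]
  hits <- hits[order(hits$left_start, hits$right_end), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Exhaustive inverted-repeat oracle
#'
#' Enumerates every arm placement `(a, b)` on every anti-diagonal of a
#' short sequence directly, applies the same acceptance rules as
#' [find_inverted_repeats()] (identity, exact-seed content, element-length
#' and overlap geometry, per-diagonal maximality and tie-breaking, simple
#' -arm rejection), and returns the accepted set. Intended as ground truth
#' in tests; refuses inputs above 2000 nt.
#'
#' @inheritParams find_inverted_repeats
#' @return A data frame in the same shape as [find_inverted_repeats()].
#' @export
brute_force_ir <- function(slice, params = scan_params()) {
  seq <- slice_residues(slice)
  n <- nchar(seq)
  if (n > 2000L) stop("brute_force_ir is limited to sequences of <= 2000 nt")
  if (n < params$min_element_len) return(empty_ir())
  s <- encode_seq(seq)
  K <- params$seed_len
  t_id <- params$min_arm_identity
  res <- vector("list", 2L * n)
  ri <- 0L

  for (c in seq.int(1L, 2L * n - 2L)) {
    p_hi <- (c - 1L) %/% 2L
    p_lo <- max(0L, c - n + 1L,
                as.integer(ceiling((c + 1L - params$max_element_len) / 2)))
    a_hi <- (c + 1L - params$min_element_len) %/% 2L
    k <- p_hi - p_lo + 1L
    if (k < params$min_arm_len || a_hi < p_lo) next
    p <- p_lo:p_hi
    xp <- s[p + 1L]
    xq <- s[c - p + 1L]
    st <- ifelse(xp > 3L | xq > 3L, 2L, ifelse(xp == 3L - xq, 1L, 0L))
    is_m <- st == 1L
    r <- rle(is_m)
    if (!any(r$values & r$lengths >= K)) next
    runend <- cumsum(r$lengths)
    seed_t <- integer(0)
    for (j in which(r$values & r$lengths >= K)) {
      seed_t <- c(seed_t, (runend[j] - r$lengths[j] + K):runend[j])
    }
    mis <- cumsum(st == 0L)
    forb <- cumsum(st == 2L)
    mis0 <- c(0L, mis)
    forb0 <- c(0L, forb)
    ta_all <- which(is_m & p <= a_hi)
    tb_all <- which(is_m)
    if (length(ta_all) == 0L || length(tb_all) == 0L) next

    # all placements at once
    len <- outer(ta_all, tb_all, function(a, b) b - a + 1L)
    mism <- outer(ta_all, tb_all, function(a, b) mis[b] - mis0[a])
    forbn <- outer(ta_all, tb_all, function(a, b) forb[b] - forb0[a])
    # window must contain a K-run starting at or after a + K - 1
    next_seed <- vapply(ta_all, function(a) {
      ok <- seed_t[seed_t >= a + K - 1L]
      if (length(ok)) min(ok) else .Machine$integer.max
    }, integer(1))
    has_seed <- outer(next_seed, tb_all, function(ns, b) b >= ns)
    valid <- len >= params$min_arm_len & forbn == 0L & has_seed &
      (len - mism) >= ceiling(t_id * len - 1e-9)
    if (!any(valid)) next
    vi <- which(valid, arr.ind = TRUE)
    wa <- ta_all[vi[, 1L]]
    wb <- tb_all[vi[, 2L]]
    wlen <- wb - wa + 1L
    wmatch <- wlen - (mis[wb] - mis0[wa])
    wscore <- wmatch - params$mismatch_penalty * (wlen - wmatch)
    o <- order(wa, wb)
    wa <- wa[o]; wb <- wb[o]
    wlen <- wlen[o]; wmatch <- wmatch[o]; wscore <- wscore[o]

    # group all accepted windows by transitive overlap; report the
    # score-best window of each group
    i <- 1L
    while (i <= length(wa)) {
      j <- i
      gmax <- wb[i]
      while (j + 1L <= length(wa) && wa[j + 1L] <= gmax) {
        j <- j + 1L
        gmax <- max(gmax, wb[j])
      }
      grp <- i:j
      best <- grp[order(-wscore[grp], -wlen[grp], -wa[grp])][1L]
      a <- p_lo + wa[best] - 1L
      b <- p_lo + wb[best] - 1L
      ri <- ri + 1L
      res[[ri]] <- data.frame(
        left_start = a, left_end = b + 1L,
        right_start = c - b, right_end = c - a + 1L,
        arm_len = wlen[best], arm_identity = wmatch[best] / wlen[best])
      i <- j + 1L
    }
  }
  if (ri == 0L) return(empty_ir())
  finalize_ir(do.call(rbind, res[seq_len(ri)]), seq)
}

#' Is an arm a simple repeat?
#'
#' Simple inverted repeats are excluded from candidacy: arms drawn only
#' from `{G,C}` or only from `{A,T}`, and mono- or dinucleotide runs
#' (perfect period-2 repeats, allowing a trailing partial period). Arms
#' containing `N` are treated as unusable.
#'
#' @param arm_seq A non-empty nucleotide string.
#' @return `TRUE` if the arm is simple (to be rejected).
#' @export
is_simple_arm <- function(arm_seq) {
  if (grepl("N", arm_seq, fixed = TRUE)) return(TRUE)
  chars <- strsplit(arm_seq, "", fixed = TRUE)[[1L]]
  u <- unique(chars)
  if (all(u %in% c("G", "C"))) return(TRUE)
  if (all(u %in% c("A", "T"))) return(TRUE)
  L <- length(chars)
  if (L <= 2L) return(TRUE)
  all(chars[3:L] == chars[1:(L - 2L)])
}

#' Mask low-complexity regions
#'
#' Replaces by `N` every position covered by a sliding window whose
#' mononucleotide Shannon entropy falls below `entropy_threshold`.
#' Removing low-complexity sequence before scanning eliminates false TIR
#' and TSD motifs that such regions generate in abundance.
#'
#' @param seq A nucleotide string.
#' @param window Window size in nt (default 64; sequences shorter than the
#'   window are scored as a single window).
#' @param entropy_threshold Entropy threshold in bits (default 1.0).
#' @return The masked string (same length).
#' @export
mask_low_complexity <- function(seq, window = 64L, entropy_threshold = 1.0) {
  if (window < 4L) stop("window must be >= 4")
  n <- nchar(seq)
  if (n == 0L) return(seq)
  codes <- encode_seq(seq)
  w <- min(window, n)
  ind <- vapply(0:3, function(b) cumsum(codes == b), numeric(n))
  starts <- 1:(n - w + 1L)
  counts <- ind[starts + w - 1L, , drop = FALSE] -
    rbind(0, ind, deparse.level = 0)[starts, , drop = FALSE]
  tot <- rowSums(counts)
  H <- numeric(length(starts))
  pos <- tot > 0
  if (any(pos)) {
    fr <- counts[pos, , drop = FALSE] / tot[pos]
    H[pos] <- -rowSums(ifelse(fr > 0, fr * log2(fr), 0))
  }
  low <- which(H < entropy_threshold)
  if (length(low) == 0L) return(seq)
  mask <- logical(n)
  for (s0 in low) mask[s0:(s0 + w - 1L)] <- TRUE
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  chars[mask] <- "N"
  paste(chars, collapse = "")
}
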