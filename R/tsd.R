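# Target site duplication detection.
#
# A TSD is the 2-10 nt direct repeat created on both sides of an element
# at integration. The primary search compares the 10-nt flanks abutting
# the element junctions; if nothing is found there, the most terminal 5 nt
# of the TIRs themselves are searched, because for some superfamilies
# (Stowaway, PiggyBac) the duplicated site is carried inside the TIR ends.

tsd_match <- function(sequence, source, left_end_offset, right_start_offset) {
  list(sequence = sequence, length = nchar(sequence), source = source,
       left_end_offset = as.integer(left_end_offset),
       right_start_offset = as.integer(right_start_offset))
}

#' Find a target site duplication in the element flanks
#'
#' Looks for the longest direct repeat of 2-10 nt that terminates at the
#' right end of `left_flank` and begins at the left start of `right_flank`
#' (i.e. abuts both element junctions, which is where integration creates
#' the duplication). With `anywhere = TRUE` the repeat may sit anywhere in
#' the two windows; ties then go to the placement closest to the
#' junctions, then to the lexicographically smallest sequence.
#'
#' @param left_flank The 10 nt immediately left of the element (pad with
#'   `N` at a sequence end).
#' @param right_flank The 10 nt immediately right of the element.
#' @param tsd_min,tsd_max Length bounds (defaults 2 and 10).
#' @param anywhere Relax the abutting requirement (default `FALSE`).
#' @return A TSD match (list with `sequence`, `length`, `source`,
#'   `left_end_offset`, `right_start_offset`) or `NULL`. Offsets count nt
#'   between the repeat copy and its junction (0 when abutting).
#' @export
find_tsd <- function(left_flank, right_flank, tsd_min = 2L, tsd_max = 10L,
                     anywhere = FALSE) {
  nl <- nchar(left_flank)
  nr <- nchar(right_flank)
  top <- min(tsd_max, nl, nr)
  if (top < tsd_min) return(NULL)
  if (!anywhere) {
    for (L in seq.int(top, tsd_min)) {
      a <- substr(left_flank, nl - L + 1L, nl)
      b <- substr(right_flank, 1L, L)
      if (a == b && !grepl("N", a, fixed = TRUE)) {
        return(tsd_match(a, "flank", 0L, 0L))
      }
    }
    return(NULL)
  }
  best <- NULL
  for (L in seq.int(top, tsd_min)) {
    for (i in seq.int(nl - L + 1L, 1L)) {      # prefer junction-proximal left
      a <- substr(left_flank, i, i + L - 1L)
      if (grepl("N", a, fixed = TRUE)) next
      for (j in seq.int(1L, nr - L + 1L)) {    # prefer junction-proximal right
        if (substr(right_flank, j, j + L - 1L) != a) next
        cand <- tsd_match(a, "flank", nl - (i + L - 1L), j - 1L)
        if (is.null(best)) { best <- cand; next }
        d_new <- cand$left_end_offset + cand$right_start_offset
        d_old <- best$left_end_offset + best$right_start_offset
        if (d_new < d_old ||
            (d_new == d_old && cand$sequence < best$sequence)) best <- cand
      }
    }
    if (!is.null(best)) return(best)  # longest length wins outright
  }
  NULL
}

#' Find a TSD with the TIR-terminal fallback
#'
#' First runs [find_tsd()] on the flanks; if that fails, searches the most
#' terminal 5 nt of the two TIRs for a direct repeat anchored at the
#' element termini -- one copy a prefix of the left TIR head, the other a
#' suffix of the right TIR tail. Matches found this way carry
#' `source = "tir_terminal"`.
#'
#' @inheritParams find_tsd
#' @param left_tir_head First 5 nt of the left arm (element start).
#' @param right_tir_tail Last 5 nt of the right arm (element end).
#' @return A TSD match or `NULL`.
#' @export
find_tsd_with_fallback <- function(left_flank, right_flank,
                                   left_tir_head, right_tir_tail,
                                   tsd_min = 2L, tsd_max = 10L,
                                   anywhere = FALSE) {
  hit <- find_tsd(left_flank, right_flank, tsd_min, tsd_max, anywhere)
  if (!is.null(hit)) return(hit)
  nh <- nchar(left_tir_head)
  nt <- nchar(right_tir_tail)
  top <- min(tsd_max, nh, nt)
  if (top < tsd_min) return(NULL)
  for (L in seq.int(top, tsd_min)) {
    a <- substr(left_tir_head, 1L, L)
    b <- substr(right_tir_tail, nt - L + 1L, nt)
    if (a == b && !grepl("N", a, fixed = TRUE)) {
      return(tsd_match(a, "tir_terminal", 0L, 0L))
    }
  }
  NULL
}
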