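# Genome containers, FASTA I/O, slicing and hard masking.
#
# Coordinates are 0-based half-open everywhere inside the package; the
# pipeline converts to 1-based inclusive only when writing human-readable
# output (FASTA headers, BED-like truth tables).

#' Construct a genome database
#'
#' A `mite_genome` holds an ordered set of named sequences, normalized to
#' the alphabet `{A,C,G,T,N}`: lowercase is uppercased and any other
#' character (IUPAC ambiguity codes, gaps) becomes `N`. `N` never takes
#' part in a reported TIR or TSD, so ambiguity codes cannot seed spurious
#' structure.
#'
#' @param seqs Character vector of sequences, named by entry id.
#' @param desc Optional character vector of descriptions (same length).
#' @return An object of class `mite_genome` with elements `ids`, `desc`,
#'   `seq` (named character vector) and `total_length`.
#' @export
genome_db <- function(seqs, desc = NULL) {
  if (length(seqs) == 0L) stop("genome database must contain at least one entry")
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) stop("all entries must be named")
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    stop("duplicate entry id: ", dup)
  }
  seqs <- vapply(unname(seqs), normalize_residues, character(1))
  if (any(nchar(seqs) < 1L)) stop("empty sequence entry")
  names(seqs) <- ids
  if (is.null(desc)) desc <- rep("", length(seqs))
  structure(
    list(ids = ids, desc = desc, seq = seqs,
         total_length = sum(nchar(seqs))),
    class = "mite_genome"
  )
}

#' @export
print.mite_genome <- function(x, ...) {
  cat(sprintf("mite_genome: %d entries, %s nt total\n",
              length(x$ids), format(x$total_length, big.mark = ",")))
  n <- min(length(x$ids), 6L)
  for (i in seq_len(n)) {
    cat(sprintf("  %s (%s nt)\n", x$ids[i],
                format(nchar(x$seq[[i]]), big.mark = ",")))
  }
  if (length(x$ids) > n) cat(sprintf("  ... and %d more\n", length(x$ids) - n))
  invisible(x)
}

#' Normalize residues to the {A,C,G,T,N} alphabet
#'
#' @param seq A single character string.
#' @return The normalized string: uppercased, all non-ACGT characters
#'   replaced by `N`.
#' @export
normalize_residues <- function(seq) {
  seq <- toupper(seq)
  gsub("[^ACGT]", "N", seq)
}

#' Read a genome database from a FASTA file
#'
#' Entries are returned in file order with residues normalized (see
#' [normalize_residues()]). Duplicate ids and empty files are rejected.
#'
#' @param path Path to a FASTA file.
#' @return A [genome_db()] object.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  full <- names(set)
  ids <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  seqs <- as.character(set)
  names(seqs) <- ids
  genome_db(seqs, desc)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences (names become headers,
#'   and may contain spaces and `key=value` annotations).
#' @param path Output path.
#' @param width Line width (default 60).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  nm <- names(seqs)
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", nm[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    if (n == 0L) next
    starts <- seq.int(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Create a genome slice
#'
#' @param parent_id Id of the parent database entry.
#' @param parent_offset 0-based offset of the slice start in the parent.
#' @param residues Slice sequence.
#' @param slice_index Ordinal of the slice within the whole run.
#' @return An object of class `genome_slice`.
#' @export
genome_slice <- function(parent_id, parent_offset, residues, slice_index = 0L) {
  structure(
    list(parent_id = parent_id, parent_offset = as.integer(parent_offset),
         residues = residues, slice_index = as.integer(slice_index)),
    class = "genome_slice"
  )
}

#' Slice database entries into bounded overlapping windows
#'
#' Entries longer than `max_slice_size` are cut into windows that advance
#' by `max_slice_size - overlap`, so that every element of up to
#' `max_element_len` nt, together with its 50-nt flank context, lies
#' entirely inside at least one window. Candidates discovered twice inside
#' an overlap are deduplicated downstream by their global span.
#'
#' @param db A [genome_db()] object.
#' @param max_slice_size Maximum window size in nt (default 100000).
#' @param overlap Overlap between consecutive windows in nt (default 900 =
#'   800 nt maximum element + 2 x 50 nt flank window).
#' @return A list of [genome_slice()] objects in database order.
#' @export
slice_entries <- function(db, max_slice_size = 100000L, overlap = 900L) {
  stopifnot(inherits(db, "mite_genome"))
  max_slice_size <- as.integer(max_slice_size)
  overlap <- as.integer(overlap)
  if (overlap >= max_slice_size) {
    stop("overlap (", overlap, ") must be smaller than max_slice_size (",
         max_slice_size, ")")
  }
  step <- max_slice_size - overlap
  out <- list()
  k <- 0L
  for (i in seq_along(db$ids)) {
    s <- db$seq[[i]]
    n <- nchar(s)
    if (n <= max_slice_size) {
      k <- k + 1L
      out[[k]] <- genome_slice(db$ids[i], 0L, s, k)
      next
    }
    start <- 0L
    repeat {
      end <- min(start + max_slice_size, n)
      k <- k + 1L
      out[[k]] <- genome_slice(db$ids[i], start, substr(s, start + 1L, end), k)
      if (end >= n) break
      start <- start + step
    }
  }
  out
}

#' Reverse complement of a nucleotide string
#'
#' Standard Watson-Crick complement, reversed; `N` maps to `N`.
#'
#' @param seq A string over `{A,C,G,T,N}`.
#' @return The reverse complement string.
#' @export
reverse_complement <- function(seq) {
  if (grepl("[^ACGTN]", seq)) stop("invalid character in sequence")
  comp <- chartr("ACGTN", "TGCAN", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Hard-mask intervals of a slice
#'
#' Residues inside the given 0-based half-open intervals are replaced by
#' `N`; length and coordinates are unchanged.
#'
#' @param slice A [genome_slice()].
#' @param intervals A list of `c(start, end)` pairs, or a 2-column matrix,
#'   0-based half-open, within slice bounds.
#' @return The masked slice.
#' @export
hard_mask <- function(slice, intervals) {
  stopifnot(inherits(slice, "genome_slice"))
  if (is.matrix(intervals)) {
    intervals <- lapply(seq_len(nrow(intervals)), function(i) intervals[i, ])
  }
  if (length(intervals) == 0L) return(slice)
  n <- nchar(slice$residues)
  chars <- strsplit(slice$residues, "", fixed = TRUE)[[1L]]
  for (iv in intervals) {
    a <- iv[[1L]]; b <- iv[[2L]]
    if (a < 0L || b > n || a > b) {
      stop("mask interval [", a, ",", b, ") out of slice bounds [0,", n, ")")
    }
    if (b > a) chars[(a + 1L):b] <- "N"
  }
  slice$residues <- paste(chars, collapse = "")
  slice
}

# Integer encoding used throughout: A=0, C=1, G=2, T=3, N=4.
encode_seq <- function(seq) {
  x <- utf8ToInt(seq)
  out <- integer(length(x))
  out[x == 65L] <- 0L  # A
  out[x == 67L] <- 1L  # C
  out[x == 71L] <- 2L  # G
  out[x == 84L] <- 3L  # T
  out[x == 78L] <- 4L  # N
  out
}

decode_seq <- function(codes) {
  intToUtf8(c(65L, 67L, 71L, 84L, 78L)[codes + 1L])
}
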