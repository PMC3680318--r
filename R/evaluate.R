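# Scoring pipeline output against simulator truth.

#' Write simulator truth to plain-text files
#'
#' `truth.bed` holds one BED6+3 row per planted copy (1000 x identity in
#' the score column, then family id, TSD and kind); `families.tsv` holds
#' the per-family table including consensus sequences.
#'
#' @param sim A `mite_simulation` from [simulate_genome()].
#' @param dir Output directory.
#' @return Invisibly, the two paths.
#' @export
write_truth <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bed <- file.path(dir, "truth.bed")
  tr <- sim$truth
  utils::write.table(
    data.frame(tr$entry_id, tr$start, tr$end, tr$flank_context_id,
               round(1000 * tr$identity), tr$strand, tr$family_id,
               tr$tsd, tr$kind),
    bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- file.path(dir, "families.tsv")
  utils::write.table(sim$families, fam, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(bed = bed, families = fam))
}

#' Read simulator truth back from files
#'
#' @param dir Directory written by [write_truth()].
#' @return A list with `truth` and `families` data frames.
#' @export
read_truth <- function(dir) {
  bed <- utils::read.table(file.path(dir, "truth.bed"), sep = "\t",
                           stringsAsFactors = FALSE)
  names(bed) <- c("entry_id", "start", "end", "flank_context_id", "score",
                  "strand", "family_id", "tsd", "kind")
  fam <- utils::read.table(file.path(dir, "families.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  list(truth = bed, families = fam)
}

# does `query` match `target` at >= identity over >= cov_min of the
# shorter sequence (local alignment)?
seq_matches <- function(query, target, identity_min, cov_min = 0.80) {
  shorter <- min(nchar(query), nchar(target))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  aln <- Biostrings::pairwiseAlignment(
    query, target, type = "local", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 2)
  al <- Biostrings::nchar(aln)
  if (al == 0L) return(FALSE)
  ident <- Biostrings::nmatch(aln) / al
  cov <- min(Biostrings::width(Biostrings::pattern(aln)),
             Biostrings::width(Biostrings::subject(aln))) / shorter
  ident >= identity_min && cov >= cov_min
}

#' Score pipeline output against the planted truth
#'
#' A planted true family is recovered when some candidate record matches
#' its consensus at `match_identity` identity or better over at least 80%
#' of the shorter sequence. Precision counts the candidates that match
#' any planted true family; leakage counts planted false families with a
#' record among the candidates.
#'
#' @param candidates_path Path to `candidates.fasta` from [mite_scan()].
#' @param false_path Path to `false.fasta`.
#' @param families Per-family truth table (from [simulate_genome()]'s
#'   `families` element or [read_truth()]).
#' @param match_identity Identity threshold for a match (default 0.90).
#' @return A list: `recall`, `precision`, `false_family_leakage`,
#'   `n_candidates`, `recovered` (named logical over true families),
#'   `false_in_false_output` (named logical over false families).
#' @export
evaluate_output <- function(candidates_path, false_path, families,
                            match_identity = 0.90) {
  cand <- if (file.exists(candidates_path) &&
              file.size(candidates_path) > 0) {
    tryCatch(read_fasta(candidates_path)$seq, error = function(e) character(0))
  } else character(0)
  fals <- if (file.exists(false_path) && file.size(false_path) > 0) {
    tryCatch(read_fasta(false_path)$seq, error = function(e) character(0))
  } else character(0)

  true_fam <- families[families$kind == "true_mite", , drop = FALSE]
  false_fam <- families[families$kind == "false_retro_like", , drop = FALSE]

  recovered <- vapply(true_fam$consensus, function(cons) {
    any(vapply(cand, seq_matches, logical(1), target = cons,
               identity_min = match_identity))
  }, logical(1))
  names(recovered) <- true_fam$family_id

  matching_cand <- vapply(cand, function(x) {
    any(vapply(true_fam$consensus, seq_matches, logical(1), query = x,
               identity_min = match_identity))
  }, logical(1))

  leakage <- vapply(false_fam$consensus, function(cons) {
    any(vapply(cand, seq_matches, logical(1), target = cons,
               identity_min = match_identity))
  }, logical(1))
  names(leakage) <- false_fam$family_id

  in_false <- vapply(false_fam$consensus, function(cons) {
    any(vapply(fals, seq_matches, logical(1), target = cons,
               identity_min = match_identity))
  }, logical(1))
  names(in_false) <- false_fam$family_id

  list(recall = if (nrow(true_fam)) mean(recovered) else NA_real_,
       precision = if (length(cand)) mean(matching_cand) else NA_real_,
       false_family_leakage = sum(leakage),
       n_candidates = length(cand),
       recovered = recovered,
       false_in_false_output = in_false)
}
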