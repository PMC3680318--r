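# The 2-Mb recovery scenario is used by several acceptance checks; run it
# once per test session and cache the results.

.scenario_cache <- new.env(parent = emptyenv())

recovery_scenario <- function() {
  if (!is.null(.scenario_cache$run)) return(.scenario_cache$run)
  sim <- simulate_genome(seed = 101)
  out <- file.path(tempdir(), "mitescan-acceptance-run")
  res <- mite_scan(sim$db, out, pipeline_params(), quiet = TRUE)
  ev <- evaluate_output(res$paths$candidates, res$paths$false, sim$families)
  .scenario_cache$run <- list(sim = sim, res = res, ev = ev)
  .scenario_cache$run
}

# candidate records matching a consensus at >= 0.90 identity over >= 0.80
# of the shorter sequence (local alignment, independent of the pipeline's
# own ungapped machinery)
n_matching_records <- function(seqs, consensus) {
  sum(vapply(seqs, function(x)
    mitescan:::seq_matches(x, consensus, 0.90), logical(1)))
}
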