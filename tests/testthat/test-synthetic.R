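test_that("make_background honors size, GC content and determinism", {
  db <- make_background(100000L, 4L, 0.43, seed = 7)
  expect_length(db$ids, 4L)
  expect_equal(db$total_length, 100000L)
  gc <- sum(vapply(db$seq, function(s)
    sum(strsplit(s, "")[[1]] %in% c("G", "C")), numeric(1))) / 100000
  expect_lt(abs(gc - 0.43), 0.01)

  at_only <- make_background(5000L, 1L, 0, seed = 8)
  expect_false(grepl("[GC]", at_only$seq[[1]]))

  expect_identical(make_background(20000L, 2L, 0.5, seed = 9),
                   make_background(20000L, 2L, 0.5, seed = 9))
})

test_that("make_mite_consensus builds a detectable TIR structure", {
  sp <- family_spec("f", 200L, 12L, 3L, 10L, 0, "true_mite")
  cons <- make_mite_consensus(sp, seed = 60)
  expect_equal(nchar(cons), 200L)
  expect_equal(substr(cons, 1, 12),
               reverse_complement(substr(cons, 189, 200)))
  hits <- find_inverted_repeats(cons)
  expect_gte(nrow(hits), 1L)
  expect_gte(max(hits$arm_len), 12L)

  # the structural invariant is enforced at spec construction
  expect_error(family_spec("bad", 50L, 25L, 3L, 10L, 0, "true_mite"),
               "tir_len")
  # different seeds give different interiors, same structure
  cons2 <- make_mite_consensus(sp, seed = 61)
  expect_false(cons == cons2)
})

test_that("plant_family creates true TSD semantics and exact truth", {
  sp <- family_spec("f", 150L, 14L, 4L, 12L, 0, "true_mite")
  cons <- make_mite_consensus(sp, seed = 62)
  db <- make_background(80000L, 2L, 0.5, seed = 63)
  pl <- plant_family(db, cons, sp, seed = 64)

  expect_equal(nrow(pl$truth), 12L)
  expect_equal(nrow(count_full_length_copies(cons, pl$db)), 12L)
  for (i in seq_len(nrow(pl$truth))) {
    tr <- pl$truth[i, ]
    s <- pl$db$seq[[tr$entry_id]]
    # extraction at truth coordinates returns the planted copy exactly
    expect_equal(substr(s, tr$start + 1, tr$end), cons)
    # the flank-source TSD at each locus is the recorded target site
    lf <- substr(s, tr$start - 9, tr$start)
    rf <- substr(s, tr$end + 1, tr$end + 10)
    hit <- find_tsd(lf, rf)
    expect_false(is.null(hit))
    expect_gte(hit$length, sp$tsd_len)
    expect_equal(substr(hit$sequence, hit$length - sp$tsd_len + 1,
                        hit$length), tr$tsd)
  }
})

test_that("mutated plants track the requested rate in the truth record", {
  sp <- family_spec("f", 300L, 15L, 3L, 12L, 0.05, "true_mite")
  cons <- make_mite_consensus(sp, seed = 65)
  db <- make_background(80000L, 1L, 0.5, seed = 66)
  pl <- plant_family(db, cons, sp, seed = 67)
  # mean copy-to-consensus identity ~ 1 - rate * (mutable fraction) * 3/4
  # of substitutions drawn; exempted 10 nt keep it slightly above 0.95
  expect_gt(mean(pl$truth$identity), 0.94)
  expect_lt(mean(pl$truth$identity), 0.99)
  # truth identity equals direct recomputation from the genome
  for (i in c(1L, 5L, 12L)) {
    tr <- pl$truth[i, ]
    copy <- substr(pl$db$seq[[tr$entry_id]], tr$start + 1, tr$end)
    expect_equal(str_identity(copy, cons), tr$identity)
  }
})

test_that("uniform placement puts the expected mass in a genome prefix", {
  # the placement model behind the sampling theory: over many plants,
  # ~37% of copies land in the first 37% of total nt
  set.seed(68)
  sp <- family_spec("f", 80L, 11L, 2L, 10L, 0, "true_mite")
  cons <- make_mite_consensus(sp, seed = 69)
  db <- make_background(50000L, 1L, 0.5, seed = 70)
  frac <- replicate(200, {
    pl <- plant_family(db, cons, sp, seed = sample.int(1e6, 1))
    mean(pl$truth$start < 0.37 * pl$db$total_length)
  })
  se <- sqrt(0.37 * 0.63 / (200 * 10))
  expect_lt(abs(mean(frac) - 0.37), 4 * se)
})

test_that("plant_false_family builds a screen-passing core with shared flanks", {
  sp <- family_spec("d", 120L, 13L, 3L, 15L, 0, "false_retro_like")
  db <- make_background(120000L, 1L, 0.5, seed = 71)
  pf <- plant_false_family(db, sp, seed = 72)

  # the core alone passes the IR screen and carries an abutting DR
  hits <- find_inverted_repeats(pf$core)
  expect_gte(nrow(hits), 1L)
  tr <- pf$truth[1, ]
  s <- pf$db$seq[[tr$entry_id]]
  lf <- substr(s, tr$start - 9, tr$start)
  rf <- substr(s, tr$end + 1, tr$end + 10)
  expect_false(is.null(find_tsd(lf, rf)))

  # every copy carries identical 50-nt flanking context
  h <- count_full_length_copies(pf$core, pf$db)
  expect_equal(nrow(h), 15L)
  fl <- collect_flanks(h, pf$db)
  expect_equal(length(unique(fl$left)), 1L)
  expect_equal(length(unique(fl$right)), 1L)
  expect_equal(count_distinct_flanks(fl), 1L)
})

test_that("plant_simple_repeats inserts verbatim negative material", {
  db <- make_background(60000L, 1L, 0.5, seed = 73)
  expect_identical(plant_simple_repeats(db, 0L, seed = 74)$db, db)
  ps <- plant_simple_repeats(db, 10L, seed = 75)
  expect_equal(nrow(ps$intervals), 10L)
  for (i in seq_len(10L)) {
    iv <- ps$intervals[i, ]
    stretch <- substr(ps$db$seq[[iv$entry_id]], iv$start + 1, iv$end)
    chars <- unique(strsplit(stretch, "")[[1]])
    expect_true(length(chars) <= 2L)
    # a planted stretch never survives the simple-arm screen
    pairs <- find_inverted_repeats(substr(ps$db$seq[[iv$entry_id]],
                                          iv$start + 1, iv$end))
    expect_equal(nrow(pairs), 0L)
  }
})

test_that("simulate_genome keeps truth coordinates exact across plantings", {
  specs <- list(
    true_specs = list(
      family_spec("t1", 100L, 12L, 3L, 10L, 0.02, "true_mite"),
      family_spec("t2", 180L, 14L, 2L, 12L, 0, "true_mite")),
    false_specs = list(
      family_spec("d1", 120L, 12L, 4L, 10L, 0, "false_retro_like")),
    n_simple = 4L, total_len = 200000L, n_entries = 2L, gc = 0.45)
  sim <- simulate_genome(specs, seed = 76)
  cons <- stats::setNames(sim$families$consensus, sim$families$family_id)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    got <- substr(sim$db$seq[[tr$entry_id]], tr$start + 1, tr$end)
    expect_equal(str_identity(got, cons[[tr$family_id]]), tr$identity)
  }
  # planted copies never overlap
  by_entry <- split(sim$truth, sim$truth$entry_id)
  for (tr in by_entry) {
    tr <- tr[order(tr$start), ]
    if (nrow(tr) > 1L) expect_true(all(diff(tr$start) >=
                                         head(tr$end - tr$start, -1)))
  }
  # determinism
  sim2 <- simulate_genome(specs, seed = 76)
  expect_identical(sim$db$seq, sim2$db$seq)
  expect_identical(sim$truth, sim2$truth)
})

test_that("write_truth and read_truth round-trip", {
  specs <- list(
    true_specs = list(family_spec("t1", 100L, 12L, 3L, 10L, 0, "true_mite")),
    false_specs = list(), n_simple = 0L,
    total_len = 60000L, n_entries = 1L, gc = 0.5)
  sim <- simulate_genome(specs, seed = 77)
  d <- withr::local_tempdir()
  write_truth(sim, d)
  back <- read_truth(d)
  expect_equal(nrow(back$truth), nrow(sim$truth))
  expect_equal(back$truth$start, sim$truth$start)
  expect_equal(back$families$consensus, sim$families$consensus)
})

test_that("evaluate_output computes recall, precision and leakage", {
  set.seed(78)
  consA <- rdna(150); consB <- rdna(200); core <- rdna(120)
  fam <- data.frame(
    family_id = c("A", "B", "D"),
    kind = c("true_mite", "true_mite", "false_retro_like"),
    consensus = c(consA, consB, core))
  cand <- write_temp_fasta(c(MD_1 = consA))
  fals <- write_temp_fasta(c(MDF_1 = core))
  ev <- evaluate_output(cand, fals, fam)
  expect_equal(ev$recall, 0.5)
  expect_equal(ev$precision, 1)
  expect_equal(ev$false_family_leakage, 0L)
  expect_true(ev$false_in_false_output[["D"]])

  # empty candidates: recall 0
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  ev2 <- evaluate_output(empty, fals, fam)
  expect_equal(ev2$recall, 0)
})
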