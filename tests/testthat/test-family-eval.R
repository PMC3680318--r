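test_that("count_full_length_copies finds planted verbatim copies", {
  set.seed(30)
  element <- rdna(120)
  db <- make_background(60000L, 2L, 0.5, seed = 31)
  pl <- plant_family(db, element,
                     family_spec("f", 120L, 12L, 3L, 12L, 0, "true_mite"),
                     seed = 32)
  hits <- count_full_length_copies(element, pl$db)
  expect_equal(nrow(hits), 12L)
  expect_true(all(hits$identity == 1))
  expect_true(all(hits$query_coverage == 1))

  # an element present only once is its own single hit
  set.seed(33)
  solo <- rdna(100)
  db2 <- genome_db(c(chr = paste0(rdna(5000), solo, rdna(5000))))
  expect_equal(nrow(count_full_length_copies(solo, db2)), 1L)
})

test_that("mutated copies are still counted at the identity tolerance", {
  set.seed(34)
  sp <- family_spec("f", 150L, 14L, 3L, 12L, 0.05, "true_mite")
  cons <- make_mite_consensus(sp, seed = 35)
  db <- make_background(60000L, 1L, 0.5, seed = 36)
  pl <- plant_family(db, cons, sp, seed = 37)
  hits <- count_full_length_copies(cons, pl$db)
  expect_equal(nrow(hits), 12L)
  # per-copy identity from the simulator's truth record matches the hits
  expect_equal(sort(round(hits$identity, 4)),
               sort(round(pl$truth$identity, 4)))
})

test_that("minus-strand hits are found and flanks element-oriented", {
  set.seed(38)
  element <- rdna(100)
  lf <- rdna(50); rf <- rdna(50)
  # plant the element forward once and reverse-complemented once
  chr <- paste0(rdna(300), lf, element, rf, rdna(300),
                reverse_complement(paste0(lf, element, rf)), rdna(300))
  db <- genome_db(c(chr = chr))
  hits <- count_full_length_copies(element, db)
  expect_equal(nrow(hits), 2L)
  expect_setequal(hits$strand, c("+", "-"))
  fl <- collect_flanks(hits, db)
  # element-oriented flanks are identical for the two copies
  expect_equal(fl$left[fl$strand == "-"], fl$left[fl$strand == "+"])
  expect_equal(fl$right[fl$strand == "-"], fl$right[fl$strand == "+"])
  expect_equal(fl$left[1], lf)
  expect_equal(fl$right[1], rf)
})

test_that("collect_flanks handles coordinates and entry-edge truncation", {
  set.seed(39)
  s <- rdna(1000)
  db <- genome_db(c(e = s))
  hits <- data.frame(entry_id = "e", start = 100L, end = 300L, strand = "+",
                     identity = 1, query_coverage = 1)
  fl <- collect_flanks(hits, db)
  expect_equal(fl$left, substr(s, 51, 100))
  expect_equal(fl$right, substr(s, 301, 350))
  expect_false(fl$left_truncated)

  hits2 <- data.frame(entry_id = "e", start = 20L, end = 120L, strand = "+",
                      identity = 1, query_coverage = 1)
  fl2 <- collect_flanks(hits2, db)
  expect_equal(nchar(fl2$left), 20L)
  expect_true(fl2$left_truncated)
  expect_false(fl2$right_truncated)
})

test_that("count_distinct_flanks groups shared contexts by single linkage", {
  set.seed(40)
  mk <- function(left, right) data.frame(left = left, right = right)
  # all identical -> one class
  shared <- mk(rep(rdna(50), 5), rep(rdna(50), 5))
  expect_equal(count_distinct_flanks(shared), 1L)
  # independent random flanks -> all distinct
  indep <- mk(replicate(5, rdna(50)), replicate(5, rdna(50)))
  expect_equal(count_distinct_flanks(indep), 5L)
  # mixture: 3 sharing one context + 3 independent -> 4 classes
  l <- rdna(50); r <- rdna(50)
  mix <- mk(c(rep(l, 3), replicate(3, rdna(50))),
            c(rep(r, 3), replicate(3, rdna(50))))
  expect_equal(count_distinct_flanks(mix), 4L)
  # subset cap bounds the count
  many <- mk(replicate(30, rdna(50)), replicate(30, rdna(50)))
  expect_lte(count_distinct_flanks(many, subset_max = 20L), 20L)
})

test_that("evaluate_candidate issues the three verdicts correctly", {
  params <- pipeline_params()
  set.seed(41)

  # true family: 15 copies at independent loci -> candidate
  sp <- family_spec("f", 120L, 12L, 3L, 15L, 0, "true_mite")
  cons <- make_mite_consensus(sp, seed = 42)
  db <- make_background(80000L, 1L, 0.5, seed = 43)
  pl <- plant_family(db, cons, sp, seed = 44)
  ev <- evaluate_candidate(cons, pl$db, params)
  expect_equal(ev$verdict, "candidate")
  expect_equal(ev$copy_count, 15L)
  expect_gte(ev$distinct_flank_count, params$flank_class_threshold)

  # retro-like decoy: 15 copies with identical flanks -> false_family
  fsp <- family_spec("d", 100L, 12L, 3L, 15L, 0, "false_retro_like")
  db2 <- make_background(80000L, 1L, 0.5, seed = 45)
  pf <- plant_false_family(db2, fsp, seed = 46)
  ev2 <- evaluate_candidate(pf$core, pf$db, params)
  expect_equal(ev2$verdict, "false_family")
  expect_equal(ev2$distinct_flank_count, 1L)

  # too few copies -> below_copy_threshold, flanks not assessed
  sp3 <- family_spec("g", 120L, 12L, 3L, 6L, 0, "true_mite")
  cons3 <- make_mite_consensus(sp3, seed = 47)
  db3 <- make_background(60000L, 1L, 0.5, seed = 48)
  pl3 <- plant_family(db3, cons3, sp3, seed = 49)
  ev3 <- evaluate_candidate(cons3, pl3$db, params)
  expect_equal(ev3$verdict, "below_copy_threshold")
  expect_true(is.na(ev3$distinct_flank_count))

  # invariants: copy_count >= 1, flank classes bounded by copies
  expect_gte(ev3$copy_count, 1L)
  expect_lte(ev$distinct_flank_count, min(ev$copy_count, params$subset_max))
})
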