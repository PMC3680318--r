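test_that("a planted inverted repeat is detected with correct geometry", {
  set.seed(10)
  for (rep in 1:5) {
    pl <- planted_ir(arm_len = 12L, interior_len = 80L)
    hits <- find_inverted_repeats(pl$seq)
    expect_gte(nrow(hits), 1L)
    # the planted pair is among the hits, within a small boundary jitter
    d <- abs(hits$left_start - pl$left_start) +
      abs(hits$right_end - pl$right_end)
    expect_lte(min(d), 6L)
    expect_gte(hits$arm_len[which.min(d)], 10L)
  }
})

test_that("scanner and brute-force oracle agree on random sequences", {
  set.seed(11)
  for (rep in 1:15) {
    s <- rdna(sample(200:500, 1))
    expect_equal(find_inverted_repeats(s), brute_force_ir(s))
  }
})

test_that("perfect palindrome folds into a single maximal pair", {
  set.seed(12)
  half <- rdna(30)
  while (is_simple_arm(half)) half <- rdna(30)
  pal <- paste0(half, reverse_complement(half))
  for (f in list(find_inverted_repeats, brute_force_ir)) {
    hits <- f(pal)
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$left_start, 0L)
    expect_equal(hits$right_end, 60L)
    expect_equal(hits$arm_len, 30L)
    expect_equal(hits$arm_identity, 1)
  }
})

test_that("homopolymers and short slices yield nothing", {
  expect_equal(nrow(brute_force_ir(strrep("A", 600))), 0L)
  expect_equal(nrow(find_inverted_repeats(strrep("A", 600))), 0L)
  expect_equal(nrow(find_inverted_repeats("ACGTACGT")), 0L)  # < min length
})

test_that("reported pairs respect the element length bounds and arm rules", {
  set.seed(13)
  params <- scan_params()
  for (rep in 1:8) {
    pl <- planted_ir(arm_len = sample(10:25, 1),
                     interior_len = sample(30:300, 1))
    hits <- find_inverted_repeats(pl$seq, params)
    if (nrow(hits) == 0L) next
    len <- hits$right_end - hits$left_start
    expect_true(all(len >= params$min_element_len &
                      len <= params$max_element_len))
    expect_true(all(hits$arm_len >= params$min_arm_len))
    expect_true(all(hits$arm_identity >= params$min_arm_identity))
    expect_true(all(hits$left_end <= hits$right_start))
    # no returned arm is simple
    arms <- substring(pl$seq, hits$left_start + 1L, hits$left_end)
    expect_false(any(vapply(arms, is_simple_arm, logical(1))))
  }
})

test_that("scanning is deterministic and reverse-complement symmetric", {
  set.seed(14)
  pl <- planted_ir(15L, 120L)
  h1 <- find_inverted_repeats(pl$seq)
  h2 <- find_inverted_repeats(pl$seq)
  expect_identical(h1, h2)
  # reverse-complementing the slice reflects coordinates
  n <- nchar(pl$seq)
  hr <- find_inverted_repeats(reverse_complement(pl$seq))
  reflected <- data.frame(
    left_start = n - hr$right_end, left_end = n - hr$right_start,
    right_start = n - hr$left_end, right_end = n - hr$left_start,
    arm_len = hr$arm_len, arm_identity = hr$arm_identity)
  reflected <- reflected[order(reflected$left_start, reflected$right_end), ]
  rownames(reflected) <- NULL
  expect_equal(reflected, h1)
})

test_that("is_simple_arm flags single/dinucleotide and one-class arms", {
  expect_true(is_simple_arm("ATATATATAT"))   # dinucleotide, also {A,T}
  expect_true(is_simple_arm("GCCGGCGCCG"))   # {G,C} only
  expect_true(is_simple_arm("AAAAAAAAAA"))   # homopolymer
  expect_true(is_simple_arm("ACACACACACA"))  # period 2, trailing partial
  expect_true(is_simple_arm("ACGNACGT"))     # N makes it unusable
  expect_false(is_simple_arm("GATTACAGAT"))
  expect_false(is_simple_arm("ACGTACGTAC"))  # period 4 is not simple
})

test_that("mask_low_complexity masks by windowed entropy", {
  expect_equal(mask_low_complexity(strrep("A", 200)), strrep("N", 200))
  expect_equal(mask_low_complexity(strrep("ACGT", 50)), strrep("ACGT", 50))
  set.seed(15)
  s <- rdna(200)
  masked <- mask_low_complexity(s)
  frac_masked <- mean(strsplit(masked, "")[[1]] == "N") -
    mean(strsplit(s, "")[[1]] == "N")
  expect_lt(frac_masked, 0.05)
  expect_equal(nchar(masked), 200L)
  # a buried homopolymer is masked, surroundings mostly survive
  s2 <- paste0(rdna(150), strrep("T", 100), rdna(150))
  m2 <- strsplit(mask_low_complexity(s2), "")[[1]]
  expect_true(all(m2[181:250] == "N"))
  expect_true(mean(m2[1:80] == "N") < 0.2)
})
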