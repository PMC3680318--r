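test_that("read_fasta parses, normalizes and validates", {
  p <- write_temp_fasta(c(chr1 = "ACGT"))
  db <- read_fasta(p)
  expect_s3_class(db, "mite_genome")
  expect_equal(db$ids, "chr1")
  expect_equal(db$total_length, 4L)

  # normalization: lowercase up-cased, non-ACGT to N
  p2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x desc here", "acgtn-x"), p2)
  db2 <- read_fasta(p2)
  expect_equal(unname(db2$seq[["x"]]), "ACGTNNN")
  expect_equal(db2$desc, "desc here")

  # multi-record file: order preserved, total equals character counts
  set.seed(1)
  seqs <- c(a = rdna(120), b = rdna(37), c = rdna(503))
  p3 <- write_temp_fasta(seqs)
  db3 <- read_fasta(p3)
  expect_equal(db3$ids, c("a", "b", "c"))
  expect_equal(db3$total_length, sum(nchar(seqs)))
  expect_equal(unname(db3$seq), unname(seqs))

  # errors: missing file, empty file, duplicate ids
  expect_error(read_fasta(file.path(tempdir(), "nope.fa")), "cannot read")
  p4 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), p4)
  expect_error(read_fasta(p4))
  p5 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">dup", "ACGT", ">dup", "GGCC"), p5)
  expect_error(read_fasta(p5), "dup")
})

test_that("slice_entries produces covering overlapping windows", {
  set.seed(2)
  # below and at the limit: one slice
  db1 <- genome_db(c(e1 = rdna(80000)))
  expect_length(slice_entries(db1), 1L)
  db2 <- genome_db(c(e1 = rdna(100000)))
  sl2 <- slice_entries(db2)
  expect_length(sl2, 1L)
  expect_equal(nchar(sl2[[1]]$residues), 100000L)

  # 250 kb: starts 0, 99100, 198200; last slice 51800 nt
  db3 <- genome_db(c(e1 = rdna(250000)))
  sl3 <- slice_entries(db3)
  expect_equal(vapply(sl3, `[[`, integer(1), "parent_offset"),
               c(0L, 99100L, 198200L))
  expect_equal(nchar(sl3[[3]]$residues), 51800L)
  expect_true(all(vapply(sl3, function(s) nchar(s$residues), integer(1))
                  <= 100000L))

  # union of slices covers the entry byte-for-byte
  reassembled <- substr(sl3[[1]]$residues, 1, 99100)
  for (i in 2:3) {
    reassembled <- paste0(reassembled,
                          substr(sl3[[i]]$residues, 1,
                                 min(99100, nchar(sl3[[i]]$residues))))
  }
  reassembled <- substr(reassembled, 1, 250000)
  pos <- sample(250000, 200)
  expect_equal(substring(reassembled, pos, pos),
               substring(db3$seq[[1]], pos, pos))

  expect_error(slice_entries(db1, max_slice_size = 1000L, overlap = 1000L),
               "overlap")
})

test_that("reverse_complement is a correct involution", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AANC"), "GNTT")
  set.seed(3)
  s <- rdna(1000)
  expect_equal(reverse_complement(reverse_complement(s)), s)
  expect_error(reverse_complement("ACGU"), "invalid")
})

test_that("hard_mask replaces intervals with N and preserves length", {
  sl <- genome_slice("e", 0L, "ACGTAC")
  expect_equal(hard_mask(sl, list(c(2L, 4L)))$residues, "ACNNAC")
  expect_equal(hard_mask(sl, list())$residues, "ACGTAC")
  # overlapping intervals mask their union
  expect_equal(hard_mask(sl, list(c(0L, 3L), c(2L, 5L)))$residues, "NNNNNC")
  expect_error(hard_mask(sl, list(c(4L, 9L))), "out of slice bounds")
  # length never changes
  set.seed(4)
  sl2 <- genome_slice("e", 0L, rdna(500))
  m <- hard_mask(sl2, list(c(10L, 60L), c(55L, 400L)))
  expect_equal(nchar(m$residues), 500L)
})

test_that("write_fasta round-trips with 60-column wrapping", {
  set.seed(5)
  seqs <- c(one = rdna(175), two = rdna(60))
  p <- write_temp_fasta(seqs)
  lines <- readLines(p)
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 60L))
  back <- read_fasta(p)
  expect_equal(unname(back$seq), unname(seqs))
})
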