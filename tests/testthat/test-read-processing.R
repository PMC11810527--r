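ADAPTER <- "AGATCGGAAG"  # 10 bp test adapter

test_that("a full adapter occurrence is removed wherever it starts", {
  r <- make_reads(paste0("ACGTACGT", ADAPTER))
  out <- trim_adapter(r, ADAPTER)
  expect_identical(out$bases, "ACGTACGT")
  expect_identical(nchar(out$quals), 8L)
  # internal occurrence with trailing garbage truncates at its start
  r2 <- make_reads(paste0("ACGTACGT", ADAPTER, "TTTT"))
  expect_identical(trim_adapter(r2, ADAPTER)$bases, "ACGTACGT")
})

test_that("reads without adapter overlap are unchanged", {
  r <- make_reads("ACGTACGTACGTACGT")
  out <- trim_adapter(r, ADAPTER)
  expect_identical(out$bases, r$bases)
  expect_identical(attr(out, "n_trimmed"), 0L)
  expect_error(trim_adapter(r, ""), "adapter")
})

test_that("the longest admissible suffix-prefix overlap is trimmed", {
  # every partial read-through length from min_match up to adapter length - 1,
  # frozen against the brute-force enumeration oracle
  set.seed(41)
  stem <- rand_dna(30)
  for (k in 3:9) {
    bases <- paste0(stem, substr(ADAPTER, 1, k))
    expected <- oracle_trim_len(bases, ADAPTER, 3)
    out <- trim_adapter(make_reads(bases), ADAPTER, 3)
    expect_identical(nchar(out$bases), expected)
    expect_identical(out$bases, substr(bases, 1, expected))
  }
  # below min_match nothing is trimmed
  b2 <- paste0(stem, substr(ADAPTER, 1, 2))
  expect_identical(trim_adapter(make_reads(b2), ADAPTER, 3)$bases, b2)
})

test_that("quality filtering trims low-quality ends and enforces the length floor", {
  # clean read: unchanged
  r <- make_reads(rand_dna(50), q = 30)
  out <- quality_filter(r)
  expect_identical(out$bases, r$bases)
  expect_identical(attr(out, "n_discarded"), 0L)

  mk <- function(n_good, n_bad) {
    bases <- rand_dna(n_good + n_bad)
    quals <- int_to_qual(c(rep(30, n_good), rep(10, n_bad)))
    read_frame("r1", bases, quals)
  }
  # 50 bp with final 15 at Q10 -> trimmed to 35 -> discarded (35 <= 40)
  expect_equal(nrow(quality_filter(mk(35, 15))), 0)
  # 50 bp with final 9 at Q10 -> trimmed to 41 -> kept (41 > 40)
  kept <- quality_filter(mk(41, 9))
  expect_equal(nrow(kept), 1)
  expect_identical(nchar(kept$bases), 41L)
  # a 40 bp survivor is discarded: boundary is "length <= 40"
  r40 <- make_reads(rand_dna(40), q = 30)
  expect_equal(nrow(quality_filter(r40)), 0)
  r41 <- make_reads(rand_dna(41), q = 30)
  expect_equal(nrow(quality_filter(r41)), 1)
})

test_that("quality filtering also trims the 5' end and drops empty reads", {
  bases <- rand_dna(60)
  quals <- int_to_qual(c(rep(5, 8), rep(30, 44), rep(15, 8)))
  out <- quality_filter(read_frame("r1", bases, quals))
  expect_identical(nchar(out$bases), 44L)
  expect_identical(out$bases, substr(bases, 9, 52))
  all_bad <- read_frame("r2", rand_dna(50), int_to_qual(rep(10, 50)))
  expect_equal(nrow(quality_filter(all_bad)), 0)
})

test_that("a perfect pair merges over the full amplicon", {
  set.seed(7)
  amp <- rand_dna(120)
  r1 <- make_reads(amp, q = 35)
  r2 <- make_reads(revcomp(amp), q = 35)
  m <- merge_pair(r1, r2)
  expect_true(m$merged)
  expect_identical(m$overlap_len, 120L)
  expect_identical(m$mismatches_in_overlap, 0L)
  expect_identical(m$bases, amp)
  expect_identical(nchar(m$quals), 120L)
})

test_that("the higher-quality base wins at overlap disagreements", {
  amp <- "ACGTACGTACGTACGTACGT"
  variant <- paste0(substr(amp, 1, 9), "A", substr(amp, 11, 20))  # pos 10: C -> A
  q_hi <- int_to_qual(rep(40, 20)); q_lo <- int_to_qual(rep(10, 20))
  # r1 higher quality -> r1 base retained
  m1 <- merge_pair(read_frame("p", amp, q_hi),
                   read_frame("p", revcomp(variant), str_rev(q_lo)))
  expect_identical(substr(m1$bases, 10, 10), "C")
  expect_identical(qual_to_int(m1$quals)[10], 40L)
  # r2 higher quality -> r2 base wins
  m2 <- merge_pair(read_frame("p", amp, q_lo),
                   read_frame("p", revcomp(variant), str_rev(q_hi)))
  expect_identical(substr(m2$bases, 10, 10), "A")
  expect_identical(qual_to_int(m2$quals)[10], 40L)
  # equal quality -> tie broken toward r1
  m3 <- merge_pair(read_frame("p", amp, q_hi),
                   read_frame("p", revcomp(variant), str_rev(q_hi)))
  expect_identical(substr(m3$bases, 10, 10), "C")
})

test_that("planted overlap mismatches respect the mismatch-fraction threshold", {
  set.seed(13)
  A <- rand_dna(20); O <- rand_dna(30); B <- rand_dna(20)
  b1 <- paste0(A, O)
  ov <- strsplit(O, "")[[1]]
  flip <- c(4, 11, 19, 27)
  ov[flip] <- vapply(ov[flip], function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                     character(1))
  rc2 <- paste0(paste(ov, collapse = ""), B)
  # brute-force oracle: no admissible overlap at 0.1, the 30 bp one at 0.25
  expect_null(oracle_overlap(b1, rc2, 10, 0.1))
  orac <- oracle_overlap(b1, rc2, 10, 0.25)
  expect_identical(orac$overlap, 30L)
  expect_identical(orac$mismatches, 4L)

  r1 <- make_reads(b1, q = 35, ids = "p")
  r2 <- make_reads(revcomp(rc2), q = 35, ids = "p")
  strict <- merge_pair(r1, r2, min_overlap = 10, max_mismatch_frac = 0.1)
  expect_false(strict$merged)
  loose <- merge_pair(r1, r2, min_overlap = 10, max_mismatch_frac = 0.25)
  expect_true(loose$merged)
  expect_identical(loose$overlap_len, orac$overlap)
  expect_identical(loose$mismatches_in_overlap, orac$mismatches)
  expect_identical(nchar(loose$bases), 50L + 50L - 30L)
})

test_that("processing never lengthens reads and keeps quals in lockstep", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(41:120, 1)
    bases <- rand_dna(n)
    quals <- int_to_qual(sample(2:40, n, replace = TRUE))
    r <- read_frame("r", bases, quals)
    tr <- trim_adapter(r, ADAPTER)
    expect_lte(nchar(tr$bases), n)
    expect_identical(nchar(tr$bases), nchar(tr$quals))
    qf <- quality_filter(tr)
    if (nrow(qf)) {
      expect_lte(nchar(qf$bases), nchar(tr$bases))
      expect_identical(nchar(qf$bases), nchar(qf$quals))
    }
  }
})

test_that("simulator pairs with no sequencing error all merge cleanly", {
  refs <- default_references()
  sim <- simulate_reads(make_truth(), refs, reads_per_gene = 40,
                        error_rate = 0, seed = 4)
  r1 <- trim_adapter(sim$r1, revcomp(refs[[1]]$adapter_rev))
  r2 <- trim_adapter(sim$r2, revcomp(refs[[1]]$adapter_fwd))
  m <- merge_pair(r1, r2)
  expect_true(all(m$merged))
  expect_true(all(m$mismatches_in_overlap == 0))
})
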