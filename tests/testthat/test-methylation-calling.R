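refs3 <- default_references()

test_that("an unconverted reference aligns to itself with no mismatches", {
  ref <- refs3$GRIA2
  r <- make_reads(ref$sequence, ids = "id1")
  aln <- bisulfite_align(r, refs3)
  expect_true(aln$aligned)
  expect_identical(aln$gene_name, "GRIA2")
  expect_identical(aln$start, 1L)
  expect_identical(aln$n_hard_mismatches, 0L)
  expect_identical(aln$n_bs_matches, 0L)
})

test_that("a fully converted read aligns with bs-matches equal to non-CpG Cs", {
  ref <- refs3$CDKN2A
  ch <- strsplit(ref$sequence, "")[[1]]
  conv <- ch
  non_cpg_c <- setdiff(which(ch == "C"), ref$cpg_positions)
  conv[non_cpg_c] <- "T"  # CpG cytosines retained (fully methylated molecule)
  aln <- bisulfite_align(make_reads(paste(conv, collapse = "")), refs3)
  expect_true(aln$aligned)
  expect_identical(aln$gene_name, "CDKN2A")
  expect_identical(aln$n_hard_mismatches, 0L)
  expect_identical(aln$n_bs_matches, length(non_cpg_c))
})

test_that("a shuffled read does not align", {
  set.seed(17)
  shuffled <- paste(sample(strsplit(refs3$TET2$sequence, "")[[1]]), collapse = "")
  # brute force over every reference and offset: mismatch floor above 0.1
  expect_gt(oracle_min_mismatch_frac(shuffled, refs3), 0.1)
  aln <- bisulfite_align(make_reads(shuffled), refs3)
  expect_false(aln$aligned)
})

test_that("alignment matches the brute-force scorer on interior fragments", {
  set.seed(29)
  ref <- refs3$TET2
  for (i in 1:5) {
    start <- sample(1:40, 1)
    L <- sample(100:150, 1)
    frag <- substr(ref$sequence, start, start + L - 1)
    aln <- bisulfite_align(make_reads(frag), refs3)
    expect_true(aln$aligned)
    expect_identical(aln$gene_name, "TET2")
    expect_identical(aln$start, start)
    expect_equal(oracle_min_mismatch_frac(frag, refs3), 0)
  }
})

test_that("per-CpG counting follows the C/T/exclude rule", {
  ref <- refs3$GRIA2
  site <- ref$target_site
  mk_cover <- function(bases_at_site) {
    n <- length(bases_at_site)
    seqs <- vapply(bases_at_site, function(b) {
      s <- strsplit(ref$sequence, "")[[1]]
      s[site] <- b
      paste(s, collapse = "")
    }, character(1))
    merged <- make_reads(seqs)
    aln <- data.frame(read_id = merged$read_id, gene_name = "GRIA2",
                      start = 1L, n_bs_matches = 0L, n_hard_mismatches = 0L,
                      aligned = TRUE, stringsAsFactors = FALSE)
    list(merged = merged, aln = aln)
  }
  all_c <- mk_cover(rep("C", 100))
  call <- call_cpg(all_c$merged, all_c$aln, ref, sample_id = "s")
  expect_equal(call$coverage, 100)
  expect_equal(call$frequency, 100)
  expect_identical(call$site_label, "GRIA2+202")

  # sequencing-error bases at the site are excluded from coverage
  mix <- mk_cover(c(rep("C", 5), rep("T", 3), "G", "A"))
  call2 <- call_cpg(mix$merged, mix$aln, ref, sample_id = "s")
  expect_equal(call2$coverage, 8)
  expect_equal(call2$ignored, 2)
  expect_equal(call2$methylated + call2$unmethylated, call2$coverage)
  expect_equal(call2$frequency, 100 * 5 / 8)

  # conservation: counted + ignored = reads covering the site
  expect_equal(call2$coverage + call2$ignored, nrow(mix$merged))
})

test_that("10,000 covering molecules with 1,137 methylated give 11.37%", {
  ref <- refs3$TET2
  site <- ref$target_site
  tpl <- strsplit(ref$sequence, "")[[1]]
  mk <- function(b) { s <- tpl; s[site] <- b; paste(s, collapse = "") }
  bases <- c(rep(mk("C"), 1137), rep(mk("T"), 8863))
  merged <- make_reads(bases)
  aln <- data.frame(read_id = merged$read_id, gene_name = "TET2", start = 1L,
                    n_bs_matches = 0L, n_hard_mismatches = 0L, aligned = TRUE,
                    stringsAsFactors = FALSE)
  call <- call_cpg(merged, aln, ref, sample_id = "s")
  expect_equal(call$frequency, 11.37)
  expect_equal(call$coverage, 10000)
})

test_that("zero coverage is a no-call error, distinct from frequency 0", {
  ref <- refs3$GRIA2
  merged <- make_reads(substr(ref$sequence, ref$target_site + 5, ref$target_site + 150))
  aln <- bisulfite_align(merged, refs3)
  expect_error(call_cpg(merged, aln, ref, sample_id = "s"), "no-call")
})

test_that("call_cpg rejects sites that are not CpGs of the reference", {
  ref <- refs3$GRIA2
  merged <- make_reads(ref$sequence)
  aln <- bisulfite_align(merged, refs3)
  bad <- setdiff(seq_len(nchar(ref$sequence)), ref$cpg_positions)[1]
  expect_error(call_cpg(merged, aln, ref, site = bad), "not a CpG")
})

test_that("sample_frequencies orders genes, flags low coverage, reports missing", {
  calls <- data.frame(sample_id = "s",
                      gene_name = c("TET2", "GRIA2", "CDKN2A"),
                      site_label = c("TET2+31", "GRIA2+202", "CDKN2A+297"),
                      methylated = c(734, 160, 204),
                      unmethylated = c(9266, 9840, 9796),
                      ignored = 0L,
                      coverage = c(10000, 10000, 10000),
                      frequency = c(7.34, 1.60, 2.04),
                      stringsAsFactors = FALSE)
  f <- sample_frequencies(calls)
  expect_equal(c(f$x, f$y, f$z), c(1.60, 2.04, 7.34))
  expect_false(f$low_coverage)
  # permuting rows changes nothing
  f2 <- sample_frequencies(calls[c(2, 3, 1), ])
  expect_identical(f, f2)
  calls$coverage[1] <- 500
  expect_true(sample_frequencies(calls)$low_coverage)
  expect_false(sample_frequencies(calls, coverage_floor = 100)$low_coverage)
  expect_error(sample_frequencies(calls[-1, ]), "TET2")
})

test_that("clean simulated reads round-trip to exact bookkeeping frequencies", {
  truth <- generate_cohort(3, 1, 0.5, c(3, 25), seed = 8)
  res <- run_pipeline_mem(truth, refs3, reads_per_gene = 250, error_rate = 0,
                          seed = 80)
  expect_equal(nrow(res), 4 * 3)
  expect_true(all(res$coverage == 250))
  expect_equal(res$frequency, res$true_freq, tolerance = 1e-12)
})
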