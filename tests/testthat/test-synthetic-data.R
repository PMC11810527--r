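test_that("build_reference satisfies its structural invariants", {
  ref <- build_reference("GRIA2", 300, 5, 2, seed = 7)
  expect_s3_class(ref, "amplicon_ref")
  expect_length(ref$cpg_positions, 5)
  expect_identical(ref$target_site, ref$cpg_positions[2])
  ch <- strsplit(ref$sequence, "")[[1]]
  # listed CpGs are genuine, and the CpG inventory is exhaustive
  for (p in ref$cpg_positions) expect_identical(paste0(ch[p], ch[p + 1]), "CG")
  all_cg <- which(ch[-length(ch)] == "C" & ch[-1] == "G")
  expect_identical(all_cg, as.integer(ref$cpg_positions))
  # primers anchor the ends and carry no CpG
  expect_identical(substr(ref$sequence, 1, nchar(ref$fwd_primer)), ref$fwd_primer)
  sfx <- revcomp(ref$rev_primer)
  expect_identical(substr(ref$sequence, 301 - nchar(sfx), 300), sfx)
  expect_true(all(ref$cpg_positions > nchar(ref$fwd_primer)))
  expect_true(all(ref$cpg_positions < 300 - nchar(sfx)))
})

test_that("build_reference handles the single-CpG case and is deterministic", {
  ref <- build_reference("TET2", 200, 1, 1, seed = 1)
  expect_length(ref$cpg_positions, 1)
  expect_identical(ref$target_site, ref$cpg_positions[1])
  a <- build_reference("GRIA2", 300, 5, 2, seed = 7)
  b <- build_reference("GRIA2", 300, 5, 2, seed = 7)
  expect_identical(a$sequence, b$sequence)
  expect_error(build_reference("GRIA2", 121, 13, 1, seed = 1), "n_cpgs")
  expect_error(build_reference("GRIA2", 80, 2, 1, seed = 1), "length")
  # interior too small for the requested CpG count
  expect_error(build_reference("X", 120, 6, 1, seed = 1,
                               fwd_primer = strrep("AT", 25),
                               rev_primer = strrep("AT", 25)),
               "cannot place")
})

test_that("generate_cohort emulates the study structure", {
  co <- generate_cohort(21, 4, 15 / 21, c(2, 31), seed = 42)
  expect_equal(nrow(co), 25)
  expect_length(unique(co$individual_id), 21)
  expect_equal(sum(co$sex[!duplicated(co$individual_id)] == "male"), 15)
  expect_true(all(co$true_age >= 2 & co$true_age <= 31))
})

test_that("cohort ground truth is clock-consistent (inverse then forward)", {
  one <- generate_cohort(1, 0, 1, c(10, 10), seed = 1)
  expect_equal(heaa_age(100 * one$meth_GRIA2, 100 * one$meth_CDKN2A,
                        100 * one$meth_TET2), 10, tolerance = 1e-9)
  co <- generate_cohort(21, 4, 15 / 21, c(2, 31), seed = 5)
  back <- heaa_age(100 * co$meth_GRIA2, 100 * co$meth_CDKN2A, 100 * co$meth_TET2)
  expect_true(all(abs(back - co$true_age) < 0.005))
  expect_true(all(co$meth_CDKN2A >= 0.0134 & co$meth_CDKN2A <= 0.0464))
  expect_true(all(co$meth_TET2 >= 0.0559 & co$meth_TET2 <= 0.1919))
})

test_that("duplicate samples share age and sex", {
  co <- generate_cohort(2, 2, 0.5, c(5, 20), seed = 3)
  expect_equal(nrow(co), 4)
  for (id in unique(co$individual_id)) {
    d <- co[co$individual_id == id, ]
    expect_equal(nrow(d), 2)
    expect_identical(d$true_age[1], d$true_age[2])
    expect_identical(d$sex[1], d$sex[2])
  }
})

test_that("degenerate methylation probabilities give exact molecule counts", {
  refs <- default_references()
  t1 <- make_truth(x = 1, y = 1, z = 1)  # fully methylated, ce = 1
  sim <- simulate_reads(t1, refs, reads_per_gene = 100, error_rate = 0, seed = 2)
  expect_equal(sim$truth$methmol_GRIA2, 100)
  expect_equal(sim$truth$methmol_TET2, 100)
  # every molecule retains C at the target site of its own amplicon
  for (g in names(refs)) {
    site <- refs[[g]]$target_site
    r1 <- sim$r1[grepl(paste0("\\|", g, "\\|"), sim$r1$read_id), ]
    expect_true(all(substr(r1$bases, site, site) == "C"))
  }
  t0 <- make_truth(x = 0, y = 0, z = 0)
  sim0 <- simulate_reads(t0, refs, reads_per_gene = 100, error_rate = 0, seed = 2)
  expect_equal(sim0$truth$methmol_GRIA2, 0)
  site <- refs$GRIA2$target_site
  r1 <- sim0$r1[grepl("\\|GRIA2\\|", sim0$r1$read_id), ]
  expect_true(all(substr(r1$bases, site, site) == "T"))
})

test_that("methylated-molecule bookkeeping follows the binomial law", {
  refs <- default_references()["TET2"]
  tr <- make_truth(z = 0.1137)
  sim <- simulate_reads(tr, refs, reads_per_gene = 10000, error_rate = 0,
                        seed = 99)
  sd3 <- 3 * sqrt(10000 * 0.1137 * (1 - 0.1137))
  expect_lt(abs(sim$truth$methmol_TET2 - 1137), sd3)
})

test_that("read simulation is deterministic given the seed", {
  refs <- default_references()
  tr <- make_truth()
  a <- simulate_reads(tr, refs, reads_per_gene = 50, error_rate = 0.01, seed = 7)
  b <- simulate_reads(tr, refs, reads_per_gene = 50, error_rate = 0.01, seed = 7)
  expect_identical(a$r1, b$r1)
  expect_identical(a$r2, b$r2)
  fa <- tempfile(fileext = ".fastq"); fb <- tempfile(fileext = ".fastq")
  write_fastq(a$r1, fa); write_fastq(b$r1, fb)
  expect_identical(unname(tools::md5sum(fa)), unname(tools::md5sum(fb)))
})

test_that("incomplete conversion inflates apparent methylation at the target", {
  refs <- default_references()["GRIA2"]
  tr <- make_truth(x = 0.02, ce = 0.8)  # 20% of unmethylated Cs stay C
  sim <- simulate_reads(tr, refs, reads_per_gene = 4000, error_rate = 0, seed = 3)
  site <- refs$GRIA2$target_site
  frac_c <- mean(substr(sim$r1$bases, site, site) == "C")
  # expected apparent fraction: m + (1 - m) * (1 - ce) = 0.216
  expect_gt(frac_c, 0.15)
  expect_lt(frac_c, 0.28)
})

test_that("over-long amplicons are rejected as unmergeable", {
  ref <- build_reference("GRIA2", 500, 3, 1, seed = 1)
  expect_error(simulate_reads(make_truth(), list(GRIA2 = ref),
                              reads_per_gene = 10, seed = 1),
               "overlap")
})
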