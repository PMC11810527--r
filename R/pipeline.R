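# Pipeline orchestration: staged, file-based, deterministic under a seed.
#
# Each stage reads only the on-disk outputs of the previous stage, so
# stages are idempotent and independently re-runnable. Per-stage read-loss
# accounting (pairs in, adapter-trimmed, quality-discarded, unmerged,
# unaligned) is logged and written next to the outputs.

#' Build a pipeline configuration
#'
#' Collects paths and all tunable parameters of the simulate → process →
#' call → age → summarize chain, with the study defaults: a 25-sample
#' cohort (21 whales, 4 replicate pairs, 15:6 male:female), 250 bp x 2
#' reads, Q20/40 bp quality filtering, a 1000x coverage QC floor and the
#' 4.47-year CI half-width.
#'
#' @param outdir output directory (created on demand).
#' @param seed integer master seed; all stage randomness derives from it.
#' @param ... overrides for any default parameter (see Details).
#' @details Parameters: `n_individuals` (21), `duplicate_pairs` (4),
#'   `sex_ratio` (15/21), `age_range` (c(2, 31)), `background_meth` (0.02),
#'   `conversion_efficiency` (1), `reads_per_gene` (2000), `error_rate`
#'   (0), `read_len` (250), `base_q` (35), `ramp_len` (0), `ramp_min` (35),
#'   `min_adapter_match` (3), `min_q` (20), `min_len` (40), `min_overlap`
#'   (10), `merge_max_mismatch` (0.25), `align_max_mismatch` (0.1),
#'   `coverage_floor` (1000), `ci_half_width` (4.47), `bin_width` (5),
#'   `ref_seed` (104729).
#' @return a `heaa_config` list.
#' @export
pipeline_config <- function(outdir, seed = 1, ...) {
  cfg <- list(
    outdir = outdir, seed = as.integer(seed),
    n_individuals = 21, duplicate_pairs = 4, sex_ratio = 15 / 21,
    age_range = c(2, 31), background_meth = 0.02, conversion_efficiency = 1,
    reads_per_gene = 2000, error_rate = 0, read_len = 250,
    base_q = 35, ramp_len = 0, ramp_min = 35,
    min_adapter_match = 3, min_q = 20, min_len = 40,
    min_overlap = 10, merge_max_mismatch = 0.25, align_max_mismatch = 0.1,
    coverage_floor = 1000, ci_half_width = HEAA_CI_HALF_WIDTH, bin_width = 5,
    ref_seed = 104729
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration parameter(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  validate_config(structure(cfg, class = "heaa_config"))
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid configuration: ", msg)
  chk(cfg$n_individuals >= 1, "n_individuals >= 1")
  chk(cfg$duplicate_pairs >= 0 && cfg$duplicate_pairs <= cfg$n_individuals,
      "0 <= duplicate_pairs <= n_individuals")
  chk(cfg$sex_ratio >= 0 && cfg$sex_ratio <= 1, "sex_ratio in [0, 1]")
  chk(cfg$error_rate >= 0 && cfg$error_rate < 0.1, "error_rate in [0, 0.1)")
  chk(cfg$conversion_efficiency >= 0 && cfg$conversion_efficiency <= 1,
      "conversion_efficiency in [0, 1]")
  chk(cfg$reads_per_gene >= 1, "reads_per_gene >= 1")
  chk(cfg$min_q >= 0 && cfg$min_len >= 0, "min_q and min_len >= 0")
  chk(cfg$min_overlap >= 1, "min_overlap >= 1")
  chk(cfg$merge_max_mismatch >= 0 && cfg$merge_max_mismatch <= 1,
      "merge_max_mismatch in [0, 1]")
  chk(cfg$align_max_mismatch >= 0 && cfg$align_max_mismatch <= 1,
      "align_max_mismatch in [0, 1]")
  chk(cfg$ci_half_width >= 0, "ci_half_width >= 0")
  chk(cfg$bin_width > 0, "bin_width > 0")
  cfg
}

#' Write / read a pipeline configuration as YAML
#' @param cfg a `heaa_config`.
#' @param path YAML file path.
#' @return `write_config`: `path` invisibly; `read_config`: the config.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(structure(cfg, class = "heaa_config"))
}

p_ <- function(cfg, ...) file.path(cfg$outdir, ...)

stage_log <- function(stage, ...) {
  kv <- c(...)
  message(sprintf("[%s] %s", stage,
                  paste(names(kv), unname(kv), sep = "=", collapse = " ")))
}

#' Run the simulation stage
#'
#' Generates the reference panel, the ground-truth cohort and per-sample
#' paired FASTQ files; writes `refs.fasta`, `refs_meta.tsv`,
#' `sample_sheet.csv`, `truth.tsv` and `reads/<sample>_R{1,2}.fastq` under
#' the configured output directory.
#'
#' @param cfg a `heaa_config`.
#' @return the truth table, invisibly.
#' @export
run_simulate <- function(cfg) {
  dir.create(p_(cfg, "reads"), recursive = TRUE, showWarnings = FALSE)
  refs <- default_references(cfg$ref_seed)
  write_references(refs, p_(cfg, "refs.fasta"), p_(cfg, "refs_meta.tsv"))
  truth <- generate_cohort(cfg$n_individuals, cfg$duplicate_pairs,
                           cfg$sex_ratio, cfg$age_range, seed = cfg$seed,
                           background_meth = cfg$background_meth,
                           conversion_efficiency = cfg$conversion_efficiency)
  out_truth <- list()
  sheet <- list()
  for (i in seq_len(nrow(truth))) {
    sim <- simulate_reads(truth[i, ], refs,
                          reads_per_gene = cfg$reads_per_gene,
                          error_rate = cfg$error_rate,
                          seed = cfg$seed + i, read_len = cfg$read_len,
                          base_q = cfg$base_q, ramp_len = cfg$ramp_len,
                          ramp_min = cfg$ramp_min)
    sid <- truth$sample_id[i]
    f1 <- p_(cfg, "reads", paste0(sid, "_R1.fastq"))
    f2 <- p_(cfg, "reads", paste0(sid, "_R2.fastq"))
    write_fastq(sim$r1, f1)
    write_fastq(sim$r2, f2)
    out_truth[[i]] <- sim$truth
    sheet[[i]] <- data.frame(sample_id = sid,
                             individual_id = truth$individual_id[i],
                             sex = truth$sex[i],
                             fastq_r1 = f1, fastq_r2 = f2,
                             stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, out_truth)
  write_tsv(truth, p_(cfg, "truth.tsv"))
  utils::write.csv(do.call(rbind, sheet), p_(cfg, "sample_sheet.csv"),
                   row.names = FALSE, quote = FALSE)
  stage_log("simulate", samples = nrow(truth),
            reads_per_gene = cfg$reads_per_gene)
  invisible(truth)
}

#' Run the read-processing stage
#'
#' For every sample in the sample sheet: trims 3' adapter read-through from
#' both mates, quality-filters (dropping a pair when either mate fails),
#' and merges the surviving pairs; writes `merged/<sample>.fastq` and the
#' per-sample loss accounting `stage_counts.tsv`.
#'
#' @param cfg a `heaa_config`.
#' @return the stage-counts table, invisibly.
#' @export
run_process <- function(cfg) {
  sheet <- utils::read.csv(p_(cfg, "sample_sheet.csv"), stringsAsFactors = FALSE)
  refs <- read_references(p_(cfg, "refs.fasta"), p_(cfg, "refs_meta.tsv"))
  ad1 <- revcomp(refs[[1]]$adapter_rev)   # read-through adapter seen by R1
  ad2 <- revcomp(refs[[1]]$adapter_fwd)   # and by R2
  dir.create(p_(cfg, "merged"), recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  for (i in seq_len(nrow(sheet))) {
    r1 <- read_fastq(sheet$fastq_r1[i])
    r2 <- read_fastq(sheet$fastq_r2[i])
    n_pairs <- nrow(r1)
    r1 <- trim_adapter(r1, ad1, cfg$min_adapter_match)
    r2 <- trim_adapter(r2, ad2, cfg$min_adapter_match)
    n_trimmed <- max(attr(r1, "n_trimmed"), attr(r2, "n_trimmed"))
    f1 <- quality_filter(r1, cfg$min_q, cfg$min_len)
    f2 <- quality_filter(r2, cfg$min_q, cfg$min_len)
    keep <- intersect(f1$read_id, f2$read_id)
    n_qual_dropped <- n_pairs - length(keep)
    f1 <- f1[match(keep, f1$read_id), , drop = FALSE]
    f2 <- f2[match(keep, f2$read_id), , drop = FALSE]
    m <- merge_pair(f1, f2, cfg$min_overlap, cfg$merge_max_mismatch)
    ok <- m$merged
    write_fastq(read_frame(m$read_id[ok], m$bases[ok], m$quals[ok]),
                p_(cfg, "merged", paste0(sheet$sample_id[i], ".fastq")))
    counts[[i]] <- data.frame(sample_id = sheet$sample_id[i],
                              pairs_in = n_pairs,
                              adapter_trimmed = n_trimmed,
                              quality_dropped = n_qual_dropped,
                              merged = sum(ok), unmerged = sum(!ok),
                              stringsAsFactors = FALSE)
    stage_log("process", sample = sheet$sample_id[i], pairs_in = n_pairs,
              quality_dropped = n_qual_dropped, merged = sum(ok),
              unmerged = sum(!ok))
  }
  counts <- do.call(rbind, counts)
  write_tsv(counts, p_(cfg, "stage_counts.tsv"))
  invisible(counts)
}

#' Run the methylation-calling stage
#'
#' Aligns every sample's merged reads to the reference panel and calls the
#' assay CpG of each gene; writes `frequencies.tsv` (one row per sample x
#' gene) and `clock_input.tsv` (one row per sample with x, y, z).
#'
#' @param cfg a `heaa_config`.
#' @return the clock-input table, invisibly.
#' @export
run_call <- function(cfg) {
  sheet <- utils::read.csv(p_(cfg, "sample_sheet.csv"), stringsAsFactors = FALSE)
  refs <- read_references(p_(cfg, "refs.fasta"), p_(cfg, "refs_meta.tsv"))
  calls <- list(); freqs <- list()
  for (i in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[i]
    merged <- read_fastq(p_(cfg, "merged", paste0(sid, ".fastq")))
    aln <- bisulfite_align(merged, refs, cfg$align_max_mismatch)
    cc <- call_targets(merged, aln, refs, sample_id = sid)
    calls[[i]] <- cc
    freqs[[i]] <- sample_frequencies(cc, cfg$coverage_floor)
    stage_log("call", sample = sid, aligned = sum(aln$aligned),
              unaligned = sum(!aln$aligned))
  }
  calls <- do.call(rbind, calls)
  freqs <- do.call(rbind, freqs)
  write_tsv(calls, p_(cfg, "frequencies.tsv"))
  write_tsv(freqs, p_(cfg, "clock_input.tsv"))
  invisible(freqs)
}

#' Run the age-estimation stage
#'
#' Applies the HEAA clock with CI attachment to `clock_input.tsv`; writes
#' `estimates.tsv` (per-biopsy x, y, z, age, CI).
#'
#' @param cfg a `heaa_config`.
#' @return the estimates table, invisibly.
#' @export
run_age <- function(cfg) {
  freqs <- read_tsv(p_(cfg, "clock_input.tsv"))
  freqs$sample_id <- as.character(freqs$sample_id)
  est <- estimate_ages(freqs, cfg$ci_half_width)
  write_tsv(est, p_(cfg, "estimates.tsv"))
  stage_log("age", samples = nrow(est),
            negative_ages = sum(est$negative_age))
  invisible(est)
}

#' Run the cohort-summary stage
#'
#' Merges replicate biopsies, computes concordance, sex-stratified
#' statistics and the age structure; writes `individuals.tsv`,
#' `histogram.tsv` and `cohort_summary.json`.
#'
#' @param cfg a `heaa_config`.
#' @return the summary list, invisibly.
#' @export
run_summarize <- function(cfg) {
  est <- read_tsv(p_(cfg, "estimates.tsv"))
  est$sample_id <- as.character(est$sample_id)
  sheet <- utils::read.csv(p_(cfg, "sample_sheet.csv"),
                           stringsAsFactors = FALSE,
                           colClasses = c(sample_id = "character",
                                          individual_id = "character"))
  ind <- merge_duplicates(est, sheet)
  conc <- replicate_concordance(ind)
  summ <- cohort_summary(ind)
  bins <- bin_ages(ind, cfg$bin_width)
  write_tsv(ind[, setdiff(names(ind), "ages")], p_(cfg, "individuals.tsv"))
  write_tsv(data.frame(bin_label = bins$bin_labels, bin_lower = bins$bin_lower,
                       count = bins$counts), p_(cfg, "histogram.tsv"))
  payload <- list(n_individuals = summ$n_individuals,
                  age_min = summ$age_min, age_max = summ$age_max,
                  age_mean = summ$age_mean, by_sex = summ$by_sex,
                  replicate_min_abs_diff = conc$min_abs_diff,
                  replicate_max_abs_diff = conc$max_abs_diff,
                  peak_bin = bins$peak_bin_label)
  jsonlite::write_json(payload, p_(cfg, "cohort_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage_log("summarize", individuals = summ$n_individuals,
            mean_age = summ$age_mean, peak_bin = bins$peak_bin_label)
  invisible(list(individuals = ind, concordance = conc, summary = summ,
                 bins = bins))
}

#' Run the whole pipeline
#' @param cfg a `heaa_config`.
#' @return the [run_summarize()] result, invisibly.
#' @export
run_all <- function(cfg) {
  run_simulate(cfg)
  run_process(cfg)
  run_call(cfg)
  run_age(cfg)
  run_summarize(cfg)
}
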