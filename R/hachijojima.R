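# The published Hachijojima humpback whale cohort.
#
# The study's deliverable dataset is a printed table of per-biopsy DNAm
# frequencies and coverages at the three assay CpGs for 25 biopsy samples
# of 21 whales (4 whales biopsied twice), with sex from genetic analysis.
# It ships with the package so the clock and cohort stages can be run on
# the real cohort without any sequencing input.

#' The Hachijojima humpback whale DNAm cohort
#'
#' Per-biopsy DNAm frequencies (%) and coverage depths at GRIA2+202,
#' CDKN2A+297 and TET2+31 for 25 biopsy samples of 21 whales collected off
#' Hachijojima Island (winters 2018-2021/2022), with sex, replicate
#' structure, sighting annotations, and the published age estimates (for
#' cross-checking; the pipeline recomputes them).
#'
#' @return `data.frame` with columns `sample_id`, `individual_id`, `sex`,
#'   `<GENE>_freq` / `<GENE>_cov` for the three genes, `age_published`,
#'   `ci_low_published`, `ci_high_published`, `note`.
#' @export
hachijojima_cohort <- function() {
  path <- system.file("extdata", "hachijojima_cohort.tsv", package = "heaa",
                      mustWork = TRUE)
  df <- read_tsv(path)
  df$sample_id <- as.character(df$sample_id)
  df$individual_id <- as.character(df$individual_id)
  df$note[is.na(df$note)] <- ""
  df
}

#' Clock input frequencies (x, y, z) of the Hachijojima cohort
#'
#' @param cohort optionally, a cohort table ([hachijojima_cohort()] layout).
#' @return `data.frame`: `sample_id`, `x`, `y`, `z` — ready for
#'   [estimate_ages()].
#' @export
hachijojima_frequencies <- function(cohort = hachijojima_cohort()) {
  data.frame(sample_id = cohort$sample_id,
             x = cohort$GRIA2_freq, y = cohort$CDKN2A_freq,
             z = cohort$TET2_freq, stringsAsFactors = FALSE)
}

#' Long-format per-gene frequencies and coverages
#'
#' @param cohort optionally, a cohort table ([hachijojima_cohort()] layout).
#' @return `data.frame`: `sample_id`, `gene_name`, `frequency`, `coverage`
#'   (one row per sample x gene) — ready for [frequency_table_summary()].
#' @export
hachijojima_long <- function(cohort = hachijojima_cohort()) {
  do.call(rbind, lapply(c("GRIA2", "CDKN2A", "TET2"), function(g) {
    data.frame(sample_id = cohort$sample_id, gene_name = g,
               frequency = cohort[[paste0(g, "_freq")]],
               coverage = cohort[[paste0(g, "_cov")]],
               stringsAsFactors = FALSE)
  }))
}

#' Sample sheet of the Hachijojima cohort
#'
#' @param cohort optionally, a cohort table ([hachijojima_cohort()] layout).
#' @return `data.frame`: `sample_id`, `individual_id`, `sex`, `note` — ready
#'   for [merge_duplicates()].
#' @export
hachijojima_sample_sheet <- function(cohort = hachijojima_cohort()) {
  cohort[, c("sample_id", "individual_id", "sex", "note")]
}
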