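# Individual-level cohort analysis: replicate merging and concordance,
# sex-stratified summaries, and the 5-year age structure.
#
# All summaries operate on the 2-decimal reported ages (not full-precision
# clock output): replicate consensus ages and cohort means are means of
# reported values, re-rounded for reporting, which is the convention the
# published per-individual and per-sex figures follow.

#' Merge replicate biopsies into individuals
#'
#' Samples are grouped by `individual_id`; the consensus age of an
#' individual is the arithmetic mean of its (2-decimal) per-sample ages,
#' re-rounded to 2 decimals.
#'
#' @param estimates estimates table ([estimate_ages()] output).
#' @param sample_sheet `data.frame` with `sample_id`, `individual_id`,
#'   `sex` (and optionally an annotation column `note`, echoed through).
#' @return `data.frame`, one row per individual: `individual_id`, `sex`,
#'   `n_samples`, `sample_ids` (comma-joined), `consensus_age`, plus a
#'   list-column `ages` with the per-sample reported ages.
#' @export
merge_duplicates <- function(estimates, sample_sheet) {
  stopifnot(all(c("sample_id", "individual_id", "sex") %in% names(sample_sheet)))
  miss <- setdiff(estimates$sample_id, sample_sheet$sample_id)
  if (length(miss)) {
    stop("sample(s) missing from sample sheet: ", paste(miss, collapse = ", "))
  }
  sheet <- sample_sheet[match(estimates$sample_id, sample_sheet$sample_id), ]
  ind_ids <- unique(sheet$individual_id)
  rows <- lapply(ind_ids, function(id) {
    sel <- sheet$individual_id == id
    sexes <- unique(sheet$sex[sel])
    if (length(sexes) != 1L) {
      stop("conflicting sex entries for individual ", id, ": ",
           paste(sexes, collapse = " / "))
    }
    ages <- estimates$age[sel]
    note <- if ("note" %in% names(sheet)) {
      paste(unique(sheet$note[sel][nzchar(sheet$note[sel])]), collapse = "; ")
    } else ""
    data.frame(individual_id = id, sex = sexes,
               n_samples = sum(sel),
               sample_ids = paste(estimates$sample_id[sel], collapse = ","),
               consensus_age = round_report(mean(ages)),
               note = note,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$ages <- lapply(ind_ids, function(id) estimates$age[sheet$individual_id == id])
  out
}

#' Replicate-biopsy age concordance
#'
#' Absolute differences between the two reported sample ages of every
#' twice-biopsied individual.
#'
#' @param individuals output of [merge_duplicates()].
#' @return list with `pairs` (`data.frame`: `individual_id`,
#'   `age_a`, `age_b`, `abs_diff`), `min_abs_diff`, `max_abs_diff` (both
#'   `NA` when no individual has two samples).
#' @export
replicate_concordance <- function(individuals) {
  dup <- individuals[individuals$n_samples == 2L, , drop = FALSE]
  if (!nrow(dup)) {
    return(list(pairs = data.frame(individual_id = character(0),
                                   age_a = numeric(0), age_b = numeric(0),
                                   abs_diff = numeric(0)),
                min_abs_diff = NA_real_, max_abs_diff = NA_real_))
  }
  pairs <- data.frame(
    individual_id = dup$individual_id,
    age_a = vapply(dup$ages, `[`, numeric(1), 1L),
    age_b = vapply(dup$ages, `[`, numeric(1), 2L),
    stringsAsFactors = FALSE
  )
  pairs$abs_diff <- round_report(abs(pairs$age_a - pairs$age_b))
  list(pairs = pairs,
       min_abs_diff = min(pairs$abs_diff),
       max_abs_diff = max(pairs$abs_diff))
}

#' Cohort age summary, overall and by sex
#'
#' @param individuals output of [merge_duplicates()].
#' @return list: `n_individuals`, `age_min`, `age_max`, `age_mean`
#'   (2-decimal), and `by_sex`, a `data.frame` with the same statistics per
#'   sex.
#' @export
cohort_summary <- function(individuals) {
  stopifnot(nrow(individuals) >= 1)
  a <- individuals$consensus_age
  by_sex <- do.call(rbind, lapply(sort(unique(individuals$sex)), function(s) {
    as_ <- a[individuals$sex == s]
    data.frame(sex = s, n = length(as_), age_min = min(as_),
               age_max = max(as_), age_mean = round_report(mean(as_)),
               stringsAsFactors = FALSE)
  }))
  list(n_individuals = nrow(individuals),
       age_min = min(a), age_max = max(a),
       age_mean = round_report(mean(a)),
       by_sex = by_sex)
}

#' Bin consensus ages into an age structure
#'
#' Half-open bins `[0, w)`, `[w, 2w)`, ... labelled in the
#' `"a.00-b.99"` display convention; the peak is the modal bin (ties go to
#' the youngest bin).
#'
#' @param individuals output of [merge_duplicates()].
#' @param width bin width in years (default 5).
#' @return list: `bin_lower` (numeric lower edges), `bin_labels`, `counts`,
#'   `peak_bin_label`.
#' @export
bin_ages <- function(individuals, width = 5) {
  stopifnot(width > 0)
  if (!nrow(individuals)) stop("empty cohort: nothing to bin")
  a <- individuals$consensus_age
  if (any(a < 0)) stop("negative consensus ages cannot be binned")
  n_bins <- floor(max(a) / width) + 1L
  lower <- (seq_len(n_bins) - 1L) * width
  counts <- vapply(lower, function(lo) sum(a >= lo & a < lo + width), integer(1))
  labels <- sprintf("%.2f-%.2f", lower, lower + width - 0.01)
  list(bin_lower = lower, bin_labels = labels, counts = counts,
       peak_bin_label = labels[which.max(counts)])
}

#' Per-gene frequency and coverage summary over biopsy samples
#'
#' Summarises DNAm frequency and coverage per gene across all biopsy
#' samples (replicates are not merged: the published per-gene ranges and
#' means are per biopsy).
#'
#' @param freq_long `data.frame` with columns `gene_name`, `frequency`,
#'   `coverage` (one row per sample x gene), e.g. from
#'   [hachijojima_long()].
#' @return `data.frame` per gene: `gene_name`, `n`, `freq_min`, `freq_max`,
#'   `freq_mean` (2-decimal), `cov_min`, `cov_max`, `cov_mean` (nearest
#'   integer).
#' @export
frequency_table_summary <- function(freq_long) {
  stopifnot(all(c("gene_name", "frequency", "coverage") %in% names(freq_long)))
  genes <- unique(freq_long$gene_name)
  do.call(rbind, lapply(genes, function(g) {
    d <- freq_long[freq_long$gene_name == g, ]
    data.frame(gene_name = g, n = nrow(d),
               freq_min = min(d$frequency), freq_max = max(d$frequency),
               freq_mean = round_report(mean(d$frequency)),
               cov_min = min(d$coverage), cov_max = max(d$coverage),
               cov_mean = round(mean(d$coverage)),
               stringsAsFactors = FALSE)
  }))
}

#' Report the age gap between two annotated individuals
#'
#' Convenience echo for known relationships (e.g. a sighted mother-calf
#' pair): returns both consensus ages and their gap. No kinship inference
#' is performed.
#'
#' @param individuals output of [merge_duplicates()].
#' @param id_a,id_b individual identifiers.
#' @return one-row `data.frame`: `id_a`, `age_a`, `id_b`, `age_b`,
#'   `age_gap`.
#' @export
age_gap <- function(individuals, id_a, id_b) {
  get1 <- function(id) {
    i <- match(id, individuals$individual_id)
    if (is.na(i)) stop("unknown individual: ", id)
    individuals$consensus_age[i]
  }
  a <- get1(id_a); b <- get1(id_b)
  data.frame(id_a = id_a, age_a = a, id_b = id_b, age_b = b,
             age_gap = round_report(abs(a - b)), stringsAsFactors = FALSE)
}
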