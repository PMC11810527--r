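# Bisulfite-aware alignment and per-CpG methylation counting.
#
# Merged amplicon reads are aligned ungapped against the reference panel
# with the asymmetric bisulfite rule for top-strand libraries: a read T over
# a reference C is a (converted) match, everything else that differs is a
# hard mismatch. At the assay CpG, a read C counts as methylated and a read
# T as unmethylated; any other base there (sequencing error) is excluded
# from coverage.

#' Align merged reads to the amplicon panel with C-to-T tolerance
#'
#' Every reference and every ungapped offset at which the read fits inside
#' the reference is scored: matching bases and read-T-over-reference-C are
#' accepted, anything else is a hard mismatch. The candidate with the fewest
#' hard mismatches wins (ties: reference order in `refs`, then smallest
#' offset); the read is flagged unaligned if the best hard-mismatch fraction
#' exceeds `max_mismatch_frac`.
#'
#' @param merged a merged-read table ([merge_pair()] output; rows with
#'   `merged = FALSE` are ignored) or any read table.
#' @param refs named list of `amplicon_ref`.
#' @param max_mismatch_frac maximum hard-mismatch fraction of the aligned
#'   length (default 0.1).
#' @return `data.frame`: `read_id`, `gene_name`, `start` (1-based position
#'   on the reference), `n_bs_matches` (read T over reference C),
#'   `n_hard_mismatches`, `aligned`.
#' @export
bisulfite_align <- function(merged, refs, max_mismatch_frac = 0.1) {
  stopifnot(length(refs) >= 1)
  use <- if ("merged" %in% names(merged)) which(merged$merged) else seq_len(nrow(merged))
  out <- data.frame(read_id = merged$read_id, gene_name = NA_character_,
                    start = NA_integer_, n_bs_matches = NA_integer_,
                    n_hard_mismatches = NA_integer_, aligned = FALSE,
                    stringsAsFactors = FALSE)
  if (!length(use)) return(out)
  bases <- merged$bases[use]
  lens <- nchar(bases)
  rawC <- charToRaw("C"); rawT <- charToRaw("T")
  ref_raw <- lapply(refs, function(r) charToRaw(r$sequence))

  for (L in unique(lens)) {
    idx <- which(lens == L)
    m <- str_mat(bases[idx])
    nn <- length(idx)
    best_mm <- rep(Inf, nn); best_bs <- rep(NA_integer_, nn)
    best_ref <- rep(NA_integer_, nn); best_start <- rep(NA_integer_, nn)
    for (ri in seq_along(refs)) {
      rr <- ref_raw[[ri]]
      if (L > length(rr)) next
      for (start in 1:(length(rr) - L + 1L)) {
        seg <- rr[start:(start + L - 1L)]
        is_bs <- (m == rawT) & (seg == rawC)
        hard <- .colSums((m != seg) & !is_bs, L, nn)
        bs <- .colSums(is_bs, L, nn)
        better <- hard < best_mm          # strict: earlier ref/offset wins ties
        if (any(better)) {
          best_mm[better] <- hard[better]
          best_bs[better] <- bs[better]
          best_ref[better] <- ri
          best_start[better] <- start
        }
      }
    }
    found <- is.finite(best_mm)
    rows <- use[idx]
    out$gene_name[rows[found]] <- names(refs)[best_ref[found]]
    out$start[rows[found]] <- best_start[found]
    out$n_bs_matches[rows[found]] <- as.integer(best_bs[found])
    out$n_hard_mismatches[rows[found]] <- as.integer(best_mm[found])
    out$aligned[rows[found]] <- best_mm[found] <= max_mismatch_frac * L + 1e-12
  }
  out
}

#' Count methylation at one CpG site
#'
#' Over all reads aligned to `ref` that cover `site`: a read `C` at the site
#' counts as methylated, a `T` as unmethylated, and any other base is
#' excluded from coverage.
#'
#' @param merged the merged-read table the alignments refer to.
#' @param alignments output of [bisulfite_align()] for `merged`.
#' @param ref the `amplicon_ref` whose site is called.
#' @param site 1-based reference position; must be one of
#'   `ref$cpg_positions` (defaults to the assay site).
#' @param sample_id label recorded in the call.
#' @return one-row `data.frame`: `sample_id`, `gene_name`, `site_label`,
#'   `methylated`, `unmethylated`, `ignored`, `coverage`, `frequency`
#'   (percent). Zero coverage at the site is an error (a no-call is distinct
#'   from a frequency of 0).
#' @export
call_cpg <- function(merged, alignments, ref, site = ref$target_site,
                     sample_id = "sample") {
  if (!site %in% ref$cpg_positions) {
    stop("site ", site, " is not a CpG position of ", ref$gene_name)
  }
  stopifnot(nrow(merged) == nrow(alignments),
            all(merged$read_id == alignments$read_id))
  lens <- nchar(merged$bases)
  cover <- alignments$aligned & alignments$gene_name == ref$gene_name &
    alignments$start <= site & (alignments$start + lens - 1L) >= site
  cover[is.na(cover)] <- FALSE
  if (!any(cover)) {
    stop("no aligned read covers ", ref$gene_name, " position ", site,
         " (no-call)")
  }
  at <- site - alignments$start[cover] + 1L
  base <- substr(merged$bases[cover], at, at)
  methylated <- sum(base == "C")
  unmethylated <- sum(base == "T")
  coverage <- methylated + unmethylated
  if (coverage == 0L) {
    stop("all reads covering ", ref$gene_name, " position ", site,
         " carry ambiguous bases (no-call)")
  }
  site_label <- if (site == ref$target_site) {
    paste0(ref$gene_name, ref$target_label)
  } else {
    paste0(ref$gene_name, "@", site)
  }
  data.frame(sample_id = sample_id, gene_name = ref$gene_name,
             site_label = site_label,
             methylated = methylated, unmethylated = unmethylated,
             ignored = sum(cover) - coverage, coverage = coverage,
             frequency = 100 * methylated / coverage,
             stringsAsFactors = FALSE)
}

#' Call the assay CpG of every reference for one sample
#'
#' @param merged merged-read table for one sample.
#' @param alignments output of [bisulfite_align()] for `merged`.
#' @param refs named list of `amplicon_ref`.
#' @param sample_id label recorded in the calls.
#' @return `data.frame` of [call_cpg()] rows, one per gene.
#' @export
call_targets <- function(merged, alignments, refs, sample_id = "sample") {
  do.call(rbind, lapply(refs, function(ref) {
    call_cpg(merged, alignments, ref, ref$target_site, sample_id)
  }))
}

#' Extract the clock input frequencies (x, y, z) for one sample
#'
#' Orders the per-gene calls as (GRIA2, CDKN2A, TET2) regardless of input
#' order and passes coverage through for QC. Calls below the coverage floor
#' are flagged, never dropped.
#'
#' @param calls `data.frame` of CpG calls for one sample (one row per gene).
#' @param coverage_floor minimum coverage regarded as adequate (default
#'   1000 for synthetic runs; the published assay worked above 10,000).
#' @return one-row `data.frame`: `sample_id`, `x`, `y`, `z`,
#'   `coverage_x/y/z`, `low_coverage` flag.
#' @export
sample_frequencies <- function(calls, coverage_floor = 1000) {
  genes <- c("GRIA2", "CDKN2A", "TET2")
  missing <- setdiff(genes, calls$gene_name)
  if (length(missing)) {
    stop("missing gene call(s): ", paste(missing, collapse = ", "))
  }
  ord <- calls[match(genes, calls$gene_name), ]
  data.frame(sample_id = ord$sample_id[1],
             x = ord$frequency[1], y = ord$frequency[2], z = ord$frequency[3],
             coverage_x = ord$coverage[1], coverage_y = ord$coverage[2],
             coverage_z = ord$coverage[3],
             low_coverage = any(ord$coverage < coverage_floor),
             stringsAsFactors = FALSE)
}
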