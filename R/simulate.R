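# Synthetic cohort and bisulfite read simulation.
#
# The generator works backwards from the epigenetic clock: a true age is
# drawn for each individual, the CDKN2A and TET2 assay-site frequencies are
# drawn within their empirically observed ranges, and the GRIA2 frequency is
# solved from the clock so that the clock applied to the true frequencies
# returns the true age exactly. Reads are then simulated from those
# frequencies so every downstream stage has an exact oracle.

# Empirical per-gene assay-site frequency ranges (%) observed in the
# published cohort; draws for y (CDKN2A) and z (TET2) stay inside them.
EMPIRICAL_FREQ_RANGES <- list(
  GRIA2  = c(0.66, 2.66),
  CDKN2A = c(1.34, 4.64),
  TET2   = c(5.59, 19.19)
)

#' Generate a synthetic biopsy cohort with clock-consistent ground truth
#'
#' Emulates the structure of the study cohort: `n_individuals` whales, of
#' which `duplicate_pairs` were biopsied twice (replicate samples `"<id>a"` /
#' `"<id>b"` sharing sex and age). True ages are drawn from a normal(12,
#' 6.5) truncated to `age_range`, matching the roughly normal observed age
#' structure. For each sample the CDKN2A (y) and TET2 (z) assay-site
#' frequencies are drawn uniformly within their empirical ranges and the
#' GRIA2 frequency (x) is solved from the HEAA clock, so that
#' `heaa_age(100 * meth_fraction)` equals `true_age` exactly. Draws giving x
#' outside [0, 100]% are retried (bounded), then an error is raised.
#'
#' @param n_individuals number of distinct whales (default 21).
#' @param duplicate_pairs how many whales have a replicate biopsy (default 4).
#' @param sex_ratio fraction of males (default 15/21); the male count is
#'   `round(sex_ratio * n_individuals)`.
#' @param age_range numeric length-2, inclusive age interval in years
#'   (default `c(2, 31)`).
#' @param seed integer seed.
#' @param background_meth methylation fraction at non-target CpGs (default
#'   0.02, typical of largely unmethylated promoters).
#' @param conversion_efficiency bisulfite conversion probability for
#'   unmethylated cytosines (default 1).
#' @param max_retries retries per sample when the solved x falls outside
#'   [0, 1] (default 50).
#' @return a `data.frame` of sample ground truth, one row per sample:
#'   `sample_id`, `individual_id`, `sex`, `true_age`, per-gene target
#'   methylation fractions `meth_GRIA2`/`meth_CDKN2A`/`meth_TET2`,
#'   `background_meth`, `conversion_efficiency`, and per-gene bookkeeping
#'   columns `reads_<gene>` / `methmol_<gene>` (NA until reads are
#'   simulated).
#' @export
generate_cohort <- function(n_individuals = 21, duplicate_pairs = 4,
                            sex_ratio = 15 / 21, age_range = c(2, 31),
                            seed = 1, background_meth = 0.02,
                            conversion_efficiency = 1, max_retries = 50) {
  stopifnot(n_individuals >= 1, duplicate_pairs >= 0,
            duplicate_pairs <= n_individuals,
            sex_ratio >= 0, sex_ratio <= 1,
            length(age_range) == 2, age_range[1] >= 0,
            age_range[1] <= age_range[2])
  set.seed(seed)

  n_male <- round(sex_ratio * n_individuals)
  sex <- rep("female", n_individuals)
  sex[sample(n_individuals, n_male)] <- "male"

  ages <- vapply(seq_len(n_individuals), function(i) {
    for (k in 1:1000) {
      a <- stats::rnorm(1, mean = 12, sd = 6.5)
      if (a >= age_range[1] && a <= age_range[2]) return(a)
    }
    stats::runif(1, age_range[1], age_range[2])
  }, numeric(1))

  dup_ids <- if (duplicate_pairs > 0) sort(sample(n_individuals, duplicate_pairs)) else integer(0)

  rows <- list()
  for (i in seq_len(n_individuals)) {
    reps <- if (i %in% dup_ids) c("a", "b") else ""
    for (r in reps) {
      frac <- NULL
      for (try in seq_len(max_retries)) {
        y <- stats::runif(1, EMPIRICAL_FREQ_RANGES$CDKN2A[1], EMPIRICAL_FREQ_RANGES$CDKN2A[2])
        z <- stats::runif(1, EMPIRICAL_FREQ_RANGES$TET2[1], EMPIRICAL_FREQ_RANGES$TET2[2])
        x <- solve_heaa_x(ages[i], y, z)
        if (x >= 0 && x <= 100) {
          frac <- c(GRIA2 = x, CDKN2A = y, TET2 = z) / 100
          break
        }
      }
      if (is.null(frac)) {
        stop("could not solve a methylation profile for age ", round(ages[i], 2),
             " within [0, 100]% after ", max_retries, " retries")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = paste0(i, r),
        individual_id = as.character(i),
        sex = sex[i],
        true_age = ages[i],
        meth_GRIA2 = frac[["GRIA2"]],
        meth_CDKN2A = frac[["CDKN2A"]],
        meth_TET2 = frac[["TET2"]],
        background_meth = background_meth,
        conversion_efficiency = conversion_efficiency,
        reads_GRIA2 = NA_integer_, methmol_GRIA2 = NA_integer_,
        reads_CDKN2A = NA_integer_, methmol_CDKN2A = NA_integer_,
        reads_TET2 = NA_integer_, methmol_TET2 = NA_integer_,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

# Per-position quality vector: flat base quality with an optional linear 3'
# decay ramp over the final ramp_len cycles down to ramp_min.
quality_profile <- function(read_len, base_q = 35, ramp_len = 0, ramp_min = 35) {
  q <- rep(base_q, read_len)
  ramp_len <- min(ramp_len, read_len)
  if (ramp_len > 0) {
    q[(read_len - ramp_len + 1):read_len] <-
      round(seq(base_q, ramp_min, length.out = ramp_len))
  }
  as.integer(q)
}

# Substitution errors at a fixed per-base rate; replaces the hit base with
# one of the other three uniformly.
add_seq_errors <- function(bases, error_rate) {
  if (error_rate <= 0 || !length(bases)) return(bases)
  lens <- nchar(bases)
  for (L in unique(lens)) {
    idx <- which(lens == L)
    m <- str_mat(bases[idx])
    hit <- which(stats::runif(length(m)) < error_rate)
    if (length(hit)) {
      old <- rawToChar(m[hit], multiple = TRUE)
      shift <- sample(1:3, length(hit), replace = TRUE)
      new <- DNA_BASES[(match(old, DNA_BASES) - 1L + shift) %% 4L + 1L]
      m[hit] <- charToRaw(paste(new, collapse = ""))
    }
    bases[idx] <- mat_str(m)
  }
  bases
}

#' Simulate bisulfite paired-end reads for one sample
#'
#' For each amplicon, `reads_per_gene` top-strand molecules are drawn from
#' the reference and bisulfite-converted in silico: the target CpG cytosine
#' stays `C` with probability `meth_fraction`, other CpG cytosines with
#' probability `background_meth`, and every unmethylated cytosine converts
#' to `T` with probability `conversion_efficiency`. Read 1 covers the
#' molecule from its 5' end, read 2 is the reverse complement from the 3'
#' end; when the molecule is shorter than the read length the read runs
#' through into the reverse complement of the opposite universal adapter
#' tail (Illumina read-through), which is what the adapter trimmer removes.
#' Substitution errors are applied independently to both mates.
#'
#' The exact count of molecules drawn methylated at each target CpG is
#' recorded in the returned truth row (`methmol_<gene>`), giving downstream
#' stages an exact oracle.
#'
#' @param truth one row of the table from [generate_cohort()].
#' @param refs named list of `amplicon_ref` (see [default_references()]).
#' @param reads_per_gene molecules simulated per amplicon (default 2000).
#' @param error_rate per-base substitution error probability (< 0.1;
#'   default 0).
#' @param seed integer seed.
#' @param read_len read length in bp (default 250).
#' @param base_q,ramp_len,ramp_min quality profile: flat `base_q` (default
#'   Q35) with an optional linear 3' decay over the last `ramp_len` cycles
#'   down to `ramp_min`.
#' @return list with `r1` and `r2` read tables and the updated `truth` row.
#' @export
simulate_reads <- function(truth, refs, reads_per_gene = 2000, error_rate = 0,
                           seed = 1, read_len = 250, base_q = 35,
                           ramp_len = 0, ramp_min = 35) {
  stopifnot(nrow(truth) == 1, reads_per_gene >= 1,
            error_rate >= 0, error_rate < 0.1)
  set.seed(seed)
  r1_all <- list(); r2_all <- list()
  for (ref in refs) {
    g <- ref$gene_name
    L <- nchar(ref$sequence)
    if (L > 2 * read_len - 10) {
      stop("amplicon ", g, " (", L, " bp) is too long for ", read_len,
           " bp reads to overlap for merging")
    }
    n <- reads_per_gene
    ch <- strsplit(ref$sequence, "")[[1]]
    m <- matrix(rep(ch, n), nrow = L)

    c_pos <- which(ch == "C")
    target <- ref$target_site
    other_cpg <- setdiff(ref$cpg_positions, target)
    nonc_cpg <- setdiff(c_pos, ref$cpg_positions)
    ce <- truth$conversion_efficiency
    mf <- truth[[paste0("meth_", g)]]
    bg <- truth$background_meth

    convert_site <- function(pos, meth_prob) {
      meth <- stats::runif(n) < meth_prob
      conv <- stats::runif(n) < ce
      m[pos, !meth & conv] <<- "T"
      meth
    }
    meth_target <- convert_site(target, mf)
    for (p in other_cpg) convert_site(p, bg)
    for (p in nonc_cpg) convert_site(p, 0)

    mol <- apply(m, 2, paste, collapse = "")
    frag1 <- paste0(mol, revcomp(ref$adapter_rev))
    frag2 <- paste0(revcomp(mol), revcomp(ref$adapter_fwd))
    b1 <- substr(frag1, 1, min(read_len, nchar(frag1[1])))
    b2 <- substr(frag2, 1, min(read_len, nchar(frag2[1])))
    b1 <- add_seq_errors(b1, error_rate)
    b2 <- add_seq_errors(b2, error_rate)

    q1 <- int_to_qual(quality_profile(nchar(b1[1]), base_q, ramp_len, ramp_min))
    q2 <- int_to_qual(quality_profile(nchar(b2[1]), base_q, ramp_len, ramp_min))
    ids <- sprintf("%s|%s|%05d", truth$sample_id, g, seq_len(n))
    r1_all[[g]] <- read_frame(ids, b1, rep(q1, n))
    r2_all[[g]] <- read_frame(ids, b2, rep(q2, n))

    truth[[paste0("reads_", g)]] <- n
    truth[[paste0("methmol_", g)]] <- sum(meth_target)
  }
  list(r1 = do.call(rbind, r1_all), r2 = do.call(rbind, r2_all), truth = truth)
}
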