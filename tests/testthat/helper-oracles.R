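# Independent brute-force oracles used to freeze expected values. These are
# deliberately naive (straight loops over every possibility) and share no
# code with the implementation they check.

# All suffix(read)/prefix(adapter) exact overlaps; returns the kept read
# length after removing the longest admissible suffix match (or a full
# internal occurrence).
oracle_trim_len <- function(bases, adapter, min_match = 3) {
  n <- nchar(bases); a <- nchar(adapter)
  for (start in seq_len(max(0, n - a + 1))) {
    if (substr(bases, start, start + a - 1) == adapter) return(start - 1L)
  }
  best <- 0L
  for (k in seq_len(min(a - 1L, n))) {
    if (substr(bases, n - k + 1L, n) == substr(adapter, 1L, k) && k >= min_match) {
      best <- k
    }
  }
  n - best
}

# Longest admissible overlap between r1 and the reverse-complemented r2.
# Returns list(overlap, mismatches) or NULL.
oracle_overlap <- function(b1, rc2, min_overlap, max_frac) {
  n1 <- nchar(b1); n2 <- nchar(rc2)
  for (o in rev(seq(min_overlap, min(n1, n2)))) {
    s1 <- strsplit(substr(b1, n1 - o + 1L, n1), "")[[1]]
    s2 <- strsplit(substr(rc2, 1L, o), "")[[1]]
    mm <- sum(s1 != s2)
    if (mm / o <= max_frac) return(list(overlap = o, mismatches = mm))
  }
  NULL
}

# Minimum hard-mismatch fraction of a read over every reference and every
# ungapped offset, under the read-T-over-ref-C tolerance.
oracle_min_mismatch_frac <- function(read, refs) {
  rch <- strsplit(read, "")[[1]]
  L <- length(rch)
  best <- Inf
  for (ref in refs) {
    ch <- strsplit(ref$sequence, "")[[1]]
    if (L > length(ch)) next
    for (start in seq_len(length(ch) - L + 1L)) {
      seg <- ch[start:(start + L - 1L)]
      hard <- sum(rch != seg & !(rch == "T" & seg == "C"))
      best <- min(best, hard / L)
    }
  }
  best
}

# Half-open binning by scalar loop.
oracle_bins <- function(ages, width) {
  nb <- floor(max(ages) / width) + 1
  counts <- integer(nb)
  for (a in ages) {
    counts[floor(a / width) + 1] <- counts[floor(a / width) + 1] + 1L
  }
  counts
}

# Simple fixtures -----------------------------------------------------------

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# One-row ground-truth table as generate_cohort() would emit it.
make_truth <- function(sample_id = "s1", x = 0.016, y = 0.02, z = 0.11,
                       background = 0.02, ce = 1) {
  data.frame(sample_id = sample_id, individual_id = sample_id, sex = "male",
             true_age = heaa_age(100 * x, 100 * y, 100 * z),
             meth_GRIA2 = x, meth_CDKN2A = y, meth_TET2 = z,
             background_meth = background, conversion_efficiency = ce,
             reads_GRIA2 = NA_integer_, methmol_GRIA2 = NA_integer_,
             reads_CDKN2A = NA_integer_, methmol_CDKN2A = NA_integer_,
             reads_TET2 = NA_integer_, methmol_TET2 = NA_integer_,
             stringsAsFactors = FALSE)
}

# Read table with uniform quality.
make_reads <- function(bases, q = 40, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("r%03d", seq_along(bases))
  quals <- vapply(nchar(bases), function(n) int_to_qual(rep(q, n)), character(1))
  read_frame(ids, bases, quals)
}

# Run simulate -> process -> call in memory for one truth table and return
# per-sample/gene recovered frequencies next to the simulator bookkeeping.
run_pipeline_mem <- function(truth, refs, reads_per_gene, error_rate, seed,
                             min_overlap = 10) {
  rows <- list()
  ad1 <- revcomp(refs[[1]]$adapter_rev)
  ad2 <- revcomp(refs[[1]]$adapter_fwd)
  for (i in seq_len(nrow(truth))) {
    sim <- simulate_reads(truth[i, ], refs, reads_per_gene = reads_per_gene,
                          error_rate = error_rate, seed = seed + i)
    r1 <- trim_adapter(sim$r1, ad1)
    r2 <- trim_adapter(sim$r2, ad2)
    f1 <- quality_filter(r1)
    f2 <- quality_filter(r2)
    keep <- intersect(f1$read_id, f2$read_id)
    f1 <- f1[match(keep, f1$read_id), ]
    f2 <- f2[match(keep, f2$read_id), ]
    m <- merge_pair(f1, f2, min_overlap = min_overlap)
    mm <- m[m$merged, ]
    aln <- bisulfite_align(mm, refs)
    calls <- call_targets(mm, aln, refs, sample_id = truth$sample_id[i])
    tr <- sim$truth
    calls$true_freq <- vapply(calls$gene_name, function(g) {
      100 * tr[[paste0("methmol_", g)]] / tr[[paste0("reads_", g)]]
    }, numeric(1))
    calls$true_fraction <- vapply(calls$gene_name, function(g) {
      tr[[paste0("meth_", g)]]
    }, numeric(1))
    rows[[i]] <- calls
  }
  do.call(rbind, rows)
}
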