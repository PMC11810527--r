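# Amplicon references for the three HEAA genes.
#
# The assay amplifies one promoter fragment each of GRIA2, CDKN2A and TET2
# with a two-step PCR; the first-PCR primers carry universal tails on which
# the Illumina sequencing primers sit. Published primer sequences give the
# amplicon ends but not the amplicon interiors or genomic coordinates, so
# references are generated synthetically: primer-anchored sequences with
# CpG sites planted at known offsets. The assay CpG labels ("+202", "+297",
# "+31") are display names bound to a reference offset, not genomic
# coordinates.

# Universal tails shared by all first-PCR primers (read-1 / read-2
# sequencing-primer binding sites).
ADAPTER_FWD <- "ACACTCTTTCCCTACACGACGCTCTTCCGATCT"
ADAPTER_REV <- "GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT"

# Gene-specific first-PCR primer portions. Forward primers contain no C and
# reverse primers no G: bisulfite PCR primers anneal to converted template,
# so the primer-covered ends of the top strand are cytosine-free and
# untouched by conversion.
GENE_PRIMERS <- list(
  GRIA2  = list(fwd = "GTGTGTGAGTGTATGGG",
                rev = "CCCTATTTCCCAAATCCTAC",
                target_label = "+202"),
  CDKN2A = list(fwd = "AATGATTTTTGGTAAAGGGGAGAT",
                rev = "CCCCATATACTTTTCAATCCTCC",
                target_label = "+297"),
  TET2   = list(fwd = "GTGGTTAAAGTAAATAGAAGGT",
                rev = "CAAAAACACTCCCCAATTTC",
                target_label = "+31")
)

#' Build a synthetic amplicon reference
#'
#' Constructs a primer-anchored amplicon sequence with `n_cpgs` CpG
#' dinucleotides planted at random interior offsets, one of which is
#' designated the assay (target) CpG. The forward primer is the sequence
#' prefix and the reverse complement of the reverse primer its suffix; no
#' CpG overlaps a primer-binding region.
#'
#' @param gene_name gene label; for `"GRIA2"`, `"CDKN2A"`, `"TET2"` the
#'   published first-PCR primers and assay-site labels are used by default.
#' @param length total amplicon length in bp (120–500, so that a 250 bp x 2
#'   read pair spans it).
#' @param n_cpgs number of CpG sites to plant (at most `length / 10`).
#' @param target_index which planted CpG (1-based) is the assay site.
#' @param seed integer seed; generation is deterministic given the seed.
#' @param fwd_primer,rev_primer gene-specific primer portions; defaults come
#'   from the published primer table for the three assay genes.
#' @param target_label display label for the assay CpG (e.g. `"+202"`).
#' @return an object of class `amplicon_ref`: a list with `gene_name`,
#'   `sequence`, `cpg_positions` (1-based offsets of CpG cytosines),
#'   `target_site`, `target_label`, `fwd_primer`, `rev_primer`,
#'   `adapter_fwd`, `adapter_rev`.
#' @export
build_reference <- function(gene_name, length, n_cpgs, target_index, seed,
                            fwd_primer = NULL, rev_primer = NULL,
                            target_label = NULL) {
  if (length < 120 || length > 500) {
    stop("amplicon length must be between 120 and 500 bp")
  }
  if (n_cpgs < 1 || n_cpgs > length / 10) {
    stop("n_cpgs must be between 1 and length/10")
  }
  if (target_index < 1 || target_index > n_cpgs) {
    stop("target_index must select one of the planted CpGs")
  }
  known <- GENE_PRIMERS[[gene_name]]
  if (is.null(fwd_primer)) fwd_primer <- known$fwd
  if (is.null(rev_primer)) rev_primer <- known$rev
  if (is.null(target_label)) {
    target_label <- if (!is.null(known)) known$target_label else "+1"
  }
  if (is.null(fwd_primer) || is.null(rev_primer)) {
    stop("no default primers for gene '", gene_name,
         "'; supply fwd_primer and rev_primer")
  }
  suffix <- revcomp(rev_primer)
  nf <- nchar(fwd_primer)
  nr <- nchar(suffix)
  int_len <- length - nf - nr
  # Interior must hold n_cpgs non-adjacent CG pairs away from both junctions.
  if (int_len < 3 * n_cpgs + 4) {
    stop("cannot place ", n_cpgs, " CpG sites in a ", int_len,
         " bp interior; increase length or reduce n_cpgs")
  }

  set.seed(seed)
  # Base interior from a C-free alphabet; cytosines are added deliberately so
  # the CpG inventory is exhaustive by construction.
  interior <- sample(c("A", "G", "T"), int_len, replace = TRUE)

  # Plant CG pairs at offsets spaced >= 3 apart, leaving the first and the
  # two final interior positions untouched (no CpG straddles a junction).
  slots <- seq(2L, int_len - 2L)
  cpg_int <- integer(0)
  for (i in seq_len(n_cpgs)) {
    ok <- slots[!slots %in% as.vector(outer(cpg_int, -2:2, `+`))]
    if (!length(ok)) stop("ran out of CpG placement slots; reduce n_cpgs")
    p <- sample(ok, 1L)
    cpg_int <- c(cpg_int, p)
  }
  cpg_int <- sort(cpg_int)
  interior[cpg_int] <- "C"
  interior[cpg_int + 1L] <- "G"

  # Sprinkle non-CpG cytosines (about one per eight interior bases) at
  # positions that cannot create a CG dinucleotide.
  n_extra <- max(1L, int_len %/% 8L)
  cand <- setdiff(seq_len(int_len - 1L), c(cpg_int, cpg_int + 1L, cpg_int - 1L))
  cand <- cand[interior[cand + 1L] != "G"]
  if (length(cand)) {
    extra <- sample(cand, min(n_extra, length(cand)))
    interior[extra] <- "C"
  }

  sequence <- paste0(fwd_primer, paste(interior, collapse = ""), suffix)
  cpg_positions <- nf + cpg_int
  ref <- structure(list(
    gene_name = gene_name,
    sequence = sequence,
    cpg_positions = cpg_positions,
    target_site = cpg_positions[target_index],
    target_label = target_label,
    fwd_primer = fwd_primer,
    rev_primer = rev_primer,
    adapter_fwd = ADAPTER_FWD,
    adapter_rev = ADAPTER_REV
  ), class = "amplicon_ref")
  validate_reference(ref)
  ref
}

#' Validate an amplicon reference
#'
#' Checks the structural invariants: CpG positions are genuine CG
#' dinucleotides, the target site is one of them, and the primers anchor the
#' sequence ends.
#'
#' @param ref an `amplicon_ref`.
#' @return `ref`, invisibly; errors on violation.
#' @export
validate_reference <- function(ref) {
  s <- ref$sequence
  n <- nchar(s)
  if (n < 120 || n > 500) stop("reference length out of range [120, 500]")
  ch <- strsplit(s, "")[[1]]
  for (p in ref$cpg_positions) {
    if (p < 1 || p >= n || ch[p] != "C" || ch[p + 1] != "G") {
      stop("position ", p, " is not a CpG cytosine in ", ref$gene_name)
    }
  }
  if (!ref$target_site %in% ref$cpg_positions) {
    stop("target_site is not among cpg_positions")
  }
  if (substr(s, 1, nchar(ref$fwd_primer)) != ref$fwd_primer) {
    stop("forward primer is not a prefix of the reference")
  }
  sfx <- revcomp(ref$rev_primer)
  if (substr(s, n - nchar(sfx) + 1, n) != sfx) {
    stop("reverse-complemented reverse primer is not a suffix of the reference")
  }
  invisible(ref)
}

#' @export
print.amplicon_ref <- function(x, ...) {
  cat(sprintf("amplicon_ref %s (%d bp): %d CpG site(s), assay CpG %s%s at offset %d\n",
              x$gene_name, nchar(x$sequence), length(x$cpg_positions),
              x$gene_name, x$target_label, x$target_site))
  invisible(x)
}

#' Default three-gene reference set
#'
#' The standard assay panel: one synthetic amplicon each for GRIA2, CDKN2A
#' and TET2, anchored on the published primers, with the assay CpG labels
#' "+202", "+297" and "+31". Lengths are chosen so a 250 bp x 2 pair spans
#' each amplicon with a long overlap.
#'
#' @param seed integer seed controlling interior sequence generation.
#' @return named list of `amplicon_ref` objects.
#' @export
default_references <- function(seed = 104729) {
  list(
    GRIA2  = build_reference("GRIA2",  240, 6, 3, seed = seed),
    CDKN2A = build_reference("CDKN2A", 234, 5, 2, seed = seed + 1L),
    TET2   = build_reference("TET2",   228, 4, 2, seed = seed + 2L)
  )
}

#' Write amplicon references to FASTA + metadata TSV
#'
#' The sequence goes to FASTA (via Biostrings); CpG coordinates, the target
#' site and primers go to a sidecar TSV so a reference set round-trips
#' through disk losslessly.
#'
#' @param refs named list of `amplicon_ref`.
#' @param fasta,meta output paths.
#' @return invisibly, `c(fasta, meta)`.
#' @export
write_references <- function(refs, fasta, meta) {
  x <- Biostrings::DNAStringSet(vapply(refs, `[[`, character(1), "sequence"))
  names(x) <- vapply(refs, `[[`, character(1), "gene_name")
  Biostrings::writeXStringSet(x, fasta)
  df <- do.call(rbind, lapply(refs, function(r) {
    data.frame(gene_name = r$gene_name,
               target_site = r$target_site,
               target_label = r$target_label,
               cpg_positions = paste(r$cpg_positions, collapse = ","),
               fwd_primer = r$fwd_primer, rev_primer = r$rev_primer,
               adapter_fwd = r$adapter_fwd, adapter_rev = r$adapter_rev,
               stringsAsFactors = FALSE)
  }))
  write_tsv(df, meta)
  invisible(c(fasta, meta))
}

#' Read amplicon references from FASTA + metadata TSV
#' @param fasta,meta paths written by [write_references()].
#' @return named list of `amplicon_ref`.
#' @export
read_references <- function(fasta, meta) {
  x <- Biostrings::readDNAStringSet(fasta)
  df <- read_tsv(meta)
  refs <- lapply(seq_len(nrow(df)), function(i) {
    g <- df$gene_name[i]
    ref <- structure(list(
      gene_name = g,
      sequence = as.character(x[[g]]),
      cpg_positions = as.integer(strsplit(df$cpg_positions[i], ",")[[1]]),
      target_site = df$target_site[i],
      target_label = df$target_label[i],
      fwd_primer = df$fwd_primer[i], rev_primer = df$rev_primer[i],
      adapter_fwd = df$adapter_fwd[i], adapter_rev = df$adapter_rev[i]
    ), class = "amplicon_ref")
    validate_reference(ref)
  })
  names(refs) <- df$gene_name
  refs
}
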