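# Read-level processing: adapter trimming, quality filtering and
# quality-aware overlap merging of read pairs.
#
# These are deliberately simple, deterministic analogues of the usual
# trimming/merging tools, sufficient for amplicon data where every proper
# pair spans the full amplicon: exact-match adapter suffix trimming,
# end-trimming quality filtering (not a sliding window), and
# longest-admissible-overlap merging with quality-weighted consensus.
# All three operate on read tables (see read_frame()) and are vectorised.

#' Trim 3' adapter read-through from reads
#'
#' Removes the classic Illumina read-through adapter: any full occurrence of
#' `adapter` truncates the read at the occurrence start; otherwise the
#' longest read suffix that exactly matches an adapter prefix of at least
#' `min_match` bases is removed. Qualities are trimmed in lockstep.
#'
#' @param reads a read table.
#' @param adapter the adapter sequence to remove (non-empty).
#' @param min_match minimum suffix/prefix overlap to trim (>= 3).
#' @return the read table with trimmed `bases`/`quals`; attribute
#'   `n_trimmed` counts reads that lost bases.
#' @export
trim_adapter <- function(reads, adapter, min_match = 3) {
  if (is.null(adapter) || !nzchar(adapter)) stop("adapter must be non-empty")
  stopifnot(min_match >= 3)
  if (!nrow(reads)) return(reads)
  len <- nchar(reads$bases)
  keep <- len
  # Full (internal or terminal) occurrence: cut at its start.
  pos <- regexpr(adapter, reads$bases, fixed = TRUE)
  hit <- pos > 0L
  keep[hit] <- pos[hit] - 1L
  # Partial read-through: longest suffix matching an adapter prefix.
  alen <- nchar(adapter)
  open <- !hit
  kmax <- min(alen - 1L, max(len))
  for (k in if (kmax >= min_match) seq(kmax, min_match) else integer(0)) {
    if (!any(open)) break
    cand <- open & len >= k &
      substr(reads$bases, len - k + 1L, len) == substr(adapter, 1L, k)
    keep[cand] <- len[cand] - k
    open <- open & !cand
  }
  out <- reads
  out$bases <- substr(reads$bases, 1L, keep)
  out$quals <- substr(reads$quals, 1L, keep)
  attr(out, "n_trimmed") <- sum(keep < len)
  out
}

#' Quality-filter reads (end trimming + minimum length)
#'
#' Bases are trimmed from the 3' end, then the 5' end, while the terminal
#' base quality is at or below `min_q`; reads whose surviving length is at
#' or below `min_len` are discarded (a 40 bp survivor is discarded under
#' the defaults, a 41 bp survivor kept).
#'
#' @param reads a read table.
#' @param min_q Phred threshold; terminal bases with quality `<= min_q` are
#'   trimmed (default 20).
#' @param min_len reads of length `<= min_len` after trimming are discarded
#'   (default 40).
#' @return the surviving reads (trimmed); attribute `n_discarded` counts
#'   dropped reads.
#' @export
quality_filter <- function(reads, min_q = 20, min_len = 40) {
  if (!nrow(reads)) {
    attr(reads, "n_discarded") <- 0L
    return(reads)
  }
  lo <- rep(1L, nrow(reads))
  hi <- nchar(reads$bases)
  term_q <- function(pos) {
    q <- rep(NA_integer_, length(pos))
    ok <- hi >= lo
    if (any(ok)) {
      q[ok] <- as.integer(charToRaw(paste(substr(reads$quals, pos, pos)[ok],
                                          collapse = ""))) - 33L
    }
    q
  }
  repeat {
    q <- term_q(hi)
    cut <- !is.na(q) & q <= min_q
    if (!any(cut)) break
    hi[cut] <- hi[cut] - 1L
  }
  repeat {
    q <- term_q(lo)
    cut <- !is.na(q) & q <= min_q
    if (!any(cut)) break
    lo[cut] <- lo[cut] + 1L
  }
  surv_len <- pmax(0L, hi - lo + 1L)
  keep <- surv_len > min_len
  out <- reads[keep, , drop = FALSE]
  out$bases <- substr(out$bases, lo[keep], hi[keep])
  out$quals <- substr(out$quals, lo[keep], hi[keep])
  rownames(out) <- NULL
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Merge read pairs by overlap consensus
#'
#' Reverse-complements read 2, scans overlap lengths from the maximum
#' possible down to `min_overlap`, and accepts the longest overlap whose
#' mismatch fraction is at most `max_mismatch_frac`. In the overlap the
#' higher-quality base wins at disagreements (ties go to read 1, making the
#' output a pure function of input order); consensus quality is the maximum
#' of the two at agreements and the winner's at disagreements.
#'
#' @param r1,r2 read tables of the two mates, matched row-by-row by
#'   `read_id` (`r2` is the raw second read; it is reverse-complemented
#'   internally).
#' @param min_overlap minimum admissible overlap length (default 10).
#' @param max_mismatch_frac maximum fraction of mismatching positions in
#'   the accepted overlap (default 0.25).
#' @return a `data.frame` with one row per input pair: `read_id`, `bases`,
#'   `quals`, `overlap_len`, `mismatches_in_overlap`, `merged`. Pairs with
#'   no admissible overlap have `merged = FALSE` and `NA` sequence.
#' @export
merge_pair <- function(r1, r2, min_overlap = 10, max_mismatch_frac = 0.25) {
  stopifnot(nrow(r1) == nrow(r2), all(r1$read_id == r2$read_id),
            min_overlap >= 1)
  n <- nrow(r1)
  out <- data.frame(read_id = r1$read_id, bases = NA_character_,
                    quals = NA_character_, overlap_len = NA_integer_,
                    mismatches_in_overlap = NA_integer_, merged = FALSE,
                    stringsAsFactors = FALSE)
  if (!n) return(out)
  b1 <- r1$bases; q1 <- r1$quals
  b2 <- revcomp(r2$bases); q2 <- str_rev(r2$quals)
  L1 <- nchar(b1); L2 <- nchar(b2)

  grp_key <- paste(L1, L2)
  for (key in unique(grp_key)) {
    idx <- which(grp_key == key)
    l1 <- L1[idx[1]]; l2 <- L2[idx[1]]
    omax <- min(l1, l2)
    if (omax < min_overlap) next
    open <- idx
    for (o in seq(omax, min_overlap)) {
      if (!length(open)) break
      s1 <- str_mat(substr(b1[open], l1 - o + 1L, l1))
      s2 <- str_mat(substr(b2[open], 1L, o))
      mm <- .colSums(s1 != s2, o, length(open))
      ok <- mm <= max_mismatch_frac * o + 1e-12
      if (any(ok)) {
        acc <- open[ok]
        u1 <- s1[, ok, drop = FALSE]; u2 <- s2[, ok, drop = FALSE]
        p1 <- str_mat(substr(q1[acc], l1 - o + 1L, l1))
        p2 <- str_mat(substr(q2[acc], 1L, o))
        p1i <- matrix(as.integer(p1), nrow = o)
        p2i <- matrix(as.integer(p2), nrow = o)
        differ <- u1 != u2
        take2 <- differ & (p2i > p1i)        # r2 wins only on strictly higher quality
        cons_b <- u1; cons_b[take2] <- u2[take2]
        cons_qi <- pmax(p1i, p2i)
        cons_qi[differ] <- p1i[differ]
        cons_qi[take2] <- p2i[take2]
        cons_q <- matrix(as.raw(cons_qi), nrow = o)
        out$bases[acc] <- paste0(substr(b1[acc], 1L, l1 - o),
                                 mat_str(cons_b),
                                 substr(b2[acc], o + 1L, l2))
        out$quals[acc] <- paste0(substr(q1[acc], 1L, l1 - o),
                                 mat_str(cons_q),
                                 substr(q2[acc], o + 1L, l2))
        out$overlap_len[acc] <- o
        out$mismatches_in_overlap[acc] <- as.integer(mm[ok])
        out$merged[acc] <- TRUE
        open <- open[!ok]
      }
    }
  }
  out
}
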