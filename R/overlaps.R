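## Pairwise peak-set comparison and cell-type-specificity counting.
##
## Two peaks overlap when more than `fraction` (default one half) of the
## narrower peak is covered by the wider peak; the inequality is strict.

## overlap width of [as, ae) and [bs, be), vectorised
.ov_width <- function(as, ae, bs, be) pmax(0L, pmin(ae, be) - pmax(as, bs))

#' Do two peaks overlap (more-than-half-of-narrower rule)?
#'
#' TRUE iff the peaks are on the same chromosome and their overlap width
#' strictly exceeds `fraction` times the width of the narrower peak. Equal
#' widths treat `a` as the narrower (the result is unaffected).
#'
#' @param a,b single peaks: lists or one-row data frames with `chrom`,
#'   `start`, `end`.
#' @param fraction required fraction of the narrower peak, in (0, 1\].
#' @return logical.
#' @examples
#' p <- function(s, e) list(chrom = "chr1", start = s, end = e)
#' peaks_overlap(p(100, 300), p(150, 600))  # 150 bp = 75% of 200 -> TRUE
#' peaks_overlap(p(0, 100), p(50, 150))     # exactly 50% -> FALSE
#' @export
peaks_overlap <- function(a, b, fraction = 0.5) {
  stopifnot(fraction > 0, fraction <= 1)
  if (a$chrom != b$chrom) return(FALSE)
  wa <- a$end - a$start
  wb <- b$end - b$start
  narrower <- min(wa, wb)
  ov <- .ov_width(a$start, a$end, b$start, b$end)
  ov > fraction * narrower
}

## For each peak in X, does any peak in Y qualify under the rule?
## Per-chromosome candidate windows via sorted starts + cummax(end).
.has_partner <- function(X, Y, fraction) {
  out <- logical(nrow(X))
  for (cc in unique(X$chrom)) {
    xi <- which(X$chrom == cc)
    Ysub <- Y[Y$chrom == cc, , drop = FALSE]
    if (!nrow(Ysub)) next
    o <- order(Ysub$start)
    ys <- Ysub$start[o]; ye <- Ysub$end[o]
    cm <- cummax(ye)
    for (i in xi) {
      hi <- findInterval(X$end[i] - 1L, ys)        # last y with start < x.end
      if (hi < 1L) next
      lo <- findInterval(X$start[i], cm) + 1L      # first y with cummax(end) > x.start
      if (lo > hi) next
      j <- lo:hi
      ov <- .ov_width(X$start[i], X$end[i], ys[j], ye[j])
      narrower <- pmin(X$end[i] - X$start[i], ye[j] - ys[j])
      if (any(ov > fraction * narrower)) out[i] <- TRUE
    }
  }
  out
}

#' Pairwise overlap statistics between two peak sets
#'
#' Counts, in each direction, the peaks having at least one qualifying
#' partner in the other set under [peaks_overlap()]. The headline
#' `n_common` and `pct_smaller` are referenced to the set with fewer peaks;
#' `pct_larger` is the symmetric figure for the larger set. Percentages are
#' rounded half-up to 2 decimals.
#'
#' @param A,B [sample_set()] objects or peak data frames; both non-empty.
#' @param fraction overlap fraction, see [peaks_overlap()].
#' @return list with `n_a`, `n_b`, `n_common`, `pct_smaller`, `pct_larger`.
#' @export
pairwise_overlap_stats <- function(A, B, fraction = 0.5) {
  pa <- .peaks_of(A); pb <- .peaks_of(B)
  if (!nrow(pa) || !nrow(pb)) stop("both peak sets must be non-empty")
  a_hits <- sum(.has_partner(pa, pb, fraction))
  b_hits <- sum(.has_partner(pb, pa, fraction))
  if (nrow(pa) <= nrow(pb)) {
    n_common <- a_hits
    pct_smaller <- percentage(a_hits, nrow(pa))
    pct_larger <- percentage(b_hits, nrow(pb))
  } else {
    n_common <- b_hits
    pct_smaller <- percentage(b_hits, nrow(pb))
    pct_larger <- percentage(a_hits, nrow(pa))
  }
  list(n_a = nrow(pa), n_b = nrow(pb), n_common = n_common,
       pct_smaller = pct_smaller, pct_larger = pct_larger)
}

#' Partition peaks into stimulated-unique, unstimulated-unique and common
#'
#' A stimulated and an unstimulated peak satisfying [peaks_overlap()]
#' define one common locus; each peak participates in at most one common
#' locus, matched greedily in genomic order. Unique counts are the
#' remainders. Inputs are expected to be pre-filtered to the FDR presence
#' cutoff (see [filter_fdr()]).
#'
#' @param stim,unstim [sample_set()] objects or peak data frames.
#' @param fraction overlap fraction.
#' @return list with `unique_stim`, `unique_unstim`, `common`.
#' @export
stim_unstim_partition <- function(stim, unstim, fraction = 0.5) {
  ps <- .peaks_of(stim); pu <- .peaks_of(unstim)
  ps <- ps[order(ps$chrom, ps$start, ps$end), , drop = FALSE]
  pu <- pu[order(pu$chrom, pu$start, pu$end), , drop = FALSE]
  matched_u <- logical(nrow(pu))
  common <- 0L
  for (i in seq_len(nrow(ps))) {
    a <- list(chrom = ps$chrom[i], start = ps$start[i], end = ps$end[i])
    for (j in seq_len(nrow(pu))) {
      if (matched_u[j]) next
      b <- list(chrom = pu$chrom[j], start = pu$start[j], end = pu$end[j])
      if (peaks_overlap(a, b, fraction)) {
        matched_u[j] <- TRUE
        common <- common + 1L
        break
      }
    }
  }
  list(unique_stim = nrow(ps) - common,
       unique_unstim = nrow(pu) - common,
       common = common)
}

#' Cell-type-specificity category counts
#'
#' Histogram of the number of cell types each consensus peak is present in
#' (1..K).
#'
#' @param consensus a `consensus_set` from [assign_sample_metrics()], or an
#'   integer vector of per-peak cell-type counts.
#' @param K total number of cell types.
#' @return named integer vector of length K; `counts[k]` is the number of
#'   consensus peaks present in exactly k cell types.
#' @export
specificity_categories <- function(consensus, K) {
  n_ct <- if (inherits(consensus, "consensus_set")) consensus$n_cell_types
          else as.integer(consensus)
  if (any(n_ct < 1L | n_ct > K))
    stop("n_cell_types values must lie in 1..K")
  counts <- tabulate(n_ct, nbins = K)
  names(counts) <- as.character(seq_len(K))
  counts
}
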