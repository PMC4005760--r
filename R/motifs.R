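## Motif scanning around peak summits: best hits, threshold sweeps,
## summit-centred density profiles, FE-ranked DR3 percentage curves and
## signed motif-to-SNP distances.

## cache chromosome sequences of a genome as plain character strings
.genome_chars <- function(genome, chroms) {
  out <- vapply(unique(chroms), function(cc) {
    if (!cc %in% names(genome)) stop("unknown chromosome '", cc, "'")
    as.character(genome[[cc]])
  }, character(1))
  names(out) <- unique(chroms)
  out
}

#' Best motif hit around one summit
#'
#' Scans every motif start offset in `[summit - flank, summit + flank -
#' motif_length]` on both strands of the `[summit - flank, summit + flank)`
#' window (the full motif must fit inside the window; parts of the window
#' beyond the chromosome are N-padded). Returns the highest-scoring hit
#' with score strictly above `threshold`, ties broken by offset ascending
#' then `+` before `-`; `NULL` when nothing exceeds the threshold.
#'
#' @param pwm a [pwm_from_iupac()] object.
#' @param genome `DNAStringSet` or FASTA path.
#' @param chrom chromosome name.
#' @param summit absolute 0-based summit position.
#' @param flank scan half-window, bp (>= motif length).
#' @param threshold log-odds threshold; defaults to the PWM's native one.
#' @return `NULL`, or a list with `offset` (motif start relative to the
#'   summit; negative = upstream), `strand`, `score`.
#' @export
scan_summit_region <- function(pwm, genome, chrom, summit, flank = 100,
                               threshold = pwm$threshold) {
  if (is.character(genome) && length(genome) == 1L) genome <- load_genome(genome)
  stopifnot(flank >= pwm$length)
  window <- read_fasta_window(genome, chrom, summit, flank)
  sc <- .scan_scores(pwm, window)
  .pick_best(sc, flank, threshold)
}

## choose the best hit from .scan_scores output; offsets relative to summit
.pick_best <- function(sc, flank, threshold) {
  n_off <- length(sc$fwd)
  if (!n_off) return(NULL)
  score <- c(sc$fwd, sc$rev)
  keep <- which(score > threshold)
  if (!length(keep)) return(NULL)
  off <- rep(seq_len(n_off) - 1L - flank, 2L)
  strand <- rep(c("+", "-"), each = n_off)
  ord <- order(-score[keep], off[keep], strand[keep] != "+")
  b <- keep[ord[1L]]
  list(offset = off[b], strand = strand[b], score = score[b])
}

## best score per peak (no threshold), vectorised over peaks
.best_scores <- function(peaks, genome, pwm, flank) {
  chars <- .genome_chars(genome, peaks$chrom)
  vapply(seq_len(nrow(peaks)), function(i) {
    w <- .window_chars(chars[[peaks$chrom[i]]], peaks$summit[i], flank)
    sc <- .scan_scores(pwm, w)
    m <- suppressWarnings(max(sc$fwd, sc$rev))
    if (is.infinite(m)) -Inf else m
  }, numeric(1))
}

#' Motif threshold sweep
#'
#' Percentage of peaks whose summit region carries a motif hit with score
#' strictly above each threshold. Non-increasing in the threshold by
#' construction.
#'
#' @param peaks peak data frame or [sample_set()].
#' @param genome `DNAStringSet` or FASTA path.
#' @param pwm a `pwm`.
#' @param thresholds numeric thresholds, sorted ascending.
#' @param flank scan half-window, bp.
#' @return data frame (`threshold`, `pct_with_hit`).
#' @export
dr3_threshold_sweep <- function(peaks, genome, pwm, thresholds,
                                flank = 100) {
  pk <- .peaks_of(peaks)
  if (is.character(genome) && length(genome) == 1L) genome <- load_genome(genome)
  if (is.unsorted(thresholds)) stop("thresholds must be sorted ascending")
  best <- .best_scores(pk, genome, pwm, flank)
  data.frame(
    threshold = thresholds,
    pct_with_hit = vapply(thresholds,
                          function(t) percentage(sum(best > t), nrow(pk)),
                          numeric(1))
  )
}

#' Summit-centred motif density profile
#'
#' Counts *all* motif hits (both strands, every offset where the full motif
#' fits) with score strictly above `threshold` in the
#' `[-profile_flank, +profile_flank)` window around each peak summit,
#' binned by the motif start offset and normalised to hits per peak per bp.
#'
#' @param peaks peak data frame or [sample_set()]; may be empty.
#' @param genome `DNAStringSet` or FASTA path.
#' @param pwm a `pwm`.
#' @param threshold log-odds threshold; defaults to the PWM's native one.
#' @param profile_flank half-window, bp.
#' @param bin bin width in bp; must divide `2 * profile_flank`.
#' @return data frame (`offset_lo`, `offset_hi`, `density`).
#' @export
motif_density_profile <- function(peaks, genome, pwm,
                                  threshold = pwm$threshold,
                                  profile_flank = 500, bin = 20) {
  if ((2 * profile_flank) %% bin != 0) stop("bin must divide 2 * profile_flank")
  pk <- .peaks_of(peaks)
  nbins <- 2L * profile_flank / bin
  lo <- seq.int(-profile_flank, profile_flank - bin, by = bin)
  counts <- numeric(nbins)
  if (nrow(pk)) {
    if (is.character(genome) && length(genome) == 1L) genome <- load_genome(genome)
    chars <- .genome_chars(genome, pk$chrom)
    for (i in seq_len(nrow(pk))) {
      w <- .window_chars(chars[[pk$chrom[i]]], pk$summit[i], profile_flank)
      sc <- .scan_scores(pwm, w)
      n_off <- length(sc$fwd)
      if (!n_off) next
      off <- seq_len(n_off) - 1L - profile_flank
      hits <- c(off[sc$fwd > threshold], off[sc$rev > threshold])
      if (length(hits))
        counts <- counts + tabulate((hits + profile_flank) %/% bin + 1L,
                                    nbins = nbins)
    }
  }
  dens <- if (nrow(pk)) counts / (nrow(pk) * bin) else counts
  data.frame(offset_lo = lo, offset_hi = lo + bin, density = dens)
}

#' DR3 percentage as a function of fold-enrichment rank
#'
#' Peaks are ranked by fold enrichment (descending; ties broken by genomic
#' position) and cut into consecutive windows of `rank_window` peaks (an
#' incomplete final window is dropped). Per window, the mean FE and the
#' percentage of peaks with a motif hit above the native threshold within
#' `scan_flank` of the summit are reported.
#'
#' @param peaks peak data frame or [sample_set()] with at least
#'   `rank_window` peaks.
#' @param genome `DNAStringSet` or FASTA path.
#' @param pwm a `pwm`.
#' @param params an [analysis_params()] (uses `rank_window`, `scan_flank`,
#'   `native_threshold`).
#' @return data frame (`window_rank`, `mean_fe`, `dr3_pct`).
#' @export
fe_window_curve <- function(peaks, genome, pwm, params = analysis_params()) {
  pk <- .peaks_of(peaks)
  w <- params$rank_window
  if (nrow(pk) < w)
    stop("need at least ", w, " peaks, got ", nrow(pk))
  ord <- order(-pk$fold_enrichment, pk$chrom, pk$start)
  pk <- pk[ord, , drop = FALSE]
  best <- .best_scores(pk, genome, pwm, params$scan_flank)
  hit <- best > params$native_threshold
  n_win <- nrow(pk) %/% w
  rows <- lapply(seq_len(n_win), function(k) {
    idx <- ((k - 1L) * w + 1L):(k * w)
    data.frame(window_rank = k,
               mean_fe = mean(pk$fold_enrichment[idx]),
               dr3_pct = percentage(sum(hit[idx]), w))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Centre position of a motif hit
#'
#' The central nucleotide of a motif starting at `start`:
#' `start + floor(length / 2)` (the spacer middle base for the 15-bp DR3).
#'
#' @param start absolute 0-based motif start.
#' @param length motif length in bp.
#' @return absolute 0-based centre position.
#' @export
motif_center <- function(start, length = 15) start + length %/% 2

#' Signed distance from motif centres to the nearest SNP
#'
#' For each motif hit the nearest SNP on the same chromosome is found and
#' the signed distance `snp_position - center` reported: negative when the
#' SNP lies upstream (toward smaller coordinates) of the motif centre.
#' Equidistant up/downstream SNPs resolve to the upstream one. Hits on
#' chromosomes without any SNP get `NA`.
#'
#' @param hits data frame with columns `chrom` and `center` (absolute
#'   0-based motif centre positions).
#' @param snps data frame with columns `chrom` and `pos` (0-based SNP
#'   positions).
#' @return numeric vector of signed distances, one per hit.
#' @export
motif_snp_distance <- function(hits, snps) {
  out <- rep(NA_real_, nrow(hits))
  for (cc in unique(hits$chrom)) {
    hi <- which(hits$chrom == cc)
    pos <- sort(snps$pos[snps$chrom == cc])
    if (!length(pos)) next
    ctr <- hits$center[hi]
    i <- findInterval(ctr, pos)                 # last snp <= center
    left <- ifelse(i >= 1L, pos[pmax(i, 1L)], -Inf)
    right <- ifelse(i < length(pos), pos[i + 1L], Inf)
    d_left <- ctr - left
    d_right <- right - ctr
    out[hi] <- ifelse(d_left <= d_right, left - ctr, right - ctr)
  }
  out
}
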