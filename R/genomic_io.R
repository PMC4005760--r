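## Standard-format I/O and the shared coordinate model.
##
## All coordinates in this package are 0-based half-open ([start, end)),
## the BED/narrowPeak convention. Summits are stored as absolute positions.

.open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

#' Read a MACS2 narrowPeak file
#'
#' Parses an ENCODE narrowPeak (BED6+4) file into a peak data frame. Column
#' 7 (signalValue) is taken as the fold enrichment, column 9 as the
#' -log10(q) value and column 10 as the summit offset from `start`; the
#' returned `summit` is the absolute 0-based summit position. Gzipped files
#' are handled by extension.
#'
#' @param path path to a narrowPeak file (optionally .gz).
#' @return data frame with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `fold_enrichment`, `neg_log10_p`, `neg_log10_q`, `summit`,
#'   sorted by (chrom, start). Zero rows for an empty file.
#' @seealso [write_narrowpeak()]
#' @export
read_narrowpeak <- function(path) {
  con <- .open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(
    chrom = character(), start = integer(), end = integer(),
    name = character(), score = numeric(), strand = character(),
    fold_enrichment = numeric(), neg_log10_p = numeric(),
    neg_log10_q = numeric(), summit = integer(),
    stringsAsFactors = FALSE
  )
  if (length(lines) == 0L) return(empty)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 10L)
  if (length(bad))
    stop("malformed narrowPeak line ", bad[1L], " in '", path,
         "': expected 10 tab-separated columns, found ", nf[bad[1L]])
  m <- matrix(unlist(fields), ncol = 10L, byrow = TRUE)

  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(m[, col]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("malformed narrowPeak line ", bad[1L], " in '", path,
           "': non-numeric ", what, " '", m[bad[1L], col], "'")
    v
  }
  start <- num(2L, "start"); end <- num(3L, "end")
  fe <- num(7L, "signalValue"); p <- num(8L, "pValue"); q <- num(9L, "qValue")
  off <- num(10L, "summit offset")

  bad <- which(start < 0 | end <= start)
  if (length(bad))
    stop("malformed narrowPeak line ", bad[1L], " in '", path,
         "': invalid interval [", start[bad[1L]], ", ", end[bad[1L]], ")")
  bad <- which(off < 0 | off >= end - start)
  if (length(bad))
    stop("narrowPeak line ", bad[1L], " in '", path,
         "': summit offset ", off[bad[1L]], " outside interval")
  if (any(fe < 0)) stop("negative fold enrichment in '", path, "'")

  out <- data.frame(
    chrom = m[, 1L], start = as.integer(start), end = as.integer(end),
    name = m[, 4L], score = num(5L, "score"), strand = m[, 6L],
    fold_enrichment = fe, neg_log10_p = p, neg_log10_q = q,
    summit = as.integer(start + off), stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write peaks as narrowPeak
#'
#' Inverse of [read_narrowpeak()]: writes the 10-column format with the
#' summit emitted as an offset from `start`. Missing optional columns are
#' filled with narrowPeak conventions (`name` generated, `score` 0, strand
#' ".", pValue -1).
#'
#' @param peaks peak data frame (at least `chrom`, `start`, `end`, `summit`,
#'   `fold_enrichment`, `neg_log10_q`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  n <- nrow(peaks)
  name <- if ("name" %in% names(peaks)) peaks$name else sprintf("peak_%d", seq_len(max(n, 0)))
  score <- if ("score" %in% names(peaks)) peaks$score else rep(0, n)
  strand <- if ("strand" %in% names(peaks)) peaks$strand else rep(".", n)
  p <- if ("neg_log10_p" %in% names(peaks)) peaks$neg_log10_p else rep(-1, n)
  out <- data.frame(
    peaks$chrom, peaks$start, peaks$end, name, score, strand,
    peaks$fold_enrichment, p, peaks$neg_log10_q,
    peaks$summit - peaks$start
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Labelled peak set for one sample
#'
#' Bundles the peak calls of one (cell type, stimulation state) sample with
#' its metadata. Peaks are sorted by (chrom, start).
#'
#' @param sample_id unique sample label.
#' @param cell_type cellular model name.
#' @param stimulated logical; `TRUE` for ligand-stimulated samples.
#' @param peaks peak data frame as returned by [read_narrowpeak()]; may
#'   have zero rows.
#' @return an object of class `sample_set`.
#' @export
sample_set <- function(sample_id, cell_type, stimulated, peaks) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L,
            is.character(cell_type), length(cell_type) == 1L,
            is.logical(stimulated), length(stimulated) == 1L,
            is.data.frame(peaks))
  need <- c("chrom", "start", "end", "summit", "fold_enrichment", "neg_log10_q")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) stop("peaks lack column(s): ", paste(miss, collapse = ", "))
  if (nrow(peaks)) {
    if (any(peaks$summit < peaks$start | peaks$summit >= peaks$end))
      stop("summit outside its interval")
    peaks <- peaks[order(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]
    rownames(peaks) <- NULL
  }
  structure(list(sample_id = sample_id, cell_type = cell_type,
                 stimulated = stimulated, peaks = peaks),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> %s (%s, %s): %d peaks\n", x$sample_id,
              x$cell_type, if (x$stimulated) "stimulated" else "unstimulated",
              nrow(x$peaks)))
  invisible(x)
}

## coerce a sample_set or bare peak data.frame to a peak data.frame
.peaks_of <- function(x) {
  if (inherits(x, "sample_set")) x$peaks
  else if (is.data.frame(x)) x
  else stop("expected a sample_set or a peak data frame")
}

#' Keep only peaks passing an FDR cutoff
#'
#' A peak is retained when its -log10(q) exceeds `fdr_neglog10`; the default
#' 2 corresponds to FDR < 1%.
#'
#' @param peaks peak data frame or `sample_set`.
#' @param fdr_neglog10 cutoff on the -log10(q) column.
#' @return object of the same kind with peaks filtered.
#' @export
filter_fdr <- function(peaks, fdr_neglog10 = 2) {
  if (inherits(peaks, "sample_set")) {
    peaks$peaks <- filter_fdr(peaks$peaks, fdr_neglog10)
    return(peaks)
  }
  out <- peaks[peaks$neg_log10_q > fdr_neglog10, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load a genome FASTA
#'
#' Reads a (possibly gzipped) FASTA into a `DNAStringSet`; sequence names
#' are truncated at the first whitespace.
#'
#' @param path FASTA path.
#' @return a [Biostrings::DNAStringSet].
#' @export
load_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Extract a fixed-width window around a position
#'
#' Returns the `[center - flank, center + flank)` window of a chromosome as
#' an uppercase A/C/G/T/N string of length exactly `2 * flank`; parts of the
#' window beyond either chromosome end are padded with `N`. Soft-masked
#' (lowercase) bases are uppercased and any other character becomes `N`.
#'
#' @param genome a `DNAStringSet` or FASTA path.
#' @param chrom chromosome name.
#' @param center absolute 0-based position.
#' @param flank half-width in bp.
#' @return character string of length `2 * flank`.
#' @export
read_fasta_window <- function(genome, chrom, center, flank) {
  if (is.character(genome) && length(genome) == 1L) genome <- load_genome(genome)
  if (!chrom %in% names(genome)) stop("unknown chromosome '", chrom, "'")
  stopifnot(flank >= 1)
  .window_chars(as.character(genome[[chrom]]), center, flank)
}

## window extraction from a chromosome already held as one character string
.window_chars <- function(chrom_seq, center, flank) {
  len <- nchar(chrom_seq)
  lo <- center - flank        # 0-based inclusive
  hi <- center + flank        # 0-based exclusive
  s_lo <- max(lo, 0L); s_hi <- min(hi, len)
  core <- if (s_hi > s_lo) substr(chrom_seq, s_lo + 1L, s_hi) else ""
  out <- paste0(strrep("N", max(0L, -lo)), core, strrep("N", max(0L, hi - len)))
  .sanitize_dna(out)
}

#' Build a score track
#'
#' A score track is a chromosome-wise step function: per chromosome a set
#' of sorted, non-overlapping half-open intervals each carrying a value;
#' the value is 0 outside every interval.
#'
#' @param df data frame with columns `chrom`, `start`, `end`, `value`.
#' @return an object of class `score_track`.
#' @export
score_track <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(df)))
  if (any(df$end <= df$start)) stop("score track intervals must have end > start")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  by_chr <- split(seq_len(nrow(df)), df$chrom)
  for (idx in by_chr) {
    if (length(idx) > 1L && any(df$start[idx][-1L] < df$end[idx][-length(idx)]))
      stop("score track intervals overlap within a chromosome")
  }
  rownames(df) <- NULL
  structure(list(data = df), class = "score_track")
}

#' Read a 4-column bedGraph into a score track
#'
#' @param path bedGraph path (optionally .gz); track/header lines starting
#'   with "track" or "#" are skipped.
#' @return a `score_track`.
#' @export
read_bedgraph <- function(path) {
  con <- .open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines) & !grepl("^(track|#)", lines)]
  if (!length(lines))
    return(score_track(data.frame(chrom = character(), start = integer(),
                                  end = integer(), value = numeric())))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 4L)) stop("malformed bedGraph line ",
                                 which(lengths(f) < 4L)[1L], " in '", path, "'")
  m <- t(vapply(f, `[`, character(4L), 1:4))
  score_track(data.frame(chrom = m[, 1L], start = as.integer(m[, 2L]),
                         end = as.integer(m[, 3L]), value = as.numeric(m[, 4L]),
                         stringsAsFactors = FALSE))
}

#' Evaluate a score track at positions
#'
#' Returns the value of the interval covering each position, or 0 where no
#' interval covers it (including the half-open right edge).
#'
#' @param track a `score_track`.
#' @param chrom chromosome name (length 1 or recycled against `position`).
#' @param position absolute 0-based positions.
#' @return numeric vector of values.
#' @export
track_value_at <- function(track, chrom, position) {
  stopifnot(inherits(track, "score_track"))
  if (length(chrom) == 1L) chrom <- rep(chrom, length(position))
  stopifnot(length(chrom) == length(position))
  out <- numeric(length(position))
  df <- track$data
  for (cc in unique(chrom)) {
    sel <- which(chrom == cc)
    sub <- df[df$chrom == cc, , drop = FALSE]
    if (!nrow(sub)) next
    i <- findInterval(position[sel], sub$start)
    hit <- i >= 1L & position[sel] < sub$end[pmax(i, 1L)]
    out[sel[hit]] <- sub$value[i[hit]]
  }
  out
}
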