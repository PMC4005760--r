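## Position weight matrices and log-odds scoring.
##
## Score scale: natural-log odds against the background, with a 0.001
## probability floor; an N in the sequence contributes ln(0.001 / 0.25).

.IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))

.PROB_FLOOR <- 0.001

#' Build a PWM from an IUPAC consensus
#'
#' Each consensus letter becomes one probability column: an unambiguous
#' base receives `match_prob` with the remainder split equally over the
#' other three bases; a k-fold degenerate letter splits `match_prob`
#' equally over its k allowed bases and the remainder equally over the
#' rest; `N` is uniform. Probabilities are floored at 0.001 and columns
#' renormalised.
#'
#' @param consensus IUPAC string, e.g. `"RGGTCANNGRGTTCA"`.
#' @param match_prob total probability given to the allowed bases, in
#'   (0.25, 0.997\].
#' @param background background base probabilities (A, C, G, T), summing
#'   to 1; default uniform.
#' @param threshold native log-odds threshold to attach (optional).
#' @param name motif name.
#' @return an object of class `pwm`: probability matrix (rows A/C/G/T),
#'   background, log-odds matrix, native threshold.
#' @export
pwm_from_iupac <- function(consensus, match_prob = 0.997,
                           background = rep(0.25, 4), threshold = NA_real_,
                           name = consensus) {
  stopifnot(match_prob > 0.25, match_prob <= 0.997,
            length(background) == 4, abs(sum(background) - 1) < 1e-9)
  letters <- strsplit(toupper(consensus), "")[[1]]
  bad <- setdiff(letters, names(.IUPAC))
  if (length(bad)) stop("invalid IUPAC letter(s): ", paste(bad, collapse = ", "))
  bases <- c("A", "C", "G", "T")
  probs <- vapply(letters, function(lt) {
    allowed <- .IUPAC[[lt]]
    m <- length(allowed)
    col <- numeric(4); names(col) <- bases
    if (m == 4L) col[] <- 0.25
    else {
      col[allowed] <- match_prob / m
      col[setdiff(bases, allowed)] <- (1 - match_prob) / (4 - m)
    }
    col <- pmax(col, .PROB_FLOOR)
    col / sum(col)
  }, numeric(4))
  rownames(probs) <- bases
  colnames(probs) <- NULL
  new_pwm(probs, background, threshold, name)
}

#' Construct a pwm object from a probability matrix
#'
#' @param probs 4 x L matrix of base probabilities, rows A/C/G/T, each
#'   column summing to 1.
#' @param background background base probabilities.
#' @param threshold native log-odds threshold (optional).
#' @param name motif name.
#' @return an object of class `pwm`.
#' @export
new_pwm <- function(probs, background = rep(0.25, 4),
                    threshold = NA_real_, name = "pwm") {
  stopifnot(nrow(probs) == 4, all(abs(colSums(probs) - 1) < 1e-9),
            all(probs >= .PROB_FLOOR - 1e-12))
  rownames(probs) <- c("A", "C", "G", "T")
  lo <- log(probs / background)
  lo <- rbind(lo, N = log(.PROB_FLOOR / 0.25))   # N row for masked bases
  structure(list(length = ncol(probs), probs = probs,
                 background = background, log_odds = lo,
                 threshold = threshold, name = name),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s: %d positions, native threshold %s\n", x$name,
              x$length, format(x$threshold)))
  invisible(x)
}

#' The built-in representative DR3-type motif
#'
#' PWM for the classical DR3-type VDR-RXR response element
#' `RGGTCANNGRGTTCA` (two RGGTCA-like hexamer half-sites spaced by three
#' nucleotides), with its native log-odds score threshold 9.184643. The
#' threshold is configurable downstream; no parity with any external
#' scanner's score scale is implied.
#'
#' @param match_prob see [pwm_from_iupac()].
#' @return an object of class `pwm`.
#' @export
pwm_dr3 <- function(match_prob = 0.997) {
  pwm_from_iupac("RGGTCANNGRGTTCA", match_prob = match_prob,
                 threshold = 9.184643, name = "DR3")
}

#' Read a JASPAR-style PFM text file
#'
#' Accepts the common JASPAR layouts: an optional `>` header followed by
#' four rows of counts, either bare or as `A [ 12 3 ... ]`. Counts are
#' converted column-wise to probabilities, floored at 0.001 and
#' renormalised.
#'
#' @param path PFM file path.
#' @param background background base probabilities.
#' @return an object of class `pwm`.
#' @export
read_jaspar_pfm <- function(path, background = rep(0.25, 4)) {
  lines <- readLines(path)
  name <- "pfm"
  if (length(lines) && startsWith(lines[1], ">")) {
    name <- sub("^>\\s*", "", lines[1])
    lines <- lines[-1]
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 4) stop("expected 4 count rows in '", path, "'")
  rows <- lapply(lines, function(l) {
    l <- gsub("^[ACGTacgt]\\s*\\[?|\\]\\s*$", "", l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  if (length(unique(lengths(rows))) != 1) stop("ragged PFM in '", path, "'")
  counts <- do.call(rbind, rows)
  probs <- apply(counts, 2, function(col) {
    p <- pmax(col / sum(col), .PROB_FLOOR)
    p / sum(p)
  })
  new_pwm(probs, background, name = name)
}

## reverse-complemented PWM: scanning the + strand with it equals scanning
## the - strand with the original
.rc_pwm_lo <- function(lo) {
  L <- ncol(lo)
  out <- lo[c("T", "G", "C", "A", "N"), L:1, drop = FALSE]
  rownames(out) <- c("A", "C", "G", "T", "N")
  out
}

## map DNA characters to rows 1..5 (A,C,G,T,N); anything else -> N
.CODE <- local({
  z <- rep(5L, 256L)
  z[utf8ToInt("A")] <- 1L; z[utf8ToInt("a")] <- 1L
  z[utf8ToInt("C")] <- 2L; z[utf8ToInt("c")] <- 2L
  z[utf8ToInt("G")] <- 3L; z[utf8ToInt("g")] <- 3L
  z[utf8ToInt("T")] <- 4L; z[utf8ToInt("t")] <- 4L
  z
})

#' Log-odds score of one sequence against a PWM
#'
#' Sum over motif positions of ln(p_j(base) / background(base)); for the
#' minus strand the reverse complement of the sequence is scored. An `N`
#' contributes ln(0.001 / 0.25).
#'
#' @param pwm a `pwm`.
#' @param seq DNA string of length `pwm$length`.
#' @param strand `"+"` or `"-"`.
#' @return numeric score.
#' @export
log_odds_score <- function(pwm, seq, strand = "+") {
  if (nchar(seq) != pwm$length)
    stop("sequence length ", nchar(seq), " != motif length ", pwm$length)
  lo <- if (strand == "-") .rc_pwm_lo(pwm$log_odds) else pwm$log_odds
  codes <- .CODE[utf8ToInt(seq)]
  sum(lo[cbind(codes, seq_len(pwm$length))])
}

## Scores at every start offset of `window` (character string), both
## strands. Returns list(fwd, rev): numeric vectors of length
## nchar(window) - L + 1 (length 0 if the window is shorter than the motif).
.scan_scores <- function(pwm, window) {
  L <- pwm$length
  n <- nchar(window)
  n_off <- n - L + 1L
  if (n_off < 1L) return(list(fwd = numeric(0), rev = numeric(0)))
  codes <- .CODE[utf8ToInt(window)]
  idx <- outer(seq_len(n_off) - 1L, seq_len(L), `+`)   # n_off x L positions
  cm <- codes[idx]
  dim(cm) <- dim(idx)
  jj <- rep(seq_len(L), each = n_off)
  fwd <- rowSums(matrix(pwm$log_odds[cbind(as.vector(cm), jj)], n_off, L))
  rc <- .rc_pwm_lo(pwm$log_odds)
  rev <- rowSums(matrix(rc[cbind(as.vector(cm), jj)], n_off, L))
  list(fwd = fwd, rev = rev)
}
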