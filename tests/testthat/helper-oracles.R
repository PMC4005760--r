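# Independent brute-force oracles. Deliberately written with plain loops
# and the defining formulas, sharing no code path with the implementation.

# triangular kernel density by direct formula
oracle_density <- function(x, summits, bandwidth) {
  vapply(x, function(xx) {
    acc <- 0
    for (s in summits) {
      k <- 1 - abs(xx - s) / bandwidth
      if (k > 0) acc <- acc + k
    }
    acc
  }, numeric(1))
}

# consensus summits by exhaustive grid evaluation: integer kernel weights,
# exhaustive span condition, plateau collapse to floor midpoint, greedy
# acceptance (density desc, position asc), rejection within <= span
oracle_consensus <- function(summits, bandwidth = 20, span = 100) {
  grid <- (min(summits) - bandwidth):(max(summits) + bandwidth)
  w <- vapply(grid, function(xx) {
    acc <- 0
    for (s in summits) {
      k <- bandwidth - abs(xx - s)
      if (k > 0) acc <- acc + k
    }
    acc
  }, numeric(1))
  half <- floor(span / 2)
  is_cand <- logical(length(grid))
  for (i in seq_along(grid)) {
    if (w[i] <= 0) next
    neigh <- which(grid >= grid[i] - half & grid <= grid[i] + half)
    if (all(w[i] >= w[neigh])) is_cand[i] <- TRUE
  }
  cand <- which(is_cand)
  if (!length(cand)) return(integer(0))
  pos <- c(); dens <- c()
  run_start <- cand[1]; prev <- cand[1]
  flush <- function(a, b) {
    pos <<- c(pos, grid[(a + b) %/% 2]) # indices; grid consecutive ints
    dens <<- c(dens, w[a])
  }
  for (i in cand[-1]) {
    if (i == prev + 1 && w[i] == w[prev]) prev <- i
    else { flush(run_start, prev); run_start <- i; prev <- i }
  }
  flush(run_start, prev)
  ord <- order(-dens, pos)
  acc <- c()
  for (i in ord) {
    ok <- TRUE
    for (a in acc) if (abs(pos[i] - a) <= span) ok <- FALSE
    if (ok) acc <- c(acc, pos[i])
  }
  sort(acc)
}

# pair overlap rule by direct arithmetic
oracle_overlap <- function(a, b, fraction = 0.5) {
  if (a$chrom != b$chrom) return(FALSE)
  ov <- min(a$end, b$end) - max(a$start, b$start)
  if (ov < 0) ov <- 0
  narrow <- min(a$end - a$start, b$end - b$start)
  ov > fraction * narrow
}

# O(n*m) all-pairs partner counts
oracle_pairwise <- function(A, B, fraction = 0.5) {
  hasA <- logical(nrow(A)); hasB <- logical(nrow(B))
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    if (oracle_overlap(A[i, ], B[j, ], fraction)) {
      hasA[i] <- TRUE; hasB[j] <- TRUE
    }
  }
  list(a_hits = sum(hasA), b_hits = sum(hasB))
}

# log-odds score of one sequence by direct formula
oracle_score <- function(pwm, seq) {
  chars <- strsplit(seq, "")[[1]]
  acc <- 0
  for (j in seq_along(chars)) {
    p <- if (chars[j] %in% c("A", "C", "G", "T")) pwm$probs[chars[j], j] else 0.001
    bg <- if (chars[j] %in% c("A", "C", "G", "T")) {
      pwm$background[match(chars[j], c("A", "C", "G", "T"))]
    } else 0.25
    acc <- acc + log(p / bg)
  }
  unname(acc)
}

oracle_revcomp <- function(seq) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(seq, "")[[1]]]), collapse = "")
}

# exhaustive enumeration of offsets x strands for the best hit
oracle_scan <- function(pwm, window, flank, threshold) {
  L <- pwm$length
  best <- NULL
  for (off in 0:(nchar(window) - L)) {
    sub <- substr(window, off + 1, off + L)
    for (strand in c("+", "-")) {
      sc <- if (strand == "+") oracle_score(pwm, sub)
            else oracle_score(pwm, oracle_revcomp(sub))
      if (sc > threshold) {
        better <- is.null(best) || sc > best$score
        if (better) best <- list(offset = off - flank, strand = strand, score = sc)
      }
    }
  }
  best
}

# nearest SNP by linear scan; ties resolve upstream (negative)
oracle_snp_distance <- function(chrom, center, snps) {
  pos <- snps$pos[snps$chrom == chrom]
  if (!length(pos)) return(NA_real_)
  best <- NULL
  for (p in pos) {
    d <- p - center
    if (is.null(best) || abs(d) < abs(best) || (abs(d) == abs(best) && d < best))
      best <- d
  }
  best
}

# random peak set on one chromosome
random_peaks <- function(n, chrom = "chr1", max_pos = 10000,
                         min_w = 20, max_w = 200) {
  start <- sample.int(max_pos, n, replace = TRUE)
  width <- as.integer(sample(min_w:max_w, n, replace = TRUE))
  df <- data.frame(chrom = chrom, start = start, end = start + width,
                   name = sprintf("p%d", seq_len(n)), score = 0, strand = ".",
                   fold_enrichment = round(runif(n, 1, 50), 3),
                   neg_log10_p = -1,
                   neg_log10_q = round(runif(n, 2.1, 20), 3),
                   summit = start + width %/% 2L,
                   stringsAsFactors = FALSE)
  df[order(df$chrom, df$start, df$end), ]
}
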