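test_that("IUPAC PWM columns follow the stated construction", {
  expect_equal(unname(pwm_from_iupac("N")$probs[, 1]), rep(0.25, 4))
  expect_equal(unname(pwm_from_iupac("A", 0.997)$probs[, 1]),
               c(0.997, 0.001, 0.001, 0.001))
  expect_equal(unname(pwm_from_iupac("R", 0.994)$probs[, 1]),
               c(0.497, 0.003, 0.497, 0.003))
  expect_error(pwm_from_iupac("AXG"), "invalid IUPAC")
  pw <- pwm_dr3()
  expect_equal(pw$length, 15L)
  expect_equal(pw$threshold, 9.184643)
  expect_true(all(abs(colSums(pw$probs) - 1) < 1e-9))
  expect_true(all(pw$probs >= 0.001))
})

test_that("log-odds scores follow the defining sum and strand symmetry", {
  uni <- new_pwm(matrix(0.25, 4, 6))
  expect_equal(log_odds_score(uni, "ACGTAC"), 0)
  a1 <- pwm_from_iupac("A", 0.997)
  expect_equal(log_odds_score(a1, "A"), log(0.997 / 0.25))
  expect_equal(log_odds_score(a1, "A"), 1.38329, tolerance = 1e-5)
  expect_equal(log_odds_score(a1, "N"), log(0.001 / 0.25))
  expect_error(log_odds_score(a1, "AA"), "length")

  set.seed(41)
  pw <- pwm_dr3()
  for (i in 1:100) {
    s <- random_dna(15)
    expect_equal(log_odds_score(pw, s, "-"),
                 log_odds_score(pw, oracle_revcomp(s), "+"))
    expect_equal(log_odds_score(pw, s, "+"), oracle_score(pw, s))
  }
})

test_that("the PWM maximum is attained exactly by the R expansions", {
  pw <- pwm_dr3()
  max_score <- sum(apply(pw$log_odds[1:4, ], 2, max))
  exps <- dr3_expansions()
  scores <- vapply(exps, function(s) log_odds_score(pw, s), numeric(1))
  expect_equal(unname(scores), rep(max_score, 4))
  # any substitution to a disallowed base strictly lowers the score
  # (positions 1 and 10 are R: both A and G attain the column maximum)
  allowed <- strsplit(c("R", "G", "G", "T", "C", "A", "N", "N", "G",
                        "R", "G", "T", "T", "C", "A"), "")
  allowed <- lapply(allowed, function(lt) switch(lt,
    R = c("A", "G"), N = c("A", "C", "G", "T"), lt))
  s0 <- exps[1]
  for (j in setdiff(1:15, c(7, 8))) {
    for (b in setdiff(c("A", "C", "G", "T"), allowed[[j]])) {
      s <- s0
      substr(s, j, j) <- b
      expect_lt(log_odds_score(pw, s), max_score)
    }
  }
  # N columns are uniform: the spacer base never changes the score
  s <- s0
  substr(s, 7, 7) <- "C"
  expect_equal(log_odds_score(pw, s), max_score)
})

test_that("summit scans find planted motifs and reject empty windows", {
  pw <- pwm_dr3()
  set.seed(42)
  site <- dr3_expansions()[2]
  seq <- plant_into(400, list(list(start = 200, seq = site)))
  g <- genome_of(seq)
  hit <- scan_summit_region(pw, g, "chr1", 207, flank = 100)
  expect_equal(hit$offset, -7)                     # motif covers the summit
  expect_equal(hit$strand, "+")
  expect_equal(hit$score, sum(apply(pw$log_odds[1:4, ], 2, max)))

  gn <- genome_of(strrep("N", 400))
  expect_null(scan_summit_region(pw, gn, "chr1", 200, flank = 100,
                                 threshold = 0))

  # minus-strand plant is found with the same score
  seq2 <- plant_into(400, list(list(start = 200, seq = oracle_revcomp(site))))
  hit2 <- scan_summit_region(pw, genome_of(seq2), "chr1", 207, flank = 100)
  expect_equal(hit2$strand, "-")
  expect_equal(hit2$score, hit$score)
})

test_that("best-hit scan matches exhaustive enumeration on random windows", {
  set.seed(43)
  pw <- pwm_dr3()
  for (i in 1:25) {
    seq <- random_dna(200)
    if (i %% 3 == 0) {  # plant to exercise the hit path
      s <- dr3_expansions()[sample(4, 1)]
      if (runif(1) < 0.5) s <- oracle_revcomp(s)
      p <- sample(0:185, 1)
      substr(seq, p + 1, p + 15) <- s
    }
    g <- genome_of(seq)
    thr <- sample(c(-Inf, 4, 9.184643), 1)
    got <- scan_summit_region(pw, g, "chr1", 100, flank = 100, threshold = thr)
    exp <- oracle_scan(pw, seq, 100, thr)
    if (is.null(exp)) expect_null(got)
    else {
      expect_equal(got$score, exp$score)
      expect_equal(got$offset, exp$offset)
      expect_equal(got$strand, exp$strand)
      expect_true(got$score > thr)
    }
  }
})

test_that("threshold sweep percentages are monotone and saturate on plants", {
  pw <- pwm_dr3()
  set.seed(44)
  # 30 peaks, all with a perfect consensus at the summit
  block <- 400
  plants <- lapply(0:29, function(i) list(start = i * block + 193,
                                          seq = dr3_expansions()[1]))
  g <- genome_of(plant_into(30 * block, plants))
  pk <- peaks_at(0:29 * block + 200, halfwidth = 50)
  max_score <- sum(apply(pw$log_odds[1:4, ], 2, max))
  sw <- dr3_threshold_sweep(pk, g, pw, c(4, 9.184643, max_score - 0.01))
  expect_equal(sw$pct_with_hit, c(100, 100, 100))
  # above the maximum nothing passes
  sw0 <- dr3_threshold_sweep(pk, g, pw, max_score + 1)
  expect_equal(sw0$pct_with_hit, 0)

  # monotone non-increasing on arbitrary (motif-free) input
  g2 <- genome_of(random_dna(30 * block))
  sw2 <- dr3_threshold_sweep(pk, g2, pw, c(-10, -5, 0, 4, 9.184643))
  expect_true(all(diff(sw2$pct_with_hit) <= 0))
})

test_that("motif density profiles localise planted hits", {
  pw <- pwm_dr3()
  set.seed(45)
  block <- 1100
  n_pk <- 30
  plants <- lapply(0:(n_pk - 1), function(i) list(start = i * block + 543,
                                                  seq = dr3_expansions()[1]))
  g <- genome_of(plant_into(n_pk * block, plants))
  pk <- peaks_at(0:(n_pk - 1) * block + 550, halfwidth = 50)
  prof <- motif_density_profile(pk, g, pw, profile_flank = 500, bin = 100)
  central <- which(prof$offset_lo <= -7 & prof$offset_hi > -7)
  expect_gte(prof$density[central], 1 / 100)       # one hit per peak per bin
  # essentially no mass outside the central bin (false positives are rare)
  expect_lt(sum(prof$density[-central]), 0.1 / 100)

  empty <- motif_density_profile(pk[0, ], g, pw, profile_flank = 500, bin = 100)
  expect_true(all(empty$density == 0))
  expect_error(motif_density_profile(pk, g, pw, profile_flank = 500, bin = 33),
               "divide")
})

test_that("uniformly planted motifs give an approximately flat profile", {
  pw <- pwm_dr3()
  set.seed(46)
  block <- 1200
  n_pk <- 400
  offs <- seq(-500, 480, by = 20)     # 20 bp grid: plants never collide,
                                      # 5 grid points per 100 bp bin
  plants <- list(); pkpos <- integer(n_pk)
  for (i in seq_len(n_pk)) {
    center <- (i - 1) * block + 600
    pkpos[i] <- center
    for (o in sort(sample(offs, 5)))
      plants[[length(plants) + 1]] <- list(start = center + o,
                                           seq = dr3_expansions()[1])
  }
  g <- genome_of(plant_into(n_pk * block, plants))
  pk <- peaks_at(pkpos, halfwidth = 50)
  prof <- motif_density_profile(pk, g, pw, profile_flank = 500, bin = 100)
  expect_lt(max(prof$density) / min(prof$density), 2)
})

test_that("FE-window curves rank peaks by FE and report window DR3 rates", {
  pw <- pwm_dr3()
  set.seed(47)
  block <- 400
  n_pk <- 300
  fe <- seq(30, 1, length.out = n_pk)    # strictly decreasing with rank
  plants <- lapply(0:99, function(i) list(start = i * block + 193,
                                          seq = dr3_expansions()[1]))
  g <- genome_of(plant_into(n_pk * block, plants))
  pk <- peaks_at(0:(n_pk - 1) * block + 200, halfwidth = 50, fe = fe)
  crv <- fe_window_curve(pk, g, pw)
  expect_equal(crv$dr3_pct, c(100, 0, 0))          # motif only in top 100
  expect_equal(crv$mean_fe, c(mean(fe[1:100]), mean(fe[101:200]),
                              mean(fe[201:300])))
  expect_error(fe_window_curve(pk[1:50, ], g, pw), "at least")
})

test_that("signed SNP distances use the upstream-negative convention", {
  hits <- data.frame(chrom = "chr1", center = c(1000, 1000, 1000))
  snps <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                     pos = c(1000, 995, 500))
  expect_equal(motif_snp_distance(hits[1, , drop = FALSE],
                                  data.frame(chrom = "chr1", pos = 1000)), 0)
  expect_equal(motif_snp_distance(hits[1, , drop = FALSE],
                                  data.frame(chrom = "chr1", pos = 995)), -5)
  expect_equal(motif_snp_distance(data.frame(chrom = "chr2", center = 100),
                                  data.frame(chrom = "chr1", pos = 995)),
               NA_real_)
  # equidistant SNPs resolve upstream
  expect_equal(motif_snp_distance(hits[1, , drop = FALSE],
                                  data.frame(chrom = "chr1", pos = c(990, 1010))),
               -10)
  expect_equal(motif_center(993, 15), 1000)

  set.seed(48)
  for (i in 1:100) {
    h <- data.frame(chrom = "chr1", center = sample(0:5000, 3))
    s <- data.frame(chrom = "chr1", pos = sample(0:5000, sample(1:10, 1)))
    got <- motif_snp_distance(h, s)
    exp <- vapply(h$center, oracle_snp_distance, numeric(1),
                  chrom = "chr1", snps = s)
    expect_equal(got, exp)
  }
})
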