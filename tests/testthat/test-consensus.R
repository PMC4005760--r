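test_that("summit density is the exact triangular kernel sum", {
  d <- summit_density(1000, 20)
  expect_equal(d(c(1000, 1010, 1020, 980)), c(1, 0.5, 0, 0))
  d2 <- summit_density(c(1000, 1000), 20)
  expect_equal(d2(1000), 2)
  d3 <- summit_density(c(1000, 1004), 20)
  expect_equal(d3(c(1000, 1002, 1004)), c(1.8, 1.8, 1.8))   # plateau
  expect_error(summit_density(numeric(0)), "non-empty")
})

test_that("consensus summits resolve modes, plateaus and greedy ties", {
  fc <- function(summits) {
    find_consensus_summits(peaks_at(summits, halfwidth = 30))$summit
  }
  expect_equal(fc(1000), 1000)                      # lone kernel mode
  expect_equal(fc(c(1000, 1000, 1004)), 1000)       # dominant mode wins
  expect_equal(fc(c(1000, 1300)), c(1000, 1300))    # independent modes
  expect_equal(fc(c(1000, 1060)), 1000)             # tie: leftmost kept,
                                                    # other within span
  expect_equal(fc(c(1000, 1004)), 1002)             # plateau midpoint
  expect_error(find_consensus_summits(list()), "no peaks")
})

test_that("consensus summit finding matches the exhaustive grid oracle", {
  set.seed(21)
  for (i in 1:40) {
    n <- sample(1:8, 1)
    summits <- sample(0:2000, n, replace = TRUE)
    bw <- sample(c(5, 10, 20), 1)
    span <- sample(c(20, 50, 100), 1)
    p <- analysis_params(bandwidth = bw, span = span)
    got <- find_consensus_summits(peaks_at(summits, halfwidth = 5), p)
    expect_equal(got$summit, oracle_consensus(summits, bw, span),
                 info = sprintf("summits=%s bw=%d span=%d",
                                paste(summits, collapse = ","), bw, span))
  }
})

test_that("elongation and midpoint truncation give disjoint <=200 bp peaks", {
  expect_equal(build_consensus_peaks(1000)[, c("start", "end")],
               data.frame(start = 900L, end = 1100L))
  pk <- build_consensus_peaks(c(1000, 1120))
  expect_equal(pk$start, c(900L, 1060L))
  expect_equal(pk$end, c(1060L, 1220L))
  pk2 <- build_consensus_peaks(c(1000, 1300))
  expect_equal(pk2$start, c(900L, 1200L))
  expect_equal(pk2$end, c(1100L, 1400L))
  expect_error(build_consensus_peaks(c(1300, 1000)), "sorted")

  # odd overlap width cuts at floor(midpoint); left keeps the boundary base
  pk3 <- build_consensus_peaks(c(1000, 1121))
  expect_equal(pk3$end[1], pk3$start[2])
  expect_equal(pk3$end[1], (1021 + 1100) %/% 2)
})

test_that("fold enrichment from pileups uses the pseudocount ratio", {
  expect_equal(fe_from_pileup(9, 4, 1), 2)
  expect_equal(fe_from_pileup(0, 0, 1), 1)
  expect_error(fe_from_pileup(1, 1, 0), "pseudocount")
  set.seed(22)
  t <- runif(200, 0, 50); c <- runif(200, 0, 50)
  hi <- t >= c
  expect_true(all(fe_from_pileup(t[hi], c[hi], 1) >= 1))
  expect_true(all(fe_from_pileup(t[!hi], c[!hi], 1) < 1))
})

test_that("per-sample metrics come from contained peaks, then tracks", {
  consensus <- data.frame(chrom = "chr1", start = 900L, end = 1100L,
                          summit = 1000L)
  inside <- sample_set("a_stim", "A", TRUE,
                       peaks_at(c(950, 1050), fe = c(3, 7), q = c(4, 6)))
  outside <- sample_set("b_stim", "B", TRUE, peaks_at(5000, fe = 2))
  tr <- list(b_stim = list(
    fe = score_track(data.frame(chrom = "chr1", start = 900L, end = 1100L,
                                value = 1.7)),
    q = score_track(data.frame(chrom = "chr1", start = 900L, end = 1100L,
                               value = 0.3))))
  cs <- assign_sample_metrics(consensus, list(inside, outside), tracks = tr)
  expect_true(cs$present[1, "a_stim"])
  expect_equal(unname(cs$fe[1, "a_stim"]), 7)   # highest-FE contained peak
  expect_equal(unname(cs$q[1, "a_stim"]), 6)
  expect_false(cs$present[1, "b_stim"])
  expect_equal(unname(cs$fe[1, "b_stim"]), 1.7) # track fallback at the summit
  expect_equal(unname(cs$q[1, "b_stim"]), 0.3)
  expect_equal(cs$n_cell_types, 1L)

  expect_error(assign_sample_metrics(consensus, list(inside),
                                     tracks = list(zz = tr$b_stim)),
               "unknown sample")
})

test_that("cell types are counted once however many samples are present", {
  # 3 cell types x 2 states; sites engineered by hand:
  #   site 1000: A_stim + A_unstim          -> 1 cell type
  #   site 2000: A_stim + B_stim            -> 2 cell types
  #   site 3000: C_unstim                   -> 1 cell type
  mk <- function(id, ct, stim, summits) sample_set(id, ct, stim, peaks_at(summits))
  samples <- list(
    mk("A_stim", "A", TRUE, c(1000, 2000)),
    mk("A_unstim", "A", FALSE, 1000),
    mk("B_stim", "B", TRUE, 2000),
    mk("B_unstim", "B", FALSE, numeric(0)),
    mk("C_stim", "C", TRUE, numeric(0)),
    mk("C_unstim", "C", FALSE, 3000)
  )
  cons <- build_consensus_peaks(find_consensus_summits(samples))
  cs <- assign_sample_metrics(cons, samples)
  expect_equal(nrow(cs$peaks), 3L)
  expect_equal(cs$n_cell_types, c(1L, 2L, 1L))
  expect_equal(unname(specificity_categories(cs, 3)), c(2L, 1L, 0L))
})

test_that("distance sweep merges and separates summits as the span moves", {
  a <- sample_set("a_stim", "A", TRUE, peaks_at(1000))
  b <- sample_set("b_stim", "B", TRUE, peaks_at(1070))
  sw <- distance_sensitivity_sweep(list(a, b), c(60, 100))
  expect_equal(sw$n_total_unique, c(2L, 1L))        # separate at 60, merged at 100

  one <- distance_sensitivity_sweep(list(a), c(60, 100, 200))
  expect_equal(one$n_conserved_all, one$n_total_unique)
  expect_error(distance_sensitivity_sweep(list(a), numeric(0)), "non-empty")
})

test_that("planted sites are recovered within 10 bp under 5 bp jitter", {
  set.seed(23)
  truth <- sort(sample(seq(1000, 200000, by = 450), 120))
  samples <- lapply(1:6, function(k) {
    jit <- sample(-5:5, length(truth), replace = TRUE)
    sample_set(paste0("s", k), paste0("ct", k), TRUE, peaks_at(truth + jit))
  })
  cs <- find_consensus_summits(samples)
  expect_equal(nrow(cs), length(truth))             # every site recovered once
  expect_true(all(abs(cs$summit - truth) <= 10))

  # determinism on identical inputs
  expect_identical(cs, find_consensus_summits(samples))

  # non-overlap and width bound after elongation
  pk <- build_consensus_peaks(cs)
  expect_true(all(pk$end - pk$start <= 200))
  expect_true(all(pk$start[-1] >= pk$end[-nrow(pk)]))
})

test_that("exact kernel sums make the density floor a no-op", {
  set.seed(24)
  summits <- sample(0:5000, 30, replace = TRUE)
  g <- vdrmeta:::.density_grid(summits, 20)
  pos <- g$w[g$w > 0] / 20
  expect_true(all(pos >= 1 / 20))                   # min positive density
  p_floor <- analysis_params()
  p_nofloor <- analysis_params(density_floor = 1e-300)
  pk <- peaks_at(summits, halfwidth = 5)
  expect_identical(find_consensus_summits(pk, p_floor),
                   find_consensus_summits(pk, p_nofloor))
})
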