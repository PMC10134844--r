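test_that("rarefaction preserves totals and matches the hypergeometric mean", {
  x <- c(a = 10L, b = 20L, c = 5L)
  expect_identical(rarefyCounts(x, 35L, seed = 1), x) # full-depth identity
  y <- rarefyCounts(x, 20L, seed = 1)
  expect_identical(sum(y), 20L)
  expect_lte(sum(y > 0), sum(x > 0)) # richness never increases
  expect_error(rarefyCounts(x, 36L), "insufficient depth")
  ## hypergeometric expectation: (9000, 1000) at depth 1000 -> mean 900
  z <- c(t1 = 9000L, t2 = 1000L)
  n <- 10000L
  draws <- vapply(seq_len(n), function(i) rarefyCounts(z, 1000L, seed = i)[1], 0L)
  ## variance of the hypergeometric count
  v <- 1000 * 0.9 * 0.1 * (10000 - 1000) / (10000 - 1)
  expect_lt(abs(mean(draws) - 900), 3 * sqrt(v / n))
})

test_that("normalizedRad has the stated structure", {
  x <- c(40, 30, 20, 10)
  ## target = richness: deterministic sorted proportions
  expect_equal(normalizedRad(x, 4L), c(0.4, 0.3, 0.2, 0.1))
  ## perfectly even community: uniform at every rank
  expect_equal(normalizedRad(rep(25, 10), 5L, n_norm = 50L, seed = 2),
               rep(0.2, 5))
  ## property sweep: non-increasing, sums to 1
  set.seed(5)
  for (i in 1:100) {
    v <- rpois(30, 50) + 1
    rad <- normalizedRad(v, 10L, n_norm = 20L, seed = i)
    expect_true(all(diff(rad) <= 1e-12))
    expect_equal(sum(rad), 1, tolerance = 1e-9)
  }
  expect_error(normalizedRad(c(3, 2, 1), 4L), "exceeds richness")
})

test_that("the Zipf decay coefficient is exact on power laws", {
  p <- (1 / (1:30)); p <- p / sum(p)
  expect_equal(fitZipf(p)$decay, 1, tolerance = 1e-10)
  expect_equal(fitZipf(rep(0.1, 10))$decay, 0, tolerance = 1e-10)
  q <- (1:50)^(-0.5); q <- q / sum(q)
  expect_equal(fitZipf(q)$decay, 0.5, tolerance = 1e-10)
  ## decay = -gamma by convention
  f <- fitZipf(p)
  expect_equal(f$decay, -f$gamma)
  ## invariant to scaling the abundances
  expect_equal(fitZipf(p * 7)$decay, fitZipf(p)$decay, tolerance = 1e-12)
  ## nls mode agrees on an exact power law
  expect_equal(fitZipf(p, method = "nls")$decay, 1, tolerance = 1e-6)
  expect_error(fitZipf(c(0.5, 0.5)), "3 ranks")
  expect_error(fitZipf(c(0.5, 0.4, 0)), "positive")
})

test_that("Pielou evenness is 1 on uniform RADs and computed from entropy", {
  expect_equal(pielouEvenness(rep(1 / 7, 7)), 1)
  expect_equal(pielouEvenness(c(0.5, 0.5)), 1)
  h <- -(0.9 * log(0.9) + 0.1 * log(0.1))
  expect_equal(pielouEvenness(c(0.9, 0.1)), h / log(2))
  expect_lt(pielouEvenness(c(0.9, 0.1)), 1)
  expect_error(pielouEvenness(0.5), "fewer than 2")
})

test_that("clrEuclidean is the Aitchison distance", {
  x <- c(a = 8, b = 1, c = 1); y <- c(a = 1, b = 8, c = 1)
  expect_equal(clrEuclidean(x, x), 0)
  ## scale invariance with pseudocount 0 and positive counts
  expect_equal(clrEuclidean(x, 3 * x, pseudocount = 0), 0, tolerance = 1e-12)
  ## direct evaluation of the CLR formula as an independent oracle
  clr <- function(v) { lv <- log(v / sum(v)); lv - mean(lv) }
  expect_equal(clrEuclidean(x, y, pseudocount = 0),
               sqrt(sum((clr(x) - clr(y))^2)), tolerance = 1e-12)
  expect_equal(clrEuclidean(x, y), clrEuclidean(y, x)) # symmetric
  expect_error(clrEuclidean(c(1, 2), c(1, 2, 3)), "mismatched")
})

test_that("diversityVsDilution reduces to OLS for one experiment", {
  set.seed(9)
  rec <- expand.grid(dilution_factor = c(0.25, 0.5, 0.75, 1),
                     replicate = 1:2)
  rec$experiment <- "e1"; rec$treatment <- "protists_viruses"
  rec$timepoint <- "T12"
  rec$evenness <- 0.5 + 0.2 * rec$dilution_factor + rnorm(8, 0, 0.01)
  f <- diversityVsDilution(rec, "evenness", "protists_viruses")
  o <- oracleOls(rec$dilution_factor, rec$evenness)
  expect_equal(f$fixed_slope, unname(o["slope"]), tolerance = 1e-6)
})

test_that("ANCOVA flags differing slopes and not equal ones", {
  makeDist <- function(seed, delta) {
    set.seed(seed)
    g <- expand.grid(dilution_factor = c(0.25, 0.5, 0.75, 1),
                     replicate = 1:2,
                     treatment = c("protists", "protists_viruses"),
                     experiment = paste0("e", 1:6))
    base <- ifelse(g$treatment == "protists", 0.5, 0.4)
    slope <- 1 + ifelse(g$treatment == "protists", 0, delta)
    g$distance <- base + slope * g$dilution_factor + rnorm(nrow(g), 0, 0.1)
    g
  }
  pe <- ancovaSlopes(makeDist(1, 0))
  expect_true(pe$interaction_p >= 0 && pe$interaction_p <= 1)
  pd <- ancovaSlopes(makeDist(1, 0.5)) # 5 x residual sd
  expect_lt(pd$interaction_p, 0.05)
  expect_error(ancovaSlopes(data.frame(distance = 1, dilution_factor = 1,
                                       treatment = "protists")),
               "2 treatments")
})

test_that("composition distances are near the sampling floor for unchanged communities", {
  ## T12 compositions identical to T0: distance is only rarefaction noise
  tr <- drawTraits(20, beta_P = 0, beta_V = 0, alpha_P = 0, alpha_V = 0,
                   noise_sd = 0, g_sd = 0, seed = 44)
  dex <- simulateExperiment(experimentDesign(seed = 44), tr)
  cm <- compositionMaintenance(dex, n_sub = 20L, seed = 3)
  ## identical underlying compositions: slopes of distance on d within 2 SE
  ## of zero, interaction not significant
  expect_true(all(abs(cm$fits$slope) <= 2 * cm$fits$slope_se))
  expect_true(all(cm$distances$distance >= 0))
  expect_gte(cm$ancova$interaction_p, 0.05)
})

test_that("per-sample diversity table covers every sample with valid indices", {
  dex <- noisyDex(n_taxa = 30, seed = 50)
  div <- diversityTable(dex, n_norm = 50L, seed = 1)
  expect_identical(nrow(div), 17L)
  expect_true(all(div$evenness >= 0 & div$evenness <= 1))
  expect_true(all(div$richness >= 1))
  ## deterministic under the same seed
  div2 <- diversityTable(dex, n_norm = 50L, seed = 1)
  expect_identical(div, div2)
})
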