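makeTraits <- function(comp, resist, experiment = "e1") {
  data.frame(taxon_id = sprintf("t%03d", seq_along(comp)),
             experiment = experiment, competitiveness = comp,
             resistance_P = resist, resistance_PV = resist,
             resistance_V = resist * 0, p_P = NA_real_, p_PV = NA_real_)
}

test_that("tradeoffPerExperiment detects a perfect anti-correlation", {
  set.seed(2)
  comp <- runif(12, 0.05, 0.2)
  res <- tradeoffPerExperiment(makeTraits(comp, -comp), "P")
  expect_equal(res$pearson_r, -1)
  expect_equal(res$ols_slope, -1)
  expect_identical(res$n, 12L)
})

test_that("Pearson r matches the covariance-formula oracle", {
  set.seed(3)
  for (i in 1:50) {
    comp <- rnorm(10, 0.1, 0.05); resist <- rnorm(10, -0.05, 0.03)
    res <- tradeoffPerExperiment(makeTraits(comp, resist), "P")
    expect_equal(res$pearson_r, oraclePearson(comp, resist),
                 tolerance = 1e-12)
    o <- oracleOls(comp, resist)
    expect_equal(res$ols_slope, unname(o["slope"]), tolerance = 1e-12)
  }
})

test_that("degenerate trade-off inputs raise errors", {
  expect_error(tradeoffPerExperiment(makeTraits(1:5 / 10, rep(0.1, 5)), "P"),
               "zero variance")
  expect_error(tradeoffPerExperiment(makeTraits(c(0.1, 0.2), c(-1, -2)), "P"),
               "fewer than 3")
})

test_that("independent traits give a null correlation at the expected rate", {
  hits <- 0L
  for (i in 1:200) {
    set.seed(1000 + i)
    comp <- rnorm(1000, 0.1, 0.05)
    resist <- rnorm(1000, -0.05, 0.03)
    res <- tradeoffPerExperiment(makeTraits(comp, resist), "P")
    if (abs(res$pearson_r) < 0.1 && res$pearson_p > 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 190L)
})

test_that("the mixed model reduces to OLS for a single experiment", {
  set.seed(4)
  comp <- rnorm(30, 0.1, 0.05)
  resist <- -0.5 * comp + rnorm(30, 0, 0.02)
  f <- tradeoffLmm(makeTraits(comp, resist), "P")
  expect_identical(f$status, "single_group_ols")
  o <- oracleOls(comp, resist)
  expect_equal(f$fixed_slope, unname(o["slope"]), tolerance = 1e-6)
  expect_equal(f$fixed_intercept, unname(o["intercept"]), tolerance = 1e-6)
})

test_that("the mixed model recovers a known fixed slope across groups", {
  ## generative model: slope -0.14, between-experiment intercept sd 0.02,
  ## residual sd 0.05; scaled-down replicate count for the unit suite
  slopes <- vapply(1:20, function(rep) {
    set.seed(500 + rep)
    tr <- do.call(rbind, lapply(1:6, function(g) {
      comp <- rnorm(300, 0.1, 0.05)
      resist <- rnorm(1, 0, 0.02) - 0.14 * comp + rnorm(300, 0, 0.05)
      makeTraits(comp, resist, experiment = paste0("e", g))
    }))
    tradeoffLmm(tr, "P")$fixed_slope
  }, 0)
  mc_se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - (-0.14)), 2 * mc_se + 1e-3)
})

test_that("zero between-group variance collapses the random intercept", {
  collapses <- vapply(1:30, function(rep) {
    set.seed(900 + rep)
    tr <- do.call(rbind, lapply(1:6, function(g) {
      comp <- rnorm(100, 0.1, 0.05)
      resist <- -0.1 * comp + rnorm(100, 0, 0.05)
      makeTraits(comp, resist, experiment = paste0("e", g))
    }))
    f <- tradeoffLmm(tr, "P")
    f$random_intercept_sd < f$residual_sd / 10
  }, logical(1))
  expect_gte(mean(collapses), 0.9)
})

test_that("permutation null is deterministic and internally consistent", {
  dex <- noisyDex(n_taxa = 25, seed = 60)
  rec <- pngrRecords(dex, quiet = TRUE)
  a <- permutationNull(rec, "PV", n_perm = 100L, seed = 17)
  b <- permutationNull(rec, "PV", n_perm = 100L, seed = 17)
  expect_identical(a$null_stats, b$null_stats)
  expect_identical(length(a$null_stats), 100L)
  expect_equal(a$z_score, (a$observed_stat - a$null_mean) / a$null_sd,
               tolerance = 1e-12)
  ## the observed statistic equals the straight estimate chain
  est <- estimateTraits(fitAllPngr(rec, quiet = TRUE))
  ok <- is.finite(est$competitiveness) & is.finite(est$resistance_PV)
  direct <- coef(lm(resistance_PV ~ competitiveness, est[ok, ]))[2]
  expect_equal(a$observed_stat, unname(direct), tolerance = 1e-10)
  expect_warning(permutationNull(rec, "PV", n_perm = 50L, seed = 1),
                 "coarse")
})

test_that("a strong generative trade-off is detected against the null", {
  tr <- drawTraits(40, beta_P = 1, beta_V = 1, noise_sd = 0.005, seed = 71)
  dex <- simulateExperiment(
    experimentDesign(seed = 71, exact_proportions = TRUE, density_cv = 0), tr)
  rec <- pngrRecords(dex, quiet = TRUE)
  p <- permutationNull(rec, "PV", n_perm = 200L, seed = 5)
  expect_lt(p$z_score, -3)
  ## the null mean reflects the mechanical coupling, not the real trade-off:
  ## it sits closer to the artifact expectation than to the observed slope
  expect_gt(p$observed_stat - p$null_mean, -Inf) # guard
  expect_gt(abs(p$observed_stat - p$null_mean), p$null_sd * 3)
})
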