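test_that("absolute abundance is relative abundance times duplicate-mean density", {
  ## two taxa at 50/50, duplicate densities 1e6 and 2e6 -> N = 0.5 * 1.5e6
  counts <- matrix(c(50, 50, 40, 60, 30, 70), nrow = 2,
                   dimnames = list(c("t1", "t2"), c("s0", "sA", "sB")))
  meta <- data.frame(
    sample_id = c("s0", "sA", "sB"), experiment = "e1",
    treatment = c("source", "protists", "protists"),
    dilution_factor = c(NA, 1, 1), replicate = c(NA, 1L, 2L),
    timepoint = c("T0", "T12", "T12"))
  dens <- data.frame(
    experiment = "e1", treatment = "protists", dilution_factor = 1,
    replicate = c(1L, 2L, 1L, 2L), timepoint = c("T0", "T0", "T12", "T12"),
    cells_per_ml = c(1e6, 2e6, 3e6, 5e6))
  dex <- DilutionExperiment(counts, meta, dens)
  ab <- estimateAbsoluteAbundance(dex)
  t0 <- ab[ab$timepoint == "T0" & ab$taxon_id == "t1", ]
  expect_equal(t0$N, 0.5 * 1.5e6)
  a12 <- ab[ab$sample_id == "sA" & ab$taxon_id == "t2", ]
  expect_equal(a12$N, 0.6 * 4e6)
})

test_that("computePngr inverts exponential growth", {
  expect_equal(computePngr(1e5, 1e5), 0)
  expect_equal(computePngr(1e5, 1e5 * exp(1.2)), 0.1)
  expect_equal(computePngr(1e5, 1e5 / exp(1)), -1 / 12)
  ## zero population sizes signal exclusion, not an error
  expect_true(is.na(computePngr(0, 1e5)))
  expect_true(is.na(computePngr(1e5, 0)))
  ## per-capita invariance: scaling a bottle pair leaves R unchanged
  expect_equal(computePngr(3 * 1e5, 3 * 2e5), computePngr(1e5, 2e5))
})

test_that("fitPngrTcdf matches lines and conventions", {
  f <- fitPngrTcdf(c(0.25, 0.5, 0.75, 1), c(0.4, 0.3, 0.2, 0.1))
  expect_equal(f$slope, -0.4)
  expect_equal(f$intercept, 0.5)
  expect_equal(f$r2, 1)
  expect_equal(f$slope_p, 0) # perfect non-flat line
  ## flat series: slope 0, reported non-significant
  g <- fitPngrTcdf(c(0.25, 0.5, 0.75, 1), rep(0.2, 4))
  expect_equal(g$slope, 0)
  expect_equal(g$slope_p, 1)
  expect_error(fitPngrTcdf(c(0.5, 0.5, 0.5), c(1, 2, 3)), "distinct")
  expect_error(fitPngrTcdf(c(0.25, 0.5), c(1, 2)), "3 points")
})

test_that("OLS agrees with the normal-equations oracle and lm", {
  set.seed(99)
  for (i in 1:200) {
    x <- runif(8); y <- rnorm(8)
    f <- fitPngrTcdf(x, y)
    o <- oracleOls(x, y)
    expect_equal(f$slope, unname(o["slope"]), tolerance = 1e-10)
    expect_equal(f$intercept, unname(o["intercept"]), tolerance = 1e-10)
  }
  ## standard errors and p-values against lm on one instance
  x <- runif(8); y <- rnorm(8)
  f <- fitPngrTcdf(x, y)
  cf <- summary(lm(y ~ x))$coefficients
  expect_equal(f$slope_se, cf[2, 2], tolerance = 1e-10)
  expect_equal(f$slope_p, cf[2, 4], tolerance = 1e-10)
})

test_that("noiseless simulate -> estimate recovers (g, -m_P, -(m_P+m_V), -m_V)", {
  dex <- noiselessDex(n_taxa = 12, seed = 21)
  rec <- pngrRecords(dex, quiet = TRUE)
  est <- estimateTraits(fitAllPngr(rec, quiet = TRUE))
  m <- merge(est, truthTraits(dex), by = "taxon_id")
  expect_identical(nrow(m), 12L)
  expect_equal(m$competitiveness, m$g, tolerance = 1e-8)
  expect_equal(m$resistance_P, -m$m_P, tolerance = 1e-8)
  expect_equal(m$resistance_PV, -(m$m_P + m$m_V), tolerance = 1e-8)
  expect_equal(m$resistance_V, -m$m_V, tolerance = 1e-8)
  ## the subtraction identity holds to numerical precision
  expect_equal(m$resistance_V, m$resistance_PV - m$resistance_P,
               tolerance = 1e-12)
})

test_that("subtraction order flag flips the viral-resistance sign", {
  dex <- noiselessDex(n_taxa = 6, seed = 8)
  fits <- fitAllPngr(pngrRecords(dex, quiet = TRUE), quiet = TRUE)
  a <- estimateTraits(fits, subtraction_order = "pv_minus_p")
  b <- estimateTraits(fits, subtraction_order = "p_minus_pv")
  expect_equal(a$resistance_V, -b$resistance_V)
})

test_that("zero-read filter drops exactly the series touching a zero", {
  counts <- matrix(
    c(10, 0, 5,    # T0: taxon b absent
      8, 2, 5,  9, 1, 5,  7, 3, 5,  6, 4, 5,
      8, 2, 5,  9, 1, 5,  7, 3, 5,  6, 4, 0), # last sample: taxon c zero
    nrow = 3, dimnames = list(c("a", "b", "c"), NULL))
  d <- rep(c(0.25, 0.5, 0.75, 1), 2)
  meta <- data.frame(
    sample_id = paste0("s", 1:9), experiment = "e1",
    treatment = c("source", rep("protists", 4), rep("protists_viruses", 4)),
    dilution_factor = c(NA, d[1:4], d[5:8]),
    replicate = c(NA, rep(1L, 8)), timepoint = c("T0", rep("T12", 8)))
  colnames(counts) <- meta$sample_id
  dens <- expand.grid(replicate = 1L, timepoint = c("T0", "T12"),
                      dilution_factor = c(0.25, 0.5, 0.75, 1),
                      treatment = c("protists", "protists_viruses"),
                      stringsAsFactors = FALSE)
  dens$experiment <- "e1"; dens$cells_per_ml <- 1e6
  dex <- DilutionExperiment(counts, meta, dens)
  rec <- suppressMessages(pngrRecords(dex))
  kept <- unique(rec[c("taxon_id", "treatment")])
  ## taxon b: zero at T0 -> gone from both series; taxon c: zero in one PV
  ## sample -> only its PV series dropped
  expect_true(all(kept$taxon_id %in% c("a", "c")))
  expect_identical(sort(kept$treatment[kept$taxon_id == "c"]), "protists")
  ## retained records all have finite positive-N rates
  expect_true(all(is.finite(rec$R)))
})

test_that("community QC has the expected sign pattern in noiseless data", {
  tr <- drawTraits(10, g_mean = 0.15, g_sd = 0.03, beta_P = 0.5,
                   beta_V = 0.5, noise_sd = 0, seed = 31)
  des <- experimentDesign(seed = 31, density_cv = 0, exact_proportions = TRUE)
  qc <- communityPngrQc(simulateExperiment(des, tr))
  expect_true(all(qc$slope < 0)) # net growth decreases with dilution factor
  expect_true(all(qc$pv_above_p)) # PV line above P line for d < 1
  ## no top-down control: flat community lines
  tr0 <- drawTraits(10, beta_P = 0, beta_V = 0, alpha_P = 0, alpha_V = 0,
                    noise_sd = 0, seed = 31)
  qc0 <- communityPngrQc(simulateExperiment(des, tr0))
  expect_equal(qc0$slope, rep(0, 2), tolerance = 1e-10)
})

test_that("a missing T12 replicate still yields fits from the remaining points", {
  dex <- noiselessDex(n_taxa = 6, seed = 13)
  drop <- which(colnames(dex) == "exp1_P_d25_r1")
  dex2 <- DilutionExperiment(assay(dex, "counts")[, -drop],
                             sampleData(dex)[-drop, ],
                             densityTable(dex), truthTraits(dex))
  rec <- pngrRecords(dex2, quiet = TRUE)
  fits <- fitAllPngr(rec, quiet = TRUE)
  pfits <- fits[fits$treatment == "protists", ]
  expect_true(all(pfits$n_points == 7))
  est <- estimateTraits(fits)
  m <- merge(est, truthTraits(dex2), by = "taxon_id")
  expect_equal(m$resistance_P, -m$m_P, tolerance = 1e-8)
})
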