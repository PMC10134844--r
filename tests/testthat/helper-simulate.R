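## Shared fixtures, built in code.

## Noiseless dataset: exact proportions, no density noise. Downstream trait
## estimates are then analytically (g, -m_P, -(m_P + m_V)).
noiselessDex <- function(n_taxa = 10, seed = 42, experiment = "exp1", ...) {
  tr <- drawTraits(n_taxa, seed = seed, ...)
  simulateExperiment(
    experimentDesign(seed = seed, exact_proportions = TRUE, density_cv = 0),
    tr, experiment = experiment)
}

## Realistic dataset: multinomial reads at depth 3188, 5% density CV.
noisyDex <- function(n_taxa = 40, seed = 42, experiment = "exp1", ...) {
  tr <- drawTraits(n_taxa, seed = seed, ...)
  simulateExperiment(experimentDesign(seed = seed), tr,
                     experiment = experiment)
}

## Independent OLS oracle: normal equations solved directly.
oracleOls <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

## Independent Pearson oracle: covariance formula.
oraclePearson <- function(x, y) {
  mean((x - mean(x)) * (y - mean(y))) / (stats::sd(x) * stats::sd(y)) *
    length(x) / (length(x) - 1)
}
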