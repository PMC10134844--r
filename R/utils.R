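#' Derive a child seed from a master seed
#'
#' Every stochastic operation in the package draws its own seed from a master
#' seed and a stream index, so results are reproducible independently of the
#' order in which bottles or samples are processed.
#'
#' @param seed master seed, a single non-negative integer below 2^31.
#' @param index stream index (non-negative integer); distinct indices give
#'   distinct, effectively independent seeds.
#' @return a single integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' childSeed(42, 1)
#' childSeed(42, 2)
childSeed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0,
            is.numeric(index), length(index) == 1L, index >= 0)
  m <- 2147483647 # 2^31 - 1, Mersenne prime; products stay below 2^53
  s <- (seed %% m) * 48271 %% m
  s <- (s + (index %% m) * 69621) %% m
  s <- (s * 48271 + 12345) %% m
  as.integer(s %% (m - 1) + 1)
}

## Closed-form simple linear regression with the slope t-test.
## Returns slope, intercept, slope_se, slope_p (two-sided, n-2 df), r2, n.
## Degenerate conventions: zero residual variance with zero slope -> p = 1
## (a flat series is reported as non-significant); zero residual variance
## with a non-zero slope (perfect line) -> p = 0.
olsLine <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 2L)
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0) stop("degenerate design: all x values identical")
  xbar <- mean(x); ybar <- mean(y)
  slope <- sum((x - xbar) * (y - ybar)) / sxx
  intercept <- ybar - slope * xbar
  resid <- y - intercept - slope * x
  rss <- sum(resid^2)
  tss <- sum((y - ybar)^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  df <- n - 2L
  scale <- max(tss, abs(ybar)^2, 1)
  if (df <= 0L) {
    se <- NA_real_; p <- NA_real_
  } else if (rss <= 1e-24 * scale) {
    se <- 0
    p <- if (abs(slope) <= 1e-12 * sqrt(scale)) 1 else 0
  } else {
    se <- sqrt(rss / df / sxx)
    p <- 2 * stats::pt(-abs(slope / se), df = df)
  }
  list(slope = slope, intercept = intercept, slope_se = se, slope_p = p,
       r2 = r2, n = n)
}

isCount <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 1 && x == floor(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
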