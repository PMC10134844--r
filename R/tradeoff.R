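.CAUSES <- c("P", "PV", "V")

resistanceColumn <- function(cause) {
  cause <- match.arg(cause, .CAUSES)
  c(P = "resistance_P", PV = "resistance_PV", V = "resistance_V")[[cause]]
}

#' Competition-resistance trade-off within each experiment
#'
#' Tests whether faster-growing taxa are less resistant to top-down control:
#' Pearson correlation and ordinary least squares of resistance (to protist
#' grazing `"P"`, protists+viruses combined `"PV"`, or viruses alone `"V"`)
#' on competitiveness (the top-down-control-free growth rate), per
#' experiment. A negative slope is the kill-the-winner signature.
#'
#' @param traits trait table from [estimateTraits()].
#' @param cause `"P"`, `"PV"` or `"V"`.
#' @return `data.frame` with one row per experiment: `n` taxa used,
#'   `pearson_r`, `pearson_p`, `ols_slope`, `ols_intercept`, `ols_p`,
#'   `n_excluded` (taxa dropped for missing values).
#' @export
tradeoffPerExperiment <- function(traits, cause = c("P", "PV", "V")) {
  cause <- match.arg(cause)
  rcol <- resistanceColumn(cause)
  out <- lapply(unique(traits$experiment), function(ex) {
    tr <- traits[traits$experiment == ex, ]
    ok <- is.finite(tr$competitiveness) & is.finite(tr[[rcol]])
    x <- tr$competitiveness[ok]; y <- tr[[rcol]][ok]
    if (length(x) < 3L)
      stop("experiment ", ex, ": fewer than 3 taxa with both traits")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("experiment ", ex, ": zero variance, correlation undefined")
    ct <- stats::cor.test(x, y)
    f <- olsLine(x, y)
    data.frame(experiment = ex, cause = cause, n = length(x),
               pearson_r = unname(ct$estimate), pearson_p = ct$p.value,
               ols_slope = f$slope, ols_intercept = f$intercept,
               ols_p = f$slope_p, n_excluded = sum(!ok),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Random-intercept fit shared by the trade-off and diversity analyses.
## y ~ x with a random intercept per group (REML via nlme); the fixed-slope
## p-value is the Wald test with a normal approximation. A single group
## reduces to OLS (status "single_group_ols"); a failed lme fit falls back
## to OLS too; a fit whose between-group sd collapses is flagged "singular".
randomInterceptFit <- function(y, x, group) {
  ok <- is.finite(y) & is.finite(x) & !is.na(group)
  y <- y[ok]; x <- x[ok]; group <- factor(group[ok])
  n_groups <- nlevels(group)
  if (length(y) < 2L) stop("need >= 2 observations")
  olsResult <- function(status) {
    sm <- summary(stats::lm(y ~ x))$coefficients
    list(fixed_intercept = sm[1, 1], fixed_intercept_se = sm[1, 2],
         fixed_slope = sm[2, 1], fixed_slope_se = sm[2, 2],
         fixed_slope_p = 2 * stats::pnorm(-abs(sm[2, 1] / sm[2, 2])),
         random_intercept_sd = 0,
         residual_sd = sqrt(sum(stats::lm(y ~ x)$residuals^2) / (length(y) - 2)),
         n_obs = length(y), n_groups = n_groups, status = status)
  }
  if (n_groups < 2L) return(olsResult("single_group_ols"))
  df <- data.frame(y = y, x = x, group = group)
  fit <- tryCatch(
    nlme::lme(y ~ x, random = ~ 1 | group, data = df, method = "REML"),
    error = function(e) NULL)
  if (is.null(fit)) return(olsResult("lme_failed_ols"))
  fe <- nlme::fixef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  vc <- nlme::VarCorr(fit)
  ri_sd <- suppressWarnings(as.numeric(vc["(Intercept)", "StdDev"]))
  res_sd <- fit$sigma
  list(fixed_intercept = unname(fe[1]), fixed_intercept_se = unname(se[1]),
       fixed_slope = unname(fe[2]), fixed_slope_se = unname(se[2]),
       fixed_slope_p = 2 * stats::pnorm(-abs(fe[2] / se[2])),
       random_intercept_sd = ri_sd, residual_sd = res_sd,
       n_obs = length(y), n_groups = n_groups,
       status = if (ri_sd < 1e-6 * res_sd) "singular" else "ok")
}

#' Cross-experiment trade-off via a linear mixed-effects model
#'
#' Random-intercept model `resistance ~ competitiveness` with experiment as
#' the grouping factor, fitted by restricted maximum likelihood. The fixed
#' slope is the overall trade-off estimate; its p-value uses the Wald normal
#' approximation.
#'
#' @inheritParams tradeoffPerExperiment
#' @return list: `fixed_intercept`, `fixed_intercept_se`, `fixed_slope`,
#'   `fixed_slope_se`, `fixed_slope_p`, `random_intercept_sd`,
#'   `residual_sd`, `n_obs`, `n_groups`, `status` (`"ok"`, `"singular"`,
#'   `"single_group_ols"` or `"lme_failed_ols"`).
#' @export
tradeoffLmm <- function(traits, cause = c("P", "PV", "V")) {
  cause <- match.arg(cause)
  rcol <- resistanceColumn(cause)
  randomInterceptFit(traits[[rcol]], traits$competitiveness,
                     traits$experiment)
}

## Pre-compile the per-series regression state used by the permutation test:
## for each retained taxon x experiment x treatment series, the centred
## dilution design and the observed rates, plus the slope/intercept under
## the identity permutation. Means over d are permutation-invariant, so a
## permuted series only moves its slope; the intercept follows as
## ybar - slope * dbar, which is exactly the mechanical slope-intercept
## coupling the permutation null is designed to expose.
permSeriesState <- function(records) {
  ok <- is.finite(records$R)
  records <- records[ok, ]
  ser <- paste(records$taxon_id, records$experiment, records$treatment,
               sep = "\r")
  idx <- split(seq_len(nrow(records)), ser)
  keep <- vapply(idx, function(i) {
    d <- records$dilution_factor[i]
    length(i) >= 3L && length(unique(d)) >= 3L
  }, logical(1))
  idx <- idx[keep]
  info <- do.call(rbind, strsplit(names(idx), "\r", fixed = TRUE))
  list(
    taxon = info[, 1], experiment = info[, 2], treatment = info[, 3],
    d = lapply(idx, function(i) records$dilution_factor[i]),
    y = lapply(idx, function(i) records$R[i]))
}

permTraitTable <- function(state, slopes, intercepts) {
  slopes <- unname(slopes); intercepts <- unname(intercepts)
  key <- paste(state$taxon, state$experiment, sep = "\r")
  isP <- state$treatment == "protists"
  isPV <- state$treatment == "protists_viruses"
  ukey <- unique(key)
  ip <- match(ukey, ifelse(isP, key, NA))
  iv <- match(ukey, ifelse(isPV, key, NA))
  info <- do.call(rbind, strsplit(ukey, "\r", fixed = TRUE))
  data.frame(taxon_id = info[, 1], experiment = info[, 2],
             competitiveness = intercepts[iv],
             resistance_P = slopes[ip], resistance_PV = slopes[iv],
             resistance_V = slopes[iv] - slopes[ip],
             stringsAsFactors = FALSE)
}

#' Permutation null for the trade-off slope
#'
#' The competitiveness and resistance of a taxon are the intercept and slope
#' of one regression (protists+viruses) or of two closely related ones
#' (protists), so ordinary least squares couples them mechanically. This
#' test rebuilds the whole estimation chain under a null in which the
#' per-capita net growth rates of each taxon x treatment series are shuffled
#' across (dilution factor, replicate) positions, the regressions refitted,
#' traits re-derived, and the trade-off slope recomputed — by default 1000
#' times. The observed slope is compared to the null distribution through a
#' Z-score (with a Shapiro-Wilk check that the null is close to normal) and
#' a two-sided normal p; an empirical two-sided p is reported alongside.
#'
#' @param records PNGR records from [pngrRecords()].
#' @param cause `"P"`, `"PV"` or `"V"`.
#' @param n_perm number of permutations (default 1000; < 100 warns).
#' @param seed integer seed; the null vector is reproducible.
#' @param perm_mode `"within_taxon"` (default: shuffle rates within each
#'   series, preserving the slope-intercept coupling) or `"taxa"` (shuffle
#'   resistance values across taxa, holding competitiveness fixed).
#' @param statistic `"auto"` uses the mixed-model fixed slope when several
#'   experiments are present and the OLS slope otherwise; `"ols"` or
#'   `"lmm"` force one.
#' @return list: `observed_stat`, `null_stats`, `null_mean`, `null_sd`,
#'   `shapiro_p`, `z_score`, `z_p`, `p_empirical`, `n_taxa`, `statistic`.
#' @export
permutationNull <- function(records, cause = c("P", "PV", "V"),
                            n_perm = 1000L, seed = 1L,
                            perm_mode = c("within_taxon", "taxa"),
                            statistic = c("auto", "ols", "lmm")) {
  cause <- match.arg(cause)
  perm_mode <- match.arg(perm_mode)
  statistic <- match.arg(statistic)
  if (n_perm < 100L)
    warning("n_perm < 100: the permutation null will be coarse")
  state <- permSeriesState(records)
  nser <- length(state$d)
  if (!nser) stop("no usable series for the permutation test")
  dbar <- vapply(state$d, mean, 0)
  ybar <- vapply(state$y, mean, 0)
  dcent <- Map(function(d, m) d - m, state$d, dbar)
  sxx <- vapply(dcent, function(z) sum(z^2), 0)

  slopesFromY <- function(ylist) {
    vapply(seq_len(nser), function(i) sum(dcent[[i]] * ylist[[i]]), 0) / sxx
  }
  multi <- length(unique(state$experiment)) > 1L
  useLmm <- statistic == "lmm" || (statistic == "auto" && multi)
  rcol <- resistanceColumn(cause)
  statFun <- function(traits) {
    ok <- is.finite(traits$competitiveness) & is.finite(traits[[rcol]])
    x <- traits$competitiveness[ok]; y <- traits[[rcol]][ok]
    if (length(x) < 3L || stats::sd(x) == 0)
      stop("insufficient taxa for the trade-off statistic")
    if (useLmm && multi)
      randomInterceptFit(y, x, traits$experiment[ok])$fixed_slope
    else olsLine(x, y)$slope
  }

  obs_slopes <- slopesFromY(state$y)
  obs_int <- ybar - obs_slopes * dbar
  obs_traits <- permTraitTable(state, obs_slopes, obs_int)
  n_taxa <- sum(is.finite(obs_traits$competitiveness) &
                is.finite(obs_traits[[rcol]]))
  observed <- statFun(obs_traits)

  set.seed(childSeed(seed, 1L))
  null_stats <- numeric(n_perm)
  if (perm_mode == "within_taxon") {
    for (p in seq_len(n_perm)) {
      yp <- lapply(state$y, function(y) y[sample.int(length(y))])
      sl <- slopesFromY(yp)
      null_stats[p] <- statFun(permTraitTable(state, sl, ybar - sl * dbar))
    }
  } else {
    ok <- is.finite(obs_traits$competitiveness) & is.finite(obs_traits[[rcol]])
    x <- obs_traits$competitiveness[ok]; y <- obs_traits[[rcol]][ok]
    grp <- obs_traits$experiment[ok]
    for (p in seq_len(n_perm)) {
      ys <- y[sample.int(length(y))]
      null_stats[p] <- if (useLmm && multi)
        randomInterceptFit(ys, x, grp)$fixed_slope else olsLine(x, ys)$slope
    }
  }
  null_mean <- mean(null_stats)
  null_sd <- stats::sd(null_stats)
  z <- (observed - null_mean) / null_sd
  list(observed_stat = observed, null_stats = null_stats,
       null_mean = null_mean, null_sd = null_sd,
       shapiro_p = stats::shapiro.test(null_stats)$p.value,
       z_score = z, z_p = 2 * stats::pnorm(-abs(z)),
       p_empirical = (1 + sum(abs(null_stats - null_mean) >=
                                abs(observed - null_mean))) / (n_perm + 1),
       n_taxa = n_taxa,
       statistic = if (useLmm && multi) "lmm" else "ols")
}
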