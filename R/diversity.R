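#' Rarefy a count vector to fixed depth
#'
#' Subsampling without replacement (via [vegan::rrarefy()]) to remove
#' library-size bias before diversity computation. The default working depth
#' elsewhere in the package is 3188 reads, the shallowest-sample depth used
#' for the analyses this package implements.
#'
#' @param x integer count vector (named by taxon).
#' @param depth target total reads; must not exceed `sum(x)`.
#' @param seed integer seed.
#' @return integer vector summing exactly to `depth`; richness never
#'   increases.
#' @export
rarefyCounts <- function(x, depth, seed = 1L) {
  if (!isCount(depth)) stop("depth must be a positive integer")
  if (sum(x) < depth)
    stop("insufficient depth: sample has ", sum(x), " reads, need ", depth)
  if (any(x < 0) || any(x != floor(x))) stop("counts must be non-negative integers")
  if (sum(x) == depth) return(x)
  set.seed(as.integer(seed))
  ## counts are validated above; rrarefy's smallest-count heuristic warning
  ## does not apply
  out <- as.integer(suppressWarnings(vegan::rrarefy(x, depth)))
  names(out) <- names(x)
  out
}

#' Rank-normalised rank abundance distribution
#'
#' Makes RAD shape comparable across communities of different richness:
#' repeatedly draw `target_richness` of the present taxa uniformly without
#' replacement, renormalise their abundances to sum to 1, sort descending,
#' and average the resulting curves element-wise over `n_norm` repetitions.
#'
#' @param x count (or relative abundance) vector.
#' @param target_richness number of ranks to normalise to (>= 2, <= observed
#'   richness).
#' @param n_norm number of subsampling repetitions (default 1000).
#' @param seed integer seed.
#' @return numeric vector of length `target_richness`, non-increasing,
#'   summing to 1.
#' @export
normalizedRad <- function(x, target_richness, n_norm = 1000L, seed = 1L) {
  present <- x[x > 0]
  s <- length(present)
  if (!isCount(target_richness) || target_richness < 2)
    stop("target_richness must be an integer >= 2")
  if (target_richness > s)
    stop("target_richness (", target_richness, ") exceeds richness (", s, ")")
  if (target_richness == s)
    return(sort(present / sum(present), decreasing = TRUE))
  set.seed(as.integer(seed))
  acc <- numeric(target_richness)
  for (i in seq_len(n_norm)) {
    p <- present[sample.int(s, target_richness)]
    acc <- acc + sort(p / sum(p), decreasing = TRUE)
  }
  acc / n_norm
}

#' Zipf decay coefficient of a rank abundance distribution
#'
#' Fits the Zipf model `p_r ~ C * r^gamma` to a strictly positive RAD. The
#' default fit is ordinary least squares of `log(p_r)` on `log(r)`, which is
#' deterministic and exact on pure power laws; `method = "nls"` refits by
#' nonlinear least squares on the untransformed abundances starting from the
#' log-log solution. The decay coefficient is reported as `-gamma`, so
#' larger means steeper (stronger dominance); the raw exponent is returned
#' alongside.
#'
#' @param rad non-increasing positive abundance vector (see
#'   [normalizedRad()]); length >= 3.
#' @param method `"ols"` (default) or `"nls"`.
#' @return list: `decay` (= `-gamma`, >= 0 for decreasing RADs), `gamma`
#'   (fitted exponent), `log_c` (fitted log intercept).
#' @export
#' @examples
#' fitZipf((1 / (1:20)) / sum(1 / (1:20)))$decay # 1
fitZipf <- function(rad, method = c("ols", "nls")) {
  method <- match.arg(method)
  if (length(rad) < 3L) stop("need at least 3 ranks")
  if (any(rad <= 0)) stop("RAD must be strictly positive")
  r <- seq_along(rad)
  f <- olsLine(log(r), log(rad))
  gamma <- f$slope; logc <- f$intercept
  if (method == "nls") {
    dat <- data.frame(p = rad, r = r)
    nf <- tryCatch(
      stats::nls(p ~ exp(lc) * r^g, data = dat,
                 start = list(lc = logc, g = gamma)),
      error = function(e) NULL)
    if (!is.null(nf)) {
      cf <- stats::coef(nf)
      gamma <- unname(cf["g"]); logc <- unname(cf["lc"])
    }
  }
  list(decay = -gamma, gamma = gamma, log_c = logc)
}

#' Pielou evenness of a rank abundance distribution
#'
#' Shannon entropy (natural log) divided by the log of the number of ranks;
#' 1 on a perfectly even community, strictly less otherwise.
#'
#' @param rad positive abundance vector (renormalised internally); length
#'   >= 2.
#' @return evenness in `[0, 1]`.
#' @export
pielouEvenness <- function(rad) {
  if (length(rad) < 2L) stop("evenness undefined for fewer than 2 ranks")
  if (any(rad < 0)) stop("abundances must be non-negative")
  p <- rad / sum(rad)
  unname(vegan::diversity(p) / log(length(p)))
}

#' Per-sample diversity indices along the dilution gradient
#'
#' For every composition sample: rarefy to `depth` (skipped when the assay
#' holds exact proportions from the simulator's noiseless mode), compute
#' richness, then the rank-normalised RAD at the experiment's target
#' richness (default: the lowest post-rarefaction T12 richness within the
#' experiment) and from it the Zipf decay coefficient and Pielou evenness.
#'
#' @param dex a [DilutionExperiment-class].
#' @param depth rarefaction depth (default 3188 reads).
#' @param n_norm RAD normalisation repetitions.
#' @param seed master seed for rarefaction and RAD subsampling substreams.
#' @param target_richness optional fixed target richness; default derived
#'   per experiment.
#' @return `data.frame`: `sample_id`, `experiment`, `treatment`,
#'   `dilution_factor`, `replicate`, `timepoint`, `richness`, `evenness`,
#'   `rad_decay`, `rad_gamma`.
#' @export
diversityTable <- function(dex, depth = 3188L, n_norm = 1000L, seed = 1L,
                           target_richness = NULL) {
  sd_ <- sampleData(dex)
  cts <- assay(dex, "counts")
  integer_counts <- all(cts == floor(cts))
  out <- list()
  for (ex in unique(sd_$experiment)) {
    s_exp <- sd_[sd_$experiment == ex, ]
    mats <- list()
    for (j in seq_len(nrow(s_exp))) {
      x <- cts[, s_exp$sample_id[j]]
      mats[[s_exp$sample_id[j]]] <- if (integer_counts)
        rarefyCounts(x, depth, childSeed(seed, 7919L + j)) else x
    }
    rich <- vapply(mats, function(x) sum(x > 0), 0L)
    tgt <- target_richness %||%
      min(rich[s_exp$timepoint == "T12"])
    for (j in seq_len(nrow(s_exp))) {
      sid <- s_exp$sample_id[j]
      rad <- normalizedRad(mats[[sid]], min(tgt, rich[[sid]]), n_norm,
                           childSeed(seed, 104729L + j))
      zf <- fitZipf(rad)
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sid, experiment = ex, treatment = s_exp$treatment[j],
        dilution_factor = s_exp$dilution_factor[j],
        replicate = s_exp$replicate[j], timepoint = s_exp$timepoint[j],
        richness = rich[[sid]], evenness = pielouEvenness(rad),
        rad_decay = zf$decay, rad_gamma = zf$gamma,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Diversity index versus dilution factor, per treatment
#'
#' Random-intercept model `index ~ dilution_factor` with experiment as the
#' grouping factor, restricted to T12 samples of one treatment; shares the
#' mixed-model machinery of [tradeoffLmm()].
#'
#' @param records diversity table from [diversityTable()].
#' @param index one of `"richness"`, `"evenness"`, `"rad_decay"`.
#' @param treatment `"protists"` or `"protists_viruses"`.
#' @return as [tradeoffLmm()].
#' @export
diversityVsDilution <- function(records,
                                index = c("richness", "evenness", "rad_decay"),
                                treatment = c("protists", "protists_viruses")) {
  index <- match.arg(index)
  treatment <- match.arg(treatment)
  rec <- records[records$timepoint == "T12" & records$treatment == treatment, ]
  if (length(unique(rec$dilution_factor)) < 2L)
    stop("need >= 2 dilution levels")
  randomInterceptFit(rec[[index]], rec$dilution_factor, rec$experiment)
}

#' Aitchison (CLR-Euclidean) distance between two compositions
#'
#' Adds a pseudocount, closes each vector to proportions, takes logs,
#' centres by the sample's mean log, and returns the Euclidean distance
#' between the two centred log-ratio vectors. Scale-invariant when the
#' pseudocount is 0 and counts strictly positive.
#'
#' @param x,y count vectors over the same taxon set (matched by name when
#'   named).
#' @param pseudocount added to every count before closure (default 1).
#' @return non-negative distance; 0 iff the CLR vectors coincide.
#' @export
clrEuclidean <- function(x, y, pseudocount = 1) {
  if (length(x) != length(y)) stop("mismatched taxon sets")
  if (!is.null(names(x)) && !is.null(names(y))) {
    if (!setequal(names(x), names(y))) stop("mismatched taxon sets")
    y <- y[names(x)]
  }
  clr <- function(v) {
    v <- v + pseudocount
    if (any(v <= 0)) stop("non-positive values after pseudocount")
    lv <- log(v / sum(v))
    lv - mean(lv)
  }
  sqrt(sum((clr(x) - clr(y))^2))
}

#' Interaction ANCOVA for composition-change slopes
#'
#' Ordinary least squares of `distance ~ d * treatment`; the two-sided
#' p-value of the interaction term tests whether the compositional response
#' to the dilution gradient differs between treatments.
#'
#' @param data `data.frame` with columns `distance`, `dilution_factor`,
#'   `treatment`.
#' @return list: `interaction_estimate`, `interaction_se`, `interaction_p`,
#'   `coefficients` (full coefficient matrix), `n`.
#' @export
ancovaSlopes <- function(data) {
  stopifnot(all(c("distance", "dilution_factor", "treatment") %in% names(data)))
  if (length(unique(data$treatment)) != 2L)
    stop("ANCOVA requires exactly 2 treatments")
  fit <- stats::lm(distance ~ dilution_factor * treatment, data = data)
  cf <- summary(fit)$coefficients
  irow <- grep(":", rownames(cf))
  list(interaction_estimate = cf[irow, 1], interaction_se = cf[irow, 2],
       interaction_p = cf[irow, 4], coefficients = cf, n = nrow(data))
}

#' Composition maintenance under top-down control
#'
#' How far each incubated community moved from the initial (T0) community:
#' for every T12 sample, the mean Aitchison distance to the experiment's T0
#' composition over `n_sub` paired rarefactions at `depth` (T0 and T12 are
#' rarefied with the same substream so repetitions are reproducible). Slopes
#' of distance on the dilution factor are fitted per experiment x treatment,
#' and a pooled interaction ANCOVA compares the two treatments' slopes.
#'
#' @param dex a [DilutionExperiment-class].
#' @param n_sub rarefaction repetitions per distance (default 100).
#' @param depth rarefaction depth (default 3188).
#' @param seed master seed.
#' @param pseudocount CLR pseudocount.
#' @return list: `distances` (`data.frame` per T12 sample), `fits`
#'   (per experiment x treatment OLS), `ancova` (see [ancovaSlopes()]).
#' @export
compositionMaintenance <- function(dex, n_sub = 100L, depth = 3188L,
                                   seed = 1L, pseudocount = 1) {
  sd_ <- sampleData(dex)
  cts <- assay(dex, "counts")
  integer_counts <- all(cts == floor(cts))
  dist_rows <- list()
  for (ex in unique(sd_$experiment)) {
    s_exp <- sd_[sd_$experiment == ex, ]
    src <- s_exp[s_exp$treatment == "source" & s_exp$timepoint == "T0", ]
    if (nrow(src) != 1L) stop("experiment ", ex, " needs one T0 sample")
    x0 <- cts[, src$sample_id]
    t12 <- s_exp[s_exp$timepoint == "T12", ]
    for (j in seq_len(nrow(t12))) {
      x12 <- cts[, t12$sample_id[j]]
      if (integer_counts) {
        dsub <- vapply(seq_len(n_sub), function(k) {
          s <- childSeed(seed, 1000L * j + k)
          clrEuclidean(rarefyCounts(x0, depth, s),
                       rarefyCounts(x12, depth, childSeed(s, 1L)),
                       pseudocount)
        }, 0)
        dist_j <- mean(dsub)
      } else {
        dist_j <- clrEuclidean(x0, x12, pseudocount)
      }
      dist_rows[[length(dist_rows) + 1L]] <- data.frame(
        sample_id = t12$sample_id[j], experiment = ex,
        treatment = t12$treatment[j],
        dilution_factor = t12$dilution_factor[j],
        replicate = t12$replicate[j], distance = dist_j,
        stringsAsFactors = FALSE)
    }
  }
  distances <- do.call(rbind, dist_rows)
  rownames(distances) <- NULL
  fits <- list()
  for (ex in unique(distances$experiment))
    for (trt in unique(distances$treatment)) {
      g <- distances[distances$experiment == ex & distances$treatment == trt, ]
      f <- olsLine(g$dilution_factor, g$distance)
      fits[[length(fits) + 1L]] <- data.frame(
        experiment = ex, treatment = trt, slope = f$slope,
        intercept = f$intercept, slope_se = f$slope_se, slope_p = f$slope_p,
        r2 = f$r2, n = f$n, stringsAsFactors = FALSE)
    }
  fits <- do.call(rbind, fits)
  rownames(fits) <- NULL
  list(distances = distances, fits = fits, ancova = ancovaSlopes(distances))
}
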