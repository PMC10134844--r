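#' Per-taxon absolute abundances from reads and cytometry densities
#'
#' Converts the relative abundance of each ASV into cells/mL by multiplying
#' with the mean total bacterial density of the duplicate bottles sharing the
#' same treatment and dilution factor. The single T0 composition sample of
#' each experiment (the shared source water) supplies the T0 relative
#' abundances for every bottle; each T12 bottle uses its own composition
#' sample. A missing T12 composition sample (e.g. a failed PCR) simply
#' yields no row for that bottle, and a missing density replicate reduces
#' the duplicate mean to the available bottle.
#'
#' @param dex a [DilutionExperiment-class].
#' @return `data.frame` with one row per taxon x bottle x timepoint:
#'   `taxon_id`, `sample_id`, `experiment`, `treatment`, `dilution_factor`,
#'   `replicate` (`NA` for the shared T0 values), `timepoint`, `reads` (the
#'   taxon's reads in the composition sample used), and `N` (cells/mL).
#'   T0 rows are emitted once per treatment x dilution cell.
#' @export
estimateAbsoluteAbundance <- function(dex) {
  stopifnot(is(dex, "DilutionExperiment"))
  cts <- assay(dex, "counts")
  sd_ <- sampleData(dex)
  den <- densityTable(dex)
  out <- list()
  for (exp_id in unique(sd_$experiment)) {
    s_exp <- sd_[sd_$experiment == exp_id, ]
    src <- s_exp[s_exp$treatment == "source" & s_exp$timepoint == "T0", ]
    if (nrow(src) != 1L)
      stop("experiment ", exp_id, " must have exactly one T0 source sample")
    c0 <- cts[, src$sample_id]
    tot0 <- sum(c0)
    if (tot0 <= 0) stop("zero total reads in sample ", src$sample_id)
    rel0 <- c0 / tot0
    d_exp <- den[den$experiment == exp_id, ]
    t12 <- s_exp[s_exp$timepoint == "T12", ]
    cells <- unique(t12[c("treatment", "dilution_factor")])
    for (k in seq_len(nrow(cells))) {
      trt <- cells$treatment[k]; dk <- cells$dilution_factor[k]
      dcell <- d_exp[d_exp$treatment == trt & d_exp$dilution_factor == dk, ]
      mean0 <- mean(dcell$cells_per_ml[dcell$timepoint == "T0"])
      mean12 <- mean(dcell$cells_per_ml[dcell$timepoint == "T12"])
      if (!is.finite(mean0) || !is.finite(mean12))
        stop("missing density records for ", exp_id, " ", trt, " d=", dk)
      out[[length(out) + 1L]] <- data.frame(
        taxon_id = rownames(cts), sample_id = src$sample_id,
        experiment = exp_id, treatment = trt, dilution_factor = dk,
        replicate = NA_integer_, timepoint = "T0", reads = c0,
        N = rel0 * mean0, stringsAsFactors = FALSE)
      smp <- t12[t12$treatment == trt & t12$dilution_factor == dk, ]
      for (j in seq_len(nrow(smp))) {
        cj <- cts[, smp$sample_id[j]]
        totj <- sum(cj)
        if (totj <= 0) stop("zero total reads in sample ", smp$sample_id[j])
        out[[length(out) + 1L]] <- data.frame(
          taxon_id = rownames(cts), sample_id = smp$sample_id[j],
          experiment = exp_id, treatment = trt, dilution_factor = dk,
          replicate = smp$replicate[j], timepoint = "T12", reads = cj,
          N = cj / totj * mean12, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-capita net growth rate over the incubation
#'
#' `R = ln(N12 / N0) / t`, assuming density-independent exponential growth
#' over the incubation. Pairs where either population size is zero return
#' `NA` — the record is excluded rather than an error raised, matching the
#' zero-read filter applied upstream.
#'
#' @param N0,N12 initial and final population sizes, cells/mL.
#' @param t incubation time in hours (default 12).
#' @return per-capita net growth rate(s), h^-1.
#' @export
#' @examples
#' computePngr(1e5, 1e5 * exp(1.2)) # 0.1
computePngr <- function(N0, N12, t = 12) {
  stopifnot(t > 0, all(N0 >= 0, na.rm = TRUE), all(N12 >= 0, na.rm = TRUE))
  ifelse(N0 > 0 & N12 > 0, log(N12 / N0) / t, NA_real_)
}

#' Per-taxon PNGR records along the dilution gradient
#'
#' Builds the regression inputs: one per-capita net growth rate per taxon x
#' bottle, from the shared T0 abundances and the bottle's own T12
#' abundances. The zero-read filter is applied per taxon x experiment x
#' treatment series: a taxon is dropped from a series when any constituent
#' composition sample (the T0 source sample or any of the treatment's T12
#' samples) recorded zero reads for it, so retained series have strictly
#' positive abundances everywhere.
#'
#' @param dex a [DilutionExperiment-class].
#' @param duration incubation hours (default 12).
#' @param replicate_mode `"pooled"` keeps one point per replicate bottle (up
#'   to 8 per series); `"mean"` averages duplicate T12 abundances first (4
#'   points per series).
#' @param quiet suppress the per-series exclusion messages.
#' @return `data.frame` of PNGR records: `taxon_id`, `experiment`,
#'   `treatment`, `dilution_factor`, `replicate`, `R` (h^-1).
#' @export
pngrRecords <- function(dex, duration = 12,
                        replicate_mode = c("pooled", "mean"),
                        quiet = FALSE) {
  replicate_mode <- match.arg(replicate_mode)
  ab <- estimateAbsoluteAbundance(dex)
  t0 <- ab[ab$timepoint == "T0", ]
  t12 <- ab[ab$timepoint == "T12", ]
  if (replicate_mode == "mean") {
    agg <- stats::aggregate(
      cbind(reads, N) ~ taxon_id + experiment + treatment + dilution_factor,
      data = t12, FUN = mean)
    agg$replicate <- NA_integer_
    t12 <- agg
  }
  key12 <- paste(t12$taxon_id, t12$experiment, t12$treatment,
                 t12$dilution_factor, sep = "\r")
  key0 <- paste(t0$taxon_id, t0$experiment, t0$treatment,
                t0$dilution_factor, sep = "\r")
  idx <- match(key12, key0)
  if (anyNA(idx)) stop("T0 record missing for some taxon x bottle")
  rec <- data.frame(taxon_id = t12$taxon_id, experiment = t12$experiment,
                    treatment = t12$treatment,
                    dilution_factor = t12$dilution_factor,
                    replicate = t12$replicate,
                    reads0 = t0$reads[idx], reads12 = t12$reads,
                    R = computePngr(t0$N[idx], t12$N, t = duration),
                    stringsAsFactors = FALSE)
  ser <- paste(rec$taxon_id, rec$experiment, rec$treatment, sep = "\r")
  bad <- unique(ser[rec$reads0 <= 0 | rec$reads12 <= 0])
  if (length(bad) && !quiet)
    message(length(bad), " taxon-series removed by the zero-read filter")
  rec <- rec[!ser %in% bad, ]
  rec$reads0 <- NULL; rec$reads12 <- NULL
  rownames(rec) <- NULL
  rec
}

#' Fit the PNGR-TCDF regression for one taxon series
#'
#' Ordinary least squares of the per-capita net growth rate on the top-down
#' control dilution factor. The slope p-value is the two-sided t-test with
#' `n - 2` degrees of freedom; a perfectly flat series is reported with
#' slope 0 and p = 1.
#'
#' @param d dilution fractions.
#' @param R per-capita net growth rates, h^-1.
#' @return list with `slope`, `intercept`, `slope_se`, `slope_p`, `r2`, `n`.
#' @export
#' @examples
#' fitPngrTcdf(c(0.25, 0.5, 0.75, 1), c(0.4, 0.3, 0.2, 0.1))
fitPngrTcdf <- function(d, R) {
  keep <- is.finite(d) & is.finite(R)
  d <- d[keep]; R <- R[keep]
  if (length(d) < 3L || length(unique(d)) < 3L)
    stop("need >= 3 points spanning >= 3 distinct dilution factors")
  olsLine(d, R)
}

#' Fit PNGR-TCDF regressions for every taxon x experiment x treatment
#'
#' @param records PNGR records from [pngrRecords()].
#' @param min_levels minimum distinct dilution factors required (default 3);
#'   series below the threshold are skipped.
#' @param quiet suppress the skipped-series message.
#' @return `data.frame` of fits: `taxon_id`, `experiment`, `treatment`,
#'   `slope` (h^-1 per unit dilution fraction), `intercept` (h^-1),
#'   `slope_se`, `slope_p`, `r2`, `n_points`.
#' @export
fitAllPngr <- function(records, min_levels = 3L, quiet = FALSE) {
  ser <- paste(records$taxon_id, records$experiment, records$treatment,
               sep = "\r")
  groups <- split(seq_len(nrow(records)), ser)
  rows <- vector("list", length(groups))
  skipped <- 0L
  for (i in seq_along(groups)) {
    g <- records[groups[[i]], ]
    ok <- is.finite(g$R)
    if (sum(ok) < 3L || length(unique(g$dilution_factor[ok])) < min_levels) {
      skipped <- skipped + 1L
      next
    }
    f <- olsLine(g$dilution_factor[ok], g$R[ok])
    rows[[i]] <- data.frame(
      taxon_id = g$taxon_id[1L], experiment = g$experiment[1L],
      treatment = g$treatment[1L], slope = f$slope, intercept = f$intercept,
      slope_se = f$slope_se, slope_p = f$slope_p, r2 = f$r2, n_points = f$n,
      stringsAsFactors = FALSE)
  }
  if (skipped && !quiet)
    message(skipped, " series skipped: fewer than ", min_levels,
            " usable dilution levels")
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(taxon_id = character(), experiment = character(),
                      treatment = character(), slope = numeric(),
                      intercept = numeric(), slope_se = numeric(),
                      slope_p = numeric(), r2 = numeric(),
                      n_points = integer())
  rownames(res) <- NULL
  res
}

#' Competitiveness and resistance estimates per taxon
#'
#' Derives the trait triplet from the two treatment regressions:
#' competitiveness `a` is the intercept under protists+viruses dilution (the
#' growth rate extrapolated to zero top-down control), resistance to protist
#' grazing `b` is the slope under protists dilution, resistance to
#' protists+viruses combined `c` is the slope under protists+viruses
#' dilution, and resistance to viruses alone is the difference of the two
#' slopes (default `c - b`; more negative = more mortality). Partial
#' estimates (a taxon retained under only one treatment) carry `NA` in the
#' missing fields.
#'
#' @param fits fit table from [fitAllPngr()].
#' @param subtraction_order `"pv_minus_p"` (default, `c - b`) or
#'   `"p_minus_pv"` (`b - c`) for the viral-resistance difference.
#' @return `data.frame`: `taxon_id`, `experiment`, `competitiveness`,
#'   `resistance_P`, `resistance_PV`, `resistance_V`, `p_P`, `p_PV`.
#' @export
estimateTraits <- function(fits, subtraction_order = c("pv_minus_p",
                                                       "p_minus_pv")) {
  subtraction_order <- match.arg(subtraction_order)
  key <- unique(fits[c("taxon_id", "experiment")])
  p_ <- fits[fits$treatment == "protists", ]
  pv <- fits[fits$treatment == "protists_viruses", ]
  kp <- paste(p_$taxon_id, p_$experiment, sep = "\r")
  kv <- paste(pv$taxon_id, pv$experiment, sep = "\r")
  kk <- paste(key$taxon_id, key$experiment, sep = "\r")
  ip <- match(kk, kp); iv <- match(kk, kv)
  b <- p_$slope[ip]; cc <- pv$slope[iv]
  rv <- if (subtraction_order == "pv_minus_p") cc - b else b - cc
  res <- data.frame(taxon_id = key$taxon_id, experiment = key$experiment,
                    competitiveness = pv$intercept[iv],
                    resistance_P = b, resistance_PV = cc, resistance_V = rv,
                    p_P = p_$slope_p[ip], p_PV = pv$slope_p[iv],
                    stringsAsFactors = FALSE)
  res[order(res$experiment, res$taxon_id), , drop = FALSE] -> res
  rownames(res) <- NULL
  res
}

#' Community-level PNGR quality control
#'
#' Regresses the whole-community per-capita net growth rate (from the
#' measured total densities per bottle) on the dilution factor, per
#' treatment. With active top-down control the community rate should
#' decrease with the dilution factor in both treatments, and the
#' protists+viruses line should lie above the protists line for d < 1
#' (viruses stay at full strength under protists-only dilution).
#'
#' @param dex a [DilutionExperiment-class].
#' @param duration incubation hours.
#' @return `data.frame` with one row per experiment x treatment: `slope`,
#'   `intercept`, `slope_p`, `r2`, `n`, plus the logical `pv_above_p`
#'   pattern check (identical within experiment).
#' @export
communityPngrQc <- function(dex, duration = 12) {
  den <- densityTable(dex)
  key <- paste(den$experiment, den$treatment, den$dilution_factor,
               den$replicate, sep = "\r")
  t0 <- den[den$timepoint == "T0", ]; t12 <- den[den$timepoint == "T12", ]
  k0 <- paste(t0$experiment, t0$treatment, t0$dilution_factor, t0$replicate,
              sep = "\r")
  k12 <- paste(t12$experiment, t12$treatment, t12$dilution_factor,
               t12$replicate, sep = "\r")
  idx <- match(k12, k0)
  if (anyNA(idx)) stop("unmatched bottle between timepoints")
  bot <- data.frame(experiment = t12$experiment, treatment = t12$treatment,
                    d = t12$dilution_factor,
                    R = computePngr(t0$cells_per_ml[idx], t12$cells_per_ml,
                                    t = duration))
  out <- list()
  for (ex in unique(bot$experiment)) {
    fits <- lapply(c("protists", "protists_viruses"), function(trt) {
      g <- bot[bot$experiment == ex & bot$treatment == trt, ]
      c(list(experiment = ex, treatment = trt), olsLine(g$d, g$R))
    })
    dd <- sort(unique(bot$d[bot$experiment == ex]))
    pv_above <- all(
      (fits[[2]]$intercept + fits[[2]]$slope * dd[dd < 1]) >=
      (fits[[1]]$intercept + fits[[1]]$slope * dd[dd < 1]) - 1e-12)
    out[[ex]] <- do.call(rbind, lapply(fits, function(f)
      data.frame(experiment = f$experiment, treatment = f$treatment,
                 slope = f$slope, intercept = f$intercept,
                 slope_p = f$slope_p, r2 = f$r2, n = f$n,
                 pv_above_p = pv_above, stringsAsFactors = FALSE)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
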