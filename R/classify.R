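#' Classify ASVs as resistant, susceptible or non-significant
#'
#' A taxon whose per-capita net growth rate rises with the top-down-control
#' dilution factor (positive PNGR-TCDF slope, p below `alpha`) is classified
#' resistant to the cause; a significant negative slope means susceptible;
#' anything else is non-significant. P-values are uncorrected by default,
#' with an optional Benjamini-Hochberg mode.
#'
#' @param fits fit table from [fitAllPngr()].
#' @param cause `"P"` (protists-diluted) or `"PV"` (protists+viruses-
#'   diluted).
#' @param alpha significance threshold (default 0.05).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return `data.frame`: `taxon_id`, `experiment`, `cause`, `slope`,
#'   `slope_p`, `category`.
#' @export
classifyAsvs <- function(fits, cause = c("P", "PV"), alpha = 0.05,
                         p_adjust = c("none", "BH")) {
  cause <- match.arg(cause)
  p_adjust <- match.arg(p_adjust)
  stopifnot(alpha > 0, alpha < 1)
  trt <- c(P = "protists", PV = "protists_viruses")[[cause]]
  f <- fits[fits$treatment == trt, ]
  p <- if (p_adjust == "BH") stats::p.adjust(f$slope_p, "BH") else f$slope_p
  category <- ifelse(p < alpha & f$slope > 0, "resistant",
              ifelse(p < alpha & f$slope < 0, "susceptible",
                     "nonsignificant"))
  res <- data.frame(taxon_id = f$taxon_id, experiment = f$experiment,
                    cause = cause, slope = f$slope, slope_p = p,
                    category = category, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Order-level summary of resistance classifications
#'
#' Aggregates ASV classifications to taxonomic orders: counts of resistant
#' and susceptible ASVs, total ASVs, and the mean resistance (mean
#' PNGR-TCDF slope) per order — over significant ASVs only or over all —
#' with orders ranked from the most to the least resistant (ties broken
#' lexicographically; orders without a defined mean rank last).
#'
#' @param classifications from [classifyAsvs()].
#' @param taxonomy `data.frame` with columns `taxon_id` and `order`; taxa
#'   without a label are grouped as `"Unassigned"`.
#' @param significant_only if `TRUE` (default) the mean is over significant
#'   ASVs only.
#' @return `data.frame`: `order`, `n_resistant`, `n_susceptible`,
#'   `n_total`, `mean_resistance`, `rank`.
#' @export
orderSummary <- function(classifications, taxonomy, significant_only = TRUE) {
  if (!nrow(classifications))
    return(data.frame(order = character(), n_resistant = integer(),
                      n_susceptible = integer(), n_total = integer(),
                      mean_resistance = numeric(), rank = integer()))
  ord <- taxonomy$order[match(classifications$taxon_id, taxonomy$taxon_id)]
  ord[is.na(ord) | ord == ""] <- "Unassigned"
  sig <- classifications$category != "nonsignificant"
  res <- do.call(rbind, lapply(sort(unique(ord)), function(o) {
    i <- ord == o
    use <- i & (if (significant_only) sig else TRUE)
    data.frame(order = o,
               n_resistant = sum(i & classifications$category == "resistant"),
               n_susceptible = sum(i & classifications$category == "susceptible"),
               n_total = sum(i),
               mean_resistance = if (any(use))
                 mean(classifications$slope[use]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  res <- res[order(-res$mean_resistance, res$order, na.last = TRUE), ]
  ## NA means sort last regardless of the minus sign
  res <- rbind(res[!is.na(res$mean_resistance), ],
               res[is.na(res$mean_resistance), ])
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}
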