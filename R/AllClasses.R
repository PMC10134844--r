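#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' DilutionExperiment: container for a top-down-control dilution experiment
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with a `counts` assay
#' (ASV x sample reads; or exact relative abundances in noiseless simulation
#' mode), per-sample design metadata in `colData`, a flow-cytometry density
#' table, and (for synthetic data) the ground-truth taxon traits.
#'
#' `colData` must carry `experiment`, `treatment` (one of `"protists"`,
#' `"protists_viruses"`, `"source"`), `dilution_factor` (fraction in (0, 1];
#' `NA` for the source-water sample), `replicate` and `timepoint` (`"T0"` or
#' `"T12"`). The density table has one row per bottle x timepoint with a
#' positive `cells_per_ml`.
#'
#' @slot densities `data.frame` of bottle densities (columns `experiment`,
#'   `treatment`, `dilution_factor`, `replicate`, `timepoint`,
#'   `cells_per_ml`).
#' @slot truth ground-truth taxon traits (`data.frame` with columns
#'   `taxon_id`, `g`, `m_P`, `m_V`, `p0`) or `NULL` for observed data.
#' @aliases DilutionExperiment-class
#' @export
setClass("DilutionExperiment",
  contains = "SummarizedExperiment",
  slots = c(densities = "data.frame", truth = "data.frameOrNULL"))

.TREATMENTS <- c("protists", "protists_viruses", "source")

validDilutionExperiment <- function(object) {
  msg <- character()
  cts <- assay(object, "counts")
  if (any(!is.finite(cts)) || any(cts < 0))
    msg <- c(msg, "counts must be finite and non-negative")
  cd <- as.data.frame(colData(object))
  need <- c("experiment", "treatment", "dilution_factor", "replicate",
            "timepoint")
  miss <- setdiff(need, names(cd))
  if (length(miss))
    msg <- c(msg, paste("colData lacks column(s):", paste(miss, collapse = ", ")))
  if (!length(miss)) {
    if (!all(cd$treatment %in% .TREATMENTS))
      msg <- c(msg, "treatment must be 'protists', 'protists_viruses' or 'source'")
    if (!all(cd$timepoint %in% c("T0", "T12")))
      msg <- c(msg, "timepoint must be 'T0' or 'T12'")
    d <- cd$dilution_factor[cd$treatment != "source"]
    if (any(is.na(d)) || any(d <= 0 | d > 1))
      msg <- c(msg, "dilution_factor must lie in (0, 1] for incubated samples")
    key <- do.call(paste, c(cd[need], sep = "\r"))
    if (anyDuplicated(key))
      msg <- c(msg, "duplicated (experiment, treatment, dilution, replicate, timepoint)")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "taxon identifiers must be unique")
  den <- object@densities
  if (nrow(den)) {
    dn <- setdiff(c("experiment", "treatment", "dilution_factor", "replicate",
                    "timepoint", "cells_per_ml"), names(den))
    if (length(dn))
      msg <- c(msg, paste("densities lacks column(s):", paste(dn, collapse = ", ")))
    else if (any(!is.finite(den$cells_per_ml)) || any(den$cells_per_ml <= 0))
      msg <- c(msg, "cells_per_ml must be positive")
  }
  if (!is.null(object@truth)) {
    tn <- setdiff(c("taxon_id", "g", "m_P", "m_V", "p0"), names(object@truth))
    if (length(tn))
      msg <- c(msg, paste("truth lacks column(s):", paste(tn, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
}

setValidity("DilutionExperiment", validDilutionExperiment)

#' Construct a DilutionExperiment
#'
#' @param counts numeric matrix, taxa in rows and samples in columns; integer
#'   read counts for observed data, or relative abundances in the simulator's
#'   exact-proportions mode.
#' @param metadata `data.frame` of per-sample design annotations, one row per
#'   column of `counts` (matched by `sample_id` or row order); see
#'   [DilutionExperiment-class] for required columns.
#' @param densities `data.frame` of bottle densities.
#' @param truth optional ground-truth taxon traits (synthetic data only).
#' @return a [DilutionExperiment-class] object.
#' @export
#' @examples
#' traits <- drawTraits(10, seed = 1)
#' dex <- simulateExperiment(experimentDesign(seed = 1), traits)
#' dex
DilutionExperiment <- function(counts, metadata, densities, truth = NULL) {
  counts <- as.matrix(counts)
  metadata <- as.data.frame(metadata)
  if ("sample_id" %in% names(metadata)) {
    if (is.null(colnames(counts)))
      stop("counts must have sample identifiers as column names")
    miss <- setdiff(colnames(counts), metadata$sample_id)
    if (length(miss))
      stop("sample(s) in counts absent from metadata: ",
           paste(miss, collapse = ", "))
    if (anyDuplicated(metadata$sample_id))
      stop("duplicated sample_id in metadata")
    metadata <- metadata[match(colnames(counts), metadata$sample_id), ,
                         drop = FALSE]
    rownames(metadata) <- metadata$sample_id
  } else if (nrow(metadata) != ncol(counts)) {
    stop("metadata must have one row per counts column")
  }
  new("DilutionExperiment",
      SummarizedExperiment(assays = list(counts = counts),
                           colData = DataFrame(metadata)),
      densities = as.data.frame(densities), truth = truth)
}

#' @describeIn DilutionExperiment-class bottle density table accessor.
#' @param object a `DilutionExperiment`.
#' @export
setGeneric("densityTable", function(object) standardGeneric("densityTable"))

#' @rdname DilutionExperiment-class
#' @export
setMethod("densityTable", "DilutionExperiment", function(object) object@densities)

#' @describeIn DilutionExperiment-class ground-truth trait accessor (synthetic
#'   data; `NULL` for observed data).
#' @export
setGeneric("truthTraits", function(object) standardGeneric("truthTraits"))

#' @rdname DilutionExperiment-class
#' @export
setMethod("truthTraits", "DilutionExperiment", function(object) object@truth)

#' @describeIn DilutionExperiment-class per-sample design table as a plain
#'   `data.frame` (with a `sample_id` column).
#' @export
setGeneric("sampleData", function(object) standardGeneric("sampleData"))

#' @rdname DilutionExperiment-class
#' @export
setMethod("sampleData", "DilutionExperiment", function(object) {
  cd <- as.data.frame(colData(object))
  cd$sample_id <- colnames(object)
  rownames(cd) <- NULL
  cd[c("sample_id", setdiff(names(cd), "sample_id"))]
})

setMethod("show", "DilutionExperiment", function(object) {
  cd <- colData(object)
  cat("class: DilutionExperiment\n")
  cat(sprintf("taxa: %d  samples: %d\n", nrow(object), ncol(object)))
  cat(sprintf("experiments: %s\n",
              paste(unique(cd$experiment), collapse = ", ")))
  cat(sprintf("samples: %d T0 (source) + %d T12\n",
              sum(cd$timepoint == "T0"), sum(cd$timepoint == "T12")))
  cat(sprintf("density records: %d\n", nrow(object@densities)))
  cat(sprintf("ground truth: %s\n",
              if (is.null(object@truth)) "absent" else
                sprintf("%d taxa", nrow(object@truth))))
})
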