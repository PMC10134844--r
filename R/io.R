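#' Pipeline configuration
#'
#' Collects the analysis constants in one validated object. Defaults match
#' the working values used throughout the package: rarefaction depth 3188
#' reads, 1000 RAD normalisations, 1000 permutations, 100 distance
#' subsamplings, alpha 0.05, 12-h incubation.
#'
#' @param depth rarefaction depth (reads).
#' @param n_norm RAD normalisation repetitions.
#' @param n_perm permutations for the null (values below 100 warn at use).
#' @param n_sub rarefaction repetitions per composition distance.
#' @param alpha significance threshold for slope classification.
#' @param duration_h incubation duration, hours.
#' @param seed master seed.
#' @param replicate_mode `"pooled"` or `"mean"` (see [pngrRecords()]).
#' @param subtraction_order viral-resistance convention (see
#'   [estimateTraits()]).
#' @param perm_mode permutation scheme (see [permutationNull()]).
#' @return list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(depth = 3188L, n_norm = 1000L, n_perm = 1000L,
                           n_sub = 100L, alpha = 0.05, duration_h = 12,
                           seed = 1L,
                           replicate_mode = c("pooled", "mean"),
                           subtraction_order = c("pv_minus_p", "p_minus_pv"),
                           perm_mode = c("within_taxon", "taxa")) {
  for (v in list(depth, n_norm, n_perm, n_sub))
    if (!isCount(v)) stop("depth, n_norm, n_perm and n_sub must be integers >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (duration_h <= 0) stop("duration_h must be positive")
  structure(list(depth = as.integer(depth), n_norm = as.integer(n_norm),
                 n_perm = as.integer(n_perm), n_sub = as.integer(n_sub),
                 alpha = alpha, duration_h = duration_h,
                 seed = as.integer(seed),
                 replicate_mode = match.arg(replicate_mode),
                 subtraction_order = match.arg(subtraction_order),
                 perm_mode = match.arg(perm_mode)),
            class = "PipelineConfig")
}

.readTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read the pipeline input tables
#'
#' Parses and cross-validates the four standard inputs: a taxa x samples
#' count table (TSV with taxon identifiers in the first column, or
#' Matrix-Market triplets with sidecar taxon/sample index files), the sample
#' metadata TSV, the flow-cytometry density CSV, and an optional taxonomy
#' TSV (`taxon_id`, `order`).
#'
#' @param counts_path count table path.
#' @param metadata_path sample metadata path.
#' @param densities_path density table path.
#' @param taxonomy_path optional taxonomy path.
#' @param counts_format `"tsv"` (default) or `"mtx"`; for `"mtx"`, files
#'   `<stem>.taxa.txt` and `<stem>.samples.txt` must sit next to the matrix.
#' @return list: `dex` (a [DilutionExperiment-class]) and `taxonomy`
#'   (`data.frame` or `NULL`).
#' @export
readTables <- function(counts_path, metadata_path, densities_path,
                       taxonomy_path = NULL,
                       counts_format = c("tsv", "mtx")) {
  counts_format <- match.arg(counts_format)
  if (counts_format == "tsv") {
    ct <- .readTsv(counts_path)
    taxa <- ct[[1L]]
    if (anyDuplicated(taxa)) stop("duplicate taxon identifier in counts: ",
                                  taxa[duplicated(taxa)][1L])
    counts <- as.matrix(ct[-1L])
    rownames(counts) <- taxa
  } else {
    if (!requireNamespace("Matrix", quietly = TRUE))
      stop("the Matrix package is required for mtx input")
    m <- Matrix::readMM(counts_path)
    stem <- sub("\\.mtx$", "", counts_path)
    rownames(m) <- readLines(paste0(stem, ".taxa.txt"))
    colnames(m) <- readLines(paste0(stem, ".samples.txt"))
    counts <- as.matrix(m)
  }
  if (!is.numeric(counts) || any(is.na(counts)))
    stop("counts must be numeric with no missing values")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  meta <- .readTsv(metadata_path)
  need <- c("sample_id", "experiment", "treatment", "dilution_factor",
            "replicate", "timepoint")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata lacks column(s): ",
                         paste(miss, collapse = ", "))
  extra <- setdiff(colnames(counts), meta$sample_id)
  if (length(extra)) stop("sample(s) in counts absent from metadata: ",
                          paste(extra, collapse = ", "))
  dd <- meta$dilution_factor[meta$treatment != "source"]
  if (any(is.na(dd)) || any(dd <= 0 | dd > 1))
    stop("dilution_factor out of (0, 1] for sample: ",
         meta$sample_id[meta$treatment != "source"][
           which(is.na(dd) | dd <= 0 | dd > 1)[1L]])
  den <- utils::read.csv(densities_path, stringsAsFactors = FALSE)
  tax <- NULL
  if (!is.null(taxonomy_path)) {
    tax <- .readTsv(taxonomy_path)
    if (!all(c("taxon_id", "order") %in% names(tax)))
      stop("taxonomy must have columns taxon_id and order")
  }
  list(dex = DilutionExperiment(counts, meta, den), taxonomy = tax)
}

#' Write a DilutionExperiment to the standard pipeline files
#'
#' Emits `counts.tsv` (taxa x samples), `metadata.tsv`, `densities.csv`,
#' and, when ground truth is attached, `truth.tsv`.
#'
#' @param dex a [DilutionExperiment-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeDataset <- function(dex, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cts <- assay(dex, "counts")
  ct <- data.frame(taxon_id = rownames(cts), cts, check.names = FALSE)
  utils::write.table(ct, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sampleData(dex), file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(densityTable(dex), file.path(dir, "densities.csv"),
                   row.names = FALSE)
  if (!is.null(truthTraits(dex)))
    utils::write.table(truthTraits(dex), file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

.writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage on one dataset: per-taxon rate estimation and
#' trait regression, trade-off tests (per experiment, mixed model when
#' several experiments are present, and the permutation null) for each
#' top-down-control cause, diversity indices with their dilution
#' regressions, composition-maintenance distances with the interaction
#' ANCOVA, resistance classification with order summaries, and a JSON run
#' manifest recording configuration, seed, package version and per-stage
#' record counts. Reruns with identical inputs and configuration are
#' byte-identical.
#'
#' @param dex a [DilutionExperiment-class].
#' @param out_dir output directory for the result tables.
#' @param config a [pipelineConfig()].
#' @param taxonomy optional taxonomy `data.frame` (`taxon_id`, `order`).
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with all result objects.
#' @export
runPipeline <- function(dex, out_dir, config = pipelineConfig(),
                        taxonomy = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  if (config$n_perm < 100L)
    warning("n_perm < 100: permutation null will be coarse")

  say("stage rates: per-taxon net growth rates and trait regressions")
  rec <- pngrRecords(dex, duration = config$duration_h,
                     replicate_mode = config$replicate_mode, quiet = quiet)
  fits <- fitAllPngr(rec, quiet = quiet)
  traits <- estimateTraits(fits, subtraction_order = config$subtraction_order)
  qc <- communityPngrQc(dex, duration = config$duration_h)
  .writeTsv(rec, file.path(out_dir, "pngr.tsv"))
  .writeTsv(fits, file.path(out_dir, "pngr_fits.tsv"))
  .writeTsv(traits, file.path(out_dir, "trait_estimates.tsv"))
  .writeTsv(qc, file.path(out_dir, "community_qc.tsv"))

  say("stage tradeoff: correlation, mixed model, permutation null")
  tradeoff <- do.call(rbind, lapply(.CAUSES, function(cz)
    tradeoffPerExperiment(traits, cz)))
  .writeTsv(tradeoff, file.path(out_dir, "tradeoff_by_experiment.tsv"))
  lmm <- do.call(rbind, lapply(.CAUSES, function(cz) {
    f <- tradeoffLmm(traits, cz)
    data.frame(cause = cz, as.data.frame(f), stringsAsFactors = FALSE)
  }))
  .writeTsv(lmm, file.path(out_dir, "tradeoff_lmm.tsv"))
  perm <- lapply(.CAUSES, function(cz)
    permutationNull(rec, cz, n_perm = config$n_perm,
                    seed = childSeed(config$seed, match(cz, .CAUSES)),
                    perm_mode = config$perm_mode))
  names(perm) <- .CAUSES
  permtab <- do.call(rbind, lapply(.CAUSES, function(cz) {
    p <- perm[[cz]]
    data.frame(cause = cz, observed_stat = p$observed_stat,
               null_mean = p$null_mean, null_sd = p$null_sd,
               shapiro_p = p$shapiro_p, z_score = p$z_score, z_p = p$z_p,
               p_empirical = p$p_empirical, n_taxa = p$n_taxa,
               statistic = p$statistic, stringsAsFactors = FALSE)
  }))
  .writeTsv(permtab, file.path(out_dir, "permutation.tsv"))
  .writeTsv(data.frame(cause = rep(.CAUSES, each = config$n_perm),
                       null_slope = unlist(lapply(perm, `[[`, "null_stats"))),
            file.path(out_dir, "permutation_null.tsv"))

  say("stage diversity: indices, dilution regressions, composition distance")
  div <- diversityTable(dex, depth = config$depth, n_norm = config$n_norm,
                        seed = childSeed(config$seed, 11L))
  .writeTsv(div, file.path(out_dir, "diversity.tsv"))
  divlmm <- do.call(rbind, lapply(c("richness", "evenness", "rad_decay"),
    function(ix) do.call(rbind, lapply(c("protists", "protists_viruses"),
      function(trt) data.frame(index = ix, treatment = trt,
        as.data.frame(diversityVsDilution(div, ix, trt)),
        stringsAsFactors = FALSE)))))
  .writeTsv(divlmm, file.path(out_dir, "diversity_lmm.tsv"))
  comp <- compositionMaintenance(dex, n_sub = config$n_sub,
                                 depth = config$depth,
                                 seed = childSeed(config$seed, 12L))
  .writeTsv(comp$distances, file.path(out_dir, "composition_distance.tsv"))
  .writeTsv(comp$fits, file.path(out_dir, "composition_fits.tsv"))
  .writeTsv(data.frame(interaction_estimate = comp$ancova$interaction_estimate,
                       interaction_se = comp$ancova$interaction_se,
                       interaction_p = comp$ancova$interaction_p,
                       n = comp$ancova$n),
            file.path(out_dir, "ancova.tsv"))

  say("stage classify: resistance categories and order summaries")
  cls <- rbind(classifyAsvs(fits, "P", alpha = config$alpha),
               classifyAsvs(fits, "PV", alpha = config$alpha))
  .writeTsv(cls, file.path(out_dir, "asv_classification.tsv"))
  if (is.null(taxonomy))
    taxonomy <- data.frame(taxon_id = character(), order = character())
  osum <- orderSummary(cls, taxonomy, significant_only = TRUE)
  .writeTsv(osum, file.path(out_dir, "order_summary.tsv"))

  manifest <- list(
    package = "killwinner",
    version = as.character(utils::packageVersion("killwinner")),
    config = unclass(config),
    n_taxa = nrow(dex), n_samples = ncol(dex),
    n_pngr_records = nrow(rec), n_fits = nrow(fits),
    n_trait_estimates = nrow(traits), n_diversity_records = nrow(div),
    n_distance_records = nrow(comp$distances),
    n_classifications = nrow(cls))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(pngr = rec, fits = fits, traits = traits, qc = qc,
                 tradeoff = tradeoff, lmm = lmm, permutation = perm,
                 diversity = div, diversity_lmm = divlmm,
                 composition = comp, classification = cls,
                 order_summary = osum, manifest = manifest))
}
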