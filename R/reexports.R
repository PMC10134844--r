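#' Re-exports from SummarizedExperiment
#'
#' Re-exported so that count matrices (`assay`) and design metadata
#' (`colData`) of a [DilutionExperiment-class] can be accessed without
#' attaching SummarizedExperiment.
#'
#' @importFrom SummarizedExperiment assay
#' @export
#' @name reexports
#' @aliases assay
#' @keywords internal
SummarizedExperiment::assay

#' @importFrom SummarizedExperiment colData
#' @export
#' @rdname reexports
#' @aliases colData
SummarizedExperiment::colData
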