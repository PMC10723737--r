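#' Container for an orthogroup-by-sample expression experiment
#'
#' \code{OrthoExperiment} extends
#' \link[SummarizedExperiment]{SummarizedExperiment}: the \code{"tpm"} assay
#' holds non-negative orthogroup-level TPM values and \code{colData} carries
#' the per-sample factors the analysis needs (\code{species}, \code{family},
#' \code{tissue}, \code{stress}, \code{bioproject}).
#'
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @export
setClass("OrthoExperiment", contains = "SummarizedExperiment")

.REQUIRED_FACTORS <- c("species", "family", "tissue", "stress", "bioproject")

setValidity("OrthoExperiment", function(object) {
  msg <- character(0)
  if (!"tpm" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'tpm' is required")
  else {
    tpm <- SummarizedExperiment::assay(object, "tpm")
    if (any(tpm < 0)) msg <- c(msg, "TPM values must be non-negative")
  }
  missing <- setdiff(.REQUIRED_FACTORS,
    colnames(SummarizedExperiment::colData(object)))
  if (length(missing))
    msg <- c(msg, paste("colData lacks required columns:",
      paste(missing, collapse = ", ")))
  if (anyDuplicated(colnames(object))) msg <- c(msg, "duplicate sample ids")
  if (anyDuplicated(rownames(object))) msg <- c(msg, "duplicate orthogroup ids")
  if (length(msg)) msg else TRUE
})

#' Construct an OrthoExperiment
#'
#' @param tpm numeric matrix of non-negative TPM values, orthogroups in rows
#'   (rownames) and samples in columns (colnames).
#' @param metadata data.frame of per-sample factors with columns
#'   \code{sample}, \code{species}, \code{family}, \code{tissue},
#'   \code{stress}, \code{bioproject} (or rownames equal to sample ids).
#' @return an \linkS4class{OrthoExperiment}.
#' @examples
#' cfg <- simulationConfig(nOrthogroups = 50, nSamples = 20, seed = 1)
#' meta <- simulateMetadata(cfg)
#' sim <- simulateExpression(cfg, meta)
#' oe <- OrthoExperiment(sim$tpm, meta)
#' oe
#' @export
OrthoExperiment <- function(tpm, metadata) {
  tpm <- as.matrix(tpm)
  if (is.null(rownames(tpm)) || is.null(colnames(tpm)))
    stop("tpm must have orthogroup rownames and sample colnames")
  if ("sample" %in% colnames(metadata)) {
    rownames(metadata) <- metadata$sample
  }
  missing <- setdiff(colnames(tpm), rownames(metadata))
  if (length(missing))
    stop("metadata lacks samples: ", paste(head(missing), collapse = ", "))
  metadata <- metadata[colnames(tpm), , drop = FALSE]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(tpm = tpm),
    colData = S4Vectors::DataFrame(metadata)
  )
  methods::new("OrthoExperiment", se)
}

#' Extract the TPM assay of an OrthoExperiment
#'
#' @param x an \linkS4class{OrthoExperiment}.
#' @return the non-negative TPM matrix.
#' @export
tpmAssay <- function(x) SummarizedExperiment::assay(x, "tpm")

#' Extract per-sample factors as a plain data.frame
#'
#' @param x an \linkS4class{OrthoExperiment}.
#' @return data.frame with a \code{sample} column plus the factor columns.
#' @export
sampleFactors <- function(x) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  data.frame(sample = colnames(x), cd, row.names = NULL,
    check.names = FALSE)
}

#' Log2-transform a TPM matrix
#'
#' @param tpm non-negative TPM matrix.
#' @return \code{log2(tpm + 1)}.
#' @export
log2Tpm <- function(tpm) log2(tpm + 1)
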