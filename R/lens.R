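#' Select the reference samples for a lens
#'
#' The stress lens is anchored on healthy samples; the tissue lens on
#' photosynthetic (leaf) samples.
#'
#' @param meta sample metadata with \code{sample}, \code{tissue} and
#'   \code{stress} columns.
#' @param lensKind \code{"tissue"} or \code{"stress"}.
#' @param healthyLabel stress level denoting unstressed samples.
#' @param leafLabel tissue level denoting photosynthetic samples.
#' @return character vector of reference sample ids.
#' @export
selectReference <- function(meta, lensKind = c("tissue", "stress"),
    healthyLabel = "healthy", leafLabel = "leaf") {
  lensKind <- match.arg(lensKind)
  req <- c("sample", "tissue", "stress")
  if (!all(req %in% colnames(meta)))
    stop("metadata lacks columns: ",
      paste(setdiff(req, colnames(meta)), collapse = ", "))
  ids <- if (lensKind == "stress") meta$sample[meta$stress == healthyLabel]
    else meta$sample[meta$tissue == leafLabel]
  if (!length(ids))
    stop("empty reference set for the ", lensKind, " lens")
  ids
}

.applyTransform <- function(tpm, transform, center = NULL, scale = NULL) {
  x <- log2Tpm(tpm)
  if (transform == "zscore") {
    x <- (x - center) / scale
  }
  x
}

#' Fit the reference linear model behind a lens function
#'
#' Fits an affine subspace to the reference samples on transformed
#' expression (default \code{log2(TPM+1)}): the mean reference profile plus
#' the leading left singular vectors of the mean-centered reference matrix.
#' The subspace models the idealized reference (healthy or leaf) expression
#' state; lens values are the residual norms from it.
#'
#' The retained rank is either the smallest r whose cumulative explained
#' variance reaches \code{tau} (\code{rankRule = "ev"}, default
#' \code{tau = 0.95}) or a fixed \code{r}; numerically zero singular values
#' are always dropped, so identical reference columns give rank 0.
#'
#' @param tpm orthogroup x sample non-negative TPM matrix (or an
#'   \linkS4class{OrthoExperiment}).
#' @param refIds reference sample ids (>= 2, all present as columns).
#' @param rankRule \code{"ev"} (explained variance) or \code{"fixed"}.
#' @param tau cumulative explained-variance threshold for \code{"ev"}.
#' @param r rank for \code{rankRule = "fixed"} (capped at the available rank).
#' @param transform \code{"log2"} (log2(TPM+1)) or \code{"zscore"}
#'   (per-orthogroup z-score of log2(TPM+1), parameters estimated on the
#'   reference samples).
#' @return a \linkS4class{LensModel}.
#' @examples
#' tpm <- matrix(2^rbind(c(0, 1, 2), c(0, 1, 2)) - 1, 2,
#'   dimnames = list(c("og1", "og2"), c("s1", "s2", "s3")))
#' fitLensModel(tpm, c("s1", "s2", "s3"))
#' @export
fitLensModel <- function(tpm, refIds, rankRule = c("ev", "fixed"),
    tau = 0.95, r = NULL, transform = c("log2", "zscore")) {
  rankRule <- match.arg(rankRule)
  transform <- match.arg(transform)
  if (methods::is(tpm, "OrthoExperiment")) tpm <- tpmAssay(tpm)
  refIds <- as.character(refIds)
  if (length(refIds) < 2) stop("at least 2 reference samples are required")
  missing <- setdiff(refIds, colnames(tpm))
  if (length(missing))
    stop("reference sample(s) not in the matrix: ",
      paste(head(missing), collapse = ", "))
  center <- numeric(0); scale <- numeric(0)
  if (transform == "zscore") {
    refLog <- log2Tpm(tpm[, refIds, drop = FALSE])
    center <- rowMeans(refLog)
    scale <- apply(refLog, 1, sd)
    scale[scale < 1e-12] <- 1
  }
  x <- .applyTransform(tpm[, refIds, drop = FALSE], transform, center, scale)
  mu <- rowMeans(x)
  xc <- x - mu
  sv <- svd(xc)
  tol <- max(dim(xc)) * max(sv$d, 0) * .Machine$double.eps
  pos <- which(sv$d > max(tol, 1e-12))
  if (!length(pos)) {
    basis <- matrix(0, nrow(x), 0)
    rank <- 0L
  } else {
    d2 <- sv$d[pos]^2
    if (rankRule == "ev") {
      rank <- which(cumsum(d2) / sum(d2) >= tau)[1]
    } else {
      if (is.null(r)) stop("rankRule 'fixed' requires r")
      rank <- min(as.integer(r), length(pos))
    }
    basis <- sv$u[, seq_len(rank), drop = FALSE]
  }
  rownames(basis) <- rownames(tpm)
  methods::new("LensModel", mu = mu, basis = basis, rank = as.integer(rank),
    transform = transform, center = center, scale = scale, refIds = refIds)
}

#' Residual-norm lens values
#'
#' For each sample x (transformed as the model was), the lens value is the
#' length of the residual after projecting the centered sample onto the
#' model's subspace:
#' \deqn{f(x) = \lVert (x - \mu) - B B^{\top} (x - \mu) \rVert_2}
#' Samples spanned by the model (in particular the reference samples under
#' a full-rank fit) score ~0; samples deviating from the reference state
#' score high.
#'
#' @param tpm orthogroup x sample non-negative TPM matrix (or an
#'   \linkS4class{OrthoExperiment}); rows must match the model dimension.
#' @param model a \linkS4class{LensModel}.
#' @return named numeric vector of lens values (>= 0), one per sample.
#' @export
residualLens <- function(tpm, model) {
  if (methods::is(tpm, "OrthoExperiment")) tpm <- tpmAssay(tpm)
  if (nrow(tpm) != length(model@mu))
    stop("matrix rows (", nrow(tpm), ") do not match the model dimension (",
      length(model@mu), ")")
  x <- .applyTransform(tpm, model@transform, model@center, model@scale)
  xc <- x - model@mu
  resid <- if (model@rank > 0)
    xc - model@basis %*% crossprod(model@basis, xc) else xc
  setNames(sqrt(colSums(resid^2)), colnames(tpm))
}
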