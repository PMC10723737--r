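#' @import methods
#' @importFrom stats cor dbinom quantile rnorm runif sd setNames p.adjust
#' @importFrom utils read.delim write.table head
NULL

#' Simulation configuration for synthetic orthogroup expression data
#'
#' Holds the study-design parameters of the synthetic generator: factor
#' level counts (families, tissues, stresses, species per family), matrix
#' dimensions, planted effect sizes (log2 fold-change units) and nuisance
#' standard deviations (log2 scale).
#'
#' @slot nFamilies number of plant families.
#' @slot nTissues number of tissue levels; the first is the photosynthetic
#'   reference tissue ("leaf").
#' @slot nStresses number of stress levels; the first is "healthy".
#' @slot nSpeciesPerFamily species simulated per family.
#' @slot nOrthogroups number of orthogroups (matrix rows).
#' @slot nSamples number of samples (matrix columns).
#' @slot fracTissueGenes fraction of orthogroups with a planted tissue
#'   (photosynthesis-analog) effect.
#' @slot fracStressGenes fraction of orthogroups with a planted stress effect.
#' @slot tissueEffect log2 fold-change magnitude of the tissue effect
#'   (tissue genes drop by this amount outside leaf tissue).
#' @slot stressEffect log2 fold-change per unit stress severity.
#' @slot familySd,batchSd,noiseSd standard deviations (log2 scale) of the
#'   family offset, bioproject batch offset, and iid noise.
#' @slot comboSkew Zipf exponent of the factor-combination sampling weights;
#'   larger values give a more skewed combination distribution.
#' @slot healthyWeight multiplicative upweight of healthy-stress
#'   combinations, reflecting the dominance of control samples in public
#'   repositories.
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationConfig",
  representation(
    nFamilies = "integer", nTissues = "integer", nStresses = "integer",
    nSpeciesPerFamily = "integer", nOrthogroups = "integer",
    nSamples = "integer", fracTissueGenes = "numeric",
    fracStressGenes = "numeric", tissueEffect = "numeric",
    stressEffect = "numeric", familySd = "numeric", batchSd = "numeric",
    noiseSd = "numeric", comboSkew = "numeric", healthyWeight = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  counts <- c(
    nFamilies = object@nFamilies, nTissues = object@nTissues,
    nStresses = object@nStresses,
    nSpeciesPerFamily = object@nSpeciesPerFamily,
    nOrthogroups = object@nOrthogroups
  )
  if (any(counts < 1L)) {
    msg <- c(msg, paste("counts must be >= 1:",
      paste(names(counts)[counts < 1L], collapse = ", ")))
  }
  if (object@nSamples < 0L) msg <- c(msg, "nSamples must be >= 0")
  fr <- c(object@fracTissueGenes, object@fracStressGenes)
  if (any(fr < 0) || any(fr > 1)) msg <- c(msg, "fractions must lie in [0, 1]")
  sds <- c(object@familySd, object@batchSd, object@noiseSd)
  if (any(sds < 0)) msg <- c(msg, "standard deviations must be >= 0")
  if (object@comboSkew < 0) msg <- c(msg, "comboSkew must be >= 0")
  if (object@healthyWeight <= 0) msg <- c(msg, "healthyWeight must be > 0")
  if (length(msg)) msg else TRUE
})

#' Orthogroup membership table
#'
#' Maps each orthogroup to, per species, the genes it contains — the parsed
#' form of an OrthoFinder \code{Orthogroups.tsv} file. Species with no genes
#' in an orthogroup hold an empty character vector.
#'
#' @slot groups named list: orthogroup id -> named list (species -> character
#'   vector of gene ids).
#' @slot species character vector: the full species roster (may include
#'   species absent from every orthogroup entry).
#' @export
setClass("OrthogroupTable",
  representation(groups = "list", species = "character")
)

setValidity("OrthogroupTable", function(object) {
  msg <- character(0)
  if (anyDuplicated(names(object@groups)))
    msg <- c(msg, "duplicate orthogroup ids")
  if (anyDuplicated(object@species)) msg <- c(msg, "duplicate species ids")
  for (og in names(object@groups)) {
    entry <- object@groups[[og]]
    bad <- setdiff(names(entry), object@species)
    if (length(bad)) {
      msg <- c(msg, paste0("orthogroup ", og, " lists species not in roster: ",
        paste(bad, collapse = ", ")))
      break
    }
    dup <- vapply(entry, anyDuplicated, 0L)
    if (any(dup > 0L)) {
      msg <- c(msg, paste0("duplicate gene ids within a species in ", og))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Lens model: affine subspace fit to reference samples
#'
#' The idealized reference expression state: a mean vector plus an
#' orthonormal basis of the leading variation among reference samples,
#' fit on transformed expression (log2(TPM+1) by default). The lens value
#' of a sample is the Euclidean norm of its residual after projection
#' onto this affine subspace.
#'
#' @slot mu numeric mean vector, one entry per orthogroup (transformed units).
#' @slot basis orthonormal matrix (orthogroups x rank) of leading left
#'   singular vectors of the centered reference matrix.
#' @slot rank integer, number of basis columns retained.
#' @slot transform character, the expression transform used ("log2" or
#'   "zscore").
#' @slot center,scale numeric vectors used by the "zscore" transform
#'   (length zero for "log2").
#' @slot refIds character, the reference sample ids the model was fit on.
#' @export
setClass("LensModel",
  representation(
    mu = "numeric", basis = "matrix", rank = "integer",
    transform = "character", center = "numeric", scale = "numeric",
    refIds = "character"
  )
)

setValidity("LensModel", function(object) {
  msg <- character(0)
  r <- object@rank
  if (ncol(object@basis) != r) msg <- c(msg, "rank must equal ncol(basis)")
  if (r > 0) {
    if (nrow(object@basis) != length(object@mu))
      msg <- c(msg, "basis rows must match length(mu)")
    gram <- crossprod(object@basis)
    if (max(abs(gram - diag(r))) > 1e-8)
      msg <- c(msg, "basis is not orthonormal (B'B != I within 1e-8)")
  }
  if (!object@transform %in% c("log2", "zscore"))
    msg <- c(msg, "transform must be 'log2' or 'zscore'")
  if (length(msg)) msg else TRUE
})

#' Interval cover of a lens range
#'
#' Uniform-length overlapping intervals covering [fmin, fmax]. Consecutive
#' intervals overlap by the fraction \code{overlap} of the common interval
#' length.
#'
#' @slot intervals numeric matrix with columns \code{lo}, \code{hi}; one row
#'   per interval in increasing order.
#' @slot overlap overlap fraction g in [0, 1).
#' @export
setClass("Cover",
  representation(intervals = "matrix", overlap = "numeric")
)

setValidity("Cover", function(object) {
  iv <- object@intervals
  msg <- character(0)
  if (!identical(colnames(iv), c("lo", "hi")))
    msg <- c(msg, "intervals must have columns lo, hi")
  else if (any(iv[, "hi"] < iv[, "lo"]))
    msg <- c(msg, "each interval must satisfy hi >= lo")
  g <- object@overlap
  if (g < 0 || g >= 1) msg <- c(msg, "overlap must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Mapper graph: one-dimensional nerve of the clustered cover
#'
#' Each node is a cluster of samples from one cover interval's preimage;
#' an edge joins two nodes exactly when they share samples, weighted by the
#' shared-sample count.
#'
#' @slot nodes data.frame with columns \code{node} (integer id),
#'   \code{interval} (0-based cover interval index), \code{size}
#'   (member count) and \code{meanLens} (mean lens value of members).
#' @slot members list of character vectors (member sample ids), parallel to
#'   \code{nodes}, named by node id.
#' @slot edges data.frame with columns \code{from}, \code{to} (node ids,
#'   from < to) and \code{weight} (shared-sample count, >= 1).
#' @slot noise character vector of samples assigned to no cluster in at
#'   least one preimage (DBSCAN noise), for reporting.
#' @export
setClass("MapperGraph",
  representation(
    nodes = "data.frame", members = "list", edges = "data.frame",
    noise = "character"
  )
)

setValidity("MapperGraph", function(object) {
  msg <- character(0)
  nd <- object@nodes
  if (!all(c("node", "interval", "size", "meanLens") %in% names(nd)))
    msg <- c(msg, "nodes must have columns node, interval, size, meanLens")
  if (length(object@members) != nrow(nd))
    msg <- c(msg, "members list must parallel nodes")
  if (any(lengths(object@members) == 0L))
    msg <- c(msg, "every node must have at least one member")
  ed <- object@edges
  if (nrow(ed)) {
    if (!all(c("from", "to", "weight") %in% names(ed)))
      msg <- c(msg, "edges must have columns from, to, weight")
    else {
      if (any(ed$from == ed$to)) msg <- c(msg, "self-edges are not allowed")
      if (any(ed$weight < 1)) msg <- c(msg, "edge weights must be >= 1")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:",
    object@nOrthogroups, "orthogroups x", object@nSamples, "samples\n")
  cat("  factors:", object@nFamilies, "families x", object@nTissues,
    "tissues x", object@nStresses, "stresses;",
    object@nSpeciesPerFamily, "species/family\n")
  cat("  effects: tissue", object@tissueEffect, "| stress",
    object@stressEffect, "(log2); sd family/batch/noise:",
    object@familySd, object@batchSd, object@noiseSd, "\n")
  cat("  seed:", object@seed, "\n")
})

setMethod("show", "OrthogroupTable", function(object) {
  cat("OrthogroupTable:", length(object@groups), "orthogroups,",
    length(object@species), "species\n")
})

setMethod("show", "LensModel", function(object) {
  cat("LensModel: dimension", length(object@mu), ", rank", object@rank,
    ", transform", object@transform, "\n")
  cat("  fit on", length(object@refIds), "reference samples\n")
})

setMethod("show", "Cover", function(object) {
  n <- nrow(object@intervals)
  cat("Cover:", n, "uniform intervals, overlap g =", object@overlap, "\n")
  if (n) cat("  range: [", object@intervals[1, "lo"], ",",
    object@intervals[n, "hi"], "]\n")
})

setMethod("show", "MapperGraph", function(object) {
  cat("MapperGraph:", nrow(object@nodes), "nodes,", nrow(object@edges),
    "edges,", length(unique(unlist(object@members))), "samples covered")
  if (length(object@noise)) cat(",", length(object@noise), "noise samples")
  cat("\n")
})
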