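#' Correlate each orthogroup's expression with a lens
#'
#' Pearson (or Spearman) correlation between each orthogroup's
#' \code{log2(TPM+1)} profile and the lens values, over the samples shared
#' by both. Zero-variance rows are assigned r = 0 and flagged as
#' degenerate; flagged rows never enter the extreme tails.
#'
#' @param tpm orthogroup x sample TPM matrix (or
#'   \linkS4class{OrthoExperiment}).
#' @param f named lens values.
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return data.frame with columns \code{orthogroup}, \code{r},
#'   \code{degenerate}.
#' @export
lensCorrelation <- function(tpm, f, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (methods::is(tpm, "OrthoExperiment")) tpm <- tpmAssay(tpm)
  shared <- intersect(colnames(tpm), names(f))
  if (length(shared) < 3)
    stop("need at least 3 shared samples, got ", length(shared))
  x <- log2Tpm(tpm[, shared, drop = FALSE])
  fv <- f[shared]
  sds <- apply(x, 1, sd)
  degenerate <- sds < 1e-12 | sd(fv) < 1e-12
  r <- rep(0, nrow(x))
  ok <- !degenerate
  if (any(ok))
    r[ok] <- as.vector(cor(t(x[ok, , drop = FALSE]), fv, method = method))
  data.frame(orthogroup = rownames(x), r = r, degenerate = degenerate,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Select the extreme tails of a correlation table
#'
#' The positive set holds the top \code{floor(tailFrac * N)} orthogroups by
#' r descending and the negative set the bottom \code{floor(tailFrac * N)}
#' ascending, with ties broken by orthogroup id; degenerate rows are
#' ranked last in both directions and so never enter a tail unless the
#' non-degenerate rows run out (in which case an error is raised).
#'
#' @param tbl output of \code{\link{lensCorrelation}}.
#' @param tailFrac tail fraction in (0, 0.5), default 0.025.
#' @return list with \code{positive} and \code{negative} character vectors
#'   of orthogroup ids, each of length \code{floor(tailFrac * N)}.
#' @export
selectExtremes <- function(tbl, tailFrac = 0.025) {
  if (tailFrac <= 0 || tailFrac >= 0.5)
    stop("tailFrac must lie in (0, 0.5)")
  N <- nrow(tbl)
  m <- floor(tailFrac * N)
  if (m == 0) stop("tail size floor(tailFrac * N) is 0")
  ok <- tbl[!tbl$degenerate, , drop = FALSE]
  if (nrow(ok) < m)
    stop("fewer than ", m, " non-degenerate orthogroups available")
  pos <- ok$orthogroup[order(-ok$r, ok$orthogroup)][seq_len(m)]
  neg <- ok$orthogroup[order(ok$r, ok$orthogroup)][seq_len(m)]
  list(positive = pos, negative = neg)
}

#' One-sided exact binomial gene-set enrichment
#'
#' Tests whether the selection overlaps a reference set more (or less)
#' than expected under Binomial(n, p0), where p0 is the reference set's
#' share of the universe. The p-value is computed by exact summation of
#' the binomial pmf.
#'
#' @param selection character vector of selected ids (subset of universe).
#' @param reference character vector of reference-set ids.
#' @param universe character vector of all ids under consideration.
#' @param direction \code{"greater"} (P(X >= k)) or \code{"less"}
#'   (P(X <= k)).
#' @param setName label carried into the result.
#' @return data.frame with columns set, k (overlap), n (selection size),
#'   p0 (background proportion), pValue, direction.
#' @export
binomialEnrichment <- function(selection, reference, universe,
    direction = c("greater", "less"), setName = "reference") {
  direction <- match.arg(direction)
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  selection <- unique(selection)
  if (length(setdiff(selection, universe)))
    stop("selection must be a subset of the universe")
  refInU <- intersect(unique(reference), universe)
  p0 <- length(refInU) / length(universe)
  k <- length(intersect(selection, refInU))
  n <- length(selection)
  pValue <- if (direction == "greater")
    sum(dbinom(k:n, n, p0)) else sum(dbinom(0:k, n, p0))
  pValue <- min(1, pValue)
  data.frame(set = setName, k = k, n = n, p0 = p0, pValue = pValue,
    direction = direction, stringsAsFactors = FALSE)
}

#' Flat-set hypergeometric enrichment with BH correction
#'
#' Upper-tail hypergeometric (Fisher one-sided) enrichment of the selection
#' in each flat term set, p-values by exact summation of the
#' hypergeometric pmf, with Benjamini-Hochberg q-values across terms.
#' Term relationships (e.g., an ontology DAG) are not used.
#'
#' @param selection character vector of selected ids (subset of universe).
#' @param termSets named list of character vectors (term -> member ids),
#'   e.g., from \code{\link{readGmt}}.
#' @param universe character vector of all ids.
#' @return data.frame with columns term, k, K (term size in universe),
#'   n, p0, pValue, qValue, ordered by pValue; empty for an empty term
#'   list.
#' @export
flatSetEnrichment <- function(selection, termSets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  selection <- unique(selection)
  if (length(setdiff(selection, universe)))
    stop("selection must be a subset of the universe")
  if (!length(termSets))
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
      n = integer(0), p0 = numeric(0), pValue = numeric(0),
      qValue = numeric(0)))
  N <- length(universe)
  n <- length(selection)
  rows <- lapply(names(termSets), function(term) {
    termInU <- intersect(unique(termSets[[term]]), universe)
    K <- length(termInU)
    k <- length(intersect(selection, termInU))
    # P(X >= k), X ~ Hypergeom(N, K, n), by exact pmf summation
    upper <- min(K, n)
    pValue <- if (k > upper) 0 else
      sum(exp(lchoose(K, k:upper) + lchoose(N - K, n - (k:upper)) -
        lchoose(N, n)))
    data.frame(term = term, k = k, K = K, n = n, p0 = K / N,
      pValue = min(1, pValue), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$qValue <- p.adjust(out$pValue, method = "BH")
  out[order(out$pValue, out$term), , drop = FALSE]
}

#' Adjusted R-squared
#'
#' The sample-size/parameter-count adjustment
#' \deqn{\bar{R}^2 = 1 - (1 - R^2) \frac{n - 1}{n - p - 1}}
#' used to summarize how much variance in a surrogate variable each
#' experimental factor explains; may be negative for weak fits.
#'
#' @param r2 unadjusted R-squared in [0, 1].
#' @param n number of observations (must exceed p + 1).
#' @param p number of model parameters excluding the intercept.
#' @return the adjusted R-squared.
#' @export
adjustedR2 <- function(r2, n, p) {
  if (any(r2 < 0 | r2 > 1)) stop("r2 must lie in [0, 1]")
  if (any(n <= p + 1)) stop("n must exceed p + 1")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Read gene sets from a GMT file
#'
#' Tab-separated: set name, description, then member ids.
#'
#' @param path GMT file path.
#' @return named list of character vectors of member ids.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t")[[1]]
    if (length(parts) < 2) stop("malformed GMT line: ", l)
    unique(parts[-(1:2)])
  })
  names(out) <- vapply(lines, function(l) strsplit(l, "\t")[[1]][1],
    character(1))
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of set descriptions.
#' @return invisibly, \code{path}.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
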