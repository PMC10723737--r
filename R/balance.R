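#' Tally (family, tissue, stress) factor combinations
#'
#' Counts samples per observed 3-way combination and reports, as the
#' \code{"nPossible"} attribute, how many combinations the observed factor
#' levels could form (n families x n tissues x n stresses).
#'
#' @param meta metadata with \code{family}, \code{tissue}, \code{stress}
#'   columns.
#' @return data.frame with columns family, tissue, stress, count, sorted by
#'   decreasing count (ties by lexicographic triple); attribute
#'   \code{"nPossible"} holds the possible-combination count.
#' @export
comboCounts <- function(meta) {
  req <- c("family", "tissue", "stress")
  missing <- setdiff(req, colnames(meta))
  if (length(missing))
    stop("metadata lacks factor column(s): ", paste(missing, collapse = ", "))
  if (!nrow(meta)) {
    out <- data.frame(family = character(0), tissue = character(0),
      stress = character(0), count = integer(0))
    attr(out, "nPossible") <- 0L
    return(out)
  }
  agg <- stats::aggregate(list(count = rep(1L, nrow(meta))),
    by = meta[req], FUN = sum)
  agg <- agg[order(-agg$count, agg$family, agg$tissue, agg$stress), ,
    drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "nPossible") <- length(unique(meta$family)) *
    length(unique(meta$tissue)) * length(unique(meta$stress))
  agg
}

#' Downsample the most common factor combinations
#'
#' The \code{topK} most common (family, tissue, stress) combinations (ties
#' broken by lexicographic triple) are each subsampled without replacement
#' to at most \code{cap} samples, using the given seed; all samples outside
#' those combinations are retained untouched. Used to test whether the
#' Mapper topology is driven by sampling bias.
#'
#' @param meta sample metadata.
#' @param topK number of most-common combinations to downsample.
#' @param cap per-combination sample cap.
#' @param seed integer RNG seed (sampling is reproducible).
#' @return the downsampled metadata (original row order preserved).
#' @export
downsampleTopCombos <- function(meta, topK = 30, cap = 30, seed = 1) {
  if (topK < 1) stop("topK must be >= 1")
  if (cap < 1) stop("cap must be >= 1")
  if (!nrow(meta)) return(meta)
  counts <- comboCounts(meta)
  top <- head(counts, topK)
  key <- paste(meta$family, meta$tissue, meta$stress, sep = "|")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  drop <- logical(nrow(meta))
  for (i in seq_len(nrow(top))) {
    k <- paste(top$family[i], top$tissue[i], top$stress[i], sep = "|")
    idx <- which(key == k)
    if (length(idx) > cap) {
      keep <- sample(idx, cap)
      drop[setdiff(idx, keep)] <- TRUE
    }
  }
  meta[!drop, , drop = FALSE]
}
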