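#' Uniform-overlap interval cover of a lens range
#'
#' Splits [fmin, fmax] into n intervals of common length
#' \eqn{L = (fmax - fmin) / (n - (n-1) g)}, interval j (0-based) being
#' \eqn{[fmin + j (1-g) L,\; fmin + j (1-g) L + L]}; consecutive intervals
#' overlap by exactly \eqn{gL} and the last interval ends at fmax.
#'
#' @param fmin,fmax range of the lens values (fmax >= fmin).
#' @param n number of intervals (>= 1).
#' @param g overlap fraction in [0, 1).
#' @return a \linkS4class{Cover}.
#' @examples
#' coverIntervals(buildCover(0, 10, n = 4, g = 0.5))
#' @export
buildCover <- function(fmin, fmax, n, g) {
  if (fmax < fmin) stop("fmax must be >= fmin")
  if (n < 1) stop("n must be >= 1")
  if (g < 0 || g >= 1) stop("overlap g must lie in [0, 1)")
  L <- (fmax - fmin) / (n - (n - 1) * g)
  lo <- fmin + (seq_len(n) - 1) * (1 - g) * L
  iv <- cbind(lo = lo, hi = lo + L)
  methods::new("Cover", intervals = iv, overlap = g)
}

.pairwiseDistance <- function(x, metric) {
  # columns of x are observations
  if (metric == "euclidean") {
    as.matrix(stats::dist(t(x)))
  } else {
    # correlation distance 1 - Pearson r; constant columns are maximally
    # distant (r undefined -> distance 1)
    suppressWarnings(r <- cor(x))
    r[is.na(r)] <- 0
    d <- 1 - r
    diag(d) <- 0
    d[d < 0] <- 0
    d
  }
}

#' DBSCAN clustering from a distance matrix
#'
#' Density-based clustering: a point is a core point when its closed
#' eps-neighborhood (itself included) holds at least \code{minPts} points;
#' clusters are the connected components of core points under
#' eps-adjacency, together with their border points (non-core points within
#' eps of a core point, attached to the cluster of their first core
#' neighbor in index order). Remaining points are noise.
#'
#' @param d symmetric distance matrix.
#' @param eps neighborhood radius (> 0).
#' @param minPts minimum neighborhood size for a core point (>= 1).
#' @return integer vector of cluster labels (1, 2, ...), 0 for noise.
#' @export
dbscanLabels <- function(d, eps, minPts) {
  if (eps <= 0) stop("eps must be > 0")
  if (minPts < 1) stop("minPts must be >= 1")
  n <- nrow(d)
  if (n == 0L) return(integer(0))
  adj <- d <= eps
  core <- rowSums(adj) >= minPts
  labels <- integer(n)
  if (any(core)) {
    coreIdx <- which(core)
    coreAdj <- adj[coreIdx, coreIdx, drop = FALSE]
    gr <- igraph::graph_from_adjacency_matrix(coreAdj, mode = "undirected",
      diag = FALSE)
    comp <- igraph::components(gr)$membership
    labels[coreIdx] <- as.integer(comp)
    border <- which(!core)
    for (i in border) {
      nb <- coreIdx[adj[i, coreIdx]]
      if (length(nb)) labels[i] <- labels[nb[1]]
    }
  }
  # renumber clusters by first appearance for determinism
  seen <- unique(labels[labels > 0L])
  if (length(seen)) labels[labels > 0L] <- match(labels[labels > 0L], seen)
  labels
}

#' Cluster the preimage of one cover interval
#'
#' Samples whose lens value falls in the closed interval [lo, hi] are
#' clustered with DBSCAN on their expression columns under the chosen
#' metric.
#'
#' @param x transformed expression matrix (columns = samples) used for
#'   distances.
#' @param f named lens values (one per column of \code{x}).
#' @param interval numeric (lo, hi).
#' @param eps,minPts DBSCAN parameters.
#' @param metric \code{"correlation"} (1 - Pearson r) or \code{"euclidean"}.
#' @return list with \code{clusters} (list of character vectors of sample
#'   ids) and \code{noise} (character vector); both empty for an empty
#'   preimage.
#' @export
preimageClusters <- function(x, f, interval, eps, minPts,
    metric = c("correlation", "euclidean")) {
  metric <- match.arg(metric)
  ids <- names(f)[f >= interval[1] & f <= interval[2]]
  if (!length(ids)) return(list(clusters = list(), noise = character(0)))
  d <- .pairwiseDistance(x[, ids, drop = FALSE], metric)
  labels <- dbscanLabels(d, eps, minPts)
  clusters <- lapply(seq_len(max(labels, 0L)), function(k) ids[labels == k])
  list(clusters = clusters, noise = ids[labels == 0L])
}

#' One-dimensional nerve of the clustered cover
#'
#' One node per cluster; two nodes are joined by an edge exactly when
#' their member sets intersect, weighted by the shared-sample count.
#'
#' @param clustersByInterval list (one element per cover interval) of lists
#'   of character vectors of sample ids.
#' @param f optional named lens values used to record each node's mean lens.
#' @param noise character vector of noise samples (reporting only).
#' @return a \linkS4class{MapperGraph}.
#' @export
mapperNerve <- function(clustersByInterval, f = NULL,
    noise = character(0)) {
  members <- list(); interval <- integer(0)
  for (j in seq_along(clustersByInterval)) {
    for (cl in clustersByInterval[[j]]) {
      members[[length(members) + 1L]] <- cl
      interval <- c(interval, j - 1L)
    }
  }
  nNode <- length(members)
  names(members) <- as.character(seq_len(nNode))
  meanLens <- vapply(members, function(m)
    if (is.null(f)) NA_real_ else mean(f[m]), numeric(1))
  nodes <- data.frame(node = seq_len(nNode), interval = interval,
    size = lengths(members), meanLens = unname(meanLens))
  edges <- .edgesFromMembers(members)
  methods::new("MapperGraph", nodes = nodes, members = members,
    edges = edges, noise = unique(noise))
}

.edgesFromMembers <- function(members) {
  nNode <- length(members)
  from <- integer(0); to <- integer(0); weight <- integer(0)
  if (nNode >= 2) {
    ids <- as.integer(names(members))
    for (a in seq_len(nNode - 1)) {
      for (b in (a + 1):nNode) {
        w <- length(intersect(members[[a]], members[[b]]))
        if (w > 0) {
          from <- c(from, ids[a]); to <- c(to, ids[b])
          weight <- c(weight, w)
        }
      }
    }
  }
  data.frame(from = from, to = to, weight = weight)
}

#' Build a Mapper graph from an expression matrix and lens values
#'
#' Composes \code{\link{buildCover}} over the lens range,
#' \code{\link{preimageClusters}} per interval, and
#' \code{\link{mapperNerve}}. Fully deterministic.
#'
#' @param tpm orthogroup x sample TPM matrix (or an
#'   \linkS4class{OrthoExperiment}); distances use \code{log2(TPM+1)}.
#' @param f named lens values, one per sample.
#' @param n number of cover intervals.
#' @param g overlap fraction in [0, 1).
#' @param eps,minPts DBSCAN parameters.
#' @param metric \code{"correlation"} or \code{"euclidean"}.
#' @return a \linkS4class{MapperGraph}.
#' @export
mapperPipeline <- function(tpm, f, n, g, eps, minPts,
    metric = c("correlation", "euclidean")) {
  metric <- match.arg(metric)
  if (methods::is(tpm, "OrthoExperiment")) tpm <- tpmAssay(tpm)
  if (is.null(names(f)) || !all(names(f) %in% colnames(tpm)))
    stop("lens values must be named by samples present in the matrix")
  x <- log2Tpm(tpm[, names(f), drop = FALSE])
  mapperFromPoints(x, f, n, g, eps, minPts, metric)
}

#' Build a Mapper graph from an arbitrary point cloud
#'
#' Same construction as \code{\link{mapperPipeline}} but on columns of
#' \code{x} as-is (no expression transform) — for worked examples and
#' pre-transformed data.
#'
#' @param x feature x point matrix (columns are points, named).
#' @inheritParams mapperPipeline
#' @return a \linkS4class{MapperGraph}.
#' @export
mapperFromPoints <- function(x, f, n, g, eps, minPts,
    metric = c("euclidean", "correlation")) {
  metric <- match.arg(metric)
  if (is.null(names(f)) || !all(names(f) %in% colnames(x)))
    stop("lens values must be named by points present in the matrix")
  x <- x[, names(f), drop = FALSE]
  cover <- buildCover(min(f), max(f), n, g)
  iv <- coverIntervals(cover)
  res <- lapply(seq_len(nrow(iv)), function(j)
    preimageClusters(x, f, iv[j, ], eps, minPts, metric))
  clusters <- lapply(res, `[[`, "clusters")
  noise <- unique(unlist(lapply(res, `[[`, "noise")))
  if (is.null(noise)) noise <- character(0)
  # a sample clustered in any interval is not noise overall
  noise <- setdiff(noise, unlist(lapply(clusters, unlist)))
  mapperNerve(clusters, f = f, noise = noise)
}

#' Convert a MapperGraph to an igraph object
#'
#' Node attributes: \code{interval}, \code{size}, \code{mean_lens};
#' edge attribute: \code{weight}.
#'
#' @param G a \linkS4class{MapperGraph}.
#' @return an \link[igraph]{igraph} graph.
#' @export
mapperToIgraph <- function(G) {
  nd <- G@nodes
  vertices <- data.frame(name = as.character(nd$node),
    interval = nd$interval, size = nd$size, mean_lens = nd$meanLens)
  ed <- G@edges
  if (nrow(ed)) {
    edges <- data.frame(from = as.character(ed$from),
      to = as.character(ed$to), weight = ed$weight)
  } else {
    edges <- data.frame(from = character(0), to = character(0),
      weight = numeric(0))
  }
  igraph::graph_from_data_frame(edges, directed = FALSE,
    vertices = vertices)
}

#' Write a MapperGraph as GraphML plus a node-membership table
#'
#' @param G a \linkS4class{MapperGraph}.
#' @param graphmlPath output GraphML path.
#' @param membershipPath optional TSV path for (node, sample) memberships.
#' @return invisibly, the paths written.
#' @export
writeMapperGraph <- function(G, graphmlPath, membershipPath = NULL) {
  igraph::write_graph(mapperToIgraph(G), graphmlPath, format = "graphml")
  if (!is.null(membershipPath)) {
    mem <- data.frame(
      node = rep(as.integer(names(G@members)), lengths(G@members)),
      sample = unlist(G@members, use.names = FALSE))
    write.table(mem, membershipPath, sep = "\t", row.names = FALSE,
      quote = FALSE)
  }
  invisible(c(graphml = graphmlPath, membership = membershipPath))
}

#' Sweep cover hyperparameters and summarize graph stability
#'
#' Runs \code{\link{mapperPipeline}} over the grid of interval counts and
#' overlaps (duplicate grid points removed) and reports graph-shape
#' summaries used to pick a stable construction.
#'
#' @param tpm TPM matrix or \linkS4class{OrthoExperiment}.
#' @param f named lens values.
#' @param nList integer vector of interval counts.
#' @param gList numeric vector of overlaps.
#' @param eps,minPts,metric fixed clustering parameters.
#' @return data.frame with columns n, g, nodes, edges, components,
#'   giantFrac (largest component's share of nodes).
#' @export
parameterSweep <- function(tpm, f, nList, gList, eps, minPts,
    metric = "correlation") {
  if (!length(nList) || !length(gList)) stop("empty parameter grid")
  grid <- unique(expand.grid(n = nList, g = gList,
    KEEP.OUT.ATTRS = FALSE))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    G <- mapperPipeline(tpm, f, grid$n[i], grid$g[i], eps, minPts, metric)
    ig <- mapperToIgraph(G)
    comp <- igraph::components(ig)
    data.frame(n = grid$n[i], g = grid$g[i],
      nodes = nrow(G@nodes), edges = nrow(G@edges),
      components = comp$no,
      giantFrac = if (nrow(G@nodes)) max(comp$csize) / nrow(G@nodes) else NA_real_)
  })
  do.call(rbind, rows)
}

.jaccard <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

#' Simplify a Mapper graph by greedy Jaccard agglomeration
#'
#' Repeatedly merges the edge-connected node pair with the highest Jaccard
#' similarity of member-sample sets (ties broken by the smaller (id, id)
#' pair) until at most \code{targetNodes} meta-nodes remain or no edges
#' remain. Meta-node members are unions of merged members; meta-edges are
#' re-derived from member intersections. The union of member samples is
#' never changed.
#'
#' @param G a \linkS4class{MapperGraph}.
#' @param targetNodes target number of meta-nodes (default 18, the
#'   interpretation scale used for both lenses).
#' @param f optional named lens values; when given, meta-node
#'   \code{meanLens} is recomputed exactly over merged members.
#' @return a simplified \linkS4class{MapperGraph}; node ids are the
#'   smallest original id in each meta-node, \code{interval} the interval
#'   of that node, \code{meanLens} the mean lens over the merged members.
#' @export
simplifyGraph <- function(G, targetNodes = 18, f = NULL) {
  if (targetNodes < 1) stop("targetNodes must be >= 1")
  members <- G@members
  # carry per-sample lens values through merges via member means
  lensByNode <- setNames(G@nodes$meanLens, names(members))
  interval <- setNames(G@nodes$interval, names(members))
  repeat {
    if (length(members) <= targetNodes) break
    edges <- .edgesFromMembers(members)
    if (!nrow(edges)) break
    jac <- vapply(seq_len(nrow(edges)), function(i)
      .jaccard(members[[as.character(edges$from[i])]],
               members[[as.character(edges$to[i])]]), numeric(1))
    best <- order(-jac, edges$from, edges$to)[1]
    a <- as.character(edges$from[best]); b <- as.character(edges$to[best])
    sizeA <- length(members[[a]]); sizeB <- length(members[[b]])
    merged <- union(members[[a]], members[[b]])
    lensByNode[a] <- (lensByNode[a] * sizeA + lensByNode[b] * sizeB) /
      (sizeA + sizeB)
    members[[a]] <- merged
    members[[b]] <- NULL
    lensByNode <- lensByNode[names(members)]
    interval <- interval[names(members)]
  }
  ids <- as.integer(names(members))
  meanLens <- if (!is.null(f))
    vapply(members, function(m) mean(f[m]), numeric(1)) else lensByNode
  nodes <- data.frame(node = ids, interval = unname(interval),
    size = lengths(members), meanLens = unname(meanLens))
  methods::new("MapperGraph", nodes = nodes, members = members,
    edges = .edgesFromMembers(members), noise = G@noise)
}

#' Factor composition of Mapper nodes
#'
#' Counts, per node, the members at each level of a metadata factor.
#' Because overlapping cover intervals put samples in several nodes, column
#' sums can exceed the number of distinct samples.
#'
#' @param G a \linkS4class{MapperGraph}.
#' @param meta metadata with a \code{sample} column and the factor column.
#' @param factor one of \code{"tissue"}, \code{"stress"}, \code{"family"}
#'   (any metadata column is accepted).
#' @return matrix of counts, nodes in rows (named by node id), factor
#'   levels in columns; row sums equal node sizes.
#' @export
nodeComposition <- function(G, meta, factor = c("tissue", "stress",
    "family")) {
  factor <- if (length(factor) > 1) match.arg(factor) else factor
  if (!factor %in% colnames(meta)) stop("metadata lacks column: ", factor)
  lev <- sort(unique(as.character(meta[[factor]])))
  lookup <- setNames(as.character(meta[[factor]]), meta$sample)
  out <- vapply(G@members, function(m) {
    if (any(!m %in% names(lookup)))
      stop("member sample(s) missing from metadata: ",
        paste(head(setdiff(m, names(lookup))), collapse = ", "))
    as.numeric(table(base::factor(lookup[m], levels = lev)))
  }, numeric(length(lev)))
  out <- matrix(out, nrow = length(G@members), ncol = length(lev),
    byrow = TRUE)
  dimnames(out) <- list(names(G@members), lev)
  out
}

#' Evenly spaced Y-shaped point cloud
#'
#' A planar worked example for Mapper: a vertical stem from (0, -2) to the
#' origin and two straight arms rising to (-armX, 2) and (armX, 2). With
#' the y-coordinate as lens and 4 overlapping intervals the Mapper graph is
#' a tree with a single degree-3 branch node; the x-coordinate lens yields
#' a different graph.
#'
#' @param nStem,nArm points per segment.
#' @param armX half-spread of the arm endpoints.
#' @return 2 x n matrix (rows "x", "y"), columns named p1, p2, ...
#' @export
yShapePoints <- function(nStem = 41, nArm = 40, armX = 1.5) {
  stem <- rbind(x = rep(0, nStem), y = seq(-2, 0, length.out = nStem))
  t <- seq(0, 1, length.out = nArm + 1)[-1]
  left <- rbind(x = -armX * t, y = 2 * t)
  right <- rbind(x = armX * t, y = 2 * t)
  pts <- cbind(stem, left, right)
  colnames(pts) <- paste0("p", seq_len(ncol(pts)))
  pts
}
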