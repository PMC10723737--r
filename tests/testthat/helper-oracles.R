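# Independent brute-force oracles, kept deliberately naive and separate
# from the package implementations they check.

# DBSCAN by direct definition: cores from neighborhood counts, core
# clusters by union-find over the eps-graph, borders attached to the
# cluster of their first core neighbor in index order.
bfDbscan <- function(d, eps, minPts) {
  n <- nrow(d)
  if (n == 0) return(integer(0))
  neighbors <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(neighbors, function(nb) length(nb) >= minPts, logical(1))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in which(core)) for (j in which(core)) {
    if (j > i && d[i, j] <= eps) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  labels <- integer(n)
  roots <- vapply(seq_len(n), find, integer(1))
  coreRoots <- unique(roots[core])
  for (i in which(core)) labels[i] <- match(roots[i], coreRoots)
  for (i in which(!core)) {
    nb <- neighbors[[i]]
    nbCore <- nb[core[nb]]
    if (length(nbCore)) labels[i] <- labels[nbCore[1]]
  }
  # renumber by first appearance, as the implementation documents
  seen <- unique(labels[labels > 0])
  if (length(seen)) labels[labels > 0] <- match(labels[labels > 0], seen)
  labels
}

# all-pairs shared-member edge list from a member list
bfNerveEdges <- function(members) {
  ids <- as.integer(names(members))
  out <- data.frame(from = integer(0), to = integer(0), weight = integer(0))
  if (length(members) < 2) return(out)
  for (a in seq_along(members)) for (b in seq_along(members)) {
    if (b > a) {
      w <- length(intersect(members[[a]], members[[b]]))
      if (w > 0) out <- rbind(out,
        data.frame(from = ids[a], to = ids[b], weight = w))
    }
  }
  out
}

# Pearson r by the textbook formula
bfPearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# random orthogroup table for round-trip / filter tests
randomOrthogroupTable <- function(nOg, species, seed) {
  set.seed(seed)
  groups <- lapply(seq_len(nOg), function(i) {
    entry <- lapply(species, function(sp) {
      k <- sample(0:3, 1)
      if (k == 0) character(0)
      else paste0(sp, "_g", sample(1000, k))
    })
    names(entry) <- species
    entry
  })
  names(groups) <- sprintf("OG%04d", seq_len(nOg))
  methods::new("OrthogroupTable", groups = groups, species = species)
}

# tiny deterministic TPM matrix with metadata for lens / mapper tests
toyExperiment <- function(nOg = 40, nSamples = 24, seed = 42) {
  cfg <- simulationConfig(nFamilies = 3, nTissues = 3, nStresses = 3,
    nSpeciesPerFamily = 2, nOrthogroups = nOg, nSamples = nSamples,
    seed = seed)
  meta <- simulateMetadata(cfg)
  sim <- simulateExpression(cfg, meta)
  list(cfg = cfg, meta = meta, tpm = sim$tpm, truth = sim$truth)
}
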