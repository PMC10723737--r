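test_that("the interval cover matches its closed form exactly", {
  cv <- buildCover(0, 10, n = 4, g = 0.5)
  iv <- coverIntervals(cv)
  expect_equal(unname(iv),
    cbind(c(0, 2, 4, 6), c(4, 6, 8, 10)), tolerance = 1e-12)
  # single interval is the whole range
  expect_equal(unname(coverIntervals(buildCover(-1, 3, 1, 0.4))),
    cbind(-1, 3))
  # random parameters: closed form, full coverage, exact adjacent overlap
  set.seed(41)
  for (i in 1:20) {
    fmin <- runif(1, -5, 0); fmax <- fmin + runif(1, 0.1, 10)
    n <- sample(1:12, 1); g <- runif(1, 0, 0.9)
    iv <- coverIntervals(buildCover(fmin, fmax, n, g))
    L <- (fmax - fmin) / (n - (n - 1) * g)
    expect_equal(unname(iv[, "lo"]),
      fmin + (0:(n - 1)) * (1 - g) * L, tolerance = 1e-12)
    expect_equal(unname(iv[, "hi"] - iv[, "lo"]), rep(L, n),
      tolerance = 1e-12)
    expect_equal(unname(iv[n, "hi"]), fmax, tolerance = 1e-12)
    if (n > 1)
      expect_equal(unname(iv[-n, "hi"] - iv[-1, "lo"]), rep(g * L, n - 1),
        tolerance = 1e-12)
  }
  expect_error(buildCover(1, 0, 2, 0.2), "fmax")
  expect_error(buildCover(0, 1, 2, 1), "overlap")
})

test_that("DBSCAN separates density clusters and flags noise", {
  pts <- c(0, 0.1, 0.2, 5, 5.1)
  d <- as.matrix(dist(pts))
  labels <- dbscanLabels(d, eps = 0.5, minPts = 2)
  expect_equal(labels, c(1, 1, 1, 2, 2))
  # isolated point with minPts 2 is noise
  d2 <- as.matrix(dist(c(0, 0.1, 9)))
  expect_equal(dbscanLabels(d2, 0.5, 2), c(1, 1, 0))
  # all mutually within eps, minPts 1: one cluster, no noise
  d3 <- as.matrix(dist(c(0, 0.1, 0.2)))
  expect_equal(dbscanLabels(d3, 1, 1), c(1, 1, 1))
})

test_that("DBSCAN agrees with a brute-force oracle on random instances", {
  set.seed(43)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    pts <- matrix(rnorm(2 * n, sd = 2), 2)
    d <- as.matrix(dist(t(pts)))
    eps <- runif(1, 0.3, 2)
    minPts <- sample(1:4, 1)
    expect_identical(dbscanLabels(d, eps, minPts),
      bfDbscan(d, eps, minPts))
  }
})

test_that("the nerve records exactly the non-empty pairwise intersections", {
  # pairwise-disjoint clusters: edgeless
  G0 <- mapperNerve(list(list(c("s1"), c("s2")), list(c("s3"))))
  expect_equal(nrow(mapperEdges(G0)), 0)
  # A={s1,s2}, B={s2,s3}, C={s4}: single edge (A,B) of weight 1
  G <- mapperNerve(list(list(c("s1", "s2"), c("s2", "s3")), list("s4")))
  ed <- mapperEdges(G)
  expect_equal(nrow(ed), 1)
  expect_equal(ed$from, 1); expect_equal(ed$to, 2); expect_equal(ed$weight, 1)
  # random member sets match the brute-force edge oracle
  set.seed(44)
  for (i in 1:20) {
    samples <- paste0("s", 1:30)
    clusters <- lapply(1:2, function(j)
      lapply(seq_len(sample(1:4, 1)), function(k)
        sample(samples, sample(2:8, 1))))
    G <- mapperNerve(clusters)
    expect_equal(mapperEdges(G), bfNerveEdges(nodeMembers(G)),
      ignore_attr = TRUE)
  }
})

test_that("the mapper pipeline composes cover, clustering and nerve", {
  toy <- toyExperiment()
  f <- setNames(runif(ncol(toy$tpm), 0, 1), colnames(toy$tpm))
  set.seed(45); f <- setNames(runif(ncol(toy$tpm)), colnames(toy$tpm))
  G <- mapperPipeline(toy$tpm, f, n = 3, g = 0.4, eps = 0.5,
    minPts = 2, metric = "euclidean")
  # independent composition of the three steps
  x <- log2Tpm(toy$tpm)
  iv <- coverIntervals(buildCover(min(f), max(f), 3, 0.4))
  clusters <- lapply(seq_len(nrow(iv)), function(j) {
    ids <- names(f)[f >= iv[j, 1] & f <= iv[j, 2]]
    d <- as.matrix(dist(t(x[, ids, drop = FALSE])))
    labs <- bfDbscan(d, 0.5, 2)
    lapply(seq_len(max(labs, 0)), function(k) ids[labs == k])
  })
  Gref <- mapperNerve(clusters, f = f)
  expect_equal(mapperNodes(G), mapperNodes(Gref))
  expect_equal(nodeMembers(G), nodeMembers(Gref))
  expect_equal(mapperEdges(G), mapperEdges(Gref))
  # determinism
  G2 <- mapperPipeline(toy$tpm, f, 3, 0.4, eps = 0.5, minPts = 2,
    metric = "euclidean")
  expect_equal(G, G2)
  # n = 1: clusters of the whole dataset, edgeless
  G1 <- mapperPipeline(toy$tpm, f, 1, 0, eps = 0.5, minPts = 2,
    metric = "euclidean")
  expect_equal(nrow(mapperEdges(G1)), 0)
  expect_true(all(mapperNodes(G1)$interval == 0))
})

test_that("cover overlap places boundary samples in adjacent preimages", {
  toy <- toyExperiment(nOg = 20, nSamples = 30, seed = 46)
  f <- setNames(seq(0, 1, length.out = 30), colnames(toy$tpm))
  G <- mapperPipeline(toy$tpm, f, n = 4, g = 0.4, eps = 10,
    minPts = 1, metric = "euclidean")
  # eps large and minPts 1: every preimage is one cluster, so every sample
  # is covered, and samples in overlap regions sit in two nodes
  covered <- unlist(nodeMembers(G))
  expect_setequal(unique(covered), names(f))
  iv <- coverIntervals(buildCover(0, 1, 4, 0.4))
  inOverlap <- names(f)[f >= iv[2, "lo"] & f <= iv[1, "hi"]]
  counts <- table(covered)
  expect_true(all(counts[inOverlap] >= 2))
})

test_that("the parameter sweep summarizes the hyperparameter grid", {
  toy <- toyExperiment(nOg = 20, nSamples = 30, seed = 47)
  f <- setNames(seq(0, 1, length.out = 30), colnames(toy$tpm))
  one <- parameterSweep(toy$tpm, f, nList = 3, gList = 0.3, eps = 10,
    minPts = 1, metric = "euclidean")
  expect_equal(nrow(one), 1)
  dup <- parameterSweep(toy$tpm, f, nList = c(3, 3), gList = c(0.3, 0.3),
    eps = 10, minPts = 1, metric = "euclidean")
  expect_equal(nrow(dup), 1)
  # in the trivial-clustering regime (one cluster per interval), the node
  # count equals n and is non-decreasing in n
  sw <- parameterSweep(toy$tpm, f, nList = c(2, 4, 6), gList = 0.3,
    eps = 10, minPts = 1, metric = "euclidean")
  expect_equal(sw$nodes, c(2, 4, 6))
  expect_true(all(diff(sw$nodes) >= 0))
  expect_error(parameterSweep(toy$tpm, f, integer(0), 0.3, 1, 1), "empty")
})

test_that("greedy Jaccard simplification follows the hand-computed merge", {
  # chain A-B-C with J(A,B) = 0.5 > J(B,C) = 0.2
  members <- list(
    "1" = c("s1", "s2", "s3"),           # A
    "2" = c("s2", "s3", "s4"),           # B: |A∩B|=2, |A∪B|=4 -> 0.5
    "3" = c("s4", "s5", "s6", "s7", "s8", "s9", "s10", "s11", "s12")
  )                                       # C: |B∩C|=1, |B∪C|=11 -> 1/11
  G <- mapperNerve(list(unname(members)))
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  expect_equal(jac(members[["1"]], members[["2"]]), 0.5)
  expect_lt(jac(members[["2"]], members[["3"]]), 0.5)
  S <- simplifyGraph(G, targetNodes = 2)
  expect_equal(nrow(mapperNodes(S)), 2)
  mem <- nodeMembers(S)
  expect_setequal(mem[["1"]], union(members[["1"]], members[["2"]]))
  expect_setequal(mem[["3"]], members[["3"]])
  # no-op when already small enough
  expect_equal(nodeMembers(simplifyGraph(G, 3)), nodeMembers(G))
  # default interpretation scale is 18 meta-nodes
  expect_equal(eval(formals(simplifyGraph)$targetNodes), 18)
})

test_that("simplification preserves the covered samples and connectivity", {
  toy <- toyExperiment(nOg = 30, nSamples = 40, seed = 48)
  set.seed(48)
  f <- setNames(runif(40), colnames(toy$tpm))
  G <- mapperPipeline(toy$tpm, f, 6, 0.4, eps = 6, minPts = 1,
    metric = "euclidean")
  for (target in c(4, 2, 1)) {
    S <- simplifyGraph(G, target, f = f)
    expect_setequal(unique(unlist(nodeMembers(S))),
      unique(unlist(nodeMembers(G))))
    expect_lte(igraph::components(mapperToIgraph(S))$no,
      igraph::components(mapperToIgraph(G))$no)
  }
})

test_that("node composition tallies metadata factors per node", {
  meta <- data.frame(sample = paste0("s", 1:6),
    tissue = c("leaf", "leaf", "leaf", "root", "root", "seed"),
    stringsAsFactors = FALSE)
  G <- mapperNerve(list(list(c("s1", "s2", "s3"), c("s3", "s4", "s5", "s6"))))
  comp <- nodeComposition(G, meta, "tissue")
  expect_equal(comp["1", "leaf"], 3)
  expect_equal(unname(comp["2", c("leaf", "root", "seed")]), c(1, 2, 1))
  # row sums are node sizes; totals can exceed the sample count (overlap)
  expect_equal(unname(rowSums(comp)), mapperNodes(G)$size)
  expect_gte(sum(comp), length(unique(meta$sample)))
  expect_error(nodeComposition(G, meta[-3, ], "tissue"), "missing")
  # counting oracle on random assignments
  set.seed(49)
  meta2 <- data.frame(sample = paste0("s", 1:20),
    tissue = sample(c("leaf", "root", "seed"), 20, TRUE))
  members <- lapply(1:4, function(i) sample(meta2$sample, 8))
  G2 <- mapperNerve(list(members))
  comp2 <- nodeComposition(G2, meta2, "tissue")
  for (i in 1:4) for (lv in colnames(comp2)) {
    expect_equal(comp2[as.character(i), lv],
      sum(meta2$tissue[match(members[[i]], meta2$sample)] == lv))
  }
})

test_that("the Y-shaped point cloud yields a branch under the y lens", {
  pts <- yShapePoints()
  fy <- setNames(pts["y", ], colnames(pts))
  for (g in c(0.2, 0.3)) {
    G <- mapperFromPoints(pts, fy, n = 4, g = g, eps = 0.3, minPts = 2)
    ig <- mapperToIgraph(G)
    # a tree: acyclic with exactly one degree-3 branch point
    expect_equal(igraph::ecount(ig),
      igraph::vcount(ig) - igraph::components(ig)$no)
    expect_equal(sum(igraph::degree(ig) == 3), 1)
  }
  # the x-coordinate lens yields a different graph
  fx <- setNames(pts["x", ], colnames(pts))
  Gx <- mapperFromPoints(pts, fx, n = 4, g = 0.3, eps = 0.3, minPts = 2)
  Gy <- mapperFromPoints(pts, fy, n = 4, g = 0.3, eps = 0.3, minPts = 2)
  expect_false(identical(
    c(nrow(mapperNodes(Gx)), sort(mapperEdges(Gx)$weight)),
    c(nrow(mapperNodes(Gy)), sort(mapperEdges(Gy)$weight))))
})

test_that("graphs serialize to GraphML with attributes and memberships", {
  toy <- toyExperiment(nOg = 20, nSamples = 30, seed = 50)
  f <- setNames(seq(0, 1, length.out = 30), colnames(toy$tpm))
  G <- mapperPipeline(toy$tpm, f, 3, 0.3, eps = 10, minPts = 1,
    metric = "euclidean")
  gml <- tempfile(fileext = ".graphml"); mem <- tempfile(fileext = ".tsv")
  writeMapperGraph(G, gml, mem)
  expect_true(file.size(gml) > 0)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), nrow(mapperNodes(G)))
  expect_true("mean_lens" %in% igraph::vertex_attr_names(back))
  memTab <- read.delim(mem)
  expect_equal(nrow(memTab), sum(mapperNodes(G)$size))
})
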