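#' Create a simulation configuration
#'
#' Builds a validated \linkS4class{SimulationConfig}. The defaults mirror
#' the study design the generator emulates: 16 families, 8 tissues (the
#' first being leaf), 10 stresses (the first being healthy), with planted
#' photosynthesis-analog tissue genes and severity-scaled stress genes on
#' top of family, batch and iid noise on the log2 scale.
#'
#' @param nFamilies,nTissues,nStresses,nSpeciesPerFamily factor level counts.
#' @param nOrthogroups,nSamples matrix dimensions.
#' @param fracTissueGenes,fracStressGenes fractions of orthogroups carrying
#'   the planted tissue / stress effect.
#' @param tissueEffect log2 drop of tissue genes outside leaf tissue.
#' @param stressEffect log2 increase of stress genes per unit severity.
#' @param familySd,batchSd,noiseSd nuisance standard deviations (log2 scale).
#' @param comboSkew Zipf exponent of factor-combination sampling weights.
#' @param healthyWeight upweight of healthy-stress combinations; controls
#'   dominate public repositories, so healthy combinations are sampled
#'   more often than any single stress.
#' @param seed integer RNG seed.
#' @return a \linkS4class{SimulationConfig}.
#' @examples
#' simulationConfig(nOrthogroups = 100, nSamples = 30, seed = 7)
#' @export
simulationConfig <- function(nFamilies = 16, nTissues = 8, nStresses = 10,
    nSpeciesPerFamily = 3, nOrthogroups = 1000, nSamples = 300,
    fracTissueGenes = 0.05, fracStressGenes = 0.05,
    tissueEffect = 3, stressEffect = 2,
    familySd = 0.25, batchSd = 0.25, noiseSd = 0.5,
    comboSkew = 1.2, healthyWeight = 6, seed = 1) {
  methods::new("SimulationConfig",
    nFamilies = as.integer(nFamilies), nTissues = as.integer(nTissues),
    nStresses = as.integer(nStresses),
    nSpeciesPerFamily = as.integer(nSpeciesPerFamily),
    nOrthogroups = as.integer(nOrthogroups), nSamples = as.integer(nSamples),
    fracTissueGenes = fracTissueGenes, fracStressGenes = fracStressGenes,
    tissueEffect = tissueEffect, stressEffect = stressEffect,
    familySd = familySd, batchSd = batchSd, noiseSd = noiseSd,
    comboSkew = comboSkew, healthyWeight = healthyWeight,
    seed = as.integer(seed))
}

.TISSUE_POOL <- c("leaf", "root", "seed", "fruit", "flower", "stem",
  "callus", "meristem")
.STRESS_POOL <- c("healthy", "drought", "heat", "cold", "salt", "light",
  "wounding", "pathogen", "nutrient", "submergence")

.levelNames <- function(pool, n, prefix) {
  if (n <= length(pool)) pool[seq_len(n)]
  else c(pool, sprintf("%s%02d", prefix, seq_len(n - length(pool))))
}

#' Tissue and stress level names used by the generator
#'
#' The first tissue level is always \code{"leaf"} (the photosynthetic
#' reference) and the first stress level is always \code{"healthy"}.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @return list with elements \code{families}, \code{species} (named list by
#'   family), \code{tissues}, \code{stresses}.
#' @export
simulationLevels <- function(cfg) {
  families <- sprintf("F%02d", seq_len(cfg@nFamilies))
  species <- lapply(families, function(f)
    sprintf("%s_sp%d", f, seq_len(cfg@nSpeciesPerFamily)))
  names(species) <- families
  list(
    families = families,
    species = species,
    tissues = .levelNames(.TISSUE_POOL, cfg@nTissues, "tissue"),
    stresses = .levelNames(.STRESS_POOL, cfg@nStresses, "stress")
  )
}

#' Simulate sample metadata with a skewed factor-combination distribution
#'
#' Draws one (family, tissue, stress) triple per sample from a Zipf-like
#' weight over all possible combinations (heaviest combinations dominate,
#' emulating the unbalanced sampling of public repositories), picks a
#' species uniformly within the family, and derives one bioproject per
#' (species, stress) pair so that batch structure is confounded with the
#' biological factors, as it is in repository data.
#'
#' Deterministic given \code{cfg@seed}; sample-level draws use an RNG
#' stream independent of the gene-level stream of
#' \code{\link{simulateExpression}}.
#'
#' @param cfg a valid \linkS4class{SimulationConfig}.
#' @return data.frame with columns \code{sample}, \code{species},
#'   \code{family}, \code{tissue}, \code{stress}, \code{bioproject};
#'   \code{nSamples = 0} yields the empty data.frame with the same columns.
#' @examples
#' meta <- simulateMetadata(simulationConfig(nSamples = 12, seed = 3))
#' head(meta)
#' @export
simulateMetadata <- function(cfg) {
  methods::validObject(cfg)
  lv <- simulationLevels(cfg)
  cols <- c("sample", "species", "family", "tissue", "stress", "bioproject")
  if (cfg@nSamples == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    return(out)
  }
  combos <- expand.grid(family = lv$families, tissue = lv$tissues,
    stress = lv$stresses, stringsAsFactors = FALSE,
    KEEP.OUT.ATTRS = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg@seed + 101L)
  # Zipf weights over a random permutation, so the heavy combinations are
  # not tied to lexicographic order.
  perm <- sample.int(nrow(combos))
  w <- 1 / rank(perm)^cfg@comboSkew
  w <- w * ifelse(combos$stress == "healthy", cfg@healthyWeight, 1)
  idx <- sample.int(nrow(combos), cfg@nSamples, replace = TRUE, prob = w)
  fam <- combos$family[idx]
  sp <- vapply(fam, function(f) sample(lv$species[[f]], 1L), character(1))
  bp_key <- paste(sp, combos$stress[idx], sep = "|")
  bp <- sprintf("PRJ%04d", as.integer(factor(bp_key, levels = unique(bp_key))))
  data.frame(
    sample = sprintf("SRR%06d", seq_len(cfg@nSamples)),
    species = unname(sp),
    family = fam,
    tissue = combos$tissue[idx],
    stress = combos$stress[idx],
    bioproject = bp,
    stringsAsFactors = FALSE
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Simulate an orthogroup expression matrix with planted signal
#'
#' Generates a log2-scale signal per orthogroup i and sample j:
#' \deqn{x_{ij} = b_i - tissueEffect \cdot 1[i \in T] 1[tissue_j \neq leaf]
#'   + stressEffect \cdot s_j \cdot 1[i \in S] + fam_{i,f(j)} + bat_{i,p(j)}
#'   + \epsilon_{ij}}
#' where T is the planted tissue (photosynthesis-analog) gene set — high in
#' leaf, dropping by \code{tissueEffect} elsewhere — S the planted stress
#' gene set scaling with per-sample severity \eqn{s_j} (0 for healthy
#' samples, uniform on [0.5, 1.5] otherwise), with per-(gene, family) and
#' per-(gene, bioproject) offsets and iid noise. The returned matrix is
#' \code{pmax(2^x - 1, 0)}: TPM-like and non-negative.
#'
#' Gene-level draws (baselines, planted sets, offsets) use an RNG stream
#' seeded from \code{cfg@seed} independent of the metadata stream, so
#' changing \code{nSamples} does not change which genes carry signal.
#'
#' @param cfg the \linkS4class{SimulationConfig} used for \code{meta}.
#' @param meta metadata from \code{\link{simulateMetadata}(cfg)}.
#' @return list with \code{tpm} (orthogroups x samples matrix) and
#'   \code{truth}: list(\code{tissueGeneIds}, \code{stressGeneIds},
#'   \code{severity} named by sample).
#' @examples
#' cfg <- simulationConfig(nOrthogroups = 60, nSamples = 15, seed = 2)
#' sim <- simulateExpression(cfg, simulateMetadata(cfg))
#' dim(sim$tpm)
#' @export
simulateExpression <- function(cfg, meta) {
  methods::validObject(cfg)
  req <- c("sample", "family", "tissue", "stress", "bioproject")
  if (!all(req %in% colnames(meta)))
    stop("metadata lacks required columns: ",
      paste(setdiff(req, colnames(meta)), collapse = ", "))
  if (nrow(meta) != cfg@nSamples)
    stop("metadata rows (", nrow(meta), ") do not match cfg nSamples (",
      cfg@nSamples, ")")
  lv <- simulationLevels(cfg)
  if (!all(meta$family %in% lv$families))
    stop("metadata families not generated by this configuration")
  G <- cfg@nOrthogroups
  N <- cfg@nSamples
  ogIds <- sprintf("OG%05d", seq_len(G))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  # gene-level stream
  set.seed(cfg@seed + 202L)
  baseline <- runif(G, 3, 8)
  nT <- floor(cfg@fracTissueGenes * G)
  nS <- floor(cfg@fracStressGenes * G)
  tissueGenes <- sort(sample(ogIds, nT))
  stressGenes <- sort(sample(ogIds, nS))
  famOff <- matrix(rnorm(G * cfg@nFamilies, 0, cfg@familySd), G,
    dimnames = list(ogIds, lv$families))

  # sample-level stream
  set.seed(cfg@seed + 303L)
  severity <- numeric(N)
  stressed <- meta$stress != "healthy"
  severity[stressed] <- runif(sum(stressed), 0.5, 1.5)
  names(severity) <- meta$sample
  projects <- unique(meta$bioproject)
  batOff <- matrix(rnorm(G * length(projects), 0, cfg@batchSd), G,
    dimnames = list(ogIds, projects))
  x <- matrix(baseline, G, N) +
    matrix(rnorm(G * N, 0, cfg@noiseSd), G, N)
  dimnames(x) <- list(ogIds, meta$sample)
  if (N > 0) {
    x <- x + famOff[, meta$family, drop = FALSE] +
      batOff[, meta$bioproject, drop = FALSE]
    nonleaf <- meta$tissue != "leaf"
    if (nT > 0 && any(nonleaf))
      x[tissueGenes, nonleaf] <- x[tissueGenes, nonleaf] - cfg@tissueEffect
    if (nS > 0)
      x[stressGenes, ] <- x[stressGenes, ] +
        cfg@stressEffect * rep(severity, each = nS)
  }
  tpm <- pmax(2^x - 1, 0)
  list(
    tpm = tpm,
    truth = list(
      tissueGeneIds = tissueGenes,
      stressGeneIds = stressGenes,
      severity = severity
    )
  )
}

#' Write a simulated dataset to disk in the pipeline's exchange formats
#'
#' Metadata as CSV, expression as CSV with orthogroup row labels
#' (first column \code{orthogroup}), truth as JSON.
#'
#' @param meta metadata data.frame.
#' @param sim result of \code{\link{simulateExpression}}.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return invisibly, the paths written.
#' @export
writeSimulation <- function(meta, sim, dir, prefix = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  metaPath <- file.path(dir, paste0(prefix, "_metadata.csv"))
  exprPath <- file.path(dir, paste0(prefix, "_expression.csv"))
  truthPath <- file.path(dir, paste0(prefix, "_truth.json"))
  utils::write.csv(meta, metaPath, row.names = FALSE, quote = FALSE)
  expr <- data.frame(orthogroup = rownames(sim$tpm), sim$tpm,
    check.names = FALSE)
  utils::write.csv(expr, exprPath, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(sim$truth, truthPath, auto_unbox = FALSE, digits = NA)
  invisible(c(metadata = metaPath, expression = exprPath, truth = truthPath))
}
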