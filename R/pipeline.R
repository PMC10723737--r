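#' Run the full topology pipeline
#'
#' Orchestrates the stages end-to-end into a flat run directory with
#' stage-prefixed files: data (simulated, or loaded from the configured
#' paths), tissue and stress lenses, full and simplified Mapper graphs with
#' node composition tables, lens-correlation ranking with extreme tails and
#' enrichment, the factor-combination audit with downsampling, and a
#' machine-readable manifest (config hash, package version, seed, outputs).
#'
#' The configuration is a plain YAML key-value file (or an equivalent named
#' list). Recognized keys, all optional, with defaults in parentheses:
#' \describe{
#'   \item{expression, metadata}{CSV paths; when absent, data are simulated.}
#'   \item{simulation}{sub-list passed to \code{\link{simulationConfig}}.}
#'   \item{healthy_label ("healthy"), leaf_label ("leaf")}{reference labels.}
#'   \item{rank_tau (0.95)}{lens explained-variance threshold.}
#'   \item{n_intervals (10), overlap (0.3), eps (0.15), min_samples (3),
#'     metric ("correlation")}{Mapper settings.}
#'   \item{target_nodes (18)}{simplified-graph size.}
#'   \item{tail_frac (0.025)}{correlation tail fraction.}
#'   \item{gene_sets}{optional GMT path for flat-set enrichment.}
#'   \item{reference_set}{optional GMT path; its first set is used for the
#'     one-sided binomial test. When simulating, the planted stress/tissue
#'     gene sets are used instead.}
#'   \item{top_k (30), cap (30)}{downsampling settings.}
#' }
#'
#' @param config path to a YAML config file, or a named list.
#' @param outdir output directory (created; must be empty or absent unless
#'   \code{overwrite}).
#' @param seed integer seed overriding the config's (and the simulation's)
#'   seed.
#' @param overwrite allow writing into an existing directory.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config = list(), outdir, seed = NULL,
    overwrite = FALSE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("config must be a list or a YAML file path")
  if (dir.exists(outdir) && !overwrite &&
      length(list.files(outdir)))
    stop("output directory exists and is non-empty: ", outdir)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  get <- function(key, default) if (!is.null(cfg[[key]])) cfg[[key]] else
    default
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  seed <- as.integer(get("seed", 1L))
  outputs <- character(0)
  emit <- function(name) {
    p <- file.path(outdir, name)
    outputs[[length(outputs) + 1L]] <<- p
    p
  }

  # --- stage 1: data -------------------------------------------------
  truth <- NULL
  if (!is.null(cfg$expression) && !is.null(cfg$metadata)) {
    meta <- utils::read.csv(cfg$metadata, stringsAsFactors = FALSE)
    exprDf <- utils::read.csv(cfg$expression, check.names = FALSE,
      stringsAsFactors = FALSE)
    tpm <- as.matrix(exprDf[, -1, drop = FALSE])
    rownames(tpm) <- exprDf[[1]]
  } else {
    simArgs <- get("simulation", list())
    simArgs$seed <- seed
    simCfg <- do.call(simulationConfig, simArgs)
    meta <- simulateMetadata(simCfg)
    sim <- simulateExpression(simCfg, meta)
    tpm <- sim$tpm
    truth <- sim$truth
    writeSimulation(meta, sim, outdir, prefix = "01_synthetic")
    outputs <- c(outputs, file.path(outdir,
      paste0("01_synthetic_", c("metadata.csv", "expression.csv",
        "truth.json"))))
  }
  oe <- OrthoExperiment(tpm, meta)

  # --- stage 2: lenses ----------------------------------------------
  healthy <- get("healthy_label", "healthy")
  leaf <- get("leaf_label", "leaf")
  tau <- get("rank_tau", 0.95)
  lenses <- list()
  for (kind in c("tissue", "stress")) {
    refIds <- selectReference(meta, kind, healthyLabel = healthy,
      leafLabel = leaf)
    model <- fitLensModel(tpm, refIds, tau = tau)
    f <- residualLens(tpm, model)
    lenses[[kind]] <- f
    write.table(data.frame(sample = names(f), lens_value = unname(f)),
      emit(sprintf("02_lens_%s.tsv", kind)),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }

  # --- stage 3: mapper graphs ---------------------------------------
  nIntervals <- get("n_intervals", 10)
  overlap <- get("overlap", 0.3)
  eps <- get("eps", 0.15)
  minPts <- get("min_samples", 3)
  metric <- get("metric", "correlation")
  targetNodes <- get("target_nodes", 18)
  graphs <- list()
  for (kind in c("tissue", "stress")) {
    G <- mapperPipeline(tpm, lenses[[kind]], nIntervals, overlap, eps,
      minPts, metric)
    S <- simplifyGraph(G, targetNodes, f = lenses[[kind]])
    graphs[[kind]] <- list(full = G, simplified = S)
    writeMapperGraph(G, emit(sprintf("03_mapper_%s_full.graphml", kind)),
      emit(sprintf("03_mapper_%s_full_members.tsv", kind)))
    writeMapperGraph(S,
      emit(sprintf("03_mapper_%s_simplified.graphml", kind)),
      emit(sprintf("03_mapper_%s_simplified_members.tsv", kind)))
    for (fac in c("tissue", "stress", "family")) {
      comp <- nodeComposition(S, meta, fac)
      write.table(data.frame(node = rownames(comp), comp,
          check.names = FALSE),
        emit(sprintf("03_composition_%s_by_%s.tsv", kind, fac)),
        sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }

  # --- stage 4: correlation ranking and enrichment ------------------
  tailFrac <- get("tail_frac", 0.025)
  universe <- rownames(tpm)
  enrichmentFiles <- list()
  for (kind in c("tissue", "stress")) {
    tbl <- lensCorrelation(tpm, lenses[[kind]])
    write.table(tbl, emit(sprintf("04_correlation_%s.tsv", kind)),
      sep = "\t", row.names = FALSE, quote = FALSE)
    tails <- selectExtremes(tbl, tailFrac)
    writeGmt(list(positive = tails$positive, negative = tails$negative),
      emit(sprintf("04_tails_%s.gmt", kind)))
    refSets <- NULL
    if (!is.null(truth)) {
      refSets <- list(
        planted_stress = truth$stressGeneIds,
        planted_tissue = truth$tissueGeneIds)
    } else if (!is.null(cfg$reference_set)) {
      refSets <- readGmt(cfg$reference_set)[1]
    }
    if (!is.null(refSets)) {
      res <- do.call(rbind, lapply(names(refSets), function(nm) rbind(
        cbind(tail = "positive", binomialEnrichment(tails$positive,
          refSets[[nm]], universe, "greater", nm)),
        cbind(tail = "negative", binomialEnrichment(tails$negative,
          refSets[[nm]], universe, "greater", nm)))))
      write.table(res, emit(sprintf("04_binomial_%s.tsv", kind)),
        sep = "\t", row.names = FALSE, quote = FALSE)
    }
    if (!is.null(cfg$gene_sets)) {
      terms <- readGmt(cfg$gene_sets)
      go <- flatSetEnrichment(tails$positive, terms, universe)
      write.table(go, emit(sprintf("04_termsets_%s_positive.tsv", kind)),
        sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }

  # --- stage 5: balance audit ---------------------------------------
  before <- comboCounts(meta)
  metaDown <- downsampleTopCombos(meta, get("top_k", 30), get("cap", 30),
    seed)
  after <- comboCounts(metaDown)
  audit <- merge(before, after, by = c("family", "tissue", "stress"),
    all.x = TRUE, suffixes = c("_before", "_after"))
  audit$count_after[is.na(audit$count_after)] <- 0L
  audit <- audit[order(-audit$count_before), ]
  write.table(audit, emit("05_combo_counts.tsv"), sep = "\t",
    row.names = FALSE, quote = FALSE)
  utils::write.csv(metaDown, emit("05_metadata_downsampled.csv"),
    row.names = FALSE, quote = FALSE)

  # --- manifest ------------------------------------------------------
  cfgPath <- file.path(outdir, "config_resolved.yaml")
  yaml::write_yaml(cfg, cfgPath)
  manifest <- list(
    package = "orthoMapper",
    version = as.character(utils::packageVersion("orthoMapper")),
    seed = seed,
    config_hash = unname(tools::md5sum(cfgPath)),
    n_orthogroups = nrow(tpm),
    n_samples = ncol(tpm),
    outputs = basename(unlist(outputs))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
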