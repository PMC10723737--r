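#' Parse an OrthoFinder-style Orthogroups.tsv file
#'
#' Reads the tab-separated dialect written by OrthoFinder: first column
#' \code{Orthogroup}, one column per species, cells holding
#' comma+space-separated gene lists; empty cells become empty gene lists.
#'
#' @param path path to the Orthogroups.tsv file.
#' @param speciesRoster character vector of all species in the analysis;
#'   every species column in the file must appear here.
#' @return an \linkS4class{OrthogroupTable}.
#' @examples
#' tmp <- tempfile(fileext = ".tsv")
#' writeLines(c("Orthogroup\tspA\tspB", "OG0\tg1, g2\tg3"), tmp)
#' parseOrthogroups(tmp, c("spA", "spB"))
#' @export
parseOrthogroups <- function(path, speciesRoster) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, check.names = FALSE, colClasses = "character",
    na.strings = NULL)
  if (!identical(colnames(df)[1], "Orthogroup"))
    stop("first column must be 'Orthogroup'")
  fileSpecies <- colnames(df)[-1]
  unknown <- setdiff(fileSpecies, speciesRoster)
  if (length(unknown))
    stop("unknown species column(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(df$Orthogroup))
    stop("duplicate orthogroup id(s): ",
      paste(unique(df$Orthogroup[duplicated(df$Orthogroup)]), collapse = ", "))
  groups <- lapply(seq_len(nrow(df)), function(i) {
    entry <- lapply(fileSpecies, function(sp) {
      cell <- df[i, sp]
      if (is.na(cell) || !nzchar(trimws(cell))) character(0)
      else trimws(strsplit(cell, ",")[[1]])
    })
    names(entry) <- fileSpecies
    entry
  })
  names(groups) <- df$Orthogroup
  methods::new("OrthogroupTable", groups = groups, species = speciesRoster)
}

#' Write an OrthogroupTable in the Orthogroups.tsv dialect
#'
#' @param tbl an \linkS4class{OrthogroupTable}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeOrthogroups <- function(tbl, path) {
  sp <- tbl@species
  rows <- vapply(names(tbl@groups), function(og) {
    cells <- vapply(sp, function(s) {
      genes <- tbl@groups[[og]][[s]]
      if (is.null(genes) || !length(genes)) "" else paste(genes, collapse = ", ")
    }, character(1))
    paste(c(og, cells), collapse = "\t")
  }, character(1))
  writeLines(c(paste(c("Orthogroup", sp), collapse = "\t"), rows), path)
  invisible(path)
}

#' Filter orthogroups by conservation and diploid copy number
#'
#' Keeps orthogroups present (>= 1 gene) in at least \code{minSpecies}
#' species AND whose mean gene count, taken across the diploid species
#' that contain the orthogroup, is at most \code{maxMeanCopies}. Polyploid
#' species are exempt from the copy filter (their gene counts scale with
#' ploidy); orthogroups absent from every diploid species pass the copy
#' filter vacuously.
#'
#' @param tbl an \linkS4class{OrthogroupTable}.
#' @param minSpecies minimum number of species an orthogroup must occur in.
#' @param maxMeanCopies maximum mean copies per diploid species containing
#'   the orthogroup.
#' @param ploidy named character vector mapping every species to
#'   \code{"diploid"} or \code{"polyploid"}.
#' @return the filtered \linkS4class{OrthogroupTable}.
#' @export
filterConserved <- function(tbl, minSpecies, maxMeanCopies = 2,
    ploidy = NULL) {
  if (minSpecies > length(tbl@species))
    stop("minSpecies exceeds the species roster size")
  if (is.null(ploidy))
    ploidy <- setNames(rep("diploid", length(tbl@species)), tbl@species)
  missing <- setdiff(tbl@species, names(ploidy))
  if (length(missing))
    stop("species missing from ploidy map: ", paste(missing, collapse = ", "))
  if (!all(ploidy %in% c("diploid", "polyploid")))
    stop("ploidy values must be 'diploid' or 'polyploid'")
  diploids <- names(ploidy)[ploidy == "diploid"]
  keep <- vapply(tbl@groups, function(entry) {
    counts <- lengths(entry)
    present <- sum(counts >= 1L)
    if (present < minSpecies) return(FALSE)
    dipCounts <- counts[intersect(names(entry), diploids)]
    dipCounts <- dipCounts[dipCounts >= 1L]
    if (length(dipCounts) && mean(dipCounts) > maxMeanCopies) return(FALSE)
    TRUE
  }, logical(1))
  methods::new("OrthogroupTable", groups = tbl@groups[keep],
    species = tbl@species)
}

#' Aggregate gene-level TPM to orthogroup level for one species
#'
#' The orthogroup value in a sample is the sum of the TPMs of that species'
#' genes in the orthogroup (the raw TPM for single-copy orthogroups). Genes
#' listed in the orthogroup table but absent from the expression table
#' contribute 0 and trigger a warning.
#'
#' @param tbl an \linkS4class{OrthogroupTable}.
#' @param species species id (must be on the table's roster).
#' @param expr numeric gene x sample TPM matrix for that species, with
#'   gene rownames and sample colnames.
#' @return orthogroup x sample numeric matrix (one row per orthogroup in
#'   \code{tbl}, zeros where the species has no genes).
#' @export
aggregateTpm <- function(tbl, species, expr) {
  if (!species %in% tbl@species)
    stop("species not on the roster: ", species)
  expr <- as.matrix(expr)
  if (any(expr < 0)) stop("TPM values must be non-negative")
  ogIds <- names(tbl@groups)
  out <- matrix(0, length(ogIds), ncol(expr),
    dimnames = list(ogIds, colnames(expr)))
  absent <- character(0)
  for (og in ogIds) {
    genes <- tbl@groups[[og]][[species]]
    if (is.null(genes) || !length(genes)) next
    found <- intersect(genes, rownames(expr))
    absent <- c(absent, setdiff(genes, rownames(expr)))
    if (length(found))
      out[og, ] <- colSums(expr[found, , drop = FALSE])
  }
  if (length(absent))
    warning(length(absent), " gene(s) absent from the expression table ",
      "contribute 0 (e.g., ", paste(head(absent, 3), collapse = ", "), ")")
  out
}

#' Merge per-species orthogroup matrices into one expression matrix
#'
#' Column-wise concatenation over species. Rows are the union of input
#' orthogroups in lexicographic order; orthogroups missing from a species'
#' matrix are filled with 0 and flagged in the \code{"filled"} attribute.
#'
#' @param matrices named list of orthogroup x sample matrices (one per
#'   species); sample ids must be globally unique.
#' @return merged orthogroup x sample matrix with attribute \code{"filled"},
#'   a data.frame of (species, orthogroup) pairs that were zero-filled.
#' @export
mergeSpecies <- function(matrices) {
  if (!length(matrices)) stop("no matrices to merge")
  allSamples <- unlist(lapply(matrices, colnames))
  if (anyDuplicated(allSamples))
    stop("duplicate sample id(s) across species: ",
      paste(unique(allSamples[duplicated(allSamples)]), collapse = ", "))
  ogIds <- sort(unique(unlist(lapply(matrices, rownames))))
  filled <- list()
  blocks <- lapply(seq_along(matrices), function(i) {
    m <- matrices[[i]]
    block <- matrix(0, length(ogIds), ncol(m),
      dimnames = list(ogIds, colnames(m)))
    block[rownames(m), ] <- m
    missing <- setdiff(ogIds, rownames(m))
    if (length(missing))
      filled[[length(filled) + 1L]] <<- data.frame(
        species = if (!is.null(names(matrices))) names(matrices)[i] else
          as.character(i),
        orthogroup = missing, stringsAsFactors = FALSE)
    block
  })
  out <- do.call(cbind, blocks)
  attr(out, "filled") <- if (length(filled)) do.call(rbind, filled) else
    data.frame(species = character(0), orthogroup = character(0))
  out
}
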