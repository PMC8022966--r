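#' Construct a BreedingData object
#'
#' @param phenotypes `n x t` numeric matrix (line ids as rownames, trait
#'   names as colnames) or a data.frame whose first column is the line id.
#' @param relationship optional `n x n` relationship matrix; rows are
#'   reindexed to phenotype order when it carries rownames.
#' @param markers optional `n x p` marker matrix, likewise reindexed.
#' @param traits optional trait configuration ([traitConfig()]); defaults to
#'   an empty configuration.
#'
#' @return validated [BreedingData-class] object.
#' @export
BreedingData <- function(phenotypes, relationship = NULL, markers = NULL,
                         traits = NULL) {
  if (is.data.frame(phenotypes)) {
    ids <- as.character(phenotypes[[1L]])
    phenotypes <- as.matrix(phenotypes[, -1L, drop = FALSE])
    rownames(phenotypes) <- ids
  }
  storage.mode(phenotypes) <- "double"
  reindex <- function(m, what) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    if (!is.null(rownames(m))) {
      miss <- setdiff(rownames(phenotypes), rownames(m))
      if (length(miss))
        stop(sprintf("%s rows missing for line(s): %s", what,
                     paste(utils::head(miss, 5L), collapse = ", ")))
      m <- m[rownames(phenotypes), , drop = FALSE]
      if (what == "relationship" && !is.null(colnames(m)))
        m <- m[, rownames(phenotypes), drop = FALSE]
    }
    m
  }
  if (is.null(traits)) {
    traits <- data.frame(trait = character(), direction = character(),
                         quantile = numeric(), fixed = numeric(),
                         stringsAsFactors = FALSE)
  }
  new("BreedingData", phenotypes = phenotypes,
      relationship = reindex(relationship, "relationship"),
      markers = reindex(markers, "markers"), traits = traits)
}

#' Load a phenotype/genotype bundle from CSV files
#'
#' Reads a phenotype table and a genotype object (marker matrix or
#' precomputed genomic relationship matrix) from comma-separated files with a
#' header row and the line identifier in the first column. Genotype rows are
#' matched to phenotype rows by identifier, never by file position. Missing
#' phenotype cells, duplicate identifiers, and dimension mismatches are
#' explicit errors naming the offending row/column.
#'
#' @param phenotypePath path to the phenotype CSV (`n` rows x `t` traits).
#' @param genotypePath path to the genotype CSV.
#' @param genotypeKind `"markers"` for an `n x p` marker matrix or `"grm"`
#'   for an `n x n` relationship matrix.
#' @param traits optional trait configuration ([traitConfig()]).
#'
#' @return a validated [BreedingData-class] object.
#'
#' @seealso [writeSelectionReport()]
#' @export
loadBundle <- function(phenotypePath, genotypePath,
                       genotypeKind = c("markers", "grm"), traits = NULL) {
  genotypeKind <- match.arg(genotypeKind)
  for (p in c(phenotypePath, genotypePath))
    if (!file.exists(p)) stop("file not found: ", p)
  ph <- read.csv(phenotypePath, check.names = FALSE)
  ids <- as.character(ph[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate line identifiers in phenotype file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  y <- as.matrix(ph[, -1L, drop = FALSE])
  storage.mode(y) <- "double"
  rownames(y) <- ids
  if (anyNA(y)) {
    idx <- which(is.na(y), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing phenotype at line '%s', trait '%s'",
                 ids[idx[1L]], colnames(y)[idx[2L]]))
  }
  gt <- read.csv(genotypePath, check.names = FALSE)
  gids <- as.character(gt[[1L]])
  if (anyDuplicated(gids))
    stop("duplicate line identifiers in genotype file")
  gm <- as.matrix(gt[, -1L, drop = FALSE])
  storage.mode(gm) <- "double"
  rownames(gm) <- gids
  if (nrow(gm) != nrow(y))
    stop(sprintf("dimension mismatch: %d phenotype lines but %d genotype rows",
                 nrow(y), nrow(gm)))
  if (genotypeKind == "grm") {
    if (ncol(gm) != nrow(gm))
      stop(sprintf("GRM must be square; got %d x %d", nrow(gm), ncol(gm)))
    BreedingData(y, relationship = gm, traits = traits)
  } else {
    BreedingData(y, markers = gm, traits = traits)
  }
}

#' Write a selection report to CSV
#'
#' Writes the ranked per-line per-loss results (line id, per-trait GEBV
#' posterior mean and posterior variance, raw and standardized PEL, rank,
#' selection flag) to a comma-separated file with a fixed header; values are
#' formatted at full double precision so a read-back reproduces the table.
#'
#' @param results a [SelectionReport-class] object or its `results`
#'   data.frame.
#' @param path output file path.
#' @return invisibly, the data.frame written.
#' @export
writeSelectionReport <- function(results, path) {
  if (is(results, "SelectionReport")) results <- results@results
  stopifnot(is.data.frame(results))
  write.csv(results, path, row.names = FALSE, quote = FALSE)
  invisible(results)
}
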