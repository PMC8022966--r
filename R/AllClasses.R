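setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' BreedingData: phenotypes plus genomic information for a set of lines
#'
#' Container for a single-cycle genomic-selection training set: one adjusted
#' phenotype record per line for `t` traits, together with either an
#' `n x n` genomic relationship matrix (GRM) or an `n x p` marker matrix from
#' which a GRM can be computed, and the per-trait improvement configuration
#' (direction of improvement and threshold rule).
#'
#' Validity requires complete phenotypes (missing records are rejected rather
#' than imputed), unique line identifiers, and a symmetric relationship matrix
#' with nonnegative diagonal whose rows are aligned to the phenotype rows.
#'
#' @slot phenotypes numeric matrix, `n` lines x `t` traits, with line
#'   identifiers as rownames and trait names as colnames.
#' @slot relationship `n x n` symmetric relationship matrix or `NULL`.
#' @slot markers `n x p` marker matrix or `NULL`.
#' @slot traits data.frame trait configuration (see [traitConfig()]).
#'
#' @seealso [BreedingData()], [loadBundle()], [computeGRM()]
#' @export
setClass("BreedingData",
  slots = c(phenotypes = "matrix",
            relationship = "matrixOrNULL",
            markers = "matrixOrNULL",
            traits = "data.frame"))

setValidity("BreedingData", function(object) {
  y <- object@phenotypes
  msgs <- character()
  if (!is.numeric(y)) msgs <- c(msgs, "phenotypes must be numeric")
  if (is.null(rownames(y))) msgs <- c(msgs, "phenotypes must have line ids as rownames")
  if (anyDuplicated(rownames(y)))
    msgs <- c(msgs, sprintf("duplicate line identifiers: %s",
      paste(unique(rownames(y)[duplicated(rownames(y))]), collapse = ", ")))
  if (anyNA(y)) {
    idx <- which(is.na(y), arr.ind = TRUE)[1L, ]
    msgs <- c(msgs, sprintf("missing phenotype at line '%s', trait '%s'",
      rownames(y)[idx[1L]], colnames(y)[idx[2L]]))
  }
  G <- object@relationship
  if (!is.null(G)) {
    if (nrow(G) != nrow(y))
      msgs <- c(msgs, sprintf(
        "relationship has %d rows but phenotypes have %d lines",
        nrow(G), nrow(y)))
    else {
      if (!.isSymmetric(G)) msgs <- c(msgs, "relationship must be symmetric")
      if (any(diag(G) < 0)) msgs <- c(msgs, "relationship diagonal must be >= 0")
    }
  }
  M <- object@markers
  if (!is.null(M) && nrow(M) != nrow(y))
    msgs <- c(msgs, sprintf("markers have %d rows but phenotypes have %d lines",
                            nrow(M), nrow(y)))
  if (nrow(object@traits) > 0 && nrow(object@traits) != ncol(y))
    msgs <- c(msgs, "trait configuration must have one row per trait")
  if (length(msgs)) msgs else TRUE
})

#' SimulationTruth: ground-truth parameters of a synthetic population
#'
#' Records the generating parameters of a simulated breeding population so
#' that parameter-recovery tests can compare posterior estimates against
#' truth: trait means, the genetic covariance among traits, per-trait
#' residual variances, the realized true genetic values, and the implied
#' narrow-sense heritabilities `h2[t] = sigmaG[t,t] / (sigmaG[t,t] + rDiag[t])`.
#'
#' @slot mu numeric `t`-vector of trait means.
#' @slot sigmaG `t x t` positive semi-definite genetic covariance matrix.
#' @slot rDiag numeric `t`-vector of residual variances (residual covariances
#'   are exactly zero by construction).
#' @slot g `n x t` matrix of true genetic values.
#' @slot h2 numeric `t`-vector of per-trait heritabilities in (0, 1).
#'
#' @seealso [simulatePopulation()], [makeFixture()]
#' @export
setClass("SimulationTruth",
  slots = c(mu = "numeric", sigmaG = "matrix", rDiag = "numeric",
            g = "matrix", h2 = "numeric"))

setValidity("SimulationTruth", function(object) {
  t <- length(object@mu)
  msgs <- character()
  if (!all(dim(object@sigmaG) == t)) msgs <- c(msgs, "sigmaG must be t x t")
  if (!.isSymmetric(object@sigmaG)) msgs <- c(msgs, "sigmaG must be symmetric")
  else if (min(eigen(object@sigmaG, symmetric = TRUE,
                     only.values = TRUE)$values) < -1e-8 * max(diag(object@sigmaG)))
    msgs <- c(msgs, "sigmaG must be positive semi-definite")
  if (length(object@rDiag) != t || any(object@rDiag <= 0))
    msgs <- c(msgs, "rDiag must be a positive t-vector")
  if (ncol(object@g) != t) msgs <- c(msgs, "g must have t columns")
  if (length(object@h2) != t || any(object@h2 <= 0) || any(object@h2 >= 1))
    msgs <- c(msgs, "h2 must lie strictly inside (0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' PosteriorChain: MCMC draws from the multi-trait GBLUP model
#'
#' Holds the retained Gibbs draws of the multi-trait genomic mixed model:
#' trait intercepts, the genetic covariance among traits, per-trait residual
#' variances, and per-line genetic values, together with posterior summaries
#' of the genomic estimated breeding values (GEBVs) and the eigendecomposition
#' of the relationship matrix used during sampling.
#'
#' @slot mu `k x t` matrix of intercept draws (`k` retained draws).
#' @slot sigmaG `t x t x k` array of genetic covariance draws.
#' @slot rDiag `k x t` matrix of residual variance draws.
#' @slot g `n x t x k` array of genetic value draws.
#' @slot gebvMean `n x t` posterior means of genetic values (the GEBVs).
#' @slot gebvVar `n x t` posterior variances of genetic values.
#' @slot lineIds character vector of line identifiers.
#' @slot traitNames character vector of trait names.
#' @slot eigenG list with components `values`, `vectors`: eigendecomposition
#'   of the (jittered) relationship matrix.
#' @slot control list echoing the MCMC settings and seed used.
#'
#' @seealso [fitMTM()], [predictiveComponents()], [computePEL()]
#' @export
setClass("PosteriorChain",
  slots = c(mu = "matrix", sigmaG = "array", rDiag = "matrix", g = "array",
            gebvMean = "matrix", gebvVar = "matrix",
            lineIds = "character", traitNames = "character",
            eigenG = "list", control = "list"))

setValidity("PosteriorChain", function(object) {
  k <- nrow(object@mu); t <- ncol(object@mu); n <- length(object@lineIds)
  msgs <- character()
  if (!all(dim(object@sigmaG) == c(t, t, k)))
    msgs <- c(msgs, "sigmaG must be t x t x k")
  if (!all(dim(object@rDiag) == c(k, t)))
    msgs <- c(msgs, "rDiag must be k x t")
  if (!all(dim(object@g) == c(n, t, k)))
    msgs <- c(msgs, "g must be n x t x k")
  if (!all(dim(object@gebvMean) == c(n, t)) ||
      !all(dim(object@gebvVar) == c(n, t)))
    msgs <- c(msgs, "GEBV summaries must be n x t")
  if (length(object@traitNames) != t)
    msgs <- c(msgs, "traitNames must have length t")
  if (any(object@rDiag <= 0))
    msgs <- c(msgs, "all residual variance draws must be positive")
  if (length(msgs)) msgs else TRUE
})

#' ParentalDistribution: truncated-MVN distribution of selected parents
#'
#' The theoretical distribution of selected parents: a multivariate normal
#' base population `MVN(mu1, P)` truncated to the upper orthant above the
#' threshold vector `yc` (all traits on the increasing-improvement scale).
#' Stores the upper-orthant probability `z = Pr(Y > yc)`, the truncated mean
#' `muS`, and the selection differential `S = muS - mu1`.
#'
#' @slot mu1 numeric `t`-vector, base-population mean.
#' @slot P `t x t` phenotypic covariance matrix.
#' @slot yc numeric `t`-vector of truncation thresholds (may be `-Inf`).
#' @slot z scalar in (0, 1], upper-orthant probability.
#' @slot muS numeric `t`-vector, mean of the truncated distribution.
#' @slot S numeric `t`-vector, selection differential `muS - mu1`.
#' @slot muS_se numeric `t`-vector, Monte-Carlo standard error of `muS`.
#'
#' @seealso [parentalDistribution()], [klMultivariate()]
#' @export
setClass("ParentalDistribution",
  slots = c(mu1 = "numeric", P = "matrix", yc = "numeric", z = "numeric",
            muS = "numeric", S = "numeric", muS_se = "numeric"))

setValidity("ParentalDistribution", function(object) {
  t <- length(object@mu1)
  msgs <- character()
  if (!all(dim(object@P) == t)) msgs <- c(msgs, "P must be t x t")
  if (length(object@yc) != t) msgs <- c(msgs, "yc must have length t")
  if (length(object@z) != 1L || object@z <= 0 || object@z > 1)
    msgs <- c(msgs, "z must be a scalar in (0, 1]")
  if (length(object@muS) != t || length(object@S) != t)
    msgs <- c(msgs, "muS and S must have length t")
  if (max(abs(object@S - (object@muS - object@mu1))) > 1e-8)
    msgs <- c(msgs, "S must equal muS - mu1")
  if (length(msgs)) msgs else TRUE
})

#' SelectionReport: ranked posterior-expected-loss results
#'
#' Full output of a selection run: the per-line per-loss table of raw and
#' standardized posterior expected loss (PEL) with ranks and selection flags,
#' the pairwise percentage overlap of the selected sets between loss
#' functions, and a top/bottom summary in the style of a selection table.
#'
#' @slot results data.frame with one row per line per loss function.
#' @slot overlap numeric matrix of pairwise selected-set overlap percentages.
#' @slot topBottom data.frame top-k/bottom-k summary per loss.
#' @slot intensity scalar selected fraction.
#'
#' @seealso [selectParents()], [writeSelectionReport()]
#' @export
setClass("SelectionReport",
  slots = c(results = "data.frame", overlap = "matrix",
            topBottom = "data.frame", intensity = "numeric"))
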