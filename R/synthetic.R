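#' Simulate a biallelic marker matrix
#'
#' Draws an `n x p` dosage matrix with entries in \{0, 1, 2\}: each marker's
#' minor-allele frequency is sampled uniformly from `mafRange` and line
#' dosages are binomial(2, maf). Columns that come out monomorphic are
#' resampled so the matrix can always be centered and standardized.
#'
#' @param n number of lines (>= 2).
#' @param p number of markers (>= 1).
#' @param mafRange length-2 interval inside (0, 0.5] for the allele
#'   frequency; a degenerate interval fixes the frequency.
#' @param seed optional integer RNG seed.
#' @return `n x p` integer dosage matrix with line ids `L1..Ln` as rownames.
#' @export
simulateMarkers <- function(n, p, mafRange = c(0.05, 0.5), seed = NULL) {
  stopifnot(n >= 2L, p >= 1L, length(mafRange) == 2L)
  if (mafRange[1] > mafRange[2] || mafRange[1] <= 0 || mafRange[2] > 0.5)
    stop("mafRange must be an interval inside (0, 0.5]")
  .seedIfGiven(seed)
  M <- matrix(0L, n, p)
  for (j in seq_len(p)) {
    repeat {
      maf <- runif(1L, mafRange[1], mafRange[2])
      col <- rbinom(n, 2L, maf)
      if (length(unique(col)) > 1L) break
    }
    M[, j] <- col
  }
  dimnames(M) <- list(paste0("L", seq_len(n)), paste0("M", seq_len(p)))
  M
}

#' Factor a relationship matrix for matrix-normal sampling
#' (diagonal shortcut avoids a dense Cholesky for grm = I)
#' @noRd
.grmFactor <- function(grm) {
  offdiag <- grm
  diag(offdiag) <- 0
  if (all(offdiag == 0)) {
    if (any(diag(grm) < 0)) stop("relationship diagonal must be >= 0")
    return(list(kind = "diag", d = sqrt(diag(grm))))
  }
  list(kind = "chol", L = .cholLower(grm, label = "relationship matrix"))
}

#' Simulate multi-trait phenotypes over a relationship matrix
#'
#' Draws true genetic values from the matrix normal with row covariance
#' `grm` and column covariance `sigmaG` (so `vec(g) ~ MVN(0, sigmaG x grm)`
#' in Kronecker form), adds independent residuals with per-trait variances
#' `rDiag` and zero residual covariances, and returns phenotypes
#' `y = mu + g + e` together with the generating truth. Non-PSD relationship
#' matrices are repaired with the smallest jitter that makes the Cholesky
#' factorization succeed (logged via `message`).
#'
#' @param grm `n x n` positive semi-definite relationship matrix.
#' @param mu numeric `t`-vector of trait means.
#' @param sigmaG `t x t` PSD genetic covariance matrix.
#' @param rDiag numeric `t`-vector of positive residual variances.
#' @param seed optional integer RNG seed.
#'
#' @return list with `phenotypes` (`n x t` matrix, line ids as rownames) and
#'   `truth` (a [SimulationTruth-class] object).
#' @export
simulatePopulation <- function(grm, mu, sigmaG, rDiag, seed = NULL) {
  t <- length(mu)
  sigmaG <- as.matrix(sigmaG)
  stopifnot(all(dim(sigmaG) == t), length(rDiag) == t, all(rDiag >= 0))
  if (!.isSymmetric(sigmaG)) stop("sigmaG must be symmetric")
  ev <- eigen(sigmaG, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) stop("sigmaG must be positive semi-definite")
  n <- nrow(grm)
  .seedIfGiven(seed)
  fac <- .grmFactor(as.matrix(grm))
  Ls <- .cholLower(sigmaG, label = "sigmaG")
  Z <- matrix(rnorm(n * t), n, t)
  g <- switch(fac$kind,
    diag = (fac$d * Z) %*% t(Ls),
    chol = fac$L %*% Z %*% t(Ls))
  eps <- matrix(rnorm(n * t), n, t) %*% diag(sqrt(rDiag), t)
  y <- sweep(g + eps, 2L, mu, "+")
  ids <- rownames(grm)
  if (is.null(ids)) ids <- paste0("L", seq_len(n))
  dimnames(y) <- list(ids, names(mu))
  dimnames(g) <- dimnames(y)
  h2 <- diag(sigmaG) / (diag(sigmaG) + rDiag)
  truth <- new("SimulationTruth", mu = mu, sigmaG = sigmaG,
               rDiag = as.numeric(rDiag), g = g, h2 = as.numeric(h2))
  list(phenotypes = y, truth = truth)
}

#' Built-in synthetic fixtures
#'
#' Deterministic seeded populations sized so the full pipeline runs in
#' seconds to minutes:
#' \describe{
#'   \item{`tiny`}{n = 12 lines, 2 traits; for unit tests.}
#'   \item{`dataset1_like`}{n = 200 lines, 4 traits on the scale of an elite
#'     wheat trial (days to heading, days to maturity, plant height, grain
#'     yield): one strongly genetically correlated trait pair (0.8), mixed
#'     improvement directions (three decreasing, one increasing) with 0.1 /
#'     0.9 quantile threshold rules.}
#'   \item{`dataset2_like`}{n = 160 lines, 4 traits in the style of a
#'     biofortification panel (yield, kernel weight, grain Zn and Fe): weak
#'     all-positive genetic correlations, all directions increasing, all
#'     thresholds at the 0.9 quantile.}
#' }
#' The genomic relationship matrix is built from simulated markers via
#' [centerScaleMarkers()] and [computeGRM()].
#'
#' @param name fixture name.
#' @param seed integer seed; each fixture has a fixed default so repeated
#'   calls are bitwise identical.
#' @return list with `bundle` (a [BreedingData-class]) and `truth`
#'   (a [SimulationTruth-class]).
#' @export
makeFixture <- function(name = c("tiny", "dataset1_like", "dataset2_like"),
                        seed = NULL) {
  name <- match.arg(name)
  corrToCov <- function(sd, R) diag(sd) %*% R %*% diag(sd)
  spec <- switch(name,
    tiny = {
      list(seed = 101L, n = 12L, p = 60L,
           mu = c(T1 = 10, T2 = 50),
           R = matrix(c(1, 0.5, 0.5, 1), 2),
           gsd = c(1, 2), h2 = c(0.5, 0.5),
           traits = traitConfig(c("T1", "T2"), "increase", quantile = 0.75))
    },
    dataset1_like = {
      R <- diag(4)
      R[1, 2] <- R[2, 1] <- 0.8   # heading/maturity pair
      R[1, 3] <- R[3, 1] <- 0.2
      R[2, 3] <- R[3, 2] <- 0.15
      R[3, 4] <- R[4, 3] <- 0.25
      R[1, 4] <- R[4, 1] <- 0.05
      R[2, 4] <- R[4, 2] <- -0.05
      list(seed = 202L, n = 200L, p = 600L,
           mu = c(DTHD = 80, DTMT = 120, Height = 103, GY = 6.3),
           R = R, gsd = sqrt(c(0.7 * 9, 0.7 * 10, 0.6 * 22, 0.4 * 0.3)),
           h2 = c(0.7, 0.7, 0.6, 0.4),
           traits = traitConfig(c("DTHD", "DTMT", "Height", "GY"),
                                c("decrease", "decrease", "decrease",
                                  "increase"),
                                quantile = c(0.1, 0.1, 0.1, 0.9)))
    },
    dataset2_like = {
      R <- diag(4)
      R[1, 2] <- R[2, 1] <- 0.2
      R[2, 4] <- R[4, 2] <- 0.16
      R[3, 4] <- R[4, 3] <- 0.26
      R[1, 3] <- R[3, 1] <- 0.05
      R[2, 3] <- R[3, 2] <- 0.05
      R[1, 4] <- R[4, 1] <- 0.05
      list(seed = 303L, n = 160L, p = 600L,
           mu = c(GY = 5.3, TKW = 33.1, GZnC = 28.1, GFeC = 38.6),
           R = R, gsd = sqrt(c(0.4 * 0.3, 0.5 * 12, 0.5 * 10, 0.5 * 11)),
           h2 = c(0.4, 0.5, 0.5, 0.5),
           traits = traitConfig(c("GY", "TKW", "GZnC", "GFeC"), "increase",
                                quantile = 0.9))
    })
  if (is.null(seed)) seed <- spec$seed
  sigmaG <- corrToCov(spec$gsd, spec$R)
  dimnames(sigmaG) <- list(names(spec$mu), names(spec$mu))
  rDiag <- diag(sigmaG) * (1 - spec$h2) / spec$h2
  M <- simulateMarkers(spec$n, spec$p, seed = seed)
  G <- computeGRM(centerScaleMarkers(M))
  sim <- simulatePopulation(G, spec$mu, sigmaG, rDiag, seed = seed + 1L)
  bundle <- BreedingData(sim$phenotypes, relationship = G, markers = M,
                         traits = spec$traits)
  list(bundle = bundle, truth = sim$truth)
}
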