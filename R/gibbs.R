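#' MCMC settings for the multi-trait GBLUP sampler
#'
#' @param nBurn burn-in sweeps discarded before storage (>= 1).
#' @param nKept number of retained draws (>= 1).
#' @param thin keep every `thin`-th post-burn-in sweep (>= 1). A production
#'   analysis typically uses a long schedule (e.g. 30000 burn-in and 10000
#'   retained draws at lag 5); the defaults here are sized for interactive
#'   work and must be scaled up for final inference.
#' @param seed integer RNG seed; chains are bitwise reproducible given the
#'   seed.
#' @param priorSigmaG inverse-Wishart prior for the genetic covariance,
#'   a list `list(df=, scale=)` with `df > t - 1`. Default (set at fit time):
#'   `df = t + 2`, `scale = diag(0.5 * phenotypic variances)` — weakly
#'   informative, centered on a 50/50 split of the phenotypic variance.
#' @param priorResid scaled-inverse-chi-square prior for each residual
#'   variance, `list(df=, scale=)` with scalar or per-trait entries. Default
#'   at fit time: `df = 4`, `scale = 0.5 * phenotypic variance`.
#' @param fixSigmaG optional `t x t` matrix: clamp the genetic covariance at
#'   this value (degenerate prior; no update). Used for oracle checks.
#' @param fixRDiag optional `t`-vector: clamp the residual variances.
#' @param verbose emit per-stage progress lines to standard error.
#' @return list of class `mcmc_control`.
#' @export
mcmcControl <- function(nBurn = 1000L, nKept = 1000L, thin = 5L, seed = 1L,
                        priorSigmaG = NULL, priorResid = NULL,
                        fixSigmaG = NULL, fixRDiag = NULL, verbose = FALSE) {
  stopifnot(nBurn >= 1L, nKept >= 1L, thin >= 1L)
  structure(list(nBurn = as.integer(nBurn), nKept = as.integer(nKept),
                 thin = as.integer(thin), seed = as.integer(seed),
                 priorSigmaG = priorSigmaG, priorResid = priorResid,
                 fixSigmaG = fixSigmaG, fixRDiag = fixRDiag,
                 verbose = isTRUE(verbose)),
            class = "mcmc_control")
}

#' Fit the multi-trait genomic mixed model by Gibbs sampling
#'
#' Samples the posterior of the multi-trait GBLUP model
#' `y_t = 1 mu_t + g_t + e_t` with `vec(g) ~ MVN(0, sigmaG x G)`
#' (Kronecker), `G` the genomic relationship matrix, and independent
#' residuals `e_t ~ MVN(0, sigma2_et I)` (diagonal residual covariance; one
#' record per line, so the random-effect design matrices are identities).
#'
#' Full conditionals: intercepts are normal (flat prior); genetic values are
#' sampled jointly per eigen-component of `G` (the one-time eigendecomposition
#' turns the `n`-dimensional update into `n` independent `t`-variate normals,
#' vectorized via a simultaneous diagonalization of `sigmaG` against the
#' residual covariance); `sigmaG` is inverse-Wishart; each residual variance
#' is scaled-inverse-chi-square. Eigenvalues of `G` are floored at a small
#' positive jitter to keep the prior proper.
#'
#' @param bundle a [BreedingData-class] with a relationship matrix (use
#'   [computeGRM()] first if only markers are available).
#' @param control an [mcmcControl()] list.
#' @return a [PosteriorChain-class] with retained draws and GEBV summaries.
#'
#' @examples
#' fx <- makeFixture("tiny")
#' ch <- fitMTM(fx$bundle, mcmcControl(nBurn = 50, nKept = 50, thin = 1))
#' gebv(ch)[1:3, ]
#' @export
fitMTM <- function(bundle, control = mcmcControl()) {
  stopifnot(is(bundle, "BreedingData"), inherits(control, "mcmc_control"))
  y <- phenotypes(bundle)
  G <- relationship(bundle)
  if (is.null(G)) {
    if (is.null(markers(bundle)))
      stop("bundle has neither a relationship matrix nor markers")
    G <- computeGRM(centerScaleMarkers(markers(bundle)))
  }
  n <- nrow(y); t <- ncol(y)
  if (is.null(colnames(y))) colnames(y) <- paste0("T", seq_len(t))
  if (is.null(rownames(y))) rownames(y) <- paste0("L", seq_len(n))
  vy <- pmax(apply(y, 2L, var), 1e-8)   # guard: constant-trait degenerate case

  prG <- control$priorSigmaG
  if (is.null(prG)) prG <- list(df = t + 2, scale = diag(0.5 * vy, t))
  if (prG$df <= t - 1) stop("priorSigmaG$df must exceed t - 1")
  prR <- control$priorResid
  if (is.null(prR)) prR <- list(df = 4, scale = 0.5 * vy)
  prR$scale <- rep_len(prR$scale, t)
  fixG <- control$fixSigmaG
  fixR <- control$fixRDiag

  eg <- eigen(.symmetrize(G), symmetric = TRUE)
  lam <- pmax(eg$values, 1e-8)
  U <- eg$vectors

  set.seed(control$seed)
  mu <- colMeans(y)
  sigmaG <- if (is.null(fixG)) diag(0.5 * vy, t) else as.matrix(fixG)
  rDiag <- if (is.null(fixR)) 0.5 * vy else rep_len(fixR, t)
  A <- matrix(0, n, t)   # genetic values in the eigenbasis of G
  g <- matrix(0, n, t)

  nSweep <- control$nBurn + control$nKept * control$thin
  keepAt <- control$nBurn + seq_len(control$nKept) * control$thin
  muS <- matrix(NA_real_, control$nKept, t)
  sgS <- array(NA_real_, c(t, t, control$nKept))
  rdS <- matrix(NA_real_, control$nKept, t)
  gS <- array(NA_real_, c(n, t, control$nKept))
  kept <- 0L
  t0 <- Sys.time()

  for (it in seq_len(nSweep)) {
    ## genetic values: rows of A are independent t-variate normals
    c_inv_sd <- 1 / sqrt(rDiag)                    # R^{-1/2} (diagonal)
    M <- sigmaG * tcrossprod(c_inv_sd)             # R^-1/2 SigmaG R^-1/2
    em <- eigen(.symmetrize(M), symmetric = TRUE)
    d <- pmax(em$values, 0)
    V <- em$vectors
    ytil <- crossprod(U, sweep(y, 2L, mu, "-"))    # U'(y - 1 mu')
    W <- (ytil * rep(c_inv_sd, each = n)) %*% V    # V' C ytilde_i, rows
    K <- outer(lam, d, function(l, dd) l * dd / (1 + l * dd))
    X <- K * W + sqrt(K) * matrix(rnorm(n * t), n, t)
    A <- (X %*% t(V)) * rep(sqrt(rDiag), each = n) # back to trait scale
    g <- U %*% A

    ## intercepts (flat prior)
    resid0 <- y - g
    mu <- colMeans(resid0) + rnorm(t) * sqrt(rDiag / n)

    ## genetic covariance | A : inverse-Wishart
    if (is.null(fixG)) {
      Sa <- crossprod(A, A / lam)
      Spost <- .symmetrize(prG$scale + Sa)
      Wdraw <- rWishart(1L, prG$df + n, solve(Spost))[, , 1L]
      sigmaG <- .symmetrize(solve(Wdraw))
    }

    ## residual variances | rest : scaled-inverse-chi-square
    if (is.null(fixR)) {
      sse <- colSums(sweep(resid0, 2L, mu, "-")^2)
      rDiag <- (prR$df * prR$scale + sse) / rchisq(t, prR$df + n)
    }
    if (!all(is.finite(mu)) || !all(is.finite(sigmaG)) ||
        !all(is.finite(rDiag)))
      stop("divergent draw at sweep ", it)

    if (kept < control$nKept && it == keepAt[kept + 1L]) {
      kept <- kept + 1L
      muS[kept, ] <- mu
      sgS[, , kept] <- sigmaG
      rdS[kept, ] <- rDiag
      gS[, , kept] <- g
    }
    if (control$verbose && it %% max(1L, nSweep %/% 10L) == 0L)
      message(sprintf("sweep %d/%d (%d draws kept, %.1fs elapsed)",
                      it, nSweep, kept,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  gebvMean <- apply(gS, c(1L, 2L), mean)
  gebvVar <- apply(gS, c(1L, 2L), var)
  dimnames(gebvMean) <- dimnames(gebvVar) <- dimnames(y)
  new("PosteriorChain", mu = muS, sigmaG = sgS, rDiag = rdS, g = gS,
      gebvMean = gebvMean, gebvVar = gebvVar,
      lineIds = rownames(y), traitNames = colnames(y),
      eigenG = list(values = lam, vectors = U),
      control = unclass(control))
}

#' Exact multi-trait BLUP for fixed variance components
#'
#' Solves the multi-trait mixed-model equations exactly for given genetic
#' covariance and residual variances, by generalized least squares on the
#' stacked system: `V = sigmaG x G + R x I`, intercepts by GLS, genetic
#' values by the BLUP identity `ghat = (sigmaG x G) V^{-1} (y - X muhat)`.
#' Dense `nt x nt` algebra — intended for moderate `n` and as the
#' independent oracle against which the Gibbs sampler is validated.
#'
#' @param bundle a [BreedingData-class] with a relationship matrix.
#' @param sigmaG `t x t` genetic covariance matrix.
#' @param rDiag `t`-vector of residual variances.
#' @return `n x t` matrix of BLUP genetic values.
#' @export
gblupFixedVariance <- function(bundle, sigmaG, rDiag) {
  y <- phenotypes(bundle)
  G <- relationship(bundle)
  if (is.null(G)) stop("bundle must carry a relationship matrix")
  n <- nrow(y); t <- ncol(y)
  sigmaG <- as.matrix(sigmaG)
  stopifnot(all(dim(sigmaG) == t), length(rDiag) == t)
  Gs <- .symmetrize(as.matrix(G))
  Vg <- kronecker(sigmaG, Gs)
  V <- Vg + kronecker(diag(as.numeric(rDiag), t), diag(n))
  X <- kronecker(diag(t), matrix(1, n, 1))
  yv <- as.numeric(y)                      # trait-major stacking
  Vi <- tryCatch(solve(V), error = function(e)
    stop("singular mixed-model system: ", conditionMessage(e)))
  XtVi <- crossprod(X, Vi)
  muhat <- solve(XtVi %*% X, XtVi %*% yv)
  ghat <- Vg %*% Vi %*% (yv - X %*% muhat)
  out <- matrix(ghat, n, t)
  dimnames(out) <- dimnames(y)
  out
}

#' Posterior-predictive components for one candidate line at one draw
#'
#' For retained draw `k` and candidate line `o`, returns the mean and
#' covariance of the line's multivariate-normal posterior predictive:
#' `m_o = mu^(k) + g_o^(k)` and, by default, the phenotypic covariance
#' `P^(k) = sigmaG^(k) + diag(rDiag^(k))` (the candidate's offspring share
#' the base population's phenotypic covariance). `type = "genetic"` returns
#' the genetic covariance only.
#'
#' @param chain a [PosteriorChain-class].
#' @param k draw index in `1..nDraws(chain)`.
#' @param o line index or line identifier.
#' @param type covariance to return: `"phenotypic"` (default) or
#'   `"genetic"`.
#' @return list with `mean` (`t`-vector) and `cov` (`t x t` matrix).
#' @export
predictiveComponents <- function(chain, k, o,
                                 type = c("phenotypic", "genetic")) {
  type <- match.arg(type)
  stopifnot(is(chain, "PosteriorChain"))
  if (is.character(o)) o <- match(o, lineIds(chain))
  stopifnot(!is.na(o), o >= 1L, o <= nLines(chain))
  dr <- chainDraw(chain, k)
  P <- as.matrix(dr$sigmaG)
  if (type == "phenotypic") P <- P + diag(dr$rDiag, nTraits(chain))
  gk <- matrix(dr$g, nLines(chain), nTraits(chain))
  list(mean = dr$mu + gk[o, ], cov = .symmetrize(P))
}
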