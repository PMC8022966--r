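#' Mean of an upper-truncated normal distribution
#'
#' Returns `E[Y | Y > yc]` for `Y ~ N(mu1, sigma^2)`:
#' `mu1 + sigma * phi(a) / (1 - Phi(a))` with `a = (yc - mu1)/sigma`. The
#' Mills ratio is evaluated on the log scale
#' (`exp(log phi(a) - log Phi^c(a))`), which stays accurate far into the
#' tail (a >> 8) where the direct ratio underflows.
#'
#' @param mu1 mean of the untruncated normal.
#' @param sigma standard deviation (> 0).
#' @param yc truncation point; `-Inf` means no truncation.
#' @return scalar (vectorized over inputs) truncated mean.
#' @export
truncatedNormalMean <- function(mu1, sigma, yc) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  a <- (yc - mu1) / sigma
  mills <- ifelse(is.infinite(a) & a < 0, 0,
                  exp(dnorm(a, log = TRUE) -
                      pnorm(a, lower.tail = FALSE, log.p = TRUE)))
  mu1 + sigma * mills
}

#' Single-trait truncation-selection summary
#'
#' Collects the quantities of univariate truncation selection at threshold
#' `yc`: the truncated parental mean `muS`, selection differential
#' `S = muS - mu1`, selection intensity `i = S / sigma`, response to
#' selection `R = h2 * S`, and the selected fraction `Pr(y > yc)`.
#'
#' @param mu1 base-population mean.
#' @param sigma2 phenotypic variance (> 0).
#' @param yc truncation threshold.
#' @param h2 narrow-sense heritability in \[0, 1\].
#' @return list of class `univariate_selection` with fields `mu1`, `sigma2`,
#'   `yc`, `h2`, `muS`, `S`, `i`, `R`, `Pr`.
#' @seealso [klUnivariate()]
#' @export
univariateSelection <- function(mu1, sigma2, yc, h2) {
  stopifnot(sigma2 > 0, h2 >= 0, h2 <= 1)
  sigma <- sqrt(sigma2)
  Pr <- pnorm(yc, mean = mu1, sd = sigma, lower.tail = FALSE)
  muS <- truncatedNormalMean(mu1, sigma, yc)
  S <- muS - mu1
  structure(list(mu1 = mu1, sigma2 = sigma2, yc = yc, h2 = h2,
                 muS = muS, S = S, i = S / sigma, R = h2 * S, Pr = Pr),
            class = "univariate_selection")
}

#' Univariate Kullback-Leibler selection loss
#'
#' KL divergence between the truncated parental distribution
#' `NT(mu1, sigma2, yc)` and the candidate/offspring distribution
#' `N(mu2, sigma2)` with `mu2 = mu1 + R`. Two algebraically equivalent
#' forms are available: `"response"` evaluates
#' `log(1/Pr) + ((S - R)^2/sigma2 - i^2)/2`, and `"heritability"` evaluates
#' `log(1/Pr) + i^2 * h2 * (h2 - 2)/2`; they agree to machine precision and
#' the loss is a decreasing function of `h2` at fixed selection intensity.
#'
#' @param sel a [univariateSelection()] object.
#' @param form which algebraic form to evaluate.
#' @return scalar nonnegative divergence.
#' @export
klUnivariate <- function(sel, form = c("response", "heritability")) {
  form <- match.arg(form)
  stopifnot(inherits(sel, "univariate_selection"))
  if (sel$Pr <= 0)
    stop("selected fraction is numerically zero; relax the threshold yc")
  switch(form,
    response = log(1 / sel$Pr) +
      0.5 * ((sel$S - sel$R)^2 / sel$sigma2 - sel$i^2),
    heritability = log(1 / sel$Pr) +
      0.5 * sel$i^2 * sel$h2 * (sel$h2 - 2))
}

#' Upper-orthant probability of a multivariate normal
#'
#' `z = Pr(Y > yc componentwise)` for `Y ~ MVN(mu, P)`, by a deterministic
#' rectangle-probability routine (Miwa's recursive integration as provided
#' by \pkg{mvtnorm}; absolute accuracy around 1e-6 at the default grid).
#' `-Inf` thresholds drop the corresponding coordinate from the integral.
#'
#' @param mu `t`-vector mean.
#' @param P `t x t` positive-definite covariance.
#' @param yc `t`-vector of lower bounds (entries may be `-Inf`).
#' @param steps Miwa grid size.
#' @return scalar probability in \[0, 1\].
#' @export
mvnUpperOrthant <- function(mu, P, yc, steps = 128L) {
  t <- length(mu)
  P <- .symmetrize(as.matrix(P))
  stopifnot(all(dim(P) == t), length(yc) == t)
  active <- is.finite(yc)
  if (!any(active)) return(1)
  mu <- mu[active]; yc <- yc[active]
  P <- P[active, active, drop = FALSE]
  if (length(mu) == 1L)
    return(unname(pnorm(yc, mu, sqrt(P[1L, 1L]), lower.tail = FALSE)))
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("P must be positive definite on the active traits")
  p <- mvtnorm::pmvnorm(lower = yc, upper = rep(Inf, length(yc)), mean = mu,
                        sigma = P, algorithm = mvtnorm::Miwa(steps = steps))
  p <- min(max(as.numeric(p), 0), 1)
  if (p < 1e-5) {
    # below Miwa's absolute accuracy: refine with a quasi-Monte-Carlo
    # evaluation under a fixed internal seed (relative-error criterion),
    # leaving the caller's RNG stream untouched
    seedExists <- exists(".Random.seed", envir = globalenv())
    if (seedExists) oldSeed <- get(".Random.seed", envir = globalenv())
    set.seed(20210120L)
    p2 <- mvtnorm::pmvnorm(lower = yc, upper = rep(Inf, length(yc)),
                           mean = mu, sigma = P,
                           algorithm = mvtnorm::GenzBretz(
                             maxpts = 100000L, abseps = 0, releps = 1e-3))
    if (seedExists) assign(".Random.seed", oldSeed, envir = globalenv())
    p <- min(max(as.numeric(p2), .Machine$double.xmin), 1)
  }
  p
}

#' Sample from an upper-truncated multivariate normal
#'
#' Draws from `MVN(mu1, P)` restricted to `y > yc` componentwise. Uses plain
#' rejection sampling when the acceptance probability (the orthant mass `z`)
#' is at least `gibbsBelow`, otherwise a coordinate-wise Gibbs sampler with
#' `burn` warm-up sweeps started from a point inside the orthant; univariate
#' truncated-normal conditionals are drawn by tail-stable inverse-CDF.
#'
#' @param n number of samples.
#' @param mu1 `t`-vector mean.
#' @param P `t x t` positive-definite covariance.
#' @param yc `t`-vector of lower truncation bounds (may be `-Inf`).
#' @param seed optional integer seed.
#' @param gibbsBelow acceptance threshold under which the Gibbs sampler is
#'   used (default 1%).
#' @param burn Gibbs warm-up sweeps.
#' @return `n x t` matrix of samples, all rows satisfying `y >= yc`.
#' @export
rTruncatedMVN <- function(n, mu1, P, yc, seed = NULL, gibbsBelow = 0.01,
                          burn = 50L) {
  t <- length(mu1)
  P <- .symmetrize(as.matrix(P))
  stopifnot(all(dim(P) == t), length(yc) == t, n >= 1L)
  .seedIfGiven(seed)
  z <- mvnUpperOrthant(mu1, P, yc)
  if (z >= gibbsBelow) {
    L <- .cholLower(P, label = "P")
    out <- matrix(NA_real_, n, t)
    got <- 0L
    while (got < n) {
      m <- min(1e6, max(100L, ceiling((n - got) / max(z, 1e-3))))
      cand <- sweep(matrix(rnorm(m * t), m, t) %*% t(L), 2L, mu1, "+")
      keep <- which(rowSums(sweep(cand, 2L, yc, ">=")) == t)
      if (length(keep)) {
        take <- utils::head(keep, n - got)
        out[got + seq_along(take), ] <- cand[take, , drop = FALSE]
        got <- got + length(take)
      }
    }
    return(out)
  }
  ## Gibbs path: conditional regressions from the precision matrix
  Q <- solve(P)
  condSd <- 1 / sqrt(diag(Q))
  cur <- pmax(mu1, yc + condSd)     # strictly inside the orthant
  cur[!is.finite(yc)] <- mu1[!is.finite(yc)]
  out <- matrix(NA_real_, n, t)
  rTailNorm <- function(m, s, lo) {
    if (!is.finite(lo)) return(rnorm(1L, m, s))
    ptail <- pnorm(lo, m, s, lower.tail = FALSE)
    u <- runif(1L) * ptail
    m + s * qnorm(u, lower.tail = FALSE)
  }
  for (sweepIdx in seq_len(burn + n)) {
    for (j in seq_len(t)) {
      delta <- cur - mu1
      mj <- mu1[j] - sum(Q[j, -j] * delta[-j]) / Q[j, j]
      cur[j] <- rTailNorm(mj, condSd[j], yc[j])
      if (!is.finite(cur[j])) cur[j] <- max(yc[j], mj)
    }
    if (sweepIdx > burn) out[sweepIdx - burn, ] <- cur
  }
  out
}

#' Moments of the truncated parental distribution
#'
#' Mean `muS` of `TMVN(mu1, P, yc)` and the orthant probability `z`. The
#' default `"analytic"` method evaluates the deterministic first-moment
#' identity for orthant-truncated normals,
#' `muS = mu1 + P q / z` with
#' `q_k = phi(yc_k; mu_k, P_kk) * Pr(Y_{-k} > yc_{-k} | Y_k = yc_k)`
#' (each conditional orthant probability computed by the deterministic
#' rectangle routine), so `muS` carries no Monte-Carlo noise. `"mc"`
#' estimates `muS` as the mean of seeded truncated-MVN samples and reports
#' its standard error (ignoring Gibbs autocorrelation, which is mild for
#' the weakly correlated covariances arising here); it serves as an
#' independent cross-check of the analytic route.
#'
#' @inheritParams rTruncatedMVN
#' @param mcDraws number of samples for the `"mc"` method.
#' @param method `"analytic"` (deterministic) or `"mc"` (sampling).
#' @return list with `muS` (`t`-vector), `z` (scalar), `se` (`t`-vector,
#'   zero for the analytic method).
#' @export
truncatedMVNMoments <- function(mu1, P, yc, mcDraws = 2000L, seed = NULL,
                                method = c("analytic", "mc")) {
  method <- match.arg(method)
  t <- length(mu1)
  P <- .symmetrize(as.matrix(P))
  z <- mvnUpperOrthant(mu1, P, yc)
  if (all(!is.finite(yc)))
    return(list(muS = mu1, z = 1, se = rep(0, t)))
  if (z < 1e-10) {
    # extreme truncation: the distribution concentrates at the orthant
    # vertex; take muS = yc on the truncated traits and the conditional
    # mean at that vertex on the unconstrained ones
    act <- is.finite(yc)
    muS <- mu1
    muS[act] <- pmax(yc[act], mu1[act])
    if (any(!act))
      muS[!act] <- mu1[!act] +
        P[!act, act, drop = FALSE] %*%
        solve(P[act, act, drop = FALSE], (muS - mu1)[act])
    return(list(muS = as.numeric(muS), z = z, se = rep(0, t)))
  }
  if (method == "mc") {
    smp <- rTruncatedMVN(mcDraws, mu1, P, yc, seed = seed)
    return(list(muS = colMeans(smp), z = z,
                se = apply(smp, 2L, sd) / sqrt(mcDraws)))
  }
  q <- numeric(t)
  for (k in seq_len(t)) {
    if (!is.finite(yc[k])) next
    dk <- dnorm(yc[k], mu1[k], sqrt(P[k, k]))
    q[k] <- if (t == 1L) dk else {
      cm <- mu1[-k] + P[-k, k] * (yc[k] - mu1[k]) / P[k, k]
      cv <- P[-k, -k, drop = FALSE] - tcrossprod(P[-k, k]) / P[k, k]
      dk * mvnUpperOrthant(cm, cv, yc[-k])
    }
  }
  list(muS = as.numeric(mu1 + P %*% q / z), z = z, se = rep(0, t))
}

#' Construct a ParentalDistribution
#'
#' Builds the truncated-MVN distribution of selected parents from the base
#' population `MVN(mu1, P)` and threshold vector `yc` (all on the
#' increasing-improvement scale), computing the orthant probability `z` and
#' the truncated mean `muS`. An orthant mass below `zFloor` is floored with
#' a warning suggesting the thresholds be relaxed.
#'
#' @inheritParams truncatedMVNMoments
#' @param zFloor lower guard for `z` inside `-log z`.
#' @return a [ParentalDistribution-class] object.
#' @export
parentalDistribution <- function(mu1, P, yc, mcDraws = 2000L, seed = NULL,
                                 method = c("analytic", "mc"),
                                 zFloor = 1e-300) {
  t <- length(mu1)
  P <- .symmetrize(as.matrix(P))
  stopifnot(all(dim(P) == t), length(yc) == t)
  z <- mvnUpperOrthant(mu1, P, yc)
  if (z < zFloor) {
    warning("orthant probability underflow; z floored at ", zFloor,
            " - consider relaxing the thresholds yc")
    z <- zFloor
  }
  mom <- truncatedMVNMoments(mu1, P, yc, mcDraws = mcDraws, seed = seed,
                             method = match.arg(method))
  new("ParentalDistribution", mu1 = as.numeric(mu1), P = P,
      yc = as.numeric(yc), z = z, muS = as.numeric(mom$muS),
      S = as.numeric(mom$muS - mu1), muS_se = as.numeric(mom$se))
}

#' Multivariate Kullback-Leibler selection loss
#'
#' KL divergence between the truncated parental distribution
#' `TMVN(mu1, P, yc)` and a candidate predictive distribution `MVN(m2, P)`
#' sharing the phenotypic covariance `P`:
#' `-log z + (muS - m2)' P^{-1} (muS - m2) / 2 - S' P^{-1} S / 2`.
#' When the candidate mean equals the multi-trait response
#' `m2 = mu1 + (sigmaG P^{-1}) S`, the quadratic term becomes
#' `S'(I - sigmaG P^{-1})' P^{-1} (I - sigmaG P^{-1}) S / 2`, the
#' heritability form of the loss; at `t = 1` the univariate loss is
#' recovered.
#'
#' @param parental a [ParentalDistribution-class].
#' @param m2 `t`-vector candidate mean.
#' @return scalar divergence.
#' @export
klMultivariate <- function(parental, m2) {
  stopifnot(is(parental, "ParentalDistribution"),
            length(m2) == length(parental@mu1))
  Pinv <- tryCatch(solve(parental@P),
                   error = function(e) stop("singular P: ",
                                            conditionMessage(e)))
  d <- parental@muS - m2
  S <- parental@S
  -log(parental@z) +
    0.5 * as.numeric(t(d) %*% Pinv %*% d) -
    0.5 * as.numeric(t(S) %*% Pinv %*% S)
}

#' Energy distance between two samples
#'
#' V-statistic estimate of the energy distance
#' `2 E||X - Y|| - E||X - X'|| - E||Y - Y'||` with Euclidean norm and
#' exponent 1, between a candidate sample `X` and a parental sample `Y`.
#' Zero when the two samples coincide; nonnegative in expectation for any
#' pair of distributions.
#'
#' @param candidateDraws `N x t` matrix of candidate samples.
#' @param parentalDraws `M x t` matrix of parental samples.
#' @return scalar energy distance estimate.
#' @export
energyScore <- function(candidateDraws, parentalDraws) {
  X <- as.matrix(candidateDraws); Y <- as.matrix(parentalDraws)
  if (ncol(X) != ncol(Y)) stop("dimension mismatch between samples")
  # block the pairwise-distance matrix so memory stays bounded for large
  # samples (at most ~4e6 temporary entries per block)
  meanDist <- function(A, B) {
    na <- nrow(A); nb <- nrow(B)
    rb2 <- rowSums(B^2)
    block <- max(1L, floor(4e6 / nb))
    tot <- 0
    for (s in seq(1L, na, by = block)) {
      idx <- s:min(s + block - 1L, na)
      Ai <- A[idx, , drop = FALSE]
      d2 <- outer(rowSums(Ai^2), rb2, "+") - 2 * tcrossprod(Ai, B)
      tot <- tot + sum(sqrt(pmax(d2, 0)))
    }
    tot / (na * nb)
  }
  2 * meanDist(X, Y) - meanDist(X, X) - meanDist(Y, Y)
}

#' Multivariate asymmetric linear loss (MALF)
#'
#' Per-trait asymmetric piecewise-linear penalty around the threshold `yc`,
#' summed over traits and averaged over candidate draws:
#' `sum_t E[tau_t max(yc_t - Y_t, 0) + (1 - tau_t) max(Y_t - yc_t, 0)]`.
#' `tau_t` near 1 penalizes predictive mass falling short of the threshold
#' much more heavily than mass exceeding it; `tau = 0.5` halves the L1
#' distance to the threshold. Draws must be on the increasing-improvement
#' scale.
#'
#' @param candidateDraws `N x t` matrix of candidate samples.
#' @param yc `t`-vector of thresholds.
#' @param tau `t`-vector (or scalar) of asymmetry weights in (0, 1).
#' @return scalar loss.
#' @export
malf <- function(candidateDraws, yc, tau = 0.9) {
  Y <- as.matrix(candidateDraws)
  t <- ncol(Y)
  stopifnot(length(yc) == t)
  tau <- rep_len(tau, t)
  if (any(tau <= 0) || any(tau >= 1))
    stop("tau must lie strictly inside (0, 1)")
  short <- sweep(-Y, 2L, yc, "+")        # yc - Y
  per <- vapply(seq_len(t), function(j) {
    mean(tau[j] * pmax(short[, j], 0) + (1 - tau[j]) * pmax(-short[, j], 0))
  }, numeric(1))
  sum(per)
}

#' Orient values to the increasing-improvement scale
#'
#' Negates the columns (or elements) belonging to decrease-direction traits
#' so that every trait is improved upwards; increase-direction traits pass
#' through unchanged. Applies to GEBVs, draws, means, and thresholds alike,
#' and is an involution (applying it twice restores the input). Covariance
#' matrices transform as `D P D` with `D = diag(+-1)`; use
#' `what = "covariance"` for those.
#'
#' @param values numeric vector of length `t`, or a matrix with `t` columns
#'   (`what = "values"`), or a `t x t` covariance matrix
#'   (`what = "covariance"`).
#' @param directions per-trait `"increase"`/`"decrease"`.
#' @param what how to interpret `values`.
#' @return transformed object of the same shape.
#' @export
applyDirectionTransform <- function(values, directions,
                                    what = c("values", "covariance")) {
  what <- match.arg(what)
  if (is.matrix(values)) t <- ncol(values) else t <- length(values)
  directions <- .checkDirections(directions, t)
  s <- ifelse(directions == "decrease", -1, 1)
  if (what == "covariance") {
    stopifnot(is.matrix(values), nrow(values) == t)
    return(values * tcrossprod(s))
  }
  if (is.matrix(values)) sweep(values, 2L, s, "*") else values * s
}
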