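## Independent closed-form / brute-force oracles used across tests.

# E|X| for X ~ N(m, s^2): folded-normal mean.
foldedNormalMean <- function(m, s) {
  s * sqrt(2 / pi) * exp(-m^2 / (2 * s^2)) + m * (1 - 2 * pnorm(-m / s))
}

# Closed-form energy distance between N(m1, s1^2) and N(m2, s2^2).
energyDistanceNormals <- function(m1, s1, m2, s2) {
  2 * foldedNormalMean(m1 - m2, sqrt(s1^2 + s2^2)) -
    foldedNormalMean(0, sqrt(2) * s1) -
    foldedNormalMean(0, sqrt(2) * s2)
}

# Random correlation-structured PSD covariance for property loops.
randomCovariance <- function(t, scale = 1) {
  A <- matrix(rnorm(t * t), t)
  S <- crossprod(A) / t + diag(0.2, t)
  scale * S
}

# Hand-rolled Henderson mixed-model equations for the multi-trait model
# with identity design: independent route to the GLS solution.
hendersonMME <- function(y, G, sigmaG, rDiag) {
  n <- nrow(y); t <- ncol(y)
  Rinv <- kronecker(diag(1 / rDiag, t), diag(n))
  Ginv <- kronecker(solve(sigmaG), solve(G))
  X <- kronecker(diag(t), matrix(1, n, 1))
  Z <- diag(n * t)
  lhs <- rbind(cbind(t(X) %*% Rinv %*% X, t(X) %*% Rinv %*% Z),
               cbind(t(Z) %*% Rinv %*% X, t(Z) %*% Rinv %*% Z + Ginv))
  rhs <- rbind(t(X) %*% Rinv %*% as.numeric(y),
               t(Z) %*% Rinv %*% as.numeric(y))
  sol <- solve(lhs, rhs)
  matrix(sol[-(1:t)], n, t)
}

# Small deterministic breeding bundle for I/O and sampler tests.
smallBundle <- function(n = 30, t = 2, seed = 42, h2 = 0.5) {
  M <- simulateMarkers(n, 8 * n, seed = seed)
  G <- computeGRM(centerScaleMarkers(M))
  sg <- randomCovariance(t, scale = 2)
  rd <- diag(sg) * (1 - h2) / h2
  sim <- simulatePopulation(G, mu = seq_len(t) * 10, sigmaG = sg,
                            rDiag = rd, seed = seed + 1)
  list(bundle = BreedingData(sim$phenotypes, relationship = G),
       truth = sim$truth, sigmaG = sg, rDiag = rd)
}

# Build a PosteriorChain by hand (for plug-in / degenerate-posterior tests).
manualChain <- function(mu, sigmaG, rDiag, g, nKept = 1L) {
  n <- nrow(g); t <- length(mu)
  new("PosteriorChain",
      mu = matrix(mu, nKept, t, byrow = TRUE),
      sigmaG = array(sigmaG, c(t, t, nKept)),
      rDiag = matrix(rDiag, nKept, t, byrow = TRUE),
      g = array(g, c(n, t, nKept)),
      gebvMean = g, gebvVar = matrix(0.1, n, t),
      lineIds = if (is.null(rownames(g))) sprintf("L%03d", seq_len(n))
                else rownames(g),
      traitNames = paste0("T", seq_len(t)),
      eigenG = list(), control = list())
}
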