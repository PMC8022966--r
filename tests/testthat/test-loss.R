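test_that("truncatedNormalMean matches integration and stays tail-stable", {
  expect_equal(truncatedNormalMean(0, 1, -Inf), 0)
  # half-normal mean sqrt(2/pi), cross-checked by numerical integration
  numint <- integrate(function(y) y * dnorm(y) / 0.5, 0, Inf)$value
  expect_equal(truncatedNormalMean(0, 1, 0), sqrt(2 / pi), tolerance = 1e-10)
  expect_equal(truncatedNormalMean(0, 1, 0), numint, tolerance = 1e-8)
  # location-scale transform of the half-normal case
  expect_equal(truncatedNormalMean(5, 2, 5), 5 + 2 * sqrt(2 / pi),
               tolerance = 1e-10)
  # deep-tail stability: finite, above the threshold, near yc + sigma/alpha
  for (a in c(8, 15, 30)) {
    m <- truncatedNormalMean(0, 1, a)
    expect_true(is.finite(m) && m > a)
    expect_equal(m, a + 1 / a, tolerance = 0.05)
  }
  expect_error(truncatedNormalMean(0, -1, 0), "positive")
})

test_that("univariate KL has its closed-form limits", {
  # h2 = 0: only the truncation-mass term survives
  s0 <- univariateSelection(2, 4, 3, h2 = 0)
  expect_equal(klUnivariate(s0), log(1 / s0$Pr), tolerance = 1e-12)
  # h2 = 1 at yc = mu1: log 2 - 1/pi
  s1 <- univariateSelection(0, 1, 0, h2 = 1)
  expect_equal(klUnivariate(s1), log(2) - 1 / pi, tolerance = 1e-10)
  # same value from numerical integration of the defining integrand
  integrand <- function(y) {
    fT <- dnorm(y) / 0.5
    logRatio <- dnorm(y, log = TRUE) - log(0.5) -
      dnorm(y, mean = s1$R, sd = 1, log = TRUE)
    logRatio * fT
  }
  expect_equal(klUnivariate(s1), integrate(integrand, 0, Inf)$value,
               tolerance = 1e-6)
})

test_that("the two algebraic KL forms agree and the loss is >= 0", {
  set.seed(4)
  for (i in 1:50) {
    sel <- univariateSelection(rnorm(1), runif(1, 0.2, 5),
                               rnorm(1, sd = 2), h2 = runif(1))
    a <- klUnivariate(sel, "response")
    b <- klUnivariate(sel, "heritability")
    expect_equal(a, b, tolerance = 1e-12)
    expect_gte(a, 0)
  }
})

test_that("univariate KL is strictly decreasing in h2", {
  h2s <- seq(0.05, 0.95, by = 0.05)
  kls <- vapply(h2s, function(h)
    klUnivariate(univariateSelection(1, 2, 2, h2 = h)), numeric(1))
  expect_true(all(diff(kls) < 0))
})

test_that("orthant probabilities match independence and closed forms", {
  expect_equal(mvnUpperOrthant(c(0, 0), diag(2), c(0, 0)), 0.25,
               tolerance = 1e-9)
  expect_equal(mvnUpperOrthant(c(0, 0), diag(2), c(-Inf, -Inf)), 1)
  # bivariate closed form: 1/4 + arcsin(rho)/(2 pi)
  P <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(mvnUpperOrthant(c(0, 0), P, c(0, 0)),
               0.25 + asin(0.5) / (2 * pi), tolerance = 1e-6)
  # Monte-Carlo oracle within 3 standard errors
  set.seed(8)
  N <- 1e6
  L <- t(chol(P))
  smp <- matrix(rnorm(2 * N), N, 2) %*% t(L)
  phat <- mean(smp[, 1] > 0 & smp[, 2] > 0)
  se <- sqrt(phat * (1 - phat) / N)
  expect_lt(abs(mvnUpperOrthant(c(0, 0), P, c(0, 0)) - phat), 3 * se)
  # -Inf components drop out of the integral
  expect_equal(mvnUpperOrthant(c(0, 0), P, c(0, -Inf)), 0.5,
               tolerance = 1e-9)
})

test_that("truncated-MVN samples respect the support on both sampler paths", {
  P <- matrix(c(1, 0.3, 0.3, 1), 2)
  # rejection path (z = 0.25-ish)
  s1 <- rTruncatedMVN(500, c(0, 0), P, c(0, 0), seed = 1)
  expect_true(all(s1 >= 0))
  # Gibbs path: push z below 1%
  yc <- c(2.2, 2.2)
  expect_lt(mvnUpperOrthant(c(0, 0), P, yc), 0.01)
  s2 <- rTruncatedMVN(500, c(0, 0), P, yc, seed = 2)
  expect_true(all(sweep(s2, 2, yc, ">=")))
})

test_that("analytic truncated moments agree with sampling and reductions", {
  # diagonal P: componentwise reduction to the univariate truncated mean
  P <- diag(c(1, 4))
  mom <- truncatedMVNMoments(c(1, -1), P, c(1.5, 0), method = "analytic")
  expect_equal(mom$muS,
               c(truncatedNormalMean(1, 1, 1.5),
                 truncatedNormalMean(-1, 2, 0)), tolerance = 1e-6)
  # no truncation: muS = mu1, z = 1
  mom0 <- truncatedMVNMoments(c(3, 4), P, c(-Inf, -Inf))
  expect_identical(mom0$muS, c(3, 4))
  expect_identical(mom0$z, 1)
  # correlated case: analytic identity vs the MC estimator within 3 SE
  P2 <- matrix(c(1, -0.4, -0.4, 2), 2)
  an <- truncatedMVNMoments(c(0, 1), P2, c(0.5, 0.8), method = "analytic")
  mc <- truncatedMVNMoments(c(0, 1), P2, c(0.5, 0.8), method = "mc",
                            mcDraws = 40000, seed = 31)
  expect_true(all(abs(an$muS - mc$muS) < 3 * mc$se + 1e-8))
})

test_that("multivariate KL reduces to the univariate loss at t = 1", {
  set.seed(6)
  for (i in 1:100) {
    mu1 <- rnorm(1); s2 <- runif(1, 0.3, 4); h2 <- runif(1)
    yc <- mu1 + runif(1, -1.5, 1.5) * sqrt(s2)
    sel <- univariateSelection(mu1, s2, yc, h2)
    par <- new("ParentalDistribution", mu1 = mu1, P = matrix(s2),
               yc = yc, z = sel$Pr, muS = sel$muS, S = sel$S, muS_se = 0)
    expect_equal(klMultivariate(par, mu1 + sel$R), klUnivariate(sel),
                 tolerance = 1e-10)
  }
})

test_that("multivariate KL quadratic term vanishes when m2 = muS", {
  P <- matrix(c(1, 0.5, 0.5, 1), 2)
  par <- parentalDistribution(c(0, 0), P, c(0, 0))
  expected <- -log(par@z) -
    0.5 * as.numeric(t(par@S) %*% solve(P) %*% par@S)
  expect_equal(klMultivariate(par, par@muS), expected, tolerance = 1e-10)
})

test_that("multivariate KL matches Monte-Carlo evaluation of its integral", {
  mu1 <- c(0, 0); P <- matrix(c(1, 0.5, 0.5, 1), 2)
  yc <- c(0, 0); m2 <- c(0.3, 0.3)
  par <- parentalDistribution(mu1, P, yc)
  kl <- klMultivariate(par, m2)
  smp <- rTruncatedMVN(1e5, mu1, P, yc, seed = 12)
  Pinv <- solve(P)
  qf <- function(y, m) rowSums((sweep(y, 2, m) %*% Pinv) * sweep(y, 2, m))
  vals <- -log(par@z) + 0.5 * (qf(smp, m2) - qf(smp, mu1))
  expect_lt(abs(kl - mean(vals)), 3 * sd(vals) / sqrt(length(vals)))
})

test_that("energy distance is zero on identical samples and matches normals", {
  set.seed(14)
  X <- matrix(rnorm(600), 200, 3)
  expect_lt(abs(energyScore(X, X)), 1e-10)
  # univariate N(0,1) vs N(2,1) against the folded-normal closed form,
  # within 3 standard errors of 10 replicate estimates
  reps <- vapply(1:10, function(i) {
    energyScore(matrix(rnorm(3000), ncol = 1),
                matrix(rnorm(3000, 2), ncol = 1))
  }, numeric(1))
  expect_lt(abs(mean(reps) - energyDistanceNormals(0, 1, 2, 1)),
            3 * sd(reps) / sqrt(10))
  # nonnegative up to MC noise, permutation-invariant
  a <- matrix(rnorm(300), 100, 3); b <- matrix(rnorm(300, 0.2), 100, 3)
  expect_gt(energyScore(a, b), -1e-10)
  expect_equal(energyScore(a[sample(100), ], b[sample(100), ]),
               energyScore(a, b), tolerance = 1e-12)
  expect_error(energyScore(a, matrix(0, 5, 2)), "dimension")
})

test_that("MALF has its closed-form reductions", {
  Y <- matrix(c(1, 1, 2, 2), 2)
  expect_equal(malf(Y, yc = c(1, 2), tau = 0.9), 0)
  # tau = 1/2 halves the L1 distance to the threshold
  set.seed(15)
  Z <- matrix(rnorm(400), 200, 2)
  yc <- c(0.3, -0.1)
  expect_equal(malf(Z, yc, tau = 0.5),
               0.5 * sum(colMeans(abs(sweep(Z, 2, yc)))), tolerance = 1e-12)
  # univariate N(0,1), yc = 0, tau = 0.9: expectation is phi(0)
  N <- 50000
  z <- matrix(rnorm(N), ncol = 1)
  se <- sd(0.9 * pmax(-z, 0) + 0.1 * pmax(z, 0)) / sqrt(N)
  expect_lt(abs(malf(z, 0, 0.9) - dnorm(0)), 3 * se)
  # permutation invariance and tau validation
  expect_identical(malf(Z[sample(200), ], yc, 0.7), malf(Z, yc, 0.7))
  expect_error(malf(Z, yc, tau = 1.2), "inside \\(0, 1\\)")
})

test_that("direction transform is an involution preserving losses", {
  dirs <- c("decrease", "increase", "decrease")
  v <- c(1, -2, 3)
  expect_identical(applyDirectionTransform(v, rep("increase", 3)), v)
  expect_identical(
    applyDirectionTransform(applyDirectionTransform(v, dirs), dirs), v)
  # losses are invariant when draws, thresholds (and covariances) are
  # negated together
  set.seed(16)
  X <- matrix(rnorm(300), 100, 3); Y <- matrix(rnorm(300, 0.5), 100, 3)
  yc <- c(0.2, -0.3, 0.1)
  Xn <- applyDirectionTransform(X, dirs); Yn <- applyDirectionTransform(Y, dirs)
  ycn <- applyDirectionTransform(yc, dirs)
  expect_equal(energyScore(Xn, Yn), energyScore(X, Y), tolerance = 1e-12)
  expect_identical(malf(Xn, ycn, 0.5), malf(X, yc, 0.5))
  # covariance transforms as D P D
  P <- diag(3) + 0.2
  D <- diag(c(-1, 1, -1))
  expect_identical(applyDirectionTransform(P, dirs, what = "covariance"),
                   D %*% P %*% D)
})
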