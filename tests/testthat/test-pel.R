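test_that("a length-1 chain gives PEL equal to the plug-in loss", {
  set.seed(90)
  mu <- c(1, 2); sg <- matrix(c(1, 0.3, 0.3, 1), 2); rd <- c(0.5, 0.5)
  g <- matrix(rnorm(12), 6, 2)
  ch <- manualChain(mu, sg, rd, g)
  yc <- c(1.2, 2.5)
  ctl <- lossControl(stride = 1, seed = 4)
  pel <- computePEL(ch, yc, loss = "kl", control = ctl)
  P <- sg + diag(rd)
  par <- parentalDistribution(mu, P, yc, method = "analytic")
  direct <- vapply(seq_len(6), function(o)
    klMultivariate(par, mu + g[o, ]), numeric(1))
  expect_equal(pel$pel_raw, direct, tolerance = 1e-12)
  expect_equal(pel$mc_se, rep(NA_real_, 6))
})

test_that("a clamped chain gives PEL equal to the KL closed form exactly", {
  set.seed(91)
  mu <- c(0, 0); sg <- diag(2); rd <- c(1, 1)
  g <- matrix(rnorm(16), 8, 2)
  # 5 identical draws: the posterior average must collapse to one term
  ch <- manualChain(mu, sg, rd, g, nKept = 5)
  yc <- c(0.5, 0.5)
  pel <- computePEL(ch, yc, loss = "kl",
                    control = lossControl(stride = 1, seed = 1))
  par <- parentalDistribution(mu, sg + diag(rd), yc, method = "analytic")
  direct <- vapply(seq_len(8), function(o)
    klMultivariate(par, mu + g[o, ]), numeric(1))
  expect_equal(pel$pel_raw, direct, tolerance = 1e-12)
  expect_equal(pel$mc_se, rep(0, 8), tolerance = 1e-12)
})

test_that("identical candidates receive identical PEL under every loss", {
  set.seed(92)
  g <- matrix(rnorm(10), 5, 2)
  g[3, ] <- g[1, ]                      # duplicate line
  ch <- manualChain(c(0, 0), diag(2), c(1, 1), g, nKept = 3)
  for (l in c("kl", "energy", "malf")) {
    pel <- computePEL(ch, c(0, 0), loss = l,
                      control = lossControl(stride = 1, seed = 2))
    expect_equal(pel$pel_raw[3], pel$pel_raw[1], tolerance = 1e-10)
  }
})

test_that("standardizePEL maps to [0, 1] preserving order", {
  expect_equal(standardizePEL(c(2, 4, 6)), c(0, 0.5, 1))
  set.seed(93)
  x <- rnorm(30)
  s <- standardizePEL(x)
  expect_identical(order(s), order(x))
  expect_identical(s[which.min(x)], 0)
  expect_identical(s[which.max(x)], 1)
  expect_error(standardizePEL(rep(1, 4)), "equal")
})

test_that("rankAndSelect flags floor(intensity * n) lines deterministically", {
  for (n in c(766L, 320L)) {
    res <- data.frame(line_id = sprintf("L%04d", seq_len(n)), loss = "kl",
                      pel_raw = runif(n), mc_se = 0)
    out <- rankAndSelect(res, intensity = 0.1)
    expect_identical(sum(out$selected), as.integer(floor(0.1 * n)))
    expect_identical(sort(out$rank), seq_len(n))
  }
  # ties at the cutoff break by line identifier, stably across runs
  res <- data.frame(line_id = c("B", "A", "C"), loss = "kl",
                    pel_raw = c(0.5, 0.5, 0.9), mc_se = 0)
  out1 <- rankAndSelect(res, intensity = 0.4)
  out2 <- rankAndSelect(res[c(2, 1, 3), ], intensity = 0.4)
  expect_identical(out1$line_id[out1$selected], "A")
  expect_identical(out2$line_id[out2$selected], "A")
  expect_error(rankAndSelect(res, intensity = 1.2), "inside \\(0, 1\\)")
})

test_that("ranking is invariant to increasing transforms of the raw loss", {
  set.seed(94)
  res <- data.frame(line_id = sprintf("L%02d", 1:40), loss = "kl",
                    pel_raw = rnorm(40), mc_se = 0)
  res2 <- res; res2$pel_raw <- exp(res$pel_raw)
  a <- rankAndSelect(res, 0.2); b <- rankAndSelect(res2, 0.2)
  expect_identical(a$line_id, b$line_id)
  expect_identical(a$rank, b$rank)
  expect_identical(a$selected, b$selected)
})

test_that("overlapStatistics reports pairwise percentages", {
  A <- sprintf("L%03d", 1:76)
  expect_equal(overlapStatistics(list(kl = A, energy = A))["kl", "energy"],
               100)
  expect_equal(overlapStatistics(list(a = A, b = paste0("X", A)))["a", "b"],
               0)
  B <- c(A[1:23], paste0("X", 1:53))
  expect_equal(overlapStatistics(list(kl = A, energy = B))["kl", "energy"],
               30.26)
  expect_error(overlapStatistics(list(a = A, b = A[1:10])), "equal size")
})

test_that("top/bottom summaries pass GEBVs through unchanged", {
  set.seed(95)
  g <- matrix(rnorm(24), 12, 2)
  ch <- manualChain(c(0, 0), diag(2), c(1, 1), g)
  pel <- computePEL(ch, c(0, 0), loss = "kl",
                    control = lossControl(stride = 1))
  ranked <- rankAndSelect(pel, 0.25)
  tb <- summarizeTopBottom(ranked, ch, k = 5)
  expect_identical(nrow(tb), 10L)
  expect_identical(tb$end, rep(c("top", "bottom"), each = 5))
  expect_identical(tb$pel_std[1], 0)
  idx <- match(tb$line_id, lineIds(ch))
  expect_equal(unname(cbind(tb$gebv_T1, tb$gebv_T2)), unname(gebv(ch)[idx, ]))
  expect_error(summarizeTopBottom(ranked, ch, k = 7), "half")
})

test_that("single-trait KL selection agrees with truncation selection", {
  # the KL loss is quadratic around the truncated parental mean, so when
  # every candidate sits below it (an ambitious threshold) the loss is
  # monotone decreasing in the candidate mean and the PEL-best line must be
  # the top-GEBV line, as in classical truncation selection
  for (r in 1:20) {
    set.seed(200 + r)
    n <- 30
    g <- matrix(rnorm(n, sd = 1), n, 1)
    ch <- manualChain(5, matrix(4), 0.4, g)  # high-heritability setting
    pel <- computePEL(ch, yc = 9, loss = "kl",
                      control = lossControl(stride = 1))
    expect_identical(which.min(pel$pel_raw), which.max(g[, 1]))
  }
})

test_that("selected sets are conserved and reported coherently", {
  fx <- makeFixture("tiny")
  ch <- fitMTM(fx$bundle, mcmcControl(nBurn = 100, nKept = 100, thin = 1,
                                      seed = 12))
  yc <- thresholdsFromRules(phenotypes(fx$bundle), traitConfigOf(fx$bundle))
  rep <- selectParents(ch, yc, intensity = 0.25,
                       directions = traitConfigOf(fx$bundle)$direction,
                       control = lossControl(stride = 20,
                                             mcDrawsParental = 150,
                                             mcDrawsCandidate = 150,
                                             seed = 3),
                       topK = 3)
  res <- selectionResults(rep)
  for (l in unique(res$loss))
    expect_identical(sum(res$selected[res$loss == l]), 3L)
  ov <- overlapMatrix(rep)
  expect_true(all(diag(ov) == 100))
  expect_true(all(ov >= 0 & ov <= 100))
  sel <- selectedLines(rep)
  expect_identical(lengths(sel), setNames(rep(3L, 3), names(sel)))
})

test_that("Monte-Carlo draw counts do not destabilize the selected set", {
  fx <- makeFixture("tiny")
  ch <- fitMTM(fx$bundle, mcmcControl(nBurn = 150, nKept = 60, thin = 1,
                                      seed = 21))
  yc <- thresholdsFromRules(phenotypes(fx$bundle), traitConfigOf(fx$bundle))
  pick <- function(draws) {
    pel <- computePEL(ch, yc, loss = "energy",
                      control = lossControl(stride = 6,
                                            mcDrawsParental = draws,
                                            mcDrawsCandidate = draws,
                                            seed = 8))
    out <- rankAndSelect(pel, 0.25)
    out$line_id[out$selected]
  }
  s1 <- pick(200); s2 <- pick(400)
  expect_gte(length(intersect(s1, s2)), length(s1) - 2L)
})
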