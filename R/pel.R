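#' Loss-evaluation settings
#'
#' @param mcDrawsParental truncated-MVN samples per posterior draw used for
#'   the parental moments and the Energy Score parental sample (>= 100).
#' @param mcDrawsCandidate candidate predictive samples per posterior draw
#'   for the Energy Score and MALF (>= 100).
#' @param stride evaluate every `stride`-th retained posterior draw (the
#'   posterior average is unbiased for any stride; larger strides trade
#'   Monte-Carlo error for runtime).
#' @param malfTau asymmetry weight(s) for [malf()], in (0, 1).
#' @param candidateCov candidate predictive covariance: `"phenotypic"`
#'   (`sigmaG + diag(rDiag)`, the default — offspring share the base
#'   population's phenotypic covariance) or `"genetic"` (`sigmaG` only).
#' @param seed integer seed for all loss-stage sampling.
#' @return list of class `loss_control`.
#' @export
lossControl <- function(mcDrawsParental = 500L, mcDrawsCandidate = 500L,
                        stride = 10L, malfTau = 0.9,
                        candidateCov = c("phenotypic", "genetic"),
                        seed = 1L) {
  stopifnot(mcDrawsParental >= 100L, mcDrawsCandidate >= 100L, stride >= 1L)
  if (any(malfTau <= 0) || any(malfTau >= 1))
    stop("malfTau must lie strictly inside (0, 1)")
  structure(list(mcDrawsParental = as.integer(mcDrawsParental),
                 mcDrawsCandidate = as.integer(mcDrawsCandidate),
                 stride = as.integer(stride), malfTau = malfTau,
                 candidateCov = match.arg(candidateCov),
                 seed = as.integer(seed)),
            class = "loss_control")
}

#' Orient a posterior draw and thresholds to the increasing scale
#' @noRd
.orientDraw <- function(dr, yc, directions) {
  s <- ifelse(directions == "decrease", -1, 1)
  list(mu = dr$mu * s,
       sigmaG = dr$sigmaG * tcrossprod(s),
       rDiag = dr$rDiag,
       g = sweep(matrix(dr$g, length(dr$g) / length(s), length(s)),
                 2L, s, "*"),
       yc = yc * s)
}

#' Posterior expected loss for every candidate line
#'
#' Averages the chosen loss over the (possibly strided) posterior draws.
#' For each evaluated draw `k` the parental distribution is rebuilt from
#' that draw's intercepts and phenotypic covariance
#' (`P^(k) = sigmaG^(k) + diag(rDiag^(k))`) truncated at `yc`, and each
#' line's predictive distribution is `MVN(mu^(k) + g_o^(k), P^(k))`. The KL
#' loss is evaluated in closed form per draw; the Energy Score and MALF by
#' Monte-Carlo sampling of the candidate predictive (and, for the Energy
#' Score, the truncated parental). Decrease-direction traits are negated
#' (values, thresholds and covariance rows/columns together) before any
#' loss is evaluated. The reported standard error is the between-draw
#' standard deviation of the loss divided by `sqrt(#draws used)`.
#'
#' @param chain a [PosteriorChain-class] from [fitMTM()].
#' @param yc named or plain `t`-vector of thresholds on the phenotype scale
#'   (see [thresholdsFromRules()]).
#' @param loss `"kl"`, `"energy"`, or `"malf"`.
#' @param directions per-trait improvement directions; default all
#'   `"increase"`.
#' @param control a [lossControl()] list.
#' @return data.frame with columns `line_id`, `loss`, `pel_raw`, `mc_se`.
#' @export
computePEL <- function(chain, yc, loss = c("kl", "energy", "malf"),
                       directions = NULL, control = lossControl()) {
  loss <- match.arg(loss)
  stopifnot(is(chain, "PosteriorChain"), inherits(control, "loss_control"))
  n <- nLines(chain); nt <- nTraits(chain)
  stopifnot(length(yc) == nt)
  directions <- .checkDirections(directions, nt)
  ks <- seq(1L, nDraws(chain), by = control$stride)
  set.seed(control$seed)
  perDraw <- matrix(NA_real_, length(ks), n)

  for (ii in seq_along(ks)) {
    dr <- .orientDraw(chainDraw(chain, ks[ii]), yc, directions)
    P <- .symmetrize(dr$sigmaG + diag(dr$rDiag, nt))
    m <- sweep(dr$g, 2L, dr$mu, "+")          # n x t candidate means
    if (loss == "kl") {
      par <- parentalDistribution(dr$mu, P, dr$yc, method = "analytic")
      Pinv <- solve(P)
      S <- par@S
      base <- -log(par@z) - 0.5 * as.numeric(crossprod(S, Pinv %*% S))
      D <- sweep(m, 2L, par@muS, "-")         # m2 - muS rowwise
      quad <- rowSums((D %*% Pinv) * D)
      perDraw[ii, ] <- base + 0.5 * quad
    } else {
      Pc <- if (control$candidateCov == "phenotypic") P
            else .symmetrize(dr$sigmaG)
      Lc <- .cholLower(Pc, label = "candidate covariance")
      Zc <- matrix(rnorm(control$mcDrawsCandidate * nt),
                   control$mcDrawsCandidate, nt) %*% t(Lc)
      if (loss == "energy") {
        Yp <- rTruncatedMVN(control$mcDrawsParental, dr$mu, P, dr$yc)
        for (o in seq_len(n))
          perDraw[ii, o] <- energyScore(sweep(Zc, 2L, m[o, ], "+"), Yp)
      } else {
        for (o in seq_len(n))
          perDraw[ii, o] <- malf(sweep(Zc, 2L, m[o, ], "+"), dr$yc,
                                 control$malfTau)
      }
    }
  }
  data.frame(line_id = lineIds(chain), loss = loss,
             pel_raw = colMeans(perDraw),
             mc_se = apply(perDraw, 2L, sd) / sqrt(length(ks)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Standardize posterior expected losses to \[0, 1\]
#'
#' Affine map `(x - min) / (max - min)` so the best (minimum-loss) line
#' scores exactly 0 and the worst exactly 1; ranking is unchanged.
#'
#' @param raw numeric vector of raw PEL values, length >= 2, not constant.
#' @return vector of the same length in \[0, 1\].
#' @export
standardizePEL <- function(raw) {
  stopifnot(length(raw) >= 2L)
  rng <- range(raw)
  if (rng[1] == rng[2])
    stop("all PEL values are equal; no ordering information")
  (raw - rng[1]) / (rng[2] - rng[1])
}

#' Rank candidates and flag the selected fraction
#'
#' Assigns ascending-PEL ranks within each loss function, breaking ties by
#' line identifier (so repeated runs select the same set), standardizes the
#' losses to \[0, 1\], and flags the lowest `floor(intensity * n)` lines as
#' selected.
#'
#' @param results data.frame from [computePEL()] (one or more losses
#'   row-bound together).
#' @param intensity selected fraction, strictly inside (0, 1).
#' @return the input with columns `pel_std`, `rank`, `selected` added,
#'   ordered by loss then rank.
#' @export
rankAndSelect <- function(results, intensity = 0.1) {
  if (intensity <= 0 || intensity >= 1)
    stop("intensity must lie strictly inside (0, 1)")
  stopifnot(is.data.frame(results),
            all(c("line_id", "loss", "pel_raw") %in% names(results)))
  out <- do.call(rbind, lapply(split(results, results$loss), function(d) {
    ord <- order(d$pel_raw, d$line_id)
    d <- d[ord, , drop = FALSE]
    d$pel_std <- standardizePEL(d$pel_raw)
    d$rank <- seq_len(nrow(d))
    d$selected <- d$rank <= floor(intensity * nrow(d))
    d
  }))
  rownames(out) <- NULL
  out
}

#' Pairwise selected-set overlap between loss functions
#'
#' For each pair of equal-size selected sets reports
#' `100 * |A intersect B| / |A|`, rounded to two decimals.
#'
#' @param selections named list of selected line-id vectors (one per loss).
#' @return symmetric numeric matrix of percentages with 100 on the diagonal.
#' @export
overlapStatistics <- function(selections) {
  stopifnot(is.list(selections), length(selections) >= 2L)
  sizes <- lengths(selections)
  if (length(unique(sizes)) != 1L)
    stop("selected sets must have equal size")
  nm <- names(selections)
  k <- length(selections)
  out <- matrix(100, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    pct <- round(100 * length(intersect(selections[[i]], selections[[j]])) /
                   sizes[i], 2)
    out[i, j] <- out[j, i] <- pct
  }
  out
}

#' Top-k / bottom-k selection table
#'
#' For each loss function, the `k` best and `k` worst lines by PEL with
#' their per-trait GEBV posterior means and posterior variances,
#' standardized PEL and rank — the summary a breeder inspects before
#' committing to crosses.
#'
#' @param results ranked results from [rankAndSelect()].
#' @param chain the [PosteriorChain-class] the results came from.
#' @param k lines to show at each end (`k <= n/2`).
#' @return data.frame with one row per shown line per loss.
#' @export
summarizeTopBottom <- function(results, chain, k = 5L) {
  stopifnot(is(chain, "PosteriorChain"), "rank" %in% names(results))
  n <- nLines(chain)
  if (k > n / 2) stop("k must not exceed half the number of lines")
  gm <- gebv(chain); gv <- gebvVariance(chain)
  traits <- chain@traitNames
  out <- do.call(rbind, lapply(split(results, results$loss), function(d) {
    d <- d[order(d$rank), , drop = FALSE]
    pick <- rbind(cbind(d[seq_len(k), , drop = FALSE], end = "top"),
                  cbind(d[n - k + seq_len(k), , drop = FALSE], end = "bottom"))
    idx <- match(pick$line_id, lineIds(chain))
    gmat <- gm[idx, , drop = FALSE]
    vmat <- gv[idx, , drop = FALSE]
    colnames(gmat) <- paste0("gebv_", traits)
    colnames(vmat) <- paste0("postvar_", traits)
    cbind(pick[, c("line_id", "loss", "end", "pel_std", "rank")],
          gmat, vmat)
  }))
  rownames(out) <- NULL
  out
}

#' Decision-theoretic parental selection
#'
#' End-to-end selection stage: computes the posterior expected loss of every
#' candidate line under one or more loss functions, standardizes and ranks,
#' flags the selected fraction, and assembles overlap and top/bottom
#' summaries. Thresholds and directions default to the bundle-style trait
#' configuration carried by `traits`.
#'
#' @param chain a [PosteriorChain-class].
#' @param yc `t`-vector of thresholds on the phenotype scale.
#' @param losses character vector among `"kl"`, `"energy"`, `"malf"`.
#' @param intensity selected fraction in (0, 1); the paper-standard choice
#'   in genomic selection is 0.1.
#' @param directions per-trait improvement directions.
#' @param control a [lossControl()].
#' @param topK rows per end in the top/bottom summary.
#' @return a [SelectionReport-class].
#'
#' @examples
#' fx <- makeFixture("tiny")
#' ch <- fitMTM(fx$bundle, mcmcControl(nBurn = 100, nKept = 60, thin = 1))
#' yc <- thresholdsFromRules(phenotypes(fx$bundle), traitConfigOf(fx$bundle))
#' rep <- selectParents(ch, yc, losses = "kl", intensity = 0.25,
#'                      directions = traitConfigOf(fx$bundle)$direction,
#'                      control = lossControl(stride = 10), topK = 2)
#' rep
#' @export
selectParents <- function(chain, yc, losses = c("kl", "energy", "malf"),
                          intensity = 0.1, directions = NULL,
                          control = lossControl(), topK = 5L) {
  losses <- match.arg(losses, several.ok = TRUE)
  res <- do.call(rbind, lapply(losses, function(l)
    computePEL(chain, yc, loss = l, directions = directions,
               control = control)))
  ranked <- rankAndSelect(res, intensity = intensity)
  sel <- lapply(split(ranked, ranked$loss),
                function(d) d$line_id[d$selected])
  ov <- if (length(losses) >= 2L) overlapStatistics(sel)
        else matrix(100, 1, 1, dimnames = list(losses, losses))
  tb <- summarizeTopBottom(ranked, chain, k = min(topK, nLines(chain) %/% 2L))
  new("SelectionReport", results = ranked, overlap = ov, topBottom = tb,
      intensity = intensity)
}
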