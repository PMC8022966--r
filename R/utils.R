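#' @import methods
#' @importFrom stats dnorm pnorm qnorm quantile rchisq rnorm runif rWishart
#'   rbinom sd setNames var
#' @importFrom utils read.csv write.csv
NULL

## Internal numerical helpers shared across modules.

.symmetrize <- function(m) (m + t(m)) / 2

#' Check symmetry to a relative tolerance
#' @noRd
.isSymmetric <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) &&
    max(abs(m - t(m))) <= tol * max(1, max(abs(m)))
}

#' Smallest-jitter PSD repair: add tau*I, escalating tenfold, until the
#' Cholesky factorization succeeds. Returns the repaired matrix.
#' @noRd
.psdJitter <- function(m, start = 1e-10, max_tries = 12L, label = "matrix") {
  m <- .symmetrize(m)
  ok <- !inherits(try(chol(m), silent = TRUE), "try-error")
  if (ok) return(m)
  tau <- start * max(1, mean(diag(m)))
  for (i in seq_len(max_tries)) {
    mj <- m + diag(tau, nrow(m))
    if (!inherits(try(chol(mj), silent = TRUE), "try-error")) {
      message(sprintf("PSD repair: added jitter %.3g to %s", tau, label))
      return(mj)
    }
    tau <- tau * 10
  }
  stop(sprintf("%s is not positive semi-definite and could not be repaired",
               label))
}

#' Lower Cholesky factor with PSD repair
#' @noRd
.cholLower <- function(m, label = "matrix") {
  t(chol(.psdJitter(m, label = label)))
}

#' Set the RNG seed if one is supplied, restoring nothing (functions that
#' accept a seed own the RNG stream for their duration).
#' @noRd
.seedIfGiven <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

#' Validate a direction vector against a trait count
#' @noRd
.checkDirections <- function(directions, t) {
  if (is.null(directions)) directions <- rep("increase", t)
  directions <- match.arg(directions, c("increase", "decrease"),
                          several.ok = TRUE)
  if (length(directions) == 1L) directions <- rep(directions, t)
  if (length(directions) != t)
    stop("'directions' must have one entry per trait")
  directions
}
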