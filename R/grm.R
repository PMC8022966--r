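#' Center and standardize a marker matrix
#'
#' Centers each marker column to mean zero and scales it to unit variance
#' using the population (divide-by-n) standard deviation. With allele dosage
#' coding in \{0, 1, 2\} this is the usual preprocessing before building a
#' genomic relationship matrix from "centered and standardized" markers.
#' The population-SD convention is used (rather than the sample SD) so that
#' `crossprod` of a column with itself is exactly `n`; the two conventions
#' change the relationship matrix by a factor `(n-1)/n`.
#'
#' @param raw `n x p` numeric genotype matrix; no monomorphic columns.
#' @return `n x p` matrix with column means 0 and population SD 1.
#' @seealso [computeGRM()]
#' @export
centerScaleMarkers <- function(raw) {
  stopifnot(is.matrix(raw), is.numeric(raw))
  n <- nrow(raw)
  mu <- colMeans(raw)
  centered <- sweep(raw, 2L, mu, "-")
  sdp <- sqrt(colSums(centered^2) / n)
  zero <- which(sdp == 0)
  if (length(zero))
    stop("zero-variance (monomorphic) marker column(s): ",
         paste(utils::head(if (is.null(colnames(raw))) zero
                           else colnames(raw)[zero], 5L), collapse = ", "))
  sweep(centered, 2L, sdp, "/")
}

#' Genomic relationship matrix from standardized markers
#'
#' Computes `G = W W' / p` from an `n x p` matrix `W` of centered,
#' unit-variance marker columns. Because the columns are already standardized
#' the denominator is simply the marker count `p` (not the VanRaden
#' `2*sum(p*q)` used for raw dosages), giving a mean diagonal near 1 for
#' large `p`. The result is symmetrized exactly.
#'
#' @param scaled `n x p` centered and standardized marker matrix
#'   (see [centerScaleMarkers()]).
#' @return `n x n` symmetric relationship matrix with line ids as dimnames.
#' @export
computeGRM <- function(scaled) {
  stopifnot(is.matrix(scaled))
  p <- ncol(scaled)
  if (p == 0L) stop("marker matrix has zero columns")
  G <- tcrossprod(scaled) / p
  G <- .symmetrize(G)
  dimnames(G) <- list(rownames(scaled), rownames(scaled))
  G
}
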