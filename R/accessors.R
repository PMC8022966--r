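#' @rdname BreedingData
#' @export
setMethod("phenotypes", "BreedingData", function(x) x@phenotypes)

#' @rdname BreedingData
#' @export
setMethod("relationship", "BreedingData", function(x) x@relationship)

#' @rdname BreedingData
#' @export
setMethod("markers", "BreedingData", function(x) x@markers)

#' @rdname BreedingData
#' @export
setMethod("traitConfigOf", "BreedingData", function(x) x@traits)

#' @rdname BreedingData
#' @export
setMethod("lineIds", "BreedingData", function(x) rownames(x@phenotypes))

#' @rdname BreedingData
#' @export
setMethod("nLines", "BreedingData", function(x) nrow(x@phenotypes))

#' @rdname BreedingData
#' @export
setMethod("nTraits", "BreedingData", function(x) ncol(x@phenotypes))

setMethod("show", "BreedingData", function(object) {
  cat(sprintf("BreedingData: %d lines, %d traits (%s)\n",
              nLines(object), nTraits(object),
              paste(colnames(object@phenotypes), collapse = ", ")))
  cat(sprintf("  relationship: %s; markers: %s\n",
              if (is.null(object@relationship)) "none"
              else sprintf("%d x %d", nrow(object@relationship),
                           ncol(object@relationship)),
              if (is.null(object@markers)) "none"
              else sprintf("%d x %d", nrow(object@markers),
                           ncol(object@markers))))
  if (nrow(object@traits)) {
    cat("  directions: ",
        paste(sprintf("%s(%s)", object@traits$trait,
                      ifelse(object@traits$direction == "increase", "+", "-")),
              collapse = " "), "\n", sep = "")
  }
})

#' @rdname PosteriorChain
#' @export
setMethod("nDraws", "PosteriorChain", function(x) nrow(x@mu))

#' @rdname PosteriorChain
#' @export
setMethod("nLines", "PosteriorChain", function(x) length(x@lineIds))

#' @rdname PosteriorChain
#' @export
setMethod("nTraits", "PosteriorChain", function(x) ncol(x@mu))

#' @rdname PosteriorChain
#' @export
setMethod("lineIds", "PosteriorChain", function(x) x@lineIds)

#' @rdname PosteriorChain
#' @export
setMethod("gebv", "PosteriorChain", function(x) x@gebvMean)

#' @rdname PosteriorChain
#' @export
setMethod("gebvVariance", "PosteriorChain", function(x) x@gebvVar)

#' @rdname PosteriorChain
#' @export
setMethod("chainDraw", "PosteriorChain", function(x, k) {
  stopifnot(k >= 1L, k <= nDraws(x))
  list(mu = x@mu[k, ],
       sigmaG = x@sigmaG[, , k, drop = FALSE][, , 1L],
       rDiag = x@rDiag[k, ],
       g = x@g[, , k, drop = FALSE][, , 1L, drop = FALSE][, , 1L])
})

setMethod("show", "PosteriorChain", function(object) {
  cat(sprintf("PosteriorChain: %d retained draws, %d lines, %d traits\n",
              nDraws(object), nLines(object), nTraits(object)))
  pm <- colMeans(object@mu)
  sg <- apply(object@sigmaG, 1:2, mean)
  rd <- colMeans(object@rDiag)
  h2 <- diag(sg) / (diag(sg) + rd)
  cat("  posterior mean intercepts: ",
      paste(sprintf("%.3g", pm), collapse = ", "), "\n", sep = "")
  cat("  posterior mean h2:         ",
      paste(sprintf("%.2f", h2), collapse = ", "), "\n", sep = "")
})

setMethod("show", "ParentalDistribution", function(object) {
  cat(sprintf("ParentalDistribution (truncated MVN), %d traits\n",
              length(object@mu1)))
  cat(sprintf("  z = Pr(Y > yc) = %.4g\n", object@z))
  cat("  selection differential S: ",
      paste(sprintf("%.3g", object@S), collapse = ", "), "\n", sep = "")
})

#' @rdname SelectionReport
#' @export
setMethod("selectionResults", "SelectionReport", function(x) x@results)

#' @rdname SelectionReport
#' @export
setMethod("overlapMatrix", "SelectionReport", function(x) x@overlap)

#' Selected line identifiers per loss function
#'
#' @param x a `SelectionReport`
#' @param loss loss function name; default returns a named list over all
#'   losses present.
#' @return character vector (or named list of them) of selected line ids.
#' @rdname SelectionReport
#' @export
setMethod("selectedLines", "SelectionReport", function(x, loss = NULL) {
  res <- x@results
  pick <- function(l) sort(res$line_id[res$loss == l & res$selected])
  losses <- unique(res$loss)
  if (is.null(loss)) return(setNames(lapply(losses, pick), losses))
  stopifnot(loss %in% losses)
  pick(loss)
})

setMethod("show", "SelectionReport", function(object) {
  losses <- unique(object@results$loss)
  n <- length(unique(object@results$line_id))
  nsel <- sum(object@results$selected & object@results$loss == losses[1L])
  cat(sprintf("SelectionReport: %d lines, %d selected (intensity %.2f)\n",
              n, nsel, object@intensity))
  cat("  losses: ", paste(losses, collapse = ", "), "\n", sep = "")
  if (length(losses) > 1L) {
    cat("  selected-set overlap (%):\n")
    print(round(object@overlap, 2))
  }
})
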