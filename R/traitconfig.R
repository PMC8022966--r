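#' Trait improvement configuration
#'
#' Builds the per-trait configuration used throughout the selection pipeline:
#' the desired direction of improvement and the rule producing the truncation
#' threshold `yc`. Each trait takes either a quantile rule (the empirical
#' quantile of the observed phenotypes, e.g. `0.1` for a trait improved
#' downwards or `0.9` for one improved upwards) or a fixed threshold on the
#' phenotype scale.
#'
#' @param trait character vector of unique trait names.
#' @param direction per-trait direction of improvement, `"increase"` or
#'   `"decrease"` (recycled if scalar).
#' @param quantile per-trait quantile in (0, 1), `NA` where a fixed threshold
#'   is given.
#' @param fixed per-trait fixed threshold on the phenotype scale, `NA` where
#'   a quantile rule is given.
#'
#' @return data.frame with columns `trait`, `direction`, `quantile`, `fixed`;
#'   exactly one of `quantile`/`fixed` is non-`NA` per trait.
#'
#' @examples
#' traitConfig(c("DTHD", "GY"), direction = c("decrease", "increase"),
#'             quantile = c(0.1, NA), fixed = c(NA, 7))
#' @export
traitConfig <- function(trait, direction = "increase",
                        quantile = NA_real_, fixed = NA_real_) {
  t <- length(trait)
  stopifnot(t >= 1L, is.character(trait))
  if (anyDuplicated(trait)) stop("trait names must be unique")
  direction <- .checkDirections(direction, t)
  quantile <- rep_len(as.numeric(quantile), t)
  fixed <- rep_len(as.numeric(fixed), t)
  both <- !is.na(quantile) & !is.na(fixed)
  neither <- is.na(quantile) & is.na(fixed)
  if (any(both))
    stop("traits with both quantile and fixed rules: ",
         paste(trait[both], collapse = ", "))
  if (any(neither))
    stop("traits with no threshold rule: ", paste(trait[neither], collapse = ", "))
  bad <- !is.na(quantile) & (quantile <= 0 | quantile >= 1)
  if (any(bad))
    stop("quantile must lie strictly inside (0, 1) for trait(s): ",
         paste(trait[bad], collapse = ", "))
  data.frame(trait = trait, direction = direction,
             quantile = quantile, fixed = fixed,
             stringsAsFactors = FALSE)
}

#' Truncation thresholds from trait rules
#'
#' Turns the per-trait threshold rules into the threshold vector `yc`:
#' quantile rules are evaluated as empirical quantiles of the observed
#' phenotypes and fixed rules pass through unchanged. The quantile estimator
#' is the linear interpolation of order statistics (R's default, type 7),
#' configurable via `type` because the threshold location shifts which lines
#' the truncated parental distribution favours.
#'
#' @param phenotypes `n x t` numeric phenotype matrix with trait colnames.
#' @param config trait configuration from [traitConfig()].
#' @param type quantile algorithm passed to [stats::quantile()]; default 7.
#'
#' @return named numeric `t`-vector `yc` on the phenotype scale.
#'
#' @examples
#' y <- cbind(a = 1:5, b = 11:15)
#' thresholdsFromRules(y, traitConfig(c("a", "b"), quantile = 0.5))
#' @export
thresholdsFromRules <- function(phenotypes, config, type = 7) {
  stopifnot(is.matrix(phenotypes), !anyNA(phenotypes))
  if (nrow(config) != ncol(phenotypes))
    stop("one trait rule per phenotype column required")
  if (!is.null(colnames(phenotypes)) &&
      !identical(colnames(phenotypes), config$trait))
    stop("trait order of config does not match phenotype columns")
  yc <- vapply(seq_len(nrow(config)), function(j) {
    if (!is.na(config$fixed[j])) return(config$fixed[j])
    q <- config$quantile[j]
    if (q <= 0 || q >= 1) stop("quantile outside (0, 1)")
    unname(quantile(phenotypes[, j], probs = q, type = type))
  }, numeric(1))
  setNames(yc, config$trait)
}
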