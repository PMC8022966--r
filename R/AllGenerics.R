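#' @rdname BreedingData
#' @param x,object a `BreedingData` (or other package) object
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname BreedingData
#' @export
setGeneric("relationship", function(x) standardGeneric("relationship"))

#' @rdname BreedingData
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))

#' @rdname BreedingData
#' @export
setGeneric("traitConfigOf", function(x) standardGeneric("traitConfigOf"))

#' @rdname BreedingData
#' @export
setGeneric("lineIds", function(x) standardGeneric("lineIds"))

#' @rdname BreedingData
#' @export
setGeneric("nLines", function(x) standardGeneric("nLines"))

#' @rdname BreedingData
#' @export
setGeneric("nTraits", function(x) standardGeneric("nTraits"))

#' @rdname PosteriorChain
#' @export
setGeneric("nDraws", function(x) standardGeneric("nDraws"))

#' @rdname PosteriorChain
#' @export
setGeneric("gebv", function(x) standardGeneric("gebv"))

#' @rdname PosteriorChain
#' @export
setGeneric("gebvVariance", function(x) standardGeneric("gebvVariance"))

#' @rdname PosteriorChain
#' @param k draw index
#' @export
setGeneric("chainDraw", function(x, k) standardGeneric("chainDraw"))

#' @rdname SelectionReport
#' @export
setGeneric("selectionResults", function(x) standardGeneric("selectionResults"))

#' @rdname SelectionReport
#' @export
setGeneric("overlapMatrix", function(x) standardGeneric("overlapMatrix"))

#' @rdname SelectionReport
#' @export
setGeneric("selectedLines", function(x, ...) standardGeneric("selectedLines"))
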