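#' Accessors for fitted PLS path models
#'
#' Extract components of a [PLSPMResult-class] without touching slots.
#'
#' @param x a [PLSPMResult-class].
#' @return `outerWeights`, `mvLoadings`, `communalities` and
#'   `redundancies` return named lists (one element per block);
#'   `lvScores` a patients x LVs matrix; `lvCorrelations` the LV
#'   correlation matrix; `pathCoefficients` a named list per endogenous
#'   LV; `rSquared` a named numeric; `gofValue` the goodness-of-fit under
#'   the fitted variant; `orientation` the +1/-1 sign record per LV;
#'   `isConverged` a logical flag.
#' @name plspm-accessors
NULL

#' @rdname plspm-accessors
#' @export
setGeneric("outerWeights", function(x) standardGeneric("outerWeights"))
#' @rdname plspm-accessors
#' @export
setGeneric("mvLoadings", function(x) standardGeneric("mvLoadings"))
#' @rdname plspm-accessors
#' @export
setGeneric("communalities", function(x) standardGeneric("communalities"))
#' @rdname plspm-accessors
#' @export
setGeneric("redundancies", function(x) standardGeneric("redundancies"))
#' @rdname plspm-accessors
#' @export
setGeneric("lvScores", function(x) standardGeneric("lvScores"))
#' @rdname plspm-accessors
#' @export
setGeneric("lvCorrelations", function(x) standardGeneric("lvCorrelations"))
#' @rdname plspm-accessors
#' @export
setGeneric("pathCoefficients", function(x) standardGeneric("pathCoefficients"))
#' @rdname plspm-accessors
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))
#' @rdname plspm-accessors
#' @export
setGeneric("gofValue", function(x) standardGeneric("gofValue"))
#' @rdname plspm-accessors
#' @export
setGeneric("orientation", function(x) standardGeneric("orientation"))
#' @rdname plspm-accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname plspm-accessors
setMethod("outerWeights", "PLSPMResult", function(x) x@outerWeights)
#' @rdname plspm-accessors
setMethod("mvLoadings", "PLSPMResult", function(x) x@mvLoadings)
#' @rdname plspm-accessors
setMethod("communalities", "PLSPMResult", function(x) x@communalities)
#' @rdname plspm-accessors
setMethod("redundancies", "PLSPMResult", function(x) x@redundancies)
#' @rdname plspm-accessors
setMethod("lvScores", "PLSPMResult", function(x) x@lvScores)
#' @rdname plspm-accessors
setMethod("lvCorrelations", "PLSPMResult", function(x) x@lvCorrelations)
#' @rdname plspm-accessors
setMethod("pathCoefficients", "PLSPMResult", function(x) x@pathCoefficients)
#' @rdname plspm-accessors
setMethod("rSquared", "PLSPMResult", function(x) x@rSquared)
#' @rdname plspm-accessors
setMethod("gofValue", "PLSPMResult", function(x) x@gof)
#' @rdname plspm-accessors
setMethod("orientation", "PLSPMResult", function(x) x@orientation)
#' @rdname plspm-accessors
setMethod("isConverged", "PLSPMResult", function(x) x@converged)
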