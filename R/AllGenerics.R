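#' Predict a tissue concentration curve from a plasma input
#'
#' Forward model: every kinetic model maps a plasma arterial input function
#' (AIF) to the concentration curve it predicts on the same grid. All
#' models are linear time-invariant in the AIF.
#'
#' @param model a [KineticModel-class].
#' @param aif plasma AIF as a [ConcCurve-class]; values must be >= 0 and
#'   the grid uniform.
#' @param ... model-specific options (the 2C-IRF method takes
#'   \code{oversample}).
#' @return A [ConcCurve-class] on the AIF grid (mM).
#' @export
setGeneric("predictCurve", function(model, aif, ...) standardGeneric("predictCurve"))

#' Short name token of a kinetic model
#'
#' @param model a [KineticModel-class].
#' @return One of \code{"2cirf"}, \code{"pr"}, \code{"2c"}, \code{"2cd"},
#'   \code{"sp"}.
#' @export
setGeneric("modelName", function(model) standardGeneric("modelName"))

#' Free parameters of a model as a named vector
#'
#' Used by the fitting layer; the inverse operation is
#' [modelFromParams()]. For the 2C-IRF model \code{tauT} is excluded by
#' default (fixed at 0) and included when \code{fixTauT = FALSE}.
#'
#' @param model a [KineticModel-class].
#' @param ... method options.
#' @return Named numeric vector in reporting units.
#' @export
setGeneric("modelParams", function(model, ...) standardGeneric("modelParams"))

#' @rdname curve-accessors
#' @export
setGeneric("curveTimes", function(x) standardGeneric("curveTimes"))

#' @rdname curve-accessors
#' @export
setGeneric("curveValues", function(x) standardGeneric("curveValues"))

#' @rdname curve-accessors
#' @export
setGeneric("curveStep", function(x) standardGeneric("curveStep"))
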