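#' @import methods
NULL

#' Sampled time-concentration curve
#'
#' A uniformly sampled time series, the basic data object of the package.
#' Time is in seconds and values are gadolinium concentrations in mM (or a
#' dimensionless retention when the curve represents a unit-input response).
#'
#' @slot t numeric vector of sample times (s), strictly increasing with
#'   uniform spacing.
#' @slot v numeric vector of values (mM), same length as \code{t}.
#'
#' @seealso [ConcCurve()], [curveTimes()], [curveValues()], [curveStep()]
#' @export
setClass("ConcCurve", representation(t = "numeric", v = "numeric"))

setValidity("ConcCurve", function(object) {
  msgs <- character(0)
  if (length(object@t) != length(object@v))
    msgs <- c(msgs, "t and v must have the same length")
  if (length(object@t) < 2L)
    msgs <- c(msgs, "a curve needs at least 2 samples")
  if (length(object@t) >= 2L) {
    dt <- diff(object@t)
    if (any(dt <= 0))
      msgs <- c(msgs, "t must be strictly increasing")
    else if (max(abs(dt - dt[1])) > 1e-9 * max(abs(dt[1]), 1e-12))
      msgs <- c(msgs, "t must be uniformly spaced (1e-9 relative)")
  }
  if (anyNA(object@t)) msgs <- c(msgs, "t contains NA")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ConcCurve
#'
#' @param t sample times in seconds, strictly increasing, uniform spacing.
#' @param v values (mM), same length as \code{t}.
#' @return A [ConcCurve-class] object.
#' @examples
#' cc <- ConcCurve(t = seq(0, 297, by = 3), v = rep(0, 100))
#' curveStep(cc)
#' @export
ConcCurve <- function(t, v) {
  new("ConcCurve", t = as.numeric(t), v = as.numeric(v))
}

#' Impulse residue function parameters
#'
#' The piecewise-exponential impulse residue function (IRF) of one
#' compartment: the residue of an ideal unit bolus equals 1 up to the
#' minimal transit time \code{tau} and then decays exponentially at washout
#' rate \code{m}.
#'
#' @slot tau minimal transit time (s), non-negative.
#' @slot m washout rate (1/s), strictly positive.
#' @seealso [IRFParams()], [irfEvaluate()], [outflowDensity()]
#' @export
setClass("IRFParams", representation(tau = "numeric", m = "numeric"))

setValidity("IRFParams", function(object) {
  msgs <- character(0)
  if (length(object@tau) != 1L || is.na(object@tau) || object@tau < 0)
    msgs <- c(msgs, "tau must be a single non-negative number")
  if (length(object@m) != 1L || is.na(object@m) || object@m <= 0)
    msgs <- c(msgs, "m must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

#' Construct IRF parameters
#'
#' @param tau minimal transit time (s).
#' @param m washout rate (1/s).
#' @return An [IRFParams-class] object.
#' @examples
#' IRFParams(tau = 3.2, m = 0.2)
#' @export
IRFParams <- function(tau, m) new("IRFParams", tau = as.numeric(tau), m = as.numeric(m))

#' Virtual parent of all kinetic models
#'
#' All forward models share the [predictCurve()] interface: given a plasma
#' arterial input function they predict the cortical (or whole-ROI)
#' concentration curve. Flow parameters are stored in the conventional
#' units (GFR in ml/min, RPF in ml/g/min) and converted to per-second scale
#' factors internally.
#'
#' @slot gfr glomerular filtration rate (ml/min), non-negative.
#' @export
setClass("KineticModel", representation(gfr = "numeric", "VIRTUAL"))

#' Two-compartment impulse-residue-function model (2C-IRF)
#'
#' The central model: a vascular compartment A (intrarenal arteries and
#' glomerular vessels) feeding a tubular compartment T, each described by a
#' piecewise-exponential impulse residue function. The cortical
#' concentration is the plasma input convolved with the flow-weighted sum
#' of the vascular IRF and the tubular retention (outflow density of A
#' convolved with the IRF of T).
#'
#' @slot gfr glomerular filtration rate (ml/min).
#' @slot rpf renal plasma flow (ml/g/min).
#' @slot irfA [IRFParams-class] of the vascular compartment (tauA, mA).
#' @slot irfT [IRFParams-class] of the tubular compartment (tauT, mT).
#' @seealso [twoCIRFModel()], [predictCurve()], [retentionCurves()],
#'   [mttSummary()]
#' @export
setClass("TwoCIRFModel", contains = "KineticModel",
         representation(rpf = "numeric", irfA = "IRFParams", irfT = "IRFParams"))

#' Patlak-Rutland model (PR)
#'
#' Linear uptake model with a vascular term and an irreversible-trapping
#' integral term; tubular outflow is neglected.
#'
#' @slot gfr glomerular filtration rate (ml/min).
#' @slot vA dimensionless vascular scale.
#' @export
setClass("PatlakModel", contains = "KineticModel", representation(vA = "numeric"))

#' Two-compartment model without dispersion (2C)
#'
#' Vascular fraction plus a tubular compartment with first-order outflow.
#'
#' @slot gfr glomerular filtration rate (ml/min).
#' @slot kOut tubular outflow rate (1/s).
#' @slot fA dimensionless vascular fraction.
#' @export
setClass("TwoCModel", contains = "KineticModel",
         representation(kOut = "numeric", fA = "numeric"))

#' Two-compartment model with vascular dispersion (2CD)
#'
#' As [TwoCModel-class] but the arterial input is first dispersed by a
#' normalized single-exponential kernel of time constant \code{d}.
#'
#' @slot d dispersion time constant (s), positive.
#' @export
setClass("TwoCDModel", contains = "TwoCModel", representation(d = "numeric"))

#' Separable compartment model (SP)
#'
#' Plasma compartment with exponential impulse response (mean transit time
#' \code{tP}) feeding a tubular compartment with transit time \code{tT};
#' the contrast arrival delay is assumed zero.
#'
#' @slot gfr glomerular filtration rate (ml/min).
#' @slot tT tubular transit time (s).
#' @slot vP dimensionless plasma volume fraction.
#' @slot tP plasma transit time (s).
#' @export
setClass("SeparableModel", contains = "KineticModel",
         representation(tT = "numeric", vP = "numeric", tP = "numeric"))

setValidity("KineticModel", function(object) {
  if (length(object@gfr) != 1L || is.na(object@gfr) || object@gfr < 0)
    "gfr must be a single non-negative number (ml/min)" else TRUE
})

setValidity("TwoCIRFModel", function(object) {
  msgs <- character(0)
  if (object@rpf < 0) msgs <- c(msgs, "rpf must be non-negative (ml/g/min)")
  okA <- validObject(object@irfA, test = TRUE)
  okT <- validObject(object@irfT, test = TRUE)
  if (!isTRUE(okA)) msgs <- c(msgs, paste("irfA:", okA))
  if (!isTRUE(okT)) msgs <- c(msgs, paste("irfT:", okT))
  if (length(msgs)) msgs else TRUE
})

setValidity("PatlakModel", function(object) {
  if (object@vA < 0) "vA must be non-negative" else TRUE
})

setValidity("TwoCModel", function(object) {
  msgs <- character(0)
  if (object@kOut < 0) msgs <- c(msgs, "kOut must be non-negative (1/s)")
  if (object@fA < 0) msgs <- c(msgs, "fA must be non-negative")
  if (length(msgs)) msgs else TRUE
})

setValidity("TwoCDModel", function(object) {
  if (length(object@d) != 1L || is.na(object@d) || object@d <= 0)
    "d must be a single positive dispersion constant (s)" else TRUE
})

setValidity("SeparableModel", function(object) {
  msgs <- character(0)
  if (object@tT <= 0) msgs <- c(msgs, "tT must be positive (s)")
  if (object@vP <= 0) msgs <- c(msgs, "vP must be positive")
  if (object@tP <= 0) msgs <- c(msgs, "tP must be positive (s)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a 2C-IRF model
#'
#' @param gfr glomerular filtration rate (ml/min).
#' @param rpf renal plasma flow (ml/g/min).
#' @param mA,tauA washout rate (1/s) and minimal transit time (s) of the
#'   vascular compartment.
#' @param mT,tauT washout rate (1/s) and minimal transit time (s) of the
#'   tubular compartment; \code{tauT} defaults to 0, the assumption used
#'   throughout simulation and fitting.
#' @return A [TwoCIRFModel-class].
#' @examples
#' twoCIRFModel(gfr = 3, rpf = 3, mA = 0.2, tauA = 3.2, mT = 0.1)
#' @export
twoCIRFModel <- function(gfr, rpf, mA, tauA, mT, tauT = 0) {
  new("TwoCIRFModel", gfr = as.numeric(gfr), rpf = as.numeric(rpf),
      irfA = IRFParams(tauA, mA), irfT = IRFParams(tauT, mT))
}

#' Construct a Patlak-Rutland model
#' @param gfr glomerular filtration rate (ml/min).
#' @param vA dimensionless vascular scale.
#' @return A [PatlakModel-class].
#' @export
patlakModel <- function(gfr, vA) {
  new("PatlakModel", gfr = as.numeric(gfr), vA = as.numeric(vA))
}

#' Construct a two-compartment model (2C or 2CD)
#' @param gfr glomerular filtration rate (ml/min).
#' @param kOut tubular outflow rate (1/s).
#' @param fA dimensionless vascular fraction.
#' @param d dispersion time constant (s); when given, a dispersed 2CD model
#'   is returned, otherwise the simplified 2C model.
#' @return A [TwoCModel-class] or [TwoCDModel-class].
#' @export
twoCModel <- function(gfr, kOut, fA, d = NULL) {
  if (is.null(d))
    new("TwoCModel", gfr = as.numeric(gfr), kOut = as.numeric(kOut),
        fA = as.numeric(fA))
  else
    new("TwoCDModel", gfr = as.numeric(gfr), kOut = as.numeric(kOut),
        fA = as.numeric(fA), d = as.numeric(d))
}

#' Construct a separable compartment model
#' @param gfr glomerular filtration rate (ml/min).
#' @param tT tubular transit time (s).
#' @param vP plasma volume fraction (dimensionless).
#' @param tP plasma transit time (s).
#' @return A [SeparableModel-class].
#' @export
separableModel <- function(gfr, tT, vP, tP) {
  new("SeparableModel", gfr = as.numeric(gfr), tT = as.numeric(tT),
      vP = as.numeric(vP), tP = as.numeric(tP))
}

#' Retention curves of the 2C-IRF model
#'
#' Unit-input retention of the vascular compartment (\code{rA}), of the
#' tubular compartment (\code{rT}) and the flow-weighted cortical retention
#' (\code{rCortex}), sampled on a common grid.
#'
#' @slot t time grid (s).
#' @slot rA dimensionless vascular retention.
#' @slot rT dimensionless tubular retention.
#' @slot rCortex flow-weighted cortical retention (1/s scale, flows applied
#'   on the per-second scale).
#' @seealso [retentionCurves()]
#' @export
setClass("RetentionCurves",
         representation(t = "numeric", rA = "numeric", rT = "numeric",
                        rCortex = "numeric"))

#' Result of a nonlinear least-squares model fit
#'
#' @slot model the fitted [KineticModel-class] carrying the estimates.
#' @slot r2 coefficient of determination of the fit.
#' @slot residualNorm sum of squared residuals.
#' @slot converged logical; TRUE when the optimizer met its step/cost
#'   tolerance.
#' @slot nIter iterations used by the best start.
#' @slot mtts named numeric (mttA, mttT, mttK) in seconds for the 2C-IRF
#'   model, length-0 otherwise.
#' @seealso [fitModel()]
#' @export
setClass("FitResult",
         representation(model = "KineticModel", r2 = "numeric",
                        residualNorm = "numeric", converged = "logical",
                        nIter = "numeric", mtts = "numeric"))

#' Pixel-wise parameter map
#'
#' Per-pixel GFR (and RPF for the 2C-IRF model) with quality-control
#' layers. Pixels outside the mask or whose fit failed are NA, which keeps
#' them distinct from fitted zeros.
#'
#' @slot gfr matrix/array of per-pixel GFR on the per-pixel scale
#'   (ml/min per pixel; multiply by the pixel count of a region to
#'   aggregate to a region total).
#' @slot rpf per-pixel RPF, same shape (NA-filled for models without RPF).
#' @slot r2 per-pixel coefficient of determination.
#' @slot converged logical array, TRUE where the fit converged.
#' @slot mask logical array of pixels that were attempted.
#' @slot nFailed number of in-mask pixels whose fit failed.
#' @seealso [mapPixels()], [roiMean()]
#' @export
setClass("ParameterMap",
         representation(gfr = "array", rpf = "array", r2 = "array",
                        converged = "array", mask = "array",
                        nFailed = "integer"))

setValidity("ParameterMap", function(object) {
  d <- dim(object@mask)
  same <- function(x) identical(dim(x), d)
  if (!same(object@gfr) || !same(object@r2) || !same(object@converged) ||
      !same(object@rpf))
    "all layers must share the mask's dimensions"
  else if (any(!is.na(object@gfr[!object@mask])))
    "values outside the mask must be NA"
  else TRUE
})
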