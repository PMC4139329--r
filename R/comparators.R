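# Comparator forward models. All share the discrete-convolution
# conventions of the 2C-IRF model: uniform grid, causal trapezoid-weighted
# convolution scaled by dt, flows converted from ml/min to per-second.

checkAif <- function(aif) {
  if (!length(curveValues(aif))) stop("empty AIF rejected")
  invisible(aif)
}

# unit-area normalization consistent with convCausal's end weights, so
# narrow kernels (time constant below the sampling interval) still
# conserve tracer mass: conv with a long-constant input approaches
# dt * (h0/2 + h1 + ... + h_{n-1}/2); normalize that to 1
normalizeKernel <- function(h, dt) {
  area <- (sum(h) - 0.5 * h[1] - 0.5 * h[length(h)]) * dt
  h / area
}

#' @describeIn predictCurve Patlak-Rutland uptake:
#'   C(t) = vA * Ap(t) + GFR_s * cumulative integral of Ap (trapezoid);
#'   tubular outflow neglected.
#' @export
setMethod("predictCurve", "PatlakModel", function(model, aif) {
  checkAif(aif)
  ap <- curveValues(aif)
  dt <- curveStep(aif)
  ConcCurve(curveTimes(aif),
            model@vA * ap + flowPerSecond(model@gfr) * cumTrapz(ap, dt))
})

# shared 2C machinery: vascular fraction + leaky tubular compartment fed
# by the (optionally dispersed) input
predictTwoC <- function(gfr, kOut, fA, aStar, t, dt) {
  tub <- convCausal(aStar, exp(-kOut * (t - t[1])), dt)
  fA * aStar + flowPerSecond(gfr) * tub
}

#' @describeIn predictCurve simplified two-compartment model (2C):
#'   C(t) = fA * Ap(t) + GFR_s * int_0^t Ap(u) exp(-kOut (t-u)) du.
#' @export
setMethod("predictCurve", "TwoCModel", function(model, aif) {
  checkAif(aif)
  t <- curveTimes(aif)
  dt <- curveStep(aif)
  ConcCurve(t, predictTwoC(model@gfr, model@kOut, model@fA,
                           curveValues(aif), t, dt))
})

#' @describeIn predictCurve two-compartment model with vascular dispersion
#'   (2CD): the input is first convolved with a unit-area exponential
#'   kernel of time constant \code{d}, then passed through the 2C model.
#' @export
setMethod("predictCurve", "TwoCDModel", function(model, aif) {
  checkAif(aif)
  t <- curveTimes(aif)
  dt <- curveStep(aif)
  h <- normalizeKernel(exp(-(t - t[1]) / model@d), dt)
  aStar <- convCausal(curveValues(aif), h, dt)
  ConcCurve(t, predictTwoC(model@gfr, model@kOut, model@fA, aStar, t, dt))
})

#' @describeIn predictCurve separable compartment model (SP): plasma
#'   compartment with unit-area exponential impulse response of mean
#'   transit time \code{tP} scaled by \code{vP}; its outflow feeds a
#'   tubular compartment of transit time \code{tT}:
#'   C = vP * (Ap conv hP) + GFR_s * (Ap conv hP conv exp(-t/tT)).
#' @export
setMethod("predictCurve", "SeparableModel", function(model, aif) {
  checkAif(aif)
  t <- curveTimes(aif)
  dt <- curveStep(aif)
  tk <- t - t[1]
  hP <- normalizeKernel(exp(-tk / model@tP), dt)
  plasma <- convCausal(curveValues(aif), hP, dt)
  tub <- convCausal(plasma, exp(-tk / model@tT), dt)
  ConcCurve(t, model@vP * plasma + flowPerSecond(model@gfr) * tub)
})

#' Published presets of the simulation study
#'
#' The per-model ground-truth parameter sets used in the Monte Carlo
#' comparison, with GFR fixed at 3.0 ml/min for every model. Rate and time
#' constants are on the second scale of the 3 s sampling grid. The
#' three-compartment model's presets (fP = 0.18, waC = 0.2, waM = 0.08,
#' wP = 0.18) are recorded in [threeCompartmentPresets] for documentation
#' only; its functional form is not part of this package.
#'
#' @param name model token: one of \code{"2cirf"}, \code{"pr"},
#'   \code{"2c"}, \code{"2cd"}, \code{"sp"}.
#' @return The corresponding [KineticModel-class] at its preset truth.
#' @examples
#' simulationPreset("2cirf")
#' @export
simulationPreset <- function(name = c("2cirf", "pr", "2c", "2cd", "sp")) {
  switch(match.arg(name),
    "2cirf" = twoCIRFModel(gfr = 3.0, rpf = 3.0, mA = 0.2, tauA = 3.2,
                           mT = 0.1, tauT = 0),
    "pr"    = patlakModel(gfr = 3.0, vA = 2.4),
    "2c"    = twoCModel(gfr = 3.0, kOut = 0.08, fA = 0.2),
    "2cd"   = twoCModel(gfr = 3.0, kOut = 0.08, fA = 0.2, d = 0.42),
    "sp"    = separableModel(gfr = 3.0, tT = 12.5, vP = 0.2, tP = 0.42))
}

#' Three-compartment model presets (documentation constants)
#'
#' Recorded ground-truth values of the external three-compartment
#' comparator; the model itself is out of scope for this package.
#' @format Named numeric vector.
#' @export
threeCompartmentPresets <- c(gfr = 3.0, rpf = 3.0, fP = 0.18, waC = 0.2,
                             waM = 0.08, wP = 0.18)
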