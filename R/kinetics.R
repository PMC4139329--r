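#' Evaluate a piecewise-exponential impulse residue function
#'
#' The IRF is the fraction of an ideal instantaneous unit bolus still
#' inside the compartment at time t: it equals 1 for t below the minimal
#' transit time tau and falls exponentially at rate m afterwards,
#' continuous at t = tau.
#'
#' @param p an [IRFParams-class].
#' @param t time(s) in seconds, each >= 0.
#' @return Dimensionless value(s) in (0, 1].
#' @examples
#' p <- IRFParams(tau = 3.2, m = 0.2)
#' irfEvaluate(p, c(0, 3.2, 8.2))   # 1, 1, exp(-1)
#' @export
irfEvaluate <- function(p, t) {
  stopifnot(is(p, "IRFParams"))
  if (any(t < 0)) stop("irfEvaluate: negative time rejected")
  .irf(p@tau, p@m, t)
}

# raw (non-S4) kernels shared with the fitting hot loop
.irf <- function(tau, m, t) ifelse(t < tau, 1, exp(-m * (t - tau)))

.tubRet <- function(tauA, mA, tauT, mT, t) {
  s <- t - tauA
  x <- s - tauT
  cascade <- if (abs(mA - mT) < 1e-12 * max(mA, mT))
    mA * pmax(x, 0) * exp(-mA * pmax(x, 0))
  else
    mA * (exp(-mT * pmax(x, 0)) - exp(-mA * pmax(x, 0))) / (mA - mT)
  out <- ifelse(s <= tauT, 1 - exp(-mA * pmax(s, 0)),
                exp(-mA * pmax(x, 0)) - exp(-mA * pmax(s, 0)) + cascade)
  ifelse(s <= 0, 0, out)
}

#' Outflow density of a compartment
#'
#' The rate at which tracer leaves the compartment after a unit bolus,
#' O(t) = -d(IRF)/dt: zero before the minimal transit time, then
#' m * exp(-m * (t - tau)). Its integral over [0, Inf) is 1 (mass
#' conservation).
#'
#' @param p an [IRFParams-class].
#' @param t time(s) in seconds, each >= 0.
#' @return Density value(s) in 1/s.
#' @examples
#' outflowDensity(IRFParams(0, 0.1), 0)   # 0.1
#' @export
outflowDensity <- function(p, t) {
  stopifnot(is(p, "IRFParams"))
  if (any(t < 0)) stop("outflowDensity: negative time rejected")
  ifelse(t < p@tau, 0, p@m * exp(-p@m * (t - p@tau)))
}

# per-second flow scale: GFR (ml/min) and RPF (ml/g/min) enter the
# convolution against a nominal unit cortical ROI volume/density
flowPerSecond <- function(x) x / 60

#' Tubular retention of the 2C-IRF model in closed form
#'
#' The convolution of the vascular outflow density
#' O_A(t) = mA exp(-mA (t - tauA)) (t >= tauA) with the tubular IRF has a
#' closed form for the piecewise-exponential IRF, used as the exact kernel
#' in [retentionCurves()] and [predictCurve()] (the discrete convolution
#' engine [convCausal()] reproduces it on refined grids and serves as its
#' cross-check). With s = t - tauA:
#' zero for s <= 0; 1 - exp(-mA s) for s <= tauT; and for s > tauT the sum
#' of the plateau part exp(-mA (s - tauT)) - exp(-mA s) and the
#' two-exponential cascade
#' mA (exp(-mT x) - exp(-mA x)) / (mA - mT), x = s - tauT.
#'
#' @param irfA,irfT [IRFParams-class] of the vascular and tubular
#'   compartments.
#' @param t times (s).
#' @return Dimensionless retention values.
#' @export
tubularRetention <- function(irfA, irfT, t) {
  .tubRet(irfA@tau, irfA@m, irfT@tau, irfT@m, t)
}

#' Retention curves of the 2C-IRF model
#'
#' For a unit input to the vascular compartment A the retention of A is its
#' IRF; the tubular compartment T receives the outflow of A, so its
#' retention is the convolution of A's outflow density with T's IRF. The
#' cortical retention is the flow-weighted sum
#' RPF * R_A + GFR * R_T with the flows on the per-second scale.
#'
#' @param model a [TwoCIRFModel-class].
#' @param t uniform time grid (s) starting at 0.
#' @return A [RetentionCurves-class].
#' @examples
#' m <- twoCIRFModel(3, 3, mA = 0.2, tauA = 3.2, mT = 0.1)
#' rc <- retentionCurves(m, seq(0, 297, by = 3))
#' @export
retentionCurves <- function(model, t) {
  stopifnot(is(model, "TwoCIRFModel"))
  dt <- t[2] - t[1]
  if (model@irfA@tau > 0 && dt > model@irfA@tau)
    warning("grid spacing exceeds the vascular minimal transit time; ",
            "retention curves may be poorly resolved")
  rA <- irfEvaluate(model@irfA, t)
  rT <- tubularRetention(model@irfA, model@irfT, t)
  rCortex <- flowPerSecond(model@rpf) * rA + flowPerSecond(model@gfr) * rT
  new("RetentionCurves", t = as.numeric(t), rA = rA, rT = rT,
      rCortex = rCortex)
}

# flow-weighted impulse response of the cortex: RPF_s * IRF_A +
# GFR_s * R_T with flows converted from ml/min (ml/g/min) to per-second
kernel2cirf <- function(model, tk) {
  flowPerSecond(model@rpf) * irfEvaluate(model@irfA, tk) +
    flowPerSecond(model@gfr) * tubularRetention(model@irfA, model@irfT, tk)
}

#' @describeIn predictCurve cortical concentration of the 2C-IRF model:
#'   the plasma AIF convolved with
#'   RPF * IRF_A + GFR * (O_A conv IRF_T) (the tubular retention kernel in
#'   closed form), flows converted to per-second scale internally.
#' @export
setMethod("predictCurve", "TwoCIRFModel", function(model, aif) {
  ap <- curveValues(aif)
  if (!length(ap)) stop("empty AIF rejected")
  if (any(ap < 0)) stop("plasma AIF values must be non-negative")
  t <- curveTimes(aif)
  dt <- curveStep(aif)
  tk <- t - t[1]
  ConcCurve(t, convCausal(ap, kernel2cirf(model, tk), dt))
})

#' Mean transit time as the area under a retention curve
#'
#' Trapezoidal integral of a unit-input retention curve. When the curve has
#' not decayed below 1e-6 of its maximum at the end of the grid the area is
#' truncated: a warning is raised and the result carries attribute
#' \code{truncated = TRUE}.
#'
#' @param retention a [ConcCurve-class] holding a dimensionless retention,
#'   or a numeric vector of retention samples (then \code{dt} is required).
#' @param dt sampling interval when \code{retention} is a bare vector.
#' @return MTT in seconds (attribute \code{truncated} flags a non-decayed
#'   curve).
#' @examples
#' t <- seq(0, 120, by = 0.1)
#' meanTransitTime(ConcCurve(t, irfEvaluate(IRFParams(3.2, 0.2), t)))  # ~8.2
#' @export
meanTransitTime <- function(retention, dt = NULL) {
  if (is(retention, "ConcCurve")) {
    v <- curveValues(retention)
    dt <- curveStep(retention)
  } else {
    v <- as.numeric(retention)
    if (is.null(dt)) stop("dt required for a bare retention vector")
  }
  truncated <- v[length(v)] >= 1e-6 * max(v)
  if (truncated)
    warning("retention curve has not decayed below 1e-6 of its maximum; ",
            "MTT is truncated")
  area <- sum((v[-1] + v[-length(v)]) / 2) * dt
  structure(area, truncated = truncated)
}

#' Compartment and whole-kidney mean transit times
#'
#' Closed forms for the piecewise-exponential IRF: MTT_A = tauA + 1/mA,
#' MTT_T = tauT + 1/mT (convolution with the unit-mass vascular outflow
#' preserves the tubular area), and MTT_K = MTT_A + MTT_T.
#'
#' @param model a [TwoCIRFModel-class].
#' @return Named numeric: \code{mttA}, \code{mttT}, \code{mttK} (s).
#' @examples
#' mttSummary(twoCIRFModel(3, 3, mA = 0.2, tauA = 3.2, mT = 0.1))
#' @export
mttSummary <- function(model) {
  stopifnot(is(model, "TwoCIRFModel"))
  mttA <- model@irfA@tau + 1 / model@irfA@m
  mttT <- model@irfT@tau + 1 / model@irfT@m
  c(mttA = mttA, mttT = mttT, mttK = mttA + mttT)
}

#' @export
setMethod("modelName", "TwoCIRFModel", function(model) "2cirf")
#' @export
setMethod("modelName", "PatlakModel", function(model) "pr")
#' @export
setMethod("modelName", "TwoCModel", function(model) "2c")
#' @export
setMethod("modelName", "TwoCDModel", function(model) "2cd")
#' @export
setMethod("modelName", "SeparableModel", function(model) "sp")

#' @export
setMethod("show", "RetentionCurves", function(object) {
  cat(sprintf("RetentionCurves on %d samples (dt = %g s)\n",
              length(object@t), object@t[2] - object@t[1]))
  cat(sprintf("  area rA = %.3f s, area rT = %.3f s\n",
              sum((object@rA[-1] + object@rA[-length(object@rA)]) / 2) *
                (object@t[2] - object@t[1]),
              sum((object@rT[-1] + object@rT[-length(object@rT)]) / 2) *
                (object@t[2] - object@t[1])))
})
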