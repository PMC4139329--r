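#' Relaxation and acquisition parameters
#'
#' Parameters of the spoiled gradient-recalled echo (SPGR) acquisition
#' needed to convert signal into gadolinium concentration. Defaults follow
#' the dynamic protocol used throughout the package: relaxivity
#' r1 = 4.1 L/s/mmol (gadolinium in plasma at physiological temperature),
#' TR = 3.3 ms, flip angle 15 degrees.
#'
#' @slot t1Pre precontrast T1 (s).
#' @slot r1 specific T1 relaxivity (L s^-1 mmol^-1).
#' @slot tr repetition time (s).
#' @slot flipDeg flip angle (degrees), in (0, 90).
#' @export
setClass("RelaxationParams",
         representation(t1Pre = "numeric", r1 = "numeric", tr = "numeric",
                        flipDeg = "numeric"))

setValidity("RelaxationParams", function(object) {
  msgs <- character(0)
  if (object@t1Pre <= 0) msgs <- c(msgs, "t1Pre must be positive (s)")
  if (object@r1 <= 0) msgs <- c(msgs, "r1 must be positive")
  if (object@tr <= 0) msgs <- c(msgs, "tr must be positive (s)")
  if (object@flipDeg <= 0 || object@flipDeg >= 90)
    msgs <- c(msgs, "flipDeg must be in (0, 90)")
  if (length(msgs)) msgs else TRUE
})

#' @rdname RelaxationParams-class
#' @param t1Pre precontrast T1 (s).
#' @param r1 relaxivity (L s^-1 mmol^-1).
#' @param tr repetition time (s).
#' @param flipDeg flip angle (degrees).
#' @return A \code{RelaxationParams} object.
#' @export
relaxationParams <- function(t1Pre, r1 = 4.1, tr = 0.0033, flipDeg = 15) {
  new("RelaxationParams", t1Pre = as.numeric(t1Pre), r1 = as.numeric(r1),
      tr = as.numeric(tr), flipDeg = as.numeric(flipDeg))
}

#' Gadolinium concentration from relaxation rates
#'
#' Linear relation between the change in longitudinal relaxation rate and
#' concentration: C = (1/T1_post - 1/T1_pre) / r1. Negative values
#' (T1_post above T1_pre, e.g. from noise) are returned as-is; callers may
#' inspect the \code{flagged} attribute rather than have them clipped.
#'
#' @param t1Pre precontrast T1 (s).
#' @param t1Post postcontrast T1 (s), same length or length 1.
#' @param r1 specific relaxivity (L s^-1 mmol^-1), default 4.1.
#' @return Concentration(s) in mM; attribute \code{flagged} marks negative
#'   entries.
#' @examples
#' gdFromRelaxation(1.0, 0.5)    # (2 - 1)/4.1
#' @export
gdFromRelaxation <- function(t1Pre, t1Post, r1 = 4.1) {
  if (any(t1Pre <= 0) || any(t1Post <= 0)) stop("T1 values must be positive")
  conc <- (1 / t1Post - 1 / t1Pre) / r1
  structure(conc, flagged = conc < 0)
}

#' SPGR steady-state signal
#'
#' S = M0 sin(a) (1 - E1) / (1 - E1 cos(a)), E1 = exp(-TR/T1). The
#' forward model inverted by [vfaT1Fit()] and
#' [dynamicToConcentration()].
#'
#' @param m0 proton-density scale (arbitrary units).
#' @param t1 longitudinal relaxation time (s).
#' @param tr repetition time (s).
#' @param flipDeg flip angle (degrees).
#' @return Signal in the units of \code{m0}.
#' @export
spgrSignal <- function(m0, t1, tr, flipDeg) {
  a <- flipDeg * pi / 180
  e1 <- exp(-tr / t1)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Variable flip angle T1 fit
#'
#' Linearization of the SPGR equation: plotting S/sin(a) against S/tan(a)
#' gives a line of slope E1 = exp(-TR/T1) and intercept M0 (1 - E1).
#'
#' @param signals SPGR signals, one per flip angle.
#' @param flipsDeg flip angles in degrees (at least two distinct).
#' @param tr repetition time (s).
#' @return List with \code{t1} (s) and \code{m0}.
#' @examples
#' s <- spgrSignal(1000, t1 = 1.2, tr = 0.0062, flipDeg = c(4, 15, 25))
#' vfaT1Fit(s, c(4, 15, 25), tr = 0.0062)$t1   # 1.2
#' @export
vfaT1Fit <- function(signals, flipsDeg, tr) {
  if (length(signals) != length(flipsDeg))
    stop("signals and flipsDeg must have the same length")
  if (length(unique(flipsDeg)) < 2L)
    stop("at least two distinct flip angles are required")
  a <- flipsDeg * pi / 180
  y <- signals / sin(a)
  x <- signals / tan(a)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  if (is.na(slope) || slope <= 0 || slope >= 1)
    stop("VFA fit failed: slope outside (0, 1), no valid T1")
  t1 <- -tr / log(slope)
  m0 <- unname(stats::coef(fit)[1]) / (1 - slope)
  list(t1 = t1, m0 = m0)
}

# invert the SPGR equation for T1 given signal and M0; E1 outside (0, 1)
# means the signal is not attainable for any positive T1
invertSpgr <- function(s, m0, tr, flipDeg) {
  a <- flipDeg * pi / 180
  e1 <- (m0 * sin(a) - s) / (m0 * sin(a) - s * cos(a))
  t1 <- ifelse(e1 > 0 & e1 < 1, -tr / log(e1), NA_real_)
  t1
}

#' Convert a dynamic SPGR signal curve to gadolinium concentration
#'
#' The baseline signal is the mean of the first \code{nBaseline}
#' precontrast frames; it pins the proton-density scale given the
#' precontrast T1. Each frame's postcontrast T1 is then solved from the
#' SPGR equation and converted with [gdFromRelaxation()]. Frames whose
#' enhancement implies a non-physical T1 are returned as NA and flagged.
#'
#' @param curve signal-intensity [ConcCurve-class] (values in scanner
#'   units).
#' @param params a [RelaxationParams-class] (carries the precontrast T1).
#' @param nBaseline number of precontrast frames averaged for the
#'   baseline; default 5.
#' @return A [ConcCurve-class] in mM; attribute \code{flagged} marks
#'   non-invertible frames.
#' @export
dynamicToConcentration <- function(curve, params, nBaseline = 5) {
  stopifnot(is(params, "RelaxationParams"))
  s <- curveValues(curve)
  if (nBaseline < 1 || nBaseline > length(s))
    stop("nBaseline must be between 1 and the number of frames")
  sBase <- mean(s[seq_len(nBaseline)])
  a <- params@flipDeg * pi / 180
  e1 <- exp(-params@tr / params@t1Pre)
  m0 <- sBase * (1 - e1 * cos(a)) / (sin(a) * (1 - e1))
  t1Post <- invertSpgr(s, m0, params@tr, params@flipDeg)
  flagged <- is.na(t1Post)
  if (any(flagged))
    warning(sum(flagged), " frame(s) imply a non-physical T1 and were flagged")
  conc <- rep(NA_real_, length(s))
  conc[!flagged] <- gdFromRelaxation(params@t1Pre, t1Post[!flagged], params@r1)
  structure(ConcCurve(curveTimes(curve), ifelse(flagged, NA_real_, conc)),
            flagged = flagged)
}

#' Convert blood concentration to plasma concentration
#'
#' Pointwise division by (1 - Hct). The default hematocrit 0.45 is the
#' rabbit value used throughout the package.
#'
#' @param aif blood-pool AIF as a [ConcCurve-class].
#' @param hct hematocrit in [0, 1).
#' @return Plasma AIF as a [ConcCurve-class].
#' @examples
#' toPlasma(ConcCurve(c(0, 3), c(1, 1)), hct = 0.45)  # values 1/0.55
#' @export
toPlasma <- function(aif, hct = 0.45) {
  if (hct < 0 || hct >= 1) stop("hct must be in [0, 1)")
  ConcCurve(curveTimes(aif), curveValues(aif) / (1 - hct))
}

#' Biexponential smoothing of the AIF tail
#'
#' Respiratory motion contaminates the slow washout of the aortic curve;
#' the samples after \code{tailStart} are fit to
#' a1 exp(-b1 t) + a2 exp(-b2 t) by Levenberg-Marquardt least squares and
#' replaced by the fit. Samples before \code{tailStart} are never altered.
#' On non-convergence the original tail is retained with a warning.
#'
#' @param aif a [ConcCurve-class].
#' @param tailStart time (s) at which the tail begins; default is the time
#'   of the AIF peak plus 60 s.
#' @return List with \code{curve} (tail-smoothed [ConcCurve-class]),
#'   \code{params} (named a1, b1, a2, b2) and \code{converged}.
#' @export
fitAifTail <- function(aif, tailStart = NULL) {
  t <- curveTimes(aif)
  v <- curveValues(aif)
  if (is.null(tailStart)) tailStart <- t[which.max(v)] + 60
  idx <- which(t >= tailStart)
  if (length(idx) < 6L) stop("tail must contain at least 6 samples")
  tt <- t[idx] - t[idx[1]]
  vv <- v[idx]
  # starting values: slow rate from the last half, fast from the first
  rate0 <- function(sel) {
    p <- pmax(vv[sel], max(vv) * 1e-6)
    f <- stats::lm(log(p) ~ tt[sel])
    max(-unname(stats::coef(f)[2]), 1e-6)
  }
  n2 <- length(idx)
  bSlow <- rate0(seq(ceiling(n2 / 2), n2))
  bFast <- max(rate0(seq_len(ceiling(n2 / 2))), bSlow * 5)
  start <- c(a1 = max(vv[1] * 0.5, 1e-6), b1 = bFast,
             a2 = max(vv[1] * 0.5, 1e-6), b2 = bSlow)
  resid <- function(p) vv - (p[1] * exp(-p[2] * tt) + p[3] * exp(-p[4] * tt))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid,
                       lower = rep(0, 4), upper = rep(Inf, 4),
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  ok <- !is.null(fit) && fit$info %in% 1:4
  if (!ok) {
    warning("biexponential tail fit did not converge; original tail retained")
    return(list(curve = aif,
                params = c(a1 = NA_real_, b1 = NA_real_, a2 = NA_real_,
                           b2 = NA_real_),
                converged = FALSE))
  }
  p <- fit$par
  v[idx] <- p[1] * exp(-p[2] * tt) + p[3] * exp(-p[4] * tt)
  list(curve = ConcCurve(t, v),
       params = c(a1 = unname(p[1]), b1 = unname(p[2]),
                  a2 = unname(p[3]), b2 = unname(p[4])),
       converged = TRUE)
}
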