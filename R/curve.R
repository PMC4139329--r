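#' Accessors for ConcCurve
#'
#' @param x a [ConcCurve-class].
#' @return \code{curveTimes}/\code{curveValues} return numeric vectors;
#'   \code{curveStep} the (uniform) sampling interval in seconds.
#' @name curve-accessors
NULL

#' @rdname curve-accessors
#' @export
setMethod("curveTimes", "ConcCurve", function(x) x@t)

#' @rdname curve-accessors
#' @export
setMethod("curveValues", "ConcCurve", function(x) x@v)

#' @rdname curve-accessors
#' @export
setMethod("curveStep", "ConcCurve", function(x) x@t[2] - x@t[1])

#' @export
setMethod("show", "ConcCurve", function(object) {
  cat(sprintf("ConcCurve: %d samples, dt = %g s, t in [%g, %g] s\n",
              length(object@t), curveStep(object), object@t[1],
              object@t[length(object@t)]))
  cat(sprintf("  values: min %.4g, max %.4g\n",
              min(object@v), max(object@v)))
})

#' @export
setMethod("show", "IRFParams", function(object) {
  cat(sprintf("IRFParams: tau = %g s, m = %g 1/s (MTT = %g s)\n",
              object@tau, object@m, object@tau + 1 / object@m))
})

#' @export
setMethod("show", "TwoCIRFModel", function(object) {
  cat("2C-IRF model\n")
  cat(sprintf("  GFR  = %g ml/min, RPF = %g ml/g/min\n", object@gfr, object@rpf))
  cat(sprintf("  vascular: tauA = %g s, mA = %g 1/s\n",
              object@irfA@tau, object@irfA@m))
  cat(sprintf("  tubular:  tauT = %g s, mT = %g 1/s\n",
              object@irfT@tau, object@irfT@m))
})

#' @export
setMethod("show", "PatlakModel", function(object) {
  cat(sprintf("Patlak-Rutland model: GFR = %g ml/min, vA = %g\n",
              object@gfr, object@vA))
})

#' @export
setMethod("show", "TwoCModel", function(object) {
  cat(sprintf("Two-compartment model (2C): GFR = %g ml/min, kOut = %g 1/s, fA = %g\n",
              object@gfr, object@kOut, object@fA))
})

#' @export
setMethod("show", "TwoCDModel", function(object) {
  cat(sprintf(
    "Two-compartment dispersion model (2CD): GFR = %g ml/min, kOut = %g 1/s, fA = %g, d = %g s\n",
    object@gfr, object@kOut, object@fA, object@d))
})

#' @export
setMethod("show", "SeparableModel", function(object) {
  cat(sprintf(
    "Separable model (SP): GFR = %g ml/min, tT = %g s, vP = %g, tP = %g s\n",
    object@gfr, object@tT, object@vP, object@tP))
})

#' @export
setMethod("show", "FitResult", function(object) {
  cat(sprintf("Fit of %s model (%s, R^2 = %.4f, SSR = %.4g)\n",
              modelName(object@model),
              if (object@converged) "converged" else "NOT converged",
              object@r2, object@residualNorm))
  p <- modelParams(object@model)
  cat("  ", paste(sprintf("%s = %.4g", names(p), p), collapse = ", "), "\n")
  if (length(object@mtts))
    cat(sprintf("  MTT_A = %.2f s, MTT_T = %.2f s, MTT_K = %.2f s\n",
                object@mtts[["mttA"]], object@mtts[["mttT"]],
                object@mtts[["mttK"]]))
})

#' @export
setMethod("show", "ParameterMap", function(object) {
  n <- sum(object@mask)
  cat(sprintf("ParameterMap: %s pixels, %d in mask, %d failed\n",
              paste(dim(object@mask), collapse = "x"), n, object@nFailed))
  ok <- object@gfr[object@mask & !is.na(object@gfr)]
  if (length(ok))
    cat(sprintf("  per-pixel GFR: mean %.4g, range [%.4g, %.4g] ml/min\n",
                mean(ok), min(ok), max(ok)))
})

#' Causal discrete convolution on a uniform grid
#'
#' Trapezoid-consistent discretization of the continuous convolution
#' \eqn{(f \ast g)(t_k) = \int_0^{t_k} f(u) g(t_k - u) du} for two
#' functions sampled on the same uniform grid starting at 0: output sample
#' k uses input samples 0..k, with half weights at the two end points and
#' overall scaling by the sampling interval.
#'
#' @param f,g numeric vectors of equal length (samples at
#'   \code{0, dt, 2*dt, ...}).
#' @param dt sampling interval (s).
#' @return Numeric vector of the same length.
#' @examples
#' dt <- 0.01; t <- seq(0, 5, by = dt)
#' # conv of exp(-t) with itself is t*exp(-t)
#' max(abs(convCausal(exp(-t), exp(-t), dt) - t * exp(-t)))
#' @export
convCausal <- function(f, g, dt) {
  n <- length(f)
  stopifnot(length(g) == n, n >= 1L, dt > 0)
  if (n == 1L) return(0)
  # rectangle-rule convolution via zero-padded FFT (padded to a highly
  # composite length), then trapezoid end corrections
  N <- stats::nextn(2L * n - 1L)
  s <- Re(stats::fft(stats::fft(c(f, rep(0, N - n))) *
                       stats::fft(c(g, rep(0, N - n))),
                     inverse = TRUE))[seq_len(n)] / N
  (s - 0.5 * f[1] * g - 0.5 * f * g[1]) * dt
}

#' Cumulative trapezoid integral on a uniform grid
#'
#' @param v numeric samples.
#' @param dt sampling interval (s).
#' @return Numeric vector: integral of the sampled function from the first
#'   grid point to each grid point.
#' @export
cumTrapz <- function(v, dt) {
  n <- length(v)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum((v[-1] + v[-n]) / 2)) * dt
}

#' Read a curve from delimited text
#'
#' Expects two columns, \code{time_s} and \code{conc_mM}, with a header
#' line; the separator is auto-detected between comma and tab.
#'
#' @param path file path.
#' @return A [ConcCurve-class].
#' @seealso [writeCurve()]
#' @export
readCurve <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep)
  if (ncol(d) < 2L)
    stop("curve file must have two columns (time_s, conc_mM)")
  ConcCurve(d[[1]], d[[2]])
}

#' Write a curve as delimited text
#'
#' @param curve a [ConcCurve-class].
#' @param path output file path.
#' @param sep field separator (default comma).
#' @return Invisibly, the path.
#' @export
writeCurve <- function(curve, path, sep = ",") {
  d <- data.frame(time_s = curveTimes(curve), conc_mM = curveValues(curve))
  utils::write.table(d, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
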