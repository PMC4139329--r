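#' Configuration of a nonlinear least-squares fit
#'
#' @slot model model token (\code{"2cirf"}, \code{"pr"}, \code{"2c"},
#'   \code{"2cd"}, \code{"sp"}).
#' @slot init named starting vector; defaults to mid-bounds.
#' @slot lower,upper named per-parameter bounds (reporting units).
#' @slot maxIter maximum Levenberg-Marquardt iterations per start.
#' @slot multistart number of seeded restarts; the best (lowest residual
#'   norm) is returned.
#' @slot seed integer seed for the restart jitter.
#' @slot fixTauT logical; when TRUE (default) the tubular minimal transit
#'   time of the 2C-IRF model is fixed at 0 during fitting.
#' @seealso [fitConfig()], [fitModel()]
#' @export
setClass("FitConfig",
         representation(model = "character", init = "numeric",
                        lower = "numeric", upper = "numeric",
                        maxIter = "numeric", multistart = "numeric",
                        seed = "numeric", fixTauT = "logical"))

# physiological starting values on the scale of a rabbit kidney exam:
# modest flows, bolus-scale vascular delay, slow tubular washout
defaultInit <- function(model, fixTauT = TRUE) {
  ini <- switch(model,
    "2cirf" = c(gfr = 2, rpf = 2, mA = 0.3, tauA = 3, mT = 0.05, tauT = 0),
    "pr"    = c(gfr = 2, vA = 1),
    "2c"    = c(gfr = 2, kOut = 0.05, fA = 0.3),
    "2cd"   = c(gfr = 2, kOut = 0.05, fA = 0.3, d = 1),
    "sp"    = c(gfr = 2, tT = 20, vP = 0.3, tP = 1),
    stop("unknown model token: ", model))
  if (model == "2cirf" && fixTauT) ini <- ini[names(ini) != "tauT"]
  ini
}

defaultBounds <- function(model, fixTauT = TRUE) {
  b <- switch(model,
    "2cirf" = list(lower = c(gfr = 0, rpf = 0, mA = 1e-4, tauA = 0,
                             mT = 1e-4, tauT = 0),
                   upper = c(gfr = 20, rpf = 20, mA = 2, tauA = 30,
                             mT = 2, tauT = 30)),
    "pr"    = list(lower = c(gfr = 0, vA = 0),
                   upper = c(gfr = 20, vA = 10)),
    "2c"    = list(lower = c(gfr = 0, kOut = 1e-4, fA = 0),
                   upper = c(gfr = 20, kOut = 2, fA = 5)),
    "2cd"   = list(lower = c(gfr = 0, kOut = 1e-4, fA = 0, d = 0.01),
                   upper = c(gfr = 20, kOut = 2, fA = 5, d = 30)),
    "sp"    = list(lower = c(gfr = 0, tT = 0.5, vP = 1e-3, tP = 0.01),
                   upper = c(gfr = 20, tT = 200, vP = 5, tP = 30)),
    stop("unknown model token: ", model))
  if (model == "2cirf" && fixTauT) {
    b$lower <- b$lower[names(b$lower) != "tauT"]
    b$upper <- b$upper[names(b$upper) != "tauT"]
  }
  b
}

#' Create a fit configuration
#'
#' @param model model token; see [FitConfig-class].
#' @param init optional named starting vector; defaults to physiological
#'   magnitudes (GFR and RPF 2, bolus-scale vascular delay, slow washout
#'   rates).
#' @param lower,upper optional named bounds overriding the defaults
#'   (GFR and RPF in [0, 20], washout rates in [1e-4, 2] 1/s, vascular
#'   delay in [0, 30] s).
#' @param maxIter maximum iterations per start (default 500).
#' @param multistart number of seeded restarts (default 5).
#' @param seed integer seed controlling the restart jitter (default 1).
#' @param fixTauT fix the 2C-IRF tubular delay at 0 (default TRUE).
#' @return A [FitConfig-class].
#' @examples
#' fitConfig("2cirf", multistart = 3)
#' @export
fitConfig <- function(model = "2cirf", init = NULL, lower = NULL,
                      upper = NULL, maxIter = 500, multistart = 5,
                      seed = 1, fixTauT = TRUE) {
  b <- defaultBounds(model, fixTauT)
  if (!is.null(lower)) b$lower[names(lower)] <- lower
  if (!is.null(upper)) b$upper[names(upper)] <- upper
  if (is.null(init)) init <- defaultInit(model, fixTauT)
  else {
    full <- defaultInit(model, fixTauT)
    full[names(init)] <- init
    init <- full
  }
  if (any(init < b$lower - 1e-12) || any(init > b$upper + 1e-12))
    stop("init must lie inside the bounds")
  if (maxIter < 1) stop("maxIter must be at least 1")
  new("FitConfig", model = model, init = init, lower = b$lower,
      upper = b$upper, maxIter = as.numeric(maxIter),
      multistart = as.numeric(multistart), seed = as.numeric(seed),
      fixTauT = isTRUE(fixTauT))
}

#' @export
setMethod("modelParams", "TwoCIRFModel", function(model, fixTauT = TRUE, ...) {
  p <- c(gfr = model@gfr, rpf = model@rpf, mA = model@irfA@m,
         tauA = model@irfA@tau, mT = model@irfT@m, tauT = model@irfT@tau)
  if (fixTauT) p[names(p) != "tauT"] else p
})

#' @export
setMethod("modelParams", "PatlakModel", function(model, ...)
  c(gfr = model@gfr, vA = model@vA))

#' @export
setMethod("modelParams", "TwoCModel", function(model, ...)
  c(gfr = model@gfr, kOut = model@kOut, fA = model@fA))

#' @export
setMethod("modelParams", "TwoCDModel", function(model, ...)
  c(gfr = model@gfr, kOut = model@kOut, fA = model@fA, d = model@d))

#' @export
setMethod("modelParams", "SeparableModel", function(model, ...)
  c(gfr = model@gfr, tT = model@tT, vP = model@vP, tP = model@tP))

#' Build a kinetic model from a named parameter vector
#'
#' Inverse of [modelParams()]; used by the fitting layer and the
#' command-line tools.
#'
#' @param name model token.
#' @param p named numeric vector in reporting units.
#' @return A [KineticModel-class].
#' @export
modelFromParams <- function(name, p) {
  p <- as.list(p)
  switch(name,
    "2cirf" = twoCIRFModel(p$gfr, p$rpf, mA = p$mA, tauA = p$tauA,
                           mT = p$mT,
                           tauT = if (is.null(p$tauT)) 0 else p$tauT),
    "pr"    = patlakModel(p$gfr, p$vA),
    "2c"    = twoCModel(p$gfr, p$kOut, p$fA),
    "2cd"   = twoCModel(p$gfr, p$kOut, p$fA, d = p$d),
    "sp"    = separableModel(p$gfr, p$tT, p$vP, p$tP),
    stop("unknown model token: ", name))
}

#' Coefficient of determination
#'
#' R^2 = 1 - SS_res / SS_tot with SS_tot about the mean of the observed
#' curve. A constant observed curve has SS_tot = 0; the result is then NaN
#' with a warning rather than a silent value.
#'
#' @param obs,pred numeric vectors or [ConcCurve-class] objects of equal
#'   length.
#' @return Dimensionless goodness of fit, at most 1.
#' @examples
#' rSquared(c(1, 2, 3), c(1.1, 1.9, 3.0))
#' @export
rSquared <- function(obs, pred) {
  if (is(obs, "ConcCurve")) obs <- curveValues(obs)
  if (is(pred, "ConcCurve")) pred <- curveValues(pred)
  if (length(obs) != length(pred)) stop("obs and pred must have equal length")
  ssTot <- sum((obs - mean(obs))^2)
  if (ssTot == 0) {
    warning("observed curve is constant; R^2 undefined")
    return(NaN)
  }
  1 - sum((obs - pred)^2) / ssTot
}

# model-specific forward predictor on raw vectors (positional parameter
# access); numerically identical to the predictCurve methods but without
# per-evaluation S4 construction, for the optimizer's hot loop
fastPredictor <- function(model, ap, tk, dt, fixTauT = TRUE) {
  n <- length(ap)
  N <- stats::nextn(2L * n - 1L)
  Fap <- stats::fft(c(ap, rep(0, N - n)))
  ap1 <- ap[1]
  # causal trapezoid convolution of the (cached) AIF with kernel g
  convAp <- function(g) {
    s <- Re(stats::fft(Fap * stats::fft(c(g, rep(0, N - n))),
                       inverse = TRUE))[seq_len(n)] / N
    (s - 0.5 * ap1 * g - 0.5 * ap * g[1]) * dt
  }
  switch(model,
    "2cirf" = if (fixTauT)
      function(p) convAp(p[2] / 60 * .irf(p[4], p[3], tk) +
                           p[1] / 60 * .tubRet(p[4], p[3], 0, p[5], tk))
    else
      function(p) convAp(p[2] / 60 * .irf(p[4], p[3], tk) +
                           p[1] / 60 * .tubRet(p[4], p[3], p[6], p[5], tk)),
    "pr" = {
      cum <- cumTrapz(ap, dt)
      function(p) p[2] * ap + p[1] / 60 * cum
    },
    "2c" = function(p)
      p[3] * ap + p[1] / 60 * convAp(exp(-p[2] * tk)),
    "2cd" = function(p) {
      aStar <- convAp(normalizeKernel(exp(-tk / p[4]), dt))
      p[3] * aStar + p[1] / 60 * convCausal(aStar, exp(-p[2] * tk), dt)
    },
    "sp" = function(p) {
      plasma <- convAp(normalizeKernel(exp(-tk / p[4]), dt))
      p[3] * plasma + p[1] / 60 * convCausal(plasma, exp(-tk / p[2]), dt)
    },
    stop("unknown model token: ", model))
}

# run one LM start; returns NULL on hard failure
oneStart <- function(start, obs, predict, cfg) {
  residFn <- function(p) predict(p) - obs
  tryCatch(
    minpack.lm::nls.lm(
      par = start, fn = residFn, lower = cfg@lower, upper = cfg@upper,
      control = minpack.lm::nls.lm.control(
        maxiter = cfg@maxIter, ftol = 1e-10, ptol = 1e-10)),
    error = function(e) NULL)
}

#' Fit a kinetic model to a tissue concentration curve
#'
#' Levenberg-Marquardt nonlinear least squares (plain, unweighted
#' residuals) with box bounds and seeded multistart: the first start is
#' \code{cfg@init}, the remaining \code{multistart - 1} are drawn
#' uniformly inside the bounds from a private RNG stream seeded by
#' \code{cfg@seed}, so the result is deterministic given (data, config,
#' seed) and the caller's RNG state is left untouched. The best start by
#' residual norm is returned. If every start fails, the result is flagged
#' non-converged with NA goodness of fit, never an unflagged fabricated
#' estimate.
#'
#' @param tissue observed cortical concentration [ConcCurve-class].
#' @param aif plasma AIF [ConcCurve-class] on the same grid.
#' @param cfg a [FitConfig-class] (or a model token, expanded with
#'   defaults).
#' @return A [FitResult-class].
#' @examples
#' aif <- toPlasma(makeAif(), 0.45)
#' truth <- simulationPreset("2cirf")
#' fit <- fitModel(predictCurve(truth, aif), aif, fitConfig("2cirf"))
#' modelParams(fit@model)
#' @export
fitModel <- function(tissue, aif, cfg = fitConfig("2cirf")) {
  if (is.character(cfg)) cfg <- fitConfig(cfg)
  obs <- curveValues(tissue)
  if (length(obs) != length(curveValues(aif)))
    stop("tissue and AIF must share one grid")
  if (max(abs(curveTimes(tissue) - curveTimes(aif))) > 1e-9)
    stop("tissue and AIF must share one grid")

  nStart <- max(1L, as.integer(cfg@multistart))
  starts <- vector("list", nStart)
  starts[[1]] <- cfg@init
  if (nStart > 1L) {
    oldSeed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(cfg@seed) %% .Machine$integer.max)
    for (i in seq(2L, nStart)) {
      s <- cfg@lower + stats::runif(length(cfg@init)) * (cfg@upper - cfg@lower)
      names(s) <- names(cfg@init)
      starts[[i]] <- s
    }
    if (is.null(oldSeed)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", oldSeed, envir = globalenv())
  }

  tk <- curveTimes(aif) - curveTimes(aif)[1]
  predict <- fastPredictor(cfg@model, curveValues(aif), tk,
                           curveStep(aif), cfg@fixTauT)
  best <- NULL
  for (s in starts) {
    fit <- oneStart(unname(s), obs, predict, cfg)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }

  if (is.null(best)) {
    return(new("FitResult",
               model = modelFromParams(cfg@model,
                                       (cfg@lower + cfg@upper) / 2),
               r2 = NA_real_, residualNorm = NA_real_, converged = FALSE,
               nIter = NA_real_, mtts = numeric(0)))
  }

  p <- best$par
  names(p) <- names(cfg@init)
  model <- modelFromParams(cfg@model, p)
  pred <- curveValues(predictCurve(model, aif))
  mtts <- if (cfg@model == "2cirf") mttSummary(model) else numeric(0)
  new("FitResult", model = model,
      r2 = suppressWarnings(rSquared(obs, pred)),
      residualNorm = sum((pred - obs)^2),
      converged = best$info %in% 1:3,
      nIter = as.numeric(best$niter), mtts = mtts)
}
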