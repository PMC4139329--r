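#' Synthetic gamma-variate arterial input function
#'
#' Generates an artificial aortic concentration curve on the standard
#' dynamic grid (100 frames, 3 s apart, the first 5 frames precontrast):
#' a gamma-variate first pass
#' amp * ((t - t0)/beta)^alpha * exp(-(t - t0)/beta) for t > t0, zero
#' before bolus arrival, plus an optional biexponential recirculation
#' tail with a smooth rise. The peak value is scaled to \code{peak} mM at
#' t0 + alpha * beta. Defaults mimic a rabbit aortic first pass: arrival
#' at 15 s (frame 6), peak about 2.5 mM at 25 s, washout to a slowly
#' decaying plateau of a few tenths of mM.
#'
#' @param t0 bolus arrival time (s).
#' @param alpha gamma-variate shape (dimensionless).
#' @param beta gamma-variate scale (s).
#' @param peak first-pass peak concentration (mM).
#' @param tail logical; add a biexponential recirculation tail. Default
#'   FALSE: a fitted gamma-variate is a first-pass description and the
#'   simulation study uses the tail-free form. Enable for more
#'   realistic in-vivo-like curves.
#' @param nFrames number of frames (default 100).
#' @param dt frame spacing (s, default 3).
#' @param nPre number of precontrast frames kept at zero; \code{t0}
#'   defaults to \code{nPre * dt} so enhancement starts right after them.
#' @return Blood-pool AIF as a [ConcCurve-class] (divide by 1 - Hct via
#'   [toPlasma()] before model fitting).
#' @examples
#' aif <- makeAif()
#' max(curveValues(aif))   # ~2.5 mM
#' @export
makeAif <- function(t0 = 15, alpha = 2.5, beta = 4, peak = 2.5,
                    tail = FALSE, nFrames = 100, dt = 3, nPre = 5) {
  stopifnot(alpha > 0, beta > 0, peak > 0)
  t <- seq(0, by = dt, length.out = nFrames)
  if (t0 >= t[nFrames]) stop("bolus arrival t0 beyond the grid end")
  s <- pmax(t - t0, 0) / beta
  amp <- peak / (alpha^alpha * exp(-alpha))
  v <- ifelse(t > t0, amp * s^alpha * exp(-s), 0)
  if (tail) {
    u <- pmax(t - t0, 0)
    rec <- (1 - exp(-u / 15)) *
      (0.30 * exp(-u / 90) + 0.15 * exp(-u / 500))
    v <- v + ifelse(t > t0, rec, 0)
  }
  v[seq_len(min(nPre, nFrames))] <- 0
  ConcCurve(t, v)
}

#' Add scaled Gaussian noise to a curve
#'
#' Zero-mean Gaussian noise whose SD is \code{level} times the mean
#' magnitude of the clean curve (mean of absolute values over all frames,
#' baseline included), the same SD at every time point. Uses the current
#' RNG stream: seed with \code{set.seed()} for reproducibility.
#'
#' @param clean a [ConcCurve-class].
#' @param level noise level as a fraction of the mean magnitude (e.g.
#'   0.05 for 5\%).
#' @return Noisy [ConcCurve-class].
#' @examples
#' set.seed(1)
#' noisy <- addNoise(makeAif(), 0.05)
#' @export
addNoise <- function(clean, level) {
  stopifnot(level > 0)
  v <- curveValues(clean)
  sdNoise <- level * mean(abs(v))
  ConcCurve(curveTimes(clean), v + stats::rnorm(length(v), 0, sdNoise))
}

#' The standard simulation noise levels
#'
#' Gaussian noise SDs as fractions of the mean curve magnitude used in the
#' reliability study: 2, 3, 5, 10 and 15 percent.
#' @format Numeric vector of fractions.
#' @export
noiseLevels <- c(0.02, 0.03, 0.05, 0.10, 0.15)

#' Monte Carlo variability study of a kinetic model
#'
#' Generates the noiseless tissue curve of \code{truth} from the given
#' plasma AIF, then for each noise level runs \code{nTrials} independent
#' noisy realizations, refits the model to each, and summarizes per
#' parameter the coefficient of variation CV = SD/mean of the estimates
#' and the bias |mean - truth| / truth * 100 (percent of the true value).
#' Non-converged fits are excluded from the summaries and counted in
#' \code{nFail}.
#'
#' @param truth a [KineticModel-class] at its ground-truth parameters.
#' @param aifPlasma plasma AIF [ConcCurve-class].
#' @param levels noise levels (fractions); default [noiseLevels].
#' @param nTrials trials per level (default 2000; 500 gives a fast run
#'   with only slightly wider sampling error).
#' @param cfg [FitConfig-class] used for every refit. The default
#'   initializes every trial at the ground truth with a single start, the
#'   usual protocol of simulation variability studies (the quantity
#'   measured is the dispersion of the estimator around a known truth);
#'   pass a custom config to study other protocols.
#' @param seed integer seed; the full table is reproducible given
#'   (truth, aif, levels, nTrials, cfg, seed).
#' @return A data.frame with columns model, noise, parameter, truth,
#'   meanEst, cv, bias, nFail, nTrials. \code{cv} is a fraction,
#'   \code{bias} a percentage.
#' @examples
#' aif <- toPlasma(makeAif(), 0.45)
#' tab <- runMonteCarlo(simulationPreset("pr"), aif, levels = 0.05,
#'                      nTrials = 20, seed = 7)
#' @export
runMonteCarlo <- function(truth, aifPlasma, levels = noiseLevels,
                          nTrials = 2000,
                          cfg = fitConfig(modelName(truth),
                                          init = modelParams(truth),
                                          multistart = 1),
                          seed = 1) {
  stopifnot(nTrials >= 1)
  clean <- predictCurve(truth, aifPlasma)
  trueP <- modelParams(truth)
  if (modelName(truth) == "2cirf" && cfg@fixTauT)
    trueP <- trueP[names(trueP) != "tauT"]
  out <- list()
  set.seed(as.integer(seed) %% .Machine$integer.max)
  for (lev in levels) {
    est <- matrix(NA_real_, nrow = nTrials, ncol = length(trueP),
                  dimnames = list(NULL, names(trueP)))
    ok <- logical(nTrials)
    for (i in seq_len(nTrials)) {
      noisy <- addNoise(clean, lev)
      fit <- fitModel(noisy, aifPlasma, cfg)
      if (fit@converged) {
        est[i, ] <- modelParams(fit@model)[names(trueP)]
        ok[i] <- TRUE
      }
    }
    e <- est[ok, , drop = FALSE]
    for (p in names(trueP)) {
      mu <- mean(e[, p])
      out[[length(out) + 1L]] <- data.frame(
        model = modelName(truth), noise = lev, parameter = p,
        truth = unname(trueP[p]), meanEst = mu,
        cv = stats::sd(e[, p]) / mu,
        bias = abs(mu - trueP[p]) / trueP[p] * 100,
        nFail = sum(!ok), nTrials = nTrials)
    }
  }
  do.call(rbind, out)
}

#' Zero-noise control of the Monte Carlo pipeline
#'
#' A single noiseless fit per model: CV is exactly 0 and bias should be
#' tiny; a quick self-consistency check of the generator-fitter loop.
#'
#' @inheritParams runMonteCarlo
#' @return A data.frame like [runMonteCarlo()]'s with cv = 0.
#' @export
zeroNoiseControl <- function(truth, aifPlasma,
                             cfg = fitConfig(modelName(truth))) {
  clean <- predictCurve(truth, aifPlasma)
  fit <- fitModel(clean, aifPlasma, cfg)
  trueP <- modelParams(truth)
  if (modelName(truth) == "2cirf" && cfg@fixTauT)
    trueP <- trueP[names(trueP) != "tauT"]
  est <- modelParams(fit@model)[names(trueP)]
  data.frame(model = modelName(truth), noise = 0, parameter = names(trueP),
             truth = unname(trueP), meanEst = unname(est), cv = 0,
             bias = abs(est - trueP) / trueP * 100,
             nFail = as.integer(!fit@converged), nTrials = 1L,
             row.names = NULL)
}

#' Plot a Monte Carlo table
#'
#' CV of a chosen parameter against noise level, one line per model
#' (requires ggplot2).
#'
#' @param tab data.frame from [runMonteCarlo()] (possibly rbind-ed over
#'   models).
#' @param parameter which parameter to plot (default "gfr").
#' @return A ggplot object.
#' @export
plotMonteCarlo <- function(tab, parameter = "gfr") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  d <- tab[tab$parameter == parameter, ]
  d$noisePct <- d$noise * 100
  d$cvPct <- d$cv * 100
  ggplot2::ggplot(d, ggplot2::aes(x = noisePct, y = cvPct,
                                  colour = model)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "noise level (% of mean magnitude)",
                  y = sprintf("CV of %s (%%)", parameter),
                  colour = "model") +
    ggplot2::theme_minimal()
}
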