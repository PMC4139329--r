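#' Pixel-wise kinetic parameter mapping
#'
#' Fits the chosen model to every in-mask pixel of a dynamic series. The
#' series is an array whose last dimension is time on the AIF grid; when
#' \code{relax} is supplied each pixel's signal curve is first converted
#' to concentration via [dynamicToConcentration()], otherwise the series
#' is taken to be concentration already. The ROI-mean curve is fitted
#' first and its estimate warm-starts every pixel fit, which sharply
#' reduces per-pixel failures. Failed pixels are NA in all layers and
#' counted.
#'
#' Per-pixel flow estimates are on the per-pixel scale (a pixel's share of
#' the ROI flow); multiply a region mean by its pixel count to aggregate
#' to a region total, as done by [roiMean()].
#'
#' @param dynamic numeric array, spatial dims x time (e.g. 64 x 64 x 100).
#' @param aifPlasma plasma AIF [ConcCurve-class]; its length must equal
#'   the series' time dimension.
#' @param mask logical array over the spatial dims; pixels to fit.
#' @param cfg a [FitConfig-class].
#' @param relax optional [RelaxationParams-class] for signal-to-
#'   concentration conversion (with \code{nBaseline} precontrast frames).
#' @param nBaseline precontrast frames for the conversion (default 5).
#' @param minR2 fits with R^2 below this are treated as failures
#'   (default 0, keep all converged fits).
#' @return A [ParameterMap-class].
#' @export
mapPixels <- function(dynamic, aifPlasma, mask, cfg = fitConfig("2cirf"),
                      relax = NULL, nBaseline = 5, minR2 = 0) {
  dims <- dim(dynamic)
  nt <- dims[length(dims)]
  sdim <- dims[-length(dims)]
  if (nt != length(curveValues(aifPlasma)))
    stop("time dimension of the series must match the AIF grid")
  mask <- array(as.logical(mask), dim = sdim)
  if (!any(mask)) stop("empty mask: no pixels to fit")

  flat <- matrix(dynamic, nrow = prod(sdim), ncol = nt)
  idx <- which(mask)
  t <- curveTimes(aifPlasma)

  toConc <- function(v) {
    if (is.null(relax)) return(v)
    curveValues(suppressWarnings(
      dynamicToConcentration(ConcCurve(t, v), relax, nBaseline)))
  }

  # ROI-mean fit as warm start
  roiCurve <- toConc(colMeans(flat[idx, , drop = FALSE]))
  roiFit <- fitModel(ConcCurve(t, roiCurve), aifPlasma, cfg)
  pixCfg <- cfg
  if (roiFit@converged) {
    # pixel concentration is intensive, so a pixel fit lives on the same
    # rate-constant scale as the ROI fit and the ROI estimate is a good
    # warm start; the per-pixel flow share is taken afterwards
    warm <- modelParams(roiFit@model)[names(cfg@init)]
    warm <- pmin(pmax(warm, cfg@lower), cfg@upper)
    pixCfg@init <- warm
    pixCfg@multistart <- 1
  }

  layer <- function() array(NA_real_, dim = sdim)
  gfr <- layer(); rpf <- layer(); r2 <- layer()
  conv <- array(FALSE, dim = sdim)
  nFailed <- 0L
  hasRpf <- cfg@model == "2cirf"

  for (i in idx) {
    v <- toConc(flat[i, ])
    if (anyNA(v)) { nFailed <- nFailed + 1L; next }
    fit <- fitModel(ConcCurve(t, v), aifPlasma, pixCfg)
    if (!fit@converged || is.na(fit@r2) || fit@r2 < minR2) {
      nFailed <- nFailed + 1L
      next
    }
    p <- modelParams(fit@model)
    gfr[i] <- p[["gfr"]] / length(idx)
    if (hasRpf) rpf[i] <- p[["rpf"]] / length(idx)
    r2[i] <- fit@r2
    conv[i] <- TRUE
  }
  new("ParameterMap", gfr = gfr, rpf = rpf, r2 = r2, converged = conv,
      mask = mask, nFailed = nFailed)
}

#' Region summary of a parameter map
#'
#' Mean and SD of the fitted per-pixel values inside an ROI, plus the
#' region total (mean times pixel count), the aggregation that relates
#' per-pixel flow to a whole-region flow.
#'
#' @param map a [ParameterMap-class].
#' @param roiMask logical array over the map's spatial dims; default the
#'   map's own mask.
#' @param layer which layer to summarize ("gfr", "rpf" or "r2").
#' @return List with \code{mean}, \code{sd}, \code{n} (fitted pixels) and
#'   \code{total} (mean * n).
#' @export
roiMean <- function(map, roiMask = NULL, layer = "gfr") {
  if (is.null(roiMask)) roiMask <- map@mask
  roiMask <- array(as.logical(roiMask), dim = dim(map@mask))
  vals <- slot(map, layer)[roiMask]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("no fitted pixels in the ROI")
  list(mean = mean(vals), sd = if (length(vals) > 1) stats::sd(vals) else 0,
       n = length(vals), total = mean(vals) * length(vals))
}

#' Reference cohort table of normal kidneys
#'
#' Per-kidney 2C-IRF estimates (GFR, RPF, vascular delay, the three mean
#' transit times and goodness of fit) for six healthy rabbits, left and
#' right kidneys. Used as the reference input for [cohortStats()] and in
#' the package's regression tests of the cohort summaries.
#'
#' @return data.frame with columns animal, side, gfr (ml/min),
#'   rpf (ml/g/min), tauA (s), mttA (s), mttT (s), mttK (s), r2.
#' @export
normalKidneyTable <- function() {
  data.frame(
    animal = rep(1:6, 2),
    side = rep(c("L", "R"), each = 6),
    gfr  = c(3.25, 3.44, 3.85, 2.92, 1.08, 2.42,
             3.58, 3.69, 3.77, 4.87, 0.94, 2.59),
    rpf  = c(2.85, 2.65, 2.15, 3.71, 2.07, 3.12,
             2.55, 2.40, 2.10, 3.04, 2.19, 2.85),
    tauA = c(2.96, 2.76, 1.85, 3.77, 1.85, 1.06,
             2.61, 2.48, 1.67, 3.19, 1.98, 1.20),
    mttA = c(5.51, 4.95, 5.91, 6.52, 4.80, 5.62,
             5.20, 4.70, 6.40, 5.92, 5.17, 6.36),
    mttT = c(13.15, 25.47, 20.81, 10.07, 6.35, 3.95,
             16.15, 30.66, 23.35, 19.42, 5.36, 6.90),
    mttK = c(18.66, 30.42, 26.72, 16.59, 11.15, 9.57,
             21.35, 35.36, 29.75, 25.34, 10.53, 13.26),
    r2   = c(0.95, 0.88, 0.97, 0.94, 0.95, 0.81,
             0.94, 0.83, 0.97, 0.94, 0.96, 0.82))
}

#' Cohort summary statistics with left-right comparison
#'
#' Group means and SDs per parameter, overall and split by side, plus a
#' two-sided paired t-test (pairing by animal) comparing left and right
#' kidneys. Rows without a partner on the other side are excluded from
#' the test but kept in the summaries.
#'
#' @param perKidney data.frame with columns \code{animal}, \code{side}
#'   ("L"/"R") and one numeric column per parameter (the layout of
#'   [normalKidneyTable()]).
#' @param params character vector of parameter columns to summarize;
#'   default all numeric columns except animal.
#' @return List with \code{summary} (data.frame: parameter, mean, sd,
#'   meanL, sdL, meanR, sdR, n) and \code{tests} (data.frame: parameter,
#'   t, df, p).
#' @examples
#' cs <- cohortStats(normalKidneyTable())
#' cs$summary[cs$summary$parameter == "gfr", ]
#' @export
cohortStats <- function(perKidney, params = NULL) {
  if (!all(c("animal", "side") %in% names(perKidney)))
    stop("perKidney needs 'animal' and 'side' columns")
  if (is.null(params))
    params <- setdiff(names(perKidney)[vapply(perKidney, is.numeric,
                                              logical(1))], "animal")
  if (nrow(perKidney) < 2L) stop("at least 2 kidneys required")
  L <- perKidney[perKidney$side == "L", ]
  R <- perKidney[perKidney$side == "R", ]
  paired <- intersect(L$animal, R$animal)
  summ <- list(); tests <- list()
  for (p in params) {
    x <- perKidney[[p]]
    summ[[p]] <- data.frame(
      parameter = p, mean = mean(x), sd = stats::sd(x),
      meanL = mean(L[[p]]), sdL = stats::sd(L[[p]]),
      meanR = mean(R[[p]]), sdR = stats::sd(R[[p]]), n = length(x))
    if (length(paired) >= 2L) {
      xl <- L[[p]][match(paired, L$animal)]
      xr <- R[[p]][match(paired, R$animal)]
      d <- xl - xr
      if (stats::sd(d) == 0) {
        # degenerate pairing (identical columns): no evidence of a
        # difference, reported as t = 0, p = 1 rather than an error
        tests[[p]] <- data.frame(parameter = p, t = 0,
                                 df = length(d) - 1, p = 1)
      } else {
        tt <- stats::t.test(xl, xr, paired = TRUE)
        tests[[p]] <- data.frame(parameter = p,
                                 t = unname(tt$statistic),
                                 df = unname(tt$parameter),
                                 p = tt$p.value)
      }
    }
  }
  list(summary = do.call(rbind, c(summ, make.row.names = FALSE)),
       tests = if (length(tests))
         do.call(rbind, c(tests, make.row.names = FALSE)) else NULL)
}

#' Read a dynamic series or mask from NIfTI
#'
#' Thin wrapper over RNifti for the standard neuroimaging voxel format.
#'
#' @param path NIfTI file path.
#' @return Numeric array (spatial dims, then time for a 4-D series).
#' @export
readVolume <- function(path) {
  as.array(RNifti::readNifti(path))
}

#' Write a parameter-map layer as NIfTI plus a PNG preview
#'
#' @param map a [ParameterMap-class].
#' @param path output NIfTI path; the PNG preview (of the first slice,
#'   NA pixels black) is written next to it unless \code{png = FALSE}.
#' @param layer which layer ("gfr", "rpf", "r2").
#' @param png write the preview image.
#' @return Invisibly, the NIfTI path.
#' @export
writeMap <- function(map, path, layer = "gfr", png = TRUE) {
  arr <- slot(map, layer)
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  if (png) {
    sl <- if (length(dim(arr)) > 2) {
      d <- dim(arr)
      array(arr, dim = c(d[1], d[2], prod(d[-(1:2)])))[, , 1]
    } else arr
    rng <- range(sl, na.rm = TRUE)
    norm <- (sl - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
    norm[is.na(norm)] <- 0
    pngPath <- sub("\\.nii(\\.gz)?$", ".png", path)
    if (pngPath == path) pngPath <- paste0(path, ".png")
    grDevices::png(pngPath, width = 4 * ncol(sl), height = 4 * nrow(sl))
    graphics::par(mar = c(0, 0, 0, 0))
    graphics::image(t(norm)[, nrow(norm):1], axes = FALSE,
                    col = grDevices::gray.colors(256, 0, 1))
    grDevices::dev.off()
  }
  invisible(path)
}

#' Read a flat key-value model configuration (JSON)
#'
#' Keys follow the on-disk convention \code{gfr, rpf, m_a, tau_a, m_t,
#' tau_t} (and the comparator models' \code{v_a, k_out, f_a, d, t_t,
#' v_p, t_p}); they are mapped to the package's camelCase parameter
#' names.
#'
#' @param path JSON file path.
#' @return Named numeric vector with camelCase names.
#' @export
readParamConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  nm <- names(raw)
  camel <- vapply(strsplit(nm, "_"), function(parts) {
    paste0(parts[1], paste0(toupper(substring(parts[-1], 1, 1)),
                            substring(parts[-1], 2), collapse = ""))
  }, character(1))
  stats::setNames(as.numeric(unlist(raw)), camel)
}

#' Serialize a fit result to JSON
#'
#' Parameters with units, goodness of fit and diagnostics, in a flat
#' structure readable by [readParamConfig()]-style tooling.
#'
#' @param fit a [FitResult-class].
#' @param path output JSON path.
#' @return Invisibly, the path.
#' @export
writeFitResult <- function(fit, path) {
  p <- as.list(modelParams(fit@model))
  out <- list(model = modelName(fit@model), params = p,
              units = list(gfr = "ml/min", rpf = "ml/g/min",
                           rates = "1/s", times = "s"),
              r2 = fit@r2, residual_norm = fit@residualNorm,
              converged = fit@converged, n_iter = fit@nIter)
  if (length(fit@mtts)) out$mtt_s <- as.list(fit@mtts)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
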