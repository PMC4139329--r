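makePhantom <- function(aif, gfrLow = 2, gfrHigh = 4, nx = 6, ny = 6) {
  # left half low GFR, right half high GFR, other parameters shared
  t <- curveTimes(aif)
  low <- curveValues(predictCurve(
    twoCIRFModel(gfrLow, 3, mA = 0.2, tauA = 3.2, mT = 0.1), aif))
  high <- curveValues(predictCurve(
    twoCIRFModel(gfrHigh, 3, mA = 0.2, tauA = 3.2, mT = 0.1), aif))
  dyn <- array(0, dim = c(nx, ny, length(t)))
  for (i in seq_len(nx)) for (j in seq_len(ny))
    dyn[i, j, ] <- if (j <= ny / 2) low else high
  list(dyn = dyn,
       left = outer(rep(TRUE, nx), seq_len(ny) <= ny / 2),
       right = outer(rep(TRUE, nx), seq_len(ny) > ny / 2))
}

test_that("pixel maps recover a two-region phantom contrast", {
  aif <- presetAif()
  ph <- makePhantom(aif)
  mask <- array(TRUE, dim = dim(ph$dyn)[1:2])
  map <- mapPixels(ph$dyn, aif, mask,
                   fitConfig("2cirf", multistart = 2, seed = 3))
  expect_s4_class(map, "ParameterMap")
  expect_equal(map@nFailed, 0L)
  mL <- roiMean(map, ph$left)
  mR <- roiMean(map, ph$right)
  expect_equal(mR$mean / mL$mean, 2, tolerance = 0.05)
  # per-pixel values are the region value divided by the mask pixel count:
  # totals over each half recover the generating region GFR
  expect_equal(mL$mean * sum(mask), 2, tolerance = 0.05)
  expect_equal(mR$mean * sum(mask), 4, tolerance = 0.05)
  expect_true(all(map@r2[mask] > 0.9999))
  expect_error(mapPixels(ph$dyn, aif, array(FALSE, dim(mask))), "empty mask")
})

test_that("uniform phantom yields a uniform map and consistent ROI stats", {
  aif <- presetAif()
  t <- curveTimes(aif)
  v <- curveValues(predictCurve(presetModel(), aif))
  dyn <- array(rep(v, each = 9), dim = c(3, 3, length(t)))
  mask <- array(TRUE, dim = c(3, 3))
  map <- mapPixels(dyn, aif, mask, fitConfig("2cirf", multistart = 1))
  expect_lt(stats::sd(map@gfr[mask]) / mean(map@gfr[mask]), 1e-4)
  # roiMean over the full mask equals the global fitted mean
  full <- roiMean(map)
  expect_equal(full$mean, mean(map@gfr[mask]))
  expect_equal(full$n, 9L)
  one <- array(FALSE, dim = c(3, 3)); one[2, 2] <- TRUE
  single <- roiMean(map, one)
  expect_equal(single$mean, map@gfr[2, 2])
  expect_equal(single$sd, 0)
})

test_that("roiMean averages exactly on a checkerboard of known values", {
  mask <- array(TRUE, dim = c(2, 2))
  gfr <- array(c(1, 3, 1, 3), dim = c(2, 2))
  map <- new("ParameterMap", gfr = gfr, rpf = gfr * NA, r2 = gfr * 0 + 1,
             converged = array(TRUE, dim = c(2, 2)), mask = mask,
             nFailed = 0L)
  expect_equal(roiMean(map)$mean, 2)
  expect_equal(roiMean(map)$total, 8)
  expect_error(roiMean(map, array(FALSE, c(2, 2))), "no fitted pixels")
})

test_that("cohort statistics reproduce the reference table summaries", {
  tab <- normalKidneyTable()
  cs <- cohortStats(tab)
  s <- cs$summary
  g <- s[s$parameter == "gfr", ]
  expect_equal(g$mean, 3.03, tolerance = 0.005)
  expect_equal(g$meanL, 2.83, tolerance = 0.005)
  expect_equal(g$meanR, 3.24, tolerance = 0.005)
  expect_equal(g$sd, 1.1, tolerance = 0.05)
  expect_equal(s[s$parameter == "rpf", "mean"], 2.64, tolerance = 0.005)
  expect_equal(s[s$parameter == "mttT", "mean"], 15.1, tolerance = 0.05)
  expect_equal(s[s$parameter == "mttK", "mean"], 20.7, tolerance = 0.05)
  expect_equal(s[s$parameter == "mttA", "mean"], 5.6, tolerance = 0.05)
  # left and right kidneys agree on the flow parameters
  expect_gt(cs$tests$p[cs$tests$parameter == "gfr"], 0.05)
  expect_gt(cs$tests$p[cs$tests$parameter == "rpf"], 0.05)
  expect_gt(cs$tests$p[cs$tests$parameter == "tauA"], 0.05)
})

test_that("cohort statistics handle degenerate and malformed input", {
  tab <- normalKidneyTable()
  # identical left/right columns: t = 0, p = 1
  sym <- tab
  sym[sym$side == "R", c("gfr", "rpf", "tauA", "mttA", "mttT", "mttK", "r2")] <-
    sym[sym$side == "L", c("gfr", "rpf", "tauA", "mttA", "mttT", "mttK", "r2")]
  cs <- cohortStats(sym)
  expect_true(all(cs$tests$t == 0))
  expect_true(all(cs$tests$p == 1))
  expect_error(cohortStats(data.frame(gfr = 1:3)), "animal")
  expect_error(cohortStats(tab[1, ]), "at least 2")
  # unpaired rows are summarized but excluded from the test
  unp <- rbind(tab, data.frame(animal = 7, side = "L", gfr = 2, rpf = 2,
                               tauA = 2, mttA = 5, mttT = 10, mttK = 15,
                               r2 = 0.9))
  cs2 <- cohortStats(unp)
  expect_equal(unique(cs2$tests$df), 5)
  expect_equal(cs2$summary[cs2$summary$parameter == "gfr", "n"], 13)
})

test_that("maps and volumes round-trip through NIfTI with PNG preview", {
  dir <- withr::local_tempdir()
  arr <- array(runif(4 * 4 * 6), dim = c(4, 4, 6))
  p <- file.path(dir, "dyn.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr), p)
  expect_equal(readVolume(p), arr, tolerance = 1e-6, ignore_attr = TRUE)
  gfr <- array(NA_real_, dim = c(4, 4)); gfr[2:3, 2:3] <- 1:4
  mask <- !is.na(gfr)
  map <- new("ParameterMap", gfr = gfr, rpf = gfr, r2 = gfr * 0 + 1,
             converged = mask, mask = mask, nFailed = 0L)
  out <- file.path(dir, "gfr.nii.gz")
  writeMap(map, out)
  expect_true(file.exists(out))
  expect_true(file.exists(file.path(dir, "gfr.png")))
  back <- readVolume(out)
  expect_equal(back[2:3, 2:3], gfr[2:3, 2:3], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("parameter configs and fit results serialize as flat JSON", {
  dir <- withr::local_tempdir()
  cfgPath <- file.path(dir, "p.json")
  jsonlite::write_json(list(gfr = 3, rpf = 3, m_a = 0.2, tau_a = 3.2,
                            m_t = 0.1, tau_t = 0),
                       cfgPath, auto_unbox = TRUE)
  p <- readParamConfig(cfgPath)
  expect_equal(p, c(gfr = 3, rpf = 3, mA = 0.2, tauA = 3.2, mT = 0.1,
                    tauT = 0))
  m <- modelFromParams("2cirf", p)
  expect_equal(m@irfA@tau, 3.2)
  aif <- presetAif()
  fit <- fitModel(predictCurve(m, aif), aif, fitConfig("2cirf"))
  outPath <- file.path(dir, "fit.json")
  writeFitResult(fit, outPath)
  res <- jsonlite::read_json(outPath, simplifyVector = TRUE)
  expect_equal(res$model, "2cirf")
  expect_equal(res$params$gfr, 3, tolerance = 1e-3)
  expect_true(res$converged)
  expect_equal(res$mtt_s$mttK, res$mtt_s$mttA + res$mtt_s$mttT,
               tolerance = 1e-9)
})
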