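test_that("relaxation-rate concentration conversion is linear in delta R1", {
  expect_equal(as.numeric(gdFromRelaxation(1, 1)), 0)
  expect_equal(as.numeric(gdFromRelaxation(1.0, 0.5, r1 = 4.1)),
               (1 / 0.5 - 1 / 1.0) / 4.1)
  c1 <- as.numeric(gdFromRelaxation(1.4, 0.7))
  c2 <- as.numeric(gdFromRelaxation(1.4, 1.4 / (1 + 2 * (1.4 / 0.7 - 1))))
  expect_equal(c2, 2 * c1, tolerance = 1e-12)
  neg <- gdFromRelaxation(0.8, 1.0)
  expect_lt(as.numeric(neg), 0)               # retained, not clipped
  expect_true(attr(neg, "flagged"))
  expect_error(gdFromRelaxation(-1, 0.5), "positive")
})

test_that("variable flip angle fit inverts the SPGR equation", {
  flips <- c(4, 15, 25)
  s <- spgrSignal(1000, t1 = 1.2, tr = 0.0062, flipDeg = flips)
  fit <- vfaT1Fit(s, flips, tr = 0.0062)
  expect_equal(fit$t1, 1.2, tolerance = 1e-6)
  expect_equal(fit$m0, 1000, tolerance = 1e-4)
  expect_error(vfaT1Fit(c(1, 1), c(10, 10), 0.0062), "distinct")
  # noiseless 3-angle fit equals the 2-angle closed form
  s2 <- s[c(1, 3)]; a2 <- flips[c(1, 3)] * pi / 180
  slope <- diff(s2 / sin(a2)) / diff(s2 / tan(a2))
  expect_equal(fit$t1, -0.0062 / log(slope), tolerance = 1e-9)
  # round trip over the physiological T1 range
  for (t1 in c(0.1, 0.5, 1.5, 3)) {
    ss <- spgrSignal(500, t1, 0.0062, flips)
    expect_equal(vfaT1Fit(ss, flips, 0.0062)$t1, t1,
                 tolerance = 1e-6 * t1)
  }
})

test_that("dynamic signal to concentration inverts the forward model", {
  t <- simGrid()
  p <- relaxationParams(t1Pre = 1.2)
  # known concentration curve -> T1 -> SPGR signal -> back to concentration
  conc <- curveValues(predictCurve(presetModel(), presetAif()))
  t1Post <- 1 / (1 / 1.2 + 4.1 * conc)
  sig <- spgrSignal(800, t1Post, p@tr, p@flipDeg)
  back <- dynamicToConcentration(ConcCurve(t, sig), p, nBaseline = 5)
  expect_equal(curveValues(back), conc, tolerance = 1e-6)
  # constant signal at baseline -> zero concentration
  flat <- dynamicToConcentration(ConcCurve(t, rep(700, 100)), p)
  expect_equal(curveValues(flat), rep(0, 100), tolerance = 1e-10)
  # non-invertible enhancement is flagged, not silently clipped
  bad <- sig; bad[50] <- 800 * sin(p@flipDeg * pi / 180) * 1.5
  expect_warning(res <- dynamicToConcentration(ConcCurve(t, bad), p),
                 "non-physical")
  expect_true(attr(res, "flagged")[50])
  expect_true(is.na(curveValues(res)[50]))
})

test_that("plasma conversion rescales by 1 - Hct", {
  cc <- ConcCurve(c(0, 3), c(1, 2))
  expect_equal(curveValues(toPlasma(cc, 0)), c(1, 2))
  expect_equal(curveValues(toPlasma(cc, 0.45)), c(1, 2) / 0.55,
               tolerance = 1e-12)
  expect_equal(curveValues(toPlasma(cc, 0.45))[1], 1.81818, tolerance = 1e-5)
  expect_error(toPlasma(cc, 1), "hct")
  # shape preserved: scalar multiple
  aif <- makeAif(tail = TRUE)
  r <- curveValues(toPlasma(aif, 0.3)) / pmax(curveValues(aif), 1e-12)
  expect_true(all(abs(r[curveValues(aif) > 0] - 1 / 0.7) < 1e-10))
})

test_that("biexponential tail smoothing recovers known tails and is conservative", {
  t <- simGrid()
  peakT <- 24
  rise <- pmax(1 - exp(-(t - 15) / 4), 0)
  tail <- 1.2 * exp(-0.05 * (t - peakT)) + 0.6 * exp(-0.004 * (t - peakT))
  v <- ifelse(t < peakT, 1.8 * rise, tail)
  aif <- ConcCurve(t, v)
  res <- fitAifTail(aif, tailStart = 90)
  expect_true(res$converged)
  idx <- t >= 90
  # exact recovery of a curve that is itself biexponential past tailStart
  expect_lt(max(abs(curveValues(res$curve)[idx] - v[idx])), 1e-4)
  # samples before the tail are never altered
  expect_equal(curveValues(res$curve)[!idx], v[!idx])
  # fitted tail is non-negative and non-increasing
  sm <- curveValues(res$curve)[idx]
  expect_true(all(sm >= 0) && all(diff(sm) <= 1e-12))
  # splice continuity at the joint (within 5%)
  j <- which(idx)[1]
  expect_lt(abs(curveValues(res$curve)[j] - v[j]) / v[j], 0.05)
  # monoexponential tail accepted (nested model)
  vm <- ifelse(t < peakT, 1.8 * rise, 1.5 * exp(-0.02 * (t - peakT)))
  resm <- fitAifTail(ConcCurve(t, vm), tailStart = 90)
  expect_true(resm$converged)
  expect_lt(max(abs(curveValues(resm$curve)[idx] - vm[idx])), 1e-4)
  expect_error(fitAifTail(aif, tailStart = 290), "6 samples")
})

test_that("signal to concentration round trip is identity across T1 range", {
  p <- relaxationParams(t1Pre = 0.9, tr = 0.0033, flipDeg = 15)
  conc <- seq(0, 3, length.out = 50)
  t1 <- 1 / (1 / 0.9 + 4.1 * conc)
  sig <- spgrSignal(1200, t1, 0.0033, 15)
  cc <- ConcCurve(seq(0, by = 3, length.out = 55),
                  c(spgrSignal(1200, 0.9, 0.0033, 15) * rep(1, 5), sig))
  out <- dynamicToConcentration(cc, p, nBaseline = 5)
  expect_equal(curveValues(out)[6:55], conc, tolerance = 1e-6)
})
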