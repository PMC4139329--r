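test_that("impulse residue function: plateau, continuity, exponential tail", {
  p <- IRFParams(tau = 3.2, m = 0.2)
  expect_equal(irfEvaluate(p, 0), 1)
  expect_equal(irfEvaluate(p, 3.2), 1)          # continuous at tau
  expect_equal(irfEvaluate(p, 8.2), exp(-1), tolerance = 1e-12)
  expect_error(irfEvaluate(p, -1), "negative")
  tt <- seq(0, 100, by = 0.1)
  v <- irfEvaluate(p, tt)
  expect_true(all(v > 0 & v <= 1))
  expect_true(all(diff(v) <= 0))
  expect_error(IRFParams(-1, 0.2))
  expect_error(IRFParams(3, 0))
})

test_that("outflow density has unit mass and respects the transit delay", {
  p <- IRFParams(tau = 3.2, m = 0.2)
  expect_equal(outflowDensity(p, 1.0), 0)
  expect_equal(outflowDensity(IRFParams(0, 0.1), 0), 0.1)
  # conservation: integral over [0, tau + 20/m] is 1 within 1e-4
  dt <- 5e-4
  tt <- seq(0, 3.2 + 20 / 0.2, by = dt)
  expect_equal(trapz(outflowDensity(p, tt), dt), 1, tolerance = 1e-4)
  t0 <- seq(0, 20 / 0.5, by = dt)
  expect_equal(trapz(outflowDensity(IRFParams(0, 0.5), t0), dt), 1,
               tolerance = 1e-4)
})

test_that("tubular retention matches the discrete convolution of outflow with IRF", {
  # zero-delay cascade: closed two-exponential form, checked at 10 points
  mA <- 0.2; mT <- 0.1
  ts <- seq(3, 120, length.out = 10)
  an <- (mA / (mA - mT)) * (exp(-mT * ts) - exp(-mA * ts))
  got <- tubularRetention(IRFParams(0, mA), IRFParams(0, mT), ts)
  expect_equal(got, an, tolerance = 1e-12)
  # numerical convolution reproduces the closed form on a fine grid,
  # with and without a vascular delay
  dt <- 0.01
  tf <- seq(0, 150, by = dt)
  for (tauA in c(0, 3.2)) {
    irfA <- IRFParams(tauA, mA); irfT <- IRFParams(0, mT)
    num <- convCausal(outflowDensity(irfA, tf), irfEvaluate(irfT, tf), dt)
    expect_lt(max(abs(num - tubularRetention(irfA, irfT, tf))), 5e-3 * dt / 0.01)
  }
})

test_that("retention curves: initial values, bounds, coarse-grid warning", {
  m <- presetModel()
  t <- simGrid()
  rc <- retentionCurves(m, t)
  expect_equal(rc@rA[1], 1)          # unit input
  expect_equal(rc@rT[1], 0)          # nothing has reached T at t = 0
  expect_true(all(diff(rc@rA) <= 0)) # vascular retention non-increasing
  expect_true(all(rc@rT >= 0))
  # r_T never exceeds 1 (unit-mass density convolved with a function <= 1)
  set.seed(7)
  for (i in 1:25) {
    mm <- twoCIRFModel(3, 3, mA = runif(1, 0.05, 1.5),
                       tauA = runif(1, 0, 10),
                       mT = runif(1, 0.02, 1), tauT = runif(1, 0, 5))
    expect_true(all(tubularRetention(mm@irfA, mm@irfT, seq(0, 400, 2)) <= 1 + 1e-12))
  }
  expect_warning(retentionCurves(twoCIRFModel(3, 3, 0.2, tauA = 1.5, 0.1),
                                 simGrid()),
                 "grid spacing")
})

test_that("cortex prediction is a causal LTI response to the plasma input", {
  m <- presetModel()
  t <- simGrid()
  zero <- ConcCurve(t, rep(0, 100))
  expect_equal(curveValues(predictCurve(m, zero)), rep(0, 100))
  aif <- presetAif()
  c1 <- curveValues(predictCurve(m, aif))
  c2 <- curveValues(predictCurve(m, ConcCurve(t, 2 * curveValues(aif))))
  expect_equal(c2, 2 * c1, tolerance = 1e-12)
  # impulse input: prediction equals the discrete-convolution oracle
  imp <- rep(0, 100); imp[1] <- 1 / 3   # area 1 mM s
  kern <- 3 / 60 * irfEvaluate(m@irfA, t) +
    3 / 60 * tubularRetention(m@irfA, m@irfT, t)
  expect_equal(curveValues(predictCurve(m, ConcCurve(t, imp))),
               convOracle(imp, kern, 3), tolerance = 1e-12)
  # time-shift equivariance for integral-sample shifts
  s <- 4L
  va <- curveValues(aif)
  shifted <- ConcCurve(t, c(rep(0, s), va[1:(100 - s)]))
  cs <- curveValues(predictCurve(m, shifted))
  expect_equal(cs[(s + 1):100], c1[1:(100 - s)], tolerance = 1e-10)
  expect_error(predictCurve(m, ConcCurve(t, -va)), "non-negative")
})

test_that("mean transit time integrates retention and matches closed forms", {
  # IRF areas: tau + 1/m
  dt <- 0.05
  for (pars in list(c(3.2, 0.2), c(0, 0.1))) {
    p <- IRFParams(pars[1], pars[2])
    tt <- seq(0, pars[1] + 20 / pars[2], by = dt)
    got <- meanTransitTime(ConcCurve(tt, irfEvaluate(p, tt)))
    expect_equal(as.numeric(got), pars[1] + 1 / pars[2],
                 tolerance = 5e-3 * (pars[1] + 1 / pars[2]))
  }
  # tubular retention area: tauT + 1/mT regardless of the vascular stage
  set.seed(3)
  for (i in 1:5) {
    mA <- runif(1, 0.1, 0.6); tauA <- runif(1, 0, 6)
    mT <- runif(1, 0.05, 0.3); tauT <- runif(1, 0, 4)
    tt <- seq(0, tauA + tauT + 25 / min(mA, mT), by = 0.1)
    area <- meanTransitTime(tubularRetention(IRFParams(tauA, mA),
                                             IRFParams(tauT, mT), tt),
                            dt = 0.1)
    expect_equal(as.numeric(area), tauT + 1 / mT,
                 tolerance = 5e-3 * (tauT + 1 / mT))
  }
  # non-decayed curve is flagged
  expect_warning(
    res <- meanTransitTime(ConcCurve(seq(0, 30, 3),
                                     irfEvaluate(IRFParams(0, 0.01),
                                                 seq(0, 30, 3)))),
    "truncated")
  expect_true(attr(res, "truncated"))
})

test_that("MTT summary is additive and reproduces the reference cohort rows", {
  m <- presetModel()
  s <- mttSummary(m)
  expect_equal(unname(s["mttA"]), 3.2 + 1 / 0.2)
  expect_equal(unname(s["mttT"]), 10)
  expect_equal(unname(s["mttK"]), unname(s["mttA"] + s["mttT"]))
  # vanishing vascular compartment: mttK -> mttT
  tiny <- twoCIRFModel(3, 3, mA = 1e6, tauA = 0, mT = 0.1)
  expect_equal(unname(mttSummary(tiny)["mttK"]), 10, tolerance = 1e-5)
  # every reference kidney satisfies MTT_A + MTT_T = MTT_K within rounding
  tab <- normalKidneyTable()
  expect_true(all(abs(tab$mttA + tab$mttT - tab$mttK) <= 0.01 + 1e-12))
})
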