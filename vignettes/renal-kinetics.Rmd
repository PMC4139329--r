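---
title: "Renal tracer kinetics with impulse residue functions"
author: "renalDCE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Renal tracer kinetics with impulse residue functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renalDCE)
```

# The model

Dynamic contrast-enhanced (DCE) MRI of the kidney records a gadolinium
concentration curve in the renal cortex, `C_cortex(t)`, driven by the
arterial input function (AIF) measured in the aorta, `A_0(t)`. Blood
concentration is converted to plasma concentration by
`A_p(t) = A_0(t) / (1 - Hct)` with a rabbit hematocrit of 0.45.

The central model (`2cirf`) describes the cortex as two compartments in
cascade. The vascular compartment A (intrarenal arteries and glomerular
vessels) and the tubular compartment T each carry a piecewise-exponential
impulse residue function (IRF),

    IRF_i(t) = 1               for t < tau_i
             = exp(-m_i (t - tau_i))  for t >= tau_i,

the fraction of an instantaneous unit bolus still inside compartment `i`
at time `t`. `tau_i` is the minimal transit time (s) and `m_i` the
washout rate (1/s). The outflow density of A is `O_A = -dIRF_A/dt`; the
tubules receive what A releases, so the unit-input tubular retention is
the convolution `R_T = O_A * IRF_T`, for which the package uses the exact
closed form (`tubularRetention()`). The predicted cortical curve is the
linear time-invariant response

    C_cortex(t) = A_p(t) * [ RPF_s IRF_A(t) + GFR_s R_T(t) ],

with `*` a causal convolution. `GFR` (glomerular filtration rate,
ml/min) and `RPF` (renal plasma flow, ml/g/min) are stored in their
conventional reporting units and divided by 60 to per-second scale
factors `GFR_s`, `RPF_s` against a nominal unit cortical ROI
volume/density before entering the kernel. Mean transit times follow
from the retention areas: `MTT_A = tau_A + 1/m_A`,
`MTT_T = tau_T + 1/m_T`, and `MTT_K = MTT_A + MTT_T` (convolution with a
unit-mass density preserves area, so the closed forms agree with
numerical integration of the retention curves).

Four comparator models share the same `predictCurve()` interface:

* `pr` — Patlak-Rutland: `C = vA A_p + GFR_s \int A_p`, no tubular
  outflow.
* `2c` — two-compartment: vascular fraction `fA` plus a tubular
  compartment with first-order outflow `kOut`.
* `2cd` — as `2c`, with the input first dispersed by a normalized
  exponential kernel of time constant `d`. The dispersion form is a
  reconstruction: only the preset value of `d` and the phrase "constant
  dispersion" are available for the cited original, and a unit-area
  single-exponential kernel is the standard vascular dispersion choice.
* `sp` — separable: a plasma compartment with exponential impulse
  response (mean transit time `tP`, amplitude `vP`) feeding a tubular
  compartment of transit time `tT`; contrast arrival delay assumed zero.

All preset rate and time constants are interpreted on the second scale
of the 3 s sampling grid; this is corroborated by the in-vivo tubular
transit times (13–30 s), which match `tT = 1/kOut = 12.5` s and not
12.5 min.

# Numerical choices

*Convolution.* Curves live on uniform grids (`ConcCurve` validates
spacing to 1e-9 relative). `convCausal()` implements the causal
trapezoid-consistent discrete convolution — output sample `k` uses input
samples `0..k` with half weights at both ends, scaled by the sampling
interval — via a zero-padded FFT; it matches a naive double-loop oracle
to better than 1e-10 relative and closed-form convolution pairs to
`O(dt^2)`. The tubular retention kernel itself is evaluated in closed
form, so no internal grid refinement is needed and the forward model is
exact up to the single outer convolution with the sampled AIF. Narrow
dispersion/plasma kernels (`2cd`, `sp`) are renormalized to unit
discrete area so tracer mass is conserved even when the time constant is
below the 3 s frame interval; as the time constant goes to zero the
kernel collapses to a discrete delta and the models reduce to their
undispersed limits exactly.

*Signal conversion.* The spoiled gradient-echo (SPGR) steady-state
equation `S = M0 sin(a)(1 - E1)/(1 - E1 cos(a))`, `E1 = exp(-TR/T1)`, is
the forward model; variable-flip-angle T1 mapping inverts it through the
standard `S/sin` vs `S/tan` linearization, and dynamic curves are
converted frame by frame by solving for `E1` given the baseline (mean of
the first 5 precontrast frames by default) and the precontrast T1.
Concentration follows from `Delta R1 / r1` with `r1 = 4.1` L/s/mmol.
Negative concentrations from noise are kept (clipping would bias the
fits) and flagged; frames whose enhancement implies a non-physical T1
become NA with a warning. The AIF tail (after its peak + 60 s by
default) can be replaced by a biexponential least-squares fit; samples
before the tail start are never altered, and on non-convergence the
original tail is retained.

*Fitting.* `fitModel()` minimizes unweighted squared residuals with the
Levenberg-Marquardt algorithm (`minpack.lm`), box bounds
(GFR, RPF in [0, 20]; washout rates in [1e-4, 2] 1/s; vascular delay in
[0, 30] s), step/cost tolerances of 1e-10 and at most 500 iterations per
start. The default start is a fixed physiological point (GFR = RPF = 2,
`mA = 0.3`, `tauA = 3`, `mT = 0.05`): mid-range magnitudes for a rabbit
kidney exam. Mid-bounds initialization was rejected because starts far
outside the data support (e.g. `tauA` = 15 s) let the optimizer settle
on boundary minima even for noiseless curves. Four additional starts
(five in total) are drawn uniformly inside the bounds from a private RNG
stream seeded by the config, so fits are deterministic given (data,
config, seed) and do not disturb the caller's RNG. `tauT` is fixed at 0
by default (the standard simulation assumption) and releasable with
`fixTauT = FALSE`. `R^2` uses all frames; a constant observed curve
yields NaN with a warning rather than a silent number.

# The synthetic data generator

`makeAif()` produces the artificial aortic curve of the simulation
study: 100 frames at 3 s, 5 precontrast frames at zero, bolus arrival
`t0 = 15` s, and a gamma-variate first pass
`((t - t0)/beta)^alpha exp(-(t - t0)/beta)` with `alpha = 2.5`,
`beta = 4` s, scaled to a 2.5 mM peak — the morphology of a rabbit
aortic first pass at a low contrast dose. A gamma-variate is a
first-pass description, so the default curve carries no recirculation
tail; `tail = TRUE` adds a biexponential recirculation plateau for more
realistic in-vivo-like curves. Tissue curves are generated by the
forward models themselves, and `addNoise()` adds zero-mean Gaussian
noise whose SD is a fixed fraction (2, 3, 5, 10 or 15%) of the mean
absolute value of the clean curve, the same SD at every frame, baseline
included.

What the generator does *not* emulate: measured AIFs have recirculation,
inflow artifacts and respiratory modulation; tissue noise in vivo is
neither Gaussian with time-constant SD nor independent across frames;
and partial-volume and T2* effects distort real concentration scales.
Passing simulation tests therefore demonstrates correctness of the
estimation machinery under the stated noise model, not in-vivo accuracy.

# The Monte Carlo protocol and an identifiability caveat

`runMonteCarlo()` measures estimator variability: for each noise level
it generates the clean curve from the true parameters, adds fresh noise
per trial, refits, and reports per parameter the coefficient of
variation (CV = SD/mean) and the bias (|mean − truth|/truth, in
percent). Trial fits are initialized at the ground truth with a single
start — the convention of simulation variability studies, where the
quantity of interest is the dispersion of the estimator around a known
truth; any other protocol can be studied by passing a custom
`fitConfig`. Failed fits are excluded and counted. The package default
is 2000 trials per level; the test-suite and acceptance runs use 500,
which leaves the sampling error of a CV estimate near 3% of its value.

One structural property of the 2C-IRF model deserves emphasis. Write the
cortical kernel as `RPF_s IRF_A + GFR_s R_T` with `tauT = 0`. On the
decaying side of the vascular delay both `IRF_A` and `R_T` live in the
two-dimensional function space spanned by `exp(-mA s)` and
`exp(-mT s)`, `s = t - tauA`, and a short calculation shows that the
derivative of the kernel with respect to `tauA` is exactly proportional
to its derivative with respect to `GFR` precisely when
`RPF_s = GFR_s`. The widely used simulation presets set
GFR = RPF = 3.0 in their respective units, which under the nominal
unit-volume normalization makes the two scale factors equal: the Fisher
information matrix is singular at the truth, GFR and `tauA` are locally
interchangeable, and no estimator can pin GFR tightly from a single
noisy curve there. The degeneracy is not merely local: even a noiseless
preset curve admits alternative parameter sets that reproduce it to
machine precision, so a global multistart search may return any of them
— self-consistency checks therefore use the deterministic single-start
fit from the default initialization. The package's Monte Carlo runs reflect this honestly
— GFR CV is near 13% already at 2% noise and near 21% at 10% noise,
while the well-conditioned RPF stays in the low single digits — and the
linear Patlak-Rutland comparator, with only two parameters, attains the
lowest GFR CV at most noise levels. Choosing a physical cortical volume
instead of the unit normalization separates the scale factors but
weakens the filtration signal and makes GFR conditioning worse, not
better. Reported GFR reliabilities for this model class are therefore
protocol-dependent, and fitted `tauA`/GFR pairs from single curves
should be read with this trade-off in mind. In vivo, the wide
between-kidney spread of GFR relative to RPF in the reference cohort
table (`normalKidneyTable()`) is consistent with the same weak
identifiability.

# Pixel-wise mapping and cohort statistics

`mapPixels()` fits every in-mask pixel of a dynamic series (optionally
converting signal to concentration first), warm-starting each pixel at
the ROI-mean fit, which sharply reduces failure rates. Pixel
concentration is intensive, so a pixel fit estimates the same rate
constants as the ROI fit; the stored per-pixel flow is that estimate
divided by the mask pixel count (a pixel's share of the region flow),
which makes region mean × pixel count recover the region total —
the relation between per-pixel and region-mean GFR in cortical ROI
analyses. Failed pixels are NA (distinct from fitted zeros) and counted.
`cohortStats()` summarizes per-kidney estimates (mean ± SD overall and
by side) and runs a two-sided paired t-test left vs right by animal;
identical paired columns are reported as t = 0, p = 1 rather than an
error, and unpaired rows are summarized but excluded from the test.

# Problem sizes

The shipped tests fit noiseless curves in well under a second each; the
Monte Carlo blocks use 500 trials per noise level for all five models
(about one minute in total), and the consistency property uses 60
random admissible parameter sets. The acceptance script repeats the full
5-level × 500-trial study from scratch at the command line.

# Known limitations

No B1-inhomogeneity or inflow correction; no T2* effects; no
whole-kidney (cortex + medulla) variant; no bolus-arrival estimation
beyond `tauA`; the three-compartment comparator is recorded as
documentation constants only (`threeCompartmentPresets`), its
functional form being external. Kidney segmentation and registration
are out of scope: masks are taken as given.
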