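# independent oracles used across the suite

# naive O(N^2) double-loop causal trapezoid convolution: output sample k
# integrates f(u) g(t_k - u) over u = 0..t_k with half weights at the ends
convOracle <- function(f, g, dt) {
  n <- length(f)
  out <- numeric(n)
  for (k in seq_len(n)) {
    acc <- 0
    for (j in seq_len(k)) {
      w <- 1
      if (j == 1L) w <- w - 0.5
      if (j == k) w <- w - 0.5
      acc <- acc + w * f[j] * g[k - j + 1L]
    }
    out[k] <- acc * dt
  }
  out
}

# plain trapezoid integral
trapz <- function(v, dt) sum((v[-1] + v[-length(v)]) / 2) * dt

# standard simulation grid (100 frames, 3 s)
simGrid <- function() seq(0, by = 3, length.out = 100)

# preset truth of the central model
presetModel <- function() twoCIRFModel(gfr = 3, rpf = 3, mA = 0.2,
                                       tauA = 3.2, mT = 0.1, tauT = 0)

# plasma AIF under the default study conditions
presetAif <- function() toPlasma(makeAif(), hct = 0.45)

relErr <- function(est, truth) abs(est - truth) / abs(truth)
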