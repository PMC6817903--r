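# Shared fixtures and independent oracles used across the test files.

# Published relative-area table (percent, 2 dp), samples x components.
published_relative_areas <- function() {
  m <- rbind(
    S1 = c(33.89, 26.74, 17.67, 12.21, 3.12, 2.17, 0.00, 1.57, 0.00, 2.64),
    S2 = c(14.24, 12.08, 39.50, 27.61, 2.33, 1.69, 0.75, 0.00, 1.46, 0.33),
    S3 = c(21.17, 15.70, 34.47, 22.32, 2.62, 1.64, 0.00, 0.00, 0.00, 2.08),
    S4 = c(15.15, 11.49, 38.95, 24.51, 2.52, 1.81, 1.79, 0.55, 1.91, 1.32),
    S5 = c(17.55, 13.77, 36.96, 23.72, 2.18, 1.53, 0.93, 0.43, 1.33, 1.59),
    S6 = c(3.44, 15.60, 6.39, 33.77, 4.73, 33.20, 2.86, 0.00, 0.00, 0.00),
    S7 = c(1.37, 0.00, 37.44, 37.44, 10.47, 11.87, 1.41, 0.00, 0.00, 0.00),
    S8 = c(5.86, 0.00, 10.80, 0.00, 78.14, 5.20, 0.00, 0.00, 0.00, 0.00),
    S9 = c(0.00, 0.00, 0.00, 0.00, 16.44, 83.56, 0.00, 0.00, 0.00, 0.00),
    S10 = c(9.63, 0.00, 17.09, 0.00, 58.66, 14.63, 0.00, 0.00, 0.00, 0.00))
  colnames(m) <- LETTERS[1:10]
  m
}

# Published total-area row (area units). The published row disagrees with
# the column sums of the published cells by up to 2e-4 for S3..S7.
published_totals <- function() {
  c(S1 = 21.2459, S2 = 19.2373, S3 = 27.1341, S4 = 23.5383, S5 = 23.0183,
    S6 = 7.7924, S7 = 17.3667, S8 = 14.6945, S9 = 11.4515, S10 = 3.9315)
}

# Published grey correlation grades and the two stated orderings.
published_grades_irritation <- function() {
  c(A = 0.8670, B = 0.8804, C = 0.7355, D = 0.7882, E = 0.7451,
    F = 0.7692, G = 0.8131, H = 0.8043, I = 0.8076, J = 0.8128)
}

published_grades_effectiveness <- function() {
  c(A = 0.7788, B = 0.7665, C = 0.7232, D = 0.6982, E = 0.8029,
    F = 0.7902, G = 0.8135, H = 0.8032, I = 0.8075, J = 0.8152)
}

# Brute-force grey relational coefficient oracle: literal evaluation of the
# definition with explicit loops, independent of the vectorized pipeline.
deng_oracle <- function(x0, factors, rho = 0.5) {
  x0n <- x0 / mean(x0)
  fn <- factors
  for (j in seq_len(ncol(factors))) fn[, j] <- factors[, j] / mean(factors[, j])
  delta <- matrix(0, nrow(factors), ncol(factors))
  for (j in seq_len(ncol(factors))) {
    for (k in seq_len(nrow(factors))) delta[k, j] <- abs(x0n[k] - fn[k, j])
  }
  dmin <- Inf; dmax <- -Inf
  for (j in seq_len(ncol(factors))) {
    for (k in seq_len(nrow(factors))) {
      dmin <- min(dmin, delta[k, j]); dmax <- max(dmax, delta[k, j])
    }
  }
  xi <- matrix(0, nrow(factors), ncol(factors))
  for (j in seq_len(ncol(factors))) {
    for (k in seq_len(nrow(factors))) {
      xi[k, j] <- (dmin + rho * dmax) / (delta[k, j] + rho * dmax)
    }
  }
  xi
}

# Ground truth used in the surrogate recovery experiments: effect sizes
# sized so both response channels have comparable signal-to-noise against
# sigma = 0.01 (absorbance spans ~0.5 OD units; swelling ~0.6 %).
recovery_ground_truth <- function(sd_abs = 0.01, sd_swell = 0.01) {
  ground_truth(
    coef_swell = c(A = -0.20, B = -0.25, C = -1.80, D = -2.00, E = -0.50,
                   F = -0.60, G = -0.05, H = -0.10, I = -0.08, J = -0.03) / 20,
    sd_abs = sd_abs, sd_swell = sd_swell)
}

# Simplex dose design: template-free fingerprints, constant administered
# dose, so per-component dosages cover the composition simplex.
simplex_doses <- function(n, seed) {
  fp <- generate_fingerprints(n, template = NULL, seed = seed)
  doses <- rep(12.5, n)
  names(doses) <- rownames(fp)
  peak_doses(fp, doses)
}

# A ground truth in which one component (B) overwhelmingly drives the
# absorbance readout; used for rank-recovery experiments.
dominant_irritant_truth <- function(sd_abs = 1e-3) {
  ground_truth(
    coef_abs = c(A = 0.001, B = 0.12, C = 0.001, D = 0.001, E = 0.001,
                 F = 0.001, G = 0.001, H = 0.001, I = 0.001, J = 0.001),
    baseline_abs = 0.005, sd_abs = sd_abs, sd_swell = 0.5)
}
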