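#' Ear-edema weight gain
#'
#' Weight gain of inflammation in the xylene ear-edema assay: the mass
#' difference between the treated (left) and untreated (right) ear punch
#' biopsies. May be negative.
#'
#' @param left,right ear punch masses (mg), both > 0.
#' @return \code{left - right} (mg).
#' @export
weight_gain <- function(left, right) {
  if (any(left <= 0) || any(right <= 0)) stopf("ear masses must be > 0")
  left - right
}

#' Ear swelling ratio
#'
#' The anti-inflammatory readout: (left - right) / right * 100, in percent.
#'
#' @param left treated-ear punch mass (mg), > 0.
#' @param right untreated-ear punch mass (mg), > 0.
#' @return Percentage, may be negative.
#' @export
ear_swelling_ratio <- function(left, right) {
  if (any(right <= 0)) stopf("right-ear mass must be > 0")
  if (any(left <= 0)) stopf("left-ear mass must be > 0")
  (left - right) / right * 100
}

#' Ground truth for the synthetic bioassay generator
#'
#' Linear additive dose-response coefficients tying each component's
#' dosage (mg/kg) to the two readouts. The default signs follow the
#' study's qualitative conclusions: A and B are irritation-dominant
#' (large positive absorbance coefficients), C and D efficacy-dominant
#' (large negative swelling coefficients), E and F moderate helpers, and
#' the minor components G-J contribute mid-level irritation and little
#' efficacy. Magnitudes are invented configuration values: the real
#' per-sample readouts were never published numerically, so the generator
#' emulates their structure, not their values.
#'
#' @param coef_abs named numeric, absorbance change per mg/kg of each
#'   component.
#' @param coef_swell named numeric, swelling-ratio change (% per mg/kg).
#' @param baseline_abs absorbance of the normal-control condition.
#' @param baseline_swell swelling ratio (%) of the untreated condition.
#' @param sd_abs,sd_swell Gaussian noise standard deviations.
#' @return Object of class \code{ground_truth}.
#' @export
ground_truth <- function(
    coef_abs = c(A = 0.060, B = 0.070, C = 0.004, D = 0.010, E = 0.006,
                 F = 0.008, G = 0.030, H = 0.015, I = 0.018, J = 0.025),
    coef_swell = c(A = -0.20, B = -0.25, C = -1.80, D = -2.00, E = -0.50,
                   F = -0.60, G = -0.05, H = -0.10, I = -0.08, J = -0.03),
    baseline_abs = 0.10, baseline_swell = 25,
    sd_abs = 0.01, sd_swell = 0.5) {
  stopifnot(length(coef_abs) == length(coef_swell),
            all(names(coef_abs) == names(coef_swell)),
            baseline_abs >= 0, baseline_swell >= 0,
            sd_abs >= 0, sd_swell >= 0)
  structure(list(coef_abs = coef_abs, coef_swell = coef_swell,
                 baseline_abs = baseline_abs, baseline_swell = baseline_swell,
                 sd_abs = sd_abs, sd_swell = sd_swell),
            class = "ground_truth")
}

#' Noise-free ground-truth responses for a dosage matrix
#'
#' The analytic mean responses of [simulate_bioassay]; used to score
#' optimized proportions against the generator's truth.
#'
#' @param doses dosage matrix (mg/kg), columns named by component.
#' @param gt a [ground_truth].
#' @return Matrix with columns \code{absorbance}, \code{swelling}.
#' @export
true_responses <- function(doses, gt) {
  if (is.vector(doses)) doses <- matrix(doses, nrow = 1,
                                        dimnames = list(NULL, names(doses)))
  lab <- colnames(doses)
  if (is.null(lab) || !all(lab %in% names(gt$coef_abs))) {
    stopf("dose columns must be named by ground-truth component labels")
  }
  abs_resp <- pmax(gt$baseline_abs + doses %*% gt$coef_abs[lab], 0)
  swell <- gt$baseline_swell + doses %*% gt$coef_swell[lab]
  cbind(absorbance = abs_resp[, 1], swelling = swell[, 1])
}

#' Generate synthetic fingerprint tables
#'
#' With a template, rows are resampled template rows with multiplicative
#' lognormal jitter of coefficient of variation \code{jitter_cv} (mean 1),
#' mimicking batch-to-batch variation around real product fingerprints.
#' Without a template, each row is a Dirichlet composition times a
#' lognormal total area.
#'
#' @param n_samples number of synthetic samples, >= 2.
#' @param template optional [peak_table] whose rows are resampled (default
#'   the bundled commercial/knockout table via [sai_peak_table]).
#' @param jitter_cv multiplicative jitter CV, >= 0; 0 reproduces template
#'   rows exactly.
#' @param dirichlet_alpha concentration vector for the template-free model.
#' @param total_area mean total area for the template-free model.
#' @param seed integer seed.
#' @return A [peak_table] with samples \code{SYN001...}.
#' @export
generate_fingerprints <- function(n_samples, template = sai_peak_table(),
                                  jitter_cv = 0.1, dirichlet_alpha = NULL,
                                  total_area = 20, seed = 1) {
  stopifnot(n_samples >= 2, jitter_cv >= 0)
  with_seed(seed, {
    if (!is.null(template)) {
      stopifnot(inherits(template, "peak_table"))
      rows <- sample.int(nrow(template), n_samples, replace = TRUE)
      areas <- unclass(template)[rows, , drop = FALSE]
      if (jitter_cv > 0) {
        sdlog <- sqrt(log(1 + jitter_cv^2))
        jit <- matrix(stats::rlnorm(length(areas), -sdlog^2 / 2, sdlog),
                      nrow(areas), ncol(areas))
        areas <- areas * jit
      }
      labels <- colnames(template)
    } else {
      if (is.null(dirichlet_alpha)) dirichlet_alpha <- rep(1, 10)
      k <- length(dirichlet_alpha)
      g <- matrix(stats::rgamma(n_samples * k, shape = dirichlet_alpha,
                                rate = 1), n_samples, k, byrow = TRUE)
      comp <- g / rowSums(g)
      tot <- stats::rlnorm(n_samples, log(total_area), 0.2)
      areas <- comp * tot
      labels <- LETTERS[seq_len(k)]
    }
    peak_table(areas, sample_ids = sprintf("SYN%03d", seq_len(n_samples)),
               component_labels = labels)
  })
}

#' Simulate bioassay readouts for dosed samples
#'
#' Linear additive dose-response: each readout is its baseline plus the
#' dot product of the sample's per-component dosages with the ground-truth
#' coefficients, plus Gaussian noise. Absorbance is floored at zero. Ear
#' masses are back-computed so that [ear_swelling_ratio] applied to them
#' reproduces the simulated swelling exactly, with the right (untreated)
#' ear fixed at a reference punch mass.
#'
#' @param doses dosage matrix (mg/kg), rows = samples, columns named by
#'   component (e.g. from [peak_doses]).
#' @param gt a [ground_truth].
#' @param right_ear_mass reference untreated punch mass (mg), default 16
#'   (a typical 8-mm mouse ear punch).
#' @param seed integer seed.
#' @return data.frame: sample, absorbance, left_ear_mass, right_ear_mass,
#'   swelling_ratio.
#' @export
simulate_bioassay <- function(doses, gt = ground_truth(),
                              right_ear_mass = 16, seed = 1) {
  stopifnot(inherits(gt, "ground_truth"), right_ear_mass > 0)
  if (is.vector(doses)) doses <- matrix(doses, nrow = 1,
                                        dimnames = list("S1", names(doses)))
  if (any(!is.finite(doses)) || any(doses < 0)) {
    stopf("dosage matrix must be finite and non-negative")
  }
  mu <- true_responses(doses, gt)
  n <- nrow(doses)
  with_seed(seed, {
    absorbance <- pmax(mu[, "absorbance"] + stats::rnorm(n, 0, gt$sd_abs), 0)
    swelling <- mu[, "swelling"] + stats::rnorm(n, 0, gt$sd_swell)
  })
  left <- right_ear_mass * (1 + swelling / 100)
  if (any(left <= 0)) {
    stopf("simulated swelling below -100%% gives non-positive ear mass; reduce effect sizes or noise")
  }
  ids <- rownames(doses)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  data.frame(sample = ids,
             absorbance = unname(absorbance),
             left_ear_mass = unname(left),
             right_ear_mass = right_ear_mass,
             swelling_ratio = unname(swelling),
             stringsAsFactors = FALSE)
}

#' The bundled commercial/knockout peak-area table
#'
#' Actual peak areas of components A-J in the five commercial injection
#' samples (S1-S5) and the five knockout samples separated from S2
#' (S6-S10).
#'
#' @return A [peak_table] of 10 samples x 10 components.
#' @export
sai_peak_table <- function() {
  read_peak_table(system.file("extdata", "sai_peak_areas.csv",
                              package = "saiopt", mustWork = TRUE))
}

#' The bundled administered doses
#'
#' 12.50 mg/kg for the commercial samples S1-S5 (three times the human
#' dose by body-surface scaling) and the stated doses for the knockout
#' samples S6-S10.
#'
#' @return Named numeric vector of doses (mg/kg).
#' @export
sai_doses <- function() {
  read_dose_table(system.file("extdata", "sai_doses.csv",
                              package = "saiopt", mustWork = TRUE))
}
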