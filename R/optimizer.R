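#' Per-component proportion ranges for candidate sampling
#'
#' The published search box, set from the grey correlation ranking and the
#' commercial samples' original proportion: lower A and B (irritation
#' leaders), raise C, D, E and F.
#'
#' @param ranges named list or 2-row matrix of \code{c(lo, hi)} intervals
#'   in proportion units; defaults to the published box
#'   A 0.5-4, B 0.5-3, C 5-10, D 1.5-6.5, E 0.5-3.5, F 0.5-3.5.
#' @return Object of class \code{component_ranges}: 2 x k matrix with rows
#'   \code{lo}, \code{hi}.
#' @export
component_ranges <- function(ranges = list(A = c(0.5, 4), B = c(0.5, 3),
                                           C = c(5, 10), D = c(1.5, 6.5),
                                           E = c(0.5, 3.5), F = c(0.5, 3.5))) {
  if (is.list(ranges)) {
    m <- vapply(ranges, function(r) as.numeric(r[1:2]), numeric(2))
  } else {
    m <- as.matrix(ranges)
  }
  if (nrow(m) != 2L || !ncol(m)) stopf("ranges must be c(lo, hi) per component")
  if (is.null(colnames(m))) stopf("ranges must be named by component label")
  if (any(!is.finite(m)) || any(m < 0)) stopf("range bounds must be finite and >= 0")
  if (any(m[1, ] > m[2, ])) {
    stopf("lower bound exceeds upper bound for component '%s'",
          colnames(m)[which(m[1, ] > m[2, ])[1]])
  }
  rownames(m) <- c("lo", "hi")
  structure(m, class = c("component_ranges", "matrix", "array"))
}

#' Response acceptance criteria
#'
#' Candidates are accepted only if both predicted responses fall strictly
#' below these thresholds. The published criteria (absorbance < 0.539,
#' ear swelling ratio < 19.198 %) correspond to the normal-control group's
#' readouts; they are configuration defaults here, not derived quantities.
#'
#' @param absorbance_max strict upper bound on predicted absorbance.
#' @param swelling_max strict upper bound on predicted swelling ratio (%).
#' @return Object of class \code{acceptance_criteria}.
#' @export
acceptance_criteria <- function(absorbance_max = 0.539, swelling_max = 19.198) {
  # +/-Inf allowed: an open criterion accepts everything, an impossible one
  # exercises the empty-feasible-set path
  stopifnot(is.numeric(absorbance_max), length(absorbance_max) == 1L,
            !is.na(absorbance_max),
            is.numeric(swelling_max), length(swelling_max) == 1L,
            !is.na(swelling_max))
  structure(list(absorbance_max = absorbance_max, swelling_max = swelling_max),
            class = "acceptance_criteria")
}

meets_criteria <- function(responses, criteria) {
  responses[, 1] < criteria$absorbance_max & responses[, 2] < criteria$swelling_max
}

#' Draw candidate proportion vectors
#'
#' Each component is drawn independently and uniformly within its interval
#' (the maximum-entropy choice for a plain box constraint).
#'
#' @param ranges a [component_ranges].
#' @param n number of candidates.
#' @param seed optional integer seed.
#' @return n x k matrix of proportion vectors, columns named by component.
#' @export
sample_candidates <- function(ranges, n = 1, seed = NULL) {
  stopifnot(inherits(ranges, "component_ranges"), n >= 1)
  k <- ncol(ranges)
  with_seed(seed, {
    u <- matrix(stats::runif(n * k), n, k)
    cand <- sweep(u, 2, ranges["hi", ] - ranges["lo", ], "*")
    cand <- sweep(cand, 2, ranges["lo", ], "+")
    colnames(cand) <- colnames(ranges)
    cand
  })
}

#' Embed candidate proportions as surrogate dosage inputs
#'
#' The surrogate is trained on per-component dosages (mg/kg), while
#' candidates live in dimensionless proportion units over a subset of
#' components (A-F; the minor components G-J are fixed at zero, having
#' been flagged for elimination). The bridge rescales each candidate so
#' its embedded dosage total equals a reference administered dose.
#'
#' @param candidates matrix of proportion vectors (cols named A..F etc.).
#' @param input_labels full component label set of the surrogate input,
#'   in order (e.g. A..J).
#' @param reference_dose total administered dose the embedded vector
#'   represents, default 12.50 mg/kg (the commercial-sample dose).
#' @return Matrix with \code{length(input_labels)} columns; non-candidate
#'   components are zero and each row sums to \code{reference_dose}.
#' @export
embed_candidates <- function(candidates, input_labels,
                             reference_dose = 12.50) {
  if (is.vector(candidates)) candidates <- matrix(candidates, nrow = 1,
                                                  dimnames = list(NULL, names(candidates)))
  assert_scalar_number(reference_dose, "reference_dose", positive = TRUE)
  if (is.null(colnames(candidates))) stopf("candidates must have component names")
  unknown <- setdiff(colnames(candidates), input_labels)
  if (length(unknown)) stopf("candidate component '%s' not a surrogate input", unknown[1])
  tot <- rowSums(candidates)
  if (any(tot <= 0)) stopf("candidate row %d is all zero", which(tot <= 0)[1])
  out <- matrix(0, nrow(candidates), length(input_labels),
                dimnames = list(rownames(candidates), input_labels))
  out[, colnames(candidates)] <- sweep(candidates, 1, reference_dose / tot, "*")
  out
}

#' Screen sampled candidates through the surrogate
#'
#' Draws candidates uniformly in the box, predicts both responses through
#' the surrogate, and keeps candidates strictly satisfying the criteria,
#' until \code{target_size} are accepted or \code{max_draws} are
#' exhausted. Deterministic given the seed.
#'
#' @param model a fitted \code{bp_surrogate}, or a function taking the
#'   embedded dosage matrix and returning a 2-column response matrix
#'   (useful for synthetic closed-form surrogates).
#' @param ranges a [component_ranges].
#' @param criteria an [acceptance_criteria].
#' @param target_size accepted candidates wanted, default 50 (published
#'   choice).
#' @param max_draws draw budget, default 1e5.
#' @param seed integer seed.
#' @param input_labels surrogate input labels; defaults to the model's own
#'   labels for a \code{bp_surrogate}.
#' @param reference_dose see [embed_candidates].
#' @param batch draws per screening batch.
#' @return Object of class \code{candidate_set}: \code{proportions}
#'   (accepted rows), \code{responses} (their predictions),
#'   \code{draws_used}, \code{acceptance_rate}, plus the configuration.
#' @export
screen_candidates <- function(model, ranges, criteria, target_size = 50,
                              max_draws = 1e5, seed = 1,
                              input_labels = NULL, reference_dose = 12.50,
                              batch = 1000) {
  stopifnot(inherits(ranges, "component_ranges"),
            inherits(criteria, "acceptance_criteria"),
            target_size >= 1, max_draws >= 1)
  if (is.null(input_labels)) {
    input_labels <- if (inherits(model, "bp_surrogate")) model$input_labels
                    else colnames(ranges)
  }
  accepted_p <- NULL
  accepted_r <- NULL
  draws <- 0L
  with_seed(seed, {
    while (draws < max_draws && NROW(accepted_p) < target_size) {
      m <- min(batch, max_draws - draws)
      cand <- sample_candidates(ranges, m)
      draws <- draws + m
      resp <- predict_responses(model, embed_candidates(cand, input_labels,
                                                        reference_dose))
      ok <- meets_criteria(resp, criteria)
      if (any(ok)) {
        accepted_p <- rbind(accepted_p, cand[ok, , drop = FALSE])
        accepted_r <- rbind(accepted_r, resp[ok, , drop = FALSE])
      }
    }
  })
  if (is.null(accepted_p)) {
    probe <- predict_responses(model,
      embed_candidates(sample_candidates(ranges, 512, seed = seed),
                       input_labels, reference_dose))
    stopf(paste0("no candidate met the criteria in %d draws; surrogate ",
                 "response range over the box: absorbance [%.4g, %.4g], ",
                 "swelling [%.4g, %.4g]"),
          draws, min(probe[, 1]), max(probe[, 1]),
          min(probe[, 2]), max(probe[, 2]))
  }
  keep <- seq_len(min(target_size, nrow(accepted_p)))
  accepted_p <- accepted_p[keep, , drop = FALSE]
  accepted_r <- accepted_r[keep, , drop = FALSE]
  colnames(accepted_r) <- c("absorbance", "swelling")
  structure(list(proportions = accepted_p,
                 responses = accepted_r,
                 target_size = target_size,
                 draws_used = draws,
                 acceptance_rate = nrow(accepted_p) / draws,
                 criteria = criteria,
                 ranges = ranges,
                 reference_dose = reference_dose,
                 input_labels = input_labels,
                 seed = seed),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("Candidate set: %d accepted / %d draws (rate %.3g)\n",
              nrow(x$proportions), x$draws_used, x$acceptance_rate))
  print(round(apply(x$proportions, 2, stats::quantile), 4))
  invisible(x)
}

#' Consensus proportion of an accepted candidate set
#'
#' Component-wise median (default, the published choice) or mean over the
#' accepted candidates.
#'
#' @param cs a [screen_candidates] result.
#' @param method \code{"median"} or \code{"mean"}.
#' @return Named numeric proportion vector.
#' @export
consensus_proportion <- function(cs, method = c("median", "mean")) {
  method <- match.arg(method)
  stopifnot(inherits(cs, "candidate_set"))
  if (!nrow(cs$proportions)) stopf("empty candidate set")
  if (method == "median") apply(cs$proportions, 2, stats::median)
  else colMeans(cs$proportions)
}

#' Confirm a consensus proportion through the surrogate
#'
#' Re-predicts both responses for the consensus vector, checks the
#' acceptance criteria, and attaches the ten-point conversion.
#'
#' @param model surrogate (see [screen_candidates]).
#' @param p named proportion vector.
#' @param criteria an [acceptance_criteria].
#' @param ranges optional [component_ranges]; a warning is raised if
#'   \code{p} falls outside the box.
#' @param input_labels,reference_dose see [embed_candidates].
#' @return Object of class \code{consensus_result}: \code{proportion},
#'   \code{ten_point}, \code{prediction} (absorbance, swelling),
#'   \code{pass}.
#' @export
confirm_proportion <- function(model, p, criteria, ranges = NULL,
                               input_labels = NULL, reference_dose = 12.50) {
  stopifnot(inherits(criteria, "acceptance_criteria"))
  if (is.null(input_labels)) {
    input_labels <- if (inherits(model, "bp_surrogate")) model$input_labels
                    else names(p)
  }
  if (!is.null(ranges)) {
    lab <- intersect(names(p), colnames(ranges))
    out_of_box <- p[lab] < ranges["lo", lab] | p[lab] > ranges["hi", lab]
    if (any(out_of_box)) {
      warnf("consensus outside sampling box for component(s): %s",
            paste(lab[out_of_box], collapse = ", "))
    }
  }
  x <- embed_candidates(matrix(p, nrow = 1, dimnames = list(NULL, names(p))),
                        input_labels, reference_dose)
  pred <- predict_responses(model, x)[1, ]
  names(pred) <- c("absorbance", "swelling")
  structure(list(proportion = p,
                 ten_point = to_ten_point(p),
                 prediction = pred,
                 pass = unname(pred[1] < criteria$absorbance_max &
                               pred[2] < criteria$swelling_max),
                 criteria = criteria),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus proportion (ten-point):\n")
  print(round_proportion(x$ten_point))
  cat(sprintf("Predicted absorbance %.4g (< %.4g), swelling %.4g%% (< %.4g%%): %s\n",
              x$prediction[1], x$criteria$absorbance_max,
              x$prediction[2], x$criteria$swelling_max,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}
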