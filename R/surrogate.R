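#' Specification of the backpropagation surrogate network
#'
#' A four-layer feed-forward network: input layer (one neuron per
#' component), two hidden layers (20 and 2 neurons by default) with
#' hyperbolic-tangent activation, and a two-neuron identity output layer
#' for (absorbance, ear swelling ratio). Trained by full-batch gradient
#' descent on mean-squared error over min-max-scaled data.
#'
#' @param input_width number of input components (10 for the full
#'   fingerprint layout).
#' @param hidden_widths integer vector of hidden-layer sizes, default
#'   \code{c(20, 2)}.
#' @param output_width number of responses, default 2.
#' @param max_epochs training iterations, default 1000.
#' @param error_goal stop when the scaled-data MSE drops below this,
#'   default 1e-4.
#' @param learning_rate initial step size on scaled data, default 0.05.
#'   The trainer halves the step when a proposal would increase the loss
#'   and grows it slightly after accepted steps, so the recorded loss
#'   history is non-increasing.
#' @param momentum momentum coefficient in [0, 1); 0 (off) by default.
#' @param weight_decay L2 penalty on weights (not biases); 0 (off) by
#'   default. Useful when the network would otherwise interpolate noise
#'   on very small training sets.
#' @param seed integer seed for weight initialization.
#' @return An object of class \code{network_spec}.
#' @export
network_spec <- function(input_width, hidden_widths = c(20, 2),
                         output_width = 2, max_epochs = 1000,
                         error_goal = 1e-4, learning_rate = 0.05,
                         momentum = 0, weight_decay = 0, seed = 1) {
  stopifnot(input_width >= 1, all(hidden_widths >= 1), output_width >= 1,
            max_epochs >= 1, error_goal > 0, learning_rate > 0,
            momentum >= 0, momentum < 1, weight_decay >= 0)
  structure(list(input_width = as.integer(input_width),
                 hidden_widths = as.integer(hidden_widths),
                 output_width = as.integer(output_width),
                 max_epochs = as.integer(max_epochs),
                 error_goal = error_goal,
                 learning_rate = learning_rate,
                 momentum = momentum,
                 weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "network_spec")
}

# --- min-max scaling to [-1, 1] -------------------------------------------

fit_scaler <- function(x) {
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  span <- hi - lo
  # constant columns map to 0 rather than dividing by zero
  span[span == 0] <- 1
  list(lo = lo, hi = hi, span = span)
}

apply_scaler <- function(sc, x) {
  sweep(sweep(x, 2, sc$lo, "-"), 2, sc$span, "/") * 2 - 1
}

invert_scaler <- function(sc, z) {
  sweep(sweep((z + 1) / 2, 2, sc$span, "*"), 2, sc$lo, "+")
}

# --- forward / backward ----------------------------------------------------

init_weights <- function(widths, seed) {
  with_seed(seed, {
    lapply(seq_len(length(widths) - 1L), function(l) {
      list(W = matrix(stats::runif(widths[l] * widths[l + 1], -0.5, 0.5),
                      widths[l], widths[l + 1]),
           b = stats::runif(widths[l + 1], -0.5, 0.5))
    })
  })
}

forward_pass <- function(layers, X) {
  n_layers <- length(layers)
  acts <- vector("list", n_layers + 1L)
  acts[[1]] <- X
  for (l in seq_len(n_layers)) {
    z <- sweep(acts[[l]] %*% layers[[l]]$W, 2, layers[[l]]$b, "+")
    acts[[l + 1]] <- if (l < n_layers) tanh(z) else z  # identity output
  }
  acts
}

# Mean squared error over all rows and output channels (scaled units).
mse_loss <- function(pred, target) mean((pred - target)^2)

backward_pass <- function(layers, acts, target) {
  n_layers <- length(layers)
  n <- nrow(target)
  grads <- vector("list", n_layers)
  # dL/dY for MSE = 2 (Y - T) / (n * k)
  delta <- 2 * (acts[[n_layers + 1L]] - target) / (n * ncol(target))
  for (l in rev(seq_len(n_layers))) {
    grads[[l]] <- list(W = crossprod(acts[[l]], delta),
                       b = colSums(delta))
    if (l > 1L) {
      delta <- (delta %*% t(layers[[l]]$W)) * (1 - acts[[l]]^2)
    }
  }
  grads
}

#' Fit the backpropagation surrogate
#'
#' Trains the network of [network_spec] on per-component dosage inputs and
#' two-channel responses. Inputs and targets are min-max scaled to
#' \eqn{[-1, 1]} per feature; training is full-batch gradient descent with
#' a backtracking step rule (a step that would increase the loss is
#' rejected and the learning rate halved), so the recorded loss history is
#' non-increasing. Training stops at \code{error_goal} or
#' \code{max_epochs}, whichever comes first. Deterministic for a fixed
#' seed.
#'
#' @param inputs numeric matrix of dosages (rows = samples).
#' @param targets numeric matrix with columns \code{absorbance} and
#'   \code{swelling} (rows aligned with \code{inputs}).
#' @param spec a [network_spec]; its \code{input_width} / \code{output_width}
#'   must match the data.
#' @return An object of class \code{bp_surrogate}: layers (weights/biases),
#'   scalers, loss \code{history}, epochs used, and the spec.
#' @export
fit_surrogate <- function(inputs, targets, spec) {
  inputs <- as.matrix(inputs)
  targets <- as.matrix(targets)
  if (nrow(inputs) != nrow(targets)) stopf("inputs and targets are not row-aligned")
  if (nrow(inputs) < 2L) stopf("need at least 2 training rows")
  if (any(!is.finite(inputs)) || any(!is.finite(targets))) {
    stopf("training data contain non-finite values")
  }
  if (ncol(inputs) != spec$input_width) {
    stopf("spec expects %d inputs, data has %d", spec$input_width, ncol(inputs))
  }
  if (ncol(targets) != spec$output_width) {
    stopf("spec expects %d outputs, data has %d", spec$output_width, ncol(targets))
  }
  in_scaler <- fit_scaler(inputs)
  out_scaler <- fit_scaler(targets)
  X <- apply_scaler(in_scaler, inputs)
  Y <- apply_scaler(out_scaler, targets)

  widths <- c(spec$input_width, spec$hidden_widths, spec$output_width)
  layers <- init_weights(widths, spec$seed)
  velocity <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))

  lr <- spec$learning_rate
  lr_max <- spec$learning_rate * 20
  wd <- spec$weight_decay
  penalty <- function(ls) {
    if (wd == 0) 0 else wd * sum(vapply(ls, function(l) sum(l$W^2), numeric(1)))
  }
  acts <- forward_pass(layers, X)
  loss <- mse_loss(acts[[length(acts)]], Y)
  obj <- loss + penalty(layers)
  if (!is.finite(loss)) stopf("initial loss is not finite")
  history <- numeric(spec$max_epochs)
  epochs <- 0L
  for (e in seq_len(spec$max_epochs)) {
    if (loss <= spec$error_goal || lr < 1e-14) break
    grads <- backward_pass(layers, acts, Y)
    proposal <- layers
    for (l in seq_along(layers)) {
      gW <- grads[[l]]$W + 2 * wd * layers[[l]]$W
      velocity[[l]]$W <- spec$momentum * velocity[[l]]$W - lr * gW
      velocity[[l]]$b <- spec$momentum * velocity[[l]]$b - lr * grads[[l]]$b
      proposal[[l]]$W <- layers[[l]]$W + velocity[[l]]$W
      proposal[[l]]$b <- layers[[l]]$b + velocity[[l]]$b
    }
    new_acts <- forward_pass(proposal, X)
    new_loss <- mse_loss(new_acts[[length(new_acts)]], Y)
    new_obj <- new_loss + penalty(proposal)
    if (!is.finite(new_loss)) {
      stopf("training diverged (non-finite loss); try a smaller learning_rate")
    }
    if (new_obj <= obj) {
      layers <- proposal
      acts <- new_acts
      loss <- new_loss
      obj <- new_obj
      lr <- min(lr * 1.05, lr_max)
    } else {
      # reject the step: keep weights, damp the step size and kill momentum
      lr <- lr * 0.5
      velocity <- lapply(velocity, function(v) list(W = v$W * 0, b = v$b * 0))
    }
    epochs <- e
    history[e] <- loss
  }
  history <- history[seq_len(epochs)]
  structure(list(layers = layers,
                 in_scaler = in_scaler,
                 out_scaler = out_scaler,
                 history = history,
                 final_loss = loss,
                 epochs = epochs,
                 converged = loss <= spec$error_goal,
                 spec = spec,
                 input_labels = colnames(inputs),
                 output_labels = colnames(targets)),
            class = "bp_surrogate")
}

#' @export
print.bp_surrogate <- function(x, ...) {
  cat(sprintf("BP surrogate %s, %d epochs, final scaled MSE %.3g%s\n",
              paste(c(x$spec$input_width, x$spec$hidden_widths,
                      x$spec$output_width), collapse = "-"),
              x$epochs, x$final_loss,
              if (x$converged) " (goal reached)" else ""))
  invisible(x)
}

#' Predict responses for dosage vectors
#'
#' @param object a fitted [fit_surrogate] model.
#' @param newdata numeric vector (one dosage profile) or matrix (one row
#'   per profile), width equal to the network's input width.
#' @param ... unused.
#' @return Matrix with one row per input and columns named after the
#'   training responses (absorbance, swelling).
#' @export
predict.bp_surrogate <- function(object, newdata, ...) {
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$spec$input_width) {
    stopf("expected %d input columns, got %d",
          object$spec$input_width, ncol(newdata))
  }
  if (any(!is.finite(newdata))) stopf("inputs must be finite")
  X <- apply_scaler(object$in_scaler, newdata)
  acts <- forward_pass(object$layers, X)
  out <- invert_scaler(object$out_scaler, acts[[length(acts)]])
  colnames(out) <- object$output_labels
  out
}

# Generic response evaluation used by the optimizer so that closed-form
# synthetic surrogates (plain functions returning a 2-column matrix) can
# stand in for a trained network in tests and simulations.
predict_responses <- function(model, X) {
  if (inherits(model, "bp_surrogate")) {
    predict(model, X)
  } else if (is.function(model)) {
    out <- model(X)
    if (is.vector(out)) out <- matrix(out, nrow = 1)
    out
  } else {
    stopf("model must be a bp_surrogate or a function")
  }
}

#' Leave-one-out holdout validation
#'
#' Fits the surrogate on all samples except the holdout and reports the
#' prediction against the observed responses for the held-out sample (the
#' published design holds out sample S5). With so few training rows this
#' measures interpolation plausibility, not generalization.
#'
#' @param inputs,targets row-aligned matrices with rownames = sample ids.
#' @param holdout_id sample id to reserve.
#' @param spec a [network_spec].
#' @return An object of class \code{validation_record}: predicted and
#'   observed response pairs, absolute and relative errors, and the fitted
#'   model.
#' @export
holdout_validate <- function(inputs, targets, holdout_id, spec) {
  inputs <- as.matrix(inputs)
  targets <- as.matrix(targets)
  ids <- rownames(inputs)
  if (is.null(ids)) stopf("inputs must have sample ids as rownames")
  if (!holdout_id %in% ids) stopf("unknown holdout sample '%s'", holdout_id)
  keep <- ids != holdout_id
  if (sum(keep) < 2L) stopf("need at least 2 training rows after holdout")
  model <- fit_surrogate(inputs[keep, , drop = FALSE],
                         targets[keep, , drop = FALSE], spec)
  pred <- predict(model, inputs[!keep, , drop = FALSE])[1, ]
  obs <- targets[!keep, , drop = FALSE][1, ]
  abs_err <- abs(pred - obs)
  rel_err <- ifelse(obs != 0, abs_err / abs(obs), NA_real_)
  structure(list(holdout_id = holdout_id,
                 predicted = pred,
                 observed = obs,
                 abs_error = abs_err,
                 rel_error = rel_err,
                 model = model),
            class = "validation_record")
}

#' @export
print.validation_record <- function(x, ...) {
  cat(sprintf("Holdout validation (sample %s)\n", x$holdout_id))
  print(data.frame(predicted = round(x$predicted, 4),
                   observed = round(x$observed, 4),
                   abs_error = round(x$abs_error, 4),
                   rel_error = round(x$rel_error, 4)))
  invisible(x)
}

#' Serialize a fitted surrogate to JSON
#'
#' @param model a \code{bp_surrogate}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
save_surrogate <- function(model, path) {
  stopifnot(inherits(model, "bp_surrogate"))
  obj <- list(
    spec = unclass(model$spec),
    layers = lapply(model$layers, function(l) list(W = l$W, b = l$b)),
    in_scaler = model$in_scaler,
    out_scaler = model$out_scaler,
    input_labels = model$input_labels,
    output_labels = model$output_labels,
    final_loss = model$final_loss,
    epochs = model$epochs
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a surrogate serialized by [save_surrogate]
#'
#' @param path JSON file written by [save_surrogate].
#' @return A \code{bp_surrogate} usable with [predict.bp_surrogate].
#' @export
load_surrogate <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(network_spec, obj$spec)
  layers <- lapply(seq_len(nrow_safe(obj$layers)), function(i) {
    list(W = as.matrix(obj$layers$W[[i]]), b = as.numeric(obj$layers$b[[i]]))
  })
  structure(list(layers = layers,
                 in_scaler = lapply(obj$in_scaler, as.numeric),
                 out_scaler = lapply(obj$out_scaler, as.numeric),
                 history = numeric(0),
                 final_loss = obj$final_loss,
                 epochs = obj$epochs,
                 converged = obj$final_loss <= spec$error_goal,
                 spec = spec,
                 input_labels = obj$input_labels,
                 output_labels = obj$output_labels),
            class = "bp_surrogate")
}

nrow_safe <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
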