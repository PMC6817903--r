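#' Mean-normalize a sequence
#'
#' Divides every value by the sequence mean, the normalization used before
#' computing grey relational coefficients so that series on different
#' measurement scales (dosages in mg/kg, absorbance, percentages) become
#' comparable. The normalized sequence has mean exactly 1.
#'
#' @param x numeric vector with strictly positive mean.
#' @return \code{x / mean(x)}.
#' @export
mean_normalize <- function(x) {
  if (!is.numeric(x) || length(x) < 1L || any(!is.finite(x))) {
    stopf("sequence must be finite numeric")
  }
  m <- mean(x)
  if (m <= 0) stopf("sequence mean must be > 0 for mean normalization (got %g)", m)
  x / m
}

#' Deng grey relational coefficients
#'
#' For a behavior sequence x0 and factor sequences xi (all mean-normalized
#' internally), the coefficient at position k for factor i is
#' \deqn{\xi_i(k) = (\Delta_{min} + \rho \Delta_{max}) /
#'                 (\Delta_i(k) + \rho \Delta_{max})}
#' with \eqn{\Delta_i(k) = |x_0(k) - x_i(k)|} and the min/max taken over
#' all factors and all positions (the two-level min-min / max-max
#' operators). \eqn{\rho} is the distinguishing coefficient in (0, 1).
#'
#' @param x0 numeric behavior sequence (the response over samples).
#' @param factors numeric matrix, one column per factor (component), rows
#'   aligned with \code{x0}; or a single numeric vector.
#' @param rho distinguishing coefficient, default 0.5.
#' @return Matrix of coefficients, rows = positions, cols = factors; all
#'   entries in (0, 1].
#' @export
deng_coefficients <- function(x0, factors, rho = 0.5) {
  assert_scalar_number(rho, "rho")
  if (rho <= 0 || rho >= 1) stopf("rho must lie strictly between 0 and 1")
  if (is.vector(factors)) factors <- matrix(factors, ncol = 1)
  if (nrow(factors) != length(x0)) {
    stopf("factor sequences (%d) and behavior sequence (%d) differ in length",
          nrow(factors), length(x0))
  }
  if (ncol(factors) < 1L) stopf("need at least one factor sequence")
  x0n <- mean_normalize(x0)
  fn <- apply(factors, 2, mean_normalize)
  if (is.vector(fn)) fn <- matrix(fn, ncol = ncol(factors))
  delta <- abs(fn - x0n)
  dmin <- min(delta)
  dmax <- max(delta)
  if (dmax == 0) {
    warnf("all factors identical to the behavior sequence after normalization; coefficients set to 1")
    xi <- array(1, dim = dim(delta))
  } else {
    xi <- (dmin + rho * dmax) / (delta + rho * dmax)
  }
  dimnames(xi) <- dimnames(factors)
  xi
}

#' Grey correlation degree
#'
#' The mean of a factor's relational coefficients over all positions; lies
#' in (0, 1], equal to 1 only when every coefficient is 1.
#'
#' @param xi numeric vector of relational coefficients for one factor.
#' @return Scalar degree.
#' @export
gray_correlation_degree <- function(xi) {
  if (!length(xi)) stopf("empty coefficient sequence")
  mean(xi)
}

#' Rank components by grey correlation degree
#'
#' @param degrees named numeric vector of degrees.
#' @param direction \code{"descending"} (largest degree first; used when a
#'   high association with the response marks the property of interest,
#'   e.g. irritation) or \code{"ascending"} (smallest first; used when a
#'   weak association with the adverse response marks effectiveness).
#' @return Character vector of labels in rank order; ties broken by
#'   lexicographic label order for determinism.
#' @export
rank_components <- function(degrees, direction = c("descending", "ascending")) {
  direction <- match.arg(direction)
  if (!length(degrees)) stopf("empty degree map")
  if (any(is.na(degrees))) {
    stopf("degree for component '%s' is NA", names(degrees)[which(is.na(degrees))[1]])
  }
  if (any(!is.finite(degrees))) {
    stopf("degree for component '%s' is not finite",
          names(degrees)[which(!is.finite(degrees))[1]])
  }
  ord <- order(if (direction == "descending") -degrees else degrees,
               names(degrees), method = "radix")
  names(degrees)[ord]
}

#' Grey correlation analysis of factor sequences against a response
#'
#' Runs the full chain: mean normalization, Deng relational coefficients,
#' grey correlation degrees, and a direction-aware ranking. Factor columns
#' whose mean is zero (component absent from every sample) cannot be
#' normalized and are dropped with a warning rather than an error.
#'
#' @param x0 numeric behavior sequence (response over samples).
#' @param factors numeric matrix of factor sequences (e.g. per-component
#'   dosages), columns named by component label.
#' @param rho distinguishing coefficient, default 0.5.
#' @param direction ranking direction, see [rank_components].
#' @param response_name optional label carried into the result.
#' @return An object of class \code{gca_result}: list with
#'   \code{coefficients} (positions x factors), \code{degrees} (named),
#'   \code{ranking} (labels in order), \code{direction}, \code{rho},
#'   \code{response_name}, and \code{dropped} (labels excluded for zero
#'   mean).
#' @export
gca <- function(x0, factors, rho = 0.5,
                direction = c("descending", "ascending"),
                response_name = "response") {
  direction <- match.arg(direction)
  if (is.vector(factors)) factors <- matrix(factors, ncol = 1)
  if (is.null(colnames(factors))) {
    colnames(factors) <- paste0("X", seq_len(ncol(factors)))
  }
  zero_mean <- colMeans(factors) <= 0
  dropped <- colnames(factors)[zero_mean]
  if (length(dropped)) {
    warnf("excluding factor(s) with zero mean from ranking: %s",
          paste(dropped, collapse = ", "))
    factors <- factors[, !zero_mean, drop = FALSE]
  }
  if (!ncol(factors)) stopf("no factor with positive mean remains")
  xi <- deng_coefficients(x0, factors, rho = rho)
  degrees <- colMeans(xi)
  structure(list(
    coefficients = xi,
    degrees = degrees,
    ranking = rank_components(degrees, direction),
    direction = direction,
    rho = rho,
    response_name = response_name,
    dropped = dropped
  ), class = "gca_result")
}

#' @export
print.gca_result <- function(x, ...) {
  cat(sprintf("Grey correlation analysis vs '%s' (rho = %g, %s ranking)\n",
              x$response_name, x$rho, x$direction))
  df <- data.frame(component = names(x$degrees),
                   degree = round(unname(x$degrees), 4))
  df$rank <- match(df$component, x$ranking)
  print(df[order(df$rank), ], row.names = FALSE)
  if (length(x$dropped)) {
    cat("excluded (zero-mean factor):", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}
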