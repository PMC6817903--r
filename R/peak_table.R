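#' Construct a validated HPLC peak-area table
#'
#' A \code{peak_table} holds the actual peak areas of each fingerprint
#' component (columns, labelled \code{A}..\code{J} by default) in each
#' sample (rows). Areas are in arbitrary chromatographic area units.
#'
#' @param areas numeric matrix, samples in rows, components in columns;
#'   all entries must be non-negative and every sample must have at least
#'   one strictly positive area.
#' @param sample_ids character vector of unique sample identifiers
#'   (defaults to the matrix rownames).
#' @param component_labels character vector of unique component labels
#'   (defaults to the matrix colnames).
#' @return An object of class \code{peak_table}: the validated numeric
#'   matrix with \code{sample_ids} as rownames and \code{component_labels}
#'   as colnames.
#' @examples
#' pt <- peak_table(matrix(c(1, 2, 3, 4), 2, 2,
#'   dimnames = list(c("S1", "S2"), c("A", "B"))))
#' sample_totals(pt)
#' @export
peak_table <- function(areas, sample_ids = rownames(areas),
                       component_labels = colnames(areas)) {
  if (!is.matrix(areas) || !is.numeric(areas)) {
    stopf("'areas' must be a numeric matrix")
  }
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(areas)))
  if (is.null(component_labels)) {
    component_labels <- LETTERS[seq_len(ncol(areas))]
  }
  sample_ids <- as.character(sample_ids)
  component_labels <- as.character(component_labels)
  if (length(sample_ids) != nrow(areas)) {
    stopf("%d sample ids for %d rows", length(sample_ids), nrow(areas))
  }
  if (length(component_labels) != ncol(areas)) {
    stopf("%d component labels for %d columns",
          length(component_labels), ncol(areas))
  }
  if (anyDuplicated(sample_ids)) {
    stopf("duplicate sample id: %s",
          paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(component_labels)) {
    stopf("duplicate component label: %s",
          paste(unique(component_labels[duplicated(component_labels)]),
                collapse = ", "))
  }
  if (any(!is.finite(areas))) {
    bad <- which(!is.finite(areas), arr.ind = TRUE)[1, ]
    stopf("non-finite area at sample '%s', component '%s'",
          sample_ids[bad[1]], component_labels[bad[2]])
  }
  if (any(areas < 0)) {
    bad <- which(areas < 0, arr.ind = TRUE)[1, ]
    stopf("negative area (%g) at sample '%s', component '%s'",
          areas[bad[1], bad[2]], sample_ids[bad[1]], component_labels[bad[2]])
  }
  zero_rows <- rowSums(areas) <= 0
  if (any(zero_rows)) {
    stopf("sample '%s' has no positive peak area",
          sample_ids[which(zero_rows)[1]])
  }
  dimnames(areas) <- list(sample_ids, component_labels)
  structure(areas, class = c("peak_table", "matrix", "array"))
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("HPLC peak-area table: %d samples x %d components\n",
              nrow(x), ncol(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Read a peak-area table from delimited text
#'
#' Expects a header row of component labels and a first column of sample
#' identifiers (or the transposed layout, components as rows, with
#' \code{transpose = TRUE} -- the layout used when tables are printed with
#' samples as columns).
#'
#' @param path path to a delimited text file.
#' @param sep field separator, default comma.
#' @param transpose logical; if \code{TRUE} the file has components as rows
#'   and samples as columns.
#' @return A validated [peak_table].
#' @export
read_peak_table <- function(path, sep = ",", transpose = FALSE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character",
                           strip.white = TRUE)
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    stopf("duplicate sample id in '%s': %s", basename(path),
          ids[duplicated(ids)][1])
  }
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- ids
  num <- suppressWarnings(array(as.numeric(m), dim = dim(m),
                                dimnames = dimnames(m)))
  if (any(is.na(num) & !is.na(m))) {
    bad <- which(is.na(num) & !is.na(m), arr.ind = TRUE)[1, ]
    stopf("non-numeric cell '%s' at row '%s', column '%s'",
          m[bad[1], bad[2]], rownames(m)[bad[1]], colnames(m)[bad[2]])
  }
  if (transpose) num <- t(num)
  peak_table(num)
}

#' Read an administered-dose table
#'
#' @param path CSV with columns \code{sample} and \code{dose}
#'   (mg per kg body weight).
#' @return Named numeric vector of doses, names are sample ids.
#' @export
read_dose_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "dose") %in% names(df))) {
    stopf("dose table must have columns 'sample' and 'dose'")
  }
  doses <- as.numeric(df$dose)
  names(doses) <- as.character(df$sample)
  if (any(!is.finite(doses) | doses <= 0)) {
    stopf("dose for sample '%s' must be a positive number",
          names(doses)[which(!is.finite(doses) | doses <= 0)[1]])
  }
  doses
}

#' Total peak area per sample
#'
#' @param t a [peak_table].
#' @return Named numeric vector: sum of component areas per sample.
#' @export
sample_totals <- function(t) {
  stopifnot(inherits(t, "peak_table"))
  tot <- rowSums(unclass(t))
  if (any(tot <= 0)) {
    stopf("sample '%s' has zero total area", names(tot)[which(tot <= 0)[1]])
  }
  tot
}

#' Relative peak areas (percent of sample total)
#'
#' Each cell is 100 * area / (sample total), so every row sums to 100.
#'
#' @param t a [peak_table].
#' @param digits if non-NULL, round the exported table to this many decimal
#'   places (the published style uses 2); internal callers keep full
#'   precision with \code{digits = NULL}.
#' @return Numeric matrix of percentages, same dimnames as \code{t}.
#' @export
relative_areas <- function(t, digits = NULL) {
  tot <- sample_totals(t)
  rel <- sweep(unclass(t), 1, tot, "/") * 100
  if (!is.null(digits)) rel <- round(rel, digits)
  rel
}

#' Per-component administered dosages
#'
#' Splits each sample's administered dose over its components in proportion
#' to peak area: dose(s, c) = dose(s) * area(s, c) / total(s). Row sums
#' therefore equal the administered doses.
#'
#' @param t a [peak_table].
#' @param doses named numeric vector of administered doses (mg/kg), one per
#'   sample of \code{t}.
#' @return Numeric matrix of per-component dosages (mg/kg).
#' @export
peak_doses <- function(t, doses) {
  stopifnot(inherits(t, "peak_table"))
  missing <- setdiff(rownames(t), names(doses))
  if (length(missing)) {
    stopf("no administered dose for sample '%s'", missing[1])
  }
  d <- doses[rownames(t)]
  if (any(!is.finite(d) | d <= 0)) {
    stopf("dose for sample '%s' must be positive",
          rownames(t)[which(!is.finite(d) | d <= 0)[1]])
  }
  frac <- sweep(unclass(t), 1, rowSums(unclass(t)), "/")
  sweep(frac, 1, d, "*")
}

#' Mean component proportion over a subset of samples
#'
#' Averages relative areas over the selected samples and renormalizes the
#' selected components to sum to \code{scale} (10 by convention, the
#' "ten-point" proportion).
#'
#' @param rel relative-area matrix (from [relative_areas]; pass the 2-dp
#'   export to match published proportion tables).
#' @param samples,components character vectors selecting rows/columns.
#' @param scale positive total of the returned proportion, default 10.
#' @return Named numeric proportion vector summing to \code{scale}.
#' @export
mean_proportion <- function(rel, samples = rownames(rel),
                            components = colnames(rel), scale = 10) {
  assert_scalar_number(scale, "scale", positive = TRUE)
  if (!length(samples) || !length(components)) {
    stopf("sample and component selections must be non-empty")
  }
  if (!all(samples %in% rownames(rel))) {
    stopf("unknown sample '%s'", setdiff(samples, rownames(rel))[1])
  }
  if (!all(components %in% colnames(rel))) {
    stopf("unknown component '%s'", setdiff(components, colnames(rel))[1])
  }
  sub <- rel[samples, components, drop = FALSE]
  mu <- colMeans(sub)
  if (sum(mu) <= 0) stopf("selected components have zero mean relative area")
  to_ten_point(mu, scale = scale)
}

#' Rescale a proportion vector to a fixed total
#'
#' @param p non-negative numeric vector with at least one positive entry.
#' @param scale positive total, default 10 (the ten-point convention).
#' @return \code{p * scale / sum(p)}.
#' @export
to_ten_point <- function(p, scale = 10) {
  assert_scalar_number(scale, "scale", positive = TRUE)
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0)) {
    stopf("proportion entries must be finite and non-negative")
  }
  s <- sum(p)
  if (s <= 0) stopf("proportion vector is all zero")
  p * scale / s
}

#' Round a proportion vector preserving its declared total
#'
#' Plain rounding of a proportion vector usually breaks the total by one
#' unit in the last place; published ten-point proportions sum exactly to
#' 10.0000, which implies controlled rounding. This applies the
#' largest-remainder correction: round all entries, then add the residual
#' (a small multiple of 10^-digits) to the largest entry.
#'
#' @param p numeric proportion vector.
#' @param digits decimal places, default 4 (published style).
#' @param preserve_sum logical; if \code{TRUE} (default) force the rounded
#'   entries to sum to \code{round(sum(p), digits)}.
#' @return Rounded numeric vector.
#' @export
round_proportion <- function(p, digits = 4, preserve_sum = TRUE) {
  r <- round(p, digits)
  if (preserve_sum) {
    resid <- round(sum(p), digits) - sum(r)
    if (abs(resid) > .Machine$double.eps * length(p)) {
      i <- which.max(p)
      r[i] <- round(r[i] + resid, digits)
    }
  }
  r
}
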