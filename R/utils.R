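#' @keywords internal
"_PACKAGE"

# Run code with a temporarily-set RNG seed, restoring the caller's RNG state.
# All stochastic entry points route through this so a single integer seed
# makes the whole pipeline reproducible without clobbering the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive per-stage seeds from one global seed; keeps every derived seed a
# valid 32-bit integer regardless of the global seed's magnitude.
derive_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) %% 1000003L) * 1000 + stage_index)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("'%s' must be a single finite number", name)
  }
  if (positive && x <= 0) stopf("'%s' must be > 0", name)
  invisible(x)
}

# Deterministic CSV writer: numbers rendered with %.10g so repeated runs of
# the pipeline produce byte-identical files.
write_csv_fixed <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.numeric(df2[[j]])) df2[[j]] <- sprintf("%.10g", df2[[j]])
  }
  utils::write.csv(df2, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
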