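#' Configuration for the full analysis pipeline
#'
#' Bundles every stage's settings: input tables, grey-correlation options,
#' network architecture, the candidate box and acceptance criteria, and a
#' single global seed that fans out to per-stage seeds.
#'
#' @param peak_table_path CSV of actual peak areas (default: bundled
#'   commercial/knockout table).
#' @param dose_table_path CSV of administered doses (default bundled).
#' @param response_path optional CSV with columns \code{sample},
#'   \code{absorbance}, \code{swelling_ratio}. If \code{NULL}, responses
#'   are simulated from \code{synthetic_truth}.
#' @param synthetic_truth a [ground_truth] used when \code{response_path}
#'   is \code{NULL}; set to \code{NULL} to require a measured table.
#' @param rho distinguishing coefficient for the grey analysis.
#' @param holdout_id sample reserved for surrogate validation, default "S5".
#' @param net arguments for [network_spec] except \code{input_width} and
#'   \code{seed} (filled in at run time).
#' @param ranges a [component_ranges].
#' @param criteria an [acceptance_criteria].
#' @param consensus_method \code{"median"} (default) or \code{"mean"}.
#' @param target_size accepted candidates wanted, default 50.
#' @param max_draws sampling budget, default 1e5.
#' @param reference_dose dose-unit bridge for candidate embedding (mg/kg).
#' @param seed global integer seed.
#' @param outdir output directory (created if absent).
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(peak_table_path = NULL, dose_table_path = NULL,
                            response_path = NULL,
                            synthetic_truth = ground_truth(),
                            rho = 0.5, holdout_id = "S5",
                            net = list(), ranges = component_ranges(),
                            criteria = acceptance_criteria(),
                            consensus_method = "median",
                            target_size = 50, max_draws = 1e5,
                            reference_dose = 12.50,
                            seed = 1, outdir = "results/pipeline") {
  if (is.null(peak_table_path)) {
    peak_table_path <- system.file("extdata", "sai_peak_areas.csv",
                                   package = "saiopt", mustWork = TRUE)
  }
  if (is.null(dose_table_path)) {
    dose_table_path <- system.file("extdata", "sai_doses.csv",
                                   package = "saiopt", mustWork = TRUE)
  }
  if (is.null(response_path) && is.null(synthetic_truth)) {
    stopf("configuration error: 'response_path' is NULL and synthetic responses are disabled ('synthetic_truth' is NULL)")
  }
  for (p in c(peak_table_path, dose_table_path, response_path)) {
    if (!is.null(p) && !file.exists(p)) stopf("input file not found: %s", p)
  }
  structure(list(peak_table_path = peak_table_path,
                 dose_table_path = dose_table_path,
                 response_path = response_path,
                 synthetic_truth = synthetic_truth,
                 rho = rho, holdout_id = holdout_id, net = net,
                 ranges = ranges, criteria = criteria,
                 consensus_method = consensus_method,
                 target_size = target_size, max_draws = max_draws,
                 reference_dose = reference_dose,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' Run the full proportion-optimization pipeline
#'
#' Stages: fingerprint arithmetic (totals, relative areas, per-component
#' dosages) -> bioassay responses (measured or simulated) -> grey
#' correlation analysis against both responses in both ranking directions
#' -> surrogate fit with holdout validation -> inverse optimization
#' (candidate screening, consensus, confirmation, ten-point conversion).
#' All intermediate tables, a JSON manifest, and a plain-text report are
#' written under \code{cfg$outdir}; a rerun with the same configuration
#' and seed reproduces every file byte-identically.
#'
#' @param cfg a [pipeline_config].
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with every stage's objects (peak table,
#'   responses, GCA results, surrogate + validation, candidate set,
#'   consensus) and the manifest.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  stage_seeds <- vapply(1:4, function(i) derive_seed(cfg$seed, i), integer(1))
  names(stage_seeds) <- c("responses", "surrogate", "optimizer", "spare")

  ## stage 1: fingerprint arithmetic
  say("stage 1/4: fingerprint arithmetic")
  pt <- read_peak_table(cfg$peak_table_path)
  doses_admin <- read_dose_table(cfg$dose_table_path)
  totals <- sample_totals(pt)
  rel <- relative_areas(pt)
  rel2 <- relative_areas(pt, digits = 2)
  dose_mat <- peak_doses(pt, doses_admin)
  write_csv_fixed(data.frame(sample = rownames(pt), unclass(pt),
                             total = totals, check.names = FALSE),
                  file.path(cfg$outdir, "peak_areas.csv"))
  write_csv_fixed(data.frame(sample = rownames(rel), rel, check.names = FALSE),
                  file.path(cfg$outdir, "relative_areas.csv"))
  write_csv_fixed(data.frame(sample = rownames(rel2), rel2, check.names = FALSE),
                  file.path(cfg$outdir, "relative_areas_2dp.csv"))
  write_csv_fixed(data.frame(sample = rownames(dose_mat), dose_mat,
                             check.names = FALSE),
                  file.path(cfg$outdir, "peak_doses.csv"))

  ## stage 2: responses
  if (!is.null(cfg$response_path)) {
    say("stage 2/4: reading measured responses")
    resp <- utils::read.csv(cfg$response_path, stringsAsFactors = FALSE)
    need <- c("sample", "absorbance", "swelling_ratio")
    if (!all(need %in% names(resp))) {
      stopf("response table must have columns %s", paste(need, collapse = ", "))
    }
  } else {
    say("stage 2/4: simulating responses (seed %d)", stage_seeds["responses"])
    resp <- simulate_bioassay(dose_mat, cfg$synthetic_truth,
                              seed = stage_seeds["responses"])
  }
  miss <- setdiff(rownames(pt), resp$sample)
  if (length(miss)) stopf("no response for sample '%s'", miss[1])
  resp <- resp[match(rownames(pt), resp$sample), ]
  write_csv_fixed(resp, file.path(cfg$outdir, "responses.csv"))

  ## stage 3: grey correlation analysis, both responses, both directions
  say("stage 3/4: grey correlation analysis")
  gca_runs <- list(
    irritation = gca(resp$absorbance, dose_mat, rho = cfg$rho,
                     direction = "descending", response_name = "absorbance"),
    irritation_asc = gca(resp$absorbance, dose_mat, rho = cfg$rho,
                         direction = "ascending", response_name = "absorbance"),
    effectiveness = gca(resp$swelling_ratio, dose_mat, rho = cfg$rho,
                        direction = "ascending", response_name = "swelling_ratio"),
    effectiveness_desc = gca(resp$swelling_ratio, dose_mat, rho = cfg$rho,
                             direction = "descending", response_name = "swelling_ratio")
  )
  gca_df <- do.call(rbind, lapply(names(gca_runs), function(nm) {
    g <- gca_runs[[nm]]
    data.frame(analysis = nm, response = g$response_name,
               direction = g$direction,
               component = names(g$degrees),
               degree = unname(g$degrees),
               rank = match(names(g$degrees), g$ranking),
               stringsAsFactors = FALSE)
  }))
  write_csv_fixed(gca_df, file.path(cfg$outdir, "gca_degrees.csv"))

  ## stage 4a: surrogate with holdout validation
  say("stage 4/4: surrogate + inverse optimization")
  targets <- cbind(absorbance = resp$absorbance,
                   swelling = resp$swelling_ratio)
  rownames(targets) <- resp$sample
  net_args <- cfg$net
  net_args$input_width <- ncol(dose_mat)
  if (is.null(net_args$seed)) net_args$seed <- stage_seeds["surrogate"]
  spec <- do.call(network_spec, net_args)
  validation <- holdout_validate(dose_mat, targets, cfg$holdout_id, spec)
  model <- validation$model
  save_surrogate(model, file.path(cfg$outdir, "surrogate.json"))
  write_csv_fixed(data.frame(epoch = seq_along(model$history),
                             mse = model$history),
                  file.path(cfg$outdir, "training_history.csv"))

  ## stage 4b: inverse optimization
  cs <- screen_candidates(model, cfg$ranges, cfg$criteria,
                          target_size = cfg$target_size,
                          max_draws = cfg$max_draws,
                          seed = stage_seeds["optimizer"],
                          reference_dose = cfg$reference_dose)
  consensus <- consensus_proportion(cs, cfg$consensus_method)
  confirmation <- confirm_proportion(model, consensus, cfg$criteria,
                                     ranges = cfg$ranges,
                                     reference_dose = cfg$reference_dose)
  write_csv_fixed(data.frame(cs$proportions, cs$responses, check.names = FALSE),
                  file.path(cfg$outdir, "accepted_candidates.csv"))
  quart <- apply(cs$proportions, 2, stats::quantile)
  write_csv_fixed(data.frame(quantile = rownames(quart), quart,
                             check.names = FALSE),
                  file.path(cfg$outdir, "candidate_quartiles.csv"))

  ## original (commercial) proportion for comparison, paper-style 2-dp route
  orig_prop <- mean_proportion(rel2, samples = intersect(paste0("S", 1:5),
                                                         rownames(rel2)),
                               components = intersect(LETTERS[1:6],
                                                      colnames(rel2)))

  manifest <- list(
    package_version = as.character(utils::packageVersion("saiopt")),
    seed = cfg$seed,
    stage_seeds = as.list(stage_seeds),
    config_hash = unname(tools::md5sum(write_config_json(cfg, tempfile()))),
    holdout_id = cfg$holdout_id,
    surrogate = list(epochs = model$epochs, final_mse = model$final_loss,
                     converged = model$converged),
    optimizer = list(accepted = nrow(cs$proportions),
                     draws_used = cs$draws_used,
                     acceptance_rate = cs$acceptance_rate),
    consensus = as.list(round(consensus, 6)),
    ten_point = as.list(round_proportion(confirmation$ten_point)),
    confirmation = list(absorbance = unname(confirmation$prediction[1]),
                        swelling = unname(confirmation$prediction[2]),
                        pass = confirmation$pass)
  )
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_report(file.path(cfg$outdir, "report.txt"), pt, totals, gca_runs,
               validation, cs, consensus, confirmation, orig_prop, cfg)
  say("done; outputs in %s", cfg$outdir)

  invisible(list(peak_table = pt, doses = doses_admin, totals = totals,
                 relative_areas = rel, peak_doses = dose_mat,
                 responses = resp, gca = gca_runs, spec = spec,
                 validation = validation, model = model,
                 candidates = cs, consensus = consensus,
                 confirmation = confirmation,
                 original_proportion = orig_prop,
                 manifest = manifest))
}

write_config_json <- function(cfg, path) {
  ser <- unclass(cfg)
  ser$outdir <- NULL  # output location is not part of the analysis identity
  ser$synthetic_truth <- if (is.null(cfg$synthetic_truth)) NULL else
    unclass(cfg$synthetic_truth)
  ser$ranges <- as.data.frame(unclass(cfg$ranges))
  ser$criteria <- unclass(cfg$criteria)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  path
}

write_report <- function(path, pt, totals, gca_runs, validation, cs,
                         consensus, confirmation, orig_prop, cfg) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  w <- function(fmt, ...) writeLines(sprintf(fmt, ...), con)
  w("Component proportion optimization report")
  w("========================================")
  w("")
  w("Fingerprint: %d samples x %d components; total areas %s",
    nrow(pt), ncol(pt),
    paste(sprintf("%s=%.4f", names(totals), totals), collapse = ", "))
  w("")
  w("Grey correlation rankings (rho = %g):", cfg$rho)
  for (nm in names(gca_runs)) {
    g <- gca_runs[[nm]]
    w("  %s [response: %s, direction: %s]: %s", nm, g$response_name,
      g$direction, paste(g$ranking, collapse = " > "))
  }
  w("")
  w("Surrogate holdout (%s): predicted (%.4f, %.4f) vs observed (%.4f, %.4f)",
    validation$holdout_id, validation$predicted[1], validation$predicted[2],
    validation$observed[1], validation$observed[2])
  w("  training: %d epochs, final scaled MSE %.3g", validation$model$epochs,
    validation$model$final_loss)
  w("")
  w("Optimization: %d accepted / %d draws (rate %.3g)",
    nrow(cs$proportions), cs$draws_used, cs$acceptance_rate)
  w("Consensus (%s) proportion: %s", cfg$consensus_method,
    paste(sprintf("%s=%.4f", names(consensus), consensus), collapse = ", "))
  tp <- round_proportion(confirmation$ten_point)
  w("Ten-point proportion:      %s",
    paste(sprintf("%s=%.4f", names(tp), tp), collapse = ", "))
  op <- round_proportion(orig_prop)
  w("Original (S1-S5) ten-point: %s",
    paste(sprintf("%s=%.4f", names(op), op), collapse = ", "))
  w("Confirmation: absorbance %.4f (< %.4g), swelling %.4f%% (< %.4g%%) -> %s",
    confirmation$prediction[1], cfg$criteria$absorbance_max,
    confirmation$prediction[2], cfg$criteria$swelling_max,
    if (confirmation$pass) "PASS" else "FAIL")
  invisible(path)
}
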