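# End-to-end orchestration: simulate -> featurize -> fit trajectories ->
# embed -> predict, with file outputs and a resolved-configuration record.
# The exported functions double as the command-line surface: each stage is a
# plain function over CSV/JSON files on disk.

#' Default pipeline configuration
#'
#' All thresholds default to the analysis conventions used throughout the
#' package: per-connection age-term significance 1e-4 with leave-one-out
#' robustness, positivity screen at 1e-3, supervised-LPP graph with k = 8
#' neighbours, age gap 8 years, penalty 100, and LASVR local adjustment
#' range 8 years.
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @param n_subjects,n_connections Synthetic cohort size.
#' @param alpha,positivity_alpha Selection thresholds.
#' @param k,age_gap,penalty Supervised-LPP graph parameters.
#' @param d Embedding dimension for the prediction stage.
#' @param delta LASVR local adjustment range (years).
#' @param C Regularisation trade-off.
#' @param out_dir Output directory.
#' @return Named list of class \code{fc_config}.
#' @export
pipeline_config <- function(seed = 1, n_subjects = 137, n_connections = 600,
                            alpha = 1e-4, positivity_alpha = 1e-3, k = 8,
                            age_gap = 8, penalty = 100, d = 7, delta = 8,
                            C = 0.1, out_dir = tempfile("fc_run_")) {
  cfg <- as.list(environment())
  if (cfg$d > cfg$n_subjects - 2) stop("'d' too large for the cohort size")
  class(cfg) <- c("fc_config", "list")
  cfg
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes simulate, featurize, fit-trajectories, embed and predict in
#' sequence and writes five artifacts beside a resolved configuration and a
#' timestamped log: the cohort table (CSV), the classified edge table (CSV),
#' the 2-D supervised-LPP embedding (CSV), the LOOCV prediction report
#' (JSON) and a small sweep table (CSV). Identical configuration and seed
#' reproduce identical artifacts.
#'
#' @param config A configuration from \code{\link{pipeline_config}}.
#' @return Invisibly, a list with the in-memory stage results and the
#'   artifact paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "fc_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  logf <- function(stage, msg)
    cat(sprintf("%s [%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                stage, msg), file = log_path, append = TRUE)

  logf("simulate", sprintf("cohort n=%d, connections=%d, seed=%d",
                           config$n_subjects, config$n_connections,
                           config$seed))
  cohort <- generate_cohort(config$n_subjects, seed = config$seed)
  spec <- plant_trajectories(config$n_connections, seed = config$seed + 1)
  features <- generate_feature_matrix(cohort, spec, seed = config$seed + 2)
  write_cohort(cohort, file.path(config$out_dir, "cohort.csv"))

  logf("fit-trajectories", "linear/quadratic fits with LOO selection")
  fits <- fit_trajectories(features, cohort)
  sel <- loo_robust_selection(features, cohort, alpha = config$alpha,
                              positivity_alpha = config$positivity_alpha,
                              fits = fits)
  fits <- classify_trajectories(fits, sel, age_range = range(cohort$age))
  utils::write.csv(fits, file.path(config$out_dir, "edges.csv"),
                   row.names = FALSE)

  logf("embed", sprintf("supervised LPP k=%d gap=%g penalty=%g", config$k,
                        config$age_gap, config$penalty))
  scan_age <- cohort$age[match(features$subject_id, cohort$subject_id)]
  emb_model <- supervised_lpp(features$values, scan_age, d = 2,
                              k = config$k, age_gap = config$age_gap,
                              penalty = config$penalty)
  emb <- data.frame(subject_id = features$subject_id, scan = features$scan,
                    age = scan_age, dim1 = emb_model$embedding[, 1],
                    dim2 = emb_model$embedding[, 2])
  utils::write.csv(emb, file.path(config$out_dir, "embedding.csv"),
                   row.names = FALSE)

  logf("predict", sprintf("LOOCV d=%d, LASVR delta=%g", config$d,
                          config$delta))
  report <- loocv_predict(features, cohort, d = config$d,
                          spec = svr_spec("lasvr", C = config$C,
                                          delta = config$delta),
                          k = config$k, age_gap = config$age_gap,
                          penalty = config$penalty)
  write_prediction_report(report,
                          file.path(config$out_dir, "prediction.json"))

  logf("sweep", "small dimension sweep, linear SVR vs LASVR")
  sweep <- sweep_parameters(features, cohort, d = c(2, 4, 7),
                            specs = list(svr_spec("linear_svr",
                                                  C = config$C),
                                         svr_spec("lasvr", C = config$C,
                                                  delta = config$delta)),
                            k = config$k, age_gap = config$age_gap,
                            penalty = config$penalty)
  utils::write.csv(sweep, file.path(config$out_dir, "sweep.csv"),
                   row.names = FALSE)

  cfg_out <- config
  class(cfg_out) <- "list"
  jsonlite::write_json(cfg_out, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  logf("done", "all artifacts written")
  invisible(list(cohort = cohort, spec = spec, features = features,
                 fits = fits, embedding = emb_model, report = report,
                 sweep = sweep, out_dir = config$out_dir))
}

#' Write / read a cohort table as CSV
#'
#' @param cohort Cohort table.
#' @param file CSV path.
#' @return \code{write_cohort}: invisibly, the file path;
#'   \code{read_cohort}: the cohort table.
#' @export
write_cohort <- function(cohort, file) {
  utils::write.csv(as.data.frame(cohort), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(file) {
  out <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "sex", "center", "n_scans")
  if (!all(need %in% names(out)))
    stop("cohort file must contain columns: ", paste(need, collapse = ", "))
  class(out) <- c("fc_cohort", "data.frame")
  out
}

#' Write / read a scan-level feature matrix as CSV
#'
#' The first two columns hold the subject id and scan index; remaining
#' columns are connections.
#'
#' @param features An \code{fc_features} object.
#' @param file CSV path.
#' @return \code{write_features}: invisibly, the file path;
#'   \code{read_features}: an \code{fc_features} object.
#' @export
write_features <- function(features, file) {
  stopifnot(inherits(features, "fc_features"))
  out <- data.frame(subject_id = features$subject_id, scan = features$scan,
                    features$values, check.names = FALSE)
  utils::write.csv(out, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_features
#' @export
read_features <- function(file) {
  out <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  fc_features(as.matrix(out[, -(1:2), drop = FALSE]), out$subject_id,
              out$scan)
}

#' Write a prediction report as JSON
#'
#' @param report An \code{fc_prediction_report}.
#' @param file JSON path.
#' @return Invisibly, the file path.
#' @export
write_prediction_report <- function(report, file) {
  out <- list(mae = report$mae, cs = as.list(report$cs),
              baseline_mae = report$baseline_mae,
              spec = as.list(report$spec), embed = report$embed,
              subjects = report$subjects)
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(file)
}
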