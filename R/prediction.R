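# Brain-age regression on manifold coordinates: linear SVR, RBF SVR and
# locally adjusted SVR (quadratic loss, no epsilon tube -- equivalent to
# (kernel) ridge regression with an intercept, solved in closed form),
# evaluated by subject-level leave-one-out cross-validation.

#' Specify a support vector regressor
#'
#' With a quadratic loss and no epsilon tube, the regularised risk
#' \eqn{\frac12 \|w\|^2 + C \sum_i (y_i - w^T z_i - b)^2} is minimised in
#' closed form by ridge regression with penalty \eqn{\lambda = 1/(2C)};
#' the RBF variant is kernel ridge regression with a Gaussian kernel whose
#' width is \code{sigma} times the mean pairwise training distance. The
#' locally adjusted variant (LASVR) refines a global linear fit with a local
#' linear fit on training samples whose age lies within \code{delta} years
#' of the global prediction.
#'
#' @param kind One of \code{"linear_svr"}, \code{"rbf_svr"}, \code{"lasvr"}.
#' @param C Regularisation trade-off (> 0). Default 0.1.
#' @param sigma RBF kernel width as a multiple of the mean pairwise training
#'   distance (RBF only). Default 1.
#' @param delta Local adjustment range in years (LASVR only). Default 8.
#' @param min_local Minimum number of training samples in the local window;
#'   below it the global prediction is returned with a fallback flag.
#'   Default 10.
#' @return A list of class \code{fc_svr_spec}.
#' @export
svr_spec <- function(kind = c("linear_svr", "rbf_svr", "lasvr"), C = 0.1,
                     sigma = 1, delta = 8, min_local = 10) {
  kind <- match.arg(kind)
  if (C <= 0) stop("'C' must be positive")
  if (kind == "rbf_svr" && sigma <= 0) stop("'sigma' must be positive")
  if (kind == "lasvr" && delta <= 0) stop("'delta' must be positive")
  structure(list(kind = kind, C = C, sigma = sigma, delta = delta,
                 min_local = min_local), class = "fc_svr_spec")
}

# closed-form ridge with unpenalised intercept
.ridge_fit <- function(Z, y, lambda) {
  Z <- as.matrix(Z)
  zm <- colMeans(Z)
  ym <- mean(y)
  Zc <- sweep(Z, 2, zm)
  w <- drop(solve(crossprod(Zc) + diag(lambda, ncol(Z), ncol(Z)),
                  crossprod(Zc, y - ym)))
  list(w = w, b = ym - sum(zm * w))
}

# training-set standardisation shared by all regressor kinds: embedding
# coordinates carry an arbitrary scale (generalised-eigenvector
# normalisation), so they are scaled once to unit training variance to make
# the trade-off C comparable across embeddings; local LASVR fits inherit the
# global scaling rather than re-standardising inside each age window
.z_scale <- function(Z) {
  zm <- colMeans(Z)
  zs <- apply(Z, 2, stats::sd)
  zs[zs == 0 | !is.finite(zs)] <- 1
  list(center = zm, sd = zs)
}

.z_apply <- function(Z, scale)
  sweep(sweep(as.matrix(Z), 2, scale$center), 2, scale$sd, "/")

.ridge_predict <- function(fit, Znew) drop(as.matrix(Znew) %*% fit$w + fit$b)

#' Fit a support vector regressor on embedded coordinates
#'
#' @param Z Training samples x dimensions matrix of manifold coordinates.
#' @param ages Chronological age per training sample.
#' @param spec Regressor specification from \code{\link{svr_spec}}.
#' @return A fitted model of class \code{fc_svr} with a
#'   \code{\link[stats]{predict}} method.
#' @examples
#' Z <- matrix(seq(0, 1, length.out = 20))
#' fit <- svr_fit(Z, 10 + 50 * Z[, 1], svr_spec("linear_svr", C = 100))
#' predict(fit, matrix(0.5))
#' @export
svr_fit <- function(Z, ages, spec = svr_spec()) {
  Z <- as.matrix(Z)
  if (nrow(Z) < 2) stop("at least 2 training samples are required")
  if (length(ages) != nrow(Z)) stop("one age per training row is required")
  if (stats::sd(ages) == 0)
    warning("all training ages equal; fitting a constant predictor")
  lambda <- 1 / (2 * spec$C)
  scale <- .z_scale(Z)
  Zs <- .z_apply(Z, scale)
  model <- list(spec = spec, scale = scale, Zs = Zs, ages = ages)
  if (spec$kind == "rbf_svr") {
    D <- as.matrix(stats::dist(Zs))
    sig <- spec$sigma * mean(D[upper.tri(D)])
    if (!is.finite(sig) || sig <= 0) sig <- 1
    K <- exp(-D^2 / (2 * sig^2))
    km <- colMeans(K)
    mk <- mean(K)
    Kc <- K - outer(rep(1, nrow(K)), km) - outer(km, rep(1, nrow(K))) + mk
    alpha <- solve(Kc + diag(lambda, nrow(K)), ages - mean(ages))
    model <- c(model, list(alpha = drop(alpha), kernel_sigma = sig,
                           km = km, mk = mk, ybar = mean(ages)))
  } else {
    model$global <- .ridge_fit(Zs, ages, lambda)
  }
  structure(model, class = "fc_svr")
}

#' Predict ages from a fitted regressor
#'
#' For LASVR models the locally adjusted prediction is returned; use
#' \code{fallback = TRUE} to also obtain the fallback flags.
#'
#' @param object A fitted \code{fc_svr} model.
#' @param newdata Samples x dimensions coordinate matrix.
#' @param fallback Return a list with predictions and LASVR fallback flags.
#' @param ... Unused.
#' @return Numeric vector of predicted ages (or a list when
#'   \code{fallback = TRUE}).
#' @export
predict.fc_svr <- function(object, newdata, fallback = FALSE, ...) {
  Znew <- .z_apply(newdata, object$scale)
  spec <- object$spec
  if (spec$kind == "rbf_svr") {
    Dx <- outer(rowSums(Znew^2), rowSums(object$Zs^2), "+") -
      2 * Znew %*% t(object$Zs)
    Kx <- exp(-pmax(Dx, 0) / (2 * object$kernel_sigma^2))
    Kxc <- Kx - rowMeans(Kx) -
      outer(rep(1, nrow(Kx)), object$km) + object$mk
    pred <- drop(Kxc %*% object$alpha) + object$ybar
    flags <- rep(FALSE, length(pred))
  } else if (spec$kind == "lasvr") {
    res <- lasvr_predict(object$global, object$Zs, object$ages, Znew,
                         delta = spec$delta, C = spec$C,
                         min_local = spec$min_local)
    pred <- res$pred
    flags <- res$fallback
  } else {
    pred <- .ridge_predict(object$global, Znew)
    flags <- rep(FALSE, length(pred))
  }
  if (fallback) list(pred = pred, fallback = flags) else pred
}

#' Locally adjusted SVR prediction
#'
#' The four-step multistage scheme: (1) a global linear SVR is learned on
#' all training samples; (2) a new sample's age is predicted globally;
#' (3) a local linear SVR is fitted on training samples whose chronological
#' age lies within \code{delta} years of the global prediction -- a
#' piecewise-linear approximation of the nonlinear age trajectory; (4) the
#' local model's prediction replaces the global one. When the local window
#' holds fewer than \code{min_local} samples the global prediction is kept
#' and flagged.
#'
#' @param global Fitted global linear model (list with \code{w}, \code{b})
#'   as produced internally by \code{\link{svr_fit}}; \code{Z} and
#'   \code{Znew} must be expressed in the coordinates the global model was
#'   fitted in.
#' @param Z Training coordinates.
#' @param ages Training ages.
#' @param Znew New coordinates.
#' @param delta Local window half-width in years.
#' @param C Regularisation trade-off of the local fits.
#' @param min_local Minimum local sample count.
#' @return List with \code{pred} and logical \code{fallback}.
#' @export
lasvr_predict <- function(global, Z, ages, Znew, delta = 8, C = 0.1,
                          min_local = 10) {
  Z <- as.matrix(Z)
  Znew <- as.matrix(Znew)
  lambda <- 1 / (2 * C)
  yhat <- .ridge_predict(global, Znew)
  pred <- yhat
  flags <- rep(FALSE, length(yhat))
  for (i in seq_along(yhat)) {
    sel <- which(ages >= yhat[i] - delta & ages <= yhat[i] + delta)
    if (length(sel) >= min_local && stats::sd(ages[sel]) > 0) {
      loc <- .ridge_fit(Z[sel, , drop = FALSE], ages[sel], lambda)
      pred[i] <- .ridge_predict(loc, Znew[i, , drop = FALSE])
    } else {
      flags[i] <- TRUE
    }
  }
  list(pred = pred, fallback = flags)
}

#' Mean absolute error
#'
#' @param pred Predicted ages.
#' @param true Chronological ages.
#' @return Mean of \eqn{|\hat{y} - y|} in years.
#' @export
mae <- function(pred, true) {
  if (length(pred) == 0 || length(pred) != length(true))
    stop("'pred' and 'true' must be non-empty and of equal length")
  mean(abs(pred - true))
}

#' Cumulative score at an error level
#'
#' Percentage of samples predicted with absolute error no higher than
#' \code{j} years.
#'
#' @param pred Predicted ages.
#' @param true Chronological ages.
#' @param j Error level(s) in years.
#' @return Percentage(s) in \code{[0, 100]}.
#' @export
cumulative_score <- function(pred, true, j) {
  if (any(j < 0)) stop("'j' must be non-negative")
  err <- abs(pred - true)
  vapply(j, function(x) 100 * mean(err <= x), numeric(1))
}

# ---------------------------------------------------------------------------
# leave-one-out cross-validation engine
#
# Per fold, the embedding model (supervised LPP or PCA) and the regressor are
# refit on the training subjects only: the held-out subject's scans and age
# label never enter the distance penalty, the graph, the prefilter basis or
# the regression fit. Multi-scan subjects stay in one fold and their per-scan
# predictions are averaged. Pairwise Euclidean distances are precomputed once
# (a training-fold distance submatrix does not depend on the held-out rows).
# Several regressor configurations and embedding dimensions can be evaluated
# in one pass: eigenvector columns are nested, so the fold embedding is
# computed once at the largest dimension and subset per configuration.

.loocv_engine <- function(features, cohort, method = "supervised_lpp",
                          k = 8, age_gap = 8, penalty = 100,
                          prefilter_rank = NULL, configs) {
  stopifnot(inherits(features, "fc_features"))
  vals <- features$values
  subj <- features$subject_id
  scan_age <- cohort$age[match(subj, cohort$subject_id)]
  if (anyNA(scan_age)) stop("features contain subjects absent from 'cohort'")
  subjects <- cohort$subject_id
  n_sub <- length(subjects)
  if (n_sub < 3) stop("at least 3 subjects are required for LOOCV")
  d_max <- max(configs$d)
  Dfull <- as.matrix(stats::dist(vals))

  pred <- matrix(NA_real_, n_sub, nrow(configs))
  fall <- matrix(FALSE, n_sub, nrow(configs))
  base_pred <- numeric(n_sub)

  for (s in seq_len(n_sub)) {
    tr <- subj != subjects[s]
    te <- !tr
    Xtr <- vals[tr, , drop = FALSE]
    ages_tr <- scan_age[tr]
    if (method == "supervised_lpp") {
      Dt <- Dfull[tr, tr]
      wide <- abs(outer(ages_tr, ages_tr, "-")) > age_gap
      Dt[wide] <- Dt[wide] * penalty
      W <- .knn_graph_quiet(Dt, k)
      model <- lpp_fit(Xtr, W, d_max, prefilter_rank)
    } else {
      model <- pca_fit(Xtr, d_max)
    }
    Ztr <- model$embedding
    Zte <- predict(model, vals[te, , drop = FALSE])
    # baseline: training subjects' mean age
    base_pred[s] <- mean(cohort$age[-s])
    for (g in seq_len(nrow(configs))) {
      dd <- configs$d[g]
      sp <- svr_spec(configs$kind[g], C = configs$C[g],
                     sigma = configs$sigma[g], delta = configs$delta[g],
                     min_local = configs$min_local[g])
      fit <- svr_fit(Ztr[, seq_len(dd), drop = FALSE], ages_tr, sp)
      pr <- predict(fit, Zte[, seq_len(dd), drop = FALSE], fallback = TRUE)
      pred[s, g] <- mean(pr$pred)           # average over repeated scans
      fall[s, g] <- any(pr$fallback)
    }
  }
  list(pred = pred, fallback = fall, baseline = base_pred,
       ages = cohort$age, subjects = subjects)
}

.knn_graph_quiet <- function(D, k)
  suppressWarnings(build_knn_graph(D, k, connect = TRUE))

.config_frame <- function(spec, d) {
  data.frame(kind = spec$kind, C = spec$C, sigma = spec$sigma,
             delta = spec$delta, min_local = spec$min_local, d = d,
             stringsAsFactors = FALSE)
}

#' Leave-one-out cross-validated brain-age prediction
#'
#' Runs subject-level LOOCV of the full prediction pipeline: in every fold
#' the supervised LPP (or PCA) embedding and the regressor are refit on the
#' training subjects only, the held-out subject's scans are projected and
#' predicted, and predictions from repeated scans are averaged. Performance
#' is summarised by the mean absolute error and cumulative scores, alongside
#' a predict-the-training-mean baseline.
#'
#' @param features An \code{fc_features} object (one row per scan).
#' @param cohort Cohort table.
#' @param d Embedding dimension.
#' @param spec Regressor specification from \code{\link{svr_spec}}.
#' @param method \code{"supervised_lpp"} or \code{"pca"}.
#' @param k,age_gap,penalty Supervised-LPP graph parameters (defaults 8, 8
#'   years, 100).
#' @param prefilter_rank Passed to \code{\link{lpp_fit}}.
#' @param cs_levels Error levels (years) for cumulative scores.
#' @return An \code{fc_prediction_report}: list with per-subject results
#'   (\code{subjects} data frame), \code{mae}, \code{cs},
#'   \code{baseline_mae}, and the configuration used.
#' @examples
#' coh <- generate_cohort(30, seed = 1)
#' feat <- generate_feature_matrix(coh, plant_trajectories(60, seed = 2),
#'                                 seed = 3)
#' rep <- loocv_predict(feat, coh, d = 2, spec = svr_spec("linear_svr"))
#' rep$mae
#' @export
loocv_predict <- function(features, cohort, d, spec = svr_spec(),
                          method = c("supervised_lpp", "pca"), k = 8,
                          age_gap = 8, penalty = 100, prefilter_rank = NULL,
                          cs_levels = c(5, 10, 20)) {
  method <- match.arg(method)
  configs <- .config_frame(spec, d)
  run <- .loocv_engine(features, cohort, method, k, age_gap, penalty,
                       prefilter_rank, configs)
  .assemble_report(run, 1, configs, method, k, age_gap, penalty, cs_levels)
}

.assemble_report <- function(run, g, configs, method, k, age_gap, penalty,
                             cs_levels) {
  pred <- run$pred[, g]
  err <- abs(pred - run$ages)
  structure(list(
    subjects = data.frame(subject_id = run$subjects, age = run$ages,
                          predicted = pred, abs_error = err,
                          fallback = run$fallback[, g],
                          stringsAsFactors = FALSE),
    mae = mean(err),
    cs = stats::setNames(cumulative_score(pred, run$ages, cs_levels),
                         paste0("CS(", cs_levels, ")")),
    baseline_mae = mean(abs(run$baseline - run$ages)),
    spec = configs[g, ],
    embed = list(method = method, k = k, age_gap = age_gap,
                 penalty = penalty, d = configs$d[g])),
    class = "fc_prediction_report")
}

#' @export
print.fc_prediction_report <- function(x, ...) {
  cat(sprintf("fc_prediction_report: %s (d = %d) via %s\n",
              x$spec$kind, x$spec$d, x$embed$method))
  cat(sprintf("  MAE %.2f years (baseline %.2f); %s\n", x$mae,
              x$baseline_mae,
              paste(sprintf("%s = %.0f%%", names(x$cs), x$cs),
                    collapse = ", ")))
  invisible(x)
}

#' Parameter sweep of the prediction pipeline
#'
#' Evaluates every combination of embedding dimension, regressor
#' specification and (optionally) graph parameters by LOOCV, reusing one
#' cross-validation pass per graph setting. Returns one row per combination
#' with MAE and cumulative scores; \code{\link{best_by_method}} condenses
#' the table to the best dimension per regressor.
#'
#' @param features An \code{fc_features} object.
#' @param cohort Cohort table.
#' @param d Vector of embedding dimensions (default 2:15).
#' @param specs List of \code{\link{svr_spec}} objects.
#' @param method,k,prefilter_rank Passed to the LOOCV engine.
#' @param age_gap,penalty Vectors of graph parameters; all combinations are
#'   evaluated.
#' @param cs_levels Error levels for cumulative scores.
#' @return Data frame with columns \code{method}, \code{C}, \code{sigma},
#'   \code{delta}, \code{d}, \code{age_gap}, \code{penalty}, \code{mae},
#'   one \code{cs*} column per level, and \code{baseline_mae}.
#' @export
sweep_parameters <- function(features, cohort, d = 2:15,
                             specs = list(svr_spec("linear_svr"),
                                          svr_spec("lasvr", delta = 8)),
                             method = "supervised_lpp", k = 8, age_gap = 8,
                             penalty = 100, prefilter_rank = NULL,
                             cs_levels = c(5, 10, 20)) {
  configs <- do.call(rbind, lapply(specs, function(sp)
    do.call(rbind, lapply(d, function(dd) .config_frame(sp, dd)))))
  grid <- expand.grid(age_gap = age_gap, penalty = penalty)
  out <- NULL
  for (gidx in seq_len(nrow(grid))) {
    run <- .loocv_engine(features, cohort, method, k, grid$age_gap[gidx],
                         grid$penalty[gidx], prefilter_rank, configs)
    for (g in seq_len(nrow(configs))) {
      pred <- run$pred[, g]
      cs <- cumulative_score(pred, run$ages, cs_levels)
      row <- data.frame(method = configs$kind[g], C = configs$C[g],
                        sigma = configs$sigma[g], delta = configs$delta[g],
                        d = configs$d[g], age_gap = grid$age_gap[gidx],
                        penalty = grid$penalty[gidx],
                        mae = mean(abs(pred - run$ages)),
                        baseline_mae = mean(abs(run$baseline - run$ages)),
                        stringsAsFactors = FALSE)
      row[paste0("cs", cs_levels)] <- as.list(cs)
      out <- rbind(out, row)
    }
  }
  out
}

#' Best result per regression method
#'
#' Condenses a \code{\link{sweep_parameters}} table to the row with minimum
#' MAE per method (and local-adjustment range for LASVR), the layout used to
#' compare SVR variants across embedding dimensions.
#'
#' @param sweep Result of \code{\link{sweep_parameters}}.
#' @return Data frame with one row per method/delta combination.
#' @export
best_by_method <- function(sweep) {
  key <- ifelse(sweep$method == "lasvr",
                paste0("lasvr(", sweep$delta, ")"), sweep$method)
  do.call(rbind, lapply(split(sweep, key), function(g)
    g[which.min(g$mae), , drop = FALSE]))
}
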