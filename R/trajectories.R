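# Per-connection developmental trajectory fitting: linear and quadratic OLS
# with sex/centre covariates, AICc model selection, positivity screening,
# leave-one-subject-out robust significance, classification and peak ages.

# multi-column OLS: coefficients, t/p for one target column, AICc
.ols_fit <- function(X, Y, target_col, use_aicc = TRUE) {
  n <- nrow(X)
  k <- ncol(X)
  qx <- qr(X)
  if (qx$rank < k) {
    sds <- apply(X[, -1, drop = FALSE], 2, stats::sd)
    bad <- colnames(X)[-1][which(sds == 0)[1]]
    if (is.na(bad)) bad <- "unknown"
    stop(sprintf("collinear design matrix (degenerate column: %s)", bad))
  }
  B <- qr.coef(qx, Y)
  R <- qr.resid(qx, Y)
  rss <- colSums(R^2)
  df <- n - k
  sigma2 <- rss / df
  xtx_inv <- chol2inv(chol(crossprod(X)))
  tc <- match(target_col, colnames(X))
  se <- sqrt(sigma2 * xtx_inv[tc, tc])
  tval <- B[target_col, ] / se
  pval <- 2 * stats::pt(-abs(tval), df)
  npar <- k + 1                                  # + residual variance
  aic <- n * (log(2 * pi) + 1) + n * log(rss / n) + 2 * npar
  if (use_aicc) aic <- aic + 2 * npar * (npar + 1) / (n - npar - 1)
  list(coef = B, t = tval, p = pval, aic = aic, df = df)
}

.design_matrices <- function(age, sex, center) {
  list(linear = cbind(intercept = 1, age = age, sex = sex, center = center),
       quadratic = cbind(intercept = 1, age = age, age2 = age^2,
                         sex = sex, center = center))
}

#' Fit linear and quadratic age trajectories per connection
#'
#' For each connection, fits by ordinary least squares the two models
#' \deqn{y = \beta_0 + \beta_1 age + \beta_{sex} sex + \beta_{center} center
#'   + \epsilon}
#' \deqn{y = \beta_0 + \beta_1 age + \beta_2 age^2 + \beta_{sex} sex +
#'   \beta_{center} center + \epsilon}
#' on one row per subject (repeated scans averaged first), computes the
#' two-tailed t statistic and p-value of the age term in the linear model and
#' of the age-squared term in the quadratic model (the quadratic curvature
#' test after removing linear age effects), and selects the best model per
#' connection by minimum AICc (small-sample corrected; plain AIC via
#' \code{use_aicc = FALSE}).
#'
#' @param features An \code{fc_features} object or a subjects x connections
#'   matrix with subject ids as rownames.
#' @param cohort Cohort table with \code{subject_id}, \code{age}, \code{sex},
#'   \code{center}.
#' @param use_aicc Use the small-sample corrected AICc (default) rather than
#'   plain AIC.
#' @param collapse Average repeated scans into one row per subject before
#'   fitting (default). With \code{FALSE}, each scan enters as a sample.
#' @return A \code{data.frame} of class \code{fc_trajectory_fits}, one row
#'   per connection, with linear-model columns (\code{lin_*}),
#'   quadratic-model columns (\code{quad_*}) and \code{best_model}.
#' @examples
#' coh <- generate_cohort(40, seed = 1)
#' spec <- plant_trajectories(20, seed = 2)
#' feat <- generate_feature_matrix(coh, spec, seed = 3)
#' fits <- fit_trajectories(feat, coh)
#' table(fits$best_model)
#' @export
fit_trajectories <- function(features, cohort, use_aicc = TRUE,
                             collapse = TRUE) {
  Y <- .feature_rows(features, cohort, collapse)
  cov <- attr(Y, "covariates")
  if (nrow(Y) < 6)
    stop("at least 6 samples are required (the quadratic model has 5 ",
         "parameters)")
  dm <- .design_matrices(cov$age, cov$sex, cov$center)
  fl <- .ols_fit(dm$linear, Y, "age", use_aicc)
  fq <- .ols_fit(dm$quadratic, Y, "age2", use_aicc)
  out <- data.frame(
    connection = seq_len(ncol(Y)),
    lin_beta0 = fl$coef["intercept", ],
    lin_beta_age = fl$coef["age", ],
    lin_beta_sex = fl$coef["sex", ],
    lin_beta_center = fl$coef["center", ],
    lin_t_age = fl$t, lin_p_age = fl$p, lin_aic = fl$aic,
    quad_beta0 = fq$coef["intercept", ],
    quad_beta_age = fq$coef["age", ],
    quad_beta_age2 = fq$coef["age2", ],
    quad_beta_sex = fq$coef["sex", ],
    quad_beta_center = fq$coef["center", ],
    quad_t_age2 = fq$t, quad_p_age2 = fq$p, quad_aic = fq$aic,
    best_model = ifelse(fq$aic < fl$aic, "quadratic", "linear"),
    row.names = colnames(Y),
    stringsAsFactors = FALSE
  )
  class(out) <- c("fc_trajectory_fits", "data.frame")
  out
}

# one row per subject (or scan), aligned with the cohort; attaches covariates
.feature_rows <- function(features, cohort, collapse = TRUE) {
  if (inherits(features, "fc_features")) {
    if (collapse) {
      Y <- collapse_scans(features, cohort$subject_id)
      cov <- cohort
    } else {
      idx <- match(features$subject_id, cohort$subject_id)
      if (anyNA(idx)) stop("features contain subjects absent from 'cohort'")
      Y <- features$values
      cov <- cohort[idx, , drop = FALSE]
    }
  } else {
    Y <- as.matrix(features)
    idx <- match(rownames(Y), cohort$subject_id)
    if (anyNA(idx))
      stop("rownames of 'features' must be cohort subject ids")
    cov <- cohort[idx, , drop = FALSE]
  }
  if (is.null(colnames(Y))) colnames(Y) <- paste0("c", seq_len(ncol(Y)))
  attr(Y, "covariates") <- cov
  Y
}

#' Positivity screen: connections positive across subjects
#'
#' One-sided one-sample t-test per connection that the mean Fisher-z value is
#' greater than 0; a connection passes when \eqn{p < \alpha}. Because the
#' physiological meaning of negative functional connectivity is contested
#' (anticorrelation versus an artefact of global-signal regression),
#' downstream selection is restricted to connections passing this screen.
#' Zero-variance columns pass when their constant value is positive, with a
#' warning.
#'
#' @param features \code{fc_features} object or subjects x connections
#'   matrix. Repeated scans are averaged per subject when a cohort is given.
#' @param alpha Significance level. Default 0.001.
#' @param cohort Optional cohort table used to collapse repeated scans.
#' @return Logical vector, one entry per connection.
#' @export
positivity_filter <- function(features, alpha = 0.001, cohort = NULL) {
  Y <- if (!is.null(cohort)) .feature_rows(features, cohort, TRUE)
       else if (inherits(features, "fc_features")) features$values
       else as.matrix(features)
  n <- nrow(Y)
  if (n < 3) stop("at least 3 rows are required for the positivity screen")
  m <- colMeans(Y)
  s <- sqrt(colSums(sweep(Y, 2, m)^2) / (n - 1))
  pass <- logical(ncol(Y))
  zv <- s == 0
  if (any(zv)) {
    warning(sprintf("%d zero-variance column(s); passing iff constant > 0",
                    sum(zv)))
    pass[zv] <- m[zv] > 0
  }
  tstat <- m[!zv] / (s[!zv] / sqrt(n))
  pass[!zv] <- stats::pt(tstat, n - 1, lower.tail = FALSE) < alpha
  pass
}

#' Leave-one-subject-out robust connection selection
#'
#' A connection is selected when (i) it passes the positivity screen and
#' (ii) its relevant age term -- the linear-model age coefficient or the
#' quadratic-model age-squared coefficient, according to the full-sample
#' AICc-selected model -- is significant at \code{alpha} in each of the N
#' refits obtained by leaving one subject out. This guards the trajectory
#' classification against single influential subjects.
#'
#' @param features \code{fc_features} object or subjects x connections
#'   matrix.
#' @param cohort Cohort table.
#' @param alpha Per-refit significance level for the age term. Default 1e-4.
#' @param positivity_alpha Level of the positivity screen. Default 1e-3.
#' @param fits Optional precomputed \code{\link{fit_trajectories}} result.
#' @param use_aicc Passed to \code{\link{fit_trajectories}} when \code{fits}
#'   is not supplied.
#' @return A \code{data.frame} with one row per connection:
#'   \code{connection}, \code{positive_pass}, \code{loo_sig},
#'   \code{loo_pass} (the conjunction), and \code{max_loo_p} (largest
#'   leave-one-out p-value of the relevant term).
#' @export
loo_robust_selection <- function(features, cohort, alpha = 1e-4,
                                 positivity_alpha = 1e-3, fits = NULL,
                                 use_aicc = TRUE) {
  Y <- .feature_rows(features, cohort, TRUE)
  cov <- attr(Y, "covariates")
  n <- nrow(Y)
  if (n < 7) stop("insufficient subjects for leave-one-out refits")
  if (is.null(fits)) fits <- fit_trajectories(features, cohort, use_aicc)
  is_quad <- fits$best_model == "quadratic"
  max_p <- rep(0, ncol(Y))
  for (s in seq_len(n)) {
    dm <- .design_matrices(cov$age[-s], cov$sex[-s], cov$center[-s])
    if (any(!is_quad)) {
      fl <- .ols_fit(dm$linear, Y[-s, !is_quad, drop = FALSE], "age")
      max_p[!is_quad] <- pmax(max_p[!is_quad], fl$p)
    }
    if (any(is_quad)) {
      fq <- .ols_fit(dm$quadratic, Y[-s, is_quad, drop = FALSE], "age2")
      max_p[is_quad] <- pmax(max_p[is_quad], fq$p)
    }
  }
  positive <- positivity_filter(Y, positivity_alpha)
  loo_sig <- max_p < alpha
  data.frame(connection = fits$connection,
             positive_pass = positive,
             loo_sig = loo_sig,
             loo_pass = positive & loo_sig,
             max_loo_p = max_p,
             row.names = rownames(fits),
             stringsAsFactors = FALSE)
}

#' Peak age of a quadratic trajectory
#'
#' The age of extremal connectivity strength, from the root of the first
#' derivative of the fitted quadratic curve: \eqn{-\beta_{age} /
#' (2 \beta_{age^2})}.
#'
#' @param beta_age Linear coefficient(s) of the quadratic model.
#' @param beta_age2 Quadratic coefficient(s); must be nonzero.
#' @param age_range Optional observed age range; peaks outside it are
#'   flagged with a warning.
#' @return Peak age(s) in years.
#' @examples
#' peak_age(8, -0.1)    # 40
#' @export
peak_age <- function(beta_age, beta_age2, age_range = NULL) {
  if (any(beta_age2 == 0))
    stop("peak age is undefined for zero quadratic coefficient")
  pk <- -beta_age / (2 * beta_age2)
  if (!is.null(age_range) &&
      any(pk < age_range[1] | pk > age_range[2], na.rm = TRUE))
    warning("some peak ages fall outside the observed age range")
  pk
}

#' Classify connections into developmental trajectory types
#'
#' Combines model selection and robust screening into the four trajectory
#' classes: connections whose best model is quadratic and that pass the
#' robust selection are \code{pos_quad} (U-shaped) or \code{neg_quad}
#' (inverted-U) by the sign of the age-squared coefficient; connections
#' whose best model is linear and that pass are \code{pos_linear} or
#' \code{neg_linear} by the sign of the age coefficient; all others are
#' \code{none}. Peak ages are attached for quadratic classes.
#'
#' @param fits Result of \code{\link{fit_trajectories}}.
#' @param selection Result of \code{\link{loo_robust_selection}}.
#' @param age_range Optional observed age range for peak-age flagging.
#' @return The \code{fits} data frame augmented with \code{positive_pass},
#'   \code{loo_pass}, \code{class} and \code{peak_age}.
#' @export
classify_trajectories <- function(fits, selection, age_range = NULL) {
  stopifnot(nrow(fits) == nrow(selection))
  cls <- rep("none", nrow(fits))
  quad <- fits$best_model == "quadratic" & selection$loo_pass
  lin <- fits$best_model == "linear" & selection$loo_pass
  cls[quad] <- ifelse(fits$quad_beta_age2[quad] > 0, "pos_quad", "neg_quad")
  cls[lin] <- ifelse(fits$lin_beta_age[lin] > 0, "pos_linear", "neg_linear")
  pk <- rep(NA_real_, nrow(fits))
  if (any(quad))
    pk[quad] <- peak_age(fits$quad_beta_age[quad],
                         fits$quad_beta_age2[quad], age_range)
  fits$positive_pass <- selection$positive_pass
  fits$loo_pass <- selection$loo_pass
  fits$class <- cls
  fits$peak_age <- pk
  fits
}

#' Summarise peak ages of passing quadratic connections
#'
#' @param fits Classified fits from \code{\link{classify_trajectories}}.
#' @return Data frame with one row per quadratic class: n, mean, sd, min,
#'   max of the peak ages.
#' @export
peak_age_summary <- function(fits) {
  out <- lapply(c("pos_quad", "neg_quad"), function(cl) {
    pk <- fits$peak_age[fits$class == cl]
    data.frame(class = cl, n = length(pk),
               mean = if (length(pk)) mean(pk) else NA_real_,
               sd = if (length(pk) > 1) stats::sd(pk) else NA_real_,
               min = if (length(pk)) min(pk) else NA_real_,
               max = if (length(pk)) max(pk) else NA_real_)
  })
  do.call(rbind, out)
}

#' Regress mean head motion out of connection features
#'
#' Residualises each feature column against an intercept and the subjects'
#' mean framewise displacement, removing motion-correlated variance before
#' trajectory refitting (the standard check that age effects are not merely
#' motion artefacts). Residuals are exactly orthogonal to the motion vector;
#' column means are removed as part of the projection. A constant motion
#' vector leaves the features unchanged, with a warning.
#'
#' @param features \code{fc_features} object or numeric matrix.
#' @param mean_fd Mean framewise displacement per row (scans) or, for an
#'   \code{fc_features} input, per subject in cohort order when \code{cohort}
#'   is supplied.
#' @param cohort Optional cohort table carrying \code{mean_fd}; used to map
#'   subject-level motion to scan rows.
#' @return Object of the same type with residualised values.
#' @export
regress_motion <- function(features, mean_fd = NULL, cohort = NULL) {
  vals <- if (inherits(features, "fc_features")) features$values
          else as.matrix(features)
  if (is.null(mean_fd)) {
    if (is.null(cohort) || is.null(cohort$mean_fd))
      stop("supply 'mean_fd' or a cohort containing it")
    ids <- if (inherits(features, "fc_features")) features$subject_id
           else rownames(vals)
    mean_fd <- cohort$mean_fd[match(ids, cohort$subject_id)]
  }
  if (length(mean_fd) != nrow(vals))
    stop("one motion value per feature row is required")
  if (any(!is.finite(mean_fd))) stop("motion values must be finite")
  if (stats::sd(mean_fd) == 0) {
    warning("constant motion vector; features returned unchanged")
    return(features)
  }
  res <- qr.resid(qr(cbind(1, mean_fd)), vals)
  if (inherits(features, "fc_features")) {
    features$values <- res
    features
  } else res
}

#' Write a classified edge table
#'
#' Exports one row per connection with 1-based region indices, trajectory
#' class, coefficients, test statistics, AICc values and peak age, in a
#' layout suitable for graph tools.
#'
#' @param fits Classified fits from \code{\link{classify_trajectories}}.
#' @param n_regions Number of regions whose upper triangle the connections
#'   enumerate (row-major order).
#' @param file Path of the CSV file to write.
#' @return Invisibly, the exported data frame.
#' @export
write_edge_table <- function(fits, n_regions, file) {
  m <- n_regions * (n_regions - 1) / 2
  if (nrow(fits) != m)
    stop("number of connections does not match n_regions")
  idx <- which(upper.tri(matrix(0, n_regions, n_regions)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]   # row-major
  out <- cbind(data.frame(region_i = idx[, 1], region_j = idx[, 2]),
               fits[, c("class", "lin_beta0", "lin_beta_age", "lin_t_age",
                        "lin_p_age", "lin_aic", "quad_beta_age",
                        "quad_beta_age2", "quad_t_age2", "quad_p_age2",
                        "quad_aic", "best_model", "peak_age")])
  utils::write.csv(out, file, row.names = FALSE)
  invisible(out)
}
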