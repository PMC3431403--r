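# Synthetic study data: cohorts, planted trajectories, features, time series,
# realignment series. The generator emulates a pooled two-centre lifespan
# cohort (a paediatric-to-middle-age centre coded 0, single scan; an
# adult-to-elderly centre coded 1, two scans per subject).

# Default age-band structure of the emulated cohort: band limits (years),
# subject counts, and group mean/sd of mean framewise displacement (mm).
# The counts drive the age-sampling mixture; the motion columns calibrate the
# U-shaped motion-age profile (children and elderly move more than young
# adults).
.age_bands <- data.frame(
  lo = c(8, 21, 31, 41, 51, 61, 71),
  hi = c(20, 30, 40, 50, 60, 70, 79),
  n  = c(34, 50, 11, 16, 7, 10, 4),
  fd_mean = c(0.194, 0.121, 0.160, 0.173, 0.199, 0.247, 0.288),
  fd_sd   = c(0.123, 0.048, 0.060, 0.067, 0.045, 0.129, 0.053)
)

# Reference design used to express planted effect sizes as t-values:
# n = 137 subjects with ages drawn from the .age_bands mixture, sex a fair
# coin, and centre assigned by the age-dependent eligibility rule below.
# .ref_sd_age is the PARTIAL sd of age given {1, sex, center} (centre is
# strongly age-dependent, which shrinks it well below the marginal sd) and
# .ref_sd_age2 the partial sd of age^2 given {1, age, sex, center}
# (Monte-Carlo, 1e6 draws, frozen here). With slope b and noise sd s, the
# age-term t statistic is approximately b * sd_partial * sqrt(n) / s.
.ref_n <- 137
.ref_sd_age <- 14.096
.ref_sd_age2 <- 316.94

.center1_min_age <- 19  # two-scan centre scanned adults only
.center0_max_age <- 49  # single-scan centre stopped at middle age

#' Generate a synthetic two-centre lifespan cohort
#'
#' Draws a cohort table with ages sampled from a mixture over the default
#' lifespan age bands (weights proportional to the band sizes of the emulated
#' two-centre study), a 0/1 sex covariate, a 0/1 centre covariate with
#' age-dependent eligibility (centre 1 scanned only adults, centre 0 only
#' subjects up to middle age), two scans per subject for centre 1, and an
#' age-dependent mean head motion following a U-shaped profile fitted through
#' the default age-band motion means (children and elderly move more).
#'
#' @param n_subjects Number of subjects (at least 4).
#' @param age_range Length-2 increasing numeric vector of admissible ages in
#'   years. Default \code{c(8, 79)}.
#' @param center_split Expected fraction of subjects in centre 1 (the
#'   two-scan centre), in (0, 1). Eligibility constraints by age may move
#'   individual subjects.
#' @param motion_sd Subject-level standard deviation (mm) around the
#'   motion-age profile. Motion is floored at 0.
#' @param seed Optional integer seed; fixed seed gives an identical table.
#' @return A \code{data.frame} of class \code{fc_cohort} with columns
#'   \code{subject_id}, \code{age}, \code{sex}, \code{center},
#'   \code{n_scans}, \code{mean_fd}.
#' @examples
#' coh <- generate_cohort(137, seed = 1)
#' range(coh$age)
#' table(coh$center, coh$n_scans)
#' @export
generate_cohort <- function(n_subjects, age_range = c(8, 79),
                            center_split = 53 / 137, motion_sd = 0.04,
                            seed = NULL) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1 || n_subjects < 4)
    stop("'n_subjects' must be a single integer >= 4")
  if (length(age_range) != 2 || !all(is.finite(age_range)) ||
      age_range[2] <= age_range[1])
    stop("'age_range' must be an increasing pair of ages")
  if (!is.numeric(center_split) || center_split <= 0 || center_split >= 1)
    stop("'center_split' must lie strictly inside (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_subjects)

  # restrict the age-band mixture to the requested range
  bands <- .age_bands
  bands$lo <- pmax(bands$lo, age_range[1])
  bands$hi <- pmin(bands$hi, age_range[2])
  bands <- bands[bands$hi > bands$lo, , drop = FALSE]
  if (nrow(bands) == 0) {                 # range inside a single band
    bands <- data.frame(lo = age_range[1], hi = age_range[2], n = 1)
  }
  b <- sample.int(nrow(bands), n, replace = TRUE, prob = bands$n)
  age <- stats::runif(n, bands$lo[b], bands$hi[b])

  sex <- stats::rbinom(n, 1, 0.5)
  center <- stats::rbinom(n, 1, center_split)
  center[age < .center1_min_age] <- 0L
  center[age > .center0_max_age] <- 1L

  # U-shaped motion-age profile: quadratic least-squares fit through the
  # age-band motion means at band midpoints
  mid <- (.age_bands$lo + .age_bands$hi) / 2
  qfit <- stats::lm.fit(cbind(1, mid, mid^2), .age_bands$fd_mean)$coefficients
  mu_fd <- qfit[1] + qfit[2] * age + qfit[3] * age^2
  mean_fd <- pmax(0, mu_fd + stats::rnorm(n, 0, motion_sd))

  out <- data.frame(
    subject_id = sprintf("sub%04d", seq_len(n)),
    age = age,
    sex = as.integer(sex),
    center = as.integer(center),
    n_scans = 1L + as.integer(center),
    mean_fd = mean_fd,
    stringsAsFactors = FALSE
  )
  class(out) <- c("fc_cohort", "data.frame")
  out
}

#' Plant per-connection developmental trajectories
#'
#' Draws a per-connection generative specification on the Fisher-z scale:
#' each connection is assigned one of five classes (positive/negative linear,
#' positive/negative quadratic, null) and coefficients
#' \eqn{y = \beta_0 + \beta_1 age + \beta_2 age^2 + \beta_{sex} sex +
#' \beta_{center} center + \epsilon}. Effect sizes are expressed as the
#' expected age-term t statistic at the reference design (137 subjects with
#' the default lifespan age mixture), so \code{effect_scale = 6} plants
#' effects a well-powered study would detect. Quadratic peaks
#' \eqn{-\beta_1/(2\beta_2)} are drawn uniformly from \code{peak_window}.
#' Baselines are chosen so the noiseless age trend stays positive over
#' \code{age_range} (its minimum is drawn from \code{baseline_range}), making
#' downstream positivity screening non-trivial but passable for planted
#' effects.
#'
#' @param n_connections Number of connections.
#' @param class_proportions Length-5 non-negative vector summing to 1, in the
#'   order (pos_linear, neg_linear, pos_quad, neg_quad, null). The default
#'   weights quadratic trajectories most heavily, mirroring the predominance
#'   of U- and inverted-U-shaped lifespan trajectories among age-sensitive
#'   association connections, with smaller linear and null shares.
#' @param effect_scale Target age-term |t| at the reference design.
#' @param noise_sd Residual standard deviation on the Fisher-z scale.
#' @param peak_window Age window (years) for planted quadratic peaks.
#' @param age_range Ages over which the positivity floor is enforced.
#' @param baseline_range Range for the minimum of the noiseless age trend.
#' @param covariate_scale Half-width of the uniform sex/centre offsets.
#' @param seed Optional integer seed.
#' @return A \code{data.frame} of class \code{fc_trajectory_spec} with one
#'   row per connection: \code{connection}, \code{class}, \code{beta0},
#'   \code{beta_age}, \code{beta_age2}, \code{beta_sex}, \code{beta_center},
#'   \code{noise_sd}, \code{peak_age} (NA for non-quadratic classes).
#' @examples
#' spec <- plant_trajectories(100, seed = 1)
#' table(spec$class)
#' @export
plant_trajectories <- function(n_connections,
                               class_proportions = c(pos_linear = 0.10,
                                                     neg_linear = 0.10,
                                                     pos_quad = 0.30,
                                                     neg_quad = 0.30,
                                                     null = 0.20),
                               effect_scale = 6, noise_sd = 0.1,
                               peak_window = c(34, 47),
                               age_range = c(8, 79),
                               baseline_range = c(0.2, 0.6),
                               covariate_scale = 0.05, seed = NULL) {
  if (n_connections < 1) stop("'n_connections' must be positive")
  if (length(class_proportions) != 5 || any(class_proportions < 0))
    stop("'class_proportions' must be 5 non-negative numbers")
  if (abs(sum(class_proportions) - 1) > 1e-8)
    stop("'class_proportions' must sum to 1")
  if (noise_sd <= 0) stop("'noise_sd' must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_connections)

  classes <- c("pos_linear", "neg_linear", "pos_quad", "neg_quad", "null")
  # largest-remainder allocation so proportions are honoured exactly, then a
  # random ordering across connections
  counts <- diff(c(0L, round(cumsum(class_proportions) * n)))
  cls <- sample(rep(classes, counts))

  # calibration: slope magnitude giving age-term |t| = effect_scale at the
  # reference design, with mild per-connection heterogeneity
  b_lin <- effect_scale * noise_sd / (.ref_sd_age * sqrt(.ref_n))
  b_quad <- effect_scale * noise_sd / (.ref_sd_age2 * sqrt(.ref_n))
  jitter <- stats::runif(n, 0.9, 1.1)

  beta_age <- beta_age2 <- numeric(n)
  peak <- rep(NA_real_, n)
  lin <- cls %in% c("pos_linear", "neg_linear")
  quad <- cls %in% c("pos_quad", "neg_quad")
  sgn <- ifelse(cls %in% c("pos_linear", "pos_quad"), 1, -1)

  beta_age[lin] <- sgn[lin] * b_lin * jitter[lin]
  beta_age2[quad] <- sgn[quad] * b_quad * jitter[quad]
  peak[quad] <- stats::runif(sum(quad), peak_window[1], peak_window[2])
  beta_age[quad] <- -2 * beta_age2[quad] * peak[quad]

  # baseline keeps the noiseless trend positive over the age range
  grid <- seq(age_range[1], age_range[2], length.out = 200)
  trend_min <- vapply(seq_len(n), function(i)
    min(beta_age[i] * grid + beta_age2[i] * grid^2), numeric(1))
  beta0 <- stats::runif(n, baseline_range[1], baseline_range[2]) - trend_min

  out <- data.frame(
    connection = seq_len(n),
    class = cls,
    beta0 = beta0,
    beta_age = beta_age,
    beta_age2 = beta_age2,
    beta_sex = stats::runif(n, -covariate_scale, covariate_scale),
    beta_center = stats::runif(n, -covariate_scale, covariate_scale),
    noise_sd = noise_sd,
    peak_age = peak,
    stringsAsFactors = FALSE
  )
  class(out) <- c("fc_trajectory_spec", "data.frame")
  out
}

#' Generate a scan-level feature matrix from a planted specification
#'
#' Produces one row per scan (subjects with \code{n_scans = 2} contribute two
#' rows sharing covariates but with independent noise); entries are
#' \eqn{\beta_0 + \beta_1 age + \beta_2 age^2 + \beta_{sex} sex +
#' \beta_{center} center + N(0, noise\_sd^2)} on the Fisher-z scale.
#'
#' @param cohort A cohort table from \code{\link{generate_cohort}}.
#' @param spec A trajectory specification from
#'   \code{\link{plant_trajectories}}.
#' @param seed Optional integer seed.
#' @return An \code{fc_features} object: list with \code{values} (scans x
#'   connections matrix), \code{subject_id} and \code{scan} per row.
#' @examples
#' coh <- generate_cohort(20, seed = 1)
#' spec <- plant_trajectories(10, seed = 2)
#' feat <- generate_feature_matrix(coh, spec, seed = 3)
#' dim(feat$values)
#' @export
generate_feature_matrix <- function(cohort, spec, seed = NULL) {
  if (nrow(cohort) == 0 || nrow(spec) == 0)
    stop("'cohort' and 'spec' must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  rows <- rep(seq_len(nrow(cohort)), cohort$n_scans)
  scan <- sequence(cohort$n_scans)
  X <- cbind(1, cohort$age[rows], cohort$age[rows]^2,
             cohort$sex[rows], cohort$center[rows])
  B <- rbind(spec$beta0, spec$beta_age, spec$beta_age2,
             spec$beta_sex, spec$beta_center)
  mu <- X %*% B
  vals <- mu + matrix(stats::rnorm(length(mu), 0, 1), nrow(mu), ncol(mu)) *
    rep(spec$noise_sd, each = nrow(mu))
  colnames(vals) <- paste0("c", spec$connection)
  rownames(vals) <- paste0(cohort$subject_id[rows], "_s", scan)
  fc_features(vals, cohort$subject_id[rows], scan)
}

#' Construct a scan-level feature container
#'
#' @param values Numeric matrix, one row per scan, one column per connection.
#' @param subject_id Character vector mapping rows to subjects.
#' @param scan Integer scan index within subject.
#' @return An object of class \code{fc_features}.
#' @export
fc_features <- function(values, subject_id,
                        scan = stats::ave(seq_along(subject_id), subject_id,
                                          FUN = seq_along)) {
  values <- as.matrix(values)
  if (nrow(values) != length(subject_id))
    stop("one 'subject_id' per row of 'values' is required")
  rownames(values) <- paste0(subject_id, "_s", as.integer(scan))
  structure(list(values = values, subject_id = as.character(subject_id),
                 scan = as.integer(scan)),
            class = "fc_features")
}

#' @export
print.fc_features <- function(x, ...) {
  cat(sprintf("fc_features: %d scans (%d subjects) x %d connections\n",
              nrow(x$values), length(unique(x$subject_id)), ncol(x$values)))
  invisible(x)
}

#' Average repeated scans into one feature row per subject
#'
#' @param features An \code{fc_features} object.
#' @param subjects Optional character vector giving the subject order of the
#'   output (default: order of first appearance).
#' @return Matrix with one row per subject, rownames the subject ids.
#' @export
collapse_scans <- function(features, subjects = unique(features$subject_id)) {
  g <- factor(features$subject_id, levels = subjects)
  if (anyNA(g)) stop("features contain subjects not listed in 'subjects'")
  out <- rowsum(features$values, g) / as.vector(table(g))
  rownames(out) <- subjects
  out
}

#' Generate multivariate time series with a target correlation structure
#'
#' Draws a zero-mean Gaussian process whose population correlation matrix
#' equals \code{target_corr}, by applying a symmetric matrix square root to
#' independent noise. Mildly indefinite targets (numerical artefacts) are
#' repaired by clipping negative eigenvalues to zero, with a warning.
#'
#' @param target_corr Symmetric positive semi-definite matrix with unit
#'   diagonal.
#' @param n_timepoints Number of timepoints (at least regions + 1
#'   recommended).
#' @param tr Repetition time in seconds (metadata for downstream filtering).
#' @param seed Optional integer seed.
#' @param psd_tol Eigenvalues below \code{-psd_tol} trigger an error;
#'   eigenvalues in \code{[-psd_tol, 0)} are clipped with a warning.
#' @return An \code{fc_timeseries} object: list with \code{values} (regions x
#'   timepoints), \code{tr}, \code{region_labels}.
#' @examples
#' R <- diag(3); R[1, 2] <- R[2, 1] <- 0.5
#' ts <- generate_timeseries(R, 500, seed = 1)
#' cor(ts$values[1, ], ts$values[2, ])
#' @export
generate_timeseries <- function(target_corr, n_timepoints, tr = 2,
                                seed = NULL, psd_tol = 1e-8) {
  target_corr <- as.matrix(target_corr)
  if (!isSymmetric(target_corr, tol = 1e-8))
    stop("'target_corr' must be symmetric")
  if (any(abs(diag(target_corr) - 1) > 1e-8))
    stop("'target_corr' must have unit diagonal")
  e <- eigen(target_corr, symmetric = TRUE)
  if (min(e$values) < -psd_tol)
    stop("'target_corr' is not positive semi-definite")
  if (min(e$values) < 0) {
    warning("clipping slightly negative eigenvalues to repair PSD target")
    e$values <- pmax(e$values, 0)
  }
  if (!is.null(seed)) set.seed(seed)
  p <- nrow(target_corr)
  S <- e$vectors %*% (sqrt(e$values) * t(e$vectors))
  vals <- S %*% matrix(stats::rnorm(p * n_timepoints), p, n_timepoints)
  labels <- rownames(target_corr)
  if (is.null(labels)) labels <- sprintf("R%03d", seq_len(p))
  fc_timeseries(vals, tr = tr, region_labels = labels)
}

#' Construct a regional time-series container
#'
#' @param values Regions x timepoints numeric matrix.
#' @param tr Repetition time in seconds.
#' @param region_labels Character labels, one per region.
#' @return An object of class \code{fc_timeseries}.
#' @export
fc_timeseries <- function(values, tr = 2,
                          region_labels = sprintf("R%03d",
                                                  seq_len(nrow(values)))) {
  values <- as.matrix(values)
  if (ncol(values) < 2) stop("time series need at least 2 timepoints")
  if (length(region_labels) != nrow(values))
    stop("one region label per row is required")
  if (any(!is.finite(values))) stop("time series contain non-finite values")
  structure(list(values = values, tr = tr,
                 region_labels = as.character(region_labels)),
            class = "fc_timeseries")
}

#' @export
print.fc_timeseries <- function(x, ...) {
  cat(sprintf("fc_timeseries: %d regions x %d timepoints (TR = %gs)\n",
              nrow(x$values), ncol(x$values), x$tr))
  invisible(x)
}

#' Generate rigid-body realignment parameter series
#'
#' Simulates six random-walk realignment series (translations along x, y, z
#' in mm; rotations about the three axes in degrees) whose resulting mean
#' framewise displacement is calibrated to \code{motion_scale}: half the
#' displacement budget goes to translations and half to rotations (converted
#' to arc length on a 50 mm sphere), using the half-normal mean of the walk
#' increments.
#'
#' @param n_timepoints Series length (at least 2).
#' @param motion_scale Target mean framewise displacement in mm (0 gives
#'   all-zero series).
#' @param seed Optional integer seed.
#' @return Numeric matrix \code{n_timepoints} x 6 with columns
#'   \code{dx, dy, dz, alpha, beta, gamma}.
#' @examples
#' rp <- generate_realignment(192, 0.2, seed = 1)
#' mean(framewise_displacement(rp))
#' @export
generate_realignment <- function(n_timepoints, motion_scale, seed = NULL) {
  if (n_timepoints < 2) stop("'n_timepoints' must be at least 2")
  if (motion_scale < 0) stop("'motion_scale' must be non-negative")
  cols <- c("dx", "dy", "dz", "alpha", "beta", "gamma")
  if (motion_scale == 0)
    return(matrix(0, n_timepoints, 6, dimnames = list(NULL, cols)))
  if (!is.null(seed)) set.seed(seed)
  half_normal <- sqrt(2 / pi)           # E|N(0,1)|
  arc <- 50 * pi / 180                  # mm of arc per degree on 50 mm sphere
  s_trans <- (motion_scale / 2) / (3 * half_normal)
  s_rot <- (motion_scale / 2) / (3 * arc * half_normal)
  inc <- cbind(matrix(stats::rnorm(3 * (n_timepoints - 1), 0, s_trans),
                      ncol = 3),
               matrix(stats::rnorm(3 * (n_timepoints - 1), 0, s_rot),
                      ncol = 3))
  out <- rbind(0, apply(inc, 2, cumsum))
  dimnames(out) <- list(NULL, cols)
  out
}
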