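# Connectivity features from ROI time series: framewise displacement,
# band-pass/detrend/nuisance preprocessing, Pearson correlation, Fisher z,
# upper-triangle vectorisation.

#' Framewise displacement from realignment parameters
#'
#' Per-timepoint head-motion scalar: the sum of absolute backward differences
#' of the three translations (mm) plus the three rotations converted from
#' degrees to arc length on a sphere of radius \code{sphere_radius}
#' (approximately the mean distance from cerebral cortex to head centre).
#' The first timepoint has no predecessor and is assigned 0.
#'
#' @param rp Matrix or data frame with one row per timepoint and six columns
#'   \code{dx, dy, dz} (mm) then \code{alpha, beta, gamma} (degrees).
#' @param sphere_radius Sphere radius in mm used for the degree-to-mm
#'   conversion. Default 50.
#' @return Numeric vector of framewise displacements (mm), same length as
#'   the number of timepoints.
#' @examples
#' rp <- matrix(0, 5, 6)
#' rp[3, 1] <- 1                       # 1 mm step along x
#' framewise_displacement(rp)
#' @export
framewise_displacement <- function(rp, sphere_radius = 50) {
  rp <- as.matrix(rp)
  if (nrow(rp) < 2) stop("realignment series needs at least 2 timepoints")
  if (ncol(rp) != 6) stop("realignment series must have 6 columns")
  bad <- which(!is.finite(rp), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-finite realignment parameter at timepoint %d",
                 bad[1, 1]))
  d <- abs(diff(rp))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      sphere_radius * (pi / 180) * rowSums(d[, 4:6, drop = FALSE]))
}

#' Mean head motion of a scan
#'
#' @param fd Framewise-displacement series from
#'   \code{\link{framewise_displacement}}.
#' @return Mean framewise displacement in mm.
#' @export
mean_head_motion <- function(fd) {
  if (length(fd) == 0) stop("empty framewise-displacement series")
  mean(fd)
}

#' Band-pass filter, detrend and nuisance-regress regional time series
#'
#' Applies, in the order given by \code{steps}: a zero-phase (second-order
#' Butterworth, forward-backward) band-pass filter; linear detrending; and
#' residualisation against the confound columns (an intercept is always
#' included), leaving each region's series exactly orthogonal to the
#' confounds. The step order is configurable because filtering and nuisance
#' regression do not commute; reordering emits a message.
#'
#' @param ts An \code{fc_timeseries} object (see \code{\link{fc_timeseries}}).
#' @param band Passband in Hz, within \code{(0, 1/(2 tr))}. Default
#'   \code{c(0.01, 0.1)}.
#' @param confounds Optional numeric matrix of nuisance series (timepoints x
#'   q), e.g. the six motion parameters and white-matter/CSF/global signals.
#' @param steps Character vector, a permutation of a subset of
#'   \code{c("filter", "detrend", "regress")}.
#' @return An \code{fc_timeseries} object of the same dimensions, with the
#'   processing steps recorded in attribute \code{"steps"}.
#' @examples
#' ts <- generate_timeseries(diag(3), 200, seed = 1)
#' out <- preprocess_timeseries(ts)
#' @export
preprocess_timeseries <- function(ts, band = c(0.01, 0.1), confounds = NULL,
                                  steps = c("filter", "detrend", "regress")) {
  stopifnot(inherits(ts, "fc_timeseries"))
  steps <- match.arg(steps, c("filter", "detrend", "regress"),
                     several.ok = TRUE)
  if (!identical(steps, intersect(c("filter", "detrend", "regress"), steps)))
    message("non-default preprocessing order: ",
            paste(steps, collapse = " -> "),
            " (filtering and regression do not commute)")
  nyq <- 1 / (2 * ts$tr)
  if (length(band) != 2 || band[1] <= 0 || band[2] >= nyq ||
      band[2] <= band[1])
    stop(sprintf("'band' must lie within (0, %g) Hz and be increasing", nyq))
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != ncol(ts$values))
      stop("confound rows must match the number of timepoints")
  }
  vals <- ts$values
  tp <- ncol(vals)
  for (s in steps) {
    if (s == "filter") {
      bf <- signal::butter(2, band / nyq, type = "pass")
      vals <- t(apply(vals, 1, function(x) signal::filtfilt(bf, x)))
    } else if (s == "detrend") {
      X <- cbind(1, seq_len(tp))
      vals <- t(qr.resid(qr(X), t(vals)))
    } else if (s == "regress") {
      if (is.null(confounds)) next
      X <- cbind(1, confounds)
      qx <- qr(X)
      if (qx$rank < ncol(X))
        warning("rank-deficient confound matrix; using least-squares ",
                "pseudo-solution")
      vals <- t(qr.resid(qx, t(vals)))
    }
  }
  out <- fc_timeseries(vals, tr = ts$tr, region_labels = ts$region_labels)
  attr(out, "steps") <- steps
  out
}

#' Pearson correlation matrix of regional time series
#'
#' @param ts An \code{fc_timeseries} object.
#' @return Symmetric regions x regions correlation matrix with unit diagonal
#'   and attribute \code{scale = "pearson_r"}.
#' @examples
#' ts <- generate_timeseries(diag(3), 100, seed = 1)
#' correlation_matrix(ts)
#' @export
correlation_matrix <- function(ts) {
  stopifnot(inherits(ts, "fc_timeseries"))
  v <- apply(ts$values, 1, stats::var)
  if (any(v == 0))
    stop(sprintf("region '%s' has zero variance",
                 ts$region_labels[which(v == 0)[1]]))
  C <- stats::cor(t(ts$values))
  dimnames(C) <- list(ts$region_labels, ts$region_labels)
  attr(C, "scale") <- "pearson_r"
  C
}

#' Fisher z-transform of a correlation matrix
#'
#' Applies \eqn{z = \mathrm{atanh}(r)} elementwise off the diagonal, clipping
#' \eqn{|r|} to \code{1 - clip_eps} first so perfect correlations map to a
#' large finite value. The diagonal (self-correlation) is set to 0 and is not
#' meaningful on the z scale.
#'
#' @param cmat Correlation matrix with attribute \code{scale = "pearson_r"}.
#' @param clip_eps Clipping margin for \eqn{|r|} near 1. Default 1e-7.
#' @return Matrix of Fisher-z values with attribute
#'   \code{scale = "fisher_z"}.
#' @export
fisher_z <- function(cmat, clip_eps = 1e-7) {
  sc <- attr(cmat, "scale")
  if (!is.null(sc) && sc != "pearson_r")
    stop("'cmat' is not on the pearson_r scale")
  if (any(abs(cmat[row(cmat) != col(cmat)]) > 1 + 1e-12))
    stop("off-diagonal entries must lie in [-1, 1]")
  z <- atanh(pmin(pmax(cmat, -(1 - clip_eps)), 1 - clip_eps))
  diag(z) <- 0
  attr(z, "scale") <- "fisher_z"
  z
}

#' Vectorise the strict upper triangle of a connectivity matrix
#'
#' Extracts the strict upper triangle in row-major order (the fixed
#' connection ordering used throughout the package): for \eqn{p} regions the
#' result has \eqn{p(p-1)/2} entries, ordered (1,2), (1,3), ..., (1,p),
#' (2,3), ... Region numbering in the names is 1-based.
#'
#' @param cmat Symmetric regions x regions matrix.
#' @param tol Symmetry tolerance.
#' @return Named numeric vector of length \eqn{p(p-1)/2} with attribute
#'   \code{n_regions}.
#' @examples
#' length(vectorize_upper(diag(116)))    # 6670 connections
#' @export
vectorize_upper <- function(cmat, tol = 1e-8) {
  cmat <- as.matrix(cmat)
  if (nrow(cmat) != ncol(cmat) ||
      max(abs(cmat - t(cmat))) > tol)
    stop("'cmat' must be symmetric")
  p <- nrow(cmat)
  tm <- t(cmat)
  v <- tm[lower.tri(tm)]               # row-major strict upper triangle
  i <- t(cmat * 0 + row(cmat))[lower.tri(cmat)]
  j <- t(cmat * 0 + col(cmat))[lower.tri(cmat)]
  names(v) <- sprintf("r%d_r%d", i, j)
  attr(v, "n_regions") <- p
  v
}

#' Reconstruct a symmetric matrix from an upper-triangle vector
#'
#' Inverse of \code{\link{vectorize_upper}}.
#'
#' @param v Connection vector of length \eqn{p(p-1)/2}.
#' @param diag_value Value placed on the diagonal. Default 0.
#' @return Symmetric \eqn{p \times p} matrix.
#' @export
devectorize_upper <- function(v, diag_value = 0) {
  m <- length(v)
  p <- (1 + sqrt(1 + 8 * m)) / 2
  if (abs(p - round(p)) > 1e-8)
    stop("length of 'v' is not p(p-1)/2 for any integer p")
  p <- round(p)
  out <- matrix(0, p, p)
  tout <- t(out)
  tout[lower.tri(tout)] <- v           # fill row-major upper triangle
  out <- t(tout)
  out <- out + t(out)
  diag(out) <- diag_value
  out
}
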