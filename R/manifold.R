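# Supervised Locality Preserving Projections of the connectivity space,
# with a PCA baseline. Both methods return a linear out-of-sample map.

#' Age-supervised pairwise distances
#'
#' Euclidean distances between feature rows, multiplied by \code{penalty}
#' for pairs whose age gap strictly exceeds \code{age_gap}. This injects the
#' age labels into graph construction: with a large penalty, samples far
#' apart in age cannot become graph neighbours, so the embedding is forced
#' to order samples chronologically. \code{penalty = 1} recovers plain
#' Euclidean distances (the unsupervised reduction).
#'
#' @param X Samples x features numeric matrix.
#' @param ages Age in years per row.
#' @param age_gap Age-gap threshold in years (strict inequality). Default 8.
#' @param penalty Multiplier (at least 1) for wide-gap pairs. Default 100.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
supervised_distance <- function(X, ages, age_gap = 8, penalty = 100) {
  X <- as.matrix(X)
  if (length(ages) != nrow(X)) stop("one age per row of 'X' is required")
  if (penalty < 1) stop("'penalty' must be at least 1")
  if (age_gap < 0) stop("'age_gap' must be non-negative")
  D <- as.matrix(stats::dist(X))
  wide <- abs(outer(ages, ages, "-")) > age_gap
  D[wide] <- D[wide] * penalty
  diag(D) <- 0
  D
}

#' Symmetrised k-nearest-neighbour graph
#'
#' Binary adjacency: \eqn{W_{ij} = 1} when j is among i's k nearest
#' neighbours by the supplied distances or vice versa (union
#' symmetrisation). Ties are broken by sample index, so the graph is
#' deterministic. A disconnected graph triggers a warning: too small a k can
#' falsely cut the continuous developmental progression into disjoint
#' sub-manifolds.
#'
#' @param D Symmetric distance matrix.
#' @param k Number of neighbours, \eqn{1 \le k < n}. Default 8.
#' @param connect Repair a disconnected graph by adding, for as long as
#'   several components remain, the shortest inter-component edge (by
#'   \code{D}). This keeps a continuous progression (e.g. a sparsely
#'   sampled age range) from being cut into disjoint sub-manifolds; the
#'   repair is deterministic and is reported by the warning. Default
#'   \code{FALSE}: the plain union-kNN graph is returned.
#' @return Binary symmetric adjacency matrix with zero diagonal.
#' @export
build_knn_graph <- function(D, k = 8, connect = FALSE) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (k < 1 || k >= n) stop("'k' must satisfy 1 <= k < n")
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(D[i, ], seq_len(n))   # ties broken by index
    ord <- ord[ord != i][seq_len(k)]
    W[i, ord] <- 1
  }
  W <- pmax(W, t(W))
  diag(W) <- 0
  comp <- .components(W)
  if (max(comp) > 1) {
    if (!connect) {
      warning("neighbour graph is disconnected; consider a larger k")
    } else {
      warning("neighbour graph is disconnected; bridging components by ",
              "shortest inter-component edges")
      while (max(comp) > 1) {
        across <- outer(comp, comp, "!=")
        Dx <- D
        Dx[!across] <- Inf
        at <- which(Dx == min(Dx), arr.ind = TRUE)[1, ]
        W[at[1], at[2]] <- W[at[2], at[1]] <- 1
        comp[comp == comp[at[2]]] <- comp[at[1]]
        comp <- match(comp, sort(unique(comp)))
      }
    }
  }
  W
}

# connected-component labels of a binary adjacency matrix
.components <- function(W) {
  n <- nrow(W)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier) > 0) {
      nb <- which(colSums(W[frontier, , drop = FALSE] > 0) > 0)
      nb <- nb[comp[nb] == 0]
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}

.n_components <- function(W) max(.components(W))

#' Fit Locality Preserving Projections
#'
#' Learns a linear map that preserves the local structure of the supplied
#' neighbour graph: after centring and projection onto a variance-preserving
#' basis of rank \code{prefilter_rank} (necessary because the number of
#' connections far exceeds the number of scans), it solves the generalised
#' eigenproblem \eqn{\tilde{X}^T L \tilde{X} a = \lambda \tilde{X}^T Deg
#' \tilde{X} a} with \eqn{Deg} the diagonal degree matrix and \eqn{L = Deg -
#' W} the graph Laplacian, and keeps the \code{d} eigenvectors of smallest
#' nonzero eigenvalue. The prefilter and the eigenvectors are composed into
#' a single feature-space map, so new samples embed by matrix product.
#' Eigenvector signs are fixed (largest-magnitude loading positive) so
#' embeddings are bit-reproducible.
#'
#' @param X Samples x features matrix.
#' @param W Symmetric non-negative weight matrix from
#'   \code{\link{build_knn_graph}}.
#' @param d Embedding dimension.
#' @param prefilter_rank Rank of the variance-preserving pre-projection.
#'   Default \code{min(n - 1, ncol(X))}.
#' @param ridge Ridge added to the denominator matrix if its Cholesky
#'   factorisation fails (with a warning).
#' @return An \code{fc_projection} object: list with \code{method},
#'   \code{projection} (features x d), \code{center}, \code{params},
#'   \code{eigenvalues} (ascending) and \code{embedding} (training
#'   coordinates).
#' @export
lpp_fit <- function(X, W, d, prefilter_rank = NULL, ridge = 1e-8) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (!isSymmetric(unname(W), tol = 1e-10) || any(W < 0))
    stop("'W' must be a symmetric non-negative weight matrix")
  if (nrow(W) != n) stop("'W' must be n x n")
  if (is.null(prefilter_rank)) prefilter_rank <- min(n - 1, ncol(X))
  if (d > prefilter_rank)
    stop("'d' cannot exceed 'prefilter_rank'")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  r <- min(prefilter_rank, n - 1, ncol(X))
  sv <- svd(Xc, nu = r, nv = r)
  keep <- which(sv$d[seq_len(r)] > max(sv$d) * 1e-12)
  V <- sv$v[, keep, drop = FALSE]
  Tm <- Xc %*% V                                  # n x r samples in basis
  deg <- rowSums(W)
  LT <- deg * Tm - W %*% Tm                       # L %*% Tm
  A <- crossprod(Tm, LT)
  B <- crossprod(Tm, deg * Tm)
  A <- (A + t(A)) / 2
  B <- (B + t(B)) / 2
  Rc <- tryCatch(chol(B), error = function(e) {
    warning("singular denominator matrix; adding ridge regularisation")
    chol(B + diag(ridge * mean(diag(B)), nrow(B)))
  })
  M <- forwardsolve(t(Rc), t(forwardsolve(t(Rc), A)))
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)                 # decreasing order
  lambda <- rev(e$values)
  U <- e$vectors[, rev(seq_len(ncol(e$vectors))), drop = FALSE]
  nonzero <- which(lambda > max(1e-10, max(abs(lambda)) * 1e-10))
  if (length(nonzero) < d)
    stop(sprintf("only %d nonzero eigenpairs available for d = %d",
                 length(nonzero), d))
  idx <- nonzero[seq_len(d)]
  a <- backsolve(Rc, U[, idx, drop = FALSE])
  proj <- V %*% a
  proj <- .fix_signs(proj)
  emb <- Xc %*% proj
  structure(list(method = "supervised_lpp", projection = proj, center = ctr,
                 params = list(d = d, prefilter_rank = prefilter_rank),
                 eigenvalues = lambda[idx], embedding = emb),
            class = "fc_projection")
}

.fix_signs <- function(P) {
  for (j in seq_len(ncol(P))) {
    i <- which.max(abs(P[, j]))
    if (P[i, j] < 0) P[, j] <- -P[, j]
  }
  P
}

#' Fit the supervised LPP embedding end to end
#'
#' Convenience wrapper: age-supervised distances
#' (\code{\link{supervised_distance}}), k-nearest-neighbour graph
#' (\code{\link{build_knn_graph}}), and \code{\link{lpp_fit}}. The penalised
#' distances drive both neighbour selection and the (binary) weights.
#'
#' @param X Samples x features matrix.
#' @param ages Age per row.
#' @param d Embedding dimension.
#' @param k Neighbour count. Default 8.
#' @param age_gap Age-gap threshold in years. Default 8.
#' @param penalty Distance penalty for wide-gap pairs. Default 100.
#' @param prefilter_rank Passed to \code{\link{lpp_fit}}.
#' @return An \code{fc_projection} object with the graph parameters recorded
#'   in \code{params}.
#' @examples
#' coh <- generate_cohort(60, seed = 1)
#' feat <- generate_feature_matrix(coh, plant_trajectories(80, seed = 2),
#'                                 seed = 3)
#' m <- supervised_lpp(feat$values, coh$age[match(feat$subject_id,
#'                                                coh$subject_id)], d = 2)
#' @export
supervised_lpp <- function(X, ages, d, k = 8, age_gap = 8, penalty = 100,
                           prefilter_rank = NULL) {
  D <- supervised_distance(X, ages, age_gap, penalty)
  W <- build_knn_graph(D, k, connect = TRUE)
  model <- lpp_fit(X, W, d, prefilter_rank)
  model$params <- c(model$params,
                    list(k = k, age_gap = age_gap, penalty = penalty))
  model
}

#' Fit a PCA embedding
#'
#' Centred principal component analysis projecting along directions of
#' maximal variance, with a deterministic sign convention
#' (largest-magnitude loading positive). The unsupervised baseline for the
#' supervised LPP embedding.
#'
#' @param X Samples x features matrix.
#' @param d Number of components.
#' @return An \code{fc_projection} object; \code{eigenvalues} holds the
#'   component variances (descending).
#' @export
pca_fit <- function(X, d) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (d > min(n - 1, ncol(X)))
    stop("'d' exceeds the available number of components")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc, nu = 0, nv = d)
  proj <- .fix_signs(sv$v)
  structure(list(method = "pca", projection = proj, center = ctr,
                 params = list(d = d),
                 eigenvalues = (sv$d[seq_len(d)]^2) / (n - 1),
                 embedding = Xc %*% proj),
            class = "fc_projection")
}

#' Project new samples into a learned embedding
#'
#' @param object An \code{fc_projection} model.
#' @param newdata Samples x features matrix with the training feature count.
#' @param ... Unused.
#' @return Samples x d coordinate matrix.
#' @export
predict.fc_projection <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$center))
    stop("'newdata' must have the training feature dimension")
  sweep(newdata, 2, object$center) %*% object$projection
}

#' @export
print.fc_projection <- function(x, ...) {
  cat(sprintf("fc_projection (%s): %d features -> %d dimensions\n",
              x$method, nrow(x$projection), ncol(x$projection)))
  invisible(x)
}
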