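#' Subject-level spatial PCA
#'
#' Top-n spatial principal components of the in-mask voxel x time matrix
#' (per-voxel mean removed), the first stage of the hierarchical group
#' decomposition: every participant contributes the same number of spatial
#' patterns to the group stage.
#'
#' @param run a cleaned [bold_run()].
#' @param mask cord [volume_mask()].
#' @param n number of components (default 20); must satisfy t > n.
#' @return list of class `subject_subspace`: `basis` (voxel x n,
#'   orthonormal), `variance_explained` (descending), `run_id`.
#' @export
subject_pca <- function(run, mask, n = 20) {
  X <- mask_matrix(run, mask)
  t <- ncol(X)
  if (t <= n) stop("t must exceed the number of requested components")
  n <- min(n, nrow(X))
  X <- X - rowMeans(X)
  sv <- svd(X, nu = n, nv = 0)
  structure(list(basis = sv$u[, seq_len(n), drop = FALSE],
                 variance_explained = sv$d[seq_len(n)]^2,
                 run_id = run$run_id),
            class = "subject_subspace")
}

#' Group subspace by generalized canonical correlation analysis
#'
#' MAXVAR-style generalized CCA: the orthonormal subject bases are stacked
#' column-wise and the left singular vectors of the stack are the
#' directions maximizing cross-subject correlation (a singular value near
#' sqrt(n_subjects) marks a direction present in every participant).
#' Deterministic and closed-form; reduces to ordinary CCA for two
#' subjects.
#'
#' @param subspaces list of `subject_subspace` objects (>= 2).
#' @param rank retained dimension; default the per-subject component
#'   count.
#' @return list of class `group_subspace`: `basis` (voxel x rank,
#'   orthonormal, ordered by cross-subject consistency), `consistency`
#'   (singular values), `source_rank`.
#' @export
group_subspace <- function(subspaces, rank = NULL) {
  if (length(subspaces) < 2) {
    stop(">=2 subjects required for the group subspace; use scope='subject'")
  }
  M <- do.call(cbind, lapply(subspaces, `[[`, "basis"))
  if (is.null(rank)) rank <- ncol(subspaces[[1]]$basis)
  rank <- min(rank, ncol(M), nrow(M))
  sv <- svd(M, nu = rank, nv = 0)
  structure(list(basis = sv$u[, seq_len(rank), drop = FALSE],
                 consistency = sv$d[seq_len(rank)],
                 source_rank = rank),
            class = "group_subspace")
}

# symmetric fixed-point ICA with log-cosh contrast on whitened rows of X;
# among restarts, the converged solution with the highest total negentropy
# (the contrast objective itself) is kept — the fixed-point iteration has
# spurious local optima and convergence alone does not discriminate them
fastica_symm <- function(X, K, n_iter = 500, tol = 1e-6, seed = 1,
                         n_restarts = 10) {
  # X: K x V, rows uncorrelated with unit variance
  V <- ncol(X)
  EG_gauss <- 0.3745672  # E[log cosh(Z)], Z standard normal
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    W <- matrix(rnorm(K * K), K, K)
    W <- sym_decorrelate(W)
    conv <- Inf
    for (it in seq_len(n_iter)) {
      WX <- W %*% X
      gwx <- tanh(WX)
      W1 <- gwx %*% t(X) / V - diag(rowMeans(1 - gwx^2)) %*% W
      W1 <- sym_decorrelate(W1)
      conv <- max(abs(abs(diag(W1 %*% t(W))) - 1))
      W <- W1
      if (conv < tol) break
    }
    J <- sum((rowMeans(log(cosh(W %*% X))) - EG_gauss)^2)
    cand <- list(W = W, conv = conv, iterations = it, negentropy = J)
    if (is.null(best)) best <- cand
    else if (conv < tol && best$conv >= tol) best <- cand
    else if ((conv < tol) == (best$conv < tol) &&
             (J > best$negentropy ||
              (J == best$negentropy && conv < best$conv))) best <- cand
  }
  best$converged <- best$conv < tol
  best
}

sym_decorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), nrow(W)) %*%
    t(e$vectors) %*% W
}

#' Spatial ICA on a group subspace or a single subject's data
#'
#' Fixed-point ICA with a log-cosh contrast, extracting K spatially
#' independent maps. For a `group_subspace` the first K basis directions
#' (already whitened) are rotated; for a single-subject run the data are
#' first whitened to rank K by spatial PCA, mirroring a hierarchical
#' decomposition in which only the final source-separation step applies at
#' the participant level. Each map is sign-flipped to positive skewness,
#' Z-scored over the mask, and the set is ordered by rostro-caudal center
#' of mass.
#'
#' @param x a `group_subspace`, or a cleaned [bold_run()] for subject
#'   scope.
#' @param mask cord [volume_mask()].
#' @param K number of components.
#' @param n_iter fixed-point iteration cap (default 500).
#' @param seed integer seed (restarts are derived from it).
#' @param scope recorded scope; inferred from `x` by default.
#' @return a [component_set()] (method `"ica"`), with attribute
#'   `converged`.
#' @export
spatial_ica <- function(x, mask, K, n_iter = 500, seed = 1, scope = NULL) {
  if (inherits(x, "group_subspace")) {
    if (K > x$source_rank) stop("K exceeds the group subspace rank")
    B <- x$basis[, seq_len(K), drop = FALSE]      # voxel x K, orthonormal
    if (is.null(scope)) scope <- "group"
  } else if (inherits(x, "bold_run")) {
    sp <- subject_pca(x, mask, n = K)
    B <- sp$basis
    if (is.null(scope)) scope <- "subject"
  } else stop("x must be a group_subspace or a bold_run")
  V <- nrow(B)
  Xw <- t(B) * sqrt(V)                            # K x V whitened
  fit <- fastica_symm(Xw, K, n_iter = n_iter, seed = seed)
  if (!fit$converged) {
    warning(sprintf("spatial ICA did not converge after %d iterations (residual %.2e); best iterate kept",
                    n_iter, fit$conv))
  }
  S <- fit$W %*% Xw                               # K x V independent maps
  maps <- apply(S, 1, function(v) {
    sk <- mean(((v - mean(v)) / sd(v))^3)
    if (sk < 0) v <- -v
    zscore_vec(v)
  })                                              # V x K
  cs <- component_set(unmask_matrix(maps, mask), mask, method = "ica",
                      scope = scope, seed = seed)
  cs <- sort_components(cs)
  attr(cs, "converged") <- fit$converged
  cs
}

#' Order components rostro-caudally by center of mass
#'
#' Components are sorted by the z center of mass of their positive part so
#' that displays and per-slot summaries read rostro-caudally; matching
#' operations never rely on this order.
#'
#' @param cs a [component_set()].
#' @param voxel_size_z z voxel size in mm (cosmetic; ordering is
#'   scale-free).
#' @return the reordered [component_set()].
#' @export
sort_components <- function(cs, voxel_size_z = 1) {
  coms <- vapply(seq_len(cs$K), function(k) {
    m <- cs$maps[, , , k, drop = TRUE]
    m[m < 0] <- 0
    if (sum(m) == 0) return(NA_real_)
    dims <- dim(m)
    z0 <- rep(seq_len(dims[3]) - 1, each = dims[1] * dims[2])
    sum(as.vector(m) * z0) / sum(m) * voxel_size_z
  }, numeric(1))
  ord <- order(coms)
  cs$maps <- cs$maps[, , , ord, drop = FALSE]
  if (!is.null(cs$time_courses)) cs$time_courses <- cs$time_courses[ord, , drop = FALSE]
  cs
}
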