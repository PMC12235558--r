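#' Synthesis operator for Total Activation
#'
#' Dense t x t operator A = H C mapping an innovation signal s to the
#' BOLD-domain signal: C integrates (cumulative sum) to the activity-
#' inducing signal and H convolves with the HRF. The generalized
#' differential penalty of Total Activation (HRF-inverse composed with a
#' first difference) is exactly the l1 norm of s under this
#' parameterization.
#'
#' @param t number of volumes.
#' @param hrf kernel samples at TR ([canonical_hrf()]).
#' @return t x t matrix.
#' @keywords internal
ta_operator <- function(t, hrf) {
  # drop leading zero kernel samples (pure latency; they would make the
  # convolution matrix singular)
  nz <- which(hrf != 0)
  if (length(nz) && nz[1] > 1) hrf <- hrf[nz[1]:length(hrf)]
  h <- numeric(t)
  h[seq_len(min(t, length(hrf)))] <- hrf[seq_len(min(t, length(hrf)))]
  # H: lower-triangular Toeplitz; C: lower-triangular ones
  H <- matrix(0, t, t)
  for (j in seq_len(t)) H[j:t, j] <- h[seq_len(t - j + 1)]
  C <- matrix(0, t, t)
  C[lower.tri(C, diag = TRUE)] <- 1
  H %*% C
}

# robust per-voxel noise sd: MAD of finest-scale (Haar) detail coefficients
robust_noise_sd <- function(Y) {
  d <- (Y[, -1, drop = FALSE] - Y[, -ncol(Y), drop = FALSE]) / sqrt(2)
  apply(d, 1, mad)
}

#' Total Activation: regularized hemodynamic deconvolution
#'
#' Per in-mask voxel, estimates the activity-inducing signal u whose HRF
#' convolution best fits the observed series under an l1 penalty on the
#' innovations s = diff(u): min_s 0.5*||y - A s||^2 + lambda*||s||_1 with
#' A = H C (see [ta_operator()]). Solved by cyclic coordinate descent on
#' the shared Gram matrix, stopped at relative duality gap `tol`. By
#' default lambda is tuned per voxel so the residual energy matches a
#' robust noise estimate (MAD of finest-scale Haar details), iteratively
#' rescaled.
#'
#' @param run a cleaned [bold_run()].
#' @param mask cord [volume_mask()].
#' @param hrf kernel samples; default [canonical_hrf()] at the run's TR.
#' @param lambda NULL for the noise-matched strategy, or a positive scalar
#'   / per-voxel vector of fixed penalty weights.
#' @param n_rescale outer lambda-rescaling iterations (ignored for fixed
#'   lambda).
#' @param tol relative duality-gap tolerance (default 1e-3; tighter values
#'   sharpen the certificate at roughly linear cost in sweeps).
#' @param max_iter coordinate-descent sweep cap per solve.
#' @return list of class `activity_signals`: `activity` (in-mask voxel x t
#'   activity-inducing signals), `innovation` (voxel x t, first column 0),
#'   `lambda_used`, `hrf`, `gap`, `converged`, `run_id`.
#' @export
total_activation <- function(run, mask, hrf = NULL, lambda = NULL,
                             n_rescale = 4, tol = 1e-3, max_iter = 2000) {
  Y <- mask_matrix(run, mask)
  t <- ncol(Y)
  if (is.null(hrf)) hrf <- canonical_hrf(run$tr)
  if (t < 2 * length(hrf)) {
    # kernel support must be well inside the run
    hrf <- hrf[seq_len(max(2, floor(t / 2)))]
  }
  A <- ta_operator(t, hrf)
  ta_solve(Y, A, lambda = lambda, n_rescale = n_rescale, tol = tol,
           max_iter = max_iter, hrf = hrf, run_id = run$run_id)
}

ta_solve <- function(Y, A, lambda = NULL, n_rescale = 4, tol = 1e-3,
                     max_iter = 2000, hrf = NULL, run_id = "") {
  V <- nrow(Y); t <- ncol(Y)
  G <- crossprod(A)
  AtY <- crossprod(A, t(Y))                 # t x V
  yty <- rowSums(Y^2)
  lam_max <- apply(abs(AtY), 2, max)
  if (is.null(lambda)) {
    sigma <- robust_noise_sd(Y)
    target <- pmax(sigma, 1e-10)^2 * t      # residual energy target
    # descend from a sparse solution with warm starts (pathwise);
    # intermediate rounds at looser tolerance, final solve at `tol`
    lam <- pmax(0.5 * lam_max, 1e-10)
    S <- matrix(0, t, V)
    tol_path <- max(tol, 1e-3)
    for (i in seq_len(n_rescale)) {
      fit <- .ta_lasso_cd(G, AtY, yty, lam, S, tol_path, max_iter)
      S <- fit$S
      rr <- pmax(yty - 2 * colSums(S * AtY) + colSums(S * (G %*% S)), 0)
      ratio <- sqrt(target / pmax(rr, 1e-12))
      lam <- pmin(pmax(lam * ratio, 1e-10), lam_max * 1.001)
    }
    fit <- .ta_lasso_cd(G, AtY, yty, lam, S, tol, max_iter)
  } else {
    lam <- rep_len(lambda, V)
    fit <- .ta_lasso_cd(G, AtY, yty, lam, matrix(0, t, V), tol, max_iter)
  }
  S <- t(fit$S)                             # voxel x t innovations (+ baseline)
  U <- t(apply(S, 1, cumsum))               # activity-inducing signals
  if (V == 1) U <- matrix(U, 1, t)
  converged <- fit$gap <= tol * pmax(fit$primal, 0.5 * yty, 1e-12)
  if (!all(converged)) {
    warning(sprintf("Total Activation: %d voxel(s) not converged; best iterate kept",
                    sum(!converged)))
  }
  structure(list(activity = U, innovation = cbind(0, S[, -1, drop = FALSE]),
                 s = S, lambda_used = lam, hrf = hrf, gap = fit$gap,
                 primal = fit$primal, sweeps = fit$sweeps,
                 converged = converged, run_id = run_id, A = A),
            class = "activity_signals")
}

#' Innovation signals from activity-inducing signals
#'
#' First difference along time; the first volume is set to zero (no
#' transition is observable there).
#'
#' @param activity an `activity_signals` object or a voxel x t matrix.
#' @return voxel x t matrix of innovations, first column zero.
#' @export
innovations <- function(activity) {
  U <- if (inherits(activity, "activity_signals")) activity$activity else activity
  U <- as.matrix(U)
  cbind(0, U[, -1, drop = FALSE] - U[, -ncol(U), drop = FALSE])
}

# phase-randomized surrogate of each row, preserving the amplitude spectrum
phase_randomize <- function(Y) {
  t <- ncol(Y)
  half <- floor((t - 1) / 2)
  out <- t(apply(Y, 1, function(y) {
    f <- fft(y)
    ph <- runif(half, 0, 2 * pi)
    rot <- rep(1 + 0i, t)
    rot[2:(half + 1)] <- exp(1i * ph)
    rot[t:(t - half + 1)] <- Conj(rot[2:(half + 1)])
    Re(fft(f * rot, inverse = TRUE)) / t
  }))
  matrix(out, nrow(Y), t)
}

#' Surrogate-based temporal thresholds for innovation significance
#'
#' Phase-randomized surrogates of each voxel's cleaned series (amplitude
#' spectrum preserved) are deconvolved with Total Activation; the alpha/2
#' and 1 - alpha/2 quantiles of the pooled surrogate innovation
#' distribution give each voxel a two-sided significance band.
#'
#' @param run cleaned [bold_run()].
#' @param mask cord [volume_mask()].
#' @param hrf kernel (default [canonical_hrf()] at the run's TR).
#' @param alpha two-sided level (default 0.05, i.e. 2.5% per tail).
#' @param n_surrogates surrogate count.
#' @param pooled pool surrogate innovations across voxels instead of per
#'   voxel.
#' @param seed integer seed for the phase draws.
#' @param lambda optional fixed per-voxel penalty for the surrogate
#'   solves; NULL (default) re-tunes per surrogate with the same
#'   noise-matched strategy as the data solve, so the null model receives
#'   the same adaptive treatment as the data.
#' @param ... passed to [total_activation()] (`tol`, `max_iter`, ...).
#' @return voxel x 2 matrix with columns `lower`, `upper`.
#' @export
surrogate_thresholds <- function(run, mask, hrf = NULL, alpha = 0.05,
                                 n_surrogates = 10, pooled = FALSE,
                                 seed = 1, lambda = NULL, tol = 1e-2, ...) {
  stopifnot(n_surrogates >= 1)
  Y <- mask_matrix(run, mask)
  t <- ncol(Y); V <- nrow(Y)
  if (is.null(hrf)) hrf <- canonical_hrf(run$tr)
  A <- ta_operator(t, hrf)
  set.seed(seed)
  pool <- vector("list", n_surrogates)
  for (i in seq_len(n_surrogates)) {
    Ys <- phase_randomize(Y)
    # surrogates receive the same lambda path as the data solve (threshold
    # calibration depends on it); only the duality gap is relaxed, since
    # these solves feed quantile estimates
    act <- suppressWarnings(
      ta_solve(Ys, A, lambda = lambda, hrf = hrf, tol = tol, ...))
    pool[[i]] <- act$innovation[, -1, drop = FALSE]  # drop structural zero
  }
  probs <- c(alpha / 2, 1 - alpha / 2)
  if (pooled) {
    q <- quantile(unlist(pool), probs, names = FALSE)
    th <- matrix(rep(q, each = V), V, 2)
  } else {
    samp <- do.call(cbind, pool)                     # voxel x (n_sur*(t-1))
    th <- t(apply(samp, 1, quantile, probs = probs, names = FALSE))
  }
  colnames(th) <- c("lower", "upper")
  th
}

#' Select significant innovation frames
#'
#' Two-step thresholding: voxels are active where the innovation leaves the
#' voxel's surrogate band; frames (volumes) with an active-voxel fraction
#' above `spatial_fraction` are retained, with inactive voxels zeroed and
#' the signed active values kept.
#'
#' @param innov voxel x t innovation matrix (see [innovations()]).
#' @param thresholds voxel x 2 matrix from [surrogate_thresholds()].
#' @param spatial_fraction minimum active fraction (default 0.05).
#' @param run_id provenance label.
#' @return list of class `significant_frames`: `frames` (n x voxel signed
#'   matrix), `run_id`, `volume`, `active_fraction`, `spatial_fraction`.
#' @export
select_frames <- function(innov, thresholds, spatial_fraction = 0.05,
                          run_id = "") {
  innov <- as.matrix(innov)
  if (nrow(innov) != nrow(thresholds)) stop("innovations and thresholds differ in voxel count")
  active <- innov < thresholds[, 1] | innov > thresholds[, 2]
  frac <- colMeans(active)
  keep <- which(frac > spatial_fraction)
  if (!length(keep)) {
    warning("no frames survive spatial thresholding")
    return(structure(list(frames = matrix(0, 0, nrow(innov)),
                          run_id = character(0), volume = integer(0),
                          active_fraction = numeric(0),
                          spatial_fraction = spatial_fraction,
                          thresholds = thresholds),
                     class = "significant_frames"))
  }
  fr <- t(innov[, keep, drop = FALSE] * active[, keep, drop = FALSE])
  structure(list(frames = fr, run_id = rep(run_id, length(keep)),
                 volume = keep, active_fraction = frac[keep],
                 spatial_fraction = spatial_fraction,
                 thresholds = thresholds),
            class = "significant_frames")
}

#' Concatenate significant frames across runs
#' @param ... `significant_frames` objects (or a single list of them).
#' @return a pooled `significant_frames` object.
#' @export
bind_frames <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && !inherits(xs[[1]], "significant_frames")) xs <- xs[[1]]
  structure(list(frames = do.call(rbind, lapply(xs, `[[`, "frames")),
                 run_id = unlist(lapply(xs, `[[`, "run_id")),
                 volume = unlist(lapply(xs, `[[`, "volume")),
                 active_fraction = unlist(lapply(xs, `[[`, "active_fraction")),
                 spatial_fraction = xs[[1]]$spatial_fraction,
                 thresholds = NULL),
            class = "significant_frames")
}

# sign-folded k-means on frames; cosine (default) or euclidean distance
kmeans_folded <- function(F, K, restarts = 5, seed = 1,
                          distance = c("cosine", "euclidean"),
                          max_iter = 100) {
  distance <- match.arg(distance)
  n <- nrow(F)
  if (n < K) stop(sprintf("fewer frames (%d) than clusters (%d)", n, K))
  set.seed(seed)
  norms <- sqrt(rowSums(F^2))
  Fn <- if (distance == "cosine") F / pmax(norms, 1e-12) else F
  Fu <- F / pmax(norms, 1e-12)    # unit rows for the ++ seeding metric
  # k-means++ style seeding under the folded-cosine metric
  seed_centers <- function() {
    picks <- sample(n, 1)
    d2 <- (1 - abs(Fu %*% Fu[picks, ]))^2
    while (length(picks) < K) {
      pr <- pmax(as.vector(d2), 1e-12)
      cand <- sample(n, 1, prob = pr / sum(pr))
      picks <- c(picks, cand)
      d2 <- pmin(d2, (1 - abs(Fu %*% Fu[cand, ]))^2)
    }
    Fn[picks, , drop = FALSE]
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- seed_centers()
    assign_old <- rep(0L, n)
    for (it in seq_len(max_iter)) {
      if (distance == "cosine") {
        sim <- Fn %*% t(centers / pmax(sqrt(rowSums(centers^2)), 1e-12))
        cl <- max.col(abs(sim), ties.method = "first")
        sgn <- sign(sim[cbind(seq_len(n), cl)])
      } else {
        d2p <- outer(rowSums(Fn^2), rowSums(centers^2), "+") - 2 * Fn %*% t(centers)
        d2m <- outer(rowSums(Fn^2), rowSums(centers^2), "+") + 2 * Fn %*% t(centers)
        d2 <- pmin(d2p, d2m)
        cl <- max.col(-d2, ties.method = "first")
        sgn <- ifelse(d2p[cbind(seq_len(n), cl)] <= d2m[cbind(seq_len(n), cl)], 1, -1)
      }
      sgn[sgn == 0] <- 1
      if (all(cl == assign_old)) break
      assign_old <- cl
      for (k in seq_len(K)) {
        mem <- which(cl == k)
        if (!length(mem)) {  # re-seed empty cluster at the worst-fit frame
          if (distance == "cosine") {
            fit <- abs(sim)[cbind(seq_len(n), assign_old)]
            centers[k, ] <- Fn[which.min(fit), ]
          } else {
            centers[k, ] <- Fn[sample(n, 1), ]
          }
        } else {
          centers[k, ] <- colMeans(Fn[mem, , drop = FALSE] * sgn[mem])
        }
      }
    }
    if (distance == "cosine") {
      obj <- sum(1 - abs(sim)[cbind(seq_len(n), cl)])
    } else {
      obj <- sum(d2[cbind(seq_len(n), cl)])
    }
    if (is.null(best) || obj < best$obj) {
      best <- list(cluster = cl, sign = sgn, obj = obj, centers = centers)
    }
  }
  best
}

#' Cluster significant frames into iCAPs
#'
#' Sign-folded k-means over the retained innovation frames (a frame and its
#' negation belong to the same cluster). Component map k is the voxelwise
#' mean of the folded frames assigned to cluster k, Z-scored over the mask.
#' Best of `restarts` seeded initializations by within-cluster dispersion.
#'
#' @param frames a `significant_frames` object ([select_frames()],
#'   [bind_frames()]).
#' @param mask cord [volume_mask()] defining the voxel order of `frames`.
#' @param K number of iCAPs.
#' @param restarts k-means restarts.
#' @param seed integer seed.
#' @param distance `"cosine"` (default) or `"euclidean"`.
#' @param scope `"group"` or `"subject"` (recorded in the result).
#' @return a [component_set()] (method `"icap"`), with attributes
#'   `cluster` (frame assignments) and `objective`.
#' @export
cluster_icaps <- function(frames, mask, K, restarts = 5, seed = 1,
                          distance = c("cosine", "euclidean"),
                          scope = "group") {
  distance <- match.arg(distance)
  F <- frames$frames
  if (nrow(F) < K) stop(sprintf("fewer frames (%d) than clusters K=%d", nrow(F), K))
  km <- kmeans_folded(F, K, restarts = restarts, seed = seed,
                      distance = distance)
  V <- ncol(F)
  maps <- matrix(0, V, K)
  for (k in seq_len(K)) {
    mem <- which(km$cluster == k)
    m <- colMeans(F[mem, , drop = FALSE] * km$sign[mem])
    # centroid sign is arbitrary under folding; fix by positive skewness so
    # the map reads through its positive tail, as for ICA components
    sk <- mean(((m - mean(m)) / max(sd(m), 1e-12))^3)
    if (sk < 0) m <- -m
    maps[, k] <- m
  }
  maps <- apply(maps, 2, zscore_vec)
  cs <- component_set(unmask_matrix(maps, mask), mask, method = "icap",
                      scope = scope, seed = seed)
  cs <- sort_components(cs)
  attr(cs, "cluster") <- km$cluster
  attr(cs, "objective") <- km$obj
  cs
}
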