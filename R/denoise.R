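#' DVARS and motion-outlier flagging
#'
#' DVARS element n is the root-mean-square, over in-mask voxels, of the
#' intensity difference between volumes n+1 and n. Volumes adjacent to a
#' DVARS excursion above the box-plot fence (75th percentile + 1.5 IQR of
#' the series) are flagged as outliers; both members of the offending pair
#' are flagged, so an isolated spike marks the spike volume itself plus its
#' successor.
#'
#' @param run a [bold_run()].
#' @param mask a [volume_mask()] on the same grid.
#' @return list with `dvars` (length t-1), `outliers` (volume indices,
#'   1-based) and `threshold` (the fence actually applied).
#' @export
compute_dvars <- function(run, mask) {
  X <- mask_matrix(run, mask)
  if (nrow(X) == 0) stop("empty mask")
  d <- X[, -1, drop = FALSE] - X[, -ncol(X), drop = FALSE]
  dvars <- sqrt(colMeans(d^2))
  q <- quantile(dvars, c(0.25, 0.75), names = FALSE)
  fence <- q[2] + 1.5 * (q[2] - q[1])
  hit <- which(dvars > fence)
  outliers <- sort(unique(c(hit, hit + 1L)))
  list(dvars = dvars, outliers = outliers, threshold = fence)
}

#' CompCor nuisance regressors from the CSF compartment
#'
#' Principal component time courses of the voxel-by-time CSF data after
#' per-voxel mean removal (optionally variance normalization), ordered by
#' explained variance and unit-normalized.
#'
#' @param run a [bold_run()] (unsmoothed).
#' @param csf CSF [volume_mask()].
#' @param n number of components (default 5).
#' @param scale variance-normalize voxels before the PCA (default FALSE).
#' @return t x n matrix with columns `compcor_01` ... `compcor_0n`.
#' @export
compcor_regressors <- function(run, csf, n = 5, scale = FALSE) {
  X <- mask_matrix(run, csf)                       # voxel x t
  if (n > min(ncol(X), nrow(X))) stop("n exceeds min(t, CSF voxel count)")
  X <- X - rowMeans(X)
  if (scale) {
    s <- pmax(apply(X, 1, sd), 1e-12)
    X <- X / s
  }
  if (all(abs(X) < 1e-14)) stop("zero-variance CSF data")
  sv <- svd(t(X), nu = n, nv = 0)                  # t x voxel; u: time courses
  u <- sv$u[, seq_len(n), drop = FALSE]
  colnames(u) <- sprintf("compcor_%02d", seq_len(n))
  u
}

#' RETROICOR physiological regressors
#'
#' Fourier expansion of the cardiac and respiratory phases plus
#' multiplicative interaction terms. For each cardiac harmonic k <=
#' `orders["cardiac"]` the pair cos(k phi_c), sin(k phi_c); likewise for
#' respiration; for each interaction order j <= `orders["interaction"]` the
#' four sum/difference products cos(j phi_c + j phi_r), cos(j phi_c - j
#' phi_r), sin(j phi_c + j phi_r), sin(j phi_c - j phi_r). The default
#' orders (3, 4, 1) give 2*3 + 2*4 + 4 = 18 columns.
#'
#' @param cardiac_phase,resp_phase phase traces in radians, one per volume.
#' @param orders named integer vector (cardiac, respiratory, interaction).
#' @return t x r matrix with labelled columns.
#' @export
retroicor_regressors <- function(cardiac_phase, resp_phase,
                                 orders = c(cardiac = 3, respiratory = 4,
                                            interaction = 1)) {
  if (any(orders < 0)) stop("orders must be non-negative")
  stopifnot(length(cardiac_phase) == length(resp_phase),
            all(is.finite(cardiac_phase)), all(is.finite(resp_phase)))
  cols <- list()
  for (k in seq_len(orders[["cardiac"]])) {
    cols[[sprintf("retroicor_c%d_cos", k)]] <- cos(k * cardiac_phase)
    cols[[sprintf("retroicor_c%d_sin", k)]] <- sin(k * cardiac_phase)
  }
  for (k in seq_len(orders[["respiratory"]])) {
    cols[[sprintf("retroicor_r%d_cos", k)]] <- cos(k * resp_phase)
    cols[[sprintf("retroicor_r%d_sin", k)]] <- sin(k * resp_phase)
  }
  for (j in seq_len(orders[["interaction"]])) {
    cols[[sprintf("retroicor_x%d_cos_sum", j)]] <- cos(j * (cardiac_phase + resp_phase))
    cols[[sprintf("retroicor_x%d_cos_dif", j)]] <- cos(j * (cardiac_phase - resp_phase))
    cols[[sprintf("retroicor_x%d_sin_sum", j)]] <- sin(j * (cardiac_phase + resp_phase))
    cols[[sprintf("retroicor_x%d_sin_dif", j)]] <- sin(j * (cardiac_phase - resp_phase))
  }
  m <- if (length(cols)) do.call(cbind, cols) else
    matrix(0, length(cardiac_phase), 0)
  m
}

#' Discrete cosine detrending basis
#'
#' First `n` non-constant type-II DCT basis vectors (lowest frequencies
#' first), unit-norm and mutually orthogonal. Basis vector k has frequency
#' k / (2 t tr) Hz.
#'
#' @param t number of volumes.
#' @param tr repetition time in seconds (only used by callers to map basis
#'   index to frequency; the basis itself depends on `t` alone).
#' @param n number of basis vectors (default 5), must satisfy n < t.
#' @return t x n matrix with columns `dct_01` ...
#' @export
dct_basis <- function(t, tr = 1, n = 5) {
  if (n >= t) stop("n must be smaller than t")
  m <- sapply(seq_len(n), function(k) {
    v <- cos(pi * k * (seq_len(t) - 0.5) / t)
    v / sqrt(sum(v^2))
  })
  m <- matrix(m, nrow = t)
  if (n > 0) colnames(m) <- sprintf("dct_%02d", seq_len(n))
  m
}

# cosine stop-band below `hz`: constant + all DCT vectors with freq < hz
highpass_stopband <- function(t, tr, hz) {
  kmax <- floor(2 * t * tr * hz)
  if (kmax >= t) kmax <- t - 1
  cbind(const = rep(1 / sqrt(t), t),
        if (kmax > 0) dct_basis(t, tr, kmax))
}

#' Assemble a nuisance design
#'
#' Combines CompCor, RETROICOR, DCT detrending, motion and outlier-indicator
#' columns into a single labelled design matrix with a family map.
#'
#' @param compcor,retroicor,dct,motion matrices (or NULL) with t rows.
#' @param outliers integer volume indices; each becomes one indicator
#'   column.
#' @param t number of volumes (required if all parts are NULL).
#' @return list of class `nuisance_design` with `matrix`, `column_labels`,
#'   `families`.
#' @export
nuisance_design <- function(compcor = NULL, retroicor = NULL, dct = NULL,
                            motion = NULL, outliers = integer(0), t = NULL) {
  parts <- list(compcor = compcor, retroicor = retroicor, dct = dct,
                motion = motion)
  parts <- Filter(Negate(is.null), parts)
  if (is.null(t)) {
    if (!length(parts)) stop("t must be given when no regressors are supplied")
    t <- nrow(parts[[1]])
  }
  if (length(outliers)) {
    if (any(outliers < 1 | outliers > t)) stop("outlier indices out of range")
    om <- sapply(outliers, function(i) { v <- numeric(t); v[i] <- 1; v })
    om <- matrix(om, nrow = t)
    colnames(om) <- sprintf("outlier_%03d", outliers)
    parts$outlier <- om
  }
  mat <- matrix(0, t, 0)
  families <- list()
  for (fam in names(parts)) {
    p <- as.matrix(parts[[fam]])
    if (nrow(p) != t) stop(sprintf("%s rows (%d) != t (%d)", fam, nrow(p), t))
    if (ncol(p) == 0) next
    if (any(colSums(abs(p)) == 0)) stop(fam, " contains an all-zero column")
    if (is.null(colnames(p))) colnames(p) <- sprintf("%s_%02d", fam, seq_len(ncol(p)))
    families[[fam]] <- ncol(mat) + seq_len(ncol(p))
    mat <- cbind(mat, p)
  }
  structure(list(matrix = mat, column_labels = colnames(mat),
                 families = families),
            class = "nuisance_design")
}

#' Clean a run by joint orthogonal projection
#'
#' The nuisance columns are first projected onto the orthogonal complement
#' of the high-pass stop band (cosines below `highpass_hz`, plus the
#' constant), then the in-mask voxel time series are residualized against
#' the augmented stop-band + orthogonalized-nuisance design in a single
#' projection. Removing nuisance this way cannot reintroduce the
#' low-frequency structure the high-pass already removed. Per-voxel means
#' are removed (the constant is part of the stop band). Collinear columns
#' are dropped with a warning.
#'
#' @param run a [bold_run()].
#' @param mask [volume_mask()]; only in-mask voxels are cleaned, the rest
#'   are zeroed.
#' @param design a [nuisance_design()] (or NULL for filtering only).
#' @param highpass_hz high-pass edge in Hz (default 0.01).
#' @return a cleaned [bold_run()].
#' @export
clean <- function(run, mask, design = NULL, highpass_hz = 0.01) {
  X <- mask_matrix(run, mask)                     # voxel x t
  t <- ncol(X)
  stop_band <- highpass_stopband(t, run$tr, highpass_hz)
  N <- if (is.null(design)) matrix(0, t, 0) else design$matrix
  if (ncol(N) && nrow(N) != t) stop("design rows != number of volumes")
  if (ncol(N)) {
    # orthogonalize nuisance w.r.t. the stop band
    N <- N - stop_band %*% (crossprod(stop_band, N))
  }
  aug <- cbind(stop_band, N)
  # SVD-based projector: numerically-zero directions (e.g. detrending DCTs
  # inside the stop band) must not count as design dimensions
  sv <- svd(aug)
  keep <- sv$d > 1e-10 * sv$d[1]
  if (sum(keep) < ncol(aug)) {
    warning(sprintf("dropping %d collinear design column(s)",
                    ncol(aug) - sum(keep)))
  }
  Q <- sv$u[, keep, drop = FALSE]
  resid <- X - (X %*% Q) %*% t(Q)
  dims <- dim(run$data)
  out <- matrix(0, prod(dims[1:3]), t)
  out[mask$data > 0, ] <- resid
  bold_run(array(out, dims), voxel_size = run$voxel_size, tr = run$tr,
           run_id = paste0(run$run_id, "_clean"))
}

#' Build the default nuisance design for a simulated or measured run
#'
#' Convenience wrapper chaining [compute_dvars()], [compcor_regressors()],
#' [retroicor_regressors()] and [dct_basis()] with the configured counts.
#'
#' @param run a [bold_run()].
#' @param cord,csf cord and CSF masks.
#' @param confounds data.frame with `cardiac_phase`, `resp_phase` and any
#'   `motion_*` columns (may be NULL).
#' @param config a [pipeline_config()].
#' @param compcor_run optional unsmoothed [bold_run()] from which the CSF
#'   CompCor components are extracted (CompCor is defined on the
#'   unsmoothed CSF signal); defaults to `run`.
#' @return a [nuisance_design()].
#' @export
default_design <- function(run, cord, csf, confounds = NULL,
                           config = pipeline_config(), compcor_run = NULL) {
  t <- dim(run$data)[4]
  if (is.null(compcor_run)) compcor_run <- run
  cc <- compcor_regressors(compcor_run, csf, n = config$n_compcor,
                           scale = config$compcor_scale)
  ret <- NULL; mot <- NULL
  if (!is.null(confounds)) {
    if (all(c("cardiac_phase", "resp_phase") %in% names(confounds))) {
      ret <- retroicor_regressors(confounds$cardiac_phase,
                                  confounds$resp_phase,
                                  config$retroicor_orders)
    }
    mcols <- grep("^motion_", names(confounds), value = TRUE)
    if (length(mcols)) {
      mot <- as.matrix(confounds[, mcols, drop = FALSE])
      keep <- apply(mot, 2, function(v) sd(v) > 0)
      mot <- mot[, keep, drop = FALSE]
      if (!ncol(mot)) mot <- NULL
    }
  }
  dv <- compute_dvars(run, cord)
  nuisance_design(compcor = cc, retroicor = ret,
                  dct = dct_basis(t, run$tr, config$n_dct),
                  motion = mot, outliers = dv$outliers, t = t)
}
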