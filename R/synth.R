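#' Canonical two-gamma hemodynamic response function sampled at TR
#'
#' Difference of two gamma densities (response peak near 6 s, undershoot
#' near 16 s, undershoot ratio 1/6), normalized to unit peak. The same
#' kernel is shared by the simulator and the Total Activation solver unless
#' a mismatch is requested explicitly.
#'
#' @param tr sampling interval in seconds.
#' @param duration kernel support in seconds.
#' @return numeric vector of kernel samples. Leading zero samples (the
#'   response at t = 0 is exactly zero) are dropped, so the kernel starts
#'   at its first nonzero lag; this keeps the discrete convolution matrix
#'   nonsingular and amounts to a fixed one-sample latency convention
#'   shared by the simulator and the deconvolution solver.
#' @export
canonical_hrf <- function(tr, duration = 32) {
  t <- seq(0, duration, by = tr)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h <- h / max(h)
  nz <- which(h != 0)
  h[nz[1]:length(h)]
}

#' Build a synthetic cord / CSF / atlas geometry
#'
#' A cylindrical cord of `n_levels` stacked compartments surrounded by a
#' disjoint CSF sheath, with a rostro-caudally ordered level atlas.
#'
#' @param n_levels number of segmental levels.
#' @param level_height_vox slices per level.
#' @param radius_vox cord radius in voxels.
#' @param csf_thickness_vox CSF sheath thickness in voxels.
#' @return list with elements `cord` ([volume_mask()]), `csf`
#'   ([volume_mask()]) and `atlas` ([level_atlas()]).
#' @export
make_geometry <- function(n_levels = 5, level_height_vox = 6,
                          radius_vox = 3, csf_thickness_vox = 1) {
  stopifnot(n_levels >= 1, level_height_vox >= 1,
            radius_vox >= 1, csf_thickness_vox >= 1)
  side <- 2L * (radius_vox + csf_thickness_vox) + 3L
  nz <- as.integer(n_levels * level_height_vox)
  cx <- (side + 1) / 2
  xy <- expand.grid(x = seq_len(side), y = seq_len(side))
  r <- sqrt((xy$x - cx)^2 + (xy$y - cx)^2)
  cord_slice <- matrix(r <= radius_vox, side, side)
  csf_slice <- matrix(r > radius_vox & r <= radius_vox + csf_thickness_vox,
                      side, side)
  cord <- array(0L, c(side, side, nz))
  csf <- array(0L, c(side, side, nz))
  labels <- array(0L, c(side, side, nz))
  for (z in seq_len(nz)) {
    cord[, , z] <- cord_slice
    csf[, , z] <- csf_slice
    lev <- ((z - 1L) %/% level_height_vox) + 1L
    labels[, , z] <- cord_slice * lev
  }
  list(cord = volume_mask(cord, "cord"),
       csf = volume_mask(csf, "csf"),
       atlas = level_atlas(labels, "+z"))
}

#' Default noise parameters for the synthetic cohort
#'
#' Block amplitudes are fixed at 1, so `thermal_sd` is the inverse of the
#' voxelwise contrast-to-noise ratio. `csf_amp` scales a shared low-rank CSF
#' process, a fraction of which (`csf_leak`) also contaminates the cord.
#' `physio_amp` scales sinusoidal cardiac/respiratory confounds,
#' `drift_amp` the slow (< 0.01 Hz) cosine drift, and `spike_amp` the
#' intensity jump at `n_spikes` randomly placed outlier volumes.
#'
#' The defaults place the generator in the physiological-noise-dominated
#' regime characteristic of spinal cord acquisitions: cardiac/respiratory
#' fluctuations and slow drifts carry amplitudes comparable to the neural
#' block amplitude, while thermal noise is weaker.
#'
#' @param thermal_sd Gaussian thermal noise SD.
#' @param csf_amp amplitude of the rank-2 CSF noise process.
#' @param physio_amp amplitude of cardiac/respiratory oscillations.
#' @param csf_leak fraction of the CSF process leaking into the cord.
#' @param drift_amp amplitude of the slow drift.
#' @param spike_amp intensity offset of motion-spike volumes.
#' @param n_spikes outlier volumes per run.
#' @return named list of class `noise_params`.
#' @export
noise_params <- function(thermal_sd = 0.5, csf_amp = 1, physio_amp = 1,
                         csf_leak = 0.1, drift_amp = 1, spike_amp = 3,
                         n_spikes = 2) {
  structure(list(thermal_sd = thermal_sd, csf_amp = csf_amp,
                 physio_amp = physio_amp, csf_leak = csf_leak,
                 drift_amp = drift_amp, spike_amp = spike_amp,
                 n_spikes = as.integer(n_spikes)),
            class = "noise_params")
}

# one level's binary block train: n_blocks transient blocks, duration >= 2
make_block_train <- function(t, n_blocks, min_dur = 4, max_dur = 8) {
  a <- numeric(t)
  onsets <- integer(0); offsets <- integer(0)
  guard <- 0
  while (length(onsets) < n_blocks && guard < 200) {
    guard <- guard + 1
    dur <- sample(seq(min_dur, max_dur), 1)
    on <- sample(seq_len(t - dur - 1), 1)
    off <- on + dur
    if (any(a[max(1, on - 2):min(t, off + 2)] > 0)) next  # keep blocks separated
    a[on:off] <- 1
    onsets <- c(onsets, on); offsets <- c(offsets, off)
  }
  if (!length(onsets)) stop("event rate yielded zero blocks at this run length")
  ord <- order(onsets)
  list(train = a, onsets = onsets[ord], offsets = offsets[ord])
}

# separable Gaussian smoothing with edge renormalization (normalized
# convolution), applied volume-wise to a 4D array
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(2.5 * sigma))
  k <- exp(-0.5 * ((-r):r / sigma)^2)
  k / sum(k)
}

smooth_separable <- function(arr, sigma) {
  dims <- dim(arr)
  for (ax in 1:3) {
    k <- gauss_kernel(sigma[ax])
    if (length(k) == 1) next
    r <- (length(k) - 1L) / 2L
    num <- array(0, dims)
    for (j in seq_along(k)) {
      off <- j - r - 1L
      idx <- seq_len(dims[ax]) + off
      valid <- idx >= 1L & idx <= dims[ax]   # zero padding
      src <- pmin(pmax(idx, 1L), dims[ax])
      shifted <- switch(ax,
                        arr[src, , , , drop = FALSE],
                        arr[, src, , , drop = FALSE],
                        arr[, , src, , drop = FALSE])
      if (!all(valid)) {
        zv <- which(!valid)
        if (ax == 1) shifted[zv, , , ] <- 0
        if (ax == 2) shifted[, zv, , ] <- 0
        if (ax == 3) shifted[, , zv, ] <- 0
      }
      num <- num + k[j] * shifted
    }
    arr <- num
  }
  arr
}

# anisotropic Gaussian smoothing restricted to a tissue compartment
# (normalized convolution: smooth(x * m) / smooth(m) within m), matching
# cord-masked smoothing practice in spinal cord pipelines
smooth_volumes <- function(arr, fwhm_mm, voxel_size, mask = NULL) {
  sigma <- fwhm_mm / voxel_size / (2 * sqrt(2 * log(2)))
  if (all(sigma <= 0)) return(arr)
  dims <- dim(arr)
  if (is.null(mask)) return(smooth_separable(arr, sigma))
  m <- array(as.numeric(mask > 0), c(dims[1:3], 1L))
  w <- smooth_separable(m, sigma)[, , , 1]
  arrm <- arr * as.vector(m[, , , 1])
  sm <- smooth_separable(arrm, sigma)
  out <- arr
  idx <- which(m[, , , 1] > 0)
  nv <- prod(dims[1:3])
  for (tt in seq_len(dims[4])) {
    out[idx + (tt - 1L) * nv] <- sm[idx + (tt - 1L) * nv] / w[idx]
  }
  out
}

# per-subject level labels: boundaries jittered by rounded Gaussian shifts
jitter_labels <- function(atlas, cord, jitter_sd) {
  nz <- dim(atlas$labels)[3]
  L <- atlas$L
  base <- round(seq(0, nz, length.out = L + 1))
  b <- base
  if (jitter_sd > 0) {
    shift <- round(rnorm(L - 1, 0, jitter_sd))
    b[2:L] <- base[2:L] + shift
    # keep boundaries strictly increasing so every level keeps >= 1 slice
    for (i in 2:L) b[i] <- min(max(b[i], b[i - 1] + 1), nz - (L - i + 1))
  }
  lab <- array(0L, dim(atlas$labels))
  for (l in seq_len(L)) {
    zr <- (b[l] + 1):b[l + 1]
    lab[, , zr] <- cord$data[, , zr, drop = FALSE] * l
  }
  lab
}

#' Simulate a multi-subject synthetic spinal-cord fMRI cohort
#'
#' Each in-cord voxel carries its level's transient block train convolved
#' with the HRF; the CSF sheath carries a shared rank-2 noise process (a
#' small fraction of which leaks into the cord); sinusoidal cardiac and
#' respiratory confounds, a slow cosine drift, motion-spike outlier volumes
#' and Gaussian thermal noise are added on top. Per-subject level boundaries
#' are shifted by rounded Gaussian jitter to emulate inter-participant
#' variability. Full ground truth (per-subject block trains, transition
#' times, per-subject labels, confound traces, outlier indices) is retained.
#'
#' @param n_subjects number of participants.
#' @param geometry output of [make_geometry()].
#' @param t volumes per run (>= 60).
#' @param tr repetition time, seconds.
#' @param event_rate transient blocks per level per run.
#' @param jitter_sd SD (slices) of per-subject level-boundary shifts.
#' @param noise [noise_params()].
#' @param smooth_fwhm_mm anisotropic Gaussian smoothing applied to the
#'   output volumes (default 2 x 2 x 6 mm), emulating the preprocessing
#'   state in which real runs reach the denoising stage; `c(0, 0, 0)`
#'   disables it (exact noiseless construction).
#' @param seed integer seed.
#' @return list with `runs` (smoothed [bold_run()]s, the analysis input),
#'   `raw_runs` (unsmoothed runs, e.g. for CompCor on the unsmoothed CSF
#'   signal), `confounds` (list of data.frames with cardiac/respiratory
#'   phases and motion parameters), and `truth` (ground-truth list:
#'   `atlas`, per-subject `activity` K x t binary trains,
#'   `innovation_times`, `subject_labels`, `outliers`, `noise`, `hrf`,
#'   `smooth_fwhm_mm`, `seed`).
#' @export
simulate_cohort <- function(n_subjects = 10, geometry = make_geometry(),
                            t = 200, tr = 2.5, event_rate = 8,
                            jitter_sd = 1, noise = noise_params(),
                            smooth_fwhm_mm = c(2, 2, 6), seed = 1) {
  stopifnot(t >= 60, n_subjects >= 1)
  set.seed(seed)
  cord <- geometry$cord; csf <- geometry$csf; atlas <- geometry$atlas
  L <- atlas$L
  dims <- dim(cord$data)
  hrf <- canonical_hrf(tr)
  cord_idx <- which(cord$data > 0)
  csf_idx <- which(csf$data > 0)
  nvox <- prod(dims)
  secs <- (seq_len(t) - 1) * tr

  runs <- vector("list", n_subjects)
  raw_runs <- vector("list", n_subjects)
  confs <- vector("list", n_subjects)
  activity <- vector("list", n_subjects)
  innov_times <- vector("list", n_subjects)
  sub_labels <- vector("list", n_subjects)
  outliers <- vector("list", n_subjects)

  for (s in seq_len(n_subjects)) {
    trains <- lapply(seq_len(L), function(l) make_block_train(t, event_rate))
    A <- do.call(rbind, lapply(trains, `[[`, "train"))        # L x t
    conv <- t(apply(A, 1, function(a) {
      convolve(a, rev(hrf), type = "open")[seq_len(t)]
    }))                                                        # L x t
    lab <- jitter_labels(atlas, cord, jitter_sd)
    vol <- matrix(0, nvox, t)
    lv <- lab[cord_idx]
    vol[cord_idx, ] <- conv[lv, , drop = FALSE]

    # shared low-rank CSF process, leaking weakly into the cord
    if (noise$csf_amp > 0) {
      tc <- matrix(rnorm(2 * t), 2, t)
      tc <- t(apply(tc, 1, function(x) filter(x, rep(1 / 4, 4), sides = 1,
                                              method = "convolution")))
      tc[is.na(tc)] <- 0
      tc <- tc / pmax(apply(tc, 1, sd), 1e-12)
      w_csf <- matrix(rnorm(length(csf_idx) * 2), ncol = 2)
      vol[csf_idx, ] <- vol[csf_idx, ] + noise$csf_amp * (w_csf %*% tc)
      w_cord <- matrix(rnorm(length(cord_idx) * 2), ncol = 2)
      vol[cord_idx, ] <- vol[cord_idx, ] +
        noise$csf_amp * noise$csf_leak * (w_cord %*% tc)
    }

    # cardiac / respiratory oscillations with slight frequency wander
    fc <- runif(1, 0.9, 1.1); fr <- runif(1, 0.22, 0.28)
    phi_c <- (2 * pi * fc * secs + cumsum(rnorm(t, 0, 0.05))) %% (2 * pi)
    phi_r <- (2 * pi * fr * secs + cumsum(rnorm(t, 0, 0.03))) %% (2 * pi)
    if (noise$physio_amp > 0) {
      tissue <- c(cord_idx, csf_idx)
      wp <- runif(length(tissue), 0.5, 1)
      phys <- sin(phi_c) + 0.8 * cos(phi_r) + 0.3 * sin(2 * phi_c)
      vol[tissue, ] <- vol[tissue, ] +
        noise$physio_amp * outer(wp, phys)
    }

    # slow cosine drift below the high-pass edge (0.01 Hz)
    if (noise$drift_amp > 0) {
      kmax <- max(1, floor(2 * t * tr * 0.01) - 1)
      dk <- sample(seq_len(kmax), 1)
      drift <- cos(pi * dk * (seq_len(t) - 0.5) / t)
      tissue <- c(cord_idx, csf_idx)
      wd <- rnorm(length(tissue), 1, 0.2)
      vol[tissue, ] <- vol[tissue, ] + noise$drift_amp * outer(wd, drift)
    }

    # motion-spike outlier volumes: global intensity jump
    out_idx <- integer(0)
    if (noise$n_spikes > 0 && noise$spike_amp > 0) {
      out_idx <- sort(sample(seq_len(t), noise$n_spikes))
      tissue <- c(cord_idx, csf_idx)
      vol[tissue, out_idx] <- vol[tissue, out_idx] + noise$spike_amp
    }

    if (noise$thermal_sd > 0) {
      tissue <- c(cord_idx, csf_idx)
      vol[tissue, ] <- vol[tissue, ] +
        matrix(rnorm(length(tissue) * t, 0, noise$thermal_sd),
               length(tissue), t)
    }

    voxel_size <- c(1, 1, 3)
    raw <- array(vol, c(dims, t))
    arr <- smooth_volumes(raw, smooth_fwhm_mm, voxel_size, mask = cord$data)
    arr <- smooth_volumes(arr, smooth_fwhm_mm, voxel_size, mask = csf$data)
    runs[[s]] <- bold_run(arr, voxel_size = voxel_size,
                          tr = tr, run_id = sprintf("sub-%02d", s))
    raw_runs[[s]] <- if (any(smooth_fwhm_mm > 0)) {
      bold_run(raw, voxel_size = voxel_size, tr = tr,
               run_id = sprintf("sub-%02d_raw", s))
    } else runs[[s]]
    confs[[s]] <- data.frame(
      cardiac_phase = phi_c, resp_phase = phi_r,
      motion_x = cumsum(rnorm(t, 0, 0.02)),
      motion_y = cumsum(rnorm(t, 0, 0.02)))
    activity[[s]] <- A
    innov_times[[s]] <- lapply(trains, function(tb) {
      list(onsets = tb$onsets, offsets = tb$offsets)
    })
    sub_labels[[s]] <- lab
    outliers[[s]] <- out_idx
  }

  truth <- list(atlas = atlas, activity = activity,
                innovation_times = innov_times, subject_labels = sub_labels,
                outliers = outliers, noise = noise, hrf = hrf,
                smooth_fwhm_mm = smooth_fwhm_mm, seed = seed)
  list(runs = runs, raw_runs = raw_runs, confounds = confs, truth = truth,
       geometry = geometry)
}
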