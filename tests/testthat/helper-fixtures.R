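# Shared fixtures, built once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# tiny geometry: 3 levels x 4 slices, radius 2 (fast unit tests)
tiny_geometry <- function() {
  fixture("tiny_geometry", function() {
    make_geometry(n_levels = 3, level_height_vox = 4, radius_vox = 2,
                  csf_thickness_vox = 1)
  })
}

# noiseless single-subject cohort on the tiny geometry
noiseless_sim <- function() {
  fixture("noiseless_sim", function() {
    simulate_cohort(
      n_subjects = 1, geometry = tiny_geometry(), t = 80, tr = 2.5,
      event_rate = 2, jitter_sd = 0,
      noise = noise_params(thermal_sd = 0, csf_amp = 0, physio_amp = 0,
                           drift_amp = 0, spike_amp = 0, n_spikes = 0),
      smooth_fwhm_mm = c(0, 0, 0), seed = 7)
  })
}

# small noisy cohort (4 subjects) for pipeline-shape tests
small_cohort <- function() {
  fixture("small_cohort", function() {
    sim <- simulate_cohort(n_subjects = 4, geometry = tiny_geometry(),
                           t = 80, tr = 2.5, event_rate = 4, seed = 21)
    cfg <- pipeline_config(K = 3, n_subject_pcs = 10, n_surrogates = 8,
                           kmeans_restarts = 3, seed = 21)
    list(sim = sim, cfg = cfg)
  })
}

small_prepared <- function() {
  fixture("small_prepared", function() {
    sc <- small_cohort()
    geo <- tiny_geometry()
    prepare_cohort(sc$sim$runs, geo$cord, geo$csf, geo$atlas,
                   sc$sim$confounds, sc$cfg, raw_runs = sc$sim$raw_runs)
  })
}

# study-condition cohort: 10 subjects, 5 levels, default noise, t = 200
study_cohort <- function() {
  fixture("study_cohort", function() {
    geo <- make_geometry(n_levels = 5, level_height_vox = 6,
                         radius_vox = 3, csf_thickness_vox = 1)
    sim <- simulate_cohort(n_subjects = 10, geometry = geo, t = 200,
                           tr = 2.5, seed = 11)
    cfg <- pipeline_config(K = 5, seed = 11)
    list(geo = geo, sim = sim, cfg = cfg)
  })
}

study_prepared <- function() {
  fixture("study_prepared", function() {
    sc <- study_cohort()
    prepare_cohort(sc$sim$runs, sc$geo$cord, sc$geo$csf, sc$geo$atlas,
                   sc$sim$confounds, sc$cfg, raw_runs = sc$sim$raw_runs)
  })
}

# single-voxel bold run from a plain time series
ts_run <- function(y, tr = 2.5) {
  bold_run(array(y, c(1, 1, 1, length(y))), tr = tr)
}

# V x t matrix as a 1 x 1 x V x t run + all-ones mask
mat_run <- function(Y, tr = 2.5) {
  V <- nrow(Y); t <- ncol(Y)
  arr <- array(0, c(1, 1, V, t)); arr[1, 1, , ] <- Y
  list(run = bold_run(arr, tr = tr),
       mask = volume_mask(array(1, c(1, 1, V))))
}
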