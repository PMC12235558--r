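#' Prepare a cohort for component extraction
#'
#' Runs the per-subject stages whose results every downstream protocol
#' reuses: nuisance-design construction and joint-projection cleaning,
#' subject-level spatial PCA (ICA stream), and Total Activation ->
#' innovations -> surrogate thresholds -> significant frames (iCAP
#' stream).
#'
#' @param runs list of [bold_run()]s on a shared grid.
#' @param cord,csf cord and CSF masks.
#' @param atlas optional [level_atlas()].
#' @param confounds optional list of per-subject confound data.frames
#'   (`cardiac_phase`, `resp_phase`, `motion_*`).
#' @param config a [pipeline_config()].
#' @param raw_runs optional list of unsmoothed runs used for CompCor (the
#'   CSF components are defined on the unsmoothed signal).
#' @return object of class `cord_cohort` holding cleaned runs, subject
#'   subspaces, per-subject significant frames, and the inputs.
#' @export
prepare_cohort <- function(runs, cord, csf, atlas = NULL, confounds = NULL,
                           config = pipeline_config(), raw_runs = NULL) {
  stopifnot(length(runs) >= 1)
  n <- length(runs)
  hrf <- canonical_hrf(runs[[1]]$tr)
  cleaned <- vector("list", n)
  subspaces <- vector("list", n)
  frames <- vector("list", n)
  designs <- vector("list", n)
  for (s in seq_len(n)) {
    conf <- if (is.null(confounds)) NULL else confounds[[s]]
    designs[[s]] <- default_design(runs[[s]], cord, csf, conf, config,
                                   compcor_run = if (!is.null(raw_runs))
                                     raw_runs[[s]])
    cleaned[[s]] <- clean(runs[[s]], cord, designs[[s]], config$highpass_hz)
    subspaces[[s]] <- subject_pca(cleaned[[s]], cord,
                                  n = min(config$n_subject_pcs,
                                          dim(runs[[s]]$data)[4] - 1))
    frames[[s]] <- icap_prep_run(cleaned[[s]], cord, config, hrf,
                                 seed = config$seed + 100003L + s)
  }
  structure(list(cleaned = cleaned, subspaces = subspaces, frames = frames,
                 designs = designs, cord = cord, csf = csf, atlas = atlas,
                 hrf = hrf, config = config, n_subjects = n),
            class = "cord_cohort")
}

# TA -> innovations -> thresholds -> frames for one cleaned run
icap_prep_run <- function(cleaned_run, cord, config, hrf, seed) {
  act <- total_activation(cleaned_run, cord, hrf = hrf,
                          tol = config$ta_tol, max_iter = config$ta_max_iter)
  th <- surrogate_thresholds(cleaned_run, cord, hrf = hrf,
                             alpha = config$alpha_temporal,
                             n_surrogates = config$n_surrogates,
                             pooled = config$pooled_thresholds,
                             seed = seed, max_iter = config$ta_max_iter)
  suppressWarnings(
    select_frames(innovations(act), th,
                  spatial_fraction = config$spatial_fraction,
                  run_id = cleaned_run$run_id))
}

#' Extract a component set from a prepared cohort
#'
#' @param cohort a `cord_cohort` from [prepare_cohort()].
#' @param method `"ica"` or `"icap"`.
#' @param K number of components.
#' @param scope `"group"` (one set) or `"subject"` (a list of sets).
#' @param seed integer seed; defaults to the cohort config's.
#' @param subjects subject indices (with repetition allowed, for
#'   bootstrap); default all.
#' @return a [component_set()] for group scope, or a list of them for
#'   subject scope.
#' @export
extract_components <- function(cohort, method = c("ica", "icap"), K,
                               scope = c("group", "subject"), seed = NULL,
                               subjects = NULL) {
  method <- match.arg(method); scope <- match.arg(scope)
  if (is.null(seed)) seed <- cohort$config$seed
  if (is.null(subjects)) subjects <- seq_len(cohort$n_subjects)
  cfg <- cohort$config
  if (method == "ica") {
    if (scope == "group") {
      gs <- group_subspace(cohort$subspaces[subjects])
      spatial_ica(gs, cohort$cord, K, n_iter = cfg$ica_iterations,
                  seed = seed, scope = "group")
    } else {
      lapply(subjects, function(s) {
        spatial_ica(cohort$cleaned[[s]], cohort$cord, K,
                    n_iter = cfg$ica_iterations, seed = seed + s,
                    scope = "subject")
      })
    }
  } else {
    if (scope == "group") {
      fr <- bind_frames(cohort$frames[subjects])
      cluster_icaps(fr, cohort$cord, K, restarts = cfg$kmeans_restarts,
                    seed = seed, distance = cfg$kmeans_distance,
                    scope = "group")
    } else {
      lapply(subjects, function(s) {
        cluster_icaps(cohort$frames[[s]], cohort$cord, K,
                      restarts = cfg$kmeans_restarts, seed = seed + s,
                      distance = cfg$kmeans_distance, scope = "subject")
      })
    }
  }
}

#' Model-order stability under participant subsampling
#'
#' For each K in `K_range`, components are extracted on the full cohort
#' and on `n_subsets` bootstrap subsets of `subset_size` participants
#' (drawn with replacement); subset and full-group maps are binarized at
#' `z`, paired by maximum-weight matching on Dice, and the matched Dice
#' values pooled per K. Distributions are summarized by median and IQR.
#'
#' @param cohort a `cord_cohort`.
#' @param method `"ica"` or `"icap"`.
#' @param K_target target model order; `K_range` defaults to K_target +/- 2
#'   (floored at 2).
#' @param K_range integer vector of model orders to scan.
#' @param n_subsets,subset_size bootstrap scheme (defaults from the cohort
#'   config).
#' @param z binarization threshold.
#' @param seed integer seed for the subset draws.
#' @return list of class `stability_report`: `values` (long data.frame K,
#'   subset, component, dice), `summary` (per-K median, IQR, n),
#'   `failures`, `method`, `K_target`.
#' @export
bootstrap_stability <- function(cohort, method, K_target,
                                K_range = NULL, n_subsets = NULL,
                                subset_size = NULL, z = NULL, seed = NULL) {
  cfg <- cohort$config
  if (is.null(K_range)) K_range <- seq(max(2, K_target - 2), K_target + 2)
  if (is.null(n_subsets)) n_subsets <- cfg$bootstrap[["n_subsets"]]
  if (is.null(subset_size)) subset_size <- cfg$bootstrap[["subset_size"]]
  if (is.null(z)) z <- cfg$z_threshold
  if (is.null(seed)) seed <- cfg$seed
  if (cohort$n_subjects < 2) stop("cohort must contain >= 2 subjects")
  set.seed(seed)
  draws <- replicate(n_subsets,
                     sample(cohort$n_subjects, subset_size, replace = TRUE),
                     simplify = FALSE)
  rows <- list(); failures <- list()
  for (K in K_range) {
    full <- extract_components(cohort, method, K, "group", seed = seed)
    full_bin <- binarize_components(full, z)
    for (b in seq_along(draws)) {
      res <- tryCatch({
        sub <- extract_components(cohort, method, K, "group",
                                  seed = seed + 31L * b,
                                  subjects = draws[[b]])
        sub_bin <- binarize_components(sub, z)
        D <- dice_matrix(sub_bin, full_bin)
        D0 <- D; D0[is.na(D0)] <- 0
        m <- match_components(D0)
        data.frame(K = K, subset = b, component = m$pairs$b,
                   dice = D[cbind(m$pairs$a, m$pairs$b)])
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1]] <-
          data.frame(K = K, subset = b, message = conditionMessage(res))
      } else rows[[length(rows) + 1]] <- res
    }
  }
  values <- do.call(rbind, rows)
  values <- values[!is.na(values$dice), , drop = FALSE]
  summary <- do.call(rbind, lapply(split(values, values$K), function(d) {
    q <- quantile(d$dice, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(K = d$K[1], median = q[2], iqr = q[3] - q[1],
               mean = mean(d$dice), sd = sd(d$dice), n = nrow(d))
  }))
  rownames(summary) <- NULL
  structure(list(values = values, summary = summary,
                 failures = if (length(failures)) do.call(rbind, failures),
                 method = method, K_target = K_target, z = z,
                 n_subsets = n_subsets, subset_size = subset_size),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report method=%s K_target=%d> %d subsets of %d\n",
              x$method, x$K_target, x$n_subsets, x$subset_size))
  print(x$summary)
  invisible(x)
}

# restrict a cleaned run to a window of volumes
crop_run <- function(run, idx) {
  bold_run(run$data[, , , idx, drop = FALSE], voxel_size = run$voxel_size,
           tr = run$tr, run_id = sprintf("%s_t%d-%d", run$run_id,
                                         min(idx), max(idx)))
}

split_indices <- function(t, n_splits) {
  len <- t %/% n_splits
  lapply(seq_len(n_splits), function(i) {
    from <- (i - 1L) * len + 1L
    to <- if (i == n_splits) t else i * len  # final split absorbs remainder
    from:to
  })
}

#' Temporal stability across run splits
#'
#' Each participant's cleaned run is divided into `n_splits` contiguous
#' equal parts (the final split absorbs any remainder); group components
#' are extracted independently per split (both streams re-run from the
#' split data, including deconvolution and surrogate thresholds for iCAP)
#' and compared to the full-run group components by matched Dice.
#'
#' @param cohort a `cord_cohort`.
#' @param method `"ica"` or `"icap"`.
#' @param n_splits number of contiguous splits (1, 2 or 4 in practice).
#' @param K model order.
#' @param z binarization threshold (default from config).
#' @param seed integer seed.
#' @return list of class `stability_report` with per-split matched Dice
#'   (`values`: split, component, dice) and the split lengths.
#' @export
split_stability <- function(cohort, method, n_splits, K, z = NULL,
                            seed = NULL) {
  cfg <- cohort$config
  if (is.null(z)) z <- cfg$z_threshold
  if (is.null(seed)) seed <- cfg$seed
  t <- dim(cohort$cleaned[[1]]$data)[4]
  idx <- split_indices(t, n_splits)
  full <- extract_components(cohort, method, K, "group", seed = seed)
  full_bin <- binarize_components(full, z)
  rows <- list()
  for (p in seq_along(idx)) {
    whole <- length(idx[[p]]) == t
    sub_cohort <- if (whole) cohort else
      split_subcohort(cohort, idx[[p]], seed + 997L * p)
    sp <- extract_components(sub_cohort, method, K, "group",
                             seed = if (whole) seed else seed + 13L * p)
    sp_bin <- binarize_components(sp, z)
    D <- dice_matrix(sp_bin, full_bin)
    D0 <- D; D0[is.na(D0)] <- 0
    m <- match_components(D0)
    rows[[p]] <- data.frame(split = p, component = m$pairs$b,
                            dice = D[cbind(m$pairs$a, m$pairs$b)])
  }
  values <- do.call(rbind, rows)
  per_split <- vapply(split(values, values$split),
                      function(d) mean(d$dice, na.rm = TRUE), numeric(1))
  structure(list(values = values, per_split_mean = per_split,
                 split_lengths = vapply(idx, length, integer(1)),
                 method = method, K = K, z = z, n_splits = n_splits),
            class = "stability_report")
}

# rebuild the per-subject features (PCA, frames) on a time window
split_subcohort <- function(cohort, idx, seed) {
  cfg <- cohort$config
  n <- cohort$n_subjects
  cleaned <- lapply(cohort$cleaned, crop_run, idx = idx)
  subspaces <- vector("list", n)
  frames <- vector("list", n)
  for (s in seq_len(n)) {
    subspaces[[s]] <- subject_pca(cleaned[[s]], cohort$cord,
                                  n = min(cfg$n_subject_pcs,
                                          length(idx) - 1))
    frames[[s]] <- icap_prep_run(cleaned[[s]], cohort$cord, cfg,
                                 cohort$hrf, seed = seed + s)
  }
  structure(list(cleaned = cleaned, subspaces = subspaces, frames = frames,
                 designs = NULL, cord = cohort$cord, csf = cohort$csf,
                 atlas = cohort$atlas, hrf = cohort$hrf, config = cfg,
                 n_subjects = n),
            class = "cord_cohort")
}
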