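#' Pipeline configuration
#'
#' Returns the full configuration used by [run_pipeline()] and the individual
#' stages. Every default reproduces the study settings this package
#' implements, so an empty override runs the reference configuration:
#' Z > 1.6 component thresholding, two-sided 5% temporal confidence band,
#' 5% spatial frame fraction, 20 subject-level principal components,
#' 500 ICA iterations, 0.01 Hz high-pass, 5 cosine detrending functions,
#' 5 CompCor components, RETROICOR orders (3 cardiac, 4 respiratory,
#' 1 interaction), and 100 bootstrap subsets of 10 participants.
#'
#' @param ... named overrides of any default (unknown names are an error).
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    K = 5L,
    z_threshold = 1.6,
    alpha_temporal = 0.05,
    spatial_fraction = 0.05,
    n_subject_pcs = 20L,
    ica_iterations = 500L,
    highpass_hz = 0.01,
    n_dct = 5L,
    n_compcor = 5L,
    compcor_scale = FALSE,     # variance-normalize CSF voxels before PCA
    retroicor_orders = c(cardiac = 3L, respiratory = 4L, interaction = 1L),
    n_surrogates = 8L,
    kmeans_restarts = 5L,
    kmeans_distance = "cosine",  # or "euclidean"
    pooled_thresholds = FALSE,   # pool surrogate innovations across voxels
    ta_tol = 1e-3,
    ta_max_iter = 2000L,
    bootstrap = c(n_subsets = 100L, subset_size = 10L),
    seed = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  counts <- c("K", "n_subject_pcs", "ica_iterations", "n_dct", "n_compcor",
              "n_surrogates", "kmeans_restarts", "ta_max_iter")
  for (f in counts) {
    if (!(is.numeric(cfg[[f]]) && cfg[[f]] >= 0)) stop(f, " must be a count >= 0")
  }
  for (f in c("alpha_temporal", "spatial_fraction")) {
    v <- cfg[[f]]
    if (!(is.numeric(v) && v > 0 && v < 1)) stop(f, " must lie in (0, 1)")
  }
  if (any(cfg$retroicor_orders < 0)) stop("retroicor_orders must be >= 0")
  if (cfg$highpass_hz < 0) stop("highpass_hz must be >= 0")
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML document holds only the overrides; [read_config()] merges it
#' onto the defaults so an empty file yields the reference configuration.
#'
#' @param path YAML file path.
#' @param config a `pipeline_config` (for writing).
#' @return [read_config()] returns a `pipeline_config`.
#' @export
read_config <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  if (!is.null(doc$retroicor_orders)) {
    doc$retroicor_orders <- unlist(doc$retroicor_orders)
  }
  if (!is.null(doc$bootstrap)) doc$bootstrap <- unlist(doc$bootstrap)
  do.call(pipeline_config, doc)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$retroicor_orders <- as.list(x$retroicor_orders)
  x$bootstrap <- as.list(x$bootstrap)
  yaml::write_yaml(x, path)
  invisible(path)
}
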