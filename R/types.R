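#' @useDynLib cordparc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats convolve cor dgamma fft filter mad median p.adjust
#'   quantile rnorm runif sd var
#' @importFrom utils read.delim write.table
"_PACKAGE"

#' Construct a BOLD run
#'
#' A `bold_run` bundles one participant's 4D time series with its grid
#' geometry and repetition time. All downstream operations (denoising,
#' deconvolution, component extraction) consume this container.
#'
#' @param data 4D numeric array indexed (x, y, z, t).
#' @param voxel_size numeric length-3, voxel edge lengths in mm.
#' @param tr repetition time in seconds.
#' @param run_id opaque label identifying the run.
#' @return An object of class `bold_run`.
#' @export
bold_run <- function(data, voxel_size = c(1, 1, 1), tr = 1, run_id = "run") {
  data <- as_array(data, 4L, "bold data")
  if (dim(data)[4] < 2L) stop("bold_run requires t >= 2 volumes")
  if (!all(is.finite(data))) stop("bold_run data must be finite")
  if (!(is.numeric(tr) && length(tr) == 1L && tr > 0)) stop("tr must be a positive scalar")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) stop("voxel_size must be 3 positive values")
  structure(list(data = data, voxel_size = voxel_size, tr = tr,
                 run_id = as.character(run_id)),
            class = "bold_run")
}

#' Construct a binary volume mask
#'
#' @param data 3D array of 0/1 (or logical) values.
#' @param role one of `"cord"` or `"csf"`.
#' @return An object of class `volume_mask`.
#' @export
volume_mask <- function(data, role = c("cord", "csf")) {
  role <- match.arg(role)
  data <- as_array(data, 3L, "mask data")
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1))) stop("mask must be binary (0/1)")
  if (sum(data) == 0) stop("mask must contain at least one nonzero voxel")
  structure(list(data = array(as.integer(data), dim(data)), role = role),
            class = "volume_mask")
}

#' Construct a segmental-level atlas
#'
#' Integer-labeled rostro-caudal compartments used as the anatomical
#' reference for evaluating data-driven components. Labels 1..L must all be
#' present and their mean z-coordinates must be strictly monotone in the
#' label index, in the direction given by `ordering`.
#'
#' @param labels 3D integer array; 0 is background, 1..L are levels.
#' @param ordering rostro-caudal direction of increasing label index along
#'   the array's z axis: `"+z"` (default) or `"-z"`.
#' @return An object of class `level_atlas` with fields `labels`, `L`,
#'   `ordering`.
#' @export
level_atlas <- function(labels, ordering = c("+z", "-z")) {
  ordering <- match.arg(ordering)
  labels <- as_array(labels, 3L, "atlas labels")
  if (any(labels < 0) || any(labels != round(labels))) {
    stop("atlas labels must be non-negative integers")
  }
  L <- max(labels)
  if (L < 1) stop("atlas must contain at least one label")
  present <- sort(unique(labels[labels > 0]))
  missing <- setdiff(seq_len(L), present)
  if (length(missing)) {
    stop(sprintf("atlas has label gaps: missing label %s",
                 paste(missing, collapse = ", ")))
  }
  mz <- label_mean_z(labels, L)
  d <- diff(mz)
  ok <- if (ordering == "+z") all(d > 0) else all(d < 0)
  if (!ok) stop("atlas label mean z-coordinates are not strictly monotone in label index")
  structure(list(labels = array(as.integer(labels), dim(labels)),
                 L = as.integer(L), ordering = ordering),
            class = "level_atlas")
}

label_mean_z <- function(labels, L) {
  dims <- dim(labels)
  zidx <- rep(seq_len(dims[3]) - 1L, each = dims[1] * dims[2])
  vapply(seq_len(L), function(l) mean(zidx[as.vector(labels) == l]), numeric(1))
}

#' Construct a component set
#'
#' K spatial maps produced by one extraction method (ICA or iCAP) at one
#' scope (group or subject). Maps are dense on the full grid, Z-scored over
#' the in-mask voxels and exactly zero outside the mask.
#'
#' @param maps 4D array (x, y, z, K) of spatial maps.
#' @param mask `volume_mask` (cord) the maps are defined on.
#' @param method `"ica"` or `"icap"`.
#' @param scope `"group"` or `"subject"`.
#' @param time_courses optional K x t matrix of component time courses.
#' @param seed integer seed used for the extraction.
#' @return An object of class `component_set`.
#' @export
component_set <- function(maps, mask, method = c("ica", "icap"),
                          scope = c("group", "subject"),
                          time_courses = NULL, seed = NA_integer_) {
  method <- match.arg(method); scope <- match.arg(scope)
  maps <- as_array(maps, 4L, "component maps")
  stopifnot(inherits(mask, "volume_mask"))
  if (!all(dim(maps)[1:3] == dim(mask$data))) stop("maps and mask grids differ")
  K <- dim(maps)[4]
  if (K < 1) stop("component_set requires K >= 1")
  inmask <- mask$data > 0
  for (k in seq_len(K)) {
    m <- maps[, , , k, drop = TRUE]
    if (any(m[!inmask] != 0)) stop("component maps must be zero outside the mask")
    if (var(m[inmask]) <= 0) stop("component map has zero variance within the mask")
  }
  structure(list(maps = maps, mask = mask, method = method, scope = scope,
                 K = as.integer(K), time_courses = time_courses,
                 seed = seed),
            class = "component_set")
}

as_array <- function(x, ndim, what) {
  if (is.null(dim(x)) && ndim == 1L) return(as.numeric(x))
  x <- as.array(x)
  if (length(dim(x)) != ndim) {
    stop(sprintf("expected %dD %s, got %dD", ndim, what, length(dim(x))))
  }
  storage.mode(x) <- "double"
  x
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_run '%s'> %d x %d x %d grid, %d volumes, TR %.3g s, voxels %s mm\n",
              x$run_id, d[1], d[2], d[3], d[4], x$tr,
              paste(signif(x$voxel_size, 3), collapse = "x")))
  invisible(x)
}

#' @export
print.volume_mask <- function(x, ...) {
  cat(sprintf("<volume_mask role=%s> %s grid, %d voxels\n", x$role,
              paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}

#' @export
print.level_atlas <- function(x, ...) {
  cat(sprintf("<level_atlas> %d levels, ordering %s, grid %s\n", x$L,
              x$ordering, paste(dim(x$labels), collapse = "x")))
  invisible(x)
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set method=%s scope=%s> K=%d on %s grid\n",
              x$method, x$scope, x$K, paste(dim(x$maps)[1:3], collapse = "x")))
  invisible(x)
}

# shared helpers ------------------------------------------------------------

mask_matrix <- function(run, mask) {
  # in-mask voxel x time matrix
  d <- dim(run$data)
  if (!all(d[1:3] == dim(mask$data))) stop("run and mask grids differ")
  flat <- matrix(run$data, prod(d[1:3]), d[4])
  flat[mask$data > 0, , drop = FALSE]
}

unmask_matrix <- function(vox_by_k, mask) {
  # rebuild dense (x,y,z,K) array from in-mask voxel x K matrix
  dims <- dim(mask$data)
  K <- ncol(vox_by_k)
  out <- array(0, c(dims, K))
  idx <- which(mask$data > 0)
  nvox <- prod(dims)
  for (k in seq_len(K)) out[idx + (k - 1L) * nvox] <- vox_by_k[, k]
  out
}

zscore_vec <- function(v) {
  s <- sd(v)
  if (!is.finite(s) || s == 0) stop("cannot Z-score a zero-variance map")
  (v - mean(v)) / s
}
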