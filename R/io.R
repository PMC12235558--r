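#' Read a NIfTI volume as a typed pipeline object
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @param kind `"bold"` (4D run), `"mask"` (3D binary), or `"atlas"`
#'   (3D integer labels).
#' @param role mask role, used when `kind = "mask"`.
#' @param ordering atlas rostro-caudal ordering, used when `kind = "atlas"`.
#' @param run_id label for the run, used when `kind = "bold"`; defaults to
#'   the file name.
#' @return A [bold_run()], [volume_mask()] or [level_atlas()].
#' @export
read_volume <- function(path, kind = c("bold", "mask", "atlas"),
                        role = "cord", ordering = "+z", run_id = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(img), dim = dim(img))  # strip header attributes
  pd <- RNifti::pixdim(img)
  nd <- length(dim(arr))
  if (kind == "bold") {
    if (nd != 4L) stop(sprintf("expected 4D bold volume, got %dD", nd))
    tr <- attr(img, "pixdim")[4]
    if (!is.finite(tr) || tr <= 0) tr <- 1
    if (is.null(run_id)) run_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
    bold_run(arr, voxel_size = pd[1:3], tr = tr, run_id = run_id)
  } else if (kind == "mask") {
    if (nd != 3L) stop(sprintf("expected 3D mask volume, got %dD", nd))
    volume_mask(arr, role = role)
  } else {
    if (nd != 3L) stop(sprintf("expected 3D atlas volume, got %dD", nd))
    level_atlas(arr, ordering = ordering)
  }
}

#' Write a pipeline object (or plain array) as NIfTI
#'
#' Grid geometry (voxel sizes; TR for 4D runs) is stored in the header so a
#' round trip through [read_volume()] restores the object exactly.
#'
#' @param x `bold_run`, `volume_mask`, `level_atlas`, or a numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size mm voxel sizes for plain arrays.
#' @param tr repetition time in seconds for plain 4D arrays.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, voxel_size = c(1, 1, 1), tr = 1) {
  if (inherits(x, "bold_run")) {
    arr <- x$data; voxel_size <- x$voxel_size; tr <- x$tr
  } else if (inherits(x, "volume_mask")) {
    arr <- x$data
  } else if (inherits(x, "level_atlas")) {
    arr <- x$labels
  } else {
    arr <- as.array(x)
  }
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  pd <- c(voxel_size, if (nd == 4L) tr)
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write a confound table as TSV
#'
#' Tables carry one row per volume and family-prefixed column names (e.g.
#' `compcor_01`, `retroicor_c1_cos`, `motion_x`, `outlier_012`,
#' `cardiac_phase`, `resp_phase`).
#'
#' @param path TSV file with a header row.
#' @param x data.frame or numeric matrix with named columns (for writing).
#' @return [read_confounds()] returns a data.frame.
#' @export
read_confounds <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, sep = "\t", check.names = FALSE)
}

#' @rdname read_confounds
#' @export
write_confounds <- function(x, path) {
  x <- as.data.frame(x)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
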