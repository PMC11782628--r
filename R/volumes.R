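#' 4D BOLD volume series
#'
#' Minimal container for a simulated scan: a 4D array (x, y, z, frame), the
#' repetition time and the isotropic voxel size used for affine/geometry.
#'
#' @param data 4D numeric array.
#' @param tr repetition time (seconds).
#' @param voxel_mm isotropic voxel edge length (mm).
#' @return object of class `vol4d`.
#' @export
vol4d <- function(data, tr = 2.0, voxel_mm = 2.2) {
  stopifnot(is.array(data), length(dim(data)) == 4, tr > 0, voxel_mm > 0)
  structure(list(data = data, tr = tr, voxel_mm = voxel_mm), class = "vol4d")
}

#' @export
print.vol4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("vol4d: %d x %d x %d voxels (%.1f mm iso), %d frames, TR %.1f s\n",
              d[1], d[2], d[3], x$voxel_mm, d[4], x$tr))
  invisible(x)
}

# frames x voxels matrix view of a vol4d (or pass-through for a matrix)
as_frame_matrix <- function(volumes) {
  if (inherits(volumes, "vol4d")) {
    d <- dim(volumes$data)
    t(matrix(volumes$data, prod(d[1:3]), d[4]))
  } else if (is.matrix(volumes)) volumes
  else stop("expected a vol4d or a frames x voxels matrix", call. = FALSE)
}

spatial_dim <- function(volumes) {
  if (inherits(volumes, "vol4d")) dim(volumes$data)[1:3] else NULL
}

# reshape a voxel vector back into a 3D array when geometry is known
as_volume <- function(v, dims) {
  if (is.null(dims)) v else array(v, dim = dims)
}
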