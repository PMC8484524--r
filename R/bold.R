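#' 4D BOLD image container
#'
#' A lightweight in-memory representation of a 4D BOLD run on a regular grid
#' in a common (MNI-like) template space: the intensity array, the voxel-to-mm
#' affine, the repetition time and an optional brain mask.
#'
#' @param data Numeric 4D array (x, y, z, t).
#' @param affine 4x4 voxel-to-mm affine (0-based voxel indices). Defaults to an
#'   isotropic grid centred on the origin.
#' @param voxel_size_mm Isotropic voxel edge in mm (used when `affine` is NULL).
#' @param tr Repetition time in seconds.
#' @param mask Logical 3D array marking in-brain voxels; defaults to all TRUE.
#' @return An object of class `bold_image`.
#' @export
bold_image <- function(data, affine = NULL, voxel_size_mm = 3, tr = 2, mask = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 4L)
  dims <- dim(data)[1:3]
  if (is.null(affine)) affine <- centered_affine(dims, voxel_size_mm)
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine)) < .Machine$double.eps) stop("affine must be invertible")
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(vox <= 0)) stop("voxel size must be positive")
  if (is.null(mask)) mask <- array(TRUE, dims)
  if (!identical(dim(mask), dims)) stop("mask shape must equal spatial shape")
  if (!(is.numeric(tr) && length(tr) == 1L && tr > 0)) stop("tr must be a positive scalar")
  structure(list(data = data, affine = affine, voxel_size_mm = vox[1],
                 tr = tr, mask = mask),
            class = "bold_image")
}

#' @export
print.bold_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_image> %d x %d x %d voxels (%.3g mm), %d volumes, TR %.3g s (%.1f min)\n",
              d[1], d[2], d[3], x$voxel_size_mm, d[4], x$tr, d[4] * x$tr / 60))
  invisible(x)
}

n_volumes <- function(img) dim(img$data)[4]

# Affine for a grid centred on the mm origin.
centered_affine <- function(dims, voxel_size_mm) {
  a <- diag(c(rep(voxel_size_mm, 3), 1))
  a[1:3, 4] <- -voxel_size_mm * (dims - 1) / 2
  a
}

#' Affine of the standard 3 mm MNI-like grid (61 x 73 x 61)
#'
#' Maps 0-based voxel indices to MNI mm over the bounding box
#' x in [-90, 90], y in [-126, 90], z in [-72, 108].
#' @return A 4x4 affine matrix.
#' @export
mni_affine_3mm <- function() {
  rbind(c(3, 0, 0, -90),
        c(0, 3, 0, -126),
        c(0, 0, 3, -72),
        c(0, 0, 0, 1))
}

# mm coordinates of every voxel centre, as an n-voxel x 3 matrix in
# column-major (R array) order.
voxel_centers_mm <- function(affine, dims) {
  idx <- as.matrix(expand.grid(x = 0:(dims[1] - 1),
                               y = 0:(dims[2] - 1),
                               z = 0:(dims[3] - 1)))
  t(affine[1:3, 1:3] %*% t(idx) + affine[1:3, 4])
}

# mm -> 0-based voxel coordinates.
mm_to_voxel <- function(affine, xyz) {
  xyz <- rbind(matrix(xyz, ncol = 3))
  t(solve(affine)[1:3, , drop = FALSE] %*% t(cbind(xyz, 1)))
}

# 0-based voxel (matrix) -> mm.
voxel_to_mm <- function(affine, ijk) {
  ijk <- rbind(matrix(ijk, ncol = 3))
  t(affine[1:3, 1:3] %*% t(ijk) + affine[1:3, 4])
}

#' Write / read a BOLD image as NIfTI-1
#'
#' @param img A `bold_image`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `write_bold` returns `path` invisibly; `read_bold` returns a
#'   `bold_image` (mask defaults to voxels with nonzero temporal variance
#'   unless a mask file is supplied).
#' @export
write_bold <- function(img, path) {
  nii <- RNifti::asNifti(img$data)
  nii <- RNifti::`pixdim<-`(nii, c(rep(img$voxel_size_mm, 3), img$tr))
  nii <- RNifti::`pixunits<-`(nii, c("mm", "s"))
  nii <- RNifti::`sform<-`(nii, structure(img$affine, code = 4L))
  nii <- RNifti::`qform<-`(nii, structure(img$affine, code = 2L))
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname write_bold
#' @param mask_path Optional NIfTI mask file.
#' @export
read_bold <- function(path, mask_path = NULL) {
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  affine <- unclass(RNifti::xform(nii))
  tr <- RNifti::pixdim(nii)[4]
  if (!is.finite(tr) || tr <= 0) tr <- 1
  mask <- NULL
  if (!is.null(mask_path)) mask <- as.array(RNifti::readNifti(mask_path)) > 0
  bold_image(arr, affine = affine, tr = tr, mask = mask)
}

#' Write a 3D map (statistic, variability, or mask) as NIfTI-1
#'
#' @param map 3D numeric or logical array.
#' @param affine 4x4 voxel-to-mm affine.
#' @param path Output path.
#' @param sidecar Optional list written as a JSON sidecar next to `path`.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, affine, path, sidecar = NULL) {
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  nii <- RNifti::asNifti(array(as.numeric(map), dim(map)))
  nii <- RNifti::`pixdim<-`(nii, vox)
  nii <- RNifti::`sform<-`(nii, structure(affine, code = 4L))
  nii <- RNifti::`qform<-`(nii, structure(affine, code = 2L))
  RNifti::writeNifti(nii, path)
  if (!is.null(sidecar)) {
    json <- sub("\\.nii(\\.gz)?$", ".json", path)
    jsonlite::write_json(sidecar, json, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read / write a 6-parameter rigid motion trace
#'
#' Whitespace-delimited text, one row per volume: three translations (mm)
#' followed by three rotations (degrees).
#' @param motion Numeric matrix with 6 columns.
#' @param path File path.
#' @return `read_motion` returns the matrix; `write_motion` returns `path`.
#' @export
write_motion <- function(motion, path) {
  stopifnot(is.matrix(motion), ncol(motion) == 6L)
  write.table(format(motion, digits = 8, scientific = FALSE), path,
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_motion
#' @export
read_motion <- function(path) {
  m <- as.matrix(read.table(path, header = FALSE))
  if (ncol(m) != 6L) stop("motion trace must have 6 columns")
  dimnames(m) <- NULL
  m
}

# Flatten 4D (x,y,z,t) to a T x V matrix of voxel time series, and back.
as_ts_matrix <- function(img) {
  d <- dim(img$data)
  t(matrix(img$data, prod(d[1:3]), d[4]))
}

from_ts_matrix <- function(ts, img) {
  d <- dim(img$data)
  d[4] <- nrow(ts)
  img$data <- array(t(ts), d)
  img
}
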