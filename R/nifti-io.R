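#' 4D BOLD volume container
#'
#' Bundles an X x Y x Z x T intensity array with its voxel-to-mm affine and
#' the repetition time. All downstream stages consume this container rather
#' than raw arrays so that grid and timing metadata travel with the data.
#'
#' @param data Numeric 4D array (X x Y x Z x T), all values finite.
#' @param affine 4x4 invertible matrix mapping 0-based voxel indices to mm.
#' @param tr Repetition time in seconds (> 0).
#' @return An object of class `volume4d` with elements `data`, `affine`, `tr`.
#' @export
volume4d <- function(data, affine, tr) {
  if (length(dim(data)) != 4L)
    stop("volume4d requires a 4-dimensional array, got ", length(dim(data)),
         " dimensions")
  if (dim(data)[4] < 2L)
    stop("volume4d requires at least 2 frames")
  if (!all(is.finite(data)))
    stop("volume4d contains non-finite voxel values")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)) ||
      abs(det(affine[1:3, 1:3])) < .Machine$double.eps)
    stop("affine must be an invertible 4x4 matrix")
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop("tr must be a single positive number (seconds)")
  structure(list(data = data, affine = affine, tr = as.numeric(tr)),
            class = "volume4d")
}

# internal: wrap without re-validating (hot paths on data already checked)
new_volume4d <- function(data, affine, tr) {
  structure(list(data = data, affine = affine, tr = tr), class = "volume4d")
}

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume4d> %d x %d x %d grid, %d frames, TR = %g s\n",
              d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}

#' 3D probability or statistic volume container
#'
#' @param data Numeric 3D array.
#' @param affine 4x4 voxel-to-mm matrix.
#' @param probability If `TRUE`, values are checked to lie in \[0, 1\]
#'   (gray-matter probability maps).
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, affine, probability = FALSE) {
  if (length(dim(data)) != 3L)
    stop("volume3d requires a 3-dimensional array, got ", length(dim(data)),
         " dimensions")
  if (probability && (min(data) < 0 || max(data) > 1))
    stop("probability map values must lie in [0, 1]")
  structure(list(data = data, affine = as.matrix(affine)), class = "volume3d")
}

#' Canonical affine for a voxel grid
#'
#' RAS-like affine centred on the grid: index (0,0,0) maps to the most
#' negative corner and the grid centre maps to mm (0,0,0).
#'
#' @param grid_shape Integer vector of length 3.
#' @param voxel_size Isotropic voxel edge in mm.
#' @return 4x4 numeric matrix.
#' @export
grid_affine <- function(grid_shape, voxel_size = 3) {
  aff <- diag(c(rep(voxel_size, 3), 1))
  aff[1:3, 4] <- -voxel_size * (grid_shape - 1) / 2
  aff
}

#' Read a 4D NIfTI-1 BOLD image
#'
#' TR is taken from the header (`pixdim[4]`) when positive; otherwise it must
#' be supplied through `tr`.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param tr Fallback repetition time in seconds when the header carries none.
#' @return A [volume4d].
#' @export
read_volume4d <- function(path, tr = NULL) {
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  if (nd != 4L)
    stop("expected a 4D NIfTI image, got ", nd, "D: ", path)
  pd <- RNifti::pixdim(img)
  hdr_tr <- if (length(pd) >= 4) pd[4] else 0
  if (is.na(hdr_tr) || hdr_tr <= 0) {
    if (is.null(tr))
      stop("NIfTI header carries no TR (pixdim[4] <= 0); supply tr explicitly")
    hdr_tr <- tr
  }
  dat <- array(as.numeric(img), dim = dim(img))
  if (!all(is.finite(dat)))
    stop("non-finite voxel values in ", path)
  volume4d(dat, xform_matrix(img), hdr_tr)
}

#' Read a 3D NIfTI-1 volume (probability map, mask, statistic map)
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param probability Validate values as probabilities.
#' @return A [volume3d].
#' @export
read_volume3d <- function(path, probability = FALSE) {
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  if (nd != 3L)
    stop("expected a 3D NIfTI image, got ", nd, "D: ", path)
  volume3d(array(as.numeric(img), dim = dim(img)), xform_matrix(img),
           probability = probability)
}

xform_matrix <- function(img) {
  m <- RNifti::xform(img)
  structure(as.vector(m), dim = c(4L, 4L))
}

#' Write a volume container to NIfTI-1
#'
#' Masks (logical data) are stored as uint8; everything else as float32.
#'
#' @param vol A [volume4d] or [volume3d] (logical 3D data allowed for masks).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  dat <- vol$data
  datatype <- if (is.logical(dat)) "uint8" else "float"
  img <- RNifti::asNifti(array(as.numeric(dat), dim = dim(dat)))
  vox <- sqrt(colSums(vol$affine[1:3, 1:3]^2))
  if (length(dim(dat)) == 4L && !is.null(vol$tr)) {
    RNifti::pixdim(img) <- c(vox, vol$tr)
  } else {
    RNifti::pixdim(img) <- vox
  }
  img <- RNifti::`qform<-`(img, structure(vol$affine, code = 2L))
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Threshold a gray-matter probability map into an analysis mask
#'
#' A voxel enters the mask iff its probability is strictly greater than
#' `threshold` (default 0.2). The strict inequality matters: it excludes
#' voxels sitting exactly at the threshold, and mask size feeds directly into
#' the GFC normalisation constant `n - 1`.
#'
#' @param prob_map A [volume3d] with values in \[0, 1\].
#' @param threshold Probability cut in \[0, 1); default 0.2.
#' @return Object of class `gm_mask`: logical 3D `data`, `affine`,
#'   `n_voxels`, and `voxels` (matrix of 1-based array indices, one row per
#'   in-mask voxel in ascending x-fastest scan order).
#' @export
build_gm_mask <- function(prob_map, threshold = 0.2) {
  if (threshold < 0 || threshold >= 1)
    stop("threshold must lie in [0, 1)")
  keep <- prob_map$data > threshold
  n <- sum(keep)
  if (n < 2L)
    stop("empty mask: only ", n, " voxel(s) exceed probability ", threshold)
  structure(list(data = keep, affine = prob_map$affine, n_voxels = n,
                 voxels = which(keep, arr.ind = TRUE)),
            class = "gm_mask")
}

#' @export
print.gm_mask <- function(x, ...) {
  cat(sprintf("<gm_mask> %d voxels on a %s grid\n", x$n_voxels,
              paste(dim(x$data), collapse = " x ")))
  invisible(x)
}

#' Extract the frames x voxels time-series matrix under a mask
#'
#' Column order is the ascending x-fastest (then y, then z) scan of the mask
#' voxels — the array's native linear order — and is identical across runs
#' and platforms for the same mask.
#'
#' @param vol A [volume4d].
#' @param mask A `gm_mask` on the same grid and affine.
#' @return Object of class `ts_matrix`: `values` (T x n_voxels), `voxel_index`
#'   (n_voxels x 3, 1-based), `tr`, `removed_frames` (indices deleted by
#'   scrubbing, initially empty).
#' @export
to_matrix <- function(vol, mask) {
  check_same_grid(dim(vol$data)[1:3], vol$affine, mask)
  d <- dim(vol$data)
  flat <- vol$data
  dim(flat) <- c(prod(d[1:3]), d[4])       # reinterpret, no copy
  ts_matrix(t(flat[which(mask$data), , drop = FALSE]),
            voxel_index = mask$voxels, tr = vol$tr)
}

ts_matrix <- function(values, voxel_index, tr, removed_frames = integer(0)) {
  structure(list(values = values, voxel_index = voxel_index, tr = tr,
                 removed_frames = removed_frames),
            class = "ts_matrix")
}

#' @export
print.ts_matrix <- function(x, ...) {
  cat(sprintf("<ts_matrix> %d frames x %d voxels, TR = %g s (%d frames scrubbed)\n",
              nrow(x$values), ncol(x$values), x$tr, length(x$removed_frames)))
  invisible(x)
}

#' Scatter per-voxel values back into a 3D volume
#'
#' Inverse of the statistic step after [to_matrix]: value `i` is written at
#' the i-th mask voxel. Out-of-mask voxels receive `background` (0 by
#' default, `NA` available for viewing).
#'
#' @param values_per_voxel Numeric vector, one value per mask voxel.
#' @param mask The `gm_mask` that defined the column order.
#' @param background Fill value outside the mask.
#' @return A [volume3d] on the mask grid.
#' @export
map_to_volume <- function(values_per_voxel, mask, background = 0) {
  if (length(values_per_voxel) != mask$n_voxels)
    stop("expected ", mask$n_voxels, " values, got ", length(values_per_voxel))
  out <- array(background, dim = dim(mask$data))
  out[which(mask$data)] <- values_per_voxel
  volume3d(out, mask$affine)
}

#' Convert 1-based voxel array indices to mm coordinates
#'
#' @param idx n x 3 matrix of 1-based indices.
#' @param affine 4x4 voxel(0-based)-to-mm matrix.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_to_mm <- function(idx, affine) {
  idx <- matrix(idx, ncol = 3)
  h <- cbind(idx - 1, 1) %*% t(affine)  # 0-based indices into the affine
  h[, 1:3, drop = FALSE]
}

check_same_grid <- function(grid, affine, mask) {
  if (!identical(as.integer(grid), as.integer(dim(mask$data))))
    stop("grid mismatch: image is ", paste(grid, collapse = "x"),
         " but mask is ", paste(dim(mask$data), collapse = "x"),
         "; inputs must share one grid (no resampling is performed)")
  if (max(abs(affine - mask$affine)) > 1e-4)
    stop("affine mismatch between image and mask; inputs must be co-registered")
  invisible(TRUE)
}
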