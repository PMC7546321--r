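#' Read a six-column motion parameter file
#'
#' Whitespace-delimited text, one row per frame: three translations (mm) and
#' three rotations. Rotations are radians by default; pass
#' `rotation_unit = "degrees"` for toolboxes that emit degrees.
#'
#' @param path File path.
#' @param rotation_unit `"radians"` (default) or `"degrees"`.
#' @return A `motion_params` matrix (rotations in radians).
#' @export
read_motion <- function(path, rotation_unit = c("radians", "degrees")) {
  rotation_unit <- match.arg(rotation_unit)
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6)
    stop("motion file must have 6 columns, got ", ncol(m), ": ", path)
  if (rotation_unit == "degrees") m[, 4:6] <- m[, 4:6] * pi / 180
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  structure(m, class = c("motion_params", "matrix", "array"))
}

#' Drop initial volumes from image and motion in lockstep
#'
#' The first frames of a resting-state run are discarded to let longitudinal
#' magnetisation reach steady state (and the subject settle); the default of
#' 10 frames at TR = 2 s discards the first 20 s.
#'
#' @param vol A [volume4d].
#' @param motion Matching `motion_params` matrix.
#' @param k Number of initial frames to drop (default 10); must be < T.
#' @return List with elements `vol` and `motion`.
#' @export
drop_initial_volumes <- function(vol, motion, k = 10L) {
  nT <- dim(vol$data)[4]
  if (k >= nT)
    stop("cannot drop ", k, " volumes from a ", nT, "-frame series")
  if (nrow(motion) != nT)
    stop("motion has ", nrow(motion), " rows but image has ", nT, " frames")
  if (k == 0L) return(list(vol = vol, motion = motion))
  keep <- (k + 1L):nT
  list(vol = new_volume4d(vol$data[, , , keep, drop = FALSE], vol$affine,
                          vol$tr),
       motion = structure(motion[keep, , drop = FALSE],
                          class = class(motion)))
}

#' Gross-motion exclusion check
#'
#' A subject fails QC if any frame's translation exceeds `max_trans_mm` on
#' any axis or any rotation exceeds `max_rot_deg` on any axis, judged on the
#' parameter values themselves (displacement from the reference frame) — the
#' common toolbox convention for a "2 mm / 2 degree" criterion.
#'
#' @param motion `motion_params` matrix (rotations radians).
#' @param max_trans_mm Translation limit, mm (default 2).
#' @param max_rot_deg Rotation limit, degrees (default 2).
#' @return List: `pass` (logical), `frame` (first offending frame or NA),
#'   `axis` (offending column name or NA).
#' @export
qc_motion_exclude <- function(motion, max_trans_mm = 2, max_rot_deg = 2) {
  lim <- c(rep(max_trans_mm, 3), rep(max_rot_deg * pi / 180, 3))
  over <- abs(motion) > rep(lim, each = nrow(motion))
  if (!any(over)) return(list(pass = TRUE, frame = NA_integer_, axis = NA_character_))
  hit <- which(over, arr.ind = TRUE)
  first <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
  list(pass = FALSE, frame = unname(first[1]),
       axis = colnames(motion)[first[2]])
}

#' Spatial Gaussian smoothing of a 4D image
#'
#' Separable per-frame 3D Gaussian convolution. The kernel standard
#' deviation per axis is `fwhm_mm / (2 sqrt(2 ln 2))` converted to voxel
#' units via the affine's column norms (0.566 voxels for a 4 mm kernel on a
#' 3 mm grid). Zero padding at the grid boundary; an interior point spread
#' keeps its total mass.
#'
#' @param vol A [volume4d].
#' @param fwhm_mm Full width at half maximum in mm (default 4; 0 = identity).
#' @return Smoothed [volume4d].
#' @export
gaussian_smooth <- function(vol, fwhm_mm = 4) {
  if (fwhm_mm < 0) stop("fwhm_mm must be non-negative")
  if (fwhm_mm == 0) return(vol)
  vox <- sqrt(colSums(vol$affine[1:3, 1:3]^2))
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / vox
  dat <- vol$data
  for (ax in 1:3) dat <- convolve_axis(dat, ax, gauss_kernel(sigma[ax]))
  new_volume4d(dat, vol$affine, vol$tr)
}

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  w <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  w / sum(w)
}

# Convolve one spatial axis of a 4D array with a 1D kernel, as a
# banded-matrix product so BLAS does the work. The truncated kernel is
# renormalised at the grid boundary (rows sum to 1), so constant images are
# exactly preserved and interior sources keep their mass.
convolve_axis <- function(arr, axis, kernel) {
  d <- dim(arr)
  n <- d[axis]
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (k in seq_along(kernel)) {
    off <- k - r - 1L
    idx <- seq_len(n)
    src <- idx + off
    ok <- src >= 1 & src <= n
    K[cbind(idx[ok], src[ok])] <- K[cbind(idx[ok], src[ok])] + kernel[k]
  }
  K <- K / rowSums(K)
  perm <- c(axis, setdiff(seq_len(4L), axis))
  a <- if (axis == 1L) arr else aperm(arr, perm)
  dp <- d[perm]
  dim(a) <- c(n, prod(dp[-1]))   # reinterpret in place, no copy
  a <- K %*% a
  dim(a) <- dp
  if (axis == 1L) a else aperm(a, order(perm))
}

#' Per-voxel linear detrending
#'
#' Ordinary-least-squares residuals of each column against an intercept and
#' the frame index: removes scanner drift up to first order and centres
#' every voxel's series at zero.
#'
#' @param ts A `ts_matrix`.
#' @return Detrended `ts_matrix`.
#' @export
linear_detrend <- function(ts) {
  n <- nrow(ts$values)
  X <- cbind(1, seq_len(n))
  ts$values <- ts$values - X %*% solve(crossprod(X), crossprod(X, ts$values))
  ts
}

#' Ideal band-pass filter
#'
#' Rectangular frequency-domain filter: discrete Fourier bins whose
#' frequency f satisfies `low_hz <= f <= high_hz` are retained, all other
#' bins (including DC when `low_hz > 0`) are zeroed, and the series is
#' transformed back. This is the filter conventionally applied in
#' resting-state connectivity toolchains; the passband default 0.01-0.08 Hz
#' isolates the low-frequency BOLD fluctuations of interest.
#'
#' @param ts A `ts_matrix`.
#' @param low_hz,high_hz Band edges in Hz; `0 <= low < high < Nyquist`.
#' @return Filtered `ts_matrix` (real-valued).
#' @export
bandpass_filter <- function(ts, low_hz = 0.01, high_hz = 0.08) {
  nyq <- 1 / (2 * ts$tr)
  if (low_hz < 0 || low_hz >= high_hz)
    stop("need 0 <= low_hz < high_hz")
  if (high_hz >= nyq)
    stop("high_hz (", high_hz, ") must be below the Nyquist frequency (",
         nyq, " Hz at TR = ", ts$tr, " s)")
  n <- nrow(ts$values)
  f <- (seq_len(n) - 1) / (n * ts$tr)
  f <- pmin(f, 1 / ts$tr - f)  # fold to physical frequency; keeps conjugate bins
  keep <- f >= low_hz & f <= high_hz
  sp <- stats::mvfft(ts$values)
  sp[!keep, ] <- 0
  ts$values <- Re(stats::mvfft(sp, inverse = TRUE)) / n
  ts
}

#' Friston 24-parameter motion expansion
#'
#' For each of the six rigid-body parameters p: the parameter itself, its
#' one-frame lag (zero-padded at the first frame), its square, and the
#' square of the lag — 24 columns in the block order
#' \[p(t), p(t-1), p(t)^2, p(t-1)^2\].
#'
#' @param motion `motion_params` matrix (frames x 6).
#' @return Frames x 24 numeric matrix with descriptive column names.
#' @export
friston24 <- function(motion) {
  if (ncol(motion) != 6) stop("expected 6 motion parameters")
  p <- unclass(motion)
  lag <- rbind(0, p[-nrow(p), , drop = FALSE])
  out <- cbind(p, lag, p^2, lag^2)
  colnames(out) <- c(colnames(motion),
                     paste0(colnames(motion), "_lag"),
                     paste0(colnames(motion), "_sq"),
                     paste0(colnames(motion), "_lag_sq"))
  out
}

#' Framewise displacement (Power convention)
#'
#' \eqn{FD_t = \sum |\Delta trans| + r \sum |\Delta rot|} with rotations in
#' radians converted to arc length on a sphere of radius `sphere_radius_mm`
#' (default 50 mm). The first frame has FD 0 by convention.
#'
#' @param motion `motion_params` matrix.
#' @param sphere_radius_mm Rotation-to-mm conversion radius.
#' @param threshold_mm Threshold used to flag high-motion frames.
#' @return Object of class `fd_trace`: `fd`, `mean_fd`, `flagged`.
#' @export
compute_fd <- function(motion, sphere_radius_mm = 50, threshold_mm = 0.2) {
  fd <- fd_from_params(motion, sphere_radius_mm)
  structure(list(fd = fd, mean_fd = mean(fd),
                 flagged = which(fd > threshold_mm),
                 threshold_mm = threshold_mm),
            class = "fd_trace")
}

#' @export
print.fd_trace <- function(x, ...) {
  cat(sprintf("<fd_trace> %d frames, mean FD = %.3f mm, %d frame(s) above %.2f mm\n",
              length(x$fd), x$mean_fd, length(x$flagged), x$threshold_mm))
  invisible(x)
}

#' Assemble the nuisance design matrix
#'
#' Intercept, the Friston-24 motion block, and the mean signals of the
#' white-matter and CSF compartments: 27 labelled columns. The global (whole
#' gray-matter) signal is deliberately NOT included — GFC is computed on data
#' that retain the global signal.
#'
#' @param motion `motion_params` (after initial-volume dropping).
#' @param wm_signal,csf_signal Numeric vectors, one value per frame.
#' @return Frames x 27 design matrix.
#' @export
build_nuisance_design <- function(motion, wm_signal, csf_signal) {
  n <- nrow(motion)
  if (length(wm_signal) != n || length(csf_signal) != n)
    stop("WM/CSF signals must match the motion frame count")
  cbind(intercept = 1, friston24(motion), wm = wm_signal, csf = csf_signal)
}

#' Regress nuisance covariates out of every voxel
#'
#' Per-column OLS residuals against the full design. Rank-deficient designs
#' are handled by dropping dependent columns with a warning (an all-zero
#' motion trace, say, contributes nothing).
#'
#' @param ts A `ts_matrix`.
#' @param design Frames x p numeric design matrix.
#' @return Residual `ts_matrix`.
#' @export
nuisance_regress <- function(ts, design) {
  design <- as.matrix(design)
  if (nrow(design) != nrow(ts$values))
    stop("design has ", nrow(design), " rows but series has ",
         nrow(ts$values), " frames")
  qr_ <- qr(design)
  if (qr_$rank < ncol(design)) {
    drop_cols <- qr_$pivot[(qr_$rank + 1L):ncol(design)]
    warning("dropping ", length(drop_cols),
            " linearly dependent design column(s): ",
            paste(colnames(design)[drop_cols], collapse = ", "))
    design <- design[, -drop_cols, drop = FALSE]
    qr_ <- qr(design)
  }
  ts$values <- ts$values - qr.fitted(qr_, ts$values)
  ts
}

#' Delete high-motion frames (scrubbing)
#'
#' Rows whose framewise displacement strictly exceeds `threshold_mm` are
#' removed and their (post-drop) indices recorded on the returned object.
#' Scrubbing runs last in the chain so that deleted frames cannot re-enter
#' through filtering.
#'
#' @param ts A `ts_matrix`.
#' @param fd An `fd_trace` with one FD value per current frame.
#' @param threshold_mm Scrub threshold (default 0.2 mm).
#' @param min_frames Error if fewer frames than this survive (default 30).
#' @return Scrubbed `ts_matrix` with `removed_frames` filled in.
#' @export
scrub <- function(ts, fd, threshold_mm = 0.2, min_frames = 30L) {
  if (length(fd$fd) != nrow(ts$values))
    stop("FD trace length ", length(fd$fd), " does not match ",
         nrow(ts$values), " frames")
  bad <- which(fd$fd > threshold_mm)
  if (length(bad) == 0L) return(ts)
  if (nrow(ts$values) - length(bad) < min_frames)
    stop("scrubbing would leave ", nrow(ts$values) - length(bad),
         " frames (< ", min_frames, ")")
  ts$values <- ts$values[-bad, , drop = FALSE]
  ts$removed_frames <- c(ts$removed_frames, bad)
  ts
}

# 6-connected erosion; falls back to the original mask (with a warning) if
# erosion would empty it.
erode_mask <- function(mask) {
  d <- dim(mask)
  shift <- function(m, ax, by) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[ax]
    if (by > 0) { idx_dst[[ax]] <- (1 + by):n; idx_src[[ax]] <- 1:(n - by) }
    else        { idx_dst[[ax]] <- 1:(n + by); idx_src[[ax]] <- (1 - by):n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  er <- mask
  for (ax in 1:3) for (by in c(-1L, 1L)) er <- er & shift(mask, ax, by)
  if (!any(er)) {
    warning("erosion emptied the mask; using the uneroded mask")
    return(mask)
  }
  er
}

#' Full single-subject preprocessing chain
#'
#' Fixed stage order: drop initial volumes -> motion QC -> spatial smoothing
#' -> linear detrend -> band-pass -> nuisance regression (Friston-24 + WM +
#' CSF, global signal retained) -> FD scrubbing. WM and CSF mean signals are
#' extracted from the smoothed image (WM after 1-voxel erosion so the
#' regressor is white-matter centred), then detrended and filtered exactly
#' like the data before entering the design, so the regression cannot
#' reintroduce out-of-band content.
#'
#' @param vol Raw [volume4d].
#' @param motion `motion_params` with one row per raw frame.
#' @param gm_mask A `gm_mask` from [build_gm_mask].
#' @param wm_mask,csf_mask Logical-data [volume3d] tissue masks.
#' @param k_drop Initial volumes to drop (default 10).
#' @param fwhm_mm Smoothing kernel (default 4 mm).
#' @param band Band-pass edges in Hz (default `c(0.01, 0.08)`).
#' @param fd_threshold Scrub threshold, mm (default 0.2).
#' @param scrub_floor Minimum surviving frames (default 30).
#' @param max_trans_mm,max_rot_deg Gross-motion QC limits.
#' @param erode_wm Erode the WM mask by one voxel before averaging.
#' @return List: `ts` (clean `ts_matrix`), `fd` (`fd_trace` on post-drop
#'   frames), `qc` (QC verdict), `report` (per-subject JSON-ready summary).
#'   If QC fails, `ts` is `NULL`.
#' @export
preprocess_subject <- function(vol, motion, gm_mask, wm_mask, csf_mask,
                               k_drop = 10L, fwhm_mm = 4,
                               band = c(0.01, 0.08), fd_threshold = 0.2,
                               scrub_floor = 30L, max_trans_mm = 2,
                               max_rot_deg = 2, erode_wm = TRUE) {
  dropped <- drop_initial_volumes(vol, motion, k_drop)
  qc <- qc_motion_exclude(dropped$motion, max_trans_mm, max_rot_deg)
  fd <- compute_fd(dropped$motion, threshold_mm = fd_threshold)
  report <- list(frames_dropped = k_drop, qc_pass = qc$pass,
                 qc_frame = qc$frame, mean_fd = fd$mean_fd,
                 scrubbed_frames = integer(0))
  if (!qc$pass)
    return(list(ts = NULL, fd = fd, qc = qc, report = report))

  sm <- gaussian_smooth(dropped$vol, fwhm_mm)
  ts <- to_matrix(sm, gm_mask)

  wm_log <- wm_mask$data > 0.5             # masks may arrive as uint8 NIfTI
  csf_log <- csf_mask$data > 0.5
  wm_use <- if (erode_wm) erode_mask(wm_log) else wm_log
  nuis <- ts_matrix(cbind(wm = mask_mean_series(sm, wm_use),
                          csf = mask_mean_series(sm, csf_log)),
                    voxel_index = NULL, tr = sm$tr)

  ts <- bandpass_filter(linear_detrend(ts), band[1], band[2])
  nuis <- bandpass_filter(linear_detrend(nuis), band[1], band[2])

  design <- build_nuisance_design(dropped$motion,
                                  nuis$values[, 1], nuis$values[, 2])
  ts <- nuisance_regress(ts, design)
  ts <- scrub(ts, fd, fd_threshold, scrub_floor)

  report$scrubbed_frames <- ts$removed_frames
  report$frames_retained <- nrow(ts$values)
  list(ts = ts, fd = fd, qc = qc, report = report)
}

mask_mean_series <- function(vol, mask_arr) {
  d <- dim(vol$data)
  flat <- vol$data
  dim(flat) <- c(prod(d[1:3]), d[4])
  colMeans(flat[which(mask_arr), , drop = FALSE])
}
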