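#' Column standardisation for correlation-as-inner-product
#'
#' Centres each voxel's series and scales it to unit Euclidean norm, so the
#' Pearson correlation of two voxels is exactly the inner product of their
#' standardised columns. Zero-variance (degenerate) columns are flagged and
#' set to zero rather than producing NaNs.
#'
#' @param values Frames x voxels numeric matrix.
#' @return List: `z` (standardised matrix), `degenerate` (logical per column).
#' @export
standardize_ts <- function(values) {
  n <- nrow(values)
  z <- values - rep(colMeans(values), each = n)
  nrm <- sqrt(colSums(z^2))
  degenerate <- nrm < .Machine$double.eps * n
  nrm[degenerate] <- 1
  z <- z * rep(1 / nrm, each = n)
  if (any(degenerate)) z[, which(degenerate)] <- 0
  list(z = z, degenerate = degenerate)
}

#' Fisher z-transform of correlation coefficients
#'
#' `z = atanh(r)` with `r` clipped to `[-1 + eps, 1 - eps]` (eps = 1e-7) so
#' perfectly correlated pairs — duplicated columns, self-correlations under
#' the include-self option — map to a large finite value instead of Inf.
#'
#' @param r Correlations, `|r| <= 1` (a small numerical overshoot is
#'   tolerated and clipped).
#' @param eps Clipping margin.
#' @return Fisher z values, same shape as `r`.
#' @export
fisher_z <- function(r, eps = 1e-7) {
  idx <- which(abs(r) > 1 - eps)   # integer indexing: cheap on big matrices
  if (length(idx)) {
    if (any(abs(r[idx]) > 1 + 1e-8))
      stop("correlations outside [-1, 1]")
    r[idx] <- sign(r[idx]) * (1 - eps)
  }
  atanh(r)
}

#' Global-brain functional connectivity, brute-force reference
#'
#' The defining computation, written as an explicit double loop over voxel
#' pairs: for voxel a,
#' \deqn{GFC(a) = \frac{1}{n-1} \sum_{b \ne a} r(T_a, T_b)}
#' (`mode = "mean_r"`), or the same average taken over Fisher z-transformed
#' correlations (`mode = "mean_z"`, the default downstream). Self-correlation
#' is excluded; `include_self = TRUE` keeps it (still dividing by n - 1) for
#' sensitivity checks. This is the test oracle — use [gfc_fast] for real data.
#'
#' @param ts A `ts_matrix` (or plain frames x voxels matrix).
#' @param mode `"mean_z"` or `"mean_r"`.
#' @param include_self Include the a = a term in the sum.
#' @return Object of class `gfc_map`: `gfc` (per-voxel values), `mode`,
#'   `n_voxels`, `n_frames`, `degenerate` flags.
#' @export
gfc_bruteforce <- function(ts, mode = c("mean_z", "mean_r"),
                           include_self = FALSE) {
  mode <- match.arg(mode)
  v <- ts_values(ts)
  check_gfc_input(v)
  n <- ncol(v)
  degenerate <- apply(v, 2, stats::sd) < .Machine$double.eps * nrow(v)
  out <- numeric(n)
  for (a in seq_len(n)) {
    acc <- 0
    for (b in seq_len(n)) {
      if (b == a && !include_self) next
      r_ab <- if (degenerate[a] || degenerate[b]) 0 else
        stats::cor(v[, a], v[, b])
      acc <- acc + if (mode == "mean_z") fisher_z(r_ab) else r_ab
    }
    out[a] <- acc / (n - 1)
  }
  out[degenerate] <- 0
  gfc_map(out, mode, n, nrow(v), degenerate)
}

#' Global-brain functional connectivity, production path
#'
#' Identical results to [gfc_bruteforce], computed efficiently.
#' `mean_r` uses the linear identity
#' \eqn{\sum_b r(a,b) = z_a \cdot S} with \eqn{S = \sum_b z_b} over
#' standardised columns, so the whole map costs O(n T). `mean_z` needs every
#' pairwise correlation before the nonlinear transform; it is computed in
#' column blocks (`crossprod` per block, then `atanh`), O(n^2 T) time but
#' memory bounded by `n x block_size`.
#'
#' @inheritParams gfc_bruteforce
#' @param block_size Columns per block in `mean_z` mode (default 512).
#' @return A `gfc_map` (see [gfc_bruteforce]).
#' @export
gfc_fast <- function(ts, mode = c("mean_z", "mean_r"), include_self = FALSE,
                     block_size = 512L) {
  mode <- match.arg(mode)
  v <- ts_values(ts)
  check_gfc_input(v)
  n <- ncol(v)
  std <- standardize_ts(v)
  z <- std$z
  if (mode == "mean_r") {
    s <- rowSums(z)
    tot <- drop(crossprod(z, s))  # sum_b r(a, b), including b = a
    if (!include_self) tot <- tot - ifelse(std$degenerate, 0, 1)
    out <- tot / (n - 1)
  } else {
    out <- numeric(n)
    self_z <- fisher_z(1)
    degen_idx <- which(std$degenerate)
    for (start in seq(1L, n, by = block_size)) {
      cols <- start:min(start + block_size - 1L, n)
      rr <- crossprod(z, z[, cols, drop = FALSE])  # n x |cols|
      zz <- fisher_z(rr)
      # pairs with a degenerate voxel count as r = 0
      if (length(degen_idx)) {
        zz[degen_idx, ] <- 0
        zz[, which(std$degenerate[cols])] <- 0
      }
      tot <- colSums(zz)
      if (!include_self)
        tot <- tot - ifelse(std$degenerate[cols], 0, self_z)
      out[cols] <- tot / (n - 1)
    }
  }
  out[std$degenerate] <- 0
  gfc_map(out, mode, n, nrow(v), std$degenerate)
}

gfc_map <- function(gfc, mode, n_voxels, n_frames, degenerate) {
  structure(list(gfc = gfc, mode = mode, n_voxels = n_voxels,
                 n_frames = n_frames, degenerate = degenerate),
            class = "gfc_map")
}

#' @export
print.gfc_map <- function(x, ...) {
  cat(sprintf("<gfc_map> %d voxels, %d frames, mode %s, range [%.4f, %.4f]\n",
              x$n_voxels, x$n_frames, x$mode, min(x$gfc), max(x$gfc)))
  invisible(x)
}

ts_values <- function(ts) {
  if (inherits(ts, "ts_matrix")) ts$values else as.matrix(ts)
}

check_gfc_input <- function(v) {
  if (ncol(v) < 2) stop("GFC needs at least 2 voxels")
  if (nrow(v) < 3) stop("GFC needs at least 3 frames, got ", nrow(v))
  invisible(v)
}

#' Per-subject GFC map with NIfTI output
#'
#' Orchestrates standardisation, [gfc_fast] and [map_to_volume] for one
#' preprocessed subject, optionally writing the 3D map to disk.
#'
#' @param ts Preprocessed `ts_matrix` (columns in mask order).
#' @param mask The `gm_mask` defining the column order.
#' @param mode `"mean_z"` (default) or `"mean_r"`.
#' @param out_path Optional path for a NIfTI-1 3D map.
#' @param ... Passed to [gfc_fast].
#' @return List: `gfc` (the `gfc_map`), `volume` ([volume3d]),
#'   `n_frames_used`.
#' @export
subject_gfc_map <- function(ts, mask, mode = c("mean_z", "mean_r"),
                            out_path = NULL, ...) {
  mode <- match.arg(mode)
  if (ncol(ts$values) != mask$n_voxels)
    stop("series has ", ncol(ts$values), " voxels but mask has ",
         mask$n_voxels)
  g <- gfc_fast(ts, mode = mode, ...)
  vol <- map_to_volume(g$gfc, mask)
  if (!is.null(out_path)) write_volume(vol, out_path)
  list(gfc = g, volume = vol, n_frames_used = nrow(ts$values))
}
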