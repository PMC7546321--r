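# Shared fixtures, all generated in code.

# Compact cohort geometry for fast end-to-end tests: 16^3 grid with effect
# regions placed inside the p >= 0.5 core of that smaller brain.
tiny_spec <- function(...) {
  args <- list(...)
  defaults <- list(
    grid_shape = c(16L, 16L, 16L),
    n_volumes = 80L,
    effect_regions = list(list(center = c(8, 9, 10), radius_mm = 6),
                          list(center = c(9, 7, 6), radius_mm = 6)),
    n_patients = 6L, n_controls = 6L,
    seed = 1L)
  do.call(cohort_spec, utils::modifyList(defaults, args))
}

# A ts_matrix wrapper around a plain matrix (mask bookkeeping not needed).
as_ts <- function(values, tr = 2) {
  structure(list(values = values, voxel_index = NULL, tr = tr,
                 removed_frames = integer(0)),
            class = "ts_matrix")
}

# Sinusoid sampled at TR seconds over n frames.
sinusoid <- function(freq_hz, n, tr = 2, phase = 0) {
  sin(2 * pi * freq_hz * (seq_len(n) - 1) * tr + phase)
}

# Mutually orthogonal, zero-mean columns: whole-period Fourier components.
orthogonal_columns <- function(n_frames, k) {
  tt <- seq_len(n_frames) - 1
  sapply(seq_len(k), function(j) sin(2 * pi * j * tt / n_frames + pi / 7))
}

# A small probability-map volume on an 8^3 grid with given values placed at
# chosen linear indices.
tiny_prob_map <- function(values, idx, shape = c(8L, 8L, 8L)) {
  arr <- array(0, shape)
  arr[idx] <- values
  volume3d(arr, grid_affine(shape, 3), probability = TRUE)
}
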