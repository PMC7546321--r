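test_that("initial volumes are dropped from image and motion in lockstep", {
  vol <- volume4d(array(rnorm(4^3 * 250), c(4, 4, 4, 250)),
                  grid_affine(c(4, 4, 4), 3), 2)
  mo <- generate_motion(250, 0.3, seed = 2)
  out <- drop_initial_volumes(vol, mo, 10)
  expect_equal(dim(out$vol$data)[4], 240L)
  expect_equal(nrow(out$motion), 240L)
  expect_equal(out$vol$data[, , , 1], vol$data[, , , 11])
  expect_equal(unclass(out$motion)[1, ], unclass(mo)[11, ])

  ident <- drop_initial_volumes(vol, mo, 0)
  expect_identical(ident$vol$data, vol$data)
  expect_error(drop_initial_volumes(vol, mo, 250), "cannot drop")
})

test_that("gross-motion QC flags per-axis excursions beyond 2 mm / 2 deg", {
  zero <- structure(matrix(0, 50, 6,
                           dimnames = list(NULL, c("trans_x", "trans_y",
                                                   "trans_z", "rot_x",
                                                   "rot_y", "rot_z"))),
                    class = c("motion_params", "matrix", "array"))
  expect_true(qc_motion_exclude(zero)$pass)

  m <- zero
  m[17, 1] <- 2.5
  res <- qc_motion_exclude(m)
  expect_false(res$pass)
  expect_equal(res$frame, 17L)
  expect_equal(res$axis, "trans_x")

  m2 <- zero
  m2[5, 5] <- 0.04                         # 0.04 rad = 2.29 deg > 2 deg
  expect_false(qc_motion_exclude(m2)$pass)
  m3 <- zero
  m3[5, 5] <- 0.03                         # 1.72 deg: within limits
  expect_true(qc_motion_exclude(m3)$pass)
})

test_that("gaussian smoothing preserves constants and interior mass", {
  const <- volume4d(array(3.5, c(12, 12, 12, 2)), grid_affine(c(12, 12, 12), 3), 2)
  sm <- gaussian_smooth(const, 4)
  expect_equal(sm$data, const$data, tolerance = 1e-12)

  delta <- array(0, c(15, 15, 15, 1))
  delta[8, 8, 8, 1] <- 1
  # volume4d needs >= 2 frames; duplicate the delta frame
  dv <- volume4d(array(rep(delta, 2), c(15, 15, 15, 2)),
                 grid_affine(c(15, 15, 15), 3), 2)
  sm2 <- gaussian_smooth(dv, 4)
  expect_lt(abs(sum(sm2$data[, , , 1]) - 1), 1e-3)   # mass preserved to 0.1%
  # peak spreads but stays centred
  expect_equal(which.max(sm2$data[, , , 1]),
               which.max(delta))
  expect_identical(gaussian_smooth(dv, 0)$data, dv$data)
  expect_error(gaussian_smooth(dv, -1), "non-negative")
})

test_that("linear detrending removes affine trends and centres columns", {
  t_idx <- 1:100
  # an in-band oscillation, phase-centred so it carries no linear component
  # (a sine with arbitrary phase is not orthogonal to a finite ramp)
  osc <- cos(2 * pi * 0.04 * 2 * (t_idx - mean(t_idx)))
  set.seed(44)
  vals <- cbind(3 + 2 * t_idx, osc, rnorm(100))
  out <- linear_detrend(as_ts(vals))
  expect_equal(max(abs(out$values[, 1])), 0, tolerance = 1e-9)
  expect_equal(unname(colMeans(out$values)), rep(0, 3), tolerance = 1e-12)
  # residuals orthogonal to the ramp
  ramp <- t_idx - mean(t_idx)
  expect_lt(max(abs(crossprod(out$values, ramp))) / sqrt(sum(ramp^2)), 1e-8)
  # the oscillation passes essentially unchanged (well under 1% of amplitude)
  expect_lt(max(abs(out$values[, 2] - (osc - mean(osc)))), 0.01)
})

test_that("ideal band-pass keeps 0.04 Hz, kills 0.2 Hz and DC", {
  # 250 frames at TR 2 s: 0.04 Hz completes exactly 20 cycles, so the
  # passband sinusoid occupies a single DFT bin and must come through intact
  n <- 250
  keep <- sinusoid(0.04, n)
  kill <- sinusoid(0.2, n)
  const <- rep(5, n)
  out <- bandpass_filter(as_ts(cbind(keep, kill, const)), 0.01, 0.08)
  expect_lt(max(abs(out$values[, 1] - keep)) / max(abs(keep)), 0.02)
  expect_lt(sqrt(mean(out$values[, 2]^2)) / sqrt(mean(kill^2)), 0.01)
  expect_equal(max(abs(out$values[, 3])), 0, tolerance = 1e-10)
  expect_error(bandpass_filter(as_ts(cbind(keep)), 0.01, 0.3), "Nyquist")
  expect_error(bandpass_filter(as_ts(cbind(keep)), 0.1, 0.05), "low_hz")
})

test_that("Friston-24 expansion matches its definition", {
  zero <- matrix(0, 10, 6,
                 dimnames = list(NULL, c("trans_x", "trans_y", "trans_z",
                                         "rot_x", "rot_y", "rot_z")))
  f0 <- friston24(zero)
  expect_equal(ncol(f0), 24L)
  expect_true(all(f0 == 0))

  m <- zero[1:3, ]
  m[, 1] <- c(1, 2, 3)
  f <- friston24(m)
  expect_equal(unname(f[, "trans_x"]), c(1, 2, 3))
  expect_equal(unname(f[, "trans_x_lag"]), c(0, 1, 2))
  expect_equal(unname(f[, "trans_x_sq"]), c(1, 4, 9))
  expect_equal(unname(f[, "trans_x_lag_sq"]), c(0, 1, 4))
  expect_error(friston24(zero[, 1:5]), "6 motion parameters")
})

test_that("framewise displacement follows the 50 mm sphere convention", {
  zero <- matrix(0, 10, 6)
  expect_equal(compute_fd(zero)$fd, rep(0, 10))
  expect_equal(compute_fd(zero)$mean_fd, 0)

  m <- zero
  m[4:10, 1] <- 0.3                        # one 0.3 mm translation step
  fd <- compute_fd(m)
  expect_equal(fd$fd[4], 0.3)
  expect_equal(fd$fd[5], 0)

  m2 <- zero
  m2[6:10, 5] <- 0.01                      # 0.01 rad rotation step
  fd2 <- compute_fd(m2)
  expect_equal(fd2$fd[6], 0.5)             # 50 mm x 0.01 rad
  expect_equal(length(compute_fd(m2, threshold_mm = 0.2)$flagged), 1L)
})

test_that("nuisance regression yields residuals orthogonal to the design", {
  set.seed(21)
  n <- 60
  design <- build_nuisance_design(
    structure(matrix(rnorm(n * 6, sd = 0.1), n, 6,
                     dimnames = list(NULL, c("trans_x", "trans_y", "trans_z",
                                             "rot_x", "rot_y", "rot_z"))),
              class = c("motion_params", "matrix", "array")),
    wm_signal = rnorm(n), csf_signal = rnorm(n))
  expect_equal(ncol(design), 27L)
  vals <- matrix(rnorm(n * 5), n, 5)
  vals[, 1] <- design[, "wm"]              # a pure nuisance column
  out <- nuisance_regress(as_ts(vals), design)
  expect_lt(max(abs(crossprod(design, out$values))), 1e-8)
  expect_equal(max(abs(out$values[, 1])), 0, tolerance = 1e-9)

  # intercept-only designs reduce to mean centring
  ic <- nuisance_regress(as_ts(vals), matrix(1, n, 1))
  expect_equal(ic$values, scale(vals, scale = FALSE), ignore_attr = TRUE)

  # rank-deficient designs are repaired with a warning
  dd <- cbind(intercept = 1, a = design[, 2], a_again = design[, 2])
  expect_warning(nuisance_regress(as_ts(vals), dd), "dependent")
})

test_that("scrubbing removes exactly the high-FD frames", {
  vals <- matrix(rnorm(240 * 4), 240, 4)
  fd0 <- structure(list(fd = rep(0.1, 240), mean_fd = 0.1,
                        flagged = integer(0), threshold_mm = 0.2),
                   class = "fd_trace")
  expect_identical(scrub(as_ts(vals), fd0)$values, vals)

  fd3 <- structure(list(fd = c(0, 0.3, 0.1), mean_fd = 0.13,
                        flagged = 2L, threshold_mm = 0.2),
                   class = "fd_trace")
  out3 <- scrub(as_ts(vals[1:3, ]), fd3, min_frames = 2)
  expect_equal(nrow(out3$values), 2L)
  expect_equal(out3$removed_frames, 2L)
  expect_equal(out3$values, vals[c(1, 3), ])

  fdv <- rep(0.05, 240)
  fdv[sample(2:240, 12)] <- 0.5
  fd12 <- structure(list(fd = fdv, mean_fd = mean(fdv),
                         flagged = which(fdv > 0.2), threshold_mm = 0.2),
                    class = "fd_trace")
  out12 <- scrub(as_ts(vals), fd12)
  expect_equal(nrow(out12$values), 228L)
  expect_equal(length(out12$removed_frames), 12L)

  fd_all <- structure(list(fd = rep(0.9, 240), mean_fd = 0.9,
                           flagged = 2:240, threshold_mm = 0.2),
                      class = "fd_trace")
  expect_error(scrub(as_ts(vals), fd_all), "frames")
})

test_that("the full chain recovers latent correlation structure", {
  # pure in-band signal + nuisance leakage, no white noise: after the chain,
  # pairwise correlations must match the clean generative signal
  regions <- list(list(center = c(10, 11, 12), radius_mm = 9),
                  list(center = c(11, 9, 7), radius_mm = 6))
  spec <- tiny_spec(grid_shape = c(20L, 20L, 20L), noise_sd = 0,
                    n_volumes = 120L, seed = 4L, effect_regions = regions)
  cohort <- generate_cohort(spec)
  mask <- build_gm_mask(cohort$gm_prob, 0.2)
  res <- preprocess_subject(cohort_image(cohort, 1), cohort$motion[[1]],
                            mask, cohort$wm_mask, cohort$csf_mask,
                            k_drop = 10L)
  # the clean reference: same latents and couplings (identical RNG stream),
  # but no WM/CSF leakage — the chain is supposed to remove that part
  spec_clean <- tiny_spec(grid_shape = c(20L, 20L, 20L), noise_sd = 0,
                          nuisance_coupling = 0, n_volumes = 120L, seed = 4L,
                          effect_regions = regions)
  clean <- generate_subject_gm_matrix(spec_clean, cohort$subjects$group[1],
                                      cohort$subjects$seed[1])
  # compare on the frames the chain kept, at voxels whose smoothing
  # neighbourhood has homogeneous coupling (deep region cores and voxels far
  # from both regions and the mask edge), so spatial smoothing does not mix
  # signals with different weights into the sampled columns
  retained <- setdiff(11:120, 10L + res$ts$removed_frames)
  vox <- mask$voxels
  dist_to <- function(ctr) sqrt(colSums((t(vox) - ctr)^2))
  d1 <- dist_to(regions[[1]]$center)
  d2 <- dist_to(regions[[2]]$center)
  d_edge <- sqrt(colSums((t(vox) - 10.5)^2))
  cols <- c(which(d1 <= 1)[1:3],                      # region-1 core
            which(d2 < 0.9)[1],                       # region-2 centre
            which(d1 > 5 & d2 > 4 & d_edge < 5.6)[1:4])  # far background
  expect_false(anyNA(cols))
  r_clean <- stats::cor(clean$values[retained, cols])
  r_chain <- stats::cor(res$ts$values[, cols])
  expect_lt(max(abs(r_clean - r_chain)), 0.05)
})
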