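test_that("gray-matter probability map has brain-like geometry", {
  gm <- generate_gm_prob_map(c(24L, 24L, 24L), 3)
  expect_true(all(gm$data >= 0 & gm$data <= 1))
  # boundary faces are (numerically) empty
  expect_lt(max(gm$data[1, , ], gm$data[, 1, ], gm$data[, , 1],
                gm$data[24, , ], gm$data[, 24, ], gm$data[, , 24]), 0.05)
  # thresholding at 0.2 keeps a plausible fraction of the grid
  frac <- mean(gm$data > 0.2)
  expect_gt(frac, 0.05)
  expect_lt(frac, 0.80)
  # effect regions sit in the high-probability core
  spec <- cohort_spec()
  for (m in effect_region_masks(spec))
    expect_true(all(gm$data[m] >= 0.5))
  # the mask is a single connected component
  mask <- build_gm_mask(gm, 0.2)
  comps <- extract_clusters(mask$data, rep(1, mask$n_voxels), mask, 26)
  expect_length(comps, 1L)
  expect_error(generate_gm_prob_map(c(4L, 24L, 24L)), "degenerate")
  expect_error(generate_gm_prob_map(c(0L, 0L, 0L)), "degenerate")
})

test_that("motion traces hit the target mean FD and stay QC-clean", {
  mo <- generate_motion(240, target_mean_fd = 0.35, spike_rate = 0.04,
                        seed = 1)
  fd <- compute_fd(mo)
  expect_gte(fd$mean_fd, 0.28)
  expect_lte(fd$mean_fd, 0.42)
  expect_gt(length(fd$flagged), 0)         # spikes exceed the 0.2 mm threshold
  expect_true(qc_motion_exclude(mo)$pass)
  expect_equal(fd$fd[1], 0)

  expect_identical(generate_motion(100, 0.3, 0.04, seed = 9),
                   generate_motion(100, 0.3, 0.04, seed = 9))
  zero <- generate_motion(50, 0, seed = 3)
  expect_true(all(zero == 0))
  expect_error(generate_motion(50, -0.1), "non-negative")
  expect_error(generate_motion(1, 0.3), "at least 2")
})

test_that("noise-free equal-coupling subjects have unit pairwise correlation", {
  spec <- tiny_spec(noise_sd = 0, regional_coupling = 0, nuisance_coupling = 0,
                    coupling_sd = 0,
                    global_coupling_patient_effect = 0.8)  # = control weight
  ts <- generate_subject_gm_matrix(spec, "patient", 42)
  cols <- ts$values[, c(1, 50, 200, ncol(ts$values))]
  cc <- stats::cor(cols)
  expect_equal(unname(cc), matrix(1, 4, 4), tolerance = 1e-10)
})

test_that("groups differ only inside the effect regions", {
  spec <- tiny_spec(coupling_sd = 0)
  ts_p <- generate_subject_gm_matrix(spec, "patient", 7)
  ts_c <- generate_subject_gm_matrix(spec, "control", 7)
  reg_lin <- unlist(lapply(effect_region_masks(spec), which))
  mask_lin <- which(generate_gm_prob_map(spec$grid_shape, spec$voxel_size)$data > 0.2)
  inside <- mask_lin %in% reg_lin
  # same subject seed: identical latents and noise, so out-of-region columns
  # are bit-identical while region columns differ by the coupling reduction
  expect_identical(ts_p$values[, !inside], ts_c$values[, !inside])
  expect_gt(min(abs(ts_p$values[, inside] - ts_c$values[, inside])), 0)
})

test_that("latent signals are band-limited to 0.01-0.08 Hz", {
  spec <- tiny_spec(noise_sd = 0, n_volumes = 150L)
  ts <- generate_subject_gm_matrix(spec, "control", 5)
  x <- ts$values[, 10]
  n <- length(x)
  f <- (seq_len(n) - 1) / (n * spec$tr)
  f <- pmin(f, 1 / spec$tr - f)
  pw <- Mod(stats::fft(x - mean(x)))^2
  in_band <- f >= 0.01 & f <= 0.08
  expect_gt(sum(pw[in_band]) / sum(pw), 0.90)
})

test_that("cohorts carry demographics, durations and reproducible truth", {
  spec <- cohort_spec()
  cohort <- generate_cohort(spec)
  subj <- cohort$subjects
  expect_equal(nrow(subj), 43L)
  expect_equal(sum(subj$group == "patient"), 20L)
  expect_true(all(is.na(subj$duration_months[subj$group == "control"])))
  expect_true(all(!is.na(subj$duration_months[subj$group == "patient"])))
  expect_true(all(subj$age >= 18 & subj$age <= 65))
  expect_equal(subj$age, round(subj$age))   # questionnaire-style integers
  # deterministic sex counts mirror the configured proportions
  expect_equal(sum(subj$sex == "male" & subj$group == "patient"), 7L)
  expect_equal(sum(subj$sex == "male" & subj$group == "control"), 4L)

  # positive coupling-duration link at the default slope
  pat <- subj$group == "patient"
  r <- stats::cor(cohort$truth$subject_coupling[pat],
                  subj$duration_months[pat])
  expect_gt(r, 0.4)

  # determinism: same spec, same cohort (including an image realisation)
  cohort2 <- generate_cohort(cohort_spec())
  expect_identical(cohort$subjects, cohort2$subjects)
  expect_identical(cohort$truth, cohort2$truth)
  img_a <- cohort_image(cohort, 3)
  img_b <- cohort_image(cohort2, 3)
  expect_identical(img_a$data, img_b$data)
})

test_that("patient coupling reduction is bounded by the control coupling", {
  expect_error(cohort_spec(global_coupling_patient_effect = 0.9,
                           global_coupling_control = 0.8),
               "patient effect coupling")
  expect_error(cohort_spec(global_coupling_patient_effect = -0.1),
               "patient effect coupling")
  expect_error(generate_subject_gm_matrix(tiny_spec(), "unknown", 1))
})

test_that("written cohorts reload with identical structure", {
  spec <- tiny_spec(n_patients = 2L, n_controls = 2L, n_volumes = 20L)
  cohort <- generate_cohort(spec)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "participants.tsv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  expect_true(file.exists(file.path(dir, "sub-001_bold.nii.gz")))

  disk <- load_cohort(dir, tr = spec$tr)
  expect_equal(disk$subjects$id, cohort$subjects$id)
  expect_equal(disk$subjects$duration_months, cohort$subjects$duration_months)
  expect_equal(unclass(disk$motion[["sub-001"]]),
               unclass(cohort$motion[["sub-001"]]), tolerance = 1e-6,
               ignore_attr = TRUE)
  img <- read_volume4d(file.path(dir, "sub-001_bold.nii.gz"))
  expect_equal(dim(img$data), c(16, 16, 16, 20))
  expect_equal(img$tr, 2)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(sort(names(truth)),
               sort(c("effect_region_voxels", "subject_coupling",
                      "control_coupling", "patient_effect_coupling")))
})
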