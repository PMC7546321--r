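test_that("voxel-wise GLM reproduces the pooled two-sample t", {
  set.seed(6)
  n1 <- 9; n2 <- 12
  grp <- rep(c("patient", "control"), c(n1, n2))
  y <- c(rnorm(n1, 0.3), rnorm(n2, 0.8))
  stack <- cbind(y, y * 2 + 1)
  fit <- fit_voxelwise_glm(stack, grp)
  # hand-computed pooled t (patient minus control)
  sp <- sqrt(((n1 - 1) * var(y[1:n1]) + (n2 - 1) * var(y[-(1:n1)])) /
               (n1 + n2 - 2))
  t_hand <- (mean(y[1:n1]) - mean(y[-(1:n1)])) / (sp * sqrt(1 / n1 + 1 / n2))
  expect_equal(fit$t[1], t_hand, tolerance = 1e-10)
  expect_equal(fit$df, n1 + n2 - 2)
  # affine transforms of the data leave t unchanged
  expect_equal(fit$t[2], t_hand, tolerance = 1e-10)
  # cross-check against stats::t.test
  tt <- t.test(y[1:n1], y[-(1:n1)], var.equal = TRUE)
  expect_equal(fit$t[1], unname(tt$statistic), tolerance = 1e-10)
})

test_that("GLM guards and covariate handling behave", {
  grp <- rep(c("patient", "control"), c(5, 5))
  const_stack <- matrix(1, 10, 3)
  fit <- fit_voxelwise_glm(const_stack, grp)
  expect_equal(fit$t, rep(0, 3))
  expect_true(all(fit$zero_variance))

  set.seed(2)
  age <- rnorm(10, 50, 8)
  stack <- matrix(rnorm(30), 10, 3)
  f0 <- fit_voxelwise_glm(stack, grp, covariates = data.frame(age = age))
  expect_equal(f0$df, 10 - 3)
  # adding a pure age effect changes nothing once age is modelled
  f1 <- fit_voxelwise_glm(stack + outer(age, c(0.2, -0.1, 0.05)), grp,
                          covariates = data.frame(age = age))
  expect_equal(f0$t, f1$t, tolerance = 1e-8)
  # adding a constant shifts the intercept only
  f2 <- fit_voxelwise_glm(stack + 5, grp, covariates = data.frame(age = age))
  expect_equal(f0$t, f2$t, tolerance = 1e-8)

  expect_error(fit_voxelwise_glm(stack, grp,
                                 covariates = data.frame(age = age,
                                                         age2 = 2 * age)),
               "age2")
  expect_error(fit_voxelwise_glm(stack, rep("patient", 10)), "both levels")
})

test_that("permutation FWE p-values are valid, monotone and reproducible", {
  set.seed(77)
  n <- 24
  grp <- rep(c("patient", "control"), each = 12)
  stack <- matrix(rnorm(n * 50), n, 50)
  stack[, 1] <- stack[, 1] + ifelse(grp == "patient", -1.6, 0)  # one signal
  covs <- data.frame(age = rnorm(n, 50, 6))
  res <- permutation_fwe(stack, grp, covs, n_perm = 300, seed = 5)
  expect_true(all(res$p_fwe >= 1 / 301 & res$p_fwe <= 1))
  # monotone: larger |t| never gets a larger adjusted p
  ord <- order(abs(res$t))
  expect_true(all(diff(res$p_fwe[ord]) <= 1e-12))
  # reproducible under the seed
  res2 <- permutation_fwe(stack, grp, covs, n_perm = 300, seed = 5)
  expect_identical(res$p_fwe, res2$p_fwe)
  expect_identical(res$max_null, res2$max_null)
  # small n_perm for the requested alpha warns
  expect_warning(permutation_fwe(stack, grp, covs, n_perm = 100,
                                 alpha = 0.001, seed = 1),
                 "cannot resolve")
  expect_error(permutation_fwe(stack, grp, covs, n_perm = 50, seed = 1),
               "at least 100")
})

test_that("cluster extraction finds components, peaks and ordering", {
  shape <- c(12L, 12L, 12L)
  pm <- volume3d(array(1, shape), grid_affine(shape, 3), probability = TRUE)
  mask <- build_gm_mask(pm, 0.5)

  # two disjoint blobs of 32 and 67 voxels
  sig <- array(FALSE, shape)
  blob1 <- as.matrix(expand.grid(x = 1:4, y = 1:4, z = 1:2))       # 32
  blob2 <- as.matrix(expand.grid(x = 8:12, y = 8:12, z = 10:12))   # 75
  blob2 <- blob2[1:67, ]
  sig[blob1] <- TRUE
  sig[blob2] <- TRUE
  tvals <- rep(-2, mask$n_voxels)
  peak_lin <- blob2[5, 1] + 12 * (blob2[5, 2] - 1) + 144 * (blob2[5, 3] - 1)
  tvals[peak_lin] <- -6.5                   # all voxels in mask order here
  cl <- extract_clusters(sig, tvals, mask, connectivity = 26)
  expect_length(cl, 2L)
  expect_equal(cl[[1]]$size, 67L)
  expect_equal(cl[[2]]$size, 32L)
  expect_equal(cl[[1]]$peak_t, -6.5)
  expect_equal(cl[[1]]$direction, "decreased")
  expect_true(peak_lin %in% (cl[[1]]$columns))
  tab <- cluster_table(cl)
  expect_equal(names(tab), c("cluster_id", "size_voxels", "peak_x_mm",
                             "peak_y_mm", "peak_z_mm", "peak_t", "direction"))
  expect_equal(tab$size_voxels, c(67, 32))

  # diagonal pair: separate under 6-connectivity, joined under 26
  sig2 <- array(FALSE, shape)
  sig2[5, 5, 5] <- TRUE
  sig2[6, 6, 6] <- TRUE
  expect_length(extract_clusters(sig2, rep(1, mask$n_voxels), mask, 6), 2L)
  expect_length(extract_clusters(sig2, rep(1, mask$n_voxels), mask, 26), 1L)

  # single voxel and empty masks
  sig3 <- array(FALSE, shape)
  sig3[3, 9, 4] <- TRUE
  one <- extract_clusters(sig3, rep(1, mask$n_voxels), mask, 26)
  expect_length(one, 1L)
  expect_equal(one[[1]]$size, 1L)
  expect_equal(one[[1]]$peak_voxel, c(3L, 9L, 4L))
  expect_length(extract_clusters(array(FALSE, shape),
                                 rep(1, mask$n_voxels), mask, 26), 0L)
  expect_equal(nrow(cluster_table(list())), 0L)
  expect_error(extract_clusters(sig3, rep(1, mask$n_voxels), mask, 10),
               "connectivity")
})

test_that("peak coordinates are reported in mm via the affine", {
  shape <- c(12L, 12L, 12L)
  pm <- volume3d(array(1, shape), grid_affine(shape, 3), probability = TRUE)
  mask <- build_gm_mask(pm, 0.5)
  sig <- array(FALSE, shape)
  sig[7, 7, 7] <- TRUE
  cl <- extract_clusters(sig, rep(1, mask$n_voxels), mask, 26)
  expect_equal(cl[[1]]$peak_mm,
               drop(voxel_to_mm(matrix(c(7, 7, 7), 1), mask$affine)))
})
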