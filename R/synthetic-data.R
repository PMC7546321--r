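#' Specification of a synthetic resting-state cohort
#'
#' Collects every knob of the synthetic-fMRI generator: cohort sizes, grid
#' geometry, acquisition timing, the coupling of each voxel to the shared
#' global signal, where and how strongly that coupling is reduced in
#' patients, and how illness duration tracks the per-subject coupling.
#'
#' The generative model for a gray-matter voxel v at frame t is
#' \deqn{y_v(t) = b_g(v) g(t) + b_r(v) s_r(t) + a_w w(t) + a_c c(t) +
#'   \sigma \epsilon_v(t)}
#' where `g` is a band-limited (0.01-0.08 Hz) global latent shared by all
#' gray-matter voxels, `s_r` a band-limited latent private to each effect
#' region, `w`/`c` white-matter and CSF nuisance latents, and epsilon white
#' noise. Controls couple to `g` with weight near
#' `global_coupling_control` everywhere; patients couple with the reduced
#' weight near `global_coupling_patient_effect` inside the effect regions
#' only. Outside the effect regions the coupling distribution is identical
#' between groups.
#'
#' @param n_patients,n_controls Group sizes (defaults 20 and 23).
#' @param grid_shape Voxel counts per axis (default 24 x 24 x 24).
#' @param voxel_size Isotropic voxel edge, mm (default 3).
#' @param n_volumes Frames acquired (default 250).
#' @param tr Repetition time, seconds (default 2).
#' @param global_coupling_control Coupling of gray-matter voxels to the
#'   global latent in controls (and in patients outside effect regions).
#' @param global_coupling_patient_effect Reduced coupling inside effect
#'   regions for patients; must lie in \[0, global_coupling_control\].
#' @param regional_coupling Weight of each region's private latent.
#' @param nuisance_coupling Leakage of WM/CSF latents into gray matter.
#' @param noise_sd White-noise standard deviation.
#' @param coupling_sd Between-subject SD of the coupling weights.
#' @param effect_regions List of `list(center = c(i, j, k), radius_mm = r)`
#'   spherical blobs (1-based voxel centers). The defaults place a deep
#'   "thalamus-like" blob and an inferior "cerebellum-like" blob, echoing the
#'   two-cluster structure typical of case-control GFC findings; no
#'   anatomical claim is made.
#' @param duration_baseline Mean illness duration, months.
#' @param duration_slope Months of illness duration per standard-deviation
#'   increase of a patient's effect-region coupling (positive links longer
#'   duration to higher connectivity).
#' @param duration_noise_sd Residual SD of duration, months.
#' @param target_mean_fd_patient,target_mean_fd_control Mean framewise
#'   displacement the motion generator aims at, mm.
#' @param fd_subject_sd Between-subject SD of the mean-FD target, mm.
#' @param spike_rate Per-frame probability of a motion spike (FD > 0.2 mm).
#' @param seed Integer master seed; every random draw derives from it.
#' @return An object of class `cohort_spec` (a validated list).
#' @export
cohort_spec <- function(n_patients = 20L,
                        n_controls = 23L,
                        grid_shape = c(24L, 24L, 24L),
                        voxel_size = 3,
                        n_volumes = 250L,
                        tr = 2.0,
                        global_coupling_control = 0.8,
                        global_coupling_patient_effect = 0.35,
                        regional_coupling = 0.5,
                        nuisance_coupling = 0.15,
                        noise_sd = 1.0,
                        coupling_sd = 0.06,
                        effect_regions = default_effect_regions(),
                        duration_baseline = 21,
                        duration_slope = 12,
                        duration_noise_sd = 9,
                        target_mean_fd_patient = 0.31,
                        target_mean_fd_control = 0.39,
                        fd_subject_sd = 0.05,
                        spike_rate = 0.04,
                        seed = 1L) {
  spec <- list(n_patients = as.integer(n_patients),
               n_controls = as.integer(n_controls),
               grid_shape = as.integer(grid_shape),
               voxel_size = voxel_size,
               n_volumes = as.integer(n_volumes),
               tr = tr,
               global_coupling_control = global_coupling_control,
               global_coupling_patient_effect = global_coupling_patient_effect,
               regional_coupling = regional_coupling,
               nuisance_coupling = nuisance_coupling,
               noise_sd = noise_sd,
               coupling_sd = coupling_sd,
               effect_regions = effect_regions,
               duration_baseline = duration_baseline,
               duration_slope = duration_slope,
               duration_noise_sd = duration_noise_sd,
               target_mean_fd_patient = target_mean_fd_patient,
               target_mean_fd_control = target_mean_fd_control,
               fd_subject_sd = fd_subject_sd,
               spike_rate = spike_rate,
               seed = as.integer(seed))
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  stopifnot(spec$n_patients > 0, spec$n_controls > 0,
            length(spec$grid_shape) == 3, all(spec$grid_shape > 0),
            spec$voxel_size > 0, spec$n_volumes >= 2, spec$tr > 0,
            spec$noise_sd >= 0, spec$coupling_sd >= 0)
  if (spec$global_coupling_patient_effect < 0 ||
      spec$global_coupling_patient_effect > spec$global_coupling_control)
    stop("patient effect coupling must lie in [0, control coupling]")
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("<cohort_spec> %d patients / %d controls, %s grid @ %g mm, ",
                     "%d volumes, TR = %g s, coupling %.2f -> %.2f in %d effect region(s)\n"),
              x$n_patients, x$n_controls,
              paste(x$grid_shape, collapse = "x"), x$voxel_size,
              x$n_volumes, x$tr, x$global_coupling_control,
              x$global_coupling_patient_effect, length(x$effect_regions)))
  invisible(x)
}

default_effect_regions <- function() {
  list(list(center = c(12, 13, 15), radius_mm = 6),    # deep, thalamus-like
       list(center = c(13, 11, 7),  radius_mm = 7.5))  # inferior, cerebellum-like
}

# Run code under a temporary RNG state so generators never disturb (or depend
# on) the caller's stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

# Deterministic per-purpose sub-seed below 2^31.
derive_seed <- function(seed, stream, index = 0L) {
  (as.numeric(seed) * 48271 + stream * 7919 + index * 104729) %% 2147483647
}

#' Synthetic gray-matter probability map
#'
#' A smooth "brain": a sigmoid of the ellipsoidal radius, near 0.95 in the
#' interior, falling to approximately 0 at the grid boundary, with small
#' low-probability cavities where the synthetic white-matter and CSF
#' compartments sit. Thresholding at 0.2 yields one connected mask of roughly
#' a quarter of the grid at the default geometry.
#'
#' @param grid_shape Voxel counts per axis (each >= 8).
#' @param voxel_size Voxel edge in mm (sets the affine only).
#' @return A [volume3d] with `probability = TRUE`.
#' @export
generate_gm_prob_map <- function(grid_shape = c(24L, 24L, 24L), voxel_size = 3) {
  if (length(grid_shape) != 3 || any(grid_shape < 8))
    stop("degenerate grid: every axis must have at least 8 voxels")
  r <- normalized_radius(grid_shape)
  p <- 0.95 / (1 + exp((r - 1) / 0.05))
  for (m in tissue_geometry(grid_shape)) p[m] <- pmin(p[m], 0.05)
  volume3d(p, grid_affine(grid_shape, voxel_size), probability = TRUE)
}

# Ellipsoidal radius normalised so the "brain boundary" sits at 1.
normalized_radius <- function(grid_shape) {
  ctr <- (grid_shape + 1) / 2
  semi <- 0.36 * grid_shape
  gx <- ((seq_len(grid_shape[1]) - ctr[1]) / semi[1])^2
  gy <- ((seq_len(grid_shape[2]) - ctr[2]) / semi[2])^2
  gz <- ((seq_len(grid_shape[3]) - ctr[3]) / semi[3])^2
  sqrt(outer(outer(gx, gy, `+`), gz, `+`))
}

# Spherical blob of voxels within radius_vox of a (possibly fractional)
# 1-based center.
sphere_mask <- function(grid_shape, center, radius_vox) {
  dx <- (seq_len(grid_shape[1]) - center[1])^2
  dy <- (seq_len(grid_shape[2]) - center[2])^2
  dz <- (seq_len(grid_shape[3]) - center[3])^2
  outer(outer(dx, dy, `+`), dz, `+`) <= radius_vox^2
}

# WM / CSF compartment geometry, scaled with the grid.
tissue_geometry <- function(grid_shape) {
  ctr <- (grid_shape + 1) / 2
  s <- grid_shape[1] / 24
  list(wm  = sphere_mask(grid_shape, ctr + c(-5.5, 0, 0) * s, 2.2 * s),
       csf = sphere_mask(grid_shape, ctr + c(0, 4.5, 0) * s, 1.6 * s))
}

#' Synthetic white-matter and CSF masks
#'
#' Companions to [generate_gm_prob_map]: the compartments carved out of the
#' gray-matter probability map, used by the preprocessing stage as sources of
#' nuisance signals.
#'
#' @inheritParams generate_gm_prob_map
#' @return List with [volume3d] elements `wm` and `csf` (logical data).
#' @export
generate_tissue_masks <- function(grid_shape = c(24L, 24L, 24L), voxel_size = 3) {
  geo <- tissue_geometry(grid_shape)
  aff <- grid_affine(grid_shape, voxel_size)
  list(wm = volume3d(geo$wm, aff), csf = volume3d(geo$csf, aff))
}

#' Logical membership mask of the configured effect regions
#'
#' @param spec A [cohort_spec].
#' @return List of logical 3D arrays, one per effect region.
#' @export
effect_region_masks <- function(spec) {
  lapply(spec$effect_regions, function(reg)
    sphere_mask(spec$grid_shape, reg$center, reg$radius_mm / spec$voxel_size))
}

#' Band-limited latent signal
#'
#' Sum of `n_comp` sinusoids at frequencies drawn uniformly inside the band,
#' with random phases and amplitudes, standardised to zero mean and unit SD.
#' Because every component lies strictly in-band, the spectral content is
#' exactly checkable: all power falls in \[band_low, band_high\] Hz.
#'
#' @param n_volumes Frames.
#' @param tr Sampling interval, seconds.
#' @param band Frequency band, Hz (kept slightly inside 0.01-0.08 so finite
#'   windows do not leak across the analysis band edge).
#' @param n_comp Number of sinusoidal components.
#' @return Numeric vector of length `n_volumes`.
#' @keywords internal
latent_signal <- function(n_volumes, tr, band = c(0.012, 0.078), n_comp = 12) {
  tt <- (seq_len(n_volumes) - 1) * tr
  f <- stats::runif(n_comp, band[1], band[2])
  ph <- stats::runif(n_comp, 0, 2 * pi)
  amp <- stats::runif(n_comp, 0.5, 1)
  x <- drop(cos(outer(tt, 2 * pi * f) + rep(ph, each = n_volumes)) %*% amp)
  as.vector(scale(x))
}

#' Synthetic six-parameter head-motion trace
#'
#' A damped random walk (AR(1), decay 0.95) in three translations (mm) and
#' three rotations (radians) whose per-frame step magnitudes follow a
#' heavy-tailed (log-normal) distribution — most frames are quiet while a
#' minority carry large displacements, the skewed FD profile typical of
#' resting-state motion. The trace is rescaled so the realised mean
#' framewise displacement matches `target_mean_fd` exactly, then salted with
#' brief spikes guaranteeing frames above the 0.2 mm scrubbing threshold.
#' Translations and rotations (on the 50 mm sphere convention) each carry
#' about half of the FD budget.
#'
#' @param n_volumes Frames (>= 2).
#' @param target_mean_fd Desired mean FD in mm; 0 yields an all-zero trace.
#' @param spike_rate Per-frame spike probability.
#' @param seed Integer seed.
#' @return Matrix `n_volumes` x 6 of class `motion_params`
#'   (columns: trans_x, trans_y, trans_z, rot_x, rot_y, rot_z).
#' @export
generate_motion <- function(n_volumes, target_mean_fd = 0.35,
                            spike_rate = 0.04, seed = 1L) {
  if (n_volumes < 2) stop("need at least 2 frames")
  if (target_mean_fd < 0) stop("target_mean_fd must be non-negative")
  m <- matrix(0, n_volumes, 6,
              dimnames = list(NULL, c("trans_x", "trans_y", "trans_z",
                                      "rot_x", "rot_y", "rot_z")))
  if (target_mean_fd > 0) {
    m <- with_seed(seed, {
      steps <- matrix(stats::rnorm(n_volumes * 6), n_volumes, 6)
      steps[, 4:6] <- steps[, 4:6] / 50  # rotations carry half the FD budget
      # quiet frames vs restless bursts: a two-state heavy-tailed step
      # magnitude gives the skewed FD profile of real traces
      mag <- ifelse(stats::runif(n_volumes) < 0.72, 1,
                    pmin(exp(stats::rnorm(n_volumes, 0, 0.5)) * 9, 22))
      steps <- steps * mag
      pos <- apply(steps, 2, function(s) {
        p <- numeric(length(s))
        for (t in 2:length(s)) p[t] <- 0.97 * p[t - 1] + s[t]
        p
      })
      # soft-saturate positions (1.3 mm / 1.3 deg) so displacement from the
      # reference frame stays well inside the 2 mm / 2 deg QC limits, then
      # rescale so the realised mean FD hits the target exactly
      saturate <- function(p, lim_t = 1.3, lim_r = 1.3 * pi / 180) {
        p[, 1:3] <- lim_t * tanh(p[, 1:3] / lim_t)
        p[, 4:6] <- lim_r * tanh(p[, 4:6] / lim_r)
        p
      }
      pos <- saturate(pos)
      pos <- saturate(pos * (target_mean_fd / mean(fd_from_params(pos))))
      pos <- pos * (target_mean_fd / mean(fd_from_params(pos)))
      spikes <- which(stats::runif(n_volumes) < spike_rate)
      spikes <- spikes[spikes > 1]
      for (s in spikes) {
        jump <- stats::runif(1, 0.25, 0.5) / 3
        pos[s, 1:3] <- pos[s, 1:3] + jump * sample(c(-1, 1), 3, replace = TRUE)
      }
      dimnames(pos) <- dimnames(m)
      pos
    })
  }
  structure(m, class = c("motion_params", "matrix", "array"))
}

# Raw FD helper shared with compute_fd (which wraps it in an fd_trace).
fd_from_params <- function(params, sphere_radius_mm = 50) {
  d <- abs(diff(params))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      sphere_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
}

# Per-subject coupling draws. Outside the effect regions every subject uses
# base coupling b0 ~ N(control, coupling_sd); inside them controls keep b0
# while patients draw around the reduced value.
subject_coupling <- function(spec, group, subject_seed) {
  with_seed(derive_seed(subject_seed, 3L), {
    b0 <- stats::rnorm(1, spec$global_coupling_control, spec$coupling_sd)
    b0 <- min(max(b0, 0), 1.5)
    eff <- if (group == "patient") {
      e <- stats::rnorm(1, spec$global_coupling_patient_effect, spec$coupling_sd)
      min(max(e, 0), spec$global_coupling_control)
    } else b0
    list(base = b0, effect = eff)
  })
}

#' Generate one subject's 4D BOLD image
#'
#' Realises the generative model documented in [cohort_spec] on the full
#' grid: band-limited global and regional latents plus WM/CSF nuisance
#' latents and white noise, with the subject's coupling weights determined by
#' group and seed. A plausible motion artefact is NOT injected into the
#' image; motion is represented solely by the companion parameter trace.
#'
#' @param spec A [cohort_spec].
#' @param group `"patient"` or `"control"`.
#' @param subject_seed Integer seed private to this subject.
#' @return A [volume4d] with attributes `coupling` (the subject's
#'   effect-region coupling weight) and `base_coupling`.
#' @export
generate_subject_timeseries <- function(spec, group, subject_seed) {
  group <- match.arg(group, c("patient", "control"))
  geom <- cohort_geometry(spec)
  cpl <- subject_coupling(spec, group, subject_seed)

  nT <- spec$n_volumes
  nv <- prod(spec$grid_shape)
  dat <- with_seed(derive_seed(subject_seed, 4L), {
    g <- latent_signal(nT, spec$tr)
    s_reg <- replicate(length(geom$regions), latent_signal(nT, spec$tr),
                       simplify = FALSE)
    w <- latent_signal(nT, spec$tr)
    cs <- latent_signal(nT, spec$tr)
    x <- matrix(stats::rnorm(nv * nT, sd = spec$noise_sd), nv, nT)

    bg <- numeric(nv)
    bg[geom$brain_idx] <- cpl$base
    for (rm_ in geom$regions) bg[rm_] <- cpl$effect
    x <- x + outer(bg, g)
    for (i in seq_along(geom$regions))
      x[geom$regions[[i]], ] <- x[geom$regions[[i]], ] +
        spec$regional_coupling * rep(s_reg[[i]], each = length(geom$regions[[i]]))
    x[geom$brain_idx, ] <- x[geom$brain_idx, ] +
      spec$nuisance_coupling * rep(w + cs, each = length(geom$brain_idx)) / 2
    x[geom$wm_idx, ] <- x[geom$wm_idx, ] + rep(w, each = length(geom$wm_idx))
    x[geom$csf_idx, ] <- x[geom$csf_idx, ] + rep(cs, each = length(geom$csf_idx))
    x + 100  # scanner-like positive baseline
  })
  dim(dat) <- c(spec$grid_shape, nT)
  vol <- new_volume4d(dat, grid_affine(spec$grid_shape, spec$voxel_size),
                      spec$tr)
  attr(vol, "coupling") <- cpl$effect
  attr(vol, "base_coupling") <- cpl$base
  vol
}

#' Generate one subject's gray-matter time-series matrix directly
#'
#' The same generative model as [generate_subject_timeseries], realised only
#' at the gray-matter voxels (probability > 0.2) and returned as a
#' frames x voxels `ts_matrix` in mask column order — no full-grid image, no
#' baseline offset. This is the economical entry point for statistical
#' studies of the connectivity and inference stages at cohort scale, where
#' the spatial stages (smoothing, masking) are not under study.
#'
#' @inheritParams generate_subject_timeseries
#' @return A `ts_matrix` with attribute `coupling`.
#' @export
generate_subject_gm_matrix <- function(spec, group, subject_seed) {
  group <- match.arg(group, c("patient", "control"))
  geom <- cohort_geometry(spec)
  cpl <- subject_coupling(spec, group, subject_seed)
  nT <- spec$n_volumes
  idx <- geom$brain_idx
  n_gm <- length(idx)
  vals <- with_seed(derive_seed(subject_seed, 4L), {
    g <- latent_signal(nT, spec$tr)
    s_reg <- replicate(length(geom$regions), latent_signal(nT, spec$tr),
                       simplify = FALSE)
    w <- latent_signal(nT, spec$tr)
    cs <- latent_signal(nT, spec$tr)
    x <- matrix(stats::rnorm(nT * n_gm, sd = spec$noise_sd), nT, n_gm)
    bg <- rep(cpl$base, n_gm)
    for (rm_ in geom$regions) bg[match(rm_, idx)] <- cpl$effect
    x <- x + outer(g, bg)
    for (i in seq_along(geom$regions)) {
      cols <- match(geom$regions[[i]], idx)
      cols <- cols[!is.na(cols)]
      x[, cols] <- x[, cols] + spec$regional_coupling * s_reg[[i]]
    }
    x + spec$nuisance_coupling * (w + cs) / 2
  })
  out <- ts_matrix(vals, voxel_index = geom$mask$voxels, tr = spec$tr)
  attr(out, "coupling") <- cpl$effect
  out
}

# Linear-index geometry shared by all subjects of a spec; memoised because it
# is identical for every subject drawn from the same geometry settings.
.geometry_cache <- new.env(parent = emptyenv())

cohort_geometry <- function(spec) {
  key <- paste(c(spec$grid_shape, spec$voxel_size,
                 unlist(spec$effect_regions)), collapse = "|")
  hit <- .geometry_cache[[key]]
  if (!is.null(hit)) return(hit)
  gm <- generate_gm_prob_map(spec$grid_shape, spec$voxel_size)
  tg <- tissue_geometry(spec$grid_shape)
  regions <- lapply(effect_region_masks(spec), which)
  geom <- list(gm_prob = gm,
               mask = build_gm_mask(gm, 0.2),
               brain_idx = which(gm$data > 0.2),
               wm_idx = which(tg$wm),
               csf_idx = which(tg$csf),
               regions = regions)
  .geometry_cache[[key]] <- geom
  geom
}

#' Generate a complete synthetic cohort
#'
#' Demographics (ages truncated to 18-65, questionnaire-style integer
#' rounding), deterministic sex counts matching the configured group
#' proportions, motion traces per subject, the gray-matter probability map
#' and tissue masks, per-subject coupling truth, and illness durations for
#' patients that rise with the subject's effect-region coupling
#' (`duration = baseline + slope * standardized coupling + noise`).
#'
#' Subject images are not materialised here (a full cohort would be large);
#' they are regenerated deterministically on demand via [cohort_image], so a
#' cohort object stays small while remaining bit-reproducible.
#'
#' @param spec A [cohort_spec].
#' @return Object of class `synthetic_cohort`: `spec`, `subjects`
#'   (data.frame), `motion` (named list), `gm_prob`, `wm_mask`, `csf_mask`,
#'   `truth` (effect-region voxel indices, per-subject couplings).
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n <- spec$n_patients + spec$n_controls
  ids <- sprintf("sub-%03d", seq_len(n))
  group <- rep(c("patient", "control"), c(spec$n_patients, spec$n_controls))
  seeds <- vapply(seq_len(n), function(i) derive_seed(spec$seed, 1L, i),
                  numeric(1))

  demo <- with_seed(derive_seed(spec$seed, 2L), {
    age <- ifelse(group == "patient",
                  stats::rnorm(n, 52.55, 8.66), stats::rnorm(n, 49.69, 6.51))
    age <- round(pmin(pmax(age, 18), 65))
    edu <- ifelse(group == "patient",
                  stats::rnorm(n, 10.2, 3.56), stats::rnorm(n, 8.61, 2.27))
    edu <- round(pmax(edu, 0))
    # deterministic sex counts at the configured proportions (7/20, 4/23 at
    # the defaults)
    sex <- character(n)
    n_male_p <- round(spec$n_patients * 7 / 20)
    n_male_c <- round(spec$n_controls * 4 / 23)
    sex[group == "patient"] <- rep(c("male", "female"),
                                   c(n_male_p, spec$n_patients - n_male_p))
    sex[group == "control"] <- rep(c("male", "female"),
                                   c(n_male_c, spec$n_controls - n_male_c))
    fd_target <- pmax(0.05, stats::rnorm(
      n, ifelse(group == "patient", spec$target_mean_fd_patient,
                spec$target_mean_fd_control), spec$fd_subject_sd))
    list(age = age, edu = edu, sex = sex, fd_target = fd_target)
  })

  coupling <- vapply(seq_len(n), function(i)
    subject_coupling(spec, group[i], seeds[i])$effect, numeric(1))

  duration <- rep(NA_real_, n)
  pat <- which(group == "patient")
  duration[pat] <- with_seed(derive_seed(spec$seed, 5L), {
    z <- (coupling[pat] - spec$global_coupling_patient_effect) / spec$coupling_sd
    d <- spec$duration_baseline + spec$duration_slope * z +
      stats::rnorm(length(pat), 0, spec$duration_noise_sd)
    pmax(1, round(d))
  })

  motion <- lapply(seq_len(n), function(i)
    generate_motion(spec$n_volumes, demo$fd_target[i], spec$spike_rate,
                    derive_seed(seeds[i], 6L)))
  names(motion) <- ids

  subjects <- data.frame(id = ids, group = group, age = demo$age,
                         sex = demo$sex, education_years = demo$edu,
                         duration_months = duration, seed = seeds,
                         stringsAsFactors = FALSE)
  masks <- generate_tissue_masks(spec$grid_shape, spec$voxel_size)
  truth <- list(
    effect_region_voxels = lapply(effect_region_masks(spec), which),
    subject_coupling = stats::setNames(coupling, ids),
    control_coupling = spec$global_coupling_control,
    patient_effect_coupling = spec$global_coupling_patient_effect)

  structure(list(spec = spec, subjects = subjects, motion = motion,
                 gm_prob = generate_gm_prob_map(spec$grid_shape,
                                                spec$voxel_size),
                 wm_mask = masks$wm, csf_mask = masks$csf, truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects (%d patients, %d controls), %s grid\n",
              nrow(x$subjects), sum(x$subjects$group == "patient"),
              sum(x$subjects$group == "control"),
              paste(x$spec$grid_shape, collapse = "x")))
  invisible(x)
}

#' Realise one subject's image from a cohort
#'
#' @param cohort A `synthetic_cohort`.
#' @param id Subject id (e.g. `"sub-001"`) or row index.
#' @return A [volume4d] (regenerated deterministically from the stored seed).
#' @export
cohort_image <- function(cohort, id) {
  i <- if (is.character(id)) match(id, cohort$subjects$id) else id
  if (is.na(i) || i < 1 || i > nrow(cohort$subjects))
    stop("unknown subject: ", id)
  generate_subject_timeseries(cohort$spec, cohort$subjects$group[i],
                              cohort$subjects$seed[i])
}

#' Write a synthetic cohort to disk in the pipeline's input layout
#'
#' Writes `sub-XXX_bold.nii.gz`, `sub-XXX_motion.txt` (6 whitespace-delimited
#' columns: translations mm, rotations radians), `gm_prob.nii.gz`,
#' `wm_mask.nii.gz`, `csf_mask.nii.gz`, `participants.tsv`, and `truth.json`
#' (so recovery tests never need the simulator's internals).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(cohort$subjects))) {
    id <- cohort$subjects$id[i]
    write_volume(cohort_image(cohort, i),
                 file.path(dir, paste0(id, "_bold.nii.gz")))
    utils::write.table(format(cohort$motion[[id]], digits = 8),
                       file.path(dir, paste0(id, "_motion.txt")),
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  write_volume(cohort$gm_prob, file.path(dir, "gm_prob.nii.gz"))
  write_volume(cohort$wm_mask, file.path(dir, "wm_mask.nii.gz"))
  write_volume(cohort$csf_mask, file.path(dir, "csf_mask.nii.gz"))
  utils::write.table(cohort$subjects[, setdiff(names(cohort$subjects), "seed")],
                     file.path(dir, "participants.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
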