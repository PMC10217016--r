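# Shared phantom builders and oracles for the test suite. All fixtures are
# generated in code; nothing is read from disk except files the tests
# themselves write to tempdir().

CLASS_MEANS <- list(liquid = 0.08, rod = 0.72, interrod = 0.68,
                    surface_zone = 0.80, demineralised = 0.30, bubble = 0.02)

# Homogeneous-speed phantom with a fully exposed face: the front is a flat
# slab advancing at the configured speed.
homog_spec <- function(speed_nm_s = 2, shape = c(48L, 48L, 48L),
                       noise_sd = 0.04, jitter_t = 2, jitter_r = 1,
                       rod_jitter_um = 1,
                       times = seq(10, by = 20, length.out = 5), seed = 7) {
  phantom_spec(shape_voxels = shape, surface_zone_um = 0, liquid_um = 2.6,
               window_radius_um = 1e3, speed_rod_nm_s = speed_nm_s,
               speed_interrod_nm_s = speed_nm_s,
               speed_surface_zone_nm_s = speed_nm_s,
               class_means = CLASS_MEANS, noise_sd = noise_sd,
               jitter_translation_voxels = jitter_t,
               jitter_rotation_deg = jitter_r,
               rod_jitter_um = rod_jitter_um, times_min = times,
               rng_seed = seed)
}

# Two-speed phantom with a circular window: inter-rod dissolves faster.
micro_spec <- function(shape = c(64L, 64L, 64L), v_rod = 1, v_interrod = 2,
                       window_um = 8, surface_um = 0, noise_sd = 0,
                       jitter_t = 0, jitter_r = 0, rod_jitter_um = 1,
                       times = c(60, 85), seed = 5) {
  phantom_spec(shape_voxels = shape, surface_zone_um = surface_um,
               liquid_um = 2.6, window_radius_um = window_um,
               speed_rod_nm_s = v_rod, speed_interrod_nm_s = v_interrod,
               speed_surface_zone_nm_s = v_rod, class_means = CLASS_MEANS,
               noise_sd = noise_sd, jitter_translation_voxels = jitter_t,
               jitter_rotation_deg = jitter_r,
               rod_jitter_um = rod_jitter_um, times_min = times,
               rng_seed = seed)
}

# Standard denoising used ahead of segmentation/registration in tests.
denoise_std <- function(fr) nlm_denoise(median_filter3d(fr, 1L), 0.04, 1L, 1L)

# Union of random disks: a lesion-like random 2D mask.
blob_mask <- function(n = 256, ndisk = 25, rmin = 15, rmax = 40) {
  m <- matrix(FALSE, n, n)
  cy <- runif(ndisk, 1, n); cx <- runif(ndisk, 1, n)
  r <- runif(ndisk, rmin, rmax)
  ix <- matrix(seq_len(n), n, n); iy <- t(ix)
  for (k in seq_len(ndisk)) m <- m | ((iy - cy[k])^2 + (ix - cx[k])^2 <= r[k]^2)
  m
}

# Independent ray oracle: farthest foreground pixel whose unit square the
# ray segment passes through (band half-width = projected square width),
# capped where the ray centre line leaves the slice.
oracle_ray <- function(mask, seed, angle_deg, voxel) {
  a <- angle_deg * pi / 180; u <- c(sin(a), cos(a))
  nr <- nrow(mask); nc <- ncol(mask)
  lim <- function(pos, d, n) {
    if (abs(d) < 1e-12) return(Inf)
    if (d > 0) (n - pos) / d else (1 - pos) / d
  }
  t_exit <- min(lim(seed[1], u[1], nr), lim(seed[2], u[2], nc))
  fg <- which(mask, arr.ind = TRUE)
  if (!nrow(fg)) return(0)
  dv <- sweep(fg, 2, seed)
  proj <- dv %*% u
  perp <- abs(dv %*% c(-u[2], u[1]))
  ok <- proj >= 0 & proj <= t_exit & perp <= (abs(u[1]) + abs(u[2])) / 2
  if (!any(ok)) return(0)
  max(proj[ok]) * voxel
}

# One jitter-recovery registration trial; returns c(rotation_deg, voxels).
registration_trial <- function(seed) {
  spec <- phantom_spec(shape_voxels = c(64L, 80L, 80L), surface_zone_um = 3,
                       liquid_um = 2.6, window_radius_um = 10,
                       noise_sd = 0.05, rod_jitter_um = 1,
                       speed_rod_nm_s = 1, speed_interrod_nm_s = 2,
                       speed_surface_zone_nm_s = 0.5,
                       jitter_translation_voxels = 3, jitter_rotation_deg = 2,
                       times_min = c(122, 147), rng_seed = seed)
  lab <- build_microstructure(spec)
  arr <- simulate_arrival_times(lab, spec)
  tr <- lesion_truth_at(arr, 122)
  ref <- denoise_std(render_frame(lab, tr, spec, 1))
  mov <- denoise_std(render_frame(lab, tr, spec, 2))
  reg <- register_rigid(mov, ref)
  transform_magnitude(compose_transform(attr(mov, "jitter"), reg$transform))
}

# Full pipeline run on the 96^3 homogeneous phantom; returns the recovered
# front speed and the volume rate against the analytic slab rate.
pipeline_speed_recovery <- function(v_nm_s, seed = 11) {
  voxel <- 0.325; nliq <- 8
  cfg <- list(
    phantom = list(shape_voxels = c(96L, 96L, 96L), surface_zone_um = 0,
                   liquid_um = nliq * voxel, window_radius_um = 1e3,
                   speed_rod_nm_s = v_nm_s, speed_interrod_nm_s = v_nm_s,
                   speed_surface_zone_nm_s = v_nm_s,
                   class_means = CLASS_MEANS, noise_sd = 0.05,
                   jitter_translation_voxels = 2, jitter_rotation_deg = 1,
                   rod_jitter_um = 1,
                   times_min = seq(10, by = 25, length.out = 8),
                   rng_seed = seed),
    segment = list(enamel_mode = "fixed",
                   enamel_value = (CLASS_MEANS$liquid +
                                     CLASS_MEANS$demineralised) / 2,
                   lesion_mode = "fixed",
                   lesion_value = (CLASS_MEANS$demineralised +
                                     CLASS_MEANS$interrod) / 2,
                   opening_radius = 0L),
    register = list(exclude_below_z = nliq + 4L),
    roi_margin_voxels = 10L)
  run <- run_pipeline(cfg, file.path(tempdir(),
                                     sprintf("recovery_v%g_s%d", v_nm_s, seed)))
  tab <- run$tables$ray_distances
  depth_um <- (96 - nliq) * voxel
  ang <- sort(unique(tab$angle_deg))
  lims <- (depth_um - 2) / abs(sin(ang * pi / 180))
  rec <- estimate_front_speed(tab, max_ray_um = lims,
                              projection = abs(sin(ang * pi / 180)))
  vt <- run$tables$volume_series
  a_roi <- sum(run$roi[50, , ]) * voxel^2
  d90 <- tab$d_total_um[tab$angle_deg == 90]
  i_last <- max(which(d90 < depth_um - 2))
  list(speed_ratio = rec / v_nm_s,
       vrate_ratio = vt$v_rate_abs_um3_s[i_last] / (a_roi * v_nm_s / 1000),
       run = run)
}
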