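test_that("microstructure geometry matches the hexagonal lattice", {
  # areal rod fraction against the closed-form lattice value
  spec <- phantom_spec(shape_voxels = c(6L, 128L, 128L), surface_zone_um = 0,
                       liquid_um = 0.65, window_radius_um = 5,
                       times_min = 122, rng_seed = 1)
  lab <- build_microstructure(spec)
  slice <- lab$labels[6, , ]
  frac <- mean(slice == 1L)
  a <- 5 + 2
  analytic <- pi * 5^2 / (2 * sqrt(3) * a^2)
  expect_lt(abs(frac - analytic) / analytic, 0.02)

  # zero surface-zone thickness leaves no surface-zone voxels
  expect_false(any(lab$labels == 3L))
  spec_sz <- phantom_spec(shape_voxels = c(32L, 48L, 48L), surface_zone_um = 3,
                          times_min = 122, rng_seed = 1)
  expect_gt(sum(build_microstructure(spec_sz)$labels == 3L), 0)

  # too-small volume errors with the minimum size
  tiny <- phantom_spec(shape_voxels = c(16L, 16L, 16L), times_min = 122)
  expect_error(build_microstructure(tiny), "voxels")
})

test_that("sealed window leaves no sources and an all-Inf arrival field", {
  spec <- micro_spec(shape = c(24L, 48L, 48L), window_um = 0)
  lab <- build_microstructure(spec)
  expect_length(lab$source_idx, 0L)
  arr <- simulate_arrival_times(lab, spec)
  expect_true(all(is.infinite(arr$tau_min)))
})

test_that("arrival times follow the closed-form travel times", {
  v <- 2  # nm/s -> 0.12 um/min
  spec <- homog_spec(v, shape = c(40L, 48L, 48L), noise_sd = 0,
                     jitter_t = 0, jitter_r = 0)
  lab <- build_microstructure(spec)
  arr <- simulate_arrival_times(lab, spec)
  nliq <- 8
  voxel <- spec$voxel_um
  v_um_min <- v * 60 / 1000
  tt_voxel <- voxel / v_um_min            # one voxel travel time, minutes
  # straight-down columns: tau at depth k voxels equals k * voxel / v
  for (k in c(5, 15, 30)) {
    tau <- arr$tau_min[nliq + 1 + k, 24, 24]
    expect_lt(abs(tau - k * voxel / v_um_min), tt_voxel)
  }
  # liquid never demineralises
  expect_true(all(is.infinite(arr$tau_min[1:nliq, , ])))
})

test_that("two-layer media accumulate travel time layer by layer", {
  # slow surface zone (v1) over faster bulk (v2): tau below the interface
  # equals h1/v1 + (z - h1)/v2 within two voxel travel times
  spec <- phantom_spec(shape_voxels = c(48L, 48L, 48L), surface_zone_um = 3.25,
                       liquid_um = 2.6, window_radius_um = 1e3,
                       speed_rod_nm_s = 2, speed_interrod_nm_s = 2,
                       speed_surface_zone_nm_s = 1, noise_sd = 0,
                       jitter_translation_voxels = 0, jitter_rotation_deg = 0,
                       times_min = 122, rng_seed = 1)
  lab <- build_microstructure(spec)
  arr <- simulate_arrival_times(lab, spec)
  voxel <- spec$voxel_um
  nliq <- 8; nsz <- 10
  v1 <- 1 * 60 / 1000; v2 <- 2 * 60 / 1000      # um/min
  for (k in c(5, 20)) {   # k voxels below the interface
    z <- nliq + nsz + k
    depth_sz <- (nsz - 1) * voxel               # source sits on the first layer
    expected <- depth_sz / v1 + (k + 1) * voxel / v2
    expect_lt(abs(arr$tau_min[z, 24, 24] - expected), 2 * voxel / v1)
  }
})

test_that("zero-speed material is never reached", {
  spec <- micro_spec(shape = c(32L, 48L, 48L), v_rod = 0, v_interrod = 2,
                     window_um = 1e3, times = c(60))
  lab <- build_microstructure(spec)
  arr <- simulate_arrival_times(lab, spec)
  rods <- lab$labels == 1L
  # rods below the source layer are unreachable
  rods[min(which(apply(lab$labels != 0L, 1, any))), , ] <- FALSE
  expect_true(all(is.infinite(arr$tau_min[rods])))
})

test_that("truth masks start at the source set and are nested in time", {
  spec <- micro_spec(shape = c(32L, 48L, 48L), times = c(30, 60, 90))
  lab <- build_microstructure(spec)
  arr <- simulate_arrival_times(lab, spec)
  m0 <- lesion_truth_at(arr, 0)
  src <- array(FALSE, dim = dim(lab$labels)); src[lab$source_idx] <- TRUE
  expect_identical(m0$mask, src)
  prev <- m0
  for (t in c(30, 60, 90)) {
    cur <- lesion_truth_at(arr, t)
    expect_true(all(cur$mask[prev$mask]))
    prev <- cur
  }
})

test_that("homogeneous lesion volume approaches the analytic slab volume", {
  v <- 2
  spec <- homog_spec(v, shape = c(48L, 48L, 48L), noise_sd = 0,
                     jitter_t = 0, jitter_r = 0)
  lab <- build_microstructure(spec)
  arr <- simulate_arrival_times(lab, spec)
  voxel <- spec$voxel_um
  t <- 35.5 * voxel / (v * 60 / 1000)     # front at 35.5 voxel depths
  mask <- lesion_truth_at(arr, t)
  vol <- lesion_volume(mask)
  face_um2 <- 48 * 48 * voxel^2
  analytic <- face_um2 * (v * 60 / 1000) * t
  expect_lt(abs(vol - analytic) / analytic, 0.03)
})

test_that("rendering is exact without noise and reproducible with it", {
  spec <- micro_spec(shape = c(32L, 48L, 48L), surface_um = 2,
                     times = c(60, 85))
  lab <- build_microstructure(spec)
  arr <- simulate_arrival_times(lab, spec)
  tr <- lesion_truth_at(arr, 60)
  fr <- render_frame(lab, tr, spec, 1)
  means <- c(0.08, 0.72, 0.68, 0.80)
  expected <- array(means[lab$labels + 1L], dim = dim(lab$labels))
  expected[tr$mask] <- 0.30
  expect_equal(fr$data, expected, tolerance = 0)

  spec_n <- micro_spec(shape = c(32L, 48L, 48L), surface_um = 2,
                       noise_sd = 0.05, jitter_t = 1, jitter_r = 0.5,
                       times = c(60, 85))
  f1 <- render_frame(lab, tr, spec_n, 2)
  f2 <- render_frame(lab, tr, spec_n, 2)
  expect_identical(f1$data, f2$data)   # bit-identical redraw

  # demineralised sample mean within 3 standard errors of its class mean
  # (frame 1: never jittered, so the truth mask indexes it directly)
  f0 <- render_frame(lab, tr, spec_n, 1)
  dem <- f0$data[tr$mask]
  se <- 0.05 / sqrt(length(dem))
  expect_lt(abs(mean(dem) - 0.30), 3 * se)
})

test_that("generate_series writes a complete, reproducible series", {
  spec <- micro_spec(shape = c(24L, 48L, 48L), noise_sd = 0.03, jitter_t = 1,
                     jitter_r = 0.5,
                     times = 122 + 25 * (0:3), seed = 4)
  d1 <- tempfile(); d2 <- tempfile()
  man <- generate_series(spec, d1)
  expect_equal(nrow(man$frames), 4L)
  expect_true(all(file.exists(man$frames$path)))
  expect_true(all(file.exists(attr(man, "truth_paths"))))
  expect_equal(diff(man$frames$t_min), rep(25, 3))
  expect_equal(man$frames$t_min[1], 122)

  generate_series(spec, d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- file.path(d2, basename(f1))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  # arrival field roundtrip
  arr <- read_arrival(file.path(d1, "arrival.tif"))
  truth <- simulate_arrival_times(build_microstructure(spec), spec)
  fin <- is.finite(truth$tau_min)
  expect_equal(is.finite(arr$tau_min), fin)
  expect_lt(max(abs(arr$tau_min[fin] - truth$tau_min[fin])), 0.05)
})

test_that("truth front depth regressed on time recovers the speed", {
  v <- 2
  spec <- homog_spec(v, shape = c(48L, 48L, 48L), noise_sd = 0,
                     jitter_t = 0, jitter_r = 0,
                     times = seq(20, by = 15, length.out = 6))
  lab <- build_microstructure(spec)
  arr <- simulate_arrival_times(lab, spec)
  voxel <- spec$voxel_um
  depth <- vapply(spec$times_min, function(t) {
    m <- lesion_truth_at(arr, t)$mask
    max(which(apply(m, 1, any))) * voxel
  }, numeric(1))
  slope_um_min <- coef(lm(depth ~ spec$times_min))[2]
  v_rec <- slope_um_min * 1000 / 60
  expect_lt(abs(v_rec - v) / v, 0.05)
})
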