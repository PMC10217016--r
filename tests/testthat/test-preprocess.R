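test_that("median filter matches an exhaustive neighbourhood-sort oracle", {
  set.seed(3)
  a <- array(runif(125), c(5, 5, 5))
  fr <- volume_frame(a, 1)
  out <- median_filter3d(fr, 1L)$data
  cl <- function(i, n) pmin(pmax(i, 1), n)
  for (z in 1:5) for (y in 1:5) for (x in 1:5) {
    nb <- a[cl((z - 1):(z + 1), 5), cl((y - 1):(y + 1), 5),
            cl((x - 1):(x + 1), 5)]
    expect_equal(out[z, y, x], median(nb))
  }
})

test_that("median filter removes an isolated impulse and keeps constants", {
  a <- array(0.4, c(9, 9, 9)); a[5, 5, 5] <- 1
  out <- median_filter3d(volume_frame(a, 1), 1L)$data
  expect_equal(out, array(0.4, c(9, 9, 9)))
  cst <- median_filter3d(volume_frame(array(0.7, c(7, 7, 7)), 1), 2L)$data
  expect_equal(cst, array(0.7, c(7, 7, 7)))
})

test_that("NLM is an identity at h = 0, on constants, and halves noise", {
  cst <- volume_frame(array(0.6, c(12, 12, 12)), 1)
  expect_lt(max(abs(nlm_denoise(cst, 0.1)$data - 0.6)), 1e-6)
  set.seed(4)
  noisy <- volume_frame(array(0.5 + rnorm(20^3, 0, 0.05), c(20, 20, 20)), 1)
  expect_lt(max(abs(nlm_denoise(noisy, 0)$data - noisy$data)), 1e-6)
  den <- nlm_denoise(noisy, 0.05, 1L, 2L)
  expect_lt(var(as.vector(den$data)), 0.5 * var(as.vector(noisy$data)))
})

test_that("filters preserve shape and metadata", {
  fr <- volume_frame(array(runif(6^3), c(6, 6, 6)), voxel_um = 0.325,
                     t_min = 147, frame_id = 2L)
  for (out in list(median_filter3d(fr, 1L), nlm_denoise(fr, 0.02, 1L, 1L))) {
    expect_identical(dim(out$data), dim(fr$data))
    expect_identical(out$voxel_um, 0.325)
    expect_identical(out$t_min, 147)
    expect_identical(out$frame_id, 2L)
  }
})

test_that("rigid transforms compose and invert consistently", {
  t1 <- rigid_transform3d(c(3, -2, 1), c(1.5, -0.7, 2))
  t2 <- rigid_transform3d(c(-1, 2, 0.5), c(-2, 1, 0.3))
  # compose against direct point mapping
  ctr <- c(10, 12, 14)
  mp <- function(tf, p) {
    R <- demintrack:::rotation_matrix_zyx(tf$rotation_deg)
    as.numeric(R %*% (p - ctr)) + ctr + tf$translation_voxels
  }
  tc <- compose_transform(t1, t2)
  p <- c(3, 20, 11)
  expect_equal(mp(tc, p), mp(t1, mp(t2, p)), tolerance = 1e-10)
  # inverse composes to the identity
  err <- transform_magnitude(compose_transform(t1, invert_transform(t1)))
  expect_lt(err[["rotation_deg"]], 1e-8)
  expect_lt(err[["translation_voxels"]], 1e-8)
})

test_that("apply_transform: identity, integer shifts, and shift-back", {
  set.seed(5)
  a <- array(runif(18^3), c(18, 18, 18))
  fr <- volume_frame(a, 1)
  expect_equal(apply_transform(fr, rigid_transform3d())$data, a,
               tolerance = 1e-12)
  # integer-voxel pure translation: exact shifted copy in the overlap
  sh <- apply_transform(fr, rigid_transform3d(c(0, 0, 0), c(1, -2, 3)))$data
  expect_equal(sh[1:17, 3:18, 1:15], a[2:18, 1:16, 4:18], tolerance = 0)
  expect_true(all(is.na(sh[18, , ])))
  # smooth phantom: +0.5 then -0.5 voxel shift returns close to original
  zz <- seq_len(24)
  smooth <- array(0, c(24, 24, 24))
  for (z in zz) smooth[z, , ] <- outer(sin(zz / 4 + z / 6), cos(zz / 5)) / 4 + 0.5
  sfr <- volume_frame(smooth, 1)
  fwd <- apply_transform(sfr, rigid_transform3d(c(0, 0, 0), c(0.5, 0, 0)))
  back <- apply_transform(fwd, rigid_transform3d(c(0, 0, 0), c(-0.5, 0, 0)))
  d <- back$data - smooth
  rms <- sqrt(mean(d[is.finite(d)]^2))
  expect_lt(rms, 0.02 * diff(range(smooth)))
})

test_that("registration recovers identity, translations and rotations", {
  # sealed window (no lesion) and strong rod/inter-rod contrast: all six
  # parameters are identifiable from the microstructure alone
  cm <- list(liquid = 0.08, rod = 0.82, interrod = 0.55, surface_zone = 0.80,
             demineralised = 0.30, bubble = 0.02)
  spec <- phantom_spec(shape_voxels = c(48L, 64L, 64L), surface_zone_um = 3,
                       liquid_um = 2.6, window_radius_um = 0,
                       class_means = cm, noise_sd = 0,
                       jitter_translation_voxels = 0, jitter_rotation_deg = 0,
                       rod_jitter_um = 1.5, times_min = c(122), rng_seed = 3)
  lab <- build_microstructure(spec)
  arr <- simulate_arrival_times(lab, spec)
  ref <- render_frame(lab, lesion_truth_at(arr, 0), spec, 1)

  self <- register_rigid(ref, ref)
  m <- transform_magnitude(self$transform)
  expect_lt(m[["rotation_deg"]], 0.05)
  expect_lt(m[["translation_voxels"]], 0.1)
  expect_true(self$converged)

  tft <- rigid_transform3d(c(0, 0, 0), c(3, -2, 1))
  movt <- apply_transform(ref, tft, fill = "replicate")
  rt <- register_rigid(movt, ref)
  et <- transform_magnitude(compose_transform(tft, rt$transform))
  expect_lt(et[["translation_voxels"]], 0.5)

  tfr <- rigid_transform3d(c(2, 0, 0), c(0, 0, 0))
  movr <- apply_transform(ref, tfr, fill = "replicate")
  rr <- register_rigid(movr, ref)
  er <- transform_magnitude(compose_transform(tfr, rr$transform))
  expect_lt(er[["rotation_deg"]], 0.25)
})
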