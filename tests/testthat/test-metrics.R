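test_that("ray distance handles disks, annuli and empty slices", {
  vox <- 0.325
  ix <- matrix(seq_len(64), 64, 64); iy <- t(ix)
  r2 <- (iy - 32)^2 + (ix - 32)^2
  disk <- r2 <= 20^2
  for (a in c(0, 37, 90, 200, 311))
    expect_lt(abs(ray_distance(disk, c(32, 32), a, vox) - 20 * vox), vox)

  # annulus: the farthest foreground wins, not the first gap
  annulus <- r2 >= 15^2 & r2 <= 20^2
  d <- ray_distance(annulus, c(32, 32), 45, vox)
  expect_lt(abs(d - 20 * vox), vox)
  expect_gt(d, 18 * vox)

  expect_equal(ray_distance(matrix(FALSE, 32, 32), c(16, 16), 10, vox), 0)
  expect_error(ray_distance(disk, c(0, 5), 0, vox), "outside")
})

test_that("ray march agrees with the exhaustive pixel oracle", {
  set.seed(42)
  for (i in 1:20) {
    m <- blob_mask(128, ndisk = 12, rmin = 10, rmax = 25)
    seed <- c(sample(30:98, 1), sample(30:98, 1))
    ang <- runif(1, 0, 360)
    expect_lt(abs(ray_distance(m, seed, ang, 1) - oracle_ray(m, seed, ang, 1)),
              1 + 1e-9)
  }
})

test_that("distance series implements the printed definitions", {
  # worked increment: 10 -> 13 um over 25 min
  ds <- distance_series(c(10, 13), c(122, 147))
  expect_equal(ds$d_cum_um[2], 3)
  expect_equal(ds$d_cum_rate_um_s[2], 3 / 1500)
  expect_equal(ds$d_cum_rate_nm_s[2], 2)
  expect_equal(ds$d_abs_um[1], 0)
  expect_true(is.na(ds$d_cum_um[1]))
  # current-value denominator, as printed
  expect_equal(ds$d_acc_pct[2], (13 - 10) / 13 * 100)
  expect_equal(distance_series(c(10, 13), c(122, 147),
                               denominator = "reference")$d_acc_pct[2], 30)

  cst <- distance_series(rep(7, 4), c(0, 10, 20, 30))
  expect_true(all(cst$d_abs_um == 0))
  expect_true(all(cst$d_cum_um[-1] == 0))
  expect_true(all(cst$d_cum_rate_um_s[-1] == 0))
})

test_that("cumulative increments telescope to the absolute difference", {
  set.seed(6)
  for (rep in 1:10) {
    d <- cumsum(runif(8, 0, 3)) + 5
    t <- sort(runif(8, 0, 400))
    while (any(diff(t) <= 0)) t <- sort(runif(8, 0, 400))
    ds <- distance_series(d, t)
    expect_equal(cumsum(c(0, ds$d_cum_um[-1])), ds$d_abs_um)
  }
})

test_that("per-slice areas match voxel counting", {
  vox <- 0.325
  m <- array(FALSE, c(6, 10, 20))
  m[2, 1:10, 1:20] <- TRUE                     # full slice
  m[4, 3, 7] <- TRUE                           # single voxel
  tab <- area_per_slice(m, vox)
  expect_equal(tab$area_um2[2], 200 * vox^2)
  expect_equal(tab$area_um2[4], vox^2)
  expect_equal(tab$area_um2[4], 0.105625)
  expect_equal(tab$area_um2[1], 0)
  expect_equal(tab$depth_um, (0:5) * vox)

  set.seed(7)
  r <- array(runif(6 * 10 * 20) < 0.4, c(6, 10, 20))
  tabr <- area_per_slice(r, vox)
  for (z in 1:6) {
    cnt <- 0L
    for (y in 1:10) for (x in 1:20) if (r[z, y, x]) cnt <- cnt + 1L
    expect_equal(tabr$area_um2[z], cnt * vox^2)
  }
})

test_that("area series implements ratios, percentages and rates", {
  areas <- matrix(c(100, 150), nrow = 1)       # one slice, two times
  tab <- area_series(areas, area_tote_um2 = 400, times_min = c(122, 147))
  expect_equal(tab$area_fd, c(1, 1.5))
  expect_equal(tab$area_abs_pct, c(0, 50))
  expect_equal(tab$area_pct[2], (150 - 100) / 150 * 100)
  expect_equal(tab$area_fe_pct, c(25, 37.5))
  expect_equal(tab$area_crate_um2_s[2], 50 / 1500)
  expect_equal(tab$area_rate_um2_s[2], 50 / 1500)
  expect_true(is.na(tab$area_pct[1]))
  # previous-value denominator switch
  prev <- area_series(areas, 400, c(122, 147), denominator = "previous")
  expect_equal(prev$area_pct[2], 50)
  # undemineralised reference slice -> NA with warning
  expect_warning(z0 <- area_series(matrix(c(0, 30), 1), 400, c(122, 147)),
                 "Area\\(t0\\)")
  expect_true(all(is.na(z0$area_fd)))
})

test_that("lesion volume matches counts and analytic spheres", {
  vox <- 0.325
  one <- array(FALSE, c(4, 4, 4)); one[2, 2, 2] <- TRUE
  expect_equal(lesion_volume(one, vox), vox^3)
  expect_equal(lesion_volume(one, vox), 0.034328125)
  expect_equal(lesion_volume(array(FALSE, c(4, 4, 4)), vox), 0)

  r_um <- 10; n <- 71; ctr <- 36
  ax <- (seq_len(n) - ctr) * vox
  ball <- outer(outer(ax^2, ax^2, "+"), ax^2, "+") <= r_um^2
  vol <- lesion_volume(ball, vox)
  expect_lt(abs(vol - 4 / 3 * pi * r_um^3) / (4 / 3 * pi * r_um^3), 0.02)
})

test_that("volume series implements the printed definitions", {
  vt <- volume_series(c(1000, 1300), v_tote_um3 = 8000,
                      times_min = c(122, 147))
  expect_equal(vt$v_f, c(1, 1.3))
  expect_equal(vt$vol_pct[1], 0)
  expect_equal(vt$vol_pct[2], (1300 - 1000) / 1300 * 100)
  expect_equal(vt$v_crate_um3_s[2], 0.2)
  expect_equal(vt$v_crate_nm3_s[2], 2e8)
  expect_equal(vt$v_fe, c(1000, 1300) / 8000)   # ratio, not percent

  # nested masks give nondecreasing volumes and nonnegative rates
  v <- cumsum(runif(6, 0, 500)) + 100
  tt <- seq(122, by = 25, length.out = 6)
  vs <- volume_series(v, 1e5, tt)
  expect_true(all(diff(vs$v_um3) >= 0))
  expect_true(all(vs$v_crate_um3_s[-1] >= 0))
  expect_equal(cumsum(c(0, diff(v))) + v[1], vs$v_um3)
})

test_that("unit scaling: areas scale with voxel^2, volumes with voxel^3", {
  set.seed(8)
  m <- array(runif(5 * 8 * 8) < 0.5, c(5, 8, 8))
  expect_equal(area_per_slice(m, 0.65)$area_um2,
               4 * area_per_slice(m, 0.325)$area_um2)
  expect_equal(lesion_volume(m, 0.65), 8 * lesion_volume(m, 0.325))
})

test_that("EDT is exact on half-spaces, balls and degenerate inputs", {
  vox <- 0.325
  m <- array(FALSE, c(24, 16, 16)); m[5:24, , ] <- TRUE
  ed <- edt3d(m, vox)
  for (z in 5:24) expect_equal(unique(as.vector(ed[z, , ])), (z - 4) * vox)
  expect_true(all(ed[1:4, , ] == 0))

  n <- 41; ctr <- 21; rv <- 13
  ax <- seq_len(n) - ctr
  ball <- outer(outer(ax^2, ax^2, "+"), ax^2, "+") <= rv^2
  eb <- edt3d(ball, 1)
  expect_lt(abs(max(eb) - rv), 1)

  expect_true(all(edt3d(array(FALSE, c(6, 6, 6)), 1) == 0))
  # all-foreground: outside counts as background
  full <- edt3d(array(TRUE, c(9, 9, 9)), 1)
  expect_equal(max(full), 5)
  expect_equal(full[1, 5, 5], 1)
})

test_that("area-depth profiles follow the lesion shape", {
  vox <- 0.325
  cone <- array(FALSE, c(10, 32, 32))
  ix <- matrix(seq_len(32), 32, 32); iy <- t(ix)
  for (z in 1:10) cone[z, , ] <- (iy - 16)^2 + (ix - 16)^2 <= (14 - z)^2
  prof <- area_vs_depth(cone, vox)
  expect_true(all(diff(prof$area_um2) < 0))
  slab <- array(TRUE, c(5, 8, 8))
  expect_equal(length(unique(area_vs_depth(slab, vox)$area_um2)), 1L)
})

test_that("line profiles sample constants, ramps and the surface zone", {
  cst <- volume_frame(array(0.3, c(8, 8, 8)), 1)
  expect_equal(unique(line_profile(cst, c(2, 2, 2), c(7, 7, 7), 20)$intensity),
               0.3)

  # intensity varies linearly along x
  ramp <- volume_frame(array(rep(seq(0, 1, length.out = 16), each = 256),
                             c(16, 16, 16)), 1)
  pr <- line_profile(ramp, c(8, 8, 2), c(8, 8, 15), 14)
  fit <- lm(pr$intensity ~ pr$position_um)
  expect_gt(summary(fit)$r.squared, 0.999)

  expect_error(line_profile(cst, c(0, 2, 2), c(7, 7, 7)), "outside")

  # bright surface zone shows as an elevated plateau of the right width
  spec <- micro_spec(shape = c(48L, 48L, 48L), surface_um = 3.25,
                     times = c(30))
  lab <- build_microstructure(spec)
  fr <- render_frame(lab, lesion_truth_at(simulate_arrival_times(lab, spec),
                                          0), spec, 1)
  prof <- line_profile(fr, c(1, 24, 24), c(48, 24, 24), 48)
  plateau <- prof$position_um[prof$intensity > 0.75]
  expect_lt(abs(diff(range(plateau)) - 3.25) / 3.25, 0.35)
})
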