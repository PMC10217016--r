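# Percentage helper shared by the distance/area/volume series: numerator
# over a selectable denominator. "current" reproduces the printed
# definitions (denominator = the value at ti); "reference" and "previous"
# are the conventional alternatives.
.pct_denom <- function(x, i, denominator) {
  switch(denominator,
         current = x[i],
         reference = x[1L],
         previous = if (i > 1L) x[i - 1L] else NA_real_,
         stop("denominator must be 'current', 'reference' or 'previous'"))
}

#' Seed for per-angle radial front measurements
#'
#' A seed is one voxel position from which rays are cast across a virtual
#' slice towards the lesion front, one ray per angle.
#'
#' @param z,y,x Voxel coordinates of the seed (1-based).
#' @param angles_deg Unique angles in `[0, 360)`. On an `xy` slice the
#'   angle is measured from the `+x` axis towards `+y`; on a `zy` slice
#'   from `+y` towards `+z` (so 90 degrees points into the depth); on a
#'   `zx` slice from `+x` towards `+z`.
#' @return An object of class `seed_spec`.
#' @export
seed_spec <- function(z, y, x, angles_deg) {
  angles_deg <- as.numeric(angles_deg) %% 360
  if (anyDuplicated(angles_deg)) stop("angles must be unique")
  structure(list(z = z, y = y, x = x, angles_deg = angles_deg),
            class = "seed_spec")
}

#' Extract a virtual slice from a volume or mask
#'
#' @param vol 3D array indexed `[z, y, x]`.
#' @param plane `"xy"` (rows = y, cols = x), `"zy"` (rows = z, cols = y) or
#'   `"zx"` (rows = z, cols = x).
#' @param index Slice index along the remaining axis.
#' @return A 2D matrix.
#' @export
extract_slice <- function(vol, plane = c("xy", "zy", "zx"), index) {
  plane <- match.arg(plane)
  switch(plane,
         xy = vol[index, , ],
         zy = vol[, , index],
         zx = vol[, index, ])
}

#' Radial distance from a seed to the far edge of the segmented front
#'
#' Marches from the seed along the given angle in steps of half a voxel,
#' sampling the binary slice by nearest neighbour, until the slice border.
#' Returns the Euclidean distance (um) from the seed to the farthest
#' sampled foreground position -- the "last segmented data" along the ray,
#' so gaps and pores before the front do not terminate the measurement.
#' Returns 0 when the ray meets no foreground.
#'
#' @param mask_slice 2D logical matrix (a virtual slice of the lesion).
#' @param seed `(row, col)` position of the seed, 1-based, inside the
#'   slice.
#' @param angle_deg Ray angle: direction `(d_row, d_col) = (sin, cos)`.
#' @param voxel_um Voxel size in micrometres.
#' @param step_voxels March step (default 0.5 voxel).
#' @return Distance in micrometres.
#' @export
ray_distance <- function(mask_slice, seed, angle_deg, voxel_um,
                         step_voxels = 0.5) {
  nr <- nrow(mask_slice); nc <- ncol(mask_slice)
  if (seed[1] < 1 || seed[1] > nr || seed[2] < 1 || seed[2] > nc)
    stop("seed lies outside the slice")
  a <- angle_deg * pi / 180
  dr <- sin(a); dc <- cos(a)
  # farthest in-bounds step count along each axis
  lim <- function(pos, d, n) {
    if (abs(d) < 1e-12) return(Inf)
    if (d > 0) (n - pos) / d else (1 - pos) / d
  }
  kmax <- floor(min(lim(seed[1], dr, nr), lim(seed[2], dc, nc)) / step_voxels)
  if (!is.finite(kmax)) kmax <- ceiling(max(nr, nc) / step_voxels)
  ks <- 0:max(kmax, 0)
  rr <- round(seed[1] + ks * step_voxels * dr)
  cc <- round(seed[2] + ks * step_voxels * dc)
  ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
  ks <- ks[ok]; rr <- rr[ok]; cc <- cc[ok]
  fg <- mask_slice[cbind(rr, cc)]
  if (!any(fg)) return(0)
  max(ks[fg]) * step_voxels * voxel_um
}

#' Distance evolution and rates along one ray
#'
#' From the per-time total distances `d(ti)` computes the absolute distance
#' `d_abs = d(ti) - d(t0)`, the cumulative increment
#' `d_cum = d(ti) - d(ti-1)`, the accumulated percentage
#' `d_acc% = (d(ti) - d(t0)) / d(ti) * 100` (current-value denominator by
#' default, as printed; see `denominator`), and the two rates
#' `d_abs_rate = d_abs / (60 (ti - t0))` and
#' `d_cum_rate = d_cum / (60 (ti - ti-1))` in um/s (nm/s columns are also
#' emitted). The reference row carries `d_abs = 0` and `NA` for the
#' undefined quantities.
#'
#' @param d_total_um Distances per time point (um), reference first.
#' @param times_min Strictly increasing acquisition times (minutes).
#' @param denominator `"current"` (as printed), `"reference"` or
#'   `"previous"` for the percentage column.
#' @return A `data.frame`, one row per time point.
#' @export
distance_series <- function(d_total_um, times_min,
                            denominator = c("current", "reference",
                                            "previous")) {
  denominator <- match.arg(denominator)
  n <- length(d_total_um)
  stopifnot(length(times_min) == n, n >= 1)
  if (n > 1 && any(diff(times_min) <= 0))
    stop("times_min must be strictly increasing")
  d <- as.numeric(d_total_um)
  d_abs <- d - d[1L]
  d_cum <- c(NA_real_, diff(d))
  d_acc <- rep(NA_real_, n)
  for (i in seq_len(n)[-1L]) {
    den <- .pct_denom(d, i, denominator)
    if (is.na(den) || den == 0) {
      warning("zero denominator for d_acc% at t = ", times_min[i],
              " min; reporting NA")
    } else d_acc[i] <- (d[i] - d[1L]) / den * 100
  }
  dt0 <- (times_min - times_min[1L]) * 60
  dti <- c(NA_real_, diff(times_min)) * 60
  out <- data.frame(
    t_min = times_min,
    d_total_um = d,
    d_abs_um = d_abs,
    d_cum_um = d_cum,
    d_acc_pct = d_acc,
    d_abs_rate_um_s = ifelse(dt0 > 0, d_abs / dt0, NA_real_),
    d_cum_rate_um_s = d_cum / dti)
  out$d_abs_rate_nm_s <- out$d_abs_rate_um_s * 1000
  out$d_cum_rate_nm_s <- out$d_cum_rate_um_s * 1000
  out
}

#' Per-seed, per-angle, per-time front distance table
#'
#' Casts rays from the seed across the chosen virtual slice of every lesion
#' mask in the series and derives the full distance/rate columns per angle.
#'
#' @param masks List of `lesion_mask` objects (time order; each must carry
#'   `t_min`).
#' @param seed A [seed_spec()].
#' @param plane Virtual-slice orientation (see [extract_slice()]): the
#'   slice through the seed used for all rays.
#' @param denominator Percentage denominator, see [distance_series()].
#' @param step_voxels March step for [ray_distance()].
#' @return A `data.frame`, one row per (angle, time).
#' @export
ray_distance_table <- function(masks, seed, plane = c("xy", "zy", "zx"),
                               denominator = "current", step_voxels = 0.5) {
  plane <- match.arg(plane)
  stopifnot(inherits(seed, "seed_spec"), length(masks) >= 1)
  times <- vapply(masks, function(m) m$t_min, numeric(1))
  voxel <- masks[[1L]]$voxel_um
  idx <- switch(plane, xy = seed$z, zy = seed$x, zx = seed$y)
  rc <- switch(plane, xy = c(seed$y, seed$x), zy = c(seed$z, seed$y),
               zx = c(seed$z, seed$x))
  slices <- lapply(masks, function(m) extract_slice(m$mask, plane, idx))
  out <- do.call(rbind, lapply(seed$angles_deg, function(a) {
    d <- vapply(slices, ray_distance, numeric(1), seed = rc, angle_deg = a,
                voxel_um = voxel, step_voxels = step_voxels)
    cbind(angle_deg = a, distance_series(d, times, denominator))
  }))
  rownames(out) <- NULL
  out
}

#' Per-time summary of ray distances over angles
#'
#' @param tab A [ray_distance_table()] result.
#' @return A `data.frame` with min/max/mean/sd of `d_total_um` per time.
#' @export
ray_summary <- function(tab) {
  sp <- split(tab$d_total_um, tab$t_min)
  out <- data.frame(t_min = as.numeric(names(sp)),
                    d_min_um = vapply(sp, min, numeric(1)),
                    d_max_um = vapply(sp, max, numeric(1)),
                    d_mean_um = vapply(sp, mean, numeric(1)),
                    d_sd_um = vapply(sp, sd, numeric(1)))
  out <- out[order(out$t_min), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Recover the mean front speed from a ray-distance table
#'
#' Averages the cumulative rate `d_cum_rate` over all (angle, increment)
#' cells whose ray is still measuring an in-volume front: cells where the
#' total distance at either end of the increment exceeds `max_ray_um` for
#' that angle (front reaching the border of the field of view) are
#' discarded.
#'
#' @param tab A [ray_distance_table()] result.
#' @param max_ray_um Maximum trustworthy total distance, either a single
#'   value or one per angle (in `sort(unique(angle))` order). `Inf` keeps
#'   every cell.
#' @param projection Per-angle multiplier applied to the rate before
#'   averaging (in `sort(unique(angle))` order, recycled). For a planar
#'   front measured on a slice that contains the depth axis, a ray at
#'   angle `theta` from the surface meets the front at `depth/sin(theta)`,
#'   so `sin(theta * pi / 180)` projects each ray's rate onto the front
#'   normal. Default 1 (no projection).
#' @return Mean front speed in nm/s.
#' @export
estimate_front_speed <- function(tab, max_ray_um = Inf, projection = 1) {
  angles <- sort(unique(tab$angle_deg))
  lim <- rep_len(max_ray_um, length(angles))
  proj <- rep_len(projection, length(angles))
  names(lim) <- names(proj) <- as.character(angles)
  keep <- logical(nrow(tab))
  for (a in angles) {
    rows <- which(tab$angle_deg == a)
    rows <- rows[order(tab$t_min[rows])]
    d <- tab$d_total_um[rows]
    ok <- d <= lim[[as.character(a)]]
    keep[rows] <- ok & c(FALSE, ok[-length(ok)])  # both increment endpoints
  }
  rate <- tab$d_cum_rate_nm_s * proj[as.character(tab$angle_deg)]
  mean(rate[keep & !is.na(rate)])
}

#' Demineralised area per virtual slice
#'
#' Foreground voxel count per `xy` plane times the voxel area.
#'
#' @param mask A `lesion_mask` (or logical array) with voxel size.
#' @param voxel_um Required when `mask` is a bare array.
#' @return `data.frame` with `z`, `depth_um` (`(z - 1) * voxel_um`) and
#'   `area_um2`.
#' @export
area_per_slice <- function(mask, voxel_um = NULL) {
  if (inherits(mask, "lesion_mask") || inherits(mask, "enamel_mask")) {
    voxel_um <- mask$voxel_um; m <- mask$mask
  } else m <- mask
  if (is.null(voxel_um)) stop("voxel_um required for a bare array")
  d <- dim(m)
  counts <- rowSums(matrix(m, nrow = d[1]))
  data.frame(z = seq_len(d[1]), depth_um = (seq_len(d[1]) - 1) * voxel_um,
             area_um2 = counts * voxel_um^2)
}

#' Area-versus-depth profile of a lesion
#'
#' The per-slice demineralised area paired with the slice depth along `z`,
#' the standard depth profile of a lesion.
#'
#' @inheritParams area_per_slice
#' @return Same table as [area_per_slice()].
#' @export
area_vs_depth <- function(mask, voxel_um = NULL)
  area_per_slice(mask, voxel_um)

#' Area evolution, normalisations and rates per slice
#'
#' For each slice `z` and time `ti` derives: `area_fd = A(ti)/A(t0)`,
#' `area_abs_pct = (A(ti) - A(t0))/A(t0) * 100`,
#' `area_pct = (A(ti) - A(ti-1))/A(ti) * 100` (current-value denominator by
#' default, as printed), `area_fe_pct = A(ti)/A_tote * 100`,
#' `area_rate = (A(ti) - A(t0)) / (60 (ti - t0))` and
#' `area_crate = (A(ti) - A(ti-1)) / (60 (ti - ti-1))` in um^2/s.
#'
#' @param areas_um2 Matrix of demineralised areas, `nz x n_times` (um^2).
#' @param area_tote_um2 Total enamel area per slice (length `nz`, um^2).
#' @param times_min Acquisition times (minutes), reference first.
#' @param denominator Denominator for `area_pct`: `"current"` (printed
#'   convention), `"reference"` or `"previous"`.
#' @return Long `data.frame`, one row per (z, time).
#' @export
area_series <- function(areas_um2, area_tote_um2, times_min,
                        denominator = c("current", "reference",
                                        "previous")) {
  denominator <- match.arg(denominator)
  areas_um2 <- as.matrix(areas_um2)
  nz <- nrow(areas_um2); nT <- ncol(areas_um2)
  stopifnot(length(times_min) == nT, length(area_tote_um2) %in% c(1L, nz))
  if (nT > 1 && any(diff(times_min) <= 0))
    stop("times_min must be strictly increasing")
  area_tote_um2 <- rep_len(area_tote_um2, nz)
  warned <- FALSE
  rows <- lapply(seq_len(nz), function(z) {
    A <- areas_um2[z, ]
    fd <- abs_pct <- pct <- rep(NA_real_, nT)
    if (A[1L] > 0) {
      fd <- A / A[1L]
      abs_pct <- (A - A[1L]) / A[1L] * 100
    } else if (any(A > 0) && !warned) {
      warned <<- TRUE
      warning("Area(t0) = 0 for some slices; area_fd and area_abs_pct are NA there")
    }
    for (i in seq_len(nT)[-1L]) {
      den <- .pct_denom(A, i, denominator)
      if (!is.na(den) && den != 0) pct[i] <- (A[i] - A[i - 1L]) / den * 100
    }
    dt0 <- (times_min - times_min[1L]) * 60
    dti <- c(NA_real_, diff(times_min)) * 60
    data.frame(z = z, t_min = times_min, area_um2 = A,
               area_tote_um2 = area_tote_um2[z],
               area_fd = fd, area_abs_pct = abs_pct, area_pct = pct,
               area_fe_pct = A / area_tote_um2[z] * 100,
               area_rate_um2_s = ifelse(dt0 > 0, (A - A[1L]) / dt0, NA_real_),
               area_crate_um2_s = c(NA_real_, diff(A)) / dti)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Lesion volume
#'
#' Foreground voxel count times the voxel volume.
#'
#' @inheritParams area_per_slice
#' @return Volume in cubic micrometres.
#' @export
lesion_volume <- function(mask, voxel_um = NULL) {
  if (inherits(mask, "lesion_mask") || inherits(mask, "enamel_mask")) {
    voxel_um <- mask$voxel_um; m <- mask$mask
  } else m <- mask
  if (is.null(voxel_um)) stop("voxel_um required for a bare array")
  sum(m) * voxel_um^3
}

#' Volume evolution, normalisations and rates
#'
#' Derives `v_f = V(ti)/V(t0)`, `vol_pct = (V(ti) - V(t0))/V(ti) * 100`
#' (current-value denominator by default, as printed),
#' `v_fe = V(ti)/V_tote` (a ratio, not a percentage),
#' `v_rate_abs = (V(ti) - V(t0)) / (60 (ti - t0))` and
#' `v_crate = (V(ti) - V(ti-1)) / (60 (ti - ti-1))` in um^3/s, plus the
#' same rates in nm^3/s (x 1e9).
#'
#' @param v_um3 Lesion volume per time point (um^3), reference first.
#' @param v_tote_um3 Total enamel volume (um^3).
#' @param times_min Acquisition times (minutes).
#' @param denominator Denominator for `vol_pct`: `"current"` (printed
#'   convention), `"reference"` or `"previous"`.
#' @return `data.frame`, one row per time point.
#' @export
volume_series <- function(v_um3, v_tote_um3, times_min,
                          denominator = c("current", "reference",
                                          "previous")) {
  denominator <- match.arg(denominator)
  n <- length(v_um3)
  stopifnot(length(times_min) == n)
  if (n > 1 && any(diff(times_min) <= 0))
    stop("times_min must be strictly increasing")
  V <- as.numeric(v_um3)
  v_f <- rep(NA_real_, n)
  if (V[1L] > 0) v_f <- V / V[1L]
  else if (any(V > 0))
    warning("V(t0) = 0; v_f is NA")
  vol_pct <- rep(NA_real_, n); vol_pct[1L] <- if (V[1L] > 0) 0 else NA_real_
  for (i in seq_len(n)[-1L]) {
    den <- .pct_denom(V, i, denominator)
    if (!is.na(den) && den != 0) vol_pct[i] <- (V[i] - V[1L]) / den * 100
  }
  dt0 <- (times_min - times_min[1L]) * 60
  dti <- c(NA_real_, diff(times_min)) * 60
  out <- data.frame(
    t_min = times_min, v_um3 = V, v_f = v_f, vol_pct = vol_pct,
    v_fe = V / v_tote_um3,
    v_rate_abs_um3_s = ifelse(dt0 > 0, (V - V[1L]) / dt0, NA_real_),
    v_crate_um3_s = c(NA_real_, diff(V)) / dti)
  out$v_rate_abs_nm3_s <- out$v_rate_abs_um3_s * 1e9
  out$v_crate_nm3_s <- out$v_crate_um3_s * 1e9
  out
}

#' Exact 3D Euclidean distance transform
#'
#' For every foreground voxel, the exact Euclidean distance (um, voxel
#' centre to voxel centre) to the nearest background voxel; background
#' voxels map to 0. Only background inside the volume counts (a half-space
#' mask therefore has an exactly linear depth profile); in the degenerate
#' all-foreground case, where no background exists, the outside of the
#' volume is treated as background and the map holds distances to the
#' border.
#'
#' @param mask Logical 3D array (or mask object).
#' @param voxel_um Voxel size (um); taken from the object when available.
#' @return 3D numeric array of distances in micrometres.
#' @export
edt3d <- function(mask, voxel_um = NULL) {
  if (inherits(mask, "lesion_mask") || inherits(mask, "enamel_mask")) {
    voxel_um <- mask$voxel_um; m <- mask$mask
  } else m <- mask
  if (is.null(voxel_um)) stop("voxel_um required for a bare array")
  d <- dim(m)
  if (any(!m)) {
    sq <- array(cpp_edt3d_sq(as.vector(m), d[1], d[2], d[3]), dim = d)
    return(sqrt(sq) * voxel_um)
  }
  padded <- array(FALSE, dim = d + 2L)
  padded[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- m
  dp <- dim(padded)
  sq <- array(cpp_edt3d_sq(as.vector(padded), dp[1], dp[2], dp[3]), dim = dp)
  sqrt(sq[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]) * voxel_um
}

# Vectorised trilinear sampling at fractional (z, y, x) positions (1-based).
sample_trilinear <- function(vol, pts) {
  d <- dim(vol)
  z <- pts[, 1]; y <- pts[, 2]; x <- pts[, 3]
  z0 <- pmin(pmax(floor(z), 1), d[1] - 1); fz <- z - z0
  y0 <- pmin(pmax(floor(y), 1), d[2] - 1); fy <- y - y0
  x0 <- pmin(pmax(floor(x), 1), d[3] - 1); fx <- x - x0
  g <- function(zi, yi, xi) vol[cbind(zi, yi, xi)]
  c00 <- g(z0, y0, x0) * (1 - fz) + g(z0 + 1, y0, x0) * fz
  c10 <- g(z0, y0 + 1, x0) * (1 - fz) + g(z0 + 1, y0 + 1, x0) * fz
  c01 <- g(z0, y0, x0 + 1) * (1 - fz) + g(z0 + 1, y0, x0 + 1) * fz
  c11 <- g(z0, y0 + 1, x0 + 1) * (1 - fz) + g(z0 + 1, y0 + 1, x0 + 1) * fz
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fx) + c1 * fx
}

#' Grey-value line profile between two points
#'
#' Trilinear intensity samples at equally spaced positions along a segment;
#' used e.g. to measure the width of the brighter surface zone.
#'
#' @param frame A [volume_frame()].
#' @param p0,p1 Endpoints as `(z, y, x)` voxel coordinates (1-based),
#'   inside the volume.
#' @param n_samples Number of samples (>= 2).
#' @return `data.frame` with `position_um` (distance from `p0`) and
#'   `intensity`.
#' @export
line_profile <- function(frame, p0, p1, n_samples = 100L) {
  stopifnot(inherits(frame, "volume_frame"), n_samples >= 2L,
            length(p0) == 3L, length(p1) == 3L)
  d <- dim(frame$data)
  for (p in list(p0, p1))
    if (any(p < 1) || any(p > d)) stop("profile endpoint outside the volume")
  ts <- seq(0, 1, length.out = n_samples)
  pts <- cbind(p0[1] + ts * (p1[1] - p0[1]),
               p0[2] + ts * (p1[2] - p0[2]),
               p0[3] + ts * (p1[3] - p0[3]))
  data.frame(position_um = ts * sqrt(sum((p1 - p0)^2)) * frame$voxel_um,
             intensity = sample_trilinear(frame$data, pts))
}
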