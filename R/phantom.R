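# Label codes shared by the phantom generator and its consumers.
PHANTOM_LABELS <- c(liquid = 0L, rod = 1L, interrod = 2L, surface_zone = 3L)

# Run `expr` with a private RNG state derived from `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

#' Parameterise a synthetic dissolving-enamel phantom
#'
#' The phantom emulates a time-lapse tomography experiment on an enamel
#' block exposed to acid: a hexagonal lattice of ~5 um rods embedded in
#' ~2 um inter-rod substance (rod axes along `z`), an optional denser
#' surface zone at the exposed face, liquid above the face, and a circular
#' varnish window through which the dissolution front enters. The front
#' advances with a per-material speed (nm/s), so setting
#' `speed_interrod_nm_s > speed_rod_nm_s` reproduces preferential
#' demineralisation of the inter-rod substance. Rendering adds per-class
#' intensities, Gaussian noise, small rigid jitter between time points and
#' optional bubble artifacts in the liquid.
#'
#' Default speeds sit inside the 0.54-5.58 nm/s range reported for enamel
#' dissolution in lactic acid at pH 2.2.
#'
#' @param shape_voxels `(nz, ny, nx)` volume shape; `z` is depth.
#' @param voxel_um Isotropic voxel size (default 0.325 um).
#' @param rod_diameter_um,interrod_width_um Rod diameter and inter-rod gap.
#' @param surface_zone_um Thickness of the denser surface zone (0 disables).
#' @param liquid_um Thickness of the liquid layer above the enamel face.
#' @param window_radius_um Radius of the exposed circular window; anything
#'   larger than the face half-diagonal exposes the whole face; 0 seals it.
#' @param speed_rod_nm_s,speed_interrod_nm_s,speed_surface_zone_nm_s Front
#'   speeds (nm/s) per material; 0 blocks propagation through that material.
#' @param class_means Intensity in `[0, 1]` per material (`liquid`, `rod`,
#'   `interrod`, `surface_zone`, `demineralised`, `bubble`).
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param jitter_translation_voxels,jitter_rotation_deg Magnitudes of the
#'   per-frame rigid jitter (uniform in `[-m, m]` per component); the first
#'   frame is never jittered.
#' @param bubble_count Number of random ellipsoidal bubbles in the liquid.
#' @param times_min Strictly increasing acquisition times in minutes from
#'   the start of acid exposure (default `122 + 25 * 0:7`, i.e. a first
#'   tomogram at t0 = 122 min and ~25 min spacing).
#' @param rod_jitter_um Positional jitter of rod centres (0 = perfect
#'   lattice).
#' @param rng_seed Seed making the whole series reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape_voxels = c(96L, 96L, 96L),
                         voxel_um = 0.325,
                         rod_diameter_um = 5,
                         interrod_width_um = 2,
                         surface_zone_um = 3,
                         liquid_um = 3,
                         window_radius_um = 10,
                         speed_rod_nm_s = 1,
                         speed_interrod_nm_s = 2,
                         speed_surface_zone_nm_s = 0.5,
                         class_means = list(liquid = 0.08, rod = 0.72,
                                            interrod = 0.68,
                                            surface_zone = 0.80,
                                            demineralised = 0.30,
                                            bubble = 0.02),
                         noise_sd = 0.05,
                         jitter_translation_voxels = 2,
                         jitter_rotation_deg = 1,
                         bubble_count = 0L,
                         times_min = 122 + 25 * (0:7),
                         rod_jitter_um = 0,
                         rng_seed = 1L) {
  shape_voxels <- as.integer(shape_voxels)
  stopifnot(length(shape_voxels) == 3L, all(shape_voxels > 0L))
  for (v in c(voxel_um, rod_diameter_um, interrod_width_um))
    if (v <= 0) stop("voxel_um, rod_diameter_um and interrod_width_um must be positive")
  for (v in c(surface_zone_um, liquid_um, window_radius_um, speed_rod_nm_s,
              speed_interrod_nm_s, speed_surface_zone_nm_s, noise_sd,
              jitter_translation_voxels, jitter_rotation_deg, rod_jitter_um))
    if (v < 0) stop("lengths, speeds, noise and jitter magnitudes must be nonnegative")
  if (length(times_min) < 1L || (length(times_min) > 1L && any(diff(times_min) <= 0)))
    stop("times_min must be strictly increasing")
  need <- c("liquid", "rod", "interrod", "surface_zone", "demineralised")
  if (!all(need %in% names(class_means)))
    stop("class_means must name: ", paste(need, collapse = ", "))
  if (is.null(class_means$bubble)) class_means$bubble <- 0.02
  en <- unlist(class_means[c("rod", "interrod", "surface_zone")])
  if (any(abs(en - class_means$demineralised) < 1e-6) ||
      any(abs(en - class_means$liquid) < 1e-6) ||
      abs(class_means$demineralised - class_means$liquid) < 1e-6)
    stop("class means for enamel, demineralised and liquid must be distinct")
  structure(list(shape_voxels = shape_voxels, voxel_um = voxel_um,
                 rod_diameter_um = rod_diameter_um,
                 interrod_width_um = interrod_width_um,
                 surface_zone_um = surface_zone_um, liquid_um = liquid_um,
                 window_radius_um = window_radius_um,
                 speed_rod_nm_s = speed_rod_nm_s,
                 speed_interrod_nm_s = speed_interrod_nm_s,
                 speed_surface_zone_nm_s = speed_surface_zone_nm_s,
                 class_means = class_means, noise_sd = noise_sd,
                 jitter_translation_voxels = jitter_translation_voxels,
                 jitter_rotation_deg = jitter_rotation_deg,
                 bubble_count = as.integer(bubble_count),
                 times_min = as.numeric(times_min),
                 rod_jitter_um = rod_jitter_um,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

# Areal rod fraction of the ideal hexagonal lattice (analytic).
hex_rod_fraction <- function(rod_diameter_um, interrod_width_um) {
  a <- rod_diameter_um + interrod_width_um
  pi * rod_diameter_um^2 / (2 * sqrt(3) * a^2)
}

#' Build the phantom's material label volume
#'
#' Lays out cylindrical rods (axes along `z`) on a hexagonal lattice with
#' centre spacing `rod_diameter_um + interrod_width_um`, fills the gaps with
#' inter-rod substance, adds the surface-zone slab at the exposed face and
#' the liquid layer above it. The exposed-window voxel set (acid entry
#' points) is attached to the result.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `label_volume`: integer array `labels`
#'   (`0` liquid, `1` rod, `2` interrod, `3` surface zone), `voxel_um`, and
#'   `source_idx` (1-based linear indices of the exposed window voxels).
#' @export
build_microstructure <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape_voxels; nz <- d[1]; ny <- d[2]; nx <- d[3]
  vx <- spec$voxel_um
  a <- spec$rod_diameter_um + spec$interrod_width_um
  min_ny <- ceiling(sqrt(3) * a / vx); min_nx <- ceiling(a / vx)
  if (ny * vx < sqrt(3) * a || nx * vx < a)
    stop(sprintf(paste0("volume too small for one rod period: need at least ",
                        "%d (y) x %d (x) voxels at %.3g um/voxel"),
                 min_ny, min_nx, vx))
  # rod centres on a hexagonal lattice covering the face (with one extra
  # period of margin), optionally jittered
  ext_y <- ny * vx; ext_x <- nx * vx
  jj <- seq(-1L, ceiling(ext_y / (sqrt(3) / 2 * a)) + 1L)
  ii <- seq(-1L, ceiling(ext_x / a) + 1L)
  cen <- expand.grid(j = jj, i = ii)
  cy <- cen$j * sqrt(3) / 2 * a
  cx <- (cen$i + (cen$j %% 2) / 2) * a
  if (spec$rod_jitter_um > 0) {
    jit <- with_seed(spec$rng_seed + 101L,
                     matrix(runif(2L * nrow(cen), -spec$rod_jitter_um,
                                  spec$rod_jitter_um), ncol = 2L))
    cy <- cy + jit[, 1L]; cx <- cx + jit[, 2L]
  }
  yy <- (seq_len(ny) - 1) * vx
  xx <- (seq_len(nx) - 1) * vx
  ym <- matrix(yy, ny, nx); xm <- matrix(xx, ny, nx, byrow = TRUE)
  mind2 <- matrix(Inf, ny, nx)
  for (k in seq_along(cy)) {
    d2 <- (ym - cy[k])^2 + (xm - cx[k])^2
    mind2 <- pmin(mind2, d2)
  }
  rod2d <- mind2 <= (spec$rod_diameter_um / 2)^2
  enamel2d <- ifelse(rod2d, PHANTOM_LABELS[["rod"]], PHANTOM_LABELS[["interrod"]])

  nliq <- round(spec$liquid_um / vx)
  nsz <- round(spec$surface_zone_um / vx)
  if (nliq + nsz >= nz) stop("liquid + surface zone thicker than the volume")
  labels <- array(PHANTOM_LABELS[["liquid"]], dim = d)
  z_sz <- seq_len(nsz) + nliq
  z_en <- seq((nliq + nsz + 1L), nz)
  for (z in z_sz) labels[z, , ] <- PHANTOM_LABELS[["surface_zone"]]
  for (z in z_en) labels[z, , ] <- enamel2d

  # exposed circular window on the first non-liquid layer
  cy0 <- (ny - 1) / 2 * vx; cx0 <- (nx - 1) / 2 * vx
  win2d <- (ym - cy0)^2 + (xm - cx0)^2 <= spec$window_radius_um^2
  z_top <- nliq + 1L
  source_idx <- if (any(win2d) && spec$window_radius_um > 0) {
    which_yx <- which(win2d)          # linear over (y, x)
    y_i <- ((which_yx - 1L) %% ny) + 1L
    x_i <- ((which_yx - 1L) %/% ny) + 1L
    (z_top - 1L) + nz * ((y_i - 1L) + ny * (x_i - 1L)) + 1L
  } else integer(0)
  structure(list(labels = labels, voxel_um = vx, source_idx = source_idx,
                 spec = spec),
            class = "label_volume")
}

#' Simulate first-arrival times of the dissolution front
#'
#' Models the advancing demineralisation front as weighted geodesic
#' propagation from the exposed window: each material has a speed (nm/s) and
#' the arrival time at a voxel is the fastest travel time over the
#' 26-connected voxel graph with Euclidean edge lengths (Dijkstra, which
#' converges to the continuous first-arrival solution as the voxel size
#' shrinks). Liquid never demineralises; a zero speed blocks a material.
#'
#' @param labels A [build_microstructure()] result.
#' @param spec The same [phantom_spec()].
#' @param connectivity 26 (default) or 6.
#' @return An object of class `arrival_field`: `tau_min` (3D array of
#'   first-arrival times in minutes, `Inf` = never reached), `voxel_um`,
#'   `source_idx`.
#' @export
simulate_arrival_times <- function(labels, spec, connectivity = 26L) {
  stopifnot(inherits(labels, "label_volume"), inherits(spec, "phantom_spec"))
  d <- dim(labels$labels)
  speeds <- c(NA, spec$speed_rod_nm_s, spec$speed_interrod_nm_s,
              spec$speed_surface_zone_nm_s)  # index = label + 1
  # nm/s -> minutes per micrometre of travel
  slow_of <- function(v) if (is.na(v) || v <= 0) Inf else 1000 / (v * 60)
  slow_by_label <- vapply(speeds, slow_of, numeric(1))
  slowness <- array(slow_by_label[labels$labels + 1L], dim = d)
  tau <- cpp_dijkstra_arrival(as.numeric(slowness), d[1], d[2], d[3],
                              as.integer(labels$source_idx - 1L),
                              labels$voxel_um, connectivity == 26L)
  tau <- array(tau, dim = d)
  structure(list(tau_min = tau, voxel_um = labels$voxel_um,
                 source_idx = labels$source_idx),
            class = "arrival_field")
}

#' Ground-truth lesion mask at a given time
#'
#' The lesion at time `t` is exactly the set of voxels the front has
#' reached: `tau <= t`. Masks are therefore nested in time by construction.
#'
#' @param arrival An [simulate_arrival_times()] result.
#' @param t_min Time in minutes (>= 0).
#' @param frame_id Optional frame id to attach.
#' @return A `lesion_mask` (logical array + metadata).
#' @export
lesion_truth_at <- function(arrival, t_min, frame_id = NA_integer_) {
  stopifnot(inherits(arrival, "arrival_field"), t_min >= 0)
  mask <- arrival$tau_min <= t_min
  new_lesion_mask(mask, voxel_um = arrival$voxel_um, t_min = t_min,
                  frame_id = frame_id)
}

new_lesion_mask <- function(mask, voxel_um, t_min = NA_real_,
                            frame_id = NA_integer_) {
  structure(list(mask = mask, voxel_um = voxel_um, t_min = t_min,
                 frame_id = frame_id),
            class = "lesion_mask")
}

#' Render one synthetic tomogram frame
#'
#' Paints each voxel with its class mean intensity, overrides lesion voxels
#' with the demineralised mean, optionally adds ellipsoidal bubbles in the
#' liquid, applies the per-frame rigid jitter (frame 1 is the unjittered
#' reference) and finally adds Gaussian noise. All random draws come from a
#' generator seeded deterministically by `spec$rng_seed` and `frame_index`,
#' so re-rendering is bit-identical. Jitter affects only the rendered frame,
#' never the ground-truth masks, which live on the reference grid.
#'
#' @param labels A [build_microstructure()] result.
#' @param lesion The ground-truth `lesion_mask` for this time point.
#' @param spec The [phantom_spec()].
#' @param frame_index 1-based index into `spec$times_min`.
#' @return A [volume_frame()]; the applied jitter is attached as
#'   `attr(, "jitter")` (a [rigid_transform3d()]).
#' @export
render_frame <- function(labels, lesion, spec, frame_index) {
  stopifnot(inherits(labels, "label_volume"), inherits(lesion, "lesion_mask"),
            frame_index >= 1L, frame_index <= length(spec$times_min))
  if (!identical(dim(lesion$mask), dim(labels$labels)))
    stop("lesion mask shape does not match the label volume")
  d <- dim(labels$labels)
  cm <- spec$class_means
  mean_by_label <- c(cm$liquid, cm$rod, cm$interrod, cm$surface_zone)
  vol <- array(mean_by_label[labels$labels + 1L], dim = d)
  vol[lesion$mask] <- cm$demineralised
  jit <- rigid_transform3d()
  with_seed(spec$rng_seed + 7919L * frame_index, {
    if (spec$bubble_count > 0L) {
      liquid <- labels$labels == PHANTOM_LABELS[["liquid"]]
      zl <- which(apply(liquid, 1L, any))
      for (b in seq_len(spec$bubble_count)) {
        ctr <- c(runif(1, min(zl), max(zl)), runif(1, 1, d[2]), runif(1, 1, d[3]))
        sem <- runif(3, 1, 3) / spec$voxel_um  # 1-3 um semi-axes, in voxels
        zi <- seq_len(d[1]); yi <- seq_len(d[2]); xi <- seq_len(d[3])
        e <- outer(outer((zi - ctr[1])^2 / sem[1]^2,
                         (yi - ctr[2])^2 / sem[2]^2, "+"),
                   (xi - ctr[3])^2 / sem[3]^2, "+") <= 1
        vol[e & liquid] <- cm$bubble
      }
    }
    if (frame_index > 1L &&
        (spec$jitter_translation_voxels > 0 || spec$jitter_rotation_deg > 0)) {
      ang <- runif(3, -spec$jitter_rotation_deg, spec$jitter_rotation_deg)
      trn <- runif(3, -spec$jitter_translation_voxels,
                   spec$jitter_translation_voxels)
      jit <- rigid_transform3d(rotation_deg = ang, translation_voxels = trn)
      vol <- resample_rigid_array(vol, jit, fill = "replicate")
    }
    if (spec$noise_sd > 0)
      vol <- vol + rnorm(length(vol), 0, spec$noise_sd)
  })
  vol <- array(pmin(pmax(vol, 0), 1), dim = d)
  fr <- volume_frame(vol, voxel_um = spec$voxel_um,
                     t_min = spec$times_min[frame_index],
                     frame_id = frame_index)
  attr(fr, "jitter") <- jit
  fr
}

#' Generate a full synthetic time-lapse series on disk
#'
#' Writes one 16-bit multi-page TIFF per entry of `spec$times_min`, the
#' matching 8-bit ground-truth lesion masks, the arrival-time field, the
#' spec itself and a YAML manifest. Reruns with the same spec produce
#' byte-identical outputs.
#'
#' @param spec A [phantom_spec()].
#' @param out_dir Output directory (created if needed).
#' @return The [time_series_manifest()], invisibly, with attributes
#'   `truth_paths`, `arrival` and `manifest_path`.
#' @export
generate_series <- function(spec, out_dir) {
  stopifnot(inherits(spec, "phantom_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  labels <- build_microstructure(spec)
  arrival <- simulate_arrival_times(labels, spec)
  nT <- length(spec$times_min)
  frame_paths <- file.path(out_dir, sprintf("frame_%02d.tif", seq_len(nT)))
  truth_paths <- file.path(out_dir, sprintf("truth_%02d.tif", seq_len(nT)))
  for (i in seq_len(nT)) {
    truth <- lesion_truth_at(arrival, spec$times_min[i], frame_id = i)
    frame <- render_frame(labels, truth, spec, i)
    write_stack(frame, frame_paths[i], bits = 16L)
    write_stack(truth$mask, truth_paths[i], bits = 8L)
  }
  write_arrival(arrival, file.path(out_dir, "arrival.tif"))
  yaml::write_yaml(unclass(spec)[setdiff(names(spec), "class_means")],
                   file.path(out_dir, "phantom_spec.yaml"))
  yaml::write_yaml(spec$class_means,
                   file.path(out_dir, "phantom_class_means.yaml"))
  man <- time_series_manifest(
    data.frame(path = frame_paths, t_min = spec$times_min,
               frame_id = seq_len(nT)),
    voxel_um = spec$voxel_um, reference_index = 1L, base_dir = out_dir)
  man_path <- file.path(out_dir, "manifest.yaml")
  write_manifest(man, man_path)
  attr(man, "truth_paths") <- truth_paths
  attr(man, "arrival") <- arrival
  attr(man, "manifest_path") <- man_path
  invisible(man)
}

#' Write / read an arrival-time field
#'
#' Finite arrival times are scaled into `[0, 0.9]` and stored as 16-bit
#' TIFF; unreachable voxels map to 1.0. The scale is kept in a JSON sidecar.
#'
#' @param arrival An `arrival_field`.
#' @param path Output `.tif` path; the sidecar is `path` + `.json`.
#' @return `path`, invisibly.
#' @export
write_arrival <- function(arrival, path) {
  tau <- arrival$tau_min
  fin <- is.finite(tau)
  scale <- if (any(fin)) max(tau[fin]) else 1
  if (scale <= 0) scale <- 1
  enc <- array(1, dim = dim(tau))
  enc[fin] <- 0.9 * tau[fin] / scale
  write_stack(enc, path, bits = 16L)
  jsonlite::write_json(list(tau_scale_min = scale,
                            voxel_um = arrival$voxel_um),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_arrival
#' @export
read_arrival <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  enc <- read_stack(path)$data
  tau <- array(Inf, dim = dim(enc))
  fin <- enc <= 0.95
  tau[fin] <- enc[fin] / 0.9 * meta$tau_scale_min
  structure(list(tau_min = tau, voxel_um = meta$voxel_um,
                 source_idx = integer(0)),
            class = "arrival_field")
}
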