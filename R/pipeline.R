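#' Default pipeline configuration
#'
#' Returns the full configuration list understood by [run_pipeline()];
#' override any entry by passing a partial list (or a YAML file with the
#' same structure) to `run_pipeline()`. Exactly one of `phantom` (a list of
#' [phantom_spec()] arguments, generating a synthetic series into the run
#' directory) or `manifest` (path to an existing series manifest) must be
#' set.
#'
#' @return Nested configuration list.
#' @export
default_run_config <- function() {
  list(
    phantom = NULL,
    manifest = NULL,
    preprocess = list(median_radius = 1L, nlm_h = 0.04, nlm_patch = 1L,
                      nlm_search = 1L),
    register = list(enabled = TRUE, levels = c(4L, 2L, 1L), ncc_min = 0.2,
                    force = FALSE, exclude_below_z = NULL),
    segment = list(enamel_mode = "auto", enamel_value = NULL,
                   lesion_mode = "auto", lesion_k = 3, lesion_value = NULL,
                   opening_radius = 1L, nesting_warn_frac = 0.05),
    roi_margin_voxels = 0L,
    seeds = NULL,          # NULL = one central depth-fan seed (zy plane)
    angles_deg = seq(70, 110, by = 5),
    denominator = "current",
    rng_seed = 1L)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the full demineralisation quantification pipeline
#'
#' Orchestrates one reproducible run: load (or synthesise) the time series,
#' denoise every frame (median, then non-local means), rigidly register
#' each frame to the reference time point, segment the enamel mask (on the
#' reference) and the lesion mask (per frame), and compute the volume,
#' per-slice area and per-angle radial distance tables. All masks, tables,
#' transforms, the effective configuration, a log and an md5 checksum
#' manifest are written under `out_dir`; given the same configuration and
#' seed the run is deterministic.
#'
#' @param config Partial configuration list or path to a YAML file; see
#'   [default_run_config()].
#' @param out_dir Run output directory (created).
#' @param verbose Print per-stage progress.
#' @return A list of class `pipeline_run`: manifest, enamel mask, lesion
#'   masks, transforms, the four result tables, paths, and the log.
#' @export
run_pipeline <- function(config = list(), out_dir, verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_run_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  logmsg <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    if (verbose) message(line)
  }
  stage <- function(name, frame_id, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed at frame %s: %s", name,
                   format(frame_id), conditionMessage(e)), call. = FALSE))
  }
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))],
                   file.path(out_dir, "config.yaml"))

  # ---- input series ----
  if (!is.null(cfg$phantom)) {
    spec <- do.call(phantom_spec, cfg$phantom)
    logmsg("generating phantom series (%s voxels, %d frames)",
           paste(spec$shape_voxels, collapse = "x"), length(spec$times_min))
    man <- stage("generate", NA, generate_series(spec,
                                                 file.path(out_dir, "input")))
  } else if (!is.null(cfg$manifest)) {
    man <- stage("load", NA, load_manifest(cfg$manifest))
  } else stop("config must set either `phantom` or `manifest`")
  nT <- nrow(man$frames)
  ref_i <- man$reference_index
  times <- man$frames$t_min

  # ---- preprocess: filter every frame ----
  pp <- cfg$preprocess
  frames <- vector("list", nT)
  for (i in seq_len(nT)) {
    fr <- stage("read", i, read_stack(man$frames$path[i],
                                      voxel_um = man$voxel_um,
                                      t_min = times[i], frame_id = i))
    fr <- stage("filter", i, {
      if (pp$median_radius >= 1) fr <- median_filter3d(fr, pp$median_radius)
      if (pp$nlm_h > 0) fr <- nlm_denoise(fr, pp$nlm_h, pp$nlm_patch,
                                          pp$nlm_search)
      fr
    })
    frames[[i]] <- fr
    logmsg("frame %d filtered (t = %s min)", i, format(times[i]))
  }

  # ---- registration to the reference time point ----
  transforms <- rep(list(rigid_transform3d()), nT)
  if (isTRUE(cfg$register$enabled)) {
    excl <- NULL
    if (!is.null(cfg$register$exclude_below_z)) {
      # the demineralising zone violates the intensity-constancy assumption;
      # mask it out of the similarity measure (the liquid and the fixed
      # liquid/enamel surface edge above the cutoff anchor the alignment)
      dref <- dim(frames[[ref_i]]$data)
      excl <- array(FALSE, dim = dref)
      zcut <- min(max(as.integer(cfg$register$exclude_below_z), 1L), dref[1])
      excl[zcut:dref[1], , ] <- TRUE
    }
    for (i in setdiff(seq_len(nT), ref_i)) {
      reg <- stage("register", i,
                   register_rigid(frames[[i]], frames[[ref_i]],
                                  levels = cfg$register$levels,
                                  exclude_mask = excl,
                                  ncc_min = cfg$register$ncc_min))
      if (!reg$converged && !isTRUE(cfg$register$force))
        stop(sprintf(paste0("stage 'register' failed at frame %d: NCC %.3f ",
                            "below %.3f (set register$force to proceed)"),
                     i, reg$ncc, cfg$register$ncc_min), call. = FALSE)
      transforms[[i]] <- reg$transform
      frames[[i]] <- stage("resample", i,
                           apply_transform(frames[[i]], reg$transform))
      logmsg("frame %d registered (NCC = %.4f)", i, reg$ncc)
    }
  }
  jsonlite::write_json(
    lapply(transforms, function(tf) list(rotation_deg = tf$rotation_deg,
                                         translation_voxels =
                                           tf$translation_voxels)),
    file.path(out_dir, "transforms.json"), digits = NA)

  # ---- segmentation ----
  sg <- cfg$segment
  epol <- if (identical(sg$enamel_mode, "fixed"))
    enamel_policy("fixed", sg$enamel_value) else enamel_policy("auto")
  enamel <- stage("segment", ref_i, segment_enamel(frames[[ref_i]], epol))
  logmsg("enamel mask: %d voxels (threshold %.4f)", sum(enamel$mask),
         enamel$threshold)
  lpol <- lesion_policy(mode = if (identical(sg$lesion_mode, "fixed"))
                          "fixed" else "auto",
                        k = sg$lesion_k, value = sg$lesion_value,
                        opening_radius = sg$opening_radius,
                        nesting_warn_frac = sg$nesting_warn_frac)
  dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
  lesions <- vector("list", nT)
  prev <- NULL
  for (i in seq_len(nT)) {
    lesions[[i]] <- withCallingHandlers(
      stage("segment", i, segment_lesion(frames[[i]], enamel, lpol,
                                         reference = frames[[ref_i]],
                                         previous = prev)),
      warning = function(w) {
        logmsg("warning: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    prev <- lesions[[i]]
    write_stack(lesions[[i]]$mask,
                file.path(out_dir, "masks", sprintf("lesion_%02d.tif", i)),
                bits = 8L)
    logmsg("frame %d lesion: %d voxels", i, sum(lesions[[i]]$mask))
  }
  write_stack(enamel$mask, file.path(out_dir, "masks", "enamel.tif"),
              bits = 8L)

  # ---- metrics on a central region of interest ----
  d <- dim(enamel$mask)
  m <- as.integer(cfg$roi_margin_voxels)
  roi <- array(FALSE, dim = d)
  roi[(1 + m):(d[1] - m), (1 + m):(d[2] - m), (1 + m):(d[3] - m)] <- TRUE
  en_roi <- enamel$mask & roi
  v_tote <- sum(en_roi) * man$voxel_um^3
  tote_slice <- area_per_slice(en_roi, man$voxel_um)$area_um2
  vols <- vapply(lesions, function(l) sum(l$mask & roi) * man$voxel_um^3,
                 numeric(1))
  vol_tab <- volume_series(vols, v_tote, times,
                           denominator = cfg$denominator)
  areas <- vapply(lesions, function(l)
    area_per_slice(l$mask & roi, man$voxel_um)$area_um2,
    numeric(d[1]))
  area_tab <- area_series(areas, tote_slice, times,
                          denominator = cfg$denominator)

  seeds <- cfg$seeds
  if (is.null(seeds)) {
    zs <- which(apply(enamel$mask, 1L, any))[1L]
    seeds <- list(list(plane = "zy", z = zs, y = round(d[2] / 2),
                       x = round(d[3] / 2), angles_deg = cfg$angles_deg))
  }
  ray_tab <- do.call(rbind, lapply(seq_along(seeds), function(si) {
    s <- seeds[[si]]
    sp <- seed_spec(s$z, s$y, s$x, s$angles_deg)
    tab <- stage("metrics", NA,
                 ray_distance_table(lesions, sp,
                                    plane = if (is.null(s$plane)) "xy"
                                            else s$plane,
                                    denominator = cfg$denominator))
    cbind(seed = si, tab)
  }))
  ray_sum <- ray_summary(ray_tab)

  dir.create(file.path(out_dir, "tables"), showWarnings = FALSE)
  tabs <- list(volume_series = vol_tab, area_series = area_tab,
               ray_distances = ray_tab, ray_summary = ray_sum)
  for (nm in names(tabs))
    write.csv(tabs[[nm]], file.path(out_dir, "tables", paste0(nm, ".csv")),
              row.names = FALSE)
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "run_manifest.json"))
  sums <- tools::md5sum(files)
  names(sums) <- substring(files, nchar(out_dir) + 2L)
  jsonlite::write_json(as.list(sums), file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE)

  structure(list(out_dir = out_dir, manifest = man, enamel = enamel,
                 lesions = lesions, transforms = transforms, tables = tabs,
                 roi = roi, config = cfg, log = log_lines),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d frames -> %s\n", length(x$lesions),
              x$out_dir))
  cat(sprintf("  lesion volume: %.1f -> %.1f um^3\n",
              x$tables$volume_series$v_um3[1],
              utils::tail(x$tables$volume_series$v_um3, 1)))
  invisible(x)
}

#' End-to-end recovery demonstration on a homogeneous phantom
#'
#' Generates a small homogeneous dissolving-enamel phantom with a known
#' front speed (fully exposed face, flat front), runs the complete pipeline
#' (render with noise and jitter, denoise, register, segment, measure) and
#' reports the configured versus recovered front speed, where the recovered
#' speed is the mean cumulative distance rate over a fan of rays around the
#' depth axis.
#'
#' @param seed RNG seed for the phantom.
#' @param fast Use a smaller grid and fewer frames.
#' @param out_dir Output directory (default: under `tempdir()`).
#' @param speed_nm_s Configured front speed (nm/s).
#' @param verbose Print pipeline progress.
#' @return Invisibly, a list with `configured_nm_s`, `recovered_nm_s`,
#'   `ratio` and the `pipeline_run`.
#' @export
run_demo <- function(seed = 1L, fast = FALSE,
                     out_dir = file.path(tempdir(), "demintrack-demo"),
                     speed_nm_s = 2.0, verbose = TRUE) {
  shape <- if (fast) c(48L, 48L, 48L) else c(64L, 96L, 96L)
  nT <- if (fast) 5L else 8L
  times <- seq(10, by = 20, length.out = nT)
  cm <- list(liquid = 0.08, rod = 0.72, interrod = 0.68, surface_zone = 0.80,
             demineralised = 0.30, bubble = 0.02)
  cfg <- list(
    phantom = list(shape_voxels = shape, surface_zone_um = 0,
                   liquid_um = 2.6, window_radius_um = 1e3,
                   speed_rod_nm_s = speed_nm_s,
                   speed_interrod_nm_s = speed_nm_s,
                   speed_surface_zone_nm_s = speed_nm_s,
                   class_means = cm, noise_sd = 0.04,
                   jitter_translation_voxels = 1.5, jitter_rotation_deg = 0.8,
                   times_min = times, rng_seed = as.integer(seed)),
    segment = list(enamel_mode = "fixed",
                   enamel_value = (cm$liquid + cm$demineralised) / 2),
    register = list(exclude_below_z = 12L),  # liquid/enamel edge + margin
    roi_margin_voxels = 5L,
    rng_seed = as.integer(seed))
  run <- run_pipeline(cfg, out_dir, verbose = verbose)
  voxel <- run$manifest$voxel_um
  nliq <- round(2.6 / voxel)
  depth_um <- (dim(run$enamel$mask)[1] - nliq) * voxel
  tab <- run$tables$ray_distances
  ang <- sort(unique(tab$angle_deg))
  lims <- (depth_um - 2 * voxel) / abs(sin(ang * pi / 180))
  recovered <- estimate_front_speed(tab, max_ray_um = lims)
  ratio <- recovered / speed_nm_s
  if (verbose) {
    cat(sprintf("configured front speed : %.3f nm/s\n", speed_nm_s))
    cat(sprintf("recovered front speed  : %.3f nm/s\n", recovered))
    cat(sprintf("recovered / configured : %.3f\n", ratio))
  }
  invisible(list(configured_nm_s = speed_nm_s, recovered_nm_s = recovered,
                 ratio = ratio, run = run))
}
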