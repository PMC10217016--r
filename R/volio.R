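#' @useDynLib demintrack, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median optim rnorm runif sd setNames
#' @importFrom utils write.csv
NULL

#' One 3D greyscale tomogram with its acquisition metadata
#'
#' A `volume_frame` holds a single reconstructed stack as a 3D numeric array
#' indexed `[z, y, x]`, where `z` is depth from the exposed enamel surface
#' and an `xy` plane is one virtual slice. Intensities are kept as floats in
#' `[0, 1]`; writers quantise to the requested bit depth on export. `NA`
#' marks voxels that fell outside the field of view after resampling and is
#' excluded from all downstream masks.
#'
#' @param data 3D numeric array, dim `c(nz, ny, nx)`, all dims >= 2.
#' @param voxel_um Isotropic voxel size in micrometres (> 0).
#' @param t_min Acquisition time in minutes from the start of acid exposure.
#' @param frame_id Integer frame identifier (1-based position in the series).
#' @return An object of class `volume_frame`.
#' @export
volume_frame <- function(data, voxel_um, t_min = NA_real_,
                         frame_id = NA_integer_) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array indexed [z, y, x]")
  if (any(dim(data) < 2L))
    stop("all dimensions must be >= 2")
  if (!is.numeric(voxel_um) || length(voxel_um) != 1L || voxel_um <= 0)
    stop("`voxel_um` must be a positive scalar")
  if (any(is.infinite(data)))
    stop("intensities must be finite (NA marks out-of-domain voxels)")
  structure(list(data = data, voxel_um = as.numeric(voxel_um),
                 t_min = as.numeric(t_min),
                 frame_id = as.integer(frame_id)),
            class = "volume_frame")
}

#' @export
print.volume_frame <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_frame> %d x %d x %d voxels (z,y,x), %.3g um/voxel, t = %s min\n",
              d[1], d[2], d[3], x$voxel_um,
              if (is.na(x$t_min)) "?" else format(x$t_min)))
  invisible(x)
}

#' Read a multi-page TIFF stack
#'
#' Pages are stacked along `z` (page 1 = `z = 1`). All pages must share one
#' shape; greyscale 8- or 16-bit samples are supported and mapped to
#' `[0, 1]`.
#'
#' @param path Path to a multi-page TIFF file.
#' @param voxel_um,t_min,frame_id Metadata attached to the returned frame.
#' @return A [volume_frame()].
#' @export
read_stack <- function(path, voxel_um = 1, t_min = NA_real_,
                       frame_id = NA_integer_) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # drop extra channels
    p
  })
  shp <- dim(pages[[1L]])
  if (!all(vapply(pages, function(p) identical(dim(p), shp), logical(1))))
    stop("TIFF pages differ in shape: ", path)
  a <- array(unlist(pages, use.names = FALSE),
             dim = c(shp[1], shp[2], length(pages)))
  volume_frame(aperm(a, c(3L, 1L, 2L)), voxel_um = voxel_um, t_min = t_min,
               frame_id = frame_id)
}

#' Write a stack as a multi-page greyscale TIFF
#'
#' Values are clipped to `[0, 1]` and quantised to the requested bit depth;
#' `NA` voxels are written as 0.
#'
#' @param frame A [volume_frame()] (or a logical/numeric 3D array).
#' @param path Output path.
#' @param bits Bits per sample: 8 or 16.
#' @return `path`, invisibly.
#' @export
write_stack <- function(frame, path, bits = 16L) {
  data <- if (inherits(frame, "volume_frame")) frame$data else frame
  if (is.logical(data)) data <- data * 1.0
  stopifnot(bits %in% c(8L, 16L))
  data[is.na(data)] <- 0
  data <- pmin(pmax(data, 0), 1)
  pages <- lapply(seq_len(dim(data)[1L]), function(z) data[z, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits),
                  compression = "none")
  invisible(path)
}

#' Time-series manifest: the 4D dataset definition
#'
#' Builds and validates the ordered list of frames that constitutes one
#' time-lapse experiment. Acquisition times must be strictly increasing and
#' the reference index (the time point every other frame is aligned to,
#' 1-based, default the first frame) must be valid.
#'
#' @param frames `data.frame` with columns `path`, `t_min` and optionally
#'   `frame_id`.
#' @param voxel_um Isotropic voxel size shared by all frames.
#' @param reference_index 1-based index of the reference time point.
#' @param base_dir Directory against which relative frame paths resolve.
#' @param check_files Error if a listed frame file is missing.
#' @return An object of class `time_series_manifest`.
#' @export
time_series_manifest <- function(frames, voxel_um, reference_index = 1L,
                                 base_dir = ".", check_files = TRUE) {
  stopifnot(is.data.frame(frames), all(c("path", "t_min") %in% names(frames)))
  if (is.null(frames$frame_id)) frames$frame_id <- seq_len(nrow(frames))
  frames <- frames[order(frames$t_min), , drop = FALSE]
  if (nrow(frames) >= 2L && any(diff(frames$t_min) <= 0))
    stop("acquisition times t_min must be strictly increasing")
  if (!is.numeric(voxel_um) || voxel_um <= 0)
    stop("`voxel_um` must be positive")
  reference_index <- as.integer(reference_index)
  if (reference_index < 1L || reference_index > nrow(frames))
    stop("reference_index out of range (1..", nrow(frames), ")")
  abs_path <- ifelse(grepl("^(/|[A-Za-z]:)", frames$path), frames$path,
                     file.path(base_dir, frames$path))
  if (check_files) {
    missing <- abs_path[!file.exists(abs_path)]
    if (length(missing))
      stop("missing frame file(s): ", paste(missing, collapse = ", "))
  }
  frames$path <- abs_path
  structure(list(frames = frames, voxel_um = as.numeric(voxel_um),
                 reference_index = reference_index),
            class = "time_series_manifest")
}

#' @export
print.time_series_manifest <- function(x, ...) {
  cat(sprintf("<time_series_manifest> %d frames, voxel %.3g um, reference #%d\n",
              nrow(x$frames), x$voxel_um, x$reference_index))
  cat(sprintf("  t_min: %s\n", paste(x$frames$t_min, collapse = ", ")))
  invisible(x)
}

#' Load a time-series manifest from YAML or JSON
#'
#' Relative frame paths are resolved against the manifest's own directory.
#'
#' @param path Manifest file (`.yaml`/`.yml` or `.json`).
#' @param check_files Error if a listed frame file is missing.
#' @return A [time_series_manifest()].
#' @export
load_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  else
    yaml::read_yaml(path)
  fr <- do.call(rbind, lapply(raw$frames, function(f)
    data.frame(path = f$path, t_min = as.numeric(f$t_min),
               frame_id = if (is.null(f$frame_id)) NA_integer_
                          else as.integer(f$frame_id))))
  if (any(is.na(fr$frame_id))) fr$frame_id <- seq_len(nrow(fr))
  ref <- if (is.null(raw$reference_index)) 1L else as.integer(raw$reference_index)
  time_series_manifest(fr, voxel_um = as.numeric(raw$voxel_um),
                       reference_index = ref,
                       base_dir = dirname(normalizePath(path)),
                       check_files = check_files)
}

#' Write a manifest to YAML
#'
#' Frame paths are stored relative to the manifest location when possible.
#'
#' @param manifest A [time_series_manifest()].
#' @param path Output `.yaml` path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  dir <- normalizePath(dirname(path))
  rel <- vapply(manifest$frames$path, function(p) {
    pn <- tryCatch(normalizePath(p, mustWork = FALSE), error = function(e) p)
    if (startsWith(pn, paste0(dir, "/"))) substring(pn, nchar(dir) + 2L) else pn
  }, character(1))
  out <- list(
    voxel_um = manifest$voxel_um,
    reference_index = manifest$reference_index,
    frames = lapply(seq_len(nrow(manifest$frames)), function(i)
      list(path = unname(rel[i]), t_min = manifest$frames$t_min[i],
           frame_id = manifest$frames$frame_id[i])))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Physical extent of an axis in micrometres
#'
#' Uses the centre-to-centre convention: `n` voxel centres span
#' `(n - 1) * voxel_um` micrometres. This matches how the printed extents of
#' typical reconstructed grids relate to their voxel counts (e.g. 812 voxels
#' at 0.325 um across 263.575 um); note that many tools print the
#' alternative `n * voxel_um` edge-to-edge convention instead.
#'
#' @param n_voxels Number of voxels along the axis (>= 1).
#' @param voxel_um Voxel size in micrometres.
#' @return Extent in micrometres.
#' @examples
#' physical_extent_um(812, 0.325)   # 263.575
#' physical_extent_um(1280, 0.325)  # 415.675
#' @export
physical_extent_um <- function(n_voxels, voxel_um) {
  if (any(n_voxels < 1)) stop("n_voxels must be >= 1")
  if (any(voxel_um <= 0)) stop("voxel_um must be positive")
  (n_voxels - 1) * voxel_um
}
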