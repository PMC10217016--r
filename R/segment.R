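# Otsu's threshold on a numeric vector (maximises between-class variance).
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  if (!length(x)) stop("no finite intensities to threshold")
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(pmax(floor((x - rng[1]) / diff(rng) * nbins) + 1L, 1L),
                     nbins), nbins)
  w <- h / sum(h)
  mids <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  w0 <- cumsum(w); mu <- cumsum(w * mids); mu_t <- mu[nbins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

ball_offsets <- function(r) {
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  g <- g[g$dz^2 + g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
  as.matrix(g)
}

binary_open <- function(mask, radius) {
  if (radius < 1) return(mask)
  d <- dim(mask)
  off <- ball_offsets(radius)
  storage.mode(off) <- "integer"
  er <- cpp_morph(as.vector(mask), d[1], d[2], d[3], off, FALSE)
  di <- cpp_morph(er, d[1], d[2], d[3], off, TRUE)
  array(di, dim = d)
}

label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  array(cpp_label_components(as.vector(mask), d[1], d[2], d[3],
                             connectivity == 26L), dim = d)
}

# Fill background cavities: background components (6-connected) that do not
# touch the volume border become foreground.
fill_holes3d <- function(mask) {
  d <- dim(mask)
  lab <- label_components(!mask, connectivity = 6L)
  border <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
                     lab[, , 1], lab[, , d[3]]))
  border <- border[border > 0]
  mask | (lab > 0 & !(lab %in% border))
}

#' Segmentation policy for the enamel (total-tissue) mask
#'
#' @param mode `"auto"` (Otsu bimodal split of the intensity histogram) or
#'   `"fixed"`.
#' @param value Threshold intensity when `mode = "fixed"`.
#' @return A list of class `enamel_policy`.
#' @export
enamel_policy <- function(mode = c("auto", "fixed"), value = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed" && (is.null(value) || !is.finite(value)))
    stop("fixed mode needs a threshold `value`")
  structure(list(mode = mode, value = value), class = "enamel_policy")
}

#' Segmentation policy for the demineralised lesion
#'
#' The automatic threshold is `location - k * scale` of the reference
#' frame's enamel intensity histogram (the lesion appears as a greyscale
#' drop), with the median as location and 1.4826 MAD as scale so that an
#' already-present lesion in the reference frame cannot drag the threshold
#' down. Speckle is removed by a morphological opening, and only components
#' connected to the exposed window (seed region) are kept, so isolated dark
#' spots deep in the enamel are not counted as lesion.
#'
#' @param mode `"auto"` or `"fixed"`.
#' @param k Number of robust standard deviations (1.4826 MAD) below the
#'   enamel median (auto mode).
#' @param value Fixed threshold intensity.
#' @param opening_radius Radius (voxels) of the binary opening; 0 disables.
#' @param connectivity Component connectivity (26 or 6).
#' @param seed `"top"` (components touching the uppermost enamel slab are
#'   kept), `"all"` (no seed filtering), or supply `seed_mask`.
#' @param seed_mask Optional logical array marking the seed region.
#' @param nesting_warn_frac Warn if more than this fraction of the previous
#'   mask's voxels disappear at the next time point (masks are reported
#'   as-is; nesting is never enforced).
#' @return A list of class `lesion_policy`.
#' @export
lesion_policy <- function(mode = c("auto", "fixed"), k = 3, value = NULL,
                          opening_radius = 1L, connectivity = 26L,
                          seed = c("top", "all"), seed_mask = NULL,
                          nesting_warn_frac = 0.05) {
  mode <- match.arg(mode)
  if (mode == "fixed" && (is.null(value) || !is.finite(value)))
    stop("fixed mode needs a threshold `value`")
  structure(list(mode = mode, k = k, value = value,
                 opening_radius = as.integer(opening_radius),
                 connectivity = as.integer(connectivity),
                 seed = match.arg(seed), seed_mask = seed_mask,
                 nesting_warn_frac = nesting_warn_frac),
            class = "lesion_policy")
}

#' Segment the enamel (total tissue) mask
#'
#' Thresholds the (denoised, reference-grid) frame, keeps the largest
#' 26-connected component and fills interior cavities, yielding the total
#' enamel region used as the denominator of area and volume fractions. The
#' mask is computed once on the reference frame and reused for every time
#' point; the denser surface zone is retained inside it.
#'
#' @param frame A [volume_frame()].
#' @param policy An [enamel_policy()].
#' @return An object of class `enamel_mask` (`mask`, `voxel_um`,
#'   `threshold`).
#' @export
segment_enamel <- function(frame, policy = enamel_policy()) {
  stopifnot(inherits(frame, "volume_frame"))
  x <- frame$data
  thr <- if (policy$mode == "fixed") policy$value else otsu_threshold(x)
  fg <- !is.na(x) & x >= thr
  if (!any(fg)) stop("empty foreground: no voxel at or above the enamel threshold")
  lab <- label_components(fg, 26L)
  sizes <- tabulate(lab[lab > 0])
  fg <- lab == which.max(sizes)
  fg <- fill_holes3d(fg)
  structure(list(mask = fg, voxel_um = frame$voxel_um, threshold = thr),
            class = "enamel_mask")
}

#' Segment the demineralised lesion at one time point
#'
#' Voxels inside the enamel mask whose intensity falls below the lesion
#' threshold, followed by speckle removal (binary opening) and seed-region
#' component filtering. An empty mask is a valid result (e.g. before any
#' demineralisation is detectable). If a previous time point's mask is
#' supplied, a warning is raised when nesting is violated by more than the
#' policy's fraction -- each tomogram is still reported as-is.
#'
#' @param frame A [volume_frame()] aligned to the reference grid.
#' @param enamel An [segment_enamel()] mask.
#' @param policy A [lesion_policy()].
#' @param reference Frame whose enamel histogram defines the auto threshold
#'   (default: `frame` itself; in a pipeline, pass the reference frame).
#' @param previous Optional previous `lesion_mask` for the nesting check.
#' @return A `lesion_mask` with attribute `threshold`.
#' @export
segment_lesion <- function(frame, enamel, policy = lesion_policy(),
                           reference = NULL, previous = NULL) {
  stopifnot(inherits(frame, "volume_frame"), inherits(enamel, "enamel_mask"))
  if (!identical(dim(frame$data), dim(enamel$mask)))
    stop("frame and enamel mask shapes differ")
  thr <- if (policy$mode == "fixed") {
    policy$value
  } else {
    ref <- if (is.null(reference)) frame else reference
    vals <- ref$data[enamel$mask & !is.na(ref$data)]
    stats::median(vals) - policy$k * stats::mad(vals)
  }
  lesion <- enamel$mask & !is.na(frame$data) & frame$data < thr
  if (any(lesion)) {
    lesion <- binary_open(lesion, policy$opening_radius) & enamel$mask
    seed_mask <- policy$seed_mask
    if (is.null(seed_mask) && policy$seed == "top" && any(lesion)) {
      zs <- which(apply(enamel$mask, 1L, any))[1L]
      seed_mask <- array(FALSE, dim = dim(lesion))
      seed_mask[zs:min(zs + 1L, dim(lesion)[1]), , ] <- TRUE
    }
    if (!is.null(seed_mask) && any(lesion)) {
      lab <- label_components(lesion, policy$connectivity)
      keep <- setdiff(unique(lab[seed_mask & lab > 0]), 0L)
      lesion <- array(lab %in% keep, dim = dim(lesion))
    }
  }
  if (!is.null(previous)) {
    prev <- previous$mask
    lost <- sum(prev & !lesion)
    if (sum(prev) > 0 && lost > policy$nesting_warn_frac * sum(prev))
      warning(sprintf(paste0("nesting violated: %d voxels (%.1f%%) of the ",
                             "previous lesion are absent at t = %s min"),
                      lost, 100 * lost / sum(prev), format(frame$t_min)))
  }
  out <- new_lesion_mask(lesion, voxel_um = frame$voxel_um,
                         t_min = frame$t_min, frame_id = frame$frame_id)
  attr(out, "threshold") <- thr
  out
}

#' Remove artifact regions from a mask
#'
#' Excludes acquisition artifacts (e.g. bubbles in the liquid that disturb
#' the reconstruction) from a lesion mask. Regions are boxes
#' (`list(type = "box", zlim =, ylim =, xlim =)` in voxel indices),
#' ellipsoids (`list(type = "ellipsoid", center =, radii =)` in voxels) or
#' a logical array.
#'
#' @param mask A `lesion_mask` (or logical array).
#' @param artifact_regions List of region descriptors (may be empty).
#' @return The mask with artifact voxels removed; the number of removed
#'   voxels is attached as `attr(, "excluded_voxels")`.
#' @export
exclude_artifacts <- function(mask, artifact_regions = list()) {
  is_obj <- inherits(mask, "lesion_mask")
  m <- if (is_obj) mask$mask else mask
  d <- dim(m)
  excl <- array(FALSE, dim = d)
  for (reg in artifact_regions) {
    if (is.logical(reg) && is.array(reg)) { excl <- excl | reg; next }
    if (identical(reg$type, "box")) {
      zl <- pmin(pmax(round(reg$zlim), 1L), d[1])
      yl <- pmin(pmax(round(reg$ylim), 1L), d[2])
      xl <- pmin(pmax(round(reg$xlim), 1L), d[3])
      excl[zl[1]:zl[2], yl[1]:yl[2], xl[1]:xl[2]] <- TRUE
    } else if (identical(reg$type, "ellipsoid")) {
      ctr <- reg$center; rad <- reg$radii
      e <- outer(outer((seq_len(d[1]) - ctr[1])^2 / rad[1]^2,
                       (seq_len(d[2]) - ctr[2])^2 / rad[2]^2, "+"),
                 (seq_len(d[3]) - ctr[3])^2 / rad[3]^2, "+") <= 1
      excl <- excl | e
    } else stop("unknown artifact region type")
  }
  removed <- sum(m & excl)
  m <- m & !excl
  out <- if (is_obj) { mask$mask <- m; mask } else m
  attr(out, "excluded_voxels") <- removed
  out
}

#' Dice overlap coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; 1 when both masks are empty.
#'
#' @param a,b Logical arrays (or mask objects) of equal shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  if (inherits(a, "lesion_mask")) a <- a$mask
  if (inherits(a, "enamel_mask")) a <- a$mask
  if (inherits(b, "lesion_mask")) b <- b$mask
  if (inherits(b, "enamel_mask")) b <- b$mask
  stopifnot(identical(dim(a), dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
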