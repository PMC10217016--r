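#' Rigid 3D transform (rotation + translation)
#'
#' Parameterised by three Euler angles in degrees (intrinsic rotations about
#' the reference frame's `z`, `y` and `x` axes, applied in that order) and a
#' translation in voxels of the reference grid. [apply_transform()] uses the
#' pull-back convention: the transform maps reference-grid coordinates to
#' the coordinates at which the moving volume is sampled, with rotation
#' about the grid centre.
#'
#' @param rotation_deg Angles `(about z, about y, about x)` in degrees.
#' @param translation_voxels Translation `(z, y, x)` in voxels.
#' @return An object of class `rigid_transform3d`.
#' @export
rigid_transform3d <- function(rotation_deg = c(0, 0, 0),
                              translation_voxels = c(0, 0, 0)) {
  stopifnot(length(rotation_deg) == 3L, length(translation_voxels) == 3L,
            all(is.finite(rotation_deg)), all(is.finite(translation_voxels)))
  structure(list(rotation_deg = as.numeric(rotation_deg),
                 translation_voxels = as.numeric(translation_voxels)),
            class = "rigid_transform3d")
}

#' @export
print.rigid_transform3d <- function(x, ...) {
  cat(sprintf("<rigid_transform3d> rot (z,y,x) = %s deg, trans (z,y,x) = %s vox\n",
              paste(signif(x$rotation_deg, 4), collapse = ", "),
              paste(signif(x$translation_voxels, 4), collapse = ", ")))
  invisible(x)
}

# 3x3 rotation matrix acting on (z, y, x) coordinate vectors.
rotation_matrix_zyx <- function(rotation_deg) {
  a <- rotation_deg * pi / 180
  cz <- cos(a[1]); sz <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cx <- cos(a[3]); sx <- sin(a[3])
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  R_xyz <- Rz %*% Ry %*% Rx            # acts on (x, y, z)
  P <- matrix(c(0, 0, 1, 0, 1, 0, 1, 0, 0), 3, 3)  # (x,y,z) <-> (z,y,x)
  P %*% R_xyz %*% P
}

# Euler angles (deg, z-y-x order) from a rotation matrix in (z,y,x) layout.
angles_from_matrix_zyx <- function(Rzyx) {
  P <- matrix(c(0, 0, 1, 0, 1, 0, 1, 0, 0), 3, 3)
  R <- P %*% Rzyx %*% P                 # back to (x, y, z) layout
  sy <- -R[3, 1]
  beta <- asin(pmin(pmax(sy, -1), 1))
  alpha <- atan2(R[2, 1], R[1, 1])      # about z
  gamma <- atan2(R[3, 2], R[3, 3])      # about x
  c(alpha, beta, gamma) * 180 / pi
}

#' Compose two rigid transforms
#'
#' `compose_transform(t1, t2)` is the single transform equivalent to
#' applying `t1` first and then `t2` with [apply_transform()].
#'
#' @param t1,t2 [rigid_transform3d()] objects.
#' @return A [rigid_transform3d()].
#' @export
compose_transform <- function(t1, t2) {
  R1 <- rotation_matrix_zyx(t1$rotation_deg)
  R2 <- rotation_matrix_zyx(t2$rotation_deg)
  Rc <- R1 %*% R2
  tc <- as.numeric(R1 %*% t2$translation_voxels) + t1$translation_voxels
  rigid_transform3d(angles_from_matrix_zyx(Rc), tc)
}

#' Invert a rigid transform
#' @param tf A [rigid_transform3d()].
#' @return The inverse [rigid_transform3d()].
#' @export
invert_transform <- function(tf) {
  R <- rotation_matrix_zyx(tf$rotation_deg)
  rigid_transform3d(angles_from_matrix_zyx(t(R)),
                    as.numeric(-t(R) %*% tf$translation_voxels))
}

#' Magnitude of a rigid transform
#'
#' Total rotation angle (degrees) and Euclidean translation norm (voxels);
#' handy for quantifying registration error as the magnitude of
#' `compose_transform(estimate, truth)` when the estimate should invert the
#' truth.
#'
#' @param tf A [rigid_transform3d()].
#' @return Named numeric: `rotation_deg`, `translation_voxels`.
#' @export
transform_magnitude <- function(tf) {
  R <- rotation_matrix_zyx(tf$rotation_deg)
  ang <- acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1)) * 180 / pi
  c(rotation_deg = ang,
    translation_voxels = sqrt(sum(tf$translation_voxels^2)))
}

# Core pull-back resampler on a bare array.
resample_rigid_array <- function(vol, tf, fill = NA_real_,
                                 interpolation = c("trilinear", "nearest"),
                                 out_dim = dim(vol)) {
  interpolation <- match.arg(interpolation)
  clamp <- identical(fill, "replicate")
  fill_val <- if (clamp) 0 else as.numeric(fill)
  d <- dim(vol)
  R <- rotation_matrix_zyx(tf$rotation_deg)
  ctr <- (out_dim - 1) / 2
  out <- cpp_resample_rigid(as.numeric(vol), d[1], d[2], d[3],
                            as.numeric(t(R)), tf$translation_voxels, ctr,
                            fill_val, interpolation == "nearest", clamp)
  array(out, dim = out_dim)
}

#' Resample a frame through a rigid transform onto the reference grid
#'
#' Trilinear interpolation for intensities (default) or nearest-neighbour
#' for masks. Output voxels whose pull-back lands outside the moving volume
#' receive `fill` (default `NA`, the out-of-domain sentinel excluded from
#' downstream masks).
#'
#' @param frame A [volume_frame()].
#' @param tf A [rigid_transform3d()].
#' @param reference A [volume_frame()] defining the output grid (default:
#'   the frame's own grid).
#' @param fill Out-of-domain fill value, or `"replicate"` to clamp sample
#'   positions to the volume border (edge extension, as a physical sample
#'   extending beyond the field of view).
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return A [volume_frame()] on the reference grid.
#' @export
apply_transform <- function(frame, tf, reference = NULL, fill = NA_real_,
                            interpolation = c("trilinear", "nearest")) {
  stopifnot(inherits(frame, "volume_frame"), inherits(tf, "rigid_transform3d"))
  out_dim <- if (is.null(reference)) dim(frame$data) else dim(reference$data)
  out <- resample_rigid_array(frame$data, tf, fill = fill,
                              interpolation = match.arg(interpolation),
                              out_dim = out_dim)
  volume_frame(out, voxel_um = frame$voxel_um, t_min = frame$t_min,
               frame_id = frame$frame_id)
}

#' 3D median filter
#'
#' Per-voxel median over the `(2r+1)^3` cube with edge-replicated borders.
#' Metadata (voxel size, time) is preserved.
#'
#' @param frame A [volume_frame()].
#' @param radius_voxels Neighbourhood radius (>= 1).
#' @return The filtered [volume_frame()].
#' @export
median_filter3d <- function(frame, radius_voxels = 1L) {
  stopifnot(inherits(frame, "volume_frame"), radius_voxels >= 1L)
  d <- dim(frame$data)
  out <- cpp_median3d(as.numeric(frame$data), d[1], d[2], d[3],
                      as.integer(radius_voxels))
  frame$data <- array(out, dim = d)
  frame
}

#' Non-local means denoising
#'
#' Each voxel is replaced by a patch-similarity-weighted average over a
#' local search window: voxels whose surrounding patches resemble the
#' centre patch contribute with weight `exp(-SSD / h^2)`. As `h -> 0` the
#' filter approaches the identity; larger `h` smooths more aggressively.
#'
#' @param frame A [volume_frame()].
#' @param h Filtering strength, on the intensity scale (>= 0).
#' @param patch_radius Patch half-width in voxels.
#' @param search_radius Search-window half-width in voxels.
#' @return The denoised [volume_frame()].
#' @export
nlm_denoise <- function(frame, h = 0.05, patch_radius = 1L,
                        search_radius = 2L) {
  stopifnot(inherits(frame, "volume_frame"), h >= 0)
  d <- dim(frame$data)
  out <- cpp_nlm3d(as.numeric(frame$data), d[1], d[2], d[3], h,
                   as.integer(patch_radius), as.integer(search_radius))
  frame$data <- array(out, dim = d)
  frame
}

downsample_array <- function(vol, f) {
  if (f == 1L) return(vol)
  d <- dim(vol)
  array(cpp_downsample(as.numeric(vol), d[1], d[2], d[3], as.integer(f)),
        dim = d %/% f)
}

#' Rigid registration to a reference frame by NCC maximisation
#'
#' Estimates the rigid transform that best aligns `moving` onto `reference`
#' by maximising the normalised cross-correlation (NCC) of the overlap --
#' a similarity measure robust to the global intensity drop as a lesion
#' grows. The 6 parameters (3 Euler angles, 3 translations) are optimised
#' with derivative-free Nelder-Mead search over a coarse-to-fine resolution
#' pyramid; the caller can supply an initial guess (the classical manual
#' pre-alignment step) and an exclusion mask covering regions that change
#' between time points (e.g. the growing lesion window).
#'
#' @param moving,reference [volume_frame()]s on grids of equal voxel size.
#' @param init Initial [rigid_transform3d()] guess.
#' @param levels Integer downsampling factors of the pyramid, coarse to
#'   fine.
#' @param exclude_mask Optional logical array on the reference grid; `TRUE`
#'   voxels are ignored by the similarity measure.
#' @param maxit Nelder-Mead iteration budget per level (recycled).
#' @param ncc_min Final NCC below this flags the result as not converged.
#' @param max_translation_voxels Search bound: candidate translations more
#'   than this far (per axis) from the initial guess are rejected. Keeps
#'   the optimiser inside the physically plausible inter-frame motion range
#'   and off degenerate high-NCC solutions with vanishing overlap.
#' @param regularization Strength of a weak quadratic prior pulling the
#'   solution towards `init` (cost `regularization * mean(((p - init)/5)^2)`
#'   against the NCC). It only matters along directions the image content
#'   does not constrain (e.g. in-plane motion of a laterally uniform
#'   scene); any real NCC gradient overrides it. 0 disables.
#' @return A list of class `registration_result`: `transform`
#'   (a [rigid_transform3d()] such that
#'   `apply_transform(moving, transform)` matches `reference`), `ncc`, and
#'   `converged`.
#' @export
register_rigid <- function(moving, reference, init = rigid_transform3d(),
                           levels = c(4L, 2L, 1L), exclude_mask = NULL,
                           maxit = c(250L, 150L, 80L), ncc_min = 0.2,
                           max_translation_voxels = 10,
                           regularization = 0.01) {
  stopifnot(inherits(moving, "volume_frame"),
            inherits(reference, "volume_frame"))
  if (abs(moving$voxel_um - reference$voxel_um) > 1e-9)
    stop("moving and reference must share one voxel size")
  maxit <- rep_len(maxit, length(levels))
  par <- c(init$rotation_deg, init$translation_voxels)
  par0 <- par
  ncc <- NA_real_
  for (li in seq_along(levels)) {
    f <- as.integer(levels[li])
    mov_l <- downsample_array(moving$data, f)
    ref_l <- downsample_array(reference$data, f)
    exc_l <- if (is.null(exclude_mask)) logical(0) else
      as.vector(downsample_array(exclude_mask * 1, f) > 0.5)
    n_full <- sum(is.finite(ref_l)) - if (length(exc_l)) sum(exc_l) else 0L
    objective <- function(p) {
      if (any(abs(p[4:6] - init$translation_voxels) > max_translation_voxels))
        return(1)
      tf <- rigid_transform3d(p[1:3], p[4:6] / f)
      res <- resample_rigid_array(mov_l, tf, fill = NA_real_)
      v <- cpp_ncc(as.numeric(res), as.numeric(ref_l), exc_l)
      if (is.na(v)) return(1)
      # discount low-overlap candidates so shrinking the overlap cannot
      # masquerade as a better match
      ov <- sum(is.finite(res) & is.finite(ref_l) &
                  (if (length(exc_l)) !exc_l else TRUE)) / n_full
      -v * min(1, ov / 0.5) + regularization * mean(((p - par0) / 5)^2)
    }
    if (li == 1L) {
      # exhaustive search over integer coarse-voxel translations and a few
      # in-plane rotations around the initial guess, so the local optimiser
      # starts inside the NCC basin (the rotation about z is the parameter
      # most prone to spurious local optima on near-periodic structures)
      steps <- as.matrix(expand.grid(az = seq(-2, 2, by = 1), dz = -2:2,
                                     dy = -2:2, dx = -2:2))
      steps[, 2:4] <- steps[, 2:4] * f
      vals <- apply(steps, 1L, function(s)
        objective(par + c(s[1], 0, 0, s[2:4])))
      best <- steps[which.min(vals), ]
      par <- par + c(best[1], 0, 0, best[2:4])
    }
    # simplex steps sized to the expected residual at this level
    scale <- c(rep(max(0.5 * f, 0.5), 3), rep(max(f, 1), 3))
    opt <- optim(par, objective, method = "Nelder-Mead",
                 control = list(maxit = maxit[li], reltol = 1e-8,
                                parscale = scale))
    par <- opt$par
    # restart with a tighter simplex: Nelder-Mead on 6 parameters profits
    # from a second pass once the coarse basin is found
    opt <- optim(par, objective, method = "Nelder-Mead",
                 control = list(maxit = maxit[li], reltol = 1e-8,
                                parscale = 0.25 * scale))
    par <- opt$par
    ncc <- -opt$value
  }
  tf <- rigid_transform3d(par[1:3], par[4:6])
  structure(list(transform = tf, ncc = ncc,
                 converged = is.finite(ncc) && ncc >= ncc_min),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> NCC = %.4f (%s)\n", x$ncc,
              if (x$converged) "converged" else "NOT converged"))
  print(x$transform)
  invisible(x)
}
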