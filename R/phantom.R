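#' NEMA-style image-quality phantom specification
#'
#' Simplified geometry: six hot spheres on a coplanar ring inside a uniform
#' cylindrical body (the true torso shell and lung insert are omitted), with
#' 4:1 hot-sphere contrast by default. Motion is modelled along one grid
#' axis (axis 3, the scanner's axial direction).
#'
#' @param sphere_diameters Hot-sphere diameters in mm, ascending
#'   (default the standard 10, 13, 17, 22, 28, 37).
#' @param contrast_ratio Hot-to-background activity ratio a_H / a_B (> 1).
#' @param background_activity Background activity in arbitrary units.
#' @param body_radius,body_length Cylinder radius / axial length in mm.
#' @param voxel_size Isotropic voxel size in mm (default 2.7, matching the
#'   usual reconstruction matrix convention).
#' @param psf_fwhm System PSF full width at half maximum in mm (default 5).
#' @param motion_axis Axis index (1-3) or unit vector along a grid axis;
#'   default axis 3.
#' @param sphere_ring_radius Radius of the sphere-centre ring in mm
#'   (default 57.2, the NEMA convention).
#' @param bg_ring_radius Radius at which background ROIs are placed, mm.
#' @param bg_angles_deg Angles (degrees) of the 12 background ROI centres;
#'   the defaults interleave the sphere angles.
#' @param liver_center World coordinates (mm) of the liver-noise VOI centre;
#'   the default grid centre lies in uniform background.
#' @param margin_mm Grid margin beyond the body radius.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(sphere_diameters = c(10, 13, 17, 22, 28, 37),
                         contrast_ratio = 4,
                         background_activity = 1,
                         body_radius = 147,
                         body_length = 120,
                         voxel_size = 2.7,
                         psf_fwhm = 5,
                         motion_axis = 3,
                         sphere_ring_radius = 57.2,
                         bg_ring_radius = 106,
                         bg_angles_deg = seq(15, 345, by = 30),
                         liver_center = c(0, 0, 0),
                         margin_mm = 15) {
  if (any(diff(sphere_diameters) <= 0) || any(sphere_diameters <= 0)) {
    stop("`sphere_diameters` must be positive and ascending")
  }
  if (contrast_ratio <= 1) stop("`contrast_ratio` must be > 1")
  if (background_activity < 0) stop("`background_activity` must be >= 0")
  axis <- motion_axis_index(motion_axis)
  structure(
    list(sphere_diameters = sphere_diameters, contrast_ratio = contrast_ratio,
         background_activity = background_activity, body_radius = body_radius,
         body_length = body_length, voxel_size = voxel_size,
         psf_fwhm = psf_fwhm, motion_axis = axis,
         sphere_ring_radius = sphere_ring_radius,
         bg_ring_radius = bg_ring_radius, bg_angles_deg = bg_angles_deg,
         liver_center = liver_center, margin_mm = margin_mm),
    class = "phantom_spec"
  )
}

# accept 1/2/3 or an axis-aligned unit vector
motion_axis_index <- function(motion_axis) {
  if (is.numeric(motion_axis) && length(motion_axis) == 1) {
    if (!motion_axis %in% 1:3) stop("`motion_axis` must be 1, 2 or 3")
    return(as.integer(motion_axis))
  }
  if (is.numeric(motion_axis) && length(motion_axis) == 3) {
    v <- motion_axis / sqrt(sum(motion_axis^2))
    axis <- which(abs(abs(v) - 1) < 1e-9)
    if (length(axis) != 1) {
      stop("`motion_axis` must be aligned with a grid axis")
    }
    return(axis)
  }
  stop("`motion_axis` must be an axis index or an axis-aligned unit vector")
}

sphere_centers <- function(spec) {
  ang <- seq(0, by = 60, length.out = length(spec$sphere_diameters)) * pi / 180
  cbind(x = spec$sphere_ring_radius * cos(ang),
        y = spec$sphere_ring_radius * sin(ang),
        z = 0)
}

#' Build the static (motion-free) phantom volume
#'
#' Voxels inside a hot sphere get `contrast_ratio * background_activity`,
#' voxels inside the body cylinder get `background_activity`, everything
#' else is 0; the result is then blurred with the isotropic Gaussian system
#' PSF.
#'
#' @param spec A [phantom_spec()].
#' @return An [image_volume()] carrying the spec in attribute `spec`.
#' @export
build_static_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  radii <- spec$sphere_diameters / 2
  if (spec$sphere_ring_radius + max(radii) > spec$body_radius) {
    stop("spheres extend outside the phantom body")
  }
  if (spec$voxel_size > min(radii)) {
    stop("voxel size exceeds the smallest sphere radius")
  }
  half_xy <- spec$body_radius + spec$margin_mm
  nxy <- 2L * ceiling(half_xy / spec$voxel_size) + 1L
  nz <- 2L * ceiling((spec$body_length / 2) / spec$voxel_size) + 1L
  cx <- (seq_len(nxy) - (nxy + 1) / 2) * spec$voxel_size
  cz <- (seq_len(nz) - (nz + 1) / 2) * spec$voxel_size

  body_xy <- outer(cx^2, cx^2, "+") <= spec$body_radius^2
  arr <- array(spec$background_activity * as.numeric(body_xy),
               dim = c(nxy, nxy, nz))
  ctr <- sphere_centers(spec)
  hot <- spec$contrast_ratio * spec$background_activity
  for (j in seq_along(radii)) {
    r <- radii[j]
    ix <- which(abs(cx - ctr[j, "x"]) <= r)
    iy <- which(abs(cx - ctr[j, "y"]) <= r)
    iz <- which(abs(cz - ctr[j, "z"]) <= r)
    d2 <- outer(outer((cx[ix] - ctr[j, "x"])^2, (cx[iy] - ctr[j, "y"])^2, "+"),
                (cz[iz] - ctr[j, "z"])^2, "+")
    sub <- arr[ix, iy, iz]
    sub[d2 <= r^2] <- hot
    arr[ix, iy, iz] <- sub
  }
  vol <- image_volume(arr, spec$voxel_size)
  if (spec$psf_fwhm > 0) vol <- smooth_volume(vol, spec$psf_fwhm)
  attr(vol, "spec") <- spec
  vol
}

#' Residual-displacement distribution of (gated) data
#'
#' Normalised histogram of the trace amplitudes at retained samples — all
#' samples when ungated, or the samples inside the gate windows. Its width
#' is the residual motion that blurs the reconstructed image.
#'
#' @param trace A [respiratory_trace()].
#' @param gate_mask Optional `gate_mask`; `NULL` means ungated.
#' @param bin_width Histogram bin width in mm (half a voxel by convention).
#' @return List of class `displacement_pdf` with `mids`, `prob`, `breaks`,
#'   `mean`, `sd` (population SD of retained displacements) and `n`.
#' @export
residual_displacement_pdf <- function(trace, gate_mask = NULL,
                                      bin_width = 1.35) {
  stopifnot(inherits(trace, "respiratory_trace"))
  if (bin_width <= 0) stop("`bin_width` must be > 0")
  keep <- if (is.null(gate_mask)) {
    rep(TRUE, length(trace$times))
  } else {
    retained_by_windows(trace$times, gate_mask$windows)
  }
  amps <- trace$amplitudes[keep]
  if (!length(amps)) stop("empty retained sample set")
  lo <- floor(min(amps) / bin_width) - 1
  hi <- ceiling(max(amps) / bin_width) + 1
  breaks <- (lo:hi) * bin_width + bin_width / 2
  h <- graphics::hist(amps, breaks = breaks, plot = FALSE)
  mu <- mean(amps)
  structure(
    list(mids = h$mids, prob = h$counts / sum(h$counts), breaks = breaks,
         bin_width = bin_width, mean = mu,
         sd = sqrt(mean((amps - mu)^2)), n = length(amps)),
    class = "displacement_pdf"
  )
}

#' Apply residual motion blur along the motion axis
#'
#' Convolves the volume along the motion axis with the residual
#' displacement distribution. The distribution is mean-centred first, so
#' gating narrows the blur kernel without shifting the image (emulating a
#' motion-state-aligned reconstruction); fractional-voxel displacements are
#' split linearly between the two neighbouring voxel offsets, conserving
#' activity.
#'
#' @param volume An [image_volume()].
#' @param pdf A [residual_displacement_pdf()] (probabilities must sum to 1
#'   within 1e-6).
#' @param motion_axis Axis index or axis-aligned unit vector; default 3.
#' @return Blurred `image_volume`.
#' @export
apply_motion_blur <- function(volume, pdf, motion_axis = 3) {
  stopifnot(inherits(volume, "image_volume"),
            inherits(pdf, "displacement_pdf"))
  if (abs(sum(pdf$prob) - 1) > 1e-6) {
    stop("displacement pdf is not normalised within 1e-6")
  }
  axis <- motion_axis_index(motion_axis)
  centred <- pdf$mids - sum(pdf$prob * pdf$mids)
  off_vox <- centred / volume$voxel_size
  f <- floor(off_vox)
  w <- off_vox - f
  span <- (min(f)):(max(f) + 1L)
  weights <- numeric(length(span))
  for (i in seq_along(off_vox)) {
    weights[span == f[i]] <- weights[span == f[i]] + pdf$prob[i] * (1 - w[i])
    weights[span == f[i] + 1] <- weights[span == f[i] + 1] + pdf$prob[i] * w[i]
  }
  K <- kernel_matrix(dim(volume$data)[axis], as.integer(span), weights)
  out <- image_volume(axis_filter(volume$data, K, axis), volume$voxel_size)
  attr(out, "spec") <- attr(volume, "spec")
  out
}

#' Reconstruction-arm specification
#'
#' An arm is a count budget (1.0 = the 6-min gold-standard acquisition),
#' an optional gate mask (gating keeps `retained_fraction` of the counts),
#' and an optional post-reconstruction smoothing step standing in for a
#' denoising stage. Reconstruction-engine differences beyond count budget,
#' gating and smoothing are deliberately not modelled.
#'
#' @param label Arm name.
#' @param count_budget Relative counts (> 0); 0.5 halves the acquisition.
#' @param gate_mask Optional `gate_mask` whose `retained_fraction` scales
#'   the counts and whose windows define the residual motion.
#' @param counts_per_unit Poisson counts per voxel per activity unit at
#'   budget 1 (noise calibration; default 50).
#' @param post_smooth_fwhm Optional Gaussian smoothing FWHM in mm applied
#'   after noise (default 0 = none).
#' @param apply_motion Whether the arm sees platform motion (default TRUE;
#'   FALSE gives the static reference arm).
#' @return A list of class `recon_arm` with derived `retained_fraction` and
#'   `noise_scale = 1 / sqrt(count_budget * retained_fraction)`.
#' @export
recon_arm <- function(label, count_budget = 1, gate_mask = NULL,
                      counts_per_unit = 50, post_smooth_fwhm = 0,
                      apply_motion = TRUE) {
  if (count_budget <= 0) stop("`count_budget` must be > 0")
  if (counts_per_unit <= 0) stop("`counts_per_unit` must be > 0")
  rf <- if (is.null(gate_mask)) 1 else gate_mask$retained_fraction
  structure(
    list(label = label, count_budget = count_budget, gate_mask = gate_mask,
         retained_fraction = rf, counts_per_unit = counts_per_unit,
         post_smooth_fwhm = post_smooth_fwhm, apply_motion = apply_motion,
         noise_scale = 1 / sqrt(count_budget * rf)),
    class = "recon_arm"
  )
}

#' Apply Poisson count noise for a reconstruction arm
#'
#' Voxel activities are scaled to expected counts (`value * count_budget *
#' retained_fraction * counts_per_unit`), Poisson-sampled, and rescaled
#' back to activity units, so halving the counts raises relative noise by
#' sqrt(2).
#'
#' @param volume An [image_volume()].
#' @param arm A [recon_arm()].
#' @param seed Optional integer seed.
#' @return Noisy `image_volume`.
#' @export
apply_count_noise <- function(volume, arm, seed = NULL) {
  stopifnot(inherits(volume, "image_volume"), inherits(arm, "recon_arm"))
  scale <- arm$count_budget * arm$retained_fraction * arm$counts_per_unit
  if (!is.finite(scale) || scale <= 0) stop("non-positive count scale")
  if (!is.null(seed)) set.seed(seed)
  counts <- stats::rpois(length(volume$data), pmax(volume$data, 0) * scale)
  out <- image_volume(array(counts / scale, dim = dim(volume$data)),
                      volume$voxel_size)
  attr(out, "spec") <- attr(volume, "spec")
  out
}

#' Simulate one reconstruction arm end to end
#'
#' Pipeline: static phantom (PSF-blurred) -> residual displacement
#' distribution under the arm's gate -> motion blur -> Poisson count noise
#' -> optional post-smoothing. Pass `trace = NULL` (or an arm with
#' `apply_motion = FALSE`) for the static reference.
#'
#' @param spec A [phantom_spec()].
#' @param trace Optional [respiratory_trace()] driving the motion.
#' @param arm A [recon_arm()].
#' @param seed Optional seed for the count noise.
#' @param noiseless If TRUE, skip the Poisson stage.
#' @param static_volume Optional precomputed [build_static_phantom()]
#'   result, to avoid rebuilding across arms.
#' @return An `image_volume` with attribute `arm`.
#' @export
simulate_arm <- function(spec, trace = NULL, arm, seed = NULL,
                         noiseless = FALSE, static_volume = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(arm, "recon_arm"))
  vol <- if (is.null(static_volume)) build_static_phantom(spec) else static_volume
  if (!is.null(trace) && isTRUE(arm$apply_motion)) {
    pdf <- residual_displacement_pdf(trace, arm$gate_mask,
                                     bin_width = spec$voxel_size / 2)
    vol <- apply_motion_blur(vol, pdf, spec$motion_axis)
  }
  if (!noiseless) vol <- apply_count_noise(vol, arm, seed)
  if (arm$post_smooth_fwhm > 0) vol <- smooth_volume(vol, arm$post_smooth_fwhm)
  attr(vol, "spec") <- spec
  attr(vol, "arm") <- arm$label
  vol
}
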