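voxel_grid_index <- function(volume, mask) which(mask)

# linear indices of an in-plane circular ROI on the slice nearest z
circle_roi_indices <- function(volume, center_xy, diameter, z = 0) {
  cx <- axis_coords(volume, 1)
  cy <- axis_coords(volume, 2)
  cz <- axis_coords(volume, 3)
  kz <- which.min(abs(cz - z))
  r <- diameter / 2
  ix <- which(abs(cx - center_xy[1]) <= r)
  iy <- which(abs(cy - center_xy[2]) <= r)
  d2 <- outer((cx[ix] - center_xy[1])^2, (cy[iy] - center_xy[2])^2, "+")
  sub <- which(d2 <= r^2, arr.ind = TRUE)
  if (!nrow(sub)) stop("ROI contains no voxels")
  n <- dim(volume$data)
  (ix[sub[, 1]]) + (iy[sub[, 2]] - 1L) * n[1] + (kz - 1L) * n[1] * n[2]
}

#' Linear indices of a spherical VOI
#'
#' @param volume An [image_volume()].
#' @param center World coordinates (mm) of the VOI centre.
#' @param diameter VOI diameter in mm.
#' @return Integer vector of linear voxel indices. Errors if the VOI is
#'   clipped by the grid boundary.
#' @export
spherical_voi <- function(volume, center, diameter) {
  stopifnot(inherits(volume, "image_volume"), length(center) == 3)
  r <- diameter / 2
  crd <- lapply(1:3, function(a) axis_coords(volume, a))
  for (a in 1:3) {
    if (center[a] - r < min(crd[[a]]) || center[a] + r > max(crd[[a]])) {
      stop("VOI is clipped by the volume boundary")
    }
  }
  idx <- lapply(1:3, function(a) which(abs(crd[[a]] - center[a]) <= r))
  d2 <- outer(outer((crd[[1]][idx[[1]]] - center[1])^2,
                    (crd[[2]][idx[[2]]] - center[2])^2, "+"),
              (crd[[3]][idx[[3]]] - center[3])^2, "+")
  sub <- which(d2 <= r^2, arr.ind = TRUE)
  if (!nrow(sub)) stop("VOI contains no voxels")
  n <- dim(volume$data)
  idx[[1]][sub[, 1]] + (idx[[2]][sub[, 2]] - 1L) * n[1] +
    (idx[[3]][sub[, 3]] - 1L) * n[1] * n[2]
}

#' Sphere and background ROI masks for the phantom
#'
#' One in-plane circular ROI per hot sphere, with the same inner diameter as
#' the sphere, on the sphere plane; and, per sphere diameter, 12 background
#' ROIs of that diameter placed at the configured background positions
#' (interleaving the sphere angles). Placement is validated: a background
#' ROI may neither overlap a sphere (15 mm clearance) nor approach the body
#' edge closer than 15 mm.
#'
#' @param volume An [image_volume()].
#' @param spec The matching [phantom_spec()].
#' @return List with `sphere` (list of index vectors, one per sphere),
#'   `background` (per sphere diameter, a list of 12 index vectors) and
#'   `sphere_mm`.
#' @export
sphere_rois <- function(volume, spec) {
  stopifnot(inherits(volume, "image_volume"), inherits(spec, "phantom_spec"))
  ctr <- sphere_centers(spec)
  diam <- spec$sphere_diameters
  ang <- spec$bg_angles_deg * pi / 180
  bg_xy <- cbind(spec$bg_ring_radius * cos(ang),
                 spec$bg_ring_radius * sin(ang))
  for (j in seq_along(diam)) {
    r_roi <- diam[j] / 2
    for (b in seq_len(nrow(bg_xy))) {
      d <- sqrt((bg_xy[b, 1] - ctr[, "x"])^2 + (bg_xy[b, 2] - ctr[, "y"])^2)
      if (any(d < r_roi + diam / 2 + spec$margin_mm)) {
        stop("background ROI collides with a hot sphere")
      }
      if (sqrt(sum(bg_xy[b, ]^2)) + r_roi + spec$margin_mm > spec$body_radius) {
        stop("background ROI too close to the body edge")
      }
    }
  }
  sph <- lapply(seq_along(diam), function(j) {
    circle_roi_indices(volume, ctr[j, c("x", "y")], diam[j], ctr[j, "z"])
  })
  bg <- lapply(seq_along(diam), function(j) {
    lapply(seq_len(nrow(bg_xy)), function(b) {
      circle_roi_indices(volume, bg_xy[b, ], diam[j], 0)
    })
  })
  list(sphere = sph, background = bg, sphere_mm = diam)
}

#' Contrast recovery (percent)
#'
#' `CR = ((C_H / C_B - 1) / (a_H / a_B - 1)) * 100`, where C_H and C_B are
#' the mean counts in the hot-sphere and background ROIs and a_H / a_B is
#' the true activity-concentration ratio. 100% means fully recovered
#' contrast.
#'
#' @param c_h Mean counts in the hot-sphere ROI.
#' @param c_b Mean background ROI counts (> 0).
#' @param contrast_ratio True ratio a_H / a_B (not 1).
#' @return CR in percent (vectorised).
#' @export
contrast_recovery <- function(c_h, c_b, contrast_ratio) {
  if (any(c_b <= 0)) stop("`c_b` must be > 0")
  if (any(contrast_ratio == 1)) stop("`contrast_ratio` must differ from 1")
  (c_h / c_b - 1) / (contrast_ratio - 1) * 100
}

#' Background variability (percent)
#'
#' `BV = (SD_bg / C_B) * 100`: the dispersion of the background measurements
#' relative to their mean.
#'
#' @param sd_bg Standard deviation of the background counts.
#' @param c_b Mean background counts (> 0).
#' @return BV in percent (vectorised).
#' @export
background_variability <- function(sd_bg, c_b) {
  if (any(c_b <= 0)) stop("`c_b` must be > 0")
  sd_bg / c_b * 100
}

#' Contrast-to-noise ratio
#'
#' CNR = CR / BV. Undefined (returned as `NA`, not infinity) when BV is 0.
#'
#' @param cr Contrast recovery, percent.
#' @param bv Background variability, percent.
#' @return CNR (vectorised), `NA` where `bv == 0`.
#' @export
cnr <- function(cr, bv) {
  out <- ifelse(bv == 0, NA_real_, cr / bv)
  if (any(bv == 0)) warning("CNR undefined where BV = 0; reported as NA")
  out
}

#' Full image-quality scoring of a phantom volume
#'
#' Computes per-sphere CR, BV and CNR. `bv_mode = "roi"` (the NEMA-style
#' default) takes the SD across the 12 background ROI means;
#' `bv_mode = "voxel"` pools all background ROI voxels and uses their SD.
#'
#' @param volume An [image_volume()] produced from `spec`.
#' @param spec The [phantom_spec()].
#' @param bv_mode `"roi"` or `"voxel"`.
#' @param rois Optional precomputed [sphere_rois()] result.
#' @return Data frame with columns `sphere_mm`, `C_H`, `C_B`, `SD_bg`,
#'   `CR`, `BV`, `CNR`.
#' @export
measure_iq <- function(volume, spec, bv_mode = c("roi", "voxel"),
                       rois = NULL) {
  bv_mode <- match.arg(bv_mode)
  if (is.null(rois)) rois <- sphere_rois(volume, spec)
  v <- volume$data
  res <- lapply(seq_along(rois$sphere_mm), function(j) {
    c_h <- mean(v[rois$sphere[[j]]])
    means <- vapply(rois$background[[j]], function(i) mean(v[i]), numeric(1))
    c_b <- mean(means)
    sd_bg <- if (bv_mode == "roi") {
      stats::sd(means)
    } else {
      stats::sd(v[unlist(rois$background[[j]])])
    }
    cr <- contrast_recovery(c_h, c_b, spec$contrast_ratio)
    bv <- background_variability(sd_bg, c_b)
    data.frame(sphere_mm = rois$sphere_mm[j], C_H = c_h, C_B = c_b,
               SD_bg = sd_bg, CR = cr, BV = bv,
               CNR = if (bv == 0) NA_real_ else cr / bv)
  })
  do.call(rbind, res)
}

#' Liver-noise statistics in a spherical VOI
#'
#' Mean, SD and SNR = mean / SD over a spherical VOI placed in uniform
#' background ("disease-free liver"), 30 mm diameter by convention.
#'
#' @param volume An [image_volume()].
#' @param voi_center World coordinates (mm); default the grid centre.
#' @param voi_diameter VOI diameter in mm (default 30).
#' @return List of class `liver_noise` with `voi_mean`, `voi_sd`, `snr`,
#'   `voi_diameter`, `n_voxels`. Errors when the VOI has zero variance.
#' @export
liver_snr <- function(volume, voi_center = c(0, 0, 0), voi_diameter = 30) {
  idx <- spherical_voi(volume, voi_center, voi_diameter)
  v <- volume$data[idx]
  s <- stats::sd(v)
  if (s == 0) stop("VOI has zero variance; SNR undefined")
  structure(
    list(voi_mean = mean(v), voi_sd = s, snr = mean(v) / s,
         voi_diameter = voi_diameter, n_voxels = length(idx)),
    class = "liver_noise"
  )
}

#' @export
print.liver_noise <- function(x, ...) {
  cat(sprintf("<liver_noise> mean %.4g, SD %.4g, SNR %.3f (%d voxels, %g mm VOI)\n",
              x$voi_mean, x$voi_sd, x$snr, x$n_voxels, x$voi_diameter))
  invisible(x)
}

#' Maximum uptake value in a lesion VOI
#'
#' Simulator units are activity-relative, so no dose/weight normalisation
#' is applied: "SUVmax" is the maximum voxel value in the VOI.
#'
#' @param volume An [image_volume()].
#' @param lesion_voi Either a vector of linear voxel indices or a list with
#'   `center` (mm) and `diameter` (mm).
#' @return Maximum voxel value.
#' @export
suv_max <- function(volume, lesion_voi) {
  idx <- if (is.list(lesion_voi)) {
    spherical_voi(volume, lesion_voi$center, lesion_voi$diameter)
  } else {
    lesion_voi
  }
  if (!length(idx)) stop("empty lesion VOI")
  max(volume$data[idx])
}
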