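#' Image volume container
#'
#' A simple 3D voxel grid of activity values with isotropic voxel size. The
#' world origin sits at the grid centre, so voxel (i, j, k) has world
#' coordinate `(i - (n + 1) / 2) * voxel_size` along each axis.
#'
#' @param data 3D numeric array of activity values (finite).
#' @param voxel_size Isotropic voxel edge length in mm.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, voxel_size) {
  if (!is.array(data) || length(dim(data)) != 3) {
    stop("`data` must be a 3D array")
  }
  if (!all(is.finite(data))) stop("volume values must be finite")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0) {
    stop("`voxel_size` must be a positive scalar (mm)")
  }
  structure(list(data = data, voxel_size = voxel_size), class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %dx%dx%d voxels @ %.2f mm, range [%.3g, %.3g]\n",
              d[1], d[2], d[3], x$voxel_size, min(x$data), max(x$data)))
  invisible(x)
}

# world coordinates of voxel centres along one axis
axis_coords <- function(volume, axis) {
  n <- dim(volume$data)[axis]
  (seq_len(n) - (n + 1) / 2) * volume$voxel_size
}

# apply an n x n kernel matrix along one array axis
axis_filter <- function(arr, K, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = d[axis])
  out <- array(K %*% m, dim = d[perm])
  aperm(out, order(perm))
}

# kernel matrix whose column j holds a unit-mass kernel centred on row j;
# truncation at the grid edge loses mass only through the boundary faces
kernel_matrix <- function(n, offsets, weights) {
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    idx <- j + offsets
    ok <- idx >= 1 & idx <= n
    K[idx[ok], j] <- weights[ok]
  }
  K
}

gaussian_kernel <- function(sigma_vox) {
  half <- max(1L, ceiling(4 * sigma_vox))
  off <- (-half):half
  w <- stats::dnorm(off, sd = sigma_vox)
  list(offsets = off, weights = w / sum(w))
}

#' Isotropic Gaussian smoothing of a volume
#'
#' Separable Gaussian convolution along all three axes; kernel mass is
#' normalised so total activity of interior structures is conserved.
#'
#' @param volume An [image_volume()].
#' @param fwhm_mm Full width at half maximum in mm; 0 returns the input.
#' @return Smoothed `image_volume`.
#' @export
smooth_volume <- function(volume, fwhm_mm) {
  stopifnot(inherits(volume, "image_volume"))
  if (fwhm_mm < 0) stop("`fwhm_mm` must be >= 0")
  if (fwhm_mm == 0) return(volume)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / volume$voxel_size
  k <- gaussian_kernel(sigma_vox)
  arr <- volume$data
  for (axis in 1:3) {
    K <- kernel_matrix(dim(arr)[axis], k$offsets, k$weights)
    arr <- axis_filter(arr, K, axis)
  }
  out <- image_volume(arr, volume$voxel_size)
  attributes(out) <- utils::modifyList(attributes(volume), attributes(out))
  out
}

#' Write / read a volume as NIfTI
#'
#' @param volume An [image_volume()].
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @return `path` invisibly, or the read `image_volume`.
#' @export
write_volume_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- rep(volume$voxel_size, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  image_volume(array(as.numeric(img), dim = dim(img)),
               RNifti::pixdim(img)[1])
}
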