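#' Gaussian point spread function on a voxel grid
#'
#' Builds a separable 3D Gaussian PSF sampled at voxel centres, the standard
#' approximation for a confocal PSF. The kernel is normalized to sum to one
#' and has odd extent along every axis; the `truncate` parameter controls
#' where the Gaussian is cut (half-extent = `ceiling(truncate * sigma / d)`
#' voxels per axis), so `truncate -> 0` degenerates to a single-voxel delta
#' kernel.
#'
#' @param sigma_xy lateral standard deviation in um (default 0.2).
#' @param sigma_z axial standard deviation in um (default 0.5).
#' @param voxel_dims voxel dimensions `c(dx, dy, dz)` in um.
#' @param truncate cut-off in units of sigma (default 3).
#' @return an object of class `"psf"`: list with `kernel` (3D array summing
#'   to 1), `voxel_dims`, `sigma_xy`, `sigma_z` and the separable 1D factors
#'   `kx`, `ky`, `kz` (each normalized to sum 1).
#' @examples
#' psf <- make_psf(0.2, 0.5, voxel_dims = c(0.11, 0.11, 0.2))
#' sum(psf$kernel)
#' @export
make_psf <- function(sigma_xy = 0.2, sigma_z = 0.5,
                     voxel_dims = c(0.11, 0.11, 0.2), truncate = 3) {
  check_scalar_pos(sigma_xy, "sigma_xy")
  check_scalar_pos(sigma_z, "sigma_z")
  voxel_dims <- check_voxel_dims(voxel_dims)
  abort_if(!is.numeric(truncate) || length(truncate) != 1L || truncate < 0,
           "`truncate` must be a single non-negative number")

  gauss_1d <- function(sigma, d) {
    h <- ceiling(truncate * sigma / d)
    u <- (-h:h) * d
    k <- exp(-0.5 * (u / sigma)^2)
    k / sum(k)
  }
  kx <- gauss_1d(sigma_xy, voxel_dims[1])
  ky <- gauss_1d(sigma_xy, voxel_dims[2])
  kz <- gauss_1d(sigma_z, voxel_dims[3])
  kernel <- outer(outer(kx, ky), kz)
  kernel <- kernel / sum(kernel)
  structure(list(kernel = kernel, voxel_dims = voxel_dims,
                 sigma_xy = sigma_xy, sigma_z = sigma_z,
                 kx = kx, ky = ky, kz = kz),
            class = "psf")
}

#' @export
print.psf <- function(x, ...) {
  cat(sprintf("Gaussian PSF: sigma_xy = %g um, sigma_z = %g um, extent %s voxels\n",
              x$sigma_xy, x$sigma_z, paste(dim(x$kernel), collapse = " x ")))
  invisible(x)
}

is_delta_psf <- function(psf) {
  all(dim(psf$kernel) == c(1L, 1L, 1L))
}

# Convolve a 3D grid with a PSF (reflective boundaries). Uses the separable
# factors when present, otherwise the dense kernel.
psf_convolve <- function(grid, psf, flip = FALSE) {
  dims <- dim(grid)
  abort_if(is.null(dims) || length(dims) != 3L, "grid must be a 3D array")
  abort_if(any(dim(psf$kernel) > dims),
           "PSF kernel is larger than the image grid along some axis")
  if (!is.null(psf$kx)) {
    # separable Gaussians are symmetric: flip is a no-op
    out <- cq_convolve_sep(as.numeric(grid), as.integer(dims),
                           psf$kx, psf$ky, psf$kz)
  } else {
    out <- cq_convolve_full(as.numeric(grid), as.integer(dims),
                            as.numeric(psf$kernel), as.integer(dim(psf$kernel)),
                            flip)
  }
  array(out, dims)
}
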