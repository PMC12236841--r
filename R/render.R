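#' Render a synthetic confocal stack from planted ground truth
#'
#' Rasterizes every planted punctum as a solid ellipsoid of its ground-truth
#' volume (axial elongation equal to the PSF anisotropy `sigma_z/sigma_xy`),
#' draws the hair-cell channel as filled cell footprints, convolves each
#' channel with the PSF, and applies a Poisson (shot) + Gaussian (read) noise
#' model on top of a constant background. Default acquisition geometry is a
#' 0.11 um pixel; the z-step is set by `voxel_dims` (0.2 um default for
#' volumetric-style stacks, 0.3 um for counting-style stacks).
#'
#' @param gt a [plant_ground_truth()] object.
#' @param psf a [make_psf()] object (delta PSF allowed).
#' @param noise list with `photons` (peak photon scale of a punctum),
#'   `read_sigma` (Gaussian read noise SD), `background` (constant offset)
#'   and `poisson` (logical; apply shot noise). Use
#'   `list(photons = 1, read_sigma = 0, background = 0, poisson = FALSE)`
#'   for a noise-free render.
#' @param voxel_dims voxel dimensions `c(dx, dy, dz)` in um.
#' @param shape integer grid shape `c(nx, ny, nz)`; default derived from the
#'   ground-truth field extent.
#' @param cell_intensity intensity of the cell-body channel relative to
#'   `photons` (default 0.35).
#' @param seed integer seed for the noise draws.
#' @return an object of class `"confocal_stack"`: list with `channels`
#'   (named list `ribbon`, `receptor`, `cell` of 3D arrays, all the same
#'   shape), `voxel_dims` and `meta`.
#' @export
render_stack <- function(gt, psf = make_psf(),
                         noise = list(photons = 150, read_sigma = 2,
                                      background = 10, poisson = TRUE),
                         voxel_dims = c(0.11, 0.11, 0.2), shape = NULL,
                         cell_intensity = 0.35, seed = 1) {
  abort_if(!inherits(gt, "ground_truth"), "`gt` must be a ground_truth object")
  abort_if(!inherits(psf, "psf"), "`psf` must be a psf object")
  voxel_dims <- check_voxel_dims(voxel_dims)
  noise <- utils::modifyList(list(photons = 150, read_sigma = 2,
                                  background = 10, poisson = TRUE), noise)
  if (is.null(shape)) shape <- ceiling(gt$field$extent_um / voxel_dims)
  shape <- as.integer(shape)
  extent <- shape * voxel_dims

  elong <- psf$sigma_z %||% NULL
  elong <- if (!is.null(psf$sigma_xy) && !is.null(psf$sigma_z))
    psf$sigma_z / psf$sigma_xy else 2.5

  p <- gt$puncta
  if (nrow(p)) {
    a <- (p$volume_um3 / ((4 / 3) * pi * elong))^(1 / 3)
    cc <- elong * a
    bad <- p$x_um - a < 0 | p$x_um + a > extent[1] |
      p$y_um - a < 0 | p$y_um + a > extent[2] |
      p$z_um - cc < 0 | p$z_um + cc > extent[3]
    abort_if(any(bad), sprintf(
      "puncta outside the rendered field: %s",
      paste(p$punctum_id[bad], collapse = ", ")))
  }

  raster_channel <- function(ch) {
    grid <- numeric(prod(shape))
    dim(grid) <- shape
    idx <- which(p$channel == ch)
    if (length(idx)) {
      a <- (p$volume_um3[idx] / ((4 / 3) * pi * elong))^(1 / 3)
      grid <- cq_add_ellipsoids(
        as.numeric(grid), shape,
        p$x_um[idx] / voxel_dims[1] - 0.5,
        p$y_um[idx] / voxel_dims[2] - 0.5,
        p$z_um[idx] / voxel_dims[3] - 0.5,
        a / voxel_dims[1], a / voxel_dims[2], elong * a / voxel_dims[3],
        rep(1, length(idx)))
    }
    array(grid, shape)
  }

  cell_grid <- numeric(prod(shape))
  dim(cell_grid) <- shape
  if (nrow(gt$cells)) {
    nz <- shape[3]
    cell_grid <- cq_add_ellipsoids(
      as.numeric(cell_grid), shape,
      rep(gt$cells$cx_um / voxel_dims[1] - 0.5, each = 1),
      gt$cells$cy_um / voxel_dims[2] - 0.5,
      rep((nz - 1) / 2, nrow(gt$cells)),
      gt$cells$ax_um / voxel_dims[1],
      gt$cells$ay_um / voxel_dims[2],
      rep(nz, nrow(gt$cells)),  # spans all slices
      rep(cell_intensity, nrow(gt$cells)))
  }
  cell_grid <- array(cell_grid, shape)

  withr::with_seed(seed, {
    channels <- list(ribbon = raster_channel("ribbon"),
                     receptor = raster_channel("receptor"),
                     cell = cell_grid)
    channels <- lapply(channels, function(g) {
      blurred <- psf_convolve(g, psf)
      signal <- noise$background + noise$photons * blurred
      out <- if (isTRUE(noise$poisson))
        array(rpois(length(signal), pmax(signal, 0)), shape)
      else signal
      if (noise$read_sigma > 0)
        out <- out + array(rnorm(length(out), 0, noise$read_sigma), shape)
      pmax(out, 0)
    })
    abort_if(max(vapply(channels, max, numeric(1))) >= 65535,
             "rendered intensities saturate the 16-bit range")
    structure(list(channels = channels, voxel_dims = voxel_dims,
                   meta = list(seed = seed, noise = noise,
                               region_label = gt$cells$region_label[1] %||% NA,
                               psf = list(sigma_xy = psf$sigma_xy,
                                          sigma_z = psf$sigma_z))),
              class = "confocal_stack")
  })
}

#' @export
print.confocal_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("Confocal stack: %d x %d x %d voxels (%g x %g x %g um), channels: %s\n",
              d[1], d[2], d[3], x$voxel_dims[1], x$voxel_dims[2],
              x$voxel_dims[3], paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Rasterize ground-truth puncta into a binary voxel mask
#'
#' Noise- and blur-free rasterization of the planted puncta of one channel,
#' used as the oracle for rendering-conservation and footprint tests.
#'
#' @inheritParams render_stack
#' @param channel `"ribbon"` or `"receptor"`.
#' @param elongation axial elongation of the rendered ellipsoids; must match
#'   the PSF anisotropy used at render time (default 0.5/0.2).
#' @return logical 3D array.
#' @export
rasterize_ground_truth <- function(gt, channel = c("ribbon", "receptor"),
                                   voxel_dims = c(0.11, 0.11, 0.2),
                                   shape = NULL, elongation = 2.5) {
  channel <- match.arg(channel)
  voxel_dims <- check_voxel_dims(voxel_dims)
  if (is.null(shape)) shape <- ceiling(gt$field$extent_um / voxel_dims)
  shape <- as.integer(shape)
  p <- gt$puncta[gt$puncta$channel == channel, , drop = FALSE]
  grid <- numeric(prod(shape))
  if (nrow(p)) {
    a <- (p$volume_um3 / ((4 / 3) * pi * elongation))^(1 / 3)
    grid <- cq_add_ellipsoids(
      grid, shape,
      p$x_um / voxel_dims[1] - 0.5, p$y_um / voxel_dims[2] - 0.5,
      p$z_um / voxel_dims[3] - 0.5,
      a / voxel_dims[1], a / voxel_dims[2], elongation * a / voxel_dims[3],
      rep(1, nrow(p)))
  }
  array(grid > 0, shape)
}
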