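#' Richardson-Lucy deconvolution of a 3D stack
#'
#' Iterative multiplicative restoration of a blurred, photon-limited image
#' given a normalized PSF:
#' \deqn{e_{k+1} = e_k \cdot \left[\frac{g}{e_k \otimes h} \otimes h^T\right]}
#' with reflective boundary handling (avoids edge ringing on small fields).
#' Ten iterations is the conventional stopping point for confocal whole-mount
#' material and the package default.
#'
#' @param grid 3D non-negative intensity array.
#' @param psf a [make_psf()] object; the kernel must sum to 1 and fit inside
#'   the grid.
#' @param n_iter number of iterations (default 10); `n_iter = 0` returns the
#'   input unchanged.
#' @param eps numerical floor guarding the ratio against division by zero.
#' @return deconvolved 3D array, non-negative, same shape as input.
#' @export
richardson_lucy <- function(grid, psf, n_iter = 10, eps = 1e-12) {
  abort_if(is.null(dim(grid)) || length(dim(grid)) != 3L,
           "`grid` must be a 3D array")
  abort_if(!inherits(psf, "psf"), "`psf` must be a psf object")
  abort_if(any(dim(psf$kernel) > dim(grid)),
           "PSF kernel is larger than the image grid")
  abort_if(!is.numeric(n_iter) || n_iter < 0, "`n_iter` must be >= 0")
  abort_if(abs(sum(psf$kernel) - 1) > 1e-6, "PSF kernel must sum to 1")
  if (n_iter == 0) return(grid)
  if (is_delta_psf(psf)) return(grid)

  est <- grid
  for (i in seq_len(n_iter)) {
    conv <- psf_convolve(est, psf)
    ratio <- grid / pmax(conv, eps)
    est <- est * psf_convolve(ratio, psf, flip = TRUE)
  }
  pmax(est, 0)
}
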