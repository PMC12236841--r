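#' Maximum intensity projection of a z-stack channel
#'
#' @param grid 3D intensity array (x, y, z).
#' @return 2D matrix: pixel (x, y) = max over z.
#' @export
max_projection <- function(grid) {
  abort_if(is.null(dim(grid)) || length(dim(grid)) != 3L || length(grid) == 0,
           "`grid` must be a non-empty 3D array")
  apply(grid, c(1, 2), max)
}

#' Binarize an image with a configurable thresholding method
#'
#' Two scale-covariant methods are provided: `"robust_background"`
#' (median + k * MAD, default k = 4) and `"otsu"`. The threshold actually
#' used is attached to the result (`attr(mask, "threshold")`) so every run
#' is auditable.
#'
#' @param image numeric matrix (2D) or array.
#' @param method `"robust_background"` (default) or `"otsu"`.
#' @param k MAD multiplier for the robust-background method.
#' @param threshold explicit numeric threshold overriding `method`.
#' @return logical mask of the same shape, TRUE where `image > threshold`.
#' @export
binarize <- function(image, method = c("robust_background", "otsu"), k = 4,
                     threshold = NULL) {
  abort_if(!is.numeric(image) || length(image) == 0,
           "`image` must be a non-empty numeric array")
  thr <- if (!is.null(threshold)) threshold else
    resolve_threshold(image, method = match.arg(method), k = k)
  mask <- image > thr
  attr(mask, "threshold") <- thr
  mask
}

#' Pixelwise product of two projections
#'
#' Multiplies two single-channel maximum projections into a merged
#' wide-dynamic-range image (the colocalization image that is subsequently
#' binarized and particle-counted). Accumulation is in double precision, so
#' 8- or 16-bit inputs cannot overflow.
#'
#' @param a,b numeric matrices of identical shape.
#' @return numeric matrix `a * b`.
#' @export
product_image <- function(a, b) {
  abort_if(!identical(dim(a), dim(b)), "`a` and `b` must have the same shape")
  as.matrix(a) * as.matrix(b)
}
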