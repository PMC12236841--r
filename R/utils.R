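# Shared validation and numeric helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, msg) {
  if (isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(NULL)
}

check_scalar_pos <- function(x, name) {
  abort_if(!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0,
           sprintf("`%s` must be a single positive finite number", name))
}

check_voxel_dims <- function(voxel_dims) {
  abort_if(!is.numeric(voxel_dims) || length(voxel_dims) != 3L ||
             any(!is.finite(voxel_dims)) || any(voxel_dims <= 0),
           "`voxel_dims` must be three positive numbers (dx, dy, dz) in um")
  as.numeric(voxel_dims)
}

rms <- function(x) sqrt(mean(x^2))

db_to_amp <- function(db, p_ref = 1) p_ref * 10^(db / 20)
amp_to_db <- function(a, p_ref = 1) 20 * log10(a / p_ref)

#' Robust background threshold (median + k * MAD)
#'
#' Scale-covariant threshold used throughout the counting and volumetric
#' pipelines: the background level is estimated by the median of all
#' intensities and its spread by the median absolute deviation (MAD, scaled
#' to be consistent with the standard deviation under normality).
#'
#' @param x numeric vector or array of intensities.
#' @param k MAD multiplier (default 4).
#' @return scalar threshold `median(x) + k * mad(x)`.
#' @export
robust_background_threshold <- function(x, k = 4) {
  check_scalar_pos(k, "k")
  median(x) + k * mad(x)
}

# Otsu's threshold computed from a 256-bin histogram of the data range.
# EBImage::otsu operates on [0,1] grayscale frames, so intensities are
# rescaled into [0,1] and the returned break point mapped back. Works for 2D
# and 3D grids alike because the criterion is histogram-based.
otsu_threshold <- function(x, levels = 256L) {
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  scaled <- (x - r[1]) / (r[2] - r[1])
  thr01 <- EBImage::otsu(EBImage::Image(matrix(as.numeric(scaled), nrow = 1L)),
                         range = c(0, 1), levels = levels)
  r[1] + thr01 * (r[2] - r[1])
}

resolve_threshold <- function(x, method = c("robust_background", "otsu"),
                              k = 4) {
  method <- match.arg(method)
  switch(method,
         robust_background = robust_background_threshold(x, k = k),
         otsu = otsu_threshold(x))
}

# Deterministic child seeds below 2^31 derived from a base seed.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 2011 + 7919 * as.numeric(i)) %% 2147483629)
}
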