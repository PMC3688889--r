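# Preprocessing of raw fiber-bundle microendoscope frames: crop away the
# bundle rim, then low-pass the honeycomb fiber-core sampling pattern.
# Phantom images have neither artifact and bypass this stage.

#' Crop a frame to the fiber-bundle field of view
#'
#' Detects the circular field of view (Otsu threshold on a heavily smoothed
#' copy, largest connected component, circle fit from its area and centroid)
#' and returns the largest inscribed axis-aligned square (side
#' `floor(r * sqrt(2))`), or the circular mask itself. Output is normalized
#' to `[0, 1]`.
#'
#' @param raw 2-D single-channel image matrix.
#' @param method `"square"` (inscribed square crop) or `"circle"` (full
#'   frame with pixels outside the fitted circle zeroed).
#' @param enabled Set `FALSE` to pass the image through untouched (the
#'   phantom path).
#' @param min_radius Smallest acceptable bundle radius in pixels.
#' @return Cropped image matrix in `[0, 1]`; the fitted circle is attached
#'   as attribute `"fov"` (`center_row`, `center_col`, `radius`).
#' @export
crop_fov <- function(raw, method = c("square", "circle"), enabled = TRUE,
                     min_radius = 16) {
  stop_if_not_image(raw, "raw")
  if (!enabled) return(raw)
  method <- match.arg(method)
  x <- normalize01(raw)
  smooth <- gaussian_blur(x, sigma = max(4, min(dim(x)) / 64))
  if (max(smooth) <= 0) stop("no fiber bundle detected (dark frame)",
                             call. = FALSE)
  thr <- EBImage::otsu(EBImage::Image(smooth), range = c(0, 1))
  mask <- smooth > thr
  if (!any(mask)) stop("no fiber bundle detected", call. = FALSE)
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(mask * 1)))
  counts <- tabulate(lab[lab > 0])
  big <- which.max(counts)
  sel <- lab == big
  area <- sum(sel)
  idx <- which(sel, arr.ind = TRUE)
  ctr <- colMeans(idx)
  radius <- sqrt(area / pi)
  if (radius < min_radius) stop("no fiber bundle detected (region too small)",
                                call. = FALSE)
  out <- if (method == "square") {
    half <- floor(radius * sqrt(2)) / 2
    rr <- max(1, ceiling(ctr[1] - half)):min(nrow(x), floor(ctr[1] + half))
    cc <- max(1, ceiling(ctr[2] - half)):min(ncol(x), floor(ctr[2] + half))
    x[rr, cc, drop = FALSE]
  } else {
    d2 <- outer((seq_len(nrow(x)) - ctr[1])^2,
                (seq_len(ncol(x)) - ctr[2])^2, `+`)
    x * (d2 <= radius^2)
  }
  out <- normalize01(out)
  attr(out, "fov") <- c(center_row = unname(ctr[1]),
                        center_col = unname(ctr[2]), radius = radius)
  out
}

#' Low-pass away the fiber-core sampling pattern
#'
#' Applies a normalized Gaussian low-pass with `sigma = core_spacing / 2`
#' (by default), which attenuates power at spatial frequencies at and above
#' `1 / core_spacing` -- the honeycomb carrier of a coherent fiber bundle --
#' by far more than 90% while preserving the image mean. The result is
#' clipped to `[0, 1]` (a no-op for in-range input, since the kernel is a
#' convex averaging).
#'
#' @param img 2-D image matrix in `[0, 1]`.
#' @param core_spacing Center-to-center fiber core spacing in pixels; > 0.
#' @param sigma Gaussian standard deviation in pixels; defaults to
#'   `core_spacing / 2`.
#' @return Filtered image matrix in `[0, 1]`.
#' @export
remove_fiber_pattern <- function(img, core_spacing, sigma = core_spacing / 2) {
  stop_if_not_image(img, "img")
  if (!is.numeric(core_spacing) || length(core_spacing) != 1 ||
      core_spacing <= 0) {
    stop("core_spacing must be a positive number of pixels", call. = FALSE)
  }
  clamp01(gaussian_blur(img, sigma))
}
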