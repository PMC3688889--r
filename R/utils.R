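# Internal helpers shared across modules.

#' @importFrom stats rnorm runif quantile sd fft
#' @importFrom utils head tail
NULL

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library calls do not perturb user simulations.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

rms <- function(x) sqrt(mean(x^2))

#' @noRd
stop_if_not_image <- function(x, name = "image") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a 2-D numeric matrix", name), call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  }
  invisible(x)
}

# Rescale an arbitrary numeric matrix to [0, 1]; constant input maps to 0.
normalize01 <- function(x) {
  rng <- range(x)
  if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else x * 0
}

# Gaussian blur on a plain matrix, kernel normalized to unit sum (energy
# conserving under the circular boundary used by EBImage::filter2).
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  as.matrix(EBImage::gblur(x, sigma = sigma))
}

# Area of an image in mm^2 given its shape (rows, cols) and pixel size in um.
image_area_mm2 <- function(shape, pixel_size) {
  prod(shape) * pixel_size^2 / 1e6
}

# mm^2 -> expected nucleus count at a density expressed per 0.25 mm^2.
density_to_count <- function(density, area_mm2) {
  as.integer(round(density * area_mm2 / 0.25))
}

count_to_density <- function(count, area_mm2) {
  count / area_mm2 * 0.25
}

#' Read a single-channel image from a TIFF or PNG file
#'
#' Multi-channel input is averaged to grayscale; intensities are normalized
#' to `[0, 1]` (integer types by their dtype maximum -- handled by the
#' readers -- float input by its own maximum when it exceeds 1).
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return A numeric matrix with values in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(x)) == 3) x <- apply(x, c(1, 2), mean)
  x <- as.matrix(x)
  if (max(x) > 1) x <- x / max(x)
  clamp01(x)
}

#' Write a grayscale image to TIFF (32-bit float) or PNG
#'
#' @param x Numeric matrix in `[0, 1]` (clipped on write).
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  x <- clamp01(x)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(x, path, bits.per.sample = 32L),
    png = png::writePNG(x, path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  invisible(path)
}
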