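#' Phantom specification for simulated sarcoma-margin images
#'
#' Bundles every parameter of the synthetic tumor / muscle / tumor+muscle
#' generators. Defaults reflect the tissue characteristics the simulations
#' emulate: nuclei are uniform disks blurred with a Gaussian of standard
#' deviation 1.1 px (the gradual intensity falloff of real stained nuclei),
#' diameters span 4-18 px at 0.83 um/px (4-15 um), densities 60-900 nuclei
#' per 0.25 mm2, and muscle appears as smooth longitudinal fibers whose
#' maximum intensity anchors the tumor-to-muscle contrast ratio.
#'
#' @param image_shape Integer `(rows, cols)` in pixels.
#' @param pixel_size Pixel pitch in um/pixel.
#' @param nucleus_diameter Nucleus diameter(s) in pixels; a vector means each
#'   nucleus draws its diameter uniformly from the vector.
#' @param density Nuclei per 0.25 mm2 of image area.
#' @param blur_sigma Standard deviation, in pixels, of the Gaussian blur
#'   applied to the drawn disks.
#' @param peak_intensity Peak disk intensity before blurring, in `(0, 1]`.
#' @param muscle_period Stripe period of the muscle fiber pattern, pixels.
#' @param muscle_orientation Fiber orientation in degrees (0 = horizontal
#'   fibers, i.e. intensity varies along rows).
#' @param muscle_amplitude Maximum intensity of the muscle pattern.
#' @param muscle_modulation Relative depth in `[0, 1)` of a slow sinusoidal
#'   amplitude modulation along the fibers (0 = perfectly periodic stripes).
#' @param contrast_ratio Maximum nuclei intensity divided by maximum muscle
#'   intensity for composite images; must be >= 1.
#' @param noise_sigma Standard deviation of optional additive Gaussian noise
#'   (0 disables it; the model treats noise as a small Gaussian deviation).
#' @param seed Integer seed; phantoms are bit-reproducible given the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_shape = c(256L, 256L),
                         pixel_size = 0.83,
                         nucleus_diameter = 10,
                         density = 300,
                         blur_sigma = 1.1,
                         peak_intensity = 1,
                         muscle_period = 20,
                         muscle_orientation = 0,
                         muscle_amplitude = 0.5,
                         muscle_modulation = 0.1,
                         contrast_ratio = 1.5,
                         noise_sigma = 0,
                         seed = 1L) {
  image_shape <- as.integer(image_shape)
  stopifnot(length(image_shape) == 2, all(image_shape >= 8))
  if (pixel_size <= 0) stop("pixel_size must be positive", call. = FALSE)
  if (any(nucleus_diameter <= 0)) {
    stop("nucleus_diameter must be positive", call. = FALSE)
  }
  if (density < 0) stop("density must be >= 0", call. = FALSE)
  if (blur_sigma <= 0) stop("blur_sigma must be > 0", call. = FALSE)
  if (peak_intensity <= 0 || peak_intensity > 1) {
    stop("peak_intensity must lie in (0, 1]", call. = FALSE)
  }
  if (muscle_period <= 2) stop("muscle_period must exceed 2 px", call. = FALSE)
  if (contrast_ratio < 1) stop("contrast_ratio must be >= 1", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  structure(list(
    image_shape = image_shape, pixel_size = pixel_size,
    nucleus_diameter = nucleus_diameter, density = density,
    blur_sigma = blur_sigma, peak_intensity = peak_intensity,
    muscle_period = muscle_period, muscle_orientation = muscle_orientation,
    muscle_amplitude = muscle_amplitude,
    muscle_modulation = muscle_modulation,
    contrast_ratio = contrast_ratio, noise_sigma = noise_sigma,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

empty_truth <- function() {
  data.frame(region_id = integer(), row = numeric(), col = numeric(),
             radius_px = numeric(), diameter_um = numeric(),
             peak_intensity = numeric())
}

new_phantom_image <- function(pixels, truth, tissue_label, spec,
                              regions = NULL) {
  stopifnot(min(pixels) >= 0, max(pixels) <= 1)
  structure(list(pixels = pixels, truth = truth,
                 tissue_label = tissue_label, spec = spec,
                 regions = regions),
            class = "phantom_image")
}

#' @export
print.phantom_image <- function(x, ...) {
  cat(sprintf("phantom_image <%s>: %d x %d px, %d nuclei, pixel %.3g um\n",
              x$tissue_label, nrow(x$pixels), ncol(x$pixels),
              nrow(x$truth), x$spec$pixel_size))
  invisible(x)
}

# Draw one batch of nuclei into `canvas` (max composition so overlapping
# nuclei saturate rather than sum above the peak). Centers are uniform
# within [lo + r, hi - r] so every disk lies fully inside its region.
draw_nuclei <- function(canvas, n, diameters, peak, row_lim, col_lim,
                        region_id) {
  truth <- empty_truth()
  if (n == 0) return(list(canvas = canvas, truth = truth))
  radii <- if (length(diameters) == 1) rep(diameters, n) else
    sample(diameters, n, replace = TRUE)
  radii <- radii / 2
  rmax <- max(radii)
  if (row_lim[2] - row_lim[1] < 2 * rmax || col_lim[2] - col_lim[1] < 2 * rmax) {
    stop("nuclei too large for the target region: placement impossible",
         call. = FALSE)
  }
  rows <- runif(n, row_lim[1] + radii, row_lim[2] - radii)
  cols <- runif(n, col_lim[1] + radii, col_lim[2] - radii)
  for (i in seq_len(n)) {
    r <- radii[i]
    rr <- floor(rows[i] - r):ceiling(rows[i] + r)
    cc <- floor(cols[i] - r):ceiling(cols[i] + r)
    rr <- rr[rr >= 1 & rr <= nrow(canvas)]
    cc <- cc[cc >= 1 & cc <= ncol(canvas)]
    d2 <- outer((rr - rows[i])^2, (cc - cols[i])^2, `+`)
    patch <- canvas[rr, cc, drop = FALSE]
    canvas[rr, cc] <- pmax(patch, ifelse(d2 <= r^2, peak, 0))
  }
  list(canvas = canvas,
       truth = data.frame(region_id = region_id, row = rows, col = cols,
                          radius_px = radii, diameter_um = NA_real_,
                          peak_intensity = peak))
}

finalize_phantom <- function(canvas, spec, truth, tissue_label,
                             regions = NULL, blur = TRUE) {
  if (blur && spec$blur_sigma > 0) {
    canvas <- gaussian_blur(canvas, spec$blur_sigma)
  }
  if (spec$noise_sigma > 0) {
    canvas <- canvas + matrix(rnorm(length(canvas), sd = spec$noise_sigma),
                              nrow(canvas))
  }
  canvas <- clamp01(canvas)
  if (nrow(truth) > 0) {
    truth$diameter_um <- 2 * truth$radius_px * spec$pixel_size
  }
  new_phantom_image(canvas, truth, tissue_label, spec, regions)
}

#' Simulate a tumor phantom (randomly placed blurred nuclear disks)
#'
#' Draws `round(density * area_mm2 / 0.25)` uniform disks at uniformly random
#' locations (overlaps permitted, composed by maximum), blurs the field with
#' a Gaussian of `blur_sigma` pixels, and returns the image together with the
#' ground-truth nucleus list.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_image` with `tissue_label = "tumor"`.
#' @export
simulate_tumor <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (any(spec$nucleus_diameter < 1 | spec$nucleus_diameter > 30)) {
    stop("nucleus_diameter outside the supported 1-30 px range",
         call. = FALSE)
  }
  n <- density_to_count(spec$density,
                        image_area_mm2(spec$image_shape, spec$pixel_size))
  if (n > prod(spec$image_shape)) {
    stop("density implies more nuclei than pixels: placement impossible",
         call. = FALSE)
  }
  with_seed(spec$seed, {
    canvas <- matrix(0, spec$image_shape[1], spec$image_shape[2])
    res <- draw_nuclei(canvas, n, spec$nucleus_diameter, spec$peak_intensity,
                       c(1, spec$image_shape[1]), c(1, spec$image_shape[2]),
                       region_id = 1L)
    finalize_phantom(res$canvas, spec, res$truth, "tumor")
  })
}

#' Simulate a muscle phantom (smooth longitudinal fibers)
#'
#' Muscle is rendered as a raised-sinusoid stripe field
#' `a * (1 + sin(2*pi*d / period)) / 2` perpendicular to the fiber
#' orientation, optionally with a mild low-frequency amplitude modulation
#' along the fibers, then rescaled so its maximum equals `muscle_amplitude`
#' (which anchors the contrast-ratio definition). The pattern is globally
#' smooth and periodic, hence sparse in the whole-image DCT.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_image` with `tissue_label = "muscle"` and empty truth.
#' @export
simulate_muscle <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  omega <- spec$muscle_orientation * pi / 180
  rowc <- seq_len(spec$image_shape[1])
  colc <- seq_len(spec$image_shape[2])
  d <- outer(rowc * cos(omega), colc * sin(omega), `+`)
  pattern <- (1 + sin(2 * pi * d / spec$muscle_period)) / 2
  m <- spec$muscle_modulation
  if (m > 0) {
    t_along <- outer(-rowc * sin(omega), colc * cos(omega), `+`)
    pattern <- pattern *
      (1 - m * (1 + sin(2 * pi * t_along / (8 * spec$muscle_period))) / 2)
  }
  pattern <- pattern / max(pattern) * spec$muscle_amplitude
  with_seed(spec$seed,
            finalize_phantom(pattern, spec, empty_truth(), "muscle",
                             blur = FALSE))
}

#' Combine tumor and muscle phantoms at a stated contrast ratio
#'
#' The nuclei image is multiplied by the weight `w` for which
#' `max(w * nuclei) / max(muscle) == contrast_ratio` and added to the muscle
#' image; if the sum exceeds 1 anywhere it is renormalized by its maximum,
#' which preserves the stated contrast ratio (a ratio of maxima is
#' scale-invariant) without saturating nuclei that sit on bright fibers.
#' The ground-truth nucleus list is carried over unchanged.
#'
#' @param nuclei A tumor `phantom_image`.
#' @param muscle A muscle `phantom_image` of the same shape.
#' @param contrast_ratio Max nuclei intensity / max muscle intensity; >= 1.
#' @return A `phantom_image` with `tissue_label = "tumor_muscle"`.
#' @export
combine_tumor_muscle <- function(nuclei, muscle,
                                 contrast_ratio = nuclei$spec$contrast_ratio) {
  stopifnot(inherits(nuclei, "phantom_image"), inherits(muscle, "phantom_image"))
  if (!identical(dim(nuclei$pixels), dim(muscle$pixels))) {
    stop("tumor and muscle phantoms have mismatched shapes", call. = FALSE)
  }
  if (contrast_ratio < 1) stop("contrast_ratio must be >= 1", call. = FALSE)
  max_m <- max(muscle$pixels)
  max_n <- max(nuclei$pixels)
  if (max_m <= 0) {
    stop("muscle phantom is blank: contrast ratio undefined", call. = FALSE)
  }
  if (max_n <= 0) stop("nuclei phantom is blank", call. = FALSE)
  w <- contrast_ratio * max_m / max_n
  out <- w * nuclei$pixels + muscle$pixels
  if (max(out) > 1) out <- out / max(out)
  spec <- nuclei$spec
  spec$contrast_ratio <- contrast_ratio
  new_phantom_image(out, nuclei$truth, "tumor_muscle", spec,
                    regions = nuclei$regions)
}

#' Tile a single image with a grid of (diameter, density) conditions
#'
#' Builds one phantom whose rectangular regions each hold nuclei of a single
#' diameter at a single density (rows of the grid vary diameter, columns vary
#' density), with per-region ground truth -- the layout used to read error
#' off a single sweep image.
#'
#' @param diameters Vector of nucleus diameters in pixels (one per grid row).
#' @param densities Vector of densities per 0.25 mm2 (one per grid column).
#' @param spec A [phantom_spec()]; its `image_shape` is partitioned evenly.
#' @return A `phantom_image` whose `truth` has one `region_id` per cell and
#'   whose `regions` field tabulates cell bounds and conditions.
#' @export
sweep_grid <- function(diameters, densities, spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"),
            length(diameters) >= 1, length(densities) >= 1)
  nr <- length(diameters)
  nc <- length(densities)
  h <- spec$image_shape[1] %/% nr
  w <- spec$image_shape[2] %/% nc
  if (h < 4 * max(diameters) || w < 4 * max(diameters)) {
    stop("grid cells too small for the requested diameters", call. = FALSE)
  }
  with_seed(spec$seed, {
    canvas <- matrix(0, spec$image_shape[1], spec$image_shape[2])
    truth <- empty_truth()
    regions <- NULL
    id <- 0L
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        id <- id + 1L
        row_lim <- c((i - 1) * h + 1, i * h)
        col_lim <- c((j - 1) * w + 1, j * w)
        area <- (h * w) * spec$pixel_size^2 / 1e6
        n <- density_to_count(densities[j], area)
        res <- draw_nuclei(canvas, n, diameters[i], spec$peak_intensity,
                           row_lim, col_lim, region_id = id)
        canvas <- res$canvas
        truth <- rbind(truth, res$truth)
        regions <- rbind(regions, data.frame(
          region_id = id, row_min = row_lim[1], row_max = row_lim[2],
          col_min = col_lim[1], col_max = col_lim[2],
          diameter_px = diameters[i], density = densities[j],
          true_count = n, area_mm2 = area))
      }
    }
    finalize_phantom(canvas, spec, truth, "tumor", regions = regions)
  })
}
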