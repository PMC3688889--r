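test_that("tumor phantom count follows density over the imaged area", {
  # 500 x 500 px at 1 um/px is exactly 0.25 mm^2, so count = density
  spec <- phantom_spec(image_shape = c(500, 500), pixel_size = 1,
                       nucleus_diameter = 10, density = 100, seed = 7)
  ph <- simulate_tumor(spec)
  expect_identical(nrow(ph$truth), 100L)
  expect_s3_class(ph, "phantom_image")
  expect_identical(ph$tissue_label, "tumor")
  # half the pixel pitch -> quarter the area -> quarter the count
  spec2 <- phantom_spec(image_shape = c(500, 500), pixel_size = 0.5,
                        density = 100, seed = 7)
  expect_identical(nrow(simulate_tumor(spec2)$truth), 25L)
})

test_that("zero density gives a blank phantom with empty truth", {
  ph <- simulate_tumor(phantom_spec(density = 0, seed = 1))
  expect_identical(nrow(ph$truth), 0L)
  expect_true(all(ph$pixels == 0))
})

test_that("phantoms are bit-reproducible from spec + seed and bounded", {
  spec <- phantom_spec(nucleus_diameter = c(4, 10, 18), density = 450,
                       noise_sigma = 0.01, seed = 42)
  a <- simulate_tumor(spec)
  b <- simulate_tumor(spec)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$truth, b$truth)
  expect_gte(min(a$pixels), 0)
  expect_lte(max(a$pixels), 1)
  # all truth rows lie inside the image with the full disk in bounds
  expect_true(all(a$truth$row - a$truth$radius_px >= 0.5))
  expect_true(all(a$truth$row + a$truth$radius_px <= 256.5))
  expect_true(all(a$truth$diameter_um == 2 * a$truth$radius_px * 0.83))
})

test_that("Gaussian blur preserves disk energy before clipping", {
  img <- disk_image(c(64, 64), c(32, 32), radius = 5)
  blurred <- scact:::gaussian_blur(img, 1.1)
  expect_lt(abs(sum(blurred) - sum(img)) / sum(img), 1e-6)
})

test_that("muscle phantom is a smooth oriented stripe field", {
  spec <- phantom_spec(muscle_period = 20, muscle_orientation = 0,
                       muscle_modulation = 0, seed = 1)
  ph <- simulate_muscle(spec)
  expect_identical(nrow(ph$truth), 0L)
  expect_equal(max(ph$pixels), spec$muscle_amplitude)
  # horizontal fibers: intensity varies along rows, constant along columns
  expect_lt(max(apply(ph$pixels, 1, stats::sd)), 1e-12)
  expect_gt(stats::sd(ph$pixels[, 1]), 0.1)
  expect_error(phantom_spec(muscle_period = 2), "muscle_period")
})

test_that("muscle phantom is sparse in the whole-image DCT", {
  ph <- simulate_muscle(phantom_spec(seed = 3))  # default mild modulation
  conc <- energy_concentration(as.vector(dct2(ph$pixels)), fraction = 0.01)
  expect_gte(conc, 0.99)
})

test_that("noise injection adds the configured Gaussian perturbation", {
  s0 <- phantom_spec(noise_sigma = 0, seed = 5)
  s1 <- phantom_spec(noise_sigma = 0.01, seed = 5)
  diff <- simulate_muscle(s1)$pixels - simulate_muscle(s0)$pixels
  expect_lt(abs(stats::sd(diff) - 0.01) / 0.01, 0.2)
})

test_that("tumor+muscle combination honors the contrast-ratio definition", {
  # disjoint supports so the weight is read off the combined maxima exactly
  nuc <- scact:::new_phantom_image(
    disk_image(c(64, 64), c(16, 16), 5), scact:::empty_truth(), "tumor",
    phantom_spec(image_shape = c(64, 64)))
  mus <- scact:::new_phantom_image(
    0.5 * disk_image(c(64, 64), c(48, 48), 5), scact:::empty_truth(),
    "muscle", phantom_spec(image_shape = c(64, 64)))
  tm <- combine_tumor_muscle(nuc, mus, contrast_ratio = 1.5)
  expect_equal(max(tm$pixels[1:32, 1:32]) / max(tm$pixels[33:64, 33:64]), 1.5)
  expect_equal(max(tm$pixels[1:32, 1:32]), 0.75)  # w = 1.5 * 0.5 / 1
  expect_identical(tm$tissue_label, "tumor_muscle")

  spec <- phantom_spec(seed = 2)
  tum <- simulate_tumor(spec)
  mus2 <- simulate_muscle(spec)
  for (ratio in c(1.2, 1.4, 1.6, 1.8)) {
    tm2 <- combine_tumor_muscle(tum, mus2, ratio)
    expect_lte(max(tm2$pixels), 1)
    expect_identical(tm2$truth, tum$truth)
  }
  blank <- scact:::new_phantom_image(matrix(0, 64, 64),
                                     scact:::empty_truth(), "muscle",
                                     phantom_spec(image_shape = c(64, 64)))
  expect_error(combine_tumor_muscle(nuc, blank), "blank")
  small <- scact:::new_phantom_image(matrix(0.1, 32, 32),
                                     scact:::empty_truth(), "muscle",
                                     phantom_spec(image_shape = c(32, 32)))
  expect_error(combine_tumor_muscle(nuc, small), "mismatched")
  expect_error(combine_tumor_muscle(nuc, mus, contrast_ratio = 0.9), ">= 1")
})

test_that("sweep grid partitions truth by region at the right counts", {
  spec <- phantom_spec(image_shape = c(256, 256), seed = 9)
  diam <- c(4, 6, 8, 10)
  dens <- c(150, 300, 450, 600)
  grid <- sweep_grid(diam, dens, spec)
  expect_identical(nrow(grid$regions), 16L)
  for (k in seq_len(16)) {
    rg <- grid$regions[k, ]
    tr <- grid$truth[grid$truth$region_id == rg$region_id, ]
    expect_identical(nrow(tr), rg$true_count)
    expect_identical(rg$true_count,
                     scact:::density_to_count(rg$density, rg$area_mm2))
    expect_true(all(tr$row >= rg$row_min & tr$row <= rg$row_max))
    expect_true(all(tr$col >= rg$col_min & tr$col <= rg$col_max))
  }
  expect_identical(sweep_grid(diam, dens, spec)$pixels, grid$pixels)
  expect_error(sweep_grid(c(10, 18), c(100, 200),
                          phantom_spec(image_shape = c(64, 64))),
               "too small")
})

test_that("phantom parameter validation rejects degenerate specs", {
  expect_error(phantom_spec(density = -1), "density")
  expect_error(phantom_spec(nucleus_diameter = 0), "diameter")
  expect_error(phantom_spec(blur_sigma = 0), "blur_sigma")
  expect_error(phantom_spec(contrast_ratio = 0.5), "contrast_ratio")
  expect_error(simulate_tumor(phantom_spec(nucleus_diameter = 40)),
               "range")
  expect_error(simulate_tumor(phantom_spec(image_shape = c(16, 16),
                                           density = 9e6)),
               "impossible")
})
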