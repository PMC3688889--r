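small_cfg <- function(...) sca_config(max_iterations = 300,
                                      rel_tolerance = 1e-8, ...)

test_that("objective equals an independently assembled evaluation", {
  set.seed(1)
  y <- matrix(runif(16 * 16), 16, 16)
  cfg <- sca_config(tau_nuclei = 0.05, tau_muscle = 0.03, tau_adipose = 0.02)
  dicts <- scact:::sca_dictionaries(dim(y), cfg)
  est <- list(nuclei = rnorm(dicts$nuclei$ncoef, sd = 0.1),
              muscle = rnorm(dicts$muscle$ncoef, sd = 0.1),
              adipose = rnorm(dicts$adipose$ncoef, sd = 0.01))
  got <- sca_objective(y, est, cfg)
  # independent elementwise evaluation of the l2 + weighted-l1 formula
  approx <- dicts$nuclei$synthesize(est$nuclei) +
    dicts$muscle$synthesize(est$muscle) +
    dicts$adipose$synthesize(est$adipose)
  want <- 0.5 * sum((y - approx)^2) + 0.05 * sum(abs(est$nuclei)) +
    0.03 * sum(abs(est$muscle)) + 0.02 * sum(abs(est$adipose))
  expect_equal(got, want, tolerance = 1e-12)
  # all-zero estimates -> 0.5 * ||y||^2 exactly
  zero <- lapply(dicts, function(d) numeric(d$ncoef))
  expect_equal(sca_objective(y, zero, cfg), 0.5 * sum(y^2))
  # y = 0 -> 0.5 * ||sum of components||^2 + penalties
  expect_equal(sca_objective(y * 0, est, cfg),
               0.5 * sum(approx^2) + 0.05 * sum(abs(est$nuclei)) +
                 0.03 * sum(abs(est$muscle)) + 0.02 * sum(abs(est$adipose)),
               tolerance = 1e-12)
  est$nuclei[1] <- NaN
  expect_error(sca_objective(y, est, cfg), "finite")
})

test_that("decomposing a zero image returns zero components", {
  dec <- sca_decompose(matrix(0, 16, 16), small_cfg())
  expect_true(all(dec$approximation == 0))
  expect_true(all(vapply(dec$estimates, function(e) all(e == 0),
                         logical(1))))
})

test_that("pixel-only limits match the soft-threshold closed form", {
  set.seed(2)
  y <- matrix(runif(16 * 16, 0, 1), 16, 16)
  # huge muscle/adipose weights deactivate those dictionaries; the exact
  # minimizer of the remaining problem is elementwise soft-thresholding
  tau_n <- 0.2
  cfg <- small_cfg(tau_nuclei = tau_n, tau_muscle = 1e6, tau_adipose = 1e6)
  dec <- sca_decompose(y, cfg)
  want <- sign(y) * pmax(abs(y) - tau_n, 0)
  expect_lt(max(abs(dec$components$nuclei - want)), 1e-8)
  expect_true(all(dec$estimates$muscle == 0))
  expect_true(all(dec$estimates$adipose == 0))
  # tau_n -> 0 recovers y exactly; tau_n >= max(y) zeroes the component
  dec0 <- sca_decompose(y, small_cfg(tau_nuclei = 1e-12, tau_muscle = 1e6,
                                     tau_adipose = 1e6))
  expect_lt(max(abs(dec0$components$nuclei - y)), 1e-6)
  dec1 <- sca_decompose(y, small_cfg(tau_nuclei = 1.01, tau_muscle = 1e6,
                                     tau_adipose = 1e6))
  expect_true(all(dec1$components$nuclei == 0))
})

test_that("GPSR variants agree with the ISTA reference on the objective", {
  set.seed(3)
  for (k in 1:5) {
    y <- matrix(runif(16 * 16), 16, 16)
    f <- sapply(c("gpsr_bb", "gpsr_basic", "ista_reference"), function(sv) {
      cfg <- sca_config(solver_variant = sv, max_iterations = 4000,
                        rel_tolerance = 1e-11)
      dec <- suppressWarnings(sca_decompose(y, cfg))
      expect_true(all(diff(dec$objective_trace) <= 1e-10))
      tail(dec$objective_trace, 1)
    })
    expect_lt(abs(f["gpsr_bb"] - f["ista_reference"]) / f["ista_reference"],
              1e-5)
    expect_lt(abs(f["gpsr_basic"] - f["ista_reference"]) /
                f["ista_reference"], 1e-5)
  }
})

test_that("decomposition is deterministic and internally consistent", {
  spec <- phantom_spec(image_shape = c(64, 64), nucleus_diameter = 6,
                       density = 600, seed = 4)
  ph <- simulate_tumor(spec)
  a <- suppressWarnings(sca_decompose(ph$pixels))
  b <- suppressWarnings(sca_decompose(ph$pixels))
  expect_identical(a$objective_trace, b$objective_trace)
  expect_identical(a$components$nuclei, b$components$nuclei)
  # approximation is exactly the sum of the three components
  expect_equal(a$approximation, a$components$nuclei + a$components$muscle +
                 a$components$adipose, tolerance = 1e-14)
  expect_equal(a$residual, ph$pixels - a$approximation, tolerance = 1e-14)
  # trace tail equals the R-side objective on the returned estimates
  expect_equal(tail(a$objective_trace, 1),
               sca_objective(ph$pixels, a$estimates, a$config),
               tolerance = 1e-10)
  expect_error(sca_decompose(ph$pixels * 2), "normalized")
})

test_that("nuclei-component energy concentrates inside true nuclei", {
  spec <- phantom_spec(image_shape = c(128, 128), nucleus_diameter = 10,
                       density = 300, seed = 5)
  ph <- combine_tumor_muscle(simulate_tumor(spec), simulate_muscle(spec),
                             contrast_ratio = 1.8)
  dec <- suppressWarnings(sca_decompose(ph$pixels))
  inside <- matrix(FALSE, 128, 128)
  for (i in seq_len(nrow(ph$truth))) {
    d2 <- outer((seq_len(128) - ph$truth$row[i])^2,
                (seq_len(128) - ph$truth$col[i])^2, `+`)
    inside <- inside | (d2 <= (ph$truth$radius_px[i] + 2)^2)
  }
  e_in <- sum(dec$components$nuclei[inside]^2)
  e_out <- sum(dec$components$nuclei[!inside]^2)
  expect_gte(e_in, 5 * e_out)
})

test_that("regularization selection scores a deterministic grid argmax", {
  spec <- phantom_spec(image_shape = c(48, 48), nucleus_diameter = 6,
                       density = 900, seed = 6)
  suite <- list(simulate_tumor(spec))
  grid <- list(nuclei = c(0.05, 0.9), muscle = 0.3, adipose = 0.2)
  cfg <- select_regularization(suite, grid,
                               base_config = sca_config(max_iterations = 60))
  search <- attr(cfg, "search")
  expect_identical(nrow(search), 2L)
  expect_equal(unname(cfg$alpha["nuclei"]),
               search$nuclei[which.max(search$f1)])
  # an absurdly large nuclei weight kills detection, so the small one wins
  expect_equal(unname(cfg$alpha["nuclei"]), 0.05)
  cfg2 <- select_regularization(suite, grid,
                                base_config = sca_config(max_iterations = 60))
  expect_identical(attr(cfg2, "search"), search)
  expect_error(select_regularization(list()), "empty")
  blank <- scact:::new_phantom_image(matrix(0, 32, 32),
                                     scact:::empty_truth(), "tumor",
                                     phantom_spec(image_shape = c(32, 32)))
  expect_error(select_regularization(list(blank)), "blank")
})
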