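fake_detections <- function(diameters) {
  structure(data.frame(row = seq_along(diameters), col = seq_along(diameters),
                       radius_px = diameters / 2 / 0.83,
                       diameter_um = diameters,
                       score = rep(1, length(diameters))),
            class = c("detection_set", "data.frame"))
}

test_that("densities are normalized per 0.25 mm2 and split at the cutoff", {
  d100 <- fake_detections(rep(6, 100))
  expect_equal(compute_density(d100, 0.25)$total_density, 100)
  expect_equal(compute_density(d100, 0.5)$total_density, 50)
  st <- compute_density(fake_detections(c(6, 6, 10)), 0.25, size_cutoff = 8)
  expect_equal(st$small_density, 2 / 0.25 * 0.25)
  expect_equal(st$large_density, 1 / 0.25 * 0.25)
  expect_equal(st$small_density + st$large_density, st$total_density)
  # boundary diameter counts as small (<= cutoff)
  st8 <- compute_density(fake_detections(8), 0.25)
  expect_equal(st8$small_density, 1)
  expect_error(compute_density(d100, 0), "positive")
})

test_that("density is additive across disjoint subregions", {
  n1 <- 14; a1 <- 0.1; n2 <- 5; a2 <- 0.06
  whole <- compute_density(fake_detections(rep(6, n1 + n2)), a1 + a2)
  s1 <- compute_density(fake_detections(rep(6, n1)), a1)
  s2 <- compute_density(fake_detections(rep(6, n2)), a2)
  weighted <- (s1$total_density * a1 + s2$total_density * a2) / (a1 + a2)
  expect_equal(whole$total_density, weighted)
})

test_that("rank-sum test matches exact enumeration on small samples", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(wilcoxon_rank_sum(1, 2), 1)
  expect_warning(p <- wilcoxon_rank_sum(c(2, 2), c(2, 2)), "identical")
  expect_equal(p, 1)
  set.seed(8)
  for (k in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    a <- round(runif(n1), 3); b <- round(runif(n2), 3)
    if (anyDuplicated(c(a, b))) next
    expect_equal(wilcoxon_rank_sum(a, b), oracle_wilcoxon_exact(a, b),
                 tolerance = 1e-12)
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("AUC equals exhaustive pair counting and finds the Youden point", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  perfect <- roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$youden_sensitivity, 1)
  expect_equal(perfect$youden_specificity, 1)
  tied <- roc_auc(rep(0.5, 8), c(0, 1, 0, 1, 0, 1, 0, 1))
  expect_equal(tied$auc, 0.5)
  set.seed(9)
  for (k in 1:10) {
    sc <- runif(12)
    lb <- rbinom(12, 1, 0.5)
    if (length(unique(lb)) < 2) next
    expect_equal(roc_auc(sc, lb)$auc, oracle_auc_pairs(sc, lb),
                 tolerance = 1e-12)
    # invariance under a strictly monotone transform of the scores
    expect_equal(roc_auc(exp(3 * sc), lb)$auc, roc_auc(sc, lb)$auc)
  }
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("Youden point maximizes sensitivity + specificity - 1", {
  set.seed(10)
  sc <- c(rnorm(20, 0), rnorm(20, 1.2))
  lb <- rep(c(0, 1), each = 20)
  r <- roc_auc(sc, lb)
  j <- r$sensitivities + r$specificities - 1
  expect_equal(r$youden_sensitivity + r$youden_specificity - 1, max(j))
  expect_true(all(r$auc >= 0 & r$auc <= 1))
})

test_that("overlay renders red/green circles on a contrast-stretched base", {
  img <- matrix(seq(0.2, 0.6, length.out = 32 * 32), 32, 32)
  none <- render_overlay(img, fake_detections(numeric(0)))
  stretched <- (img - min(img)) / (max(img) - min(img))
  expect_equal(none[, , 1], stretched)
  expect_equal(none[, , 2], stretched)

  one <- structure(data.frame(row = 16, col = 16, radius_px = 4,
                              diameter_um = 10, score = 1),
                   class = c("detection_set", "data.frame"))
  ov <- render_overlay(img, one, cutoff_um = 8)
  red <- ov[, , 1] == 1 & ov[, , 2] == 0 & ov[, , 3] == 0
  green <- ov[, , 2] > ov[, , 1]
  expect_gt(sum(red), 0)           # a 10 um nucleus is drawn red
  expect_identical(sum(green), 0L) # and nothing is drawn green
  small <- one; small$diameter_um <- 6
  ov2 <- render_overlay(img, small, cutoff_um = 8)
  expect_gt(sum(ov2[, , 2] == 1 & ov2[, , 1] == 0), 0)

  cst <- matrix(0.3, 16, 16)
  expect_equal(render_overlay(cst, fake_detections(numeric(0)))[, , 1], cst)
})

test_that("diameter distribution uses 1-um bins with a smooth overlay", {
  d <- c(4.2, 5.1, 5.3, 9.8, 10.4, 10.6)
  dist <- diameter_distribution(d)
  expect_equal(diff(dist$breaks), rep(1, length(dist$breaks) - 1))
  expect_equal(sum(dist$counts), length(d))
  expect_true(length(dist$density_x) > 0)
  empty <- diameter_distribution(numeric(0))
  expect_identical(sum(empty$counts), 0L)
})
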