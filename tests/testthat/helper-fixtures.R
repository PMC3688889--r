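# Shared fixtures and independent oracles, built in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Binary disk (pixel-center coverage), optionally Gaussian-blurred.
disk_image <- function(shape, center, radius, value = 1, blur_sigma = 0) {
  d2 <- outer((seq_len(shape[1]) - center[1])^2,
              (seq_len(shape[2]) - center[2])^2, `+`)
  img <- matrix(0, shape[1], shape[2])
  img[d2 <= radius^2] <- value
  if (blur_sigma > 0) img <- as.matrix(EBImage::gblur(img, blur_sigma))
  img
}

# Blurred partial ring (an adipocyte-rim surrogate): the arc spans angles
# [a0, a1] at the given radius.
arc_image <- function(shape, center, radius, a0, a1, width = 3,
                      blur_sigma = 1.2) {
  d <- sqrt(outer((seq_len(shape[1]) - center[1])^2,
                  (seq_len(shape[2]) - center[2])^2, `+`))
  ang <- atan2(outer(seq_len(shape[1]) - center[1], rep(1, shape[2])),
               outer(rep(1, shape[1]), seq_len(shape[2]) - center[2]))
  img <- matrix(0, shape[1], shape[2])
  img[abs(d - radius) <= width / 2 & ang >= a0 & ang <= a1] <- 1
  if (blur_sigma > 0) img <- as.matrix(EBImage::gblur(img, blur_sigma))
  img
}

# Fraction of energy in the k largest-magnitude coefficients.
topk_energy <- function(coef, k) {
  e <- sort(coef^2, decreasing = TRUE)
  sum(e[seq_len(k)]) / sum(e)
}

# Brute-force circle oracle, independent of the gradient-vote transform:
# for each candidate radius, correlate the central-difference gradient
# magnitude with a one-pixel-wide ring template (ring sum via shift-and-add)
# and return the global argmax over (row, col, radius).
oracle_circle_max <- function(img, radii) {
  h <- nrow(img); w <- ncol(img)
  gr <- matrix(0, h, w); gc <- matrix(0, h, w)
  gr[2:(h - 1), ] <- (img[3:h, ] - img[1:(h - 2), ]) / 2
  gc[, 2:(w - 1)] <- (img[, 3:w] - img[, 1:(w - 2)]) / 2
  mag <- sqrt(gr^2 + gc^2)
  best <- c(score = -Inf, row = NA, col = NA, radius = NA)
  for (r in radii) {
    ang <- seq(0, 2 * pi, length.out = max(16, ceiling(2 * pi * r)) + 1)
    ang <- ang[-length(ang)]
    offs <- unique(round(cbind(r * cos(ang), r * sin(ang))))
    score <- matrix(0, h, w)
    for (k in seq_len(nrow(offs))) {
      dr <- offs[k, 1]; dc <- offs[k, 2]
      src_r <- (1 + max(0, dr)):(h + min(0, dr))
      src_c <- (1 + max(0, dc)):(w + min(0, dc))
      score[src_r - dr, src_c - dc] <-
        score[src_r - dr, src_c - dc] + mag[src_r, src_c]
    }
    score <- score / nrow(offs)
    if (max(score) > best["score"]) {
      ix <- unname(which(score == max(score), arr.ind = TRUE)[1, ])
      best <- c(score = max(score), row = ix[1], col = ix[2], radius = r)
    }
  }
  best
}

# Exact two-tailed rank-sum p-value by full enumeration of all
# choose(n1 + n2, n1) group assignments (no ties assumed).
oracle_wilcoxon_exact <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(length(pooled), n1)
  u_all <- apply(splits, 2, function(ix) sum(rk[ix]) - n1 * (n1 + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(p, 1)
}

# AUC by exhaustive pair counting (ties between classes count 1/2).
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  mean(cmp)
}

# Maximum-cardinality matching count on the detection/truth eligibility
# graph (center distance <= true radius), via igraph.
oracle_matching_count <- function(detections, truth) {
  nd <- nrow(detections); nt <- nrow(truth)
  el <- NULL
  for (i in seq_len(nd)) {
    d2 <- (truth$row - detections$row[i])^2 + (truth$col - detections$col[i])^2
    for (j in which(d2 <= truth$radius_px^2)) el <- rbind(el, c(i, nd + j))
  }
  if (is.null(el)) return(0L)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nd + nt - igraph::vcount(g)))
  igraph::V(g)$type <- seq_len(igraph::vcount(g)) > nd
  igraph::max_bipartite_match(g)$matching_size
}

# Small tumor(+muscle) phantom -> SCA -> detection -> matching, shared by
# the acceptance tests.
run_phantom_case <- function(diameter, ratio, seed, density = 300,
                             shape = c(256L, 256L),
                             sca_cfg = sca_config(),
                             det_cfg = detect_config()) {
  spec <- phantom_spec(image_shape = shape, nucleus_diameter = diameter,
                       density = density, seed = seed)
  ph <- simulate_tumor(spec)
  if (!is.na(ratio)) {
    ph <- combine_tumor_muscle(ph, simulate_muscle(spec), ratio)
  }
  dec <- suppressWarnings(sca_decompose(ph$pixels, sca_cfg))
  det <- detect_nuclei(dec$components$nuclei, det_cfg,
                       pixel_size = spec$pixel_size)
  mt <- match_detections(det, ph$truth)
  list(phantom = ph, decomposition = dec, detections = det, match = mt,
       percent_error = percent_error(nrow(det), nrow(ph$truth)))
}
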