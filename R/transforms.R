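# Sparsifying dictionaries: pixel basis (nuclei), whole-image orthonormal
# DCT (muscle), and an FFT-based wedge-windowed curvelet-type tight frame
# (adipose). Each operator exposes analyze (forward), synthesize (inverse /
# adjoint) and its redundancy; synthesize is the exact adjoint of analyze in
# all three cases, which is what the GPSR gradient requires.

.transform_cache <- new.env(parent = emptyenv())

# Orthonormal DCT-II matrix of order n (cached).
dct_matrix <- function(n) {
  key <- paste0("dct", n)
  if (!is.null(.transform_cache[[key]])) return(.transform_cache[[key]])
  k <- 0:(n - 1)
  D <- sqrt(2 / n) * cos(pi * outer(k, k + 0.5) / n)
  D[1, ] <- D[1, ] / sqrt(2)
  .transform_cache[[key]] <- D
  D
}

#' Two-dimensional orthonormal type-II DCT of a full image
#'
#' Computed over the entire image (not in blocks); Parseval's identity holds
#' exactly, so coefficient energy equals pixel energy.
#'
#' @param x Numeric matrix.
#' @return Matrix of DCT coefficients with the same dimensions.
#' @export
dct2 <- function(x) {
  dct_matrix(nrow(x)) %*% x %*% t(dct_matrix(ncol(x)))
}

#' @rdname dct2
#' @param coef Matrix of DCT coefficients.
#' @export
idct2 <- function(coef) {
  t(dct_matrix(nrow(coef))) %*% coef %*% dct_matrix(ncol(coef))
}

# --- curvelet-type frame ----------------------------------------------------

# Meyer polynomial smooth step on [0, 1].
meyer_step <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t^4 * (35 - 84 * t + 70 * t^2 - 20 * t^3)
}

# Frequency-plane windows: isotropic Meyer-type radial bands split into
# overlapping angular wedges (theta mod pi, so each window is symmetric under
# frequency negation up to the Nyquist lines). Squares sum to 1 everywhere,
# giving a tight frame with constant 1.
curvelet_windows <- function(p, n_scales, n_orient) {
  key <- sprintf("cw_%d_%d_%d", p, n_scales, n_orient)
  if (!is.null(.transform_cache[[key]])) return(.transform_cache[[key]])
  fr <- c(seq(0, floor(p / 2)), seq(-ceiling(p / 2) + 1, -1)) / p
  rho <- sqrt(outer(fr^2, fr^2, `+`))
  theta <- atan2(outer(fr, rep(1, p)), outer(rep(1, p), fr))
  theta <- theta %% pi
  cuts <- 0.25 / 2^(0:n_scales)          # c_1 > c_2 > ... > c_{J+1}
  edge_up <- function(a, b) sin(pi / 2 * meyer_step((rho - a) / (b - a)))
  edge_dn <- function(a, b) cos(pi / 2 * meyer_step((rho - a) / (b - a)))
  radial <- vector("list", n_scales + 1)
  for (j in seq_len(n_scales)) {        # j = 1 finest
    w <- edge_up(cuts[j + 1], cuts[j])
    if (j > 1) {
      w[rho >= cuts[j]] <- edge_dn(cuts[j], cuts[j - 1])[rho >= cuts[j]]
    }
    radial[[j]] <- w
  }
  radial[[n_scales + 1]] <- {           # isotropic lowpass
    w <- edge_dn(cuts[n_scales + 1], cuts[n_scales])
    w[rho <= cuts[n_scales + 1]] <- 1
    w
  }
  tt <- theta / (pi / n_orient)
  angular <- lapply(seq_len(n_orient) - 1, function(k) {
    u <- ((tt - k + n_orient / 2) %% n_orient) - n_orient / 2
    w <- matrix(0, p, p)
    ris <- u >= -1 & u < 0
    fal <- u >= 0 & u < 1
    w[ris] <- sin(pi / 2 * meyer_step(u[ris] + 1))
    w[fal] <- cos(pi / 2 * meyer_step(u[fal]))
    w
  })
  # Symmetrize each window under frequency negation (the grid map
  # k -> (p - k) mod p). The raw angular windows differ from their
  # negated copies only on the Nyquist row/column; averaging the squares
  # restores exact symmetry while preserving the partition of unity, so
  # every subband of a real image is exactly real.
  neg <- c(1, p:2)
  symmetrize <- function(w) sqrt((w^2 + w[neg, neg]^2) / 2)
  # Decimation factor per scale: band j (j >= 2) is supported strictly
  # inside the open frequency box of width 1/2^(j-1) (its window vanishes
  # at the box edge), so its subband can be folded (spectrum summed modulo
  # p / D) onto a grid D = 2^(j-1) times smaller without aliasing; the
  # lowpass folds by 2^n_scales. Capped so no grid drops below 8 px.
  dec <- function(j) {
    d <- if (j == 1) 1L else if (j <= n_scales) 2L^(j - 1L) else
      2L^n_scales
    min(d, p %/% 8L)
  }
  windows <- list()
  layout <- NULL
  for (j in seq_len(n_scales)) {
    for (k in seq_len(n_orient)) {
      windows[[length(windows) + 1]] <- symmetrize(radial[[j]] * angular[[k]])
      layout <- rbind(layout,
                      data.frame(scale = j, orientation = k,
                                 decimation = dec(j)))
    }
  }
  windows[[length(windows) + 1]] <- radial[[n_scales + 1]]
  layout <- rbind(layout, data.frame(scale = n_scales + 1, orientation = NA,
                                     decimation = dec(n_scales + 1)))
  layout$grid <- p %/% layout$decimation
  layout$length <- layout$grid^2
  layout$offset <- c(0, cumsum(layout$length))[seq_len(nrow(layout))]
  out <- list(windows = windows, layout = layout)
  .transform_cache[[key]] <- out
  out
}

# Fold a p x p spectrum onto a q x q grid (sum over the D^2 period blocks);
# exact when the spectrum's support fits one open period box.
fold_spectrum <- function(M, D) {
  if (D == 1) return(M)
  q <- nrow(M) %/% D
  out <- matrix(0 + 0i, q, q)
  for (a in 0:(D - 1)) for (b in 0:(D - 1)) {
    out <- out + M[a * q + seq_len(q), b * q + seq_len(q)]
  }
  out
}

unfold_spectrum <- function(M, D) {
  if (D == 1) return(M)
  M[rep(seq_len(nrow(M)), D), rep(seq_len(ncol(M)), D)]
}

#' Dictionary operators for sparse component analysis
#'
#' Construct one of the three sparsifying dictionaries as a
#' `dictionary_operator`: a list with `analyze` (image to flat coefficient
#' vector), `synthesize` (coefficient vector to image; the exact adjoint of
#' `analyze`, and its inverse -- all three operators are orthonormal bases or
#' tight frames with frame constant 1), `ncoef` and `redundancy`.
#'
#' * `dict_pixel()` -- the identity basis; captures small, spatially isolated
#'   nuclei. Redundancy 1.
#' * `dict_dct()` -- whole-image orthonormal DCT-II; captures globally smooth
#'   periodic muscle fibers. Redundancy 1.
#' * `dict_curvelet()` -- directional multiscale frame for curvilinear
#'   adipose outlines: the image is zero-padded to a dyadic square, analyzed
#'   in the frequency plane through Meyer-type radial bands split into
#'   overlapping angular wedges whose squares sum to one (a tight frame with
#'   frame constant 1). Coarser subbands are decimated by folding their
#'   spectra onto smaller grids -- exact because each window vanishes at its
#'   fold-period boundary -- which localizes coefficient energy; the windows
#'   are symmetric under frequency negation, so each subband of a real
#'   image is itself real. Redundancy about `n_orient + n_orient/4 + ...`
#'   on the padded grid (reported in the `redundancy` field).
#'
#' @param shape Image shape `(rows, cols)`.
#' @param n_scales Number of directional bandpass scales (curvelet only).
#' @param n_orient Number of angular wedges per bandpass scale over
#'   `[0, pi)` (curvelet only).
#' @return A `dictionary_operator`.
#' @export
dict_pixel <- function(shape) {
  shape <- as.integer(shape)
  structure(list(
    name = "pixel", shape = shape,
    ncoef = prod(shape), redundancy = 1,
    analyze = function(x) as.vector(x),
    synthesize = function(v) matrix(v, shape[1], shape[2])
  ), class = "dictionary_operator")
}

#' @rdname dict_pixel
#' @export
dict_dct <- function(shape) {
  shape <- as.integer(shape)
  structure(list(
    name = "dct", shape = shape,
    ncoef = prod(shape), redundancy = 1,
    analyze = function(x) as.vector(dct2(x)),
    synthesize = function(v) idct2(matrix(v, shape[1], shape[2]))
  ), class = "dictionary_operator")
}

#' @rdname dict_pixel
#' @export
dict_curvelet <- function(shape, n_scales = 2L, n_orient = 8L) {
  shape <- as.integer(shape)
  p <- max(32L, 2^ceiling(log2(max(shape))))
  win <- curvelet_windows(p, n_scales, n_orient)
  lay <- win$layout
  nw <- length(win$windows)
  ncoef <- sum(lay$length)
  # unitary FFT pairs; windows are symmetric under frequency negation and
  # folding preserves Hermitian symmetry, so every subband of a real image
  # is real
  ufft <- function(z) fft(z) / sqrt(length(z))
  uifft <- function(z) fft(z, inverse = TRUE) / sqrt(length(z))
  analyze <- function(x) {
    xp <- matrix(0 + 0i, p, p)
    xp[seq_len(shape[1]), seq_len(shape[2])] <- x
    X <- ufft(xp)
    out <- numeric(ncoef)
    for (w in seq_len(nw)) {
      cw <- uifft(fold_spectrum(X * win$windows[[w]], lay$decimation[w]))
      out[lay$offset[w] + seq_len(lay$length[w])] <- Re(cw)
    }
    out
  }
  synthesize <- function(v) {
    Z <- matrix(0 + 0i, p, p)
    for (w in seq_len(nw)) {
      q <- lay$grid[w]
      cw <- matrix(complex(real = v[lay$offset[w] + seq_len(lay$length[w])],
                           imaginary = 0), q, q)
      Z <- Z + unfold_spectrum(ufft(cw), lay$decimation[w]) *
        win$windows[[w]]
    }
    Re(uifft(Z))[seq_len(shape[1]), seq_len(shape[2])]
  }
  structure(list(
    name = "curvelet", shape = shape, padded = p,
    n_scales = n_scales, n_orient = n_orient, layout = lay,
    ncoef = ncoef, redundancy = ncoef / prod(shape),
    analyze = analyze, synthesize = synthesize
  ), class = "dictionary_operator")
}

#' @export
print.dictionary_operator <- function(x, ...) {
  cat(sprintf("dictionary_operator <%s>: %d x %d px, %d coefficients (redundancy %.3g)\n",
              x$name, x$shape[1], x$shape[2], x$ncoef, x$redundancy))
  invisible(x)
}

#' Fraction of transform energy captured by the largest coefficients
#'
#' Energy-concentration diagnostic used to verify that each tissue class is
#' sparse in its own dictionary (e.g. a muscle phantom concentrates >= 99%
#' of its DCT energy in <= 1% of coefficients).
#'
#' @param coef Numeric coefficient vector.
#' @param fraction Fraction of coefficients kept (by magnitude).
#' @return Fraction of squared-magnitude energy in the kept coefficients.
#' @export
energy_concentration <- function(coef, fraction = 0.01) {
  k <- max(1L, floor(length(coef) * fraction))
  e <- sort(coef^2, decreasing = TRUE)
  sum(e[seq_len(k)]) / sum(e)
}
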