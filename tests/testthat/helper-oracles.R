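# Shared fixtures and independent oracles used across the suite.

# Build a gray_histogram directly from an integer sample.
hist_from_sample <- function(x, max_level = 255L) {
  structure(list(counts = tabulate(x + 1L, nbins = max_level + 1L),
                 n_pixels = length(x), max_level = max_level),
            class = "gray_histogram")
}

# Independent per-pixel EM oracle: treats every pixel as a datum and
# applies the textbook E/M updates directly, starting from a given
# parameter set.  Deliberately ignores the histogram so it exercises a
# different code path than the package's histogram-weighted EM.
perpixel_em <- function(x, init, n_iter, sd_floor = 0.5) {
  params <- init
  for (it in seq_len(n_iter)) {
    m <- length(params$weights)
    dens <- matrix(0, length(x), m)
    k <- 1L
    if (!is.na(params$rayleigh_sigma)) {
      s2 <- params$rayleigh_sigma^2
      dens[, 1L] <- (x / s2) * exp(-x^2 / (2 * s2))
      dens[x < 0, 1L] <- 0
      k <- 2L
    }
    for (j in seq_along(params$gauss_means))
      dens[, k + j - 1L] <- dnorm(x, params$gauss_means[j], params$gauss_sds[j])
    wd <- sweep(dens, 2L, params$weights, `*`)
    r <- wd / rowSums(wd)
    nk <- colSums(r)
    w <- nk / length(x)
    ray <- params$rayleigh_sigma
    if (!is.na(ray)) ray <- sqrt(sum(r[, 1L] * x^2) / (2 * nk[1L]))
    mus <- params$gauss_means
    sds <- params$gauss_sds
    off <- if (is.na(params$rayleigh_sigma)) 0L else 1L
    for (j in seq_along(mus)) {
      kk <- off + j
      mus[j] <- sum(r[, kk] * x) / nk[kk]
      sds[j] <- max(sqrt(sum(r[, kk] * (x - mus[j])^2) / nk[kk]), sd_floor)
    }
    params <- mixture_params(w, ray, mus, sds, params$class_of_component)
  }
  params
}

# Ground-truth 4-component mixture used in recovery checks: all
# component means separated by at least 3 sds of their neighbors.
recovery_truth <- function() {
  mixture_params(weights = c(0.35, 0.30, 0.20, 0.15),
                 rayleigh_sigma = 20,
                 gauss_means = c(90, 140, 200),
                 gauss_sds = c(10, 12, 10),
                 class_of_component = c("background", "background",
                                        "background", "target"))
}

# 90-degree counter-clockwise rotation of a matrix.
rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]

# Total MRF energy computed by direct summation, independent of the
# package's energy_breakdown (used as the exhaustive re-summation
# oracle).
oracle_total_energy <- function(y, e_bg, e_fg, v, beta, alpha) {
  tot <- 0
  h <- nrow(y); w <- ncol(y)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    tot <- tot + if (y[i, j] == 1L) e_fg[i, j] else e_bg[i, j]
    if (!is.null(v))
      tot <- tot + alpha * (if (y[i, j] == 1L) 1 - v[i, j] else v[i, j])
    if (i < h && y[i, j] != y[i + 1L, j]) tot <- tot + beta
    if (j < w && y[i, j] != y[i, j + 1L]) tot <- tot + beta
  }
  tot
}

# Small random energy instance for ICM tests.
random_energy_instance <- function(seed, h = 8L, w = 8L) {
  set.seed(seed)
  list(e_bg = matrix(runif(h * w, 0, 3), h, w),
       e_fg = matrix(runif(h * w, 0, 3), h, w),
       v = matrix(runif(h * w), h, w))
}

# Horizontal Gaussian-profile ridge image: bright line of profile sd
# s0 across the middle row.
gaussian_ridge <- function(s0, n = 41L) {
  r <- matrix(seq_len(n), n, n)
  exp(-(r - (n + 1) / 2)^2 / (2 * s0^2))
}

# Centerline vesselness response at a single scale with fixed c_r
# (building block of the dense-scale brute-force oracle).
centerline_response <- function(img, s, beta_r = 0.5, c_r = 0.05) {
  hf <- hessian_at_scale(img, s)
  mid <- (nrow(img) + 1L) %/% 2L
  ctr <- (ncol(img) + 1L) %/% 2L
  ev <- eigvals2x2(hf$lxx[mid, ctr], hf$lxy[mid, ctr], hf$lyy[mid, ctr])
  line_response(ev[1L], ev[2L], beta_r = beta_r, c_r = c_r)
}

# Small phantom configuration used throughout the MRF / end-to-end
# tests (keeps runtimes modest without changing the image model).
test_phantom_config <- function(seed, size = c(64L, 64L),
                                noise_variance = 0.02) {
  phantom_config(size = size, seed = seed, noise_variance = noise_variance)
}
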