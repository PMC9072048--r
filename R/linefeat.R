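# Scale-normalized Gaussian-derivative Hessian analysis and the
# eigenvalue line-similarity (vesselness) response, maximized over a
# scale grid.  Axis convention: x runs along columns, y along rows.

# Sampled Gaussian-derivative kernels, truncated at radius 4s and
# moment-calibrated so that discrete polynomial responses are exact:
# order 0 sums to 1, order 1 has first moment 1 (correlation sense),
# order 2 has zero sum and second moment 2.
gauss_deriv_kernel <- function(s, order) {
  stopifnot(s > 0, order %in% 0:2)
  r <- ceiling(4 * s)
  u <- (-r):r
  g <- exp(-u^2 / (2 * s^2)) / (sqrt(2 * pi) * s)
  if (order == 0L) {
    g / sum(g)
  } else if (order == 1L) {
    k <- (u / s^2) * g              # -g'(u): correlation gives d/dx
    k / sum(u * k)
  } else {
    k <- ((u^2 - s^2) / s^4) * g    # g''(u)
    k <- k - mean(k)
    k * (2 / sum(u^2 * k))
  }
}

# symmetric (edge-duplicating) reflection index for padding
reflect_index <- function(n, r) {
  pos <- (1L - r):(n + r)
  p <- (pos - 1L) %% (2L * n)
  ifelse(p < n, p + 1L, 2L * n - p)
}

# 1-D correlation along the row index (vertical direction), reflected
conv_rows <- function(mat, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(mat)
  padded <- mat[reflect_index(n, r), , drop = FALSE]
  out <- matrix(0, n, ncol(mat))
  for (j in seq_along(k))
    out <- out + k[j] * padded[j:(j + n - 1L), , drop = FALSE]
  out
}

conv_sep <- function(mat, k_row, k_col) {
  t(conv_rows(t(conv_rows(mat, k_row)), k_col))
}

#' Gamma-normalized Hessian at one scale
#'
#' Convolves the image with second-derivative-of-Gaussian kernels of
#' standard deviation `s` and multiplies by `s^gamma` (default
#' `gamma = 2`, the standard second-order normalization, so responses
#' are comparable across scales).  Boundaries are handled by symmetric
#' reflection.  `lxx` differentiates along columns (x), `lyy` along
#' rows (y).
#'
#' @param img a [gray_image()] (normalized to `[0, 1]` internally) or
#'   a bare numeric matrix used as-is.
#' @param s Gaussian scale in pixels, `s > 0`.
#' @param gamma scale-normalization exponent.
#' @return List of class `hessian_field` with matrices `lxx`, `lxy`,
#'   `lyy` and the scalar `scale`.
#' @export
hessian_at_scale <- function(img, s, gamma = 2) {
  if (!is.numeric(s) || length(s) != 1L || s <= 0)
    stop("scale `s` must be a single positive number")
  mat <- as_intensity_matrix(img)
  g0 <- gauss_deriv_kernel(s, 0L)
  g1 <- gauss_deriv_kernel(s, 1L)
  g2 <- gauss_deriv_kernel(s, 2L)
  norm <- s^gamma
  structure(
    list(lxx = norm * conv_sep(mat, g0, g2),
         lxy = norm * conv_sep(mat, g1, g1),
         lyy = norm * conv_sep(mat, g2, g0),
         scale = s),
    class = "hessian_field")
}

#' Eigenvalues of a symmetric 2x2 matrix, ordered by magnitude
#'
#' Closed-form eigenvalues of `[[lxx, lxy], [lxy, lyy]]`, returned as
#' `(lambda1, lambda2)` with `|lambda1| <= |lambda2|`; exact magnitude
#' ties are broken by signed value ascending.
#'
#' @param lxx,lxy,lyy matrix entries (scalars).
#' @return Numeric vector `c(lambda1, lambda2)`.
#' @export
eigvals2x2 <- function(lxx, lxy, lyy) {
  e <- eigvals2x2_vec(lxx, lxy, lyy)
  c(e$l1, e$l2)
}

# vectorized core shared with multiscale_response
eigvals2x2_vec <- function(lxx, lxy, lyy) {
  m <- (lxx + lyy) / 2
  disc <- sqrt(((lxx - lyy) / 2)^2 + lxy^2)
  a <- m - disc  # a <= b always
  b <- m + disc
  swap <- abs(b) < abs(a)   # strict: magnitude ties keep signed order
  l1 <- ifelse(swap, b, a)
  l2 <- ifelse(swap, a, b)
  list(l1 = l1, l2 = l2)
}

#' Line-similarity (vesselness) response from Hessian eigenvalues
#'
#' Frangi-style 2-D measure.  For bright structures on a dark
#' background the response is 0 wherever `lambda2 >= 0`, otherwise
#' `exp(-(l1/l2)^2 / (2 beta_r^2)) * (1 - exp(-(l1^2 + l2^2) / (2 c_r^2)))`:
#' the first factor suppresses blobs, the second suppresses
#' low-contrast noise.  Dark-on-bright polarity flips the sign test.
#'
#' @param lambda1,lambda2 Hessian eigenvalues with
#'   `|lambda1| <= |lambda2|` (vectorized).
#' @param beta_r blob-suppression shape parameter, `> 0`.
#' @param c_r structure-contrast parameter, `> 0`.
#' @param polarity `"bright"` (default) or `"dark"`.
#' @return Response values in `[0, 1]`.
#' @export
line_response <- function(lambda1, lambda2, beta_r = 0.5, c_r = 1,
                          polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  if (beta_r <= 0) stop("`beta_r` must be positive")
  if (c_r <= 0) stop("`c_r` must be positive")
  rb2 <- ifelse(lambda2 == 0, 0, (lambda1 / lambda2)^2)
  s2 <- lambda1^2 + lambda2^2
  v <- exp(-rb2 / (2 * beta_r^2)) * (1 - exp(-s2 / (2 * c_r^2)))
  off <- if (polarity == "bright") lambda2 >= 0 else lambda2 <= 0
  v[off] <- 0
  v
}

#' Multiscale line-similarity feature map
#'
#' Evaluates the line response at every scale on the grid and keeps
#' the pointwise maximum; `best_scale_idx` records the argmax (first
#' index on ties).  When the spatial scale matches the structure
#' width, the normalized response is maximized, so the best scale
#' estimates local width.  With `c_r = NULL` the contrast parameter is
#' chosen per scale as half the maximum Hessian Frobenius norm over
#' the image at that scale.
#'
#' @param img a [gray_image()] or numeric matrix.
#' @param scales strictly increasing positive scale grid (pixels).
#' @param beta_r blob-suppression parameter.
#' @param c_r fixed contrast parameter, or `NULL` for the per-scale
#'   adaptive choice.
#' @param polarity `"bright"` or `"dark"`.
#' @param gamma scale-normalization exponent.
#' @return Object of class `feature_map`: list with `v` (matrix in
#'   `[0, 1]`), `best_scale_idx` (integer matrix of indices into
#'   `scales`; 0 where the response is 0 at every scale is not used —
#'   ties take the first scale), and `scales`.
#' @export
multiscale_response <- function(img, scales, beta_r = 0.5, c_r = NULL,
                                polarity = c("bright", "dark"), gamma = 2) {
  polarity <- match.arg(polarity)
  if (length(scales) < 1L) stop("scale grid must be non-empty")
  if (any(scales <= 0) || is.unsorted(scales, strictly = TRUE))
    stop("scale grid must be positive and strictly increasing")
  mat <- as_intensity_matrix(img)
  v <- matrix(0, nrow(mat), ncol(mat))
  idx <- matrix(1L, nrow(mat), ncol(mat))
  for (i in seq_along(scales)) {
    hf <- hessian_at_scale(mat, scales[i], gamma = gamma)
    eg <- eigvals2x2_vec(hf$lxx, hf$lxy, hf$lyy)
    cr_i <- c_r
    if (is.null(cr_i)) {
      frob <- sqrt(hf$lxx^2 + 2 * hf$lxy^2 + hf$lyy^2)
      cr_i <- max(frob) / 2
    }
    if (cr_i < 1e-8) next  # flat image at this scale: response stays 0
    vi <- line_response(eg$l1, eg$l2, beta_r = beta_r, c_r = cr_i,
                        polarity = polarity)
    better <- vi > v
    v[better] <- vi[better]
    idx[better] <- i
  }
  structure(list(v = v, best_scale_idx = idx, scales = scales),
            class = "feature_map")
}

is_feature_map <- function(x) inherits(x, "feature_map")

#' @export
print.feature_map <- function(x, ...) {
  cat(sprintf("<feature_map> %dx%d, %d scales [%s], response range [%.4f, %.4f]\n",
              nrow(x$v), ncol(x$v), length(x$scales),
              paste(x$scales, collapse = ", "), min(x$v), max(x$v)))
  invisible(x)
}

#' Export a feature map as 32-bit float TIFF
#'
#' @param fmap a [multiscale_response()] result.
#' @param path output `.tif`/`.tiff` path.
#' @return `path`, invisibly.
#' @export
write_feature_map <- function(fmap, path) {
  stopifnot(is_feature_map(fmap))
  tiff::writeTIFF(fmap$v, where = path, bits.per.sample = 32L)
  invisible(path)
}
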