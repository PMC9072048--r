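# Deterministic boundary refinement: binary boundary map, discrete
# eight-direction map toward same-label interior, and offset-based
# label remapping with a manual scaling factor.
#
# Compass codes (0..7): E, NE, N, NW, W, SW, S, SE.  North is "up"
# (decreasing row index).  Smaller code = higher tie-break priority.

COMPASS_OFFSETS <- matrix(c(
   0L,  1L,   # E
  -1L,  1L,   # NE
  -1L,  0L,   # N
  -1L, -1L,   # NW
   0L, -1L,   # W
   1L, -1L,   # SW
   1L,  0L,   # S
   1L,  1L    # SE
), ncol = 2L, byrow = TRUE)

#' Boundary map of a label field
#'
#' Flags every pixel with at least one 4-neighbor carrying a different
#' label; image-border pixels compare only their existing neighbors.
#'
#' @param y binary label matrix.
#' @return Integer matrix over `{0, 1}`; 1 marks boundary pixels.
#' @export
boundary_map <- function(y) {
  validate_label_field(y)
  h <- nrow(y); w <- ncol(y)
  b <- matrix(FALSE, h, w)
  if (h > 1L) {
    d <- y[-1L, , drop = FALSE] != y[-h, , drop = FALSE]
    b[-h, ] <- b[-h, ] | d
    b[-1L, ] <- b[-1L, ] | d
  }
  if (w > 1L) {
    d <- y[, -1L, drop = FALSE] != y[, -w, drop = FALSE]
    b[, -w] <- b[, -w] | d
    b[, -1L] <- b[, -1L] | d
  }
  mode(b) <- "integer"
  b
}

# quantize the direction (dr, dc) into one of 8 compass sectors of 45
# degrees centered on the compass axes
compass_code <- function(dr, dc) {
  ang <- atan2(-dr, dc)           # N (up) = +90 degrees
  as.integer(round(ang / (pi / 4)) %% 8)
}

#' Eight-direction map toward same-label interior
#'
#' For every boundary pixel, finds the nearest (Euclidean) interior
#' pixel (`b = 0`) carrying the same label, and quantizes the
#' direction to it into eight 45-degree sectors centered on the
#' compass directions.  Equidistant candidates are resolved by the
#' fixed priority E > NE > N > NW > W > SW > S > SE.  Boundary pixels
#' whose class has no interior pixel anywhere in the image receive the
#' sentinel and are left unrefined.
#'
#' @param y binary label matrix.
#' @param b boundary map derived from `y` (see [boundary_map()]).
#' @return Integer matrix: compass code 0..7 at boundary pixels, -1
#'   elsewhere (and at unresolvable boundary pixels).
#' @export
direction_map <- function(y, b) {
  validate_label_field(y)
  stopifnot(identical(dim(b), dim(y)))
  h <- nrow(y); w <- ncol(y)
  d <- matrix(-1L, h, w)
  interior <- b == 0L
  chebyshev_ring <- function(r) {
    dr <- c(rep(-r, 2L * r + 1L), rep(r, 2L * r + 1L),
            rep(seq(-r + 1L, r - 1L), 2L))
    dc <- c(rep(seq(-r, r), 2L),
            rep(-r, 2L * r - 1L), rep(r, 2L * r - 1L))
    cbind(dr, dc)
  }
  r_max <- max(h, w) - 1L
  for (lab in 0:1) {
    intr <- interior & y == lab
    idx <- which(b == 1L & y == lab)   # unresolved boundary pixels
    if (length(idx) == 0L || !any(intr)) next
    tr <- ((idx - 1L) %% h) + 1L
    tc <- ((idx - 1L) %/% h) + 1L
    # sweep offsets in (Euclidean distance, compass priority) order;
    # offsets become final once the swept Chebyshev radius reaches
    # their Euclidean distance, so nearer unseen offsets cannot exist
    sweep_offsets <- function(cand) {
      codes <- compass_code(cand[, 1L], cand[, 2L])
      for (q in order(cand[, 3L], codes)) {
        rr <- tr + cand[q, 1L]
        cc <- tc + cand[q, 2L]
        ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
        ok[ok] <- intr[(cc[ok] - 1L) * h + rr[ok]]
        if (any(ok)) {
          d[idx[ok]] <<- codes[q]
          keep <- !ok
          idx <<- idx[keep]; tr <<- tr[keep]; tc <<- tc[keep]
          if (length(idx) == 0L) break
        }
      }
    }
    pending <- NULL  # offsets seen but farther than the swept radius
    r <- 0L
    while (length(idx) > 0L && r < r_max) {
      r <- r + 1L
      ring <- chebyshev_ring(r)
      cand <- rbind(pending, cbind(ring, ring[, 1L]^2 + ring[, 2L]^2))
      ready <- cand[, 3L] <= r^2
      pending <- cand[!ready, , drop = FALSE]
      if (any(ready)) sweep_offsets(cand[ready, , drop = FALSE])
    }
    # far-corner offsets beyond the swept radius for any stragglers
    if (length(idx) > 0L && !is.null(pending) && nrow(pending) > 0L)
      sweep_offsets(pending)
  }
  d
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Offset-based boundary label refinement
#'
#' Interior pixels are kept verbatim.  Each boundary pixel `p` takes
#' the (input) label found at `p + round(r * u(d(p)))`, where `u` is
#' the unit offset of its compass code (diagonals use `(+-1, +-1)`)
#' and rounding is half-away-from-zero.  Offsets landing outside the
#' image, and boundary pixels with the sentinel direction, leave the
#' pixel unchanged.  All reads use the input field, so the operation
#' is order-independent and deterministic.
#'
#' @param y binary label matrix.
#' @param b boundary map from [boundary_map()].
#' @param d direction map from [direction_map()].
#' @param r non-negative scaling factor; `r = 0` is the identity.
#' @return Refined binary label matrix.
#' @export
refine_labels <- function(y, b, d, r = 1.0) {
  validate_label_field(y)
  stopifnot(identical(dim(b), dim(y)), identical(dim(d), dim(y)))
  if (r < 0) stop("scaling factor `r` must be >= 0")
  h <- nrow(y); w <- ncol(y)
  out <- y
  bnd <- which(b == 1L & d >= 0L)
  if (length(bnd) == 0L) return(out)
  for (p in bnd) {
    i <- ((p - 1L) %% h) + 1L
    j <- ((p - 1L) %/% h) + 1L
    off <- COMPASS_OFFSETS[d[i, j] + 1L, ]
    ti <- i + round_half_away(r * off[1L])
    tj <- j + round_half_away(r * off[2L])
    if (ti >= 1L && ti <= h && tj >= 1L && tj <= w)
      out[i, j] <- y[ti, tj]
  }
  out
}

#' One-call boundary refinement
#'
#' Convenience wrapper chaining [boundary_map()], [direction_map()]
#' and [refine_labels()].
#'
#' @param y binary label matrix.
#' @param r scaling factor passed to [refine_labels()].
#' @return Refined binary label matrix.
#' @export
refine_segmentation <- function(y, r = 1.0) {
  b <- boundary_map(y)
  d <- direction_map(y, b)
  refine_labels(y, b, d, r)
}
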