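# Seeded generator of curvilinear phantoms with ground truth.  The
# skeleton is a tree of constrained random-walk strokes (binary
# branching with angular jitter), dilated to a per-stroke width;
# background gray levels come from a Rayleigh + two-Gaussian mixture,
# the target from a single Gaussian, and zero-mean Gaussian noise of
# configurable variance is added on the normalized [0, 1] scale.

#' Phantom generator configuration
#'
#' Defaults emulate the statistical image model the pipeline assumes:
#' a dark Rayleigh background mode plus two mid-gray Gaussian modes, a
#' bright Gaussian target, and a tree of strokes whose widths vary per
#' branch.  The noise variance lives on the normalized `[0, 1]` scale,
#' so its meaning is independent of bit depth.
#'
#' @param size `c(height, width)` in pixels, each `>= 3`.
#' @param n_branches number of root strokes.
#' @param depth tree recursion depth (1 = no children).
#' @param steps length of a root stroke in unit steps; children get
#'   60\% of their parent's length.
#' @param angle_jitter per-step heading jitter sd in radians; 0 gives
#'   straight strokes.
#' @param width_range integer `c(w_min, w_max)` stroke widths in
#'   pixels, `w_min >= 1`.
#' @param target_mean,target_sd gray-level Gaussian of the bright
#'   target.
#' @param bg_rayleigh_sigma Rayleigh scale of the dark background mode.
#' @param bg_gauss_means,bg_gauss_sds the two mid-gray background
#'   Gaussians.
#' @param bg_weights mixing weights of the three background
#'   components (Rayleigh first); must sum to 1.
#' @param bg_constant if not `NULL`, replaces the whole background
#'   mixture by this constant gray level (degenerate background, used
#'   in deterministic checks).
#' @param noise_variance additive Gaussian noise variance on the
#'   normalized scale, `>= 0`.
#' @param bit_depth 8 or 16.
#' @param seed non-negative integer.
#' @return List of class `phantom_config`.
#' @export
phantom_config <- function(size = c(512L, 512L),
                           n_branches = 2L,
                           depth = 3L,
                           steps = NULL,
                           angle_jitter = 0.15,
                           width_range = c(2L, 5L),
                           target_mean = 200, target_sd = 10,
                           bg_rayleigh_sigma = 20,
                           bg_gauss_means = c(90, 140),
                           bg_gauss_sds = c(10, 12),
                           bg_weights = c(0.35, 0.40, 0.25),
                           bg_constant = NULL,
                           noise_variance = 0.02,
                           bit_depth = 8L,
                           seed = 0L) {
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 3L))
    stop("`size` must be two integers >= 3")
  if (is.null(steps)) steps <- as.integer(round(0.5 * min(size)))
  if (n_branches < 1L) stop("`n_branches` must be >= 1")
  if (depth < 1L) stop("`depth` must be >= 1")
  if (width_range[1L] < 1L || width_range[2L] < width_range[1L])
    stop("`width_range` must satisfy 1 <= w_min <= w_max")
  if (target_sd <= 0 || any(bg_gauss_sds <= 0) || bg_rayleigh_sigma <= 0)
    stop("all scale/sd parameters must be positive")
  if (abs(sum(bg_weights) - 1) > 1e-9)
    stop("`bg_weights` must sum to 1")
  if (noise_variance < 0) stop("`noise_variance` must be >= 0")
  if (seed < 0 || seed != round(seed))
    stop("`seed` must be a non-negative integer")
  structure(list(
    size = size, n_branches = as.integer(n_branches),
    depth = as.integer(depth), steps = as.integer(steps),
    angle_jitter = angle_jitter,
    width_range = as.integer(width_range),
    target_mean = target_mean, target_sd = target_sd,
    bg_rayleigh_sigma = bg_rayleigh_sigma,
    bg_gauss_means = bg_gauss_means, bg_gauss_sds = bg_gauss_sds,
    bg_weights = bg_weights, bg_constant = bg_constant,
    noise_variance = noise_variance,
    bit_depth = as.integer(bit_depth), seed = as.integer(seed)
  ), class = "phantom_config")
}

# Random-walk stroke with border bouncing; returns the continuous
# (row, col) positions after each unit step.  Consumes the current
# RNG stream.
walk_stroke <- function(start, heading, steps, jitter, h, w) {
  pos <- start
  theta <- heading
  path <- matrix(0, steps + 1L, 2L)
  path[1L, ] <- pos
  for (s in seq_len(steps)) {
    if (jitter > 0) theta <- theta + stats::rnorm(1L, 0, jitter)
    dr <- sin(theta); dc <- cos(theta)
    if (pos[1L] + dr < 1 || pos[1L] + dr > h) { dr <- -dr; theta <- -theta }
    if (pos[2L] + dc < 1 || pos[2L] + dc > w) {
      dc <- -dc; theta <- pi - theta
    }
    pos <- c(pos[1L] + dr, pos[2L] + dc)
    pos[1L] <- min(max(pos[1L], 1), h)
    pos[2L] <- min(max(pos[2L], 1), w)
    path[s + 1L, ] <- pos
  }
  path
}

# Mark every pixel whose center lies within width/2 (Euclidean) of the
# continuous path, i.e. a tube of the requested width, so stroke area
# is ~ width * length independently of orientation.  The path is
# resampled at quarter-step resolution before stamping.
stamp_stroke <- function(mask, path, width) {
  h <- nrow(mask); w <- ncol(mask)
  n <- nrow(path)
  if (n > 1L) {
    f <- seq(0, 1, by = 0.25)[-5L]
    pr <- as.vector(outer(path[-n, 1L], rep(1, 4L)) +
                    outer(path[-1L, 1L] - path[-n, 1L], f))
    pc <- as.vector(outer(path[-n, 2L], rep(1, 4L)) +
                    outer(path[-1L, 2L] - path[-n, 2L], f))
    pr <- c(pr, path[n, 1L]); pc <- c(pc, path[n, 2L])
  } else {
    pr <- path[1L, 1L]; pc <- path[1L, 2L]
  }
  rad <- width / 2
  span <- ceiling(rad)
  offs <- expand.grid(dr = -span:span, dc = -span:span)
  cr <- round(pr); cc <- round(pc)
  for (p in seq_along(pr)) {
    ri <- cr[p] + offs$dr
    ci <- cc[p] + offs$dc
    ok <- (ri - pr[p])^2 + (ci - pc[p])^2 <= rad^2 &
      ri >= 1L & ri <= h & ci >= 1L & ci <= w
    if (any(ok)) mask[cbind(ri[ok], ci[ok])] <- TRUE
  }
  mask
}

draw_skeleton <- function(cfg) {
  h <- cfg$size[1L]; w <- cfg$size[2L]
  mask <- matrix(FALSE, h, w)
  # stack of strokes: start row/col, heading, length, remaining depth
  queue <- lapply(seq_len(cfg$n_branches), function(b) {
    list(start = c(stats::runif(1, 0.2 * h, 0.8 * h),
                   stats::runif(1, 0.2 * w, 0.8 * w)),
         heading = stats::runif(1, 0, 2 * pi),
         steps = cfg$steps,
         depth = cfg$depth)
  })
  while (length(queue) > 0L) {
    st <- queue[[1L]]
    queue <- queue[-1L]
    if (st$steps < 2L) next
    path <- walk_stroke(st$start, st$heading, st$steps,
                        cfg$angle_jitter, h, w)
    width <- if (cfg$width_range[1L] == cfg$width_range[2L])
      cfg$width_range[1L]
    else sample(cfg$width_range[1L]:cfg$width_range[2L], 1L)
    mask <- stamp_stroke(mask, path, width)
    if (st$depth > 1L) {
      for (child in 1:2) {
        at <- path[max(2L, round(stats::runif(1, 0.3, 0.9) * nrow(path))), ]
        sign_ <- if (child == 1L) 1 else -1
        queue <- c(queue, list(list(
          start = as.numeric(at),
          heading = st$heading + sign_ * (pi / 4) +
            stats::rnorm(1, 0, cfg$angle_jitter),
          steps = as.integer(round(st$steps * 0.6)),
          depth = st$depth - 1L)))
      }
    }
  }
  mask
}

# noise + clip + quantize on the normalized scale; consumes RNG stream
apply_noise_quantize <- function(norm, variance, max_level) {
  if (variance > 0)
    norm <- norm + stats::rnorm(length(norm), 0, sqrt(variance))
  norm <- pmin(pmax(norm, 0), 1)
  matrix(as.integer(floor(norm * max_level + 0.5)), nrow(norm), ncol(norm))
}

#' Generate a curvilinear phantom with ground truth
#'
#' Builds a random stroke tree, dilates it to per-branch widths to
#' form the truth mask, fills background and foreground from the
#' configured mixtures, and adds seeded Gaussian noise.  If the
#' resulting foreground fraction is not in `(0, 0.5)` the phantom is
#' regenerated with a perturbed seed, up to 5 attempts.
#'
#' @param cfg a [phantom_config()].
#' @return List of class `phantom_pair`: `image` (a [gray_image()]),
#'   `truth` (binary label matrix), `meta` (resolved config, the seed
#'   actually used, and the foreground fraction).
#' @export
generate_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  max_level <- as.integer(2L^cfg$bit_depth - 1L)
  h <- cfg$size[1L]; w <- cfg$size[2L]
  for (attempt in 0:4) {
    seed_used <- cfg$seed + 1000L * attempt
    res <- with_seed(seed_used, {
      truth <- draw_skeleton(cfg)
      frac <- mean(truth)
      if (frac <= 0 || frac >= 0.5) NULL
      else {
        clean <- matrix(0L, h, w)
        n_bg <- sum(!truth)
        if (is.null(cfg$bg_constant)) {
          # draw inline so everything rides the same seeded stream
          comp <- sample.int(3L, n_bg, replace = TRUE, prob = cfg$bg_weights)
          vals <- numeric(n_bg)
          sel <- comp == 1L
          vals[sel] <- stats::rweibull(sum(sel), shape = 2,
                                       scale = cfg$bg_rayleigh_sigma * sqrt(2))
          for (g in 1:2) {
            sel <- comp == g + 1L
            vals[sel] <- stats::rnorm(sum(sel), cfg$bg_gauss_means[g],
                                      cfg$bg_gauss_sds[g])
          }
          clean[!truth] <- as.integer(pmin(pmax(round(vals), 0), max_level))
        } else {
          clean[!truth] <- as.integer(cfg$bg_constant)
        }
        n_fg <- sum(truth)
        fg_vals <- stats::rnorm(n_fg, cfg$target_mean, cfg$target_sd)
        clean[truth] <- as.integer(pmin(pmax(round(fg_vals), 0), max_level))
        noisy <- apply_noise_quantize(clean / max_level,
                                      cfg$noise_variance, max_level)
        list(truth = truth, pixels = noisy, frac = frac)
      }
    })
    if (!is.null(res)) {
      truth_int <- res$truth
      mode(truth_int) <- "integer"
      return(structure(list(
        image = gray_image(res$pixels, bit_depth = cfg$bit_depth),
        truth = truth_int,
        meta = list(config = cfg, seed_used = seed_used,
                    foreground_fraction = res$frac)
      ), class = "phantom_pair"))
    }
  }
  stop("could not generate a phantom with foreground fraction in (0, 0.5) ",
       "after 5 attempts")
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat(sprintf("<phantom_pair> %dx%d, %d-bit, foreground fraction %.4f, seed %d\n",
              x$image$height, x$image$width, x$image$bit_depth,
              x$meta$foreground_fraction, x$meta$seed_used))
  invisible(x)
}

#' Add Gaussian noise on the normalized scale
#'
#' Adds i.i.d. zero-mean Gaussian noise with the given variance to the
#' image normalized to `[0, 1]`, clips to `[0, 1]`, and re-quantizes
#' (round half up) at the image's bit depth.
#'
#' @param img a [gray_image()].
#' @param variance noise variance on the normalized scale, `>= 0`.
#' @param seed integer seed.
#' @return A [gray_image()] of the same shape and bit depth.
#' @export
add_gaussian_noise <- function(img, variance, seed = 0L) {
  stopifnot(is_gray_image(img))
  if (variance < 0) stop("`variance` must be >= 0")
  if (variance == 0) return(img)
  px <- with_seed(seed,
    apply_noise_quantize(normalize_image(img), variance, img$max_level))
  gray_image(px, bit_depth = img$bit_depth)
}
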