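# Finite mixture model of the gray-level histogram: one Rayleigh plus
# Gaussian components for the background, one Gaussian for the bright
# target.  Fitting is histogram-weighted EM, exactly equivalent to
# per-pixel EM because responsibilities depend on a pixel only through
# its gray level.

SD_FLOOR <- 0.5    # gray levels; guards against singular spikes
P_FLOOR  <- 1e-12  # density floor before taking -log
E_MAX    <- -log(P_FLOOR)

#' Construct mixture-model parameters
#'
#' Components are stored in a fixed order: the Rayleigh component (if
#' any) first, then background Gaussians, then the target Gaussian
#' last.  `class_of_component` tags each one `"background"` or
#' `"target"`.
#'
#' @param weights mixing weights, one per component; must sum to 1
#'   within 1e-9.
#' @param rayleigh_sigma scale of the Rayleigh component, or `NA` if
#'   the model has none.
#' @param gauss_means,gauss_sds parameters of the Gaussian components
#'   (in component order, excluding the Rayleigh).
#' @param class_of_component character vector, one entry per
#'   component, each `"background"` or `"target"`.
#' @return An object of class `mixture_params`.
#' @export
mixture_params <- function(weights, rayleigh_sigma = NA_real_,
                           gauss_means = numeric(), gauss_sds = numeric(),
                           class_of_component) {
  n_ray <- as.integer(!is.na(rayleigh_sigma))
  m <- n_ray + length(gauss_means)
  if (length(weights) != m)
    stop("expected ", m, " weights for ", m, " components, got ", length(weights))
  if (length(gauss_sds) != length(gauss_means))
    stop("`gauss_means` and `gauss_sds` lengths differ")
  if (any(weights <= 0) || any(weights >= 1 + 1e-9))
    stop("all weights must lie in (0, 1)")
  if (abs(sum(weights) - 1) > 1e-9)
    stop("weights must sum to 1 (got ", format(sum(weights)), ")")
  if (n_ray == 1L && rayleigh_sigma <= 0)
    stop("`rayleigh_sigma` must be positive")
  if (any(gauss_sds <= 0)) stop("all Gaussian sds must be positive")
  if (length(class_of_component) != m)
    stop("`class_of_component` must have one entry per component")
  if (!all(class_of_component %in% c("background", "target")))
    stop("component classes must be 'background' or 'target'")
  if (sum(class_of_component == "target") > 1L)
    stop("at most one component may be tagged 'target'")
  if (n_ray == 1L && class_of_component[1L] != "background")
    stop("the Rayleigh component models background")
  structure(
    list(weights = as.numeric(weights),
         rayleigh_sigma = as.numeric(rayleigh_sigma),
         gauss_means = as.numeric(gauss_means),
         gauss_sds = as.numeric(gauss_sds),
         class_of_component = class_of_component),
    class = "mixture_params")
}

is_mixture_params <- function(x) inherits(x, "mixture_params")

n_components <- function(params) length(params$weights)

has_rayleigh <- function(params) !is.na(params$rayleigh_sigma)

#' @export
print.mixture_params <- function(x, ...) {
  m <- n_components(x)
  cat(sprintf("<mixture_params> %d components\n", m))
  k <- 1L
  if (has_rayleigh(x)) {
    cat(sprintf("  [%d] Rayleigh  sigma=%.3f  w=%.4f  (%s)\n",
                k, x$rayleigh_sigma, x$weights[1L], x$class_of_component[1L]))
    k <- 2L
  }
  for (j in seq_along(x$gauss_means)) {
    cat(sprintf("  [%d] Gaussian  mu=%.3f sd=%.3f  w=%.4f  (%s)\n",
                k, x$gauss_means[j], x$gauss_sds[j], x$weights[k],
                x$class_of_component[k]))
    k <- k + 1L
  }
  invisible(x)
}

rayleigh_density <- function(t, sigma) {
  d <- (t / sigma^2) * exp(-t^2 / (2 * sigma^2))
  d[t < 0] <- 0
  d
}

# length(t) x M matrix of per-component densities, component order as stored
component_densities <- function(t, params) {
  m <- n_components(params)
  dens <- matrix(0, length(t), m)
  k <- 1L
  if (has_rayleigh(params)) {
    dens[, 1L] <- rayleigh_density(t, params$rayleigh_sigma)
    k <- 2L
  }
  for (j in seq_along(params$gauss_means)) {
    dens[, k] <- stats::dnorm(t, params$gauss_means[j], params$gauss_sds[j])
    k <- k + 1L
  }
  dens
}

#' Mixture density at given gray levels
#'
#' Evaluates the weighted sum of the Rayleigh density
#' `(t / sigma^2) exp(-t^2 / (2 sigma^2))` and the Gaussian component
#' densities at gray level(s) `t`.
#'
#' @param t numeric vector of gray levels.
#' @param params a [mixture_params()] object.
#' @return Numeric vector of densities (per unit gray level).
#' @export
mixture_pdf <- function(t, params) {
  stopifnot(is_mixture_params(params))
  as.numeric(component_densities(t, params) %*% params$weights)
}

# ---------------------------------------------------------------------------
# EM fitting

#' Component specification for [fit_em()]
#'
#' @param n_rayleigh 0 or 1 Rayleigh background components.
#' @param n_background_gauss number of Gaussian background components.
#' @param n_target 0 or 1 target Gaussian (always the last component).
#' @return A list of counts with class `mixture_spec`.
#' @export
mixture_spec <- function(n_rayleigh = 1L, n_background_gauss = 2L,
                         n_target = 1L) {
  n_rayleigh <- as.integer(n_rayleigh)
  n_background_gauss <- as.integer(n_background_gauss)
  n_target <- as.integer(n_target)
  if (!n_rayleigh %in% 0:1) stop("`n_rayleigh` must be 0 or 1")
  if (!n_target %in% 0:1) stop("`n_target` must be 0 or 1")
  if (n_background_gauss < 0) stop("`n_background_gauss` must be >= 0")
  if (n_rayleigh + n_background_gauss + n_target < 1L)
    stop("the mixture needs at least one component")
  structure(list(n_rayleigh = n_rayleigh,
                 n_background_gauss = n_background_gauss,
                 n_target = n_target),
            class = "mixture_spec")
}

hist_quantile <- function(hist, p) {
  cdf <- cumsum(hist$counts) / hist$n_pixels
  t <- 0:hist$max_level
  vapply(p, function(pp) t[which(cdf >= pp)[1L]], numeric(1))
}

hist_mean <- function(hist) {
  sum((0:hist$max_level) * hist$counts) / hist$n_pixels
}

hist_var <- function(hist) {
  mu <- hist_mean(hist)
  sum(((0:hist$max_level) - mu)^2 * hist$counts) / hist$n_pixels
}

# Deterministic quantile-based initialization.  The Rayleigh takes the
# lowest quartile of the mass; background Gaussians start at evenly
# spaced quantiles of the mid-range; the target Gaussian (the bright
# minority class) starts at the 99th percentile with a small weight,
# so it does not capture an upper background mode.
em_init <- function(hist, spec) {
  n_gauss <- spec$n_background_gauss + spec$n_target
  global_sd <- sqrt(max(hist_var(hist), SD_FLOOR^2))
  t <- 0:hist$max_level
  if (spec$n_rayleigh == 1L) {
    q25 <- hist_quantile(hist, 0.25)
    low <- t <= q25
    mass <- sum(hist$counts[low])
    sig <- if (mass > 0) sqrt(sum(hist$counts[low] * t[low]^2) / (2 * mass)) else 1
    rayleigh_sigma <- max(sig, 1)
    lo <- 0.25
    w_ray <- 0.25
  } else {
    rayleigh_sigma <- NA_real_
    lo <- 0
    w_ray <- 0
  }
  if (n_gauss > 0L) {
    w_target <- if (spec$n_target == 1L) 0.05 else 0
    n_bg <- spec$n_background_gauss
    hi <- if (spec$n_target == 1L) 0.95 else 1
    if (n_bg > 0L) {
      pj <- lo + (hi - lo) * (seq_len(n_bg) - 0.5) / n_bg
      bg_means <- hist_quantile(hist, pj)
      bg_w <- rep((1 - w_ray - w_target) / n_bg, n_bg)
    } else {
      bg_means <- numeric(); bg_w <- numeric()
      if (spec$n_target == 1L) w_target <- 1 - w_ray
      else w_ray <- 1
    }
    means <- c(bg_means,
               if (spec$n_target == 1L) hist_quantile(hist, 0.99))
    sds <- rep(max(global_sd / (2 * n_gauss), SD_FLOOR), n_gauss)
    w_g <- c(bg_w, if (spec$n_target == 1L) w_target)
  } else {
    means <- numeric(); sds <- numeric(); w_g <- numeric()
    w_ray <- 1
  }
  cls <- c(rep("background", spec$n_rayleigh + spec$n_background_gauss),
           rep("target", spec$n_target))
  mixture_params(weights = c(if (spec$n_rayleigh) w_ray, w_g),
                 rayleigh_sigma = rayleigh_sigma,
                 gauss_means = means, gauss_sds = sds,
                 class_of_component = cls)
}

param_vector <- function(params) {
  c(params$weights,
    if (has_rayleigh(params)) params$rayleigh_sigma,
    params$gauss_means, params$gauss_sds)
}

#' Fit the gray mixture model by histogram-weighted EM
#'
#' The E step computes responsibilities per gray level (not per
#' pixel), weighted by the histogram counts `h_t`; the M step uses the
#' closed forms obtained by zeroing the partial derivatives of the
#' expected complete-data log-likelihood:
#' `w_k = sum_t h_t r_kt / n`,
#' `mu_k = sum_t h_t r_kt t / sum_t h_t r_kt` (and `sigma_k^2`
#' likewise) for Gaussians, and
#' `sigma^2 = sum_t h_t r_t t^2 / (2 sum_t h_t r_t)` for the Rayleigh.
#' Iteration stops when the RMSE between successive stacked parameter
#' vectors falls below `tol`, or after `max_iter` iterations.
#'
#' Initialization is deterministic, from histogram quantiles (see the
#' vignette).  If a component's responsibility mass collapses, it is
#' reinitialized from a seeded random quantile with a warning — the
#' only use of `seed`.
#'
#' @param hist a [compute_histogram()] result.
#' @param spec a [mixture_spec()]; the pipeline default is 1 Rayleigh
#'   + 2 background Gaussians + 1 target Gaussian.
#' @param tol convergence tolerance on the parameter-vector RMSE.
#' @param max_iter maximum EM iterations.
#' @param seed seed for the (rare) collapse-recovery reinitialization.
#' @return A [mixture_params()] object with attributes
#'   `loglik_trace` (log-likelihood after each M step, non-decreasing),
#'   `n_iter`, and `converged`.
#' @export
fit_em <- function(hist, spec = mixture_spec(), tol = 1e-6,
                   max_iter = 500L, seed = 0L) {
  stopifnot(is_gray_histogram(hist), inherits(spec, "mixture_spec"))
  if (hist$n_pixels <= 0L) stop("empty histogram")
  occupied <- which(hist$counts > 0L)
  if (length(occupied) < 2L)
    stop("degenerate histogram: all pixels share one gray level")
  t <- 0:hist$max_level
  h <- as.numeric(hist$counts)
  n <- hist$n_pixels
  params <- em_init(hist, spec)
  m <- n_components(params)
  trace <- numeric(0)
  converged <- FALSE
  global_sd <- sqrt(max(hist_var(hist), SD_FLOOR^2))
  with_seed(seed, {
    for (iter in seq_len(max_iter)) {
      old <- param_vector(params)
      # E step on gray levels
      dens <- component_densities(t, params)
      wdens <- sweep(dens, 2L, params$weights, `*`)
      denom <- rowSums(wdens)
      resp <- wdens / denom
      zero <- denom <= 0
      if (any(zero))
        resp[zero, ] <- matrix(params$weights, sum(zero), m, byrow = TRUE)
      # M step, histogram-weighted
      hr <- h * resp                       # (L+1) x M
      nk <- colSums(hr)
      collapsed <- nk < 1e-8 * n
      w <- pmax(nk, 1e-12) / n
      w <- w / sum(w)
      k <- 1L
      ray <- params$rayleigh_sigma
      if (has_rayleigh(params)) {
        if (!collapsed[1L])
          ray <- sqrt(sum(hr[, 1L] * t^2) / (2 * nk[1L]))
        k <- 2L
      }
      means <- params$gauss_means
      sds <- params$gauss_sds
      for (j in seq_along(means)) {
        kk <- k + j - 1L
        if (!collapsed[kk]) {
          means[j] <- sum(hr[, kk] * t) / nk[kk]
          sds[j] <- max(sqrt(sum(hr[, kk] * (t - means[j])^2) / nk[kk]),
                        SD_FLOOR)
        }
      }
      # collapse recovery: reseed the dead component from a random quantile
      if (any(collapsed)) {
        for (kk in which(collapsed)) {
          warning("mixture component ", kk,
                  " lost all responsibility mass; reinitialized")
          if (has_rayleigh(params) && kk == 1L) {
            ray <- max(hist_quantile(hist, stats::runif(1, 0.05, 0.3)), 1)
          } else {
            j <- kk - as.integer(has_rayleigh(params))
            means[j] <- hist_quantile(hist, stats::runif(1, 0.1, 0.9))
            sds[j] <- max(global_sd / 4, SD_FLOOR)
          }
          w[kk] <- 0.05
          w <- w / sum(w)
        }
      }
      params <- mixture_params(weights = w, rayleigh_sigma = ray,
                               gauss_means = means, gauss_sds = sds,
                               class_of_component = params$class_of_component)
      dens_new <- component_densities(t, params)
      ll <- sum(h * log(pmax(as.numeric(dens_new %*% params$weights), 1e-300)))
      trace <- c(trace, ll)
      rmse <- sqrt(mean((param_vector(params) - old)^2))
      if (rmse < tol) { converged <- TRUE; break }
    }
  })
  attr(params, "loglik_trace") <- trace
  attr(params, "n_iter") <- length(trace)
  attr(params, "converged") <- converged
  params
}

# ---------------------------------------------------------------------------
# Likelihood energies

#' Per-pixel negative log-likelihood energy maps
#'
#' The background class-conditional density renormalizes the
#' background components among themselves; the target density is the
#' target Gaussian alone.  Class priors are not applied here — they
#' are carried by the MRF, so they are not double-counted.  Energies
#' are `-log(max(p, 1e-12))`, hence clamped to `E_max = -log(1e-12)`.
#'
#' @param img a [gray_image()] on the same gray range as the fitting
#'   histogram.
#' @param params fitted [mixture_params()] with at least one
#'   background component and exactly one target component.
#' @return List of class `energy_map_pair` with matrices `e_bg` and
#'   `e_fg` (same shape as the image) and the scalar `e_max`.
#' @export
likelihood_energy <- function(img, params) {
  stopifnot(is_gray_image(img), is_mixture_params(params))
  cls <- params$class_of_component
  if (sum(cls == "target") != 1L)
    stop("params must contain exactly one target component")
  if (sum(cls == "background") < 1L)
    stop("params must contain at least one background component")
  t <- 0:img$max_level
  dens <- component_densities(t, params)
  bg <- cls == "background"
  w_bg <- params$weights[bg] / sum(params$weights[bg])
  p_bg <- as.numeric(dens[, bg, drop = FALSE] %*% w_bg)
  p_fg <- dens[, which(cls == "target")]
  e_bg_lut <- -log(pmax(p_bg, P_FLOOR))
  e_fg_lut <- -log(pmax(p_fg, P_FLOOR))
  idx <- img$pixels + 1L
  structure(
    list(e_bg = matrix(e_bg_lut[idx], img$height, img$width),
         e_fg = matrix(e_fg_lut[idx], img$height, img$width),
         e_max = E_MAX),
    class = "energy_map_pair")
}

# ---------------------------------------------------------------------------
# Sampling and serialization

#' Draw integer gray levels from a mixture model
#'
#' Samples component memberships and values, then rounds and clamps to
#' `[0, max_level]`.  Used by the phantom generator and as the
#' ground-truth generator in parameter-recovery checks.
#'
#' @param n number of draws.
#' @param params a [mixture_params()] object.
#' @param seed integer seed.
#' @param max_level top gray level for clamping (default 255).
#' @return Integer vector of length `n`.
#' @export
sample_mixture <- function(n, params, seed = 0L, max_level = 255L) {
  stopifnot(is_mixture_params(params))
  with_seed(seed, {
    comp <- sample.int(n_components(params), n, replace = TRUE,
                       prob = params$weights)
    x <- numeric(n)
    k <- 1L
    if (has_rayleigh(params)) {
      sel <- comp == 1L
      # Rayleigh(sigma) == Weibull(shape 2, scale sigma * sqrt(2))
      x[sel] <- stats::rweibull(sum(sel), shape = 2,
                                scale = params$rayleigh_sigma * sqrt(2))
      k <- 2L
    }
    for (j in seq_along(params$gauss_means)) {
      sel <- comp == (k + j - 1L)
      x[sel] <- stats::rnorm(sum(sel), params$gauss_means[j],
                             params$gauss_sds[j])
    }
    as.integer(pmin(pmax(round(x), 0), max_level))
  })
}

#' Serialize mixture parameters to JSON
#'
#' @param params a [mixture_params()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
params_to_json <- function(params, path) {
  stopifnot(is_mixture_params(params))
  obj <- list(schema_version = 1L,
              weights = params$weights,
              rayleigh_sigma = params$rayleigh_sigma,
              gauss_means = params$gauss_means,
              gauss_sds = params$gauss_sds,
              class_of_component = params$class_of_component)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Deserialize mixture parameters from JSON
#'
#' @param path a file written by [params_to_json()].
#' @return A [mixture_params()] object.
#' @export
params_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) || obj$schema_version != 1L)
    stop("unsupported mixture parameter schema")
  rs <- obj$rayleigh_sigma
  if (is.null(rs) || length(rs) == 0L) rs <- NA_real_
  mixture_params(weights = obj$weights, rayleigh_sigma = rs,
                 gauss_means = obj$gauss_means, gauss_sds = obj$gauss_sds,
                 class_of_component = obj$class_of_component)
}
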