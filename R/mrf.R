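# MRF labeling energy (gray likelihood + isotropic MLL/Potts prior +
# multiscale feature term) and its ICM minimization.  Label fields are
# integer matrices over {0 = background, 1 = feature}.

validate_label_field <- function(y) {
  if (!is.matrix(y) || !is.numeric(y))
    stop("label field must be a numeric matrix")
  if (!all(y %in% c(0L, 1L)))
    stop("label field values must be 0 (background) or 1 (feature)")
  invisible(y)
}

fmap_values <- function(fmap, dim_ref = NULL) {
  v <- if (is_feature_map(fmap)) fmap$v else fmap
  if (!is.matrix(v)) stop("`fmap` must be a feature_map or numeric matrix")
  if (!is.null(dim_ref) && !identical(dim(v), dim(dim_ref)))
    stop("feature map shape does not match the label field")
  v
}

#' Isotropic MLL (Potts) prior energy
#'
#' `U(y) = beta * #{4-neighbor pairs with unequal labels}`, each
#' unordered pair counted once.
#'
#' @param y binary label matrix.
#' @param beta non-negative smoothness weight.
#' @return Scalar energy.
#' @export
prior_energy <- function(y, beta) {
  validate_label_field(y)
  if (beta < 0) stop("`beta` must be >= 0")
  h <- nrow(y); w <- ncol(y)
  n_diff <- 0L
  if (h > 1L) n_diff <- n_diff + sum(y[-1L, , drop = FALSE] != y[-h, , drop = FALSE])
  if (w > 1L) n_diff <- n_diff + sum(y[, -1L, drop = FALSE] != y[, -w, drop = FALSE])
  beta * n_diff
}

#' Multiscale feature energy
#'
#' Mismatch penalty coupling the label field to the line-similarity
#' response `v`: a feature-labeled pixel contributes
#' `alpha * (1 - v_i)`, a background-labeled pixel `alpha * v_i`.
#'
#' @param y binary label matrix.
#' @param fmap a [multiscale_response()] result or a response matrix.
#' @param alpha non-negative feature weight.
#' @return Scalar energy.
#' @export
feature_energy <- function(y, fmap, alpha) {
  validate_label_field(y)
  if (alpha < 0) stop("`alpha` must be >= 0")
  v <- fmap_values(fmap, y)
  alpha * sum(ifelse(y == 1L, 1 - v, v))
}

energy_breakdown <- function(epair, y, v, beta, alpha) {
  lik <- sum(ifelse(y == 1L, epair$e_fg, epair$e_bg))
  pri <- prior_energy(y, beta)
  fea <- if (is.null(v)) 0 else feature_energy(y, v, alpha)
  structure(list(likelihood_term = lik, prior_term = pri,
                 feature_term = fea, total = lik + pri + fea),
            class = "energy_breakdown")
}

#' Total MRF energy of a labeling
#'
#' Sums the likelihood term (per-pixel negative log class-conditional
#' likelihood of the chosen label), the Potts prior and the feature
#' term.
#'
#' @param img a [gray_image()].
#' @param params fitted [mixture_params()].
#' @param y binary label matrix.
#' @param fmap feature map (or `NULL` to drop the feature term).
#' @param beta,alpha energy weights, `>= 0`.
#' @return List of class `energy_breakdown` with `likelihood_term`,
#'   `prior_term`, `feature_term`, `total`.
#' @export
total_energy <- function(img, params, y, fmap = NULL, beta = 0, alpha = 0) {
  validate_label_field(y)
  if (!identical(dim(y), dim(img$pixels)))
    stop("label field shape does not match the image")
  epair <- likelihood_energy(img, params)
  energy_breakdown(epair, y, if (is.null(fmap)) NULL else fmap_values(fmap, y),
                   beta, alpha)
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("<energy_breakdown> total %.4f = likelihood %.4f + prior %.4f + feature %.4f\n",
              x$total, x$likelihood_term, x$prior_term, x$feature_term))
  invisible(x)
}

#' ICM on explicit energy maps
#'
#' Low-level iterated-conditional-modes driver.  The label field is
#' initialized by per-pixel maximum likelihood (`e_fg < e_bg`; ties go
#' to background).  Each sweep visits pixels in raster order (row by
#' row, left to right) and assigns the label minimizing the local
#' conditional energy — the unary terms plus `beta` times the number
#' of disagreeing 4-neighbors under the current labels.  Ties keep the
#' current label.  Sweeping stops at the first sweep with no changes,
#' or after `max_iter` sweeps.  Because each move is non-increasing,
#' the recorded per-sweep total energy never increases.
#'
#' @param e_bg,e_fg likelihood energy matrices (see
#'   [likelihood_energy()]).
#' @param v feature response matrix in `[0, 1]`, or `NULL`.
#' @param beta,alpha energy weights, `>= 0`.
#' @param max_iter maximum number of sweeps, `>= 1`.
#' @return List of class `icm_result`: `labels` (binary matrix),
#'   `energy_trace` (total energy after each sweep), `iterations`,
#'   `converged` (`TRUE` if a sweep changed nothing).
#' @export
icm_label <- function(e_bg, e_fg, v = NULL, beta = 0, alpha = 0,
                      max_iter = 100L) {
  stopifnot(is.matrix(e_bg), is.matrix(e_fg), identical(dim(e_bg), dim(e_fg)))
  if (beta < 0 || alpha < 0) stop("`beta` and `alpha` must be >= 0")
  if (max_iter < 1L) stop("`max_iter` must be >= 1")
  h <- nrow(e_bg); w <- ncol(e_bg)
  if (!is.null(v)) {
    if (!identical(dim(v), dim(e_bg)))
      stop("feature map shape does not match the energy maps")
    u_bg <- e_bg + alpha * v
    u_fg <- e_fg + alpha * (1 - v)
  } else {
    u_bg <- e_bg
    u_fg <- e_fg
  }
  # ML initialization from the likelihood alone; ties -> background
  y <- matrix(0L, h, w)
  y[e_fg < e_bg] <- 1L
  epair <- list(e_bg = e_bg, e_fg = e_fg)
  trace <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  for (sweep in seq_len(max_iter)) {
    changed <- 0L
    for (i in seq_len(h)) {
      for (j in seq_len(w)) {
        n1 <- 0L; nn <- 0L
        if (i > 1L) { nn <- nn + 1L; n1 <- n1 + y[i - 1L, j] }
        if (i < h)  { nn <- nn + 1L; n1 <- n1 + y[i + 1L, j] }
        if (j > 1L) { nn <- nn + 1L; n1 <- n1 + y[i, j - 1L] }
        if (j < w)  { nn <- nn + 1L; n1 <- n1 + y[i, j + 1L] }
        c0 <- u_bg[i, j] + beta * n1          # disagreements if label 0
        c1 <- u_fg[i, j] + beta * (nn - n1)   # disagreements if label 1
        cur <- y[i, j]
        new <- if (cur == 0L) {
          if (c1 < c0) 1L else 0L             # strict improvement only
        } else {
          if (c0 < c1) 0L else 1L
        }
        if (new != cur) { y[i, j] <- new; changed <- changed + 1L }
      }
    }
    iterations <- sweep
    trace <- c(trace, energy_breakdown(epair, y, v, beta, alpha)$total)
    if (changed == 0L) { converged <- TRUE; break }
  }
  structure(list(labels = y, energy_trace = trace,
                 iterations = iterations, converged = converged),
            class = "icm_result")
}

#' MAP segmentation by ICM
#'
#' Builds the likelihood energy maps from the fitted mixture, couples
#' them with the feature map, and runs [icm_label()].
#'
#' @param img a [gray_image()].
#' @param params fitted [mixture_params()].
#' @param fmap a [multiscale_response()] result (or `NULL` to disable
#'   the feature term).
#' @param beta Potts prior weight.
#' @param alpha feature term weight.
#' @param max_iter maximum ICM sweeps.
#' @return An `icm_result` (see [icm_label()]).
#' @export
icm_segment <- function(img, params, fmap = NULL, beta = 1.5, alpha = 1.0,
                        max_iter = 100L) {
  epair <- likelihood_energy(img, params)
  v <- if (is.null(fmap)) NULL else fmap_values(fmap, img$pixels)
  icm_label(epair$e_bg, epair$e_fg, v = v, beta = beta, alpha = alpha,
            max_iter = max_iter)
}

#' @export
print.icm_result <- function(x, ...) {
  cat(sprintf("<icm_result> %dx%d labels, %d sweep(s)%s, final energy %.4f, %d feature pixels\n",
              nrow(x$labels), ncol(x$labels), x$iterations,
              if (x$converged) " (converged)" else "",
              x$energy_trace[length(x$energy_trace)], sum(x$labels)))
  invisible(x)
}
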