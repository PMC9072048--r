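# Segmentation metrics, the gray-level k-means baseline, and the
# noise-robustness experiment harness.

#' Confusion-matrix segmentation metrics
#'
#' Pixel-wise comparison of a predicted and a true binary label field.
#' Reports accuracy, sensitivity (foreground recall), specificity
#' (background recall), per-class IoU, and their two-class mean
#' (MIoU).  `pr_ratio` is the correct-calls over all-calls ratio
#' `T / (T + F)` with `T = tp + tn` and `F = fp + fn`; under this
#' reading it is identical to accuracy and is reported alongside it.
#' Metrics with an empty denominator are returned as `NA` (a defined
#' sentinel, not a propagated `NaN`).
#'
#' @param pred,truth binary label matrices of identical shape.
#' @return List of class `metric_report`: counts `tp`, `fp`, `tn`,
#'   `fn` and metrics `accuracy`, `sensitivity`, `specificity`,
#'   `pr_ratio`, `iou_bg`, `iou_fg`, `miou`.
#' @export
confusion_metrics <- function(pred, truth) {
  validate_label_field(pred)
  validate_label_field(truth)
  if (!identical(dim(pred), dim(truth)))
    stop("`pred` and `truth` shapes differ")
  tp <- sum(pred == 1L & truth == 1L)
  fp <- sum(pred == 1L & truth == 0L)
  tn <- sum(pred == 0L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  n <- tp + fp + tn + fn
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  iou_bg <- safe_div(tn, tn + fn + fp)
  iou_fg <- safe_div(tp, tp + fp + fn)
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = safe_div(tp + tn, n),
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    pr_ratio = safe_div(tp + tn, n),
    iou_bg = iou_bg, iou_fg = iou_fg,
    miou = mean(c(iou_bg, iou_fg))
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<metric_report> accuracy %.4f  sensitivity %.4f  specificity %.4f\n",
    "                iou_bg %.4f  iou_fg %.4f  miou %.4f\n"),
    x$accuracy, x$sensitivity, x$specificity, x$iou_bg, x$iou_fg, x$miou))
  invisible(x)
}

#' Write a metric report as JSON and CSV
#'
#' @param report a [confusion_metrics()] result (extra list entries
#'   are carried through to the JSON).
#' @param json_path,csv_path output paths; either may be `NULL`.
#' @return Invisibly, the report.
#' @export
write_metric_report <- function(report, json_path = NULL, csv_path = NULL) {
  fields <- c("tp", "fp", "tn", "fn", "accuracy", "sensitivity",
              "specificity", "pr_ratio", "iou_bg", "iou_fg", "miou")
  if (!is.null(json_path))
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  if (!is.null(csv_path)) {
    df <- data.frame(metric = fields,
                     value = vapply(fields, function(f)
                       as.numeric(report[[f]]), numeric(1)))
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  invisible(report)
}

#' Gray-level k-means baseline (k = 2)
#'
#' Lloyd's algorithm on the weighted gray histogram: centroids start
#' at the 25th and 75th percentile gray levels, levels are assigned to
#' the nearest centroid, and centroids are updated as count-weighted
#' means until the assignment reaches a fixed point.  The cluster with
#' the higher mean becomes the feature class.  The procedure is
#' deterministic; `seed` is accepted for interface symmetry with the
#' rest of the package.
#'
#' @param img a [gray_image()] with at least two distinct gray levels.
#' @param seed unused (deterministic initialization); kept so callers
#'   can treat all segmenters uniformly.
#' @return Binary label matrix (1 = feature).
#' @export
kmeans_gray <- function(img, seed = 0L) {
  stopifnot(is_gray_image(img))
  hist <- compute_histogram(img)
  levels_present <- which(hist$counts > 0L) - 1L
  if (length(levels_present) < 2L)
    stop("constant image: k-means needs at least 2 distinct gray levels")
  cent <- as.numeric(stats::quantile(as.vector(img$pixels), c(0.25, 0.75)))
  if (cent[1L] == cent[2L])
    cent <- range(levels_present)
  t <- 0:hist$max_level
  h <- hist$counts
  assign_old <- rep(0L, length(t))
  for (iter in seq_len(100L)) {
    # nearest centroid; ties go to the lower one
    assign_new <- ifelse(abs(t - cent[1L]) <= abs(t - cent[2L]), 1L, 2L)
    if (identical(assign_new, assign_old)) break
    assign_old <- assign_new
    for (k in 1:2) {
      sel <- assign_new == k & h > 0L
      if (any(sel)) cent[k] <- sum(t[sel] * h[sel]) / sum(h[sel])
    }
  }
  feature_cluster <- which.max(cent)
  lut <- as.integer(assign_old == feature_cluster)
  matrix(lut[img$pixels + 1L], img$height, img$width)
}

#' Full segmentation pipeline
#'
#' Chains the four stages on one image: gray-histogram mixture fit
#' ([fit_em()]), likelihood energies, multiscale line-similarity
#' feature map ([multiscale_response()]), MRF/ICM labeling
#' ([icm_segment()]), and boundary refinement
#' ([refine_segmentation()]).
#'
#' @param img a [gray_image()].
#' @param cfg a `run_config` (see [default_run_config()]).
#' @return List of class `segmentation_result`: `labels` (refined
#'   binary matrix), `labels_icm` (pre-refinement), `params` (fitted
#'   mixture), `fmap`, `energy_trace`, `iterations`, `config`.
#' @export
segment_image <- function(img, cfg = default_run_config()) {
  stopifnot(is_gray_image(img))
  validate_run_config(cfg)
  hist <- compute_histogram(img)
  params <- fit_em(hist,
                   spec = mixture_spec(
                     n_rayleigh = 1L,
                     n_background_gauss = cfg$mixture$n_background_gauss,
                     n_target = 1L),
                   tol = cfg$mixture$tol,
                   max_iter = cfg$mixture$max_iter,
                   seed = cfg$seed)
  fmap <- multiscale_response(img, scales = cfg$scales,
                              beta_r = cfg$response$beta_r,
                              c_r = cfg$response$c_r,
                              polarity = cfg$polarity)
  icm <- icm_segment(img, params, fmap,
                     beta = cfg$energy$beta, alpha = cfg$energy$alpha,
                     max_iter = cfg$icm$max_iter)
  refined <- refine_segmentation(icm$labels, r = cfg$refine$r)
  structure(list(labels = refined,
                 labels_icm = icm$labels,
                 params = params,
                 fmap = fmap,
                 energy_trace = icm$energy_trace,
                 iterations = icm$iterations,
                 config = cfg),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %dx%d, %d feature pixels, %d ICM sweep(s)\n",
              nrow(x$labels), ncol(x$labels), sum(x$labels), x$iterations))
  invisible(x)
}

#' Noise-robustness experiment
#'
#' For each noise variance, generates `n_seeds` phantoms (seeds
#' `cfg$seed + 1 .. cfg$seed + n_seeds`), runs the full pipeline, and
#' records the segmentation error `1 - accuracy`.
#'
#' @param cfg a [phantom_config()]; its `noise_variance` is
#'   overridden per row.
#' @param variances non-empty numeric vector of noise variances.
#' @param n_seeds phantoms per variance, `>= 1`.
#' @param run_cfg pipeline configuration.
#' @return List of class `robustness_table`: `summary` (one row per
#'   variance: `variance`, `mean_error`, `sd_error`) and `runs` (one
#'   row per variance/seed with full provenance).
#' @export
noise_robustness <- function(cfg, variances, n_seeds = 10L,
                             run_cfg = default_run_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  if (length(variances) < 1L) stop("`variances` must be non-empty")
  if (n_seeds < 1L) stop("`n_seeds` must be >= 1")
  runs <- do.call(rbind, lapply(variances, function(v) {
    do.call(rbind, lapply(seq_len(n_seeds), function(k) {
      ck <- cfg
      ck$noise_variance <- v
      ck$seed <- cfg$seed + k
      ph <- generate_phantom(ck)
      seg <- segment_image(ph$image, run_cfg)
      m <- confusion_metrics(seg$labels, ph$truth)
      data.frame(variance = v, seed = ck$seed,
                 accuracy = m$accuracy, error = 1 - m$accuracy)
    }))
  }))
  summary <- do.call(rbind, lapply(split(runs, runs$variance), function(d)
    data.frame(variance = d$variance[1L],
               mean_error = mean(d$error),
               sd_error = stats::sd(d$error))))
  summary <- summary[order(summary$variance), ]
  rownames(summary) <- NULL
  structure(list(summary = summary, runs = runs),
            class = "robustness_table")
}

#' @export
print.robustness_table <- function(x, ...) {
  cat("<robustness_table>\n")
  print(x$summary)
  invisible(x)
}

#' Write a robustness table as CSV
#'
#' Writes the per-variance summary to `summary_path` and, optionally,
#' the per-(variance, seed) runs to `runs_path`.
#'
#' @param tab a [noise_robustness()] result.
#' @param summary_path,runs_path output CSV paths; `runs_path` may be
#'   `NULL`.
#' @return Invisibly, `tab`.
#' @export
write_robustness_table <- function(tab, summary_path, runs_path = NULL) {
  stopifnot(inherits(tab, "robustness_table"))
  utils::write.csv(tab$summary, summary_path, row.names = FALSE)
  if (!is.null(runs_path))
    utils::write.csv(tab$runs, runs_path, row.names = FALSE)
  invisible(tab)
}
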