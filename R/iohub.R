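#' curvseg: segmentation of bright curvilinear structures
#'
#' Statistical segmentation of bright curvilinear structures in 2-D
#' grayscale images.  The main entry point is [segment_image()], which
#' chains histogram mixture fitting ([fit_em()]), multiscale Hessian
#' line-similarity filtering ([multiscale_response()]), MRF/ICM label
#' estimation ([icm_segment()]) and boundary refinement
#' ([refine_segmentation()]).  Synthetic phantoms with ground truth are
#' produced by [generate_phantom()]; [confusion_metrics()],
#' [kmeans_gray()] and [noise_robustness()] evaluate the result.
#'
#' Conventions used throughout: pixel coordinates are (row, col) with
#' row 1 at the top; the x axis of the Hessian runs along columns and
#' the y axis along rows; gray levels are integers in `[0, max_level]`
#' and are divided by `max_level` before any feature or noise
#' computation, so noise variances are on the normalized `[0, 1]`
#' scale regardless of bit depth.
#'
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# GrayImage

#' Construct a grayscale image
#'
#' A `gray_image` is an integer pixel matrix plus its declared bit
#' depth.  Values must lie in `[0, max_level]` with
#' `max_level = 2^bit_depth - 1`; images smaller than 3x3 are rejected
#' because the Hessian filters need a neighborhood.
#'
#' @param pixels numeric matrix of integer gray levels (rows = image
#'   rows, row 1 at the top).
#' @param bit_depth 8 or 16.
#' @return An object of class `gray_image` with fields `pixels`
#'   (integer matrix), `height`, `width`, `bit_depth`, `max_level`.
#' @export
gray_image <- function(pixels, bit_depth = 8L) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  if (nrow(pixels) < 3L || ncol(pixels) < 3L)
    stop("image must be at least 3x3 (got ", nrow(pixels), "x", ncol(pixels), ")")
  max_level <- as.integer(2L^bit_depth - 1L)
  if (any(!is.finite(pixels))) stop("pixel values must be finite")
  if (any(pixels != round(pixels)))
    stop("pixel values must be integer gray levels")
  if (any(pixels < 0L) || any(pixels > max_level))
    stop("pixel values must lie in [0, ", max_level, "]")
  px <- pixels
  storage.mode(px) <- "integer"
  structure(
    list(pixels = px, height = nrow(px), width = ncol(px),
         bit_depth = bit_depth, max_level = max_level),
    class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %dx%d, %d-bit, gray range [%d, %d]\n",
              x$height, x$width, x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

is_gray_image <- function(x) inherits(x, "gray_image")

#' Normalize a grayscale image to [0, 1]
#'
#' Divides integer gray levels by `max_level`.  Feature extraction and
#' the noise-variance convention operate on this scale.
#'
#' @param img a [gray_image()].
#' @return Numeric matrix with values in `[0, 1]`.
#' @export
normalize_image <- function(img) {
  stopifnot(is_gray_image(img))
  img$pixels / img$max_level
}

# Accept either a gray_image (normalized first) or a bare numeric matrix.
as_intensity_matrix <- function(img) {
  if (is_gray_image(img)) normalize_image(img)
  else if (is.matrix(img) && is.numeric(img)) img
  else stop("expected a gray_image or a numeric matrix")
}

# ---------------------------------------------------------------------------
# Image file I/O

png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 26L)
  if (length(hdr) < 25L) stop("unreadable or truncated PNG file: ", path)
  as.integer(hdr[25L])
}

image_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") "png"
  else if (ext %in% c("tif", "tiff")) "tiff"
  else stop("unsupported image format '", ext, "' (PNG and TIFF only)")
}

#' Read a single-channel PNG or TIFF image
#'
#' Reads an 8- or 16-bit grayscale raster losslessly.  Multi-channel
#' input is rejected unless `to_gray = TRUE`, in which case RGB(A)
#' data is converted by ITU-R BT.601 luminance
#' (0.299 R + 0.587 G + 0.114 B) and rounded.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @param to_gray convert multi-channel input to luminance instead of
#'   erroring.  Default `FALSE`: silent conversion hides data errors.
#' @return A [gray_image()] whose bit depth matches the file.
#' @export
read_gray_image <- function(path, to_gray = FALSE) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  fmt <- image_format(path)
  if (fmt == "png") {
    arr <- png::readPNG(path)
    depth <- png_bit_depth(path)
    if (!depth %in% c(8L, 16L))
      stop("unsupported PNG bit depth: ", depth)
  } else {
    arr <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    depth <- attr(arr, "bits.per.sample")
    if (is.null(depth)) depth <- 8L
    depth <- as.integer(depth[1L])
    if (!depth %in% c(8L, 16L))
      stop("unsupported TIFF bit depth: ", depth)
    # as.is = TRUE yields integer sample values already; drop the
    # TIFF metadata attributes that info = TRUE attaches
    arr <- array(as.numeric(arr), dim = dim(arr)) / (2^depth - 1)
  }
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3L]
    if (!to_gray)
      stop("image has ", nch, " channels; expected single-channel ",
           "(set to_gray = TRUE for BT.601 luminance conversion)")
    arr <- if (nch >= 3L) {
      0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L]
    } else {
      arr[, , 1L]  # gray + alpha: keep the gray channel
    }
  }
  max_level <- 2^depth - 1
  gray_image(round(arr * max_level), bit_depth = depth)
}

#' Write a grayscale image to PNG or TIFF
#'
#' 8-bit images may be written to PNG or TIFF; 16-bit images to TIFF
#' only (the PNG writer in use emits 8 bits per sample).
#'
#' @param img a [gray_image()].
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path) {
  stopifnot(is_gray_image(img))
  fmt <- image_format(path)
  scaled <- img$pixels / img$max_level
  if (fmt == "png") {
    if (img$bit_depth != 8L)
      stop("16-bit output requires TIFF; PNG output is 8-bit only")
    png::writePNG(scaled, target = path)
  } else {
    tiff::writeTIFF(scaled, where = path, bits.per.sample = img$bit_depth)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Histogram

#' Gray-level histogram of an image
#'
#' Counts pixels at every gray level `t` in `[0, max_level]`.  All
#' mixture computations run on this histogram rather than on pixels,
#' which makes EM cost proportional to the number of gray levels.
#'
#' @param img a [gray_image()].
#' @return An object of class `gray_histogram`: list with `counts`
#'   (length `max_level + 1`, index `t + 1` holds the count of level
#'   `t`), `n_pixels`, and `max_level`.
#' @export
compute_histogram <- function(img) {
  stopifnot(is_gray_image(img))
  counts <- tabulate(as.vector(img$pixels) + 1L, nbins = img$max_level + 1L)
  structure(
    list(counts = counts, n_pixels = img$height * img$width,
         max_level = img$max_level),
    class = "gray_histogram")
}

#' @export
print.gray_histogram <- function(x, ...) {
  nz <- which(x$counts > 0L) - 1L
  cat(sprintf("<gray_histogram> %d pixels over [0, %d], %d occupied levels (range %d..%d)\n",
              x$n_pixels, x$max_level, length(nz),
              if (length(nz)) min(nz) else NA_integer_,
              if (length(nz)) max(nz) else NA_integer_))
  invisible(x)
}

is_gray_histogram <- function(x) inherits(x, "gray_histogram")

# ---------------------------------------------------------------------------
# Run configuration

#' Default pipeline configuration
#'
#' Returns the full set of tunable knobs with their defaults.  See the
#' package vignette for the rationale behind each value.
#'
#' * `mixture`: 1 Rayleigh + `n_background_gauss` background Gaussians
#'   + 1 target Gaussian; EM stops when the parameter-vector RMSE
#'   drops below `tol` or after `max_iter` iterations.
#' * `scales`: Gaussian-derivative scales (pixels) for the Hessian
#'   filter, strictly increasing.
#' * `response`: vesselness shape parameters; `c_r = NULL` selects the
#'   per-scale adaptive value (half the maximum Hessian Frobenius norm).
#' * `energy`: `beta` weights the Potts prior, `alpha` the feature term.
#' * `icm$max_iter`: cap on ICM sweeps.
#' * `refine$r`: boundary-offset scaling factor.
#' * `polarity`: `"bright"` for bright structures on dark background.
#'
#' @return Nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 0L,
    polarity = "bright",
    mixture = list(n_background_gauss = 2L, tol = 1e-6, max_iter = 500L),
    scales = c(1, 2, 3, 4, 6, 8),
    response = list(beta_r = 0.5, c_r = NULL),
    energy = list(beta = 1.5, alpha = 1.0),
    icm = list(max_iter = 100L),
    refine = list(r = 1.0)
  ), class = "run_config")
}

#' Validate a pipeline configuration
#'
#' @param cfg a configuration list as from [default_run_config()].
#' @return `cfg`, invisibly, or an error describing the violation.
#' @export
validate_run_config <- function(cfg) {
  stopifnot(is.list(cfg))
  sc <- cfg$scales
  if (length(sc) < 1L || any(sc <= 0) || is.unsorted(sc, strictly = TRUE))
    stop("`scales` must be a non-empty, strictly increasing, positive vector")
  if (cfg$energy$beta < 0) stop("`beta` must be >= 0")
  if (cfg$energy$alpha < 0) stop("`alpha` must be >= 0")
  if (cfg$refine$r < 0) stop("refinement factor `r` must be >= 0")
  if (cfg$seed < 0 || cfg$seed != round(cfg$seed))
    stop("`seed` must be a non-negative integer")
  if (!cfg$polarity %in% c("bright", "dark"))
    stop("`polarity` must be 'bright' or 'dark'")
  if (cfg$mixture$n_background_gauss < 1L)
    stop("at least one background Gaussian is required")
  if (cfg$icm$max_iter < 1L) stop("`icm$max_iter` must be >= 1")
  invisible(cfg)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a YAML pipeline configuration
#'
#' Keys absent from the file fall back to [default_run_config()]; the
#' merged configuration is validated before being returned.
#'
#' @param path YAML file; may set any subset of the default keys.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  user <- yaml::read_yaml(path)
  cfg <- merge_config(default_run_config(), user)
  cfg$seed <- as.integer(cfg$seed)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

# ---------------------------------------------------------------------------
# Seeded RNG scope

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded generators never perturb the global
#' random stream.
#'
#' @param seed non-negative integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}
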