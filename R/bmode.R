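#' B-mode image container
#'
#' A `bmode_image` stores a 2-D grid of echo intensities in `[0, 1]`
#' (row index increases downward, as displayed on the scanner) together with
#' the physical, isotropic pixel size in millimetres. All scale parameters of
#' the detector are expressed in mm and converted to pixels through this
#' field, so the pipeline is invariant to the acquisition resolution.
#'
#' @param intensities Numeric matrix with values in `[0, 1]`, at least 2 x 2.
#' @param pixel_size_mm Positive isotropic pixel size in mm.
#'
#' @return An object of class `bmode_image`.
#' @export
bmode_image <- function(intensities, pixel_size_mm) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("`intensities` must be a numeric matrix", call. = FALSE)
  if (nrow(intensities) < 2L || ncol(intensities) < 2L)
    stop("image must be at least 2 x 2", call. = FALSE)
  if (!all(is.finite(intensities)))
    stop("intensities must all be finite", call. = FALSE)
  if (min(intensities) < 0 || max(intensities) > 1)
    stop("intensities must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(pixel_size_mm) || length(pixel_size_mm) != 1L ||
      !is.finite(pixel_size_mm) || pixel_size_mm <= 0)
    stop("`pixel_size_mm` must be a single positive number", call. = FALSE)
  structure(
    list(intensities = intensities, pixel_size_mm = as.numeric(pixel_size_mm)),
    class = "bmode_image"
  )
}

#' @export
print.bmode_image <- function(x, ...) {
  cat(sprintf("<bmode_image> %d x %d px, %.4g mm/px (%.1f x %.1f mm)\n",
              nrow(x$intensities), ncol(x$intensities), x$pixel_size_mm,
              nrow(x$intensities) * x$pixel_size_mm,
              ncol(x$intensities) * x$pixel_size_mm))
  invisible(x)
}

#' @export
dim.bmode_image <- function(x) dim(x$intensities)

# mm -> px conversion for an image.
mm_to_px <- function(mm, img) mm / img$pixel_size_mm

#' Load a grayscale B-mode image from a PNG or TIFF file
#'
#' Intensities are rescaled linearly from the native bit depth to `[0, 1]`
#' (the PNG/TIFF readers already divide by the bit-depth maximum, e.g.
#' 32768 in a 16-bit file maps to 32768/65535). Multi-channel rasters are
#' collapsed to grayscale by the channel mean, since scanner exports are
#' often RGB-encoded grayscale.
#'
#' @param path Path to a single-frame PNG or TIFF file.
#' @param pixel_size_mm Isotropic pixel size of the raster, in mm.
#'
#' @return A [bmode_image].
#' @export
load_bmode <- function(path, pixel_size_mm) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path, all = FALSE),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)",
         call. = FALSE)
  )
  if (is.list(raw)) stop("multi-frame images are not supported", call. = FALSE)
  if (length(dim(raw)) == 3L) {
    # drop a constant alpha channel, then average the color channels
    if (dim(raw)[3L] %in% c(2L, 4L)) raw <- raw[, , -dim(raw)[3L], drop = FALSE]
    raw <- apply(raw, c(1L, 2L), mean)
  }
  bmode_image(pmin(pmax(raw, 0), 1), pixel_size_mm)
}

#' Write a B-mode image to a PNG or TIFF file
#'
#' @param img A [bmode_image].
#' @param path Output path; the container is chosen from the extension.
#' @param bits Bits per sample (8 or 16). TIFF supports both, PNG both.
#'
#' @return `path`, invisibly.
#' @export
write_bmode <- function(img, path, bits = 8L) {
  stopifnot(inherits(img, "bmode_image"), bits %in% c(8L, 16L))
  ext <- tolower(tools::file_ext(path))
  m <- img$intensities
  if (ext == "png") {
    png::writePNG(m, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m, path, bits.per.sample = as.integer(bits))
  } else stop("unsupported image format: .", ext, call. = FALSE)
  invisible(path)
}

#' Resample a B-mode image to a target pixel size
#'
#' Bilinear interpolation on pixel centers; output dimensions are
#' `round(dim * pixel_size_mm / target_pixel_mm)`. The detector's scale
#' parameters are given in mm, so analyses run at 0.09 mm/px by convention,
#' matching the usual resolution of longitudinal carotid acquisitions.
#'
#' @param img A [bmode_image].
#' @param target_pixel_mm Target pixel size in mm (default 0.09).
#'
#' @return A resampled [bmode_image] with `pixel_size_mm = target_pixel_mm`.
#' @export
resample_bmode <- function(img, target_pixel_mm = 0.09) {
  stopifnot(inherits(img, "bmode_image"))
  if (!is.numeric(target_pixel_mm) || target_pixel_mm <= 0)
    stop("`target_pixel_mm` must be positive", call. = FALSE)
  scale <- img$pixel_size_mm / target_pixel_mm
  if (abs(scale - 1) < 1e-12) return(img)
  m <- img$intensities
  nr <- as.integer(round(nrow(m) * scale))
  nc <- as.integer(round(ncol(m) * scale))
  if (nr < 2L || nc < 2L)
    stop("resampled image would be smaller than 2 x 2", call. = FALSE)
  out <- bilinear_resize(m, nr, nc)
  bmode_image(pmin(pmax(out, 0), 1), target_pixel_mm)
}

# Bilinear resize with pixel-center alignment (sample i of n maps to
# position (i - 0.5) * n_in / n_out + 0.5 in input coordinates).
bilinear_resize <- function(m, nr, nc) {
  src <- function(n_out, n_in) {
    p <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
    pmin(pmax(p, 1), n_in)
  }
  ry <- src(nr, nrow(m)); rx <- src(nc, ncol(m))
  y0 <- pmin(floor(ry), nrow(m) - 1L); x0 <- pmin(floor(rx), ncol(m) - 1L)
  wy <- ry - y0; wx <- rx - x0
  a <- m[y0, x0, drop = FALSE]; b <- m[y0 + 1L, x0, drop = FALSE]
  c_ <- m[y0, x0 + 1L, drop = FALSE]; d <- m[y0 + 1L, x0 + 1L, drop = FALSE]
  WY <- matrix(wy, nr, nc); WX <- matrix(wx, nr, nc, byrow = TRUE)
  a * (1 - WY) * (1 - WX) + b * WY * (1 - WX) +
    c_ * (1 - WY) * WX + d * WY * WX
}

#' Noise specification for robustness studies
#'
#' Two artificial noise models are supported. With `n ~ N(0, sigma^2)` i.i.d.
#' per pixel, the speckle model is `I_S = I + I^gamma * n` (multiplicative,
#' `gamma = 1/2` matching log-compressed ultrasound speckle, so the noise
#' vanishes where the image is black), and the Gaussian model is
#' `I_G = I + n` (additive, emulating lumen artifacts and non-uniform
#' backgrounds).
#'
#' The noise standard deviation is derived from the requested SNR: with
#' signal power `P = mean(I^2)`, `sigma^2 = P * 10^(-snr_db/10)` for the
#' Gaussian model, and `sigma^2 = P * 10^(-snr_db/10) / mean(I^(2*gamma))`
#' for the speckle model, so that the expected noise power matches the
#' target in both models. SNR is defined before clipping to `[0, 1]`.
#'
#' @param model `"gaussian"` or `"speckle"`.
#' @param snr_db Target signal-to-noise ratio in dB (any real value).
#' @param gamma Speckle exponent (default 1/2).
#' @param seed Integer seed; the same spec applied to the same image gives a
#'   byte-identical result.
#'
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(model = c("speckle", "gaussian"), snr_db,
                       gamma = 0.5, seed = 1L) {
  model <- match.arg(model)
  if (!is.numeric(snr_db) || length(snr_db) != 1L || is.na(snr_db))
    stop("`snr_db` must be a single number", call. = FALSE)
  if (!is.numeric(gamma) || gamma <= 0)
    stop("`gamma` must be positive", call. = FALSE)
  structure(list(model = model, snr_db = as.numeric(snr_db),
                 gamma = as.numeric(gamma), seed = as.integer(seed)),
            class = "noise_spec")
}

# Run expr with a local RNG stream; the caller's RNG state is untouched.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Add artificial noise to a B-mode image
#'
#' @param img A [bmode_image].
#' @param spec A [noise_spec].
#'
#' @return A [bmode_image] with noise added and intensities clipped to
#'   `[0, 1]`. An infinite `snr_db` returns the image unchanged.
#' @export
add_noise <- function(img, spec) {
  stopifnot(inherits(img, "bmode_image"), inherits(spec, "noise_spec"))
  I <- img$intensities
  if (is.infinite(spec$snr_db) && spec$snr_db > 0) return(img)
  P <- mean(I^2)
  if (P == 0 && spec$model == "gaussian") P <- .Machine$double.eps
  n <- with_local_seed(spec$seed, stats::rnorm(length(I)))
  dim(n) <- dim(I)
  if (spec$model == "gaussian") {
    sigma <- sqrt(P * 10^(-spec$snr_db / 10))
    out <- I + sigma * n
  } else {
    amp <- I^spec$gamma
    m2 <- mean(amp^2)
    if (m2 == 0) return(img)  # all-black image: speckle has no effect
    sigma <- sqrt(P * 10^(-spec$snr_db / 10) / m2)
    out <- I + amp * (sigma * n)
  }
  bmode_image(pmin(pmax(out, 0), 1), img$pixel_size_mm)
}
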