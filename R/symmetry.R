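#' Configuration of the phase-symmetry map
#'
#' The symmetry map responds to dark, roughly horizontal tubular structures
#' whose width lies in the expected range of CCA diameters
#' `[d_min_mm, d_max_mm]`. These two diameters set the soft half-amplitude
#' cut-offs of the band-pass filter used before the monogenic (Riesz)
#' decomposition.
#'
#' @param d_min_mm,d_max_mm Diameter range in mm (`0 < d_min < d_max`).
#'   Defaults come from [estimate_diameter_bounds()].
#' @param epsilon Stabilizer of the phase-symmetry ratio. `NULL` (default)
#'   sets it per image to `1e-3` times the 99th percentile of the local
#'   amplitude, which keeps the measure invariant to affine intensity
#'   rescaling.
#' @param noise_floor Amplitude threshold `T` subtracted from the symmetry
#'   numerator (default 0).
#'
#' @return An object of class `symmetry_config`.
#' @export
symmetry_config <- function(d_min_mm = NULL, d_max_mm = NULL,
                            epsilon = NULL, noise_floor = 0) {
  if (is.null(d_min_mm) || is.null(d_max_mm)) {
    b <- estimate_diameter_bounds()
    d_min_mm <- d_min_mm %||% b$d_min_mm
    d_max_mm <- d_max_mm %||% b$d_max_mm
  }
  stopifnot(is.numeric(d_min_mm), is.numeric(d_max_mm),
            d_min_mm > 0, d_max_mm > d_min_mm, noise_floor >= 0)
  if (!is.null(epsilon)) stopifnot(epsilon > 0)
  structure(list(d_min_mm = d_min_mm, d_max_mm = d_max_mm,
                 epsilon = epsilon, noise_floor = noise_floor),
            class = "symmetry_config")
}

#' @rdname symmetry_config
#' @param params A `parameter_set`, whose diameter range is reused.
#' @export
symmetry_config_from <- function(params) {
  stopifnot(inherits(params, "parameter_set"))
  symmetry_config(params$d_min_mm, params$d_max_mm)
}

# Internal: band-pass + Riesz analysis of an image (optionally also the two
# Gaussian blurs of the contrast stage, sharing the single forward FFT).
# Returns list(even, odd1, odd2[, g_on, g_off]) cropped to the image window.
sym_analysis <- function(img, cfg, sigma_on_px = NULL, sigma_off_px = NULL) {
  m <- img$intensities
  d_min_px <- cfg$d_min_mm / img$pixel_size_mm
  d_max_px <- cfg$d_max_mm / img$pixel_size_mm
  if (d_min_px < 2)
    stop("d_min is below 2 px at this pixel size; the band-pass filter ",
         "degenerates at the Nyquist frequency", call. = FALSE)
  pf <- padded_fft(m, ceiling(d_max_px))
  tr <- cached_transfers(pf, d_min_px, d_max_px, sigma_on_px, sigma_off_px)
  p1 <- ifft_crop_packed(pf, tr$X1)         # even + i * odd_horizontal
  if (is.null(sigma_on_px)) {
    odd2 <- ifft_crop(pf, tr$X2v)
    return(list(even = p1$a, odd1 = p1$b, odd2 = odd2))
  }
  p2 <- ifft_crop_packed(pf, tr$X2)         # odd_vertical + i * g_on
  g_off <- ifft_crop(pf, tr$X3)
  list(even = p1$a, odd1 = p1$b, odd2 = p2$a, g_on = p2$b, g_off = g_off)
}

#' Band-pass filter an image to the CCA diameter scale range
#'
#' Isotropic difference-of-Gaussians frequency response
#' `B(f) = exp(-f^2 / (2 s_hi^2)) - exp(-f^2 / (2 s_lo^2))` with
#' half-amplitude cut-offs at spatial frequencies `1/d_max` and `1/d_min`
#' (per mm), applied through the 2-D FFT of a mirror-padded copy of the
#' image. The DC coefficient is forced to zero, so the output is zero-mean
#' up to cropping effects.
#'
#' @param img A [bmode_image].
#' @param cfg A [symmetry_config].
#'
#' @return A numeric matrix (the even, band-passed component).
#' @export
bandpass <- function(img, cfg = symmetry_config()) {
  stopifnot(inherits(img, "bmode_image"), inherits(cfg, "symmetry_config"))
  sym_analysis(img, cfg)$even
}

#' Monogenic (Riesz) odd components of an even band-passed image
#'
#' Applies the Riesz transform in the frequency domain, with transfer
#' functions proportional to `u/||w||` and `v/||w||` (zero at DC), oriented
#' so that a vertical cosine ridge maps to its vertical Hilbert transform.
#' The Euclidean norm of the two outputs is the local odd energy; together
#' with the even input it gives local amplitude and phase.
#'
#' @param even Real matrix, typically the output of [bandpass()]
#'   (zero-mean).
#'
#' @return A list with matrices `odd1` (horizontal) and `odd2` (vertical).
#' @export
monogenic <- function(even) {
  stopifnot(is.matrix(even), is.numeric(even))
  F <- stats::fft(even)
  H <- riesz_transfer(fft_freq(nrow(even)), fft_freq(ncol(even)))
  n <- length(even)
  list(odd1 = Re(stats::fft(F * H$H1, inverse = TRUE)) / n,
       odd2 = Re(stats::fft(F * H$H2, inverse = TRUE)) / n)
}

# Internal: symmetry values from the analysis components.
sym_from_parts <- function(even, odd1, odd2, cfg) {
  o <- sqrt(odd1^2 + odd2^2)
  A <- sqrt(even^2 + o^2)
  eps <- cfg$epsilon %||% (1e-3 * stats::quantile(A, 0.99, names = FALSE))
  if (eps <= 0) eps <- .Machine$double.eps
  pmin(pmax(-even - o - cfg$noise_floor, 0) / (A + eps), 1)
}

#' Dark-structure phase-symmetry map
#'
#' Contrast-invariant symmetry measure for dark bands surrounded by brighter
#' tissue. With `e` the band-passed even part, `o` the norm of the Riesz
#' odd pair and `A = sqrt(e^2 + o^2)` the local amplitude,
#' `Sym = max(0, -e - o - T) / (A + eps)`. At the center of a dark band the
#' local phase is an even trough (`e < 0`, `o ~ 0`) and Sym approaches 1;
#' at edges (`o` dominant) and on bright ridges (`e > 0`) it is ~0. Since
#' only the phase enters, the measure is independent of local contrast and
#' brightness.
#'
#' @inheritParams bandpass
#'
#' @return A `symmetry_map`: a numeric matrix in `[0, 1]` with the same
#'   shape as the image.
#' @export
symmetry_map <- function(img, cfg = symmetry_config()) {
  stopifnot(inherits(img, "bmode_image"), inherits(cfg, "symmetry_config"))
  a <- sym_analysis(img, cfg)
  s <- sym_from_parts(a$even, a$odd1, a$odd2, cfg)
  structure(s, class = c("symmetry_map", class(s)))
}

#' Export a symmetry map as a raster file (debug aid)
#'
#' Values are quantized over `[0, 1]`: 16 bits per sample for TIFF output,
#' 8 for PNG.
#'
#' @param sym A [symmetry_map()] result.
#' @param path Output path (`.png` or `.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_symmetry_map <- function(sym, path) {
  m <- pmin(pmax(unclass(sym), 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(m, target = path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(m, path, bits.per.sample = 16L)
  else stop("unsupported export format: .", ext, call. = FALSE)
  invisible(path)
}
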