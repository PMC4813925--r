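#' Population statistics of the CCA internal diameter
#'
#' Mean and standard deviation (in mm) of the common carotid artery internal
#' diameter in a reference population, as reported by population studies.
#' Used to derive the scale parameters of the detector from domain knowledge
#' rather than per-dataset tuning.
#'
#' @param mean_mm,sd_mm Mean and standard deviation in mm (`sd_mm > 0`).
#' @param label Free-text description of the population.
#'
#' @return An object of class `population_stats`.
#' @export
population_stats <- function(mean_mm, sd_mm, label = "") {
  stopifnot(is.numeric(mean_mm), is.numeric(sd_mm), sd_mm > 0)
  structure(list(mean_mm = mean_mm, sd_mm = sd_mm, label = label),
            class = "population_stats")
}

#' Estimate the CCA diameter search range from population statistics
#'
#' The minimum diameter `d_min` is the lower bound of the one-sided 99%
#' normal population interval for the narrowest reference group (left CCA in
#' women), `d_min = mean - z * sd` with `z = qnorm(0.99) ~ 2.3263`. The
#' maximum internal diameter comes from the widest group (men),
#' `mean + z * sd`, and is enlarged by both artery walls: twice the
#' intima-media thickness at the plaque threshold (1.5 mm, the consensus
#' cut-off above which a thickening counts as plaque) plus twice an
#' adventitia allowance of 2 mm.
#'
#' These are population prediction bounds (the SD is not divided by
#' `sqrt(n)`): the range must cover individual arteries, not the mean. With
#' the default population values this gives
#' `d_min ~ 4.03 mm`, an internal maximum of `~ 8.80 mm` and
#' `d_max ~ 15.80 mm`.
#'
#' @param women_left [population_stats] of the narrow reference group
#'   (default: left CCA in women, 6.05 +/- 0.87 mm).
#' @param men [population_stats] of the wide reference group
#'   (default: CCA in men, 6.52 +/- 0.98 mm).
#' @param imt_plaque_mm Upper bound of the plaque-free intima-media complex
#'   (default 1.5 mm).
#' @param adventitia_mm Extra echogenic adventitia width per wall
#'   (default 2 mm).
#' @param conf One-sided normal coverage (default 0.99).
#'
#' @return A list with `d_min_mm`, `internal_max_mm` and `d_max_mm`.
#' @export
estimate_diameter_bounds <- function(
    women_left = population_stats(6.05, 0.87, "left CCA, women"),
    men = population_stats(6.52, 0.98, "CCA, men"),
    imt_plaque_mm = 1.5, adventitia_mm = 2.0, conf = 0.99) {
  stopifnot(inherits(women_left, "population_stats"),
            inherits(men, "population_stats"))
  z <- stats::qnorm(conf)
  d_min <- women_left$mean_mm - z * women_left$sd_mm
  if (d_min <= 0) stop("derived d_min is non-positive", call. = FALSE)
  internal_max <- men$mean_mm + z * men$sd_mm
  d_max <- internal_max + 2 * imt_plaque_mm + 2 * adventitia_mm
  list(d_min_mm = d_min, internal_max_mm = internal_max, d_max_mm = d_max)
}

#' Derive all detector scale parameters from the diameter range
#'
#' Every scale in the pipeline follows from the CCA diameter range
#' `[d_min, d_max]`:
#' \itemize{
#'   \item `sigma_peak = d_min / 4` - Gaussian-derivative scale for peak
#'     detection in the DP gain profile (candidate lumens are at least a
#'     lumen diameter apart).
#'   \item `sigma_on = d_min / 2` - on-center blur radius of the
#'     lumen-to-wall contrast operator (averages only lumen intensities).
#'   \item `sigma_off = (d_max - d_min) / 4` - offset blur radius, half the
#'     width of the wall region between the minimum and maximum diameters.
#'   \item `delta = (d_max + d_min) / 4` - vertical offset from the lumen
#'     centerline to the center of the expected wall region.
#'   \item `rf = d_min / 2` - vertical radius for band-integrated features,
#'     keeping the band inside the lumen.
#' }
#'
#' @param d_min_mm,d_max_mm CCA diameter range in mm (`0 < d_min < d_max`).
#' @param pixel_size_mm Pixel size used for the pixel-unit view
#'   (default 0.09 mm).
#'
#' @return An object of class `parameter_set`: a list with the mm-valued
#'   fields `d_min_mm`, `d_max_mm`, `sigma_peak_mm`, `sigma_on_mm`,
#'   `sigma_off_mm`, `delta_mm`, `rf_mm` and `pixel_size_mm`.
#' @seealso [parameters_px()] for the pixel-unit view, [carotid_parameters()]
#'   for the shipped defaults.
#' @export
derive_parameters <- function(d_min_mm, d_max_mm, pixel_size_mm = 0.09) {
  stopifnot(is.numeric(d_min_mm), is.numeric(d_max_mm),
            d_min_mm > 0, d_max_mm > d_min_mm, pixel_size_mm > 0)
  structure(list(
    d_min_mm = d_min_mm,
    d_max_mm = d_max_mm,
    sigma_peak_mm = d_min_mm / 4,
    sigma_on_mm = d_min_mm / 2,
    sigma_off_mm = (d_max_mm - d_min_mm) / 4,
    delta_mm = (d_max_mm + d_min_mm) / 4,
    rf_mm = d_min_mm / 2,
    pixel_size_mm = pixel_size_mm
  ), class = "parameter_set")
}

#' Default carotid detector parameters
#'
#' [estimate_diameter_bounds()] followed by [derive_parameters()] with the
#' default population statistics.
#'
#' @inheritParams derive_parameters
#' @return A `parameter_set`.
#' @export
carotid_parameters <- function(pixel_size_mm = 0.09) {
  b <- estimate_diameter_bounds()
  derive_parameters(b$d_min_mm, b$d_max_mm, pixel_size_mm)
}

#' Pixel-unit view of a parameter set
#'
#' Converts the mm-valued scales to pixels by dividing by the pixel size.
#' Offsets that index rows (`delta`, `rf`) are rounded to integers; blur and
#' derivative scales stay real-valued.
#'
#' @param params A `parameter_set`.
#' @param pixel_size_mm Optional override of the pixel size.
#'
#' @return A list with `d_min`, `d_max`, `sigma_peak`, `sigma_on`,
#'   `sigma_off` (real px), `delta`, `rf` (integer px).
#' @export
parameters_px <- function(params, pixel_size_mm = NULL) {
  stopifnot(inherits(params, "parameter_set"))
  px <- pixel_size_mm %||% params$pixel_size_mm
  list(
    d_min = params$d_min_mm / px,
    d_max = params$d_max_mm / px,
    sigma_peak = params$sigma_peak_mm / px,
    sigma_on = params$sigma_on_mm / px,
    sigma_off = params$sigma_off_mm / px,
    delta = as.integer(round(params$delta_mm / px)),
    rf = as.integer(round(params$rf_mm / px))
  )
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set> (mm)\n")
  v <- unlist(x[c("d_min_mm", "d_max_mm", "sigma_peak_mm", "sigma_on_mm",
                  "sigma_off_mm", "delta_mm", "rf_mm")])
  print(round(v, 2))
  cat(sprintf("pixel size: %.4g mm\n", x$pixel_size_mm))
  invisible(x)
}

#' Read/write a parameter set as a flat key=value file (mm units)
#'
#' @param params A `parameter_set`.
#' @param path File path.
#' @return `read_parameters()` returns a `parameter_set`; `write_parameters()`
#'   returns `path` invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "parameter_set"))
  keys <- c("d_min_mm", "d_max_mm", "pixel_size_mm")
  writeLines(sprintf("%s=%.10g", keys, unlist(params[keys])), path)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  vals <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                          vapply(kv, `[`, "", 1L))
  derive_parameters(vals[["d_min_mm"]], vals[["d_max_mm"]],
                    vals[["pixel_size_mm"]])
}
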