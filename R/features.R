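#' Difference-of-offset-Gaussian (DooG) lumen-to-wall contrast maps
#'
#' Estimates the intensity difference between a putative lumen centerline
#' position and the expected location of the artery wall a fixed vertical
#' offset away: `C+-(x) = G_off(x +- delta * Dy) - G_on(x)`, with `G_on` and
#' `G_off` Gaussian blurs of the image at scales `sigma_on` (lumen radius)
#' and `sigma_off` (wall-region radius), `Dy` the downward unit vector and
#' `delta` the centerline-to-wall distance. `C+` looks toward the far
#' (deeper) wall, `C-` toward the near wall. The `delta` rows nearest the
#' bottom (`C+`) / top (`C-`) borders reference positions outside the image
#' and are marked `NA` (invalid), matching the candidate discard rule.
#'
#' @param img A [bmode_image].
#' @param params A `parameter_set` (uses `sigma_on_mm`, `sigma_off_mm`,
#'   `delta_mm`).
#'
#' @return An object of class `contrast_maps`: list with matrices `c_plus`
#'   and `c_minus` (invalid margins `NA`) and the integer `delta_px`.
#' @export
contrast_maps <- function(img, params = carotid_parameters()) {
  stopifnot(inherits(img, "bmode_image"), inherits(params, "parameter_set"))
  px <- parameters_px(params, img$pixel_size_mm)
  g <- blur_pair(img, px$sigma_on, px$sigma_off)
  contrast_from_blurs(g$g_on, g$g_off, px$delta)
}

# Internal: the two Gaussian blurs (mirror boundary, shared FFT).
blur_pair <- function(img, sigma_on_px, sigma_off_px) {
  pf <- padded_fft(img$intensities, ceiling(4 * max(sigma_on_px, sigma_off_px)))
  p <- ifft_crop(pf, gaussian_transfer(pf, sigma_on_px),
                 gaussian_transfer(pf, sigma_off_px))
  list(g_on = p$a, g_off = p$b)
}

# Internal: assemble C+/C- from the blurred images and an integer offset.
contrast_from_blurs <- function(g_on, g_off, delta_px) {
  H <- nrow(g_on)
  if (delta_px >= H)
    stop("`delta` offset is not smaller than the image height", call. = FALSE)
  na_row <- rep(NA_real_, ncol(g_on))
  shift_up <- rbind(g_off[-seq_len(delta_px), , drop = FALSE],
                    matrix(na_row, delta_px, ncol(g_on), byrow = TRUE))
  shift_dn <- rbind(matrix(na_row, delta_px, ncol(g_on), byrow = TRUE),
                    g_off[seq_len(H - delta_px), , drop = FALSE])
  structure(list(c_plus = shift_up - g_on,    # wall delta rows below
                 c_minus = shift_dn - g_on,   # wall delta rows above
                 delta_px = as.integer(delta_px)),
            class = "contrast_maps")
}

#' Line-integrated feature of a candidate path
#'
#' Arithmetic mean of a feature map along the path, one sample per column.
#'
#' @param map Numeric matrix (symmetry map, image intensities or a contrast
#'   map).
#' @param rows Integer vector of path rows (one per column), or a
#'   `candidate_path`.
#' @param na_action `"error"` (default) fails when the path touches an
#'   invalid (`NA`) contrast margin - such candidates should have been
#'   discarded; `"omit"` averages the valid samples only.
#'
#' @return A single number.
#' @export
line_feature <- function(map, rows, na_action = c("error", "omit")) {
  na_action <- match.arg(na_action)
  if (inherits(rows, "candidate_path")) rows <- rows$rows
  m <- unclass(map)
  stopifnot(is.matrix(m), length(rows) == ncol(m),
            all(rows >= 1L), all(rows <= nrow(m)))
  v <- m[cbind(rows, seq_along(rows))]
  if (anyNA(v)) {
    if (na_action == "error")
      stop("path touches the invalid contrast margin", call. = FALSE)
    v <- v[!is.na(v)]
    if (!length(v)) stop("no valid samples along the path", call. = FALSE)
  }
  mean(v)
}

#' Band-integrated feature of a candidate path
#'
#' Mean of [line_feature()] over the `2 * rf_px + 1` copies of the path
#' shifted vertically by `-rf_px .. rf_px` rows. Samples whose shifted row
#' leaves the image, or that fall on an invalid contrast margin, are
#' dropped and the denominator renormalized.
#'
#' @inheritParams line_feature
#' @param rf_px Vertical band radius in pixels (>= 0).
#'
#' @return A single number.
#' @export
band_feature <- function(map, rows, rf_px) {
  if (inherits(rows, "candidate_path")) rows <- rows$rows
  m <- unclass(map)
  stopifnot(is.matrix(m), length(rows) == ncol(m), rf_px >= 0)
  H <- nrow(m)
  tot <- 0; cnt <- 0L
  for (r in (-rf_px):rf_px) {
    rr <- rows + r
    ok <- rr >= 1L & rr <= H
    if (!any(ok)) next
    v <- m[cbind(rr[ok], which(ok))]
    v <- v[!is.na(v)]
    tot <- tot + sum(v); cnt <- cnt + length(v)
  }
  if (cnt == 0L) stop("no valid samples in the band", call. = FALSE)
  tot / cnt
}

#' Discard candidates hugging the top or bottom image borders
#'
#' Drops candidates whose every point lies closer than `delta_px` to the
#' top border, or closer than `delta_px` to the bottom border, where the
#' DooG contrast is indeterminate. A candidate with at least one point
#' inside the valid region is kept (the rule requires the path to fall
#' *completely* inside a margin).
#'
#' @param cands A [detect_candidates()] tibble.
#' @param delta_px Margin width in pixels.
#' @param height Image height in pixels.
#'
#' @return The filtered tibble, original order preserved.
#' @export
filter_candidates <- function(cands, delta_px, height) {
  if (!nrow(cands)) return(cands)
  keep <- vapply(cands$rows, function(r) {
    top <- all(r - 1L < delta_px)            # entirely within the top margin
    bot <- all(height - r < delta_px)        # entirely within the bottom margin
    !(top || bot)
  }, logical(1))
  out <- cands[keep, , drop = FALSE]
  attr(out, "dp") <- attr(cands, "dp")
  attr(out, "sym") <- attr(cands, "sym")
  out
}

#' Extract the eight per-candidate features
#'
#' Line- and band-integrated symmetry, intensity and lumen-to-wall contrast
#' (`C+`, `C-`) for each candidate: `symmetry_line`, `symmetry_band`,
#' `intensity_line`, `intensity_band`, `contrast_plus_line`,
#' `contrast_plus_band`, `contrast_minus_line`, `contrast_minus_band`.
#' Candidates are expected to be border-filtered already
#' ([filter_candidates()]); residual invalid contrast samples (paths
#' partially entering a margin) are averaged over the valid region.
#'
#' @param img A [bmode_image].
#' @param sym The [symmetry_map()] of `img`.
#' @param cmaps The [contrast_maps()] of `img`.
#' @param cands A border-filtered candidate tibble.
#' @param rf_px Band radius in pixels.
#'
#' @return `cands` with the eight feature columns appended.
#' @export
extract_features <- function(img, sym, cmaps, cands, rf_px) {
  stopifnot(inherits(img, "bmode_image"), inherits(cmaps, "contrast_maps"))
  maps <- list(symmetry = unclass(sym), intensity = img$intensities,
               contrast_plus = cmaps$c_plus, contrast_minus = cmaps$c_minus)
  for (nm in names(maps)) {
    cands[[paste0(nm, "_line")]] <- vapply(
      cands$rows, function(r) line_feature(maps[[nm]], r, na_action = "omit"),
      numeric(1))
    cands[[paste0(nm, "_band")]] <- vapply(
      cands$rows, function(r) band_feature(maps[[nm]], r, rf_px), numeric(1))
  }
  cands
}

#' @export
print.contrast_maps <- function(x, ...) {
  cat(sprintf("<contrast_maps> %d x %d px, delta = %d px\n",
              nrow(x$c_plus), ncol(x$c_plus), x$delta_px))
  invisible(x)
}
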