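#' Specification of a synthetic longitudinal carotid phantom
#'
#' Describes one synthetic B-mode image: a nearly horizontal dark lumen band
#' (the CCA) bounded on both sides by a layered bright/dark/bright wall
#' (intima/media/adventitia), over textured tissue background, with optional
#' jugular-like dark distractor above the artery, optional plaque
#' (local protrusion of the far lumen-intima boundary), optional far-field
#' attenuation zone below the artery (`deep_band`: the echo fades to a
#' dark, noisy floor toward the image bottom) and optional acoustic shadow
#' column. Speckle noise is applied with the multiplicative model of
#' [noise_spec()].
#'
#' The centerline is a shallow curve: linear tilt + quadratic bow + one
#' low-frequency sinusoid, with combined slope well below the 1 px/column
#' excursion that the 8-connected path model can follow.
#'
#' @param image_height_mm,image_width_mm Physical image size (default
#'   35 x 40 mm).
#' @param pixel_size_mm Pixel size (default 0.09 mm).
#' @param lumen_diameter_mm Internal (lumen) diameter.
#' @param center_depth_mm Depth of the centerline at the image center.
#' @param tilt_mm,bow_mm Linear drop across the width / quadratic bow.
#' @param wave_amp_mm,wave_periods,wave_phase Sinusoidal centerline
#'   component.
#' @param lumen_level,tissue_level Base intensities of lumen and tissue.
#' @param texture_sd,texture_scale_mm Amplitude and correlation length of
#'   the background echo texture.
#' @param intima_mm,media_mm,adventitia_mm Wall layer widths (bright intima
#'   0.3 mm, dark media 0.5 mm, bright adventitia 1.5 mm).
#' @param intima_level,media_level,adventitia_level Wall layer intensities.
#' @param distractor `NULL`, or list with `diameter_mm`, `gap_mm` (distance
#'   above the CCA near-wall adventitia), `lumen_level`, `clean` (anechoic
#'   venous interior).
#' @param plaque `NULL`, or list with `height_mm` (protrusion of the far LI
#'   boundary into the lumen, capped below the lumen radius),
#'   `width_mm`, `center_frac` (column position in 0..1), `level`.
#' @param deep_band `NULL`, or list with `gap_mm` (distance below the
#'   far-wall adventitia where attenuation sets in), `level` (dark floor
#'   intensity), `noise_sd` (unstructured far-field noise) and optional
#'   `ramp_mm` (transition length, default 2). Models the attenuated
#'   far field below the artery: a wide dark region with random-phase
#'   noise rather than another vessel-like band.
#' @param shadow `NULL`, or list with `center_frac`, `width_mm`, `strength`
#'   (0..1 attenuation).
#' @param speckle_snr_db Inherent acquisition speckle level (default 40 dB;
#'   `Inf` disables it).
#' @param seed Integer seed; a spec renders byte-identically.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_height_mm = 35, image_width_mm = 40,
                         pixel_size_mm = 0.09,
                         lumen_diameter_mm = 6, center_depth_mm = 16,
                         tilt_mm = 0.5, bow_mm = 0.5,
                         wave_amp_mm = 0.8, wave_periods = 1.2,
                         wave_phase = 0,
                         lumen_level = 0.08, tissue_level = 0.55,
                         texture_sd = 0.04, texture_scale_mm = 0.5,
                         intima_mm = 0.3, media_mm = 0.5,
                         adventitia_mm = 1.5,
                         intima_level = 0.75, media_level = 0.25,
                         adventitia_level = 0.85,
                         distractor = NULL, plaque = NULL,
                         deep_band = NULL, shadow = NULL,
                         speckle_snr_db = 40, seed = 1L) {
  spec <- as.list(environment())
  stopifnot(lumen_diameter_mm > 0, image_height_mm > 0, image_width_mm > 0,
            pixel_size_mm > 0, tissue_level <= 1, lumen_level >= 0)
  structure(spec, class = "phantom_spec")
}

# Row-band mask helper: TRUE where top < row <= bottom (per-column bounds).
band_mask <- function(Y, top, bot) {
  H <- nrow(Y); W <- ncol(Y)
  Y > matrix(top, H, W, byrow = TRUE) & Y <= matrix(bot, H, W, byrow = TRUE)
}

# Smooth correlated noise field with unit-free sd target.
texture_field <- function(H, W, scale_px, sd_target) {
  n <- matrix(stats::rnorm(H * W), H, W)
  pf <- padded_fft(n, ceiling(2 * scale_px))
  t <- ifft_crop(pf, gaussian_transfer(pf, scale_px))
  t / stats::sd(t) * sd_target
}

#' Render a synthetic carotid phantom with ground truth
#'
#' @param spec A [phantom_spec()].
#'
#' @return An object of class `carotid_phantom`: list with `image` (a
#'   [bmode_image]), `annotation` (tibble with one row per column:
#'   `column`, `near_li_row`, `far_li_row`, `centerline_row`) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  px <- spec$pixel_size_mm
  H <- as.integer(round(spec$image_height_mm / px))
  W <- as.integer(round(spec$image_width_mm / px))
  mm <- function(v) v / px

  # centerline curve (rows, real-valued)
  s <- (seq_len(W) - (W + 1) / 2) / W            # -0.5 .. 0.5
  yc <- mm(spec$center_depth_mm) + mm(spec$tilt_mm) * s +
    mm(spec$bow_mm) * (4 * s^2 - 1) +
    mm(spec$wave_amp_mm) * sin(2 * pi * spec$wave_periods * s +
                                 spec$wave_phase)
  half <- mm(spec$lumen_diameter_mm) / 2
  wi <- mm(spec$intima_mm); wm <- mm(spec$media_mm); wa <- mm(spec$adventitia_mm)
  wall <- wi + wm + wa

  near_li <- yc - half
  far_li0 <- yc + half
  far_li <- far_li0
  if (!is.null(spec$plaque)) {
    p <- spec$plaque
    h_px <- min(mm(p$height_mm), half - mm(0.5))   # keep centerline in lumen
    prof <- exp(-((seq_len(W) - p$center_frac * W) / (mm(p$width_mm) / 2))^2)
    far_li <- far_li0 - h_px * prof
  }
  if (min(near_li - wall) < 2 || max(far_li0 + wall) > H - 2)
    stop("phantom geometry does not fit inside the image", call. = FALSE)

  img <- with_local_seed(spec$seed, {
    shapes <- matrix(spec$tissue_level, H, W)
    Y <- matrix(seq_len(H), H, W)

    paint <- function(top, bot, level) {
      m <- band_mask(Y, top, bot)
      shapes[m] <<- level
    }
    # near wall, outside-in: adventitia / media / intima
    paint(near_li - wall, near_li - wi - wm, spec$adventitia_level)
    paint(near_li - wi - wm, near_li - wi, spec$media_level)
    paint(near_li - wi, near_li, spec$intima_level)
    # far wall, inside-out
    paint(far_li0, far_li0 + wi, spec$intima_level)
    paint(far_li0 + wi, far_li0 + wi + wm, spec$media_level)
    paint(far_li0 + wi + wm, far_li0 + wall, spec$adventitia_level)
    # lumen, then plaque filling between the protruded and nominal far LI
    paint(near_li, far_li, spec$lumen_level)
    if (!is.null(spec$plaque)) paint(far_li, far_li0, spec$plaque$level %||% 0.65)

    if (!is.null(spec$distractor)) {
      d <- spec$distractor
      dh <- mm(d$diameter_mm) / 2
      rim <- mm(0.3)
      ctr <- min(near_li - wall) - mm(d$gap_mm) - rim - dh
      ctr <- max(ctr, dh + rim + 2)   # clamp to keep the band inside the top
      if (ctr + dh + rim >= min(near_li - wall) - 2)
        stop("distractor does not fit above the artery", call. = FALSE)
      lvl <- d$lumen_level %||% (if (isTRUE(d$clean)) 0.04 else 0.15)
      paint(rep(ctr - dh - rim, W), rep(ctr - dh, W), 0.65)
      paint(rep(ctr + dh, W), rep(ctr + dh + rim, W), 0.65)
      paint(rep(ctr - dh, W), rep(ctr + dh, W), lvl)
    }

    # echo texture, weighted by local echogenicity so the lumen stays dark
    tex <- texture_field(H, W, mm(spec$texture_scale_mm), spec$texture_sd)
    shapes <- shapes + tex * pmin(shapes / spec$tissue_level, 1.5)

    if (!is.null(spec$shadow)) {
      sh <- spec$shadow
      prof <- exp(-((seq_len(W) - sh$center_frac * W) /
                      (mm(sh$width_mm) / 2))^2)
      shapes <- shapes * matrix(1 - sh$strength * prof, H, W, byrow = TRUE)
    }

    # far-field attenuation below the artery: the echo fades to a dark
    # floor carrying fine-grained random-phase noise (no band structure)
    if (!is.null(spec$deep_band)) {
      db <- spec$deep_band
      start <- max(far_li0 + wall) + mm(db$gap_mm)
      ramp <- mm(db$ramp_mm %||% 2)
      wgt <- matrix(pmin(pmax((seq_len(H) - start) / ramp, 0), 1), H, W)
      grain <- texture_field(H, W, mm(0.25), db$noise_sd %||% 0.08)
      shapes <- shapes * (1 - wgt) + wgt * ((db$level %||% 0.12) + grain)
    }

    # soften band edges (sub-pixel transition, ~1 px)
    pf <- padded_fft(shapes, 8L)
    shapes <- ifft_crop(pf, gaussian_transfer(pf, 1))
    bmode_image(pmin(pmax(shapes, 0), 1), px)
  })
  img <- add_noise(img, noise_spec("speckle", spec$speckle_snr_db,
                                   seed = spec$seed + 104729L))

  ann <- tibble::tibble(column = seq_len(W), near_li_row = near_li,
                        far_li_row = far_li, centerline_row = yc)
  structure(list(image = img, annotation = ann, spec = spec),
            class = "carotid_phantom")
}

#' @export
print.carotid_phantom <- function(x, ...) {
  cat("<carotid_phantom>\n")
  print(x$image)
  cat(sprintf("  lumen diameter %.2f mm; distractor: %s; plaque: %s\n",
              x$spec$lumen_diameter_mm,
              !is.null(x$spec$distractor), !is.null(x$spec$plaque)))
  invisible(x)
}

#' Generate a bank of random carotid phantoms
#'
#' Draws i.i.d. phantom specifications: lumen diameter uniform on
#' 4.5-8.5 mm, randomized centerline curvature and depth, and optional
#' structures with fixed prevalences (distractor above the CCA 50%,
#' plaques 20%, acoustic shadows 10%, far-field attenuation zone below the
#' CCA 40%).
#' About 60% of distractors are rendered "clean" (anechoic, vein-like),
#' which makes them at least as symmetric as the artery itself - the
#' failure mode that defeats purely symmetry-greedy selection.
#'
#' @param n Number of phantoms.
#' @param seed Root seed; each phantom gets its own derived stream, so any
#'   single image is reproducible independently of the others.
#' @param distractor_prob,plaque_prob,shadow_prob,deep_band_prob Structure
#'   prevalences.
#' @param speckle_snr_db Inherent speckle level passed to every spec.
#'
#' @return A tibble with columns `id`, `image`, `annotation`, `spec` (the
#'   latter three are list-columns).
#' @export
generate_dataset <- function(n, seed = 1L, distractor_prob = 0.5,
                             plaque_prob = 0.2, shadow_prob = 0.1,
                             deep_band_prob = 0.4, speckle_snr_db = 40) {
  stopifnot(n >= 1)
  specs <- with_local_seed(seed, {
    im_seeds <- sample.int(2147483646L, n)
    lapply(seq_len(n), function(i) {
      has_distractor <- stats::runif(1) < distractor_prob
      has_plaque <- stats::runif(1) < plaque_prob
      has_shadow <- stats::runif(1) < shadow_prob
      has_deep <- stats::runif(1) < deep_band_prob
      # with a distractor the artery sits a little deeper so both fit
      depth <- if (has_distractor) stats::runif(1, 16.5, 21)
               else stats::runif(1, 13, 21)
      phantom_spec(
        lumen_diameter_mm = stats::runif(1, 4.5, 8.5),
        center_depth_mm = depth,
        tilt_mm = stats::runif(1, -2, 2),
        bow_mm = stats::runif(1, -1.5, 1.5),
        wave_amp_mm = stats::runif(1, 0.3, 1.2),
        wave_periods = stats::runif(1, 0.8, 1.6),
        wave_phase = stats::runif(1, 0, 2 * pi),
        lumen_level = stats::runif(1, 0.05, 0.12),
        tissue_level = stats::runif(1, 0.45, 0.65),
        texture_sd = stats::runif(1, 0.03, 0.06),
        distractor = if (has_distractor) list(
          diameter_mm = stats::runif(1, 3, 6),
          gap_mm = stats::runif(1, 1, 4),
          clean = stats::runif(1) < 0.6
        ),
        plaque = if (has_plaque) list(
          height_mm = stats::runif(1, 1, 2.5),
          width_mm = stats::runif(1, 5, 15),
          center_frac = stats::runif(1, 0.25, 0.75),
          level = stats::runif(1, 0.55, 0.75)
        ),
        deep_band = if (has_deep) list(
          gap_mm = stats::runif(1, 1.5, 4),
          level = stats::runif(1, 0.06, 0.15),
          noise_sd = stats::runif(1, 0.05, 0.12)
        ),
        shadow = if (has_shadow) list(
          center_frac = stats::runif(1, 0.15, 0.85),
          width_mm = stats::runif(1, 2, 5),
          strength = stats::runif(1, 0.3, 0.6)
        ),
        speckle_snr_db = speckle_snr_db,
        seed = im_seeds[i]
      )
    })
  })
  ph <- lapply(specs, generate_phantom)
  out <- tibble::tibble(
    id = seq_len(n),
    image = lapply(ph, `[[`, "image"),
    annotation = lapply(ph, `[[`, "annotation"),
    spec = specs
  )
  attr(out, "seed") <- seed
  out
}

#' Write a phantom bank to disk
#'
#' One PNG per image, one annotation CSV per image (`column`,
#' `near_li_row`, `far_li_row`, `centerline_row`) and a `manifest.json`
#' with the generating specifications.
#'
#' @param dataset A [generate_dataset()] tibble.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(dataset))) {
    stem <- file.path(dir, sprintf("phantom_%03d", dataset$id[i]))
    write_bmode(dataset$image[[i]], paste0(stem, ".png"))
    utils::write.csv(dataset$annotation[[i]], paste0(stem, ".csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(seed = attr(dataset, "seed"),
         pixel_size_mm = dataset$image[[1L]]$pixel_size_mm,
         specs = lapply(dataset$spec, function(s) unclass(s))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}
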