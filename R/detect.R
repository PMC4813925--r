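#' Detect the CCA lumen centerline in one image
#'
#' End-to-end pipeline: resampling to the analysis pixel size, symmetry
#' map, DP candidate detection, border filtering, feature extraction and
#' per-image normalization, then selection by the requested method
#' (`"proposed"` needs a trained [lumen gate][fit_logistic]; the baselines
#' do not).
#'
#' @param img A [bmode_image].
#' @param params A `parameter_set` (defaults to [carotid_parameters()]).
#' @param gate A `lumen_gate` (required for `method = "proposed"`).
#' @param method Selection strategy.
#'
#' @return An object of class `lumen_detection`: list with `rows` (the
#'   detected centerline, one row per column of the *resampled* image, or
#'   `NULL` if no candidate survived), `method`, `fallback`, `candidates`
#'   (tibble with features, and posteriors for the proposed method),
#'   `image` (the resampled image) and `params`.
#' @export
detect_lumen <- function(img, params = carotid_parameters(), gate = NULL,
                         method = c("proposed", "best_sym", "bottom_most")) {
  method <- match.arg(method)
  stopifnot(inherits(img, "bmode_image"))
  if (abs(img$pixel_size_mm - params$pixel_size_mm) > 1e-9)
    img <- resample_bmode(img, params$pixel_size_mm)
  an <- analyze_image(img, params)
  cands <- an$candidates
  fallback <- FALSE
  if (method == "best_sym") {
    rows <- an$best_sym$rows
  } else if (method == "bottom_most") {
    rows <- if (nrow(cands)) select_bottom_most(cands)$rows else NULL
  } else {
    if (is.null(gate))
      stop("`gate` is required for the proposed method; train one with ",
           "`train_gate()` or load one with `read_gate()`", call. = FALSE)
    if (nrow(cands)) {
      sel <- select_lumen(normalize_features(cands), gate)
      rows <- sel$rows
      fallback <- sel$fallback
      cands$posterior <- sel$scores$posterior
      cands$accepted <- sel$scores$accepted
    } else rows <- NULL
  }
  structure(list(rows = rows, method = method, fallback = fallback,
                 candidates = cands, image = img, params = params),
            class = "lumen_detection")
}

#' @export
print.lumen_detection <- function(x, ...) {
  cat(sprintf("<lumen_detection> method %s: %s%s; %d candidate(s)\n",
              x$method,
              if (is.null(x$rows)) "no lumen found"
              else sprintf("centerline at mean row %.1f", mean(x$rows)),
              if (x$fallback) " [gate fallback]" else "",
              nrow(x$candidates)))
  invisible(x)
}

#' Export a detection result as JSON
#'
#' @param det A `lumen_detection`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_detection <- function(det, path) {
  cands <- det$candidates
  cands$rows <- NULL
  jsonlite::write_json(
    list(method = det$method, fallback = det$fallback,
         chosen_rows = det$rows, candidates = cands),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Train a lumen gate on an annotated image bank
#'
#' Runs the candidate stage on every (noiseless) image, labels candidates
#' against the LI boundaries, normalizes features per image and fits the
#' one-dimensional logistic gate on the pooled candidates. Images whose
#' candidate stage produced no in-lumen candidate are skipped with a
#' message.
#'
#' @param dataset A [generate_dataset()]-style tibble with `image` and
#'   `annotation` list-columns.
#' @param feature Feature used by the gate (default `"contrast_plus_line"`,
#'   the strongest feature on clean images; `"symmetry_line"` is the most
#'   noise-robust alternative).
#' @param params A `parameter_set`.
#' @param correct_fraction Positive-label rule (default 0.8).
#' @param threshold Posterior acceptance cut (default 0.5).
#'
#' @return A `lumen_gate`.
#' @export
train_gate <- function(dataset, feature = "contrast_plus_line",
                       params = carotid_parameters(),
                       correct_fraction = 0.8, threshold = 0.5) {
  pooled <- lapply(seq_len(nrow(dataset)), function(i) {
    an <- analyze_image(dataset$image[[i]], params,
                        truth = dataset$annotation[[i]],
                        correct_fraction = correct_fraction)
    cc <- an$candidates
    if (!nrow(cc) || !any(cc$label == "positive")) return(NULL)
    cc <- normalize_features(cc)
    cc[cc$label != "excluded", c(feature, "label")]
  })
  tr <- dplyr::bind_rows(pooled)
  skipped <- sum(vapply(pooled, is.null, logical(1)))
  if (skipped) message(skipped, " image(s) without an in-lumen candidate ",
                       "were skipped for training")
  fit_logistic(tr[[feature]], tr$label, feature_name = feature,
               threshold = threshold)
}
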