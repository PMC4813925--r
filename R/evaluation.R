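#' Fraction of path points inside the lumen
#'
#' A path point is counted as correct when it lies strictly between the
#' near- and far-wall lumen-intima boundaries of its column; a point that
#' touches an LI boundary counts as misdetected.
#'
#' @param rows Integer vector of path rows (or a `candidate_path`).
#' @param truth Wall annotation tibble with per-column `near_li_row` and
#'   `far_li_row`; must have one row per path column.
#'
#' @return Fraction in `[0, 1]`.
#' @export
path_correct_fraction <- function(rows, truth) {
  if (inherits(rows, "candidate_path")) rows <- rows$rows
  if (length(rows) != nrow(truth))
    stop("path and annotation widths differ", call. = FALSE)
  mean(rows > truth$near_li_row & rows < truth$far_li_row)
}

#' Is a detected path a correct lumen detection?
#'
#' @inheritParams path_correct_fraction
#' @param frac Required fraction of in-lumen points (default 0.8; a path
#'   with at least this fraction of points between the LI boundaries counts
#'   as correct).
#'
#' @return Logical.
#' @export
is_correct <- function(rows, truth, frac = 0.8) {
  path_correct_fraction(rows, truth) >= frac
}

#' ROC curve, AUC and best balanced accuracy
#'
#' Threshold sweep over the unique scores (predict positive when
#' `score >= threshold`), trapezoidal area under the curve, and the best
#' accuracy over thresholds computed with equal class priors,
#' `(TPR + TNR) / 2`.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels 0/1 labels; both classes must be present.
#'
#' @return An object of class `lumen_roc`: list with `curve` (tibble
#'   `threshold`, `fpr`, `tpr`), `auc` and `best_accuracy`.
#' @export
roc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  if (length(unique(labels)) < 2L)
    stop("both classes must be present", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / np,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / nn,
                numeric(1))
  curve <- tibble::tibble(threshold = c(Inf, thr), fpr = c(0, fpr),
                          tpr = c(0, tpr))
  o <- order(curve$fpr, curve$tpr)
  x <- c(curve$fpr[o], 1); y <- c(curve$tpr[o], 1)
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  structure(list(curve = curve, auc = auc,
                 best_accuracy = max((tpr + (1 - fpr)) / 2)),
            class = "lumen_roc")
}

#' @export
print.lumen_roc <- function(x, ...) {
  cat(sprintf("<lumen_roc> AUC %.3f, best balanced accuracy %.3f (%d pts)\n",
              x$auc, x$best_accuracy, nrow(x$curve)))
  invisible(x)
}

#' Configuration of the cross-validated evaluation experiment
#'
#' @param folds Number of cross-validation folds (default 5).
#' @param repetitions Number of randomized repetitions of the fold split
#'   and noise simulation. The default (5) keeps interactive runs short;
#'   the full protocol uses 50.
#' @param snr_grid_db SNR levels for the robustness sweep (default 30 down
#'   to -30 dB).
#' @param noise_models Subset of `c("speckle", "gaussian")`.
#' @param correct_fraction Required fraction of in-lumen points for a
#'   detection to count as correct (default 0.8).
#' @param features Features whose gated selectors are evaluated.
#' @param threshold Posterior acceptance cut of the gate (default 0.5).
#' @param seed Root seed for fold splits and noise streams.
#'
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(folds = 5L, repetitions = 5L,
                              snr_grid_db = seq(30, -30, by = -10),
                              noise_models = "speckle",
                              correct_fraction = 0.8,
                              features = c("symmetry_line",
                                           "contrast_plus_line"),
                              threshold = 0.5, seed = 1L) {
  stopifnot(folds >= 2L, repetitions >= 1L,
            all(noise_models %in% c("speckle", "gaussian")),
            correct_fraction > 0, correct_fraction <= 1)
  structure(list(folds = as.integer(folds),
                 repetitions = as.integer(repetitions),
                 snr_grid_db = snr_grid_db, noise_models = noise_models,
                 correct_fraction = correct_fraction, features = features,
                 threshold = threshold, seed = as.integer(seed)),
            class = "experiment_config")
}

# Random K-fold assignment: a partition of 1..n into folds of near-equal
# size.
make_folds <- function(n, k, seed) {
  with_local_seed(seed, sample(rep_len(seq_len(k), n)))
}

# Internal: analyze one image at one noise condition; returns the kept
# candidate tibble with features (and labels when truth is given) plus the
# per-image summary.
analyze_image <- function(img, params, cfg_sym = NULL, truth = NULL,
                          correct_fraction = 0.8) {
  cfg_sym <- cfg_sym %||% symmetry_config_from(params)
  px <- parameters_px(params, img$pixel_size_mm)
  a <- sym_analysis(img, cfg_sym, px$sigma_on, px$sigma_off)
  sym <- sym_from_parts(a$even, a$odd1, a$odd2, cfg_sym)
  dp <- dp_forward(sym)
  cands <- candidates_from_dp(dp, px$sigma_peak)
  n_raw <- nrow(cands)
  best <- select_best_sym(dp)
  cmaps <- contrast_from_blurs(a$g_on, a$g_off, px$delta)
  kept <- filter_candidates(cands, px$delta, nrow(img$intensities))
  attr(kept, "dp") <- NULL; attr(kept, "sym") <- NULL
  if (nrow(kept))
    kept <- extract_features(img, sym, cmaps, kept, px$rf)
  summary <- list(n_raw = n_raw, n_kept = nrow(kept))
  if (!is.null(truth)) {
    kept$correct_fraction <- vapply(kept$rows, path_correct_fraction,
                                    numeric(1), truth = truth)
    kept <- label_candidates(kept, truth, frac = correct_fraction)
    summary$best_sym_fraction <- path_correct_fraction(best, truth)
    summary$max_fraction <- if (nrow(kept)) max(kept$correct_fraction) else 0
  }
  list(candidates = kept, best_sym = best, dp = dp, sym = sym,
       cmaps = cmaps, summary = summary)
}

#' Run the cross-validated phantom evaluation
#'
#' The full experimental protocol on an annotated image bank:
#' \enumerate{
#'   \item Every image is analyzed noiselessly and at every
#'     (noise model, SNR) combination of the sweep: candidate detection,
#'     border filtering, feature extraction, per-image normalization and
#'     correctness against the LI boundaries.
#'   \item Per repetition, images are split into K folds. The
#'     one-dimensional logistic gate of each feature is trained on the
#'     *noiseless* candidates of the training folds (positives = in-lumen
#'     candidates, negatives = candidates below the artery; images without
#'     a positive candidate are skipped). All selectors are then evaluated
#'     on the test folds at every noise condition.
#'   \item Images whose candidate stage found no acceptable candidate for
#'     a given condition are removed from the selection metric for that
#'     condition, so the reported selection performance is conditionally
#'     independent of the candidate stage (reported separately).
#' }
#'
#' @param dataset A [generate_dataset()] tibble (or any tibble with
#'   `image`/`annotation` list-columns).
#' @param cfg An [experiment_config()].
#' @param params A `parameter_set`.
#' @param progress Print a line per analyzed image.
#'
#' @return An object of class `lumen_report`; see the fields described in
#'   the package vignette. Dispersions across repetitions are reported both
#'   as SD and SEM.
#' @export
run_experiment <- function(dataset, cfg = experiment_config(),
                           params = carotid_parameters(), progress = FALSE) {
  n <- nrow(dataset)
  if (n < cfg$folds) stop("fewer images than folds", call. = FALSE)
  conditions <- dplyr::bind_rows(
    tibble::tibble(noise_model = "none", snr_db = Inf),
    tidyr::expand_grid(noise_model = cfg$noise_models,
                       snr_db = as.numeric(cfg$snr_grid_db))
  )
  noise_seeds <- with_local_seed(cfg$seed,
    matrix(sample.int(2147483646L, n * nrow(conditions)), n))

  cand_list <- vector("list", n * nrow(conditions))
  img_list <- vector("list", n * nrow(conditions))
  k <- 0L
  for (i in seq_len(n)) {
    if (progress) message("image ", i, "/", n)
    for (ci in seq_len(nrow(conditions))) {
      k <- k + 1L
      img <- dataset$image[[i]]
      if (conditions$noise_model[ci] != "none")
        img <- add_noise(img, noise_spec(conditions$noise_model[ci],
                                         conditions$snr_db[ci],
                                         seed = noise_seeds[i, ci]))
      an <- analyze_image(img, params, truth = dataset$annotation[[i]],
                          correct_fraction = cfg$correct_fraction)
      cc <- an$candidates
      if (nrow(cc)) {
        cc <- normalize_features(cc)
        cc$image <- dataset$id[i]
        cc$noise_model <- conditions$noise_model[ci]
        cc$snr_db <- conditions$snr_db[ci]
        cc$rows <- NULL  # paths not needed beyond the per-candidate stats
        cand_list[[k]] <- cc
      }
      img_list[[k]] <- tibble::tibble(
        image = dataset$id[i],
        noise_model = conditions$noise_model[ci],
        snr_db = conditions$snr_db[ci],
        n_kept = an$summary$n_kept,
        best_sym_fraction = an$summary$best_sym_fraction,
        max_fraction = an$summary$max_fraction)
    }
  }
  cand <- dplyr::bind_rows(cand_list)
  imgs <- dplyr::bind_rows(img_list)
  evaluate_candidate_tables(cand, imgs, cfg)
}

# Internal: stage 2 of run_experiment, separated for testability.
evaluate_candidate_tables <- function(cand, imgs, cfg) {
  frac_req <- cfg$correct_fraction
  imgs$eligible <- imgs$max_fraction >= frac_req
  imgs$best_sym_correct <- imgs$best_sym_fraction >= frac_req

  # bottom-most baseline: repetition-independent
  bm <- cand |>
    dplyr::group_by(.data$image, .data$noise_model, .data$snr_db) |>
    dplyr::slice_max(.data$mean_row, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::transmute(.data$image, .data$noise_model, .data$snr_db,
                     bottom_most_correct = .data$correct_fraction >= frac_req)
  imgs <- dplyr::left_join(imgs, bm,
                           by = c("image", "noise_model", "snr_db"))

  ids <- sort(unique(imgs$image))
  noiseless <- cand[cand$noise_model == "none", , drop = FALSE]

  perf_rows <- list(); clf_rows <- list(); curve_rows <- list()
  for (rep in seq_len(cfg$repetitions)) {
    fold <- make_folds(length(ids), cfg$folds, cfg$seed + 7919L * rep)
    names(fold) <- ids
    test_pred <- list()
    for (kf in seq_len(cfg$folds)) {
      train_ids <- ids[fold != kf]
      test_ids <- ids[fold == kf]
      tr <- noiseless[noiseless$image %in% train_ids &
                        noiseless$label != "excluded", , drop = FALSE]
      # skip training images that yielded no in-lumen candidate
      has_pos <- tapply(tr$label == "positive", tr$image, any)
      tr <- tr[tr$image %in% names(has_pos)[has_pos], , drop = FALSE]
      te <- cand[cand$image %in% test_ids, , drop = FALSE]
      for (feat in cfg$features) {
        gate <- fit_logistic(tr[[feat]], tr$label,
                             feature_name = feat,
                             threshold = cfg$threshold)
        post <- gate_score(gate, te[[feat]])
        sel <- te |>
          dplyr::mutate(posterior = post,
                        accepted = post >= gate$threshold) |>
          dplyr::group_by(.data$image, .data$noise_model, .data$snr_db) |>
          dplyr::summarise(correct = {
            i <- if (any(.data$accepted))
              which(.data$accepted)[which.max(.data$mean_row[.data$accepted])]
            else which.max(.data$posterior)
            .data$correct_fraction[i] >= frac_req
          }, .groups = "drop")
        sel$feature <- feat
        sel$rep <- rep
        test_pred[[length(test_pred) + 1L]] <- list(
          sel = sel,
          roc = dplyr::mutate(
            te[te$noise_model == "none" & te$label != "excluded",
               c("image", feat, "label")],
            posterior = gate_score(gate, te[[feat]][
              te$noise_model == "none" & te$label != "excluded"]),
            feature = feat))
      }
    }
    sel_all <- dplyr::bind_rows(lapply(test_pred, `[[`, "sel"))
    roc_all <- dplyr::bind_rows(lapply(test_pred, `[[`, "roc"))
    # selection performance per condition, eligible images only
    el <- imgs[imgs$eligible, c("image", "noise_model", "snr_db")]
    sel_el <- dplyr::inner_join(sel_all, el,
                                by = c("image", "noise_model", "snr_db"))
    perf_rows[[rep]] <- sel_el |>
      dplyr::group_by(.data$feature, .data$noise_model, .data$snr_db) |>
      dplyr::summarise(correct_pct = 100 * mean(.data$correct),
                       n_eligible = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(rep = rep)
    # classifier metrics on pooled noiseless test predictions
    clf_rows[[rep]] <- roc_all |>
      dplyr::group_by(.data$feature) |>
      dplyr::group_modify(function(d, g) {
        r <- roc(d$posterior, as.integer(d$label == "positive"))
        tibble::tibble(auc = r$auc, best_accuracy = r$best_accuracy)
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(rep = rep)
    if (rep == 1L) curve_rows <- roc_all
  }
  perf <- dplyr::bind_rows(perf_rows)

  baselines <- imgs[imgs$eligible, ] |>
    dplyr::group_by(.data$noise_model, .data$snr_db) |>
    dplyr::summarise(
      best_sym = 100 * mean(.data$best_sym_correct),
      bottom_most = 100 * mean(.data$bottom_most_correct, na.rm = TRUE),
      n_eligible = dplyr::n(), .groups = "drop") |>
    tidyr::pivot_longer(c("best_sym", "bottom_most"), names_to = "method",
                        values_to = "mean_pct") |>
    dplyr::mutate(sd_pct = 0, sem_pct = 0)

  performance <- perf |>
    dplyr::group_by(.data$feature, .data$noise_model, .data$snr_db) |>
    dplyr::summarise(mean_pct = mean(.data$correct_pct),
                     sd_pct = stats::sd(.data$correct_pct),
                     sem_pct = stats::sd(.data$correct_pct) /
                       sqrt(dplyr::n()),
                     n_eligible = mean(.data$n_eligible),
                     .groups = "drop") |>
    dplyr::mutate(method = paste0("proposed_", .data$feature),
                  sd_pct = ifelse(is.na(.data$sd_pct), 0, .data$sd_pct),
                  sem_pct = ifelse(is.na(.data$sem_pct), 0, .data$sem_pct)) |>
    dplyr::select(!"feature") |>
    dplyr::bind_rows(baselines) |>
    dplyr::arrange(.data$method, .data$noise_model, dplyr::desc(.data$snr_db))

  candidate_stage <- imgs |>
    dplyr::group_by(.data$noise_model, .data$snr_db) |>
    dplyr::summarise(pct_any_full = 100 * mean(.data$max_fraction >= 1),
                     pct_any_correct = 100 * mean(.data$eligible),
                     .groups = "drop")

  candidate_curve <- tidyr::expand_grid(
    dplyr::distinct(imgs, .data$noise_model, .data$snr_db),
    required_fraction = seq(0, 1, by = 0.05)) |>
    dplyr::rowwise() |>
    dplyr::mutate(pct_images = 100 * mean(
      imgs$max_fraction[imgs$noise_model == .data$noise_model &
                          imgs$snr_db == .data$snr_db] >=
        .data$required_fraction)) |>
    dplyr::ungroup()

  classifier <- dplyr::bind_rows(clf_rows) |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(auc_mean = mean(.data$auc),
                     auc_sd = stats::sd(.data$auc),
                     best_accuracy_mean = mean(.data$best_accuracy),
                     best_accuracy_sd = stats::sd(.data$best_accuracy),
                     .groups = "drop")

  structure(list(performance = performance,
                 candidate_stage = candidate_stage,
                 candidate_curve = candidate_curve,
                 classifier = classifier,
                 roc_scores = curve_rows,
                 images = imgs, config = cfg),
            class = "lumen_report")
}

#' @export
print.lumen_report <- function(x, ...) {
  cat("<lumen_report>\n\nCandidate stage (% images with a correct candidate):\n")
  print(as.data.frame(x$candidate_stage), row.names = FALSE, digits = 3)
  cat("\nSelection performance (% correct detections, eligible images):\n")
  print(as.data.frame(x$performance[, c("method", "noise_model", "snr_db",
                                        "mean_pct", "sd_pct", "sem_pct")]),
        row.names = FALSE, digits = 3)
  cat("\nClassifier (noiseless test folds):\n")
  print(as.data.frame(x$classifier), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Export an evaluation report
#'
#' @param report A `lumen_report`.
#' @param path Output path: `.json` for the whole report, `.csv` for the
#'   selection-performance table only.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(
      list(performance = report$performance,
           candidate_stage = report$candidate_stage,
           classifier = report$classifier,
           config = unclass(report$config)),
      path, auto_unbox = TRUE, digits = NA, na = "null")
  } else if (ext == "csv") {
    utils::write.csv(report$performance, path, row.names = FALSE)
  } else stop("unsupported report format: .", ext, call. = FALSE)
  invisible(path)
}
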