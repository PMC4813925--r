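#' Per-image feature normalization
#'
#' Makes features relative to the best candidate in the image: symmetry and
#' contrast features have the per-image maximum subtracted (so the best
#' candidate sits at 0 and the rest are negative), the intensity features
#' have the per-image minimum subtracted (darkest candidate at 0, the rest
#' positive). This image-wise referencing is what lets a threshold trained
#' on clean images extrapolate to heavy noise.
#'
#' @param feats Tibble of candidate features ([extract_features()] output)
#'   for a *single image*.
#'
#' @return The tibble with the feature columns normalized.
#' @export
normalize_features <- function(feats) {
  if (!nrow(feats)) stop("no candidates to normalize", call. = FALSE)
  for (nm in grep("^(symmetry|contrast_(plus|minus))_(line|band)$",
                  names(feats), value = TRUE))
    feats[[nm]] <- feats[[nm]] - max(feats[[nm]])
  for (nm in grep("^intensity_(line|band)$", names(feats), value = TRUE))
    feats[[nm]] <- feats[[nm]] - min(feats[[nm]])
  feats
}

#' Label candidates against ground-truth wall annotations
#'
#' Training labels for the feature gate: a candidate that runs through the
#' lumen (correct with respect to the lumen-intima boundaries, see
#' [is_correct()]) is `positive`; a candidate lying entirely below the far
#' LI boundary is `negative`; everything else - in particular candidates
#' above the CCA, which may be genuinely CCA-like (jugular vein) - is
#' `excluded` from training.
#'
#' @param cands Candidate tibble.
#' @param truth A wall annotation (see [generate_phantom()]): tibble with
#'   `near_li_row` and `far_li_row` per column.
#' @param frac Minimum fraction of in-lumen points for the positive label
#'   (default 0.8).
#'
#' @return `cands` with a `label` column
#'   (`"positive"`/`"negative"`/`"excluded"`).
#' @export
label_candidates <- function(cands, truth, frac = 0.8) {
  far <- truth$far_li_row
  cands$label <- vapply(cands$rows, function(r) {
    if (path_correct_fraction(r, truth) >= frac) "positive"
    else if (all(r > far)) "negative"
    else "excluded"
  }, character(1))
  cands
}

#' Fit the one-dimensional logistic gate
#'
#' Maximum-likelihood logistic regression of the class label on a single
#' normalized feature. With `equal_priors = TRUE` (the default) the classes
#' are reweighted inversely to their counts, so the fitted posterior
#' corresponds to equal a priori class probabilities regardless of how many
#' negative candidates the training images produced.
#'
#' @param values Numeric vector of (normalized) feature values.
#' @param labels Vector of 0/1 (or `"negative"`/`"positive"`) labels; both
#'   classes must be present.
#' @param equal_priors Reweight classes to equal priors (default `TRUE`).
#' @param feature_name Name of the feature (stored in the model).
#' @param threshold Posterior cut for acceptance (default 0.5).
#'
#' @return An object of class `lumen_gate` with fields `feature_name`,
#'   `slope`, `intercept`, `threshold`, `normalization` and `n`.
#' @export
fit_logistic <- function(values, labels, equal_priors = TRUE,
                         feature_name = "feature", threshold = 0.5) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.integer(as.character(labels) == "positive")
  labels <- as.integer(labels)
  if (!all(is.finite(values))) stop("non-finite feature values", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to fit the gate", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("`threshold` must lie in (0, 1)", call. = FALSE)
  w <- rep(1, length(labels))
  if (equal_priors) {
    n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
    w[labels == 1L] <- length(labels) / (2 * n1)
    w[labels == 0L] <- length(labels) / (2 * n0)
  }
  # quasibinomial gives the same ML coefficients without the non-integer
  # weight warning; separation warnings are expected on clean data
  fit <- suppressWarnings(
    stats::glm(labels ~ values, family = stats::quasibinomial(), weights = w))
  structure(list(
    feature_name = feature_name,
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    threshold = threshold,
    normalization = if (grepl("^intensity", feature_name))
      "subtract_min" else "subtract_max",
    n = length(labels)
  ), class = "lumen_gate")
}

#' Posterior score of a gate on feature values
#'
#' @param gate A `lumen_gate`.
#' @param values Numeric vector of normalized feature values.
#' @return Posterior probabilities in (0, 1).
#' @export
gate_score <- function(gate, values) {
  stopifnot(inherits(gate, "lumen_gate"))
  stats::plogis(gate$slope * values + gate$intercept)
}

#' @export
print.lumen_gate <- function(x, ...) {
  cat(sprintf(
    "<lumen_gate> %s: posterior = plogis(%.3g * v %+.3g), cut %.2f (n = %d)\n",
    x$feature_name, x$slope, x$intercept, x$threshold, x$n))
  invisible(x)
}

#' Read/write a gate model as JSON
#'
#' @param gate A `lumen_gate`.
#' @param path JSON file path.
#' @return `read_gate()` returns a `lumen_gate`; `write_gate()` returns
#'   `path` invisibly.
#' @export
write_gate <- function(gate, path) {
  stopifnot(inherits(gate, "lumen_gate"))
  jsonlite::write_json(unclass(gate), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gate
#' @export
read_gate <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(g[c("feature_name", "slope", "intercept", "threshold",
                "normalization", "n")], class = "lumen_gate")
}

#' Select the lumen among gated candidates
#'
#' Feature-based selection followed by the positional heuristic: candidates
#' whose gate posterior reaches the threshold are accepted, and among the
#' accepted the *bottom-most* one (largest mean row; rows grow downward) is
#' chosen as the CCA lumen, reflecting that CCA look-alikes (jugular vein,
#' sternocleidomastoid muscle) lie above the artery. If no candidate passes
#' the gate the highest-posterior candidate is returned with
#' `fallback = TRUE`, so the detector always localizes one ROI.
#'
#' @param cands Candidate tibble with *normalized* features
#'   ([normalize_features()]).
#' @param gate A `lumen_gate`.
#'
#' @return An object of class `lumen_selection`: list with `chosen_id`
#'   (a `candidate_id`, or `NA` when there are no candidates), `rows` of
#'   the chosen path, `scores` (tibble of candidate_id, posterior,
#'   accepted), `fallback` and `method = "proposed"`.
#' @export
select_lumen <- function(cands, gate) {
  if (!nrow(cands))
    return(structure(list(chosen_id = NA_integer_, rows = NULL,
                          scores = tibble::tibble(candidate_id = integer(),
                                                  posterior = numeric(),
                                                  accepted = logical()),
                          fallback = FALSE, method = "proposed"),
                     class = "lumen_selection"))
  v <- cands[[gate$feature_name]]
  if (is.null(v)) stop("feature `", gate$feature_name,
                       "` not present in candidates", call. = FALSE)
  post <- gate_score(gate, v)
  acc <- post >= gate$threshold
  fallback <- !any(acc)
  i <- if (fallback) which.max(post)
       else which(acc)[which.max(cands$mean_row[acc])]
  structure(list(
    chosen_id = cands$candidate_id[i],
    rows = cands$rows[[i]],
    scores = tibble::tibble(candidate_id = cands$candidate_id,
                            posterior = post, accepted = acc),
    fallback = fallback, method = "proposed"
  ), class = "lumen_selection")
}

#' Baseline: path with the maximum aggregated symmetry
#'
#' Backtracks the path ending at the global maximum of the DP gain profile
#' (ties broken toward the smaller row). This is the greedy selector that
#' the candidate-gating pipeline improves upon.
#'
#' @param dp A [dp_forward()] result.
#' @return A `candidate_path`.
#' @export
select_best_sym <- function(dp) {
  stopifnot(inherits(dp, "dp_result"))
  backtrack(dp, which.max(dp$profile))
}

#' Baseline: bottom-most candidate without feature gating
#'
#' @param cands Border-filtered candidate tibble (>= 1 row).
#' @return The chosen candidate as a `candidate_path`.
#' @export
select_bottom_most <- function(cands) {
  if (!nrow(cands)) stop("no candidates", call. = FALSE)
  i <- which.max(cands$mean_row)
  structure(list(rows = cands$rows[[i]], gain = cands$gain[i],
                 end_row = cands$end_row[i]),
            class = "candidate_path")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.lumen_gate <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", x$feature_name),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.lumen_gate <- function(x, ...) {
  tibble::tibble(feature_name = x$feature_name, threshold = x$threshold,
                 normalization = x$normalization, n = x$n)
}
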