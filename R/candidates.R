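#' Dynamic-programming optimization of a symmetry map
#'
#' Propagates, left to right, the accumulated symmetry gain
#' `G*(p_n) = max over connected predecessors G*(p_{n-1}) + Sym(p_n)` with
#' `G*(p_1) = Sym(p_1)`, where two points in adjacent columns are connected
#' when their rows differ by at most one (8-connectivity). The last column
#' of the gain table is the DP gain profile: entry `r` is the best
#' accumulated symmetry over all admissible paths ending at row `r`.
#'
#' Ties in the maximization are broken deterministically in favor of the
#' straight predecessor (same row), then the one above, then the one below,
#' which yields smooth, reproducible centerlines.
#'
#' @param sym Numeric matrix (typically a [symmetry_map()]).
#'
#' @return An object of class `dp_result`: list with `gain_table` (matrix),
#'   `backpointers` (matrix of predecessor row offsets in `{-1, 0, +1}`)
#'   and `profile` (last column of the gain table).
#' @export
dp_forward <- function(sym) {
  m <- unclass(sym)
  stopifnot(is.matrix(m), is.numeric(m), nrow(m) >= 1L, ncol(m) >= 1L)
  H <- nrow(m); N <- ncol(m)
  G <- matrix(0, H, N)
  B <- matrix(0L, H, N)
  G[, 1L] <- m[, 1L]
  if (N > 1L) for (n in 2:N) {
    prev <- G[, n - 1L]
    best <- prev                       # straight predecessor, offset 0
    bp <- integer(H)
    if (H > 1L) {
      up <- c(-Inf, prev[-H])          # predecessor one row above (offset -1)
      take <- up > best
      best[take] <- up[take]; bp[take] <- -1L
      dn <- c(prev[-1L], -Inf)         # predecessor one row below (offset +1)
      take <- dn > best
      best[take] <- dn[take]; bp[take] <- 1L
    }
    G[, n] <- best + m[, n]
    B[, n] <- bp
  }
  structure(list(gain_table = G, backpointers = B, profile = G[, N]),
            class = "dp_result")
}

#' Backtrack the optimal path ending at a given row
#'
#' @param dp A [dp_forward()] result.
#' @param end_row Row index (1-based) in the last column.
#'
#' @return An object of class `candidate_path`: list with `rows` (one row
#'   index per column), `gain` (the accumulated symmetry,
#'   `dp$profile[end_row]`) and `end_row`.
#' @export
backtrack <- function(dp, end_row) {
  stopifnot(inherits(dp, "dp_result"))
  H <- nrow(dp$gain_table); N <- ncol(dp$gain_table)
  end_row <- as.integer(end_row)
  if (end_row < 1L || end_row > H) stop("`end_row` out of range", call. = FALSE)
  rows <- integer(N)
  rows[N] <- end_row
  if (N > 1L) for (n in N:2) rows[n - 1L] <- rows[n] + dp$backpointers[rows[n], n]
  structure(list(rows = rows, gain = dp$profile[end_row], end_row = end_row),
            class = "candidate_path")
}

# Gaussian first-derivative response of a 1-D profile, mirror boundary.
gaussian_derivative <- function(profile, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  t <- (-r):r
  k <- -t / sigma^2 * exp(-t^2 / (2 * sigma^2))
  n <- length(profile)
  ext <- profile[reflect_index(seq(1L - r, n + r), n)]
  # response at i uses samples i-r .. i+r; positive where the smoothed
  # profile increases
  out <- numeric(n)
  for (j in seq_along(t)) out <- out + k[j] * ext[seq_len(n) + (r - t[j])]
  out
}

#' Detect significant local maxima in a DP gain profile
#'
#' A first-order Gaussian-derivative filter of scale `sigma_peak_px` is
#' applied to the profile (mirror boundary). A row is flagged when the
#' smoothed slope is positive `h` rows above it and negative `h` rows below
#' it, with `h = max(1, round(sigma_peak_px / 2))`, i.e. the smoothed
#' profile has a local maximum there. Runs of adjacent flagged rows are
#' collapsed to the single row with the maximum raw profile gain.
#'
#' @param profile Numeric vector of per-row accumulated gains.
#' @param sigma_peak_px Scale of the derivative filter, in pixels (>= 1).
#'
#' @return Sorted integer vector of peak rows (possibly empty).
#' @export
detect_peaks <- function(profile, sigma_peak_px) {
  stopifnot(is.numeric(profile), sigma_peak_px >= 1)
  n <- length(profile)
  h <- max(1L, as.integer(round(sigma_peak_px / 2)))
  if (n < 2L * h + 1L) return(integer(0))
  d <- gaussian_derivative(profile, sigma_peak_px)
  idx <- (h + 1L):(n - h)
  flag <- d[idx - h] > 0 & d[idx + h] < 0
  rows <- idx[flag]
  if (!length(rows)) return(integer(0))
  run <- cumsum(c(TRUE, diff(rows) != 1L))
  vapply(split(rows, run),
         function(r) r[which.max(profile[r])], integer(1), USE.NAMES = FALSE)
}

#' Detect all locally optimal lumen centerline candidates
#'
#' Full candidate stage: symmetry map, DP optimization, peak detection in
#' the gain profile and backtracking of one path per peak.
#'
#' @param img A [bmode_image].
#' @param params A `parameter_set` (provides `sigma_peak_mm` and, unless
#'   `cfg` is given, the diameter range of the symmetry filter).
#' @param cfg Optional [symmetry_config] override.
#'
#' @return A tibble with one row per candidate, sorted by decreasing gain:
#'   `candidate_id`, `end_row`, `gain`, `mean_row` and a list-column `rows`
#'   (the full path). The `dp_result` and the symmetry map are attached as
#'   attributes `dp` and `sym`.
#' @export
detect_candidates <- function(img, params = carotid_parameters(), cfg = NULL) {
  stopifnot(inherits(img, "bmode_image"), inherits(params, "parameter_set"))
  cfg <- cfg %||% symmetry_config_from(params)
  sym <- symmetry_map(img, cfg)
  dp <- dp_forward(sym)
  candidates_from_dp(dp, params$sigma_peak_mm / img$pixel_size_mm,
                     sym = sym)
}

# Internal: peak picking + backtracking given a dp_result.
candidates_from_dp <- function(dp, sigma_peak_px, sym = NULL) {
  peaks <- detect_peaks(dp$profile, sigma_peak_px)
  paths <- lapply(peaks, function(r) backtrack(dp, r))
  out <- tibble::tibble(
    candidate_id = seq_along(peaks),
    end_row = as.integer(peaks),
    gain = vapply(paths, `[[`, numeric(1), "gain"),
    mean_row = vapply(paths, function(p) mean(p$rows), numeric(1)),
    rows = lapply(paths, `[[`, "rows")
  )
  out <- out[order(-out$gain), , drop = FALSE]
  out$candidate_id <- seq_len(nrow(out))
  attr(out, "dp") <- dp
  if (!is.null(sym)) attr(out, "sym") <- sym
  out
}

#' Export candidates to JSON or CSV
#'
#' @param cands A [detect_candidates()] tibble.
#' @param path Output path; `.json` writes
#'   `{candidates: [{end_row, gain, rows}]}`, `.csv` writes one row per
#'   (candidate_id, column, row).
#' @return `path`, invisibly.
#' @export
write_candidates <- function(cands, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(
      list(candidates = lapply(seq_len(nrow(cands)), function(i) list(
        end_row = cands$end_row[i], gain = cands$gain[i],
        rows = cands$rows[[i]]))),
      path, auto_unbox = TRUE, digits = NA)
  } else if (ext == "csv") {
    long <- tidyr::unnest(
      dplyr::mutate(cands[, c("candidate_id", "rows")],
                    column = lapply(.data$rows, seq_along)),
      cols = c("rows", "column"))
    utils::write.csv(long[, c("candidate_id", "column", "rows")],
                     path, row.names = FALSE)
  } else stop("unsupported export format: .", ext, call. = FALSE)
  invisible(path)
}
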