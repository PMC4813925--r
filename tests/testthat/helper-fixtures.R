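# Fixtures are generated in code. Small images use a coarse pixel size so
# the mm-valued scales stay meaningful at test-sized grids.

# Horizontal dark band with a Gaussian depth profile on a bright background.
band_image <- function(H = 120, W = 140, y0 = 60, width_mm = 6,
                       bg = 0.8, depth = 0.7, pixel_mm = 0.3,
                       invert = FALSE) {
  sigma_px <- (width_mm / pixel_mm) / 2.355  # FWHM = band width
  prof <- depth * exp(-((seq_len(H) - y0)^2) / (2 * sigma_px^2))
  m <- matrix(bg, H, W) - prof
  if (invert) m <- bg - m
  bmode_image(pmin(pmax(m, 0), 1), pixel_mm)
}

# Hard-edged three-layer phantom: wall / lumen / wall.
three_band_image <- function(H = 200, W = 120, y0 = 100, lumen_mm = 6,
                             wall = 0.8, lumen = 0.1, pixel_mm = 0.3) {
  half <- (lumen_mm / pixel_mm) / 2
  y <- seq_len(H)
  m <- matrix(wall, H, W)
  m[abs(y - y0) <= half, ] <- lumen
  bmode_image(m, pixel_mm)
}

# Parameter set scaled for the coarse test pixel size.
test_params <- function(pixel_mm = 0.3) {
  derive_parameters(4.03, 15.8, pixel_size_mm = pixel_mm)
}

# Brute-force oracle for the DP recursion: enumerate every 8-connected
# left-to-right path and return the best gain per end row.
enumerate_profile <- function(m) {
  H <- nrow(m); N <- ncol(m)
  best <- rep(-Inf, H)
  walk <- function(row, col, gain) {
    if (col == N) {
      if (gain > best[row]) best[row] <<- gain
      return(invisible())
    }
    for (d in -1:1) {
      r2 <- row + d
      if (r2 >= 1 && r2 <= H) walk(r2, col + 1L, gain + m[r2, col + 1L])
    }
  }
  for (r in seq_len(H)) walk(r, 1L, m[r, 1L])
  best
}

# Small phantom bank shared by the heavier tests (memoized per session).
.bank_env <- new.env(parent = emptyenv())
shared_bank <- function(n = 20, seed = 42) {
  key <- paste0("bank_", n, "_", seed)
  if (is.null(.bank_env[[key]]))
    .bank_env[[key]] <- generate_dataset(n, seed = seed)
  .bank_env[[key]]
}
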