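# Internal frequency-domain machinery shared by the symmetry and contrast
# stages. All filtering is done on a mirror-padded copy of the image so that
# paths starting at the first/last columns are not corrupted by wrap-around.

# Reflect an arbitrary integer index into 1..n (half-sample symmetric mirror,
# period 2n). Works for pads larger than the image itself.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

# Mirror-pad a matrix to exactly (nr_out, nc_out), original content at
# offset (top, left).
mirror_pad <- function(m, nr_out, nc_out, top, left) {
  ri <- reflect_index(seq_len(nr_out) - top, nrow(m))
  ci <- reflect_index(seq_len(nc_out) - left, ncol(m))
  m[ri, ci, drop = FALSE]
}

# FFT bin frequencies in cycles per sample.
fft_freq <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n %/% 2, k, k - n) / n
}

# Choose an FFT-friendly padded size: at least dim + 2*pad, highly composite.
padded_size <- function(n, pad) {
  stats::nextn(n + 2L * pad, c(2L, 3L, 5L))
}

# Prepare a mirror-padded forward FFT of an image matrix, together with the
# frequency grids needed to build transfer functions.
# pad_px: minimum padding on each side, in pixels.
padded_fft <- function(m, pad_px) {
  nr <- nrow(m); nc <- ncol(m)
  P <- padded_size(nr, pad_px)
  Q <- padded_size(nc, pad_px)
  top <- (P - nr) %/% 2L
  left <- (Q - nc) %/% 2L
  mp <- mirror_pad(m, P, Q, top, left)
  list(
    F = stats::fft(mp),
    P = P, Q = Q,
    rows = top + seq_len(nr), cols = left + seq_len(nc),
    fy = fft_freq(P),  # vertical (row) frequency, cycles/px
    fx = fft_freq(Q)   # horizontal (column) frequency, cycles/px
  )
}

# Radial frequency magnitude grid (cycles/px) for a padded_fft object.
freq_radius <- function(pf) {
  sqrt(outer(pf$fy^2, pf$fx^2, "+"))
}

# Isotropic difference-of-Gaussians band-pass transfer with half-amplitude
# cut-offs at 1/d_max and 1/d_min (both in px here). DC is exactly zero.
bandpass_transfer <- function(pf, d_min_px, d_max_px) {
  f <- freq_radius(pf)
  s_hi <- (1 / d_min_px) / sqrt(2 * log(2))
  s_lo <- (1 / d_max_px) / sqrt(2 * log(2))
  B <- exp(-f^2 / (2 * s_hi^2)) - exp(-f^2 / (2 * s_lo^2))
  B[1L, 1L] <- 0
  B
}

# Gaussian low-pass transfer for blurring with standard deviation sigma_px.
gaussian_transfer <- function(pf, sigma_px) {
  f <- freq_radius(pf)
  exp(-2 * pi^2 * sigma_px^2 * f^2)
}

# Riesz transfer pair. Convention chosen so that a vertical cosine
# cos(2*pi*y/lambda) maps to sin(2*pi*y/lambda) in the vertical component.
# Nyquist lines (even dims) are zeroed to keep the transfer Hermitian, so
# that filtered outputs of real images are real.
riesz_transfer <- function(fy, fx) {
  r <- sqrt(outer(fy^2, fx^2, "+"))
  r[1L, 1L] <- 1  # avoid 0/0; transfer is 0 at DC anyway
  H1 <- -1i * outer(rep(1, length(fy)), fx) / r   # horizontal component
  H2 <- -1i * outer(fy, rep(1, length(fx))) / r   # vertical component
  H1[1L, 1L] <- 0; H2[1L, 1L] <- 0
  ny_r <- which(abs(abs(fy) - 0.5) < .Machine$double.eps^0.5)
  ny_c <- which(abs(abs(fx) - 0.5) < .Machine$double.eps^0.5)
  if (length(ny_r)) { H1[ny_r, ] <- 0; H2[ny_r, ] <- 0 }
  if (length(ny_c)) { H1[, ny_c] <- 0; H2[, ny_c] <- 0 }
  list(H1 = H1, H2 = H2)
}

# Cache of combined frequency-domain transfers. Detection runs over image
# banks reuse identical filter grids for every same-sized image; entries are
# keyed by padded dims + filter scales and the cache is kept small.
transfer_cache <- new.env(parent = emptyenv())

cached_transfers <- function(pf, d_min_px, d_max_px,
                             sigma_on_px = NULL, sigma_off_px = NULL) {
  key <- paste(pf$P, pf$Q,
               signif(c(d_min_px, d_max_px,
                        sigma_on_px %||% -1, sigma_off_px %||% -1), 10),
               collapse = "|")
  hit <- transfer_cache[[key]]
  if (!is.null(hit)) return(hit)
  B <- bandpass_transfer(pf, d_min_px, d_max_px)
  H <- riesz_transfer(pf$fy, pf$fx)
  val <- list(X1 = B + 1i * (B * H$H1))  # -> even + i * odd_horizontal
  if (!is.null(sigma_on_px)) {
    val$X2 <- B * H$H2 + 1i * gaussian_transfer(pf, sigma_on_px)
    val$X3 <- gaussian_transfer(pf, sigma_off_px)
  } else {
    val$X2v <- B * H$H2                  # -> odd_vertical only
  }
  keys <- ls(transfer_cache)
  if (length(keys) >= 6L) rm(list = keys[1L], envir = transfer_cache)
  assign(key, val, envir = transfer_cache)
  val
}

# Inverse FFT of F * X, cropped back to the original image window.
# When Y is supplied, X and Y are packed into one complex inverse transform
# (both must be Hermitian transfers), returning list(a, b).
ifft_crop <- function(pf, X, Y = NULL) {
  if (!is.null(Y)) return(ifft_crop_packed(pf, X + 1i * Y))
  z <- stats::fft(pf$F * X, inverse = TRUE) / (pf$P * pf$Q)
  Re(z)[pf$rows, pf$cols, drop = FALSE]
}

# As ifft_crop, but X already packs two Hermitian transfers as X_a + i*X_b.
ifft_crop_packed <- function(pf, X) {
  z <- stats::fft(pf$F * X, inverse = TRUE) / (pf$P * pf$Q)
  list(a = Re(z)[pf$rows, pf$cols, drop = FALSE],
       b = Im(z)[pf$rows, pf$cols, drop = FALSE])
}
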