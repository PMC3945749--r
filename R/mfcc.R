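# Mel-frequency cepstral coefficients: 13 static + velocity + acceleration.

LOG_FLOOR <- 1e-10

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filterbank
#'
#' `n_filters` triangular filters with centers equally spaced on the mel
#' scale (`mel(f) = 2595 log10(1 + f/700)`) covering 0 Hz to Nyquist, defined
#' over the one-sided DFT bins of an `n_fft`-point transform.
#'
#' @param n_filters Number of filters (default 32).
#' @param n_fft DFT length in samples.
#' @param rate Sampling rate in Hz.
#' @return A `n_filters x (n_fft/2 + 1)` weight matrix; each row is
#'   non-negative and unimodal.
#' @export
mel_filterbank <- function(n_filters = 32L, n_fft = 1200L, rate = 48000) {
  n_bins <- n_fft %/% 2L + 1L
  bin_hz <- (seq_len(n_bins) - 1L) * rate / n_fft
  edges_hz <- mel_to_hz(seq(0, hz_to_mel(rate / 2), length.out = n_filters + 2L))
  fb <- matrix(0, n_filters, n_bins)
  for (j in seq_len(n_filters)) {
    lo <- edges_hz[j]; ce <- edges_hz[j + 1L]; hi <- edges_hz[j + 2L]
    up <- (bin_hz - lo) / (ce - lo)
    down <- (hi - bin_hz) / (hi - ce)
    fb[j, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# Orthonormal DCT-II matrix (n x n): row k (0-based) has entries
# sqrt(2/n) cos(pi (i + 0.5) k / n), row 0 scaled by 1/sqrt(2).
dct_matrix <- function(n) {
  k <- seq_len(n) - 1L
  i <- seq_len(n) - 1L
  m <- sqrt(2 / n) * cos(pi * outer(k, i + 0.5) / n)
  m[1L, ] <- m[1L, ] / sqrt(2)
  m
}

# Velocity by 5-point linear regression (+-2 frames, edge replication);
# acceleration is the velocity of the velocity.
delta_features <- function(x, width = 2L) {
  n <- nrow(x)
  denom <- 2 * sum(seq_len(width)^2)
  out <- matrix(0, n, ncol(x))
  for (d in seq_len(width)) {
    plus <- x[pmin(seq_len(n) + d, n), , drop = FALSE]
    minus <- x[pmax(seq_len(n) - d, 1L), , drop = FALSE]
    out <- out + d * (plus - minus)
  }
  out / denom
}

frame_features <- function(values, kind, grid, rate,
                           excluded = integer(0)) {
  structure(values, kind = kind, grid = grid, rate = rate,
            excluded = excluded,
            class = c("frame_features", class(values)))
}

#' Feature kind of a frame-features matrix
#' @param ff A `frame_features` matrix.
#' @return The representation kind string.
#' @export
feature_kind <- function(ff) attr(ff, "kind")

#' Compute 39-dimensional MFCC frame features
#'
#' Per 25 ms Hamming frame (1200 samples at 48 kHz, hop 720, overlap 480):
#' one-sided power spectrum, 32 triangular mel-filter energies, logarithm
#' (floored at `1e-10`), orthonormal DCT, first `n_coef` cepstral
#' coefficients kept. Velocity and acceleration blocks are appended, giving
#' 13 + 13 + 13 = 39 dimensions by default.
#'
#' @param clip An [audio_clip] of at least one window length (25 ms).
#' @param n_filters Number of mel filters (default 32).
#' @param n_coef Number of cepstral coefficients kept (default 13).
#' @param include_c0 Keep the 0th (energy) coefficient as the first of the
#'   `n_coef` (default `TRUE`); when `FALSE`, coefficients 1..`n_coef` are
#'   used instead.
#' @param grid Analysis [frame_grid].
#' @return A `frame_features` matrix, `n_frames x (3 * n_coef)`, kind
#'   `"MFCC39"`.
#' @export
compute_mfcc <- function(clip, n_filters = 32L, n_coef = 13L,
                         include_c0 = TRUE, grid = frame_grid()) {
  stopifnot(inherits(clip, "audio_clip"))
  if (length(clip$samples) < grid$window_length) {
    abort("clip is shorter than one analysis window (25 ms)")
  }
  power <- stft_power(clip, grid)
  fb <- mel_filterbank(n_filters, grid$window_length, clip$rate)
  energies <- power %*% t(fb)                       # n_frames x n_filters
  log_e <- log(pmax(energies, LOG_FLOOR))
  cep <- log_e %*% t(dct_matrix(n_filters))         # n_frames x n_filters
  keep <- if (include_c0) seq_len(n_coef) else seq_len(n_coef) + 1L
  static <- cep[, keep, drop = FALSE]
  vel <- delta_features(static)
  acc <- delta_features(vel)
  out <- cbind(static, vel, acc)
  colnames(out) <- c(paste0("c", keep - 1L),
                     paste0("d", keep - 1L),
                     paste0("a", keep - 1L))
  frame_features(out, kind = "MFCC39", grid = grid, rate = clip$rate)
}
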