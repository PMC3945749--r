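# Perceptual linear prediction with RASTA filtering of band trajectories.

hz_to_bark <- function(f) 6 * asinh(f / 600)
bark_to_hz <- function(b) 600 * sinh(b / 6)

# Number of 1-Bark-spaced critical bands (centers at 0.5, 1.5, ... Bark)
# covering 0..Nyquist: 26 bands at a 48 kHz sampling rate.
n_bark_bands <- function(rate) {
  as.integer(floor(hz_to_bark(rate / 2) - 0.5) + 1L)
}

#' Critical-band (Bark) filterbank
#'
#' Trapezoidal critical-band masking curves on the Bark scale
#' (`bark(f) = 6 asinh(f/600)`): unit response within +-0.5 Bark of each
#' center, a steep low side (`10^(2.5 (d + 0.5))` down to -1.3 Bark) and a
#' shallower high side (`10^(-(d - 0.5))` up to +2.5 Bark). Centers are at
#' 0.5, 1.5, ... Bark, 1-Bark spacing, covering 0 to Nyquist.
#'
#' @param n_fft DFT length in samples.
#' @param rate Sampling rate in Hz.
#' @return A `n_bands x (n_fft/2 + 1)` weight matrix.
#' @export
bark_filterbank <- function(n_fft = 1200L, rate = 48000) {
  n_bins <- n_fft %/% 2L + 1L
  bin_bark <- hz_to_bark((seq_len(n_bins) - 1L) * rate / n_fft)
  centers <- seq(0.5, by = 1, length.out = n_bark_bands(rate))
  fb <- matrix(0, length(centers), n_bins)
  for (j in seq_along(centers)) {
    d <- bin_bark - centers[j]
    w <- numeric(n_bins)
    w[d >= -0.5 & d <= 0.5] <- 1
    lo <- d >= -1.3 & d < -0.5
    w[lo] <- 10^(2.5 * (d[lo] + 0.5))
    hi <- d > 0.5 & d <= 2.5
    w[hi] <- 10^(-(d[hi] - 0.5))
    fb[j, ] <- w
  }
  fb
}

# 40-phon equal-loudness weight at frequency f (Hz).
equal_loudness <- function(f) {
  fsq <- f^2
  (fsq / (fsq + 1.6e5))^2 * ((fsq + 1.44e6) / (fsq + 9.61e6))
}

#' Auditory spectrum of one power-spectrum frame
#'
#' The perceptual front end: critical-band integration at 1-Bark spacing,
#' equal-loudness pre-emphasis (40-phon approximation) at the band centers,
#' and cube-root (`exponent 0.33`) intensity-to-loudness compression.
#' Band energies are floored at `floor_value` after equal-loudness
#' weighting, so an all-zero frame yields every band at
#' `floor_value^0.33`.
#'
#' @param power_frame One-sided power-spectrum frame (length `n_fft/2 + 1`),
#'   non-negative.
#' @param rate Sampling rate in Hz.
#' @param n_fft DFT length the frame came from.
#' @param compress Compression exponent (default 0.33).
#' @param floor_value Energy floor (default `1e-10`).
#' @return Numeric vector of compressed band energies (26 bands at 48 kHz).
#' @export
plp_auditory_spectrum <- function(power_frame, rate = 48000, n_fft = 1200L,
                                  compress = 0.33, floor_value = LOG_FLOOR) {
  fb <- bark_filterbank(n_fft, rate)
  if (length(power_frame) != ncol(fb)) {
    abort(sprintf("power frame must have %d bins, got %d",
                  ncol(fb), length(power_frame)))
  }
  centers_hz <- bark_to_hz(seq(0.5, by = 1, length.out = nrow(fb)))
  bands <- as.numeric(fb %*% power_frame) * equal_loudness(centers_hz)
  pmax(bands, floor_value)^compress
}

#' RASTA filtering of log band-energy trajectories
#'
#' Applies the relative-spectral band-pass filter
#' `H(z) = 0.1 (2 + z^-1 - z^-3 - 2 z^-4) / (1 - 0.98 z^-1)` independently
#' to each sub-band trajectory (columns). The numerator coefficients sum to
#' zero, so the filter has an exact spectral zero at DC: constant or slowly
#' varying components of each trajectory — e.g. fixed channel coloration on a
#' log-spectral scale — are suppressed.
#'
#' @param trajectories Matrix of band trajectories, `n_frames x n_bands`
#'   (log-domain band energies), with at least 5 frames.
#' @return Filtered matrix of the same dimension; the first four frames (the
#'   warm-up) are zero.
#' @details The first `4` frames only prime the FIR delay line and produce
#'   zero output, so the recursive pole at `0.98` never sees the onset step
#'   of the trajectories; without this standard initialization a constant
#'   input would leave a long `0.98^t` startup transient instead of being
#'   nulled outright.
#' @export
rasta_filter <- function(trajectories) {
  x <- as.matrix(trajectories)
  n <- nrow(x)
  b <- 0.1 * c(2, 1, 0, -1, -2)
  nb <- length(b)
  if (n < nb) {
    abort(sprintf("RASTA filtering needs at least %d frames, got %d", nb, n))
  }
  y <- matrix(0, n, ncol(x))
  for (t in seq(nb, n)) {
    acc <- 0.98 * y[t - 1L, ]
    for (i in seq_len(nb)) {
      if (b[i] != 0) acc <- acc + b[i] * x[t - i + 1L, ]
    }
    y[t, ] <- acc
  }
  dimnames(y) <- dimnames(x)
  y
}

# Cepstral coefficients c_1..n_cep of an all-pole model 1/A(z) with
# predictor coefficients a (a_1..a_p) via the standard recursion.
lpc_to_cepstra <- function(a, n_cep) {
  p <- length(a)
  cc <- numeric(n_cep)
  a_ext <- c(a, numeric(max(0L, n_cep - p)))
  for (n in seq_len(n_cep)) {
    acc <- if (n <= p) a[n] else 0
    if (n > 1L) {
      k <- seq_len(n - 1L)
      acc <- acc + sum((k / n) * cc[k] * a_ext[n - k])
    }
    cc[n] <- acc
  }
  cc
}

# Autocorrelation r_0..r_p implied by sampled auditory spectrum values
# (treated as an even spectrum sampled at the band positions).
audspec_autocorr <- function(bands, p) {
  m <- length(bands)
  s <- c(bands, rev(bands[2:(m - 1L)]))
  r <- Re(fft(s, inverse = TRUE)) / length(s)
  r[seq_len(p + 1L)]
}

#' Compute RASTA-PLP cepstral coefficient frame features
#'
#' Per 25 ms Hamming frame (hop 720 samples, i.e. 10 ms overlap at 48 kHz):
#' one-sided power spectrum, critical-band integration on the Bark scale,
#' logarithm, RASTA band-pass filtering of each band trajectory across
#' frames, exponentiation back, equal-loudness weighting and cube-root
#' compression, an order-12 all-pole fit ([levinson_durbin]) to the
#' resulting auditory spectrum, and conversion to cepstral coefficients.
#' The default feature vector is `c_1..c_12` (12-dimensional).
#'
#' @param clip An [audio_clip] of at least 25 ms.
#' @param order All-pole model order (default 12).
#' @param n_cep Number of cepstral coefficients (default 12).
#' @param include_c0 Prepend `c_0 = log(gain)` as the first coefficient,
#'   replacing the last (keeps the dimension at `n_cep`). Default `FALSE`.
#' @param do_rasta Apply the RASTA filter (default `TRUE`); `FALSE` gives
#'   plain PLPCC.
#' @param grid Analysis [frame_grid].
#' @return A `frame_features` matrix, `n_frames x n_cep`, kind
#'   `"RASTA_PLPCC12"` (or `"PLPCC12"` without RASTA).
#' @export
compute_rasta_plpcc <- function(clip, order = 12L, n_cep = 12L,
                                include_c0 = FALSE, do_rasta = TRUE,
                                grid = frame_grid()) {
  stopifnot(inherits(clip, "audio_clip"))
  if (length(clip$samples) < grid$window_length) {
    abort("clip is shorter than one analysis window (25 ms)")
  }
  power <- stft_power(clip, grid)
  fb <- bark_filterbank(grid$window_length, clip$rate)
  bands <- power %*% t(fb)                           # n_frames x n_bands
  bands <- pmax(bands, LOG_FLOOR)
  if (do_rasta) {
    bands <- exp(rasta_filter(log(bands)))
  }
  centers_hz <- bark_to_hz(seq(0.5, by = 1, length.out = nrow(fb)))
  bands <- sweep(bands, 2L, equal_loudness(centers_hz), `*`)
  bands <- pmax(bands, LOG_FLOOR)^0.33

  out <- matrix(NA_real_, nrow(bands), n_cep)
  for (i in seq_len(nrow(bands))) {
    r <- audspec_autocorr(bands[i, ], order)
    model <- levinson_durbin(r, order)
    cc <- lpc_to_cepstra(model$coefficients, n_cep)
    if (include_c0) {
      out[i, ] <- c(log(max(model$gain, LOG_FLOOR)), cc[seq_len(n_cep - 1L)])
    } else {
      out[i, ] <- cc
    }
  }
  colnames(out) <- if (include_c0) {
    paste0("c", 0:(n_cep - 1L))
  } else {
    paste0("c", seq_len(n_cep))
  }
  frame_features(out, kind = if (do_rasta) "RASTA_PLPCC12" else "PLPCC12",
                 grid = grid, rate = clip$rate)
}
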