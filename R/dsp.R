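# Short-time analysis front end: framing, windowing, power spectra.

window_vector <- function(n, kind = c("hamming", "hann")) {
  kind <- match.arg(kind)
  i <- seq_len(n) - 1L
  switch(kind,
    hamming = 0.54 - 0.46 * cos(2 * pi * i / (n - 1)),
    hann    = 0.5 - 0.5 * cos(2 * pi * i / (n - 1))
  )
}

#' Define a short-time analysis frame grid
#'
#' @param window_length Window length in samples.
#' @param hop Hop between consecutive frame starts, in samples
#'   (`window_length - overlap`).
#' @param window_kind `"hamming"` or `"hann"`.
#' @return A `frame_grid` object.
#' @details The default grid (1200-sample Hamming window, hop 720, i.e.
#'   25 ms frames with 480-sample overlap at 48 kHz) is the one used for all
#'   feature extraction; the spectrogram uses a 256-sample Hann window with
#'   50 percent overlap.
#' @export
frame_grid <- function(window_length = 1200L, hop = 720L,
                       window_kind = c("hamming", "hann")) {
  window_kind <- match.arg(window_kind)
  window_length <- as.integer(window_length)
  hop <- as.integer(hop)
  if (hop <= 0L || hop > window_length) {
    abort("hop must satisfy 0 < hop <= window_length")
  }
  structure(list(window_length = window_length, hop = hop,
                 window_kind = window_kind),
            class = "frame_grid")
}

#' Number of full frames a signal yields under a grid
#'
#' Tail samples that do not fill a complete window are dropped, never padded:
#' `floor((n - window_length) / hop) + 1`.
#'
#' @param n Signal length in samples.
#' @param grid A [frame_grid].
#' @return Integer frame count (0 if the signal is shorter than one window).
#' @export
count_frames <- function(n, grid) {
  if (n < grid$window_length) return(0L)
  as.integer((n - grid$window_length) %/% grid$hop + 1L)
}

#' Slice a clip into overlapping windowed frames
#'
#' @param clip An [audio_clip] or numeric vector.
#' @param grid A [frame_grid].
#' @return A numeric matrix of dimension `n_frames x window_length`; each row
#'   is one frame multiplied by the grid's window function.
#' @export
frame_signal <- function(clip, grid = frame_grid()) {
  x <- if (inherits(clip, "audio_clip")) clip$samples else as.numeric(clip)
  n <- length(x)
  if (n < grid$window_length) {
    abort(sprintf("clip (%d samples) is shorter than one window (%d samples)",
                  n, grid$window_length))
  }
  nf <- count_frames(n, grid)
  w <- window_vector(grid$window_length, grid$window_kind)
  starts <- (seq_len(nf) - 1L) * grid$hop
  idx <- outer(starts, seq_len(grid$window_length), `+`)
  frames <- matrix(x[idx], nrow = nf)
  sweep(frames, 2L, w, `*`)
}

# One-sided short-time power spectrum: rows are frames, columns DFT bins
# 0..window_length/2. DFT length equals the window length (no zero padding).
stft_power <- function(clip, grid = frame_grid()) {
  frames <- frame_signal(clip, grid)
  nb <- grid$window_length %/% 2L + 1L
  spec <- mvfft(t(frames))[seq_len(nb), , drop = FALSE]
  t(Mod(spec)^2)
}

#' Power spectrogram of an audio clip
#'
#' Short-time power spectrum on the standard display grid: Hann window of
#' 256 sampling points with 50 percent overlap, one-sided squared-magnitude
#' DFT. At 48 kHz this gives a bin width of 187.5 Hz.
#'
#' @param clip An [audio_clip].
#' @param window_length Window length in samples (default 256).
#' @param overlap Fractional overlap between consecutive windows (default 0.5).
#' @param window_kind Window function (default `"hann"`).
#' @return A `mimic_spectrogram` object: list with `power`
#'   (`n_frames x n_bins` matrix), `bin_hz`, `frame_s`, and the grid.
#' @export
spectrogram <- function(clip, window_length = 256L, overlap = 0.5,
                        window_kind = c("hann", "hamming")) {
  window_kind <- match.arg(window_kind)
  hop <- as.integer(round(window_length * (1 - overlap)))
  grid <- frame_grid(window_length, hop, window_kind)
  rate <- if (inherits(clip, "audio_clip")) clip$rate else 48000
  power <- stft_power(clip, grid)
  structure(
    list(power = power, bin_hz = rate / window_length,
         frame_s = hop / rate, grid = grid, rate = rate,
         id = if (inherits(clip, "audio_clip")) clip$id else NA_character_),
    class = "mimic_spectrogram"
  )
}

#' Tidy a spectrogram into long form
#'
#' @param x A `mimic_spectrogram`.
#' @param ... Ignored.
#' @return A tibble with columns `time`, `frequency`, `power`.
#' @export
tidy.mimic_spectrogram <- function(x, ...) {
  nf <- nrow(x$power)
  nb <- ncol(x$power)
  tibble(
    time = rep((seq_len(nf) - 1L) * x$frame_s, times = nb),
    frequency = rep((seq_len(nb) - 1L) * x$bin_hz, each = nf),
    power = as.vector(x$power)
  )
}

#' Spectrogram heat map
#'
#' @param object A `mimic_spectrogram`.
#' @param db_floor Dynamic-range floor in dB relative to the peak.
#' @param ... Ignored.
#' @return A ggplot raster of log-power over time and frequency.
#' @export
autoplot.mimic_spectrogram <- function(object, db_floor = -80, ...) {
  df <- tidy.mimic_spectrogram(object)
  ref <- max(df$power, 1e-300)
  df$db <- pmax(10 * log10(pmax(df$power, 1e-300) / ref), db_floor)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$frequency,
                                   fill = .data$db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "dB") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)", title = object$id) +
    ggplot2::theme_minimal()
}
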