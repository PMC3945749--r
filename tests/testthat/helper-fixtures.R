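# Shared fixtures: tiny clips, oracle implementations, random model draws.

# Pure tone clip; frequency 1000 Hz is an exact multiple of the hop rate
# (1000 * 720 / 48000 = 15), so all analysis frames see the same phase.
tone_clip <- function(freq = 1000, dur = 0.5, rate = 48000, amp = 0.9,
                      noise_sd = 0, seed = 1, id = "tone") {
  set.seed(seed)
  t <- (seq_len(round(dur * rate)) - 1) / rate
  x <- amp * sin(2 * pi * freq * t)
  if (noise_sd > 0) x <- x + rnorm(length(x)) * noise_sd
  audio_clip(x / max(abs(x)) * amp, rate = rate, id = id)
}

noise_clip <- function(dur = 1, rate = 48000, amp = 0.5, seed = 1,
                       id = "noise") {
  set.seed(seed)
  x <- rnorm(round(dur * rate))
  audio_clip(x / max(abs(x)) * amp, rate = rate, id = id)
}

# Brute-force O(N^2) DFT oracle.
direct_dft <- function(x) {
  n <- length(x)
  k <- seq_len(n) - 1
  vapply(k, function(kk) {
    sum(x * exp(-2i * pi * kk * (seq_len(n) - 1) / n))
  }, complex(1))
}

# Direct Yule-Walker solve oracle for the predictor coefficients.
yule_walker_direct <- function(r, p) {
  R <- toeplitz(r[seq_len(p)])
  as.numeric(solve(R, r[2:(p + 1)]))
}

# Random stable LP model via random reflection coefficients and the step-up
# recursion (independent of levinson_durbin).
random_stable_lp <- function(p, kmax = 0.95) {
  k <- runif(p, -kmax, kmax)
  a <- numeric(0)  # error-filter coefficients, grown order by order
  for (m in seq_len(p)) {
    a <- if (m == 1) k[1] else c(a + k[m] * rev(a), k[m])
  }
  structure(list(order = p, coefficients = -a, gain = 1, reflection = k),
            class = "lp_model")
}

# Small library under the reference study condition.
small_library <- function(seed = 11, pert = perturbation_spec(),
                          mimic_mode = "perturbed",
                          counts = c(21, 21, 20, 20), ...) {
  build_library(library_spec(counts[1], counts[2], counts[3], counts[4],
                             perturbation = pert, seed = seed,
                             mimic_mode = mimic_mode, ...))
}

# Fraction of total spectral power inside [lo, hi] Hz.
band_power_fraction <- function(clip, lo, hi) {
  p <- Mod(fft(clip$samples))^2
  n <- length(p)
  f <- (seq_len(n) - 1) * clip$rate / n
  f <- pmin(f, clip$rate - f)
  sum(p[f >= lo & f <= hi]) / sum(p)
}
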