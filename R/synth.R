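# Seeded synthesis of bird-like calls in five spectral-signature classes.

CALL_CLASSES <- c("FM", "BB", "HR", "Trill", "NB-Trill")
FREQ_MIN <- 500
FREQ_MAX <- 8000

#' Specify a synthetic call
#'
#' Parameter bundle for one synthetic call, covering the five broad
#' spectral-signature classes seen in bird vocalizations: frequency-modulated
#' sweeps (`FM`), broadband noise bursts (`BB`), harmonic stacks (`HR`),
#' repeated trills (`Trill`) and narrowband trills (`NB-Trill`). All
#' frequencies must lie in the 500 Hz - 8 kHz band typical of bird calls.
#'
#' @param call_class One of `"FM"`, `"BB"`, `"HR"`, `"Trill"`, `"NB-Trill"`.
#' @param duration Call duration in seconds.
#' @param f_start,f_end FM sweep endpoints in Hz (FM and Trill elements).
#' @param f0 Harmonic fundamental (HR) or carrier/center frequency
#'   (NB-Trill, BB), in Hz.
#' @param n_harmonics Number of harmonics in a harmonic stack.
#' @param trill_rate Element repetition rate, elements per second
#'   (Trill, NB-Trill modulation rate, BB burst rate).
#' @param element_duration Duration of one trill element or noise burst,
#'   seconds.
#' @param bandwidth Noise bandwidth (BB) or twice the peak frequency
#'   deviation (NB-Trill), in Hz.
#' @param amplitude Linear peak amplitude in (0, 1]; every clip is
#'   peak-normalized to this value.
#' @return A `call_spec` object.
#' @export
call_spec <- function(call_class, duration = 0.5,
                      f_start = 1000, f_end = 4000,
                      f0 = 1000, n_harmonics = 4L,
                      trill_rate = 12, element_duration = 0.05,
                      bandwidth = 2000, amplitude = 0.9) {
  if (!call_class %in% CALL_CLASSES) {
    abort(paste0("call_class must be one of ", paste(CALL_CLASSES, collapse = ", ")))
  }
  if (duration <= 0) abort("duration must be positive")
  if (n_harmonics < 1L) abort("n_harmonics must be >= 1")
  if (amplitude <= 0 || amplitude > 1) abort("amplitude must be in (0, 1]")
  used <- switch(call_class,
    FM = c(f_start, f_end),
    Trill = c(f_start, f_end),
    HR = c(f0, f0 * n_harmonics),
    `NB-Trill` = c(f0 - bandwidth / 2, f0 + bandwidth / 2),
    BB = c(f0 - bandwidth / 2, f0 + bandwidth / 2)
  )
  if (any(used < FREQ_MIN - 1e-6) || any(used > FREQ_MAX + 1e-6)) {
    abort(sprintf("frequencies must lie in [%g, %g] Hz (got %g-%g)",
                  FREQ_MIN, FREQ_MAX, min(used), max(used)))
  }
  structure(
    list(call_class = call_class, duration = duration,
         f_start = f_start, f_end = f_end, f0 = f0,
         n_harmonics = as.integer(n_harmonics), trill_rate = trill_rate,
         element_duration = element_duration, bandwidth = bandwidth,
         amplitude = amplitude),
    class = "call_spec"
  )
}

# Frequency band a spec's energy is expected to occupy.
spec_band <- function(spec) {
  switch(spec$call_class,
    FM = range(spec$f_start, spec$f_end),
    Trill = range(spec$f_start, spec$f_end),
    HR = c(spec$f0, spec$f0 * spec$n_harmonics),
    `NB-Trill` = c(spec$f0 - spec$bandwidth / 2, spec$f0 + spec$bandwidth / 2),
    BB = c(spec$f0 - spec$bandwidth / 2, spec$f0 + spec$bandwidth / 2)
  )
}

#' Specify the mimic perturbation model
#'
#' How a synthetic mimic deviates from its putative model call: additive
#' white noise at a target signal-to-noise ratio, a multiplicative frequency
#' offset, a duration scaling, and optional slow amplitude modulation. This
#' stands in for the natural imperfection of mimicry; the defaults (20 dB
#' SNR, 2 percent frequency jitter) define the package's reference study
#' condition.
#'
#' @param snr_db Signal-to-noise ratio of the added white noise in dB;
#'   `Inf` adds no noise.
#' @param freq_jitter_pct Maximum multiplicative frequency offset in percent;
#'   each mimic draws its offset uniformly from
#'   `[-freq_jitter_pct, +freq_jitter_pct]`.
#' @param time_stretch Duration scale factor (> 0).
#' @param amp_mod_depth Depth of slow (2 Hz) amplitude-envelope modulation,
#'   in \[0, 1\].
#' @return A `perturbation_spec` object.
#' @export
perturbation_spec <- function(snr_db = 20, freq_jitter_pct = 2,
                              time_stretch = 1, amp_mod_depth = 0) {
  if (is.na(snr_db)) abort("snr_db must be finite or Inf")
  if (time_stretch <= 0) abort("time_stretch must be positive")
  if (amp_mod_depth < 0 || amp_mod_depth > 1) {
    abort("amp_mod_depth must be in [0, 1]")
  }
  structure(
    list(snr_db = snr_db, freq_jitter_pct = freq_jitter_pct,
         time_stretch = time_stretch, amp_mod_depth = amp_mod_depth),
    class = "perturbation_spec"
  )
}

#' The identity perturbation (a perfect mimic)
#' @return A [perturbation_spec] that copies the model exactly.
#' @export
identity_perturbation <- function() {
  perturbation_spec(snr_db = Inf, freq_jitter_pct = 0,
                    time_stretch = 1, amp_mod_depth = 0)
}

# Raised-cosine fade at both edges, length `fade_s` seconds each.
apply_fades <- function(x, rate, fade_s = 0.005) {
  n <- length(x)
  nf <- min(round(fade_s * rate), n %/% 2)
  if (nf > 0) {
    ramp <- 0.5 - 0.5 * cos(pi * (seq_len(nf) - 0.5) / nf)
    x[seq_len(nf)] <- x[seq_len(nf)] * ramp
    x[(n - nf + 1L):n] <- x[(n - nf + 1L):n] * rev(ramp)
  }
  x
}

# Evaluate RNG-dependent code under a fixed seed, restoring the caller's
# RNG state afterwards.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Fixed-length band-limited white noise via DFT masking: exact confinement
# to [f_lo, f_hi].
bandlimited_noise <- function(n, rate, f_lo, f_hi) {
  x <- rnorm(n)
  spec <- fft(x)
  freqs <- (seq_len(n) - 1L) * rate / n
  freqs <- pmin(freqs, rate - freqs)  # fold to [0, Nyquist]
  mask <- freqs >= f_lo & freqs <= f_hi
  Re(fft(spec * mask, inverse = TRUE)) / n
}

synth_core <- function(spec, rate) {
  n <- round(spec$duration * rate)
  t <- (seq_len(n) - 1L) / rate
  # smooth attack-release amplitude envelope common to natural calls; this
  # slow modulation also keeps the spectral profile visible to features that
  # suppress stationary components (RASTA)
  env <- sin(pi * (seq_len(n) - 0.5) / n)^0.7
  env * switch(spec$call_class,
    FM = {
      # linear chirp f_start -> f_end
      k <- (spec$f_end - spec$f_start) / spec$duration
      sin(2 * pi * (spec$f_start * t + k * t^2 / 2))
    },
    HR = {
      phases <- runif(spec$n_harmonics, 0, 2 * pi)
      amps <- 1 / seq_len(spec$n_harmonics)
      rowSums(vapply(seq_len(spec$n_harmonics), function(k) {
        amps[k] * sin(2 * pi * k * spec$f0 * t + phases[k])
      }, numeric(n)))
    },
    `NB-Trill` = {
      dev <- min(spec$bandwidth / 2, 200)
      fm <- spec$trill_rate
      # instantaneous frequency f0 + dev * sin(2 pi fm t)
      sin(2 * pi * spec$f0 * t - dev / fm * cos(2 * pi * fm * t))
    },
    Trill = {
      ne <- max(1L, floor(spec$duration * spec$trill_rate))
      n_el <- round(spec$element_duration * rate)
      n_gap <- round(0.010 * rate)  # 10 ms silent gaps
      te <- (seq_len(n_el) - 1L) / rate
      k <- (spec$f_end - spec$f_start) / spec$element_duration
      el <- sin(2 * pi * (spec$f_start * te + k * te^2 / 2))
      el <- apply_fades(el, rate, 0.002)
      out <- rep(c(el, numeric(n_gap)), ne)
      length(out) <- n  # truncate or zero-pad to the exact duration
      out[is.na(out)] <- 0
      out
    },
    BB = {
      band <- spec_band(spec)
      noise <- bandlimited_noise(n, rate, band[1], band[2])
      if (spec$trill_rate > 0) {
        # burst train: element_duration on, 10 ms off
        n_el <- round(spec$element_duration * rate)
        n_gap <- round(0.010 * rate)
        gate <- rep(c(rep(1, n_el), rep(0, n_gap)),
                    length.out = n)
        # soften gate edges (2 ms raised cosine) to limit spectral smear
        env <- stats::filter(gate, rep(1 / round(0.002 * rate),
                                       round(0.002 * rate)), sides = 2)
        env[is.na(env)] <- gate[is.na(env)]
        noise * as.numeric(env)
      } else {
        noise
      }
    }
  )
}

#' Synthesize one call from a specification
#'
#' Deterministic for a fixed seed. The waveform is faded in and out with 5 ms
#' raised-cosine ramps and peak-normalized to the spec's amplitude; at least
#' 90 percent of its spectral power falls inside the spec's frequency band.
#'
#' @param spec A [call_spec].
#' @param rate Sampling rate in Hz (default 48000).
#' @param seed Integer seed for the stochastic components (harmonic phases,
#'   noise realizations).
#' @param id,species,role,model_id Metadata for the returned clip.
#' @return An [audio_clip] of exactly `round(duration * rate)` samples.
#' @export
synthesize_call <- function(spec, rate = 48000, seed = 1L, id = "call",
                            species = "synthetic", role = "model",
                            model_id = NA_character_) {
  stopifnot(inherits(spec, "call_spec"))
  band <- spec_band(spec)
  if (band[2] >= rate / 2) {
    abort(sprintf("maximum frequency %g Hz is not below Nyquist (%g Hz)",
                  band[2], rate / 2))
  }
  x <- with_local_seed(seed, synth_core(spec, rate))
  x <- apply_fades(x, rate, 0.005)
  peak <- max(abs(x))
  if (peak > 0) x <- x * (spec$amplitude / peak)
  audio_clip(x, rate = rate, id = id, species = species, role = role,
             call_class = spec$call_class, model_id = model_id,
             spec = spec, synth_seed = seed)
}

#' Derive a synthetic mimic from a model call
#'
#' Applies the perturbation model: frequency jitter and time stretch are
#' realized by re-synthesizing the model's [call_spec] with scaled
#' frequencies and duration (so the two act independently), then white noise
#' is added at the target SNR and an optional slow amplitude modulation is
#' applied. The identity perturbation returns a bit-identical copy of the
#' model's samples.
#'
#' For clips that carry no `call_spec` (e.g. loaded recordings), time stretch
#' falls back to interpolation resampling and nonzero frequency jitter is an
#' error.
#'
#' @param model An [audio_clip] with role `"model"`.
#' @param pert A [perturbation_spec].
#' @param seed Integer seed.
#' @param id Identifier for the mimic clip.
#' @param species Species label of the mimic (default `"mimic-sp"`).
#' @return An [audio_clip] with role `"mimic"` and `model_id = model$id`. The
#'   attribute `"gain_applied"` records the common rescaling factor applied
#'   after noise injection (1 unless the noisy peak exceeded 1), so the
#'   injected noise can be measured exactly as `mimic - gain * clean`.
#' @export
make_mimic <- function(model, pert = perturbation_spec(), seed = 1L,
                       id = paste0(model$id, "-mimic"), species = "mimic-sp") {
  stopifnot(inherits(model, "audio_clip"), inherits(pert, "perturbation_spec"))
  if (length(model$samples) == 0L) abort("model clip is empty")

  out <- with_local_seed(seed, {
    jit <- if (pert$freq_jitter_pct > 0) {
      runif(1, -pert$freq_jitter_pct, pert$freq_jitter_pct) / 100
    } else 0

    clean <- if (jit == 0 && pert$time_stretch == 1) {
      model$samples
    } else if (!is.null(model$spec)) {
      sp <- model$spec
      scale_f <- 1 + jit
      sp$f_start <- sp$f_start * scale_f
      sp$f_end <- sp$f_end * scale_f
      sp$f0 <- sp$f0 * scale_f
      sp$bandwidth <- sp$bandwidth * scale_f
      sp$duration <- sp$duration * pert$time_stretch
      # rescale back into the legal band if the jitter pushed an edge out;
      # a single factor suffices because jitter scales both edges equally
      b <- spec_band(sp)
      fac <- 1
      if (b[2] > FREQ_MAX) fac <- FREQ_MAX / b[2]
      else if (b[1] < FREQ_MIN) fac <- FREQ_MIN / b[1]
      if (fac != 1) {
        sp$f_start <- sp$f_start * fac
        sp$f_end <- sp$f_end * fac
        sp$f0 <- sp$f0 * fac
        sp$bandwidth <- sp$bandwidth * fac
      }
      sp <- do.call(call_spec, unclass(sp))
      seed2 <- if (is.null(model$synth_seed)) seed else model$synth_seed
      synth_core_seeded <- with_local_seed(seed2, synth_core(sp, model$rate))
      x <- apply_fades(synth_core_seeded, model$rate, 0.005)
      peak <- max(abs(x))
      if (peak > 0) x <- x * (sp$amplitude / peak)
      x
    } else {
      if (jit != 0) {
        abort("frequency jitter requires a clip synthesized from a call_spec")
      }
      n_out <- round(length(model$samples) * pert$time_stretch)
      approx(seq_along(model$samples),
             model$samples,
             xout = seq(1, length(model$samples), length.out = n_out))$y
    }

    if (pert$amp_mod_depth > 0) {
      t <- (seq_along(clean) - 1L) / model$rate
      env <- 1 - pert$amp_mod_depth * (0.5 + 0.5 * sin(2 * pi * 2 * t))
      clean <- clean * env
    }

    if (is.finite(pert$snr_db)) {
      p_sig <- mean(clean^2)
      noise <- rnorm(length(clean))
      noise <- noise * sqrt(p_sig / 10^(pert$snr_db / 10) / mean(noise^2))
      noisy <- clean + noise
    } else {
      noisy <- clean
    }
    list(clean = clean, noisy = noisy)
  })

  gain <- 1
  peak <- max(abs(out$noisy))
  if (peak > 1) gain <- 0.99 / peak
  clip <- audio_clip(out$noisy * gain, rate = model$rate, id = id,
                     species = species, role = "mimic",
                     call_class = model$call_class, model_id = model$id,
                     spec = NULL, synth_seed = seed)
  attr(clip, "gain_applied") <- gain
  attr(clip, "clean") <- out$clean
  clip
}
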