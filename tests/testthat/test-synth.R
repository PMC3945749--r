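test_that("synthesized calls have the requested length and class structure", {
  for (cc in c("FM", "BB", "HR", "Trill", "NB-Trill")) {
    sp <- switch(cc,
      FM = call_spec("FM", 0.5, f_start = 1000, f_end = 4000),
      BB = call_spec("BB", 0.5, f0 = 3000, bandwidth = 2000),
      HR = call_spec("HR", 0.5, f0 = 900, n_harmonics = 5),
      Trill = call_spec("Trill", 0.5, f_start = 2000, f_end = 3500),
      `NB-Trill` = call_spec("NB-Trill", 0.5, f0 = 3000, bandwidth = 300))
    cl <- synthesize_call(sp, seed = 7, id = cc)
    expect_length(cl$samples, 24000)
    expect_equal(max(abs(cl$samples)), 0.9, tolerance = 1e-12)
    expect_identical(cl$call_class, cc)
  }
})

test_that("FM sweep spectrogram peak frequency is non-decreasing", {
  cl <- synthesize_call(call_spec("FM", 0.5, f_start = 500, f_end = 8000),
                        seed = 3)
  peaks <- apply(spectrogram(cl)$power, 1, which.max)
  expect_true(all(diff(peaks) >= 0))
})

test_that("harmonic stacks place spectral peaks at integer multiples of f0", {
  cl <- synthesize_call(call_spec("HR", 0.5, f0 = 1000, n_harmonics = 5),
                        seed = 2)
  # DFT peak-picking oracle: strongest bin within each 500 Hz-wide window
  # around the expected harmonic
  p <- Mod(direct_dft(cl$samples[1:4800]))^2  # 0.1 s slice, 10 Hz bins
  f <- (seq_along(p) - 1) * cl$rate / length(p)
  for (h in 1:5) {
    win <- which(f >= h * 1000 - 250 & f <= h * 1000 + 250)
    peak_f <- f[win[which.max(p[win])]]
    expect_lt(abs(peak_f - h * 1000), 10 + 1e-9)
  }
})

test_that("each class confines at least 90% of power to its stated band", {
  specs <- list(
    call_spec("FM", 0.4, f_start = 1000, f_end = 4000),
    call_spec("BB", 0.4, f0 = 3000, bandwidth = 2000),
    call_spec("HR", 0.4, f0 = 900, n_harmonics = 5),
    call_spec("Trill", 0.4, f_start = 2000, f_end = 3500),
    call_spec("NB-Trill", 0.4, f0 = 3000, bandwidth = 300))
  for (sp in specs) {
    cl <- synthesize_call(sp, seed = 7)
    b <- mimicmatch:::spec_band(sp)
    expect_gt(band_power_fraction(cl, b[1] - 100, b[2] + 100), 0.9)
  }
})

test_that("frequencies above Nyquist are rejected", {
  sp <- call_spec("HR", 0.3, f0 = 1800, n_harmonics = 4)
  expect_error(synthesize_call(sp, rate = 8000), "Nyquist")
  expect_error(call_spec("FM", 0.3, f_start = 400, f_end = 4000), "frequencies")
  expect_error(call_spec("FM", 0.3, f_start = 1000, f_end = 9000), "frequencies")
})

test_that("synthesis is deterministic for a fixed seed", {
  sp <- call_spec("BB", 0.3, f0 = 3000, bandwidth = 2000)
  a <- synthesize_call(sp, seed = 42)
  b <- synthesize_call(sp, seed = 42)
  c <- synthesize_call(sp, seed = 43)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples, c$samples))
})

test_that("identity perturbation copies the model exactly", {
  mod <- synthesize_call(call_spec("HR", 0.5, f0 = 1200, n_harmonics = 4),
                         seed = 5, id = "m1")
  mim <- make_mimic(mod, identity_perturbation(), seed = 9)
  expect_identical(mim$samples, mod$samples)
  expect_identical(mim$role, "mimic")
  expect_identical(mim$model_id, "m1")
})

test_that("injected noise realizes the requested SNR within 0.5 dB", {
  mod <- synthesize_call(call_spec("HR", 0.5, f0 = 1200, n_harmonics = 4),
                         seed = 5, id = "m1")
  for (snr in c(30, 20, 10)) {
    mim <- make_mimic(mod, perturbation_spec(snr_db = snr, freq_jitter_pct = 0),
                      seed = 9)
    g <- attr(mim, "gain_applied")
    noise <- mim$samples - g * mod$samples
    measured <- 10 * log10(mean((g * mod$samples)^2) / mean(noise^2))
    expect_lt(abs(measured - snr), 0.5)
  }
})

test_that("time stretch scales the duration", {
  mod <- synthesize_call(call_spec("FM", 0.5, f_start = 1000, f_end = 3000),
                         seed = 5, id = "m1")
  mim <- make_mimic(mod, perturbation_spec(snr_db = Inf, freq_jitter_pct = 0,
                                           time_stretch = 1.1), seed = 2)
  expect_lte(abs(length(mim$samples) - 26400), 1)
  expect_error(perturbation_spec(time_stretch = 0), "positive")
})

test_that("frequency jitter shifts the spectral peak proportionally", {
  # single-harmonic stack = clean tone whose peak tracks the jitter exactly
  mod <- synthesize_call(call_spec("HR", 0.5, f0 = 3000, n_harmonics = 1L),
                         seed = 5, id = "m1")
  mim <- make_mimic(mod, perturbation_spec(snr_db = Inf, freq_jitter_pct = 5),
                    seed = 31)
  peak_of <- function(cl) {
    p <- Mod(fft(cl$samples))^2
    n <- length(p)
    (which.max(p[1:(n %/% 2)]) - 1) * cl$rate / n
  }
  shift <- peak_of(mim) / peak_of(mod) - 1
  expect_lt(abs(shift), 0.05 + 0.005)
  expect_gt(abs(shift), 0.001)  # the drawn jitter is almost surely nonzero
})

test_that("mimic-model feature distance grows as SNR falls", {
  mod <- synthesize_call(call_spec("HR", 0.3, f0 = 1200, n_harmonics = 4),
                         seed = 5, id = "m1")
  fo <- pool_frames(compute_rasta_plpcc(mod))
  snrs <- c(Inf, 30, 20, 10, 0)
  mean_dist <- vapply(snrs, function(s) {
    mean(vapply(1:20, function(sd) {
      mm <- make_mimic(mod, perturbation_spec(snr_db = s, freq_jitter_pct = 0),
                       seed = sd)
      lp_distance(pool_frames(compute_rasta_plpcc(mm)), fo, 2)
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cor(seq_along(snrs), mean_dist, method = "spearman"), 0)
})

test_that("build_library reproduces role counts and is deterministic", {
  lib <- small_library(seed = 4, counts = c(21, 21, 20, 20))
  expect_length(lib$clips, 82)
  rc <- role_counts(lib)
  expect_identical(rc$n[match(c("mimic", "model", "other", "conspecific"),
                              rc$role)], c(21L, 21L, 20L, 20L))
  expect_setequal(unique(lib$manifest$call_class),
                  c("FM", "BB", "HR", "Trill", "NB-Trill"))
  mims <- lib$manifest[lib$manifest$role == "mimic", ]
  expect_true(all(mims$model_id %in% lib$manifest$id))

  lib2 <- small_library(seed = 4, counts = c(21, 21, 20, 20))
  expect_identical(lapply(lib$clips, `[[`, "samples"),
                   lapply(lib2$clips, `[[`, "samples"))
})

test_that("the 357-file composition and degenerate libraries work", {
  # 63 mimics + 84 heterospecific (63 models + 21 other) + 210 conspecific
  spec <- library_spec(63, 63, 21, 210, seed = 1)
  expect_identical(spec$n_mimic + spec$n_model + spec$n_other +
                     spec$n_conspecific, 357L)
  empty <- build_library(library_spec(0, 0, 0, 0, seed = 1))
  expect_length(empty$clips, 0)
  expect_error(library_spec(5, 0, 3, 3), "model")
})

test_that("library WAV round trip preserves samples to quantization accuracy", {
  dir <- withr::local_tempdir()
  lib <- build_library(library_spec(2, 2, 2, 2, seed = 3,
                                    duration_range = c(0.1, 0.2)))
  man <- write_library(lib, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  lib2 <- read_library(file.path(dir, "manifest.csv"))
  expect_identical(sort(names(lib2$clips)), sort(names(lib$clips)))
  for (id in names(lib$clips)) {
    expect_lt(max(abs(lib2$clips[[id]]$samples - lib$clips[[id]]$samples)),
              2^-15)
    expect_identical(lib2$clips[[id]]$role, lib$clips[[id]]$role)
  }
})
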