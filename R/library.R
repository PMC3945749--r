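# Seeded assembly of whole call libraries with the study's role structure.

# Add ambient background noise (emulating field-recording background) at a
# given clip-level SNR, then re-normalize the peak.
add_ambient_noise <- function(clip, snr_db) {
  if (!is.finite(snr_db)) return(clip)
  p <- mean(clip$samples^2)
  nz <- rnorm(length(clip$samples))
  nz <- nz * sqrt(p / 10^(snr_db / 10) / mean(nz^2))
  x <- clip$samples + nz
  peak0 <- max(abs(clip$samples))
  clip$samples <- x / max(abs(x)) * peak0
  clip
}

#' Specify a synthetic call library
#'
#' Role counts follow the mimicry study design: `mimic` calls (each a
#' perturbed copy of one `model` call), `model` calls (putative
#' heterospecific models), `other` heterospecific non-model calls, and
#' `conspecific` non-mimicked calls of the mimicking species. The reference
#' compositions are 63/63/21/210 (the 357-file library, models counted among
#' the 84 heterospecific files) and 21/21/20/20 (the 82-file subset).
#'
#' @param n_mimic,n_model,n_other,n_conspecific Non-negative role counts.
#' @param perturbation A [perturbation_spec] applied to derive each mimic
#'   from its model.
#' @param seed Integer seed; the whole library is a deterministic function
#'   of the spec including this seed.
#' @param mimic_mode `"perturbed"` (mimics derived from their models) or
#'   `"unrelated"` (mimics drawn as independent random calls while keeping
#'   their `model_id` assignment — the chance-level control).
#' @param duration_range Range of call durations in seconds, drawn uniformly.
#' @param ambient_snr_range Range of per-clip ambient background SNR in dB;
#'   every clip, whatever its role, receives broadband background noise at a
#'   clip-level SNR drawn uniformly from this range, emulating the ambient
#'   noise floor of field recordings. `c(Inf, Inf)` disables it.
#' @return A `library_spec` object.
#' @export
library_spec <- function(n_mimic, n_model, n_other, n_conspecific,
                         perturbation = perturbation_spec(), seed = 1L,
                         mimic_mode = c("perturbed", "unrelated"),
                         duration_range = c(0.25, 0.6),
                         ambient_snr_range = c(20, 30)) {
  mimic_mode <- match.arg(mimic_mode)
  counts <- c(n_mimic, n_model, n_other, n_conspecific)
  if (any(counts < 0)) abort("role counts must be non-negative")
  if (n_mimic > 0 && n_model == 0) {
    abort("a library with mimics requires at least one model call")
  }
  structure(
    list(n_mimic = as.integer(n_mimic), n_model = as.integer(n_model),
         n_other = as.integer(n_other),
         n_conspecific = as.integer(n_conspecific),
         perturbation = perturbation, seed = as.integer(seed),
         mimic_mode = mimic_mode, duration_range = duration_range,
         ambient_snr_range = ambient_snr_range),
    class = "library_spec"
  )
}

# Draw a random call_spec; classes are cycled so all five are covered.
random_call_spec <- function(call_class, duration_range) {
  duration <- runif(1, duration_range[1], duration_range[2])
  switch(call_class,
    FM = {
      f1 <- runif(1, FREQ_MIN, FREQ_MAX - 1000)
      f2 <- runif(1, f1 + 800, FREQ_MAX)
      if (runif(1) < 0.5) { tmp <- f1; f1 <- f2; f2 <- tmp }  # up or down sweep
      call_spec("FM", duration, f_start = f1, f_end = f2)
    },
    HR = {
      f0 <- runif(1, FREQ_MIN, 1800)
      nh <- sample(2:min(6L, floor(FREQ_MAX / f0)), 1)
      call_spec("HR", duration, f0 = f0, n_harmonics = nh)
    },
    Trill = {
      f1 <- runif(1, FREQ_MIN, FREQ_MAX - 1500)
      f2 <- f1 + runif(1, 500, min(3000, FREQ_MAX - f1))
      call_spec("Trill", duration, f_start = f1, f_end = f2,
                trill_rate = runif(1, 8, 16),
                element_duration = runif(1, 0.03, 0.06))
    },
    `NB-Trill` = {
      bw <- runif(1, 150, 400)
      f0 <- runif(1, FREQ_MIN + bw / 2, FREQ_MAX - bw / 2)
      call_spec("NB-Trill", duration, f0 = f0, bandwidth = bw,
                trill_rate = runif(1, 15, 40))
    },
    BB = {
      bw <- runif(1, 1000, 4000)
      f0 <- runif(1, FREQ_MIN + bw / 2, FREQ_MAX - bw / 2)
      call_spec("BB", duration, f0 = f0, bandwidth = bw,
                trill_rate = runif(1, 6, 12),
                element_duration = runif(1, 0.03, 0.08))
    }
  )
}

#' Build a synthetic call library
#'
#' Deterministically generates every clip of a [library_spec]: model calls
#' with random specs cycling through all five spectral-signature classes,
#' mimics derived from the models via the perturbation model (models are
#' recycled when there are more mimics than models), and independent random
#' `other` and `conspecific` calls.
#'
#' @param spec A [library_spec].
#' @param rate Sampling rate in Hz.
#' @return A `call_library`: list with `clips` (named list of [audio_clip])
#'   and `manifest` (a tibble with columns `id`, `species`, `role`,
#'   `call_class`, `model_id`, `duration`).
#' @export
build_library <- function(spec, rate = 48000) {
  stopifnot(inherits(spec, "library_spec"))
  with_local_seed(spec$seed, {
    n_total <- spec$n_mimic + spec$n_model + spec$n_other + spec$n_conspecific
    clip_seeds <- sample.int(.Machine$integer.max - 1L,
                             max(2L * n_total, 1L))
    si <- 0L
    next_seed <- function() {
      si <<- si + 1L
      clip_seeds[si]
    }
    classes_for <- function(n) {
      if (n == 0L) character(0)
      else rep(CALL_CLASSES, length.out = n)[sample.int(n)]
    }

    models <- list()
    if (spec$n_model > 0) {
      cls <- classes_for(spec$n_model)
      models <- lapply(seq_len(spec$n_model), function(i) {
        synthesize_call(random_call_spec(cls[i], spec$duration_range),
                        rate = rate, seed = next_seed(),
                        id = sprintf("mod%03d", i),
                        species = sprintf("model-sp%03d", i), role = "model")
      })
    }

    mimics <- list()
    if (spec$n_mimic > 0) {
      midx <- rep(seq_len(spec$n_model), length.out = spec$n_mimic)
      mimics <- lapply(seq_len(spec$n_mimic), function(i) {
        mod <- models[[midx[i]]]
        if (spec$mimic_mode == "perturbed") {
          make_mimic(mod, spec$perturbation, seed = next_seed(),
                     id = sprintf("mim%03d", i))
        } else {
          cl <- synthesize_call(
            random_call_spec(sample(CALL_CLASSES, 1), spec$duration_range),
            rate = rate, seed = next_seed(), id = sprintf("mim%03d", i),
            species = "mimic-sp", role = "model")
          cl$role <- "mimic"
          cl$model_id <- mod$id
          cl
        }
      })
    }

    others <- list()
    if (spec$n_other > 0) {
      cls <- classes_for(spec$n_other)
      others <- lapply(seq_len(spec$n_other), function(i) {
        synthesize_call(random_call_spec(cls[i], spec$duration_range),
                        rate = rate, seed = next_seed(),
                        id = sprintf("oth%03d", i),
                        species = sprintf("other-sp%03d", i), role = "other")
      })
    }

    consp <- list()
    if (spec$n_conspecific > 0) {
      cls <- classes_for(spec$n_conspecific)
      consp <- lapply(seq_len(spec$n_conspecific), function(i) {
        synthesize_call(random_call_spec(cls[i], spec$duration_range),
                        rate = rate, seed = next_seed(),
                        id = sprintf("con%03d", i),
                        species = "mimic-sp", role = "conspecific")
      })
    }

    clips <- c(mimics, models, others, consp)
    if (any(is.finite(spec$ambient_snr_range))) {
      clips <- lapply(clips, function(cl) {
        add_ambient_noise(cl, runif(1, spec$ambient_snr_range[1],
                                    spec$ambient_snr_range[2]))
      })
    }
    names(clips) <- vapply(clips, function(cl) cl$id, character(1))
    manifest <- purrr::map_dfr(clips, function(cl) {
      tibble(id = cl$id, species = cl$species, role = cl$role,
             call_class = cl$call_class, model_id = cl$model_id,
             duration = clip_duration(cl))
    })
    structure(list(clips = clips, manifest = manifest, spec = spec,
                   rate = rate),
              class = "call_library")
  })
}

#' @export
print.call_library <- function(x, ...) {
  cat(sprintf("<call_library> %d clips @ %d Hz (seed %d)\n",
              length(x$clips), as.integer(x$rate), x$spec$seed))
  if (nrow(x$manifest) > 0) {
    print(dplyr::count(x$manifest, .data$role))
  }
  invisible(x)
}

#' Role counts of a call library
#' @param library A `call_library`.
#' @return A tibble with columns `role` and `n`.
#' @export
role_counts <- function(library) {
  dplyr::count(library$manifest, .data$role)
}

#' Write a call library to WAV files plus a manifest CSV
#'
#' @param library A `call_library`.
#' @param dir Output directory (created if needed).
#' @return The manifest tibble (with a `path` column), invisibly.
#' @export
write_library <- function(library, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(library$clips, function(cl) {
    p <- file.path(dir, paste0(cl$id, ".wav"))
    write_wav(cl, p)
    p
  }, character(1))
  manifest <- dplyr::mutate(library$manifest,
                            path = unname(paths[.data$id]),
                            .after = "id")
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a call library from a manifest CSV and its WAV files
#'
#' @param manifest_path Path to a `manifest.csv` written by [write_library]
#'   (columns `id`, `path`, `species`, `role`, `call_class`, `model_id`;
#'   relative paths are resolved against the manifest's directory).
#' @return A `call_library` (clips carry no synthesis spec).
#' @export
read_library <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  clips <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, basename(p))
    load_audio(p, id = man$id[i], species = man$species[i],
               role = man$role[i], call_class = man$call_class[i],
               model_id = man$model_id[i])
  })
  names(clips) <- man$id
  manifest <- purrr::map_dfr(clips, function(cl) {
    tibble(id = cl$id, species = cl$species, role = cl$role,
           call_class = cl$call_class, model_id = cl$model_id,
           duration = clip_duration(cl))
  })
  rate <- if (length(clips)) clips[[1]]$rate else 48000
  structure(list(clips = clips, manifest = manifest, spec = NULL,
                 rate = rate),
            class = "call_library")
}
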