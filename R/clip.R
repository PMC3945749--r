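#' Construct a labeled mono audio clip
#'
#' The basic waveform container of the package: a finite mono sample sequence
#' with its sampling rate and the metadata the matching pipeline needs
#' (species, role in the mimicry design, spectral-signature class, and for
#' mimic clips the identity of the putative model call).
#'
#' @param samples Numeric vector of samples; must be finite with peak
#'   absolute value at most 1.
#' @param rate Sampling rate in Hz (default 48000).
#' @param id Character identifier, unique within a library.
#' @param species Species label (free text).
#' @param role One of `"mimic"`, `"model"`, `"other"`, `"conspecific"`, or
#'   `NA` when unknown.
#' @param call_class Spectral-signature class (`"FM"`, `"BB"`, `"HR"`,
#'   `"Trill"`, `"NB-Trill"`), or `NA`.
#' @param model_id For mimic clips, the id of the putative model call.
#' @param spec Optional [call_spec] the clip was synthesized from (carried so
#'   perturbations can re-synthesize; `NULL` for loaded recordings).
#' @param synth_seed Seed the clip was synthesized with, if any.
#' @return An object of class `audio_clip`.
#' @export
audio_clip <- function(samples, rate = 48000, id = "clip",
                       species = NA_character_, role = NA_character_,
                       call_class = NA_character_, model_id = NA_character_,
                       spec = NULL, synth_seed = NULL) {
  if (!is.numeric(samples) || length(samples) == 0L) {
    abort("samples must be a non-empty numeric vector")
  }
  if (!all(is.finite(samples))) abort("samples must be finite")
  if (max(abs(samples)) > 1 + 1e-12) abort("peak |sample| must be <= 1")
  if (!is.numeric(rate) || rate <= 0) abort("rate must be a positive number")
  if (!is.na(role) && !role %in% c("mimic", "model", "other", "conspecific")) {
    abort("role must be one of mimic, model, other, conspecific")
  }
  structure(
    list(samples = as.numeric(samples), rate = rate, id = id,
         species = species, role = role, call_class = call_class,
         model_id = model_id, spec = spec, synth_seed = synth_seed),
    class = "audio_clip"
  )
}

#' Duration of an audio clip in seconds
#' @param clip An [audio_clip].
#' @return Duration in seconds.
#' @export
clip_duration <- function(clip) length(clip$samples) / clip$rate

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip %s> %.3f s @ %d Hz", x$id,
              clip_duration(x), as.integer(x$rate)))
  if (!is.na(x$role)) cat(sprintf(" | %s", x$role))
  if (!is.na(x$call_class)) cat(sprintf(" | %s", x$call_class))
  if (!is.na(x$model_id)) cat(sprintf(" | model: %s", x$model_id))
  cat("\n")
  invisible(x)
}

#' Waveform plot of an audio clip
#'
#' @param object An [audio_clip].
#' @param ... Ignored.
#' @return A ggplot object showing the oscillogram.
#' @export
autoplot.audio_clip <- function(object, ...) {
  df <- tibble(
    time = seq_along(object$samples) / object$rate,
    amplitude = object$samples
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "amplitude", title = object$id) +
    ggplot2::theme_minimal()
}
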