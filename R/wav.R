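# Minimal RIFF/WAVE I/O for 16-bit PCM mono files.

#' Write an audio clip to a 16-bit PCM WAV file
#'
#' Samples are clipped to \[-1, 1\] and quantized to 16-bit signed integers
#' (scale factor 32767).
#'
#' @param clip An [audio_clip], or a numeric vector of samples in \[-1, 1\].
#' @param path Output file path.
#' @param rate Sampling rate in Hz; ignored (taken from the clip) when `clip`
#'   is an `audio_clip`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path, rate = 48000) {
  if (inherits(clip, "audio_clip")) {
    rate <- clip$rate
    samples <- clip$samples
  } else {
    samples <- clip
  }
  if (!is.numeric(samples) || !all(is.finite(samples))) {
    abort("samples must be finite numeric values")
  }
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + n_bytes, con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")   # PCM
  writeBin(1L, con, size = 2L, endian = "little")   # mono
  writeBin(as.integer(rate), con, size = 4L, endian = "little")
  writeBin(as.integer(rate) * 2L, con, size = 4L, endian = "little")  # byte rate
  writeBin(2L, con, size = 2L, endian = "little")   # block align
  writeBin(16L, con, size = 2L, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}

#' Load a mono PCM WAV file as an audio clip
#'
#' Reads 16-bit PCM RIFF/WAVE files. Samples are rescaled to \[-1, 1\]
#' (division by 32767) and the sampling rate is taken from the header.
#' Multi-channel or non-PCM files are rejected.
#'
#' @param path Path to a WAV file.
#' @param id Clip identifier; defaults to the file name without extension.
#' @param species,role,call_class,model_id Optional metadata carried on the
#'   returned clip (see [audio_clip]).
#' @return An [audio_clip].
#' @export
load_audio <- function(path, id = NULL, species = NA_character_,
                       role = NA_character_, call_class = NA_character_,
                       model_id = NA_character_) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort(paste0("not a RIFF file: ", path))
  readBin(con, "integer", 1L, size = 4L, endian = "little")
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort(paste0("not a WAVE file: ", path))

  fmt <- NULL
  samples <- NULL
  repeat {
    chunk_id <- readChar(con, 4L, useBytes = TRUE)
    if (length(chunk_id) == 0L || nchar(chunk_id) < 4L) break
    chunk_size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(chunk_id, "fmt ")) {
      raw <- readBin(con, "raw", chunk_size)
      fmt <- list(
        audio_format = sum(as.integer(raw[1:2]) * c(1L, 256L)),
        n_channels   = sum(as.integer(raw[3:4]) * c(1L, 256L)),
        sample_rate  = sum(as.integer(raw[5:8]) * c(1, 256, 65536, 16777216)),
        bits         = sum(as.integer(raw[15:16]) * c(1L, 256L))
      )
    } else if (identical(chunk_id, "data")) {
      if (is.null(fmt)) abort("malformed WAV: data chunk before fmt chunk")
      if (fmt$audio_format != 1L || fmt$bits != 16L) {
        abort("unsupported WAV encoding: only 16-bit PCM is supported")
      }
      if (fmt$n_channels != 1L) {
        abort(paste0("mono audio required, got ", fmt$n_channels, " channels"))
      }
      samples <- readBin(con, "integer", chunk_size / 2L, size = 2L,
                         signed = TRUE, endian = "little") / 32767
      break
    } else {
      # skip unknown chunk (word-aligned)
      readBin(con, "raw", chunk_size + chunk_size %% 2L)
    }
  }
  if (is.null(samples)) abort(paste0("no data chunk found in ", path))
  if (is.null(id)) id <- sub("\\.[Ww][Aa][Vv]$", "", basename(path))
  audio_clip(samples, rate = fmt$sample_rate, id = id, species = species,
             role = role, call_class = call_class, model_id = model_id)
}
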