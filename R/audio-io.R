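#' Construct an audio segment
#'
#' An `audio_segment` holds one short mono recording of a single ingestive
#' event as raw 16-bit integer samples, together with its sampling rate and
#' optional behavior/forage labels.
#'
#' @param samples Integer vector of 16-bit samples in `[-32768, 32767]`.
#' @param rate Sampling rate in Hz; the pipeline operates at 22050 Hz.
#' @param behavior Optional label, one of `"bite"`, `"chew"`, `"chew_bite"`.
#' @param forage_species Optional label, `"alfalfa"` or `"tall_fescue"`.
#' @param forage_height Optional label, `"tall"` or `"short"`.
#' @param source_path Optional path the segment was read from.
#' @return An object of class `audio_segment`.
#' @export
audio_segment <- function(samples, rate = SAMPLE_RATE, behavior = NULL,
                          forage_species = NULL, forage_height = NULL,
                          source_path = NULL) {
  samples <- as.integer(round(samples))
  if (length(samples) && (min(samples) < INT16_MIN || max(samples) > INT16_MAX)) {
    stop("samples outside the 16-bit range [-32768, 32767]", call. = FALSE)
  }
  if (!is.null(behavior)) behavior <- match_enum(behavior, BEHAVIORS, "behavior")
  if (!is.null(forage_species)) {
    forage_species <- match_enum(forage_species, FORAGE_SPECIES, "forage_species")
  }
  if (!is.null(forage_height)) {
    forage_height <- match_enum(forage_height, FORAGE_HEIGHTS, "forage_height")
  }
  structure(
    list(samples = samples, rate = as.integer(rate), behavior = behavior,
         forage_species = forage_species, forage_height = forage_height,
         source_path = source_path),
    class = "audio_segment"
  )
}

#' @export
print.audio_segment <- function(x, ...) {
  cat(sprintf("<audio_segment> %d samples @ %d Hz (%.3f s)",
              length(x$samples), x$rate, duration_s(x)))
  if (!is.null(x$behavior)) cat(" |", x$behavior)
  if (!is.null(x$forage_species)) {
    cat(sprintf(" | %s/%s", x$forage_species, x$forage_height %||% "?"))
  }
  cat("\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Segment duration in seconds
#' @param segment An `audio_segment`.
#' @return Duration `length(samples)/rate` in seconds.
#' @export
duration_s <- function(segment) {
  length(segment$samples) / segment$rate
}

#' Read a mono PCM WAV file
#'
#' Reads a RIFF/PCM WAV file into an [audio_segment]. Multi-channel input
#' is averaged to mono. Only 16-bit PCM is read natively; 8-bit PCM and
#' 32-bit IEEE float are converted to 16-bit with a warning.
#'
#' @param path Path to a WAV file.
#' @param expected_rate Required sampling rate (default 22050 Hz).
#' @param resample If `TRUE`, linearly resample files recorded at another
#'   rate; otherwise a differing rate is an error.
#' @return An [audio_segment].
#' @export
read_wav <- function(path, expected_rate = SAMPLE_RATE, resample = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", 1, size = 4, endian = "little")  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      u16 <- function(off) sum(as.integer(body[off + 1:2]) * c(1, 256))
      u32 <- function(off) sum(as.integer(body[off + 1:4]) * 256^(0:3))
      fmt <- list(format = u16(0), channels = u16(2), rate = u32(4),
                  bits = u16(14))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size)  # skip unknown chunk
    }
    if (size %% 2 == 1) readBin(con, "raw", 1)  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("missing fmt/data chunk in ", path, call. = FALSE)
  }

  if (fmt$format == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", length(data_raw) / 2, size = 2,
                 signed = TRUE, endian = "little")
  } else if (fmt$format == 1L && fmt$bits == 8L) {
    warning("8-bit PCM converted to 16-bit")
    x <- (as.integer(readBin(data_raw, "integer", length(data_raw), size = 1,
                             signed = FALSE)) - 128L) * 256L
  } else if (fmt$format == 3L && fmt$bits == 32L) {
    warning("32-bit float converted to 16-bit")
    x <- clip_int16(readBin(data_raw, "double", length(data_raw) / 4, size = 4,
                            endian = "little") * 32767)
  } else {
    stop(sprintf("unsupported WAV encoding (format %d, %d bits)",
                 fmt$format, fmt$bits), call. = FALSE)
  }

  if (fmt$channels > 1L) {
    x <- round(colMeans(matrix(x, nrow = fmt$channels)))
  }
  if (fmt$rate != expected_rate) {
    if (!resample) {
      stop(sprintf("%s is sampled at %d Hz, expected %d Hz (set resample = TRUE)",
                   path, fmt$rate, expected_rate), call. = FALSE)
    }
    n_out <- max(1L, round(length(x) * expected_rate / fmt$rate))
    x <- stats::approx(seq_along(x), x, n = n_out)$y
  }
  audio_segment(clip_int16(x), rate = expected_rate, source_path = path)
}

#' Write an audio segment as 16-bit mono PCM WAV
#'
#' @param segment An [audio_segment].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(segment, path) {
  x <- segment$samples
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- length(x) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")             # PCM
  writeBin(1L, con, size = 2, endian = "little")             # mono
  writeBin(as.integer(segment$rate), con, size = 4, endian = "little")
  writeBin(as.integer(segment$rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")             # block align
  writeBin(16L, con, size = 2, endian = "little")            # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(as.integer(x), con, size = 2, endian = "little")
  invisible(path)
}

#' Normalize 16-bit amplitudes to the unit scale
#'
#' Divides raw 16-bit sample values by 2^16 = 65536, the normalization the
#' spectral pipeline applies before any Fourier transform.
#'
#' @param samples Integer (16-bit) sample vector.
#' @return Numeric vector `samples / 65536`.
#' @export
normalize_amplitude <- function(samples) {
  as.numeric(samples) / 65536
}

#' Absolute normalized magnitude (ANM) spectrum
#'
#' Computes the real-FFT of the normalized amplitudes of a segment and
#' rescales the absolute magnitudes to sum to one. The transform length is
#' the segment length (no zero-padding), so frequency resolution follows
#' the segment duration.
#'
#' @param segment An [audio_segment] with at least one nonzero sample.
#' @return A list of class `anm_spectrum` with `magnitudes` (summing to 1),
#'   `bin_freqs` in Hz, and `m`, the number of real-FFT values.
#' @export
anm_spectrum <- function(segment) {
  x <- normalize_amplitude(segment$samples)
  n <- length(x)
  if (n == 0L || all(x == 0)) {
    stop("anm_spectrum undefined for silent input: magnitude sum is zero",
         call. = FALSE)
  }
  m <- n %/% 2L + 1L
  mag <- abs(stats::fft(x)[seq_len(m)])
  structure(
    list(magnitudes = mag / sum(mag),
         bin_freqs = (seq_len(m) - 1) * segment$rate / n,
         m = m),
    class = "anm_spectrum"
  )
}

#' Read a segment manifest CSV
#'
#' The manifest is the tabular inventory of segment files with columns
#' `file`, `behavior`, `forage_species`, `forage_height`, `duration_s`.
#' Rows violating the schema (unknown labels, non-positive durations,
#' duplicate files) are rejected with their row numbers.
#'
#' @param path Path to a manifest CSV.
#' @return A `data.frame` manifest.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such manifest: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(df)
}

#' @rdname read_manifest
#' @param manifest A manifest `data.frame`.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a segment manifest
#'
#' @param manifest A `data.frame` with the manifest schema.
#' @return The validated manifest (invisibly usable).
#' @export
validate_manifest <- function(manifest) {
  required <- c("file", "behavior", "forage_species", "forage_height",
                "duration_s")
  missing <- setdiff(required, names(manifest))
  if (length(missing)) {
    stop("manifest is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!manifest$behavior %in% BEHAVIORS)
  if (length(bad)) {
    stop(sprintf("invalid behavior %s in manifest row(s) %s",
                 paste(unique(manifest$behavior[bad]), collapse = ", "),
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  bad <- which(!manifest$forage_species %in% FORAGE_SPECIES)
  if (length(bad)) {
    stop("invalid forage_species in manifest row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(!manifest$forage_height %in% FORAGE_HEIGHTS)
  if (length(bad)) {
    stop("invalid forage_height in manifest row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(manifest$duration_s) | manifest$duration_s <= 0)
  if (length(bad)) {
    stop("non-positive duration_s in manifest row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(manifest$file)) {
    stop("duplicate file paths in manifest", call. = FALSE)
  }
  manifest
}
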