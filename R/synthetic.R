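#' Per-class sound specification for the synthetic generator
#'
#' Describes the distribution of one (behavior x forage species x forage
#' height) cell of ingestive sounds: the mean and spread of the normalized
#' amplitude descriptor (peak-to-peak sample range / 2^16, unitless in
#' (0, 1]) and of the event duration in seconds, plus the frequency band
#' carrying the signal energy. Ingestive sounds sit almost entirely below
#' 1 kHz, so the default carrier band respects that ceiling.
#'
#' @param behavior One of `"bite"`, `"chew"`, `"chew_bite"`.
#' @param forage_species `"alfalfa"` or `"tall_fescue"`.
#' @param forage_height `"tall"` or `"short"`.
#' @param mean_amplitude Mean normalized amplitude in (0, 1].
#' @param mean_duration Mean event duration in seconds (> 0).
#' @param amplitude_sd,duration_sd Standard deviations (>= 0).
#' @param carrier_band Length-2 numeric `(low_hz, high_hz)` inside
#'   (0, 11025); defaults to 60-950 Hz.
#' @return An object of class `class_sound_spec`.
#' @export
class_sound_spec <- function(behavior, forage_species, forage_height,
                             mean_amplitude, mean_duration,
                             amplitude_sd = 0, duration_sd = 0,
                             carrier_band = c(60, 950)) {
  behavior <- match_enum(behavior, BEHAVIORS, "behavior")
  forage_species <- match_enum(forage_species, FORAGE_SPECIES, "forage_species")
  forage_height <- match_enum(forage_height, FORAGE_HEIGHTS, "forage_height")
  if (!is.numeric(mean_amplitude) || mean_amplitude <= 0 || mean_amplitude > 1) {
    stop("mean_amplitude must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(mean_duration) || mean_duration <= 0) {
    stop("mean_duration must be > 0", call. = FALSE)
  }
  if (amplitude_sd < 0 || duration_sd < 0) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  if (length(carrier_band) != 2L || carrier_band[1] <= 0 ||
      carrier_band[2] <= carrier_band[1] || carrier_band[2] >= 11025) {
    stop("carrier_band must satisfy 0 < low < high < 11025 Hz", call. = FALSE)
  }
  structure(
    list(behavior = behavior, forage_species = forage_species,
         forage_height = forage_height,
         mean_amplitude = mean_amplitude, mean_duration = mean_duration,
         amplitude_sd = amplitude_sd, duration_sd = duration_sd,
         carrier_band = as.numeric(carrier_band)),
    class = "class_sound_spec"
  )
}

# Published per-cell acoustic descriptors for the dairy-cow jaw-movement
# recordings: normalized amplitude and duration (s) for each behavior x
# forage species x forage height cell, with pooled standard errors of the
# cell means per behavior.
SOUND_TABLE <- data.frame(
  behavior = rep(c("bite", "chew", "chew_bite"), each = 4),
  forage_species = rep(rep(c("alfalfa", "tall_fescue"), each = 2), 3),
  forage_height = rep(c("tall", "short"), 6),
  amplitude = c(0.387, 0.323, 0.420, 0.488,
                0.127, 0.084, 0.107, 0.102,
                0.435, 0.343, 0.492, 0.549),
  duration = c(0.200, 0.152, 0.212, 0.205,
               0.148, 0.073, 0.128, 0.137,
               0.294, 0.230, 0.301, 0.301),
  amplitude_sem = rep(c(0.017, 0.003, 0.012), each = 4),
  duration_sem = rep(c(0.006, 0.005, 0.005), each = 4),
  stringsAsFactors = FALSE
)

#' Default sound specifications for all behavior/forage cells
#'
#' Builds the twelve [class_sound_spec] objects for the behavior x forage
#' species x forage height grid, parameterized by the published normalized
#' amplitude and duration means of the dairy-cow jaw-movement recordings.
#' The table reports pooled standard errors of cell means rather than
#' per-segment spreads, so per-segment standard deviations are taken as
#' `sem_factor` times the pooled SEM (default 5, giving realistic
#' within-class overlap).
#'
#' @param sem_factor Multiplier converting the pooled SEM into a
#'   per-segment standard deviation.
#' @return A named list of twelve `class_sound_spec` objects.
#' @export
default_sound_specs <- function(sem_factor = 5) {
  specs <- lapply(seq_len(nrow(SOUND_TABLE)), function(i) {
    row <- SOUND_TABLE[i, ]
    class_sound_spec(
      behavior = row$behavior,
      forage_species = row$forage_species,
      forage_height = row$forage_height,
      mean_amplitude = row$amplitude,
      mean_duration = row$duration,
      amplitude_sd = sem_factor * row$amplitude_sem,
      duration_sd = sem_factor * row$duration_sem
    )
  })
  names(specs) <- paste(SOUND_TABLE$behavior, SOUND_TABLE$forage_species,
                        SOUND_TABLE$forage_height, sep = ".")
  specs
}

#' Device beep specification
#'
#' The recording device emits short sinusoidal beeps with center frequency
#' between 3.6 and 4.5 kHz, recorded along with the cow sounds. This spec
#' drives the optional beep injection in the synthetic generator.
#'
#' @param center_freq Beep frequency in Hz, within `[3600, 4500]`.
#' @param duration Beep duration in seconds.
#' @param level Beep amplitude on the normalized (0, 1] peak scale.
#' @param rate Expected number of beeps per second of audio (Poisson).
#' @return An object of class `beep_spec`.
#' @export
beep_spec <- function(center_freq = 4000, duration = 0.06, level = 0.25,
                      rate = 0.5) {
  if (center_freq < 3600 || center_freq > 4500) {
    stop("center_freq must lie in [3600, 4500] Hz", call. = FALSE)
  }
  if (duration <= 0 || level <= 0 || rate < 0) {
    stop("duration and level must be > 0, rate >= 0", call. = FALSE)
  }
  structure(
    list(center_freq = center_freq, duration = duration, level = level,
         rate = rate),
    class = "beep_spec"
  )
}

# Band-limited Gaussian noise of length n: white noise FFT-masked to the
# carrier band. Deterministic under the caller's RNG stream.
band_noise <- function(n, band, rate) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  freqs <- (seq_len(n) - 1) * rate / n
  freqs <- pmin(freqs, rate - freqs)  # fold to [0, rate/2]
  keep <- freqs >= band[1] & freqs <= band[2]
  spec[!keep] <- 0
  Re(stats::fft(spec, inverse = TRUE)) / n
}

#' Generate one synthetic ingestive sound segment
#'
#' Draws duration from `Normal(mean_duration, duration_sd)` truncated at
#' 0.02 s and normalized amplitude from
#' `Normal(mean_amplitude, amplitude_sd)` truncated to (0, 1], then
#' synthesizes a band-limited waveform whose temporal envelope depends on
#' the behavior: a bite is a single impulsive burst with fast exponential
#' decay, a chew is sustained stationary noise, and a chew-bite is chew
#' texture with a burst superimposed in the final third. The waveform is
#' scaled so its peak-to-peak sample range equals the drawn amplitude
#' times 2^16 (up to integer rounding).
#'
#' @param spec A [class_sound_spec].
#' @param seed Integer seed; the output is fully determined by
#'   `(spec, seed)`.
#' @return An [audio_segment] carrying the spec's labels.
#' @export
generate_segment <- function(spec, seed) {
  stopifnot(inherits(spec, "class_sound_spec"))
  with_seed(seed, {
    dur <- stats::rnorm(1, spec$mean_duration, spec$duration_sd)
    while (dur <= 0.02) dur <- stats::rnorm(1, spec$mean_duration, spec$duration_sd)
    amp <- stats::rnorm(1, spec$mean_amplitude, spec$amplitude_sd)
    while (amp <= 0 || amp > 1) amp <- stats::rnorm(1, spec$mean_amplitude, spec$amplitude_sd)

    n <- max(64L, as.integer(round(dur * SAMPLE_RATE)))
    t_idx <- seq_len(n)
    base <- band_noise(n, spec$carrier_band, SAMPLE_RATE)

    wave <- switch(
      spec$behavior,
      bite = {
        # impulsive burst: sharp attack, exponential decay over the event
        env <- exp(-5 * (t_idx - 1) / n) * (1 - exp(-(t_idx) / (0.002 * SAMPLE_RATE)))
        base * env
      },
      chew = {
        # sustained grinding noise with gentle onset/offset ramps
        ramp <- pmin(1, t_idx / (0.01 * SAMPLE_RATE),
                     (n - t_idx + 1) / (0.01 * SAMPLE_RATE))
        base * ramp
      },
      chew_bite = {
        # chew texture plus an impulsive burst in the final third
        ramp <- pmin(1, t_idx / (0.01 * SAMPLE_RATE),
                     (n - t_idx + 1) / (0.01 * SAMPLE_RATE))
        chew_part <- base * ramp * 0.45
        burst_start <- as.integer(floor(2 * n / 3)) + 1L
        burst_len <- n - burst_start + 1L
        burst <- band_noise(burst_len, spec$carrier_band, SAMPLE_RATE)
        benv <- exp(-8 * (seq_len(burst_len) - 1) / burst_len)
        chew_part[burst_start:n] <- chew_part[burst_start:n] + burst * benv
        chew_part
      }
    )

    # scale so peak-to-peak/2^16 equals the drawn amplitude descriptor
    pp <- max(wave) - min(wave)
    target_pp <- amp * 65536
    scaled <- wave * (target_pp / pp)
    scaled <- scaled - (max(scaled) + min(scaled)) / 2  # center in range
    audio_segment(clip_int16(scaled), rate = SAMPLE_RATE,
                  behavior = spec$behavior,
                  forage_species = spec$forage_species,
                  forage_height = spec$forage_height)
  })
}

#' Inject device beeps into a segment
#'
#' Adds sinusoidal tones at the beep center frequency at Poisson-placed
#' random positions (expected `rate` beeps per second). Samples are
#' clipped to the valid 16-bit range.
#'
#' @param segment An [audio_segment].
#' @param beep A [beep_spec].
#' @param seed Integer seed for beep count and placement.
#' @return The segment with beeps added.
#' @export
inject_beep <- function(segment, beep, seed) {
  stopifnot(inherits(beep, "beep_spec"))
  if (beep$rate == 0) return(segment)
  with_seed(seed, {
    x <- as.numeric(segment$samples)
    n <- length(x)
    n_beeps <- stats::rpois(1, beep$rate * n / segment$rate)
    if (n_beeps > 0) {
      beep_n <- max(8L, as.integer(round(beep$duration * segment$rate)))
      starts <- sample.int(max(1L, n - beep_n + 1L), n_beeps, replace = TRUE)
      tone <- beep$level * 32767 *
        sin(2 * pi * beep$center_freq * (seq_len(beep_n) - 1) / segment$rate)
      taper <- pmin(1, (seq_len(beep_n) - 1) / (0.005 * segment$rate),
                    (beep_n - seq_len(beep_n)) / (0.005 * segment$rate))
      tone <- tone * taper
      for (s in starts) {
        e <- min(n, s + beep_n - 1L)
        x[s:e] <- x[s:e] + tone[seq_len(e - s + 1L)]
      }
    }
    out <- segment
    out$samples <- clip_int16(x)
    out
  })
}

#' Generate a labeled synthetic dataset on disk
#'
#' Writes one WAV file per requested segment plus a manifest CSV. Each
#' file's content is determined by `(seed, its index)`, so two runs with
#' the same arguments produce identical WAV bytes and manifests.
#'
#' @param specs List of [class_sound_spec] objects.
#' @param counts Integer vector, one count per spec (recycled if length 1).
#' @param out_dir Output directory (created if needed).
#' @param beep Optional [beep_spec]; when supplied, beeps are injected
#'   into every segment.
#' @param seed Integer master seed.
#' @return The manifest `data.frame` (also written to
#'   `file.path(out_dir, "manifest.csv")`).
#' @export
generate_dataset <- function(specs, counts, out_dir, beep = NULL, seed = 1L) {
  if (length(counts) == 1L) counts <- rep(counts, length(specs))
  stopifnot(length(counts) == length(specs), all(counts >= 1))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  rows <- vector("list", sum(counts))
  idx <- 0L
  for (k in seq_along(specs)) {
    spec <- specs[[k]]
    for (j in seq_len(counts[k])) {
      idx <- idx + 1L
      seg <- generate_segment(spec, derive_seed(seed, idx))
      if (!is.null(beep)) {
        seg <- inject_beep(seg, beep, derive_seed(seed, idx + 500000L))
      }
      fname <- sprintf("%s_%s_%s_%05d.wav", spec$behavior,
                       spec$forage_species, spec$forage_height, idx)
      write_wav(seg, file.path(out_dir, fname))
      rows[[idx]] <- data.frame(
        file = fname, behavior = spec$behavior,
        forage_species = spec$forage_species,
        forage_height = spec$forage_height,
        duration_s = duration_s(seg), stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}
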