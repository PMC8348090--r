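#' Short-time Fourier transform configuration
#'
#' Defaults follow the featurization the classifiers consume: a 23 ms
#' (512-sample) rolling window advanced in 10 ms (220-sample) steps at
#' 22.05 kHz.
#'
#' @param win_length Window length in samples (default 512).
#' @param hop_length Hop between windows in samples (default 220).
#' @param window Analysis window, `"hann"` (default) or `"rect"`.
#' @param n_fft FFT length, `>= win_length` (default 512).
#' @return An object of class `stft_config`.
#' @export
stft_config <- function(win_length = 512L, hop_length = 220L,
                        window = c("hann", "rect"), n_fft = 512L) {
  window <- match.arg(window)
  if (hop_length > win_length) stop("hop_length must be <= win_length", call. = FALSE)
  if (n_fft < win_length) stop("n_fft must be >= win_length", call. = FALSE)
  structure(list(win_length = as.integer(win_length),
                 hop_length = as.integer(hop_length),
                 window = window, n_fft = as.integer(n_fft)),
            class = "stft_config")
}

#' Mel filterbank configuration
#'
#' 26 triangular filters spaced on the Mel scale between 0 Hz and the
#' Nyquist frequency, concentrating resolution below 1 kHz where the
#' ingestive-sound energy sits.
#'
#' @param n_mels Number of Mel bands (default 26).
#' @param f_min,f_max Frequency range in Hz (defaults 0 and 11025).
#' @param log_floor_db Lower clamp for the dB-scaled output (default -80).
#' @param use_dct If `TRUE`, a type-II DCT is applied across the Mel bands
#'   to produce cepstral coefficients instead of log-Mel energies.
#' @return An object of class `mel_config`.
#' @export
mel_config <- function(n_mels = 26L, f_min = 0, f_max = 11025,
                       log_floor_db = -80, use_dct = FALSE) {
  if (n_mels < 1L) stop("n_mels must be >= 1", call. = FALSE)
  if (!(f_min < f_max)) stop("need f_min < f_max", call. = FALSE)
  structure(list(n_mels = as.integer(n_mels), f_min = f_min, f_max = f_max,
                 log_floor_db = log_floor_db, use_dct = isTRUE(use_dct)),
            class = "mel_config")
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Slice a signal into overlapping frames
#'
#' Produces `floor((N - win) / hop) + 1` frames of `win_length` samples.
#' Signals shorter than one window are zero-padded to a single frame.
#'
#' @param samples Numeric or integer sample vector.
#' @param cfg An [stft_config].
#' @return A `T x win_length` matrix of frames.
#' @export
frame_signal <- function(samples, cfg = stft_config()) {
  x <- as.numeric(samples)
  n <- length(x)
  if (n == 0L) stop("cannot frame an empty signal", call. = FALSE)
  if (n < cfg$win_length) {
    x <- c(x, numeric(cfg$win_length - n))
    n <- cfg$win_length
  }
  n_frames <- (n - cfg$win_length) %/% cfg$hop_length + 1L
  starts <- (seq_len(n_frames) - 1L) * cfg$hop_length
  idx <- outer(starts, seq_len(cfg$win_length), `+`)
  matrix(x[idx], nrow = n_frames)
}

stft_window <- function(cfg) {
  switch(cfg$window,
         hann = 0.5 * (1 - cos(2 * pi * (seq_len(cfg$win_length) - 1) /
                                 cfg$win_length)),
         rect = rep(1, cfg$win_length))
}

#' Per-frame power spectrogram
#'
#' Windows each frame, takes its real FFT (each frame transformed
#' independently; no overlap-add), and returns squared magnitudes over the
#' `n_fft/2 + 1` non-negative-frequency bins.
#'
#' @param frames A frame matrix from [frame_signal()].
#' @param cfg The [stft_config] used to build the frames.
#' @return A `T x (n_fft/2 + 1)` matrix of power values.
#' @export
power_spectrogram <- function(frames, cfg = stft_config()) {
  w <- stft_window(cfg)
  n_bins <- cfg$n_fft %/% 2L + 1L
  windowed <- sweep(frames, 2L, w, `*`)
  if (cfg$n_fft > cfg$win_length) {
    windowed <- cbind(windowed,
                      matrix(0, nrow(windowed), cfg$n_fft - cfg$win_length))
  }
  # mvfft transforms columns; frames are rows
  spec <- stats::mvfft(t(windowed))[seq_len(n_bins), , drop = FALSE]
  t(Mod(spec)^2)
}

#' Triangular Mel filterbank matrix
#'
#' Filter centers are equally spaced on the Mel scale
#' (`m = 2595 log10(1 + f/700)`) between `f_min` and `f_max` and mapped to
#' FFT bin frequencies, giving denser coverage at low frequencies.
#'
#' @param cfg A [mel_config].
#' @param rate Sampling rate in Hz.
#' @param n_fft FFT length.
#' @return An `n_mels x (n_fft/2 + 1)` non-negative matrix.
#' @export
mel_filterbank <- function(cfg = mel_config(), rate = SAMPLE_RATE,
                           n_fft = 512L) {
  n_bins <- n_fft %/% 2L + 1L
  mel_pts <- seq(hz_to_mel(cfg$f_min), hz_to_mel(cfg$f_max),
                 length.out = cfg$n_mels + 2L)
  hz_pts <- mel_to_hz(mel_pts)
  if (min(diff(hz_pts)) < rate / n_fft / 2) {
    stop("n_mels too large for the FFT bin resolution", call. = FALSE)
  }
  bin_freqs <- (seq_len(n_bins) - 1L) * rate / n_fft
  fb <- matrix(0, cfg$n_mels, n_bins)
  for (m in seq_len(cfg$n_mels)) {
    lo <- hz_pts[m]; ctr <- hz_pts[m + 1L]; hi <- hz_pts[m + 2L]
    up <- (bin_freqs - lo) / (ctr - lo)
    down <- (hi - bin_freqs) / (hi - ctr)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Log-Mel spectrogram of a segment
#'
#' Runs the full featurization: framing, per-frame real FFT, Mel
#' filterbank projection, and conversion to decibels
#' (`10 log10(energy + eps)`, clamped at `log_floor_db`). With
#' `use_dct = TRUE` in the Mel config, a type-II orthonormal DCT across
#' bands yields cepstral coefficients instead.
#'
#' @param segment An [audio_segment] (or bare sample vector).
#' @param stft_cfg An [stft_config].
#' @param mel_cfg A [mel_config].
#' @param eps Numerical guard added before the log (default 1e-10).
#' @return An object of class `mel_spectrogram` with `values`
#'   (`T x n_mels`), `frame_times` in seconds, and the configs.
#' @export
log_mel_spectrogram <- function(segment, stft_cfg = stft_config(),
                                mel_cfg = mel_config(), eps = 1e-10) {
  samples <- if (inherits(segment, "audio_segment")) segment$samples else segment
  rate <- if (inherits(segment, "audio_segment")) segment$rate else SAMPLE_RATE
  if (length(samples) == 0L) {
    stop("cannot featurize an empty segment", call. = FALSE)
  }
  frames <- frame_signal(normalize_amplitude(samples), stft_cfg)
  pow <- power_spectrogram(frames, stft_cfg)
  fb <- mel_filterbank(mel_cfg, rate, stft_cfg$n_fft)
  mel_energy <- pow %*% t(fb)
  values <- pmax(10 * log10(mel_energy + eps), mel_cfg$log_floor_db)
  if (mel_cfg$use_dct) values <- values %*% t(dct_matrix(mel_cfg$n_mels))
  structure(
    list(values = values,
         frame_times = (seq_len(nrow(values)) - 1L) * stft_cfg$hop_length / rate,
         stft_config = stft_cfg, mel_config = mel_cfg),
    class = "mel_spectrogram"
  )
}

# Orthonormal type-II DCT matrix (n x n).
dct_matrix <- function(n) {
  k <- seq_len(n) - 1L
  m <- sqrt(2 / n) * cos(pi * outer(k, (2 * (k) + 1) / (2 * n)))
  m[1, ] <- m[1, ] / sqrt(2)
  m
}

#' Fix the time dimension of a spectrogram for model input
#'
#' Center-crops spectrograms longer than `t_fixed` frames and
#' symmetrically pads shorter ones with the dB floor, yielding the
#' constant `t_fixed x n_mels` shape the classifiers require. The default
#' of 98 frames corresponds to 1 s of audio, the typical upper bound of an
#' ingestive event.
#'
#' @param mel A `mel_spectrogram` or bare `T x n_mels` matrix.
#' @param t_fixed Target frame count (default 98).
#' @param floor_db Pad value (defaults to the config's `log_floor_db`).
#' @return A `t_fixed x n_mels` matrix.
#' @export
to_fixed_input <- function(mel, t_fixed = 98L, floor_db = NULL) {
  values <- if (inherits(mel, "mel_spectrogram")) mel$values else mel
  if (is.null(floor_db)) {
    floor_db <- if (inherits(mel, "mel_spectrogram")) {
      mel$mel_config$log_floor_db
    } else {
      -80
    }
  }
  t_now <- nrow(values)
  if (t_now == t_fixed) return(values)
  if (t_now > t_fixed) {
    start <- (t_now - t_fixed) %/% 2L + 1L
    return(values[start:(start + t_fixed - 1L), , drop = FALSE])
  }
  pad_total <- t_fixed - t_now
  pad_left <- pad_total %/% 2L
  pad_right <- pad_total - pad_left
  rbind(matrix(floor_db, pad_left, ncol(values)),
        values,
        matrix(floor_db, pad_right, ncol(values)))
}
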