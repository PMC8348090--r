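#' Bandstop filter specification
#'
#' The recording device's beeps occupy 3.6-4.5 kHz, well away from the
#' sub-1 kHz ingestive sounds, so a fixed bandstop over that range removes
#' them while passing the signal of interest.
#'
#' @param stop_low,stop_high Stopband edges in Hz, `0 < low < high < 11025`.
#' @param order Butterworth prototype order (default 4).
#' @return An object of class `bandstop_spec`.
#' @export
bandstop_spec <- function(stop_low = 3600, stop_high = 4500, order = 4L) {
  if (!(stop_low > 0 && stop_low < stop_high && stop_high < 11025)) {
    stop("need 0 < stop_low < stop_high < 11025 Hz", call. = FALSE)
  }
  if (order < 1L) stop("order must be >= 1", call. = FALSE)
  structure(list(stop_low = stop_low, stop_high = stop_high,
                 order = as.integer(order), design = "butterworth"),
            class = "bandstop_spec")
}

#' Zero-phase bandstop filtering of device beeps
#'
#' Applies a Butterworth bandstop filter forward and backward
#' (zero-phase), so impulsive bite transients are attenuated in the
#' stopband without phase distortion. Output is re-quantized to 16-bit.
#'
#' @param segment An [audio_segment].
#' @param spec A [bandstop_spec].
#' @return The filtered [audio_segment].
#' @export
bandstop_filter <- function(segment, spec = bandstop_spec()) {
  stopifnot(inherits(spec, "bandstop_spec"))
  n <- length(segment$samples)
  if (n <= 3 * spec$order) {
    stop(sprintf("segment too short to filter: %d samples <= 3 x order %d",
                 n, spec$order), call. = FALSE)
  }
  nyq <- segment$rate / 2
  flt <- signal::butter(spec$order, c(spec$stop_low, spec$stop_high) / nyq,
                        type = "stop")
  y <- signal::filtfilt(flt, as.numeric(segment$samples))
  out <- segment
  out$samples <- clip_int16(y)
  out
}

# Frequency-response magnitude of the zero-phase bandstop at `freq_hz`,
# used as an independent oracle in tests: |H(f)|^2 for filtfilt.
bandstop_response_db <- function(spec, freq_hz, rate = SAMPLE_RATE) {
  nyq <- rate / 2
  flt <- signal::butter(spec$order, c(spec$stop_low, spec$stop_high) / nyq,
                        type = "stop")
  w <- pi * freq_hz / nyq
  z <- exp(1i * w)
  h <- sum(flt$b * z^(-(seq_along(flt$b) - 1))) /
    sum(flt$a * z^(-(seq_along(flt$a) - 1)))
  20 * log10(Mod(h)^2)  # squared: filter runs forward and backward
}

#' Staggered block-mean envelope
#'
#' Computes means of absolute raw 16-bit sample values over windows of
#' `block_size` samples started at `n_offsets` staggered offsets (offset
#' step `block_size / n_offsets`). For each non-overlapping block of the
#' signal, the maximum over all windows overlapping that block is
#' retained, so short high-power events straddling a block boundary still
#' register. A tail shorter than `block_size` forms its own block averaged
#' over its actual length.
#'
#' @param samples Integer sample vector (raw 16-bit values, not
#'   normalized).
#' @param block_size Samples per block (default 1100, i.e. ~50 ms).
#' @param n_offsets Number of staggered window offsets (default 4).
#' @return A list of class `envelope_mask` with `block_means` (the
#'   retained maxima), `mask` (all `TRUE` until thresholded), and
#'   `block_size`.
#' @export
block_envelope <- function(samples, block_size = 1100L, n_offsets = 4L) {
  stopifnot(block_size >= 1L, n_offsets >= 1L)
  x <- abs(as.numeric(samples))
  n <- length(x)
  n_blocks <- ceiling(n / block_size)
  if (n == 0L) {
    return(structure(list(block_means = numeric(0), mask = logical(0),
                          block_size = as.integer(block_size)),
                     class = "envelope_mask"))
  }
  step <- max(1L, as.integer(floor(block_size / n_offsets)))
  starts <- seq.int(1L, n, by = step)
  cs <- c(0, cumsum(x))
  ends <- pmin(starts + block_size - 1L, n)
  win_means <- (cs[ends + 1L] - cs[starts]) / (ends - starts + 1L)

  block_means <- numeric(n_blocks)
  for (b in seq_len(n_blocks)) {
    b_start <- (b - 1L) * block_size + 1L
    b_end <- min(b * block_size, n)
    overlap <- starts <= b_end & ends >= b_start
    block_means[b] <- max(win_means[overlap])
  }
  structure(list(block_means = block_means,
                 mask = rep(TRUE, n_blocks),
                 block_size = as.integer(block_size)),
            class = "envelope_mask")
}

#' Threshold an envelope into an informative-block mask
#'
#' A block is informative when its retained block mean is at least the
#' threshold; blocks whose maximal mean falls below it are marked for
#' discard. Equality keeps the block.
#'
#' @param envelope An `envelope_mask` from [block_envelope()].
#' @param threshold Unitless 16-bit-scale threshold (default 100).
#' @return The envelope with its `mask` field set.
#' @export
informative_mask <- function(envelope, threshold = 100) {
  stopifnot(inherits(envelope, "envelope_mask"))
  envelope$mask <- envelope$block_means >= threshold
  envelope
}

#' Remove uninformative (low-power) audio
#'
#' Drops every block whose retained block mean falls below the threshold
#' and concatenates the surviving blocks; nothing is supplemented for the
#' discarded stretches. Downstream featurization works in the frequency
#' domain, so the missing time-domain stretches do not disturb it.
#'
#' @param segment An [audio_segment].
#' @param block_size Samples per block (default 1100).
#' @param threshold Discard threshold on the block means (default 100).
#' @param n_offsets Staggered offsets passed to [block_envelope()].
#' @return The segment with uninformative blocks removed (possibly empty).
#' @export
remove_uninformative <- function(segment, block_size = 1100L,
                                 threshold = 100, n_offsets = 4L) {
  n <- length(segment$samples)
  if (n == 0L) return(segment)
  env <- informative_mask(
    block_envelope(segment$samples, block_size, n_offsets), threshold)
  keep <- rep(FALSE, n)
  for (b in which(env$mask)) {
    b_start <- (b - 1L) * block_size + 1L
    b_end <- min(b * block_size, n)
    keep[b_start:b_end] <- TRUE
  }
  out <- segment
  out$samples <- segment$samples[keep]
  out
}
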