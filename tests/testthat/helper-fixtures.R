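# Shared fixtures, all generated in code at test time.

make_tone <- function(freq, duration = 1, amp = 16384, rate = 22050) {
  audio_segment(round(amp * sin(2 * pi * freq * (seq_len(round(duration * rate)) - 1) / rate)),
                rate = rate)
}

rms <- function(segment) sqrt(mean(as.numeric(segment$samples)^2))

# absolute-magnitude spectral energy in [lo, hi] Hz, per second of audio
band_energy <- function(segment, lo, hi) {
  a <- abs(stats::fft(normalize_amplitude(segment$samples)))
  m <- length(a) %/% 2L + 1L
  f <- (seq_len(m) - 1) * segment$rate / length(segment$samples)
  sum(a[seq_len(m)][f >= lo & f <= hi]) / duration_s(segment)
}

# a tiny labeled feature set for model tests: three well-separated
# synthetic behaviors at a reduced t_fixed so training stays fast
tiny_feature_set <- function(n_per_class = 8, t_fixed = 12, seed = 100) {
  specs <- default_sound_specs()[c("bite.alfalfa.short", "chew.alfalfa.short",
                                   "chew_bite.alfalfa.short")]
  feats <- list(); labels <- character(0)
  i <- 0L
  for (sp in specs) {
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      seg <- generate_segment(sp, seed + i)
      feats[[i]] <- to_fixed_input(log_mel_spectrogram(seg), t_fixed)
      labels[i] <- sp$behavior
    }
  }
  list(x = feats, y = labels)
}

# fixed small manifest for dataset-op tests
toy_manifest <- function(n_bite = 6, n_chew = 10, n_cb = 8) {
  counts <- c(bite = n_bite, chew = n_chew, chew_bite = n_cb)
  do.call(rbind, lapply(names(counts), function(b) {
    data.frame(file = sprintf("%s_%03d.wav", b, seq_len(counts[[b]])),
               behavior = b,
               forage_species = rep_len(c("alfalfa", "tall_fescue"), counts[[b]]),
               forage_height = rep_len(c("tall", "short"), counts[[b]]),
               duration_s = 0.2 + seq_len(counts[[b]]) / 100,
               stringsAsFactors = FALSE)
  }))
}
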