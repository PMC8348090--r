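test_that("framing follows floor((N - win)/hop) + 1 with zero-padding of short input", {
  expect_equal(nrow(frame_signal(numeric(22050))), 98L)
  expect_equal(nrow(frame_signal(numeric(512))), 1L)
  f <- frame_signal(rep(1, 511))
  expect_equal(dim(f), c(1L, 512L))
  expect_equal(f[1, 512], 0)  # padded tail

  # brute-force sliding-window oracle over a range of lengths
  brute <- function(n) {
    n <- max(n, 512)
    count <- 0L; s <- 1L
    while (s + 511 <= n) { count <- count + 1L; s <- s + 220L }
    count
  }
  lens <- c(1:5, 511, 512, 513, 731, 732, 733, seq(1000, 5000, by = 97))
  for (n in lens) {
    expect_equal(nrow(frame_signal(numeric(n))), brute(n), info = paste("N =", n))
  }
})

test_that("power spectrogram has 257 bins, obeys Parseval, and locates tones", {
  cfg <- stft_config()
  frames <- frame_signal(make_tone(2000)$samples / 65536, cfg)
  pow <- power_spectrogram(frames, cfg)
  expect_equal(ncol(pow), 257L)
  expect_equal(which.max(pow[5, ]) - 1L, round(2000 * 512 / 22050))

  # Parseval: FFT power sums to n x windowed-frame energy (real signal:
  # count the mirrored bins twice)
  w <- jawdio:::stft_window(cfg)
  fr <- frames[7, ] * w
  full <- sum(pow[7, ]) + sum(pow[7, 2:256])
  expect_equal(full, 512 * sum(fr^2), tolerance = 1e-8)

  zero <- power_spectrogram(matrix(0, 1, 512), cfg)
  expect_true(all(zero == 0))
})

test_that("mel filterbank is triangular, ordered, and low-frequency dense", {
  fb <- mel_filterbank(mel_config(), 22050, 512L)
  expect_equal(dim(fb), c(26L, 257L))
  expect_true(all(fb >= 0))

  centers <- apply(fb, 1, which.max)
  expect_true(all(diff(centers) > 0))
  # more centers below 1 kHz than a linear spacing would give
  center_hz <- (centers - 1) * 22050 / 512
  expect_gt(sum(center_hz < 1000), 26 * 1000 / 11025)

  # unimodal rows: rise then fall
  for (m in c(1, 13, 26)) {
    row <- fb[m, ]
    peak <- which.max(row)
    expect_true(all(diff(row[1:peak]) >= 0))
    expect_true(all(diff(row[peak:length(row)]) <= 0))
  }

  # coverage: every bin between the first and last filter edges is touched
  sums <- colSums(fb)
  inner <- which(sums > 0)
  expect_true(all(sums[min(inner):max(inner)] > 0))

  expect_error(mel_filterbank(mel_config(n_mels = 260L), 22050, 512L), "n_mels")
})

test_that("log-Mel spectrogram scales in dB and floors silence", {
  seg <- generate_segment(default_sound_specs()[[1]], 12)
  mel <- log_mel_spectrogram(seg)
  expect_equal(ncol(mel$values), 26L)
  expect_true(all(is.finite(mel$values)))

  silent <- log_mel_spectrogram(audio_segment(rep(0L, 22050)))
  expect_true(all(silent$values == -80))
  expect_equal(dim(silent$values), c(98L, 26L))

  # doubling the input raises dB values by 20*log10(2) where above floor
  seg2 <- audio_segment(seg$samples %/% 2L)
  seg4 <- audio_segment(seg2$samples * 2L)
  m2 <- log_mel_spectrogram(seg2)$values
  m4 <- log_mel_spectrogram(seg4)$values
  above <- m2 > -60 & m4 > -60
  expect_true(mean(abs((m4 - m2)[above] - 20 * log10(2))) < 0.01)

  expect_error(log_mel_spectrogram(audio_segment(integer(0))), "empty")

  # determinism: identical inputs give bit-identical matrices
  expect_identical(log_mel_spectrogram(seg)$values, mel$values)
})

test_that("optional DCT path yields cepstral coefficients", {
  seg <- generate_segment(default_sound_specs()[[2]], 9)
  cep <- log_mel_spectrogram(seg, mel_cfg = mel_config(use_dct = TRUE))
  mel <- log_mel_spectrogram(seg)
  expect_equal(dim(cep$values), dim(mel$values))
  # orthonormal DCT preserves per-frame energy
  expect_equal(rowSums(cep$values^2), rowSums(mel$values^2), tolerance = 1e-8)
})

test_that("to_fixed_input crops centrally and pads symmetrically at the floor", {
  m <- matrix(as.numeric(seq_len(10 * 26)), 10, 26)
  expect_identical(to_fixed_input(m, 10), m)

  padded <- to_fixed_input(m, 20)
  expect_equal(dim(padded), c(20L, 26L))
  expect_true(all(padded[1:5, ] == -80))
  expect_true(all(padded[16:20, ] == -80))
  expect_identical(padded[6:15, ], m)

  big <- matrix(rnorm(200 * 26), 200, 26)
  cropped <- to_fixed_input(big, 98)
  expect_identical(cropped, big[52:149, ])
})
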