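test_that("generated segments follow the spec distribution and are deterministic", {
  spec <- class_sound_spec("bite", "tall_fescue", "short",
                           mean_amplitude = 0.488, mean_duration = 0.205,
                           amplitude_sd = 0.085, duration_sd = 0.03)
  a <- generate_segment(spec, 7)
  b <- generate_segment(spec, 7)
  expect_identical(a$samples, b$samples)
  expect_equal(a$rate, 22050L)
  expect_equal(a$behavior, "bite")

  # degenerate sds: every draw identical in amplitude and duration
  fixed <- class_sound_spec("chew", "alfalfa", "tall",
                            mean_amplitude = 0.2, mean_duration = 0.1)
  descr <- lapply(1:5, function(s) segment_descriptors(generate_segment(fixed, s)))
  expect_equal(length(unique(vapply(descr, `[[`, 0, "duration"))), 1L)
  amps <- vapply(descr, `[[`, 0, "amplitude")
  expect_true(all(abs(amps - 0.2) < 2 / 65536))  # integer rounding only
})

test_that("segment energy is confined to the carrier band", {
  spec <- class_sound_spec("chew", "alfalfa", "short", 0.3, 0.2,
                           carrier_band = c(100, 800))
  seg <- generate_segment(spec, 3)
  total <- band_energy(seg, 0, 11025)
  inband <- band_energy(seg, 90, 810)
  expect_gt(inband / total, 0.95)
})

test_that("behavior classes are separable by a trivial threshold classifier", {
  specs <- default_sound_specs()
  correct <- unlist(lapply(seq_along(specs), function(k) {
    vapply(1:17, function(j) {
      seg <- generate_segment(specs[[k]], 1000 * k + j)
      d <- segment_descriptors(seg)
      pred <- if (d$amplitude < 0.2) "chew"
              else if (d$duration < 0.222) "bite" else "chew_bite"
      pred == specs[[k]]$behavior
    }, NA)
  }))
  expect_gte(mean(correct), 0.8)
})

test_that("beep injection adds a tone at the beep frequency and clips safely", {
  silence <- audio_segment(rep(0L, 22050))
  beeped <- inject_beep(silence, beep_spec(4000, rate = 1), 7)
  expect_false(all(beeped$samples == 0L))
  sp <- anm_spectrum(beeped)
  peak_freq <- sp$bin_freqs[which.max(sp$magnitudes)]
  expect_lt(abs(peak_freq - 4000), 22050 / 22050 + 1e-9)

  # rate 0 is the identity
  expect_identical(inject_beep(silence, beep_spec(rate = 0), 1)$samples,
                   silence$samples)

  # overflow-level beep is clipped to the int16 range
  loud <- audio_segment(rep(30000L, 22050))
  clipped <- inject_beep(loud, beep_spec(4000, level = 1, rate = 5), 3)
  expect_true(all(clipped$samples <= 32767L & clipped$samples >= -32768L))
})

test_that("beep spec validates its frequency range", {
  expect_error(beep_spec(3000), "3600")
  expect_error(beep_spec(5000), "3600")
  expect_error(class_sound_spec("bite", "alfalfa", "tall", 1.5, 0.2), "0, 1")
  expect_error(class_sound_spec("bite", "alfalfa", "tall", 0.5, 0.2,
                                carrier_band = c(100, 12000)), "11025")
})

test_that("generate_dataset writes a faithful, reproducible corpus", {
  specs <- default_sound_specs()[c(1, 5, 9)]  # one cell per behavior
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_dataset(specs, c(2, 3, 4), d1, seed = 5)
  m2 <- generate_dataset(specs, c(2, 3, 4), d2, seed = 5)
  expect_equal(nrow(m1), 9L)
  expect_equal(as.vector(table(factor(m1$behavior, levels = c("bite", "chew", "chew_bite")))),
               c(2L, 3L, 4L))
  expect_equal(m1, m2)
  for (f in m1$file) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  # re-reading reproduces durations recorded in the manifest
  seg <- read_wav(file.path(d1, m1$file[1]))
  expect_equal(duration_s(seg), m1$duration_s[1])

  m3 <- generate_dataset(specs, 1, withr::local_tempdir(), seed = 1)
  expect_equal(nrow(m3), 3L)
  expect_setequal(m3$behavior, c("bite", "chew", "chew_bite"))
})
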