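test_that("bandstop filter attenuates the beep band and passes low frequencies", {
  spec <- bandstop_spec()
  # the designed filter's own frequency response is the oracle
  expect_lt(jawdio:::bandstop_response_db(spec, 4000), -30)
  expect_gt(jawdio:::bandstop_response_db(spec, 500), -1)

  tone4k <- make_tone(4000, amp = 16384)
  tone500 <- make_tone(500, amp = 16384)
  atten_4k <- 20 * log10(rms(bandstop_filter(tone4k, spec)) / rms(tone4k))
  change_500 <- 20 * log10(rms(bandstop_filter(tone500, spec)) / rms(tone500))
  expect_lt(atten_4k, -30)
  expect_lt(abs(change_500), 1)

  zeros <- audio_segment(rep(0L, 2000))
  expect_true(all(bandstop_filter(zeros, spec)$samples == 0L))

  expect_error(bandstop_filter(audio_segment(rep(10L, 10)), spec), "too short")
  expect_error(bandstop_spec(4500, 3600), "stop_low")
})

test_that("block envelope retains staggered-window maxima per block", {
  const <- rep(200L, 2200)
  env <- block_envelope(const)
  expect_equal(env$block_means, c(200, 200))
  expect_equal(block_envelope(rep(0L, 3300))$block_means, c(0, 0, 0))

  # loud first block, silent second: a straddling window lifts block 2
  x <- c(rep(500L, 1100), rep(0L, 1100))
  env <- block_envelope(x, n_offsets = 4)
  # brute-force oracle: enumerate all window means at offset step 275
  starts <- seq(1, 2200, by = 275)
  wm <- vapply(starts, function(s) {
    e <- min(s + 1099, 2200); mean(abs(x[s:e]))
  }, 0)
  ends <- pmin(starts + 1099, 2200)
  brute <- vapply(1:2, function(b) {
    lo <- (b - 1) * 1100 + 1; hi <- b * 1100
    max(wm[starts <= hi & ends >= lo])
  }, 0)
  expect_equal(env$block_means, brute)
  expect_gt(env$block_means[2], 0)  # plain mean of block 2 would be 0
})

test_that("informative mask thresholds block means with >= kept", {
  env <- structure(list(block_means = c(200, 50, 100), mask = rep(TRUE, 3),
                        block_size = 1100L), class = "envelope_mask")
  expect_equal(informative_mask(env, 100)$mask, c(TRUE, FALSE, TRUE))
  expect_equal(informative_mask(env, 1000)$mask, rep(FALSE, 3))
  expect_equal(informative_mask(env, 0)$mask, rep(TRUE, 3))

  # monotone: raising the threshold never adds a TRUE block
  set.seed(42)
  env$block_means <- runif(3, 0, 300)
  thresholds <- sort(runif(10, 0, 300))
  masks <- lapply(thresholds, function(th) informative_mask(env, th)$mask)
  for (i in seq_len(length(masks) - 1)) {
    expect_true(all(masks[[i]] | !masks[[i + 1]]))
  }
})

test_that("uninformative-data removal drops silent blocks and nothing else", {
  # the widest straddling window holds 825 loud samples, mean 0.75 * 120 =
  # 90 < 100, so no window can rescue the silent blocks
  loud_then_silent <- audio_segment(c(rep(120L, 2200), rep(0L, 22000)))
  out <- remove_uninformative(loud_then_silent)
  expect_identical(out$samples, rep(120L, 2200))

  const <- audio_segment(rep(200L, 5500))
  expect_identical(remove_uninformative(const)$samples, const$samples)

  silent <- audio_segment(rep(0L, 5500))
  expect_length(remove_uninformative(silent)$samples, 0L)
})

test_that("removal matches a brute-force mask on randomized block signals", {
  set.seed(7)
  for (trial in 1:5) {
    n_blocks <- sample(3:8, 1)
    levels <- sample(c(0, 30, 80, 150, 400), n_blocks, replace = TRUE)
    x <- unlist(lapply(levels, function(l) {
      as.integer(round(l * abs(rnorm(1100)) / mean(abs(rnorm(10000)))))
    }))
    seg <- audio_segment(pmin(x, 32767L))
    out <- remove_uninformative(seg, n_offsets = 4)
    # brute force: all window means at step 275, per-block maxima, >= 100
    n <- length(seg$samples)
    starts <- seq(1, n, by = 275)
    ends <- pmin(starts + 1099, n)
    wm <- vapply(seq_along(starts), function(i) {
      mean(abs(seg$samples[starts[i]:ends[i]]))
    }, 0)
    keep <- unlist(lapply(seq_len(ceiling(n / 1100)), function(b) {
      lo <- (b - 1) * 1100 + 1; hi <- min(b * 1100, n)
      if (max(wm[starts <= hi & ends >= lo]) >= 100) lo:hi else integer(0)
    }))
    expect_identical(out$samples, seg$samples[keep])
  }
})

test_that("removal shortens, never lengthens, and is idempotent on real signals", {
  specs <- default_sound_specs()
  for (k in c(1, 6, 11)) {
    seg <- generate_segment(specs[[k]], 300 + k)
    once <- remove_uninformative(seg)
    twice <- remove_uninformative(once)
    expect_lte(length(once$samples), length(seg$samples))
    expect_identical(twice$samples, once$samples)
  }
})

test_that("cleaning removes beep-band energy while preserving the low band", {
  spec <- default_sound_specs()[["chew.tall_fescue.tall"]]
  checked <- 0L
  for (j in 1:6) {
    seg <- generate_segment(spec, j)
    beeped <- inject_beep(seg, beep_spec(4000, rate = 30, level = 0.3), j + 99)
    if (identical(beeped$samples, seg$samples)) next  # no beep drawn
    cleaned <- remove_uninformative(bandstop_filter(beeped))
    beep_removed <- 1 - band_energy(cleaned, 3600, 4500) /
      band_energy(beeped, 3600, 4500)
    low_change <- abs(band_energy(cleaned, 0, 1000) /
                        band_energy(beeped, 0, 1000) - 1)
    expect_gte(beep_removed, 0.9)
    expect_lte(low_change, 0.1)
    checked <- checked + 1L
  }
  expect_gte(checked, 3L)
})
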