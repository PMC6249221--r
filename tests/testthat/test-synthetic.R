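test_that("parameter validation rejects out-of-range settings", {
  expect_error(synth_params(sh_center_hz = 1), "sh_center_hz")
  expect_error(synth_params(sh_center_hz = 9), "sh_center_hz")
  expect_error(synth_params(nsh_rate_bpm = 30), "nsh_rate_bpm")
  expect_error(synth_params(fs = 250, seg_len_s = 0.0003), "positive integer")
  expect_error(synth_params(wander_hz = 1.5), "wander_hz")
})

test_that("NSH segments have the right length, QRS count and spectral placement", {
  seg <- gen_nsh_segment(synth_params(seed = 1))
  expect_length(seg$samples, 2000L)
  expect_identical(seg$label, 0L)
  amax <- spec_argmax(seg$samples, 250, band = c(1, 30))
  expect_gte(amax, 4)
  expect_lte(amax, 20)

  # clean 60 bpm train: exactly 8 QRS wavelets in 8 s, counted as excursions
  # above half the maximum (P/T bumps stay far below that level)
  clean <- gen_nsh_segment(synth_params(nsh_rate_bpm = 60, noise_sd = 0,
                                        wander_amp = 0, seed = 2))
  r <- rle(clean$samples > 0.5 * max(clean$samples))
  expect_identical(sum(r$values), 8L)
})

test_that("segment generation is bit-reproducible under a fixed seed", {
  p <- synth_params(seed = 7)
  expect_identical(gen_nsh_segment(p)$samples, gen_nsh_segment(p)$samples)
  p$sh_kind <- "VF"
  expect_identical(gen_sh_segment(p)$samples, gen_sh_segment(p)$samples)
  p2 <- p
  p2$seed <- 8
  expect_false(identical(gen_sh_segment(p)$samples, gen_sh_segment(p2)$samples))
})

test_that("VF-like segments concentrate power near the center frequency", {
  seg <- gen_sh_segment(synth_params(sh_center_hz = 4, seed = 2))
  expect_identical(seg$label, 1L)
  amax <- spec_argmax(seg$samples, 250, band = c(1, 30))
  expect_lt(abs(amax - 4), 1)
  # periodogram integration: essentially no power above 10 Hz
  expect_lt(band_power_fraction(seg$samples, 250, cutoff = 10), 0.2)
})

test_that("clean VT-like trains have their fundamental at rate/60 Hz", {
  seg <- gen_sh_segment(synth_params(sh_kind = "VT", vt_rate_bpm = 150,
                                     noise_sd = 0, wander_amp = 0, seed = 3))
  # 8 s window -> 0.125 Hz bins; a periodic train at 2.5 Hz puts all
  # in-band power on exact multiples of 2.5 Hz
  n <- length(seg$samples)
  pw <- Mod(fft(seg$samples))[seq_len(n / 2)]^2
  freqs <- (seq_len(n / 2) - 1) * 250 / n
  inband <- freqs >= 1 & freqs <= 30
  harmonics <- inband & (freqs %% 2.5 < 1e-9)
  expect_gt(sum(pw[harmonics]) / sum(pw[inband]), 0.99)
  expect_gt(pw[freqs == 2.5], 0)
})

test_that("spectral contract holds across many seeded segments", {
  vf_ok <- vapply(1:100, function(s) {
    x <- gen_sh_segment(synth_params(seed = s))$samples
    spec_argmax(x, 250, band = c(1, 30)) < 10
  }, logical(1))
  nsh_ok <- vapply(1:100, function(s) {
    x <- gen_nsh_segment(synth_params(seed = 10000 + s))$samples
    a <- spec_argmax(x, 250, band = c(1, 30))
    a >= 4 && a <= 20
  }, logical(1))
  expect_gte(mean(vf_ok), 0.95)
  expect_gte(mean(nsh_ok), 0.95)
})

test_that("record sets have the advertised structure and label counts", {
  p <- synth_params(seed = 3)
  recs <- gen_record_set(10, 20, 0.2, p)
  expect_length(recs, 10L)
  expect_length(unique(vapply(recs, function(r) r$record_id, character(1))),
                10L)
  truth <- attr(recs, "truth")
  expect_identical(nrow(truth), 200L)
  expect_identical(sum(truth$label), 40L)
  # each record is segs_per_record concatenated 8 s segments
  expect_true(all(vapply(recs, function(r) length(r$samples), numeric(1)) ==
                    20 * 2000))

  none <- gen_record_set(3, 4, 0, synth_params(seed = 4))
  expect_true(all(attr(none, "truth")$rhythm == "N"))

  a <- gen_record_set(3, 4, 0.5, synth_params(seed = 5))
  b <- gen_record_set(3, 4, 0.5, synth_params(seed = 6))
  expect_identical(sum(attr(a, "truth")$label), sum(attr(b, "truth")$label))
  expect_false(identical(a[[1]]$samples, b[[1]]$samples))

  expect_error(gen_record_set(1, 4, 0.5, p), "n_records")
  expect_error(gen_record_set(4, 4, 1.2, p), "sh_fraction")
})
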