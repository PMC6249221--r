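test_that("segmentation uses floor division and drops the remainder", {
  rec <- ecg_record("long", rnorm(120000, 0, 0.1), 250)
  segs <- segment_record(rec, 8)
  expect_length(segs, 60L)
  expect_true(all(vapply(segs, function(s) length(s$samples), numeric(1)) ==
                    2000))
  starts <- vapply(segs, function(s) s$start, integer(1))
  expect_identical(starts, seq(0L, by = 2000L, length.out = 60L))

  rec2 <- ecg_record("short", rnorm(2017), 250)
  expect_length(segment_record(rec2, 8), 1L)

  rec3 <- ecg_record("tiny", rnorm(100), 250)
  expect_warning(out <- segment_record(rec3, 8), "shorter")
  expect_length(out, 0L)
})

test_that("segment labels round-trip the generator's ground truth", {
  recs <- gen_record_set(4, 6, 0.5, synth_params(seed = 21))
  truth <- attr(recs, "truth")
  segs <- unlist(lapply(recs, segment_record), recursive = FALSE)
  got <- data.frame(
    record_id = vapply(segs, function(s) s$record_id, character(1)),
    start = vapply(segs, function(s) as.integer(s$start), integer(1)),
    label = vapply(segs, function(s) s$label, integer(1)))
  merged <- merge(truth, got, by = c("record_id", "start"))
  expect_identical(nrow(merged), nrow(truth))
  expect_identical(merged$label.x, merged$label.y)
})

test_that("dominant-rhythm labeling breaks ties toward the shockable class", {
  ann <- data.frame(sample = c(0L, 1000L), rhythm = c("N", "VF"))
  rec <- ecg_record("tie", rnorm(2000, 0, 0.3), 250, ann)
  segs <- segment_record(rec, 8)
  expect_identical(segs[[1]]$label, 1L)
  expect_identical(segs[[1]]$rhythm, "VF")
})

test_that("exclusion rules remove low-amplitude VF, slow VT and noisy windows", {
  p2 <- synth_params(seed = 23)
  vf <- gen_sh_segment(p2)
  vf$samples <- vf$samples * 0.15 / diff(range(vf$samples))  # p2p 150 uV
  slow_vt <- gen_sh_segment(synth_params(sh_kind = "VT", vt_rate_bpm = 120,
                                         noise_sd = 0, wander_amp = 0,
                                         seed = 24))
  fast_vt <- gen_sh_segment(synth_params(sh_kind = "VT", vt_rate_bpm = 190,
                                         noise_sd = 0, wander_amp = 0,
                                         seed = 25))
  nsh <- gen_nsh_segment(synth_params(seed = 26))
  noisy <- ecg_segment("x", 0L, rnorm(2000), 250, 0L, rhythm = "noise")
  asys <- ecg_segment("x", 0L, rnorm(2000, 0, 0.01), 250, 0L,
                      rhythm = "asystole")
  trans <- ecg_segment("x", 0L, rnorm(2000), 250, 0L, rhythm = "transition")

  kept <- apply_exclusions(list(vf, slow_vt, fast_vt, nsh, noisy, asys, trans),
                           fs = 250)
  tab <- attr(kept, "exclusions")
  expect_identical(tab$reason[1], "low-amplitude VF")
  expect_identical(tab$reason[2], "slow VT")
  expect_identical(tab$reason[5:7], c("noise", "asystole", "transition"))
  expect_length(kept, 2L)  # fast VT and the clean NSH survive
  expect_setequal(vapply(kept, function(s) s$rhythm, character(1)),
                  c("VT", "N"))

  expect_error(apply_exclusions(list(nsh)), "fs")
})

test_that("the filter chain rejects DC and stopband tones and keeps length", {
  fs <- 250
  t <- (0:1999) / fs
  # constant input: high-pass removes DC entirely
  y0 <- preprocess_segment(rep(1, 2000), fs)
  expect_length(y0, 2000L)
  expect_lt(max(abs(y0)), 1e-6)

  rms <- function(v) sqrt(mean(v^2))
  for (f in c(0.3, 45)) {
    x <- sin(2 * pi * f * t)
    y <- preprocess_segment(x, fs)
    expect_lt(rms(y) / rms(x), 0.10)
  }

  # passband: measured gain at 10 Hz agrees with the chain's closed-form
  # magnitude response (edge transients excluded) and stays above 70%
  x10 <- sin(2 * pi * 10 * t)
  y10 <- preprocess_segment(x10, fs)
  core <- 251:1750
  g_meas <- rms(y10[core]) / rms(x10[core])
  g_theory <- preprocess_response(10, fs)
  expect_gt(g_meas, 0.70)
  expect_lt(abs(g_meas - g_theory), 0.02)
})

test_that("preprocessing rejects non-finite input and preserves ecg_segment class", {
  expect_error(preprocess_segment(c(1, NA, 3), 250), "non-finite")
  seg <- gen_nsh_segment(synth_params(seed = 30))
  out <- preprocess_segment(seg)
  expect_s3_class(out, "ecg_segment")
  expect_length(out$samples, length(seg$samples))
})

test_that("re-segmenting concatenated segments reproduces the boundaries", {
  recs <- gen_record_set(2, 5, 0.4, synth_params(seed = 31))
  segs <- segment_record(recs[[1]], 8)
  rebuilt <- ecg_record("rebuilt", unlist(lapply(segs, `[[`, "samples")), 250,
                        recs[[1]]$annotations)
  segs2 <- segment_record(rebuilt, 8)
  expect_length(segs2, length(segs))
  for (i in seq_along(segs))
    expect_identical(segs2[[i]]$samples, segs[[i]]$samples)
})
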