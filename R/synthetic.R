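#' Parameters for the synthetic ECG generator
#'
#' Bundles the knobs of the built-in generator of labeled shockable (SH) and
#' non-shockable (NSH) ECG segments. The generator reproduces the spectral
#' structure the channel-construction step relies on: QRS-complex trains whose
#' magnitude-spectrum maximum falls between 4 and 20 Hz for NSH rhythms, and
#' fibrillation-like oscillations with the spectral maximum near 4 Hz and
#' negligible power above 10 Hz for SH rhythms. Amplitudes are in millivolts,
#' with NSH QRS peak-to-peak around 1 mV and VF around 0.7 mV, comfortably
#' above the 200 uV exclusion floor applied to VF.
#'
#' @param fs sampling rate in Hz (default 250).
#' @param seg_len_s segment length in seconds (default 8; `fs * seg_len_s`
#'   must be a positive integer, 2000 at the defaults).
#' @param nsh_rate_bpm heart rate of the synthetic QRS train, beats/min
#'   (>= 40; default 75).
#' @param sh_center_hz dominant frequency of the VF-like oscillation in Hz,
#'   must lie in (2, 8) (default 4).
#' @param sh_kind `"VF"` (amplitude/frequency-modulated oscillation) or
#'   `"VT"` (monomorphic wide-complex train).
#' @param vt_rate_bpm rate of the VT-like train, beats/min (default 180).
#' @param noise_sd standard deviation of additive Gaussian noise, mV
#'   (default 0.02).
#' @param wander_amp amplitude of the sinusoidal baseline wander, mV
#'   (default 0.05).
#' @param wander_hz baseline-wander frequency in Hz, below 1 Hz
#'   (default 0.3).
#' @param seed integer RNG seed; identical parameters and seed give
#'   bit-identical segments. `NULL` draws from the current RNG stream.
#' @return an object of class `synth_params`.
#' @export
synth_params <- function(fs = 250, seg_len_s = 8, nsh_rate_bpm = 75,
                         sh_center_hz = 4, sh_kind = c("VF", "VT"),
                         vt_rate_bpm = 180, noise_sd = 0.02,
                         wander_amp = 0.05, wander_hz = 0.3, seed = NULL) {
  sh_kind <- match.arg(sh_kind)
  n <- fs * seg_len_s
  if (fs <= 0 || seg_len_s <= 0 || abs(n - round(n)) > 1e-9 || n < 2)
    stop("fs * seg_len_s must be a positive integer")
  if (sh_center_hz <= 2 || sh_center_hz >= 8)
    stop("sh_center_hz must lie in (2, 8)")
  if (nsh_rate_bpm < 40) stop("nsh_rate_bpm must be >= 40")
  if (vt_rate_bpm <= 0) stop("vt_rate_bpm must be positive")
  if (noise_sd < 0 || wander_amp < 0) stop("noise/wander scales must be >= 0")
  if (wander_hz >= 1 || wander_hz <= 0)
    stop("wander_hz must lie in (0, 1) Hz")
  structure(list(fs = fs, seg_len_s = seg_len_s, n = as.integer(round(n)),
                 nsh_rate_bpm = nsh_rate_bpm, sh_center_hz = sh_center_hz,
                 sh_kind = sh_kind, vt_rate_bpm = vt_rate_bpm,
                 noise_sd = noise_sd, wander_amp = wander_amp,
                 wander_hz = wander_hz, seed = seed),
            class = "synth_params")
}

# Mexican-hat (Ricker) wavelet; sigma in seconds sets the biphasic QRS width
# (~4*sigma) and the spectral peak sqrt(2)/(2*pi*sigma).
ricker <- function(t, sigma) {
  u <- t / sigma
  (1 - u^2) * exp(-u^2 / 2)
}

# common additive nuisance terms, drawn from the active RNG stream
add_nuisance <- function(x, t, params) {
  if (params$wander_amp > 0) {
    x <- x + params$wander_amp *
      sin(2 * pi * params$wander_hz * t + stats::runif(1, 0, 2 * pi))
  }
  if (params$noise_sd > 0) {
    x <- x + stats::rnorm(length(t), 0, params$noise_sd)
  }
  x
}

#' Generate a non-shockable synthetic ECG segment
#'
#' A QRS-like train of narrow biphasic (Ricker) wavelets at `nsh_rate_bpm`
#' with small P- and T-like Gaussian bumps, baseline wander and Gaussian
#' noise. The QRS wavelet width (sigma = 20 ms) places the spectral envelope
#' maximum near 11 Hz, so the magnitude-spectrum argmax over 1--30 Hz falls
#' in the 4--20 Hz band characteristic of QRS complexes.
#'
#' @param params a [synth_params()] object.
#' @return an [ecg_segment()] with label 0 and rhythm `"N"`.
#' @export
gen_nsh_segment <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  with_seed(params$seed, {
    t <- (seq_len(params$n) - 1) / params$fs
    period <- 60 / params$nsh_rate_bpm
    beats <- seq(period / 2, params$seg_len_s, by = period)
    beats <- beats[beats <= max(t)]
    sigma_qrs <- 0.02
    x <- numeric(params$n)
    for (tb in beats) {
      x <- x + 0.7 * ricker(t - tb, sigma_qrs) +
        0.06 * exp(-((t - tb - 0.26)^2) / (2 * 0.05^2)) +  # T-like bump
        0.03 * exp(-((t - tb + 0.17)^2) / (2 * 0.03^2))    # P-like bump
    }
    x <- add_nuisance(x, t, params)
    ecg_segment("synthetic", 0L, x, params$fs, 0L, rhythm = "N")
  })
}

#' Generate a shockable synthetic ECG segment
#'
#' `sh_kind = "VF"` produces a fibrillation-like oscillation: a sinusoid whose
#' instantaneous frequency wanders around `sh_center_hz` following an
#' Ornstein--Uhlenbeck process (relaxation 0.5 /s, stationary sd 0.4 Hz) with
#' slow amplitude modulation, keeping essentially all power below 10 Hz.
#' `sh_kind = "VT"` produces a monomorphic wide-complex train (sigma = 50 ms
#' Ricker wavelets) at `vt_rate_bpm`, whose fundamental is `vt_rate_bpm/60` Hz.
#'
#' @param params a [synth_params()] object.
#' @return an [ecg_segment()] with label 1 and rhythm `"VF"` or `"VT"`.
#' @export
gen_sh_segment <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  with_seed(params$seed, {
    t <- (seq_len(params$n) - 1) / params$fs
    if (params$sh_kind == "VF") {
      dt <- 1 / params$fs
      theta <- 0.5
      sd_f <- 0.4
      dev <- numeric(params$n)
      eps <- stats::rnorm(params$n - 1)
      sig_ou <- sd_f * sqrt(2 * theta)
      for (i in seq_len(params$n - 1)) {
        dev[i + 1] <- dev[i] - theta * dev[i] * dt + sig_ou * sqrt(dt) * eps[i]
      }
      freq <- pmin(pmax(params$sh_center_hz + dev, 2.2), 9.5)
      phase <- 2 * pi * cumsum(freq) / params$fs
      amp <- 0.28 * (1 + 0.25 * sin(2 * pi * 0.25 * t +
                                      stats::runif(1, 0, 2 * pi)))
      x <- amp * sin(phase)
      rhythm <- "VF"
    } else {
      period <- 60 / params$vt_rate_bpm
      beats <- seq(period / 2, params$seg_len_s, by = period)
      beats <- beats[beats <= max(t)]
      x <- numeric(params$n)
      for (tb in beats) x <- x + 0.8 * ricker(t - tb, 0.05)
      rhythm <- "VT"
    }
    x <- add_nuisance(x, t, params)
    ecg_segment("synthetic", 0L, x, params$fs, 1L, rhythm = rhythm)
  })
}

#' Generate a multi-record synthetic dataset
#'
#' Emulates the patient-per-record structure of the public arrhythmia
#' databases: each record is a concatenation of labeled 8-s segments with a
#' per-record annotation track marking the rhythm at each segment onset.
#' Record IDs are unique; the per-record SH segment count is
#' `round(segs_per_record * sh_fraction)`, so label counts are identical
#' across seeds while the waveforms differ.
#'
#' @param n_records number of records (>= 2).
#' @param segs_per_record segments concatenated into each record.
#' @param sh_fraction proportion of shockable segments per record, in
#'   `[0, 1]`.
#' @param params a [synth_params()] object; its `seed` drives all randomness.
#' @return a list of [ecg_record()] objects; attribute `truth` is a data
#'   frame with one row per generated segment (`record_id`, `start`,
#'   `label`, `rhythm`).
#' @export
gen_record_set <- function(n_records, segs_per_record, sh_fraction,
                           params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  if (n_records < 2) stop("n_records must be >= 2")
  if (sh_fraction < 0 || sh_fraction > 1)
    stop("sh_fraction must lie in [0, 1]")
  with_seed(params$seed, {
    n_sh <- round(segs_per_record * sh_fraction)
    records <- vector("list", n_records)
    truth <- list()
    for (i in seq_len(n_records)) {
      labels <- sample(c(rep(1L, n_sh), rep(0L, segs_per_record - n_sh)))
      seg_seeds <- sample.int(.Machine$integer.max - 1L, segs_per_record)
      samples <- vector("list", segs_per_record)
      ann <- data.frame(sample = integer(), rhythm = character())
      rid <- sprintf("R%03d", i)
      for (j in seq_len(segs_per_record)) {
        p <- params
        p$seed <- seg_seeds[j]
        seg <- if (labels[j] == 1L) gen_sh_segment(p) else gen_nsh_segment(p)
        samples[[j]] <- seg$samples
        start <- (j - 1L) * params$n
        ann <- rbind(ann, data.frame(sample = start, rhythm = seg$rhythm))
        truth[[length(truth) + 1L]] <-
          data.frame(record_id = rid, start = start, label = labels[j],
                     rhythm = seg$rhythm)
      }
      records[[i]] <- ecg_record(rid, unlist(samples), params$fs, ann)
    }
    structure(records, truth = do.call(rbind, truth))
  })
}
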