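#' Cut a record into non-overlapping fixed-length segments
#'
#' Divides a record into `floor(length / (fs * seg_len_s))` consecutive
#' non-overlapping windows; the trailing remainder is discarded. Each window
#' is labeled shockable when its dominant annotated rhythm (the rhythm
#' covering the most samples in the window, ties broken toward the shockable
#' class) is VF, VT or ventricular flutter.
#'
#' @param record an [ecg_record()].
#' @param seg_len_s segment length in seconds (default 8).
#' @return a list of [ecg_segment()] objects (empty, with a warning, when the
#'   record is shorter than one segment).
#' @export
segment_record <- function(record, seg_len_s = 8) {
  stopifnot(inherits(record, "ecg_record"))
  n_seg_samp <- as.integer(round(record$fs * seg_len_s))
  n <- length(record$samples)
  if (n < n_seg_samp) {
    warning(sprintf("record %s shorter than one segment; no segments produced",
                    record$record_id))
    return(list())
  }
  n_segs <- n %/% n_seg_samp
  ann <- record$annotations
  # rhythm for every sample (piecewise constant from each onset)
  rhythm_at <- function(from, to) {
    if (!nrow(ann)) return("N")
    idx <- findInterval(from:to, ann$sample)
    idx[idx == 0L] <- 1L
    ann$rhythm[idx]
  }
  sh_codes <- c("VF", "VT", "VFL")
  lapply(seq_len(n_segs) - 1L, function(k) {
    from <- k * n_seg_samp
    rh <- rhythm_at(from, from + n_seg_samp - 1L)
    tab <- table(rh)
    top <- max(tab)
    cand <- names(tab)[tab == top]
    dominant <- if (any(cand %in% sh_codes)) cand[cand %in% sh_codes][1]
                else cand[1]
    ecg_segment(record$record_id, from,
                record$samples[(from + 1L):(from + n_seg_samp)],
                record$fs, as.integer(dominant %in% sh_codes),
                rhythm = dominant)
  })
}

# rate estimate (beats/min) by peak detection on the rectified signal with a
# 150 ms refractory period; used only for the slow-VT exclusion rule
estimate_rate_bpm <- function(x, fs) {
  r <- abs(x - stats::median(x))
  thr <- 0.4 * max(r)
  refract <- round(0.15 * fs)
  # local maxima above threshold
  cand <- which(r >= thr)
  cand <- cand[cand > 1 & cand < length(r)]
  cand <- cand[r[cand] >= r[cand - 1] & r[cand] >= r[cand + 1]]
  if (!length(cand)) return(0)
  # greedy refractory enforcement by amplitude
  keep <- integer()
  for (i in cand[order(r[cand], decreasing = TRUE)]) {
    if (!length(keep) || all(abs(keep - i) >= refract)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  if (length(keep) < 2) return(0)
  60 * (length(keep) - 1) / ((keep[length(keep)] - keep[1]) / fs)
}

#' Apply annotation-driven exclusion rules
#'
#' Flags and removes the segment classes the rhythm-annotation protocol deems
#' untestable: noise/artifact, asystole and transition windows; VT whose
#' estimated rate is below 150 beats/min (slow VT carries no defibrillation
#' benefit); and VF whose peak-to-peak amplitude is below 200 uV. Amplitudes
#' must be calibrated in mV for the 200 uV rule to be meaningful.
#'
#' @param segments list of [ecg_segment()] objects.
#' @param fs sampling rate in Hz (required for the VT rate estimate).
#' @return the retained segments; attribute `exclusions` is a data frame of
#'   every input segment with its `excluded` flag and `reason`.
#' @export
apply_exclusions <- function(segments, fs) {
  if (missing(fs) || is.null(fs) || !is.finite(fs) || fs <= 0)
    stop("fs required: amplitude/rate rules need calibrated sampling")
  noisy <- c("noise", "artifact", "asystole", "transition")
  out <- lapply(segments, function(seg) {
    if (seg$rhythm %in% noisy) {
      seg$excluded <- TRUE
      seg$reason <- seg$rhythm
    } else if (seg$rhythm == "VT") {
      rate <- estimate_rate_bpm(seg$samples, fs)
      if (rate < 150) {
        seg$excluded <- TRUE
        seg$reason <- "slow VT"
      }
    } else if (seg$rhythm %in% c("VF", "VFL")) {
      p2p <- diff(range(seg$samples))
      if (p2p < 0.2) {  # 200 uV on the mV scale
        seg$excluded <- TRUE
        seg$reason <- "low-amplitude VF"
      }
    }
    seg
  })
  tab <- do.call(rbind, lapply(out, function(s)
    data.frame(record_id = s$record_id, start = s$start, label = s$label,
               rhythm = s$rhythm, excluded = s$excluded,
               reason = ifelse(is.na(s$reason), "", s$reason))))
  structure(Filter(function(s) !s$excluded, out), exclusions = tab)
}

# cached Butterworth designs (order 5, high-pass 1 Hz / low-pass 30 Hz)
preproc_filters <- function(fs) {
  list(hp = signal::butter(5, 1 / (fs / 2), type = "high"),
       lp = signal::butter(5, 30 / (fs / 2), type = "low"))
}

#' Preprocess one segment into a pECG
#'
#' The three-stage filter chain producing the preprocessed ECG (pECG):
#' a 5-tap centered moving average (smoothing), a 1 Hz high-pass removing
#' drift and baseline wander, and a 30 Hz Butterworth low-pass suppressing
#' high-frequency interference. The Butterworth stages are order 5 and
#' applied forward-backward (zero phase) so QRS morphology is not skewed.
#' Output length always equals input length.
#'
#' @param segment an [ecg_segment()] or a plain numeric vector.
#' @param fs sampling rate in Hz (taken from the segment when available).
#' @return the same type as the input, with filtered samples.
#' @export
preprocess_segment <- function(segment, fs = NULL) {
  x <- if (inherits(segment, "ecg_segment")) segment$samples else segment
  if (is.null(fs)) {
    if (inherits(segment, "ecg_segment")) fs <- segment$fs
    else stop("fs required for a plain numeric segment")
  }
  if (!all(is.finite(x))) stop("segment contains non-finite samples")
  n <- length(x)
  # centered 5-tap moving average; edges padded by replication
  xp <- c(rep(x[1], 2), x, rep(x[n], 2))
  sm <- as.numeric(stats::filter(xp, rep(1 / 5, 5), sides = 2))[3:(n + 2)]
  flt <- preproc_filters(fs)
  # zero-phase (forward-backward) Butterworth stages realized spectrally:
  # the mirror-extended segment is periodic, so multiplying its spectrum by
  # the squared magnitude response applies the exact filtfilt response
  # without start-up transients at the segment edges
  p <- c(sm, rev(sm))
  N <- length(p)
  w <- 2 * pi * (0:(N - 1)) / N
  hresp <- function(coef) exp(-1i * outer(w, seq_along(coef) - 1)) %*% coef
  g <- Mod(hresp(flt$hp$b) / hresp(flt$hp$a))^2 *
       Mod(hresp(flt$lp$b) / hresp(flt$lp$a))^2
  y <- Re(stats::fft(stats::fft(p) * as.vector(g), inverse = TRUE) / N)[1:n]
  stopifnot(length(y) == n)
  if (inherits(segment, "ecg_segment")) {
    segment$samples <- y
    segment
  } else {
    y
  }
}

#' Magnitude response of the full preprocessing chain
#'
#' Computes the composite magnitude response of the 5-tap moving average and
#' the two zero-phase Butterworth stages at given frequencies. This is the
#' closed-form counterpart of pushing a pure tone through
#' [preprocess_segment()]; the squared responses of the Butterworth stages
#' reflect the forward-backward application.
#'
#' @param f_hz frequencies (Hz) at which to evaluate.
#' @param fs sampling rate in Hz.
#' @return numeric vector of magnitude gains in `[0, 1]`.
#' @export
preprocess_response <- function(f_hz, fs = 250) {
  flt <- preproc_filters(fs)
  w <- 2 * pi * f_hz / fs
  resp <- function(coef, wi) {
    z <- exp(-1i * wi * (seq_along(coef) - 1))
    sum(coef * z)
  }
  ma <- abs(sapply(w, function(wi) sum(exp(-1i * wi * (-2:2))) / 5))
  hp <- sapply(w, function(wi)
    Mod(resp(flt$hp$b, wi) / resp(flt$hp$a, wi))^2)
  lp <- sapply(w, function(wi)
    Mod(resp(flt$lp$b, wi) / resp(flt$lp$a, wi))^2)
  as.numeric(ma * hp * lp)
}
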