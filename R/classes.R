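#' Construct an ECG record
#'
#' An `ecg_record` holds one patient's raw single-channel ECG trace in
#' millivolts together with its sampling rate and rhythm annotations. Rhythm
#' annotations are piecewise-constant: each row marks the sample at which a
#' rhythm starts, and that rhythm holds until the next onset (or the end of
#' the record).
#'
#' @param record_id character scalar, unique record identifier (one record per
#'   patient).
#' @param samples numeric vector, the ECG trace in mV.
#' @param fs sampling rate in Hz.
#' @param annotations data frame with columns `sample` (0-based onset index,
#'   sorted, within the record) and `rhythm` (character code, e.g. `"VF"`,
#'   `"VT"`, `"VFL"`, `"N"`, `"noise"`, `"asystole"`, `"transition"`).
#' @return an object of class `ecg_record`.
#' @export
ecg_record <- function(record_id, samples, fs,
                       annotations = data.frame(sample = 0L, rhythm = "N")) {
  stopifnot(is.character(record_id), length(record_id) == 1L,
            is.numeric(samples), fs > 0,
            is.data.frame(annotations),
            all(c("sample", "rhythm") %in% names(annotations)))
  if (nrow(annotations)) {
    if (is.unsorted(annotations$sample))
      stop("annotations must be sorted by onset sample")
    if (any(annotations$sample < 0) ||
        any(annotations$sample >= length(samples)))
      stop("annotation onsets must lie within the signal")
  }
  structure(list(record_id = record_id, samples = as.numeric(samples),
                 fs = fs, annotations = annotations),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s: %d samples @ %g Hz (%.1f s), %d annotation(s)>\n",
              x$record_id, length(x$samples), x$fs,
              length(x$samples) / x$fs, nrow(x$annotations)))
  invisible(x)
}

#' Construct an ECG analysis segment
#'
#' One fixed-length analysis window cut from a record; the unit the shock
#' advice algorithm classifies. `label` is the binary class (1 = shockable,
#' 0 = non-shockable); `rhythm` keeps the underlying annotated rhythm code so
#' that the exclusion rules (slow VT, low-amplitude VF, noise) can be applied.
#'
#' @param record_id record the segment came from.
#' @param start 0-based index of the first sample within the record.
#' @param samples numeric vector of length `fs * seg_len_s`, in mV.
#' @param fs sampling rate in Hz.
#' @param label 1 (shockable) or 0 (non-shockable).
#' @param rhythm dominant annotated rhythm code for the window.
#' @param excluded logical, set by [apply_exclusions()].
#' @param reason character reason when excluded, `NA` otherwise.
#' @return an object of class `ecg_segment`.
#' @export
ecg_segment <- function(record_id, start, samples, fs, label,
                        rhythm = if (label == 1) "VF" else "N",
                        excluded = FALSE, reason = NA_character_) {
  stopifnot(label %in% c(0L, 1L), is.numeric(samples), fs > 0, start >= 0)
  structure(list(record_id = record_id, start = as.integer(start),
                 samples = as.numeric(samples), fs = fs,
                 label = as.integer(label), rhythm = rhythm,
                 excluded = isTRUE(excluded), reason = reason),
            class = "ecg_segment")
}

#' @export
print.ecg_segment <- function(x, ...) {
  cat(sprintf("<ecg_segment %s@%d: %d samples @ %g Hz, label %d (%s)%s>\n",
              x$record_id, x$start, length(x$samples), x$fs, x$label,
              x$rhythm, if (x$excluded) paste0(", EXCLUDED: ", x$reason) else ""))
  invisible(x)
}

#' Three-channel CNN input built from one segment
#'
#' Stacks the preprocessed segment (pECG) with the shockable-oriented and
#' non-shockable-oriented signals reconstructed from its mode decomposition.
#' These are the three aligned input channels of the convolutional network.
#'
#' @param pecg,sh_signal,nsh_signal numeric vectors of equal length.
#' @param label inherited binary class label.
#' @param record_id originating record, kept for record-wise fold assignment.
#' @return an object of class `channel_stack`.
#' @export
channel_stack <- function(pecg, sh_signal, nsh_signal, label,
                          record_id = NA_character_) {
  n <- length(pecg)
  if (length(sh_signal) != n || length(nsh_signal) != n)
    stop("channel lengths differ")
  structure(list(pecg = as.numeric(pecg), sh_signal = as.numeric(sh_signal),
                 nsh_signal = as.numeric(nsh_signal),
                 label = as.integer(label), record_id = record_id),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  cat(sprintf("<channel_stack %s: 3 x %d, label %d>\n",
              x$record_id, length(x$pecg), x$label))
  invisible(x)
}

# 3 x L numeric matrix view used by the CNN engine
as_channel_matrix <- function(stack) {
  rbind(pecg = stack$pecg, sh = stack$sh_signal, nsh = stack$nsh_signal)
}
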