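#' Run the shock advice algorithm on one raw segment
#'
#' Executes the full decision pipeline on a raw fixed-length ECG window:
#' preprocessing (moving average + high-pass + low-pass), mode decomposition
#' with pinned centers, channel stacking, deep-feature extraction by the
#' pre-trained CNN, and classification by the pre-trained secondary
#' classifier (label 1 = deliver shock advice). Per-stage wall-clock timings
#' are returned for latency bookkeeping; they are informational only.
#'
#' A near-flat input (peak-to-peak below 1 uV) still completes the pipeline
#' but raises a low-confidence warning, since no rhythm evidence is present.
#'
#' @param x numeric vector (raw segment, mV) or an [ecg_segment()]; length
#'   must match the extractor's `input_len`.
#' @param extractor a trained [cnn_model()].
#' @param classifier a fitted [train_classifier()] model, or `NULL` to use
#'   the fCNN softmax directly.
#' @param fs sampling rate in Hz (default 250).
#' @param mvmd an [mvmd_params()] object.
#' @return list with `label` (0/1), `features` (the deep feature vector),
#'   `timings` (named seconds per stage) and `stack` (the channel stack).
#' @export
run_saa <- function(x, extractor, classifier = NULL, fs = 250,
                    mvmd = mvmd_params()) {
  stopifnot(inherits(extractor, "cnn_model"))
  if (inherits(x, "ecg_segment")) {
    fs <- x$fs
    x <- x$samples
  }
  if (length(x) != extractor$config$input_len)
    stop(sprintf("segment length %d != extractor input_len %d",
                 length(x), extractor$config$input_len))
  if (diff(range(x)) < 1e-3)
    warning("near-flat input: label is low-confidence")
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  pecg <- preprocess_segment(x, fs)
  timings["preprocess"] <- tic() - t0

  t0 <- tic()
  ms <- mvmd_decompose(pecg, fs, mvmd)
  timings["mvmd"] <- tic() - t0

  t0 <- tic()
  stack <- build_channels(pecg, ms, label = NA_integer_)
  timings["channels"] <- tic() - t0

  t0 <- tic()
  features <- extract_features(extractor, stack)
  timings["features"] <- tic() - t0

  t0 <- tic()
  label <- if (is.null(classifier)) {
    predict_fcnn(extractor, stack)$label
  } else {
    predict(classifier, features)
  }
  timings["classify"] <- tic() - t0

  list(label = as.integer(label), features = features,
       timings = timings, stack = stack)
}
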