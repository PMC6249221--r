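#' Parameters for pinned-center variational mode decomposition
#'
#' Configures the modified VMD used for channel construction: the segment is
#' decomposed into `n_modes` narrow-band modes, of which the modes listed in
#' `fixed_freqs` have their center frequencies pinned for the whole run --
#' a DC mode at 0 Hz plus the five shockable-band centers 2, 3.5, 5, 6.5 and
#' 8 Hz by default. The remaining (free) centers are updated by the usual
#' power-weighted-mean rule and settle above 10 Hz on QRS-dominated input.
#'
#' @param n_modes total number of modes K (default 10).
#' @param fixed_freqs pinned center frequencies in Hz (default
#'   `c(0, 2, 3.5, 5, 6.5, 8)`); all must be below 10 Hz (0 Hz marks the DC
#'   mode) and there must be at most `n_modes` of them.
#' @param alpha bandwidth penalty of the quadratic data term (default 2000,
#'   the conventional VMD default).
#' @param tau dual-ascent step enforcing exact reconstruction (default 0.1;
#'   0 disables the constraint).
#' @param tol convergence tolerance on the summed relative mode change per
#'   iteration (default 1e-6).
#' @param max_iter iteration cap (default 500).
#' @param init_free_range range (Hz) over which free centers are initialized
#'   uniformly; default `c(10, 0.4 * fs)` evaluated at decomposition time as
#'   10 Hz up to 80% of Nyquist.
#' @return an object of class `mvmd_params`.
#' @export
mvmd_params <- function(n_modes = 10, fixed_freqs = c(0, 2, 3.5, 5, 6.5, 8),
                        alpha = 2000, tau = 0.1, tol = 1e-6, max_iter = 500,
                        init_free_range = NULL) {
  if (n_modes < length(fixed_freqs))
    stop("n_modes must be >= number of fixed frequencies")
  if (any(fixed_freqs < 0) || any(fixed_freqs[fixed_freqs > 0] >= 10))
    stop("pinned centers must be 0 (DC) or in (0, 10) Hz")
  if (tol <= 0 || max_iter < 1 || alpha <= 0 || tau < 0)
    stop("invalid alpha/tau/tol/max_iter")
  structure(list(n_modes = as.integer(n_modes), fixed_freqs = fixed_freqs,
                 alpha = alpha, tau = tau, tol = tol,
                 max_iter = as.integer(max_iter),
                 init_free_range = init_free_range),
            class = "mvmd_params")
}

#' Decompose a pECG segment into modes with pinned centers
#'
#' Runs frequency-domain VMD (Wiener-filter mode updates, power-weighted
#' center updates, dual ascent on the reconstruction constraint) on the
#' mirror-extended signal, with the single modification that pinned center
#' frequencies are never updated. Free centers are initialized uniformly over
#' `init_free_range` and move by the standard update; on ECG-like input they
#' settle above 10 Hz, so the pinned modes capture the sub-10 Hz
#' (shockable-oriented) content. Iterates until the summed relative mode
#' change drops below `tol` or `max_iter` is reached (then the best iterate
#' is returned with `converged = FALSE` and a warning).
#'
#' @param pecg numeric vector, the preprocessed segment.
#' @param fs sampling rate in Hz.
#' @param params an [mvmd_params()] object.
#' @return an object of class `mode_set`: list with `modes` (K x N matrix),
#'   `center_freqs_hz`, `fixed_mask`, `n_iters`, `converged`,
#'   `omega_history_hz` (iterations x K) and the `fs` used.
#' @export
mvmd_decompose <- function(pecg, fs, params = mvmd_params()) {
  stopifnot(is.numeric(pecg), fs > 0, inherits(params, "mvmd_params"))
  if (!all(is.finite(pecg))) stop("non-finite samples in input")
  n <- length(pecg)
  if (n < 8) stop("input too short to decompose")
  K <- params$n_modes
  nfix <- length(params$fixed_freqs)
  nfree <- K - nfix
  rng <- params$init_free_range
  if (is.null(rng)) rng <- c(10, 0.4 * fs)
  free0 <- if (nfree > 0)
    seq(rng[1], rng[2], length.out = nfree + 2)[2:(nfree + 1)] else numeric()
  omega0 <- c(params$fixed_freqs, free0) / fs   # cycles/sample
  fixed <- c(rep(1L, nfix), rep(0L, nfree))

  # mirror extension halves boundary leakage; crop back afterwards
  h <- n %/% 2
  f_ext <- c(rev(pecg[seq_len(h)]), pecg, rev(pecg[(n - (n - h) + 1):n]))
  if (length(f_ext) %% 2 == 1) f_ext <- c(f_ext, f_ext[length(f_ext)])

  res <- .mvmd_core(f_ext, omega0, fixed, params$alpha, params$tau,
                    params$tol, params$max_iter)
  if (!res$converged)
    warning(sprintf("MVMD did not converge in %d iterations; returning best iterate",
                    params$max_iter))
  modes <- res$modes[, (h + 1):(h + n), drop = FALSE]
  rownames(modes) <- sprintf("mode%02d", seq_len(K))
  structure(list(modes = modes, center_freqs_hz = as.numeric(res$omega) * fs,
                 fixed_mask = as.logical(fixed),
                 pinned_freqs_hz = params$fixed_freqs,
                 n_iters = res$n_iters, converged = res$converged,
                 omega_history_hz = res$omega_history * fs, fs = fs),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("<mode_set: %d modes x %d samples, %d iters%s>\n",
              nrow(x$modes), ncol(x$modes), x$n_iters,
              if (x$converged) "" else " (not converged)"))
  cat("  centers (Hz):",
      paste0(sprintf("%.2f", x$center_freqs_hz),
             ifelse(x$fixed_mask, "*", "")), "\n")
  cat("  (* = pinned)\n")
  invisible(x)
}

#' Build the three CNN input channels from a mode decomposition
#'
#' The shockable-oriented signal is the sum of the modes pinned at the five
#' sub-10 Hz centers (2, 3.5, 5, 6.5, 8 Hz); the non-shockable-oriented
#' signal is the sum of the free modes, whose centers sit above 10 Hz. The
#' DC mode (pinned at 0 Hz) is dropped from both. Together with the pECG
#' itself these form the aligned three-channel CNN input.
#'
#' @param pecg the preprocessed segment the modes were computed from (numeric
#'   vector or [ecg_segment()]).
#' @param modes a [mvmd_decompose()] result.
#' @param label binary class label carried into the stack (taken from the
#'   segment when `pecg` is an [ecg_segment()]).
#' @param record_id originating record id.
#' @return a [channel_stack()].
#' @export
build_channels <- function(pecg, modes, label = NA_integer_,
                           record_id = NA_character_) {
  stopifnot(inherits(modes, "mode_set"))
  if (inherits(pecg, "ecg_segment")) {
    if (is.na(label)) label <- pecg$label
    if (is.na(record_id)) record_id <- pecg$record_id
    pecg <- pecg$samples
  }
  if (length(pecg) != ncol(modes$modes))
    stop("pecg length does not match the decomposition")
  pin <- modes$pinned_freqs_hz
  fixed <- modes$fixed_mask
  if (sum(fixed) != length(pin))
    stop("fixed/free bookkeeping mismatch in mode_set")
  sh_rows <- which(fixed)[pin > 0]
  free_rows <- which(!fixed)
  sh <- if (length(sh_rows))
    colSums(modes$modes[sh_rows, , drop = FALSE]) else numeric(length(pecg))
  nsh <- if (length(free_rows))
    colSums(modes$modes[free_rows, , drop = FALSE]) else numeric(length(pecg))
  channel_stack(pecg, sh, nsh, label, record_id)
}

#' Preprocess and decompose a list of segments into channel stacks
#'
#' Convenience wrapper running [preprocess_segment()], [mvmd_decompose()] and
#' [build_channels()] over a list of segments; the standard way to prepare a
#' CNN training or evaluation set.
#'
#' @param segments list of [ecg_segment()] objects.
#' @param params an [mvmd_params()] object.
#' @param preprocess logical, run the filter chain first (default `TRUE`).
#' @return a list of [channel_stack()] objects.
#' @export
segments_to_stacks <- function(segments, params = mvmd_params(),
                               preprocess = TRUE) {
  lapply(segments, function(seg) {
    p <- if (preprocess) preprocess_segment(seg) else seg
    ms <- mvmd_decompose(p$samples, p$fs, params)
    build_channels(p, ms)
  })
}
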