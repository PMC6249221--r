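#' Frequency of the magnitude-spectrum maximum
#'
#' Locates the frequency at which the discrete Fourier magnitude spectrum of a
#' signal attains its maximum, restricted to a frequency band. Used throughout
#' the package to check the spectral placement of QRS trains (4--20 Hz) and
#' fibrillation waveforms (around 4 Hz).
#'
#' @param x numeric vector, the signal.
#' @param fs sampling rate in Hz.
#' @param band length-2 numeric, inclusive frequency band in Hz to search.
#' @return the frequency (Hz) of the maximum magnitude within `band`.
#' @export
spec_argmax <- function(x, fs, band = c(1, 30)) {
  stopifnot(is.numeric(x), length(x) > 1, fs > 0)
  n <- length(x)
  mag <- Mod(stats::fft(x))[seq_len(floor(n / 2) + 1)]
  freqs <- (seq_len(floor(n / 2) + 1) - 1) * fs / n
  sel <- freqs >= band[1] & freqs <= band[2]
  if (!any(sel)) stop("band contains no Fourier bins")
  freqs[sel][which.max(mag[sel])]
}

#' Fraction of signal power above (or below) a cutoff frequency
#'
#' Integrates the periodogram over positive frequencies and reports the
#' proportion of power on one side of a cutoff. The DC bin is excluded so the
#' measure reflects oscillatory content only.
#'
#' @param x numeric vector, the signal.
#' @param fs sampling rate in Hz.
#' @param cutoff cutoff frequency in Hz.
#' @param above if `TRUE` (default) return the fraction strictly above the
#'   cutoff, otherwise the fraction at or below it.
#' @return a proportion in `[0, 1]`.
#' @export
band_power_fraction <- function(x, fs, cutoff = 10, above = TRUE) {
  stopifnot(is.numeric(x), length(x) > 1, fs > 0, cutoff > 0)
  n <- length(x)
  pw <- Mod(stats::fft(x))[seq_len(floor(n / 2) + 1)]^2
  freqs <- (seq_len(floor(n / 2) + 1) - 1) * fs / n
  pw <- pw[freqs > 0]
  freqs <- freqs[freqs > 0]
  tot <- sum(pw)
  if (tot == 0) return(0)
  if (above) sum(pw[freqs > cutoff]) / tot else sum(pw[freqs <= cutoff]) / tot
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# state; if seed is NULL the expression uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
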