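#' Linear window features
#'
#' The five linear descriptors of a window: root mean square, peak-to-peak
#' amplitude, zero-crossing rate, and the peak and median frequencies of
#' the in-band Welch power spectral density.
#'
#' @param x numeric window.
#' @return a scalar.
#' @name linear_features
NULL

#' @rdname linear_features
#' @export
rms <- function(x) {
  if (!length(x)) stop_ehg("empty window")
  sqrt(mean(x^2))
}

#' @rdname linear_features
#' @export
amplitude <- function(x) {
  if (!length(x)) stop_ehg("empty window")
  max(x) - min(x)
}

#' @rdname linear_features
#' @param fs_hz sampling rate in Hz.
#' @details Zero-crossing rate counts strict sign changes between
#'   consecutive samples per second of signal; an exact zero inherits the
#'   previous sign so a touch of zero is not counted twice.
#' @export
zero_crossing_rate <- function(x, fs_hz) {
  if (!length(x)) stop_ehg("empty window")
  s <- sign(x)
  # an exact zero inherits the previous nonzero sign
  if (any(s == 0)) {
    for (i in seq_along(s)) if (s[i] == 0) s[i] <- if (i > 1) s[i - 1] else 1
  }
  sum(diff(s) != 0) / (length(x) / fs_hz)
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: Hann-tapered segments (default 512
#' samples, 50% overlap), one-sided density scaling so that the integral of
#' the PSD approximates the signal variance.
#'
#' @param x numeric window (length >= `nperseg`).
#' @param fs_hz sampling rate in Hz.
#' @param nperseg segment length in samples.
#' @param overlap fractional segment overlap.
#' @return an object of class `psd_estimate`: list with `frequencies` (Hz),
#'   `power` (unit^2/Hz) and the estimator parameters.
#' @export
psd_welch <- function(x, fs_hz, nperseg = 512, overlap = 0.5) {
  n <- length(x)
  if (n < nperseg) stop_ehg("window (%d) shorter than PSD segment (%d)", n, nperseg)
  hop <- round(nperseg * (1 - overlap))
  k <- floor((n - nperseg) / hop) + 1
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nperseg - 1) / nperseg))  # periodic Hann
  scale <- fs_hz * sum(w^2)
  acc <- numeric(nperseg %/% 2 + 1)
  for (i in seq_len(k)) {
    seg <- x[((i - 1) * hop + 1):((i - 1) * hop + nperseg)]
    spec <- Mod(fft(seg * w)[seq_len(nperseg %/% 2 + 1)])^2 / scale
    acc <- acc + spec
  }
  p <- acc / k
  # one-sided: double everything except DC and Nyquist
  p[2:(length(p) - 1)] <- 2 * p[2:(length(p) - 1)]
  structure(list(frequencies = fs_hz * (0:(nperseg %/% 2)) / nperseg,
                 power = p, nperseg = nperseg, overlap = overlap,
                 taper = "hann"),
            class = "psd_estimate")
}

band_slice <- function(psd, band) {
  sel <- psd$frequencies >= band$low_hz & psd$frequencies <= band$high_hz
  if (!any(sel)) stop_ehg("no PSD bins inside band [%g, %g] Hz",
                          band$low_hz, band$high_hz)
  sel
}

#' @rdname linear_features
#' @param psd a [psd_welch()] estimate.
#' @param band a [band_definition()].
#' @details Maximum frequency is the frequency of the largest in-band PSD
#'   value (ties resolved to the lowest frequency).
#' @export
max_frequency <- function(psd, band) {
  sel <- band_slice(psd, band)
  f <- psd$frequencies[sel]
  p <- psd$power[sel]
  f[which.max(p)]  # which.max takes the first (lowest-frequency) maximum
}

#' @rdname linear_features
#' @details Medium frequency is the median (50%-power) frequency of the
#'   in-band spectrum: the frequency below which half of the in-band power
#'   lies, linearly interpolated between PSD bins.
#' @export
medium_frequency <- function(psd, band) {
  sel <- band_slice(psd, band)
  f <- psd$frequencies[sel]
  p <- psd$power[sel]
  tot <- sum(p)
  if (tot <= 0) stop_ehg("zero in-band power")
  cs <- cumsum(p)
  half <- tot / 2
  i <- which(cs >= half)[1]
  if (i == 1) return(f[1])
  # linear interpolation within the bin that crosses half power
  f[i - 1] + (half - cs[i - 1]) / p[i] * (f[i] - f[i - 1])
}
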