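#' Wavelet parameter set
#'
#' Defaults for the time-frequency features: an analytic generalized Morse
#' wavelet with symmetry parameter gamma = 3 and time-bandwidth product 60
#' (so beta = 20), 10 voices per octave over 7 octaves below Nyquist, with
#' L1 normalization (equal-amplitude tones attain equal scalogram
#' magnitude); and a Daubechies order-12 orthogonal DWT over 7 decomposition
#' levels.
#'
#' @param gamma Morse symmetry parameter.
#' @param time_bandwidth Morse time-bandwidth product (`beta * gamma`).
#' @param voices_per_octave CWT voices per octave.
#' @param n_octaves octaves below Nyquist covered by the scale grid.
#' @param dwt_levels DWT decomposition depth.
#' @return a named list of parameter blocks.
#' @export
wavelet_params <- function(gamma = 3, time_bandwidth = 60,
                           voices_per_octave = 10, n_octaves = 7,
                           dwt_levels = 7) {
  stopifnot(gamma > 0, voices_per_octave >= 4, dwt_levels >= 1)
  list(cwt = list(gamma = gamma, time_bandwidth = time_bandwidth,
                  beta = time_bandwidth / gamma,
                  voices_per_octave = voices_per_octave,
                  n_octaves = n_octaves, normalization = "L1"),
       dwt = list(family = "db12", levels = dwt_levels))
}

# Morse analytic filter bank in the frequency domain, cached per
# (N, fs, params).  Columns are scales; the filter is peak-normalized to 2
# at the wavelet peak frequency, which with an analytic wavelet makes a
# unit-amplitude real tone attain ridge magnitude 1 at every frequency
# (the L1 convention).
morse_filter_bank <- function(N, fs, cwt) {
  key <- sprintf("morse_%d_%g_%g_%g_%d_%d", N, fs, cwt$gamma,
                 cwt$time_bandwidth, cwt$voices_per_octave, cwt$n_octaves)
  hit <- .ehg_cache[[key]]
  if (!is.null(hit)) return(hit)
  beta <- cwt$beta; gamma <- cwt$gamma
  omega_p <- (beta / gamma)^(1 / gamma)  # peak angular frequency
  n_scales <- cwt$n_octaves * cwt$voices_per_octave + 1
  freqs <- fs / 2 * 2^(-(n_scales - 1):0 / cwt$voices_per_octave)  # ascending
  scales <- omega_p / (2 * pi * freqs / fs)                         # samples
  omega <- 2 * pi * seq(0, N - 1) / N
  pos <- omega > 0 & omega <= pi  # analytic: positive frequencies only
  filt <- matrix(0, nrow = N, ncol = n_scales)
  for (s in seq_len(n_scales)) {
    so <- scales[s] * omega[pos] / omega_p
    filt[pos, s] <- 2 * exp(beta * log(so) + (beta / gamma) * (1 - so^gamma))
  }
  bank <- list(filt = filt, frequencies = freqs, scales = scales)
  .ehg_cache[[key]] <- bank
  bank
}

#' Continuous wavelet transform scalogram
#'
#' Magnitude of the analytic Morse CWT on a dyadic frequency grid
#' (`voices_per_octave` voices over `n_octaves` octaves below Nyquist),
#' computed in the frequency domain.  Rows of the magnitude matrix are
#' frequencies in ascending order, columns are time samples.
#'
#' @param x numeric window (length >= 64).
#' @param fs_hz sampling rate in Hz.
#' @param params a [wavelet_params()] list.
#' @return an object of class `scalogram`: list with `magnitude`
#'   (frequency x time), `frequencies` (Hz, ascending) and `times` (s).
#' @export
cwt_scalogram <- function(x, fs_hz, params = wavelet_params()) {
  N <- length(x)
  if (N < 64) stop_ehg("window too short for CWT (need >= 64 samples)")
  bank <- morse_filter_bank(N, fs_hz, params$cwt)
  X <- fft(as.numeric(x))
  W <- stats::mvfft(bank$filt * X, inverse = TRUE) / N
  structure(list(magnitude = mag_transpose_cpp(W),
                 frequencies = bank$frequencies,
                 times = seq(0, N - 1) / fs_hz),
            class = "scalogram")
}

#' Plot a scalogram
#'
#' Time-frequency heat map of the CWT magnitude (log-frequency axis), the
#' usual way EHG spectral content is inspected.
#'
#' @param x a [cwt_scalogram()].
#' @param ... passed to [graphics::image()].
#' @export
plot.scalogram <- function(x, ...) {
  graphics::image(x$times, log2(x$frequencies), t(x$magnitude),
                  xlab = "time (s)", ylab = "log2 frequency (Hz)",
                  useRaster = TRUE, ...)
  invisible(x)
}

#' Scalogram energy
#'
#' Sum of squared scalogram magnitudes over the whole time-frequency plane.
#'
#' @param s a [cwt_scalogram()].
#' @return a nonnegative scalar (arbitrary units).
#' @export
tf_energy <- function(s) sum(s$magnitude^2)

#' Scalogram flux
#'
#' Mean absolute difference between the scalogram and a copy shifted by
#' `(k1, k2)` cells along (time, frequency): 0 degrees compares adjacent
#' frequency rows (0, 1), 90 degrees adjacent time columns (1, 0), and 45
#' degrees the diagonal (1, 1).  The mean over valid cells makes the value
#' comparable across scalogram sizes.
#'
#' @param s a [cwt_scalogram()].
#' @param angle one of 0, 45, 90 (degrees).
#' @return a nonnegative scalar.
#' @export
tf_flux <- function(s, angle) {
  off <- switch(as.character(angle),
                "0" = c(0L, 1L), "45" = c(1L, 1L), "90" = c(1L, 0L),
                stop_ehg("angle must be 0, 45 or 90"))
  k1 <- off[1]; k2 <- off[2]  # (time, frequency) offsets
  M <- s$magnitude
  if (nrow(M) <= k2 || ncol(M) <= k1)
    stop_ehg("scalogram too small for flux offsets")
  flux_mean_cpp(M, k1, k2)
}

# Daubechies extremal-phase order-12 scaling (lowpass analysis) filter;
# published orthonormal coefficients, sum = sqrt(2), sum of squares = 1.
DB12_LO <- c(
  -1.52907175806851093e-06, 1.27769522193797666e-05,
  -2.42415457570307852e-05, -8.85041092082043202e-05,
  3.88653062820931434e-04, 6.54512821250959586e-06,
  -2.17950361862776030e-03, 2.24860724099523778e-03,
  6.71149900879550957e-03, -1.28408251983006833e-02,
  -1.22186490697482799e-02, 4.15462774950844382e-02,
  1.08491302558221848e-02, -9.64321200965070763e-02,
  5.35956967435215030e-03, 1.82478605927579668e-01,
  -2.37792572560697260e-02, -3.16178453752785527e-01,
  -4.47638856537746280e-02, 5.15886478427815653e-01,
  6.57198722579307115e-01, 3.77355135214212656e-01,
  1.09566272821185154e-01, 1.31122579572295183e-02)

# one level of periodized orthogonal analysis: correlation with the even
# translates of the scaling / wavelet filters, via FFT circular correlation
dwt_step <- function(x, lo_fft, hi_fft) {
  X <- fft(x)
  n <- length(x)
  a <- Re(fft(X * Conj(lo_fft), inverse = TRUE)) / n
  d <- Re(fft(X * Conj(hi_fft), inverse = TRUE)) / n
  list(a = a[seq(1, n, by = 2)], d = d[seq(1, n, by = 2)])
}

dwt_filters_fft <- function(n) {
  key <- sprintf("db12fft_%d", n)
  hit <- .ehg_cache[[key]]
  if (!is.null(hit)) return(hit)
  L <- length(DB12_LO)
  lo <- c(DB12_LO, numeric(n - L))
  hi <- c((-1)^(0:(L - 1)) * rev(DB12_LO), numeric(n - L))
  out <- list(lo = fft(lo), hi = fft(hi))
  .ehg_cache[[key]] <- out
  out
}

#' DWT subband energies
#'
#' Orthogonal Daubechies-12 decomposition of the window over
#' `params$dwt$levels` levels (the window is zero-padded to the next power
#' of two and the transform is fully periodized, so the decomposition is
#' exactly orthonormal and Parseval holds to machine precision).  Level j
#' details cover the dyadic band `(fs/2^(j+1), fs/2^j)` Hz.
#'
#' @param x numeric window.
#' @param params a [wavelet_params()] list.
#' @return list with `detail` (named energies `E1..E<levels>`), `approx`
#'   (approximation energy) and `total` (`sum(x^2)`).
#' @export
dwt_level_energies <- function(x, params = wavelet_params()) {
  levels <- params$dwt$levels
  n <- 2^ceiling(log2(length(x)))
  if (n / 2^levels < 2)
    stop_ehg("window too short for a %d-level decomposition", levels)
  a <- c(as.numeric(x), numeric(n - length(x)))
  detail <- numeric(levels)
  for (j in seq_len(levels)) {
    ff <- dwt_filters_fft(length(a))
    st <- dwt_step(a, ff$lo, ff$hi)
    detail[j] <- sum(st$d^2)
    a <- st$a
  }
  names(detail) <- paste0("E", seq_len(levels))
  list(detail = detail, approx = sum(a^2), total = sum(x^2))
}

#' Adjacent-level DWT energy differences
#'
#' The six DWT features: differences of log energies between adjacent
#' detail levels, `DWT_dj = log(E[j+1]) - log(E[j])`.  Log energies make
#' the features invariant to signal gain; energies are floored at 1e-300
#' before the log.  Set `log = FALSE` for the raw differences
#' `E[j+1] - E[j]`.
#'
#' @param energies the `detail` energies from [dwt_level_energies()] (or
#'   the full list).
#' @param log take differences of log energies (default) or raw energies.
#' @return named numeric vector `DWT_d1 ... DWT_d<levels-1>`.
#' @export
dwt_adjacent_differences <- function(energies, log = TRUE) {
  if (is.list(energies)) energies <- energies$detail
  e <- pmax(energies, 1e-300)
  d <- if (log) diff(base::log(e)) else diff(e)
  names(d) <- paste0("DWT_d", seq_along(d))
  d
}
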