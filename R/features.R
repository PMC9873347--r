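#' Canonical feature registry
#'
#' The 33 per-window features, in canonical order: 5 linear (MaxFreq,
#' MedFreq, RMS, ZCR, Amp), 18 entropy-based (SampEn, FuzzEn local/global,
#' PerEn, DispEn, bEn and the twelve-sector PhEn profile), and 10 wavelet
#' time-frequency (CWT Energy, Flux at 0/45/90 degrees, and six DWT
#' adjacent-level log-energy differences).
#'
#' @return character vector of the 33 canonical feature names.
#' @export
feature_names <- function() {
  c("MaxFreq", "MedFreq", "RMS", "ZCR", "Amp",
    "SampEn", "FuzzEnLoc", "FuzzEnGlob", "PerEn", "DispEn", "bEn",
    paste0("PhEn_k", seq(2, 24, by = 2)),
    "Energy", "Flux0", "Flux45", "Flux90",
    paste0("DWT_d", 1:6))
}

#' Extract the 33 features from one window
#'
#' Computes the full canonical feature vector on a single-channel,
#' single-subband window (2400 samples at the default 120 s x 20 Hz).
#'
#' @param x numeric window.
#' @param fs_hz sampling rate in Hz.
#' @param band the [band_definition()] the window was filtered to (sets the
#'   support of the spectral features).
#' @param entropy entropy parameters, see [entropy_params()].
#' @param wavelet wavelet parameters, see [wavelet_params()].
#' @return named numeric vector of length 33, names as [feature_names()].
#' @export
extract_window_features <- function(x, fs_hz, band,
                                    entropy = entropy_params(),
                                    wavelet = wavelet_params()) {
  psd <- psd_welch(x, fs_hz)
  sc <- cwt_scalogram(x, fs_hz, wavelet)
  dwt <- dwt_level_energies(x, wavelet)
  out <- c(
    MaxFreq = max_frequency(psd, band),
    MedFreq = medium_frequency(psd, band),
    RMS = rms(x),
    ZCR = zero_crossing_rate(x, fs_hz),
    Amp = amplitude(x),
    SampEn = as.numeric(sample_entropy(x, entropy$sampen$m, entropy$sampen$r_coeff)),
    FuzzEnLoc = as.numeric(fuzzy_entropy(x, entropy$fuzzen$m, entropy$fuzzen$r,
                                         entropy$fuzzen$n, "local")),
    FuzzEnGlob = as.numeric(fuzzy_entropy(x, entropy$fuzzen$m, entropy$fuzzen$r,
                                          entropy$fuzzen$n, "global")),
    PerEn = permutation_entropy(x, entropy$peren$order, entropy$peren$delay),
    DispEn = dispersion_entropy(x, entropy$dispen$m, entropy$dispen$c),
    bEn = bubble_entropy(x, entropy$ben$m),
    phen_profile(x, entropy$phen$ks),
    Energy = tf_energy(sc),
    Flux0 = tf_flux(sc, 0),
    Flux45 = tf_flux(sc, 45),
    Flux90 = tf_flux(sc, 90),
    dwt_adjacent_differences(dwt))
  stopifnot(identical(names(out), feature_names()))
  out
}

#' Extract the windowed feature table for a set of records
#'
#' For every non-excluded record, channel and subband: z-score the raw
#' channel, band-pass filter, cut overlapping windows, and compute the 33
#' features per window.  The fixed pipeline order (z-score of the raw
#' record, then filtering, then windowing) preserves the relative energies
#' of the three subbands.
#'
#' @param records an `ehg_cohort` or list of `ehg_record`s.
#' @param channels channel names to process (default: all in the records).
#' @param bands list of [band_definition()]s (default [ehg_bands()]).
#' @param window_s,overlap windowing parameters (120 s, 50%).
#' @param split optional [split_records()] assignment to join in.
#' @param trim_s seconds discarded from each end of the filtered signal
#'   before windowing (default 0: filter transients are kept, the windows
#'   being long relative to the filter ringing).
#' @param entropy,wavelet feature parameters.
#' @return a tibble with provenance columns `record_id`, `label`,
#'   `channel`, `band`, `window_index`, `split`, then the 33 features.
#' @export
extract_features <- function(records, channels = NULL, bands = ehg_bands(),
                             window_s = 120, overlap = 0.5, split = NULL,
                             trim_s = 0,
                             entropy = entropy_params(),
                             wavelet = wavelet_params()) {
  if (inherits(records, "ehg_record")) records <- list(records)
  records <- Filter(function(r) !isTRUE(r$excluded), records)
  if (!length(records)) stop_ehg("no non-excluded records to process")
  split_of <- NULL
  if (!is.null(split)) {
    split_of <- stats::setNames(split$split, split$record_id)
  }
  rows <- list()
  for (rec in records) {
    chs <- channels %||% names(rec$channels)
    for (ch in chs) {
      z <- zscore(rec$channels[[ch]])
      for (band in bands) {
        filtered <- bandpass(z, band, rec$fs_hz)
        if (trim_s > 0) {
          drop <- round(trim_s * rec$fs_hz)
          filtered <- filtered[(drop + 1):(length(filtered) - drop)]
        }
        wins <- segment_windows(filtered, rec$fs_hz, window_s, overlap)
        feats <- t(vapply(wins, extract_window_features,
                          numeric(length(feature_names())),
                          fs_hz = rec$fs_hz, band = band,
                          entropy = entropy, wavelet = wavelet))
        tab <- tibble::tibble(
          record_id = rec$record_id, label = rec$label,
          channel = ch, band = band$name,
          window_index = seq_along(wins),
          split = if (is.null(split_of)) NA_character_
                  else unname(split_of[rec$record_id]))
        rows[[length(rows) + 1L]] <- cbind(tab, tibble::as_tibble(feats))
      }
    }
  }
  tibble::as_tibble(do.call(rbind, rows))
}
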