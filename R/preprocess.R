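#' EHG subband definitions
#'
#' The three analysis subbands partitioning the conventional EHG range:
#' F1 (0.3-1 Hz), F2 (1-2 Hz) and F3 (2-3 Hz).  F1 covers the propagation
#' (Fast Wave Low) content; F2/F3 cover excitability content where maternal
#' ECG interference and its harmonics also live.
#'
#' @param name band name, one of `"F1"`, `"F2"`, `"F3"`.
#' @return a `band_definition` (list with `name`, `low_hz`, `high_hz`).
#' @export
ehg_band <- function(name = c("F1", "F2", "F3")) {
  name <- match.arg(name)
  edges <- list(F1 = c(0.3, 1), F2 = c(1, 2), F3 = c(2, 3))[[name]]
  band_definition(name, edges[1], edges[2])
}

#' @rdname ehg_band
#' @param low_hz,high_hz band edges in Hz, `0 < low < high`.
#' @export
band_definition <- function(name, low_hz, high_hz) {
  if (!(low_hz > 0 && high_hz > low_hz))
    stop_ehg("band edges must satisfy 0 < low < high")
  structure(list(name = name, low_hz = low_hz, high_hz = high_hz),
            class = "band_definition")
}

#' @rdname ehg_band
#' @export
ehg_bands <- function() lapply(c("F1", "F2", "F3"), ehg_band)

#' Filter records by gestational age at recording
#'
#' Keeps records whose gestational age at recording lies in
#' `[low_weeks, high_weeks]` (bounds inclusive).  Records outside the range,
#' or without gestational-age metadata, are flagged as excluded (with a
#' reason) rather than dropped, so curation stays auditable.
#'
#' @param records an `ehg_cohort` or list of `ehg_record`s.
#' @param low_weeks,high_weeks inclusive bounds in weeks (default 27-33).
#' @return the records with updated `excluded`/`exclusion_reason` flags.
#' @export
filter_records_by_ga <- function(records, low_weeks = 27, high_weeks = 33) {
  out <- lapply(records, function(r) {
    ga <- r$gestational_age_rec_weeks
    if (is.na(ga)) {
      r$excluded <- TRUE
      r$exclusion_reason <- "no-metadata"
    } else if (ga < low_weeks || ga > high_weeks) {
      r$excluded <- TRUE
      r$exclusion_reason <- sprintf("gestational age %.1f outside [%g, %g]",
                                    ga, low_weeks, high_weeks)
    }
    r
  })
  class(out) <- class(records)
  attributes(out) <- attributes(records)
  out
}

#' Flag manually excluded records
#'
#' Visual-examination exclusions (artifact-ridden recordings) are supplied
#' as an explicit id -> reason list; no automatic artifact detector is run.
#'
#' @param records list of `ehg_record`s.
#' @param exclusions named character vector or list, `record_id = reason`.
#' @return records with exclusion flags applied.
#' @export
apply_manual_exclusions <- function(records, exclusions) {
  out <- lapply(records, function(r) {
    if (r$record_id %in% names(exclusions)) {
      r$excluded <- TRUE
      r$exclusion_reason <- as.character(exclusions[[r$record_id]])
    }
    r
  })
  class(out) <- class(records)
  attributes(out) <- attributes(records)
  out
}

#' Balanced random subsampling per class
#'
#' Randomly keeps exactly `per_class` non-excluded records of each class
#' (seeded, reproducible), mirroring balanced-cohort curation.
#'
#' @param records list of `ehg_record`s.
#' @param per_class records to keep per class.
#' @param seed integer seed.
#' @return the selected records (class order preserved as P then T).
#' @export
balance_by_subsampling <- function(records, per_class, seed = 1) {
  active <- Filter(function(r) !isTRUE(r$excluded), records)
  labels <- vapply(active, `[[`, "", "label")
  picked <- list()
  for (cl in c("P", "T")) {
    idx <- which(labels == cl)
    if (length(idx) < per_class)
      stop_ehg("class %s has only %d records, %d requested",
               cl, length(idx), per_class)
    keep <- with_seed(derive_seed(seed, "balance", cl),
                      sort(sample(idx, per_class)))
    picked <- c(picked, active[keep])
  }
  structure(picked, class = "ehg_cohort")
}

#' z-score normalization
#'
#' Centers and scales to zero mean and unit population standard deviation
#' (divide by N).  Applied to each raw channel of a record before subband
#' filtering, so relative subband energies are preserved.
#'
#' @param x numeric vector of length >= 2 with positive variance.
#' @return the standardized vector.
#' @export
zscore <- function(x) {
  if (length(x) < 2) stop_ehg("zscore needs at least 2 samples")
  s <- sd_pop(x)
  if (s == 0) stop_ehg("degenerate signal: zero variance")
  (x - mean(x)) / s
}

# cache of designed Butterworth sections keyed by (band, fs)
butter_design <- function(low, high, fs) {
  key <- sprintf("butter_%g_%g_%g", low, high, fs)
  if (!is.null(.ehg_cache[[key]])) return(.ehg_cache[[key]])
  flt <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  .ehg_cache[[key]] <- flt
  flt
}

#' Zero-phase band-pass filtering
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), giving zero phase shift and an effective 8th-order
#' magnitude response: unity gain at the band midpoint, steep roll-off an
#' octave outside either edge.
#'
#' @param x numeric signal.
#' @param band a [band_definition()].
#' @param fs_hz sampling rate in Hz.
#' @return the filtered signal, same length as `x`.
#' @export
bandpass <- function(x, band, fs_hz) {
  if (band$high_hz >= fs_hz / 2)
    stop_ehg("band edge %g Hz is not below Nyquist (%g Hz)",
             band$high_hz, fs_hz / 2)
  flt <- butter_design(band$low_hz, band$high_hz, fs_hz)
  as.numeric(signal::filtfilt(flt, x))
}

#' Segment a signal into overlapping windows
#'
#' Cuts fully contained windows of `window_s` seconds with fractional
#' overlap `overlap` (default 120 s, 50%); a 30-min record at 20 Hz yields
#' 29 windows of 2400 samples.
#'
#' @param x numeric signal.
#' @param fs_hz sampling rate in Hz.
#' @param window_s window length in seconds.
#' @param overlap fractional overlap in `[0, 1)`.
#' @return a list of numeric windows.
#' @export
segment_windows <- function(x, fs_hz, window_s = 120, overlap = 0.5) {
  len <- round(window_s * fs_hz)
  if (length(x) < len)
    stop_ehg("signal (%d samples) shorter than one window (%d samples)",
             length(x), len)
  hop <- round(len * (1 - overlap))
  n_win <- floor((length(x) - len) / hop) + 1
  lapply(seq_len(n_win), function(i) x[((i - 1) * hop + 1):((i - 1) * hop + len)])
}

#' Record-level train/validation/test split
#'
#' Assigns whole records (never individual windows) to train, validation
#' and test, stratified by class.  Per class, the validation and test sizes
#' are `round(fraction * n)` and train takes the remainder, so a 20-record
#' class under (0.70, 0.15, 0.15) yields 14/3/3.  A class with fewer than 3
#' records degenerates (with a warning) to all-train.
#'
#' @param records list of labeled `ehg_record`s.
#' @param fractions length-3 numeric summing to 1 (train, validation, test).
#' @param seed integer seed.
#' @return a tibble with columns `record_id`, `label`, `split`, carrying
#'   attributes `fractions` and `seed`.
#' @export
split_records <- function(records, fractions = c(0.70, 0.15, 0.15), seed = 1) {
  if (abs(sum(fractions) - 1) > 1e-8) stop_ehg("fractions must sum to 1")
  ids <- vapply(records, `[[`, "", "record_id")
  labels <- vapply(records, `[[`, "", "label")
  split <- character(length(ids))
  degenerate <- FALSE
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n <- length(idx)
    if (n < 3) {
      warning(sprintf("class %s has %d record(s); assigning all to train", cl, n))
      split[idx] <- "train"
      degenerate <- TRUE
      next
    }
    n_val <- round(fractions[2] * n)
    n_test <- round(fractions[3] * n)
    ord <- with_seed(derive_seed(seed, "split", cl), sample(idx))
    split[ord[seq_len(n_val)]] <- "validation"
    split[ord[n_val + seq_len(n_test)]] <- "test"
    split[ord[seq(n_val + n_test + 1, length.out = n - n_val - n_test)]] <- "train"
  }
  out <- tibble::tibble(record_id = ids, label = labels, split = split)
  attr(out, "fractions") <- fractions
  attr(out, "seed") <- seed
  attr(out, "degenerate") <- degenerate
  out
}
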