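#' Class profile for the synthetic EHG generator
#'
#' A class profile holds the generative parameters of one delivery class
#' (preterm `"P"` or term `"T"`): how often contraction bursts occur, how
#' long and how strong they are, where in the spectrum their oscillatory
#' content lives, how regular (tone-like) that content is, how much
#' maternal-ECG-like interference is present, and the spectral slope of the
#' 1/f^alpha baseline noise.  The regularity knob is what drives entropy
#' contrasts between classes; the burst gain drives energy contrasts.
#'
#' @param label class label, `"P"` (preterm) or `"T"` (term).
#' @param burst_rate expected number of contraction bursts per 30 minutes.
#' @param burst_duration_s length-2 numeric, mean and SD of burst duration
#'   in seconds.
#' @param burst_gain burst-to-baseline RMS ratio (dimensionless).
#' @param carrier_band_hz length-2 numeric `(low, high)` in Hz; the burst
#'   oscillation content is drawn from this band.  Must lie inside
#'   `(0, fs/2)`.
#' @param regularity fraction in `[0, 1]` of the burst carrier that is a
#'   coherent tone; the remainder is band-limited noise in the same band.
#' @param ecg_interference_gain RMS of the ~1.4 Hz maternal-ECG-like pulse
#'   train (fundamental plus two harmonics), relative to the baseline RMS.
#' @param baseline_noise_exponent spectral slope alpha of the 1/f^alpha
#'   baseline noise.
#' @param baseline_rms target RMS of the baseline noise (unitless; the
#'   pipeline z-scores records anyway).
#' @return an object of class `ehg_class_profile`.
#' @export
class_profile <- function(label,
                          burst_rate = 5,
                          burst_duration_s = c(55, 15),
                          burst_gain = 3,
                          carrier_band_hz = c(0.4, 0.9),
                          regularity = 0.5,
                          ecg_interference_gain = 0.2,
                          baseline_noise_exponent = 1,
                          baseline_rms = 1) {
  label <- match.arg(label, c("P", "T"))
  if (burst_rate < 0) stop_ehg("burst_rate must be >= 0")
  if (regularity < 0 || regularity > 1) stop_ehg("regularity must be in [0, 1]")
  if (burst_gain < 0 || ecg_interference_gain < 0 || baseline_rms <= 0)
    stop_ehg("gains must be >= 0 and baseline_rms > 0")
  if (length(carrier_band_hz) != 2 || carrier_band_hz[1] <= 0 ||
      carrier_band_hz[2] < carrier_band_hz[1] || carrier_band_hz[2] >= 10)
    stop_ehg("carrier_band_hz must satisfy 0 < low <= high < 10 Hz")
  structure(list(
    label = label, burst_rate = burst_rate,
    burst_duration_s = burst_duration_s, burst_gain = burst_gain,
    carrier_band_hz = carrier_band_hz, regularity = regularity,
    ecg_interference_gain = ecg_interference_gain,
    baseline_noise_exponent = baseline_noise_exponent,
    baseline_rms = baseline_rms), class = "ehg_class_profile")
}

#' Default preterm / term class profiles
#'
#' The shipped defaults encode the study conditions assumed throughout the
#' test-suite simulations: preterm records carry more frequent, stronger and
#' more regular contraction bursts than term records (burst-gain ratio 2,
#' regularity contrast 0.5), with identical baseline noise and identical
#' maternal-ECG interference, so class information lives in burst energy and
#' burst regularity only.
#'
#' @param ... overrides passed on to [class_profile()].
#' @return an `ehg_class_profile`.
#' @export
preterm_profile <- function(...) {
  args <- list(label = "P", burst_rate = 6, burst_duration_s = c(60, 15),
               burst_gain = 4, carrier_band_hz = c(0.4, 0.9),
               regularity = 0.8, ecg_interference_gain = 0.2)
  args[names(list(...))] <- list(...)
  do.call(class_profile, args)
}

#' @rdname preterm_profile
#' @export
term_profile <- function(...) {
  args <- list(label = "T", burst_rate = 4, burst_duration_s = c(50, 15),
               burst_gain = 2, carrier_band_hz = c(0.4, 0.9),
               regularity = 0.3, ecg_interference_gain = 0.2)
  args[names(list(...))] <- list(...)
  do.call(class_profile, args)
}

#' Simulation configuration
#'
#' @param n_P,n_T number of preterm / term records in a cohort.
#' @param fs_hz sampling rate in Hz (the clinical recordings are 20 Hz).
#' @param duration_s record duration in seconds (default 30 minutes).
#' @param n_channels number of bipolar channels (default 3: S1-S3).
#' @param seed integer seed; a fixed seed makes the cohort a pure function
#'   of `(profiles, config)`.
#' @return an object of class `ehg_sim_config`.
#' @export
sim_config <- function(n_P = 20, n_T = 20, fs_hz = 20, duration_s = 1800,
                       n_channels = 3, seed = 1) {
  if (fs_hz <= 0 || duration_s <= 0 || n_channels < 1)
    stop_ehg("invalid simulation config")
  structure(list(n_P = as.integer(n_P), n_T = as.integer(n_T),
                 fs_hz = fs_hz, duration_s = duration_s,
                 n_channels = as.integer(n_channels),
                 seed = as.integer(seed)),
            class = "ehg_sim_config")
}

# 1/f^alpha Gaussian noise with exact unit RMS.  The shaping is flattened
# below 0.05 Hz: surface EHG amplifiers are AC-coupled, and an unbounded
# 1/f tail would make the windowed variance drift across a 30-min record.
shaped_noise <- function(n, fs, alpha) {
  z <- fft(rnorm(n))
  f <- fs * c(0:floor(n / 2), -((ceiling(n / 2) - 1):1)) / n
  shape <- pmax(abs(f), 0.05)^(-alpha / 2)
  shape[1] <- 0  # no DC
  x <- Re(fft(z * shape, inverse = TRUE)) / n
  x / sd_pop(x)
}

# white noise brick-wall filtered to `band` (Hz), unit RMS
bandlimited_noise <- function(n, fs, band) {
  z <- fft(rnorm(n))
  f <- abs(fs * c(0:floor(n / 2), -((ceiling(n / 2) - 1):1)) / n)
  z[f < band[1] | f > band[2]] <- 0
  x <- Re(fft(z, inverse = TRUE)) / n
  r <- sd_pop(x)
  if (r == 0) numeric(n) else x / r
}

#' Generate one synthetic EHG record
#'
#' Builds `n_channels` channels of `duration_s * fs_hz` samples: a 1/f^alpha
#' noise floor, shared-timing contraction bursts (Hann-enveloped mixtures of
#' a coherent tone and band-limited noise), and an optional maternal-ECG-like
#' pulse train at 1.4 Hz with two harmonics.  Channels share burst timing
#' (a contraction is a whole-uterus event) but have independent noise and
#' independent per-channel burst gains.  Burst ground truth is stored in the
#' record's `annotations`.
#'
#' @param profile an [class_profile()].
#' @param config an [sim_config()].
#' @param record_index integer; together with `config$seed` and the class
#'   label it determines the record's private random stream, so the same
#'   `(profile, config, record_index)` always reproduces the same samples.
#' @return an `ehg_record` (see [ehg_record()]).
#' @export
generate_record <- function(profile, config, record_index) {
  stopifnot(inherits(profile, "ehg_class_profile"),
            inherits(config, "ehg_sim_config"))
  if (profile$carrier_band_hz[2] >= config$fs_hz / 2)
    stop_ehg("carrier band upper edge %.2f Hz is not below Nyquist (%.2f Hz)",
             profile$carrier_band_hz[2], config$fs_hz / 2)
  fs <- config$fs_hz
  n <- round(config$duration_s * fs)
  nch <- config$n_channels
  with_seed(derive_seed(config$seed, record_index, profile$label), {
    # shared burst timing
    n_bursts <- rpois(1, profile$burst_rate * config$duration_s / 1800)
    midpoints <- sort(runif(n_bursts, 0, config$duration_s))
    durations <- pmax(10, rnorm(n_bursts, profile$burst_duration_s[1],
                                profile$burst_duration_s[2]))
    carrier_hz <- runif(n_bursts, profile$carrier_band_hz[1],
                        profile$carrier_band_hz[2])
    phases <- runif(n_bursts, 0, 2 * pi)
    gain_jitter <- matrix(runif(nch * max(n_bursts, 1), 0.8, 1.2),
                          nrow = max(n_bursts, 1))
    ecg_phase <- runif(1, 0, 2 * pi)
    channels <- vector("list", nch)
    for (ch in seq_len(nch)) {
      x <- profile$baseline_rms * shaped_noise(n, fs, profile$baseline_noise_exponent)
      for (b in seq_len(n_bursts)) {
        i0 <- max(1L, round((midpoints[b] - durations[b] / 2) * fs))
        i1 <- min(n, round((midpoints[b] + durations[b] / 2) * fs))
        if (i1 - i0 < 2) next
        idx <- i0:i1
        tt <- (idx - 1) / fs
        env <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = length(idx))))
        tone <- sin(2 * pi * carrier_hz[b] * tt + phases[b]) * sqrt(2)
        noise <- bandlimited_noise(length(idx), fs, profile$carrier_band_hz)
        carrier <- profile$regularity * tone + (1 - profile$regularity) * noise
        s <- env * carrier
        r <- sd_pop(s)
        if (r > 0) {
          s <- s / r * profile$burst_gain * gain_jitter[b, ch] * profile$baseline_rms
          x[idx] <- x[idx] + s
        }
      }
      if (profile$ecg_interference_gain > 0) {
        tt <- (0:(n - 1)) / fs
        ecg <- cos(2 * pi * 1.4 * tt + ecg_phase) +
          0.5 * cos(2 * pi * 2.8 * tt + 2 * ecg_phase) +
          0.25 * cos(2 * pi * 4.2 * tt + 3 * ecg_phase)
        x <- x + ecg / sd_pop(ecg) *
          profile$ecg_interference_gain * profile$baseline_rms
      }
      channels[[ch]] <- x
    }
    names(channels) <- paste0("S", seq_len(nch))
    ann <- tibble::tibble(
      burst_index = seq_len(n_bursts),
      midpoint_s = midpoints, duration_s = durations,
      carrier_hz = carrier_hz)
    for (ch in seq_len(nch))
      ann[[paste0("gain_S", ch)]] <-
        if (n_bursts) profile$burst_gain * gain_jitter[seq_len(n_bursts), ch]
        else numeric(0)
    ehg_record(
      record_id = sprintf("%s%03d", profile$label, record_index),
      channels = channels, fs_hz = fs, label = profile$label,
      annotations = ann, profile = profile)
  })
}

#' Generate a labeled synthetic cohort
#'
#' Produces `config$n_P` preterm followed by `config$n_T` term records.  If
#' `dir` is given, records are written as WFDB (.hea/.dat, format 16) with a
#' mirrored CSV per record, a ground-truth `manifest.csv`, and the resolved
#' configuration as JSON.
#'
#' @param p_profile,t_profile class profiles for the two groups.
#' @param config an [sim_config()].
#' @param dir optional output directory.
#' @return an `ehg_cohort` (a list of `ehg_record`s) with a `manifest`
#'   attribute (tibble).
#' @export
generate_cohort <- function(p_profile, t_profile, config, dir = NULL) {
  stopifnot(config$n_P >= 1, config$n_T >= 1)
  profiles <- c(rep(list(p_profile), config$n_P),
                rep(list(t_profile), config$n_T))
  records <- vector("list", length(profiles))
  for (i in seq_along(profiles))
    records[[i]] <- generate_record(profiles[[i]], config, i)
  names(records) <- vapply(records, `[[`, "", "record_id")
  manifest <- do.call(rbind, lapply(records, function(r) {
    pr <- r$profile
    tibble::tibble(
      record_id = r$record_id, label = r$label,
      burst_rate = pr$burst_rate, burst_gain = pr$burst_gain,
      regularity = pr$regularity,
      ecg_interference_gain = pr$ecg_interference_gain,
      baseline_noise_exponent = pr$baseline_noise_exponent,
      n_bursts = nrow(r$annotations))
  }))
  cohort <- structure(records, class = "ehg_cohort", manifest = manifest)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (r in cohort) {
      write_wfdb_record(r, dir)
      write.csv(as.data.frame(r$channels),
                file.path(dir, paste0(r$record_id, ".csv")), row.names = FALSE)
    }
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    jsonlite::write_json(unclass(config), file.path(dir, "sim_config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  cohort
}

#' @export
print.ehg_cohort <- function(x, ...) {
  m <- attr(x, "manifest")
  cat(sprintf("<ehg_cohort> %d records (%d P, %d T)\n", length(x),
              sum(m$label == "P"), sum(m$label == "T")))
  invisible(x)
}
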