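#' Construct an EHG record
#'
#' The unit of analysis and of train/validation/test splitting: a
#' multichannel signal with sampling rate, class label and gestational-age
#' metadata.  Channels are named S1, S2, ... (bipolar electrode pairs).
#'
#' @param record_id character identifier.
#' @param channels named list of equal-length numeric vectors.
#' @param fs_hz sampling rate in Hz.
#' @param label `"P"`, `"T"` or `NA`.
#' @param gestational_age_rec_weeks gestational age at recording (weeks).
#' @param gestational_age_del_weeks gestational age at delivery (weeks).
#' @param excluded logical exclusion flag; `exclusion_reason` says why.
#' @param exclusion_reason character or `NA`.
#' @param annotations optional tibble of burst ground truth (synthetic
#'   records only).
#' @param profile the generating [class_profile()] for synthetic records.
#' @return an object of class `ehg_record`.
#' @export
ehg_record <- function(record_id, channels, fs_hz, label = NA_character_,
                       gestational_age_rec_weeks = NA_real_,
                       gestational_age_del_weeks = NA_real_,
                       excluded = FALSE, exclusion_reason = NA_character_,
                       annotations = NULL, profile = NULL) {
  if (fs_hz <= 0) stop_ehg("fs_hz must be positive")
  lens <- vapply(channels, length, 0L)
  if (length(unique(lens)) != 1)
    stop_ehg("all channels must have equal length")
  if (!is.na(label) && !label %in% c("P", "T"))
    stop_ehg("label must be 'P' or 'T'")
  structure(list(
    record_id = record_id, channels = channels, fs_hz = fs_hz,
    label = label,
    gestational_age_rec_weeks = gestational_age_rec_weeks,
    gestational_age_del_weeks = gestational_age_del_weeks,
    excluded = excluded, exclusion_reason = exclusion_reason,
    annotations = annotations, profile = profile), class = "ehg_record")
}

#' @export
print.ehg_record <- function(x, ...) {
  cat(sprintf("<ehg_record> %s: %d channel(s) x %d samples @ %g Hz, label %s%s\n",
              x$record_id, length(x$channels), length(x$channels[[1]]),
              x$fs_hz, x$label,
              if (isTRUE(x$excluded)) sprintf(" [excluded: %s]", x$exclusion_reason) else ""))
  invisible(x)
}

#' Write an EHG record in WFDB format
#'
#' Emits `<record_id>.hea` and `<record_id>.dat` (format 16: little-endian
#' 16-bit two's-complement integers, channel-interleaved).  A per-channel
#' ADC gain is chosen so the signal spans the 16-bit range and is recorded
#' in the header; metadata go into `#`-comment lines (`Group`, `Gestation`
#' = gestational age at recording, `Delivery` = gestational age at
#' delivery), which [read_wfdb_record()] parses back.
#'
#' @param record an `ehg_record`.
#' @param dir output directory.
#' @return invisibly, the header path.
#' @export
write_wfdb_record <- function(record, dir) {
  stopifnot(inherits(record, "ehg_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nch <- length(record$channels)
  n <- length(record$channels[[1]])
  dat <- paste0(record$record_id, ".dat")
  gains <- vapply(record$channels, function(x) {
    m <- max(abs(x))
    if (m == 0) 1 else 32000 / m
  }, 0)
  digital <- matrix(0L, nrow = nch, ncol = n)
  for (i in seq_len(nch))
    digital[i, ] <- as.integer(round(record$channels[[i]] * gains[i]))
  hdr <- c(sprintf("%s %d %g %d", record$record_id, nch, record$fs_hz, n))
  for (i in seq_len(nch)) {
    first <- digital[i, 1]
    chk <- sum(digital[i, ]) %% 65536
    if (chk >= 32768) chk <- chk - 65536
    hdr <- c(hdr, sprintf("%s 16 %.6f(0)/nu 16 0 %d %d 0 %s",
                          dat, gains[i], first, chk, names(record$channels)[i]))
  }
  if (!is.na(record$label)) hdr <- c(hdr, sprintf("# Group %s", record$label))
  if (!is.na(record$gestational_age_rec_weeks))
    hdr <- c(hdr, sprintf("# Gestation %g", record$gestational_age_rec_weeks))
  if (!is.na(record$gestational_age_del_weeks))
    hdr <- c(hdr, sprintf("# Delivery %g", record$gestational_age_del_weeks))
  writeLines(hdr, file.path(dir, paste0(record$record_id, ".hea")))
  con <- file(file.path(dir, dat), "wb")
  on.exit(close(con))
  writeBin(as.integer(digital), con, size = 2, endian = "little")
  invisible(file.path(dir, paste0(record$record_id, ".hea")))
}

#' Read a WFDB record
#'
#' Reads a `.hea`/`.dat` pair written in format 16 (the format of the
#' clinical EHG archives and of [write_wfdb_record()]).  Channels are mapped
#' to S1, S2, ... in header order; `Gestation`/`Rectime` comments populate
#' the gestational age at recording, `Delivery` the age at delivery, and
#' `Group` the class label.
#'
#' @param path path to the `.hea` file, or the record path without
#'   extension.
#' @param expect_channels required channel count (default 3); a mismatch is
#'   an error.
#' @param expect_fs required sampling rate, or `NULL` to accept any.
#' @return an `ehg_record` with channels in physical units (digital values
#'   divided by the header gain).
#' @export
read_wfdb_record <- function(path, expect_channels = 3, expect_fs = 20) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop_ehg("header file not found: %s", hea)
  lines <- readLines(hea, warn = FALSE)
  comments <- grep("^#", lines, value = TRUE)
  lines <- grep("^#", lines, value = TRUE, invert = TRUE)
  lines <- lines[nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  record_id <- rec[1]
  nch <- as.integer(rec[2])
  fs <- if (length(rec) >= 3) as.numeric(rec[3]) else 250
  n <- if (length(rec) >= 4) as.integer(rec[4]) else NA_integer_
  if (!is.null(expect_channels) && nch != expect_channels)
    stop_ehg("record %s declares %d channels, expected %d",
             record_id, nch, expect_channels)
  if (!is.null(expect_fs) && fs != expect_fs)
    stop_ehg("record %s has sampling rate %g, expected %g", record_id, fs, expect_fs)
  sig <- lapply(lines[2:(1 + nch)], function(l) strsplit(trimws(l), "\\s+")[[1]])
  dat_file <- sig[[1]][1]
  fmt <- sig[[1]][2]
  if (fmt != "16") stop_ehg("unsupported WFDB signal format '%s' (only 16)", fmt)
  gains <- vapply(sig, function(s) {
    g <- sub("\\(.*$", "", sub("/.*$", "", s[3]))
    g <- as.numeric(g)
    if (is.na(g) || g == 0) 200 else g  # WFDB default gain
  }, 0)
  dat_path <- file.path(dirname(hea), dat_file)
  if (!file.exists(dat_path)) stop_ehg("signal file not found: %s", dat_path)
  raw_n <- file.size(dat_path) / 2
  con <- file(dat_path, "rb")
  on.exit(close(con))
  digital <- readBin(con, "integer", n = raw_n, size = 2, endian = "little")
  if (is.na(n)) n <- length(digital) %/% nch
  digital <- matrix(digital[seq_len(n * nch)], nrow = nch)
  channels <- lapply(seq_len(nch), function(i) digital[i, ] / gains[i])
  names(channels) <- paste0("S", seq_len(nch))
  meta <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "\\s"), comments, value = TRUE)
    if (!length(hit)) return(NA)
    trimws(sub(paste0("^#\\s*", key, "\\s+"), "", hit[1]))
  }
  ga_rec <- suppressWarnings(as.numeric(meta("Gestation")))
  if (is.na(ga_rec)) ga_rec <- suppressWarnings(as.numeric(meta("Rectime")))
  label <- meta("Group")
  if (!is.na(label) && !label %in% c("P", "T")) label <- NA_character_
  ehg_record(record_id = record_id, channels = channels, fs_hz = fs,
             label = if (is.na(label)) NA_character_ else label,
             gestational_age_rec_weeks = ga_rec,
             gestational_age_del_weeks = suppressWarnings(as.numeric(meta("Delivery"))))
}
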