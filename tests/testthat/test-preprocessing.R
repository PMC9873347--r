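test_that("WFDB records round-trip through write and read", {
  cfg <- sim_config(n_P = 1, n_T = 1, duration_s = 300, seed = 7)
  rec <- generate_record(preterm_profile(), cfg, 1)
  rec$gestational_age_rec_weeks <- 30.4
  rec$gestational_age_del_weeks <- 34.1
  dir <- withr::local_tempdir()
  write_wfdb_record(rec, dir)
  back <- read_wfdb_record(file.path(dir, paste0(rec$record_id, ".hea")))
  expect_identical(back$record_id, rec$record_id)
  expect_identical(back$label, "P")
  expect_equal(back$gestational_age_rec_weeks, 30.4)
  expect_equal(back$gestational_age_del_weeks, 34.1)
  for (ch in names(rec$channels)) {
    gain <- 32000 / max(abs(rec$channels[[ch]]))
    expect_lt(max(abs(back$channels[[ch]] - rec$channels[[ch]])), 1 / gain)
  }
})

test_that("WFDB reader validates channel count, rate and files", {
  dir <- withr::local_tempdir()
  expect_error(read_wfdb_record(file.path(dir, "nope.hea")), "not found")
  writeLines(c("r2 2 20 100", "r2.dat 16 100(0)/nu 16 0 0 0 0 S1",
               "r2.dat 16 100(0)/nu 16 0 0 0 0 S2"),
             file.path(dir, "r2.hea"))
  writeBin(integer(200), file.path(dir, "r2.dat"), size = 2)
  expect_error(read_wfdb_record(file.path(dir, "r2.hea")), "2 channels")
  expect_error(read_wfdb_record(file.path(dir, "r2.hea"), expect_channels = 2,
                                expect_fs = 250), "sampling rate")
  # a minimal conforming header with a Gestation comment parses
  writeLines(c("r3 1 20 10", "r3.dat 16 1000(0)/nu 16 0 0 0 0 S1",
               "# Gestation 30.4"), file.path(dir, "r3.hea"))
  writeBin(1:10, file.path(dir, "r3.dat"), size = 2)
  r3 <- read_wfdb_record(file.path(dir, "r3.hea"), expect_channels = 1)
  expect_equal(r3$gestational_age_rec_weeks, 30.4)
})

test_that("gestational-age filtering is inclusive and flags, not deletes", {
  mk <- function(id, ga) ehg_record(id, list(S1 = rnorm(50)), 20, "T",
                                    gestational_age_rec_weeks = ga)
  recs <- list(mk("a", 26.9), mk("b", 27.0), mk("c", 33.0), mk("d", 33.1),
               mk("e", NA))
  out <- filter_records_by_ga(recs, 27, 33)
  kept <- vapply(out, function(r) !r$excluded, TRUE)
  expect_identical(unname(kept), c(FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_identical(out[[5]]$exclusion_reason, "no-metadata")
  expect_length(filter_records_by_ga(list()), 0)
  all_in <- filter_records_by_ga(recs[2:3], 27, 33)
  expect_true(all(!vapply(all_in, `[[`, TRUE, "excluded")))
})

test_that("balanced subsampling is seeded and validates class sizes", {
  mk <- function(id, lab) ehg_record(id, list(S1 = rnorm(10)), 20, lab)
  recs <- c(lapply(1:5, function(i) mk(paste0("P", i), "P")),
            lapply(1:20, function(i) mk(paste0("T", i), "T")))
  sel <- balance_by_subsampling(recs, 5, seed = 3)
  labs <- vapply(sel, `[[`, "", "label")
  expect_identical(as.vector(table(labs)[c("P", "T")]), c(5L, 5L))
  sel2 <- balance_by_subsampling(recs, 5, seed = 3)
  expect_identical(vapply(sel, `[[`, "", "record_id"),
                   vapply(sel2, `[[`, "", "record_id"))
  expect_error(balance_by_subsampling(recs, 6), "class P")
})

test_that("z-score gives zero mean, unit population SD, and is idempotent", {
  z <- zscore(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1) * sqrt(1.5), tolerance = 1e-12)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sqrt(mean(z^2)) - 1), 1e-12)
  expect_error(zscore(rep(2, 10)), "zero variance")
  set.seed(1); x <- rnorm(500) * 3 + 7
  expect_equal(zscore(zscore(x)), zscore(x), tolerance = 1e-10)
})

test_that("band-pass keeps in-band tones and rejects out-of-band tones", {
  fs <- 20
  t <- seq(0, 300, by = 1 / fs)
  keep <- (10 * fs):(length(t) - 10 * fs)  # discard 10-s edges
  x1 <- sin(2 * pi * 0.65 * t)
  y1 <- bandpass(x1, ehg_band("F1"), fs)
  expect_lt(abs(sqrt(mean(y1[keep]^2)) / sqrt(mean(x1[keep]^2)) - 1), 0.02)
  x2 <- sin(2 * pi * 2.5 * t)
  y2 <- bandpass(x2, ehg_band("F1"), fs)
  expect_lt(sqrt(mean(y2[keep]^2)) / sqrt(mean(x2[keep]^2)), 0.1)
  expect_identical(bandpass(numeric(4000), ehg_band("F2"), fs), numeric(4000))
  expect_error(bandpass(x1, band_definition("bad", 2, 11), fs), "Nyquist")
  # linearity
  set.seed(2); w <- rnorm(4000)
  expect_equal(bandpass(3.7 * w, ehg_band("F2"), fs),
               3.7 * bandpass(w, ehg_band("F2"), fs), tolerance = 1e-10)
})

test_that("windowing yields fully contained half-overlapping segments", {
  x <- seq_len(36000)
  w <- segment_windows(x, 20, 120, 0.5)
  expect_length(w, 29)
  expect_true(all(lengths(w) == 2400))
  expect_identical(w[[2]][1:1200], w[[1]][1201:2400])
  expect_length(segment_windows(seq_len(2400), 20), 1)
  expect_error(segment_windows(seq_len(2399), 20), "shorter")
})

test_that("record splitting is stratified, seeded, 14/3/3 at 20 per class", {
  mk <- function(id, lab) ehg_record(id, list(S1 = rnorm(10)), 20, lab)
  recs <- c(lapply(1:20, function(i) mk(paste0("P", i), "P")),
            lapply(1:20, function(i) mk(paste0("T", i), "T")))
  sp <- split_records(recs, seed = 11)
  tab <- table(sp$label, sp$split)
  expect_identical(as.vector(tab["P", c("train", "validation", "test")]),
                   c(14L, 3L, 3L))
  expect_identical(as.vector(tab["T", c("train", "validation", "test")]),
                   c(14L, 3L, 3L))
  expect_identical(sp, split_records(recs, seed = 11))
  # disjoint exhaustive partition
  expect_setequal(sp$record_id, vapply(recs, `[[`, "", "record_id"))
  expect_false(any(duplicated(sp$record_id)))
  all_train <- split_records(recs, fractions = c(1, 0, 0), seed = 1)
  expect_true(all(all_train$split == "train"))
})

test_that("a tiny class degenerates to all-train with a warning", {
  mk <- function(id, lab) ehg_record(id, list(S1 = rnorm(10)), 20, lab)
  recs <- c(lapply(1:2, function(i) mk(paste0("P", i), "P")),
            lapply(1:9, function(i) mk(paste0("T", i), "T")))
  expect_warning(sp <- split_records(recs, seed = 1), "all to train")
  expect_true(all(sp$split[sp$label == "P"] == "train"))
})
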