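# a small, fast cohort for pipeline-level tests: 6 + 6 records of 10 min
small_cohort <- function(seed = 1, contrast = TRUE) {
  cfg <- sim_config(n_P = 6, n_T = 6, duration_s = 600, seed = seed)
  if (contrast)
    generate_cohort(preterm_profile(), term_profile(), cfg)
  else
    generate_cohort(term_profile(label = "P"), term_profile(), cfg)
}

small_config <- function(seed = 1)
  study_config(channels = "S1", bands = list(ehg_band("F1")), k = 10,
               seed = seed)

test_that("the full study runs, separates a contrast cohort, and audits clean", {
  co <- small_cohort(seed = 5)
  rep <- run_full_study(co, small_config(seed = 5))
  expect_s3_class(rep, "study_report")
  d <- rep$datasets$S1F1
  expect_identical(d$status, "ok")
  expect_gte(length(d$selection$final_features), 7)
  expect_lte(length(d$selection$final_features), 13)
  expect_true(d$family %in% classifier_families())
  s <- summary(rep)
  expect_gt(s$test_accuracy, 0.8)
  # no-leakage audit: selection saw only training records; test records
  # never appear in the pooled folds
  sp <- rep$split
  expect_identical(d$selection_splits, "train")
  expect_true(all(d$selection_records %in% sp$record_id[sp$split == "train"]))
  test_ids <- sp$record_id[sp$split == "test"]
  pool_ids <- sp$record_id[sp$split != "test"]
  expect_length(intersect(test_ids, pool_ids), 0)
  # Mann-Whitney screen covers all 33 features
  expect_identical(d$screen$feature, feature_names())
})

test_that("feature extraction emits the documented table shape", {
  co <- small_cohort(seed = 7)[1:3]
  tab <- extract_features(co, channels = "S1",
                          bands = list(ehg_band("F1"), ehg_band("F2")))
  # 600 s at 20 Hz: floor((12000 - 2400)/1200) + 1 = 9 windows per record
  expect_identical(nrow(tab), 3L * 2L * 9L)
  expect_identical(colnames(tab),
                   c("record_id", "label", "channel", "band", "window_index",
                     "split", feature_names()))
  expect_true(all(tab$band %in% c("F1", "F2")))
})

test_that("study reruns with the same seed are identical; reports persist", {
  co <- small_cohort(seed = 9)
  r1 <- run_full_study(co, small_config(seed = 9))
  r2 <- run_full_study(co, small_config(seed = 9))
  expect_identical(summary(r1), summary(r2))
  expect_identical(r1$datasets$S1F1$selection$final_features,
                   r2$datasets$S1F1$selection$final_features)
  dir <- withr::local_tempdir()
  write_study_report(r1, dir)
  expect_true(file.exists(file.path(dir, "metrics_summary.csv")))
  expect_true(file.exists(file.path(dir, "screen_stars.csv")))
  expect_true(file.exists(file.path(dir, "S1F1_cv_folds.csv")))
  man <- jsonlite::read_json(file.path(dir, "run_manifest.json"))
  expect_identical(man$datasets$S1F1$status, "ok")
  expect_identical(man$config$seed, 9L)
})

test_that("cli subcommands simulate, extract and run-study work end to end", {
  dir <- withr::local_tempdir()
  sim_dir <- file.path(dir, "cohort")
  expect_identical(ehg_cli(c("simulate", "--out", sim_dir, "--n-p", "3",
                             "--n-t", "3", "--duration", "600",
                             "--seed", "4")), 0L)
  expect_length(list.files(sim_dir, pattern = "\\.hea$"), 6)
  expect_true(file.exists(file.path(sim_dir, "manifest.csv")))
  expect_true(file.exists(file.path(sim_dir, "sim_config.json")))
  # rerun: byte-identical signal files
  sim_dir2 <- file.path(dir, "cohort2")
  ehg_cli(c("simulate", "--out", sim_dir2, "--n-p", "3", "--n-t", "3",
            "--duration", "600", "--seed", "4"))
  f1 <- list.files(sim_dir, pattern = "\\.dat$", full.names = TRUE)
  f2 <- list.files(sim_dir2, pattern = "\\.dat$", full.names = TRUE)
  for (i in seq_along(f1))
    expect_identical(readBin(f1[i], "raw", file.size(f1[i])),
                     readBin(f2[i], "raw", file.size(f2[i])))
  feat_csv <- file.path(dir, "features.csv")
  expect_identical(ehg_cli(c("extract", "--records", sim_dir, "--out",
                             feat_csv, "--channels", "S1",
                             "--bands", "F1")), 0L)
  tab <- read.csv(feat_csv)
  expect_identical(nrow(tab), 6L * 9L)
  expect_true(all(feature_names() %in% colnames(tab)))
  # unknown command and missing inputs exit nonzero
  expect_identical(ehg_cli(c("extract", "--records",
                             file.path(dir, "missing"), "--out", feat_csv)), 1L)
  expect_identical(suppressMessages(ehg_cli("frobnicate")), 1L)
})

test_that("degenerate and near-null inputs keep the pipeline honest", {
  # identical class profiles: accuracy should hover near chance
  co <- small_cohort(seed = 11, contrast = FALSE)
  rep <- run_full_study(co, small_config(seed = 11))
  s <- summary(rep)
  expect_lt(s$test_accuracy, 0.9)  # no spurious perfect separation
  expect_identical(rep$datasets$S1F1$status, "ok")
})
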