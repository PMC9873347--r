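#' Study configuration
#'
#' Bundles every knob of an end-to-end run: which channels and subbands to
#' analyse (each `(channel, band)` pair becomes one dataset with its own
#' selection and classifier), windowing, record-split fractions, candidate
#' classifier families, cross-validation folds and the global seed.
#'
#' @param channels channel names, or `NULL` for all channels present.
#' @param bands list of [band_definition()]s.
#' @param window_s,overlap windowing parameters.
#' @param fractions train/validation/test record fractions.
#' @param families candidate classifier families.
#' @param k cross-validation folds.
#' @param sfs_classifier base classifier for sequential selection.
#' @param positive_class positive (detected) class.
#' @param seed global seed; stage seeds are derived from it.
#' @return an object of class `study_config`.
#' @export
study_config <- function(channels = NULL, bands = ehg_bands(),
                         window_s = 120, overlap = 0.5,
                         fractions = c(0.70, 0.15, 0.15),
                         families = classifier_families(), k = 23,
                         sfs_classifier = "lda", positive_class = "P",
                         seed = 1) {
  structure(list(channels = channels, bands = bands, window_s = window_s,
                 overlap = overlap, fractions = fractions,
                 families = families, k = as.integer(k),
                 sfs_classifier = sfs_classifier,
                 positive_class = positive_class, seed = as.integer(seed)),
            class = "study_config")
}

# pick the family with the best validation accuracy (AUC breaks ties):
# train each candidate on the training windows only, score on validation
choose_family <- function(train_tab, valid_tab, selected, config) {
  Xtr <- as.matrix(as.data.frame(train_tab)[, selected, drop = FALSE])
  Xva <- as.matrix(as.data.frame(valid_tab)[, selected, drop = FALSE])
  rows <- lapply(config$families, function(fam) {
    spec <- classifier_spec(fam, seed = derive_seed(config$seed, "family", fam),
                            positive_class = config$positive_class)
    res <- tryCatch({
      model <- train_classifier(spec, Xtr, train_tab$label)
      pr <- predict(model, Xva)
      m <- suppressWarnings(compute_metrics(valid_tab$label, pr$class,
                                            pr$score, config$positive_class))
      tibble::tibble(family = fam, accuracy = m[["accuracy"]], auc = m[["auc"]])
    }, error = function(e) tibble::tibble(family = fam, accuracy = NA_real_,
                                          auc = NA_real_))
    res
  })
  tab <- do.call(rbind, rows)
  ok <- tab[!is.na(tab$accuracy), , drop = FALSE]
  if (!nrow(ok)) stop_ehg("no classifier family could be trained")
  ok <- ok[order(-ok$accuracy, -ok$auc, ok$family), ]
  list(best = ok$family[1], table = tab)
}

#' Run the full classification study
#'
#' The end-to-end pipeline on a labeled cohort: record-level stratified
#' 70/15/15 split, then for every `(channel, band)` dataset: z-score ->
#' subband filter -> 120-s windows -> 33 features; four-algorithm feature
#' selection on training windows only; classifier-family choice by
#' validation accuracy (AUC tie-break); k-fold cross-validation of the
#' chosen family over the pooled train+validation windows with evaluation
#' on the record-independent test set; and a Mann-Whitney screen of all 33
#' features.  Failures in one dataset are caught and recorded so partial
#' results survive.
#'
#' @param records a labeled `ehg_cohort` or list of `ehg_record`s.
#' @param config a [study_config()].
#' @return an object of class `study_report`: per-dataset results
#'   (`datasets`), the record split, the resolved config.
#' @export
run_full_study <- function(records, config = study_config()) {
  if (inherits(records, "ehg_record")) records <- list(records)
  records <- Filter(function(r) !isTRUE(r$excluded), records)
  split <- split_records(records, config$fractions,
                         seed = derive_seed(config$seed, "split"))
  features <- extract_features(records, channels = config$channels,
                               bands = config$bands,
                               window_s = config$window_s,
                               overlap = config$overlap, split = split)
  datasets <- list()
  for (ch in unique(features$channel)) for (bd in unique(features$band)) {
    id <- paste0(ch, bd)
    tab <- features[features$channel == ch & features$band == bd, , drop = FALSE]
    datasets[[id]] <- tryCatch({
      train_tab <- tab[tab$split == "train", , drop = FALSE]
      valid_tab <- tab[tab$split == "validation", , drop = FALSE]
      sel <- select_features(train_tab, train_tab$label,
                             seed = derive_seed(config$seed, "select", id),
                             sfs_classifier = config$sfs_classifier)
      fam <- choose_family(train_tab, valid_tab, sel$final_features, config)
      spec <- classifier_spec(fam$best,
                              seed = derive_seed(config$seed, "cv", id),
                              positive_class = config$positive_class)
      cv <- kfold_cross_validate(tab, spec, selected = sel$final_features,
                                 k = config$k,
                                 seed = derive_seed(config$seed, "cv", id))
      screen <- mann_whitney_screen(tab)
      list(dataset = id, status = "ok", selection = sel,
           selection_records = unique(train_tab$record_id),
           selection_splits = unique(train_tab$split),
           family = fam$best, family_table = fam$table,
           cv = cv, screen = screen,
           n_windows = nrow(tab))
    }, error = function(e)
      list(dataset = id, status = "error", message = conditionMessage(e)))
  }
  structure(list(datasets = datasets, split = split, config = config,
                 n_records = length(records)), class = "study_report")
}

#' Summarize a study report
#'
#' @param object a `study_report`.
#' @param ... unused.
#' @return tibble with one row per dataset: chosen family, selected feature
#'   count, and mean +/- SD test accuracy/sensitivity/specificity/AUC.
#' @export
summary.study_report <- function(object, ...) {
  rows <- lapply(object$datasets, function(d) {
    if (d$status != "ok")
      return(tibble::tibble(dataset = d$dataset, family = NA_character_,
                            n_features = NA_integer_, test_accuracy = NA_real_,
                            test_accuracy_sd = NA_real_, test_auc = NA_real_))
    s <- d$cv$summary
    pick <- function(metric, col) {
      r <- s[s$split == "test" & s$metric == metric, ]
      if (nrow(r)) r[[col]] else NA_real_
    }
    tibble::tibble(dataset = d$dataset, family = d$family,
                   n_features = length(d$selection$final_features),
                   test_accuracy = pick("accuracy", "mean"),
                   test_accuracy_sd = pick("accuracy", "sd"),
                   test_auc = pick("auc", "mean"))
  })
  do.call(rbind, rows)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d records, %d dataset(s)\n",
              x$n_records, length(x$datasets)))
  print(summary(x))
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits, per dataset, the per-fold and summary metric CSVs, the
#' Mann-Whitney star matrix CSV, and a JSON manifest with the resolved
#' configuration, seeds, record split and selected features, so a run is
#' fully reproducible from its output directory.
#'
#' @param report a `study_report`.
#' @param dir output directory.
#' @return invisibly, the manifest path.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- unclass(report$config)
  cfg$bands <- lapply(cfg$bands, unclass)
  manifest <- list(config = cfg,
                   n_records = report$n_records,
                   split = as.data.frame(report$split),
                   datasets = list())
  summaries <- list()
  screens <- list()
  for (d in report$datasets) {
    if (d$status != "ok") {
      manifest$datasets[[d$dataset]] <- list(status = d$status,
                                             message = d$message)
      next
    }
    write.csv(as.data.frame(d$cv$folds),
              file.path(dir, sprintf("%s_cv_folds.csv", d$dataset)),
              row.names = FALSE)
    summaries[[d$dataset]] <- cbind(dataset = d$dataset, family = d$family,
                                    as.data.frame(d$cv$summary))
    screens[[d$dataset]] <- cbind(dataset = d$dataset,
                                  as.data.frame(d$screen))
    manifest$datasets[[d$dataset]] <- list(
      status = "ok", family = d$family,
      final_features = d$selection$final_features,
      ftest_top10 = d$selection$ftest_top10,
      chi2_top10 = d$selection$chi2_top10,
      regression_selected = d$selection$regression_selected,
      seqsel_selected = d$selection$seqsel_selected)
  }
  if (length(summaries))
    write.csv(do.call(rbind, summaries), file.path(dir, "metrics_summary.csv"),
              row.names = FALSE)
  if (length(screens))
    write.csv(do.call(rbind, screens), file.path(dir, "screen_stars.csv"),
              row.names = FALSE)
  path <- file.path(dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
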