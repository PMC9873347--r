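#' k-fold cross-validation with a record-independent test set
#'
#' The train and validation windows are pooled and randomly partitioned
#' into `k` folds (default 23; when the pool size is not divisible by `k`
#' the remainder is spread over the leading folds).  For each fold a model
#' is trained on the other `k - 1` folds and evaluated on (a) its own
#' training windows, (b) the held-out fold, and (c) the fixed test set,
#' whose records never appear in the pool — any record overlap between
#' pool and test is a hard error.
#'
#' @param features a window feature table with `record_id`, `label` and
#'   `split` columns (from [extract_features()] joined with
#'   [split_records()]).
#' @param spec a [classifier_spec()].
#' @param selected character vector of feature columns to use.
#' @param k number of folds.
#' @param seed integer seed for the fold permutation.
#' @return an object of class `cv_result`: per-fold metric tibble
#'   (`folds`), mean +/- SD per split (`summary`), and the spec.
#' @export
kfold_cross_validate <- function(features, spec, selected = feature_names(),
                                 k = 23, seed = 1) {
  pool <- features[features$split %in% c("train", "validation"), , drop = FALSE]
  test <- features[features$split == "test", , drop = FALSE]
  leaked <- intersect(unique(pool$record_id), unique(test$record_id))
  if (length(leaked))
    stop_ehg("record leakage between pool and test: %s",
             paste(leaked, collapse = ", "))
  n <- nrow(pool)
  if (n < k) stop_ehg("pooled windows (%d) fewer than folds (%d)", n, k)
  M <- as.matrix(as.data.frame(pool)[, selected, drop = FALSE])
  y <- pool$label
  Mtest <- as.matrix(as.data.frame(test)[, selected, drop = FALSE])
  ytest <- test$label
  # equal fold sizes, remainder over the leading folds
  sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
  perm <- with_seed(derive_seed(seed, "cvfolds"), sample(n))
  fold_id <- integer(n)
  fold_id[perm] <- rep(seq_len(k), times = sizes)
  rows <- list()
  for (f in seq_len(k)) {
    tr <- fold_id != f
    model <- train_classifier(spec, M[tr, , drop = FALSE], y[tr])
    eval_on <- function(X, yy, split) {
      pr <- predict(model, X)
      m <- suppressWarnings(
        compute_metrics(yy, pr$class, pr$score, spec$positive_class))
      tibble::tibble(fold = f, split = split, !!!as.list(unclass(m)))
    }
    rows[[length(rows) + 1L]] <- rbind(
      eval_on(M[tr, , drop = FALSE], y[tr], "train"),
      eval_on(M[!tr, , drop = FALSE], y[!tr], "validation"),
      if (nrow(Mtest)) eval_on(Mtest, ytest, "test"))
  }
  folds <- do.call(rbind, rows)
  metrics <- setdiff(colnames(folds), c("fold", "split"))
  summ <- do.call(rbind, lapply(split(folds, folds$split), function(d) {
    tibble::tibble(split = d$split[1],
                   metric = metrics,
                   mean = unname(vapply(metrics, function(m) mean(d[[m]], na.rm = TRUE), 0)),
                   sd = unname(vapply(metrics, function(m) sd(d[[m]], na.rm = TRUE), 0)))
  }))
  structure(list(folds = folds, summary = summ, k = k, spec = spec,
                 n_pool = n, n_test = nrow(test), seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, k = %d (%d pooled, %d test windows)\n",
              x$spec$family, x$k, x$n_pool, x$n_test))
  s <- x$summary[x$summary$metric %in% c("accuracy", "sensitivity",
                                         "specificity", "auc"), ]
  for (sp in unique(s$split)) {
    d <- s[s$split == sp, ]
    cat(sprintf("  %-10s %s\n", sp,
                paste(sprintf("%s %.3f+/-%.3f", d$metric, d$mean, d$sd),
                      collapse = "  ")))
  }
  invisible(x)
}

#' Mann-Whitney feature screening
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of each feature between
#' the two classes: exact for small samples (total n <= 20, no ties),
#' otherwise the normal approximation with tie correction.  Star codes mark
#' p < 0.05 (*), < 0.01 (**), < 0.001 (***), < 0.0001 (****).
#'
#' @param feature_table table containing the canonical feature columns.
#' @param labels class labels (`"P"`/`"T"`), or `NULL` to use the table's
#'   `label` column.
#' @return a tibble with `feature`, `p_value` and `stars`.
#' @export
mann_whitney_screen <- function(feature_table, labels = NULL) {
  labels <- labels %||% feature_table$label
  y <- label_factor(labels)
  if (min(table(y)) < 3) stop_ehg("need >= 3 windows per class")
  feats <- intersect(feature_names(), colnames(feature_table))
  res <- lapply(feats, function(f) {
    a <- feature_table[[f]][y == "P"]
    b <- feature_table[[f]][y == "T"]
    p <- if (sd(c(a, b)) == 0) 1.0 else {
      exact <- (length(a) + length(b)) <= 20 && !anyDuplicated(c(a, b))
      suppressWarnings(wilcox.test(a, b, exact = exact,
                                   alternative = "two.sided")$p.value)
    }
    tibble::tibble(feature = f, p_value = p,
                   stars = cut(p, c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
                               labels = c("****", "***", "**", "*", "ns")))
  })
  do.call(rbind, res)
}
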