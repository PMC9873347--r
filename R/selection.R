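feature_matrix <- function(X) {
  X <- as.data.frame(X)[, intersect(feature_names(), colnames(X)), drop = FALSE]
  as.matrix(X)
}

label_factor <- function(y) factor(as.character(y), levels = c("T", "P"))

#' Rank features by one-way F statistic
#'
#' Features are ordered by decreasing between-class to within-class
#' variance ratio; a feature with zero within-class variance but distinct
#' class means gets an infinite statistic and ranks first.  Ties are broken
#' by canonical feature-name order.
#'
#' @param X feature table (the 33 canonical columns; extra columns are
#'   ignored).
#' @param y class labels (`"P"`/`"T"`).
#' @param top number of names to return (default 10).
#' @return character vector of feature names, best first; the statistics
#'   are attached as attribute `statistic`.
#' @export
rank_ftest <- function(X, y, top = 10) {
  M <- feature_matrix(X)
  y <- label_factor(y)
  if (min(table(y)) < 2) stop_ehg("need >= 2 samples per class")
  stat <- apply(M, 2, function(v) {
    mg <- tapply(v, y, mean)
    ng <- tapply(v, y, length)
    gm <- mean(v)
    ssb <- sum(ng * (mg - gm)^2)
    ssw <- sum((v - mg[y])^2)
    dfb <- nlevels(y) - 1
    dfw <- length(v) - nlevels(y)
    if (ssw == 0) {
      if (ssb == 0) return(0)
      return(Inf)
    }
    (ssb / dfb) / (ssw / dfw)
  })
  ord <- order(-stat, names(stat))
  ranked <- names(stat)[ord]
  structure(head(ranked, top), statistic = stat[ord][seq_len(min(top, length(ranked)))])
}

#' Rank features by chi-square statistic
#'
#' Each feature is discretized into `n_bins` equal-width bins and the
#' chi-square statistic of the bin-by-class contingency table (no
#' continuity correction, empty bins dropped) ranks the features.  A
#' constant feature has a single bin and statistic 0.
#'
#' @inheritParams rank_ftest
#' @param n_bins number of equal-width bins.
#' @return character vector of feature names, best first, with attribute
#'   `statistic`.
#' @export
rank_chi2 <- function(X, y, n_bins = 10, top = 10) {
  M <- feature_matrix(X)
  y <- label_factor(y)
  stat <- apply(M, 2, function(v) {
    rng <- max(v) - min(v)
    if (rng == 0) return(0)
    b <- pmin(floor((v - min(v)) / rng * n_bins) + 1, n_bins)
    tab <- table(b, y)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    if (nrow(tab) < 2) return(0)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - E)^2 / E)
  })
  ord <- order(-stat, names(stat))
  structure(head(names(stat)[ord], top),
            statistic = stat[ord][seq_len(min(top, length(stat)))])
}

#' Select features by linear regression p-values
#'
#' Fits one ordinary least squares model of the numeric label (P = 1,
#' T = 0) on all features jointly and keeps coefficients with p < `alpha`,
#' sorted by ascending p-value, at most `top`.  Collinear columns dropped
#' by the fit are excluded with a warning.  When there are too few samples
#' for the joint fit (`n <= p + 1`) the function falls back to univariate
#' regressions per feature, flagged via attribute `fallback`.
#'
#' @inheritParams rank_ftest
#' @param alpha significance threshold (default 0.05).
#' @return character vector of selected names (ascending p), with
#'   attributes `p_value` and `fallback`.
#' @export
select_regression <- function(X, y, alpha = 0.05, top = 10) {
  M <- feature_matrix(X)
  y01 <- as.numeric(label_factor(y)) - 1
  fallback <- nrow(M) <= ncol(M) + 1
  if (!fallback) {
    df <- data.frame(.y = y01, M, check.names = FALSE)
    fit <- lm(.y ~ ., data = df)
    sm <- summary(fit)$coefficients
    dropped <- setdiff(colnames(M), sub("^`|`$", "", rownames(sm)))
    if (length(dropped))
      warning(sprintf("dropped %d collinear feature(s): %s",
                      length(dropped), paste(dropped, collapse = ", ")))
    p <- sm[-1, "Pr(>|t|)"]
    names(p) <- sub("^`|`$", "", rownames(sm)[-1])
  } else {
    p <- apply(M, 2, function(v) {
      if (sd(v) == 0) return(1)
      summary(lm(y01 ~ v))$coefficients[2, "Pr(>|t|)"]
    })
  }
  p <- p[p < alpha]
  p <- p[order(p, names(p))]
  structure(head(names(p), top),
            p_value = head(p, top), fallback = fallback)
}

# stratified fold ids for internal CV
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

sfs_cv_accuracy <- function(M, y, cols, k, seed, base_classifier) {
  fold <- stratified_folds(y, k, seed)
  correct <- 0
  for (f in seq_len(k)) {
    tr <- fold != f
    Xtr <- M[tr, cols, drop = FALSE]
    Xte <- M[!tr, cols, drop = FALSE]
    pred <- tryCatch({
      if (base_classifier == "lda") {
        fit <- MASS::lda(Xtr, grouping = y[tr])
        predict(fit, Xte)$class
      } else {
        fit <- e1071::svm(Xtr, y[tr], kernel = "linear", cost = 1, scale = TRUE)
        predict(fit, Xte)
      }
    }, error = function(e) factor(rep(levels(y)[1], sum(!tr)), levels = levels(y)))
    correct <- correct + sum(pred == y[!tr])
  }
  correct / length(y)
}

#' Greedy sequential forward feature selection
#'
#' Starting from the empty set, repeatedly adds the candidate feature that
#' most improves the stratified `cv_folds`-fold cross-validated accuracy of
#' a cheap base classifier (LDA by default, a linear-kernel SVM
#' optionally), stopping when no candidate improves accuracy by more than
#' `min_improvement` or `max_features` is reached.  Candidate ties are
#' broken by canonical feature-name order; folds are seeded so the
#' selection is deterministic.
#'
#' @inheritParams rank_ftest
#' @param base_classifier `"lda"` or `"svm_linear"`.
#' @param max_features maximum selected set size (default 13).
#' @param cv_folds internal CV folds (default 5).
#' @param min_improvement minimum accuracy gain to keep adding.
#' @param seed integer seed for the folds.
#' @return character vector of selected names, in selection order, with
#'   attribute `cv_accuracy` (the accuracy trajectory).
#' @export
sequential_forward_selection <- function(X, y, base_classifier = c("lda", "svm_linear"),
                                         max_features = 13, cv_folds = 5,
                                         min_improvement = 1e-4, seed = 1) {
  base_classifier <- match.arg(base_classifier)
  M <- feature_matrix(X)
  y <- label_factor(y)
  if (length(y) < 20) stop_ehg("sequential selection needs >= 20 samples")
  selected <- character(0)
  best_acc <- 0
  trajectory <- numeric(0)
  candidates <- colnames(M)
  repeat {
    accs <- vapply(candidates, function(f)
      sfs_cv_accuracy(M, y, c(selected, f), cv_folds,
                      derive_seed(seed, "sfs"), base_classifier), 0)
    ord <- order(-accs, candidates)
    if (accs[ord[1]] <= best_acc + min_improvement) break
    pick <- candidates[ord[1]]
    selected <- c(selected, pick)
    best_acc <- accs[ord[1]]
    trajectory <- c(trajectory, best_acc)
    candidates <- setdiff(candidates, pick)
    if (length(selected) >= max_features || !length(candidates)) break
  }
  structure(selected, cv_accuracy = trajectory)
}

#' Combine the four selection algorithms into a final feature set
#'
#' Applies the combination rule: sequential-selection features that also
#' appear in any of the other three lists are kept, and regression-selected
#' features that also appear in the F-test or chi-square top lists are
#' added.  The result is padded with the highest-ranking unused F-test
#' features up to a minimum of 7 and truncated by F-test rank to a maximum
#' of 13, so every model uses between 7 and 13 predictors.
#'
#' @param ftest,chi2,regression,seqsel the four ordered name lists.
#' @param ftest_full full F-statistic ranking over all 33 features, used
#'   for padding/truncation (defaults to `ftest`).
#' @param min_features,max_features the enforced size range.
#' @return character vector of final feature names with attribute
#'   `provenance`, a data frame recording which algorithm(s) contributed
#'   each feature.
#' @export
combine_selections <- function(ftest, chi2, regression, seqsel,
                               ftest_full = NULL,
                               min_features = 7, max_features = 13) {
  all_names <- union(union(ftest, chi2), union(regression, seqsel))
  if (!length(all_names)) stop_ehg("all four selections are empty")
  ftest_full <- ftest_full %||% ftest
  rule <- union(intersect(seqsel, union(union(ftest, chi2), regression)),
                intersect(regression, union(ftest, chi2)))
  final <- rule
  padded <- character(0)
  if (length(final) < min_features) {
    pool <- setdiff(union(ftest_full, feature_names()), final)
    padded <- head(pool, min_features - length(final))
    final <- c(final, padded)
  }
  if (length(final) > max_features) {
    frank <- match(final, union(ftest_full, feature_names()))
    final <- final[order(frank)][seq_len(max_features)]
  }
  prov <- data.frame(
    feature = final,
    from_ftest = final %in% ftest,
    from_chi2 = final %in% chi2,
    from_regression = final %in% regression,
    from_seqsel = final %in% seqsel,
    padded = final %in% padded)
  structure(final, provenance = prov)
}

#' Run all four selection algorithms and combine them
#'
#' Convenience wrapper producing a full `selection_result`: the per-
#' algorithm rankings plus the combined 7-13 final features.  Selection
#' must only ever see training windows; the caller passes the training
#' subset and the split provenance is recorded.
#'
#' @inheritParams rank_ftest
#' @param seed integer seed (sequential selection folds).
#' @param sfs_classifier base classifier for the sequential search.
#' @return an object of class `selection_result`.
#' @export
select_features <- function(X, y, seed = 1, sfs_classifier = "lda") {
  ftest10 <- rank_ftest(X, y, top = 10)
  ftest_full <- rank_ftest(X, y, top = length(feature_names()))
  chi10 <- rank_chi2(X, y, top = 10)
  reg <- select_regression(X, y)
  sfs <- sequential_forward_selection(X, y, base_classifier = sfs_classifier,
                                      seed = seed)
  final <- combine_selections(ftest10, chi10, reg, sfs, ftest_full = ftest_full)
  structure(list(
    ftest_top10 = as.character(ftest10),
    chi2_top10 = as.character(chi10),
    regression_selected = as.character(reg),
    regression_p = attr(reg, "p_value"),
    seqsel_selected = as.character(sfs),
    final_features = as.character(final),
    provenance = attr(final, "provenance"),
    seed = seed), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>\n")
  cat("  F-test top10:  ", paste(x$ftest_top10, collapse = ", "), "\n")
  cat("  chi2 top10:    ", paste(x$chi2_top10, collapse = ", "), "\n")
  cat("  regression:    ", paste(x$regression_selected, collapse = ", "), "\n")
  cat("  sequential:    ", paste(x$seqsel_selected, collapse = ", "), "\n")
  cat("  final (", length(x$final_features), "): ",
      paste(x$final_features, collapse = ", "), "\n", sep = "")
  invisible(x)
}
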