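#' Classifier families
#'
#' The supported presets mirror common interactive-toolbox models:
#' quadratic/cubic SVM (polynomial kernel of degree 2/3, box constraint 1),
#' fine Gaussian SVM (RBF with kernel scale `sqrt(p)/4`), weighted KNN
#' (k = 10, squared-inverse-distance weights), bagged tree (30 learners)
#' and linear/quadratic discriminant analysis.  Features are standardized
#' with training-set statistics inside [train_classifier()].
#'
#' @return character vector of recognized family names.
#' @export
classifier_families <- function() {
  c("svm_quadratic", "svm_cubic", "svm_fine_gaussian",
    "knn_weighted", "bagged_tree",
    "discriminant_linear", "discriminant_quadratic")
}

#' Classifier specification
#'
#' @param family one of [classifier_families()].
#' @param seed integer seed (used by the bootstrap of the bagged tree).
#' @param positive_class the class whose detection sensitivity measures
#'   (default `"P"`, preterm).
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(family, seed = 1, positive_class = "P") {
  family <- match.arg(family, classifier_families())
  structure(list(family = family, seed = as.integer(seed),
                 positive_class = positive_class), class = "classifier_spec")
}

#' Train a classifier
#'
#' Fits the requested family on a feature matrix.  Features are centered
#' and scaled with the training statistics (stored in the model handle and
#' re-applied at prediction time); all models expose a continuous
#' positive-class score for ROC analysis.
#'
#' @param spec a [classifier_spec()].
#' @param X_train numeric matrix or feature table (rows = windows).
#' @param y_train class labels (`"P"`/`"T"`), both classes present.
#' @return an object of class `ehg_model`.
#' @export
train_classifier <- function(spec, X_train, y_train) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as.matrix(as.data.frame(X_train))
  y <- label_factor(y_train)
  if (nlevels(droplevels(y)) < 2) stop_ehg("training labels contain a single class")
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  Z <- scale(X, ctr, scl)
  p <- ncol(Z)
  fit <- switch(spec$family,
    svm_quadratic = e1071::svm(Z, y, kernel = "polynomial", degree = 2,
                               gamma = 1 / p, coef0 = 1, cost = 1, scale = FALSE),
    svm_cubic = e1071::svm(Z, y, kernel = "polynomial", degree = 3,
                           gamma = 1 / p, coef0 = 1, cost = 1, scale = FALSE),
    svm_fine_gaussian = e1071::svm(Z, y, kernel = "radial",
                                   gamma = 16 / p, cost = 1, scale = FALSE),
    knn_weighted = list(Z = Z, y = y, k = 10L),
    bagged_tree = {
      df <- data.frame(.y = y, Z, check.names = FALSE)
      with_seed(derive_seed(spec$seed, "bag"), lapply(1:30, function(b) {
        idx <- sample(nrow(df), replace = TRUE)
        rpart::rpart(.y ~ ., data = df[idx, ], method = "class",
                     control = rpart::rpart.control(cp = 0.01, xval = 0))
      }))
    },
    discriminant_linear = MASS::lda(Z, grouping = y),
    discriminant_quadratic = MASS::qda(Z, grouping = y))
  structure(list(spec = spec, fit = fit, center = ctr, scale = scl,
                 levels = levels(y)), class = "ehg_model")
}

#' Predict classes and positive-class scores
#'
#' @param object an `ehg_model` from [train_classifier()].
#' @param newdata feature matrix with the training columns.
#' @param ... unused.
#' @return list with `class` (factor) and `score` (numeric, monotone in
#'   positive-class confidence).
#' @export
predict.ehg_model <- function(object, newdata, ...) {
  Z <- scale(as.matrix(as.data.frame(newdata)), object$center, object$scale)
  spec <- object$spec
  pos <- spec$positive_class
  fam <- spec$family
  if (fam %in% c("svm_quadratic", "svm_cubic", "svm_fine_gaussian")) {
    pred <- predict(object$fit, Z, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    score <- if (startsWith(colnames(dv)[1], pos)) dv[, 1] else -dv[, 1]
    return(list(class = pred, score = as.numeric(score)))
  }
  if (fam == "knn_weighted") {
    fit <- object$fit
    # squared-inverse-distance weighted vote over the k nearest neighbours
    D2 <- outer(rowSums(Z^2), rep(1, nrow(fit$Z))) +
      outer(rep(1, nrow(Z)), rowSums(fit$Z^2)) - 2 * tcrossprod(Z, fit$Z)
    k <- min(fit$k, ncol(D2))
    is_pos <- fit$y == pos
    score <- apply(D2, 1, function(d) {
      nn <- order(d)[seq_len(k)]
      w <- 1 / pmax(d[nn], 1e-12)
      sum(w[is_pos[nn]]) / sum(w)
    })
    cls <- ifelse(score >= 0.5, pos, setdiff(object$levels, pos))
    return(list(class = factor(cls, levels = object$levels),
                score = as.numeric(score)))
  }
  if (fam == "bagged_tree") {
    votes <- vapply(object$fit, function(tr)
      predict(tr, data.frame(Z, check.names = FALSE), type = "prob")[, pos],
      numeric(nrow(Z)))
    if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1)
    score <- rowMeans(votes)
    cls <- ifelse(score >= 0.5, pos, setdiff(object$levels, pos))
    return(list(class = factor(cls, levels = object$levels), score = score))
  }
  # discriminant models
  pr <- predict(object$fit, Z)
  list(class = pr$class, score = as.numeric(pr$posterior[, pos]))
}

# rank-sum (Mann-Whitney) AUC of scores for the positive class
auc_score <- function(y_true, scores, positive) {
  pos <- y_true == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NaN)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binary classification metric suite
#'
#' Computes accuracy, sensitivity (= recall), specificity, PPV
#' (= precision), NPV, F-score and AUC from predictions and scores.  All
#' confusion-matrix identities hold exactly; a zero-denominator ratio is
#' reported as `NaN` with a warning.
#'
#' @param y_true,y_pred observed and predicted labels.
#' @param scores numeric scores monotone in positive-class confidence
#'   (used for AUC; may be `NULL`).
#' @param positive_class label treated as positive (default `"P"`).
#' @return named numeric vector of class `metric_set`.
#' @export
compute_metrics <- function(y_true, y_pred, scores = NULL, positive_class = "P") {
  stopifnot(length(y_true) == length(y_pred))
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  tp <- sum(y_true == positive_class & y_pred == positive_class)
  fn <- sum(y_true == positive_class & y_pred != positive_class)
  tn <- sum(y_true != positive_class & y_pred != positive_class)
  fp <- sum(y_true != positive_class & y_pred == positive_class)
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator)", what))
      return(NaN)
    }
    num / den
  }
  acc <- ratio(tp + tn, tp + tn + fp + fn, "accuracy")
  sens <- ratio(tp, tp + fn, "sensitivity")
  spec <- ratio(tn, tn + fp, "specificity")
  ppv <- ratio(tp, tp + fp, "PPV")
  npv <- ratio(tn, tn + fn, "NPV")
  f <- if (is.nan(ppv) || is.nan(sens) || (ppv + sens) == 0) NaN
       else 2 * ppv * sens / (ppv + sens)
  auc <- if (is.null(scores)) NA_real_
         else auc_score(y_true, scores, positive_class)
  structure(c(accuracy = acc, sensitivity = sens, specificity = spec,
              ppv = ppv, npv = npv, auc = auc, f_score = f,
              precision = ppv, recall = sens),
            class = "metric_set",
            confusion = c(TP = tp, FN = fn, TN = tn, FP = fp))
}
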