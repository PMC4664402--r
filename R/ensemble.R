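#' Ensemble configuration
#'
#' Settings for the stacked prediction model: the base-learner roster, the
#' meta-level random forest, feature selection and cross-validation. Defaults
#' follow the reference configuration used throughout the package's
#' simulation study: linear (or logistic) regression, a linear-kernel support
#' vector machine and a random forest with `mtry = 1`, blended by a
#' meta-level random forest with `mtry = 1`, with the top 30% of variables
#' kept by |Pearson correlation| with the phenotype.
#'
#' @param learners base-learner roster, a subset of
#'   `c("regression", "svm", "forest")`, in order.
#' @param ntree trees per random forest (base and meta). The reference value
#'   is 1000; smaller values give near-identical calibration at a fraction of
#'   the cost and are used for desk-scale Monte-Carlo runs.
#' @param mtry variables tried per split, default 1.
#' @param feature_fraction fraction of variables kept by feature selection
#'   (0 < fraction <= 1), default 0.30.
#' @param min_features lower bound on the number of variables kept
#'   (default 5, capped at the number available). Selection is a
#'   dimensionality-reduction device for large panels; starving a small
#'   gene-sized panel below the size of a plausible interaction destroys
#'   the method's ability to see epistasis, so small panels keep all their
#'   variables. Set to 1 for the pure fractional rule.
#' @param selection ranking criterion: absolute Pearson correlation with the
#'   phenotype (default) or random-forest permutation importance.
#' @param k number of cross-validation folds, default 5.
#' @param stratify stratify folds by class for binary traits (default TRUE).
#' @param global_selection if TRUE, feature selection is performed once on
#'   the full data instead of within each training fold (used only to mirror
#'   analyses that pre-commit to a marker set; default FALSE, no leakage).
#' @return an object of class `ensemble_control`.
#' @export
ensemble_control <- function(learners = c("regression", "svm", "forest"),
                             ntree = 1000, mtry = 1,
                             feature_fraction = 0.30, min_features = 5,
                             selection = c("correlation", "importance"),
                             k = 5, stratify = TRUE,
                             global_selection = FALSE) {
  learners <- match.arg(learners, several.ok = TRUE)
  selection <- match.arg(selection)
  if (length(learners) < 1) stop("base-learner roster must be non-empty")
  if (feature_fraction <= 0 || feature_fraction > 1)
    stop("feature_fraction must be in (0, 1]")
  if (min_features < 1) stop("min_features must be >= 1")
  if (k < 2) stop("k must be >= 2")
  structure(list(learners = learners, ntree = ntree, mtry = mtry,
                 feature_fraction = feature_fraction,
                 min_features = as.integer(min_features),
                 selection = selection,
                 k = as.integer(k), stratify = stratify,
                 global_selection = global_selection),
            class = "ensemble_control")
}

#' Rank and select predictive features
#'
#' Ranks columns of `x` by absolute Pearson correlation with `y` (or by
#' random-forest permutation importance) and keeps the top
#' `ceiling(feature_fraction * ncol(x))`, bounded below by
#' `min_features` (see [ensemble_control()]). Constant columns get score 0
#' and rank last; ties break by ascending column index.
#'
#' @param x predictor matrix.
#' @param y phenotype vector.
#' @param control an [ensemble_control()].
#' @return integer vector of selected column indices.
#' @export
select_features <- function(x, y, control = ensemble_control()) {
  x <- as.matrix(x)
  if (ncol(x) < 1) stop("x must have at least one column")
  if (control$selection == "correlation") {
    score <- suppressWarnings(abs(as.vector(stats::cor(x, y))))
    score[is.na(score)] <- 0
  } else {
    fit <- ranger::ranger(
      y = y, x = as.data.frame(x), num.trees = control$ntree,
      mtry = min(control$mtry, ncol(x)), importance = "permutation",
      num.threads = 1, seed = sample.int(1e9, 1))
    score <- fit$variable.importance
  }
  keep <- ceiling(control$feature_fraction * ncol(x))
  keep <- min(ncol(x), max(keep, control$min_features))
  order(-score, seq_len(ncol(x)))[seq_len(keep)]
}

clamp01 <- function(p) pmin(1, pmax(0, p))

## One base learner: returns list(predict = function(newx), train_pred).
## `train_pred` is the prediction vector handed to the meta-learner for the
## training samples — the base model's own predictions on its training
## data, as in the reference stacking recipe. (An out-of-bag variant for
## the forest channel was evaluated: it improves raw signal capture but
## changes the training-noise structure of P_final in a way that breaks
## the shared-fold calibration of the interaction test, so it is not
## used.) Binary traits are predicted on the probability scale.
fit_base_learner <- function(kind, x, y, binary, ntree = 1000, mtry = 1) {
  if (kind == "regression") {
    df <- data.frame(y = y, x)
    fit <- if (binary)
      suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
    else
      stats::lm(y ~ ., data = df)
    pr <- function(newx) {
      p <- stats::predict(fit, newdata = data.frame(newx), type = "response")
      if (binary) clamp01(p) else p
    }
    return(list(predict = pr, train_pred = as.numeric(pr(x))))
  }
  if (kind == "svm") {
    fit <- e1071::svm(x, y, kernel = "linear", scale = FALSE)
    pr <- function(newx) {
      p <- as.vector(stats::predict(fit, newx))
      if (binary) clamp01(p) else p
    }
    return(list(predict = pr, train_pred = as.numeric(pr(x))))
  }
  ## random forest (regression mode; 0/1 targets give probabilities)
  fit <- ranger::ranger(y = y, x = as.data.frame(x),
                        num.trees = ntree, mtry = min(mtry, ncol(x)),
                        num.threads = 1, seed = sample.int(1e9, 1))
  pr <- function(newx)
    stats::predict(fit, data = as.data.frame(newx),
                   num.threads = 1)$predictions
  list(predict = pr, train_pred = as.numeric(pr(x)))
}

#' Fit a stacked ensemble on a training set
#'
#' Performs feature selection, trains the base-learner roster on the selected
#' features (plus covariates, which bypass selection), then trains a
#' meta-level random forest on the base-learner predictions stacked with the
#' selected features (and covariates). Binary traits are handled on the
#' probability scale throughout.
#'
#' @param x SNP/predictor matrix (may be NULL if only covariates are used).
#' @param y phenotype (numeric, or 0/1 for binary traits).
#' @param covariates optional covariate matrix; always retained as
#'   meta-features.
#' @param trait `"continuous"` or `"binary"`.
#' @param control an [ensemble_control()].
#' @param features optional pre-computed feature indices (skips selection).
#' @return an object of class `ensemble_stack` with a [predict][stats::predict]
#'   method.
#' @export
ensemble_stack <- function(x, y, covariates = NULL,
                           trait = c("continuous", "binary"),
                           control = ensemble_control(), features = NULL) {
  trait <- match.arg(trait)
  binary <- trait == "binary"
  if (!is.null(x)) x <- as.matrix(x)
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  n <- length(y)
  if (n < max(10, control$k)) stop("training set too small")
  if (binary && length(unique(y)) < 2)
    stop("single-class training data; use stratified folds")

  ## degenerate constant target: every learner would predict the constant
  if (stats::var(y) == 0) {
    obj <- structure(list(constant = y[1], trait = trait, control = control,
                          features = integer(0)),
                     class = "ensemble_stack")
    return(obj)
  }

  impute_means <- NULL
  if (!is.null(x)) {
    impute_means <- colMeans(x, na.rm = TRUE)
    impute_means[is.nan(impute_means)] <- 0
    for (j in seq_len(ncol(x)))
      x[is.na(x[, j]), j] <- impute_means[j]
    if (is.null(features)) features <- select_features(x, y, control)
    xsel <- x[, features, drop = FALSE]
  } else {
    features <- integer(0)
    xsel <- NULL
  }
  base_input <- cbind(xsel, covariates)
  if (is.null(base_input) || ncol(base_input) == 0)
    stop("no predictors: both x and covariates are empty")

  base <- lapply(control$learners, fit_base_learner,
                 x = base_input, y = y, binary = binary,
                 ntree = control$ntree, mtry = control$mtry)
  base_preds <- vapply(base, function(b) b$train_pred, numeric(n))
  meta_input <- cbind(base_preds, base_input)
  colnames(meta_input) <- paste0("V", seq_len(ncol(meta_input)))
  meta <- ranger::ranger(y = y, x = as.data.frame(meta_input),
                         num.trees = control$ntree,
                         mtry = min(control$mtry, ncol(meta_input)),
                         num.threads = 1, seed = sample.int(1e9, 1))
  structure(list(base = base, meta = meta, features = features,
                 impute_means = impute_means, trait = trait,
                 control = control, n_meta_inputs = ncol(meta_input)),
            class = "ensemble_stack")
}

#' @export
print.ensemble_stack <- function(x, ...) {
  cat("Stacked ensemble (", x$trait, " trait)\n", sep = "")
  if (!is.null(x$constant)) {
    cat("  degenerate fit: constant target", x$constant, "\n")
    return(invisible(x))
  }
  cat("  base learners:", paste(x$control$learners, collapse = ", "), "\n")
  cat("  selected features:", paste(x$features, collapse = ", "), "\n")
  cat("  meta forest inputs:", x$n_meta_inputs, "\n")
  invisible(x)
}

#' @param object an `ensemble_stack`.
#' @param x new SNP matrix; `covariates` new covariates.
#' @rdname ensemble_stack
#' @export
predict.ensemble_stack <- function(object, x = NULL, covariates = NULL, ...) {
  if (!is.null(object$constant)) {
    n <- if (!is.null(x)) nrow(as.matrix(x)) else nrow(as.matrix(covariates))
    return(rep(object$constant, n))
  }
  if (!is.null(x)) {
    x <- as.matrix(x)
    for (j in seq_len(ncol(x)))
      x[is.na(x[, j]), j] <- object$impute_means[j]
    xsel <- x[, object$features, drop = FALSE]
  } else xsel <- NULL
  base_input <- cbind(xsel, if (!is.null(covariates)) as.matrix(covariates))
  base_preds <- vapply(object$base,
                       function(b) as.numeric(b$predict(base_input)),
                       numeric(nrow(base_input)))
  if (nrow(base_input) == 1) base_preds <- matrix(base_preds, nrow = 1)
  meta_input <- cbind(base_preds, base_input)
  colnames(meta_input) <- paste0("V", seq_len(ncol(meta_input)))
  p <- stats::predict(object$meta, data = as.data.frame(meta_input),
                      num.threads = 1)$predictions
  if (object$trait == "binary") clamp01(p) else p
}

## Deterministic fold assignment from the current RNG state; stratified by
## class for binary traits so every training fold sees both classes.
make_folds <- function(y, k, stratify, binary) {
  n <- length(y)
  fold <- integer(n)
  if (binary && stratify) {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    fold <- sample(rep_len(seq_len(k), n))
  }
  fold
}

#' Cross-validated ensemble phenotype predictions
#'
#' Splits the samples into `k` folds; within each training fold performs
#' feature selection (unless `global_selection`), fits the stacked ensemble
#' and predicts the held-out fold. Every prediction in `P_final` comes from a
#' model whose training data excluded that sample.
#'
#' Two training schemes are available. `"kfold"` is classic k-fold
#' cross-validation: fold `f` is predicted by a model trained on the other
#' `k - 1` folds. Its predictions are mutually coupled across folds (sample
#' i trains the model that predicts sample j and vice versa), which inflates
#' the null variance of any statistic that pools predictions across folds —
#' see [assoc_continuous()]. `"rotational"` is non-reciprocal cross-fitting:
#' fold `f` is predicted by a model trained on the next
#' `floor((k - 1)/2)` folds in cyclic order, so no two samples ever train
#' each other's models. This makes the pooled correlation between `P_final`
#' and `P_actual` exactly calibrated under the null, at the cost of smaller
#' training sets.
#'
#' @param x SNP matrix (NULL for covariate-only predictions).
#' @param y phenotype.
#' @param covariates optional covariate matrix.
#' @param trait `"continuous"` or `"binary"`.
#' @param control an [ensemble_control()].
#' @param seed optional integer seed; fold assignment and forest seeds derive
#'   from it.
#' @param folds optional integer vector of fold labels in `1..k`, one per
#'   sample, overriding the internal assignment. Use this to share one fold
#'   partition between [cv_ensemble()] and [cv_linear()] — the interaction
#'   test requires a shared partition for correct calibration.
#' @return an object of class `cv_prediction` with fields `P_actual`,
#'   `P_final`, `folds`, `trait`.
#' @export
#' @param scheme `"kfold"` (default) or `"rotational"`; see Details.
#' @export
cv_ensemble <- function(x, y, covariates = NULL,
                        trait = c("continuous", "binary"),
                        control = ensemble_control(), seed = NULL,
                        folds = NULL, scheme = c("kfold", "rotational")) {
  trait <- match.arg(trait)
  scheme <- match.arg(scheme)
  binary <- trait == "binary"
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  if (n < 2 * control$k) stop("need at least 2*k samples")
  if (scheme == "rotational" && control$k < 3)
    stop("rotational scheme needs k >= 3")
  if (!is.null(x)) x <- as.matrix(x)
  fold <- if (!is.null(folds)) {
    stopifnot(length(folds) == n, all(folds %in% seq_len(control$k)))
    as.integer(folds)
  } else make_folds(y, control$k, control$stratify, binary)
  global_feat <- NULL
  if (control$global_selection && !is.null(x)) {
    ximp <- x
    for (j in seq_len(ncol(ximp)))
      ximp[is.na(ximp[, j]), j] <- mean(ximp[, j], na.rm = TRUE)
    global_feat <- select_features(ximp, y, control)
  }
  P_final <- numeric(n)
  k <- control$k
  m_rot <- (k - 1L) %/% 2L
  for (f in seq_len(k)) {
    tr <- if (scheme == "kfold") fold != f
          else fold %in% (((f + seq_len(m_rot) - 1L) %% k) + 1L)
    te <- fold == f   # predict exactly this fold with this fold's model
    fit <- ensemble_stack(if (!is.null(x)) x[tr, , drop = FALSE],
                          y[tr],
                          if (!is.null(covariates))
                            as.matrix(covariates)[tr, , drop = FALSE],
                          trait = trait, control = control,
                          features = global_feat)
    P_final[te] <- predict(fit,
                           x = if (!is.null(x)) x[te, , drop = FALSE],
                           covariates = if (!is.null(covariates))
                             as.matrix(covariates)[te, , drop = FALSE])
  }
  structure(list(P_actual = y, P_final = P_final, folds = fold,
                 trait = trait, control = control, scheme = scheme),
            class = "cv_prediction")
}

#' Cross-validated all-SNP regression predictions
#'
#' The comparison predictor for the interaction test: all SNPs enter a single
#' linear (or logistic) regression with no feature selection, trained and
#' predicted under the same cross-validation folds discipline as the
#' ensemble.
#'
#' @inheritParams cv_ensemble
#' @param k number of folds.
#' @return a `cv_prediction` whose `P_final` is the regression prediction
#'   (`P_linear`).
#' @export
cv_linear <- function(x, y, covariates = NULL,
                      trait = c("continuous", "binary"),
                      k = 5, seed = NULL, stratify = TRUE, folds = NULL,
                      scheme = c("kfold", "rotational")) {
  trait <- match.arg(trait)
  scheme <- match.arg(scheme)
  binary <- trait == "binary"
  if (!is.null(seed)) set.seed(seed)
  x <- as.matrix(x)
  n <- length(y)
  if (n < 2 * k) stop("need at least 2*k samples")
  if (scheme == "rotational" && k < 3) stop("rotational scheme needs k >= 3")
  fold <- if (!is.null(folds)) {
    stopifnot(length(folds) == n, all(folds %in% seq_len(k)))
    as.integer(folds)
  } else make_folds(y, k, stratify, binary)
  P <- numeric(n)
  X <- cbind(x, covariates)
  m_rot <- (k - 1L) %/% 2L
  for (f in seq_len(k)) {
    tr <- if (scheme == "kfold") fold != f
          else fold %in% (((f + seq_len(m_rot) - 1L) %% k) + 1L)
    te <- fold == f
    df <- data.frame(y = y[tr], X[tr, , drop = FALSE])
    nd <- data.frame(X[te, , drop = FALSE])
    if (binary) {
      fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                         family = stats::binomial()))
      P[te] <- clamp01(stats::predict(fit, newdata = nd, type = "response"))
    } else {
      fit <- stats::lm(y ~ ., data = df)
      P[te] <- stats::predict(fit, newdata = nd)
    }
  }
  structure(list(P_actual = y, P_final = P, folds = fold,
                 trait = trait, control = NULL, scheme = scheme),
            class = "cv_prediction")
}

#' @export
print.cv_prediction <- function(x, ...) {
  cat("Cross-validated predictions (", x$trait, " trait), n = ",
      length(x$P_actual), "\n", sep = "")
  r <- suppressWarnings(stats::cor(x$P_final, x$P_actual))
  cat("  cor(P_final, P_actual) =", round(r, 4), "\n")
  invisible(x)
}

#' @export
plot.cv_prediction <- function(x, ...) {
  plot(x$P_final, x$P_actual, xlab = "P_final (cross-validated prediction)",
       ylab = "P_actual (observed phenotype)", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
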