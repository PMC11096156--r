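#' Feature table
#'
#' The n x 237 design matrix of texture features with one luster grade per
#' row.
#'
#' @param x numeric matrix (samples x features), ideally with column names
#'   from [feature_names()].
#' @param labels factor (or character) of luster grades, one per row.
#' @return List of class `feature_table` with `matrix`, `labels`,
#'   `feature_names`.
#' @export
feature_table <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (nrow(x) != length(labels))
    stop("one label per sample is required", call. = FALSE)
  if (!all(is.finite(x)))
    stop("feature matrix contains missing or non-finite values",
         call. = FALSE)
  if (any(table(labels) < 2))
    stop("every class present needs at least 2 samples", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))
  structure(list(matrix = x, labels = labels, feature_names = colnames(x)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("Feature table:", nrow(x$matrix), "samples x", ncol(x$matrix),
      "features\n")
  print(table(x$labels))
  invisible(x)
}

subset_table <- function(tbl, idx) {
  structure(list(matrix = tbl$matrix[idx, , drop = FALSE],
                 labels = droplevels(tbl$labels[idx]),
                 feature_names = tbl$feature_names),
            class = "feature_table")
}

round_half_up <- function(x) floor(x + 0.5)

#' Stratified train/test split
#'
#' Each class contributes `round(train_fraction * n_class)` samples
#' (half-up, clamped so both sides keep at least one sample per class) to
#' the training set; 116 balanced samples at fraction 0.8 give the 92/24
#' split.
#'
#' @param table a [feature_table()].
#' @param train_fraction fraction of each class assigned to training.
#' @param seed optional integer seed; the partition is a pure function of
#'   `(table, train_fraction, seed)`.
#' @return List with `train` and `test` feature tables and the index
#'   vectors `train_idx`, `test_idx`.
#' @export
stratified_split <- function(table, train_fraction = 0.8, seed = NULL) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  y <- table$labels
  train_idx <- integer(0)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    n_tr <- min(max(round_half_up(train_fraction * length(idx)), 1L),
                length(idx) - 1L)
    train_idx <- c(train_idx, sample(idx, n_tr))
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(y), train_idx)
  list(train = subset_table(table, train_idx),
       test = subset_table(table, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

# Stratified k-fold assignment; uses the current RNG stream.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(sample(k), length(idx))
  }
  fold
}

#' Randomized-search space for the two classifiers
#'
#' SVM candidates draw a kernel from `kernels`, cost log-uniformly from
#' `C_range` and kernel coefficient gamma log-uniformly from `gamma_range`;
#' random-forest candidates draw the tree count and `mtry` (max features
#' per split) uniformly from integer ranges. (randomForest splits on the
#' Gini criterion only, so no criterion is searched.)
#'
#' @param iterations sampled candidate configurations.
#' @param folds stratified cross-validation folds used to score them.
#' @param kernels SVM kernels ("radial" is the rbf kernel, "polynomial"
#'   the poly kernel).
#' @param C_range,gamma_range SVM log-uniform ranges.
#' @param ntree_range,mtry_range random-forest integer ranges.
#' @return List of class `search_space`.
#' @export
search_space <- function(iterations = 500L, folds = 5L,
                         kernels = c("radial", "polynomial", "sigmoid"),
                         C_range = c(1e-2, 1e2), gamma_range = c(1e-4, 1),
                         ntree_range = c(5L, 200L), mtry_range = c(1L, 20L)) {
  stopifnot(iterations >= 1, folds >= 2)
  structure(list(iterations = as.integer(iterations),
                 folds = as.integer(folds), kernels = kernels,
                 C_range = C_range, gamma_range = gamma_range,
                 ntree_range = ntree_range, mtry_range = mtry_range),
            class = "search_space")
}

sample_candidate <- function(kind, space, p) {
  runif_log <- function(r) exp(runif(1, log(r[1]), log(r[2])))
  if (kind == "svm") {
    list(kernel = sample(space$kernels, 1),
         cost = runif_log(space$C_range),
         gamma = runif_log(space$gamma_range))
  } else {
    list(ntree = sample(space$ntree_range[1]:space$ntree_range[2], 1),
         mtry = min(sample(space$mtry_range[1]:space$mtry_range[2], 1), p))
  }
}

# Fit one classifier. SVM inputs are z-scored with a scaler fit here;
# the scaler travels with the model.
fit_candidate <- function(kind, params, x, y) {
  if (kind == "svm") {
    ctr <- colMeans(x)
    scl <- apply(x, 2, sd)
    scl[scl == 0] <- 1
    xs <- scale(x, center = ctr, scale = scl)
    fit <- e1071::svm(xs, y, kernel = params$kernel, cost = params$cost,
                      gamma = params$gamma, scale = FALSE)
    list(kind = kind, fit = fit, params = params,
         scaler = list(center = ctr, scale = scl))
  } else {
    fit <- randomForest::randomForest(x, y, ntree = params$ntree,
                                      mtry = min(params$mtry, ncol(x)))
    list(kind = kind, fit = fit, params = params, scaler = NULL)
  }
}

predict_candidate <- function(model, x) {
  if (!is.null(model$scaler))
    x <- scale(x, center = model$scaler$center, scale = model$scaler$scale)
  predict(model$fit, x)
}

# Mean held-out accuracy over a fixed fold assignment.
cv_accuracy <- function(kind, params, x, y, fold) {
  acc <- vapply(sort(unique(fold)), function(f) {
    tr <- fold != f
    if (length(unique(y[tr])) < nlevels(y))
      stop("cross-validation fold lost a class; too few samples per class",
           call. = FALSE)
    m <- fit_candidate(kind, params, x[tr, , drop = FALSE], y[tr])
    mean(predict_candidate(m, x[!tr, , drop = FALSE]) == y[!tr])
  }, numeric(1))
  mean(acc)
}

#' Fit a luster grading classifier with randomized hyperparameter search
#'
#' Samples `n_iter` candidate configurations from the search space, scores
#' each by mean accuracy under stratified k-fold cross-validation on the
#' training data (the fold assignment is drawn once and shared by all
#' candidates), and refits the best candidate on the full training set.
#' SVM features are z-score standardized with a scaler fit on the training
#' data; the scaler is stored and reapplied by `predict()`.
#'
#' @param x training [feature_table()], or a numeric matrix.
#' @param labels training grades (ignored when `x` is a feature table).
#' @param model_kind `"rfc"` (random forest) or `"svm"`.
#' @param space a [search_space()].
#' @param n_iter candidates to sample (defaults to `space$iterations`).
#' @param seed optional integer seed; the fit is deterministic given it.
#' @return Object of class `luster_grader` with elements `model_kind`,
#'   `best_params`, `cv_accuracy`, the refitted `model`, `levels` and
#'   `feature_names`.
#' @export
luster_grader <- function(x, labels = NULL, model_kind = c("rfc", "svm"),
                          space = search_space(), n_iter = space$iterations,
                          seed = NULL) {
  model_kind <- match.arg(model_kind)
  if (inherits(x, "feature_table")) {
    labels <- x$labels
    x <- x$matrix
  }
  x <- as.matrix(x)
  y <- as.factor(labels)
  if (!is.null(seed)) set.seed(seed)
  fold <- stratified_folds(y, space$folds)
  best <- NULL
  best_score <- -Inf
  scores <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    cand <- sample_candidate(model_kind, space, ncol(x))
    scores[i] <- cv_accuracy(model_kind, cand, x, y, fold)
    if (scores[i] > best_score) {
      best_score <- scores[i]
      best <- cand
    }
  }
  structure(list(model_kind = model_kind, best_params = best,
                 cv_accuracy = best_score, cv_scores = scores,
                 model = fit_candidate(model_kind, best, x, y),
                 levels = levels(y), feature_names = colnames(x),
                 n_train = nrow(x)),
            class = "luster_grader")
}

#' @export
print.luster_grader <- function(x, ...) {
  cat("Luster grading model (", toupper(x$model_kind), ")\n", sep = "")
  cat("  trained on", x$n_train, "samples,",
      length(x$feature_names), "features\n")
  cat("  best CV accuracy:", round(x$cv_accuracy, 4), "\n")
  cat("  hyperparameters:",
      paste(names(x$best_params),
            vapply(x$best_params, function(v) format(v, digits = 3), ""),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.luster_grader <- function(object, ...) {
  print(object)
  cat("  candidates searched:", length(object$cv_scores),
      "| CV accuracy range:",
      paste(round(range(object$cv_scores), 4), collapse = " - "), "\n")
  invisible(object)
}

#' Predict luster grades
#'
#' @param object a fitted [luster_grader()].
#' @param newdata feature table or matrix with the training feature layout.
#' @param ... unused.
#' @return Factor of predicted grades.
#' @export
predict.luster_grader <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_table")) newdata <- newdata$matrix
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$feature_names))
    stop("feature layout mismatch: model expects ",
         length(object$feature_names), " features, got ", ncol(newdata),
         call. = FALSE)
  predict_candidate(object$model, newdata)
}

#' Confusion matrix and macro-averaged metrics
#'
#' Precision, recall and F1 are averaged over all classes (macro); a class
#' never predicted contributes precision 0 (the 0/0 convention). Accuracy
#' is the confusion-matrix trace over its total.
#'
#' @param truth,pred factors on the same level set.
#' @return List with `confusion` (rows = truth), per-class vectors and
#'   macro `precision`, `recall`, `f1`, `accuracy`.
#' @export
classification_metrics <- function(truth, pred) {
  lev <- levels(as.factor(truth))
  truth <- factor(truth, levels = lev)
  pred <- factor(pred, levels = lev)
  cm <- table(truth = truth, pred = pred)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(confusion = cm,
       precision_by_class = prec, recall_by_class = rec, f1_by_class = f1,
       precision = mean(prec), recall = mean(rec), f1 = mean(f1),
       accuracy = sum(tp) / sum(cm))
}

#' Evaluate a fitted grader on a test set
#'
#' @param object a [luster_grader()].
#' @param test test [feature_table()].
#' @return [classification_metrics()] of the test predictions.
#' @export
evaluate_grader <- function(object, test) {
  pred <- predict(object, test)
  classification_metrics(factor(test$labels, levels = object$levels), pred)
}

#' Repeated split/tune/evaluate experiment
#'
#' Runs `n_runs` independent cycles of stratified 8/2 split, randomized
#' hyperparameter search (optionally after PCA reduction of the split) and
#' evaluation, then aggregates the maximum, minimum and average of the
#' macro precision, recall, F1 and accuracy over the runs — on the train
#' and on the test split.
#'
#' @param table full [feature_table()].
#' @param model_kind `"rfc"` or `"svm"`.
#' @param n_runs independent runs.
#' @param train_fraction train share of the split.
#' @param space a [search_space()].
#' @param n_iter search candidates per run.
#' @param pca_k if non-`NULL`, reduce each split to this many principal
#'   components (fit on the run's training half only) before training.
#' @param seed root seed; per-run seeds are drawn from it.
#' @return Object of class `grade_report`: `per_run` data frame,
#'   `confusions` (list of test confusion matrices), `aggregate` (max, min,
#'   avg per metric for train and test) and the run settings.
#' @export
repeated_experiment <- function(table, model_kind = c("rfc", "svm"),
                                n_runs = 10L, train_fraction = 0.8,
                                space = search_space(),
                                n_iter = space$iterations,
                                pca_k = NULL, seed = 1L) {
  model_kind <- match.arg(model_kind)
  stopifnot(n_runs >= 1)
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max, 2L * n_runs)
  rows <- list(); confusions <- list()
  for (r in seq_len(n_runs)) {
    sp <- stratified_split(table, train_fraction, seed = run_seeds[2 * r - 1])
    train <- sp$train; test <- sp$test
    if (!is.null(pca_k)) {
      red <- pca_reduce(train, test, k = pca_k)
      train <- feature_table(red$train_scores, train$labels)
      test <- feature_table(red$test_scores, test$labels)
    }
    fit <- luster_grader(train, model_kind = model_kind, space = space,
                         n_iter = n_iter, seed = run_seeds[2 * r])
    mtr <- evaluate_grader(fit, train)
    mte <- evaluate_grader(fit, test)
    rows[[r]] <- data.frame(
      run = r,
      train_precision = mtr$precision, train_recall = mtr$recall,
      train_f1 = mtr$f1, train_accuracy = mtr$accuracy,
      test_precision = mte$precision, test_recall = mte$recall,
      test_f1 = mte$f1, test_accuracy = mte$accuracy)
    confusions[[r]] <- mte$confusion
  }
  per_run <- do.call(rbind, rows)
  metrics <- setdiff(names(per_run), "run")
  aggregate <- data.frame(
    metric = metrics,
    max = vapply(per_run[metrics], max, numeric(1)),
    min = vapply(per_run[metrics], min, numeric(1)),
    avg = vapply(per_run[metrics], mean, numeric(1)),
    row.names = NULL)
  structure(list(per_run = per_run, confusions = confusions,
                 aggregate = aggregate, model_kind = model_kind,
                 pca_k = pca_k, n_runs = n_runs, seed = seed),
            class = "grade_report")
}

#' @export
print.grade_report <- function(x, digits = 3, ...) {
  cat("Repeated grading experiment (", toupper(x$model_kind),
      if (!is.null(x$pca_k)) paste0(", PCA k=", x$pca_k), "): ",
      x$n_runs, " runs\n", sep = "")
  agg <- x$aggregate
  agg[c("max", "min", "avg")] <- round(agg[c("max", "min", "avg")], digits)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' @export
plot.grade_report <- function(x, ...) {
  agg <- x$aggregate[grep("^test_", x$aggregate$metric), ]
  mids <- barplot(agg$avg, names.arg = sub("test_", "", agg$metric),
                  ylim = c(0, 1), ylab = "macro metric (test)",
                  main = paste("Average over", x$n_runs, "runs,",
                               toupper(x$model_kind)), ...)
  segments(mids, agg$min, mids, agg$max)
  invisible(x)
}

#' PCA dimension reduction fit on the training split
#'
#' Features are z-scored with training statistics, the principal components
#' are fit on the training matrix only (no leakage), and both splits are
#' projected on the first `k` components.
#'
#' @param train,test feature tables or matrices; `test` may be `NULL`.
#' @param k number of components retained.
#' @param scale z-score features before the decomposition.
#' @return List with `model` (class `pca_model`: `rotation`,
#'   `explained_variance_ratio`, `center`, `scale`, `k`), `train_scores`
#'   and `test_scores`.
#' @export
pca_reduce <- function(train, test = NULL, k = 6L, scale = TRUE) {
  xtr <- if (inherits(train, "feature_table")) train$matrix else as.matrix(train)
  xte <- if (inherits(test, "feature_table")) test$matrix
         else if (!is.null(test)) as.matrix(test)
  if (k > min(nrow(xtr), ncol(xtr)))
    stop("k = ", k, " exceeds min(n_train, n_features)", call. = FALSE)
  ctr <- colMeans(xtr)
  scl <- if (scale) {
    s <- apply(xtr, 2, sd); s[s == 0] <- 1; s
  } else rep(1, ncol(xtr))
  pc <- prcomp(scale(xtr, center = ctr, scale = scl), center = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  project <- function(x) scale(x, center = ctr, scale = scl) %*% rot
  list(model = structure(list(rotation = rot,
                              explained_variance_ratio = evr,
                              center = ctr, scale = scl, k = k),
                         class = "pca_model"),
       train_scores = project(xtr),
       test_scores = if (!is.null(xte)) project(xte))
}

#' @export
print.pca_model <- function(x, ...) {
  cat("PCA model:", length(x$center), "features ->", x$k, "components\n")
  cat("  variance explained by the first", x$k, "components:",
      sprintf("%.1f%%", 100 * sum(x$explained_variance_ratio[seq_len(x$k)])),
      "\n")
  invisible(x)
}

feature_family_of <- function(nms) {
  fam <- feature_families(nms)
  miss <- is.na(fam)
  out <- as.character(fam)
  out[miss] <- sub("_.*$", "", nms[miss])
  out
}

#' Backward sequential feature selection
#'
#' Standard backward elimination: starting from the full feature set, each
#' step removes the feature whose removal gives the highest stratified
#' cross-validated accuracy (ties broken toward the lowest feature index),
#' until `round(fraction * p)` features remain. Hyperparameters stay frozen
#' (pass the tuned values of a [luster_grader()]); the fold assignment is
#' drawn once and reused by every candidate evaluation.
#'
#' @param table a [feature_table()].
#' @param model_kind `"rfc"` or `"svm"`.
#' @param fraction share of features to retain, in (0, 1].
#' @param params frozen hyperparameters (defaults: a 100-tree forest with
#'   `mtry = sqrt(p)`, or an rbf SVM with `cost = 1`, `gamma = 1/p`).
#' @param folds cross-validation folds for scoring.
#' @param seed integer seed for the fold assignment.
#' @return Object of class `selection_mask` with `fraction`, `selected`
#'   (named logical vector), `family_counts` and the final CV score.
#' @export
sequential_select <- function(table, model_kind = c("rfc", "svm"), fraction,
                              params = NULL, folds = 5L, seed = NULL) {
  model_kind <- match.arg(model_kind)
  stopifnot(fraction > 0, fraction <= 1)
  x <- table$matrix; y <- table$labels
  p <- ncol(x)
  if (is.null(params)) {
    params <- if (model_kind == "rfc")
      list(ntree = 100L, mtry = max(1L, floor(sqrt(p))))
    else list(kernel = "radial", cost = 1, gamma = 1 / p)
  }
  if (inherits(params, "luster_grader")) params <- params$best_params
  n_keep <- max(1L, round_half_up(fraction * p))
  if (!is.null(seed)) set.seed(seed)
  fold <- stratified_folds(y, folds)
  current <- seq_len(p)
  score <- NA_real_
  while (length(current) > n_keep) {
    cand_scores <- vapply(seq_along(current), function(i) {
      keep <- current[-i]
      pars <- params
      if (model_kind == "rfc") pars$mtry <- min(pars$mtry, length(keep))
      cv_accuracy(model_kind, pars, x[, keep, drop = FALSE], y, fold)
    }, numeric(1))
    drop_i <- which.max(cand_scores)  # first max = lowest index on ties
    score <- cand_scores[drop_i]
    current <- current[-drop_i]
  }
  selected <- setNames(seq_len(p) %in% current, colnames(x))
  fam <- feature_family_of(colnames(x))
  counts <- base::table(factor(fam, levels = unique(fam))[selected])
  structure(list(fraction = fraction, selected = selected,
                 family_counts = counts,
                 cv_score = score, model_kind = model_kind, params = params),
            class = "selection_mask")
}

#' @export
print.selection_mask <- function(x, ...) {
  cat("Backward SFS mask: ", sum(x$selected), " of ", length(x$selected),
      " features retained (fraction ", x$fraction, ")\n", sep = "")
  print(x$family_counts)
  invisible(x)
}
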