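# The five-classifier bank: linear SVM (one-against-one), CART decision tree,
# random forest (19 trees), kNN (k = 10, Manhattan) and a one-hidden-layer
# MLP; class weights sqrt(N_total/N_i), exhaustive grid search with 3-fold
# stratified cross-validation scored by the weighted mean of per-class
# accuracies, and rejection of predictions whose maximal posterior falls
# below 90%.

CLASSIFIER_KINDS <- c("SVM", "DT", "RF", "kNN", "NN")

#' Class weights for an imbalanced training set
#'
#' `w_i = sqrt(N_total / N_i)`.
#'
#' @param labels vector of class labels.
#' @return named numeric vector, one weight per class.
#' @export
class_weights <- function(labels) {
  tab <- table(labels)
  if (any(tab == 0)) stop("empty class")
  stats::setNames(sqrt(length(labels) / as.vector(tab)), names(tab))
}

#' Classifier specification
#'
#' @param kind one of "SVM", "DT", "RF", "kNN", "NN".
#' @param grid named list of candidate hyperparameter values (a list of
#'   parameter combinations); `NULL` for the built-in default grid.
#' @param probability_threshold rejection threshold on the maximal posterior
#'   (default 0.90).
#' @param cv_folds stratified cross-validation folds (default 3).
#' @param seed integer seed controlling folds and stochastic fits.
#' @return list of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = CLASSIFIER_KINDS, grid = NULL,
                            probability_threshold = 0.90, cv_folds = 3L,
                            seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(grid)) grid <- default_grid(kind)
  stopifnot(probability_threshold >= 0, probability_threshold <= 1,
            length(grid) >= 1L)
  structure(list(kind = kind, grid = grid,
                 probability_threshold = probability_threshold,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "classifier_spec")
}

# published settings where stated (19 trees, k = 10, 15 hidden units); depth /
# C grids are this package's defaults (the original grids are not public)
default_grid <- function(kind) {
  switch(kind,
         SVM = lapply(10^seq(-2, 2), function(C) list(C = C)),
         DT = lapply(list(Inf, 5, 10), function(d) list(max_depth = d)),
         RF = lapply(list(Inf, 5, 10), function(d)
           list(max_depth = d, n_trees = 19L)),
         kNN = list(list(k = 10L)),
         NN = list(list(hidden = 15L, epochs = 400L)))
}

# feature matrix from a feature table (canonical columns present in the data)
feature_matrix <- function(table, features = NULL) {
  if (is.null(features)) {
    features <- intersect(feature_names(), colnames(table))
    if (!length(features)) {
      features <- setdiff(colnames(table),
                          c("nucleus_id", "tissue_class", "strain", "day"))
    }
  }
  X <- as.matrix(table[, features, drop = FALSE])
  storage.mode(X) <- "double"
  X
}

# stratified fold assignment, deterministic given the RNG state
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

fit_kind <- function(kind, X, y, w, classes, params) {
  switch(kind,
         SVM = fit_svm(X, y, w, classes, C = params$C %||% 1),
         DT = fit_cart(X, y, w, classes,
                       max_depth = params$max_depth %||% Inf),
         RF = fit_forest(X, y, w, classes,
                         n_trees = params$n_trees %||% 19L,
                         max_depth = params$max_depth %||% Inf),
         kNN = fit_knn(X, y, w, classes, k = params$k %||% 10L),
         NN = fit_mlp(X, y, w, classes, hidden = params$hidden %||% 15L,
                      epochs = params$epochs %||% 400L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# weighted mean of per-class accuracies (CA_k = correct-in-k / predicted-as-k)
# with weights normalized to sum 1; classes never predicted contribute 0
weighted_score <- function(pred, truth, wts) {
  wts <- wts / sum(wts)
  s <- 0
  for (k in names(wts)) {
    nk <- sum(pred == k)
    s <- s + wts[[k]] * if (nk > 0) sum(pred == k & truth == k) / nk else 0
  }
  s
}

#' Exhaustive grid search with stratified cross-validation
#'
#' Every grid point is scored by `cv_folds`-fold stratified cross-validation;
#' the fold score is the dot product of per-class accuracies with the
#' (normalized) class weights. The best point is refit on all data.
#'
#' @param spec a [classifier_spec()].
#' @param table normalized feature table with a `tissue_class` column
#'   ("unexpected" rows are excluded from training).
#' @param features optional feature-name subset.
#' @return object of class `wn_classifier` with elements `model`, `kind`,
#'   `best_params`, `cv_score`, `features`, `classes`, `weights`, `spec`.
#' @export
grid_search <- function(spec, table, features = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  keep <- table$tissue_class != "unexpected"
  tab <- table[keep, , drop = FALSE]
  y <- as.character(tab$tissue_class)
  if (min(table(y)) < spec$cv_folds) {
    stop("every class needs at least ", spec$cv_folds, " samples")
  }
  X <- feature_matrix(tab, features)
  classes <- sort(unique(y))
  wts <- class_weights(y)[classes]
  w <- unname(wts[y])
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(spec$seed)
  fold <- stratified_folds(y, spec$cv_folds)
  scores <- vapply(spec$grid, function(params) {
    fs <- vapply(seq_len(spec$cv_folds), function(f) {
      tr <- fold != f
      set.seed(spec$seed + f)
      m <- fit_kind(spec$kind, X[tr, , drop = FALSE], y[tr], w[tr],
                    classes, params)
      p <- predict_proba(m, X[!tr, , drop = FALSE])
      pred <- classes[max.col(p, ties.method = "first")]
      weighted_score(pred, y[!tr], wts)
    }, 0)
    mean(fs)
  }, 0)
  best <- which.max(scores)
  set.seed(spec$seed)
  model <- fit_kind(spec$kind, X, y, w, classes, spec$grid[[best]])
  structure(list(model = model, kind = spec$kind,
                 best_params = spec$grid[[best]],
                 cv_score = unname(scores[best]), cv_scores = scores,
                 features = colnames(X), classes = classes,
                 weights = wts, spec = spec),
            class = "wn_classifier")
}

#' Train one classifier of the bank
#'
#' Convenience wrapper: builds the spec for `kind` and runs [grid_search()].
#'
#' @param table normalized feature table with `tissue_class`.
#' @param kind one of "SVM", "DT", "RF", "kNN", "NN".
#' @param features optional feature subset.
#' @param seed integer seed.
#' @param ... passed to [classifier_spec()].
#' @return a `wn_classifier`.
#' @export
train_classifier <- function(table, kind, features = NULL, seed = 1L, ...) {
  grid_search(classifier_spec(kind, seed = seed, ...), table, features)
}

#' @export
print.wn_classifier <- function(x, ...) {
  cat(sprintf("<wn_classifier> %s; CV score %.4f\n", x$kind, x$cv_score))
  cat("best:", paste(names(x$best_params), unlist(x$best_params),
                     sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Predict with posterior-probability rejection
#'
#' Returns the class posterior for every row; predictions whose maximal
#' posterior falls below `threshold` are kept but flagged `accepted = FALSE`
#' (high accuracy matters more than sensitivity, so uncertain nuclei are
#' excluded from final results rather than forced into a class).
#'
#' @param fit a `wn_classifier`.
#' @param table feature table (same normalization as training).
#' @param threshold rejection threshold; default from the spec (0.90).
#' @return data.frame: `nucleus_id`, `class`, `posterior_max`, `accepted`,
#'   plus one posterior column per class.
#' @export
predict_with_rejection <- function(fit, table, threshold = NULL) {
  stopifnot(inherits(fit, "wn_classifier"))
  if (is.null(threshold)) threshold <- fit$spec$probability_threshold
  X <- feature_matrix(table, fit$features)
  P <- predict_proba(fit$model, X)
  stopifnot(max(abs(rowSums(P) - 1)) < 1e-8)
  mx <- apply(P, 1, max)
  cls <- fit$classes[max.col(P, ties.method = "first")]
  out <- data.frame(
    nucleus_id = if ("nucleus_id" %in% colnames(table)) table$nucleus_id
                 else seq_len(nrow(table)),
    class = cls, posterior_max = mx, accepted = mx >= threshold)
  cbind(out, as.data.frame(P))
}

#' Mean class accuracy (MCA)
#'
#' `MCA = (1/n) sum_k CA_k` with `CA_k = C_k / N_k`, where `C_k` is the number
#' of nuclei correctly classified as class `k` and `N_k` the total number of
#' nuclei *classified as* class `k` (a per-predicted-class precision, as the
#' source defines it). Only accepted predictions count; rows whose true class
#' is "unexpected" are excluded; classes with no accepted prediction are
#' dropped from the mean with a warning.
#'
#' @param predictions data.frame from [predict_with_rejection()] (or any with
#'   `class` and `accepted`).
#' @param truth true class per row of `predictions`.
#' @return MCA as a fraction in `[0, 1]`, with attribute `"per_class"`.
#' @export
mca <- function(predictions, truth) {
  stopifnot(nrow(predictions) == length(truth))
  acc <- if ("accepted" %in% colnames(predictions)) predictions$accepted
         else rep(TRUE, nrow(predictions))
  use <- acc & truth != "unexpected"
  pred <- predictions$class[use]
  tr <- truth[use]
  classes <- sort(unique(tr))
  ca <- vapply(classes, function(k) {
    nk <- sum(pred == k)
    if (nk == 0) NA_real_ else sum(pred == k & tr == k) / nk
  }, 0)
  if (anyNA(ca)) {
    warning("classes with no accepted prediction excluded from MCA: ",
            paste(classes[is.na(ca)], collapse = ", "))
  }
  structure(mean(ca, na.rm = TRUE), per_class = ca)
}
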