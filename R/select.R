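# Feature scaling and mRMR selection: min-max normalization, mutual
# information on equal-width discretizations, greedy minimum-redundancy
# maximum-relevance ranking, and the accuracy-vs-subset-size curve whose
# plateau locates the smallest sufficient feature subset.

#' Impute flagged/undefined feature values
#'
#' Replaces `NA` entries by the column median of the defined values (columns
#' with no defined value become 0). The flag table travels unchanged.
#'
#' @param table feature table.
#' @return imputed table.
#' @export
impute_features <- function(table) {
  for (cn in setdiff(colnames(table), c("nucleus_id", "tissue_class",
                                        "strain", "day"))) {
    v <- table[[cn]]
    if (is.logical(v) && all(is.na(v))) v <- as.numeric(v)
    if (!is.numeric(v) || !anyNA(v)) next
    med <- stats::median(v, na.rm = TRUE)
    if (is.na(med)) med <- 0
    table[[cn]][is.na(v)] <- med
  }
  table
}

#' Min-max normalization
#'
#' Projects every feature column onto `[0, 1]` by `(x - min)/(max - min)`.
#' Constant columns carry no information and are dropped with a warning.
#' Idempotent: normalizing twice equals normalizing once.
#'
#' @param table feature table (metadata columns `nucleus_id`, `tissue_class`,
#'   `strain`, `day` pass through).
#' @return normalized table.
#' @export
minmax_normalize <- function(table) {
  meta <- intersect(c("nucleus_id", "tissue_class", "strain", "day"),
                    colnames(table))
  feats <- setdiff(colnames(table), meta)
  drop <- character(0)
  for (cn in feats) {
    v <- table[[cn]]
    if (!is.numeric(v)) next
    if (anyNA(v)) stop("normalize after imputing undefined values (",
                       cn, " has NA)")
    rng <- range(v)
    if (rng[1] == rng[2]) {
      drop <- c(drop, cn)
    } else {
      table[[cn]] <- (v - rng[1]) / (rng[2] - rng[1])
    }
  }
  if (length(drop)) {
    warning("dropping constant feature column(s): ",
            paste(drop, collapse = ", "))
    table <- table[, setdiff(colnames(table), drop), drop = FALSE]
  }
  table
}

#' Mutual information (bits)
#'
#' Plug-in mutual information of the joint distribution after equal-width
#' discretization of numeric inputs into `bins` bins (non-numeric inputs are
#' used as-is). Symmetric and non-negative.
#'
#' @param x,y vectors of equal length (feature column, or class labels).
#' @param bins number of bins for numeric inputs (default 10).
#' @return mutual information in bits.
#' @export
mutual_information <- function(x, y, bins = 10L) {
  if (!length(x) || length(x) != length(y)) {
    stop("x and y must be non-empty and of equal length")
  }
  stopifnot(bins >= 2L)
  dx <- discretize_ew(x, bins)
  dy <- discretize_ew(y, bins)
  pj <- table(dx, dy) / length(dx)
  px <- rowSums(pj); py <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log2(pj[nz] / outer(px, py)[nz]))
}

discretize_ew <- function(v, bins) {
  if (!is.numeric(v)) return(as.character(v))
  rng <- range(v)
  if (rng[1] == rng[2]) return(rep(1L, length(v)))
  idx <- floor((v - rng[1]) / (rng[2] - rng[1]) * bins) + 1L
  pmin(idx, bins)
}

#' mRMR feature ranking
#'
#' Greedy forward ranking: the first feature maximizes the relevance
#' `MI(f; class)`; each subsequent step picks the unselected feature
#' maximizing relevance minus (MID, default) or divided by (MIQ) the mean
#' mutual information with the already-selected features.
#'
#' @param table feature table (normalized).
#' @param labels class labels (default the table's `tissue_class`, with
#'   "unexpected" rows excluded from the ranking).
#' @param bins discretization bins (default 10).
#' @param criterion "MID" (difference) or "MIQ" (quotient).
#' @return object of class `mrmr_ranking`: data.frame with `rank`, `feature`,
#'   `relevance`, `redundancy`, `score`.
#' @export
mrmr_rank <- function(table, labels = NULL, bins = 10L,
                      criterion = c("MID", "MIQ")) {
  criterion <- match.arg(criterion)
  if (is.null(labels)) {
    if (!"tissue_class" %in% colnames(table)) stop("labels required")
    keep <- table$tissue_class != "unexpected"
    labels <- table$tissue_class[keep]
    table <- table[keep, , drop = FALSE]
  }
  feats <- setdiff(colnames(table), c("nucleus_id", "tissue_class",
                                      "strain", "day"))
  if (!length(feats)) stop("no feature columns")
  rel <- vapply(feats, function(f)
    mutual_information(table[[f]], labels, bins), 0)
  # pairwise feature MI cache, filled lazily
  mi_cache <- new.env(parent = emptyenv())
  fmi <- function(f, g) {
    key <- paste(sort(c(f, g)), collapse = "|")
    if (!is.null(mi_cache[[key]])) return(mi_cache[[key]])
    v <- mutual_information(table[[f]], table[[g]], bins)
    mi_cache[[key]] <- v
    v
  }
  selected <- character(0)
  rows <- list()
  remaining <- feats
  for (step in seq_along(feats)) {
    if (step == 1L) {
      sc <- rel[remaining]
      red <- stats::setNames(rep(0, length(remaining)), remaining)
    } else {
      red <- vapply(remaining, function(f)
        mean(vapply(selected, function(g) fmi(f, g), 0)), 0)
      sc <- if (criterion == "MID") rel[remaining] - red
            else rel[remaining] / pmax(red, .Machine$double.eps)
    }
    pick <- remaining[which.max(sc)]
    rows[[step]] <- data.frame(rank = step, feature = pick,
                               relevance = unname(rel[pick]),
                               redundancy = unname(red[pick]),
                               score = unname(sc[which.max(sc)]))
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  structure(do.call(rbind, rows),
            criterion = criterion, bins = bins,
            class = c("mrmr_ranking", "data.frame"))
}

#' Accuracy vs feature-subset size
#'
#' For `n = 1..n_max` trains each classifier on the top-`n` ranked features
#' under stratified `cv_folds`-fold cross-validation (all predictions kept —
#' no rejection at this stage) and records the pooled-prediction MCA. The
#' plateau point is the smallest `n` whose mean-over-classifiers MCA comes
#' within `tolerance` of the curve's maximum.
#'
#' @param table normalized feature table with `tissue_class`.
#' @param ranking an `mrmr_ranking` (or character vector of feature names).
#' @param classifiers kinds to evaluate (default "kNN" — the fast member of
#'   the bank; pass several for a full comparison plot).
#' @param cv_seed integer seed for folds and fits.
#' @param n_max largest subset size (default: full ranking).
#' @param tolerance plateau tolerance in MCA (default 0.01 = 1 point).
#' @param cv_folds folds (default 3).
#' @return data.frame `n`, `classifier`, `mca`, with attributes
#'   `"plateau"` (smallest sufficient `n`, mean curve) and
#'   `"plateau_by_classifier"`.
#' @export
subset_curve <- function(table, ranking, classifiers = "kNN", cv_seed = 1L,
                         n_max = NULL, tolerance = 0.01, cv_folds = 3L) {
  feats <- if (inherits(ranking, "data.frame")) ranking$feature
           else as.character(ranking)
  keep <- table$tissue_class != "unexpected"
  tab <- table[keep, , drop = FALSE]
  y <- as.character(tab$tissue_class)
  if (length(unique(y)) < 2L) stop("need at least 2 classes")
  if (min(table(y)) < cv_folds) stop("a class has fewer members than folds")
  if (is.null(n_max)) n_max <- length(feats)
  classes <- sort(unique(y))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(cv_seed)
  fold <- stratified_folds(y, cv_folds)
  Xall <- feature_matrix(tab, feats)
  rows <- list()
  for (kind in classifiers) {
    for (n in seq_len(n_max)) {
      X <- Xall[, seq_len(n), drop = FALSE]
      pred <- character(length(y))
      for (f in seq_len(cv_folds)) {
        tr <- fold != f
        set.seed(cv_seed + 1000L * f + n)
        wts <- class_weights(y[tr])
        m <- fit_kind(kind, X[tr, , drop = FALSE], y[tr],
                      unname(wts[y[tr]]), classes, list())
        p <- predict_proba(m, X[!tr, , drop = FALSE])
        pred[!tr] <- classes[max.col(p, ties.method = "first")]
      }
      v <- suppressWarnings(
        mca(data.frame(class = pred, accepted = TRUE), y))
      rows[[length(rows) + 1L]] <- data.frame(n = n, classifier = kind,
                                              mca = as.numeric(v))
    }
  }
  out <- do.call(rbind, rows)
  mean_curve <- tapply(out$mca, out$n, mean)
  plateau <- min(as.integer(names(mean_curve))[
    mean_curve >= max(mean_curve) - tolerance])
  by_cl <- vapply(unique(out$classifier), function(k) {
    cur <- out$mca[out$classifier == k]
    min(which(cur >= max(cur) - tolerance))
  }, 0L)
  structure(out, plateau = plateau, plateau_by_classifier = by_cl,
            tolerance = tolerance)
}
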