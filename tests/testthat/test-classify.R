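# 4-class blob table used by several cases
blob_table <- function(n_per = 40, sd = 0.4, seed = 42) {
  set.seed(seed)
  mu <- matrix(c(0, 0, 3, 0, 0, 3, 3, 3), 4, 2, byrow = TRUE)
  X <- do.call(rbind, lapply(1:4, function(k)
    sweep(matrix(stats::rnorm(2 * n_per, sd = sd), n_per, 2), 2, mu[k, ],
          `+`)))
  tab <- data.frame(
    f1 = X[, 1], f2 = X[, 2],
    tissue_class = rep(c("hypodermal", "intestinal", "muscle", "neuronal"),
                       each = n_per))
  minmax_normalize(tab)
}

test_that("class weights follow sqrt(N_total / N_i)", {
  expect_equal(unname(class_weights(rep("a", 30))), 1)
  w <- class_weights(rep(c("a", "b"), c(75, 25)))
  expect_equal(unname(w["b"]), 2)
  w2 <- class_weights(rep(c("a", "b"), c(80, 20)))
  expect_equal(unname(w2), c(sqrt(1.25), sqrt(5)), tolerance = 1e-12)
  # scale invariance: doubling every count leaves weights unchanged
  w3 <- class_weights(rep(c("a", "b"), c(160, 40)))
  expect_equal(w2, w3)
})

test_that("every classifier separates linearly separable blobs", {
  tab <- blob_table()
  for (kind in c("SVM", "RF", "kNN", "NN")) {
    fit <- train_classifier(tab, kind, seed = 7)
    pr <- predict_with_rejection(fit, tab, threshold = 0)
    expect_gte(as.numeric(mca(pr, tab$tissue_class)), 1 - 1e-9)
  }
  # posteriors always sum to 1
  fit <- train_classifier(tab, "SVM", seed = 7)
  pr <- predict_with_rejection(fit, tab, threshold = 0.5)
  pcols <- c("hypodermal", "intestinal", "muscle", "neuronal")
  expect_equal(unname(rowSums(pr[, pcols])), rep(1, nrow(pr)))
})

test_that("random forest uses 19 trees and tree-vote posteriors", {
  tab <- blob_table(n_per = 15)
  fit <- train_classifier(tab, "RF", seed = 3)
  expect_equal(fit$model$n_trees, 19L)
  expect_length(fit$model$trees, 19L)
  pr <- predict_with_rejection(fit, tab, threshold = 0)
  expect_true(all(abs(pr$posterior_max * 19 -
                        round(pr$posterior_max * 19)) < 1e-9))
})

test_that("kNN: unanimous neighbourhood gives posterior 1", {
  tab <- data.frame(f1 = c(rep(0, 11), rep(5, 11)),
                    f2 = c(rep(0, 11), rep(5, 11)),
                    tissue_class = rep(c("muscle", "neuronal"), each = 11))
  fit <- train_classifier(tab, "kNN", seed = 1)
  pr <- predict_with_rejection(fit, data.frame(f1 = 0.01, f2 = 0.01),
                               threshold = 0.9)
  expect_equal(pr$class, "muscle")
  expect_equal(pr$posterior_max, 1)
  expect_true(pr$accepted)
})

test_that("grid search: single point returned, determinism, class minimum", {
  tab <- blob_table(n_per = 12)
  sp <- classifier_spec("kNN", seed = 5)
  fit <- grid_search(sp, tab)
  expect_equal(fit$best_params, list(k = 10L))
  f1 <- train_classifier(tab, "DT", seed = 9)
  f2 <- train_classifier(tab, "DT", seed = 9)
  expect_equal(f1$best_params, f2$best_params)
  expect_equal(f1$cv_scores, f2$cv_scores)
  tiny <- tab[c(1:2, 13:14, 25:26, 37:38), ]
  expect_error(train_classifier(tiny, "kNN"), "at least")
})

test_that("balanced classes reduce the weighted CV score to plain MCA", {
  pred <- c("a", "a", "b", "b", "a", "b")
  truth <- c("a", "b", "b", "b", "a", "a")
  wts <- c(a = 1, b = 1)
  s <- wormnuc:::weighted_score(pred, truth, wts)
  m <- mca(data.frame(class = pred, accepted = TRUE), truth)
  expect_equal(as.numeric(s), as.numeric(m))
})

test_that("rejection thresholds 0 and 1 behave as stated", {
  tab <- blob_table(n_per = 20, sd = 1.0)
  fit <- train_classifier(tab, "RF", seed = 2)
  p0 <- predict_with_rejection(fit, tab, threshold = 0)
  expect_true(all(p0$accepted))
  p1 <- predict_with_rejection(fit, tab, threshold = 1)
  expect_true(all(p1$accepted == (p1$posterior_max >= 1)))
})

test_that("mca implements the predicted-as-class denominator", {
  # confusion [[8,2],[2,8]]: CA = (0.8, 0.8), MCA = 0.8
  pred <- c(rep("a", 10), rep("b", 10))
  truth <- c(rep("a", 8), "b", "b", "a", "a", rep("b", 8))
  m <- mca(data.frame(class = pred, accepted = TRUE), truth)
  expect_equal(as.numeric(m), 0.8)
  expect_equal(unname(attr(m, "per_class")), c(0.8, 0.8))
  # all correct
  m2 <- mca(data.frame(class = truth, accepted = TRUE), truth)
  expect_equal(as.numeric(m2), 1)
  # unexpected rows are excluded
  m3 <- mca(data.frame(class = c(pred, "a", "a"), accepted = TRUE),
            c(truth, "unexpected", "unexpected"))
  expect_equal(as.numeric(m3), 0.8)
  # a never-predicted class warns and is dropped
  expect_warning(
    m4 <- mca(data.frame(class = rep("a", 4), accepted = TRUE),
              c("a", "a", "b", "a")),
    "no accepted prediction")
  expect_equal(as.numeric(m4), 0.75)
})
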