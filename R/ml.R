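# Self-contained learners for the five-classifier bank. Nothing in the target
# environment provides CART/forest/SVM/kNN/MLP with the settings used here,
# so they are implemented directly: each fit is deterministic given the seed
# in its spec and exposes class posteriors via predict_proba().

# ---- CART ------------------------------------------------------------------
# Classification tree with entropy impurity ("information gain") and random
# candidate thresholds per feature, the best of which is taken ("best random
# split"). Supports per-sample weights; leaves store weighted class
# frequencies.

entropy_impurity <- function(wcounts) {
  tot <- sum(wcounts)
  if (tot <= 0) return(0)
  p <- wcounts[wcounts > 0] / tot
  -sum(p * log2(p))
}

fit_cart <- function(X, y, w, classes, max_depth = Inf, min_split = 5L,
                     mtry = ncol(X), n_thresholds = 12L) {
  grow <- function(idx, depth) {
    wc <- vapply(classes, function(k) sum(w[idx][y[idx] == k]), 0)
    node <- list(leaf = TRUE, prob = if (sum(wc) > 0) wc / sum(wc)
                 else rep(1 / length(classes), length(classes)))
    if (depth >= max_depth || length(idx) < min_split ||
        length(unique(y[idx])) == 1L) {
      return(node)
    }
    imp0 <- entropy_impurity(wc)
    feats <- if (mtry < ncol(X)) sample.int(ncol(X), mtry) else seq_len(ncol(X))
    best <- list(gain = 1e-12)
    for (f in feats) {
      v <- X[idx, f]
      lo <- min(v); hi <- max(v)
      if (lo == hi) next
      thr <- stats::runif(n_thresholds, lo, hi)
      for (t in thr) {
        left <- v <= t
        if (!any(left) || all(left)) next
        wl <- vapply(classes, function(k) sum(w[idx][left & y[idx] == k]), 0)
        wr <- wc - wl
        sl <- sum(wl); sr <- sum(wr)
        gain <- imp0 - (sl * entropy_impurity(wl) +
                          sr * entropy_impurity(wr)) / (sl + sr)
        if (gain > best$gain) best <- list(gain = gain, f = f, t = t)
      }
    }
    if (is.null(best$f)) return(node)
    left <- idx[X[idx, best$f] <= best$t]
    right <- setdiff(idx, left)
    list(leaf = FALSE, f = best$f, t = best$t,
         left = grow(left, depth + 1L), right = grow(right, depth + 1L))
  }
  structure(list(root = grow(seq_len(nrow(X)), 0L), classes = classes),
            class = "wn_cart")
}

predict_cart_row <- function(node, x) {
  while (!node$leaf) {
    node <- if (x[node$f] <= node$t) node$left else node$right
  }
  node$prob
}

predict_proba.wn_cart <- function(model, X) {
  out <- t(apply(X, 1, function(x) predict_cart_row(model$root, x)))
  colnames(out) <- model$classes
  out
}

# ---- Random forest ---------------------------------------------------------
# Bagged CARTs (19 by default) with sqrt(p) feature subsampling; the forest
# posterior is the fraction of tree votes per class.

fit_forest <- function(X, y, w, classes, n_trees = 19L, max_depth = Inf) {
  mtry <- max(1L, floor(sqrt(ncol(X))))
  trees <- vector("list", n_trees)
  n <- nrow(X)
  for (b in seq_len(n_trees)) {
    idx <- sample.int(n, n, replace = TRUE)
    trees[[b]] <- fit_cart(X[idx, , drop = FALSE], y[idx], w[idx], classes,
                           max_depth = max_depth, mtry = mtry)
  }
  structure(list(trees = trees, classes = classes, n_trees = n_trees),
            class = "wn_forest")
}

predict_proba.wn_forest <- function(model, X) {
  K <- length(model$classes)
  votes <- matrix(0, nrow(X), K, dimnames = list(NULL, model$classes))
  for (tr in model$trees) {
    p <- predict_proba.wn_cart(tr, X)
    hit <- max.col(p, ties.method = "first")
    votes[cbind(seq_len(nrow(X)), hit)] <-
      votes[cbind(seq_len(nrow(X)), hit)] + 1
  }
  votes / model$n_trees
}

# ---- kNN -------------------------------------------------------------------
# k = 10, Manhattan distance; posterior = neighbour vote fraction. (A k-d
# tree accelerates the original; at these data sizes direct distances are
# exact and fast.)

fit_knn <- function(X, y, w, classes, k = 10L) {
  structure(list(X = X, y = y, classes = classes,
                 k = min(k, nrow(X))), class = "wn_knn")
}

predict_proba.wn_knn <- function(model, X) {
  n <- nrow(X)
  K <- length(model$classes)
  out <- matrix(0, n, K, dimnames = list(NULL, model$classes))
  for (i in seq_len(n)) {
    d <- colSums(abs(t(model$X) - X[i, ]))
    nb <- order(d)[seq_len(model$k)]
    tab <- table(factor(model$y[nb], levels = model$classes))
    out[i, ] <- tab / model$k
  }
  out
}

# ---- Linear SVM (one-against-one) ------------------------------------------
# Squared-hinge linear SVM per class pair, minimized with BFGS (convex,
# differentiable, deterministic from zero init). Decision values are mapped to
# pairwise probabilities by Platt sigmoid scaling fitted on the training
# decision values, then coupled by averaging into class posteriors.

fit_svm_pair <- function(X, ypm, w, C) {
  p <- ncol(X)
  obj <- function(th) {
    wv <- th[1:p]; b <- th[p + 1]
    marg <- as.vector(1 - ypm * (X %*% wv + b))
    viol <- pmax(marg, 0)
    0.5 * sum(wv^2) + C * sum(w * viol^2)
  }
  grad <- function(th) {
    wv <- th[1:p]; b <- th[p + 1]
    marg <- as.vector(1 - ypm * (X %*% wv + b))
    act <- marg > 0
    gw <- wv - 2 * C * as.vector(t(X[act, , drop = FALSE]) %*%
                                   (w[act] * ypm[act] * marg[act]))
    gb <- -2 * C * sum(w[act] * ypm[act] * marg[act])
    c(gw, gb)
  }
  fit <- stats::optim(rep(0, p + 1), obj, grad, method = "BFGS",
                      control = list(maxit = 200))
  list(w = fit$par[1:p], b = fit$par[p + 1])
}

platt_fit <- function(f, ypm) {
  # logistic fit of P(y = +1 | f); fall back to a steep sigmoid when the
  # classes are perfectly separated
  y01 <- as.integer(ypm > 0)
  fit <- suppressWarnings(stats::glm(y01 ~ f, family = stats::binomial()))
  cf <- stats::coef(fit)
  if (any(!is.finite(cf))) cf <- c(0, 10)
  cf
}

fit_svm <- function(X, y, w, classes, C = 1) {
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  models <- lapply(pairs, function(pr) {
    sel <- y %in% pr
    ypm <- ifelse(y[sel] == pr[1], 1, -1)
    m <- fit_svm_pair(X[sel, , drop = FALSE], ypm, w[sel], C)
    f <- as.vector(X[sel, , drop = FALSE] %*% m$w + m$b)
    m$platt <- platt_fit(f, ypm)
    m$pair <- pr
    m
  })
  structure(list(models = models, classes = classes), class = "wn_svm")
}

predict_proba.wn_svm <- function(model, X) {
  K <- length(model$classes)
  P <- matrix(0, nrow(X), K, dimnames = list(NULL, model$classes))
  for (m in model$models) {
    f <- as.vector(X %*% m$w + m$b)
    r <- stats::plogis(m$platt[1] + m$platt[2] * f)  # P(first of pair)
    P[, m$pair[1]] <- P[, m$pair[1]] + r
    P[, m$pair[2]] <- P[, m$pair[2]] + (1 - r)
  }
  P / rowSums(P)
}

# ---- MLP -------------------------------------------------------------------
# One hidden layer (15 tanh units), softmax output, cross-entropy loss with
# L2 penalty 0.001, trained full-batch by Adam (lr 0.001, beta 0.9/0.999,
# eps 1e-8).

fit_mlp <- function(X, y, w, classes, hidden = 15L, epochs = 400L,
                    lr = 1e-3, l2 = 1e-3, beta1 = 0.9, beta2 = 0.999,
                    eps = 1e-8) {
  p <- ncol(X); K <- length(classes)
  Y <- outer(y, classes, `==`) * 1
  sw <- w / sum(w)
  W1 <- matrix(stats::runif(p * hidden, -1, 1) / sqrt(p), p, hidden)
  b1 <- rep(0, hidden)
  W2 <- matrix(stats::runif(hidden * K, -1, 1) / sqrt(hidden), hidden, K)
  b2 <- rep(0, K)
  pars <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  m <- lapply(pars, function(z) z * 0)
  v <- lapply(pars, function(z) z * 0)
  for (t in seq_len(epochs)) {
    H <- tanh(sweep(X %*% pars$W1, 2, pars$b1, `+`))
    Z <- sweep(H %*% pars$W2, 2, pars$b2, `+`)
    Z <- Z - apply(Z, 1, max)
    E <- exp(Z); S <- E / rowSums(E)
    delta2 <- (S - Y) * sw           # dL/dZ per row
    g <- list(W2 = t(H) %*% delta2 + l2 * pars$W2,
              b2 = colSums(delta2),
              W1 = NULL, b1 = NULL)
    delta1 <- (delta2 %*% t(pars$W2)) * (1 - H^2)
    g$W1 <- t(X) %*% delta1 + l2 * pars$W1
    g$b1 <- colSums(delta1)
    for (nm in names(pars)) {
      m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g[[nm]]
      v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g[[nm]]^2
      mh <- m[[nm]] / (1 - beta1^t)
      vh <- v[[nm]] / (1 - beta2^t)
      pars[[nm]] <- pars[[nm]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  structure(list(pars = pars, classes = classes), class = "wn_mlp")
}

predict_proba.wn_mlp <- function(model, X) {
  pars <- model$pars
  H <- tanh(sweep(X %*% pars$W1, 2, pars$b1, `+`))
  Z <- sweep(H %*% pars$W2, 2, pars$b2, `+`)
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  P <- E / rowSums(E)
  colnames(P) <- model$classes
  P
}

# generic dispatcher (internal; not an S3 generic to keep the surface small)
predict_proba <- function(model, X) {
  switch(class(model)[1],
         wn_cart = predict_proba.wn_cart(model, X),
         wn_forest = predict_proba.wn_forest(model, X),
         wn_knn = predict_proba.wn_knn(model, X),
         wn_svm = predict_proba.wn_svm(model, X),
         wn_mlp = predict_proba.wn_mlp(model, X),
         stop("unknown model class"))
}
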