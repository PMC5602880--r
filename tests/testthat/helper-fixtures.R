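# shared fixtures: analytic shapes, brute-force oracles and a cached scene

mk_disk <- function(r, pad = 6L, value = 1L) {
  n <- 2L * r + 2L * pad + 1L
  ctr <- (n + 1) / 2
  ii <- matrix(seq_len(n), n, n)
  jj <- t(ii)
  matrix(as.integer((ii - ctr)^2 + (jj - ctr)^2 <= r^2) * value, n, n)
}

mk_two_disks <- function(r = 20L, sep = 30L, nr = 70L, nc = 110L) {
  ii <- matrix(seq_len(nr), nr, nc)
  jj <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  c1 <- c(35, 40); c2 <- c(35, 40 + sep)
  m <- (ii - c1[1])^2 + (jj - c1[2])^2 <= r^2 |
    (ii - c2[1])^2 + (jj - c2[2])^2 <= r^2
  matrix(as.integer(m), nr, nc)
}

# dumbbell: two disks bridged by a bar of half-width `neck`
mk_dumbbell <- function(r = 15L, gap = 50L, neck = 4L, nr = 60L, nc = 120L) {
  ii <- matrix(seq_len(nr), nr, nc)
  jj <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  c1 <- c(30, 30); c2 <- c(30, 30 + gap)
  m <- (ii - c1[1])^2 + (jj - c1[2])^2 <= r^2 |
    (ii - c2[1])^2 + (jj - c2[2])^2 <= r^2 |
    (abs(ii - 30) <= neck & jj >= 30 & jj <= 30 + gap)
  matrix(as.integer(m), nr, nc)
}

# O(n^2) nearest-zero distance oracle
brute_distance_map <- function(mask) {
  zi <- which(mask == 0, arr.ind = TRUE)
  out <- matrix(0, nrow(mask), ncol(mask))
  fg <- which(mask != 0, arr.ind = TRUE)
  if (nrow(fg) == 0L) return(out)
  for (t in seq_len(nrow(fg))) {
    out[fg[t, 1], fg[t, 2]] <-
      sqrt(min((zi[, 1] - fg[t, 1])^2 + (zi[, 2] - fg[t, 2])^2))
  }
  out
}

# exhaustive Otsu oracle over integer cut points
brute_otsu <- function(x) {
  x <- as.numeric(x)
  lv <- sort(unique(x))
  cuts <- lv[-length(lv)]
  n <- length(x)
  best <- -Inf; thr <- cuts[1]
  for (t in cuts) {
    lo <- x <= t
    w0 <- mean(lo)
    sb <- w0 * (1 - w0) * (mean(x[lo]) - mean(x[!lo]))^2
    if (sb > best + 1e-12) { best <- sb; thr <- t }
  }
  thr
}

# brute-force GLCM (double loop) on a quantized raster with NA background
brute_glcm <- function(q, shift, levels, symmetric = TRUE) {
  C <- matrix(0, levels, levels)
  nr <- nrow(q); nc <- ncol(q)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    i2 <- i + shift[1]; j2 <- j + shift[2]
    if (i2 < 1 || i2 > nr || j2 < 1 || j2 > nc) next
    if (is.na(q[i, j]) || is.na(q[i2, j2])) next
    C[q[i, j], q[i2, j2]] <- C[q[i, j], q[i2, j2]] + 1
  }
  if (symmetric) C <- C + t(C)
  C / sum(C)
}

# plug-in MI oracle for discrete vectors
brute_mi <- function(x, y) {
  pj <- table(x, y) / length(x)
  px <- rowSums(pj); py <- colSums(pj)
  s <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (pj[i, j] > 0) s <- s + pj[i, j] * log2(pj[i, j] / (px[i] * py[j]))
  }
  unname(s)
}

# round half away from zero (the usual "printed value" convention)
round_half_up <- function(x, digits = 2) floor(x * 10^digits + 0.5) / 10^digits

# per-truth-nucleus IoU against the best-overlapping predicted region
iou_per_truth <- function(truth, pred) {
  ids <- sort(setdiff(unique(as.vector(truth)), 0L))
  vapply(ids, function(k) {
    tm <- truth == k
    ov <- table(pred[tm])
    ov <- ov[names(ov) != "0"]
    if (!length(ov)) return(0)
    bk <- as.integer(names(ov)[which.max(ov)])
    pm <- pred == bk
    sum(tm & pm) / sum(tm | pm)
  }, 0)
}

# cached default scene shared across test files
.scene_cache <- new.env(parent = emptyenv())
test_scene <- function(n = 20, age_day = 1, clump = 0, noise = 60, seed = 1) {
  key <- paste(n, age_day, clump, noise, seed, sep = "_")
  if (is.null(.scene_cache[[key]])) {
    .scene_cache[[key]] <- generate_scene(n, age_day = age_day,
                                          clump_fraction = clump,
                                          noise_level = noise, seed = seed)
  }
  .scene_cache[[key]]
}

# planted-informative-feature table: 5 informative of 49, signal spread so
# that accuracy keeps rising up to the 5th feature
planted_table <- function(n = 300, seed = 9, sd_noise = 0.75) {
  set.seed(seed)
  cls <- sample(c("hypodermal", "intestinal", "muscle", "neuronal"),
                n, TRUE, prob = c(8, 2, 2, 3) / 15)
  ci <- as.integer(factor(cls, levels = c("hypodermal", "intestinal",
                                          "muscle", "neuronal")))
  inf <- vapply(1:5, function(j) ci + stats::rnorm(n, sd = sd_noise),
                numeric(n))
  noise <- matrix(stats::runif(n * 44), n, 44)
  tab <- data.frame(cbind(inf, noise))
  colnames(tab) <- c(paste0("inf", 1:5), paste0("noise", 1:44))
  tab$tissue_class <- cls
  minmax_normalize(tab)
}
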