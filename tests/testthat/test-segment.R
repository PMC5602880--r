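test_that("fusion formula reproduces the worked example", {
  img <- two_channel_image(green = rbind(c(100, 0), c(100, 0)),
                           red = rbind(c(50, 80), c(60, 0)), P = 200)
  fz <- fuse_channels(img, 0.6, 0.4)
  expect_equal(fz$I_b, rbind(c(1L, 0L), c(1L, 0L)))
  expect_equal(fz$fused, rbind(c(170, 0), c(180, 0)))
})

test_that("fusion degenerate cases: zero red, masked red, zero green", {
  g <- rbind(c(100, 0), c(100, 0))
  img <- two_channel_image(g, g * 0, P = 200)
  fz <- fuse_channels(img)
  expect_equal(fz$fused, g * (200 * 0.6 / 100))
  # red ignored where I_b = 0
  img2 <- two_channel_image(g, rbind(c(0, 99), c(0, 99)), P = 200)
  fz2 <- fuse_channels(img2)
  expect_equal(fz2$fused[, 2], c(0, 0))
  expect_error(
    fuse_channels(two_channel_image(g * 0, g, P = 200)),
    "all-zero green")
})

test_that("fusion linearity: scaling channels and P scales the fused image", {
  set.seed(7)
  g <- matrix(sample(0:100, 400, TRUE), 20, 20)
  r <- matrix(sample(0:100, 400, TRUE), 20, 20)
  f1 <- fuse_channels(two_channel_image(g, r, P = 200))
  f2 <- fuse_channels(two_channel_image(3 * g, 3 * r, P = 600))
  expect_equal(f2$fused, 3 * f1$fused)
  expect_identical(f2$I_b, f1$I_b)
})

test_that("otsu equals exhaustive between-class-variance search", {
  expect_error(otsu_threshold(matrix(5, 3, 3)), "constant")
  x <- c(rep(10, 50), rep(200, 50))
  t0 <- otsu_threshold(x)
  expect_gt(t0, 9); expect_lt(t0, 200)
  set.seed(21)
  for (t in 1:20) {
    x <- sample(0:255, 500, TRUE, prob = stats::runif(256)^2)
    if (length(unique(x)) < 2) next
    expect_equal(as.numeric(otsu_threshold(x)), brute_otsu(x))
  }
})

test_that("otsu separates a bimodal gaussian mixture to < 1% error", {
  set.seed(8)
  lo <- stats::rnorm(5000, 50, 10)
  hi <- stats::rnorm(5000, 180, 10)
  x <- round(pmin(pmax(c(lo, hi), 0), 255))
  thr <- otsu_threshold(x)
  err <- (sum(lo > thr) + sum(hi <= thr)) / 10000
  expect_lt(err, 0.01)
})

test_that("binarize: stationary image agrees across modes, constant empty", {
  img <- matrix(10, 80, 80)
  set.seed(3)
  for (k in 1:6) {
    c0 <- sample(15:65, 2)
    ii <- matrix(seq_len(80), 80, 80); jj <- t(ii)
    img[(ii - c0[1])^2 + (jj - c0[2])^2 <= 49] <- 200
  }
  bg <- binarize(img, window = 41L, force = "global")
  bl <- binarize(img, window = 41L, force = "local")
  expect_gte(mean(bg == bl), 0.98)
  emp <- binarize(matrix(4, 30, 30))
  expect_equal(attr(emp, "mode"), "empty")
  expect_true(all(emp == 0L))
})

test_that("local thresholding recovers foreground under strong shading", {
  n <- 300
  img <- matrix(0, n, n); truth <- matrix(0L, n, n)
  set.seed(2)
  ctrs <- cbind(stats::runif(12, 30, n - 30), stats::runif(12, 30, n - 30))
  ii <- matrix(seq_len(n), n, n); jj <- t(ii)
  for (k in 1:12) {
    d2 <- (ii - round(ctrs[k, 1]))^2 + (jj - round(ctrs[k, 2]))^2
    img[d2 <= 144] <- 100
    truth[d2 <= 144] <- 1L
  }
  img <- img + matrix(rep(seq(0, 400, length.out = n), each = n), n, n)
  bw <- binarize(img, window = 151L)
  expect_equal(attr(bw, "mode"), "local")
  expect_gte(mean(bw[truth == 1L] == 1L), 0.95)
})

test_that("seed detection: isolated, disjoint, dumbbell", {
  one <- mk_disk(15)
  D <- distance_map(one)
  s <- detect_seeds(D, 2)
  expect_equal(nrow(s), 1L)
  ctr <- (nrow(one) + 1) / 2
  expect_lte(max(abs(c(s$row, s$col) - ctr)), 1)
  two <- mk_two_disks(15, 45)
  s2 <- detect_seeds(distance_map(two), 2)
  expect_equal(nrow(s2), 2L)
  db <- mk_dumbbell(r = 15, gap = 40, neck = 6)
  s3 <- detect_seeds(distance_map(db), 2)
  expect_equal(nrow(s3), 2L)
  # empty foreground
  s4 <- detect_seeds(matrix(0, 10, 10), 2)
  expect_equal(nrow(s4), 0L)
})

test_that("merge rule follows n > m * r exactly and r = 1 boundary case", {
  D <- matrix(0, 21, 41)
  D[11, ] <- c(seq(1, 10, length.out = 11), rep(7.5, 19),
               seq(10, 1, length.out = 11))
  D[11, 11] <- 10; D[11, 31] <- 8
  seeds <- data.frame(row = c(11, 11), col = c(11, 31), value = c(10, 8))
  m <- merge_seeds(seeds, D, r = 0.928)  # n = 7.5 > 8 * 0.928 = 7.424
  expect_equal(nrow(m), 1L)
  expect_equal(unlist(m[1, c("row", "col")]), c(row = 11, col = 21))
  D2 <- D; D2[11, 12:30] <- pmin(D2[11, 12:30], 7.0)
  m2 <- merge_seeds(seeds, D2, r = 0.928)  # 7.0 < 7.424
  expect_equal(nrow(m2), 2L)
  # strict inequality: n = m at r = 1 does not merge
  D3 <- matrix(5, 9, 9)
  s3 <- data.frame(row = c(5, 5), col = c(3, 7), value = c(5, 5))
  expect_equal(nrow(merge_seeds(s3, D3, r = 1)), 2L)
})

test_that("increasing r only reduces the number of merges", {
  set.seed(13)
  db <- mk_dumbbell(r = 15, gap = 46, neck = 9)
  D <- distance_map(db)
  s <- detect_seeds(D, 2)
  Ds <- attr(s, "smoothed")
  n_after <- vapply(c(0.5, 0.7, 0.928, 0.99),
                    function(r) nrow(merge_seeds(s, Ds, r)), 0L)
  expect_true(all(diff(n_after) >= 0))
})

test_that("watershed partitions the foreground, one region per seed", {
  two <- mk_two_disks(20, 30)  # overlapping disks -> one blob
  expect_equal(max(label_components(two)), 1L)
  D <- distance_map(two)
  seeds <- data.frame(row = c(35, 35), col = c(40, 70), value = D[35, c(40, 70)])
  lab <- split_clusters(two, seeds, D)
  expect_equal(sort(unique(as.vector(lab[two == 1L]))), c(1L, 2L))
  expect_true(all(lab[two == 0L] == 0L))
  areas <- tabulate(lab[lab > 0L])
  expect_lt(abs(areas[1] / areas[2] - 1), 0.05)
  expect_equal(lab[35, 40], 1L)
  expect_equal(lab[35, 70], 2L)
  # one seed in one blob -> label = blob
  one <- mk_disk(12)
  D1 <- distance_map(one)
  s1 <- detect_seeds(D1, 2)
  l1 <- split_clusters(one, s1, D1)
  expect_equal(matrix(as.integer(l1 > 0), nrow(one)), one)
  expect_error(
    split_clusters(one, data.frame(row = c(5, 5), col = c(5, 5)), D1),
    "duplicate")
})

test_that("three chained disks split into three seed-owning regions", {
  nr <- 70L; nc <- 150L
  ii <- matrix(seq_len(nr), nr, nc); jj <- matrix(seq_len(nc), nr, nc, TRUE)
  ctr <- list(c(35, 35), c(35, 70), c(35, 105))
  m <- Reduce(`|`, lapply(ctr, function(cc)
    (ii - cc[1])^2 + (jj - cc[2])^2 <= 400))
  m <- matrix(as.integer(m), nr, nc)
  D <- distance_map(m)
  seeds <- data.frame(row = c(35, 35, 35), col = c(35, 70, 105),
                      value = D[cbind(c(35, 35, 35), c(35, 70, 105))])
  lab <- split_clusters(m, seeds, D)
  expect_equal(max(lab), 3L)
  for (k in 1:3) expect_equal(lab[ctr[[k]][1], ctr[[k]][2]], k)
})

test_that("filter_regions removes small and dark regions, renumbers", {
  lab <- matrix(0L, 40, 40)
  lab[5:20, 5:20] <- 1L      # big bright
  lab[30:32, 30:32] <- 2L    # 9-px speck
  lab[25:28, 5:20] <- 3L     # big but dark
  fused <- matrix(0, 40, 40)
  fused[lab == 1L] <- 100
  fused[lab == 2L] <- 100
  fused[lab == 3L] <- 5
  out <- filter_regions(lab, fused, min_area = 80, min_mean_intensity = 20)
  expect_equal(sort(unique(as.vector(out))), c(0L, 1L))
  expect_true(all(out[lab == 1L] == 1L))
  # thresholds (0, 0) are the identity
  expect_identical(filter_regions(lab, fused, 0, 0), lab)
})
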