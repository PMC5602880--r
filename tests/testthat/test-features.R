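test_that("extract_region: trivial cases and mask round-trip", {
  lab <- matrix(0L, 8, 8); lab[4, 5] <- 1L
  reg <- extract_region(lab, NULL, 1L)
  expect_equal(reg$N, 1L)
  expect_equal(nrow(reg$boundary), 1L)
  sq <- matrix(0L, 9, 9); sq[3:7, 3:7] <- 1L
  rs <- extract_region(sq, NULL, 1L)
  expect_equal(rs$N, 25L)
  expect_equal(nrow(unique(rs$boundary)), 16L)
  # boundary pixels + interior rebuild the mask
  m2 <- rs$mask * 0L
  m2[rs$boundary] <- 1L
  m2 <- wormnuc:::fill_holes(m2)
  expect_equal(m2, rs$mask)
  expect_error(extract_region(sq, NULL, 3L), "not in label map")
})

test_that("boundary is counter-clockwise from the topmost-leftmost pixel", {
  sq <- matrix(0L, 9, 9); sq[3:7, 3:7] <- 1L
  reg <- extract_region(sq, NULL, 1L)
  b <- reg$boundary
  # cropped coordinates; offset maps back to image coordinates
  expect_equal(unname(b[1, ] + reg$offset - 1L), c(3L, 3L))
  x <- b[, 2]; y <- -b[, 1]
  expect_gt(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y), 0)
})

test_that("geometric features on analytic shapes", {
  g20 <- geometric_features(extract_region(mk_disk(20), NULL, 1L))
  expect_lt(abs(g20["circularity"] - 1), 0.1)
  expect_lt(g20["ellipticity"], 0.05)
  expect_gt(g20["solidity"], 0.95)
  rect <- matrix(0L, 20, 50); rect[6:15, 6:45] <- 1L
  gr <- geometric_features(extract_region(rect, NULL, 1L))
  expect_equal(unname(gr["ellipticity"]), 0.75)
  expect_equal(unname(gr["solidity"]), 1)
  expect_equal(unname(gr["area"]), 400)
  g30 <- geometric_features(extract_region(mk_disk(30), NULL, 1L))
  expect_lt(abs(g30["curv_mean"] * 30 - 1), 0.15)
})

test_that("curvature of collinear points is zero and disks are positive", {
  bnd <- cbind(rep(5L, 40), 1:40)  # a straight line of boundary points
  k <- wormnuc:::boundary_curvature(bnd, 10L)
  expect_equal(k[20], 0)
  bdisk <- extract_region(mk_disk(25), NULL, 1L)$boundary
  kd <- wormnuc:::boundary_curvature(bdisk, 10L)
  expect_true(all(kd > 0))  # counter-clockwise convex contour
})

test_that("circularity and solidity are stable across scale and rotation", {
  circ <- vapply(c(10, 20, 35, 50), function(r)
    geometric_features(extract_region(mk_disk(r), NULL, 1L))["circularity"],
    0)
  expect_lt(diff(range(circ)) / mean(circ), 0.05)
  rect <- matrix(0L, 30, 60); rect[6:25, 6:55] <- 1L
  f0 <- geometric_features(extract_region(rect, NULL, 1L))
  f90 <- geometric_features(extract_region(t(rect)[, nrow(rect):1], NULL, 1L))
  for (nm in c("area", "solidity", "circularity", "ellipticity")) {
    expect_lt(abs(f0[nm] - f90[nm]) / max(abs(f0[nm]), 1e-9), 0.03)
  }
})

test_that("intensity moments match the printed 1/(N-1) formulas", {
  lab <- matrix(0L, 4, 4); lab[1, 1:3] <- 1L
  img <- two_channel_image(matrix(c(1, 2, 3, rep(0, 13)), 4, 4, byrow = TRUE),
                           matrix(0, 4, 4) + 1, P = 10)
  reg <- extract_region(lab, img, 1L)
  iv <- intensity_features(reg, "green")
  expect_equal(unname(iv["g_mean"]), 2)
  expect_equal(unname(iv["g_var"]), 1)
  # {0,0,0,4}: skewness exactly 1 under the printed formula
  lab4 <- matrix(0L, 4, 4); lab4[2, ] <- 1L
  img4 <- two_channel_image(matrix(rep(c(0, 0, 0, 4), 4), 4, 4, byrow = TRUE),
                            matrix(1, 4, 4), P = 10)
  # ensure the extracted pixels are exactly {0,0,0,4}
  reg4 <- extract_region(lab4, img4, 1L)
  expect_setequal(reg4$green_pixels, c(0, 0, 0, 4))
  iv4 <- intensity_features(reg4, "green")
  expect_equal(unname(iv4["g_skew"]), 1)
  # symmetric values -> zero skewness
  labs <- matrix(0L, 4, 4); labs[1, ] <- 1L
  imgs <- two_channel_image(matrix(c(1, 2, 2, 3), 4, 4, byrow = TRUE) * 0 +
                              matrix(rep(c(1, 2, 2, 3), each = 4), 4, 4),
                            matrix(1, 4, 4), P = 10)
  ivs <- intensity_features(extract_region(labs, imgs, 1L), "green")
  expect_equal(unname(ivs["g_skew"]), 0)
  # zero variance flags skewness/kurtosis
  ivc <- intensity_features(extract_region(labs, two_channel_image(
    matrix(5, 4, 4), matrix(1, 4, 4), P = 10), 1L), "green")
  expect_equal(unname(ivc["g_skew"]), 0)
  expect_equal(attr(ivc, "flags"), "zero_variance")
  # intensity shift leaves higher moments unchanged
  set.seed(2)
  v <- matrix(sample(10:60, 16, TRUE), 4, 4)
  labf <- matrix(1L, 4, 4)
  i1 <- intensity_features(extract_region(labf, two_channel_image(
    v, v, P = 500), 1L), "green")
  i2 <- intensity_features(extract_region(labf, two_channel_image(
    v + 100, v, P = 500), 1L), "green")
  expect_equal(i1[c("g_var", "g_skew", "g_kurt")],
               i2[c("g_var", "g_skew", "g_kurt")])
})

test_that("GLCM: constant region, stripe enumeration, brute-force oracle", {
  lab <- matrix(0L, 12, 12); lab[3:10, 3:10] <- 1L
  img <- two_channel_image(matrix(5, 12, 12), matrix(7, 12, 12), P = 10)
  reg <- extract_region(lab, img, 1L)
  C <- glcm(reg, "green", glcm_spec(offset = 1), 0)
  expect_equal(sum(C), 1)
  expect_equal(C[1, 1], 1)  # single nonzero entry p(k,k) = 1
  # 1 x 9 alternating stripe, offset 7, 0 degrees: pairs (0,1) and (1,0) only
  labs <- matrix(0L, 3, 11); labs[2, 2:10] <- 1L
  gv <- matrix(0, 3, 11); gv[2, 2:10] <- rep(c(0, 9), length.out = 9)
  imgs <- two_channel_image(gv, gv, P = 10)
  regs <- extract_region(labs, imgs, 1L)
  Cs <- glcm(regs, "green", glcm_spec(offset = 7, levels = 2), 0)
  expect_equal(Cs[1, 1] + Cs[2, 2], 0)
  expect_equal(Cs[1, 2] + Cs[2, 1], 1)
  # oracle equivalence on random regions
  set.seed(31)
  for (t in 1:20) {
    vals <- matrix(sample(0:40, 144, TRUE), 12, 12)
    mk <- matrix(as.integer(stats::runif(144) > 0.3), 12, 12)
    mk[6, 6] <- 1L
    regt <- structure(list(nucleus_id = 1L, mask = mk,
                           green_pixels = vals[mk == 1L],
                           red_pixels = vals[mk == 1L], N = sum(mk)),
                      class = "nucleus_region")
    sp <- glcm_spec(offset = 2, levels = 8)
    q <- matrix(NA_integer_, 12, 12)
    q[mk == 1L] <- wormnuc:::quantize_levels(vals[mk == 1L], 8)
    expect_equal(glcm(regt, "green", sp, 45), brute_glcm(q, c(-2, 2), 8))
    expect_equal(glcm(regt, "green", sp, 90), brute_glcm(q, c(-2, 0), 8))
  }
  # region thinner than the offset -> NULL and flagged features
  thin <- matrix(0L, 3, 3); thin[2, 2] <- 1L
  rt <- extract_region(thin, img <- two_channel_image(matrix(1, 3, 3),
                                                      matrix(1, 3, 3), P = 2),
                       1L)
  expect_null(glcm(rt, "green", glcm_spec(offset = 7), 0))
  gf <- glcm_features(NULL)
  expect_true(all(is.na(gf)))
  expect_equal(attr(gf, "flags"), "no_valid_pairs")
})

test_that("GLCM statistics match hand-evaluated matrices", {
  gf <- glcm_features(matrix(0.25, 2, 2))
  expect_equal(unname(gf["energy"]), 0.25)
  expect_equal(unname(gf["contrast"]), 0.5)
  expect_equal(unname(gf["homogeneity"]), 0.75)
  expect_equal(unname(gf["correlation"]), 0)
  # checkerboard at offset 1: perfect anti-dependence
  cb <- matrix(rep(c(1, 2), length.out = 64), 8, 8)
  cb[, seq(2, 8, 2)] <- 3 - cb[, seq(2, 8, 2)]
  labf <- matrix(1L, 8, 8)
  regc <- structure(list(nucleus_id = 1L, mask = labf,
                         green_pixels = as.vector(cb),
                         red_pixels = as.vector(cb), N = 64L),
                    class = "nucleus_region")
  Cc <- glcm(regc, "green", glcm_spec(offset = 1, levels = 2), 0)
  expect_equal(unname(glcm_features(Cc)["correlation"]), -1)
})

test_that("GLCM feature set permutes under 90-degree rotation", {
  sc <- generate_scene(1, age_day = 1, clump_fraction = 0, noise_level = 0,
                       seed = 12, dim = c(300L, 300L))
  lab <- sc$truth$label_map
  g <- sc$image$green; r <- sc$image$red
  rot90 <- function(m) t(m)[, nrow(m):1]
  img0 <- two_channel_image(g, r, P = sc$image$P)
  img9 <- two_channel_image(rot90(g), rot90(r), P = sc$image$P)
  lab9 <- rot90(lab)
  reg0 <- extract_region(lab, img0, 1L)
  reg9 <- extract_region(lab9, img9, 1L)
  sp <- glcm_spec()
  # rotating the image by 90 deg maps direction d to (d + 90) mod 180
  for (pair in list(c(0, 90), c(45, 135), c(90, 0), c(135, 45))) {
    f0 <- glcm_features(glcm(reg0, "green", sp, pair[1]))
    f9 <- glcm_features(glcm(reg9, "green", sp, pair[2]))
    expect_equal(f0, f9, tolerance = 1e-10)
  }
})

test_that("feature_table: header, single disk row, empty map", {
  sc <- generate_scene(1, age_day = 1, clump_fraction = 0, noise_level = 0,
                       seed = 3, dim = c(300L, 300L))
  ft <- feature_table(sc$truth$label_map, sc$image,
                      classes = sc$truth$classes)
  expect_equal(nrow(ft), 1L)
  expect_equal(colnames(ft), c("nucleus_id", feature_names(), "tissue_class"))
  expect_false(anyNA(ft[, feature_names()]))
  expect_false(any(attr(ft, "flags")[1, ]))
  ft0 <- feature_table(matrix(0L, 20, 20),
                       two_channel_image(matrix(1, 20, 20),
                                         matrix(1, 20, 20), P = 2))
  expect_equal(nrow(ft0), 0L)
  expect_equal(colnames(ft0), c("nucleus_id", feature_names()))
})
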