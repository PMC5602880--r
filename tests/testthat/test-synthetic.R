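test_that("single noiseless nucleus: one label, rim-to-interior contrast", {
  sc <- generate_scene(1, age_day = 1, clump_fraction = 0, noise_level = 0,
                       seed = 7, dim = c(600L, 600L))
  lm <- sc$truth$label_map
  expect_equal(sort(unique(as.vector(lm))), c(0L, 1L))
  g <- sc$image$green
  # lamina band (within 4 px of the edge, excluding the dim outermost px)
  din <- distance_map(matrix(as.integer(lm == 1L), nrow(lm)))
  band <- din > 1 & din <= 4
  core <- din > 6
  expect_gt(mean(g[band]), mean(g[core]))
})

test_that("identical seeds reproduce scenes bit-exactly; seeds differ", {
  a <- generate_scene(20, age_day = 1, clump_fraction = 0.3, noise_level = 5,
                      seed = 1, dim = c(500L, 500L))
  b <- generate_scene(20, age_day = 1, clump_fraction = 0.3, noise_level = 5,
                      seed = 1, dim = c(500L, 500L))
  expect_identical(a$image$green, b$image$green)
  expect_identical(a$image$red, b$image$red)
  expect_identical(a$truth$label_map, b$truth$label_map)
  c2 <- generate_scene(20, age_day = 1, clump_fraction = 0.3, noise_level = 5,
                       seed = 2, dim = c(500L, 500L))
  expect_false(identical(a$truth$label_map, c2$truth$label_map))
})

test_that("scene invariants: labels vs classes, mix, bounds", {
  sc <- test_scene(n = 20, clump = 0.3, noise = 60, seed = 1)
  lm <- sc$truth$label_map
  ids <- setdiff(sort(unique(as.vector(lm))), 0L)
  expect_true(all(as.character(ids) %in% names(sc$truth$classes)))
  counts <- table(sc$truth$specs$tissue_class)[
    c("hypodermal", "intestinal", "muscle", "neuronal")]
  # largest-remainder rounding of 8:2:2:3 at n = 20
  expect_equal(sum(counts), 20L)
  expect_true(all(counts >= floor(c(8, 2, 2, 3) / 15 * 20)))
  expect_equal(names(which.max(counts)), "hypodermal")
  expect_true(all(sc$image$green >= 0 & sc$image$green <= sc$image$P))
  expect_true(all(sc$image$red >= 0 & sc$image$red <= sc$image$P))
})

test_that("red channel is noisier than green", {
  sc <- test_scene(n = 12, clump = 0, noise = 60, seed = 4)
  bg <- sc$truth$label_map == 0
  expect_gt(stats::sd(sc$image$red[bg]), 1.5 * stats::sd(sc$image$green[bg]))
})

test_that("noiseless Otsu on green recovers >= 99% of truth foreground", {
  sc <- generate_scene(20, age_day = 1, clump_fraction = 0, noise_level = 0,
                       seed = 5)
  thr <- otsu_threshold(sc$image$green)
  expect_gte(mean(sc$image$green[sc$truth$label_map > 0] > thr), 0.99)
})

test_that("aging: identity at same day, solidity drops, noise rises", {
  sc <- generate_scene(15, age_day = 1, clump_fraction = 0, noise_level = 40,
                       seed = 3, dim = c(800L, 800L))
  expect_identical(degrade_with_age(sc, 1, 1), sc)
  old <- degrade_with_age(sc, 1, 16)
  expect_error(degrade_with_age(sc, 4, 16), "not 4")
  hyp <- sc$truth$specs$nucleus_id[sc$truth$specs$tissue_class == "hypodermal"]
  sol <- function(s) mean(vapply(hyp, function(k)
    geometric_features(extract_region(s$truth$label_map, NULL, k))["solidity"],
    0))
  expect_lt(sol(old), sol(sc))
  expect_gt(stats::sd(old$image$green[old$truth$label_map == 0]),
            stats::sd(sc$image$green[sc$truth$label_map == 0]))
})

test_that("class-conditional feature separation (KS on 200 nuclei)", {
  specs <- do.call(rbind, lapply(1:5, function(s)
    test_scene(n = 40, clump = 0, noise = 60, seed = 40 + s)$truth$specs))
  area <- pi * specs$a * specs$b
  ellip <- 1 - specs$b / specs$a
  cl <- specs$tissue_class
  expect_gte(nrow(specs), 200 - 10)
  suppressWarnings({
    expect_lt(stats::ks.test(area[cl == "hypodermal"],
                             area[cl == "muscle"])$p.value, 0.01)
    expect_lt(stats::ks.test(area[cl == "intestinal"],
                             area[cl == "neuronal"])$p.value, 0.01)
    expect_lt(stats::ks.test(ellip[cl == "muscle"],
                             ellip[cl == "neuronal"])$p.value, 0.01)
  })
})

test_that("placement fails gracefully when the canvas is too small", {
  expect_error(generate_scene(150, age_day = 1, clump_fraction = 0,
                              noise_level = 0, seed = 1,
                              dim = c(120L, 120L)),
               "canvas too small")
})

test_that("write_scene round-trips rasters and classes", {
  sc <- generate_scene(3, age_day = 1, clump_fraction = 0, noise_level = 10,
                       seed = 2, dim = c(300L, 300L))
  stem <- file.path(withr::local_tempdir(), "scene")
  paths <- write_scene(sc, stem)
  expect_true(all(file.exists(paths)))
  expect_equal(read_tiff_gray(paths["g"]), sc$image$green)
  lm <- read_tiff_gray(paths["truth"])
  expect_equal(lm, sc$truth$label_map * 1.0)
  cc <- utils::read.csv(paths["classes"])
  expect_equal(cc$tissue_class, unname(sc$truth$classes))
})
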