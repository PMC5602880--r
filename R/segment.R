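#' Two-channel nucleus image container
#'
#' Pairs a green-channel raster (nuclear lamina, LMN-1::GFP-like) with a
#' red-channel raster (chromatin, HIS-72::mCherry-like) of identical shape,
#' together with the global intensity ceiling `P` (the maximal intensity over
#' the whole data set, used by the fusion formula). When `P` is not supplied
#' it falls back to the maximum over both channels of this image.
#'
#' @param green,red numeric matrices of gray levels, same shape.
#' @param P global maximal intensity of the data set (gray levels).
#' @param pixel_size physical pixel size in micrometres (metadata only).
#' @return an object of class `two_channel_image`.
#' @export
two_channel_image <- function(green, red, P = NULL, pixel_size = NA_real_) {
  stopifnot(is.matrix(green), is.matrix(red))
  if (!all(dim(green) == dim(red))) {
    stop("green and red channels must have identical dimensions")
  }
  if (any(green < 0) || any(red < 0)) stop("negative gray levels")
  if (is.null(P)) P <- max(green, red)
  if (P <= 0) stop("intensity ceiling P must be positive")
  structure(list(green = green, red = red, P = P, pixel_size = pixel_size),
            class = "two_channel_image")
}

#' @export
print.two_channel_image <- function(x, ...) {
  cat(sprintf("<two_channel_image> %d x %d px, P = %g\n",
              nrow(x$green), ncol(x$green), x$P))
  invisible(x)
}

#' Otsu's threshold
#'
#' Exhaustive maximization of the between-class variance over the intensity
#' histogram. For integer-valued images every integer level in the range is a
#' candidate cut; otherwise the range is binned into `nbins` equal-width bins.
#' A value `x` is assigned to the lower class iff `x <= threshold`.
#'
#' @param image numeric matrix or vector with at least two distinct values.
#' @param nbins number of histogram bins for non-integer data (default 256).
#' @return the threshold gray level, with attribute `"effectiveness"`
#'   (between-class variance over total variance at the optimum, in `[0,1]`).
#' @export
otsu_threshold <- function(image, nbins = 256L) {
  x <- as.numeric(image)
  rng <- range(x)
  if (rng[1] == rng[2]) stop("constant image: Otsu threshold undefined")
  integral <- all(x == round(x)) && diff(rng) <= 65535
  if (integral) {
    levels <- rng[1]:rng[2]
    counts <- tabulate(x - rng[1] + 1L, nbins = length(levels))
    mids <- levels
  } else {
    br <- seq(rng[1], rng[2], length.out = nbins + 1L)
    idx <- pmin(pmax(findInterval(x, br, rightmost.closed = TRUE), 1L), nbins)
    counts <- tabulate(idx, nbins = nbins)
    mids <- (br[-1] + br[-length(br)]) / 2
  }
  n <- sum(counts)
  w0 <- cumsum(counts) / n
  mu_t <- sum(counts * mids) / n
  mu0 <- cumsum(counts * mids) / n
  # between-class variance for cut after bin k (class0 = bins 1..k)
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, length(counts))
  sigma_b[valid] <- (mu_t * w0[valid] - mu0[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  k <- which.max(sigma_b)  # lowest optimal cut on ties
  thr <- mids[k]
  total_var <- sum(counts * (mids - mu_t)^2) / n
  structure(thr, effectiveness = unname(sigma_b[k] / total_var))
}

#' Fuse the green and red channels
#'
#' Implements the intensity fusion
#' \deqn{I_g \frac{P W_g}{P_g} + I_r I_b \frac{P W_r}{P_r}}
#' where \eqn{P_g, P_r} are the per-image channel maxima and \eqn{I_b} is the
#' global Otsu binarization of the green channel, acting as a filter kernel so
#' that the (noisier) red channel contributes only inside green foreground.
#'
#' @param img a [two_channel_image()].
#' @param w_g,w_r fusion weights (defaults 0.6 and 0.4).
#' @return list with `fused` (numeric matrix) and `I_b` (0/1 integer matrix).
#' @export
fuse_channels <- function(img, w_g = 0.6, w_r = 0.4) {
  stopifnot(inherits(img, "two_channel_image"), w_g >= 0, w_r >= 0)
  P_g <- max(img$green)
  if (P_g <= 0) stop("all-zero green channel: nothing to fuse")
  I_b <- matrix(as.integer(img$green > otsu_threshold(img$green)),
                nrow(img$green), ncol(img$green))
  fused <- img$green * (img$P * w_g / P_g)
  P_r <- max(img$red)
  if (P_r > 0 && w_r > 0) {
    fused <- fused + img$red * I_b * (img$P * w_r / P_r)
  }
  list(fused = fused, I_b = I_b)
}

#' Binarize a fused image (global Otsu with local fallback)
#'
#' Global Otsu is used when it passes a deterministic effectiveness check;
#' otherwise a per-pixel local threshold is computed from the surrounding
#' `window` x `window` region (edge windows clipped). Because a dense
#' per-pixel Otsu at window 701 is prohibitively slow, local thresholds are
#' computed on a coarse grid (stride `window %/% 4`) and bilinearly
#' interpolated; `exact = TRUE` forces the dense computation.
#'
#' The failure check declares global Otsu unusable when the foreground
#' fraction falls outside `fg_bounds` or the Otsu effectiveness metric
#' (between/total variance) is below `min_effectiveness`. A constant image
#' yields an empty mask.
#'
#' @param fused numeric matrix.
#' @param window odd local-window width in pixels (default 701).
#' @param fg_bounds admissible global foreground fraction (default
#'   `c(0.001, 0.40)`).
#' @param min_effectiveness minimal Otsu effectiveness (default 0.5).
#' @param force one of "auto", "global", "local".
#' @param exact logical; dense per-pixel local thresholding.
#' @return 0/1 integer matrix, with attribute `"mode"` ("global", "local" or
#'   "empty").
#' @export
binarize <- function(fused, window = 701L, fg_bounds = c(0.001, 0.40),
                     min_effectiveness = 0.5, force = c("auto", "global", "local"),
                     exact = FALSE) {
  force <- match.arg(force)
  stopifnot(window >= 3L, window %% 2L == 1L)
  if (min(fused) == max(fused)) {
    return(structure(matrix(0L, nrow(fused), ncol(fused)), mode = "empty"))
  }
  thr <- otsu_threshold(fused)
  mask <- matrix(as.integer(fused > thr), nrow(fused), ncol(fused))
  if (force != "local") {
    fg <- mean(mask)
    ok <- fg >= fg_bounds[1] && fg <= fg_bounds[2] &&
      attr(thr, "effectiveness") >= min_effectiveness
    if (force == "global" || ok) return(structure(mask, mode = "global"))
  }
  tsurf <- local_threshold_surface(fused, window, exact)
  # tolerance absorbs bilinear-interpolation rounding noise at exact ties
  eps <- 1e-7 * (abs(tsurf) + 1)
  structure(matrix(as.integer(fused - tsurf > eps),
                   nrow(fused), ncol(fused)),
            mode = "local")
}

# threshold surface for local (adaptive) Otsu
local_threshold_surface <- function(fused, window, exact = FALSE) {
  nr <- nrow(fused); nc <- ncol(fused)
  half <- window %/% 2L
  win_otsu <- function(i, j) {
    sub <- fused[max(1L, i - half):min(nr, i + half),
                 max(1L, j - half):min(nc, j + half)]
    if (min(sub) == max(sub)) NA_real_ else as.numeric(otsu_threshold(sub))
  }
  if (exact) {
    tsurf <- matrix(NA_real_, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) tsurf[i, j] <- win_otsu(i, j)
    tsurf[is.na(tsurf)] <- max(fused)  # constant window: nothing above it
    return(tsurf)
  }
  stride <- max(window %/% 4L, 1L)
  gi <- unique(pmin(seq(1L, nr + stride - 1L, by = stride), nr))
  gj <- unique(pmin(seq(1L, nc + stride - 1L, by = stride), nc))
  gv <- matrix(NA_real_, length(gi), length(gj))
  for (a in seq_along(gi)) for (b in seq_along(gj)) {
    gv[a, b] <- win_otsu(gi[a], gj[b])
  }
  if (all(is.na(gv))) return(matrix(max(fused), nr, nc))
  if (any(is.na(gv))) gv[is.na(gv)] <- mean(gv, na.rm = TRUE)
  bilinear_expand(gv, gi, gj, nr, nc)
}

# bilinear interpolation of grid values gv at rows gi / cols gj onto the full
# nr x nc raster (constant extrapolation beyond the grid hull)
bilinear_expand <- function(gv, gi, gj, nr, nc) {
  ri <- findInterval(seq_len(nr), gi, all.inside = TRUE)
  rj <- findInterval(seq_len(nc), gj, all.inside = TRUE)
  i0 <- gi[ri]; i1 <- gi[pmin(ri + 1L, length(gi))]
  j0 <- gj[rj]; j1 <- gj[pmin(rj + 1L, length(gj))]
  ti <- ifelse(i1 > i0, (seq_len(nr) - i0) / (i1 - i0), 0)
  tj <- ifelse(j1 > j0, (seq_len(nc) - j0) / (j1 - j0), 0)
  ti <- pmin(pmax(ti, 0), 1); tj <- pmin(pmax(tj, 0), 1)
  A <- gv[ri, rj, drop = FALSE]
  B <- gv[pmin(ri + 1L, length(gi)), rj, drop = FALSE]
  C <- gv[ri, pmin(rj + 1L, length(gj)), drop = FALSE]
  D <- gv[pmin(ri + 1L, length(gi)), pmin(rj + 1L, length(gj)), drop = FALSE]
  Ti <- matrix(ti, nr, nc)
  Tj <- matrix(tj, nr, nc, byrow = TRUE)
  A * (1 - Ti) * (1 - Tj) + B * Ti * (1 - Tj) + C * (1 - Ti) * Tj + D * Ti * Tj
}

#' Detect nucleus seeds on a distance map
#'
#' Gaussian-smooths the distance map and returns its strict local maxima over
#' the 8-neighbourhood (plateaus resolved to their centroid) restricted to the
#' foreground, each with its smoothed distance value.
#'
#' @param D distance map from [distance_map()].
#' @param sigma Gaussian smoothing sd in pixels (default 2).
#' @return a `data.frame` with columns `row`, `col` (1-based) and `value`
#'   (smoothed distance), ordered by row then column; attribute
#'   `"smoothed"` carries the smoothed map for downstream mergence.
#' @export
detect_seeds <- function(D, sigma = 2) {
  stopifnot(sigma >= 0)
  Ds <- gaussian_blur(D, sigma)
  fg <- D > 0
  if (!any(fg)) {
    return(structure(data.frame(row = integer(0), col = integer(0),
                                value = numeric(0)), smoothed = Ds))
  }
  mx <- local_maxima(Ds, fg)
  structure(data.frame(row = mx[, 1], col = mx[, 2],
                       value = Ds[mx]), smoothed = Ds)
}

#' Merge seeds belonging to one nucleus
#'
#' For a pair of seeds, let `m` be the lower of their distance values and `n`
#' the minimum of the distance map along the straight (Bresenham) line between
#' them. If `n > m * r` the pair is replaced by a single seed at their
#' midpoint (distance value re-read from the map). Pairs are examined nearest
#' first and the rule is iterated to a fixpoint.
#'
#' @param seeds seed `data.frame` from [detect_seeds()].
#' @param D distance map on which `m` and `n` are measured (use the smoothed
#'   map for consistency with seed detection).
#' @param r mergence ratio in (0, 1]; default 0.928 (close to the ratio of
#'   lowest to highest nuclear intensity in the original data set).
#' @return merged seed `data.frame` (columns `row`, `col`, `value`).
#' @export
merge_seeds <- function(seeds, D, r = 0.928) {
  stopifnot(r > 0, r <= 1)
  s <- as.data.frame(seeds)[, c("row", "col", "value")]
  repeat {
    k <- nrow(s)
    if (k < 2L) break
    pr <- t(utils::combn(k, 2L))
    d2 <- (s$row[pr[, 1]] - s$row[pr[, 2]])^2 +
      (s$col[pr[, 1]] - s$col[pr[, 2]])^2
    pr <- pr[order(d2), , drop = FALSE]
    merged <- FALSE
    for (q in seq_len(nrow(pr))) {
      a <- pr[q, 1]; b <- pr[q, 2]
      m <- min(s$value[a], s$value[b])
      line <- bresenham_line(c(s$row[a] - 1L, s$col[a] - 1L),
                             c(s$row[b] - 1L, s$col[b] - 1L))
      n <- min(D[line])
      if (n > m * r) {
        mid <- round(c((s$row[a] + s$row[b]) / 2, (s$col[a] + s$col[b]) / 2))
        s <- s[-c(a, b), , drop = FALSE]
        s <- rbind(s, data.frame(row = mid[1], col = mid[2],
                                 value = D[mid[1], mid[2]]))
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  rownames(s) <- NULL
  s[order(s$row, s$col), , drop = FALSE]
}

#' Split clustered nuclei by seeded watershed
#'
#' Computes the watershed transform of the negated distance map with the seed
#' pixels forced to negative infinity, restricted to the foreground mask. The
#' number of regions equals the number of seeds and each region contains its
#' seed.
#'
#' @param mask binary foreground mask.
#' @param seeds seed `data.frame` (columns `row`, `col`).
#' @param D distance map used for flooding order.
#' @return integer label map (0 background; labels 1..k in seed order).
#' @export
split_clusters <- function(mask, seeds, D) {
  mask <- as_binary(mask)
  if (nrow(seeds) == 0L) return(matrix(0L, nrow(mask), ncol(mask)))
  if (anyDuplicated(seeds[, c("row", "col")])) {
    stop("duplicate seed locations")
  }
  rc <- cbind(as.integer(seeds$row - 1L), as.integer(seeds$col - 1L))
  .cpp_watershed(D, mask, rc, seq_len(nrow(rc)))
}

#' Remove small and dark regions
#'
#' Excludes labelled regions whose pixel area is below `min_area` or whose
#' mean fused intensity is below `min_mean_intensity`; surviving labels are
#' renumbered consecutively from 1 preserving order.
#'
#' @param labels integer label map.
#' @param fused fused intensity image.
#' @param min_area minimal area in px^2 (default 80).
#' @param min_mean_intensity minimal mean fused intensity; default half the
#'   global Otsu threshold of the fused image.
#' @return filtered label map.
#' @export
filter_regions <- function(labels, fused, min_area = 80,
                           min_mean_intensity = NULL) {
  if (is.null(min_mean_intensity)) {
    min_mean_intensity <-
      if (min(fused) == max(fused)) 0 else 0.5 * otsu_threshold(fused)
  }
  k <- max(labels)
  if (k == 0L) return(labels)
  idx <- labels[labels > 0L]
  area <- tabulate(idx, nbins = k)
  msum <- vapply(split(fused[labels > 0L], idx), sum, 0)
  mmean <- rep(0, k)
  mmean[as.integer(names(msum))] <- msum / area[as.integer(names(msum))]
  keep <- which(area >= min_area & mmean >= min_mean_intensity)
  relabel_map(labels, keep)
}

# keep only the given labels, renumbering consecutively in their sorted order
relabel_map <- function(labels, keep) {
  lut <- integer(max(labels, 1L))
  lut[keep] <- seq_along(keep)
  out <- labels
  pos <- labels > 0L
  out[pos] <- lut[labels[pos]]
  out
}

#' Rough segmentation of a two-channel image
#'
#' Chains fusion, binarization, distance transform, seed detection, seed
#' mergence, watershed splitting and region filtering into the rough label
#' map (boundary refinement is [refine_all()]).
#'
#' @param img a [two_channel_image()].
#' @param config parameter list, see [default_config()].
#' @return list with `fused`, `I_b`, `binary`, `D`, `D_smooth`, `seeds_raw`,
#'   `seeds`, `labels`.
#' @export
segment_image <- function(img, config = default_config()) {
  cf <- utils::modifyList(default_config(), config)
  fz <- fuse_channels(img, cf$w_g, cf$w_r)
  binary <- binarize(fz$fused, cf$local_window, force = cf$threshold_mode)
  if (!any(binary == 1L)) {
    lab <- matrix(0L, nrow(binary), ncol(binary))
    return(list(fused = fz$fused, I_b = fz$I_b, binary = binary,
                D = binary * 0, D_smooth = binary * 0,
                seeds_raw = data.frame(), seeds = data.frame(), labels = lab))
  }
  D <- distance_map(binary)
  seeds_raw <- detect_seeds(D, cf$sigma)
  Ds <- attr(seeds_raw, "smoothed")
  seeds <- merge_seeds(seeds_raw, Ds, cf$r)
  labels <- split_clusters(binary, seeds, D)
  labels <- filter_regions(labels, fz$fused, cf$min_area,
                           cf$min_mean_intensity)
  list(fused = fz$fused, I_b = fz$I_b, binary = binary, D = D, D_smooth = Ds,
       seeds_raw = as.data.frame(seeds_raw), seeds = seeds, labels = labels)
}

#' Default pipeline configuration
#'
#' All numeric parameters of the segmentation/refinement pipeline with their
#' published defaults: fusion weights 0.6/0.4, local window 701 px, seed
#' smoothing sigma 2 px, mergence ratio r = 0.928, refinement weight w2 = 0.4,
#' GLCM offset 7, rejection threshold 0.90.
#'
#' @return named list of parameters.
#' @export
default_config <- function() {
  list(
    w_g = 0.6, w_r = 0.4,
    local_window = 701L, threshold_mode = "auto",
    sigma = 2, r = 0.928,
    min_area = 80, min_mean_intensity = NULL,
    w2 = 0.4, margin = NULL,
    glcm_offset = 7L, glcm_levels = 32L,
    probability_threshold = 0.90,
    cv_folds = 3L
  )
}
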