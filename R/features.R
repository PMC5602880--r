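# Per-nucleus feature battery: 9 geometric + 4 intensity per channel + 4 GLCM
# statistics x 4 directions per channel = 49 canonical features.

#' Canonical feature names
#'
#' The frozen 49-column feature layout: 9 geometric, 4 intensity per channel,
#' and contrast/correlation/energy/homogeneity of the GLCM at 0/45/90/135
#' degrees per channel.
#'
#' @return character vector of length 49.
#' @export
feature_names <- function() {
  geo <- c("area", "perimeter", "circularity", "ellipticity", "solidity",
           "curv_max", "curv_min", "curv_sd", "curv_mean")
  intens <- as.vector(outer(c("g", "r"), c("mean", "var", "skew", "kurt"),
                            function(a, b) paste(a, b, sep = "_")))
  tex <- as.vector(outer(
    c("g", "r"),
    as.vector(outer(c("contrast", "correlation", "energy", "homogeneity"),
                    c(0, 45, 90, 135),
                    function(a, b) paste0("glcm_", a, "_", b))),
    function(a, b) paste(a, b, sep = "_")))
  c(geo, sort(intens), sort(tex))
}

#' Extract one nucleus region
#'
#' @param labels label map.
#' @param img a [two_channel_image()] (or `NULL` for mask-only geometry).
#' @param nucleus_id label id.
#' @return object of class `nucleus_region`: `nucleus_id`, `mask` (cropped),
#'   `offset` (top-left of the crop in image coordinates), `boundary` (ordered
#'   closed contour as a 2-column row/col matrix in cropped coordinates,
#'   counter-clockwise from the topmost-leftmost boundary pixel),
#'   `green_pixels`, `red_pixels`, `N`.
#' @export
extract_region <- function(labels, img = NULL, nucleus_id) {
  pix <- which(labels == nucleus_id, arr.ind = TRUE)
  if (nrow(pix) == 0L) stop("nucleus id ", nucleus_id, " not in label map")
  r0 <- min(pix[, 1]); c0 <- min(pix[, 2])
  mask <- matrix(0L, max(pix[, 1]) - r0 + 1L, max(pix[, 2]) - c0 + 1L)
  mask[cbind(pix[, 1] - r0 + 1L, pix[, 2] - c0 + 1L)] <- 1L
  boundary <- .cpp_trace_contour(mask) + 1L  # 1-based cropped coords
  # orient counter-clockwise in (x = col, y = -row)
  if (nrow(boundary) >= 3L) {
    x <- boundary[, 2]; y <- -boundary[, 1]
    a2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
    if (a2 < 0) {
      boundary <- boundary[c(1L, nrow(boundary):2L), , drop = FALSE]
    }
  }
  gp <- rp <- NULL
  if (!is.null(img)) {
    gp <- img$green[labels == nucleus_id]
    rp <- img$red[labels == nucleus_id]
  }
  structure(list(nucleus_id = nucleus_id, mask = mask,
                 offset = c(row = r0, col = c0), boundary = boundary,
                 green_pixels = gp, red_pixels = rp, N = nrow(pix)),
            class = "nucleus_region")
}

#' Geometric features of a nucleus
#'
#' Area `A` (contour plus enclosed pixels), perimeter `P` (digital arc length
#' of the traced contour: unit steps count 1, diagonal steps sqrt(2)),
#' circularity `4*pi*A/P^2`, ellipticity `1 - b/a` from the minimum-area
#' enclosing rectangle (rotating calipers over the convex hull of the pixel
#' corners), solidity `A/A_c` with the convex area `A_c` counted in pixels,
#' and curvature statistics: the curvature at each boundary point is the
#' inverse radius of the circle through that point and the two points 10
#' boundary positions away (cyclic), signed by turning direction; features are
#' the signed max, signed min, sd, and the mean absolute curvature.
#'
#' Contours shorter than 21 points use spacing `floor((len-1)/2)` and are
#' flagged low quality (attribute `"flags"`).
#'
#' @param region a [extract_region()] result.
#' @return named numeric vector of the 9 geometric features.
#' @export
geometric_features <- function(region) {
  stopifnot(inherits(region, "nucleus_region"))
  if (region$N == 0L) stop("empty region")
  bnd <- region$boundary
  A <- region$N
  P <- contour_arc_length(bnd)
  flags <- character(0)
  if (P <= 0) {  # single-pixel region
    out <- c(area = A, perimeter = 0, circularity = NA, ellipticity = NA,
             solidity = 1, curv_max = NA, curv_min = NA, curv_sd = NA,
             curv_mean = NA)
    return(structure(out, flags = "degenerate_contour"))
  }
  circ <- 4 * pi * A / P^2
  corners <- pixel_corners(bnd)
  hull <- corners[grDevices::chull(corners[, 1], corners[, 2]), , drop = FALSE]
  rect <- min_area_rect(hull)
  ellip <- 1 - rect["b"] / rect["a"]
  # convex area in pixels: pixel centers within the hull of the boundary
  # pixel centers (corner hull would add a half-pixel ring)
  ctr <- cbind(x = bnd[, 2], y = bnd[, 1])
  chull_ctr <- ctr[grDevices::chull(ctr[, 1], ctr[, 2]), , drop = FALSE]
  Ac <- convex_pixel_count(chull_ctr, dim(region$mask))
  solidity <- min(1, A / Ac)
  spacing <- if (nrow(bnd) >= 21L) 10L else max(1L, (nrow(bnd) - 1L) %/% 2L)
  if (nrow(bnd) < 21L) flags <- c(flags, "short_contour")
  kappa <- boundary_curvature(bnd, spacing)
  out <- c(area = A, perimeter = P, circularity = circ,
           ellipticity = unname(ellip), solidity = solidity,
           curv_max = max(kappa), curv_min = min(kappa),
           curv_sd = stats::sd(kappa), curv_mean = mean(abs(kappa)))
  structure(out, flags = flags)
}

# digital arc length of a closed contour: 1 per axial step, sqrt(2) diagonal
contour_arc_length <- function(bnd) {
  n <- nrow(bnd)
  if (n < 2L) return(0)
  nxt <- rbind(bnd[-1, , drop = FALSE], bnd[1, , drop = FALSE])
  step <- pmax(abs(nxt[, 1] - bnd[, 1]), abs(nxt[, 2] - bnd[, 2]))
  diag <- (abs(nxt[, 1] - bnd[, 1]) == 1) & (abs(nxt[, 2] - bnd[, 2]) == 1)
  sum(ifelse(diag, sqrt(2), step))
}

# the 4 corners of each boundary pixel in (x = col, y = row) coordinates
pixel_corners <- function(bnd) {
  x <- bnd[, 2]; y <- bnd[, 1]
  cbind(x = c(x - 0.5, x + 0.5, x - 0.5, x + 0.5),
        y = c(y - 0.5, y - 0.5, y + 0.5, y + 0.5))
}

# minimum-area enclosing rectangle by rotating calipers over hull vertices;
# returns c(a = long side, b = short side)
min_area_rect <- function(hull) {
  n <- nrow(hull)
  if (n == 1L) return(c(a = 0, b = 0))
  best <- c(Inf, 0, 0)
  for (e in seq_len(n)) {
    p <- hull[e, ]; q <- hull[if (e == n) 1L else e + 1L, ]
    d <- q - p
    len <- sqrt(sum(d^2))
    if (len == 0) next
    u <- d / len
    v <- c(-u[2], u[1])
    pu <- hull %*% u
    pv <- hull %*% v
    du <- max(pu) - min(pu); dv <- max(pv) - min(pv)
    if (du * dv < best[1]) best <- c(du * dv, du, dv)
  }
  c(a = max(best[2], best[3]), b = min(best[2], best[3]))
}

# number of pixel centers inside (or on) a convex polygon, scanning the mask's
# bounding box
convex_pixel_count <- function(hull, dims) {
  n <- nrow(hull)
  if (n < 3L) return(max(1L, n))
  # ensure counter-clockwise orientation in (x, y)
  a2 <- sum(hull[, 1] * c(hull[-1, 2], hull[1, 2]) -
              c(hull[-1, 1], hull[1, 1]) * hull[, 2])
  if (a2 < 0) hull <- hull[n:1, , drop = FALSE]
  xs <- matrix(rep(seq_len(dims[2]), each = dims[1]), dims[1], dims[2])
  ys <- matrix(rep(seq_len(dims[1]), dims[2]), dims[1], dims[2])
  inside <- matrix(TRUE, dims[1], dims[2])
  eps <- 1e-9
  for (e in seq_len(n)) {
    p <- hull[e, ]; q <- hull[if (e == n) 1L else e + 1L, ]
    cr <- (q[1] - p[1]) * (ys - p[2]) - (q[2] - p[2]) * (xs - p[1])
    inside <- inside & (cr >= -eps)
  }
  sum(inside)
}

# signed curvature at every boundary point from the circumscribed circle of
# (i - spacing, i, i + spacing), cyclic; collinear -> 0
boundary_curvature <- function(bnd, spacing) {
  n <- nrow(bnd)
  if (n < 3L) return(0)
  idx <- seq_len(n)
  im <- ((idx - 1L - spacing) %% n) + 1L
  ip <- ((idx - 1L + spacing) %% n) + 1L
  # (x, y) with y = -row so the sign convention matches counter-clockwise
  x1 <- bnd[im, 2]; y1 <- -bnd[im, 1]
  x2 <- bnd[idx, 2]; y2 <- -bnd[idx, 1]
  x3 <- bnd[ip, 2]; y3 <- -bnd[ip, 1]
  # twice signed triangle area
  cr <- (x2 - x1) * (y3 - y2) - (y2 - y1) * (x3 - x2)
  a <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  b <- sqrt((x3 - x2)^2 + (y3 - y2)^2)
  cc <- sqrt((x3 - x1)^2 + (y3 - y1)^2)
  den <- a * b * cc
  kappa <- ifelse(den > 0, 2 * cr / den, 0)
  kappa
}

#' Intensity features of a nucleus
#'
#' Mean, variance, skewness and kurtosis of the pixel intensities within the
#' mask, with the `1/(N-1)` denominator of all three central-moment formulas
#' as printed in the source feature table (not the textbook `1/N`). `sigma`
#' is the sample standard deviation. Zero variance flags skewness/kurtosis as
#' undefined (stored 0, attribute `"flags"`).
#'
#' @param region a [extract_region()] result (with image pixels).
#' @param channel "green" or "red".
#' @return named numeric vector `<ch>_mean`, `<ch>_var`, `<ch>_skew`,
#'   `<ch>_kurt` (prefix `g_` or `r_`).
#' @export
intensity_features <- function(region, channel = c("green", "red")) {
  channel <- match.arg(channel)
  x <- if (channel == "green") region$green_pixels else region$red_pixels
  if (is.null(x)) stop("region extracted without image pixels")
  N <- length(x)
  if (N < 2L) stop("need at least 2 pixels for intensity moments")
  m <- mean(x)
  v <- sum((x - m)^2) / (N - 1)
  s <- sqrt(v)
  flags <- character(0)
  if (s == 0) {
    sk <- 0; ku <- 0
    flags <- "zero_variance"
  } else {
    sk <- sum(((x - m) / s)^3) / (N - 1)
    ku <- sum(((x - m) / s)^4) / (N - 1)
  }
  pre <- if (channel == "green") "g" else "r"
  out <- c(m, v, sk, ku)
  names(out) <- paste(pre, c("mean", "var", "skew", "kurt"), sep = "_")
  structure(out, flags = flags)
}

#' GLCM specification
#'
#' @param offset pixel offset (default 7, the mean nuclear texture scale).
#' @param levels number of equal-width quantization bins (default 32).
#' @param symmetric count each pair in both orders (default TRUE).
#' @param normalized divide by the total count (default TRUE).
#' @return list of class `glcm_spec`.
#' @export
glcm_spec <- function(offset = 7L, levels = 32L, symmetric = TRUE,
                      normalized = TRUE) {
  stopifnot(offset >= 1L, levels >= 2L)
  structure(list(offset = as.integer(offset), levels = as.integer(levels),
                 directions = c(0, 45, 90, 135),
                 symmetric = symmetric, normalized = normalized),
            class = "glcm_spec")
}

#' Gray-level co-occurrence matrix of a nucleus region
#'
#' Counts pairs of quantized intensities at the spec's offset along one
#' direction; only pairs with both pixels inside the mask are counted.
#' Quantization: `levels` equal-width bins over the region's min-max range.
#' Directions follow the usual image convention: 0 = east, 45 = north-east,
#' 90 = north, 135 = north-west (rows grow downward).
#'
#' @param region a [extract_region()] result.
#' @param channel "green" or "red".
#' @param spec a [glcm_spec()].
#' @param direction one of 0, 45, 90, 135 (degrees).
#' @return `levels x levels` matrix (normalized if requested), or `NULL` when
#'   the region admits no valid pixel pair at this offset.
#' @export
glcm <- function(region, channel = c("green", "red"), spec = glcm_spec(),
                 direction = 0) {
  channel <- match.arg(channel)
  stopifnot(direction %in% spec$directions)
  vals <- if (channel == "green") region$green_pixels else region$red_pixels
  if (is.null(vals)) stop("region extracted without image pixels")
  mask <- region$mask
  q <- matrix(NA_integer_, nrow(mask), ncol(mask))
  q[mask == 1L] <- quantize_levels(vals, spec$levels)
  o <- spec$offset
  shift <- switch(as.character(direction),
                  "0" = c(0L, o), "45" = c(-o, o),
                  "90" = c(-o, 0L), "135" = c(-o, -o))
  C <- glcm_accumulate(q, shift, spec$levels, spec$symmetric)
  if (sum(C) == 0) return(NULL)
  if (spec$normalized) C <- C / sum(C)
  C
}

quantize_levels <- function(vals, levels) {
  rng <- range(vals)
  if (rng[1] == rng[2]) return(rep(1L, length(vals)))
  idx <- floor((vals - rng[1]) / (rng[2] - rng[1]) * levels) + 1L
  pmin(idx, levels)
}

# co-occurrence counts of quantized raster q (NA outside mask) at a shift
glcm_accumulate <- function(q, shift, levels, symmetric) {
  nr <- nrow(q); nc <- ncol(q)
  dr <- shift[1]; dc <- shift[2]
  C <- matrix(0, levels, levels)
  if (nr - abs(dr) < 1L || nc - abs(dc) < 1L) return(C)
  r1 <- max(1L, 1L - dr):min(nr, nr - dr)
  c1 <- max(1L, 1L - dc):min(nc, nc - dc)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(C)
  tab <- table(factor(a[ok], levels = seq_len(levels)),
               factor(b[ok], levels = seq_len(levels)))
  C <- C + unclass(tab)
  if (symmetric) C <- C + t(C)
  unname(C)
}

#' Haralick statistics of a normalized GLCM
#'
#' Contrast `sum |i-j|^2 p(i,j)`, correlation
#' `sum (i-mu_i)(j-mu_j) p(i,j) / (sigma_i sigma_j)` with `mu`/`sigma` the
#' mean/sd of the row and column marginals, energy `sum p^2`, homogeneity
#' `sum p/(1+|i-j|)`.
#'
#' @param C normalized co-occurrence matrix (or `NULL`).
#' @return named vector `contrast`, `correlation`, `energy`, `homogeneity`
#'   (all `NA` with flag when `C` is `NULL`; correlation `NA`-flagged when a
#'   marginal sd is 0).
#' @export
glcm_features <- function(C) {
  if (is.null(C)) {
    return(structure(c(contrast = NA_real_, correlation = NA_real_,
                       energy = NA_real_, homogeneity = NA_real_),
                     flags = "no_valid_pairs"))
  }
  L <- nrow(C)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  pi_ <- rowSums(C); pj_ <- colSums(C)
  mu_i <- sum(seq_len(L) * pi_); mu_j <- sum(seq_len(L) * pj_)
  s_i <- sqrt(sum((seq_len(L) - mu_i)^2 * pi_))
  s_j <- sqrt(sum((seq_len(L) - mu_j)^2 * pj_))
  flags <- character(0)
  corr <- if (s_i * s_j > 0) {
    sum((i - mu_i) * (j - mu_j) * C) / (s_i * s_j)
  } else {
    flags <- "zero_marginal_sd"
    NA_real_
  }
  structure(c(contrast = sum(abs(i - j)^2 * C),
              correlation = corr,
              energy = sum(C^2),
              homogeneity = sum(C / (1 + abs(i - j)))),
            flags = flags)
}

#' Feature table of a labelled image
#'
#' One row per nucleus with the canonical 49-feature layout (see
#' [feature_names()]) plus `nucleus_id`. Undefined entries are `NA` in the
#' table and marked in the logical flag table stored as attribute `"flags"`.
#'
#' @param labels label map.
#' @param img a [two_channel_image()].
#' @param spec a [glcm_spec()].
#' @param classes optional named vector mapping nucleus id to tissue class;
#'   adds a `tissue_class` column.
#' @return data.frame of class `feature_table`.
#' @export
feature_table <- function(labels, img, spec = glcm_spec(), classes = NULL) {
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  nm <- feature_names()
  out <- as.data.frame(matrix(NA_real_, length(ids), length(nm),
                              dimnames = list(NULL, nm)))
  flg <- as.data.frame(matrix(FALSE, length(ids), length(nm),
                              dimnames = list(NULL, nm)))
  for (k in seq_along(ids)) {
    reg <- extract_region(labels, img, ids[k])
    geo <- geometric_features(reg)
    out[k, names(geo)] <- geo
    if (length(attr(geo, "flags"))) flg[k, names(geo)] <- is.na(geo)
    for (ch in c("green", "red")) {
      iv <- intensity_features(reg, ch)
      out[k, names(iv)] <- iv
      if (length(attr(iv, "flags"))) {
        flg[k, paste(substr(ch, 1, 1), c("skew", "kurt"), sep = "_")] <- TRUE
      }
      for (d in spec$directions) {
        gf <- glcm_features(glcm(reg, ch, spec, d))
        cols <- paste(substr(ch, 1, 1),
                      paste0("glcm_", names(gf), "_", d), sep = "_")
        out[k, cols] <- gf
        flg[k, cols] <- is.na(gf)
      }
    }
  }
  out <- cbind(nucleus_id = ids, out)
  if (!is.null(classes)) {
    out$tissue_class <- unname(classes[as.character(ids)])
  }
  structure(out, flags = flg, class = c("feature_table", "data.frame"))
}
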