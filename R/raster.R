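#' @useDynLib wormnuc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Exact Euclidean distance transform
#'
#' Distance of every foreground pixel to the nearest zero pixel of the mask
#' (exact, via the lower-envelope-of-parabolas algorithm). Background pixels
#' map to 0.
#'
#' @param mask binary matrix (0 = background, nonzero = foreground).
#' @return numeric matrix of distances, same shape as `mask`.
#' @export
distance_map <- function(mask) {
  mask <- as_binary(mask)
  if (all(mask == 1L)) {
    stop("mask contains no zero pixel: distance to nearest zero is undefined")
  }
  .cpp_edt(mask)
}

#' Label connected components
#'
#' @param mask binary matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer matrix; 0 background, components numbered 1..k in
#'   raster-scan discovery order.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  .cpp_label(as_binary(mask), as.integer(connectivity))
}

#' Gaussian blur
#'
#' Separable Gaussian convolution with reflected borders; `sigma = 0` returns
#' the input unchanged.
#'
#' @param img numeric matrix.
#' @param sigma standard deviation in pixels.
#' @return blurred matrix.
#' @export
gaussian_blur <- function(img, sigma) {
  stopifnot(is.matrix(img), sigma >= 0)
  .cpp_gauss_blur(img, sigma)
}

# coerce to an integer 0/1 matrix
as_binary <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  m
}

# fill holes of a binary mask: background components not touching the border
# are interior holes
fill_holes <- function(mask) {
  mask <- as_binary(mask)
  bg <- .cpp_label(1L - mask, 4L)
  if (max(bg) == 0L) return(mask)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  hole <- bg > 0L & !(bg %in% border)
  mask[hole] <- 1L
  mask
}

#' Binary dilation by a disk
#'
#' Euclidean dilation: every background pixel within distance `r` of the mask
#' becomes foreground.
#'
#' @param mask binary matrix.
#' @param r radius in pixels.
#' @return dilated 0/1 integer matrix.
#' @export
dilate_disk <- function(mask, r) {
  mask <- as_binary(mask)
  if (r <= 0) return(mask)
  d <- .cpp_edt(1L - mask)  # distance from background pixels to the mask
  as_binary(mask == 1L | (d > 0 & d <= r))
}

# pixels of the Bresenham segment between two 0-based (row, col) points,
# returned as a 2-column 1-based index matrix
bresenham_line <- function(p, q) {
  x0 <- p[2]; y0 <- p[1]; x1 <- q[2]; y1 <- q[1]
  dx <- abs(x1 - x0); dy <- -abs(y1 - y0)
  sx <- ifelse(x0 < x1, 1, -1); sy <- ifelse(y0 < y1, 1, -1)
  err <- dx + dy
  pts <- matrix(0L, dx - dy + 1L, 2L)
  n <- 0L
  repeat {
    n <- n + 1L
    pts[n, ] <- c(y0, x0)
    if (x0 == x1 && y0 == y1) break
    e2 <- 2 * err
    if (e2 >= dy) { err <- err + dy; x0 <- x0 + sx }
    if (e2 <= dx) { err <- err + dx; y0 <- y0 + sy }
  }
  pts[seq_len(n), , drop = FALSE] + 1L
}

# strict local maxima of a matrix over the 8-neighbourhood, with plateaus
# resolved to their centroid pixel. Returns a 2-col matrix of 1-based (row,
# col). Only pixels where `fg` is TRUE are considered.
local_maxima <- function(img, fg = NULL) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- img
  ge_all <- matrix(TRUE, nr, nc)
  eq_any <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc, drop = FALSE]
    ge_all <- ge_all & (img >= nb)
    eq_any <- eq_any | (img == nb)
  }
  cand <- ge_all
  if (!is.null(fg)) cand <- cand & fg
  if (!any(cand)) return(matrix(integer(0), 0L, 2L))
  strict <- cand & !eq_any
  out <- which(strict, arr.ind = TRUE)
  # plateau candidates: local max but tied with a neighbour
  plat <- cand & eq_any
  if (any(plat)) {
    lab <- .cpp_label(matrix(as.integer(plat), nr, nc), 8L)
    for (k in seq_len(max(lab))) {
      idx <- which(lab == k, arr.ind = TRUE)
      # a plateau counts only if no neighbour of the plateau exceeds it
      # (guaranteed by ge_all on each member), take the centroid snapped to
      # the nearest member pixel
      ctr <- colMeans(idx)
      d2 <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2
      out <- rbind(out, idx[which.min(d2), , drop = FALSE])
    }
  }
  colnames(out) <- c("row", "col")
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}
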