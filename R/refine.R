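# Precise segmentation: per-nucleus boundary refinement by 2-means clustering
# of window pixels in a two-dimensional space (I = weighted fused intensity,
# B = weighted rough-mask membership). Pixels outside the rough mask are
# replaced by a flat background at the mean intensity of the rough boundary,
# so the clustering separates "nucleus-like" from "boundary-like" pixels.

#' Build the refinement window of one nucleus
#'
#' The window is the bounding box of the rough region dilated by `margin`
#' (clipped to the image). Inside it, the composite image keeps the fused
#' values on the rough mask and replaces everything else by the mean fused
#' intensity of the rough boundary pixels.
#'
#' @param fused fused intensity image.
#' @param labels rough label map.
#' @param nucleus_id label to refine.
#' @param margin window margin in px; default 25% of the region's bounding-box
#'   diagonal, at least 5 px.
#' @return list of class `nucleus_window`: `bounds` (r0, r1, c0, c1),
#'   `composite`, `rough_mask`, `boundary_mean`, `nucleus_id`.
#' @export
build_window <- function(fused, labels, nucleus_id, margin = NULL) {
  pix <- which(labels == nucleus_id, arr.ind = TRUE)
  if (nrow(pix) == 0L) stop("nucleus id ", nucleus_id, " not in label map")
  r0 <- min(pix[, 1]); r1 <- max(pix[, 1])
  c0 <- min(pix[, 2]); c1 <- max(pix[, 2])
  if (is.null(margin)) {
    margin <- max(5, round(0.25 * sqrt((r1 - r0 + 1)^2 + (c1 - c0 + 1)^2)))
  }
  r0 <- max(1L, r0 - margin); r1 <- min(nrow(fused), r1 + margin)
  c0 <- max(1L, c0 - margin); c1 <- min(ncol(fused), c1 + margin)
  sub_f <- fused[r0:r1, c0:c1, drop = FALSE]
  rough <- matrix(as.integer(labels[r0:r1, c0:c1, drop = FALSE] ==
                               nucleus_id), nrow(sub_f), ncol(sub_f))
  bnd <- boundary_pixels(rough)
  boundary_mean <- mean(sub_f[bnd == 1L])
  composite <- sub_f
  composite[rough == 0L] <- boundary_mean
  structure(list(bounds = c(r0 = r0, r1 = r1, c0 = c0, c1 = c1),
                 composite = composite, rough_mask = rough,
                 boundary_mean = boundary_mean, nucleus_id = nucleus_id),
            class = "nucleus_window")
}

# inner boundary of a binary mask: foreground pixels 4-adjacent to background
boundary_pixels <- function(mask) {
  mask <- as_binary(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  core <- pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  matrix(as.integer(mask == 1L & !core), nr, nc)
}

#' Refine one nucleus boundary by 2-means
#'
#' Each window pixel is mapped to the point `(I, B)` with
#' `I = composite * w1` (w1 = reciprocal of the window's maximal composite
#' value) and `B = rough_mask * w2`. The two k-means centers are initialized
#' deterministically at the feature means of rough-foreground and
#' rough-background pixels; the cluster with the higher mean `B` is
#' foreground. The returned mask is the largest connected foreground
#' component with holes filled. Degenerate windows (all pixels identical in
#' `(I, B)`) and refinements that would empty the region fall back to the
#' rough mask.
#'
#' @param window a `nucleus_window` from [build_window()].
#' @param w2 rough-membership weight (default 0.4).
#' @return refined 0/1 mask over the window.
#' @export
refine_boundary <- function(window, w2 = 0.4) {
  stopifnot(inherits(window, "nucleus_window"), w2 >= 0)
  comp <- window$composite
  rough <- window$rough_mask
  mx <- max(comp)
  if (mx <= 0) return(rough)
  w1 <- 1 / mx
  I <- as.vector(comp) * w1
  B <- as.vector(rough) * w2
  X <- cbind(I, B)
  if (all(rough == 1L) || all(rough == 0L)) return(rough)
  c_fg <- colMeans(X[rough == 1L, , drop = FALSE])
  c_bg <- colMeans(X[rough == 0L, , drop = FALSE])
  if (sum((c_fg - c_bg)^2) < 1e-24) return(rough)
  km <- two_means(X, rbind(c_fg, c_bg))
  fg_cluster <- which.max(c(mean(B[km == 1L]), mean(B[km == 2L])))
  ref <- matrix(as.integer(km == fg_cluster), nrow(comp), ncol(comp))
  if (!any(ref == 1L)) return(rough)
  lab <- label_components(ref, 8L)
  sizes <- tabulate(lab[lab > 0L])
  ref <- matrix(as.integer(lab == which.max(sizes)), nrow(ref), ncol(ref))
  fill_holes(ref)
}

# deterministic 2-means (Lloyd) with fixed initial centers; the objective is
# non-increasing, so iteration to a fixpoint terminates
two_means <- function(X, centers, max_iter = 100L) {
  assign <- rep(1L, nrow(X))
  for (it in seq_len(max_iter)) {
    d1 <- (X[, 1] - centers[1, 1])^2 + (X[, 2] - centers[1, 2])^2
    d2 <- (X[, 1] - centers[2, 1])^2 + (X[, 2] - centers[2, 2])^2
    new_assign <- ifelse(d2 < d1, 2L, 1L)  # ties to cluster 1
    if (it > 1L && all(new_assign == assign)) break
    assign <- new_assign
    if (!any(assign == 1L) || !any(assign == 2L)) break
    centers[1, ] <- colMeans(X[assign == 1L, , drop = FALSE])
    centers[2, ] <- colMeans(X[assign == 2L, , drop = FALSE])
  }
  assign
}

#' Refine every nucleus of a label map
#'
#' Applies [build_window()] and [refine_boundary()] to each label and
#' reassembles the refined masks into one label map. A contested pixel keeps
#' the nucleus whose rough region it belonged to; otherwise first-processed
#' wins (refined regions barely overlap because each is confined to its
#' window). Label ids are preserved.
#'
#' @param fused fused intensity image.
#' @param labels rough label map.
#' @param w2 rough-membership weight (default 0.4).
#' @param margin window margin, see [build_window()].
#' @return refined label map, same shape and ids as `labels`.
#' @export
refine_all <- function(fused, labels, w2 = 0.4, margin = NULL) {
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  out <- matrix(0L, nrow(labels), ncol(labels))
  for (id in ids) {
    win <- build_window(fused, labels, id, margin)
    ref <- refine_boundary(win, w2)
    b <- win$bounds
    sub_out <- out[b["r0"]:b["r1"], b["c0"]:b["c1"], drop = FALSE]
    sub_rough <- labels[b["r0"]:b["r1"], b["c0"]:b["c1"], drop = FALSE]
    # claim: refined pixels that are free, plus all pixels of own rough region
    take <- (ref == 1L & (sub_out == 0L | sub_rough == id))
    sub_out[take] <- id
    out[b["r0"]:b["r1"], b["c0"]:b["c1"]] <- sub_out
  }
  out
}
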