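# Segmentation and classification scoring: pixel precision/sensitivity from
# the TP/FP/FN area formulas, object-level correct/over/under-segmentation
# categories, and the report tables (per-tissue-per-day precision/sensitivity
# with a Sum row; category counts with percentages; per-class accuracy + MCA).

#' Pixel-level segmentation score
#'
#' `TP = |A_G intersect A_S|`, `FP = |A_S| - TP`, `FN = |A_G| - TP`,
#' `P = TP/(TP+FP)`, `S = TP/(TP+FN)`, where `A_G` is the reference
#' (manual/truth) foreground and `A_S` the automatic segmentation.
#'
#' @param truth,pred binary masks of equal shape.
#' @return list `TP`, `FP`, `FN`, `precision`, `sensitivity`; both rates `NA`
#'   with a flag attribute when truth and prediction are empty.
#' @export
seg_score <- function(truth, pred) {
  stopifnot(all(dim(truth) == dim(pred)))
  t <- truth != 0; p <- pred != 0
  TP <- sum(t & p); FP <- sum(!t & p); FN <- sum(t & !p)
  if (TP + FP + FN == 0L) {
    return(structure(list(TP = 0L, FP = 0L, FN = 0L, precision = NA_real_,
                          sensitivity = NA_real_), flags = "empty_masks"))
  }
  list(TP = TP, FP = FP, FN = FN,
       precision = if (TP + FP > 0) TP / (TP + FP) else NA_real_,
       sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_)
}

#' Object-level segmentation categories
#'
#' Automates the manual correct/over/under-segmentation triage: a truth
#' nucleus is *over-segmented* when two or more predicted regions each claim
#' at least `claim_floor` of its area; *under-segmented* when its
#' best-matching predicted region also claims at least `claim_floor` of
#' another truth nucleus; *correctly segmented* when exactly one predicted
#' region overlaps it with IoU >= `iou_min` and that region claims no other
#' truth nucleus; anything else is unmatched. Categories partition the truth
#' nuclei.
#'
#' @param truth,pred integer label maps of equal shape.
#' @param iou_min IoU for a correct match (default 0.5).
#' @param claim_floor fraction of a truth nucleus a region must cover to
#'   "claim" it (default 0.2).
#' @return list of class `seg_categories`: counts, percentages, total and the
#'   per-nucleus category vector.
#' @export
categorize_objects <- function(truth, pred, iou_min = 0.5, claim_floor = 0.2) {
  stopifnot(all(dim(truth) == dim(pred)))
  tids <- setdiff(sort(unique(as.vector(truth))), 0L)
  # overlap counts truth x pred over jointly nonzero pixels
  area_t <- stats::setNames(vapply(tids, function(k) sum(truth == k), 0L),
                            tids)
  pos <- truth > 0L & pred > 0L
  ov <- table(truth = truth[pos], pred = pred[pos])
  area_p <- stats::setNames(
    vapply(sort(unique(as.vector(pred[pred > 0L]))),
           function(k) sum(pred == k), 0L),
    sort(unique(as.vector(pred[pred > 0L]))))
  # claims: which predicted region claims >= claim_floor of which truth
  claims <- ov >= outer(area_t[rownames(ov)], rep(1, ncol(ov))) * claim_floor
  cat_of <- stats::setNames(rep("unmatched", length(tids)), tids)
  for (tk in as.character(tids)) {
    row <- if (tk %in% rownames(ov)) ov[tk, ] else NULL
    if (is.null(row) || sum(row) == 0) next
    claimants <- colnames(ov)[claims[tk, ]]
    if (length(claimants) >= 2L) {
      cat_of[tk] <- "over"
      next
    }
    best <- colnames(ov)[which.max(row)]
    # does the best region claim another truth nucleus too?
    other <- rownames(ov)[claims[, best] & rownames(ov) != tk]
    if (length(other)) {
      cat_of[tk] <- "under"
      next
    }
    iou <- ov[tk, best] / (area_t[tk] + area_p[best] - ov[tk, best])
    if (length(claimants) == 1L && claimants == best && iou >= iou_min) {
      cat_of[tk] <- "correct"
    }
  }
  counts <- c(correct = sum(cat_of == "correct"),
              over = sum(cat_of == "over"),
              under = sum(cat_of == "under"),
              unmatched = sum(cat_of == "unmatched"))
  structure(list(counts = counts, total = length(tids),
                 percentages = counts / max(1L, length(tids)),
                 category = cat_of),
            class = "seg_categories")
}

#' Transfer truth classes onto predicted regions
#'
#' Predicted label ids are arbitrary (seed order), so evaluation against a
#' ground-truth label map needs a mapping: each predicted region inherits the
#' tissue class of the truth nucleus holding the majority of its pixels;
#' regions with no truth overlap become "unexpected".
#'
#' @param truth truth label map.
#' @param classes named vector truth nucleus id -> tissue class.
#' @param pred predicted label map.
#' @return named character vector predicted id -> tissue class.
#' @export
transfer_classes <- function(truth, classes, pred) {
  ids <- setdiff(sort(unique(as.vector(pred))), 0L)
  out <- stats::setNames(rep("unexpected", length(ids)), ids)
  for (k in ids) {
    ov <- table(truth[pred == k])
    ov <- ov[names(ov) != "0"]
    if (length(ov)) {
      out[as.character(k)] <-
        unname(classes[names(ov)[which.max(ov)]])
    }
  }
  out
}

#' Segmentation category table (counts and percentages)
#'
#' Rebuilds the published layout: per condition (rows), total nuclei and
#' correct/over/under counts with percentages of the total.
#'
#' @param counts data.frame with columns `condition`, `total`, `correct`,
#'   `over`, `under`.
#' @return data.frame adding `correct_pct`, `over_pct`, `under_pct` (percent,
#'   2 decimals).
#' @export
category_table <- function(counts) {
  stopifnot(all(c("condition", "total", "correct", "over", "under") %in%
                  colnames(counts)))
  for (nm in c("correct", "over", "under")) {
    counts[[paste0(nm, "_pct")]] <- round(100 * counts[[nm]] / counts$total, 2)
  }
  counts
}

#' Per-tissue/day precision-sensitivity table with Sum row
#'
#' Groups scores by tissue, day and channel mode, averages precision and
#' sensitivity per group, and appends per tissue x channel a "Sum" row equal
#' to the unweighted mean over the day rows.
#'
#' @param scores data.frame with columns `tissue`, `day`, `channel`,
#'   `precision`, `sensitivity` (one row per scored nucleus or image).
#' @return data.frame with one row per (tissue, channel, day) plus Sum rows
#'   (`day = "Sum"`).
#' @export
report_tables <- function(scores) {
  need <- c("tissue", "day", "channel", "precision", "sensitivity")
  stopifnot(all(need %in% colnames(scores)))
  agg <- stats::aggregate(
    cbind(precision, sensitivity) ~ tissue + channel + day, data = scores,
    FUN = mean)
  agg$day <- as.character(agg$day)
  out <- list()
  for (ti in unique(agg$tissue)) for (ch in unique(agg$channel)) {
    sub <- agg[agg$tissue == ti & agg$channel == ch, , drop = FALSE]
    if (!nrow(sub)) next
    sub <- sub[order(suppressWarnings(as.numeric(sub$day))), , drop = FALSE]
    sum_row <- data.frame(tissue = ti, channel = ch, day = "Sum",
                          precision = mean(sub$precision),
                          sensitivity = mean(sub$sensitivity))
    out[[length(out) + 1L]] <- rbind(sub, sum_row)
  }
  do.call(rbind, out)
}

#' Per-class accuracy table with MCA
#'
#' @param per_class named numeric vector of per-class accuracies (fractions
#'   or percent, returned on the same scale).
#' @return list `per_class`, `mca` (unweighted mean).
#' @export
mca_from_class_accuracies <- function(per_class) {
  list(per_class = per_class, mca = mean(per_class))
}
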