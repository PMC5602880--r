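# Age-trend quantification: per (strain, tissue, day) mean +/- SD of a chosen
# feature and Welch's unequal-variance t-test between strains at each shared
# day.

#' Age trend of a nuclear feature
#'
#' Groups a feature table by strain, tissue class and day, reports n, mean and
#' SD, and tests the strain difference at every day shared by exactly two
#' strains with Welch's t-test. Groups of n < 2 have undefined SD (flagged
#' `NA`) and are skipped in testing.
#'
#' @param table feature table with metadata columns `strain`, `day`,
#'   `tissue_class`.
#' @param feature feature column to summarize (e.g. "area", "solidity").
#' @param tissue tissue class to restrict to (default "hypodermal", the
#'   tissue whose aging trajectory is most informative); `NULL` keeps all.
#' @return list of class `trend_summary`: `summary` (data.frame strain x day)
#'   and `tests` (data.frame day, strains, t, df, p_value).
#' @export
trend <- function(table, feature, tissue = "hypodermal") {
  stopifnot(all(c("strain", "day") %in% colnames(table)),
            feature %in% colnames(table))
  if (!is.null(tissue) && "tissue_class" %in% colnames(table)) {
    table <- table[table$tissue_class %in% tissue, , drop = FALSE]
  }
  gr <- interaction(table$strain, table$day, drop = TRUE)
  summ <- do.call(rbind, lapply(split(table, gr), function(g) {
    data.frame(strain = g$strain[1], day = g$day[1], n = nrow(g),
               mean = mean(g[[feature]]),
               sd = if (nrow(g) >= 2) stats::sd(g[[feature]]) else NA_real_)
  }))
  summ <- summ[order(summ$strain, summ$day), , drop = FALSE]
  rownames(summ) <- NULL
  strains <- unique(table$strain)
  tests <- NULL
  if (length(strains) == 2L) {
    days <- intersect(unique(table$day[table$strain == strains[1]]),
                      unique(table$day[table$strain == strains[2]]))
    tests <- do.call(rbind, lapply(sort(days), function(d) {
      x <- table[[feature]][table$strain == strains[1] & table$day == d]
      y <- table[[feature]][table$strain == strains[2] & table$day == d]
      if (length(x) < 2L || length(y) < 2L ||
          (stats::var(x) == 0 && stats::var(y) == 0)) {
        return(data.frame(day = d, t = NA_real_, df = NA_real_,
                          p_value = NA_real_))
      }
      ht <- stats::t.test(x, y, var.equal = FALSE)
      data.frame(day = d, t = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = ht$p.value)
    }))
    if (!is.null(tests)) attr(tests, "strains") <- strains
  }
  structure(list(summary = summ, tests = tests, feature = feature),
            class = "trend_summary")
}

#' @export
print.trend_summary <- function(x, ...) {
  cat("<trend_summary>", x$feature, "\n")
  print(x$summary)
  if (!is.null(x$tests)) {
    cat("Welch's t-test", paste(attr(x$tests, "strains"), collapse = " vs "),
        "\n")
    print(x$tests)
  }
  invisible(x)
}
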