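#' Black- versus white-stripe degree of polarization comparison
#'
#' Pairs the two stripe classes within each (animal, ROI) and summarizes
#' the polarization asymmetry: the per-pair relative difference
#' `(d_black - d_white) / d_white` (plus the alternative
#' black-denominator convention, since "percent difference" is ambiguous),
#' its median, a paired Wilcoxon signed-rank test, and the Pearson
#' correlation between paired degrees.
#'
#' @param table A study table ([analyze_series()] output): one `black` and
#'   one `white` row per (zebra_id, roi_label) with a `d` column.
#' @return A list: `n_pairs`, `median_rel_diff` (white denominator),
#'   `median_rel_diff_black_denom`, `wilcoxon` (test object), `pearson_r`,
#'   and the per-pair data.frame `pairs`.
#' @export
stripe_d_comparison <- function(table) {
  pr <- pair_classes(table)
  if (nrow(pr) < 2) stop("need at least 2 complete black/white pairs")
  rel_w <- (pr$d_black - pr$d_white) / pr$d_white
  rel_b <- (pr$d_black - pr$d_white) / pr$d_black
  wt <- suppressWarnings(wilcox.test(pr$d_black, pr$d_white, paired = TRUE))
  if (is.nan(wt$p.value) && all(pr$d_black == pr$d_white))
    wt$p.value <- 1  # identical classes: no evidence of any difference
  list(n_pairs = nrow(pr),
       median_rel_diff = median(rel_w),
       median_rel_diff_black_denom = median(rel_b),
       wilcoxon = wt,
       pearson_r = cor(pr$d_black, pr$d_white),
       pairs = cbind(pr, rel_diff = rel_w))
}

#' Phase agreement between black and white stripes
#'
#' Restricted to ROIs that pass the significance gate (both stripe-class
#' fits significant), since phase is meaningless at low polarization.
#' Reports the gated count, the Pearson correlation between black and
#' white phases, and a paired t-test on the circular phase difference. If
#' phases of the two classes were systematically orthogonal, the striping
#' could cancel the polarization signal; agreement of phases rules that
#' out.
#'
#' @param table A study table with `phase_deg` and `significant` columns.
#' @param alpha Significance level (recorded; gating uses the table's
#'   `significant` flags, which were computed at fit time).
#' @return A list: `n_gated`, `pearson_r`, `mean_abs_phase_diff`,
#'   `paired_t`, and the gated per-pair data.frame `pairs`.
#' @export
phase_correlation <- function(table, alpha = 0.05) {
  pr <- pair_classes(table)
  pr <- pr[pr$significant_black & pr$significant_white, , drop = FALSE]
  if (nrow(pr) < 3) stop("fewer than 3 gated pairs: phase analysis unreliable")
  dphi <- circ_phase_diff(pr$phase_black, pr$phase_white)
  list(n_gated = nrow(pr),
       pearson_r = cor(pr$phase_black, pr$phase_white),
       mean_abs_phase_diff = mean(abs(dphi)),
       paired_t = tryCatch(t.test(dphi), error = function(e) NULL),
       pairs = cbind(pr, phase_diff = dphi))
}

#' Grouped distribution summary of degrees of polarization
#'
#' Box-plot statistics as numbers, per (roi_label, class) and — when an
#' `illumination` column is present — illumination condition: quartiles,
#' mean, t-based 95% confidence interval of the mean, and outliers by the
#' 1.5 x IQR rule.
#'
#' @param table A study table.
#' @param value Column to summarize (default `"d"`).
#' @return A data.frame, one row per group, with columns `roi_label`,
#'   `class`, (`illumination`,) `n`, `mean`, `ci_lo`, `ci_hi`, `q1`,
#'   `median`, `q3`, `n_outliers`; attribute `outliers` lists the flagged
#'   values per group.
#' @export
cohort_summary <- function(table, value = "d") {
  keys <- intersect(c("roi_label", "class", "illumination"), names(table))
  groups <- split(table, table[keys], drop = TRUE)
  outliers <- list()
  rows <- lapply(names(groups), function(g) {
    v <- groups[[g]][[value]]
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    out <- v[v < q[1] - 1.5 * iqr | v > q[3] + 1.5 * iqr]
    outliers[[g]] <<- out
    ci <- if (length(v) > 1) {
      m <- mean(v); se <- sd(v) / sqrt(length(v))
      m + c(-1, 1) * qt(0.975, length(v) - 1) * se
    } else c(NA_real_, NA_real_)
    cbind(groups[[g]][1, keys, drop = FALSE],
          data.frame(n = length(v), mean = mean(v), ci_lo = ci[1],
                     ci_hi = ci[2], q1 = q[1], median = q[2], q3 = q[3],
                     n_outliers = length(out)))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "outliers") <- outliers
  res
}

# Reshape a long study table (one row per class) into one row per
# (zebra_id, roi_label) pair with *_black / *_white columns.
pair_classes <- function(table) {
  need <- c("zebra_id", "roi_label", "class", "d")
  if (!all(need %in% names(table)))
    stop("study table must have columns: ", paste(need, collapse = ", "))
  b <- table[table$class == "black", , drop = FALSE]
  w <- table[table$class == "white", , drop = FALSE]
  keep <- c("d", intersect(c("phase_deg", "fit_r", "significant"), names(table)))
  m <- merge(b[, c("zebra_id", "roi_label", keep)],
             w[, c("zebra_id", "roi_label", keep)],
             by = c("zebra_id", "roi_label"), suffixes = c("_black", "_white"))
  names(m) <- sub("^d_", "d_", names(m))
  names(m) <- sub("^phase_deg_", "phase_", names(m))
  m[complete.cases(m[, c("d_black", "d_white")]), , drop = FALSE]
}
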