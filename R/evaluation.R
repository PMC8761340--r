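#' Dice similarity coefficient
#'
#' Spatial overlap of two binary masks on the same grid:
#' `2 |A intersect B| / (|A| + |B|)`. Defined as 1 when both masks are empty
#' (flagged with a warning); symmetric and bounded in \[0, 1\].
#'
#' @param a,b [label_mask()] objects (or bare binary arrays) on one grid.
#' @return The DSC.
#' @export
dsc <- function(a, b) {
  da <- if (is_mask(a)) a$data else as.array(a)
  db <- if (is_mask(b)) b$data else as.array(b)
  if (!identical(dim(da), dim(db))) stop("masks must share a grid")
  sa <- sum(da == 1)
  sb <- sum(db == 1)
  if (sa + sb == 0) {
    warning("both masks empty; DSC defined as 1")
    return(1)
  }
  2 * sum(da == 1 & db == 1) / (sa + sb)
}

#' Intraclass correlation, single measure, absolute agreement
#'
#' ICC(2,1): two-way random-effects, single-measure, absolute-agreement
#' intraclass correlation between the manual and automatic volumes,
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))` with k = 2 raters
#' and mean squares from the two-way ANOVA decomposition (rows = cases,
#' columns = raters). Unlike a Pearson correlation it penalizes systematic
#' bias between the raters.
#'
#' @param pairs n x 2 matrix or data.frame of (reference, predicted) volumes,
#'   n >= 3.
#' @return The ICC.
#' @export
icc_absolute_agreement <- function(pairs) {
  x <- as.matrix(pairs)
  if (ncol(x) != 2L) stop("pairs must have two columns")
  if (nrow(x) < 3L) stop("ICC needs at least 3 pairs")
  if (any(!is.finite(x))) stop("volumes must be finite")
  n <- nrow(x)
  k <- 2
  grand <- mean(x)
  if (sum((x - grand)^2) < 1e-12) stop("zero total variance; ICC undefined")
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((x - outer(row_m, rep(1, k)) -
              outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Tumor-volume group
#'
#' The four similar-sized volume strata used in place of T-stage for size
#' analysis: V1 (v <= 3), V2 (3 < v <= 7), V3 (7 < v <= 15), V4 (v > 15),
#' volumes in cm^3.
#'
#' @param v volume in cm^3, >= 0.
#' @return `"V1"`, `"V2"`, `"V3"`, or `"V4"`.
#' @export
volume_group <- function(v) {
  if (length(v) != 1L || !is.finite(v) || v < 0)
    stop("volume must be a single non-negative number")
  if (v <= 3) "V1" else if (v <= 7) "V2" else if (v <= 15) "V3" else "V4"
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Rank-sum comparison of two groups with midrank tie handling: exact
#' enumeration when both groups have at most 20 observations and no ties are
#' present, the normal approximation with tie correction otherwise.
#'
#' @param x,y non-empty numeric vectors.
#' @return Two-sided p-value.
#' @export
wilcoxon_ranksum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty")
  exact <- length(x) <= 20L && length(y) <= 20L &&
    !anyDuplicated(c(x, y))
  suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = !exact)$p.value)
}

#' Per-case segmentation result
#'
#' @param case_id identifier.
#' @param dsc Dice similarity coefficient in \[0, 1\].
#' @param ref_volume_cm3,pred_volume_cm3 manual and automatic volumes.
#' @param fold fold index the case was held out in.
#' @param t_stage,n_stage,location subgroup labels.
#' @return One-row data.frame; the volume group is derived from the
#'   reference volume.
#' @export
case_result <- function(case_id, dsc, ref_volume_cm3, pred_volume_cm3,
                        fold = 0L, t_stage = "T2", n_stage = "N0",
                        location = "OROPHARYNX") {
  stopifnot(dsc >= 0, dsc <= 1, ref_volume_cm3 >= 0, pred_volume_cm3 >= 0)
  data.frame(case_id = case_id, dsc = dsc,
             ref_volume_cm3 = ref_volume_cm3,
             pred_volume_cm3 = pred_volume_cm3, fold = as.integer(fold),
             t_stage = t_stage, n_stage = n_stage, location = location,
             volume_group = volume_group(ref_volume_cm3),
             stringsAsFactors = FALSE)
}

mean_sd <- function(x) {
  c(mean = mean(x), sd = if (length(x) > 1L) sd(x) else 0, n = length(x))
}

#' Cohort evaluation report
#'
#' Summarizes per-case results the way clinical segmentation studies report performance: ICC of
#' the (manual, automatic) volumes computed per fold and summarized as
#' mean and SD across folds; DSC summarized across cases (and, for reference,
#' across folds); per-subgroup DSC (mean, SD, n) for T-stage, N-stage,
#' location and volume group; and all pairwise two-sided Wilcoxon rank-sum
#' p-values within each stratification, flagged at `alpha`. No
#' multiple-testing correction is applied.
#'
#' @param results data.frame of [case_result()] rows.
#' @param alpha significance level (default 0.05).
#' @return An object of class `mvseg_report`.
#' @export
evaluate_cohort <- function(results, alpha = 0.05) {
  stopifnot(is.data.frame(results), nrow(results) >= 1L)
  results <- results[order(results$case_id), , drop = FALSE]
  icc_per_fold <- c()
  for (f in sort(unique(results$fold))) {
    sub <- results[results$fold == f, ]
    if (nrow(sub) < 3L) {
      warning("fold ", f, " has fewer than 3 cases; ICC skipped")
      next
    }
    icc_per_fold[as.character(f)] <-
      icc_absolute_agreement(sub[, c("ref_volume_cm3", "pred_volume_cm3")])
  }
  dsc_by_fold <- vapply(split(results$dsc, results$fold), mean, numeric(1))
  subgroups <- list()
  pvals <- list()
  for (strat in c("t_stage", "n_stage", "location", "volume_group")) {
    groups <- split(results$dsc, results[[strat]])
    tab <- do.call(rbind, lapply(groups, mean_sd))
    subgroups[[strat]] <- data.frame(group = rownames(tab), tab,
                                     row.names = NULL)
    gnames <- names(groups)
    if (length(gnames) >= 2L) {
      cmb <- combn(gnames, 2)
      pv <- apply(cmb, 2, function(gp)
        wilcoxon_ranksum(groups[[gp[1]]], groups[[gp[2]]]))
      pvals[[strat]] <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                                   p_value = pv,
                                   significant = pv < alpha)
    }
  }
  structure(list(
    n = nrow(results),
    icc_per_fold = icc_per_fold,
    icc = mean_sd(unname(icc_per_fold)),
    dsc_cases = mean_sd(results$dsc),
    dsc_folds = mean_sd(unname(dsc_by_fold)),
    ref_volume = mean_sd(results$ref_volume_cm3),
    pred_volume = mean_sd(results$pred_volume_cm3),
    subgroups = subgroups, pairwise = pvals, alpha = alpha,
    results = results), class = "mvseg_report")
}

#' @export
print.mvseg_report <- function(x, ...) {
  fmt <- function(ms) sprintf("%.2f±%.2f", ms["mean"], ms["sd"])
  cat(sprintf("Segmentation report (n = %d)\n", x$n))
  cat(sprintf("  ICC (across folds):   %s\n", fmt(x$icc)))
  cat(sprintf("  DSC (across cases):   %s\n", fmt(x$dsc_cases)))
  cat(sprintf("  Volume ref/pred cm3:  %s / %s\n", fmt(x$ref_volume),
              fmt(x$pred_volume)))
  for (strat in names(x$subgroups)) {
    cat(" ", strat, "\n")
    tab <- x$subgroups[[strat]]
    for (r in seq_len(nrow(tab)))
      cat(sprintf("    %-12s %3d  %.2f±%.2f\n", tab$group[r], tab$n[r],
                  tab$mean[r], tab$sd[r]))
  }
  invisible(x)
}

#' Write a report as JSON and CSV
#'
#' @param report an [evaluate_cohort()] result.
#' @param json_path output JSON path; per-case CSV written next to it.
#' @return `json_path`, invisibly.
#' @export
write_report <- function(report, json_path) {
  stopifnot(inherits(report, "mvseg_report"))
  payload <- report[c("n", "icc_per_fold", "icc", "dsc_cases", "dsc_folds",
                      "ref_volume", "pred_volume", "subgroups", "pairwise",
                      "alpha")]
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  write.csv(report$results,
            file.path(dirname(json_path),
                      sub("\\.json$", "_cases.csv", basename(json_path))),
            row.names = FALSE)
  invisible(json_path)
}
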