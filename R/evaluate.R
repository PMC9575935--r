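# Three-way evaluation protocol: confusion accounting with the exact metric
# denominators used in the validation studies, stratified reports, and the
# univariable nonparametric tests.
#
# Denominator conventions (they matter with an abstaining classifier):
# sensitivity and specificity keep indeterminates in the denominator
# (calls(KD|KD)/total KD, calls(FC|FC)/total FC) while PPV and NPV exclude
# them (correct KD calls / all KD calls, correct FC calls / all FC calls).
# Consequently sensitivity + indeterminate rate + misclassification rate is
# exactly 100% within each true class.

#' Three-way confusion summary
#'
#' @param truth true classes, `"KD"`/`"FC"`.
#' @param calls classifier calls, `"KD"`/`"FC"`/`"INDETERMINATE"`.
#' @return An object of class `kd_confusion`: the 2x3 `counts` table, the
#'   four headline metrics and the per-class indeterminate and
#'   misclassification rates, all as exact proportions in [0,1] (`NA` when a
#'   denominator is zero). The print method renders percentages to one
#'   decimal (round half even).
#' @export
summarize_calls <- function(truth, calls) {
  if (length(truth) != length(calls)) {
    stop(kd_error("kd_validation_error", "truth and calls must align 1:1"))
  }
  truth <- as.character(truth); calls <- as.character(calls)
  if (!all(truth %in% c("KD", "FC"))) {
    stop(kd_error("kd_validation_error", "truth must be 'KD' or 'FC'"))
  }
  if (!all(calls %in% c("KD", "FC", "INDETERMINATE"))) {
    stop(kd_error("kd_validation_error",
                  "calls must be 'KD', 'FC' or 'INDETERMINATE'"))
  }
  counts <- table(factor(truth, levels = c("KD", "FC")),
                  factor(calls, levels = c("KD", "FC", "INDETERMINATE")))
  counts <- unclass(counts)
  n_kd <- sum(counts["KD", ]); n_fc <- sum(counts["FC", ])
  structure(list(
    counts = counts,
    n_kd = n_kd, n_fc = n_fc,
    sensitivity = safe_ratio(counts["KD", "KD"], n_kd),
    specificity = safe_ratio(counts["FC", "FC"], n_fc),
    ppv = safe_ratio(counts["KD", "KD"], counts["KD", "KD"] + counts["FC", "KD"]),
    npv = safe_ratio(counts["FC", "FC"], counts["FC", "FC"] + counts["KD", "FC"]),
    indeterminate_rate_kd = safe_ratio(counts["KD", "INDETERMINATE"], n_kd),
    indeterminate_rate_fc = safe_ratio(counts["FC", "INDETERMINATE"], n_fc),
    misclassified_rate_kd = safe_ratio(counts["KD", "FC"], n_kd),
    misclassified_rate_fc = safe_ratio(counts["FC", "KD"], n_fc)),
    class = "kd_confusion")
}

#' Confusion summary from a results data frame
#'
#' Joins classifier results to truth by patient id (error on any mismatch)
#' and summarizes.
#'
#' @param cohort labelled `kd_cohort` (or data frame with `id`, `diagnosis`).
#' @param results data frame with `id`, `call` as from [classify_two_step()].
#' @return A `kd_confusion`.
#' @export
confusion_from_results <- function(cohort, results) {
  if (!all(results$id %in% cohort$id) || !all(cohort$id %in% results$id)) {
    stop(kd_error("kd_validation_error",
                  "result ids and cohort ids do not match 1:1"))
  }
  m <- match(cohort$id, results$id)
  summarize_calls(cohort$diagnosis, results$call[m])
}

pct1 <- function(x) ifelse(is.na(x), "--", sprintf("%.1f%%", round(100 * x, 1)))

#' @export
print.kd_confusion <- function(x, ...) {
  cat("<kd_confusion>\n")
  print(x$counts)
  cat(sprintf("sensitivity %s  specificity %s  PPV %s  NPV %s\n",
              pct1(x$sensitivity), pct1(x$specificity), pct1(x$ppv), pct1(x$npv)))
  cat(sprintf("indeterminate KD %s, FC %s; misclassified KD %s, FC %s\n",
              pct1(x$indeterminate_rate_kd), pct1(x$indeterminate_rate_fc),
              pct1(x$misclassified_rate_kd), pct1(x$misclassified_rate_fc)))
  invisible(x)
}

#' Stratified performance report
#'
#' Per-stratum confusion summaries for the reporting stratifiers: `"age"`
#' (< 1 vs >= 1 year), `"illness_day"` (< 8 vs 8-10), `"criteria"`
#' (<= 2 / 3 / >= 4 principal criteria) and `"coronary"` (coronary outcome
#' label). Strata with no records are omitted; zero-denominator metrics
#' within a stratum are `NA`, never 0.
#'
#' @param cohort labelled `kd_cohort`.
#' @param results results data frame (`id`, `call`).
#' @param stratifier one of `"age"`, `"illness_day"`, `"criteria"`,
#'   `"coronary"`.
#' @return Named list of `kd_confusion` (class `kd_stratified`).
#' @export
stratified_report <- function(cohort, results,
                              stratifier = c("age", "illness_day",
                                             "criteria", "coronary")) {
  stratifier <- match.arg(stratifier)
  m <- match(cohort$id, results$id)
  if (anyNA(m)) {
    stop(kd_error("kd_validation_error", "results missing cohort id(s)"))
  }
  calls <- results$call[m]
  strata <- switch(stratifier,
    age = {
      if (any(is.na(cohort$age_years))) {
        stop(kd_error("kd_validation_error", "age_years required"))
      }
      ifelse(cohort$age_years < 1, "<1y", ">=1y")
    },
    illness_day = ifelse(cohort$illness_days < 8, "<8d", "8-10d"),
    criteria = {
      cc <- criteria_count(cohort)
      ifelse(cc <= 2, "le2", ifelse(cc == 3, "3", "ge4"))
    },
    coronary = label_coronary_cohort(cohort))
  out <- lapply(split(seq_len(nrow(cohort)), strata), function(idx) {
    summarize_calls(cohort$diagnosis[idx], calls[idx])
  })
  structure(out, class = c("kd_stratified", "list"), stratifier = stratifier)
}

#' @export
print.kd_stratified <- function(x, ...) {
  cat(sprintf("<kd_stratified> by %s\n", attr(x, "stratifier")))
  for (nm in names(x)) {
    s <- x[[nm]]
    cat(sprintf("  %-12s n=%4d  sens %s  spec %s  PPV %s  NPV %s\n",
                nm, sum(s$counts), pct1(s$sensitivity), pct1(s$specificity),
                pct1(s$ppv), pct1(s$npv)))
  }
  invisible(x)
}

#' Fisher's exact test, two-sided
#'
#' Two-sided p-value for a 2x2 table under the minimum-likelihood convention:
#' the hypergeometric probabilities (margins fixed) of all tables at most as
#' probable as the observed one (relative tolerance 1e-7) are summed. Other
#' two-sided conventions (tail doubling) exist and can give larger values;
#' the convention is recorded in the result.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return List with `p` in (0, 1] and `convention`.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0) ||
      any(table != round(table))) {
    stop(kd_error("kd_validation_error",
                  "table must be 2x2 with non-negative integer counts"))
  }
  if (sum(table) == 0) {
    stop(kd_error("kd_validation_error", "table total must be positive"))
  }
  p <- stats::fisher.test(table)$p.value
  list(p = min(p, 1), convention = "two-sided minimum-likelihood")
}

#' Mann-Whitney U test
#'
#' U statistic with midrank tie handling. The p-value is exact (full
#' enumeration of the rank distribution) when `n_a + n_b <= 20` and there
#' are no ties; otherwise a normal approximation with tie correction and
#' continuity correction is used. The method is recorded in the output.
#'
#' @param a,b non-empty numeric samples.
#' @return List with `U` (for sample `a`), `p` and `method`.
#' @export
mann_whitney_u <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) {
    stop(kd_error("kd_validation_error", "both samples must be non-empty"))
  }
  r <- rank(c(a, b))
  u <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 20) && !ties
  p <- stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value
  list(U = u, p = min(p, 1),
       method = if (exact) "exact" else "normal approximation, tie + continuity correction")
}

#' KD/FC median ratios by illness-day bin
#'
#' For each analyte and illness-day bin (< 8 vs 8-10 days), the ratio of the
#' KD median to the FC median among observed values, with the Mann-Whitney
#' p-value of the KD vs FC comparison. Ratios with an empty group or a zero
#' FC median are flagged undefined rather than raising.
#'
#' @param cohort labelled `kd_cohort`.
#' @param analytes analyte names (default Taiwan panel).
#' @return Data frame `analyte`, `bin`, `n_kd`, `n_fc`, `median_kd`,
#'   `median_fc`, `ratio`, `p`, `note`.
#' @export
median_ratio_report <- function(cohort, analytes = kd_analytes("taiwan")) {
  bins <- list("<8d" = cohort$illness_days < 8,
               "8-10d" = cohort$illness_days >= 8)
  rows <- list()
  for (an in analytes) {
    for (bn in names(bins)) {
      sel <- bins[[bn]]
      kd <- cohort[[an]][sel & cohort$diagnosis == "KD"]
      fc <- cohort[[an]][sel & cohort$diagnosis == "FC"]
      kd <- kd[!is.na(kd)]; fc <- fc[!is.na(fc)]
      note <- ""
      if (!length(kd) || !length(fc)) {
        med_kd <- if (length(kd)) stats::median(kd) else NA_real_
        med_fc <- if (length(fc)) stats::median(fc) else NA_real_
        ratio <- NA_real_; p <- NA_real_; note <- "empty group"
      } else {
        med_kd <- stats::median(kd); med_fc <- stats::median(fc)
        if (med_fc == 0) {
          ratio <- NA_real_; note <- "undefined (FC median = 0)"
        } else ratio <- med_kd / med_fc
        p <- mann_whitney_u(kd, fc)$p
      }
      rows[[length(rows) + 1L]] <- data.frame(
        analyte = an, bin = bn, n_kd = length(kd), n_fc = length(fc),
        median_kd = med_kd, median_fc = med_fc, ratio = ratio, p = p,
        note = note, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
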