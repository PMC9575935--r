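# Enrollment inclusion rules and coronary outcome labelling.

#' Apply the study inclusion filters
#'
#' Removes records with more than 10 days of fever at evaluation, and febrile
#' controls presenting none of the five principal criteria (a febrile control
#' is, by definition, a child with unexplained fever *and* at least one
#' principal sign). Fever >= 38.0 C is an enrollment precondition, not a
#' stored field, so the filter acts on `illness_days` only. Idempotent.
#'
#' @param cohort a `kd_cohort`.
#' @return A list with `cohort` (retained records, order preserved),
#'   `exclusions` (data frame `id`, `reason_code`, `reason`) and
#'   `counts_by_reason` (reason x diagnosis totals).
#' @export
apply_inclusion_filters <- function(cohort) {
  stopifnot(inherits(cohort, "kd_cohort"))
  cc <- criteria_count(cohort)
  fever_long <- cohort$illness_days > 10L
  fc_no_crit <- !fever_long & !is.na(cohort$diagnosis) &
    cohort$diagnosis == "FC" & cc == 0L
  drop <- fever_long | fc_no_crit
  reason_code <- ifelse(fever_long, "FEVER_GT_10D", "FC_NO_CRITERIA")[drop]
  reason_text <- ifelse(
    reason_code == "FEVER_GT_10D",
    "days of fever greater than 10 at evaluation",
    "febrile control without any principal clinical criterion")
  exclusions <- data.frame(id = cohort$id[drop], reason_code = reason_code,
                           reason = reason_text, stringsAsFactors = FALSE)
  counts <- table(
    reason = factor(reason_code, levels = c("FEVER_GT_10D", "FC_NO_CRITERIA")),
    diagnosis = factor(cohort$diagnosis[drop], levels = c("KD", "FC")))
  kept <- cohort[!drop, , drop = FALSE]
  attr(kept, "provenance") <- attr(cohort, "provenance")
  class(kept) <- class(cohort)
  list(cohort = kept, exclusions = exclusions, counts_by_reason = counts)
}

#' Label a coronary Z-score trajectory
#'
#' Classifies a patient's coronary artery outcome from RCA/LAD Z-scores over
#' follow-up. A Z-score >= 2.5 is abnormal and >= 5 an aneurysm; dilation is
#' judged resolved when every measurement taken at or after 8 weeks (day 56,
#' closed boundary) from diagnosis is below 2.5.
#'
#' @param z_scores data frame with columns `day`, `artery` (RCA/LAD) and `z`,
#'   or the compact string encoding accepted by [parse_coronary_z()].
#' @return One of `"NORMAL"`, `"DILATED"`, `"ANEURYSM"`, `"UNRESOLVED"`,
#'   `"NO_FOLLOWUP"`, `"MISSING"`.
#' @export
label_coronary <- function(z_scores) {
  if (is.character(z_scores) || (length(z_scores) == 1L && is.na(z_scores))) {
    z_scores <- parse_coronary_z(z_scores)
  }
  if (is.null(z_scores) || nrow(z_scores) == 0L) return("MISSING")
  if (any(!is.finite(z_scores$z))) {
    stop(kd_error("kd_validation_error", "coronary z values must be finite"))
  }
  if (any(z_scores$z >= 5)) return("ANEURYSM")
  if (all(z_scores$z < 2.5)) return("NORMAL")
  late <- z_scores[z_scores$day >= 56L, , drop = FALSE]
  if (nrow(late) == 0L) return("NO_FOLLOWUP")
  if (all(late$z < 2.5)) "DILATED" else "UNRESOLVED"
}

#' Coronary labels for every record of a cohort
#'
#' @param cohort a `kd_cohort` with a `coronary_z` column.
#' @return Character vector of labels, one per record.
#' @export
label_coronary_cohort <- function(cohort) {
  vapply(cohort$coronary_z, label_coronary, character(1), USE.NAMES = FALSE)
}
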