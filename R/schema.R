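#' @keywords internal
"_PACKAGE"

#' @importFrom stats median quantile setNames rbinom rlnorm runif qnorm pnorm
#'   fisher.test wilcox.test predict cov chisq.test
#' @importFrom utils read.table write.table packageVersion
NULL

# ---- canonical schema ------------------------------------------------------

#' Names of the five principal clinical criteria
#'
#' Rash, conjunctival injection, extremity changes, oropharyngeal changes and
#' cervical lymphadenopathy (>1.5 cm): the principal diagnostic signs of
#' Kawasaki disease. Classic KD requires fever plus at least four of the five.
#'
#' @return Character vector of the five canonical criterion column names.
#' @export
kd_criteria <- function() {
  c("rash", "conjunctival_injection", "extremity_changes",
    "oropharyngeal_changes", "cervical_lymphadenopathy")
}

#' Names of the laboratory analytes in the cohort schema
#'
#' Units are fixed per analyte and never auto-converted: wbc 10^3 cells/uL,
#' eos_pct/mono_pct/lymph_pct/neut_pct/bands_pct percent, hemoglobin g/dL,
#' platelets 10^3/uL, crp mg/L, alt U/L, esr mm/h, ggt U/L.
#'
#' @param profile `"full"` for all twelve analytes, or `"taiwan"` for the
#'   nine analytes routinely collected at the Taiwan centre (bands, GGT and
#'   ESR excluded).
#' @return Character vector of canonical analyte column names.
#' @export
kd_analytes <- function(profile = c("full", "taiwan")) {
  profile <- match.arg(profile)
  full <- c("wbc", "eos_pct", "hemoglobin", "mono_pct", "lymph_pct",
            "neut_pct", "bands_pct", "platelets", "crp", "alt", "esr", "ggt")
  if (profile == "taiwan") setdiff(full, c("bands_pct", "esr", "ggt")) else full
}

#' Default modelling feature set
#'
#' The discriminant and the stratum forests share one feature list: illness
#' days, the five principal clinical criteria encoded 0/1, and a laboratory
#' panel.
#'
#' @inheritParams kd_analytes
#' @return Character vector of feature names in schema order.
#' @export
kd_features <- function(profile = c("taiwan", "full")) {
  profile <- match.arg(profile)
  c("illness_days", kd_criteria(), kd_analytes(profile))
}

# physiologic validity ranges; values outside become missing with a warning
kd_lab_ranges <- function() {
  pct <- c(0, 100)
  list(wbc = c(0, 200), eos_pct = pct, hemoglobin = c(0, 25), mono_pct = pct,
       lymph_pct = pct, neut_pct = pct, bands_pct = pct,
       platelets = c(0, 3000), crp = c(0, 1000), alt = c(0, 10000),
       esr = c(0, 200), ggt = c(0, 5000))
}

kd_all_columns <- function() {
  c("id", "diagnosis", "age_years", "sex", "illness_days",
    kd_criteria(), kd_analytes("full"), "coronary_z")
}

kd_mandatory_columns <- function() c("id", "illness_days", kd_criteria())

# ---- column dictionary -----------------------------------------------------

# Header variants seen across sites map onto canonical names; matching is
# case-insensitive after stripping non-alphanumerics.
kd_column_dictionary <- function() {
  list(
    id = c("id", "patientid", "subjectid", "record"),
    diagnosis = c("diagnosis", "dx", "group", "label", "class"),
    age_years = c("ageyears", "age", "agey"),
    sex = c("sex", "gender"),
    illness_days = c("illnessdays", "feverdays", "daysoffever", "illnessday"),
    rash = c("rash"),
    conjunctival_injection = c("conjunctivalinjection", "conjunctivitis",
                               "conjunctival"),
    extremity_changes = c("extremitychanges", "extremity"),
    oropharyngeal_changes = c("oropharyngealchanges", "oralchanges",
                              "oralandpharyngealchanges", "oropharyngeal"),
    cervical_lymphadenopathy = c("cervicallymphadenopathy", "cervicallymphnode",
                                 "lymphadenopathy", "cervical"),
    wbc = c("wbc", "wbckperul", "whitebloodcells", "wbccount"),
    eos_pct = c("eospct", "eosinophils", "eosinophilspct", "eos"),
    hemoglobin = c("hemoglobin", "hgb", "hb", "hemoglobingdl"),
    mono_pct = c("monopct", "monocytes", "monocytespct", "mono"),
    lymph_pct = c("lymphpct", "lymphocytes", "lymphocytespct", "lymph"),
    neut_pct = c("neutpct", "neutrophils", "neutrophilspct", "neut"),
    bands_pct = c("bandspct", "bands", "immatureneutrophils"),
    platelets = c("platelets", "plt", "plateletcount", "plateletskperul"),
    crp = c("crp", "creactiveprotein", "crpmgl"),
    alt = c("alt", "alanineaminotransferase", "altul"),
    esr = c("esr", "erythrocytesedimentationrate", "esrmmh"),
    ggt = c("ggt", "gammaglutamyltransferase", "ggtul"),
    coronary_z = c("coronaryz", "coronaryzscores", "coronary")
  )
}

normalize_header <- function(x) gsub("[^a-z0-9]", "", tolower(x))

map_headers <- function(headers) {
  dict <- kd_column_dictionary()
  norm <- normalize_header(headers)
  out <- rep(NA_character_, length(headers))
  for (canon in names(dict)) {
    hit <- which(norm %in% normalize_header(dict[[canon]]))
    if (length(hit)) out[hit[1]] <- canon
  }
  out
}

# ---- cohort construction & validation --------------------------------------

#' Construct a validated cohort table
#'
#' A cohort is a `data.frame` with the canonical schema columns (one row per
#' patient) and class `"kd_cohort"`. Missing optional columns are added as
#' all-missing; values outside an analyte's physiologic validity range are set
#' to missing with a warning.
#'
#' @param df data frame holding at least `id`, `illness_days` and the five
#'   criterion columns.
#' @param provenance free-text source tag stored as an attribute.
#' @return A `kd_cohort` data frame.
#' @export
as_kd_cohort <- function(df, provenance = "unspecified") {
  stopifnot(is.data.frame(df))
  missing_mand <- setdiff(kd_mandatory_columns(), names(df))
  if (length(missing_mand)) {
    stop(kd_error("kd_schema_error", paste0(
      "missing mandatory column(s): ", paste(missing_mand, collapse = ", "))))
  }
  out <- data.frame(id = as.character(df$id), stringsAsFactors = FALSE)
  n <- nrow(df)
  get_or_na <- function(col, default) {
    if (col %in% names(df)) df[[col]] else rep(default, n)
  }
  out$diagnosis <- toupper(as.character(get_or_na("diagnosis", NA_character_)))
  if (any(!is.na(out$diagnosis) & !out$diagnosis %in% c("KD", "FC"))) {
    stop(kd_error("kd_validation_error",
                  "diagnosis must be 'KD', 'FC' or missing"))
  }
  out$age_years <- as.numeric(get_or_na("age_years", NA_real_))
  sex <- as.character(get_or_na("sex", "unknown"))
  sex[is.na(sex) | !sex %in% c("M", "F")] <- "unknown"
  out$sex <- sex
  out$illness_days <- as.integer(round(as.numeric(df$illness_days)))
  for (cr in kd_criteria()) out[[cr]] <- parse_flag(df[[cr]])
  for (an in kd_analytes("full")) out[[an]] <- as.numeric(get_or_na(an, NA_real_))
  out$coronary_z <- as.character(get_or_na("coronary_z", NA_character_))

  if (anyDuplicated(out$id)) {
    stop(kd_error("kd_validation_error", paste0(
      "duplicate patient id(s): ",
      paste(unique(out$id[duplicated(out$id)]), collapse = ", "))))
  }
  if (any(is.na(out$illness_days)) || any(out$illness_days < 1L)) {
    stop(kd_error("kd_validation_error",
                  "illness_days must be an integer >= 1 for every record"))
  }
  if (any(!is.na(out$age_years) & out$age_years < 0)) {
    stop(kd_error("kd_validation_error", "age_years must be non-negative"))
  }
  for (cr in kd_criteria()) {
    if (any(is.na(out[[cr]]))) {
      stop(kd_error("kd_validation_error", paste0(
        "criterion '", cr, "' is missing for id(s): ",
        paste(out$id[is.na(out[[cr]])], collapse = ", "))))
    }
  }
  ranges <- kd_lab_ranges()
  n_bad <- 0L
  for (an in kd_analytes("full")) {
    r <- ranges[[an]]
    bad <- !is.na(out[[an]]) & (out[[an]] < r[1] | out[[an]] > r[2])
    if (any(bad)) {
      n_bad <- n_bad + sum(bad)
      out[[an]][bad] <- NA_real_
    }
  }
  if (n_bad > 0L) {
    warning(sprintf(
      "%d lab value(s) outside physiologic validity ranges set to missing",
      n_bad), call. = FALSE)
  }
  out <- out[, kd_all_columns()]
  attr(out, "provenance") <- provenance
  class(out) <- c("kd_cohort", "data.frame")
  out
}

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(ifelse(is.na(x), NA, x != 0))
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(s))
  out[s %in% c("1", "true", "t", "yes", "y")] <- TRUE
  out[s %in% c("0", "false", "f", "no", "n")] <- FALSE
  out
}

#' Number of principal criteria present
#'
#' @param cohort a `kd_cohort` (or data frame with the five criterion columns).
#' @return Integer vector, one count in 0..5 per record.
#' @export
criteria_count <- function(cohort) {
  as.integer(rowSums(as.matrix(as.data.frame(cohort)[, kd_criteria()])))
}

#' @export
print.kd_cohort <- function(x, ...) {
  cat(sprintf("<kd_cohort> %d records (%s KD, %s FC, %s unlabeled) from '%s'\n",
              nrow(x), sum(x$diagnosis == "KD", na.rm = TRUE),
              sum(x$diagnosis == "FC", na.rm = TRUE),
              sum(is.na(x$diagnosis)), attr(x, "provenance") %||% "?"))
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

kd_error <- function(class, message) {
  structure(class = c(class, "kd_error", "error", "condition"),
            list(message = message, call = NULL))
}

# ---- coronary z-score encoding ---------------------------------------------

#' Encode / decode coronary Z-score trajectories
#'
#' A trajectory is stored in delimited files as a single compact string,
#' `"day:artery:z"` triplets separated by `";"`, e.g.
#' `"14:RCA:2.8;56:RCA:1.9"`. `parse_coronary_z` returns a data frame with
#' columns `day`, `artery`, `z`; `format_coronary_z` is its inverse.
#'
#' @param x for `parse_coronary_z` a single encoded string (or `NA`); for
#'   `format_coronary_z` a data frame with columns `day`, `artery`, `z`.
#' @return A data frame (possibly zero rows), or an encoded string.
#' @export
parse_coronary_z <- function(x) {
  empty <- data.frame(day = integer(), artery = character(), z = numeric())
  if (length(x) != 1L || is.na(x) || !nzchar(trimws(x))) return(empty)
  parts <- strsplit(strsplit(trimws(x), ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) != 3L, logical(1))
  if (any(bad)) stop(kd_error("kd_validation_error",
                              "malformed coronary_z entry"))
  out <- data.frame(
    day = as.integer(vapply(parts, `[[`, "", 1L)),
    artery = toupper(vapply(parts, `[[`, "", 2L)),
    z = as.numeric(vapply(parts, `[[`, "", 3L)))
  if (any(!out$artery %in% c("RCA", "LAD")) || any(!is.finite(out$z))) {
    stop(kd_error("kd_validation_error",
                  "coronary_z arteries must be RCA/LAD with finite z"))
  }
  out
}

#' @rdname parse_coronary_z
#' @export
format_coronary_z <- function(x) {
  if (is.null(x) || nrow(x) == 0L) return(NA_character_)
  paste(sprintf("%d:%s:%s", as.integer(x$day), x$artery,
                sprintf("%.17g", x$z)), collapse = ";")
}
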