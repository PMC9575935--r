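# Delimited-text cohort I/O.
#
# Files are UTF-8 with a header row; comma is the default separator, tab is
# accepted; missing values are empty cells or "NA". Header names are mapped
# onto the canonical schema through the column dictionary so that common
# site-specific variants ("WBC", "wbc_k_per_ul", ...) are recognised.

#' Read a patient cohort from a delimited text file
#'
#' Unknown columns are ignored with a warning; unparseable numeric cells
#' become missing values with a warning; row order is preserved. Mandatory
#' columns are `id`, `illness_days` and the five principal criteria.
#'
#' @param path file path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @param na_strings strings read as missing.
#' @return A validated [as_kd_cohort()] table.
#' @export
read_cohort <- function(path, sep = ",", na_strings = c("", "NA")) {
  if (!file.exists(path)) {
    stop(kd_error("kd_io_error", paste0("cohort file not found: ", path)))
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           na.strings = na_strings, comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           fileEncoding = "UTF-8")
  canon <- map_headers(names(raw))
  unknown <- names(raw)[is.na(canon)]
  if (length(unknown)) {
    warning(sprintf("ignoring unknown column(s): %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  }
  keep <- !is.na(canon)
  raw <- raw[, keep, drop = FALSE]
  names(raw) <- canon[keep]
  missing_mand <- setdiff(kd_mandatory_columns(), names(raw))
  if (length(missing_mand)) {
    stop(kd_error("kd_schema_error", paste0(
      "missing mandatory column(s): ", paste(missing_mand, collapse = ", "))))
  }
  # numeric coercion with a logged count of unparseable cells
  n_unparseable <- 0L
  for (col in c("age_years", "illness_days", kd_analytes("full"))) {
    if (!col %in% names(raw)) next
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    n_unparseable <- n_unparseable + sum(is.na(vals) & !is.na(raw[[col]]))
    raw[[col]] <- vals
  }
  if (n_unparseable > 0L) {
    warning(sprintf("%d unparseable cell(s) set to missing", n_unparseable),
            call. = FALSE)
  }
  absent <- setdiff(kd_analytes("full"), names(raw))
  if (length(absent)) {
    warning(sprintf("analyte column(s) absent, treated as all-missing: %s",
                    paste(absent, collapse = ", ")), call. = FALSE)
  }
  as_kd_cohort(raw, provenance = path)
}

#' Write a cohort to a delimited text file
#'
#' Numeric values are written with 17 significant digits so that
#' `read_cohort(write_cohort(x))` is an exact round trip.
#'
#' @param cohort a `kd_cohort`.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  stopifnot(inherits(cohort, "kd_cohort"))
  out <- as.data.frame(cohort)
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      v <- sprintf("%.17g", out[[col]])
      v[is.na(out[[col]])] <- NA_character_
      out[[col]] <- v
    } else if (is.logical(out[[col]])) {
      out[[col]] <- as.integer(out[[col]])
    }
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, na = "",
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an exclusion log
#'
#' @param log data frame with columns `id`, `reason_code`, `reason` as
#'   produced by [apply_inclusion_filters()].
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(log, path, sep = ",") {
  utils::write.table(log, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
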