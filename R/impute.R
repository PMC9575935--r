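# k-nearest-neighbour imputation of missing laboratory values.
#
# Features are standardized robustly (median centre, IQR scale) because lab
# distributions are right-skewed. Distances between a query and a reference
# row are Euclidean over the standardized features observed in *both* rows,
# normalized by the number of shared features, so rows with different
# missingness patterns remain comparable. Each missing analyte is replaced by
# the mean of that analyte among the k nearest reference rows in which it is
# observed; ties in distance are broken by ascending reference row index.

#' Fit a k-nearest-neighbour lab imputer
#'
#' @param cohort training `kd_cohort` (the imputation reference).
#' @param k number of donor neighbours (default 5).
#' @param features analyte names to impute over; default the Taiwan panel.
#' @return An object of class `kd_imputer`.
#' @export
fit_imputer <- function(cohort, k = 5L, features = kd_analytes("taiwan")) {
  stopifnot(inherits(cohort, "kd_cohort"))
  if (nrow(cohort) == 0L) {
    stop(kd_error("kd_validation_error", "cannot fit imputer on empty cohort"))
  }
  k <- as.integer(k)
  if (k < 1L || k > nrow(cohort)) {
    stop(kd_error("kd_validation_error", sprintf(
      "k = %d must be between 1 and the number of reference records (%d)",
      k, nrow(cohort))))
  }
  x <- as.matrix(as.data.frame(cohort)[, features, drop = FALSE])
  n_obs <- colSums(!is.na(x))
  short <- features[n_obs < k]
  if (length(short)) {
    stop(kd_error("kd_validation_error", sprintf(
      "feature(s) with fewer than k = %d observed values: %s",
      k, paste(short, collapse = ", "))))
  }
  centers <- apply(x, 2, stats::median, na.rm = TRUE)
  scales <- apply(x, 2, stats::IQR, na.rm = TRUE)
  scales[scales <= 0] <- 1  # constant features get unit scale
  structure(list(k = k, features = features, centers = centers,
                 scales = scales, ref_raw = x,
                 ref_std = sweep(sweep(x, 2, centers), 2, scales, "/")),
            class = "kd_imputer")
}

# pairwise NA-aware squared distances and shared-feature counts via masked
# matrix products; query rows as Q (n_q x p), reference as R (n_r x p)
masked_distances <- function(q_std, ref_std) {
  mq <- !is.na(q_std); mr <- !is.na(ref_std)
  a <- q_std; a[!mq] <- 0
  b <- ref_std; b[!mr] <- 0
  n_shared <- mq %*% t(mr)
  d2 <- (a^2) %*% t(mr) + mq %*% t(b^2) - 2 * a %*% t(b)
  d2[d2 < 0] <- 0  # numerical noise
  d <- sqrt(d2 / n_shared)
  d[n_shared == 0] <- Inf
  d
}

#' Impute missing laboratory values
#'
#' Observed values are never changed; every modelled analyte is non-missing
#' in the output. A query row sharing no observed feature with any reference
#' row falls back to the reference medians with a warning.
#'
#' @param model a fitted [fit_imputer()] model.
#' @param cohort `kd_cohort` to complete.
#' @return The cohort with modelled analytes completed.
#' @export
impute_labs <- function(model, cohort) {
  stopifnot(inherits(model, "kd_imputer"), inherits(cohort, "kd_cohort"))
  if (nrow(cohort) == 0L) return(cohort)
  feats <- model$features
  q_raw <- as.matrix(as.data.frame(cohort)[, feats, drop = FALSE])
  if (!any(is.na(q_raw))) return(cohort)
  q_std <- sweep(sweep(q_raw, 2, model$centers), 2, model$scales, "/")
  d <- masked_distances(q_std, model$ref_std)
  orphan <- which(apply(d, 1, function(r) all(!is.finite(r))))
  if (length(orphan)) {
    warning(sprintf(
      "%d record(s) share no observed feature with the reference; imputing with reference medians",
      length(orphan)), call. = FALSE)
  }
  out <- cohort
  for (an in feats) {
    need <- which(is.na(q_raw[, an]))
    if (!length(need)) next
    donors <- which(!is.na(model$ref_raw[, an]))
    for (i in need) {
      if (i %in% orphan) {
        out[[an]][i] <- model$centers[[an]]
        next
      }
      ord <- donors[order(d[i, donors], donors)]
      sel <- ord[seq_len(min(model$k, length(ord)))]
      out[[an]][i] <- mean(model$ref_raw[sel, an])
    }
  }
  out
}

#' @export
print.kd_imputer <- function(x, ...) {
  cat(sprintf("<kd_imputer> k = %d, %d features, %d reference records\n",
              x$k, length(x$features), nrow(x$ref_raw)))
  invisible(x)
}
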