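# Step 1: Fisher linear discriminant scoring with dual thresholds.
#
# The discriminant direction solves (Sw + lambda I) w = mu_KD - mu_FC with
# the pooled within-class covariance Sw and a small ridge
# lambda = 1e-6 * trace(Sw)/p, which keeps the system solvable when binary
# criteria make Sw near-singular. Scores are oriented so that higher means
# more KD-like; the intercept centres the score at the midpoint of the class
# means. Two thresholds carve the score line into FC / indeterminate / KD
# zones; each is calibrated so the corresponding predictive value meets its
# target on the calibration data while calling as many patients as possible.

#' Fit the step-1 linear discriminant
#'
#' @param cohort labelled, imputed `kd_cohort` (both classes with >= 2
#'   records; no missing values among `features`).
#' @param features model features; default [kd_features()] Taiwan profile.
#' @param ridge ridge multiplier on `trace(Sw)/p` (default 1e-6).
#' @return An object of class `kd_lda` with named `weights`, `intercept` and
#'   the feature list. Orientation: mean KD score > mean FC score.
#' @export
fit_lda <- function(cohort, features = kd_features("taiwan"), ridge = 1e-6) {
  xy <- model_matrix(cohort, features, require_labels = TRUE)
  x <- xy$x; y <- xy$y
  n1 <- sum(y == "KD"); n2 <- sum(y == "FC")
  if (n1 < 2L || n2 < 2L) {
    stop(kd_error("kd_validation_error",
                  "each class needs at least 2 records to fit the discriminant"))
  }
  mu1 <- colMeans(x[y == "KD", , drop = FALSE])
  mu2 <- colMeans(x[y == "FC", , drop = FALSE])
  s1 <- stats::cov(x[y == "KD", , drop = FALSE])
  s2 <- stats::cov(x[y == "FC", , drop = FALSE])
  sw <- ((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2)
  p <- ncol(x)
  lambda <- ridge * sum(diag(sw)) / p
  sw_r <- sw + diag(lambda, p)
  w <- tryCatch(solve(sw_r, mu1 - mu2), error = function(e) {
    stop(kd_error("kd_fitting_error", paste0(
      "pooled within-class covariance is singular after regularization: ",
      conditionMessage(e))))
  })
  if (sum(w * (mu1 - mu2)) < 0) w <- -w  # enforce KD-positive orientation
  intercept <- -sum(w * (mu1 + mu2) / 2)
  structure(list(features = features, weights = setNames(as.numeric(w), features),
                 intercept = intercept, n_kd = n1, n_fc = n2, ridge = lambda),
            class = "kd_lda")
}

# numeric design matrix: criteria encoded 0/1, labs/illness days as-is
model_matrix <- function(cohort, features, require_labels = FALSE) {
  stopifnot(inherits(cohort, "kd_cohort"))
  df <- as.data.frame(cohort)
  missing_cols <- setdiff(features, names(df))
  if (length(missing_cols)) {
    stop(kd_error("kd_schema_error", paste0(
      "cohort lacks modelled feature(s): ", paste(missing_cols, collapse = ", "))))
  }
  x <- sapply(features, function(f) as.numeric(df[[f]]))
  x <- matrix(x, nrow = nrow(df), dimnames = list(NULL, features))
  if (anyNA(x)) {
    bad <- features[colSums(is.na(x)) > 0]
    stop(kd_error("kd_validation_error", paste0(
      "missing values in modelled feature(s) (impute first): ",
      paste(bad, collapse = ", "))))
  }
  y <- NULL
  if (require_labels) {
    y <- df$diagnosis
    if (any(is.na(y))) {
      stop(kd_error("kd_validation_error", "diagnosis labels required"))
    }
    if (length(unique(y)) < 2L) {
      stop(kd_error("kd_validation_error",
                    "both classes must be present in the training cohort"))
    }
  }
  list(x = x, y = y)
}

#' Discriminant scores for a cohort
#'
#' `score_i = weights . x_i + intercept`; higher is more KD-like.
#'
#' @param model a `kd_lda`.
#' @param cohort imputed `kd_cohort`.
#' @return Numeric score vector, one value per record.
#' @export
lda_scores <- function(model, cohort) {
  stopifnot(inherits(model, "kd_lda"))
  x <- model_matrix(cohort, model$features)$x
  as.numeric(x %*% model$weights + model$intercept)
}

#' Calibrate the dual score thresholds
#'
#' Candidate cuts are midpoints between adjacent sorted unique scores plus
#' plus/minus infinity. `tau_kd` is the smallest cut such that calling
#' `score >= tau_kd` KD achieves PPV >= `target_ppv` (maximizing the number
#' called KD subject to the constraint); `tau_fc` symmetrically maximizes FC
#' calls subject to NPV >= `target_npv` on `score <= tau_fc`. If the two
#' feasible zones overlap (`tau_kd < tau_fc`) both collapse to the overlap
#' midpoint, leaving an empty indeterminate zone.
#'
#' @param scores numeric scores; `labels` matching `"KD"`/`"FC"` vector.
#' @param labels true class labels.
#' @param target_ppv,target_npv predictive-value targets in (0, 1].
#' @return An object of class `kd_thresholds`: `tau_kd`, `tau_fc`, targets
#'   and the achieved PPV/NPV on the calibration data.
#' @export
calibrate_thresholds <- function(scores, labels, target_ppv = 0.95,
                                 target_npv = 0.95) {
  stopifnot(length(scores) == length(labels),
            target_ppv > 0, target_ppv <= 1, target_npv > 0, target_npv <= 1)
  labels <- as.character(labels)
  if (!all(labels %in% c("KD", "FC"))) {
    stop(kd_error("kd_validation_error", "labels must be 'KD' or 'FC'"))
  }
  if (length(unique(labels)) < 2L) {
    stop(kd_error("kd_calibration_error",
                  "both classes required to calibrate thresholds"))
  }
  us <- sort(unique(scores))
  cuts <- c(-Inf, if (length(us) > 1) (us[-1] + us[-length(us)]) / 2, Inf)
  is_kd <- labels == "KD"
  eps <- 1e-12
  # tau_kd: rule score >= cut => KD
  ppv_at <- vapply(cuts, function(ct) {
    called <- scores >= ct
    if (!any(called)) return(NA_real_)
    sum(called & is_kd) / sum(called)
  }, numeric(1))
  feas_kd <- !is.na(ppv_at) & ppv_at >= target_ppv - eps
  if (!any(feas_kd)) {
    stop(kd_error("kd_calibration_error", sprintf(
      "PPV target %.3f unattainable; best achievable PPV = %.4f",
      target_ppv, max(ppv_at, na.rm = TRUE))))
  }
  tau_kd <- min(cuts[feas_kd])
  # tau_fc: rule score <= cut => FC
  npv_at <- vapply(cuts, function(ct) {
    called <- scores <= ct
    if (!any(called)) return(NA_real_)
    sum(called & !is_kd) / sum(called)
  }, numeric(1))
  feas_fc <- !is.na(npv_at) & npv_at >= target_npv - eps
  if (!any(feas_fc)) {
    stop(kd_error("kd_calibration_error", sprintf(
      "NPV target %.3f unattainable; best achievable NPV = %.4f",
      target_npv, max(npv_at, na.rm = TRUE))))
  }
  tau_fc <- max(cuts[feas_fc])
  if (tau_kd < tau_fc) {  # overlapping feasible zones: empty indeterminate zone
    mid <- (tau_kd + tau_fc) / 2
    tau_kd <- mid; tau_fc <- mid
  }
  calls <- classify_scores(scores, tau_kd, tau_fc)
  achieved_ppv <- safe_ratio(sum(calls == "KD" & is_kd), sum(calls == "KD"))
  achieved_npv <- safe_ratio(sum(calls == "FC" & !is_kd), sum(calls == "FC"))
  structure(list(tau_kd = tau_kd, tau_fc = tau_fc,
                 target_ppv = target_ppv, target_npv = target_npv,
                 achieved_ppv = achieved_ppv, achieved_npv = achieved_npv),
            class = "kd_thresholds")
}

safe_ratio <- function(num, den) if (den > 0) num / den else NA_real_

# closed boundaries, KD checked first
classify_scores <- function(scores, tau_kd, tau_fc) {
  ifelse(scores >= tau_kd, "KD",
         ifelse(scores <= tau_fc, "FC", "INDETERMINATE"))
}

#' Step-1 three-way classification
#'
#' KD iff `score >= tau_kd`; FC iff `score <= tau_fc`; otherwise
#' indeterminate. Boundaries are closed and the KD rule is checked first, so
#' the three calls always partition the cohort.
#'
#' @param model a `kd_lda`; `thresholds` a `kd_thresholds`.
#' @param thresholds calibrated thresholds.
#' @param cohort imputed `kd_cohort`.
#' @return Character vector of calls in `KD`/`FC`/`INDETERMINATE`.
#' @export
classify_step1 <- function(model, thresholds, cohort) {
  stopifnot(inherits(thresholds, "kd_thresholds"))
  classify_scores(lda_scores(model, cohort),
                  thresholds$tau_kd, thresholds$tau_fc)
}

#' @export
print.kd_lda <- function(x, ...) {
  cat(sprintf("<kd_lda> %d features, trained on %d KD / %d FC\n",
              length(x$features), x$n_kd, x$n_fc))
  print(round(x$weights, 4))
  cat("intercept:", format(x$intercept, digits = 4), "\n")
  invisible(x)
}

#' @export
print.kd_thresholds <- function(x, ...) {
  cat(sprintf(
    "<kd_thresholds> tau_fc = %.4g <= tau_kd = %.4g | achieved PPV %.1f%% (target %.0f%%), NPV %.1f%% (target %.0f%%)\n",
    x$tau_fc, x$tau_kd, 100 * x$achieved_ppv, 100 * x$target_ppv,
    100 * x$achieved_npv, 100 * x$target_npv))
  invisible(x)
}
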