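# Step 2: criteria-count-stratified random-forest rescue, and the combined
# two-step pipeline.
#
# Patients left indeterminate by the discriminant are routed, by how many
# principal criteria they present, to one of four stratum forests
# (<=2, 3, 4, 5 criteria). Each forest is trained on its *full* stratum of
# the training cohort (not only on step-1 indeterminates, which would leave
# tiny samples), and its KD vote fraction is thresholded by the same
# PPV/NPV calibration as step 1 — computed on out-of-bag votes so the
# calibration is honest — falling back to a single 0.5 cut when stratum
# calibration is infeasible. Strata with too few training records per class
# get a majority-prior stub flagged in the model.

#' Criteria-count stratum of each record
#'
#' Bins `<=2`, `3`, `4`, `5` partition the possible counts 0..5.
#'
#' @param counts integer criteria counts (or a `kd_cohort`).
#' @return Character vector over `"le2"`, `"3"`, `"4"`, `"5"`.
#' @export
stratum_key <- function(counts) {
  if (inherits(counts, "kd_cohort")) counts <- criteria_count(counts)
  ifelse(counts <= 2, "le2", as.character(counts))
}

forest_strata <- function() c("le2", "3", "4", "5")

#' Default step-2 forest configuration
#'
#' @param n_trees trees per forest (default 500).
#' @param min_per_class minimum training records per class for a stratum to
#'   get a real forest rather than a majority-prior stub (default 10).
#' @param seed integer base seed; each stratum uses `seed + stratum index`.
#' @param target_ppv,target_npv vote-threshold calibration targets.
#' @param mtry,replace,sampsize,maxnodes optional passthroughs to
#'   [randomForest::randomForest()] (defaults: its own defaults).
#' @return A named list of settings.
#' @export
forest_config <- function(n_trees = 500L, min_per_class = 10L, seed = 1L,
                          target_ppv = 0.95, target_npv = 0.95,
                          mtry = NULL, replace = TRUE, sampsize = NULL,
                          maxnodes = NULL) {
  list(n_trees = as.integer(n_trees), min_per_class = as.integer(min_per_class),
       seed = as.integer(seed), target_ppv = target_ppv,
       target_npv = target_npv, mtry = mtry, replace = replace,
       sampsize = sampsize, maxnodes = maxnodes)
}

#' Fit the per-stratum rescue forests
#'
#' @param cohort labelled, imputed training `kd_cohort`.
#' @param features shared feature list (same as step 1).
#' @param config a [forest_config()].
#' @return Named list (one `kd_stratum_forest` per stratum key).
#' @export
fit_stratum_forests <- function(cohort, features = kd_features("taiwan"),
                                config = forest_config()) {
  if (nrow(cohort) == 0L) {
    stop(kd_error("kd_validation_error", "empty training cohort"))
  }
  xy <- model_matrix(cohort, features, require_labels = TRUE)
  strata <- stratum_key(criteria_count(cohort))
  overall_prior <- mean(xy$y == "KD")
  out <- list()
  for (i in seq_along(forest_strata())) {
    st <- forest_strata()[i]
    idx <- which(strata == st)
    ykd <- xy$y[idx] == "KD"
    if (length(idx) == 0L || min(sum(ykd), sum(!ykd)) < config$min_per_class) {
      prior <- if (length(idx)) mean(ykd) else overall_prior
      out[[st]] <- structure(
        list(stratum = st, stub = TRUE, prior = prior,
             vote_thresholds = list(tau_kd = 0.5, tau_fc = 0.5),
             n = length(idx)),
        class = "kd_stratum_forest")
      next
    }
    y <- factor(xy$y[idx], levels = c("FC", "KD"))
    x <- xy$x[idx, , drop = FALSE]
    seed_i <- config$seed + i
    args <- list(x = x, y = y, ntree = config$n_trees,
                 replace = config$replace)
    if (!is.null(config$mtry)) args$mtry <- config$mtry
    if (!is.null(config$sampsize)) args$sampsize <- config$sampsize
    if (!is.null(config$maxnodes)) args$maxnodes <- config$maxnodes
    rf <- with_seed(seed_i, do.call(randomForest::randomForest, args))
    oob <- rf$votes[, "KD"]
    ok <- is.finite(oob)
    vt <- tryCatch({
      th <- calibrate_thresholds(oob[ok], xy$y[idx][ok],
                                 target_ppv = config$target_ppv,
                                 target_npv = config$target_npv)
      list(tau_kd = th$tau_kd, tau_fc = th$tau_fc,
           achieved_ppv = th$achieved_ppv, achieved_npv = th$achieved_npv)
    }, kd_calibration_error = function(e) {
      # infeasible stratum calibration: single 0.5 cut, no indeterminate zone
      list(tau_kd = 0.5, tau_fc = 0.5, fallback = TRUE)
    })
    out[[st]] <- structure(
      list(stratum = st, stub = FALSE, forest = rf, vote_thresholds = vt,
           n = length(idx), seed = seed_i),
      class = "kd_stratum_forest")
  }
  out
}

stratum_vote <- function(sf, x) {
  if (sf$stub) return(rep(sf$prior, nrow(x)))
  as.numeric(predict(sf$forest, newdata = x, type = "prob")[, "KD"])
}

#' Train the full two-step model
#'
#' Fits, in order: the kNN lab imputer on the training cohort; the step-1
#' discriminant on the imputed cohort; the dual score thresholds; and the
#' four stratum forests with their vote thresholds.
#'
#' @param cohort labelled training `kd_cohort`.
#' @param features model features (step 1 and step 2 share them).
#' @param k imputer neighbour count.
#' @param target_ppv,target_npv step-1 calibration targets.
#' @param config step-2 [forest_config()].
#' @return An object of class `kd_twostep`.
#' @export
train_two_step <- function(cohort, features = kd_features("taiwan"), k = 5L,
                           target_ppv = 0.95, target_npv = 0.95,
                           config = forest_config(target_ppv = target_ppv,
                                                  target_npv = target_npv)) {
  analyte_feats <- intersect(features, kd_analytes("full"))
  imputer <- fit_imputer(cohort, k = k, features = analyte_feats)
  imputed <- impute_labs(imputer, cohort)
  lda <- fit_lda(imputed, features = features)
  scores <- lda_scores(lda, imputed)
  thresholds <- calibrate_thresholds(scores, imputed$diagnosis,
                                     target_ppv = target_ppv,
                                     target_npv = target_npv)
  forests <- fit_stratum_forests(imputed, features = features, config = config)
  structure(list(imputer = imputer, lda = lda, thresholds = thresholds,
                 forests = forests, features = features, config = config),
            class = "kd_twostep")
}

#' Classify a cohort with the two-step model
#'
#' Pipeline: impute missing labs, score with the discriminant, call KD/FC/
#' indeterminate against the dual thresholds; step-1 KD/FC calls are final.
#' Step-1 indeterminates are routed by criteria count to their stratum
#' forest, whose KD vote fraction against the stratum vote thresholds yields
#' the final call (possibly still indeterminate).
#'
#' @param model a `kd_twostep`.
#' @param cohort `kd_cohort` to classify (labels not required).
#' @return Data frame `id`, `call`, `stage` (`STEP1`/`STEP2`), `score` (LDA
#'   score at step 1, vote fraction at step 2) and `stratum` (step 2 only).
#' @export
classify_two_step <- function(model, cohort) {
  stopifnot(inherits(model, "kd_twostep"))
  imputed <- impute_labs(model$imputer, cohort)
  scores <- lda_scores(model$lda, imputed)
  calls <- classify_scores(scores, model$thresholds$tau_kd,
                           model$thresholds$tau_fc)
  res <- data.frame(id = cohort$id, call = calls, stage = "STEP1",
                    score = scores, stratum = NA_character_,
                    stringsAsFactors = FALSE)
  ind <- which(calls == "INDETERMINATE")
  if (length(ind)) {
    x <- model_matrix(imputed, model$features)$x
    strata <- stratum_key(criteria_count(imputed))
    for (st in unique(strata[ind])) {
      rows <- ind[strata[ind] == st]
      sf <- model$forests[[st]]
      v <- stratum_vote(sf, x[rows, , drop = FALSE])
      res$call[rows] <- classify_scores(v, sf$vote_thresholds$tau_kd,
                                        sf$vote_thresholds$tau_fc)
      res$stage[rows] <- "STEP2"
      res$score[rows] <- v
      res$stratum[rows] <- st
    }
  }
  res
}

#' @export
print.kd_twostep <- function(x, ...) {
  cat("<kd_twostep>\n")
  print(x$lda)
  print(x$thresholds)
  for (st in forest_strata()) {
    sf <- x$forests[[st]]
    cat(sprintf("  stratum %-3s: %s (n = %d)\n", st,
                if (sf$stub) sprintf("majority-prior stub (p_KD = %.2f)", sf$prior)
                else sprintf("forest, vote cuts [%.3f, %.3f]",
                             sf$vote_thresholds$tau_fc, sf$vote_thresholds$tau_kd),
                sf$n))
  }
  invisible(x)
}
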