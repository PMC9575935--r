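# Independent oracles used across the suite. Each recomputes a quantity by
# brute force (enumeration, exhaustive search, direct loops), never through
# the implementation it checks.

# two-sided Fisher p by full hypergeometric enumeration over all tables with
# the observed margins, minimum-likelihood convention
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ])   # row 1 total
  n <- sum(tab[2, ])   # row 2 total
  k <- sum(tab[, 1])   # column 1 total
  lo <- max(0L, k - n); hi <- min(k, m)
  dens <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(dens[dens <= p_obs * (1 + 1e-7)])
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
oracle_mw_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - na * (na + 1) / 2
  }
  u_obs <- u_of(seq_len(na))
  combos <- utils::combn(na + nb, na)
  us <- apply(combos, 2, u_of)
  pl <- mean(us <= u_obs); pu <- mean(us >= u_obs)
  min(1, 2 * min(pl, pu))
}

# brute-force kNN imputation mirroring the documented variant: robust
# standardization, shared-feature-normalized Euclidean distance, per-analyte
# donor pools, index tie-break
oracle_knn_impute <- function(cohort, k, features) {
  x <- as.matrix(as.data.frame(cohort)[, features, drop = FALSE])
  centers <- apply(x, 2, median, na.rm = TRUE)
  scales <- apply(x, 2, IQR, na.rm = TRUE)
  scales[scales <= 0] <- 1
  z <- sweep(sweep(x, 2, centers), 2, scales, "/")
  n <- nrow(x)
  out <- x
  for (i in seq_len(n)) {
    miss <- which(is.na(x[i, ]))
    if (!length(miss)) next
    d <- rep(Inf, n)
    for (j in seq_len(n)) {
      shared <- which(!is.na(z[i, ]) & !is.na(z[j, ]))
      if (length(shared)) d[j] <- sqrt(sum((z[i, shared] - z[j, shared])^2) /
                                         length(shared))
    }
    for (f in miss) {
      donors <- which(!is.na(x[, f]))
      if (all(!is.finite(d))) { out[i, f] <- centers[f]; next }
      ord <- donors[order(d[donors], donors)]
      sel <- ord[seq_len(min(k, length(ord)))]
      out[i, f] <- mean(x[sel, f])
    }
  }
  out
}

# exhaustive threshold scan: try calling the top j scores KD for every j and
# the bottom j scores FC for every j; return the maximal feasible call sets
oracle_threshold_calls <- function(scores, labels, target_ppv, target_npv) {
  n <- length(scores)
  ord_desc <- order(scores, decreasing = TRUE)
  best_kd <- logical(n)
  for (j in seq_len(n)) {
    # a cut at a score value captures all tied values too
    cutoff <- scores[ord_desc[j]]
    called <- scores >= cutoff
    ppv <- sum(called & labels == "KD") / sum(called)
    if (ppv >= target_ppv - 1e-12 && sum(called) > sum(best_kd)) {
      best_kd <- called
    }
  }
  best_fc <- logical(n)
  ord_asc <- order(scores)
  for (j in seq_len(n)) {
    cutoff <- scores[ord_asc[j]]
    called <- scores <= cutoff
    npv <- sum(called & labels == "FC") / sum(called)
    if (npv >= target_npv - 1e-12 && sum(called) > sum(best_fc)) {
      best_fc <- called
    }
  }
  list(kd = best_kd, fc = best_fc)
}

# exhaustive depth-1 Gini stump: best single split over all features
oracle_stump <- function(x, y) {
  gini <- function(lab) {
    if (!length(lab)) return(0)
    p <- mean(lab == "KD"); 2 * p * (1 - p)
  }
  best <- list(impurity = Inf)
  for (f in seq_len(ncol(x))) {
    vals <- sort(unique(x[, f]))
    if (length(vals) < 2) next
    cuts <- (vals[-1] + vals[-length(vals)]) / 2
    for (ct in cuts) {
      left <- x[, f] <= ct
      imp <- mean(left) * gini(y[left]) + mean(!left) * gini(y[!left])
      if (imp < best$impurity - 1e-12) {
        best <- list(impurity = imp, feature = f, cut = ct,
                     p_kd_left = mean(y[left] == "KD"),
                     p_kd_right = mean(y[!left] == "KD"))
      }
    }
  }
  best
}

# direct 2x3 count/metric recomputation by looping over records
oracle_confusion <- function(truth, calls) {
  cnt <- function(tr, cl) sum(truth == tr & calls == cl)
  n_kd <- sum(truth == "KD"); n_fc <- sum(truth == "FC")
  list(sensitivity = cnt("KD", "KD") / n_kd,
       specificity = cnt("FC", "FC") / n_fc,
       ppv = cnt("KD", "KD") / (cnt("KD", "KD") + cnt("FC", "KD")),
       npv = cnt("FC", "FC") / (cnt("FC", "FC") + cnt("KD", "FC")),
       ind_kd = cnt("KD", "INDETERMINATE") / n_kd,
       ind_fc = cnt("FC", "INDETERMINATE") / n_fc)
}

# --- fixture builders -------------------------------------------------------

# minimal valid cohort; any canonical column can be overridden via ...
toy_cohort <- function(n, diagnosis = rep(c("KD", "FC"), length.out = n),
                       illness_days = rep(5L, n), ...) {
  df <- data.frame(id = sprintf("P%03d", seq_len(n)), diagnosis = diagnosis,
                   illness_days = illness_days, stringsAsFactors = FALSE)
  for (cr in kd_criteria()) df[[cr]] <- rep(TRUE, n)
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  as_kd_cohort(df, provenance = "test")
}

# labelled cohort with two well-separated lab profiles, complete data
separable_cohort <- function(n_kd = 20, n_fc = 20, seed = 1) {
  set.seed(seed)
  n <- n_kd + n_fc
  g <- c(rep("KD", n_kd), rep("FC", n_fc))
  df <- data.frame(id = sprintf("S%03d", seq_len(n)), diagnosis = g,
                   illness_days = sample(1:9, n, replace = TRUE),
                   age_years = runif(n, 0.2, 5), stringsAsFactors = FALSE)
  for (cr in kd_criteria()) {
    df[[cr]] <- ifelse(g == "KD", runif(n) < 0.9, runif(n) < 0.4)
  }
  df$cervical_lymphadenopathy[df$diagnosis == "FC"] <-
    df$cervical_lymphadenopathy[df$diagnosis == "FC"] |
    rowSums(sapply(kd_criteria(), function(cr) df[[cr]]))[df$diagnosis == "FC"] == 0
  for (an in kd_analytes("taiwan")) {
    mu <- if (an == "crp") c(80, 20) else c(12, 9)
    df[[an]] <- rlnorm(n, log(ifelse(g == "KD", mu[1], mu[2])), 0.3)
  }
  df$hemoglobin <- pmin(df$hemoglobin, 25)
  for (an in grep("_pct$", kd_analytes("taiwan"), value = TRUE)) {
    df[[an]] <- pmin(df[[an]], 100)
  }
  as_kd_cohort(df, provenance = "test-separable")
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "kdtriage", mustWork = TRUE)
}

read_fixture <- function(name) {
  read.csv(fixture_path(name), comment.char = "#", stringsAsFactors = FALSE)
}

# expand a truth/call/count table into per-patient vectors
expand_confusion <- function(df) {
  truth <- rep(df$truth, df$count)
  calls <- rep(df$call, df$count)
  list(truth = truth, calls = calls)
}
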