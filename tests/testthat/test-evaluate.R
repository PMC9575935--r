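test_that("the published confusion counts yield the published headline metrics", {
  fx <- expand_confusion(read_fixture("taiwan_confusion.csv"))
  s <- summarize_calls(fx$truth, fx$calls)
  expect_equal(s$sensitivity, 379 / 418)
  expect_equal(s$specificity, 223 / 259)
  expect_equal(s$ppv, 379 / 409)
  expect_equal(s$npv, 223 / 247)
  expect_equal(round(100 * s$sensitivity, 1), 90.7)
  expect_equal(round(100 * s$specificity, 1), 86.1)
  expect_equal(round(100 * s$ppv, 1), 92.7)
  expect_equal(round(100 * s$npv, 1), 90.3)
  expect_equal(s$indeterminate_rate_kd, 15 / 418)
  expect_equal(s$indeterminate_rate_fc, 6 / 259)
  expect_equal(s$misclassified_rate_kd, 24 / 418)
  expect_equal(s$misclassified_rate_fc, 30 / 259)
})

test_that("a perfect classifier scores 100% everywhere and zero rates", {
  truth <- rep(c("KD", "FC"), c(7, 9))
  s <- summarize_calls(truth, truth)
  for (m in c("sensitivity", "specificity", "ppv", "npv")) {
    expect_equal(s[[m]], 1)
  }
  expect_equal(s$indeterminate_rate_kd + s$indeterminate_rate_fc +
                 s$misclassified_rate_kd + s$misclassified_rate_fc, 0)
})

test_that("summaries match a hand-count oracle and ignore record order", {
  set.seed(31)
  truth <- sample(c("KD", "FC"), 30, replace = TRUE)
  truth[1:2] <- c("KD", "FC")
  calls <- sample(c("KD", "FC", "INDETERMINATE"), 30, replace = TRUE)
  s <- summarize_calls(truth, calls)
  o <- oracle_confusion(truth, calls)
  expect_equal(s$sensitivity, o$sensitivity)
  expect_equal(s$specificity, o$specificity)
  expect_equal(s$ppv, o$ppv)
  expect_equal(s$npv, o$npv)
  perm <- sample(30)
  s2 <- summarize_calls(truth[perm], calls[perm])
  expect_equal(s2$counts, s$counts)
  # exact partition identity within each true class
  expect_equal(s$sensitivity + s$indeterminate_rate_kd +
                 s$misclassified_rate_kd, 1)
  expect_equal(s$specificity + s$indeterminate_rate_fc +
                 s$misclassified_rate_fc, 1)
})

test_that("zero-denominator metrics are NA, never zero", {
  s <- summarize_calls(rep("KD", 4), rep(c("KD", "INDETERMINATE"), 2))
  expect_true(is.na(s$specificity))
  expect_true(is.na(s$npv))
  expect_equal(s$sensitivity, 0.5)
})

test_that("id joins are enforced", {
  co <- toy_cohort(3)
  res <- data.frame(id = c("P001", "P002", "P004"),
                    call = c("KD", "FC", "KD"))
  expect_error(confusion_from_results(co, res),
               class = "kd_validation_error")
  res$id <- co$id
  expect_s3_class(confusion_from_results(co, res), "kd_confusion")
})

test_that("the published age-stratified counts reproduce the infant correct rate", {
  ag <- read_fixture("taiwan_age_strata.csv")
  # rebuild per-patient truth/call vectors from the counts
  co <- toy_cohort(sum(ag$n), diagnosis = "KD",
                   age_years = rep(c(0.5, 2), ag$n))
  calls <- unlist(mapply(function(c_, m, i) {
    rep(c("KD", "FC", "INDETERMINATE"), c(c_, m, i))
  }, ag$correct, ag$misclassified, ag$indeterminate, SIMPLIFY = FALSE))
  res <- data.frame(id = co$id, call = calls)
  rep_age <- stratified_report(co, res, "age")
  inf <- rep_age[["<1y"]]
  expect_equal(inf$sensitivity, 140 / 157)
  expect_equal(round(100 * inf$sensitivity, 1), 89.2)
  expect_equal(sum(inf$counts), 157)
  old <- rep_age[[">=1y"]]
  expect_equal(old$sensitivity, 239 / 261)
})

test_that("criteria-count stratification reproduces the published per-stratum rates", {
  cs <- read_fixture("taiwan_criteria_strata.csv")
  n <- sum(cs$n)
  crit_of <- function(st) switch(st, le2 = 2L, `3` = 3L, ge4 = 4L)
  counts <- unlist(mapply(rep, vapply(cs$stratum, crit_of, integer(1)), cs$n,
                          SIMPLIFY = FALSE))
  diagnosis <- rep(cs$group, cs$n)
  df <- data.frame(id = sprintf("T%03d", seq_len(n)), diagnosis = diagnosis,
                   illness_days = 5L, stringsAsFactors = FALSE)
  for (cr in kd_criteria()) df[[cr]] <- FALSE
  ord <- list(kd_criteria()[1:2], kd_criteria()[1:3], kd_criteria()[1:4])
  for (i in seq_len(n)) {
    for (cr in ord[[counts[i] - 1L]]) df[[cr]][i] <- TRUE
  }
  co <- as_kd_cohort(df)
  own <- ifelse(diagnosis == "KD", "KD", "FC")
  other <- ifelse(diagnosis == "KD", "FC", "KD")
  calls <- unlist(mapply(function(ok, mis, ind, own_, other_) {
    rep(c(own_, other_, "INDETERMINATE"), c(ok, mis, ind))
  }, cs$correct, cs$misclassified, cs$indeterminate,
     rep(cs$group, 1), ifelse(cs$group == "KD", "FC", "KD"),
     SIMPLIFY = FALSE))
  res <- data.frame(id = co$id, call = calls)
  rep_cc <- stratified_report(co, res, "criteria")
  expect_equal(rep_cc[["3"]]$sensitivity, 16 / 36)
  expect_equal(round(100 * rep_cc[["3"]]$sensitivity, 1), 44.4)
  expect_equal(rep_cc[["le2"]]$sensitivity, 2 / 14)
  expect_equal(rep_cc[["ge4"]]$sensitivity, 361 / 368)
  expect_equal(rep_cc[["le2"]]$specificity, 157 / 158)
  expect_equal(rep_cc[["3"]]$specificity, 56 / 59)
  expect_equal(rep_cc[["ge4"]]$specificity, 10 / 42)
})

test_that("a single-stratum cohort reduces stratified reporting to the plain summary", {
  co <- separable_cohort(8, 8, seed = 32)
  co$illness_days <- rep(4L, 16)
  res <- data.frame(id = co$id, call = rep(c("KD", "FC"), each = 8))
  sr <- stratified_report(co, res, "illness_day")
  expect_equal(names(sr), "<8d")
  s <- summarize_calls(co$diagnosis, res$call)
  expect_equal(sr[["<8d"]]$counts, s$counts)
})

test_that("fisher_exact handles the trivial and published-table cases", {
  expect_equal(fisher_exact(matrix(1, 2, 2))$p, 1)
  # cervical lymphadenopathy in the <=2-criteria stratum: printed p = 1
  expect_equal(round(fisher_exact(matrix(c(3, 11, 42, 116), 2, byrow = TRUE))$p, 3), 1)
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)),
               class = "kd_validation_error")
})

test_that("fisher_exact equals hypergeometric enumeration on random small tables", {
  set.seed(33)
  for (i in 1:60) {
    n <- sample(4:60, 1)
    tab <- matrix(as.numeric(rmultinom(1, n, runif(4, 0.05, 1))), 2, 2)
    expect_equal(fisher_exact(tab)$p, oracle_fisher_p(tab), tolerance = 1e-9,
                 label = paste(tab, collapse = ","))
  }
})

test_that("mann_whitney_u covers the symmetric, extreme and oracle cases", {
  sym <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(sym$U, 4.5)
  expect_equal(sym$p, 1, tolerance = 1e-9)
  sep <- mann_whitney_u(c(1, 2), c(10, 11))
  expect_equal(sep$U, 0)
  expect_equal(sep$p, 2 / choose(4, 2), tolerance = 1e-9)
  expect_equal(sep$method, "exact")
  expect_error(mann_whitney_u(numeric(0), 1:3), class = "kd_validation_error")
  set.seed(34)
  for (i in 1:8) {
    a <- round(rnorm(5), 3); b <- round(rnorm(sample(4:7, 1), 0.5), 3)
    r <- mann_whitney_u(a, b)
    expect_equal(r$p, oracle_mw_p(a, b), tolerance = 1e-9)
  }
})

test_that("the approximate branch tracks the exact branch near the size boundary", {
  set.seed(35)
  for (i in 1:5) {
    a <- rnorm(10); b <- rnorm(10, 0.3)
    exact_p <- mann_whitney_u(a, b)$p  # n = 20, no ties: exact branch
    approx_p <- wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(exact_p - approx_p), 0.01)
  }
})

test_that("median ratios report per-bin KD/FC ratios with guards", {
  co <- separable_cohort(10, 10, seed = 36)
  co$illness_days <- rep(c(4L, 9L), 10)
  rr <- median_ratio_report(co, analytes = c("crp", "wbc"))
  expect_equal(nrow(rr), 4)
  row <- rr[rr$analyte == "crp" & rr$bin == "<8d", ]
  kd <- co$crp[co$illness_days < 8 & co$diagnosis == "KD"]
  fc <- co$crp[co$illness_days < 8 & co$diagnosis == "FC"]
  expect_equal(row$ratio, median(kd) / median(fc))
  expect_equal(row$p, mann_whitney_u(kd, fc)$p)
  # identical distributions give ratio 1
  co2 <- toy_cohort(8, crp = rep(c(5, 6, 7, 8), 2),
                    diagnosis = rep(c("KD", "FC"), each = 4))
  rr2 <- median_ratio_report(co2, analytes = "crp")
  expect_equal(rr2$ratio[rr2$bin == "<8d"], 1)
  # zero FC median flagged undefined, not an error
  co3 <- toy_cohort(6, eos_pct = c(1, 2, 3, 0, 0, 0),
                    diagnosis = rep(c("KD", "FC"), each = 3))
  rr3 <- median_ratio_report(co3, analytes = "eos_pct")
  expect_true(is.na(rr3$ratio[rr3$bin == "<8d"]))
  expect_match(rr3$note[rr3$bin == "<8d"], "undefined")
  # empty bin flagged, not an error
  expect_match(rr3$note[rr3$bin == "8-10d"], "empty")
})
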