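# Model bundle persistence: a directory holding a JSON manifest, the
# discriminant and thresholds as JSON text, and the imputer/forest
# components. The manifest fingerprint is an md5 over a canonical text
# rendering of the fitted numbers, so retraining on identical data and seeds
# reproduces it bit for bit.

bundle_schema_version <- 1L

model_fingerprint <- function(model) {
  num <- function(x) sprintf("%.12g", as.numeric(x))
  parts <- c(
    "features", model$features,
    "weights", num(model$lda$weights), num(model$lda$intercept),
    "thresholds", num(unlist(model$thresholds[c("tau_kd", "tau_fc",
                                                "target_ppv", "target_npv")])),
    "imputer", num(model$imputer$k), num(model$imputer$centers),
    num(model$imputer$scales), num(nrow(model$imputer$ref_raw)))
  for (st in forest_strata()) {
    sf <- model$forests[[st]]
    parts <- c(parts, st, num(sf$n),
               if (sf$stub) c("stub", num(sf$prior))
               else c(num(sf$seed), num(sf$vote_thresholds$tau_kd),
                      num(sf$vote_thresholds$tau_fc)))
  }
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(parts, tf)
  unname(tools::md5sum(tf))
}

#' Write a fitted two-step model to a bundle directory
#'
#' @param model a `kd_twostep`.
#' @param dir directory to create/populate.
#' @return `dir`, invisibly.
#' @export
write_model_bundle <- function(model, dir) {
  stopifnot(inherits(model, "kd_twostep"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lda <- list(features = model$features,
              weights = as.list(model$lda$weights),
              intercept = model$lda$intercept,
              n_kd = model$lda$n_kd, n_fc = model$lda$n_fc,
              thresholds = model$thresholds[c("tau_kd", "tau_fc", "target_ppv",
                                              "target_npv", "achieved_ppv",
                                              "achieved_npv")])
  jsonlite::write_json(lda, file.path(dir, "lda.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  saveRDS(model$imputer, file.path(dir, "imputer.rds"))
  saveRDS(model$forests, file.path(dir, "forests.rds"))
  manifest <- list(
    schema_version = bundle_schema_version,
    package = "kdtriage",
    package_version = as.character(utils::packageVersion("kdtriage")),
    features = model$features,
    imputer_k = model$imputer$k,
    forest_seeds = setNames(lapply(forest_strata(), function(st)
      if (model$forests[[st]]$stub) NA_integer_ else model$forests[[st]]$seed),
      forest_strata()),
    stub_strata = forest_strata()[vapply(model$forests[forest_strata()],
                                         `[[`, logical(1), "stub")],
    fingerprint = model_fingerprint(model))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a model bundle
#'
#' @param dir bundle directory written by [write_model_bundle()].
#' @return A `kd_twostep`.
#' @export
read_model_bundle <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) {
    stop(kd_error("kd_io_error", paste0("not a model bundle: ", dir)))
  }
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  if (!identical(as.integer(manifest$schema_version), bundle_schema_version)) {
    stop(kd_error("kd_io_error", sprintf(
      "unsupported bundle schema version %s", manifest$schema_version)))
  }
  lda_raw <- jsonlite::read_json(file.path(dir, "lda.json"),
                                 simplifyVector = TRUE)
  lda <- structure(list(features = lda_raw$features,
                        weights = unlist(lda_raw$weights),
                        intercept = lda_raw$intercept,
                        n_kd = lda_raw$n_kd, n_fc = lda_raw$n_fc),
                   class = "kd_lda")
  thresholds <- structure(lda_raw$thresholds, class = "kd_thresholds")
  structure(list(imputer = readRDS(file.path(dir, "imputer.rds")),
                 lda = lda, thresholds = thresholds,
                 forests = readRDS(file.path(dir, "forests.rds")),
                 features = lda_raw$features, manifest = manifest),
            class = "kd_twostep")
}
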