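# One entry point wiring the whole analysis: simulate -> features ->
# train-svm -> predict -> agreement -> intensity -> ancova -> report.
# Every stage writes plain-text artifacts (CSV / JSON) into the output
# directory, guarded by a manifest recording the configuration hash and
# seed; completed stages are skipped unless forced.

.default_run_config <- function() {
  list(
    out_dir = "finsexer_run",
    seed = 1L,
    sim = list(n_per_cell = 25L),
    svm = list(bins = 64L, gamma = NULL, cost = 1),
    ancova = list(covariate = "body_weight_g", max_degree = 3,
                  alpha_stay = 0.05, outlier_threshold = 3)
  )
}

.pipeline_stages <- c("simulate", "features", "train-svm", "predict",
                      "agreement", "intensity", "ancova", "report")

.stage_artifacts <- function(out_dir) {
  list(
    "simulate" = file.path(out_dir, "metadata.csv"),
    "features" = file.path(out_dir, "features.csv"),
    "train-svm" = file.path(out_dir, "svm_model.json"),
    "predict" = file.path(out_dir, "scores.csv"),
    "agreement" = file.path(out_dir, "agreement.json"),
    "intensity" = file.path(out_dir, "intensity.csv"),
    "ancova" = file.path(out_dir, "ancova.json"),
    "report" = file.path(out_dir, "report.json")
  )
}

.read_manifest <- function(path) {
  if (file.exists(path)) jsonlite::read_json(path, simplifyVector = TRUE) else NULL
}

#' Run the sexing pipeline
#'
#' Executes the requested stages in dependency order. A stage whose
#' artifact already exists under the same configuration hash is skipped
#' (logged) unless `force = TRUE`. A stage whose upstream artifact is
#' missing fails with an error naming the stage to run first.
#'
#' @param config Nested list (see the package vignette): `out_dir`, `seed`,
#'   `sim` (arguments to [sim_config()]), `svm` (`bins`, `gamma`, `cost`),
#'   `ancova` (arguments to [ancova_spec()]). Missing entries take
#'   defaults.
#' @param stages Character subset of
#'   `simulate, features, train-svm, predict, agreement, intensity,
#'   ancova, report` (default: all).
#' @param force Rerun stages whose artifacts already exist.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the named list of artifact paths written or reused.
#' @export
run_pipeline <- function(config = list(), stages = .pipeline_stages,
                         force = FALSE, quiet = FALSE) {
  cfg <- utils::modifyList(.default_run_config(), config)
  stages <- match.arg(stages, .pipeline_stages, several.ok = TRUE)
  stages <- .pipeline_stages[.pipeline_stages %in% stages]
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  art <- .stage_artifacts(out_dir)
  manifest_path <- file.path(out_dir, "manifest.json")
  cfg_for_hash <- cfg[setdiff(names(cfg), "out_dir")]
  cfg_hash <- rlang::hash(cfg_for_hash)
  manifest <- .read_manifest(manifest_path)
  if (is.null(manifest) || !identical(manifest$config_hash, cfg_hash)) {
    manifest <- list(config_hash = cfg_hash, seed = cfg$seed, stages = list())
  }
  say <- function(...) if (!quiet) message(...)
  need <- function(stage) {
    if (!file.exists(art[[stage]])) {
      stop("missing artifact for stage `", stage, "`; run it first", call. = FALSE)
    }
  }
  done <- function(stage) {
    manifest$stages[[stage]] <<- list(artifact = art[[stage]],
                                      completed = TRUE)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  }
  fresh <- function(stage) {
    if (force) return(TRUE)
    if (!file.exists(art[[stage]])) return(TRUE)
    if (isTRUE(manifest$stages[[stage]]$completed)) {
      say("skipping `", stage, "` (up to date)")
      return(FALSE)
    }
    TRUE
  }

  for (stage in stages) {
    if (!fresh(stage)) next
    say("running `", stage, "`")
    switch(stage,
      "simulate" = {
        sc <- do.call(sim_config, utils::modifyList(cfg$sim, list(seed = cfg$seed)))
        cohort <- simulate_cohort(sc)
        write_cohort(cohort, out_dir)
      },
      "features" = {
        need("simulate")
        cohort <- load_cohort(art[["simulate"]], out_dir)
        feats <- fin_features(cohort, bins = cfg$svm$bins)
        write_features(feats, art[["features"]])
      },
      "train-svm" = {
        need("features")
        feats <- read_features(art[["features"]])
        model <- svm_train(feats, gamma = cfg$svm$gamma, cost = cfg$svm$cost)
        svm_save(model, art[["train-svm"]])
      },
      "predict" = {
        need("features"); need("train-svm")
        feats <- read_features(art[["features"]])
        model <- svm_load(art[["train-svm"]])
        scores <- svm_score(model, feats)
        utils::write.csv(scores, art[["predict"]], row.names = FALSE)
      },
      "agreement" = {
        need("predict")
        scores <- utils::read.csv(art[["predict"]], stringsAsFactors = FALSE)
        rep <- agreement_report(scores)
        jsonlite::write_json(rep, art[["agreement"]], auto_unbox = TRUE, digits = NA)
      },
      "intensity" = {
        need("predict")
        scores <- utils::read.csv(art[["predict"]], stringsAsFactors = FALSE)
        scores <- add_intensity(scores)
        utils::write.csv(scores, art[["intensity"]], row.names = FALSE)
      },
      "ancova" = {
        need("intensity"); need("simulate")
        scores <- utils::read.csv(art[["intensity"]], stringsAsFactors = FALSE)
        meta <- utils::read.csv(art[["simulate"]], stringsAsFactors = FALSE)
        dat <- dplyr::inner_join(
          scores[, c("id", "z")],
          meta[, c("id", "group", "true_sex", "body_weight_g", "total_length_mm")],
          by = "id")
        dat$sex <- dat$true_sex
        spec <- do.call(ancova_spec, cfg$ancova)
        fit <- backward_eliminate(fit_ancova(dat, spec))
        filt <- filter_outliers(fit)
        lm_out <- ls_means(filt$fit)
        out <- list(
          covariate = spec$covariate,
          kept_terms = filt$fit$terms,
          eliminated = filt$fit$eliminated,
          anova = as.data.frame(ancova_anova(filt$fit)),
          ls_means = as.data.frame(lm_out$means),
          contrasts = as.data.frame(lm_out$contrasts),
          outlier_ids = filt$outliers$id
        )
        jsonlite::write_json(out, art[["ancova"]], auto_unbox = TRUE, digits = NA)
      },
      "report" = {
        need("agreement")
        agr <- jsonlite::read_json(art[["agreement"]], simplifyVector = TRUE)
        rep <- list(config_hash = cfg_hash, seed = cfg$seed, agreement = agr)
        if (file.exists(art[["ancova"]])) {
          rep$ancova <- jsonlite::read_json(art[["ancova"]], simplifyVector = TRUE)
        }
        jsonlite::write_json(rep, art[["report"]], auto_unbox = TRUE, digits = NA)
      }
    )
    done(stage)
  }
  invisible(art[stages])
}
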