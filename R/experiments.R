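# The two study-level harnesses:
#   evaluation-1 — CV generalization estimates per pipeline, compared with
#                  out-of-sample performance of the finalized model;
#   evaluation-2 — the four OOS confound-handling methods, on a
#                  same-distribution and a shifted cohort.

resolve_datasets <- function(config) {
  if (!is.null(config$synthetic)) {
    sc_args <- config$synthetic
    shift_args <- sc_args$shift
    sc_args$shift <- NULL
    n_oos <- sc_args$n_oos %||% 200
    sc_args$n_oos <- NULL
    sc <- do.call(synthetic_config, sc_args)
    train <- generate_confounded_dataset(sc)
    oos_same <- generate_shifted_oos(sc, shift_config(), n_oos)
    oos_shifted <- NULL
    if (!is.null(shift_args)) {
      oos_shifted <- generate_shifted_oos(sc, do.call(shift_config, shift_args),
                                          n_oos)
    }
    list(train = train, oos = oos_same, oos_shifted = oos_shifted,
         config = unclass(sc), hashes = list(synthetic = content_hash(unclass(sc))))
  } else if (!is.null(config$files)) {
    f <- config$files
    train <- load_dataset(f$features, f$pheno, f$target_col, f$confound_cols)
    oos <- NULL
    if (!is.null(f$oos_features)) {
      oos <- load_dataset(f$oos_features, f$oos_pheno, f$target_col,
                          f$confound_cols)
    }
    list(train = train, oos = oos, oos_shifted = NULL, config = config$files,
         hashes = as.list(tools::md5sum(unlist(f[c("features", "pheno")]))))
  } else {
    stop2("config must contain exactly one of 'synthetic' or 'files'")
  }
}

#' Read an experiment configuration from YAML
#'
#' The file holds either a `synthetic:` block (arguments of
#' [synthetic_config()], optionally `n_oos:` and a nested `shift:` block of
#' [shift_config()] arguments) or a `files:` block (`features`, `pheno`,
#' `target_col`, optional `confound_cols`, `oos_features`, `oos_pheno`),
#' plus optional `pipelines:`, `estimator:` (`kind`, `inner_folds`),
#' `cv:` (`n_folds`, `n_repeats`, `seed`) and `out_dir:`.
#'
#' @param path YAML file path.
#' @return the parsed config list.
#' @export
read_experiment_config <- function(path) {
  yaml::read_yaml(path)
}

config_pieces <- function(config, seed = NULL) {
  est_args <- config$estimator %||% list()
  est <- estimator_spec(est_args$kind %||% "ridge",
                        grid = est_args$grid,
                        inner_folds = est_args$inner_folds %||% 5)
  cv_args <- config$cv %||% list()
  cv <- cv_scheme(cv_args$n_folds %||% 10, cv_args$n_repeats %||% 10,
                  cv_args$stratified %||% TRUE,
                  seed %||% cv_args$seed %||% 0)
  list(estimator = est, cv = cv)
}

#' Evaluation 1: CV generalization estimates vs out-of-sample performance
#'
#' Runs every requested pipeline under repeated stratified k-fold CV on the
#' training sample, finalizes each pipeline on the full training sample, and
#' scores the held-out cohort — one consolidated row per pipeline with the
#' CV means and the OOS metrics side by side.
#'
#' @param config experiment config list (see [read_experiment_config()]).
#' @param seed overriding integer seed (default: the config's).
#' @return list: `table` (data frame, one row per pipeline), `reports`
#'   (named list of `evaluation_report`s), `provenance`.
#' @export
run_evaluation_one <- function(config, seed = NULL) {
  data <- resolve_datasets(config)
  pieces <- config_pieces(config, seed)
  pipelines <- config$pipelines %||% all_pipelines()
  reports <- list()
  rows <- lapply(pipelines, function(pl) {
    rep_ <- run_pipeline_cv(data$train, pl, pieces$estimator, pieces$cv)
    reports[[pl]] <<- rep_
    s <- stats::setNames(rep_$summary$mean, rep_$summary$metric)
    row <- data.frame(pipeline = pl, estimator = pieces$estimator$kind,
                      cv_auc = s["auc"], cv_f1 = s["f1"],
                      cv_balanced_accuracy = s["balanced_accuracy"],
                      row.names = NULL)
    if (!is.null(data$oos)) {
      dm <- finalize_model(data$train, pl, pieces$estimator,
                           seed = pieces$cv$seed)
      om <- oos_train_to_test(dm, data$oos)$metrics
      row$oos_auc <- om$auc
      row$oos_f1 <- om$f1
      row$oos_balanced_accuracy <- om$balanced_accuracy
    }
    row
  })
  list(table = do.call(rbind, rows), reports = reports,
       provenance = list(config = data$config, hashes = data$hashes,
                         cv = unclass(pieces$cv),
                         estimator = pieces$estimator$kind))
}

#' Evaluation 2: four OOS confound-handling methods per cohort
#'
#' Finalizes one confound-removing pipeline on the training sample and
#' scores each OOS cohort under: train-to-test application of the removal
#' model, self-WDCR on the OOS sample, self-CVCR on the OOS sample, and
#' whole-data removal on the combined train + OOS sample (re-split into the
#' original membership, decoder re-fitted).
#'
#' @param config experiment config list; its `synthetic$shift` block (or
#'   `files$oos_*` entries) defines the shifted cohort.
#' @param pipeline the removal pipeline (default `"CVCR-ZAC"` for
#'   train-to-test/self methods; the combined method uses its WDCR analogue
#'   by construction).
#' @param seed overriding integer seed.
#' @return list: `table` (method x cohort data frame), `details` (nested
#'   per-cohort results incl. diagnostics), `provenance`.
#' @export
run_evaluation_two <- function(config, pipeline = "CVCR-ZAC", seed = NULL) {
  data <- resolve_datasets(config)
  pieces <- config_pieces(config, seed)
  if (is.character(pipeline)) pipeline <- parse_pipeline(pipeline)
  if (pipeline$removal == "NCR") stop2("evaluation-2 needs a removing pipeline")
  model <- finalize_model(data$train, pipeline, pieces$estimator,
                          seed = pieces$cv$seed)
  cohorts <- list(same_distribution = data$oos)
  if (!is.null(data$oos_shifted)) cohorts$shifted <- data$oos_shifted
  cohorts <- Filter(Negate(is.null), cohorts)
  if (length(cohorts) == 0) stop2("evaluation-2 needs at least one OOS cohort")
  details <- list()
  rows <- list()
  for (nm in names(cohorts)) {
    oos <- cohorts[[nm]]
    runs <- list(
      `train-to-test` = oos_train_to_test(model, oos),
      `test-wdcr` = oos_self_removal(model, oos, "WDCR"),
      `test-cvcr` = oos_self_removal(model, oos, "CVCR",
                                     seed = pieces$cv$seed),
      `combined-wdcr` = oos_combined_wdcr(
        data$train, oos,
        pipeline_spec("WDCR", if (pipeline$normalization == "NZ") "NZ"
                      else pipeline$normalization),
        pieces$estimator, seed = pieces$cv$seed)
    )
    details[[nm]] <- runs
    rows[[nm]] <- do.call(rbind, lapply(names(runs), function(m) {
      mt <- runs[[m]]$metrics
      data.frame(cohort = nm, method = m, auc = mt$auc, f1 = mt$f1,
                 balanced_accuracy = mt$balanced_accuracy, row.names = NULL)
    }))
  }
  list(table = do.call(rbind, rows), details = details,
       provenance = list(config = data$config, hashes = data$hashes,
                         pipeline = pipeline$label,
                         estimator = pieces$estimator$kind,
                         cv = unclass(pieces$cv)))
}

#' Write an experiment table with its provenance sidecar
#'
#' The TSV holds the consolidated table; the JSON sidecar embeds the full
#' resolved configuration and content hashes of the inputs.
#'
#' @param result a [run_evaluation_one()] / [run_evaluation_two()] result.
#' @param prefix output path prefix.
#' @return invisibly, the file paths.
#' @export
write_experiment_result <- function(result, prefix) {
  f_tsv <- paste0(prefix, ".tsv")
  f_json <- paste0(prefix, "_provenance.json")
  utils::write.table(result$table, f_tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(
    c(result$provenance, list(table_hash = content_hash(result$table))),
    f_json, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(c(table = f_tsv, provenance = f_json))
}
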