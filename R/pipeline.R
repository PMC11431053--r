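# End-to-end pipeline: simulate -> patchify -> train -> vote -> evaluate,
# with every artifact written next to a config snapshot for reproducibility.

#' Default end-to-end run configuration
#'
#' @param n_patients cohort size.
#' @param class_mix per-class proportions.
#' @param volumes_per_patient volumes per patient.
#' @param test_fraction fraction of patients held out (grouped by patient).
#' @param epochs,batch_size,seed,input_size training settings
#'   (`input_size` is the network input side; the desk-scale default is
#'   112).
#' @param profile backbone profile.
#' @param tau voting threshold.
#' @param out_dir artifact directory, or `NULL` to keep everything in
#'   memory.
#' @return List of class `octex_run_config`.
#' @export
run_config <- function(n_patients = 30L, class_mix = rep(0.2, 5),
                       volumes_per_patient = 2L, test_fraction = 0.25,
                       epochs = 5L, batch_size = 16L, seed = 1L,
                       input_size = 112L, profile = "test", tau = 0.8,
                       out_dir = NULL) {
  out <- list(n_patients = as.integer(n_patients), class_mix = class_mix,
              volumes_per_patient = as.integer(volumes_per_patient),
              test_fraction = test_fraction, epochs = as.integer(epochs),
              batch_size = as.integer(batch_size), seed = as.integer(seed),
              input_size = as.integer(input_size), profile = profile,
              tau = tau, out_dir = out_dir)
  class(out) <- "octex_run_config"
  out
}

subset_cohort <- function(cohort, ids) {
  keep <- vapply(cohort$patients, function(p) p$patient_id %in% ids,
                 logical(1))
  cohort$patients <- cohort$patients[keep]
  cohort
}

#' Run the full pipeline on a synthetic cohort
#'
#' Simulates a cohort, splits patients into training and held-out sets,
#' trains the classifier on training patches, predicts every held-out
#' volume through the cross-shaped voting rule, and evaluates volume- and
#' patient-level verdicts against ground truth. All randomness derives
#' from `config$seed`.
#'
#' @param config an [run_config()].
#' @param synth_cfg an [synthetic_config()].
#' @param verbose print stage progress.
#' @return List of class `octex_run`: `fit`, `volume_metrics`,
#'   `patient_metrics`, `predictions` (per-volume data.frame), and paths of
#'   written artifacts (when `out_dir` is set).
#' @export
run_end_to_end <- function(config = run_config(),
                           synth_cfg = synthetic_config(),
                           verbose = FALSE) {
  required <- c("n_patients", "class_mix", "volumes_per_patient",
                "test_fraction", "epochs", "batch_size", "seed",
                "input_size", "profile", "tau")
  missing_blocks <- setdiff(required, names(config))
  if (length(missing_blocks) > 0) {
    stop("run config is missing required block(s): ",
         paste(missing_blocks, collapse = ", "))
  }
  say <- function(...) if (verbose) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  say("simulate: ", config$n_patients, " patients")
  cohort <- stage("simulate",
                  generate_cohort(config$n_patients, config$class_mix,
                                  config$volumes_per_patient, synth_cfg,
                                  seed = config$seed))
  ids <- vapply(cohort$patients, `[[`, character(1), "patient_id")
  n_test <- max(1L, round(config$test_fraction * length(ids)))
  test_ids <- with_seed(config$seed, sample(ids, n_test))
  train_cohort <- subset_cohort(cohort, setdiff(ids, test_ids))
  test_cohort <- subset_cohort(cohort, test_ids)

  say("patchify")
  train_ds <- stage("patchify", generate_patch_dataset(train_cohort))
  say("train: ", length(train_ds$patches), " patches, ",
      config$epochs, " epochs")
  fit <- stage("train", train_model(
    train_ds,
    model_cfg = model_config(profile = config$profile),
    train_cfg = train_config(batch_size = config$batch_size,
                             epochs = config$epochs, seed = config$seed,
                             target_size = config$input_size),
    verbose = verbose))

  say("predict + vote: ", length(test_ids), " held-out patients")
  preds <- list()
  pat_truth <- pat_pred <- logical(0)
  for (pat in test_cohort$patients) {
    vol_pos <- logical(length(pat$volumes))
    for (v in seq_along(pat$volumes)) {
      sv <- pat$volumes[[v]]
      pg <- stage("predict", predict_volume(
        fit$model, sv$volume, synth_cfg$window_size, synth_cfg$stride,
        tau = config$tau))
      vol_pos[v] <- pg$verdict$positive
      preds[[length(preds) + 1L]] <- data.frame(
        patient_id = pat$patient_id, volume = v, class = sv$class_label,
        truth = sv$binary, predicted = pg$verdict$positive,
        max_risk = max(pg$risk), stringsAsFactors = FALSE)
    }
    pat_truth <- c(pat_truth, pat$binary)
    pat_pred <- c(pat_pred, patient_verdict(vol_pos))
  }
  preds <- do.call(rbind, preds)
  vol_metrics <- stage("evaluate", classification_metrics(
    confusion_counts(preds$predicted, preds$truth), conf.level = 0.95))
  pat_metrics <- stage("evaluate", classification_metrics(
    confusion_counts(pat_pred, pat_truth), conf.level = 0.95))

  out <- list(fit = fit, predictions = preds,
              volume_metrics = vol_metrics, patient_metrics = pat_metrics,
              test_ids = test_ids, config = config)
  class(out) <- "octex_run"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    save_checkpoint(fit$model, file.path(config$out_dir, "model.rds"))
    utils::write.csv(preds, file.path(config$out_dir, "predictions.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(volume = unclass(vol_metrics)[c("accuracy", "sensitivity",
                                           "specificity", "ppv", "npv",
                                           "f1")],
           patient = unclass(pat_metrics)[c("accuracy", "sensitivity",
                                            "specificity", "ppv", "npv",
                                            "f1")],
           seed = config$seed),
      file.path(config$out_dir, "metrics.json"),
      auto_unbox = TRUE, digits = NA, na = "null")
    yaml::write_yaml(config[setdiff(names(config), "out_dir")],
                     file.path(config$out_dir, "run_config.yaml"))
    out$artifacts <- file.path(config$out_dir,
                               c("model.rds", "predictions.csv",
                                 "metrics.json", "run_config.yaml"))
  }
  out
}
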