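# End-to-end orchestration: simulate -> tile features -> LASSO -> SVM ->
# patient aggregation -> pathology score -> evaluation, with seed fan-out
# and diff-able CSV/JSON artifacts.

#' Pipeline configuration
#'
#' One root seed fans out to named per-stage substreams (cohort, split,
#' LASSO folds, SVM folds, bootstrap), so stage-wise and monolithic runs
#' agree for a fixed seed.
#'
#' @param cohort a [cohort_config()]; its `seed` is overridden by the
#'   derived cohort substream.
#' @param glcm a [glcm_config()].
#' @param split_ratio primary fraction (default 0.8).
#' @param stratify_split stratify the split by outcome.
#' @param lasso_folds,lasso_rule LASSO CV folds and penalty rule.
#' @param svm_folds,cost_grid,gamma_grid SVM grid-search settings.
#' @param bootstrap_B bootstrap replicates for patient-level AUC CIs.
#' @param hl_bins Hosmer-Lemeshow bins (reduced automatically when a cohort
#'   is smaller than `2 * hl_bins`).
#' @param seed root seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            glcm = glcm_config(),
                            split_ratio = 0.8,
                            stratify_split = TRUE,
                            lasso_folds = 10,
                            lasso_rule = "min",
                            svm_folds = 5,
                            cost_grid = 2^seq(-3, 7, 2),
                            gamma_grid = 2^seq(-9, 1, 2),
                            bootstrap_B = 500,
                            hl_bins = 10,
                            seed = 1) {
  structure(list(cohort = cohort, glcm = glcm, split_ratio = split_ratio,
                 stratify_split = stratify_split, lasso_folds = lasso_folds,
                 lasso_rule = lasso_rule, svm_folds = svm_folds,
                 cost_grid = cost_grid, gamma_grid = gamma_grid,
                 bootstrap_B = bootstrap_B, hl_bins = hl_bins,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Evaluate a patient score table
#'
#' Discrimination, threshold metrics, calibration, Hosmer-Lemeshow and the
#' decision curve for one cohort's scores; the same routine serves the
#' in-process pipeline and re-evaluation of a saved score table.
#'
#' @param scores predicted probabilities (pathology scores).
#' @param labels binary outcomes.
#' @param threshold operating threshold; default Youden's J on these scores.
#' @param B bootstrap replicates for the AUC CI.
#' @param hl_bins Hosmer-Lemeshow bins (capped at `floor(n / 2)`).
#' @param seed RNG seed for the bootstrap.
#' @return list: `roc`, `metrics`, `calibration`, `hosmer_lemeshow`,
#'   `decision_curve`, `threshold`.
#' @export
evaluate_patients <- function(scores, labels, threshold = NULL, B = 500,
                              hl_bins = 10, seed = 1) {
  threshold <- threshold %||% youden_threshold(scores, labels)
  g <- min(hl_bins, floor(length(scores) / 2))
  list(roc = compute_auc(scores, labels, ci = "bootstrap", B = B, seed = seed),
       metrics = threshold_metrics(scores, labels, threshold),
       calibration = suppressWarnings(calibration_curve(scores, labels, g = g)),
       hosmer_lemeshow = suppressWarnings(hosmer_lemeshow(scores, labels, g = g)),
       decision_curve = decision_curve(scores, labels),
       threshold = threshold)
}

#' Run the full pathology-signature pipeline
#'
#' Generates (or accepts) a cohort, splits it 80:20 into primary and
#' validation sets, extracts the 104 texture features per tile, standardizes
#' and LASSO-selects them on the primary tiles, trains the RBF-SVM tile
#' classifier, aggregates tile probabilities to patient means, fits the
#' logistic pathology score and the multivariable adjustment model, and
#' evaluates both cohorts. If the LASSO retains no feature (as expected under
#' a null cohort with `effect_size = 0` it may), the tile classifier
#' degenerates to the non-informative constant probability 0.5.
#'
#' @param config a [pipeline_config()].
#' @param cohort optional pre-built [generate_cohort()] result; by default a
#'   cohort is generated from `config$cohort` with a derived seed.
#' @param outdir optional directory for CSV/JSON artifacts.
#' @return object of class `pathsig_report`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- list(cohort = derive_seed(config$seed, 1),
                split = derive_seed(config$seed, 2),
                lasso = derive_seed(config$seed, 3),
                svm = derive_seed(config$seed, 4),
                boot = derive_seed(config$seed, 5))
  if (is.null(cohort)) {
    cc <- config$cohort
    cc$seed <- seeds$cohort
    cohort <- generate_cohort(cc)
  }
  split <- split_cohort(cohort$patients, ratio = config$split_ratio,
                        seed = seeds$split, stratify = config$stratify_split)
  features <- cohort_feature_table(cohort, config$glcm)
  fcols <- feature_names(config$glcm)
  is_primary <- features$patient_id %in% split$primary$patient_id

  std <- standardize_fit(features[is_primary, fcols])
  z <- standardize_apply(std, features[, fcols])

  lasso <- lasso_select(z[is_primary, , drop = FALSE],
                        features$label[is_primary],
                        groups = features$patient_id[is_primary],
                        n_folds = config$lasso_folds,
                        rule = config$lasso_rule, seed = seeds$lasso)

  if (length(lasso$selected) > 0) {
    classifier <- train_tile_classifier(
      z[is_primary, lasso$selected, drop = FALSE],
      features$label[is_primary], cv_folds = config$svm_folds,
      cost_grid = config$cost_grid, gamma_grid = config$gamma_grid,
      seed = seeds$svm)
    tile_prob <- predict_tile_prob(classifier, z[, lasso$selected, drop = FALSE])
  } else {
    warning("LASSO selected no features; tile classifier is non-informative",
            call. = FALSE)
    classifier <- NULL
    tile_prob <- rep(0.5, nrow(features))
  }

  agg <- aggregate_patients(tile_prob, features$patient_id)
  patients <- merge(cohort$patients, agg, by = "patient_id", all.x = TRUE)
  dropped <- patients$patient_id[is.na(patients$mean_prob)]
  if (length(dropped)) {
    warning("excluding patient(s) with no selected tiles: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    patients <- patients[!is.na(patients$mean_prob), ]
  }
  patients$cohort <- ifelse(patients$patient_id %in% split$primary$patient_id,
                            "primary", "validation")
  prim <- patients[patients$cohort == "primary", ]
  vali <- patients[patients$cohort == "validation", ]

  if (length(unique(prim$mean_prob)) > 1) {
    signature <- suppressWarnings(fit_signature(prim$mean_prob, prim$label))
  } else {
    # degenerate (no informative tiles): flat signature at the prevalence
    signature <- structure(list(beta0 = qlogis(mean(prim$label == "PR")),
                                beta1 = 0, separation = FALSE,
                                positive = "PR"),
                           class = "pathology_signature")
  }
  patients$pathology_score <- pathology_score(signature, patients$mean_prob)
  prim <- patients[patients$cohort == "primary", ]
  vali <- patients[patients$cohort == "validation", ]

  multivariable <- tryCatch(fit_multivariable(prim),
                            error = function(e) e$message)

  thr <- youden_threshold(prim$pathology_score, prim$label)
  evaluation <- list(
    tile_level = list(
      primary = compute_auc(tile_prob[is_primary], features$label[is_primary]),
      validation = compute_auc(tile_prob[!is_primary], features$label[!is_primary])),
    primary = evaluate_patients(prim$pathology_score, prim$label,
                                threshold = thr, B = config$bootstrap_B,
                                hl_bins = config$hl_bins, seed = seeds$boot),
    validation = evaluate_patients(vali$pathology_score, vali$label,
                                   threshold = thr, B = config$bootstrap_B,
                                   hl_bins = config$hl_bins,
                                   seed = derive_seed(seeds$boot, 1)))
  univariable <- univariable_tests(
    prim[, c("label", "age", "gender", "t_stage", "n_stage", "cea",
             "pathology_score")])
  summary_tab <- summarize_cohort(
    prim[, c("label", "age", "gender", "t_stage", "n_stage", "cea")])

  report <- structure(list(config = config, seeds = seeds,
                           cohort = cohort, split = split,
                           standardization = std, lasso = lasso,
                           classifier = classifier, signature = signature,
                           patients = patients, features = features,
                           tile_prob = tile_prob,
                           multivariable = multivariable,
                           evaluation = evaluation,
                           univariable = univariable,
                           summary = summary_tab),
                      class = "pathsig_report")
  if (!is.null(outdir)) write_report_artifacts(report, outdir)
  report
}

#' @export
print.pathsig_report <- function(x, ...) {
  ev <- x$evaluation
  cat("pathsig pipeline report\n")
  cat(sprintf("  patients: %d primary / %d validation; tiles: %d\n",
              sum(x$patients$cohort == "primary"),
              sum(x$patients$cohort == "validation"), nrow(x$features)))
  cat(sprintf("  LASSO-selected features: %d\n", length(x$lasso$selected)))
  cat(sprintf("  tile-level AUC: primary %.3f, validation %.3f\n",
              ev$tile_level$primary$auc, ev$tile_level$validation$auc))
  cat(sprintf("  pathology-signature AUC: primary %.3f [%.3f, %.3f], validation %.3f [%.3f, %.3f]\n",
              ev$primary$roc$auc, ev$primary$roc$ci[1], ev$primary$roc$ci[2],
              ev$validation$roc$auc, ev$validation$roc$ci[1],
              ev$validation$roc$ci[2]))
  cat(sprintf("  Hosmer-Lemeshow p: primary %.3f, validation %.3f\n",
              ev$primary$hosmer_lemeshow$p_value,
              ev$validation$hosmer_lemeshow$p_value))
  invisible(x)
}

report_metrics <- function(report) {
  ev <- report$evaluation
  metr <- function(e) list(auc = e$roc$auc, auc_ci = unname(e$roc$ci),
                           threshold = e$threshold,
                           accuracy = e$metrics$accuracy,
                           sensitivity = e$metrics$sensitivity,
                           specificity = e$metrics$specificity,
                           f1 = e$metrics$f1,
                           hl_statistic = e$hosmer_lemeshow$statistic,
                           hl_p = e$hosmer_lemeshow$p_value)
  list(n_selected_features = length(report$lasso$selected),
       selected_features = report$lasso$selected,
       signature = list(beta0 = report$signature$beta0,
                        beta1 = report$signature$beta1),
       tile_level_auc = list(primary = ev$tile_level$primary$auc,
                             validation = ev$tile_level$validation$auc),
       primary = metr(ev$primary),
       validation = metr(ev$validation))
}

#' Write pipeline artifacts
#'
#' Writes `cohort.csv`, `features.csv`, `scores.csv`, `model.json`,
#' `report.json` and a `manifest.json` (seed, configuration, versions) to a
#' directory.
#'
#' @param report a [run_pipeline()] result.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_report_artifacts <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$cohort$patients, file.path(outdir, "cohort.csv"),
            row.names = FALSE)
  write.csv(report$features, file.path(outdir, "features.csv"),
            row.names = FALSE)
  write.csv(report$patients[, c("patient_id", "label", "cohort", "mean_prob",
                                "pathology_score")],
            file.path(outdir, "scores.csv"), row.names = FALSE)
  model <- list(standardization = list(mean = report$standardization$mean,
                                       sd = report$standardization$sd,
                                       features = report$standardization$features),
                selected_features = report$lasso$selected,
                chosen_lambda = report$lasso$chosen_lambda,
                svm = if (!is.null(report$classifier)) {
                  list(cost = report$classifier$cost,
                       gamma = report$classifier$gamma,
                       cv_auc = report$classifier$cv_auc)
                },
                signature = list(beta0 = report$signature$beta0,
                                 beta1 = report$signature$beta1))
  jsonlite::write_json(model, file.path(outdir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(report_metrics(report), file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(seed = report$config$seed,
                   config = unclass(report$config[c("split_ratio",
                                                    "lasso_folds", "lasso_rule",
                                                    "svm_folds", "bootstrap_B",
                                                    "hl_bins")]),
                   cohort = unclass(report$config$cohort[
                     c("n_patients", "pr_prevalence", "tiles_per_patient_min",
                       "tiles_per_patient_max", "effect_size", "tile_size")]),
                   r_version = as.character(getRversion()),
                   package_version = as.character(utils::packageVersion("pathsig")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Plot a pipeline report
#'
#' Draws the ROC curve, calibration curve and decision curve of one cohort's
#' patient-level evaluation.
#'
#' @param x a [run_pipeline()] result.
#' @param cohort `"primary"` or `"validation"`.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.pathsig_report <- function(x, cohort = c("primary", "validation"), ...) {
  cohort <- match.arg(cohort)
  ev <- x$evaluation[[cohort]]
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(ev$roc$points$fpr, ev$roc$points$tpr, type = "l", lwd = 2,
                 xlab = "1 - specificity", ylab = "Sensitivity",
                 main = sprintf("ROC (%s), AUC = %.3f", cohort, ev$roc$auc))
  graphics::abline(0, 1, lty = 3)
  cal <- ev$calibration
  graphics::plot(cal$mean_predicted, cal$observed_fraction, xlim = c(0, 1),
                 ylim = c(0, 1), pch = 19, type = "b",
                 xlab = "Predicted probability", ylab = "Observed fraction",
                 main = sprintf("Calibration, H-L p = %.3f",
                                ev$hosmer_lemeshow$p_value))
  graphics::abline(0, 1, lty = 3)
  dc <- ev$decision_curve
  graphics::plot(dc$threshold, dc$net_benefit, type = "l", lwd = 2,
                 ylim = range(c(dc$net_benefit, dc$treat_all, 0)),
                 xlab = "Threshold probability", ylab = "Net benefit",
                 main = "Decision curve")
  graphics::lines(dc$threshold, dc$treat_all, lty = 2)
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topright", c("model", "treat all", "treat none"),
                   lty = c(1, 2, 3), lwd = c(2, 1, 1), bty = "n")
  invisible(x)
}
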