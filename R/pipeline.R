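# Pipeline orchestration: simulate -> segment -> extract -> select/score ->
# evaluate, with a frozen resolved config, stage-granular logging, and
# delimited-text / JSON outputs in one run directory per invocation.

#' Default pipeline configuration
#'
#' Every tunable of the pipeline with its documented default.  The config
#' round-trips through JSON via [write_config()] / [read_config()].
#'
#' @param seed master seed for every random draw of the run.
#' @return nested named list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    n_patients = 128L,
    p_highrisk = 0.25,
    phantom = unclass(phantom_spec()),
    outcome = unclass(outcome_params()),
    stages = list(simulate = TRUE, segment = TRUE, extract = TRUE,
                  select = TRUE, evaluate = TRUE),
    use_truth_masks = FALSE,
    external_mask_dir = NULL,
    box_pad = 4L,
    segmentation = list(fuzziness = 2, tol = 1e-5, max_iter = 200),
    features = list(n_bins = 32L, distance = 1L, gldm_alpha = 0L),
    svm = list(C = 1, k_folds = 10L, n_repeats = 50L, max_features = 4L,
               metric = "auc", min_improve = 1e-6, scoring = "cv"),
    stats = list(gate_p = 0.05, adc_cutoff = 0.825),
    write_volumes = FALSE,
    figures = FALSE)
}

#' Write / read a pipeline config as JSON
#'
#' @param config nested list as produced by [default_config()].
#' @param path JSON file path.
#' @return `read_config` returns the config list; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

log_stage <- function(log_path, stage, t0, extra = "") {
  line <- sprintf("%s\tstage=%s\telapsed=%.2fs\t%s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage,
                  as.numeric(Sys.time()) - t0, extra)
  cat(line, "\n", file = log_path, append = TRUE)
}

run_stage <- function(stage, log_path, expr) {
  t0 <- as.numeric(Sys.time())
  res <- tryCatch(expr, error = function(e) {
    log_stage(log_path, stage, t0, paste0("FAILED: ", conditionMessage(e)))
    stop_radscore(sprintf("pipeline stage '%s' failed: %s", stage,
                          conditionMessage(e)), "radscore_stage_error")
  })
  log_stage(log_path, stage, t0)
  res
}

#' Run the full radiomics pipeline
#'
#' Executes the enabled stages on a synthetic cohort (or volumes loaded
#' from `input_dir`) and writes the per-patient feature table, SVM scores,
#' selected features, ROC / survival tables, a machine-readable
#' `summary.json`, the frozen `config.json`, and a stage log into
#' `out_dir`.  Identical config + seed give identical outputs.
#'
#' @param config nested list, see [default_config()].
#' @param out_dir run directory (created if missing).
#' @param input_dir optional cohort directory (as written by
#'   [generate_cohort()]) used when `stages$simulate` is FALSE.
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         input_dir = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  cat("", file = log_path)
  write_config(config, file.path(out_dir, "config.json"))
  spec <- do.call(phantom_spec, config$phantom)
  params <- do.call(outcome_params, config$outcome)
  st <- config$stages

  cohort <- run_stage("simulate", log_path, {
    if (isTRUE(st$simulate)) {
      generate_cohort(config$n_patients, spec = spec, params = params,
                      seed = config$seed, p_highrisk = config$p_highrisk,
                      keep_volumes = isTRUE(st$segment) || isTRUE(st$extract),
                      out_dir = if (isTRUE(config$write_volumes))
                        file.path(out_dir, "volumes") else NULL)
    } else {
      if (is.null(input_dir))
        stop("simulation disabled and no input_dir supplied")
      load_cohort(input_dir)
    }
  })
  covars <- cohort$covariates
  n <- nrow(covars)

  masks <- run_stage("segment", log_path, {
    if (!isTRUE(st$segment) && !isTRUE(st$extract)) NULL
    else lapply(seq_len(n), function(i) {
      truth <- cohort$imaging[[i]]$mask
      if (!is.null(config$external_mask_dir)) {
        nf <- read_nifti(file.path(config$external_mask_dir,
                                   paste0(covars$patient_id[i],
                                          "_mask.nii.gz")))
        tumor_mask(nf$data > 0.5, nf$spacing, nf$affine)
      } else if (isTRUE(config$use_truth_masks) || !isTRUE(st$segment)) {
        truth
      } else {
        box <- seed_box_from_mask(truth$mask, pad = config$box_pad)
        segment_volume(cohort$imaging[[i]]$pair, box,
                       fuzziness = config$segmentation$fuzziness,
                       tol = config$segmentation$tol,
                       max_iter = config$segmentation$max_iter)
      }
    })
  })

  features <- run_stage("extract", log_path, {
    if (!isTRUE(st$extract)) NULL else {
    fcfg <- do.call(feature_config, config$features)
    tab <- t(vapply(seq_len(n), function(i)
      extract_feature_vector(cohort$imaging[[i]]$pair, masks[[i]],
                             config = fcfg),
      numeric(214)))
    df <- data.frame(patient_id = covars$patient_id, tab,
                     check.names = FALSE)
    write.csv(df, file.path(out_dir, "features.csv"), row.names = FALSE)
    tab
    }
  })

  selection <- run_stage("select", log_path, {
    if (!isTRUE(st$select) || is.null(features)) NULL else {
    y <- ifelse(covars$event > 0, 1, -1)
    sv <- config$svm
    sel <- sequential_forward_selection(
      features, y, k_folds = sv$k_folds, n_repeats = sv$n_repeats,
      seed = derive_seed(config$seed, 9001), max_features = sv$max_features,
      min_improve = sv$min_improve, metric = sv$metric, C = sv$C)
    scores <- if (identical(sv$scoring, "refit"))
      predict(sel$model, features)
    else
      cv_scores(features, y, sel$selected, k_folds = sv$k_folds,
                n_repeats = sv$n_repeats,
                seed = derive_seed(config$seed, 9002), C = sv$C)
    write.csv(data.frame(patient_id = covars$patient_id,
                         svm_score = scores, event = covars$event),
              file.path(out_dir, "scores.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(selected = colnames(features)[sel$selected],
           indices = sel$selected, trace = sel$trace),
      file.path(out_dir, "selected_features.json"), auto_unbox = TRUE,
      digits = NA)
    list(selection = sel, scores = scores)
    }
  })

  summary <- run_stage("evaluate", log_path, {
    if (!isTRUE(st$evaluate) || is.null(selection)) NULL else {
    scores <- selection$scores
    event <- covars$event
    adc <- covars$adc_value
    roc_svm <- roc_auc_and_cutoff(scores, event)
    roc_adc <- roc_auc_and_cutoff(-adc, event)  # low ADC calls positive
    roc_comb <- combined_roc(scores, adc, event)
    svm_high <- as.integer(scores > roc_svm$cutoff)
    adc_low <- as.integer(adc < config$stats$adc_cutoff)
    km_svm <- km_logrank(covars$followup_time, event, svm_high)
    km_bone <- km_logrank(covars$followup_time, event, covars$bone_invasion)
    km_adc <- km_logrank(covars$followup_time, event, adc_low)
    cox_tab <- data.frame(sex_male = as.integer(covars$sex == "M"),
                          age = covars$age,
                          str = as.integer(covars$resection_extent == "STR"),
                          bone_invasion = covars$bone_invasion,
                          adc_low = adc_low, svm_high = svm_high)
    cox <- tryCatch(cox_ph(cox_tab, covars$followup_time, event,
                           gate_p = config$stats$gate_p),
                    radscore_convergence_error = function(e) NULL)
    group_tab <- cohort_table_stats(
      data.frame(sex = covars$sex, age = covars$age,
                 resection_extent = covars$resection_extent,
                 bone_invasion = covars$bone_invasion,
                 adc_value = adc, svm_score = scores, event = event),
      group = "event")
    write.csv(if (is.null(cox)) data.frame() else cox$table,
              file.path(out_dir, "cox.csv"), row.names = FALSE)
    write.csv(group_tab, file.path(out_dir, "group_stats.csv"),
              row.names = FALSE)
    write.csv(km_svm$km_curves, file.path(out_dir, "km_svm.csv"),
              row.names = FALSE)
    smry <- list(
      n_patients = n, n_events = sum(event),
      prevalence = mean(event),
      n_features = ncol(features),
      selected_features = colnames(features)[selection$selection$selected],
      auc_svm = roc_svm$auc, svm_cutoff = roc_svm$cutoff,
      sensitivity = roc_svm$sensitivity, specificity = roc_svm$specificity,
      auc_adc = roc_adc$auc, adc_cutoff = -roc_adc$cutoff,
      auc_combined = roc_comb$auc,
      logrank_p_svm = km_svm$logrank_p, logrank_p_bone = km_bone$logrank_p,
      logrank_p_adc = km_adc$logrank_p,
      cox_multivariate = if (is.null(cox)) NULL else cox$multivariate_vars,
      seed = config$seed)
    jsonlite::write_json(smry, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    if (isTRUE(config$figures))
      pipeline_figures(out_dir, roc_svm, roc_adc, km_svm)
    smry
    }
  })

  if (!is.null(features))
    log_stage(log_path, "checksums", as.numeric(Sys.time()),
              paste0("features.csv=",
                     unname(tools::md5sum(file.path(out_dir,
                                                    "features.csv")))))
  invisible(summary)
}

pipeline_figures <- function(out_dir, roc_svm, roc_adc, km_svm) {
  grDevices::pdf(file.path(out_dir, "figures.pdf"), width = 7, height = 7)
  on.exit(grDevices::dev.off(), add = TRUE)
  plot(roc_svm$curve$fpr, roc_svm$curve$tpr, type = "s", col = "firebrick",
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("ROC: SVM score (AUC %.2f), ADC (AUC %.2f)",
                      roc_svm$auc, roc_adc$auc))
  graphics::lines(roc_adc$curve$fpr, roc_adc$curve$tpr, type = "s",
                  col = "steelblue")
  graphics::abline(0, 1, lty = 3)
  km <- km_svm$km_curves
  plot(NULL, xlim = c(0, max(km$time)), ylim = c(0, 1),
       xlab = "months", ylab = "progression-free survival",
       main = "Kaplan-Meier by dichotomized SVM score")
  for (g in unique(km$group)) {
    sub <- km[km$group == g, ]
    graphics::lines(c(0, sub$time), c(1, sub$survival), type = "s",
                    col = if (g == unique(km$group)[1]) "steelblue"
                          else "firebrick")
  }
}

# Load a cohort directory written by generate_cohort(out_dir = ...).
load_cohort <- function(input_dir) {
  covars <- read.csv(file.path(input_dir, "covariates.csv"),
                     stringsAsFactors = FALSE)
  imaging <- lapply(covars$patient_id, function(pid) {
    t1 <- read_nifti(file.path(input_dir, paste0(pid, "_t1c.nii.gz")))
    t2 <- read_nifti(file.path(input_dir, paste0(pid, "_t2.nii.gz")))
    mk <- read_nifti(file.path(input_dir, paste0(pid, "_mask.nii.gz")))
    list(pair = volume_pair(t1$data, t2$data, t1$spacing,
                            affine_t1c = t1$affine, affine_t2 = t2$affine),
         mask = tumor_mask(mk$data > 0.5, mk$spacing, mk$affine))
  })
  list(covariates = covars, imaging = imaging)
}
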