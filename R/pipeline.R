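# End-to-end experiment orchestration: synthesize (or load) a cohort, build
# the requested plane variants, derive labels per task, split, augment,
# train, and evaluate each (variant, task) arm. All randomness is derived
# from one master seed, so a re-run with the same configuration reproduces
# the report exactly.

#' Experiment configuration
#'
#' @param params a [phantomParams()] list describing the synthetic cohort
#'   (its own `seed` governs cohort generation).
#' @param variants subset of c("PJ", "TM", "ZC").
#' @param tasks subset of c("median", "y1", "y3", "y5").
#' @param train a [trainConfig()].
#' @param modelVariant "reduced" or "full" (see [resnetCbam()]).
#' @param baselines subset of c("svm", "lr", "knn"); evaluated on
#'   feature vectors scored by the trained PJ extractor (requires "PJ" among
#'   the variants).
#' @param seed master seed for splitting/augmentation/initialization.
#' @param outDir optional directory for persisted intermediates.
#' @param connectivity,medianKernel,window preprocessing settings.
#' @param splitRatio training fraction.
#' @param nRepeats number of repeated random resampling rounds per task
#'   (fresh split/augmentation/initialization seeds each round); the report
#'   carries per-round rows and a mean summary.
#' @return an `experimentConfig` list.
#' @export
experimentConfig <- function(params = phantomParams(),
                             variants = c("PJ", "TM", "ZC"),
                             tasks = "median",
                             train = trainConfig(),
                             modelVariant = "reduced",
                             baselines = character(),
                             seed = 1L, outDir = NULL,
                             connectivity = 26L, medianKernel = 3L,
                             window = c(-50, 300), splitRatio = 0.7,
                             nRepeats = 1L) {
  if (length(variants) < 1L || length(tasks) < 1L)
    stop("at least one variant and one task are required")
  variants <- match.arg(variants, c("PJ", "TM", "ZC"), several.ok = TRUE)
  tasks <- match.arg(tasks, c("median", "y1", "y3", "y5"), several.ok = TRUE)
  if (length(baselines) && !("PJ" %in% variants))
    stop("baselines require the PJ variant (they reuse its trained extractor)")
  structure(list(params = params, variants = variants, tasks = tasks,
                 train = train, modelVariant = modelVariant,
                 baselines = baselines, seed = as.integer(seed),
                 outDir = outDir, connectivity = connectivity,
                 medianKernel = medianKernel, window = window,
                 splitRatio = splitRatio, nRepeats = as.integer(nRepeats)),
            class = "experimentConfig")
}

.task_labels <- function(records, task) {
  switch(task,
    median = medianSplitLabels(records),
    y1 = horizonLabels(records, 12),
    y3 = horizonLabels(records, 36),
    y5 = horizonLabels(records, 60))
}

# deterministic sub-seed (kept well below 2^31)
.sub_seed <- function(seed, i) (abs(seed) %% 100000L) * 1000L + i

#' Run a full experiment
#'
#' Per (variant, task): trains the classifier on augmented, class-balanced
#' training planes and reports confusion metrics and ROC/AUC on the held-out
#' test patients; for the median task it additionally stratifies test
#' patients by the model's prediction (predicted 1 = low risk) and reports
#' Kaplan-Meier curves with a log-rank test. Optional feature-score baselines
#' reuse the trained PJ extractor.
#'
#' @param config an [experimentConfig()].
#' @param verbose print stage progress.
#' @return an `experimentReport` list: `metricsTable` (one row per arm),
#'   `arms` (per-arm details: metrics, ROC, K-M, log-rank, predictions),
#'   `baselineTable`, `config`.
#' @export
runExperiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experimentConfig"))
  say <- function(...) if (verbose) message(sprintf(...))
  say("[cohort] generating %d phantom patients", config$params$nPatients)
  cohort <- generateCohort(config$params)
  records <- cohort$records

  say("[planes] preprocessing and building %s", paste(config$variants, collapse = "/"))
  prepped <- lapply(cohort$patients, function(p) {
    vol <- medianDenoise(p$volume, config$medianKernel)
    msk <- huWindow(vol, p$mask, config$window[1], config$window[2])
    groups <- sortGroups(groupComponents(msk, config$connectivity))
    list(volume = vol, mask = msk, groups = groups)
  })
  planes <- list()
  for (v in config$variants)
    planes[[v]] <- lapply(prepped, function(p) switch(v,
      PJ = buildPjPlane(p$volume, p$mask, p$groups, window = config$window),
      TM = buildTmPlane(p$volume, p$mask, window = config$window),
      ZC = buildZcPlane(p$volume, p$mask, p$groups, window = config$window)))

  arms <- list()
  rows <- list()
  base_rows <- list()
  pj_models <- list()
  arm_i <- 0L
  for (task in config$tasks) {
    labs <- .task_labels(records, task)
    for (rep_i in seq_len(config$nRepeats)) {
    split <- splitDataset(labs, config$splitRatio,
                          seed = .sub_seed(config$seed,
                                           match(task, config$tasks) + 10L * rep_i))
    for (v in config$variants) {
      arm_i <- arm_i + 1L
      say("[train] %s / %s (round %d)", v, task, rep_i)
      idmap <- setNames(seq_len(nrow(records)), records$patient_id)
      tr_idx <- idmap[split$train]
      te_idx <- idmap[split$test]
      tr_lab <- labs$label[tr_idx]
      te_lab <- labs$label[te_idx]
      aug <- augmentBalance(planes[[v]][tr_idx], tr_lab,
                            seed = .sub_seed(config$seed, 100L + arm_i))
      model <- resnetCbam(config$modelVariant,
                          seed = .sub_seed(config$seed, 200L + arm_i))
      cfg <- config$train
      cfg$seed <- .sub_seed(config$seed, 300L + arm_i)
      fit <- trainModel(model, aug$planes, aug$labels, cfg)
      prob <- predictProb(fit$model, planes[[v]][te_idx])
      pred <- as.integer(prob[, 2] > 0.5)
      arm <- list(variant = v, task = task,
                  metrics = confusionMetrics(pred, te_lab),
                  roc = rocAuc(prob[, 2], te_lab),
                  history = fit$history,
                  pred = data.frame(patient_id = split$test,
                                    label = te_lab, score = prob[, 2],
                                    pred = pred))
      if (task == "median") {
        hi <- te_idx[pred == 0]   # predicted high risk
        lo <- te_idx[pred == 1]
        if (length(hi) && length(lo)) {
          arm$km <- list(
            high = kmEstimate(records$time_months[hi], records$event[hi]),
            low = kmEstimate(records$time_months[lo], records$event[lo]))
          arm$logrank <- logrankTest(records$time_months[hi], records$event[hi],
                                     records$time_months[lo], records$event[lo])
        }
      }
      arm$round <- rep_i
      arms[[if (config$nRepeats == 1L) paste(v, task, sep = "_")
            else paste(v, task, rep_i, sep = "_")]] <- arm
      m <- arm$metrics
      rows[[arm_i]] <- data.frame(
        variant = v, task = task, round = rep_i, n_train = length(aug$labels),
        n_test = length(te_lab), accuracy = m$accuracy,
        precision = m$precision, specificity = m$specificity,
        recall = m$recall, f1 = m$f1, auc = arm$roc$auc,
        logrank_p = if (!is.null(arm$logrank)) arm$logrank$p_value else NA_real_)
      if (v == "PJ") pj_models[[task]] <- fit$model
    }
    }
    if (length(config$baselines)) {
      split <- splitDataset(labs, config$splitRatio,
                            seed = .sub_seed(config$seed,
                                             match(task, config$tasks) + 10L))
      say("[baselines] %s / %s", paste(config$baselines, collapse = "/"), task)
      fv <- buildFeatureVectors(prepped, pj_models[[task]])
      idmap <- setNames(seq_len(nrow(records)), records$patient_id)
      tr_idx <- idmap[split$train]; te_idx <- idmap[split$test]
      for (kind in config$baselines) {
        bl <- fitBaseline(kind, fv[tr_idx, ], labs$label[tr_idx],
                          fv[te_idx, ], labs$label[te_idx])
        base_rows[[length(base_rows) + 1L]] <- data.frame(
          kind = kind, task = task, accuracy = bl$metrics$accuracy,
          auc = bl$roc$auc)
      }
    }
  }
  metricsTable <- do.call(rbind, rows)
  num_cols <- c("accuracy", "precision", "specificity", "recall", "f1", "auc")
  summaryTable <- aggregate(metricsTable[num_cols],
                            metricsTable[c("variant", "task")],
                            mean, na.rm = TRUE)
  report <- list(metricsTable = metricsTable,
                 summaryTable = summaryTable,
                 arms = arms,
                 baselineTable = if (length(base_rows)) do.call(rbind, base_rows)
                                 else NULL,
                 config = config)
  class(report) <- "experimentReport"
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(report$metricsTable,
              file.path(config$outDir, "metrics.csv"), row.names = FALSE)
    write.csv(records, file.path(config$outDir, "records.csv"), row.names = FALSE)
    for (nm in names(arms))
      write.csv(arms[[nm]]$pred,
                file.path(config$outDir, paste0("pred_", nm, ".csv")),
                row.names = FALSE)
    if (!is.null(report$baselineTable))
      write.csv(report$baselineTable,
                file.path(config$outDir, "baselines.csv"), row.names = FALSE)
  }
  report
}

#' @export
print.experimentReport <- function(x, ...) {
  cat("experimentReport:\n")
  print(x$metricsTable, row.names = FALSE, digits = 3)
  if (x$config$nRepeats > 1L) {
    cat("means over rounds:\n")
    print(x$summaryTable, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$baselineTable)) {
    cat("baselines:\n")
    print(x$baselineTable, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
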