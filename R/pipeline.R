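# End-to-end experiment: simulate -> preprocess -> fit/select -> recommend
# -> evaluate, with master-seed discipline and a serializable report bundle.

#' Experiment configuration
#'
#' @param generator a [generator_config()]; its seed is overridden by a
#'   sub-seed derived from `seed` so that one master seed drives the whole
#'   experiment.
#' @param imputation `"median_mode"` or `"distribution_sample"`.
#' @param algorithms learners evaluated on all features (OLS is only ever
#'   fitted on selected features, since the full feature set may exceed the
#'   per-arm sample size).
#' @param select_features run lasso selection and the selected-features
#'   evaluation.
#' @param wtp willingness-to-pay threshold, euro per QALY.
#' @param seed master seed; every stochastic stage consumes a sub-seed
#'   derived from it and the stage name.
#' @param tuning hyperparameter tuning mode passed to [loocv()];
#'   `"pretuned"` (grid search once per arm/target, then LOOCV) by default,
#'   `"nested"` for fully nested tuning.
#' @param counterfactual prediction source for the discordant patients'
#'   substituted values. With per-arm fitting the recommended-arm model
#'   never trains on a discordant patient (they sit in the other arm), so
#'   the `"full"`-data fit is already out-of-sample for every substituted
#'   value and the two options coincide; the flag is kept to make that
#'   choice explicit.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(generator = generator_config(),
                              imputation = c("median_mode",
                                             "distribution_sample"),
                              algorithms = c("ridge", "lasso", "tree", "svr"),
                              select_features = TRUE,
                              wtp = 25000,
                              seed = 1,
                              tuning = c("pretuned", "nested"),
                              counterfactual = c("full", "loocv")) {
  imputation <- match.arg(imputation)
  tuning <- match.arg(tuning)
  counterfactual <- match.arg(counterfactual)
  if (!length(algorithms)) stopf("algorithm list must be nonempty")
  algorithms <- vapply(algorithms, match.arg, character(1),
                       choices = setdiff(model_algorithms, "mean_ref"))
  if (!inherits(generator, "generator_config")) {
    stopf("'generator' must be a generator_config")
  }
  check_nonnegative(wtp, "wtp")
  check_count(seed, "seed")
  structure(list(generator = generator, imputation = imputation,
                 algorithms = unname(algorithms),
                 select_features = select_features, wtp = wtp, seed = seed,
                 tuning = tuning, counterfactual = counterfactual),
            class = "experiment_config")
}

#' Load an experiment configuration from YAML
#'
#' Top-level keys mirror the arguments of [experiment_config()]; the
#' `generator` key holds [generator_config()] arguments.
#'
#' @param path YAML file.
#' @return An `experiment_config`.
#' @export
load_experiment_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  gen_args <- y$generator %||% list()
  if (!is.null(gen_args$cost_lognormal_params)) {
    gen_args$cost_lognormal_params <- unlist(gen_args$cost_lognormal_params)
  }
  for (w in c("effect_modifier_weights", "bt_cost_multiplier_weights")) {
    if (!is.null(gen_args[[w]])) gen_args[[w]] <- unlist(gen_args[[w]])
  }
  args <- y[setdiff(names(y), "generator")]
  args$generator <- do.call(generator_config, gen_args)
  do.call(experiment_config, args)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stopf("stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

#' Preprocess a trial dataset into a design matrix
#'
#' Fixed order: merge baseline sources with the outcome table (patients
#' missing either dependent variable are dropped), remove degenerate
#' features (per-arm), impute, one-hot encode.
#'
#' @param dataset a `trial_dataset`.
#' @param imputation `"median_mode"` or `"distribution_sample"`.
#' @param seed seed for the sampling imputation.
#' @return list with `design` (a `design_matrix`), `outcomes` (aligned
#'   rows), `arm` (aligned labels) and the degenerate-feature `report`.
#' @export
preprocess_trial <- function(dataset,
                             imputation = c("median_mode",
                                            "distribution_sample"),
                             seed = 1) {
  imputation <- match.arg(imputation)
  fm <- merge_sources(list(baseline = dataset$baseline), dataset$outcomes)
  arm <- dataset$patients$arm[match(fm$ids, dataset$patients$patient_id)]
  dropped <- drop_degenerate_features(fm, arm_split = arm)
  fm <- if (imputation == "median_mode") {
    impute_median_mode(dropped$matrix)
  } else {
    impute_distribution_sample(dropped$matrix, seed = seed)
  }
  dm <- encode_features(fm)
  keep <- match(dm$ids, dataset$outcomes$patient_id)
  list(design = dm, outcomes = dataset$outcomes[keep, ], arm = arm,
       report = dropped$report)
}

# Pool per-arm LOOCV predictions of one learner for one target over all
# patients. `features_by_arm` optionally restricts each arm's design to a
# selected feature set; an empty selection degrades the learner to the
# mean reference for that arm.
pooled_arm_loocv <- function(algorithm, X, y, arm, features_by_arm = NULL,
                             tuning = "pretuned") {
  preds <- numeric(length(y))
  hyper_used <- list()
  for (a in arm_levels) {
    idx <- which(arm == a)
    feats <- if (is.null(features_by_arm)) colnames(X) else features_by_arm[[a]]
    algo_a <- algorithm
    if (!length(feats)) {
      algo_a <- "mean_ref"
      feats <- colnames(X)[1]
    }
    cv <- loocv(algo_a, X[idx, feats, drop = FALSE], y[idx], tuning = tuning)
    preds[idx] <- cv$predictions
    hyper_used[[a]] <- cv$hyper
  }
  m <- cv_metrics(preds, y)
  list(predictions = preds, mae = m$mae, rmse = m$rmse,
       abs_errors = m$abs_errors, hyper = hyper_used)
}

metrics_table <- function(results, ref) {
  rows <- lapply(names(results), function(algo) {
    r <- results[[algo]]
    data.frame(
      model = algo,
      mae_outcome = r$outcome$mae, rmse_outcome = r$outcome$rmse,
      mae_cost = r$cost$mae, rmse_cost = r$cost$rmse,
      p_outcome = compare_to_reference(r$outcome$abs_errors,
                                       ref$outcome$abs_errors),
      p_cost = compare_to_reference(r$cost$abs_errors,
                                    ref$cost$abs_errors))
  })
  ref_row <- data.frame(model = "reference",
                        mae_outcome = ref$outcome$mae,
                        rmse_outcome = ref$outcome$rmse,
                        mae_cost = ref$cost$mae, rmse_cost = ref$cost$rmse,
                        p_outcome = NA_real_, p_cost = NA_real_)
  out <- rbind(do.call(rbind, rows), ref_row)
  rownames(out) <- NULL
  out
}

#' Run the full individualized cost-effectiveness experiment
#'
#' Executes the stages in order — simulate, preprocess, all-features LOOCV
#' benchmark, lasso feature selection, selected-features LOOCV benchmark,
#' final per-arm fits, per-patient recommendation at the willingness-to-pay
#' threshold, received-vs-recommended contingency, and counterfactual
#' policy evaluation — and returns the paper-shaped report bundle. Every
#' stochastic stage consumes a sub-seed derived from the master seed, so
#' identical configurations yield identical bundles.
#'
#' @param config an [experiment_config()].
#' @return A list of class `report_bundle` with elements `improvement`,
#'   `metrics_all`, `metrics_selected`, `selection`, `best`, `records`,
#'   `contingency`, `policy` and `provenance`.
#' @export
run_experiment <- function(config) {
  if (!inherits(config, "experiment_config")) {
    stopf("'config' must be an experiment_config")
  }
  seed <- config$seed

  gen <- config$generator
  gen$seed <- derive_seed(seed, "simulate")
  sim <- run_stage("simulate", generate_trial(gen))
  ds <- sim$dataset

  prep <- run_stage("preprocess",
                    preprocess_trial(ds, config$imputation,
                                     seed = derive_seed(seed, "impute")))
  X <- prep$design$X
  arm <- prep$arm
  targets <- list(outcome = prep$outcomes$qaly, cost = prep$outcomes$cost)

  improvement <- run_stage("improvement_summary", {
    phq <- ds$phq9[match(prep$design$ids, ds$phq9$patient_id), ]
    improvement_summary(arm, phq$phq9_baseline, phq$phq9_month6)
  })

  ref <- run_stage("reference", lapply(targets, function(y) {
    pooled_arm_loocv("mean_ref", X, y, arm)
  }))

  all_algos <- setdiff(config$algorithms, "ols")
  results_all <- run_stage("fit_all_features", {
    res <- lapply(all_algos, function(algo) {
      lapply(targets, function(y) {
        pooled_arm_loocv(algo, X, y, arm, tuning = config$tuning)
      })
    })
    names(res) <- all_algos
    res
  })
  metrics_all <- metrics_table(results_all, ref)

  selection <- NULL
  metrics_selected <- NULL
  features_by <- NULL
  if (config$select_features) {
    selection <- run_stage("select_features", {
      sel <- list()
      for (a in arm_levels) {
        for (tg in names(targets)) {
          idx <- which(arm == a)
          sel[[paste(a, tg, sep = ".")]] <- select_features_lasso(
            X[idx, , drop = FALSE], targets[[tg]][idx],
            seed = derive_seed(seed, paste("select", a, tg)),
            arm = a, target = tg)
        }
      }
      sel
    })
    features_by <- lapply(stats::setNames(names(targets), names(targets)),
      function(tg) {
        lapply(stats::setNames(arm_levels, arm_levels), function(a) {
          selection[[paste(a, tg, sep = ".")]]$features
        })
      })
    sel_algos <- unique(c(config$algorithms, "ols"))
    results_sel <- run_stage("fit_selected_features", {
      res <- lapply(sel_algos, function(algo) {
        lapply(names(targets), function(tg) {
          pooled_arm_loocv(algo, X, targets[[tg]], arm,
                           features_by_arm = features_by[[tg]],
                           tuning = config$tuning)
        }) |> stats::setNames(names(targets))
      })
      names(res) <- sel_algos
      res
    })
    metrics_selected <- metrics_table(results_sel, ref)
  }

  # pick the best learner per target by pooled LOOCV MAE
  scores <- metrics_selected %||% metrics_all
  scores <- scores[scores$model != "reference", ]
  best <- list(outcome = scores$model[which.min(scores$mae_outcome)],
               cost = scores$model[which.min(scores$mae_cost)])

  final_models <- run_stage("final_fits", {
    fits <- list()
    for (tg in names(targets)) {
      for (a in arm_levels) {
        idx <- which(arm == a)
        feats <- if (is.null(features_by)) colnames(X) else
          features_by[[tg]][[a]]
        key <- paste0(tolower(a), "_", tg)
        if (!length(feats)) {
          fits[[key]] <- fit_mean_reference(targets[[tg]][idx])
        } else {
          Xa <- X[idx, feats, drop = FALSE]
          ya <- targets[[tg]][idx]
          hp <- inner_cv_select(best[[tg]], Xa, ya,
                                default_grid(best[[tg]], Xa, ya))
          fits[[key]] <- fit_quietly(best[[tg]], Xa, ya, hp)
          fits[[key]]$arm <- a
          fits[[key]]$target <- tg
        }
      }
    }
    fits
  })

  records <- run_stage("recommend", {
    preds <- predict_both_arms(final_models, X)
    recommendation_records(prep$design$ids, preds, arm, wtp = config$wtp)
  })
  contingency_tab <- contingency(records$received, records$recommended)

  policy <- run_stage("counterfactual", {
    # Only discordant patients are substituted with predictions, and a
    # discordant patient belongs to the *other* arm, so the recommended-arm
    # model never trained on them: the full-data fit is already out-of-sample
    # for every substituted value.
    rec_bt <- records$recommended == "BT"
    pq <- ifelse(rec_bt, records$q_bt, records$q_tau)
    pc <- ifelse(rec_bt, records$c_bt, records$c_tau)
    counterfactual_policy_value(prep$outcomes$qaly, prep$outcomes$cost,
                                pq, pc, records$concordant)
  })

  cfg_yaml <- yaml::as.yaml(list(
    imputation = config$imputation, algorithms = config$algorithms,
    select_features = config$select_features, wtp = config$wtp,
    seed = config$seed, tuning = config$tuning,
    generator = unclass(strip_weights(config$generator))))
  bundle <- structure(list(
    improvement = improvement,
    metrics_all = metrics_all,
    metrics_selected = metrics_selected,
    selection = selection,
    best = best,
    records = records,
    contingency = contingency_tab,
    policy = policy,
    ground_truth = sim$truth,
    provenance = list(config = cfg_yaml,
                      config_hash = sprintf("%x", poly_hash(cfg_yaml)),
                      seed = seed,
                      package_version = as.character(
                        utils::packageVersion("indicer")))),
    class = "report_bundle")
  bundle
}

strip_weights <- function(gen) {
  gen$effect_modifier_weights <- as.list(gen$effect_modifier_weights)
  gen$bt_cost_multiplier_weights <- as.list(gen$bt_cost_multiplier_weights)
  gen$cost_lognormal_params <- as.list(gen$cost_lognormal_params)
  gen
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf(
    paste0("<report_bundle: %d patients, best outcome/cost model %s/%s,",
           " concordance %.2f%%, QALY %+.2f%% cost %+.2f%%>\n"),
    x$contingency$n, x$best$outcome, x$best$cost,
    x$contingency$concordance_pct,
    x$policy$pct_change_qaly, x$policy$pct_change_cost))
  invisible(x)
}

#' Write a report bundle to a directory
#'
#' Serializes every table of the bundle as CSV/JSON. The write is atomic:
#' files are assembled in a temporary sibling directory which is renamed
#' into place only on success, so a failed run leaves no partial output.
#'
#' @param bundle a `report_bundle`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  parent <- dirname(normalizePath(dir, mustWork = FALSE))
  dir.create(parent, recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile("bundle_", tmpdir = parent)
  dir.create(tmp)
  ok <- FALSE
  on.exit(if (!ok) unlink(tmp, recursive = TRUE), add = TRUE)

  wj <- function(x, f) jsonlite::write_json(
    x, file.path(tmp, f), digits = NA, auto_unbox = TRUE, null = "null",
    dataframe = "columns")
  utils::write.csv(bundle$improvement$summary,
                   file.path(tmp, "improvement.csv"), row.names = FALSE)
  wj(list(p_value = bundle$improvement$p_value), "improvement_test.json")
  utils::write.csv(bundle$metrics_all, file.path(tmp, "metrics_all.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$metrics_selected)) {
    utils::write.csv(bundle$metrics_selected,
                     file.path(tmp, "metrics_selected.csv"),
                     row.names = FALSE)
  }
  if (!is.null(bundle$selection)) {
    wj(lapply(bundle$selection, function(s) {
      list(arm = s$arm, target = s$target, lambda = s$lambda,
           cv_error = s$cv_error, features = as.list(s$features),
           coefficients = as.list(s$coefficients))
    }), "selection.json")
  }
  utils::write.csv(as.data.frame(bundle$records),
                   file.path(tmp, "records.csv"), row.names = FALSE)
  utils::write.csv(ce_plane_export(bundle$records),
                   file.path(tmp, "ce_plane.csv"), row.names = FALSE)
  ct <- bundle$contingency
  wj(list(counts = as.vector(t(ct$counts)),
          percentages = as.vector(t(ct$percentages)),
          layout = "received (TAU,BT) x recommended (TAU,BT), row-major",
          concordance_pct = ct$concordance_pct, n = ct$n),
     "contingency.json")
  wj(unclass(bundle$policy), "policy.json")
  wj(list(best = bundle$best), "best.json")
  utils::write.csv(as.data.frame(bundle$ground_truth),
                   file.path(tmp, "ground_truth.csv"), row.names = FALSE)
  wj(bundle$provenance, "provenance.json")

  unlink(dir, recursive = TRUE)
  if (!file.rename(tmp, dir)) stopf("could not move bundle into '%s'", dir)
  ok <- TRUE
  invisible(dir)
}

#' Read back a written report bundle
#'
#' Reloads the tables serialized by [write_report_bundle()]. Intended for
#' resuming downstream analysis from a stored run; model objects are not
#' serialized, only their evaluation tables and per-patient outputs.
#'
#' @param dir directory written by [write_report_bundle()].
#' @return list of the reloaded tables.
#' @export
read_report_bundle <- function(dir) {
  rj <- function(f) jsonlite::read_json(file.path(dir, f),
                                        simplifyVector = TRUE)
  rc <- function(f) utils::read.csv(file.path(dir, f),
                                    stringsAsFactors = FALSE)
  out <- list(
    improvement = list(summary = rc("improvement.csv"),
                       p_value = rj("improvement_test.json")$p_value),
    metrics_all = rc("metrics_all.csv"),
    records = rc("records.csv"),
    ce_plane = rc("ce_plane.csv"),
    contingency = rj("contingency.json"),
    policy = rj("policy.json"),
    best = rj("best.json")$best,
    ground_truth = rc("ground_truth.csv"),
    provenance = rj("provenance.json"))
  if (file.exists(file.path(dir, "metrics_selected.csv"))) {
    out$metrics_selected <- rc("metrics_selected.csv")
  }
  if (file.exists(file.path(dir, "selection.json"))) {
    out$selection <- rj("selection.json")
  }
  out
}
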