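# Synthetic two-arm trial generator with known ground-truth potential
# outcomes for both arms.
#
# Structural model (see the methods vignette for rationale):
#   z_i ~ N(0,1)                      latent depression severity
#   x_ij = load_j * z_i + N(0,1)      numeric baseline features; the first
#                                     `n_informative_features` carry loadings
#   s_out = mean of informative x     severity index driving utilities
#   s_cost = 0.6 x_1 + 0.6 x_2        index driving resource use
#   u0  = u_mean - b * s_out + e0     baseline utility
#   u3  = u0 + r/2 + e3,  u6 = u0 + r + e6          (TAU trajectory)
#   BT adds the per-patient effect delta_i, ramped 0 / 0.5 / 1 over the
#   three measurements; utilities are clamped to [-0.5, 1].
#   delta_i = mean_bt_effect + w' x_i + het_sd * N(0,1)
# Costs arise from follow-up resource use (consultations, productivity
# hours, rare hospital admissions) shared between both potential arms; BT
# scales non-hospital use by a multiplier and adds the platform cost. Both
# potential (QALY, cost) pairs are recorded as ground truth; the observed
# outcome is exactly the potential outcome of the assigned arm.

#' Configuration for the synthetic trial generator
#'
#' Defaults describe a 350-patient two-arm trial (the size of a typical
#' blended-treatment effectiveness trial at the 6-month measurement) with a
#' modest average BT utility benefit, patient-level effect heterogeneity,
#' right-skewed societal costs driven by rare expensive hospital admissions,
#' and 25% missing baseline cells.
#'
#' Presets:
#' * `"default"`: heterogeneous BT effect independent of features.
#' * `"informative"`: feature-driven treatment effects and cost multipliers,
#'   and feature-dependent admission risk, so that baseline features carry
#'   genuine signal for outcome, cost and recommendation learning.
#' * `"null"`: no treatment effect, no feature signal, no platform cost.
#'
#' @param n_patients number of patients (>= 2).
#' @param arm_probability_bt probability of allocation to BT.
#' @param n_numeric_features,n_categorical_features,levels_per_categorical
#'   baseline feature-table shape.
#' @param mean_bt_effect mean BT-vs-TAU utility shift at month 6.
#' @param effect_heterogeneity_sd SD of the residual per-patient effect.
#' @param cost_lognormal_params `c(mu, sigma)` of the lognormal scale that
#'   multiplies each patient's productivity hours (resource-cost scale).
#' @param hospital_admission_rate probability of >= 1 hospital admission.
#' @param hospital_unit_cost euro per admission.
#' @param bt_platform_cost euro added to every BT patient's cost.
#' @param missing_rate MCAR masking rate for baseline feature cells.
#' @param seed integer seed; identical config + seed reproduces the dataset
#'   bit for bit.
#' @param preset one of `"default"`, `"informative"`, `"null"`; explicit
#'   arguments override preset values.
#' @param utility_noise_sd per-measurement utility noise SD.
#' @param baseline_utility_mean,severity_utility_slope location and severity
#'   slope of baseline utility.
#' @param recovery_mean,recovery_sd distribution of the 6-month natural
#'   recovery in utility under TAU.
#' @param n_informative_features,informative_loading how many numeric
#'   features load on the latent severity, and how strongly.
#' @param effect_modifier_weights named vector (over numeric features) of
#'   linear treatment-effect modifiers, or `NULL`.
#' @param admission_severity_slope logit-scale slope of admission risk on the
#'   cost severity index.
#' @param bt_cost_log_multiplier,bt_cost_multiplier_weights log multiplier
#'   (base + named feature weights) applied to BT non-hospital resource use.
#' @param consultation_unit_cost,hourly_rate unit prices used for costing.
#' @param consult_rate_base,consult_rate_severity,consult_rate_baseline_coef
#'   linear model of the 6-month consultation intensity:
#'   `base + severity * s_cost + coef * baseline consultations`, floored at 0.
#' @param hours_base,hours_severity,hours_noise_sd linear model of
#'   productivity hours lost over 6 months, multiplied by the lognormal
#'   resource-cost scale and floored at 0.
#' @param mar_missingness if `TRUE`, masking probability increases with
#'   severity (a missing-at-random mechanism); default is MCAR.
#' @param noise_scale multiplies all outcome-level noise; at 0 the potential
#'   outcomes are deterministic (and, with the feature-independent dials off,
#'   exactly linear) functions of the baseline features.
#' @return A validated object of class `generator_config`.
#' @export
generator_config <- function(n_patients = 350,
                             arm_probability_bt = 0.5,
                             n_numeric_features = 30,
                             n_categorical_features = 10,
                             levels_per_categorical = 3,
                             mean_bt_effect = 0.03,
                             effect_heterogeneity_sd = 0.05,
                             cost_lognormal_params = c(mu = 0, sigma = 0.35),
                             hospital_admission_rate = 0.08,
                             hospital_unit_cost = 4000,
                             bt_platform_cost = 300,
                             missing_rate = 0.25,
                             seed = 1,
                             preset = c("default", "informative", "null"),
                             utility_noise_sd = 0.05,
                             baseline_utility_mean = 0.62,
                             severity_utility_slope = 0.08,
                             recovery_mean = 0.03,
                             recovery_sd = 0.05,
                             n_informative_features = 4,
                             informative_loading = 0.8,
                             effect_modifier_weights = NULL,
                             admission_severity_slope = 0,
                             bt_cost_log_multiplier = 0,
                             bt_cost_multiplier_weights = NULL,
                             consultation_unit_cost = 100,
                             hourly_rate = 35,
                             consult_rate_base = 2,
                             consult_rate_severity = 1.5,
                             consult_rate_baseline_coef = 0.8,
                             hours_base = 40,
                             hours_severity = 14,
                             hours_noise_sd = 10,
                             mar_missingness = FALSE,
                             noise_scale = 1) {
  preset <- match.arg(preset)
  supplied <- names(match.call())[-1]
  cfg <- list(
    n_patients = n_patients, arm_probability_bt = arm_probability_bt,
    n_numeric_features = n_numeric_features,
    n_categorical_features = n_categorical_features,
    levels_per_categorical = levels_per_categorical,
    mean_bt_effect = mean_bt_effect,
    effect_heterogeneity_sd = effect_heterogeneity_sd,
    cost_lognormal_params = cost_lognormal_params,
    hospital_admission_rate = hospital_admission_rate,
    hospital_unit_cost = hospital_unit_cost,
    bt_platform_cost = bt_platform_cost,
    missing_rate = missing_rate, seed = seed, preset = preset,
    utility_noise_sd = utility_noise_sd,
    baseline_utility_mean = baseline_utility_mean,
    severity_utility_slope = severity_utility_slope,
    recovery_mean = recovery_mean, recovery_sd = recovery_sd,
    n_informative_features = n_informative_features,
    informative_loading = informative_loading,
    effect_modifier_weights = effect_modifier_weights,
    admission_severity_slope = admission_severity_slope,
    bt_cost_log_multiplier = bt_cost_log_multiplier,
    bt_cost_multiplier_weights = bt_cost_multiplier_weights,
    consultation_unit_cost = consultation_unit_cost,
    hourly_rate = hourly_rate,
    consult_rate_base = consult_rate_base,
    consult_rate_severity = consult_rate_severity,
    consult_rate_baseline_coef = consult_rate_baseline_coef,
    hours_base = hours_base, hours_severity = hours_severity,
    hours_noise_sd = hours_noise_sd,
    mar_missingness = mar_missingness, noise_scale = noise_scale)

  preset_patch <- switch(preset,
    default = list(),
    informative = list(
      effect_modifier_weights = c(num_1 = 0.035, num_3 = -0.035),
      effect_heterogeneity_sd = 0.02,
      admission_severity_slope = 1.0,
      hospital_unit_cost = 2000,
      cost_lognormal_params = c(mu = 0, sigma = 0.25),
      bt_cost_log_multiplier = -0.08,
      bt_cost_multiplier_weights = c(num_2 = -0.08)),
    null = list(
      mean_bt_effect = 0, effect_heterogeneity_sd = 0,
      bt_platform_cost = 0, severity_utility_slope = 0,
      informative_loading = 0, recovery_sd = 0.03,
      bt_cost_log_multiplier = 0,
      consult_rate_severity = 0, hours_severity = 0,
      hospital_admission_rate = 0,
      cost_lognormal_params = c(mu = 0, sigma = 0.15)))
  for (nm in setdiff(names(preset_patch), supplied)) {
    cfg[[nm]] <- preset_patch[[nm]]
  }
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  cfg$n_patients <- check_count(cfg$n_patients, "n_patients", min = 2L)
  check_probability(cfg$arm_probability_bt, "arm_probability_bt")
  cfg$n_numeric_features <-
    check_count(cfg$n_numeric_features, "n_numeric_features", min = 2L)
  cfg$n_categorical_features <-
    check_count(cfg$n_categorical_features, "n_categorical_features",
                min = 0L)
  cfg$levels_per_categorical <-
    check_count(cfg$levels_per_categorical, "levels_per_categorical",
                min = 2L)
  if (!is_scalar_number(cfg$mean_bt_effect)) {
    stopf("field 'mean_bt_effect' must be a single number")
  }
  check_nonnegative(cfg$effect_heterogeneity_sd, "effect_heterogeneity_sd")
  p <- cfg$cost_lognormal_params
  if (length(p) != 2 || anyNA(p)) {
    stopf("field 'cost_lognormal_params' must be c(mu, sigma)")
  }
  check_nonnegative(p[[2]], "cost_lognormal_params[sigma]")
  check_probability(cfg$hospital_admission_rate, "hospital_admission_rate")
  check_nonnegative(cfg$hospital_unit_cost, "hospital_unit_cost")
  check_nonnegative(cfg$bt_platform_cost, "bt_platform_cost")
  check_probability(cfg$missing_rate, "missing_rate")
  if (cfg$missing_rate >= 1) stopf("field 'missing_rate' must be < 1")
  cfg$seed <- check_count(cfg$seed, "seed")
  check_nonnegative(cfg$utility_noise_sd, "utility_noise_sd")
  check_nonnegative(cfg$noise_scale, "noise_scale")
  cfg$n_informative_features <-
    check_count(cfg$n_informative_features, "n_informative_features",
                min = 1L)
  if (cfg$n_informative_features > cfg$n_numeric_features) {
    stopf("field 'n_informative_features' exceeds 'n_numeric_features'")
  }
  structure(cfg, class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    "<generator_config: n=%d, preset='%s', mean BT effect=%.3f, seed=%d>\n",
    x$n_patients, x$preset, x$mean_bt_effect, as.integer(x$seed)))
  invisible(x)
}

#' Generate a synthetic two-arm trial
#'
#' Draws a complete trial dataset — mixed-type baseline features, arm labels,
#' EQ-5D utilities (and nearest value-set profiles) at months 0/3/6,
#' six-month resource use, PHQ-9 at baseline and month 6, and observed
#' (QALY, cost) outcomes — together with ground-truth potential outcomes
#' under *both* arms for every patient. All patient-level randomness is
#' shared between the two potential arms, so the observed outcome equals the
#' ground-truth value of the assigned arm exactly.
#'
#' When `config$missing_rate > 0`, baseline feature cells are masked via
#' [inject_missingness()] (outcome-defining fields are never masked).
#'
#' @param config a [generator_config()].
#' @param value_set value set used to attach EQ-5D profiles to the simulated
#'   utilities (nearest-profile inversion).
#' @return A list with elements `dataset` (class `trial_dataset`) and
#'   `truth` (class `ground_truth`, one row per patient with
#'   `true_qaly_tau`, `true_qaly_bt`, `true_cost_tau`, `true_cost_bt`).
#' @export
generate_trial <- function(config, value_set = synthetic_value_set()) {
  if (!inherits(config, "generator_config")) {
    config <- validate_generator_config(config)
  }
  cfg <- config
  n <- cfg$n_patients
  ns <- cfg$noise_scale
  withr::with_seed(derive_seed(cfg$seed, "trial"), {
    ids <- sprintf("P%04d", seq_len(n))
    arm <- ifelse(stats::runif(n) < cfg$arm_probability_bt, "BT", "TAU")

    # --- baseline features -------------------------------------------------
    z <- stats::rnorm(n)
    p <- cfg$n_numeric_features
    k <- cfg$n_informative_features
    load <- c(rep(cfg$informative_loading, k), rep(0, p - k))
    X <- sapply(seq_len(p), function(j) load[j] * z + stats::rnorm(n))
    colnames(X) <- paste0("num_", seq_len(p))
    s_out <- rowMeans(X[, seq_len(k), drop = FALSE])
    s_cost <- 0.6 * X[, 1] + 0.6 * X[, 2]

    L <- cfg$levels_per_categorical
    if (cfg$n_categorical_features == 0) {
      cats <- as.data.frame(matrix(nrow = n, ncol = 0))
    } else
    cats <- as.data.frame(lapply(seq_len(cfg$n_categorical_features),
      function(j) {
        if (j == 1) {
          # first categorical tracks severity
          br <- stats::qnorm(seq(0, 1, length.out = L + 1), sd = sqrt(2))
          cut(z + stats::rnorm(n), breaks = br, labels = paste0("l", 1:L),
              include.lowest = TRUE)
        } else {
          factor(sample(paste0("l", 1:L), n, replace = TRUE),
                 levels = paste0("l", 1:L))
        }
      }))
    names(cats) <- paste0("cat_", seq_len(cfg$n_categorical_features))

    consult_baseline <- stats::rpois(n, pmax(0.3, 3 + 1.2 * s_cost))

    # --- utility trajectories (potential, both arms) -----------------------
    nz <- function(sd) stats::rnorm(n, 0, sd) * ns
    u0_pre <- cfg$baseline_utility_mean -
      cfg$severity_utility_slope * s_out + nz(cfg$utility_noise_sd)
    r <- cfg$recovery_mean + nz(cfg$recovery_sd)
    delta <- cfg$mean_bt_effect +
      cfg$effect_heterogeneity_sd * stats::rnorm(n)
    if (!is.null(cfg$effect_modifier_weights)) {
      w <- cfg$effect_modifier_weights
      delta <- delta + drop(X[, names(w), drop = FALSE] %*% w)
    }
    e3 <- nz(cfg$utility_noise_sd); e6 <- nz(cfg$utility_noise_sd)
    u_tau <- cbind(u0_pre, u0_pre + 0.5 * r + e3, u0_pre + r + e6)
    u_bt <- u_tau + cbind(0, 0.5 * delta, delta)
    u_tau <- clamp(u_tau, -0.5, 1)
    u_bt <- clamp(u_bt, -0.5, 1)
    qaly_of <- function(u) 0.125 * u[, 1] + 0.25 * u[, 2] + 0.125 * u[, 3]
    true_qaly_tau <- qaly_of(u_tau)
    true_qaly_bt <- qaly_of(u_bt)

    # --- resource use and costs (potential, both arms) ---------------------
    mu_ln <- cfg$cost_lognormal_params[[1]]
    sg_ln <- cfg$cost_lognormal_params[[2]]
    scale_i <- exp(mu_ln + sg_ln * stats::rnorm(n) * ns)
    rate6 <- pmax(0, cfg$consult_rate_base +
                    cfg$consult_rate_severity * s_cost +
                    cfg$consult_rate_baseline_coef * consult_baseline)
    cons_tau <- if (ns == 0) rate6 else stats::rpois(n, rate6)
    hours_tau <- pmax(0, (cfg$hours_base + cfg$hours_severity * s_cost +
                            nz(cfg$hours_noise_sd)) * scale_i)
    adm_p <- if (cfg$hospital_admission_rate == 0) rep(0, n) else {
      stats::plogis(stats::qlogis(cfg$hospital_admission_rate) +
                      cfg$admission_severity_slope * s_cost)
    }
    admissions <- if (ns == 0) adm_p * 1.3 else {
      (stats::runif(n) < adm_p) * (1 + stats::rpois(n, 0.3))
    }
    log_mult <- rep(cfg$bt_cost_log_multiplier, n)
    if (!is.null(cfg$bt_cost_multiplier_weights)) {
      w <- cfg$bt_cost_multiplier_weights
      log_mult <- log_mult + drop(X[, names(w), drop = FALSE] %*% w)
    }
    mult <- exp(log_mult)
    cons_bt <- if (ns == 0) mult * cons_tau else round(mult * cons_tau)
    hours_bt <- mult * hours_tau

    uct <- unit_cost_table(
      unit_costs = c(consultation = cfg$consultation_unit_cost,
                     hospital_admission = cfg$hospital_unit_cost),
      hourly_rate = cfg$hourly_rate,
      bt_platform_cost = cfg$bt_platform_cost)
    res_tau <- data.frame(consultation = cons_tau,
                          hospital_admission = admissions)
    res_bt <- data.frame(consultation = cons_bt,
                         hospital_admission = admissions)
    true_cost_tau <- pmax(0, societal_cost(res_tau, hours_tau, "TAU", uct))
    true_cost_bt <- pmax(0, societal_cost(res_bt, hours_bt, "BT", uct))

    # --- PHQ-9, coupled to the same latent trajectory ----------------------
    phq0 <- clamp(round(15.4 + 3.5 * s_out + stats::rnorm(n, 0, 2) * ns),
                  0, 27)
    improve_tau <- 5.9 + 18 * (r - cfg$recovery_mean) +
      stats::rnorm(n, 0, 3) * ns
    phq6_tau <- clamp(round(phq0 - improve_tau), 0, 27)
    phq6_bt <- clamp(round(phq0 - improve_tau - 40 * delta), 0, 27)

    # --- observed rows follow the assigned arm -----------------------------
    bt <- arm == "BT"
    u_obs <- u_tau; u_obs[bt, ] <- u_bt[bt, ]
    qaly_obs <- ifelse(bt, true_qaly_bt, true_qaly_tau)
    cost_obs <- ifelse(bt, true_cost_bt, true_cost_tau)
    cons_obs <- ifelse(bt, cons_bt, cons_tau)
    hours_obs <- ifelse(bt, hours_bt, hours_tau)
    phq6_obs <- ifelse(bt, phq6_bt, phq6_tau)

    profiles <- nearest_profiles(as.vector(u_obs), value_set)
    eq5d <- data.frame(
      patient_id = rep(ids, 3),
      month = rep(c(0L, 3L, 6L), each = n),
      profiles,
      utility = as.vector(u_obs))
    eq5d <- eq5d[order(eq5d$patient_id, eq5d$month), ]
    rownames(eq5d) <- NULL

    baseline <- data.frame(
      patient_id = ids, X, cats,
      consent = "yes",
      consult_baseline = consult_baseline,
      phq9_baseline = phq0,
      eq5d_utility_baseline = u_obs[, 1],
      stringsAsFactors = FALSE)

    dataset <- structure(list(
      patients = data.frame(patient_id = ids, arm = arm,
                            stringsAsFactors = FALSE),
      baseline = baseline,
      eq5d = eq5d,
      resource_use = data.frame(patient_id = ids,
                                consultation = cons_obs,
                                hospital_admission = admissions,
                                hours_lost = hours_obs),
      phq9 = data.frame(patient_id = ids, phq9_baseline = phq0,
                        phq9_month6 = phq6_obs),
      outcomes = data.frame(patient_id = ids, qaly = qaly_obs,
                            cost = cost_obs),
      unit_costs = uct,
      config = cfg,
      latent = data.frame(patient_id = ids, severity = s_out,
                          cost_severity = s_cost, delta = delta)),
      class = "trial_dataset")

    truth <- structure(
      data.frame(patient_id = ids,
                 true_qaly_tau = true_qaly_tau, true_qaly_bt = true_qaly_bt,
                 true_cost_tau = true_cost_tau, true_cost_bt = true_cost_bt),
      class = c("ground_truth", "data.frame"))
    stopifnot(all(truth$true_qaly_tau >= -0.25 & truth$true_qaly_tau <= 0.5),
              all(truth$true_qaly_bt >= -0.25 & truth$true_qaly_bt <= 0.5),
              all(truth$true_cost_tau >= 0), all(truth$true_cost_bt >= 0))
  })
  if (cfg$missing_rate > 0) {
    dataset <- inject_missingness(
      dataset, cfg$missing_rate, seed = derive_seed(cfg$seed, "missingness"),
      mechanism = if (cfg$mar_missingness) "mar" else "mcar")
  }
  list(dataset = dataset, truth = truth)
}

# Map continuous utilities to the nearest profile of a value set.
nearest_profiles <- function(u, vs) {
  grid <- as.matrix(expand.grid(mobility = 1:5, self_care = 1:5,
                                usual_activities = 1:5,
                                pain_discomfort = 1:5,
                                anxiety_depression = 1:5))
  gu <- utility_from_profile(grid, vs)
  ord <- order(gu)
  gu_s <- gu[ord]
  idx <- findInterval(u, gu_s, all.inside = TRUE)
  lower_closer <- abs(u - gu_s[idx]) <= abs(gu_s[pmin(idx + 1, length(gu_s))] - u)
  pick <- ifelse(lower_closer, idx, pmin(idx + 1, length(gu_s)))
  as.data.frame(grid[ord[pick], , drop = FALSE])
}

#' @export
print.trial_dataset <- function(x, ...) {
  nmiss <- sum(is.na(x$baseline))
  cat(sprintf(
    "<trial_dataset: %d patients (%d TAU / %d BT), %d baseline columns, %d missing cells>\n",
    nrow(x$patients), sum(x$patients$arm == "TAU"),
    sum(x$patients$arm == "BT"), ncol(x$baseline) - 1L, nmiss))
  invisible(x)
}

#' Mask baseline feature cells
#'
#' Masks baseline feature cells completely at random at the given expected
#' rate (or, with `mechanism = "mar"`, with probability increasing in the
#' patient's latent severity). Outcome-defining fields — arm assignment,
#' EQ-5D measurements, resource use, costs and QALYs — are never masked.
#' The pre-masking values and the mask itself are retained in attributes
#' `original` and `mask` of `dataset$baseline` so that imputation quality
#' can be assessed.
#'
#' @param dataset a `trial_dataset`.
#' @param rate expected fraction of masked baseline cells, in `[0, 1)`.
#' @param seed integer seed; the same seed reproduces the same mask.
#' @param mechanism `"mcar"` (default) or `"mar"`.
#' @return The dataset with masked baseline cells.
#' @export
inject_missingness <- function(dataset, rate, seed = 1,
                               mechanism = c("mcar", "mar")) {
  if (!inherits(dataset, "trial_dataset")) {
    stopf("'dataset' must be a trial_dataset")
  }
  mechanism <- match.arg(mechanism)
  if (!is_scalar_number(rate) || rate < 0) stopf("rate must be >= 0")
  if (rate >= 1) stopf("rate must be < 1")
  if (rate == 0) return(dataset)
  base <- dataset$baseline
  cols <- setdiff(names(base), "patient_id")
  n <- nrow(base)
  withr::with_seed(derive_seed(seed, "mask"), {
    if (mechanism == "mcar") {
      cell_p <- matrix(rate, n, length(cols))
    } else {
      w <- stats::plogis(dataset$latent$severity)
      cell_p <- matrix(clamp(rate * w / mean(w), 0, 0.99), n, length(cols))
    }
    mask <- matrix(stats::runif(n * length(cols)) < cell_p, n, length(cols),
                   dimnames = list(NULL, cols))
  })
  original <- base
  for (j in seq_along(cols)) base[[cols[j]]][mask[, j]] <- NA
  attr(base, "original") <- original
  attr(base, "mask") <- mask
  dataset$baseline <- base
  dataset
}

#' Write a simulated trial to disk
#'
#' Writes a wide baseline CSV (arm, baseline features, six-month resource
#' totals and observed outcomes), a long repeated-measures CSV (EQ-5D and
#' PHQ-9), a JSON ground-truth sidecar and the generator configuration as
#' YAML.
#'
#' @param sim result of [generate_trial()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ds <- sim$dataset
  wide <- Reduce(function(a, b) merge(a, b, by = "patient_id", sort = FALSE),
                 list(ds$patients, ds$baseline, ds$resource_use, ds$outcomes))
  utils::write.csv(wide, file.path(dir, "baseline.csv"), row.names = FALSE)
  eq <- ds$eq5d
  eq$measure <- "eq5d"
  phq_long <- data.frame(patient_id = rep(ds$phq9$patient_id, 2),
                         month = rep(c(0L, 6L), each = nrow(ds$phq9)),
                         score = c(ds$phq9$phq9_baseline,
                                   ds$phq9$phq9_month6),
                         measure = "phq9")
  utils::write.csv(eq, file.path(dir, "repeated_measures_eq5d.csv"),
                   row.names = FALSE)
  utils::write.csv(phq_long, file.path(dir, "repeated_measures_phq9.csv"),
                   row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "ground_truth.json"),
                       digits = NA, dataframe = "columns")
  cfg <- sim$dataset$config
  cfg$effect_modifier_weights <- as.list(cfg$effect_modifier_weights)
  cfg$bt_cost_multiplier_weights <- as.list(cfg$bt_cost_multiplier_weights)
  cfg$cost_lognormal_params <- as.list(cfg$cost_lognormal_params)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
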