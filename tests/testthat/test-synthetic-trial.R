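# Synthetic trial generator: contracts, ground-truth oracles, missingness.

test_that("generated trials honour the size contract with both arms populated", {
  sim <- generate_trial(generator_config(n_patients = 350, seed = 1))
  ds <- sim$dataset
  expect_identical(nrow(ds$patients), 350L)
  expect_identical(nrow(sim$truth), 350L)
  expect_true(all(table(ds$patients$arm) > 0))
  expect_setequal(unique(ds$eq5d$month), c(0L, 3L, 6L))
  expect_identical(nrow(ds$eq5d), 3L * 350L)
  # utilities stay inside the value-set range, QALYs inside the horizon range
  expect_true(all(ds$eq5d$utility >= -0.5 & ds$eq5d$utility <= 1))
  expect_true(all(sim$truth$true_qaly_tau >= -0.25 &
                    sim$truth$true_qaly_tau <= 0.5))
})

test_that("null effects make both potential arms identical", {
  sim <- generate_trial(generator_config(
    n_patients = 100, effect_heterogeneity_sd = 0, mean_bt_effect = 0,
    bt_platform_cost = 0, seed = 2))
  expect_identical(sim$truth$true_qaly_bt, sim$truth$true_qaly_tau)
  expect_identical(sim$truth$true_cost_bt, sim$truth$true_cost_tau)
})

test_that("mean ground-truth QALY effect matches the trapezoidal closed form", {
  # the BT utility shift is ramped 0 / 0.5 / 1 over months 0/3/6, so the
  # trapezoid passes 0.125*0 + 0.25*(delta/2) + 0.125*delta = 0.25*delta
  sim <- generate_trial(generator_config(n_patients = 2000,
                                         mean_bt_effect = 0.05, seed = 7))
  d <- sim$truth$true_qaly_bt - sim$truth$true_qaly_tau
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 0.25 * 0.05), 3 * se)
})

test_that("identical config and seed reproduce the dataset bit for bit", {
  cfg <- generator_config(n_patients = 80, seed = 9, missing_rate = 0.2)
  s1 <- generate_trial(cfg)
  s2 <- generate_trial(cfg)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
  s3 <- generate_trial(generator_config(n_patients = 80, seed = 10,
                                        missing_rate = 0.2))
  expect_false(identical(s1$dataset$outcomes$qaly, s3$dataset$outcomes$qaly))
})

test_that("observed outcomes equal the assigned arm's potential outcomes exactly", {
  sim <- quick_trial(n = 200, seed = 3)
  bt <- sim$dataset$patients$arm == "BT"
  expect_identical(sim$dataset$outcomes$qaly,
                   ifelse(bt, sim$truth$true_qaly_bt, sim$truth$true_qaly_tau))
  expect_identical(sim$dataset$outcomes$cost,
                   ifelse(bt, sim$truth$true_cost_bt, sim$truth$true_cost_tau))
})

test_that("rare expensive hospital admissions give costs a right-skewed tail", {
  sim <- quick_trial(n = 600, seed = 21)
  cost <- sim$dataset$outcomes$cost
  skew <- mean(((cost - mean(cost)) / sd(cost))^3)
  expect_gt(skew, 0)
  # admissions are rare but present and expensive
  adm <- sim$dataset$resource_use$hospital_admission
  expect_gt(mean(adm > 0), 0.01)
  expect_lt(mean(adm > 0), 0.3)
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(generator_config(n_patients = 1), "n_patients")
  expect_error(generator_config(arm_probability_bt = 1.5),
               "arm_probability_bt")
  expect_error(generator_config(effect_heterogeneity_sd = -0.1),
               "effect_heterogeneity_sd")
  expect_error(generator_config(missing_rate = 1), "missing_rate")
  expect_error(generator_config(hospital_admission_rate = 2),
               "hospital_admission_rate")
  expect_error(generator_config(levels_per_categorical = 1),
               "levels_per_categorical")
})

test_that("missingness injection masks at the requested rate, reproducibly", {
  sim <- quick_trial(n = 250, seed = 5, missing_rate = 0)
  ds <- sim$dataset
  expect_identical(inject_missingness(ds, 0), ds)
  expect_error(inject_missingness(ds, 1), "< 1")

  m1 <- inject_missingness(ds, 0.4, seed = 17)
  m2 <- inject_missingness(ds, 0.4, seed = 17)
  expect_identical(attr(m1$baseline, "mask"), attr(m2$baseline, "mask"))
  n_cells <- nrow(ds$baseline) * (ncol(ds$baseline) - 1L)
  n_masked <- sum(attr(m1$baseline, "mask"))
  # 99% binomial interval around rate * n_cells
  expect_gte(n_masked, qbinom(0.005, n_cells, 0.4))
  expect_lte(n_masked, qbinom(0.995, n_cells, 0.4))
  # original values retained for imputation-quality checks
  expect_identical(attr(m1$baseline, "original"), ds$baseline)
})

test_that("outcome-defining fields are never masked", {
  sim <- quick_trial(n = 150, seed = 6, missing_rate = 0.5)
  ds <- sim$dataset
  expect_false(anyNA(ds$patients$arm))
  expect_false(anyNA(ds$outcomes))
  expect_false(anyNA(ds$eq5d$utility))
  expect_false(anyNA(ds$resource_use))
})

test_that("the MAR hook masks severe patients more often", {
  sim <- quick_trial(n = 400, seed = 8, missing_rate = 0)
  m <- inject_missingness(sim$dataset, 0.3, seed = 4, mechanism = "mar")
  per_row <- rowSums(attr(m$baseline, "mask"))
  expect_gt(cor(sim$dataset$latent$severity, per_row), 0.1)
})

test_that("written trials round-trip their ground truth and config", {
  sim <- quick_trial(n = 30, seed = 12, missing_rate = 0.1)
  dir <- withr::local_tempdir()
  write_trial(sim, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "baseline.csv", "repeated_measures_eq5d.csv",
    "repeated_measures_phq9.csv", "ground_truth.json", "config.yaml")))))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$true_qaly_bt, sim$truth$true_qaly_bt)
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_identical(cfg$n_patients, 30L)
  wide <- read.csv(file.path(dir, "baseline.csv"))
  expect_identical(nrow(wide), 30L)
  expect_true(all(c("arm", "qaly", "cost") %in% names(wide)))
})
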