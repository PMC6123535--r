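# Merging, degenerate-feature pruning, imputation, encoding, PHQ-9 summary.

test_that("sources merge on patient id, dropping patients without both outcomes", {
  outcomes <- data.frame(patient_id = paste0("P", 1:5),
                         qaly = c(0.3, 0.4, 0.2, 0.35, 0.25),
                         cost = c(100, 200, NA, 400, 500))
  t1 <- data.frame(patient_id = paste0("P", 1:5), a = 1:5, b = letters[1:5])
  t2 <- data.frame(patient_id = paste0("P", 5:1), c = 11:15, d = 1:5,
                   e = runif(5))
  t3 <- data.frame(patient_id = paste0("P", 1:5), f = 5:1, g = rnorm(5))
  fm <- merge_sources(list(q1 = t1, q2 = t2, q3 = t3), outcomes)
  expect_identical(length(fm$ids), 4L)   # P3 lacks cost
  expect_identical(length(fm$kinds), 7L) # 2 + 3 + 2 feature columns
  expect_false("P3" %in% fm$ids)
  # row alignment respects each source's own id order
  expect_equal(fm$data$c[fm$ids == "P5"], 11)
})

test_that("single-source merge is the identity and collisions get source prefixes", {
  outcomes <- data.frame(patient_id = c("A", "B"), qaly = c(0.1, 0.2),
                         cost = c(5, 6))
  t1 <- data.frame(patient_id = c("A", "B"), age = c(30, 40))
  fm <- merge_sources(list(t1), outcomes)
  expect_identical(fm$data$age, c(30, 40))
  t2 <- data.frame(patient_id = c("A", "B"), age = c(1, 2))
  fm2 <- merge_sources(list(t1, t2), outcomes)
  expect_setequal(names(fm2$data), c("src1.age", "src2.age"))
  t_dup <- data.frame(patient_id = c("A", "A"), x = 1:2)
  expect_error(merge_sources(list(bad = t_dup), outcomes), "bad")
})

test_that("degenerate features are removed, including within-arm degeneracy", {
  df <- data.frame(patient_id = paste0("P", 1:6),
                   ok1 = rnorm(6), ok2 = c("a", "b", "a", "b", "a", "b"),
                   ok3 = 1:6,
                   const = rep(5, 6), gone = rep(NA_real_, 6))
  fm <- feature_matrix(df)
  res <- drop_degenerate_features(fm)
  expect_setequal(names(res$matrix$data), c("ok1", "ok2", "ok3"))
  expect_setequal(res$report$removed$feature, c("const", "gone"))

  # no degenerate columns: identity
  res2 <- drop_degenerate_features(res$matrix)
  expect_identical(res2$matrix$data, res$matrix$data)
  expect_identical(res2$report$n_removed, 0L)

  # constant within BT but varying in TAU: removed under an arm split
  arm <- c("TAU", "TAU", "TAU", "BT", "BT", "BT")
  df$armconst <- c(1, 2, 3, 7, 7, 7)
  fm3 <- feature_matrix(df[c("patient_id", "ok1", "armconst")])
  res3 <- drop_degenerate_features(fm3, arm_split = arm)
  expect_false("armconst" %in% names(res3$matrix$data))
  expect_match(
    res3$report$removed$reason[res3$report$removed$feature == "armconst"],
    "within_arm:BT")
})

test_that("median/mode imputation fills from the observed column summaries", {
  fm <- toy_feature_matrix()
  out <- impute_median_mode(fm)
  expect_identical(out$data$score[3], 4)       # median of {1,2,10,4,6}
  expect_identical(out$data$sex[4], "f")       # mode of {f,m,f,f,m}
  expect_identical(out$data$age[3], median(c(30, 40, 50, 60, 35)))
  expect_false(anyNA(out$data))
  # observed cells unchanged
  expect_identical(out$data$age[-3], fm$data$age[-3])
  # identity on complete matrices
  expect_identical(impute_median_mode(out), out)
})

test_that("mode ties break to the lexicographically smallest level", {
  fm <- feature_matrix(data.frame(patient_id = 1:5,
                                  g = c("b", "a", "b", "a", NA)))
  expect_identical(impute_median_mode(fm)$data$g[5], "a")
})

test_that("imputed values never leave the observed support", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      df <- data.frame(patient_id = 1:30,
                       num = sample(c(NA, rnorm(5)), 30, replace = TRUE),
                       cat = sample(c(NA, letters[1:4]), 30, replace = TRUE))
      df$num[1] <- 0; df$cat[1] <- "a"  # guarantee an observed value
      fm <- feature_matrix(df)
      out <- impute_median_mode(fm)
      obs_num <- df$num[!is.na(df$num)]
      expect_true(all(out$data$num >= min(obs_num) &
                        out$data$num <= max(obs_num)))
      expect_true(all(out$data$cat %in% df$cat[!is.na(df$cat)]))
    }
  })
})

test_that("distribution-sampling imputation is reproducible and unbiased", {
  fm <- toy_feature_matrix()
  expect_identical(impute_distribution_sample(fm, seed = 4),
                   impute_distribution_sample(fm, seed = 4))
  expect_false(identical(impute_distribution_sample(fm, seed = 4)$data$age,
                         impute_distribution_sample(fm, seed = 5)$data$age))

  # single observed value: fill with it, warn
  fm1 <- feature_matrix(data.frame(patient_id = 1:3, v = c(7, NA, NA)))
  expect_warning(out <- impute_distribution_sample(fm1), "single observed")
  expect_identical(out$data$v, c(7, 7, 7))

  # CLT check: fills follow Normal(observed mean, observed SD)
  withr::with_seed(8, obs <- rnorm(100, 5, 2))
  big <- feature_matrix(data.frame(patient_id = 1:10100,
                                   v = c(obs, rep(NA_real_, 10000))))
  out2 <- impute_distribution_sample(big, seed = 99)
  fills <- out2$data$v[101:10100]
  expect_lt(abs(mean(fills) - mean(obs)), 3 * sd(obs) / sqrt(10000))
})

test_that("encoding expands categoricals against the modal reference level", {
  df <- data.frame(patient_id = 1:4, x = c(1.5, 2, 3, 4),
                   g = c("a", "b", "c", "a"))
  dm <- encode_features(feature_matrix(df))
  expect_identical(ncol(dm$X), 3L)  # 1 numeric + (3 - 1) indicators
  expect_setequal(colnames(dm$X), c("x", "g=b", "g=c"))  # "a" is the mode
  expect_identical(unname(dm$X[, "g=b"]), c(0, 1, 0, 0))
  # provenance maps each design column to exactly one source feature
  expect_identical(nrow(dm$provenance), 3L)
  expect_identical(anyDuplicated(dm$provenance$column), 0L)
  expect_setequal(unique(dm$provenance$source), c("x", "g"))

  # all-numeric matrices pass through
  dfn <- data.frame(patient_id = 1:3, a = 1:3, b = c(2, 4, 6))
  dmn <- encode_features(feature_matrix(dfn))
  expect_identical(unname(dmn$X[, "a"]), as.numeric(1:3))
})

test_that("unseen levels at transform time map to a zero indicator block", {
  train <- feature_matrix(data.frame(patient_id = 1:4,
                                     g = c("a", "a", "b", "b")))
  dm <- encode_features(train)
  new <- feature_matrix(data.frame(patient_id = 5:6, g = c("z", "b")))
  expect_warning(Xn <- encode_apply(dm, new), "unseen")
  expect_identical(unname(Xn[1, ]), 0)      # level z: all-zero block
  expect_identical(unname(Xn[2, "g=b"]), 1)
})

test_that("PHQ-9 improvement summary counts improvers and applies a Welch t-test", {
  # no change: nobody improves
  arm <- c("TAU", "TAU", "BT", "BT")
  s <- c(10, 12, 11, 9)
  out0 <- improvement_summary(arm, s, s)
  expect_identical(out0$summary$n_improved, c(0L, 0L))

  # hand-computed Welch t on TAU ends {10, 8} vs BT ends {4, 2}
  out <- improvement_summary(arm, c(15, 15, 15, 15), c(10, 8, 4, 2))
  expect_identical(out$summary$mean_end, c(9, 3))
  t_hand <- (9 - 3) / sqrt(var(c(10, 8)) / 2 + var(c(4, 2)) / 2)
  df_hand <- (1 + 1)^2 / (1 / 1 + 1 / 1)
  expect_equal(out$p_value, 2 * pt(-t_hand, df_hand))
  expect_error(improvement_summary(c("TAU", "TAU"), c(1, 2), c(1, 2)),
               "both arms")
})

test_that("a positive mean BT effect lowers the BT arm's mean end PHQ-9", {
  sim <- quick_trial(n = 350, seed = 14, missing_rate = 0)
  ds <- sim$dataset
  out <- improvement_summary(ds$patients$arm, ds$phq9$phq9_baseline,
                             ds$phq9$phq9_month6)
  means <- setNames(out$summary$mean_end, out$summary$arm)
  expect_lt(means[["BT"]], means[["TAU"]])
})
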