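# ICER, plane geometry, NMB recommendation rule, contingency and
# counterfactual policy evaluation.

test_that("predict_both_arms returns four clipped predictions incl. the counterfactual arm", {
  models <- list(tau_outcome = fit_mean_reference(c(0.2, 0.3)),
                 bt_outcome = fit_mean_reference(c(0.4, 0.5)),
                 tau_cost = fit_mean_reference(c(1000, 2000)),
                 bt_cost = fit_mean_reference(c(1500, 2500)))
  X <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("a", "b")))
  pb <- predict_both_arms(models, X)
  expect_identical(pb$q_tau, rep(0.25, 3))
  expect_identical(pb$q_bt, rep(0.45, 3))   # every patient gets both arms
  expect_identical(pb$c_tau, rep(1500, 3))
  expect_identical(pb$c_bt, rep(2000, 3))

  # clipping to the attainable QALY range and nonnegative costs
  mx <- list(tau_outcome = fit_mean_reference(c(0.9, 0.9)),
             bt_outcome = fit_mean_reference(c(-4, -4)),
             tau_cost = fit_mean_reference(c(-50, -50)),
             bt_cost = fit_mean_reference(c(10, 10)))
  pb2 <- predict_both_arms(mx, X)
  expect_identical(pb2$q_tau, rep(0.5, 3))
  expect_identical(pb2$q_bt, rep(-0.25, 3))
  expect_identical(pb2$c_tau, rep(0, 3))

  # feature mismatch is rejected with the missing column's name
  d <- toy_linear_data()
  mm <- models
  mm$tau_outcome <- fit_ridge(d$X, d$y, 1)
  expect_error(predict_both_arms(mm, X), "x1")
})

test_that("icer divides where meaningful and flags dominance and zero effect", {
  one <- icer(5000, 0.2)
  expect_identical(one$icer, 25000)
  expect_identical(one$status, "ratio")
  expect_identical(icer(100, 0)$status, "undefined_zero_delta_q")
  expect_identical(icer(-10, 0.1)$status, "bt_dominates")
  expect_identical(icer(10, -0.1)$status, "tau_dominates")
  # the SW far-outlier: cheaper but less effective, ratio still defined
  out <- icer(-60420, -0.04)
  expect_equal(out$icer, 1510500)
  expect_identical(out$status, "ratio")
  expect_identical(classify_quadrant(-0.04, -60420), "SW")
})

test_that("quadrants follow the sign pattern with an axis catch-all", {
  expect_identical(classify_quadrant(0.1, 1000), "NE")
  expect_identical(classify_quadrant(0, 0), "axis")
  grid <- expand.grid(dq = c(-1, 1), dc = c(-1, 1))
  got <- classify_quadrant(grid$dq, grid$dc)
  expect_identical(got, c("SW", "SE", "NW", "NE"))
  expect_identical(classify_quadrant(0, 5), "axis")
  expect_identical(classify_quadrant(-1, 0), "axis")
})

test_that("the NMB rule reproduces the ICER threshold and dominance case analysis", {
  expect_identical(recommend(0.2, 4000, 25000), "BT")    # ICER 20k < 25k
  expect_identical(recommend(0.2, 6000, 25000), "TAU")   # ICER 30k > 25k
  expect_identical(recommend(0.1, -500, 25000), "BT")    # SE: BT dominates
  expect_identical(recommend(-0.1, 500, 25000), "TAU")   # NW: TAU dominates
  expect_identical(recommend(0.1, 2500, 25000), "TAU")   # NMB exactly 0
  expect_error(recommend(0.1, 0, wtp = 0), "wtp")

  # exhaustive sign x threshold grid against an independent case analysis
  oracle <- function(dq, dc, wtp) {
    if (dq > 0 && dc <= 0) return("BT")
    if (dq <= 0 && dc >= 0) return("TAU")
    if (dq > 0 && dc > 0) return(if (dc / dq < wtp) "BT" else "TAU")
    if (dq < 0 && dc < 0) return(if (dc / dq > wtp) "BT" else "TAU")
    if (dq == 0) return(if (dc < 0) "BT" else "TAU")
    stop("unreachable")
  }
  for (wtp in c(1000, 25000, 35000)) {
    for (dq in c(-0.3, -0.01, 0, 0.01, 0.3)) {
      for (dc in c(-8000, -250, 0, 250, 8000)) {
        expect_identical(recommend(dq, dc, wtp), oracle(dq, dc, wtp),
                         label = sprintf("dq=%g dc=%g wtp=%g", dq, dc, wtp))
      }
    }
  }
})

test_that("BT recommendations are monotone in WTP when all effects are positive", {
  withr::with_seed(9, {
    dq <- runif(100, 0.001, 0.3)
    dc <- rnorm(100, 1000, 3000)
  })
  wtps <- c(5000, 15000, 25000, 35000, 60000)
  counts <- sapply(wtps, function(w) sum(recommend(dq, dc, w) == "BT"))
  expect_true(all(diff(counts) >= 0))
  # boundary patient flips exactly at icer = wtp
  expect_identical(recommend(0.1, 2500, 25000), "TAU")
  expect_identical(recommend(0.1, 2500, 25000 + 1e-6), "BT")
})

test_that("contingency reproduces printed cell percentages and concordance", {
  received <- c(rep("BT", 70 + 102), rep("TAU", 85 + 93))
  recommended <- c(rep("BT", 70), rep("TAU", 102), rep("BT", 85),
                   rep("TAU", 93))
  ct <- contingency(received, recommended)
  expect_equal(ct$concordance_pct, 100 * 163 / 350)
  expect_equal(round(ct$concordance_pct, 2), 46.57)
  expect_equal(round(ct$percentages["BT", "BT"], 2), 20.00)
  expect_equal(round(ct$percentages["BT", "TAU"], 2), 29.14)
  expect_equal(round(ct$percentages["TAU", "BT"], 2), 24.29)
  expect_equal(round(ct$percentages["TAU", "TAU"], 2), 26.57)

  all_c <- contingency(c("BT", "TAU"), c("BT", "TAU"))
  expect_identical(all_c$concordance_pct, 100)
  expect_error(contingency("BT", c("BT", "TAU")), "equal length")
})

test_that("counterfactual policy value substitutes only discordant patients", {
  # all concordant: exactly the observed totals, zero percent change
  pe <- counterfactual_policy_value(c(0.3, 0.4), c(100, 200),
                                    c(9, 9), c(9, 9), c(TRUE, TRUE))
  expect_identical(pe$pct_change_qaly, 0)
  expect_identical(pe$pct_change_cost, 0)
  expect_identical(pe$recommended$total_cost, 300)

  # one discordant patient swaps observed 2000 for predicted 1000
  pe2 <- counterfactual_policy_value(
    observed_q = c(0.3, 0.2), observed_c = c(2000, 500),
    predicted_q = c(0.3, 0.2), predicted_c = c(1000, 999),
    concordant = c(FALSE, TRUE))
  expect_identical(pe2$recommended$total_cost - pe2$observed$total_cost,
                   -1000)

  # predictions := observed values reduces exactly to the observed totals
  withr::with_seed(3, {
    q <- runif(50, 0, 0.5); cc <- rlnorm(50, 7)
    conc <- runif(50) < 0.5
  })
  pe3 <- counterfactual_policy_value(q, cc, q, cc, conc)
  expect_identical(pe3$recommended$total_qaly, pe3$observed$total_qaly)
  expect_identical(pe3$pct_change_cost, 0)

  expect_warning(
    pe4 <- counterfactual_policy_value(c(0, 0), c(1, 1), c(1, 1), c(1, 1),
                                       c(FALSE, FALSE)),
    "zero")
  expect_true(is.na(pe4$pct_change_qaly))
})

test_that("oracle predictions make the recommended allocation NMB-optimal", {
  sim <- quick_trial(n = 300, seed = 19, missing_rate = 0)
  tr <- sim$truth
  arm <- sim$dataset$patients$arm
  for (wtp in c(25000, 35000)) {
    dq <- tr$true_qaly_bt - tr$true_qaly_tau
    dc <- tr$true_cost_bt - tr$true_cost_tau
    rec <- recommend(dq, dc, wtp)
    nmb <- function(q, c) sum(wtp * q - c)
    pol <- nmb(ifelse(rec == "BT", tr$true_qaly_bt, tr$true_qaly_tau),
               ifelse(rec == "BT", tr$true_cost_bt, tr$true_cost_tau))
    obs <- nmb(ifelse(arm == "BT", tr$true_qaly_bt, tr$true_qaly_tau),
               ifelse(arm == "BT", tr$true_cost_bt, tr$true_cost_tau))
    all_bt <- nmb(tr$true_qaly_bt, tr$true_cost_bt)
    all_tau <- nmb(tr$true_qaly_tau, tr$true_cost_tau)
    expect_gte(pol, obs)
    expect_gte(pol, all_bt)
    expect_gte(pol, all_tau)
  }
})

test_that("recommendation records and the CE-plane export are internally consistent", {
  sim <- quick_trial(n = 60, seed = 25, missing_rate = 0)
  tr <- sim$truth
  preds <- data.frame(q_tau = tr$true_qaly_tau, q_bt = tr$true_qaly_bt,
                      c_tau = tr$true_cost_tau, c_bt = tr$true_cost_bt)
  rec <- recommendation_records(tr$patient_id, preds,
                                sim$dataset$patients$arm, wtp = 25000)
  expect_identical(rec$concordant, rec$recommended == rec$received)
  # quadrant consistent with the signs of the deltas
  expect_identical(rec$quadrant, classify_quadrant(rec$delta_q, rec$delta_c))
  # dominance flags coincide with the quadrant interiors
  expect_identical(rec$icer_status == "bt_dominates", rec$quadrant == "SE")
  expect_identical(rec$icer_status == "tau_dominates", rec$quadrant == "NW")

  ce <- ce_plane_export(rec)
  expect_identical(nrow(ce), nrow(rec))
  expect_named(ce, c("patient_id", "delta_q", "delta_c", "concordant"))
  empty <- ce_plane_export(rec[0, ])
  expect_identical(nrow(empty), 0L)
})
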