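# Individualized cost-effectiveness: per-patient ICERs, cost-effectiveness
# plane positions, treatment recommendations at a willingness-to-pay
# threshold, received-vs-recommended contingency, and counterfactual
# evaluation of the recommended allocation.
#
# Plane conventions (delta = BT - TAU): NE = BT more effective and more
# expensive; SE = BT more effective and cheaper (BT dominates); SW = BT
# less effective and cheaper; NW = BT less effective and more expensive
# (TAU dominates). The decision rule is the net monetary benefit
# NMB = wtp * delta_q - delta_c: recommend BT iff NMB > 0. Within NE this
# is exactly "BT iff ICER < wtp" (above the threshold BT is too
# expensive), within SW it is "BT iff the savings per QALY forgone exceed
# wtp", and in SE/NW it reproduces dominance; it also handles the
# delta_q = 0 ray where the ICER is undefined.

#' Predict QALY and cost under both arms
#'
#' Applies the four fitted (arm x target) models to each patient's encoded
#' baseline features, yielding point predictions of the potential outcome
#' and cost under TAU and under BT — including the counterfactual arm the
#' patient did not receive. QALY predictions are clipped to the attainable
#' range of the 0.5-year horizon and cost predictions are floored at 0.
#'
#' @param models named list with elements `tau_outcome`, `bt_outcome`,
#'   `tau_cost`, `bt_cost`, each a `model_fit` trained on the corresponding
#'   arm subset.
#' @param X encoded baseline features (patients x design columns).
#' @param min_utility lower bound of the value set's utility range (default
#'   -0.5), so QALYs are clipped to `[0.5 * min_utility, 0.5]`.
#' @return data.frame with columns `q_tau`, `q_bt`, `c_tau`, `c_bt`.
#' @export
predict_both_arms <- function(models, X, min_utility = -0.5) {
  need <- c("tau_outcome", "bt_outcome", "tau_cost", "bt_cost")
  if (!all(need %in% names(models))) {
    stopf("models must contain: %s", paste(need, collapse = ", "))
  }
  for (nm in need) {
    if (!inherits(models[[nm]], "model_fit")) {
      stopf("models$%s is not a model_fit", nm)
    }
  }
  q_lo <- 0.5 * min_utility
  data.frame(
    q_tau = clamp(predict(models$tau_outcome, X), q_lo, 0.5),
    q_bt = clamp(predict(models$bt_outcome, X), q_lo, 0.5),
    c_tau = pmax(0, predict(models$tau_cost, X)),
    c_bt = pmax(0, predict(models$bt_cost, X)))
}

#' Incremental cost-effectiveness ratio of a (delta cost, delta QALY) pair
#'
#' `delta_c / delta_q` where the ratio is decision-relevant (NE and SW
#' quadrants); in the SE interior BT dominates and in the NW interior TAU
#' dominates, so a ratio would be meaningless and a dominance flag is
#' returned instead; `delta_q = 0` yields `undefined_zero_delta_q`.
#'
#' @param delta_c incremental cost (BT - TAU), euro.
#' @param delta_q incremental QALYs (BT - TAU).
#' @return data.frame with columns `icer` (numeric, `NA` where flagged) and
#'   `status` (`"ratio"`, `"bt_dominates"`, `"tau_dominates"`,
#'   `"undefined_zero_delta_q"`). Vectorized.
#' @export
icer <- function(delta_c, delta_q) {
  if (length(delta_c) != length(delta_q)) {
    stopf("delta_c and delta_q must be aligned")
  }
  status <- rep("ratio", length(delta_q))
  status[delta_q == 0] <- "undefined_zero_delta_q"
  status[delta_q > 0 & delta_c < 0] <- "bt_dominates"
  status[delta_q < 0 & delta_c > 0] <- "tau_dominates"
  val <- ifelse(status == "ratio", delta_c / delta_q, NA_real_)
  data.frame(icer = val, status = status, stringsAsFactors = FALSE)
}

#' Cost-effectiveness plane quadrant
#'
#' @param delta_q,delta_c incremental QALYs and cost (BT - TAU).
#' @return `"NE"`, `"SE"`, `"SW"`, `"NW"`, or `"axis"` when either
#'   difference is exactly zero. Vectorized.
#' @export
classify_quadrant <- function(delta_q, delta_c) {
  if (length(delta_c) != length(delta_q)) {
    stopf("delta_q and delta_c must be aligned")
  }
  out <- rep("axis", length(delta_q))
  out[delta_q > 0 & delta_c > 0] <- "NE"
  out[delta_q > 0 & delta_c < 0] <- "SE"
  out[delta_q < 0 & delta_c < 0] <- "SW"
  out[delta_q < 0 & delta_c > 0] <- "NW"
  out
}

#' Recommend an arm at a willingness-to-pay threshold
#'
#' Net-monetary-benefit rule: recommend BT iff
#' `wtp * delta_q - delta_c > 0`. Ties (NMB exactly 0) go to TAU, the
#' status-quo arm.
#'
#' @param delta_q,delta_c incremental QALYs and cost (BT - TAU).
#' @param wtp willingness to pay per QALY gained, euro (> 0); 25,000 is the
#'   conservative end of commonly cited thresholds.
#' @return Character vector of `"TAU"` / `"BT"`.
#' @export
recommend <- function(delta_q, delta_c, wtp = 25000) {
  if (!is_scalar_number(wtp) || wtp <= 0) stopf("wtp must be > 0")
  if (length(delta_c) != length(delta_q)) {
    stopf("delta_q and delta_c must be aligned")
  }
  ifelse(wtp * delta_q - delta_c > 0, "BT", "TAU")
}

#' Per-patient recommendation records
#'
#' Assembles the full per-patient record: predicted (QALY, cost) under both
#' arms, their differences, ICER/dominance status, plane quadrant, the
#' recommendation at `wtp`, the received arm and the concordance flag.
#'
#' @param patient_id patient identifiers.
#' @param predictions data.frame from [predict_both_arms()].
#' @param received arm actually received per patient.
#' @param wtp willingness-to-pay threshold, euro per QALY.
#' @return data.frame of class `recommendation_records`.
#' @export
recommendation_records <- function(patient_id, predictions, received,
                                   wtp = 25000) {
  received <- check_arm(received, "received")
  if (length(patient_id) != nrow(predictions) ||
      length(received) != nrow(predictions)) {
    stopf("patient_id, predictions and received must be aligned")
  }
  dq <- predictions$q_bt - predictions$q_tau
  dc <- predictions$c_bt - predictions$c_tau
  ic <- icer(dc, dq)
  rec <- recommend(dq, dc, wtp)
  out <- data.frame(patient_id = patient_id, predictions,
                    delta_q = dq, delta_c = dc,
                    icer = ic$icer, icer_status = ic$status,
                    quadrant = classify_quadrant(dq, dc),
                    recommended = rec, received = received,
                    concordant = rec == received,
                    stringsAsFactors = FALSE)
  class(out) <- c("recommendation_records", "data.frame")
  attr(out, "wtp") <- wtp
  out
}

#' Received-by-recommended contingency table
#'
#' @param received,recommended equal-length arm vectors.
#' @return list with `counts` (2x2, received x recommended), `percentages`
#'   (cells as percent of N), `concordance_pct` (percent of patients whose
#'   received arm equals the recommended one) and `n`.
#' @export
contingency <- function(received, recommended) {
  received <- check_arm(received, "received")
  recommended <- check_arm(recommended, "recommended")
  if (length(received) != length(recommended)) {
    stopf("received and recommended must have equal length")
  }
  counts <- table(received = factor(received, arm_levels),
                  recommended = factor(recommended, arm_levels))
  n <- length(received)
  list(counts = counts,
       percentages = 100 * counts / n,
       concordance_pct = 100 * sum(diag(counts)) / n,
       n = n)
}

#' Counterfactual value of the recommended allocation
#'
#' Population-level evaluation of the policy "allocate every patient to the
#' recommended arm": concordant patients keep their *observed* outcome and
#' cost; discordant patients are substituted with the model's *prediction*
#' under the recommended arm. Percent changes compare the recommended-
#' allocation totals with the observed totals (totals and means move
#' identically since N is fixed).
#'
#' @param observed_q,observed_c observed QALY and cost per patient.
#' @param predicted_q,predicted_c predicted QALY and cost *under the
#'   recommended arm* per patient.
#' @param concordant logical; `TRUE` where the received arm equals the
#'   recommended arm.
#' @return list of class `policy_evaluation`: observed and recommended
#'   totals/means, `pct_change_qaly`, `pct_change_cost` (`NA` with a
#'   warning when an observed total is 0), and concordance counts.
#' @export
counterfactual_policy_value <- function(observed_q, observed_c,
                                        predicted_q, predicted_c,
                                        concordant) {
  n <- length(observed_q)
  if (any(lengths(list(observed_c, predicted_q, predicted_c,
                       concordant)) != n)) {
    stopf("all per-patient inputs must be aligned")
  }
  pol_q <- ifelse(concordant, observed_q, predicted_q)
  pol_c <- ifelse(concordant, observed_c, predicted_c)
  pct <- function(new, old) {
    if (old == 0) {
      warnf("observed total is zero; percent change undefined")
      return(NA_real_)
    }
    100 * (new - old) / old
  }
  structure(list(
    observed = list(total_qaly = sum(observed_q), total_cost = sum(observed_c),
                    mean_qaly = mean(observed_q), mean_cost = mean(observed_c)),
    recommended = list(total_qaly = sum(pol_q), total_cost = sum(pol_c),
                       mean_qaly = mean(pol_q), mean_cost = mean(pol_c)),
    pct_change_qaly = pct(sum(pol_q), sum(observed_q)),
    pct_change_cost = pct(sum(pol_c), sum(observed_c)),
    n_concordant = sum(concordant),
    n_discordant = sum(!concordant)),
    class = "policy_evaluation")
}

#' @export
print.policy_evaluation <- function(x, ...) {
  cat(sprintf(
    paste0("<policy_evaluation: %d concordant / %d discordant;",
           " QALY change %+.2f%%, cost change %+.2f%%>\n"),
    x$n_concordant, x$n_discordant, x$pct_change_qaly, x$pct_change_cost))
  invisible(x)
}

#' Plot-ready cost-effectiveness plane table
#'
#' @param records a [recommendation_records()] data.frame.
#' @return data.frame with one row per record: `patient_id`, `delta_q`,
#'   `delta_c`, `concordant` — the (delta QALY, delta cost) scatter with
#'   concordant and discordant patients distinguishable.
#' @export
ce_plane_export <- function(records) {
  cols <- c("patient_id", "delta_q", "delta_c", "concordant")
  if (!nrow(records)) {
    return(data.frame(patient_id = character(), delta_q = numeric(),
                      delta_c = numeric(), concordant = logical()))
  }
  out <- as.data.frame(records)[, cols]
  rownames(out) <- NULL
  out
}
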