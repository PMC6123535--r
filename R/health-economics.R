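# EQ-5D valuation, QALY integration and societal costing.

eq5d_dimensions <- c("mobility", "self_care", "usual_activities",
                     "pain_discomfort", "anxiety_depression")

#' Construct an EQ-5D-5L value set
#'
#' A value set maps every EQ-5D-5L response profile (5 dimensions, levels
#' 1-5) to a utility weight. Two representations are supported: an additive
#' decrement table (`dimension`, `level`, `decrement`; utility =
#' 1 - sum of decrements) or a full 3125-row profile table
#' (`mobility`, ..., `anxiety_depression`, `utility`). The no-problem profile
#' (1,1,1,1,1) must value to exactly 1, and all utilities must lie in
#' `[-0.5, 1]`.
#'
#' Country tariffs (e.g. the Dutch 5L tariff) are not bundled; load them from
#' file with [load_value_set()]. A synthetic additive set with a realistic
#' worst-state value of -0.446 is available via [synthetic_value_set()].
#'
#' @param table data.frame in one of the two layouts described above.
#' @param name short tag recorded with the value set.
#' @return An object of class `value_set`.
#' @export
value_set <- function(table, name = "custom") {
  if (!is.data.frame(table)) stopf("value set table must be a data.frame")
  if (all(c("dimension", "level", "decrement") %in% names(table))) {
    kind <- "additive"
    table$dimension <- as.character(table$dimension)
    if (!setequal(unique(table$dimension), eq5d_dimensions)) {
      stopf("additive value set must cover exactly the dimensions: %s",
            paste(eq5d_dimensions, collapse = ", "))
    }
    dec <- matrix(NA_real_, nrow = 5, ncol = 5,
                  dimnames = list(NULL, eq5d_dimensions))
    for (d in eq5d_dimensions) {
      rows <- table[table$dimension == d, ]
      if (!setequal(rows$level, 1:5)) {
        stopf("dimension '%s' must define decrements for levels 1..5", d)
      }
      dec[rows$level, d] <- rows$decrement
    }
    if (any(dec[1, ] != 0)) stopf("level-1 decrements must all be 0")
    if (any(apply(dec, 2, is.unsorted))) {
      stopf("decrements must be nondecreasing in level")
    }
    worst <- 1 - sum(dec[5, ])
    if (worst < -0.5) stopf("worst-state utility %.3f is below -0.5", worst)
    vs <- list(kind = kind, decrements = dec, name = name)
  } else if (all(c(eq5d_dimensions, "utility") %in% names(table))) {
    kind <- "profile"
    if (nrow(table) != 5^5) stopf("profile value set must have 3125 rows")
    key <- profile_key(as.matrix(table[eq5d_dimensions]))
    if (anyDuplicated(key)) stopf("duplicate profiles in value set table")
    u <- numeric(5^5)
    u[key] <- table$utility
    if (u[profile_key(matrix(1, 1, 5))] != 1) {
      stopf("profile (1,1,1,1,1) must map to utility 1")
    }
    if (any(u < -0.5 | u > 1)) stopf("utilities must lie in [-0.5, 1]")
    vs <- list(kind = kind, lookup = u, name = name)
  } else {
    stopf(paste("value set table must have columns dimension/level/decrement",
                "or the five EQ-5D dimensions plus 'utility'"))
  }
  class(vs) <- "value_set"
  vs
}

profile_key <- function(m) {
  # base-5 index of a profile matrix (levels 1..5), 1-based
  as.integer((m[, 1] - 1) * 625 + (m[, 2] - 1) * 125 + (m[, 3] - 1) * 25 +
               (m[, 4] - 1) * 5 + m[, 5])
}

#' Bundled synthetic additive value set
#'
#' A transparent additive tariff used for simulation and testing: utility is
#' 1 minus per-dimension decrements that rise with level, with a worst-state
#' value of -0.446 (the same order as published five-level tariffs that admit
#' worse-than-death states). It is *synthetic* — it is not any country's
#' tariff and must not be used to value real trial data.
#'
#' @return A `value_set` of kind `"additive"`.
#' @export
synthetic_value_set <- function() {
  path <- system.file("extdata", "synthetic_value_set.csv", package = "indicer")
  if (nzchar(path)) return(load_value_set(path))
  value_set(synthetic_value_set_table(), name = "synthetic-additive")
}

synthetic_value_set_table <- function() {
  data.frame(
    dimension = rep(eq5d_dimensions, each = 5),
    level = rep(1:5, times = 5),
    decrement = c(
      0, 0.035, 0.057, 0.153, 0.262,   # mobility
      0, 0.036, 0.061, 0.145, 0.244,   # self care
      0, 0.039, 0.060, 0.137, 0.260,   # usual activities
      0, 0.046, 0.072, 0.175, 0.330,   # pain / discomfort
      0, 0.052, 0.080, 0.189, 0.350    # anxiety / depression
    )
  )
}

#' Read a value set from CSV
#'
#' @param path CSV file in either of the layouts accepted by [value_set()].
#' @param name tag for the loaded set; defaults to the file name.
#' @return A `value_set`.
#' @export
load_value_set <- function(path, name = basename(path)) {
  if (!file.exists(path)) stopf("value set file not found: %s", path)
  value_set(utils::read.csv(path, stringsAsFactors = FALSE), name = name)
}

#' @export
print.value_set <- function(x, ...) {
  cat(sprintf("<value_set '%s' (%s), utility range [%.3f, 1.000]>\n",
              x$name, x$kind, utility_range(x)[1]))
  invisible(x)
}

utility_range <- function(vs) {
  if (vs$kind == "additive") c(1 - sum(vs$decrements[5, ]), 1)
  else range(vs$lookup)
}

#' Utility weight of EQ-5D-5L response profiles
#'
#' @param profile integer vector of length 5 (levels 1-5 in dimension order
#'   mobility, self-care, usual activities, pain/discomfort,
#'   anxiety/depression), or an n x 5 matrix/data.frame of profiles.
#' @param vs a [value_set()].
#' @return Numeric utility weight(s). Deterministic; incomplete profiles are
#'   rejected (imputation happens upstream of valuation).
#' @export
utility_from_profile <- function(profile, vs) {
  if (!inherits(vs, "value_set")) stopf("'vs' must be a value_set")
  if (is.data.frame(profile)) profile <- as.matrix(profile)
  if (is.vector(profile)) profile <- matrix(profile, nrow = 1)
  if (ncol(profile) != 5) stopf("profiles must have 5 dimensions")
  if (anyNA(profile)) stopf("profile has unanswered dimensions")
  if (any(profile %% 1 != 0) || any(profile < 1) || any(profile > 5)) {
    stopf("profile levels must be integers in 1..5")
  }
  if (vs$kind == "additive") {
    dec <- vs$decrements
    decs <- vapply(1:5, function(d) dec[profile[, d], d],
                   numeric(nrow(profile)))
    if (is.null(dim(decs))) decs <- matrix(decs, nrow = 1)
    u <- 1 - rowSums(decs)
  } else {
    u <- vs$lookup[profile_key(profile)]
  }
  unname(u)
}

#' Utility trajectory over the analysis horizon
#'
#' Ordered (time, utility) measurements from baseline, in years. Times must
#' be strictly increasing, start at 0 and not exceed the horizon.
#'
#' @param times numeric vector of measurement times in years since baseline.
#' @param utilities utility weights at those times.
#' @param horizon analysis horizon in years (default 0.5, the 6-month
#'   analysis window).
#' @return An object of class `utility_trajectory`.
#' @export
utility_trajectory <- function(times, utilities, horizon = 0.5) {
  if (length(times) == 0) stopf("trajectory must have at least one point")
  if (length(times) != length(utilities)) {
    stopf("times and utilities must have equal length")
  }
  if (anyNA(times) || anyNA(utilities)) stopf("trajectory contains NA")
  if (times[1] != 0) stopf("first measurement time must be 0")
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  if (!is_scalar_number(horizon) || horizon <= 0) {
    stopf("horizon must be a positive number")
  }
  if (times[length(times)] > horizon) {
    stopf("last measurement time exceeds the horizon")
  }
  structure(list(times = as.numeric(times), utilities = as.numeric(utilities),
                 horizon = horizon),
            class = "utility_trajectory")
}

#' QALYs from a utility trajectory
#'
#' Integrates the linearly interpolated utility trajectory over
#' `[0, horizon]` by the trapezoidal rule — utility weights multiplied by the
#' time spent in each health state, with linear transitions between states.
#' If the last measurement falls short of the horizon, the final utility is
#' carried forward. Over a 0.5-year horizon with utilities at most 1 the
#' result is at most 0.5.
#'
#' @param trajectory a [utility_trajectory()].
#' @return QALYs, in years.
#' @export
qaly <- function(trajectory) {
  if (!inherits(trajectory, "utility_trajectory")) {
    stopf("'trajectory' must be a utility_trajectory")
  }
  t <- trajectory$times
  u <- trajectory$utilities
  n <- length(t)
  area <- if (n > 1) sum(diff(t) * (u[-1] + u[-n]) / 2) else 0
  area + (trajectory$horizon - t[n]) * u[n]
}

#' Unit cost table for societal costing
#'
#' Societal-perspective unit costs: per-unit prices for healthcare resource
#' categories, an hourly rate valuing productivity losses, and the per-patient
#' platform cost of the online component of blended treatment (hosting,
#' maintenance and therapist feedback).
#'
#' @param unit_costs named nonnegative numeric vector, euro per unit of each
#'   resource category.
#' @param hourly_rate euro per hour of lost productivity.
#' @param bt_platform_cost euro per participant in the BT arm.
#' @return An object of class `unit_cost_table`.
#' @export
unit_cost_table <- function(unit_costs = c(consultation = 100,
                                           hospital_admission = 4000),
                            hourly_rate = 35,
                            bt_platform_cost = 300) {
  if (is.null(names(unit_costs)) || any(!nzchar(names(unit_costs)))) {
    stopf("unit_costs must be a named vector")
  }
  for (nm in names(unit_costs)) check_nonnegative(unit_costs[[nm]], nm)
  check_nonnegative(hourly_rate, "hourly_rate")
  check_nonnegative(bt_platform_cost, "bt_platform_cost")
  structure(list(unit_costs = unit_costs, hourly_rate = hourly_rate,
                 bt_platform_cost = bt_platform_cost),
            class = "unit_cost_table")
}

#' Read a unit cost table from YAML
#'
#' Expected keys: `unit_costs` (mapping category -> euro), `hourly_rate`,
#' `bt_platform_cost`.
#'
#' @param path YAML file.
#' @return A [unit_cost_table()].
#' @export
load_unit_costs <- function(path) {
  if (!file.exists(path)) stopf("unit cost file not found: %s", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$unit_costs)) stopf("unit cost file lacks 'unit_costs'")
  unit_cost_table(unit_costs = unlist(y$unit_costs),
                  hourly_rate = y$hourly_rate %||% 35,
                  bt_platform_cost = y$bt_platform_cost %||% 0)
}

#' Total societal cost over the horizon
#'
#' Sum of resource quantities times unit costs, plus valued productivity
#' losses, plus the BT platform cost for patients in the blended arm.
#' Additive across categories and monotone in each quantity.
#'
#' @param resource_use named numeric vector (one patient) or data.frame
#'   (patients x categories) of resource quantities; names must be categories
#'   of `costs`.
#' @param hours_lost productivity hours lost (scalar or per patient).
#' @param arm `"TAU"` or `"BT"` (scalar or per patient).
#' @param costs a [unit_cost_table()].
#' @return Total cost(s) in euro.
#' @export
societal_cost <- function(resource_use, hours_lost = 0, arm = "TAU",
                          costs = unit_cost_table()) {
  if (!inherits(costs, "unit_cost_table")) {
    stopf("'costs' must be a unit_cost_table")
  }
  if (is.data.frame(resource_use)) {
    q <- as.matrix(resource_use)
  } else {
    q <- matrix(resource_use, nrow = 1,
                dimnames = list(NULL, names(resource_use)))
  }
  if (is.null(colnames(q))) stopf("resource_use must be named by category")
  unknown <- setdiff(colnames(q), names(costs$unit_costs))
  if (length(unknown)) {
    stopf("unknown resource categor%s: %s",
          if (length(unknown) > 1) "ies" else "y",
          paste(unknown, collapse = ", "))
  }
  if (anyNA(q) || any(q < 0)) stopf("resource quantities must be >= 0")
  if (any(hours_lost < 0)) stopf("hours_lost must be >= 0")
  arm <- check_arm(arm)
  total <- drop(q %*% costs$unit_costs[colnames(q)]) +
    hours_lost * costs$hourly_rate +
    ifelse(arm == "BT", costs$bt_platform_cost, 0)
  unname(total)
}
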