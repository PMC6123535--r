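# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && is.finite(x)
}

check_probability <- function(x, field) {
  if (!is_scalar_number(x) || x < 0 || x > 1) {
    stopf("field '%s' must be a single probability in [0, 1]", field)
  }
  invisible(x)
}

check_nonnegative <- function(x, field) {
  if (!is_scalar_number(x) || x < 0) {
    stopf("field '%s' must be a single nonnegative number", field)
  }
  invisible(x)
}

check_count <- function(x, field, min = 0L) {
  if (!is_scalar_number(x) || x %% 1 != 0 || x < min) {
    stopf("field '%s' must be an integer >= %d", field, min)
  }
  invisible(as.integer(x))
}

# Deterministic 31-bit polynomial hash of a string; used for stage sub-seeds
# and config fingerprints. Arithmetic stays below 2^53 so doubles are exact.
poly_hash <- function(s, mod = 2147483629) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% mod
  h
}

# Sub-seed for a named pipeline stage. Each stage gets an offset that depends
# only on its own name, so inserting a stage never perturbs the seeds of the
# others. Result is always a valid 32-bit seed.
derive_seed <- function(master, stage) {
  master <- as.numeric(master) %% 2147483629
  as.integer((master + poly_hash(stage) * 7919) %% 2147483629)
}

arm_levels <- c("TAU", "BT")

check_arm <- function(arm, field = "arm") {
  arm <- as.character(arm)
  if (any(!arm %in% arm_levels)) {
    stopf("field '%s' must contain only 'TAU' or 'BT'", field)
  }
  arm
}
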