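# Shared fixtures, built in code at test time.

toy_feature_matrix <- function() {
  feature_matrix(data.frame(
    patient_id = paste0("P", 1:6),
    age = c(30, 40, NA, 50, 60, 35),
    score = c(1, 2, NA, 10, 4, 6),
    sex = c("f", "m", "f", NA, "f", "m"),
    stringsAsFactors = FALSE))
}

toy_vs <- function() synthetic_value_set()

# small complete design matrix + linear response
toy_linear_data <- function(n = 40, p = 4, sd = 0.5, seed = 42) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
    beta <- c(2, -1, 0.5, 0)[1:p]
    y <- drop(X %*% beta) + 1 + rnorm(n, 0, sd)
    list(X = X, y = y, beta = beta)
  })
}

quick_trial <- function(n = 120, seed = 3, ...) {
  generate_trial(generator_config(n_patients = n, seed = seed, ...))
}
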