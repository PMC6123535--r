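# Feature-table preprocessing: merge, degenerate-feature pruning, single
# imputation (median/mode or distribution sampling) and one-hot encoding.
# The pipeline order is fixed: merge -> drop -> impute -> encode.

#' Mixed-type feature matrix
#'
#' A light container for a patients x features table admitting missing
#' cells. Columns are either `numeric` or `categorical`; categorical cells
#' are stored as character and may only take observed levels or `NA`.
#'
#' @param data data.frame of feature columns plus an id column.
#' @param id name of the patient-id column (default `"patient_id"`).
#' @param kinds optional named character vector (`"numeric"` /
#'   `"categorical"`) overriding the per-column kind inferred from the
#'   column type.
#' @return An object of class `feature_matrix` with elements `ids`, `data`
#'   and `kinds`.
#' @export
feature_matrix <- function(data, id = "patient_id", kinds = NULL) {
  if (!is.data.frame(data)) stopf("'data' must be a data.frame")
  if (!id %in% names(data)) stopf("id column '%s' not found", id)
  ids <- as.character(data[[id]])
  if (anyDuplicated(ids)) stopf("duplicate patient id in feature table")
  vals <- data[setdiff(names(data), id)]
  if (anyDuplicated(names(vals))) stopf("column names must be unique")
  inferred <- vapply(vals, function(col) {
    if (is.numeric(col)) "numeric" else "categorical"
  }, character(1))
  if (!is.null(kinds)) inferred[names(kinds)] <- kinds
  for (j in names(vals)) {
    vals[[j]] <- if (inferred[[j]] == "categorical") {
      as.character(vals[[j]])
    } else {
      as.numeric(vals[[j]])
    }
  }
  structure(list(ids = ids, data = vals, kinds = inferred),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix: %d patients x %d features (%d numeric, %d categorical), %d missing cells>\n",
              length(x$ids), length(x$kinds), sum(x$kinds == "numeric"),
              sum(x$kinds == "categorical"), sum(is.na(x$data))))
  invisible(x)
}

missing_mask <- function(m) as.matrix(is.na(m$data))

#' Merge keyed tabular sources into one feature matrix
#'
#' Joins several per-patient tables on `patient_id`. The merged matrix has
#' one row per patient present in the outcome table with *both* dependent
#' variables (QALY and cost) non-missing; all other patients are dropped.
#' A column name appearing in more than one source is disambiguated with a
#' `source.` prefix.
#'
#' @param sources named list of data.frames, each keyed by `patient_id`.
#'   A duplicated patient id within one source is an error.
#' @param outcomes data.frame with columns `patient_id`, `qaly`, `cost`.
#' @return A [feature_matrix()] whose row order follows `outcomes`.
#' @export
merge_sources <- function(sources, outcomes) {
  if (!is.data.frame(outcomes) ||
      !all(c("patient_id", "qaly", "cost") %in% names(outcomes))) {
    stopf("'outcomes' must have columns patient_id, qaly, cost")
  }
  if (!length(sources)) stopf("'sources' must be a nonempty list")
  if (is.null(names(sources)) || any(!nzchar(names(sources)))) {
    names(sources) <- paste0("src", seq_along(sources))
  }
  keep <- !is.na(outcomes$qaly) & !is.na(outcomes$cost)
  ids <- as.character(outcomes$patient_id[keep])

  feature_names <- unlist(lapply(sources, function(s) {
    setdiff(names(s), "patient_id")
  }), use.names = FALSE)
  dup <- unique(feature_names[duplicated(feature_names)])

  merged <- list()
  for (src in names(sources)) {
    tab <- sources[[src]]
    if (!"patient_id" %in% names(tab)) {
      stopf("source '%s' lacks a patient_id column", src)
    }
    if (anyDuplicated(tab$patient_id)) {
      stopf("duplicate patient id within source '%s'", src)
    }
    rows <- match(ids, as.character(tab$patient_id))
    for (cl in setdiff(names(tab), "patient_id")) {
      out_name <- if (cl %in% dup) paste(src, cl, sep = ".") else cl
      col <- tab[[cl]][rows]
      if (is.factor(col)) col <- as.character(col)
      merged[[out_name]] <- col
    }
  }
  df <- data.frame(patient_id = ids, merged, stringsAsFactors = FALSE,
                   check.names = FALSE)
  feature_matrix(df)
}

#' Remove degenerate features
#'
#' Drops features that are entirely missing or have fewer than two distinct
#' observed values — overall and, when `arm_split` is supplied, within each
#' arm subgroup (splitting a trial by arm can silently lose factor levels,
#' so a feature constant within either arm is unusable for per-arm models).
#' Idempotent.
#'
#' @param m a [feature_matrix()].
#' @param arm_split optional arm label per patient.
#' @return list with elements `matrix` (the pruned [feature_matrix()]) and
#'   `report` (data.frame of removed features and reasons, plus an `empty`
#'   flag set when nothing survives).
#' @export
drop_degenerate_features <- function(m, arm_split = NULL) {
  stopifnot(inherits(m, "feature_matrix"))
  if (!is.null(arm_split) && length(arm_split) != length(m$ids)) {
    stopf("'arm_split' must have one label per patient")
  }
  removed <- character(); reason <- character()
  groups <- if (is.null(arm_split)) list(all = rep(TRUE, length(m$ids)))
            else split(seq_along(m$ids), arm_split)
  for (j in names(m$data)) {
    col <- m$data[[j]]
    obs <- col[!is.na(col)]
    if (!length(obs)) {
      removed <- c(removed, j); reason <- c(reason, "all_missing")
      next
    }
    if (length(unique(obs)) < 2) {
      removed <- c(removed, j); reason <- c(reason, "single_level")
      next
    }
    if (!is.null(arm_split)) {
      for (g in names(groups)) {
        sub <- col[groups[[g]]]
        sub <- sub[!is.na(sub)]
        if (length(unique(sub)) < 2) {
          removed <- c(removed, j)
          reason <- c(reason, paste0("degenerate_within_arm:", g))
          break
        }
      }
    }
  }
  keep <- setdiff(names(m$data), removed)
  m$data <- m$data[keep]
  m$kinds <- m$kinds[keep]
  report <- data.frame(feature = removed, reason = reason,
                       stringsAsFactors = FALSE)
  list(matrix = m,
       report = list(removed = report, n_removed = nrow(report),
                     empty = length(keep) == 0))
}

column_mode <- function(x) {
  # modal observed level; ties broken by the lexicographically smallest level
  tab <- table(x)
  names(tab)[which.max(tab)][1]  # table() is sorted by level name
}

#' Median / mode imputation
#'
#' Fills missing numeric cells with the column median of the observed values
#' (even counts: mean of the two central values) and missing categorical
#' cells with the modal observed level (ties: lexicographically smallest).
#' Observed cells are unchanged; applying it to a complete matrix is the
#' identity, and fills never leave the observed support of a column.
#'
#' @param m a [feature_matrix()]; every column must have at least one
#'   observed value (drop degenerate features first).
#' @return The completed [feature_matrix()].
#' @export
impute_median_mode <- function(m) {
  stopifnot(inherits(m, "feature_matrix"))
  for (j in names(m$data)) {
    col <- m$data[[j]]
    nas <- is.na(col)
    if (!any(nas)) next
    if (all(nas)) stopf("column '%s' is fully missing; drop it upstream", j)
    fill <- if (m$kinds[[j]] == "numeric") {
      stats::median(col[!nas])
    } else {
      column_mode(col[!nas])
    }
    col[nas] <- fill
    m$data[[j]] <- col
  }
  m
}

#' Distribution-sampling imputation
#'
#' Fills missing numeric cells by sampling from a normal distribution with
#' the mean and SD of the column's observed values, and missing categorical
#' cells by sampling from the observed level frequencies. Reproducible under
#' `seed`. A numeric column with a single observed value (undefined SD) is
#' filled with that value, with a warning.
#'
#' @param m a [feature_matrix()].
#' @param seed integer seed.
#' @return The completed [feature_matrix()].
#' @export
impute_distribution_sample <- function(m, seed = 1) {
  stopifnot(inherits(m, "feature_matrix"))
  withr::with_seed(derive_seed(seed, "impute"), {
    for (j in names(m$data)) {
      col <- m$data[[j]]
      nas <- is.na(col)
      if (!any(nas)) next
      if (all(nas)) stopf("column '%s' is fully missing; drop it upstream", j)
      obs <- col[!nas]
      if (m$kinds[[j]] == "numeric") {
        if (length(unique(obs)) == 1) {
          warnf("column '%s' has a single observed value; filling with it", j)
          col[nas] <- obs[1]
        } else {
          col[nas] <- stats::rnorm(sum(nas), mean(obs), stats::sd(obs))
        }
      } else {
        freq <- table(obs)
        col[nas] <- sample(names(freq), sum(nas), replace = TRUE,
                           prob = as.numeric(freq))
      }
      m$data[[j]] <- col
    }
  })
  m
}

#' One-hot encode a complete feature matrix
#'
#' Numeric features pass through; each categorical feature with L observed
#' levels contributes L - 1 indicator columns, with the modal level (ties:
#' lexicographically smallest) as the reference. A provenance map links
#' every design column back to its source feature and level.
#'
#' @param m a fully imputed [feature_matrix()].
#' @return An object of class `design_matrix`: list with `ids`, the numeric
#'   matrix `X`, the `provenance` data.frame and the `encoding` spec used by
#'   [encode_apply()].
#' @export
encode_features <- function(m) {
  stopifnot(inherits(m, "feature_matrix"))
  if (anyNA(m$data)) stopf("matrix must be fully imputed before encoding")
  cols <- list(); prov <- list(); encoding <- list()
  for (j in names(m$data)) {
    if (m$kinds[[j]] == "numeric") {
      cols[[j]] <- m$data[[j]]
      prov[[length(prov) + 1L]] <- data.frame(column = j, source = j,
                                              level = NA_character_)
      encoding[[j]] <- list(kind = "numeric")
    } else {
      lev <- sort(unique(m$data[[j]]))
      ref <- column_mode(m$data[[j]])
      for (l in setdiff(lev, ref)) {
        nm <- paste0(j, "=", l)
        cols[[nm]] <- as.numeric(m$data[[j]] == l)
        prov[[length(prov) + 1L]] <- data.frame(column = nm, source = j,
                                                level = l)
      }
      encoding[[j]] <- list(kind = "categorical", levels = lev,
                            reference = ref)
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- m$ids
  structure(list(ids = m$ids, X = X,
                 provenance = do.call(rbind, prov), encoding = encoding),
            class = "design_matrix")
}

#' Encode new data with a fitted encoding
#'
#' Applies the encoding spec of an existing [encode_features()] result to a
#' new feature matrix (e.g. the held-out patient of a cross-validation
#' split). A categorical level unseen at encoding time maps to an all-zero
#' indicator block, with a warning.
#'
#' @param dm a `design_matrix` (carries the encoding spec).
#' @param m a complete [feature_matrix()] with the same feature columns.
#' @return A numeric matrix with the same columns as `dm$X`.
#' @export
encode_apply <- function(dm, m) {
  stopifnot(inherits(dm, "design_matrix"), inherits(m, "feature_matrix"))
  missing_feat <- setdiff(names(dm$encoding), names(m$data))
  if (length(missing_feat)) {
    stopf("new data lacks feature(s): %s", paste(missing_feat, collapse = ", "))
  }
  n <- length(m$ids)
  X <- matrix(0, n, ncol(dm$X), dimnames = list(m$ids, colnames(dm$X)))
  for (j in names(dm$encoding)) {
    spec <- dm$encoding[[j]]
    if (spec$kind == "numeric") {
      X[, j] <- as.numeric(m$data[[j]])
    } else {
      vals <- as.character(m$data[[j]])
      unseen <- setdiff(unique(vals), spec$levels)
      if (length(unseen)) {
        warnf("feature '%s': unseen level(s) %s mapped to zero block",
              j, paste(unseen, collapse = ", "))
      }
      for (l in setdiff(spec$levels, spec$reference)) {
        X[, paste0(j, "=", l)] <- as.numeric(vals == l)
      }
    }
  }
  X
}

#' Per-arm PHQ-9 improvement summary
#'
#' Summarizes depression-severity change per arm — mean PHQ-9 at baseline
#' and at 6 months, and counts of patients improved (end below start) and
#' not improved — and tests whether the mean end scores differ between arms
#' with a two-sample Welch t-test.
#'
#' @param arm arm label per patient (`"TAU"`/`"BT"`), both arms nonempty.
#' @param start,end paired PHQ-9 scores at baseline and month 6.
#' @return list with `summary` (one row per arm) and `p_value`.
#' @export
improvement_summary <- function(arm, start, end) {
  arm <- check_arm(arm)
  if (length(start) != length(arm) || length(end) != length(arm)) {
    stopf("'arm', 'start' and 'end' must be aligned per patient")
  }
  if (!all(arm_levels %in% arm)) stopf("both arms must be nonempty")
  rows <- lapply(arm_levels, function(a) {
    s <- start[arm == a]; e <- end[arm == a]
    data.frame(arm = a, n = length(s), mean_start = mean(s),
               mean_end = mean(e), n_improved = sum(e < s),
               n_not_improved = sum(e >= s))
  })
  p <- stats::t.test(end[arm == "TAU"], end[arm == "BT"])$p.value
  list(summary = do.call(rbind, rows), p_value = p)
}
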