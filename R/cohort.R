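#' Read a per-slice feature table
#'
#' Feature tables are CSV files with header
#' `patient_id,plane,slice_index,<feature>,...`, one row per slice. Rows are
#' grouped by patient and plane and ordered by `slice_index`, which must be
#' 1-based, strictly increasing and contiguous within each patient/plane.
#' Feature columns not in the canonical registry are kept but flagged with a
#' warning.
#'
#' @param path Path to the CSV file.
#' @param plane Optional filter: keep only `"coronal"` or `"sagittal"` rows.
#' @return A tibble with columns `patient_id`, `plane`, `slice_index` and one
#'   numeric column per feature.
#' @seealso [write_feature_table()], [discretize_features()]
#' @export
read_feature_table <- function(path, plane = NULL) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_feature_table(tbl, path)
  if (!is.null(plane)) {
    plane <- match.arg(plane, c("coronal", "sagittal"))
    tbl <- dplyr::filter(tbl, .data$plane == !!plane)
  }
  extra <- setdiff(names(tbl), c(.acdx_meta_cols, feature_registry()$feature))
  if (length(extra) > 0)
    warning("feature columns not in the canonical registry: ",
            paste(extra, collapse = ", "), call. = FALSE)
  dplyr::arrange(tbl, .data$patient_id, .data$plane, .data$slice_index)
}

.acdx_meta_cols <- c("patient_id", "plane", "slice_index")

validate_feature_table <- function(tbl, what = "feature table") {
  miss <- setdiff(.acdx_meta_cols, names(tbl))
  if (length(miss) > 0)
    stop(what, ": missing mandatory columns ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(tbl$plane %in% c("coronal", "sagittal")))
    stop(what, ": `plane` must be coronal or sagittal", call. = FALSE)
  feat <- setdiff(names(tbl), .acdx_meta_cols)
  bad <- feat[!vapply(tbl[feat], function(x) is.numeric(x) || is.character(x),
                      TRUE)]
  if (length(bad) > 0)
    stop(what, ": non-numeric feature columns: ", paste(bad, collapse = ", "),
         call. = FALSE)
  num <- feat[vapply(tbl[feat], is.numeric, TRUE)]
  for (f in num) {
    if (anyNA(tbl[[f]])) {
      row <- which(is.na(tbl[[f]]))[1]
      stop(what, ": non-numeric or missing value in column ", f, ", row ", row,
           call. = FALSE)
    }
  }
  chk <- dplyr::summarise(
    dplyr::group_by(tbl, .data$patient_id, .data$plane),
    ok = all(sort(.data$slice_index) == seq_along(.data$slice_index)),
    .groups = "drop"
  )
  if (any(!chk$ok)) {
    bad <- chk[!chk$ok, ]
    stop(what, ": slice indices not contiguous from 1 for patient ",
         bad$patient_id[1], " (", bad$plane[1], ")", call. = FALSE)
  }
  invisible(tbl)
}

#' Write a per-slice feature table
#'
#' @param tbl A feature table as returned by [read_feature_table()] or
#'   [synthesize_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(tbl, path) {
  validate_feature_table(tbl)
  readr::write_csv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Read / write cohort labels
#'
#' Label files are CSV with columns `patient_id,label`, where `label` is
#' `"capsulitis"` (the positive class) or `"non_capsulitis"`.
#'
#' @param path CSV path.
#' @return A tibble with columns `patient_id`, `label`.
#' @export
read_labels <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (!all(c("patient_id", "label") %in% names(tbl)))
    stop("label file must have columns patient_id,label", call. = FALSE)
  if (!all(tbl$label %in% c("capsulitis", "non_capsulitis")))
    stop("labels must be capsulitis / non_capsulitis", call. = FALSE)
  tbl[c("patient_id", "label")]
}

#' @rdname read_labels
#' @param labels A tibble with columns `patient_id`, `label`.
#' @export
write_labels <- function(labels, path) {
  readr::write_csv(labels[c("patient_id", "label")], path, progress = FALSE)
  invisible(path)
}

#' Restrict a feature table to one class's selected features
#'
#' Model building runs in single-class mode: each formal model uses the five
#' canonical features of exactly one class, never a mix. This drops all other
#' feature columns.
#'
#' @param tbl A feature table.
#' @param class Feature class, e.g. `"GLCM"` or `"FIRST"`.
#' @return The table restricted to `patient_id`, `plane`, `slice_index` and
#'   the class's five features.
#' @export
select_features <- function(tbl, class) {
  want <- selected_features(class)
  miss <- setdiff(want, names(tbl))
  if (length(miss) > 0)
    stop("features missing from table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  tbl[c(.acdx_meta_cols, want)]
}

#' Fit an L/M/H discretization scheme
#'
#' Per feature, thresholds are the empirical 1/3 and 2/3 quantiles pooled
#' over every slice of every cohort patient (both planes), with the quantile
#' at probability p defined as the smallest observed value v such that the
#' fraction of observations `<= v` is at least p. A feature constant across
#' the cohort gets `t1 = t2 =` that constant (all values discretize to L)
#' with a warning.
#'
#' The scheme is meant to be fitted once on a reference cohort and then
#' frozen (see [write_scheme()]), so held-out patients are discretized
#' without leakage.
#'
#' @param tbl A feature table (continuous values).
#' @return A tibble of class `acdx_scheme` with columns `feature`, `t1`, `t2`.
#' @examples
#' tbl <- tibble::tibble(patient_id = "p1", plane = "coronal",
#'                       slice_index = 1:6, F_a = c(1, 2, 3, 4, 5, 6))
#' fit_discretization(tbl) # thresholds 2 and 4
#' @export
fit_discretization <- function(tbl) {
  feat <- setdiff(names(tbl), .acdx_meta_cols)
  if (length(feat) == 0) stop("no feature columns", call. = FALSE)
  if (nrow(tbl) == 0) stop("empty cohort", call. = FALSE)
  th <- purrr::map(tbl[feat], function(x) {
    v <- sort(x)
    n <- length(v)
    t1 <- v[ceiling(n / 3)]
    t2 <- v[ceiling(2 * n / 3)]
    if (t1 == t2 && v[1] == v[n])
      warning("feature constant across cohort; all values will map to L",
              call. = FALSE)
    c(t1, t2)
  })
  structure(
    tibble::tibble(
      feature = feat,
      t1 = unname(vapply(th, `[`, 0, 1)),
      t2 = unname(vapply(th, `[`, 0, 2))
    ),
    class = c("acdx_scheme", class(tibble::tibble()))
  )
}

#' Discretize a feature table to L/M/H levels
#'
#' Each continuous value x becomes `"L"` if `x <= t1`, `"M"` if
#' `t1 < x <= t2`, `"H"` if `x > t2` — boundary values belong to the lower
#' level, and with a degenerate scheme (`t1 == t2`) no value can map to M.
#'
#' @param tbl A feature table with continuous values.
#' @param scheme An `acdx_scheme` from [fit_discretization()] or
#'   [read_scheme()]; must cover every feature column of `tbl`.
#' @return The table with feature columns replaced by level labels.
#' @export
discretize_features <- function(tbl, scheme) {
  feat <- setdiff(names(tbl), .acdx_meta_cols)
  miss <- setdiff(feat, scheme$feature)
  if (length(miss) > 0)
    stop("scheme does not cover features: ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (f in feat) {
    i <- match(f, scheme$feature)
    x <- tbl[[f]]
    tbl[[f]] <- ifelse(x <= scheme$t1[i], "L",
                       ifelse(x <= scheme$t2[i], "M", "H"))
  }
  tbl
}

#' Persist / load a discretization scheme
#'
#' Schemes are stored as YAML mapping each feature identifier to its
#' `[t1, t2]` threshold pair, so a scheme fitted on a reference cohort can be
#' frozen and applied to new patients.
#'
#' @param scheme An `acdx_scheme`.
#' @param path YAML file path.
#' @return `write_scheme()`: `path` invisibly; `read_scheme()`: the scheme.
#' @export
write_scheme <- function(scheme, path) {
  out <- stats::setNames(
    purrr::map2(scheme$t1, scheme$t2, ~ c(.x, .y)), scheme$feature
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  raw <- yaml::read_yaml(path)
  t1 <- vapply(raw, `[`, 0, 1)
  t2 <- vapply(raw, `[`, 0, 2)
  if (any(t1 > t2)) stop("scheme has t1 > t2", call. = FALSE)
  structure(
    tibble::tibble(feature = names(raw), t1 = unname(t1), t2 = unname(t2)),
    class = c("acdx_scheme", class(tibble::tibble()))
  )
}

#' Generic redundancy filter for new cohorts
#'
#' The canonical 30-feature selection is shipped as a static registry. For a
#' new cohort where that list may not apply, this filter drops features with
#' near-zero variance and then one member of each pair with absolute Pearson
#' correlation above `cor_cutoff`.
#'
#' @param tbl A feature table (continuous values).
#' @param var_cutoff Drop features whose variance is below this (default
#'   1e-8).
#' @param cor_cutoff Pairwise absolute correlation threshold (default 0.95).
#' @return The filtered feature table.
#' @export
filter_features <- function(tbl, var_cutoff = 1e-8, cor_cutoff = 0.95) {
  feat <- setdiff(names(tbl), .acdx_meta_cols)
  v <- vapply(tbl[feat], stats::var, 0)
  keep <- feat[v >= var_cutoff]
  if (length(keep) > 1) {
    cm <- abs(stats::cor(as.matrix(tbl[keep])))
    drop <- character()
    for (i in seq_len(length(keep) - 1)) {
      if (keep[i] %in% drop) next
      for (j in seq(i + 1, length(keep))) {
        if (keep[j] %in% drop) next
        if (cm[i, j] > cor_cutoff) drop <- c(drop, keep[j])
      }
    }
    keep <- setdiff(keep, drop)
  }
  tbl[c(.acdx_meta_cols, keep)]
}
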