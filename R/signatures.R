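#' Slice-level disease pattern
#'
#' A pattern states, for some features of one class, which discretized
#' levels count as a disease sign; features not mentioned are don't-cares.
#' A patient plane matches when at least `min_slices` of its slices satisfy
#' every constraint simultaneously (within one slice). With
#' `consecutive = TRUE` the matching slices must be adjacent.
#'
#' @param ... Named constraints: `GLCM_Contrast = "H"`,
#'   `GLCM_Id = c("L", "M")`, ... Names are feature identifiers; values are
#'   subsets of `c("L", "M", "H")`.
#' @param min_slices Number of slices that must match (default 1).
#' @param consecutive Require the matching slices to be adjacent (only
#'   relevant when `min_slices > 1`).
#' @return An object of class `acdx_pattern`.
#' @examples
#' slice_pattern(GLCM_Contrast = "H", GLCM_Id = "L")
#' @export
slice_pattern <- function(..., min_slices = 1L, consecutive = FALSE) {
  constraints <- list(...)
  if (length(constraints) == 1 && is.list(constraints[[1]]) &&
      is.null(names(constraints)[1]))
    constraints <- constraints[[1]]
  if (length(constraints) == 0 || is.null(names(constraints)) ||
      any(!nzchar(names(constraints))))
    stop("pattern needs at least one named feature constraint", call. = FALSE)
  cls <- unique(sub("_.*$", "", names(constraints)))
  if (length(cls) > 1)
    stop("single-class mode: pattern mixes classes ",
         paste(cls, collapse = ", "), call. = FALSE)
  constraints <- lapply(constraints, function(v) {
    v <- as.character(v)
    if (!all(v %in% c("L", "M", "H")) || length(v) == 0)
      stop("constraint levels must be a nonempty subset of L/M/H",
           call. = FALSE)
    unique(v)
  })
  stopifnot(min_slices >= 1)
  structure(
    list(constraints = constraints, min_slices = as.integer(min_slices),
         consecutive = isTRUE(consecutive)),
    class = "acdx_pattern"
  )
}

#' @export
print.acdx_pattern <- function(x, ...) {
  con <- vapply(names(x$constraints), function(f) {
    paste0(f, " in {", paste(x$constraints[[f]], collapse = ","), "}")
  }, "")
  cat("<acdx_pattern>", paste(con, collapse = " & "))
  if (x$min_slices > 1)
    cat(" [>=", x$min_slices, if (x$consecutive) "consecutive", "slices]")
  cat("\n")
  invisible(x)
}

#' Per-plane diagnostic signature
#'
#' A signature holds one slice pattern per imaging plane; a patient is
#' diagnosed positive when at least one available plane satisfies its
#' pattern (logical OR across planes).
#'
#' @param coronal,sagittal `acdx_pattern`s (either may be omitted, not both).
#' @return An object of class `acdx_signature`.
#' @export
signature <- function(coronal = NULL, sagittal = NULL) {
  pats <- purrr::compact(list(coronal = coronal, sagittal = sagittal))
  if (length(pats) == 0)
    stop("signature needs a pattern for at least one plane", call. = FALSE)
  stopifnot(all(vapply(pats, inherits, TRUE, "acdx_pattern")))
  structure(list(patterns = pats), class = "acdx_signature")
}

#' @export
print.acdx_signature <- function(x, ...) {
  cat("<acdx_signature> (planes combined with OR)\n")
  for (pl in names(x$patterns)) {
    cat(" ", pl, ": ")
    print(x$patterns[[pl]])
  }
  invisible(x)
}

#' Default GLCM signature (placeholder)
#'
#' A configurable starting point, not a validated clinical rule: high
#' Contrast and Cluster prominence with low inverse difference (Id) on
#' either plane. Any real deployment should recalibrate it with
#' [mine_candidate_patterns()] on exemplar patients from the target cohort.
#'
#' @return An `acdx_signature` over the GLCM class.
#' @export
default_glcm_signature <- function() {
  p <- slice_pattern(GLCM_Contrast = "H", GLCM_ClusterProminence = "H",
                     GLCM_Id = "L")
  signature(coronal = p, sagittal = p)
}

#' Compile a slice pattern to a temporal-logic formula
#'
#' For `min_slices = 1` the pattern becomes
#' `EF( AND_f <allowed level labels of f> tt )`: eventually a state is
#' reached where, for every constrained feature, some transition with an
#' allowed level of that feature is enabled. Because every enabled action at
#' any LTS state belongs to the current slice, the conjunction of diamonds
#' can only be witnessed by a single slice's level assignment — it cannot
#' straddle two slices, which a sequential diamond chain could.
#'
#' @param pattern An `acdx_pattern`.
#' @return An `acdx_formula` (EF-rooted).
#' @examples
#' deparse_formula(compile_pattern(slice_pattern(GLCM_Contrast = "H")))
#' @export
compile_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "acdx_pattern"))
  conj <- NULL
  for (f in names(pattern$constraints)) {
    labs <- action_label(pattern$constraints[[f]], f)
    leaf <- list(op = "dia", labels = labs, arg = list(op = "tt"))
    conj <- if (is.null(conj)) leaf else list(op = "and", lhs = conj, rhs = leaf)
  }
  structure(list(op = "EF", arg = conj), class = "acdx_formula")
}

# slice-entry states of an LTS whose slice satisfies the pattern's
# conjunction; used for min_slices > 1 counting
matching_entry_states <- function(lts, pattern) {
  f <- compile_pattern(pattern)$arg
  sat <- eval_formula(f, lts, nrow(lts$states), lts$transitions, quiet = TRUE)
  sat[lts$entry]
}

check_plane <- function(lts, pattern, return_verdict = FALSE) {
  if (pattern$min_slices == 1L) {
    v <- check_formula(lts, compile_pattern(pattern), quiet = TRUE)
    if (return_verdict) return(v)
    return(v$value)
  }
  hits <- matching_entry_states(lts, pattern)
  ok <- if (pattern$consecutive) {
    r <- rle(hits)
    any(r$values & r$lengths >= pattern$min_slices)
  } else {
    sum(hits) >= pattern$min_slices
  }
  if (return_verdict) structure(list(value = ok, witness = NULL),
                                class = "acdx_verdict") else ok
}

#' Classify one patient from per-plane LTSs
#'
#' Checks each available plane's compiled pattern against that plane's LTS
#' and ORs the verdicts: `TRUE` (capsulitis) if at least one plane matches.
#'
#' @param coronal,sagittal `acdx_lts` objects (either may be `NULL`).
#' @param signature An `acdx_signature` covering at least one supplied plane.
#' @return Logical diagnosis (`TRUE` = capsulitis).
#' @export
classify_patient <- function(coronal = NULL, sagittal = NULL, signature) {
  ltss <- purrr::compact(list(coronal = coronal, sagittal = sagittal))
  if (length(ltss) == 0)
    stop("supply at least one plane's LTS", call. = FALSE)
  planes <- intersect(names(ltss), names(signature$patterns))
  if (length(planes) == 0)
    stop("signature has no pattern for any supplied plane (",
         paste(names(ltss), collapse = ", "), ")", call. = FALSE)
  any(vapply(planes, function(pl) {
    check_plane(ltss[[pl]], signature$patterns[[pl]])
  }, TRUE))
}

#' Classify a whole discretized cohort
#'
#' Runs the full formal pipeline per patient: builds a CCS model and its LTS
#' for each plane present in the table, checks the signature's compiled
#' pattern on each, and combines planes with OR.
#'
#' @param tbl A discretized feature table (one class's features; see
#'   [select_features()] and [discretize_features()]).
#' @param signature An `acdx_signature`.
#' @return A tibble with columns `patient_id`, `diagnosis` (logical).
#' @export
classify_cohort <- function(tbl, signature) {
  split_tbl <- split(tbl, tbl$patient_id)
  res <- purrr::map_lgl(split_tbl, function(pt) {
    ltss <- lapply(split(pt, pt$plane), function(ex) {
      lts_from_model(build_ccs_model(ex))
    })
    classify_patient(coronal = ltss$coronal, sagittal = ltss$sagittal,
                     signature = signature)
  })
  tibble::tibble(patient_id = names(res), diagnosis = unname(res))
}

#' Mine candidate patterns from exemplar patients
#'
#' Enumerates every conjunction of single-level constraints over the class's
#' features (sizes 1 up to the number of features) and keeps those matched —
#' by at least one slice, in any plane — by at least a `support` fraction of
#' the exemplar patients. This merges commonalities among patients in the
#' same health state into candidate disease signatures; results are ordered
#' by decreasing constraint size, then decreasing support.
#'
#' @param tbl A discretized feature table of the exemplar patients (one
#'   feature class).
#' @param support Minimum fraction of exemplars that must match (default 1).
#' @return A tibble with columns `pattern` (list of `acdx_pattern`), `size`,
#'   `support`.
#' @export
mine_candidate_patterns <- function(tbl, support = 1) {
  if (nrow(tbl) == 0) stop("no exemplar slices", call. = FALSE)
  feat <- setdiff(names(tbl), .acdx_meta_cols)
  cls <- unique(sub("_.*$", "", feat))
  if (length(cls) > 1)
    stop("single-class mode: restrict the table with select_features() first",
         call. = FALSE)
  patients <- unique(tbl$patient_id)
  lv <- as.matrix(tbl[feat])
  pat_of_row <- tbl$patient_id
  out_pat <- list(); out_size <- integer(); out_sup <- numeric()
  for (size in seq_along(feat)) {
    subsets <- utils::combn(feat, size, simplify = FALSE)
    assigns <- expand.grid(rep(list(c("L", "M", "H")), size),
                           stringsAsFactors = FALSE)
    for (fs in subsets) {
      sub_lv <- lv[, fs, drop = FALSE]
      for (r in seq_len(nrow(assigns))) {
        want <- as.character(assigns[r, ])
        hit <- rowSums(sub_lv == rep(want, each = nrow(sub_lv))) == size
        sup <- length(unique(pat_of_row[hit])) / length(patients)
        if (sup >= support) {
          cons <- stats::setNames(as.list(want), fs)
          out_pat[[length(out_pat) + 1]] <- slice_pattern(cons)
          out_size <- c(out_size, size)
          out_sup <- c(out_sup, sup)
        }
      }
    }
  }
  ord <- order(-out_size, -out_sup)
  tibble::tibble(pattern = out_pat[ord], size = out_size[ord],
                 support = out_sup[ord])
}

#' Read / write signature files
#'
#' Signatures are YAML: one block per plane mapping feature identifiers to
#' allowed level lists, plus optional `min_slices` and `consecutive` fields.
#'
#' @param path YAML path.
#' @return `read_signature()`: an `acdx_signature`.
#' @export
read_signature <- function(path) {
  raw <- yaml::read_yaml(path)
  ms <- raw$min_slices %||% 1L
  cons <- isTRUE(raw$consecutive)
  mk <- function(block) {
    if (is.null(block)) return(NULL)
    slice_pattern(lapply(block, as.character), min_slices = ms,
                  consecutive = cons)
  }
  signature(coronal = mk(raw$coronal), sagittal = mk(raw$sagittal))
}

#' @rdname read_signature
#' @param sig An `acdx_signature`.
#' @export
write_signature <- function(sig, path) {
  out <- lapply(sig$patterns, function(p) lapply(p$constraints, as.list))
  p1 <- sig$patterns[[1]]
  out$min_slices <- p1$min_slices
  out$consecutive <- p1$consecutive
  yaml::write_yaml(out, path)
  invisible(path)
}
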