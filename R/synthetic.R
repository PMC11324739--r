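#' Generate a textured image phantom stack
#'
#' Deterministic (per seed) 2-D phantoms standing in for MRI slices. Each
#' rectangular region is filled with one of two textures: `"smooth"` — a
#' gentle linear intensity gradient with faint noise, yielding low GLCM
#' contrast — or `"noisy"` — high-amplitude salt-and-pepper variation,
#' yielding high GLCM contrast. The smooth-vs-noisy contrast ordering is a
#' guaranteed qualitative property, not a calibrated value.
#'
#' @param shape Integer vector `c(rows, cols)` (default 32 x 32).
#' @param regions A data frame with columns `row1`, `row2`, `col1`, `col2`,
#'   `texture` (`"smooth"`/`"noisy"`), `mean`, `amplitude`. Default: one
#'   whole-image smooth region (mean 100, amplitude 40).
#' @param n_slices Number of slices in the stack (default 1).
#' @param seed RNG seed.
#' @return A list of [image_region()] objects.
#' @export
generate_phantom <- function(shape = c(32L, 32L), regions = NULL,
                             n_slices = 1L, seed = 1L) {
  if (length(shape) != 2 || any(shape < 2))
    stop("degenerate shape: need at least 2 x 2", call. = FALSE)
  if (is.null(regions))
    regions <- data.frame(row1 = 1, row2 = shape[1], col1 = 1, col2 = shape[2],
                          texture = "smooth", mean = 100, amplitude = 40)
  if (any(regions$row1 < 1 | regions$row2 > shape[1] |
          regions$col1 < 1 | regions$col2 > shape[2] |
          regions$row1 > regions$row2 | regions$col1 > regions$col2))
    stop("region out of bounds", call. = FALSE)
  if (!all(regions$texture %in% c("smooth", "noisy")))
    stop("texture must be smooth or noisy", call. = FALSE)
  set.seed(seed)
  lapply(seq_len(n_slices), function(s) {
    img <- matrix(0, shape[1], shape[2])
    for (r in seq_len(nrow(regions))) {
      rg <- regions[r, ]
      rr <- rg$row1:rg$row2; cc <- rg$col1:rg$col2
      npx <- length(rr) * length(cc)
      if (rg$texture == "smooth") {
        ramp <- matrix(rep(seq(-0.5, 0.5, length.out = length(cc)),
                           each = length(rr)), length(rr))
        img[rr, cc] <- rg$mean + rg$amplitude * ramp +
          stats::rnorm(npx, 0, rg$amplitude * 0.01)
      } else {
        img[rr, cc] <- rg$mean +
          rg$amplitude * sample(c(-1, 1), npx, replace = TRUE) *
            stats::runif(npx, 0.5, 1)
      }
    }
    image_region(img)
  })
}

.acdx_level_mu <- c(L = -2, M = 0, H = 2)

# truncated standard normal in [-1.4, 1.4] scaled by sd 0.5: level clusters
# occupy disjoint intervals (L in [-2.7, -1.3], M in [-0.7, 0.7], H in
# [1.3, 2.7]), so cluster membership survives any threshold between clusters
draw_level_values <- function(levels) {
  lo <- stats::pnorm(-1.4); hi <- stats::pnorm(1.4)
  .acdx_level_mu[levels] +
    0.5 * stats::qnorm(stats::runif(length(levels), lo, hi))
}

# tertile quotas matching fit_discretization's quantile definition exactly
level_quotas <- function(n) {
  q1 <- ceiling(n / 3); q2 <- ceiling(2 * n / 3)
  c(L = q1, M = q2 - q1, H = n - q2)
}

#' Synthesize a cohort of slice-wise feature tables
#'
#' Emulates the structure of a two-plane shoulder-MRI radiomics cohort:
#' `n_pos` capsulitis and `n_neg` control patients, around
#' `slices_per_patient` slices per patient per plane, with all 30 selected
#' features. Continuous values are drawn from three well-separated level
#' clusters (means -2/0/+2, sd 0.5, truncated) and the intended level counts
#' per feature are balanced to the exact cohort tertile quotas, so that
#' [fit_discretization()] + [discretize_features()] on the generated cohort
#' reproduces every intended level.
#'
#' The signature is planted on continuous values, not post-hoc labels: a
#' patient meant to test positive gets, in one randomly chosen signature
#' plane, `min_slices` slices whose constrained features draw from allowed
#' levels; a patient meant to test negative has every slice of every
#' signature plane "broken" — one constrained feature drawn from a
#' disallowed level — so no slice can satisfy the pattern. With a
#' `confusion_target`, positives are split into TP/FN and negatives into
#' FP/TN accordingly.
#'
#' @param n_pos,n_neg Number of capsulitis / control patients.
#' @param slices_per_patient Mean slice count (default 22).
#' @param slice_jitter Uniform jitter of the per-exam slice count (default 4;
#'   0 gives uniform slice counts).
#' @param planes Imaging planes to generate (default coronal + sagittal).
#' @param feature_class Class carrying the signature (default `"GLCM"`).
#' @param signature The `acdx_signature` to plant
#'   (default [default_glcm_signature()]).
#' @param confusion_target Optional `acdx_confusion` with
#'   `tp + fn == n_pos` and `fp + tn == n_neg`; without it all positives are
#'   planted and all negatives broken (a perfectly classifiable cohort).
#' @param seed RNG seed; the whole cohort is a deterministic function of the
#'   spec and seed.
#' @return A list with `features` (tibble: `patient_id`, `plane`,
#'   `slice_index`, 30 feature columns), `labels` (tibble), `levels` (the
#'   intended discretized table), `roles` (tibble: `patient_id`, `label`,
#'   `role` in TP/FP/FN/TN), and `intended` (tibble of intended diagnoses).
#' @export
synthesize_cohort <- function(n_pos = 32L, n_neg = 23L,
                              slices_per_patient = 22L, slice_jitter = 4L,
                              planes = c("coronal", "sagittal"),
                              feature_class = "GLCM",
                              signature = default_glcm_signature(),
                              confusion_target = NULL, seed = 1L) {
  if (n_pos < 1) stop("need at least one positive patient", call. = FALSE)
  if (n_neg < 0) stop("n_neg must be nonnegative", call. = FALSE)
  planes <- match.arg(planes, c("coronal", "sagittal"), several.ok = TRUE)
  stopifnot(inherits(signature, "acdx_signature"))
  active <- selected_features(feature_class)
  for (p in signature$patterns) {
    bad <- setdiff(names(p$constraints), active)
    if (length(bad) > 0)
      stop("signature constrains features outside class ", feature_class,
           ": ", paste(bad, collapse = ", "), call. = FALSE)
  }
  sig_planes <- intersect(planes, names(signature$patterns))
  if (length(sig_planes) == 0)
    stop("signature covers none of the generated planes", call. = FALSE)

  set.seed(seed)
  if (is.null(confusion_target)) {
    roles_pos <- rep("TP", n_pos); roles_neg <- rep("TN", n_neg)
  } else {
    ct <- confusion_target
    stopifnot(inherits(ct, "acdx_confusion"))
    if (ct$tp + ct$fn != n_pos || ct$fp + ct$tn != n_neg)
      stop("confusion_target inconsistent with cohort sizes (need tp+fn = ",
           n_pos, ", fp+tn = ", n_neg, ")", call. = FALSE)
    roles_pos <- sample(c(rep("TP", ct$tp), rep("FN", ct$fn)))
    roles_neg <- sample(c(rep("FP", ct$fp), rep("TN", ct$tn)))
  }
  ids <- sprintf("pt%03d", seq_len(n_pos + n_neg))
  roles <- tibble::tibble(
    patient_id = ids,
    label = c(rep("capsulitis", n_pos), rep("non_capsulitis", n_neg)),
    role = c(roles_pos, roles_neg)
  )

  ms <- max(vapply(signature$patterns, `[[`, 1L, "min_slices"))
  grid <- dplyr::bind_rows(lapply(ids, function(pid) {
    dplyr::bind_rows(lapply(planes, function(pl) {
      n_sl <- slices_per_patient +
        if (slice_jitter > 0) sample(-slice_jitter:slice_jitter, 1) else 0L
      n_sl <- max(n_sl, ms, 1L)
      tibble::tibble(patient_id = pid, plane = pl, slice_index = seq_len(n_sl))
    }))
  }))
  n_rows <- nrow(grid)
  all_feat <- feature_registry()$feature
  lv <- matrix(NA_character_, n_rows, length(all_feat),
               dimnames = list(NULL, all_feat))

  # plant / break per patient-plane
  for (pid in ids) {
    role <- roles$role[roles$patient_id == pid]
    want_match <- role %in% c("TP", "FP")
    planted_plane <- if (want_match) sample(sig_planes, 1) else NA_character_
    for (pl in sig_planes) {
      pat <- signature$patterns[[pl]]
      cons <- pat$constraints
      rows <- which(grid$patient_id == pid & grid$plane == pl)
      if (identical(pl, planted_plane)) {
        k <- pat$min_slices
        start <- if (pat$consecutive) {
          sample(length(rows) - k + 1L, 1)
        } else NA
        planted <- if (pat$consecutive) rows[start:(start + k - 1L)]
                   else rows[sample.int(length(rows), k)]
        for (f in names(cons))
          lv[planted, f] <- sample(cons[[f]], length(planted), replace = TRUE)
        # remaining slices left free: extra matches only reinforce the verdict
      } else {
        breakable <- names(cons)[lengths(lapply(cons, function(a) {
          setdiff(c("L", "M", "H"), a)
        })) > 0]
        if (length(breakable) == 0)
          stop("signature pattern for ", pl, " cannot be violated ",
               "(every constraint allows all levels)", call. = FALSE)
        # a plane fails the pattern when fewer than min_slices slices match:
        # break all but min_slices - 1 slices, which may then match freely
        n_brk <- max(length(rows) - (pat$min_slices - 1L), 0L)
        to_break <- rows[seq_len(n_brk)]
        brk <- sample(breakable, length(to_break), replace = TRUE)
        for (i in seq_along(to_break)) {
          disallowed <- setdiff(c("L", "M", "H"), cons[[brk[i]]])
          lv[to_break[i], brk[i]] <- sample(disallowed, 1)
        }
      }
    }
  }

  # balance every feature's level counts to the exact tertile quotas
  quota <- level_quotas(n_rows)
  for (f in all_feat) {
    fixed <- table(factor(lv[, f], levels = c("L", "M", "H")))
    if (any(fixed > quota))
      stop("feature ", f, ": planted/broken level counts exceed the tertile ",
           "quotas; the requested signature is too constraining for this ",
           "cohort size", call. = FALSE)
    fill <- rep(c("L", "M", "H"), quota - fixed)
    free <- which(is.na(lv[, f]))
    lv[free, f] <- sample(fill)
  }

  vals <- apply(lv, 2, draw_level_values)
  features <- dplyr::bind_cols(grid, tibble::as_tibble(vals))
  levels_tbl <- dplyr::bind_cols(grid, tibble::as_tibble(lv))
  list(
    features = features,
    labels = roles[c("patient_id", "label")],
    levels = levels_tbl,
    roles = roles,
    intended = tibble::tibble(patient_id = ids,
                              diagnosis = roles$role %in% c("TP", "FP"))
  )
}

#' Synthesize a cohort calibrated to a confusion matrix, and verify it
#'
#' Runs [synthesize_cohort()] with a required `confusion_target`, then pushes
#' the generated tables through the real pipeline — fit tertiles, discretize,
#' restrict to the signature's class, build the CCS/LTS models and classify,
#' evaluate — and asserts that the realized confusion matrix equals the
#' target exactly. A mismatch is an internal error (a pipeline bug), not a
#' user error.
#'
#' @inheritParams synthesize_cohort
#' @param confusion_target An `acdx_confusion` (required).
#' @return A list with the `synthesize_cohort()` elements plus `scheme`,
#'   `discretized`, `predictions` and `evaluation`.
#' @export
calibrate_fixture <- function(n_pos = 32L, n_neg = 23L, confusion_target,
                              feature_class = "GLCM",
                              signature = default_glcm_signature(),
                              seed = 1L, ...) {
  if (missing(confusion_target) || !inherits(confusion_target, "acdx_confusion"))
    stop("calibrate_fixture() requires an acdx_confusion target", call. = FALSE)
  cohort <- synthesize_cohort(
    n_pos = n_pos, n_neg = n_neg, feature_class = feature_class,
    signature = signature, confusion_target = confusion_target, seed = seed,
    ...
  )
  scheme <- fit_discretization(cohort$features)
  disc <- discretize_features(cohort$features, scheme)
  pred <- classify_cohort(select_features(disc, feature_class), signature)
  ev <- evaluate_cohort(pred, cohort$labels)
  got <- ev$confusion
  if (!identical(unclass(got)[c("tp", "fp", "fn", "tn")],
                 unclass(confusion_target)[c("tp", "fp", "fn", "tn")]))
    stop("internal error: realized confusion matrix ", format(got),
         " does not equal the requested target ", format(confusion_target),
         call. = FALSE)
  c(cohort, list(scheme = scheme, discretized = disc, predictions = pred,
                 evaluation = ev))
}
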