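test_that("patterns compile to EF over conjunctions of diamonds", {
  f <- compile_pattern(slice_pattern(GLCM_Contrast = "H"))
  expect_equal(deparse_formula(f), "EF(<H_contrast>tt)")
  f2 <- compile_pattern(slice_pattern(GLCM_Contrast = "H", GLCM_Id = "L"))
  expect_equal(deparse_formula(f2), "EF((<H_contrast>tt & <L_id>tt))")
  # level sets expand to label sets
  f3 <- compile_pattern(slice_pattern(GLCM_Contrast = c("M", "H")))
  expect_equal(deparse_formula(f3), "EF(<M_contrast,H_contrast>tt)")
})

test_that("pattern construction enforces single-class levels", {
  expect_error(slice_pattern(), "at least one")
  expect_error(slice_pattern(GLCM_Contrast = "X"), "subset of L/M/H")
  expect_error(slice_pattern(GLCM_Contrast = "H", FIRST_Energy = "L"),
               "single-class")
})

test_that("compiled verdict equals the slice-table scan on random exams", {
  # the load-bearing equivalence of the whole pipeline
  set.seed(31)
  feats <- paste0("TOY_", c("alpha", "beta", "gamma"))
  for (i in 1:400) {
    exam <- random_exam(sample(3, 1), feats)
    lts <- lts_from_model(build_ccs_model(exam))
    k <- sample(3, 1)
    cons <- lapply(seq_len(k), function(j) {
      sample(c("L", "M", "H"), sample(2, 1))
    })
    names(cons) <- sample(feats, k)
    p <- slice_pattern(cons)
    got <- check_formula(lts, compile_pattern(p), quiet = TRUE)$value
    expect_equal(got, pattern_scan_oracle(exam, p),
                 info = paste(deparse_formula(compile_pattern(p)),
                              paste(unlist(exam[-(1:3)]), collapse = "")))
  }
})

test_that("conjunctions cannot straddle adjacent slices", {
  # slice 1 has H contrast only, slice 2 L id only: no single slice matches
  exam <- tibble::tibble(
    patient_id = "p", plane = "coronal", slice_index = 1:2,
    GLCM_Contrast = c("H", "M"), GLCM_Id = c("H", "L")
  )
  lts <- lts_from_model(build_ccs_model(exam))
  p <- slice_pattern(GLCM_Contrast = "H", GLCM_Id = "L")
  expect_false(check_formula(lts, compile_pattern(p), quiet = TRUE)$value)
  # whereas a sequential diamond chain would match across the boundary
  chain <- parse_formula("EF(<H_contrast><L_id>tt)")
  expect_true(check_formula(lts, chain, quiet = TRUE)$value)
})

test_that("adding a constraint never flips a verdict to TRUE", {
  set.seed(37)
  feats <- paste0("TOY_", c("alpha", "beta", "gamma"))
  for (i in 1:50) {
    exam <- random_exam(sample(3, 1), feats)
    lts <- lts_from_model(build_ccs_model(exam))
    base <- slice_pattern(TOY_alpha = sample(c("L", "M", "H"), 1))
    wider <- slice_pattern(
      TOY_alpha = base$constraints$TOY_alpha,
      TOY_beta = sample(c("L", "M", "H"), 1)
    )
    vb <- check_formula(lts, compile_pattern(base), quiet = TRUE)$value
    vw <- check_formula(lts, compile_pattern(wider), quiet = TRUE)$value
    expect_true(vb >= vw)
  }
})

test_that("plane verdicts combine with OR", {
  sig <- signature(
    coronal = slice_pattern(GLCM_Contrast = "H"),
    sagittal = slice_pattern(GLCM_Contrast = "H")
  )
  mk_lts <- function(level) {
    lts_from_model(new_ccs_from_levels(list(
      action_label(level, "GLCM_Contrast")
    )))
  }
  expect_true(classify_patient(coronal = mk_lts("L"),
                               sagittal = mk_lts("H"), signature = sig))
  expect_false(classify_patient(coronal = mk_lts("L"),
                                sagittal = mk_lts("L"), signature = sig))
  expect_true(classify_patient(sagittal = mk_lts("H"), signature = sig))
  # plane mismatch is a configuration error
  cor_only <- signature(coronal = slice_pattern(GLCM_Contrast = "H"))
  expect_error(classify_patient(sagittal = mk_lts("H"),
                                signature = cor_only), "no pattern")
  expect_error(classify_patient(signature = sig), "at least one plane")
})

test_that("min_slices counts matching slices, optionally consecutive", {
  exam <- tibble::tibble(
    patient_id = "p", plane = "coronal", slice_index = 1:5,
    GLCM_Contrast = c("H", "L", "H", "H", "L")
  )
  lts <- lts_from_model(build_ccs_model(exam))
  sig_n <- function(n, consec = FALSE) signature(
    coronal = slice_pattern(GLCM_Contrast = "H", min_slices = n,
                            consecutive = consec)
  )
  expect_true(classify_patient(coronal = lts, signature = sig_n(3)))
  expect_false(classify_patient(coronal = lts, signature = sig_n(4)))
  expect_true(classify_patient(coronal = lts, signature = sig_n(2, TRUE)))
  expect_false(classify_patient(coronal = lts, signature = sig_n(3, TRUE)))
  # min_slices beyond the slice count is FALSE, not an error
  expect_false(classify_patient(coronal = lts, signature = sig_n(9)))
})

test_that("mined patterns cover shared exemplar signs at full support", {
  exs <- dplyr::bind_rows(
    tibble::tibble(patient_id = "e1", plane = "coronal", slice_index = 1:2,
                   GLCM_Contrast = c("H", "L"), GLCM_Id = c("L", "M")),
    tibble::tibble(patient_id = "e2", plane = "coronal", slice_index = 1:2,
                   GLCM_Contrast = c("M", "H"), GLCM_Id = c("H", "L"))
  )
  out <- mine_candidate_patterns(exs, support = 1)
  keys <- vapply(out$pattern, function(p) {
    paste(names(p$constraints),
          vapply(p$constraints, paste, "", collapse = ""),
          collapse = ";", sep = "=")
  }, "")
  # both exemplars have a slice with contrast H and id L simultaneously
  expect_true("GLCM_Contrast=H;GLCM_Id=L" %in% keys)
  expect_true("GLCM_Contrast=H" %in% keys)
  # ordered by decreasing size
  expect_true(all(diff(out$size) <= 0))
  # every returned pattern satisfies its support when re-checked
  for (r in seq_len(nrow(out))) {
    p <- out$pattern[[r]]
    hit <- vapply(split(exs, exs$patient_id), pattern_scan_oracle, TRUE,
                  pattern = p)
    expect_gte(mean(hit), 1)
  }
})

test_that("disjoint exemplars yield no full-support size-2 patterns", {
  exs <- dplyr::bind_rows(
    tibble::tibble(patient_id = "e1", plane = "coronal", slice_index = 1,
                   GLCM_Contrast = "H", GLCM_Id = "H"),
    tibble::tibble(patient_id = "e2", plane = "coronal", slice_index = 1,
                   GLCM_Contrast = "L", GLCM_Id = "L")
  )
  out <- mine_candidate_patterns(exs, support = 1)
  expect_equal(nrow(out), 0)
  # at support 0.5 every level seen in either exemplar comes back at size 1
  half <- mine_candidate_patterns(exs, support = 0.5)
  expect_gte(nrow(half[half$size == 1, ]), 4)
  expect_error(mine_candidate_patterns(exs[0, ]), "no exemplar")
})

test_that("signatures survive a YAML round trip", {
  sig <- signature(
    coronal = slice_pattern(GLCM_Contrast = "H", GLCM_Id = c("L", "M"),
                            min_slices = 2),
    sagittal = slice_pattern(GLCM_ClusterProminence = "H", min_slices = 2)
  )
  path <- withr::local_tempfile(fileext = ".yaml")
  write_signature(sig, path)
  back <- read_signature(path)
  expect_equal(back$patterns$coronal$constraints,
               sig$patterns$coronal$constraints)
  expect_equal(back$patterns$sagittal$min_slices, 2L)
})
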