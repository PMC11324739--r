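mk_table <- function(patients = 2, slices = 3, planes = "coronal",
                     features = c("GLCM_Contrast", "GLCM_Id")) {
  g <- expand.grid(slice_index = seq_len(slices), plane = planes,
                   patient_id = sprintf("p%d", seq_len(patients)),
                   stringsAsFactors = FALSE)
  tbl <- tibble::as_tibble(g[c("patient_id", "plane", "slice_index")])
  for (f in features) tbl[[f]] <- stats::rnorm(nrow(tbl))
  tbl
}

test_that("registry bookkeeping: 94 extracted, 30 selected, 6 x 5 grouping", {
  expect_equal(sum(feature_class_sizes()), 94)
  reg <- feature_registry()
  expect_equal(nrow(reg), 30)
  expect_equal(unname(table(reg$class)[unique(reg$class)]),
               rep(5L, 6), ignore_attr = TRUE)
  expect_setequal(unique(reg$class),
                  c("FIRST", "GLCM", "GLDM", "GLRLM", "GLSZM", "SHAPE"))
})

test_that("canonical per-class selections are exact", {
  expect_setequal(sub("^GLCM_", "", selected_features("GLCM")),
                  c("ClusterProminence", "Contrast", "DifferenceAverage",
                    "DifferenceVariance", "Id"))
  expect_setequal(sub("^FIRST_", "", selected_features("FIRST")),
                  c("Energy", "Median", "Minimum", "TotalEnergy", "Variance"))
  expect_setequal(sub("^SHAPE_", "", selected_features("SHAPE")),
                  c("Flatness", "LeastAxisLength", "MeshVolume",
                    "SurfaceArea", "VoxelVolume"))
})

test_that("feature tables round-trip through CSV bit-identically", {
  set.seed(7)
  co <- synthesize_cohort(n_pos = 3, n_neg = 2, slices_per_patient = 4,
                          slice_jitter = 1, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(co$features, path)
  back <- read_feature_table(path)
  expect_equal(as.data.frame(back), as.data.frame(co$features))

  # plane filter
  cor_only <- read_feature_table(path, plane = "coronal")
  expect_true(all(cor_only$plane == "coronal"))
})

test_that("malformed tables are rejected with informative errors", {
  tbl <- mk_table()
  expect_error(validate_err <- write_feature_table(tbl[-1, ]), "contiguous")
  tbl2 <- tbl
  tbl2$slice_index[2] <- 5 # 1,5,3 for p1
  expect_error(write_feature_table(tbl2), "contiguous")
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tbl[, -1], path)
  expect_error(read_feature_table(path), "patient_id")
  tbl3 <- tbl
  tbl3$GLCM_Contrast[3] <- NA
  expect_error(write_feature_table(tbl3), "row 3")
})

test_that("unknown feature columns are preserved but flagged", {
  tbl <- mk_table(features = c("GLCM_Contrast", "GLCM_Bogus"))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tbl, path)
  expect_warning(back <- read_feature_table(path), "GLCM_Bogus")
  expect_true("GLCM_Bogus" %in% names(back))
})

test_that("select_features keeps exactly one class and errors on absence", {
  co <- synthesize_cohort(n_pos = 2, n_neg = 1, slices_per_patient = 3,
                          slice_jitter = 0, seed = 1)
  sel <- select_features(co$features, "GLCM")
  expect_equal(setdiff(names(sel), c("patient_id", "plane", "slice_index")),
               selected_features("GLCM"))
  expect_error(select_features(sel, "FIRST"), "missing")
})

test_that("tertile thresholds follow the empirical quantile definition", {
  tbl <- tibble::tibble(patient_id = "p1", plane = "coronal",
                        slice_index = 1:6, F_a = c(1, 2, 3, 4, 5, 6))
  sc <- fit_discretization(tbl)
  expect_equal(c(sc$t1, sc$t2), c(2, 4))

  tbl3 <- tibble::tibble(patient_id = "p1", plane = "coronal",
                         slice_index = 1:3, F_a = c(10, 20, 30))
  sc3 <- fit_discretization(tbl3)
  expect_equal(c(sc3$t1, sc3$t2), c(10, 20))

  cst <- tibble::tibble(patient_id = "p1", plane = "coronal",
                        slice_index = 1:4, F_a = rep(9, 4))
  expect_warning(scc <- fit_discretization(cst), "constant")
  expect_equal(c(scc$t1, scc$t2), c(9, 9))
})

test_that("discretization maps boundaries to the lower level", {
  sc <- structure(tibble::tibble(feature = "F_a", t1 = 2, t2 = 4),
                  class = c("acdx_scheme", class(tibble::tibble())))
  tbl <- tibble::tibble(patient_id = "p", plane = "coronal",
                        slice_index = 1:5, F_a = c(1, 2, 3, 4, 5))
  d <- discretize_features(tbl, sc)
  expect_equal(d$F_a, c("L", "L", "M", "M", "H"))

  deg <- structure(tibble::tibble(feature = "F_a", t1 = 9, t2 = 9),
                   class = class(sc))
  d2 <- discretize_features(
    tibble::tibble(patient_id = "p", plane = "coronal", slice_index = 1:3,
                   F_a = c(3, 9, 10)), deg)
  expect_equal(d2$F_a, c("L", "L", "H"))

  expect_error(
    discretize_features(
      tibble::tibble(patient_id = "p", plane = "coronal", slice_index = 1,
                     F_b = 1), sc),
    "cover")
})

test_that("discretization is monotone and hits every level on fitted data", {
  set.seed(3)
  for (rep in 1:10) {
    tbl <- mk_table(patients = 3, slices = 7)
    sc <- fit_discretization(tbl)
    d <- discretize_features(tbl, sc)
    for (f in c("GLCM_Contrast", "GLCM_Id")) {
      ord <- order(tbl[[f]])
      lv <- factor(d[[f]][ord], levels = c("L", "M", "H"), ordered = TRUE)
      expect_true(all(diff(as.integer(lv)) >= 0))
      expect_setequal(unique(as.character(lv)), c("L", "M", "H"))
    }
  }
})

test_that("schemes survive a YAML round trip", {
  tbl <- mk_table()
  sc <- fit_discretization(tbl)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scheme(sc, path)
  back <- read_scheme(path)
  expect_equal(tidy(back), tidy(sc))
})

test_that("generic filter drops constant and collinear features", {
  tbl <- mk_table(features = "F_a")
  tbl$F_const <- 1
  tbl$F_dup <- tbl$F_a * 2 + 1e-9
  out <- filter_features(tbl)
  expect_true("F_a" %in% names(out))
  expect_false("F_const" %in% names(out))
  expect_false("F_dup" %in% names(out))
})

test_that("labels round-trip and reject unknown classes", {
  lab <- tibble::tibble(patient_id = c("a", "b"),
                        label = c("capsulitis", "non_capsulitis"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_labels(lab, path)
  expect_equal(as.data.frame(read_labels(path)), as.data.frame(lab))
  readr::write_csv(tibble::tibble(patient_id = "a", label = "sick"), path)
  expect_error(read_labels(path), "capsulitis")
})
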