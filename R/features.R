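#' Image region
#'
#' Bundle a 2-D grayscale intensity array with an in-region mask and a voxel
#' volume. The default mask covers the whole slice, mirroring whole-slice
#' analysis without a segmented region of interest; a threshold mask can be
#' supplied for ROI-style analysis.
#'
#' @param intensities Numeric matrix of gray values; all masked values must be
#'   finite.
#' @param mask Logical matrix of the same shape (default: all `TRUE`).
#' @param voxel_volume Positive scalar, mm^3 per voxel (default 1).
#' @return An object of class `acdx_region`.
#' @examples
#' r <- image_region(matrix(1:6, 2, 3))
#' @export
image_region <- function(intensities, mask = NULL, voxel_volume = 1) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("`intensities` must be a numeric matrix", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, dim(intensities))
  if (!is.logical(mask) || !identical(dim(mask), dim(intensities)))
    stop("`mask` must be a logical matrix with the same shape as `intensities`",
         call. = FALSE)
  if (!any(mask)) stop("mask selects no voxels", call. = FALSE)
  if (!all(is.finite(intensities[mask])))
    stop("masked intensities must all be finite", call. = FALSE)
  if (!is.numeric(voxel_volume) || length(voxel_volume) != 1 || voxel_volume <= 0)
    stop("`voxel_volume` must be a positive scalar", call. = FALSE)
  structure(
    list(intensities = intensities, mask = mask, voxel_volume = voxel_volume),
    class = "acdx_region"
  )
}

as_region <- function(x) {
  if (inherits(x, "acdx_region")) x else image_region(x)
}

#' @export
print.acdx_region <- function(x, ...) {
  cat(sprintf("<acdx_region> %d x %d, %d masked voxels, voxel volume %g\n",
              nrow(x$intensities), ncol(x$intensities), sum(x$mask),
              x$voxel_volume))
  invisible(x)
}

#' First-order intensity features
#'
#' Computes the five selected first-order features over the masked voxels:
#' Energy (sum of squared intensities), Total energy (Energy times voxel
#' volume), Median (midpoint-interpolated order statistic), Minimum, and
#' Variance (population variance, dividing by N). No intensity shift is
#' applied before squaring.
#'
#' @param region An [image_region()], or a numeric matrix (whole-slice mask).
#' @return A tibble with columns `feature`, `value` (5 rows).
#' @examples
#' compute_first_order(matrix(c(1, 2, 3), 1))
#' @export
compute_first_order <- function(region) {
  region <- as_region(region)
  x <- region$intensities[region$mask]
  energy <- sum(x^2)
  tibble::tibble(
    feature = c("FIRST_Energy", "FIRST_Median", "FIRST_Minimum",
                "FIRST_TotalEnergy", "FIRST_Variance"),
    value = c(energy, stats::median(x), min(x),
              region$voxel_volume * energy, mean((x - mean(x))^2))
  )
}

#' Quantize a region to gray levels
#'
#' Equal-width binning of the in-mask intensity range into `n_levels` bins,
#' producing integer levels 1..n_levels. A constant image maps entirely to
#' level 1. Out-of-mask voxels are set to `NA`.
#'
#' @param region An [image_region()] or numeric matrix.
#' @param n_levels Number of gray-level bins (default 32, minimum 2).
#' @return Integer matrix of levels with `NA` outside the mask.
#' @examples
#' quantize_region(matrix(c(0, 1, 2, 3), 2), n_levels = 2)
#' @export
quantize_region <- function(region, n_levels = 32) {
  region <- as_region(region)
  if (n_levels < 2) stop("`n_levels` must be at least 2", call. = FALSE)
  x <- region$intensities
  v <- x[region$mask]
  rng <- range(v)
  lev <- matrix(NA_integer_, nrow(x), ncol(x))
  if (rng[1] == rng[2]) {
    lev[region$mask] <- 1L
  } else {
    w <- (rng[2] - rng[1]) / n_levels
    l <- pmin(floor((v - rng[1]) / w) + 1L, n_levels)
    lev[region$mask] <- as.integer(l)
  }
  lev
}

#' GLCM offset set
#'
#' The four unique 2-D direction vectors at pixel distance delta = 1, i.e.
#' angles 0, 45, 90 and 135 degrees, as (row, col) displacements.
#'
#' @return A list of length-2 integer vectors.
#' @export
default_offsets <- function() {
  list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
}

#' Gray-level co-occurrence matrices
#'
#' Counts, for each offset, how often a pair of gray levels occurs in two
#' in-mask pixels separated by that displacement. With `symmetric = TRUE` the
#' transposed counts are added (both pair orders); with `normalize = TRUE`
#' each matrix is divided by its total count. Offsets with no valid pixel
#' pair are dropped.
#'
#' @param levels Integer matrix of quantized gray levels 1..`n_levels`
#'   (`NA` outside the region), as produced by [quantize_region()].
#' @param n_levels Number of gray levels; defaults to `max(levels)`.
#' @param offsets List of (row, col) displacement vectors
#'   (default [default_offsets()]).
#' @param symmetric,normalize Logical flags (default `TRUE`).
#' @return A list of `acdx_glcm` objects, one per offset with at least one
#'   valid pair; names encode the offsets.
#' @examples
#' g <- compute_glcm(matrix(c(1L, 2L, 1L, 2L), 2), offsets = list(c(0L, 1L)))
#' g[[1]]$p
#' @export
compute_glcm <- function(levels, n_levels = NULL, offsets = default_offsets(),
                         symmetric = TRUE, normalize = TRUE) {
  if (!is.matrix(levels)) stop("`levels` must be a matrix", call. = FALSE)
  lv <- levels[!is.na(levels)]
  if (length(lv) == 0) stop("no in-mask levels", call. = FALSE)
  if (any(lv < 1 | lv != floor(lv)))
    stop("`levels` must contain positive integer gray levels", call. = FALSE)
  if (is.null(n_levels)) n_levels <- max(lv)
  if (n_levels < max(lv)) stop("`n_levels` smaller than max level", call. = FALSE)
  out <- list()
  nr <- nrow(levels); nc <- ncol(levels)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    if (dr == 0 && dc == 0) stop("offset must be nonzero", call. = FALSE)
    # index windows so that (r, c) and (r + dr, c + dc) are both in range
    if (max(1, 1 - dr) > min(nr, nr - dr) ||
        max(1, 1 - dc) > min(nc, nc - dc)) next
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    a <- levels[r1, c1, drop = FALSE]
    b <- levels[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    p <- matrix(0, n_levels, n_levels)
    tab <- table(factor(a[ok], levels = 1:n_levels),
                 factor(b[ok], levels = 1:n_levels))
    p <- p + unclass(tab)
    if (symmetric) p <- p + t(p)
    if (normalize) p <- p / sum(p)
    out[[paste0("(", dr, ",", dc, ")")]] <- structure(
      list(p = unname(p),
           settings = list(n_levels = n_levels, offset = c(dr, dc),
                           symmetric = symmetric, normalize = normalize)),
      class = "acdx_glcm"
    )
  }
  if (length(out) == 0)
    stop("degenerate co-occurrence matrix: no valid pixel pair for any offset",
         call. = FALSE)
  out
}

#' @export
print.acdx_glcm <- function(x, ...) {
  s <- x$settings
  cat(sprintf("<acdx_glcm> %d levels, offset (%d,%d)%s%s\n", s$n_levels,
              s$offset[1], s$offset[2],
              if (s$symmetric) ", symmetric" else "",
              if (s$normalize) ", normalized" else ""))
  print(x$p)
  invisible(x)
}

#' GLCM texture features
#'
#' Computes the five selected co-occurrence features from one or several
#' normalized symmetric GLCMs; with several matrices (one per offset) the
#' per-offset feature values are averaged. With level indices i, j and
#' difference distribution p_{|i-j|}:
#' Contrast = sum (i-j)^2 p(i,j); Cluster prominence =
#' sum (i+j-mu_x-mu_y)^4 p(i,j); Difference average = sum_k k p_{|i-j|}(k);
#' Difference variance = sum_k (k - DA)^2 p_{|i-j|}(k);
#' Id (inverse difference) = sum p(i,j)/(1+|i-j|).
#'
#' @param glcm An `acdx_glcm`, or a list of them as returned by
#'   [compute_glcm()].
#' @return A tibble with columns `feature`, `value` (5 rows).
#' @examples
#' g <- compute_glcm(matrix(c(1L, 1L, 2L, 2L), 2, byrow = TRUE),
#'                   n_levels = 2, offsets = list(c(0L, 1L)))
#' compute_glcm_features(g)
#' @export
compute_glcm_features <- function(glcm) {
  if (inherits(glcm, "acdx_glcm")) glcm <- list(glcm)
  stopifnot(length(glcm) >= 1, all(vapply(glcm, inherits, TRUE, "acdx_glcm")))
  per <- vapply(glcm, function(m) {
    p <- m$p
    if (abs(sum(p) - 1) > 1e-9)
      stop("GLCM must be normalized (entries summing to 1)", call. = FALSE)
    if (max(abs(p - t(p))) > 1e-9)
      stop("GLCM must be symmetric", call. = FALSE)
    n <- nrow(p)
    i <- row(p); j <- col(p)
    mu_x <- sum(i * p); mu_y <- sum(j * p)
    # difference distribution over k = |i - j|
    k <- 0:(n - 1)
    pd <- vapply(k, function(d) sum(p[abs(i - j) == d]), 0)
    da <- sum(k * pd)
    c(ClusterProminence = sum((i + j - mu_x - mu_y)^4 * p),
      Contrast = sum((i - j)^2 * p),
      DifferenceAverage = da,
      DifferenceVariance = sum((k - da)^2 * pd),
      Id = sum(p / (1 + abs(i - j))))
  }, numeric(5))
  tibble::tibble(
    feature = paste0("GLCM_", rownames(per)),
    value = unname(rowMeans(per))
  )
}

#' All native features of one slice
#'
#' Convenience wrapper: first-order features on the raw intensities plus GLCM
#' features on the quantized region, returned as one wide one-row tibble
#' keyed by feature identifier.
#'
#' @inheritParams compute_first_order
#' @inheritParams quantize_region
#' @inheritParams compute_glcm
#' @return A one-row tibble with one column per feature identifier.
#' @export
slice_features <- function(region, n_levels = 32, offsets = default_offsets()) {
  region <- as_region(region)
  fo <- compute_first_order(region)
  lev <- quantize_region(region, n_levels)
  gl <- compute_glcm_features(
    compute_glcm(lev, n_levels = max(lev, na.rm = TRUE), offsets = offsets)
  )
  tidyr::pivot_wider(rbind(fo, gl), names_from = "feature",
                     values_from = "value")
}
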