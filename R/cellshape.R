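# Support-cell orientation from segmented label images: per-region
# moment-ellipse fitting (the particle-analysis ellipse with matching
# second central moments), 0-90 degree orientation histograms, and the
# one-way chi-square uniformity test.

# Pixel coordinates of a label, in the y-up frame used package-wide:
# pixel (row r, col c) -> (x = c, y = nrow + 1 - r).
label_pixels <- function(label_image, label) {
  idx <- which(label_image == label, arr.ind = TRUE)
  cbind(x = idx[, 2], y = nrow(label_image) + 1 - idx[, 1])
}

#' Moment ellipse of one labelled region
#'
#' Fits the region to the ellipse with matching second central moments:
#' centroid from the first moments, axis lengths `4 * sqrt(eigenvalue)` of
#' the central second-moment matrix (so a rendered ellipse recovers its own
#' axes), and orientation from the leading eigenvector. The orientation is
#' folded to the unsigned range `[0, 90]` (angle between the major axis and
#' the horizontal); the signed axial angle is also returned for reuse.
#' Near-circular regions (axis ratio < 1.05) have no meaningful major axis
#' and are flagged.
#'
#' @param label_image Integer matrix of region labels (0 = background).
#' @param label Region label to measure.
#' @param min_area Minimum pixel count (default 5).
#' @return A one-row tibble: `label`, `centroid_x`, `centroid_y`,
#'   `major_len`, `minor_len`, `orientation_deg` (in `[0, 90]`),
#'   `axial_angle_deg` (signed, (-90, 90]), `area`, `eccentricity_flag`.
#' @export
region_ellipse <- function(label_image, label, min_area = 5) {
  px <- label_pixels(label_image, label)
  if (nrow(px) == 0) stop("label ", label, " not present", call. = FALSE)
  if (nrow(px) < min_area) {
    stop("region ", label, " smaller than ", min_area, " pixels",
         call. = FALSE)
  }
  ctr <- colMeans(px)
  centered <- sweep(px, 2, ctr)
  mom <- crossprod(centered) / nrow(px)
  eig <- eigen(mom, symmetric = TRUE)
  major <- 4 * sqrt(max(eig$values[1], 0))
  minor <- 4 * sqrt(max(eig$values[2], 0))
  axial <- wrap_axial(atan2(eig$vectors[2, 1], eig$vectors[1, 1]) * 180 / pi)
  tibble::tibble(
    label = label,
    centroid_x = unname(ctr[1]), centroid_y = unname(ctr[2]),
    major_len = major, minor_len = minor,
    orientation_deg = abs(axial),
    axial_angle_deg = axial,
    area = nrow(px),
    eccentricity_flag = minor <= 0 || major / max(minor, 1e-12) < 1.05
  )
}

#' Moment ellipses for every region in a label image
#'
#' @param label_image Integer matrix of labels.
#' @param min_area Minimum region area in pixels; smaller regions are
#'   excluded with reason `"too_small"` rather than erroring.
#' @return A tibble with one row per label: the [region_ellipse()] columns
#'   plus `excluded` and `exclude_reason` (`"too_small"` or
#'   `"near_circular"`).
#' @export
region_ellipses <- function(label_image, min_area = 5) {
  labels <- sort(setdiff(unique(as.vector(label_image)), 0))
  if (length(labels) == 0) {
    stop("label image contains no regions", call. = FALSE)
  }
  purrr::map_dfr(labels, function(lb) {
    px_n <- sum(label_image == lb)
    if (px_n < min_area) {
      return(tibble::tibble(
        label = lb, centroid_x = NA_real_, centroid_y = NA_real_,
        major_len = NA_real_, minor_len = NA_real_,
        orientation_deg = NA_real_, axial_angle_deg = NA_real_,
        area = px_n, eccentricity_flag = NA,
        excluded = TRUE, exclude_reason = "too_small"
      ))
    }
    r <- region_ellipse(label_image, lb, min_area)
    dplyr::mutate(
      r,
      excluded = r$eccentricity_flag,
      exclude_reason = ifelse(r$eccentricity_flag, "near_circular",
                              NA_character_)
    )
  })
}

#' Histogram of region orientations over 0-90 degrees
#'
#' Equal-width bins over the unsigned orientation range; flagged
#' (near-circular or too-small) shapes are excluded.
#'
#' @param shapes Tibble from [region_ellipses()] (or with columns
#'   `orientation_deg` and optionally `excluded`).
#' @param n_bins Number of bins (default 9, i.e. 10-degree bins).
#' @return A tibble `bin_low`, `bin_high`, `bin_mid`, `count`, with
#'   attributes `n_included` and `n_excluded`.
#' @export
orientation_histogram <- function(shapes, n_bins = 9) {
  stopifnot(n_bins >= 2)
  excluded <- if ("excluded" %in% names(shapes)) shapes$excluded else
    rep(FALSE, nrow(shapes))
  ori <- shapes$orientation_deg[!excluded]
  if (length(ori) == 0) {
    stop("no unflagged shapes to histogram", call. = FALSE)
  }
  width <- 90 / n_bins
  idx <- pmin(pmax(ceiling(ori / width), 1L), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  edges <- seq(0, 90, length.out = n_bins + 1)
  out <- tibble::tibble(
    bin_low = edges[-(n_bins + 1)], bin_high = edges[-1],
    bin_mid = (edges[-(n_bins + 1)] + edges[-1]) / 2,
    count = counts
  )
  attr(out, "n_included") <- length(ori)
  attr(out, "n_excluded") <- sum(excluded)
  out
}

#' Support-cell orientation pipeline
#'
#' Measures the moment ellipse of every region in a segmented label image,
#' histograms the unsigned orientations over `[0, 90]` degrees, and runs
#' the one-way chi-square test against a uniform orientation distribution.
#' Coordinated (e.g. horizontally skewed) support-cell elongation rejects
#' uniformity; isotropic fields do not.
#'
#' @param label_image Integer matrix of region labels.
#' @param n_bins Histogram bins (default 9).
#' @param alpha Significance threshold (default 0.01).
#' @param min_area Minimum region area, pixels.
#' @return A list of class `nm_support_cells`: `shapes`, `histogram`,
#'   `uniform_test`, `n_excluded`.
#' @export
support_cell_pipeline <- function(label_image, n_bins = 9, alpha = 0.01,
                                  min_area = 5) {
  shapes <- region_ellipses(label_image, min_area)
  valid <- sum(!shapes$excluded)
  if (valid < 5) {
    stop("need at least 5 valid regions, got ", valid, call. = FALSE)
  }
  hist <- orientation_histogram(shapes, n_bins)
  ut <- chisq_uniform_test(hist$count, alpha)
  structure(
    list(shapes = shapes, histogram = hist, uniform_test = ut,
         n_excluded = sum(shapes$excluded)),
    class = "nm_support_cells"
  )
}

#' @export
print.nm_support_cells <- function(x, ...) {
  cat(sprintf("Support-cell orientation: %d regions (%d excluded)\n",
              nrow(x$shapes), x$n_excluded))
  print(x$uniform_test)
  invisible(x)
}

#' @export
tidy.nm_support_cells <- function(x, ...) x$shapes

#' @export
glance.nm_support_cells <- function(x, ...) {
  dplyr::mutate(glance(x$uniform_test), n_excluded = x$n_excluded)
}

#' Plot a support-cell orientation histogram
#'
#' @param object An `nm_support_cells` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nm_support_cells <- function(object, ...) {
  h <- object$histogram
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = h$bin_high[1] - h$bin_low[1], fill = "grey70",
                      colour = "grey30") +
    ggplot2::labs(
      x = "cell orientation vs horizontal (deg)", y = "count",
      title = sprintf("uniformity p = %.3g", object$uniform_test$p_value)
    ) +
    ggplot2::theme_minimal()
}
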