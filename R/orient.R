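# Hair-cell orientation from kinocilium-line annotations, rose-diagram
# summaries, pair-opposition scoring, and progenitor division-angle
# geometry.

#' Orientation of a kinocilium line
#'
#' An annotated line runs from the pole opposite the kinocilium toward the
#' pole where the kinocilium sits, so the line's direction is the cell's
#' polarity direction. Image-viewer coordinates have y growing downward;
#' with `image_frame = TRUE` the y component is negated first so
#' anticlockwise stays positive on screen-displayed data.
#'
#' @param x1,y1,x2,y2 Line endpoints, pixels. Vectors recycle.
#' @param image_frame If `TRUE` (default) endpoints are in image (y-down)
#'   coordinates.
#' @return A tibble with `dir_angle_deg` in (-180, 180] and
#'   `axial_angle_deg` in (-90, 90].
#' @examples
#' orientation_from_line(0, 0, 1, 0)  # points right: dir 0, axial 0
#' @export
orientation_from_line <- function(x1, y1, x2, y2, image_frame = TRUE) {
  dx <- x2 - x1
  dy <- y2 - y1
  if (any(dx == 0 & dy == 0)) {
    stop("zero-length kinocilium line", call. = FALSE)
  }
  if (image_frame) dy <- -dy
  dir <- wrap_directional(atan2(dy, dx) * 180 / pi)
  tibble::tibble(dir_angle_deg = dir, axial_angle_deg = wrap_axial(dir))
}

#' Rose-diagram bin counts of directional angles
#'
#' Equal-width, half-open (anticlockwise-closed) bins over (-180, 180].
#'
#' @param dir_angles Directional angles, degrees (wrapped mod 360).
#' @param n_bins Number of bins (>= 4, default 12).
#' @return A tibble with `bin_low`, `bin_high`, `bin_mid`, `count`.
#' @export
rose_counts <- function(dir_angles, n_bins = 12) {
  stopifnot(n_bins >= 4)
  d <- wrap_directional(dir_angles[is.finite(dir_angles)])
  width <- 360 / n_bins
  idx <- pmin(pmax(ceiling((d + 180) / width), 1L), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  edges <- seq(-180, 180, length.out = n_bins + 1)
  tibble::tibble(
    bin_low = edges[-(n_bins + 1)], bin_high = edges[-1],
    bin_mid = (edges[-(n_bins + 1)] + edges[-1]) / 2,
    count = counts
  )
}

#' Rose diagram of directional angles
#'
#' @param dir_angles Directional angles, degrees.
#' @param n_bins Number of bins.
#' @return A ggplot object (polar bar chart, 0 degrees to the right,
#'   anticlockwise positive).
#' @export
plot_rose <- function(dir_angles, n_bins = 12) {
  rc <- rose_counts(dir_angles, n_bins)
  ggplot2::ggplot(rc, ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = 360 / n_bins, fill = "steelblue",
                      colour = "grey20") +
    ggplot2::coord_polar(start = pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(-180, 180),
                                breaks = seq(-135, 180, by = 45)) +
    ggplot2::labs(x = NULL, y = "count") +
    ggplot2::theme_minimal()
}

#' Do two sister hair cells point toward each other?
#'
#' A pair is "correctly oriented" when each cell's kinocilium direction is
#' within `tolerance` degrees of the unit vector from that cell toward its
#' sister. The default tolerance of 90 degrees is the positive-inner-product
#' criterion: each cell at least leans toward the other.
#'
#' @param c1,c2 Single-row data frames (or lists) with `x`, `y`,
#'   `dir_angle_deg`.
#' @param tolerance Half-width of the angular acceptance region, degrees.
#' @return Logical.
#' @export
pair_opposition <- function(c1, c2, tolerance = 90) {
  dx <- c2$x - c1$x
  dy <- c2$y - c1$y
  if (dx == 0 && dy == 0) stop("coincident cell positions", call. = FALSE)
  if (is.na(c1$dir_angle_deg) || is.na(c2$dir_angle_deg)) {
    stop("both cells need a kinocilium direction", call. = FALSE)
  }
  toward12 <- atan2(dy, dx) * 180 / pi
  off1 <- abs(wrap_directional(c1$dir_angle_deg - toward12))
  off2 <- abs(wrap_directional(c2$dir_angle_deg - (toward12 + 180)))
  off1 < tolerance && off2 < tolerance
}

#' Score pair opposition across a table of simulated or annotated pairs
#'
#' @param pairs Long tibble as produced by [simulate_pairs()] (`pair_id`,
#'   `member`, `x`, `y`, `dir_angle_deg`).
#' @param tolerance Passed to [pair_opposition()].
#' @return A tibble with one row per pair: `pair_id`, `opposed`.
#' @export
score_pairs <- function(pairs, tolerance = 90) {
  pairs |>
    dplyr::group_by(.data$pair_id) |>
    dplyr::group_modify(function(df, key) {
      stopifnot(nrow(df) == 2)
      tibble::tibble(opposed = pair_opposition(df[1, ], df[2, ], tolerance))
    }) |>
    dplyr::ungroup()
}

#' Division angle with respect to the neuromast radius
#'
#' The angle between the daughter-daughter vector and the vector from the
#' organ center to the center of division (daughter midpoint), folded to
#' the smallest angle in `[0, 90]` degrees. Works in 2D and 3D.
#'
#' @param d1,d2 Daughter positions, numeric vectors of equal length (2 or 3).
#' @param center Organ center, same length.
#' @return Degrees in `[0, 90]`.
#' @export
division_angle <- function(d1, d2, center) {
  stopifnot(length(d1) == length(d2), length(d1) == length(center))
  u <- d2 - d1
  if (all(u == 0)) stop("daughters coincide", call. = FALSE)
  v <- (d1 + d2) / 2 - center
  if (sqrt(sum(v^2)) < 1e-12) {
    stop("division midpoint coincides with the organ center", call. = FALSE)
  }
  cosang <- abs(sum(u * v)) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Division angles for a table of division events
#'
#' @param events Tibble with `d1x`, `d1y`, `d2x`, `d2y`, `cx`, `cy` (and
#'   optional `d1z`, `d2z`, `cz` for 3D data), e.g. from
#'   [simulate_divisions()] or [read_divisions()].
#' @return The input tibble with `division_angle_deg` added.
#' @export
division_angles <- function(events) {
  has_z <- all(c("d1z", "d2z", "cz") %in% names(events))
  ang <- purrr::map_dbl(seq_len(nrow(events)), function(i) {
    e <- events[i, ]
    if (has_z) {
      division_angle(c(e$d1x, e$d1y, e$d1z), c(e$d2x, e$d2y, e$d2z),
                     c(e$cx, e$cy, e$cz))
    } else {
      division_angle(c(e$d1x, e$d1y), c(e$d2x, e$d2y), c(e$cx, e$cy))
    }
  })
  dplyr::mutate(events, division_angle_deg = ang)
}

#' Compare division-angle samples between conditions
#'
#' Two-sample t-test (Welch by default) of division angles, e.g. wild type
#' vs mutant. Samples that are both constant are degenerate for the t
#' statistic; they return `p = 1` with a flag when the means agree and a
#' flagged `NA` otherwise.
#'
#' @param a,b Numeric vectors of division angles (degrees), each `n >= 2`.
#' @param var_equal Use the pooled-variance test instead of Welch.
#' @return A tibble: `statistic`, `df`, `p_value`, `mean_a`, `mean_b`,
#'   `n_a`, `n_b`, `degenerate`.
#' @export
compare_division_angles <- function(a, b, var_equal = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    same <- isTRUE(all.equal(mean(a), mean(b)))
    return(tibble::tibble(
      statistic = if (same) 0 else NA_real_, df = NA_real_,
      p_value = if (same) 1 else NA_real_,
      mean_a = mean(a), mean_b = mean(b),
      n_a = length(a), n_b = length(b), degenerate = TRUE
    ))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  tibble::tibble(
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b),
    n_a = length(a), n_b = length(b), degenerate = FALSE
  )
}
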