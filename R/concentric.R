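# Concentricity analysis: does an underlying circular structure organize
# the polarity axes? An ellipse is fitted to the cell centers, each cell is
# projected to its nearest boundary point, and the signed axial deviation
# between the cell's polarity axis and the local tangent is tested for
# uniformity. Tangent-aligned ("concentric") fields give a deviation
# distribution peaked at 0; randomly oriented fields give a uniform one.

#' Ellipse model
#'
#' @param cx,cy Center, pixels.
#' @param a,b Semi-major and semi-minor axis lengths (`a >= b > 0`).
#' @param theta Axial rotation of the major axis, degrees in (-90, 90].
#' @return A list of class `nm_ellipse` with fields `cx`, `cy`, `a`, `b`,
#'   `theta`, and `near_circular` flag (axis ratio below 1.05, where `theta`
#'   is ill-conditioned).
#' @export
ellipse_model <- function(cx, cy, a, b, theta = 0) {
  stopifnot(is.finite(cx), is.finite(cy), a > 0, b > 0)
  if (b > a) {
    tmp <- a; a <- b; b <- tmp
    theta <- theta + 90
  }
  structure(
    list(cx = cx, cy = cy, a = a, b = b, theta = wrap_axial(theta),
         near_circular = a / b < 1.05),
    class = "nm_ellipse"
  )
}

#' @export
print.nm_ellipse <- function(x, ...) {
  cat(sprintf(
    "Ellipse: center (%.3f, %.3f), semi-axes a = %.3f, b = %.3f, theta = %.2f deg%s\n",
    x$cx, x$cy, x$a, x$b, x$theta,
    if (x$near_circular) " [near-circular: theta ill-conditioned]" else ""
  ))
  invisible(x)
}

#' @export
tidy.nm_ellipse <- function(x, ...) {
  tibble::tibble(cx = x$cx, cy = x$cy, a = x$a, b = x$b, theta = x$theta,
                 near_circular = x$near_circular)
}

#' Points on an ellipse boundary
#'
#' @param ellipse An [ellipse_model()].
#' @param t Boundary parameter(s), radians.
#' @return A matrix with columns `x`, `y` (lab frame).
#' @export
ellipse_point <- function(ellipse, t) {
  xy <- cbind(ellipse$a * cos(t), ellipse$b * sin(t)) %*% t(rot2(ellipse$theta))
  cbind(x = xy[, 1] + ellipse$cx, y = xy[, 2] + ellipse$cy)
}

#' Least-squares ellipse fit via principal component analysis
#'
#' Fits an ellipse to scattered points: the center is the centroid, the
#' rotation is the first principal axis of the centered coordinates, and the
#' semi-axes are sqrt(2) times the standard deviations along the two
#' principal axes — exact when points sample the boundary uniformly in
#' parameter, since var(a cos t) = a^2 / 2.
#'
#' @param points A data frame / tibble with columns `x`, `y`, or a 2-column
#'   matrix. At least 3 non-collinear points.
#' @return An [ellipse_model()].
#' @export
fit_ellipse_pca <- function(points) {
  if (is.data.frame(points)) points <- cbind(points$x, points$y)
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("need at least 3 points", call. = FALSE)
  ctr <- colMeans(points)
  centered <- sweep(points, 2, ctr)
  cov_n <- crossprod(centered) / nrow(points)
  eig <- eigen(cov_n, symmetric = TRUE)
  if (eig$values[2] <= 1e-12 * max(eig$values[1], 1)) {
    stop("degenerate (collinear) point scatter: ellipse fit failed",
         call. = FALSE)
  }
  theta <- wrap_axial(atan2(eig$vectors[2, 1], eig$vectors[1, 1]) * 180 / pi)
  ellipse_model(ctr[1], ctr[2], sqrt(2 * eig$values[1]),
                sqrt(2 * eig$values[2]), theta)
}

#' Nearest point on an ellipse boundary
#'
#' Finds the boundary point minimizing the Euclidean distance to `p` by a
#' coarse scan over the boundary parameter (720 points) followed by bounded
#' golden-section/parabolic refinement on the bracketing interval. The grid
#' stage guards the known instability of Newton iterations near the ellipse
#' evolute; the refinement brings the distance within 1e-6 a of the true
#' minimum.
#'
#' @param ellipse An [ellipse_model()].
#' @param p Length-2 numeric `(x, y)`.
#' @param n_grid Coarse grid size (default 720).
#' @return A list: `point` (x, y on the boundary), `t` (parameter,
#'   radians), `distance`, and `degenerate` flag (`p` at the exact center,
#'   where every direction ties; the major-axis vertex is returned by
#'   convention).
#' @export
nearest_point_on_ellipse <- function(ellipse, p, n_grid = 720) {
  stopifnot(length(p) == 2, all(is.finite(p)))
  # work in the ellipse frame
  q <- drop(t(rot2(-ellipse$theta) %*% (p - c(ellipse$cx, ellipse$cy))))
  degenerate <- sqrt(sum(q^2)) < 1e-12 * ellipse$a
  if (degenerate) {
    # documented convention: the major-axis vertex is returned when p sits
    # exactly at the center (for a circle all boundary points tie)
    t_star <- 0
  } else {
    dist2 <- function(t) {
      (ellipse$a * cos(t) - q[1])^2 + (ellipse$b * sin(t) - q[2])^2
    }
    tg <- seq(-pi, pi, length.out = n_grid + 1)[-1]
    i <- which.min(dist2(tg))
    span <- 2 * pi / n_grid
    opt <- stats::optimize(dist2, lower = tg[i] - span, upper = tg[i] + span,
                           tol = 1e-12)
    t_star <- opt$minimum
    # polish to machine precision: Newton on d'(t) = 0 (safe here, far from
    # the evolute thanks to the bracketing grid stage)
    a <- ellipse$a; b <- ellipse$b
    for (it in 1:5) {
      dcos <- a * cos(t_star) - q[1]
      dsin <- b * sin(t_star) - q[2]
      g1 <- -dcos * a * sin(t_star) + dsin * b * cos(t_star)
      g2 <- a^2 * sin(t_star)^2 - dcos * a * cos(t_star) +
        b^2 * cos(t_star)^2 - dsin * b * sin(t_star)
      if (!is.finite(g2) || g2 <= 0) break
      step <- g1 / g2
      if (abs(step) > span) break
      t_star <- t_star - step
      if (abs(step) < 1e-14) break
    }
  }
  pt <- ellipse_point(ellipse, t_star)
  list(
    point = c(x = unname(pt[1, "x"]), y = unname(pt[1, "y"])),
    t = t_star,
    distance = sqrt(sum((c(pt[1, 1], pt[1, 2]) - p)^2)),
    degenerate = degenerate
  )
}

#' Axial angle of the ellipse tangent at parameter t
#'
#' The tangent direction at parameter `t` is `(-a sin t, b cos t)` rotated
#' by the ellipse rotation; its axial (mod-180) angle is returned.
#'
#' @param ellipse An [ellipse_model()].
#' @param t Boundary parameter(s), radians.
#' @return Axial angle(s) in degrees, (-90, 90].
#' @export
tangent_axial_angle <- function(ellipse, t) {
  d <- cbind(-ellipse$a * sin(t), ellipse$b * cos(t)) %*% t(rot2(ellipse$theta))
  wrap_axial(atan2(d[, 2], d[, 1]) * 180 / pi)
}

#' Signed deviations of cell polarity axes from the nearest ellipse tangent
#'
#' Each cell is projected to the closest point on the ellipse boundary; the
#' deviation is the signed axial difference from the tangent there to the
#' cell's polarity axis (positive = anticlockwise). Deviations are
#' frame-free: rotating the whole field rotates tangents and axes alike.
#'
#' @param cells Tibble with `x`, `y`, `axial_angle_deg`.
#' @param ellipse An [ellipse_model()].
#' @return The input tibble with added columns `tangent_angle_deg`,
#'   `deviation_deg`, `boundary_t`, `boundary_distance`.
#' @export
tangent_deviations <- function(cells, ellipse) {
  stopifnot(nrow(cells) >= 1)
  proj <- purrr::map(seq_len(nrow(cells)), function(i) {
    nearest_point_on_ellipse(ellipse, c(cells$x[i], cells$y[i]))
  })
  t_star <- purrr::map_dbl(proj, "t")
  tangent <- tangent_axial_angle(ellipse, t_star)
  dplyr::mutate(
    cells,
    tangent_angle_deg = tangent,
    deviation_deg = axial_difference(tangent, cells$axial_angle_deg),
    boundary_t = t_star,
    boundary_distance = purrr::map_dbl(proj, "distance")
  )
}

#' Nearest-neighbor polarity alignment
#'
#' For each cell, the Euclidean nearest other cell and the signed axial
#' difference between their polarity axes. Coordinate ties are broken by
#' the lower cell id.
#'
#' @param cells Tibble with `cell_id`, `x`, `y`, `axial_angle_deg`; at
#'   least 2 rows.
#' @return The input tibble with `neighbor_id`, `neighbor_distance`,
#'   `neighbor_angle_diff_deg` added.
#' @export
nearest_neighbor_alignment <- function(cells) {
  n <- nrow(cells)
  stopifnot(n >= 2)
  d <- as.matrix(stats::dist(cbind(cells$x, cells$y)))
  diag(d) <- Inf
  nn <- apply(d, 1, which.min)  # which.min returns first = lowest index tie
  dplyr::mutate(
    cells,
    neighbor_id = cells$cell_id[nn],
    neighbor_distance = d[cbind(seq_len(n), nn)],
    neighbor_angle_diff_deg = axial_difference(cells$axial_angle_deg,
                                               cells$axial_angle_deg[nn])
  )
}

#' Concentricity test of an orientation field
#'
#' The headline pipeline: fit an ellipse to the cell centers, compute each
#' cell's signed tangent deviation, bin the deviations into 12 axial bins,
#' test the histogram against uniformity (chi-square, default alpha 0.01),
#' and fit an axial von Mises distribution to describe the preferred
#' deviation and its spread. The field is labelled `"Concentric"` when the
#' uniformity test is significant.
#'
#' @param cells Tibble with `x`, `y`, `axial_angle_deg` (and optionally
#'   `cell_id`).
#' @param alpha Significance threshold for the uniformity test.
#' @param n_bins Histogram bins over (-90, 90].
#' @param ellipse Optional pre-fitted [ellipse_model()] (e.g. fitted to a
#'   separate reference cell set); default fits to the scored cells' own
#'   centers.
#' @param strict_mu If `TRUE`, additionally require the fitted |mu| < 30
#'   degrees for the `"Concentric"` label (a strongly radial field is also
#'   non-uniform). Off by default.
#' @return A list of class `nm_concentricity`: `ellipse`, `cells` (with
#'   deviations), `histogram`, `uniform_test`, `vm_fit`, `label`, `low_n`.
#' @export
concentricity_test <- function(cells, alpha = 0.01, n_bins = 12,
                               ellipse = NULL, strict_mu = FALSE) {
  stopifnot(nrow(cells) >= 1)
  low_n <- nrow(cells) < 5
  if (is.null(ellipse)) ellipse <- fit_ellipse_pca(cells)
  scored <- tangent_deviations(cells, ellipse)
  hist <- bin_axial(scored$deviation_deg, n_bins)
  ut <- chisq_uniform_test(hist, alpha)
  vm <- fit_von_mises_axial(scored$deviation_deg)
  concentric <- ut$significant && (!strict_mu || abs(vm$mu) < 30)
  structure(
    list(
      ellipse = ellipse, cells = scored, histogram = hist,
      uniform_test = ut, vm_fit = vm,
      label = if (concentric) "Concentric" else "NotConcentric",
      low_n = low_n, alpha = alpha
    ),
    class = "nm_concentricity"
  )
}

#' @export
print.nm_concentricity <- function(x, ...) {
  cat(sprintf("Concentricity analysis of %d cells: %s\n",
              nrow(x$cells), x$label))
  print(x$ellipse)
  print(x$uniform_test)
  print(x$vm_fit)
  if (x$low_n) cat("  warning: fewer than 5 cells; label unreliable\n")
  invisible(x)
}

#' @export
tidy.nm_concentricity <- function(x, ...) {
  x$cells
}

#' @export
glance.nm_concentricity <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$cells),
    label = x$label,
    p_value = x$uniform_test$p_value,
    statistic = x$uniform_test$statistic,
    df = x$uniform_test$df,
    mu = x$vm_fit$mu,
    kappa = x$vm_fit$kappa,
    mean_resultant_length = x$vm_fit$mean_resultant_length,
    ellipse_a = x$ellipse$a,
    ellipse_b = x$ellipse$b,
    ellipse_theta = x$ellipse$theta,
    low_n = x$low_n
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a concentricity result
#'
#' Left: the cell field with polarity axes and the fitted ellipse. Right:
#' the tangent-deviation histogram with the fitted axial von Mises density.
#'
#' @param object An `nm_concentricity` result.
#' @param ... Unused.
#' @return A ggplot object (patchwork-free two-panel via facets is avoided;
#'   the deviation histogram is returned, with the field plot available via
#'   [plot_field()]).
#' @export
autoplot.nm_concentricity <- function(object, ...) {
  h <- tidy(object$histogram)
  dens <- tibble::tibble(
    angle = seq(-90, 90, by = 1),
    density = dvonmises_axial(seq(-90, 90, by = 1), object$vm_fit$mu,
                              object$vm_fit$kappa) * 180 / length(h$count)
  )
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_mid, y = .data$probability)) +
    ggplot2::geom_col(width = 180 / nrow(h), fill = "grey70",
                      colour = "grey30") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(x = .data$angle, y = .data$density),
                       colour = "red") +
    ggplot2::labs(
      x = "deviation from nearest ellipse tangent (deg)",
      y = "probability",
      title = sprintf("%s (p = %.3g)", object$label,
                      object$uniform_test$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an orientation field with its fitted ellipse
#'
#' @param cells Tibble with `x`, `y`, `axial_angle_deg`.
#' @param ellipse Optional [ellipse_model()]; fitted to the cells if absent.
#' @param axis_len Half-length of the plotted polarity segments, pixels.
#' @return A ggplot object.
#' @export
plot_field <- function(cells, ellipse = NULL, axis_len = 3) {
  if (is.null(ellipse)) ellipse <- fit_ellipse_pca(cells)
  tgrid <- seq(-pi, pi, length.out = 361)
  ering <- tibble::as_tibble(ellipse_point(ellipse, tgrid))
  segs <- dplyr::mutate(
    cells,
    x0 = .data$x - axis_len * cos(.data$axial_angle_deg * pi / 180),
    x1 = .data$x + axis_len * cos(.data$axial_angle_deg * pi / 180),
    y0 = .data$y - axis_len * sin(.data$axial_angle_deg * pi / 180),
    y1 = .data$y + axis_len * sin(.data$axial_angle_deg * pi / 180)
  )
  ggplot2::ggplot(segs, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = ering, ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "steelblue") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1),
                          colour = "goldenrod3") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}
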