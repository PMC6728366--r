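#' Wrap an angle to the axial range (-90, 90]
#'
#' Orientations without direction (a cell's polarity axis, an ellipse tangent)
#' are defined modulo 180 degrees. The package reports them on the half-open
#' interval (-90, 90], measured anticlockwise from the +x (anterior-posterior)
#' axis in a y-up frame, so that the boundary angle -90 maps to +90.
#'
#' @param angle Numeric vector of angles in degrees.
#' @return Numeric vector of the same length in (-90, 90].
#' @examples
#' wrap_axial(c(100, -90, 45, 270))
#' @export
wrap_axial <- function(angle) {
  if (!is.numeric(angle) || any(!is.finite(angle))) {
    stop("`angle` must be finite numeric", call. = FALSE)
  }
  m <- angle %% 180
  ifelse(m > 90, m - 180, m)
}

#' Wrap an angle to the directional range (-180, 180]
#'
#' @param angle Numeric vector of angles in degrees.
#' @return Numeric vector in (-180, 180].
#' @export
wrap_directional <- function(angle) {
  if (!is.numeric(angle) || any(!is.finite(angle))) {
    stop("`angle` must be finite numeric", call. = FALSE)
  }
  m <- angle %% 360
  ifelse(m > 180, m - 360, m)
}

#' Signed axial difference between two orientations
#'
#' The smallest angle between two axes, positive when `to_angle` is reached
#' from `from_angle` by an anticlockwise rotation. A 90-degree separation is
#' a tie between the two turning senses; the half-open convention breaks it
#' to +90.
#'
#' @param from_angle,to_angle Axial angles in degrees (vectors recycle).
#' @return Signed degrees in (-90, 90].
#' @examples
#' axial_difference(10, 80)   #  70
#' axial_difference(80, 10)   # -70
#' @export
axial_difference <- function(from_angle, to_angle) {
  wrap_axial(to_angle - from_angle)
}

#' Bin axial angles into an equal-width histogram over (-90, 90]
#'
#' Bins are left-open, right-closed, so an input of exactly -90 (wrapped to
#' +90 on entry) lands in the last bin. Counts are normalised to
#' probabilities when the sample is non-empty.
#'
#' @param angles Numeric vector of angles in degrees (wrapped axially).
#' @param n_bins Number of bins (default 12, i.e. 15-degree bins).
#' @return A list of class `nm_angle_histogram` with `bin_edges` (length
#'   `n_bins + 1`), `counts`, `probabilities`, `n`, and `empty` flag.
#' @export
bin_axial <- function(angles, n_bins = 12) {
  stopifnot(n_bins >= 2)
  a <- wrap_axial(angles[is.finite(angles)])
  edges <- seq(-90, 90, length.out = n_bins + 1)
  width <- 180 / n_bins
  if (length(a) == 0) {
    counts <- integer(n_bins)
  } else {
    idx <- pmin(pmax(ceiling((a + 90) / width), 1L), n_bins)
    counts <- tabulate(idx, nbins = n_bins)
  }
  n <- sum(counts)
  structure(
    list(
      bin_edges = edges,
      counts = counts,
      probabilities = if (n > 0) counts / n else rep(NA_real_, n_bins),
      n = n,
      empty = n == 0
    ),
    class = "nm_angle_histogram"
  )
}

#' Chi-square goodness-of-fit test of a binned angle histogram against
#' uniformity
#'
#' Tests the null hypothesis that angles have no preferred direction by
#' comparing the observed bin counts with the uniform expectation n/k. The
#' upper-tail p-value comes from the chi-square distribution with k - 1
#' degrees of freedom. A field is called significantly non-uniform at
#' `alpha` (default 0.01).
#'
#' @param hist An `nm_angle_histogram` (from [bin_axial()]) or a bare vector
#'   of bin counts.
#' @param alpha Significance threshold (default 0.01).
#' @return A list of class `nm_uniformity_test`: `statistic`, `df`,
#'   `p_value`, `n`, `significant`, `alpha`, and `low_expected` warning flag
#'   when any expected count is below 1.
#' @export
chisq_uniform_test <- function(hist, alpha = 0.01) {
  counts <- if (inherits(hist, "nm_angle_histogram")) hist$counts else hist
  stopifnot(is.numeric(counts), all(counts >= 0))
  n <- sum(counts)
  if (n <= 0) stop("total count must be positive", call. = FALSE)
  k <- length(counts)
  expected <- n / k
  statistic <- sum((counts - expected)^2 / expected)
  df <- k - 1L
  p <- stats::pchisq(statistic, df = df, lower.tail = FALSE)
  structure(
    list(
      statistic = statistic, df = df, p_value = p, n = n,
      significant = p < alpha, alpha = alpha,
      low_expected = expected < 1
    ),
    class = "nm_uniformity_test"
  )
}

# A1(kappa) = I1(kappa)/I0(kappa), the mean resultant length of a von Mises
# distribution; exponentially scaled Bessel ratio is stable for large kappa.
vm_a1 <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

# Maximum-likelihood inversion kappa = A1^{-1}(rbar): Best & Fisher series
# start, then Newton refinement on A1 (A1'(k) = 1 - A1/k - A1^2).
vm_a1inv <- function(rbar, kappa_max = 1000) {
  if (rbar <= 0) return(0)
  if (rbar >= vm_a1(kappa_max)) return(kappa_max)
  k <- if (rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  }
  for (i in 1:25) {
    a <- vm_a1(k)
    deriv <- 1 - a / k - a^2
    if (!is.finite(deriv) || deriv <= 0) break
    step <- (a - rbar) / deriv
    k <- k - step
    if (k <= 0) k <- 1e-8
    if (abs(step) < 1e-12 * max(1, k)) break
  }
  min(k, kappa_max)
}

#' Fit an axial von Mises distribution
#'
#' Axial angles are doubled (and wrapped to (-180, 180]) so that an
#' orientation distribution becomes an ordinary directional one; the mean
#' direction and mean resultant length are computed on the doubled angles,
#' the concentration kappa is recovered by the standard maximum-likelihood
#' inversion of the Bessel ratio A1, and the axial mean mu is half the
#' doubled mean direction. With this convention kappa has its usual von
#' Mises meaning on the doubled scale.
#'
#' @param angles Axial angles in degrees; at least 2 finite values.
#' @param kappa_max Cap for the concentration (default 1000); fully
#'   concentrated samples (mean resultant length near 1) return the cap with
#'   `capped = TRUE`.
#' @return A list of class `nm_vm_fit`: `mu` (degrees, axial), `kappa`,
#'   `mean_resultant_length`, `n`, `capped`.
#' @export
fit_von_mises_axial <- function(angles, kappa_max = 1000) {
  a <- angles[is.finite(angles)]
  if (length(a) < 2) stop("need at least 2 angles", call. = FALSE)
  doubled <- wrap_directional(2 * wrap_axial(a)) * pi / 180
  cbar <- mean(cos(doubled))
  sbar <- mean(sin(doubled))
  rbar <- sqrt(cbar^2 + sbar^2)
  mean_dir <- atan2(sbar, cbar) * 180 / pi
  mu <- wrap_axial(mean_dir / 2)
  kappa <- vm_a1inv(rbar, kappa_max)
  structure(
    list(
      mu = mu, kappa = kappa, mean_resultant_length = rbar,
      n = length(a), capped = kappa >= kappa_max
    ),
    class = "nm_vm_fit"
  )
}

# Axial von Mises density (per degree) on (-90, 90]: the doubled-angle von
# Mises pushed back to the axial scale; integrates to 1 over 180 degrees.
dvonmises_axial <- function(theta, mu, kappa) {
  phi <- wrap_directional(2 * (theta - mu)) * pi / 180
  exp(kappa * (cos(phi) - 1)) / (180 * besselI(kappa, 0, expon.scaled = TRUE))
}

# Quadrant of a directional angle. Boundaries are half-open with ties
# broken to the anticlockwise bin, so exactly 45 degrees counts as "up":
# right [-45, 45), up [45, 135), left [135, 180] U (-180, -135), down
# [-135, -45).
angle_quadrant <- function(dir_angles) {
  d <- wrap_directional(dir_angles)
  dplyr::case_when(
    d >= -45 & d < 45 ~ "right",
    d >= 45 & d < 135 ~ "up",
    d >= 135 | d < -135 ~ "left",
    TRUE ~ "down"
  )
}

#' Binomial test of anterior-posterior vs dorso-ventral axis preference
#'
#' Directional kinocilium angles are binned into four quadrants (right, up,
#' left, down; half-open anticlockwise boundaries, so exactly 45 degrees
#' counts as "up"). The exact two-sided binomial test asks whether the
#' right + left (A-P) count differs from 50% of the total.
#'
#' @param dir_angles Directional angles in degrees.
#' @return A list of class `nm_binomial_axis`: `counts` (named quadrant
#'   counts), `ap_count`, `n`, `p_value`.
#' @export
binomial_axis_test <- function(dir_angles) {
  d <- dir_angles[is.finite(dir_angles)]
  if (length(d) < 1) stop("need at least 1 angle", call. = FALSE)
  q <- factor(angle_quadrant(d), levels = c("right", "up", "left", "down"))
  counts <- table(q)
  ap <- sum(counts[c("right", "left")])
  p <- stats::binom.test(ap, length(d), p = 0.5)$p.value
  structure(
    list(
      counts = as.integer(counts), quadrant = names(counts),
      ap_count = as.integer(ap), n = length(d), p_value = p
    ),
    class = "nm_binomial_axis"
  )
}

#' Fisher's exact comparison of axis preference between two samples
#'
#' Each sample of directional angles is collapsed to an (A-P, D-V) pair of
#' counts via the quadrants of [binomial_axis_test()], and the resulting 2x2
#' table is tested with the two-sided Fisher's exact test (hypergeometric
#' enumeration). A table with a zero margin carries no information; it
#' returns p = 1 with `degenerate = TRUE`.
#'
#' @param angles_a,angles_b Directional angle vectors (degrees), non-empty.
#' @param by_bin If `TRUE`, compare full rose-bin counts with a 2xk
#'   Freeman-Halton style exact test instead of the 2x2 axis table.
#' @param n_bins Bin count for `by_bin = TRUE`.
#' @return A list of class `nm_fisher_axis`: `table` (2x2 or 2xk matrix),
#'   `p_value`, `degenerate`.
#' @export
fisher_axis_comparison <- function(angles_a, angles_b, by_bin = FALSE,
                                   n_bins = 12) {
  stopifnot(length(angles_a) >= 1, length(angles_b) >= 1)
  if (by_bin) {
    tab <- rbind(
      a = rose_counts(angles_a, n_bins)$count,
      b = rose_counts(angles_b, n_bins)$count
    )
  } else {
    axis_counts <- function(x) {
      q <- angle_quadrant(x)
      c(ap = sum(q %in% c("right", "left")), dv = sum(q %in% c("up", "down")))
    }
    tab <- rbind(a = axis_counts(angles_a), b = axis_counts(angles_b))
  }
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  p <- if (degenerate) 1 else stats::fisher.test(tab)$p.value
  structure(
    list(table = tab, p_value = p, degenerate = degenerate),
    class = "nm_fisher_axis"
  )
}

#' @export
print.nm_uniformity_test <- function(x, ...) {
  cat(sprintf(
    "Chi-square uniformity test: X2 = %.4g, df = %d, p = %.4g (%s at alpha = %g)\n",
    x$statistic, x$df, x$p_value,
    if (x$significant) "non-uniform" else "uniform", x$alpha
  ))
  if (x$low_expected) cat("  warning: expected count < 1 per bin\n")
  invisible(x)
}

#' @export
print.nm_vm_fit <- function(x, ...) {
  cat(sprintf(
    "Axial von Mises fit: mu = %.2f deg, kappa = %.3g%s, Rbar = %.3f, n = %d\n",
    x$mu, x$kappa, if (x$capped) " (capped)" else "",
    x$mean_resultant_length, x$n
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.nm_angle_histogram <- function(x, ...) {
  nb <- length(x$counts)
  tibble::tibble(
    bin_low = x$bin_edges[-(nb + 1)],
    bin_high = x$bin_edges[-1],
    bin_mid = (x$bin_edges[-(nb + 1)] + x$bin_edges[-1]) / 2,
    count = x$counts,
    probability = x$probabilities
  )
}

#' @export
glance.nm_uniformity_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, df = x$df, p_value = x$p_value,
    n = x$n, significant = x$significant, alpha = x$alpha
  )
}

#' @export
glance.nm_vm_fit <- function(x, ...) {
  tibble::tibble(
    mu = x$mu, kappa = x$kappa,
    mean_resultant_length = x$mean_resultant_length,
    n = x$n, capped = x$capped
  )
}
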