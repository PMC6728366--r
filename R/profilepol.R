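# Cortical angular-intensity polarity: extract an intensity profile around
# a cell cortex, align profiles so the maximum sits at 0 degrees, average
# with SEM, fit a Gaussian peak with Monte Carlo parameter errors, and form
# polarity ratios (0 vs 90 and 0 vs 180 degrees) with propagated errors.

#' Angular intensity profile
#'
#' A profile samples intensity at uniformly spaced angular positions
#' covering (-180, 180] (for the default 1-degree grid this is the wrapped
#' support (-179, ..., +180]).
#'
#' @param angles Ordered angular grid, degrees; must be uniformly spaced.
#' @param intensity Intensity at each angle.
#' @param sem Optional per-angle standard error of the mean.
#' @param aligned Has the profile been shifted so the maximum sits at 0?
#' @param normalized Has the profile been scaled to a maximum of 1?
#' @return A tibble of class `nm_profile` with columns `angle_deg`,
#'   `intensity` (and `sem` if given); alignment state is carried in
#'   attributes `aligned` and `normalized`.
#' @export
angular_profile <- function(angles, intensity, sem = NULL,
                            aligned = FALSE, normalized = FALSE) {
  stopifnot(length(angles) == length(intensity), length(angles) >= 2)
  steps <- diff(angles)
  if (max(abs(steps - steps[1])) > 1e-6) {
    stop("angular grid must be uniform", call. = FALSE)
  }
  out <- tibble::tibble(angle_deg = angles, intensity = intensity)
  if (!is.null(sem)) {
    stopifnot(length(sem) == length(angles), all(sem >= 0))
    out$sem <- sem
  }
  structure(out, aligned = aligned, normalized = normalized,
            class = c("nm_profile", class(out)))
}

profile_attrs <- function(p) {
  list(aligned = isTRUE(attr(p, "aligned")),
       normalized = isTRUE(attr(p, "normalized")))
}

# Bilinear interpolation of an image (matrix) at (x, y) in the y-up frame:
# pixel (row r, col c) has x = c, y = nrow + 1 - r.
interp_bilinear <- function(img, x, y) {
  h <- nrow(img)
  r <- h + 1 - y
  c0 <- pmin(pmax(floor(x), 1), ncol(img) - 1)
  r0 <- pmin(pmax(floor(r), 1), h - 1)
  fx <- pmin(pmax(x - c0, 0), 1)
  fr <- pmin(pmax(r - r0, 0), 1)
  i00 <- img[cbind(r0, c0)]
  i01 <- img[cbind(r0, c0 + 1)]
  i10 <- img[cbind(r0 + 1, c0)]
  i11 <- img[cbind(r0 + 1, c0 + 1)]
  (1 - fr) * ((1 - fx) * i00 + fx * i01) + fr * ((1 - fx) * i10 + fx * i11)
}

#' Extract a cortical intensity profile along a contour
#'
#' Averages image intensity over a band of the given thickness normal to a
#' closed contour (the cuticular-plate circumference), parameterizes each
#' contour vertex by its angle about the contour centroid, and resamples to
#' a uniform angular grid by circular linear interpolation.
#'
#' @param image Numeric matrix (intensity image); pixel `(r, c)` maps to
#'   `(x = c, y = nrow + 1 - r)`.
#' @param contour Data frame or 2-column matrix of contour vertices
#'   (`x`, `y`), closed implicitly; at least 8 vertices.
#' @param thickness Band thickness in pixels (default 4).
#' @param n_samples Angular samples of the output grid (default 360).
#' @return An [angular_profile()].
#' @export
extract_profile <- function(image, contour, thickness = 4, n_samples = 360) {
  if (is.data.frame(contour)) contour <- cbind(contour$x, contour$y)
  stopifnot(nrow(contour) >= 8, thickness >= 1)
  cx <- mean(contour[, 1]); cy <- mean(contour[, 2])
  margin <- thickness / 2 + 1
  if (any(contour[, 1] < 1 + margin | contour[, 1] > ncol(image) - margin |
          contour[, 2] < 1 + margin | contour[, 2] > nrow(image) - margin)) {
    stop("contour touches the image border", call. = FALSE)
  }
  ang <- atan2(contour[, 2] - cy, contour[, 1] - cx) * 180 / pi
  # outward normal approximated by the radial direction about the centroid
  offs <- seq(-(thickness - 1) / 2, (thickness - 1) / 2, length.out = thickness)
  vals <- vapply(seq_len(nrow(contour)), function(i) {
    nx <- cos(ang[i] * pi / 180); ny <- sin(ang[i] * pi / 180)
    mean(interp_bilinear(image, contour[i, 1] + offs * nx,
                         contour[i, 2] + offs * ny))
  }, numeric(1))
  ord <- order(ang)
  ang_s <- ang[ord]; val_s <- vals[ord]
  # circular linear interpolation onto the uniform grid
  step <- 360 / n_samples
  grid <- seq(-180 + step, 180, by = step)
  ang_ext <- c(ang_s[length(ang_s)] - 360, ang_s, ang_s[1] + 360)
  val_ext <- c(val_s[length(val_s)], val_s, val_s[1])
  intensity <- stats::approx(ang_ext, val_ext, xout = grid, ties = mean)$y
  angular_profile(grid, intensity)
}

#' Align a profile so its maximum sits at 0 degrees and wrap to (-179, 180]
#'
#' Circularly shifts the intensity values so the maximum lands on the grid
#' point at 0 degrees (the grid point nearest 0 for odd grids). The
#' intensity multiset is preserved; the operation is idempotent. Multiple
#' equal maxima are resolved to the first in scan order and flagged.
#'
#' @param profile An [angular_profile()].
#' @return The aligned profile (`aligned` attribute set; attribute
#'   `max_ties = TRUE` when the maximum was not unique).
#' @export
align_and_wrap <- function(profile) {
  stopifnot(nrow(profile) >= 1)
  v <- profile$intensity
  ties <- sum(v == max(v)) > 1
  i_max <- which.max(v)
  i_zero <- which.min(abs(profile$angle_deg))
  shift <- (i_max - i_zero) %% length(v)
  v2 <- if (shift == 0) v else c(v[(shift + 1):length(v)], v[1:shift])
  s2 <- if (!is.null(profile[["sem"]])) {
    if (shift == 0) profile$sem else
      c(profile[["sem"]][(shift + 1):length(v)], profile[["sem"]][1:shift])
  } else NULL
  out <- angular_profile(profile$angle_deg, v2, sem = s2, aligned = TRUE,
                         normalized = profile_attrs(profile)$normalized)
  attr(out, "max_ties") <- ties
  out
}

#' Average aligned profiles pointwise with standard errors
#'
#' @param profiles List of aligned [angular_profile()]s on identical grids
#'   (>= 2).
#' @return An [angular_profile()] with `sem` = pointwise standard error of
#'   the mean.
#' @export
average_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 2)
  grid <- profiles[[1]]$angle_deg
  for (p in profiles) {
    if (!isTRUE(all.equal(p$angle_deg, grid))) {
      stop("profiles must share one angular grid", call. = FALSE)
    }
  }
  m <- vapply(profiles, function(p) p$intensity,
              numeric(length(grid)))
  mean_i <- rowMeans(m)
  sem <- apply(m, 1, stats::sd) / sqrt(ncol(m))
  angular_profile(grid, mean_i, sem = sem,
                  aligned = all(vapply(profiles,
                                       function(p) profile_attrs(p)$aligned,
                                       logical(1))))
}

#' Normalize a profile to a maximum intensity of 1
#'
#' @param profile An [angular_profile()].
#' @return The scaled profile (`normalized` attribute set); `sem`, if
#'   present, is scaled by the same factor.
#' @export
normalize_max1 <- function(profile) {
  mx <- max(profile$intensity)
  if (mx <= 0) stop("profile maximum must be positive", call. = FALSE)
  angular_profile(profile$angle_deg, profile$intensity / mx,
                  sem = if (!is.null(profile[["sem"]])) profile[["sem"]] / mx,
                  aligned = profile_attrs(profile)$aligned,
                  normalized = TRUE)
}

#' Fit a Gaussian peak to an aligned profile with Monte Carlo errors
#'
#' Fits `I(theta) = baseline + amplitude * exp(-theta^2 / (2 sigma^2))` by
#' nonlinear least squares (Levenberg-Marquardt), initialized from the
#' profile maximum, half-maximum width, and minimum. Parameter errors are
#' the standard deviations of the parameters over `n_mc` refits of
#' synthetic data sets formed by adding Gaussian noise at the residual
#' standard deviation to the fitted curve.
#'
#' @param profile An aligned [angular_profile()] with >= 8 points.
#' @param n_mc Monte Carlo replicates (default 100).
#' @param seed Seed for the Monte Carlo noise.
#' @param center_free If `TRUE` the peak center is a free parameter
#'   (useful for unaligned profiles); default fixes it at 0.
#' @return A list of class `nm_gauss_fit`: `amplitude`, `center`, `sigma`,
#'   `baseline`, `param_errors` (named vector), `rss`, `residual_sd`,
#'   `degenerate` flag (flat profile, sigma unidentifiable).
#' @export
fit_gaussian_peak <- function(profile, n_mc = 100, seed = 1,
                              center_free = FALSE) {
  stopifnot(nrow(profile) >= 8)
  th <- profile$angle_deg
  y <- profile$intensity
  amp0 <- max(y) - min(y)
  base0 <- min(y)
  if (amp0 <= 1e-12 * max(abs(y), 1) || amp0 == 0) {
    return(structure(
      list(amplitude = 0, center = 0, sigma = NA_real_,
           baseline = mean(y),
           param_errors = c(amplitude = NA_real_, center = NA_real_,
                            sigma = NA_real_, baseline = NA_real_),
           rss = sum((y - mean(y))^2),
           residual_sd = stats::sd(y), degenerate = TRUE),
      class = "nm_gauss_fit"
    ))
  }
  half <- base0 + amp0 / 2
  above <- abs(th[y >= half])
  sig0 <- max(stats::median(above), 5) / sqrt(2 * log(2))
  fit_once <- function(yy) {
    df <- data.frame(th = th, y = yy)
    if (center_free) {
      fit <- minpack.lm::nlsLM(
        y ~ b + A * exp(-(th - m)^2 / (2 * s^2)), data = df,
        start = list(A = amp0, m = th[which.max(yy)], s = sig0, b = base0),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
      cf <- stats::coef(fit)
      c(amplitude = unname(cf["A"]), center = unname(cf["m"]),
        sigma = abs(unname(cf["s"])), baseline = unname(cf["b"]))
    } else {
      fit <- minpack.lm::nlsLM(
        y ~ b + A * exp(-th^2 / (2 * s^2)), data = df,
        start = list(A = amp0, s = sig0, b = base0),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
      cf <- stats::coef(fit)
      c(amplitude = unname(cf["A"]), center = 0,
        sigma = abs(unname(cf["s"])), baseline = unname(cf["b"]))
    }
  }
  est <- fit_once(y)
  pred <- est["baseline"] +
    est["amplitude"] * exp(-(th - est["center"])^2 / (2 * est["sigma"]^2))
  resid <- y - pred
  rss <- sum(resid^2)
  res_sd <- sqrt(rss / max(length(y) - length(est), 1))
  boot <- withr::with_seed(seed, {
    vapply(seq_len(n_mc), function(i) {
      fit_once(pred + stats::rnorm(length(y), 0, res_sd))
    }, numeric(4))
  })
  structure(
    list(amplitude = unname(est["amplitude"]), center = unname(est["center"]),
         sigma = unname(est["sigma"]), baseline = unname(est["baseline"]),
         param_errors = apply(boot, 1, stats::sd),
         rss = rss, residual_sd = res_sd, degenerate = FALSE),
    class = "nm_gauss_fit"
  )
}

#' @export
print.nm_gauss_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("Gaussian peak fit: degenerate (flat profile; sigma unidentifiable)\n")
    return(invisible(x))
  }
  e <- x$param_errors
  cat(sprintf(
    "Gaussian peak fit: A = %.4g +/- %.2g, sigma = %.4g +/- %.2g deg, baseline = %.4g +/- %.2g (rss %.3g)\n",
    x$amplitude, e["amplitude"], x$sigma, e["sigma"], x$baseline,
    e["baseline"], x$rss
  ))
  invisible(x)
}

#' @export
tidy.nm_gauss_fit <- function(x, ...) {
  tibble::tibble(
    term = c("amplitude", "center", "sigma", "baseline"),
    estimate = c(x$amplitude, x$center, x$sigma, x$baseline),
    std.error = unname(x$param_errors)
  )
}

#' @export
glance.nm_gauss_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, residual_sd = x$residual_sd,
                 degenerate = x$degenerate)
}

# Mean and SE of the 3 grid values nearest an anchor angle, circularly.
anchor_mean <- function(profile, anchor) {
  d <- abs(wrap_directional(profile$angle_deg - anchor))
  idx <- order(d)[1:3]
  v <- profile$intensity[idx]
  se <- if (!is.null(profile[["sem"]])) {
    sqrt(sum(profile[["sem"]][idx]^2)) / 3
  } else {
    stats::sd(v) / sqrt(3)
  }
  c(mean = mean(v), se = se)
}

#' Polarity ratios of an aligned cortical profile
#'
#' Averages the three grid values surrounding the 0, 90 and 180 degree
#' positions of an aligned profile and forms the ratios 0/180 and 0/90,
#' with first-order error propagation
#' `sd(r)/r = sqrt((sd(a)/a)^2 + (sd(b)/b)^2)`.
#'
#' @param profile An aligned [angular_profile()]; per-angle `sem` is used
#'   for the anchor standard errors when present (otherwise the spread of
#'   the three values is used).
#' @return A tibble: `ratio` (`"0/180"`, `"0/90"`), `estimate`, `std_error`,
#'   plus the anchor means/errors as attributes.
#' @export
polarity_ratio <- function(profile) {
  if (!profile_attrs(profile)$aligned) {
    stop("profile must be aligned (see align_and_wrap())", call. = FALSE)
  }
  a0 <- anchor_mean(profile, 0)
  a90 <- anchor_mean(profile, 90)
  a180 <- anchor_mean(profile, 180)
  if (a90["mean"] == 0 || a180["mean"] == 0) {
    stop("zero denominator anchor mean", call. = FALSE)
  }
  ratio_se <- function(a, b) {
    r <- a["mean"] / b["mean"]
    unname(r * sqrt((a["se"] / a["mean"])^2 + (b["se"] / b["mean"])^2))
  }
  out <- tibble::tibble(
    ratio = c("0/180", "0/90"),
    estimate = c(unname(a0["mean"] / a180["mean"]),
                 unname(a0["mean"] / a90["mean"])),
    std_error = c(ratio_se(a0, a180), ratio_se(a0, a90))
  )
  attr(out, "anchors") <- rbind(`0` = a0, `90` = a90, `180` = a180)
  out
}

#' Plot an angular profile
#'
#' @param object An [angular_profile()].
#' @param ... Unused.
#' @return A ggplot object; SEM ribbon included when present.
#' @export
autoplot.nm_profile <- function(object, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$angle_deg, y = .data$intensity))
  if (!is.null(object[["sem"]])) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$intensity - .data$sem,
                   ymax = .data$intensity + .data$sem),
      fill = "grey80"
    )
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "angular position (deg)", y = "intensity") +
    ggplot2::theme_minimal()
}
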