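# Synthetic neuromasts: seeded generators reproducing the statistical
# structure the downstream analyses assume (elliptical rosette geometry,
# uniform / bimodal / tangent-aligned orientation fields, kinocilium pairs,
# elongated-cell label images, ring-shaped cortical intensity profiles,
# progenitor division events). None of this emulates microscopy optics; it
# gives every pipeline stage a ground truth.

# Derive a per-component substream seed from one global seed so that adding
# one generator call does not shift the draws of another. Kept below 2^31.
sub_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(as.numeric(seed)) * 69069 + h * 30269) %% 2147483629)
}

rot2 <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

# Best-Fisher (1979) rejection sampler for the von Mises distribution.
# Returns radians in (-pi, pi]; kappa = 0 falls back to the circular uniform.
rvonmises_rad <- function(n, mu = 0, kappa = 1) {
  if (n == 0) return(numeric(0))
  if (kappa < 1e-10) {
    return(stats::runif(n, -pi, pi))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(2 * (n - length(out)), 16L)
    u1 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(m)
    keep <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    u3 <- stats::runif(m)
    vals <- (sign(u3 - 0.5) * acos(pmin(pmax(f, -1), 1)))[keep]
    out <- c(out, vals)
  }
  theta <- out[seq_len(n)] + mu
  ifelse(theta > pi, theta - 2 * pi, ifelse(theta <= -pi, theta + 2 * pi, theta))
}

# Axial von Mises noise in degrees: sampled on doubled angles so kappa keeps
# its standard directional meaning, then halved back to the axial scale.
# kappa at or above the cap (or infinite) is the noiseless limit.
r_axial_noise <- function(n, kappa, kappa_max = 1000) {
  if (!is.finite(kappa) || kappa >= kappa_max) return(numeric(n))
  rvonmises_rad(n, 0, kappa) * 180 / pi / 2
}

#' Sample axial angles from a von Mises orientation distribution
#'
#' Draws on the doubled-angle circle (where `kappa` has its standard von
#' Mises meaning) and halves back to the axial scale, giving orientations
#' concentrated around `mu`.
#'
#' @param n Number of draws.
#' @param mu Axial mean, degrees.
#' @param kappa Concentration (>= 0; 0 = uniform).
#' @param seed Optional integer seed.
#' @return Axial angles in degrees, (-90, 90].
#' @export
r_axial_vonmises <- function(n, mu = 0, kappa = 1, seed = NULL) {
  draw <- function() wrap_axial(mu + rvonmises_rad(n, 0, kappa) * 90 / pi)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Configuration for a synthetic orientation field
#'
#' @param n_cells Number of hair cells (>= 1). Real neuromasts carry roughly
#'   15-40.
#' @param ellipse Organ geometry, an [ellipse_model()] (pixel units).
#' @param radial_jitter Band thickness as a fraction of the boundary radius,
#'   in `[0, 1)`: cells sit uniformly between `(1 - radial_jitter)` and 1
#'   times the boundary.
#' @param orientation_model One of `"uniform"` (random axial angles, the
#'   PCP-mutant-like phenotype), `"axial_bimodal"` (directional angles along
#'   a body axis, the wild-type phenotype), or `"concentric"` (axes aligned
#'   with the local ellipse tangent, the Wnt-mutant-like phenotype).
#' @param axis_angle Axis for the bimodal model, degrees (0 = A-P, 90 = D-V).
#' @param kappa Von Mises concentration of the orientation noise (>= 0);
#'   values at or above 1000 (or `Inf`) mean no noise.
#' @param seed Integer seed; identical config + seed gives identical fields.
#' @return A validated list of class `nm_field_config`.
#' @export
field_config <- function(n_cells = 30,
                         ellipse = ellipse_model(0, 0, 25, 18, 0),
                         radial_jitter = 0.15,
                         orientation_model = c("uniform", "axial_bimodal",
                                               "concentric"),
                         axis_angle = 0, kappa = 4, seed = 1) {
  orientation_model <- match.arg(orientation_model)
  stopifnot(n_cells >= 1, kappa >= 0,
            radial_jitter >= 0, radial_jitter < 1)
  structure(
    list(n_cells = as.integer(n_cells), ellipse = ellipse,
         radial_jitter = radial_jitter,
         orientation_model = orientation_model,
         axis_angle = axis_angle, kappa = kappa, seed = as.integer(seed)),
    class = "nm_field_config"
  )
}

#' Simulate a neuromast orientation field
#'
#' Places `n_cells` cell centers uniformly in ellipse parameter on a boundary
#' band of the configured organ ellipse (rosette geometry), then draws each
#' cell's axial polarity angle from the configured orientation model:
#' uniform on (-90, 90], bimodal along a body axis, or aligned with the
#' local tangent plus axial von Mises noise of concentration `kappa`.
#'
#' @param config An [field_config()].
#' @return A tibble of cell records: `cell_id`, `x`, `y`, `axial_angle_deg`,
#'   `dir_angle_deg` (populated for the bimodal model, `NA` otherwise),
#'   `cell_class`. The generating config is attached as attribute `config`.
#' @examples
#' cells <- simulate_field(field_config(orientation_model = "concentric",
#'                                      kappa = 8, seed = 42))
#' @export
simulate_field <- function(config) {
  stopifnot(inherits(config, "nm_field_config"))
  e <- config$ellipse
  n <- config$n_cells
  withr::with_seed(config$seed, {
    t <- stats::runif(n, -pi, pi)
    s <- 1 - config$radial_jitter * stats::runif(n)
    xy <- cbind(s * e$a * cos(t), s * e$b * sin(t)) %*% t(rot2(e$theta))
    x <- xy[, 1] + e$cx
    y <- xy[, 2] + e$cy
    dir_angle <- rep(NA_real_, n)
    axial <- switch(
      config$orientation_model,
      uniform = {
        u <- stats::runif(n, -90, 90)
        wrap_axial(ifelse(u == -90, 90, u))
      },
      axial_bimodal = {
        flip <- stats::rbinom(n, 1, 0.5) * 180
        noise <- if (!is.finite(config$kappa) || config$kappa >= 1000) {
          numeric(n)
        } else {
          rvonmises_rad(n, 0, config$kappa) * 180 / pi
        }
        dir_angle <- wrap_directional(config$axis_angle + flip + noise)
        wrap_axial(dir_angle)
      },
      concentric = {
        tangent <- tangent_axial_angle(e, t)
        wrap_axial(tangent + r_axial_noise(n, config$kappa))
      }
    )
    out <- tibble::tibble(
      cell_id = seq_len(n), x = x, y = y,
      axial_angle_deg = axial, dir_angle_deg = dir_angle,
      cell_class = "hair"
    )
  })
  attr(out, "config") <- config
  out
}

#' Simulate hair-cell pairs with kinocilia pointing toward each other
#'
#' Hair cells arise in pairs from a common progenitor, with the kinocilium
#' of each daughter pointing toward its sister. Each simulated pair sits on
#' a random inter-cell axis; the first cell always points toward the second
#' (plus Gaussian angular noise), and with probability `opposition_prob` the
#' second points back, otherwise its direction is uniform-random.
#'
#' @param n_pairs Number of pairs (>= 0).
#' @param opposition_prob Probability the second cell opposes, in `[0, 1]`.
#' @param angle_noise_sd Gaussian SD of the pointing noise, degrees.
#' @param seed Integer seed.
#' @return A tibble with one row per cell: `pair_id`, `member` (1 or 2),
#'   `cell_id`, `x`, `y`, `dir_angle_deg`, `axial_angle_deg`, `cell_class`.
#' @export
simulate_pairs <- function(n_pairs, opposition_prob = 1,
                           angle_noise_sd = 0, seed = 1) {
  stopifnot(n_pairs >= 0, opposition_prob >= 0, opposition_prob <= 1,
            angle_noise_sd >= 0)
  if (n_pairs == 0) {
    return(tibble::tibble(
      pair_id = integer(), member = integer(), cell_id = integer(),
      x = numeric(), y = numeric(), dir_angle_deg = numeric(),
      axial_angle_deg = numeric(), cell_class = character()
    ))
  }
  withr::with_seed(seed, {
    phi <- stats::runif(n_pairs, -180, 180)
    sep <- 4
    cx <- (seq_len(n_pairs) - 1) %% 10 * 15
    cy <- (seq_len(n_pairs) - 1) %/% 10 * 15
    opposed <- stats::runif(n_pairs) < opposition_prob
    d1 <- wrap_directional(phi + stats::rnorm(n_pairs, 0, angle_noise_sd))
    d2 <- ifelse(
      opposed,
      wrap_directional(phi + 180 + stats::rnorm(n_pairs, 0, angle_noise_sd)),
      stats::runif(n_pairs, -180, 180)
    )
    d2 <- wrap_directional(ifelse(d2 == -180, 180, d2))
  })
  ux <- cos(phi * pi / 180)
  uy <- sin(phi * pi / 180)
  tibble::tibble(
    pair_id = rep(seq_len(n_pairs), each = 2),
    member = rep(1:2, n_pairs),
    cell_id = seq_len(2 * n_pairs),
    x = as.vector(rbind(cx - sep / 2 * ux, cx + sep / 2 * ux)),
    y = as.vector(rbind(cy - sep / 2 * uy, cy + sep / 2 * uy)),
    dir_angle_deg = as.vector(rbind(d1, d2)),
    axial_angle_deg = wrap_axial(as.vector(rbind(d1, d2))),
    cell_class = "hair"
  )
}

#' Render cells as an elongated-cell label image
#'
#' Draws one filled elliptical region per cell into an integer label image
#' (background 0), with the region's major axis along the cell's axial
#' polarity angle. Pixel `(row r, col c)` maps to `(x = c, y = nrow + 1 - r)`
#' so angles stay anticlockwise-positive on the mathematical (y-up) frame.
#' Overlapping placements are retried with small positional jitter.
#'
#' @param cells Tibble with `x`, `y`, `axial_angle_deg` (e.g. from
#'   [simulate_field()]).
#' @param shape `(height, width)` of the image in pixels.
#' @param cell_axes `(major, minor)` semi-axis lengths of each cell, pixels.
#' @param max_retries Placement retries per cell before failing.
#' @param seed Seed for the retry jitter.
#' @return Integer matrix (`height` x `width`) of labels; cell `i` has label
#'   `i`.
#' @export
simulate_label_image <- function(cells, shape = c(128, 128),
                                 cell_axes = c(8, 3), max_retries = 25,
                                 seed = 1) {
  h <- shape[1]; w <- shape[2]
  img <- matrix(0L, h, w)
  if (nrow(cells) == 0) return(img)
  major <- cell_axes[1]; minor <- cell_axes[2]
  stopifnot(major >= minor, minor > 0)
  withr::with_seed(sub_seed(seed, "labeljitter"), {
    for (i in seq_len(nrow(cells))) {
      placed <- FALSE
      for (try in 0:max_retries) {
        jit <- if (try == 0) c(0, 0) else {
          stats::runif(2, -2.5 - try / 2, 2.5 + try / 2)
        }
        cxy <- c(cells$x[i] + jit[1], cells$y[i] + jit[2])
        ang <- cells$axial_angle_deg[i]
        rr <- round(h + 1 - cxy[2] + c(-major - 1, major + 1))
        cc <- round(cxy[1] + c(-major - 1, major + 1))
        rows <- max(1, min(rr)):min(h, max(rr))
        cols <- max(1, min(cc)):min(w, max(cc))
        px <- expand.grid(r = rows, c = cols)
        dx <- px$c - cxy[1]
        dy <- (h + 1 - px$r) - cxy[2]
        th <- ang * pi / 180
        u <- dx * cos(th) + dy * sin(th)
        v <- -dx * sin(th) + dy * cos(th)
        inside <- (u / major)^2 + (v / minor)^2 <= 1
        if (!any(inside)) next
        idx <- cbind(px$r[inside], px$c[inside])
        if (any(img[idx] != 0L)) next
        img[idx] <- as.integer(i)
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("could not place cell ", i, " without overlap after ",
             max_retries, " retries", call. = FALSE)
      }
    }
  })
  img
}

#' Configuration for a synthetic cortical intensity profile
#'
#' Models the angular intensity distribution around a hair cell's cuticular
#' plate as a Gaussian peak on a constant baseline with additive i.i.d.
#' Gaussian noise.
#'
#' @param amplitude Peak height above baseline (intensity units).
#' @param peak_center Peak position, degrees in (-180, 180].
#' @param sigma Peak width (Gaussian SD), degrees > 0.
#' @param baseline Constant offset (>= 0).
#' @param noise_sd Additive noise SD (>= 0).
#' @param n_samples Angular samples over 360 degrees (>= 8).
#' @param seed Integer seed.
#' @return A validated list of class `nm_profile_config`.
#' @export
profile_config <- function(amplitude = 3, peak_center = 0, sigma = 25,
                           baseline = 1, noise_sd = 0, n_samples = 360,
                           seed = 1) {
  stopifnot(sigma > 0, baseline >= 0, noise_sd >= 0, n_samples >= 8)
  structure(
    list(amplitude = amplitude,
         peak_center = wrap_directional(peak_center), sigma = sigma,
         baseline = baseline, noise_sd = noise_sd,
         n_samples = as.integer(n_samples), seed = as.integer(seed)),
    class = "nm_profile_config"
  )
}

#' Simulate an angular cortical intensity profile
#'
#' Evaluates `baseline + amplitude * exp(-d(theta, peak_center)^2 /
#' (2 sigma^2))` on a uniform angular grid over (-180, 180], where `d` is
#' the wrapped directional difference, and adds Gaussian noise.
#'
#' @param config A [profile_config()].
#' @return An [angular_profile()] tibble (`angle_deg`, `intensity`).
#' @export
simulate_profile <- function(config) {
  stopifnot(inherits(config, "nm_profile_config"))
  step <- 360 / config$n_samples
  angles <- seq(-180 + step, 180, by = step)
  d <- wrap_directional(angles - config$peak_center)
  mu <- config$baseline +
    config$amplitude * exp(-d^2 / (2 * config$sigma^2))
  noise <- if (config$noise_sd > 0) {
    withr::with_seed(config$seed,
                     stats::rnorm(length(angles), 0, config$noise_sd))
  } else {
    0
  }
  angular_profile(angles, mu + noise)
}

#' Simulate hair-cell progenitor division events
#'
#' Each event places a pair of daughter centers around a division midpoint
#' at a random radius and direction from a fixed organ center, with the
#' daughter-separation axis at an angle off the local radius set by the
#' model: `"radial"` (0 degrees), `"tangential"` (90), or `"uniform"`
#' (uniform on `[0, 90]`).
#'
#' @param n Number of events (>= 0).
#' @param angle_model One of `"radial"`, `"tangential"`, `"uniform"`.
#' @param seed Integer seed.
#' @return A tibble of events: `event_id`, `timepoint`, `d1x`, `d1y`,
#'   `d2x`, `d2y`, `cx`, `cy`.
#' @export
simulate_divisions <- function(n, angle_model = c("radial", "tangential",
                                                  "uniform"), seed = 1) {
  angle_model <- match.arg(angle_model)
  stopifnot(n >= 0)
  if (n == 0) {
    return(tibble::tibble(
      event_id = integer(), timepoint = numeric(), d1x = numeric(),
      d1y = numeric(), d2x = numeric(), d2y = numeric(),
      cx = numeric(), cy = numeric()
    ))
  }
  withr::with_seed(seed, {
    alpha <- stats::runif(n, -pi, pi)
    radius <- stats::runif(n, 6, 20)
    psi <- switch(angle_model,
                  radial = rep(0, n),
                  tangential = rep(90, n),
                  uniform = stats::runif(n, 0, 90))
    side <- sample(c(-1, 1), n, replace = TRUE)
  })
  mx <- radius * cos(alpha)
  my <- radius * sin(alpha)
  axis_ang <- alpha + side * psi * pi / 180
  sep <- 3
  tibble::tibble(
    event_id = seq_len(n),
    timepoint = 5 * seq_len(n),
    d1x = mx - sep / 2 * cos(axis_ang), d1y = my - sep / 2 * sin(axis_ang),
    d2x = mx + sep / 2 * cos(axis_ang), d2y = my + sep / 2 * sin(axis_ang),
    cx = 0, cy = 0
  )
}
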