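# Shared fixtures, built in code at test time.

# Points uniform in parameter on an ellipse boundary (lab frame).
boundary_points <- function(n, cx = 0, cy = 0, a = 1, b = 1, theta = 0) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  xy <- cbind(a * cos(t), b * sin(t))
  th <- theta * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  xy <- xy %*% t(rot)
  tibble::tibble(x = xy[, 1] + cx, y = xy[, 2] + cy)
}

# Rigid motion of a cell table: rotate by delta degrees about the origin,
# then translate; polarity angles co-rotate.
transform_field <- function(cells, delta = 0, dx = 0, dy = 0) {
  th <- delta * pi / 180
  x2 <- cells$x * cos(th) - cells$y * sin(th) + dx
  y2 <- cells$x * sin(th) + cells$y * cos(th) + dy
  dplyr::mutate(cells, x = x2, y = y2,
                axial_angle_deg = wrap_axial(axial_angle_deg + delta))
}

# Brute-force nearest boundary point by dense parametric scan.
brute_nearest_distance <- function(ellipse, p, n = 1e6) {
  t <- seq(-pi, pi, length.out = n + 1)[-1]
  th <- ellipse$theta * pi / 180
  bx <- ellipse$a * cos(t); by <- ellipse$b * sin(t)
  x <- bx * cos(th) - by * sin(th) + ellipse$cx
  y <- bx * sin(th) + by * cos(th) + ellipse$cy
  sqrt(min((x - p[1])^2 + (y - p[2])^2))
}

# Exact two-sided binomial p at p0 = 1/2 by direct enumeration.
enum_binom_p <- function(k, n) {
  probs <- stats::dbinom(0:n, n, 0.5)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-10)])
}

# Exact two-sided Fisher p for a 2x2 table by enumeration over all tables
# with the observed margins.
enum_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(ks, c1, n - c1, r1)
  obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Exact binomial 99% acceptance band for the rejection count in `reps`
# trials at rate `p`.
binom_band <- function(reps, p, conf = 0.99) {
  lo <- stats::qbinom((1 - conf) / 2, reps, p)
  hi <- stats::qbinom(1 - (1 - conf) / 2, reps, p)
  c(lo, hi)
}
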