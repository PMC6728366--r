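test_that("PCA ellipse fit recovers dense uniform-in-parameter boundaries", {
  circ <- fit_ellipse_pca(boundary_points(360, cx = 1, cy = 2, a = 5, b = 5))
  expect_lt(abs(circ$cx - 1), 1e-9)
  expect_lt(abs(circ$cy - 2), 1e-9)
  expect_lt(abs(circ$a - 5) / 5, 1e-3)
  expect_lt(abs(circ$b - 5) / 5, 1e-3)
  expect_true(circ$near_circular)
  ell <- fit_ellipse_pca(boundary_points(720, a = 10, b = 4))
  expect_lt(abs(ell$theta), 0.5)
  expect_lt(abs(ell$a - 10) / 10, 0.01)
  expect_lt(abs(ell$b - 4) / 4, 0.01)
  rot <- fit_ellipse_pca(boundary_points(720, a = 10, b = 4, theta = 30))
  expect_lt(abs(rot$theta - 30), 0.5)
  expect_error(fit_ellipse_pca(tibble::tibble(x = c(0, 1), y = c(0, 1))),
               "at least 3")
  expect_error(fit_ellipse_pca(tibble::tibble(x = 0:9, y = 0:9)),
               "collinear")
})

test_that("ellipse-fit center error scales with coordinate noise", {
  sigma <- 0.05 * 4
  hits <- 0
  for (r in 1:200) {
    set.seed(5000 + r)
    pts <- boundary_points(100, a = 10, b = 4)
    pts$x <- pts$x + rnorm(100, 0, sigma)
    pts$y <- pts$y + rnorm(100, 0, sigma)
    fit <- fit_ellipse_pca(pts)
    if (sqrt(fit$cx^2 + fit$cy^2) <= 3 * sigma / sqrt(100)) hits <- hits + 1
  }
  expect_gte(hits, 0.95 * 200 - 3 * sqrt(200 * 0.95 * 0.05))
})

test_that("nearest boundary point matches the brute-force scan", {
  # radial projection on a circle
  np <- nearest_point_on_ellipse(ellipse_model(0, 0, 3, 3), c(6, 0))
  expect_equal(unname(np$point), c(3, 0), tolerance = 1e-9)
  # a boundary point projects to itself
  e <- ellipse_model(2, -1, 8, 5, 40)
  bp <- ellipse_point(e, t = 1.1)
  np2 <- nearest_point_on_ellipse(e, c(bp[1, 1], bp[1, 2]))
  expect_lt(np2$distance, 1e-6 * e$a)
  # oracle agreement on random draws (scaled-down version of the full scan)
  set.seed(77)
  for (i in 1:25) {
    e <- ellipse_model(runif(1, -5, 5), runif(1, -5, 5),
                       runif(1, 5, 20), runif(1, 1, 5), runif(1, -90, 90))
    p <- c(runif(1, -30, 30), runif(1, -30, 30))
    d_opt <- nearest_point_on_ellipse(e, p)$distance
    d_brute <- brute_nearest_distance(e, p, n = 2e5)
    expect_lte(d_opt, d_brute + 1e-6 * e$a)
  }
  # exact center: documented major-axis-vertex convention with a flag
  ctr <- nearest_point_on_ellipse(ellipse_model(1, 1, 4, 2, 0), c(1, 1))
  expect_true(ctr$degenerate)
  expect_equal(unname(ctr$point), c(5, 1), tolerance = 1e-9)
})

test_that("tangent angles agree with numerical differentiation", {
  circ <- ellipse_model(0, 0, 7, 7, 0)
  expect_equal(tangent_axial_angle(circ, 0), 90)
  expect_equal(tangent_axial_angle(circ, pi / 2), 0)
  set.seed(21)
  e <- ellipse_model(3, -2, 9, 4, -35)
  t <- runif(100, -pi, pi)
  eps <- 1e-7
  p1 <- ellipse_point(e, t + eps)
  p0 <- ellipse_point(e, t - eps)
  fd <- wrap_axial(atan2(p1[, 2] - p0[, 2], p1[, 1] - p0[, 1]) * 180 / pi)
  got <- tangent_axial_angle(e, t)
  expect_true(all(abs(wrap_axial(got - fd)) < 1e-5))
})

test_that("tangent deviations are zero for tangent-aligned cells and 90 for radial", {
  e <- ellipse_model(0, 0, 10, 10, 0)
  pts <- boundary_points(24, a = 10, b = 10)
  tang <- dplyr::mutate(pts,
                        axial_angle_deg = wrap_axial(atan2(y, x) * 180 / pi + 90))
  expect_true(all(abs(tangent_deviations(tang, e)$deviation_deg) < 1e-9))
  radial <- dplyr::mutate(pts,
                          axial_angle_deg = wrap_axial(atan2(y, x) * 180 / pi))
  expect_true(all(abs(abs(tangent_deviations(radial, e)$deviation_deg) - 90)
                  < 1e-9))
})

test_that("tangent deviations are invariant under rigid motion of the field", {
  cells <- simulate_field(field_config(n_cells = 30,
                                       orientation_model = "concentric",
                                       kappa = 3, seed = 19))
  base <- concentricity_test(cells)
  moved <- transform_field(cells, delta = 30, dx = 12, dy = -7)
  rot <- concentricity_test(moved)
  expect_equal(rot$cells$deviation_deg, base$cells$deviation_deg,
               tolerance = 1e-6)
  expect_equal(rot$uniform_test$p_value, base$uniform_test$p_value,
               tolerance = 1e-9)
  expect_equal(rot$vm_fit$kappa, base$vm_fit$kappa, tolerance = 1e-6)
})

test_that("nearest-neighbor alignment finds neighbors and signs differences", {
  cells <- tibble::tibble(
    cell_id = 1:3, x = c(0, 1, 10), y = c(0, 0, 0),
    axial_angle_deg = c(0, 90, 45)
  )
  nn <- nearest_neighbor_alignment(cells)
  expect_equal(nn$neighbor_id, c(2L, 1L, 2L))
  expect_equal(nn$neighbor_angle_diff_deg[1], 90)  # tie broken to +90
  expect_equal(nn$neighbor_angle_diff_deg[3], 45)
  # parallel field: all differences zero
  par <- tibble::tibble(cell_id = 1:5, x = runif(5), y = runif(5),
                        axial_angle_deg = 20)
  expect_true(all(nearest_neighbor_alignment(par)$neighbor_angle_diff_deg == 0))
  # adjacent cells on a noiseless concentric rim differ by the rim spacing
  rim <- boundary_points(36, a = 10, b = 10)
  rim <- dplyr::mutate(rim, cell_id = dplyr::row_number(),
                       axial_angle_deg = wrap_axial(atan2(y, x) * 180 / pi + 90))
  nn2 <- nearest_neighbor_alignment(rim)
  expect_true(all(abs(abs(nn2$neighbor_angle_diff_deg) - 10) < 1e-9))
})

test_that("concentricity labels match the generating model", {
  conc <- simulate_field(field_config(n_cells = 30,
                                      orientation_model = "concentric",
                                      kappa = 4, seed = 101))
  res <- concentricity_test(conc)
  expect_equal(res$label, "Concentric")
  unif <- simulate_field(field_config(n_cells = 30,
                                      orientation_model = "uniform",
                                      seed = 101))
  res2 <- concentricity_test(unif)
  expect_identical(res2$label %in% c("Concentric", "NotConcentric"), TRUE)
  # noiseless tangent field: mu 0, kappa capped
  e <- ellipse_model(0, 0, 15, 15, 0)
  clean <- simulate_field(field_config(n_cells = 30, ellipse = e,
                                       radial_jitter = 0,
                                       orientation_model = "concentric",
                                       kappa = Inf, seed = 5))
  res3 <- concentricity_test(clean, ellipse = e)
  expect_true(all(abs(res3$cells$deviation_deg) < 1e-5))
  expect_lt(abs(res3$vm_fit$mu), 1e-5)
  expect_true(res3$vm_fit$capped)
  # deterministic given identical input
  expect_equal(glance(concentricity_test(conc)), glance(res))
  # low-n flag
  low <- concentricity_test(conc[1:4, ])
  expect_true(low$low_n)
})
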