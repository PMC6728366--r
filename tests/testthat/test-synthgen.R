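test_that("field generator is deterministic and respects angle ranges", {
  cfg <- field_config(n_cells = 25, orientation_model = "uniform", seed = 9)
  a <- simulate_field(cfg)
  b <- simulate_field(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 25)
  expect_true(all(a$axial_angle_deg > -90 & a$axial_angle_deg <= 90))
  cfg2 <- field_config(n_cells = 25, orientation_model = "axial_bimodal",
                       kappa = 6, seed = 9)
  d <- simulate_field(cfg2)
  expect_true(all(d$dir_angle_deg > -180 & d$dir_angle_deg <= 180))
  expect_equal(d$axial_angle_deg, wrap_axial(d$dir_angle_deg))
})

test_that("cell centers lie within the jittered elliptical annulus", {
  e <- ellipse_model(5, -3, 30, 18, 25)
  cfg <- field_config(n_cells = 200, ellipse = e, radial_jitter = 0.2,
                      seed = 4)
  cells <- simulate_field(cfg)
  # radial scale in the ellipse frame must fall in [1 - jitter, 1]
  th <- e$theta * pi / 180
  u <- (cells$x - e$cx) * cos(th) + (cells$y - e$cy) * sin(th)
  v <- -(cells$x - e$cx) * sin(th) + (cells$y - e$cy) * cos(th)
  s <- sqrt((u / e$a)^2 + (v / e$b)^2)
  expect_true(all(s <= 1 + 1e-9 & s >= 0.8 - 1e-9))
})

test_that("noiseless concentric fields sit exactly on the generating tangents", {
  e <- ellipse_model(0, 0, 12, 12, 0)
  cfg <- field_config(n_cells = 40, ellipse = e, radial_jitter = 0,
                      orientation_model = "concentric", kappa = Inf,
                      seed = 2)
  cells <- simulate_field(cfg)
  dev <- tangent_deviations(cells, e)
  expect_true(all(abs(dev$deviation_deg) < 1e-5))
})

test_that("uniform model fills the 12 bins evenly at large n", {
  cells <- simulate_field(field_config(n_cells = 1e4,
                                       orientation_model = "uniform",
                                       seed = 31))
  h <- bin_axial(cells$axial_angle_deg)
  se <- sqrt((1 / 12) * (11 / 12) / 1e4)
  expect_true(all(abs(h$probabilities - 1 / 12) < 3 * se))
})

test_that("pair generator honours the opposition probability", {
  none <- simulate_pairs(0)
  expect_equal(nrow(none), 0)
  perfect <- simulate_pairs(50, opposition_prob = 1, angle_noise_sd = 0,
                            seed = 8)
  expect_true(all(score_pairs(perfect)$opposed))
  expect_identical(perfect, simulate_pairs(50, 1, 0, seed = 8))
  # chance rate of the default criterion on random second directions:
  # the acceptance region is the half-circle toward the sister, so 1/2
  rand <- simulate_pairs(4000, opposition_prob = 0, angle_noise_sd = 0,
                         seed = 15)
  frac <- mean(score_pairs(rand)$opposed)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("label images round-trip orientation through the moment ellipse", {
  for (ang in c(0, 45)) {
    cells <- tibble::tibble(x = 40, y = 40, axial_angle_deg = ang)
    img <- simulate_label_image(cells, shape = c(80, 80),
                                cell_axes = c(20, 6))
    shp <- region_ellipse(img, 1)
    expect_lt(abs(shp$orientation_deg - abs(ang)), 1)
    expect_gt(shp$major_len, shp$minor_len)
  }
  empty <- simulate_label_image(tibble::tibble(x = numeric(),
                                               y = numeric(),
                                               axial_angle_deg = numeric()))
  expect_true(all(empty == 0L))
  # impossible placement errors out after retries
  crowded <- tibble::tibble(x = c(20, 20), y = c(20, 20),
                            axial_angle_deg = c(0, 0))
  expect_error(
    simulate_label_image(crowded, shape = c(40, 40), cell_axes = c(15, 12)),
    "overlap"
  )
})

test_that("profile generator matches its analytic model", {
  clean <- simulate_profile(profile_config(amplitude = 3, peak_center = 0,
                                           sigma = 25, baseline = 1,
                                           noise_sd = 0))
  expect_equal(max(clean$intensity), 4)
  expect_equal(clean$angle_deg[which.max(clean$intensity)], 0)
  flat <- simulate_profile(profile_config(amplitude = 0, baseline = 2,
                                          noise_sd = 0))
  expect_true(all(flat$intensity == 2))
  # determinism with noise
  n1 <- simulate_profile(profile_config(noise_sd = 0.3, seed = 12))
  n2 <- simulate_profile(profile_config(noise_sd = 0.3, seed = 12))
  expect_identical(n1, n2)
  # wrapped peak: center near the +/-180 seam keeps the full Gaussian mass
  seam <- simulate_profile(profile_config(amplitude = 2, peak_center = 175,
                                          sigma = 20, baseline = 0,
                                          noise_sd = 0))
  expect_equal(seam$angle_deg[which.max(seam$intensity)], 175)
  expect_gt(seam$intensity[seam$angle_deg == -175], 1.5)
})

test_that("division generator produces the advertised angle distributions", {
  rad <- division_angles(simulate_divisions(20, "radial", seed = 3))
  expect_true(all(abs(rad$division_angle_deg) < 1e-5))
  tan <- division_angles(simulate_divisions(20, "tangential", seed = 3))
  expect_true(all(abs(tan$division_angle_deg - 90) < 1e-5))
  unif <- division_angles(simulate_divisions(1e4, "uniform", seed = 3))
  se <- 90 / sqrt(12) / sqrt(1e4)
  expect_lt(abs(mean(unif$division_angle_deg) - 45), 3 * se)
  expect_equal(nrow(simulate_divisions(0, "uniform")), 0)
})
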