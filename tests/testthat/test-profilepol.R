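# Render a ring image whose angular intensity follows a Gaussian hotspot,
# for round-trip tests of extract_profile.
render_ring <- function(size = 121, r0 = 35, ring_w = 5, baseline = 1,
                        amplitude = 0, hotspot = 0, sigma = 30) {
  ctr <- (size + 1) / 2
  img <- matrix(0, size, size)
  for (r in 1:size) {
    for (cc in 1:size) {
      x <- cc - ctr
      y <- (size + 1 - r) - ctr
      rad <- sqrt(x^2 + y^2)
      if (abs(rad - r0) <= ring_w) {
        ang <- atan2(y, x) * 180 / pi
        d <- wrap_directional(ang - hotspot)
        img[r, cc] <- baseline + amplitude * exp(-d^2 / (2 * sigma^2))
      }
    }
  }
  img
}

ring_contour <- function(size = 121, r0 = 35, n = 90) {
  ctr <- (size + 1) / 2
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  tibble::tibble(x = ctr + r0 * cos(t), y = ctr + r0 * sin(t))
}

test_that("profile extraction recovers flat and hotspot ring images", {
  flat <- render_ring(baseline = 7)
  prof <- extract_profile(flat, ring_contour(), thickness = 4)
  expect_true(all(abs(prof$intensity - 7) < 1e-6))
  thin <- extract_profile(flat, ring_contour(), thickness = 1)
  expect_equal(thin$intensity, prof$intensity, tolerance = 1e-9)
  hot <- render_ring(baseline = 1, amplitude = 4, hotspot = 37)
  prof2 <- extract_profile(hot, ring_contour(), thickness = 4)
  step <- 360 / nrow(prof2)
  expect_lte(abs(wrap_directional(
    prof2$angle_deg[which.max(prof2$intensity)] - 37)), step)
  # border contact errors out
  expect_error(extract_profile(flat, ring_contour(r0 = 60)), "border")
})

test_that("alignment centers the maximum, conserves intensity, idempotent", {
  prof <- simulate_profile(profile_config(amplitude = 2, peak_center = 37,
                                          sigma = 20, noise_sd = 0))
  al <- align_and_wrap(prof)
  expect_equal(al$angle_deg[which.max(al$intensity)], 0)
  expect_equal(sort(al$intensity), sort(prof$intensity))
  expect_equal(range(al$angle_deg), c(-179, 180))
  al2 <- align_and_wrap(al)
  expect_equal(al2$intensity, al$intensity)
  # ties flagged
  ties <- align_and_wrap(angular_profile(seq(-179, 180), rep(1, 360)))
  expect_true(attr(ties, "max_ties"))
})

test_that("averaging gives pointwise means and SEMs", {
  g <- seq(-179, 180)
  p1 <- angular_profile(g, rep(0, 360), aligned = TRUE)
  p2 <- angular_profile(g, rep(2, 360), aligned = TRUE)
  avg <- average_profiles(list(p1, p2))
  expect_true(all(avg$intensity == 1))
  expect_true(all(avg$sem == 1))
  ident <- average_profiles(list(p2, p2, p2))
  expect_true(all(ident$intensity == 2) && all(ident$sem == 0))
  # grand mean equals mean of per-profile means
  set.seed(4)
  ps <- lapply(1:5, function(i) angular_profile(g, runif(360)))
  avg2 <- average_profiles(ps)
  expect_equal(mean(avg2$intensity),
               mean(vapply(ps, function(p) mean(p$intensity), numeric(1))))
  expect_error(average_profiles(list(p1, angular_profile(g / 2, rep(1, 360)))),
               "grid")
})

test_that("normalization scales to max 1 and preserves shape", {
  prof <- simulate_profile(profile_config(amplitude = 9, baseline = 1,
                                          noise_sd = 0))
  nm <- normalize_max1(prof)
  expect_equal(max(nm$intensity), 1)
  expect_equal(nm$intensity * 10, prof$intensity)
  expect_equal(normalize_max1(nm)$intensity, nm$intensity)
  expect_error(normalize_max1(angular_profile(1:10, rep(-1, 10))),
               "positive")
})

test_that("Gaussian peak fit recovers noiseless parameters exactly", {
  prof <- align_and_wrap(simulate_profile(
    profile_config(amplitude = 3, peak_center = 0, sigma = 25, baseline = 1,
                   noise_sd = 0)))
  fit <- fit_gaussian_peak(prof, n_mc = 10, seed = 1)
  expect_lt(abs(fit$amplitude - 3) / 3, 1e-6)
  expect_lt(abs(fit$sigma - 25) / 25, 1e-6)
  expect_lt(abs(fit$baseline - 1), 1e-6)
  expect_false(fit$degenerate)
  # flat profile is flagged degenerate
  flat <- fit_gaussian_peak(angular_profile(seq(-179, 180), rep(2, 360),
                                            aligned = TRUE))
  expect_true(flat$degenerate)
  expect_true(is.na(flat$sigma))
  # determinism of the Monte Carlo errors
  noisy <- align_and_wrap(simulate_profile(
    profile_config(amplitude = 3, sigma = 25, baseline = 1, noise_sd = 0.15,
                   seed = 2)))
  f1 <- fit_gaussian_peak(noisy, n_mc = 30, seed = 7)
  f2 <- fit_gaussian_peak(noisy, n_mc = 30, seed = 7)
  expect_identical(f1$param_errors, f2$param_errors)
  expect_true(all(f1$param_errors[c("amplitude", "sigma", "baseline")] > 0))
})

test_that("polarity ratios and their propagated errors match closed forms", {
  g <- seq(-179, 180)
  flat <- angular_profile(g, rep(3, 360), sem = rep(0, 360), aligned = TRUE)
  pr <- polarity_ratio(flat)
  expect_equal(pr$estimate, c(1, 1))
  expect_equal(pr$std_error, c(0, 0))
  # step profile: 2 near 0 degrees, 1 elsewhere
  v <- rep(1, 360)
  v[abs(wrap_directional(g)) <= 10] <- 2
  stepped <- angular_profile(g, v, sem = rep(0, 360), aligned = TRUE)
  pr2 <- polarity_ratio(stepped)
  expect_equal(pr2$estimate, c(2, 2))
  # propagation formula on hand-computable anchors: a = 4 +/- 0.4,
  # b = 2 +/- 0.2 gives r = 2 +/- 2 sqrt(0.02)
  v3 <- rep(2, 360)
  v3[abs(wrap_directional(g)) <= 10] <- 4
  # per-angle sem s gives anchor se = sqrt(3 s^2)/3 = s/sqrt(3), so s =
  # se * sqrt(3) produces anchor errors 0.4 (near 0) and 0.2 (elsewhere)
  se3 <- rep(0.2 * sqrt(3), 360)
  se3[abs(wrap_directional(g)) <= 10] <- 0.4 * sqrt(3)
  prof3 <- angular_profile(g, v3, sem = se3, aligned = TRUE)
  pr3 <- polarity_ratio(prof3)
  expect_equal(pr3$estimate[1], 2)
  expect_equal(pr3$std_error[1], 2 * sqrt(0.01 + 0.01), tolerance = 1e-9)
  # unaligned input is rejected
  expect_error(polarity_ratio(angular_profile(g, v)), "aligned")
})
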