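test_that("continuous engine collapses to a single first-order curve as sigma -> 0", {
  tg <- seq(0, 30, 0.5)
  A <- 30
  m <- drm_model(list(family = "extreme", f0 = 0, psi = 1, mu = 15.7, sigma = 1e-5),
                 A = A, channel_weight = 1)
  sim <- simulate_alpha(m, tg, temperature_c = 105)
  k <- arrhenius_rate(A, 15.7, celsius_to_kelvin(105))
  expect_equal(sim$alpha, first_order_alpha(k, tg), tolerance = 1e-6)
})

test_that("conversion starts at zero and saturates at the channel weight", {
  m <- drm_model(list(family = "extreme", f0 = 0.04736, psi = 0.34469,
                      mu = 15.74, sigma = 0.15),
                 A = 40, channel_weight = 0.34469)
  tg <- c(seq(0, 30, 0.5), 1e5)
  sim <- simulate_alpha(m, tg, temperature_c = 130)
  expect_identical(sim$alpha[1], 0)
  expect_equal(sim$alpha[length(tg)], 0.34469, tolerance = 1e-8)
  expect_true(all(sim$alpha <= 0.34469 + 1e-12))
})

test_that("quadrature agrees with a dense 10001-level discrete sum", {
  pars <- list(family = "extreme", f0 = 0.04736, psi = 0.34469,
               mu = 15.74, sigma = 0.15)
  m <- drm_model(pars, A = 38, channel_weight = 0.34469)
  tg <- seq(0, 30, 0.5)
  for (tc in c(60, 105, 130)) {
    sim <- simulate_alpha(m, tg, temperature_c = tc)
    e <- seq(pars$mu - 8 * pars$sigma, pars$mu + 25 * pars$sigma,
             length.out = 10001)
    f <- ddf_extreme(e, 0, pars$psi, pars$mu, pars$sigma)
    f <- f / sum(f)
    k <- arrhenius_rate(38, e, celsius_to_kelvin(tc))
    brute <- 0.34469 * (1 - colSums(f * exp(-outer(k, tg))))
    expect_equal(sim$alpha, brute, tolerance = 1e-6)
  }
})

test_that("doubling the quadrature resolution changes alpha below 1e-8", {
  for (preset in c("zp434_control_radicle", "zp704_control_radicle",
                   "zp704_radicle_c9")) {
    m <- drm_preset(preset)
    tg <- seq(0, 30, 1)
    s1 <- simulate_alpha(m, tg, temperature_c = 105)
    s2 <- simulate_alpha(m, tg, temperature_c = 105, n_panels = 128, order = 8)
    expect_lt(max(abs(s1$alpha - s2$alpha)), 1e-8)
  }
})

test_that("discrete engine reproduces a term-by-term hand summation", {
  m <- drm_preset("zp434_radicle_c9_discrete")
  m$preexp$A <- 1e6
  tg <- c(0, 0.001, 0.005, 0.02, 10)
  sim <- simulate_alpha(m, tg, temperature_k = 378.15)
  w <- sapply(0:8, function(i) factorial(8) / (factorial(i) * factorial(8 - i)) / 2^8)
  e <- 19.3 + 0:8
  k <- 1e6 * exp(-e * 1000 / (8.314 * 378.15))
  hand <- 1 - colSums(w * exp(-outer(k, tg)))
  expect_equal(sim$alpha, hand, tolerance = 1e-12)
})

test_that("a one-level set equals the plain first-order curve and saturates", {
  m <- single_reaction_model(15.7, A = 30)
  tg <- seq(0, 30, 0.5)
  sim <- simulate_alpha(m, tg, temperature_c = 60)
  k <- arrhenius_rate(30, 15.7, 333.15)
  expect_equal(sim$alpha, first_order_alpha(k, tg), tolerance = 1e-12)
  long <- simulate_alpha(m, c(0, 1e6), temperature_c = 60)
  expect_equal(long$alpha[2], m$channel_weight, tolerance = 1e-10)
})

test_that("continuous and discrete engines agree for a narrow matched peak", {
  sigma <- 0.05
  mu <- 16
  cont <- drm_model(list(family = "extreme", f0 = 0, psi = 1, mu = mu,
                         sigma = sigma), A = 30, channel_weight = 1)
  # fine discrete grid carrying the same kernel as weights
  e <- seq(mu - 8 * sigma, mu + 22 * sigma, by = sigma / 50)
  w <- ddf_extreme(e, 0, 1, mu, sigma)
  tg <- seq(0, 30, 0.5)
  kk <- arrhenius_rate(30, e, 378.15)
  disc_alpha <- 1 - colSums((w / sum(w)) * exp(-outer(kk, tg)))
  sim <- simulate_alpha(cont, tg, temperature_k = 378.15)
  expect_equal(sim$alpha, disc_alpha, tolerance = 1e-4)
})

test_that("alpha(t) is monotone and accelerates with temperature", {
  for (preset in c("zp434_control_radicle", "zp704_control_ros",
                   "zp704_radicle_c12", "zp434_radicle_c9_discrete")) {
    m <- drm_preset(preset)
    tg <- seq(0, 30, 0.25)
    s60 <- simulate_alpha(m, tg, temperature_c = 60)
    s130 <- simulate_alpha(m, tg, temperature_c = 130)
    expect_true(all(diff(s60$alpha) >= -1e-12))
    expect_true(all(s130$alpha >= s60$alpha - 1e-12))
    expect_true(all(s60$alpha >= 0 & s60$alpha <= m$channel_weight + 1e-12))
  }
})

test_that("curve_deviation measures the maximum conversion gap in percent", {
  tg <- seq(0, 10, 0.5)
  a <- first_order_alpha(0.3, tg)
  c1 <- conversion_curve(tg, a, 333.15)
  expect_equal(curve_deviation(c1, c1), 0)
  a_shift <- pmin(a + 0.01, 1)
  a_shift[1] <- 0
  shifted <- conversion_curve(tg, a_shift, 333.15)
  expect_equal(curve_deviation(c1, shifted), 1, tolerance = 1e-9)
})

test_that("compensation-linked pre-exponential factors enter the simulation", {
  dist <- list(family = "extreme", f0 = 0, psi = 1, mu = 15, sigma = 0.3)
  m_comp <- drm_model(dist, compensation = list(a_mu = 30, phi = 0.4, mu = 15))
  m_const <- drm_model(dist, A = 30)
  tg <- seq(0, 30, 0.5)
  s1 <- simulate_alpha(m_comp, tg, temperature_c = 105)
  s2 <- simulate_alpha(m_const, tg, temperature_c = 105)
  # same A at the centre, different weighting across the support
  expect_false(isTRUE(all.equal(s1$alpha, s2$alpha, tolerance = 1e-10)))
  expect_true(all(diff(s1$alpha) >= -1e-12))
})

test_that("fit_drm round trip on noiseless log-normal curves recovers the centre", {
  m <- drm_preset("zp704_radicle_c9")
  tg <- log_time_grid(1e-4, 30, 200)
  curves <- lapply(c(60, 105, 130), function(tc) {
    simulate_alpha(m, tg, temperature_c = tc)
  })
  fit <- fit_drm(curves, "lognormal")
  expect_equal(unname(fit$estimate[["mu"]]), 19.7, tolerance = 0.01)
  expect_lt(max(fit$deviations$deviation_pct), 1e-2)
})

test_that("fit_drm self-consistency: refit of self-generated curves is near-exact", {
  m <- drm_preset("zp434_control_radicle")
  tg <- seq(0, 30, 0.5)
  curves <- lapply(c(60, 105, 130), function(tc) {
    simulate_alpha(m, tg, temperature_c = tc)
  })
  fit <- fit_drm(curves, "extreme")
  expect_lt(max(fit$deviations$deviation_pct), 1e-3)
  expect_equal(unname(fit$estimate[["channel_weight"]]), 0.34469, tolerance = 1e-3)
})

test_that("fitting a mismatched family still tracks the curves but fits worse", {
  m <- drm_preset("zp434_control_radicle")
  tg <- seq(0, 30, 0.5)
  curves <- lapply(c(60, 105, 130), function(tc) {
    simulate_alpha(m, tg, temperature_c = tc)
  })
  fit_true <- fit_drm(curves, "extreme")
  fit_wrong <- fit_drm(curves, "lorentz")
  expect_lt(max(fit_wrong$deviations$deviation_pct), 5)
  expect_gt(fit_wrong$rss, fit_true$rss)
})

test_that("fit_drm needs at least two distinct temperatures", {
  m <- drm_preset("zp434_control_radicle")
  tg <- seq(0, 30, 0.5)
  one <- list(simulate_alpha(m, tg, temperature_c = 105))
  expect_error(fit_drm(one, "extreme"), class = "drykin_precondition_error")
})
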