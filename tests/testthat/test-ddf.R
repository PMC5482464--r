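t4_zp434_radicle <- list(f0 = 0.04736, psi = 0.34469, mu = 15.74, sigma = 0.15)
t4_zp704_radicle <- list(f0 = 0.01402, psi = 0.53760, mu = 22.11, sigma = 1.39)
t5_c9 <- list(psi = 0.51009, a_sharp = 0.52622, mu = 19.7, sigma = 0.052)

test_that("extreme density: peak identity, printed-parameter value, tail limit", {
  p <- t4_zp434_radicle
  expect_equal(ddf_extreme(p$mu, p$f0, p$psi, p$mu, p$sigma), p$f0 + p$psi)
  expect_equal(ddf_extreme(15.74, 0.04736, 0.34469, 15.74, 0.15), 0.39205)
  expect_equal(ddf_extreme(p$mu + 60 * p$sigma, p$f0, p$psi, p$mu, p$sigma),
               p$f0, tolerance = 1e-10)
  expect_equal(ddf_extreme(p$mu - 10 * p$sigma, p$f0, p$psi, p$mu, p$sigma),
               p$f0, tolerance = 1e-10)
})

test_that("lorentz density: peak identity, printed-parameter value, FWHM = sigma", {
  p <- t4_zp704_radicle
  peak <- ddf_lorentz(p$mu, p$f0, p$psi, p$mu, p$sigma)
  expect_equal(peak, p$f0 + 2 * p$psi / (pi * p$sigma))
  expect_equal(peak, 0.26024071196, tolerance = 1e-9)
  # full width at half the above-baseline peak equals sigma
  half <- p$f0 + (peak - p$f0) / 2
  expect_equal(ddf_lorentz(p$mu + p$sigma / 2, p$f0, p$psi, p$mu, p$sigma), half)
  expect_equal(ddf_lorentz(p$mu - p$sigma / 2, p$f0, p$psi, p$mu, p$sigma), half)
})

test_that("lognormal density: median centre, closed-form mode, normalisation", {
  p <- t5_c9
  area <- p$psi * p$a_sharp
  # mode at mu * exp(-sigma^2): frozen value for the printed high-concentration row
  mode_e <- p$mu * exp(-p$sigma^2)
  expect_equal(mode_e, 19.6468031545, tolerance = 1e-9)
  grid <- seq(1, 60, by = 1e-4)
  dens <- ddf_lognormal(grid, area, p$mu, p$sigma)
  expect_equal(grid[which.max(dens)], mode_e, tolerance = 2e-5)
  # half the mass lies below the median mu
  below <- sum(dens[grid <= p$mu]) * 1e-4
  expect_equal(below, area / 2, tolerance = 1e-3)
  # total integral equals psi * A#
  expect_equal(sum(dens) * 1e-4, area, tolerance = 1e-3)
})

test_that("all continuous densities stay above baseline and decay to it", {
  grid <- seq(0.5, 80, by = 0.01)
  ex <- ddf_extreme(grid, 0.03, 0.4, 15, 0.5)
  lo <- ddf_lorentz(grid, 0.02, 0.3, 20, 1.2)
  ln <- ddf_lognormal(grid, 0.3, 18, 0.1)
  expect_true(all(ex >= 0.03))
  expect_true(all(lo >= 0.02))
  expect_true(all(ln >= 0))
  expect_lt(ln[1], 1e-8)
  expect_lt(ln[length(ln)], 1e-8)
})

test_that("binomial reactivity: combinatorial mass, normalisation, moments", {
  r <- binomial_reactivity(8, 0.5, grid_origin = 19.3, grid_spacing = 1)
  expect_equal(binomial_ddf(4, r), 70 / 256) # C(8,4)/2^8
  expect_equal(sum(r$weight), 1, tolerance = 1e-12)
  expect_equal(r$weight, choose(8, 0:8) * 0.5^8) # independent evaluation
  expect_equal(poisson_mean(r), 4)
  expect_equal(reactivity_dispersion(r), sqrt(2))
  expect_equal(round(reactivity_dispersion(r), 1), 1.4)
  expect_equal(reactivity_mode(r), 23.3)
  r0 <- binomial_reactivity(8, 0, grid_origin = 10)
  expect_equal(poisson_mean(r0), 0)
  expect_error(binomial_ddf(9, r), class = "drykin_domain_error")
})

test_that("poisson approximation improves as N grows at fixed N*p", {
  tv <- vapply(c(8, 16, 32), function(N) {
    p <- 4 / N
    i <- 0:N
    0.5 * (sum(abs(dbinom(i, N, p) - dpois(i, 4))) + (1 - ppois(N, 4)))
  }, numeric(1))
  expect_true(all(diff(tv) < 0))
})

test_that("experimental_ddf maps a linear profile to a constant density", {
  prof <- structure(tibble::tibble(alpha = seq(0, 1, 0.05),
                                   ea_kj_mol = 10 + 10 * seq(0, 1, 0.05),
                                   ea_se_kj_mol = 0),
                    class = c("ea_profile", "tbl_df", "tbl", "data.frame"),
                    method = "integral", n_temperatures = 3L)
  pts <- experimental_ddf(prof)
  expect_equal(pts$density, rep(0.1, nrow(pts)), tolerance = 1e-12)
})

test_that("experimental_ddf matches the analytic inverse derivative on a quadratic profile", {
  al <- seq(0.05, 0.95, 0.05)
  prof <- structure(tibble::tibble(alpha = al, ea_kj_mol = 10 + 10 * al^2,
                                   ea_se_kj_mol = 0),
                    class = c("ea_profile", "tbl_df", "tbl", "data.frame"),
                    method = "integral", n_temperatures = 3L)
  pts <- experimental_ddf(prof)
  interior <- 2:(nrow(pts) - 1)
  analytic <- 1 / (20 * sqrt((pts$ea_kj_mol - 10) / 10))
  expect_equal(pts$density[interior], analytic[interior], tolerance = 1e-10)
})

test_that("experimental_ddf rejects flat (delta-like) profiles", {
  prof <- structure(tibble::tibble(alpha = seq(0.1, 0.9, 0.1),
                                   ea_kj_mol = rep(15.7, 9), ea_se_kj_mol = 0),
                    class = c("ea_profile", "tbl_df", "tbl", "data.frame"),
                    method = "integral", n_temperatures = 3L)
  expect_error(experimental_ddf(prof), class = "drykin_derivation_error")
})

test_that("experimental_ddf splits non-monotone profiles and keeps both flanks", {
  al <- seq(0.05, 0.95, 0.05)
  ea <- 15 - 8 * (al - 0.5)^2 # rises then falls
  prof <- structure(tibble::tibble(alpha = al, ea_kj_mol = ea, ea_se_kj_mol = 0),
                    class = c("ea_profile", "tbl_df", "tbl", "data.frame"),
                    method = "integral", n_temperatures = 3L)
  pts <- experimental_ddf(prof)
  expect_true(all(diff(pts$ea_kj_mol) >= 0))
  expect_gt(nrow(pts), 10)
})

test_that("fit_ddf recovers every family exactly from noiseless model samples", {
  grid <- seq(10, 25, by = 0.1)
  cases <- list(
    list(family = "extreme",
         pars = c(f0 = 0.04736, psi = 0.34469, mu = 15.74, sigma = 0.45)),
    list(family = "lorentz",
         pars = c(f0 = 0.01402, psi = 0.53760, mu = 22.11, sigma = 1.39)),
    list(family = "lognormal",
         pars = c(area = 0.26843, mu = 19.7, sigma = 0.052)))
  for (cs in cases) {
    dens <- ddf_density(grid, cs$family, as.list(cs$pars))
    pts <- tibble::tibble(ea_kj_mol = grid, density = dens)
    fit <- fit_ddf(pts, cs$family)
    expect_equal(fit$estimate[names(cs$pars)], cs$pars, tolerance = 1e-6)
    expect_lt(fit$rss, 1e-20)
    expect_equal(fit$chi2_red, fit$rss / (length(grid) - fit$n_par))
  }
})

test_that("fit_ddf honours explicit initial values and precondition on size", {
  grid <- seq(12, 20, by = 0.5)
  dens <- ddf_extreme(grid, 0.02, 0.3, 15.5, 0.6)
  pts <- tibble::tibble(ea_kj_mol = grid, density = dens)
  fit <- fit_ddf(pts, "extreme", init = list(mu = 15, sigma = 0.5))
  expect_equal(unname(fit$estimate[["mu"]]), 15.5, tolerance = 1e-6)
  expect_error(fit_ddf(pts[1:4, ], "extreme"), class = "drykin_precondition_error")
})

test_that("the generating family fits better than a mismatched one", {
  grid <- seq(12, 22, by = 0.1)
  dens <- ddf_extreme(grid, 0.03, 0.4, 16, 0.8)
  pts <- tibble::tibble(ea_kj_mol = grid, density = dens)
  fit_true <- fit_ddf(pts, "extreme")
  fit_wrong <- fit_ddf(pts, "lorentz")
  expect_gt(fit_wrong$chi2_red, fit_true$chi2_red)
})

test_that("reduced chi-square convention matches the printed table ratios", {
  # the published Lorentz radicle fit reports RSS / chi2 = 2.0, i.e. n - p = 2
  tab <- fixture_table("ddf_params_continuous")
  row <- tab[tab$hybrid == "ZP704" & tab$part == "radicle", ]
  expect_equal(row$rss / row$chi2, 2.0, tolerance = 1e-4)
})

test_that("tidy and glance summarise a ddf fit", {
  grid <- seq(12, 20, by = 0.25)
  pts <- tibble::tibble(ea_kj_mol = grid,
                        density = ddf_extreme(grid, 0.02, 0.3, 15.5, 0.6))
  fit <- fit_ddf(pts, "extreme")
  td <- tidy(fit)
  expect_setequal(td$term, c("f0", "psi", "mu", "sigma"))
  expect_true(all(is.finite(td$std.error)))
  gl <- glance(fit)
  expect_equal(gl$family, "extreme")
  expect_true(gl$converged)
  # JSON serialisation carries the table-style field names
  path <- tempfile(fileext = ".json")
  write_ddf_fit_json(fit, path)
  js <- jsonlite::read_json(path)
  expect_equal(js$mu, 15.5, tolerance = 1e-5)
  expect_true(all(c("f0", "psi", "sigma", "rss", "chi2_red") %in% names(js)))
  unlink(path)
})
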