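#' Density-distribution families of activation-energy counterparts
#'
#' Peak-function densities used to describe the spread of activation-energy
#' counterparts across the ensemble of parallel first-order desorption
#' reactions, each evaluated at energies `ea` (kJ mol-1):
#'
#' * `ddf_extreme()` — Extreme (Gumbel Type I) peak,
#'   `f0 + psi * exp(-exp(-z) - z + 1)` with `z = (ea - mu)/sigma`;
#'   peaks at `mu` with height `f0 + psi`.
#' * `ddf_lorentz()` — Lorentz (Cauchy) peak,
#'   `f0 + (2 psi / pi) * sigma / (4 (ea - mu)^2 + sigma^2)`; area-normalised
#'   Lorentzian with full width at half maximum `sigma`, peak
#'   `f0 + 2 psi / (pi sigma)` at `mu`.
#' * `ddf_lognormal()` — Log-normal peak,
#'   `area / (ea sigma sqrt(2 pi)) * exp(-ln(ea/mu)^2 / (2 sigma^2))`, where
#'   `mu` (kJ mol-1) is the energy-axis centre (median) and `sigma` the
#'   dimensionless log-scale; mode at `mu * exp(-sigma^2)`. `area` is the
#'   integral of the peak over (0, Inf), conventionally factored as the
#'   product of an overall reaction contribution psi and a distribution
#'   area A#.
#'
#' @param ea Energies at which to evaluate, kJ mol-1.
#' @param f0 Baseline ("onset") density, mol kJ-1.
#' @param psi Overall reaction contribution in \[0, 1\] (peak amplitude scale).
#' @param mu Location / centre, kJ mol-1.
#' @param sigma Scale: kJ mol-1 for extreme and lorentz, dimensionless
#'   log-scale for lognormal (> 0).
#' @param area Total area of the log-normal peak (psi * A#).
#' @return Density values, mol kJ-1.
#' @examples
#' ddf_extreme(15.74, f0 = 0.04736, psi = 0.34469, mu = 15.74, sigma = 0.15)
#' @export
ddf_extreme <- function(ea, f0, psi, mu, sigma) {
  stopifnot(sigma > 0)
  z <- (ea - mu) / sigma
  f0 + psi * exp(-exp(-z) - z + 1)
}

#' @rdname ddf_extreme
#' @export
ddf_lorentz <- function(ea, f0, psi, mu, sigma) {
  stopifnot(sigma > 0)
  f0 + (2 * psi / pi) * sigma / (4 * (ea - mu)^2 + sigma^2)
}

#' @rdname ddf_extreme
#' @export
ddf_lognormal <- function(ea, area, mu, sigma) {
  stopifnot(sigma > 0, mu > 0, all(ea > 0))
  area / (ea * sigma * sqrt(2 * pi)) * exp(-(log(ea / mu))^2 / (2 * sigma^2))
}

# evaluate a family by tag on a named parameter list
ddf_density <- function(ea, family, pars) {
  switch(family,
    extreme   = ddf_extreme(ea, pars$f0, pars$psi, pars$mu, pars$sigma),
    lorentz   = ddf_lorentz(ea, pars$f0, pars$psi, pars$mu, pars$sigma),
    lognormal = ddf_lognormal(ea, pars$area %||% (pars$psi * pars$a_sharp),
                              pars$mu, pars$sigma),
    abort(sprintf("unknown ddf family '%s'", family), class = "drykin_bad_family")
  )
}

# baseline-removed kernel (the part that integrates to the channel mass)
ddf_kernel <- function(ea, family, pars) {
  switch(family,
    extreme   = ddf_extreme(ea, 0, pars$psi, pars$mu, pars$sigma),
    lorentz   = ddf_lorentz(ea, 0, pars$psi, pars$mu, pars$sigma),
    lognormal = ddf_lognormal(ea, pars$area %||% (pars$psi * pars$a_sharp),
                              pars$mu, pars$sigma),
    abort(sprintf("unknown ddf family '%s'", family), class = "drykin_bad_family")
  )
}

#' Discrete binomial reactivity level set
#'
#' Places N + 1 activation-energy levels on a uniform grid
#' `ea_i = grid_origin + i * grid_spacing`, i = 0..N, weighted by the binomial
#' probability mass `B(i; N, p) = C(N, i) p^i (1-p)^(N-i)` — the stochastic
#' description of water desorption from N identical, independent centres.
#'
#' @param n_trials Integer N > 0, the number of desorption reactions.
#' @param p_success Success probability p in \[0, 1\].
#' @param grid_origin Energy of level 0 (epsilon_0), kJ mol-1.
#' @param grid_spacing Level spacing (delta epsilon), kJ mol-1; default 1.
#' @return A tibble of class `discrete_reactivity` with columns `level`,
#'   `ea_kj_mol`, `weight`; parameters are carried as attributes.
#' @examples
#' binomial_reactivity(8, 0.5, grid_origin = 19.3)
#' @export
binomial_reactivity <- function(n_trials, p_success, grid_origin,
                                grid_spacing = 1) {
  stopifnot(n_trials > 0, n_trials == round(n_trials),
            p_success >= 0, p_success <= 1, grid_spacing > 0)
  lev <- 0:n_trials
  out <- tibble::tibble(
    level = lev,
    ea_kj_mol = grid_origin + lev * grid_spacing,
    weight = stats::dbinom(lev, n_trials, p_success))
  structure(out, class = c("discrete_reactivity", class(out)),
            n_trials = n_trials, p_success = p_success,
            grid_origin = grid_origin, grid_spacing = grid_spacing)
}

#' @rdname binomial_reactivity
#' @param i Level index (0 <= i <= N), vectorised.
#' @param reactivity A `discrete_reactivity` object.
#' @return `binomial_ddf()`: the probability mass at level `i`.
#' @export
binomial_ddf <- function(i, reactivity) {
  stopifnot(inherits(reactivity, "discrete_reactivity"))
  n <- attr(reactivity, "n_trials")
  if (any(i < 0) || any(i > n)) {
    abort("level index out of 0..N.", class = "drykin_domain_error")
  }
  stats::dbinom(i, n, attr(reactivity, "p_success"))
}

#' Moments of a discrete reactivity model
#'
#' `poisson_mean()` returns the mean number of desorption events lambda = N p
#' (the rate parameter of the Poisson approximation valid for small p).
#' `reactivity_dispersion()` returns the energy-scale dispersion
#' `sqrt(N p (1-p)) * grid_spacing` (kJ mol-1), and `reactivity_mode()` the
#' energy of the most probable level.
#'
#' @param reactivity A [binomial_reactivity()] object.
#' @return A scalar.
#' @export
poisson_mean <- function(reactivity) {
  stopifnot(inherits(reactivity, "discrete_reactivity"))
  attr(reactivity, "n_trials") * attr(reactivity, "p_success")
}

#' @rdname poisson_mean
#' @export
reactivity_dispersion <- function(reactivity) {
  stopifnot(inherits(reactivity, "discrete_reactivity"))
  n <- attr(reactivity, "n_trials"); p <- attr(reactivity, "p_success")
  sqrt(n * p * (1 - p)) * attr(reactivity, "grid_spacing")
}

#' @rdname poisson_mean
#' @export
reactivity_mode <- function(reactivity) {
  stopifnot(inherits(reactivity, "discrete_reactivity"))
  reactivity$ea_kj_mol[which.max(reactivity$weight)]
}

#' Experimental density distribution from an activation-energy profile
#'
#' Derives the experimentally based density f_exp(Ea) = d alpha / d Ea along
#' the isoconversional profile: the profile is split into maximal monotone
#' segments of Ea(alpha); within each segment (Ea, alpha) pairs are sorted by
#' Ea and differentiated by central difference quotients; segments shorter
#' than 3 points are discarded; the remainder is concatenated and re-sorted.
#' Small negative densities from noisy differentiation are clipped to zero
#' (their count is recorded in the `n_clipped` attribute).
#'
#' @param profile An [ea_profile()] with at least 4 levels.
#' @return A tibble of class `ddf_points` with columns `ea_kj_mol`, `density`.
#' @export
experimental_ddf <- function(profile) {
  stopifnot(inherits(profile, "ea_profile"))
  if (nrow(profile) < 4) {
    abort("need at least 4 profile levels.", class = "drykin_derivation_error")
  }
  ea <- profile$ea_kj_mol
  al <- profile$alpha
  # maximal monotone segments of Ea(alpha); ties break a segment (delta-like)
  s <- sign(diff(ea))
  seg_id <- cumsum(c(1, abs(diff(s)) > 0))
  pieces <- list()
  for (g in unique(seg_id)) {
    idx <- which(seg_id == g)
    idx <- sort(unique(c(idx, max(idx) + 1)))  # segment of diffs -> points
    idx <- idx[idx <= length(ea)]
    if (length(idx) < 3) next
    if (any(s[seg_id == g] == 0)) next         # flat: no finite density
    o <- order(ea[idx])
    e_s <- ea[idx][o]; a_s <- al[idx][o]
    pieces[[length(pieces) + 1]] <-
      tibble::tibble(ea_kj_mol = e_s, density = grad_nonuniform(e_s, a_s))
  }
  if (length(pieces) == 0) {
    abort("no monotone segment of length >= 3; density underivable (delta-like profile).",
          class = "drykin_derivation_error")
  }
  out <- dplyr::arrange(dplyr::bind_rows(pieces), .data$ea_kj_mol)
  n_clip <- sum(out$density < 0)
  if (n_clip > 0) {
    warn(sprintf("clipped %d negative experimental density value(s) to 0.", n_clip))
    out$density <- pmax(out$density, 0)
  }
  structure(out, class = c("ddf_points", class(out)), n_clipped = n_clip)
}

#' Fit a density-distribution family to experimental density points
#'
#' Non-linear least squares (Levenberg-Marquardt) of one of the continuous
#' peak families against (ea, density) points. Initialisation is by moments
#' (centre at the argmax point, scale from the half-width, baseline from the
#' minimum density, amplitude peak-matched) unless `init` is given; five
#' random-perturbation restarts around the initial values (fixed seed) guard
#' against local minima and the best residual sum of squares wins. The
#' location parameter is constrained to the span of the supplied energies: a
#' peak fit cannot place its centre outside the observed window (on one-sided
#' data an unconstrained amplitude otherwise drifts to a degenerate flank
#' solution). Reports RSS and the reduced chi-square RSS / (n - p).
#'
#' @param points A [experimental_ddf()] result, or any tibble with columns
#'   `ea_kj_mol` and `density`.
#' @param family `"extreme"`, `"lorentz"` or `"lognormal"`.
#' @param init Optional named list of starting values
#'   (`f0`, `psi`, `mu`, `sigma` or `area`, `mu`, `sigma`).
#' @param n_restarts Number of perturbation restarts (default 5).
#' @return An object of class `ddf_fit`: list with elements `family`,
#'   `estimate` (named vector), `se`, `rss`, `chi2_red`, `n`, `n_par`,
#'   `data`, `fitted`, `converged`.
#' @export
fit_ddf <- function(points, family = c("extreme", "lorentz", "lognormal"),
                    init = NULL, n_restarts = 5) {
  family <- match.arg(family)
  stopifnot(all(c("ea_kj_mol", "density") %in% names(points)))
  df <- tibble::tibble(e = points$ea_kj_mol, f = points$density)
  df <- dplyr::arrange(df, .data$e)
  n_par <- if (family == "lognormal") 3L else 4L
  if (nrow(df) <= n_par) {
    abort("need more points than free parameters.", class = "drykin_precondition_error")
  }
  start <- init_moments(df, family)
  if (!is.null(init)) start[names(init)] <- init
  lo_e <- min(df$e); hi_e <- max(df$e)
  bounds <- ddf_bounds(family, lo_e, hi_e)
  par_names <- names(bounds$lower)
  resid_fn <- function(p) {
    ddf_density(df$e, family, as.list(setNames(p, par_names))) - df$f
  }
  one_fit <- function(st) {
    st <- pmin(pmax(unlist(st)[par_names], bounds$lower), bounds$upper)
    tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn,
                         lower = bounds$lower, upper = bounds$upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
  }
  fits <- list(one_fit(start))
  # fixed-seed perturbation restarts
  rng <- local_rng(20170623L)
  for (r in seq_len(n_restarts)) {
    pert <- lapply(start, function(v) v * exp(rng(0.15)) + 1e-8 * abs(rng(1)))
    fits[[r + 1]] <- one_fit(pert)
  }
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) {
    abort("non-linear least squares failed from every start.",
          class = "drykin_fit_error")
  }
  rss_all <- vapply(fits, function(f) sum(f$fvec^2), numeric(1))
  best <- fits[[which.min(rss_all)]]
  est <- setNames(best$par, par_names)
  rss <- sum(best$fvec^2)
  converged <- best$info %in% 1:4
  if (!converged) {
    warn(sprintf("ddf fit did not fully converge (nls.lm info = %d); best iterate returned.",
                 best$info))
  }
  # standard errors from the Gauss-Newton approximation at the optimum
  se <- tryCatch({
    jac <- numeric_jacobian(resid_fn, best$par)
    s2 <- rss / max(nrow(df) - n_par, 1)
    setNames(sqrt(diag(s2 * solve(crossprod(jac)))), par_names)
  }, error = function(e) setNames(rep(NA_real_, n_par), par_names))
  structure(list(
    family = family,
    estimate = est,
    se = se,
    rss = rss,
    chi2_red = rss / (nrow(df) - n_par),
    n = nrow(df),
    n_par = n_par,
    data = tibble::tibble(ea_kj_mol = df$e, density = df$f),
    fitted = df$f + best$fvec,
    converged = converged
  ), class = "ddf_fit")
}

numeric_jacobian <- function(fn, p, eps = 1e-7) {
  f0 <- fn(p)
  jac <- matrix(0, length(f0), length(p))
  for (j in seq_along(p)) {
    h <- eps * max(abs(p[j]), 1)
    pj <- p; pj[j] <- pj[j] + h
    jac[, j] <- (fn(pj) - f0) / h
  }
  jac
}

ddf_bounds <- function(family, lo_e, hi_e) {
  if (family == "lognormal") {
    list(lower = c(area = 1e-10, mu = lo_e, sigma = 1e-5),
         upper = c(area = Inf, mu = hi_e, sigma = 5))
  } else {
    list(lower = c(f0 = 0, psi = 1e-10, mu = lo_e, sigma = 1e-5),
         upper = c(f0 = Inf, psi = 1, mu = hi_e, sigma = Inf))
  }
}

init_moments <- function(df, family) {
  i_pk <- which.max(df$f)
  mu0 <- df$e[i_pk]
  pk <- df$f[i_pk]
  base <- max(min(df$f), 0)
  # half-width estimate from the first crossing of half the above-baseline peak
  half <- base + (pk - base) / 2
  lower_half <- df$e[df$f <= half & df$e > mu0]
  hw <- if (length(lower_half) > 0) abs(lower_half[1] - mu0) else diff(range(df$e)) / 4
  hw <- max(hw, diff(range(df$e)) / 50)
  if (family == "lognormal") {
    sig0 <- max(hw / (mu0 * sqrt(2 * log(2))), 1e-3)
    list(area = pk * mu0 * sig0 * sqrt(2 * pi), mu = mu0, sigma = sig0)
  } else if (family == "extreme") {
    list(f0 = base, psi = min(max(pk - base, 1e-6), 1), mu = mu0, sigma = hw)
  } else {
    list(f0 = base, psi = min(max((pk - base) * pi * hw / 2, 1e-6), 1),
         mu = mu0, sigma = hw)
  }
}

# deterministic normal sampler that does not disturb the global RNG stream
local_rng <- function(seed) {
  state <- seed
  function(sd_val) {
    state <<- (state * 69069 + 1) %% 2^31
    u1 <- (state + 0.5) / 2^31
    state <<- (state * 69069 + 1) %% 2^31
    u2 <- (state + 0.5) / 2^31
    sd_val * sqrt(-2 * log(u1)) * cos(2 * pi * u2)
  }
}

#' @export
print.ddf_fit <- function(x, ...) {
  cat(sprintf("<ddf_fit> %s family, %d points\n", x$family, x$n))
  print(round(x$estimate, 6))
  cat(sprintf("RSS = %.6g, reduced chi-square = %.6g\n", x$rss, x$chi2_red))
  invisible(x)
}

#' Tidy a fitted density-distribution model
#'
#' @param x A [fit_ddf()] result.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter (`term`, `estimate`, `std.error`);
#'   `glance()`: one-row tibble with `family`, `rss`, `chi2.red`, `nobs`,
#'   `converged`.
#' @exportS3Method generics::tidy
tidy.ddf_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimate),
                 estimate = unname(x$estimate),
                 std.error = unname(x$se[names(x$estimate)]))
}

#' @rdname tidy.ddf_fit
#' @exportS3Method generics::glance
glance.ddf_fit <- function(x, ...) {
  tibble::tibble(family = x$family, rss = x$rss, chi2.red = x$chi2_red,
                 nobs = x$n, converged = x$converged)
}

#' Serialize a fitted density-distribution model to JSON
#'
#' Field names mirror the conventional parameter tables: `f0`, `psi`, `mu`,
#' `sigma` (`area` for the log-normal family), `rss`, `chi2_red`.
#'
#' @param x A [fit_ddf()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ddf_fit_json <- function(x, path) {
  stopifnot(inherits(x, "ddf_fit"))
  payload <- c(list(family = x$family), as.list(x$estimate),
               list(rss = x$rss, chi2_red = x$chi2_red, n = x$n))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
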