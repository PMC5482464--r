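#' Distributed reactivity model (DRM)
#'
#' Couples a distribution of activation-energy counterparts — one of the
#' continuous peak families or a discrete [binomial_reactivity()] level set —
#' with a pre-exponential law and an overall channel weight, sufficient to
#' forward-simulate the conversion alpha(t) at any temperature as a mixture
#' of parallel, irreversible first-order reactions:
#' `alpha(t) = psi_total * (1 - Integral f^(e) exp(-k(e) t) de)` with
#' `k(e) = A(e) exp(-e * 1000 / (R T))`, where `f^` is the baseline-removed,
#' unit-normalised density. For a discrete level set the integral becomes the
#' binomially weighted sum over levels.
#'
#' @param distribution Either a named list `list(family =, f0 =, psi =, mu =,
#'   sigma =)` (family `"extreme"`, `"lorentz"`; log-normal takes `area` —
#'   or `psi` and `a_sharp` whose product is the area — `mu`, `sigma`), a
#'   [fit_ddf()] result, or a [binomial_reactivity()] object.
#' @param A Constant pre-exponential factor, min-1. Ignored when
#'   `compensation` is given.
#' @param compensation Optional compensation-law pre-exponential
#'   `list(a_mu =, phi =, mu =)` giving `A(e) = a_mu * exp(phi * (e - mu))`.
#' @param channel_weight Saturation level psi_total of the distributed
#'   channel, in (0, 1]. Conversion curves level off at this value.
#' @return An object of class `drm_model`.
#' @export
drm_model <- function(distribution, A = NULL, compensation = NULL,
                      channel_weight = 1) {
  if (inherits(distribution, "ddf_fit")) {
    distribution <- c(list(family = distribution$family),
                      as.list(distribution$estimate))
  }
  if (channel_weight <= 0 || channel_weight > 1) {
    abort("`channel_weight` must lie in (0, 1].", class = "drykin_domain_error")
  }
  preexp <- if (!is.null(compensation)) {
    stopifnot(all(c("a_mu", "phi", "mu") %in% names(compensation)),
              compensation$a_mu > 0)
    c(list(type = "compensation"), compensation)
  } else {
    if (is.null(A) || A <= 0) {
      abort("provide a positive constant `A` or a `compensation` law.",
            class = "drykin_domain_error")
    }
    list(type = "constant", A = A)
  }
  structure(list(distribution = distribution, preexp = preexp,
                 channel_weight = channel_weight),
            class = "drm_model")
}

#' @export
print.drm_model <- function(x, ...) {
  fam <- if (inherits(x$distribution, "discrete_reactivity")) {
    sprintf("binomial(N = %d, p = %.3f)",
            attr(x$distribution, "n_trials"), attr(x$distribution, "p_success"))
  } else x$distribution$family
  aa <- if (x$preexp$type == "constant") sprintf("A = %.4g min-1", x$preexp$A)
        else sprintf("A(e) = %.4g * exp(%.3g (e - %.4g))",
                     x$preexp$a_mu, x$preexp$phi, x$preexp$mu)
  cat(sprintf("<drm_model> %s, %s, channel weight %.4g\n", fam, aa,
              x$channel_weight))
  invisible(x)
}

# pre-exponential factor evaluated on the energy support
preexp_at <- function(model, ea) {
  p <- model$preexp
  if (p$type == "constant") rep(p$A, length(ea))
  else p$a_mu * exp(p$phi * (ea - p$mu))
}

# truncated support of the baseline-removed kernel: f^ >= 1e-8 of its peak,
# intersected with ea > 0 (closed forms per family)
ddf_support <- function(distribution, rel = 1e-8) {
  fam <- distribution$family
  mu <- distribution$mu; sigma <- distribution$sigma
  L <- -log(rel)
  if (fam == "extreme") {
    # left tail double-exponential, right tail exp(1 - z)
    lo <- mu - sigma * log(log(1 / rel) + 2)
    hi <- mu + sigma * (1 + L)
  } else if (fam == "lorentz") {
    half <- (sigma / 2) * sqrt(1 / rel) # 4 d^2 = sigma^2 / rel
    lo <- mu - half; hi <- mu + half
  } else if (fam == "lognormal") {
    w <- sigma * sqrt(2 * L)
    lo <- mu * exp(-w - sigma^2); hi <- mu * exp(w + sigma^2)
  } else {
    abort(sprintf("unknown ddf family '%s'", fam), class = "drykin_bad_family")
  }
  lo <- max(lo, 1e-6)
  if (hi <= lo) {
    abort("empty truncated support for the distribution.",
          class = "drykin_degenerate_distribution")
  }
  c(lo, hi)
}

# closed-form CDF and quantile function of each (baseline-removed) kernel,
# used to place quadrature panels
ddf_cdf <- function(e, distribution) {
  mu <- distribution$mu; sigma <- distribution$sigma
  switch(distribution$family,
    extreme   = exp(-exp(-(e - mu) / sigma)),
    lorentz   = 0.5 + atan(2 * (e - mu) / sigma) / pi,
    lognormal = stats::plnorm(e, log(mu), sigma))
}

ddf_quantile <- function(q, distribution) {
  mu <- distribution$mu; sigma <- distribution$sigma
  switch(distribution$family,
    extreme   = mu - sigma * log(-log(q)),
    lorentz   = mu + (sigma / 2) * tan(pi * (q - 0.5)),
    lognormal = stats::qlnorm(q, log(mu), sigma))
}

# Composite Gauss-Legendre rule after the probability transform u = F(e):
# Integral f^(e) S(e) de over the truncated support becomes
# Integral S(F^-1(u)) du / (F(hi) - F(lo)), a smooth bounded integrand in u.
# Panels are equal-probability by construction, so narrow peaks and heavy
# tails are resolved with a fixed node budget, and the weights sum to one
# exactly (the renormalisation of the truncated density).
quadrature_nodes <- function(distribution, n_panels = 64, order = 8) {
  sup <- ddf_support(distribution)
  q_lim <- ddf_cdf(sup, distribution)
  gl <- pracma::gaussLegendre(order, 0, 1)
  bounds <- seq(0, 1, length.out = n_panels + 1)
  v <- numeric(0); w_v <- numeric(0)
  for (i in seq_len(n_panels)) {
    a <- bounds[i]; b <- bounds[i + 1]
    v <- c(v, a + (b - a) * gl$x)
    w_v <- c(w_v, (b - a) * gl$w)
  }
  # smoothstep map v -> u damps the quantile map's endpoint singularities
  u <- q_lim[1] + (q_lim[2] - q_lim[1]) * v * v * (3 - 2 * v)
  w <- w_v * 6 * v * (1 - v)
  nodes <- pmin(pmax(ddf_quantile(u, distribution), sup[1]), sup[2])
  list(x = nodes, w = w / sum(w))
}

#' Forward-simulate conversion from a distributed reactivity model
#'
#' Evaluates alpha(t) at one fixed temperature. Continuous distributions are
#' integrated by composite Gauss-Legendre quadrature on the truncated support
#' (panel boundaries at density quantiles; doubling the panel count changes
#' alpha by < 1e-8). Discrete level sets are summed exactly.
#'
#' @param model A [drm_model()].
#' @param t_grid Times, minutes; must start at 0.
#' @param temperature_c,temperature_k The operating temperature (supply one).
#' @param n_panels,order Quadrature resolution (continuous only).
#' @return A [conversion_curve()].
#' @export
simulate_alpha <- function(model, t_grid, temperature_c = NULL,
                           temperature_k = NULL, n_panels = 64, order = 8) {
  stopifnot(inherits(model, "drm_model"))
  if (is.null(temperature_k)) {
    if (is.null(temperature_c)) {
      abort("supply `temperature_c` or `temperature_k`.", class = "drykin_domain_error")
    }
    temperature_k <- celsius_to_kelvin(temperature_c)
  }
  if (t_grid[1] != 0) abort("`t_grid` must start at 0.", class = "drykin_bad_curve")
  dist <- model$distribution
  if (inherits(dist, "discrete_reactivity")) {
    ea <- dist$ea_kj_mol
    w <- dist$weight
  } else {
    q <- quadrature_nodes(dist, n_panels = n_panels, order = order)
    ea <- q$x
    w <- q$w # probability-transform weights of the normalised density
  }
  k <- arrhenius_rate(preexp_at(model, ea), ea, temperature_k)
  surv <- exp(-outer(k, t_grid)) # levels x times
  alpha <- model$channel_weight * (1 - colSums(w * surv))
  alpha[1] <- 0
  conversion_curve(t_grid, pmin(pmax(alpha, 0), 1), temperature_k = temperature_k,
                   label = "simulated")
}

#' Maximum deviation between two conversion curves
#'
#' `100 * max_t |alpha_obs(t) - alpha_mod(t)|`: the maximum absolute
#' deviation on the conversion scale, expressed in percent. The modelled
#' curve is resampled onto the observed time grid by linear interpolation
#' first.
#'
#' @param observed,modeled [conversion_curve()]s.
#' @return Percent deviation (scalar).
#' @export
curve_deviation <- function(observed, modeled) {
  stopifnot(inherits(observed, "conversion_curve"),
            inherits(modeled, "conversion_curve"))
  mod_alpha <- approx(modeled$time_min, modeled$alpha, xout = observed$time_min,
                      rule = 2, ties = "ordered")$y
  100 * max(abs(observed$alpha - mod_alpha))
}

#' Fit a distributed reactivity model to multi-temperature conversion curves
#'
#' Joint least squares of simulated alpha(t) against all curves over the
#' distribution parameters (`mu`, `sigma`), the constant pre-exponential
#' factor `A` and the channel weight `psi_total`, by Levenberg-Marquardt on
#' box-bounded parameters. Starting values are data-driven unless `init`
#' is supplied: the channel weight from the observed saturation level, and
#' (`mu`, `A`) from an Arrhenius regression of the half-saturation times
#' across temperatures.
#'
#' @param curves List of [conversion_curve()]s at >= 2 distinct temperatures.
#' @param family `"extreme"`, `"lorentz"` or `"lognormal"`.
#' @param init Optional named list overriding starting values
#'   (`mu`, `sigma`, `A`, `channel_weight`).
#' @param n_panels,order Quadrature resolution passed to [simulate_alpha()].
#' @return An object of class `drm_fit`: list with `model` (the fitted
#'   [drm_model()]), `estimate`, `deviations` (per-curve percent deviation),
#'   `rss`, `converged`.
#' @export
fit_drm <- function(curves, family = c("extreme", "lorentz", "lognormal"),
                    init = NULL, n_panels = 48, order = 6) {
  family <- match.arg(family)
  curves <- lapply(curves, function(cv) {
    if (inherits(cv, "mass_loss_curve")) as_conversion_curve(cv) else cv
  })
  stopifnot(all(vapply(curves, inherits, logical(1), "conversion_curve")))
  temps <- vapply(curves, attr, numeric(1), "temperature_k")
  if (length(unique(temps)) < 2) {
    abort("need curves at >= 2 distinct temperatures.",
          class = "drykin_precondition_error")
  }
  start <- drm_init(curves, temps, family)
  if (!is.null(init)) {
    map <- c(mu = "mu", sigma = "sigma", A = "lnA", channel_weight = "psi")
    for (nm in names(init)) {
      v <- init[[nm]]
      if (nm == "A") v <- log(v)
      start[[map[[nm]]]] <- v
    }
  }
  par0 <- unlist(start)[c("mu", "sigma", "psi", "lnA")]
  lower <- c(mu = 0.5, sigma = if (family == "lognormal") 1e-4 else 1e-3,
             psi = 1e-3, lnA = log(1e-4))
  upper <- c(mu = 500, sigma = if (family == "lognormal") 3 else 100,
             psi = 1, lnA = log(1e12))
  par0 <- pmin(pmax(par0, lower), upper)

  build_model <- function(p) {
    dist <- if (family == "lognormal") {
      list(family = "lognormal", area = 1, mu = p[["mu"]], sigma = p[["sigma"]])
    } else {
      list(family = family, f0 = 0, psi = 1, mu = p[["mu"]], sigma = p[["sigma"]])
    }
    drm_model(dist, A = exp(p[["lnA"]]), channel_weight = p[["psi"]])
  }
  residual_fn <- function(p) {
    m <- tryCatch(build_model(p), error = function(e) NULL)
    if (is.null(m)) return(rep(1e3, sum(vapply(curves, nrow, integer(1)))))
    unlist(lapply(curves, function(cv) {
      sim <- simulate_alpha(m, cv$time_min, temperature_k = attr(cv, "temperature_k"),
                            n_panels = n_panels, order = order)
      sim$alpha - cv$alpha
    }))
  }
  opt <- minpack.lm::nls.lm(par = par0, fn = residual_fn,
                            lower = lower, upper = upper,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  p_hat <- opt$par
  model <- build_model(p_hat)
  devs <- purrr::map_dbl(curves, function(cv) {
    sim <- simulate_alpha(model, cv$time_min,
                          temperature_k = attr(cv, "temperature_k"),
                          n_panels = n_panels, order = order)
    curve_deviation(cv, sim)
  })
  est <- c(mu = p_hat[["mu"]], sigma = p_hat[["sigma"]],
           channel_weight = p_hat[["psi"]], A = exp(p_hat[["lnA"]]))
  converged <- opt$info %in% 1:4
  if (!converged) {
    warn(sprintf("DRM fit did not fully converge (nls.lm info = %d); best iterate returned.",
                 opt$info))
  }
  structure(list(model = model, estimate = est,
                 deviations = tibble::tibble(
                   temperature_k = temps, deviation_pct = devs),
                 rss = sum(opt$fvec^2), converged = converged),
            class = "drm_fit")
}

# Arrhenius regression of half-saturation times for starting values
drm_init <- function(curves, temps, family) {
  psi0 <- min(max(vapply(curves, function(cv) max(cv$alpha), numeric(1))), 0.999)
  k_half <- vapply(curves, function(cv) {
    target <- 0.5 * max(cv$alpha)
    th <- tryCatch(time_to_alpha(cv, target), error = function(e) NA_real_)
    if (!is.finite(th) || th <= 0) return(NA_real_)
    log(2) / th
  }, numeric(1))
  ok <- is.finite(k_half)
  if (sum(ok) >= 2) {
    fit <- lm(log(k_half[ok]) ~ I(1 / temps[ok]))
    mu0 <- max(-coef(fit)[[2]] * gas_constant() / 1000, 1)
    lnA0 <- coef(fit)[[1]]
  } else {
    mu0 <- 15; lnA0 <- log(choose_preexponential(15))
  }
  sigma0 <- if (family == "lognormal") 0.05 else max(0.05 * mu0, 0.05)
  list(mu = mu0, sigma = sigma0, psi = psi0, lnA = lnA0)
}

#' @export
print.drm_fit <- function(x, ...) {
  cat(sprintf("<drm_fit> %s family%s\n", x$model$distribution$family,
              if (x$converged) "" else " (not converged)"))
  print(round(x$estimate, 6))
  cat(sprintf("RSS = %.6g; max curve deviation = %.4g%%\n", x$rss,
              max(x$deviations$deviation_pct)))
  invisible(x)
}

#' Tidy a fitted distributed reactivity model
#'
#' @param x A [fit_drm()] result.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter; `glance()`: one-row summary with
#'   `family`, `rss`, `max.deviation.pct`, `converged`.
#' @exportS3Method generics::tidy
tidy.drm_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimate), estimate = unname(x$estimate))
}

#' @rdname tidy.drm_fit
#' @exportS3Method generics::glance
glance.drm_fit <- function(x, ...) {
  tibble::tibble(family = x$model$distribution$family, rss = x$rss,
                 max.deviation.pct = max(x$deviations$deviation_pct),
                 converged = x$converged)
}
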