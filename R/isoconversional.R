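#' Time to reach a conversion level
#'
#' Returns the time t_alpha at which the curve reaches `alpha_level`, by
#' monotone piecewise-linear interpolation after an isotonic-regression pass
#' (pool-adjacent-violators) that enforces non-decreasing alpha(t). Never
#' extrapolates: levels outside the observed range raise an error.
#'
#' @param curve A [conversion_curve()].
#' @param alpha_level Conversion level(s) in (0, 1).
#' @return Time(s) in minutes.
#' @export
time_to_alpha <- function(curve, alpha_level) {
  stopifnot(inherits(curve, "conversion_curve"))
  a <- monotone_alpha(curve$alpha)
  if (any(alpha_level > max(a)) || any(alpha_level < min(a))) {
    abort("alpha level outside the observed range; refusing to extrapolate.",
          class = "drykin_extrapolation_error")
  }
  approx(a, curve$time_min, xout = alpha_level, ties = "ordered")$y
}

# pool-adjacent-violators pass; parameter-free monotone smoother
monotone_alpha <- function(alpha) {
  if (all(diff(alpha) >= 0)) return(alpha)
  isoreg(seq_along(alpha), alpha)$yf
}

#' Conversion rate at a conversion level
#'
#' d(alpha)/dt at t_alpha, estimated by central difference quotients on the
#' (optionally smoothed) curve and interpolated to t_alpha. A non-positive
#' rate at the query point (e.g. a constant-alpha segment) raises an error
#' because the Friedman regression takes its logarithm.
#'
#' @inheritParams time_to_alpha
#' @param smooth If `TRUE`, apply a local quadratic (Savitzky-Golay style,
#'   window 5) smoothing pass before differencing. Off by default.
#' @return Rate(s), min-1.
#' @export
rate_at_alpha <- function(curve, alpha_level, smooth = FALSE) {
  stopifnot(inherits(curve, "conversion_curve"))
  if (nrow(curve) < 5) {
    abort("need at least 5 points to estimate a rate.", class = "drykin_bad_curve")
  }
  t <- curve$time_min
  a <- monotone_alpha(curve$alpha)
  if (smooth) a <- savgol5(a)
  d <- grad_nonuniform(t, a)
  t_alpha <- time_to_alpha(curve, alpha_level)
  rate <- approx(t, d, xout = t_alpha, ties = "ordered")$y
  if (any(rate <= 0)) {
    abort("non-positive rate at the query level (log undefined).",
          class = "drykin_nonpositive_rate")
  }
  rate
}

# central difference quotients on a possibly non-uniform grid
grad_nonuniform <- function(x, y) {
  n <- length(x)
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    d[i] <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
  }
  d
}

# local quadratic smoothing, window 5 (interior); ends kept as-is
savgol5 <- function(y) {
  n <- length(y)
  if (n < 5) return(y)
  out <- y
  w <- c(-3, 12, 17, 12, -3) / 35 # quadratic Savitzky-Golay weights
  for (i in 3:(n - 2)) out[i] <- sum(w * y[(i - 2):(i + 2)])
  out
}

#' Model-free activation-energy profile
#'
#' Estimates the effective activation energy Ea(alpha) from conversion curves
#' at three or more distinct fixed temperatures, without assuming a reaction
#' model. Method `"integral"` regresses -ln t_alpha on 1/T; `"friedman"`
#' (differential) regresses ln(d alpha/dt) at alpha on 1/T. In both cases
#' Ea,alpha = -slope * R. Grid levels at which fewer than three curves
#' bracket the level (or the rate is non-positive) are dropped with a warning.
#'
#' @param curves A list of [conversion_curve()]s (or [mass_loss_curve()]s,
#'   converted automatically) at distinct temperatures; at least 3.
#' @param method `"integral"` or `"friedman"`.
#' @param alpha_grid Conversion levels; default `seq(0.05, 0.95, by = 0.05)`.
#' @param smooth Passed to [rate_at_alpha()] for the Friedman method.
#' @return A tibble of class `ea_profile` with columns `alpha`, `ea_kj_mol`,
#'   `ea_se_kj_mol` and attributes `method`, `n_temperatures`.
#' @export
ea_profile <- function(curves, method = c("integral", "friedman"),
                       alpha_grid = seq(0.05, 0.95, by = 0.05),
                       smooth = FALSE) {
  method <- match.arg(method)
  curves <- lapply(curves, function(cv) {
    if (inherits(cv, "mass_loss_curve")) as_conversion_curve(cv) else cv
  })
  stopifnot(all(vapply(curves, inherits, logical(1), "conversion_curve")))
  temps <- vapply(curves, attr, numeric(1), "temperature_k")
  if (length(unique(temps)) < 3) {
    abort("need conversion curves at >= 3 distinct temperatures.",
          class = "drykin_estimation_error")
  }
  rows <- purrr::map(alpha_grid, function(al) {
    y <- vapply(curves, function(cv) {
      tryCatch({
        if (method == "integral") -log(time_to_alpha(cv, al))
        else log(rate_at_alpha(cv, al, smooth = smooth))
      }, error = function(e) NA_real_)
    }, numeric(1))
    ok <- is.finite(y)
    if (sum(ok) < 3) return(NULL)
    fit <- lm(y[ok] ~ I(1 / temps[ok]))
    slope <- coef(fit)[[2]]
    se <- tryCatch(summary(fit)$coefficients[2, 2], error = function(e) NA_real_)
    tibble::tibble(alpha = al,
                   ea_kj_mol = -slope * gas_constant() / 1000,
                   ea_se_kj_mol = if (is.finite(se)) se * gas_constant() / 1000 else 0,
                   n_used = sum(ok))
  })
  dropped <- alpha_grid[vapply(rows, is.null, logical(1))]
  if (length(dropped) > 0) {
    warn(sprintf("dropped %d alpha level(s) with < 3 usable temperatures: %s",
                 length(dropped), paste(signif(dropped, 3), collapse = ", ")))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    abort("no alpha level retained; cannot estimate a profile.",
          class = "drykin_estimation_error")
  }
  structure(out, class = c("ea_profile", class(out)),
            method = method, n_temperatures = length(temps))
}

#' Plateau average of an activation-energy profile
#'
#' Unweighted mean and sample standard deviation of Ea over the closed
#' conversion range in which the profile is nearly constant — the regime in
#' which dehydration can be treated as a single-step process.
#'
#' @param profile An [ea_profile()].
#' @param alpha_range Closed interval of conversion, e.g. `c(0.20, 0.90)`.
#' @return A one-row tibble: `mean_ea`, `sd_ea`, `alpha_min`, `alpha_max`,
#'   `n_levels`.
#' @export
plateau_average <- function(profile, alpha_range = c(0.20, 0.90)) {
  stopifnot(inherits(profile, "ea_profile"), length(alpha_range) == 2)
  sel <- profile$alpha >= alpha_range[1] & profile$alpha <= alpha_range[2]
  if (sum(sel) < 1) {
    abort("no profile levels inside `alpha_range`.", class = "drykin_range_error")
  }
  ea <- profile$ea_kj_mol[sel]
  tibble::tibble(mean_ea = mean(ea),
                 sd_ea = if (length(ea) > 1) sd(ea) else 0,
                 alpha_min = alpha_range[1], alpha_max = alpha_range[2],
                 n_levels = length(ea))
}

#' Serialize an activation-energy profile
#'
#' @param profile An [ea_profile()].
#' @param path Output CSV path (columns `alpha,ea_kj_mol,ea_se_kj_mol,method`).
#' @return `path`, invisibly.
#' @export
write_ea_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "ea_profile"))
  out <- tibble::as_tibble(profile)[, c("alpha", "ea_kj_mol", "ea_se_kj_mol")]
  out$method <- attr(profile, "method")
  readr::write_csv(out, path)
  invisible(path)
}
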