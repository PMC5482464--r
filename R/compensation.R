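#' Kinetic compensation-effect line
#'
#' Fits the empirical linear covariation `ln A = a + b * ea` between the
#' pre-exponential factor and the activation-energy counterpart across a set
#' of related reactions (ordinary least squares of ln A on ea). The slope b
#' is the compensation constant phi; the pre-exponential at a reference
#' energy mu follows as `A_mu = exp(a + b * mu)`.
#'
#' @param pairs A data frame with columns `ea` (kJ mol-1) and `A` (min-1,
#'   all positive); at least 3 rows.
#' @param group_label Optional free-text label carried on the result.
#' @return An object of class `compensation_line`: list with `intercept_a`,
#'   `slope_b`, `r_squared`, `group_label`, `n` and the underlying `lm` fit.
#' @examples
#' fit_compensation(data.frame(ea = c(10, 15, 20), A = exp(-2 + 0.5 * c(10, 15, 20))))
#' @export
fit_compensation <- function(pairs, group_label = "") {
  stopifnot(all(c("ea", "A") %in% names(pairs)))
  if (nrow(pairs) < 3) {
    abort("need at least 3 (ea, A) pairs.", class = "drykin_precondition_error")
  }
  if (any(pairs$A <= 0)) {
    abort("all pre-exponential factors must be positive.",
          class = "drykin_domain_error")
  }
  fit <- lm(log(A) ~ ea, data = pairs)
  structure(list(intercept_a = coef(fit)[[1]],
                 slope_b = coef(fit)[[2]],
                 r_squared = summary(fit)$r.squared,
                 group_label = group_label,
                 n = nrow(pairs),
                 fit = fit),
            class = "compensation_line")
}

#' @export
print.compensation_line <- function(x, ...) {
  cat(sprintf("<compensation_line> %s: ln A = %.4f + %.4f * ea (R^2 = %.4f, n = %d)\n",
              x$group_label, x$intercept_a, x$slope_b, x$r_squared, x$n))
  invisible(x)
}

#' @rdname fit_compensation
#' @param x A `compensation_line`.
#' @param mu Reference energy, kJ mol-1.
#' @return `preexponential_at()`: A_mu = exp(a + b * mu), min-1.
#' @export
preexponential_at <- function(x, mu) {
  stopifnot(inherits(x, "compensation_line"))
  exp(x$intercept_a + x$slope_b * mu)
}

#' Tidy a compensation line
#'
#' @param x A [fit_compensation()] result.
#' @param ... Unused.
#' @return `tidy()`: rows for intercept and slope; `glance()`: one-row tibble
#'   with `r.squared`, `nobs`, `group`.
#' @exportS3Method generics::tidy
tidy.compensation_line <- function(x, ...) {
  tibble::tibble(term = c("intercept_a", "slope_b"),
                 estimate = c(x$intercept_a, x$slope_b),
                 std.error = summary(x$fit)$coefficients[, 2])
}

#' @rdname tidy.compensation_line
#' @exportS3Method generics::glance
glance.compensation_line <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, nobs = x$n, group = x$group_label)
}

#' Group compensation lines into kinetic branches
#'
#' Single-linkage grouping of fitted `ln A = a + b * ea` lines by their
#' relative distance in (slope, intercept) space: two lines are linked when
#' both their slopes and intercepts differ by less than `tolerance`
#' (relative to the median magnitude of each coefficient). Lines that remain
#' unlinked form their own branch — the algorithmic counterpart of judging
#' "almost overlapping" lines on a compensation plot.
#'
#' @param lines A list of [fit_compensation()] results (>= 2).
#' @param tolerance Relative tolerance (default 0.05, i.e. 5%).
#' @return A tibble with one row per line: `group_label`, `slope_b`,
#'   `intercept_a`, `branch` (integer label).
#' @export
detect_branches <- function(lines, tolerance = 0.05) {
  stopifnot(length(lines) >= 2,
            all(vapply(lines, inherits, logical(1), "compensation_line")))
  slopes <- vapply(lines, `[[`, numeric(1), "slope_b")
  inters <- vapply(lines, `[[`, numeric(1), "intercept_a")
  s_ref <- max(stats::median(abs(slopes)), 1e-12)
  i_ref <- max(stats::median(abs(inters)), 1e-12)
  # chebyshev distance in tolerance-scaled coordinates; cut at 1
  pts <- cbind(slopes / (tolerance * s_ref), inters / (tolerance * i_ref))
  d <- dist(pts, method = "maximum")
  branch <- if (max(d) == 0) rep(1L, length(lines)) else {
    cutree(hclust(d, method = "single"), h = 1)
  }
  tibble::tibble(
    group_label = vapply(lines, `[[`, character(1), "group_label"),
    slope_b = slopes, intercept_a = inters,
    branch = as.integer(branch))
}
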