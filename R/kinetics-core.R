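#' drykin: distributed reactivity modelling of isothermal dehydration
#'
#' Tools for analysing isothermal mass-loss curves recorded at several fixed
#' operating temperatures: model-free isoconversional estimation of the
#' effective activation energy, derivation and fitting of the density
#' distribution of activation-energy counterparts, forward simulation of the
#' distributed reactivity model (DAEM), kinetic compensation-effect analysis,
#' and a synthetic-data generator with known ground truth.
#'
#' @keywords internal
#' @importFrom rlang .data abort warn %||%
#' @importFrom generics tidy glance augment
#' @importFrom ggplot2 autoplot
#' @importFrom stats lm coef approx sd setNames qnorm rnorm isoreg dist hclust cutree
#' @importFrom utils head tail
"_PACKAGE"

#' Physical constants and unit helpers
#'
#' `gas_constant()` returns the molar gas constant R in J mol-1 K-1.
#' `celsius_to_kelvin()` converts operating temperatures given in degrees
#' Celsius to absolute temperature.
#'
#' @param temp_c Temperature(s) in degrees Celsius.
#' @return `gas_constant()`: a scalar; `celsius_to_kelvin()`: numeric vector in K.
#' @examples
#' celsius_to_kelvin(c(60, 105, 130))
#' @export
gas_constant <- function() 8.314

#' @rdname gas_constant
#' @export
celsius_to_kelvin <- function(temp_c) temp_c + 273.15

#' Conversion fraction of a dehydrating specimen
#'
#' The extent of reaction alpha = (m0 - mt) / (m0 - m_inf), where `m0` is the
#' initial mass, `mt` the mass at time t and `m_inf` the final ("equilibrium")
#' mass. Values that fall outside \[0, 1\] by no more than `tol` (measurement
#' scatter) are clipped back to the interval; larger excursions indicate an
#' inconsistent measurement and raise an error.
#'
#' @param m0 Initial specimen mass, grams.
#' @param mt Mass at the query time, grams (vectorised).
#' @param m_inf Final equilibrium mass, grams. Must satisfy `m_inf < m0`.
#' @param tol Absolute clip tolerance on the conversion scale (default 0.02).
#' @return Dimensionless conversion fraction(s) in \[0, 1\].
#' @examples
#' conversion_fraction(10, 7, 4) # 0.5
#' @export
conversion_fraction <- function(m0, mt, m_inf, tol = 0.02) {
  if (any(m0 <= m_inf)) {
    abort("degenerate specimen: `m0` must exceed `m_inf`.",
          class = "drykin_degenerate_specimen")
  }
  alpha <- (m0 - mt) / (m0 - m_inf)
  if (any(alpha < -tol) || any(alpha > 1 + tol)) {
    abort(
      "inconsistent measurement: conversion outside [0, 1] by more than the clip tolerance.",
      class = "drykin_inconsistent_measurement"
    )
  }
  pmin(pmax(alpha, 0), 1)
}

#' Arrhenius rate constant
#'
#' k = A exp(-ea * 1000 / (R T)) with the activation-energy counterpart `ea`
#' in kJ mol-1 and R in J mol-1 K-1. The factor 1000 converting kJ to J is
#' applied here and nowhere else in the package.
#'
#' @param A Pre-exponential factor, min-1 (> 0).
#' @param ea Activation-energy counterpart, kJ mol-1.
#' @param temperature_k Absolute temperature, K (> 0).
#' @return Rate constant(s), min-1.
#' @examples
#' arrhenius_rate(2, 0, 333.15) # zero-barrier limit: returns A
#' @export
arrhenius_rate <- function(A, ea, temperature_k) {
  if (any(temperature_k <= 0)) {
    abort("`temperature_k` must be positive.", class = "drykin_domain_error")
  }
  if (any(A <= 0)) abort("`A` must be positive.", class = "drykin_domain_error")
  A * exp(-ea * 1000 / (gas_constant() * temperature_k))
}

#' Isothermal first-order conversion
#'
#' alpha(t) = 1 - exp(-k t) for a single irreversible first-order reaction at
#' constant temperature.
#'
#' @param k Rate constant, min-1 (>= 0).
#' @param t Time(s), minutes (>= 0).
#' @return Conversion fraction(s) in \[0, 1).
#' @export
first_order_alpha <- function(k, t) {
  if (any(k < 0) || any(t < 0)) {
    abort("`k` and `t` must be non-negative.", class = "drykin_domain_error")
  }
  1 - exp(-k * t)
}

#' Pre-exponential factor completing conversion within a time window
#'
#' Chooses A so that a single first-order reaction with activation energy `ea`
#' reaches `alpha_target` after `t_complete` minutes at the lowest operating
#' temperature — mirroring oven experiments whose duration is set so the
#' specimen effectively equilibrates within the measurement window.
#'
#' @param ea Activation-energy counterpart, kJ mol-1.
#' @param temperature_c Lowest operating temperature, degrees C (default 60).
#' @param t_complete Window length, minutes (default 30).
#' @param alpha_target Conversion to reach by `t_complete` (default 0.98).
#' @return Pre-exponential factor, min-1.
#' @export
choose_preexponential <- function(ea, temperature_c = 60, t_complete = 30,
                                  alpha_target = 0.98) {
  k_needed <- -log(1 - alpha_target) / t_complete
  k_needed / exp(-ea * 1000 / (gas_constant() * celsius_to_kelvin(temperature_c)))
}

#' Mass-loss curve at one fixed operating temperature
#'
#' Bundles one specimen's (time, mass) series with its operating temperature
#' and initial/equilibrium masses as a tibble of class `mass_loss_curve` with
#' columns `time_min` and `mass_g`; the metadata travel as attributes.
#'
#' @param times Sampling times, minutes; strictly increasing, first entry 0.
#' @param masses Recorded masses, grams; same length as `times`.
#' @param temperature_c Operating temperature, degrees Celsius.
#' @param m_inf Final equilibrium mass, grams; must be below the initial mass.
#' @param label Free-text specimen identifier.
#' @param tol Mass tolerance (grams) allowed outside \[m_inf, m0\].
#' @return A `mass_loss_curve` tibble.
#' @export
mass_loss_curve <- function(times, masses, temperature_c, m_inf, label = "",
                            tol = NULL) {
  stopifnot(length(times) == length(masses), length(times) >= 2)
  if (any(diff(times) <= 0)) {
    abort("`times` must be strictly increasing.", class = "drykin_bad_curve")
  }
  if (times[1] != 0) abort("`times` must start at 0.", class = "drykin_bad_curve")
  m0 <- masses[1]
  if (m_inf >= m0) {
    abort("degenerate specimen: `m_inf` must be below the initial mass.",
          class = "drykin_degenerate_specimen")
  }
  tol <- tol %||% (0.02 * (m0 - m_inf))
  if (any(masses > m0 + tol) || any(masses < m_inf - tol)) {
    abort("masses stray outside [m_inf, m0] beyond tolerance.",
          class = "drykin_inconsistent_measurement")
  }
  out <- tibble::tibble(time_min = as.numeric(times), mass_g = as.numeric(masses))
  structure(out,
            class = c("mass_loss_curve", class(out)),
            temperature_c = temperature_c,
            temperature_k = celsius_to_kelvin(temperature_c),
            m0 = m0, m_inf = m_inf, label = label)
}

#' @export
print.mass_loss_curve <- function(x, ...) {
  cat(sprintf(
    "<mass_loss_curve> %s at %.2f degC: %d readings, m0 = %.4f g, m_inf = %.4f g\n",
    attr(x, "label"), attr(x, "temperature_c"), nrow(x),
    attr(x, "m0"), attr(x, "m_inf")))
  NextMethod()
}

#' Conversion curve at one fixed temperature
#'
#' A tibble of class `conversion_curve` with columns `time_min` and `alpha`,
#' carrying the absolute temperature as an attribute. Constructed directly
#' from vectors or from a [mass_loss_curve()] via [as_conversion_curve()].
#'
#' @param times Times, minutes, strictly increasing from 0.
#' @param alphas Conversion fractions in \[0, 1\], `alphas[1] == 0`.
#' @param temperature_k Absolute temperature, K.
#' @param label Specimen identifier.
#' @return A `conversion_curve` tibble.
#' @export
conversion_curve <- function(times, alphas, temperature_k, label = "") {
  stopifnot(length(times) == length(alphas))
  if (any(diff(times) <= 0)) {
    abort("`times` must be strictly increasing.", class = "drykin_bad_curve")
  }
  if (abs(alphas[1]) > 1e-12) {
    abort("`alphas` must start at 0.", class = "drykin_bad_curve")
  }
  if (any(alphas < -1e-12) || any(alphas > 1 + 1e-12)) {
    abort("`alphas` must lie in [0, 1].", class = "drykin_bad_curve")
  }
  out <- tibble::tibble(time_min = as.numeric(times), alpha = as.numeric(alphas))
  structure(out, class = c("conversion_curve", class(out)),
            temperature_k = temperature_k, label = label)
}

#' @rdname conversion_curve
#' @param curve A [mass_loss_curve()].
#' @param tol Clip tolerance passed to [conversion_fraction()].
#' @export
as_conversion_curve <- function(curve, tol = 0.02) {
  stopifnot(inherits(curve, "mass_loss_curve"))
  alphas <- conversion_fraction(attr(curve, "m0"), curve$mass_g,
                                attr(curve, "m_inf"), tol = tol)
  alphas[1] <- 0
  conversion_curve(curve$time_min, alphas,
                   temperature_k = attr(curve, "temperature_k"),
                   label = attr(curve, "label"))
}

#' @export
print.conversion_curve <- function(x, ...) {
  cat(sprintf("<conversion_curve> %s at %.2f K: %d points, alpha in [%.3f, %.3f]\n",
              attr(x, "label"), attr(x, "temperature_k"), nrow(x),
              min(x$alpha), max(x$alpha)))
  NextMethod()
}

#' Estimate the equilibrium mass from the curve tail
#'
#' The equilibrium ("final") mass is normally measured directly; when it is
#' not available, the mean of the last readings can stand in for it,
#' provided the curve has effectively levelled off. Off by default in every
#' analysis path — supply the measured `m_inf` where it exists.
#'
#' @param curve A [mass_loss_curve()].
#' @param tail_fraction Fraction of trailing readings to average (default 0.2).
#' @return Estimated equilibrium mass, grams.
#' @export
estimate_m_inf <- function(curve, tail_fraction = 0.2) {
  stopifnot(inherits(curve, "mass_loss_curve"),
            tail_fraction > 0, tail_fraction <= 1)
  n <- nrow(curve)
  k <- max(ceiling(tail_fraction * n), 2)
  mean(curve$mass_g[(n - k + 1):n])
}

#' Read and write mass-loss curve CSV files
#'
#' One file per (specimen, temperature): commented header lines
#' `# key: value` holding `temperature_c`, `m_inf` and `label`, followed by
#' columns `time_min,mass_g`.
#'
#' @param path File path.
#' @return `read_mass_loss_csv()` returns a [mass_loss_curve()];
#'   `write_mass_loss_csv()` returns `path` invisibly.
#' @export
read_mass_loss_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (l in meta_lines) {
    kv <- sub("^#\\s*", "", l)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  for (k in c("temperature_c", "m_inf")) {
    if (is.null(meta[[k]])) {
      abort(sprintf("missing `%s` in header comments of %s", k, path),
            class = "drykin_bad_file")
    }
  }
  dat <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  mass_loss_curve(dat$time_min, dat$mass_g,
                  temperature_c = as.numeric(meta$temperature_c),
                  m_inf = as.numeric(meta$m_inf),
                  label = meta$label %||% "")
}

#' @rdname read_mass_loss_csv
#' @param curve A [mass_loss_curve()].
#' @export
write_mass_loss_csv <- function(curve, path) {
  stopifnot(inherits(curve, "mass_loss_curve"))
  header <- c(
    sprintf("# temperature_c: %.10g", attr(curve, "temperature_c")),
    sprintf("# m_inf: %.10g", attr(curve, "m_inf")),
    sprintf("# label: %s", attr(curve, "label")),
    "time_min,mass_g")
  body <- sprintf("%.10g,%.10g", curve$time_min, curve$mass_g)
  writeLines(c(header, body), path)
  invisible(path)
}
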