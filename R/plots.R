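#' Plot methods
#'
#' `autoplot()` methods returning ggplot objects: activation-energy profiles
#' with per-level regression uncertainty, experimental density points with a
#' fitted family overlaid, conversion/mass-loss curves, and DRM fits
#' (observed points with modelled curves).
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name drykin-autoplot
NULL

#' @rdname drykin-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.ea_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$alpha, y = .data$ea_kj_mol)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$ea_kj_mol - .data$ea_se_kj_mol,
      ymax = .data$ea_kj_mol + .data$ea_se_kj_mol)) +
    ggplot2::labs(x = expression(alpha),
                  y = expression(E[a] ~ "(kJ" ~ mol^-1 * ")"),
                  title = sprintf("%s isoconversional profile", attr(object, "method"))) +
    ggplot2::theme_minimal()
}

#' @rdname drykin-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.ddf_fit <- function(object, ...) {
  dat <- object$data
  grid <- tibble::tibble(
    ea_kj_mol = seq(min(dat$ea_kj_mol), max(dat$ea_kj_mol), length.out = 400))
  grid$density <- ddf_density(grid$ea_kj_mol, object$family,
                              as.list(object$estimate))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$ea_kj_mol, y = .data$density)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = expression(epsilon[a] ~ "(kJ" ~ mol^-1 * ")"),
                  y = expression(f(epsilon[a]) ~ "(mol" ~ kJ^-1 * ")"),
                  title = sprintf("%s density fit", object$family)) +
    ggplot2::theme_minimal()
}

#' @rdname drykin-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.conversion_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time_min, y = .data$alpha)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (min)", y = expression(alpha),
                  title = sprintf("%.1f K", attr(object, "temperature_k"))) +
    ggplot2::theme_minimal()
}

#' @rdname drykin-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.mass_loss_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time_min, y = .data$mass_g)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (min)", y = "mass (g)",
                  title = sprintf("%s at %.0f degC", attr(object, "label"),
                                  attr(object, "temperature_c"))) +
    ggplot2::theme_minimal()
}

#' Compensation-effect plot
#'
#' Draws the fitted `ln A = a + b * ea` lines over a shared energy range,
#' coloured by branch when a branch assignment is given.
#'
#' @param lines List of [fit_compensation()] results.
#' @param ea_range Energy range (kJ mol-1) over which to draw the lines.
#' @param branches Optional result of [detect_branches()].
#' @return A ggplot.
#' @export
plot_compensation <- function(lines, ea_range = c(5, 30), branches = NULL) {
  dat <- purrr::imap_dfr(lines, function(l, i) {
    tibble::tibble(
      group = if (nzchar(l$group_label)) l$group_label else paste0("line", i),
      ea = seq(ea_range[1], ea_range[2], length.out = 50),
      ln_A = l$intercept_a + l$slope_b *
        seq(ea_range[1], ea_range[2], length.out = 50))
  })
  if (!is.null(branches)) {
    dat <- dplyr::left_join(
      dat, dplyr::transmute(branches,
                            group = .data$group_label,
                            branch = factor(.data$branch)),
      by = "group")
    p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$ea, y = .data$ln_A,
                                           group = .data$group,
                                           colour = .data$branch))
  } else {
    p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$ea, y = .data$ln_A,
                                           group = .data$group,
                                           colour = .data$group))
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = expression(epsilon[a] ~ "(kJ" ~ mol^-1 * ")"),
                  y = "ln A") +
    ggplot2::theme_minimal()
}
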