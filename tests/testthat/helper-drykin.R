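# a DRM whose distribution is a single activation-energy level: a degenerate
# binomial level set with all mass on level 0
single_reaction_model <- function(ea, A = NULL, channel_weight = 1) {
  drm_model(binomial_reactivity(1, 0, grid_origin = ea),
            A = A %||% choose_preexponential(ea),
            channel_weight = channel_weight)
}

# noiseless single-first-order conversion curves built directly from the
# closed form (independent of the simulation engine)
first_order_curves <- function(ea, A, temps_k, dt = 0.5, duration = 30) {
  t_grid <- seq(0, duration, by = dt)
  lapply(temps_k, function(Tk) {
    k <- A * exp(-ea * 1000 / (8.314 * Tk))
    conversion_curve(t_grid, 1 - exp(-k * t_grid), temperature_k = Tk)
  })
}

paper_temps_k <- c(333.15, 378.15, 403.15)

# log-spaced time grid resolving fast kinetics down to sub-second scales
log_time_grid <- function(t_min = 1e-5, t_max = 30, n = 400) {
  c(0, exp(seq(log(t_min), log(t_max), length.out = n)))
}

`%||%` <- rlang::`%||%`
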