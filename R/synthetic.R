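#' Configuration for a synthetic isothermal drying experiment
#'
#' Describes one emulated oven experiment: a ground-truth [drm_model()], the
#' set of fixed operating temperatures, the measurement window and sampling
#' interval, the specimen mass scale, and the measurement-noise level. The
#' defaults mirror the conditions of multi-temperature isothermal drying of
#' maize seedling parts: operating temperatures 60/105/130 degC, windows up
#' to 30 min, initial specimen masses of a few grams, an equilibrium residue
#' around 30% of the initial mass (dry-matter content), and small
#' multiplicative balance noise with readings recorded as the average of
#' three replicate runs.
#'
#' @param true_model A [drm_model()] (continuous or discrete distribution).
#' @param temperatures Operating temperatures, degrees C; >= 3 distinct
#'   values for isoconversional use. Default `c(60, 105, 130)`.
#' @param duration Window length, minutes (default 30).
#' @param sampling_interval Reading interval, minutes (default 0.5).
#' @param m0 Initial mass, grams; `NULL` draws one uniformly from
#'   1.5566-8.7066 g (the specimen mass range).
#' @param m_inf_fraction Equilibrium residue as a fraction of `m0`
#'   (default 0.3).
#' @param noise_rel Relative SD of one balance reading (default 0.005).
#' @param n_replicates Replicate runs averaged into each recorded curve
#'   (default 3).
#' @param seed Integer seed; mandatory, used for every stochastic draw.
#' @param label Specimen label prefix.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(true_model, temperatures = c(60, 105, 130),
                             duration = 30, sampling_interval = 0.5,
                             m0 = NULL, m_inf_fraction = 0.3,
                             noise_rel = 0.005, n_replicates = 3,
                             seed, label = "synthetic") {
  stopifnot(inherits(true_model, "drm_model"))
  if (missing(seed) || !is.numeric(seed)) {
    abort("`seed` is mandatory for any stochastic draw.", class = "drykin_domain_error")
  }
  if (length(unique(temperatures)) != length(temperatures)) {
    abort("`temperatures` must be distinct.", class = "drykin_domain_error")
  }
  if (noise_rel < 0) abort("`noise_rel` must be >= 0.", class = "drykin_domain_error")
  stopifnot(m_inf_fraction > 0, m_inf_fraction < 1, n_replicates >= 1)
  structure(list(true_model = true_model, temperatures = temperatures,
                 duration = duration, sampling_interval = sampling_interval,
                 m0 = m0, m_inf_fraction = m_inf_fraction,
                 noise_rel = noise_rel, n_replicates = n_replicates,
                 seed = as.integer(seed), label = label),
            class = "synthetic_config")
}

# evaluate expr under a seed, leaving the caller's RNG stream untouched
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic multi-temperature drying experiment
#'
#' Simulates alpha(t) from the ground-truth model at each configured
#' temperature, maps conversion to mass via
#' `m(t) = m0 - alpha(t) * (m0 - m_inf)`, and emulates the recording
#' protocol: each reported mass is the average of `n_replicates` replicate
#' readings carrying multiplicative Gaussian noise of SD
#' `noise_rel * m(t)`, clamped to the physical range \[m_inf, m0\]. The
#' initial mass (t = 0) is recorded exactly — specimens are weighed before
#' entering the oven. Output is deterministic given the seed.
#'
#' @param config A [synthetic_config()].
#' @return A named list of [mass_loss_curve()]s, one per temperature, with
#'   the configuration attached as attribute `config`.
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_local_seed(config$seed, {
    m0 <- config$m0 %||% stats::runif(1, 1.5566, 8.7066)
    m_inf <- config$m_inf_fraction * m0
    t_grid <- seq(0, config$duration, by = config$sampling_interval)
    psi <- config$true_model$channel_weight
    curves <- lapply(config$temperatures, function(tc) {
      sim <- simulate_alpha(config$true_model, t_grid, temperature_c = tc)
      m_true <- m0 - sim$alpha * (m0 - m_inf)
      if (config$noise_rel > 0) {
        reads <- replicate(config$n_replicates, {
          r <- m_true * (1 + stats::rnorm(length(m_true), sd = config$noise_rel))
          pmin(pmax(r, m_inf), m0)
        })
        m_rec <- rowMeans(reads)
      } else {
        m_rec <- m_true
      }
      m_rec[1] <- m0
      mass_loss_curve(t_grid, m_rec, temperature_c = tc, m_inf = m_inf,
                      label = sprintf("%s_T%g", config$label, tc),
                      tol = max(0.02 * (m0 - m_inf),
                                4 * config$noise_rel * m0))
    })
    names(curves) <- sprintf("T%g", config$temperatures)
    top <- simulate_alpha(config$true_model, t_grid,
                          temperature_c = max(config$temperatures))
    if (max(top$alpha) < 0.95 * psi) {
      warn(paste("conversion does not reach 95% of the channel weight at the",
                 "highest temperature within the window; recovery ranges will truncate."))
    }
    structure(curves, config = config)
  })
}

.preset_registry <- function() {
  t4 <- fixture_table("ddf_params_continuous")
  t5 <- fixture_table("ddf_params_lognormal")
  cont <- function(hybrid, part) {
    row <- t4[t4$hybrid == hybrid & t4$part == part, ]
    dist <- list(family = row$family, f0 = row$f0, psi = row$psi,
                 mu = row$mu, sigma = row$sigma)
    drm_model(dist, A = choose_preexponential(row$mu),
              channel_weight = row$psi)
  }
  lnorm <- function(conc) {
    row <- t5[abs(t5$concentration_m - conc) < 1e-3 * conc, ]
    dist <- list(family = "lognormal", area = row$psi * row$a_sharp,
                 mu = row$mu, sigma = row$sigma)
    drm_model(dist, A = choose_preexponential(row$mu),
              channel_weight = row$psi)
  }
  list(
    zp434_control_radicle = function() cont("ZP434", "radicle"),
    zp434_control_plumule = function() cont("ZP434", "plumule"),
    zp434_control_ros     = function() cont("ZP434", "ros"),
    zp704_control_radicle = function() cont("ZP704", "radicle"),
    zp704_control_plumule = function() cont("ZP704", "plumule"),
    zp704_control_ros     = function() cont("ZP704", "ros"),
    zp704_radicle_c9  = function() lnorm(5.20e-09),
    zp704_radicle_c12 = function() lnorm(5.20e-12),
    zp704_radicle_c15 = function() lnorm(5.20e-15),
    zp434_radicle_c9_discrete = function() {
      # most probable level at 23.3 kJ/mol: origin 19.3, N = 8, p = 0.5, unit grid
      drm_model(binomial_reactivity(8, 0.5, grid_origin = 19.3, grid_spacing = 1),
                A = choose_preexponential(23.3), channel_weight = 1)
    })
}

#' Packaged ground-truth model presets
#'
#' Builds a [drm_model()] from the packaged parameter tables of fitted
#' density distributions, keyed by (hybrid, seedling part, treatment):
#' Extreme-family controls for ZP434, Lorentz-family controls for ZP704,
#' Log-normal models for the ZP704 radicle under three 24-epibrassinolide
#' concentrations, and one discrete binomial preset. The constant
#' pre-exponential factor is set by [choose_preexponential()] at the
#' distribution centre so conversion completes within the 30-min window at
#' the lowest operating temperature.
#'
#' @param name One of `"zp434_control_radicle"`, `"zp434_control_plumule"`,
#'   `"zp434_control_ros"`, `"zp704_control_radicle"`,
#'   `"zp704_control_plumule"`, `"zp704_control_ros"`, `"zp704_radicle_c9"`,
#'   `"zp704_radicle_c12"`, `"zp704_radicle_c15"`,
#'   `"zp434_radicle_c9_discrete"`.
#' @return A [drm_model()].
#' @examples
#' drm_preset("zp434_control_radicle")
#' @export
drm_preset <- function(name) {
  reg <- .preset_registry()
  if (!name %in% names(reg)) {
    abort(sprintf("unknown preset '%s'; available: %s", name,
                  paste(names(reg), collapse = ", ")),
          class = "drykin_lookup_error")
  }
  reg[[name]]()
}

#' Packaged fixture tables
#'
#' Reference tables bundled with the package, parsed from CSV with values
#' exactly as printed in the source study: seedling sugar contents
#' (`"sugars"`, mg kg-1 dry matter), principal dimensions
#' (`"morphometrics"`, mm), mineral composition (`"minerals"`, mg kg-1),
#' and the fitted density-distribution parameter sets
#' (`"ddf_params_continuous"` for the Extreme/Lorentz control fits,
#' `"ddf_params_lognormal"` for the Log-normal treatment fits). These are
#' lookup data; no analysis is defined on the first three.
#'
#' @param name Table tag (see above).
#' @return A tibble.
#' @examples
#' fixture_table("ddf_params_lognormal")
#' @export
fixture_table <- function(name) {
  files <- c(sugars = "table_sugars.csv",
             morphometrics = "table_morphometrics.csv",
             minerals = "table_minerals.csv",
             ddf_params_continuous = "table_ddf_continuous.csv",
             ddf_params_lognormal = "table_ddf_lognormal.csv")
  if (!name %in% names(files)) {
    abort(sprintf("unknown fixture '%s'; available: %s", name,
                  paste(names(files), collapse = ", ")),
          class = "drykin_lookup_error")
  }
  path <- system.file("extdata", files[[name]], package = "drykin")
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_guess()))
}
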