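# drykin

Distributed reactivity modelling of isothermal dehydration kinetics.

## The problem

When a plant specimen (here: radicle, plumule, or rest-of-seed of maize
seedlings) is dried at a fixed oven temperature, its mass-loss curve carries
kinetic information about how strongly water is bound to the tissue. The
conversion fraction

    alpha(t) = (m0 - m(t)) / (m0 - m_inf)

normalises the curve between 0 (initial mass m0) and 1 (equilibrium mass
m_inf). Water is not held by a single kind of site: desorption proceeds as a
large ensemble of independent, parallel, irreversible first-order reactions
whose activation-energy counterparts epsilon_a are spread by a density
f(epsilon_a) — the distributed activation energy model (DAEM). At a fixed
absolute temperature T,

    alpha(t) = psi * [ 1 - Integral f(e) exp( -A(e) exp(-1000 e / (R T)) t ) de ]

with e in kJ mol^-1, R = 8.314 J mol^-1 K^-1, A the pre-exponential factor
(min^-1) and psi the overall contribution of the distributed channel. For a
discrete level set the integral becomes a binomially weighted sum
B(i; N, p) over energies e_i = e0 + i * de.

The package implements the full analysis chain for curves recorded at three
or more fixed temperatures:

* **Model-free (isoconversional) estimation** of the effective activation
  energy Ea(alpha): the integral form regresses -ln t_alpha on 1/T, the
  differential (Friedman) form regresses ln(dalpha/dt)_alpha on 1/T; in both
  cases Ea,alpha = -slope * R. Plateau averaging summarises the range where
  Ea is nearly constant.
* **Experimental density distribution** of activation-energy counterparts,
  f_exp(Ea) = dalpha/dEa along the profile, and non-linear least-squares
  fits of the Extreme (Gumbel), Lorentz (Cauchy) and Log-normal peak
  families with RSS and reduced chi-square statistics, plus the discrete
  binomial reactivity model and its Poisson approximation.
* **Forward simulation** of alpha(t) from any fitted or preset model
  (adaptive composite Gauss-Legendre quadrature after a probability
  transform), curve-deviation scoring, and joint multi-temperature DRM
  refitting.
* **Kinetic compensation analysis**: the empirical line ln A = a + b * e
  and single-linkage grouping of lines into kinetic branches.
* **Synthetic experiments** with known ground truth emulating the oven
  protocol (60/105/130 degC, 30-min windows, gram-scale specimens,
  triplicate-averaged balance readings with multiplicative noise), plus the
  published parameter tables bundled as fixtures.

## Worked example

Build the packaged ground-truth model for the ZP434 control radicle
(an Extreme density centred at 15.74 kJ mol^-1), emulate a noisy oven
experiment at 60/105/130 degC, and recover the kinetics:

```r
library(drykin)

model <- drm_preset("zp434_control_radicle")
model
#> <drm_model> extreme, A = 38.3 min-1, channel weight 0.3447

curves <- generate_experiment(synthetic_config(model, seed = 1))
profile <- ea_profile(curves, method = "integral",
                      alpha_grid = seq(0.02, 0.34, 0.02))
plateau_average(profile, c(0.05, 0.30))
#> # A tibble: 1 x 5
#>   mean_ea sd_ea alpha_min alpha_max n_levels
#>     <dbl> <dbl>     <dbl>     <dbl>    <int>
#> 1    15.9 0.752      0.05       0.3       12

refit <- fit_drm(lapply(curves, as_conversion_curve), family = "extreme")
refit$deviations
#> # A tibble: 3 x 2
#>   temperature_k deviation_pct
#>           <dbl>         <dbl>
#> 1          333.         0.766
#> 2          378.         0.894
#> 3          403.         0.890
```

The plateau mean (15.9 kJ mol^-1) recovers the generating centre within the
regression scatter, and the refitted model tracks every noisy curve to
better than 1% conversion. The same chain applied to noiseless curves from
the Lorentz-family preset (centre 22.11 kJ mol^-1, FWHM 1.39) recovers the
density itself:

```r
model <- drm_preset("zp704_control_radicle")
tg <- c(0, exp(seq(log(1e-4), log(30), length.out = 400)))
curves <- lapply(c(60, 105, 130),
                 function(tc) simulate_alpha(model, tg, temperature_c = tc))
profile <- ea_profile(curves, "integral", alpha_grid = seq(0.02, 0.98, 0.02))
fit <- fit_ddf(experimental_ddf(profile), family = "lorentz")
tidy(fit)
#> # A tibble: 4 x 3
#>   term  estimate std.error
#>   <chr>    <dbl>     <dbl>
#> 1 f0       0       0.00576
#> 2 psi      0.603   0.0231
#> 3 mu      22.0     0.00515
#> 4 sigma    1.06    0.0302
```

The centre comes back at 22.0 kJ mol^-1; the fitted width is somewhat below
the generating value because the isothermal reaction front smears the
derived density (see the methods vignette). `autoplot()` methods exist for
curves, profiles, density fits; `tidy()`/`glance()` for all fitted objects.

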