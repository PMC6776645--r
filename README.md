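# cubofuse

Quantitative single-particle analysis of cubosome–bilayer fusion from
TIRF microscopy image stacks.

Cubosomes — nanoparticles of a bicontinuous cubic lipid phase — are
drug-delivery vehicles whose interaction with membranes can be watched
one particle at a time: on a supported lipid bilayer (SLB) under total
internal reflection fluorescence (TIRF) illumination, a dye-loaded
particle diffuses to the surface, docks, and fuses, leaving a spreading
fluorescent footprint while its peak intensity decays. `cubofuse`
implements the finite-source diffusion model that explains the decay,
a seeded synthetic-movie generator for validating every analysis stage,
and the full measurement pipeline: spot tracking and
mean-squared-displacement sizing, fusion-event segmentation and
power-law fitting, and bilayer-formation (surface coverage) kinetics.

## The model in brief

For a docked particle of side length $R$, density $\rho$, feeding a
bilayer of height $h$ where its lipid diffuses with coefficient $D$,
mass balance reads $\rho R^2 \dot R = -D h\,\delta c$. With a 2-D
point-source peak concentration $c_\mathrm{max} \sim 1/t$, no dye
outside the footprint, and a footprint diameter $L \sim \sqrt t$, the
driving gradient scales as $\delta c \sim t^{-3/2}$, which integrates to

$$R^3(t) = R_0^3 - 6C\,(t_\mathrm{start}^{-1/2} - t^{-1/2}), \qquad
C = \frac{2 A D h}{B \rho}.$$

On the self-similar branch $R(t) \propto t^{-1/6}$, so the peak
intensity of a fusing particle ($I_\mathrm{max} \propto R$) decays as
$I = a\,t^{-n}$ with $n = 1/6$ — in sharp contrast to $n = 1$ for a
point release of dye. Fitting $n$ per event therefore discriminates
whole-particle fusion from dye dumping.

## Worked example

Check the model's three scaling laws against their numerical oracles:

```r
library(cubofuse)
model_check()
#>                      check  expected  measured   tol pass
#> 1 point-source c_max decay 1.0000000 0.9971976 2e-02 TRUE
#> 2            delta_c decay 1.5000000 1.5000000 1e-06 TRUE
#> 3 self-similar I_max decay 0.1666667 0.1666667 1e-03 TRUE
```

The point-release exponent (row 1) is measured from an explicit
finite-difference solution of the 2-D diffusion equation; the other two
are evaluated on the model curves. Render one synthetic fusion event and
recover its decay law through the extraction and fitting machinery:

```r
scene <- tirf_scene(dim = c(64, 64), n_frames = 250, read_sigma = 0,
                    seed = 3)
event <- tirf_event(landing_time = 0.3, position = c(5.07, 5.11),
                    a = 2, n = 0.23, dwell = 0.45)
movie <- render_movie(scene, list(event), noise = FALSE)
trace <- extract_trace(movie, movie$truth$x_um, movie$truth$y_um,
                       landing_frame = movie$truth$landing_frame,
                       onset_frame = movie$truth$fusion_frame,
                       background_mode = "annulus")
fit_power_law(trace, noise_floor_k = 0)
#> Power-law decay fit  I = a * t^(-n)  [ols]
#>   a = 2 counts s^n, n = 0.23, R^2(log-log) = 1.0000
#>   225 points fitted over t in [0.03, 6.75] s
```

The generating parameters ($a = 2$ counts·s^n^, $n = 0.23$) come back
exactly: `a` is the coefficient of the power law in seconds and `n` its
exponent, the two numbers reported for every segmented event. An
end-to-end ensemble — 200 noisy events on the model branch pushed
through detection, linking, segmentation and fitting:

```r
study <- fusion_ensemble_study(n_events = 200, seed = 1)
round(c(mean_n = study$mean_n, sd_n = study$sd_n,
        n_fitted = study$n_fitted), 4)
#>   mean_n     sd_n n_fitted
#>   0.1727   0.0447 201.0000
```

The ensemble mean exponent lands at the model's $1/6 \approx 0.17$,
distinguishing whole-particle fusion from the $n = 1$ point-source
alternative (201 events: segmentation occasionally reports a spurious
extra site, a property the ground-truth matching makes visible). A `condition` label on each event lets
`aggregate_events()` and `plot_exponent_scatter()` compare fusion-time
and exponent distributions across bilayer or particle compositions.

Bilayer formation is analysed the same way, against a
nucleation-and-growth simulator:

```r
sim <- simulate_nucleation_growth(rate = 0.002, growth_speed = 0.25,
                                  dim = c(96, 96), n_frames = 80,
                                  seed = 4)
fit_erf_growth(coverage_curve(sim, threshold = 50))
#> Error-function coverage growth fit
#>   theta_max = 1, t_c = 19.36 s, tau = 6.24 s
#>   max growth rate 0.06393 /s at t_c; R^2 = 0.9981
```

A pipeline driver ties the stages to files
(`run_pipeline(config, "simulate"|"track"|"fuse"|"coverage"|"model-check"|"all")`,
YAML configuration, TIFF/CSV/JSON artifacts), with a thin command-line
wrapper in `inst/scripts/cubofuse.R`.

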