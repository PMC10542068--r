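# crankfit

Release kinetics of an antioxidant from a plane-sheet active packaging
film into a finite, well-stirred food simulant — forward models, diffusion
coefficient estimation, an independent PDE oracle, and a synthetic study
generator.

Active films (here: a zein/gellan-gum sheet carrying a rosemary-extract
antioxidant, measured as mg GAE/kg simulant) slowly hand their payload to
the food they contact. The package is for researchers who measure such
release curves and want the diffusion coefficient *D*, with the
limited-volume mass balance treated properly.

## The model

Fick's second law in the film, a no-flux midplane, partition equilibrium
`C_F(L,t) = K_FS C_S(t)` at the surface, and a finite bath give the
classical eigenfunction solution

    C_S,t / C_S,inf = 1 - sum_n [ 2a(1+a) / (1 + a + a^2 q_n^2) ] exp(-D q_n^2 t / L^2)

with `a = V_S / (K_FS V_F)` and `q_n` the positive roots of
`tan(q) = -a q`. For `a < 0.01`, where the series needs impractically many
roots, the short-time form
`C_S,t / C_S,inf = (1+a) [1 - exp(w) erfc(sqrt(w))]` with
`w = D t / (a^2 L^2)` is used instead. `D` is estimated by
deterministic least squares over `log10(D)` on the normalised curve, with
`R^2` reported against the observations.

An independent finite-volume solver of the same initial–boundary value
problem (`solve_release_pde()`, conservative, implicit, surface-graded
mesh) validates the analytical forms to ~1e-3.

## Worked example

```r
library(crankfit)

sc <- release_scenarios()[["fatty_24C"]]   # fatty simulant, 24 degC preset
sc
#> Release scenario 'fatty_24C': fatty simulant, 24 degC
#>   D = 21.14 x 10^-14 m^2/s, alpha = 0.0181, K_FS = 0.552
#>   L = 5e-05 m, C_S_inf = 100 mg GAE/kg, noise CV = 0.05

curve <- generate_release_curve(sc, noise_cv = 0)   # noiseless forward model
fit <- fit_diffusion(curve, scenario_geometry(sc), alpha = sc$alpha_true)
fit
#> Limited-volume diffusion fit
#>   D_hat : 21.1400 x 10^-14 m^2/s  (series model, alpha = 0.0181)
#>   R^2   : 1.0000   SSE: 1e-22   converged: TRUE
#>   C_S_inf used: 100 mg GAE/kg

max(ct_over_c0(curve))   # released fraction of the film's initial content
#> [1] 0.644
```

The fit returns the generating `D` (21.140 x 10^-14 m^2/s) exactly, with
`R^2 = 1.000`; the final `C_t/C_0` of 0.644 is the scenario's configured
release fraction. With the scenario's 5% measurement noise switched on,
the same call returns a `fit_result` whose `D_hat` scatters widely — the
3-hourly schedule samples long after this parameter regime has
equilibrated, so noisy data carry almost no information about `D` (see
the vignette's identifiability section).

Curves from CSV go through `read_release_csv()`; a YAML-configured
simulate–fit–report pipeline is available as `run_release_study()` (see
`inst/extdata/example-run.yaml`) or from the shell via
`inst/scripts/crankfit-cli.R`.

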