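# callusmod

Quantifying collagen-fiber organization in regenerating bone callus and
modeling its apparent stiffening during distraction osteogenesis.

## The problem

In distraction osteogenesis a cut bone is lengthened about 1 mm/day for
~15 days; the gap fills with a collagen-rich fibrous callus whose apparent
axial stiffness, measured in vivo through instrumented fixators, climbs to
roughly 50 N/mm before mineralization. `callusmod` is for researchers who
image that tissue (confocal z-stacks of stained collagen) and record its
mechanics, and who want a reproducible path from raw stacks to a fitted
structural explanation of the stiffening.

The core model is multiplicative:

```
K(t) = eta_theta(t) * eta_d(t) * eta_m(t) * K1
```

* `eta_theta` — orientation: unit-sphere averaging of a uniaxial fiber
  stress against the fiber elevation density, normalized to day 0. The
  un-normalized integral is `1/(12*pi)` for isotropic fibers, `1/(4*pi)`
  for full alignment — aligned fibers contribute three times more.
* `eta_d = C1 * (rho(t)/rho0)^2` — density: open-cell cellular-solid
  scaling, with `rho(t)` a linear fit through mean-gray-value densitometry
  and `rho0` the measured day-0 value.
* `eta_m` — maturation: first-order naive-to-mature collagen conversion at
  `K2 = 0.1/day` (`m_c(age) = 1 - exp(-K2*age)`), started `t'` days before
  distraction (`t'` bounded to the 0–7 day latency window).

`C1`, `t'`, `K1` are fitted to stiffness observations by separable bounded
least squares. The imaging side implements sum/max z-projections, gradient
structure-tensor orientation fields, energy-weighted orientation
distributions with their (linear) standard deviation, and
mean-gray-value densitometry. A seeded synthetic-data generator produces
fibered phantom stacks and forward-simulated stiffness series with known
ground truth, so the whole pipeline is testable offline.

## Worked example

Fit the model to the packaged demo series (a clearly labeled *synthetic*
in vivo-like recording, generated by the forward model plus 5% noise):

```r
library(callusmod)
obs <- read.csv(system.file("extdata", "stiffness_invivo_synthetic.csv",
                            package = "callusmod"))
obs$stiffness <- obs$stiffness_N_per_mm
fit <- callus_fit(stiffness ~ day, obs,
                  laws = reference_laws(), params = model_params(rho0 = 20))
summary(fit)
#> Callus stiffening model fit
#>   C1 = 0.9200, t' = 0.2416 d, K1 = 23.8672 N/mm  (C1*K1 = 21.9579)
#>   R^2 = 0.9970, p = 4.17e-17, n = 16
#>   converged: TRUE after 15 restart(s), 8 objective evaluations
#>   note: C1 and K1 enter the model only through their product; identified
#>   product C1*K1 = 21.9579, split by anchoring C1 at 0.92.
#>   residual sd: 0.8569 N/mm
```

`K1` is the apparent stiffness mature day-0-organized fibers would have;
`t'` says the fibers had matured only a fraction of a day before
distraction began; the identifiability note is printed because the data
constrain only the product `C1*K1` (see the vignette). The fitted forward
trajectory decomposes the stiffening:

```r
stiffness_trajectory(reference_laws(), c(0, 5, 10, 15), model_params(rho0 = 20))
#>   day eta_theta     eta_d      eta_m          K
#> 1   0  1.000000 0.9099993 0.01488806  0.3233937
#> 2   5  1.047020 1.2977808 0.40249941 13.0549174
#> 3  10  1.100272 1.7542070 0.63759757 29.3751310
#> 4  15  1.160015 2.2792779 0.78019182 49.2396087
```

Orientation contributes a modest 16% by day 15, density more than doubles
its contribution, and maturation sweeps from near zero to 0.78 — together
reaching ~49 N/mm.

An end-to-end run from synthetic stacks (projection → orientation
distribution → temporal laws → trajectory → fit) is one call:

```r
rec <- run_pipeline(pipeline_config(
  stacks = timecourse_config(), out_dir = "out",
  stiffness = system.file("extdata", "stiffness_invivo_synthetic.csv",
                          package = "callusmod")))
report(rec)
```

A thin command-line wrapper lives at `inst/cli/callus.R`
(`Rscript callus.R run --config config.yaml`, plus `simulate`,
`analyze-stack`, `model`, `fit-model` subcommands).

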