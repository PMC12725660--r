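# stGclamp

Kinetic modelling of blood glucose regulation with a transient glucose
store, for hyperglycemic clamp data in mice.

## The problem

During a glucose load, blood glucose is cleared by two mechanisms with
different time courses: an early, insulin-independent one — *glucose
effectiveness*, glucose promoting its own disposal — and a later
insulin-dependent one. Conventional glucose-tolerance analyses (AUCs over
a tolerance test) cannot separate them. `stGclamp` is for researchers who
want to decompose clamp or IVGTT data into these two components and track
how each changes with obesity.

The core is a four-state ODE model in which insulin-independent uptake
fills a transient glucose store `stG` of finite capacity `k7`:

    dG/dt   = k1/(1 + I + k8·G) − k2·G·I − k5·G·(k7 − stG) + f(t)
    dI/dt   = k3·G − k4·I
    dstG/dt = k5·G·(k7 − stG) − k6·stG·I
    dAG/dt  = k2·G·I − k1/(1 + I + k8·G) + k5·G·(k7 − stG)

with `G` blood glucose (mg/dL), `I` insulin (ng/mL), `AG` cumulative
uptake, and `f(t)` the glucose infusion. Flux `k5·G·(k7 − stG)` is glucose
effectiveness: large while the store is empty, self-limiting as it fills;
`k2·G·I` is insulin-dependent uptake; `k1/(1 + I + k8·G)` is endogenous
glucose production.

The package provides:

- **Simulation** — closed-loop hyperglycemic clamp (target = fasting +
  200 mg/dL, deterministic titration controller), IVGTT bolus, arbitrary
  fixed schedules; windowed decomposition of disposal into
  insulin-independent (flux 5) and insulin-dependent (flux 2) integrals.
- **Per-mouse estimation** — meta-evolutionary programming followed by
  bounded Levenberg–Marquardt least squares on normalized residuals over
  the glucose, insulin and cumulative-uptake streams, with a per-fit
  identifiability report.
- **Group statistics** — IQR outlier screening, pairwise Welch tests with
  Benjamini–Hochberg adjustment, Williams-type step-down trend tests with
  a seeded Monte-Carlo null, Spearman rank correlation.
- **Synthetic cohorts** — a generator emulating chow-fed and
  high-fat-diet mouse groups (sizes 13/13/16/13/10/10, monotone parameter
  trends with age on diet, measurement noise), so the whole pipeline is
  testable without animal data.

## Worked example

```r
library(stGclamp)

p <- referenceParams("CD")          # a lean, chow-fed-like mouse
prot <- infusionProtocol("clamp", bodyWeight = 25, initialRate = 0.15)
traj <- runClamp(p, prot)
traj
#> Trajectory: 362 points over [0, 180] min
#>   G 120..334.7 mg/dL  I 0.4..3.12 ng/mL  stG max 445.3  AG final 1822
#>   total infused: 36.4 mg over 28 intervals

decomposeFluxes(traj)
#> FluxDecomposition (10-min windows)
#>   window_end_min flux5_integral flux2_integral
#> 1             10      177.97817       5.788009
#> 2             20      150.32688      12.113833
#> 3             60       65.47702      24.902147
#> 4            120       71.42813      32.595856
#> 5            180       76.61213      34.917120
```

The flux-5 integrals (insulin-independent disposal) are largest in the
first 10-minute window and fall as the store fills, while the flux-2
integrals (insulin-dependent disposal) rise monotonically — the two-phase
structure the model exists to expose. The infusion demand is
correspondingly biphasic: it dips once the store saturates and rises again
as insulin accumulates.

Fitting a noisy synthetic record recovers the generating kinetics:

```r
set.seed(1)
rec <- simulateRecord(p, prot, glucoseCV = 0.05, insulinCV = 0.10)
fit <- fitMouse(rec, fitConfig(populationSize = 64, generations = 80,
                               seed = 1), identifiability = TRUE)
fit
#> FitResult: RSS = 0.126394 (converged, 6799 objective evaluations, seed 1)
#> ModelParameters (glucose-store kinetic model)
#>   rates: k1=32.55 k2=0.009157 k3=0.000196 k4=0.01884 k5=0.000145 k6=0.002495 k7=571.8 k8=0.02728
#>   initial: G0=116.2 mg/dL  I0=0.3928 ng/mL
```

True values were k3 = 2e-4 (recovered within 2%) and k7 = 600 (within
5%), while the EGP pair k1/k8 has wandered far from truth — and the
identifiability report attached to the fit says exactly that, flagging
`k1`, `k2`, `k6` and `k8` as weakly determined, which is the honest
reading of what a single noisy clamp constrains. A full cohort
analysis is three calls: `generateCohort()` → `fitCohort()` →
`runGroupComparison()`, the last producing per-parameter box statistics,
BH-adjusted Welch pairs and step-down trend decisions. A thin command-line
wrapper over the same calls ships in `inst/scripts/stgclamp`.

See the vignette (`vignettes/glucose-store-model.Rmd`) for the model's
assumptions, the controller design, normalization and bounds choices, and
what the synthetic cohorts do and do not emulate.

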