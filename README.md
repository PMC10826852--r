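# eitmon

Simulation and image reconstruction for electrical impedance tomography
(EIT) monitoring of intracerebral hemorrhage.

Bedside monitoring of hemorrhagic stroke needs a continuous, radiation-free
signal of hematoma growth; repeated CT gives only snapshots. EIT injects
milliampere currents through scalp electrodes and measures boundary
voltages. Blood (0.70 S/m) is much more conductive than white or gray
matter (0.06–0.10 S/m), so a growing hemorrhage perturbs the measurements,
and the conductivity *change* between two measurement times can be imaged.
This package implements the whole simulation study for researchers in
biomedical inverse problems: layered head phantoms with growing blood
inclusions, a complete electrode model (CEM) finite element forward solver,
and three reconstruction algorithms whose detection performance is compared
on a grid of growth scenarios.

## Models and algorithms

Forward model: ∇·(σ∇u) = 0 with CEM boundary conditions
(contact impedances z_ℓ, electrode current constraints,
Σ I_ℓ = Σ U_ℓ = 0), P1 finite elements, pairwise "skip-s" current
injections and adjacent differential voltage observation, additive Gaussian
noise at 0.067 % of the maximum healthy-state amplitude.

Given frames V₁ = U(σ₁) + e₁ and V₂ = U(σ₂) + e₂, the change
δσ = σ₂ − σ₁ is estimated three ways:

* **TV** — total-variation regularized absolute imaging of σ₁ and σ₂
  independently (lagged Gauss–Newton with positivity), δσ by subtraction;
* **LD** — one-step linear difference imaging: Tikhonov solution of
  δV ≈ J δσ with a distance-based Gaussian smoothness prior;
* **MO** — the stroke-monitoring algorithm: joint nonlinear estimation of
  (σ₁, δσ) with δσ supported on a region of interest (the brain), smoothed
  TV on δσ, parallel-level-sets weighted TV on σ₁ (edges aligned with a
  structural reference image are cheap), lagged Gauss–Newton with a
  prior-conditioned LSQR (MLSQR) search direction, initialized by an
  anatomically guided three-compartment fit.

Detectability per scenario pair (D₁, D₂) uses the adjusted normalized
integral Q = I − max|I_diag| on integrals I = ∫ δσ dx normalized per
algorithm and location; Q > 0 means the pair is distinguishable from the
no-growth noise floor.

## Worked example

A scaled-down 2D replication (16 electrodes, disc inclusions at the
10–30 mm sphere diameters, 0.067 % noise), monitoring algorithm over all
21 ordered pairs of the cortical growth chain:

```r
library(eitmon)
det <- run_experiment(states = c(0, seq(0.010, 0.030, 0.005)),
                      locations = "cortical", algorithms = "mo", seed = 1)
glance(det)
#> # A tibble: 1 × 5
#>   algorithm location n_pairs n_detected smallest_detected_ml
#>   <chr>     <chr>      <int>      <int>                <dbl>
#> 1 mo        cortical      21         15                0.524
subset(tidy(det), d1 == 0.015 & d2 == 0.020,
       select = c(d1, d2, volume_change_ml, Q))
#> # A tibble: 1 × 4
#>      d1    d2 volume_change_ml     Q
#>   <dbl> <dbl>            <dbl> <dbl>
#> 1 0.015 0.02             2.42 0.147
autoplot(det)   # Q heat map; Q <= 0 rendered white
```

Every no-growth diagonal pair has Q ≤ 0 (noise floor); every growth pair
is detected, down to the 0.52 ml healthy→10 mm step; the 15→20 mm
expansion (2.42 ml, the smallest change the full-scale study reports as
detected) has Q = 0.147. Single reconstructions are available directly
via `reconstruct_absolute()`, `reconstruct_linear()` and
`reconstruct_monitoring()`, with `tidy()`/`glance()` accessors and
`autoplot()` field rendering; meshes and fields export to VTK and Gmsh MSH
(`write_vtk()`, `write_msh()`), frames to CSV.

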