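---
title: "Monitoring intracerebral hemorrhage growth with EIT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring intracerebral hemorrhage growth with EIT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Intracerebral hemorrhage (ICH) patients in intensive care need continuous
surveillance for hematoma expansion and rebleeding, but the reference
technique — repeated CT — gives only occasional snapshots. Electrical
impedance tomography (EIT) injects milliampere currents through scalp
electrodes and measures the resulting boundary voltages; because blood
(about 0.70 S/m) is considerably more conductive than white or gray matter
(0.06–0.10 S/m), a growing hemorrhage changes the measured voltages, and an
imaging algorithm can, in principle, reconstruct the conductivity change
between two measurement times at the bedside.

`eitmon` implements this pipeline end to end as a simulation study: a
parametric layered head phantom with a nest of concentric blood spheres, a
complete electrode model (CEM) finite element forward solver, three
reconstruction algorithms, and a detectability analysis over a grid of
growth scenarios.

## Forward model

The interior potential satisfies $\nabla\cdot(\sigma\nabla u)=0$ with the
CEM boundary conditions on each electrode $e_\ell$ (contact impedance
$z_\ell$, prescribed total current, zero current on bare boundary) and the
charge/ground conventions $\sum_\ell I_\ell = \sum_\ell U_\ell = 0$. The
FEM discretization uses piecewise linear potentials and a piecewise linear
nodal conductivity; the electrode voltages are expanded in a zero-mean
basis so the discrete system is symmetric positive definite and one sparse
Cholesky factorization serves every current pattern and every adjoint
(Jacobian) solve. Voltages are observed as adjacent differential pairs
(1–2, 2–3, …, L–1) for every injection of a pairwise "skip-s" pattern; with
L = 32 the skip of 12 reproduces the 1–13, 2–14, … layout, and the default
L = 16 study uses the same construction with skip 4.

Measurement noise is i.i.d. additive Gaussian. Its standard deviation is
specified relative to the maximum amplitude of the noise-free healthy-state
data; the default 0.067 % corresponds to a prototype stroke-EIT
measurement device.

Parameters that matter, with defaults:

* layer radii (m): scalp 0.090, skull 0.085, CSF 0.078, brain 0.076 —
  literature-typical thicknesses, configurable; the source study's exact
  anatomy is not distributed, so a parametric geometry stands in for it;
* tissue conductivities (S/m) at 1 kHz: scalp 0.32, skull 0.02, CSF 2.00,
  white 0.06, gray 0.10, blood 0.70 (permittivities are recorded in
  `tissue_table()` but unused: the model is real-valued quasi-static);
* contact impedances: $z_\ell = 10^{-3}\,\Omega\,\mathrm{m}^2$ uniform,
  assumed known — no published value exists for the reference device, and
  contact-impedance estimation is out of scope;
* currents: 1 mA pairwise injections.

## Meshes and the inverse crime

Three meshes are used per experiment: a fine simulation mesh (data
generation), a finer potential mesh and a coarser conductivity mesh for
reconstruction (nodal conductivities are interpolated onto the potential
mesh with a sparse P1 interpolation matrix). Simulating and inverting on
the same discretization would make the problem artificially easy (the
inverse crime); the deliberate mesh mismatch leaves a realistic
discretization error on top of the additive noise.

The phantom generators are deterministic and structured: graded polar
rings in 2D (ring node counts halve toward the centre so aspect ratios stay
bounded) and a Kuhn-triangulated cube mapped radially onto the ball in 3D.
Layer interfaces coincide with mesh surfaces by construction; hemorrhage
spheres are labelled by element centroid, with an optional locally refined
axis grid in 3D so the labelled volume converges to $\pi D^3/6$.

## The three algorithms

**TV absolute imaging** reconstructs $\sigma_1$ and $\sigma_2$
independently by minimizing
$\|L_e(V-U(\sigma))\|^2 + \alpha\int(\|\nabla\sigma\|^2+\beta^2)^{1/2}$
with a lagged Gauss–Newton iteration (TV weights frozen when forming the
Hessian), projected backtracking line search enforcing
$\sigma \ge \sigma_{\min} = 10^{-5}$ S/m, and the best-fitting constant
conductivity as the start; $\delta\sigma$ is the subtraction. Both frames
are fitted from their own constant starts — nothing couples them.

**Linear difference imaging (LD)** linearizes at the constant fit
$\sigma_0$ of the first frame and solves one Tikhonov system for
$\delta\sigma$ from $\delta V = V_2 - V_1$, with difference-noise
covariance $\Gamma_{e1}+\Gamma_{e2}$ and a distance-based Gaussian
smoothness prior: marginal std $2\sigma_0$, correlation solved from a 1 %
level at distance $d = \ell_\Omega/4$, where $\ell_\Omega$ is the
anterior–posterior extent of the domain. No positivity constraint: the
sign of the change is informative.

**The monitoring algorithm (MO)** estimates $(\sigma_1, \delta\sigma)$
jointly from both frames' full nonlinear models, with
$\sigma_2 = \sigma_1 + K\delta\sigma$ and $K$ the extension-by-zero of the
region of interest (the brain compartment). $\delta\sigma$ carries smoothed
TV; $\sigma_1$ carries parallel-level-sets weighted TV, whose tensor
$B = I - (1-\gamma)\hat\nu\hat\nu^T$ makes conductivity edges cheap where
the structural reference image $\kappa$ (a scalp/skull/brain indicator map,
the stand-in for a registered CT) has edges: $\gamma = \gamma_1 \ll 1$ on
elements whose $\|\nabla\kappa\|$ exceeds half its maximum, else 1. The
defaults $\gamma_1 = 0.01$ and threshold fraction 0.5 are package choices
(no published values exist); only the level-set geometry of $\kappa$
matters, so its values 0/1/2 are arbitrary. The outer loop is again lagged
Gauss–Newton with positivity projection ($\sigma_1>0$,
$\sigma_1+K\delta\sigma>0$); the search direction solves the stacked
normal equations matrix-free by prior-conditioned LSQR: with a Cholesky
factor $F^TF = H_{\mathrm{prior}}$ (block diagonal: weighted-TV Hessian
for $\sigma_1$, TV Hessian for $\delta\sigma$, each with a mass-matrix
jitter of $10^{-12}$ times the trace scale so the factor exists), the
substitution $d = F^{-1}w$ turns the step into a damped least squares
problem solved by LSQR (tolerance $10^{-6}$, at most 200 inner
iterations). Initialization is the anatomically guided three-compartment
fit: one conductivity per scalp/skull/brain, Nelder–Mead on log values
started from literature-typical tissue values, with $\delta\sigma = 0$.

## Regularization scales

The published weights for the full-scale 3D study
($\alpha_{\delta\sigma} = 0.005$, $\alpha_{\sigma_1} = 10^{-7}$,
$\beta = 0.001$, TV $\alpha = 0.01$) are tied to that study's geometry,
channel count and noise weighting, and are retained as the defaults of the
reconstruction functions. They are far too weak on the desk-scale 2D
phantom, where the noise-weighted misfit is several orders of magnitude
larger relative to the regularizers. Following the same procedure as the
original tuning — manual adjustment for reconstruction quality —
`run_experiment()` uses 2D-scale defaults chosen once on a single
20→25 mm growth case by inspecting localization and the stability of
$\sigma_1$: TV absolute $\alpha = 300$, monitoring
$\alpha_{\delta\sigma} = 300$, $\alpha_{\sigma_1} = 30$, all with
$\beta = 0.001$. The LD prior needs no rescaling (its convention is
scale-free).

## The detectability score

For every ordered pair of states $(D_i, D_j)$, $D_j \ge D_i$, the
reconstructed change is integrated over the domain,
$I_{D_i,D_j} = \int_\Omega \delta\sigma\,dx$ (exact for P1 fields via the
lumped mass vector). Per algorithm and location, integrals are normalized
by their maximum absolute value over all pairs — the most natural reading
of "normalized separately" — and the adjusted score subtracts the worst
no-growth diagonal:
$Q_{D_i,D_j} = I_{D_i,D_j} - \max_k |I_{D_k,D_k}|$ (on normalized values).
$Q \le 0$ means indistinguishable from noise; heat maps render such cells
white.

Each state is simulated twice (once as the earlier, once as the later
measurement, with deterministic seeds derived from the master seed), so a
no-growth pair compares two independent noise realizations — the only
reading under which the diagonal reflects the measurement noise level —
while off-diagonal pairs reuse the same realizations, as in a monitoring
time series.

## Scaled-down study conditions

The full-scale study (2.5 M-element anatomical mesh, 116 k-node inversion
mesh, L = 32) is not reproducible at desk scale. The packaged replication
uses the 2D disk phantom with L = 16 electrodes, disc inclusions at the
3D sphere diameters (volume bookkeeping uses the sphere chain, so a
15→20 mm step is reported as 2.42 ml), relative noise 0.067 %, and meshes
of roughly 7.6 k / 2.1 k / 0.57 k nodes (simulation / potential /
conductivity), with 12 outer Gauss–Newton iterations per reconstruction.
These sizes keep a full 21-pair monitoring grid within minutes on one CPU
while preserving the two-mesh protocol; they are stated here as the
package's study conditions.

What the generator emulates: layered anatomy with a thin resistive skull
and conductive CSF, growing blood inclusions at a cortical and a deep
location, pairwise injections with differential adjacent observation, and
device-level Gaussian noise. What it does not: anatomical irregularity
(the layers are concentric), electrode placement and contact-impedance
errors, drift or correlated noise, and 3D current spreading in the 2D
study — so passing tests show algorithmic correctness and the relative
ranking of the algorithms under these idealized conditions, not clinical
performance.

## Numerical choices and degenerate inputs

* One-point quadrature for all TV-type integrals (exact for the
  element-constant gradients of P1 fields); $\beta$ inside the square
  root.
* The Gaussian covariance of the smoothness prior is numerically rank
  deficient at smooth correlation lengths; a diagonal jitter (smallest
  power of ten between $10^{-10}$ and $10^{-5}$ times the variance that
  makes the Cholesky succeed) bounds its condition number. The prior is
  assembled densely — fine up to a few thousand nodes, a documented
  memory cliff beyond.
* A constant reference image yields $\gamma \equiv 1$ and
  $\hat\nu \equiv 0$ with a warning (weighted TV degrades to TV).
* Line searches accept on simple cost decrease after projection; failure
  to decrease terminates the outer loop with a flag, so the cost trace is
  non-increasing by construction.
* MLSQR stagnation (iteration cap) returns the best iterate with a
  warning rather than failing the reconstruction.
* All randomness flows through explicit seeds; per-cell seeds derive
  deterministically from (master seed, location, state, frame role).

## Known limitations

* Depth localization: the reconstructed change of the monitoring algorithm
  concentrates at the correct lateral position with its peak close to the
  true inclusion, but a low-amplitude positive pedestal extends toward the
  domain centre, where measurement sensitivity is smallest. TV
  regularization does not suppress such flat extensions (a plateau costs
  TV only at its boundary). The centre of mass of the positive part is
  therefore biased inward by roughly 12–16 mm under the study conditions,
  which exceeds one inclusion radius for the smaller spheres; the blob
  peak, in contrast, lands within a mesh element of the truth. Detection
  (the Q score) is unaffected.
* The three-compartment fit returns effective-medium values, not tissue
  values, whenever the conductivity mesh under-resolves the thin skull and
  CSF layers: the fitted skull conductivity compensates downward (or the
  layers trade off) to match the data. This is the modeling error the
  nonlinear difference parameterization is designed to absorb into
  $\sigma_1$.
* The 3D path (ball phantom, 32-electrode ring layout) is demo grade:
  electrode patches are facet-resolution limited, and the 10-5-derived
  electrode coordinates of the full-scale study are approximated by three
  latitude rings plus the vertex.
* Tabular results, tidy()/glance() accessors and ggplot2 heat maps are
  tibble-native; meshes, fields and operators are plain S3 + Matrix
  objects — a deliberate split, since the numerical core is not tabular.

## Reproducing the study numbers

```{r}
library(eitmon)
det <- run_experiment(states = c(0, seq(0.010, 0.030, 0.005)),
                      locations = "cortical", algorithms = "mo", seed = 1)
glance(det)
autoplot(det)
smallest_detected_increase(det)   # ml
```

`scripts/acceptance.R` runs exactly this experiment from a fresh seed and
reports the smallest detected cortical volume increase.
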