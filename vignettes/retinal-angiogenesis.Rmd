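---
title: "Methods: a hybrid phase-field / agent model of tumor-induced angiogenesis in the retina"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a hybrid phase-field / agent model of tumor-induced angiogenesis in the retina}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhangio)
```

## The model and its assumptions

`rhangio` couples three descriptions of the perilesional retina:

1. **A prescribed tumor.**  Retinal hemangioblastomas are rounded and grow
   extremely slowly (≈35 % in volume per year), so the lesion is not a
   dynamical field but a growing ellipsoid indicator φ with equal lateral
   semiaxes.  The growth factor is stored per tau as the multiplicative
   volume factor `tgr`; each semiaxis carries the exponent t/3 so the
   product of the three semiaxes reproduces the volumetric rate exactly
   (`semiaxes_at()`).  A consequence worth stating: over the day-to-week
   horizons the simulator targets, tumor growth is visually negligible,
   while vascular events play out in hours.

2. **A capillary phase field.**  c ≈ +1 marks intravascular space, c ≈ −1
   tissue, with a diffuse interface maintained by Cahn–Hilliard dynamics
   (mobility M, interface parameter ε).  The Cahn–Hilliard flow conserves
   mass and relaxes interfaces; with the default mature-endothelium
   proliferation rate α_p = 0 the bulk source vanishes identically and
   *all* vessel growth enters through the tip-cell imprint.  A variant
   with α_p = α_pSC (`"sc_proliferation_bug"` scenario) reproduces the
   known pathology of indiscriminate capillary thickening that motivates
   keeping stalk-cell proliferation separate from the bulk term.

3. **A quasi-steady angiogenic factor.**  AF kinetics (diffusion,
   production inside the avascular part of the tumor, uptake by vessels,
   degradation) is much faster than growth or sprouting, so af solves an
   elliptic balance each step.  The Heaviside convention is H(0) = 0: the
   interface midpoint belongs to tissue, so production is suppressed
   strictly inside vessels and uptake applies strictly inside vessels —
   the two masks never double-count a node.  When φ = 1 and H(c) = 1
   simultaneously both the production mask (zero) and the uptake term
   apply, following the equation literally.

**Tip cells** are discrete agents: activation requires a vessel node
(c ≥ 1 − c_tol), AF above T_c and gradient norm above G_m; Delta-Notch
lateral inhibition forbids placements closer than δ₄ to an active tip.
Deactivation mirrors the AF conditions (not the c condition — a tip's own
imprint lowers c locally and must not kill it).  Velocity is χ∇af with
speed capped at χG_M.  The imprint overwrites every node within R_c with
c_c = S_p(af)·πR_c²/|v|, carrying tip mass and stalk-cell proliferation
into the continuum.  The per-step order is deactivate → activate →
velocities → imprint → move, so the imprint uses the velocity of the
current step.

## Parameters

All computation is in simulation units: sau = 800 µm, tau = 26 min,
afau = 6000 pg/mL.  `default_parameters()` converts the physical table
(units declared as strings, parsed by an explicit unit-signature grammar)
and `validate_parameters()` enforces the structural invariants
(G_m < G_M, dt_min ≤ dt_max, positivity).  Highlights, with defaults:

| symbol | meaning | physical default | simulation value |
|---|---|---|---|
| M | capillary mobility | 1e-9 mm²/s | 2.4375e-6 |
| ε | interface parameter | 1.5625 µm² | 2.44e-6 |
| χ | chemotactic sensitivity | 8.33333 µm²·mL/(min·ng) | 0.002031 |
| T_c | activation AF threshold | 3000 pg/mL | 0.5 |
| G_m, G_M | gradient window | 14, 42 ng·mL⁻¹·mm⁻¹ | 1.8667, 5.6 |
| R_c | tip-cell radius | 10 µm | 0.0125 |
| δ₄ | Notch exclusion distance | 40 µm | 0.05 |
| D_af | AF diffusivity | 4.24e-5 mm²/s | 0.10335 |
| V_pT | AF production (headline) | 47.3 pg·mL⁻¹·s⁻¹ | 12.298 |
| V_uc | AF uptake (headline) | 2.3e-4 s⁻¹ | 0.3588 |
| V_d | AF degradation | 0.92 h⁻¹ | 0.3987 |
| dt_min, dt_max | step bounds | 26, 1300 min | 1, 50 |

Three printed nondimensional values in the source table do not agree with
their own physical entries; this package treats the physical value as the
source of truth and ships the recomputed number, overridable per entry:
the yearly growth factor converts to 1.0000149 per tau (printed 1.00002),
V_d to 0.3987 (printed 0.44), M to 2.4375e-6 (printed 2e-6).  The
chemotactic-sensitivity units are adopted as µm²·mL·min⁻¹·ng⁻¹, the only
signature under which the printed conversion arithmetic closes.

## Numerics

*Discretization.*  Uniform node-centered grid; the reference operators are
second-order central differences with the ghost-node zero-flux closure,
giving a symmetric Neumann Laplacian with zero column sums — which is what
makes the Cahn–Hilliard step conserve `sum(c)·h^dim` exactly.  Any
spacing must satisfy h ≤ R_c so a tip imprint always covers a node (the
constructors warn, or reject in strict mode).

*Cahn–Hilliard step.*  Backward Euler on the µ-eliminated system, solved
by Newton with an absolute residual tolerance of 1e-8 and a backtracking
line search on the residual norm; the sparse Jacobian
I − dtM(LD − εL²) − dt·diag(source′) is refactorized per iteration.  A
non-convergent step is rejected with a diagnostic and the driver retries
at halved dt down to dt_min.  The interface width √ε ≈ 1.2 µm is smaller
than any practical spacing — the same under-resolution the reference
meshes have — so interfaces are effectively sharp on the grid; the energy
and mass properties hold regardless, and the tanh-profile residual test
is run in 1D where the interface can be resolved.

*AF solve.*  One sparse SPD solve per step (−D_af·L + diag(V_uc·H + V_d));
singular configurations (V_d = 0 with no vessel) are reported explicitly.
Relative residual must be ≤ 1e-8.

*Adaptive stepping.*  dt = max(dt_min, dt_max/(1 + α|E′|²)) with α = 100
and E′ = −‖∇µ‖².  The norm is the domain L² norm (an L∞ variant is a
config switch; the source writes only ‖∇µ‖).  The rule is used only when
no tip is active.  Whenever it proposes dt > dt_min, a bisection probes
trial advances (tumor at t+dt, one capillary step, AF re-solve,
activation predicates) for the earliest activation in the span, stopping
at dt_min resolution.  A trial step that fails to converge counts as
"activating", which can only shrink dt — conservative by construction.

*Velocity-law reading.*  The capped law |v| = χG for G_m ≤ G < G_M and
|v| = χG_M above is adopted (the flattened typesetting of the first
branch is ambiguous; the constant-speed alternative remains available by
post-processing the gradient before `tip_velocity()`).  The imprint
denominator is floored at v_min = 1e-6 sau/tau.  The c ≥ 1 activation
condition is implemented as c ≥ 1 − c_tol with c_tol = 1e-3, since
evolved diffuse fields rarely hit 1.0 exactly; Notch exclusion sweeps
candidates greedily in node order (deterministic; a seeded random order
is available).

## Initial vessel networks

Real inputs are binary 2D segmentations with a pixel size.  The package
reconstructs:

* **2D**: nodes mapping into vessel pixels get c = +1, others −1 (ties on
  pixel borders toward the lower index).
* **3D**: the mask's Euclidean distance transform (exact two-pass
  algorithm), restricted to the Zhang–Suen thinning skeleton, gives a
  per-pixel local radius; the vessel body is the union of balls of that
  radius centered on skeleton points placed at depth z0 (default
  mid-depth — the axial placement is not otherwise constrained by the
  data).  Projecting the 3D body back to the z0 plane recovers the 2D
  region to within a grid cell; this conservativity is what the
  construction is tested against, and any skeleton satisfying it would be
  acceptable.  Balls (rather than in-plane disks) were chosen, so a
  vessel's axial half-thickness equals its local radius.

The **synthetic generator** (`synth_plexus()`) stands in for patient
segmentations: gently curved, non-overlapping vessel paths of prescribed
widths that avoid an avascular disk (the future lesion site) by
construction, rasterized at 2 µm/px and reproducible bitwise from a seed.
It emulates a planar plexus of distinguishable vessels around an
avascular lesion; it does **not** emulate the true anastomosing retinal
capillary meshwork, foveal avascular zone geometry, or segmentation
noise.  A green test on a synthetic scenario therefore establishes the
mechanics of the pipeline, not patient-level quantitative predictions.

## Scenario world and two calibration notes

Scenario fixtures use the clinically printed lesion diameters (208 and
490 µm classes) and headline production; two choices were genuinely open:

* The sprouting demonstration (`"2d_sprouting"`) uses the uptake value
  1.78e-3 s⁻¹ — one of the three couples used for the month-long
  simulations in the source work, the top of the range that vascularizes
  every lesion.  Under the most favorable headline uptake (2.3e-4 s⁻¹)
  our reduced synthetic geometry keeps one marginal activation site
  flickering indefinitely, whereas at the stated higher uptake the tip
  population settles to zero within days once the new vessels suppress
  the AF field — the phenomenon the scenario exists to demonstrate.

* The minimal-size grid (`"2d_minimal_size"`) uses ten capillary-caliber
  (6–8 µm) vessels at 130 µm from the lesion center so that more than one
  production rate is capable.

## Known limitations

* **Uptake direction of the minimal size.**  At the default parameters
  the AF decay length is √(D_af/V_d) = 0.5 sau, so wherever the gradient
  threshold G ≥ G_m is met, af ≈ G·ℓ ≥ T_c follows automatically: the
  *gradient* criterion is the binding activation constraint in every
  desk-scale 2D world we constructed.  Raising V_uc steepens AF gradients
  (locally at vessel dips, globally by shortening the effective decay
  length) and therefore weakly *lowers* the minimal activating size,
  while production keeps its expected direction (more production, smaller
  minimal size).  Reproducing the opposite uptake trend appears to
  require patient-scale, dense, three-dimensional vascular geometry; the
  corresponding acceptance assertion is left failing rather than
  weakened, with the instrumented analysis preserved in the test file.
* The retina is flat here: no curvature, no layered anisotropy, uniform
  grids only.
* Anastomosis is emergent field overlap, not a tracked event; there is no
  blood flow, so perfusion-dependent uptake is folded into V_uc.
* Multi-year, full-lesion 3D runs are out of scope for the test budgets;
  3D support is exercised at reconstruction scale (`"p1_like"`).

Nothing in this vignette states an empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.
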