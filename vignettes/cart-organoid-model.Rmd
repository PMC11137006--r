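---
title: "A multiscale agent-based model of CAR T-cell therapy on heterogeneous organoids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multiscale agent-based model of CAR T-cell therapy on heterogeneous organoids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartsim)
```

# The model

`cartsim` simulates a tumour-derived organoid — a spherical aggregate of
off-lattice cancer-cell agents — under chimeric antigen receptor (CAR)
T-cell immunotherapy. Three coupled layers evolve on a strict clock
hierarchy:

* **Microenvironment** (diffusion step, default 0.01 min). Each substrate
  obeys a reaction–diffusion equation on a Cartesian voxel mesh (20 µm
  edge): diffusion, first-order decay, and per-cell secretion/uptake in the
  cell's containing voxel. Two substrates are carried: oxygen (mmHg;
  D = 1e5 µm²/min, decay 0.1/min, taken up at 10/min by cancer cells and
  1/min by T cells) and an immunostimulatory factor (arbitrary units;
  D = 1e3 µm²/min, decay 0.016/min, secreted at 10/min by live cancer
  cells). Only the *gradient direction* of the immunostimulatory factor
  matters for behaviour, so its absolute unit is irrelevant. "Dirichlet
  nodes" — voxels re-clamped to a fixed value after every step — provide
  continuous sources; by default the domain's boundary voxels clamp oxygen
  at 38 mmHg (physioxia), a configurable stand-in because no boundary or
  initial oxygen condition is part of the model's published parameter set.

* **Cell mechanics** (mechanics step, 0.1 min). Overdamped motion: forces
  are expressed directly as velocities (µm/min), i.e. a unit drag
  coefficient is absorbed into the constants. The pairwise contact model is
  polynomial: repulsion `sqrt(Ca*Cb) * (1 - d/(Ra+Rb))^2` below contact
  (an elastic resistance to deformation; C = 10 µm/min for cancer, 5 for
  T cells), adhesion `C_cca * (1 - d/R_A)^2` in the ring up to
  `R_A = 1.25 (Ra+Rb)`. The functional form is our choice within this
  model family — the constants and the 1.25 adhesion reach are the model's
  published values, the quadratic polynomial is the standard contact law
  used by centre-based frameworks of this type. `C_cca` defaults to
  0.4 µm/min, a typical weak-adhesion value in the same family; it is a
  free knob.

* **Cell cycle, death and volume** (cycle step, 6 min). The cycle is a
  directed graph G1→S→G2→M→division with mean durations 20.4, 13.6, 3.0
  and 1.6 h. Phase exit is memoryless (per-step probability
  `dt/T_phase`), which makes the *mean* simulated phase duration exactly
  `T_phase`; a fixed-duration mode is available behind
  `fixed_phase_durations` for sensitivity checks. Oncoprotein expression
  `o` and oxygen scale only the G1 exit rate:
  `T_G1_eff = T_G1 / (o * f(O2))`, with `f` ramping linearly from 0 at
  5 mmHg to 1 at 10 mmHg. Death is apoptosis (T-cell kill) or necrosis
  (below 5 mmHg, exponential waiting time with mean 6 h); dead cells stop
  cycling and secreting, shrink exponentially toward zero volume and leave
  the mechanics population below 5 % of the reference volume while
  remaining in the cumulative dead count. Volumes relax implicitly toward
  a division target of twice the reference volume; daughters take half the
  mother's volume each, so volume is continuous across division.

* **Immunosurveillance** (mechanics cadence). CAR T-cells are
  self-propelled: with probability `dt/t_per` (persistence time 10 min)
  they redraw a random unit direction `d_r`, and they blend it with the
  up-gradient unit direction `d` of the immunostimulatory factor:
  `v_mig = v_mot (b d + (1-b) d_r) / ||b d + (1-b) d_r||`, speed
  `v_mot = 2` µm/min, bias `b = 0.5`. Within 18 µm of a live, recognisable
  target, an adhesion forms with probability `r_adh dt` (`r_adh` =
  0.2/min) to the nearest candidate; the T-cell then switches off its
  motility and the target freezes its cycling. Each attached step attempts
  a kill with probability `r_K dt × immunogenicity` (`r_K` = 0.06/min);
  immunogenicity is `o` above the recognition threshold 0.5 and zero below
  it (Type 4 cells can never be killed), or identically 1 in multi-antigen
  (syn-Notch-like) mode. Attachments time out at 60 min. Each T-cell
  draws a lifespan once, from a normal(10 d, 5 d) truncated at zero, and
  is removed when its age exceeds it; long-term persistence mode makes
  lifespans infinite.

## Intratumour heterogeneity

Each cancer cell carries a scalar oncoprotein expression `o`, drawn once
at seeding from a normal(1, 0.25) restricted to [0, 2] and inherited
*exactly* at division. We read "restricted" as truncation-by-resampling
(rejection sampling) rather than clipping: clipping would put probability
atoms at 0 and 2 and distort the type fractions. Since no mutation
operator is applied during a run, any drift of the population mean comes
from selection alone: `o` multiplies the G1 exit rate, so high-`o` clones
expand faster, and an untreated organoid's mean expression rises over
time. Cells are binned for reporting: Type 1 (1.5 ≤ o < 2), Type 2
(1 ≤ o < 1.5), Type 3 (0.5 ≤ o < 1), Type 4 (o < 0.5); the measure-zero
point o = 2 is assigned to Type 1.

## Resolved ambiguities

Several details of the published description are contradictory or
under-specified; the package resolves them as follows and exposes each
choice in the configuration.

* **Sign of the migration blend.** The printed update formula,
  `v = v_mot ((1-b) d_r - b d)/||...||`, sends a fully biased cell
  (b = 1) *down* the gradient, contradicting the surrounding text ("b = 1
  performs deterministic motion over the gradient direction"). We
  implement the text's semantics, `b d + (1-b) d_r`.
* **Random direction sampling.** The printed construction
  `(sin φ cos θ, sin φ sin θ, cos φ)` with θ ~ U[0, π], φ ~ U[0, 2π] is
  *not* area-uniform on the sphere. We replicate it by default for
  fidelity and provide `angles_uniform = TRUE` for area-uniform draws;
  chemotaxis outcomes are insensitive because the biased blend is
  renormalised to constant speed. Division axes, by contrast, are sampled
  properly uniform (and tested with a Rayleigh-type statistic).
* **Dose size.** Dose ratios are taken against the live cancer-cell count
  at the *first* dose; later doses administer `ratio_k / ratio_1` times
  the first dose's absolute count, so equal ratios give the same absolute
  amount of T-cells, as multiple-dose experiments require.
* **T-cell placement.** Dosed T-cells land uniformly at random in
  cell-free space outside the organoid's bounding sphere plus one cell
  diameter — they reach the organoid through its exposed surface without
  privileging a direction.
* **Attachment freezing.** Adhesion freezes the *target's cycling* and
  the *T-cell's motility* only; interaction forces continue to act on
  both.
* **Oxygen response thresholds** (arrest 5 mmHg, full proliferation
  10 mmHg, necrosis 5 mmHg, mean time-to-necrosis 6 h) are
  predecessor-model-style defaults, configurable and not validated
  against this model's published outputs.
* **Save cadence.** The published save interval (1400 min) is not an
  integer multiple of the cycle step (6 min); saves fire at the first
  cycle step crossing each multiple of `t_save`.

## Numerical scheme

Diffusion uses locally-one-dimensional (LOD) implicit splitting: per
substrate, one implicit decay step (`c / (1 + λ dt)`, exact for D = 0)
followed by a tridiagonal implicit solve along each axis with zero-flux
ends. The scheme is unconditionally stable, positivity-preserving, exactly
mass-conserving without decay/sources, and first-order accurate in `dt`
(halving the step halves the discrepancy against a fine-step explicit
reference — both properties are asserted in the test suite). Secretion and
uptake are rate-limited implicit exchanges with the cell's containing
voxel (voxel edge ≈ one cell diameter), scaled by the cell-to-voxel volume
ratio; uptake can never produce a negative concentration.

Positions integrate by forward Euler at the 0.1-min mechanics step; a
per-step displacement above one cell radius is flagged as a time-step
warning. The engine keeps a voxelised neighbour grid (30 µm bins,
refreshed every 20 mechanics steps as published) plus a Verlet pair list
with a 6 µm skin, rebuilt on the same cadence, on any population change,
and whenever accumulated displacement threatens the skin — the pair list
is an implementation detail that never changes which pairs interact.

All stochastic draws (R and compiled code alike) flow through R's global
random number generator, seeded once per run from the configuration seed.
This makes every run bitwise reproducible from its manifest. We chose the
single shared stream over per-module streams: the determinism contract is
identical, and no pre-installed counter-based generator is available to
both the R and compiled sides.

## What the seeding fixture does and does not emulate

`seed_organoid()` places cells on a jittered face-centred-cubic packing
trimmed to a centred sphere — a dense but non-overlapping aggregate with
at least 1.8 cell radii between neighbours, each cell with an independent
oncoprotein draw and a randomised cycle phase (phases sampled proportional
to their mean durations). This emulates a freshly formed, well-mixed
organoid. It does not emulate extracellular matrix, stromal or vascular
components, lumen formation, or any spatial correlation of expression
levels present in patient-derived organoids; conclusions about those
features are outside what passing tests can show.

## Scales used by the tests and the acceptance script

The published headline experiments run ~4000-cell organoids for 30
simulated days with 20 replicates — about six CPU-hours per run in the
original implementation, which is a cluster-scale budget. The package
therefore defines a desk preset (`desk_config()`): a 300 µm domain, a few
hundred cells, a few days, with the diffusion step relaxed to 0.05 min
(the implicit solver is unconditionally stable; the relaxed step is
checked against the 0.01-min reference in the suite). The test suite and
the acceptance script use smoke scales chosen as this package's own
trade-off between statistical signal and turnaround: oncoprotein sampling
at the published n = 3963; untreated-control drift over 10 replicates of
150-cell/5-day runs (the selection signal, ~0.01 oncoprotein units/day,
is already decisive there); a dose scan at ratios 0.25/1/2 with 3
replicates of 200-cell/6-day runs and hourly saves — at a few hundred
cells any effective dose eventually reduces the organoid to its
unrecognisable Type 4 residue, so the dose-*ordered* observable is the
kill speed, measured as the tumour minimum within hours of dosing
(`min_live_before()`); and waiting-time laws at 10⁴–10⁵ events.
The qualitative orderings being asserted (tumour minimum by dose,
dead-per-CAR-T against dose, selection lowering survivor oncoprotein) are
scale-robust; absolute 30-day figures are not reproduced at desk scale.

## Known limitations

* No vasculature: the Dirichlet-node mechanism exists, but no vessel
  geometry is generated.
* No T-cell proliferation, recruitment, cytokine signalling or
  immunosuppressive stroma; exhaustion is a lifespan draw, not a
  stimulation-dependent state.
* Oxygen thresholds and the adhesion constant are defaults of this model
  family, not calibrated values.
* Forward Euler mechanics with the published 0.1-min step is accurate for
  the gentle force scales used here but is not symplectic or adaptive;
  the fine-step oracle tests bound the error at these scales only.

# A worked example

```{r example, eval = FALSE}
cfg <- desk_config(
  n_cells = 200, days = 6, seed = 1,
  dose_days = 1, dose_ratios = 1
)
sim <- simulate_organoid(cfg)
glance(sim)
autoplot(sim)
radial_distribution(sim$final_cancer) |> plot_radial_distribution()
```
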