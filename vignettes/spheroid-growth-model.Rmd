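---
title: "A hybrid stochastic model of tumor spheroid growth: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid stochastic model of tumor spheroid growth: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, the numerical
choices, and the limits of what the synthetic experiments can show.

## The biological system and the modeling question

Multicellular tumor spheroids (MCTS) are avascular cell aggregates grown in
suspension; they reproduce the radial zonation of micro-tumors — a
proliferating rim, a quiescent middle zone, and a necrotic core — because
nutrients reach the interior only by diffusion from the medium while
inhibitory metabolites accumulate inside.  Growth curves alone cannot
discriminate between candidate control mechanisms (contact inhibition and
nutrient limitation, for instance, can produce the same radius-vs-time
curve), so the model here is built to be confronted with *spatial*
read-outs as well: radial profiles of cycling cells (Ki67-positive
analogue), dying cells (TUNEL-positive analogue) and extracellular matrix
(ECM, collagen-IV analogue), measured as a function of distance to the
spheroid border.

## Model structure

The model is hybrid:

* **Cells** are discrete agents occupying one or two sites of an
  unstructured three-dimensional lattice, advanced in continuous time by an
  exact stochastic simulation (Gillespie) algorithm.
* **Molecules** — glucose `G`, oxygen `O`, lactate `L`, ECM and necrotic
  waste `W` — are continuum concentration fields obeying reaction–diffusion
  equations on a regular grid.  Because molecular relaxation (minutes) is
  much faster than cellular dynamics (hours), every field is relaxed to its
  steady state at fixed intervals (`dt_field`) rather than integrated in
  time.

### The cell lattice

`build_lattice()` jitters a cubic grid of pitch `spacing` (default 16.8 um,
the measured cell diameter) by up to `jitter * spacing` per coordinate,
applies a few soft-sphere relaxation sweeps that push apart any pair closer
than `spacing` (a plain jittered grid biases nearest-neighbor distances
10–20% low, because the nearest of ~9 neighbors is selected), and takes the
**Gabriel graph** of the relaxed points as the neighbor relation: two sites
are adjacent iff the sphere with their segment as diameter contains no
third site.  The Gabriel graph is a subgraph of the Delaunay tessellation
and contains the Euclidean minimum spanning tree, so the lattice is always
connected; with zero jitter it reduces exactly to the 6-neighbor cubic
adjacency (co-spherical ties are excluded).  We chose it over a full
Delaunay construction because it is exactly and deterministically
computable with a short geometric predicate, has no degenerate cases after
jittering, and retains the properties the model actually uses: local,
symmetric, connected adjacency with controlled mean spacing.  The
outermost grid layer is flagged as permanently-free growth medium: cells
never occupy it, but it counts as free space for distance queries.

### Cell cycle, growth, division

The cycle is split into `m_d` Poisson stages (default 10), each advancing
at rate `m_d * k_div`, so the total cycle time is Erlang-distributed with
mean `tau = 1/k_div` (default 24 h) and coefficient of variation
`1/sqrt(m_d)`.  On the transition into stage `m_g` (default 5) the cell
doubles its volume by occupying a free neighbor site; if none exists, the
chain of cells along the shortest path — through occupied sites only — to
the nearest free site within `push_cap` hops is shifted outward by one
site each (ties broken by smallest site index, for reproducibility).  If
no free site is reachable the growth attempt is simply repeated at the
next stage event.  The `m_d`-th transition splits the cell into two
one-site daughters.

Each daughter then decides *stochastically* whether to keep cycling:

```
p_div = exp(-L / dL) * H(ECM - ECM_min)        (variants 1-3)
p_div = ... * H(n_exp_max - n_exp)             (variant 4)
```

`L` is the number of cells the daughter would have to push aside to reach
free space (a border cell has `L = 0`), so this is a probabilistic,
mechanical form of contact inhibition: deterministic thresholds produce a
sharp rim/quiescence interface, while the exponential form reproduces the
gradual decline of the cycling fraction with depth.  The ECM gate
`H(ECM - ECM_min)` encodes that cycle entry requires a minimal matrix
density (integrin signaling); it is responsible for the counterintuitive
*dip* of the cycling fraction in the outermost cell layer, where freshly
colonized territory has not yet accumulated matrix.  Quiescence is
permanent by default (`p_re * k_re = 0`); the probing re-entry mechanism
(rate `k_re`, acceptance `p_re` times the `p_div` form) is implemented and
switchable.

### Metabolism

Glucose and oxygen uptake follow a cross-inhibited Michaelis–Menten model
(`glucose_uptake()`, `oxygen_uptake()`): each rate saturates in its own
substrate and its maximal rate is reduced by the other substrate, with the
eight constants of the published EMT6/Ro consumption fit as defaults.  ATP
production combines glycolysis and oxidative phosphorylation,

```
p_ATP = 2 q_G + (17/3) q_O2    (0 below G_crit = 0.01 mM)
```

with 17 ATP per pyruvate (3 O2 per pyruvate); the shuttle-dependent
18-ATP alternative is a parameter.  Oxidizing one glucose consumes 6 O2,
so the aerobically used glucose flux is `q_O2/6` and the fermented
remainder produces two lactate each:

```
p_L = max(0, 2 q_G - q_O2 / 3)
```

At saturating supply the model cell oxidizes only ~8% of its glucose — the
Warburg-like regime — and `p_ATP` stays in a narrow band (~1000–1700 mM/h,
80–130e-17 mol/cell/s per 2700 um^3 cell) over wide concentration ranges,
because each pathway compensates the other.  The conversion between tissue
rates (mM/h) and per-cell rates (mol/cell/s) is `rate_mmh_to_molcells()`.

### The four growth-control variants

| variant | division gate | death rule |
|---|---|---|
| 1 | `H(G*O - p_oxyglc)` | `H(p_oxyglc - G*O)` |
| 2 | `H(p_ATP - 900)` | `H(900 - p_ATP)` |
| 3 | `H(p_ATP - 900)` | ATP rule OR lactate Hill `L^2/(20^2+L^2)` |
| 4 | variant 3 gate, halved per adverse flag | as variant 3 |

Variant 4 halves the cycling speed when local waste exceeds `W_max` or
oxygen falls below `O_min` (quartered when both hold), and it accumulates
an exposure counter `n_exp` at one nominal cell cycle per `tau` while
either flag holds; a cell whose exposure reaches `n_exp_max = 8` cycles
becomes permanently quiescent at its next division.  Two printed-form
ambiguities were resolved on substance grounds: the lactate Hill
denominator is `L_max^n + L^n` (the difference form diverges and
contradicts the stated half-rate at 20 mM), and the ATP and lactate death
hazards combine as independent risks (noisy-OR) rather than as a product,
which would abolish starvation death in lactate-free regions; the literal
product is available as `knec_combination = "product"`.

Dying cells keep their sites (they remain TUNEL-positive mass) and lyse at
`k_lys = 0.01/h` — deliberately slow, the in-vitro regime without
macrophage clearance; only such slow lysis lets a necrotic core persist.
Lysis frees the sites for reuse.  Waste is released by dying cells and
taken up by viable ones (sources `k_gen_W * phi_dead`, sinks
`k_upt_W * phi * W`).

### Fields and their boundary conditions

All five species satisfy steady-state reaction–diffusion balances on a
regular grid covering the lattice box, with 7-point central differences
and harmonic-mean face diffusivities at the tumor/medium interface (the
flux-continuous choice).  Dirichlet values on the box faces idealize a
hanging drop with medium renewal: medium concentrations for `G`/`O`, zero
for `L`, ECM, `W`.  Diffusivity inside tissue is `med_ratio = 30` times
smaller than in the medium for the freely diffusing species.  The tumor
mask is the set of occupied grid nodes after a morphological closing.

The coupled `G`/`O` problem is nonlinear (cross-inhibited uptake): it is
solved by a damped Newton linearization whose derivative term sits on the
matrix diagonal, keeping the operator an M-matrix and hence the iterates
non-negative; convergence is declared when the relative nonlinear residual
falls below `tol = 1e-8` (default), and damping halves on residual
increase.  Lactate, ECM and waste are then single linear solves with
frozen sources.  Linear systems use CHOLMOD Cholesky factorizations; a
cached factor serves as conjugate-gradient preconditioner between
refactorizations (CG relative residual 1e-12, three orders below the field
tolerance, so the direct and iterative paths agree to well under 1e-8).

### Coupling and time stepping

`run_simulation()` alternates Gillespie event processing within a field
window and a steady-state refresh of all fields at window boundaries; all
per-site rates (`k_div`, `k_nec`, the ECM gate, the exposure flag) are
interpolated trilinearly from the grid and frozen for the window, and a
cell's own rate is refreshed whenever its state or sites change.  The
bookkeeping is audited every window: the incrementally maintained total
rate is compared against a from-scratch recomputation, and occupancy
exclusivity/ownership is re-verified.  Runs are bitwise reproducible given
the seed.

## Parameters: defaults and provenance

Fixed by the source material: the eight uptake constants, `G_crit` = 0.01
mM, `p_ATP_min` = 900 mM/h, `L_max` = 20 mM (Hill `n` = 2),
`ECM_min` = 0.003, `n_exp_max` = 8 cycles, `k_lys` = 0.01/h, the four
nutrient conditions, and the 2700 um^3 reference cell volume / 16.8 um
cell diameter.

Chosen by calibration (no published per-cell-line values exist for these,
so they are this package's own choices, set once against the qualitative
behaviors this system is known for — proliferative rim width, necrotic
core emergence, saturation ordering of the four conditions — and
documented here):

* `tau` = 24 h, `m_d` = 10, `m_g` = 5.
* `dL` = 2 sites: pushing range of the contact-inhibition probability;
  the front advance speed (~0.7 um/h at desk scale) is set mostly by
  `tau`, while `dL` controls how deep interior cells keep cycling.
* `k_nec_max` = 0.1/h (~10 h from fatal starvation to TUNEL-positive),
  `k_apt` = 0 (apoptosis negligible for this system).
* Tissue diffusivities (um^2/h): `O` 3.6e6, `G` and `L` 3.6e5 (classic
  tissue values ~1e-5 and ~1e-6 cm^2/s), waste 1e5 (macromolecular
  debris), ECM 50 (a deposited network barely spreads).
* ECM turnover `k_gen_ECM` = 8e-4, `k_deg_ECM` = 0.05 per hour: the
  interior plateau is then ~0.009 (dimensionless intensity, order of dim
  collagen-IV fluorescence), which puts the fixed gate 0.003 at roughly a
  third of the plateau so that the sub-threshold region is exactly the
  freshly colonized outermost layer.  With a plateau of order 1 the 0.003
  gate could never act at the border (steady-state ECM at new border sites
  is a geometric fraction, ~0.1-0.5, of the plateau), and the observed
  border proliferation dip would be unreproducible.
* `p_oxyglc` = 1 mM^2 (variant 1 only): places the variant-1 quiescence
  boundary at a comparable depth to the ATP rule under the hypernourished
  condition.
* `O_min` = 0.07 mM: the hypoxic condition's medium concentration, so
  that condition IV is uniformly oxygen-deprived (its interior is strictly
  below the boundary value), which is what makes it saturate early.
* `k_gen_W` = 0.05/h, `k_upt_W` = 0.02/h, `D_W` = 1e5 um^2/h uniform
  (debris aggregates diffuse slowly in medium too, keeping the inhibitor
  cloud around the spheroid), and `W_max` = 1.5e-4: waste is a
  dimensionless concentration with a free scale, and the threshold is
  placed at the level the waste field attains at the *rim* once a
  substantial necrotic core has developed (~1e-3 in the core, a fifth of
  that at the rim, at desk scale).  Waste effects then engage for the
  hyponourished condition from mid-run while the nutrient-rich conditions
  stay below threshold outside their cores at desk-scale radii.

## Desk-scale study conditions

The reference experiments start from ~10000 cells and run for 48 days;
the package's default experiment is deliberately smaller, chosen as the
scale a desk machine explores interactively: 800 initial cells (initial
radius ~100 um) on a 34^3-site lattice, 216 h of growth (the spheroid then
spans about half the box, leaving a medium shell), field refresh every 1 h
in the test configurations (0.1 h remains the package default; the steady-state fields make the refresh interval a pure
accuracy knob, and halving it does not visibly change desk-scale
trajectories), field grid at twice the lattice spacing.  All sizes are
stated here as the package's own choices.

What the desk-scale runs *do* show, per nutrient condition: near-linear
radius growth with later slowdown; the hypoxic condition IV arresting
outright once its uniform oxygen deprivation exhausts the 8-cycle exposure
tolerance; the hyponourished condition I falling behind the richer
conditions II/III through starvation death, core lysis and waste-halved
cycling at the rim; II and III growing similarly and largest; a cycling
fraction that declines with border distance and is depressed in the
outermost layer when the ECM gate is active; and a central necrotic core
under glucose limitation.  What they do *not* show: full waste-driven
arrest of condition I inside the window (the 8-cycle exposure delay is
192 h and the waste cloud needs a developed core first, so the complete
arrest lies beyond the desk horizon); the absolute radii and time scales
of full-scale growth experiments (those require the 10^4-cell, 48-day runs
and per-cell-line parameter fits); lactate reaching its 20 mM
half-death concentration (a ~400+ um spheroid is needed to accumulate
that much lactate); and any comparison against experimental
reference profiles (none are bundled with the package).

## The likelihood/AIC comparison surface

`gaussian_loglik()` scores model curves against measured means and
standard deviations as independent Gaussians (points with larger
uncertainty weigh less; the exponent carries the conventional negative
sign), `aic()` applies the `2k - 2 lnL` penalty, and
`score_against_reference()` interpolates simulated curves linearly onto
the reference abscissae.  The parameter counts attributed to the variants
(8, 8, 10, 17) reproduce the nesting differences (+2 for the lactate
response, +9 for the waste machinery) that matter for model ordering;
absolute counts only shift all AICs by a constant.

## The image-analysis pipeline and its synthetic ground truth

The imaging module mirrors the quantitative section analysis used for
stained cryosections: four passes of a 3x3 median filter (edge-preserving
smoothing; reflective padding; the 3x3 case uses an exact pmin/pmax
median network), watershed segmentation of the thresholded nuclei channel
(flooding the inverted intensity landscape via EBImage, with a tolerance
merging spurious basins), per-pixel marker thresholds `I_*` and
per-nucleus fractional thresholds `phi_*` (defaults 0.15/0.45/0.20/0.35/
0.05 for HOECHST/TUNEL/phi-TUNEL/Ki67/phi-Ki67), sensitivity/specificity/
classification-error bookkeeping, lumen estimation by repeated 3x3
dilation plus hole filling, border extraction, half-open 1-um radial
binning, and projected cell areas from a *discrete* Voronoi assignment of
raster pixels to nucleus centroids (clipped to the lumen; boundary-
touching cells excluded), with equivalent diameter `2 sqrt(A/pi)`.  The
discrete tessellation was chosen over an exact polygon construction
because the measurement it emulates is itself pixel-limited, and it
recovers the closed-form areas of square and hexagonal point lattices to
raster precision.

`generate_synthetic_section()` provides ground truth the real micrographs
cannot: nuclei as Gaussian blobs on a jittered triangular packing inside a
disc (so the packing limit is explicit), a known marker-positive subset,
a radial ECM intensity, additive Gaussian noise and background.  It
emulates well-separated, roughly equal-sized nuclei; it does **not**
emulate touching/overlapping nuclei, intensity bleed-through between
channels, sectioning artifacts or staining gradients, so a passing
pipeline demonstrates correctness of the operators, not robustness on
difficult real sections.

## Numerical and degenerate-input choices

* Field solves: relative nonlinear residual `1e-8`, at most 200 Newton
  sweeps, damping halved on residual growth; negative overshoots smaller
  than the tolerance are clipped to zero, anything larger fails loudly.
* The discrete maximum principle holds for the pure-sink species: interior
  `G`/`O` never exceed their boundary values.
* Pushing paths and the re-entry probe break ties by smallest site index;
  all stochastic draws go through R's RNG, so a seed fixes the full
  trajectory.
* Degenerate inputs error explicitly: occupied-site queries on free sites,
  division of one-site cells, lysis of viable cells, negative
  concentrations, singular steady-state operators (no Dirichlet face and
  no decay), collinear Voronoi inputs, over-dense synthetic sections.
* An interior free region created by lysis is treated as enclosed holes
  when classifying the border (mirroring the hole-filling of the image
  pipeline), so radial profiles measure distance to the *outer* surface.

## Known limitations

* Rates are frozen within a field window (operator splitting); events
  within a window see slightly stale concentrations.  At the default
  cadences this is far below the stochastic noise.
* Pushed two-site cells move site-by-site and may transiently span
  non-adjacent sites; occupancy exclusivity is always preserved and
  audited.
* The lattice is static: no off-lattice mechanics, no deformable shapes,
  no refinement.
* Parameter estimation is out of scope: the package simulates forward and
  scores against references; it does not optimize.
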