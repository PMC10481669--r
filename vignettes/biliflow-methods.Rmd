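---
title: "Methods: the lobule bile-pressure model and zone-resolved morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the lobule bile-pressure model and zone-resolved morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biliflow)
```

## The model and its assumptions

`biliflow` treats the liver lobule as a radially symmetric cylindrical
annulus between the central-vein radius $\rho_0$ and the lobule radius
$L$. Bile is generated by osmotic water influx across the hepatocyte
apical membrane into the canalicular lumen and drains periportally
through the canalicular meshwork, modelled as a porous medium. Steady
state mass balance for water and osmolytes plus Darcy's law give three
coupled first-order ODEs for the radial bulk velocity $w$, canalicular
pressure $p$ and osmolyte concentration $c$:

$$\frac{(\rho w)'}{\rho} = \kappa A \left( RT (c - c_0) - p \right),
\qquad \frac{(\rho c w)'}{\rho} = g, \qquad p' = -K(\rho)\, w,$$

with $w(\rho_0) = 0$ (no flux through the vein wall) and $p(L) = p_L$
(the bile-duct pressure). The osmolyte equation integrates exactly to
$\rho c w = G(\rho) = \int_{\rho_0}^{\rho} \tilde\rho\, g\, d\tilde\rho$,
eliminating $c = G/(\rho w)$. The Darcy coefficient follows from a
parallel-tube porous-medium closure,
$K = 8 \mu \tau^2 / (\varepsilon_{BC}\, r_{BC}^2\, f)$.

Assumptions worth keeping in mind: the lobule is radially symmetric (no
3D network-resolved flow), flow is steady, bile behaves as a Newtonian
fluid of constant viscosity, osmolytes are a single effective species,
and secretion $g$ is taken spatially constant unless a profile is
supplied.

## Parameters

| symbol | meaning | unit | default |
|---|---|---|---|
| $\kappa$ | apical water permeability | m/(Pa s) | $4.7\times10^{-10}$ |
| $c_0$ | hepatocyte osmolyte concentration | mol/m³ (= mmol/l) | 300 |
| $\mu$ | bile viscosity | Pa s | $9.2\times10^{-4}$ |
| $\tau$ | canalicular tortuosity | — | 1.8 |
| $f$ | free lumen ratio | — | 0.28 |
| $p_L$ | bile-duct boundary pressure | Pa | 1,000 control / 2,000 PSC |
| $T$ | temperature | K | 310 |
| $g$ | osmolyte secretion rate | mol/(m³ s) | calibrated (see below) |

Temperature is not part of the published parameter set; it enters only
through $RT$, and body temperature (310 K) is the configurable default.
The secretion rate is the one genuinely free input: it is not measurable
at tissue scale, so `calibrate_secretion()` inverts the forward model —
bisection on the scalar $g$, which the axis-median pressure increases in
monotonically — against a reference axis-median pressure (the control
reference, 1,922 Pa, in the acceptance script). All other constants are
literature values; no fitting is involved.

## Numerics

**Singular start.** At the central vein $w = 0$ makes $c = G/(\rho w)$ a
$0/0$ limit. Writing $u = \rho w$, the limit concentration $c^*$ solves
the quadratic
$\kappa A RT c^{*2} - \kappa A (RT c_0 + p_0) c^* - g = 0$, whose
positive root always exceeds $c_0 + p_0/RT$ for $g > 0$, so initial
influx is strictly outward. Integration starts at
$\rho_0 + \delta$, $\delta = 10^{-3} (L - \rho_0)$, from the
leading-order series $u = \rho_0 \kappa A (RT(c^* - c_0) - p_0)\delta$.
Two details matter in practice. First, the effective centre secretion
used in the quadratic is the slope of the *discretized* $G$, so that the
start state lies exactly on the quasi-steady manifold of the system the
integrator actually sees — off-manifold starts inside the stiff boundary
layer cost orders of magnitude in step count on coarse, ragged
geometries. Second, the integration states are $(c, p)$, not $(u, p)$:
$c$ stays $O(c_0)$ and $p$ stays $O(p_L)$, whereas $u$ traverses many
decades through the start layer, which wrecks error control and
finite-difference Jacobians. The $c$-equation is obtained by
differentiating $c = G/u$:
$c' = (\rho c / G)\,\bigl(g - \kappa A c\, (RT(c - c_0) - p)\bigr)$,
and $u = G/c$ is recovered afterwards.

**Shooting.** The residual $r(p_0) = p(L) - p_L$ is monotone increasing
(a larger central pressure suppresses influx and therefore the pressure
drop), $r(p_L) \le 0$ under non-negative secretion, and the bracket is
expanded geometrically upward before Brent refinement
(`stats::uniroot`). Defaults: terminal tolerance 0.1 Pa on $|p(L)-p_L|$
(terminal pressures are $O(10^3)$ Pa), integrator relative tolerance
$10^{-8}$ (`deSolve::lsoda`). The impermeable limit $\kappa = 0$ and the
secretion-free limit $g = 0$ are returned exactly (no flow, uniform
pressure) rather than integrated.

**Degenerate inputs.** Geometry validation rejects non-monotone grids
and non-positive profiles, naming the offending grid point. A zero
denominator in $K$ is an error, not a warning. If the central quadratic
has no positive root (possible only in hand-constructed corner cases),
the solver falls back to $c^* = c_0 + \epsilon$ with a warning.

**Zone summaries.** Pressure zones are 11 equal-width radial bins of the
annulus, displayed 0 (CV) to 10 (PV); bin construction is not prescribed
by the plotting convention, and equal width in $\rho$ is the simplest
choice. The "axis median" is ambiguous between the median of the
pointwise profile and the median of zone medians; both are computed and
the pointwise median is canonical.

## Network morphometry

Spatial graphs carry nodes with 3D coordinates and edges with radii;
lengths are always recomputed from coordinates. The CV→PV coordinate of
a point is its distance from the CV *edge* divided by the CV-edge-to-PV-
edge distance — a straight-line normalization matching how axes are
imaged as straight tile strips, not a geodesic. Edges belong to the zone
of their midpoint; length-splitting across zone boundaries is
deliberately avoided because boundary-spanning edges are counted
separately by the crossing statistic. Per zone the package reports the
length-weighted mean radius, lumen volume fraction and surface density
(normalized by the annular-sector tissue volume actually sampled),
connectivity $= 1/\#$ connected components of the zone-induced subgraph,
crossings of the zone's CV-side boundary per boundary area (arc length ×
imaging depth — the normalization is configurable since only the unit,
#/mm², is standard), and junctions (full-graph degree ≥ 3) per network
length.

When a network is reduced to radial profiles for the pressure model
(`network_to_geometry()`), $\varepsilon_{BC}$ and $A$ are the exact
per-shell sums $\sum \pi r^2 \ell / V$ and $\sum 2\pi r \ell / V$, but
$r_{BC}$ is the *length-weighted* mean radius: the viscous resistance of
a parallel-channel network is set by the typical canalicular calibre,
and letting rare cystic dilations (rosettes) dominate a volume-weighted
mean would collapse $K$ by orders of magnitude where a single rosette
sits. Empty shells are filled by linear interpolation from populated
neighbours, with a warning.

## Rosette conventions

Rosettes in 3D are contiguous runs of segments with diameter strictly
greater than 6 µm, merged across shared nodes into single segments (the
alternative, per-edge counting, is available via `merge_runs = FALSE`);
a segment is characterized by its maximal edge radius, binned at integer
radii $j = 3..8$ µm, with radii ≥ 9 µm clamped into the top bin (with a
warning) rather than dropped — conservative volume accounting. The
estimated volume is $V = \sum_j \frac{4}{3}\pi (j + j_{off})^3 N_j$ with
$j_{off} = 0.2$ µm, reflecting that rosettes binned at $[j, j+1)$ are on
average larger than $j$. On 2D sections a rosette is a lumen with
diameter > 6 µm bounded by > 2 hepatocytes; marker positivity is
any-bounding-cell with strict thresholds (Sox9 nuclear > 200, pan-CK
cellular > 1,000). All inequalities are strict; ties are excluded.

## What the synthetic generator emulates — and what it does not

The generator produces, per seed, an annular-sector spatial network
(stratified node placement along the axis, nearest-predecessor spanning
tree plus short-range extra links for branch points), radial geometry
profiles, and 2D section tables. The regime defaults are the study
conditions: control lobule radius 512 µm and PSC 968 µm (the reported
cohort medians); PSC calibres dilated by the factor 1.116 (the reported
~11.6 % mean-radius increase); baseline edge radius 0.55 µm with
lognormal jitter truncated below 3 µm (canalicular radii in such
reconstructions are ~0.5–0.8 µm; truncation guarantees zero false
rosettes by construction); rosette insertion probability 0.005 per edge
in controls vs 0.04 in PSC, radii uniform on [3, 8] µm; Sox9/pan-CK
positive fractions 0.28 and 0.04 (the reported ~28 % and ~4 %). A
rosette is inserted by splitting its host edge and dilating only the
middle third — a compact blob on an otherwise ordinary canaliculus —
because whole-edge dilation (~20 µm tubes) would be morphologically
wrong and let rosette volume dominate zone statistics. Two disease knobs
shape the spatial structure: `rosette_cv_bias` tilts insertion
pericentrally (rosette burden relative to network volume is highest in
CV zones), and `dropout_fraction` removes edges with the same axial
bias, emulating network degradation that co-localizes with rosette
formation; the cohort simulator uses bias 0.8 and the PSC default
dropout 0.1. Adjacency is decided in normalized coordinates, so two
regimes sharing a seed share topology, and the dilation contract (PSC
per-zone mean radius ≥ control at matched seeds, without dropout) holds
edge by edge.

The cohort simulator mirrors the imaging design: 3 control patients with
one CV–PV axis each and 4 disease patients with three axes each, pooled
per (sample, zone) with no within-sample averaging before correlation.
The null cohort draws every sample from the control regime, so rosette
burden varies only by sampling noise. Even in the null, rosette volume
feeds back weakly on predicted pressure through $\varepsilon_{BC}$ —
that channel is physics, not a bug — which is why the null uses the
sparse control burden where the channel is negligible.

What the generator does **not** emulate: real reconstruction artefacts
(fake end branches, radius estimation bias from voxelization),
patient-to-patient variability in geometry profiles beyond seed noise,
spatial clustering of rosettes, pericentral–periportal zonation of
secretion, or any image-level process. Passing tests therefore
demonstrate correctness of the algorithms and the direction-level
statistical structure, not quantitative agreement with any patient
cohort.

## Problem sizes and design choices

Analytic geometries use 101 radial grid points; synthetic networks use
45 nodes per zone × 11 zones (≈ 500 nodes, ≈ 700 edges) for cohort work,
which keeps a full two-arm cohort (15 axes, each through generation,
morphometry, rosette quantification, geometry reduction and pressure
solve) around a few seconds and makes 50-replicate sign-consistency
studies practical. The balance-residual checks use an 801-point grid
where quadrature error would otherwise mask integrator accuracy. The
independent cross-check for the solver is a trapezoidal-collocation
solution of the same boundary-value problem (nondimensionalized damped
Newton on the full residual system), written separately from the
shooting path and kept in the test suite.

## Known limitations

* The pressure model is radial and steady; no network-resolved or
  time-dependent flow.
* $g$ is constant by default; zonated secretion profiles are accepted
  but untested against data.
* Crossing-statistic normalization (boundary arc × depth) is one
  reasonable reading of a #/mm² unit; absolute crossing densities are
  therefore convention-dependent.
* Connectivity of sparse zone subgraphs is a small-count statistic; its
  per-zone values on synthetic networks are noisy, and only directions
  and contrasts should be interpreted.
* The 2D section generator draws intensities from simple uniform
  mixtures; it supports threshold-rule testing, not intensity-model
  inference.
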