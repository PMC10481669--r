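# biliflow

Canalicular bile-pressure modelling and zone-resolved network morphometry
for the liver lobule.

In cholestatic disease such as primary sclerosing cholangitis (PSC), the
bile canaliculi — the sub-micron lumina between apposed hepatocyte apical
membranes that drain bile toward the portal field — remodel dramatically:
calibres dilate, the network fragments, and aberrant lumina wider than
6 µm bounded by more than two hepatocytes ("liver cell rosettes") appear
throughout the lobule. Because canalicular pressure cannot be measured
directly, it must be predicted from network geometry with a biophysical
model. `biliflow` is for quantitative hepatologists and tissue
biophysicists who have (or want to emulate) skeletonized 3D
reconstructions of canalicular networks along the central-vein-to-portal-
vein (CV–PV) axis and want to go from geometry to predicted pressure,
rosette burden, and the statistics linking them.

## The model

The lobule is a radially symmetric annulus from the central-vein radius
ρ₀ to the lobule radius L. Mass conservation of water and osmolytes plus
Darcy flow through the canalicular meshwork give, for the radial bulk
velocity w, canalicular pressure p and osmolyte concentration c:

    (ρw)′/ρ = κ A (RT(c − c₀) − p)        osmotic water influx
    (ρcw)′/ρ = g                          osmolyte secretion
    p′      = −K(ρ) w                     Darcy's law

with boundary conditions w(ρ₀) = 0 and p(L) = p_L (the bile-duct
pressure: 1,000 Pa in controls, 2,000 Pa behind PSC strictures). The
osmolyte equation integrates to ρcw = G(ρ) = ∫ᵨ₀^ρ ρ̃ g dρ̃, which
eliminates c; the resistance follows from porous-media theory,

    K(ρ) = 8 μ τ² / (ε_BC(ρ) · r_BC(ρ)² · f(ρ)),

with bile viscosity μ = 9.2×10⁻⁴ Pa·s, tortuosity τ = 1.8, free lumen
ratio f = 0.28, water permeability κ = 4.7×10⁻¹⁰ m/(Pa·s) and
c₀ = 300 mmol/l. The two-point boundary-value problem is singular at the
central vein (c = G/(ρw) is a 0/0 limit there); `biliflow` resolves the
limit analytically via a quadratic fixed point and solves the remaining
problem by shooting on the central pressure p₀ with bracketed Brent
iteration. Alongside the solver, the package computes the six
zone-resolved network statistics (radius, volume fraction,
surface/volume, connectivity = 1/#disjoint pieces, boundary crossings,
junction density), detects rosettes as contiguous runs of super-threshold
segments, estimates their volume as V = Σⱼ (4/3)π(j + 0.2)³ Nⱼ over
radius bins j = 3…8 µm, applies the 2D section rules (> 6 µm, > 2 cells,
Sox9 > 200, pan-CK > 1,000), and runs the Pearson/t-test correlation
stage. A seeded synthetic generator emulates control and PSC-like lobules
(512 vs 968 µm radius, ~11.6 % dilated calibres, sparse rosettes) so the
whole pipeline is testable without imaging data.

## Worked example

```r
library(biliflow)

geom <- gen_radial_geometry(synthetic_config("control", seed = 1))
sol  <- solve_pressure(geom, bile_params(g = 0.87))  # g in mol/(m^3 s)
glance(sol)
#> # A tibble: 1 × 5
#>   p0_pa axis_median_pa elevation_pa residual_pa iterations
#>   <dbl>          <dbl>        <dbl>       <dbl>      <int>
#> 1 2189.          1920.        1068.   0.0000393          8

zone_pressure_summary(sol)$zones
#> # A tibble: 11 × 3
#>    zone median_pa     n
#>   <dbl>     <dbl> <int>
#> 1     0     2186.    10
#> 2     1     2166.     9
#> 3     2     2130.     9
#> # ...
```

The axis-median canalicular pressure is ~1,920 Pa, the centre runs
~1,070 Pa above the portal boundary, and the per-zone medians fall
monotonically from zone 0 (pericentral) to zone 10 (periportal) — the
one-way architecture that drives bile opposite to blood flow. On the
disease side:

```r
net <- gen_network(synthetic_config("psc", seed = 1))
ros <- detect_rosettes(assign_zones(net))
glance(ros)
#> # A tibble: 1 × 3
#>   n_segments total_volume_um3 max_radius_um
#>        <int>            <dbl>         <dbl>
#> 1         22           17407.          7.58
```

22 rosette segments (maximal radius 7.6 µm) were inserted and recovered;
`rosette_network_ratio()` relates their estimated volume to the network
volume per zone, and `simulate_cohort()` + `assemble_report()` reproduce
the pooled per-zone correlation analysis (rosette burden vs predicted
pressure, and vs connectivity). `autoplot()` methods render the pressure
profile, zone statistics and network projections.

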