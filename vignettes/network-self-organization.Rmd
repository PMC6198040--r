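---
title: "Polar versus nematic self-organization of microtubule-motor networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polar versus nematic self-organization of microtubule-motor networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mtnet)
```

## The model

`mtnet` simulates mixtures of dynamic microtubules and two-headed
crosslinking motors in a thin three-dimensional box, periodic in x and y
and harmonically confined in z. The aim is to reproduce, at desk scale,
the two prototypical network states of such mixtures — radial,
polarity-sorted asters and aligned, mixed-polarity nematic networks — and
the two dimensionless parameters that decide between them: the number of
motors per filament, `N_mot/N_MT`, and the ratio of filament growth speed
to motor speed, `v_g/v_m`.

**Filaments.** Each filament is a discretized elastic rod (segment length
0.5 µm, bending rigidity 20 pN µm²) with a static minus end and a dynamic
plus end. A fixed pool of immobile nucleators fires as a first-order
process at rate `k_nuc`; each busy nucleator owns exactly one filament, so
the filament number is bounded by the nucleator count and settles at a
nucleator-limited steady state. Plus ends follow a two-state model without
rescue: growth at `v_g exp(f_a/f_g)` under antagonistic tip load
`f_a < 0` (the factor is capped at 1 for assisting loads, which the model
does not accelerate), stochastic catastrophe at `k_cat`, shrinkage at
`v_s`, and deletion (freeing the nucleator) when the length reaches zero.
By default `k_cat` is tied to the growth speed so the mean length at
catastrophe, `L_0 + v_g/k_cat`, equals 2.5 µm at every growth speed
scanned; this keeps the filament density comparable across the `v_g` axis
of a phase scan. A fixed-`k_cat` mode is available by passing `kcat`
explicitly.

**Motors.** A motor is a pair of heads joined by a Hookean link (rest
length 0.05 µm, stiffness 100 pN/µm). Unbound motors form a well-mixed
pool (diffusion is assumed fast); a free motor binds a uniformly chosen
filament site at rate `k_on`, and the partner head then binds any other
filament within the capture radius `r_b` at the same rate, attaching at
the nearest point. Bound heads walk toward the plus end with the linear
force-velocity law `v = v_m (1 + f·d/f_stall)`, clamped below at zero (no
load-driven backstepping; assisting loads are taken literally). A head
that reaches the plus end stays there — the end dwell — until it unbinds
at `k_end`; a growing end that outruns the head reverts it to side-bound.
Unbinding is load-accelerated by Kramers' law,
`k = k_base exp(|f|/f_unbind)`, using the magnitude of the spring force.
On a shrinking filament, a head whose attachment point has depolymerized
detaches: carrying motors on a tip shrinking at 500 nm/s would fabricate
end-bound clusters out of depolymerization rather than motor transport.

**Sterics.** Filament vertices of different filaments repel through a
soft core, `f_s = κ_s (d_0 − d)` for `d < d_0`, zero beyond. With
`d_0 = 0.1` µm the excluded region around a 2.5 µm filament (cylinder
plus end caps) has a volume of 0.02 µm³. The force direction is the
separation vector with its component along the mean filament axis
removed, applied as an exact action-reaction pair: this conserves
momentum exactly and is exactly perpendicular to both filament axes in
the parallel and anti-parallel contacts that dominate bundles, so steric
forces never oppose sliding along the axis. (Perpendicularity to *both*
axes and exact momentum conservation cannot hold simultaneously for
crossing filaments at vertex resolution; we chose to keep the
conservation law exact.) When the separation is parallel to the common
axis, a seeded random perpendicular direction is used.

## Numerical scheme

Motion is overdamped Langevin dynamics with per-vertex drag
`γ = 3πη·(segment length)` and thermal noise `sqrt(2 k_B T γ / dt)`.
The integrator is explicit Euler–Maruyama with three stabilizing
elements:

* **Bending** is taken semi-implicitly: each filament solves
  `(I + (dt/γ) κ_b D₄) x' = x_pred` per coordinate (banded LDLᵀ), so the
  bending stiffness never binds the time step.
* **Crosslink and steric springs** are treated diagonally-implicitly: the
  response of a vertex to its attached spring forces is scaled by
  `1/(1 + dt·K/γ)`, where `K` is the total spring stiffness attached to
  that vertex. Motors accumulate on filament overlaps — dozens of
  crosslinks can bridge one filament pair — and this local implicit
  damping keeps the scheme stable for arbitrarily many stacked springs
  (the symmetric pair mode has amplification `|1 − 2κdt/(γ + κdt)| < 1`
  for any κ). The cost is a slight slow-down of the relaxation of
  heavily bridged pairs; equilibria are unaffected.
* **Inextensibility** is enforced by two sweeps of position-based
  segment-length projection followed by periodic arc-length resampling
  anchored at the minus end (so growth and shrinkage never move the minus
  end; only forces do). Segment lengths are exact after resampling and
  accurate to a small tolerance in between.

With these choices the default step is `dt = 2` ms. A step in which any
vertex moves farther than one segment length aborts the run with a
diagnostic rather than continuing on an unstable trajectory. All
randomness comes from one generator seeded from R's RNG at entry, with a
fixed draw order per step (nucleation, instability, attachment, walking,
detachment, noise), so a run is an exact deterministic function of
(configuration, seed).

## Classification

Every doubly bound motor is a crosslink record carrying the end-bound
flags of its heads and the internal angle θ between the plus-end-directed
local tangents at the two attachment points. End-bound status takes
precedence: both ends → V, one end → T; side-side links split by angle
into Hp (θ < π/3), Hap (θ > 2π/3) and X (closed interval between). The
aster-strength parameter is `c_max = C_max/N_MT`, with `C_max` the node
count of the largest connected component of the filament graph whose
edges are V links, evaluated on the final frame; no V links means
`c_max = 0` (isolated filaments are not clusters). Networks with
`c_max ≥ 0.01` are asters. Otherwise the polarity-sorting parameter
`P = H̄p/(H̄p + H̄ap)`, time-averaged over the trailing 4% of the run,
places the network on the nematic (0.5) to polar (1) gradient. A run with
neither V links nor side-side links is reported as unclassified, with `P`
missing rather than 0.5.

## Extensile behavior

Anti-parallel (Hap) crosslinks slide filaments backward as both motors
walk toward their respective plus ends. The metric is the mean dot
product between the unit minus-end displacement over a lag Δt = 100 s
(minimum-image across the periodic box) and the unit plus-end direction;
minus ends are used precisely to avoid counting plus-end growth as
motion. Filaments displaced less than 1 nm are excluded (the direction of
a zero vector is undefined). Negative means backward transport. In the
desk-scale nematic cell the mean is about −0.74, and its magnitude falls
monotonically as the motor speed is lowered to zero; it does not vanish
at zero motor speed because growing plus ends push against the crowded
network and recoil their filaments backward. At desk density this
growth-pushing contribution is considerably larger relative to the
motor contribution than in a dilute large-box system — a known
consequence of the small, crowded geometry, not of the motor model.

## Single-filament theory

The control role of `v_g/v_m` comes from the distribution of motors on
one growing filament. With binding at `k'_on` per unit length on the
existing lattice, side unbinding at `k_off`, walking at `v_m` and growth
at `v_g`, the side density obeys an advection-reaction equation with a
moving source boundary; the end-bound population is fed by the flux
`(v_m − v_g) ρ(tip)` and drained at `k_end`. Solving by characteristics
(for `v_m > v_g`):

* `ρ(x,t) = ρ₀ (1 − e^{−k_off x / v_m})` on the occupied domain — a
  depletion layer of width `v_m/k_off` at the minus end, because bound
  motors stream toward the tip;
* `n_s(t) = ρ₀ (L − (v_m/k_off)(1 − e^{−k_off L/v_m}))`, `L = v_g t`;
* tip density `ρ₀ (1 − e^{−(k_off/v') t})` with `v' = v_m/v_g`, hence
* `n_e(t) = n_∞ (1 − ψ e^{−(k_off/v') t} − (1 − ψ) e^{−k_end t})` with
  `n_∞ = ρ₀ (v_m − v_g)/k_end` and `ψ = (1 − k_off/(v' k_end))^{-1}`,
  evaluated by its analytic limit when `k_off/v' = k_end`.

These forms were derived here and are verified against an independent
method-of-lines integration (first-order upwind with an area-weighted
moving source; the oracle refuses CFL-violating steps) to better than
0.5% over a 3 × 3 grid of `v'` and `k_off/k_end`; where transcriptions
of such results disagree on the form of ψ, the numerical oracle is the
authority. Two consequences matter for networks: the end/side ratio
`n_e/n_s` at a given time depends on the speeds only through `v_m/v_g`
(the scale cancels), and end accumulation is strongest on short, young
filaments — which is why end-end V links dominate early and give way to
side-side links as filaments lengthen. When `v_m ≤ v_g` the tip outruns
the motors and `n_e ≡ 0` (returned clamped, with a warning). A
discrete-event stochastic simulator of the same process converges to the
oracle as replicates grow; four replicates reproduce the ratio curve
within Monte-Carlo error.

The default `k'_on = 2 µm⁻¹s⁻¹` (with `k_off = 0.1 s⁻¹`, so
`ρ₀ = 20 µm⁻¹`) puts a few tens of motors on a 2.5 µm filament,
a realistic lattice occupancy for processive kinesins.

## Study conditions and problem sizes

The desk-scale geometry is a 10 × 10 × 0.4 µm box — one sixteenth of the
full 40 × 40 × 0.4 µm area, with counts scaled to preserve
filaments-per-area and motors-per-filament; the full geometry is
available behind `paper_config()`. The two reference cells are:

* **nematic**: `v_g = v_m = 30` nm/s, 200 nucleators, 460 motors
  (2.3 per filament, as in the reference dense network). 200 filaments of
  mean length 2.5 µm put the cell at a ~10% steric volume fraction, the
  bottom of the density range the full-scale classified phase spaces
  cover; at lower densities steric crowding no longer suppresses
  polarity sorting and the small system drifts toward the transition
  zone;
* **aster**: `v_g = 5` nm/s (= `v_m/6`), 40 nucleators, 640 motors
  (16 per filament, the upper end of the scanned motor range).

Runs last six mean filament lifetimes (the lifetime is the mean growth
phase `1/k_cat` plus the shrinkage time), long enough for the crosslink
populations to plateau, with 100 frames per run. Phase scans for the
collapse analysis use `v_g/v_m ∈ {1/3, 1/2, 1}` (plus ×3-scaled speeds),
filament numbers 40 and 80, and motor numbers 160–640; the collapse
score bins points by control coordinates rounded to two significant
figures and requires graded states to agree within `|ΔP| ≤ 0.1`.

Parameters not fixed by printed values (unbinding forces, stiffnesses,
nucleation rate, viscosity) are package defaults chosen once from
standard kinesin/microtubule ranges: `v_s = 500` nm/s, `f_g = 1.7` pN,
`L_0 = 0.1` µm, `k_on = 5 s⁻¹`, `k_off = 0.1 s⁻¹`, `k_end = 0.05 s⁻¹`,
`f_stall = 5` pN, `f_unbind = 2.5` pN, `κ_m = 100` pN/µm,
`κ_s = 50` pN/µm, `k_nuc = 1 s⁻¹`, `η = 0.05` pN s/µm². The emergent
classification rests on the printed speeds, geometry, mean length and
count ratios rather than on these defaults.

## What the synthetic generators do and do not show

The fixture module builds ideal asters (coincident plus ends, V-linked),
ideal mixed-polarity bundles (aligned filaments, side-side links with an
exactly enumerable expected P under random pairing), random crosslink
geometries, and synthetic census series with prescribed counts. They
share the simulator's frame container, so census, classifier and metric
code cannot tell fixture from simulation — which is exactly what makes
them valid unit-test inputs and exactly why passing on them says nothing
about the physics engine itself; the engine is validated separately
against its micro-oracles (stall, growth-force factor, dwell statistics,
length-at-catastrophe, diffusion against the drag model, Bernoulli
attachment statistics, anti-parallel sliding) and by the emergent
classification of the two reference cells.

Known limitations: no hydrodynamic interactions, no depletion/crowding
attraction, no rescue events, no minus-end dynamics, no motor-motor
exclusion (the single-filament theory is the continuous, non-interacting
limit), and a minus-end-directed motor mode that is provided as a
directionality switch but not validated. Steric interactions act between
vertices at 0.5 µm resolution, so very thin filament crossings can pass
between vertices; the densities simulated here keep this artifact rare.
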