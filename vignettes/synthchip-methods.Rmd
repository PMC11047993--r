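---
title: "Models and numerics behind synthchip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerics behind synthchip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(synthchip)
```

`synthchip` is a desk-scale simulator of a high-throughput electrochemical
DNA-synthesis chip.  The platform it models writes arbitrary oligonucleotide
sets on a dense microelectrode array: a DRAM-like addressing fabric applies a
deprotection voltage to any chosen subset of ten million electrode sites, and
a static-droplet-array (SDA) microfluidic layer caps each site with an
isolated aqueous droplet so that the protons generated during electrochemical
DMT removal cannot diffuse to neighbouring sites.  This vignette records the
models, their assumptions, the parameters that matter, and the numerical
choices — the things a reviewer or a future maintainer would want to know
before trusting or extending the code.

## 1. The addressing fabric

The electrode array is `n_rows x n_cols` = 3163 x 3163 (just over 10^7 units
at a 3.16 um pitch, i.e. 10^7 per cm^2).  One 12-bit row decoder drives the
gates of a whole row; 128 column sub-decoders, each owning 25 consecutive
columns and sharing one 5-bit offset bus, drive the sources.  The external
interface is therefore 12 + 128 + 5 = 145 pins, and any single drive state
("instance") selects at most one unit per enabled block — up to 128 units in
one row, all at the same within-block offset.

Conventions and consequences:

* Everything is 0-based.  The worked example decodes row code
  `0b001010011010` to row 666 and block 44 with offset `0b01011` (11) to
  column 44 x 25 + 11 = 1111; the arithmetic only works with 0-based block
  indices, which fixes the convention package-wide.
* The column decode space is 128 x 25 = 3200 > 3163.  The 37 surplus outputs
  are treated as unconnected: decoding silently drops them
  (`decode_columns()`), while `encode_instance()` refuses to emit them.
* `schedule_mask()` turns an arbitrary activation mask into the ordered
  instance list the refresh logic would execute: lexicographic (row, offset)
  sweep, one instance per non-empty pair, enabling exactly the blocks whose
  unit is active.  This is an exact cover — the tests verify it against a
  per-unit enumeration oracle — and its length is bounded below by
  `ceiling(n_active / 128)` (19,532 groups for the quarter-array load of a
  synthesis sub-step).
* A full-array refresh pass is `n_rows x cols_per_block` = 79,075 instances;
  at the 80 ns dwell this is 6.326 ms, reported to two significant figures
  as 6.3 ms to match the design arithmetic, with the exact value exposed.

## 2. Per-unit storage-capacitor dynamics

Each unit is an access transistor plus a 1 pF storage capacitor; the exposed
electrode sits on the capacitor node.  We abstract the transistor as an ideal
switch in series with an on-resistance `R_on`, giving a single-pole RC model.
`R_on` is not guessed: it is calibrated so that one 80 ns pulse from the 5 V
supply lands exactly on the 3 V set-point,

\[ R_{on} = \frac{t_{on}}{C\,\ln\!\frac{V_{dd}}{V_{dd}-V_{target}}}
   \approx 87.3\ \mathrm{k\Omega}\ (\tau \approx 87.3\ \mathrm{ns}), \]

and the same pole then predicts ~1.02 V after a 20 ns pulse — both printed
operating points from one parameter, which is the main evidence the
single-pole abstraction is adequate.  Programmable set-points therefore span
~0–3 V as the dwell sweeps 0–80 ns.

Off-state leakage is not specified for the real device; we model it as a
resistance `R_off` across the capacitor, with a default of 2.5e11 ohm chosen
so that one full 6.326 ms refresh pass lets 3 V droop by ~2.5 % — comfortably
inside the 5 % ripple envelope the design budgets for — and we expose it in
the configuration since any real value would have to be measured.

Refresh is modelled as a voltage-gated top-up: the fabric charges a unit
until its set-point is reached and then moves on.  A literal fixed-duration
recharge every pass would ratchet the capacitor toward the 5 V rail (each
80 ns pulse overshoots when starting above 0 V), contradicting the stable
plateau the design describes; gating at the set-point reproduces it.  In the
steady state the peak equals the set-point and the trough is its exponential
decay over the remainder of the refresh period.  Closed forms are
cross-checked in the tests against brute-force Euler integration to <0.1 %.

Limitations: no electrochemical load current (the faradaic current drawn
during deprotection is not quantified in the source design), no line
parasitics, no charge injection.  Droop under load is therefore unknowable
here; the reported ripple is the unloaded bound.

## 3. Two-phase droplet microfluidics

### Geometry

The SDA layer tiles one capillary-valve unit per electrode on the same
3.16 um pitch, with adjacent rows mirrored about the x-axis.  Only two of
its dimensions are design constants: the pitch and the 0.2 um capillary
valve width.  Everything else (chamber, neck, channel widths) is
configuration-exposed, with defaults chosen — as the one calibration this
module performs — so that the simulated steady droplet areas land in the
regime of the reference design (droplets of ~1.7–2.0 um^2 exceeding half the
chamber area).  The default tile is:

* a main channel (0.7 um) that runs below the chamber and dead-ends just
  past the chamber mouth;
* the reaction chamber (2.0 x 1.2 um) as a pocket above it, reached through
  a short flush neck (0.45 x 0.15 um);
* the capillary valve: a 0.2 um slit from the chamber's far side into the
  end-of-tile riser, venting displaced oil;
* the bypass loop: a 0.35 um down-shaft just past the mouth, a bottom run
  under the chamber, and the riser (two 90-degree bends) rejoining the front
  of the next unit.

The sequencing is purely capillary.  For the non-wetting aqueous phase
(contact angle 135 degrees through water) each route has an entry pressure
set by its width and corners, and we measured these in the solver itself
with single-feature probe domains: a straight 0.45 um neck yields before the
cornered 0.35 um shaft, which yields long before the 0.2 um valve.  An
advancing aqueous front therefore fills the chamber first (oil escaping
through the valve), then diverts under it, and never enters the valve.  When
the plug tail recedes it sweeps across the flush chamber mouth and shears
the connecting thread at the neck — the narrowest section of the receding
path — leaving one droplet per chamber.  The short neck matters: a long
neck lets the pressurised plug siphon the chamber back out before the
thread snaps.

### Fluids and flow model

The continuous phase is the fluorocarbon oil FC-3283 (mu = 1.365e-3 Pa s,
rho = 1820 kg/m^3); the dispersed phase is water at standard properties.
The interfacial tension is not printed anywhere for this pair in the source
design; we default to 0.040 N/m, typical of fluorocarbon/water, and expose
it.  Injection is a constant 3 mm/s plug of oil behind a finite aqueous
plug that starts in the injection channel (the SDA itself and the
channel front start oil-filled).

The solver is a 2D incompressible two-phase code on a uniform MAC grid:
Chorin projection with a variable-coefficient pressure Poisson equation
(warm-started red-black SOR), first-order upwind momentum advection,
explicit viscous terms, continuum-surface-force surface tension with
curvature from corner-averaged interface normals, and conservative
level-set interface capture (limited-upwind transport plus
compression–diffusion reinitialisation, interface half-thickness of one
cell).  Walls are no-slip; the static contact angle enters through ghost
values of the phase field inside solid cells.  Time steps respect the
advective, viscous and capillary stability limits.

### The one deliberate departure from raw physical parameters

At the physical operating point the capillary number is Ca ~ 1.0e-4 and the
Reynolds number Re ~ 4e-3: the flow is quasi-static, and an explicit
capillary time-step limit would demand ~10^6–10^7 steps per transit —
intractable for any explicit solver.  Interface shapes and pinch-off volumes
in this regime are insensitive to Ca and Re provided both stay small (Ca
well below ~0.05, Re at or below order 1), so the solver integrates the
nondimensional equations at numerical values `re_num = 1` and
`ca_num = 0.003` by default, preserving the viscosity ratio, density ratio,
contact angle, geometry and injection-rate boundary condition exactly.  Both
knobs are exposed; setting them to 0 forces the raw physical values.  The
sensitivity of the steady areas across ca_num 0.0025–0.005 is a few percent
in the uniform columns, and the choice of 0.003 sits where the two
finite-Ca artefacts (vent-limited underfilling at larger Ca, post-snap
drainage at smaller Ca) balance.

### What the simulation does and does not show

The default 4x4 array at the default grid (cell = pitch/32, ~0.1 um)
reproduces, in roughly ten minutes on one core (hardware-dependent): sequential chamber filling,
valve blocking, tail pinch-off at the neck, one confined droplet per
chamber exceeding half the chamber area, clear bypass channels at steady
state, a slightly larger first (inlet-nearest) column — the upstream column
enjoys the longest pressurised filling window — and uniform later columns.
It is a 2D model with a heuristic contact-angle closure on a ~4-cell-wide
diffuse interface; it does not resolve 3D menisci, channel depth, wetting
films, electrowetting, or the proton chemistry inside the droplets.
Quantitative droplet areas therefore carry the stated ±15 % tolerance, and
the analytic validations (Young–Laplace pressure jump within 10 %,
Poiseuille profile within 2 %, kinematic blob advection with <1 % area
drift, grid-refinement stability within 10 % at fixed physical interface
thickness) bound the numerical error, not the modelling error.

## 4. Synthesis orchestration

`cycle_plan()` splits the unfinished sites of an oligo job set into four
disjoint activation masks (A, C, G, T — fixed sub-step order; the real
instrument's order is a reagent-plumbing choice with no effect on the
simulation).  On uniform-random targets each mask holds about a quarter of
the sites, the load the addressing analysis assumes.  `run_synthesis()`
iterates cycles until every site reaches its target, scheduling each
non-empty mask through `schedule_mask()` and holding it for an
electrochemical deprotection time `t_hold_s` (default 60 s — typical of
electrochemical DMT removal; it is not specified in the source design),
during which the addressing fabric refreshes all held voltages once per
6.3 ms pass.  The termination bookkeeping (synthesised product equals the
target at every site) is asserted, not assumed.

`confinement_audit()` states the platform's headline claim at the level
where the model makes it literally true: in confined mode a site deprotects
iff it is activated and its chamber holds a confined droplet, and no
neighbour is ever at risk; the unconfined mode is a qualitative
counterfactual that flags 4-neighbours of active sites, not a proton
transport model (none is quantified in the source design).

## 5. Reproducibility plumbing

All stochastic fixtures (`gen_random_mask()`, `gen_random_oligos()`) are
pure functions of their seed and restore the caller's RNG state.  The
configuration object round-trips losslessly through YAML and rejects
unknown keys; `write_manifest()` records the config hash, seed and package
version next to simulation outputs.  Masks travel as 0-based `row,col` CSV,
schedules as JSONL (one instance per line), waveforms and censuses as CSV,
and oligo sets as FASTA via Biostrings, with `site=row,col` header
annotations for explicit placement.

## 6. Problem sizes used in the shipped checks

The test-suite and the acceptance script use: the full-size addressing
fabric (its data structures are O(active sites), so 10^7-unit geometries are
cheap as long as masks stay sparse or are handled per-instance); small
10x10 fabrics wherever a brute-force enumeration oracle is the reference;
the default 4x4 SDA array at cell = pitch/32 for the droplet acceptance run;
a 1x1 unit for conservation and grid-refinement checks; and a 40x40-cell box
or short channels for the analytic flow validations.
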