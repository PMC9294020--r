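---
title: "Hydraulics of the stented ureter: model, assumptions and design choices"
author: "stentflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydraulics of the stented ureter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stentflow)
```

## The physical model

`stentflow` models steady urinary drainage through a ureter carrying a
double-J stent as a network of laminar hydraulic conductances. The flow in
the stented ureter sits deep in the laminar regime — with millimetre
conduits, millimetre-per-second velocities and water-like fluid properties
(density 997.044 kg/m³, viscosity 0.001 Pa·s) the Reynolds numbers are in
the tens, far below the 2300 transition — so each flow path admits a
closed-form fully developed solution, and mass flow responds linearly to
the pressure drop. This justifies the Ohmic analogy: an element carries
`ṁ = G·ΔP`, and the whole device is a linear resistor network between two
pressure reservoirs, the kidney pelvis (97.8 Pa gauge) and the bladder
(0 Pa).

Four closures supply the conductances:

* **Stent lumen** — Hagen–Poiseuille pipe flow,
  `G = ρπd⁴/(128μL)`.
* **Extraluminal annulus** — concentric-annulus Poiseuille flow between the
  stent outer wall and the ureter lumen. Where the lumen tapers, the
  element is composed as a series (harmonic) chain of at least eight
  locally concentric sub-segments; the proximal taper is what drives the
  transfer of flow from the annulus into the stent, so it must be resolved.
* **Side hole** — a short Poiseuille tube across the 0.5 mm wall in series
  with a Sampson orifice loss, `R_vol = 128μt/(πd⁴) + 3μ/(d/2)³`. The
  reference analysis resolves holes with a 3D mesh and states no lumped
  loss model, so this closure is this package's own choice; a
  short-tube-only variant is selectable (`model = "tube_only"`) for
  sensitivity checks. At the hole diameter and wall thickness used, tube
  and orifice resistances are comparable, so dropping the orifice term
  roughly doubles the hole conductance.
* **Porous wall** — Darcy flow integrated radially across the cylindrical
  shell, `G = 2πραΔz/(μ ln(r_o/r_i))`, linear in the permeability α and
  exactly zero for the unporous wall. The inertial loss coefficient of the
  general porous-medium momentum sink is taken as zero (creeping flow), so
  the wall element is linear like everything else. Axial conduction along
  the wall is neglected: the wall cross-section is small compared to the
  lumen and wall flow is essentially radial exchange.

## Discretisation

The 34 shaft side holes define the axial stations of the network (the
8 coil holes — four per coil — sit in the reservoirs and are lumped into
the end attachments). Between consecutive stations lies one *reporting
segment*, matching the surfaces midway between hole pairs on which
compartmental flows are reported; each segment owns an (intraluminal,
extraluminal) midpoint node pair where the distributed wall exchange of
that segment is lumped. Stent end openings are short pipes of one segment
length with the coil holes in parallel. A hole-less stent keeps the same
35 reporting segments so profiles stay comparable.

A complete occlusion removes the extraluminal and wall edges whose axial
extent intersects it — the obstruction presses the ureter wall onto the
stent — and leaves the lumen intact, which is precisely why the
intraluminal flow equals the total flow at the occluded segment. Any
extraluminal midpoint node orphaned by the removal is dropped from the
system.

### Per-segment decomposition

At each reporting surface the total axial flow is split as
`m_total = m_intra + m_extra + m_wall`. Because the network neglects axial
transport within the wall material, `m_wall` is identically zero and the
identity reduces to the intraluminal/extraluminal split; the *radial* wall
exchange lumped in each segment is reported separately
(`wall_exchange`, positive into the lumen). Sign conventions: axial flows
are positive towards the bladder; hole and wall flows are positive into
the stent lumen.

## Parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| ureter length | 240 | mm | typical adult/porcine scale; not printed in the reference geometry, only the relative axial structure matters |
| lumen profile | 6.0→3.0 (proximal third), 2.5, 2.4, 2.9 at VUJ | mm | reference anatomy; proximal/middle/distal regions are length thirds |
| stent ID / OD | 1.5 / 2.5 | mm | reference stent |
| side holes | 42 × 0.8 (4 per coil) | mm | reference stent |
| minimum radial clearance δ_min | 0.1 | mm | the printed mid/distal lumen (2.5/2.4 mm) does not exceed the stent OD (2.5 mm), which would seal the annulus, yet extraluminal flow is reported there; the effective lumen is `max(printed, OD + 2δ_min)`, making the assumption explicit and configurable |
| occlusion | 6 mm, centred between holes 21 and 22 | mm | reference obstruction |
| boundary pressures | 97.8 / 0 | Pa | physiological pelvis–bladder drop |
| permeability α | case-dependent, 0 or 10⁻¹⁸–10⁻¹⁰ | m² | range of hydrogel-like device materials |
| activity threshold | 0.01 | — | a side hole is *active* if it exchanges ≥1% of the total flow |

"Average total mass flow" is the arithmetic mean of `m_total` over **all**
35 reporting surfaces; the total is constant along the ureter up to the
solver residual, so the mean is a stabilised readout rather than a choice
of subset.

## Numerical choices

* The free-node conductance system is symmetric positive definite and
  solved by sparse Cholesky factorisation with two steps of iterative
  refinement.
* Edge flows are evaluated in a *mixed pressure representation*: alongside
  the pressures `p`, the complementary system for the pressure deficit
  `q = P_ref − p` is solved, and each edge drop uses whichever
  representation is locally small. Near the inlet the drops are ~10⁻⁴ of
  the absolute pressure and the naive `p_a − p_b` loses ten digits to
  cancellation; the mixed form keeps the maximum relative Kirchhoff
  residual near 10⁻¹⁴ instead of 10⁻¹².
* An independent dense solver (explicit edge stamping, LAPACK column-pivot
  QR) acts as an oracle; the suite checks normwise agreement to 10⁻¹⁰ on
  the nine reference cases and on randomised 50-node networks.
* Degenerate inputs: a closed annulus anywhere raises an error naming the
  axial position; disconnected or singular systems raise errors naming the
  offending nodes; a network whose every pressure is prescribed is solved
  trivially; zero pressure drop yields identically zero flows.
* Permeability inversion runs in log₁₀(α) space with a bracketing root
  find (the map spans eight decades of α), to a relative flow tolerance of
  10⁻⁶; observations at or below the bracket-floor flow return the floor
  with an `at_floor` flag, observations above the achievable interval are
  errors that state the interval.

## The scenario generator

`random_scenario()` draws property-testing scenarios around the reference
conditions: geometric dimensions perturbed uniformly within ±20%,
permeability either zero (probability 0.15) or log-uniform over
10⁻¹⁸–10⁻¹⁰ m², side holes present with probability 0.8, occlusion with
probability 0.25 (always strictly between side holes 21 and 22), all under
the fixed 97.8 Pa drive. It emulates anatomical variability of a straight,
axisymmetric, rigid ureter only. It does **not** emulate ureteral
curvature, peristalsis, wall compliance, micturition-driven transients,
non-Newtonian urine, or anisotropic/heterogeneous wall porosity — so tests
passing over these draws demonstrate robustness of the network solution
and of the qualitative flow-partition phenomenology, not fidelity to any
individual patient.

## Design decisions on genuinely open points

* **Hole indexing.** Holes are numbered 1–42 from kidney to bladder; the
  34 shaft holes are spaced uniformly along the ureter, which places holes
  21 and 22 astride the mid-ureter and holes 35–36 near the VUJ,
  reproducing the reference numbering without printed coordinates.
* **Occlusion semantics.** Only the extraluminal and wall paths are
  severed; the lumen is untouched. The alternative — also penalising the
  lumen — contradicts the reported bypass behaviour.
* **End attachments.** Coil geometry is out of scope; the coils' four
  holes act in parallel with the end opening, making the ends
  non-limiting resistances.
* **Velocity summaries** use analytic laminar profiles (parabolic pipe,
  closed-form annulus), a closure-level stand-in for the 3D velocity
  field: mean values follow exactly from `u = ṁ/(ρA)`, peak values are
  profile factors (2 for the pipe; the annulus factor follows from the
  location `r*² = (R_o²−R_i²)/(2 ln(R_o/R_i))` of the profile maximum).

## Known limitations

* **The annular clearance dominates the mid-ureter.** With δ_min = 0.1 mm
  the mid-ureter annulus conductance is ~10⁻⁷ kg·s⁻¹·Pa⁻¹ per segment,
  two orders below the lumen, so the extraluminal compartment carries well
  under 1% of the total flow there. Consequences: the occlusion bypass at
  side hole 21 is a sharp *local* maximum (orders of magnitude above its
  unoccluded value) but smaller than the taper-entry hole fluxes, and the
  porous-wall gain in total drainage is a fraction of a percent rather
  than several percent. Both scale directly with the assumed clearance,
  which is the single most influential unprinted dimension of the
  reference geometry.
* **The permeability→flow map is flat.** Because the wall path acts in
  parallel with 34 side holes, average flow changes by well under a
  percent per decade of permeability below 10⁻¹⁰ m². Noise-free inversion
  round-trips to better than 1%, but percent-level observation noise is
  amplified into decade-level permeability error —
  `permeability_recovery()` measures exactly this amplification rather
  than hiding it.
* **The annulus→pipe limit is logarithmic.** The concentric-annulus
  conductance approaches the pipe value only like `1/ln(R_o/R_i)` as the
  core vanishes: at `R_i/R_o = 10⁻³` the ratio is still 0.855. The tests
  therefore verify monotone convergence and the deep limit rather than
  fast convergence.
* Reported wall flow through a reporting surface (`m_wall`) is exactly
  zero by construction; the model cannot distinguish axial transport
  inside the wall material from zero.

## Problem sizes

The default network has 140 nodes and 174–209 edges depending on the case;
a solve takes tens of milliseconds. The test suite solves the nine
reference cases once (cached), sweeps five permeabilities over the default
and 25 randomised geometries, cross-checks the dense oracle on 100
randomised 50-node networks, and runs a 20-draw noisy recovery benchmark;
the acceptance script repeats the headline computations from scratch.
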