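---
title: "Model and methods: simulating contractile actomyosin patches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: simulating contractile actomyosin patches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`actomyosim` simulates 2D patches of actomyosin cortex as networks of
semiflexible actin filaments connected by three species of stochastic,
two-handed connectors — passive crosslinkers, Arp2/3 branch links and
two-headed myosin motors — and reads out contractility as the decay constant
`B` of an exponential fit `R(t) = A exp(-B t)` to the network radius during a
contraction phase. The package's scientific object is the *paired
perturbation sweep*: for a population of random network architectures, how
does `B` respond to doubling myosin, doubling F-actin, increasing Arp2/3, or
reducing total polymer mass? This vignette documents the model, its
parameters, the numerical choices and the limits of what the simulations
show.

## Filaments

A filament is a polyline of vertices 0.2 µm apart (the rest segment length
`l`); vertex 1 is the minus end, the last vertex the growing plus (barbed)
end. Two energy terms act along the backbone:

* **Bending** — the discrete worm-like chain energy
  `E = (κ / 2l) Σ θ_i²`, with `θ_i` the angle between consecutive segments
  and `κ = 0.075 pN µm²` the bending modulus of F-actin (persistence length
  `κ/kT ≈ 18 µm`). Forces are the analytic negative gradient; the test suite
  checks them against central-difference gradients to 1e-6.
* **Extension** — inextensibility is enforced by stiff penalty springs of
  2000 pN/µm per segment rather than by constrained dynamics. This keeps the
  integrator explicit and testable: a segment under a typical peak motor-scale
  load of ~6 pN stretches 1.5%, within the ±2% inextensibility tolerance the
  package targets. Thermal fluctuations add `sqrt(kT/k) ≈ 0.7%` RMS jitter
  per segment, so instantaneous extremes over ~10⁵ steps and ~10³ segments
  reach several percent without any mechanical cause; the tolerance is
  therefore enforced in distribution — at the reference condition ~96% of
  segments sit within ±2% at any sampled state (median strain 0.6%), with
  the worst single excursion of a whole run staying below ~7% — rather than
  on the single worst thermal excursion.

Vertices follow the overdamped Langevin equation integrated by explicit
Euler–Maruyama:

```
x(t + dt) = x(t) + (dt/γ) F(t) + sqrt(2 kT dt / γ) ξ,   ξ ~ N(0, I₂)
```

with per-vertex drag `γ = drag_per_length × l`. Defaults: `kT = 0.0042
pN µm` (room temperature), `drag_per_length = 7.5 pN s/µm²` (an effective
cytoplasm viscosity of order 1 Pa s), `dt = 3e-5 s`. The package refuses to
run when `dt ≥ γ / (10 k_max)`, `k_max` being the largest total spring
stiffness that can act on one vertex (penalty springs, connector spring,
branch torsion equivalent, confinement wall, tethers); the error names the
dominant stiffness. With the defaults the bound is `3.5e-5 s`, so the 12 s
two-phase protocol takes 4×10⁵ steps. A 1 ms step — typical for engines with
implicit or constrained integrators — is two orders of magnitude beyond this
explicit-scheme bound, which is why the default is what it is.

All engine randomness (thermal noise, binding, unbinding, branch sides)
flows through one xoshiro256++ stream seeded by a single integer, so
trajectories are bit-reproducible; R-level placement (nucleators, Arp2/3
anchors, injected binders) uses R's RNG under locally scoped seeds derived
from the architecture's `architecture_seed` and `dynamics_seed`.

## Connectors

All three species are Hookean springs (100 pN/µm) between two "hands" bound
to fiber abscissae. A free hand binds any segment whose closest point lies
within its capture range with probability `1 − exp(−k_on Δt)` per candidate,
candidates evaluated in randomized order; a bound hand detaches with
probability `1 − exp(−k_off Δt)`, independent of force (a slip-bond option,
`kramers_f`, multiplies the rate by `exp(F/f_char)` but is off by default).
A connector never holds both hands on the same fiber.

* **Crosslinkers** (k_on 10/s, k_off 0.1/s, range 0.1 µm, rest 0.05 µm) are
  passive; their attachment points never move along the fiber.
* **Arp2/3** links bind once during assembly, nucleate a daughter filament
  at exactly 72° to the mother tangent (side chosen at random), and
  thereafter act as a permanent translational plus rotational link: a
  torsional spring (0.5 pN µm/rad) holds the daughter's base direction at
  72° to the local mother tangent.
* **Motors** model bipolar myosin-II minifilaments: capture range 0.25 µm
  and rest length 0.2 µm (the physical reach of a ~300 nm minifilament),
  k_off 2/s, and hands that walk toward plus ends with the linear
  force–velocity law `v = v₀ max(0, 1 − load/f_s)`, `v₀ = 1 µm/s`,
  `f_s = 6 pN`, where `load` is the component of the link force opposing
  plus-end motion. A hand reaching the plus end detaches rather than
  dwelling, which avoids artefactual end-clustering; contraction in this
  model therefore relies on filament buckling rather than end-dwelling
  asymmetry, consistent with the observation that stiffening the filaments
  strongly reduces contraction. The 2/s unbinding rate gives an engagement
  of ~0.5 s: motors stroke intermittently instead of acting as long-lived
  crosslinks. This matters for the control experiments — with engagements
  longer than the 2 s assay, motor complexes alone crosslink the network
  and contract it, erasing the defining role of the passive crosslinkers.

The motor reach deserves a note, because it shapes the sweep results: with
point-like motors most complexes sit in mesh voids and never engage, and
doubling F-actin then *increases* contractility simply by recruiting idle
motors. With minifilament-scale reach, motor engagement is near saturation
at reference density, and doubling F-actin instead mostly adds drag and
elastic constraint — the regime in which added actin most often slows
contraction while added myosin reliably speeds it.

## Two-phase protocol

**Phase 1 — assembly (10 s).** `n_nucleators` two-vertex seeds (0.1 µm) are
placed uniformly in a disc (radius 6 µm at full scale) with isotropic
orientations. Plus ends grow at 0.5 µm/s, each increment debited from a
finite polymer pool; when the pool empties, growth freezes. Mean filament
length is therefore `pool / filament count`, which is the lever used by the
polymer-mass perturbations. Free Arp2/3 entities bind nearby filaments and
nucleate daughters (at most once each). A soft harmonic wall (100 pN/µm)
confines the growing network to the disc. Growth speed is deliberately high
enough that the pool, not the 10 s, limits filament length at reference
parameters.

**Phase 2 — contraction (2 s).** Nucleation, branching and growth are
frozen; motors and crosslinkers are injected uniformly over the network's
bounding disc, unbound; the wall is removed so the patch is free to
contract, and the system is integrated with stochastic binder dynamics. The
network radius is sampled every 0.04 s (51 points); sampling is pure
observation. The strict phase-2 injection follows the protocol reading that
motors and crosslinkers appear only after assembly; an
`assembly_connectors` argument to `assemble_network()` lets them act during
phase 1 instead for robustness checks.

**Radius estimator.** `network_radius()` returns `sqrt(2 × mean d²)` over
all vertices (`d` = distance to the vertex centroid), calibrated so that a
uniformly covered disc of radius R reads R. It is translation- and
rotation-invariant and insensitive to the discretization because vertices
are equispaced. Bounding-radius and convex-hull alternatives are available
behind the `method` argument but the RMS form is the package default and the
one used by all reported numbers.

**Contraction rate.** `fit_contraction_rate()` fits `A exp(-B t)` by
nonlinear least squares (Levenberg–Marquardt), initialized from the
log-linear regression; `B` is unconstrained in sign, and non-convergence
falls back to the log-linear estimate with `converged = FALSE`. On noiseless
exponentials the fit recovers `B` to 1e-6; at 1% amplitude noise its bias is
below 1%.

**Percolation readout.** `connectivity_report()` builds the graph whose
nodes are fibers and whose edges are doubly bound connectors of any species
and reports the polymer-length fraction in the largest component;
`uniform_contraction` means ≥ 90% — the operational definition of a network
that contracts as one piece. It is evaluated on the end-of-run state, after
binder occupancy has equilibrated.

## Random architectures and the perturbation sweep

`sample_architecture()` draws the four entity counts and the polymer pool
log-uniformly from ranges spanning a factor of 8 (counts) and 4 (pool)
around the reference architecture (160 nucleators, 160 Arp2/3, 960 motors,
1920 crosslinkers, 480 µm polymer in the 6 µm disc), producing networks from
sparse, fragmented ones to dense, strongly percolated ones. Polymer density
(µm of polymer per µm² of domain) is the density metric used for
stratification. Every architecture is a pure function of
`(master_seed, index)`.

Perturbation presets fix the paired comparisons: `myosin_x2` (motors × 2),
`actin_x2` (pool × 2 at fixed nucleator count — longer filaments; doubling
nucleators at fixed pool is available through a custom multiplier),
`arp_x1.33` (Arp2/3 × 4/3, rounded half-up), `polymer_x0.7` (pool × 0.7 —
shorter filaments), plus combinations. Reference and perturbed runs share
both seeds (matched-pair design; `run_pair(matched_seeds = FALSE)` gives the
unmatched variant), and an identity perturbation replays bit-identically —
the package's strongest reproducibility check.

`run_sweep()` runs each architecture's reference once and reuses it across
perturbations, writes one CSV of scatter data per perturbation, and resumes
completed rows on re-run. `summarize_sweep()` reports, per perturbation, the
fraction of architectures whose `B` increased, the median relative change,
the same stratified by density quartile, and the number of percolation
failures.

## Problem sizes and what the tests show

The packaged tests and examples run at reduced scale so that the whole suite
stays desk-sized: calibration experiments (diffusion, equipartition,
relaxation) use one or a few free fibers; the necessity and rigidity
controls use a quarter-area reference (3 µm domain, 40 seeded filaments);
the paired sweep uses 16 architectures at the 2.5 µm domain scale with
counts scaled by area so the density spectrum is preserved. The full-scale
128-architecture sweep at 6 µm is exactly the same code path
(`run_sweep(128, specs, sampling_ranges(), seed)`) and is meant as a batch
job, not an interactive one.

What the generator emulates is a cortex patch that is isotropic and
homogeneous at the domain scale, with composition varied over an order of
magnitude; what it does not emulate are oriented or bundled architectures,
filament turnover during contraction (growth is frozen in phase 2),
three-dimensionality, capping dynamics (capping is represented only through
its consequences — filament number and polymer mass), or hydrodynamic
coupling (isotropic local drag only). Passing tests therefore support
conclusions about the *relative* response of contractility to composition
changes in disordered 2D networks, not absolute rates in tissue.

## Known limitations and numerical notes

* Binding/unbinding events are evaluated every 10 integration steps (0.3 ms)
  with the correspondingly longer effective time step — statistically
  equivalent for rates ≤ 10/s, and it keeps neighbourhood searches off the
  inner loop. Cell-list searches use a 0.45 µm grid rebuilt at the event
  cadence.
* Unbound connectors do not diffuse: they wait at their anchor (injection
  position, or the point where they last let go). Diffusion of micron-scale
  complexes over 2 s would add ~0.1–0.3 µm of positional spread; at the
  occupancy levels of the reference this is a second-order effect.
* Per-vertex drag is isotropic; slender-body anisotropy (factor ~2 between
  parallel and perpendicular drag) shifts absolute rates, not the paired
  comparisons.
* The first segment of a daughter filament starts at 0.1 µm and interior
  segments are created at 0.2 µm by the splitting rule, so segment rest
  lengths live in [0.1, 0.3) µm; the torsional branch spring acts on the
  daughter's base segment whatever its length.
* Motor-free (or crosslinker-free) networks fit to |B| of a few 1e-3/s, not
  exactly zero: binder springs binding at finite separation and relaxing to
  rest length produce a small, reproducible compaction. Controls are
  therefore judged against an equivalence bound (within sampling error of
  zero, or below 5% of the full system's rate), which is the resolution
  floor of the readout.
* With both crosslinkers and Arp2/3 removed, dense motor populations still
  compact the vertex cloud at ~0.01/s by clustering filaments into local
  asters; the end state is fragmented (`uniform_contraction = FALSE`), so
  this is clumping, not network contraction — the radius scalar alone cannot
  distinguish the two, which is why the sweep carries the connectivity
  flag.
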