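---
title: "Modelling flow-driven fibrinolysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling flow-driven fibrinolysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fibrolyse)
```

## The problem

An occlusive fibrin clot in a tube is perfused by a pressure-driven flow
carrying a pro-fibrinolytic agent (clinically, tissue plasminogen
activator and the plasminogen/plasmin system it recruits).  The agent
binds avidly to fibrin, so it does not percolate through the clot: it
accumulates at the upstream face, dissolves the fibers there, and the
lysis front creeps towards the outlet, accelerating as it goes.  Flow is
barely restored until most of the clot is gone, and then recanalizes
abruptly.  `fibrolyse` implements two coupled descriptions of this
process:

1. an **analytical one-dimensional front model** that collapses the
   entire lytic cascade into a single effective species (the anti-fibrin
   agent) reacting with fibrin at second order, and
2. a **mesoscopic lattice-Boltzmann simulator** in which the clot is a
   porous medium whose voxel-level resistance evolves with the local
   fibrin concentration, coupled to explicit transport of the agent and
   the same second-order reaction.

## The analytical model

Two species: fibrin `F(x, t)` and anti-fibrin agent `Fbar(x, t)`.  The
agent is advected at constant permeation speed `u_f`, does not diffuse,
and is blocked wherever fibrin is intact (`F >= F*`); fibrin is consumed
at rate `k1 F Fbar`.  The clot of length `L` is sliced into `n = L /
Delta` layers.  The agent accumulates at the first intact slice at the
linear rate `Fbar0 u_f / Delta`, so integrating the reaction gives the
time to lyse the first slice,

    t0 = sqrt( 2 Delta log(F0 / F*) / (k1 u_f Fbar0) ),

and, because the accumulated agent is carried to the next slice (one
slice takes `Delta / u_f` to traverse) where it keeps growing, the
recursion

    t_k = Delta / u_f + sqrt( t_{k-1}^2 + 2 Delta log(F0 / F*) / (k1 u_f Fbar0) ).

Successive gaps shrink: the front accelerates, as observed in tube
experiments.  Without the advection term the squares telescope, giving
the closed form `t_total = sqrt(2 L log(F0/F*) / (k1 u_f Fbar0))`, and
the schedule is insensitive to the slicing once `Delta << L`
(`delta_convergence()` quantifies this; the packaged tests require the
total time to move by less than 1% under halving at `Delta <= L/50`).

`fit_k1()` calibrates the single free parameter `k1` against measured
front positions by least squares on the position curve, searching on
`log k1` (the loss is empirically unimodal in one parameter; Brent
search on `[1e-3, 1e5]` is ample).  Points are unweighted.  Note the
schedule depends on `k1` and `Fbar0` only through their product, so the
fit is meaningful only with the inlet concentration fixed from the
experiment.

## The mesoscopic simulator

### Fluid: BGK lattice-Boltzmann with gray (partial-bounce-back) nodes

The flow solver is a standard BGK lattice-Boltzmann scheme (D2Q9 for the
2D runs; the kernel is stencil-driven and also accepts D3Q19).  Walls
are half-way bounce-back.  The clot is not resolved at the fiber scale:
each voxel carries a bounce-back fraction `gamma` in `[0, 1]` and the
streaming step blends transmitted and reflected populations, which
endows the voxel with an effective permeability

    gamma = 1 / (1 + 2 k / (nu dt)).

The voxel permeability itself comes from Davies' law for fibrous media,
`k = Rf^2 / (16 ns^1.5 (1 + 56 ns^3))`, with the fiber radius `Rf` and
solid fraction `ns` tied to the local fibrin concentration: lysis thins
fibers radially, so `F` is proportional to the fiber cross-section,
`Rf = Rf0 sqrt(F / F0)` and `ns` proportional to `F`.  The chain is
anchored by `calibrate_clot()`: given the initial fiber radius (140 nm)
and either the reference permeability (1e-13 m^2) or the solid
fraction, it solves Davies' law by monotone root finding and fixes the
strand-length density and the mass-to-cross-section closure.  The
closure constant is chosen so a fully lysed voxel has zero radius -
the only choice consistent with complete dissolution.

The macroscopic velocity on gray nodes is the moment sum scaled by
`(1 - gamma)`; in a pressure-driven composite channel this velocity is
continuous across the clot face and obeys Darcy's law with the mapped
permeability to within ~3% over `k` from 1e-14 to 1e-11 m^2
(`darcy_permeametry()` reproduces this, and `poiseuille_benchmark()`
verifies the open-channel parabola to ~0.02%).

Two driving modes exist: fixed-density inlet/outlet planes (the
production mode) and a uniform body force on a periodic domain (used by
the Poiseuille validation, where the analytic solution is cleanest).
The fixed-density closure imposes the equilibrium distribution at the
set density with the velocity extrapolated from the adjacent bulk node.
This deliberately diffusive closure was chosen over sharper ones
(Zou-He-type or non-equilibrium extrapolation) because those reflect
acoustic waves; combined with a high-`gamma` slab they are linearly
unstable for relaxation times just above 1/2, exactly the regime the
physical pressure drops require (the lattice pressure unit scales as
`1/dt^2`, so large gradients force a small `dt`, hence `tau` near 1/2).
The benchmark runs sit at `tau` between 0.512 and 0.525, the largest
relaxation times whose pressure unit still accommodates the driving
gradients within the 10% compressibility guard (see the limitations
section for the sensitivity this entails).

Steadiness is judged on the L2 norm of the velocity change and on the
net axial flow (a pointwise maximum criterion bottoms out at round-off
on these near-stagnant porous flows).  Because pore pressure diffuses
through a low-permeability slab extremely slowly, each re-solve is
preconditioned by re-initializing the populations on the 1D
series-resistance pressure profile implied by the current permeability
field, keeping the current momentum; re-solves then converge in a few
hundred to a few thousand steps.

### Anti-fibrin transport with front blocking

The agent is an Eulerian concentration field updated by a conservative
finite-volume scheme: first-order upwind advection plus central
diffusion (`D = 3.3e-11 m^2/s`, the diffusivity of tPA).  Blocking
implements the accumulation semantics of the 1D model: a voxel with
intact fibrin (`F >= F*`) receives every incoming flux but emits
nothing - neither advective nor diffusive.  In one dimension this
reproduces the linear accumulation law exactly (the packaged test
verifies the growth rate to 2%).  Taking the transport gate literally in
both directions would forbid that accumulation, which is why the
blocking acts on outgoing fluxes only.

One discretization subtlety matters.  The flux that *deposits* onto a
blocked voxel uses that voxel's local Darcy velocity - its permeability
times the local pressure gradient - rather than the face-averaged
lattice velocity.  The physical Brinkman boundary layer of a fibrin
clot is tens of nanometres, far below the voxel size, so the true
intake profile across a homogeneous slab is transversely flat; the
lattice flow field, however, carries a two-voxel wall-layer artifact
(a deficit at the wall voxel, an overshoot at its neighbour) that would
otherwise imprint itself on the supply, seed a dissolution-fingering
instability mid-run, and detach the simulated front from the 1D
prediction well before the genuine late-stage acceleration.  With the
Darcy intake, interior column fronts advance within one voxel of the
analytical schedule for the first two-thirds of the lysis.  Where the
clot is heterogeneous the intake is proportional to local permeability,
so preferential channelling - the physics the heterogeneous ensembles
probe - is preserved.

Reaction (`react()`) is explicit Euler on `F <- F - k1 F Fbar dt`,
clamped at zero, with a positivity guard `k1 max(Fbar) dt <= 1`; the
coupled loop sub-cycles the reaction where accumulated agent would
violate it.  The reaction continues below `F*` until full dissolution -
the threshold governs transport blocking and lysed bookkeeping only -
and the agent acts catalytically (no sink), matching the governing
equations.

### Coupling and stopping

Lysis changes permeability about four orders of magnitude more slowly
than the flow relaxes, so the flow is re-solved to quasi-steady state
every 20 reaction steps (4 s each at the benchmark scale), or sooner if
any voxel's `gamma` jumps by more than 0.5.  Halving the cadence moves
the total lysis time by less than 0.5%, so this is a resolution choice,
not a physics dial.  A run ends when the slice-average front has
traversed the clot, when the remaining mass drops below a configured
fraction, at `t_max`, or - the usual endpoint for the fast heterogeneous
ensembles - when the flow reaches the solver's low-Mach envelope
(lattice velocity 0.1): at that point the vessel is effectively
recanalized and the incompressible low-Mach description has nothing
more to say.

### Front observables

Simulation records carry two front readings.  `front_m` is the
largest contiguous depth over which every transverse slice-average is
below `F*` - the bookkeeping the simulator's own validation uses.
`front_mid_m` is the median of the per-column contiguous fronts: the
front "at the middle of the interface", which is how the tube
experiments read a non-flat interface.  The distinction matters late in
a run, when thin films of intact fibrin hug the no-slip walls (their
supply is genuinely slow) and gate the slice-average metric while the
bulk interface has long moved on; a 2D channel over-weights walls
relative to the cylindrical reality.  Comparisons against the 1D model
use `front_mid_m`.

## Synthetic clots: what the generators emulate

All test inputs are generated, seeded fields:

* **homogeneous** - uniform fibrin at the target mean;
* **type 1** - per-voxel fibrin drawn from a uniform law centred on the
  target mean; the "dispersion" percentage is the half-range (100%
  dispersion at 2 mg/ml spans 0-4 mg/ml).  The alternative reading of
  the percentage as a standard deviation is incompatible with that
  stated range, which is why the half-range convention was adopted;
* **type 2** - 25 disks of high fibrin concentration at uniformly random
  centres (overlapping and boundary-clipped), in a matrix whose
  concentration is solved so the whole-clot mean equals the target
  exactly.  The disk radius is a free parameter of the ensemble
  experiments (nothing pins down "medium sized"); the default is
  0.5 mm, and the desk-scale ensembles use 0.35 mm, scaled with the
  clot cross-section so the outer concentration stays positive.

The generators emulate compositional heterogeneity only.  Real thrombi
also vary in fiber radius, local reaction rate, and cellular content,
none of which are sampled here; passing ensemble tests therefore speaks
to the transport-permeability pathway of heterogeneity, not to
biochemical variability.

## Study conditions of the packaged experiments

The benchmark configurations (`benchmark_config()`) freeze the
conditions the reproduction scripts use.  The clot is 5 mm long
(50 voxels at `dx = 1e-4` m).  The homogeneous front-trajectory case
keeps the full 5.8 mm tube width; 3 mg/ml fibrin, threshold 0.2 mg/ml,
inlet agent 1e-5 mg/ml, `k1 = 280 (s mg/ml)^-1`, gradient 8250 Pa/m.
The ensemble cases use a 3 mm section (30 voxels, keeping
21-replicate studies affordable on one CPU; their metrics are mass- and
throughput-based and do not gate on transverse slice means), a 2 mg/ml
target mean, inlet agent 2e-5 mg/ml, `k1 = 1400 (s mg/ml)^-1`, and
8000 Pa/m.  These reaction rates are "accelerated kinetics" relative to
physiological tPA activity, a standard device to bring lysis times to
simulable scales; the analytical comparison is self-consistent because
the 1D prediction uses the same parameters and the simulation's own
measured initial permeation velocity.

Operational definitions used by the headline experiments, stated here
because the underlying quantities are not standard:

* **departure instant** (`departure_experiment()`): first sample at
  which the simulated mid-interface front leads the analytical front by
  more than two voxels - both curves are voxel-quantized, so a
  separation is resolved only beyond their combined quantization;
* **post-lysis throughput**: the throughput at the instant the
  mid-interface front completes the clot.  Flow keeps rising afterwards
  while the wall films drain, but that is aftermath, not lysis;
* **recanalization onset** (`recanalization_onset()`): first instant
  the throughput exceeds 50% of its final value (fraction
  configurable, always reported);
* **half-lysis spread** (`run_ensemble()`): half the range of the
  half-lysis times across replicates, relative to their mean.

## Numerical choices and degenerate inputs

* `tau` is guarded to `(0.5, 2]`; lattice velocities above 0.3 abort a
  solve, and coupled runs stop gracefully at 0.1 (see above).
* Pressure drops implying a relative density contrast above 10% are
  rejected outright.
* `Delta` is redefined as `L / round(L / Delta)` so slices tile the
  clot; a fully dissolved voxel maps to infinite permeability (an open
  marker, `gamma = 0`), and square-root arguments driven slightly
  negative by round-off clamp to zero.
* Ensemble replicate seeds are `base_seed + replicate`; every stochastic
  artifact records its seed.
* Type-2 specifications whose disks would force a negative outer
  concentration are errors, not warnings.

## Known limitations

* The coupled pipeline is 2D; the fluid kernel accepts D3Q19 but no
  lysis experiment exercises it.  A 2D channel over-weights wall films
  relative to a cylinder, which is why both front readings exist.
* The late-lysis acceleration beyond the 1D prediction is sensitive to
  the gray-node time step: at `tau = 0.525` the breakthrough weakens
  and the front no longer outruns the schedule, while at `tau = 0.512`
  it does.  The homogeneous benchmark therefore uses the finer step;
  the ensemble cases, whose mass- and throughput-based metrics move
  only a few percent between the two, use the coarser, five-fold
  cheaper one.  This sensitivity is a genuine limitation of the
  gray-lattice description near the recanalization transition.
* In the 3 mm-wide ensemble channel, heterogeneity advances the
  recanalization onset more strongly (about twice) than in wider
  domains: preferential channels occupy a larger fraction of a narrow
  section.  Ensemble effect sizes should be read with the section
  width in mind.
* Clot fragments stay in place until dissolved; no fragmentation,
  embolization, or moving boundaries.
* The agent is one species with one rate constant; no
  plasminogen/plasmin cascade, no consumption of the agent.
* The constant permeation-velocity assumption of the 1D model is an
  input, not a result; the simulator shows where it breaks (the last
  third of the lysis).
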