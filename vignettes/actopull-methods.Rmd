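---
title: "Mechanochemical modeling of probe-pulled actomyosin networks"
author: "actopull"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanochemical modeling of probe-pulled actomyosin networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`actopull` simulates a crosslinked actomyosin network under a tensile load
delivered through a semi-spherical probe, the setting of AFM pulling
experiments on the cortical cytoskeleton of adherent cells. The model is a
coarse-grained mechanochemical one in the tradition of active-network
simulators such as MEDYAN and Cytosim: stochastic chemistry alternates with
mechanical energy minimization, so that the network is always observed at
mechanical equilibrium while its chemical composition evolves in time.

**Filaments.** An actin filament is a chain of beads connected by
"cylinders". Each cylinder holds up to 40 monomers at a 2.7 nm axial rise
(108 nm when full); only terminal cylinders may be partial. The cylinder is
inextensible in spirit — a stiff harmonic stretching term (100 pN/nm) keeps
it near its equilibrium length `n_monomers x 2.7 nm` — and filament
flexibility comes from a bending energy `k_b (1 - cos phi)` between
consecutive cylinder axes with `k_b = 672.5 pN nm`, which reproduces the
~10–17 um persistence length of F-actin at this discretization.

**Motors and crosslinkers.** Non-muscle myosin II (NMII) mini-filaments and
alpha-actinin are harmonic springs connecting binding sites on two
cylinders. Each cylinder carries four sites at fractional positions 1/8,
3/8, 5/8, 7/8 — a symmetric, non-terminal placement. Motor rest lengths are
drawn uniformly in [175, 225] nm at binding, linker rest lengths in
[30, 40] nm. A mini-filament carries 20 NMII heads, 10 per side, from the
printed equivalence of 2 uM NMII to 0.1 uM mini-filament. The ensemble
spring constant is the printed NMII stretching constant, 2.5 pN/nm: the
head number enters the *force scales* of the kinetics (unbinding
characteristic force 12.6 pN per head, stall force 15 pN per head), not
the elasticity, which is dominated by the mini-filament backbone. With
this choice the tension on a freshly bound motor (up to ~125 pN for the
worst-case 50 nm rest-length mismatch) sits on the same scale as its
mechanochemistry, whereas multiplying the stiffness by the head count
would make every binding event supply several hundred pN of prestress —
larger than any force the motors themselves can generate, which we judged
unphysical.

**Boundaries and the probe.** Beads are repelled by the six box faces and
by the probe surface with the exponential `eps exp(-d / lambda)`
(`eps = 41 pN nm`, `lambda = 2.7 nm`), where `d` is the distance to the
surface. The probe is a 250 nm-radius sphere whose center rides on the top
face, so its lower hemisphere protrudes into the box. Probe-attached
filaments are held by stiff zero-rest-length anchor springs
(100 pN/nm, configurable: "stiff" is not quantified in the source data)
from their minus-end bead to fixed points on the lower hemisphere.

**Excluded volume.** Non-adjacent cylinder pairs repel through
`E = k_ev (1/d^4 - 1/d_cut^4)` for `d < d_cut`, where `d` is the minimum
distance between the two segments and `d_cut = 108 nm` is one cylinder
length. The kernel is monotone in `d`, vanishes smoothly at the cutoff,
and diverges as segments approach overlap, which prevents filament
crossings during minimization. Its gradient is exact: the minimizing
segment parameters are an interior optimum or a clamped boundary point, so
the envelope theorem gives the derivative of the minimum distance
directly. We chose this transparent kernel over an integrated
segment–segment repulsion because the printed constant (100000, with an
ambiguous unit) only fixes an overall scale. Below 2 nm the kernel
continues linearly with matched value and slope — the barrier stays steep
(about 1.2e4 pN) but bounded, so a configuration that starts in deep
contact (a polymerization step can land a tip inside another cylinder)
remains minimizable instead of trapping the line search on a
quasi-singular wall.

## Chemistry

Reactions are simulated with the Gibson–Bruck next reaction method: every
channel keeps an absolute scheduled firing time in an indexed binary heap,
and a propensity change from `a` to `a'` rescales the pending time by
`a/a'` instead of redrawing. Channels with identical per-instance rates are
aggregated — a single channel carries, say, all plus-end polymerization,
and the filament that grows is drawn at firing time, weighted by the
Brownian-ratchet factors. This composition is exact for exponential
clocks and is what makes the engine fast enough at full scale.

* **Treadmilling.** Polymerization rates are per G-actin molecule in a
  (0.5 um)^3 compartment (plus end 0.151/s, minus end 0.017/s; equivalent
  to ~11.4 and ~1.3 per uM per s), depolymerization 1.4/s and 0.8/s per
  end. In `well_mixed` mode the whole box acts as one compartment and the
  per-molecule propensity is scaled by `compartment_volume / box_volume`;
  in grid mode species hop between compartments at the printed diffusion
  rates and ends consume G-actin locally. Attached filaments polymerize
  and depolymerize at the plus end only. Filaments never shrink below 3
  monomers — a geometric floor that keeps a bead pair well separated.
* **Binding.** Motor binding fires per free head (0.2/s x 20 heads x free
  mini-filaments), linker binding per free copy (0.009/s), gated on the
  availability of candidate site pairs: unoccupied pairs whose current
  separation lies within the species' rest-length window, excluding
  same-cylinder and adjacent-cylinder pairs. Candidates and all
  force-dependent propensities are refreshed from the geometry after every
  minimization and held frozen in between — the alternating cycle
  justifies treating forces as constant on the chemistry timescale.
* **Force dependence.** Alpha-actinin unbinds as a slip bond
  (`0.3/s x exp(F/17.2 pN)`), the motor ensemble as a catch bond per side
  (`0.2/s x exp(-F/(12.6 pN x 10 heads))`), walking stalls linearly at
  15 pN per head, and polymerization against a surface is suppressed by
  `exp(-F/1.5 pN)` whenever a filament tip sits within one monomer rise of
  a wall or the probe, with `F` the boundary repulsion force at the tip.
  Forces are spring-tension magnitudes, `k |l - l0|`.
* **Walking.** A walk event moves one bound side one site (27 nm) toward
  that filament's plus end; a step onto an occupied site, or past the
  plus-most site, is a no-op (statistically a thinned Poisson attempt).
  Ensembles release when either side lets go; a cylinder removed by
  depolymerization releases every bond it carried.

`advance_chemistry()` rebuilds its channel set from the state on entry;
bonds and copy numbers persist in the state, so redrawing the exponential
clocks across calls is statistically exact by memorylessness. Within a
call the no-redraw contract holds.

## Mechanics and minimization

`minimize_network()` performs limited-memory BFGS (memory 8) on all bead
coordinates with an Armijo backtracking line search, stopping when the
largest per-bead force falls below `force_tol` (default 1 pN, desk preset
2 pN) or at the iteration cap (1e5). The line search only ever accepts a
decrease, so energy is non-increasing across every call; quasi-Newton
curvature pairs are dropped when they fail the positive-curvature test.
The compiled energy kernel uses a uniform cell list over cylinder
midpoints for the excluded-volume pair sweep, and the boundary exponential
is truncated to zero beyond 40 screening lengths (a ~4e-18 relative
error) with a linear continuation on the overlap side to avoid overflow.

## The pulling protocol

A run places 300 free seed filaments (uniform random position and
orientation, placements crossing the walls rejected) and 30 filaments
hanging vertically from probe anchors, each seed one full cylinder of 40
monomers. Free G-actin tops the pool up to 20 uM total actin; 2 uM NMII
(0.1 uM mini-filaments) and 2 uM alpha-actinin enter solution at t = 5 s.
Pull events displace the probe, its anchors, and the top boundary upward
in 100 sub-steps (0.01 s each, minimizing after every sub-step), so a
whole event occupies 1 s during which no chemistry fires — the structural
response to pulling is purely mechanical. Between events the network
evolves chemically for the scheduled interval (150 s canonically) in
`chem_mech_interval` slices, each followed by minimization. The four
canonical cases: (i) five 500 nm steps; (ii) 250, 250, 250, 500, 500 nm;
(iii) five 250 nm steps; (iv) no probe and no attached filaments, with the
top boundary still following the case-i height profile so box geometry is
matched. Variants reproduce the release experiment (anchors cut at a
scheduled time, probe left as a passive obstacle), static probe, reduced
motor or crosslinker concentration, and shortened pulling intervals.

## Analysis metrics

The alignment index is `<|dz| / sqrt(dx^2+dy^2+dz^2)>` — the mean cosine
of the acute angle between a segment and the pulling (Z) axis: 1 for
Z-parallel, 0 for in-plane segments, 1/2 for isotropic orientations. The
printed formula omits the absolute value but defines the angle as acute;
`|dz|` realizes that convention and keeps the index in [0, 1]. On
simulation snapshots one segment per cylinder is used, weighted by its
monomer count (the weighting is our choice; segment counting would
over-weight short partial cylinders). On traced polylines the
experimental estimator is followed exactly: all point pairs 10 indices
apart along a trace, averaged within the trace, then unweighted across
traces; coincident point pairs carry no angle and are skipped. The
polarity variant uses the signed cosine of the minus-to-plus end-to-end
vector and spans [-1, 1].

The bundle region is the vertical 500 nm-diameter cylinder through the
box's x–y midpoint spanning the current box height; the bundle fraction is
the share of F-actin monomers inside it, with monomer positions
interpolated along each cylinder at the monomer rise. Recruitment rates
are ordinary least-squares slopes over consecutive 50 s windows stamped at
window centers. The radius of gyration is the RMS distance of monomer
positions from their center of mass; its rate is a finite difference.
Axial and radial distributions are unit-mass histograms with half-open
bins in physical nm — no pixel indexing anywhere.

## The synthetic-data generator

`generate_fixture()` builds geometries whose metric values are known by
construction: Z-parallel bundles packed in a 500 nm cylinder (alignment
and bundle fraction exactly 1), isotropic networks (alignment 1/2 in
expectation), in-plane networks (alignment 0), and traced polylines
sampled as random walks on the anisotropic confocal voxel grid
(dx = dy = 0.178 um, dz = 0.25 um) with a tunable upward drift. These
fixtures emulate the *geometry* of segmented microscopy data — ordered 3D
polylines at realistic voxel spacing — but none of its imaging artifacts:
no tracing errors, no intensity-dependent breakage, no anisotropic
point-spread blurring. Tests that pass on them certify the estimators,
not the tracing pipeline that produces real traces.

## Problem sizes and numerical choices

The full-scale protocol (330 filaments, 900 s, five pulls) is the
headline condition; replicated property checks run on the `desk_small`
preset — a 1.5 x 1.5 x 1 um box with 60 free and 8 attached filaments and
two pulling events — which preserves every physical constant and the full
mechanochemical cycle while keeping a replicate to about two minutes on
one CPU. For the same reason the desk preset coarsens the cycle to 1 s
slices and relaxes the minimizer tolerance to 2 pN; both are exposed as
parameters and neither changes any physical rate. Chemistry-only
treadmilling studies advance in 5 s slices so the tip ratchet weights
refresh as filaments grow toward the walls.

Under the printed kinetics the treadmilling balance sits at a G-actin
concentration of `(1.4 + 0.8)/(11.37 + 1.28) = 0.17 uM`, so 330 filaments
in the 11.25 um^3 box equilibrate near a mean length of 1.1 um
unconfined; wall-ratchet suppression in the 1.25 um-high box brings the
simulated plateau to about 1.05–1.08 um, reached within ~10 s and held
thereafter. This is the number the package reports for the steady state;
it is noticeably longer than the ~0.8 um quoted for the original
full-mechanics simulations, where bending confinement and crowding act on
top of the ratchet.

Ties and degenerate inputs: simultaneous scheduled times are impossible
almost surely and broken by heap order; zero-length segments are rejected
by the metrics (and skipped, with a count, in the polarity
distribution); a cylinder collapsing to zero length is a hard error from
the energy kernel; empty snapshots are errors for every mass-weighted
metric.

## Known limitations

* Bead dynamics are quasi-static: no thermal (Langevin) motion,
  hydrodynamics, or filament twist. Fluctuation-driven phenomena are out
  of reach by design.
* Binding consumes species from the pair's compartment in grid mode, but
  the binding propensity uses the total copy number — a well-mixed
  approximation at the reaction level; diffusion-limited binding
  gradients are not resolved.
* Per-end eligibility aggregation treats all eligible ends as
  exchangeable, which is exact for the rates but means per-filament event
  histories are not reproducible independently of the whole run.
* The grid reaction-diffusion mode is substantially slower in this
  implementation and is intended for validation (diffusion equilibration,
  local consumption) rather than full protocol runs, which default to
  `well_mixed`.
* Only two of the three pulling-magnitude conditions are exercised by the
  default replicated test battery (the strongest and the force-free
  control); the intermediate cases are available through the same
  configuration surface.
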