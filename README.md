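# actopull

Coarse-grained mechanochemical simulation of actomyosin networks under
tensile force applied through a moving probe, with the analysis metrics
used to characterize force-induced actin bundle formation.

## The problem

When a functionalized AFM probe pulls on the cortical actin cytoskeleton
of an adherent cell, the network reorganizes in two steps: filaments align
with the force axis essentially instantly after each pull (a mechanical
response), and F-actin then accumulates slowly into a consolidated bundle
between pulls (a chemical response driven by myosin activity and
crosslinker turnover). `actopull` is a desk-scale simulator for this
"mechanics before chemistry" phenomenology, for cytoskeletal modelers who
want a transparent, scriptable R implementation of the active-network
simulation recipe:

- actin filaments as bead–cylinder chains (up to 40 monomers per 108 nm
  cylinder) with stretching (100 pN/nm), bending
  (`k_b (1 - cos φ)`, `k_b = 672.5` pN·nm), excluded-volume and
  boundary/probe repulsion (`ε e^{-d/λ}`, ε = 41 pN·nm, λ = 2.7 nm);
- NMII mini-filaments and α-actinin as harmonic springs with
  force-dependent kinetics: slip unbinding
  `k = k₀ e^{F/17.2 pN}` for α-actinin, catch unbinding
  `k = k₀ e^{-F/(12.6 pN × heads)}` and linear stall at 15 pN per head
  for motors, Brownian-ratchet suppression `e^{-F/1.5 pN}` of
  polymerization against surfaces;
- stochastic chemistry (treadmilling, binding/unbinding, motor walking,
  compartment diffusion) by the Gibson–Bruck next reaction method,
  alternating with conjugate-direction (L-BFGS) mechanical energy
  minimization;
- pulling protocols that displace the probe in 100 sub-steps per second
  of simulated time, and the analysis suite: alignment index
  `⟨|Δz|/√(Δx²+Δy²+Δz²)⟩` on cylinders or traced polylines, filament
  polarity, bundle-region F-actin fraction and 50 s recruitment-rate
  fits, radius of gyration and its rate, axial and radial mass
  distributions.

## Worked example

Metric sanity on constructed geometry:

```r
library(actopull)

copy_number(20, 11.25)        # actin copies in the 3 x 3 x 1.25 um box
#> [1] 135498

alignment_index(generate_fixture("bundle", 50, seed = 1))    # Z-parallel
#> [1] 1
alignment_index(generate_fixture("planar", 50, seed = 1))    # in-plane
#> [1] 0
alignment_index(generate_fixture("isotropic", 5000, seed = 1))
#> [1] 0.4971274                                   # -> 1/2 for isotropy
```

A replicated-scale pulling run (60 free + 8 probe-attached filaments,
two 500 nm pulls 60 s apart; about two minutes on one CPU):

```r
p    <- desk_small_parameters()
sch  <- make_schedule("i", interval = 60, n_events = 2)
traj <- run_simulation(p, sch, seed = 1)

al <- trajectory_metrics(traj, "alignment")
al <- al[!duplicated(al$time), ]
al$value[match(c(60, 61, 120, 121), al$time)]
#> [1] 0.4335994 0.5025415 0.4835250 0.5457117
```

The alignment index jumps upward within the 1 s of each pull (0.434 →
0.503 at the first event, 0.484 → 0.546 at the second) and barely moves
during the 59 s of chemistry in between — the mechanical and chemical
timescales separate exactly as in the full-scale phenomenology. The same
trajectory gives a final bundle-region F-actin fraction of 0.243, versus
0.120 for the matched force-free control (`make_schedule("iv")` with
`n_attached = 0`), whose radius of gyration instead contracts from 604 nm
to 578 nm as motors pull the free network into a cluster.

The command-line front end wraps the same functions:

```sh
Rscript inst/cli/actopull.R simulate --case i --seed 1 --out out/
Rscript inst/cli/actopull.R analyze --traj out/trajectory.traj \
        --metrics alignment,bundle,rg --out out/metrics.csv
```

## Layout

- `R/`, `src/` — parameters and network construction; energy model,
  analytic forces, and minimizer (Rcpp); next-reaction chemistry engine;
  pulling protocols; analysis metrics; trajectory/trace I/O and fixture
  generation.
- `vignettes/actopull-methods.Rmd` — the model, its assumptions, every
  tunable parameter with units, and the numerical choices.
- `tests/testthat/` — unit, property, and end-to-end scientific checks.
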