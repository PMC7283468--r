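# mechamigr

Discrete-element simulation of a single, polarized, deformable 3D cell
migrating on a flat elastic-ligand substrate, with switchable
mechanosensing.

## The scientific problem

Mesenchymal cells migrate by protruding a lamellipodial front, forming
focal adhesions (FAs) to the substrate, contracting actomyosin stress
fibers (SFs), and retracting their rear. How fast — and in what style —
they do this depends jointly on a mechanical property of the environment
(substrate/ligand stiffness) and a biochemical one (receptor–ligand
affinity, i.e. how quickly adhesions disassemble). Two molecular
mechanosensing mechanisms shape this dependence:

* **FA maturation** (`fa_mat`): force stabilizes an adhesion, lowering its
  disassembly rate as `r = beta * r_off0 * exp(-zeta_FA |F_FA|)`;
* **SF strengthening** (`sf_str`): a fiber whose contraction stalls steps
  its force up by one actomyosin unit, `|F_SF| = n_str * F_am *
  phi(dL)`, up to `n_str = 5`, with the logistic factor `phi` weakening
  the fiber as it shortens.

`mechamigr` implements the whole cell as a discrete-element system: a
closed triangulated cortex (springs + dashpots on edges; area, volume and
bending elasticity), an actin polarity field on the surface that
demarcates lamellipodium and lamellum, Maugis–Dugdale-type adhesive
contact with the plane, stochastic discrete FAs (two springs in series —
the soft ligand spring sets the felt stiffness), contractile SFs, and
overdamped dynamics `M v = F` solved each 0.05-s step. Depending on where
a condition sits in the (k_ECM, adhesion lifetime) plane and which
mechanisms are on, cells migrate **progressively** (smooth,
keratocyte-like, balanced FA turnover) or by **collective retraction**
(cyclic load-and-fail: at least `n_thr = 15` FA ruptures within one
minute detach the whole rear), or not at all — which the package
classifies, maps and aggregates.

It is aimed at computational mechanobiologists who want a transparent,
scriptable re-implementation of this class of whole-cell motor-clutch
models for exploration, calibration and extension.

## A worked example

A two-hour migration run at fixture resolution (subdivision-2 mesh,
162 nodes), on a stiff ligand with long-lived adhesions and both
mechanosensing mechanisms active:

```r
library(mechamigr)

sim <- simulate_cell(condition = mm_condition(k_ECM = 0.5, r_off0 = 5e-4),
                     setup = mm_setup(fa_mat = TRUE, sf_str = TRUE),
                     duration = 2 * 3600, seed = 2, subdivision = 2)
summary(sim)
#> mode: none | displacement 0.23 um | retractions 0 | ruptures 14
#> mean FA count 34.7 | mean traction 69644.0 Pa
```

The printed numbers are the run's migration-mode label, the net
x-displacement of the interface center of mass, the count of full
(collective) retraction events and of individual FA ruptures, and the
time-averaged FA count and total traction `|T_cell| = sum_i |T_i|` over
the substrate triangles (Pa). At this coarse fixture resolution the
stiff/long-lived condition builds tens of adhesions, strengthens its
fibers to the cap and ruptures adhesions in bursts, but accumulates
little net displacement within two hours (see the methods vignette for
what the scaled-down configuration does and does not reproduce).

Key single-quantity computations:

```r
expected_fa_lifetime(c(5e-2, 1.08e-2, 2.3e-3, 5e-4))
#> 0.3326628  1.5342542  7.2318212 33.3249983   # minutes
stiffness_to_modulus(c(1e-3, 4.16e-2, 5e-1))
#> 0.25  10.40 125.00                           # kPa
1 / sf_weakening_phi(-mm_params()$dL50)
#> 2                                            # force halved at dL50

tr <- reduced_two_spring_experiment(k_ECM = 4.16e-2, duration = 7200)
max(tr$n_str)
#> 5                                            # strengthening cap
```

The full parameter study is enumerated with
`enumerate_conditions(study_grid()$k_ECM, study_grid()$r_off0,
all_setups(), reps = 5)` (480 runs), executed with `simulate_cell()` per
manifest row, and summarized per condition with `aggregate_study()`.
A thin command-line front end lives at `inst/cli/mechamigr.R`.

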