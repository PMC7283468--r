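---
title: "A discrete-element model of mechanosensitive single-cell migration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A discrete-element model of mechanosensitive single-cell migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechamigr)
```

## The model

`mechamigr` simulates a single polarized, deformable 3D cell migrating on a
flat substrate decorated with elastic ligands, using the discrete element
method: both the cell and the substrate plane are triangulated, and all
mechanics are node- and triangle-wise forces.

**Cortex.** The cell is an empty, closed triangulated shell (an icosphere of
radius $R_c = 8\ \mu m$). Each edge is a Kelvin-Voigt element: a linear
spring acting on the deviation of the edge length from its built rest
length, $|F| = k_{cortex}(d_{ij} - d^*_{ij})$, in parallel with a dashpot
acting on the axial projection of the relative velocity,
$|F| = -\Lambda_d\, \hat n_{ij} \cdot \vec v_{ij}$. Four additional
passive terms keep the shell cell-like: local (per-triangle) and global
area conservation, volume conservation, and hinge bending resistance on
the dihedral angle between adjacent triangles. Each is implemented as the
exact negative gradient of a discrete energy,

$$E_A = \tfrac{k_{loc}}{2}\sum_t \frac{(A_t - A_t^{ref})^2}{A_t^{ref}}
      + \tfrac{k_{glob}}{2}\frac{(A - A^{ref})^2}{A^{ref}},\qquad
  E_V = \tfrac{k_{vol}}{2}\frac{(V - V^{ref})^2}{V^{ref}},$$
$$E_B = k_{bend}\sum_{hinges}\bigl(1 - \cos(\theta - \theta^{ref})\bigr),$$

with the built sphere as the reference (so the rest shape has spontaneous
curvature rather than preferring flatness). The test suite verifies every
force against central finite differences of these energies, and that all
cortex forces are internal (zero net force and torque).

**Overdamped dynamics.** Cells live at low Reynolds number, so inertia is
dropped: at every step the friction operator times the velocities balances
the applied forces, $M\,v = F$. $M$ collects liquid (Stokes) drag
$\Gamma_{liquid}$ on every node, substrate contact friction
$\Gamma_{subs}$ on interface nodes, and the cortex dashpots, which couple
edge-connected nodes through the axis projector
$\Lambda_d\,\hat n \hat n^T$. $M$ is symmetric positive definite and is
solved matrix-free with a Jacobi-preconditioned conjugate gradient, warm
started from the previous step; `assemble_friction()` exposes the same
operator as a sparse matrix for diagnostics. Positions advance by
$v\,\Delta t$ with $\Delta t = 0.05$ s; a displacement of more than
0.5 $\mu m$ in a single step aborts the run as a numerical instability.

**Actin polarity field.** A globular-actin surface concentration $G$ lives
on the triangles. The periphery of the cell-substrate interface acts as a
source ($k_{gen}$), every triangle decays ($k_{deg}$), and the field
diffuses along the surface ($D_{actin}$), discretized finite-volume over
triangle adjacency with flux weights (shared edge length)/(centroid
distance). The steady state decays from the rim with length scale
$\sqrt{D_{actin}/k_{deg}} \approx 2.2\ \mu m$. Thresholds on $G$,
expressed as fractions of the current peak concentration (attained on the
source ring), demarcate
the lamellipodium (Lp, outer band, leading front only) and the lamellum
(Lm, the band behind it, front and rear); the polarity axis (+x) splits
front from rear at the interface center of mass, ties to the front.

**Protrusion.** Each Lp triangle receives
$\vec F_{prot} = k_{prot}\, G\, \widehat{\nabla G}$ projected onto the
substrate tangent plane; an equal and opposite counter force is spread
uniformly over all cortex nodes, so protrusion is internally balanced and
cannot translate the cell by itself.

**Adhesion.** Two channels couple cell and substrate. (1) Transient
adhesive contact in the Maugis-Dugdale family: each near-plane triangle is
replaced by the sphere fitted to it and its neighbors (the rigid plane has
infinite radius) and feels a Hertzian repulsive core plus a constant
adhesive (Dugdale) stress $\sigma_0 = w/h_0$ over the finite range $h_0$;
with $w = 0$ the law is exactly Hertz. (2) Discrete focal adhesions: a
lamellar node within 0.075 $\mu m$ of the plane binds stochastically at
rate $r_{on}$ to a fixed anchor (its instantaneous projection), forming a
stiff FA spring ($k_{FA}$) in series with the soft ligand spring
($k_{ECM}$); the series stiffness is dominated by the ligand, which is how
substrate stiffness is felt on a rigid plane. Bonds carry tension only.
FAs disassemble stochastically at
$r = \beta\, r_{off,0}\, e^{-\zeta_{FA}|F|}$ ($\beta = 1$ front, 2 rear;
the exponential catch-like stabilization is the FA-maturation mechanism
and is dropped when that switch is off; the rate is multiplied by 10
outside the Lm), and rupture deterministically when $|F| > F_{rup} =
7.7$ nN, leaving the node refractory for 30 min.

**Stress fibers.** Unbound FA pairs at least $8\ \mu m$ apart connect at
random into fibers that pull their two endpoint nodes together with force
$n_{str} F_{am} \varphi(\Delta L)$, where
$\varphi = 1/(1 + e^{-\mu(\Delta L + \Delta L_{50})})$ halves the force at
a shortening of $\Delta L_{50}$ (fiber-strain-induced weakening). The
fiber length is averaged over a 10-s moving window; when successive window
means differ by less than $L_{thr}$ the fiber has stalled, and with SF
strengthening on, $n_{str}$ steps up by one, capped at 5. A fiber persists
while at least one endpoint keeps its FA and dies when both are gone.

**Full (collective) retraction.** When at least $n_{thr} = 15$ ruptures
fall within a trailing 60-s window, all FAs are removed, orphaned fibers
die, every lamellar node becomes refractory, and the event is logged; the
window bookkeeping then resets so one cascade is one event.

## Initialization

The cell starts as a sphere tangent to the plane and is advanced under
cortex, contact and a uniform spreading load only - no FAs, no fibers, no
mechanosensing - in one-minute increments until the interface area changes
by less than 1% per minute (budget `init_duration`). The spreading load is
a standing force of the model, representing the active spreading machinery
the cortex model itself lacks; because it persists during migration, the
initialized shape is an equilibrium of forces that remain switched on, and
migration does not start with a recoil transient. The actin field is then
relaxed to steady state. Initialization contains no randomness and is
identical for every condition and setup.

One modeling choice deserves emphasis: **adhesions engage unstretched.**
The two published spring rest lengths sum to 1.5 nm while nodes bind from
up to 75 nm above the plane, so a bond pre-stretched at formation would
carry tens of nN on stiff ligands and rupture in the next step. Following
the motor-clutch picture the FA module is built on, each bond records the
gap it spans at formation as its rest length, and force grows only with
stretch beyond it.

## Parameters

The published working values are the defaults of `mm_params()` (SI units
throughout); `?mm_params` lists them. Three printed units are
reinterpreted, as configurable design decisions: the actin diffusivity is
taken as $8\times10^{-14}\ m^2/s$ (a surface diffusivity, not a rate);
the fiber-weakening constants are read on the meter scale
($\Delta L_{50} = 3.5\ \mu m$, $\mu = 5\times10^{6}\ m^{-1}$), because
fibers are at least 8 $\mu m$ long and their force is stated to persist
until strains of roughly $-0.25$ to $-0.4$, which micrometer-scale
half-weakening reproduces and picometer-scale would not.

A second group of parameters is not in the published table and carries
calibrated defaults:

* `k_area_loc`, `k_area_glob` ($2.9\times10^{-4}$ N/m), `k_vol`
  ($5\times10^{3}$ Pa), `k_bend` ($10^{-18}$ J): chosen so the spread cell
  conserves volume to within 5% and relaxes toward its rounded rest shape.
* `Gamma_subs` (0.05 N s/m), `Gamma_liquid` ($10^{-3}$ N s/m): contact and
  liquid friction; set so detached rear nodes retract on the
  10 $\mu m$/h scale and the velocity solve stays well conditioned.
* `theta_Lp` (0.74), `theta_Lm` (0.23): region thresholds as fractions of
  the steady-state peak concentration, calibrated so the Lp is the outer
  ring of the front (a 1-2 $\mu m$ band, matching the actin decay length)
  and the Lm the band behind it. Normalizing by the peak rather than by the
  source balance $k_{gen}/k_{deg}$ keeps the bands geometrically similar
  across mesh resolutions, because the rim peak itself falls as the source
  ring narrows with refinement.
* `E_contact` ($10^{4}$ Pa), `w_adh` ($10^{-5}$ J/m$^2$), `h0_adh`
  (50 nm), `d_contact` (50 nm): contact constants, set so transient
  contact holds the initialized cell on the plane while contributing far
  less than FA forces to the tractions.
* `k_prot` is a gain with units N per (molecules/m$^2$) - the printed
  units of the published proportionality constant do not produce newtons -
  calibrated once so the mean protrusion force per Lp triangle on the
  initialized cell is 0.12 nN, the model's own reported working magnitude.
* `r_sf` (3 s$^{-1}$ per unbound FA): the fiber-formation attempt rate,
  unstated in the published description ("at random"); at this rate most
  eligible adhesions become fiber-bound within well under a minute.
* `spread_pressure` (245 Pa): the standing spreading load discussed
  above, expressed as a pressure over the reference cortex area and divided
  evenly over the nodes, so the total load is resolution-independent. The
  spread cell conserves its volume to within about 5%.

## Problem sizes and what the tests show

The packaged test suite and the acceptance script run the model at fixture
resolution: subdivision-2 icospheres (162 nodes, 320 triangles) and
simulated spans of minutes to a few hours, which one CPU covers in
minutes. The production configuration (subdivision 3, 642 nodes, 24
simulated hours, the full 6 x 4 x 4 x 5 study of
`enumerate_conditions()`) uses identical code paths and is supported but
not exercised routinely.

The scaled-down runs reproduce the model's mechanistic skeleton - FA
populations balancing assembly against disassembly, fibers strengthening
to the cap faster on stiffer ligands, catch-bond stabilization extending
FA lifetimes, rupture bursts confined to stiff-ligand, long-lived-adhesion
conditions and absent without mechanosensing. They do not reproduce
quantitative whole-study outcomes (24-h displacements, traction maps
averaged over the last 800 min): at 162 nodes the rear lamellum hosts only
on the order of twenty adhesions, so a collective-failure cascade defined
as 15 ruptures in one minute sits at the very edge of what the coarse
mesh can synchronize, and whole-run displacement accumulates too few
retraction cycles to compare with the 24-h study. Those comparisons
require the production resolution and duration.

Nothing in the generator emulates experimental noise: the only stochastic
elements are the FA formation/disassembly draws and fiber pairing, exactly
as in the model itself.

## Numerical choices

* Explicit forces with an implicit (solved) friction operator; CG
  tolerance $10^{-9}$ relative, warm started.
* Actin stepping is explicit with sub-cycling whenever $\Delta t$ exceeds
  the finite-volume stability bound; the bound is recomputed every step
  from the deformed geometry.
* Per-triangle surface gradients are in-plane least squares over
  edge-neighbor centroid differences, with a guarded zero when the
  gradient norm is negligible.
* Sphere fits (contact curvature) use the algebraic least-squares fit on
  the triangle plus its edge-neighbor vertices; near-planar stencils are
  treated as flat and the effective radius capped at $4 R_c$.
* Stochastic sub-steps run in a fixed order after the mechanical update:
  fiber stall bookkeeping, FA rupture, FA disassembly, full-retraction
  check, FA formation, fiber formation, fiber pruning. A single RNG stream
  (R's, seeded per run) drives all draws.
* Rupture uses a strict inequality ($|F| > F_{rup}$), and the
  full-retraction window resets after firing.

## Known limitations

* The mesh cannot remodel: connections are immutable, the front cannot
  grow new surface past its adhesions, which is why full retraction plus a
  lamellar refractory period is needed for progress - and why simulated
  cells are slow.
* One adhesion per node and one fiber per adhesion; fibers neither merge
  nor branch, and there is no explicit motor kinetics (the stepwise
  force-strengthening abstraction stands in for it).
* The substrate is rigid; ligand compliance lives entirely in the FA's
  series spring, so long-range substrate deformations are absent.
* At fixture resolution the collective-retraction cascade is
  under-resolved (see above); conclusions about where in the
  stiffness-affinity plane each migration mode lives require the
  production mesh.
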