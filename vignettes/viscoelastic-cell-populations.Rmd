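---
title: "Modeling cell populations with sub-cellular Kelvin-Voigt networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cell populations with sub-cellular Kelvin-Voigt networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 6)
library(viscocell)
```

## The model

`viscocell` simulates a 2D cross-section of an epithelial tissue as a
population of deformable agents.  Each cell is a network of linear
Kelvin-Voigt elements (a spring of constant $k$ in parallel with a
dashpot of viscosity $\eta$) joining point masses ("nodes"):

* a closed **plasma-membrane ring** of $n$ nodes, consecutive nodes
  joined by membrane elements (the cortical cytoskeleton);
* a closed **nuclear-membrane ring** of $n$ nodes;
* $n$ **radial cytoskeletal elements**, pairing membrane node $i$ with
  nucleus node $i$;
* $n$ diametral **nucleoskeletal chords**, joining nucleus node $i$ to
  node $(i + \lfloor n/2\rfloor) \bmod n$, which let the nucleus resist
  shape and volume changes;
* an **osmotic pressure** load $P_{in} - P_{env}$ acting outward and
  perpendicular to the membrane.

The force of an element joining nodes $a, b$ is
$$ f_a = \left[ k\,(|r_{ab}| - L_0) + \eta\,(v_b - v_a)\!\cdot\!\hat u
\right] \hat u, \qquad f_b = -f_a, $$
with $\hat u$ the unit axis from $a$ to $b$.  The dashpot acts on the
axial component of the relative velocity, so every force pair is central
and torque-free and the network conserves momentum exactly.

Cells interact through three channels:

* **Adhesion**: any two membrane (or ECM) nodes of different owners
  closer than $d_a$ are joined by an adhesion Voigt element whose $k$
  and $\eta$ combine the two owners' attachment templates in series
  ($k = k_A k_B/(k_A+k_B)$); the bond ruptures only beyond $d_r > d_a$.
  The nonempty band $[d_a, d_r]$ gives the loading/unloading hysteresis
  of adhesive contacts.  Apoptotic cells disassemble their junctions
  unilaterally.
* **Repulsion**: a membrane node at distance $d < d_{rep}$ from its
  *nearest* foreign membrane polyline is pushed along its own inward
  normal with magnitude $k_{rep}(d_{rep}-d)$ (zero and continuous at
  $d=d_{rep}$); the reaction lands on the nearest foreign segment's
  endpoints with barycentric weights, conserving momentum.  Only the
  nearest surface acts: summing one ramp per nearby cell would crush
  newborn daughters wedged between several neighbors.
* **Substrate drag**: in 2D-culture mode the adhesion intensity between
  cell and substrate is represented by the per-node drag coefficient
  $D$; a scenario's "low adhesion" condition is literally a low drag
  field ($10^{-4} D_0$).

The **ECM** is a series chain of Voigt elements (an open line or closed
ring), optionally rigid, whose nodes adhere to and repel cells through
the identical machinery.

## Dynamics and the integrator

Motion is overdamped: inertia is irrelevant at cellular Reynolds
numbers, so node masses are book-kept but unused.  The update is

$$ v_i = \frac{F_i}{D_i + H_i}, \qquad x_i \leftarrow x_i + v_i\,\Delta t,$$

where $H_i$ is the summed viscosity of node $i$'s incident elements.
The node's *own* axial dashpot term is treated implicitly (it lives in
the denominator), while neighbor dashpot contributions enter $F_i$
explicitly at the previous step's velocities.  This split matters: a
fully explicit dashpot update diverges whenever $\eta > D$ regardless of
$\Delta t$, which is exactly the regime of the low-adhesion cultures.
The semi-implicit form reproduces the closed-form relaxation
$x(t) = x_0\,e^{-k t/(D+\eta)}$ of a single tethered element exactly in
the limit, is unconditionally stable in $\eta$, and reduces to plain
overdamped Euler when $\eta = 0$.  Startup rejects any $\Delta t$ above
the element-wise bound $\min (D_{min}+\eta)/k$.

Diagnostic force accounting (`accumulate_forces()`) always reports the
full antisymmetric Voigt forces, so conservation checks are exact
regardless of the integrator split.

Each step runs, in order: motility parameter cycling, substrate drag
refresh, adhesion bond update, force accumulation, integration,
biological events (growth attempts, division trigger and surgery,
apoptosis reaping, scenario hooks), and scheduled outputs.  All
randomness (growth insertion positions, tie-breaks) draws from the run
seed, so runs are reproducible bit-for-bit.

## Cellular processes

**Growth** inserts nodes.  An attempt fires every $\tau_g$ seconds per
cell and succeeds only in the growth volume region: with current area
$V_{cur}$ and rest area $V_{rest}$, growth is allowed at
$V_{cur} \ge c_g V_{rest}$, forbidden at $V_{cur} \le c_s V_{rest}$, and
the previous regime is retained in between (hysteresis).  An insertion
adds one membrane node and the paired nucleus node at flanking midpoints
(+4 elements), scales the total membrane rest perimeter and the radial
rest lengths by $(n{+}1)/n$ and the rest area by $((n{+}1)/n)^2$, and
re-pairs the chords.  A compressed cell therefore parks until its
surroundings yield -- the mechanism that confines proliferation to the
colony rim.

**Mitosis** triggers when the rest area has doubled while the cell is in
the growth region.  The division axis is the minor principal axis of the
membrane second-moment tensor (perpendicular to the elongation
direction) through the nucleus center of mass -- or, in a polarized
cell, orthogonal to the basal membrane stretch, so division lays the
daughters side by side along the ECM.  Nodes split into two contiguous
groups; chords are deleted (the nuclear structure collapses); the two
nucleus groups are pulled apart orthogonally to the axis while a
contractile pair squeezes the two group interfaces toward each other.
Nodes are assigned to the groups by the side of the division line they
lie on (index-based halving is the fallback for non-star-shaped rings):
random growth insertions make node spacing uneven, and splitting by
node count alone can cut the area as unevenly as 2:1.  A deformed cell
whose cut would leave the smaller daughter under 30% of the area
postpones mitosis until its geometry allows a near-equal split.  When
the nucleus-group centroids separate past $L_{div}$ the topology surgery
runs: group-crossing ring elements are cut and each daughter is closed
through two fresh nodes at the furrow-interface midpoints (offset
slightly towards its own side), so the daughters tile the parent along a
common cut line and the split conserves the parent's area to about 1%.
Each daughter is then repopulated by midpoint insertion at the farthest
consecutive pair back to (at least) the founder count, reset to the
founder rest template ($V_{rest}$ = the parent's initial rest area,
scaled up if extra nodes were inherited), and given a fresh regular
nucleus ring aligned with its membrane angles (the daughter nuclei are
newly placed, not inherited).  Division forces stay at full strength
until $0.8 L_{div}$ and fade to zero at $1.1 L_{div}$: fading to zero
*at* the threshold would make it unreachable, while a hard cutoff would
release the furrow impulsively.

**Apoptosis** disassembles all junctions unilaterally, divides every
rest length by 5 and removes the inner pressure; the dynamics then
collapse the cell, and it is deleted once its area falls below a
prescribed minimal fraction (10%) of the initial rest area.  The state
is absorbing: an apoptotic cell never grows, divides or re-bonds.

**Polarization** labels ECM-contacting membrane nodes basal, the
angular sector opposite the basal centroid apical, and the remainder
lateral.

**Motility** partitions the membrane into anterior and posterior
regions.  Each region's radial rest lengths ramp from their initial to
their threshold values and back over half a period ($\sin^2$, C1 at the
junctions, antiphase between regions, exact return to initial values
each period): the anterior extends (protrusion), then the posterior
contracts (retraction).  The region's substrate drag dips only during
the *first half of its own stroke*, so the front slides while
protruding, re-anchors before retraction, and the rear slides while
being pulled up.  That drag asymmetry is what rectifies a reciprocal
shape cycle into net crawling; with drag and length cycles exactly in
phase the two strokes cancel (we verified the centroid then drifts
slightly backward).

## Parameters

Lengths are um, time s, force nN, mass ng.  The printed source values
for a typical cell were not recoverable, so these are package defaults,
chosen once to give a stable, proliferating epithelial cell and exposed
in `cell_params()` / `adhesion_rule()`:

| parameter | default | role |
|---|---|---|
| $R$, $r_n$ | 7.5, 2.5 | cell / nucleus radius |
| $n$ | 40 (20 in population scenarios) | nodes per ring |
| $k_{mem}, \eta_{mem}$ | 2.5, 0.5 | membrane ring elements (both rings) |
| $k_{rad}, \eta_{rad}$ | 1, 0.5 | radial cytoskeleton |
| $k_{chord}, \eta_{chord}$ | 1, 0.5 | nucleoskeletal chords |
| $D_0$ | 20 | reference substrate drag per membrane node |
| $D_{nuc}$ | 2 | nucleus node drag |
| $P_{in}-P_{env}$ | 0.4 | osmotic inflation |
| $c_s, c_g$ | 0.65, 0.8 | stop / growth volume gates |
| $\tau_g$ | 2 s | growth attempt interval |
| $F^n_{div}, F^m_{div}, L_{div}$ | 2, 6, 5 | spindle pull, contractile ring, separation |
| $d_a, d_r$ | 1.5, 3.0 | bond creation / rupture distances |
| $d_{rep}, k_{rep}$ | 1.0, 3 | repulsion range / stiffness |
| adhesion template $k,\eta,L_0$ | 2, 0.2, 0.5 | per-cell; bonds combine in series |

Two of these deserve comment.  The volume gates sit well below 1
because cells in contact equilibrate a few percent under their rest
area; with $c_g$ near 1 every contacting cell parks permanently in the
hysteresis band and cultures never grow past a handful of cells.  The
pressure differential 0.4 nN/um keeps membranes taut against the
repulsion and adhesion loads at interfaces.  The acinus scenario narrows
the recovery gate to $c_g = 0.72$ so rim cells compressed by their
neighbors can resume growing and reach the surrounding matrix.

## Numerical choices

* **Time step.** Population runs use $\Delta t = 0.05$ s at low
  substrate drag and $0.1$ s at high drag -- the step follows the
  fastest membrane relaxation time, which scales like $(D+H)/k$.
* **Pressure discretization.** The per-node load is
  $\tfrac12 (P_{in}-P_{env})\,\mathrm{rot}_{90}(r_{i+1}-r_{i-1})$: half
  the neighbor-chord vector rotated outward.  Chord vectors telescope
  around a closed ring, so the net pressure force is exactly zero on any
  ring, convex or not.  (The per-node magnitude is half the neighbor
  chord length; for a regular $n$-gon of radius $R$ this is
  $R\sin(2\pi/n)$, indistinguishable from the arc length $2\pi R/n$ at
  the discretizations used.)
* **Normals.** Outward normals are perpendicular to the chord joining a
  node's ring neighbors, oriented by the ring's counterclockwise
  convention; coincident neighbors raise a degenerate-geometry error.
* **Ring untangling.** Division surgery and crowding occasionally fold
  a membrane locally (two nearby edges cross).  Folds are removed every
  few steps by a local 2-opt move -- reversing the ring span between the
  crossing edges, membrane and nucleus slots together so the radial
  pairing is preserved -- and a ring that has turned fully inside out
  (negative signed area) has its stored orientation restored.  Prompt
  repair matters because the pressure load on an inverted sub-path
  points into the cell and feeds the fold; the same pathology, left
  alone, collapses cells into slivers.
* **Mitotic force balance.** With an odd node count the two groups
  differ by one node; each group's total pull is fixed at
  $F^n_{div}\lfloor n/2\rfloor$ and divided evenly within the group, so
  the world total is identically zero.
* **Tie-breaks.** A degenerate (isotropic) second-moment tensor selects
  the axis through membrane node 1; equidistant bond candidates are all
  admitted (the rule is a distance threshold, not a nearest-neighbor
  match).
* **Occupied area.** $A_T$ is the union area of the cell polygons,
  computed as the sum of areas minus pairwise Sutherland-Hodgman
  overlaps of near cells (overlaps at equilibrium are below a percent,
  and cells are near-convex, so the correction is accurate there).

## Tissue statistics

With $\lambda$ = total internal cell-cell boundary length plus half the
patch perimeter, $A_T$ the occupied area and $n_c$ the cell count, the
package reports the edge density $\rho = \lambda/A_T$ and the form
factor $\Gamma = \rho\sqrt{A_T/n_c}$.  A membrane segment is internal
when its midpoint lies within `eps` (default $d_a$, so metric and
mechanical adjacency agree) of another cell's membrane; each physical
interface is counted once by averaging the two sides' detections.
$\Gamma$ is scale- and rigid-motion-invariant, attains $\sqrt\pi$ for a
circular cell, $2$ for a pair of unit squares, and $\approx 1.861$ for
the infinite honeycomb; larger values mean more polygonal or dendritic
cultures.  Neighbor graphs connect cells sharing internal boundary or at
least one adhesion bond; means are reported over all cells and over
interior cells (no external perimeter), the latter tending to 6 in large
monolayers.

```{r single-cell}
w <- make_world(scenario_spec("single_cell", n = 40))
for (i in 1:200) w <- integrate_step(w, 0.05)
form_factor(w)    # ~ sqrt(pi) = 1.7725: a relaxed cell is circular
```

## Scenarios: what the generator emulates

`make_world()` builds nine named initial conditions: a single cell, the
two-founder monolayer at configurable substrate drag, a crawling cell,
an epithelium seeded on an ECM line, a cyst in an ECM opening, an
inverted cyst around an ECM ring, a rigid ECM line with a rectangular
gap of width $W$ (in units of the free cell radius), a tensegrity bud
(deformable ECM line with a low-drag dip at its center), and the
acinus: a single cell inside a deformable ECM ring that proliferates,
polarizes its ECM-contacting outer layer, and differentiates -- once
the exposed rim is fully on the matrix, or once the colony reaches the
differentiation age `t_diff` (default 1000 s; colonies whose rim stalls
just short of full contact would otherwise deadlock) -- after which
polarized outer cells stop proliferating and the enclosed inner cells
enter apoptosis, leaving a single polarized ring around a cell-free
lumen.

```{r acinus, eval = FALSE}
sim <- run_scenario(scenario_spec("acinus", n = 20),
                    n_steps = 15000, dt = 0.1, seed = 1)
plot(sim)
```

These synthetic worlds are idealized: cells are mechanically identical
within a scenario, there is no biochemical signaling (growth factors,
chemotaxis), no thermal noise, and the third dimension is absent.
Passing tests therefore demonstrate that the *mechanical* rule set
reproduces the emergent morphologies -- monolayer packing with ~6
neighbors per interior cell, drag-dependent culture shape, lumen
formation -- not that any particular real cell line is quantitatively
matched.

Problem sizes in the test-suite and acceptance runs are scaled for a
single CPU: populations use $n = 20$ nodes per cell, monolayers grow
from 2 to 64 cells (three seeds per substrate condition), and the
acinus runs at a ring radius of 28 um (roughly 10-16 cells).  The
statistics are computed identically at larger sizes.

The adhesion-intensity sweep compares the form factor at a matched 40
cells over the drags $\{0.01, 0.03, 0.1, 0.3\}\,D_0$, two seeds
averaged per level.  The window is the model's drag-sensitive regime:
below about $0.01\,D_0$ the element viscosities floor the node mobility
($v = F/(D+H)$ with $H \approx 1.6$ nN s/um, so $D \ll H$ changes
nothing), and above about $0.3\,D_0$ the culture shape saturates;
outside the window the level ordering reflects seed noise rather than
adhesion.  Within it $\Gamma$ increases monotonically with drag, the
property the sweep asserts.

## Known limitations

* Cells are soft rings without bending stiffness; robustness against
  folding comes from the untangling pass rather than a cortical bending
  energy.
* Repulsion pushes along the querying cell's inward normal, so deeply
  interpenetrated configurations (which the dynamics avoid but surgery
  can transiently create) are corrected by geometry, not by the force
  law.
* The adjacency statistics depend on the contact tolerance `eps`; the
  default ties it to $d_a$, and metrics on irregular, partially
  detached cultures should be read with that in mind.
* Mass is carried but unused (overdamped regime); an inertial
  integrator is out of scope.
* No reaction-diffusion signaling layer; scenario rules (apoptosis
  triggers, differentiation timing) are geometric predicates supplied
  as hooks.
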