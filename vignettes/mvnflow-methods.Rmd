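---
title: "Methods: discrete RBC tracking in cortical microvascular networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discrete RBC tracking in cortical microvascular networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mvnflow simulates blood flow in cortical microvascular networks (MVNs) as a
biphasic fluid: plasma obeys Poiseuille flow on a vascular graph, and red
blood cells (RBCs) are tracked one by one through that flow field. This
vignette documents the model, its assumptions, the tunable parameters, the
numerical choices, and what the synthetic networks used throughout the test
suite can and cannot stand in for.

## The vascular graph and its units

A network is a graph of nodes (bifurcations and endpoints, with 3-D
positions in micrometres; `z` is cortical depth, zero at the pial surface
and increasing downward) and vessels (straight-pipe segments carrying a
diameter, a tortuous length and one of seven type labels: PA, DA, A, C, V,
AV, PV). Approximating each tortuous vessel by a straight pipe with the
same length and resistance neglects only diameter variation along a single
vessel. Pressures are expressed in mmHg at all interfaces (1 mmHg =
133.322 Pa exactly, `MMHG_TO_PA`); all hydrodynamic arithmetic is done in
SI units internally. Depth bins everywhere are half-open `[lower, upper)`,
so a capillary start point at exactly 200 um belongs to the second
analysis layer.

## Plasma flow

Flow in vessel *ij* is `q_ij = (p_i - p_j) / R_e,ij` with the effective
resistance

    R_e = mu_vitro(ht, d) * 128 mu_plasma L / (pi d^4).

Kirchhoff balances at interior nodes give a sparse symmetric
positive-definite system in the node pressures, solved by a sparse
Cholesky factorization (`Matrix`); inside the coupled RBC loop only the
numeric factorization is updated, the symbolic analysis being reused. The
discrete maximum principle (interior pressures between the extreme
boundary values) and node-balance residuals below 1e-10 are asserted in
the test suite against a dense full-matrix oracle.

`mu_plasma` defaults to 1.2e-3 Pa s and is configurable
(`rheology_params()`). Because all pressure boundary values are given in
mmHg, the plasma viscosity rescales flows and velocities but not the
pressure field.

## Blood rheology

The relative apparent viscosity uses the empirical *in-vitro* law: the
in-vivo parameterizations were calibrated on mesenteric networks for
diameters of 4-40 um, whereas roughly a third of cortical capillaries are
narrower than 4 um, so the in-vitro form is the appropriate closure. The
law needs the discharge hematocrit `hd`, obtained from the tube
hematocrit `ht` by inverting

    ht/hd = hd + (1 - hd)(1 + 1.7 exp(-0.415 d) - 0.6 exp(-0.011 d)),

which is quadratic in `hd`; the closed-form root is the production path
and a bracketed bisection serves as the test oracle. `hd >= ht` always
(the Fahraeus effect). Diameters below 2.5 um trigger a warning because
the law is evaluated outside its calibrated range there; the simulation
disables the warning but the arithmetic is unchanged.

## Discrete RBC transport

Each time step performs two sub-steps: (1) the pressure/flow solve with
every vessel's resistance evaluated at its instantaneous tube hematocrit
(cell count x cell volume / vessel lumen volume, clipped at 0.99); (2)
RBC propagation.

* **Cell velocity.** `v_RBC = v_bulk * hd/ht`, floored at `v_bulk`. This
  is the closure consistent with the hematocrit model: cells move faster
  than bulk blood in narrow tubes.
* **Time step.** `dt` is fixed for the whole run at the
  `(1 - coverage)` quantile of the vessel transit times `L/|v|` from the
  initial pure-plasma solve, with `coverage = 0.998`, so at least 99.8%
  of vessels cannot be traversed within one step. Multiple node crossings
  per step are allowed and handled by carrying the remaining travel time
  across nodes. The step is not recomputed after warm-up; the criterion
  is a one-time choice.
* **Divergent capillary bifurcations.** The cell follows the outgoing
  branch with the largest bulk velocity (the pressure-force rule). The
  alternative largest-flow-rate rule is evaluated alongside and an
  agreement fraction reported; on symmetric fixtures the two rules agree
  identically, which the suite asserts.
* **Divergent arteriolar bifurcations.** Phase separation follows the
  classical empirical logit law with coefficients (-13.29, 6.98, 0.964)
  scaled by `(1 - hd)/d_parent`; RBC flux fractions are zero below the
  low-flow threshold, one above its complement, monotone in the flow
  fraction, and exactly complementary for two daughters. The cell is
  assigned to a daughter by sampling this fraction with the run's seeded
  RNG. Coefficients live in `simulation_config(phase_sep_coef=)` so
  alternative parameterizations can be swapped in.
* **No overlap.** The effective cell length is the cell volume (49 fL by
  default, mouse) divided by the lumen cross-section, capped at the
  vessel length. Cells queue behind each other with at least this centre
  spacing; a cell that does not fit into its downstream vessel waits at
  the node and proceeds as soon as it fits (first blocked, first
  admitted). Convergent nodes merge fluxes additively; the
  phase-separation law is not applied in reverse.
* **Injection.** At every inflow boundary edge cells are scheduled at
  `hd * q / V_RBC` per second — the rate that maintains the boundary tube
  hematocrit (0.3 by default) in expectation — with a uniformly seeded
  phase offset, and are spread along the entry segment within the step.
  Cells are counted exactly: injected = exited + resident at every step.
* **Warm-up and recording.** The turn-over time is the total vascular
  volume over the total boundary inflow. The simulation runs 15 turn-over
  times before recording; cells injected during the following turn-over
  are tracked (edge sequence, entry times, entry-node pressures), and the
  run continues up to a configurable drain period so recorded cells can
  finish their paths.

## Diameter upscaling

Measured capillary diameters in these reconstructions are narrower than
the literature consensus, so capillary diameters (label C only) are
shifted upward histogram-bin by histogram-bin until they match a goal
beta distribution with mean 4.0 um and standard deviation 1.0 um on
[2.5, 9.0] um. The shape parameters follow from the moments on the unit
interval (the defaults give alpha = 1.5, beta = 5). The range is divided
into 500 bins (width 0.013 um); per-bin goal counts are the beta
probability mass times the total count, rounded half-up with the residual
carried to the next bin so the goals total the vessel count. Processing
runs from the smallest-diameter bin upward; surplus vessels (largest
diameters in the bin, above the cut at which the kept count equals the
goal) are shifted by the constant difference between the bin's upper edge
and the cut, which places them into the next bin where they are counted
again. Deficits are never back-filled — under-full bins are simply left
as they are — and the procedure is deterministic, with within-bin ties
broken by position. When the input distribution is stochastically smaller
than the goal, the output histogram matches the goal bin for bin exactly;
the suite asserts this, and the acceptance script reports the recovered
moments on 10,000 uniformly drawn sub-goal diameters.

## Vessel-type labeling corrections

Provisional labels must come with the input; morphological classification
from image stacks is out of scope. Three corrections are applied by
walking outward from every penetrating-tree root: (1) the capillary bed
starts only after two consecutive vessels narrower than 7.0 um —
provisional capillaries before that point return to the arteriolar
(venular) class, and the second thin vessel is the first capillary;
(2) no capillary keeps a diameter above 9.0 um (relabeled toward the
majority class of its graph neighbours) and no arteriole/venule below
6.0 um (relabeled C; use 4.8 um for small-caliber networks); (3) within
an arteriolar tree, when the angle between two consecutive centreline
chords at a node drops below 125 degrees, all downstream vessels become A
(a straight continuation measures 180 degrees; a tie at exactly 125 does
not trigger). The venular V/AV split uses the same rule and can be
disabled. A vessel violating both bounds at once cannot occur (the
thresholds do not overlap); two-sided relabeling conflicts between
neighbouring walks resolve toward the neighbour majority and are
reported.

## Boundary conditions

Pressure boundary values follow a two-level scheme:

1. **Pial surface.** Arteriolar inflows get a cubic polynomial in the
   adjacent vessel diameter; venular outflows a uniform 10 mmHg. The
   cubic is fitted at build time by least squares to a bundled table of
   pial arteriole pressure points. The bundled table is *synthetic* — a
   literature-shaped stand-in with plausible magnitudes (pressures rising
   from ~38 mmHg at 10 um to ~73 mmHg at 80 um), not digitized
   measurements — and should be replaced via the `points` argument when
   real calibration data are available.
2. **Deep boundaries.** Cutting a realistic network (12.5% of the width
   on each side; at 1.2 mm depth for a full-depth mouse network) exposes
   deep in- and outflow stumps that carry most of the exchange with the
   surrounding tissue. The network is implanted into a larger artificial
   MVN: a hole the size of the implant's bounding box is cut from the
   host (vessels with both endpoints inside removed), the implant is
   centred in the cut-out, and every deep stump is stitched to the
   nearest remaining host capillary vertex. A steady solve of the
   compound network at a constant tube hematocrit of 0.3 (no RBC
   tracking; the constant mirrors the inflow hematocrit, which the source
   description leaves unstated) yields pressures at the stitched nodes,
   which are then imposed as pressure boundary conditions — also at nodes
   that turn out to be outflows — for the discrete simulation on the
   implant alone. At constant hematocrit the two levels are exactly
   consistent: re-solving the implant alone under the transferred
   pressures reproduces the compound solve's stitch flows, which the
   suite asserts to 1e-8.

## The artificial network generator

The generator serves both as the boundary-condition host and as the test
bed for every stage, emulating the inputs that real reconstructions would
provide.

* **Capillary bed**: stacked planar honeycomb lattices (hexagon edge
  60 um by default, chosen to give capillary densities in the literature
  range; vertical spacing equal to the hexagon edge). Between adjacent
  layers one of the three in-plane edge-orientation classes (cycling with
  depth) is removed from both layers and replaced by vertical vessels at
  every node — this keeps every interior bifurcation at exactly three
  adjacent edges, the degree-3 topology of real capillary beds. Diameters
  are drawn from the goal beta distribution.
* **Penetrating trees**: parametric rooted trees standing in for measured
  penetrating vessels, which are not available. The trunk descends to a
  template (rat-scale) depth and all depths are scaled by the
  mouse-to-rat cortical thickness ratio 0.66; side branches (one per
  trunk node by default) step outward and slightly downward, halving
  their lumen area (d / sqrt(2)) per segment, truncated with a warning at
  the 2.5 um floor. DA trees are labeled DA (trunk) and A (branches), AV
  trees mirror-wise; the first trunk segment is labeled PA/PV so that
  paths through fully artificial networks traverse all five vessel
  classes. Roots sit on a rhombic lattice (spacing 350 um by default)
  with alternating kinds.
* **Assembly**: each tree leaf joins its nearest capillary node (ties to
  the lowest node id); the result must be a single connected component.

What these networks do **not** emulate: real angio-architecture beyond
degree-3 topology and depth extent — no depth-dependent capillary
density, no measured tortuosity or diameter correlations, no realistic
DA:AV ratio per region. Tests passing on them demonstrate the mechanics
and conservation properties of the pipeline, not agreement with any
measured cortical network; the quantities that depend on real topology
(e.g. the published per-layer pressure-drop percentages) are therefore
not asserted anywhere.

## Trajectory analysis

Analyses operate on recorded trajectories (edge sequence, entry times and
entry-node pressures per cell).

* **Validity.** A full path visits PA -> DA+A -> C -> V+AV -> PV in
  order; to be robust to labeling errors a path may deviate for at most
  two consecutive edges provided it resumes at a stage at least as far
  along. The tolerance resets after every accepted edge (per-excursion,
  not a global budget — the natural reading of robustness against local
  labeling errors). Capillary-only analyses also accept
  (PA or DA+A) -> C -> (V+AV or PV). Cells injected at deep boundaries
  have unknown history and classify as invalid, exactly as deep inflows
  must be excluded in the real setting.
* **Layers.** Five 200-um analysis layers cover the top 1000 um; a
  trajectory belongs to the layer of its capillary start point (first
  arteriole-to-capillary transition node).
* **Preferences.** Per start point, the relative end-point frequency is
  the fraction of its cells reaching that end point; an end point (or
  path) is preferred when the top frequency exceeds 0.5 and the runner-up
  stays below 0.3. Five per-pair characteristics (euclidean distance,
  mean path length, mean summed tube resistance, mean flow rate, mean
  cell velocity) are normalized per start point by their maximum and
  correlated with the frequencies (Pearson, pooling all pairs; start
  points visited by a single cell are excluded and flagged). The
  per-edge flow rate along a recorded path is reconstructed as cell
  speed times lumen area, a proxy that ignores the Fahraeus factor but
  preserves the ordering the correlation needs.
* **Averaged curves.** Pressure (linear) or diameter (piecewise
  constant) is resampled onto a 100-point normalized-path-length grid
  per trajectory, averaged per layer, and the abscissa rescaled by the
  layer's mean total path length; grid density only limits resolution.
* **Pressure-drop decomposition.** Mean pressure at the first node of
  each type group and mean path length at that transition, per layer;
  per-type fractions are successive inlet differences over the total
  drop from the PA inlet to the PV inlet. Two labeling-sensitivity
  variants re-run the decomposition with the first capillary edge
  treated as arteriolar, or the last arteriolar edge as capillary.
* **Transit and feeding.** Capillary transit time (its standard
  deviation is the transit-time heterogeneity), transit path length,
  cell velocity, observed unique capillary paths, feeding branches
  (distinct arteriole-to-capillary transition vessels) with their summed
  blood and cell fluxes, the per-AV feeding matrix with the primary-DA
  fraction, and the in-plane least-squares fit of end depth on start
  depth (per-cell pairs; the per-start-point alternative weighting is a
  matter of pooling and can be applied by deduplicating records).

## Problem sizes and determinism

The end-to-end demonstration (also the heaviest test) implants a
generated network of about 3,000 vessels (1 mm footprint, 1 mm depth,
2 DAs and 2 AVs, trimmed 12.5% per side and at 0.9 mm) into a ~6,000
vessel host, runs the full 15 + 1 turn-over protocol with a drain phase,
and analyzes the recorded paths; unit tests use much smaller fixtures
(chains, Y-splits, sub-millimetre beds). One global seed fans out to
per-stage seeds; identical configurations reproduce byte-identical
trajectory artifacts, which the suite asserts.

## Known limitations

* No oxygen transport or discharge is modelled anywhere.
* The in-vitro viscosity law below 2.5 um and the phase-separation
  coefficients outside their calibrated diameter range are
  extrapolations.
* Vessels are rigid; no compliance, no unsteady inertial effects.
* The synthetic pial-pressure table is a placeholder for digitized
  measurements (see above).
* Real reconstructed MVNs are not bundled; all shipped results derive
  from the generator.
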