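---
title: "Cell-shape topology and division-plane positioning in early plant embryos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-shape topology and division-plane positioning in early plant embryos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryodiv)
```

## Overview

Early *Arabidopsis* embryogenesis proceeds through an invariant sequence of
divisions up to the 16-cell stage, after which division-plane orientation
becomes variable while cell shapes paradoxically become more uniform.
`embryodiv` implements the quantitative machinery needed to study this on
segmented 3D label images, and ships a synthetic-embryo generator so that
every stage of the pipeline can be exercised, tested, and calibrated
without any microscopy data. Four analysis layers are provided:

1. a **lineage-based topology descriptor** — the number of division faces
   of a cell — with shape classes and shape-distribution entropy;
2. a **graph-cut theory** of division topology on polyhedral cell graphs;
3. a **stochastic voxel model** of division-plane positioning by interface
   area minimization (Metropolis Monte Carlo);
4. **scoring machinery** comparing simulated to observed divisions (match
   score, area/distance solution tables, plane families, rule compliance,
   orientation classes, directional length asymmetries, and two-generation
   pattern sequences).

## The face-count descriptor

Automatic corner detection on noisy voxel walls is fragile, so cell shape
is described *topologically*: a cell's faces are the distinct *origins* of
the interfaces that bound it. An origin is either one of the two initial
interfaces of the first embryonic cell — the outer surface and the
suspensor wall, counted separately — or the generation at which a division
created the wall (the generation of the lowest common ancestor's division,
read from the lineage tree). Several neighbours across fragments of the
same wall therefore count once, and the descriptor is invariant to
relabeling and cropping of neighbours.

The first embryonic cell has two faces; the noise-free stereotyped
sequence gives 3, 4, {4, 5}, {4, 5, 5, 6} faces at generations 1–4. Cells
with 4, 5 and 6 faces are topologically a tetrahedron (T), a triangular
prism (P) and a cuboid (C); anything else falls in a catch-all class O.
Heterogeneity of the shape distribution at a generation is summarized by
the Shannon entropy $-\sum_f p_f \log p_f$ with $0 \log 0 = 0$. The
logarithm is natural (nats) with a `base` option; only relative
comparisons are ever used, so the base is a display choice.

```{r faces}
emb <- make_stereotyped_embryo(4)
d4 <- shape_distribution(emb$image, emb$tree, 4)
d4
shape_entropy(d4)
```

## The synthetic embryo generator

`make_stereotyped_embryo()` builds the embryo proper as a truncated sphere
resting on a one-voxel suspensor slab (a reserved label, so the two
initial interfaces are distinguishable — the 1C cell must count two
faces), then applies the stereotyped sequence: two longitudinal anticlinal
quarterings, a transverse apical/basal division, and the G4 round whose
periclinal walls create the inner cells. All cuts are exact planes, so
ground-truth orientation labels exist for classifier validation.
Connectivity is 6-neighbourhood throughout, matching the face-adjacency
used for interface areas.

Choices a reader should know about:

* **Grid and calibration.** The default grid is 56×56×28 voxels at the
  confocal-like calibration 0.17×0.17×0.35 µm, an embryo radius of about
  3.8 µm. Shapes are defined in physical coordinates, so asymmetry ratios
  are physical ratios.
* **Periclinal cut orientation.** The G4 walls are flat planes oriented
  parallel to the local outer surface (normal towards the cell's surface
  centroid), with the inner daughter receiving 20% of the mother volume —
  these divisions are strongly asymmetric in real embryos, and this
  fraction leaves a safe clearance between the inner cell and the surface.
* **Positioning noise** displaces each plane anchor by a uniform draw of
  up to the given fraction of the cell's extent along the cut normal. The
  canonical face counts are guaranteed noise-free and verified by test up
  to 5% noise. At 10% noise the flat apical periclinal planes occasionally
  graze the spherical surface (the inner daughter then picks up a spurious
  outer-surface origin); a curved-wall generator would be needed to push
  the guarantee further, and real dermatogen walls are indeed curved. This
  is a known limitation of the generator, not of the descriptor.
* **Variable divisions** (`make_variable_generation()`) draw a plane
  orientation class per cell from a per-domain distribution — vertical
  walls parallel to an existing lateral wall (`anticlinal_longitudinal`),
  horizontal walls (`anticlinal_transverse`), surface-parallel walls
  (`periclinal`), and vertical walls containing the radial direction
  (`radial`) — at a volume fraction of 0.5 plus configurable noise. The
  magnitude of positioning noise in real embryos is not known
  quantitatively; the defaults are free parameters of the generator, and
  the tests exercise both the noise-free and moderately noisy regimes.

What passing tests on these synthetic embryos do *not* show: real walls
are curved, cells grow between divisions, and segmentation errors create
wall fragments, none of which the generator emulates. The descriptor and
classifiers are designed to be robust to the last point (origin pooling,
planarity thresholds), but claims about real embryos require real data.

## Division topology as graph cuts

An idealized cell shape is a 3-connected planar graph with a fixed
embedding (vertices, edges, faces as ordered cycles; Euler's relation
$V - E + F = 2$). A division is modeled as a cut: a bipartition of the
vertices into two connected sets whose cut edges are crossed exactly once
by a single closed curve on the cell surface — divisions avoid existing
vertices, in line with the avoidance of four-way junctions. Operationally,
`enumerate_cuts()` accepts a bipartition when both daughter graphs,
rebuilt by truncating each mother face at the cut and closing it with one
new edge, have a single cycle of new vertices (the new wall) and pass the
polyhedral invariants. On the tetrahedron, prism and cuboid this
admissibility coincides with connectedness of both sides, and the
enumeration yields 7, 22 and 63 cuts. Daughters are classified by graph
isomorphism against the canonical catalogue.

Two structural results are checked exhaustively by the test suite: if the
edges inherited by the p-vertex side contain a cycle, one daughter keeps
exactly the mother's face count (and the other at most it); if they are
acyclic, at least one daughter gains a face. In particular no tetrahedron
cut produces two tetrahedra — tetrahedral cells are an obligatory source
of shape novelty.

```{r cuts}
table(vapply(enumerate_cuts(canonical_graph("P")), function(ct)
  paste(sort(ct$daughter_classes), collapse = "+"), character(1)))
theoretical_daughter_distribution("T")
```

The "topologically random division" null is uniform over admissible cuts
by default; a uniform-over-p weighting is also provided
(`weighting = "p_classes"`) because the self-reproduction contrast between
shapes depends on this convention. Under the uniform-over-cuts null this
package obtains $P(C \to CC)/P(P \to PP) = (3/63)/(1/22) \approx 1.05$,
and 0.80–0.83 under the per-class weightings
(`self_reproducibility_ratio()`); the qualitative absorbing-state
structure (C self-reproduces, T cannot) is the same under every weighting.

## The division simulator

The positioning model is cell-autonomous: given the 3D binary mask of a
mother cell, a volume ratio $\rho$ is drawn uniformly in [0.2, 0.5], each
voxel is assigned to daughter A with probability $\rho$, and Metropolis
Monte Carlo minimizes the interface area. One cycle is $N$ single-voxel
flip proposals ($N$ = mask voxels); an area-decreasing flip is always
accepted, others with probability $e^{-\beta\,\Delta A}$. After each cycle
$\beta$ is adjusted multiplicatively
($\beta' = \beta\,(1 + \kappa\,(\text{observed} - \text{target}))$,
$\kappa = 0.5$, clamped to $[10^{-4}, 10^4]$) so that about 5% of the
proposals that would increase area are accepted; $\beta_0$ makes a flip
costing one median voxel-face area acceptable with probability ½. The
interface area is the sum of shared voxel-face areas under
6-connectivity, which respects anisotropic calibrations exactly for
axis-aligned walls and ranks oblique walls consistently at the
resolutions used.

Three numerical choices depart from the bare model and matter at the mask
sizes this package targets (16³–32³):

* **Volume tether.** Single-voxel flips do not conserve volume. On small
  masks the minority daughter disappears by curvature-driven shrinkage
  long before 500 cycles, which would contradict the model's own contract
  (an achieved volume ratio, plane families at the drawn ratio). The
  energy therefore includes $w\,|n_A - \rho N|$ with $w$ equal to one
  median voxel-face area (`volume_tether`, set 0 for the untethered
  model). Area remains the only term shaping the interface.
* **Cooling tail.** At the 5% setpoint the small-mask system is rough; a
  tail of cycles during which the acceptance target decays to ~2% of the
  setpoint (`cooling_cycles`) lets each run settle into a single local
  area minimum. Setpoint statistics are always reported from the main
  phase only.
* **Greedy quench and cleanup.** A final zero-temperature phase
  (`anneal_cycles`) removes residual roughness (the tether is kept, since
  untethered descent slides oblique cuts toward the nearest corner), and
  by default each daughter is reduced to its largest 6-connected
  component with stray voxels reassigned (`cleanup`, recorded in the
  result), because match scoring assumes compact daughters.

```{r sim}
mask <- make_shape_mask(shape_spec("cuboid", extent = c(16, 16, 16)),
                        voxel_grid(c(20, 20, 20), c(1, 1, 1)))
res <- simulate_division(mask, simulator_config(n_cycles = 300,
                                                cooling_cycles = 150),
                         seed = 1)
res
```

## Scoring and the division rule

With observed daughters $A, B$ and simulated daughters $A', B'$ over the
same mother, the match score is
$\max\{|A \cap A'| + |B \cap B'|,\ |A \cap B'| + |B \cap A'|\} / |A \cup B|$,
which lies in [0.5, 1]. Batches of simulations are summarized in a
solution table (area, distance from the mother-cell center to the nearest
interface face center, achieved ratio, score) — the quantitative version
of the area-versus-distance distribution plots from which the division
rule is read.

The rule — *the plane minimizes area among the solutions that pass
through the cell center* — is operationalized by `rule_compliance()`:
simulations are grouped into families by hierarchical clustering on the
match-score distance (average linkage, threshold 0.25; single linkage
provably chains the plane-orientation modes together through
low-volume-ratio oblique cuts), "passing through the center" means a
distance below δ (default: the 10th percentile of all simulated
distances, reported), and the observed division is compliant when its
best-matching family contains a center-passing solution of minimal area
among all center-passing solutions, within a 5% area tolerance that
absorbs residual voxel-scale roughness. A Pareto dominance rank
formalizes the "bottom-left" position; an empty center neighbourhood is
flagged inconclusive rather than forced either way.

Orientation labels use the embryo frame: anticlinal versus periclinal is
decided by how the wall splits the mother's outer-surface contact (a
periclinal wall leaves at most a rim — less than 25% of the contact — on
the inner daughter; flat cuts of curved cells always leave a rim, which a
binary touch test would misread), or for inner cells by the angle between
the wall normal and the radial direction (45°, ties anticlinal).
Transverse means the wall normal is within 45° of the apical–basal axis;
vertical walls are longitudinal, or radial when their normal is more than
60° from the radial direction. Interfaces whose planarity is too low are
labelled oblique. All thresholds are package choices validated against
the generator's ground-truth cuts.

Directional lengths (L, R along the left/right radial directions, H
longitudinal) are measured as chords through the cell center. For
generated shapes the recorded construction center is used: chords through
the centroid are mathematically blind to affine left/right skew (any
triangle's centroid bisects the chord parallel to a side), so the
centroid would be the wrong reference exactly where asymmetry matters.
For arbitrary cells the centroid is the fallback.

Two-generation sequences of orientation labels are counted per domain by
`pattern_sequences()`, which pools sequences into attractor classes: two
crossed flat cuts produce the same 2×2 checkerboard arrangement whichever
orientation comes first, so (transverse, then longitudinal twice) and
(longitudinal, then transverse twice) are one class.

## Problem sizes and determinism

The shipped tests and the acceptance script run entirely on synthetic
data: embryos on the 56×56×28 default grid, simulator masks of 16³
voxels (300 setpoint cycles, 150 cooling, 25 quench), 80–120 runs per
solution table, and exhaustive enumerations on masks of up to 12 voxels
for the sampler-versus-oracle comparison. These sizes make every figure
of merit reproducible in minutes on one CPU while keeping the separation
between the model's relaxation and volume-drift timescales. All
randomness flows through explicit seeds (R's RNG); identical seeds give
bit-identical embryos, partitions and tables.

## Limitations

* The generator's flat periclinal walls bound the noise level under which
  canonical topology is guaranteed (5%); real walls are curved.
* The simulator's tether, cooling and quench are desk-scale numerical
  devices; inferences about wall-positioning energetics in real cells
  should rest on the relative geometry of families, not on absolute
  interface areas, which carry a small roughness excess.
* Family identification is a clustering heuristic controlled by a
  threshold; pathological mothers (near-degenerate symmetry) can merge or
  split families.
* Observed-frequency comparisons (domain-specific division rates in real
  embryos) require segmented image collections that this package does not
  ship; `shape_gof_test()` provides the machinery once such counts are
  available.
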