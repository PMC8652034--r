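---
title: "Family-wide secondary structure diagrams: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-wide secondary structure diagrams: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sse2d)
```

`sse2d` turns a set of related protein domains into per-domain 2D secondary
structure diagrams and one family overlay. This vignette explains the models
behind each stage, the parameters that matter, what the synthetic generator
does and does not emulate, and the design choices made where more than one
reasonable option existed.

## The layout model

Each domain is reduced to a set of layout *elements*: every helix, and every
β-sheet as one rigid body. Element `i` gets a 3D anchor `a_i` — the midpoint
of a helix's total-least-squares axis, or the centroid of a sheet's strand
midpoints — and the diagram seeks 2D positions `p_i` minimizing

$$ S(p) \;=\; \sum_{i<j} \big(\lVert p_i-p_j\rVert - \lVert a_i-a_j\rVert\big)^2
   \;+\; \lambda \sum_{i \in \text{started}} \lVert p_i - s_i\rVert^2 . $$

The first term is a raw (unweighted) distance-difference stress, the same
quantity metric multidimensional scaling minimizes: it is zero exactly when
the 2D diagram reproduces every pairwise 3D distance, which is achievable
precisely when the anchors are coplanar. The second term restrains elements
towards a *starting layout* `s` — the diagram of a previously computed
family member — which is what makes diagrams across a family land in one
shared frame and remain visually comparable. With `lambda = 0` the stress is
invariant under any rigid motion of the whole diagram, so the absolute frame
is fixed only by the initialization and, when present, the start.

Tunable parameters (all in `layoutConfig()`):

* `lambda` (default **0.05**, dimensionless) — weight of the deviation
  penalty per element. 0 decouples members entirely; large values freeze
  shared elements at the start position and push all residual stress into
  the unshared ones.
* `minOverlap` (default **0.5**) — minimum fraction of the new member's
  element labels that a previous diagram must cover to be adopted as start.
* `maxIter` (**2000**) and `tol` (**1e-8** relative objective change) — the
  optimizer budget. Hitting the cap records a warning in the diagram and
  returns the best iterate.
* `primaryThreshold` (**0.5**) — labels with occurrence frequency at or
  above it are *primary*, the rest *secondary* ("common to most members" is
  the intent; the boundary value itself counts as primary).

### Optimization scheme

The optimizer is a deterministic gradient descent with Armijo backtracking
line search; the analytic gradient of `S` is cheap and the line search
guarantees monotone descent (asserted per iteration in the test suite). No
random restarts are used by default — determinism across reruns was judged
more valuable than occasional escape from a poor local minimum, and the
initialization below makes poor minima rare for protein-sized element counts
(3–15). Placement is staged as the primary/secondary split suggests:

1. primary elements are optimized with only primary–primary pair terms;
2. primaries are frozen and secondary elements are optimized with every pair
   term that involves at least one secondary element.

Staging means rare elements can never distort the conserved core of the
family picture, and a member's primary layout is fully reproducible from
the primary anchors alone.

The initialization projects the 3D anchors onto their best-fit plane
(principal axes of the *primary* anchors, x along the first axis, with
deterministic sign conventions). For coplanar anchors this is already the
exact optimum. When a starting layout exists, labels it covers take its
coordinates verbatim, and the projection of the remaining labels is rigidly
rotated onto the started subset first.

For three elements the continuous optimum can be checked independently: any
three pairwise distances embed exactly in the plane, and an exhaustive
enumeration of placements on a 5×5 grid gives an upper bound the optimizer
must beat. Both checks are in the test suite and the acceptance script.

### Angles

After positions are fixed, each element's angle is the in-plane orientation
of its 3D axis projected into the same frame: the helix axis direction, or
for sheets the direction-sign-weighted mean of the member strands' N→C axes
(sign-weighting makes antiparallel partners reinforce rather than cancel;
an unweighted mean of a perfect hairpin would be the zero vector). An axis
perpendicular to the projection plane has no defined in-plane direction and
falls back to angle 0 with a recorded warning. If glyph rectangles then
overlap, each element may rotate by up to ±15° in 5° steps (deterministic
sweep in label order) to minimize the total pairwise overlap area — a purely
cosmetic refinement that never moves centers.

## Detection calibration

Detection uses Cα-only distance rules in the P-SEA tradition: short-range
distances d(i,i+2) and d(i,i+3) classify each residue, runs become elements.
The windows are centred on the canonical trace geometry that ideal secondary
structure produces — helix d2 = 5.43 Å and d3 = 5.05 Å (2.3 Å radius, 1.5 Å
rise, 100°/residue), extended-strand d2 = 6.60 Å (3.3 Å rise) — with widths
of 1.3–1.6 Å: `helixD2 [4.8, 6.1]`, `helixD3 [4.35, 5.75]`,
`strandD2 [5.8, 7.4]`. The margin matters quantitatively: coordinate noise
of σ per axis perturbs a pairwise distance by roughly σ√2, so at the 0.3 Å
noise level the family generator emulates, a window edge closer than
~0.5 Å to the canonical value misclassifies a noticeable fraction of
windows. Narrower, off-centre windows (e.g. a strand window starting at
6.4 Å) lose the majority of short strands at that noise level.

Three robustness devices, all configurable in `detectionParams()`:

* **profile smoothing** (`smoothWin = 3`): a running *median* over adjacent
  windows — it rejects single-window outliers outright, and unlike a running
  mean it cannot be dragged by one extreme turn value next to a short
  strand; a constant ideal profile is unchanged.
* **gap closing** (`closeGap = 2`): flag gaps of ≤ 2 residues inside a run
  are filled, so one bad window never splits an element.
* **minimum window runs**: ≥ 2 consecutive strand windows and ≥ 3 helix
  windows. Turn junctions can brush the helix windows (a tightly curved
  coil is locally indistinguishable from a helix in d2/d3 alone — real
  P-SEA disambiguates with angles and dihedrals, which a Cα-only rule set
  deliberately forgoes); requiring three consecutive helix windows
  suppresses these while real helices (≥ 6 residues) always provide them.
  Consequently strands shorter than 4 residues and helices shorter than 6
  are not detectable — an explicit trade-off.

Measured on the generator's families at σ = 0.3 Å: no fragmented elements,
2–8% missed elements (mostly short strands), ~1% spurious elements.

## Cross-annotation

The reference member is the one closest to the family's *consensus
architecture*, defined as the per-type upper-quartile element count (ties:
more elements, then smallest id). A maximum-count rule would systematically
select members with fragmented detections, and a modal-composition rule
fails when many members have deletions; the quartile resists both failure
modes, and a wrong reference is costly — it shifts the sequence-order
naming of the entire family.

Every other member is rigidly superposed onto the reference and matched by
order-preserving, type-constrained dynamic programming on SSE midpoint
distance (score `10 − d` Å, matches beyond 10 Å forbidden, gap penalty 0).
Because a plain all-Cα prefix superposition mis-registers members with
missing leading elements, several candidate superpositions are tried — the
prefix fit plus one per sequence shift of the SSE correspondence — each
refined once on its matched-SSE Cα, and the candidate with the best DP score
wins. Matched elements inherit the reference label; unmatched ones get fresh
labels suffixed with the member id, keeping labels globally unique.

## Sheets

Strands pair when the mean nearest-Cα distance (averaged over both
directions) is ≤ 5.5 Å — typical ladders sit at 4.8–5.0 Å. Pairing
components must be simple paths; β-barrels (cycles) and bifurcated sheets
(degree ≥ 3) are rejected with an error naming the strands rather than
approximated, since flattening them would silently misrepresent the
topology. The template places strands in path order at 4.8-unit spacing
(canonicalized to start at the end with the smaller label, so input order is
irrelevant), lengths proportional to residue counts (3.3 units/residue;
helices use 1.5), and direction signs propagated through the
parallel/antiparallel ladder orientations. The template is rigid: layout
only ever moves and rotates a sheet as a whole.

## The synthetic generator

`makeIdealHelix`/`makeIdealStrand` produce canonical traces;
`makeDomain` joins recipe elements with 3-residue coil linkers and emits
ground-truth ranges and labels (same naming convention as annotation);
`makeFamily` replicates a base domain with i.i.d. Gaussian coordinate
jitter and per-element deletions, with one RNG substream per member so
removing a member never shifts the others' noise.

Linkers deserve a note: a *straight* interpolated linker at ~3.3 Å per step
has d(i,i+2) ≈ 6.6 Å — exactly extended-strand geometry — so naive linkers
would be read (correctly!) as strands and merge into their neighbours. The
generator therefore builds linkers that are genuinely coil-like: a lateral
zigzag for long gaps, a bulged arc for short ones, and for mid-range gaps a
small penalty optimization that solves the three linker coordinates against
explicit constraints (consecutive steps in [2.87, 3.75] Å, every 2-chord
below 5.45 Å, every 3-chord outside [4.1, 6.05] Å). The defaults of
`familySpec` — 10 members, `jitterSigma = 0.3` Å, no deletions — are the
study conditions used throughout the tests and the acceptance script.

What the generator does **not** emulate: real side chains and
hydrogen-bonding (so detection cannot be benchmarked against DSSP-grade
assignments), sheet twist, structural rearrangements beyond rigid jitter,
alternate conformations, or chain breaks from missing density. Passing
tests therefore demonstrate correctness of the pipeline's geometry and
bookkeeping under controlled noise — not detection accuracy on experimental
coordinates, where the configurable windows may need re-fitting.

## Numerical and degenerate-input behavior

* Tie-breaks are lexicographic (labels, domain ids) everywhere; the
  pipeline is deterministic end to end, and identical configuration gives
  byte-identical JSON and SVG.
* A single-element domain is placed at the origin with zero stress; an
  SSE-free domain yields an empty diagram, which still renders as a valid
  empty SVG.
* Coincident points reject axis fitting and superposition with geometry
  errors; a superposition of a mirror image still returns a proper rotation
  (det = +1) with positive RMSD.
* Distances at PDB precision round-trip to 1e-3 Å; JSON files are written
  at full double precision and round-trip byte-identically.
* Angles live in [−π, π); the family overlay averages angles circularly
  (the mean of −170° and 170° is 180°, not 0°).

## Problem sizes

The shipped tests and the acceptance script use families of 10 members with
3–5 elements each, single domains of 5–10 elements, and 20 random domains
for the concordance study — comfortably representative of CATH-style domain
diagrams, where element counts rarely exceed ~20, while keeping a full run
in tens of seconds.

## Known limitations

* β-barrels and bifurcated sheets are rejected, not drawn.
* Helix subtypes (3₁₀, π) are not distinguished; hydrogen-bond-based
  assignment is out of scope.
* Connector routing is a single-offset polyline; crossings are not
  minimized.
* The overlap-reduction angle sweep is local (±15°) and cosmetic; severely
  crowded layouts can retain overlaps.
* Label recovery assumes family members share a common fold; the DP
  matcher is order-preserving, so circular permutants will not annotate
  consistently.
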