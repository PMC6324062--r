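---
title: "Analysing coarse-grained membrane-protein simulations with cgmem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing coarse-grained membrane-protein simulations with cgmem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgmem)
```

`cgmem` post-processes coarse-grained (MARTINI-style) snapshots of
membrane proteins in DPPC bilayers. This vignette explains the models and
procedures behind each stage, the tunable parameters and why their
defaults are what they are, what the synthetic-system generator does and
does not emulate, and the numerical and design choices that were
genuinely open.

## The frame model

A snapshot is a `cg_frame`: bead coordinates in Ångström, a chemical
class per bead (protein, choline, phosphate, glycerol, tail beads 1–4,
water, ion), residue/chain identity, and an orthorhombic box. Periodic
boundaries are applied laterally (x, y) only; z is the membrane normal
and treated as non-periodic, the standard membrane-simulation geometry.
GRO input (nm) is converted to Å on read because bilayer thicknesses are
conventionally quoted in Å. Lipids are grouped by
`(residue_name, residue_index)` — CG coordinate formats carry no bonds —
and each lipid must carry exactly one phosphate bead, the reference
point for every leaflet and thickness calculation. Triclinic boxes are
rejected explicitly: self-assembled systems are orthorhombic and the
minimum-image code stays simple. The classification table ships with
DPPC, water, ions and the twenty amino-acid residues, and is extensible
through a YAML config for other lipid species.

## Leaflet assignment and flip-flops

Leaflets are the two large connected components of a proximity graph
over phosphate beads (edge cutoff `leaflet_cutoff = 15` Å, roughly twice
the typical nearest-phosphate spacing at 64 Å² per lipid, so one leaflet
stays connected through packing fluctuations while 37 Å of bilayer keeps
the two leaflets apart). A plane-threshold rule would misassign lipids
wherever the protein bends the membrane; the graph rule follows the
deformation. UPPER is the component of greater mean z once the midplane
is centred at zero. Lipids in small satellite components — typically a
lipid caught mid-flip near the midplane — are attached to the large
component of their nearest phosphate neighbour. Anything other than
exactly two large components (≥ 5% of phosphates each) is a non-bilayer
state and raises a typed error; the pipeline converts it into a
structured failure record rather than a crash, since pre-assembly inputs
are expected in routine operation.

A flip-flop is a leaflet-label change that persists for
`persistence_frames = 5` consecutive frames. The persistence rule
separates genuine translocation from interdigitation flicker; a
single-frame excursion produces no event. The event records the first
frame showing the new label during the transition and the first frame of
its persistent run; for a clean instantaneous flip both are the flip
frame.

## Radial distribution and annular shells

For each lipid, r is the minimum-image distance from its phosphate bead
to the nearest protein bead. g(r) divides the count in each annulus by
the mean lateral phosphate density, so g → 1 far from the protein. For a
compact protein the annulus area πr² correction is exact per leaflet
(the leaflet-plane offset cancels in the Jacobian); residual deviations
at large r come from the finite, discrete system. Defaults:
`bin_width = 1` Å (below the bead diameter), `r_max = 40` Å (inside half
a typical box edge), moving-average smoothing over 3 bins before minima
are located. Shell boundaries are the first k local minima after the
first peak; the number of shells delineated is exposed as a parameter
(default 2) rather than fixed, because there is no canonical count — the
second boundary is what the surface stage uses to define "bulk".

## Membrane surfaces, thickness, deformation

Each leaflet surface is a Gaussian-weighted mean of its phosphate z
values over a lateral grid: `grid_spacing = 2` Å resolves per-residue
variation, and `surface_bandwidth = 5` Å (with support truncated at 3
bandwidths) guarantees several phosphates support each cell at typical
CG lipid densities; a cell with a single supporting phosphate takes that
phosphate's z exactly, and unsupported cells are NaN. Thickness is
phosphate-to-phosphate, upper minus lower per cell. Bulk thickness is
the mean over cells laterally farther from any protein bead than the
second annular shell boundary (fallback `r_bulk_fallback = 25` Å when no
RDF is available); if no cell qualifies, the farthest 25% of cells are
used and a warning raised. The deformation map is thickness minus bulk
thickness, so its mean over bulk cells is zero by construction.

Per-residue depth is the z offset of the residue position (backbone bead
where present, otherwise the bead centroid) from the local midplane at
the nearest defined grid cell; residues laterally outside all defined
cells fall back to the bulk thickness and are flagged.

## Contacts and residue environment

A contact is a protein-bead/non-protein-bead pair within
`cutoff = 6` Å — the common CG bead-contact convention; no published
value is canonical, so it is exposed as a parameter. Counting is per
bead pair, not per lipid: a lipid touching a residue through three beads
contributes three contacts, which is what per-bead-class sequence tracks
require. Counts accumulate over the supplied frames; both raw sums and
the number of frames analysed are stored so per-frame rates remain
derivable. The command-line pipeline defaults to the final 10% of
frames, approximating a post-assembly snapshot. Residue environment is
the argmax of summed head-group, acyl-tail and solvent counts, with zero
contacts labelled BURIED and ties resolved by the fixed precedence
HEADGROUP > ACYL_TAIL > SOLVENT. Ions are tracked separately from water
internally and merged into a single water+ion track for display.

## Topology

User-supplied secondary structure always takes precedence; geometric
assignment from backbone-bead virtual bonds is approximate by nature.
The geometric rule marks a window helical when the i→i+3 distance falls
in 4.2–6.0 Å (an ideal CG α-helix gives ≈ 5 Å) and requires two
consecutive agreeing windows, which prevents tight turns from reading as
helix; extended state needs i→i+2 ≥ 6.3 Å. Minimum segment lengths are
4 (helix) and 3 (strand).

A segment is transmembrane when its residues cross both leaflet
surfaces, evaluated at each residue's local surface height — not a
planar average — so deformed membranes are treated consistently with the
surface maps. Chains with a TM segment are MEMBRANE_SPANNING; otherwise
a chain is INTERFACIAL when ≥ 20% of residues sit within ±6 Å of the
half-thickness depth, else SOLUBLE. The interfacial band rule is this
package's documented choice; only the membrane-spanning class has an
established published convention.

2D diagrams project each segment into the plane spanned by the membrane
normal and the chain's dominant lateral direction (orientation PCA over
the TM segments, so one coherent diagram per chain). Helix backbones are
first averaged over about two helical turns to expose the helix axis;
terminal residue projections are pinned exactly. Each segment is fitted
by a least-squares clamped cubic B-spline — with a clamped knot vector
the endpoint constraint simply fixes the first and last coefficients, so
the constrained fit remains an ordinary least-squares problem and knot
refinement can only decrease the residual. Knots are inserted where the
local fit RMSD (5-residue window) exceeds `kink_tol = 2` Å; a gentle
kink is already representable by a single cubic within that tolerance,
so tests that require a knot to localize a planted kink tighten the
tolerance instead of the geometry. Segments under 4 residues fall back
to flagged polylines, and discontinuous loops are emitted as dashed
connections.

## Ensemble analyses

Member sequences are aligned with a built-in progressive
profile–profile aligner (affine-gap dynamic programming, BLOSUM62, gap
open −10, extend −0.5, neighbour-joining guide tree on pairwise
identity); an external MSA tool such as mafft can be plugged in through
a command adapter when fidelity at family scale matters. Per-residue
head/tail/solvent fractions, secondary structure and depth are carried
onto alignment columns; the consensus secondary structure is the modal
state over members present at a column, with the modal fraction as
conservation and the fraction of members without a gap as coverage.

The contact propensity scale interprets the "unbiased probability" as
residue-level incidence: p(aa, cat) is the fraction of residues of a
type, among those with at least one non-protein contact, that make at
least one contact in the category. Incidence keeps abundant residue
types from dominating; a count-share alternative is exposed as
`mode = "count_share"`. Normalization anchors glycine at 0 and the
maximum at 100; types less contact-prone than glycine are negative by
construction, and a collection where no type exceeds glycine is rejected
as degenerate.

Depth distributions use z′ = 2·depth/local thickness, putting the
phosphate surfaces at ±1 — the normalization convention is this
package's choice; only the fact of normalization is established.
Pore-inner residues are excluded by a concrete rule of our own: solvent
contacts, |z′| < 0.8, and a lateral position inside the convex hull of
the chain's TM-segment axes. Histograms run over z′ ∈ [−2, 2] in 0.1
bins; relative mode normalizes each amino-acid histogram to sum to 1.
Residue types are clustered by average-linkage hierarchical clustering
on the Jensen–Shannon distance between relative histograms, cut at 4
clusters by default (the hydrophobic-core / interfacial-aromatic /
basic / polar-solvent pattern); both the distance and the cluster count
are exposed because no published algorithm is specified for this step.
Input types are processed in alphabetical order, making merges
deterministic.

## The synthetic-system generator

`generate_fixture()` emulates a post-assembly snapshot: DPPC lipids on a
jittered lattice at 64 Å² per lipid (typical fluid-phase
phosphatidylcholine; lattice jitter 1 Å), two leaflets at a planted
phosphate-plane separation — 37 Å for the α-helical class, 33 Å for the
β-barrel class — an idealized helix bundle (default 7 helices, the
classic GPCR topology) or β-barrel spanning the bilayer, an annular ring
of lipids packed against the protein surface as self-assembly would
leave it, optional radial thinning (full depth within the stated range,
Gaussian shoulder beyond), planted flip-flops implemented by mirroring a
lipid through the midplane, and a coarse water lattice with a few ions
outside the membrane slab. Every planted quantity — leaflet labels,
flips, analytic surfaces, TM counts, per-residue environment bands — is
recorded as ground truth.

What the generator does **not** emulate: real lipid conformational
disorder (each lipid is a rigid template plus rigid-body noise),
protein side chains (backbone beads only), membrane undulations,
curvature, cholesterol or mixed lipid compositions, and any actual
dynamics or energetics. Tests passing on fixtures therefore demonstrate
that the analysis machinery recovers planted structure at realistic
densities and noise levels — not that the defaults are optimal for any
particular force field or lipid type.

`generate_cohort()` samples residue-level contact incidences from
per-amino-acid probability triples. The default triples are distinct
per type and chosen so nearly every sampled residue makes at least one
contact; since the propensity denominator conditions on having a
contact, this keeps the recovered probabilities close to the planted
marginals, which is what the parameter-recovery tests check.

## Problem sizes and determinism

The shipped tests and the acceptance script run at deliberately modest
scale: bilayers of 64–512 lipids, bundles of 1–7 helices, trajectories
of up to 100 frames, cohorts of 500–2000 residues per amino-acid type,
and brute-force oracles on systems of at most 500 beads. These sizes are
large enough for every planted quantity to be recovered at its stated
tolerance while keeping a full run in the order of seconds to minutes on
one CPU. All stochastic steps are seeded; identical seeds give
bitwise-identical fixture files and byte-identical analysis products.

## Known limitations

* Leaflet assignment requires phosphate-bearing lipids; cholesterol-like
  species are out of scope.
* Geometric secondary-structure assignment is approximate; supply an
  atomistic-derived assignment where available.
* The RDF normalization assumes a laterally homogeneous bulk; strongly
  phase-separated systems would violate it.
* Thickness is phosphate-to-phosphate by definition; hydrophobic
  thickness is not computed.
* The built-in aligner is progressive and greedy; for large diverse
  families use the mafft adapter.
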