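# cgmem

Post-processing of coarse-grained (MARTINI-style) molecular-dynamics
snapshots of membrane proteins embedded in phospholipid bilayers.

Membrane proteins sit in a dynamic lipid environment that structure
determination rarely resolves. Self-assembly simulations place a protein
structure in an explicit DPPC bilayer; the work then shifts to analysis:
which leaflet does each lipid belong to, which lipids flip between
leaflets, how are annular lipid shells arranged around the protein, how
does the protein deform the membrane, which residues touch head-groups,
acyl tails or solvent, and what does the transmembrane topology look
like. `cgmem` implements this per-structure analysis pipeline and the
ensemble analyses that aggregate it across many structures of a protein
or family. It is aimed at structural bioinformaticians and simulators who
have CG coordinate files (GRO/PDB) and want reproducible, scriptable
per-residue lipid-interaction annotation.

## Methods at a glance

* **Leaflets** — phosphate beads form a spatial proximity graph
  (minimum-image distances, 15 Å cutoff); its two large connected
  components are the leaflets, UPPER being the one of greater mean *z*
  after centring the bilayer midplane. A graph rule, unlike a plane
  threshold, follows curved and locally deformed bilayers.
* **Flip-flops** — a leaflet-label change that persists ≥ 5 frames;
  single-frame flickers are noise.
* **Annular shells** — *g(r)* of phosphates vs. distance to the nearest
  protein bead, normalized by the mean lateral phosphate density; shell
  boundaries are the smoothed local minima of *g*.
* **Surfaces and deformation** — per-leaflet *z*-surfaces are
  Gaussian-weighted means of phosphate *z* on a 2 Å lateral grid
  (bandwidth 5 Å). Thickness is phosphate-to-phosphate:
  *t*(x,y) = *z*<sub>up</sub> − *z*<sub>low</sub>; deformation is
  *t* − *t*<sub>bulk</sub>, with the bulk taken beyond the second annular
  shell.
* **Contacts** — bead pairs within 6 Å (minimum image), accumulated per
  residue and per lipid chemical group (choline, phosphate, glycerol,
  tail beads 1–4), water and ions; stacked head/tail/solvent fractions
  sum to 1.
* **Topology** — helices/strands from provided or geometric secondary
  structure; a segment is transmembrane when its residues cross both
  local leaflet surfaces. 2D diagrams use least-squares cubic B-splines
  with adaptive knot insertion so kinks survive.
* **Ensembles** — members are aligned (built-in progressive BLOSUM62
  aligner or mafft) and per-residue annotations aggregated by column;
  the amino-acid contact propensity scale is
  *s* = 100·(*p* − *p*<sub>Gly</sub>)/(max *p* − *p*<sub>Gly</sub>), so
  glycine is 0 and the most contact-prone type is 100; depth
  distributions use *z′* = 2·depth/thickness (phosphate surfaces at ±1)
  and are clustered by Jensen–Shannon distance.

A synthetic-system generator (`generate_fixture()`) builds bilayers,
helix bundles and β-barrels with planted ground truth, so the whole
pipeline is testable without any simulation data.

## Worked example

```r
library(cgmem)

# a GPCR-like 7-helix bundle in a 37 A DPPC bilayer, with ground truth
fx  <- generate_fixture(fixture_spec(protein = helix_bundle(), seed = 1))
res <- run_analyse(fx, "bundle_out")
res
#> <cgmem_analysis> status: ok (bundle_out)
#>   7 membrane spanning α helices

res$surfaces
#> <membrane_surfaces> 32 x 32 grid (2.00 A), bulk thickness 37.09 A
#> deformation range: [-2.03, 1.38] A

res$rdf
#> <cg_rdf> 32 bins to 32.0 A, 120 phosphates
#> shell boundaries (A): 7.5, 14.5
```

The chain summary counts seven membrane-spanning α-helices — the planted
GPCR topology. The recovered bulk thickness (37.09 Å) reproduces the
planted 37 Å phosphate-plane separation, and the first annular-shell
boundary at 7.5 Å delimits the ring of lipids packed against the protein
surface. `bundle_out/` contains the per-residue contact table
(`contacts.csv`), sequence-view tracks (`tracks.csv`), surface maps
(`surfaces.csv`/`.json`), the topology diagram (`topology_A.svg`) and a
run manifest.

The propensity scale on a synthetic cohort:

```r
ps <- contact_propensity_scale(generate_cohort(n_per_type = 500, seed = 1))
ps$s_head[ps$aa == "G"]   # 0    (glycine anchors the scale)
max(ps$s_head)            # 100  (most head-group-prone type)
```

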