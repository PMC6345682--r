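---
title: "Methods: comparative structural analysis of halophilic Xi-class glutathione transferases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative structural analysis of halophilic Xi-class glutathione transferases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halogst)
```

## Scope and scientific background

Glutathione transferases (GSTs) of the Xi class — glutathionyl-hydroquinone
reductases (GHRs) — carry a catalytic cysteine inside a strictly conserved
CPWA motif at the start of helix α2, in the thiol-cofactor binding site
(G-site) of the canonical GST fold (an N-terminal thioredoxin-like domain
plus a C-terminal all-helical domain). Haloalkaliphilic archaea add two
twists to this picture: their proteomes are strongly acidified, with
aspartate/glutamate enrichment spread over the protein surface as an
adaptation to molar salt, and they use the dipeptide
γ-glutamyl-cysteine (γ-Glu-Cys) instead of glutathione (GSH) as their
reducing thiol, since they lack a glutathione synthetase.

`halogst` packages the comparative analyses needed to characterize such an
enzyme against its mesophilic homologs:

1. **Structure bookkeeping** (`read_structure`, `missing_residues`): PDB
   parsing with first-class negative author residue numbers (His-tag
   constructs number the tag Met as −6 so the mature chain starts at 1),
   SEQRES-vs-modeled accounting, unit-cell capture.
2. **Superposition** (`align_sequences`, `kabsch`, `superpose_monomer`,
   `superpose_dimer`): sequence-alignment-driven rigid superposition of
   monomers and dimers with iterative outlier rejection, reporting RMSD over
   equivalent Cα atoms, the number of aligned residues, and sequence
   identity.
3. **Composition** (`composition_delta`): per-residue count differences and
   category summaries (acidic, basic, hydrophobic, glycine) between a
   halophilic query and a mesophilic reference.
4. **Surface** (`shrake_rupley`, `charge_evenness`, `coulomb_surface`):
   solvent accessibility, a permutation test quantifying whether charged
   residues are evenly spread over the surface, and a simplified Coulomb
   potential score.
5. **Ligand transplantation** (`transplant_ligand`, `truncate_gsh_to_gec`,
   `measure_distance`, `detect_clashes`): homology-based placement of GSH
   from a holo reference into an apo target, deletion of the glycyl moiety
   to model γ-Glu-Cys, and G-site distance / steric-clash measurement.
6. **Sequence features and phylogeny** (`scan_protein_motif`,
   `transfer_annotations`, `scan_restriction_sites`, `translate_orf`,
   `p_distance_matrix`, `nj_tree`, `bootstrap_support`).
7. **Synthetic data** (`make_helix_structure`, `make_transformed_copy`,
   `make_gsh_like_ligand`, `make_sequence_family`): fixtures with planted
   ground truth for every stage.

## Models and algorithms

### Rigid superposition

Residue pairing comes from a global Needleman–Wunsch alignment (BLOSUM62,
affine gap penalties 10/0.5) of the modeled chain sequences, restricted to
residues with a Cα atom. The Kabsch algorithm then gives the closed-form
least-squares rotation via SVD of the cross-covariance matrix, with the
reflection branch corrected so det(R) = +1. Structure-comparison tools
conventionally refine such fits by discarding poorly matching pairs;
we follow that convention: up to `cycles` (default 5) rounds discard pairs
whose deviation exceeds `reject_factor` (default 2.0) times the current
RMSD, and the fit is recomputed. Consequences worth knowing:

* `n_aligned + n_rejected` always equals the initial pair count;
* RMSD is monotonically non-increasing across cycles;
* the reported identity uses aligned non-gap columns as denominator — the
  convention most comparison tools print. Other denominators (shorter
  sequence length, alignment length) give systematically different numbers.

Dimer superposition evaluates both chain-to-chain assignments
(AB↔A′B′ and AB↔B′A′) as single concatenated point sets and reports the
lower-RMSD assignment. Residue pairing never crosses chains.

### Composition deltas

`composition_delta(q, r)` reports count(q) − count(r) per amino acid,
plus category sums with fixed membership: negative {D, E}, positive
{K, R, H} (histidine counted positive), hydrophobic {A, V, L, I, M, F, W},
and glycine alone. The deltas always sum to the length difference; the
reversed comparison is the elementwise negation.

### Solvent accessibility and surface statistics

SASA uses the Shrake–Rupley sphere-point method with a deterministic
golden-spiral point set (default 960 points/atom), probe radius 1.4 Å, and
van der Waals radii C 1.70, N 1.55, O 1.52, S 1.80 Å. Per-residue relative
accessibility divides by the theoretical Gly-X-Gly maxima (Tien et al.
2013) and is capped at 1 (isolated-atom toy structures can exceed the
all-atom maxima; the cap keeps thresholds meaningful). A residue is
"surface" at relative SASA ≥ 0.25. Because the point set is fixed in the
global frame, total SASA is invariant under rigid motion only up to
discretization error (≲0.5% at 960 points); the tests assert exactly that.

"Evenly distributed surface charge" is a visual claim in the halophile
literature; to make it testable this package defines its own statistic:
the mean nearest-neighbour distance among side-chain centroids of charged
surface residues, compared against a permutation null that reassigns the
charged labels uniformly among all surface residues. `p_clustered` is the
fraction of null draws with a statistic at most the observed one; small
values mean clustering, values near 1 mean hyper-uniform spreading. This
statistic and its null are this package's design, not a published method.

The Figure-style electrostatic surface is approximated by an unscreened
Coulomb sum q_j / d_ij over charged side-chain centroids (d capped at 1 Å;
charges −1 D/E, +1 K/R, +0.1 H). Only the sign pattern is meaningful; no
Poisson–Boltzmann solver is attempted.

### Ligand transplantation

The γ-Glu-Cys modeling procedure is a pure rigid transplant: superpose the
holo reference onto the apo target, apply the same transform to the GSH
heavy atoms, then delete the five glycyl atoms (N3, CA3, C3, O31, O32 in
the chemical-component naming). Nothing is rebuilt, renamed, or minimized —
deleting atoms is exactly what the modeling convention calls for, and
internal distances of surviving atoms are preserved to machine precision.
Deleting twice is an error, not a no-op. Distances use a small selection
grammar (`chain A and resi 57 and name SG`; `ligand and name SG2`);
"sulfhydryl" measurements use SG atoms with mode `min`. Clashes use the
strict criterion d < r_a + r_b − tolerance with tolerance 0.4 Å.

### Phylogeny

Distances are p-distances with pairwise gap deletion — a deliberate,
MEGA-compatible default, since distance-model choices are rarely printed in
methods sections; tree topology, not branch-length reproduction, is the
goal. Neighbor joining follows Saitou–Nei with two determinism rules:
Q-matrix ties break to the lowest (i, j) index pair, and a negative branch
estimate at a join is clamped to zero with the deficit moved to its sister
branch (preserving their sum; at the final three-way join negatives are
clamped without transfer). Bootstrap support resamples alignment columns
with replacement, rebuilds the tree per replicate, and scores each internal
branch of the full-data tree by its bipartition frequency — supports
annotate the original tree, not a consensus. Supports below the display
threshold (default 40%) are masked in newick/print output but retained in
the data.

### Sequence features

Motif scanning accepts literal residues and bracketed classes
(`CP[WFY][AS]`), reports 1-based positions (protein numbering must line up
with published residue numbers like Cys57; an `offset` parameter
accommodates tagged constructs), and finds overlapping hits. Restriction
scanning expands IUPAC codes and reports 0-based forward-strand offsets
(0-based because they feed slicing). ORF translation uses the standard
code, errors on internal stops, and warns on a missing start/stop.

## The synthetic world

All tests run offline on generated fixtures; their defaults state the world
the suite verifies:

* **Helices**: ideal α-helix Cα traces (rise 1.5 Å, 100°/residue, radius
  2.3 Å → 3.8 Å consecutive Cα spacing). Sufficient for superposition and
  centroid geometry; no side chains, no packing.
* **Planted transforms**: rotation/translation plus isotropic Gaussian
  coordinate noise. With σ = 0.5 Å per axis, the expected post-fit RMSD is
  √3·σ; Monte-Carlo recovery over 200 seeds must land within 5%.
* **GSH-like ligand**: the 20 heavy atoms of glutathione with
  chemical-component names and plausible bond lengths (1.2–1.8 Å along the
  tripeptide graph); geometry is schematic, not a crystal conformer.
* **Sequence families**: a root sequence evolved along a stated tree, per
  column, substituting to a uniform different residue with probability
  rate × branch length (capped at 0.75). A Jukes–Cantor-like toy model: no
  rate heterogeneity, no indels, no substitution matrix structure.

A green test on this world establishes algorithmic correctness (exact
recovery on additive matrices, calibrated type-I error, deterministic
output), not agreement with any published measurement. The published-value
criteria (monomer RMSD 1.31 Å vs the *E. coli* homolog, +12 Asp/+17 Glu,
the 2.9 Å/1.4 Å G-site distances, the 14/11 missing C-terminal residues)
require the real depositions; the acceptance tests run those computations
whenever the files are placed under `inst/extdata/real/` and fail loudly
in offline environments rather than pretending.

## Numerical and design choices

* **Altloc resolution**: highest occupancy wins; ties break to the
  lexicographically smallest altloc id. Deterministic and standard.
* **Residue ordering**: (resseq, icode) with blank icode before "A";
  negative resseq sorts naturally (His-tag Met(−6) precedes residue 1).
* **SEQRES gap placement**: the modeled sequence is embedded into SEQRES
  greedily left-to-right; with repeated residues the embedding is
  ambiguous and the leftmost is chosen. Gap segments are tagged
  N-terminal/internal/C-terminal by position.
* **Entry codes**: normalized case-insensitively with letter-O→digit-0
  correction (print typography regularly renders 4G0I as "4GOI"); the
  normalization is logged, never silent.
* **Permutation p-values** are plain null fractions (`mean(null <= obs)`),
  reproducible bit-exactly from (seed, n_perm); the RNG state of the caller
  is saved and restored.
* **Degenerate Kabsch input** (collinear points) is flagged, not errored:
  the rotation about the degenerate axis is arbitrary but the RMSD is
  still meaningful.

## Known limitations

* No electron-density, structure-factor, or refinement-statistics handling;
  the structural inputs are final models.
* The Coulomb score is not an electrostatics calculation; it has no
  dielectric, no screening, and arbitrary units.
* NJ branch lengths from non-additive matrices inherit the usual NJ
  distortions; only additive inputs are reconstructed exactly.
* The alignment-identity and rejection-cycle conventions were chosen to
  match common practice, but published tables rarely state their tool
  settings; small differences in n_aligned against any given publication
  are expected.
* Offline operation is a design constraint: nothing is fetched, and
  analyses of real depositions run only when the user supplies the files.
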