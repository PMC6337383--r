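---
title: "Methods: pose clustering, dynamic pharmacophores and screening analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pose clustering, dynamic pharmacophores and screening analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynophoreR)
```

## Scope and assumptions

This package implements the analysis layer of a structure-based
ligand-discovery campaign against an amino-acid transporter. The physical
engines are out of scope by design: homology models, docked poses, MD
trajectories, docking scores and conformer libraries are *inputs*, consumed
as SDF, (multi-model) PDB and CSV. Consequences of that boundary:

* Protonation states are taken as given in the input files; no pKa logic.
* Docking-internal energy terms are not reproduced; the per-residue energy
  decomposition targets *rank* agreement between residues, not absolute
  engine values.
* Conformer generation is upstream: a "molecule" in screening is a set of
  conformers sharing a name in the SDF.

Units are fixed package-wide: Å for coordinates and radii, kcal/mol for
energies, ps for time. Atom indices are 1-based (R convention) in every data
structure and in the pharmacophore JSON schema. Residue numbering is
preserved verbatim from the source PDB, and residues are reported in the
one-letter-plus-number convention ("F252"), because binding-site narratives
in this field are written in exactly those labels.

## Common scaffold clustering

Poses of a congeneric series share a core scaffold whose atoms are put in
correspondence by an explicit, ordered `scaffold_map` per ligand. The
dissimilarity between poses is the scaffold RMSD *without superposition* —
poses live in the shared receptor frame, so a rigid-body fit would erase
exactly the binding-mode differences being measured. Optional automorphism
lists handle graph symmetries of the core (the minimum over permutations is
taken); no symmetry is assumed by default.

Complete linkage was chosen (and is fixed at a 2.0 Å cut height) because it
bounds the cluster *diameter*: every pair of poses in a recovered cluster
deviates by less than the cutoff, which is the property a "common binding
mode" claim needs. Cut semantics are strict: merges at a height exactly
equal to the cutoff are not applied. Merge ties are broken by the
lexicographically lowest pair of smallest original member indices, making
the dendrogram deterministic; cluster ids are assigned by size descending,
then lowest member index.

A cluster is a *common scaffold cluster* (CSC) when it contains poses of at
least 4 distinct ligands (of 5 docked); everything else is residual. The
"pose closest to the centroid" is implemented as the **medoid** — the pose
minimizing mean scaffold RMSD to its cluster mates — because a coordinate
centroid of poses is not itself a pose; ties go to the lowest pose index.

## Interaction detection

The source campaign names its interaction channels but inherited the
geometric criteria from closed tools, so the criteria are fixed here from
common practice and exposed in one overridable `perception_rules()` object,
logged with every pipeline run:

| rule | default | notes |
|---|---|---|
| contact | 5.0 Å | proximity channel / exclusion-sphere candidates |
| H-bond | D···A ≤ 3.5 Å, ∠(D–H···A) ≥ 120° | distance-only when no explicit H (the PDB norm) |
| hydrophobic | ≤ 4.5 Å | between hydrophobic heavy atoms |
| halogen bond | X···A ≤ 3.8 Å, ∠(C–X···A) ≥ 140° | X ∈ {Cl, Br, I} |
| H feature pocket | ≥ 3 hydrophobic pocket atoms ≤ 5.0 Å of fragment centroid | |
| aromatic | ring-centroid distance ≤ 5.5 Å | |
| ionizable | complementary partner ≤ 5.0 Å | |
| exclusion spheres | radius 1.0 Å | at non-partner pocket heavy atoms within 5 Å |
| tolerance radii | 1.5 Å per feature kind | |

Hydrophobic typing: S, Cl, Br, I, and carbons whose bonded neighbours are
exclusively C/H/S/halogen. This deliberately makes aryl chlorines
hydrophobic-feature carriers, matching how halogenated inhibitors of this
transporter engage the hydrophobic sub-pocket while still being available
as halogen-bond donors. Proteins carry no bond table, so intra-residue
bonds are inferred from covalent distance (≤ 1.85 Å) and the same rule is
applied. Donor/acceptor roles: with explicit hydrogens, donors are N/O
bearing an H; without them, nitrogens with non-negative formal charge are
assumed protonated. Protein donors are nitrogens plus hydroxyl oxygens;
protein acceptors are oxygens. These are declared rules, not inferences —
SIFt/DIFt channels are only as sharp as their declarations.

The energy decomposition includes a residue when *any of its atoms* is
within 12 Å of the grid center (center-based, not ligand-distance-based),
uses vacuum dielectric (ε = 1) Coulomb with the constant
332.0636 kcal·Å/(mol·e²), and 4ε[(σ/r)¹² − (σ/r)⁶] with Lorentz–Berthelot
combining. Totals are exactly conserved against the unpartitioned
ligand-pocket double sum restricted to included residues.

## Per-frame pharmacophores and occupancy

A feature's identity across frames is its **signature**: kind plus sorted
generating ligand atom set. Signatures ignore direction vectors — direction
is a per-frame geometric annotation, not an identity criterion. Occupancy is
`100·count/n_frames`; frames in which nothing is perceivable still count in
the denominator (they are recorded as `NULL` models). The major/minor
threshold is 70%, the conventional boundary between persistent recognition
elements and transient contacts; it is a parameter everywhere.

Excluded-volume spheres mark positions sterically claimed by the pocket:
every protein heavy atom within the 5 Å contact shell that is *not* a
partner of an emitted feature becomes a 1.0 Å sphere. Partner atoms are
excluded so the sphere count measures feature-independent sterics; the
radius is a package choice (the source tool does not publish one).

RDF codes describe model geometry for clustering: for each unordered pair
of feature kinds (21 blocks), inter-feature distances enter a 0–20 Å
histogram with 0.5 Å bins and Gaussian smearing (σ = 0.5 Å); blocks are
L2-normalized individually and concatenated (840 values). The code is
invariant under rigid motion and feature reordering, and scale-sensitive.
Model similarity is the cosine of codes — a bounded similarity is what a
0.5 similarity cutoff presupposes — and clustering is average linkage on
1 − similarity, cut strictly below 0.5. Each cluster's representative model
(RPM) is its medoid; across several trajectories, medoids are deduplicated
by identical signature *sets* to form the distinct-model ensemble used for
common-hits screening.

## Screening

Matching enumerates kind-compatible injective correspondences between model
and conformer features of size n or n−1 (`max_omit = 1` reproduces the
n/n−1 hit rule). Before alignment, candidate pairs are pruned by pairwise
distance compatibility — |Δd| within the sum of the paired tolerance
radii — which is exact with respect to the subsequent acceptance test (a
correspondence violating it cannot place both features inside their
spheres); the test suite checks this against unpruned enumeration.
Accepted correspondences are aligned by Kabsch superposition (proper
rotations only; the exported `kabsch()` refuses collinear sets, while the
internal aligner also handles 1- and 2-point matches so n−1 matching of
3-feature models stays defined). An alignment is a hit when every matched
conformer feature lies inside its model feature's radius and no conformer
heavy atom falls strictly inside an exclusion sphere.

The fit score `10·N + 9·max(0, 1 − rmsd/r̄)` is a package definition (the
commercial score is undisclosed). Its shape is forced by the hit rule: the
feature-count term strictly dominates the geometric term, so an n-feature
match always outranks an (n−1)-feature match, and the geometric bonus only
orders matches of equal count. Direction vectors are ignored during
matching in this version (position spheres only); this is logged.
Common-hits ranking is hit count, then mean fit over hitting models — the
reference statistic is not published, so the choice is declared, not
asserted.

## Consensus, enrichment and efficiency metrics

Each of ChemPLP, GoldScore and fit is min–max normalized over the supplied
population and summed (range [0, 3]). A degenerate column (max = min)
contributes the neutral 0.5 to every record rather than 0 or 1, so an
uninformative score neither rewards nor punishes. AUC is the rank-sum
(Mann–Whitney) estimate with half-credit ties. RIE normalizes the mean
exponential rank weight of actives by its exact expectation under uniform
random ranks; α defaults to 20 (the reference value is unstated) and is a
flag. FQ divides the *unrounded* LE by the size-dependent scale
`LE_scale(HAC) = 0.0715 + 7.5328/HAC + 25.7079/HAC² − 361.4722/HAC³`;
feeding rounded LE instead reproduces none of the published table. The
published efficiency table is reproduced at 2 decimals for LE (all five
ligands), LLE (ligands 8 and 11) and FQ (ligands 8, 10, 11); the remaining
printed LLE/FQ entries differ from recomputation by 0.01 (consistent with
unrounded source potencies) and are deliberately not used as targets.

## The synthetic world

The generators state a world once; tests assert against its truth tables.

* **Pose ensembles** (`gen_pose_ensemble`): 5 ligands × 100 poses in 30
  planted clusters (12 common, 18 restricted to ≤ 3 ligands), mirroring the
  campaign's ensemble shape. Clusters are rigid placements of a 14-heavy-atom
  fused-bicyclic amino-acid scaffold (the parent ligand's HAC) on a 6 Å grid
  with random rotations; poses add isotropic N(0, 0.3 Å) jitter. 6 Å
  separation against 0.3 Å jitter and a 2.0 Å cutoff makes planted recovery
  exact rather than approximate — the test is of correctness, not luck; the
  generator warns when separation < 2·jitter.
* **Toy pocket** (`gen_toy_pocket`): residues placed so the planted ligand
  realizes exactly five hydrogen bonds at 2.9 Å (three donated by the
  ammonium, two accepted by the carboxylate), an aliphatic and an aromatic
  sub-pocket, and a remote glutamate/asparagine pair at 2.9 Å. The perceived
  model is 1 H + 1 AR + 1 HBD + 2 HBA. The aromatic ring sits 5.3 Å above
  the ligand ring plane: inside the 5.5 Å aromatic cutoff but with every
  ring carbon beyond the 5.0 Å hydrophobic-pocket shell, so the AR and H
  channels toggle independently.
* **Trajectories** (`gen_trajectory`): each frame jitters all coordinates
  (σ = 0.05 Å) and independently realizes each feature's geometric condition
  with its stated probability by displacing the partner atoms 3 Å outward
  ("off"). Defaults plant one clearly major (0.95), one borderline-major
  (0.75), one minor (0.40) feature and a 0.92-occupancy residue pair;
  10,000 frames at 2 ps spacing emulate a 20 ns production run. Because the
  toggles are geometric, recovered occupancies equal the truth table exactly
  and match the planted probabilities within binomial 3σ.
* **Score populations** (`gen_screening_population`): actives ~ N(δ, 1),
  decoys ~ N(0, 1), 97/5300 by default; E[AUC] = Φ(δ/√2), the closed form
  the enrichment tests check at δ = 1 (0.7602).
* **Decoy libraries** (`gen_decoy_library`): all-carbon chains that expose
  only hydrophobic features, a guaranteed-negative background for planted
  1-in-101 retrieval.

What a green test does **not** establish: the synthetic world has no
force-field physics, no correlated feature dynamics, no decoy property
matching, and pocket residues are minimal fragments. Green means the
*algorithms* are correct on data whose ground truth is known — it does not
re-derive the campaign's biological conclusions, whose headline numbers
(hit rates, IC50s, the specific AUC/RIE of the published models) depend on
commercial engines, undeposited structures and wet-lab assays.

## Numerical choices and edge cases

* Distance matrices are explicitly symmetrized ((D + Dᵀ)/2) before
  agglomeration so exact tie detection is immune to float asymmetry.
* `which.min` tie-breaking (lowest index) is relied on for medoids and is
  part of the documented contract.
* A single-feature model has no pair distances: its RDF code is a zero
  vector (with a warning) and is assigned cosine similarity 0 to everything.
* Degenerate Kabsch inputs (collinear, < 3 points) error in the exported
  function; the screening aligner falls back to principal-axis segment
  alignment, which is deterministic though roll-underdetermined.
* Empty perception (ligand far from pocket) is an error for a single frame
  and a counted `NULL` within a trajectory stream.
* Consensus on an empty record set, ROC with an empty class, RIE with all
  or no actives, Spearman on a constant vector: all are errors, not NAs.

## Pipeline defaults and the run log

Every stated constant is a named default materialized into the JSON-lines
run log: clustering height 2.0 Å, CSC rule 4-of-5, contact 5 Å, energy
radius 12 Å, one omitted feature, model similarity 0.5, major threshold
70%, RIE α 20. The pipeline's default trajectory length is 200 frames — a
desk-scale stand-in documented here; the 10,000-frame regime is exercised
by the acceptance suite. Re-running an identical config and seed reproduces
byte-identical artifacts; all generator randomness flows through explicit
seeds and restores the caller's RNG state.

## Known limitations

* No π-stacking geometry beyond centroid distance; no cation-π.
* SIFt/DIFt channels are declared rules, not a reproduction of any
  commercial tool's internals; absolute percentages will differ from tools
  with different criteria even on identical inputs.
* Feature directions are perceived but unused in matching (v1).
* MOL2/PDBQT, charge assignment and 2D depiction are out of scope;
  fingerprint *generation* (MACCS/ECFP/FP2) is delegated to external tools,
  only the Tanimoto comparison is provided.
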