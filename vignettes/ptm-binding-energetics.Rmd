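---
title: "Scoring PTM effects on protein-protein binding from MD-derived energies"
author: "ptmbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring PTM effects on protein-protein binding from MD-derived energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmbind)
```

## Scope and assumptions

`ptmbind` covers the analysis layer of an MD--MM/GBSA workflow for
predicting how acetylation and phosphorylation modulate protein-protein
binding. Upstream stages — structure preparation, modification of
coordinates, the MD runs themselves, and the per-snapshot generalized
Born energy evaluation — are out of scope; their outputs (per-snapshot,
per-role energy tables; per-residue decomposition tables; trajectories;
DSSP assignments; orthologue alignments) are this package's inputs.

Key modelling assumptions inherited from that workflow and kept here:

* **End-point energetics.** The binding free energy is the snapshot
  average of `G_complex − G_receptor − G_ligand`; unbound states are
  taken from the complex simulation, not from independent runs of the
  isolated components.
* **Entropy omitted.** The `−TS` term of the free-energy sum is absent
  by default (a conventional omission in end-point comparisons of
  closely related systems, where it largely cancels in ΔΔG). When a
  table carries a `ts` column it is subtracted.
* **Sign convention.** Negative ΔΔG_bind = stabilizing. The *sign* is
  the prediction; the magnitude is not interpreted quantitatively.
* **Single partition per evaluation.** For an *n*-meric complex, each
  subunit in turn is the ligand against the remainder as receptor
  (`partition_schemes()`), yielding *n* binding energies.

## Dataset curation

`evaluate_structure()` applies the selection rules for building a
simulatable dataset: no fusion chains, no engineered mutations, mean
crystallized percentage (construct vs. full protein) and mean resolved
percentage (resolved vs. construct) each at least 70 **per structure**
(a per-structure mean over chains, not a dataset-wide one — filtering is
a per-structure decision), X-ray resolution ≤ 3.0 Å ("3.0 or better",
hence inclusive; not applicable to NMR, and method `"other"` skips the
criterion with a warning), non-membrane, multimeric, and at least one
mapped modification site. Reason codes enumerate *every* failed
criterion so relaxing one threshold removes exactly one code.

`deduplicate_complexes()` identifies redundant depositions by the
multiset of protein accessions over chains (so a homodimer of P1 is a
different complex from a P1:P2 heterodimer). Ties in "better resolution"
are broken by higher mean resolved percentage, then by smallest
structure id — the ordering is a declared convention, since no published
tie-break exists for this situation.

The percentage-resolved denominator is the crystallized construct, not
the full protein: "resolved" means *not in gaps of the construct*, which
is only meaningful relative to what was crystallized.

## Energy bookkeeping

* `binding_energy()` — per-snapshot ΔG, mean, and SEM (sample sd/√n,
  n−1 denominator; absent for a single snapshot).
* `ddg()` — difference of means, classified by sign; its error is the
  root-sum-square of the two variant SEMs (a declared convention for the
  "local effects explain the overall effect" band below).
* `residue_contribution_delta()` — per-residue differences with the
  interface rule |Δ| **strictly** > 0.5 kcal/mol (the boundary value is
  not interface). Residues present in only one variant — possible when
  subunit gaps differ — contribute 0 in the missing variant and are
  flagged rather than dropped.
* `local_vs_global_gap()` — chain ΔΔG minus the summed per-site deltas.
  Within ±SEM of zero the local contributions explain the overall
  effect; otherwise the sign labels the long-range effect as
  destabilizing or stabilizing. Chains carrying no sites but a nonzero
  ΔΔG are pure long-range cases.
* `state_contribution_split()` — ΔG per molecular component
  (bound complex vs. unbound receptor/ligand), each expressed as a
  signed percentage of the sum of absolute ΔG values; the identity
  `ΔΔG_bind = ΔG_complex − ΔG_receptor − ΔG_ligand` is checked on every
  call.

Units are kcal/mol throughout. Table readers honour a `# units:` header
and refuse anything but kcal/mol rather than guessing a conversion.

## Conformational metrics

`kabsch_superpose()` implements SVD-based least-squares superposition
with the determinant correction, so a reflection is never returned even
for near-planar or mirror-image inputs; collinear point sets error out
(no unique rotation). RMSD is unweighted — mass weighting is a
reasonable alternative but the unweighted form is the declared
convention. `rmsd_series()` fits every frame to the reference before
measuring (an unfitted mode exists, mainly for tests).

`rmsd_auc_difference()` compares two deviation curves by trapezoid area
divided by duration — effectively the difference of time-averaged RMSDs,
robust to unequal sampling within a shared span.

`gromos_cluster()` is the greedy neighbor-counting algorithm: the frame
with the most neighbors within the cutoff becomes a cluster center,
center and neighbors are removed, repeat. The 0.25 cutoff is in **nm**
(2.5 Å), following the unit convention of the MD tooling this mirrors.
All ties (neighbor counts, cluster sizes) go to the lowest frame index,
making the partition deterministic. By default the trailing half of the
trajectory is clustered — matching the practice of clustering equally
spaced snapshots from the converged final segment of a production run —
and `frames`/`tail_fraction` make this configurable.

`periodic_image_min_distance()` checks all 26 neighbor translations of
an orthorhombic box. The violation threshold defaults to 12 Å, a typical
production nonbonded cutoff: closer approach means a molecule can
interact with its own image and its energies are unusable. No published
numeric threshold exists for this check; 12 Å is the package's declared
default.

## Conservation and taxonomy

Type-specific rules, applied in alignment-column space:

| modification | rule |
|---|---|
| acetyl-K | K at the site column or ±1 column |
| phospho-S/T | S **or** T at the exact column |
| phospho-Y | Y at the exact column |

The ±1 tolerance for acetylation reflects that a one-position shift
typically preserves the modifiable lysine's function; S and T are
interchangeable phospho-acceptors; tyrosine phosphorylation is scored
strictly. The denominator excludes the reference record (conservation is
asked *of the orthologues*), one alignment record counts once (paralog
duplicates are not collapsed — a declared convention), and fully gapped
orthologues count as non-conserving rather than being excluded.
Window columns outside the alignment never match.

`lowest_common_ancestor()` works on an explicit parent-pointer taxonomy
(buildable from Newick via `ape`), returning the deepest node ancestral
to every conserving taxon. DSSP codes are simplified as H/G/I → H,
E/B → E, S/T/C/`-` → C before placement analysis
(`simplify_secondary_structure()`, `ss_preference()`).

`conservation_ddg_correlation()` defaults to Pearson with a Spearman
option; the choice is genuinely open (no canonical statistic exists for
this comparison) and rank correlation is the robust alternative when
fractions pile up near 0/1.

## Effect-size statistics

`unpaired_t_test()` wraps the standard two-sided test; the default is
Student's pooled-variance variant, with Welch by flag (which of the two
an analysis used is often unstated — the package exposes both and
defaults to the pooled test). Degenerate zero-variance cases: both
groups constant and equal → p = 1 by convention; a single constant group
falls back to Welch, which remains defined. `cohens_d()` uses the pooled
(n−1) standard deviation and reports the absolute d alongside the signed
value; bands are the conventional 0.2/0.5/0.8 cuts with d > 0.8 large.

## The synthetic-data generator

The generator is first-class, tested code, not a fixture dump. One root
seed feeds named substreams (`.stream_seed`), so adding a generator
never perturbs another's draws and every output is byte-identical under
a fixed config.

What it emulates, and the defaults:

* **Effect structure** (`gen_energy_tables()`): each site draws a true
  local contribution from Normal(μ_type, σ_local) with μ_acetyl = −1.0,
  μ_pS = +1.5, μ_pT = μ_pY = +1.0 and σ_local = 0.5 kcal/mol — signs
  chosen so acetylation is net locally stabilizing and phosphorylation
  destabilizing (serine most strongly), the qualitative pattern the
  analysis is meant to recover; the magnitudes are round values giving
  ~98% sign agreement at σ = 0.5, not fits to any real distribution.
  Each complex draws a long-range term from Normal(0, 2.0) kcal/mol, of
  the same order as the local sums so both regimes of the local-vs-global
  comparison occur.
* **Exactness by construction.** Snapshot noise (sd 2.0 kcal/mol,
  100 snapshots) is de-meaned, so the mean ΔG difference between
  variants equals Σ(locals) + long-range *exactly*, making pipeline
  recovery errors attributable to the pipeline alone. The per-residue
  decompositions sum to the *local* part of the binding energy (baseline
  ΔG for the non-modified variant, plus site contributions for the
  modified one); the long-range term deliberately enters only the role
  energies, so the decomposition gap recovers it exactly.
* **Cohort size**: 40 dimers × 60-residue chains, 5 acetyl + 3 phospho
  sites each — 200 acetyl sites, enough that the mean recovered local
  effect has a ~0.035 kcal/mol standard error, comfortably inside the
  ±0.1 recovery bound used in the tests, while the whole cohort
  generates in seconds.
* **Trajectories** (`gen_trajectory_pair()`): an idealized Cα helix
  drifting along a fixed random per-atom field (2 Å) with Gaussian
  jitter (0.3 Å); the modified copy adds an independent per-atom field
  of magnitude δ (default 2 Å). Per-atom random fields are non-rigid, so
  superposition cannot remove them and representative-vs-representative
  RMSD grows monotonically with δ.
* **Alignments** (`gen_alignment_and_tree()`): 50 orthologues, per-site
  conservation probability 0.7, realized *exactly* per the type rules;
  all non-designated positions use an alphabet free of K/S/T/Y so
  conservation is never accidental and the ground-truth matrix is exact,
  not approximate. Reference gap columns are inserted to exercise
  ungapped-position bookkeeping. The taxonomy is a random binary tree
  over the orthologue taxa.

What the generator does **not** emulate — and hence what green tests do
not show about real data: physically realistic energy distributions and
their correlations between residues, force-field- or
conformation-dependent decomposition structure, sequence evolution
beyond per-site Bernoulli conservation, solvent, and real trajectory
kinetics. Passing tests demonstrate that the bookkeeping, classification
rules and statistics recover known ground truth under controlled noise;
they do not validate MM/GBSA itself.

## Numerical choices and degenerate inputs

* Superposition: SVD with determinant correction; symmetric to operand
  order at 1e-9; collinear inputs error.
* Clustering distances: pairwise fitted RMSD; cutoff comparisons use ≤.
* AUC: trapezoid rule; series must share their time span to 1e-9.
* Interface rule: strict inequality at 0.5 kcal/mol.
* SEM: n−1 variance, absent at n = 1; ΔΔG error: root-sum-square.
* State split: all-zero ΔG triple errors (`degenerate_split`) rather
  than returning 0/0.
* Correlation: constant margins error (`degenerate_correlation`).
* t test: zero-variance conventions as above.
* Tie-breaks everywhere are deterministic (lowest index / smallest id).

## Problem sizes used in the shipped checks

The test suite and acceptance script run entirely on synthetic data at
sizes chosen to exercise every property while generating in seconds: the
default 40-complex cohort (100 snapshots each) for effect recovery, a
50-orthologue × 200-site alignment for conservation recovery, 200
random 10-frame trajectories against the brute-force clustering oracle,
100 random taxonomies against the path-intersection LCA oracle, and
10,000 null replicates for the t-test calibration check. Published
cohort-scale statistics that depend on the original study's
supplementary data tables (chain-level effect sizes, representative-RMSD
exceedance counts) are not recomputable without those tables and are
surfaced as an explicitly failing check rather than silently skipped.

## Known limitations

* No mmCIF/PDB header parsing: curation metadata arrives as tables.
* Orthorhombic boxes only for the periodic-image check.
* No multiple-testing correction (none is part of the analysis design);
  users comparing many groups should correct downstream.
* The MMPBSA-dialect reader covers the common comma-separated
  `Residue,...,TOTAL` layout only.
* Residue-number mapping between structures and protein sequences must
  be supplied explicitly (`residue_map()`); no SIFTS-style inference is
  attempted, because silent off-by-one mapping errors are worse than a
  required input.
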