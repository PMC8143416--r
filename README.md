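# ptmbind

Quantifying how post-translational modifications (PTMs) — lysine
acetylation and serine/threonine/tyrosine phosphorylation — affect the
stability of protein–protein interactions, starting from molecular
dynamics (MD) derived energy data.

It is written for structural bioinformaticians who run end-point
MM/GBSA free-energy workflows over cohorts of modified vs. non-modified
protein complexes and need the downstream bookkeeping done reproducibly:
dataset curation, site mapping, ΔΔG accounting, per-residue
decomposition, conformational-change metrics and conservation scoring.
The package does **not** run MD or evaluate force-field energies; those
stages produce its inputs.

## The model

For each conformational snapshot, the free energy of a molecular species
is the MM/GBSA sum

```
G = E_bonded + E_electrostatic + E_vdW + G_polar + G_nonpolar − TS
```

(the entropy term TS is routinely omitted). The binding free energy of a
ligand subunit to the receptor (the rest of the complex) is the snapshot
average

```
ΔG_bind = ⟨ G_complex − G_receptor − G_ligand ⟩
```

and the effect of introducing modifications is

```
ΔΔG_bind = ΔG_bind(modified) − ΔG_bind(non-modified)
```

with negative ΔΔG_bind meaning the PTMs stabilize binding. Per-residue
decomposition of ΔΔG_bind yields local contributions; a residue with
|ΔΔG_bind,contribution| > 0.5 kcal/mol is classified as
interface-located. The gap between a chain's overall ΔΔG_bind and the
sum of its per-site local contributions measures long-range (allosteric)
effects. Conformational change is quantified by superposition RMSD
against the initial structure, the time-normalized difference of areas
under RMSD curves, and RMSD between representatives of the largest
gromos clusters (greedy neighbor-counting, 0.25 nm cutoff). Site
conservation is scored across orthologue alignments with type-specific
rules (lysine acetylation: K within ±1 alignment column; S/T
phosphosites: S or T at the exact column; Y phosphosites: strict), and
the lowest common ancestor of the conserving taxa localizes how widely a
prediction transfers.

Because cohort-scale MD is not reproducible at desk scale, the package
ships a seed-deterministic synthetic-data generator
(`generator_config()`, `gen_*()`) that emulates every input with known
ground truth — true local effects per site, chain-level long-range
terms, conservation probabilities, trajectory divergence — so the whole
pipeline is testable end to end.

## Worked example

```r
library(ptmbind)
cfg <- generator_config(seed = 42)
cx  <- gen_energy_tables(cfg, "CPX001")   # one synthetic dimer, both variants

be_mod    <- binding_energy(cx$snapshots_mod)
be_nonmod <- binding_energy(cx$snapshots_nonmod)
eff <- ddg(be_mod, be_nonmod)

rd  <- residue_contribution_delta(cx$decomp_mod, cx$decomp_nonmod)
gap <- local_vs_global_gap(eff$ddg_bind, rd$delta, eff$sem)

cat(sprintf("dG_bind (modified):     %.2f +/- %.2f kcal/mol\n", be_mod$dg_bind, be_mod$sem),
    sprintf("dG_bind (non-modified): %.2f +/- %.2f kcal/mol\n", be_nonmod$dg_bind, be_nonmod$sem),
    sprintf("ddG_bind = %.2f kcal/mol (%s)\n", eff$ddg_bind, eff$effect),
    sprintf("interface residues (|delta| > 0.5 kcal/mol): %d\n", sum(rd$interface)),
    sprintf("long-range gap = %.2f kcal/mol (%s)\n", gap$gap, gap$classification),
    sprintf("true long-range term  = %.2f kcal/mol\n", cx$truth$long_range), sep = "")
```

which prints:

```
dG_bind (modified):     -26.30 +/- 0.31 kcal/mol
dG_bind (non-modified): -26.68 +/- 0.38 kcal/mol
ddG_bind = 0.38 kcal/mol (destabilizing)
interface residues (|delta| > 0.5 kcal/mol): 7
long-range gap = 1.35 kcal/mol (long_range_destabilizing)
true long-range term  = 1.35 kcal/mol
```

The modifications destabilize this complex's binding by 0.38 kcal/mol
overall; 7 residues change their binding contribution by more than the
0.5 kcal/mol interface threshold, and the +1.35 kcal/mol gap between the
chain-level ΔΔG_bind and the summed local contributions is recovered
exactly from the generator's ground-truth long-range term. Conservation
works the same way:

```r
at   <- gen_alignment_and_tree(generator_config(seed = 42, n_orthologs = 20,
                                                n_align_sites = 4))
s1   <- at$sites[1, ]
cons <- conservation_fraction(at$alignment, s1$position, s1$ptm_type, s1$residue)
cat(sprintf("site %s%d conservation: %.2f (%d orthologues)\n",
            s1$residue, s1$position, cons$fraction, cons$n_orthologs),
    sprintf("LCA of conserving taxa: %s\n",
            lowest_common_ancestor(at$tree, cons$conserving_taxa)), sep = "")
```

```
site K3 conservation: 0.80 (20 orthologues)
LCA of conserving taxa: node1
```

See `vignettes/ptm-binding-energetics.Rmd` for the full account of the
methods, parameters and design choices.

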