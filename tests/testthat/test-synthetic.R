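test_that("generators are pure functions of the config seed", {
  cfg <- generator_config(seed = 17, n_snapshots = 20, n_frames = 6,
                          n_traj_residues = 8, n_orthologs = 10,
                          n_align_sites = 4)
  expect_identical(gen_ptm_table(cfg), gen_ptm_table(cfg))
  expect_identical(gen_energy_tables(cfg), gen_energy_tables(cfg))
  expect_identical(gen_trajectory_pair(cfg), gen_trajectory_pair(cfg))
  expect_identical(gen_alignment_and_tree(cfg), gen_alignment_and_tree(cfg))
  # a different seed changes the draws
  expect_false(identical(gen_energy_tables(cfg),
                         gen_energy_tables(generator_config(seed = 18,
                                                            n_snapshots = 20))))
})

test_that("curation fixtures carry their own expected decisions", {
  fx <- gen_curation_fixtures(generator_config(seed = 1))
  for (i in seq_along(fx$structures)) {
    s <- fx$structures[[i]]
    exp_row <- fx$expected[fx$expected$structure_id == s$structure_id, ]
    dec <- evaluate_structure(s, fx$ptm_mapped[[s$structure_id]])
    expect_equal(dec$kept, exp_row$kept, info = s$structure_id)
    if (!exp_row$kept) {
      expect_identical(dec$reasons, exp_row$reason, info = s$structure_id)
    }
  }
  # duplicate pairs shrink by exactly the number of duplicates
  kept <- Filter(function(s)
    evaluate_structure(s, fx$ptm_mapped[[s$structure_id]])$kept,
    fx$structures)
  dedup <- deduplicate_complexes(kept)
  drop_ids <- fx$expected$structure_id[fx$expected$tag == "dup_drop"]
  expect_equal(length(dedup), length(kept) - length(drop_ids))
  expect_false(any(drop_ids %in% vapply(dedup, `[[`, "", "structure_id")))
})

test_that("generated site tables respect densities and flag corrupt rows", {
  cfg <- generator_config(seed = 23)
  pt <- gen_ptm_table(cfg)
  out <- validate_sites(pt$sites, pt$sequences)
  # exactly the deliberately corrupted rows are rejected
  expect_equal(sort(as.integer(rownames(out$rejected))),
               sort(pt$truth$invalid_rows))
  expect_true(all(out$rejected$reason == "residue_mismatch"))

  # density 0 produces no genuine sites
  none <- gen_ptm_table(generator_config(seed = 23, acetyl_density = 0,
                                         phospho_density = 0, n_invalid = 0))
  expect_equal(nrow(none$sites), 0L)

  # acetylation density 1 saturates every lysine
  sat <- gen_ptm_table(generator_config(seed = 23, acetyl_density = 1,
                                        phospho_density = 0, n_invalid = 0),
                       n_proteins = 2L)
  for (acc in names(sat$sequences)) {
    kpos <- which(strsplit(sat$sequences[[acc]], "")[[1]] == "K")
    got <- sort(sat$sites$position[sat$sites$protein_accession == acc])
    expect_equal(got, kpos)
  }
  # acetylation is only ever generated under normal conditions
  expect_true(all(pt$sites$condition[pt$sites$ptm_type == "acetylation"] ==
                    "normal"))
})

test_that("energy tables encode the ground-truth effects exactly", {
  # noise-free limit: ddG equals the sum of the type means
  cfg0 <- generator_config(seed = 29, sigma_local = 0, sigma_longrange = 0,
                           snapshot_noise_sd = 0, n_snapshots = 10)
  g0 <- gen_energy_tables(cfg0)
  d0 <- ddg(binding_energy(g0$snapshots_mod),
            binding_energy(g0$snapshots_nonmod))
  mu <- ifelse(g0$sites$ptm_type == "acetylation", cfg0$mu_acetyl,
               ifelse(g0$sites$residue == "S", cfg0$mu_phospho_S,
                      ifelse(g0$sites$residue == "T", cfg0$mu_phospho_T,
                             cfg0$mu_phospho_Y)))
  expect_equal(d0$ddg_bind, sum(mu), tolerance = 1e-9)

  # with noise, the de-meaned construction keeps the mean difference exact
  cfg <- generator_config(seed = 29, n_snapshots = 50)
  g <- gen_energy_tables(cfg)
  bem <- binding_energy(g$snapshots_mod)
  ben <- binding_energy(g$snapshots_nonmod)
  expect_equal(ddg(bem, ben)$ddg_bind, g$truth$ddg_true, tolerance = 1e-8)

  # decompositions sum to the local part of the binding energy
  expect_equal(sum(g$decomp_nonmod$contribution), g$truth$dg0,
               tolerance = 1e-9)
  expect_equal(sum(g$decomp_mod$contribution),
               g$truth$dg0 + sum(g$truth$locals), tolerance = 1e-9)

  # per-site deltas recover the true local contributions; the chain-level
  # gap recovers the long-range term
  rd <- residue_contribution_delta(g$decomp_mod, g$decomp_nonmod)
  key <- paste(rd$chain, rd$resnum)
  skey <- paste(g$sites$chain, g$sites$resnum)
  expect_equal(rd$delta[match(skey, key)], g$truth$locals, tolerance = 1e-9)
  expect_equal(sum(rd$delta), sum(g$truth$locals), tolerance = 1e-9)
  gap <- local_vs_global_gap(ddg(bem, ben)$ddg_bind, rd$delta,
                             sem = ddg(bem, ben)$sem)
  expect_equal(gap$gap, g$truth$long_range, tolerance = 1e-7)
})

test_that("trajectory pairs diverge by the configured amount", {
  # no divergence and no jitter collapses the representative RMSD to zero
  cfg0 <- generator_config(seed = 31, n_frames = 10, n_traj_residues = 10,
                           jitter_sd = 0, delta = 0)
  tp0 <- gen_trajectory_pair(cfg0)
  r0 <- kabsch_superpose(tp0$nonmod$frames[[10]], tp0$mod$frames[[10]])$rmsd
  expect_equal(r0, 0, tolerance = 1e-9)

  # representative-vs-representative RMSD grows with the divergence delta
  cfg <- generator_config(seed = 31, n_frames = 30, n_traj_residues = 15,
                          jitter_sd = 0.2)
  deltas <- 1:10
  reps <- vapply(deltas, function(d) {
    tp <- gen_trajectory_pair(cfg, delta = d)
    cn <- cluster_representative(gromos_cluster(tp$nonmod))
    cm <- cluster_representative(gromos_cluster(tp$mod))
    kabsch_superpose(tp$nonmod$frames[[cn]], tp$mod$frames[[cm]])$rmsd
  }, numeric(1))
  expect_gt(cor(deltas, reps, method = "spearman"), 0.9)
})

test_that("synthetic alignments realize the conservation ground truth exactly", {
  cfg <- generator_config(seed = 37, n_orthologs = 20, n_align_sites = 6)
  at <- gen_alignment_and_tree(cfg)
  for (s in seq_len(nrow(at$sites))) {
    out <- conservation_fraction(at$alignment, at$sites$position[s],
                                 at$sites$ptm_type[s], at$sites$residue[s])
    expect_equal(out$fraction, mean(at$truth$conserved[, s]))
    expect_equal(out$column, at$sites$column[s])
  }
  # saturation in both directions
  all1 <- gen_alignment_and_tree(generator_config(seed = 37, p_conserve = 1,
                                                  n_orthologs = 10,
                                                  n_align_sites = 4))
  for (s in seq_len(nrow(all1$sites))) {
    expect_equal(conservation_fraction(all1$alignment, all1$sites$position[s],
                                       all1$sites$ptm_type[s],
                                       all1$sites$residue[s])$fraction, 1)
  }
  all0 <- gen_alignment_and_tree(generator_config(seed = 37, p_conserve = 0,
                                                  n_orthologs = 10,
                                                  n_align_sites = 4))
  for (s in seq_len(nrow(all0$sites))) {
    expect_equal(conservation_fraction(all0$alignment, all0$sites$position[s],
                                       all0$sites$ptm_type[s],
                                       all0$sites$residue[s])$fraction, 0)
  }
  # every ortholog taxon is a leaf of the attached taxonomy
  expect_true(all(at$alignment$taxon_id[-1] %in% at$tree$id))
})

test_that("a full fixture cohort round-trips through the writers", {
  cfg <- generator_config(seed = 41, n_complexes = 2, n_snapshots = 10,
                          n_frames = 4, n_traj_residues = 6,
                          n_orthologs = 6, n_align_sites = 3)
  dir <- withr::local_tempdir()
  write_synthetic_cohort(cfg, dir)
  expect_true(file.exists(file.path(dir, "structures.tsv")))
  expect_true(file.exists(file.path(dir, "CPX002_mod_energies.tsv")))
  snaps <- read_snapshot_energies(file.path(dir, "CPX001_mod_energies.tsv"))
  expect_s3_class(snaps, "data.frame")
  expect_equal(binding_energy(snaps)$n_snapshots, 10L)
  aln <- read_alignment(file.path(dir, "alignment.fasta"), reference = "REF")
  expect_equal(length(aln$sequence), 7L)
  tr <- read_taxonomy(file.path(dir, "taxonomy.nwk"))
  expect_true(all(aln$taxon_id[-1] %in% tr$id))
})
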