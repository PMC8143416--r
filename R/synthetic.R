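#' Configuration for the synthetic-data generators
#'
#' Bundles every knob of the synthetic cohort: dataset sizes, true effect
#' sizes of each modification type on local binding contributions
#' (kcal/mol), chain-level long-range effect spread, snapshot noise,
#' alignment/taxonomy shape and trajectory drift. One root seed drives all
#' generators through named substreams, so adding a generator never
#' perturbs another one's draws.
#'
#' Default effect directions emulate the observed pattern that lysine
#' acetylation tends to contribute to binding in a locally stabilizing way
#' (negative mean) while phosphorylation is locally destabilizing
#' (positive means), with serine phosphosites the most destabilizing.
#'
#' @param seed Root integer seed.
#' @param n_complexes Number of complexes in the cohort.
#' @param chain_length Residues per chain (dimers).
#' @param n_acetyl_sites,n_phospho_sites Modification sites per complex.
#' @param acetyl_density,phospho_density Per-residue modification
#'   probabilities used by [gen_ptm_table()].
#' @param n_invalid Deliberately corrupted rows added by
#'   [gen_ptm_table()].
#' @param mu_acetyl,mu_phospho_S,mu_phospho_T,mu_phospho_Y True mean local
#'   contribution change per site type (kcal/mol).
#' @param sigma_local Spread of true local contributions (kcal/mol).
#' @param sigma_longrange Spread of the chain-level long-range term
#'   (kcal/mol).
#' @param n_snapshots Snapshots per energy table.
#' @param snapshot_noise_sd Per-snapshot noise on role energies
#'   (kcal/mol).
#' @param n_orthologs,p_conserve,n_align_sites Alignment shape:
#'   orthologue rows, per-orthologue conservation probability, number of
#'   modification-site columns.
#' @param n_frames,n_traj_residues,drift_mag,delta,jitter_sd Trajectory
#'   shape: frames, helix length (C-alpha atoms), shared drift magnitude
#'   (Angstrom), extra divergence of the modified endpoint (Angstrom), and
#'   per-coordinate jitter sd (Angstrom).
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_complexes = 40L,
                             chain_length = 60L,
                             n_acetyl_sites = 5L,
                             n_phospho_sites = 3L,
                             acetyl_density = 0.3,
                             phospho_density = 0.2,
                             n_invalid = 3L,
                             mu_acetyl = -1.0,
                             mu_phospho_S = 1.5,
                             mu_phospho_T = 1.0,
                             mu_phospho_Y = 1.0,
                             sigma_local = 0.5,
                             sigma_longrange = 2.0,
                             n_snapshots = 100L,
                             snapshot_noise_sd = 2.0,
                             n_orthologs = 50L,
                             p_conserve = 0.7,
                             n_align_sites = 10L,
                             n_frames = 50L,
                             n_traj_residues = 20L,
                             drift_mag = 2.0,
                             delta = 2.0,
                             jitter_sd = 0.3) {
  cfg <- as.list(environment())
  stopifnot(cfg$sigma_local >= 0, cfg$sigma_longrange >= 0,
            cfg$snapshot_noise_sd >= 0, cfg$jitter_sd >= 0,
            cfg$p_conserve >= 0, cfg$p_conserve <= 1,
            cfg$acetyl_density >= 0, cfg$acetyl_density <= 1,
            cfg$phospho_density >= 0, cfg$phospho_density <= 1)
  structure(cfg, class = "generator_config")
}

# deterministic substream seed below 2^31, derived from root seed + name
.stream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(as.numeric(seed)) * 1009 + h) %% 2147483647)
}

.with_stream <- function(config, name, code) {
  withr::with_seed(.stream_seed(config$seed, name), code)
}

# amino-acid alphabet free of modifiable residues, so conservation and
# site placement are never accidental
.safe_alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M",
                    "N", "P", "Q", "R", "V", "W")

#' Curation fixtures with attached expected decisions
#'
#' Builds a deterministic set of structure records: one passing every
#' criterion, one failing each single criterion, an NMR structure (which
#' skips the resolution criterion), and duplicate complex identities
#' exercising both deduplication tie-breaks.
#'
#' @param config [generator_config()] (only the seed is used; the fixture
#'   set itself is fixed by construction).
#' @return List with `structures` (list of [structure_meta()]),
#'   `ptm_mapped` (named logical per structure) and `expected` (data frame
#'   `structure_id`, `tag`, `kept`, `reason`).
#' @export
gen_curation_fixtures <- function(config = generator_config()) {
  ch <- function(id, acc, full = 100, cryst = 90, res = 85,
                 fusion = FALSE, mut = FALSE) {
    chain_meta(id, acc, full_length = full, n_crystallized = cryst,
               n_resolved = res, is_fusion = fusion,
               has_engineered_mutations = mut)
  }
  dimer <- function(...) list(ch("A", "P1", ...), ch("B", "P2", ...))
  s <- list(
    structure_meta("PASS1", "xray", 2.0, FALSE, dimer()),
    structure_meta("FAILRES", "xray", 3.2, FALSE, dimer()),
    structure_meta("FAILFUS", "xray", 2.0, FALSE,
                   list(ch("A", "P1", fusion = TRUE), ch("B", "P2"))),
    structure_meta("FAILMUT", "xray", 2.0, FALSE,
                   list(ch("A", "P1", mut = TRUE), ch("B", "P2"))),
    structure_meta("FAILCRY", "xray", 2.0, FALSE,
                   list(ch("A", "P1", cryst = 60, res = 55),
                        ch("B", "P2", cryst = 60, res = 55))),
    structure_meta("FAILRSV", "xray", 2.0, FALSE,
                   list(ch("A", "P1", cryst = 90, res = 50),
                        ch("B", "P2", cryst = 90, res = 50))),
    structure_meta("FAILMEM", "xray", 2.0, TRUE, dimer()),
    structure_meta("FAILMON", "xray", 2.0, FALSE, list(ch("A", "P1"))),
    structure_meta("FAILPTM", "xray", 2.0, FALSE, dimer()),
    structure_meta("NMR1", "nmr", NA, FALSE,
                   list(ch("A", "P8"), ch("B", "P9"))),
    # duplicate pair resolved by resolution
    structure_meta("DUPA1", "xray", 2.0, FALSE,
                   list(ch("A", "P3"), ch("B", "P4"))),
    structure_meta("DUPA2", "xray", 2.5, FALSE,
                   list(ch("A", "P3"), ch("B", "P4"))),
    # duplicate pair resolved by resolved-percentage tie-break
    structure_meta("DUPB1", "xray", 2.2, FALSE,
                   list(ch("A", "P5", res = 83), ch("B", "P6", res = 83))),
    structure_meta("DUPB2", "xray", 2.2, FALSE,
                   list(ch("A", "P5", res = 79), ch("B", "P6", res = 79)))
  )
  ids <- vapply(s, `[[`, character(1), "structure_id")
  ptm_mapped <- stats::setNames(ids != "FAILPTM", ids)
  expected <- data.frame(
    structure_id = ids,
    tag = c("pass", "fail_resolution", "fail_fusion", "fail_mutations",
            "fail_pct_crystallized", "fail_pct_resolved", "fail_membrane",
            "fail_monomer", "fail_no_ptm", "pass_nmr",
            "dup_keep", "dup_drop", "dup_keep", "dup_drop"),
    kept = !(ids %in% c("FAILRES", "FAILFUS", "FAILMUT", "FAILCRY",
                        "FAILRSV", "FAILMEM", "FAILMON", "FAILPTM")),
    reason = c("", "resolution", "fusion", "engineered_mutations",
               "pct_crystallized", "pct_resolved", "membrane", "monomer",
               "no_mapped_ptm", "", "", "", "", ""),
    stringsAsFactors = FALSE)
  list(structures = s, ptm_mapped = ptm_mapped, expected = expected)
}

#' Synthetic modification-site table with sequences and ground truth
#'
#' Draws protein sequences over an alphabet that also contains K/S/T/Y,
#' modifies each lysine with probability `acetyl_density` (normal
#' conditions; acetylation is not generated under stress, mirroring its
#' absence there) and each S/T/Y with probability `phospho_density`
#' (condition drawn uniformly), then appends `n_invalid` corrupted rows
#' whose recorded residue disagrees with the sequence.
#'
#' @param config [generator_config()].
#' @param n_proteins Number of sequences.
#' @return List with `sites`, `sequences` (named character) and `truth`
#'   (`invalid_rows`: indices into `sites` of the corrupted rows).
#' @export
gen_ptm_table <- function(config = generator_config(), n_proteins = 6L) {
  .with_stream(config, "ptm_table", {
    L <- config$chain_length
    alphabet <- c(.safe_alphabet, "K", "S", "T", "Y")
    sequences <- stats::setNames(vapply(seq_len(n_proteins), function(i)
      paste(sample(alphabet, L, replace = TRUE), collapse = ""),
      character(1)), paste0("P", seq_len(n_proteins)))
    rows <- list()
    for (acc in names(sequences)) {
      chars <- strsplit(sequences[[acc]], "")[[1L]]
      for (pos in which(chars == "K")) {
        if (stats::runif(1) < config$acetyl_density) {
          rows[[length(rows) + 1L]] <- ptm_sites(acc, pos, "K",
                                                 "acetylation", "normal",
                                                 "synthetic")
        }
      }
      for (pos in which(chars %in% c("S", "T", "Y"))) {
        if (stats::runif(1) < config$phospho_density) {
          cond <- sample(c("normal", "stress"), 1L)
          rows[[length(rows) + 1L]] <- ptm_sites(acc, pos, chars[pos],
                                                 "phosphorylation", cond,
                                                 "synthetic")
        }
      }
    }
    sites <- if (length(rows)) do.call(rbind, rows) else
      ptm_sites(character(0), integer(0), character(0), character(0),
                character(0))
    invalid_rows <- integer(0)
    if (config$n_invalid > 0 && n_proteins > 0) {
      for (k in seq_len(config$n_invalid)) {
        acc <- sample(names(sequences), 1L)
        chars <- strsplit(sequences[[acc]], "")[[1L]]
        pos <- sample(which(!chars %in% c("K", "S", "T", "Y")), 1L)
        bad <- ptm_sites(acc, pos, sample(c("K", "S"), 1L),
                         "acetylation", "normal", "synthetic_invalid")
        bad$ptm_type <- ifelse(bad$residue == "K", "acetylation",
                               "phosphorylation")
        sites <- rbind(sites, bad)
        invalid_rows <- c(invalid_rows, nrow(sites))
      }
    }
    rownames(sites) <- NULL
    list(sites = sites, sequences = sequences,
         truth = list(invalid_rows = invalid_rows))
  })
}

# split a vector of role totals into the five MM/GBSA components
.split_components <- function(total) {
  f <- c(e_bonded = 0.05, e_electrostatic = 0.45, e_vdw = 0.25,
         g_polar = 0.20, g_nonpolar = 0.05)
  out <- as.data.frame(outer(total, f))
  names(out) <- names(f)
  out
}

#' Synthetic snapshot energies and decompositions for one complex
#'
#' Constructs a dimer (chains A and B, chain B the ligand) with
#' modification sites whose true local contributions are drawn from
#' `Normal(mu_type, sigma_local)` and a chain-level long-range term drawn
#' from `Normal(0, sigma_longrange)`. Per-snapshot role energies are built
#' so that the mean per-snapshot binding-energy difference between the
#' modified and non-modified variant equals the sum of true local
#' contributions plus the long-range term exactly (snapshot noise is
#' de-meaned); the per-residue decompositions sum to the local part of the
#' binding energy (baseline for the non-modified variant, baseline plus
#' site contributions for the modified one), so the long-range term is
#' recoverable as the decomposition gap.
#'
#' @param config [generator_config()].
#' @param complex_id Identifier used for the substream and in the output.
#' @return List with `complex_id`, `sites` (chain, resnum, ptm_type,
#'   residue, true_local), `snapshots_nonmod`, `snapshots_mod` (snapshot
#'   energy data frames), `decomp_nonmod`, `decomp_mod` (per-residue
#'   tables) and `truth` (`locals`, `long_range`, `ddg_true`, `dg0`).
#' @export
gen_energy_tables <- function(config = generator_config(),
                              complex_id = "CPX1") {
  .with_stream(config, paste0("energy:", complex_id), {
    L <- config$chain_length
    n_ac <- config$n_acetyl_sites
    n_ph <- config$n_phospho_sites
    chains <- rep(c("A", "B"), each = L)
    resnums <- rep(seq_len(L), 2L)
    pick <- sample(2L * L, n_ac + n_ph)
    ptype <- c(rep("acetylation", n_ac), rep("phosphorylation", n_ph))
    residue <- c(rep("K", n_ac),
                 sample(c("S", "T", "Y"), n_ph, replace = TRUE,
                        prob = c(0.6, 0.3, 0.1)))
    mu <- ifelse(ptype == "acetylation", config$mu_acetyl,
                 ifelse(residue == "S", config$mu_phospho_S,
                        ifelse(residue == "T", config$mu_phospho_T,
                               config$mu_phospho_Y)))
    locals <- stats::rnorm(length(mu), mu, config$sigma_local)
    sites <- data.frame(chain = chains[pick], resnum = resnums[pick],
                        ptm_type = ptype, residue = residue,
                        true_local = locals, stringsAsFactors = FALSE)
    long_range <- stats::rnorm(1L, 0, config$sigma_longrange)
    dg0 <- stats::rnorm(1L, -25, 5)
    g_rec0 <- -800 + stats::rnorm(1L, 0, 20)
    g_lig0 <- -500 + stats::rnorm(1L, 0, 20)
    g_cpx0 <- g_rec0 + g_lig0 + dg0

    ns <- config$n_snapshots
    demeaned <- function() {
      e <- stats::rnorm(ns, 0, config$snapshot_noise_sd)
      if (ns > 1L) e - mean(e) else e * 0
    }
    build_snapshots <- function(g_cpx_mean) {
      totals <- list(complex = g_cpx_mean + demeaned(),
                     receptor = g_rec0 + demeaned(),
                     ligand = g_lig0 + demeaned())
      do.call(rbind, lapply(names(totals), function(role) {
        cbind(data.frame(snapshot = seq_len(ns),
                         time = 100 * seq_len(ns), role = role,
                         stringsAsFactors = FALSE),
              .split_components(totals[[role]]))
      }))
    }
    snapshots_nonmod <- build_snapshots(g_cpx0)
    snapshots_mod <- build_snapshots(g_cpx0 + sum(locals) + long_range)

    base <- stats::rnorm(2L * L, 0, 0.2)
    base <- base - mean(base) + dg0 / (2L * L)
    decomp_nonmod <- data.frame(chain = chains, resnum = resnums,
                                contribution = base,
                                stringsAsFactors = FALSE)
    decomp_mod <- decomp_nonmod
    decomp_mod$contribution[pick] <- decomp_mod$contribution[pick] + locals
    list(complex_id = complex_id, sites = sites,
         snapshots_nonmod = snapshots_nonmod, snapshots_mod = snapshots_mod,
         decomp_nonmod = decomp_nonmod, decomp_mod = decomp_mod,
         truth = list(locals = locals, long_range = long_range,
                      ddg_true = sum(locals) + long_range, dg0 = dg0))
  })
}

#' Synthetic cohort of complexes
#'
#' @param config [generator_config()].
#' @return List of [gen_energy_tables()] results, one per complex, ids
#'   `CPX001`, `CPX002`, ...
#' @export
gen_cohort <- function(config = generator_config()) {
  lapply(seq_len(config$n_complexes), function(i)
    gen_energy_tables(config, sprintf("CPX%03d", i)))
}

# idealized alpha-helix C-alpha coordinates
.helix_coords <- function(n) {
  i <- seq_len(n)
  cbind(2.3 * cos(i * 100 * pi / 180),
        2.3 * sin(i * 100 * pi / 180),
        1.5 * i)
}

#' Synthetic trajectory pair with controlled divergence
#'
#' Both trajectories start from the same idealized helical C-alpha
#' conformation and drift along a shared per-atom displacement field with
#' added jitter; the modified trajectory additionally drifts along an
#' independent per-atom field of magnitude `delta`, so the conformational
#' divergence of the endpoints (and of the cluster representatives) is
#' controlled by `delta`.
#'
#' @param config [generator_config()].
#' @param delta Extra endpoint divergence in Angstrom (default:
#'   `config$delta`).
#' @return List with `nonmod`, `mod` ([md_trajectory()] objects),
#'   `initial` ([md_frame()]) and `truth` (`delta`).
#' @export
gen_trajectory_pair <- function(config = generator_config(),
                                delta = config$delta) {
  .with_stream(config, "trajectory", {
    n <- config$n_traj_residues
    X0 <- .helix_coords(n)
    labels <- data.frame(chain = "A", resnum = seq_len(n), atom = "CA",
                         backbone = TRUE, stringsAsFactors = FALSE)
    unit_field <- function() {
      u <- matrix(stats::rnorm(3L * n), ncol = 3L)
      u / sqrt(rowSums(u^2))
    }
    drift <- unit_field() * config$drift_mag
    dfield <- unit_field() * delta
    nf <- config$n_frames
    jitter <- function() matrix(stats::rnorm(3L * n, 0, config$jitter_sd),
                                ncol = 3L)
    make <- function(extra) {
      frames <- lapply(seq_len(nf), function(t) {
        md_frame(X0 + (t / nf) * (drift + extra) + jitter(), labels)
      })
      md_trajectory(frames, times = as.numeric(seq_len(nf)))
    }
    nonmod <- make(matrix(0, n, 3L))
    mod <- make(dfield)
    list(nonmod = nonmod, mod = mod, initial = md_frame(X0, labels),
         truth = list(delta = delta))
  })
}

#' Synthetic orthologue alignment, taxonomy tree and ground truth
#'
#' Builds a reference sequence carrying `n_align_sites` modification sites
#' (spaced so the +/-1 acetylation windows never overlap) and
#' `n_orthologs` orthologue rows in which each site is conserved with
#' probability `p_conserve`, realized per the type-specific rule:
#' conserved acetylation places a lysine at the site column or one column
#' up/downstream (equal chance), conserved S/T phosphosites place S or T
#' at the exact column, conserved Y phosphosites place Y. All remaining
#' positions use an alphabet free of K/S/T/Y so conservation is never
#' accidental. A random taxonomy over the orthologue taxa is attached.
#'
#' @param config [generator_config()].
#' @return List with `alignment` ([orth_alignment()]), `tree`
#'   ([taxonomy_tree()]), `phylo` (the underlying `ape` tree), `sites`
#'   (data frame `position`, `column`, `ptm_type`, `residue`) and `truth`
#'   (`conserved`: orthologs-by-sites logical matrix; `p_conserve`).
#' @export
gen_alignment_and_tree <- function(config = generator_config()) {
  .with_stream(config, "alignment", {
    ns <- config$n_align_sites
    no <- config$n_orthologs
    spacing <- 5L
    site_pos <- 3L + spacing * (seq_len(ns) - 1L)   # ungapped positions
    L <- max(site_pos) + 3L
    types <- rep(c("acetylation", "phosphorylation"), length.out = ns)
    residue <- ifelse(types == "acetylation", "K",
                      sample(c("S", "T", "Y"), ns, replace = TRUE,
                             prob = c(0.6, 0.3, 0.1)))
    ref <- sample(.safe_alphabet, L, replace = TRUE)
    ref[site_pos] <- residue
    # insert a reference gap column after every 7th residue to exercise
    # ungapped-position bookkeeping
    gap_after <- seq(7L, L - 1L, by = 7L)
    ncol_aln <- L + length(gap_after)
    ref_aln <- character(ncol_aln)
    col_of <- integer(L)
    j <- 0L
    for (i in seq_len(L)) {
      j <- j + 1L
      ref_aln[j] <- ref[i]
      col_of[i] <- j
      if (i %in% gap_after) {
        j <- j + 1L
        ref_aln[j] <- "-"
      }
    }
    site_col <- col_of[site_pos]
    conserved <- matrix(stats::runif(no * ns) < config$p_conserve, no, ns)
    seqs <- character(no)
    for (o in seq_len(no)) {
      row <- sample(.safe_alphabet, ncol_aln, replace = TRUE)
      for (s in seq_len(ns)) {
        if (!conserved[o, s]) next
        if (types[s] == "acetylation") {
          row[site_col[s] + sample(-1L:1L, 1L)] <- "K"
        } else if (residue[s] %in% c("S", "T")) {
          row[site_col[s]] <- sample(c("S", "T"), 1L)
        } else {
          row[site_col[s]] <- "Y"
        }
      }
      seqs[o] <- paste(row, collapse = "")
    }
    taxa <- sprintf("t%03d", seq_len(no))
    aln <- orth_alignment(c("REF", taxa),
                          c(paste(ref_aln, collapse = ""), seqs),
                          reference = 1L)
    phylo <- ape::rtree(no, tip.label = taxa)
    tree <- taxonomy_from_phylo(phylo)
    list(alignment = aln, tree = tree, phylo = phylo,
         sites = data.frame(position = site_pos, column = site_col,
                            ptm_type = types, residue = residue,
                            stringsAsFactors = FALSE),
         truth = list(conserved = conserved, p_conserve = config$p_conserve))
  })
}

#' Write a complete synthetic fixture cohort to a directory
#'
#' Emits the curation metadata table, modification-site table and
#' sequences, per-variant energy and decomposition tables for every
#' complex, a trajectory pair, the orthologue alignment with its Newick
#' taxonomy, and a ground-truth JSON.
#'
#' @param config [generator_config()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_cohort <- function(config = generator_config(), dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fx <- gen_curation_fixtures(config)
  write_structure_meta(fx$structures, file.path(dir, "structures.tsv"))
  pt <- gen_ptm_table(config)
  write_ptm_table(pt$sites, file.path(dir, "ptm_sites.tsv"))
  seqinr::write.fasta(as.list(pt$sequences), names = names(pt$sequences),
                      file.out = file.path(dir, "sequences.fasta"))
  cohort <- gen_cohort(config)
  truth <- list()
  for (cx in cohort) {
    write_snapshot_energies(cx$snapshots_nonmod,
      file.path(dir, paste0(cx$complex_id, "_nonmod_energies.tsv")))
    write_snapshot_energies(cx$snapshots_mod,
      file.path(dir, paste0(cx$complex_id, "_mod_energies.tsv")))
    write_decomposition(cx$decomp_nonmod,
      file.path(dir, paste0(cx$complex_id, "_nonmod_decomp.tsv")))
    write_decomposition(cx$decomp_mod,
      file.path(dir, paste0(cx$complex_id, "_mod_decomp.tsv")))
    truth[[cx$complex_id]] <- cx$truth
  }
  tp <- gen_trajectory_pair(config)
  write_xyz_trajectory(tp$nonmod, file.path(dir, "traj_nonmod.xyz"))
  write_xyz_trajectory(tp$mod, file.path(dir, "traj_mod.xyz"))
  at <- gen_alignment_and_tree(config)
  write_alignment(at$alignment, file.path(dir, "alignment.fasta"))
  ape::write.tree(at$phylo, file.path(dir, "taxonomy.nwk"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
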