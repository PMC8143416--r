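#' Chain-level structure metadata
#'
#' Describes one protein chain of a deposited structure: which protein it
#' corresponds to, how much of the protein was crystallized and how much of
#' the crystallized construct is actually resolved (not in gaps).
#'
#' @param chain_id Chain identifier (e.g. "A").
#' @param protein_accession Protein (UniProt-style) accession of the chain.
#' @param organism_tag Free-text organism tag.
#' @param is_fusion Is the chain a fusion construct?
#' @param has_engineered_mutations Does the chain carry engineered mutations?
#' @param full_length Length of the full protein sequence (residues).
#' @param n_crystallized Number of residues in the crystallized construct.
#' @param n_resolved Number of residues actually resolved (not in gaps).
#' @return An object of class `chain_meta`.
#' @export
chain_meta <- function(chain_id, protein_accession, organism_tag = "yeast",
                       is_fusion = FALSE, has_engineered_mutations = FALSE,
                       full_length, n_crystallized, n_resolved) {
  full_length <- as.numeric(full_length)
  n_crystallized <- as.numeric(n_crystallized)
  n_resolved <- as.numeric(n_resolved)
  if (full_length <= 0) stop("full_length must be positive")
  if (n_resolved < 0 || n_crystallized < n_resolved ||
      full_length < n_crystallized) {
    stop("require 0 <= n_resolved <= n_crystallized <= full_length")
  }
  structure(list(
    chain_id = as.character(chain_id),
    protein_accession = as.character(protein_accession),
    organism_tag = as.character(organism_tag),
    is_fusion = isTRUE(is_fusion),
    has_engineered_mutations = isTRUE(has_engineered_mutations),
    full_length = full_length,
    n_crystallized = n_crystallized,
    n_resolved = n_resolved
  ), class = "chain_meta")
}

#' Structure-level metadata
#'
#' @param structure_id Structure identifier (e.g. a PDB id).
#' @param method Experimental method: `"xray"`, `"nmr"` or `"other"`.
#' @param resolution Resolution in Angstrom; `NA` for NMR structures.
#' @param is_membrane Is the complex membrane-embedded?
#' @param chains List of [chain_meta()] objects (at least one).
#' @return An object of class `structure_meta`.
#' @export
structure_meta <- function(structure_id, method = c("xray", "nmr", "other"),
                           resolution = NA_real_, is_membrane = FALSE,
                           chains) {
  method <- match.arg(method)
  if (!length(chains)) stop("at least one chain is required")
  if (!all(vapply(chains, inherits, logical(1), "chain_meta"))) {
    stop("chains must be a list of chain_meta objects")
  }
  resolution <- as.numeric(resolution)
  if (!is.na(resolution) && resolution <= 0) stop("resolution must be > 0")
  structure(list(
    structure_id = as.character(structure_id),
    method = method,
    resolution = resolution,
    is_membrane = isTRUE(is_membrane),
    chains = chains
  ), class = "structure_meta")
}

#' Dataset-selection criteria
#'
#' Thresholds used to curate the structure dataset: construct completeness
#' (fraction of the full protein that was crystallized), resolved fraction
#' (residues not in gaps, relative to the crystallized construct), maximum
#' crystallographic resolution, and the multimer / mapped-PTM requirements.
#'
#' @param min_pct_crystallized Minimum mean percentage of the full protein
#'   length present in the crystallized construct (default 70).
#' @param min_pct_resolved Minimum mean percentage of crystallized residues
#'   that are resolved (default 70).
#' @param max_resolution Maximum X-ray resolution in Angstrom (default 3.0,
#'   inclusive: "3.0 A or better").
#' @param require_multimer Keep multimers only (default `TRUE`).
#' @param require_mapped_ptm Keep only structures with at least one mapped
#'   modification site (default `TRUE`).
#' @return A `curation_criteria` object.
#' @export
curation_criteria <- function(min_pct_crystallized = 70,
                              min_pct_resolved = 70,
                              max_resolution = 3.0,
                              require_multimer = TRUE,
                              require_mapped_ptm = TRUE) {
  stopifnot(min_pct_crystallized > 0, min_pct_crystallized <= 100,
            min_pct_resolved > 0, min_pct_resolved <= 100,
            max_resolution > 0)
  structure(list(
    min_pct_crystallized = min_pct_crystallized,
    min_pct_resolved = min_pct_resolved,
    max_resolution = max_resolution,
    require_multimer = isTRUE(require_multimer),
    require_mapped_ptm = isTRUE(require_mapped_ptm)
  ), class = "curation_criteria")
}

# mean completeness percentages over the chains of one structure
.completeness_means <- function(meta) {
  pc <- vapply(meta$chains, function(ch)
    100 * ch$n_crystallized / ch$full_length, numeric(1))
  pr <- vapply(meta$chains, function(ch) {
    if (ch$n_crystallized == 0) 0 else 100 * ch$n_resolved / ch$n_crystallized
  }, numeric(1))
  list(pct_crystallized = mean(pc), pct_resolved = mean(pr))
}

#' Evaluate one structure against the curation criteria
#'
#' A structure is kept iff all of the following hold: no fusion chains, no
#' engineered mutations, mean crystallized percentage and mean resolved
#' percentage over chains both at or above their thresholds, resolution at
#' or below the maximum for X-ray structures (the resolution criterion is
#' not applicable to NMR structures), not membrane-embedded, more than one
#' chain, and at least one mapped modification site. Reason codes enumerate
#' every failed criterion.
#'
#' @param meta A [structure_meta()] object.
#' @param ptm_mapped Does the structure have at least one mapped PTM site?
#' @param criteria A [curation_criteria()] object.
#' @return A list with `structure_id`, `kept` (flag) and `reasons`
#'   (character vector of reason codes, empty when kept).
#' @export
evaluate_structure <- function(meta, ptm_mapped,
                               criteria = curation_criteria()) {
  stopifnot(inherits(meta, "structure_meta"),
            inherits(criteria, "curation_criteria"))
  if (meta$method == "xray" && is.na(meta$resolution)) {
    stop("resolution_required: xray structure without resolution")
  }
  if (meta$method == "other") {
    warning("method 'other' for ", meta$structure_id,
            ": resolution criterion skipped")
  }
  reasons <- character(0)
  if (any(vapply(meta$chains, `[[`, logical(1), "is_fusion"))) {
    reasons <- c(reasons, "fusion")
  }
  if (any(vapply(meta$chains, `[[`, logical(1), "has_engineered_mutations"))) {
    reasons <- c(reasons, "engineered_mutations")
  }
  cm <- .completeness_means(meta)
  if (cm$pct_crystallized < criteria$min_pct_crystallized) {
    reasons <- c(reasons, "pct_crystallized")
  }
  if (cm$pct_resolved < criteria$min_pct_resolved) {
    reasons <- c(reasons, "pct_resolved")
  }
  if (meta$method == "xray" && meta$resolution > criteria$max_resolution) {
    reasons <- c(reasons, "resolution")
  }
  if (meta$is_membrane) reasons <- c(reasons, "membrane")
  if (criteria$require_multimer && length(meta$chains) <= 1) {
    reasons <- c(reasons, "monomer")
  }
  if (criteria$require_mapped_ptm && !isTRUE(ptm_mapped)) {
    reasons <- c(reasons, "no_mapped_ptm")
  }
  list(structure_id = meta$structure_id,
       kept = length(reasons) == 0L,
       reasons = reasons)
}

#' Remove redundant structures of the same complex
#'
#' Complex identity is the multiset of protein accessions over chains (so a
#' homodimer and a heterodimer of the same proteins differ). Among
#' structures sharing an identity, the one with the lowest resolution value
#' wins; ties are broken by the highest mean resolved percentage, then by
#' the lexicographically smallest structure id. NMR structures (no
#' resolution) sort after any structure with a numeric resolution.
#'
#' @param structures List of [structure_meta()] objects that passed
#'   [evaluate_structure()].
#' @return The deduplicated list, in input order of the winners.
#' @export
deduplicate_complexes <- function(structures) {
  if (!length(structures)) return(structures)
  key <- vapply(structures, function(s) {
    paste(sort(vapply(s$chains, `[[`, character(1), "protein_accession")),
          collapse = "|")
  }, character(1))
  keep <- logical(length(structures))
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) == 1L) { keep[idx] <- TRUE; next }
    res <- vapply(structures[idx], function(s)
      ifelse(is.na(s$resolution), Inf, s$resolution), numeric(1))
    resolved <- vapply(structures[idx], function(s)
      .completeness_means(s)$pct_resolved, numeric(1))
    ids <- vapply(structures[idx], `[[`, character(1), "structure_id")
    ord <- order(res, -resolved, ids)
    keep[idx[ord[1L]]] <- TRUE
  }
  structures[keep]
}

#' Classify kept structures by the conditions of their mapped sites
#'
#' Each kept structure is counted in exactly one bin according to the set of
#' conditions (normal / stress) among the modification sites mapped to it.
#'
#' @param kept List of [structure_meta()] objects after curation.
#' @param sites Data frame of mapped sites with at least columns
#'   `structure_id` and `condition` (`"normal"` or `"stress"`).
#' @return A list with counts `n_normal_only`, `n_stress_only`, `n_both`.
#' @export
classify_condition_coverage <- function(kept, sites) {
  ids <- vapply(kept, `[[`, character(1), "structure_id")
  if (nrow(sites) && !all(sites$structure_id %in% ids)) {
    stop("mapped sites reference structures outside the kept set")
  }
  n_normal_only <- n_stress_only <- n_both <- 0L
  for (id in ids) {
    conds <- unique(sites$condition[sites$structure_id == id])
    if (!length(conds)) {
      stop("structure ", id,
           " has zero mapped sites; should have been filtered")
    }
    if (setequal(conds, "normal")) n_normal_only <- n_normal_only + 1L
    else if (setequal(conds, "stress")) n_stress_only <- n_stress_only + 1L
    else n_both <- n_both + 1L
  }
  list(n_normal_only = n_normal_only,
       n_stress_only = n_stress_only,
       n_both = n_both)
}

#' Simulation-job inventory from condition coverage
#'
#' Every kept structure requires one non-modified control simulation;
#' structures with normal-condition sites additionally require one
#' normal-condition modified simulation, and likewise for stress.
#'
#' @param cov Coverage list as returned by [classify_condition_coverage()],
#'   or a numeric vector of length 3 `(n_normal_only, n_stress_only,
#'   n_both)`.
#' @return A list with `n_nonmodified`, `n_normal`, `n_stress`, `n_total`.
#' @export
count_simulation_jobs <- function(cov) {
  if (is.numeric(cov) && length(cov) == 3L) {
    cov <- list(n_normal_only = cov[[1L]], n_stress_only = cov[[2L]],
                n_both = cov[[3L]])
  }
  stopifnot(cov$n_normal_only >= 0, cov$n_stress_only >= 0, cov$n_both >= 0)
  n_nonmod <- cov$n_normal_only + cov$n_stress_only + cov$n_both
  n_normal <- cov$n_normal_only + cov$n_both
  n_stress <- cov$n_stress_only + cov$n_both
  list(n_nonmodified = n_nonmod,
       n_normal = n_normal,
       n_stress = n_stress,
       n_total = n_nonmod + n_normal + n_stress)
}

#' Read structure metadata from a per-chain table
#'
#' Expects a tab-separated file with one row per chain and columns
#' `structure_id method resolution is_membrane chain_id protein_accession
#' organism_tag is_fusion has_engineered_mutations full_length
#' n_crystallized n_resolved`. Missing resolution is written as `NA`.
#'
#' @param path Path to the table.
#' @return List of [structure_meta()] objects, in first-appearance order.
#' @export
read_structure_meta <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("structure_id", "method", "resolution", "is_membrane",
              "chain_id", "protein_accession", "organism_tag", "is_fusion",
              "has_engineered_mutations", "full_length", "n_crystallized",
              "n_resolved")
  if (!all(needed %in% names(df))) {
    stop("missing columns: ", paste(setdiff(needed, names(df)), collapse = ", "))
  }
  lapply(unique(df$structure_id), function(id) {
    rows <- df[df$structure_id == id, , drop = FALSE]
    chains <- lapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      chain_meta(r$chain_id, r$protein_accession, r$organism_tag,
                 as.logical(r$is_fusion), as.logical(r$has_engineered_mutations),
                 r$full_length, r$n_crystallized, r$n_resolved)
    })
    structure_meta(id, rows$method[1L], as.numeric(rows$resolution[1L]),
                   as.logical(rows$is_membrane[1L]), chains)
  })
}

#' Write structure metadata to a per-chain table
#'
#' Inverse of [read_structure_meta()].
#'
#' @param structures List of [structure_meta()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_meta <- function(structures, path) {
  rows <- do.call(rbind, lapply(structures, function(s) {
    do.call(rbind, lapply(s$chains, function(ch) {
      data.frame(structure_id = s$structure_id, method = s$method,
                 resolution = s$resolution, is_membrane = s$is_membrane,
                 chain_id = ch$chain_id,
                 protein_accession = ch$protein_accession,
                 organism_tag = ch$organism_tag, is_fusion = ch$is_fusion,
                 has_engineered_mutations = ch$has_engineered_mutations,
                 full_length = ch$full_length,
                 n_crystallized = ch$n_crystallized,
                 n_resolved = ch$n_resolved,
                 stringsAsFactors = FALSE)
    }))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
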