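#' Construct a table of modification sites
#'
#' @param protein_accession Accessions.
#' @param position 1-based positions in the full protein sequence.
#' @param residue Modified residue, one of `K`, `S`, `T`, `Y`.
#' @param ptm_type `"acetylation"` or `"phosphorylation"`.
#' @param condition `"normal"` or `"stress"`.
#' @param source_id Free-text provenance tag.
#' @return A data frame with one row per site.
#' @export
ptm_sites <- function(protein_accession, position, residue, ptm_type,
                      condition, source_id = "") {
  n <- length(position)
  df <- data.frame(protein_accession = rep_len(as.character(protein_accession), n),
                   position = as.integer(position),
                   residue = rep_len(as.character(residue), n),
                   ptm_type = rep_len(as.character(ptm_type), n),
                   condition = rep_len(as.character(condition), n),
                   source_id = rep_len(as.character(source_id), n),
                   stringsAsFactors = FALSE)
  stopifnot(all(df$position >= 1L),
            all(df$residue %in% c("K", "S", "T", "Y")),
            all(df$ptm_type %in% c("acetylation", "phosphorylation")),
            all(df$condition %in% c("normal", "stress")))
  df
}

# legal residue/type combinations
.legal_combo <- function(ptm_type, residue) {
  (ptm_type == "acetylation" & residue == "K") |
    (ptm_type == "phosphorylation" & residue %in% c("S", "T", "Y"))
}

#' Validate modification sites against protein sequences
#'
#' A site is kept iff the sequence letter at its position equals the
#' recorded residue and the residue/type combination is chemically legal
#' (acetylation on K; phosphorylation on S, T or Y).
#'
#' @param sites Site table as from [ptm_sites()] or [read_ptm_table()].
#' @param sequences Named character vector (or list) of protein sequences,
#'   names are accessions.
#' @return A list with `valid` (kept rows) and `rejected` (dropped rows plus
#'   a `reason` column: `illegal_type_residue`, `position_out_of_range` or
#'   `residue_mismatch`).
#' @export
validate_sites <- function(sites, sequences) {
  sequences <- unlist(sequences)
  missing <- setdiff(unique(sites$protein_accession), names(sequences))
  if (length(missing)) {
    stop("unknown_accession: ", paste(missing, collapse = ", "))
  }
  reason <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    if (!.legal_combo(sites$ptm_type[i], sites$residue[i])) {
      reason[i] <- "illegal_type_residue"
      next
    }
    seq <- sequences[[sites$protein_accession[i]]]
    if (sites$position[i] > nchar(seq)) {
      reason[i] <- "position_out_of_range"
      next
    }
    if (substr(seq, sites$position[i], sites$position[i]) != sites$residue[i]) {
      reason[i] <- "residue_mismatch"
    }
  }
  rejected <- sites[reason != "", , drop = FALSE]
  rejected$reason <- reason[reason != ""]
  list(valid = sites[reason == "", , drop = FALSE], rejected = rejected)
}

#' Residue-numbering map between a structure chain and its protein
#'
#' @param structure_id,chain_id Identifiers.
#' @param structure_resnum Residue numbers as in the structure file.
#' @param protein_position Corresponding 1-based positions in the full
#'   protein sequence (strictly increasing).
#' @param resolved Logical; is the residue resolved (not in a gap)?
#' @return An object of class `residue_map`.
#' @export
residue_map <- function(structure_id, chain_id, structure_resnum,
                        protein_position, resolved = TRUE) {
  entries <- data.frame(structure_resnum = as.integer(structure_resnum),
                        protein_position = as.integer(protein_position),
                        resolved = rep_len(as.logical(resolved),
                                           length(structure_resnum)))
  if (anyDuplicated(entries$structure_resnum)) {
    stop("structure residue numbers must be unique within a chain")
  }
  if (is.unsorted(entries$protein_position, strictly = TRUE)) {
    stop("protein positions must be strictly increasing")
  }
  structure(list(structure_id = as.character(structure_id),
                 chain_id = as.character(chain_id),
                 entries = entries),
            class = "residue_map")
}

#' Map validated sites onto a structure chain
#'
#' A site lands on the chain iff its protein position appears in the residue
#' map with `resolved = TRUE`; sites falling in gaps or beyond the
#' crystallized construct are dropped and reported.
#'
#' @param sites Validated site table (rows for the chain's protein).
#' @param rmap A [residue_map()].
#' @return List with `mapped` (data frame: `structure_id`, `chain_id`,
#'   `structure_resnum` plus the site columns) and `dropped` (site rows plus
#'   `reason`: `gap` or `not_crystallized`).
#' @export
map_sites_to_chain <- function(sites, rmap) {
  stopifnot(inherits(rmap, "residue_map"))
  e <- rmap$entries
  idx <- match(sites$position, e$protein_position)
  reason <- character(nrow(sites))
  reason[is.na(idx)] <- "not_crystallized"
  in_gap <- !is.na(idx) & !e$resolved[ifelse(is.na(idx), 1L, idx)]
  reason[in_gap] <- "gap"
  ok <- reason == ""
  mapped <- cbind(data.frame(structure_id = rmap$structure_id,
                             chain_id = rmap$chain_id,
                             structure_resnum = e$structure_resnum[idx[ok]],
                             stringsAsFactors = FALSE),
                  sites[ok, , drop = FALSE])
  rownames(mapped) <- NULL
  dropped <- sites[!ok, , drop = FALSE]
  dropped$reason <- reason[!ok]
  list(mapped = mapped, dropped = dropped)
}

#' Per-chain modification profiles and multiplicity histogram
#'
#' Builds one profile per (structure, chain) with counts of acetylated
#' lysines and phosphorylated serines/threonines/tyrosines, and a histogram
#' of the total number of modifications per chain. Chains known to the
#' dataset but carrying no mapped site are counted in the 0 bin when listed
#' in `all_chains`.
#'
#' @param mapped Mapped-site data frame from [map_sites_to_chain()]
#'   (possibly concatenated over chains).
#' @param all_chains Optional data frame with columns `structure_id`,
#'   `chain_id` enumerating every chain of the dataset (defaults to the
#'   chains present in `mapped`).
#' @return List with `profiles` (data frame: chain key, `n_acetyl_K`,
#'   `n_phospho_S`, `n_phospho_T`, `n_phospho_Y`, `total`) and `histogram`
#'   (data frame `n_ptm`, `n_chains`, `fraction` over all chains).
#' @export
per_chain_distribution <- function(mapped, all_chains = NULL) {
  if (is.null(all_chains)) {
    all_chains <- unique(mapped[, c("structure_id", "chain_id"), drop = FALSE])
  }
  key <- function(s, c) paste(s, c, sep = ":")
  chains <- key(all_chains$structure_id, all_chains$chain_id)
  mkey <- if (nrow(mapped)) key(mapped$structure_id, mapped$chain_id) else character(0)
  if (nrow(mapped) && !all(mkey %in% chains)) {
    stop("mapped sites reference chains absent from all_chains")
  }
  count_cat <- function(k, type, res) {
    sum(mkey == k & mapped$ptm_type == type & mapped$residue == res)
  }
  profiles <- data.frame(
    structure_id = all_chains$structure_id,
    chain_id = all_chains$chain_id,
    n_acetyl_K = vapply(chains, count_cat, integer(1), "acetylation", "K"),
    n_phospho_S = vapply(chains, count_cat, integer(1), "phosphorylation", "S"),
    n_phospho_T = vapply(chains, count_cat, integer(1), "phosphorylation", "T"),
    n_phospho_Y = vapply(chains, count_cat, integer(1), "phosphorylation", "Y"),
    row.names = NULL, stringsAsFactors = FALSE)
  profiles$total <- profiles$n_acetyl_K + profiles$n_phospho_S +
    profiles$n_phospho_T + profiles$n_phospho_Y
  tab <- table(factor(profiles$total, levels = 0:max(c(profiles$total, 0L))))
  histogram <- data.frame(n_ptm = as.integer(names(tab)),
                          n_chains = as.integer(tab),
                          fraction = as.integer(tab) / nrow(profiles))
  list(profiles = profiles, histogram = histogram)
}

#' Percentage of modified entries carrying more than one modification
#'
#' @param n_modified_entries Number of entries with at least one
#'   modification.
#' @param n_single_ptm_entries Number of entries with exactly one.
#' @return Percentage with more than one modification, rounded to one
#'   decimal.
#' @export
multi_ptm_fraction <- function(n_modified_entries, n_single_ptm_entries) {
  if (n_modified_entries == 0) stop("empty_set: no modified entries")
  stopifnot(n_single_ptm_entries >= 0,
            n_single_ptm_entries <= n_modified_entries)
  round(100 * (n_modified_entries - n_single_ptm_entries) /
          n_modified_entries, 1)
}

#' Count sites per modified residue type
#'
#' Tallies a site table by residue (K/S/T/Y) and returns the per-residue
#' counts together with the total, optionally restricted to one condition.
#'
#' @param sites Site table.
#' @param condition Optional condition filter (`"normal"` or `"stress"`).
#' @return List with `counts` (named integer vector over K, S, T, Y) and
#'   `total`.
#' @export
count_sites_by_residue <- function(sites, condition = NULL) {
  if (!is.null(condition)) sites <- sites[sites$condition == condition, ]
  counts <- vapply(c(K = "K", S = "S", T = "T", Y = "Y"),
                   function(r) sum(sites$residue == r), integer(1))
  list(counts = counts, total = sum(counts))
}

#' Read a modification-site table
#'
#' Tab-separated with header
#' `accession position residue ptm_type condition source`.
#'
#' @param path Path to the table.
#' @return Site data frame as produced by [ptm_sites()].
#' @export
read_ptm_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("accession", "position", "residue", "ptm_type", "condition",
              "source")
  if (!all(needed %in% names(df))) {
    stop("missing columns: ", paste(setdiff(needed, names(df)), collapse = ", "))
  }
  data.frame(protein_accession = df$accession,
             position = as.integer(df$position),
             residue = df$residue, ptm_type = df$ptm_type,
             condition = df$condition, source_id = df$source,
             stringsAsFactors = FALSE)
}

#' Write a modification-site table
#'
#' Inverse of [read_ptm_table()].
#'
#' @param sites Site data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ptm_table <- function(sites, path) {
  out <- data.frame(accession = sites$protein_accession,
                    position = sites$position, residue = sites$residue,
                    ptm_type = sites$ptm_type, condition = sites$condition,
                    source = sites$source_id, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
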