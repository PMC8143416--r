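#' Construct an orthologue alignment
#'
#' @param taxon_id Character vector of taxon identifiers, one per record.
#' @param taxon_name Display names (defaults to the ids).
#' @param sequence Aligned sequences with `-` for gaps, all equal length.
#' @param reference Index of the reference (query-organism) record.
#' @return Object of class `orth_alignment`.
#' @export
orth_alignment <- function(taxon_id, sequence, taxon_name = taxon_id,
                           reference = 1L) {
  sequence <- toupper(as.character(sequence))
  stopifnot(length(taxon_id) == length(sequence),
            length(unique(nchar(sequence))) == 1L,
            reference >= 1L, reference <= length(sequence))
  structure(list(taxon_id = as.character(taxon_id),
                 taxon_name = as.character(taxon_name),
                 sequence = sequence,
                 reference = as.integer(reference)),
            class = "orth_alignment")
}

#' Read an alignment from gapped FASTA
#'
#' @param path FASTA path; gap character `-`.
#' @param reference Index or record name of the reference sequence
#'   (default: first record).
#' @return [orth_alignment()].
#' @export
read_alignment <- function(path, reference = 1L) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             set.attributes = FALSE)
  ids <- names(recs)
  if (is.character(reference)) reference <- match(reference, ids)
  if (is.na(reference)) stop("reference record not found")
  orth_alignment(ids, unlist(recs), reference = reference)
}

#' Write an alignment to gapped FASTA
#'
#' @param aln [orth_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqinr::write.fasta(as.list(aln$sequence), names = aln$taxon_id,
                      file.out = path, nbchar = 80)
  invisible(path)
}

#' Alignment column of an ungapped reference position
#'
#' @param aln [orth_alignment()].
#' @param ungapped_pos 1-based position in the reference sequence with
#'   gaps removed.
#' @return Column index into the alignment.
#' @export
column_of_position <- function(aln, ungapped_pos) {
  stopifnot(inherits(aln, "orth_alignment"), ungapped_pos >= 1L)
  ref <- strsplit(aln$sequence[aln$reference], "")[[1L]]
  nongap <- which(ref != "-")
  if (ungapped_pos > length(nongap)) {
    stop("position ", ungapped_pos, " beyond ungapped reference length ",
         length(nongap))
  }
  nongap[[ungapped_pos]]
}

#' Type-specific conservation rule for one orthologue
#'
#' Acetylated lysines count as conserved when the orthologue has a lysine
#' at the site's alignment column or one column up/downstream (spatial
#' tolerance that preserves function). Serine/threonine phosphosites are
#' conserved when either S or T occupies the exact column; tyrosine
#' phosphosites require Y at the exact column. Columns outside the
#' alignment never match.
#'
#' @param sequence Aligned orthologue sequence.
#' @param column Alignment column of the site.
#' @param ptm_type `"acetylation"` or `"phosphorylation"`.
#' @param residue The modified residue in the reference (K/S/T/Y).
#' @return Logical flag.
#' @export
is_conserved <- function(sequence, column, ptm_type, residue) {
  chars <- strsplit(sequence, "")[[1L]]
  at <- function(j) if (j >= 1L && j <= length(chars)) chars[[j]] else ""
  if (ptm_type == "acetylation") {
    any(vapply(column + (-1L:1L), at, character(1)) == "K")
  } else if (residue %in% c("S", "T")) {
    at(column) %in% c("S", "T")
  } else if (residue == "Y") {
    at(column) == "Y"
  } else {
    stop("unsupported ptm_type/residue combination")
  }
}

#' Conservation fraction of one site across orthologues
#'
#' Applies [is_conserved()] to every non-reference record; the fraction is
#' the number of conserving orthologues over the number of orthologues
#' (reference excluded). Orthologues entirely gapped at the relevant
#' columns count as non-conserving.
#'
#' @param aln [orth_alignment()].
#' @param position Site position in the ungapped reference sequence.
#' @param ptm_type,residue Modification type and residue (as in the site
#'   table).
#' @return List with `fraction`, `conserving_taxa` (ids), `n_orthologs`
#'   and `column`.
#' @export
conservation_fraction <- function(aln, position, ptm_type, residue) {
  col <- column_of_position(aln, position)
  ref_char <- substr(aln$sequence[aln$reference], col, col)
  if (ref_char != residue) {
    stop("reference_mismatch: reference has '", ref_char, "' at position ",
         position, ", site says '", residue, "'")
  }
  others <- setdiff(seq_along(aln$sequence), aln$reference)
  cons <- vapply(others, function(i)
    is_conserved(aln$sequence[i], col, ptm_type, residue), logical(1))
  list(fraction = if (length(others)) mean(cons) else 0,
       conserving_taxa = aln$taxon_id[others[cons]],
       n_orthologs = length(others),
       column = col)
}

#' Construct a taxonomy tree from parent pointers
#'
#' @param id Node identifiers.
#' @param parent Parent identifier per node; `NA` (exactly once) marks the
#'   root.
#' @param name Optional display names.
#' @return Object of class `taxonomy_tree`.
#' @export
taxonomy_tree <- function(id, parent, name = id) {
  id <- as.character(id); parent <- as.character(parent)
  stopifnot(length(id) == length(parent), !anyDuplicated(id))
  root <- id[is.na(parent)]
  if (length(root) != 1L) stop("exactly one root (parent = NA) required")
  if (!all(parent[!is.na(parent)] %in% id)) {
    stop("every non-root parent must be a node in the tree")
  }
  # acyclicity: every node must reach the root
  for (n in id) {
    seen <- character(0); cur <- n
    while (!is.na(parent[match(cur, id)])) {
      if (cur %in% seen) stop("cycle detected at node ", n)
      seen <- c(seen, cur)
      cur <- parent[match(cur, id)]
    }
  }
  structure(list(id = id, parent = parent, name = as.character(name),
                 root = root),
            class = "taxonomy_tree")
}

#' Convert an ape phylogeny into a taxonomy tree
#'
#' Internal nodes get ids `node<k>` unless the phylo object carries node
#' labels.
#'
#' @param phy An `ape::phylo` object.
#' @return [taxonomy_tree()].
#' @export
taxonomy_from_phylo <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  node_lab <- if (!is.null(phy$node.label) && all(nzchar(phy$node.label)))
    phy$node.label else paste0("node", seq_len(nnode))
  ids <- c(phy$tip.label, node_lab)
  parent <- rep(NA_character_, length(ids))
  parent[phy$edge[, 2L]] <- ids[phy$edge[, 1L]]
  taxonomy_tree(ids, parent)
}

#' Read a taxonomy from Newick or a two-column parent table
#'
#' @param path File path; `.nwk`/`.tree`/`.newick` files are parsed with
#'   \pkg{ape}, anything else as a tab-separated table with columns `id`
#'   and `parent` (root row has empty/NA parent).
#' @return [taxonomy_tree()].
#' @export
read_taxonomy <- function(path) {
  if (grepl("\\.(nwk|newick|tree)$", path, ignore.case = TRUE)) {
    taxonomy_from_phylo(ape::read.tree(path))
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
    taxonomy_tree(df$id, df$parent,
                  if ("name" %in% names(df)) df$name else df$id)
  }
}

# path from a node up to the root, inclusive, node first
.root_path <- function(tree, node) {
  path <- character(0); cur <- node
  repeat {
    path <- c(path, cur)
    p <- tree$parent[match(cur, tree$id)]
    if (is.na(p)) break
    cur <- p
  }
  path
}

#' Lowest common ancestor of a taxon set
#'
#' The deepest node that is an ancestor-or-self of every given taxon.
#'
#' @param tree [taxonomy_tree()].
#' @param taxa Non-empty character vector of taxon ids.
#' @return The LCA node id.
#' @export
lowest_common_ancestor <- function(tree, taxa) {
  taxa <- unique(as.character(taxa))
  if (!length(taxa)) stop("empty taxon set")
  unknown <- setdiff(taxa, tree$id)
  if (length(unknown)) {
    stop("unknown taxa: ", paste(unknown, collapse = ", "))
  }
  # walk up from the first taxon; the first node ancestral to all wins
  for (anc in .root_path(tree, taxa[1L])) {
    if (all(vapply(taxa, function(t) anc %in% .root_path(tree, t),
                   logical(1)))) {
      return(anc)
    }
  }
  tree$root
}

#' Simplify DSSP secondary-structure codes
#'
#' Maps the 8-letter DSSP alphabet (plus `-` for unassigned) onto three
#' elements: helix `H` (H, G, I), sheet `E` (E, B), non-structured `C`
#' (S, T, C, -).
#'
#' @param code Character vector of single-letter codes.
#' @return Character vector over `{H, E, C}`.
#' @export
simplify_secondary_structure <- function(code) {
  map <- c(H = "H", G = "H", I = "H", E = "E", B = "E",
           S = "C", T = "C", C = "C", "-" = "C")
  out <- map[as.character(code)]
  if (anyNA(out)) {
    stop("unknown secondary-structure code: ",
         paste(unique(code[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

#' Secondary-structure placement of sites versus background residues
#'
#' Compares the distribution of modification sites over the simplified
#' secondary-structure elements with that of matched non-modified residues
#' of the same amino-acid type.
#'
#' @param site_codes Simplified codes (`H`/`E`/`C`) of the modified
#'   residues.
#' @param background_codes Simplified codes of the matched non-modified
#'   residues.
#' @return Data frame with one row per element: `element`,
#'   `fraction_sites`, `fraction_background`, `difference`.
#' @export
ss_preference <- function(site_codes, background_codes) {
  stopifnot(length(site_codes) > 0, length(background_codes) > 0)
  lev <- c("H", "E", "C")
  fs <- as.numeric(table(factor(site_codes, lev))) / length(site_codes)
  fb <- as.numeric(table(factor(background_codes, lev))) / length(background_codes)
  data.frame(element = lev, fraction_sites = fs, fraction_background = fb,
             difference = fs - fb, stringsAsFactors = FALSE)
}

#' Correlation between site conservation and local binding effect
#'
#' @param fraction Conservation fractions.
#' @param delta Per-site binding contribution differences (kcal/mol).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `r`, `p` (two-sided), `n` and `method`.
#' @export
conservation_ddg_correlation <- function(fraction, delta,
                                         method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(fraction) == length(delta))
  if (length(fraction) < 3L) stop("need at least 3 pairs")
  if (stats::sd(fraction) == 0 || stats::sd(delta) == 0) {
    stop("degenerate_correlation: constant input")
  }
  ct <- stats::cor.test(fraction, delta, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(fraction),
       method = method)
}
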