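#' Total free energy of one MM/GBSA snapshot record
#'
#' Sums the molecular-mechanics terms (bonded, electrostatic, van der
#' Waals) and the solvation terms (polar generalized-Born, nonpolar
#' surface-area), minus the entropy term when one is supplied. The entropy
#' term is routinely omitted in end-point MM/GBSA work and defaults to
#' absent.
#'
#' @param components Named list or one-row data frame with `e_bonded`,
#'   `e_electrostatic`, `e_vdw`, `g_polar`, `g_nonpolar` and optionally
#'   `ts`, all in kcal/mol.
#' @return Free energy G in kcal/mol.
#' @export
total_free_energy <- function(components) {
  terms <- c("e_bonded", "e_electrostatic", "e_vdw", "g_polar", "g_nonpolar")
  vals <- vapply(terms, function(t) as.numeric(components[[t]]), numeric(1))
  if (any(!is.finite(vals))) stop("non-finite energy component")
  g <- sum(vals)
  ts <- components[["ts"]]
  if (!is.null(ts) && !is.na(ts)) {
    if (!is.finite(ts)) stop("non-finite entropy term")
    g <- g - as.numeric(ts)
  }
  g
}

# per-snapshot role totals from a snapshot-energy data frame
.role_totals <- function(snapshots) {
  comp_cols <- c("e_bonded", "e_electrostatic", "e_vdw", "g_polar",
                 "g_nonpolar")
  g <- rowSums(as.matrix(snapshots[, comp_cols]))
  if ("ts" %in% names(snapshots)) {
    ts <- snapshots$ts
    g <- g - ifelse(is.na(ts), 0, ts)
  }
  data.frame(snapshot = snapshots$snapshot, role = snapshots$role, g = g)
}

#' Binding free energy from per-snapshot role energies
#'
#' For each snapshot, the binding free energy is
#' `G_complex - G_receptor - G_ligand`; the reported value is the mean over
#' snapshots with its standard error (sample sd / sqrt(n), absent for a
#' single snapshot).
#'
#' @param snapshots Data frame with columns `snapshot`, `time`, `role`
#'   (`complex`/`receptor`/`ligand`) and the energy components of
#'   [total_free_energy()], one row per (snapshot, role).
#' @return An object of class `binding_energy`: list with `dg_bind` (mean,
#'   kcal/mol), `sem` (`NA` for n = 1), `n_snapshots`, `role_means` (named:
#'   complex, receptor, ligand) and `per_snapshot` (vector of snapshot
#'   binding energies, named by snapshot index).
#' @export
binding_energy <- function(snapshots) {
  stopifnot(all(c("snapshot", "role") %in% names(snapshots)))
  tot <- .role_totals(snapshots)
  wide <- stats::reshape(tot, idvar = "snapshot", timevar = "role",
                         direction = "wide")
  roles <- c("g.complex", "g.receptor", "g.ligand")
  if (!all(roles %in% names(wide)) || anyNA(wide[, roles])) {
    stop("incomplete_snapshot: every snapshot needs complex, receptor and ligand records")
  }
  wide <- wide[order(wide$snapshot), ]
  dg <- wide$g.complex - wide$g.receptor - wide$g.ligand
  names(dg) <- wide$snapshot
  n <- length(dg)
  structure(list(
    dg_bind = mean(dg),
    sem = if (n >= 2L) stats::sd(dg) / sqrt(n) else NA_real_,
    n_snapshots = n,
    role_means = c(complex = mean(wide$g.complex),
                   receptor = mean(wide$g.receptor),
                   ligand = mean(wide$g.ligand)),
    per_snapshot = dg
  ), class = "binding_energy")
}

#' Binding free-energy change upon modification
#'
#' `ddG_bind = dG_bind(modified) - dG_bind(non-modified)`; a negative value
#' indicates that the modifications stabilize binding, a positive value
#' that they destabilize it.
#'
#' @param modified,nonmodified [binding_energy()] results for the modified
#'   and non-modified complex under the same receptor/ligand partition.
#' @return List with `ddg_bind` (kcal/mol), `effect` (`stabilizing`,
#'   `destabilizing` or `neutral`) and `sem` (root-sum-square of the two
#'   variant standard errors, `NA` when either is absent).
#' @export
ddg <- function(modified, nonmodified) {
  stopifnot(inherits(modified, "binding_energy"),
            inherits(nonmodified, "binding_energy"))
  d <- modified$dg_bind - nonmodified$dg_bind
  effect <- if (d < 0) "stabilizing" else if (d > 0) "destabilizing" else "neutral"
  sem <- sqrt(modified$sem^2 + nonmodified$sem^2)
  list(ddg_bind = d, effect = effect, sem = sem)
}

#' Per-residue binding-contribution differences
#'
#' Subtracts decomposed per-residue binding contributions of the
#' non-modified complex from those of the modified complex. A residue with
#' an absolute difference strictly larger than the threshold (default 0.5
#' kcal/mol) is classified as interface-located. Residues present in only
#' one variant (gap asymmetry between subunits) contribute 0 kcal/mol in
#' the missing variant and are flagged.
#'
#' @param mod,nonmod Data frames with columns `chain`, `resnum`,
#'   `contribution` (kcal/mol).
#' @param threshold Interface threshold in kcal/mol (strict inequality).
#' @return Data frame with `chain`, `resnum`, `contribution_modified`,
#'   `contribution_nonmodified`, `delta`, `interface` and `flag`
#'   (`""`, `absent_in_modified` or `absent_in_nonmodified`).
#' @export
residue_contribution_delta <- function(mod, nonmod, threshold = 0.5) {
  key <- function(df) paste(df$chain, df$resnum, sep = ":")
  mk <- key(mod); nk <- key(nonmod)
  if (anyDuplicated(mk) || anyDuplicated(nk)) {
    stop("duplicate residue keys in a decomposition table")
  }
  all_keys <- union(mk, nk)
  im <- match(all_keys, mk); inm <- match(all_keys, nk)
  parts <- do.call(rbind, strsplit(all_keys, ":", fixed = TRUE))
  cm <- ifelse(is.na(im), 0, mod$contribution[im])
  cn <- ifelse(is.na(inm), 0, nonmod$contribution[inm])
  out <- data.frame(chain = parts[, 1L],
                    resnum = as.integer(parts[, 2L]),
                    contribution_modified = cm,
                    contribution_nonmodified = cn,
                    delta = cm - cn,
                    stringsAsFactors = FALSE)
  out$interface <- abs(out$delta) > threshold
  out$flag <- ifelse(is.na(im), "absent_in_modified",
                     ifelse(is.na(inm), "absent_in_nonmodified", ""))
  out[order(out$chain, out$resnum), ]
}

#' Gap between a chain's overall ddG and the sum of its local site effects
#'
#' The overall effect of the modifications on a subunit's binding need not
#' equal the sum of the local per-site contribution differences; the
#' discrepancy is attributed to long-range (conformational/allosteric)
#' effects. Gaps within one standard error of zero are taken as explained
#' by the local contributions.
#'
#' @param chain_ddg The chain's overall ddG_bind (kcal/mol).
#' @param site_deltas Per-site contribution differences on that chain
#'   (kcal/mol); may be empty.
#' @param sem Standard error of `chain_ddg`.
#' @return List with `gap` (kcal/mol) and `classification`
#'   (`local_explains`, `long_range_destabilizing` or
#'   `long_range_stabilizing`).
#' @export
local_vs_global_gap <- function(chain_ddg, site_deltas, sem) {
  gap <- chain_ddg - sum(site_deltas)
  cls <- if (is.finite(sem) && abs(gap) <= sem) "local_explains"
         else if (gap > 0) "long_range_destabilizing"
         else if (gap < 0) "long_range_stabilizing"
         else "local_explains"
  list(gap = gap, classification = cls)
}

#' Bound/unbound state contributions to the overall ddG
#'
#' For each molecular component (complex = bound state; receptor and ligand
#' = unbound states), `dG_role = <G_role>_modified - <G_role>_nonmodified`.
#' Each dG is expressed as a signed percentage of the sum of the three
#' absolute dG values. The identity
#' `ddG_bind = dG_complex - dG_receptor - dG_ligand` is verified.
#'
#' @param role_means_modified,role_means_nonmodified Named numeric vectors
#'   with elements `complex`, `receptor`, `ligand` (mean G per role,
#'   kcal/mol), e.g. the `role_means` of [binding_energy()].
#' @return List with `dg` (named vector of the three dG values), `pct`
#'   (signed percentages, summing to 100 in absolute value) and
#'   `implied_ddg_bind`.
#' @export
state_contribution_split <- function(role_means_modified,
                                     role_means_nonmodified) {
  roles <- c("complex", "receptor", "ligand")
  stopifnot(all(roles %in% names(role_means_modified)),
            all(roles %in% names(role_means_nonmodified)))
  dg <- role_means_modified[roles] - role_means_nonmodified[roles]
  denom <- sum(abs(dg))
  if (denom == 0) stop("degenerate_split: all three dG values are zero")
  list(dg = dg,
       pct = 100 * dg / denom,
       implied_ddg_bind = unname(dg["complex"] - dg["receptor"] - dg["ligand"]))
}

#' Enumerate receptor/ligand partitions of an n-meric complex
#'
#' A single binding energy is computed for dimers; for an n-mer, binding
#' of each subunit (the ligand) to the remainder of the complex (the
#' receptor) is evaluated, giving n binding-energy values.
#'
#' @param n_subunits Number of subunits (>= 2).
#' @return List of n partition schemes, each a list with `n_subunits` and
#'   `ligand_index`.
#' @export
partition_schemes <- function(n_subunits) {
  stopifnot(n_subunits >= 2L)
  lapply(seq_len(n_subunits), function(i)
    list(n_subunits = as.integer(n_subunits), ligand_index = i))
}

#' Read a per-snapshot energy table
#'
#' Tab-separated with columns `snapshot time role e_bonded e_elec e_vdw
#' g_polar g_nonpolar` and optionally `ts`. A leading comment line of the
#' form `# units: kcal/mol` is honoured; any other declared unit is
#' refused rather than converted.
#'
#' @param path Path to the table.
#' @return Snapshot-energy data frame for [binding_energy()].
#' @export
read_snapshot_energies <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#")) {
    unit <- sub("^#\\s*units:\\s*", "", first)
    if (trimws(unit) != "kcal/mol") {
      stop("unsupported unit '", trimws(unit), "': tables must be in kcal/mol")
    }
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  ren <- c(e_elec = "e_electrostatic")
  names(df)[names(df) %in% names(ren)] <- ren[names(df)[names(df) %in% names(ren)]]
  needed <- c("snapshot", "time", "role", "e_bonded", "e_electrostatic",
              "e_vdw", "g_polar", "g_nonpolar")
  if (!all(needed %in% names(df))) {
    stop("missing columns: ", paste(setdiff(needed, names(df)), collapse = ", "))
  }
  df
}

#' Write a per-snapshot energy table
#'
#' Inverse of [read_snapshot_energies()]; writes a `# units: kcal/mol`
#' header line.
#'
#' @param snapshots Snapshot-energy data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snapshot_energies <- function(snapshots, path) {
  out <- snapshots
  names(out)[names(out) == "e_electrostatic"] <- "e_elec"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# units: kcal/mol", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-residue decomposition table
#'
#' Tab-separated with columns `chain resnum contribution` (kcal/mol).
#'
#' @param path Path to the table.
#' @return Data frame for [residue_contribution_delta()].
#' @export
read_decomposition <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("chain", "resnum", "contribution")
  if (!all(needed %in% names(df))) {
    stop("missing columns: ", paste(setdiff(needed, names(df)), collapse = ", "))
  }
  df
}

#' Write a per-residue decomposition table
#'
#' @param decomp Decomposition data frame (`chain`, `resnum`,
#'   `contribution`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_decomposition <- function(decomp, path) {
  utils::write.table(decomp[, c("chain", "resnum", "contribution")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an MMPBSA-style comma-separated decomposition export
#'
#' Parses the common end-point decomposition dialect: a section header line
#' (e.g. `Total Energy Decomposition:`), a CSV header starting with
#' `Residue`, and rows like `A:42,...,<total>` where the residue field is
#' `chain:resnum` and the last numeric column is the total contribution in
#' kcal/mol. Only the requested section is read.
#'
#' @param path Path to the file.
#' @param section Section header prefix to read (default
#'   `"Total Energy Decomposition"`).
#' @return Data frame with `chain`, `resnum`, `contribution`.
#' @export
read_mmpbsa_decomposition <- function(path,
                                      section = "Total Energy Decomposition") {
  lines <- readLines(path)
  start <- grep(paste0("^", section), lines)
  if (!length(start)) stop("section not found: ", section)
  body <- lines[(start[1L] + 1L):length(lines)]
  hdr <- grep("^Residue", body)[1L]
  if (is.na(hdr)) stop("no 'Residue' header after section ", section)
  rows <- character(0)
  for (ln in body[(hdr + 1L):length(body)]) {
    if (!nzchar(trimws(ln)) || !grepl(",", ln)) break
    rows <- c(rows, ln)
  }
  fields <- strsplit(rows, ",", fixed = TRUE)
  res <- vapply(fields, `[[`, character(1), 1L)
  total <- vapply(fields, function(f) as.numeric(f[[length(f)]]), numeric(1))
  parts <- do.call(rbind, strsplit(res, ":", fixed = TRUE))
  data.frame(chain = trimws(parts[, 1L]),
             resnum = as.integer(parts[, 2L]),
             contribution = total, stringsAsFactors = FALSE)
}
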