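#' Construct a coordinate frame
#'
#' @param coords Numeric matrix, one row per atom, columns x/y/z in
#'   Angstrom.
#' @param labels Data frame with columns `chain`, `resnum`, `atom`,
#'   `backbone` (logical), one row per atom; rows must be unique.
#' @return Object of class `md_frame`.
#' @export
md_frame <- function(coords, labels) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L, nrow(coords) == nrow(labels),
            all(c("chain", "resnum", "atom", "backbone") %in% names(labels)))
  key <- paste(labels$chain, labels$resnum, labels$atom)
  if (anyDuplicated(key)) stop("atom labels must be unique")
  structure(list(coords = unname(coords), labels = labels),
            class = "md_frame")
}

#' Construct a trajectory
#'
#' @param frames List of [md_frame()] objects sharing labels.
#' @param times Frame times in ps, strictly increasing; defaults to
#'   `1:n`.
#' @return Object of class `md_trajectory`.
#' @export
md_trajectory <- function(frames, times = seq_along(frames)) {
  stopifnot(length(frames) >= 1L, length(times) == length(frames))
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing")
  }
  n <- nrow(frames[[1L]]$coords)
  if (!all(vapply(frames, function(f) nrow(f$coords) == n, logical(1)))) {
    stop("all frames must share atom count")
  }
  structure(list(frames = frames, times = as.numeric(times)),
            class = "md_trajectory")
}

.selection_index <- function(frame, selection = c("backbone", "all_atoms")) {
  selection <- match.arg(selection)
  idx <- if (selection == "backbone") which(frame$labels$backbone)
         else seq_len(nrow(frame$coords))
  if (!length(idx)) stop("empty selection")
  idx
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' two conformations of the same atom set, via SVD of the covariance
#' matrix with a reflection correction so the returned rotation has
#' determinant +1.
#'
#' @param reference,mobile [md_frame()] objects (or bare n-by-3 coordinate
#'   matrices) with matching atoms, n >= 3.
#' @return List with `rotation` (3x3, applied to row vectors on the right),
#'   `translation` (length-3), and `rmsd` (Angstrom). The fitted mobile
#'   coordinates are `mobile %*% rotation + translation` (row-wise).
#' @export
kabsch_superpose <- function(reference, mobile) {
  P <- if (inherits(mobile, "md_frame")) mobile$coords else as.matrix(mobile)
  Q <- if (inherits(reference, "md_frame")) reference$coords else as.matrix(reference)
  stopifnot(nrow(P) == nrow(Q), nrow(P) >= 3L, ncol(P) == 3L, ncol(Q) == 3L)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  # collinear point sets have no unique optimal rotation
  if (svd(Pc, nu = 0, nv = 0)$d[2L] < 1e-8 &&
      svd(Qc, nu = 0, nv = 0)$d[2L] < 1e-8) {
    stop("degenerate geometry: atoms are collinear")
  }
  s <- svd(crossprod(Pc, Qc))              # t(Pc) %*% Qc = U D V'
  d <- sign(det(s$u) * det(s$v))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- Pc %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  list(rotation = R, translation = as.numeric(cq - cp %*% R), rmsd = rmsd)
}

# fitted (or raw) RMSD between two coordinate matrices
.pair_rmsd <- function(ref, mob, fit = TRUE) {
  if (fit) kabsch_superpose(ref, mob)$rmsd
  else sqrt(mean(rowSums((mob - ref)^2)))
}

#' RMSD of every trajectory frame against a reference conformation
#'
#' Each frame is least-squares fitted to the reference over the selected
#' atoms before the deviation is measured (set `fit = FALSE` for the raw,
#' unfitted deviation).
#'
#' @param traj [md_trajectory()].
#' @param reference [md_frame()] sharing the trajectory's labels (typically
#'   the initial structure).
#' @param selection `"backbone"` or `"all_atoms"`.
#' @param fit Superpose before measuring (default `TRUE`).
#' @return List of class `rmsd_series` with `times` (ps), `values`
#'   (Angstrom) and `selection`.
#' @export
rmsd_series <- function(traj, reference, selection = "backbone", fit = TRUE) {
  stopifnot(inherits(traj, "md_trajectory"), inherits(reference, "md_frame"))
  idx <- .selection_index(reference, selection)
  ref <- reference$coords[idx, , drop = FALSE]
  values <- vapply(traj$frames, function(f)
    .pair_rmsd(ref, f$coords[idx, , drop = FALSE], fit = fit), numeric(1))
  structure(list(times = traj$times, values = values, selection = selection),
            class = "rmsd_series")
}

#' Time-normalized difference of areas under two RMSD curves
#'
#' Computes trapezoid areas under the modified and non-modified RMSD
#' series, subtracts them (modified minus non-modified) and divides by the
#' duration. A positive value means the modified complex deviates more
#' from the initial structure on average; the value is close to the
#' difference of the mean RMSDs.
#'
#' @param series_mod,series_nonmod `rmsd_series` objects spanning the same
#'   time interval.
#' @return Difference in Angstrom.
#' @export
rmsd_auc_difference <- function(series_mod, series_nonmod) {
  t1 <- series_mod$times; t2 <- series_nonmod$times
  if (length(t1) < 2L || length(t2) < 2L) stop("series too short")
  if (abs(t1[1L] - t2[1L]) > 1e-9 ||
      abs(t1[length(t1)] - t2[length(t2)]) > 1e-9) {
    stop("mismatched spans: both series must cover the same time interval")
  }
  trap <- function(x, y) sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
  dur <- t1[length(t1)] - t1[1L]
  (trap(t1, series_mod$values) - trap(t2, series_nonmod$values)) / dur
}

#' Gromos (Daura) clustering of trajectory frames
#'
#' Computes the pairwise fitted-RMSD matrix over the selected atoms, then
#' greedily picks the frame with the most neighbors within the cutoff as a
#' cluster center, assigns the center and its neighbors to a cluster,
#' removes them, and repeats until no frames are left. Ties in neighbor
#' count (and in cluster size when sorting) go to the lowest frame index.
#'
#' @param traj [md_trajectory()].
#' @param cutoff Neighbor cutoff in nm (default 0.25, i.e. 2.5 Angstrom,
#'   following the source tool's unit convention).
#' @param selection `"backbone"` or `"all_atoms"` (default: all atoms, the
#'   entire protein including modified residues).
#' @param frames Optional integer vector of frame indices to cluster;
#'   `NULL` clusters the final segment of the trajectory given by
#'   `tail_fraction`.
#' @param tail_fraction Fraction of trailing frames clustered when
#'   `frames` is `NULL` (default 0.5, the last half of the production
#'   phase); use 1 to cluster everything.
#' @return List of class `cluster_result`: `clusters` (list of lists with
#'   `members` and `center`, frame indices into the trajectory, ordered by
#'   decreasing size), `frames` (the clustered indices) and `rmsd_matrix`.
#' @export
gromos_cluster <- function(traj, cutoff = 0.25, selection = "all_atoms",
                           frames = NULL, tail_fraction = 0.5) {
  stopifnot(inherits(traj, "md_trajectory"), cutoff > 0)
  nf <- length(traj$frames)
  if (is.null(frames)) {
    n_keep <- max(1L, ceiling(tail_fraction * nf))
    frames <- seq.int(nf - n_keep + 1L, nf)
  }
  cutoff_A <- cutoff * 10                 # nm -> Angstrom
  idx <- .selection_index(traj$frames[[frames[1L]]], selection)
  coords <- lapply(frames, function(i)
    traj$frames[[i]]$coords[idx, , drop = FALSE])
  n <- length(frames)
  rm <- matrix(0, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      rm[i, j] <- rm[j, i] <- .pair_rmsd(coords[[i]], coords[[j]])
    }
  }
  remaining <- seq_len(n)
  clusters <- list()
  while (length(remaining)) {
    nb <- vapply(remaining, function(i)
      sum(rm[i, remaining] <= cutoff_A), integer(1))  # includes self
    center <- remaining[which.max(nb)]    # which.max takes first = lowest index
    members <- remaining[rm[center, remaining] <= cutoff_A]
    clusters[[length(clusters) + 1L]] <-
      list(members = frames[members], center = frames[center])
    remaining <- setdiff(remaining, members)
  }
  sizes <- vapply(clusters, function(cl) length(cl$members), integer(1))
  centers <- vapply(clusters, function(cl) cl$center, numeric(1))
  clusters <- clusters[order(-sizes, centers)]
  structure(list(clusters = clusters, frames = frames, rmsd_matrix = rm),
            class = "cluster_result")
}

#' Representative frame of the largest cluster
#'
#' @param cl A `cluster_result` from [gromos_cluster()].
#' @return Frame index of the top cluster's center.
#' @export
cluster_representative <- function(cl) {
  stopifnot(inherits(cl, "cluster_result"))
  cl$clusters[[1L]]$center
}

#' Minimum distance of a molecule to its periodic images
#'
#' For an orthorhombic box, checks the 26 nonzero neighbor-cell
#' translations and reports the minimum interatomic distance between the
#' atom set and its translated copy. A distance below the nonbonded cutoff
#' means the molecule can interact with its own periodic image,
#' invalidating downstream energy analysis.
#'
#' @param frame [md_frame()] with all coordinates wrapped into the box
#'   (each coordinate within `[0, edge]`).
#' @param box Numeric length-3 vector of box edge lengths in Angstrom.
#' @param threshold Violation threshold in Angstrom (default 12, a typical
#'   production nonbonded cutoff).
#' @return List with `min_distance` (Angstrom) and `violation` (flag).
#' @export
periodic_image_min_distance <- function(frame, box, threshold = 12) {
  X <- if (inherits(frame, "md_frame")) frame$coords else as.matrix(frame)
  box <- as.numeric(box)
  stopifnot(length(box) == 3L, all(box > 0))
  if (any(X < -1e-9) || any(sweep(X, 2L, box) > 1e-9)) {
    stop("unwrapped_coordinates: atoms outside the box")
  }
  shifts <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  shifts <- shifts[rowSums(abs(shifts)) > 0, , drop = FALSE]
  dmin <- Inf
  for (s in seq_len(nrow(shifts))) {
    tr <- shifts[s, ] * box
    Y <- sweep(X, 2L, tr, "+")
    # min pair distance between X and its translated copy Y
    d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
    dmin <- min(dmin, sqrt(max(0, min(d2))))
  }
  list(min_distance = dmin, violation = dmin < threshold)
}

#' Write a trajectory in labelled-XYZ text format
#'
#' One block per frame: a line `frame <i> time <t> natoms <n>` followed by
#' one line per atom: `chain resnum atom backbone x y z`.
#'
#' @param traj [md_trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  lab <- traj$frames[[1L]]$labels
  for (i in seq_along(traj$frames)) {
    f <- traj$frames[[i]]
    writeLines(sprintf("frame %d time %.6g natoms %d", i, traj$times[i],
                       nrow(f$coords)), con)
    writeLines(sprintf("%s %d %s %d %.6f %.6f %.6f", lab$chain, lab$resnum,
                       lab$atom, as.integer(lab$backbone),
                       f$coords[, 1L], f$coords[, 2L], f$coords[, 3L]), con)
  }
  invisible(path)
}

#' Read a labelled-XYZ trajectory
#'
#' Inverse of [write_xyz_trajectory()].
#'
#' @param path Path to the file.
#' @return [md_trajectory()].
#' @export
read_xyz_trajectory <- function(path) {
  lines <- readLines(path)
  starts <- grep("^frame ", lines)
  frames <- list(); times <- numeric(0)
  for (k in seq_along(starts)) {
    hdr <- strsplit(lines[starts[k]], "\\s+")[[1L]]
    n <- as.integer(hdr[6L])
    times <- c(times, as.numeric(hdr[4L]))
    block <- lines[(starts[k] + 1L):(starts[k] + n)]
    fields <- do.call(rbind, strsplit(block, "\\s+"))
    labels <- data.frame(chain = fields[, 1L],
                         resnum = as.integer(fields[, 2L]),
                         atom = fields[, 3L],
                         backbone = fields[, 4L] == "1",
                         stringsAsFactors = FALSE)
    coords <- matrix(as.numeric(fields[, 5:7]), ncol = 3L)
    frames[[k]] <- md_frame(coords, labels)
  }
  md_trajectory(frames, times)
}
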