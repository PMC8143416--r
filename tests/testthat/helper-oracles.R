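# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Horn's quaternion-based optimal-superposition RMSD
horn_rmsd <- function(ref, mob) {
  Qc <- sweep(ref, 2, colMeans(ref))
  Pc <- sweep(mob, 2, colMeans(mob))
  S <- t(Pc) %*% Qc
  N <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(Pc^2) + sum(Qc^2) - 2 * lam)) / nrow(ref))
}

# brute-force greedy neighbor-counting clustering on a precomputed
# distance matrix (plain loops, no shared code)
brute_gromos <- function(dist_mat, cutoff) {
  n <- nrow(dist_mat)
  remaining <- seq_len(n)
  out <- list()
  while (length(remaining) > 0) {
    best_i <- NA; best_n <- -1
    for (i in remaining) {
      cnt <- 0
      for (j in remaining) if (dist_mat[i, j] <= cutoff) cnt <- cnt + 1
      if (cnt > best_n) { best_n <- cnt; best_i <- i }
    }
    members <- c()
    for (j in remaining) if (dist_mat[best_i, j] <= cutoff) members <- c(members, j)
    out[[length(out) + 1]] <- list(members = members, center = best_i)
    remaining <- setdiff(remaining, members)
  }
  sizes <- sapply(out, function(cl) length(cl$members))
  centers <- sapply(out, function(cl) cl$center)
  out[order(-sizes, centers)]
}

# LCA by intersecting root paths and taking the deepest common node
brute_lca <- function(tree, taxa) {
  path_up <- function(node) {
    p <- character(0)
    while (!is.na(node)) {
      p <- c(p, node)
      node <- tree$parent[match(node, tree$id)]
    }
    p
  }
  common <- Reduce(intersect, lapply(taxa, path_up))
  depth <- sapply(common, function(n) length(path_up(n)))
  common[which.max(depth)]
}

# random rotation matrix (proper) from QR of a Gaussian matrix
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# quick frame builders for conformation tests
toy_labels <- function(n) data.frame(chain = "A", resnum = seq_len(n),
                                     atom = "CA", backbone = TRUE,
                                     stringsAsFactors = FALSE)
toy_frame <- function(coords) md_frame(coords, toy_labels(nrow(coords)))
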