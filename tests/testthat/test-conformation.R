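test_that("Kabsch superposition recovers rigid transforms and matches Horn", {
  withr::with_seed(41, {
    X <- matrix(rnorm(12 * 3, sd = 3), ncol = 3)
  })
  # identical frames: zero RMSD, identity rotation
  fit <- kabsch_superpose(X, X)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)

  # pure translation is removed entirely
  expect_equal(kabsch_superpose(X, sweep(X, 2, c(3, 0, 0), "+"))$rmsd, 0,
               tolerance = 1e-9)

  # 90-degree rotation about z plus per-atom noise: equal to the
  # quaternion-method oracle
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  withr::with_seed(42, {
    Y4 <- matrix(rnorm(12), ncol = 3)
  })
  mobile <- X[1:4, ] %*% Rz + 0.3 * Y4
  k <- kabsch_superpose(X[1:4, ], mobile)
  expect_equal(k$rmsd, horn_rmsd(X[1:4, ], mobile), tolerance = 1e-9)
  expect_equal(det(k$rotation), 1, tolerance = 1e-9)

  # arbitrary rigid transform of a noisy cloud, vs oracle + symmetry
  withr::with_seed(43, {
    for (rep in 1:20) {
      A <- matrix(rnorm(30), ncol = 3)
      B <- A %*% random_rotation() + matrix(rnorm(30, sd = 0.5), ncol = 3)
      expect_equal(kabsch_superpose(A, B)$rmsd, horn_rmsd(A, B),
                   tolerance = 1e-9)
      expect_equal(kabsch_superpose(A, B)$rmsd, kabsch_superpose(B, A)$rmsd,
                   tolerance = 1e-9)
    }
  })

  # the returned transform actually reproduces the fitted RMSD
  moved <- sweep(mobile %*% k$rotation, 2, k$translation, "+")
  expect_equal(sqrt(mean(rowSums((moved - X[1:4, ])^2))), k$rmsd,
               tolerance = 1e-9)

  collinear <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(collinear, collinear), "degenerate")
})

test_that("mirror-image conformations are never matched by a reflection", {
  withr::with_seed(44, X <- matrix(rnorm(30), ncol = 3))
  mirror <- X %*% diag(c(-1, 1, 1))
  fit <- kabsch_superpose(X, mirror)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_gt(fit$rmsd, 0)
})

test_that("RMSD series against the initial structure behaves under fitting", {
  withr::with_seed(45, X <- matrix(rnorm(30, sd = 4), ncol = 3))
  ref <- toy_frame(X)
  same <- md_trajectory(list(toy_frame(X), toy_frame(X)), times = c(1, 2))
  expect_equal(rmsd_series(same, ref, "all_atoms")$values, c(0, 0),
               tolerance = 1e-9)

  shifted <- md_trajectory(list(toy_frame(sweep(X, 2, c(3, 0, 0), "+"))))
  expect_equal(rmsd_series(shifted, ref, "all_atoms", fit = TRUE)$values, 0,
               tolerance = 1e-9)
  expect_equal(rmsd_series(shifted, ref, "all_atoms", fit = FALSE)$values, 3,
               tolerance = 1e-9)

  # fitted RMSD never exceeds the raw deviation
  withr::with_seed(46, {
    frames <- lapply(1:5, function(i)
      toy_frame(X + matrix(rnorm(30, sd = i / 2), ncol = 3)))
  })
  traj <- md_trajectory(frames)
  fitted <- rmsd_series(traj, ref, "all_atoms", fit = TRUE)$values
  raw <- rmsd_series(traj, ref, "all_atoms", fit = FALSE)$values
  expect_true(all(fitted <= raw + 1e-9))
})

test_that("AUC difference is the time-normalized trapezoid area gap", {
  mk <- function(t, v) structure(list(times = t, values = v,
                                      selection = "backbone"),
                                 class = "rmsd_series")
  t <- seq(0, 10000, by = 100)  # 10 ns in ps
  expect_equal(rmsd_auc_difference(mk(t, rep(2, length(t))),
                                   mk(t, rep(1, length(t)))), 1)
  expect_equal(rmsd_auc_difference(mk(t, rep(1.3, length(t))),
                                   mk(t, rep(1.3, length(t)))), 0)
  # linear ramp 0 -> 2 has the same area as the constant 1 (hand trapezoid)
  ramp <- seq(0, 2, length.out = length(t))
  expect_equal(rmsd_auc_difference(mk(t, ramp), mk(t, rep(1, length(t)))), 0,
               tolerance = 1e-12)
  # antisymmetry under swapping the series
  withr::with_seed(47, v1 <- runif(length(t), 0, 3))
  withr::with_seed(48, v2 <- runif(length(t), 0, 3))
  expect_equal(rmsd_auc_difference(mk(t, v1), mk(t, v2)),
               -rmsd_auc_difference(mk(t, v2), mk(t, v1)), tolerance = 1e-12)
  expect_error(rmsd_auc_difference(mk(t, v1), mk(t + 5, v2)), "mismatched")
})

test_that("gromos clustering handles degenerate and well-separated inputs", {
  withr::with_seed(49, X <- matrix(rnorm(15, sd = 2), ncol = 3))
  same <- md_trajectory(lapply(1:6, function(i) toy_frame(X)))
  cl <- gromos_cluster(same, cutoff = 0.25, frames = 1:6)
  expect_length(cl$clusters, 1L)
  expect_equal(sort(cl$clusters[[1]]$members), 1:6)
  expect_equal(cl$clusters[[1]]$center, 1L)  # tie broken by lowest index

  # two tight groups far apart: non-rigid perturbations well beyond cutoff
  withr::with_seed(50, {
    bend <- matrix(rnorm(15, sd = 4), ncol = 3)
    g1 <- lapply(1:4, function(i) toy_frame(X + matrix(rnorm(15, sd = 0.05), ncol = 3)))
    g2 <- lapply(1:3, function(i) toy_frame(X + bend + matrix(rnorm(15, sd = 0.05), ncol = 3)))
  })
  traj <- md_trajectory(c(g1, g2))
  cl2 <- gromos_cluster(traj, cutoff = 0.25, frames = 1:7)
  expect_length(cl2$clusters, 2L)
  expect_equal(sort(cl2$clusters[[1]]$members), 1:4)
  expect_equal(sort(cl2$clusters[[2]]$members), 5:7)
})

test_that("gromos clustering equals the brute-force greedy oracle", {
  withr::with_seed(51, {
    for (rep in 1:20) {
      frames <- lapply(1:10, function(i)
        toy_frame(matrix(rnorm(24, sd = runif(1, 0.5, 2)), ncol = 3)))
      traj <- md_trajectory(frames)
      cl <- gromos_cluster(traj, cutoff = 0.25, frames = 1:10)
      oracle <- brute_gromos(cl$rmsd_matrix, 2.5)
      expect_equal(lapply(cl$clusters, function(x) sort(x$members)),
                   lapply(oracle, function(x) sort(x$members)))
      expect_equal(sapply(cl$clusters, `[[`, "center"),
                   sapply(oracle, `[[`, "center"))
      # partition invariants: sizes non-increasing, frames covered once
      sizes <- sapply(cl$clusters, function(x) length(x$members))
      expect_true(all(diff(sizes) <= 0))
      expect_equal(sort(unlist(lapply(cl$clusters, `[[`, "members"))), 1:10)
    }
  })
})

test_that("clustering defaults to the trailing half of the trajectory", {
  withr::with_seed(52, X <- matrix(rnorm(15, sd = 2), ncol = 3))
  traj <- md_trajectory(lapply(1:10, function(i) toy_frame(X)))
  cl <- gromos_cluster(traj)
  expect_equal(cl$frames, 6:10)
  expect_equal(sort(cl$clusters[[1]]$members), 6:10)
})

test_that("periodic-image distance matches geometry and brute force", {
  centred <- toy_frame(matrix(c(20, 20, 20), 1, 3))
  # md_frame needs >= 1 atom; superposition limit does not apply here
  out <- periodic_image_min_distance(centred, c(40, 40, 40))
  expect_equal(out$min_distance, 40)
  expect_false(out$violation)

  two <- toy_frame(matrix(c(0, 20, 20, 30, 20, 20), 2, 3, byrow = TRUE))
  out2 <- periodic_image_min_distance(two, c(40, 40, 40))
  expect_equal(out2$min_distance, 10)
  expect_true(out2$violation)

  # brute force over all 26 translations and atom pairs
  withr::with_seed(53, cloud <- matrix(runif(150, 5, 30), ncol = 3))
  box <- c(35, 40, 45)
  got <- periodic_image_min_distance(cloud, box)
  brute <- Inf
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    shifted <- sweep(cloud, 2, c(dx, dy, dz) * box, "+")
    for (i in 1:nrow(cloud)) for (j in 1:nrow(cloud)) {
      brute <- min(brute, sqrt(sum((cloud[i, ] - shifted[j, ])^2)))
    }
  }
  expect_equal(got$min_distance, brute, tolerance = 1e-9)

  expect_error(periodic_image_min_distance(
    toy_frame(matrix(c(-1, 5, 5), 1, 3)), c(10, 10, 10)),
    "unwrapped_coordinates")
})

test_that("trajectories survive the labelled-XYZ round trip", {
  tp <- gen_trajectory_pair(generator_config(seed = 9, n_frames = 4,
                                             n_traj_residues = 6))
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz_trajectory(tp$mod, path)
  back <- read_xyz_trajectory(path)
  expect_equal(back$times, tp$mod$times)
  expect_equal(back$frames[[3]]$coords, tp$mod$frames[[3]]$coords,
               tolerance = 1e-5)
  expect_equal(back$frames[[1]]$labels, tp$mod$frames[[1]]$labels)
})
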