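# Coarse-grained trajectory statistics: Rg, SASA, normalization, k-means,
# GROMOS clustering, stability, empirical FRET, interaction statistics,
# contact maps and the nonbonded energy decomposition.

test_that("radius_of_gyration matches hand cases and the direct-sum oracle", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1)), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0))), 1)
  withr::with_seed(10, {
    coords <- matrix(rnorm(150), ncol = 3)
    expect_equal(radius_of_gyration(coords), oracle_rg(coords),
                 tolerance = 1e-12)
  })
  expect_error(radius_of_gyration(matrix(0, 2, 3), integer(0)), "empty")
})

test_that("sasa reproduces analytic spheres and union areas", {
  # isolated bead: probe-expanded sphere area
  one <- sasa(matrix(0, 1, 3), 0.26, probe = 0.14)
  expect_equal(one, 4 * pi * 0.4^2, tolerance = 1e-3)
  # two distant beads: additivity
  two <- sasa(rbind(c(0, 0, 0), c(5, 0, 0)), c(0.26, 0.3), probe = 0.14)
  expect_equal(two, 4 * pi * (0.4^2 + 0.44^2), tolerance = 1e-3)
  # overlapping spheres vs dense-grid oracle
  centers <- rbind(c(0, 0, 0), c(0.45, 0, 0))
  got <- sasa(centers, c(0.26, 0.3), probe = 0.14)
  want <- oracle_union_area(centers, c(0.26, 0.3) + 0.14)
  expect_equal(got, want, tolerance = 0.02)
  expect_error(sasa(matrix(0, 1, 3), NA_real_), "radius")
})

test_that("normalize_series follows the min-max formula", {
  ns <- normalize_series(c(2, 4, 6))
  expect_equal(ns$X_norm, c(0, 0.5, 1))
  withr::with_seed(20, {
    x <- rnorm(200, 5, 3)
    ns <- normalize_series(x)
    expect_equal(ns$X_norm, (x - min(x)) / (max(x) - min(x)))
    expect_true(all(ns$X_norm >= 0 & ns$X_norm <= 1))
    # invertible given stored extremes
    expect_equal(ns$X_norm * (ns$X_max - ns$X_min) + ns$X_min, x)
  })
  expect_error(normalize_series(rep(3, 10)), "constant")
})

test_that("kmeans_states separates blobs and is seed-deterministic", {
  withr::with_seed(30, {
    pts <- rbind(matrix(rnorm(120, 0.1, 0.02), ncol = 2),
                 matrix(rnorm(120, 0.5, 0.02), ncol = 2),
                 matrix(rnorm(120, 0.9, 0.02), ncol = 2))
  })
  truth <- rep(1:3, each = 60)
  km <- kmeans_states(pts, k = 3, seed = 5)
  # perfect recovery up to label permutation
  expect_equal(length(unique(paste(truth, km$assignments))), 3L)
  expect_equal(sort(km$proportions), rep(1 / 3, 3))
  km2 <- kmeans_states(pts, k = 3, seed = 5)
  expect_identical(km$assignments, km2$assignments)
  k1 <- kmeans_states(pts, k = 1, seed = 1)
  expect_equal(k1$proportions, 1)
  expect_error(kmeans_states(pts[1:2, ], k = 3), "at least k")
})

test_that("gromos_cluster groups frames as constructed", {
  # all frames identical -> one cluster with every frame
  f <- matrix(rnorm(30), ncol = 3)
  traj <- bead_trajectory(rep(list(f), 6))
  cl <- gromos_cluster(traj, cutoff = 0.1)
  expect_length(cl$clusters, 1L)
  expect_equal(cl$sizes, 6L)

  # two rigid conformers (straight line vs L-shape), 50/50
  conf_a <- cbind(0:9, 0, 0)
  conf_b <- cbind(c(0:4, rep(4, 5)), c(rep(0, 5), 1:5), 0)
  frames <- c(rep(list(conf_a), 5), rep(list(conf_b), 5))
  cl2 <- gromos_cluster(bead_trajectory(frames), cutoff = 0.5)
  expect_length(cl2$clusters, 2L)
  expect_equal(sort(cl2$sizes), c(5L, 5L))

  # RMSD is invariant to rigid-body motion: rotating+translating a frame
  # keeps it in its cluster
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  frames[[5]] <- conf_a %*% t(R) + matrix(3, 10, 3)
  cl3 <- gromos_cluster(bead_trajectory(frames), cutoff = 0.5)
  expect_equal(sort(cl3$sizes), c(5L, 5L))
})

test_that("gromos auto-cutoff hits the target largest-cluster fraction", {
  sim <- gen_polymer_ensemble(n_beads = 24, compactness = 0.3,
                              n_frames = 40, seed = 12)
  cl <- gromos_cluster(sim$traj, target_fraction = 0.5)
  expect_gte(cl$largest_fraction, 0.45)
  expect_lte(cl$largest_fraction, 0.55)
  expect_error(gromos_cluster(sim$traj, target_fraction = 0.001,
                              tol = 0.001),
               "unreachable")
})

test_that("stability_score measures dispersion of the largest cluster", {
  # 2500 points exactly filling every cell of the 50x50 grid
  centers <- (seq_len(50) - 0.5) / 50
  full <- as.matrix(expand.grid(centers, centers))
  sc <- stability_score(full, rep(1, nrow(full)))
  expect_equal(sc$S, 1)
  expect_equal(sc$stability, log10(2500), tolerance = 1e-12)

  # same N_max, tighter cloud -> strictly larger score
  withr::with_seed(40, {
    loose <- matrix(runif(400, 0, 1), ncol = 2)
    tight <- matrix(runif(400, 0.45, 0.55), ncol = 2)
  })
  expect_gt(stability_score(tight, rep(1, 200))$stability,
            stability_score(loose, rep(1, 200))$stability)

  # single point: S floored at one cell
  sc1 <- stability_score(matrix(c(0.5, 0.5), 1), 1)
  expect_equal(sc1$S, 1 / 2500)
  expect_error(stability_score(matrix(0, 0, 2), integer(0)), "empty")
})

test_that("stability_subsample reports per-fold scores", {
  withr::with_seed(41, pts <- matrix(runif(600), ncol = 2))
  folds <- stability_subsample(pts, rep(1, 300), folds = 3, seed = 2)
  expect_equal(nrow(folds), 3L)
  expect_true(is.finite(attr(folds, "sd")))
  expect_equal(sum(folds$N_max), 300)
})

test_that("empirical_fret matches hand computation and its monotonicity", {
  # 3-frame toy: terminal distance 4, 5, 6 nm
  frames <- lapply(c(4, 5, 6), function(d)
    rbind(c(0, 0, 0), c(1, 1, 1), c(d, 0, 0)))
  traj <- bead_trajectory(frames)
  ef <- empirical_fret(traj, cbind(1L, 3L), alpha = 1)
  expect_equal(ef$d_bar, 5)
  expect_equal(ef$v, 1)                 # sample SD of {4,5,6}
  expect_equal(ef$E_FRET, 1 / 5)

  # rigid trajectory: SD floored, finite score, flagged
  rig <- bead_trajectory(rep(list(frames[[1]]), 4))
  expect_warning(efr <- empirical_fret(rig, cbind(1L, 3L)), "rigid")
  expect_true(is.finite(efr$E_FRET))
  expect_true(efr$floored)

  # equal mean, larger spread -> strictly smaller score
  wide <- lapply(c(3, 5, 7), function(d)
    rbind(c(0, 0, 0), c(1, 1, 1), c(d, 0, 0)))
  ef_wide <- empirical_fret(bead_trajectory(wide), cbind(1L, 3L))
  expect_equal(ef_wide$d_bar, 5)
  expect_lt(ef_wide$E_FRET, ef$E_FRET)

  expect_error(empirical_fret(bead_trajectory(frames[1]), cbind(1L, 3L)),
               "variance")
})

test_that("empirical_fret is invariant to frame order and rigid motion", {
  sim <- gen_polymer_ensemble(n_beads = 12, n_frames = 8, seed = 3)
  pairs <- cbind(1L, 12L)
  e0 <- empirical_fret(sim$traj, pairs)$E_FRET
  perm <- bead_trajectory(sim$traj$frames[sample(8)])
  expect_equal(empirical_fret(perm, pairs)$E_FRET, e0)
  th <- 1.1
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- bead_trajectory(lapply(sim$traj$frames, function(f)
    f %*% t(R) + matrix(rnorm(1), nrow(f), 3)))
  expect_equal(empirical_fret(moved, pairs)$E_FRET, e0, tolerance = 1e-10)
})

test_that("interaction_cutoff matches constructions and the brute-force oracle", {
  # constant geometry: every residue 0.6 nm (6 Angstrom) from the binder
  f <- rbind(c(0, 0, 0), c(0, 0, 0.6))
  traj <- bead_trajectory(rep(list(f), 5))
  ic <- interaction_cutoff(traj, group_A = 1L, residues_A = 1L, group_B = 2L)
  expect_equal(ic$d_cutoff_A, 6)

  # seeded 10-frame, 20-bead toy vs nested-loop oracle
  sim <- gen_polymer_ensemble(n_beads = 16, n_frames = 10, binder_count = 4,
                              binder_residence = 0.6, seed = 8)
  A <- 1:16; B <- 17:20
  got <- interaction_cutoff(sim$traj, A, residues_A = A, group_B = B)
  want <- oracle_cutoff(sim$traj$frames, A, A, B)
  expect_equal(got$d_cutoff_nm, want, tolerance = 1e-12)
  expect_equal(got$d_cutoff_A, 10 * want, tolerance = 1e-12)
  expect_error(interaction_cutoff(sim$traj, integer(0), integer(0), B),
               "non-empty")
})

test_that("interaction_profile matches constructions and the oracle", {
  # binder permanently 0.3 nm from residue 7 only
  chain <- cbind(seq(0, 15), 0, 0)    # beads 1 nm apart
  f <- rbind(chain, c(6, 0.3, 0))     # binder above bead 7 (x = 6)
  traj <- bead_trajectory(rep(list(f), 3))
  prof <- interaction_profile(traj, 1:16, 1:16, 17L, cutoff = 6)
  expect_equal(unname(prof[7]), 1)
  expect_equal(sum(prof), 1)

  # far binder: all-zero profile
  f2 <- rbind(chain, c(100, 100, 100))
  prof0 <- interaction_profile(bead_trajectory(list(f2)), 1:16, 1:16, 17L, 6)
  expect_true(all(prof0 == 0))

  sim <- gen_polymer_ensemble(n_beads = 14, n_frames = 10, binder_count = 5,
                              binder_residence = 0.5, seed = 21)
  got <- interaction_profile(sim$traj, 1:14, 1:14, 15:19, cutoff = 6)
  want <- oracle_profile(sim$traj$frames, 1:14, 1:14, 15:19, 0.6)
  expect_equal(unname(got), unname(want), tolerance = 1e-12)
})

test_that("contact_map is symmetric, bounded, masked near the diagonal", {
  # straight chain, cutoff below bond length: nothing beyond the mask
  chain <- cbind(seq(0, 9), 0, 0)
  cm <- contact_map(bead_trajectory(list(chain)), 1:10, cutoff = 0.5,
                    min_separation = 2)
  expect_true(all(cm[!is.na(cm)] == 0))
  expect_true(all(is.na(diag(cm))))

  # hairpin: ends permanently in contact
  hp <- cbind(c(0, 1, 2, 2, 1, 0), c(0, 0, 0, 0.3, 0.3, 0.3), 0)
  cmh <- contact_map(bead_trajectory(rep(list(hp), 4)), 1:6, cutoff = 0.5)
  expect_equal(cmh[1, 6], 1)
  expect_equal(cmh, t(cmh))

  sim <- gen_polymer_ensemble(n_beads = 10, n_frames = 6, seed = 14)
  cms <- contact_map(sim$traj, 1:10, cutoff = 0.8)
  ok <- !is.na(cms)
  expect_true(all(cms[ok] >= 0 & cms[ok] <= 1))
  expect_equal(cms, t(cms))
})

test_that("nonbonded_energy matches the closed-form pair evaluation", {
  topo <- bead_topology(c("a", "b"), charge = c(1, 1),
                        sigma = c(0.3, 0.5), epsilon = c(2, 4.5))
  fr <- rbind(c(0, 0, 0), c(0.5, 0, 0))
  e <- nonbonded_energy(fr, topo, 1L, 2L)
  want <- oracle_pair_energy(0.5, 1, 1, 0.3, 0.5, 2, 4.5)
  expect_equal(e$E_inter, want, tolerance = 1e-10)
  expect_equal(e$E_AB, want, tolerance = 1e-10)
  expect_equal(e$E_A, 0)

  # beyond cutoff: exactly zero
  fr2 <- rbind(c(0, 0, 0), c(1.2, 0, 0))
  expect_equal(nonbonded_energy(fr2, topo, 1L, 2L)$E_inter, 0)

  # symmetry in group order
  withr::with_seed(50, {
    coords <- matrix(runif(24, 0, 1.5), ncol = 3)
    topo8 <- bead_topology(letters[1:8], charge = rnorm(8, 0, 0.5),
                           sigma = runif(8, 0.3, 0.5),
                           epsilon = runif(8, 1, 4))
  })
  eAB <- nonbonded_energy(coords, topo8, 1:4, 5:8)
  eBA <- nonbonded_energy(coords, topo8, 5:8, 1:4)
  expect_equal(eAB$E_inter, eBA$E_inter, tolerance = 1e-12)

  # overlapping beads raise a singularity error
  fr3 <- rbind(c(0, 0, 0), c(0, 0, 1e-6))
  expect_error(nonbonded_energy(fr3, topo, 1L, 2L), "singular")
})

test_that("decomposition sums pairwise cross terms over multiple beads", {
  withr::with_seed(51, {
    coords <- matrix(runif(18, 0, 1.2), ncol = 3)
    topo6 <- bead_topology(letters[1:6], charge = rnorm(6, 0, 1),
                           sigma = runif(6, 0.3, 0.5),
                           epsilon = runif(6, 1, 4))
  })
  A <- 1:3; B <- 4:6
  e <- nonbonded_energy(coords, topo6, A, B)
  manual <- 0
  for (i in A) for (j in B) {
    r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    manual <- manual + oracle_pair_energy(r, topo6$charge[i], topo6$charge[j],
                                          topo6$sigma[i], topo6$sigma[j],
                                          topo6$epsilon[i], topo6$epsilon[j])
  }
  expect_equal(e$E_inter, manual, tolerance = 1e-10)
})
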