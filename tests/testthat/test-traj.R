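# Superposition, RMSF, DCCM, clustering, distances and hydrogen bonds.

test_that("superposition recovers identity and known rotations", {
  ref <- make_ref_coords(10, seed = 1)
  s <- kabsch_superpose(ref, ref)
  expect_equal(s$rotation, diag(3), tolerance = 1e-12)
  expect_equal(s$rmsd, 0, tolerance = 1e-12)
  rot <- random_rotation(2)
  mob <- ref %*% t(rot) + matrix(rep(c(1, -2, 3), each = 10), 10, 3)
  s2 <- kabsch_superpose(mob, ref)
  expect_lt(s2$rmsd, 1e-10)
  expect_equal(s2$transformed, ref, tolerance = 1e-10)
  expect_equal(det(s2$rotation), 1, tolerance = 1e-12)
  expect_error(kabsch_superpose(ref[1:2, ], ref[1:2, ]), "at least 3")
})

test_that("superposition RMSD agrees with an independent reference fit", {
  # bio3d's fit.xyz is the independent oracle here
  for (seed in 1:5) {
    a <- make_ref_coords(8, seed = seed)
    b <- a + matrix(rnorm(24, sd = 0.5), 8, 3)
    ours <- kabsch_superpose(a, b)$rmsd
    xyz_a <- as.vector(t(a)); xyz_b <- as.vector(t(b))
    fitted <- bio3d::fit.xyz(fixed = xyz_b, mobile = xyz_a,
                             fixed.inds = 1:24, mobile.inds = 1:24)
    theirs <- bio3d::rmsd(fitted, xyz_b)
    expect_equal(ours, theirs, tolerance = 1e-3)  # bio3d rounds to 3 dp
  }
})

test_that("superposition RMSD is invariant to rigid pre-transformation", {
  a <- make_ref_coords(12, seed = 3)
  b <- a + matrix(rnorm(36, sd = 0.8), 12, 3)
  base <- kabsch_superpose(a, b)$rmsd
  for (seed in 4:6) {
    rot <- random_rotation(seed)
    moved <- a %*% t(rot) + matrix(rep(rnorm(3, sd = 10), each = 12), 12, 3)
    expect_equal(kabsch_superpose(moved, b)$rmsd, base, tolerance = 1e-9)
  }
})

test_that("average structure converges and handles symmetric fixtures", {
  ref <- make_ref_coords(6, seed = 5)
  ens_same <- coord_ensemble(array(rep(ref, each = 3), c(3, 6, 3)))
  avg <- average_structure(ens_same)
  expect_equal(avg$average, ref, tolerance = 1e-10, ignore_attr = TRUE)
  # two frames displaced symmetrically about the reference
  d <- matrix(rnorm(18, sd = 0.1), 6, 3)
  co <- array(NA_real_, c(2, 6, 3))
  co[1, , ] <- ref + d; co[2, , ] <- ref - d
  avg2 <- average_structure(coord_ensemble(co))
  expect_equal(avg2$average, ref, tolerance = 0.02, ignore_attr = TRUE)
  # mean shift decreases over iterations on a random ensemble
  ens <- gen_ensemble(make_ref_coords(20, seed = 6), 10, base_amplitude = 0.5,
                      rigid_body = list(angle_sd = 5, trans_sd = 1), seed = 8)
  sh <- average_structure(ens, max_iter = 6, tol = 0)$shifts
  expect_true(all(diff(sh) <= 1e-8))
})

test_that("RMSF matches closed forms and the naive loop", {
  # static ensemble
  ref <- make_ref_coords(5, seed = 7)
  stat <- coord_ensemble(array(rep(ref, each = 4), c(4, 5, 3)))
  attr(stat, "aligned") <- TRUE
  expect_equal(rmsf(stat, group_by = "atom")$rmsf, rep(0, 5))
  # two frames at +/- 1 Angstrom along x for one atom
  co <- array(rep(ref, each = 2), c(2, 5, 3))
  co[1, 3, 1] <- co[1, 3, 1] + 1
  co[2, 3, 1] <- co[2, 3, 1] - 1
  two <- coord_ensemble(co); attr(two, "aligned") <- TRUE
  expect_equal(rmsf(two, group_by = "atom")$rmsf, c(0, 0, 1, 0, 0))
  # vectorised equals the double loop on a 5-atom, 10-frame fixture
  ens <- gen_ensemble(ref, 10, base_amplitude = 0.4, seed = 9)
  attr(ens, "aligned") <- TRUE
  expect_equal(rmsf(ens, group_by = "atom")$rmsf, naive_rmsf(ens$coords),
               tolerance = 1e-12)
  expect_warning(rmsf(gen_ensemble(ref, 3, seed = 1)), "aligned")
})

test_that("RMSF of pure rigid-body motion vanishes after alignment", {
  ens <- gen_ensemble(make_ref_coords(15, seed = 10), 20, base_amplitude = 0,
                      rigid_body = list(angle_sd = 8, trans_sd = 2), seed = 11)
  aligned <- average_structure(ens, max_iter = 20, tol = 1e-12)$ensemble
  expect_lt(max(rmsf(aligned, group_by = "atom")$rmsf), 1e-8)
})

test_that("monomer averaging collapses chains and rejects ragged ones", {
  ref <- make_ref_coords(8, seed = 12)
  ens <- gen_ensemble(ref, 6, base_amplitude = 0.3,
                      chain_ids = rep(c("A", "B"), each = 4),
                      residue_ids = rep(1:4, 2), seed = 13)
  attr(ens, "aligned") <- TRUE
  prof <- rmsf(ens, average_chains = TRUE)
  expect_equal(nrow(prof), 4)
  per_chain <- rmsf(ens)
  expect_equal(prof$rmsf,
               (per_chain$rmsf[per_chain$chain == "A"] +
                  per_chain$rmsf[per_chain$chain == "B"]) / 2)
  ragged <- gen_ensemble(ref, 6, chain_ids = c(rep("A", 5), rep("B", 3)),
                         residue_ids = c(1:5, 1:3), seed = 14)
  attr(ragged, "aligned") <- TRUE
  expect_error(rmsf(ragged, average_chains = TRUE), "unequal")
})

test_that("Welch statistic matches the hand formula and detects shifts", {
  a <- matrix(c(1.0, 1.1, 0.9, 2.0, 2.2, 1.8), nrow = 2, byrow = TRUE)
  b <- matrix(c(1.2, 1.0, 1.1, 2.1, 1.9, 2.0), nrow = 2, byrow = TRUE)
  res <- rmsf_difference_test(a, b)
  va <- var(a[1, ]) / 3; vb <- var(b[1, ]) / 3
  t_hand <- (mean(a[1, ]) - mean(b[1, ])) / sqrt(va + vb)
  expect_equal(res$t[1], t_hand, tolerance = 1e-12)
  # identical replicates: zero-variance flag and p = 1
  same <- matrix(rep(c(1, 2, 3), 5), nrow = 3)
  r0 <- rmsf_difference_test(same, same)
  expect_true(all(r0$zero_var))
  expect_equal(r0$p, rep(1, 3))
  # a 10-SD shift at one residue is detected at p < 0.001
  set.seed(31)
  A <- matrix(rnorm(10 * 5, mean = 1, sd = 0.05), 10, 5)
  B <- matrix(rnorm(10 * 5, mean = 1, sd = 0.05), 10, 5)
  B[4, ] <- B[4, ] + 0.5    # 10 SD
  r1 <- rmsf_difference_test(A, B)
  expect_lt(r1$p[4], 0.001)
  expect_true(all(r1$p_adj >= r1$p))
})

test_that("DCCM has the exact algebraic structure and matches the naive loop", {
  ref <- make_ref_coords(6, seed = 15)
  ens <- gen_ensemble(ref, 20, base_amplitude = 0.5, seed = 16)
  attr(ens, "aligned") <- TRUE
  C <- dccm(ens)
  expect_equal(unclass(C), naive_dccm(ens$coords), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(C, t(C), ignore_attr = TRUE)
  expect_equal(diag(C), rep(1, 6), ignore_attr = TRUE)
  expect_true(all(C >= -1 & C <= 1))
})

test_that("duplicated and negated trajectories give +1 and -1 correlation", {
  ref <- make_ref_coords(3, seed = 17)
  ens <- gen_ensemble(ref, 30, base_amplitude = 0.5, seed = 18)
  co <- ens$coords
  dev <- sweep(co[, 1, , drop = FALSE], c(2, 3),
               apply(co[, 1, , drop = FALSE], c(2, 3), mean))
  co2 <- array(NA_real_, c(30, 5, 3))
  co2[, 1:3, ] <- co
  mu1 <- apply(co[, 1, , drop = FALSE], c(2, 3), mean)
  co2[, 4, ] <- co[, 1, ]                     # duplicate of atom 1
  co2[, 5, ] <- sweep(-dev[, 1, ], 2, as.vector(mu1), "+")  # negated deviations
  ens2 <- coord_ensemble(co2); attr(ens2, "aligned") <- TRUE
  C <- dccm(ens2)
  expect_equal(C[1, 4], 1, tolerance = 1e-12)
  expect_equal(C[1, 5], -1, tolerance = 1e-12)
})

test_that("independent atoms decorrelate and zero-variance atoms are flagged", {
  ref <- make_ref_coords(12, seed = 19)
  ens <- gen_ensemble(ref, 2000, base_amplitude = 0.5, seed = 20)
  attr(ens, "aligned") <- TRUE
  C <- dccm(ens)
  off <- abs(C[upper.tri(C)])
  expect_gte(mean(off < 0.1), 0.99)
  # zero-variance atom
  co <- ens$coords[1:50, 1:4, ]
  co[, 2, ] <- rep(ref[2, ], each = 50)
  enz <- coord_ensemble(co); attr(enz, "aligned") <- TRUE
  Cz <- dccm(enz)
  expect_equal(attr(Cz, "zero_variance"), 2L)
  expect_equal(Cz[2, c(1, 3, 4)], rep(0, 3), ignore_attr = TRUE)
  expect_equal(Cz[2, 2], 1)
})

test_that("block-covariance ensembles recover the prescribed sign structure", {
  ref <- make_ref_coords(20, seed = 21)
  ens <- gen_ensemble(ref, 2000,
                      blocks = list(list(atoms = 1:10, corr = 0.8, sign = 1),
                                    list(atoms = 11:20, corr = 0.8, sign = -1)),
                      seed = 22)
  aligned <- average_structure(ens, max_iter = 2)$ensemble
  C <- dccm(aligned)
  within <- c(C[1:10, 1:10][upper.tri(diag(10))],
              C[11:20, 11:20][upper.tri(diag(10))])
  between <- as.vector(C[1:10, 11:20])
  expect_gt(mean(within), 0.5)
  expect_lt(mean(between), -0.3)
})

test_that("two well-separated bundles cluster cleanly at epsilon 1.5", {
  ref <- make_ref_coords(16, seed = 23)
  pose2 <- ref[9:16, ]; pose2[, 1] <- pose2[, 1] + 10
  ens <- gen_ensemble(ref, 60, base_amplitude = 0.2,
                      orientation_mixture = list(atoms = 9:16, pose = pose2,
                                                 fraction = 0.7),
                      seed = 24)
  cl <- cluster_orientations(ens, substrate_sel = 9:16, fit_sel = 1:8,
                             epsilon = 1.5)
  expect_equal(length(cl$fractions), 2)
  expect_equal(sum(cl$fractions), 1)
  truth <- attr(ens, "pose_labels")
  # cluster labels must reproduce the generating pose partition exactly
  expect_equal(length(unique(cl$labels[truth == 1])), 1)
  expect_equal(length(unique(cl$labels[truth == 2])), 1)
  expect_true(all(sort(cl$fractions, decreasing = TRUE) == cl$fractions))
  expect_equal(cl$labels[cl$medoids[1]], 1)
})

test_that("merge heights equal a brute-force average-linkage agglomeration", {
  ref <- make_ref_coords(10, seed = 25)
  ens <- gen_ensemble(ref, 6, base_amplitude = 1.5, seed = 26)
  cl <- cluster_orientations(ens, substrate_sel = 1:10, fit_sel = 1:10,
                             epsilon = 0.5)
  aligned <- average_structure(ens, fit_sel = 1:10)$ensemble
  flat <- matrix(aligned$coords, nrow = 6)
  dmat <- as.matrix(dist(flat)) / sqrt(10)
  expect_equal(cl$merge_heights, naive_average_linkage_heights(dmat),
               tolerance = 1e-10)
})

test_that("clustering is deterministic and permutation-consistent", {
  ref <- make_ref_coords(12, seed = 27)
  pose2 <- ref[7:12, ]; pose2[, 2] <- pose2[, 2] + 8
  ens <- gen_ensemble(ref, 40, base_amplitude = 0.2,
                      orientation_mixture = list(atoms = 7:12, pose = pose2,
                                                 fraction = 0.75),
                      seed = 28)
  cl1 <- cluster_orientations(ens, 7:12, 1:6, epsilon = 1.5)
  cl2 <- cluster_orientations(ens, 7:12, 1:6, epsilon = 1.5)
  expect_identical(cl1$labels, cl2$labels)
  perm <- rev(seq_len(40))
  ens_p <- coord_ensemble(ens$coords[perm, , ], ens$atom_names,
                          ens$residue_ids, ens$residue_names, ens$chain_ids)
  cl_p <- cluster_orientations(ens_p, 7:12, 1:6, epsilon = 1.5)
  # the induced frame partition is identical under permutation
  same1 <- outer(cl1$labels, cl1$labels, "==")
  same_p <- outer(cl_p$labels[order(perm)], cl_p$labels[order(perm)], "==")
  expect_identical(same1, same_p)
})

test_that("donor-acceptor distances and histograms behave", {
  co <- array(0, c(3, 2, 3))
  co[, 2, 1] <- 3; co[, 2, 2] <- 4
  ens <- coord_ensemble(co)
  da <- donor_acceptor_distances(ens, 1, 2)
  expect_equal(da$distances, rep(5, 3))       # 3-4-5 triangle
  expect_equal(sum(da$histogram$count), 3)
  expect_equal(sum(da$histogram$count > 0), 1)  # degenerate single bin
  ens2 <- gen_ensemble(make_ref_coords(4, seed = 29), 25,
                       base_amplitude = 0.4, seed = 30)
  da2 <- donor_acceptor_distances(ens2, 1, 3)
  expect_equal(sum(da2$histogram$count), 25)
  expect_error(donor_acceptor_distances(ens, 1, 9), "not present")
})

test_that("hydrogen-bond occupancy counts frames meeting both criteria", {
  # donor at origin, H on the donor-acceptor axis: angle 180, distance 2.8
  co <- array(0, c(4, 3, 3))
  co[, 2, 1] <- 1.0        # hydrogen
  co[, 3, 1] <- 2.8        # acceptor
  ens <- coord_ensemble(co)
  expect_equal(hbond_occupancy(ens, donor = 1, acceptor = 3,
                               hydrogen = 2)$occupancy, 1.0)
  # move the acceptor out of range in half the frames
  co2 <- co; co2[c(1, 3), 3, 1] <- 5
  ens2 <- coord_ensemble(co2)
  hb <- hbond_occupancy(ens2, donor = 1, acceptor = 3, hydrogen = 2)
  expect_equal(hb$occupancy, 0.5)
  expect_equal(hb$flags, c(FALSE, TRUE, FALSE, TRUE))
  # all-far geometry
  co3 <- co; co3[, 3, 1] <- 5
  expect_equal(hbond_occupancy(coord_ensemble(co3), 1, 3, 2)$occupancy, 0)
  # angle criterion needs a hydrogen
  expect_error(hbond_occupancy(ens, donor = 1, acceptor = 3), "hydrogen")
  # bent geometry fails the angle cutoff even at short distance
  co4 <- co; co4[, 2, ] <- 0; co4[, 2, 2] <- 1  # H perpendicular
  expect_equal(hbond_occupancy(coord_ensemble(co4), 1, 3, 2)$occupancy, 0)
})
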