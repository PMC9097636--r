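# Superposition, RMSD matrices, RMSF and distance monitors.

test_that("superposition is exact under rigid motion and self-comparison", {
  h <- gen_helix_with_motif(3, 4, 20, "S", n_res = 25)
  expect_lt(superpose_backbone(h, h)$rmsd, 1e-9)
  R <- foxdyn:::rotation_about(c(1, 2, -1), 1.1)
  moved <- foxdyn:::transform_structure(h, R, c(5, -3, 12))
  sp <- superpose_backbone(moved, h)
  expect_lt(sp$rmsd, 1e-9)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  # transformed copy actually lands on the target
  expect_lt(max(abs(foxdyn:::coords_matrix(sp$transformed) -
                      foxdyn:::coords_matrix(h))), 1e-8)
  expect_error(superpose_backbone(h[h$residue_number <= 2, ], h),
               class = "foxdyn_insufficient_atoms")
})

test_that("Kabsch rmsd matches a brute-force rotation-search oracle", {
  for (seed in 1:4) {
    pts <- foxdyn:::with_seed(seed, {
      list(P = matrix(rnorm(12, sd = 2), 4, 3),
           Q = matrix(rnorm(12, sd = 2), 4, 3))
    })
    ours <- superpose_coords(pts$P, pts$Q)$rmsd
    oracle <- bruteforce_min_rmsd(pts$P, pts$Q)
    expect_equal(ours, oracle, tolerance = 1e-4)
    expect_lte(ours, oracle + 1e-8)   # never worse than the search
  }
})

test_that("superposition agrees with bio3d's fitting routine", {
  h <- gen_helix_with_motif(4, 5, 50, "T", n_res = 15)
  jig <- gen_trajectory(h, 2, rigid_amplitude = 4, jitter_sigma = 0.3,
                        seed = 6)
  a <- jig$frames[[1]]; b <- jig$frames[[2]]
  ours <- superpose_backbone(a, b)$rmsd
  sel <- which(a$atom_name %in% c("N", "CA", "C", "O"))
  xyz_a <- as.vector(t(foxdyn:::coords_matrix(a)))
  xyz_b <- as.vector(t(foxdyn:::coords_matrix(b)))
  idx <- as.vector(rbind(3 * sel - 2, 3 * sel - 1, 3 * sel))
  ref <- bio3d::rmsd(xyz_b, xyz_a, a.inds = idx, b.inds = idx, fit = TRUE)
  expect_equal(ours, ref, tolerance = 1e-3)
})

test_that("pairwise RMSD matrices are symmetric with zero diagonal", {
  h <- gen_helix_with_motif(3, 4, 0, "S", n_res = 12)
  same <- list(a = h, b = h, c = h)
  expect_lt(max(pairwise_rmsd_matrix(same)), 1e-9)
  tr <- gen_trajectory(h, 4, rigid_amplitude = 2, jitter_sigma = 0.4,
                       seed = 12)
  m <- pairwise_rmsd_matrix(tr$frames)
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 0))
  expect_true(all(m[upper.tri(m)] > 0))
})

test_that("pairwise RMSD reproduces a constructed optimal-fit residual", {
  # displace each atom of a long straight segment perpendicular to it by
  # alternating +/- delta: centroid and principal axes are unchanged, the
  # optimal superposition is the identity, and the RMSD equals delta.
  n <- 200
  base <- structure_record(rep(c("N", "CA", "C", "O"), n),
                           rep(seq_len(n), each = 4), "ALA",
                           x = seq_len(4 * n) * 0.8,
                           y = rep(0, 4 * n), z = rep(0, 4 * n))
  delta <- 0.25
  shifted <- base
  shifted$y <- shifted$y + rep(c(delta, -delta), length.out = 4 * n)
  m <- pairwise_rmsd_matrix(list(base, shifted))
  expect_equal(m[1, 2], delta, tolerance = 1e-3)
})

test_that("per-residue CA deviation localises a constructed displacement", {
  n <- 200                                 # large rigid anchor
  h <- gen_helix_with_motif(3, 4, 0, "S", n_res = n)
  moved <- h
  i <- which(moved$atom_name == "CA" & moved$residue_number == 50)
  moved$x[i] <- moved$x[i] + 2
  pr <- per_residue_ca_rmsd(list(h, moved, h))
  expect_equal(unname(pr[["50"]]), 2 / sqrt(2), tolerance = 0.02)
  expect_lt(max(pr[names(pr) != "50"]), 0.05)
  # invariant to the order of non-reference models
  pr2 <- per_residue_ca_rmsd(list(h, h, moved))
  expect_equal(unname(pr2[["50"]]), unname(pr[["50"]]), tolerance = 1e-9)
})

test_that("RMSF is zero under rigid motion and scales with jitter", {
  h <- gen_helix_with_motif(3, 4, 0, "S", n_res = 40)
  rigid <- gen_trajectory(h, 40, rigid_amplitude = 8, jitter_sigma = 0,
                          seed = 21)
  expect_lt(max(compute_rmsf(rigid)$rmsf), 1e-9)
  j1 <- gen_trajectory(h, 400, rigid_amplitude = 2, jitter_sigma = 0.1,
                       seed = 22)
  r1 <- compute_rmsf(j1)
  expect_true(all(r1$rmsf > 0))
  expect_equal(median(r1$rmsf), sqrt(3) * 0.1, tolerance = 0.1)
  j2 <- gen_trajectory(h, 400, rigid_amplitude = 2, jitter_sigma = 0.2,
                       seed = 22)
  r2 <- compute_rmsf(j2)
  expect_equal(median(r2$rmsf / r1$rmsf), 2, tolerance = 0.1)
})

test_that("geometry outputs are invariant under global rigid motion", {
  h <- gen_helix_with_motif(3, 4.2, 35, "S", n_res = 20)
  tr <- gen_trajectory(h, 10, rigid_amplitude = 1, jitter_sigma = 0.2,
                       seed = 31)
  R <- foxdyn:::rotation_about(c(0.3, -1, 2), 0.8)
  moved <- as_trajectory(lapply(tr$frames, foxdyn:::transform_structure,
                                rotation = R, translation = c(7, 8, -9)))
  expect_equal(compute_rmsf(moved)$rmsf, compute_rmsf(tr)$rmsf,
               tolerance = 1e-9)
  gt <- attr(h, "ground_truth")
  g0 <- evaluate_motif_geometry(tr, gt$trp, gt$xaa)
  g1 <- evaluate_motif_geometry(moved, gt$trp, gt$xaa)
  expect_equal(g1$d, g0$d, tolerance = 1e-9)
  expect_equal(g1$alpha, g0$alpha, tolerance = 1e-9)
})

test_that("distance monitors read constructed geometries and report errors", {
  rec <- structure_record(c("NZ", "O", "OD1"), c(210, 201, 199),
                          c("LYS", "GLY", "ASP"),
                          x = c(0, 3, 0), y = c(0, 0, 2.8), z = c(0, 0, 0))
  spec <- rbind(distance_spec("d1", 210, "NZ", 201, "O"),
                distance_spec("d5", 199, "OD1", 210, "NZ"))
  frames <- as_trajectory(list(rec, rec, rec))
  mon <- monitor_distances(frames, spec)
  expect_equal(mon$d1$series, rep(3, 3))
  expect_equal(mon$d5$mean, 2.8)
  expect_equal(mon$d1$sd, 0)
  expect_equal(sum(mon$d1$histogram$count), 3)
  # unresolved selector names the monitor and frame
  bad <- distance_spec("d9", 999, "NZ", 201, "O")
  err <- expect_error(monitor_distances(frames, bad),
                      class = "foxdyn_selector_error")
  expect_match(conditionMessage(err), "d9")
  expect_match(conditionMessage(err), "frame 1")
})

test_that("bundled monitor specs exist for all four numbering schemes", {
  for (iso in c("FOXO1", "FOXO3", "FOXO4", "FOXO6")) {
    sp <- foxo_distance_specs(iso)
    expect_equal(sp$label, paste0("d", 1:6))
  }
  sp3 <- foxo_distance_specs("FOXO3")
  expect_equal(sp3$res_a[sp3$label == "d1"], 207)   # Lys207
  expect_equal(sp3$res_b[sp3$label == "d1"], 198)   # Gly198
  sp4 <- foxo_distance_specs("FOXO4")
  expect_equal(sp4$res_b[sp4$label == "d3"], 147)   # Ser147
  spc <- foxo_distance_specs("FOXO1", carbonyl = "C")
  expect_equal(spc$atom_b[spc$label == "d1"], "C")
})
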