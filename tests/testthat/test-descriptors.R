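# Trajectory featurization: centers of mass, distances, RMSD, z-scoring

test_that("center of mass reproduces the mass-weighted formula", {
  coords <- array(0, c(1, 4, 3))
  coords[1, , ] <- rbind(c(0, 0, 0), c(2, 0, 0), c(1, 3, 0), c(0, 0, 4))
  tr <- trajectory_frames(coords, atom_names = c("CA", "C", "N", "CB"),
                          residue_ids = rep(1L, 4),
                          masses = c(12, 12, 14, 16))
  # direct sum(m_i x_i) / sum(m_i) oracle
  w <- c(12, 12, 14, 16)
  expected <- colSums(coords[1, , ] * w) / sum(w)
  expect_equal(drop(center_of_mass_series(tr, 1L)), expected)
  # single atom: COM equals the atom position
  tr1 <- trajectory_frames(array(c(1, 2, 3), c(1, 1, 3)), "CA", 1L)
  expect_equal(drop(center_of_mass_series(tr1, 1L)), c(1, 2, 3))
  # two equal-mass atoms at (0,0,0) and (2,0,0) -> (1,0,0)
  co <- array(0, c(1, 2, 3)); co[1, 2, 1] <- 2
  tr2 <- trajectory_frames(co, c("CA", "CA"), c(1L, 1L), masses = c(1, 1))
  expect_equal(drop(center_of_mass_series(tr2, 1L)), c(1, 0, 0))
  # geometric center when masses are absent
  expect_equal(drop(center_of_mass_series(trajectory_frames(
    coords, c("CA", "C", "N", "CB"), rep(1L, 4)), 1L)),
    colMeans(coords[1, , ]))
  # backbone restriction drops the CB atom
  expect_equal(drop(center_of_mass_series(tr, 1L, "backbone")),
               colSums(coords[1, 1:3, ] * w[1:3]) / sum(w[1:3]))
  expect_error(center_of_mass_series(tr, 99L), "no atoms")
})

test_that("pairwise distances give 15 rows in fixed order with correct values", {
  # residues collapsed to single atoms at hand-placed positions
  pos <- rbind(c(0, 0, 0), c(3, 4, 0), c(10, 0, 0), c(0, 10, 0),
               c(0, 0, 10), c(6, 8, 0))
  coords <- array(0, c(2, 6, 3))
  coords[1, , ] <- pos; coords[2, , ] <- pos + 1  # rigid translation
  tr <- trajectory_frames(coords, rep("CA", 6), 1:6)
  sel <- residue_selection(1:6)
  d <- pairwise_distance_series(tr, sel)
  expect_equal(dim(d), c(15L, 2L))
  expect_equal(rownames(d)[1:3], c("d_1_2", "d_1_3", "d_1_4"))
  # 3-4-5 triangle: residues 1 and 2
  expect_equal(unname(d["d_1_2", 1]), 5)
  # translation invariance
  expect_equal(d[, 1], d[, 2])
  # exhaustive brute-force oracle over all pairs
  pairs <- combn(6, 2)
  oracle <- apply(pairs, 2, function(p) sqrt(sum((pos[p[1], ] - pos[p[2], ])^2)))
  expect_equal(unname(d[, 1]), oracle)
  # coincident residues give all-zero rows
  co0 <- array(0, c(1, 6, 3))
  tr0 <- trajectory_frames(co0, rep("CA", 6), 1:6)
  expect_true(all(pairwise_distance_series(tr0, sel) == 0))
})

test_that("RMSD is zero for frame 0 and invariant to rigid motion", {
  set.seed(9)
  traj <- toy_trajectory(n_frames = 4, jitter = function(fr, f)
    fr + matrix(rnorm(length(fr), sd = 0.3 * (f - 1)), nrow(fr), 3))
  sel <- residue_selection(1:6)
  r <- rmsd_series(traj, sel)
  expect_equal(r[1], 0, tolerance = 1e-10)
  expect_true(all(r >= 0))
  # rigidly moving every frame leaves the best-fit RMSD unchanged
  r2 <- rmsd_series(rigid_transform(traj), sel)
  expect_equal(r, r2, tolerance = 1e-8)
  # a pure rigid translation of frame 0 has RMSD 0 after fitting
  shifted <- toy_trajectory(n_frames = 2, jitter = function(fr, f)
    if (f == 2) fr + 7 else fr)
  expect_equal(rmsd_series(shifted, sel)[2], 0, tolerance = 1e-10)
  # ... but not without fitting
  expect_gt(rmsd_series(shifted, sel, fit = FALSE)[2], 1)
  expect_error(rmsd_series(
    trajectory_frames(array(0, c(1, 2, 3)), c("CA", "CA"), c(1L, 2L)),
    residue_selection(1:6)), "three")
})

test_that("best-fit RMSD agrees with an independent Kabsch implementation", {
  skip_if_not_installed("bio3d")
  set.seed(21)
  # 4-atom toy: one atom displaced, plus random perturbations
  ref <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 1.5, 0), c(0, 0, 1.5))
  for (case in 1:4) {
    moved <- ref + matrix(rnorm(12, sd = 0.4), 4, 3)
    coords <- array(0, c(2, 4, 3))
    coords[1, , ] <- ref; coords[2, , ] <- moved
    tr <- trajectory_frames(coords, rep("CA", 4), c(1L, 2L, 3L, 4L))
    # selection needs 6 residues; use a bespoke 4-atom selection through the
    # low-level path by padding residues is not possible, so superpose the
    # raw coordinate sets directly against bio3d
    fitted <- allodyn:::superpose_coords(moved, ref)
    ours <- sqrt(mean(rowSums((fitted - ref)^2)))
    # bio3d fit.xyz performs the independent Kabsch superposition
    fitted_oracle <- bio3d::fit.xyz(fixed = as.vector(t(ref)),
                                    mobile = as.vector(t(moved)),
                                    fixed.inds = 1:12, mobile.inds = 1:12)
    oracle <- sqrt(mean((fitted_oracle - as.vector(t(ref)))^2) * 3)
    expect_equal(ours, oracle, tolerance = 1e-8)
  }
})

test_that("z-scoring standardizes rows, zeroes constants and is idempotent", {
  m <- rbind(c(1, 2, 3, 4), rep(5, 4), c(-2, 0, 7, 1))
  m <- rbind(m, matrix(rnorm(13 * 4), 13, 4))
  z <- zscore_rows(m)
  # direct formula oracle with sample sd: (1,2,3,4) -> +-1.1619, +-0.3873
  expect_equal(unname(z[1, ]), c(-1.1619, -0.3873, 0.3873, 1.1619),
               tolerance = 1e-4)
  expect_equal(unname(z[1, ]), (m[1, ] - mean(m[1, ])) / sd(m[1, ]))
  # constant row maps to zeros
  expect_true(all(z[2, ] == 0))
  # non-constant rows have mean 0, sd 1
  expect_lt(max(abs(rowMeans(z[-2, ]))), 1e-6)
  expect_lt(max(abs(apply(z[-2, ], 1, sd) - 1)), 1e-6)
  # idempotence on non-constant rows
  expect_equal(zscore_rows(z)[-2, ], z[-2, ], tolerance = 1e-10)
  expect_error(zscore_rows(rbind(c(1, NA))), "finite|two")
  expect_true(isTRUE(attr(z, "normalized")))
})

test_that("assembled descriptor matrix has 16 rows and records metadata", {
  set.seed(4)
  traj <- toy_trajectory(n_frames = 40, jitter = function(fr, f)
    fr + matrix(rnorm(length(fr), sd = 0.2), nrow(fr), 3))
  sel <- residue_selection(1:6, "backbone")
  m <- assemble_descriptor_matrix(traj, sel)
  expect_equal(nrow(m), 16L)
  expect_equal(rownames(m)[1], "RMSD")
  expect_equal(attr(m, "atom_set"), "backbone")
  expect_equal(attr(m, "coverage_ns"), 40 * 0.05)
  expect_true(attr(m, "normalized"))
  # 2000 frames at 0.05 ns -> 100 ns coverage
  expect_equal(2000 * 0.05, 100)
  # identical frames give an all-zero normalized matrix
  const <- toy_trajectory(n_frames = 5)
  expect_true(all(assemble_descriptor_matrix(const, sel) == 0))
  # both atom-set variants share shape and row order
  m2 <- assemble_descriptor_matrix(traj, residue_selection(1:6, "all_atoms"))
  expect_identical(dim(m), dim(m2))
  expect_identical(rownames(m), rownames(m2))
})

test_that("distance rows are invariant under global rotation and translation", {
  set.seed(14)
  traj <- toy_trajectory(n_frames = 6, jitter = function(fr, f)
    fr + matrix(rnorm(length(fr), sd = 0.3), nrow(fr), 3))
  sel <- residue_selection(1:6)
  d1 <- pairwise_distance_series(traj, sel)
  d2 <- pairwise_distance_series(rigid_transform(traj, angle = 1.2), sel)
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("reference-residue mapping recovers identity and survives rigid motion", {
  traj <- toy_trajectory(n_frames = 1)
  ref_res <- c(1L, 2L, 3L, 4L, 5L, 6L)
  # identity: target = reference
  sel <- map_reference_residues(traj, traj, ref_res)
  expect_equal(sel$residue_ids, ref_res)
  # rigidly moved target maps back to the same residues
  moved <- rigid_transform(traj, angle = 0.9, shift = c(12, -5, 3))
  sel2 <- map_reference_residues(moved, traj, ref_res)
  expect_equal(sel2$residue_ids, ref_res)
})

test_that("nearest-residue assignment matches a brute-force distance table", {
  # 8-residue target vs 6-residue reference with hand-placed centers;
  # no shared backbone naming so mapping runs in a common frame
  mk <- function(centers, names_ = "X") {
    n <- nrow(centers)
    trajectory_frames(array(centers, c(1, n, 3)),
                      rep(names_, n), seq_len(n))
  }
  ref_centers <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0),
                       c(10, 10, 0), c(5, 5, 5), c(0, 0, 10))
  set.seed(7)
  tgt_centers <- ref_centers[c(3, 1, 6, 2, 5, 4), ] + 0.4
  tgt_centers <- rbind(tgt_centers, c(50, 50, 50), c(-40, 0, 0))
  target <- mk(tgt_centers)
  reference <- mk(ref_centers)
  sel <- map_reference_residues(target, reference, 1:6)
  # brute-force all-pairs oracle
  oracle <- apply(ref_centers, 1, function(rc)
    which.min(rowSums(sweep(tgt_centers, 2, rc)^2)))
  expect_equal(sel$residue_ids, as.integer(oracle))
  # collision: two reference residues nearest to one target residue
  collide <- mk(rbind(c(0, 0, 0), c(100, 100, 100)))
  expect_error(map_reference_residues(collide, reference, 1:6), "collision")
})

test_that("residue selection enforces six distinct residues", {
  expect_error(residue_selection(1:5), "six")
  expect_error(residue_selection(c(1, 1, 2, 3, 4, 5)), "six")
  expect_silent(residue_selection(c(10, 33, 64, 81, 134, 145)))
})
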