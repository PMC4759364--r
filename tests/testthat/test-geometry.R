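test_that("Kabsch superposition handles exact and transformed copies", {
  set.seed(1)
  pts <- matrix(rnorm(18), 6, 3)
  sp <- kabsch_superpose(pts, pts)
  expect_equal(sp$rmsd, 0, tolerance = 1e-12)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-8)

  R <- rot_axis_angle(c(0, 0, 1), pi / 2)
  moved <- pts %*% t(R) + matrix(c(1, 0, 0), 6, 3, byrow = TRUE)
  sp2 <- kabsch_superpose(moved, pts)
  expect_equal(sp2$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(sp2$rotation), 1, tolerance = 1e-10)
  expect_equal(apply_superposition(moved, sp2), pts, tolerance = 1e-9)

  expect_error(kabsch_superpose(pts, pts[1:5, ]), "mismatch")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "ill-conditioned")
})

test_that("Kabsch matches the rotation-search oracle and never increases RMSD", {
  set.seed(7)
  for (k in 1:20) {
    a <- matrix(rnorm(18), 6, 3)
    b <- matrix(rnorm(18), 6, 3)
    sp <- kabsch_superpose(a, b)
    before <- sqrt(mean(rowSums((sweep(a, 2, colMeans(a) - colMeans(b)) - b)^2)))
    expect_lte(sp$rmsd, before + 1e-12)
    expect_lt(abs(sp$rmsd - oracle_min_rmsd(a, b)), 1e-6)
  }
})

test_that("RMSD series is zero for copies and fit-invariant for rigid moves", {
  frm <- build_hairpin(hairpin_peptide("EF1"))
  traj <- trajectory(list(frm$xyz, frm$xyz, frm$xyz), atoms = frm$atoms)
  rs <- rmsd_series(traj, frm)
  expect_equal(rs$values, rep(0, 3), tolerance = 1e-10)

  shifted <- frm$xyz + matrix(c(1, 0, 0), nrow(frm$xyz), 3, byrow = TRUE)
  R <- rot_axis_angle(c(1, 1, 0), 0.7)
  rotated <- frm$xyz %*% t(R)
  traj2 <- trajectory(list(shifted, rotated), atoms = frm$atoms)
  rs2 <- rmsd_series(traj2, frm)
  expect_equal(rs2$values, c(0, 0), tolerance = 1e-9)
})

test_that("RMSD of a distorted toy frame agrees with the rotation-search oracle", {
  set.seed(11)
  base <- matrix(rnorm(12), 4, 3)
  moved <- base
  moved[4, ] <- moved[4, ] + c(0.3, 0, 0)
  atoms <- data.frame(residue_index = 1:4, residue_name = "GLY",
                      atom_name = "CA", stringsAsFactors = FALSE)
  traj <- trajectory(list(moved), atoms = atoms)
  rs <- rmsd_series(traj, frame(atoms, base), fit_selection = "CA")
  expect_equal(rs$values[1], oracle_min_rmsd(moved, base),
               tolerance = 1e-6)
})

test_that("radius of gyration matches closed forms and is rigid-motion invariant", {
  one <- ca_frame(matrix(c(1, 2, 3), 1, 3))
  expect_equal(radius_of_gyration(one, "CA"), 0)

  two <- ca_frame(rbind(c(0, 0, 0), c(0.2, 0, 0)))
  expect_equal(radius_of_gyration(two, "CA"), 0.1, tolerance = 1e-12)

  s <- 0.37
  square <- ca_frame(rbind(c(0, 0, 0), c(s, 0, 0), c(s, s, 0), c(0, s, 0)))
  expect_equal(radius_of_gyration(square, "CA"), s / sqrt(2),
               tolerance = 1e-12)

  R <- rot_axis_angle(c(0, 1, 0), 1.1)
  moved <- ca_frame(square$xyz %*% t(R) + 5)
  expect_equal(radius_of_gyration(moved, "CA"),
               radius_of_gyration(square, "CA"), tolerance = 1e-12)

  # mass weighting differs from uniform when masses differ
  mix <- frame(data.frame(residue_index = c(1L, 1L),
                          residue_name = "GLY",
                          atom_name = c("N", "O"),
                          stringsAsFactors = FALSE),
               rbind(c(0, 0, 0), c(0.2, 0, 0)))
  rg_m <- radius_of_gyration(mix, "heavy", mass_weighted = TRUE)
  rg_u <- radius_of_gyration(mix, "heavy", mass_weighted = FALSE)
  expect_false(isTRUE(all.equal(rg_m, rg_u)))
  expect_equal(rg_u, 0.1, tolerance = 1e-12)
})

test_that("RMSF recovers per-atom fluctuation amplitudes", {
  frm <- build_hairpin(hairpin_peptide("EF1"))
  static <- trajectory(list(frm$xyz, frm$xyz, frm$xyz), atoms = frm$atoms)
  rf <- rmsf(static)
  expect_true(all(rf$rmsf_nm < 1e-10))
  expect_equal(nrow(rf), 19L)  # one CA per residue

  # one atom oscillating +/- d with others fixed: RMSF = d for that atom
  d <- 0.05
  atoms <- data.frame(residue_index = 1:4, residue_name = "GLY",
                      atom_name = "CA", stringsAsFactors = FALSE)
  base <- rbind(c(0, 0, 0), c(0.4, 0, 0), c(0, 0.4, 0), c(0.2, 0.2, 0.3))
  up <- base; up[4, 3] <- up[4, 3] + d
  dn <- base; dn[4, 3] <- dn[4, 3] - d
  tr <- trajectory(list(up, dn), atoms = atoms)
  rf2 <- rmsf(tr, fit_selection = "CA", target_atoms = "CA",
              fit_residue_range = c(1, 3))
  expect_equal(rf2$rmsf_nm[4], d, tolerance = 1e-9)
  expect_true(all(rf2$rmsf_nm[1:3] < 1e-9))

  expect_error(rmsf(trajectory(list(frm$xyz), atoms = frm$atoms)),
               "2 frames")
})

test_that("RMSF is invariant under a global rigid-body motion of all frames", {
  set.seed(3)
  frm <- build_hairpin(hairpin_peptide("EF1"))
  frames <- lapply(1:4, function(k) frm$xyz + rnorm(length(frm$xyz), 0, 0.01))
  tr <- trajectory(frames, atoms = frm$atoms)
  R <- rot_axis_angle(c(1, 0, 1), 0.9)
  moved <- lapply(frames, function(m) m %*% t(R) + 3)
  tr2 <- trajectory(moved, atoms = frm$atoms)
  expect_equal(rmsf(tr)$rmsf_nm, rmsf(tr2)$rmsf_nm, tolerance = 1e-9)
})

test_that("strand-split RMSF mode reports both strands under an N-side fit", {
  run <- generate_ensembles("EF1", seed = 5, sweeps = 600L)
  traj <- run$trajectories[[1]]
  rf <- rmsf(traj, fit_selection = "main-chain", target_atoms = "CA",
             fit_residue_range = c(1, 10))
  expect_equal(sort(unique(rf$residue_index)), 1:19)
  n_side <- rf$rmsf_nm[rf$residue_index <= 10]
  c_side <- rf$rmsf_nm[rf$residue_index >= 11]
  expect_true(all(is.finite(c(n_side, c_side))))
  # fitting the N strand leaves it tighter than the far strand on average
  expect_lt(mean(n_side), mean(c_side) + 0.5)
})
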