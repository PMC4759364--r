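test_that("built chains reproduce the requested torsions", {
  seqp <- hairpin_peptide("EF1")
  tor <- hairpin_torsions(19)
  frm <- build_hairpin(seqp, tor)
  meas <- measure_torsions(frm)
  expect_equal(meas$phi[2:19], tor$phi[2:19], tolerance = 1e-6)
  expect_equal(meas$psi[1:18], tor$psi[1:18], tolerance = 1e-6)
})

test_that("ideal hairpin closes the register; extended torsions do not", {
  seqp <- hairpin_peptide("EF1")
  frm <- build_hairpin(seqp)
  hb <- hbond_register(seqp)
  lens <- vapply(seq_len(nrow(hb)), function(k) hbond_length(frm, hb[k, ]),
                 numeric(1))
  expect_true(all(lens < 0.25))

  ext <- build_hairpin(seqp, torsion_state(rep(-139, 19), rep(135, 19)))
  lens_ext <- vapply(seq_len(nrow(hb)), function(k)
    hbond_length(ext, hb[k, ]), numeric(1))
  # all register bonds broken; only the turn-adjacent pair (8,11), three
  # residues apart along the chain, stays under 1 nm when extended
  expect_true(all(lens_ext > 0.8))
  expect_true(all(lens_ext[1:6] > 1))

  expect_error(torsion_state(c(0, 200), c(0, 0)))
  expect_error(build_hairpin(seqp, torsion_state(0, 0)))
})

test_that("toy energy rewards the native hairpin and the full census", {
  p <- toy_energy_params()
  ef1 <- hairpin_peptide("EF1")
  ef2 <- hairpin_peptide("EF2")
  e_native <- toy_energy(hairpin_torsions(19), p, ef1)
  e_ext <- toy_energy(torsion_state(rep(-139, 19), rep(135, 19)), p, ef1)
  expect_lt(e_native, e_ext)
  # extended chain: attraction wells disengaged, energy ~ torsion bias only
  expect_gt(e_ext, -1)

  # 8 wells (EF1) bind deeper than 6 wells (EF2) at identical weights
  expect_lt(toy_energy(hairpin_torsions(19), p, ef1),
            toy_energy(hairpin_torsions(19), p, ef2))

  # frame input agrees with torsion input
  e_frame <- toy_energy(build_hairpin(ef1), p, ef1)
  expect_equal(e_frame, e_native, tolerance = 1e-6)
})

test_that("Metropolis sweeps are seed-deterministic and respect the T -> 0 limit", {
  seqp <- hairpin_peptide("EF1")
  p <- toy_energy_params()
  st <- hairpin_torsions(19)
  set.seed(99)
  a <- mc_sweep(st, temperature = 1, params = p, seq = seqp, n_sweeps = 5)
  set.seed(99)
  b <- mc_sweep(st, temperature = 1, params = p, seq = seqp, n_sweeps = 5)
  expect_identical(a$state$phi, b$state$phi)
  expect_identical(a$energy, b$energy)

  # near-zero temperature: energy cannot increase from the proposal chain
  e0 <- toy_energy(st, p, seqp)
  set.seed(1)
  cold <- mc_sweep(st, temperature = 1e-9, params = p, seq = seqp,
                   n_sweeps = 10)
  expect_lte(cold$energy, e0 + 1e-9)
})

test_that("temperature ladders match the packaged protocol and geometric mode", {
  lad <- remd_ladder(mode = "table2")
  expect_equal(lad$n_replicas, 48L)
  expect_equal(lad$temperatures[1], 300)
  expect_equal(lad$temperatures[48], 450.5)
  gaps <- diff(lad$temperatures)
  expect_true(all(gaps >= 2.5 & gaps <= 4))

  geo <- remd_ladder(300, 450.5, 4L)
  ratios <- geo$temperatures[-1] / geo$temperatures[-4]
  expect_equal(max(ratios) - min(ratios), 0, tolerance = 1e-12)
  expect_equal(geo$temperatures[c(1, 4)], c(300, 450.5))
  expect_error(remd_ladder(300, 450, 1L))
})

test_that("replica-exchange bookkeeping is consistent and deterministic", {
  seqp <- hairpin_peptide("EF1")
  p <- toy_energy_params()
  lad <- remd_ladder(300, 400, 4L)
  run <- remd_run(seqp, p, lad, sweeps = 200L, exchange_interval = 10L,
                  seed = 42L, save_stride = 5L)
  expect_true(all(run$exchange_accepts <= run$exchange_attempts))
  # every epoch assigns each replica exactly one temperature
  expect_true(all(apply(run$replica_temperature_history, 1, sort) == 1:4))
  run2 <- remd_run(seqp, p, lad, sweeps = 200L, exchange_interval = 10L,
                   seed = 42L, save_stride = 5L)
  for (t in 1:4) {
    expect_identical(run$trajectories[[t]]$coords,
                     run2$trajectories[[t]]$coords)
  }
  expect_identical(run$replica_temperature_history,
                   run2$replica_temperature_history)
  # burn-in discards the first 10% of sweeps: (200 - 20)/5 frames remain
  expect_equal(n_frames(run$trajectories[[1]]), 36L)
})

test_that("mean energy is non-decreasing in temperature", {
  seqp <- hairpin_peptide("EF1")
  run <- remd_run(seqp, toy_energy_params(), remd_ladder(300, 450.5, 6L),
                  sweeps = 1500L, exchange_interval = 10L, seed = 4L,
                  save_stride = 5L)
  means <- vapply(run$energies, mean, numeric(1))
  expect_gt(means[6], means[1])
  expect_gt(cor(seq_along(means), means, method = "spearman"), 0.5)
})

test_that("swap probability is exact for equal energies and Boltzmann-consistent", {
  expect_equal(swap_probability(1 / 1.0, 1 / 1.5, 5, 5), 1)
  expect_equal(swap_probability(1, 0.5, 2, 1), 1)
  # hotter replica holding lower energy: acceptance < 1
  p <- swap_probability(1, 0.5, 1, 2)
  expect_equal(p, exp((1 - 0.5) * (1 - 2)))
  expect_equal(metropolis_probability(-1, 2), 1)
  expect_equal(metropolis_probability(1, 2), exp(-0.5))
})

test_that("ensemble generation is reproducible and profile-aware", {
  r1 <- generate_ensembles("EF1", seed = 17, sweeps = 300L)
  r2 <- generate_ensembles("EF1", seed = 17, sweeps = 300L)
  expect_identical(r1$trajectories[[1]]$coords, r2$trajectories[[1]]$coords)
  expect_equal(r1$ladder$n_replicas, 8L)
  expect_equal(r1$trajectories[[1]]$temperature, 300)
  # EF2 profile carries its own atom layout (proline has no amide H)
  r3 <- generate_ensembles("EF2", seed = 17, sweeps = 100L)
  at <- r3$trajectories[[1]]$atoms
  expect_false(any(at$residue_index == 12 & at$atom_name == "H"))
})
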