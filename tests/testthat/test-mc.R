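test_that("rotation moves stay in the rotation group and reach the uniform distribution", {
  rs <- rotate_move(diag(3), halfwidth = 0.05, n = 2000, seed = 1)
  o <- rs$orientation
  expect_equal(o %*% t(o), diag(3), tolerance = 1e-12)
  expect_equal(det(o), 1, tolerance = 1e-12)
  # zero-angle limit: identity
  tiny <- rotate_move(diag(3), halfwidth = 1e-9, n = 1, seed = 2)
  expect_equal(tiny$orientation, diag(3), tolerance = 1e-6)
  # equilibration of the z axis to uniform on the sphere (cap counting)
  rs2 <- rotate_move(diag(3), halfwidth = 0.3, n = 2e5, seed = 3)
  z <- rs2$z_axes[1e5:2e5, ]
  for (axis in list(c(0, 0, 1), c(1, 0, 0))) {
    frac <- mean(z %*% axis > 0.5)  # cap of 60 deg: expected 0.25
    expect_lt(abs(frac - 0.25), 0.05)
  }
})

test_that("moves with zero energy change are always accepted", {
  m <- model_spec("patchy")
  b <- box_spec(12)
  cfg <- config_from_positions(rbind(c(2, 2, 2), c(9, 9, 9)), b, m)
  cfg$orientations <- list(diag(3), diag(3))
  tr <- run_mc(cfg, mc_params(n_steps = 500, temperature = 0.5,
                              displacement_halfwidth = 0.045, seed = 4,
                              save_interval = 500))
  acc <- tr$acceptance
  expect_equal(unname(acc$displacement["rate"]), 1)
  expect_equal(unname(acc$rotation["rate"]), 1)
})

test_that("hard-core overlaps are always rejected", {
  m <- model_spec("patchy")
  b <- box_spec(6)
  cfg <- config_from_positions(rbind(c(3, 3, 3), c(3, 3, 4.02)), b, m)
  cfg$orientations <- list(diag(3), diag(3))
  tr <- run_mc(cfg, mc_params(n_steps = 2000, temperature = 0.3,
                              displacement_halfwidth = 0.3, save_interval = 10,
                              seed = 5))
  dmin <- vapply(tr$frames, function(fr) {
    sqrt(sum(minimum_image(fr[1, ] - fr[2, ], b)^2))
  }, numeric(1))
  expect_true(all(dmin >= 1))
})

test_that("a patchy pair samples the Boltzmann bonded fraction from quadrature", {
  m <- model_spec("patchy")
  b <- box_spec(4)
  oracle <- boltzmann_patchy_pair(m, temperature = 0.4, box = b)
  cfg <- lattice_init(m, b, 2 / 64, seed = 1)
  tr <- run_mc(cfg, mc_params(n_steps = 2.5e5, temperature = 0.4,
                              displacement_halfwidth = 0.3,
                              rotation_angle_halfwidth = 0.3,
                              save_interval = 50, seed = 6))
  bonded <- vapply(seq_along(tr$frames), function(i) {
    p <- tr$frames[[i]]; o <- tr$orientation_frames[[i]]
    patchy_pair_energy(minimum_image(p[2, ] - p[1, ], b),
                       matrix(o[1, ], 3, 3, byrow = TRUE),
                       matrix(o[2, ], 3, 3, byrow = TRUE),
                       m$patch)$n_bonds >= 1
  }, logical(1))
  # effective sample size reduced by autocorrelation (conservative factor 25)
  se <- sqrt(oracle$p_bond * (1 - oracle$p_bond) / (length(bonded) / 25))
  expect_lt(abs(mean(bonded) - oracle$p_bond), 3 * se)
})

test_that("incremental energy bookkeeping matches full recomputation", {
  # continuous potential (LJ), where drift could actually accumulate
  m <- model_spec("lj_particle")
  b <- box_spec(8)
  cfg <- lattice_init(m, b, 0.15, seed = 2)
  tr <- run_mc(cfg, mc_params(n_steps = 200, temperature = 0.9,
                              displacement_halfwidth = 0.2, save_interval = 200,
                              seed = 7))
  expect_gt(tr$acceptance$displacement["attempted"], 1e4)
  expect_lt(abs(tr$acceptance$energy - tr$acceptance$energy_recomputed), 1e-8)
  # patchy bookkeeping
  mp <- model_spec("patchy")
  cfgp <- lattice_init(mp, box_spec(7), 0.3, seed = 3)
  trp <- run_mc(cfgp, mc_params(n_steps = 200, temperature = 0.61, seed = 8,
                                save_interval = 200))
  expect_lt(abs(trp$acceptance$energy - trp$acceptance$energy_recomputed), 1e-8)
})

test_that("the MC pressure tensor matches the ideal term plus the MD virial", {
  b <- box_spec(10)
  # ideal gas: pxx = pyy = pzz = rho T
  mi <- model_spec("lj_particle", epsilon = 1e-12)
  cfg <- lattice_init(mi, b, 0.2, seed = 4)
  p <- mc_pressure_tensor(cfg, temperature = 0.8)
  expect_equal(unname(p), rep(0.2 * 0.8, 3), tolerance = 1e-9)
  # frozen LJ configuration: virial parts identical between engines
  m <- model_spec("lj_particle")
  cfg2 <- random_insert(m, b, 0.3, seed = 5)
  tr <- run_md(cfg2, md_params(n_steps = 2000, temperature = 0.65, seed = 9,
                               save_interval = 2000))
  frozen <- tr$config
  p_mc <- mc_pressure_tensor(frozen, temperature = 0.65)
  p_md <- compute_pressure_tensor(frozen)
  kin <- colSums(frozen$velocities^2) / 1000
  ideal <- n_particles(frozen) * 0.65 / 1000
  expect_equal(unname(p_mc - ideal), unname(p_md - kin), tolerance = 1e-10)
})

test_that("the pressure tensor is refused for the discontinuous patchy potential", {
  mp <- model_spec("patchy")
  cfg <- lattice_init(mp, box_spec(7), 0.2, seed = 6)
  expect_error(mc_pressure_tensor(cfg, 0.61), "unsupported model")
  expect_error(compute_pressure_tensor(cfg, 0.61), "unsupported model")
})

test_that("patchy particles condense into a dense domain at low temperature", {
  m <- model_spec("patchy")
  box <- box_spec((250 / 0.36)^(1 / 3))
  cfg <- lattice_init(m, box, 0.36, seed = 7)
  rho_max0 <- max(max_density_series(
    traj_from_frames(list(cfg$positions), box))$max_density)
  reached <- FALSE
  total <- 0
  state <- cfg
  while (total < 5e5 && !reached) {
    tr <- run_mc(state, mc_params(n_steps = 5e4, temperature = 0.61,
                                  save_interval = 1e4, seed = 8 + total))
    total <- total + 5e4
    state <- tr$config
    if (max(max_density_series(tr)$max_density) > 2 * 0.36) reached <- TRUE
  }
  expect_true(reached)
})
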