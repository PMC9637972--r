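test_that("cell-list pair enumeration agrees with brute force, including across the boundary", {
  set.seed(11)
  for (k in 1:25) {
    ar <- sample(c(1, 2), 1)
    b <- box_spec(stats::runif(1, 6, 12), ar)
    n <- sample(20:60, 1)
    pos <- cbind(stats::runif(n, 0, b$Lx), stats::runif(n, 0, b$Ly),
                 stats::runif(n, 0, b$Lz))
    cfg <- config_from_positions(pos, b)
    rc <- stats::runif(1, 1, 0.49 * b$Lx)
    expect_identical(pair_key(neighbor_pairs(cfg, rc)),
                     pair_key(brute_pairs(pos, b, rc)))
  }
  # explicit boundary pair
  b <- box_spec(10)
  cfg <- config_from_positions(rbind(c(0.2, 5, 5), c(9.9, 5, 5)), b)
  expect_equal(nrow(neighbor_pairs(cfg, 1)), 1)
  # particles in a line beyond the cutoff
  cfg2 <- config_from_positions(rbind(c(1, 5, 5), c(2.1, 5, 5), c(3.2, 5, 5)), b)
  expect_equal(nrow(neighbor_pairs(cfg2, 1)), 0)
  expect_error(neighbor_pairs(cfg, 6), "geometry error")
})

test_that("R and C++ total energies agree on random configurations", {
  set.seed(12)
  b <- box_spec(9)
  for (kind in c("lj_particle", "lj_chain", "hp_chain")) {
    m <- model_spec(kind, r_cut = if (kind == "lj_particle") 3 else 4)
    cfg <- random_insert(m, b, 0.1, seed = 21)
    e_cpp <- total_energy(cfg)
    # independent R-level sum over brute-force pairs
    pos <- cfg$positions
    n <- nrow(pos)
    pr <- brute_pairs(pos, b, m$pair$r_cut)
    e_r <- 0
    types <- if (kind == "hp_chain") rep(m$hp_sequence, length.out = n) else rep("H", n)
    for (q in seq_len(nrow(pr))) {
      i <- pr[q, 1]; j <- pr[q, 2]
      if (m$chain_length > 1 &&
          (i - 1) %/% 10 == (j - 1) %/% 10 && abs(i - j) == 1) next
      r <- sqrt(sum(minimum_image(pos[i, ] - pos[j, ], b)^2))
      pp <- if (kind == "hp_chain" && !(types[i] == "H" && types[j] == "H"))
        m$wca else m$pair
      e_r <- e_r + pair_energy(r, pp)
    }
    if (m$chain_length > 1) {
      for (i in seq_len(n - 1)) {
        if ((i - 1) %/% 10 != i %/% 10) next
        r <- sqrt(sum(minimum_image(pos[i, ] - pos[i + 1, ], b)^2))
        e_r <- e_r + bond_energy(r, m$bond)
      }
    }
    expect_equal(e_cpp, e_r, tolerance = 1e-10, label = kind)
  }
})

test_that("energy is conserved without the thermostat", {
  m <- model_spec("lj_particle")
  b <- box_spec(10)
  cfg <- config_from_positions(rbind(c(5, 5, 5), c(5, 5, 5 + 2^(1 / 6) + 0.05)), b,
                               velocities = matrix(0, 2, 3))
  tr <- run_md(cfg, md_params(n_steps = 1e4, friction = 0, temperature = 1,
                              save_interval = 100, relax_steps = 0,
                              cap_steps = 0, seed = 1))
  etot <- tr$pe + tr$ke
  expect_lt(max(abs(etot - etot[1])), 1e-4)
})

test_that("total momentum is conserved without the thermostat", {
  m <- model_spec("lj_particle")
  b <- box_spec(8)
  cfg <- random_insert(m, b, 0.1, seed = 31)
  tr0 <- run_md(cfg, md_params(n_steps = 200, temperature = 0.8, seed = 2,
                               save_interval = 200))
  cfg1 <- tr0$config
  cfg1$velocities <- sweep(cfg1$velocities, 2, colMeans(cfg1$velocities))
  tr <- run_md(cfg1, md_params(n_steps = 2000, friction = 0, temperature = 0.8,
                               save_interval = 2000, relax_steps = 0,
                               cap_steps = 0, seed = 3))
  expect_lt(max(abs(colSums(tr$config$velocities))), 1e-10)
})

test_that("the thermostat gives equipartition at the target temperature", {
  m <- model_spec("lj_particle")
  b <- box_spec(10)
  cfg <- random_insert(m, b, 0.3, seed = 41)
  tr <- run_md(cfg, md_params(n_steps = 3e4, temperature = 0.65,
                              save_interval = 500, seed = 4,
                              pressure_interval = 0))
  t_kin <- mean(tr$ke[tr$steps > 1.5e4]) / (1.5 * 300)  # 2<KE>/3N
  expect_lt(abs(t_kin - 0.65) / 0.65, 0.02)
})

test_that("a free particle follows the underdamped Langevin mean-square displacement", {
  m <- model_spec("lj_particle", epsilon = 1e-12)
  b <- box_spec(40)
  n <- 200
  set.seed(5)
  pos <- cbind(stats::runif(n, 0, 40), stats::runif(n, 0, 40), stats::runif(n, 0, 40))
  cfg <- config_from_positions(pos, b, model = m)
  gamma <- 0.1; T <- 1; tmax <- 5
  tr <- run_md(cfg, md_params(n_steps = 1000, dt = 0.005, temperature = T,
                              friction = gamma, save_interval = 1000,
                              relax_steps = 0, cap_steps = 0, seed = 6,
                              pressure_interval = 0))
  disp <- minimum_image(tr$frames[[1]] - pos, b)
  msd <- mean(rowSums(disp^2)) / 3
  msd_theory <- 2 * T / gamma * (tmax - (1 - exp(-gamma * tmax)) / gamma)
  expect_lt(abs(msd - msd_theory) / msd_theory, 0.12)
})

test_that("the pressure tensor reproduces the ideal-gas law and the pair virial", {
  b <- box_spec(10)
  m <- model_spec("lj_particle", epsilon = 1e-12)
  cfg <- random_insert(m, b, 0.3, seed = 51)
  tr <- run_md(cfg, md_params(n_steps = 4000, temperature = 0.9, seed = 7,
                              save_interval = 4000, relax_steps = 0, cap_steps = 0))
  pr <- tr$pressure[tr$pressure$step > 1000, ]
  p_mean <- mean(c(pr$pxx, pr$pyy, pr$pzz))
  expect_lt(abs(p_mean - 0.27) / 0.27, 0.05)
  # two fixed particles: pxx V = r f(r) exactly
  m1 <- model_spec("lj_particle")
  cfg2 <- config_from_positions(rbind(c(2, 5, 5), c(4.2, 5, 5)), b, m1,
                                velocities = matrix(0, 2, 3))
  pt <- compute_pressure_tensor(cfg2)
  r <- 2.2
  f <- pair_force(r, m1$pair)
  expect_equal(unname(pt["pxx"]) * 1000, r * f, tolerance = 1e-12)
  expect_equal(unname(pt["pyy"]), 0)
})

test_that("an equilibrated homogeneous fluid has an isotropic pressure tensor", {
  m <- model_spec("lj_particle")
  b <- box_spec(8)
  cfg <- random_insert(m, b, 0.5, seed = 61)
  tr <- run_md(cfg, md_params(n_steps = 2e4, temperature = 0.9, seed = 8,
                              save_interval = 2e4))
  pr <- tr$pressure[tr$pressure$step > 1e4, ]
  an <- pr$pzz - (pr$pxx + pr$pyy) / 2
  se <- stats::sd(an) / sqrt(length(an) / 10)  # ~10-sample correlation margin
  expect_lt(abs(mean(an)), 3 * se + 1e-3)
})

test_that("kinetic and configurational temperatures agree for an equilibrated fluid", {
  m <- model_spec("lj_particle")
  b <- box_spec(8)
  cfg <- random_insert(m, b, 0.5, seed = 71)
  tr <- run_md(cfg, md_params(n_steps = 2e4, temperature = 0.9, seed = 9,
                              save_interval = 2000, pressure_interval = 0))
  # T_conf = <|F|^2> / <laplacian U>, laplacian via central differences
  mcpp <- spidec:::model_to_cpp(m, n_particles(cfg))
  L <- c(8, 8, 8)
  set.seed(14)
  t_conf <- sapply(tail(seq_along(tr$frames), 5), function(k) {
    pos <- tr$frames[[k]]
    f <- spidec:::cpp_forces_virial(pos, L, mcpp)$forces
    h <- 1e-4
    sub <- sample(nrow(pos), 30)
    lap <- 0
    for (i in sub) for (a in 1:3) {
      pp <- pos; pp[i, a] <- pp[i, a] + h
      pm <- pos; pm[i, a] <- pm[i, a] - h
      dfa <- (spidec:::cpp_forces_virial(pp, L, mcpp)$forces[i, a] -
                spidec:::cpp_forces_virial(pm, L, mcpp)$forces[i, a]) / (2 * h)
      lap <- lap - dfa
    }
    sum(f[sub, ]^2) / lap
  })
  t_kin <- mean(tail(tr$ke, 5)) / (1.5 * n_particles(cfg))
  expect_lt(abs(mean(t_conf) - t_kin) / t_kin, 0.07)
})

test_that("trajectories are bitwise deterministic per seed", {
  m <- model_spec("lj_particle")
  b <- box_spec(8)
  cfg <- random_insert(m, b, 0.2, seed = 81)
  t1 <- run_md(cfg, md_params(n_steps = 1000, seed = 10, save_interval = 250))
  t2 <- run_md(cfg, md_params(n_steps = 1000, seed = 10, save_interval = 250))
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$config$velocities, t2$config$velocities)
  t3 <- run_md(cfg, md_params(n_steps = 1000, seed = 11, save_interval = 250))
  expect_false(identical(t1$config$positions, t3$config$positions))
})

test_that("spinodal decomposition develops a dense domain from a homogeneous start", {
  m <- model_spec("lj_particle")
  cfg <- random_insert(m, box_spec(10), 0.3, seed = 91)
  tr <- run_md(cfg, md_params(n_steps = 5e4, temperature = 0.65,
                              save_interval = 2000, seed = 12,
                              pressure_interval = 0))
  expect_gt(max(max_density_series(tr)$max_density), 0.6)
})

test_that("a blown-up integration reports the failing step", {
  m <- model_spec("lj_particle")
  b <- box_spec(8)
  cfg <- random_insert(m, b, 0.5, seed = 101)
  # absurd time step with overlapping start and no safeguards
  expect_error(
    run_md(cfg, md_params(n_steps = 2000, dt = 0.5, temperature = 0.65,
                          relax_steps = 0, cap_steps = 0, seed = 13,
                          save_interval = 100)),
    "integration error")
})
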