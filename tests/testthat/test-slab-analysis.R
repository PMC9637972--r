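test_that("density profiles count exactly and flatten for uniform systems", {
  b <- box_spec(10, 2)
  set.seed(21)
  n <- 4000
  pos <- cbind(stats::runif(n, 0, 10), stats::runif(n, 0, 10),
               stats::runif(n, 0, 20))
  prof <- density_profile(list(pos), slice_thickness = 1, recenter = FALSE, box = b)
  # counting invariant: sum(rho * slice volume) = N exactly
  expect_equal(sum(prof$densities * prof$slice_volume), n)
  # uniform within Poisson noise (expected count per slice = 200)
  expect_lt(max(abs(prof$densities - n / 2000)), 5 * sqrt(200) / 100)
  expect_error(density_profile(list(), box = b), "empty")
})

test_that("a synthetic two-phase configuration recovers both plateau densities", {
  b <- box_spec(10, 4)
  set.seed(22)
  frames <- lapply(1:20, function(k) {
    nd <- stats::rpois(1, 0.7 * 100 * 10)   # slab z in [15, 25)
    nb <- stats::rpois(1, 0.05 * 100 * 30)
    rbind(cbind(stats::runif(nd, 0, 10), stats::runif(nd, 0, 10),
                stats::runif(nd, 15, 25)),
          cbind(stats::runif(nb, 0, 10), stats::runif(nb, 0, 10),
                sample(c(stats::runif(nb, 0, 15), stats::runif(nb, 25, 40)), nb)))
  })
  prof <- density_profile(frames, slice_thickness = 0.1, box = b)
  fit <- fit_interface(prof)
  expect_lt(abs(fit$rho_d - 0.7) / 0.7, 0.02)
  expect_lt(abs(fit$rho_b - 0.05) / 0.05, 0.12)
  # consistency: slab counting sees one slab with bracketing cutoffs
  prof1 <- density_profile(frames, slice_thickness = 1, box = b)
  expect_equal(as.integer(count_slabs(prof1, rho_H = 0.55, rho_L = 0.25)), 1L)
})

test_that("recentered profiles are invariant under periodic translation", {
  b <- box_spec(8, 3)
  set.seed(23)
  nd <- 500
  pos <- rbind(cbind(stats::runif(nd, 0, 8), stats::runif(nd, 0, 8),
                     stats::rnorm(nd, 12, 1.5) %% 24),
               cbind(stats::runif(60, 0, 8), stats::runif(60, 0, 8),
                     stats::runif(60, 0, 24)))
  p0 <- density_profile(list(pos), slice_thickness = 0.5, box = b)
  shifted <- pos
  shifted[, 3] <- (shifted[, 3] + 7.123) %% 24
  p1 <- density_profile(list(shifted), slice_thickness = 0.5, box = b)
  expect_lt(mean(abs(p0$densities - p1$densities)), 0.02)
})

test_that("the interface fit recovers exact and noisy tanh parameters", {
  prof <- make_tanh_profile(0.7, 0.05, 10, 2, noise_sd = 0)
  fit <- fit_interface(prof)
  expect_equal(coef(fit), c(rho_d = 0.7, rho_b = 0.05, z0 = 10, w = 2),
               tolerance = 1e-3)
  # noisy replicates: estimates within 3 standard errors almost always
  miss <- 0
  for (k in 1:30) {
    pn <- make_tanh_profile(0.7, 0.05, 10, 2, noise_sd = 0.01, seed = k)
    fn <- fit_interface(pn)
    ok <- abs(fn$rho_d - 0.7) < 3 * fn$se[["rho_d"]] &&
      abs(fn$rho_b - 0.05) < 3 * fn$se[["rho_b"]] &&
      abs(fn$w - 2) < 3 * fn$se[["w"]]
    if (!ok) miss <- miss + 1
  }
  expect_lte(miss, 2)
  # flat, single-phase profile is a degenerate input
  flat <- make_tanh_profile(0.3, 0.3, 10, 2)
  expect_error(fit_interface(flat), "convergence error")
})

test_that("slab counting follows the circular H/L transition rule", {
  expect_equal(as.integer(count_slabs(c(0.7, 0.7, 0.7, 0.7, 0.1, 0.1, 0.1, 0.1))), 1L)
  expect_equal(as.integer(count_slabs(c(0.7, 0.7, 0.1, 0.1, 0.7, 0.7, 0.1, 0.1))), 2L)
  # intermediate slices are filtered out before counting
  expect_equal(as.integer(count_slabs(c(0.7, 0.4, 0.1, 0.4, 0.7, 0.1))), 2L)
  allh <- count_slabs(rep(0.8, 10))
  expect_equal(as.integer(allh), 0L)
  expect_equal(attr(allh, "phase"), "dense")
  alll <- count_slabs(rep(0.05, 10))
  expect_equal(attr(alll, "phase"), "dilute")
  ind <- count_slabs(rep(0.4, 10))
  expect_true(is.na(ind))
  expect_true(attr(ind, "indeterminate"))
  expect_error(count_slabs(c(0.1, 0.9), rho_H = 0.2, rho_L = 0.5))
})

test_that("tau_PS is the first crossing of the max-density plateau", {
  steps <- seq(100, 8000, by = 100)
  rise <- 0.7 * pmin(1, steps / 4000)
  set.seed(24)
  ser <- data.frame(step = steps, max_density = rise + stats::rnorm(80, 0, 0.005))
  tps <- detect_tau_ps(ser)
  expect_true(abs(tps - 4000) <= 400)
  # monotonically rising series has no plateau
  ser2 <- data.frame(step = steps, max_density = steps / 8000)
  tps2 <- detect_tau_ps(ser2)
  expect_true(is.na(tps2))
  expect_false(attr(tps2, "converged"))
})

test_that("tau_SS applies the persistence rule to slab counts", {
  expect_equal(tau_ss_from_counts(c(3, 2, 2, 1, 1, 1, 1, 1, 1), 1:9), 4)
  expect_true(is.na(tau_ss_from_counts(c(3, 2, 2, 2, 2, 2, 2), 1:7)))
  expect_equal(tau_ss_from_counts(c(2, 1, 2, 1, 1, 1, 1, 1), 1:8), 4)
  # a short trailing run qualifies only when it reaches the end
  expect_equal(tau_ss_from_counts(c(2, 2, 1, 1, 1), 1:5), 3)
  expect_true(is.na(tau_ss_from_counts(c(2, 1, 1, 2, 2, 2, 2, 2, 2), 1:9)))
})

test_that("voxel masks classify by periodic spanning dimensionality", {
  for (lab in c("sphere", "cylinder", "slab", "hollow_cylinder",
                "hollow_sphere", "homogeneous_dense", "homogeneous_dilute")) {
    mask <- make_voxel_morphology(lab, c(16, 16, 16))
    expect_equal(as.character(classify_voxel_mask(mask)), lab, label = lab)
  }
  # anisotropic grid, shapes along z
  expect_equal(as.character(classify_voxel_mask(
    make_voxel_morphology("cylinder", c(12, 12, 30)))), "cylinder")
  expect_equal(as.character(classify_voxel_mask(
    make_voxel_morphology("slab", c(12, 12, 30)))), "slab")
  expect_error(make_voxel_morphology("sphere", c(10, 10, 10), radius = 6),
               "impossible geometry")
  # two disconnected balls: largest classified, multiplicity recorded
  m2 <- make_voxel_morphology("sphere", c(20, 20, 20), radius = 4)
  m2[2:3, 2:3, 2:3] <- TRUE
  out <- classify_voxel_mask(m2)
  expect_equal(as.character(out), "sphere")
  expect_equal(attr(out, "multiplicity"), 2L)
})

test_that("interfacial tension reproduces the anisotropy formula and block errors", {
  iso <- data.frame(step = 1:100, pxx = 1, pyy = 1, pzz = 1)
  g0 <- interfacial_tension(iso, Lz = 20, window = 1:100)
  expect_equal(unname(g0["gamma"]), 0)
  an <- data.frame(step = 1:100, pxx = 0.9, pyy = 1.1, pzz = 1.1)
  g1 <- interfacial_tension(an, Lz = 20, window = 1:100)
  expect_equal(unname(g1["gamma"]), 1.0)
  expect_error(interfacial_tension(an, 20, window = integer(0)), "empty")
})

test_that("a homogeneous bulk simulation has zero interfacial tension", {
  m <- model_spec("lj_particle")
  cfg <- random_insert(m, box_spec(8), 0.5, seed = 25)
  tr <- run_md(cfg, md_params(n_steps = 2e4, temperature = 0.9, seed = 26,
                              save_interval = 2e4))
  g <- interfacial_tension(tr$pressure, Lz = 8)
  expect_lt(abs(g[["gamma"]]), 2 * g[["se"]] + 0.01)
})

test_that("chain radius of gyration matches closed forms and unwraps the backbone", {
  b <- box_spec(30)
  m <- model_spec("lj_chain")
  rod <- cbind(10 + 0:9, rep(5, 10), rep(5, 10))
  tr <- traj_from_frames(list(rod), b, m)
  rg <- chain_rg(tr, window = 1)
  expect_equal(rg$mean, sqrt(8.25), tolerance = 1e-12)
  # all beads coincident
  pt <- matrix(5, 10, 3)
  expect_equal(chain_rg(traj_from_frames(list(pt), b, m), window = 1)$mean, 0)
  # a rod crossing the periodic boundary unwraps to the same Rg
  rod2 <- rod
  rod2[, 1] <- (rod2[, 1] + 15) %% 30
  rg2 <- chain_rg(traj_from_frames(list(rod2), b, m), window = 1)
  expect_equal(rg2$mean, sqrt(8.25), tolerance = 1e-12)
})

test_that("weight-fraction conversion follows the mass-per-slice arithmetic", {
  # one molecule of 741.5 Da in a 51.47 x 51.47 x 2 A^3 slice of water at 1 kg/L:
  # mass ratio = (741.5 * 1.66054e-27 kg) / (5297.3 A^3 * 1e-27 kg)
  slice_vol <- 51.47^2 * 2
  expected <- 741.5 * 1.66053906660e-27 / (slice_vol * 1e-27)
  got <- to_weight_fraction(1 / slice_vol, 741.5)
  expect_equal(got, expected, tolerance = 1e-9)
  expect_equal(to_weight_fraction(0, 741.5), 0)
  expect_equal(to_weight_fraction(1 / slice_vol, 2 * 741.5), 2 * expected,
               tolerance = 1e-12)
  expect_error(to_weight_fraction(1, -5), "positive")
  prof <- make_tanh_profile(0.002, 1e-5, 50, 8, box = box_spec(51.47, 5),
                            n_slices = 130)
  wt <- to_weight_fraction(prof, 741.5)
  expect_equal(wt$densities, prof$densities * 741.5 * 1.66053906660)
})
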