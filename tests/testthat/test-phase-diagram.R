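test_that("the critical-point fit recovers exact synthetic binodals", {
  Tc <- 1.085; rc <- 0.317; A <- -0.1; B <- 0.5; beta <- 0.32
  Tv <- seq(0.65, 1.0, length.out = 7)
  mid <- rc + A * (Tv - Tc)
  wid <- B * (Tc - Tv)^beta
  pts <- data.frame(temperature = Tv, rho_b = mid - wid / 2, rho_d = mid + wid / 2)
  fit <- fit_critical_point(pts)
  expect_equal(fit$T_c, Tc, tolerance = 1e-6)
  expect_equal(fit$rho_c, rc, tolerance = 1e-6)
  expect_equal(fit$A, A, tolerance = 1e-5)
  expect_equal(fit$B, B, tolerance = 1e-5)
  # at T = Tc the fitted branches merge at rho_c
  at_tc <- predict(fit, Tc)
  expect_equal(at_tc$rho_b, at_tc$rho_d)
  expect_equal(at_tc$rho_b, rc, tolerance = 1e-6)
  expect_error(fit_critical_point(pts[1:2, ]), "3 temperatures")
})

test_that("noisy binodals are recovered within their standard errors", {
  Tc <- 1.085; rc <- 0.317; A <- -0.1; B <- 0.5
  Tv <- seq(0.65, 1.0, length.out = 8)
  mid <- rc + A * (Tv - Tc)
  wid <- B * (Tc - Tv)^0.32
  set.seed(31)
  miss_tc <- 0
  for (k in 1:25) {
    noise <- function(x) x * (1 + stats::rnorm(length(x), 0, 0.01))
    pts <- data.frame(temperature = Tv,
                      rho_b = noise(mid - wid / 2),
                      rho_d = noise(mid + wid / 2))
    fit <- suppressWarnings(fit_critical_point(pts))
    if (abs(fit$T_c - Tc) > 3 * fit$se[["T_c"]] + 1e-12) miss_tc <- miss_tc + 1
  }
  expect_lte(miss_tc, 3)
})

test_that("morphology boundaries follow the midpoint and tie rules", {
  bd <- boundaries_from_labels(c(0.03, 0.05), c("homogeneous_dilute", "sphere"))
  expect_equal(bd$rho0, 0.04)
  # a full ordered sequence
  rho <- c(0.02, 0.05, 0.1, 0.2, 0.3, 0.5)
  lab <- c("homogeneous_dilute", "sphere", "sphere", "cylinder", "slab", "slab")
  bd2 <- boundaries_from_labels(rho, lab)
  expect_equal(bd2$rho0, c(0.035, 0.15, 0.25))
  expect_equal(bd2$to, c("sphere", "cylinder", "slab"))
  # ambiguous run contributes its own density as the boundary
  bd3 <- boundaries_from_labels(c(0.03, 0.04, 0.05),
                                c("homogeneous_dilute", NA, "sphere"))
  expect_equal(bd3$rho0, 0.04)
  # single label everywhere: no boundaries
  expect_equal(nrow(boundaries_from_labels(rho, rep("slab", 6))), 0)
  expect_warning(
    boundaries_from_labels(c(0.1, 0.2, 0.3), c("cylinder", "sphere", "slab")),
    "non-monotone")
})

test_that("aspect-ratio boundary scaling is recovered exactly from its own model", {
  ar <- c(1, 1.5, 2, 3, 5)
  xi <- ar - 1
  rho <- (0.26 + 0.015 * xi) / (1 + xi)
  fit <- fit_boundary_scaling(ar, rho)
  expect_equal(fit$rho_1, 0.26, tolerance = 1e-10)
  expect_equal(fit$rho_inf, 0.015, tolerance = 1e-10)
  # xi = 0 gives rho_1; xi -> infinity tends to rho_inf
  expect_equal((fit$rho_1 + fit$rho_inf * 0) / (1 + 0), fit$rho_1)
  expect_equal((fit$rho_1 + fit$rho_inf * 1e9) / (1 + 1e9), fit$rho_inf,
               tolerance = 1e-6)
  expect_error(fit_boundary_scaling(c(1, 2), c(0.1, 0.2)), "3 aspect ratios")
  # joint fit with a shared extrapolated density
  r1s <- c(0.04, 0.1375, 0.2625)
  m <- sapply(r1s, function(r1) (r1 + 0.015 * xi) / (1 + xi))
  jf <- fit_boundary_scaling(ar, m, shared_rho_inf = TRUE)
  expect_equal(jf$rho_1, r1s, tolerance = 1e-10)
  expect_equal(jf$rho_inf, 0.015, tolerance = 1e-10)
  expect_equal(length(jf$rho_inf), 1)
})

test_that("van der Waals theory closes at the critical point with a valid Maxwell construction", {
  th <- vdw_theory(c(0.9, 0.999, 1.05))
  # near Tc both curves close at rho_c
  expect_lt(abs(th$rho_b[2] - 1), 0.1)
  expect_lt(abs(th$rho_d[2] - 1), 0.1)
  expect_true(all(is.na(th[3, c("rho_b", "rho_d")])))
  # ordering: binodal outside spinodal, both bracketing rho_c
  expect_true(th$rho_b[1] < th$rho_sp_lo[1])
  expect_true(th$rho_sp_lo[1] < 1 && 1 < th$rho_sp_hi[1])
  expect_true(th$rho_sp_hi[1] < th$rho_d[1])
  # equal pressures on the two branches at T = 0.9 Tc
  press <- function(x, t) x * t / (1 - x / 3) - 9 / 8 * x^2
  expect_lt(abs(press(th$rho_b[1], 0.9) - press(th$rho_d[1], 0.9)), 1e-10)
  expect_equal(press(th$rho_b[1], 0.9), th$pressure[1], tolerance = 1e-10)
})

test_that("Flory-Huggins theory has the symmetric-blend critical point and ordering", {
  L <- 10
  chi_c <- 2 / L
  th <- flory_huggins_theory(L, c(chi_c * 0.9, chi_c * 1.0001, chi_c * 1.5))
  expect_true(all(is.na(th[1, -1])))
  # closure just above chi_c at phi = 1/2
  expect_lt(abs(th$phi_b_lo[2] - 0.5), 0.05)
  # symmetry and ordering
  expect_equal(th$phi_b_lo[3] + th$phi_b_hi[3], 1, tolerance = 1e-10)
  expect_true(th$phi_b_lo[3] < th$phi_sp_lo[3])
  expect_true(th$phi_sp_hi[3] < th$phi_b_hi[3])
})

test_that("scaled-down binodal and tension series behave monotonically toward Tc", {
  m <- model_spec("lj_particle")
  b <- box_spec(7, 3)
  temps <- c(0.65, 0.8, 0.95)
  pts <- NULL
  for (Tk in temps) {
    cfg <- random_insert(m, b, 0.3, seed = 200 + round(100 * Tk))
    tr <- run_md(cfg, md_params(n_steps = 6e4, temperature = Tk,
                                save_interval = 3000,
                                seed = 300 + round(100 * Tk)))
    pts <- rbind(pts, phase_point(tr, temperature = Tk))
  }
  wid <- pts$rho_d - pts$rho_b
  expect_true(all(diff(wid) < 0))
  expect_true(all(pts$rho_d > pts$rho_b))
  # interfacial tension decreases toward the critical temperature
  expect_true(all(diff(pts$gamma) < 0))
  expect_true(pts$gamma[1] > 0)
})

test_that("MD and MC coexistence densities agree for LJ particles", {
  m <- model_spec("lj_particle")
  b <- box_spec(7, 3)
  Tk <- 0.8
  cfg <- random_insert(m, b, 0.3, seed = 401)
  trmd <- run_md(cfg, md_params(n_steps = 8e4, temperature = Tk,
                                save_interval = 4000, seed = 402,
                                pressure_interval = 0))
  pmd <- phase_point(trmd, temperature = Tk)
  # MC sampling of the same coexistence, started from the equilibrated slab
  # (both engines must hold the same stationary two-phase state)
  cfg2 <- trmd$config
  cfg2$velocities <- NULL
  trmc <- run_mc(cfg2, mc_params(n_steps = 4e4, temperature = Tk,
                                 displacement_halfwidth = 0.25,
                                 save_interval = 2000, seed = 404))
  pmc <- phase_point(trmc, temperature = Tk)
  expect_lt(abs(pmd$rho_d - pmc$rho_d), 0.06)
  expect_lt(abs(pmd$rho_b - pmc$rho_b), 0.05)
})
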