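#' Coexistence densities (and tension) from one slab trajectory
#'
#' Applies the standard averaging rule (second half of the trajectory, or
#' post-fusion window when slab fusion completes late, see
#' [analysis_window()]), computes the recentered fine density profile, fits
#' the interface, and — when a pressure series is present — the
#' Kirkwood-Buff interfacial tension over the matching sample window.
#'
#' @param traj a \code{spidec_traj} showing a slab.
#' @param temperature the run temperature (recorded in the output).
#' @param axis slab normal.
#' @param rho_H,rho_L slab-counting cutoffs for the window rule.
#' @return A one-row data.frame (class \code{"phase_point"} kept as plain
#'   data): \code{temperature}, \code{rho_b}, \code{rho_d}, \code{w},
#'   \code{gamma}, \code{gamma_se}.
#' @export
phase_point <- function(traj, temperature = traj$params$temperature,
                        axis = "z", rho_H = 0.55, rho_L = 0.25) {
  win <- analysis_window(traj, rho_H, rho_L)
  prof <- density_profile(traj, axis = axis, slice_thickness = 0.1, window = win)
  fit <- fit_interface(prof)
  gamma <- gamma_se <- NA_real_
  if (!is.null(traj$pressure) && nrow(traj$pressure) > 0 && traj$engine == "md") {
    frac0 <- (win[1] - 1) / length(traj$frames)
    pwin <- seq(floor(frac0 * nrow(traj$pressure)) + 1, nrow(traj$pressure))
    g <- interfacial_tension(traj$pressure, traj$box$Lz, window = pwin)
    gamma <- g[["gamma"]]; gamma_se <- g[["se"]]
  }
  data.frame(temperature = temperature, rho_b = fit$rho_b, rho_d = fit$rho_d,
             w = fit$w, gamma = gamma, gamma_se = gamma_se)
}

#' Fit the critical point of a binodal
#'
#' Joint least squares of the coexistence densities against the
#' rectilinear-diameter law and the order-parameter scaling law
#' \deqn{(\rho_b + \rho_d)/2 = \rho_c + A (T - T_c)}
#' \deqn{\rho_d - \rho_b = B (T_c - T)^\beta}
#' with the 3-D Ising exponent fixed at \eqn{\beta = 0.32}. Both equations
#' share \eqn{T_c} and are fit simultaneously. Temperatures within 2% of the
#' running \eqn{T_c} estimate are excluded (profiles too close to critical
#' are unreliable) and the fit repeated once.
#'
#' @param points data.frame with columns \code{temperature}, \code{rho_b},
#'   \code{rho_d} (e.g. rows from [phase_point()]).
#' @param beta_exponent order-parameter exponent (fixed, not fitted).
#' @return Object of class \code{"critical_fit"}: \code{T_c}, \code{rho_c},
#'   \code{A}, \code{B}, \code{beta_exponent}, \code{se} (named), \code{used}
#'   (logical row mask).
#' @export
fit_critical_point <- function(points, beta_exponent = 0.32) {
  if (nrow(points) < 3) stop("need at least 3 temperatures to fit the critical point")
  d <- points[order(points$temperature), ]
  width <- d$rho_d - d$rho_b
  if (any(diff(width) > 0))
    warning("fit warning: rho_d - rho_b is not monotonically decreasing in T")
  do_fit <- function(dd) {
    Tv <- dd$temperature
    dia <- (dd$rho_b + dd$rho_d) / 2
    wid <- dd$rho_d - dd$rho_b
    resid_fun <- function(th) {
      Tc <- th[1]; rc <- th[2]; A <- th[3]; B <- th[4]
      dtc <- pmax(Tc - Tv, 0)
      c(dia - (rc + A * (Tv - Tc)),
        wid - B * dtc^beta_exponent)
    }
    # for fixed Tc both equations are linear: profile the 1-D Tc objective
    solve_given_Tc <- function(Tc) {
      cfd <- stats::lm.fit(cbind(1, Tv - Tc), dia)$coefficients
      B <- sum(wid * (Tc - Tv)^beta_exponent) / sum((Tc - Tv)^(2 * beta_exponent))
      unname(c(Tc, cfd[1], cfd[2], B))
    }
    obj_Tc <- function(Tc) sum(resid_fun(solve_given_Tc(Tc))^2)
    rng <- diff(range(Tv))
    op <- stats::optimize(obj_Tc, c(max(Tv) + 1e-8 * max(rng, 1), max(Tv) + 10 * rng),
                          tol = 1e-12)
    th <- solve_given_Tc(op$minimum)
    # standard errors from the Jacobian at the optimum
    r0 <- resid_fun(th)
    nres <- length(r0)
    J <- matrix(NA_real_, nres, 4)
    h <- pmax(abs(th), 1) * 1e-6
    for (k in 1:4) {
      tp <- th; tp[k] <- tp[k] + h[k]
      tm <- th; tm[k] <- tm[k] - h[k]
      J[, k] <- (resid_fun(tp) - resid_fun(tm)) / (2 * h[k])
    }
    s2 <- sum(r0^2) / max(1, nres - 4)
    cv <- tryCatch(s2 * solve(crossprod(J)), error = function(e) matrix(NA, 4, 4))
    list(par = th, se = sqrt(pmax(diag(cv), 0)))
  }
  f1 <- do_fit(d)
  used <- d$temperature < 0.98 * f1$par[1]
  f <- if (sum(used) >= 3 && any(!used)) do_fit(d[used, ]) else f1
  if (sum(used) < 3) used <- rep(TRUE, nrow(d))
  names(f$se) <- c("T_c", "rho_c", "A", "B")
  structure(list(T_c = f$par[1], rho_c = f$par[2], A = f$par[3], B = f$par[4],
                 beta_exponent = beta_exponent, se = f$se, used = used,
                 points = d),
            class = "critical_fit")
}

#' @export
print.critical_fit <- function(x, ...) {
  cat(sprintf("<critical_fit> T_c = %.4g (se %.2g), rho_c = %.4g (se %.2g), A = %.3g, B = %.3g, beta = %.2f\n",
              x$T_c, x$se[["T_c"]], x$rho_c, x$se[["rho_c"]], x$A, x$B,
              x$beta_exponent))
  invisible(x)
}

#' @export
coef.critical_fit <- function(object, ...) {
  c(T_c = object$T_c, rho_c = object$rho_c, A = object$A, B = object$B)
}

#' Predicted coexistence densities from a critical fit
#' @param object a \code{critical_fit}.
#' @param temperature temperatures at which to evaluate.
#' @param ... unused.
#' @return data.frame with \code{temperature}, \code{rho_b}, \code{rho_d}.
#' @export
predict.critical_fit <- function(object, temperature, ...) {
  dtc <- pmax(object$T_c - temperature, 0)
  mid <- object$rho_c + object$A * (temperature - object$T_c)
  wid <- object$B * dtc^object$beta_exponent
  data.frame(temperature = temperature, rho_b = mid - wid / 2, rho_d = mid + wid / 2)
}

#' Morphology boundaries from a labeled density scan
#'
#' Boundaries between adjacent differing labels are taken at the midpoint of
#' the two densities; a run whose label is ambiguous (\code{NA}) contributes
#' its own density as the boundary between its neighbours' labels. A label
#' sequence that is non-monotone in the canonical morphology order triggers
#' a consistency warning naming the offending densities.
#'
#' @param rho0 ordered initial densities.
#' @param labels morphology labels (character; \code{NA} = ambiguous).
#' @return data.frame with \code{from}, \code{to}, \code{rho0} per boundary.
#' @export
boundaries_from_labels <- function(rho0, labels) {
  o <- order(rho0)
  rho0 <- rho0[o]; labels <- labels[o]
  ord <- match(labels, .morphology_levels)
  if (any(diff(ord[!is.na(ord)]) < 0)) {
    bad <- rho0[!is.na(ord)][which(diff(ord[!is.na(ord)]) < 0) + 1]
    warning(sprintf("consistency warning: non-monotone morphology sequence near rho0 = %s",
                    paste(signif(bad, 4), collapse = ", ")))
  }
  out <- data.frame(from = character(0), to = character(0), rho0 = numeric(0))
  i <- 1
  while (i < length(rho0)) {
    if (is.na(labels[i])) { i <- i + 1; next }
    # next defined label
    j <- i + 1
    while (j <= length(rho0) && is.na(labels[j])) j <- j + 1
    if (j > length(rho0)) break
    if (labels[j] != labels[i]) {
      bd <- if (j == i + 1) (rho0[i] + rho0[j]) / 2 else mean(rho0[(i + 1):(j - 1)])
      out <- rbind(out, data.frame(from = labels[i], to = labels[j], rho0 = bd))
    }
    i <- j
  }
  out
}

#' Scan initial densities for dense-phase morphologies
#'
#' Runs one short simulation per (aspect ratio, initial density, seed) at
#' the given temperature, classifies the post-separation morphology (majority
#' over seeds; a tie marks the run ambiguous, assigning its density as the
#' boundary), and locates the inter-morphology boundaries by the midpoint
#' rule. The lowest and highest boundaries are the effective spinodal
#' densities. Runs are long enough to pass the phase-separation time: after
#' \code{n_steps} the max-density plateau is checked and the run extended
#' once if still coarsening.
#'
#' @param model a [model_spec()] (\code{lj_particle}/chain models use MD;
#'   \code{patchy} uses MC).
#' @param Lx box side (x and y).
#' @param temperature run temperature.
#' @param density_grid ordered initial densities to scan.
#' @param Lz_over_Lx aspect ratio(s); one scan per ratio.
#' @param seeds integer seeds for the majority vote.
#' @param n_steps steps per run (MD steps or MC sweeps).
#' @param save_interval frames cadence for classification.
#' @param dt MD time step; default per system kind.
#' @param verbose print one line per run.
#' @return Object of class \code{"morphology_scan"}: \code{rows} (data.frame
#'   \code{Lz_over_Lx}, \code{rho0}, \code{label}, \code{ambiguous}),
#'   \code{boundaries} (per aspect ratio), \code{spinodal} (lowest/highest
#'   boundary per ratio).
#' @export
scan_boundaries <- function(model, Lx, temperature, density_grid,
                            Lz_over_Lx = 1, seeds = 1:3,
                            n_steps = 1e5, save_interval = 2000,
                            dt = default_dt(model), verbose = FALSE) {
  stopifnot(!is.unsorted(density_grid))
  rows <- NULL
  for (ar in Lz_over_Lx) {
    box <- box_spec(Lx, ar)
    for (rho0 in density_grid) {
      labs <- character(0)
      for (sd in seeds) {
        lab <- run_and_classify(model, box, rho0, temperature, sd,
                                n_steps, save_interval, dt)
        labs <- c(labs, lab)
        if (verbose)
          message(sprintf("scan: Lz/Lx=%.3g rho0=%.4g seed=%d -> %s", ar, rho0, sd, lab))
      }
      tab <- sort(table(labs), decreasing = TRUE)
      ambiguous <- length(tab) > 1 && tab[1] == tab[2]
      rows <- rbind(rows, data.frame(
        Lz_over_Lx = ar, rho0 = rho0,
        label = if (ambiguous) NA_character_ else names(tab)[1],
        ambiguous = ambiguous))
    }
  }
  boundaries <- lapply(split(rows, rows$Lz_over_Lx), function(rr)
    boundaries_from_labels(rr$rho0, rr$label))
  spinodal <- lapply(boundaries, function(b)
    if (nrow(b)) c(lower = min(b$rho0), upper = max(b$rho0)) else c(lower = NA, upper = NA))
  structure(list(rows = rows, boundaries = boundaries, spinodal = spinodal,
                 model = model$system_kind, temperature = temperature, Lx = Lx),
            class = "morphology_scan")
}

run_and_classify <- function(model, box, rho0, temperature, seed,
                             n_steps, save_interval, dt) {
  if (model$system_kind == "patchy") {
    cfg <- lattice_init(model, box, rho0, seed = seed)
    tr <- run_mc(cfg, mc_params(n_steps = n_steps, temperature = temperature,
                                save_interval = save_interval, seed = seed))
  } else {
    cfg <- random_insert(model, box, rho0, seed = seed)
    tr <- run_md(cfg, md_params(dt = dt, temperature = temperature,
                                n_steps = n_steps, save_interval = save_interval,
                                pressure_interval = 0, seed = seed))
    tps <- suppressWarnings(tryCatch(detect_tau_ps(tr), error = function(e) NA))
    if (!is.na(tps) && !isTRUE(attr(tps, "converged"))) {
      # still coarsening: extend once
      tr2 <- run_md(tr$config, md_params(dt = dt, temperature = temperature,
                                         n_steps = n_steps, save_interval = save_interval,
                                         pressure_interval = 0, seed = seed + 1000L,
                                         relax_steps = 0, cap_steps = 0))
      tr <- tr2
    }
  }
  as.character(classify_morphology(tr))
}

#' @export
print.morphology_scan <- function(x, ...) {
  cat(sprintf("<morphology_scan> %s at T = %.3g, Lx = %.3g; %d runs\n",
              x$model, x$temperature, x$Lx, nrow(x$rows)))
  for (ar in names(x$boundaries)) {
    b <- x$boundaries[[ar]]
    if (nrow(b))
      cat(sprintf("  Lz/Lx = %s: %s\n", ar,
                  paste(sprintf("%s->%s @ %.4g", b$from, b$to, b$rho0), collapse = ", ")))
  }
  invisible(x)
}

#' Aspect-ratio scaling of morphology boundaries
#'
#' Fits boundary densities across box aspect ratios to
#' \deqn{\rho_0(\xi) = \frac{\rho_1 + \rho_\infty \xi}{1 + \xi}, \qquad
#'   \xi = L_z/L_x - 1}
#' by linear least squares in the basis \eqn{1/(1+\xi)}, \eqn{\xi/(1+\xi)}.
#' With \code{shared_rho_inf}, several transitions are fit jointly with a
#' common extrapolated density \eqn{\rho_\infty} (per-transition
#' \eqn{\rho_1}), the form in which the lower (or upper) boundaries share
#' one infinite-box spinodal density.
#'
#' @param Lz_over_Lx aspect ratios (>= 3 values).
#' @param rho0 boundary densities; a vector (one transition) or a matrix /
#'   data.frame with one column per transition.
#' @param shared_rho_inf fit a common \eqn{\rho_\infty} across columns.
#' @return Object of class \code{"boundary_scaling"} with \code{rho_1}
#'   (per transition), \code{rho_inf} (scalar if shared, else per
#'   transition), and \code{fitted}.
#' @export
fit_boundary_scaling <- function(Lz_over_Lx, rho0, shared_rho_inf = FALSE) {
  xi <- Lz_over_Lx - 1
  if (length(unique(Lz_over_Lx)) < 3) stop("need at least 3 aspect ratios")
  m <- as.matrix(rho0)
  nt <- ncol(m)
  b1 <- 1 / (1 + xi)
  b2 <- xi / (1 + xi)
  if (!shared_rho_inf || nt == 1) {
    fits <- lapply(seq_len(nt), function(k) {
      cf <- stats::lm.fit(cbind(rho_1 = b1, rho_inf = b2), m[, k])$coefficients
      cf
    })
    rho_1 <- vapply(fits, `[[`, numeric(1), "rho_1")
    rho_inf <- vapply(fits, `[[`, numeric(1), "rho_inf")
  } else {
    # stacked design: per-transition rho_1 columns + one shared rho_inf column
    y <- as.vector(m)
    X <- matrix(0, length(y), nt + 1)
    for (k in seq_len(nt)) X[(k - 1) * length(xi) + seq_along(xi), k] <- b1
    X[, nt + 1] <- rep(b2, nt)
    cf <- stats::lm.fit(X, y)$coefficients
    rho_1 <- cf[seq_len(nt)]
    rho_inf <- cf[nt + 1]
  }
  fitted <- sapply(seq_len(nt), function(k) {
    ri <- if (length(rho_inf) == 1) rho_inf else rho_inf[k]
    (rho_1[k] + ri * xi) / (1 + xi)
  })
  structure(list(rho_1 = unname(rho_1), rho_inf = unname(rho_inf),
                 xi = xi, fitted = fitted, shared = shared_rho_inf),
            class = "boundary_scaling")
}

#' @export
print.boundary_scaling <- function(x, ...) {
  cat(sprintf("<boundary_scaling> rho_1 = %s; rho_inf = %s%s\n",
              paste(signif(x$rho_1, 4), collapse = ", "),
              paste(signif(x$rho_inf, 4), collapse = ", "),
              if (x$shared) " (shared)" else ""))
  invisible(x)
}

#' Van der Waals coexistence and spinodal curves
#'
#' For the van der Waals equation of state written in critical units,
#' \eqn{(P + \tfrac{9}{8} k_B T_c \rho^2/\rho_c)(1 - \rho/3\rho_c) =
#' \rho k_B T}, computes at each \eqn{T < T_c} the spinodal densities
#' (\eqn{\partial P/\partial \rho = 0}) and the binodal densities by the
#' Maxwell construction (equal pressure and equal chemical potential),
#' solved by bracketing the coexistence pressure between the spinodal
#' extrema.
#'
#' @param T_over_Tc temperatures in units of \eqn{T_c}.
#' @return data.frame with \code{T_over_Tc}, \code{rho_b}, \code{rho_d},
#'   \code{rho_sp_lo}, \code{rho_sp_hi} (densities in units of \eqn{\rho_c};
#'   \code{NA} rows for \eqn{T \ge T_c}) and \code{pressure} (coexistence
#'   pressure, units \eqn{\rho_c k_B T_c}).
#' @export
vdw_theory <- function(T_over_Tc) {
  press <- function(x, t) x * t / (1 - x / 3) - 9 / 8 * x^2
  mu <- function(x, t) t * log(x / (1 - x / 3)) + t * (x / 3) / (1 - x / 3) - 9 / 4 * x
  dp <- function(x, t) t / (1 - x / 3)^2 - 9 / 4 * x
  out <- data.frame(T_over_Tc = T_over_Tc, rho_b = NA_real_, rho_d = NA_real_,
                    rho_sp_lo = NA_real_, rho_sp_hi = NA_real_, pressure = NA_real_)
  for (i in seq_along(T_over_Tc)) {
    t <- T_over_Tc[i]
    if (t >= 1) next
    sp_lo <- stats::uniroot(dp, c(1e-9, 1 - 1e-9), t = t, tol = 1e-12)$root
    sp_hi <- stats::uniroot(dp, c(1 + 1e-9, 3 - 1e-9), t = t, tol = 1e-12)$root
    p_lo <- max(press(sp_hi, t), 1e-12)   # local minimum (may be negative)
    p_hi <- press(sp_lo, t)               # local maximum
    roots_at <- function(p) {
      x1 <- stats::uniroot(function(x) press(x, t) - p, c(1e-12, sp_lo),
                           tol = 1e-13)$root
      x3 <- stats::uniroot(function(x) press(x, t) - p, c(sp_hi, 3 - 1e-9),
                           tol = 1e-13)$root
      c(x1, x3)
    }
    g <- function(p) { r <- roots_at(p); mu(r[2], t) - mu(r[1], t) }
    pstar <- stats::uniroot(g, c(p_lo * (1 + 1e-9) + 1e-13, p_hi * (1 - 1e-9)),
                            tol = 1e-14)$root
    r <- roots_at(pstar)
    out$rho_b[i] <- r[1]; out$rho_d[i] <- r[2]
    out$rho_sp_lo[i] <- sp_lo; out$rho_sp_hi[i] <- sp_hi
    out$pressure[i] <- pstar
  }
  out
}

#' Flory-Huggins binodal and spinodal of a symmetric blend
#'
#' For the symmetric binary blend free energy per site
#' \eqn{f = \frac{\phi}{L}\ln\phi + \frac{1-\phi}{L}\ln(1-\phi) +
#' \chi\phi(1-\phi)}, the critical point is \eqn{\phi_c = 1/2},
#' \eqn{\chi_c = 2/L}; the spinodal solves \eqn{d^2 f/d\phi^2 = 0},
#' \eqn{\chi_s(\phi) = [1/\phi + 1/(1-\phi)]/(2L)}, and the symmetric
#' binodal solves \eqn{df/d\phi = 0} at \eqn{\phi \ne 1/2}:
#' \eqn{\frac{1}{L}\ln\frac{\phi}{1-\phi} + \chi(1 - 2\phi) = 0}.
#'
#' @param L beads per chain (both species).
#' @param chi_grid interaction parameters.
#' @return data.frame with \code{chi}, \code{phi_b_lo}, \code{phi_b_hi},
#'   \code{phi_sp_lo}, \code{phi_sp_hi} (\code{NA} for \eqn{\chi \le \chi_c}).
#' @export
flory_huggins_theory <- function(L, chi_grid) {
  stopifnot(L >= 1)
  chi_c <- 2 / L
  out <- data.frame(chi = chi_grid, phi_b_lo = NA_real_, phi_b_hi = NA_real_,
                    phi_sp_lo = NA_real_, phi_sp_hi = NA_real_)
  for (i in seq_along(chi_grid)) {
    chi <- chi_grid[i]
    if (chi <= chi_c) next
    disc <- sqrt(1 - 2 / (L * chi))
    out$phi_sp_lo[i] <- (1 - disc) / 2
    out$phi_sp_hi[i] <- (1 + disc) / 2
    fb <- function(phi) log(phi / (1 - phi)) / L + chi * (1 - 2 * phi)
    lower <- max(exp(-L * chi - 1), 1e-300)
    phi_lo <- stats::uniroot(fb, c(lower, out$phi_sp_lo[i]), tol = 1e-14)$root
    out$phi_b_lo[i] <- phi_lo
    out$phi_b_hi[i] <- 1 - phi_lo
  }
  out
}
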