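#' Langevin molecular-dynamics parameters
#'
#' Constant-NVT Langevin dynamics in reduced units (\eqn{m = 1},
#' \eqn{k_B = 1}). Defaults follow the standard protocol for these model
#' systems: time step 0.005 \eqn{\tau} for particle systems and 0.001
#' \eqn{\tau} for chain systems, friction coefficient 0.1 \eqn{m/\tau}.
#' The integrator is velocity-Verlet with BAOAB Langevin splitting; with
#' \code{friction = 0} the thermostat (noise and drag) is off and the
#' dynamics is microcanonical.
#'
#' Random insertion can leave overlapping cores. Two safeguards relax them:
#' \code{relax_steps} displacement-limited steepest-descent iterations before
#' dynamics, and a per-step displacement cap during the first
#' \code{cap_steps} MD steps. Set both to 0 for strict Hamiltonian dynamics
#' from a prepared state.
#'
#' @param dt time step (\eqn{\tau}).
#' @param temperature thermostat temperature (\eqn{\epsilon/k_B}).
#' @param friction Langevin friction coefficient (\eqn{m/\tau}); 0 disables
#'   the thermostat.
#' @param n_steps number of MD steps.
#' @param save_interval steps between saved trajectory frames.
#' @param pressure_interval steps between pressure-tensor samples (default 10).
#' @param seed integer seed for the run's random-number stream.
#' @param relax_steps steepest-descent pre-relaxation iterations.
#' @param cap_steps number of initial MD steps with capped displacement.
#' @param cap_disp maximum per-half-step displacement during capping
#'   (\eqn{\sigma}).
#' @param skin neighbor-list skin (\eqn{\sigma}).
#' @return An object of class \code{"md_params"}.
#' @export
md_params <- function(dt = 0.005, temperature = 1, friction = 0.1,
                      n_steps = 1e4, save_interval = 500,
                      pressure_interval = 10, seed = 1L,
                      relax_steps = 500, cap_steps = 1000, cap_disp = 0.05,
                      skin = 0.4) {
  stopifnot(dt > 0, friction >= 0, n_steps >= 1, temperature > 0)
  structure(list(dt = dt, temperature = temperature, friction = friction,
                 n_steps = n_steps, save_interval = save_interval,
                 pressure_interval = pressure_interval, seed = as.integer(seed),
                 relax_steps = relax_steps, cap_steps = cap_steps,
                 cap_disp = cap_disp, skin = skin),
            class = "md_params")
}

# low-level model encoding passed to the C++ kernels
model_to_cpp <- function(model, n = NULL) {
  kind <- match(model$system_kind, c("lj_particle", "lj_chain", "hp_chain", "patchy")) - 1L
  out <- list(kind = kind, chain_len = model$chain_length,
              eps = model$epsilon, sigma = model$sigma)
  if (kind <= 2L) out$rc <- model$pair$r_cut
  if (kind %in% c(1L, 2L)) {
    out$k_spring <- model$bond$k_spring
    out$r0 <- model$bond$r0
  }
  if (kind == 2L && !is.null(n)) {
    per_chain <- as.integer(model$hp_sequence == "P")
    out$types <- rep(per_chain, length.out = n)
  }
  if (kind == 3L) {
    out$cos_theta_s <- model$patch$cos_theta_s
    out$lambda <- model$patch$lambda_range
    out$patch_directions <- model$patch$patch_directions
  }
  out
}

default_dt <- function(model) if (model$chain_length > 1) 0.001 else 0.005

#' Run Langevin molecular dynamics
#'
#' Advances a configuration under constant-NVT Langevin dynamics, recording
#' trajectory frames, per-frame energies, and diagonal pressure-tensor
#' samples. Runs with identical seeds produce identical trajectories.
#'
#' @param config a \code{spidec_config} from [random_insert()] or
#'   [lattice_init()] (any non-patchy model).
#' @param params an [md_params()] object.
#' @return An object of class \code{"spidec_traj"}: a list with the final
#'   \code{config} (including velocities), \code{frames} (list of wrapped
#'   N x 3 position matrices), \code{steps}, \code{pe}, \code{ke} per frame,
#'   \code{pressure} (data.frame step, pxx, pyy, pzz), \code{params} and
#'   \code{model}.
#' @examples
#' cfg <- random_insert(model_spec("lj_particle"), box_spec(8), rho0 = 0.2, seed = 1)
#' tr <- run_md(cfg, md_params(n_steps = 200, save_interval = 100, temperature = 0.9))
#' @export
run_md <- function(config, params) {
  model <- config$model
  if (model$system_kind == "patchy")
    stop("patchy particles are simulated with run_mc(), not MD")
  L <- box_lengths(config$box)
  n <- n_particles(config)
  mcpp <- model_to_cpp(model, n)
  pos <- config$positions
  if (params$relax_steps > 0)
    pos <- relax_positions(pos, L, mcpp, params$relax_steps, params$cap_disp, params$skin)
  res <- cpp_md_run(pos, config$velocities, L, mcpp,
                    params[c("dt", "temperature", "friction", "n_steps",
                             "save_interval", "pressure_interval", "seed",
                             "cap_steps", "cap_disp", "skin")])
  final <- config
  final$positions <- res$positions
  final$velocities <- res$velocities
  pressure <- as.data.frame(res$pressure)
  names(pressure) <- c("step", "pxx", "pyy", "pzz")
  structure(list(config = final,
                 frames = res$trajectory,
                 steps = res$traj_steps,
                 pe = res$frame_pe, ke = res$frame_ke,
                 pressure = pressure,
                 params = params, model = model, box = config$box,
                 engine = "md"),
            class = "spidec_traj")
}

# displacement-limited steepest descent to remove insertion overlaps;
# the unscaled step must stay below 2/k_spring or the stiff bond modes diverge
relax_positions <- function(pos, L, mcpp, n_iter, dmax, skin) {
  k <- if (!is.null(mcpp$k_spring)) mcpp$k_spring else 0
  alpha <- min(1e-4, if (k > 0) 0.5 / k else Inf)
  for (it in seq_len(n_iter)) {
    fv <- cpp_forces_virial(pos, L, mcpp)
    f <- fv$forces
    fn <- sqrt(rowSums(f^2))
    if (max(fn) < 50) break
    step <- pmin(alpha * fn, dmax) / pmax(fn, 1e-12)
    pos <- pos + f * step
    for (a in 1:3) pos[, a] <- pos[, a] - L[a] * floor(pos[, a] / L[a])
  }
  pos
}

#' @export
print.spidec_traj <- function(x, ...) {
  cat(sprintf("<spidec_traj> %s engine, %s: N = %d, %d frames (to step %g)\n",
              x$engine, x$model$system_kind, nrow(x$config$positions),
              length(x$frames), max(x$steps)))
  invisible(x)
}

#' Diagonal pressure tensor of a configuration
#'
#' Virial pressure per diagonal component,
#' \eqn{p_{aa} = (\sum_i m v_a^2 + \sum_{pairs} r_a f_a) / V}, with pair
#' separations evaluated under the minimum-image convention and bond
#' contributions included for chains. If the configuration carries no
#' velocities the kinetic part is replaced by the ideal term \eqn{\rho T}
#' (supply \code{temperature}), as appropriate for configurations sampled by
#' MC.
#'
#' @param config a \code{spidec_config} (continuous potentials only; the
#'   pressure tensor is not defined for the discontinuous patchy potential).
#' @param temperature temperature for the ideal-gas kinetic term when
#'   velocities are absent.
#' @return Named vector \code{c(pxx, pyy, pzz)} in \eqn{\epsilon/\sigma^3}.
#' @export
compute_pressure_tensor <- function(config, temperature = NULL) {
  if (config$model$system_kind == "patchy")
    stop("unsupported model: the pressure tensor is not defined for the discontinuous patchy potential")
  L <- box_lengths(config$box)
  V <- box_volume(config$box)
  n <- n_particles(config)
  fv <- cpp_forces_virial(config$positions, L, model_to_cpp(config$model, n))
  w <- fv$virial
  if (!is.null(config$velocities)) {
    kin <- colSums(config$velocities^2)
  } else {
    if (is.null(temperature))
      stop("temperature required when the configuration has no velocities")
    kin <- rep(n * temperature, 3)
  }
  p <- (kin + w) / V
  names(p) <- c("pxx", "pyy", "pzz")
  p
}

#' Enumerate interacting pairs within a cutoff
#'
#' Cell-list pair enumeration under periodic boundary conditions: every pair
#' with minimum-image separation below \code{r_cut} appears exactly once.
#'
#' @param config a \code{spidec_config} (or any object with positions/box).
#' @param r_cut cutoff; must not exceed half the smallest box side.
#' @return Two-column integer matrix of 1-based pair indices (i < j).
#' @export
neighbor_pairs <- function(config, r_cut) {
  cpp_neighbor_pairs(config$positions, box_lengths(config$box), r_cut)
}

#' Total potential energy of a configuration
#'
#' Brute-force double sum (all minimum-image pairs plus bonds); intended for
#' cross-checks and small systems.
#'
#' @param config a \code{spidec_config}.
#' @export
total_energy <- function(config) {
  orient <- NULL
  if (config$model$system_kind == "patchy")
    orient <- orientations_to_matrix(config$orientations)
  cpp_total_energy(config$positions, orient, box_lengths(config$box),
                   model_to_cpp(config$model, n_particles(config)))
}

orientations_to_matrix <- function(orientations) {
  if (is.matrix(orientations)) return(orientations)
  do.call(rbind, lapply(orientations, function(o) as.vector(t(o))))
}

matrix_to_orientations <- function(m) {
  lapply(seq_len(nrow(m)), function(i) matrix(m[i, ], 3, 3, byrow = TRUE))
}
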