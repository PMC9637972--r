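#' Metropolis Monte Carlo parameters
#'
#' One MC step is a sweep: one attempted move per particle. For patchy
#' particles each attempt is a displacement or a rotation with equal
#' probability; for LJ particles only displacements are attempted.
#' Displacements are drawn uniformly inside a cube of side
#' \code{2 * displacement_halfwidth} (default side \eqn{0.09\sigma}) centred
#' on the current position. A rotation tilts the particle z axis uniformly
#' within a spherical cap of half-angle \code{rotation_angle_halfwidth} and
#' spins about the new z axis by an angle uniform in the same +/- bound; the
#' proposal is symmetric, preserving detailed balance.
#'
#' @param n_steps number of sweeps.
#' @param temperature temperature (\eqn{\epsilon/k_B}).
#' @param displacement_halfwidth half the displacement-cube side (\eqn{\sigma}).
#' @param rotation_angle_halfwidth rotation bound (radians).
#' @param save_interval sweeps between saved frames (2000 is the patchy
#'   default; 100 suits LJ-particle MC).
#' @param seed integer seed.
#' @return An object of class \code{"mc_params"}.
#' @export
mc_params <- function(n_steps = 1e5, temperature = 0.61,
                      displacement_halfwidth = 0.045,
                      rotation_angle_halfwidth = 0.05,
                      save_interval = 2000, seed = 1L) {
  stopifnot(n_steps >= 1, temperature > 0, displacement_halfwidth > 0,
            rotation_angle_halfwidth > 0)
  structure(list(n_steps = n_steps, temperature = temperature,
                 displacement_halfwidth = displacement_halfwidth,
                 rotation_angle_halfwidth = rotation_angle_halfwidth,
                 save_interval = save_interval, seed = as.integer(seed)),
            class = "mc_params")
}

#' Run Metropolis Monte Carlo
#'
#' Supported models: \code{"patchy"} (displacement + rotation moves,
#' hard-core overlaps always rejected) and \code{"lj_particle"}
#' (displacements only). Acceptance follows
#' \eqn{\min(1, e^{-\Delta U / T})}; acceptance rates are reported per move
#' type. The returned object can be passed back through \code{config} for
#' chained runs.
#'
#' @param config a \code{spidec_config} (from [lattice_init()] for patchy).
#' @param params an [mc_params()] object.
#' @return A \code{spidec_traj} with \code{frames}, \code{steps} (sweeps),
#'   \code{energy_series}, final \code{config}, and \code{acceptance} (a list
#'   with attempted/accepted counts and rates per move type, plus the
#'   incremental-vs-recomputed energy bookkeeping pair).
#' @export
run_mc <- function(config, params) {
  model <- config$model
  if (!model$system_kind %in% c("patchy", "lj_particle"))
    stop("run_mc supports patchy and lj_particle models")
  patchy <- model$system_kind == "patchy"
  L <- box_lengths(config$box)
  orient <- if (patchy) orientations_to_matrix(config$orientations) else NULL
  cppp <- c(params, list(rotations = patchy))
  res <- cpp_mc_run(config$positions, orient, L,
                    model_to_cpp(model, n_particles(config)), cppp)
  final <- config
  final$positions <- res$positions
  if (patchy) final$orientations <- matrix_to_orientations(res$orientations)
  acc <- list(
    displacement = c(attempted = res$try_disp, accepted = res$acc_disp,
                     rate = if (res$try_disp > 0) res$acc_disp / res$try_disp else NA),
    rotation = c(attempted = res$try_rot, accepted = res$acc_rot,
                 rate = if (res$try_rot > 0) res$acc_rot / res$try_rot else NA),
    energy = res$energy, energy_recomputed = res$energy_recomputed)
  structure(list(config = final,
                 frames = res$trajectory,
                 orientation_frames = if (patchy) res$traj_orientations else NULL,
                 steps = res$traj_steps,
                 energy_series = res$energy_series,
                 acceptance = acc,
                 params = params, model = model, box = config$box,
                 engine = "mc"),
            class = "spidec_traj")
}

#' Single Monte Carlo rotation move
#'
#' Applies \code{n} successive rotation proposals to an orientation and
#' returns the final orientation together with the visited z-axis
#' directions. Used to verify rotation-group closure and the equilibration
#' of patch axes to the uniform distribution on the sphere.
#'
#' @param orient 3 x 3 rotation matrix (rows = body axes in the lab frame).
#' @param halfwidth rotation bound (radians).
#' @param n number of successive moves.
#' @param seed integer seed.
#' @return List with \code{orientation} (3 x 3) and \code{z_axes}
#'   (\code{n} x 3 unit vectors).
#' @export
rotate_move <- function(orient, halfwidth = 0.05, n = 1, seed = 1L) {
  .check_rotation(orient)
  cpp_rotate_sample(orient, halfwidth, as.integer(n), as.integer(seed))
}

#' Pressure tensor from an MC configuration
#'
#' The kinetic contribution is replaced by the ideal term \eqn{\rho T} at the
#' sampling temperature; the virial part is identical to the MD pressure on
#' the same frozen configuration. Not defined for patchy particles (the
#' potential is discontinuous).
#'
#' @param config a \code{spidec_config} with a continuous potential.
#' @param temperature sampling temperature.
#' @return Named vector \code{c(pxx, pyy, pzz)}.
#' @export
mc_pressure_tensor <- function(config, temperature) {
  if (config$model$system_kind == "patchy")
    stop("unsupported model: the pressure tensor is not defined for the discontinuous patchy potential")
  cfg <- config
  cfg$velocities <- NULL
  compute_pressure_tensor(cfg, temperature = temperature)
}
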