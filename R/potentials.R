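#' Pairwise interaction parameters
#'
#' Container for the parameters of one nonbonded pair interaction in reduced
#' units (lengths in the bead diameter \eqn{\sigma}, energies in the well
#' depth \eqn{\epsilon}). Four functional forms are supported:
#' \describe{
#'   \item{\code{"plain"}}{the bare 12-6 Lennard-Jones potential,
#'     \eqn{U_{LJ}(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]}.}
#'   \item{\code{"cut_shifted"}}{LJ truncated at \code{r_cut} and shifted so
#'     the energy is continuous (zero) at the cutoff.}
#'   \item{\code{"force_shifted"}}{LJ with both the energy and its first
#'     derivative brought to zero at \code{r_cut}.}
#'   \item{\code{"wca"}}{the purely repulsive Weeks-Chandler-Andersen core,
#'     LJ truncated and shifted at its minimum \eqn{2^{1/6}\sigma}.}
#' }
#'
#' @param epsilon well depth (\eqn{\epsilon} units), > 0.
#' @param sigma bead diameter (\eqn{\sigma} units), > 0.
#' @param r_cut cutoff distance; ignored for \code{"wca"} (implied
#'   \eqn{2^{1/6}\sigma}) and may be \code{Inf} for \code{"plain"}.
#' @param mode one of \code{"plain"}, \code{"cut_shifted"},
#'   \code{"force_shifted"}, \code{"wca"}.
#' @return An object of class \code{"pair_params"}.
#' @examples
#' p <- pair_params(mode = "cut_shifted", r_cut = 3)
#' lj_cut_shifted_energy(3, p)  # 0 at the cutoff
#' @export
pair_params <- function(epsilon = 1, sigma = 1, r_cut = 3, mode = "cut_shifted") {
  mode <- match.arg(mode, c("plain", "cut_shifted", "force_shifted", "wca"))
  stopifnot(epsilon > 0, sigma > 0)
  if (mode == "wca") r_cut <- 2^(1 / 6) * sigma
  if (mode %in% c("cut_shifted", "force_shifted") && r_cut <= sigma)
    stop("r_cut must exceed sigma for truncated modes")
  structure(list(epsilon = epsilon, sigma = sigma, r_cut = r_cut, mode = mode),
            class = "pair_params")
}

#' Harmonic bond parameters
#'
#' Bonds use the convention \eqn{U(r) = \tfrac{1}{2} k (r - r_0)^2}, the same
#' convention in which the chain spring constants 75,000 / 750 / 75
#' \eqn{\epsilon/\sigma^2} are quoted.
#'
#' @param k_spring spring constant (\eqn{\epsilon/\sigma^2}), > 0.
#' @param r0 equilibrium bond length (\eqn{\sigma}), > 0.
#' @return An object of class \code{"bond_params"}.
#' @export
bond_params <- function(k_spring = 75000, r0 = 1) {
  stopifnot(k_spring > 0, r0 > 0)
  structure(list(k_spring = k_spring, r0 = r0), class = "bond_params")
}

#' Unit vectors to the vertices of a regular tetrahedron
#'
#' @return A 4 x 3 matrix of unit row vectors with pairwise angles
#'   \eqn{\arccos(-1/3)}.
#' @export
tetrahedron_vertices <- function() {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  v / sqrt(3)
}

#' Kern-Frenkel patch parameters
#'
#' Four equal circular patches centred on the vertices of a tetrahedron.
#' The default half-angle cosine 0.65 makes the four caps cover exactly a
#' fraction \eqn{2(1-\cos\theta_s)} = 0.7 of the particle surface without
#' overlapping (see [patch_coverage()]), the coverage that defines this
#' tetrahedral patchy model.
#'
#' @param cos_theta_s cosine of the patch half-angle, in (-1, 1).
#' @param lambda_range attraction range beyond the hard core (\eqn{\sigma}).
#' @param patch_directions 4 x 3 matrix of unit vectors in the particle frame;
#'   defaults to tetrahedron vertices.
#' @return An object of class \code{"patch_params"}.
#' @export
patch_params <- function(cos_theta_s = 0.65, lambda_range = 0.5,
                         patch_directions = tetrahedron_vertices()) {
  stopifnot(cos_theta_s > -1, cos_theta_s < 1, lambda_range > 0)
  patch_directions <- as.matrix(patch_directions)
  stopifnot(ncol(patch_directions) == 3)
  nrm <- sqrt(rowSums(patch_directions^2))
  if (any(abs(nrm - 1) > 1e-10)) stop("patch_directions must be unit vectors")
  structure(list(cos_theta_s = cos_theta_s, lambda_range = lambda_range,
                 patch_directions = patch_directions),
            class = "patch_params")
}

.check_r <- function(r) {
  if (any(!is.finite(r)) || any(r <= 0)) stop("pair distance r must be positive")
}

#' Lennard-Jones pair energy
#'
#' The bare 12-6 potential \eqn{U_{LJ}(r)=4\epsilon[(\sigma/r)^{12}-(\sigma/r)^6]}.
#'
#' @param r pair distance(s), > 0.
#' @param p a [pair_params()] object (only \code{epsilon}, \code{sigma} used).
#' @return Energy in \eqn{\epsilon} units (vectorised over \code{r}).
#' @export
lj_energy <- function(r, p = pair_params(mode = "plain")) {
  .check_r(r)
  sr6 <- (p$sigma / r)^6
  4 * p$epsilon * (sr6^2 - sr6)
}

#' Derivative of the bare LJ energy with respect to r
#' @inheritParams lj_energy
#' @return dU/dr (the force magnitude on particle 2 along +r is -dU/dr).
#' @export
lj_energy_deriv <- function(r, p = pair_params(mode = "plain")) {
  .check_r(r)
  sr6 <- (p$sigma / r)^6
  4 * p$epsilon * (-12 * sr6^2 + 6 * sr6) / r
}

#' Cut-and-shifted LJ energy
#'
#' \eqn{U_{LJ}(r) - U_{LJ}(r_c)} inside the cutoff, zero at and beyond it.
#' The force inside the cutoff is the unmodified LJ force (the constant shift
#' has zero derivative).
#'
#' @inheritParams lj_energy
#' @export
lj_cut_shifted_energy <- function(r, p = pair_params(mode = "cut_shifted")) {
  .check_r(r)
  u <- lj_energy(r, p) - lj_energy(p$r_cut, p)
  ifelse(r < p$r_cut, u, 0)
}

#' Force-shifted LJ energy and force
#'
#' Both the energy and its derivative vanish at the cutoff:
#' \eqn{U(r) = U_{LJ}(r) - U_{LJ}(r_c) - U'_{LJ}(r_c)(r - r_c)} for
#' \eqn{r < r_c}, zero otherwise. Used with \eqn{r_c = 6\sigma} for chain
#' systems.
#'
#' @inheritParams lj_energy
#' @return A list with components \code{energy} and \code{force}
#'   (\code{force} is \eqn{-dU/dr}, positive = repulsive), each vectorised.
#' @export
lj_force_shifted_energy_force <- function(r, p = pair_params(mode = "force_shifted", r_cut = 6)) {
  .check_r(r)
  rc <- p$r_cut
  du_rc <- lj_energy_deriv(rc, p)
  inside <- r < rc
  e <- ifelse(inside, lj_energy(r, p) - lj_energy(rc, p) - du_rc * (r - rc), 0)
  f <- ifelse(inside, -(lj_energy_deriv(r, p) - du_rc), 0)
  list(energy = e, force = f)
}

#' WCA (purely repulsive) energy
#'
#' \eqn{U_{LJ}(r) + \epsilon} for \eqn{r < 2^{1/6}\sigma}, zero otherwise.
#' Continuous, non-negative, monotonically decreasing on its support.
#'
#' @inheritParams lj_energy
#' @export
wca_energy <- function(r, p = pair_params(mode = "wca")) {
  .check_r(r)
  rmin <- 2^(1 / 6) * p$sigma
  ifelse(r < rmin, lj_energy(r, p) + p$epsilon, 0)
}

#' Generic pair energy dispatching on the parameter mode
#' @inheritParams lj_energy
#' @export
pair_energy <- function(r, p) {
  switch(p$mode,
         plain = lj_energy(r, p),
         cut_shifted = lj_cut_shifted_energy(r, p),
         force_shifted = lj_force_shifted_energy_force(r, p)$energy,
         wca = wca_energy(r, p))
}

#' Generic pair force (-dU/dr) dispatching on the parameter mode
#' @inheritParams lj_energy
#' @export
pair_force <- function(r, p) {
  switch(p$mode,
         plain = -lj_energy_deriv(r, p),
         cut_shifted = ifelse(r < p$r_cut, -lj_energy_deriv(r, p), 0),
         force_shifted = lj_force_shifted_energy_force(r, p)$force,
         wca = ifelse(r < 2^(1 / 6) * p$sigma, -lj_energy_deriv(r, p), 0))
}

#' Harmonic bond energy
#'
#' \eqn{U(r) = \tfrac{1}{2} k (r - r_0)^2}.
#'
#' @param r bond length(s), > 0.
#' @param b a [bond_params()] object.
#' @export
bond_energy <- function(r, b = bond_params()) {
  .check_r(r)
  0.5 * b$k_spring * (r - b$r0)^2
}

#' Kern-Frenkel patchy pair energy
#'
#' Hard core of diameter \eqn{\sigma}; in the shell
#' \eqn{\sigma \le r < \sigma + \lambda} the energy is \eqn{-\epsilon} times
#' the number of bonded patch pairs. Patch \eqn{\alpha} of particle 1 and
#' patch \eqn{\beta} of particle 2 are bonded when
#' \eqn{\hat r \cdot n_{1\alpha} > \cos\theta_s} and
#' \eqn{-\hat r \cdot n_{2\beta} > \cos\theta_s}, with \eqn{\hat r} pointing
#' from particle 1 to particle 2. All bonded \eqn{(\alpha,\beta)} pairs are
#' summed.
#'
#' @param r_vec displacement vector from particle 1 to particle 2 (length 3).
#' @param orient1,orient2 3 x 3 rotation matrices whose rows are the particle
#'   body axes expressed in the lab frame.
#' @param p a [patch_params()] object.
#' @param epsilon bond energy scale.
#' @param sigma hard-core diameter.
#' @return A list with \code{energy} (\code{Inf} on hard-core overlap),
#'   \code{n_bonds}, and \code{overlap} (logical).
#' @export
patchy_pair_energy <- function(r_vec, orient1, orient2, p = patch_params(),
                               epsilon = 1, sigma = 1) {
  stopifnot(length(r_vec) == 3)
  .check_rotation(orient1)
  .check_rotation(orient2)
  r <- sqrt(sum(r_vec^2))
  if (r < sigma)
    return(list(energy = Inf, n_bonds = 0L, overlap = TRUE))
  if (r >= sigma + p$lambda_range)
    return(list(energy = 0, n_bonds = 0L, overlap = FALSE))
  rhat <- r_vec / r
  # patch axes in the lab frame: body vector v -> t(O) %*% v with rows = axes
  n1 <- p$patch_directions %*% orient1  # 4 x 3, rows are lab-frame patch axes
  n2 <- p$patch_directions %*% orient2
  k1 <- sum(as.vector(n1 %*% rhat) > p$cos_theta_s)
  k2 <- sum(as.vector(n2 %*% (-rhat)) > p$cos_theta_s)
  nb <- as.integer(k1 * k2)
  list(energy = -epsilon * nb, n_bonds = nb, overlap = FALSE)
}

.check_rotation <- function(o) {
  if (!is.matrix(o) || any(dim(o) != 3) ||
      max(abs(o %*% t(o) - diag(3))) > 1e-8 || det(o) < 0)
    stop("orientation must be a proper 3x3 rotation matrix")
  invisible(TRUE)
}
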