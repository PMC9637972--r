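#' Periodic rectangular simulation box
#'
#' Boxes are rectangular with equal side lengths in x and y and
#' \eqn{L_z \ge L_x}, periodic in all three directions. Coordinates are kept
#' in \code{[0, L)} with the origin at a corner.
#'
#' @param Lx side length in x (and y).
#' @param Lz_over_Lx aspect ratio, >= 1.
#' @return An object of class \code{"box_spec"} with fields \code{Lx},
#'   \code{Ly}, \code{Lz}.
#' @export
box_spec <- function(Lx, Lz_over_Lx = 1) {
  stopifnot(Lx > 0, Lz_over_Lx >= 1)
  structure(list(Lx = Lx, Ly = Lx, Lz = Lx * Lz_over_Lx), class = "box_spec")
}

box_lengths <- function(box) c(box$Lx, box$Ly, box$Lz)
box_volume <- function(box) box$Lx * box$Ly * box$Lz

#' Model system specification
#'
#' Defines one of the four supported model systems:
#' \describe{
#'   \item{\code{"lj_particle"}}{LJ particles with a cut-and-shifted potential,
#'     cutoff \eqn{3\sigma}.}
#'   \item{\code{"lj_chain"}}{10-bead chains; non-adjacent beads interact via a
#'     force-shifted LJ potential with cutoff \eqn{6\sigma}; adjacent beads
#'     are connected by stiff harmonic bonds (k = 75,000
#'     \eqn{\epsilon/\sigma^2}, equilibrium length \eqn{\sigma}) and excluded
#'     from the nonbonded potential.}
#'   \item{\code{"hp_chain"}}{as \code{lj_chain} but with two bead types: H-H
#'     pairs use the force-shifted LJ attraction, H-P and P-P pairs the purely
#'     repulsive WCA potential. The default sequence places P beads at
#'     positions 1 and 5 (1-based); an alternative places them at 5 and 6.}
#'   \item{\code{"patchy"}}{hard spheres with four tetrahedral Kern-Frenkel
#'     patches (surface coverage 0.7, range \eqn{\lambda = 0.5\sigma}).}
#' }
#'
#' @param system_kind one of \code{"lj_particle"}, \code{"lj_chain"},
#'   \code{"hp_chain"}, \code{"patchy"}.
#' @param epsilon,sigma energy and length scales of the pair interaction.
#' @param r_cut cutoff; defaults to 3 for particles, 6 for chains.
#' @param k_spring bond spring constant for chains.
#' @param chain_length beads per chain (chains only).
#' @param hp_sequence character vector of \code{"H"}/\code{"P"} labels of
#'   length \code{chain_length} (hp_chain only).
#' @param patch a [patch_params()] object (patchy only).
#' @return An object of class \code{"model_spec"}.
#' @examples
#' model_spec("lj_particle")
#' model_spec("hp_chain", hp_sequence = hp_sequence_default(10, c(5, 6)))
#' @export
model_spec <- function(system_kind = c("lj_particle", "lj_chain", "hp_chain", "patchy"),
                       epsilon = 1, sigma = 1, r_cut = NULL,
                       k_spring = 75000, chain_length = 10,
                       hp_sequence = NULL, patch = patch_params()) {
  system_kind <- match.arg(system_kind)
  m <- list(system_kind = system_kind, epsilon = epsilon, sigma = sigma)
  if (system_kind == "lj_particle") {
    m$pair <- pair_params(epsilon, sigma, r_cut %||% (3 * sigma), "cut_shifted")
    m$chain_length <- 1L
  } else if (system_kind %in% c("lj_chain", "hp_chain")) {
    m$pair <- pair_params(epsilon, sigma, r_cut %||% (6 * sigma), "force_shifted")
    m$wca <- pair_params(epsilon, sigma, mode = "wca")
    m$bond <- bond_params(k_spring, sigma)
    m$chain_length <- as.integer(chain_length)
    if (system_kind == "hp_chain") {
      m$hp_sequence <- hp_sequence %||% hp_sequence_default(chain_length)
      stopifnot(length(m$hp_sequence) == chain_length,
                all(m$hp_sequence %in% c("H", "P")))
    }
  } else { # patchy
    m$patch <- patch
    m$chain_length <- 1L
  }
  structure(m, class = "model_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default hydrophobic-polar sequence
#'
#' P beads at the given positions (default 1 and 5, 1-based), H elsewhere.
#'
#' @param chain_length beads per chain.
#' @param p_positions integer positions of the P beads.
#' @export
hp_sequence_default <- function(chain_length = 10, p_positions = c(1, 5)) {
  s <- rep("H", chain_length)
  s[p_positions] <- "P"
  s
}

#' Minimum-image displacement
#'
#' Maps each displacement component into \code{(-L/2, L/2]}.
#'
#' @param dr displacement vector or N x 3 matrix.
#' @param box a [box_spec()].
#' @export
minimum_image <- function(dr, box) {
  L <- box_lengths(box)
  if (is.matrix(dr)) {
    for (a in 1:3) dr[, a] <- dr[, a] - L[a] * round(dr[, a] / L[a])
    dr
  } else {
    dr - L * round(dr / L)
  }
}

#' Wrap positions into the primary box [0, L)
#' @param x N x 3 matrix of positions.
#' @param box a [box_spec()].
#' @export
wrap_positions <- function(x, box) {
  L <- box_lengths(box)
  for (a in 1:3) x[, a] <- x[, a] - L[a] * floor(x[, a] / L[a])
  x
}

new_configuration <- function(positions, box, model,
                              molecule_index = NULL, orientations = NULL,
                              velocities = NULL, rho0 = NULL, seed = NULL) {
  n <- nrow(positions)
  structure(list(
    positions = positions,
    box = box,
    model = model,
    molecule_index = molecule_index %||% seq_len(n),
    orientations = orientations,
    velocities = velocities,
    rho0_requested = rho0,
    rho0_realized = n / box_volume(box),
    seed = seed
  ), class = "spidec_config")
}

#' @export
print.spidec_config <- function(x, ...) {
  cat(sprintf("<spidec_config> %s: N = %d, box %.3g x %.3g x %.3g, rho = %.4g\n",
              x$model$system_kind, nrow(x$positions),
              x$box$Lx, x$box$Ly, x$box$Lz, x$rho0_realized))
  invisible(x)
}

#' Number of particles (beads) in a configuration
#' @param config a \code{spidec_config}.
#' @export
n_particles <- function(config) nrow(config$positions)

#' Random insertion at a target density
#'
#' Inserts particles (or whole chains) uniformly at random into the box at
#' number density \code{rho0}; this is the initialisation used for MD runs,
#' which start from a homogeneous, low-density state inside the spinodal.
#' \eqn{N} is \code{rho0 * V} rounded to the nearest whole molecule.
#' Chains are grown as random walks with fixed bond length \code{r0} and
#' uniformly random bond directions; a bead placement falling within
#' \eqn{0.9\sigma} of an existing bead is retried up to a bounded number of
#' times (residual overlaps are tolerated: the MD engine caps early-step
#' displacements instead of rejection sampling). Patchy particles get
#' orientations drawn uniformly over rotations.
#'
#' @param model a [model_spec()].
#' @param box a [box_spec()].
#' @param rho0 target number density of particles/beads (\eqn{\sigma^{-3}}).
#' @param seed integer seed; identical seeds give identical configurations.
#' @param region optional \code{c(zlo, zhi)}: restrict insertion to the slab
#'   \code{zlo <= z < zhi} (used to prepare preformed-slab initial states);
#'   \code{rho0} then refers to the density within the region.
#' @return A \code{spidec_config}.
#' @export
random_insert <- function(model, box, rho0, seed = 1L, region = NULL) {
  stopifnot(rho0 > 0)
  L <- box_lengths(box)
  vol <- box_volume(box)
  zlo <- 0; zhi <- L[3]
  if (!is.null(region)) {
    zlo <- region[1]; zhi <- region[2]
    stopifnot(zhi > zlo, zlo >= 0, zhi <= L[3])
    vol <- L[1] * L[2] * (zhi - zlo)
  }
  cl <- model$chain_length
  n_mol <- max(1L, as.integer(round(rho0 * vol / cl)))
  n <- n_mol * cl
  rng <- local_rng(seed)
  on.exit(rng$restore())
  if (cl == 1L) {
    pos <- cbind(stats::runif(n, 0, L[1]), stats::runif(n, 0, L[2]),
                 stats::runif(n, zlo, zhi))
    if (model$system_kind == "patchy") {
      # hard-core aware sequential insertion with bounded retries
      pos <- insert_hard_spheres(n, L, zlo, zhi, model$sigma)
      orient <- random_rotations(n)
      return(new_configuration(pos, box, model, orientations = orient,
                               rho0 = rho0, seed = seed))
    }
    return(new_configuration(pos, box, model, rho0 = rho0, seed = seed))
  }
  # chains: self-avoiding-ish random walks with fixed bond length
  r0 <- model$bond$r0
  pos <- matrix(NA_real_, n, 3)
  mol <- rep(seq_len(n_mol), each = cl)
  k <- 0L
  for (m in seq_len(n_mol)) {
    for (attempt_mol in 1:200) {
      cur <- c(stats::runif(1, 0, L[1]), stats::runif(1, 0, L[2]),
               stats::runif(1, zlo, zhi))
      chain <- matrix(NA_real_, cl, 3)
      chain[1, ] <- cur
      ok <- TRUE
      for (b in 2:cl) {
        placed <- FALSE
        for (attempt in 1:50) {
          u <- stats::rnorm(3)
          u <- u / sqrt(sum(u^2))
          cand <- chain[b - 1, ] + r0 * u
          # check against beads of this chain only (cheap; inter-chain
          # overlaps are relaxed by the engine's displacement cap)
          d2 <- rowSums((chain[seq_len(b - 1), , drop = FALSE] -
                           matrix(cand, b - 1, 3, byrow = TRUE))^2)
          if (min(d2) >= (0.9 * model$sigma)^2) { chain[b, ] <- cand; placed <- TRUE; break }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) break
    }
    if (!ok) stop("packing error: chain insertion failed after bounded retries")
    pos[k + seq_len(cl), ] <- chain
    k <- k + cl
  }
  pos <- wrap_positions(pos, box)
  new_configuration(pos, box, model, molecule_index = mol, rho0 = rho0, seed = seed)
}

insert_hard_spheres <- function(n, L, zlo, zhi, sigma) {
  pos <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (attempt in 1:2000) {
      cand <- c(stats::runif(1, 0, L[1]), stats::runif(1, 0, L[2]),
                stats::runif(1, zlo, zhi))
      if (i == 1L) { placed <- TRUE; pos[1, ] <- cand; break }
      dr <- pos[seq_len(i - 1), , drop = FALSE] -
        matrix(cand, i - 1, 3, byrow = TRUE)
      for (a in 1:3) dr[, a] <- dr[, a] - L[a] * round(dr[, a] / L[a])
      if (min(rowSums(dr^2)) >= sigma^2) { placed <- TRUE; pos[i, ] <- cand; break }
    }
    if (!placed) stop("packing error: hard-sphere insertion failed after bounded retries")
  }
  pos
}

#' Cubic-lattice initialisation
#'
#' Places particles on a cubic lattice spanning the box at density
#' \code{rho0}; this is the initialisation used for MC runs. Patchy
#' orientations are randomised uniformly over rotations.
#'
#' @inheritParams random_insert
#' @export
lattice_init <- function(model, box, rho0, seed = 1L) {
  stopifnot(rho0 > 0, model$chain_length == 1L)
  L <- box_lengths(box)
  n <- max(1L, as.integer(round(rho0 * box_volume(box))))
  # lattice constant from density; grid spans the (possibly elongated) box
  a <- (box_volume(box) / n)^(1 / 3)
  nx <- max(1L, as.integer(ceiling(L[1] / a)))
  ny <- max(1L, as.integer(ceiling(L[2] / a)))
  nz <- max(1L, as.integer(ceiling(n / (nx * ny))))
  grid <- expand.grid(i = seq_len(nx) - 1, j = seq_len(ny) - 1, k = seq_len(nz) - 1)
  grid <- grid[seq_len(min(n, nrow(grid))), , drop = FALSE]
  pos <- cbind((grid$i + 0.5) * L[1] / nx,
               (grid$j + 0.5) * L[2] / ny,
               (grid$k + 0.5) * L[3] / nz)
  rng <- local_rng(seed)
  on.exit(rng$restore())
  orient <- if (model$system_kind == "patchy") random_rotations(nrow(pos)) else NULL
  new_configuration(pos, box, model, orientations = orient, rho0 = rho0, seed = seed)
}

#' Uniformly random rotation matrices
#'
#' Draws rotations uniformly (Haar measure) via quaternions; returns a list of
#' 3 x 3 matrices whose rows are the particle body axes in the lab frame.
#'
#' @param n number of rotations.
#' @export
random_rotations <- function(n) {
  lapply(seq_len(n), function(i) {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    quat_to_matrix(q)
  })
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# Scoped RNG: use a private stream without disturbing the caller's .Random.seed
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  list(restore = function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
}
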