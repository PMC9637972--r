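#' Synthetic two-interface (slab) density profile
#'
#' Generates a symmetric double-interface profile — a slab of density
#' \code{rho_d} centered in the box in a background of density \code{rho_b},
#' with tanh interfaces of width \code{w} at distance \code{z0} either side
#' of the center — plus optional additive Gaussian noise. Running the fit
#' model forward makes every interface-fit test self-checking.
#'
#' @param rho_d,rho_b dense and bulk densities.
#' @param z0 interface distance from the box center (slab half-width).
#' @param w interface width.
#' @param noise_sd standard deviation of additive Gaussian noise (density
#'   units).
#' @param n_slices number of slices.
#' @param box a [box_spec()]; profiles span \code{[0, Lz)}.
#' @param seed integer seed for the noise.
#' @return A \code{density_profile}.
#' @export
make_tanh_profile <- function(rho_d = 0.7, rho_b = 0.05, z0 = 10, w = 2,
                              noise_sd = 0, n_slices = NULL,
                              box = box_spec(10, 4), seed = 1L) {
  L <- box$Lz
  n_slices <- n_slices %||% round(L / 0.1)
  thick <- L / n_slices
  zc <- (seq_len(n_slices) - 0.5) * thick
  z <- zc - L / 2
  rho <- rho_b + (rho_d - rho_b) / 2 *
    (tanh((z + z0) / w) - tanh((z - z0) / w))
  if (noise_sd > 0) {
    rng <- local_rng(seed)
    on.exit(rng$restore())
    rho <- rho + stats::rnorm(n_slices, 0, noise_sd)
  }
  structure(list(axis = "z", slice_thickness = thick, bin_centers = zc,
                 densities = rho, n_frames_averaged = 1L,
                 axis_length = L, slice_volume = box_volume(box) / n_slices,
                 n_particles = NA_integer_),
            class = "density_profile")
}

#' Sample ideal freely jointed chains
#'
#' Chains of \code{n_beads} beads with fixed bond length and independent,
#' uniformly random bond directions; no excluded volume. The closed forms
#' \eqn{\langle R_{ee}^2\rangle = (n-1) b^2} and
#' \eqn{\langle R_g^2\rangle = b^2 (n^2 - 1) / (6n)} make this the reference
#' ensemble for chain-size checks (for \eqn{n = 10}, \eqn{b = 1}:
#' \eqn{\langle R_g^2\rangle = 1.65}, RMS \eqn{R_g = 1.2845}).
#'
#' @param n_beads beads per chain (>= 2).
#' @param bond bond length.
#' @param n_chains number of chains.
#' @param seed integer seed.
#' @return List with \code{chains} (list of n_beads x 3 matrices is avoided
#'   for speed: a 3-D array \code{n_beads x 3 x n_chains}), \code{rg}
#'   (per-chain RMS radius of gyration), \code{ree2} (squared end-to-end
#'   distances).
#' @export
sample_fjc <- function(n_beads = 10, bond = 1, n_chains = 1000, seed = 1L) {
  stopifnot(n_beads >= 2)
  rng <- local_rng(seed)
  on.exit(rng$restore())
  nb <- n_beads - 1
  # uniform directions via normalized gaussians, all chains at once
  u <- matrix(stats::rnorm(3 * nb * n_chains), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * bond
  dim(u) <- c(nb, n_chains, 3)
  pos <- array(0, c(n_beads, n_chains, 3))
  for (b in 2:n_beads) pos[b, , ] <- pos[b - 1, , ] + u[b - 1, , ]
  com <- apply(pos, c(2, 3), mean)
  rg2 <- numeric(n_chains)
  for (b in seq_len(n_beads)) {
    d <- pos[b, , ] - com
    rg2 <- rg2 + rowSums(d^2)
  }
  rg2 <- rg2 / n_beads
  ree2 <- rowSums((pos[n_beads, , ] - pos[1, , ])^2)
  list(positions = aperm(pos, c(1, 3, 2)), rg = sqrt(rg2), ree2 = ree2)
}

#' Deterministic Fibonacci sphere lattice
#'
#' @param n number of quasi-uniform points on the unit sphere.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Surface fraction covered by the patches
#'
#' Fraction of the particle surface lying inside at least one patch cone
#' (angular half-width \eqn{\arccos(\cos\theta_s)}), computed by
#' deterministic spherical quadrature over a Fibonacci lattice. The union is
#' handled by a point-in-any-cap test, not by adding cap areas, so patch
#' overlap is counted once. With the tetrahedral geometry and
#' \eqn{\cos\theta_s = 0.35} the coverage is 0.7.
#'
#' @param p a [patch_params()] object.
#' @param resolution number of quadrature directions (default 2e5).
#' @return Covered surface fraction in [0, 1].
#' @export
patch_coverage <- function(p = patch_params(), resolution = 2e5) {
  pts <- fibonacci_sphere(resolution)
  dots <- pts %*% t(p$patch_directions)
  mean(apply(dots > p$cos_theta_s, 1, any))
}

#' Voxel masks of reference morphologies
#'
#' Constructs periodic-aware ground-truth masks for
#' [classify_voxel_mask()]: a centered ball, an axis-spanning rod, a
#' plane-spanning slab, their hollow variants, and the two homogeneous
#' cases.
#'
#' @param label target morphology.
#' @param dims integer grid dimensions, e.g. \code{c(16, 16, 16)}.
#' @param radius ball/rod radius or slab/shell half-thickness in voxels;
#'   defaults to a quarter of the smallest grid side.
#' @return 3-D logical array.
#' @export
make_voxel_morphology <- function(label = .morphology_levels, dims = c(16, 16, 16),
                                  radius = NULL) {
  label <- match.arg(label)
  dims <- as.integer(dims)
  radius <- radius %||% (min(dims) / 4)
  if (label %in% c("sphere", "hollow_sphere") && 2 * radius >= min(dims))
    stop("impossible geometry: sphere diameter exceeds the box")
  ctr <- (dims + 1) / 2
  g <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]), k = seq_len(dims[3]))
  dx <- g$i - ctr[1]; dy <- g$j - ctr[2]; dz <- g$k - ctr[3]
  mask <- switch(label,
    homogeneous_dilute = rep(FALSE, nrow(g)),
    homogeneous_dense = rep(TRUE, nrow(g)),
    sphere = dx^2 + dy^2 + dz^2 <= radius^2,
    cylinder = dx^2 + dy^2 <= radius^2,          # spans z
    slab = abs(dz) <= radius,                    # spans x and y
    hollow_cylinder = !(dx^2 + dy^2 <= radius^2),  # dilute rod through dense
    hollow_sphere = !(dx^2 + dy^2 + dz^2 <= radius^2)
  )
  array(mask, dims)
}

#' Boltzmann oracle for a patchy pair in a periodic box
#'
#' Exact (quadrature) equilibrium bonded fraction of two Kern-Frenkel
#' particles in a periodic box, for cross-checking Metropolis sampling. The
#' pair energy depends only on which radial shell the separation falls in
#' and on the patch counts \eqn{k_1 k_2}, where \eqn{k_i} is the number of
#' patch centers of particle \eqn{i} within the cone of a uniformly random
#' direction; so the configurational integral factorises into shell volumes
#' times an orientational average evaluated on a Fibonacci lattice:
#' \deqn{P(bond) = \frac{V_{shell} E[e^{\epsilon k_1 k_2 / T}
#'   1(k_1 k_2 \ge 1)]}{V_{out} + V_{shell} E[e^{\epsilon k_1 k_2 / T}]}}
#' Quadrature convergence is verified by refinement; an estimate that moves
#' more than 1e-3 on doubling the resolution raises an error.
#'
#' @param model a patchy [model_spec()].
#' @param temperature temperature (\eqn{\epsilon/k_B}); \code{Inf} gives the
#'   geometric (volume-fraction) limit.
#' @param box a [box_spec()] with \eqn{L/2 > \sigma + \lambda}.
#' @param resolution quadrature directions.
#' @return List with \code{p_bond}, \code{mean_energy} and the patch-count
#'   distribution \code{k_prob}.
#' @export
boltzmann_patchy_pair <- function(model, temperature, box = box_spec(4),
                                  resolution = 2e5) {
  stopifnot(model$system_kind == "patchy")
  p <- model$patch
  sig <- model$sigma
  lam <- p$lambda_range
  if (sig + lam >= min(box_lengths(box)) / 2)
    stop("box too small: interaction shell clipped by periodic images")
  kp <- function(res) {
    pts <- fibonacci_sphere(res)
    k <- rowSums(pts %*% t(p$patch_directions) > p$cos_theta_s)
    tabulate(k + 1L, nbins = 5L) / res  # P(k = 0..4)
  }
  k_prob <- kp(resolution)
  k_prob2 <- kp(2 * resolution)
  V <- box_volume(box)
  v_hard <- 4 / 3 * pi * sig^3
  v_shell <- 4 / 3 * pi * ((sig + lam)^3 - sig^3)
  v_out <- V - v_hard - v_shell
  calc <- function(kpr) {
    kk <- outer(0:4, 0:4)
    pkk <- outer(kpr, kpr)
    beta_eps <- if (is.infinite(temperature)) 0 else model$epsilon / temperature
    wfull <- exp(beta_eps * kk)
    z_shell <- sum(pkk * wfull)
    num <- sum(pkk * wfull * (kk >= 1))
    e_shell <- sum(pkk * wfull * (-model$epsilon * kk))
    Z <- v_out + v_shell * z_shell
    list(p_bond = v_shell * num / Z,
         mean_energy = v_shell * e_shell / Z)
  }
  a <- calc(k_prob)
  b <- calc(k_prob2)
  if (abs(a$p_bond - b$p_bond) > 1e-3)
    stop("resolution error: quadrature not converged")
  list(p_bond = b$p_bond, mean_energy = b$mean_energy, k_prob = k_prob2)
}
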