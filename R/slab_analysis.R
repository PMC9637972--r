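#' Density profile along a box axis
#'
#' Divides the box into uniform slices along the chosen axis and averages the
#' per-slice number density over the requested frames. Before binning, each
#' frame is translated so that the center of mass sits at the box center;
#' under periodic wrap the center of mass is computed as a circular (angular)
#' mean, which is well defined when the naive mean is not. Default slice
#' thickness is \eqn{0.1\sigma} for interface fitting; use \eqn{1\sigma} for
#' slab counting.
#'
#' @param traj a \code{spidec_traj}, or a list of N x 3 position matrices.
#' @param axis \code{"x"}, \code{"y"} or \code{"z"}.
#' @param slice_thickness target slice thickness (\eqn{\sigma}); the actual
#'   thickness divides the axis length exactly.
#' @param recenter translate the center of mass to the box center per frame.
#' @param window integer frame indices to average (default: all frames).
#' @param box a [box_spec()]; required when \code{traj} is a bare list.
#' @return An object of class \code{"density_profile"} with
#'   \code{bin_centers}, \code{densities} (\eqn{\sigma^{-3}}), \code{axis},
#'   \code{slice_thickness}, \code{n_frames_averaged}, \code{axis_length},
#'   \code{slice_volume}, \code{n_particles}.
#' @export
density_profile <- function(traj, axis = "z", slice_thickness = 0.1,
                            recenter = TRUE, window = NULL, box = NULL) {
  frames <- get_frames(traj)
  box <- box %||% traj$box
  if (length(frames) == 0) stop("empty trajectory window")
  if (!is.null(window)) frames <- frames[window]
  if (length(frames) == 0) stop("empty trajectory window")
  ax <- match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))
  L <- box_lengths(box)
  Lax <- L[ax]
  nbins <- max(1L, round(Lax / slice_thickness))
  thick <- Lax / nbins
  slice_vol <- box_volume(box) / Lax * thick
  acc <- numeric(nbins)
  for (fr in frames) {
    z <- fr[, ax]
    if (recenter) {
      z <- recenter_axis(z, Lax)
    }
    idx <- pmin(nbins, floor(z / thick) + 1L)
    acc <- acc + tabulate(idx, nbins)
  }
  dens <- acc / (length(frames) * slice_vol)
  structure(list(axis = c("x", "y", "z")[ax],
                 slice_thickness = thick,
                 bin_centers = (seq_len(nbins) - 0.5) * thick,
                 densities = dens,
                 n_frames_averaged = length(frames),
                 axis_length = Lax,
                 slice_volume = slice_vol,
                 n_particles = nrow(frames[[1]])),
            class = "density_profile")
}

# circular-mean recentering of one coordinate axis, result in [0, L)
recenter_axis <- function(z, L) {
  th <- 2 * pi * z / L
  com_angle <- atan2(mean(sin(th)), mean(cos(th)))
  shift <- L / 2 - com_angle * L / (2 * pi)
  zz <- (z + shift) %% L
  zz
}

get_frames <- function(traj) {
  if (inherits(traj, "spidec_traj")) traj$frames
  else if (is.matrix(traj)) list(traj)
  else if (is.list(traj) && (length(traj) == 0 || is.matrix(traj[[1]]))) traj
  else stop("cannot interpret trajectory input")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("<density_profile> axis %s, %d slices of %.3g, %d frame(s); rho in [%.3g, %.3g]\n",
              x$axis, length(x$densities), x$slice_thickness,
              x$n_frames_averaged, min(x$densities), max(x$densities)))
  invisible(x)
}

#' @export
plot.density_profile <- function(x, ...) {
  graphics::plot(x$bin_centers, x$densities, type = "l",
                 xlab = sprintf("%s (sigma)", x$axis),
                 ylab = expression(rho ~ (sigma^-3)), ...)
  invisible(x)
}

#' Fit the two-phase interface profile
#'
#' Least-squares fit of the half-profile (positive side of the box center,
#' where the slab is centered after recentering) to
#' \deqn{\rho(z) = \frac{\rho_d + \rho_b}{2} -
#'       \frac{\rho_d - \rho_b}{2}\tanh[(z - z_0)/w]}
#' yielding the dense-phase density \eqn{\rho_d}, the bulk (dilute)
#' density \eqn{\rho_b}, the interface midpoint \eqn{z_0} and width \eqn{w}.
#'
#' @param profile a [density_profile()] (recentered, dense phase centered).
#' @return An object of class \code{"interface_fit"} with fields
#'   \code{rho_d}, \code{rho_b}, \code{z0}, \code{w}, \code{se} (named
#'   standard errors), \code{residual} (residual standard error).
#' @export
fit_interface <- function(profile) {
  zc <- profile$bin_centers - profile$axis_length / 2
  keep <- zc >= 0
  z <- zc[keep]
  rho <- profile$densities[keep]
  if (length(z) < 8) stop("convergence error: too few slices for interface fit")
  n_edge <- max(2L, round(length(z) / 10))
  rho_d0 <- mean(rho[seq_len(n_edge)])
  rho_b0 <- mean(rho[seq(length(rho) - n_edge + 1, length(rho))])
  if (rho_d0 - rho_b0 < 0.02 * max(rho_d0, 1e-12))
    stop("convergence error: profile has no detectable interface (single phase?)")
  mid <- (rho_d0 + rho_b0) / 2
  z00 <- z[which.min(abs(rho - mid))]
  dat <- data.frame(z = z, rho = rho)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      rho ~ (rho_d + rho_b) / 2 - (rho_d - rho_b) / 2 * tanh((z - z0) / w),
      data = dat,
      start = list(rho_d = rho_d0, rho_b = rho_b0, z0 = z00, w = 1),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("convergence error in interface fit: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  if (cf[["w"]] < 0) {
    # tanh identity: flipping the sign of w swaps the phases
    cf[c("rho_d", "rho_b")] <- cf[c("rho_b", "rho_d")]
    cf[["w"]] <- -cf[["w"]]
  }
  if (cf[["w"]] > profile$axis_length)
    stop("convergence error: fitted interface width exceeds the box")
  if (cf[["rho_d"]] < cf[["rho_b"]])
    stop("convergence error: fitted dense density below bulk density")
  structure(list(rho_d = cf[["rho_d"]], rho_b = cf[["rho_b"]],
                 z0 = cf[["z0"]], w = cf[["w"]],
                 se = se, residual = summary(fit)$sigma, fit = fit),
            class = "interface_fit")
}

#' @export
print.interface_fit <- function(x, ...) {
  cat(sprintf("<interface_fit> rho_d = %.4g, rho_b = %.4g, z0 = %.4g, w = %.4g (res. SE %.3g)\n",
              x$rho_d, x$rho_b, x$z0, x$w, x$residual))
  invisible(x)
}

#' @export
coef.interface_fit <- function(object, ...) {
  c(rho_d = object$rho_d, rho_b = object$rho_b, z0 = object$z0, w = object$w)
}

#' Count slabs from a coarse density profile
#'
#' Each slice is labeled H if its density exceeds \code{rho_H}, L if it is
#' below \code{rho_L}, and filtered out otherwise. On the filtered circular
#' sequence (periodic wrap), every H-to-L or L-to-H transition is an
#' interface; the number of slabs is half the number of interfaces.
#'
#' @param profile a [density_profile()] (typically \eqn{1\sigma} slices) or a
#'   numeric vector of slice densities.
#' @param rho_H,rho_L high/low density cutoffs; defaults 0.55 and 0.25, the
#'   centers of the usual working ranges 0.5-0.6 and 0.1-0.4.
#' @return Integer slab count. \code{NA} with attribute
#'   \code{indeterminate = TRUE} when every slice is filtered out; when all
#'   retained slices share one label the count is 0 and the attribute
#'   \code{phase} is \code{"dense"} or \code{"dilute"}.
#' @export
count_slabs <- function(profile, rho_H = 0.55, rho_L = 0.25) {
  stopifnot(rho_H > rho_L)
  dens <- if (inherits(profile, "density_profile")) profile$densities else profile
  lab <- ifelse(dens > rho_H, "H", ifelse(dens < rho_L, "L", NA))
  lab <- lab[!is.na(lab)]
  if (length(lab) == 0) {
    out <- NA_integer_
    attr(out, "indeterminate") <- TRUE
    return(out)
  }
  transitions <- sum(lab != c(lab[-1], lab[1]))
  out <- as.integer(transitions / 2)
  if (transitions == 0)
    attr(out, "phase") <- if (lab[1] == "H") "dense" else "dilute"
  out
}

#' Maximum slice density over time
#'
#' Per-frame maximum of the coarse density profile along an axis; the raw
#' material for the phase-separation time \eqn{\tau_{PS}}.
#'
#' @inheritParams density_profile
#' @return data.frame with \code{step} and \code{max_density}.
#' @export
max_density_series <- function(traj, axis = "z", slice_thickness = 1, box = NULL) {
  frames <- get_frames(traj)
  box <- box %||% traj$box
  steps <- if (inherits(traj, "spidec_traj")) traj$steps else seq_along(frames)
  md <- vapply(seq_along(frames), function(i) {
    p <- density_profile(frames[i], axis = axis, slice_thickness = slice_thickness,
                         recenter = FALSE, box = box)
    max(p$densities)
  }, numeric(1))
  data.frame(step = steps, max_density = md)
}

#' Time of phase separation
#'
#' After spinodal decomposition, the maximum slice density reaches a plateau.
#' The plateau is estimated as the median of the final quarter of the
#' max-density series and \eqn{\tau_{PS}} is the first time the series
#' reaches it. If the final quarter is still rising relative to the third
#' quarter the series has not plateaued and \code{NA} is returned with
#' attribute \code{converged = FALSE}.
#'
#' @param traj a \code{spidec_traj} (or a data.frame with \code{step},
#'   \code{max_density} as produced by [max_density_series()]).
#' @param slice_thickness coarse slice thickness (\eqn{\sigma}).
#' @param axis profile axis.
#' @return \eqn{\tau_{PS}} in steps, with attribute \code{plateau}.
#' @export
detect_tau_ps <- function(traj, slice_thickness = 1, axis = "z") {
  ser <- if (is.data.frame(traj)) traj
         else max_density_series(traj, axis = axis, slice_thickness = slice_thickness)
  n <- nrow(ser)
  if (n < 8) stop("series too short to detect a plateau")
  q3 <- ser$max_density[seq(floor(n / 2) + 1, floor(3 * n / 4))]
  q4 <- ser$max_density[seq(floor(3 * n / 4) + 1, n)]
  plateau <- stats::median(q4)
  if (stats::median(q4) > 1.05 * stats::median(q3)) {
    out <- NA_real_
    attr(out, "converged") <- FALSE
    return(out)
  }
  hit <- which(ser$max_density >= plateau)
  out <- ser$step[hit[1]]
  attr(out, "plateau") <- plateau
  attr(out, "converged") <- TRUE
  out
}

#' Time of complete slab fusion
#'
#' The first saved frame at which the slab count reaches 1 and persists
#' (anti-flicker: the count must stay at 1 for at least \code{persistence}
#' consecutive saved frames, or to the trajectory end for a trailing run of
#' at least 3). Returns \code{NA} (not an error) when a single slab is never
#' reached.
#'
#' @param traj a \code{spidec_traj}.
#' @param rho_H,rho_L slab-counting cutoffs, see [count_slabs()].
#' @param persistence required consecutive single-slab frames.
#' @param slice_thickness coarse slice thickness.
#' @param axis profile axis.
#' @return \eqn{\tau_{SS}} in steps, or \code{NA}; attribute
#'   \code{slab_counts} holds the per-frame counts.
#' @export
detect_tau_ss <- function(traj, rho_H = 0.55, rho_L = 0.25, persistence = 5,
                          slice_thickness = 1, axis = "z") {
  frames <- get_frames(traj)
  steps <- if (inherits(traj, "spidec_traj")) traj$steps else seq_along(frames)
  counts <- vapply(seq_along(frames), function(i) {
    p <- density_profile(frames[i], axis = axis, slice_thickness = slice_thickness,
                         recenter = FALSE, box = traj$box)
    as.integer(count_slabs(p, rho_H, rho_L))
  }, integer(1))
  out <- tau_ss_from_counts(counts, steps, persistence)
  attr(out, "slab_counts") <- counts
  out
}

#' Apply the single-slab persistence rule to a slab-count series
#'
#' @param counts integer slab counts per saved frame.
#' @param steps step (or time) of each frame.
#' @param persistence required consecutive single-slab frames (a trailing run
#'   of at least 3 reaching the series end also qualifies).
#' @return The step of the first persistent single-slab frame, or \code{NA}.
#' @export
tau_ss_from_counts <- function(counts, steps = seq_along(counts), persistence = 5) {
  r <- rle(counts == 1L & !is.na(counts))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    if (r$lengths[k] >= persistence ||
        (ends[k] == length(counts) && r$lengths[k] >= 3))
      return(steps[starts[k]])
  }
  NA_real_
}

# ---------------------------------------------------------------------------
# Morphology classification
# ---------------------------------------------------------------------------

.morphology_levels <- c("homogeneous_dilute", "sphere", "cylinder", "slab",
                        "hollow_cylinder", "hollow_sphere", "homogeneous_dense")

#' Classify a periodic voxel mask into a dense-phase morphology
#'
#' Labels by spanning dimensionality of the periodic connected components
#' (6-connectivity): a dense component wrapping around 0 box directions is a
#' sphere, 1 a cylinder, 2 a slab; when the dense phase wraps all 3, the
#' complement decides: a dilute component wrapping 1 direction is a hollow
#' cylinder, 0 a hollow sphere, none at all a homogeneous dense phase. An
#' all-FALSE mask is homogeneous dilute. With several disconnected dense
#' components the largest is classified and the attribute
#' \code{multiplicity} records the count.
#'
#' @param mask 3-D logical array; TRUE marks dense voxels.
#' @return A character label from
#'   \code{homogeneous_dilute, sphere, cylinder, slab, hollow_cylinder,
#'   hollow_sphere, homogeneous_dense}.
#' @export
classify_voxel_mask <- function(mask) {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  if (!any(mask)) return(structure("homogeneous_dilute", multiplicity = 0L))
  if (all(mask)) return(structure("homogeneous_dense", multiplicity = 1L))
  dense <- periodic_components(mask)
  big <- which.max(dense$sizes)
  span_d <- sum(dense$spans[big, ])
  mult <- length(dense$sizes)
  lab <- if (span_d == 0) "sphere"
         else if (span_d == 1) "cylinder"
         else if (span_d == 2) "slab"
         else {
           dil <- periodic_components(!mask)
           bigd <- which.max(dil$sizes)
           span_l <- sum(dil$spans[bigd, ])
           if (span_l == 0) "hollow_sphere"
           else if (span_l == 1) "hollow_cylinder"
           else structure("slab", ambiguous = TRUE) # bicontinuous; transient
         }
  structure(as.character(lab), multiplicity = mult,
            ambiguous = isTRUE(attr(lab, "ambiguous")))
}

# periodic connected components (6-connectivity) with spanning detection:
# BFS assigns unwrapped lattice coordinates; revisiting a voxel through a
# different periodic image flags wrap-around in that axis.
periodic_components <- function(mask) {
  dm <- dim(mask)
  idx <- which(mask)
  comp <- integer(length(mask))
  sizes <- integer(0)
  spans <- matrix(FALSE, 0, 3)
  unwrap <- matrix(NA_real_, length(mask), 3)
  nid <- 0L
  coords <- arrayInd(idx, dm)
  rownames(coords) <- NULL
  pos_of <- integer(length(mask))
  pos_of[idx] <- seq_along(idx)
  for (s in idx) {
    if (comp[s] != 0L) next
    nid <- nid + 1L
    span <- c(FALSE, FALSE, FALSE)
    comp[s] <- nid
    ci <- coords[pos_of[s], ]
    unwrap[s, ] <- ci
    queue <- s
    size <- 0L
    while (length(queue) > 0) {
      cur <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      size <- size + 1L
      cc <- coords[pos_of[cur], ]
      uw <- unwrap[cur, ]
      for (a in 1:3) for (d in c(-1L, 1L)) {
        nb <- cc
        nb[a] <- nb[a] + d
        wrapd <- 0L
        if (nb[a] < 1L) { nb[a] <- dm[a]; wrapd <- -1L }
        if (nb[a] > dm[a]) { nb[a] <- 1L; wrapd <- 1L }
        lin <- nb[1] + (nb[2] - 1L) * dm[1] + (nb[3] - 1L) * dm[1] * dm[2]
        if (!mask[lin]) next
        uw_nb <- uw
        uw_nb[a] <- uw[a] + d
        if (comp[lin] == 0L) {
          comp[lin] <- nid
          unwrap[lin, ] <- uw_nb
          queue <- c(queue, lin)
        } else if (comp[lin] == nid) {
          if (any(abs(unwrap[lin, ] - uw_nb) > 0.5)) {
            span <- span | (abs(unwrap[lin, ] - uw_nb) > 0.5)
          }
        }
      }
    }
    sizes <- c(sizes, size)
    spans <- rbind(spans, span)
  }
  list(comp = array(comp, dm), sizes = sizes, spans = spans)
}

# periodic 6-neighborhood dilation / erosion of a logical 3-D array
periodic_dilate <- function(mask) {
  out <- mask
  for (a in 1:3) for (d in c(-1, 1)) out <- out | shift_array(mask, a, d)
  out
}
periodic_erode <- function(mask) {
  out <- mask
  for (a in 1:3) for (d in c(-1, 1)) out <- out & shift_array(mask, a, d)
  out
}
shift_array <- function(x, axis, d) {
  dm <- dim(x)
  id <- lapply(dm, seq_len)
  id[[axis]] <- ((id[[axis]] - 1 - d) %% dm[axis]) + 1
  do.call(`[`, c(list(x), id))
}

#' Classify the dense-phase morphology of a trajectory window
#'
#' For each frame in the window the local density is sampled on a regular
#' grid of points (cell about \code{cell_size}) by counting particles within
#' \code{smoothing_radius} of each grid point — a volume-weighted density
#' field, insensitive to how the particles partition between the phases. A
#' frame is homogeneous when the field's extremes stay within \code{margin}
#' Poisson standard deviations of the overall density (\code{dense_cut}
#' splits the homogeneous case into dilute and dense). Otherwise the field
#' is thresholded at the midpoint of its minimum and maximum — an estimate of
#' the midpoint between \eqn{\rho_b} and \eqn{\rho_d} — and the resulting
#' periodic voxel mask is classified by spanning dimensionality with
#' [classify_voxel_mask()]. The window label is the majority over frames.
#'
#' @param traj a \code{spidec_traj} (use a post-separation window).
#' @param window frame indices; default the last 5 frames.
#' @param smoothing_radius density-sampling ball radius (\eqn{\sigma}).
#' @param cell_size target grid spacing (\eqn{\sigma}).
#' @param dense_cut density above which a homogeneous state counts as the
#'   dense (rather than dilute) single phase.
#' @param margin homogeneity margin in Poisson standard deviations.
#' @return Majority label (character) with attribute \code{per_frame}.
#' @export
classify_morphology <- function(traj, window = NULL,
                                smoothing_radius = 2.8, cell_size = 1.5,
                                dense_cut = 0.4, margin = 6) {
  frames <- get_frames(traj)
  box <- traj$box
  if (is.null(window)) window <- seq(max(1, length(frames) - 4), length(frames))
  labs <- vapply(window, function(i)
    classify_frame(frames[[i]], box, smoothing_radius, cell_size, dense_cut, margin),
    character(1))
  tab <- sort(table(labs), decreasing = TRUE)
  structure(names(tab)[1], per_frame = labs)
}

classify_frame <- function(pos, box, smoothing_radius, cell_size, dense_cut,
                           margin) {
  L <- box_lengths(box)
  r <- min(smoothing_radius, 0.45 * min(L))
  vol_r <- 4 / 3 * pi * r^3
  nc <- pmax(4L, as.integer(round(L / cell_size)))
  field <- cpp_field_density(pos, L, nc, r)
  mu <- nrow(pos) / prod(L)
  sig <- sqrt(mu / vol_r)
  fmax <- max(field); fmin <- min(field)
  # dilute side: a dense domain lifts the max far above Poisson noise;
  # dense side: a bubble (hollow morphologies) pulls the min below half the
  # mean, which dense-liquid fluctuations (sub-Poissonian) never do
  separated <- (fmax > mu + margin * sig) ||
    (mu > dense_cut && fmin < 0.5 * mu)
  if (!separated)
    return(if (mu > dense_cut) "homogeneous_dense" else "homogeneous_dilute")
  mask <- array(field >= (fmax + fmin) / 2, dim(field))
  as.character(classify_voxel_mask(mask))
}

#' Kirkwood-Buff interfacial tension from a pressure-tensor series
#'
#' \deqn{\gamma = \frac{L_z}{2}\left\langle p_{zz} -
#'   \frac{p_{xx} + p_{yy}}{2}\right\rangle}
#' averaged over the analysis window (the factor \eqn{L_z/2} accounts for
#' the two interfaces of a periodic slab). The standard error comes from
#' block averaging with 5 blocks.
#'
#' @param pressure data.frame with columns \code{pxx}, \code{pyy}, \code{pzz}
#'   (and optionally \code{step}), as produced by [run_md()].
#' @param Lz box length along the slab normal.
#' @param window sample indices to average; default the second half.
#' @param n_blocks number of blocks for the error estimate.
#' @return Named vector \code{c(gamma, se)} in \eqn{\epsilon/\sigma^2}.
#' @export
interfacial_tension <- function(pressure, Lz, window = NULL, n_blocks = 5) {
  an <- pressure$pzz - (pressure$pxx + pressure$pyy) / 2
  if (is.null(window)) window <- seq(floor(length(an) / 2) + 1, length(an))
  an <- an[window]
  if (length(an) == 0) stop("empty pressure window")
  gamma <- Lz / 2 * mean(an)
  se <- NA_real_
  if (length(an) >= n_blocks) {
    blk <- split(an, cut(seq_along(an), n_blocks, labels = FALSE))
    bm <- vapply(blk, mean, numeric(1))
    se <- Lz / 2 * stats::sd(bm) / sqrt(n_blocks)
  }
  c(gamma = gamma, se = se)
}

#' Radius of gyration of chains
#'
#' Per-chain mass-weighted radius of gyration with the chain unwrapped
#' across periodic images (bead-to-bead minimum image along the backbone).
#' Optionally restrict to chains in the dense slab: with
#' \code{selector = "dense"} the profile is recentered and fit with
#' [fit_interface()], and chains whose centers lie within the fitted slab
#' half-width \eqn{|z - z_{center}| < z_0} are kept.
#'
#' @param traj a \code{spidec_traj} of a chain system.
#' @param window frame indices (default: second half of the frames).
#' @param selector \code{"all"} or \code{"dense"}.
#' @param axis slab normal for the dense selector.
#' @return List with \code{rg} (vector over chains and frames), \code{mean},
#'   and \code{n_chains_per_frame}.
#' @export
chain_rg <- function(traj, window = NULL, selector = c("all", "dense"),
                     axis = "z") {
  selector <- match.arg(selector)
  frames <- get_frames(traj)
  model <- traj$model
  box <- traj$box
  cl <- model$chain_length
  if (is.null(cl) || cl < 2) stop("chain topology required for chain_rg")
  if (is.null(window)) window <- seq(floor(length(frames) / 2) + 1, length(frames))
  L <- box_lengths(box)
  ax <- match(axis, c("x", "y", "z"))
  fit <- NULL
  if (selector == "dense") {
    prof <- density_profile(frames[window], axis = axis, slice_thickness = 0.1,
                            recenter = TRUE, box = box)
    fit <- fit_interface(prof)
  }
  rgs <- c()
  nsel <- integer(0)
  for (i in window) {
    pos <- frames[[i]]
    n_chain <- nrow(pos) / cl
    zc <- if (selector == "dense") recenter_axis(pos[, ax], L[ax]) else NULL
    sel_count <- 0L
    for (m in seq_len(n_chain)) {
      rows <- ((m - 1) * cl + 1):(m * cl)
      xyz <- pos[rows, , drop = FALSE]
      # unwrap along the backbone
      for (b in 2:cl) {
        d <- xyz[b, ] - xyz[b - 1, ]
        d <- d - L * round(d / L)
        if (sqrt(sum(d^2)) > min(L) / 2)
          stop("broken-chain unwrap ambiguity: bond longer than half the box")
        xyz[b, ] <- xyz[b - 1, ] + d
      }
      if (selector == "dense") {
        zm <- mean(recenter_axis(pos[rows, ax], L[ax]))
        # chain center distance from the (recentered) box center
        if (abs(zm - L[ax] / 2) >= fit$z0) next
      }
      sel_count <- sel_count + 1L
      com <- colMeans(xyz)
      rgs <- c(rgs, sqrt(mean(rowSums((xyz - matrix(com, cl, 3, byrow = TRUE))^2))))
    }
    nsel <- c(nsel, sel_count)
  }
  list(rg = rgs, mean = mean(rgs), n_chains_per_frame = nsel, fit = fit)
}

#' Convert a number-density profile to weight fractions
#'
#' Converts molecule-center number densities (per cubic angstrom) to
#' weight-per-weight concentrations: each slice's solute mass
#' (\eqn{count \times MW / N_A}) over the mass of water filling the slice.
#' Since both scale with the slice volume the conversion is per-density:
#' \eqn{wt/wt = \rho_{\AA^{-3}} \times MW \times 1.66054 / d_w} with
#' \eqn{d_w} in kg/L.
#'
#' @param profile a [density_profile()] whose densities are molecule centers
#'   per cubic angstrom, or a numeric vector of such densities.
#' @param molecular_weight solute molecular weight in Da.
#' @param water_density water density in kg/L (1 by default).
#' @return The profile with densities replaced by wt/wt concentrations (or a
#'   numeric vector if one was supplied).
#' @export
to_weight_fraction <- function(profile, molecular_weight, water_density = 1) {
  if (molecular_weight <= 0) stop("molecular_weight must be positive")
  if (water_density <= 0) stop("water_density must be positive")
  fac <- molecular_weight * 1.66053906660 / water_density
  if (inherits(profile, "density_profile")) {
    profile$densities <- profile$densities * fac
    profile$units <- "wt/wt"
    profile
  } else {
    profile * fac
  }
}

#' Frame window for equilibrium averages
#'
#' The averaging rule for slab observables: the second half of the
#' trajectory, or from \eqn{\tau_{SS}} to the end when complete slab fusion
#' happens in the second half.
#'
#' @param traj a \code{spidec_traj}.
#' @param rho_H,rho_L slab-counting cutoffs.
#' @return Integer frame indices.
#' @export
analysis_window <- function(traj, rho_H = 0.55, rho_L = 0.25) {
  n <- length(traj$frames)
  second_half <- seq(floor(n / 2) + 1, n)
  tss <- suppressWarnings(detect_tau_ss(traj, rho_H, rho_L))
  if (!is.na(tss)) {
    i0 <- which(traj$steps >= tss)[1]
    if (i0 > second_half[1]) return(seq(i0, n))
  }
  second_half
}
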