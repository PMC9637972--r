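#' Write a trajectory (or single configuration) as extended XYZ
#'
#' One block per frame: atom count, a comment line carrying
#' \code{Lattice="..."}, a \code{Properties=} descriptor and \code{Step=},
#' then one line per atom. The species column encodes the bead type
#' (\code{LJ}, \code{H}, \code{P}, or \code{PATCH}); patchy orientations are
#' stored as three extra per-atom vectors (\code{axis_x}, \code{axis_y},
#' \code{axis_z}), the rows of the rotation matrix.
#'
#' @param traj a \code{spidec_traj} or \code{spidec_config}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_extxyz <- function(traj, path) {
  if (inherits(traj, "spidec_config")) {
    frames <- list(traj$positions)
    orients <- if (!is.null(traj$orientations))
      list(orientations_to_matrix(traj$orientations)) else NULL
    steps <- 0
    model <- traj$model; box <- traj$box
  } else {
    frames <- traj$frames
    orients <- traj$orientation_frames
    steps <- traj$steps
    model <- traj$model; box <- traj$box
  }
  L <- box_lengths(box)
  has_orient <- !is.null(orients) && length(orients) > 0
  props <- if (has_orient)
    "Properties=species:S:1:pos:R:3:axis_x:R:3:axis_y:R:3:axis_z:R:3"
  else "Properties=species:S:1:pos:R:3"
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    n <- nrow(fr)
    species <- species_labels(model, n)
    writeLines(as.character(n), con)
    writeLines(sprintf(
      'Lattice="%.10g 0 0 0 %.10g 0 0 0 %.10g" %s Step=%g pbc="T T T"',
      L[1], L[2], L[3], props, steps[k]), con)
    if (has_orient) {
      om <- orients[[k]]
      lines <- sprintf(paste0("%s %.10g %.10g %.10g ",
                              "%.10g %.10g %.10g %.10g %.10g %.10g %.10g %.10g %.10g"),
                       species, fr[, 1], fr[, 2], fr[, 3],
                       om[, 1], om[, 2], om[, 3], om[, 4], om[, 5], om[, 6],
                       om[, 7], om[, 8], om[, 9])
    } else {
      lines <- sprintf("%s %.10g %.10g %.10g", species, fr[, 1], fr[, 2], fr[, 3])
    }
    writeLines(lines, con)
  }
  invisible(path)
}

species_labels <- function(model, n) {
  switch(model$system_kind,
         lj_particle = rep("LJ", n),
         lj_chain = rep("LJ", n),
         hp_chain = rep(model$hp_sequence, length.out = n),
         patchy = rep("PATCH", n))
}

#' Read an extended-XYZ trajectory
#'
#' Counterpart of [write_extxyz()]; returns frames, per-frame steps, box,
#' species and (when present) orientation columns.
#'
#' @param path extended-XYZ file.
#' @return List with \code{frames}, \code{steps}, \code{box},
#'   \code{species}, \code{orientation_frames} (or NULL).
#' @export
read_extxyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); orients <- list(); steps <- numeric(0)
  species <- NULL; box <- NULL
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    comment <- lines[i + 1]
    lat <- regmatches(comment, regexpr('Lattice="[^"]*"', comment))
    lv <- as.numeric(strsplit(sub('Lattice="', "", sub('"$', "", lat)), "\\s+")[[1]])
    if (is.null(box)) {
      box <- box_spec(lv[1], lv[9] / lv[1])
      box$Ly <- lv[5]; box$Lz <- lv[9]
    }
    stp <- regmatches(comment, regexpr("Step=[-0-9.eE+]+", comment))
    steps <- c(steps, if (length(stp)) as.numeric(sub("Step=", "", stp)) else NA)
    body <- lines[(i + 2):(i + 1 + n)]
    tok <- strsplit(trimws(body), "\\s+")
    species <- vapply(tok, `[[`, character(1), 1)
    nums <- t(vapply(tok, function(t) as.numeric(t[-1]), numeric(length(tok[[1]]) - 1)))
    frames[[length(frames) + 1]] <- nums[, 1:3, drop = FALSE]
    if (ncol(nums) >= 12)
      orients[[length(orients) + 1]] <- nums[, 4:12, drop = FALSE]
    i <- i + 2 + n
  }
  list(frames = frames, steps = steps, box = box, species = species,
       orientation_frames = if (length(orients)) orients else NULL)
}

#' Write / read a pressure-tensor time series as CSV
#' @param pressure data.frame with columns step, pxx, pyy, pzz.
#' @param path CSV file.
#' @export
write_pressure_csv <- function(pressure, path) {
  utils::write.csv(pressure, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pressure_csv
#' @export
read_pressure_csv <- function(path) {
  utils::read.csv(path)
}

#' Write a density profile as CSV (z, rho columns)
#' @param profile a \code{density_profile}.
#' @param path CSV file.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(data.frame(z = profile$bin_centers, rho = profile$densities),
                   path, row.names = FALSE)
  invisible(path)
}

#' Run metadata as JSON
#'
#' Records everything needed to reproduce a run: model, box, densities,
#' engine parameters, seed and acceptance statistics where applicable.
#'
#' @param traj a \code{spidec_traj}.
#' @param path output JSON file.
#' @export
write_run_metadata <- function(traj, path) {
  md <- list(
    engine = traj$engine,
    system_kind = traj$model$system_kind,
    n_particles = nrow(traj$config$positions),
    box = box_lengths(traj$box),
    rho0_requested = traj$config$rho0_requested,
    rho0_realized = traj$config$rho0_realized,
    params = unclass(traj$params),
    seed = traj$params$seed,
    acceptance = if (!is.null(traj$acceptance))
      traj$acceptance[c("displacement", "rotation")] else NULL
  )
  jsonlite::write_json(md, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
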