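# shared test utilities: brute-force oracles and small builders

# all-pairs brute-force neighbor enumeration under minimum image
brute_pairs <- function(pos, box, r_cut) {
  n <- nrow(pos)
  out <- NULL
  for (i in seq_len(n - 1)) {
    dr <- pos[(i + 1):n, , drop = FALSE] -
      matrix(pos[i, ], n - i, 3, byrow = TRUE)
    dr <- minimum_image(dr, box)
    hit <- which(rowSums(dr^2) < r_cut^2)
    if (length(hit)) out <- rbind(out, cbind(i, i + hit))
  }
  out
}

pair_key <- function(p) {
  if (is.null(p) || nrow(p) == 0) return(character(0))
  sort(paste(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2])))
}

# configuration from explicit positions (LJ particles by default)
config_from_positions <- function(pos, box, model = model_spec("lj_particle"),
                                  velocities = NULL) {
  cfg <- spidec:::new_configuration(as.matrix(pos), box, model)
  cfg$velocities <- velocities
  cfg
}

# bare trajectory object from a list of frames
traj_from_frames <- function(frames, box, model = NULL, steps = seq_along(frames)) {
  structure(list(frames = frames, steps = steps, box = box, model = model,
                 engine = "fixture"),
            class = "spidec_traj")
}

# random rotation matrix (rows = body axes)
rand_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  spidec:::quat_to_matrix(q)
}
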