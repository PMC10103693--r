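# Small shared fixtures, built in code.

# Optics for fast imaging tests: 128x128 px, 2 s at 15 Hz, bright noiseless
# spots on zero background unless overridden.
test_optics <- function(background = 0, ...) {
  optics_config(image_shape = c(128L, 128L), duration = 2, frame_rate = 15,
                photon_scale = 5000, background = background, ...)
}

# Five slowly diffusing particles on a grid with > 10 px separation.
grid_trajectories <- function(optics = test_optics(), d = 0.002,
                              n_frames = optics$n_frames, seed = 7) {
  pos <- expand.grid(x = c(30, 64, 98), y = c(40, 90))[1:5, ]
  do.call(rbind, lapply(1:5, function(i) {
    tr <- simulate_trajectory(d, 1, n_frames, optics$dt, seed = seed + i,
                              origin = c(pos$x[i], pos$y[i]) * optics$pixel_size)
    cbind(particle_id = i, tr)
  }))
}

# Exhaustive minimum-cost assignment for tiny matrices (oracle for the
# Hungarian implementation); n rows <= m cols.
brute_force_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  best <- Inf
  rec <- function(prefix, remaining) {
    if (length(prefix) == n) {
      v <- sum(cost[cbind(seq_len(n), prefix)])
      if (v < best) best <<- v
      return()
    }
    for (j in remaining) rec(c(prefix, j), setdiff(remaining, j))
  }
  rec(integer(0), seq_len(m))
  best
}

# Composition matrix with known CST labels.
labelled_compositions <- function(n_per_cst, seed = 1) {
  labels <- rep(c("I", "II", "III", "IV", "V"), n_per_cst)
  list(labels = labels,
       table = simulate_composition_table(labels, seed = seed))
}
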