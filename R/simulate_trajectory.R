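# Cache for Cholesky factors of fractional Gaussian noise correlation
# matrices, keyed by (alpha, n_increments). D and dt only rescale the
# increments, so one factor serves all particles of a population.
.fgn_cache <- new.env(parent = emptyenv())

fgn_chol <- function(alpha, n_inc) {
  key <- sprintf("%.12g_%d", alpha, n_inc)
  if (!is.null(.fgn_cache[[key]])) return(.fgn_cache[[key]])
  k <- 0:(n_inc - 1)
  # autocorrelation of unit-variance fGn with Hurst H = alpha/2
  rho <- 0.5 * (abs(k + 1)^alpha - 2 * abs(k)^alpha + abs(k - 1)^alpha)
  L <- chol(stats::toeplitz(rho))
  .fgn_cache[[key]] <- L
  L
}

#' Simulate one probe-particle trajectory
#'
#' Generates a 2-D random walk observed at regular frame intervals. With
#' `anomalous_exponent = 1` the walk is Brownian: per-axis increments are
#' independent Gaussians with variance `2 * diffusivity * dt`, so the
#' expected 2-D MSD at lag tau is `4 * D * tau`. With
#' `anomalous_exponent < 1` the walk is fractional Brownian motion with
#' Hurst index `alpha / 2`, giving `E[MSD(tau)] = 4 * D * tau^alpha` —
#' the subdiffusive stand-in used for particles trapped in the mucus mesh.
#'
#' @param diffusivity Generalized diffusion coefficient, um^2/s (um^2/s^alpha
#'   for subdiffusive walks). Must be >= 0; 0 yields a stationary particle.
#' @param anomalous_exponent Anomalous exponent alpha in (0, 1].
#' @param n_frames Number of observed frames (>= 2).
#' @param dt Time between frames, seconds.
#' @param seed Optional integer seed; the same seed reproduces the
#'   trajectory bit for bit.
#' @param origin Starting position `c(x, y)` in micrometres.
#'
#' @return A data.frame with columns `frame` (0-based), `x_um`, `y_um`,
#'   with the frame interval in attribute `dt`.
#' @export
simulate_trajectory <- function(diffusivity, anomalous_exponent = 1,
                                n_frames, dt, seed = NULL,
                                origin = c(0, 0)) {
  stop_if_not_scalar_pos(diffusivity, "diffusivity", allow_zero = TRUE)
  stop_if_not_scalar_pos(dt, "dt")
  if (!is.numeric(anomalous_exponent) || length(anomalous_exponent) != 1L ||
      !is.finite(anomalous_exponent) ||
      anomalous_exponent <= 0 || anomalous_exponent > 1)
    stop("'anomalous_exponent' must be in (0, 1]")
  if (!is.numeric(n_frames) || length(n_frames) != 1L || n_frames < 2)
    stop("'n_frames' must be >= 2")
  n_frames <- as.integer(n_frames)
  inc <- with_seed(seed, trajectory_increments(
    diffusivity, anomalous_exponent, n_frames - 1L, dt))
  out <- data.frame(
    frame = 0:(n_frames - 1L),
    x_um = origin[1] + c(0, cumsum(inc[, 1])),
    y_um = origin[2] + c(0, cumsum(inc[, 2])))
  attr(out, "dt") <- dt
  out
}

# n_inc x 2 matrix of per-frame displacement increments in um
trajectory_increments <- function(diffusivity, alpha, n_inc, dt) {
  if (diffusivity == 0) return(matrix(0, n_inc, 2))
  scale <- sqrt(2 * diffusivity * dt^alpha)  # per-axis increment SD
  z <- matrix(rnorm(2L * n_inc), n_inc, 2)
  if (alpha == 1) return(scale * z)
  L <- fgn_chol(alpha, n_inc)
  scale * crossprod(L, z)
}

#' Describe one particle population of a synthetic sample
#'
#' @param fraction Proportion of particles in this population, in \[0, 1\].
#' @param diffusivity Generalized diffusion coefficient, um^2/s.
#' @param anomalous_exponent Anomalous exponent alpha in (0, 1].
#' @param name Optional population label (e.g. `"mobile"`, `"trapped"`).
#'
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(fraction, diffusivity, anomalous_exponent = 1,
                            name = NULL) {
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1)
    stop("'fraction' must be in [0, 1]")
  stop_if_not_scalar_pos(diffusivity, "diffusivity", allow_zero = TRUE)
  structure(list(fraction = fraction, diffusivity = diffusivity,
                 anomalous_exponent = anomalous_exponent,
                 name = name %||% sprintf("D%g_a%g", diffusivity,
                                          anomalous_exponent)),
            class = "population_spec")
}

#' Simulate all particles of one video sample
#'
#' Draws `n_particles` trajectories from a mixture of populations.
#' Population sizes are assigned by deterministic quota,
#' `round(fraction * n)`, with any remainder going to the largest-fraction
#' population, so label counts are exact rather than binomial. Ground-truth
#' population labels are retained for recovery tests. Starting positions
#' are uniform over the central 80% of the field of view.
#'
#' @param populations List of [population_spec()] objects whose fractions
#'   sum to 1 (within 1e-9).
#' @param n_particles Number of particles (0 gives a valid empty set).
#' @param optics An [optics_config()]; sets frame count, interval and field.
#' @param seed Optional integer seed.
#'
#' @return An object of class `trajectory_set`: a list with elements
#'   `trajectories` (data.frame `particle_id, frame, x_um, y_um`), `truth`
#'   (data.frame `particle_id, population, diffusivity,
#'   anomalous_exponent`), `dt`, and `optics`.
#' @export
simulate_sample <- function(populations, n_particles, optics = optics_config(),
                            seed = NULL) {
  if (inherits(populations, "population_spec")) populations <- list(populations)
  fr <- vapply(populations, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-9)
    stop("population fractions must sum to 1")
  if (n_particles < 0) stop("'n_particles' must be >= 0")
  n_particles <- as.integer(n_particles)
  counts <- as.integer(round(fr * n_particles))
  counts[which.max(fr)] <- counts[which.max(fr)] + (n_particles - sum(counts))
  field <- optics$image_shape * optics$pixel_size  # c(height, width) in um
  res <- with_seed(seed, {
    traj <- vector("list", n_particles)
    truth <- vector("list", n_particles)
    pid <- 0L
    for (ip in seq_along(populations)) {
      p <- populations[[ip]]
      for (j in seq_len(counts[ip])) {
        pid <- pid + 1L
        origin <- c(runif(1, 0.1 * field[2], 0.9 * field[2]),
                    runif(1, 0.1 * field[1], 0.9 * field[1]))
        tr <- simulate_trajectory(p$diffusivity, p$anomalous_exponent,
                                  optics$n_frames, optics$dt,
                                  origin = origin)
        traj[[pid]] <- cbind(particle_id = pid, tr)
        truth[[pid]] <- data.frame(
          particle_id = pid, population = p$name,
          diffusivity = p$diffusivity,
          anomalous_exponent = p$anomalous_exponent)
      }
    }
    list(traj = traj, truth = truth)
  })
  trajectories <- if (n_particles > 0) do.call(rbind, res$traj) else
    data.frame(particle_id = integer(), frame = integer(),
               x_um = numeric(), y_um = numeric())
  truth <- if (n_particles > 0) do.call(rbind, res$truth) else
    data.frame(particle_id = integer(), population = character(),
               diffusivity = numeric(), anomalous_exponent = numeric())
  structure(list(trajectories = trajectories, truth = truth,
                 dt = optics$dt, optics = optics),
            class = "trajectory_set")
}

#' Write / read trajectory tables in the shared CSV schema
#'
#' The on-disk schema is `sample_id,probe,particle_id,frame,x_um,y_um`
#' with 0-based frames and micrometre coordinates (origin top-left).
#'
#' @param set A `trajectory_set` or a data.frame already in the schema.
#' @param path File path.
#' @param sample_id,probe Identifiers stamped on every row when `set` is a
#'   `trajectory_set`.
#' @return `read_trajectories_csv` returns the data.frame;
#'   `write_trajectories_csv` returns `path` invisibly.
#' @export
write_trajectories_csv <- function(set, path, sample_id = "sample1",
                                   probe = "probe1") {
  df <- if (inherits(set, "trajectory_set")) {
    cbind(sample_id = sample_id, probe = probe, set$trajectories)
  } else set
  need <- c("sample_id", "probe", "particle_id", "frame", "x_um", "y_um")
  if (!all(need %in% names(df))) stop("missing trajectory CSV columns")
  write.csv(df[need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectories_csv
#' @export
read_trajectories_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "probe", "particle_id", "frame", "x_um", "y_um")
  if (!all(need %in% names(df))) stop("missing trajectory CSV columns")
  df
}
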