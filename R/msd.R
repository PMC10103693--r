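#' Time-averaged mean squared displacement of one trajectory
#'
#' Computes the overlapping-window time average
#' `MSD(tau) = mean over t of |r(t + tau) - r(t)|^2` using every valid
#' start frame. Missing frames (gaps) simply contribute no pairs. A
#' non-overlapping estimator is available behind `overlap = FALSE` for
#' variance studies.
#'
#' @param traj data.frame with columns `frame`, `x_um`, `y_um` (one
#'   particle, strictly increasing frames).
#' @param tau Lag time in seconds; must be an integer multiple of `dt`
#'   (within 1e-9 relative).
#' @param dt Frame interval in seconds; defaults to `attr(traj, "dt")`.
#' @param overlap Use overlapping windows (default TRUE).
#' @param msd_floor Floor (um^2) substituted inside `log10_msd` when the
#'   MSD is exactly 0, so downstream mixture fits never see -Inf.
#'
#' @return One-row data.frame `tau, msd, n_pairs, log10_msd, eligible`.
#'   A trajectory shorter than `tau` yields `n_pairs = 0`, `msd = NA` and
#'   `eligible = FALSE` (the explicit "insufficient span" result).
#' @export
time_averaged_msd <- function(traj, tau, dt = attr(traj, "dt"),
                              overlap = TRUE, msd_floor = 1e-6) {
  if (is.null(dt)) stop("'dt' is required (not found as an attribute)")
  stop_if_not_scalar_pos(tau, "tau")
  lag <- tau / dt
  if (abs(lag - round(lag)) > 1e-9 * max(1, lag))
    stop("'tau' must be an integer multiple of 'dt'")
  lag <- as.integer(round(lag))
  r <- msd_single(traj$frame, traj$x_um, traj$y_um, lag, overlap)
  msd <- r[["msd"]]; n_pairs <- r[["n_pairs"]]
  data.frame(tau = tau, msd = msd, n_pairs = n_pairs,
             log10_msd = if (is.na(msd)) NA_real_ else
               log10(max(msd, msd_floor)),
             eligible = n_pairs >= 1)
}

msd_single <- function(frame, x, y, lag, overlap = TRUE) {
  j <- match(frame + lag, frame)
  ok <- !is.na(j)
  if (!overlap && any(ok)) {
    # keep starts spaced >= lag apart
    starts <- which(ok)
    sel <- logical(length(starts)); last <- -Inf
    for (k in seq_along(starts)) {
      if (frame[starts[k]] >= last + lag) { sel[k] <- TRUE
        last <- frame[starts[k]] }
    }
    ok[starts[!sel]] <- FALSE
  }
  n <- sum(ok)
  if (n == 0) return(c(msd = NA_real_, n_pairs = 0))
  d2 <- (x[j[ok]] - x[ok])^2 + (y[j[ok]] - y[ok])^2
  c(msd = mean(d2), n_pairs = n)
}

#' Per-particle MSD at tau = 1 s for a set of trajectories
#'
#' The headline summary of the particle-tracking pipeline: one
#' time-averaged MSD record per particle at a 1-second lag (15 frames at
#' the default 15 Hz). Particles whose tracks contribute fewer than
#' `min_pairs` displacement pairs at this lag are reported ineligible.
#'
#' @param trajectories A `trajectory_set` or a data.frame with columns
#'   `particle_id, frame, x_um, y_um` (optionally `sample_id`, `probe`,
#'   carried through).
#' @param dt Frame interval, seconds (default 1/15).
#' @param tau Lag, seconds (default 1).
#' @param min_pairs Minimum displacement pairs for eligibility (default 15).
#' @param msd_floor See [time_averaged_msd()].
#'
#' @return data.frame with one row per particle: `particle_id, tau, msd,
#'   n_pairs, log10_msd, eligible` plus any grouping columns present.
#'   Empty input yields an empty data.frame with a warning.
#' @export
msd_at_one_second <- function(trajectories, dt = NULL, tau = 1,
                              min_pairs = 15, msd_floor = 1e-6) {
  df <- if (inherits(trajectories, "trajectory_set")) {
    dt <- dt %||% trajectories$dt
    trajectories$trajectories
  } else trajectories
  dt <- dt %||% attr(df, "dt") %||% (1 / 15)
  lag <- tau / dt
  if (abs(lag - round(lag)) > 1e-9 * max(1, lag))
    stop("'tau' must be an integer multiple of 'dt'")
  lag <- as.integer(round(lag))
  if (nrow(df) == 0) {
    warning("no trajectories supplied")
    return(data.frame(particle_id = integer(), tau = numeric(),
                      msd = numeric(), n_pairs = integer(),
                      log10_msd = numeric(), eligible = logical()))
  }
  extras <- intersect(c("sample_id", "probe"), names(df))
  key <- if (length(extras))
    interaction(df[c(extras, "particle_id")], drop = TRUE, lex.order = TRUE)
  else factor(df$particle_id, levels = unique(df$particle_id))
  idx <- split(seq_len(nrow(df)), key)
  rec <- t(vapply(idx, function(i)
    msd_single(df$frame[i], df$x_um[i], df$y_um[i], lag), numeric(2)))
  first <- vapply(idx, `[[`, integer(1), 1L)
  out <- data.frame(df[first, c(extras, "particle_id"), drop = FALSE],
                    tau = tau, msd = rec[, "msd"],
                    n_pairs = as.integer(rec[, "n_pairs"]),
                    row.names = NULL)
  out$log10_msd <- ifelse(is.na(out$msd), NA_real_,
                          log10(pmax(out$msd, msd_floor)))
  out$eligible <- out$n_pairs >= min_pairs
  out
}
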