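# --- separable convolution with replicated edges ------------------------

conv_rows <- function(img, k) {
  r <- (length(k) - 1L) %/% 2L
  nc <- ncol(img)
  pad <- img[, c(rep(1L, r), seq_len(nc), rep(nc, r)), drop = FALSE]
  out <- matrix(0, nrow(img), nc)
  for (j in seq_along(k))
    out <- out + k[j] * pad[, j:(j + nc - 1L), drop = FALSE]
  out
}

conv_sep <- function(img, k) t(conv_rows(t(conv_rows(img, k)), k))

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-r:r, sd = sigma)
  k / sum(k)
}

box_kernel <- function(radius) rep(1 / (2 * radius + 1), 2 * radius + 1)

# Band-pass: small-scale Gaussian smooth minus local (boxcar) background,
# clamped at zero. Flat frames map to all-zero output.
band_pass <- function(img, sigma = 1, bg_radius = 5) {
  bp <- conv_sep(img, gauss_kernel(sigma)) - conv_sep(img, box_kernel(bg_radius))
  bp[bp < 0] <- 0
  bp
}

#' Detect fluorescent spots in a video stack
#'
#' Crocker-Grier-style localization: each frame is band-pass filtered
#' (Gaussian blur minus rolling boxcar background), local maxima above an
#' intensity percentile threshold are found, and each maximum is refined
#' to sub-pixel precision by an intensity-weighted centroid in a square
#' window (re-centred up to three times). Maxima closer together than the
#' refinement window are reported once and flagged `ambiguous`; ambiguous
#' spots are excluded from linking to avoid identity swaps.
#'
#' @param stack An `image_stack` (list of matrices) or a single matrix.
#' @param optics An [optics_config()]; needed for the um conversion.
#' @param percentile Intensity quantile of the band-passed frame used as
#'   detection threshold (default 0.995).
#' @param window Odd refinement window width in pixels (default 11).
#' @param sigma Band-pass smoothing scale in pixels (default 1).
#' @param bg_radius Boxcar background radius in pixels (default `window`).
#'
#' @return data.frame `frame` (0-based), `x_um`, `y_um`, `mass`,
#'   `sigma_px`, `ambiguous`.
#' @export
detect_spots <- function(stack, optics = NULL, percentile = 0.995,
                         window = 11, sigma = 1, bg_radius = window) {
  if (is.matrix(stack)) stack <- list(stack)
  optics <- optics %||% attr(stack, "optics")
  if (is.null(optics)) stop("an optics_config is required")
  if (window %% 2 != 1) stop("'window' must be odd")
  out <- vector("list", length(stack))
  for (f in seq_along(stack)) {
    img <- stack[[f]]
    if (!is.matrix(img)) stop("frames must be 2-D matrices")
    sp <- detect_frame(img, percentile, window, sigma, bg_radius)
    if (nrow(sp)) sp$frame <- f - 1L
    out[[f]] <- sp
  }
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0)
    return(data.frame(frame = integer(), x_um = numeric(), y_um = numeric(),
                      mass = numeric(), sigma_px = numeric(),
                      ambiguous = logical()))
  data.frame(frame = res$frame,
             x_um = px_to_um(res$x_px, optics$pixel_size),
             y_um = px_to_um(res$y_px, optics$pixel_size),
             mass = res$mass, sigma_px = res$sigma_px,
             ambiguous = res$ambiguous)
}

detect_frame <- function(img, percentile, window, sigma, bg_radius) {
  empty <- data.frame(frame = integer(), x_px = numeric(), y_px = numeric(),
                      mass = numeric(), sigma_px = numeric(),
                      ambiguous = logical())
  bp <- band_pass(img, sigma, bg_radius)
  if (max(bp) <= 0) return(empty)
  thr <- as.numeric(quantile(bp, percentile))
  nr <- nrow(bp); nc <- ncol(bp)
  if (nr < 3 || nc < 3) return(empty)
  core <- bp[2:(nr - 1), 2:(nc - 1)]
  is_max <- core > thr & core > 0
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & core >= bp[2:(nr - 1) + dr, 2:(nc - 1) + dc]
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  rows <- idx[, 1] + 1L; cols <- idx[, 2] + 1L
  # plateau dedupe: suppress candidates within 2 px of a brighter one
  o <- order(bp[cbind(rows, cols)], decreasing = TRUE)
  rows <- rows[o]; cols <- cols[o]
  keep <- rep(TRUE, length(rows))
  for (i in seq_along(rows)) {
    if (!keep[i]) next
    if (i < length(rows)) {
      later <- (i + 1):length(rows)
      close <- abs(rows[later] - rows[i]) <= 2 & abs(cols[later] - cols[i]) <= 2
      keep[later][close] <- FALSE
    }
  }
  rows <- rows[keep]; cols <- cols[keep]
  half <- (window - 1L) %/% 2L
  refine <- function(r0, c0) {
    for (it in 1:3) {
      rs <- max(1, r0 - half):min(nr, r0 + half)
      cs <- max(1, c0 - half):min(nc, c0 + half)
      w <- bp[rs, cs, drop = FALSE]
      tot <- sum(w)
      if (tot <= 0) return(c(c0 - 0.5, r0 - 0.5, 0, NA))
      cx <- sum(t(w) * (cs - 0.5)) / tot
      cy <- sum(w * (rs - 0.5)) / tot
      r1 <- floor(cy) + 1L; c1 <- floor(cx) + 1L
      if (r1 == r0 && c1 == c0) break
      r0 <- r1; c0 <- c1
    }
    vx <- sum(t(w) * ((cs - 0.5) - cx)^2) / tot
    vy <- sum(w * ((rs - 0.5) - cy)^2) / tot
    c(cx, cy, tot, sqrt((vx + vy) / 2))
  }
  ref <- t(vapply(seq_along(rows),
                  function(i) refine(rows[i], cols[i]), numeric(4)))
  # merged-spot rule: centroids closer than the window are reported once,
  # flagged ambiguous
  n <- nrow(ref)
  ambiguous <- rep(FALSE, n)
  drop <- rep(FALSE, n)
  if (n > 1) {
    d <- as.matrix(stats::dist(ref[, 1:2, drop = FALSE]))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (d[i, j] < window) {
        ambiguous[c(i, j)] <- TRUE
        drop[j] <- TRUE  # rows are ordered brightest first
      }
    }
  }
  data.frame(frame = 0L, x_px = ref[!drop, 1], y_px = ref[!drop, 2],
             mass = ref[!drop, 3], sigma_px = ref[!drop, 4],
             ambiguous = ambiguous[!drop])
}

# --- minimum-cost bipartite assignment (Hungarian / shortest augmenting
#     path, O(n^2 m)); returns, per row, the assigned column or NA --------

hungarian_assign <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0 || m == 0) return(rep(NA_integer_, n))
  flip <- n > m
  if (flip) { cost <- t(cost); tmp <- n; n <- nrow(cost); m <- ncol(cost) }
  INF <- .Machine$double.xmax / 4
  u <- numeric(n); v <- numeric(m + 1)    # v[1] is the dummy column 0
  p <- integer(m + 1); way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i; j0 <- 1L
    minv <- rep(INF, m + 1); used <- rep(FALSE, m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in which(!used[-1]) + 1L) {
        cur <- cost[i0, j - 1L] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(m + 1)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]; p[j0] <- p[j1]; j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign_row <- rep(NA_integer_, n)
  for (j in 2:(m + 1)) if (p[j] > 0) assign_row[p[j]] <- j - 1L
  if (!flip) return(assign_row)
  out <- rep(NA_integer_, ncol(cost))   # original rows
  for (r in seq_along(assign_row))
    if (!is.na(assign_row[r])) out[assign_row[r]] <- r
  out
}

#' Trajectory-linking parameters
#'
#' @param max_displacement Maximum allowed displacement between consecutive
#'   observations of a particle, in um (applies across memory gaps too).
#' @param memory Number of frames a particle may vanish and still be
#'   re-linked to its track.
#' @param min_track_length Minimum observations for a track to be kept.
#' @return An object of class `link_params`.
#' @export
link_params <- function(max_displacement = 0.5, memory = 2,
                        min_track_length = 30) {
  stop_if_not_scalar_pos(max_displacement, "max_displacement")
  if (memory < 0) stop("'memory' must be >= 0")
  if (min_track_length < 2) stop("'min_track_length' must be >= 2")
  structure(list(max_displacement = max_displacement,
                 memory = as.integer(memory),
                 min_track_length = as.integer(min_track_length)),
            class = "link_params")
}

#' Link detected spots into trajectories
#'
#' Frame-by-frame globally optimal assignment: candidate track ends (last
#' seen within `memory` frames) are matched to the new frame's spots by
#' minimum total squared displacement (Hungarian algorithm), subject to a
#' hard gate of `max_displacement` per link. Unmatched spots start new
#' tracks; tracks shorter than `min_track_length` are discarded, as are
#' spots flagged ambiguous by the detector.
#'
#' @param spots data.frame from [detect_spots()].
#' @param params A [link_params()].
#' @return data.frame `particle_id, frame, x_um, y_um`.
#' @export
link_trajectories <- function(spots, params = link_params()) {
  spots <- spots[!isTRUE_vec(spots$ambiguous), , drop = FALSE]
  empty <- data.frame(particle_id = integer(), frame = integer(),
                      x_um = numeric(), y_um = numeric())
  if (nrow(spots) == 0) return(empty)
  spots <- spots[order(spots$frame), , drop = FALSE]
  frames <- sort(unique(spots$frame))
  # track state
  last_frame <- integer(0); last_x <- numeric(0); last_y <- numeric(0)
  members <- list()   # per track: list of row indices into spots
  BIG <- 1e12
  for (f in frames) {
    cur <- which(spots$frame == f)
    cand <- which(last_frame >= f - 1L - params$memory & last_frame < f)
    assigned_track <- rep(NA_integer_, length(cur))
    if (length(cand) && length(cur)) {
      dx <- outer(last_x[cand], spots$x_um[cur], `-`)
      dy <- outer(last_y[cand], spots$y_um[cur], `-`)
      d2 <- dx^2 + dy^2
      cost <- ifelse(d2 <= params$max_displacement^2, d2, BIG)
      a <- hungarian_assign(cost)   # per candidate track, spot index or NA
      for (k in seq_along(cand)) {
        if (!is.na(a[k]) && cost[k, a[k]] < BIG)
          assigned_track[a[k]] <- cand[k]
      }
    }
    for (k in seq_along(cur)) {
      tr <- assigned_track[k]
      if (is.na(tr)) {   # new track
        members[[length(members) + 1L]] <- cur[k]
        last_frame <- c(last_frame, f)
        last_x <- c(last_x, spots$x_um[cur[k]])
        last_y <- c(last_y, spots$y_um[cur[k]])
      } else {
        members[[tr]] <- c(members[[tr]], cur[k])
        last_frame[tr] <- f
        last_x[tr] <- spots$x_um[cur[k]]
        last_y[tr] <- spots$y_um[cur[k]]
      }
    }
  }
  keep <- which(lengths(members) >= params$min_track_length)
  if (!length(keep)) return(empty)
  do.call(rbind, lapply(seq_along(keep), function(i) {
    rows <- members[[keep[i]]]
    data.frame(particle_id = i, frame = spots$frame[rows],
               x_um = spots$x_um[rows], y_um = spots$y_um[rows])
  }))
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else x %in% TRUE
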