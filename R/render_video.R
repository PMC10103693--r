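# Pixel <-> micrometre convention, shared by the renderer and the detector:
# pixel (row r, col c), 1-based, covers [c-1, c) x [r-1, r) in pixel units,
# so its centre is at (c - 0.5, r - 0.5); x_um = (c - 0.5) * pixel_size.
um_to_px <- function(u, pixel_size) u / pixel_size       # continuous px coord
px_to_um <- function(p, pixel_size) p * pixel_size

#' Render a trajectory set into a synthetic fluorescence video stack
#'
#' Each frame is the configured background plus one symmetric Gaussian spot
#' of width `psf_sigma` (in px) per particle, scaled to `photon_scale` peak
#' expected counts, with Poisson shot noise applied per pixel. Pixels are
#' unsigned 16-bit (values clamped to 65535). Particles outside the field
#' of view are an error under `out_of_field = "reject"` (the default) or
#' silently clipped under `"clip"`.
#'
#' @param set A `trajectory_set` from [simulate_sample()], or a data.frame
#'   with columns `particle_id, frame, x_um, y_um`.
#' @param optics An [optics_config()].
#' @param seed Optional integer seed for the shot noise.
#' @param noise Apply Poisson shot noise (default TRUE). With `FALSE` the
#'   stack holds the expected counts, rounded.
#'
#' @return An object of class `image_stack`: a list of integer matrices
#'   (rows x cols), one per frame, with the optics in attribute `optics`.
#' @export
render_video <- function(set, optics = NULL, seed = NULL, noise = TRUE) {
  df <- if (inherits(set, "trajectory_set")) {
    optics <- optics %||% set$optics
    set$trajectories
  } else set
  if (is.null(optics)) stop("an optics_config is required")
  nr <- optics$image_shape[1]; nc <- optics$image_shape[2]
  n_frames <- if (nrow(df) > 0) max(df$frame) + 1L else optics$n_frames
  px <- um_to_px(df$x_um, optics$pixel_size)
  py <- um_to_px(df$y_um, optics$pixel_size)
  out <- px < 0 | px > nc | py < 0 | py > nr
  if (any(out)) {
    if (optics$out_of_field == "reject")
      stop(sprintf("%d particle positions outside the field of view; %s",
                   sum(out), "set out_of_field = \"clip\" to render anyway"))
  }
  sig <- optics$psf_sigma
  r_win <- ceiling(4 * sig)
  with_seed(seed, {
    stack <- vector("list", n_frames)
    for (f in seq_len(n_frames) - 1L) {
      img <- matrix(optics$background, nr, nc)
      idx <- which(df$frame == f)
      for (i in idx) {
        # pixel-centre grid around the spot
        c0 <- floor(px[i] + 0.5); r0 <- floor(py[i] + 0.5)
        if (c0 + r_win < 1 || c0 - r_win > nc ||
            r0 + r_win < 1 || r0 - r_win > nr) next
        cs <- max(1, c0 - r_win):min(nc, c0 + r_win)
        rs <- max(1, r0 - r_win):min(nr, r0 + r_win)
        gx <- exp(-((cs - 0.5) - px[i])^2 / (2 * sig^2))
        gy <- exp(-((rs - 0.5) - py[i])^2 / (2 * sig^2))
        img[rs, cs] <- img[rs, cs] + optics$photon_scale * outer(gy, gx)
      }
      if (noise) img[] <- rpois(length(img), img)
      img[img > 65535] <- 65535
      stack[[f + 1L]] <- matrix(as.integer(round(img)), nr, nc)
    }
    structure(stack, optics = optics, class = "image_stack")
  })
}

#' Write / read a video stack as multi-page 16-bit TIFF
#'
#' One page per frame, unsigned 16-bit.
#'
#' @param stack An `image_stack` (list of integer matrices).
#' @param path File path.
#' @param optics Optics to re-attach on read (TIFF does not carry them).
#' @return `read_video_tiff` returns an `image_stack`; `write_video_tiff`
#'   returns `path` invisibly.
#' @export
write_video_tiff <- function(stack, path) {
  pages <- lapply(stack, function(m) m / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' @rdname write_video_tiff
#' @export
read_video_tiff <- function(path, optics = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  stack <- lapply(pages, function(m)
    matrix(as.integer(round(m * 65535)), nrow(m), ncol(m)))
  structure(stack, optics = optics, class = "image_stack")
}
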