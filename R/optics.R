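#' Microscope and acquisition settings for simulated videos
#'
#' Bundles the optical parameters of the video microscopy setup emulated by
#' the synthetic-video generator: an EM-CCD acquisition at 25 nm/px and
#' 15 Hz recording 20 s videos by default.
#'
#' @param pixel_size Pixel size in micrometres per pixel (default 0.025,
#'   i.e. 25 nm/px).
#' @param frame_rate Acquisition rate in Hz (default 15).
#' @param duration Video length in seconds (default 20). `duration *
#'   frame_rate` must be a whole number of frames, at least 2.
#' @param image_shape Integer vector `c(rows, cols)` of the frame in pixels.
#' @param psf_sigma Standard deviation of the rendered Gaussian point-spread
#'   function, in pixels.
#' @param photon_scale Peak expected photon count of a rendered spot.
#' @param background Expected background level, in counts.
#' @param out_of_field How to treat particles that leave the field of view
#'   at render time: `"reject"` (error, the default) or `"clip"` (render
#'   only in-field portions).
#'
#' @return An object of class `optics_config`.
#' @export
optics_config <- function(pixel_size = 0.025, frame_rate = 15, duration = 20,
                          image_shape = c(512L, 512L), psf_sigma = 2,
                          photon_scale = 500, background = 20,
                          out_of_field = c("reject", "clip")) {
  stop_if_not_scalar_pos(pixel_size, "pixel_size")
  stop_if_not_scalar_pos(frame_rate, "frame_rate")
  stop_if_not_scalar_pos(duration, "duration")
  stop_if_not_scalar_pos(psf_sigma, "psf_sigma")
  stop_if_not_scalar_pos(photon_scale, "photon_scale")
  stop_if_not_scalar_pos(background, "background", allow_zero = TRUE)
  nf <- duration * frame_rate
  if (abs(nf - round(nf)) > 1e-9 || round(nf) < 2)
    stop("duration * frame_rate must be a whole number of frames >= 2")
  if (length(image_shape) != 2L || any(image_shape < 8))
    stop("image_shape must be c(rows, cols), each >= 8")
  structure(
    list(pixel_size = pixel_size, frame_rate = frame_rate,
         duration = duration, n_frames = as.integer(round(nf)),
         dt = 1 / frame_rate, image_shape = as.integer(image_shape),
         psf_sigma = psf_sigma, photon_scale = photon_scale,
         background = background,
         out_of_field = match.arg(out_of_field)),
    class = "optics_config")
}

#' @export
print.optics_config <- function(x, ...) {
  cat(sprintf(
    "optics_config: %.0f nm/px, %g Hz, %g s (%d frames), %dx%d px\n",
    x$pixel_size * 1000, x$frame_rate, x$duration, x$n_frames,
    x$image_shape[1], x$image_shape[2]))
  invisible(x)
}
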