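#' Physical calibration of a volumetric time-lapse acquisition
#'
#' Bundles the physical metadata of a two-channel 4D recording: frame
#' interval, voxel sizes and recording duration. Defaults mirror a typical
#' light-sheet protocol for trunk vasculature in zebrafish embryos: volumes
#' every 5 s with a 4 um z-step for 1000-2000 s.
#'
#' @param frame_interval_s Time between consecutive volumes, seconds.
#' @param z_step_um Axial spacing between z-slices, micrometres.
#' @param xy_pixel_um Lateral pixel size, micrometres.
#' @param duration_s Total recording duration, seconds. Must cover at least
#'   two frames.
#' @param volume_shape Integer vector `c(z, y, x)`: voxels per axis of each
#'   volume. Only needed when volumes are rendered or read.
#' @param rng_seed Integer seed used by generators that consume this config.
#'
#' @return An object of class `ca_acquisition` (a list with the fields above
#'   plus `n_frames`).
#' @examples
#' acq <- acquisition_config(duration_s = 600)
#' acq$n_frames
#' @export
acquisition_config <- function(frame_interval_s = 5,
                               z_step_um = 4,
                               xy_pixel_um = 0.5,
                               duration_s = 1000,
                               volume_shape = NULL,
                               rng_seed = 1L) {
  check_number(frame_interval_s, "frame_interval_s", 0, strict = TRUE)
  check_number(z_step_um, "z_step_um", 0, strict = TRUE)
  check_number(xy_pixel_um, "xy_pixel_um", 0, strict = TRUE)
  check_number(duration_s, "duration_s", 0, strict = TRUE)
  n_frames <- floor(duration_s / frame_interval_s) + 1L
  if (n_frames < 2L) {
    abort("`duration_s` must cover at least 2 frames at `frame_interval_s`.")
  }
  if (!is.null(volume_shape)) {
    if (length(volume_shape) != 3L || any(volume_shape < 1)) {
      abort("`volume_shape` must be three positive integers (z, y, x).")
    }
    volume_shape <- as.integer(volume_shape)
  }
  structure(
    list(
      frame_interval_s = frame_interval_s,
      z_step_um = z_step_um,
      xy_pixel_um = xy_pixel_um,
      duration_s = duration_s,
      n_frames = as.integer(n_frames),
      volume_shape = volume_shape,
      rng_seed = as.integer(rng_seed)
    ),
    class = "ca_acquisition"
  )
}

#' @export
print.ca_acquisition <- function(x, ...) {
  cat("<ca_acquisition>\n")
  cat(sprintf(
    "  %d frames every %g s (%g s total); voxel %g x %g x %g um (x,y,z)\n",
    x$n_frames, x$frame_interval_s, x$duration_s,
    x$xy_pixel_um, x$xy_pixel_um, x$z_step_um
  ))
  if (!is.null(x$volume_shape)) {
    cat(sprintf(
      "  volume %d x %d x %d voxels (z,y,x)\n",
      x$volume_shape[1], x$volume_shape[2], x$volume_shape[3]
    ))
  }
  invisible(x)
}

#' Frame times of an acquisition
#'
#' @param acquisition A [acquisition_config()] object.
#' @return Numeric vector of frame times in seconds (frame 0 at t = 0).
#' @export
frame_times <- function(acquisition) {
  stopifnot(inherits(acquisition, "ca_acquisition"))
  (seq_len(acquisition$n_frames) - 1) * acquisition$frame_interval_s
}
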