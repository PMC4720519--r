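#' Render a two-channel volumetric movie from a ground-truth scene
#'
#' Renders each cell as a 3D Gaussian nucleus in the nuclear channel and a
#' broader cytoplasmic Gaussian in the indicator channel whose peak intensity
#' follows the cell's noise-free kinetic trace. Kernels are specified in
#' micrometres and evaluated on the (anisotropic) voxel grid, so a given
#' physical distance contributes identically along any axis. Camera noise is
#' Poisson shot noise plus Gaussian read noise; with `noise = TRUE` voxel
#' values are integer camera counts.
#'
#' @param scene A [generate_scene()] result; `acquisition$volume_shape` must
#'   be set (scenes fill it in automatically).
#' @param noise Add Poisson + Gaussian camera noise and quantize to integer
#'   counts. With `noise = FALSE` the noiseless continuous model values are
#'   returned (useful for oracle tests).
#' @param background Background intensity, arbitrary units.
#' @param nuclear_amp Peak nucleus intensity in the nuclear channel.
#' @param nucleus_sigma_um,cyto_sigma_um Isotropic Gaussian widths (um) of
#'   the rendered nucleus and cytoplasm.
#' @param cyto_radius_um Hard cytoplasm cutoff (um): the indicator blob is
#'   zero beyond this distance, reflecting the bounded cell body (and keeping
#'   neighbouring ROIs free of cross-talk at realistic cell spacings).
#' @param read_noise_sd Gaussian read-noise standard deviation (counts).
#'
#' @return An object of class `ca_movie`: list with `nuclear` and
#'   `indicator` 4D arrays indexed `[z, y, x, t]` and the `acquisition`.
#'   Voxel centres sit at physical coordinates `(index - 1) * voxel size`.
#' @export
render_movie <- function(scene,
                         noise = TRUE,
                         background = 10,
                         nuclear_amp = 150,
                         nucleus_sigma_um = 2,
                         cyto_sigma_um = 4,
                         cyto_radius_um = 4.5,
                         read_noise_sd = 2) {
  stopifnot(inherits(scene, "ca_scene"))
  acq <- scene$acquisition
  if (is.null(acq$volume_shape)) abort("scene acquisition has no volume_shape")
  dims <- unname(acq$volume_shape)
  n_frames <- acq$n_frames
  vox <- c(z = acq$z_step_um, y = acq$xy_pixel_um, x = acq$xy_pixel_um)
  extent_um <- (dims - 1) * vox

  tr <- scene$trajectories
  out_of_vol <- tr$x_um < 0 | tr$x_um > extent_um["x"] |
    tr$y_um < 0 | tr$y_um > extent_um["y"] |
    tr$z_um < 0 | tr$z_um > extent_um["z"]
  if (any(out_of_vol)) {
    bad <- unique(tr$cell_id[out_of_vol])
    abort(sprintf(
      "trajectory of cell(s) %s leaves the rendering volume",
      paste(bad, collapse = ", ")
    ))
  }

  # noise-free kinetic trace per cell, sampled at frame times
  t_s <- frame_times(acq)
  model_f <- lapply(seq_len(nrow(scene$cells)), function(i) {
    id <- scene$cells$cell_id[i]
    spike_kinetics(t_s, scene$spikes[scene$spikes$cell_id == id, ],
                   scene$cells$baseline_F0[i])
  })
  names(model_f) <- scene$cells$cell_id

  axis_coord <- list(
    z = (seq_len(dims[1]) - 1) * vox["z"],
    y = (seq_len(dims[2]) - 1) * vox["y"],
    x = (seq_len(dims[3]) - 1) * vox["x"]
  )

  add_blob <- function(vol, c_um, sigma, amp, r_cut = 3.5 * sigma) {
    # c_um = c(x, y, z) centre; evaluate within min(3.5 sigma, r_cut)
    r <- min(3.5 * sigma, r_cut)
    zi <- which(abs(axis_coord$z - c_um[3]) <= r)
    yi <- which(abs(axis_coord$y - c_um[2]) <= r)
    xi <- which(abs(axis_coord$x - c_um[1]) <= r)
    if (!length(zi) || !length(yi) || !length(xi)) return(vol)
    dz2 <- (axis_coord$z[zi] - c_um[3])^2
    dy2 <- (axis_coord$y[yi] - c_um[2])^2
    dx2 <- (axis_coord$x[xi] - c_um[1])^2
    d2 <- outer(outer(dz2, dy2, "+"), dx2, "+")
    patch <- amp * exp(-d2 / (2 * sigma^2)) * (d2 <= r_cut^2)
    vol[zi, yi, xi] <- vol[zi, yi, xi] + patch
    vol
  }

  nuclear <- array(background, dim = c(dims, n_frames))
  indicator <- array(background, dim = c(dims, n_frames))
  traj_by_frame <- split(tr, tr$frame)

  for (f in seq_len(n_frames)) {
    rows <- traj_by_frame[[as.character(f - 1L)]]
    if (is.null(rows)) next
    voln <- array(background, dim = dims)
    voli <- array(background, dim = dims)
    for (k in seq_len(nrow(rows))) {
      c_um <- c(rows$x_um[k], rows$y_um[k], rows$z_um[k])
      id <- rows$cell_id[k]
      voln <- add_blob(voln, c_um, nucleus_sigma_um, nuclear_amp)
      voli <- add_blob(voli, c_um, cyto_sigma_um, model_f[[id]][f],
                       r_cut = cyto_radius_um)
    }
    nuclear[, , , f] <- voln
    indicator[, , , f] <- voli
  }

  if (noise) {
    nuclear[] <- local_seed(scene$rng_seed + 401L, {
      rpois(length(nuclear), nuclear) + rnorm(length(nuclear), 0, read_noise_sd)
    })
    indicator[] <- local_seed(scene$rng_seed + 402L, {
      rpois(length(indicator), indicator) +
        rnorm(length(indicator), 0, read_noise_sd)
    })
    nuclear[] <- pmin(pmax(round(nuclear), 0), 65535)
    indicator[] <- pmin(pmax(round(indicator), 0), 65535)
  }

  structure(
    list(nuclear = nuclear, indicator = indicator, acquisition = acq),
    class = "ca_movie"
  )
}

#' @export
print.ca_movie <- function(x, ...) {
  d <- dim(x$nuclear)
  cat(sprintf(
    "<ca_movie> 2 channels, %d frames of %d x %d x %d voxels (z,y,x)\n",
    d[4], d[1], d[2], d[3]
  ))
  invisible(x)
}
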