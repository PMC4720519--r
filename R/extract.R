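#' Fit per-cell spherical ROI diameters
#'
#' Each tracked cell gets one spherical region of interest, centred on its
#' nucleus at every frame, with a diameter chosen from `d_range_um` (4-11 um,
#' covering the nucleus and part of the cytoplasm). The diameter is the
#' largest value on a `grid_um` grid such that the cell's sphere clears every
#' neighbouring cell's sphere at every frame both cells are present. If even
#' the minimum diameter overlaps a neighbour, the minimum is used and
#' `overlap_flag` is set.
#'
#' @param trajectories Tibble with `cell_id`, `frame`, `x_um`, `y_um`,
#'   `z_um` for all cells (the cell and its neighbours).
#' @param d_range_um Length-2 allowed diameter range, micrometres.
#' @param grid_um Search grid step for the diameter, micrometres.
#' @return A tibble with one row per cell: `cell_id`, `roi_diameter_um`,
#'   `overlap_flag`.
#' @examples
#' tr <- tibble::tibble(
#'   cell_id = rep(c("a", "b"), each = 3), frame = rep(0:2, 2),
#'   x_um = rep(c(0, 10), each = 3), y_um = 0, z_um = 0
#' )
#' fit_roi_diameter(tr) # both get 10 um: spheres just touch
#' @export
fit_roi_diameter <- function(trajectories, d_range_um = c(4, 11),
                             grid_um = 0.5) {
  check_columns(trajectories, c("cell_id", "frame", "x_um", "y_um", "z_um"),
                "trajectories")
  ids <- unique(trajectories$cell_id)
  # minimum centre-to-centre distance to every other cell over shared frames
  min_gap <- setNames(rep(Inf, length(ids)), ids)
  if (length(ids) > 1) {
    for (i in seq_along(ids)) {
      a <- trajectories[trajectories$cell_id == ids[i], ]
      for (j in seq_along(ids)) {
        if (i == j) next
        b <- trajectories[trajectories$cell_id == ids[j], ]
        m <- dplyr::inner_join(a, b, by = "frame",
                               suffix = c("_a", "_b"))
        if (nrow(m) == 0) next
        dd <- sqrt((m$x_um_a - m$x_um_b)^2 + (m$y_um_a - m$y_um_b)^2 +
                     (m$z_um_a - m$z_um_b)^2)
        min_gap[i] <- min(min_gap[i], min(dd))
      }
    }
  }
  grid <- seq(d_range_um[1], d_range_um[2], by = grid_um)
  purrr::map_dfr(seq_along(ids), function(i) {
    # neighbours get (at least) the same diameter, so spheres clear when
    # centre distance >= diameter (sum of the two radii)
    feasible <- grid[grid <= min_gap[i]]
    if (length(feasible) == 0) {
      tibble::tibble(cell_id = ids[i], roi_diameter_um = d_range_um[1],
                     overlap_flag = TRUE)
    } else {
      tibble::tibble(cell_id = ids[i], roi_diameter_um = max(feasible),
                     overlap_flag = FALSE)
    }
  })
}

# max voxel intensity within a physical sphere; returns NA when no voxel
# centre falls inside the sphere within the volume
sphere_max <- function(volume, acquisition, center_um, diameter_um) {
  vox <- c(acquisition$z_step_um, acquisition$xy_pixel_um,
           acquisition$xy_pixel_um)
  d <- dim(volume)
  r <- diameter_um / 2
  # candidate index ranges per axis (voxel centres at (i-1)*vox)
  zi <- which(abs((seq_len(d[1]) - 1) * vox[1] - center_um[3]) <= r)
  yi <- which(abs((seq_len(d[2]) - 1) * vox[2] - center_um[2]) <= r)
  xi <- which(abs((seq_len(d[3]) - 1) * vox[3] - center_um[1]) <= r)
  if (!length(zi) || !length(yi) || !length(xi)) return(NA_real_)
  dz2 <- ((zi - 1) * vox[1] - center_um[3])^2
  dy2 <- ((yi - 1) * vox[2] - center_um[2])^2
  dx2 <- ((xi - 1) * vox[3] - center_um[1])^2
  dist2 <- outer(outer(dz2, dy2, "+"), dx2, "+")
  inside <- dist2 <= r^2
  if (!any(inside)) return(NA_real_)
  max(volume[zi, yi, xi][inside])
}

#' Extract per-cell fluorescence traces from the indicator channel
#'
#' The fluorescence value F of a cell at a frame is the highest voxel
#' intensity of the indicator channel within the cell's spherical ROI,
#' centred on the tracked nucleus. Sphere membership is evaluated on voxel
#' centres in micrometres, so anisotropic voxels are handled exactly: a voxel
#' one 4-um z-step away and one 4 um away laterally are treated identically.
#' Frames where the trajectory has a gap, or where the ROI contains no voxel
#' centre, yield missing values (with a warning for the latter).
#'
#' @param movie A `ca_movie`.
#' @param trajectories Tracked nuclei (tibble with `cell_id`, `frame`,
#'   `x_um`, `y_um`, `z_um`).
#' @param roi Optional ROI table from [fit_roi_diameter()]; fitted
#'   automatically when omitted.
#' @return A tibble `cell_id`, `frame`, `t_s`, `F`, `roi_diameter_um`,
#'   `overlap_flag`.
#' @export
extract_trace <- function(movie, trajectories, roi = NULL) {
  stopifnot(inherits(movie, "ca_movie"))
  check_columns(trajectories, c("cell_id", "frame", "x_um", "y_um", "z_um"),
                "trajectories")
  if (is.null(roi)) roi <- fit_roi_diameter(trajectories)
  tr <- dplyr::inner_join(trajectories, roi, by = "cell_id")
  t_all <- frame_times(movie$acquisition)
  f_vals <- vapply(seq_len(nrow(tr)), function(k) {
    sphere_max(
      movie$indicator[, , , tr$frame[k] + 1L], movie$acquisition,
      c(tr$x_um[k], tr$y_um[k], tr$z_um[k]), tr$roi_diameter_um[k]
    )
  }, numeric(1))
  if (anyNA(f_vals)) {
    warn(sprintf(
      "%d frame(s) had an ROI with no voxel centre inside the volume; F set to NA",
      sum(is.na(f_vals))
    ))
  }
  tibble::tibble(
    cell_id = tr$cell_id, frame = as.integer(tr$frame),
    t_s = t_all[tr$frame + 1L], F = f_vals,
    roi_diameter_um = tr$roi_diameter_um, overlap_flag = tr$overlap_flag
  )
}
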