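static_traj <- function(id, x, y, z, n = 5) {
  tibble::tibble(cell_id = id, frame = 0:(n - 1), x_um = x, y_um = y, z_um = z)
}

test_that("ROI diameters honour the 4-11 um range and neighbour clearance", {
  # isolated cell: the 11-um maximum
  one <- fit_roi_diameter(static_traj("a", 20, 20, 20))
  expect_equal(one$roi_diameter_um, 11)
  expect_false(one$overlap_flag)

  # two cells 10 um apart: spheres of 10 um just touch
  two <- fit_roi_diameter(dplyr::bind_rows(
    static_traj("a", 10, 10, 10), static_traj("b", 20, 10, 10)
  ))
  expect_equal(two$roi_diameter_um, c(10, 10))
  expect_false(any(two$overlap_flag))

  # two cells 3 um apart: minimum diameter, overlap flagged
  close <- fit_roi_diameter(dplyr::bind_rows(
    static_traj("a", 10, 10, 10), static_traj("b", 13, 10, 10)
  ))
  expect_equal(close$roi_diameter_um, c(4, 4))
  expect_true(all(close$overlap_flag))

  # brute-force grid check on random pair geometries
  set.seed(5)
  for (case in 1:25) {
    gap <- runif(1, 3, 14)
    tr <- dplyr::bind_rows(static_traj("a", 10, 10, 10),
                           static_traj("b", 10 + gap, 10, 10))
    got <- fit_roi_diameter(tr)
    grid <- seq(4, 11, 0.5)
    feasible <- grid[grid <= gap]
    want <- if (length(feasible) == 0) 4 else max(feasible)
    expect_equal(got$roi_diameter_um, rep(want, 2))
    expect_equal(got$overlap_flag, rep(length(feasible) == 0, 2))
  }
})

test_that("trace extraction is the max voxel inside the physical sphere", {
  acq <- acquisition_config(duration_s = 20, xy_pixel_um = 0.5,
                            volume_shape = c(7, 24, 24))
  n_fr <- acq$n_frames
  dims <- c(7, 24, 24)

  # uniform volume: F equals the constant everywhere
  mv <- structure(list(
    nuclear = array(1, c(dims, n_fr)),
    indicator = array(7, c(dims, n_fr)),
    acquisition = acq
  ), class = "ca_movie")
  tr <- static_traj("a", 6, 6, 12, n = n_fr)
  out <- extract_trace(mv, tr,
                       roi = tibble::tibble(cell_id = "a",
                                            roi_diameter_um = 8,
                                            overlap_flag = FALSE))
  expect_true(all(out$F == 7))
  expect_equal(nrow(out), n_fr)

  # a single bright voxel inside the sphere dominates
  mv2 <- mv
  mv2$indicator[4, 13, 13, ] <- 500 # z = 12, y = 6, x = 6 um
  out2 <- extract_trace(mv2, tr,
                        roi = tibble::tibble(cell_id = "a",
                                             roi_diameter_um = 8,
                                             overlap_flag = FALSE))
  expect_true(all(out2$F == 500))
})

test_that("extraction matches the exhaustive voxel-scan oracle", {
  acq <- acquisition_config(duration_s = 10, xy_pixel_um = 0.5,
                            volume_shape = c(7, 16, 16))
  set.seed(9)
  for (case in 1:40) {
    vol <- array(runif(7 * 16 * 16), c(7, 16, 16))
    center <- c(runif(1, 1, 6.5), runif(1, 1, 6.5), runif(1, 4, 20))
    diam <- runif(1, 4, 11)
    got <- caosc:::sphere_max(vol, acq, center, diam)
    want <- oracle_sphere_max(vol, c(4, 0.5, 0.5), center, diam)
    expect_identical(got, want, info = sprintf("case %d", case))
  }
})

test_that("anisotropic voxels are treated by physical distance", {
  # voxel 1 z-step away (4 um) and voxel 8 xy-pixels away (4 um) both sit
  # exactly on a 8-um-diameter sphere boundary: both included
  acq <- acquisition_config(duration_s = 10, xy_pixel_um = 0.5,
                            volume_shape = c(5, 24, 24))
  vol <- array(0, c(5, 24, 24))
  center <- c(6, 6, 8) # x, y, z um -> voxel (z 3, y 13, x 13)
  vol[4, 13, 13] <- 50  # 4 um away in z
  vol[3, 13, 21] <- 60  # 4 um away in x
  got <- caosc:::sphere_max(vol, acq, center, 8)
  expect_equal(got, 60)
  # shrink the sphere slightly: both excluded
  got2 <- caosc:::sphere_max(vol, acq, center, 7.9)
  expect_equal(got2, 0)
})

test_that("enlarging the ROI never decreases F", {
  acq <- acquisition_config(duration_s = 10, xy_pixel_um = 1,
                            volume_shape = c(5, 16, 16))
  set.seed(13)
  vol <- array(runif(5 * 16 * 16), c(5, 16, 16))
  center <- c(7, 7, 8)
  vals <- vapply(seq(4, 11, 0.5), function(d) {
    caosc:::sphere_max(vol, acq, center, d)
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("round-trip: extracting a rendered noise-free movie recovers the trace", {
  acq <- acquisition_config(duration_s = 200, xy_pixel_um = 1)
  sc <- generate_scene("wildtype", acq, n_boundaries = 1, n_da = 1,
                       rates = list(tip = 1.2, stalk = 0, da = 0),
                       rng_seed = 17)
  mv <- render_movie(sc, noise = FALSE)
  out <- extract_trace(mv, sc$trajectories)
  model <- render_scene_traces(sc, noise_frac = 0)
  cmp <- dplyr::inner_join(out, model, by = c("cell_id", "frame"),
                           suffix = c("_roi", "_model"))
  # the ROI max reads the blob centre plus the rendering background, under-
  # read only by a bounded voxel-quantization factor
  ratio <- cmp$F_roi / (cmp$F_model + 10)
  expect_true(all(ratio <= 1 + 1e-9))
  expect_true(all(ratio > 0.85))
  # dF/F0 is recovered: same peaks, near-identical normalised shape
  d_roi <- compute_dff(dplyr::select(cmp, cell_id, frame,
                                     t_s = t_s_roi, F = F_roi))
  d_model <- compute_dff(dplyr::select(cmp, cell_id, frame,
                                       t_s = t_s_model, F = F_model))
  expect_lt(max(abs(d_roi$dff - d_model$dff)), 0.15)
  expect_gt(cor(d_roi$dff, d_model$dff), 0.99)
  pk_roi <- detect_peaks(d_roi, 0.2)
  pk_model <- detect_peaks(d_model, 0.2)
  expect_equal(pk_roi$apex_frame, pk_model$apex_frame)
})
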