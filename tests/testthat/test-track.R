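blob_volume <- function(dims, centers_um, acq, amp = 150, sigma = 2,
                        background = 10) {
  vox <- c(acq$z_step_um, acq$xy_pixel_um, acq$xy_pixel_um)
  vol <- array(background, dims)
  for (c_um in centers_um) {
    for (z in seq_len(dims[1])) for (y in seq_len(dims[2])) {
      dz2 <- ((z - 1) * vox[1] - c_um[3])^2
      dy2 <- ((y - 1) * vox[2] - c_um[2])^2
      dx2 <- ((seq_len(dims[3]) - 1) * vox[3] - c_um[1])^2
      vol[z, y, ] <- vol[z, y, ] + amp * exp(-(dz2 + dy2 + dx2) / (2 * sigma^2))
    }
  }
  vol
}

test_that("single noise-free blob yields one centred detection", {
  acq <- acquisition_config(xy_pixel_um = 1, volume_shape = c(9, 24, 24))
  truth <- c(11.3, 12.6, 16.4) # x, y, z in um
  vol <- blob_volume(c(9, 24, 24), list(truth), acq)
  det <- detect_nuclei(vol, acq)
  expect_equal(nrow(det), 1)
  # brute-force argmax + centre-of-mass oracle agreement: within one voxel
  expect_lt(abs(det$x_um - truth[1]), 1)
  expect_lt(abs(det$y_um - truth[2]), 1)
  expect_lt(abs(det$z_um - truth[3]), 4)
  # empty volume: no detections; missing calibration errors
  expect_equal(nrow(detect_nuclei(array(0, c(9, 24, 24)), acq)), 0)
  expect_error(detect_nuclei(vol), "calibration")
})

test_that("two well-separated blobs yield two detections", {
  acq <- acquisition_config(xy_pixel_um = 1, volume_shape = c(9, 24, 40))
  a <- c(10, 12, 16); b <- c(30, 12, 16) # 20 um apart
  vol <- blob_volume(c(9, 24, 40), list(a, b), acq)
  det <- detect_nuclei(vol, acq)
  expect_equal(nrow(det), 2)
  det <- det[order(det$x_um), ]
  expect_lt(abs(det$x_um[1] - 10), 1)
  expect_lt(abs(det$x_um[2] - 30), 1)
})

test_that("static nuclei link into constant trajectories", {
  acq <- acquisition_config(duration_s = 45, volume_shape = c(5, 20, 20))
  det <- purrr::map_dfr(0:9, function(f) {
    tibble::tibble(frame = f, x_um = c(5, 15), y_um = 5, z_um = 8)
  })
  tracks <- link_tracks(det, acq)
  expect_equal(length(unique(tracks$cell_id)), 2)
  spans <- dplyr::count(tracks, cell_id)
  expect_true(all(spans$n == 10))
  disp <- dplyr::summarise(dplyr::group_by(tracks, cell_id),
                           d = max(x_um) - min(x_um))
  expect_true(all(disp$d == 0))
  # no detection is ever assigned to two trajectories
  expect_false(any(duplicated(tracks$det_row)))
})

test_that("linking equals the exhaustive minimum-displacement assignment", {
  set.seed(31)
  for (case in 1:60) {
    n_prev <- sample(1:4, 1)
    n_cur <- sample(1:4, 1)
    a <- matrix(runif(3 * n_prev, 0, 20), n_prev, 3)
    b <- matrix(runif(3 * n_cur, 0, 20), n_cur, 3)
    got <- caosc:::assign_gated(a, b, max_cost = 8)
    want <- oracle_assignment(a, b, max_cost = 8)
    # compare total assignment cost (several assignments may tie)
    cost_of <- function(m) {
      matched <- which(!is.na(m))
      sum(vapply(matched, function(i) sqrt(sum((a[i, ] - b[m[i], ])^2)),
                 numeric(1))) +
        8 * 1.0000001 * (sum(is.na(m)) + (nrow(b) - sum(!is.na(m))))
    }
    expect_equal(cost_of(got), cost_of(want), tolerance = 1e-6,
                 info = sprintf("case %d", case))
  }
})

test_that("swapping nuclei are linked by minimum total displacement", {
  acq <- acquisition_config(duration_s = 45, volume_shape = c(5, 30, 30))
  # two nuclei approach and pass each other with small per-frame steps
  det <- purrr::map_dfr(0:9, function(f) {
    tibble::tibble(frame = f, x_um = c(5 + f, 25 - f), y_um = c(5, 8),
                   z_um = 8)
  })
  tracks <- link_tracks(det, acq, max_disp_um = 4)
  expect_equal(length(unique(tracks$cell_id)), 2)
  # each track keeps its own y-lane (minimum-displacement solution)
  lanes <- dplyr::summarise(dplyr::group_by(tracks, cell_id),
                            y = unique(y_um))
  expect_equal(sort(lanes$y), c(5, 8))
})

test_that("a gap up to gap_max frames is bridged into one trajectory", {
  acq <- acquisition_config(duration_s = 60, volume_shape = c(5, 20, 20))
  frames <- setdiff(0:12, 5:6) # two missing frames
  det <- tibble::tibble(frame = frames, x_um = 5 + 0.2 * frames, y_um = 5,
                        z_um = 8)
  tracks <- link_tracks(det, acq, max_disp_um = 3, gap_max = 2)
  expect_equal(length(unique(tracks$cell_id)), 1)
  # gap frames stay missing, not interpolated
  expect_false(any(tracks$frame %in% 5:6))
})

test_that("tracking achieves perfect links on clean movies and >=95% with noise", {
  acq <- acquisition_config(duration_s = 150, xy_pixel_um = 1.5)
  sc <- generate_scene("wildtype", acq, n_boundaries = 3, n_da = 4,
                       rng_seed = 11)
  # noise-free rendering, well-separated cells, small steps
  mv <- render_movie(sc, noise = FALSE)
  tracks <- link_tracks(detect_nuclei_movie(mv), acq)
  acc <- link_accuracy(tracks, sc)
  expect_equal(acc$accuracy, 1)
  expect_equal(length(unique(tracks$cell_id)), nrow(sc$cells))

  mv_noisy <- render_movie(sc, noise = TRUE)
  tracks_n <- link_tracks(detect_nuclei_movie(mv_noisy), acq)
  acc_n <- link_accuracy(tracks_n, sc)
  expect_gte(acc_n$accuracy, 0.95)
})

test_that("mitosis is flagged for parent and daughters and excluded", {
  # constructed trajectories: parent ends, two daughters start nearby
  acq <- acquisition_config(duration_s = 95)
  mk <- function(id, frames, x) {
    tibble::tibble(cell_id = id, frame = frames, t_s = frames * 5,
                   x_um = x, y_um = 10, z_um = 10,
                   mitosis_flag = FALSE, excluded = FALSE)
  }
  tr <- dplyr::bind_rows(
    mk("parent", 0:9, 20),
    mk("d1", 10:19, 18), mk("d2", 10:19, 22),
    mk("bystander", 0:19, 60)
  )
  out <- flag_mitosis(tr, split_radius_um = 6)
  flagged <- unique(out$cell_id[out$mitosis_flag])
  expect_setequal(flagged, c("parent", "d1", "d2"))
  expect_true(all(out$excluded[out$mitosis_flag]))
  expect_false(any(out$mitosis_flag[out$cell_id == "bystander"]))

  # no divisions -> no flags
  quiet <- dplyr::bind_rows(mk("a", 0:19, 20), mk("b", 0:19, 60))
  expect_false(any(flag_mitosis(quiet)$mitosis_flag))

  # division at the movie's final frame transition: daughters exist only as
  # detections, the parent is still flagged
  tr2 <- dplyr::bind_rows(mk("parent", 0:9, 20), mk("bystander", 0:10, 60))
  dets <- dplyr::bind_rows(
    tr2[, c("frame", "x_um", "y_um", "z_um")],
    tibble::tibble(frame = 10L, x_um = c(18, 22), y_um = 10, z_um = 10)
  )
  out2 <- flag_mitosis(tr2, dets, split_radius_um = 6)
  expect_true(all(out2$mitosis_flag[out2$cell_id == "parent"]))
  expect_false(any(out2$mitosis_flag[out2$cell_id == "bystander"]))
})

test_that("divisions in rendered scenes are flagged via ground truth", {
  acq <- acquisition_config(duration_s = 150, xy_pixel_um = 1.5)
  sc <- generate_scene("wildtype", acq, n_boundaries = 2, n_da = 3,
                       n_mitosis = 1, rng_seed = 13)
  mv <- render_movie(sc, noise = FALSE)
  det <- detect_nuclei_movie(mv)
  tracks <- link_tracks(det, acq)
  tracks <- flag_mitosis(tracks, det)
  # the tracks overlapping the dividing lineage are flagged
  m <- match_tracks(tracks, sc)
  lineage <- c(sc$mitosis$parent, unlist(sc$mitosis$daughters))
  lineage_tracks <- m$cell_id[m$true_cell_id %in% lineage]
  flagged <- unique(tracks$cell_id[tracks$mitosis_flag])
  expect_true(all(lineage_tracks %in% flagged))
  # non-lineage tracks are not flagged
  other <- setdiff(m$cell_id[!is.na(m$true_cell_id)], lineage_tracks)
  expect_false(any(other %in% flagged))
})
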