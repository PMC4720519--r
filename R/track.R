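#' @section Tracking:
#' Nuclei are detected per frame in the nuclear channel by Gaussian
#' smoothing, absolute thresholding and 26-neighbour local maxima with
#' intensity-weighted sub-voxel centroid refinement; detections are linked
#' frame-to-frame by optimal (Hungarian) assignment on Euclidean distance in
#' physical units, gated at `max_disp_um`, with gap closing across up to
#' `gap_max` missing frames.
#' @name caosc-track
#' @keywords internal
NULL

# separable 3D Gaussian smoothing; sigma given in voxels per axis (z, y, x)
gaussian_smooth_3d <- function(vol, sigma_vox) {
  smooth_axis <- function(a, sigma, axis) {
    if (sigma <= 0) return(a)
    r <- max(1L, ceiling(3 * sigma))
    k <- exp(-(-r:r)^2 / (2 * sigma^2))
    k <- k / sum(k)
    d <- dim(a)
    out <- array(0, d)
    for (off in -r:r) {
      w <- k[off + r + 1]
      n <- d[axis]
      src <- seq_len(n) + off
      keep <- src >= 1 & src <= n
      if (!any(keep)) next
      idx_dst <- which(keep)
      idx_src <- src[keep]
      if (axis == 1) {
        out[idx_dst, , ] <- out[idx_dst, , ] + w * a[idx_src, , ]
      } else if (axis == 2) {
        out[, idx_dst, ] <- out[, idx_dst, ] + w * a[, idx_src, ]
      } else {
        out[, , idx_dst] <- out[, , idx_dst] + w * a[, , idx_src]
      }
    }
    out
  }
  vol <- smooth_axis(vol, sigma_vox[1], 1L)
  vol <- smooth_axis(vol, sigma_vox[2], 2L)
  smooth_axis(vol, sigma_vox[3], 3L)
}

#' Detect nuclei in one volume
#'
#' @param volume 3D array `[z, y, x]` of the nuclear channel.
#' @param acquisition An [acquisition_config()] supplying the physical voxel
#'   sizes (required).
#' @param sigma_um Smoothing scale, micrometres; match it to the expected
#'   nucleus radius.
#' @param threshold Absolute intensity floor on the smoothed volume.
#' @param min_separation_um Detections closer than this are merged (the
#'   brighter one is kept).
#'
#' @return A tibble with columns `x_um`, `y_um`, `z_um` (sub-voxel centroid,
#'   physical units, origin at the volume corner), `intensity` (raw voxel
#'   value at the detection peak).
#' @export
detect_nuclei <- function(volume,
                          acquisition,
                          sigma_um = 2,
                          threshold = 30,
                          min_separation_um = 4) {
  if (missing(acquisition) || !inherits(acquisition, "ca_acquisition")) {
    abort("`acquisition` with physical calibration is required")
  }
  vox <- c(acquisition$z_step_um, acquisition$xy_pixel_um,
           acquisition$xy_pixel_um)
  d <- dim(volume)
  sm <- gaussian_smooth_3d(volume, sigma_um / vox)

  cand <- which(sm >= threshold)
  if (length(cand) == 0) {
    return(tibble::tibble(x_um = numeric(), y_um = numeric(),
                          z_um = numeric(), intensity = numeric()))
  }
  idx <- arrayInd(cand, d)
  # local maximum over the 26-neighbourhood
  is_max <- vapply(seq_along(cand), function(k) {
    z <- idx[k, 1]; y <- idx[k, 2]; x <- idx[k, 3]
    zz <- max(1, z - 1):min(d[1], z + 1)
    yy <- max(1, y - 1):min(d[2], y + 1)
    xx <- max(1, x - 1):min(d[3], x + 1)
    sm[z, y, x] >= max(sm[zz, yy, xx])
  }, logical(1))
  idx <- idx[is_max, , drop = FALSE]
  vals <- sm[cbind(idx)]

  # order bright-first and merge near-duplicates (plateau ties included)
  ord <- order(-vals, idx[, 1], idx[, 2], idx[, 3])
  idx <- idx[ord, , drop = FALSE]
  pos_um <- cbind(
    x = (idx[, 3] - 1) * vox[3],
    y = (idx[, 2] - 1) * vox[2],
    z = (idx[, 1] - 1) * vox[1]
  )
  keep <- rep(TRUE, nrow(idx))
  for (k in seq_len(nrow(idx))) {
    if (!keep[k]) next
    if (k < nrow(idx)) {
      later <- (k + 1):nrow(idx)
      dd <- sqrt(rowSums((pos_um[later, , drop = FALSE] -
                            matrix(pos_um[k, ], length(later), 3,
                                   byrow = TRUE))^2))
      keep[later][dd < min_separation_um] <- FALSE
    }
  }
  idx <- idx[keep, , drop = FALSE]

  # sub-voxel refinement: intensity-weighted centroid of the smoothed signal
  # above its local floor, within a window of ~2 sigma
  refine <- function(z, y, x) {
    win <- ceiling(2 * sigma_um / vox)
    zz <- max(1, z - win[1]):min(d[1], z + win[1])
    yy <- max(1, y - win[2]):min(d[2], y + win[2])
    xx <- max(1, x - win[3]):min(d[3], x + win[3])
    w <- sm[zz, yy, xx, drop = FALSE]
    w <- pmax(w - min(w), 0)
    tot <- sum(w)
    if (tot == 0) {
      return(c((x - 1) * vox[3], (y - 1) * vox[2], (z - 1) * vox[1]))
    }
    wz <- apply(w, 1, sum); wy <- apply(w, 2, sum); wx <- apply(w, 3, sum)
    c(
      sum((xx - 1) * vox[3] * wx) / tot,
      sum((yy - 1) * vox[2] * wy) / tot,
      sum((zz - 1) * vox[1] * wz) / tot
    )
  }
  cent <- t(vapply(seq_len(nrow(idx)),
                   function(k) refine(idx[k, 1], idx[k, 2], idx[k, 3]),
                   numeric(3)))
  tibble::tibble(
    x_um = cent[, 1], y_um = cent[, 2], z_um = cent[, 3],
    intensity = volume[cbind(idx)]
  )
}

#' Detect nuclei in every frame of a movie
#'
#' @param movie A `ca_movie`.
#' @inheritParams detect_nuclei
#' @return A tibble of detections with columns `frame` (0-based), `x_um`,
#'   `y_um`, `z_um`, `intensity`.
#' @export
detect_nuclei_movie <- function(movie, sigma_um = 2, threshold = 30,
                                min_separation_um = 4) {
  stopifnot(inherits(movie, "ca_movie"))
  n_frames <- dim(movie$nuclear)[4]
  purrr::map_dfr(seq_len(n_frames), function(f) {
    det <- detect_nuclei(movie$nuclear[, , , f], movie$acquisition,
                         sigma_um = sigma_um, threshold = threshold,
                         min_separation_um = min_separation_um)
    if (nrow(det) == 0) return(NULL)
    dplyr::mutate(det, frame = f - 1L, .before = 1)
  })
}

# gated optimal assignment between two point sets; returns integer vector of
# length nrow(a): matched index in b or NA. Ties broken toward lower indices.
assign_gated <- function(a, b, max_cost) {
  n <- nrow(a); m <- nrow(b)
  if (n == 0 || m == 0) return(rep(NA_integer_, n))
  cost <- matrix(0, n, m)
  for (i in seq_len(n)) {
    cost[i, ] <- sqrt(colSums((t(b) - a[i, ])^2))
  }
  big <- 1e8
  gated <- cost > max_cost
  size <- n + m
  full <- matrix(big, size, size)
  full[seq_len(n), seq_len(m)] <- ifelse(gated, big, cost)
  # dummy assignment (start/stop) costs just above the gate
  for (i in seq_len(n)) full[i, m + i] <- max_cost * 1.0000001
  for (j in seq_len(m)) full[n + j, j] <- max_cost * 1.0000001
  full[(n + 1):size, (m + 1):size] <- 0
  # deterministic tie-break: prefer low row/col indices
  eps <- outer(seq_len(size), seq_len(size),
               function(i, j) i * 1e-7 + j * 1e-10)
  sol <- clue::solve_LSAP(full + eps)
  match <- as.integer(sol)[seq_len(n)]
  match[match > m | gated[cbind(seq_len(n), pmin(match, m))]] <- NA_integer_
  match
}

#' Link per-frame detections into nucleus trajectories
#'
#' @param detections Tibble from [detect_nuclei_movie()] (columns `frame`,
#'   `x_um`, `y_um`, `z_um`).
#' @param acquisition An [acquisition_config()] (for frame times).
#' @param max_disp_um Gating radius: maximum displacement per frame interval,
#'   micrometres.
#' @param gap_max Maximum number of consecutive missing frames bridged by gap
#'   closing.
#' @param min_length Tracks spanning fewer frames are dropped.
#'
#' @return A tibble of trajectories: `cell_id`, `frame`, `t_s`, `x_um`,
#'   `y_um`, `z_um`, `mitosis_flag`, `excluded`, plus `det_row` (row index of
#'   the source detection, for evaluation). Gap frames are absent rows
#'   (missing, not interpolated).
#' @export
link_tracks <- function(detections,
                        acquisition,
                        max_disp_um = 6,
                        gap_max = 2,
                        min_length = 3) {
  check_columns(detections, c("frame", "x_um", "y_um", "z_um"), "detections")
  stopifnot(inherits(acquisition, "ca_acquisition"))
  det <- dplyr::arrange(detections, .data$frame)
  det$det_row <- seq_len(nrow(det))
  frames <- sort(unique(det$frame))
  track_of <- rep(NA_integer_, nrow(det))
  n_tracks <- 0L

  by_frame <- split(seq_len(nrow(det)), det$frame)
  prev_idx <- integer(0)
  for (f in frames) {
    cur_idx <- by_frame[[as.character(f)]]
    if (length(prev_idx) == 0) {
      for (i in cur_idx) {
        n_tracks <- n_tracks + 1L
        track_of[i] <- n_tracks
      }
    } else {
      a <- as.matrix(det[prev_idx, c("x_um", "y_um", "z_um")])
      b <- as.matrix(det[cur_idx, c("x_um", "y_um", "z_um")])
      gap_frames <- f - det$frame[prev_idx[1]]
      match <- assign_gated(a, b, max_disp_um)
      assigned <- rep(FALSE, length(cur_idx))
      for (i in seq_along(prev_idx)) {
        if (!is.na(match[i])) {
          track_of[cur_idx[match[i]]] <- track_of[prev_idx[i]]
          assigned[match[i]] <- TRUE
        }
      }
      for (j in which(!assigned)) {
        n_tracks <- n_tracks + 1L
        track_of[cur_idx[j]] <- n_tracks
      }
    }
    prev_idx <- cur_idx
  }
  det$track <- track_of

  # gap closing: join a track ending at f to one starting at f+g+1 (g >= 1)
  repeat {
    ends <- dplyr::summarise(
      dplyr::group_by(det, .data$track),
      f_end = max(.data$frame), f_start = min(.data$frame)
    )
    merged <- FALSE
    end_pos <- dplyr::inner_join(
      ends, det, by = c("track", "f_end" = "frame")
    )
    start_pos <- dplyr::inner_join(
      ends, det, by = c("track", "f_start" = "frame")
    )
    for (g in seq_len(max(gap_max, 0))) {
      for (k in seq_len(nrow(end_pos))) {
        e <- end_pos[k, ]
        cand <- start_pos[start_pos$f_start == e$f_end + g + 1, ]
        if (nrow(cand) == 0) next
        dd <- sqrt((cand$x_um - e$x_um)^2 + (cand$y_um - e$y_um)^2 +
                     (cand$z_um - e$z_um)^2)
        ok <- which(dd <= max_disp_um * (g + 1))
        if (length(ok) == 0) next
        j <- ok[which.min(dd[ok])]
        det$track[det$track == cand$track[j]] <- e$track
        merged <- TRUE
        break
      }
      if (merged) break
    }
    if (!merged) break
  }

  # drop short tracks, relabel deterministically by first appearance
  span <- dplyr::summarise(
    dplyr::group_by(det, .data$track),
    n = dplyr::n(), f0 = min(.data$frame),
    x0 = .data$x_um[which.min(.data$frame)]
  )
  keep <- span$track[span$n >= min_length]
  det <- det[det$track %in% keep, ]
  span <- span[span$track %in% keep, ]
  span <- dplyr::arrange(span, .data$f0, .data$x0)
  relabel <- setNames(seq_len(nrow(span)), span$track)
  t_all <- frame_times(acquisition)
  out <- tibble::tibble(
    cell_id = sprintf("track_%03d", relabel[as.character(det$track)]),
    frame = as.integer(det$frame),
    t_s = t_all[det$frame + 1L],
    x_um = det$x_um, y_um = det$y_um, z_um = det$z_um,
    mitosis_flag = FALSE, excluded = FALSE,
    det_row = det$det_row
  )
  dplyr::arrange(out, .data$cell_id, .data$frame)
}

#' Flag mitotic trajectories for exclusion
#'
#' Cells never show calcium rises during M phase, so dividing cells must be
#' excluded from quantification. Two division signatures are recognised:
#'
#' 1. a trajectory ending at frame `f` with at least two detections (or new
#'    trajectories) appearing at `f + 1` within `split_radius_um` of its last
#'    position — parent and both daughters are flagged;
#' 2. a new trajectory appearing at `f + 1` within `split_radius_um` of a
#'    trajectory present at both `f` and `f + 1` — covers linkers that
#'    continue the parent track into one daughter.
#'
#' @param trajectories Tibble from [link_tracks()].
#' @param detections Optional per-frame detection tibble (`frame`, `x_um`,
#'   `y_um`, `z_um`); lets signature 1 fire even when a daughter was too
#'   short-lived to form a track. Defaults to the trajectory positions.
#' @param split_radius_um Maximum parent-to-daughter distance, micrometres.
#' @return `trajectories` with `mitosis_flag` and `excluded` set on flagged
#'   tracks.
#' @export
flag_mitosis <- function(trajectories, detections = NULL,
                         split_radius_um = 6) {
  tr <- trajectories
  if (is.null(detections)) {
    detections <- tr[, c("frame", "x_um", "y_um", "z_um")]
  }
  ids <- unique(tr$cell_id)
  info <- dplyr::summarise(
    dplyr::group_by(tr, .data$cell_id),
    f_start = min(.data$frame), f_end = max(.data$frame)
  )
  flagged <- character(0)
  last_frame <- max(tr$frame)
  first_frame <- min(tr$frame)

  pos_at <- function(id, f) {
    r <- tr[tr$cell_id == id & tr$frame == f, ]
    if (nrow(r) == 0) return(NULL)
    c(r$x_um[1], r$y_um[1], r$z_um[1])
  }

  # signature 1: ended parent with >= 2 nearby detections the next frame
  for (k in seq_len(nrow(info))) {
    fe <- info$f_end[k]
    if (fe >= last_frame) next
    p <- pos_at(info$cell_id[k], fe)
    nxt <- detections[detections$frame == fe + 1, , drop = FALSE]
    if (nrow(nxt) < 2) next
    dd <- sqrt((nxt$x_um - p[1])^2 + (nxt$y_um - p[2])^2 +
                 (nxt$z_um - p[3])^2)
    near <- which(dd <= split_radius_um)
    if (length(near) >= 2) {
      flagged <- c(flagged, info$cell_id[k])
      # flag daughter tracks that start at fe + 1 near the parent
      daughters <- info$cell_id[info$f_start == fe + 1 &
                                  info$cell_id != info$cell_id[k]]
      for (d in daughters) {
        q <- pos_at(d, fe + 1)
        if (sqrt(sum((q - p)^2)) <= split_radius_um) flagged <- c(flagged, d)
      }
    }
  }

  # signature 2: new track appearing next to a continuing track
  for (k in seq_len(nrow(info))) {
    fs <- info$f_start[k]
    if (fs <= first_frame) next
    q <- pos_at(info$cell_id[k], fs)
    for (j in seq_len(nrow(info))) {
      if (j == k) next
      if (info$f_start[j] <= fs - 1 && info$f_end[j] >= fs) {
        p_before <- pos_at(info$cell_id[j], fs - 1)
        if (is.null(p_before)) next
        if (sqrt(sum((q - p_before)^2)) <= split_radius_um) {
          flagged <- c(flagged, info$cell_id[k], info$cell_id[j])
        }
      }
    }
  }

  flagged <- unique(flagged)
  tr$mitosis_flag <- tr$cell_id %in% flagged
  tr$excluded <- tr$excluded | tr$mitosis_flag
  tr
}
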