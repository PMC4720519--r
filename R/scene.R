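#' Generate a ground-truth scene of sprouting endothelial cells
#'
#' Builds a synthetic cohort of cells with known roles, trajectories,
#' baselines and spike trains, mirroring the configurations seen in trunk
#' angiogenesis recordings:
#'
#' * `"wildtype"`: at each somite boundary one budding tip cell and one
#'   following stalk cell, both oscillating (tip faster than stalk), plus
#'   quiescent non-budding cells along the dorsal aorta (rate 0). Tip and
#'   stalk cells migrate dorsally; aorta cells are quasi-static.
#' * `"vegfr_inhibited"`: identical geometry but every spike rate is zero,
#'   emulating pharmacological receptor blockade.
#' * `"dll4_kd"`: loss of lateral inhibition at sprout selection: each
#'   boundary carries two budding oscillating neighbours with probability
#'   `p_double_budding` (one otherwise), and no stalk cells.
#'
#' Baseline fluorescence varies between cells (log-normal), reflecting
#' variable indicator expression.
#'
#' @param preset One of `"wildtype"`, `"vegfr_inhibited"`, `"dll4_kd"`.
#' @param acquisition An [acquisition_config()]; its `volume_shape` is filled
#'   in automatically (from cell extents plus a margin) when missing.
#' @param n_boundaries Number of somite boundaries along the aorta.
#' @param n_da Number of non-budding aorta cells.
#' @param rates Named list of Poisson spike rates per minute for
#'   `tip`, `stalk`, `da`.
#' @param refractory_s Dead time between spikes, seconds.
#' @param p_double_budding For `"dll4_kd"`: probability that a boundary
#'   carries two budding oscillating cells.
#' @param migration_um_per_frame Dorsal migration step of budding cells,
#'   micrometres per frame.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of per-cell
#'   baseline fluorescence (arbitrary units).
#' @param n_mitosis Number of aorta cells that divide mid-recording (used to
#'   exercise mitosis flagging).
#' @param rng_seed Integer seed; scenes are reproducible given the seed.
#'
#' @return An object of class `ca_scene`: a list with tibbles `cells`
#'   (`cell_id`, `role`, `budding`, `boundary_x_um`, `baseline_F0`,
#'   `rate_per_min`), `trajectories` (`cell_id`, `frame`, `t_s`, `x_um`,
#'   `y_um`, `z_um`), `spikes` (`cell_id` + spike-train columns), the numeric
#'   vector `boundaries_x_um`, and the `acquisition`.
#' @examples
#' sc <- generate_scene("vegfr_inhibited",
#'   acquisition_config(duration_s = 200), rng_seed = 1)
#' nrow(sc$spikes) # no spikes under receptor blockade
#' @export
generate_scene <- function(preset = c("wildtype", "vegfr_inhibited", "dll4_kd"),
                           acquisition = acquisition_config(),
                           n_boundaries = 6,
                           n_da = 8,
                           rates = list(tip = 1.2, stalk = 0.6, da = 0),
                           refractory_s = 20,
                           p_double_budding = 0.8,
                           migration_um_per_frame = 0.3,
                           baseline_meanlog = log(100),
                           baseline_sdlog = 0.3,
                           n_mitosis = 0,
                           rng_seed = 1L) {
  if (is.character(preset)) {
    preset <- match.arg(preset)
  } else {
    abort(sprintf(
      "`preset` must be one of: %s.",
      paste(c("wildtype", "vegfr_inhibited", "dll4_kd"), collapse = ", ")
    ))
  }
  stopifnot(inherits(acquisition, "ca_acquisition"))
  if (preset == "vegfr_inhibited") {
    rates <- list(tip = 0, stalk = 0, da = 0)
  }

  boundaries_x_um <- 20 + (seq_len(n_boundaries) - 1) * 30
  span_x <- max(boundaries_x_um) + 20

  cells <- local_seed(rng_seed, {
    rows <- list()
    for (b in seq_len(n_boundaries)) {
      bx <- boundaries_x_um[b]
      if (preset == "dll4_kd") {
        n_bud <- if (runif(1) < p_double_budding) 2L else 1L
        for (k in seq_len(n_bud)) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            role = "tip", budding = TRUE, boundary_x_um = bx,
            x0 = bx - 2 + (k - 1) * 9, y0 = 12, speed = migration_um_per_frame
          )
        }
      } else {
        rows[[length(rows) + 1]] <- tibble::tibble(
          role = "tip", budding = TRUE, boundary_x_um = bx,
          x0 = bx - 2, y0 = 14, speed = migration_um_per_frame
        )
        rows[[length(rows) + 1]] <- tibble::tibble(
          role = "stalk", budding = TRUE, boundary_x_um = bx,
          x0 = bx + 6, y0 = 9, speed = migration_um_per_frame / 2
        )
      }
    }
    # non-budding aorta cells along the vessel, kept clear of budding cells
    # so nuclei stay resolvable (>= ~8 um spacing at the start)
    bud_x <- unlist(lapply(rows, function(r) r$x0))
    da_x <- seq(8, span_x - 8, length.out = n_da) + runif(n_da, -2, 2)
    for (x in da_x) {
      near <- bud_x[abs(bud_x - x) < 7]
      if (length(near) > 0) {
        xb <- near[which.min(abs(near - x))]
        x <- xb + sign(x - xb + 0.5) * 7
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        role = "da", budding = FALSE, boundary_x_um = NA_real_,
        x0 = x, y0 = 4, speed = 0
      )
    }
    out <- dplyr::bind_rows(rows)
    out$cell_id <- sprintf("cell_%02d", seq_len(nrow(out)))
    out$baseline_F0 <- rlnorm(nrow(out), baseline_meanlog, baseline_sdlog)
    out$rate_per_min <- unlist(rates[out$role], use.names = FALSE)
    dplyr::select(
      out, "cell_id", "role", "budding", "boundary_x_um",
      "baseline_F0", "rate_per_min", "x0", "y0", "speed"
    )
  })

  n_frames <- acquisition$n_frames
  t_s <- frame_times(acquisition)
  traj <- local_seed(rng_seed + 211L, {
    purrr::map_dfr(seq_len(nrow(cells)), function(i) {
      ph <- runif(3, 0, 2 * pi)
      wig <- if (cells$budding[i]) 0.4 else 0.15
      tibble::tibble(
        cell_id = cells$cell_id[i],
        frame = seq_len(n_frames) - 1L,
        t_s = t_s,
        x_um = cells$x0[i] + wig * sin(2 * pi * (0:(n_frames - 1)) / 80 + ph[1]),
        y_um = cells$y0[i] + cells$speed[i] * (0:(n_frames - 1)) +
          wig * sin(2 * pi * (0:(n_frames - 1)) / 60 + ph[2]),
        z_um = 20 + wig * sin(2 * pi * (0:(n_frames - 1)) / 70 + ph[3])
      )
    })
  })

  # optional divisions among aorta cells: parent stops, two daughters appear
  mitosis <- NULL
  if (n_mitosis > 0) {
    da_ids <- cells$cell_id[cells$role == "da"]
    stopifnot(n_mitosis <= length(da_ids))
    split_frame <- floor(n_frames / 2)
    for (m in seq_len(n_mitosis)) {
      pid <- da_ids[m]
      parent_rows <- traj$cell_id == pid & traj$frame >= split_frame
      last_pos <- traj[traj$cell_id == pid & traj$frame == split_frame - 1L, ]
      traj <- traj[!parent_rows, ]
      for (d in 1:2) {
        did <- sprintf("%s_d%d", pid, d)
        off <- if (d == 1) -3.5 else 3.5
        fr <- split_frame:(n_frames - 1L)
        traj <- dplyr::bind_rows(traj, tibble::tibble(
          cell_id = did, frame = as.integer(fr), t_s = t_s[fr + 1L],
          x_um = last_pos$x_um + off, y_um = last_pos$y_um, z_um = last_pos$z_um
        ))
        cells <- dplyr::bind_rows(cells, dplyr::mutate(
          cells[cells$cell_id == pid, ],
          cell_id = did, rate_per_min = 0
        ))
      }
      mitosis <- dplyr::bind_rows(mitosis, tibble::tibble(
        parent = pid,
        daughters = list(sprintf("%s_d%d", pid, 1:2)),
        split_frame = as.integer(split_frame)
      ))
    }
  }

  spikes <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    tr <- generate_spike_train(
      cells$rate_per_min[i], acquisition$duration_s,
      refractory_s = refractory_s,
      rng_seed = rng_seed + 7919L * i
    )
    if (nrow(tr) == 0) return(NULL)
    dplyr::mutate(tr, cell_id = cells$cell_id[i], .before = 1)
  })
  if (nrow(spikes) == 0) {
    spikes <- tibble::tibble(
      cell_id = character(), spike_time_s = numeric(),
      amplitude_dff = numeric(), rise_time_s = numeric(),
      decay_time_s = numeric()
    )
  }

  if (is.null(acquisition$volume_shape)) {
    margin <- 10
    acquisition$volume_shape <- as.integer(c(
      ceiling((max(traj$z_um) + margin) / acquisition$z_step_um) + 1L,
      ceiling((max(traj$y_um) + margin) / acquisition$xy_pixel_um) + 1L,
      ceiling((max(traj$x_um) + margin) / acquisition$xy_pixel_um) + 1L
    ))
  }

  structure(
    list(
      preset = preset,
      cells = dplyr::select(cells, -"x0", -"y0", -"speed"),
      trajectories = traj,
      spikes = spikes,
      mitosis = mitosis,
      boundaries_x_um = boundaries_x_um,
      acquisition = acquisition,
      rng_seed = as.integer(rng_seed)
    ),
    class = "ca_scene"
  )
}

#' @export
print.ca_scene <- function(x, ...) {
  cat(sprintf(
    "<ca_scene> preset '%s': %d cells (%s), %d spikes, %d boundaries, %d frames\n",
    x$preset, nrow(x$cells),
    paste(sprintf("%d %s", table(x$cells$role), names(table(x$cells$role))),
          collapse = ", "),
    nrow(x$spikes), length(x$boundaries_x_um), x$acquisition$n_frames
  ))
  invisible(x)
}

#' Tidy a ground-truth scene into its cell table
#'
#' @param x A `ca_scene`.
#' @param ... Unused.
#' @return The `cells` tibble with a per-cell ground-truth spike count added.
#' @method tidy ca_scene
#' @export
tidy.ca_scene <- function(x, ...) {
  counts <- dplyr::count(x$spikes, .data$cell_id, name = "n_true_spikes")
  out <- dplyr::left_join(x$cells, counts, by = "cell_id")
  out$n_true_spikes[is.na(out$n_true_spikes)] <- 0L
  out
}

#' Render noisy fluorescence traces for every cell of a scene
#'
#' Trace-level counterpart of [render_movie()]: samples each cell's kinetic
#' model at the acquisition frame times and adds Gaussian noise proportional
#' to the cell's baseline.
#'
#' @param scene A `ca_scene`.
#' @param noise_frac Gaussian noise standard deviation as a fraction of each
#'   cell's baseline F0 (default 3%).
#' @return A tibble `cell_id`, `frame`, `t_s`, `F` for all cells.
#' @export
render_scene_traces <- function(scene, noise_frac = 0.03) {
  stopifnot(inherits(scene, "ca_scene"))
  purrr::map_dfr(seq_len(nrow(scene$cells)), function(i) {
    id <- scene$cells$cell_id[i]
    tr <- scene$spikes[scene$spikes$cell_id == id, ]
    f <- render_trace(
      tr, scene$cells$baseline_F0[i], scene$acquisition,
      noise_sd = noise_frac * scene$cells$baseline_F0[i],
      rng_seed = scene$rng_seed + 31L * i, cell_id = id
    )
    # restrict to frames where the cell exists (divisions truncate tracks)
    fr <- scene$trajectories$frame[scene$trajectories$cell_id == id]
    f[f$frame %in% fr, ]
  })
}
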