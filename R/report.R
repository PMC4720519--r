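#' Two-sample comparison of per-cell metrics
#'
#' Classical two-sample Student's t test (equal-variance by default, the
#' form conventionally reported for these cell-group comparisons), two-sided,
#' significance at alpha = 0.05. Welch and paired variants are available by
#' flag; no multiple-testing correction is applied unless requested via
#' `p_adjust_method` on [compare_many()].
#'
#' @param values_A,values_B Numeric vectors (each of length >= 2).
#' @param labels Length-2 character vector of group labels.
#' @param var_equal Use the pooled-variance Student form (default `TRUE`);
#'   `FALSE` gives Welch.
#' @param paired Paired test (requires equal lengths).
#' @return An object of class `ca_comparison` wrapping the test with group
#'   summaries; see [tidy.ca_comparison()].
#' @examples
#' cmp <- compare_groups(c(1, 2, 3, 4), c(5, 6, 7, 8))
#' tidy(cmp)
#' @export
compare_groups <- function(values_A, values_B,
                           labels = c("A", "B"),
                           var_equal = TRUE,
                           paired = FALSE) {
  if (length(values_A) < 2 || length(values_B) < 2) {
    abort("each group needs at least 2 values")
  }
  ht <- t.test(values_A, values_B, var.equal = var_equal, paired = paired)
  structure(
    list(
      labels = labels,
      n = c(length(values_A), length(values_B)),
      means = c(mean(values_A), mean(values_B)),
      sds = c(sd(values_A), sd(values_B)),
      t_statistic = unname(ht$statistic),
      df = unname(ht$parameter),
      p_value = ht$p.value,
      significant = ht$p.value < 0.05,
      var_equal = var_equal,
      paired = paired
    ),
    class = "ca_comparison"
  )
}

#' @export
print.ca_comparison <- function(x, ...) {
  cat(sprintf(
    "<ca_comparison> %s (n=%d, mean %.3g +/- %.3g) vs %s (n=%d, mean %.3g +/- %.3g)\n  t = %.3f, df = %.1f, p = %.3g%s\n",
    x$labels[1], x$n[1], x$means[1], x$sds[1],
    x$labels[2], x$n[2], x$means[2], x$sds[2],
    x$t_statistic, x$df, x$p_value,
    if (x$significant) " (significant at 0.05)" else ""
  ))
  invisible(x)
}

#' Tidy a group comparison
#' @param x A `ca_comparison`.
#' @param ... Unused.
#' @return One-row tibble with group summaries, t statistic, p value and
#'   the significance call.
#' @method tidy ca_comparison
#' @export
tidy.ca_comparison <- function(x, ...) {
  tibble::tibble(
    group_A = x$labels[1], group_B = x$labels[2],
    n_A = x$n[1], n_B = x$n[2],
    mean_A = x$means[1], mean_B = x$means[2],
    sd_A = x$sds[1], sd_B = x$sds[2],
    t_statistic = x$t_statistic, df = x$df,
    p_value = x$p_value, significant = x$significant
  )
}

#' @rdname tidy.ca_comparison
#' @method glance ca_comparison
#' @export
glance.ca_comparison <- function(x, ...) {
  tibble::tibble(
    t_statistic = x$t_statistic, df = x$df, p_value = x$p_value,
    significant = x$significant,
    method = if (x$paired) "paired t" else if (x$var_equal)
      "Student t (pooled)" else "Welch t"
  )
}

#' Compare one metric across several group pairs
#'
#' @param metrics Metric tibble with a `group` column.
#' @param value Name of the metric column to compare.
#' @param pairs Two-column data frame of group label pairs; defaults to all
#'   unordered pairs.
#' @param p_adjust_method Optional [stats::p.adjust()] method (e.g.
#'   `"holm"`); `"none"` by default.
#' @inheritParams compare_groups
#' @return A tibble, one row per pair (see [tidy.ca_comparison()]), with
#'   `p_adjusted` when adjustment is requested.
#' @export
compare_many <- function(metrics, value, pairs = NULL, var_equal = TRUE,
                         p_adjust_method = "none") {
  check_columns(metrics, c("group", value), "metrics")
  groups <- unique(metrics$group)
  if (is.null(pairs)) {
    pairs <- utils::combn(groups, 2)
    pairs <- tibble::tibble(group_A = pairs[1, ], group_B = pairs[2, ])
  }
  out <- purrr::map_dfr(seq_len(nrow(pairs)), function(k) {
    a <- metrics[[value]][metrics$group == pairs$group_A[k]]
    b <- metrics[[value]][metrics$group == pairs$group_B[k]]
    tidy(compare_groups(a, b, labels = c(pairs$group_A[k], pairs$group_B[k]),
                        var_equal = var_equal))
  })
  if (p_adjust_method != "none") {
    out$p_adjusted <- stats::p.adjust(out$p_value, p_adjust_method)
    out$significant <- out$p_adjusted < 0.05
  }
  out
}

#' Run the full quantification pipeline on a synthetic scene
#'
#' Executes scene generation, (optionally) movie rendering + nucleus
#' tracking + ROI extraction, dF/F0 normalisation, threshold calibration,
#' peak detection, per-cell metrics, tip-stalk synchrony and boundary
#' counts, and role-wise group comparisons. Deterministic given `rng_seed`.
#'
#' @param preset Scene preset (see [generate_scene()]).
#' @param mode `"traces"` quantifies rendered per-cell traces directly
#'   (ground-truth trajectories); `"movie"` renders the two-channel movie
#'   and runs detection + tracking + extraction first.
#' @param rng_seed Integer seed for every stochastic stage.
#' @param acquisition Acquisition configuration.
#' @param out_dir Optional directory: stage tables are written as CSV and a
#'   `summary.json` is emitted.
#' @param threshold Optional numeric dF/F0 threshold overriding cohort
#'   calibration.
#' @param ... Passed to [generate_scene()].
#' @return A list of class `ca_run` with elements `scene`, `tracks` (movie
#'   mode), `traces`, `dff`, `threshold`, `peaks`, `metrics` (with roles and
#'   exclusion applied), `synchrony`, `boundary_counts`, `comparisons`, and
#'   `summary` (named list of headline numbers).
#' @export
run_pipeline <- function(preset = "wildtype",
                         mode = c("traces", "movie"),
                         rng_seed = 1L,
                         acquisition = acquisition_config(),
                         out_dir = NULL,
                         threshold = NULL,
                         ...) {
  mode <- match.arg(mode)
  scene <- generate_scene(preset, acquisition = acquisition,
                          rng_seed = rng_seed, ...)
  truth <- tidy(scene)

  tracks <- NULL
  if (mode == "movie") {
    movie <- render_movie(scene)
    detections <- detect_nuclei_movie(movie)
    tracks <- link_tracks(detections, scene$acquisition)
    tracks <- flag_mitosis(tracks, detections)
    id_map <- match_tracks(tracks, scene)
    traces <- extract_trace(movie, tracks[!tracks$excluded, ])
    # label tracks by their matched ground-truth cell for role annotation
    traces <- dplyr::left_join(traces, id_map, by = "cell_id")
    role_tbl <- dplyr::select(truth, true_cell_id = "cell_id", "role",
                              "budding", "boundary_x_um")
    traces <- dplyr::left_join(traces, role_tbl, by = "true_cell_id")
    pos0 <- dplyr::summarise(
      dplyr::group_by(tracks, .data$cell_id),
      boundary_ref_x_um = .data$x_um[which.min(.data$frame)]
    )
  } else {
    traces <- render_scene_traces(scene)
    excluded_ids <- if (!is.null(scene$mitosis)) {
      unique(c(scene$mitosis$parent, unlist(scene$mitosis$daughters)))
    } else character(0)
    traces <- traces[!traces$cell_id %in% excluded_ids, ]
    traces <- dplyr::left_join(
      traces,
      dplyr::select(truth, "cell_id", "role", "budding", "boundary_x_um"),
      by = "cell_id"
    )
    pos0 <- dplyr::summarise(
      dplyr::group_by(scene$trajectories, .data$cell_id),
      boundary_ref_x_um = .data$x_um[which.min(.data$frame)]
    )
  }

  dff <- compute_dff(traces)
  thr <- if (!is.null(threshold)) {
    structure(list(reference_100pct = threshold / 0.2, threshold = threshold,
                   frac = 0.2, cohort_id = "override",
                   n_peaks_pooled = NA_integer_, top_peaks = NULL),
              class = "ca_threshold")
  } else {
    tryCatch(
      calibrate_threshold(dff, cohort_id = preset),
      error = function(e) {
        # quiescent cohorts (e.g. receptor-inhibited) carry no peaks;
        # fall back to the provisional absolute floor
        structure(list(reference_100pct = 1, threshold = 0.2, frac = 0.2,
                       cohort_id = paste0(preset, "_floor"),
                       n_peaks_pooled = 0L, top_peaks = NULL),
                  class = "ca_threshold")
      }
    )
  }
  peaks <- detect_peaks(dff, thr)
  metrics <- oscillation_metrics(dff, peaks)
  roles <- dplyr::distinct(
    dplyr::select(traces, "cell_id", "role", "budding", "boundary_x_um")
  )
  metrics <- dplyr::left_join(metrics, roles, by = "cell_id")
  metrics <- dplyr::left_join(metrics, pos0, by = "cell_id")

  # tip-stalk synchrony per boundary (when both roles are present)
  sync <- NULL
  tip_stalk <- dplyr::filter(metrics, .data$role %in% c("tip", "stalk"),
                             !is.na(.data$boundary_x_um))
  if (nrow(tip_stalk) > 0) {
    pairs <- tidyr::pivot_wider(
      dplyr::select(tip_stalk, "boundary_x_um", "role", "cell_id"),
      names_from = "role", values_from = "cell_id",
      values_fn = function(x) x[1]
    )
    if (all(c("tip", "stalk") %in% names(pairs))) {
      pairs <- dplyr::filter(pairs, !is.na(.data$tip), !is.na(.data$stalk))
      if (nrow(pairs) > 0) {
        sync <- synchrony_table(
          peaks, tibble::tibble(cell_A = pairs$tip, cell_B = pairs$stalk)
        )
      }
    }
  }

  counts <- count_oscillating_cells(metrics, scene$boundaries_x_um)

  comparisons <- NULL
  freq_by_role <- dplyr::filter(dplyr::rename(metrics, group = "role"),
                                !is.na(.data$group))
  if (length(unique(freq_by_role$group)) >= 2 &&
      all(table(freq_by_role$group) >= 2)) {
    comparisons <- compare_many(freq_by_role, "frequency_per_min")
  }

  mean_freq <- function(r) {
    v <- metrics$frequency_per_min[metrics$role == r]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  summary <- list(
    preset = preset, mode = mode, rng_seed = rng_seed,
    n_cells = nrow(metrics),
    threshold = thr$threshold,
    reference_100pct = thr$reference_100pct,
    mean_frequency_tip = mean_freq("tip"),
    mean_frequency_stalk = mean_freq("stalk"),
    mean_frequency_da = mean_freq("da"),
    mean_dff_tip = mean(metrics$mean_dff[metrics$role == "tip"]),
    pct_oscillating = 100 * mean(metrics$oscillating),
    mean_time_to_peak_s = mean(peaks$time_to_peak_s, na.rm = TRUE)
  )

  run <- structure(
    list(scene = scene, tracks = tracks, traces = traces, dff = dff,
         threshold = thr, peaks = peaks, metrics = metrics,
         synchrony = sync, boundary_counts = counts,
         comparisons = comparisons, summary = summary),
    class = "ca_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.ca_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<ca_run> preset '%s' (%s mode, seed %d): %d cells, threshold %.3g\n",
    s$preset, s$mode, s$rng_seed, s$n_cells, s$threshold
  ))
  cat(sprintf(
    "  mean frequency (per min): tip %.3g, stalk %.3g, da %.3g\n",
    s$mean_frequency_tip, s$mean_frequency_stalk, s$mean_frequency_da
  ))
  invisible(x)
}

#' Write all stage outputs of a run to a directory
#'
#' @param run A `ca_run`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(run$tracks)) {
    write_table(run$tracks, file.path(dir, "tracks.csv"), "tracks")
  }
  write_table(run$traces, file.path(dir, "traces.csv"), "traces")
  write_table(run$dff, file.path(dir, "dff.csv"), "dff")
  write_table(run$peaks, file.path(dir, "peaks.csv"), "peaks")
  write_table(run$metrics, file.path(dir, "metrics.csv"), "metrics")
  if (!is.null(run$synchrony)) {
    readr::write_csv(run$synchrony, file.path(dir, "synchrony.csv"), na = "")
  }
  readr::write_csv(run$boundary_counts$counts,
                   file.path(dir, "boundary_counts.csv"), na = "")
  if (!is.null(run$comparisons)) {
    readr::write_csv(run$comparisons, file.path(dir, "comparisons.csv"),
                     na = "")
  }
  thr <- run$threshold
  jsonlite::write_json(
    list(reference_100pct = thr$reference_100pct, threshold = thr$threshold,
         cohort_id = thr$cohort_id, n_peaks_pooled = thr$n_peaks_pooled,
         top_peaks = thr$top_peaks),
    file.path(dir, "threshold.json"), auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(run$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Match tracked trajectories to ground-truth scene cells
#'
#' Greedy nearest matching on mean distance over shared frames; used to
#' annotate tracks with ground-truth roles and to score link accuracy.
#'
#' @param tracks Trajectories from [link_tracks()].
#' @param scene The generating `ca_scene`.
#' @param max_dist_um Maximum mean distance for a valid match.
#' @return Tibble `cell_id` (track), `true_cell_id` (scene cell or `NA`).
#' @export
match_tracks <- function(tracks, scene, max_dist_um = 5) {
  truth <- scene$trajectories
  track_ids <- unique(tracks$cell_id)
  true_ids <- unique(truth$cell_id)
  md <- matrix(Inf, length(track_ids), length(true_ids),
               dimnames = list(track_ids, true_ids))
  for (i in seq_along(track_ids)) {
    a <- tracks[tracks$cell_id == track_ids[i], ]
    m <- dplyr::inner_join(a, truth, by = "frame", suffix = c("_a", "_b"))
    if (nrow(m) == 0) next
    dd <- sqrt((m$x_um_a - m$x_um_b)^2 + (m$y_um_a - m$y_um_b)^2 +
                 (m$z_um_a - m$z_um_b)^2)
    agg <- tapply(dd, m$cell_id_b, mean)
    md[i, names(agg)] <- agg
  }
  out <- tibble::tibble(cell_id = track_ids, true_cell_id = NA_character_)
  taken <- character(0)
  ord <- order(apply(md, 1, min))
  for (i in ord) {
    cand <- md[i, ]
    cand[names(cand) %in% taken] <- Inf
    j <- which.min(cand)
    if (is.finite(cand[j]) && cand[j] <= max_dist_um) {
      out$true_cell_id[i] <- colnames(md)[j]
      taken <- c(taken, colnames(md)[j])
    }
  }
  out
}

#' Score linking accuracy of tracks against a ground-truth scene
#'
#' Every detection is identified with its nearest ground-truth cell at that
#' frame; a frame-to-consecutive-frame link within a track is correct when
#' both endpoints carry the same ground-truth identity.
#'
#' @param tracks Trajectories from [link_tracks()].
#' @param scene The generating `ca_scene`.
#' @return A list with `n_links`, `n_correct`, `accuracy`.
#' @export
link_accuracy <- function(tracks, scene) {
  truth <- scene$trajectories
  truth_by_frame <- split(truth, truth$frame)
  gt_id <- vapply(seq_len(nrow(tracks)), function(k) {
    tf <- truth_by_frame[[as.character(tracks$frame[k])]]
    if (is.null(tf)) return(NA_character_)
    dd <- sqrt((tf$x_um - tracks$x_um[k])^2 + (tf$y_um - tracks$y_um[k])^2 +
                 (tf$z_um - tracks$z_um[k])^2)
    tf$cell_id[which.min(dd)]
  }, character(1))
  d <- tibble::tibble(cell_id = tracks$cell_id, frame = tracks$frame,
                      gt = gt_id)
  d <- dplyr::arrange(d, .data$cell_id, .data$frame)
  same_track <- d$cell_id[-1] == d$cell_id[-nrow(d)]
  consecutive <- diff(d$frame) == 1
  links <- which(same_track & consecutive)
  correct <- d$gt[links] == d$gt[links + 1]
  list(
    n_links = length(links),
    n_correct = sum(correct),
    accuracy = if (length(links)) mean(correct) else NA_real_
  )
}
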