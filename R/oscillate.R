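#' @section Oscillation quantification:
#' Raw traces F(t) are normalised to dF/F0 with F0 the mean over the
#' quietest 50-s window; oscillations are calcium rises whose dF/F0 apex
#' exceeds 20% of a cohort-calibrated reference (the mean of the three
#' highest peaks among oscillating wild-type cells); per-cell metrics are
#' oscillation frequency (per minute) and mean dF/F0.
#' @name caosc-oscillate
#' @keywords internal
NULL

# sampling interval of a trace, inferred from its time stamps
infer_dt <- function(t_s) {
  d <- diff(sort(unique(t_s)))
  if (length(d) == 0) abort("trace has fewer than 2 time points")
  min(d)
}

# minimum sliding-window mean (the quietest window); NA samples are excluded
# from window means; windows with no finite sample are skipped
baseline_min_window <- function(f, n_win) {
  n <- length(f)
  if (n_win > n) abort("trace is shorter than the baseline window")
  best <- Inf
  for (i in seq_len(n - n_win + 1)) {
    w <- f[i:(i + n_win - 1)]
    w <- w[is.finite(w)]
    if (length(w) == 0) next
    best <- min(best, mean(w))
  }
  if (!is.finite(best)) abort("trace has no finite samples")
  best
}

#' Estimate per-cell baseline fluorescence F0
#'
#' F0 is the mean fluorescence over a sliding window of `window_s` seconds,
#' taken at the window position minimising that mean — the quietest stretch
#' of the recording. Anchoring the window at the quietest stretch keeps the
#' baseline honest for cells that oscillate from the first frame.
#'
#' @param traces Tibble with `cell_id`, `t_s`, `F` (missing samples allowed
#'   as `NA`).
#' @param window_s Baseline window length, seconds (default 50).
#' @return A tibble `cell_id`, `F0`.
#' @examples
#' tr <- tibble::tibble(cell_id = "c", t_s = seq(0, 95, 5), F = 100)
#' compute_baseline(tr)$F0
#' @export
compute_baseline <- function(traces, window_s = 50) {
  check_columns(traces, c("cell_id", "t_s", "F"), "traces")
  check_number(window_s, "window_s", 0, strict = TRUE)
  dplyr::summarise(
    dplyr::group_by(traces, .data$cell_id),
    F0 = {
      dt <- infer_dt(.data$t_s)
      if (max(.data$t_s) - min(.data$t_s) < window_s) {
        abort(sprintf(
          "trace of cell %s spans less than the %g-s baseline window",
          .data$cell_id[1], window_s
        ))
      }
      n_win <- max(1L, round(window_s / dt))
      baseline_min_window(.data$F[order(.data$t_s)], n_win)
    },
    .groups = "drop"
  )
}

#' Normalise traces to dF/F0
#'
#' Computes `dff = (F - F0) / F0` per sample. Missing samples propagate as
#' missing. The result is invariant under positive rescaling of F.
#'
#' @inheritParams compute_baseline
#' @param baselines Optional `cell_id`/`F0` tibble; computed with
#'   [compute_baseline()] when omitted.
#' @return The input with `F0` and `dff` columns added.
#' @export
compute_dff <- function(traces, baselines = NULL, window_s = 50) {
  check_columns(traces, c("cell_id", "t_s", "F"), "traces")
  if (is.null(baselines)) baselines <- compute_baseline(traces, window_s)
  check_columns(baselines, c("cell_id", "F0"), "baselines")
  if (any(baselines$F0 <= 0)) {
    abort(sprintf(
      "non-positive baseline F0 for cell(s): %s",
      paste(baselines$cell_id[baselines$F0 <= 0], collapse = ", ")
    ))
  }
  out <- dplyr::left_join(traces, baselines, by = "cell_id")
  dplyr::mutate(out, dff = (.data$F - .data$F0) / .data$F0)
}

# peak detection on one numeric series --------------------------------------
# returns indices and kinetic quantities; exhaustively checkable.
# A peak is a local maximum at or above the absolute threshold whose RISE
# from the preceding trough (the minimum since the previously accepted peak,
# or since the trace start) also reaches the threshold: an oscillation is an
# increase of the threshold size, so the rise is measured on the rising
# side. Candidates are processed in time order and must clear the previously
# accepted apex by min_separation_s.
detect_peaks_series <- function(dff, t_s, threshold, min_separation_s,
                                onset_frac = 0.1) {
  ok <- which(is.finite(dff))
  x <- dff[ok]
  t <- t_s[ok]
  n <- length(x)
  if (n < 2) return(NULL)

  # local maxima (boundaries eligible; plateaus yield their first sample)
  is_max <- vapply(seq_len(n), function(i) {
    left_ok <- i == 1 || x[i] > x[i - 1]
    right_ok <- i == n || x[i] >= x[i + 1]
    left_ok && right_ok
  }, logical(1))
  cand <- which(is_max & x >= threshold)
  if (length(cand) == 0) return(NULL)

  # scan candidates in time order with hysteresis: a new event needs a rise
  # of >= threshold from the trough since the last accepted apex, and the
  # signal must first have dropped by >= rearm_frac * threshold below that
  # apex (otherwise a higher candidate replaces the current apex: it is the
  # same rise, e.g. a noise maximum on a slow rising flank)
  rearm_frac <- 0.5
  kept <- integer(0)
  for (i in cand) {
    if (length(kept) == 0) {
      trough <- min(x[1:i])
      if (x[i] - trough >= threshold) kept <- i
      next
    }
    prev <- kept[length(kept)]
    seg_min <- min(x[prev:i])
    rearmed <- (x[prev] - seg_min) >= rearm_frac * threshold
    if (rearmed && t[i] - t[prev] >= min_separation_s &&
        x[i] - seg_min >= threshold) {
      kept <- c(kept, i)
    } else if (!rearmed && x[i] > x[prev]) {
      kept[length(kept)] <- i # same rise: apex moves up
    }
  }
  if (length(kept) == 0) return(NULL)

  # onset: last upward crossing of onset_frac * apex before the apex,
  # linearly interpolated between samples
  onset <- vapply(kept, function(i) {
    level <- onset_frac * x[i]
    j <- i
    while (j > 1 && x[j - 1] > level) j <- j - 1
    if (j == 1) return(NA_real_) # apex at start or never below level
    # crossing between samples j-1 and j
    t[j - 1] + (t[j] - t[j - 1]) * (level - x[j - 1]) / (x[j] - x[j - 1])
  }, numeric(1))

  tibble::tibble(
    apex_idx = ok[kept],
    apex_time_s = t[kept],
    apex_dff = x[kept],
    onset_time_s = onset,
    time_to_peak_s = (t[kept] - onset) / (1 - onset_frac)
  )
}

#' Detect calcium oscillation peaks in dF/F0 traces
#'
#' A calcium oscillation is an increase of dF/F0 of at least the detection
#' threshold, so a peak is a local maximum that (i) reaches the threshold in
#' absolute dF/F0 and (ii) rises by at least the threshold from the
#' preceding trough — the minimum since the previously accepted peak (or the
#' trace start). Candidates are scanned in time order and must lie at least
#' `min_separation_s` after the previously accepted apex; measuring the rise
#' on the rising side keeps closely following spikes countable when the
#' decay of the previous spike has not returned to baseline. The onset of
#' each rise is the last upward crossing of
#' `onset_frac * apex` before the apex (linearly interpolated between
#' samples); assuming a linear rise, the reported `time_to_peak_s` corrects
#' the apex-to-onset interval for the onset fraction:
#' `(apex - onset) / (1 - onset_frac)`. Rises whose onset is undetectable
#' (apex at the trace start) get a missing time-to-peak.
#'
#' @param dff_traces Tibble with `cell_id`, `frame`, `t_s`, `dff`.
#' @param threshold A [calibrate_threshold()] object or a bare numeric
#'   dF/F0 threshold.
#' @param min_separation_s Minimum apex separation, seconds.
#' @param onset_frac Onset definition: fraction of the apex height whose
#'   last upward crossing marks the start of the rise.
#' @return A tibble `cell_id`, `apex_frame`, `apex_time_s`, `apex_dff`,
#'   `onset_time_s`, `time_to_peak_s` (zero rows for quiescent cells).
#' @export
detect_peaks <- function(dff_traces, threshold, min_separation_s = 10,
                         onset_frac = 0.1) {
  check_columns(dff_traces, c("cell_id", "t_s", "dff"), "dff_traces")
  thr <- if (inherits(threshold, "ca_threshold")) threshold$threshold
         else threshold
  check_number(thr, "threshold", 0, strict = TRUE)
  has_frame <- "frame" %in% names(dff_traces)
  out <- purrr::map_dfr(split(dff_traces, dff_traces$cell_id), function(d) {
    d <- d[order(d$t_s), ]
    p <- detect_peaks_series(d$dff, d$t_s, thr, min_separation_s, onset_frac)
    if (is.null(p)) return(NULL)
    tibble::tibble(
      cell_id = d$cell_id[1],
      apex_frame = if (has_frame) d$frame[p$apex_idx] else p$apex_idx - 1L,
      apex_time_s = p$apex_time_s,
      apex_dff = p$apex_dff,
      onset_time_s = p$onset_time_s,
      time_to_peak_s = p$time_to_peak_s
    )
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      cell_id = character(), apex_frame = integer(),
      apex_time_s = numeric(), apex_dff = numeric(),
      onset_time_s = numeric(), time_to_peak_s = numeric()
    )
  }
  out
}

#' Detection threshold from pooled peak heights
#'
#' The 100% reference is the mean of the three highest pooled dF/F0 peak
#' heights; the oscillation threshold is `frac` (20%) of that reference.
#'
#' @param peak_heights Numeric vector of pooled dF/F0 peak apex heights
#'   (>= 3 values).
#' @param frac Threshold as a fraction of the reference (default 0.2).
#' @param cohort_id Label stored in the result.
#' @return An object of class `ca_threshold`: list with `reference_100pct`,
#'   `threshold`, `cohort_id`, `n_peaks_pooled`, `top_peaks`.
#' @examples
#' threshold_from_peaks(c(2.0, 1.5, 1.0, 0.5, 0.4))$threshold # 0.30
#' @export
threshold_from_peaks <- function(peak_heights, frac = 0.2,
                                 cohort_id = "wildtype") {
  peak_heights <- peak_heights[is.finite(peak_heights)]
  if (length(peak_heights) < 3) {
    abort(paste(
      "fewer than 3 pooled peaks; calibration impossible -",
      "supply an explicit numeric threshold instead"
    ))
  }
  top <- sort(peak_heights, decreasing = TRUE)[1:3]
  ref <- mean(top)
  structure(
    list(
      reference_100pct = ref,
      threshold = frac * ref,
      frac = frac,
      cohort_id = cohort_id,
      n_peaks_pooled = length(peak_heights),
      top_peaks = top
    ),
    class = "ca_threshold"
  )
}

#' @export
print.ca_threshold <- function(x, ...) {
  cat(sprintf(
    "<ca_threshold> cohort '%s': reference (100%%) = %.4g, threshold (%.0f%%) = %.4g (from %d pooled peaks)\n",
    x$cohort_id, x$reference_100pct, 100 * x$frac, x$threshold,
    x$n_peaks_pooled
  ))
  invisible(x)
}

#' Calibrate the cohort-level oscillation threshold
#'
#' Self-calibrating two-pass procedure on a wild-type cohort: provisional
#' peaks are detected with an absolute dF/F0 floor (`provisional_floor`) to
#' identify oscillating cells; their peak heights are pooled and the three
#' highest averaged into the 100% reference; the working threshold is `frac`
#' of the reference. Detection is then repeated with the updated threshold
#' and the reference recomputed until the pooled peak set is stable.
#'
#' @param dff_traces Wild-type dF/F0 traces (tibble with `cell_id`, `t_s`,
#'   `dff`).
#' @param provisional_floor Absolute dF/F0 floor of the first pass.
#' @param frac Threshold fraction of the reference (default 0.2).
#' @param min_separation_s Passed to [detect_peaks()].
#' @param cohort_id Label stored in the result.
#' @param max_iter Safety cap on refinement rounds.
#' @return A `ca_threshold` (see [threshold_from_peaks()]) with an
#'   `iterations` field.
#' @export
calibrate_threshold <- function(dff_traces,
                                provisional_floor = 0.2,
                                frac = 0.2,
                                min_separation_s = 10,
                                cohort_id = "wildtype",
                                max_iter = 20) {
  thr <- provisional_floor
  prev_sig <- NULL
  res <- NULL
  for (it in seq_len(max_iter)) {
    peaks <- detect_peaks(dff_traces, thr, min_separation_s)
    if (nrow(peaks) < 3) {
      abort(paste(
        "fewer than 3 pooled peaks in the cohort; calibration impossible -",
        "supply an explicit numeric threshold instead"
      ))
    }
    res <- threshold_from_peaks(peaks$apex_dff, frac, cohort_id)
    sig <- paste(peaks$cell_id, peaks$apex_frame, collapse = ";")
    if (identical(sig, prev_sig)) break
    prev_sig <- sig
    thr <- res$threshold
  }
  res$iterations <- it
  res
}

#' Per-cell oscillation metrics
#'
#' Frequency is the number of detected oscillations per minute of observed
#' recording; mean dF/F0 is the arithmetic mean of every (non-missing) dF/F0
#' sample of the cell. The observed duration defaults to each cell's own
#' time span (`max(t_s) - min(t_s)`).
#'
#' @param dff_traces Tibble with `cell_id`, `t_s`, `dff`.
#' @param peaks Tibble from [detect_peaks()].
#' @param observed_duration_s Optional fixed duration (seconds) overriding
#'   the per-cell span; must be > 0.
#' @return A tibble `cell_id`, `n_peaks`, `frequency_per_min`, `mean_dff`,
#'   `observed_duration_s`, `oscillating`.
#' @examples
#' # 12 peaks over 600 s is 1.2 per minute
#' @export
oscillation_metrics <- function(dff_traces, peaks,
                                observed_duration_s = NULL) {
  check_columns(dff_traces, c("cell_id", "t_s", "dff"), "dff_traces")
  if (!is.null(observed_duration_s)) {
    check_number(observed_duration_s, "observed_duration_s", 0, strict = TRUE)
  }
  counts <- dplyr::count(peaks, .data$cell_id, name = "n_peaks")
  out <- dplyr::summarise(
    dplyr::group_by(dff_traces, .data$cell_id),
    mean_dff = mean(.data$dff, na.rm = TRUE),
    observed_duration_s = if (is.null(observed_duration_s)) {
      max(.data$t_s) - min(.data$t_s)
    } else observed_duration_s,
    .groups = "drop"
  )
  if (any(out$observed_duration_s <= 0)) {
    abort("observed duration must be positive for every cell")
  }
  out <- dplyr::left_join(out, counts, by = "cell_id")
  out$n_peaks[is.na(out$n_peaks)] <- 0L
  dplyr::transmute(
    out,
    cell_id = .data$cell_id,
    n_peaks = as.integer(.data$n_peaks),
    frequency_per_min = .data$n_peaks / (.data$observed_duration_s / 60),
    mean_dff = .data$mean_dff,
    observed_duration_s = .data$observed_duration_s,
    oscillating = .data$n_peaks >= 1L
  )
}
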