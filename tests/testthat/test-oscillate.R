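make_trace <- function(f, dt = 5, id = "c1") {
  tibble::tibble(cell_id = id, frame = seq_along(f) - 1L,
                 t_s = (seq_along(f) - 1) * dt, F = f)
}

test_that("baseline is the quietest 50-s window mean", {
  # constant trace
  expect_equal(compute_baseline(make_trace(rep(100, 40)))$F0, 100)
  # too-short trace errors
  expect_error(compute_baseline(make_trace(rep(100, 8))), "window")

  # transient bumps occupying less than half the trace leave F0 at baseline
  set.seed(42)
  for (rep in 1:20) {
    f <- rep(100, 60)
    bump_at <- sample(15:45, 1)
    f[bump_at:(bump_at + 8)] <- 100 + runif(9, 20, 120)
    tr <- make_trace(f)
    expect_equal(compute_baseline(tr)$F0, 100)
    # matches the exhaustive sliding-window oracle exactly
    expect_equal(compute_baseline(tr)$F0, oracle_baseline(f, 10))
  }
})

test_that("dF/F0 normalisation is elementwise and scale invariant", {
  tr <- make_trace(c(rep(100, 12), 120, rep(100, 12)))
  d <- compute_dff(tr)
  expect_equal(d$dff[d$F == 120], 0.2)
  expect_true(all(d$dff[d$F == 100] == 0))
  # F = F0 everywhere -> dff identically 0
  expect_true(all(compute_dff(make_trace(rep(77, 30)))$dff == 0))
  # power-of-two scaling leaves dff bit-identical
  tr2 <- dplyr::mutate(tr, F = F * 4)
  expect_identical(compute_dff(tr2)$dff, d$dff)
  # arbitrary positive scaling agrees to floating-point accuracy
  tr3 <- dplyr::mutate(tr, F = F * 3.7)
  expect_equal(compute_dff(tr3)$dff, d$dff, tolerance = 1e-12)
  # non-positive baseline errors
  expect_error(
    compute_dff(tr, baselines = tibble::tibble(cell_id = "c1", F0 = 0)),
    "baseline"
  )
})

test_that("threshold calibration reproduces the worked arithmetic", {
  thr <- threshold_from_peaks(c(2.0, 1.5, 1.0, 0.5, 0.4))
  expect_identical(thr$reference_100pct, 1.5)
  expect_equal(thr$threshold, 0.3)
  # linearity: doubling peak heights doubles the threshold
  thr2 <- threshold_from_peaks(2 * c(2.0, 1.5, 1.0, 0.5, 0.4))
  expect_equal(thr2$threshold, 0.6)
  expect_error(threshold_from_peaks(c(1, 2)), "explicit")
})

test_that("cohort calibration finds a stable threshold and flat cohorts error", {
  acq <- acquisition_config(duration_s = 1000)
  traces <- purrr::map_dfr(1:10, function(i) {
    render_trace(
      generate_spike_train(1, 1000, rng_seed = i), 100, acq,
      noise_sd = 2, rng_seed = 100 + i, cell_id = sprintf("c%02d", i)
    )
  })
  dff <- compute_dff(traces)
  thr <- calibrate_threshold(dff)
  expect_s3_class(thr, "ca_threshold")
  expect_equal(thr$threshold, 0.2 * thr$reference_100pct)
  expect_equal(thr$reference_100pct, mean(thr$top_peaks))
  # re-detection at the calibrated threshold reproduces the pooled peak set
  peaks <- detect_peaks(dff, thr)
  expect_equal(thr$reference_100pct,
               mean(sort(peaks$apex_dff, decreasing = TRUE)[1:3]))

  flat <- compute_dff(make_trace(rep(100, 60)))
  expect_error(calibrate_threshold(flat), "explicit")
})

test_that("peak detection matches the exhaustive oracle on random traces", {
  set.seed(7)
  grid_vals <- seq(-0.1, 1, by = 0.05)
  for (case in 1:300) {
    n <- sample(10:50, 1)
    x <- sample(grid_vals, n, replace = TRUE)
    t <- (seq_len(n) - 1) * 5
    thr <- sample(c(0.2, 0.3, 0.5), 1)
    sep <- sample(c(10, 20), 1)
    got <- detect_peaks(
      tibble::tibble(cell_id = "c", frame = seq_len(n) - 1L, t_s = t, dff = x),
      thr, min_separation_s = sep
    )
    want <- oracle_peaks(x, t, thr, sep)
    expect_equal(got$apex_frame, want - 1L,
                 info = sprintf("case %d", case))
  }
})

test_that("peak examples: quiescent, single bump, two separated bumps", {
  t <- seq(0, 200, 5)
  quiet <- tibble::tibble(cell_id = "c", t_s = t, dff = 0)
  expect_equal(nrow(detect_peaks(quiet, 0.3)), 0)

  tri <- approx(c(0, 100, 110, 200), c(0, 0, 0.5, 0), xout = t)$y
  one <- detect_peaks(tibble::tibble(cell_id = "c", t_s = t, dff = tri), 0.3)
  expect_equal(nrow(one), 1)
  expect_equal(one$apex_time_s, 110)

  two <- approx(c(0, 100, 110, 120, 140, 150, 200),
                c(0, 0, 0.5, 0, 0.6, 0, 0), xout = t)$y
  got <- detect_peaks(tibble::tibble(cell_id = "c", t_s = t, dff = two),
                      0.3, min_separation_s = 10)
  expect_equal(nrow(got), 2)
  expect_equal(got$apex_time_s, c(110, 140))
})

test_that("time-to-peak recovers a constructed linear ramp", {
  # linear rise t = 100 s -> apex t = 110 s on a fine grid
  t <- seq(0, 200, 0.1)
  dff <- approx(c(0, 100, 110, 200), c(0, 0, 0.8, 0), xout = t)$y
  pk <- detect_peaks(tibble::tibble(cell_id = "c", t_s = t, dff = dff), 0.2)
  expect_equal(pk$time_to_peak_s, 10, tolerance = 0.11)
  # apex in the first sample -> onset (and time-to-peak) missing
  pk0 <- detect_peaks(
    tibble::tibble(cell_id = "c", t_s = 0:40 * 5,
                   dff = c(0.8, rep(0, 40))), 0.2
  )
  expect_true(is.na(pk0$time_to_peak_s[1]))
})

test_that("time-to-peak recovers the generator's mean rise time", {
  # fast 2D-style sampling (0.1 s) of isolated spikes with rises drawn
  # uniformly from the observed 5.6-18.7 s range
  acq <- acquisition_config(frame_interval_s = 0.1, duration_s = 150)
  set.seed(21)
  ttp <- c()
  true_rise <- c()
  for (i in 1:200) {
    rise <- runif(1, 5.6, 18.7)
    tr <- tibble::tibble(spike_time_s = 60, amplitude_dff = runif(1, 0.5, 1.5),
                         rise_time_s = rise, decay_time_s = 15)
    f <- render_trace(tr, 100, acq, noise_sd = 0.5, rng_seed = 1000 + i,
                      cell_id = sprintf("s%03d", i))
    d <- compute_dff(f)
    pk <- detect_peaks(d, 0.2)
    if (nrow(pk) == 1) {
      ttp <- c(ttp, pk$time_to_peak_s)
      true_rise <- c(true_rise, rise)
    }
  }
  expect_gte(length(ttp), 195)
  expect_lt(abs(mean(ttp) - mean(true_rise)), 1)
  expect_lt(abs(mean(ttp) - (5.6 + 18.7) / 2), 1)
})

test_that("oscillation metrics follow their defining arithmetic", {
  t <- seq(0, 600, 5)
  dff <- tibble::tibble(cell_id = "c", t_s = t,
                        dff = rep_len(c(0, 0.4), length(t)))
  peaks <- tibble::tibble(cell_id = rep("c", 12),
                          apex_time_s = seq(25, 575, 50))
  m <- oscillation_metrics(dff, peaks)
  expect_equal(m$frequency_per_min, 12 / 10)
  expect_equal(m$mean_dff, mean(rep_len(c(0, 0.4), length(t))))
  expect_true(m$oscillating)
  # no peaks: frequency 0, not oscillating
  m0 <- oscillation_metrics(dff, peaks[0, ])
  expect_equal(m0$frequency_per_min, 0)
  expect_false(m0$oscillating)
  expect_error(oscillation_metrics(dff, peaks, observed_duration_s = 0),
               "observed_duration_s")
})

test_that("the whole normalisation chain is scale invariant end-to-end", {
  acq <- acquisition_config(duration_s = 1000)
  traces <- purrr::map_dfr(1:8, function(i) {
    render_trace(generate_spike_train(1, 1000, rng_seed = i), 100, acq,
                 noise_sd = 2, rng_seed = 50 + i,
                 cell_id = sprintf("c%02d", i))
  })
  base <- compute_dff(traces)
  thr_b <- calibrate_threshold(base)
  pk_b <- detect_peaks(base, thr_b)
  m_b <- oscillation_metrics(base, pk_b)

  scaled <- dplyr::mutate(traces, F = F * 8) # power of two: exact
  d_s <- compute_dff(scaled)
  thr_s <- calibrate_threshold(d_s)
  pk_s <- detect_peaks(d_s, thr_s)
  m_s <- oscillation_metrics(d_s, pk_s)

  expect_identical(d_s$dff, base$dff)
  expect_identical(thr_s$threshold, thr_b$threshold)
  expect_identical(pk_s, pk_b)
  expect_identical(m_s, m_b)
})
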