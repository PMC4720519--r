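#' Simulate a ground-truth calcium spike train
#'
#' Draws oscillation onset times from a homogeneous Poisson process with a
#' hard refractory period: each inter-spike interval is the refractory time
#' plus an exponential waiting time. This is the simplest point process
#' producing sustained, non-periodic oscillations while guaranteeing that
#' consecutive spikes remain resolvable at volumetric sampling rates.
#'
#' Each spike carries its own ground-truth kinetics: a peak amplitude (in
#' delta-F/F0 units), a rise time drawn uniformly from `rise_range_s`
#' (matching rise times observed for endothelial calcium transients in vivo),
#' and an exponential decay constant.
#'
#' @param rate_per_min Underlying Poisson rate, events per minute (>= 0). The
#'   realised long-run rate is lower because of the refractory period; see
#'   [expected_spike_count()].
#' @param duration_s Length of the simulated recording, seconds.
#' @param refractory_s Hard dead time after each spike, seconds.
#' @param rng_seed Integer seed; the train is reproducible given the seed.
#' @param amplitude_meanlog,amplitude_sdlog Log-normal parameters of spike
#'   peak amplitudes (delta-F/F0 units).
#' @param rise_range_s Length-2 range the per-spike linear rise time is drawn
#'   from, seconds.
#' @param decay_s Exponential decay time constant applied to every spike,
#'   seconds.
#'
#' @return A tibble of class `ca_spike_train` with columns `spike_time_s`
#'   (onset of the rise), `amplitude_dff`, `rise_time_s`, `decay_time_s`,
#'   sorted by onset time.
#' @examples
#' train <- generate_spike_train(1.2, 600, rng_seed = 7)
#' nrow(train)
#' min(diff(train$spike_time_s)) >= 20
#' @export
generate_spike_train <- function(rate_per_min,
                                 duration_s,
                                 refractory_s = 20,
                                 rng_seed = 1L,
                                 amplitude_meanlog = 0,
                                 amplitude_sdlog = 0.25,
                                 rise_range_s = c(5.6, 18.7),
                                 decay_s = 15) {
  check_number(rate_per_min, "rate_per_min", 0)
  check_number(duration_s, "duration_s", 0, strict = TRUE)
  check_number(refractory_s, "refractory_s", 0)
  rate_per_s <- rate_per_min / 60

  times <- numeric(0)
  if (rate_per_s > 0) {
    times <- local_seed(rng_seed, {
      out <- numeric(0)
      t <- rexp(1, rate_per_s)
      while (t < duration_s) {
        out <- c(out, t)
        t <- t + refractory_s + rexp(1, rate_per_s)
      }
      out
    })
  }
  n <- length(times)
  kin <- local_seed(rng_seed + 1013L, list(
    amplitude_dff = rlnorm(n, amplitude_meanlog, amplitude_sdlog),
    rise_time_s = runif(n, rise_range_s[1], rise_range_s[2]),
    decay_time_s = rep(decay_s, n)
  ))
  out <- tibble::tibble(
    spike_time_s = times,
    amplitude_dff = kin$amplitude_dff,
    rise_time_s = kin$rise_time_s,
    decay_time_s = kin$decay_time_s
  )
  class(out) <- c("ca_spike_train", class(out))
  out
}

#' Refractory-corrected expected spike count
#'
#' For a Poisson process of rate `rate_per_min` thinned by a hard refractory
#' period, the mean inter-spike interval is `refractory_s + 1/rate`, so the
#' long-run realised rate is `rate / (1 + rate * refractory_s)`.
#'
#' @inheritParams generate_spike_train
#' @return Expected number of spikes in `duration_s` seconds.
#' @examples
#' expected_spike_count(1.2, 600, 20) # < 12 because of the dead time
#' @export
expected_spike_count <- function(rate_per_min, duration_s, refractory_s = 20) {
  rate_per_s <- rate_per_min / 60
  duration_s * rate_per_s / (1 + rate_per_s * refractory_s)
}

#' Continuous-time fluorescence kinetic model
#'
#' Evaluates the noise-free fluorescence F(t) implied by a spike train: each
#' spike contributes a linear rise from its onset to
#' `baseline_F0 * amplitude_dff` over `rise_time_s`, followed by exponential
#' decay with `decay_time_s`. Spike contributions add on top of the baseline
#' (calcium transients in these cells engage the whole cytoplasm, so a single
#' whole-cell kinetic term per spike suffices).
#'
#' @param t_s Times at which to evaluate, seconds.
#' @param train A `ca_spike_train` tibble.
#' @param baseline_F0 Baseline fluorescence, arbitrary units (> 0).
#' @return Numeric vector of fluorescence values at `t_s`.
#' @export
spike_kinetics <- function(t_s, train, baseline_F0) {
  check_number(baseline_F0, "baseline_F0", 0, strict = TRUE)
  f <- rep(baseline_F0, length(t_s))
  if (nrow(train) == 0) return(f)
  for (i in seq_len(nrow(train))) {
    t0 <- train$spike_time_s[i]
    rise <- train$rise_time_s[i]
    dec <- train$decay_time_s[i]
    amp <- train$amplitude_dff[i] * baseline_F0
    dt <- t_s - t0
    up <- dt >= 0 & dt < rise
    down <- dt >= rise
    f[up] <- f[up] + amp * dt[up] / rise
    f[down] <- f[down] + amp * exp(-(dt[down] - rise) / dec)
  }
  f
}

#' Render a sampled fluorescence trace from a spike train
#'
#' Samples the continuous kinetic model of [spike_kinetics()] at the frame
#' times of an acquisition and adds independent Gaussian measurement noise.
#'
#' @param train A `ca_spike_train` tibble (possibly empty).
#' @param baseline_F0 Baseline fluorescence, arbitrary units (> 0).
#' @param acquisition An [acquisition_config()].
#' @param noise_sd Standard deviation of additive Gaussian noise, same units
#'   as `baseline_F0` (>= 0).
#' @param rng_seed Integer seed for the noise draw.
#' @param cell_id Identifier stored in the output.
#'
#' @return A tibble with columns `cell_id`, `frame` (0-based), `t_s`, `F`.
#' @examples
#' acq <- acquisition_config(duration_s = 100)
#' quiet <- render_trace(generate_spike_train(0, 100), 100, acq, noise_sd = 0)
#' all(quiet$F == 100)
#' @export
render_trace <- function(train,
                         baseline_F0,
                         acquisition,
                         noise_sd = 3,
                         rng_seed = 1L,
                         cell_id = "cell_1") {
  check_number(baseline_F0, "baseline_F0", 0, strict = TRUE)
  check_number(noise_sd, "noise_sd", 0)
  stopifnot(inherits(acquisition, "ca_acquisition"))
  t_s <- frame_times(acquisition)
  f <- spike_kinetics(t_s, train, baseline_F0)
  if (noise_sd > 0) {
    f <- f + local_seed(rng_seed, rnorm(length(f), 0, noise_sd))
  }
  tibble::tibble(
    cell_id = cell_id,
    frame = seq_along(t_s) - 1L,
    t_s = t_s,
    F = f
  )
}

# Evaluate an expression with a temporary RNG state.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
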