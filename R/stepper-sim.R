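# Software stand-in for the mechanical continuous stepper: a cam with two
# fins lifts and drops two pistons, producing (a) an optical-switch voltage
# trace that is the ground-truth channel and (b) foot-like ~1.1 g impact
# impulses that drive the pedometer under test.

#' Noise specification for the simulated stepper
#'
#' @param spike_rate expected single-sample voltage spikes per minute on the
#'   optical trace (Poisson-placed). Emulates optical/DAQ sensor noise.
#' @param spike_amplitude_v amplitude of injected spikes, volts.
#' @param timing_jitter_sd standard deviation of Gaussian timing jitter on
#'   impulse arrival times, seconds. Emulates step-to-step variability.
#' @param amplitude_jitter_sd standard deviation of Gaussian jitter on
#'   impulse peak acceleration, g.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(spike_rate = 0, spike_amplitude_v = 3,
                       timing_jitter_sd = 0, amplitude_jitter_sd = 0) {
  vals <- c(spike_rate, spike_amplitude_v, timing_jitter_sd, amplitude_jitter_sd)
  if (any(vals < 0)) stop("noise_spec fields must be non-negative")
  structure(list(spike_rate = spike_rate,
                 spike_amplitude_v = spike_amplitude_v,
                 timing_jitter_sd = timing_jitter_sd,
                 amplitude_jitter_sd = amplitude_jitter_sd),
            class = "noise_spec")
}

#' Default noise level emulating bench conditions
#'
#' A mild, fixed noise model used by [run_experiment()]: two optical spikes
#' per minute, 20 ms timing jitter and 0.05 g amplitude jitter on impacts.
#' @return `noise_spec`
#' @export
bench_noise <- function() {
  noise_spec(spike_rate = 2, spike_amplitude_v = 3,
             timing_jitter_sd = 0.02, amplitude_jitter_sd = 0.05)
}

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched. seed = NULL uses the current stream.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Step event times for a regular train: first step at 60/cadence s (no event
# at t = 0), so a noise-free count is exactly floor(duration * cadence / 60).
step_times <- function(cadence, duration) {
  interval <- 60 / cadence
  n <- floor(duration * cadence / 60 + 1e-9)
  interval * seq_len(n)
}

check_cadence <- function(cadence) {
  if (cadence < cadence_bounds()[1] || cadence > cadence_bounds()[2])
    stop("cadence must be in [30, 110] steps/min")
}

#' Simulate the optical-switch ground-truth voltage trace
#'
#' The optical switch sees the two cam fins pass once per step, producing
#' rectangular voltage peaks that alternate between a left-fin and a
#' right-fin amplitude. Sampling is 100 Hz by default. Optional Poisson
#' noise injects single-sample voltage spikes, the failure mode the
#' downstream moving-mean filter and alternation check are built to remove.
#'
#' Default amplitudes (left 1.5 V, right 2.5 V on a 0 V baseline) are chosen
#' self-consistently with the quantization cuts of [quantize_trace()]; they
#' are configurable because real fin-signal amplitude depends on the optical
#' hardware. Peak width defaults to 9 samples (0.09 s), comparable to the
#' dwell time of a fin in front of the switch and wide enough to survive the
#' growing moving-mean windows of the convergence loop.
#'
#' @param cadence steps per minute, in 30-110.
#' @param duration trial length in seconds (> 0).
#' @param noise a [noise_spec()]; only the optical spike fields are used.
#' @param left_peak_v,right_peak_v peak amplitudes, volts.
#' @param sample_rate samples per second.
#' @param peak_width peak width in samples; must be shorter than the
#'   inter-step interval or adjacent peaks would merge.
#' @param seed integer seed for the spike process; same seed, same trace.
#' @return object of class `optical_trace`: fields `sample_rate`,
#'   `voltages`, and `true_steps` (a `data.frame` of `time_s`, `side` with
#'   side in `"left"`/`"right"`).
#' @export
generate_optical_trace <- function(cadence, duration, noise = noise_spec(),
                                   left_peak_v = 1.5, right_peak_v = 2.5,
                                   sample_rate = 100, peak_width = 9,
                                   seed = NULL) {
  check_cadence(cadence)
  if (duration <= 0) stop("duration must be > 0")
  interval_samples <- 60 / cadence * sample_rate
  if (peak_width >= interval_samples)
    stop("peak_width (", peak_width, " samples) must be below the inter-step ",
         "interval (", round(interval_samples, 1), " samples) or peaks merge")
  n_samples <- round(duration * sample_rate)
  voltages <- numeric(n_samples)
  times <- step_times(cadence, duration)
  sides <- rep_len(c("left", "right"), length(times))
  amps <- ifelse(sides == "left", left_peak_v, right_peak_v)
  # each pulse ends at the step time (the fin clears the switch as the
  # piston drops), so the final passage is always fully recorded even when
  # the last step falls exactly at the end of the trace
  for (i in seq_along(times)) {
    end <- round(times[i] * sample_rate)
    idx <- (end - peak_width + 1):end
    idx <- idx[idx >= 1 & idx <= n_samples]
    voltages[idx] <- amps[i]
  }
  if (noise$spike_rate > 0) {
    voltages <- with_local_seed(seed, {
      n_spikes <- stats::rpois(1, noise$spike_rate * duration / 60)
      if (n_spikes > 0) {
        pos <- sample.int(n_samples, min(n_spikes, n_samples))
        voltages[pos] <- pmax(voltages[pos], noise$spike_amplitude_v)
      }
      voltages
    })
  }
  structure(list(sample_rate = sample_rate,
                 voltages = voltages,
                 true_steps = data.frame(time_s = times, side = sides)),
            class = "optical_trace")
}

#' Simulate the foot-impact impulse train seen by the pedometer
#'
#' Each piston drop produces an acceleration impulse of about 1.1 g, the
#' magnitude of foot impact during walking. Events are regular at
#' 60/cadence s with optional Gaussian timing and amplitude jitter; jitter
#' never changes the event count, so the noise-free count identity
#' `floor(duration * cadence / 60)` is preserved.
#'
#' @inheritParams generate_optical_trace
#' @param peak_g nominal impulse peak, in g.
#' @param noise a [noise_spec()]; only the jitter fields are used.
#' @return object of class `impulse_train`: fields `events` (a `data.frame`
#'   of `time_s`, `peak_g`, time-sorted) and `duration`.
#' @export
generate_impulse_train <- function(cadence, duration, peak_g = 1.1,
                                   noise = noise_spec(), seed = NULL) {
  check_cadence(cadence)
  if (duration <= 0) stop("duration must be > 0")
  times <- step_times(cadence, duration)
  n <- length(times)
  ev <- with_local_seed(seed, {
    if (noise$timing_jitter_sd > 0)
      times <- times + stats::rnorm(n, 0, noise$timing_jitter_sd)
    peaks <- rep(peak_g, n)
    if (noise$amplitude_jitter_sd > 0)
      peaks <- peaks + stats::rnorm(n, 0, noise$amplitude_jitter_sd)
    data.frame(time_s = times, peak_g = peaks)
  })
  if (any(ev$peak_g < 0)) {
    message(sum(ev$peak_g < 0), " jittered impulse peak(s) fell below 0 g; clipped to 0")
    ev$peak_g <- pmax(ev$peak_g, 0)
  }
  ev <- ev[order(ev$time_s), , drop = FALSE]
  rownames(ev) <- NULL
  structure(list(events = ev, duration = duration), class = "impulse_train")
}

#' Write an optical trace as a two-column CSV (time_s, volts)
#' @param trace an `optical_trace`
#' @param path output file
#' @export
write_trace_csv <- function(trace, path) {
  n <- length(trace$voltages)
  utils::write.csv(data.frame(time_s = sprintf("%.6f", (seq_len(n) - 1) / trace$sample_rate),
                              volts = sprintf("%.6f", trace$voltages)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an impulse train as an event CSV (time_s, peak_g)
#' @param train an `impulse_train`
#' @param path output file
#' @export
write_train_csv <- function(train, path) {
  utils::write.csv(data.frame(time_s = sprintf("%.6f", train$events$time_s),
                              peak_g = sprintf("%.6f", train$events$peak_g)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
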