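# Deterministic replica of the embedded pedometer's step-counting logic.
#
# The device accepts an impulse as a candidate step when its acceleration
# peak reaches the threshold. Candidate impulses are then debounced: a bout
# of consecutive impulses, each arriving within the debounce time of the
# previous one, must reach the debounce step count before it is considered
# continuous walking. Once promoted, every impulse in the bout is credited
# (retroactively for the accumulated debounce impulses) and counting
# continues while gaps stay within the debounce time; a longer gap closes
# the bout and the machine returns to debouncing. While still debouncing, a
# long gap discards the accumulated impulses.
#
# Gap comparison is inclusive: a gap exactly equal to the debounce time
# passes. This makes a debounce time of 2000 ms sufficient (at exact
# equality) for a regular 30 steps/min train, whose inter-step gap is 2 s.

# absolute slack on gap comparisons, seconds; absorbs floating-point error
# in event times like k * 60/110
.gap_eps <- 1e-9

#' Apply the acceleration threshold to an impulse train
#'
#' @param train an [generate_impulse_train()] object.
#' @param threshold_mg minimum peak acceleration, milli-g; impulses with
#'   `peak_g * 1000 >= threshold_mg` are retained.
#' @return numeric vector of candidate impulse times, seconds, sorted.
#' @export
detect_impulses <- function(train, threshold_mg) {
  keep <- train$events$peak_g * 1000 >= threshold_mg - 1e-9
  train$events$time_s[keep]
}

#' Run the debounce state machine over candidate impulse times
#'
#' @param impulse_times sorted numeric vector of candidate impulse times, s.
#' @param settings one-row settings `data.frame` (see [sensor_settings()]);
#'   only `debounce_steps` and `debounce_time_ms` are used here.
#' @param retroactive if `TRUE` (default, matching the behaviour implied by
#'   the device documentation where a fully connected 12-impulse bout yields
#'   12 steps), the accumulated debounce impulses are credited when a bout
#'   is promoted. If `FALSE`, only impulses after promotion count
#'   (`length - debounce_steps` per promoted bout).
#' @return object of class `pedometer_result`: `steps`,
#'   `discarded_impulses` (candidates dropped in debouncing), and `bouts`
#'   (a `data.frame` of `start_s`, `end_s`, `steps` for promoted bouts).
#' @export
count_steps <- function(impulse_times, settings, retroactive = TRUE) {
  if (is.unsorted(impulse_times)) stop("impulse times must be sorted")
  dt_s <- settings$debounce_time_ms / 1000
  dsteps <- settings$debounce_steps
  n <- length(impulse_times)
  if (n == 0L)
    return(structure(list(steps = 0L, discarded_impulses = 0L,
                          bouts = data.frame(start_s = numeric(0),
                                             end_s = numeric(0),
                                             steps = integer(0))),
                     class = "pedometer_result"))
  # Within a maximal run of impulses whose successive gaps are all within
  # the debounce window, the machine is simple: the run is promoted iff it
  # reaches debounce_steps, and then every impulse in it is credited
  # (retroactive mode). Runs are independent, so split at long gaps.
  # A "grouping of impulses" needs at least two chained impulses to be
  # continuous steps: even with debounce_steps = 1, an isolated impulse
  # whose window expires with no successor is discarded, so a regular
  # train with gaps beyond the debounce time always counts 0.
  run_id <- cumsum(c(TRUE, diff(impulse_times) > dt_s + .gap_eps))
  run_len <- tabulate(run_id)
  promoted <- run_len >= dsteps & run_len >= 2L
  per_run <- if (retroactive) run_len else pmax(run_len - dsteps, 0L)
  steps_per_run <- ifelse(promoted, per_run, 0L)
  run_start <- impulse_times[!duplicated(run_id)]
  run_end <- impulse_times[!duplicated(run_id, fromLast = TRUE)]
  bouts <- data.frame(start_s = run_start[promoted],
                      end_s = run_end[promoted],
                      steps = as.integer(steps_per_run[promoted]))
  structure(list(steps = as.integer(sum(steps_per_run)),
                 discarded_impulses = as.integer(sum(run_len[!promoted])),
                 bouts = bouts),
            class = "pedometer_result")
}

#' Simulate the pedometer end to end on an impulse train
#'
#' Composition of [detect_impulses()] and [count_steps()].
#'
#' @inheritParams count_steps
#' @param train an `impulse_train`.
#' @param settings one-row settings `data.frame` with `threshold_mg`,
#'   `debounce_steps`, `debounce_time_ms`.
#' @return a `pedometer_result`.
#' @export
simulate_sensor <- function(train, settings, retroactive = TRUE) {
  count_steps(detect_impulses(train, settings$threshold_mg), settings,
              retroactive = retroactive)
}

#' Lowest cadence detectable at a given debounce time
#'
#' A regular train at cadence c has inter-step gaps of 60000/c ms; under the
#' inclusive gap convention it is counted as continuous steps iff that gap
#' does not exceed the debounce time, so the minimum detectable integer
#' cadence is `ceiling(60000 / debounce_time_ms)`. A 1000 ms debounce
#' therefore misses everything below 60 steps/min, and capturing
#' 30 steps/min requires at least 2000 ms.
#'
#' @param debounce_time_ms debounce window, ms (> 0).
#' @return integer cadence in steps/min.
#' @export
min_detectable_cadence <- function(debounce_time_ms) {
  if (any(debounce_time_ms <= 0)) stop("debounce_time_ms must be > 0")
  as.integer(ceiling(60000 / debounce_time_ms - .gap_eps))
}

#' @export
print.pedometer_result <- function(x, ...) {
  cat("Pedometer result:", x$steps, "steps,",
      x$discarded_impulses, "impulses discarded,",
      nrow(x$bouts), "bout(s)\n")
  invisible(x)
}
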