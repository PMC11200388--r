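# Setting space of the embedded pedometer: step-detection threshold,
# debounce steps, and debounce time, plus the cadence axis the device is
# evaluated over.

#' Pedometer setting grids
#'
#' The embedded pedometer exposes three settings: a step-detection
#' threshold (minimum acceleration peak, in milli-g), a debounce step count
#' (consecutive qualifying impulses required before a bout is accepted as
#' walking), and a debounce time (maximum allowed gap between consecutive
#' impulses, in ms). The register documentation gives 35 threshold options
#' spanning 32-996 mg, 7 debounce-step options (1-7), and 31 debounce-time
#' options (80-2480 ms in 80 ms increments). The exact spacing of the 35
#' threshold register values is not published; `threshold_grid()` uses 35
#' uniformly spaced values so a hardware-faithful grid can be swapped in via
#' the `grid` arguments of downstream functions.
#'
#' @return Numeric vector of grid values.
#' @export
threshold_grid <- function() seq(32, 996, length.out = 35)

#' @rdname threshold_grid
#' @export
debounce_steps_grid <- function() 1:7

#' @rdname threshold_grid
#' @export
debounce_time_grid <- function() seq(80, 2480, by = 80)

#' Cadence axis bounds (steps/min) over which the device is characterised
#' @return Numeric length-2 vector `c(low, high)`.
#' @export
cadence_bounds <- function() c(30, 110)

#' Construct a single sensor-setting combination
#'
#' Validates membership in the three setting grids and returns a one-row
#' `data.frame` with columns `threshold_mg`, `debounce_steps`,
#' `debounce_time_ms` -- the row format used throughout the package.
#'
#' @param threshold_mg step-detection threshold in milli-g; must lie on
#'   [threshold_grid()] (to within floating-point tolerance).
#' @param debounce_steps integer in 1..7.
#' @param debounce_time_ms debounce window in ms, a multiple of 80 in
#'   80..2480.
#' @return one-row `data.frame`.
#' @examples
#' sensor_settings(480, 6, 2240)
#' @export
sensor_settings <- function(threshold_mg, debounce_steps, debounce_time_ms) {
  if (!any(abs(threshold_grid() - threshold_mg) < 1e-6))
    stop("threshold_mg ", threshold_mg, " is not on the 35-value grid 32-996 mg")
  if (!debounce_steps %in% debounce_steps_grid())
    stop("debounce_steps must be an integer in 1..7")
  if (!debounce_time_ms %in% debounce_time_grid())
    stop("debounce_time_ms must be a multiple of 80 in 80..2480 ms")
  data.frame(threshold_mg = threshold_mg,
             debounce_steps = as.integer(debounce_steps),
             debounce_time_ms = debounce_time_ms)
}

#' Enumerate the full setting space
#'
#' Cartesian product of the three setting grids: 35 x 7 x 31 = 7595
#' combinations, in deterministic lexicographic order (threshold varies
#' slowest, then debounce steps, then debounce time).
#'
#' @param threshold,steps,time optional replacement grids.
#' @return `data.frame` with columns `threshold_mg`, `debounce_steps`,
#'   `debounce_time_ms`; 7595 rows for the default grids.
#' @export
enumerate_settings <- function(threshold = threshold_grid(),
                               steps = debounce_steps_grid(),
                               time = debounce_time_grid()) {
  grid <- expand.grid(debounce_time_ms = time,
                      debounce_steps = as.integer(steps),
                      threshold_mg = threshold,
                      KEEP.OUT.ATTRS = FALSE)
  grid[, c("threshold_mg", "debounce_steps", "debounce_time_ms")]
}

#' Subsample the setting space on a regular stride
#'
#' Keeps grid indices 1, 1+s, 1+2s, ... along each axis (anchored at the
#' grid minima). The experiment design samples debounce steps, debounce
#' time, and threshold every 2, 4, and 5 grid points respectively, giving
#' 4 x 8 x 7 = 224 combinations.
#'
#' @param steps_stride,time_stride,threshold_stride positive integer
#'   strides along each axis.
#' @return `data.frame` as in [enumerate_settings()].
#' @export
subsample_settings <- function(steps_stride = 2, time_stride = 4,
                               threshold_stride = 5) {
  strides <- c(steps_stride, time_stride, threshold_stride)
  if (any(strides < 1) || any(strides != round(strides)))
    stop("strides must be positive integers")
  take <- function(grid, stride, name) {
    if (stride > length(grid))
      warning("stride ", stride, " exceeds ", name, " axis length ",
              length(grid), "; only the first value is retained")
    grid[seq(1, length(grid), by = stride)]
  }
  enumerate_settings(threshold = take(threshold_grid(), threshold_stride, "threshold"),
                     steps = take(debounce_steps_grid(), steps_stride, "debounce steps"),
                     time = take(debounce_time_grid(), time_stride, "debounce time"))
}

# Fixed normalization bounds: grid extremes, not observed-data extremes, so
# that predictions over the full setting space stay in [0,1].
normalization_bounds <- function() {
  list(threshold = range(threshold_grid()),
       debounce_steps = range(debounce_steps_grid()),
       debounce_time = range(debounce_time_grid()),
       cadence = cadence_bounds())
}

#' Min-max normalize settings and cadence to the unit hypercube
#'
#' Each predictor is scaled to 0-1 using the fixed grid extremes
#' (threshold 32-996 mg, debounce steps 1-7, debounce time 80-2480 ms,
#' cadence 30-110 steps/min). Component order of the returned matrix is
#' `(threshold, debounce_steps, debounce_time, cadence)` and is the order
#' used throughout the error model.
#'
#' @param settings `data.frame` of setting rows (recycled against
#'   `cadence` if either has length/nrow 1).
#' @param cadence numeric vector of cadences in steps/min; values outside
#'   30-110 are an error (the model never extrapolates).
#' @return numeric matrix with columns
#'   `threshold`, `debounce_steps`, `debounce_time`, `cadence`.
#' @export
normalize_predictors <- function(settings, cadence) {
  b <- normalization_bounds()
  if (any(cadence < b$cadence[1] - 1e-9) || any(cadence > b$cadence[2] + 1e-9))
    stop("cadence outside the supported range 30-110 steps/min")
  n <- max(nrow(settings), length(cadence))
  if (nrow(settings) == 1L && n > 1L)
    settings <- settings[rep(1L, n), , drop = FALSE]
  if (length(cadence) == 1L && n > 1L)
    cadence <- rep(cadence, n)
  scale01 <- function(x, r) (x - r[1]) / (r[2] - r[1])
  cbind(threshold = scale01(settings$threshold_mg, b$threshold),
        debounce_steps = scale01(settings$debounce_steps, b$debounce_steps),
        debounce_time = scale01(settings$debounce_time_ms, b$debounce_time),
        cadence = scale01(cadence, b$cadence))
}

#' Invert [normalize_predictors()]
#'
#' @param X numeric matrix with the four normalized columns in the fixed
#'   order `(threshold, debounce_steps, debounce_time, cadence)`.
#' @return `data.frame` with raw-unit columns `threshold_mg`,
#'   `debounce_steps`, `debounce_time_ms`, `cadence_spm`.
#' @export
denormalize_predictors <- function(X) {
  b <- normalization_bounds()
  unscale <- function(u, r) r[1] + u * (r[2] - r[1])
  data.frame(threshold_mg = unscale(X[, 1], b$threshold),
             debounce_steps = unscale(X[, 2], b$debounce_steps),
             debounce_time_ms = unscale(X[, 3], b$debounce_time),
             cadence_spm = unscale(X[, 4], b$cadence))
}
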