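# Setting recommendation: evaluate every setting combination over a
# cadence range with the fitted error model, keep those within +/-10%
# error at every integer cadence, and rank by the weighted composite
# score w * AE + (1 - w) * STD.

#' Construct a cadence range
#'
#' @param low,high bounds in steps/min, with `30 <= low < high <= 110`;
#'   evaluation runs over every integer cadence in `[low, high]`.
#' @param label free-text description.
#' @return object of class `cadence_range`.
#' @export
cadence_range <- function(low, high, label = "") {
  if (!(30 <= low && low < high && high <= 110))
    stop("need 30 <= low < high <= 110 steps/min")
  structure(list(low = low, high = high, label = label),
            class = "cadence_range")
}

#' The three cadence ranges of interest
#'
#' Walking-speed bands for disabled low-mobility ambulators
#' (30-60 steps/min), disabled high-mobility ambulators (30-90 steps/min),
#' and healthy individuals (30-110 steps/min).
#'
#' @return list of three [cadence_range()] objects.
#' @export
preset_ranges <- function() {
  list(cadence_range(30, 60, "disabled low-mobility"),
       cadence_range(30, 90, "disabled high-mobility"),
       cadence_range(30, 110, "healthy"))
}

# Predicted-error matrix: one row per setting, one column per integer
# cadence in the range. Chunked by cadence to keep the design matrices
# small.
prediction_matrix <- function(model, settings, range) {
  cadences <- seq(range$low, range$high)
  E <- matrix(NA_real_, nrow(settings), length(cadences))
  for (j in seq_along(cadences))
    E[, j] <- predict(model, settings, cadences[j])
  E
}

summarize_errors <- function(E, w, tolerance, signed_ae) {
  ae <- if (signed_ae) rowMeans(E) else rowMeans(abs(E))
  mu <- rowMeans(E)
  std <- sqrt(pmax(rowSums((E - mu)^2), 0) / (ncol(E) - 1))
  data.frame(ae = ae, std = std,
             composite = w * ae + (1 - w) * std,
             max_abs_error = apply(abs(E), 1, max),
             within_tolerance = rowSums(abs(E) > tolerance + 1e-12) == 0)
}

#' Evaluate one setting combination over a cadence range
#'
#' Predicts the signed error at every integer cadence in the range, then
#' reports AE (mean absolute predicted error), STD (sample standard
#' deviation of the signed errors), the composite score
#' `w * AE + (1 - w) * STD`, and whether every error magnitude stays
#' within the tolerance.
#'
#' By default AE is the mean of |error|: the goal is minimizing the
#' magnitude of error, and a signed mean would reward settings whose large
#' positive and negative errors cancel. Set `signed_ae = TRUE` for the
#' literal signed mean.
#'
#' @param model a fitted `error_model`.
#' @param settings one-row settings `data.frame`.
#' @param range a [cadence_range()].
#' @param w composite weight on AE, in `[0, 1]`.
#' @param tolerance pointwise error tolerance (default 0.10, i.e. +/-10%).
#' @param signed_ae use the signed mean error as AE.
#' @return one-row `data.frame`: settings columns plus `ae`, `std`,
#'   `composite`, `max_abs_error`, `within_tolerance`.
#' @export
evaluate_setting <- function(model, settings, range, w = 0.5,
                             tolerance = 0.10, signed_ae = FALSE) {
  if (w < 0 || w > 1) stop("w must be in [0, 1]")
  E <- prediction_matrix(model, settings[1, , drop = FALSE], range)
  cbind(settings[1, , drop = FALSE],
        summarize_errors(E, w, tolerance, signed_ae),
        row.names = NULL)
}

#' Recommend setting combinations for a cadence range
#'
#' Evaluates every combination of the setting space (7595 by default)
#' over the integer cadences of `range`, filters to combinations whose
#' predicted error magnitude stays within `tolerance` at every cadence,
#' and ranks the survivors by ascending composite score (ties broken by
#' STD, then AE, then threshold, debounce time, debounce steps).
#'
#' If no combination passes the tolerance, an empty table is returned with
#' a warning and the best out-of-tolerance candidates attached as
#' `attr(, "best_out_of_tolerance")`.
#'
#' @inheritParams evaluate_setting
#' @param settings candidate settings (default [enumerate_settings()]).
#' @param top_n number of recommendations to return.
#' @return `data.frame` of up to `top_n` rows, best first, with the
#'   columns of [evaluate_setting()] plus `rank`.
#' @export
recommend_settings <- function(model, range, w = 0.5, tolerance = 0.10,
                               top_n = 10, settings = enumerate_settings(),
                               signed_ae = FALSE) {
  if (w < 0 || w > 1) stop("w must be in [0, 1]")
  E <- prediction_matrix(model, settings, range)
  ev <- cbind(settings, summarize_errors(E, w, tolerance, signed_ae),
              row.names = NULL)
  ord <- order(ev$composite, ev$std, ev$ae, ev$threshold_mg,
               ev$debounce_time_ms, ev$debounce_steps)
  ev <- ev[ord, , drop = FALSE]
  ok <- ev[ev$within_tolerance, , drop = FALSE]
  if (nrow(ok) == 0L) {
    best <- utils::head(ev, top_n)
    warning("no setting stays within +/-", 100 * tolerance,
            "% over ", range$low, "-", range$high, " steps/min; best ",
            "out-of-tolerance composite = ", signif(best$composite[1], 4))
    out <- ok
    attr(out, "best_out_of_tolerance") <- best
    return(out)
  }
  out <- utils::head(ok, top_n)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' @export
print.cadence_range <- function(x, ...) {
  cat(sprintf("Cadence range %d-%d steps/min%s\n", x$low, x$high,
              if (nzchar(x$label)) paste0(" (", x$label, ")") else ""))
  invisible(x)
}
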