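#' Simulate a list-mode-style event stream
#'
#' Draws homogeneous Poisson coincidence-event times over the span of a
#' respiratory trace and tags each event with the axial displacement of the
#' emitting object at that instant (linear interpolation of the trace). The
#' event rate is time-homogeneous: phantom activity is effectively constant
#' over one bed position, and decay correction is out of scope.
#'
#' @param trace A [respiratory_trace()].
#' @param rate Expected event rate in counts per second (> 0).
#' @param seed Optional integer seed.
#' @return An object of class `event_stream`: list with sorted `times` (s),
#'   `displacements` (mm), `total_counts` and `span`.
#' @examples
#' tr <- simulate_trace(waveform_params(duration = 30, seed = 3))
#' ev <- simulate_events(tr, rate = 200, seed = 3)
#' ev$total_counts
#' @export
simulate_events <- function(trace, rate, seed = NULL) {
  stopifnot(inherits(trace, "respiratory_trace"))
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) || rate <= 0) {
    stop("`rate` must be a positive finite scalar")
  }
  if (!is.null(seed)) set.seed(seed)
  span <- trace_span(trace)
  n <- stats::rpois(1, rate * diff(span))
  times <- sort(stats::runif(n, span[1], span[2]))
  disp <- if (n > 0) {
    stats::approx(trace$times, trace$amplitudes, xout = times)$y
  } else {
    numeric(0)
  }
  structure(
    list(times = times, displacements = disp, total_counts = n, span = span),
    class = "event_stream"
  )
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf("<event_stream> %d events over [%.2f, %.2f] s\n",
              x$total_counts, x$span[1], x$span[2]))
  invisible(x)
}

#' Count events in a half-open time window
#'
#' @param stream An [simulate_events()] result.
#' @param t0,t1 Window bounds in seconds; events with `t0 <= t < t1` count.
#' @return Integer event count.
#' @export
counts_in_window <- function(stream, t0, t1) {
  stopifnot(inherits(stream, "event_stream"))
  if (!is.finite(t0) || !is.finite(t1) || t0 >= t1) {
    stop("`t0` must be strictly less than `t1`")
  }
  sum(stream$times >= t0 & stream$times < t1)
}
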