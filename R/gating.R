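# events retained by a set of non-overlapping, time-ordered windows
retained_by_windows <- function(event_times, windows) {
  if (is.null(windows) || nrow(windows) == 0) {
    return(rep(FALSE, length(event_times)))
  }
  edges <- as.numeric(rbind(windows$t0, windows$t1))
  if (is.unsorted(edges)) stop("gate windows must be ordered and disjoint")
  findInterval(event_times, edges) %% 2L == 1L
}

new_gate_mask <- function(method, windows, retained, params = list()) {
  structure(
    list(method = method, windows = windows, retained = retained,
         retained_fraction = if (length(retained)) mean(retained) else NA_real_,
         params = params),
    class = "gate_mask"
  )
}

#' @export
print.gate_mask <- function(x, ...) {
  cat(sprintf("<gate_mask> %s: %d windows, retained fraction %.3f\n",
              x$method, nrow(x$windows), x$retained_fraction))
  invisible(x)
}

#' Method 1: fixed-offset quiescent-period gating
#'
#' Applies the same phase rule to every breath: with scan-mean cycle
#' duration Tbar, the retained window in a cycle starting at time s is
#' `[s + offset_fraction * Tbar, s + (offset_fraction + duty_fraction) *
#' Tbar)`, clipped to the cycle. Because cycles are anchored at breath
#' peaks, the default offset of 0.3 with duty 0.5 brackets the mid-cycle
#' end-expiration trough. The fixed offset is the method's defining
#' limitation: when breathing is irregular the window placement does not
#' adapt to the individual breath.
#'
#' @param cycles A [segment_cycles()] `cycle_set`.
#' @param events An [simulate_events()] `event_stream`.
#' @param offset_fraction Window start as a fraction of the mean period,
#'   in `[0, 1)`; default 0.3.
#' @param duty_fraction Target fraction of data retained, in `(0, 1]`;
#'   default 0.5 (quiescent-period gating discards half the counts).
#' @return A `gate_mask` with the per-cycle windows, a per-event logical
#'   `retained` vector and the achieved `retained_fraction`.
#' @export
gate_method1_qpg <- function(cycles, events, offset_fraction = 0.3,
                             duty_fraction = 0.5) {
  stopifnot(inherits(cycles, "cycle_set"), inherits(events, "event_stream"))
  if (cycles$n_cycles < 1) stop("no cycles to gate")
  if (offset_fraction < 0 || offset_fraction >= 1) {
    stop("`offset_fraction` must be in [0, 1)")
  }
  if (duty_fraction <= 0 || duty_fraction > 1) {
    stop("`duty_fraction` must be in (0, 1]")
  }
  tbar <- mean(cycles$durations)
  if (!is.finite(tbar) || tbar <= 0) stop("degenerate mean cycle duration")
  cyc <- cycles$cycles
  t0 <- cyc$start_time + offset_fraction * tbar
  t1 <- pmin(cyc$end_time, cyc$start_time + (offset_fraction + duty_fraction) * tbar)
  ok <- t1 > t0 & t0 < cyc$end_time
  windows <- data.frame(cycle_index = cyc$cycle[ok], t0 = t0[ok], t1 = t1[ok])
  retained <- retained_by_windows(events$times, windows)
  new_gate_mask("method1", windows, retained,
                list(offset_fraction = offset_fraction,
                     duty_fraction = duty_fraction, mean_period = tbar))
}

#' Greedy amplitude-driven window expansion
#'
#' Core step of cycle-specific gating: starting from an anchor sample
#' (default the amplitude minimum, ties toward the earlier sample), the
#' window grows one sample at a time toward whichever adjacent sample has
#' the lower amplitude (ties toward the earlier side), stopping at the first
#' step at which the window holds at least `duty_fraction` of the events.
#'
#' @param amplitudes Amplitude of each trace sample in the cycle.
#' @param counts Event count attached to each sample.
#' @param duty_fraction Target fraction of the cycle's events.
#' @param anchor Index of the starting sample; default `which.min(amplitudes)`.
#' @return Integer vector `c(lo, hi, count)`: window sample bounds
#'   (inclusive) and the event count it holds.
#' @export
greedy_quiescent_window <- function(amplitudes, counts,
                                    duty_fraction = 0.5,
                                    anchor = which.min(amplitudes)) {
  m <- length(amplitudes)
  stopifnot(length(counts) == m, m >= 1, anchor >= 1, anchor <= m)
  target <- duty_fraction * sum(counts)
  lo <- hi <- as.integer(anchor)
  cnt <- counts[anchor]
  while (cnt < target && (lo > 1L || hi < m)) {
    left <- if (lo > 1L) amplitudes[lo - 1L] else Inf
    right <- if (hi < m) amplitudes[hi + 1L] else Inf
    if (left <= right) {
      lo <- lo - 1L
      cnt <- cnt + counts[lo]
    } else {
      hi <- hi + 1L
      cnt <- cnt + counts[hi]
    }
  }
  c(lo, hi, cnt)
}

#' Method 2: cycle-specific amplitude-driven gating
#'
#' For every breath, the gate is seeded at the cycle's amplitude minimum
#' (end-expiration) and expanded contiguously, one trace sample at a time
#' toward the lower-amplitude neighbour, until it encompasses the duty
#' fraction (default 50%) of that cycle's counts. Unlike Method 1 the
#' window placement adapts to each breath, which is what makes the method
#' robust to irregular breathing.
#'
#' @inheritParams gate_method1_qpg
#' @param trace The [respiratory_trace()] the cycles were segmented from.
#' @return A `gate_mask`; `params$achieved` records the per-cycle retained
#'   fraction (the stopping rule may overshoot the duty target by at most
#'   one sample's worth of events). Cycles holding no events contribute an
#'   empty window with a warning.
#' @export
gate_method2_adaptive <- function(cycles, trace, events, duty_fraction = 0.5) {
  stopifnot(inherits(cycles, "cycle_set"), inherits(trace, "respiratory_trace"),
            inherits(events, "event_stream"))
  if (cycles$n_cycles < 1) stop("no cycles to gate")
  if (duty_fraction <= 0 || duty_fraction > 1) {
    stop("`duty_fraction` must be in (0, 1]")
  }
  tms <- trace$times
  a <- trace$amplitudes
  dt <- 1 / trace$sample_rate
  cyc <- cycles$cycles
  win <- vector("list", nrow(cyc))
  achieved <- rep(NA_real_, nrow(cyc))
  empty <- 0L
  for (i in seq_len(nrow(cyc))) {
    s <- which(tms >= cyc$start_time[i] & tms < cyc$end_time[i])
    if (!length(s)) next
    ev <- events$times[events$times >= cyc$start_time[i] &
                         events$times < cyc$end_time[i]]
    if (!length(ev)) {
      empty <- empty + 1L
      next
    }
    bin <- findInterval(ev, tms[s])
    bin[bin < 1L] <- 1L
    counts <- tabulate(bin, nbins = length(s))
    g <- greedy_quiescent_window(a[s], counts, duty_fraction)
    win[[i]] <- data.frame(cycle_index = cyc$cycle[i],
                           t0 = tms[s[g[1]]],
                           t1 = min(cyc$end_time[i], tms[s[g[2]]] + dt))
    achieved[i] <- g[3] / sum(counts)
  }
  if (empty > 0) {
    warning(sprintf("%d cycle(s) contained no events; empty gate windows", empty))
  }
  windows <- do.call(rbind, win[!vapply(win, is.null, logical(1))])
  if (is.null(windows)) {
    windows <- data.frame(cycle_index = integer(0), t0 = numeric(0),
                          t1 = numeric(0))
  }
  retained <- retained_by_windows(events$times, windows)
  new_gate_mask("method2", windows, retained,
                list(duty_fraction = duty_fraction, achieved = achieved))
}

#' Overlap fraction between two gate masks
#'
#' Fraction of counts selected by both gating methods: the number of events
#' retained by both masks divided by the geometric mean of the two retained
#' counts (so the metric stays defined when duty fractions differ; it
#' reduces to intersection / |A| for equal-size masks). Overlap near 1 means
#' the two methods reconstructed from essentially the same counts; low
#' overlap flags irregular breathing.
#'
#' @param mask_a,mask_b `gate_mask` objects computed over the same event
#'   stream.
#' @param events The shared `event_stream` (used for a consistency check).
#' @return List of class `overlap_result` with `overlap`,
#'   `intersection_counts` and `per_method_counts`.
#' @export
compute_overlap <- function(mask_a, mask_b, events) {
  stopifnot(inherits(mask_a, "gate_mask"), inherits(mask_b, "gate_mask"),
            inherits(events, "event_stream"))
  if (length(mask_a$retained) != events$total_counts ||
      length(mask_b$retained) != events$total_counts) {
    stop("masks were not computed over this event stream")
  }
  na <- sum(mask_a$retained)
  nb <- sum(mask_b$retained)
  if (na == 0 || nb == 0) stop("a mask retains zero events; overlap undefined")
  inter <- sum(mask_a$retained & mask_b$retained)
  structure(
    list(overlap = inter / sqrt(as.numeric(na) * as.numeric(nb)),
         intersection_counts = inter,
         per_method_counts = c(na, nb)),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> overlap = %.3f (%d of %d/%d events)\n",
              x$overlap, x$intersection_counts,
              x$per_method_counts[1], x$per_method_counts[2]))
  invisible(x)
}

#' Spectral R value of a respiratory trace
#'
#' Surrogate for the commercial respiration-detection trigger: the
#' percentage of total periodogram power (0 to Nyquist, mean removed)
#' concentrated in the single largest in-band frequency bin, where the band
#' defaults to 0.1-0.4 Hz (respiration-like frequencies). A clean breathing
#' trace concentrates most of its power at the breathing frequency and
#' scores far above the 15 trigger threshold; broadband noise spreads power
#' over all bins and scores near zero.
#'
#' @param trace A [respiratory_trace()] of at least 30 s (spectral
#'   resolution) with non-zero variance.
#' @param band Respiration band in Hz, default `c(0.1, 0.4)`.
#' @param threshold Trigger threshold, default 15.
#' @return List of class `r_value` with `r` (percent), `band`,
#'   `passes_threshold` and `peak_frequency`.
#' @export
compute_r_value <- function(trace, band = c(0.1, 0.4), threshold = 15) {
  stopifnot(inherits(trace, "respiratory_trace"))
  span <- diff(trace_span(trace))
  if (span < 30) stop("trace must span at least 30 s for spectral resolution")
  x <- trace$amplitudes - mean(trace$amplitudes)
  if (stats::var(x) == 0) stop("trace has zero variance; R value undefined")
  n <- length(x)
  m <- floor(n / 2)
  pw <- Mod(stats::fft(x))^2
  pw <- pw[2:(m + 1)]
  freq <- (1:m) * trace$sample_rate / n
  inband <- freq >= band[1] & freq <= band[2]
  if (!any(inband)) stop("no periodogram bins inside the requested band")
  r <- 100 * max(pw[inband]) / sum(pw)
  structure(
    list(r = r, band = band, passes_threshold = r > threshold,
         peak_frequency = freq[inband][which.max(pw[inband])],
         threshold = threshold),
    class = "r_value"
  )
}

#' @export
print.r_value <- function(x, ...) {
  cat(sprintf("<r_value> R = %.2f (band %.2f-%.2f Hz, peak %.3f Hz): %s\n",
              x$r, x$band[1], x$band[2], x$peak_frequency,
              if (x$passes_threshold) sprintf("exceeds threshold %g", x$threshold)
              else sprintf("below threshold %g", x$threshold)))
  invisible(x)
}

#' Export a gate mask to JSON
#'
#' @param mask A `gate_mask`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gate_mask_json <- function(mask, path) {
  stopifnot(inherits(mask, "gate_mask"))
  jsonlite::write_json(
    list(method = mask$method,
         retained_fraction = mask$retained_fraction,
         n_windows = nrow(mask$windows),
         windows = mask$windows),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
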