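#' Detect breath peaks in a respiratory trace
#'
#' Finds local maxima of the amplitude signal, filters them by topographic
#' prominence, and enforces a minimum peak-to-peak spacing (highest peaks
#' kept first). Plateau maxima are reported at their first sample; ties are
#' thereby broken toward the earlier time.
#'
#' @param trace A [respiratory_trace()] with at least 3 samples.
#' @param min_peak_distance Minimum time between reported peaks, seconds.
#'   The default keeps the literal 10 ms tracker convention, which at
#'   breathing rates never rejects a genuine breath; pass e.g. `1` as a
#'   stricter sanity setting.
#' @param prominence_threshold Minimum prominence in mm. Default: 20% of the
#'   trace's dynamic range, chosen to exclude noise and artifacts.
#' @return Sorted numeric vector of peak times (seconds), with the matching
#'   sample indices in attribute `index`. A flat trace yields an empty
#'   result with a "no respiration detected" warning.
#' @export
detect_breath_peaks <- function(trace, min_peak_distance = 0.01,
                                prominence_threshold = NULL) {
  stopifnot(inherits(trace, "respiratory_trace"))
  a <- trace$amplitudes
  tms <- trace$times
  n <- length(a)
  if (n < 3) stop("trace shorter than 3 samples: cannot detect peaks")
  rng <- diff(range(a))
  if (rng == 0) {
    warning("no respiration detected: trace has zero dynamic range")
    out <- numeric(0)
    attr(out, "index") <- integer(0)
    return(out)
  }
  if (is.null(prominence_threshold)) prominence_threshold <- 0.2 * rng
  if (prominence_threshold <= 0) stop("`prominence_threshold` must be > 0")

  r <- rle(a)
  nr <- length(r$values)
  if (nr < 3) {
    out <- numeric(0)
    attr(out, "index") <- integer(0)
    return(out)
  }
  run_start <- cumsum(r$lengths) - r$lengths + 1L
  v <- r$values
  is_max <- c(FALSE, v[2:(nr - 1)] > v[1:(nr - 2)] &
                v[2:(nr - 1)] > v[3:nr], FALSE)
  cand <- run_start[is_max]
  if (!length(cand)) {
    out <- numeric(0)
    attr(out, "index") <- integer(0)
    return(out)
  }

  prom <- vapply(cand, function(i) {
    h <- a[i]
    left_higher <- which(a[seq_len(i - 1)] > h)
    lb <- if (length(left_higher)) max(left_higher) else 1L
    right_higher <- which(a[(i + 1):n] > h)
    rb <- if (length(right_higher)) i + min(right_higher) else n
    h - max(min(a[lb:i]), min(a[i:rb]))
  }, numeric(1))
  keep <- cand[prom >= prominence_threshold]
  if (!length(keep)) {
    out <- numeric(0)
    attr(out, "index") <- integer(0)
    return(out)
  }

  # greedy minimum-distance pruning, tallest peaks have priority
  ord <- order(a[keep], decreasing = TRUE)
  sel <- logical(length(keep))
  for (i in ord) {
    if (!any(sel) ||
        all(abs(tms[keep[i]] - tms[keep[sel]]) >= min_peak_distance)) {
      sel[i] <- TRUE
    }
  }
  idx <- sort(keep[sel])
  out <- tms[idx]
  attr(out, "index") <- idx
  out
}

#' Segment a trace into breath cycles
#'
#' One cycle per consecutive peak pair: cycle i spans the half-open
#' interval from peak i to peak i+1, so its amplitude minimum
#' (`min_amp_time`, the end-expiration anchor used by amplitude-driven
#' gating; argmin ties break toward the earlier sample) lies in its
#' interior. Cycle *durations* — the quantity tvar is built on — are
#' measured between successive end-expiration boundaries: the amplitude
#' minima between peaks, opened by the amplitude minimum of the segment
#' before the first peak. Measuring breath-to-breath intervals at the
#' minima (rather than peak spacing, which averages adjacent periods)
#' recovers period variability without attenuation. Partial breaths before
#' the first and after the last detected peak are not counted.
#'
#' @param trace A [respiratory_trace()].
#' @param peak_times Peak times from [detect_breath_peaks()]; at least 2.
#' @return An object of class `cycle_set`: list with `cycles` (data frame
#'   with `cycle`, `start_time`, `end_time`, `peak_time`, `min_amp_time`,
#'   `duration`), `durations`, `boundaries` (the minima), `n_cycles`, and
#'   `tvar`/`tvar_mode` slots (filled by [compute_tvar()]).
#' @export
segment_cycles <- function(trace, peak_times) {
  stopifnot(inherits(trace, "respiratory_trace"))
  pk <- sort(as.numeric(peak_times))
  if (length(pk) < 2) stop("cannot segment cycles: fewer than 2 peaks")
  tms <- trace$times
  a <- trace$amplitudes
  ncyc <- length(pk) - 1L
  start <- pk[-length(pk)]
  end <- pk[-1]
  min_amp_time <- vapply(seq_len(ncyc), function(i) {
    idx <- which(tms >= start[i] & tms < end[i])
    tms[idx[which.min(a[idx])]]
  }, numeric(1))
  lead <- which(tms < pk[1])
  opening <- if (length(lead)) tms[lead[which.min(a[lead])]] else tms[1]
  boundaries <- c(opening, min_amp_time)
  cycles <- data.frame(
    cycle = seq_len(ncyc), start_time = start, end_time = end,
    peak_time = start, min_amp_time = min_amp_time,
    duration = diff(boundaries)
  )
  structure(
    list(cycles = cycles, durations = cycles$duration,
         boundaries = boundaries, n_cycles = ncyc,
         tvar = NA_real_, tvar_mode = NA_character_),
    class = "cycle_set"
  )
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf("<cycle_set> %d breaths, mean period %.3f s", x$n_cycles,
              mean(x$durations)))
  if (!is.na(x$tvar)) cat(sprintf(", tvar (%s) = %.4g", x$tvar_mode, x$tvar))
  cat("\n")
  invisible(x)
}

#' Compute the breathing-regularity metric tvar
#'
#' tvar is the dispersion of the breath-cycle durations over a scan. The
#' default mode `"sd"` is the sample standard deviation of the durations
#' (units s); mode `"var"` gives the sample variance (units s^2). Reported
#' objects always carry the mode used, since the two conventions coexist in
#' the field.
#'
#' @param cycle_set A [segment_cycles()] result with at least 2 cycles.
#' @param mode `"sd"` (default) or `"var"`.
#' @return The `cycle_set` with its `tvar` and `tvar_mode` slots filled.
#' @examples
#' tr <- simulate_trace(waveform_params(duration = 60, seed = 2))
#' cs <- compute_tvar(segment_cycles(tr, detect_breath_peaks(tr)))
#' cs$tvar
#' @export
compute_tvar <- function(cycle_set, mode = c("sd", "var")) {
  stopifnot(inherits(cycle_set, "cycle_set"))
  mode <- match.arg(mode)
  if (cycle_set$n_cycles < 2) {
    stop("tvar requires at least 2 cycles")
  }
  cycle_set$tvar <- switch(mode,
    sd = stats::sd(cycle_set$durations),
    var = stats::var(cycle_set$durations))
  cycle_set$tvar_mode <- mode
  cycle_set
}

#' Detect and segment in one call
#'
#' Convenience wrapper: peak detection, cycle segmentation and tvar.
#'
#' @inheritParams detect_breath_peaks
#' @param tvar_mode Passed to [compute_tvar()].
#' @return A `cycle_set` with tvar filled.
#' @export
analyze_cycles <- function(trace, min_peak_distance = 0.01,
                           prominence_threshold = NULL,
                           tvar_mode = "sd") {
  pk <- detect_breath_peaks(trace, min_peak_distance, prominence_threshold)
  compute_tvar(segment_cycles(trace, pk), tvar_mode)
}
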