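#' Waveform generator parameters
#'
#' Parameters for the cycle-by-cycle raised-cosine breathing simulator. Each
#' breath i draws a period from Normal(`mean_period`, `period_jitter_sd`)
#' truncated below at half the mean period, and a depth from
#' Normal(`amplitude`, `amplitude_jitter_sd`) truncated at zero. Amplitude is
#' half the peak-to-peak excursion, so the default of 15 mm reproduces a
#' +/-15 mm motion platform setting. White measurement noise and a
#' random-walk baseline drift can be added per sample.
#'
#' @param mean_period Mean breath period in seconds (> 0).
#' @param period_jitter_sd SD of per-cycle period jitter, seconds (>= 0).
#' @param amplitude Half peak-to-peak breath depth in mm (default 15).
#' @param amplitude_jitter_sd SD of per-cycle depth jitter, mm (>= 0).
#' @param baseline_drift_sd Per-sample SD of the random-walk baseline, mm.
#' @param noise_sd Per-sample white noise SD, mm.
#' @param duration Trace length in seconds; must be at least 3 mean periods.
#' @param sample_rate Sampling rate in Hz (default 25).
#' @param seed Optional integer seed; identical parameters and seed give a
#'   bit-identical trace.
#' @return A list of class `waveform_params`.
#' @seealso [simulate_trace()], [waveform_presets()]
#' @export
waveform_params <- function(mean_period = 4, period_jitter_sd = 0,
                            amplitude = 15, amplitude_jitter_sd = 0,
                            baseline_drift_sd = 0, noise_sd = 0,
                            duration = 120, sample_rate = 25, seed = NULL) {
  p <- list(mean_period = mean_period, period_jitter_sd = period_jitter_sd,
            amplitude = amplitude, amplitude_jitter_sd = amplitude_jitter_sd,
            baseline_drift_sd = baseline_drift_sd, noise_sd = noise_sd,
            duration = duration, sample_rate = sample_rate, seed = seed)
  num <- p[setdiff(names(p), "seed")]
  if (!all(vapply(num, function(x) is.numeric(x) && length(x) == 1 &&
                    is.finite(x), logical(1)))) {
    stop("all waveform parameters must be finite scalars")
  }
  if (mean_period <= 0) stop("`mean_period` must be > 0")
  if (sample_rate <= 0) stop("`sample_rate` must be > 0")
  if (duration < 3 * mean_period) {
    stop("`duration` must be at least 3 mean periods")
  }
  sds <- c(period_jitter_sd, amplitude_jitter_sd, baseline_drift_sd, noise_sd)
  if (any(sds < 0)) stop("jitter, drift and noise SDs must be >= 0")
  if (amplitude <= 0) stop("`amplitude` must be > 0")
  structure(p, class = "waveform_params")
}

#' Waveform presets for the two breathing classes
#'
#' Two stock parameter sets emulating a typical (regular) and an irregular
#' breathing pattern on a motion platform: both breathe at a 4 s mean period
#' with +/-15 mm excursion; the irregular class has four times the period
#' jitter and three times the depth jitter of the typical class.
#'
#' @param duration Trace length in seconds.
#' @param seed Optional seed applied to both presets.
#' @return Named list with elements `typical` and `irregular`, each a
#'   [waveform_params()].
#' @export
waveform_presets <- function(duration = 120, seed = NULL) {
  list(
    typical = waveform_params(mean_period = 4, period_jitter_sd = 0.25,
                              amplitude = 15, amplitude_jitter_sd = 1,
                              baseline_drift_sd = 0.02, noise_sd = 0.3,
                              duration = duration, seed = seed),
    irregular = waveform_params(mean_period = 4, period_jitter_sd = 1,
                                amplitude = 15, amplitude_jitter_sd = 3,
                                baseline_drift_sd = 0.05, noise_sd = 0.3,
                                duration = duration, seed = seed)
  )
}

# normal draw truncated below at `lower` by rejection; sd == 0 degenerates
rnorm_trunc <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(max(mean, lower), n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower)
  }
  x
}

#' Simulate a respiratory trace
#'
#' Concatenates raised-cosine breaths: within breath i of period T_i and
#' depth A_i the displacement at phase p in `[0, 1)` is `A_i * (1 - cos(2 pi
#' p))`, so every breath starts and ends at its end-expiration minimum and
#' peaks mid-cycle at 2 A_i (peak-to-peak excursion twice the `amplitude`
#' parameter, i.e. a +/- amplitude platform throw). Per-sample white noise
#' and random-walk baseline drift are added afterwards.
#'
#' @param params A [waveform_params()].
#' @return A [respiratory_trace()] with attributes `params` and `n_cycles`
#'   (number of complete breaths inside `duration`).
#' @examples
#' tr <- simulate_trace(waveform_params(mean_period = 4, duration = 60, seed = 1))
#' attr(tr, "n_cycles")
#' @export
simulate_trace <- function(params) {
  if (!inherits(params, "waveform_params")) {
    params <- do.call(waveform_params, params)
  }
  if (!is.null(params$seed)) set.seed(params$seed)
  periods <- numeric(0)
  depths <- numeric(0)
  total <- 0
  # draw cycle by cycle so the seed stream is stable across durations
  while (total < params$duration) {
    periods <- c(periods, rnorm_trunc(1, params$mean_period,
                                      params$period_jitter_sd,
                                      0.5 * params$mean_period))
    depths <- c(depths, rnorm_trunc(1, params$amplitude,
                                    params$amplitude_jitter_sd, 0))
    total <- sum(periods)
  }
  bounds <- c(0, cumsum(periods))
  n <- floor(params$duration * params$sample_rate) + 1L
  times <- (seq_len(n) - 1L) / params$sample_rate
  k <- findInterval(times, bounds, rightmost.closed = TRUE)
  k[k > length(periods)] <- length(periods)
  phase <- (times - bounds[k]) / periods[k]
  amp <- depths[k] * (1 - cos(2 * pi * phase))
  if (params$noise_sd > 0) amp <- amp + stats::rnorm(n, 0, params$noise_sd)
  if (params$baseline_drift_sd > 0) {
    amp <- amp + cumsum(stats::rnorm(n, 0, params$baseline_drift_sd))
  }
  tr <- respiratory_trace(times, amp, params$sample_rate)
  attr(tr, "params") <- params
  attr(tr, "n_cycles") <- sum(cumsum(periods) <= params$duration + 1e-9)
  tr
}
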