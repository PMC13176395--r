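# Independent oracles and small fixtures used across the suite.

# pure sinusoid trace built directly (not via the simulator)
sine_trace <- function(freq = 0.25, amplitude = 1, duration = 60,
                       sample_rate = 25, phase = 0) {
  t <- seq(0, duration, by = 1 / sample_rate)
  respiratory_trace(t, amplitude * sin(2 * pi * freq * t + phase))
}

# brute-force local maxima with prominence, by direct scan (independent of
# the package's rle-based implementation)
oracle_peaks <- function(a, prominence) {
  n <- length(a)
  out <- integer(0)
  i <- 2L
  while (i < n) {
    if (a[i] > a[i - 1]) {
      j <- i
      while (j < n && a[j + 1] == a[j]) j <- j + 1
      if (j < n && a[j + 1] < a[j]) {
        h <- a[i]
        lh <- which(a[seq_len(i - 1)] > h)
        lb <- if (length(lh)) max(lh) else 1L
        rh <- which(a[(j + 1):n] > h)
        rb <- if (length(rh)) j + min(rh) else n
        if (h - max(min(a[lb:i]), min(a[j:rb])) >= prominence) {
          out <- c(out, i)
        }
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# exhaustive search for the minimal contiguous event window containing the
# anchor sample: minimal length, then minimal amplitude sum, then earliest
# start — the benchmark the greedy expansion must reproduce
oracle_min_window <- function(amplitudes, counts, duty, anchor) {
  m <- length(amplitudes)
  target <- duty * sum(counts)
  best <- NULL
  for (lo in 1:anchor) {
    for (hi in anchor:m) {
      if (sum(counts[lo:hi]) >= target) {
        cand <- c(lo, hi, sum(amplitudes[lo:hi]))
        if (is.null(best) ||
            (hi - lo) < (best[2] - best[1]) ||
            ((hi - lo) == (best[2] - best[1]) && cand[3] < best[3] - 1e-12) ||
            ((hi - lo) == (best[2] - best[1]) &&
               abs(cand[3] - best[3]) <= 1e-12 && lo < best[1])) {
          best <- cand
        }
        break  # longer hi for this lo cannot be shorter
      }
    }
  }
  best[1:2]
}

# random unimodal (valley-shaped) toy cycle; integer amplitudes create ties
random_valley <- function(n, integer_amps = FALSE) {
  pit <- sample(seq_len(n), 1)
  left <- sort(runif(pit - 1, 1, 10), decreasing = TRUE)
  right <- sort(runif(n - pit, 1, 10))
  a <- c(left, 0, right)
  if (integer_amps) a <- round(a)
  a
}

# hand-built cycle_set covering [0, n_cycles * period) with uniform cycles
toy_cycle_set <- function(n_cycles = 1, period = 4, start = 0) {
  starts <- start + period * (seq_len(n_cycles) - 1)
  cycles <- data.frame(
    cycle = seq_len(n_cycles), start_time = starts,
    end_time = starts + period, peak_time = starts,
    min_amp_time = starts + period / 2, duration = rep(period, n_cycles)
  )
  structure(list(cycles = cycles, durations = cycles$duration,
                 boundaries = c(starts, starts[n_cycles] + period),
                 n_cycles = n_cycles, tvar = NA_real_,
                 tvar_mode = NA_character_),
            class = "cycle_set")
}

# event stream from explicit times (for deterministic gating arithmetic)
manual_events <- function(times) {
  structure(list(times = sort(times), displacements = numeric(length(times)),
                 total_counts = length(times), span = range(times)),
            class = "event_stream")
}

# sphere centres implied by the phantom layout (ring at 60-degree steps)
sphere_centers_for_tests <- function(spec) {
  ang <- seq(0, by = 60, length.out = length(spec$sphere_diameters)) * pi / 180
  cbind(spec$sphere_ring_radius * cos(ang),
        spec$sphere_ring_radius * sin(ang),
        0)
}

# standard simulated scan used by several gating tests
sim_scan <- function(jitter = 1, seed = 1, duration = 120, rate = 1000,
                     noise_sd = 0) {
  p <- waveform_params(mean_period = 4, period_jitter_sd = jitter,
                       duration = duration, noise_sd = noise_sd, seed = seed)
  trace <- simulate_trace(p)
  events <- simulate_events(trace, rate, seed = seed + 1L)
  cycles <- analyze_cycles(trace)
  list(trace = trace, events = events, cycles = cycles)
}
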