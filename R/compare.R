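#' Default reconstruction-arm grid
#'
#' Four physically distinguishable arms emulating the usual six-way
#' comparison (reconstruction-engine differences are not modelled, so the
#' two gated pairs differ only by optional post-smoothing):
#' full-count ungated (gold standard), half-count ungated (clinical
#' standard), and the two gating methods at full budget (gating itself
#' halves the retained counts, so gated arms match the half-count ungated
#' arm in counts). Set `dle_like = TRUE` to append post-smoothed variants
#' of the two gated arms.
#'
#' @param dle_like Append smoothed gated arms (default FALSE).
#' @param counts_per_unit Poisson calibration passed to every arm.
#' @return List of arm definition lists (label, count_budget, gating,
#'   apply_motion, post_smooth_fwhm).
#' @export
default_arms <- function(dle_like = FALSE, counts_per_unit = 50) {
  arms <- list(
    list(label = "ungated_full", count_budget = 1, gating = "none",
         apply_motion = TRUE, post_smooth_fwhm = 0),
    list(label = "ungated_half", count_budget = 0.5, gating = "none",
         apply_motion = TRUE, post_smooth_fwhm = 0),
    list(label = "method1_gated", count_budget = 1, gating = "method1",
         apply_motion = TRUE, post_smooth_fwhm = 0),
    list(label = "method2_gated", count_budget = 1, gating = "method2",
         apply_motion = TRUE, post_smooth_fwhm = 0)
  )
  if (dle_like) {
    arms <- c(arms, list(
      list(label = "method1_smoothed", count_budget = 1, gating = "method1",
           apply_motion = TRUE, post_smooth_fwhm = 5),
      list(label = "method2_smoothed", count_budget = 1, gating = "method2",
           apply_motion = TRUE, post_smooth_fwhm = 5)
    ))
  }
  for (i in seq_along(arms)) arms[[i]]$counts_per_unit <- counts_per_unit
  arms
}

#' Experiment configuration
#'
#' @param waveforms Named list of [waveform_params()] (one per breathing
#'   class); defaults to [waveform_presets()].
#' @param arms Arm definitions as produced by [default_arms()].
#' @param n_repeats Acquisitions per waveform (default 3).
#' @param event_rate List-mode event rate, counts/s.
#' @param phantom A [phantom_spec()].
#' @param seed Base integer seed; every scan and arm derives its own seed
#'   from it.
#' @param tvar_threshold Regular/irregular stratification threshold.
#' @param duty_fraction,offset_fraction Gating settings.
#' @param noiseless Skip Poisson noise (for ordering checks).
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(waveforms = waveform_presets(),
                              arms = default_arms(),
                              n_repeats = 3,
                              event_rate = 1000,
                              phantom = phantom_spec(),
                              seed = 1,
                              tvar_threshold = 1.5,
                              duty_fraction = 0.5,
                              offset_fraction = 0.3,
                              noiseless = FALSE) {
  if (n_repeats < 1) stop("`n_repeats` must be >= 1")
  if (length(arms) < 2) stop("need at least 2 arms")
  if (is.null(names(waveforms)) || any(names(waveforms) == "")) {
    stop("`waveforms` must be a named list")
  }
  structure(
    list(waveforms = waveforms, arms = arms, n_repeats = n_repeats,
         event_rate = event_rate, phantom = phantom, seed = seed,
         tvar_threshold = tvar_threshold, duty_fraction = duty_fraction,
         offset_fraction = offset_fraction, noiseless = noiseless),
    class = "experiment_config"
  )
}

#' Run a multi-arm gating experiment
#'
#' For every waveform x repeat: simulate a trace and event stream, detect
#' cycles, gate with both methods, record tvar / overlap / R, then simulate
#' and score every reconstruction arm. Fully seeded: rerunning with the
#' same config reproduces the report bit for bit.
#'
#' @param config An [experiment_config()].
#' @return List of class `gating_experiment` with `metrics` (one row per
#'   scan x arm x sphere: CR/BV/CNR plus liver noise), `scans` (one row per
#'   scan: tvar, overlap, R, retained fractions) and the `config`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  static <- build_static_phantom(config$phantom)
  metrics <- list()
  scans <- list()
  scan_id <- 0L
  for (wname in names(config$waveforms)) {
    for (rep in seq_len(config$n_repeats)) {
      scan_id <- scan_id + 1L
      seed <- config$seed + 7919L * scan_id
      p <- config$waveforms[[wname]]
      p$seed <- seed
      trace <- simulate_trace(p)
      events <- simulate_events(trace, config$event_rate, seed = seed + 1L)
      cs <- analyze_cycles(trace)
      m1 <- gate_method1_qpg(cs, events, config$offset_fraction,
                             config$duty_fraction)
      m2 <- gate_method2_adaptive(cs, trace, events, config$duty_fraction)
      ov <- compute_overlap(m1, m2, events)
      rv <- compute_r_value(trace)
      scans[[scan_id]] <- data.frame(
        scan = scan_id, waveform = wname, repeat_no = rep, seed = seed,
        n_cycles = cs$n_cycles, tvar = cs$tvar, overlap = ov$overlap,
        r_value = rv$r, retained_m1 = m1$retained_fraction,
        retained_m2 = m2$retained_fraction)
      for (ai in seq_along(config$arms)) {
        ad <- config$arms[[ai]]
        mask <- switch(ad$gating, none = NULL, method1 = m1, method2 = m2,
                       stop("unknown gating: ", ad$gating))
        arm <- recon_arm(ad$label, ad$count_budget, mask,
                         ad$counts_per_unit %||% 50,
                         ad$post_smooth_fwhm %||% 0,
                         ad$apply_motion %||% TRUE)
        vol <- simulate_arm(config$phantom, trace, arm,
                            seed = seed + 100L + ai,
                            noiseless = config$noiseless,
                            static_volume = static)
        iq <- measure_iq(vol, config$phantom)
        liver <- tryCatch(liver_snr(vol, config$phantom$liver_center),
                          error = function(e) NULL)
        iq$scan <- scan_id
        iq$waveform <- wname
        iq$repeat_no <- rep
        iq$arm <- ad$label
        iq$liver_mean <- if (is.null(liver)) NA_real_ else liver$voi_mean
        iq$liver_sd <- if (is.null(liver)) NA_real_ else liver$voi_sd
        iq$liver_snr <- if (is.null(liver)) NA_real_ else liver$snr
        metrics[[length(metrics) + 1L]] <- iq
      }
    }
  }
  structure(
    list(metrics = do.call(rbind, metrics), scans = do.call(rbind, scans),
         config = config),
    class = "gating_experiment"
  )
}

#' @export
print.gating_experiment <- function(x, ...) {
  cat(sprintf("<gating_experiment> %d scans x %d arms, %d metric rows\n",
              nrow(x$scans), length(x$config$arms), nrow(x$metrics)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Omnibus-then-pairwise statistical comparison
#'
#' Kruskal-Wallis omnibus across all arms; pairwise tests (Wilcoxon
#' signed-rank for paired ordinal-like data, paired t for noise metrics)
#' are run only when the omnibus is significant (gatekeeping, which keeps
#' the familywise error at the omnibus level), with Bonferroni adjustment
#' `p_adj = min(1, p * family_size)`.
#'
#' @param samples Named list of numeric vectors, one per arm (>= 2 arms,
#'   >= 2 observations each; equal lengths when `paired`).
#' @param paired Whether pairwise tests are paired (default TRUE: arms are
#'   reconstructions of the same scans).
#' @param family_size Bonferroni family; default the number of pairwise
#'   comparisons.
#' @param alpha Omnibus gate level (default 0.05).
#' @param gatekeep Set FALSE to force pairwise tests regardless of the
#'   omnibus result.
#' @param pairwise_test `"wilcoxon"` or `"t"`.
#' @return List of class `arm_comparison`: `omnibus_p`, `pairwise_p` (raw),
#'   `adjusted_p`, `performed`, `family_size`.
#' @export
omnibus_then_pairwise <- function(samples, paired = TRUE, family_size = NULL,
                                  alpha = 0.05, gatekeep = TRUE,
                                  pairwise_test = c("wilcoxon", "t")) {
  pairwise_test <- match.arg(pairwise_test)
  k <- length(samples)
  if (k < 2) stop("need at least 2 arms")
  if (any(vapply(samples, length, integer(1)) < 2)) {
    stop("each arm needs at least 2 observations")
  }
  if (paired && length(unique(vapply(samples, length, integer(1)))) != 1) {
    stop("paired comparison requires equal-length arms")
  }
  if (is.null(names(samples))) names(samples) <- paste0("arm", seq_len(k))
  omnibus_p <- stats::kruskal.test(samples)$p.value
  npairs <- choose(k, 2)
  family <- family_size %||% npairs
  raw <- matrix(NA_real_, k, k, dimnames = list(names(samples), names(samples)))
  performed <- !gatekeep || omnibus_p < alpha
  if (performed) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        p <- if (pairwise_test == "wilcoxon") {
          suppressWarnings(stats::wilcox.test(samples[[i]], samples[[j]],
                                              paired = paired)$p.value)
        } else {
          stats::t.test(samples[[i]], samples[[j]], paired = paired)$p.value
        }
        raw[i, j] <- raw[j, i] <- p
      }
    }
  }
  adj <- raw
  adj[] <- pmin(1, raw * family)
  structure(
    list(omnibus_p = omnibus_p, pairwise_p = raw,
         adjusted_p = adj, performed = performed,
         family_size = family, pairwise_test = pairwise_test),
    class = "arm_comparison"
  )
}

#' @export
print.arm_comparison <- function(x, ...) {
  cat(sprintf("<arm_comparison> Kruskal-Wallis p = %.4g; pairwise %s %s\n",
              x$omnibus_p, x$pairwise_test,
              if (x$performed) sprintf("(Bonferroni family %d)", x$family_size)
              else "not performed (omnibus not significant)"))
  if (x$performed) print(round(x$adjusted_p, 4))
  invisible(x)
}

#' Compare arms from an experiment report
#'
#' Extracts one observation per scan and arm for a metric and runs
#' [omnibus_then_pairwise()]. Image metrics default to the smallest sphere
#' (most motion-sensitive); liver metrics ignore `sphere_mm`.
#'
#' @param report A [run_experiment()] result.
#' @param metric One of `"CR"`, `"BV"`, `"CNR"`, `"liver_sd"`,
#'   `"liver_snr"`.
#' @param sphere_mm Sphere diameter to compare at (default the smallest).
#' @param ... Passed to [omnibus_then_pairwise()]. Liver noise defaults to
#'   the paired t test, other metrics to Wilcoxon.
#' @return An `arm_comparison`.
#' @export
compare_arms <- function(report, metric = "CNR", sphere_mm = NULL, ...) {
  stopifnot(inherits(report, "gating_experiment"))
  m <- report$metrics
  if (!metric %in% names(m)) stop("unknown metric: ", metric)
  if (!grepl("^liver", metric)) {
    sphere_mm <- sphere_mm %||% min(m$sphere_mm)
    m <- m[m$sphere_mm == sphere_mm, ]
  } else {
    m <- m[m$sphere_mm == min(m$sphere_mm), ]  # liver stats repeat per sphere
  }
  arm_labels <- vapply(report$config$arms, `[[`, character(1), "label")
  samples <- lapply(arm_labels, function(a) m[m$arm == a, metric])
  names(samples) <- arm_labels
  dots <- list(...)
  if (is.null(dots$pairwise_test)) {
    dots$pairwise_test <- if (grepl("^liver", metric)) "t" else "wilcoxon"
  }
  do.call(omnibus_then_pairwise, c(list(samples = samples), dots))
}

#' Regress gating overlap on tvar
#'
#' Ordinary least squares of overlap against tvar; a negative slope is the
#' signature that irregular breathing (high tvar) drives the two gating
#' methods to select different counts.
#'
#' @param tvar Numeric vector, or a data frame with columns `tvar` and
#'   `overlap` (e.g. the `scans` table of [run_experiment()]).
#' @param overlap Numeric vector (ignored when `tvar` is a data frame).
#' @return List with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
regress_overlap_on_tvar <- function(tvar, overlap = NULL) {
  if (is.data.frame(tvar)) {
    overlap <- tvar$overlap
    tvar <- tvar$tvar
  }
  if (length(tvar) < 3) stop("need at least 3 (tvar, overlap) pairs")
  if (stats::var(tvar) == 0) stop("tvar is constant; regression undefined")
  fit <- stats::lm(overlap ~ tvar)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4],
       n = length(tvar))
}

#' Stratify records by breathing regularity
#'
#' Partitions records into a regular cohort (tvar <= threshold; boundary
#' values count as regular, irregularity being strictly above threshold)
#' and an irregular cohort (tvar > threshold).
#'
#' @param records Data frame with a `tvar` column, or a numeric tvar
#'   vector.
#' @param threshold Default 1.5.
#' @return List with `regular`, `irregular` and `threshold`.
#' @export
stratify_by_tvar <- function(records, threshold = 1.5) {
  tv <- if (is.data.frame(records)) records$tvar else records
  if (is.null(tv)) stop("records carry no tvar")
  reg <- tv <= threshold
  if (is.data.frame(records)) {
    list(regular = records[reg, , drop = FALSE],
         irregular = records[!reg, , drop = FALSE], threshold = threshold)
  } else {
    list(regular = records[reg], irregular = records[!reg],
         threshold = threshold)
  }
}
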