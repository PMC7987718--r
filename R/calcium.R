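# Stimulus-aligned dF/F and AUC analysis of fluorescence traces.

#' Stimulus-aligned dF/F for one stimulus epoch
#'
#' The baseline F0 is the mean raw fluorescence from 10 s to 200 ms before
#' stimulus onset (defaults); the series is `(F - F0) / F0` with time
#' re-zeroed to the onset.
#'
#' @param time_s Sample times, s (strictly increasing).
#' @param f Raw fluorescence, same length.
#' @param onset_s Stimulus onset, s.
#' @param baseline_from_s,baseline_to_s Baseline window relative to onset,
#'   s (must satisfy `baseline_from_s < baseline_to_s < 0`).
#' @return `data.frame(rel_time_s, dff)` covering all samples, with time
#'   relative to the onset.
#' @export
dff <- function(time_s, f, onset_s, baseline_from_s = -10,
                baseline_to_s = -0.2) {
  stopifnot(length(time_s) == length(f), all(diff(time_s) > 0))
  if (!(baseline_from_s < baseline_to_s && baseline_to_s < 0)) {
    stop("need baseline_from_s < baseline_to_s < 0", call. = FALSE)
  }
  sel <- time_s >= onset_s + baseline_from_s & time_s <= onset_s + baseline_to_s
  if (!any(sel)) stop("baseline window contains no samples", call. = FALSE)
  f0 <- mean(f[sel])
  if (f0 <= 0) stop("non-physical baseline: F0 <= 0", call. = FALSE)
  data.frame(rel_time_s = time_s - onset_s, dff = (f - f0) / f0)
}

#' Within-fly average of stimulus-aligned dF/F traces
#'
#' Computes dF/F per stimulus epoch, resamples each epoch by linear
#' interpolation onto a common relative-time grid at the native sample
#' spacing, and averages pointwise across stimuli. Epochs truncated by the
#' recording edges (insufficient pre-onset baseline or post-stimulus tail)
#' are excluded and counted.
#'
#' @param time_s,f Recording samples, as in [dff()].
#' @param onsets_s Stimulus onset times, s.
#' @param stim_duration_s Stimulus duration, s.
#' @param pre_s Pre-onset span of the common grid, s (also the baseline
#'   span required for an epoch to be usable).
#' @param post_s Post-onset span of the common grid, s; defaults to the
#'   stimulus duration plus 10 s of decay.
#' @param baseline_from_s,baseline_to_s Passed to [dff()].
#' @return A list with `rel_time_s` (common grid), `dff` (pointwise mean),
#'   `n_stimuli_used` and `n_excluded`.
#' @export
within_fly_average <- function(time_s, f, onsets_s, stim_duration_s = 5,
                               pre_s = 10, post_s = stim_duration_s + 10,
                               baseline_from_s = -10, baseline_to_s = -0.2) {
  stopifnot(length(onsets_s) >= 1L)
  dt <- stats::median(diff(time_s))
  grid <- seq(-pre_s, post_s, by = dt)
  usable <- onsets_s[onsets_s - pre_s >= min(time_s) &
                     onsets_s + post_s <= max(time_s)]
  n_excl <- length(onsets_s) - length(usable)
  if (length(usable) == 0L) {
    stop("no stimulus epoch fully inside the recording", call. = FALSE)
  }
  traces <- vapply(usable, function(o) {
    d <- dff(time_s, f, o, baseline_from_s, baseline_to_s)
    stats::approx(d$rel_time_s, d$dff, xout = grid)$y
  }, numeric(length(grid)))
  list(rel_time_s = grid, dff = rowMeans(traces),
       n_stimuli_used = length(usable), n_excluded = n_excl)
}

#' Area under an aligned dF/F curve
#'
#' Subtracts the mean dF/F over the 1 s immediately before the stimulus
#' (`[-baseline_s, 0)`), then trapezoid-integrates the baseline-subtracted
#' trace from stimulus onset until `end_offset_s` after stimulus end
#' (window `[0, stim_duration_s + end_offset_s]`). With the defaults a flat
#' trace yields AUC 0 regardless of its level.
#'
#' @param rel_time_s Times relative to stimulus onset, s.
#' @param dff Aligned dF/F values, same length.
#' @param stim_duration_s Stimulus duration, s.
#' @param end_offset_s Integration extension past stimulus end, s.
#' @param baseline_s Pre-stimulus baseline span, s.
#' @return Scalar AUC, dF/F x s.
#' @export
auc_dff <- function(rel_time_s, dff, stim_duration_s = 5, end_offset_s = 1,
                    baseline_s = 1) {
  stopifnot(length(rel_time_s) == length(dff), all(diff(rel_time_s) > 0))
  end <- stim_duration_s + end_offset_s
  if (min(rel_time_s) > 0 || max(rel_time_s) < end) {
    stop("integration window [0, ", end, "] not covered by samples",
         call. = FALSE)
  }
  bsel <- rel_time_s >= -baseline_s & rel_time_s < 0
  if (!any(bsel)) stop("pre-stimulus baseline window contains no samples",
                       call. = FALSE)
  bl <- mean(dff[bsel])
  inside <- rel_time_s >= 0 & rel_time_s <= end
  t_int <- rel_time_s[inside]
  y_int <- dff[inside]
  # close the window exactly at 0 and at stim end + offset
  if (length(t_int) == 0L || t_int[1] > 0) {
    t_int <- c(0, t_int)
    y_int <- c(stats::approx(rel_time_s, dff, xout = 0)$y, y_int)
  }
  if (t_int[length(t_int)] < end) {
    t_int <- c(t_int, end)
    y_int <- c(y_int, stats::approx(rel_time_s, dff, xout = end)$y)
  }
  pracma::trapz(t_int, y_int - bl)
}

#' Condition-level summary of per-fly AUCs
#'
#' Mean, SE and n (number of flies) per condition, plus Kruskal-Wallis and
#' Holm-adjusted pairwise Mann-Whitney U tests across conditions when
#' there are at least two. Conditions with a single fly get an undefined
#' SE and are flagged.
#'
#' @param auc Per-fly AUC values (one value per fly: within-fly averages
#'   are computed upstream).
#' @param condition Condition factor, same length.
#' @return A list with `summary` (`data.frame(condition, n, mean, se)`)
#'   and `tests` (a [kruskal_mwu()] result, or `NULL` with one condition).
#' @export
calcium_group_summary <- function(auc, condition) {
  condition <- factor(condition)
  stopifnot(length(auc) == length(condition), all(table(condition) >= 1L))
  agg <- do.call(rbind, lapply(levels(condition), function(cc) {
    v <- auc[condition == cc]
    data.frame(condition = cc, n = length(v), mean = mean(v),
               se = if (length(v) > 1L) stats::sd(v) / sqrt(length(v))
                    else NA_real_)
  }))
  if (any(agg$n == 1L)) {
    warning("condition(s) with a single fly: SE undefined")
  }
  tests <- if (nlevels(condition) >= 2L) kruskal_mwu(auc, condition) else NULL
  list(summary = agg, tests = tests)
}
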