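#' Invadopodia detection from growth-cone actin traces
#'
#' The growth cone's LifeAct (filamentous actin) integrated density,
#' sampled every 5 min over the regenerative timelapse, is background
#' subtracted, thresholded at its own mean over the analyzed window, and
#' scanned for maximal runs of supra-threshold frames. Runs of 4 or more
#' consecutive timepoints (>= 20 min at 5-min sampling) are invadopodia
#' formation events; durations classify them as transient (20-35 min),
#' intermediate (40-55 min) or stable (>= 60 min). Events are compiled per
#' group, overall and restricted to frames when the growth cone sat at the
#' dorsal root entry zone (DREZ).
#'
#' @name regenquant-invadopodia
NULL

#' Growth-cone intensity trace container
#'
#' @param values growth-cone integrated density per frame, a.u.
#' @param background matched per-frame background integrated density
#'   (sampled dorsal to the spinal cord), a.u.
#' @param interval_minutes sampling interval (5 min in the study).
#' @param window_start 1-based index of the first analyzed frame (the
#'   frame at which regenerative extension began).
#' @param state per-frame growth-cone state, "navigating" or "at_drez".
#' @return list of class `intensity_trace`.
#' @export
intensity_trace <- function(values, background,
                            interval_minutes = 5, window_start = 1L,
                            state = rep("navigating", length(values))) {
  n <- length(values)
  stopifnot(length(background) == n, length(state) == n,
            interval_minutes > 0, window_start >= 1, window_start <= n,
            all(state %in% c("navigating", "at_drez")))
  structure(list(frames = seq_len(n), values = as.numeric(values),
                 background = as.numeric(background),
                 interval_minutes = interval_minutes,
                 window_start = as.integer(window_start),
                 state = state),
            class = "intensity_trace")
}

#' Background-subtract a trace
#'
#' Per-frame `value - background`; negative values are preserved (no
#' clamping), matching spreadsheet subtraction of the matched background
#' sample.
#'
#' @param trace an [intensity_trace()].
#' @return numeric corrected series.
#' @export
background_subtract <- function(trace) {
  stopifnot(inherits(trace, "intensity_trace"))
  trace$values - trace$background
}

#' Self-referential mean threshold
#'
#' The event threshold is the arithmetic mean of the background-subtracted
#' trace over all analyzed frames (frame >= `window_start`) — the
#' "threshold line" of the original workflow.
#'
#' @param corrected background-subtracted intensity series.
#' @param window_start first analyzed frame.
#' @return scalar threshold, a.u.
#' @export
mean_threshold <- function(corrected, window_start = 1L) {
  n <- length(corrected)
  if (window_start < 1 || window_start > n) stop("empty analysis window")
  mean(corrected[seq.int(window_start, n)])
}

#' Detect invadopodia formation events by run-length scanning
#'
#' Maximal runs of frames strictly above threshold become events when they
#' span at least `min_consecutive` timepoints (4 or more consecutive
#' timepoints, equating to 20 min or more at 5-min sampling). Runs touching
#' either end of the analyzed window are kept. A frame exactly at the
#' threshold does not extend a run.
#'
#' @param corrected background-subtracted series.
#' @param threshold intensity threshold (typically [mean_threshold()]).
#' @param interval_minutes frame interval, minutes.
#' @param min_consecutive minimum run length in frames.
#' @param window_start first analyzed frame; earlier frames are ignored.
#' @return data.frame with `start_frame`, `end_frame`, `n_frames`,
#'   `duration_min` (run length x interval), zero rows when no event.
#' @export
detect_events <- function(corrected, threshold, interval_minutes = 5,
                          min_consecutive = 4L, window_start = 1L) {
  stopifnot(is.finite(threshold), min_consecutive >= 1)
  n <- length(corrected)
  idx <- seq.int(window_start, n)
  above <- corrected[idx] > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_consecutive
  out <- data.frame(
    start_frame = idx[starts[keep]],
    end_frame = idx[ends[keep]],
    n_frames = r$lengths[keep]
  )
  out$duration_min <- out$n_frames * interval_minutes
  out
}

#' Classify an event duration into a stability class
#'
#' The printed bands — transient 20-35 min, intermediate 40-55 min, stable
#' 60-70+ min — partition the durations reachable at 5-min sampling. For
#' other intervals the bands are half-open with no gaps: transient
#' \[20, 40), intermediate \[40, 60), stable \[60, Inf).
#'
#' @param duration_minutes event duration (>= 20 min; shorter runs are not
#'   events).
#' @return "transient", "intermediate" or "stable" (vectorized).
#' @export
classify_event <- function(duration_minutes) {
  if (any(duration_minutes < 20)) {
    stop("durations < 20 min are not invadopodia events")
  }
  ifelse(duration_minutes < 40, "transient",
         ifelse(duration_minutes < 60, "intermediate", "stable"))
}

#' Detect and classify all events in one trace
#'
#' Convenience pipeline: background subtraction, mean threshold over the
#' analyzed window, run-length detection, duration classification, and
#' at-DREZ assignment (an event is at the DREZ iff a strict majority of
#' its frames carry the `at_drez` state; the per-event at-DREZ frame
#' fraction is emitted so the stricter all-frames rule is recomputable).
#'
#' @param trace an [intensity_trace()].
#' @param min_consecutive minimum run length in frames.
#' @return data.frame of events with `stability_class`, `at_drez`,
#'   `frac_frames_at_drez`.
#' @export
trace_events <- function(trace, min_consecutive = 4L) {
  stopifnot(inherits(trace, "intensity_trace"))
  corrected <- background_subtract(trace)
  thr <- mean_threshold(corrected, trace$window_start)
  ev <- detect_events(corrected, thr, trace$interval_minutes,
                      min_consecutive, trace$window_start)
  if (nrow(ev)) {
    ev$stability_class <- classify_event(ev$duration_min)
    ev$frac_frames_at_drez <- mapply(function(s, e) {
      mean(trace$state[s:e] == "at_drez")
    }, ev$start_frame, ev$end_frame)
    ev$at_drez <- ev$frac_frames_at_drez > 0.5
  } else {
    ev$stability_class <- character(0)
    ev$frac_frames_at_drez <- numeric(0)
    ev$at_drez <- logical(0)
  }
  ev
}

#' Compile invadopodia events across a treatment / genotype group
#'
#' Pools event durations across all traces of a group (the study's
#' compilation unit), and separately the durations of events that occurred
#' while the growth cone was at the DREZ; per-trace mean at-DREZ durations
#' are also reported to expose the pseudo-replication question.
#'
#' @param traces list of [intensity_trace()]s, each with a per-frame state
#'   annotation.
#' @param group_label text label.
#' @return list of class `event_compilation`: `durations_all`,
#'   `durations_at_drez`, `per_trace_mean_at_drez`, `events` (row-bound
#'   per-trace event tables with a `trace` column).
#' @export
compile_events <- function(traces, group_label = "group") {
  stopifnot(length(traces) >= 1,
            all(vapply(traces, inherits, TRUE, "intensity_trace")))
  per <- lapply(seq_along(traces), function(i) {
    ev <- trace_events(traces[[i]])
    if (nrow(ev)) ev$trace <- i else ev$trace <- integer(0)
    ev
  })
  events <- do.call(rbind, per)
  at <- events[events$at_drez, , drop = FALSE]
  per_trace_mean <- vapply(per, function(ev) {
    d <- ev$duration_min[ev$at_drez]
    if (length(d)) mean(d) else NA_real_
  }, 0)
  structure(list(group_label = group_label,
                 durations_all = events$duration_min,
                 durations_at_drez = at$duration_min,
                 per_trace_mean_at_drez = per_trace_mean,
                 events = events),
            class = "event_compilation")
}

#' Orthogonal basal width of a growth-cone actin profile
#'
#' Full width of the contiguous region around the global intensity peak at
#' half the peak's background-corrected height (FWHM), with the crossing
#' positions linearly interpolated between samples; the local background is
#' the profile minimum. Distinguishes wide invadopodia-like bases from
#' narrow filopodia. A flat profile has no defined width.
#'
#' @param values intensity series along the orthogonal measurement line.
#' @param positions sample positions, um.
#' @return list with `width_um` (NA when flagged) and `flag`.
#' @export
basal_width <- function(values, positions) {
  stopifnot(length(values) == length(positions), length(values) >= 3,
            all(diff(positions) > 0))
  if (diff(range(values)) == 0) {
    return(list(width_um = NA_real_, flag = "flat_profile"))
  }
  bg <- min(values)
  i <- which.max(values)
  half <- bg + (values[i] - bg) / 2
  # walk outward from the peak to the first samples below half
  lo <- i
  while (lo > 1 && values[lo - 1] >= half) lo <- lo - 1
  hi <- i
  while (hi < length(values) && values[hi + 1] >= half) hi <- hi + 1
  left <- if (lo == 1) {
    positions[1] - (positions[2] - positions[1]) / 2
  } else {
    cross_at(positions[lo - 1], positions[lo], values[lo - 1], values[lo], half)
  }
  right <- if (hi == length(values)) {
    positions[hi] + (positions[hi] - positions[hi - 1]) / 2
  } else {
    cross_at(positions[hi], positions[hi + 1], values[hi], values[hi + 1], half)
  }
  list(width_um = right - left, flag = "ok")
}

cross_at <- function(x0, x1, y0, y1, level) {
  if (y1 == y0) return((x0 + x1) / 2)
  x0 + (level - y0) / (y1 - y0) * (x1 - x0)
}
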