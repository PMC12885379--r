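#' Synthetic assay data with ground truth
#'
#' Seeded generators that fabricate every input the analysis modules
#' consume, standing in for the microscope. Each generator returns the
#' simulated record together with a ground-truth sidecar describing exactly
#' what was planted (event spans, responder classes, shiver frames, puncta
#' centers, track drifts), so downstream recovery can be checked against
#' truth. Identical seed and spec give bit-identical output.
#'
#' Conventions: the analysis coordinate frame has +y = dorsal, units are
#' micrometers; frame indices are 1-based throughout (the calcium schedule
#' speaks of "the 16th frame").
#'
#' @name regenquant-synthetic
NULL

new_ground_truth <- function(assay, ...) {
  structure(list(assay = assay, ...), class = "ground_truth")
}

#' Specification of a synthetic LifeAct growth-cone trace
#'
#' Describes a growth-cone integrated-density time series sampled at fixed
#' intervals (the overnight timelapses imaged every 5 min for 22-24 h),
#' with rectangular supra-baseline actin events planted at known frames.
#'
#' @param n_frames number of frames (>= 1).
#' @param interval_minutes sampling interval, minutes.
#' @param baseline_level baseline growth-cone signal above background, a.u.
#' @param events list of `c(start_frame, n_frames, amplitude)` triples; the
#'   amplitude is added on top of the baseline for the event's frames.
#'   Events must lie within the trace and must not overlap.
#' @param noise_sd Gaussian noise sd added independently to signal and
#'   background samples, a.u.
#' @param background_level flat background integrated density, a.u.
#' @param drez_arrival_frame first frame at which the growth cone is at the
#'   DREZ (all later frames annotated `at_drez`), or `NULL` for a trace
#'   that is navigating throughout.
#' @param window_start first analyzed frame (extension onset).
#' @param seed integer RNG seed.
#' @return A list of class `trace_spec`.
#' @export
trace_spec <- function(n_frames, interval_minutes = 5, baseline_level = 100,
                       events = list(), noise_sd = 0, background_level = 50,
                       drez_arrival_frame = NULL, window_start = 1L,
                       seed = 1L) {
  stopifnot(n_frames >= 1, interval_minutes > 0, noise_sd >= 0,
            window_start >= 1, window_start <= n_frames)
  events <- lapply(events, function(e) {
    e <- as.numeric(e)
    if (length(e) != 3L) stop("each event is c(start_frame, n_frames, amplitude)")
    if (e[1] < 1 || e[1] + e[2] - 1 > n_frames) {
      stop("event frames must lie within [1, n_frames]")
    }
    e
  })
  if (length(events) >= 2L) {
    spans <- do.call(rbind, lapply(events, function(e) c(e[1], e[1] + e[2] - 1)))
    o <- order(spans[, 1])
    spans <- spans[o, , drop = FALSE]
    if (any(spans[-1, 1] <= spans[-nrow(spans), 2])) {
      stop("planted events overlap")
    }
  }
  structure(list(n_frames = as.integer(n_frames),
                 interval_minutes = interval_minutes,
                 baseline_level = baseline_level, events = events,
                 noise_sd = noise_sd, background_level = background_level,
                 drez_arrival_frame = drez_arrival_frame,
                 window_start = as.integer(window_start),
                 seed = as.integer(seed)),
            class = "trace_spec")
}

#' Generate a LifeAct growth-cone intensity trace
#'
#' The emitted trace has `value = baseline + events + background (+ noise)`
#' and a matched per-frame background series, so that background
#' subtraction recovers `baseline + events`. With `noise_sd = 0` the
#' planted events are exactly the frames whose background-subtracted value
#' exceeds the trace mean, provided each event amplitude is positive.
#'
#' @param spec a [trace_spec()].
#' @return list with `trace` (an `intensity_trace`, see
#'   [intensity_trace()]) and `truth` (planted event spans).
#' @export
gen_lifeact_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  set.seed(spec$seed)
  n <- spec$n_frames
  signal <- rep(spec$baseline_level, n)
  truth_events <- data.frame(start_frame = integer(0), end_frame = integer(0),
                             n_frames = integer(0), amplitude = numeric(0))
  for (e in spec$events) {
    idx <- seq.int(e[1], e[1] + e[2] - 1)
    signal[idx] <- signal[idx] + e[3]
    truth_events <- rbind(truth_events,
                          data.frame(start_frame = e[1],
                                     end_frame = e[1] + e[2] - 1,
                                     n_frames = e[2], amplitude = e[3]))
  }
  background <- rep(spec$background_level, n)
  if (spec$noise_sd > 0) {
    signal <- signal + stats::rnorm(n, 0, spec$noise_sd)
    background <- background + stats::rnorm(n, 0, spec$noise_sd)
  }
  state <- rep("navigating", n)
  if (!is.null(spec$drez_arrival_frame)) {
    stopifnot(spec$drez_arrival_frame >= 1, spec$drez_arrival_frame <= n)
    state[seq.int(spec$drez_arrival_frame, n)] <- "at_drez"
  }
  trace <- intensity_trace(values = signal + background,
                           background = background,
                           interval_minutes = spec$interval_minutes,
                           window_start = spec$window_start, state = state)
  truth <- new_ground_truth("lifeact_trace", events = truth_events,
                            drez_arrival_frame = spec$drez_arrival_frame)
  list(trace = trace, truth = truth)
}

#' Generate a dual-channel orthogonal line-profile pair
#'
#' Emulates the 8-um line drawn across the junction of a regenerating
#' axon's distal tip and the glial limitans in an orthogonal view: two
#' unimodal (Gaussian) profiles on a shared medial-to-lateral axis. The
#' boundary peak sits at the line midpoint; the axon peak is displaced by
#' `separation_um` (negative = medial = inside the spinal cord).
#'
#' @param separation_um axon center minus boundary center, um.
#' @param axon_width_um,boundary_width_um full widths at half maximum of
#'   the two fluorescence peaks, um.
#' @param noise_sd Gaussian intensity noise sd (a.u.; peaks have height 1).
#' @param seed integer RNG seed.
#' @param line_length_um length of the measurement line (medial end = 0).
#' @param spacing_um sample spacing along the line.
#' @return list with `pair` (an [orth_profile_pair()]) and `truth`
#'   (planted peak centers).
#' @export
gen_orth_profiles <- function(separation_um, axon_width_um = 1.5,
                              boundary_width_um = 1.5, noise_sd = 0,
                              seed = 1L, line_length_um = 8,
                              spacing_um = 0.25) {
  stopifnot(axon_width_um > 0, boundary_width_um > 0, noise_sd >= 0)
  boundary_center <- line_length_um / 2
  axon_center <- boundary_center + separation_um
  if (axon_center < 0 || axon_center > line_length_um) {
    stop("separation places the axon peak center off the line")
  }
  set.seed(seed)
  pos <- seq(0, line_length_um, by = spacing_um)
  fwhm_to_sd <- 1 / (2 * sqrt(2 * log(2)))
  axon <- exp(-(pos - axon_center)^2 / (2 * (axon_width_um * fwhm_to_sd)^2))
  boundary <- exp(-(pos - boundary_center)^2 /
                    (2 * (boundary_width_um * fwhm_to_sd)^2))
  if (noise_sd > 0) {
    axon <- axon + stats::rnorm(length(pos), 0, noise_sd)
    boundary <- boundary + stats::rnorm(length(pos), 0, noise_sd)
  }
  pair <- orth_profile_pair(positions = pos, axon_values = axon,
                            boundary_values = boundary)
  truth <- new_ground_truth("orth_profiles", axon_center_um = axon_center,
                            boundary_center_um = boundary_center,
                            separation_um = separation_um)
  list(pair = pair, truth = truth)
}

#' Generate an object track with planted linear drift
#'
#' @param n_frames number of samples (>= 2).
#' @param drift_um_per_frame length-2 numeric, per-frame (dx, dy) in um
#'   (+y = dorsal).
#' @param jitter_sd isotropic Gaussian positional jitter sd, um.
#' @param start_xy starting position, um.
#' @param seed integer RNG seed.
#' @param object_id,role identifiers for the emitted [object_track()].
#' @return list with `track` and `truth` (drift vector and noise-free
#'   endpoint displacement).
#' @export
gen_tracks <- function(n_frames, drift_um_per_frame = c(0, 0.05),
                       jitter_sd = 0, start_xy = c(0, 0), seed = 1L,
                       object_id = "obj1", role = "glial_nucleus") {
  stopifnot(n_frames >= 2, length(drift_um_per_frame) == 2,
            jitter_sd >= 0)
  set.seed(seed)
  steps <- seq_len(n_frames) - 1
  x <- start_xy[1] + steps * drift_um_per_frame[1]
  y <- start_xy[2] + steps * drift_um_per_frame[2]
  if (jitter_sd > 0) {
    x <- x + stats::rnorm(n_frames, 0, jitter_sd)
    y <- y + stats::rnorm(n_frames, 0, jitter_sd)
  }
  track <- object_track(object_id = object_id, role = role,
                        frames = seq_len(n_frames), x = x, y = y)
  disp <- (n_frames - 1) * drift_um_per_frame
  truth <- new_ground_truth("track", drift_um_per_frame = drift_um_per_frame,
                            endpoint_displacement_um = disp,
                            endpoint_distance_um = sqrt(sum(disp^2)))
  list(track = track, truth = truth)
}

#' Specification of a synthetic GCaMP6s recording
#'
#' Describes one animal's evoked calcium assay: a rapid 24-frame (5-s
#' interval) timelapse in which room-temperature water is added just before
#' frame 8 and cold (4 C) water just before frame 16. Cells are planted as
#' `rapid` (z-crossing at the cold frame, synchronous with the stimulus),
#' `delayed` (first crossing at a planted onset after the cold frame), or
#' `none` (never crossing).
#'
#' @param classes data.frame with columns `cell_id`, `role` ("drg" or
#'   "spinal"), `class` ("rapid", "delayed", "none") and `onset_frame`
#'   (first-crossing frame for delayed cells; `NA` otherwise). The study
#'   design traces 30 spinal neurons per animal.
#' @param n_frames,interval_seconds,rt_frame,cold_frame schedule.
#' @param rise_frames frames over which the transient rises to peak (1 =
#'   the cell reaches peak in the first post-stimulus capture, the GCaMP6s
#'   "fluoresces quickly" behavior).
#' @param decay_per_frame multiplicative per-frame decay of the transient
#'   after its peak, in (0,1) (slow decay: default 0.8).
#' @param peak_amplitude_sd_units planted peak z-amplitude: with
#'   `noise_sd = 0` the scored z at the peak frame equals this value
#'   exactly (the generator calibrates the trace shape numerically).
#' @param noise_sd additive Gaussian intensity noise, a.u.
#' @param baseline_level baseline fluorescence, a.u.
#' @param seed integer RNG seed.
#' @return A list of class `calcium_spec`.
#' @export
calcium_spec <- function(classes, n_frames = 24L, interval_seconds = 5,
                         rt_frame = 8L, cold_frame = 16L, rise_frames = 1L,
                         decay_per_frame = 0.8,
                         peak_amplitude_sd_units = 3, noise_sd = 0,
                         baseline_level = 100, seed = 1L) {
  stopifnot(is.data.frame(classes),
            all(c("cell_id", "role", "class") %in% names(classes)),
            rt_frame < cold_frame, cold_frame <= n_frames,
            decay_per_frame > 0, decay_per_frame < 1,
            rise_frames >= 1, noise_sd >= 0,
            peak_amplitude_sd_units > 0)
  if (!all(classes$class %in% c("rapid", "delayed", "none"))) {
    stop("class must be rapid, delayed or none")
  }
  if (!all(classes$role %in% c("drg", "spinal"))) {
    stop("role must be drg or spinal")
  }
  if (is.null(classes$onset_frame)) classes$onset_frame <- NA_integer_
  d <- classes$class == "delayed"
  if (any(d & (is.na(classes$onset_frame) |
                 classes$onset_frame < cold_frame + 1 |
                 classes$onset_frame > n_frames))) {
    stop("delayed cells need onset_frame in [cold_frame + 1, n_frames]")
  }
  structure(list(classes = classes, n_frames = as.integer(n_frames),
                 interval_seconds = interval_seconds,
                 rt_frame = as.integer(rt_frame),
                 cold_frame = as.integer(cold_frame),
                 rise_frames = as.integer(rise_frames),
                 decay_per_frame = decay_per_frame,
                 peak_amplitude_sd_units = peak_amplitude_sd_units,
                 noise_sd = noise_sd, baseline_level = baseline_level,
                 seed = as.integer(seed)),
            class = "calcium_spec")
}

#' Helper: cohort class table for [calcium_spec()]
#'
#' @param n_rapid,n_delayed,n_none spinal-cell counts per planted class.
#' @param n_drg number of DRG neurons (all planted rapid).
#' @param delayed_onset onset frame(s) for delayed spinal cells (recycled).
#' @param cold_frame schedule cold frame, used to default `delayed_onset`.
#' @return data.frame suitable for the `classes` argument.
#' @export
calcium_classes <- function(n_rapid, n_delayed, n_none, n_drg = 1L,
                            delayed_onset = NULL, cold_frame = 16L) {
  if (is.null(delayed_onset)) delayed_onset <- cold_frame + 2L
  n_sp <- n_rapid + n_delayed + n_none
  data.frame(
    cell_id = c(sprintf("drg%02d", seq_len(n_drg)),
                sprintf("sp%02d", seq_len(n_sp))),
    role = c(rep("drg", n_drg), rep("spinal", n_sp)),
    class = c(rep("rapid", n_drg), rep("rapid", n_rapid),
              rep("delayed", n_delayed), rep("none", n_none)),
    onset_frame = c(rep(NA_integer_, n_drg), rep(NA_integer_, n_rapid),
                    rep_len(as.integer(delayed_onset), n_delayed),
                    rep(NA_integer_, n_none)),
    stringsAsFactors = FALSE
  )
}

# Build a unit-free trace shape whose sample z-score at `peak_frame` equals
# `target_z` exactly. The z-score of a shape is invariant to positive
# scaling, so amplitude cannot tune it; instead the shape itself is
# calibrated: a pure one-frame spike attains the maximum z = (n-1)/sqrt(n),
# and adding weight `lambda` of the kinetic tail (rise + exponential decay)
# plus a small alternating baseline wiggle lowers z monotonically. uniroot
# finds the lambda at which z(peak) = target_z.
calibrate_calcium_shape <- function(n_frames, peak_frame, rise_frames,
                                    decay_per_frame, target_z) {
  n <- n_frames
  z_max <- (n - 1) / sqrt(n)
  if (target_z >= z_max) {
    stop(sprintf("peak amplitude %.3f sd-units unreachable; max is %.3f for %d frames",
                 target_z, z_max, n))
  }
  spike <- numeric(n); spike[peak_frame] <- 1
  extra <- numeric(n)
  if (rise_frames > 1) {
    pre <- seq_len(rise_frames - 1)
    idx <- peak_frame - rev(pre)
    keep <- idx >= 1
    extra[idx[keep]] <- (pre / rise_frames)[keep]
  }
  post <- seq_len(n - peak_frame)
  if (length(post)) extra[peak_frame + post] <- decay_per_frame^post
  # alternating wiggle keeps pre-stimulus sd positive without crossings
  wig <- numeric(n)
  pre_idx <- seq_len(max(peak_frame - rise_frames, 2L))
  wig[pre_idx] <- 0.05 * (-1)^pre_idx
  z_at <- function(lambda) {
    s <- spike + lambda * (extra + wig)
    (s[peak_frame] - mean(s)) / stats::sd(s)
  }
  if (z_at(0) <= target_z) stop("internal calibration failure")
  hi <- 1
  while (z_at(hi) > target_z) hi <- hi * 2
  lambda <- stats::uniroot(function(l) z_at(l) - target_z, c(0, hi),
                           tol = 1e-12)$root
  spike + lambda * (extra + wig)
}

#' Generate a GCaMP6s calcium recording
#'
#' Per-cell traces follow the planted responder classes. With
#' `noise_sd = 0`, a rapid cell's z-score at the cold frame equals
#' `peak_amplitude_sd_units` exactly, a delayed cell first crosses at its
#' planted onset, and a `none` cell's |z| stays near 1, far below the 2.0
#' activation threshold.
#'
#' @param spec a [calcium_spec()].
#' @return list with `recording` (a [calcium_recording()]) and `truth`
#'   (planted classes).
#' @export
gen_calcium <- function(spec) {
  stopifnot(inherits(spec, "calcium_spec"))
  set.seed(spec$seed)
  cl <- spec$classes
  n <- spec$n_frames
  traces <- matrix(0, nrow = nrow(cl), ncol = n,
                   dimnames = list(cl$cell_id, NULL))
  amp <- 20 # a.u.; arbitrary positive scale, z is scale-free
  for (i in seq_len(nrow(cl))) {
    shape <- switch(
      cl$class[i],
      rapid = calibrate_calcium_shape(n, spec$cold_frame, spec$rise_frames,
                                      spec$decay_per_frame,
                                      spec$peak_amplitude_sd_units),
      delayed = calibrate_calcium_shape(n, cl$onset_frame[i],
                                        spec$rise_frames,
                                        spec$decay_per_frame,
                                        spec$peak_amplitude_sd_units),
      none = 0.05 * (-1)^seq_len(n) # |z| <= ~1
    )
    traces[i, ] <- spec$baseline_level + amp * shape
  }
  if (spec$noise_sd > 0) {
    traces <- traces + matrix(stats::rnorm(length(traces), 0, spec$noise_sd),
                              nrow = nrow(traces))
  }
  rec <- calcium_recording(matrix = traces, roles = cl$role,
                           rt_frame = spec$rt_frame,
                           cold_frame = spec$cold_frame,
                           interval_seconds = spec$interval_seconds)
  truth <- new_ground_truth("calcium", classes = cl)
  list(recording = rec, truth = truth)
}

#' Specification of a synthetic behavioral recording
#'
#' One larva filmed at 50-ms intervals for 600 frames (30 s). Bouts are
#' non-overlapping; frames outside any bout are still. A shiver bout is a
#' stationary head oscillation (sinusoid, 2 frames per half-cycle) with no
#' centroid displacement; a swim bout is correlated head + centroid
#' forward displacement.
#'
#' @param n_frames,interval_ms movie geometry.
#' @param bouts list of `list(start, length, kind, amplitude, net_speed)`
#'   with `kind` in "shiver", "swim", "still"; `amplitude` is the head
#'   oscillation amplitude (um) and `net_speed` the forward speed
#'   (um/frame; ignored for shiver/still).
#' @param seed integer RNG seed.
#' @return A list of class `behavior_spec`.
#' @export
behavior_spec <- function(n_frames = 600L, interval_ms = 50, bouts = list(),
                          seed = 1L) {
  stopifnot(n_frames >= 1, interval_ms > 0)
  for (b in bouts) {
    stopifnot(all(c("start", "length", "kind") %in% names(b)),
              b$kind %in% c("shiver", "swim", "still"),
              b$start >= 1, b$start + b$length - 1 <= n_frames)
    if (!is.null(b$amplitude)) stopifnot(b$amplitude >= 0)
  }
  if (length(bouts) >= 2L) {
    spans <- do.call(rbind, lapply(bouts, function(b)
      c(b$start, b$start + b$length - 1)))
    o <- order(spans[, 1]); spans <- spans[o, , drop = FALSE]
    if (any(spans[-1, 1] <= spans[-nrow(spans), 2])) stop("bouts overlap")
  }
  structure(list(n_frames = as.integer(n_frames), interval_ms = interval_ms,
                 bouts = bouts, seed = as.integer(seed)),
            class = "behavior_spec")
}

#' Generate head and body-centroid behavioral tracks
#'
#' @param spec a [behavior_spec()].
#' @return list with `head` and `centroid` ([object_track()]s) and `truth`
#'   (logical shiver-frame vector and per-bout table).
#' @export
gen_behavior_tracks <- function(spec) {
  stopifnot(inherits(spec, "behavior_spec"))
  set.seed(spec$seed)
  n <- spec$n_frames
  head_x <- numeric(n); head_y <- numeric(n)
  cen_x <- numeric(n); cen_y <- numeric(n)
  shiver <- logical(n)
  base_head <- c(0, 1) # head sits 1 um dorsal of centroid at rest
  pos <- c(0, 0)       # running centroid position
  frame <- 1L
  bouts <- spec$bouts[order(vapply(spec$bouts, `[[`, 0, "start"))]
  bout_of <- rep(0L, n)
  for (i in seq_along(bouts)) {
    b <- bouts[[i]]
    bout_of[seq.int(b$start, b$start + b$length - 1)] <- i
  }
  for (f in seq_len(n)) {
    i <- bout_of[f]
    osc <- 0
    if (i > 0L) {
      b <- bouts[[i]]
      k <- f - b$start
      if (b$kind == "swim") {
        pos <- pos + c(b$net_speed %||% 1, 0)
        osc <- (b$amplitude %||% 0.5) * sinpi(k / 2) * 0.2
      } else if (b$kind == "shiver") {
        osc <- (b$amplitude %||% 2) * sinpi(k / 2) # period 4 frames
        shiver[f] <- TRUE
      }
    }
    cen_x[f] <- pos[1]; cen_y[f] <- pos[2]
    head_x[f] <- pos[1] + base_head[1] + osc
    head_y[f] <- pos[2] + base_head[2]
  }
  frames <- seq_len(n)
  head <- object_track("head", "head", frames, head_x, head_y)
  centroid <- object_track("centroid", "centroid", frames, cen_x, cen_y)
  bt <- if (length(bouts)) {
    data.frame(start = vapply(bouts, `[[`, 0, "start"),
               length = vapply(bouts, `[[`, 0, "length"),
               kind = vapply(bouts, `[[`, "", "kind"))
  } else {
    data.frame(start = numeric(0), length = numeric(0), kind = character(0))
  }
  truth <- new_ground_truth("behavior", shiver_frames = shiver, bouts = bt)
  list(head = head, centroid = centroid, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic HCR image with Gaussian puncta
#'
#' Flat background with well-separated Gaussian puncta planted uniformly
#' inside a polygonal region (pairwise center distance >= 3 sigma), with
#' optional Poisson shot noise. The image is a plain numeric matrix with a
#' `pixel_size_um` attribute; row 1 / column 1 is the (0,0) um corner and
#' pixel centers sit at (i - 0.5) * pixel size.
#'
#' @param n_puncta number of puncta to plant.
#' @param region_mask polygon as a 2-column matrix of (x, y) vertices, um.
#' @param punctum_sigma_um Gaussian sd of a punctum, um.
#' @param punctum_peak peak amplitude above background, a.u. (counts when
#'   Poisson noise is on).
#' @param background flat background level, a.u.
#' @param poisson_noise if `TRUE`, pixel values are Poisson draws with the
#'   noise-free image as mean.
#' @param pixel_size_um pixel pitch, um.
#' @param seed integer RNG seed.
#' @param max_tries rejection-sampling budget before declaring the mask too
#'   small for the separation rule.
#' @return list with `image` (matrix, attribute `pixel_size_um`) and
#'   `truth` (data.frame of planted centers in um).
#' @export
gen_hcr_image <- function(n_puncta, region_mask, punctum_sigma_um = 0.15,
                          punctum_peak = 200, background = 10,
                          poisson_noise = FALSE, pixel_size_um = 0.1,
                          seed = 1L, max_tries = 5000L) {
  stopifnot(punctum_sigma_um > 0, punctum_peak > 0, background >= 0,
            n_puncta >= 0)
  mask <- as.matrix(region_mask)
  stopifnot(ncol(mask) == 2, nrow(mask) >= 3)
  set.seed(seed)
  pad <- 4 * punctum_sigma_um
  xr <- range(mask[, 1]); yr <- range(mask[, 2])
  nx <- ceiling((xr[2] + pad) / pixel_size_um)
  ny <- ceiling((yr[2] + pad) / pixel_size_um)
  if (min(xr[1], yr[1]) < 0) stop("mask must lie in the positive quadrant")
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0L
  min_sep <- 3 * punctum_sigma_um
  while (nrow(centers) < n_puncta) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("mask too small to place the requested puncta at >= 3 sigma separation")
    }
    cand <- c(stats::runif(1, xr[1], xr[2]), stats::runif(1, yr[1], yr[2]))
    if (!point_in_polygon(cand[1], cand[2], mask)) next
    if (nrow(centers) > 0 &&
        any(sqrt(colSums((t(centers) - cand)^2)) < min_sep)) next
    centers <- rbind(centers, cand)
  }
  # pixel-center coordinate grids (um)
  xs <- (seq_len(nx) - 0.5) * pixel_size_um
  ys <- (seq_len(ny) - 0.5) * pixel_size_um
  img <- matrix(background, nrow = ny, ncol = nx)
  if (n_puncta > 0) {
    for (i in seq_len(nrow(centers))) {
      gx <- exp(-(xs - centers[i, 1])^2 / (2 * punctum_sigma_um^2))
      gy <- exp(-(ys - centers[i, 2])^2 / (2 * punctum_sigma_um^2))
      img <- img + punctum_peak * outer(gy, gx)
    }
  }
  if (poisson_noise) {
    img <- matrix(stats::rpois(length(img), lambda = img),
                  nrow = ny, ncol = nx)
  }
  attr(img, "pixel_size_um") <- pixel_size_um
  truth_df <- if (n_puncta > 0) {
    data.frame(x_um = centers[, 1], y_um = centers[, 2])
  } else {
    data.frame(x_um = numeric(0), y_um = numeric(0))
  }
  list(image = img,
       truth = new_ground_truth("hcr_image", centers = truth_df,
                                n_puncta = n_puncta))
}
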