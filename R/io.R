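#' Plain-text readers and writers
#'
#' Every assay input is tidy CSV with `# key: value` header comment lines
#' carrying the record-level metadata (intervals, schedule frames, line
#' orientation); ground truth and results are JSON. Images travel as CSV
#' matrices with a pixel-size header (the environment provides no TIFF
#' reader for R, and text round-trips exactly).
#'
#' @name regenquant-io
NULL

write_header_csv <- function(df, path, header = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(header)) {
    writeLines(sprintf("# %s: %s", k, format(header[[k]])), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_header_csv <- function(path) {
  lines <- readLines(path)
  hdr_lines <- grep("^#", lines)
  header <- list()
  for (l in lines[hdr_lines]) {
    m <- regmatches(l, regexec("^#\\s*([^:]+):\\s*(.*)$", l))[[1]]
    if (length(m) == 3) {
      v <- m[3]
      num <- suppressWarnings(as.numeric(v))
      header[[trimws(m[2])]] <- if (!is.na(num)) num else trimws(v)
    }
  }
  df <- utils::read.csv(text = paste(lines[setdiff(seq_along(lines), hdr_lines)],
                                     collapse = "\n"),
                        stringsAsFactors = FALSE)
  list(data = df, header = header)
}

#' Write / read an intensity trace as CSV
#'
#' Columns `frame`, `value`, `background`, `state`; header keys
#' `interval_minutes`, `window_start`.
#'
#' @param trace an [intensity_trace()].
#' @param path file path.
#' @return `path` (writer) or an `intensity_trace` (reader).
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "intensity_trace"))
  df <- data.frame(frame = trace$frames, value = trace$values,
                   background = trace$background, state = trace$state)
  write_header_csv(df, path, list(interval_minutes = trace$interval_minutes,
                                  window_start = trace$window_start))
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  r <- read_header_csv(path)
  intensity_trace(values = r$data$value, background = r$data$background,
                  interval_minutes = r$header$interval_minutes %||% 5,
                  window_start = as.integer(r$header$window_start %||% 1),
                  state = r$data$state %||% rep("navigating", nrow(r$data)))
}

#' Write / read an orthogonal profile pair as CSV
#'
#' Columns `position_um`, `axon`, `boundary`; header keys
#' `line_length_um`, `medial_end`. The medial end must be declared
#' (coordinate 0); there is no auto-detection of line orientation.
#'
#' @param pair an [orth_profile_pair()].
#' @param path file path.
#' @return `path` (writer) or an `orth_profile_pair` (reader).
#' @export
write_profile_csv <- function(pair, path) {
  stopifnot(inherits(pair, "orth_profile_pair"))
  df <- data.frame(position_um = pair$positions, axon = pair$axon_values,
                   boundary = pair$boundary_values)
  write_header_csv(df, path, list(line_length_um = pair$line_length_um,
                                  medial_end = 0))
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  r <- read_header_csv(path)
  if (is.null(r$header$medial_end)) {
    stop("profile CSV must declare 'medial_end' in its header")
  }
  L <- r$header$line_length_um %||% max(r$data$position_um)
  me <- r$header$medial_end
  pos <- r$data$position_um
  ax <- r$data$axon
  bd <- r$data$boundary
  if (isTRUE(all.equal(me, L))) {
    # line scanned lateral-first: flip into the canonical medial-end-0 frame
    o <- order(L - pos)
    pos <- (L - pos)[o]; ax <- ax[o]; bd <- bd[o]
  } else if (me != 0) {
    stop("medial_end must be 0 or the line length")
  }
  orth_profile_pair(positions = pos, axon_values = ax, boundary_values = bd,
                    line_length_um = L)
}

#' Write / read object tracks as CSV
#'
#' One row per object per frame; columns `object_id`, `role`, `frame`,
#' `x_um`, `y_um` (MTrackJ-style exports map directly).
#'
#' @param tracks an [object_track()] or list of them.
#' @param path file path.
#' @return `path` (writer) or a named list of `object_track`s (reader).
#' @export
write_tracks_csv <- function(tracks, path) {
  if (inherits(tracks, "object_track")) tracks <- list(tracks)
  df <- do.call(rbind, lapply(tracks, as.data.frame))
  write_header_csv(df, path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  r <- read_header_csv(path)
  sp <- split(r$data, r$data$object_id)
  out <- lapply(sp, function(d) {
    d <- d[order(d$frame), ]
    object_track(d$object_id[1], d$role[1], d$frame, d$x_um, d$y_um)
  })
  out[order(names(out))]
}

#' Write / read a calcium recording as tidy CSV
#'
#' Tidy form: columns `cell_id`, `role`, `frame`, `value`; header keys
#' `rt_frame`, `cold_frame`, `interval_seconds`. The reader also accepts
#' the wide form (`cell_id`, `role`, `f1` ... `fN`).
#'
#' @param recording a [calcium_recording()].
#' @param path file path.
#' @return `path` (writer) or a `calcium_recording` (reader).
#' @export
write_calcium_csv <- function(recording, path) {
  stopifnot(inherits(recording, "calcium_recording"))
  m <- recording$matrix
  df <- data.frame(
    cell_id = rep(rownames(m), each = ncol(m)),
    role = rep(recording$roles, each = ncol(m)),
    frame = rep(seq_len(ncol(m)), times = nrow(m)),
    value = as.vector(t(m))
  )
  write_header_csv(df, path,
                   list(rt_frame = recording$rt_frame,
                        cold_frame = recording$cold_frame,
                        interval_seconds = recording$interval_seconds))
}

#' @rdname write_calcium_csv
#' @export
read_calcium_csv <- function(path) {
  r <- read_header_csv(path)
  d <- r$data
  if ("frame" %in% names(d)) {
    ids <- unique(d$cell_id)
    frames <- sort(unique(d$frame))
    m <- matrix(NA_real_, length(ids), length(frames),
                dimnames = list(ids, NULL))
    m[cbind(match(d$cell_id, ids), match(d$frame, frames))] <- d$value
    roles <- d$role[match(ids, d$cell_id)]
  } else {
    fcols <- grep("^f\\d+$", names(d), value = TRUE)
    fcols <- fcols[order(as.integer(sub("^f", "", fcols)))]
    m <- as.matrix(d[, fcols])
    rownames(m) <- d$cell_id
    roles <- d$role
  }
  calcium_recording(m, roles,
                    rt_frame = as.integer(r$header$rt_frame %||% 8),
                    cold_frame = as.integer(r$header$cold_frame %||% 16),
                    interval_seconds = r$header$interval_seconds %||% 5)
}

#' Write / read a behavioral recording as CSV
#'
#' Columns `frame`, `head_x`, `head_y`, `centroid_x`, `centroid_y`;
#' header keys `interval_ms`, `immersion_frame`.
#'
#' @param rec a [behavior_recording()].
#' @param path file path.
#' @return `path` (writer) or a `behavior_recording` (reader).
#' @export
write_behavior_csv <- function(rec, path) {
  stopifnot(inherits(rec, "behavior_recording"))
  df <- data.frame(frame = rec$head$frame,
                   head_x = rec$head$x_um, head_y = rec$head$y_um,
                   centroid_x = rec$centroid$x_um,
                   centroid_y = rec$centroid$y_um)
  write_header_csv(df, path, list(interval_ms = rec$interval_ms,
                                  immersion_frame = rec$immersion_frame,
                                  analysis_n_frames = rec$analysis_n_frames))
}

#' @rdname write_behavior_csv
#' @export
read_behavior_csv <- function(path) {
  r <- read_header_csv(path)
  d <- r$data
  behavior_recording(
    head = object_track("head", "head", d$frame, d$head_x, d$head_y),
    centroid = object_track("centroid", "centroid", d$frame, d$centroid_x,
                            d$centroid_y),
    interval_ms = r$header$interval_ms %||% 50,
    immersion_frame = as.integer(r$header$immersion_frame %||% 1),
    analysis_n_frames = as.integer(r$header$analysis_n_frames %||% 400))
}

#' Write / read an image as a CSV matrix
#'
#' Rows are image rows; header key `pixel_size_um`.
#'
#' @param image numeric matrix with `pixel_size_um` attribute.
#' @param path file path.
#' @return `path` (writer) or a matrix with `pixel_size_um` (reader).
#' @export
write_image_csv <- function(image, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pixel_size_um: %s",
                     format(attr(image, "pixel_size_um"))), con)
  utils::write.table(unclass(image), con, row.names = FALSE,
                     col.names = FALSE, sep = ",")
  invisible(path)
}

#' @rdname write_image_csv
#' @export
read_image_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  ps <- NULL
  for (l in lines[hdr]) {
    m <- regmatches(l, regexec("pixel_size_um:\\s*([0-9.eE+-]+)", l))[[1]]
    if (length(m) == 2) ps <- as.numeric(m[2])
  }
  m <- as.matrix(utils::read.table(
    text = paste(lines[setdiff(seq_along(lines), hdr)], collapse = "\n"),
    sep = ","))
  dimnames(m) <- NULL
  attr(m, "pixel_size_um") <- ps
  m
}

#' Write a JSON result file with provenance
#'
#' @param x result list (coerced via unclass).
#' @param path file path.
#' @param seed seed used, if any.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path, seed = NULL) {
  payload <- list(
    result = strip_classes(x),
    provenance = list(
      package = "regenquant",
      version = as.character(utils::packageVersion("regenquant")),
      seed = seed,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

strip_classes <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    oldClass(x) <- NULL
    lapply(x, strip_classes)
  } else {
    if (!is.data.frame(x)) oldClass(x) <- NULL
    x
  }
}
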