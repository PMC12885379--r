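#' Glial migration metrics from object tracks
#'
#' After central-axon axotomy, satellite glia around the DRG re-organize
#' dorsally ahead of the regrowing axon. These metrics operate on manually
#' clicked x,y tracks (MTrackJ-style exports): per-frame dorsal offsets of
#' the growth cone and dorsal-most glial nucleus relative to the DRG
#' dorsal border over the 140 analyzed timepoints, total t0-to-t140
#' nucleus migration, and DRG-to-nucleus displacement components for
#' fixed-tissue target plots. The coordinate convention is +y = dorsal,
#' units um.
#'
#' @name regenquant-glia
NULL

#' Object track container
#'
#' @param object_id identifier.
#' @param role one of "growth_cone", "glial_nucleus", "drg_dorsal_border",
#'   "head", "centroid".
#' @param frames strictly increasing 1-based frame indices.
#' @param x,y coordinates, um (+y dorsal).
#' @return data.frame of class `object_track` with columns `object_id`,
#'   `role`, `frame`, `x_um`, `y_um`.
#' @export
object_track <- function(object_id, role, frames, x, y) {
  roles <- c("growth_cone", "glial_nucleus", "drg_dorsal_border", "head",
             "centroid")
  stopifnot(role %in% roles, length(frames) == length(x),
            length(x) == length(y), all(diff(frames) > 0),
            all(is.finite(x)), all(is.finite(y)))
  structure(data.frame(object_id = object_id, role = role,
                       frame = as.integer(frames), x_um = as.numeric(x),
                       y_um = as.numeric(y), stringsAsFactors = FALSE),
            class = c("object_track", "data.frame"))
}

track_at <- function(track, frames) {
  i <- match(frames, track$frame)
  if (anyNA(i)) {
    stop(sprintf("track '%s' missing frames: %s", track$object_id[1],
                 paste(frames[is.na(i)], collapse = ", ")))
  }
  track[i, , drop = FALSE]
}

#' Per-frame dorsal offsets relative to a reference track
#'
#' `dy(f) = y_object(f) - y_reference(f)` over the analysis window
#' (positive = dorsal of the DRG border), the quantity compiled over the
#' 140 analyzed timepoints after regenerative extension begins.
#'
#' @param object,reference [object_track()]s; the reference is typically
#'   the DRG dorsal border.
#' @param start_frame first analyzed frame (extension onset; always
#'   supplied, never inferred).
#' @param n_timepoints window length in frames (140 in the study).
#' @return list of class `migration_summary`: `offsets_um` (per-frame),
#'   `mean_dorsal_offset_um`, `frames`.
#' @export
dorsal_offsets <- function(object, reference, start_frame,
                           n_timepoints = 140L) {
  stopifnot(inherits(object, "object_track"),
            inherits(reference, "object_track"), n_timepoints >= 1)
  frames <- seq.int(start_frame, start_frame + n_timepoints - 1)
  ob <- track_at(object, frames)
  re <- track_at(reference, frames)
  dy <- ob$y_um - re$y_um
  structure(list(frames = frames, offsets_um = dy,
                 mean_dorsal_offset_um = mean(dy),
                 n_timepoints = as.integer(n_timepoints)),
            class = "migration_summary")
}

#' Select the dorsal-most glial nucleus at a frame
#'
#' The nucleus with maximal dorsal offset from the reference at the given
#' frame (typically the window's first frame, after which the identity is
#' held fixed); ties break toward the smaller object id.
#'
#' @param nuclei list of nucleus [object_track()]s (>= 1).
#' @param reference DRG dorsal border track.
#' @param frame frame index at which to evaluate.
#' @return the winning `object_id`.
#' @export
select_dorsal_most <- function(nuclei, reference, frame) {
  if (length(nuclei) == 0) stop("no nucleus tracks supplied")
  ref_y <- track_at(reference, frame)$y_um
  dys <- vapply(nuclei, function(tr) track_at(tr, frame)$y_um - ref_y, 0)
  ids <- vapply(nuclei, function(tr) tr$object_id[1], "")
  best <- which(dys == max(dys))
  ids[best[order(ids[best])[1]]]
}

#' Total migration between two frames
#'
#' Displacement of a track between t0 and t140 (frame indices, not
#' durations). Both the Euclidean norm and the raw (dx, dy) components are
#' returned, since the original subtraction of x,y pairs does not pin a
#' norm and the dorsal component is of independent interest.
#'
#' @param track an [object_track()].
#' @param t0,t140 the two frame indices.
#' @return list with `distance_um`, `dx_um`, `dy_um`.
#' @export
total_migration <- function(track, t0, t140) {
  a <- track_at(track, t0)
  b <- track_at(track, t140)
  dx <- b$x_um - a$x_um
  dy <- b$y_um - a$y_um
  list(distance_um = sqrt(dx^2 + dy^2), dx_um = dx, dy_um = dy)
}

#' Displacements of nuclei from the DRG dorsal border (target plot data)
#'
#' Per-nucleus displacement components and Euclidean distance from the
#' border point, suitable for target plots with 5-um rings.
#'
#' @param nuclei_xy data.frame or matrix with columns x, y (um), one row
#'   per nucleus.
#' @param drg_border_xy length-2 numeric, the border point (um).
#' @return data.frame with `dx_um`, `dy_um`, `r_um`.
#' @export
target_distances <- function(nuclei_xy, drg_border_xy) {
  m <- as.matrix(nuclei_xy)
  if (nrow(m) == 0) stop("no nuclei supplied")
  stopifnot(ncol(m) == 2, length(drg_border_xy) == 2)
  dx <- m[, 1] - drg_border_xy[1]
  dy <- m[, 2] - drg_border_xy[2]
  data.frame(dx_um = dx, dy_um = dy, r_um = sqrt(dx^2 + dy^2))
}
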