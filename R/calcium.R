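#' Stimulus-locked GCaMP6s synchrony scoring
#'
#' The evoked calcium assay images a DRG and 30 spinal neuron somas for 24
#' frames at 5-s intervals; room-temperature water is added just before
#' frame 8 and cold (4 C) water just before frame 16. Each cell's trace is
#' z-scored against its own mean and sample standard deviation over the
#' timelapse; z >= 2.0 is a neuronal activation event. Cells are
#' `rapid_synchronous` when active in the first cold-water capture (frame
#' 16), `delayed` when first active at frame 17 or later, and `none`
#' otherwise. An animal is included only if at least one DRG neuron
#' activated rapidly at the cold frame.
#'
#' @name regenquant-calcium
NULL

#' Calcium recording container
#'
#' @param matrix cell x frame matrix of ROI integrated densities, with
#'   rownames as cell ids.
#' @param roles per-cell role, "drg" or "spinal".
#' @param rt_frame,cold_frame 1-based frames of the room-temperature and
#'   cold water additions (8 and 16 in the assay).
#' @param interval_seconds frame interval (5 s).
#' @return list of class `calcium_recording`.
#' @export
calcium_recording <- function(matrix, roles, rt_frame = 8L,
                              cold_frame = 16L, interval_seconds = 5) {
  stopifnot(is.matrix(matrix), nrow(matrix) == length(roles),
            all(roles %in% c("drg", "spinal")),
            rt_frame < cold_frame, cold_frame <= ncol(matrix))
  if (is.null(rownames(matrix))) {
    rownames(matrix) <- sprintf("cell%03d", seq_len(nrow(matrix)))
  }
  structure(list(matrix = matrix, roles = roles,
                 cell_ids = rownames(matrix),
                 n_frames = ncol(matrix),
                 rt_frame = as.integer(rt_frame),
                 cold_frame = as.integer(cold_frame),
                 interval_seconds = interval_seconds),
            class = "calcium_recording")
}

#' z-score every cell's trace
#'
#' `z(c, f) = (F(c, f) - mean_c) / sd_c` with the mean and sample (n-1)
#' standard deviation taken over the cell's frames — by default the full
#' timelapse (the described spreadsheet workflow), optionally the
#' pre-stimulus frames only. A zero-variance cell cannot be z-scored; its
#' row is NA and it is flagged unanalyzable.
#'
#' @param recording a [calcium_recording()].
#' @param baseline "full" (all frames) or "pre_stimulus" (frames before
#'   `rt_frame`).
#' @return matrix of z-scores with attribute `unanalyzable` (logical
#'   per-cell vector) and `baseline`.
#' @export
zscore_cells <- function(recording, baseline = c("full", "pre_stimulus")) {
  stopifnot(inherits(recording, "calcium_recording"))
  baseline <- match.arg(baseline)
  m <- recording$matrix
  cols <- if (baseline == "full") seq_len(ncol(m)) else
    seq_len(recording$rt_frame - 1)
  mu <- rowMeans(m[, cols, drop = FALSE])
  sd <- apply(m[, cols, drop = FALSE], 1, stats::sd)
  bad <- sd == 0 | !is.finite(sd)
  if (any(bad)) {
    warning(sprintf("%d cell(s) with zero variance flagged unanalyzable",
                    sum(bad)))
  }
  z <- (m - mu) / ifelse(bad, NA_real_, sd)
  attr(z, "unanalyzable") <- bad
  attr(z, "baseline") <- baseline
  z
}

#' Classify one cell's activation category
#'
#' Category per the schedule: `rapid_synchronous` iff z >= threshold at
#' the cold frame (inclusive, "2.0 or more"); else `delayed` iff the first
#' crossing at or after the cold frame is at cold_frame + 1 or later; else
#' `none`. Crossings before the cold frame do not drive the category but
#' the earliest one is logged (`rt_responder` flag / `pre_cold_crossing`),
#' since the original three categories do not cover cells active only in
#' the room-temperature window.
#'
#' @param zrow one cell's z-score series.
#' @param cold_frame cold-water frame index.
#' @param threshold activation threshold (2.0).
#' @return list of class `activation_call`: `category`,
#'   `first_active_frame` (first crossing at/after cold frame, NA if
#'   none), `z_at_cold_frame`, `pre_cold_crossing`, `rt_responder`.
#' @export
classify_cell <- function(zrow, cold_frame, threshold = 2.0) {
  stopifnot(length(zrow) >= cold_frame)
  if (anyNA(zrow)) {
    return(structure(list(category = "unanalyzable",
                          first_active_frame = NA_integer_,
                          z_at_cold_frame = NA_real_,
                          pre_cold_crossing = NA_integer_,
                          rt_responder = FALSE),
                     class = "activation_call"))
  }
  crossings <- which(zrow >= threshold)
  pre <- crossings[crossings < cold_frame]
  post <- crossings[crossings >= cold_frame]
  category <- if (zrow[cold_frame] >= threshold) {
    "rapid_synchronous"
  } else if (length(post)) {
    "delayed"
  } else {
    "none"
  }
  structure(list(category = category,
                 first_active_frame = if (length(post)) post[1] else NA_integer_,
                 z_at_cold_frame = zrow[cold_frame],
                 pre_cold_crossing = if (length(pre)) pre[1] else NA_integer_,
                 rt_responder = length(pre) > 0 && category == "none"),
            class = "activation_call")
}

#' Score a whole recording
#'
#' @param recording a [calcium_recording()].
#' @param threshold activation threshold.
#' @param baseline passed to [zscore_cells()].
#' @return data.frame of per-cell calls (`cell_id`, `role`, `category`,
#'   `first_active_frame`, `z_at_cold_frame`, `rt_responder`).
#' @export
score_cells <- function(recording, threshold = 2.0,
                        baseline = c("full", "pre_stimulus")) {
  z <- zscore_cells(recording, baseline = match.arg(baseline))
  calls <- lapply(seq_len(nrow(z)), function(i) {
    classify_cell(z[i, ], recording$cold_frame, threshold)
  })
  data.frame(
    cell_id = recording$cell_ids,
    role = recording$roles,
    category = vapply(calls, `[[`, "", "category"),
    first_active_frame = vapply(calls, `[[`, 1L, "first_active_frame"),
    z_at_cold_frame = vapply(calls, `[[`, 0, "z_at_cold_frame"),
    rt_responder = vapply(calls, `[[`, TRUE, "rt_responder"),
    stringsAsFactors = FALSE
  )
}

#' Per-animal synchrony summary
#'
#' Percentages of analyzable spinal cells in each category, plus the
#' inclusion flag: the animal is included iff at least one DRG neuron was
#' rapidly active in the first cold-water capture.
#'
#' @param recording a [calcium_recording()].
#' @param animal_id label carried into the summary.
#' @param threshold,baseline scoring options.
#' @return list of class `synchrony_summary` with `pct_spinal_rapid`,
#'   `pct_spinal_delayed`, `pct_spinal_none`, `drg_rapid_count`,
#'   `included`, `n_spinal_analyzable`, and the per-cell `calls` table.
#' @export
summarize_animal <- function(recording, animal_id = "animal", threshold = 2.0,
                             baseline = c("full", "pre_stimulus")) {
  calls <- score_cells(recording, threshold, baseline)
  sp <- calls[calls$role == "spinal" & calls$category != "unanalyzable", ]
  if (nrow(sp) == 0) stop("no analyzable spinal cells")
  drg <- calls[calls$role == "drg", ]
  n <- nrow(sp)
  structure(list(
    animal_id = animal_id,
    pct_spinal_rapid = 100 * sum(sp$category == "rapid_synchronous") / n,
    pct_spinal_delayed = 100 * sum(sp$category == "delayed") / n,
    pct_spinal_none = 100 * sum(sp$category == "none") / n,
    drg_rapid_count = sum(drg$category == "rapid_synchronous"),
    included = sum(drg$category == "rapid_synchronous") >= 1,
    n_spinal_analyzable = n,
    calls = calls
  ), class = "synchrony_summary")
}

#' Compare spinal responder proportions between groups
#'
#' Pools rapid and delayed spinal-cell counts per group and runs pairwise
#' two-sided Fisher's exact tests on the rapid-vs-delayed tables.
#'
#' @param summaries_by_group named list of lists of `synchrony_summary`s.
#' @return data.frame of pairwise comparisons with pooled counts and
#'   p-values.
#' @export
compare_groups <- function(summaries_by_group) {
  stopifnot(is.list(summaries_by_group), length(summaries_by_group) >= 2)
  if (any(lengths(summaries_by_group) == 0)) stop("empty group")
  pool <- lapply(summaries_by_group, function(gr) {
    calls <- do.call(rbind, lapply(gr, function(s)
      s$calls[s$calls$role == "spinal", ]))
    c(rapid = sum(calls$category == "rapid_synchronous"),
      delayed = sum(calls$category == "delayed"))
  })
  labs <- names(summaries_by_group)
  if (is.null(labs)) labs <- paste0("group", seq_along(pool))
  out <- NULL
  for (i in seq_len(length(pool) - 1)) {
    for (j in seq.int(i + 1, length(pool))) {
      tab <- rbind(pool[[i]], pool[[j]])
      tr <- fisher_exact(tab)
      out <- rbind(out, data.frame(
        group1 = labs[i], group2 = labs[j],
        rapid1 = tab[1, 1], delayed1 = tab[1, 2],
        rapid2 = tab[2, 1], delayed2 = tab[2, 2],
        p_value = tr$p_value, stringsAsFactors = FALSE))
    }
  }
  out
}
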