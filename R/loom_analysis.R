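#' Build a looming-stimulus schedule
#'
#' Looms of the requested final sizes are presented 10 mm left or right of
#' the animal once per minute in random order; each expands linearly from 0
#' to its final diameter over 500 ms (15 frames at 30 fps). A moving
#' grating (20 s, ending 10 s before the next loom) re-centers the animal
#' between events. The default single-repetition session over six sizes and
#' both sides lasts 12 min; a 1 h session accommodates five repetitions.
#'
#' @param final_sizes Final dot diameters, mm, each in `[0, 12]`.
#' @param reps Repetitions of every size-by-side combination.
#' @param seed Integer seed for the presentation order.
#' @param inter_event Seconds between loom onsets (default 60).
#' @param offset_mm Lateral placement of the dot, mm (default 10).
#' @return list of class `loom_schedule`: `events` data.frame (`t_onset`,
#'   `side`, `final_diam`, `offset_mm`, `expand_s`, `expand_frames`),
#'   `inter_event`, `grating = c(duration = 20, gap = 10)`.
#' @export
build_schedule <- function(final_sizes = c(0, 2, 4, 6, 8, 12), reps = 1,
                           seed = 1, inter_event = 60, offset_mm = 10) {
  if (any(final_sizes < 0 | final_sizes > 12)) {
    stop_zfsocial("parameter_error", "loom final sizes must lie in [0, 12] mm")
  }
  stopifnot(reps >= 0, inter_event > 0)
  grid <- expand.grid(final_diam = final_sizes, side = c("left", "right"),
                      rep = seq_len(max(reps, 1L)),
                      stringsAsFactors = FALSE)[, 1:2]
  if (reps == 0) grid <- grid[0, , drop = FALSE]
  n <- nrow(grid)
  ord <- if (n) withr::with_seed(seed, sample.int(n)) else integer(0)
  events <- grid[ord, , drop = FALSE]
  events$t_onset <- seq_len(n) * inter_event
  events$offset_mm <- rep(offset_mm, n)
  events$expand_s <- rep(0.5, n)
  events$expand_frames <- rep(15L, n)
  rownames(events) <- NULL
  structure(list(events = events[, c("t_onset", "side", "final_diam",
                                     "offset_mm", "expand_s", "expand_frames")],
                 inter_event = inter_event,
                 grating = c(duration = 20, gap = 10)),
            class = "loom_schedule")
}

#' Detect an escape response to one loom
#'
#' An escape is scored when the peak inter-frame speed within
#' `[t_onset, t_onset + window]` exceeds `speed_thresh`. Latency is the time
#' from onset to the first threshold crossing; `direction_away` reports
#' whether the net lateral displacement over the window points away from
#' the loom side. Events with no tracked frames in the window are marked
#' unscorable.
#'
#' @param table Session [trajectory_table()].
#' @param event One row of a schedule's `events`.
#' @param window Scoring window from onset, s (>= the 0.5 s expansion).
#' @param speed_thresh Speed threshold, mm/s; default 5x the session median
#'   moving-frame speed (adaptive per animal).
#' @return One-row data.frame: `escaped`, `latency`, `direction_away`,
#'   `unscorable`, `peak_speed`, `speed_thresh`.
#' @export
detect_escape <- function(table, event, window = 1.0, speed_thresh = NULL) {
  stopifnot(window >= event$expand_s)
  fps <- tt_fps(table)
  if (is.null(speed_thresh)) speed_thresh <- adaptive_speed_threshold(table)
  speed <- c(sqrt(diff(table$x)^2 + diff(table$y)^2) * fps, NA)
  sel <- which(table$t >= event$t_onset & table$t <= event$t_onset + window)
  sel <- sel[!is.na(speed[sel])]
  if (!length(sel)) {
    return(data.frame(escaped = NA, latency = NA_real_,
                      direction_away = NA, unscorable = TRUE,
                      peak_speed = NA_real_, speed_thresh = speed_thresh))
  }
  peak <- max(speed[sel])
  escaped <- peak >= speed_thresh
  latency <- if (escaped) {
    table$t[sel[which(speed[sel] >= speed_thresh)[1]]] - event$t_onset
  } else NA_real_
  dx <- table$x[sel[length(sel)]] - table$x[sel[1]]
  direction_away <- if (escaped) {
    if (event$side == "left") dx > 0 else dx < 0
  } else NA
  data.frame(escaped = escaped, latency = latency,
             direction_away = direction_away, unscorable = FALSE,
             peak_speed = peak, speed_thresh = speed_thresh)
}

# 5x the median per-frame speed over moving frames; robust to the dwell
# frames between bouts, which would otherwise drag the median to zero
adaptive_speed_threshold <- function(table, factor = 5) {
  speed <- sqrt(diff(table$x)^2 + diff(table$y)^2) * tt_fps(table)
  moving <- speed[!is.na(speed) & speed > 0]
  if (!length(moving)) {
    stop_zfsocial("empty_series", "no moving frames; cannot set threshold")
  }
  factor * stats::median(moving)
}

#' Score every loom in a session
#'
#' @param table Session [trajectory_table()].
#' @param schedule The session's [build_schedule()] (optionally with planted
#'   ground truth from [simulate_loom_session()]).
#' @param window,speed_thresh Passed to [detect_escape()].
#' @return `schedule$events` with the detector columns appended.
#' @export
score_looms <- function(table, schedule, window = 1.0, speed_thresh = NULL) {
  stopifnot(inherits(schedule, "loom_schedule"))
  if (is.null(speed_thresh)) speed_thresh <- adaptive_speed_threshold(table)
  res <- do.call(rbind, lapply(seq_len(nrow(schedule$events)), function(i) {
    detect_escape(table, schedule$events[i, ], window, speed_thresh)
  }))
  cbind(schedule$events, res)
}

#' Escape fraction per loom final size
#'
#' @param events Scored events from [score_looms()].
#' @param conf Confidence level of the per-size binomial interval.
#' @return data.frame per `final_diam`: `n`, `n_escaped`, `fraction`,
#'   `ci_lo`, `ci_hi` (exact binomial). Unscorable events are excluded from
#'   the denominators.
#' @export
response_curve <- function(events, conf = 0.95) {
  ok <- events[!events$unscorable, , drop = FALSE]
  out <- do.call(rbind, lapply(split(ok, ok$final_diam), function(g) {
    n <- nrow(g); k <- sum(g$escaped)
    ci <- stats::binom.test(k, n, conf.level = conf)$conf.int
    data.frame(final_diam = g$final_diam[1], n = n, n_escaped = k,
               fraction = k / n, ci_lo = ci[1], ci_hi = ci[2])
  }))
  rownames(out) <- NULL
  out[order(out$final_diam), ]
}
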