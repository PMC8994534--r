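#' Heading from frame-to-frame displacement
#'
#' Frame records carry centroids only, so heading is estimated as the angle
#' of the displacement vector between consecutive frames, attributed to the
#' interval start. Displacements below `min_step` carry no orientation
#' information and yield `NaN`.
#'
#' @param table A [trajectory_table()].
#' @param min_step Minimum displacement, mm; defaults to body length / 10
#'   (or 0.5 mm when the body length is unknown).
#' @return Numeric vector of headings (radians), `NaN` where undefined;
#'   the last frame is always `NaN`.
#' @export
heading_series <- function(table, min_step = NULL) {
  if (is.null(min_step)) {
    bl <- tt_body_length(table)
    min_step <- if (is.na(bl)) 0.5 else bl / 10
  }
  stopifnot(min_step >= 0)
  n <- nrow(table)
  dx <- diff(table$x)
  dy <- diff(table$y)
  h <- atan2(dy, dx)
  h[sqrt(dx^2 + dy^2) < min_step] <- NaN
  c(h, NaN)
}

# acute angle (radians, [0, pi/2]) between a heading and the divider line,
# plus whether the heading points toward the divider
divider_angle <- function(heading, arena) {
  # divider lies along the x axis (y = divider_at); toward-divider is the
  # sign of the y heading component pointing at that wall
  toward_sign <- if (arena$divider_at == 0) -1 else 1
  a <- abs(wrap_angle(heading))      # angle to +x axis, [0, pi]
  acute <- pmin(a, pi - a)
  list(angle = acute, toward = sign(sin(heading)) == toward_sign)
}

#' Percentage of time orienting to the divider
#'
#' Orienting — heading at 45–90 degrees to the divider while facing the
#' conspecific — is a hallmark of larval social engagement. The orienting
#' angle is the acute angle between the displacement heading and the divider
#' line; by default only headings with a positive component toward the
#' divider qualify (a larva facing directly away from its partner is not
#' orienting, even at 90 degrees to the wall). The denominator is all frames
#' with a defined heading.
#'
#' @param table A [trajectory_table()] in a [rect_arena()].
#' @param band Inclusive angular band in degrees (default `c(45, 90)`).
#' @param min_step Passed to [heading_series()].
#' @param require_toward Require the toward-divider heading component.
#' @return Percentage in `[0, 100]`.
#' @export
pct_time_orienting <- function(table, band = c(45, 90), min_step = NULL,
                               require_toward = TRUE) {
  arena <- tt_arena(table)
  if (is.null(arena) || !is_rect(arena)) {
    stop_zfsocial("geometry_error", "orienting requires a rectangular arena")
  }
  h <- heading_series(table, min_step)
  ok <- !is.na(h)
  if (!any(ok)) stop_zfsocial("empty_series", "no defined-heading frames")
  da <- divider_angle(h[ok], arena)
  deg <- da$angle * 180 / pi
  # inclusive band bounds, robust to radian->degree rounding
  hit <- deg >= band[1] - 1e-9 & deg <= band[2] + 1e-9
  if (require_toward) hit <- hit & da$toward
  100 * sum(hit) / sum(ok)
}

#' Relative place preference toward the divider
#'
#' Mean over frames of the relative proximity to the divider, measured from
#' the wall opposite the divider and normalized to the tank length: 1 = at
#' the divider, 0 = at the far wall, 0.5 = uniform occupancy.
#'
#' @param table A [trajectory_table()] in a [rect_arena()].
#' @return Dimensionless value in `[0, 1]`.
#' @export
place_preference <- function(table) {
  arena <- tt_arena(table)
  if (is.null(arena) || !is_rect(arena)) {
    stop_zfsocial("geometry_error", "place preference requires a rectangular arena")
  }
  y <- table$y[!is.na(table$y)]
  prox <- if (arena$divider_at == 0) (arena$length - y) / arena$length else
    y / arena$length
  mean(prox)
}

#' Percentage of time in motion
#'
#' A frame counts as motion when the animal moved at least one-third of its
#' body length since the previous frame (inclusive threshold). Animals that
#' spend less than 10% of the experiment in motion are excluded from group
#' comparisons by [apply_exclusion()].
#'
#' @param table A [trajectory_table()] with a known body length.
#' @return Percentage in `[0, 100]`.
#' @export
pct_time_in_motion <- function(table) {
  bl <- tt_body_length(table)
  if (is.na(bl)) {
    stop_zfsocial("config_error", "pct_time_in_motion needs body_length")
  }
  step <- sqrt(diff(table$x)^2 + diff(table$y)^2)
  step <- step[!is.na(step)]
  if (!length(step)) return(0)
  100 * sum(step >= bl / 3) / length(step)
}

#' Score one dyad animal over both phases
#'
#' Convenience wrapper producing one `DyadScore` row per phase.
#'
#' @param table A dyad trajectory table.
#' @param t_split Divider-removal time, s.
#' @param partner_genotype Genotype label of the stimulus fish.
#' @return data.frame with columns `animal_id`, `phase`, `pct_orienting`,
#'   `place_pref`, `pct_motion`, `excluded`, `partner_genotype`.
#' @export
score_dyad <- function(table, t_split, partner_genotype = NA_character_) {
  phases <- split_phases(table, t_split)
  pct_motion <- pct_time_in_motion(table)   # over the whole experiment
  out <- do.call(rbind, lapply(names(phases), function(ph) {
    tab <- phases[[ph]]
    data.frame(animal_id = attr(table, "animal_id"),
               phase = if (ph == "presocial") "presocial" else "social",
               pct_orienting = pct_time_orienting(tab),
               place_pref = place_preference(tab),
               pct_motion = pct_motion, excluded = FALSE,
               partner_genotype = partner_genotype)
  }))
  rownames(out) <- NULL
  out
}

#' Exclude low-motion animals
#'
#' Animals that spent less than 10% of the experiment in motion (strictly
#' `pct_motion < threshold`) are marked excluded and removed.
#'
#' @param scores data.frame of dyad scores (one or more rows per animal).
#' @param threshold Exclusion threshold, percent (default 10).
#' @return The retained rows; all rows, with the `excluded` flag set, in
#'   attribute `all_scores`.
#' @export
apply_exclusion <- function(scores, threshold = 10) {
  scores$excluded <- scores$pct_motion < threshold
  out <- scores[!scores$excluded, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_scores") <- scores
  out
}

#' Regroup focal animals by stimulus-fish genotype
#'
#' For the pooled analysis, wt and het focal animals are re-labeled by the
#' genotype of the respective stimulus fish (their dyad partner), which
#' becomes the classifier.
#'
#' @param scores Dyad scores with `animal_id`.
#' @param pairs data.frame (`focal_id`, `partner_id`, `partner_genotype`).
#' @return `scores` with columns `partner_genotype` and `stimulus_group`
#'   (`"<genotype>-stimulus"`); animals with no pairing entry are labeled
#'   `"unknown"` and flagged in `pairing_unknown`.
#' @export
regroup_by_stimulus <- function(scores, pairs) {
  stopifnot(all(c("focal_id", "partner_id", "partner_genotype") %in%
                  names(pairs)))
  if (any(pairs$focal_id == pairs$partner_id)) {
    stop_zfsocial("pairing_error", "self-pairing in pairing table: ",
                  pairs$focal_id[pairs$focal_id == pairs$partner_id][1])
  }
  m <- match(scores$animal_id, pairs$focal_id)
  scores$partner_genotype <- pairs$partner_genotype[m]
  scores$pairing_unknown <- is.na(m)
  scores$partner_genotype[is.na(m)] <- "unknown"
  scores$stimulus_group <- paste0(scores$partner_genotype, "-stimulus")
  scores
}
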