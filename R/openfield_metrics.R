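#' Average swimming speed
#'
#' Total path length divided by total tracked duration. Segments with an
#' untracked endpoint are excluded from the numerator and their time from
#' the denominator, so tracking gaps do not dilute the estimate. Reported
#' in input position units per second (mm/s for calibrated tables).
#'
#' @param table A [trajectory_table()].
#' @return Speed (position units per second).
#' @export
average_speed <- function(table) {
  if (nrow(table) < 2) {
    stop_zfsocial("insufficient_length", "average_speed needs >= 2 frames")
  }
  seg <- sqrt(diff(table$x)^2 + diff(table$y)^2)
  dt <- diff(table$t)
  ok <- !is.na(seg)
  if (!any(ok)) stop_zfsocial("empty_series", "no tracked segments")
  sum(seg[ok]) / sum(dt[ok])
}

#' Thigmotaxis index
#'
#' Wall-hugging tendency in a circular open arena. The default
#' operationalization is outer-third occupancy: the fraction of tracked
#' frames at radial distance `r > (2/3) R`; under uniform occupancy of the
#' disc this equals `1 - (2/3)^2 = 5/9`. The alternative `"mean_r"` reports
#' the mean normalized radius `r/R` instead. The definition used is attached
#' as an attribute for auditability.
#'
#' @param table A [trajectory_table()] in a [circle_arena()].
#' @param method `"outer_third"` (default) or `"mean_r"`.
#' @return Value in `[0, 1]` with attribute `definition`.
#' @export
thigmotaxis_index <- function(table, method = c("outer_third", "mean_r")) {
  method <- match.arg(method)
  arena <- tt_arena(table)
  if (is.null(arena) || !is_circle(arena)) {
    stop_zfsocial("geometry_error", "thigmotaxis requires a circular arena")
  }
  ok <- !is.na(table$x) & !is.na(table$y)
  r <- sqrt((table$x[ok] - arena$center[1])^2 +
            (table$y[ok] - arena$center[2])^2)
  val <- if (method == "outer_third") mean(r > (2 / 3) * arena$radius) else
    mean(r / arena$radius)
  structure(val, definition = method)
}

#' Classify stunted animals in a body-length cohort
#'
#' An animal is stunted when its length (nose to end of trunk) is strictly
#' below a threshold of 1.5 sample standard deviations below the mean
#' wild-type length. The threshold is estimated from the wt stratum only
#' (sample SD, `ddof = 1`) and applied to every animal.
#'
#' @param cohort data.frame with `genotype` and `length_mm` (and optionally
#'   `animal_id`), e.g. from [generate_length_cohort()].
#' @param wt_label Genotype label of the wild-type stratum.
#' @param n_sd Number of SDs below the wt mean (default 1.5).
#' @return `cohort` with a logical `stunted` column; attributes `wt_mean`,
#'   `wt_sd`, `threshold`.
#' @export
classify_stunted <- function(cohort, wt_label = "wt", n_sd = 1.5) {
  stopifnot(all(c("genotype", "length_mm") %in% names(cohort)))
  wt <- cohort$length_mm[cohort$genotype == wt_label]
  if (length(wt) < 2) {
    stop_zfsocial("insufficient_data",
                  "need >= 2 wild-type animals to estimate the SD, got ",
                  length(wt))
  }
  wt_mean <- mean(wt)
  wt_sd <- stats::sd(wt)
  threshold <- wt_mean - n_sd * wt_sd
  cohort$stunted <- cohort$length_mm < threshold
  structure(cohort, wt_mean = wt_mean, wt_sd = wt_sd, threshold = threshold)
}
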