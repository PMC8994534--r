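FRAME_COLS <- c("t", "x", "y", "heading", "stim_x", "stim_y", "stim_diam",
                "epoch_id")

#' Construct a trajectory table
#'
#' The universal currency of the package: one row per video frame, carrying
#' the animal centroid, an optional heading, and the state of the projected
#' stimulus. Timestamps are interval starts; a per-frame quantity is
#' attributed to `[t, t + 1/fps)`.
#'
#' @param frames data.frame with columns `t` (s from session start), `x`, `y`
#'   (animal centroid, mm; `NaN` when the animal was not tracked), `heading`
#'   (radians, `NaN` when unknown), `stim_x`, `stim_y` (stimulus center, mm,
#'   `NaN` when no stimulus is shown), `stim_diam` (mm, 0 when no stimulus),
#'   `epoch_id` (integer label of the stimulus epoch, -1 between epochs).
#'   Missing optional columns are added.
#' @param fps Nominal frame rate, Hz. The median inter-frame interval must be
#'   within 10% of `1/fps`.
#' @param animal_id Identifier string.
#' @param body_length Animal body length in mm (nose to end of trunk), or
#'   `NA` when unmeasured. Required by motion-fraction metrics.
#' @param genotype Optional label (e.g. `"wt"`, `"het"`, `"mut"`).
#' @param arena An [circle_arena()] or [rect_arena()].
#' @return data.frame of class `trajectory_table` with metadata attributes
#'   `fps`, `animal_id`, `body_length`, `genotype`, `arena`.
#' @export
trajectory_table <- function(frames, fps, animal_id = "animal",
                             body_length = NA_real_, genotype = NA_character_,
                             arena = NULL) {
  stopifnot(is.data.frame(frames), is.numeric(fps), fps > 0)
  for (col in setdiff(FRAME_COLS, names(frames))) {
    fill <- if (col == "stim_diam") 0 else if (col == "epoch_id") -1L else NaN
    frames[[col]] <- rep(fill, nrow(frames))
  }
  missing_cols <- setdiff(c("t", "x", "y"), names(frames))
  if (length(missing_cols)) {
    stop_zfsocial("format_error", "missing mandatory column(s): ",
                  paste(missing_cols, collapse = ", "))
  }
  frames <- frames[FRAME_COLS]
  n <- nrow(frames)
  if (n > 1) {
    dt <- diff(frames$t)
    bad <- which(dt <= 0)
    if (length(bad)) {
      stop_zfsocial("validation_error", "time not strictly increasing at row ",
                    bad[1] + 1L, " (t = ", frames$t[bad[1] + 1L], ")")
    }
    med_dt <- stats::median(dt)
    if (abs(med_dt - 1 / fps) > 0.1 / fps) {
      stop_zfsocial("validation_error", sprintf(
        "median inter-frame interval %.4g s inconsistent with fps = %g", med_dt, fps))
    }
  }
  frames$stim_diam[is.na(frames$stim_diam)] <- 0
  if (any(frames$stim_diam < 0)) {
    stop_zfsocial("validation_error", "negative stim_diam")
  }
  if (!is.na(body_length) && body_length <= 0) {
    stop_zfsocial("validation_error", "body_length must be > 0")
  }
  frames$epoch_id <- as.integer(frames$epoch_id)
  structure(frames,
            fps = fps, animal_id = animal_id, body_length = body_length,
            genotype = genotype, arena = arena,
            class = c("trajectory_table", "data.frame"))
}

#' @export
print.trajectory_table <- function(x, ...) {
  cat(sprintf("<trajectory_table> %s: %d frames @ %g fps (%.1f s)\n",
              attr(x, "animal_id"), nrow(x), attr(x, "fps"),
              if (nrow(x)) diff(range(x$t)) else 0))
  if (!is.null(attr(x, "arena"))) print(attr(x, "arena"))
  invisible(x)
}

tt_fps <- function(table) attr(table, "fps")
tt_arena <- function(table) attr(table, "arena")
tt_body_length <- function(table) attr(table, "body_length")

#' Read and write per-frame trajectory streams
#'
#' Frame streams are plain CSV with header
#' `t,x,y,heading,stim_x,stim_y,stim_diam,epoch_id` and `NaN` spelled `nan`.
#' Session metadata (animal id, fps, body length, genotype, arena) lives in a
#' JSON sidecar next to the CSV (`<path>.json`). Floats are written at full
#' precision (17 significant digits) so that `read_frames(write_frames(x))`
#' reproduces every field bit-for-bit.
#'
#' @param path CSV file path.
#' @param fps Frame rate in Hz; defaults to the sidecar value when present.
#' @param arena Arena geometry; defaults to the sidecar value.
#' @param px_per_mm Optional calibration: when given, `x`, `y`, `stim_x`,
#'   `stim_y`, `stim_diam` in the file are interpreted as pixels and divided
#'   by this factor on read. Published thresholds are metric, so all internal
#'   computation is in mm.
#' @param sidecar Logical; write/read the JSON metadata sidecar.
#' @return `read_frames` returns a [trajectory_table()]; `write_frames`
#'   invisibly returns `path`.
#' @export
read_frames <- function(path, fps = NULL, arena = NULL, px_per_mm = NULL,
                        sidecar = TRUE) {
  if (!file.exists(path)) stop_zfsocial("io_error", "no such file: ", path)
  meta <- NULL
  sidecar_path <- paste0(path, ".json")
  if (sidecar && file.exists(sidecar_path)) {
    meta <- jsonlite::fromJSON(sidecar_path, simplifyVector = TRUE)
  }
  if (is.null(fps)) fps <- meta$fps
  if (is.null(fps)) stop_zfsocial("format_error", "fps not given and no sidecar")
  if (is.null(arena) && !is.null(meta$arena)) arena <- arena_from_list(meta$arena)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("t", "x", "y"), names(df))
  if (length(missing_cols)) {
    stop_zfsocial("format_error", "missing mandatory column(s): ",
                  paste(missing_cols, collapse = ", "))
  }
  num_cols <- intersect(FRAME_COLS, names(df))
  for (col in num_cols) df[[col]] <- as.numeric(df[[col]])
  if (!is.null(px_per_mm)) {
    for (col in c("x", "y", "stim_x", "stim_y", "stim_diam")) {
      if (col %in% names(df)) df[[col]] <- df[[col]] / px_per_mm
    }
  }
  trajectory_table(df, fps = fps,
                   animal_id = meta$animal_id %||% "animal",
                   body_length = meta$body_length %||% NA_real_,
                   genotype = meta$genotype %||% NA_character_,
                   arena = arena)
}

#' @param table A [trajectory_table()].
#' @rdname read_frames
#' @export
write_frames <- function(table, path, sidecar = TRUE) {
  stopifnot(inherits(table, "trajectory_table"))
  fmt <- function(v) {
    out <- sprintf("%.17g", v)
    out[is.nan(v)] <- "nan"
    out[is.na(v) & !is.nan(v)] <- "nan"
    out
  }
  cols <- lapply(FRAME_COLS, function(col) {
    if (col == "epoch_id") as.character(table[[col]]) else fmt(table[[col]])
  })
  lines <- c(paste(FRAME_COLS, collapse = ","),
             if (nrow(table)) do.call(paste, c(cols, sep = ",")))
  ok <- tryCatch({
    writeLines(lines, path); TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_zfsocial("io_error", "cannot write ", path)
  if (sidecar) {
    meta <- list(animal_id = attr(table, "animal_id"), fps = attr(table, "fps"),
                 body_length = attr(table, "body_length"),
                 genotype = attr(table, "genotype"))
    if (!is.null(attr(table, "arena"))) meta$arena <- arena_to_list(attr(table, "arena"))
    if (!is.null(attr(table, "seed"))) meta$seed <- attr(table, "seed")
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null")
  }
  invisible(path)
}

#' Interpolate short tracking gaps
#'
#' Runs of at most `max_gap_frames` consecutive missing animal positions are
#' filled by linear interpolation between the flanking observed frames.
#' Longer runs are left missing and reported in the `long_gaps` attribute;
#' downstream metrics exclude them from every denominator. Observed frames
#' are never modified, so the operation is idempotent.
#'
#' @param table A [trajectory_table()].
#' @param max_gap_frames Longest run of missing frames to fill (default 3).
#' @return The table with gaps filled; attribute `long_gaps` is a data.frame
#'   (`start`, `end`, `length` in frame indices) of runs left missing.
#' @export
fill_gaps <- function(table, max_gap_frames = 3) {
  stopifnot(max_gap_frames >= 0)
  miss <- is.na(table$x) | is.na(table$y)
  if (max_gap_frames > 0 && any(miss)) {
    table$x <- zoo::na.approx(table$x, x = table$t, maxgap = max_gap_frames,
                              na.rm = FALSE)
    table$y <- zoo::na.approx(table$y, x = table$t, maxgap = max_gap_frames,
                              na.rm = FALSE)
  }
  still <- is.na(table$x) | is.na(table$y)
  gaps <- data.frame(start = integer(0), end = integer(0), length = integer(0))
  if (any(still)) {
    r <- rle(still)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    gaps <- data.frame(start = starts[keep], end = ends[keep],
                       length = r$lengths[keep])
  }
  attr(table, "long_gaps") <- gaps
  table
}

`%||%` <- function(a, b) if (is.null(a)) b else a
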