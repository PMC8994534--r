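#' Per-frame animal-dot distance
#'
#' Euclidean distance between the animal centroid and the stimulus center,
#' restricted to frames on which a dot is displayed (`stim_diam > 0`).
#' Frames with an untracked animal yield `NA` and are excluded from every
#' downstream mean.
#'
#' @param table A [trajectory_table()] with stimulus columns.
#' @return data.frame (`t`, `epoch_id`, `dist` in mm), one row per
#'   stimulus-on frame.
#' @export
animal_dot_distance <- function(table) {
  on <- which(table$stim_diam > 0)
  if (!length(on)) {
    warn_zfsocial("empty_series", "no stimulus-on frames")
    return(data.frame(t = numeric(0), epoch_id = integer(0), dist = numeric(0)))
  }
  d <- sqrt((table$x[on] - table$stim_x[on])^2 +
            (table$y[on] - table$stim_y[on])^2)
  data.frame(t = table$t[on], epoch_id = table$epoch_id[on], dist = d)
}

#' Observed mean animal-dot distance (IADr) in chunks
#'
#' The "real" observed animal-dot distance, averaged in contiguous chunks of
#' `chunk` seconds within a stimulus epoch (default 300 s, one chunk per
#' 5-min presentation). Chunks in which fewer than half the frames carry a
#' valid distance are flagged and excluded.
#'
#' @param distances data.frame from [animal_dot_distance()] (one epoch).
#' @param chunk Chunk length, s.
#' @return data.frame (`chunk_id`, `IADr`, `n_frames`, `n_valid`, `valid`).
#' @export
compute_IADr <- function(distances, chunk = 300) {
  stopifnot(chunk > 0, nrow(distances) > 0)
  rel <- distances$t - distances$t[1]
  id <- floor(rel / chunk)
  out <- do.call(rbind, lapply(split(distances$dist, id), function(d) {
    data.frame(IADr = mean(d, na.rm = TRUE), n_frames = length(d),
               n_valid = sum(!is.na(d)))
  }))
  out$chunk_id <- as.integer(names(split(distances$dist, id)))
  out$valid <- out$n_valid >= 0.5 * out$n_frames
  rownames(out) <- NULL
  out[c("chunk_id", "IADr", "n_frames", "n_valid", "valid")]
}

#' Time-shifted animal-dot distances (IADs)
#'
#' The chance-encounter expectation: the animal position sequence is
#' circularly shifted in time relative to the stimulus sequence within each
#' epoch, and the mean distance recomputed per shift. Because of the time
#' shift the result reflects the distance expected from chance encounters
#' alone. Offsets default to 10 values evenly spaced in
#' (`min_offset`, epoch duration − `min_offset`), all > 60 s.
#'
#' @param table A [trajectory_table()].
#' @param epoch Epoch id to score.
#' @param offsets Offsets in seconds, or `NULL` for the default placement.
#' @param n_offsets Number of default offsets.
#' @param min_offset Minimum offset from either end of the epoch, s.
#' @return data.frame (`offset_s`, `offset_frames`, `IADs`, `n_valid`).
#' @export
compute_shifted_IADs <- function(table, epoch, offsets = NULL, n_offsets = 10,
                                 min_offset = 60) {
  fps <- tt_fps(table)
  idx <- which(table$epoch_id == epoch & table$stim_diam > 0)
  if (!length(idx)) stop_zfsocial("empty_series", "no frames in epoch ", epoch)
  n <- length(idx)
  dur <- n / fps
  if (is.null(offsets)) {
    if (dur <= 2 * min_offset + 1 / fps) {
      stop_zfsocial("insufficient_length", sprintf(
        "epoch %d lasts %.1f s; need > %g s for shifted offsets", epoch, dur,
        2 * min_offset))
    }
    offsets <- min_offset +
      seq_len(n_offsets) / (n_offsets + 1) * (dur - 2 * min_offset)
  }
  ax <- table$x[idx]; ay <- table$y[idx]
  sx <- table$stim_x[idx]; sy <- table$stim_y[idx]
  out <- lapply(offsets, function(off) {
    s <- as.integer(round(off * fps)) %% n
    perm <- ((seq_len(n) - 1L + s) %% n) + 1L
    d <- sqrt((ax[perm] - sx)^2 + (ay[perm] - sy)^2)
    data.frame(offset_s = off, offset_frames = s, IADs = mean(d, na.rm = TRUE),
               n_valid = sum(!is.na(d)))
  })
  do.call(rbind, out)
}

#' Social index per stimulus epoch
#'
#' The social index `SI = (mIADs - IADr) / mIADs` relates the observed
#' animal-dot distance `IADr` to the mean time-shifted distance `mIADs`
#' expected from chance encounters. `SI = 1` is perfect tracking (observed
#' distance 0), `SI = 0` chance-level behavior, and `SI < 0` avoidance.
#'
#' @param table A [trajectory_table()] with stimulus epochs.
#' @param chunk_s IADr chunk length, s.
#' @param n_offsets,min_offset_s Shifted-null configuration; see
#'   [compute_shifted_IADs()].
#' @return data.frame of class `si_result`, one row per epoch: `epoch_id`,
#'   `dot_diam`, `IADr`, `mIADs`, `SI`, `n_frames`, plus the per-offset
#'   distances in attribute `IADs` and the configuration in attribute
#'   `si_config`. Epochs with degenerate geometry (`mIADs = 0`) get `NA`
#'   with a warning.
#' @export
compute_SI <- function(table, chunk_s = 300, n_offsets = 10,
                       min_offset_s = 60) {
  dist <- animal_dot_distance(table)
  if (!nrow(dist)) {
    stop_zfsocial("empty_series", "no stimulus-on frames; cannot compute SI")
  }
  epochs <- sort(unique(dist$epoch_id))
  shifted <- list()
  rows <- lapply(epochs, function(ep) {
    dep <- dist[dist$epoch_id == ep, ]
    chunks <- compute_IADr(dep, chunk = chunk_s)
    ok <- chunks$valid
    IADr <- if (any(ok)) {
      stats::weighted.mean(chunks$IADr[ok], chunks$n_valid[ok])
    } else NA_real_
    sh <- compute_shifted_IADs(table, ep, n_offsets = n_offsets,
                               min_offset = min_offset_s)
    shifted[[as.character(ep)]] <<- sh
    mIADs <- mean(sh$IADs)
    SI <- if (!is.finite(mIADs) || mIADs == 0) {
      warn_zfsocial("undefined_si", "mIADs = 0 in epoch ", ep,
                    "; SI undefined")
      NA_real_
    } else (mIADs - IADr) / mIADs
    data.frame(epoch_id = ep,
               dot_diam = max(table$stim_diam[table$epoch_id == ep]),
               IADr = IADr, mIADs = mIADs, SI = SI, n_frames = nrow(dep))
  })
  out <- do.call(rbind, rows)
  attr(out, "IADs") <- shifted
  attr(out, "si_config") <- list(chunk_s = chunk_s, n_offsets = n_offsets,
                                 min_offset_s = min_offset_s,
                                 shift_topology = "circular within epoch")
  class(out) <- c("si_result", "data.frame")
  out
}
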