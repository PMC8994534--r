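# Independent brute-force oracles: naive double loops, no vectorized reuse
# of the package implementation. Used to pin the metric computations.

bf_mean_dot_distance <- function(tbl) {
  tot <- 0; n <- 0
  for (i in seq_len(nrow(tbl))) {
    if (tbl$stim_diam[i] > 0 && !is.na(tbl$x[i]) && !is.na(tbl$stim_x[i])) {
      dx <- tbl$x[i] - tbl$stim_x[i]
      dy <- tbl$y[i] - tbl$stim_y[i]
      tot <- tot + sqrt(dx * dx + dy * dy)
      n <- n + 1
    }
  }
  tot / n
}

bf_shifted_mean_distance <- function(tbl, epoch, shift_frames) {
  idx <- which(tbl$epoch_id == epoch & tbl$stim_diam > 0)
  n <- length(idx)
  tot <- 0; m <- 0
  for (i in seq_len(n)) {
    j <- ((i - 1 + shift_frames) %% n) + 1
    ax <- tbl$x[idx[j]]; ay <- tbl$y[idx[j]]
    sx <- tbl$stim_x[idx[i]]; sy <- tbl$stim_y[idx[i]]
    if (!is.na(ax) && !is.na(sx)) {
      tot <- tot + sqrt((ax - sx)^2 + (ay - sy)^2)
      m <- m + 1
    }
  }
  tot / m
}

bf_path_length <- function(tbl) {
  tot <- 0
  for (i in 2:nrow(tbl)) {
    dx <- tbl$x[i] - tbl$x[i - 1]
    dy <- tbl$y[i] - tbl$y[i - 1]
    if (!is.na(dx) && !is.na(dy)) tot <- tot + sqrt(dx * dx + dy * dy)
  }
  tot
}

bf_average_speed <- function(tbl) {
  tot <- 0; tt <- 0
  for (i in 2:nrow(tbl)) {
    dx <- tbl$x[i] - tbl$x[i - 1]
    dy <- tbl$y[i] - tbl$y[i - 1]
    if (!is.na(dx) && !is.na(dy)) {
      tot <- tot + sqrt(dx * dx + dy * dy)
      tt <- tt + (tbl$t[i] - tbl$t[i - 1])
    }
  }
  tot / tt
}

bf_place_preference <- function(tbl, L, divider_at = 0) {
  tot <- 0; n <- 0
  for (i in seq_len(nrow(tbl))) {
    if (!is.na(tbl$y[i])) {
      prox <- if (divider_at == 0) (L - tbl$y[i]) / L else tbl$y[i] / L
      tot <- tot + prox
      n <- n + 1
    }
  }
  tot / n
}

bf_pct_orienting <- function(tbl, min_step, L_div_at = 0, band = c(45, 90)) {
  n_def <- 0; n_hit <- 0
  for (i in seq_len(nrow(tbl) - 1)) {
    dx <- tbl$x[i + 1] - tbl$x[i]
    dy <- tbl$y[i + 1] - tbl$y[i]
    if (is.na(dx) || is.na(dy) || sqrt(dx * dx + dy * dy) < min_step) next
    n_def <- n_def + 1
    h <- atan2(dy, dx)
    a <- abs(atan2(sin(h), cos(h)))
    acute <- min(a, pi - a) * 180 / pi
    toward <- if (L_div_at == 0) sin(h) < 0 else sin(h) > 0
    if (toward && acute >= band[1] && acute <= band[2]) n_hit <- n_hit + 1
  }
  100 * n_hit / n_def
}

# small deterministic hand-built table helper
make_table <- function(x, y, fps = 10, stim_x = NaN, stim_y = NaN,
                       stim_diam = 0, epoch_id = -1L, heading = NaN,
                       arena = NULL, body_length = 5) {
  n <- length(x)
  trajectory_table(
    data.frame(t = (seq_len(n) - 1) / fps, x = x, y = y, heading = heading,
               stim_x = stim_x, stim_y = stim_y, stim_diam = stim_diam,
               epoch_id = epoch_id),
    fps = fps, body_length = body_length, arena = arena)
}

default_stimulus <- function(seed = 1, fps = 30, dot = 4) {
  simulate_knot_stimulus(knot_path_params(), stimulus_program(dot),
                         fps = fps, seed = seed)
}
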