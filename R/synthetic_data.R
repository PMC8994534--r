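#' Bout-swimming agent parameters
#'
#' Larval zebrafish swim in discrete bouts: brief propulsive events, each
#' with an associated turn, separated by glides. The simulated agent draws
#' inter-bout intervals from an exponential distribution, per-bout turn
#' angles from a wrapped normal, and per-bout displacements from a gamma
#' distribution. Social attraction is a single knob `k`: at each bout the
#' mean turn steers toward the stimulus bearing (or, for negative `k`, the
#' anti-bearing) with weight `|k| / (10 + |k|)`, so `k = 0` ignores the
#' stimulus entirely, large `k` tracks it, and negative `k` flees it.
#'
#' @param bout_rate Mean bouts per second (Hz).
#' @param bout_disp_mean Mean per-bout displacement, mm.
#' @param bout_disp_shape Gamma shape of the per-bout displacement
#'   (dimensionless; larger is less skewed).
#' @param turn_sd SD of the wrapped-normal per-bout turn, radians.
#' @param k Attraction gain (dimensionless). `k = 0`: stimulus-independent;
#'   `k > 0`: attraction; `k < 0`: avoidance.
#' @param body_length Body length, mm (nose to end of trunk).
#' @param escape_speed Speed of an executed escape maneuver, mm/s.
#' @param escape_p50 Loom final diameter giving 50% escape probability, mm.
#' @param escape_slope Slope of the logistic escape-probability curve, 1/mm.
#' @return A list of class `agent_params`.
#' @examples
#' agent_params(k = 5)
#' @export
agent_params <- function(bout_rate = 1.5, bout_disp_mean = 4,
                         bout_disp_shape = 4, turn_sd = 0.6, k = 0,
                         body_length = 5, escape_speed = 300,
                         escape_p50 = 4, escape_slope = 0.8) {
  stopifnot(bout_rate > 0, bout_disp_mean > 0, bout_disp_shape > 0,
            turn_sd > 0, body_length > 0, escape_speed > 0,
            escape_p50 > 0, escape_slope > 0, is.finite(k))
  structure(list(bout_rate = bout_rate, bout_disp_mean = bout_disp_mean,
                 bout_disp_shape = bout_disp_shape, turn_sd = turn_sd, k = k,
                 body_length = body_length, escape_speed = escape_speed,
                 escape_p50 = escape_p50, escape_slope = escape_slope),
            class = "agent_params")
}

# turn-bias weight: 0 at k = 0, -> 1 as k -> Inf, sign preserved;
# half-saturation at |k| = 10 so the social-drive knob stays graded over
# the k = 1..20 range instead of saturating immediately
attraction_weight <- function(k) k / (10 + abs(k))

# mean turn at a bout: steer toward the stimulus bearing for k > 0, toward
# the anti-bearing (directly away) for k < 0, with strength |k|/(10+|k|)
turn_bias <- function(k, bearing, heading) {
  wk <- attraction_weight(k)
  if (wk == 0) return(0)
  target <- if (wk > 0) bearing else bearing + pi
  abs(wk) * wrap_angle(target - heading)
}

wrap_angle <- function(a) atan2(sin(a), cos(a))

# glide profile: a bout's displacement is spread over ~150 ms with linearly
# decaying per-frame weights, emulating the propulsive burst + glide
glide_weights <- function(fps) {
  g <- max(1L, as.integer(round(0.15 * fps)))
  w <- rev(seq_len(g))
  w / sum(w)
}

# draw event times on (0, duration). With refractory = 0 this is a Poisson
# process. A positive refractory (the agent's glide duration) models the
# larval motor refractory period: intervals are refractory + exponential,
# with the exponential mean adjusted so the overall rate stays `rate`;
# successive bouts then never overlap within a glide.
draw_bout_times <- function(rate, duration, refractory = 0) {
  if (refractory > 0) {
    if (refractory >= 1 / rate) {
      stop_zfsocial("parameter_error",
                    "bout_rate too high for the glide refractory period")
    }
    exp_rate <- 1 / (1 / rate - refractory)
  } else {
    exp_rate <- rate
  }
  n_guess <- max(16L, ceiling(rate * duration + 6 * sqrt(rate * duration)))
  draw <- function() refractory + stats::rexp(n_guess, exp_rate)
  times <- cumsum(draw())
  while (times[length(times)] < duration) {
    times <- c(times, times[length(times)] + cumsum(draw()))
  }
  times[times < duration]
}

# compute one bout's glide positions for frames f0..f0+g-1 (clipped to n).
# Wall contact is specular: the position folds back inside and the travel
# direction reflects off the wall, so the animal slides along the boundary
# instead of being pinned against it. Caller assigns $xy into its frame
# matrix and adopts $heading.
apply_glide <- function(f0, pos, heading, disp, gw, arena, n) {
  dir <- c(cos(heading), sin(heading))
  g_eff <- min(length(gw), n - f0 + 1L)
  xy <- matrix(NA_real_, g_eff, 2L)
  for (i in seq_len(g_eff)) {
    newp <- pos + disp * gw[i] * dir
    if (is_circle(arena)) {
      dc <- newp - arena$center
      r <- sqrt(sum(dc^2))
      if (r > arena$radius) {
        nrm <- dc / r
        dir <- dir - 2 * sum(dir * nrm) * nrm
        r2 <- 2 * arena$radius - r
        if (r2 < 0) r2 <- 0.999 * arena$radius  # overshoot beyond one fold
        newp <- arena$center + nrm * r2
      }
    } else {
      hi <- c(arena$width, arena$length)
      for (ax in 1:2) {
        if (newp[ax] < 0) { newp[ax] <- -newp[ax]; dir[ax] <- -dir[ax] }
        if (newp[ax] > hi[ax]) { newp[ax] <- 2 * hi[ax] - newp[ax]; dir[ax] <- -dir[ax] }
        newp[ax] <- min(max(newp[ax], 0), hi[ax])
      }
    }
    pos <- newp
    xy[i, ] <- pos
  }
  list(pos = pos, f = f0:(f0 + g_eff - 1L), xy = xy,
       heading = atan2(dir[2], dir[1]))
}

# last-observation-carried-forward for the position matrix
locf_fill <- function(v) {
  idx <- seq_along(v)
  idx[is.na(v)] <- 0L
  idx <- cummax(idx)
  out <- v[pmax(idx, 1L)]
  out[idx == 0L] <- v[which(!is.na(v))[1L]]
  out
}

#' Knot-shaped stimulus path parameters
#'
#' The projected dot traverses a closed, self-crossing Lissajous figure
#' `x = Ax sin(p w t)`, `y = Ay sin(q w t + phase)` with `w = 2 pi / period`,
#' which fills the dish and revisits every region — the "knot" path of the
#' biological-motion assay. In `boutlike` mode the dot advances along the
#' same figure in discrete steps at `bout_rate` with dwell in between,
#' mimicking larval bout kinetics; in `smooth` mode it glides continuously.
#'
#' @param amplitude_x,amplitude_y Half-extents of the figure, mm.
#' @param freq_ratio Integer pair `c(p, q)` with `p != q`.
#' @param period Time to close the figure once, s. The default (140 s for
#'   the default amplitudes, figure perimeter ~214 mm) gives the dot a mean
#'   speed of ~1.5 mm/s, matching the bout-swimming larva it imitates.
#' @param step_mode `"boutlike"` or `"smooth"`.
#' @param bout_rate Steps per second in `boutlike` mode, Hz.
#' @param phase Phase offset of the y component, radians.
#' @return A list of class `knot_path_params`.
#' @export
knot_path_params <- function(amplitude_x = 14, amplitude_y = 14,
                             freq_ratio = c(2, 3), period = 140,
                             step_mode = c("boutlike", "smooth"),
                             bout_rate = 1, phase = pi / 2) {
  step_mode <- match.arg(step_mode)
  stopifnot(amplitude_x > 0, amplitude_y > 0, length(freq_ratio) == 2L,
            all(freq_ratio == round(freq_ratio)), freq_ratio[1] != freq_ratio[2],
            period > 0, bout_rate > 0)
  structure(list(amplitude_x = amplitude_x, amplitude_y = amplitude_y,
                 freq_ratio = as.integer(freq_ratio), period = period,
                 step_mode = step_mode, bout_rate = bout_rate, phase = phase),
            class = "knot_path_params")
}

knot_point <- function(params, tau) {
  w <- 2 * pi / params$period
  cbind(params$amplitude_x * sin(params$freq_ratio[1] * w * tau),
        params$amplitude_y * sin(params$freq_ratio[2] * w * tau + params$phase))
}

#' Stimulus presentation program
#'
#' Dots of varying sizes are projected intermittently, each for a 5-min
#' period by default, separated by stimulus-free gaps.
#'
#' @param dot_diams Dot diameters, mm, one epoch per entry (0 allowed: a
#'   no-dot control epoch is scored like any other but never displayed).
#' @param duration Epoch duration, s (default 300, the 5-min presentation).
#' @param gap Stimulus-free gap before each epoch, s.
#' @return A list of class `stimulus_program` with an `epochs` data.frame
#'   (`epoch_id`, `dot_diam`, `start`, `duration`).
#' @export
stimulus_program <- function(dot_diams = 4, duration = 300, gap = 60) {
  stopifnot(all(dot_diams >= 0), duration > 0, gap >= 0)
  n <- length(dot_diams)
  starts <- gap + (seq_len(n) - 1) * (duration + gap)
  structure(list(epochs = data.frame(epoch_id = seq_len(n), dot_diam = dot_diams,
                                     start = starts, duration = duration),
                 gap = gap),
            class = "stimulus_program")
}

#' Simulate the knot-path dot stimulus
#'
#' @param params A [knot_path_params()].
#' @param program A [stimulus_program()].
#' @param fps Frame rate, Hz.
#' @param seed Integer seed (used only in `boutlike` mode).
#' @param arena Optional arena; the path must stay inside it.
#' @return data.frame with per-frame `t`, `stim_x`, `stim_y`, `stim_diam`,
#'   `epoch_id` (`-1`, `stim_diam = 0`, positions `NaN` between epochs).
#' @export
simulate_knot_stimulus <- function(params, program, fps = 30, seed = 1,
                                   arena = NULL) {
  stopifnot(inherits(params, "knot_path_params"),
            inherits(program, "stimulus_program"), fps > 0)
  if (!is.null(arena) && is_circle(arena)) {
    tau <- seq(0, params$period, length.out = 2048L)
    pts <- knot_point(params, tau)
    if (max(sqrt(rowSums(pts^2))) > arena$radius) {
      stop_zfsocial("parameter_error", "knot path exceeds the arena")
    }
  }
  ep <- program$epochs
  total <- max(ep$start + ep$duration) + program$gap
  n <- ceiling(total * fps)
  t <- (seq_len(n) - 1) / fps
  out <- data.frame(t = t, stim_x = NaN, stim_y = NaN, stim_diam = 0,
                    epoch_id = -1L)
  withr::with_seed(seed, {
    for (i in seq_len(nrow(ep))) {
      in_ep <- t >= ep$start[i] & t < ep$start[i] + ep$duration[i]
      if (!any(in_ep)) next
      tau <- t[in_ep] - ep$start[i]
      if (params$step_mode == "smooth") {
        pts <- knot_point(params, tau)
      } else {
        steps <- draw_bout_times(params$bout_rate, ep$duration[i])
        anchors <- c(0, steps)
        pos_at <- knot_point(params, anchors)
        idx <- findInterval(tau, anchors)
        pts <- pos_at[idx, , drop = FALSE]
      }
      out$epoch_id[in_ep] <- i
      out$stim_diam[in_ep] <- ep$dot_diam[i]
      out$stim_x[in_ep] <- pts[, 1]
      out$stim_y[in_ep] <- pts[, 2]
    }
  })
  # a 0-mm control epoch keeps its epoch label but displays nothing
  zero <- out$stim_diam == 0
  out$stim_x[zero] <- NaN
  out$stim_y[zero] <- NaN
  out
}

#' Simulate a bout-swimming agent in a circular arena
#'
#' The agent starts at a random position and heading. Bout times follow a
#' Poisson process at `bout_rate`. At each bout the heading rotates by a
#' wrapped-normal turn whose mean is the bearing error toward the dot
#' weighted by `k/(1+|k|)` when a dot is displayed (zero otherwise, and for
#' `k = 0` always), then the agent translates by a gamma-distributed
#' displacement spread over a short glide. Positions reflect at the wall.
#' With `k = 0` the random-number stream never depends on the stimulus, so
#' the trajectory is statistically (and for a fixed seed, exactly)
#' independent of it.
#'
#' @param agent An [agent_params()].
#' @param stimulus Per-frame stimulus track from [simulate_knot_stimulus()],
#'   or `NULL` for a stimulus-free session of `duration` seconds.
#' @param arena A [circle_arena()].
#' @param fps Frame rate, Hz.
#' @param seed Integer seed; same seed, same bits.
#' @param duration Session length, s (only when `stimulus` is `NULL`).
#' @return A [trajectory_table()] carrying the stimulus columns and, in
#'   `heading`, the agent's internal post-bout heading (piecewise constant).
#' @export
simulate_agent <- function(agent, stimulus = NULL, arena = circle_arena(20),
                           fps = 30, seed = 1, duration = 300) {
  stopifnot(inherits(agent, "agent_params"), is_circle(arena))
  if (is.null(stimulus)) {
    n <- ceiling(duration * fps)
    stimulus <- data.frame(t = (seq_len(n) - 1) / fps, stim_x = NaN,
                           stim_y = NaN, stim_diam = 0, epoch_id = -1L)
  }
  n <- nrow(stimulus)
  dur <- n / fps
  gw <- glide_weights(fps)
  wk <- attraction_weight(agent$k)
  scale <- agent$bout_disp_mean / agent$bout_disp_shape
  mat <- matrix(NA_real_, n, 2L)
  headings <- rep(NA_real_, n)
  withr::with_seed(seed, {
    r0 <- arena$radius * 0.8 * sqrt(stats::runif(1))
    a0 <- stats::runif(1, -pi, pi)
    pos <- c(arena$center[1] + r0 * cos(a0), arena$center[2] + r0 * sin(a0))
    heading <- stats::runif(1, -pi, pi)
    mat[1L, ] <- pos
    headings[1L] <- heading
    bt <- draw_bout_times(agent$bout_rate, dur, refractory = length(gw) / fps)
    bf <- pmin(floor(bt * fps) + 1L, n)
    for (j in seq_along(bf)) {
      f0 <- bf[j]
      mu <- 0
      if (wk != 0 && stimulus$stim_diam[f0] > 0) {
        bearing <- atan2(stimulus$stim_y[f0] - pos[2],
                         stimulus$stim_x[f0] - pos[1])
        mu <- turn_bias(agent$k, bearing, heading)
      }
      heading <- wrap_angle(heading + stats::rnorm(1, mu, agent$turn_sd))
      disp <- stats::rgamma(1, shape = agent$bout_disp_shape, scale = scale)
      gl <- apply_glide(f0, pos, heading, disp, gw, arena, n)
      pos <- gl$pos
      heading <- gl$heading
      mat[gl$f, ] <- gl$xy
      headings[f0] <- heading
    }
  })
  frames <- data.frame(t = stimulus$t, x = locf_fill(mat[, 1]),
                       y = locf_fill(mat[, 2]), heading = locf_fill(headings),
                       stim_x = stimulus$stim_x, stim_y = stimulus$stim_y,
                       stim_diam = stimulus$stim_diam,
                       epoch_id = stimulus$epoch_id)
  out <- trajectory_table(frames, fps = fps, animal_id = sprintf("sim-%d", seed),
                          body_length = agent$body_length, arena = arena)
  attr(out, "seed") <- seed
  out
}

#' Simulate a split-dyad session
#'
#' Two agents in mirrored rectangular tanks that share a divider wall at
#' `y = 0` (each tank in its own coordinates; the partner is seen across the
#' divider at its mirrored position `(x, -y)`). During the presocial phase
#' the divider is opaque and both agents swim with no social bias (`k = 0`
#' behavior); when it is removed, each agent's bout turning is biased toward
#' the partner's mirrored position with its own gain `k`, which drives both
#' orienting toward, and drift of the place preference toward, the divider.
#'
#' @param agentA,agentB [agent_params()] for the two animals.
#' @param arena A [rect_arena()] (both tanks share the geometry).
#' @param presocial_s,social_s Phase durations, s (default 5 min each).
#' @param fps Frame rate, Hz (the assay records at 10 fps).
#' @param seed Integer seed.
#' @return list with trajectory tables `A`, `B` (epoch_id `-1` presocial,
#'   `1` social) and `t_divider_removed`.
#' @export
simulate_dyad <- function(agentA, agentB, arena = rect_arena(50, 20),
                          presocial_s = 300, social_s = 300, fps = 10,
                          seed = 1) {
  stopifnot(inherits(agentA, "agent_params"), inherits(agentB, "agent_params"),
            is_rect(arena))
  dur <- presocial_s + social_s
  n <- ceiling(dur * fps)
  gw <- glide_weights(fps)
  agents <- list(agentA, agentB)
  mats <- list(matrix(NA_real_, n, 2L), matrix(NA_real_, n, 2L))
  heads <- list(rep(NA_real_, n), rep(NA_real_, n))
  withr::with_seed(seed, {
    pos <- list(); heading <- list()
    for (i in 1:2) {
      pos[[i]] <- c(stats::runif(1, 0, arena$width),
                    stats::runif(1, 0, arena$length))
      heading[[i]] <- stats::runif(1, -pi, pi)
      mats[[i]][1L, ] <- pos[[i]]
      heads[[i]][1L] <- heading[[i]]
    }
    refr <- length(gw) / fps
    ev <- rbind(data.frame(t = draw_bout_times(agentA$bout_rate, dur, refr), who = 1L),
                data.frame(t = draw_bout_times(agentB$bout_rate, dur, refr), who = 2L))
    ev <- ev[order(ev$t), ]
    for (j in seq_len(nrow(ev))) {
      i <- ev$who[j]
      other <- 3L - i
      ag <- agents[[i]]
      f0 <- min(floor(ev$t[j] * fps) + 1L, n)
      social <- ev$t[j] >= presocial_s
      wk <- if (social) attraction_weight(ag$k) else 0
      mu <- 0
      if (wk != 0) {
        # mirrored partner position across the shared divider at y = 0
        tgt <- c(pos[[other]][1], -pos[[other]][2])
        bearing <- atan2(tgt[2] - pos[[i]][2], tgt[1] - pos[[i]][1])
        mu <- turn_bias(ag$k, bearing, heading[[i]])
      }
      heading[[i]] <- wrap_angle(heading[[i]] + stats::rnorm(1, mu, ag$turn_sd))
      disp <- stats::rgamma(1, shape = ag$bout_disp_shape,
                            scale = ag$bout_disp_mean / ag$bout_disp_shape)
      gl <- apply_glide(f0, pos[[i]], heading[[i]], disp, gw, arena, n)
      pos[[i]] <- gl$pos
      heading[[i]] <- gl$heading
      mats[[i]][gl$f, ] <- gl$xy
      heads[[i]][f0] <- heading[[i]]
    }
  })
  t <- (seq_len(n) - 1) / fps
  epoch <- ifelse(t >= presocial_s, 1L, -1L)
  mk <- function(i, id) {
    frames <- data.frame(t = t, x = locf_fill(mats[[i]][, 1]),
                         y = locf_fill(mats[[i]][, 2]),
                         heading = locf_fill(heads[[i]]),
                         stim_x = NaN, stim_y = NaN, stim_diam = 0,
                         epoch_id = epoch)
    out <- trajectory_table(frames, fps = fps, animal_id = id,
                            body_length = agents[[i]]$body_length,
                            arena = arena)
    attr(out, "seed") <- seed
    out
  }
  list(A = mk(1L, sprintf("dyadA-%d", seed)), B = mk(2L, sprintf("dyadB-%d", seed)),
       t_divider_removed = presocial_s)
}

#' Split a dyad trajectory into presocial and social phases
#'
#' @param table A trajectory table from [simulate_dyad()].
#' @param t_split Divider-removal time, s.
#' @return list of two trajectory tables, `presocial` and `social`.
#' @export
split_phases <- function(table, t_split) {
  cut1 <- as.data.frame(table)[table$t < t_split, ]
  cut2 <- as.data.frame(table)[table$t >= t_split, ]
  mk <- function(df) trajectory_table(df, fps = tt_fps(table),
                                      animal_id = attr(table, "animal_id"),
                                      body_length = tt_body_length(table),
                                      genotype = attr(table, "genotype"),
                                      arena = tt_arena(table))
  list(presocial = mk(cut1), social = mk(cut2))
}

#' Simulate a looming-stimulus session with planted escapes
#'
#' The agent swims with no social bias. Before each loom a moving grating
#' (20 s, ending 10 s before onset) re-centers the animal, modeled as a
#' turn bias toward the dish center. Each loom appears 10 mm to the
#' animal's left or right (world frame) and expands linearly from 0 to its
#' final diameter over 500 ms. With probability
#' `plogis((final_diam - escape_p50) * escape_slope)` the agent executes an
#' escape: a high-speed maneuver (per-frame speed = `escape_speed`) directed
#' away from the loom side, starting within the expansion window. Ground
#' truth (escape flag, latency, loom position) is returned in the schedule.
#'
#' @param agent An [agent_params()].
#' @param schedule A [build_schedule()] result.
#' @param arena A [circle_arena()].
#' @param fps Frame rate, Hz.
#' @param seed Integer seed.
#' @return list: `table` (trajectory with loom stimulus columns; `epoch_id`
#'   is the event index during expansion) and `schedule` whose `events`
#'   gain `escaped_true`, `latency_true`, `loom_x`, `loom_y`.
#' @export
simulate_loom_session <- function(agent, schedule, arena = circle_arena(20),
                                  fps = 30, seed = 1) {
  stopifnot(inherits(agent, "agent_params"), inherits(schedule, "loom_schedule"),
            is_circle(arena))
  events <- schedule$events
  dur <- max(events$t_onset) + schedule$inter_event
  n <- ceiling(dur * fps)
  t <- (seq_len(n) - 1) / fps
  gw <- glide_weights(fps)
  scale <- agent$bout_disp_mean / agent$bout_disp_shape
  # grating windows: 20 s ending 10 s before each onset
  grating <- rep(FALSE, n)
  for (on in events$t_onset) {
    grating[t >= on - 30 & t < on - 10] <- TRUE
  }
  mat <- matrix(NA_real_, n, 2L)
  nev <- nrow(events)
  loom_pos <- matrix(NA_real_, nev, 2L)
  withr::with_seed(seed, {
    escaped_true <- stats::runif(nev) <
      stats::plogis((events$final_diam - agent$escape_p50) * agent$escape_slope)
    latency_true <- stats::runif(nev, 0.1, 0.4)
    esc_jitter <- stats::runif(nev, -0.5, 0.5)
    r0 <- arena$radius * 0.5 * sqrt(stats::runif(1))
    a0 <- stats::runif(1, -pi, pi)
    pos <- c(arena$center[1] + r0 * cos(a0), arena$center[2] + r0 * sin(a0))
    heading <- stats::runif(1, -pi, pi)
    mat[1L, ] <- pos
    ev <- rbind(data.frame(t = draw_bout_times(agent$bout_rate, dur,
                                           length(gw) / fps),
                           type = "bout", idx = 0L),
                data.frame(t = events$t_onset, type = "loom",
                           idx = seq_len(nev)),
                data.frame(t = events$t_onset + latency_true, type = "escape",
                           idx = seq_len(nev))[escaped_true, ])
    ev <- ev[order(ev$t), ]
    for (j in seq_len(nrow(ev))) {
      f0 <- min(floor(ev$t[j] * fps) + 1L, n)
      if (ev$type[j] == "loom") {
        i <- ev$idx[j]
        side_sign <- if (events$side[i] == "left") -1 else 1
        loom_pos[i, ] <- c(pos[1] + side_sign * events$offset_mm[i], pos[2])
      } else if (ev$type[j] == "escape") {
        i <- ev$idx[j]
        away <- if (events$side[i] == "left") 0 else pi
        av <- c(cos(away + esc_jitter[i]), sin(away + esc_jitter[i]))
        # near the wall a larva escapes along it, not into it: project the
        # flight direction onto the wall tangent when it points outward
        dc <- pos - arena$center
        rr <- sqrt(sum(dc^2))
        if (rr > 0.75 * arena$radius && sum(av * dc / rr) > 0) {
          nrm <- dc / rr
          av <- av - sum(av * nrm) * nrm
          if (sqrt(sum(av^2)) < 1e-8) av <- c(-nrm[2], nrm[1])
          av <- av / sqrt(sum(av^2))
        }
        heading <- atan2(av[2], av[1])
        step <- agent$escape_speed / fps
        # integrate each escape frame in sub-steps with specular wall
        # reflection: the flight follows the wall curvature, so the
        # recorded per-frame chord keeps its full speed
        dir <- c(cos(heading), sin(heading))
        for (s in 1:2) {
          f <- f0 + s - 1L
          if (f > n) break
          for (sub in 1:4) {
            newp <- pos + (step / 4) * dir
            dc <- newp - arena$center
            rr2 <- sqrt(sum(dc^2))
            if (rr2 > arena$radius) {
              nrm <- dc / rr2
              dir <- dir - 2 * sum(dir * nrm) * nrm
              newp <- arena$center + nrm * max(2 * arena$radius - rr2, 0)
            }
            pos <- newp
          }
          mat[f, 1L] <- pos[1]
          mat[f, 2L] <- pos[2]
        }
      } else {
        mu <- 0
        if (grating[f0]) {
          bearing <- atan2(arena$center[2] - pos[2], arena$center[1] - pos[1])
          mu <- 0.7 * wrap_angle(bearing - heading)
        }
        heading <- wrap_angle(heading + stats::rnorm(1, mu, agent$turn_sd))
        disp <- stats::rgamma(1, shape = agent$bout_disp_shape, scale = scale)
        gl <- apply_glide(f0, pos, heading, disp, gw, arena, n)
        pos <- gl$pos
        heading <- gl$heading
        mat[gl$f, ] <- gl$xy
      }
    }
  })
  stim_x <- rep(NaN, n); stim_y <- rep(NaN, n)
  stim_diam <- rep(0, n); epoch_id <- rep(-1L, n)
  exp_frames <- max(1L, as.integer(round(events$expand_s[1] * fps)))
  for (i in seq_len(nev)) {
    f_on <- min(floor(events$t_onset[i] * fps) + 1L, n)
    ff <- f_on:min(f_on + exp_frames - 1L, n)
    stim_x[ff] <- loom_pos[i, 1]
    stim_y[ff] <- loom_pos[i, 2]
    stim_diam[ff] <- events$final_diam[i] * seq_along(ff) / exp_frames
    epoch_id[ff] <- i
  }
  frames <- data.frame(t = t, x = locf_fill(mat[, 1]), y = locf_fill(mat[, 2]),
                       heading = NaN, stim_x = stim_x, stim_y = stim_y,
                       stim_diam = stim_diam, epoch_id = epoch_id)
  table <- trajectory_table(frames, fps = fps,
                            animal_id = sprintf("loom-%d", seed),
                            body_length = agent$body_length, arena = arena)
  attr(table, "seed") <- seed
  events$escaped_true <- escaped_true
  events$latency_true <- latency_true
  events$loom_x <- loom_pos[, 1]
  events$loom_y <- loom_pos[, 2]
  schedule$events <- events
  list(table = table, schedule = schedule)
}

#' Generate a body-length cohort with a stunted subpopulation
#'
#' Lengths are normal(`base_mean`, `base_sd`); with the per-genotype rate
#' in `stunt_rates` an individual is stunted and shifted down by
#' `stunt_shift`. Defaults emulate a heterozygote-incross clutch in which
#' most homozygous mutants, but also a sizeable minority of wt and het
#' siblings, are stunted.
#'
#' @param n_wt,n_het,n_mut Animals per genotype (0 allowed).
#' @param base_mean,base_sd Non-stunted length distribution, mm.
#' @param stunt_shift Downward length shift of stunted animals, mm.
#' @param stunt_rates Named probabilities for `wt`, `het`, `mut`.
#' @param seed Integer seed.
#' @return data.frame (`animal_id`, `genotype`, `length_mm`, `stunted_true`).
#' @export
generate_length_cohort <- function(n_wt, n_het, n_mut, base_mean = 6.5,
                                   base_sd = 0.4, stunt_shift = 1.5,
                                   stunt_rates = c(wt = 0.3, het = 0.3,
                                                   mut = 0.78),
                                   seed = 1) {
  stopifnot(all(stunt_rates >= 0), all(stunt_rates <= 1),
            all(c("wt", "het", "mut") %in% names(stunt_rates)))
  counts <- c(wt = n_wt, het = n_het, mut = n_mut)
  withr::with_seed(seed, {
    out <- do.call(rbind, lapply(names(counts), function(g) {
      ng <- counts[[g]]
      if (ng == 0) return(NULL)
      stunted <- stats::runif(ng) < stunt_rates[[g]]
      len <- stats::rnorm(ng, base_mean, base_sd) - stunt_shift * stunted
      data.frame(animal_id = sprintf("%s-%03d", g, seq_len(ng)), genotype = g,
                 length_mm = len, stunted_true = stunted)
    }))
  })
  if (is.null(out)) {
    out <- data.frame(animal_id = character(0), genotype = character(0),
                      length_mm = numeric(0), stunted_true = logical(0))
  }
  rownames(out) <- NULL
  out
}
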