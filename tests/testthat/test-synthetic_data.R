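test_that("smooth knot path closes on itself after one period", {
  p <- knot_path_params(step_mode = "smooth", period = 140)
  expect_lt(max(abs(knot_point(p, 0) - knot_point(p, 140))), 1e-9)
  st <- simulate_knot_stimulus(p, stimulus_program(4, duration = 300, gap = 60),
                               fps = 30, seed = 1)
  # frames one full period apart within the epoch coincide
  i1 <- which(st$t == 60)
  i2 <- which(st$t == 200)
  expect_lt(abs(st$stim_x[i1] - st$stim_x[i2]), 1e-9)
  expect_lt(abs(st$stim_y[i1] - st$stim_y[i2]), 1e-9)
})

test_that("a single 300 s epoch of a 4 mm dot is labeled and sized correctly", {
  st <- simulate_knot_stimulus(knot_path_params(), stimulus_program(4),
                               fps = 30, seed = 1)
  expect_identical(sort(unique(st$epoch_id)), c(-1L, 1L))
  expect_identical(sort(unique(st$stim_diam)), c(0, 4))
  expect_equal(sum(st$stim_diam > 0), 300 * 30)
  # path must stay inside the watch glass when asked to check
  expect_error(simulate_knot_stimulus(knot_path_params(amplitude_x = 30),
                                      stimulus_program(4), fps = 30, seed = 1,
                                      arena = circle_arena(20)),
               class = "zfsocial_parameter_error")
})

test_that("boutlike stimulus advances in discrete steps at the bout rate", {
  st <- simulate_knot_stimulus(knot_path_params(step_mode = "boutlike",
                                                bout_rate = 1),
                               stimulus_program(4), fps = 30, seed = 9)
  on <- st$stim_diam > 0
  moves <- sum(diff(st$stim_x[on]) != 0 | diff(st$stim_y[on]) != 0)
  expect_gte(moves, qpois(0.005, 300))
  expect_lte(moves, qpois(0.995, 300))
  # dwell between steps: the vast majority of frames are stationary
  expect_lt(moves / sum(on), 0.05)
})

test_that("every simulator is bit-reproducible under a fixed seed", {
  st <- default_stimulus(seed = 4)
  a1 <- simulate_agent(agent_params(k = 3), st, seed = 11)
  a2 <- simulate_agent(agent_params(k = 3), st, seed = 11)
  a3 <- simulate_agent(agent_params(k = 3), st, seed = 12)
  expect_identical(as.data.frame(a1), as.data.frame(a2))
  expect_false(identical(as.data.frame(a1), as.data.frame(a3)))

  d1 <- simulate_dyad(agent_params(k = 10), agent_params(), seed = 21)
  d2 <- simulate_dyad(agent_params(k = 10), agent_params(), seed = 21)
  expect_identical(as.data.frame(d1$A), as.data.frame(d2$A))
  expect_identical(as.data.frame(d1$B), as.data.frame(d2$B))

  sch1 <- build_schedule(c(0, 4, 12), reps = 2, seed = 5)
  sch2 <- build_schedule(c(0, 4, 12), reps = 2, seed = 5)
  expect_identical(sch1, sch2)
  l1 <- simulate_loom_session(agent_params(), sch1, seed = 31)
  l2 <- simulate_loom_session(agent_params(), sch2, seed = 31)
  expect_identical(as.data.frame(l1$table), as.data.frame(l2$table))
  expect_identical(l1$schedule$events, l2$schedule$events)

  c1 <- generate_length_cohort(50, 50, 50, seed = 41)
  c2 <- generate_length_cohort(50, 50, 50, seed = 41)
  expect_identical(c1, c2)
})

test_that("a k = 0 agent is exactly independent of the stimulus", {
  st <- default_stimulus(seed = 6)
  with_stim <- simulate_agent(agent_params(k = 0), st, fps = 30, seed = 13)
  no_stim <- simulate_agent(agent_params(k = 0), NULL, fps = 30, seed = 13,
                            duration = nrow(st) / 30)
  expect_identical(with_stim$x, no_stim$x)
  expect_identical(with_stim$y, no_stim$y)
})

test_that("strong attraction pulls the agent closer than k = 0 on the same seed", {
  st <- default_stimulus(seed = 2)
  for (s in c(3, 17, 29)) {
    d0 <- median(animal_dot_distance(simulate_agent(agent_params(k = 0), st,
                                                    seed = s))$dist)
    d50 <- median(animal_dot_distance(simulate_agent(agent_params(k = 50), st,
                                                     seed = s))$dist)
    expect_lt(d50, d0)
  }
})

test_that("mean per-bout displacement obeys the law of large numbers", {
  ag <- agent_params()
  big <- circle_arena(2000)  # effectively unbounded: no wall contact
  tbl <- simulate_agent(ag, NULL, arena = big, fps = 30, seed = 8,
                        duration = 7000)
  step <- sqrt(diff(tbl$x)^2 + diff(tbl$y)^2)
  g <- length(zfsocial:::glide_weights(30))
  n_bouts <- sum(step > 0) / g
  expect_gt(n_bouts, 9000)
  mean_disp <- sum(step) / n_bouts
  se <- (ag$bout_disp_mean / sqrt(ag$bout_disp_shape)) / sqrt(n_bouts)
  expect_lt(abs(mean_disp - ag$bout_disp_mean), 3 * se)
})

test_that("the agent never leaves the arena and speeds are bounded", {
  st <- default_stimulus(seed = 3)
  ag <- agent_params(k = 20)
  tbl <- simulate_agent(ag, st, seed = 19)
  r <- sqrt(tbl$x^2 + tbl$y^2)
  expect_lte(max(r), 20 + 1e-9)
  # largest per-frame step <= largest glide fraction of an (astronomically
  # improbable) max gamma draw
  gw_max <- max(zfsocial:::glide_weights(30))
  d_max <- qgamma(1 - 1e-15, shape = ag$bout_disp_shape,
                  scale = ag$bout_disp_mean / ag$bout_disp_shape)
  expect_lte(max(sqrt(diff(tbl$x)^2 + diff(tbl$y)^2)), gw_max * d_max)
})

test_that("asocial dyads are symmetric; social gain pulls toward the divider", {
  pre <- soc <- matrix(NA_real_, 6, 2)
  for (s in 1:6) {
    d <- simulate_dyad(agent_params(k = 0), agent_params(k = 0), seed = s)
    for (i in 1:2) {
      ph <- split_phases(d[[i]], d$t_divider_removed)
      pre[s, i] <- mean(ph$presocial$y)
      soc[s, i] <- mean(ph$social$y)
    }
    expect_equal(nrow(split_phases(d$A, 300)$presocial), 3000L)
    expect_equal(nrow(split_phases(d$A, 300)$social), 3000L)
  }
  # mean distance-to-divider ~ L/2 = 25 mm in both phases for k = 0
  expect_lt(abs(mean(pre) - 25), 4)
  expect_lt(abs(mean(soc) - 25), 4)

  for (s in 1:3) {
    d <- simulate_dyad(agent_params(k = 10), agent_params(k = 0), seed = 100 + s)
    ph <- split_phases(d$A, d$t_divider_removed)
    expect_gt(place_preference(ph$social), place_preference(ph$presocial))
  }
})

test_that("loom ground truth follows the planted logistic", {
  # degenerate size 0: escape probability logistic(-p50 * slope) ~ 0.04
  sch0 <- build_schedule(0, reps = 50, seed = 7)
  ls0 <- simulate_loom_session(agent_params(), sch0, seed = 23)
  p0 <- plogis(-4 * 0.8)
  k0 <- sum(ls0$schedule$events$escaped_true)
  expect_lte(k0, qbinom(0.995, 100, p0))
  # at the half-maximum size the planted fraction sits in the binomial CI of 0.5
  sch <- build_schedule(4, reps = 30, seed = 8)
  ls <- simulate_loom_session(agent_params(), sch, seed = 24)
  k <- sum(ls$schedule$events$escaped_true)
  expect_gte(k, qbinom(0.005, 60, 0.5))
  expect_lte(k, qbinom(0.995, 60, 0.5))
})

test_that("escapes from a left loom displace the animal rightward", {
  sch <- build_schedule(12, reps = 20, seed = 9)
  sch$events$side <- "left"
  ls <- simulate_loom_session(agent_params(), sch, seed = 25)
  tb <- ls$table
  ev <- ls$schedule$events
  checked <- 0
  for (i in which(ev$escaped_true)) {
    f_on <- which(tb$t >= ev$t_onset[i])[1]
    # only interior starts: near the wall the flight follows the boundary
    if (sqrt(tb$x[f_on]^2 + tb$y[f_on]^2) > 8) next
    fe <- floor((ev$t_onset[i] + ev$latency_true[i]) * 30) + 1L
    expect_gt(tb$x[fe] - tb$x[fe - 1L], 0)  # first flight frame goes right
    checked <- checked + 1
  }
  expect_gte(checked, 3)
})

test_that("length cohorts honor stunt rates and empty strata", {
  # no stunting anywhere: flags only from the normal tail
  coh <- generate_length_cohort(2000, 0, 0, stunt_rates = c(wt = 0, het = 0,
                                                            mut = 0), seed = 2)
  cls <- classify_stunted(coh)
  expect_gt(mean(cls$stunted), 0.03)
  expect_lt(mean(cls$stunted), 0.11)

  # strongly shifted mutants are flagged at their planted rate
  coh2 <- generate_length_cohort(500, 0, 500, stunt_shift = 3,
                                 stunt_rates = c(wt = 0, het = 0, mut = 0.78),
                                 seed = 3)
  cls2 <- classify_stunted(coh2)
  frac_mut <- mean(cls2$stunted[cls2$genotype == "mut"])
  expect_gte(frac_mut, qbinom(0.005, 500, 0.78) / 500)
  expect_lte(frac_mut, qbinom(0.995, 500, 0.78) / 500)

  # an empty stratum is silently empty
  coh3 <- generate_length_cohort(10, 10, 0, seed = 4)
  expect_equal(sum(coh3$genotype == "mut"), 0L)
})
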