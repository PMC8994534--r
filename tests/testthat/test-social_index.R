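test_that("animal-dot distance is plain Euclidean geometry", {
  tbl <- make_table(x = c(3, 0, 5), y = c(4, 0, 0),
                    stim_x = c(0, 0, 5), stim_y = c(0, 0, 0),
                    stim_diam = 4, epoch_id = 1L)
  d <- animal_dot_distance(tbl)
  expect_equal(d$dist, c(5, 0, 0))
  none <- make_table(x = 0:2, y = 0:2)
  expect_warning(res <- animal_dot_distance(none),
                 class = "zfsocial_empty_series")
  expect_equal(nrow(res), 0L)
})

test_that("IADr chunking averages correctly and flags sparse chunks", {
  d <- data.frame(t = seq(0, 299.9, by = 0.1), epoch_id = 1L, dist = 7)
  ch <- compute_IADr(d, chunk = 300)
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$IADr, 7)

  saw <- data.frame(t = seq(0, 299.99, by = 0.01), epoch_id = 1L,
                    dist = rep(seq(0, 10, length.out = 100), 300))
  expect_lt(abs(compute_IADr(saw, 300)$IADr - 5), 0.1)

  sparse <- data.frame(t = seq(0, 9.9, by = 0.1), epoch_id = 1L,
                       dist = c(rep(NA, 60), rep(1, 40)))
  expect_false(compute_IADr(sparse, chunk = 10)$valid)
})

test_that("a shift-invariant trajectory gives every IADs = IADr, SI = 0", {
  n <- 3000
  st_x <- 10 * cos(seq(0, 6 * pi, length.out = n))
  st_y <- 10 * sin(seq(0, 6 * pi, length.out = n))
  tbl <- make_table(x = rep(4, n), y = rep(-3, n), fps = 10,
                    stim_x = st_x, stim_y = st_y, stim_diam = 4, epoch_id = 1L)
  si <- compute_SI(tbl)
  sh <- compute_shifted_IADs(tbl, 1)
  expect_equal(sh$IADs, rep(si$IADr, 10), tolerance = 1e-12)
  expect_equal(si$SI, 0, tolerance = 1e-12)
})

test_that("a forced zero offset reproduces IADr exactly", {
  tbl <- simulate_agent(agent_params(k = 5), default_stimulus(seed = 1),
                        seed = 2)
  sh0 <- compute_shifted_IADs(tbl, 1, offsets = 0)
  expect_identical(sh0$IADs, mean(animal_dot_distance(tbl)$dist))
})

test_that("a perfect tracker scores SI = 1 exactly", {
  st <- default_stimulus(seed = 3)
  on <- st$stim_diam > 0
  tbl <- make_table(x = ifelse(on, st$stim_x, 0), y = ifelse(on, st$stim_y, 0),
                    fps = 30, stim_x = st$stim_x, stim_y = st$stim_y,
                    stim_diam = st$stim_diam, epoch_id = st$epoch_id)
  si <- compute_SI(tbl)
  expect_identical(si$IADr, 0)
  expect_identical(si$SI, 1)
})

test_that("IADr and IADs agree with the brute-force oracle to 1e-9", {
  st <- simulate_knot_stimulus(knot_path_params(period = 70),
                               stimulus_program(4, duration = 100, gap = 0),
                               fps = 10, seed = 4)
  tbl <- simulate_agent(agent_params(k = 5), st, fps = 10, seed = 5)
  expect_equal(nrow(animal_dot_distance(tbl)), 1000L)
  si <- compute_SI(tbl, chunk_s = 100, min_offset_s = 10)
  expect_lt(abs(si$IADr - bf_mean_dot_distance(tbl)) / si$IADr, 1e-9)
  sh <- compute_shifted_IADs(tbl, 1, min_offset = 10)
  for (i in seq_len(nrow(sh))) {
    oracle <- bf_shifted_mean_distance(tbl, 1, sh$offset_frames[i])
    expect_lt(abs(sh$IADs[i] - oracle) / oracle, 1e-9)
  }
})

test_that("SI is invariant under rigid motions of the whole assay", {
  tbl <- simulate_agent(agent_params(k = 5), default_stimulus(seed = 6),
                        seed = 7)
  si0 <- compute_SI(tbl)
  th <- 37 * pi / 180
  rot <- function(x, y) list(x = cos(th) * x - sin(th) * y + 3,
                             y = sin(th) * x + cos(th) * y - 7)
  a <- rot(tbl$x, tbl$y); s <- rot(tbl$stim_x, tbl$stim_y)
  tbl2 <- make_table(x = a$x, y = a$y, fps = 30, stim_x = s$x, stim_y = s$y,
                     stim_diam = tbl$stim_diam, epoch_id = tbl$epoch_id)
  si1 <- compute_SI(tbl2)
  expect_equal(si1$SI, si0$SI, tolerance = 1e-12)
})

test_that("degenerate inputs raise classed signals", {
  short <- make_table(x = rep(0, 500), y = rep(0, 500), fps = 10,
                      stim_x = 1, stim_y = 0, stim_diam = 4, epoch_id = 1L)
  expect_error(compute_shifted_IADs(short, 1), class = "zfsocial_insufficient_length")

  # animal glued to a fixed dot: mIADs = 0, SI undefined
  n <- 3000
  degen <- make_table(x = rep(1, n), y = rep(2, n), fps = 10,
                      stim_x = 1, stim_y = 2, stim_diam = 4, epoch_id = 1L)
  expect_warning(si <- compute_SI(degen), class = "zfsocial_undefined_si")
  expect_true(is.na(si$SI))
})

test_that("SI never exceeds 1 on arbitrary sessions", {
  st <- default_stimulus(seed = 8)
  for (s in 1:8) {
    k <- c(-30, -5, 0, 0.5, 2, 10, 40, 100)[s]
    si <- compute_SI(simulate_agent(agent_params(k = k), st, seed = s))
    expect_lte(si$SI, 1)
  }
})

test_that("an avoidance agent scores negative SI", {
  st <- default_stimulus(seed = 9)
  for (s in 1:5) {
    si <- compute_SI(simulate_agent(agent_params(k = -20), st, seed = s))
    expect_lt(si$SI, 0)
  }
})
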