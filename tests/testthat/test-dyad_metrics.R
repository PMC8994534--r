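tank <- rect_arena(50, 20)

# build a rectangular-tank table from a sequence of unit-step headings
path_from_headings <- function(h, start = c(10, 25), step = 1, fps = 10) {
  x <- start[1] + c(0, cumsum(step * cos(h)))
  y <- start[2] + c(0, cumsum(step * sin(h)))
  make_table(x = x, y = y, fps = fps, arena = tank)
}

test_that("heading follows the displacement vector and respects min_step", {
  tbl <- make_table(x = c(0, 1, 1, 1.01), y = c(0, 0, 1, 1), arena = tank)
  h <- heading_series(tbl, min_step = 0.5)
  expect_equal(h[1], 0)           # +x
  expect_equal(h[2], pi / 2)      # +y
  expect_true(is.nan(h[3]))       # sub-threshold step
  expect_true(is.nan(h[4]))       # last frame
})

test_that("orienting percentage matches crafted heading geometries", {
  # always perpendicular, toward the divider (divider at y = 0)
  expect_equal(pct_time_orienting(path_from_headings(rep(-pi / 2, 60)),
                                  min_step = 0), 100)
  # always parallel to the divider
  expect_equal(pct_time_orienting(path_from_headings(rep(0, 30), start = c(2, 25)),
                                  min_step = 0), 0)
  # perpendicular but facing away only counts when require_toward is off
  away <- path_from_headings(rep(pi / 2, 30), start = c(10, 2))
  expect_equal(pct_time_orienting(away, min_step = 0), 0)
  expect_equal(pct_time_orienting(away, min_step = 0, require_toward = FALSE),
               100)
  # band bounds are inclusive on both ends
  expect_equal(pct_time_orienting(path_from_headings(rep(-pi / 4, 30)),
                                  min_step = 0), 100)
  # headings uniform over the toward-divider semicircle cover the band half
  # the time: the acute angle to the divider is uniform on [0, 90] degrees
  h <- -pi * (seq_len(360) - 0.5) / 360
  expect_equal(pct_time_orienting(path_from_headings(h, step = 0.2),
                                  min_step = 0), 50)
})

test_that("orienting is invariant to uniform speed rescaling", {
  withr::with_seed(11, h <- runif(200, -pi, pi))
  p1 <- pct_time_orienting(path_from_headings(h, step = 1), min_step = 0)
  p3 <- pct_time_orienting(path_from_headings(h, step = 3), min_step = 0)
  expect_equal(p1, p3)
})

test_that("place preference is the normalized proximity to the divider", {
  expect_equal(place_preference(make_table(x = rep(5, 10), y = rep(0, 10),
                                           arena = tank)), 1)
  expect_equal(place_preference(make_table(x = rep(5, 10), y = rep(50, 10),
                                           arena = tank)), 0)
  y_unif <- seq(0.5, 49.5, by = 1)
  expect_equal(place_preference(make_table(x = rep(5, 50), y = y_unif,
                                           arena = tank)), 0.5)
})

test_that("mirroring a trajectory across the tank midline flips place preference", {
  withr::with_seed(12, y <- runif(500, 0, 50))
  pp <- place_preference(make_table(x = rep(5, 500), y = y, arena = tank))
  pp_mirror <- place_preference(make_table(x = rep(5, 500), y = 50 - y,
                                           arena = tank))
  expect_equal(pp_mirror, 1 - pp, tolerance = 1e-12)
})

test_that("motion fraction counts the inclusive body-length/3 threshold", {
  still <- make_table(x = rep(1, 50), y = rep(1, 50), body_length = 5)
  expect_equal(pct_time_in_motion(still), 0)
  # body length 6 gives a binary-exact threshold of 2 mm per frame
  exact <- make_table(x = cumsum(rep(2, 50)), y = rep(0, 50),
                      body_length = 6)
  expect_equal(pct_time_in_motion(exact), 100)
  below <- make_table(x = cumsum(rep(2 - 1e-9, 50)), y = rep(0, 50),
                      body_length = 6)
  expect_equal(pct_time_in_motion(below), 0)
  no_bl <- make_table(x = 1:5, y = 1:5, body_length = NA)
  expect_error(pct_time_in_motion(no_bl), class = "zfsocial_config_error")
})

test_that("exclusion drops animals strictly below 10% motion", {
  scores <- data.frame(animal_id = c("a", "b", "c"),
                       pct_motion = c(9.9, 10.0, 55),
                       place_pref = 0.5, excluded = FALSE)
  kept <- apply_exclusion(scores)
  expect_identical(kept$animal_id, c("b", "c"))
  expect_identical(attr(kept, "all_scores")$excluded, c(TRUE, FALSE, FALSE))
})

test_that("a cohort with planted immobile agents is excluded at its prevalence", {
  ids <- sprintf("an-%02d", 1:10)
  scores <- do.call(rbind, lapply(1:10, function(i) {
    ag <- if (i <= 2) agent_params(bout_rate = 0.05, bout_disp_mean = 0.5) else
      agent_params()
    tbl <- simulate_agent(ag, NULL, fps = 10, seed = 400 + i, duration = 120)
    data.frame(animal_id = ids[i], pct_motion = pct_time_in_motion(tbl))
  }))
  kept <- apply_exclusion(scores)
  expect_equal(sum(attr(kept, "all_scores")$excluded), 2L)
})

test_that("regrouping by stimulus genotype relabels, flags and rejects", {
  scores <- data.frame(animal_id = c("f1", "f2", "f3"), place_pref = 0.6)
  pairs <- data.frame(focal_id = c("f1", "f2"), partner_id = c("p1", "p2"),
                      partner_genotype = c("mut", "wt"))
  out <- regroup_by_stimulus(scores, pairs)
  expect_identical(out$stimulus_group,
                   c("mut-stimulus", "wt-stimulus", "unknown-stimulus"))
  expect_identical(out$pairing_unknown, c(FALSE, FALSE, TRUE))
  expect_equal(nrow(out), nrow(scores))  # counts conserved

  bad <- data.frame(focal_id = "f1", partner_id = "f1",
                    partner_genotype = "wt")
  expect_error(regroup_by_stimulus(scores, bad), class = "zfsocial_pairing_error")
})

test_that("social gain produces dyad asymmetry only in the social phase", {
  ppA_soc <- ppB_soc <- ppA_pre <- ppB_pre <- numeric(10)
  for (s in 1:10) {
    d <- simulate_dyad(agent_params(k = 10), agent_params(k = 0), seed = 200 + s)
    phA <- split_phases(d$A, d$t_divider_removed)
    phB <- split_phases(d$B, d$t_divider_removed)
    ppA_pre[s] <- place_preference(phA$presocial)
    ppA_soc[s] <- place_preference(phA$social)
    ppB_pre[s] <- place_preference(phB$presocial)
    ppB_soc[s] <- place_preference(phB$social)
  }
  expect_gt(mean(ppA_soc), mean(ppB_soc))
  expect_gt(mean(ppA_soc) - mean(ppA_pre), 0.2)
  expect_lt(abs(mean(ppA_pre) - mean(ppB_pre)), 0.1)
})
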