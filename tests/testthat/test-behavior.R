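# Behavioral scoring formulas: place preference, exclusion rules, somatic
# signs, scorer reconciliation, center zone, and object interactions.

test_that("preference score is the paired minus unpaired time percentage", {
  arena <- behavior_arena("two_chamber")
  pr <- preference_score(two_chamber_track(0.6), arena, "left")
  expect_equal(pr$preference_score, 20, tolerance = 1e-9)
  expect_equal(pr$pct_paired, 60, tolerance = 1e-9)

  pr50 <- preference_score(two_chamber_track(0.5), arena, "left")
  expect_equal(pr50$preference_score, 0, tolerance = 1e-9)

  pr_r <- preference_score(two_chamber_track(0.6), arena, "right")
  expect_equal(pr_r$preference_score, -20, tolerance = 1e-9)

  expect_error(preference_score(two_chamber_track(0.5),
                                behavior_arena("open_field"), "left"),
               "two_chamber")
})

test_that("occupancy is conserved: chamber times plus boundary equal the session", {
  arena <- behavior_arena("two_chamber")
  n <- 600
  x <- rep(c(10, 25, 40), n / 3) # includes samples exactly on the divider
  tr <- photowd:::new_track_session(
    data.frame(t_s = (seq_len(n) - 1) / 10, x_cm = x, y_cm = 10),
    arena = arena, rate_hz = 10)
  pr <- preference_score(tr, arena, "left")
  total_pct <- pr$pct_paired + pr$pct_unpaired +
    100 * pr$time_boundary_s / pr$time_total_s
  expect_equal(total_pct, 100, tolerance = 1e-9)
  expect_gt(pr$time_boundary_s, 0)
})

test_that("pretest exclusion is strictly above 70%", {
  arena <- behavior_arena("two_chamber")
  expect_false(pretest_exclusion(preference_score(two_chamber_track(0.700),
                                                  arena, "left")))
  expect_true(pretest_exclusion(preference_score(two_chamber_track(0.71),
                                                 arena, "left")))
  expect_true(pretest_exclusion(preference_score(two_chamber_track(0.29),
                                                 arena, "left")))
  expect_false(pretest_exclusion(preference_score(two_chamber_track(0.5),
                                                  arena, "left")))
})

test_that("delta preference is a checked simple difference", {
  arena <- behavior_arena("two_chamber")
  test_day <- preference_score(two_chamber_track(0.65), arena, "left",
                               subject = "m1")
  pre_day <- preference_score(two_chamber_track(0.55), arena, "left",
                              subject = "m1")
  expect_equal(delta_preference(test_day, pre_day), 20, tolerance = 1e-9)
  expect_equal(delta_preference(pre_day, pre_day), 0)
  expect_equal(delta_preference(test_day, pre_day),
               -delta_preference(pre_day, test_day))

  other_side <- preference_score(two_chamber_track(0.55), arena, "right",
                                 subject = "m1")
  expect_error(delta_preference(test_day, other_side), "paired side")
  other_mouse <- preference_score(two_chamber_track(0.55), arena, "left",
                                  subject = "m2")
  expect_error(delta_preference(test_day, other_mouse), "subjects")
})

test_that("preference increases monotonically with the generator bias", {
  arena <- behavior_arena("two_chamber")
  biases <- c(-0.5, -0.2, 0, 0.2, 0.5)
  means <- vapply(biases, function(b) {
    mean(vapply(1:20, function(sd)
      preference_score(simulate_track(arena, b, duration_s = 120, seed = sd),
                       arena, "left")$preference_score, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_equal(cor(means, biases, method = "spearman"), 1)
})

test_that("somatic summaries count, merge, include, and pool correctly", {
  ev <- data.frame(sign = c(rep("shaking", 3), rep("paw_licking", 4)),
                   start_s = c(1, 5, 9, 20, 25, 30, 35),
                   end_s = c(2, 6.5, 10, 22, 26, 31, 37))
  s <- somatic_summary(ev)
  per <- s$per_sign
  expect_false(per$included[per$sign == "shaking"]) # 3 occurrences: excluded
  expect_true(per$included[per$sign == "paw_licking"]) # 4: included
  expect_equal(s$total_count, sum(per$count))
  expect_equal(s$total_duration_s, sum(per$duration_s), tolerance = 1e-9)

  s0 <- somatic_summary(ev[0, ])
  expect_equal(s0$total_count, 0)
  expect_equal(s0$total_duration_s, 0)

  overlap <- data.frame(sign = "grooming", start_s = c(1, 2), end_s = c(3, 5))
  expect_message(sm <- somatic_summary(overlap), "merged")
  expect_equal(sm$per_sign$count, 1)
  expect_equal(sm$per_sign$duration_s, 4)

  expect_error(somatic_summary(data.frame(sign = "x", start_s = 2,
                                          end_s = 1)), "end_s")
})

test_that("pooled somatic totals equal per-sign sums on random fixtures", {
  set.seed(15)
  for (i in 1:5) {
    k <- sample(5:30, 1)
    st <- sort(runif(k, 0, 500))
    ev <- data.frame(sign = sample(letters[1:4], k, replace = TRUE),
                     start_s = st, end_s = st + runif(k, 0.2, 3))
    s <- suppressMessages(somatic_summary(ev))
    expect_equal(s$total_count, sum(s$per_sign$count))
    expect_equal(s$total_duration_s, sum(s$per_sign$duration_s))
  }
})

test_that("scorer reconciliation averages small gaps and trusts the blind score", {
  expect_equal(reconcile_scorers(10.0, 10.4), 10.2)
  expect_equal(reconcile_scorers(10.0, 11.0), 10.0)
  expect_equal(reconcile_scorers(7.3, 7.3), 7.3)
  expect_equal(reconcile_scorers(c(10, 10), c(10.4, 11)), c(10.2, 10))
  expect_error(reconcile_scorers(-1, 2), "nonnegative")
})

test_that("center-zone metrics count entries and measure distance", {
  arena <- behavior_arena("open_field")
  rate <- 10
  never <- photowd:::new_track_session(
    data.frame(t_s = (0:99) / rate, x_cm = 2, y_cm = seq(1, 40, length.out = 100)),
    arena = arena, rate_hz = rate)
  m0 <- center_zone_metrics(never, arena)
  expect_equal(m0$visits, 0)
  expect_equal(m0$time_s, 0)

  crossing <- photowd:::new_track_session(
    data.frame(t_s = (0:99) / rate, x_cm = seq(1, 42, length.out = 100),
               y_cm = 21.5),
    arena = arena, rate_hz = rate)
  m1 <- center_zone_metrics(crossing, arena)
  expect_equal(m1$visits, 1)
  expect_gt(m1$time_s, 0)

  side <- 10
  sq <- data.frame(
    t_s = (0:39) / rate,
    x_cm = c(seq(5, 15, length.out = 10), rep(15, 10),
             seq(15, 5, length.out = 10), rep(5, 10)),
    y_cm = c(rep(5, 10), seq(5, 15, length.out = 10), rep(15, 10),
             seq(15, 5, length.out = 10)))
  sq_tr <- photowd:::new_track_session(sq, arena = arena, rate_hz = rate)
  dist <- center_zone_metrics(sq_tr, arena)$distance_cm
  expect_lt(abs(dist - 4 * side), 4 * side * 0.15)
})

test_that("object interactions use the inclusive 2 cm rule and feed peri-event times", {
  arena <- behavior_arena("open_field", object_xy = c(21.5, 21.5))
  rate <- 30
  far <- photowd:::new_track_session(
    data.frame(t_s = (0:99) / rate, x_cm = 26.5, y_cm = 21.5),
    arena = arena, rate_hz = rate)
  expect_equal(object_interactions(far, arena)$approaches, 0)

  n <- 300
  x <- seq(10, 33, length.out = n)
  pass <- photowd:::new_track_session(
    data.frame(t_s = (seq_len(n) - 1) / rate, x_cm = x, y_cm = 21.5),
    arena = arena, rate_hz = rate)
  oi <- object_interactions(pass, arena)
  expect_equal(oi$approaches, 1)
  # 4 cm of path inside the radius at (23/n) cm per sample, 30 Hz
  expected_time <- 4 / (23 / (n - 1)) / rate
  expect_lt(abs(oi$interaction_time_s - expected_time), 2 / rate)

  exact <- photowd:::new_track_session(
    data.frame(t_s = c(0, 1/rate), x_cm = c(30, 23.5), y_cm = 21.5),
    arena = arena, rate_hz = rate)
  expect_equal(object_interactions(exact, arena)$approaches, 1)

  expect_error(object_interactions(far, behavior_arena("open_field")),
               "object")
  expect_error(behavior_arena("open_field", object_xy = c(100, 10)),
               "outside")

  # entry timestamps round-trip into the peri-event extractor
  fs <- 50
  t <- seq(0, 60, by = 1 / fs)
  z <- rnorm(length(t))
  ev <- oi$event_times + 20
  m <- extract_peri_event(z, t, ev, pre_s = 2, post_s = 2)
  expect_equal(nrow(m), length(ev))
})
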