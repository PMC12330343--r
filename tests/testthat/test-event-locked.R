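# Peri-event analysis: window alignment and accounting, delta z and 500-ms
# AUC, response classification, group summaries, and the shuffled null.

test_that("peri-event extraction aligns rows and excludes boundary events", {
  fs <- 50
  t <- seq(0, 100, by = 1 / fs)
  z <- rnorm(length(t))
  m <- extract_peri_event(z, t, events = 50, pre_s = 5, post_s = 5)
  expect_equal(nrow(m), 1)
  expect_lte(abs(ncol(m) - 10 * fs), 1)
  off <- attr(m, "offset_s")
  expect_equal(sum(off == 0), 1)

  m2 <- extract_peri_event(z, t, events = c(2, 50), pre_s = 5, post_s = 5)
  expect_equal(nrow(m2), 1)
  expect_equal(attr(m2, "n_excluded"), 1)
  expect_error(extract_peri_event(z, t, events = 2, pre_s = 5, post_s = 5),
               "in bounds")
})

test_that("event-locked responses place the column-mean peak just after zero", {
  p <- quick_params(seed = 31, background_rate_hz = 0,
                    events = list(n = 10, start_s = 66, end_s = 114,
                                  min_gap_s = 4),
                    event_response = list(p_respond = 1, amp_mean = 0.08,
                                          latency_s = 0.2,
                                          mix = c(increase = 1, decrease = 0,
                                                  none = 0)))
  q <- quick_z(p)
  m <- extract_peri_event(q$z, q$trace$time_s, q$sim$events, pre_s = 3,
                          post_s = 3)
  off <- attr(m, "offset_s")
  peak_off <- off[which.max(colMeans(m))]
  # latency (0.2 s) + kernel rise-to-peak (~0.28 s), with interpolation slack
  expect_gt(peak_off, 0)
  expect_lt(peak_off, 1.0)
})

test_that("mean windows are the stated half-open intervals", {
  fs <- 10
  t <- seq(0, 40, by = 1 / fs)
  z <- as.numeric(t > 20) # step exactly at the event
  met <- peri_event_metrics(z, t, events = 20, pre_s = 5, post_s = 5)
  expect_equal(met$mean_pre, 0)
  expect_equal(met$mean_post, 1)
  expect_equal(met$delta_z, 1)
})

test_that("auc_500ms integrates only post-event samples", {
  fs <- 100
  t <- seq(0, 40, by = 1 / fs)
  set.seed(5)
  z <- rnorm(length(t))
  met1 <- peri_event_metrics(z, t, events = 20)
  z2 <- z
  z2[t < 20] <- z2[t < 20] + 50 # arbitrary pre-window rewrite
  met2 <- peri_event_metrics(z2, t, events = 20)
  expect_identical(met1$auc_500ms, met2$auc_500ms)
  expect_true(met1$mean_pre != met2$mean_pre)
})

test_that("classification thresholds delta z and matches peaks in the window", {
  met <- data.frame(t_event = c(10, 20, 30), mean_pre = 0, mean_post = 0,
                    delta_z = c(2, -2, 0), auc_500ms = 0)
  trans <- photowd:::empty_transient_set(1)
  trans[1, ] <- list(10.5, 5, 5, 0.3, 1)
  out <- classify_events(met, trans, theta = 1, response_window_s = 2)
  expect_equal(out$category, c("increase", "decrease", "no_change"))
  expect_equal(out$has_peak, c(TRUE, FALSE, FALSE))
  expect_error(classify_events(met, trans, theta = 0), "positive")
})

test_that("every event receives exactly one category", {
  set.seed(8)
  met <- data.frame(t_event = seq_len(200), mean_pre = 0, mean_post = 0,
                    delta_z = rnorm(200, 0, 2), auc_500ms = 0)
  out <- classify_events(met, photowd:::empty_transient_set(1), theta = 1)
  expect_true(all(out$category %in% c("increase", "decrease", "no_change")))
  expect_equal(length(out$category), 200)
})

test_that("synthetic increase events are classified as increases", {
  hits <- 0; total <- 0
  for (sd in 1:10) {
    p <- quick_params(seed = sd, duration_s = 240, background_rate_hz = 0,
                      injection_time_s = 20,
                      events = list(n = 8, start_s = 30, end_s = 230,
                                    min_gap_s = 15),
                      event_response = list(p_respond = 1, amp_mean = 0.1,
                                            latency_s = 0.2,
                                            mix = c(increase = 1,
                                                    decrease = 0, none = 0)))
    q <- quick_z(p)
    met <- peri_event_metrics(q$z, q$trace$time_s, q$sim$events)
    cl <- classify_events(met, photowd:::empty_transient_set(1), theta = 1)
    hits <- hits + sum(cl$category == "increase")
    total <- total + nrow(cl)
  }
  expect_gte(hits / total, 0.9)
})

test_that("pre-event ramp (decrease) events are classified as decreases", {
  p <- quick_params(seed = 41, background_rate_hz = 0,
                    events = list(n = 8, start_s = 66, end_s = 114,
                                  min_gap_s = 6),
                    event_response = list(p_respond = 1, amp_mean = 0.1,
                                          latency_s = 0.2,
                                          mix = c(increase = 0, decrease = 1,
                                                  none = 0)))
  q <- quick_z(p)
  met <- peri_event_metrics(q$z, q$trace$time_s, q$sim$events)
  cl <- classify_events(met, photowd:::empty_transient_set(1), theta = 1)
  expect_gt(mean(cl$category == "decrease"), 0.5)
})

test_that("response summaries average per subject and flag singleton SEM", {
  ev <- data.frame(subject = rep(c("a", "b", "c"), each = 4),
                   group = rep(c("g1", "g1", "g2"), each = 4),
                   has_peak = TRUE,
                   category = "increase")
  s <- summarize_responses(ev)
  expect_equal(s$per_group$proportion_with_peak, c(1, 1))
  expect_equal(s$per_group$sem_proportion_with_peak[s$per_group$group == "g1"], 0)
  expect_true(is.na(
    s$per_group$sem_proportion_with_peak[s$per_group$group == "g2"]))
  sums <- s$per_group$increase + s$per_group$decrease + s$per_group$no_change
  expect_equal(sums, c(1, 1), tolerance = 1e-9)
})

test_that("per-subject then group averaging weights subjects equally", {
  ev <- data.frame(
    subject = c(rep("a", 8), rep("b", 2)),
    group = "g",
    has_peak = c(rep(TRUE, 8), rep(FALSE, 2)),
    category = "no_change")
  s <- summarize_responses(ev)
  # subject means are 1 and 0 -> group mean 0.5 (not the pooled 0.8)
  expect_equal(s$per_group$proportion_with_peak, 0.5)
})

test_that("the shuffled null is centered, reproducible, and exceeded by real effects", {
  set.seed(3)
  fs <- 50
  t <- seq(0, 200, by = 1 / fs)
  z <- rnorm(length(t))
  null1 <- shuffle_null(z, t, n_events = 10, n_shuffles = 200, seed = 7)
  null2 <- shuffle_null(z, t, n_events = 10, n_shuffles = 200, seed = 7)
  expect_identical(null1, null2)
  expect_lt(abs(mean(null1)), 3 * sd(null1) / sqrt(length(null1)))
  expect_error(shuffle_null(z, t, 10, n_shuffles = 50), "100")

  p <- quick_params(seed = 51, background_rate_hz = 0,
                    events = list(n = 10, start_s = 66, end_s = 114,
                                  min_gap_s = 4),
                    event_response = list(p_respond = 1, amp_mean = 0.1,
                                          latency_s = 0.2,
                                          mix = c(increase = 1, decrease = 0,
                                                  none = 0)))
  q <- quick_z(p)
  met <- peri_event_metrics(q$z, q$trace$time_s, q$sim$events)
  null <- shuffle_null(q$z, q$trace$time_s, n_events = nrow(met),
                       n_shuffles = 200, seed = 11)
  expect_gt(mean(met$delta_z), quantile(null, 0.975))
})

test_that("group-average traces carry subject-level SEM", {
  fs <- 20
  t <- seq(0, 60, by = 1 / fs)
  z <- sin(t)
  m1 <- extract_peri_event(z, t, events = c(20, 30), pre_s = 2, post_s = 2)
  m2 <- extract_peri_event(z + 1, t, events = c(20, 30), pre_s = 2, post_s = 2)
  avg <- average_peri_event(list(s1 = m1, s2 = m2))
  expect_equal(nrow(avg), ncol(m1))
  expect_true(all(is.finite(avg$sem)))
  avg1 <- average_peri_event(list(s1 = m1))
  expect_true(all(is.na(avg1$sem)))
})
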