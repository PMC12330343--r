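# Synthetic recording generator: construction contracts, determinism, and
# the statistical structure the analysis assumes.

test_that("parameter validation rejects bad inputs with named messages", {
  expect_error(sim_params(sampling_rate_hz = 10), "16 Hz")
  expect_error(sim_params(kernel = list(tau_rise_s = 2, tau_decay_s = 1)),
               "tau_rise_s < tau_decay_s")
  expect_error(sim_params(background_rate_hz = -1), "background_rate_hz")
  expect_error(sim_params(event_response = list(p_respond = 1.5,
                                                amp_mean = 0.1,
                                                latency_s = 0.2,
                                                mix = c(increase = 1))),
               "p_respond")
  expect_error(sim_params(amp_mean = NaN), "non-finite")
  expect_error(sim_params(condition_effect = list(amp_scale_post = 0,
                                                  p_respond_post = 0.5)),
               "amp_scale_post")
})

test_that("with no transients, artifact, or noise the 465 channel is its bleach curve", {
  p <- quick_params(background_rate_hz = 0, noise_sd_465 = 0, noise_sd_405 = 0,
                    artifact = list(coupling_465 = 0, coupling_405 = 0,
                                    step_rate_hz = 0, step_sd = 0))
  sim <- simulate_recording(p)
  expected <- photowd:::bleach_curve(sim$recording$time_s, p$bleach_465)
  expect_equal(sim$recording$f465, expected, tolerance = 0)
})

test_that("identical seeds reproduce recordings and cohorts bitwise", {
  p <- quick_params(seed = 9, events = list(n = 5, start_s = 70, end_s = 115,
                                            min_gap_s = 5))
  a <- simulate_recording(p)
  b <- simulate_recording(p)
  expect_identical(a$recording$f465, b$recording$f465)
  expect_identical(a$recording$f405, b$recording$f405)
  expect_identical(a$truth$transient_times_s, b$truth$transient_times_s)

  base <- quick_params(duration_s = 60)
  c1 <- simulate_cohort(2, base, master_seed = 5)
  c2 <- simulate_cohort(2, base, master_seed = 5)
  expect_identical(lapply(c1, function(s) s$recording$f465),
                   lapply(c2, function(s) s$recording$f465))
})

test_that("background transient counts follow the Poisson mean", {
  counts <- vapply(1:100, function(sd) {
    p <- sim_params(duration_s = 600, sampling_rate_hz = 25.4325,
                    background_rate_hz = 0.1, seed = sd)
    length(simulate_recording(p)$truth$transient_times_s)
  }, numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 60), 3 * se)
})

test_that("transient inter-event times pass a KS test against the exponential", {
  pass <- vapply(1:100, function(sd) {
    p <- sim_params(duration_s = 600, sampling_rate_hz = 25.4325,
                    background_rate_hz = 0.1, seed = sd)
    gaps <- diff(simulate_recording(p)$truth$onset_times_s)
    stats::ks.test(gaps, "pexp", rate = 0.1)$p.value > 0.01
  }, logical(1))
  expect_gte(sum(pass), 95)
})

test_that("withdrawal suppression scales post-injection amplitudes exactly", {
  p1 <- quick_params(seed = 4, background_rate_hz = 0.2)
  p2 <- quick_params(seed = 4, background_rate_hz = 0.2,
                     condition = "withdrawal",
                     condition_effect = list(amp_scale_post = 0.5,
                                             p_respond_post = 0.9))
  t1 <- simulate_recording(p1)$truth
  t2 <- simulate_recording(p2)$truth
  post <- t1$onset_times_s > p1$injection_time_s
  expect_equal(t2$transient_amps[post], 0.5 * t1$transient_amps[post])
  expect_equal(t2$transient_amps[!post], t1$transient_amps[!post])
})

test_that("null condition effect leaves the withdrawal generator unchanged", {
  p_ctrl <- quick_params(seed = 11, events = list(n = 10, start_s = 65,
                                                  end_s = 115, min_gap_s = 4))
  p_null <- quick_params(seed = 11, events = list(n = 10, start_s = 65,
                                                  end_s = 115, min_gap_s = 4),
                         condition = "withdrawal",
                         condition_effect = list(amp_scale_post = 1,
                                                 p_respond_post = NA))
  a <- simulate_recording(p_ctrl)
  b <- simulate_recording(p_null)
  expect_identical(a$recording$f465, b$recording$f465)
})

test_that("responded-event fractions track p_respond within binomial bounds", {
  pre_frac <- post_frac <- numeric(0)
  for (sd in 1:4) {
    p <- sim_params(duration_s = 2400, sampling_rate_hz = 25.4325,
                    injection_time_s = 1200, background_rate_hz = 0,
                    events = list(n = 100, start_s = 20, end_s = 2380,
                                  min_gap_s = 5),
                    condition = "withdrawal",
                    condition_effect = list(amp_scale_post = 0.5,
                                            p_respond_post = 0.44),
                    seed = sd)
    tr <- simulate_recording(p)$truth
    pre <- tr$event_times <= 1200
    pre_frac <- c(pre_frac, tr$event_times[pre] %in% tr$responded_events)
    post_frac <- c(post_frac, tr$event_times[!pre] %in% tr$responded_events)
  }
  ci_pre <- stats::binom.test(sum(pre_frac), length(pre_frac))$conf.int
  ci_post <- stats::binom.test(sum(post_frac), length(post_frac))$conf.int
  expect_true(ci_pre[1] <= 0.9 && 0.9 <= ci_pre[2])
  expect_true(ci_post[1] <= 0.44 && 0.44 <= ci_post[2])
})

test_that("increasing amp_mean increases mean ground-truth amplitude", {
  amps <- vapply(c(0.03, 0.06, 0.12), function(a) {
    p <- quick_params(seed = 2, background_rate_hz = 0.2, amp_mean = a,
                      amp_sd = 0.005)
    mean(simulate_recording(p)$truth$transient_amps)
  }, numeric(1))
  expect_true(all(diff(amps) > 0))
})

test_that("the isosbestic channel carries bleach, artifact, and noise only", {
  p <- quick_params(seed = 3, background_rate_hz = 0.3,
                    noise_sd_465 = 0, noise_sd_405 = 0)
  sim <- simulate_recording(p)
  b405 <- photowd:::bleach_curve(sim$recording$time_s, p$bleach_405)
  implied <- b405 * (1 + p$artifact$coupling_405 * sim$truth$artifact)
  expect_equal(sim$recording$f405, implied, tolerance = 1e-12)
})

test_that("cohort design is 2x2 with withdrawal only on nicotine MEC days", {
  base <- quick_params(duration_s = 60)
  sessions <- simulate_cohort(2, base, master_seed = 3)
  expect_length(sessions, 8)
  grid <- unique(data.frame(
    exposure = vapply(sessions, `[[`, "", "exposure"),
    injection = vapply(sessions, `[[`, "", "injection")))
  expect_equal(nrow(grid), 4)
  for (s in sessions) {
    wd <- s$exposure == "nicotine" && s$injection == "MEC"
    expect_identical(s$truth$condition,
                     if (wd) "withdrawal" else "control")
  }
  expect_error(simulate_cohort(0, base), "n_per_group")
})

test_that("tracks are deterministic, confined, and bias shifts occupancy", {
  arena <- behavior_arena("two_chamber")
  t1 <- simulate_track(arena, bias = 0.3, duration_s = 60, seed = 5)
  t2 <- simulate_track(arena, bias = 0.3, duration_s = 60, seed = 5)
  expect_identical(t1$x_cm, t2$x_cm)
  expect_true(all(t1$x_cm >= 0 & t1$x_cm <= arena$width_cm))
  expect_true(all(t1$y_cm >= 0 & t1$y_cm <= arena$height_cm))
  expect_error(simulate_track(arena, bias = 1.5), "bias")

  occ0 <- vapply(1:50, function(sd) {
    tr <- simulate_track(arena, bias = 0, duration_s = 120, seed = sd)
    preference_score(tr, arena, "left")$pct_paired / 100
  }, numeric(1))
  expect_lt(abs(mean(occ0) - 0.5), 3 * sd(occ0) / sqrt(50))

  tr1 <- simulate_track(arena, bias = 1, duration_s = 300, seed = 2)
  expect_gt(preference_score(tr1, arena, "left")$pct_paired / 100, 0.9)
})
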