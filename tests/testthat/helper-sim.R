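# Shared fixtures: small, fast simulation configurations built in code.

# short dual-channel session at a reduced rate (fast to preprocess)
quick_params <- function(seed = 1, ...) {
  args <- list(duration_s = 120, sampling_rate_hz = 101.73,
               injection_time_s = 60, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_params, args)
}

# simulate + preprocess + per-session robust z in one call
quick_z <- function(params) {
  sim <- simulate_recording(params)
  tr <- process_recording(sim$recording)
  sc <- fit_robust_scaler(tr$dff)
  list(sim = sim, trace = tr, z = apply_zscore(tr$dff, sc), scaler = sc)
}

# unit-peak transient kernel bump added onto a trace
add_bump <- function(z, time_s, t0, amp, tau_rise = 0.1, tau_decay = 0.5) {
  z + amp * photowd:::transient_kernel(time_s - t0, tau_rise, tau_decay)
}

# reduced-rate cohort config for effect-direction experiments
cohort_config <- function(seed, amp_scale_post = 0.5, p_respond_post = 0.44,
                          n_per_group = 6, duration_s = 320,
                          n_events = 15, windows = FALSE,
                          injection_time_s = 10) {
  list(
    simulate = list(
      n_per_group = n_per_group, duration_s = duration_s,
      sampling_rate_hz = 25.4325, injection_time_s = injection_time_s,
      n_events = n_events,
      events_start_s = if (n_events > 0) injection_time_s + 10 else NA,
      events_end_s = if (n_events > 0) duration_s - 10 else NA,
      background_rate_hz = 0.05,
      kernel = list(tau_rise_s = 0.1, tau_decay_s = 0.5),
      amp_mean = 0.03, amp_sd = 0.006,
      event_response = list(p_respond = 0.9, amp_mean = 0.05,
                            latency_s = 0.2,
                            mix = c(increase = 1, decrease = 0, none = 0)),
      withdrawal = list(amp_scale_post = amp_scale_post,
                        p_respond_post = p_respond_post)),
    windows = list(enabled = windows, window_s = 300, gap_s = 0),
    seed = seed)
}

expect_all_finite <- function(x) expect_true(all(is.finite(x)))

# track visiting the left chamber for frac_left of its samples
two_chamber_track <- function(frac_left, n = 1000, rate = 10) {
  arena <- behavior_arena("two_chamber")
  n_left <- round(frac_left * n)
  x <- c(rep(12.5, n_left), rep(37.5, n - n_left))
  photowd:::new_track_session(
    data.frame(t_s = (seq_len(n) - 1) / rate, x_cm = x, y_cm = 12.5),
    arena = arena, rate_hz = rate)
}

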