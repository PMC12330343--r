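#' Simulation parameters for a dual-channel photometry session
#'
#' Bundles every knob of the synthetic recording generator: session geometry,
#' per-channel double-exponential photobleaching, the transient kernel,
#' background (Poisson) and event-locked transient statistics, the shared
#' motion-artifact step process, measurement noise, and the post-injection
#' condition effect that models withdrawal-induced suppression.
#'
#' Defaults follow the recording conditions of the paradigm the analysis is
#' built for: 1,017.3 Hz sampling, 600 s sessions, GCaMP6s-like kinetics
#' (0.1 s rise, 1.5 s decay; use \code{tau_decay_s = 0.5} for a GRAB-DA-like
#' sensor), a 0.1 Hz spontaneous transient rate, and an injection at
#' mid-session.
#'
#' @param duration_s session length in seconds.
#' @param sampling_rate_hz sampling rate in Hz; must exceed 16 Hz (twice the
#'   8 Hz acquisition low-pass).
#' @param bleach_465,bleach_405 per-channel photobleaching, a list with
#'   \code{baseline} (a.u.), \code{weight_fast} in \code{[0,1]},
#'   \code{tau_fast_s}, \code{tau_slow_s}, and \code{floor} (a.u.).
#' @param kernel transient kernel, list with \code{tau_rise_s} and
#'   \code{tau_decay_s} (rise must be shorter than decay).
#' @param background_rate_hz Poisson rate of spontaneous transients (Hz).
#' @param amp_mean,amp_sd transient amplitude distribution in fractional
#'   fluorescence units (negative draws are truncated at zero).
#' @param artifact shared motion artifact, list with \code{coupling_465},
#'   \code{coupling_405}, \code{step_rate_hz}, \code{step_sd}.
#' @param noise_sd_465,noise_sd_405 additive Gaussian measurement noise (a.u.).
#' @param events novel-object interaction schedule, list with \code{n},
#'   \code{start_s}, \code{end_s}, \code{min_gap_s}.
#' @param event_response list with \code{p_respond} in \code{[0,1]},
#'   \code{amp_mean}, \code{latency_s}, and \code{mix}, the per-event response
#'   category mixture over \code{increase}, \code{decrease} (a pre-event ramp
#'   terminating at the event), and \code{none}.
#' @param condition_effect list with \code{amp_scale_post} in \code{(0,1]} and
#'   \code{p_respond_post} in \code{[0,1]}, applied after
#'   \code{injection_time_s} when \code{condition = "withdrawal"}.
#' @param injection_time_s time of the SAL/MEC injection (seconds).
#' @param condition \code{"control"} (no post-injection change) or
#'   \code{"withdrawal"} (condition effect active).
#' @param sensor sensor label, \code{"GCaMP6s"} or \code{"GRAB-DA"}.
#' @param seed integer random seed.
#'
#' @return A validated list of class \code{"sim_params"}.
#' @export
sim_params <- function(duration_s = 600,
                       sampling_rate_hz = 1017.3,
                       bleach_465 = list(baseline = 2.0, weight_fast = 0.4,
                                         tau_fast_s = 60, tau_slow_s = 1200,
                                         floor = 1.0),
                       bleach_405 = list(baseline = 1.6, weight_fast = 0.4,
                                         tau_fast_s = 60, tau_slow_s = 1200,
                                         floor = 0.8),
                       kernel = list(tau_rise_s = 0.1, tau_decay_s = 1.5),
                       background_rate_hz = 0.1,
                       amp_mean = 0.05, amp_sd = 0.01,
                       artifact = list(coupling_465 = 0.02, coupling_405 = 0.02,
                                       step_rate_hz = 0.2, step_sd = 0.3),
                       noise_sd_465 = 0.005, noise_sd_405 = 0.005,
                       events = list(n = 0, start_s = NA, end_s = NA,
                                     min_gap_s = 12),
                       event_response = list(p_respond = 0.9, amp_mean = 0.08,
                                             latency_s = 0.2,
                                             mix = c(increase = 1, decrease = 0,
                                                     none = 0)),
                       condition_effect = list(amp_scale_post = 1,
                                               p_respond_post = NA),
                       injection_time_s = 300,
                       condition = c("control", "withdrawal"),
                       sensor = c("GCaMP6s", "GRAB-DA"),
                       seed = 1L) {
  condition <- match.arg(condition)
  sensor <- match.arg(sensor)
  if (is.na(condition_effect$p_respond_post))
    condition_effect$p_respond_post <- event_response$p_respond

  p <- list(duration_s = duration_s, sampling_rate_hz = sampling_rate_hz,
            bleach_465 = bleach_465, bleach_405 = bleach_405, kernel = kernel,
            background_rate_hz = background_rate_hz, amp_mean = amp_mean,
            amp_sd = amp_sd, artifact = artifact,
            noise_sd_465 = noise_sd_465, noise_sd_405 = noise_sd_405,
            events = events, event_response = event_response,
            condition_effect = condition_effect,
            injection_time_s = injection_time_s, condition = condition,
            sensor = sensor, seed = as.integer(seed))
  validate_sim_params(p)
  class(p) <- "sim_params"
  p
}

validate_sim_params <- function(p) {
  num_fields <- unlist(p[!(names(p) %in% c("condition", "sensor", "events"))])
  stopifnot(is.numeric(num_fields))
  bad <- names(num_fields)[!is.finite(num_fields)]
  if (length(bad) > 0)
    stop("non-finite simulation parameter: ", paste(bad, collapse = ", "))
  stopifnot_msg(p$duration_s > 0, "duration_s must be positive")
  stopifnot_msg(p$sampling_rate_hz > 16,
                "sampling_rate_hz must exceed 16 Hz (twice the 8 Hz low-pass)")
  stopifnot_msg(p$kernel$tau_rise_s > 0 && p$kernel$tau_decay_s > 0 &&
                  p$kernel$tau_rise_s < p$kernel$tau_decay_s,
                "kernel requires 0 < tau_rise_s < tau_decay_s")
  stopifnot_msg(p$background_rate_hz >= 0, "background_rate_hz must be >= 0")
  stopifnot_msg(p$amp_sd >= 0, "amp_sd must be >= 0")
  stopifnot_msg(p$noise_sd_465 >= 0 && p$noise_sd_405 >= 0,
                "noise sds must be >= 0")
  stopifnot_msg(p$artifact$step_rate_hz >= 0 && p$artifact$step_sd >= 0,
                "artifact rates/sds must be >= 0")
  er <- p$event_response
  stopifnot_msg(er$p_respond >= 0 && er$p_respond <= 1,
                "event_response$p_respond must lie in [0,1]")
  ce <- p$condition_effect
  stopifnot_msg(ce$amp_scale_post > 0 && ce$amp_scale_post <= 1,
                "condition_effect$amp_scale_post must lie in (0,1]")
  stopifnot_msg(ce$p_respond_post >= 0 && ce$p_respond_post <= 1,
                "condition_effect$p_respond_post must lie in [0,1]")
  for (ch in c("bleach_465", "bleach_405")) {
    b <- p[[ch]]
    stopifnot_msg(b$weight_fast >= 0 && b$weight_fast <= 1,
                  paste0(ch, "$weight_fast must lie in [0,1]"))
    stopifnot_msg(b$tau_fast_s > 0 && b$tau_slow_s > 0,
                  paste0(ch, " taus must be positive"))
  }
  invisible(p)
}

stopifnot_msg <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Difference-of-exponentials transient kernel, normalized to unit peak.
transient_kernel <- function(t, tau_rise, tau_decay) {
  t_peak <- tau_rise * log((tau_rise + tau_decay) / tau_rise)
  peak <- (1 - exp(-t_peak / tau_rise)) * exp(-t_peak / tau_decay)
  k <- numeric(length(t))
  pos <- t >= 0
  k[pos] <- (1 - exp(-t[pos] / tau_rise)) * exp(-t[pos] / tau_decay) / peak
  k
}

bleach_curve <- function(t, b) {
  b$baseline * (b$weight_fast * exp(-t / b$tau_fast_s) +
                  (1 - b$weight_fast) * exp(-t / b$tau_slow_s)) + b$floor
}

# Add one kernel (or pre-event ramp) into the signal accumulator in place.
add_component <- function(C, time_s, fs, t0, amp, kernel, shape = "kernel") {
  n <- length(C)
  if (shape == "kernel") {
    span_s <- kernel$tau_decay_s * 10
    i0 <- max(1L, floor(t0 * fs) + 1L)
    i1 <- min(n, ceiling((t0 + span_s) * fs) + 1L)
    if (i0 > n) return(C)
    idx <- i0:i1
    C[idx] <- C[idx] + amp * transient_kernel(time_s[idx] - t0,
                                              kernel$tau_rise_s,
                                              kernel$tau_decay_s)
  } else { # "ramp": linear rise over ramp_s ending at t0, fast decay after
    ramp_s <- 4; fall_s <- 0.3
    i0 <- max(1L, floor((t0 - ramp_s) * fs) + 1L)
    i1 <- min(n, ceiling((t0 + fall_s * 8) * fs) + 1L)
    if (i0 > n) return(C)
    idx <- i0:i1
    u <- time_s[idx] - t0
    seg <- ifelse(u <= 0, pmax(0, 1 + u / ramp_s), exp(-u / fall_s))
    C[idx] <- C[idx] + amp * seg
  }
  C
}

# Piecewise-constant jump process shared by both channels.
artifact_trace <- function(time_s, duration_s, step_rate_hz, step_sd) {
  n_steps <- rpois(1, step_rate_hz * duration_s)
  if (n_steps == 0) return(numeric(length(time_s)))
  at <- sort(runif(n_steps, 0, duration_s))
  sizes <- rnorm(n_steps, 0, step_sd)
  levels <- c(0, cumsum(sizes))
  levels[findInterval(time_s, at) + 1L]
}

#' Simulate one dual-channel photometry session with ground truth
#'
#' Generates 465 nm and 405 nm fluorescence traces as
#' \code{F_ch(t) = B_ch(t) * (1 + s_ch * C(t) + m_ch * A(t)) + noise}, where
#' \code{B_ch} is the per-channel double-exponential bleach curve, \code{C(t)}
#' the sum of unit-peak difference-of-exponential transients (signal channel
#' only, \code{s_465 = 1}, \code{s_405 = 0}), and \code{A(t)} a
#' piecewise-constant jump process shared by both channels (motion artifact).
#' Spontaneous transients arrive as a Poisson process; each novel-object
#' interaction in the event schedule elicits a response with probability
#' \code{p_respond}, drawn from the configured increase/decrease/none mixture.
#' After \code{injection_time_s}, sessions with \code{condition =
#' "withdrawal"} scale all transient amplitudes by \code{amp_scale_post} and
#' respond with probability \code{p_respond_post} instead.
#'
#' @param params a \code{\link{sim_params}} object.
#' @param session optional named list of session labels (subject_id, day,
#'   exposure, injection) attached to the recording.
#' @return list with \code{recording} (a \code{raw_recording}), \code{events}
#'   (an \code{event_log} containing the injection and any interactions), and
#'   \code{truth} (ground-truth transient times/amplitudes, responded events,
#'   per-event categories, bleach parameters, artifact trace, condition
#'   labels).
#' @export
simulate_recording <- function(params, session = NULL) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  set.seed(p$seed)
  fs <- p$sampling_rate_hz
  n <- floor(p$duration_s * fs)
  time_s <- (seq_len(n) - 1) / fs
  wd <- p$condition == "withdrawal"

  # spontaneous transients
  n_bg <- rpois(1, p$background_rate_hz * p$duration_s)
  bg_times <- sort(runif(n_bg, 0, p$duration_s))
  bg_amps <- pmax(0, rnorm(n_bg, p$amp_mean, p$amp_sd))
  if (wd) {
    post <- bg_times > p$injection_time_s
    bg_amps[post] <- bg_amps[post] * p$condition_effect$amp_scale_post
  }

  # event schedule + event-locked responses
  ev <- p$events
  ev_times <- numeric(0)
  if (!is.null(ev$n) && ev$n > 0) {
    lo <- if (is.na(ev$start_s)) p$injection_time_s + 10 else ev$start_s
    hi <- if (is.na(ev$end_s)) p$duration_s - 10 else ev$end_s
    ev_times <- draw_spaced_times(ev$n, lo, hi, ev$min_gap_s)
  }
  er <- p$event_response
  resp_times <- resp_amps <- numeric(0)
  responded <- logical(length(ev_times))
  categories <- character(length(ev_times))
  for (i in seq_along(ev_times)) {
    te <- ev_times[i]
    post <- te > p$injection_time_s
    p_resp <- if (wd && post) p$condition_effect$p_respond_post else er$p_respond
    hit <- runif(1) < p_resp
    cat_i <- sample(names(er$mix), 1, prob = er$mix)
    a <- pmax(0, rnorm(1, er$amp_mean, p$amp_sd))
    if (wd && post) a <- a * p$condition_effect$amp_scale_post
    if (!hit) {
      categories[i] <- "none"
      next
    }
    categories[i] <- cat_i
    if (cat_i == "none") next
    responded[i] <- cat_i == "increase"
    resp_times <- c(resp_times, te + er$latency_s)
    resp_amps <- c(resp_amps, if (cat_i == "decrease") -a else a)
  }

  C <- numeric(n)
  for (i in seq_along(bg_times))
    C <- add_component(C, time_s, fs, bg_times[i], bg_amps[i], p$kernel)
  for (i in seq_along(resp_times)) {
    shape <- if (resp_amps[i] < 0) "ramp" else "kernel"
    C <- add_component(C, time_s, fs, resp_times[i], abs(resp_amps[i]),
                       p$kernel, shape)
  }

  A <- artifact_trace(time_s, p$duration_s, p$artifact$step_rate_hz,
                      p$artifact$step_sd)
  B465 <- bleach_curve(time_s, p$bleach_465)
  B405 <- bleach_curve(time_s, p$bleach_405)
  f465 <- B465 * (1 + C + p$artifact$coupling_465 * A) +
    rnorm(n, 0, p$noise_sd_465)
  f405 <- B405 * (1 + p$artifact$coupling_405 * A) +
    rnorm(n, 0, p$noise_sd_405)

  all_t <- c(bg_times, resp_times[resp_amps > 0])
  all_a <- c(bg_amps, resp_amps[resp_amps > 0])
  ord <- order(all_t)

  rec <- new_raw_recording(time_s, f465, f405, fs, p$sensor, session)
  log_df <- data.frame(
    timestamp_s = c(p$injection_time_s, ev_times),
    label = c("injection", rep("novel_object_interaction", length(ev_times))),
    metadata = "", stringsAsFactors = FALSE)
  log <- new_event_log(log_df[order(log_df$timestamp_s), , drop = FALSE])
  # ground-truth times are kernel-peak times (onset + rise-to-peak lag),
  # i.e. where a peak detector should find each transient
  kp_lag <- p$kernel$tau_rise_s *
    log((p$kernel$tau_rise_s + p$kernel$tau_decay_s) / p$kernel$tau_rise_s)
  truth <- list(transient_times_s = all_t[ord] + kp_lag,
                onset_times_s = all_t[ord], transient_amps = all_a[ord],
                responded_events = ev_times[responded],
                event_times = ev_times, event_categories = categories,
                bleach_465 = p$bleach_465, bleach_405 = p$bleach_405,
                artifact = A, condition = p$condition, sensor = p$sensor,
                params = p)
  list(recording = rec, events = log, truth = truth)
}

# n event times in [lo, hi] with minimum spacing, deterministic given RNG state
draw_spaced_times <- function(n, lo, hi, min_gap) {
  if (n * min_gap > (hi - lo)) min_gap <- (hi - lo) / (n + 1)
  slack <- (hi - lo) - (n - 1) * min_gap
  u <- sort(runif(n, 0, slack))
  lo + u + (seq_len(n) - 1) * min_gap
}

#' Simulate a 2x2 (exposure x injection) photometry cohort
#'
#' Builds the two-group, two-day design of the withdrawal experiments:
#' \code{exposure} in tartrate/nicotine crossed with \code{injection} SAL
#' (day 1) / MEC (day 2), with \code{n_per_group} subjects per exposure. The
#' withdrawal condition effect is applied only to nicotine+MEC sessions, and
#' only after the injection time. Per-session seeds are derived
#' deterministically from \code{master_seed}.
#'
#' @param n_per_group subjects per exposure group (>= 1).
#' @param base a \code{\link{sim_params}} template; its \code{condition} and
#'   \code{seed} are overridden per session.
#' @param withdrawal_effect condition effect (list with \code{amp_scale_post},
#'   \code{p_respond_post}) for nicotine+MEC sessions.
#' @param master_seed integer master seed.
#' @return list of session records, each with \code{subject_id}, \code{day},
#'   \code{exposure}, \code{injection}, \code{recording}, \code{events},
#'   \code{truth}.
#' @export
simulate_cohort <- function(n_per_group, base,
                            withdrawal_effect = list(amp_scale_post = 0.5,
                                                     p_respond_post = 0.44),
                            master_seed = 1L) {
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  sessions <- list()
  k <- 0L
  for (gi in seq_along(exposures <- c("tartrate", "nicotine"))) {
    for (subj in seq_len(n_per_group)) {
      sid <- sprintf("%s_%02d", substr(exposures[gi], 1, 3), subj)
      for (day in 1:2) {
        inj <- c("SAL", "MEC")[day]
        wd <- exposures[gi] == "nicotine" && inj == "MEC"
        p <- base
        p$condition <- if (wd) "withdrawal" else "control"
        p$condition_effect <- if (wd) {
          list(amp_scale_post = withdrawal_effect$amp_scale_post,
               p_respond_post = withdrawal_effect$p_respond_post)
        } else {
          list(amp_scale_post = 1, p_respond_post = p$event_response$p_respond)
        }
        idx <- (gi - 1L) * n_per_group + subj
        p$seed <- as.integer((as.numeric(master_seed) + 7919 * idx +
                                104729 * day) %% 2147483647)
        validate_sim_params(p)
        sim <- simulate_recording(p, session = list(
          subject_id = sid, day = day, exposure = exposures[gi],
          injection = inj))
        k <- k + 1L
        sessions[[k]] <- c(list(subject_id = sid, day = day,
                                exposure = exposures[gi], injection = inj), sim)
      }
    }
  }
  sessions
}
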