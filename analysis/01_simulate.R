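#!/usr/bin/env Rscript
# Simulate the study's two cohorts with ground truth and write them to disk.
#
# Cohort A ("spontaneous"): 6 tartrate + 6 nicotine subjects, one SAL day and
# one MEC day each, 620 s sessions with the injection mid-session and no
# novel-object events -- the substrate for the 5-min pre/post-injection
# window comparisons.
#
# Cohort B ("novel object"): same 2x2 design, 320 s post-injection test with
# 15 novel-object interactions per session -- the substrate for peri-event,
# response-classification, and ROC analyses. Nicotine+MEC sessions carry the
# withdrawal effect: transient amplitudes halved and response probability
# dropping from 0.90 to 0.44 after the injection.
#
# Sessions are simulated at 25.4325 Hz (1,017.3 / 40); the generator itself
# defaults to the full acquisition rate.

suppressMessages(library(photowd))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L
out <- file.path("results", "cohorts")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("master seed: ", seed)

base_common <- list(
  sampling_rate_hz = 25.4325,
  background_rate_hz = 0.05,
  kernel = list(tau_rise_s = 0.1, tau_decay_s = 0.5),
  amp_mean = 0.03, amp_sd = 0.006,
  event_response = list(p_respond = 0.9, amp_mean = 0.05, latency_s = 0.2,
                        mix = c(increase = 1, decrease = 0, none = 0)))
withdrawal <- list(amp_scale_post = 0.5, p_respond_post = 0.44)

write_cohort <- function(sessions, tag) {
  manifest <- do.call(rbind, lapply(sessions, function(s) {
    stem <- sprintf("%s_%s_d%d", tag, s$subject_id, s$day)
    rp <- file.path(out, paste0(stem, ".csv"))
    ep <- file.path(out, paste0(stem, "_events.csv"))
    tp <- file.path(out, paste0(stem, "_truth.json"))
    write_recording(s$recording, rp)
    write_events(s$events, ep)
    write_ground_truth(s$truth, tp)
    data.frame(cohort = tag, recording = rp, events = ep, truth = tp,
               subject = s$subject_id, exposure = s$exposure,
               injection = s$injection, day = s$day,
               n_true_transients = length(s$truth$transient_times_s))
  }))
  manifest
}

# Cohort A: spontaneous activity around the injection
pa <- do.call(sim_params, c(base_common,
                            list(duration_s = 620, injection_time_s = 310,
                                 seed = seed)))
cohort_a <- simulate_cohort(6, pa, withdrawal_effect = withdrawal,
                            master_seed = seed)
man_a <- write_cohort(cohort_a, "spont")

# Cohort B: novel-object test after the injection
pb <- do.call(sim_params, c(base_common,
                            list(duration_s = 320, injection_time_s = 10,
                                 events = list(n = 15, start_s = 20,
                                               end_s = 310, min_gap_s = 12),
                                 seed = seed)))
cohort_b <- simulate_cohort(6, pb, withdrawal_effect = withdrawal,
                            master_seed = seed + 1000L)
man_b <- write_cohort(cohort_b, "novel")

manifest <- rbind(man_a, man_b)
write_table(manifest, file.path("results", "manifest.csv"))

message(sprintf("wrote %d sessions (%d + %d) under %s",
                nrow(manifest), nrow(man_a), nrow(man_b), out))
message(sprintf("ground-truth transients per session: median %d",
                median(manifest$n_true_transients)))
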