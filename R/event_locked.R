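# Peri-event analysis around novel-object interactions: aligned windows,
# mean z in the 5 s before/after each interaction, delta z-score, 500-ms
# post-event AUC, peak-matched response rates, and the
# increase/decrease/no-change classification used for dopamine responses.

#' Extract peri-event windows as a trials x samples matrix
#'
#' Each row is the z-scored signal around one event, aligned so that the
#' column at offset 0 is the first sample at or after the event time. Events
#' whose full \code{[-pre_s, +post_s]} window does not fit inside the
#' recording are excluded and counted.
#'
#' @param zscore z-scored trace.
#' @param time_s matching times (seconds).
#' @param events numeric event times, or an \code{event_log} (its
#'   novel-object interaction rows are used).
#' @param pre_s,post_s window extent before/after the event (seconds).
#' @return matrix with one row per included event; attributes
#'   \code{offset_s} (per-column time offsets), \code{event_times}, and
#'   \code{n_excluded}.
#' @export
extract_peri_event <- function(zscore, time_s, events, pre_s = 5, post_s = 5) {
  ev <- event_times_of(events)
  fs <- 1 / median(diff(time_s))
  n_pre <- round(pre_s * fs)
  n_post <- round(post_s * fs)
  n <- length(zscore)
  rows <- list()
  kept <- numeric(0)
  for (te in ev) {
    i0 <- findInterval(te, time_s, left.open = TRUE) + 1L # first t >= te
    if (i0 - n_pre < 1L || i0 + n_post - 1L > n) next
    rows[[length(rows) + 1L]] <- zscore[(i0 - n_pre):(i0 + n_post - 1L)]
    kept <- c(kept, te)
  }
  if (length(rows) == 0) stop("no event with a full peri-event window in bounds")
  m <- do.call(rbind, rows)
  structure(m, offset_s = (seq_len(ncol(m)) - n_pre - 1L) / fs,
            event_times = kept, n_excluded = length(ev) - length(kept))
}

event_times_of <- function(events) {
  if (inherits(events, "event_log"))
    events$timestamp_s[events$label == "novel_object_interaction"]
  else as.numeric(events)
}

#' Per-event peri-event metrics
#'
#' For each event time t: \code{mean_pre} = mean z over \code{[t-pre_s, t)},
#' \code{mean_post} = mean z over \code{(t, t+post_s]},
#' \code{delta_z = mean_post - mean_pre}, and \code{auc_500ms} = trapezoidal
#' integral of z over the samples in \code{(t, t+auc_window_s]} (the post-only
#' window that limits contamination from unrelated ongoing transients).
#' Events whose windows leave the recording are dropped with a count.
#'
#' @inheritParams extract_peri_event
#' @param auc_window_s AUC window after the event (seconds, default 0.5).
#' @return data frame with \code{t_event}, \code{mean_pre}, \code{mean_post},
#'   \code{delta_z}, \code{auc_500ms}; attribute \code{n_excluded}.
#' @export
peri_event_metrics <- function(zscore, time_s, events, pre_s = 5, post_s = 5,
                               auc_window_s = 0.5) {
  ev <- event_times_of(events)
  n <- length(time_s)
  keep <- ev - pre_s >= time_s[1] & ev + post_s <= time_s[n]
  dropped <- sum(!keep)
  ev <- ev[keep]
  if (length(ev) == 0) stop("no event with a full peri-event window in bounds")
  res <- lapply(ev, function(te) {
    pre_i <- which(time_s >= te - pre_s & time_s < te)
    post_i <- which(time_s > te & time_s <= te + post_s)
    auc_i <- which(time_s > te & time_s <= te + auc_window_s)
    auc <- if (length(auc_i) >= 2)
      pracma::trapz(time_s[auc_i], zscore[auc_i]) else NA_real_
    data.frame(t_event = te, mean_pre = mean(zscore[pre_i]),
               mean_post = mean(zscore[post_i]),
               delta_z = mean(zscore[post_i]) - mean(zscore[pre_i]),
               auc_500ms = auc)
  })
  out <- do.call(rbind, res)
  attr(out, "n_excluded") <- dropped
  out
}

#' Classify peri-event responses
#'
#' Adds \code{has_peak} (a detected transient peak falls within
#' \code{(t, t+response_window_s]}) and the dopamine-style category:
#' \code{increase} when \code{delta_z >= theta}, \code{decrease} when
#' \code{delta_z <= -theta}, else \code{no_change}. Every event receives
#' exactly one category.
#'
#' @param metrics data frame from \code{\link{peri_event_metrics}}.
#' @param transients a \code{transient_set} for the same session.
#' @param theta positive category threshold in z units.
#' @param response_window_s window after the event within which a transient
#'   peak counts as a response.
#' @return \code{metrics} with \code{has_peak} and \code{category} columns.
#' @export
classify_events <- function(metrics, transients, theta = 1,
                            response_window_s = 2) {
  if (theta <= 0) stop("theta must be positive")
  pk <- transients$peak_time_s
  metrics$has_peak <- vapply(metrics$t_event, function(te)
    any(pk > te & pk <= te + response_window_s), logical(1))
  metrics$category <- ifelse(metrics$delta_z >= theta, "increase",
                             ifelse(metrics$delta_z <= -theta, "decrease",
                                    "no_change"))
  metrics
}

#' Summarize classified peri-event responses by group
#'
#' Computes per-subject response proportions (fraction of interactions with a
#' matched transient peak, and the increase/decrease/no-change shares), then
#' averages across the subjects of each group with the subject as the
#' averaging unit; SEM is across subjects and flagged absent (NA) for
#' single-subject groups.
#'
#' @param events data frame of classified events with columns \code{subject},
#'   \code{group}, \code{has_peak}, \code{category}.
#' @return list with \code{per_subject} and \code{per_group} data frames.
#' @export
summarize_responses <- function(events) {
  stopifnot(nrow(events) > 0,
            all(c("subject", "group", "has_peak", "category") %in%
                  names(events)))
  cats <- c("increase", "decrease", "no_change")
  per_subj <- do.call(rbind, lapply(
    split(events, events[c("subject", "group")], drop = TRUE),
    function(d) {
      props <- vapply(cats, function(cc) mean(d$category == cc), numeric(1))
      data.frame(subject = d$subject[1], group = d$group[1],
                 n_events = nrow(d),
                 proportion_with_peak = mean(d$has_peak),
                 t(props))
    }))
  rownames(per_subj) <- NULL
  per_group <- do.call(rbind, lapply(split(per_subj, per_subj$group),
    function(d) {
      sem <- function(v) if (nrow(d) > 1) sd(v) / sqrt(nrow(d)) else NA_real_
      data.frame(group = d$group[1], n_subjects = nrow(d),
                 n_events = sum(d$n_events),
                 proportion_with_peak = mean(d$proportion_with_peak),
                 sem_proportion_with_peak = sem(d$proportion_with_peak),
                 increase = mean(d$increase), decrease = mean(d$decrease),
                 no_change = mean(d$no_change))
    }))
  rownames(per_group) <- NULL
  list(per_subject = per_subj, per_group = per_group)
}

#' Per-subject then group-average peri-event trace
#'
#' @param mats named list of peri-event matrices (one per subject) with a
#'   common \code{offset_s} attribute.
#' @return data frame with \code{offset_s}, group \code{mean}, and \code{sem}
#'   across subjects (NA if a single subject).
#' @export
average_peri_event <- function(mats) {
  stopifnot(length(mats) > 0)
  subj_means <- do.call(rbind, lapply(mats, colMeans))
  data.frame(offset_s = attr(mats[[1]], "offset_s"),
             mean = colMeans(subj_means),
             sem = if (nrow(subj_means) > 1)
               apply(subj_means, 2, sd) / sqrt(nrow(subj_means))
             else NA_real_)
}

#' Shuffled-event null distribution of delta z-score
#'
#' Draws \code{n_events} pseudo-event times uniformly inside the usable span
#' of the recording, \code{n_shuffles} times, and returns the per-shuffle mean
#' delta z-score. Used to check the specificity of event-locked effects.
#'
#' @inheritParams peri_event_metrics
#' @param n_events number of pseudo-events per shuffle.
#' @param n_shuffles number of shuffles (>= 100).
#' @param seed integer seed.
#' @return numeric vector of per-shuffle mean delta z.
#' @export
shuffle_null <- function(zscore, time_s, n_events, n_shuffles = 1000,
                         seed = 1L, pre_s = 5, post_s = 5) {
  if (n_shuffles < 100) stop("n_shuffles must be >= 100")
  set.seed(as.integer(seed))
  lo <- time_s[1] + pre_s
  hi <- time_s[length(time_s)] - post_s
  vapply(seq_len(n_shuffles), function(s) {
    ev <- runif(n_events, lo, hi)
    mean(peri_event_metrics(zscore, time_s, ev, pre_s, post_s)$delta_z)
  }, numeric(1))
}
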