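# Behavioral scoring: real-time place preference, open field center zone,
# novel-object interactions, somatic withdrawal signs, and the blinded/live
# scorer reconciliation rule.

# per-sample dwell times: each sample holds until the next one; the last
# sample gets the median interval
sample_dt <- function(t) {
  if (length(t) < 2) return(rep(1, length(t)))
  d <- diff(t)
  c(d, median(d))
}

#' Place preference score from a two-chamber track
#'
#' Percent of session time in the light-paired chamber minus percent in the
#' non-paired chamber. Chamber membership is strict (samples on the dividing
#' line belong to neither), and the denominator is total session time.
#'
#' @param track a \code{track_session} in a two-chamber arena.
#' @param arena the \code{\link{behavior_arena}} (kind \code{two_chamber}).
#' @param paired_side \code{"left"} or \code{"right"}: the light-paired
#'   chamber.
#' @param subject optional subject id carried into the result.
#' @return list of class \code{"preference_result"} with \code{pct_paired},
#'   \code{pct_unpaired}, \code{preference_score}, \code{paired_side},
#'   \code{subject}, and dwell-time bookkeeping.
#' @export
preference_score <- function(track, arena, paired_side = c("left", "right"),
                             subject = NA_character_) {
  if (arena$kind != "two_chamber") stop("preference requires a two_chamber arena")
  paired_side <- match.arg(paired_side)
  mid <- arena$width_cm / 2
  dt <- sample_dt(track$t_s)
  total <- sum(dt)
  t_left <- sum(dt[track$x_cm < mid])
  t_right <- sum(dt[track$x_cm > mid])
  pct <- c(left = 100 * t_left / total, right = 100 * t_right / total)
  other <- setdiff(c("left", "right"), paired_side)
  structure(list(pct_paired = unname(pct[paired_side]),
                 pct_unpaired = unname(pct[other]),
                 preference_score = unname(pct[paired_side] - pct[other]),
                 paired_side = paired_side, subject = subject,
                 time_total_s = total,
                 time_boundary_s = total - t_left - t_right),
            class = "preference_result")
}

#' Pretest exclusion rule
#'
#' A mouse is excluded when its pretest preference for either chamber exceeds
#' 70% of session time (strictly greater).
#'
#' @param pretest a \code{preference_result} from the pretest day.
#' @return logical: TRUE if the animal is excluded.
#' @export
pretest_exclusion <- function(pretest) {
  stopifnot(inherits(pretest, "preference_result"))
  max(pretest$pct_paired, pretest$pct_unpaired) > 70
}

#' Change in preference relative to pretest
#'
#' Preference score on the test day minus preference score on the pretest
#' day, for the same animal and light pairing.
#'
#' @param test,pretest \code{preference_result}s for the same subject and
#'   paired side.
#' @return the difference in percentage points.
#' @export
delta_preference <- function(test, pretest) {
  if (!identical(test$paired_side, pretest$paired_side))
    stop("test and pretest use different paired sides")
  if (!is.na(test$subject) && !is.na(pretest$subject) &&
      !identical(test$subject, pretest$subject))
    stop("test and pretest belong to different subjects")
  test$preference_score - pretest$preference_score
}

#' Summarize scored somatic withdrawal signs
#'
#' Counts occurrences and total durations per sign from a scored-event table,
#' merges overlapping intervals of the same sign (with a notice), pools
#' counts and durations across signs, and flags each sign as included only
#' when it was observed more than 3 times. The inclusion flag applies to
#' per-sign reporting only; pooled totals always include every sign.
#'
#' @param scored_events data frame with columns \code{sign}, \code{start_s},
#'   \code{end_s} (end >= start).
#' @return list of class \code{"somatic_summary"} with \code{per_sign}
#'   (sign, count, duration_s, included) and pooled \code{total_count},
#'   \code{total_duration_s}.
#' @export
somatic_summary <- function(scored_events) {
  if (nrow(scored_events) == 0)
    return(structure(list(per_sign = data.frame(sign = character(0),
                                                count = integer(0),
                                                duration_s = numeric(0),
                                                included = logical(0)),
                          total_count = 0L, total_duration_s = 0),
                     class = "somatic_summary"))
  if (any(scored_events$end_s < scored_events$start_s))
    stop("somatic events require end_s >= start_s")
  per <- lapply(split(scored_events, scored_events$sign), function(d) {
    iv <- merge_intervals(d$start_s, d$end_s)
    if (nrow(iv) < nrow(d))
      message("merged ", nrow(d) - nrow(iv),
              " overlapping '", d$sign[1], "' intervals")
    data.frame(sign = d$sign[1], count = nrow(iv),
               duration_s = sum(iv$end - iv$start))
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  per$included <- per$count > 3
  structure(list(per_sign = per, total_count = sum(per$count),
                 total_duration_s = sum(per$duration_s)),
            class = "somatic_summary")
}

merge_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) me <- max(me, end[i])
    else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' Reconcile blinded and live sniffing scores
#'
#' When the blinded and live scorer disagree by more than 0.5 s the blinded
#' score is used; otherwise the two are averaged. Vectorized.
#'
#' @param blind_s,live_s nonnegative sniff times (seconds).
#' @return reconciled times (seconds).
#' @export
reconcile_scorers <- function(blind_s, live_s) {
  if (any(blind_s < 0) || any(live_s < 0))
    stop("sniff times must be nonnegative")
  ifelse(abs(blind_s - live_s) > 0.5, blind_s, (blind_s + live_s) / 2)
}

#' Center-zone visits, time, and distance traveled in the open field
#'
#' A visit is a maximal run of consecutive samples inside the centered
#' center-zone square; time in zone accumulates per-sample dwell times;
#' distance is the summed Euclidean step length over the whole session.
#'
#' @param track a \code{track_session}.
#' @param arena an open-field \code{\link{behavior_arena}}.
#' @return list with \code{visits}, \code{time_s}, \code{distance_cm}.
#' @export
center_zone_metrics <- function(track, arena) {
  if (arena$kind != "open_field") stop("center zone requires an open_field arena")
  half <- arena$center_cm / 2
  cx <- arena$width_cm / 2
  cy <- arena$height_cm / 2
  inz <- abs(track$x_cm - cx) <= half & abs(track$y_cm - cy) <= half
  dt <- sample_dt(track$t_s)
  entries <- sum(inz & !c(FALSE, head(inz, -1)))
  dist <- sum(sqrt(diff(track$x_cm)^2 + diff(track$y_cm)^2))
  list(visits = entries, time_s = sum(dt[inz]), distance_cm = dist)
}

#' Novel-object approaches and interaction time
#'
#' An interaction sample is one within the interaction radius (2 cm by
#' default, inclusive) of the object; approaches are entries into the radius,
#' and the entry timestamps are returned so they can feed the peri-event
#' analysis.
#'
#' @param track a \code{track_session}.
#' @param arena an open-field \code{\link{behavior_arena}} with
#'   \code{object_xy} set.
#' @return list with \code{approaches}, \code{interaction_time_s},
#'   \code{event_times}.
#' @export
object_interactions <- function(track, arena) {
  if (is.null(arena$object_xy)) stop("arena has no object position")
  d <- sqrt((track$x_cm - arena$object_xy[1])^2 +
              (track$y_cm - arena$object_xy[2])^2)
  inr <- d <= arena$interaction_radius_cm
  dt <- sample_dt(track$t_s)
  entry <- inr & !c(FALSE, head(inr, -1))
  list(approaches = sum(entry),
       interaction_time_s = sum(dt[inr]),
       event_times = track$t_s[entry])
}
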