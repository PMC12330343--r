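# End-to-end orchestration: simulate (or load) a 2x2 cohort, preprocess each
# animal, detect transients, run the injection-window and peri-event
# analyses, build group ROC curves, and write tables + a JSON summary. All
# stages are driven by one validated config and a single master seed.

pipeline_defaults <- function() {
  list(
    preprocess = list(lowpass_cutoff_hz = 8, smooth_window_s = 1,
                      detrend = "double_exp", scaler_scope = "per_subject"),
    detection = list(prominence_mult = 2.9),
    windows = list(enabled = TRUE, window_s = 300, gap_s = 0),
    perievent = list(pre_s = 5, post_s = 5, auc_window_s = 0.5,
                     theta = 1, response_window_s = 2),
    roc = list(score_kind = "mean_post_5s", positive = "MEC"),
    seed = 1L, out_dir = NULL, log_level = "info")
}

#' Validate a pipeline run configuration
#'
#' Accepts a YAML file path or a list. Exactly one of \code{manifest} (a CSV
#' listing recording/event files with subject, exposure, injection, day
#' columns) or \code{simulate} (a block of \code{\link{sim_params}} fields
#' plus \code{n_per_group} and \code{withdrawal}) must be present. Missing
#' option blocks are filled with the documented defaults; violations are
#' reported with the offending key.
#'
#' @param config path to a YAML file, or a config list.
#' @return validated config list of class \code{"run_config"}.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  def <- pipeline_defaults()
  for (blk in names(def)) {
    if (is.list(def[[blk]])) {
      config[[blk]] <- utils::modifyList(def[[blk]],
                                         as.list(config[[blk]]))
    } else if (is.null(config[[blk]])) config[[blk]] <- def[[blk]]
  }
  has_man <- !is.null(config$manifest)
  has_sim <- !is.null(config$simulate)
  if (has_man == has_sim)
    stop("config must contain exactly one of 'manifest' or 'simulate'")
  if (has_man) {
    if (!file.exists(config$manifest))
      stop("manifest: file not found: ", config$manifest)
    man <- read.csv(config$manifest)
    need <- c("recording", "events", "subject", "exposure", "injection", "day")
    miss <- setdiff(need, names(man))
    if (length(miss))
      stop("manifest: missing columns: ", paste(miss, collapse = ", "))
    for (f in c(man$recording, man$events))
      if (!file.exists(f)) stop("manifest: referenced file not found: ", f)
  }
  if (config$perievent$theta <= 0)
    stop("perievent$theta: must be positive")
  if (config$preprocess$lowpass_cutoff_hz <= 0)
    stop("preprocess$lowpass_cutoff_hz: must be positive")
  if (!config$preprocess$detrend %in% c("double_exp", "single_exp", "none"))
    stop("preprocess$detrend: must be double_exp, single_exp, or none")
  class(config) <- c("run_config", "list")
  config
}

sim_params_from_config <- function(sim, seed) {
  args <- sim[setdiff(names(sim), c("n_per_group", "withdrawal", "n_events",
                                    "events_start_s", "events_end_s"))]
  args$seed <- seed
  if (!is.null(sim$n_events))
    args$events <- list(n = sim$n_events,
                        start_s = sim$events_start_s %||% NA,
                        end_s = sim$events_end_s %||% NA,
                        min_gap_s = 12)
  do.call(sim_params, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_manifest_sessions <- function(config) {
  man <- read.csv(config$manifest)
  lapply(seq_len(nrow(man)), function(i) {
    rec <- read_recording(man$recording[i])
    ev <- read_events(man$events[i])
    list(subject_id = man$subject[i], day = man$day[i],
         exposure = man$exposure[i], injection = man$injection[i],
         recording = rec, events = ev, truth = NULL)
  })
}

#' Run the full photometry analysis pipeline
#'
#' Simulates or loads a cohort, preprocesses every animal (robust scaler
#' fitted on its concatenated dF/F), detects transients, compares pre/post
#' injection windows, computes peri-event metrics and classifications around
#' novel-object interactions, summarizes response proportions, and builds
#' per-exposure ROC curves of SAL vs MEC event scores. Deterministic given
#' the config seed. If \code{out_dir} is set, writes the per-session
#' transient table, the per-event table, the window-comparison table, the
#' ROC summary, and a JSON summary; outputs are written only after every
#' stage succeeded, so a failure leaves no partial bundle.
#'
#' @param config a \code{run_config}, config list, or YAML path (validated
#'   via \code{\link{validate_config}}).
#' @return result bundle (invisibly if written to disk): sessions, transient
#'   and event tables, window comparisons, response summary, ROC results,
#'   and the summary list.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  stage <- function(name, key, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed for ", key, ": ",
           conditionMessage(e), call. = FALSE))
  }

  sessions <- if (!is.null(config$simulate)) {
    sim <- config$simulate
    base <- sim_params_from_config(sim, seed = config$seed)
    stage("simulate", "cohort",
          simulate_cohort(sim$n_per_group %||% 4, base,
                          withdrawal_effect = sim$withdrawal %||%
                            list(amp_scale_post = 0.5, p_respond_post = 0.44),
                          master_seed = config$seed))
  } else stage("load", "manifest", load_manifest_sessions(config))

  # preprocess per animal so the robust scaler sees all of its sessions
  # (scaler_scope = "per_session" fits one scaler per session instead)
  pp <- config$preprocess
  if (!pp$scaler_scope %in% c("per_subject", "per_session"))
    stop("preprocess$scaler_scope: must be per_subject or per_session")
  by_subj <- if (pp$scaler_scope == "per_subject") {
    split(seq_along(sessions), vapply(sessions, `[[`, "", "subject_id"))
  } else as.list(seq_along(sessions))
  for (sid in seq_along(by_subj)) {
    idx <- by_subj[[sid]]
    key <- sessions[[idx[1]]]$subject_id
    proc <- stage("preprocess", key, process_subject(
      lapply(sessions[idx], `[[`, "recording"),
      lowpass_cutoff_hz = pp$lowpass_cutoff_hz,
      smooth_window_s = pp$smooth_window_s, detrend = pp$detrend))
    for (k in seq_along(idx)) sessions[[idx[k]]]$trace <- proc$traces[[k]]
  }

  trans_rows <- list(); win_rows <- list(); ev_rows <- list()
  pe <- config$perievent
  for (s in sessions) {
    key <- sprintf("%s day %s", s$subject_id, s$day)
    tr <- s$trace
    ts <- stage("detect", key, detect_transients(
      tr$zscore, tr$time_s, prominence_mult = config$detection$prominence_mult))
    if (nrow(ts)) {
      trans_rows[[length(trans_rows) + 1L]] <-
        cbind(subject = s$subject_id, day = s$day, exposure = s$exposure,
              injection = s$injection, as.data.frame(ts))
    }
    inj_t <- s$events$timestamp_s[s$events$label == "injection"]
    w <- config$windows
    if (isTRUE(w$enabled) && length(inj_t) == 1) {
      lo_ok <- inj_t - w$gap_s - w$window_s >= tr$time_s[1]
      hi_ok <- inj_t + w$gap_s + w$window_s <= tr$time_s[length(tr$time_s)]
      if (lo_ok && hi_ok) {
        wc <- stage("windows", key, injection_comparison(
          tr$zscore, tr$time_s, inj_t, window_s = w$window_s,
          gap_s = w$gap_s,
          prominence_mult = config$detection$prominence_mult))
        win_rows[[length(win_rows) + 1L]] <- data.frame(
          subject = s$subject_id, day = s$day, exposure = s$exposure,
          injection = s$injection, delta_peak_count = wc$delta_peak_count,
          delta_mean_auc = wc$delta_mean_auc,
          delta_mean_amplitude = wc$delta_mean_amplitude)
      }
    }
    ev_t <- event_times_of(s$events)
    if (length(ev_t) > 0) {
      m <- stage("perievent", key, {
        met <- peri_event_metrics(tr$zscore, tr$time_s, ev_t,
                                  pre_s = pe$pre_s, post_s = pe$post_s,
                                  auc_window_s = pe$auc_window_s)
        classify_events(met, ts, theta = pe$theta,
                        response_window_s = pe$response_window_s)
      })
      ev_rows[[length(ev_rows) + 1L]] <-
        cbind(subject = s$subject_id, day = s$day, exposure = s$exposure,
              injection = s$injection, m)
    }
  }
  transients <- if (length(trans_rows)) do.call(rbind, trans_rows) else NULL
  windows <- if (length(win_rows)) do.call(rbind, win_rows) else NULL
  events <- if (length(ev_rows)) do.call(rbind, ev_rows) else NULL

  responses <- rocs <- NULL
  if (!is.null(events)) {
    ev2 <- events
    ev2$group <- paste(ev2$exposure, ev2$injection, sep = "_")
    responses <- stage("summarize", "cohort", summarize_responses(ev2))
    kind <- config$roc$score_kind
    score <- if (kind == "delta_z") events$delta_z else events$mean_post
    rocs <- lapply(split(seq_len(nrow(events)), events$exposure),
                   function(i) {
                     if (length(unique(events$injection[i])) < 2) return(NULL)
                     roc_curve(score[i], events$injection[i],
                               positive = config$roc$positive,
                               score_kind = kind)
                   })
    rocs <- rocs[!vapply(rocs, is.null, logical(1))]
  }

  summary <- list(
    seed = config$seed,
    n_sessions = length(sessions),
    parameters = config[c("preprocess", "detection", "windows", "perievent",
                          "roc")],
    window_deltas_by_group = if (!is.null(windows)) {
      lapply(split(windows, paste(windows$exposure, windows$injection,
                                  sep = "_")),
             function(d) list(n = nrow(d),
                              mean_delta_peak_count = mean(d$delta_peak_count),
                              mean_delta_auc = mean(d$delta_mean_auc,
                                                    na.rm = TRUE),
                              mean_delta_amplitude =
                                mean(d$delta_mean_amplitude, na.rm = TRUE)))
    },
    response_proportions = if (!is.null(responses)) responses$per_group,
    roc = if (!is.null(rocs))
      lapply(rocs, function(r) list(auc = r$auc, ci95 = r$ci95,
                                    n_pos = r$n_pos, n_neg = r$n_neg)))

  bundle <- list(config = config, sessions = sessions,
                 transients = transients, windows = windows, events = events,
                 responses = responses, rocs = rocs, summary = summary)
  class(bundle) <- "pipeline_bundle"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    if (!is.null(transients))
      write_table(transients, file.path(od, "transients.csv"))
    if (!is.null(windows))
      write_table(windows, file.path(od, "window_comparisons.csv"))
    if (!is.null(events))
      write_table(events, file.path(od, "events.csv"))
    if (!is.null(responses))
      write_table(responses$per_group, file.path(od, "responses.csv"))
    jsonlite::write_json(summary, file.path(od, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    return(invisible(bundle))
  }
  bundle
}

#' Render a human-readable report from a pipeline bundle
#'
#' Writes a plain-text summary and one figure per analysis family (peri-event
#' group averages, score density histograms, and ROC curves) into
#' \code{out_dir}.
#'
#' @param bundle a \code{pipeline_bundle} from \code{\link{run_pipeline}}.
#' @param out_dir output directory.
#' @return (invisibly) the paths written.
#' @export
report <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "pipeline_bundle"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)

  txt <- file.path(out_dir, "report.txt")
  con <- file(txt, "w")
  writeLines(c("photowd pipeline report",
               sprintf("sessions: %d, seed: %s", bundle$summary$n_sessions,
                       bundle$summary$seed), ""), con)
  if (!is.null(bundle$summary$roc)) {
    for (g in names(bundle$summary$roc)) {
      r <- bundle$summary$roc[[g]]
      writeLines(sprintf("ROC %s: AUC = %.4f (95%% CI %.4f-%.4f)",
                         g, r$auc, r$ci95[1], r$ci95[2]), con)
    }
  }
  if (!is.null(bundle$responses)) {
    writeLines("", con)
    writeLines("response proportions by group:", con)
    pg <- bundle$responses$per_group
    for (i in seq_len(nrow(pg)))
      writeLines(sprintf("  %s: with-peak %.2f (incr %.2f / decr %.2f / none %.2f)",
                         pg$group[i], pg$proportion_with_peak[i],
                         pg$increase[i], pg$decrease[i], pg$no_change[i]), con)
  }
  close(con)
  paths <- c(paths, txt)

  if (!is.null(bundle$events)) {
    f <- file.path(out_dir, "fig_peri_event.pdf")
    grDevices::pdf(f, width = 6, height = 4)
    groups <- split(bundle$events, bundle$events$injection)
    graphics::plot(NULL, xlim = c(-1, 1) * 1.2, ylim =
                     range(bundle$events$delta_z), xlab = "",
                   ylab = "delta z-score", xaxt = "n",
                   main = "Peri-event delta z by injection")
    graphics::axis(1, at = seq_along(groups), labels = names(groups))
    for (gi in seq_along(groups))
      graphics::points(jitter(rep(gi, nrow(groups[[gi]])), amount = 0.1),
                       groups[[gi]]$delta_z, pch = 16,
                       col = grDevices::adjustcolor(gi, 0.5))
    grDevices::dev.off()
    paths <- c(paths, f)

    f <- file.path(out_dir, "fig_density.pdf")
    grDevices::pdf(f, width = 6, height = 4)
    kind <- bundle$config$roc$score_kind
    score <- if (kind == "delta_z") bundle$events$delta_z else
      bundle$events$mean_post
    dh <- density_hist(score, 0.2, score_kind = kind)
    mids <- head(dh$bin_edges, -1) + dh$bin_width / 2
    graphics::plot(mids, dh$density, type = "h", lwd = 6, lend = 1,
                   xlab = kind, ylab = "probability density",
                   main = "Event score density (0.2 bins)")
    grDevices::dev.off()
    paths <- c(paths, f)
  }
  if (!is.null(bundle$rocs) && length(bundle$rocs)) {
    f <- file.path(out_dir, "fig_roc.pdf")
    grDevices::pdf(f, width = 5, height = 5)
    graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 2, col = "grey40",
                   xlab = "false positive rate", ylab = "true positive rate",
                   main = "SAL vs MEC discriminability")
    for (gi in seq_along(bundle$rocs))
      graphics::lines(bundle$rocs[[gi]]$fpr, bundle$rocs[[gi]]$tpr, col = gi,
                      lwd = 2)
    graphics::legend("bottomright", legend = sprintf(
      "%s (AUC %.3f)", names(bundle$rocs),
      vapply(bundle$rocs, `[[`, numeric(1), "auc")), col =
        seq_along(bundle$rocs), lwd = 2, bty = "n")
    grDevices::dev.off()
    paths <- c(paths, f)
  }
  invisible(paths)
}
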