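# Spontaneous transient detection on robust z-scored traces: local maxima
# kept when their topographic prominence reaches 2.9 x SD of the analyzed
# segment, with half-width at half prominence and per-transient trapezoidal
# AUC, plus the 5-min pre/post-injection window comparison.

# Local maxima as runs of equal values strictly above both neighbors; runs
# touching an edge are not peaks. A plateau peak is placed at the middle
# sample (floor). Prominence is topographic: height minus the higher of the
# two minima separating the peak from the nearest strictly higher terrain (or
# the trace edge) on each side. Computed in O(n) by compressing the trace to
# its run-length extrema and sweeping a monotonic stack in each direction;
# validated against the definitional scan in prominence_bruteforce().
peak_structure <- function(x) {
  n <- length(x)
  empty <- list(index = integer(0), prominence = numeric(0))
  if (n < 3) return(empty)
  r <- rle(x)
  v <- r$values
  m <- length(v)
  if (m < 3) return(empty)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  core <- 2:(m - 1L)
  pk_c <- core[v[core] > v[core - 1L] & v[core] > v[core + 1L]]
  P <- length(pk_c)
  if (P == 0) return(empty)
  # original-sample index of each peak: floor middle of its plateau run
  pk_idx <- (starts[pk_c] + ends[pk_c]) %/% 2L
  h <- v[pk_c]
  # min compressed value strictly between consecutive peaks (and from each
  # edge to the outermost peaks)
  bounds <- c(0L, pk_c, m + 1L)
  seg_min <- vapply(seq_len(P + 1L), function(s) {
    lo <- bounds[s] + 1L
    hi <- bounds[s + 1L] - 1L
    if (lo > hi) Inf else min(v[lo:hi])
  }, numeric(1))
  # stack entries carry (height, min value between that peak and the next
  # surviving entry toward the sweep origin, edge included), so popping
  # accumulates the running minimum back to the nearest strictly higher peak
  # or the trace edge
  sweep_side <- function(order_idx, gap_before) {
    res <- numeric(P)
    sh <- sm <- numeric(0)
    top <- 0L
    for (j in order_idx) {
      cur <- gap_before[j]
      while (top > 0L && sh[top] <= h[j]) {
        cur <- min(cur, sm[top])
        top <- top - 1L
      }
      res[j] <- cur # includes the edge segment when the stack is empty
      top <- top + 1L
      sh[top] <- h[j]
      sm[top] <- cur
    }
    res
  }
  lmin <- sweep_side(seq_len(P), seg_min[seq_len(P)])
  rmin <- sweep_side(rev(seq_len(P)), seg_min[1L + seq_len(P)])
  list(index = pk_idx, prominence = h - pmax(lmin, rmin))
}

local_maxima <- function(x) peak_structure(x)$index

peak_prominences <- function(x, peaks) {
  ps <- peak_structure(x)
  stopifnot(identical(ps$index, peaks))
  ps$prominence
}

#' Brute-force prominence oracle
#'
#' Independent O(n^2)-style reference implementation of topographic
#' prominence, written directly from the definition: for every local maximum,
#' scan left and right to the nearest strictly higher sample or the trace
#' edge, take the minimum value in each direction, and subtract the higher of
#' the two minima from the peak height. Used to validate
#' \code{\link{detect_transients}} exactly.
#'
#' @param x numeric trace (intended for length <= 1e5).
#' @return data frame with \code{index} and \code{prominence} for every local
#'   maximum (plateaus at their floor-middle sample).
#' @export
prominence_bruteforce <- function(x) {
  n <- length(x)
  idx <- integer(0)
  for (i in seq_len(n)) {
    if (i == 1L || i == n) next
    # plateau-aware local-max test
    l <- i - 1L
    while (l >= 1L && x[l] == x[i]) l <- l - 1L
    r <- i + 1L
    while (r <= n && x[r] == x[i]) r <- r + 1L
    if (l < 1L || r > n) next
    if (x[l] >= x[i] || x[r] >= x[i]) next
    if (i != ((l + 1L) + (r - 1L)) %/% 2L) next # not the plateau middle
    idx <- c(idx, i)
  }
  prom <- numeric(length(idx))
  for (k in seq_along(idx)) {
    p <- idx[k]
    h <- x[p]
    seen <- h
    lmin <- h
    for (j in rev(seq_len(p - 1L))) {
      if (x[j] > h) break
      if (x[j] < lmin) lmin <- x[j]
    }
    rmin <- h
    for (j in seq(p + 1L, n)) {
      if (x[j] > h) break
      if (x[j] < rmin) rmin <- x[j]
    }
    prom[k] <- h - max(lmin, rmin)
  }
  data.frame(index = idx, prominence = prom)
}

#' Detect calcium/dopamine transients by peak prominence
#'
#' Finds local maxima in the z-scored trace and keeps those whose topographic
#' prominence is at least \code{prominence_mult} (default 2.9) times the
#' standard deviation of the analyzed segment. For each kept peak the
#' half-width at half prominence is measured by linear interpolation, and the
#' per-transient AUC is the trapezoidal integral of z over that
#' half-prominence extent.
#'
#' @param zscore robust z-scored trace.
#' @param time_s matching time vector (seconds).
#' @param segment optional c(t0, t1) restricting the analysis (>= 10 s).
#' @param prominence_mult prominence threshold in units of segment SD.
#' @param sd_scope \code{"segment"} (default): the SD is computed over the
#'   analyzed segment; \code{"trace"}: over the whole trace.
#' @return data frame of class \code{"transient_set"} with \code{peak_time_s},
#'   \code{amplitude} (z at the peak), \code{prominence},
#'   \code{half_width_s}, \code{auc}; the threshold used is attached as
#'   attribute \code{detection_threshold}.
#' @export
detect_transients <- function(zscore, time_s, segment = NULL,
                              prominence_mult = 2.9,
                              sd_scope = c("segment", "trace")) {
  sd_scope <- match.arg(sd_scope)
  stopifnot(length(zscore) == length(time_s))
  if (is.null(segment)) segment <- range(time_s)
  if (segment[2] <= segment[1]) stop("empty or reversed segment")
  sel <- which(time_s >= segment[1] & time_s <= segment[2])
  if (length(sel) == 0) stop("empty segment")
  if (diff(range(time_s[sel])) < 10)
    stop("segment must span at least 10 s")
  z <- zscore[sel]
  t <- time_s[sel]
  thr <- prominence_mult *
    (if (sd_scope == "segment") sd(z) else sd(zscore))
  peaks <- local_maxima(z)
  if (length(peaks) == 0)
    return(empty_transient_set(thr))
  prom <- peak_prominences(z, peaks)
  keep <- prom >= thr
  peaks <- peaks[keep]
  prom <- prom[keep]
  if (length(peaks) == 0)
    return(empty_transient_set(thr))
  hw <- matrix(NA_real_, length(peaks), 2)
  for (k in seq_along(peaks))
    hw[k, ] <- half_prom_extent(z, t, peaks[k], prom[k])
  auc <- vapply(seq_along(peaks), function(k)
    transient_auc(z, t, extent = hw[k, ]), numeric(1))
  structure(data.frame(peak_time_s = t[peaks], amplitude = z[peaks],
                       prominence = prom, half_width_s = hw[, 2] - hw[, 1],
                       auc = auc),
            detection_threshold = thr,
            class = c("transient_set", "data.frame"))
}

empty_transient_set <- function(thr) {
  structure(data.frame(peak_time_s = numeric(0), amplitude = numeric(0),
                       prominence = numeric(0), half_width_s = numeric(0),
                       auc = numeric(0)),
            detection_threshold = thr,
            class = c("transient_set", "data.frame"))
}

# Left/right crossing times of the half-prominence reference level, by linear
# interpolation; clipped at the segment edges.
half_prom_extent <- function(z, t, p, prom) {
  ref <- z[p] - prom / 2
  n <- length(z)
  tl <- t[1]
  j <- p
  while (j > 1L && z[j - 1L] > ref) j <- j - 1L
  if (j > 1L) {
    tl <- t[j - 1L] + (t[j] - t[j - 1L]) * (ref - z[j - 1L]) /
      (z[j] - z[j - 1L])
  }
  tr <- t[n]
  j <- p
  while (j < n && z[j + 1L] > ref) j <- j + 1L
  if (j < n) {
    tr <- t[j] + (t[j + 1L] - t[j]) * (z[j] - ref) / (z[j] - z[j + 1L])
  }
  c(tl, tr)
}

#' Trapezoidal area under a z-scored trace segment
#'
#' Composite trapezoid of z over \code{[extent[1], extent[2]]}, including
#' linearly interpolated values at the two extent endpoints.
#'
#' @param zscore z-scored trace.
#' @param time_s matching times (seconds).
#' @param extent c(t0, t1) with t0 < t1, inside the trace.
#' @return area in z * s.
#' @export
transient_auc <- function(zscore, time_s, extent) {
  if (extent[2] <= extent[1]) stop("reversed or empty extent")
  if (extent[1] < time_s[1] || extent[2] > time_s[length(time_s)])
    stop("extent lies outside the trace")
  i1 <- findInterval(extent[1], time_s, left.open = TRUE) + 1L
  i2 <- findInterval(extent[2], time_s)
  interp_at <- function(t0) {
    i <- findInterval(t0, time_s)
    if (i >= length(time_s) || time_s[i] == t0) return(zscore[i])
    zscore[i] + (zscore[i + 1L] - zscore[i]) *
      (t0 - time_s[i]) / (time_s[i + 1L] - time_s[i])
  }
  inside <- if (i1 <= i2) i1:i2 else integer(0)
  tt <- c(extent[1], time_s[inside], extent[2])
  zz <- c(interp_at(extent[1]), zscore[inside], interp_at(extent[2]))
  keep <- !duplicated(tt)
  pracma::trapz(tt[keep], zz[keep])
}

#' Pre/post-injection window comparison of transient statistics
#'
#' Differences (post minus pre) in transient count, mean per-transient AUC,
#' and mean peak amplitude between two detected transient sets, following the
#' 5-min-before vs 5-min-after-injection comparison. Mean-based deltas are NA
#' (flagged absent) when either window holds no transient.
#'
#' @param transients_pre,transients_post \code{transient_set}s from the pre-
#'   and post-injection windows.
#' @param window_s window length (seconds), recorded in the result.
#' @return list of class \code{"window_comparison"} with \code{window_s},
#'   \code{delta_peak_count}, \code{delta_mean_auc},
#'   \code{delta_mean_amplitude}, and the per-window summaries.
#' @export
compare_windows <- function(transients_pre, transients_post, window_s = 300) {
  pre <- summarize_set(transients_pre)
  post <- summarize_set(transients_post)
  structure(list(window_s = window_s,
                 delta_peak_count = post$n - pre$n,
                 delta_mean_auc = post$mean_auc - pre$mean_auc,
                 delta_mean_amplitude = post$mean_amp - pre$mean_amp,
                 pre = pre, post = post),
            class = "window_comparison")
}

summarize_set <- function(ts) {
  list(n = nrow(ts),
       mean_auc = if (nrow(ts)) mean(ts$auc) else NA_real_,
       mean_amp = if (nrow(ts)) mean(ts$amplitude) else NA_real_)
}

#' @rdname compare_windows
#' @param zscore z-scored trace.
#' @param time_s matching times (seconds).
#' @param injection_time_s injection instant (seconds).
#' @param gap_s optional symmetric gap excluded around the injection.
#' @param ... passed to \code{\link{detect_transients}} (each window uses its
#'   own segment SD by default).
#' @export
injection_comparison <- function(zscore, time_s, injection_time_s,
                                 window_s = 300, gap_s = 0, ...) {
  lo <- injection_time_s - gap_s - window_s
  hi <- injection_time_s + gap_s + window_s
  if (lo < time_s[1])
    stop("pre window extends ", format(time_s[1] - lo),
         " s before the recording start")
  if (hi > time_s[length(time_s)])
    stop("post window extends ", format(hi - time_s[length(time_s)]),
         " s past the recording end")
  pre <- detect_transients(zscore, time_s,
                           segment = c(lo, injection_time_s - gap_s), ...)
  post <- detect_transients(zscore, time_s,
                            segment = c(injection_time_s + gap_s, hi), ...)
  wc <- compare_windows(pre, post, window_s = window_s)
  # whole-window integral of z, alongside the per-transient AUC default
  wc$window_auc_pre <- transient_auc(zscore, time_s,
                                     c(lo, injection_time_s - gap_s))
  wc$window_auc_post <- transient_auc(zscore, time_s,
                                      c(injection_time_s + gap_s, hi))
  wc$delta_window_auc <- wc$window_auc_post - wc$window_auc_pre
  wc
}

#' Match detected peaks to ground-truth transient times
#'
#' Greedy nearest-first matching within a tolerance: candidate pairs are
#' ranked by absolute time difference and accepted one at a time, each
#' detected peak and each true transient matching at most once. Returns the
#' recall/precision of the detection against the ground truth.
#'
#' @param detected_times_s detected peak times (seconds).
#' @param true_times_s ground-truth transient (kernel-peak) times.
#' @param tol_s matching tolerance (seconds, default 0.25).
#' @return list with \code{n_matched}, \code{recall}, \code{precision}.
#' @export
match_peaks <- function(detected_times_s, true_times_s, tol_s = 0.25) {
  nd <- length(detected_times_s)
  nt <- length(true_times_s)
  if (nd == 0 || nt == 0)
    return(list(n_matched = 0L,
                recall = if (nt) 0 else NA_real_,
                precision = if (nd) 0 else NA_real_))
  dmat <- abs(outer(detected_times_s, true_times_s, "-"))
  cand <- which(dmat <= tol_s, arr.ind = TRUE)
  cand <- cand[order(dmat[cand]), , drop = FALSE]
  used_d <- logical(nd)
  used_t <- logical(nt)
  n <- 0L
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]
    j <- cand[r, 2]
    if (!used_d[i] && !used_t[j]) {
      used_d[i] <- TRUE
      used_t[j] <- TRUE
      n <- n + 1L
    }
  }
  list(n_matched = n, recall = n / nt, precision = n / nd)
}
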