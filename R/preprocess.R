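# Conversion of raw two-channel fluorescence into dF/F and robust z-score.
# Pipeline order: 8 Hz low-pass -> double-exponential detrend per channel ->
# regression of the smoothed isosbestic onto the signal channel -> dF/F ->
# per-animal robust z from the MAD-filtered concatenated dF/F.

#' Zero-phase Butterworth low-pass filter
#'
#' Applies a Butterworth low-pass forward and backward (zero phase, DC gain
#' exactly 1 in the interior) with odd-reflection padding so that edge
#' transients from the filter start-up decay inside the padding, not the data.
#'
#' @param x numeric trace.
#' @param fs sampling rate (Hz).
#' @param cutoff_hz cutoff frequency; must be below the Nyquist rate.
#' @param order Butterworth order per pass (applied twice).
#' @return filtered trace, same length as \code{x}.
#' @export
lowpass <- function(x, fs, cutoff_hz = 8, order = 2) {
  if (cutoff_hz >= fs / 2)
    stop("cutoff_hz must be below the Nyquist frequency (", fs / 2, " Hz)")
  n <- length(x)
  if (n < 4) return(x)
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  pad <- min(n - 1L, ceiling(10 * fs / cutoff_hz))
  left <- 2 * x[1] - x[seq(pad + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - pad)]
  xp <- c(left, x, right)
  y <- signal::filter(bf, xp)
  y <- rev(as.numeric(signal::filter(bf, rev(as.numeric(y)))))
  y[(pad + 1):(pad + n)]
}

# Variable-projection SSE for a sum of exponentials plus offset: for fixed
# taus the linear coefficients are solved exactly, so the nonlinear search is
# only over the taus. Taus are clamped to [T/1e3, 20T]: beyond that an
# exponential is indistinguishable from the constant term over the session
# and the linear solve degenerates.
clamp_log_taus <- function(log_taus, Tdur) {
  pmin(pmax(log_taus, log(Tdur / 1e3)), log(20 * Tdur))
}

varpro_fit <- function(ts, ys, log_taus, Tdur = max(ts) - min(ts)) {
  taus <- exp(clamp_log_taus(log_taus, Tdur))
  k <- length(taus) + 1L
  n <- length(ts)
  M <- matrix(1, n, k)
  for (j in seq_along(taus)) M[, j] <- exp(-ts / taus[j])
  # tiny ridge on the exponential coefficients only: when a tau is so slow
  # the exponential is flat over the session, constant mass goes to the
  # offset p3 (the operating level) instead of the exponential; bias on
  # identified components is O(1e-8)
  lam <- sqrt(1e-8 * sum(ys^2))
  Maug <- rbind(M, cbind(diag(lam, k - 1, k - 1), 0))
  yaug <- c(ys, numeric(k - 1))
  # photobleach components and floor are physically nonnegative; small
  # active-set NNLS over the (at most 3) linear coefficients
  coefs <- nnls3(Maug, yaug)
  if (is.null(coefs)) return(list(sse = Inf))
  list(sse = sum((ys - M %*% coefs)^2), coefs = coefs, taus = taus)
}

# Nonnegative least squares for a 3-column (or fewer) design: exhaustive
# active-set search over which coefficients are pinned at zero, via the
# normal equations (the design is 2-3 well-scaled columns).
nnls3 <- function(M, y) {
  k <- ncol(M)
  XtX <- crossprod(M)
  Xty <- crossprod(M, y)
  yty <- sum(y^2)
  # unconstrained solution: if feasible it is the NNLS optimum
  b <- try(solve(XtX, Xty), silent = TRUE)
  if (!inherits(b, "try-error") && all(is.finite(b)) && all(b >= 0))
    return(as.numeric(b))
  best <- NULL
  best_sse <- Inf
  for (m in 0:(2^k - 2)) {
    free <- which(bitwAnd(m, 2^(seq_len(k) - 1)) > 0)
    cf <- numeric(k)
    if (length(free) > 0) {
      b <- tryCatch(solve(XtX[free, free, drop = FALSE], Xty[free]),
                    error = function(e) NULL)
      if (is.null(b)) next
      cf[free] <- b
    }
    if (any(cf < 0)) next
    sse <- yty - 2 * sum(cf * Xty) + sum(cf * (XtX %*% cf))
    if (sse < best_sse) {
      best <- cf
      best_sse <- sse
    }
  }
  best
}

#' Remove photobleaching with a double-exponential fit
#'
#' Fits \code{y(t) = p1 exp(-t/tau1) + p2 exp(-t/tau2) + p3} to the whole
#' trace by nonlinear least squares (variable projection over the two taus
#' with multi-start initialization and nonnegative p1, p2, p3, on a
#' deterministic subsample of at most \code{n_fit} points) and removes the
#' within-session variation of the fitted decay:
#' \code{detrended = y - trend(t) + trend(t_end)}, which equals
#' \code{residual + p3} whenever the decay has run its course inside the
#' session. Retaining the fitted terminal fluorescence (rather than the raw
#' \code{p3}) keeps the operating level well-defined even on sessions too
#' short to separate a slow exponential from the constant floor, so the later
#' dF/F division always operates on a physical fluorescence level. If the
#' double-exponential search fails, a single-exponential fit is used with a
#' warning.
#'
#' @param x positive-valued fluorescence trace, length >= 100.
#' @param time_s matching time vector (seconds).
#' @param n_fit maximum number of points used in the fit.
#' @return list with \code{detrended}, \code{trend} (the full fitted
#'   bleach curve including the offset), and \code{coefficients}
#'   (p1, p2, p3, tau1, tau2, model).
#' @export
detrend_double_exp <- function(x, time_s, n_fit = 350) {
  n <- length(x)
  if (n < 100) stop("detrending requires at least 100 samples")
  if (any(x <= 0)) stop("detrending requires a positive-valued trace")
  sub <- unique(round(seq(1, n, length.out = min(n, n_fit))))
  ts <- time_s[sub]; ys <- x[sub]
  # normalize the fit to unit scale so the tau search is exactly equivariant
  # under a common gain on the input (gain-invariance of dF/F downstream)
  y_scale <- median(ys)
  ys <- ys / y_scale
  Tdur <- max(time_s) - min(time_s)
  starts <- list(log(c(Tdur / 10, Tdur)),
                 log(c(Tdur / 20, Tdur / 2)),
                 log(c(Tdur / 5, 2 * Tdur)))
  best <- list(sse = Inf)
  for (s in starts) {
    opt <- tryCatch(
      optim(s, function(lt) varpro_fit(ts, ys, lt, Tdur)$sse,
            method = "Nelder-Mead",
            control = list(maxit = 100, reltol = 1e-9)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (opt$value < best$sse) {
      improved <- best$sse / opt$value - 1
      best <- c(varpro_fit(ts, ys, opt$par, Tdur),
                list(par = clamp_log_taus(opt$par, Tdur)))
    } else improved <- 0
    # further restarts only while they still find materially better optima
    if (is.finite(best$sse) && !is.na(improved) && improved < 1e-4 &&
        !identical(s, starts[[1]])) break
  }
  t_end <- max(time_s)
  if (is.finite(best$sse)) {
    best$coefs <- best$coefs * y_scale
    ord <- order(best$taus)
    taus <- best$taus[ord]
    ps <- best$coefs[ord]
    p3 <- best$coefs[3]
    decay <- ps[1] * (exp(-time_s / taus[1]) - exp(-t_end / taus[1])) +
      ps[2] * (exp(-time_s / taus[2]) - exp(-t_end / taus[2]))
    trend <- ps[1] * exp(-time_s / taus[1]) +
      ps[2] * exp(-time_s / taus[2]) + p3
    return(list(detrended = x - decay, trend = trend,
                coefficients = list(p1 = unname(ps[1]), p2 = unname(ps[2]),
                                    p3 = unname(p3), tau1 = taus[1],
                                    tau2 = taus[2], model = "double_exp")))
  }
  warning("double-exponential fit failed; falling back to single exponential")
  opt1 <- optim(log(Tdur / 3), function(lt) varpro_fit(ts, ys, lt, Tdur)$sse,
                method = "Brent", lower = log(Tdur / 1e3),
                upper = log(20 * Tdur))
  f1 <- varpro_fit(ts, ys, opt1$par, Tdur)
  f1$coefs <- f1$coefs * y_scale
  decay <- f1$coefs[1] * (exp(-time_s / f1$taus[1]) -
                            exp(-t_end / f1$taus[1]))
  list(detrended = x - decay,
       trend = f1$coefs[1] * exp(-time_s / f1$taus[1]) + f1$coefs[2],
       coefficients = list(p1 = unname(f1$coefs[1]), p2 = 0,
                           p3 = unname(f1$coefs[2]), tau1 = f1$taus[1],
                           tau2 = Inf, model = "single_exp"))
}

# Centered moving average with edge-shrinking windows; width 1 is identity.
movavg_centered <- function(x, w) {
  n <- length(x)
  w <- max(1L, as.integer(w))
  if (w == 1L) return(x)
  hl <- (w - 1L) %/% 2L
  hr <- w - 1L - hl
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - hl, 1L)
  hi <- pmin(i + hr, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Regress the smoothed isosbestic channel onto the signal channel
#'
#' Least-squares fit \code{f465 ~ a * smooth(f405) + b}, where the smoothing
#' is a centered moving average of width \code{smooth_window_s}. The fitted
#' 405 trace is the motion/artifact reference used for dF/F.
#'
#' @param f465_d,f405_d detrended signal and isosbestic traces (equal length).
#' @param fs sampling rate (Hz).
#' @param smooth_window_s moving-average width in seconds (>= one sample).
#' @return list with \code{fit405}, slope \code{a}, intercept \code{b}, and
#'   \code{smooth_window_s}.
#' @export
fit_isosbestic <- function(f465_d, f405_d, fs, smooth_window_s = 1) {
  stopifnot(length(f465_d) == length(f405_d))
  w <- max(1L, round(smooth_window_s * fs))
  sm <- movavg_centered(f405_d, w)
  if (var(sm) == 0) {
    warning("smoothed 405 trace has zero variance; slope set to 0")
    a <- 0
    b <- mean(f465_d)
  } else {
    a <- cov(f465_d, sm) / var(sm)
    b <- mean(f465_d) - a * mean(sm)
  }
  list(fit405 = a * sm + b, a = a, b = b, smooth_window_s = smooth_window_s)
}

#' Fractional fluorescence change dF/F
#'
#' \code{(F465 - Ffit405) / reference}, computed sample-wise. By default the
#' reference is the fitted isosbestic trace itself (the classical
#' \code{(F465 - Ffit405)/Ffit405}). The full pipeline passes the signal
#' channel's fitted bleach curve as the reference instead: transients ride
#' multiplicatively on the decaying fluorescence, so dividing by a
#' time-tracking estimate of that level keeps a transient of a given
#' fractional size the same height in dF/F at the start and end of a
#' session, where a constant reference would make late-session transients
#' look smaller. Refuses to divide when the reference approaches zero
#' (floor at \code{1e-6 * median(reference)}) rather than clipping silently.
#'
#' @param f465_d detrended signal trace.
#' @param fit405 fitted isosbestic reference.
#' @param reference strictly positive divisor trace (default \code{fit405}).
#' @return dF/F trace in fractional units.
#' @export
compute_dff <- function(f465_d, fit405, reference = fit405) {
  stopifnot(length(f465_d) == length(fit405),
            length(reference) == length(fit405))
  floor_eps <- 1e-6 * median(reference)
  if (any(reference <= floor_eps))
    stop("dF/F reference falls at/below the division floor (",
         format(floor_eps), ") at ", sum(reference <= floor_eps), " samples")
  (f465_d - fit405) / reference
}

#' Robust z-score scaler from MAD-filtered dF/F
#'
#' Fitted once per animal on the concatenated dF/F of all its sessions:
#' samples farther than 2 x MAD from the raw median are removed as
#' high-amplitude events, then \code{center} is the median of the filtered
#' trace and \code{scale} is the MAD of the filtered trace rescaled to be a
#' consistent estimate of the Gaussian SD. Because the 2 x MAD filter
#' truncates the distribution at 1.349 sigma, the usual 1.4826 factor would
#' underestimate sigma by ~20% even on event-free Gaussian data; the constant
#' used here additionally corrects for that truncation, so on clean Gaussian
#' noise the robust z has unit variance. \code{apply_zscore} maps any session
#' of the same animal through \code{(x - center) / scale}.
#'
#' @param x concatenated dF/F, length >= 100.
#' @return object of class \code{"robust_scaler"} with \code{center},
#'   \code{scale}, \code{filter_threshold}, and a \code{constant} flag.
#' @export
fit_robust_scaler <- function(x) {
  if (length(x) < 100) stop("scaler requires at least 100 samples")
  m0 <- median(x)
  mad0 <- median(abs(x - m0))
  keep <- abs(x - m0) <= 2 * mad0
  centered <- median(x[keep])
  # MAD-to-sigma constant for data truncated at 2 x MAD = 1.349 sigma:
  # solve P(|X| <= m | |X| <= c) = 1/2 for Gaussian X, scale by 1/m
  c_trunc <- 2 * qnorm(0.75)
  k_mad <- 1 / qnorm(0.5 + (2 * pnorm(c_trunc) - 1) / 4)
  scl <- k_mad * median(abs(x[keep] - centered))
  constant <- FALSE
  if (scl == 0) {
    if (all(x == x[1])) constant <- TRUE
    else stop("degenerate trace: robust scale is zero on a non-constant trace")
  }
  structure(list(center = centered, scale = scl,
                 filter_threshold = 2 * mad0, constant = constant),
            class = "robust_scaler")
}

#' @rdname fit_robust_scaler
#' @param dff a dF/F trace.
#' @param scaler a fitted \code{robust_scaler}.
#' @return robust z-scored trace (zeros if the fitted trace was constant).
#' @export
apply_zscore <- function(dff, scaler) {
  stopifnot(inherits(scaler, "robust_scaler"))
  if (scaler$constant) return(numeric(length(dff)) * 0)
  (dff - scaler$center) / scaler$scale
}

#' Full preprocessing of one recording to dF/F
#'
#' Runs low-pass filtering, per-channel double-exponential detrending,
#' isosbestic regression, and dF/F on a \code{raw_recording}. Z-scoring is a
#' separate per-animal step (\code{\link{fit_robust_scaler}} on the
#' concatenated dF/F of all the animal's sessions, then
#' \code{\link{apply_zscore}}); \code{\link{process_subject}} does both for a
#' list of sessions from one animal.
#'
#' @param rec a \code{raw_recording}.
#' @param lowpass_cutoff_hz acquisition low-pass cutoff (Hz).
#' @param smooth_window_s isosbestic smoothing window (s).
#' @param detrend \code{"double_exp"}, \code{"single_exp"}, or \code{"none"}.
#' @return list of class \code{"processed_trace"} with \code{time_s},
#'   \code{dff}, \code{fits} (detrend coefficients per channel, regression a
#'   and b, smoothing window), and \code{lowpass_cutoff_hz}; \code{zscore} is
#'   NULL until a scaler is applied.
#' @export
process_recording <- function(rec, lowpass_cutoff_hz = 8,
                              smooth_window_s = 1,
                              detrend = c("double_exp", "single_exp", "none")) {
  stopifnot(inherits(rec, "raw_recording"))
  detrend <- match.arg(detrend)
  fs <- rec$sampling_rate_hz
  f465 <- lowpass(rec$f465, fs, lowpass_cutoff_hz)
  f405 <- lowpass(rec$f405, fs, lowpass_cutoff_hz)
  if (detrend == "none") {
    d465 <- list(detrended = f465, coefficients = list(model = "none"))
    d405 <- list(detrended = f405, coefficients = list(model = "none"))
  } else {
    d465 <- detrend_double_exp(f465, rec$time_s)
    d405 <- detrend_double_exp(f405, rec$time_s)
  }
  iso <- fit_isosbestic(d465$detrended, d405$detrended, fs, smooth_window_s)
  # divide by the 465 channel's fitted bleach curve: a time-tracking
  # physical level, so fractional transient amplitudes are comparable
  # across the session despite photobleaching
  ref <- if (detrend == "none") iso$fit405 else d465$trend
  dff <- compute_dff(d465$detrended, iso$fit405, reference = ref)
  structure(list(time_s = rec$time_s, dff = dff, zscore = NULL,
                 sampling_rate_hz = fs, session = rec$session,
                 sensor = rec$sensor,
                 fits = list(detrend_465 = d465$coefficients,
                             detrend_405 = d405$coefficients,
                             a = iso$a, b = iso$b,
                             smooth_window_s = smooth_window_s),
                 lowpass_cutoff_hz = lowpass_cutoff_hz),
            class = "processed_trace")
}

#' @rdname process_recording
#' @param recordings list of \code{raw_recording}s from one animal.
#' @param ... passed to \code{process_recording}.
#' @return list with \code{traces} (processed traces with \code{zscore}
#'   filled) and the fitted \code{scaler}.
#' @export
process_subject <- function(recordings, ...) {
  traces <- lapply(recordings, process_recording, ...)
  scaler <- fit_robust_scaler(unlist(lapply(traces, `[[`, "dff")))
  traces <- lapply(traces, function(tr) {
    tr$zscore <- apply_zscore(tr$dff, scaler)
    tr
  })
  list(traces = traces, scaler = scaler)
}
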