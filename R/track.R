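#' Behavioral arena geometry
#'
#' Describes the arenas used by the behavioral assays: the two-chamber
#' real-time place preference box (two 25 x 25 cm chambers side by side), the
#' open field (43 x 43 cm with a 21 x 21 cm center zone) with an optional
#' novel object, or a home cage.
#'
#' @param kind arena type.
#' @param chamber_cm side of each place-preference chamber (cm).
#' @param size_cm side of the open field (cm).
#' @param center_cm side of the centered center zone (cm).
#' @param object_xy optional c(x, y) position of a novel object (cm).
#' @param interaction_radius_cm interaction radius around the object; an
#'   interaction is scored when the animal is within this distance or less.
#' @param width_cm,height_cm home-cage dimensions (cm).
#' @return list of class \code{"behavior_arena"}.
#' @export
behavior_arena <- function(kind = c("two_chamber", "open_field", "home_cage"),
                           chamber_cm = 25, size_cm = 43, center_cm = 21,
                           object_xy = NULL, interaction_radius_cm = 2,
                           width_cm = 30, height_cm = 15) {
  kind <- match.arg(kind)
  a <- switch(kind,
    two_chamber = list(kind = kind, width_cm = 2 * chamber_cm,
                       height_cm = chamber_cm, chamber_cm = chamber_cm),
    open_field = list(kind = kind, width_cm = size_cm, height_cm = size_cm,
                      center_cm = center_cm, object_xy = object_xy,
                      interaction_radius_cm = interaction_radius_cm),
    home_cage = list(kind = kind, width_cm = width_cm, height_cm = height_cm))
  if (a$width_cm <= 0 || a$height_cm <= 0)
    stop("arena dimensions must be positive")
  if (kind == "open_field" && center_cm > size_cm)
    stop("center zone must lie within the arena")
  if (!is.null(a$object_xy)) {
    if (a$object_xy[1] < 0 || a$object_xy[1] > a$width_cm ||
        a$object_xy[2] < 0 || a$object_xy[2] > a$height_cm)
      stop("object position lies outside the arena")
    if (interaction_radius_cm <= 0) stop("interaction radius must be positive")
  }
  class(a) <- "behavior_arena"
  a
}

#' Simulate an animal position track
#'
#' Reflected Gaussian random walk confined to the arena. In a two-chamber
#' arena, \code{bias} adds a constant drift along x toward the paired (left,
#' low-x) chamber, so stationary occupancy of the paired chamber increases
#' monotonically with \code{bias}; \code{bias = 0} gives symmetric occupancy.
#'
#' @param arena a \code{\link{behavior_arena}}.
#' @param bias drift strength in \code{[-1, 1]}; positive values favor the
#'   left (paired) chamber, negative the right.
#' @param duration_s track length (seconds).
#' @param seed integer seed.
#' @param rate_hz track sampling rate (Hz, EthoVision-like default 30).
#' @param step_sd per-sample step SD (cm).
#' @param drift_cm maximal per-sample drift at |bias| = 1 (cm).
#' @param start_xy starting position; default arena center.
#' @return a \code{track_session} data frame (t_s, x_cm, y_cm) with the arena
#'   and rate attached as attributes.
#' @export
simulate_track <- function(arena, bias = 0, duration_s = 300, seed = 1L,
                           rate_hz = 30, step_sd = 1.0, drift_cm = 0.15,
                           start_xy = NULL) {
  stopifnot(inherits(arena, "behavior_arena"))
  if (abs(bias) > 1) stop("bias must lie in [-1, 1]")
  set.seed(as.integer(seed))
  n <- floor(duration_s * rate_hz)
  if (is.null(start_xy)) start_xy <- c(arena$width_cm / 2, arena$height_cm / 2)
  dx <- rnorm(n - 1, -bias * drift_cm, step_sd)
  dy <- rnorm(n - 1, 0, step_sd)
  x <- reflect_walk(start_xy[1], dx, 0, arena$width_cm)
  y <- reflect_walk(start_xy[2], dy, 0, arena$height_cm)
  new_track_session(data.frame(t_s = (seq_len(n) - 1) / rate_hz,
                               x_cm = x, y_cm = y),
                    arena = arena, rate_hz = rate_hz)
}

reflect_walk <- function(x0, steps, lo, hi) {
  x <- numeric(length(steps) + 1)
  x[1] <- x0
  for (i in seq_along(steps)) {
    z <- x[i] + steps[i]
    while (z < lo || z > hi) {
      if (z < lo) z <- 2 * lo - z
      if (z > hi) z <- 2 * hi - z
    }
    x[i + 1] <- z
  }
  x
}
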