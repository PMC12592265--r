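# Route-outcome classification.  Each ascent interacts with a horizontal
# odour band in one of three ways: the ant walks over it, detours around
# its lateral edge, or U-turns back down the trunk.  Trips the recording
# truncates mid-decision are "incomplete" and excluded from denominators.

#' Classify a trajectory's interaction with the odour band
#'
#' Categories:
#' \describe{
#'   \item{walked_over}{some contiguous upward passage through the band's
#'     vertical span stays horizontally inside the band (majority of the
#'     in-span frames inside its x extent; a spanning jump between two
#'     frames is judged at the interpolated mid-span x).}
#'   \item{detour}{the ant gets above the band top, but every upward
#'     passage through the span runs outside the band's x extent.}
#'   \item{u_turn}{the ant approaches within `d_app` below the band,
#'     never reaches above its top, and returns down -- ending below the
#'     band bottom at or beyond the arena's bottom edge (or at least
#'     below its own starting height).}
#'   \item{incomplete}{anything else (e.g. the video ends mid-ascent).}
#' }
#'
#' @param traj an [trajectory()] object.
#' @param arena an [arena_geometry()] object.
#' @param band band rectangle; defaults to `arena$band`.
#' @param d_app approach distance (mm) below the band bottom that counts
#'   as having responded to it; default 100.
#' @return one-row data.frame of class `route_outcome`: `ant_id`,
#'   `session`, `category`, `first_encounter_t`, `crossing_x`,
#'   `max_y_reached`.
#' @export
classify_route <- function(traj, arena, band = arena$band, d_app = 100) {
  x <- traj$thorax_x; y <- traj$thorax_y; tt <- traj$t
  in_arena <- x >= 0 & x <= arena$width & y >= 0 & y <= arena$height
  if (!any(in_arena)) stop_insufficient("trajectory never enters the arena")

  below <- y < band$y_min
  above <- y > band$y_max
  zone <- ifelse(below, 1L, ifelse(above, 3L, 2L))
  n <- length(zone)

  inside_x <- function(xx) xx >= band$x_min & xx <= band$x_max

  # upward transits: below -> (in-span frames) -> above
  transit_inside <- logical(0)
  transit_mid_x <- numeric(0)
  r <- rle(zone)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (k in seq_along(r$values)) {
    if (r$values[k] != 2L) next
    prev <- if (k > 1) r$values[k - 1] else NA_integer_
    nxt <- if (k < length(r$values)) r$values[k + 1] else NA_integer_
    if (identical(prev, 1L) && identical(nxt, 3L)) {
      idx <- starts[k]:ends[k]
      transit_inside <- c(transit_inside, mean(inside_x(x[idx])) >= 0.5)
      transit_mid_x <- c(transit_mid_x, mean(x[idx]))
    }
  }
  # direct below -> above jumps with no in-span frame
  jump <- which(zone[-n] == 1L & zone[-1] == 3L)
  for (i in jump) {
    ymid <- (band$y_min + band$y_max) / 2
    f <- (ymid - y[i]) / (y[i + 1] - y[i])
    xm <- x[i] + f * (x[i + 1] - x[i])
    transit_inside <- c(transit_inside, inside_x(xm))
    transit_mid_x <- c(transit_mid_x, xm)
  }

  reached_above <- any(above)
  approached <- any(y >= band$y_min - d_app)
  first_enc <- if (approached) tt[which(y >= band$y_min - d_app)[1]] else NA_real_
  y_end <- y[n]

  if (reached_above && any(transit_inside)) {
    category <- "walked_over"
    crossing_x <- transit_mid_x[which(transit_inside)[1]]
  } else if (reached_above) {
    category <- "detour"
    crossing_x <- NA_real_
  } else if (approached && y_end < band$y_min &&
             (y_end <= 0 || y_end <= y[1])) {
    category <- "u_turn"
    crossing_x <- NA_real_
  } else {
    category <- "incomplete"
    crossing_x <- NA_real_
  }

  out <- data.frame(ant_id = attr(traj, "ant_id") %||% "ant",
                    session = attr(traj, "session") %||% "session",
                    category = category,
                    first_encounter_t = first_enc,
                    crossing_x = crossing_x,
                    max_y_reached = max(y),
                    stringsAsFactors = FALSE)
  class(out) <- c("route_outcome", "data.frame")
  out
}

#' Outcome frequencies with exact binomial confidence intervals
#'
#' Proportions over the classified categories (`incomplete` trips are
#' excluded from the denominator), with Clopper-Pearson intervals.
#'
#' @param outcomes data.frame with a `category` column (rbind of
#'   [classify_route()] rows), or a character vector of categories.
#' @param conf.level confidence level for the intervals (default 0.95).
#' @return data.frame: `category`, `n`, `proportion`, `ci_lo`, `ci_hi`;
#'   one row per category of the classified set plus an attribute
#'   `n_incomplete`.
#' @export
outcome_frequencies <- function(outcomes, conf.level = 0.95) {
  cats <- if (is.data.frame(outcomes)) outcomes$category else outcomes
  if (length(cats) < 1) stop_insufficient("no classified trajectories")
  n_incomplete <- sum(cats == "incomplete")
  cats <- cats[cats != "incomplete"]
  levels <- c("walked_over", "detour", "u_turn")
  N <- length(cats)
  rows <- lapply(levels, function(lv) {
    k <- sum(cats == lv)
    ci <- if (N > 0) {
      stats::binom.test(k, N, conf.level = conf.level)$conf.int
    } else c(NA_real_, NA_real_)
    data.frame(category = lv, n = k,
               proportion = if (N > 0) k / N else NA_real_,
               ci_lo = ci[1], ci_hi = ci[2], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_incomplete") <- n_incomplete
  out
}
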