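#' Construct an ant trajectory
#'
#' A trajectory is a frame-indexed record of two digitised body points --
#' the tip of the head and the centre of the thorax -- for one ant during
#' one ascent through the recording area.  Coordinates are arena-frame
#' millimetres with the y axis pointing up the trunk.
#'
#' @param t time of each frame in seconds, strictly increasing.
#' @param head_x,head_y head-tip coordinates (mm).
#' @param thorax_x,thorax_y thorax-centre coordinates (mm).
#' @param ant_id opaque label for the individual.
#' @param condition `"control"` or `"test"`.
#' @param session free-form session label (nest / odour / day).
#' @param frame_rate nominal frames per second (default 25).
#' @return a `data.frame` of class `ant_trajectory` with columns
#'   `t, head_x, head_y, thorax_x, thorax_y` and metadata attributes.
#' @export
trajectory <- function(t, head_x, head_y, thorax_x, thorax_y,
                       ant_id = "ant", condition = "control",
                       session = "session", frame_rate = 25) {
  n <- length(t)
  stopifnot(length(head_x) == n, length(head_y) == n,
            length(thorax_x) == n, length(thorax_y) == n)
  if (n >= 2 && any(diff(t) <= 0))
    stop_format("frame times must be strictly increasing")
  if (!is.numeric(frame_rate) || frame_rate <= 0)
    stop_format("frame_rate must be a positive number")
  out <- data.frame(t = as.numeric(t),
                    head_x = as.numeric(head_x), head_y = as.numeric(head_y),
                    thorax_x = as.numeric(thorax_x),
                    thorax_y = as.numeric(thorax_y))
  structure(out,
            ant_id = as.character(ant_id),
            condition = match.arg(condition, c("control", "test")),
            session = as.character(session),
            frame_rate = frame_rate,
            class = c("ant_trajectory", "data.frame"))
}

#' @export
print.ant_trajectory <- function(x, ...) {
  cat(sprintf("<ant_trajectory> %s (%s, %s): %d frames, %.2f s @ %g fps\n",
              attr(x, "ant_id"), attr(x, "condition"), attr(x, "session"),
              nrow(x), if (nrow(x)) max(x$t) - min(x$t) else 0,
              attr(x, "frame_rate")))
  invisible(x)
}

#' Read a digitised trajectory from a tracking-export CSV
#'
#' Reads one row per video frame with head and thorax coordinates, as
#' exported by point-tracking software.  If a `frame` column is present,
#' time is `frame / frame_rate`; a `t` column (seconds) takes precedence;
#' with neither, frames are numbered 0, 1, 2, ... in file order.  Rows
#' with any unparseable or non-finite coordinate are dropped and counted
#' (the count is returned in attribute `n_dropped`).
#'
#' @param path CSV file with a header row.
#' @param frame_rate frames per second used to convert frame indices to
#'   seconds (default 25).
#' @param column_map optional named character vector mapping the canonical
#'   names (`head_x`, `head_y`, `thorax_x`, `thorax_y`, and optionally
#'   `frame` or `t`) to the column names actually present in the file,
#'   e.g. `c(head_x = "pt1_cam1_X")`.
#' @param scale multiplicative factor applied to all coordinates (e.g. a
#'   pixel-to-millimetre calibration); default 1.
#' @param ant_id,condition,session trajectory metadata.
#' @return an [trajectory()] object; attribute `n_dropped` gives the
#'   number of discarded rows.
#' @export
read_trajectory <- function(path, frame_rate = 25, column_map = NULL,
                            scale = 1, ant_id = basename(path),
                            condition = "control", session = "session") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("head_x", "head_y", "thorax_x", "thorax_y")
  name_for <- function(canon) {
    if (!is.null(column_map) && canon %in% names(column_map))
      column_map[[canon]] else canon
  }
  for (canon in need) {
    col <- name_for(canon)
    if (!col %in% names(raw))
      stop_format(sprintf("missing mandatory column '%s'", col))
  }
  coords <- lapply(need, function(canon) {
    suppressWarnings(as.numeric(raw[[name_for(canon)]]))
  })
  names(coords) <- need

  tcol <- name_for("t"); fcol <- name_for("frame")
  if (tcol %in% names(raw)) {
    tt <- suppressWarnings(as.numeric(raw[[tcol]]))
  } else if (fcol %in% names(raw)) {
    tt <- suppressWarnings(as.numeric(raw[[fcol]])) / frame_rate
  } else {
    tt <- (seq_len(nrow(raw)) - 1) / frame_rate
  }

  ok <- is.finite(tt)
  for (v in coords) ok <- ok & is.finite(v)
  n_dropped <- sum(!ok)
  if (sum(ok) < 3)
    stop_insufficient(sprintf(
      "fewer than 3 valid rows in '%s' (%d parsed)", path, sum(ok)))

  traj <- trajectory(tt[ok],
                     coords$head_x[ok] * scale, coords$head_y[ok] * scale,
                     coords$thorax_x[ok] * scale, coords$thorax_y[ok] * scale,
                     ant_id = ant_id, condition = condition,
                     session = session, frame_rate = frame_rate)
  attr(traj, "n_dropped") <- n_dropped
  traj
}

#' Write a trajectory to the package's CSV dialect
#'
#' @param traj an [trajectory()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(frame = round(traj$t * attr(traj, "frame_rate")),
                   head_x = traj$head_x, head_y = traj$head_y,
                   thorax_x = traj$thorax_x, thorax_y = traj$thorax_y)
  write_metrics_table(df, path)
  invisible(path)
}

#' Write / read a per-ant metrics table
#'
#' Plain comma-separated text with a header row.  Numeric fields are
#' written with 17 significant digits so a write/read cycle preserves
#' every value to better than 1e-12.
#'
#' @param records a data.frame (possibly zero rows), one row per ant.
#' @param path output file.
#' @return `path` invisibly (writer); a data.frame (reader).
#' @export
write_metrics_table <- function(records, path) {
  if (!is.data.frame(records))
    records <- as.data.frame(records, stringsAsFactors = FALSE)
  out <- records
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = 17, format = "g")
  }
  tryCatch(
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE),
    error = function(e) stop(sprintf("cannot write '%s': %s",
                                     path, conditionMessage(e))))
  invisible(path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Arena geometry for the recording area and odour band
#'
#' The recording area is the rectangle `[0, width] x [0, height]` in
#' arena-frame millimetres with +y pointing up the trunk.  The default
#' matches a 70 cm wide by 1 m high recording window with a 50 cm by 5 cm
#' horizontal odour strip centred in it.
#'
#' @param width,height recording-area extent in mm.
#' @param band odour-strip rectangle: named list or vector with
#'   `x_min, x_max, y_min, y_max` (mm).  Default: 500 mm wide, 50 mm
#'   tall, centred in the arena.
#' @return a list of class `arena_geometry`.
#' @export
arena_geometry <- function(width = 700, height = 1000, band = NULL) {
  if (is.null(band)) {
    band <- list(x_min = (width - 500) / 2, x_max = (width + 500) / 2,
                 y_min = height / 2 - 25, y_max = height / 2 + 25)
  }
  band <- as.list(band)[c("x_min", "x_max", "y_min", "y_max")]
  if (anyNA(match(c("x_min", "x_max", "y_min", "y_max"), names(band))))
    stop_format("band must supply x_min, x_max, y_min, y_max")
  band <- lapply(band, as.numeric)
  with(band, {
    if (!(x_min < x_max && y_min < y_max))
      stop_format("degenerate band rectangle")
    if (x_min < 0 || x_max > width || y_min <= 0 || y_max >= height)
      stop_format("band must lie strictly inside the arena's vertical extent")
  })
  structure(list(width = width, height = height, band = band),
            class = "arena_geometry")
}

#' @export
print.arena_geometry <- function(x, ...) {
  cat(sprintf(
    "<arena_geometry> %g x %g mm, band x:[%g, %g] y:[%g, %g]\n",
    x$width, x$height, x$band$x_min, x$band$x_max,
    x$band$y_min, x$band$y_max))
  invisible(x)
}
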