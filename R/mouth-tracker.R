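#' Mouth aperture from a 68-point landmark frame
#'
#' Euclidean distance h between the inner upper-lip point P62 and the
#' inner lower-lip point P66 of the standard 68-point facial annotation.
#'
#' @param points A 68 x 2 numeric matrix of (x, y) pixel coordinates,
#'   rows indexed P0--P67.
#' @return Aperture in pixels.
#' @export
mouth_aperture <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || nrow(points) != 68L || ncol(points) != 2L) {
    stop("a landmark frame must contain exactly 68 (x, y) points")
  }
  p62 <- points[63L, ]  # P62, 0-based landmark index
  p66 <- points[67L, ]
  sqrt(sum((p66 - p62)^2))
}

#' Classify mouth state from aperture
#'
#' Open iff h strictly exceeds the threshold (default 10 pixels; the
#' value is resolution-dependent).
#'
#' @param h Aperture in pixels (non-negative).
#' @param open_threshold Open-mouth threshold in pixels.
#' @return `"OPEN"` or `"CLOSED"` (vectorized over `h`).
#' @export
classify_mouth <- function(h, open_threshold = 10) {
  if (any(h < 0)) stop("aperture must be non-negative")
  ifelse(h > open_threshold, "OPEN", "CLOSED")
}

.aperture_series <- function(frames) {
  sqrt((frames$p66x - frames$p62x)^2 + (frames$p66y - frames$p62y)^2)
}

#' Segment a landmark stream into open/closed interval events
#'
#' Per-frame states are computed with [classify_mouth()]; frames whose
#' detector confidence falls below `conf_threshold` carry the previous
#' frame's state forward so timing is preserved through brief detector
#' failures. Runs shorter than `debounce_frames` are absorbed into the
#' surrounding state, and each maximal run becomes one event whose
#' duration is the run's timestamp span plus one median frame period.
#'
#' @param frames Data frame with columns `t_ms`, `p0x`, `p0y`, ...,
#'   `p67x`, `p67y` and optionally `confidence` (see
#'   [read_landmark_csv()]); timestamps strictly increasing.
#' @param open_threshold Open-mouth threshold in pixels.
#' @param debounce_frames Minimum run length kept as its own state.
#' @param conf_threshold Confidence below which a frame's state is
#'   carried forward.
#' @return Data frame of events: `state` (`"OPEN"`/`"CLOSED"`),
#'   `start_ms`, `duration_ms`.
#' @export
segment_events <- function(frames, open_threshold = 10, debounce_frames = 2L,
                           conf_threshold = 0.7) {
  if (nrow(frames) == 0L) {
    return(data.frame(state = character(0), start_ms = numeric(0),
                      duration_ms = numeric(0)))
  }
  t <- frames$t_ms
  if (is.unsorted(t, strictly = TRUE)) {
    stop("frame timestamps must be strictly increasing")
  }
  if (nrow(frames) < 2L) stop("at least two frames are required")
  states <- classify_mouth(.aperture_series(frames), open_threshold)
  if (!is.null(frames$confidence)) {
    low <- frames$confidence < conf_threshold
    for (i in seq_along(states)) {
      if (low[i] && i > 1L) states[i] <- states[i - 1L]
    }
  }
  states <- .debounce(states, debounce_frames)
  r <- rle(states)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dt <- stats::median(diff(t))
  data.frame(state = r$values,
             start_ms = t[starts],
             duration_ms = t[ends] - t[starts] + dt)
}

# Merge runs shorter than min_len into the neighbouring state. Short runs
# take the state of the preceding kept run (or the following one at the
# stream head), applied iteratively until stable.
.debounce <- function(states, min_len) {
  min_len <- as.integer(min_len)
  if (min_len <= 1L) return(states)
  repeat {
    r <- rle(states)
    if (length(r$lengths) <= 1L) return(states)
    short <- which(r$lengths < min_len)
    if (length(short) == 0L) return(states)
    i <- short[1L]
    r$values[i] <- if (i > 1L) r$values[i - 1L] else r$values[i + 1L]
    states <- inverse.rle(r)
  }
}

#' Reconstruct per-frame states from an event table
#'
#' Inverse of [segment_events()] at a given frame rate; used for
#' round-trip checks.
#'
#' @param events Event data frame (`state`, `start_ms`, `duration_ms`).
#' @param fps Frames per second.
#' @return Data frame with `t_ms` and `state`.
#' @export
events_to_states <- function(events, fps = 30) {
  stopifnot(fps > 0)
  dt <- 1000 / fps
  total <- sum(events$duration_ms)
  t <- seq(events$start_ms[1L], events$start_ms[1L] + total - dt / 2, by = dt)
  bounds <- cumsum(c(0, events$duration_ms)) + events$start_ms[1L]
  # look states up at frame-period centers so event boundaries that
  # coincide with frame times (the common case after segmentation at the
  # same rate) are never hit by floating-point ties
  idx <- findInterval(t + dt / 2, bounds, rightmost.closed = FALSE)
  idx[idx > nrow(events)] <- nrow(events)
  data.frame(t_ms = t, state = events$state[idx])
}

#' Read / write landmark and interval CSV streams
#'
#' Landmark CSV columns: `t_ms, p0x, p0y, ..., p67x, p67y, confidence`.
#' Interval CSV columns: `state, start_ms, duration_ms`.
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_landmark_csv <- function(path) {
  frames <- utils::read.csv(path, check.names = FALSE)
  need <- landmark_columns()
  missing <- setdiff(setdiff(need, "confidence"), names(frames))
  if (length(missing) > 0L) {
    stop("landmark CSV is missing column(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  frames
}

#' @rdname read_landmark_csv
#' @param frames Landmark data frame.
#' @export
write_landmark_csv <- function(frames, path) {
  utils::write.csv(frames, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_landmark_csv
#' @export
read_interval_csv <- function(path) {
  ev <- utils::read.csv(path)
  need <- c("state", "start_ms", "duration_ms")
  if (!all(need %in% names(ev))) {
    stop("interval CSV must have columns state, start_ms, duration_ms")
  }
  if (!all(ev$state %in% c("OPEN", "CLOSED"))) {
    stop("interval states must be OPEN or CLOSED")
  }
  ev[need]
}

#' @rdname read_landmark_csv
#' @param events Interval event data frame.
#' @export
write_interval_csv <- function(events, path) {
  utils::write.csv(events[c("state", "start_ms", "duration_ms")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Column names of the landmark CSV schema
#' @return Character vector `t_ms, p0x, p0y, ..., p67y, confidence`.
#' @export
landmark_columns <- function() {
  pts <- as.vector(rbind(paste0("p", 0:67, "x"), paste0("p", 0:67, "y")))
  c("t_ms", pts, "confidence")
}
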