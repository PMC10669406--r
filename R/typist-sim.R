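#' Synthetic typist profile
#'
#' Parameters of the timing-stream generator that emulates a person
#' typing Morse code with mouth movements. All mean durations are in
#' milliseconds; every generated duration is multiplied by log-normal
#' jitter `exp(N(0, jitter_cv))` and by a linear drift ramp running from
#' 1 at the first event to `drift_factor` at the last (drift > 1 models
#' gradual slowing from fatigue).
#'
#' @param dot_ms Mean short-opening (dot) duration. Default 200.
#' @param element_ratio Dash/dot duration ratio. Default 3.
#' @param short_gap_ms Mean intra-character closing duration. Default 200.
#' @param gap_ratio Long-closing / short-closing ratio. Default 3.
#' @param jitter_cv Coefficient of variation of the multiplicative
#'   log-normal jitter; 0 disables noise.
#' @param drift_factor Multiplicative change in all mean durations from
#'   stream start to end; 1 is stationary.
#' @param seed Integer RNG seed; makes streams fully reproducible.
#' @return An object of class `typist_profile`.
#' @export
typist_profile <- function(dot_ms = 200, element_ratio = 3,
                           short_gap_ms = 200, gap_ratio = 3,
                           jitter_cv = 0, drift_factor = 1, seed = 1L) {
  stopifnot(dot_ms > 0, element_ratio > 1, short_gap_ms > 0, gap_ratio > 1,
            jitter_cv >= 0, drift_factor > 0)
  structure(list(dot_ms = dot_ms, element_ratio = element_ratio,
                 short_gap_ms = short_gap_ms, gap_ratio = gap_ratio,
                 jitter_cv = jitter_cv, drift_factor = drift_factor,
                 seed = as.integer(seed)),
            class = "typist_profile")
}

#' Preset typist profiles
#'
#' `"expert"` mimics practised, steady typing (low jitter, no drift);
#' `"disabled"` mimics typing by a person with a motor impairment
#' (higher jitter plus gradual slowing across the stream).
#'
#' @param name `"expert"` or `"disabled"`.
#' @param seed Integer RNG seed.
#' @return A `typist_profile`.
#' @export
preset_profile <- function(name = c("expert", "disabled"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
         expert   = typist_profile(jitter_cv = 0.05, drift_factor = 1, seed = seed),
         disabled = typist_profile(jitter_cv = 0.15, drift_factor = 1.5, seed = seed))
}

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a ground-truth-labeled timing stream
#'
#' For each character of `text`, each Morse element becomes an OPEN event
#' (`dot_ms` for a dot, `dot_ms * element_ratio` for a dash), elements
#' within a character are separated by short CLOSED events, and each
#' character is terminated by a long CLOSED event
#' (`short_gap_ms * gap_ratio`). Jitter and drift are then applied per
#' event.
#'
#' @param text Text to type (must be encodable by `table`).
#' @param profile A `typist_profile`.
#' @param table A `code_table`.
#' @return An object of class `labeled_stream`: a list with `events`
#'   (data frame `state`, `start_ms`, `duration_ms`), `element_labels`
#'   (`"SHORT"`/`"LONG"` per event), `text` and `profile`.
#' @export
generate_timing_stream <- function(text, profile = typist_profile(),
                                   table = morse_table()) {
  seqs <- encode_text(text, table)
  states <- character(0)
  base <- numeric(0)
  labels <- character(0)
  dash_ms <- profile$dot_ms * profile$element_ratio
  long_gap <- profile$short_gap_ms * profile$gap_ratio
  for (elems in seqs) {
    for (j in seq_along(elems)) {
      states <- c(states, "OPEN")
      if (elems[j] == ".") {
        base <- c(base, profile$dot_ms); labels <- c(labels, "SHORT")
      } else {
        base <- c(base, dash_ms); labels <- c(labels, "LONG")
      }
      if (j < length(elems)) {
        states <- c(states, "CLOSED")
        base <- c(base, profile$short_gap_ms); labels <- c(labels, "SHORT")
      }
    }
    states <- c(states, "CLOSED")
    base <- c(base, long_gap); labels <- c(labels, "LONG")
  }
  n <- length(base)
  ramp <- if (n > 1L) 1 + (profile$drift_factor - 1) * (seq_len(n) - 1) / (n - 1)
          else rep(1, n)
  jitter <- if (profile$jitter_cv > 0) {
    .with_seed(profile$seed, exp(stats::rnorm(n, 0, profile$jitter_cv)))
  } else rep(1, n)
  dur <- base * ramp * jitter
  events <- data.frame(state = states,
                       start_ms = cumsum(c(0, dur[-n])),
                       duration_ms = dur)
  structure(list(events = events, element_labels = labels,
                 text = gsub("[[:space:]]", "", tolower(text)),
                 profile = profile),
            class = "labeled_stream")
}

#' Render a timing stream as a synthetic landmark stream
#'
#' Frames are sampled at `fps`; during OPEN events the P62/P66 separation
#' equals `open_h`, during CLOSED events `closed_h`. The remaining 66
#' points are constant (a fixed schematic face), so the stream exercises
#' only the aperture rule.
#'
#' @param stream A `labeled_stream` (or an event data frame).
#' @param fps Frames per second. Default 30.
#' @param open_h Aperture in pixels during OPEN events (> 10).
#' @param closed_h Aperture during CLOSED events (<= 10).
#' @return A landmark data frame in the [read_landmark_csv()] schema.
#' @export
generate_landmark_stream <- function(stream, fps = 30, open_h = 15,
                                     closed_h = 2) {
  stopifnot(fps > 0, open_h > 10, closed_h <= 10, closed_h >= 0)
  events <- if (inherits(stream, "labeled_stream")) stream$events else stream
  states <- events_to_states(events, fps)
  n <- nrow(states)
  # schematic 68-point face: P62 at (100, 100), everything else parked on
  # a circle; only P66 moves
  base_x <- round(100 + 40 * cos(seq(0, 2 * pi, length.out = 68)), 2)
  base_y <- round(100 + 40 * sin(seq(0, 2 * pi, length.out = 68)), 2)
  base_x[63L] <- 100; base_y[63L] <- 100
  frames <- matrix(rep(as.vector(rbind(base_x, base_y)), each = n), nrow = n)
  colnames(frames) <- landmark_columns()[-c(1L, 138L)]
  frames <- as.data.frame(frames)
  frames$p66x <- 100
  frames$p66y <- 100 + ifelse(states$state == "OPEN", open_h, closed_h)
  cbind(t_ms = states$t_ms, frames, confidence = 1)
}
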