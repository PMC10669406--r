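# Straight-line transliteration of the adaptive threshold update loop
# (limitation, clamped prediction error, five triangular sets,
# center-of-gravity defuzzification, additive update). Deliberately
# shares no code with the package implementation; used to cross-check
# ftr_step()/ftr_run() trajectories.
oracle_ftr_trajectory <- function(I, Y0, L = 100, divisor = 3, mult = 2) {
  A <- c(-1, -0.5, 0, 0.5, 1)
  B <- c(-1, -0.5, 0, 0.5, 1)
  w <- 0.5
  y <- Y0
  Y <- numeric(length(I))
  elements <- character(length(I))
  for (k in seq_along(I)) {
    th <- y * mult
    elements[k] <- if (I[k] >= th) "LONG" else "SHORT"
    x <- if (I[k] < th) I[k] else I[k] / divisor
    e <- (x - y) / L
    if (e > 1) e <- 1
    if (e < -1) e <- -1
    S <- pmax(0, 1 - abs(e - A) / w)
    ep <- sum(S * B) / sum(S)
    y <- y + ep * L
    Y[k] <- y
  }
  list(Y = Y, elements = elements)
}

# noise-free event stream for a text, as a plain data frame
noise_free_events <- function(text, dot_ms = 200) {
  generate_timing_stream(text, typist_profile(dot_ms = dot_ms))$events
}

# random duration sequence mixing two time scales, for property tests
random_durations <- function(n, dot_ms = 200) {
  is_long <- stats::runif(n) < 0.4
  base <- ifelse(is_long, 3 * dot_ms, dot_ms)
  base * exp(stats::rnorm(n, 0, 0.1))
}
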