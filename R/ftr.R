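#' Fuzzy time recognition (FTR) configuration
#'
#' All tunable constants of the adaptive duration-threshold controller.
#' The controller tracks a base value Y (on the dot/short-element time
#' scale) and classifies each incoming duration against
#' `threshold = Y * threshold_multiplier`. Durations at or above the
#' threshold are first divided by `limitation_divisor`, which brings a
#' dash (nominally 3x a dot) back onto the dot scale before the
#' prediction error is computed.
#'
#' @param L Error tolerance range in milliseconds; one controller step can
#'   move Y by at most `L`. Default 100 ms.
#' @param limitation_divisor Divisor applied to above-threshold durations
#'   before error computation. Default 3, the nominal dash/dot ratio.
#' @param threshold_multiplier Ratio of classification threshold to Y.
#'   Default 2, placing the threshold midway between the dot scale (1x)
#'   and the dash scale (3x).
#' @param set_centers_A Five ascending centers in \[-1, 1\] of the input
#'   (fuzzifier) sets LN, SN, ZE, SP, LP.
#' @param set_centers_B Five ascending central values in \[-1, 1\] of the
#'   output (defuzzifier) sets.
#' @param membership_half_width Half-width of the triangular membership
#'   functions (dimensionless). With the default centers and half-width
#'   0.5 neighbouring sets overlap and grades sum to 1 on \[-1, 1\].
#' @param init_frames Minimum number of warm-up durations M buffered
#'   before the initial threshold is estimated. Default 3.
#' @param warmup_max Hard cap on the warm-up length: with the default
#'   `"split"` estimator, warm-up extends past `init_frames` until the
#'   buffer spans both time scales (max/min at least half the nominal
#'   dash/dot ratio), because a homogeneous buffer cannot reveal whether
#'   its durations are dots or dashes; at `warmup_max` durations the
#'   buffer is assumed to be all short elements and initialization
#'   proceeds. Default 10.
#' @param init_method How Y(0) is estimated from the warm-up buffer:
#'   `"split"` (default) places Y at the mean of the buffer's short
#'   cluster (durations within `limitation_divisor / 2` of the minimum),
#'   waiting for both scales as described under `warmup_max`; `"min"`
#'   uses the smallest of the first `init_frames` durations; `"mean"`
#'   uses mean(first `init_frames`)/`threshold_multiplier`. The last two
#'   never extend the warm-up.
#' @param Y0_override Optional fixed Y(0) in ms; skips warm-up entirely.
#' @param adaptive If `FALSE` the threshold is initialized but never
#'   updated (fixed-threshold baseline for comparisons).
#' @return An object of class `ftr_config`.
#' @export
ftr_config <- function(L = 100,
                       limitation_divisor = 3,
                       threshold_multiplier = 2,
                       set_centers_A = c(-1, -0.5, 0, 0.5, 1),
                       set_centers_B = c(-1, -0.5, 0, 0.5, 1),
                       membership_half_width = 0.5,
                       init_frames = 3L,
                       warmup_max = 10L,
                       init_method = c("split", "min", "mean"),
                       Y0_override = NULL,
                       adaptive = TRUE) {
  init_method <- match.arg(init_method)
  stopifnot(L > 0, limitation_divisor > 1, threshold_multiplier > 1,
            membership_half_width > 0, init_frames >= 1,
            warmup_max >= init_frames)
  if (length(set_centers_A) != 5L || length(set_centers_B) != 5L) {
    stop("exactly five fuzzy sets are required on each side")
  }
  if (is.unsorted(set_centers_A, strictly = TRUE) ||
      is.unsorted(set_centers_B, strictly = TRUE)) {
    stop("fuzzy set centers must be strictly ascending")
  }
  if (!is.null(Y0_override)) stopifnot(Y0_override > 0)
  structure(list(L = L,
                 limitation_divisor = limitation_divisor,
                 threshold_multiplier = threshold_multiplier,
                 set_centers_A = set_centers_A,
                 set_centers_B = set_centers_B,
                 membership_half_width = membership_half_width,
                 init_frames = as.integer(init_frames),
                 warmup_max = as.integer(warmup_max),
                 init_method = init_method,
                 Y0_override = Y0_override,
                 adaptive = adaptive),
            class = "ftr_config")
}

#' Read an FTR configuration from a YAML file
#'
#' Keys mirror the arguments of [ftr_config()]; missing keys keep their
#' defaults.
#'
#' @param path YAML file path.
#' @return An `ftr_config`.
#' @export
read_ftr_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(ftr_config))
  extra <- setdiff(names(vals), known)
  if (length(extra) > 0L) {
    stop("unknown FTR config key(s): ", paste(extra, collapse = ", "))
  }
  do.call(ftr_config, vals)
}

#' Fresh controller state
#'
#' @param cfg An `ftr_config`. With `Y0_override` set the state starts
#'   initialized; otherwise it buffers the first `init_frames` durations.
#' @return An object of class `ftr_state` with fields `Y` (threshold base,
#'   ms), `threshold` (`Y * threshold_multiplier`), `k` (step index) and
#'   `warmup_buffer`.
#' @export
ftr_state <- function(cfg = ftr_config()) {
  st <- list(Y = NA_real_, threshold = NA_real_, k = 0L,
             warmup_buffer = numeric(0), initialized = FALSE)
  class(st) <- "ftr_state"
  if (!is.null(cfg$Y0_override)) {
    st$Y <- cfg$Y0_override
    st$threshold <- cfg$Y0_override * cfg$threshold_multiplier
    st$initialized <- TRUE
  }
  st
}

#' Limitation function: normalize a duration against the threshold
#'
#' Durations below the threshold pass unchanged; durations at or above it
#' are divided by `limitation_divisor`, mapping dashes near the dot scale.
#'
#' @param I Duration in ms (non-negative).
#' @param threshold Current classification threshold in ms.
#' @param cfg An `ftr_config`.
#' @return Limited duration x in ms.
#' @export
limit_input <- function(I, threshold, cfg = ftr_config()) {
  if (any(I < 0)) stop("durations must be non-negative")
  stopifnot(threshold > 0)
  ifelse(I < threshold, I, I / cfg$limitation_divisor)
}

#' Clamped prediction error
#'
#' `(x - Y_prev) / L`, clamped to \[-1, 1\].
#'
#' @param x Limited duration in ms.
#' @param Y_prev Previous threshold base in ms.
#' @param L Error tolerance range in ms.
#' @return Dimensionless error in \[-1, 1\].
#' @export
prediction_error <- function(x, Y_prev, L) {
  stopifnot(L > 0)
  pmin(1, pmax(-1, (x - Y_prev) / L))
}

#' Fuzzy inference with center-of-gravity defuzzification
#'
#' The error is fuzzified over five triangular sets (LN, SN, ZE, SP, LP)
#' centred at `set_centers_A`; the correction is the membership-weighted
#' mean of the output central values `set_centers_B`. With the default
#' symmetric sets this is an odd, piecewise-linear map of \[-1, 1\] onto
#' itself.
#'
#' @param e Error in \[-1, 1\] (clamping is [prediction_error()]'s job).
#' @param cfg An `ftr_config`.
#' @return Defuzzified correction e' in
#'   `[min(set_centers_B), max(set_centers_B)]`.
#' @export
fuzzy_correction <- function(e, cfg = ftr_config()) {
  if (any(e < -1 | e > 1)) stop("error must lie in [-1, 1]")
  vapply(e, function(ei) {
    grades <- pmax(0, 1 - abs(ei - cfg$set_centers_A) / cfg$membership_half_width)
    total <- sum(grades)
    if (total <= 0) {
      # possible only under non-covering custom sets; nearest center wins
      grades[which.min(abs(ei - cfg$set_centers_A))] <- 1
      total <- 1
    }
    sum(grades * cfg$set_centers_B) / total
  }, numeric(1))
}

#' Apply one threshold update
#'
#' `Y(k) = Y(k-1) + e' * L`; `threshold = Y(k) * threshold_multiplier`.
#'
#' @param state An initialized `ftr_state`.
#' @param e_prime Defuzzified correction.
#' @param cfg An `ftr_config`.
#' @return Updated `ftr_state`.
#' @export
update_threshold <- function(state, e_prime, cfg = ftr_config()) {
  if (!state$initialized) stop("controller state is not initialized")
  Y <- state$Y + e_prime * cfg$L
  if (Y <= 0) stop("controller divergence: threshold base driven to <= 0")
  state$Y <- Y
  state$threshold <- Y * cfg$threshold_multiplier
  state$k <- state$k + 1L
  state
}

#' Classify a duration as short or long
#'
#' Long iff the duration is at or above the threshold in force before the
#' current step's update (the unit delay in the controller loop).
#'
#' @param I Duration in ms.
#' @param state An initialized `ftr_state`.
#' @return `"SHORT"` or `"LONG"`.
#' @export
classify_element <- function(I, state) {
  if (!state$initialized) stop("controller not ready: still in warm-up")
  ifelse(I >= state$threshold, "LONG", "SHORT")
}

# A warm-up buffer spanning both time scales separates dots from dashes;
# the cut sits at half the nominal dash/dot ratio.
.warmup_ready <- function(buffer, cfg) {
  n <- length(buffer)
  if (n < cfg$init_frames) return(FALSE)
  if (cfg$init_method != "split") return(TRUE)
  n >= cfg$warmup_max ||
    (min(buffer) > 0 && max(buffer) / min(buffer) >= cfg$limitation_divisor / 2)
}

.ftr_initialize <- function(buffer, cfg) {
  Y0 <- switch(cfg$init_method,
               split = {
                 shorts <- buffer[buffer <= min(buffer) * cfg$limitation_divisor / 2]
                 mean(shorts)
               },
               min  = min(buffer),
               mean = mean(buffer) / cfg$threshold_multiplier)
  if (Y0 <= 0) stop("warm-up durations give a non-positive initial threshold")
  Y0
}

#' One controller step
#'
#' During warm-up (fewer than `init_frames` durations seen and no
#' `Y0_override`) the duration is buffered and no element is emitted.
#' Once initialized each step classifies against the previous threshold,
#' limits the input, computes the clamped prediction error, defuzzifies
#' it and updates the threshold.
#'
#' @param state An `ftr_state`.
#' @param I Duration in ms.
#' @param cfg An `ftr_config`.
#' @return A list with `element` (`"SHORT"`/`"LONG"`, or `NA` during
#'   warm-up), intermediates `x`, `e`, `e_prime`, `threshold_prev`, and
#'   `new_state`.
#' @export
ftr_step <- function(state, I, cfg = ftr_config()) {
  if (length(I) != 1L || is.na(I) || I < 0) stop("duration must be one non-negative number")
  if (!state$initialized) {
    state$warmup_buffer <- c(state$warmup_buffer, I)
    if (.warmup_ready(state$warmup_buffer, cfg)) {
      state$Y <- .ftr_initialize(state$warmup_buffer, cfg)
      state$threshold <- state$Y * cfg$threshold_multiplier
      state$initialized <- TRUE
    }
    return(list(element = NA_character_, x = NA_real_, e = NA_real_,
                e_prime = NA_real_, threshold_prev = NA_real_,
                new_state = state))
  }
  threshold_prev <- state$threshold
  element <- classify_element(I, state)
  x <- limit_input(I, threshold_prev, cfg)
  e <- prediction_error(x, state$Y, cfg$L)
  e_prime <- fuzzy_correction(e, cfg)
  if (cfg$adaptive) {
    state <- update_threshold(state, e_prime, cfg)
  } else {
    state$k <- state$k + 1L
  }
  list(element = element, x = x, e = e, e_prime = e_prime,
       threshold_prev = threshold_prev, new_state = state)
}

#' Run the controller over a duration sequence
#'
#' Offline driver: feeds every duration through [ftr_step()]. Durations
#' consumed during warm-up are classified retrospectively against the
#' initial threshold once it exists, so every input receives an element
#' label.
#'
#' @param durations Numeric vector of durations in ms.
#' @param cfg An `ftr_config`.
#' @return A list with `elements` (character vector, `"SHORT"`/`"LONG"`;
#'   `NA` only if the stream ends before initialization) and `trace`, a
#'   data frame with one row per duration: `k`, `I`, `element`, `x`, `e`,
#'   `e_prime`, `Y`, `threshold` (values after the step; `x`/`e`/`e_prime`
#'   are `NA` for warm-up rows).
#' @export
ftr_run <- function(durations, cfg = ftr_config()) {
  n <- length(durations)
  st <- ftr_state(cfg)
  elements <- character(n)
  x <- e <- ep <- Yv <- th <- rep(NA_real_, n)
  warmup_idx <- integer(0)
  for (i in seq_len(n)) {
    was_init <- st$initialized
    res <- ftr_step(st, durations[i], cfg)
    st <- res$new_state
    elements[i] <- res$element
    x[i] <- res$x; e[i] <- res$e; ep[i] <- res$e_prime
    Yv[i] <- st$Y; th[i] <- st$threshold
    if (!was_init) {
      warmup_idx <- c(warmup_idx, i)
      if (st$initialized) {
        elements[warmup_idx] <-
          ifelse(durations[warmup_idx] >= st$threshold, "LONG", "SHORT")
        th[warmup_idx] <- st$threshold
        Yv[warmup_idx] <- st$Y
      }
    }
  }
  if (!st$initialized && length(st$warmup_buffer) > 0) {
    # stream ended inside warm-up: initialize from whatever was buffered
    st$Y <- .ftr_initialize(st$warmup_buffer, cfg)
    st$threshold <- st$Y * cfg$threshold_multiplier
    st$initialized <- TRUE
    elements[warmup_idx] <-
      ifelse(durations[warmup_idx] >= st$threshold, "LONG", "SHORT")
    th[warmup_idx] <- st$threshold
    Yv[warmup_idx] <- st$Y
  }
  list(elements = elements,
       trace = data.frame(k = seq_len(n), I = durations, element = elements,
                          x = x, e = e, e_prime = ep, Y = Yv, threshold = th),
       state = st)
}
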