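#' Illumination compensation parameters
#'
#' @param c Output scale constant (> 0).
#' @param v Logarithm parameter; the log base is `v + 1`. Default 9
#'   (base-10 log), which with `c = 1` fixes both endpoints of \[0, 1\].
#' @param gamma Gamma exponent; values > 1 darken (brightness reduction),
#'   values < 1 brighten. Default 2.
#' @param dark_mean_cutoff Mean intensity below which the log transform
#'   is selected.
#' @param bright_mean_cutoff Mean intensity above which the gamma
#'   transform is selected.
#' @return An object of class `compensation_params`.
#' @export
compensation_params <- function(c = 1, v = 9, gamma = 2,
                                dark_mean_cutoff = 0.3,
                                bright_mean_cutoff = 0.7) {
  stopifnot(c > 0, v > 0, gamma > 0, dark_mean_cutoff < bright_mean_cutoff)
  structure(list(c = c, v = v, gamma = gamma,
                 dark_mean_cutoff = dark_mean_cutoff,
                 bright_mean_cutoff = bright_mean_cutoff),
            class = "compensation_params")
}

.clip01 <- function(values, like) {
  matrix(pmin(1, pmax(0, values)), nrow(like), ncol(like))
}

.check_gray <- function(img) {
  img <- as.matrix(img)
  if (!is.numeric(img)) stop("image must be a numeric matrix")
  if (any(img < 0 | img > 1, na.rm = TRUE)) {
    stop("intensities must be normalized to [0, 1]")
  }
  img
}

#' Logarithmic intensity transform
#'
#' `S = c * log_{v+1}(1 + v * r)`, clipped to \[0, 1\]. Expands the dark
#' range of an under-exposed image; with `c = 1` the endpoints 0 and 1
#' are fixed for every `v > 0`.
#'
#' @param img Numeric matrix of intensities in \[0, 1\].
#' @param params A `compensation_params`.
#' @return Transformed matrix in \[0, 1\].
#' @export
log_transform <- function(img, params = compensation_params()) {
  img <- .check_gray(img)
  if (params$v <= 0) stop("v must be positive")
  out <- params$c * log1p(params$v * img) / log(params$v + 1)
  .clip01(out, img)
}

#' Gamma (power-law) intensity transform
#'
#' `S = c * r^gamma`, clipped to \[0, 1\].
#'
#' @inheritParams log_transform
#' @return Transformed matrix in \[0, 1\].
#' @export
gamma_transform <- function(img, params = compensation_params()) {
  img <- .check_gray(img)
  if (params$gamma <= 0) stop("gamma must be positive")
  .clip01(params$c * img^params$gamma, img)
}

#' Choose a compensation transform from global brightness
#'
#' Log transform for under-exposed images (mean intensity below the dark
#' cutoff), gamma for over-exposed ones (mean above the bright cutoff),
#' none in between.
#'
#' @inheritParams log_transform
#' @return `"NONE"`, `"LOG"` or `"GAMMA"`.
#' @export
select_compensation <- function(img, params = compensation_params()) {
  m <- mean(.check_gray(img))
  if (m < params$dark_mean_cutoff) "LOG"
  else if (m > params$bright_mean_cutoff) "GAMMA"
  else "NONE"
}

#' Apply the automatically selected compensation
#'
#' @inheritParams log_transform
#' @return List with `image` (possibly transformed) and `method`.
#' @export
auto_compensate <- function(img, params = compensation_params()) {
  method <- select_compensation(img, params)
  img <- switch(method,
                LOG = log_transform(img, params),
                GAMMA = gamma_transform(img, params),
                NONE = .check_gray(img))
  list(image = img, method = method)
}

#' Rotate a grayscale image about its center
#'
#' Bilinear resampling on the same-size canvas; samples falling outside
#' the source are filled by edge replication so content near the border
#' is not lost to cropping.
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param angle_deg Rotation in degrees, counter-clockwise positive.
#' @return Rotated matrix of the same dimensions.
#' @export
rotate_image <- function(img, angle_deg) {
  img <- .check_gray(img)
  if (angle_deg %% 360 == 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  th <- angle_deg * pi / 180
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  # inverse map: for each output pixel find its source location
  out_r <- matrix(seq_len(nr), nr, nc)
  out_c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dy <- out_r - cy; dx <- out_c - cx
  src_x <-  cos(th) * dx + sin(th) * dy + cx
  src_y <- -sin(th) * dx + cos(th) * dy + cy
  x0 <- floor(src_x); y0 <- floor(src_y)
  fx <- src_x - x0; fy <- src_y - y0
  cl <- function(v, n) pmin(n, pmax(1, v))
  at <- function(r, c) img[cbind(cl(r, nr), cl(c, nc))]
  val <- (1 - fx) * (1 - fy) * at(y0, x0) +
         fx * (1 - fy) * at(y0, x0 + 1) +
         (1 - fx) * fy * at(y0 + 1, x0) +
         fx * fy * at(y0 + 1, x0 + 1)
  matrix(pmin(1, pmax(0, val)), nr, nc)
}

#' Confidence-driven automatic image straightening
#'
#' Evaluates the detector confidence on the unrotated image; while it is
#' below `threshold`, candidate rotations are explored in `step_deg`
#' increments until the confidence reaches the threshold or the candidate
#' angle magnitude exceeds 180 degrees. Each candidate rotation counts as
#' one adjustment.
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param confidence_fn Detector adapter: either `function(image)` or
#'   `function(image, angle)` returning a confidence in \[0, 1\] (`angle`
#'   is the candidate rotation applied, in degrees).
#' @param threshold Confidence required to stop (default 0.7).
#' @param step_deg Rotation step in degrees (default 5).
#' @param direction Search order: `"auto"` alternates sign with growing
#'   magnitude (+s, -s, +2s, -2s, ...); `"pos"` / `"neg"` step one-sided.
#' @return List of class `straighten_result`: `angle` (degrees applied),
#'   `adjustments` (candidate rotations tried), `confidence` (final),
#'   `success`, and `image` (the winning rotation, or the input on
#'   failure).
#' @export
straighten <- function(img, confidence_fn, threshold = 0.7, step_deg = 5,
                       direction = c("auto", "pos", "neg")) {
  direction <- match.arg(direction)
  stopifnot(threshold > 0, threshold < 1, step_deg > 0)
  img <- .check_gray(img)
  eval_conf <- function(image, angle) {
    if (length(formals(confidence_fn)) >= 2L) confidence_fn(image, angle)
    else confidence_fn(image)
  }
  conf0 <- eval_conf(img, 0)
  if (conf0 >= threshold) {
    return(structure(list(angle = 0, adjustments = 0L, confidence = conf0,
                          success = TRUE, image = img),
                     class = "straighten_result"))
  }
  n_max <- floor(180 / step_deg)
  angles <- switch(direction,
                   auto = as.vector(rbind(seq_len(n_max), -seq_len(n_max))) * step_deg,
                   pos  = seq_len(n_max) * step_deg,
                   neg  = -seq_len(n_max) * step_deg)
  adjustments <- 0L
  best_conf <- conf0
  for (a in angles) {
    adjustments <- adjustments + 1L
    rot <- rotate_image(img, a)
    conf <- eval_conf(rot, a)
    if (conf >= threshold) {
      return(structure(list(angle = a, adjustments = adjustments,
                            confidence = conf, success = TRUE, image = rot),
                       class = "straighten_result"))
    }
    best_conf <- max(best_conf, conf)
  }
  structure(list(angle = 0, adjustments = adjustments, confidence = best_conf,
                 success = FALSE, image = img),
            class = "straighten_result")
}
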