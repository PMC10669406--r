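# build a 68 x 2 point matrix with a chosen P62 -> P66 offset
make_points <- function(p62 = c(100, 50), p66 = c(100, 50)) {
  pts <- matrix(rep(c(10, 20), each = 68), ncol = 2)
  pts[63, ] <- p62
  pts[67, ] <- p66
  pts
}

# landmark frames at fixed spacing with a given aperture sequence
make_frames <- function(h, dt = 33, confidence = 1) {
  n <- length(h)
  base <- as.data.frame(matrix(5, n, 136))
  names(base) <- landmark_columns()[2:137]
  base$p62x <- rep(100, n); base$p62y <- rep(100, n)
  base$p66x <- rep(100, n); base$p66y <- 100 + h
  cbind(t_ms = (seq_len(n) - 1) * dt, base,
        confidence = rep(confidence, length.out = n))
}

test_that("mouth aperture is the P62-P66 Euclidean distance", {
  expect_equal(mouth_aperture(make_points()), 0)
  expect_equal(mouth_aperture(make_points(c(100, 50), c(103, 54))), 5)
  expect_equal(mouth_aperture(make_points(c(0, 0), c(0, 12))), 12)
  expect_error(mouth_aperture(matrix(0, 67, 2)), "68")
  # translation invariance
  pts <- make_points(c(10, 20), c(14, 23))
  shifted <- pts + matrix(rep(c(31, -17), each = 68), ncol = 2)
  expect_equal(mouth_aperture(shifted), mouth_aperture(pts))
})

test_that("the open-mouth rule is strict at the pixel threshold", {
  expect_identical(classify_mouth(12), "OPEN")
  expect_identical(classify_mouth(10), "CLOSED")
  expect_identical(classify_mouth(0), "CLOSED")
  expect_identical(classify_mouth(10.5, open_threshold = 10), "OPEN")
  expect_error(classify_mouth(-1), "non-negative")
})

test_that("segmentation turns state runs into timed events", {
  frames <- make_frames(c(rep(15, 15), rep(2, 15)), dt = 33)
  ev <- segment_events(frames)
  expect_identical(ev$state, c("OPEN", "CLOSED"))
  expect_equal(ev$duration_ms, c(15 * 33, 15 * 33))
  expect_equal(ev$start_ms[1], 0)
  # all-closed stream: a single event spanning the stream
  ev1 <- segment_events(make_frames(rep(2, 30)))
  expect_identical(ev1$state, "CLOSED")
  expect_equal(ev1$duration_ms, 30 * 33)
  # empty stream, malformed timestamps
  expect_equal(nrow(segment_events(make_frames(numeric(0)))), 0)
  bad <- make_frames(rep(15, 5)); bad$t_ms <- rev(bad$t_ms)
  expect_error(segment_events(bad), "increasing")
})

test_that("single-frame flicker is debounced into the surrounding state", {
  frames <- make_frames(c(rep(15, 10), 2, rep(15, 10)))
  ev <- segment_events(frames, debounce_frames = 2)
  expect_identical(ev$state, "OPEN")
  expect_equal(nrow(ev), 1)
  # without debouncing the flicker survives
  ev0 <- segment_events(frames, debounce_frames = 1)
  expect_equal(nrow(ev0), 3)
})

test_that("low-confidence frames carry the previous state forward", {
  h <- c(rep(15, 10), rep(2, 10))
  conf <- rep(1, 20); conf[11:12] <- 0.4
  frames <- make_frames(h, confidence = conf)
  ev <- segment_events(frames, debounce_frames = 1)
  # the two dropped frames stay OPEN, so the OPEN run is two frames longer
  expect_equal(ev$duration_ms[1], 12 * 33)
  expect_equal(sum(ev$duration_ms), 20 * 33)
})

test_that("event durations conserve the covered time span", {
  set.seed(11)
  for (rep in 1:10) {
    h <- ifelse(runif(60) < 0.5, 15, 2)
    ev <- segment_events(make_frames(h), debounce_frames = 1)
    expect_equal(sum(ev$duration_ms), 60 * 33)
  }
})

test_that("segmentation is idempotent on its own reconstruction", {
  truth <- generate_timing_stream("par", typist_profile())
  frames <- generate_landmark_stream(truth, fps = 30)
  ev1 <- segment_events(frames)
  frames2 <- generate_landmark_stream(ev1, fps = 30)
  ev2 <- segment_events(frames2)
  expect_identical(ev1$state, ev2$state)
  expect_equal(ev1$duration_ms, ev2$duration_ms, tolerance = 1e-8)
})

test_that("landmark and interval CSVs round-trip", {
  frames <- make_frames(c(15, 15, 2, 2))
  fp <- withr::local_tempfile(fileext = ".csv")
  write_landmark_csv(frames, fp)
  expect_equal(read_landmark_csv(fp), frames)
  ev <- segment_events(frames, debounce_frames = 1)
  ip <- withr::local_tempfile(fileext = ".csv")
  write_interval_csv(ev, ip)
  expect_equal(read_interval_csv(ip), ev)
  writeLines("state,start_ms\nOPEN,0", ip)
  expect_error(read_interval_csv(ip), "duration_ms")
})
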