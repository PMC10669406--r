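test_that("limitation function passes short durations and divides long ones", {
  cfg <- ftr_config()
  expect_equal(limit_input(400, 600, cfg), 400)
  expect_equal(limit_input(900, 600, cfg), 300)
  expect_equal(limit_input(600, 600, cfg), 200)  # boundary is inclusive
  expect_error(limit_input(-1, 600, cfg), "non-negative")
})

test_that("prediction error is scaled by L and clamped to [-1, 1]", {
  expect_equal(prediction_error(400, 400, 100), 0)
  expect_equal(prediction_error(500, 400, 100), 1)
  expect_equal(prediction_error(100, 400, 100), -1)
  expect_equal(prediction_error(430, 400, 100), 0.3)
})

test_that("center-of-gravity defuzzification with default sets", {
  cfg <- ftr_config()
  expect_equal(fuzzy_correction(0, cfg), 0)
  expect_equal(fuzzy_correction(1, cfg), 1)
  expect_equal(fuzzy_correction(-1, cfg), -1)
  expect_equal(fuzzy_correction(0.25, cfg), 0.25)  # ZE and SP each at grade 0.5
  expect_error(fuzzy_correction(1.2, cfg), "\\[-1, 1\\]")
  # odd symmetry under the default symmetric sets
  e <- seq(0, 1, by = 0.05)
  expect_equal(fuzzy_correction(-e, cfg), -fuzzy_correction(e, cfg))
  # output bounded by the defuzzifier central values
  ep <- fuzzy_correction(seq(-1, 1, by = 0.01), cfg)
  expect_true(all(ep >= min(cfg$set_centers_B) & ep <= max(cfg$set_centers_B)))
})

test_that("threshold update law and classification boundary", {
  cfg <- ftr_config(Y0_override = 400)
  st <- ftr_state(cfg)
  up <- update_threshold(st, 0.5, cfg)
  expect_equal(up$Y, 450); expect_equal(up$threshold, 900)
  expect_equal(update_threshold(st, 0, cfg)$threshold, 800)
  dn <- update_threshold(st, -1, cfg)
  expect_equal(dn$Y, 300); expect_equal(dn$threshold, 600)
  st$threshold <- 600
  expect_identical(classify_element(700, st), "LONG")
  expect_identical(classify_element(200, st), "SHORT")
  expect_identical(classify_element(600, st), "LONG")  # inclusive
  expect_error(classify_element(100, ftr_state(ftr_config())), "warm-up")
})

test_that("single controller steps match hand traces", {
  cfg <- ftr_config(Y0_override = 200)
  # stationary dots are a fixed point
  st <- ftr_state(cfg)
  for (i in 1:10) {
    r <- ftr_step(st, 200, cfg)
    st <- r$new_state
    expect_identical(r$element, "SHORT")
  }
  expect_equal(st$Y, 200); expect_equal(st$threshold, 400)
  # a dash at the fixed point: limited back to the dot scale, no drift
  r <- ftr_step(ftr_state(cfg), 600, cfg)
  expect_identical(r$element, "LONG")
  expect_equal(r$x, 200); expect_equal(r$e, 0)
  expect_equal(r$new_state$threshold, 400)
  # an off-threshold dot drags Y by a full L
  r <- ftr_step(ftr_state(cfg), 300, cfg)
  expect_identical(r$element, "SHORT")
  expect_equal(r$x, 300); expect_equal(r$e, 1); expect_equal(r$e_prime, 1)
  expect_equal(r$new_state$Y, 300); expect_equal(r$new_state$threshold, 600)
})

test_that("warm-up buffers, extends on homogeneous input, then initializes", {
  cfg <- ftr_config()  # split estimator, M = 3
  st <- ftr_state(cfg)
  for (I in c(600, 600, 600)) {  # all dashes: scale still ambiguous
    r <- ftr_step(st, I, cfg)
    st <- r$new_state
    expect_true(is.na(r$element))
  }
  expect_false(st$initialized)
  r <- ftr_step(st, 200, cfg)  # both scales now seen
  st <- r$new_state
  expect_true(st$initialized)
  expect_equal(st$Y, 200)  # short cluster mean
  expect_equal(st$threshold, 400)
  # homogeneous stream: cap forces all-short initialization
  st <- ftr_state(cfg)
  for (i in seq_len(cfg$warmup_max)) st <- ftr_step(st, 200, cfg)$new_state
  expect_true(st$initialized)
  expect_equal(st$threshold, 400)
  # fixed-M estimators do not extend
  for (m in c("min", "mean")) {
    cfgm <- ftr_config(init_method = m)
    st <- ftr_state(cfgm)
    for (I in c(200, 600, 200)) st <- ftr_step(st, I, cfgm)$new_state
    expect_true(st$initialized)
    expect_equal(st$Y, if (m == "min") 200 else mean(c(200, 600, 200)) / 2)
  }
})

test_that("ftr_run labels warm-up events and matches the step-by-step path", {
  cfg <- ftr_config(Y0_override = 200)
  durs <- c(200, 600, 200, 200, 600)
  run <- ftr_run(durs, cfg)
  st <- ftr_state(cfg)
  for (i in seq_along(durs)) {
    r <- ftr_step(st, durs[i], cfg)
    st <- r$new_state
    expect_identical(run$elements[i], r$element)
    expect_equal(run$trace$Y[i], st$Y)
  }
  # warm-up events get retrospective labels under the default config
  run2 <- ftr_run(c(200, 200, 600, 200), ftr_config())
  expect_identical(run2$elements, c("SHORT", "SHORT", "LONG", "SHORT"))
  # stream ending inside warm-up still yields labels
  run3 <- ftr_run(c(200, 210), ftr_config())
  expect_false(any(is.na(run3$elements)))
})

test_that("trajectories agree with an independent straight-line oracle", {
  set.seed(42)
  cfg <- ftr_config(Y0_override = 200)
  for (rep in 1:200) {
    durs <- random_durations(25)
    run <- ftr_run(durs, cfg)
    orc <- oracle_ftr_trajectory(durs, Y0 = 200)
    expect_equal(run$trace$Y, orc$Y)
    expect_identical(run$elements, orc$elements)
  }
})

test_that("clamping bounds every error and every threshold move", {
  set.seed(7)
  cfg <- ftr_config(Y0_override = 150)
  for (rep in 1:20) {
    durs <- random_durations(100)
    tr <- ftr_run(durs, cfg)$trace
    expect_true(all(abs(tr$e) <= 1))
    expect_true(all(abs(diff(c(150, tr$Y))) <= cfg$L + 1e-12))
  }
})

test_that("threshold tracks a drifting dot duration", {
  # dot drifts 200 -> 400 ms over 500 elements, dash = 3 x dot, alternating
  n <- 500
  dot <- seq(200, 400, length.out = n)
  I <- ifelse(seq_len(n) %% 2 == 1, dot, 3 * dot)
  run <- ftr_run(I, ftr_config())
  after_warmup <- 11:n
  expect_true(all(run$trace$threshold[after_warmup] > dot[after_warmup]))
  expect_true(all(run$trace$threshold[after_warmup] < 3 * dot[after_warmup]))
  expect_identical(run$elements,
                   ifelse(seq_len(n) %% 2 == 1, "SHORT", "LONG"))
})

test_that("configuration is validated and loadable from YAML", {
  expect_error(ftr_config(L = 0), "L > 0")
  expect_error(ftr_config(set_centers_A = c(0, 1, 2)), "five")
  expect_error(ftr_config(set_centers_B = c(1, 0.5, 0, -0.5, -1)), "ascending")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("L: 80", "init_frames: 4", "init_method: mean"), path)
  cfg <- read_ftr_config(path)
  expect_equal(cfg$L, 80)
  expect_equal(cfg$init_frames, 4L)
  expect_identical(cfg$init_method, "mean")
  expect_equal(cfg$limitation_divisor, 3)
  writeLines("bogus_key: 1", path)
  expect_error(read_ftr_config(path), "bogus_key")
})
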