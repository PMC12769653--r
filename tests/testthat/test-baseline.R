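test_that("subtractive and divisive corrections match the worked examples", {
  st <- make_state(list(c(5, 6, 7)), event = list(rep("fixation", 3)))
  st <- suppressMessages(baseline_correct(st, event = "fixation",
                                          last_k = 3))
  b <- st$steps[[1]]$stats$baseline
  expect_equal(b, 6)
  expect_equal(st$data$pp_bc, c(5, 6, 7) - 6)

  st2 <- make_state(list(c(5, 10)), event = list(rep("fixation", 2)))
  st2 <- suppressMessages(baseline_correct(st2, event = "fixation",
                                           last_k = 1, method = "divisive"))
  expect_equal(st2$data$pp_bc, c(0.5, 1))   # b = 10 (last sample)
})

test_that("the stored baseline is exactly the mean of the last k window samples", {
  set.seed(5)
  fixlen <- 300
  tr <- c(1000 + rnorm(fixlen, 0, 4), rep(1200, 200))
  ev <- c(rep("fixation", fixlen), rep("letters", 200))
  st <- make_state(list(tr), event = list(ev))
  st <- suppressMessages(baseline_correct(st, event = "fixation",
                                          last_k = 100))
  m <- mean(tr[(fixlen - 99):fixlen])
  expect_equal(st$steps[[1]]$stats$baseline, m, tolerance = 1e-12)
  expect_equal(st$data$pp_bc, tr - m, tolerance = 1e-12)
})

test_that("numeric and per-trial windows resolve on the trial clock", {
  st <- make_state(list(c(10, 20, 30, 40), c(100, 200, 300, 400)))
  st <- suppressMessages(baseline_correct(st, window = c(0, 1), last_k = 2))
  expect_equal(st$steps[[1]]$stats$baseline, c(15, 150))
  win <- data.frame(trial = 1:2, t0 = c(0, 2), t1 = c(0, 3))
  st2 <- make_state(list(c(10, 20, 30, 40), c(100, 200, 300, 400)))
  st2 <- suppressMessages(baseline_correct(st2, window = win, last_k = 2))
  expect_equal(st2$steps[[1]]$stats$baseline, c(10, 350))
})

test_that("unresolvable or empty windows flag the trial", {
  st <- make_state(list(c(NA, NA, NA, 5, 6)),
                   event = list(c("fixation", "fixation", "fixation",
                                  "letters", "letters")))
  st <- suppressMessages(baseline_correct(st, event = "fixation",
                                          last_k = 3))
  rec <- st$steps[[1]]$stats
  expect_false(rec$succeeded)
  expect_true(all(is.na(st$data$pp_bc)))
  st2 <- make_state(list(c(5, 0, 0)), event = list(rep("fixation", 3)))
  st2 <- suppressMessages(baseline_correct(st2, event = "fixation",
                                           last_k = 2, method = "divisive"))
  expect_false(st2$steps[[1]]$stats$succeeded)   # b = 0 divisive
  expect_error(suppressMessages(
    baseline_correct(make_state(list(1:3), event = list(rep("a", 3))),
                     event = "fixation")), "unresolvable")
})

test_that("chain_steps composes identically to sequential calls", {
  set.seed(13)
  tr <- 1000 + rnorm(600, 0, 5)
  tr[200:230] <- 0
  tr[400] <- 2000
  ev <- c(rep("fixation", 300), rep("letters", 300))
  mk <- function() make_state(list(tr), event = list(ev))
  chained <- suppressMessages(chain_steps(mk(), list(
    "deblink", "artifact_rejection",
    list(op = "filter_position", region = valid_region(0, 1920, 0, 1080)),
    list(op = "smooth", window = 20),
    "interpolate",
    list(op = "baseline_correct", event = "fixation"))))
  manual <- suppressMessages(
    baseline_correct(
      interpolate_pupil(
        smooth_pupil(
          filter_position(
            artifact_rejection(deblink(mk())),
            valid_region(0, 1920, 0, 1080)),
          window = 20)),
      event = "fixation"))
  expect_identical(chained$data, manual$data)
  expect_identical(chained$current, "pp_db_ar_xy_sm_ip_bc")
  # empty chain is the identity
  st0 <- mk()
  expect_identical(chain_steps(st0, list())$data, st0$data)
})

test_that("a failing step aborts with the step name and partial state", {
  st <- make_state(list(rep(1000, 100)))
  err <- tryCatch(
    suppressMessages(chain_steps(st, list("deblink",
                                          list(op = "downsample",
                                               target_hz = 333)))),
    pupilpipe_chain_error = function(e) e)
  expect_s3_class(err, "pupilpipe_chain_error")
  expect_match(conditionMessage(err), "downsample")
  expect_true("pp_db" %in% names(err$state$data))   # partial state kept
  expect_error(chain_steps(st, list("not_a_step")), "unknown step")
})

test_that("column conservation: each step adds exactly one stage column", {
  set.seed(3)
  tr <- 1000 + rnorm(300, 0, 5)
  st <- make_state(list(tr), event = list(rep("fixation", 300)))
  cols0 <- names(st$data)
  st1 <- suppressMessages(deblink(st))
  expect_identical(setdiff(names(st1$data), cols0), "pp_db")
  expect_identical(st1$data[cols0], st$data[cols0])
  st2 <- suppressMessages(artifact_rejection(st1))
  expect_identical(setdiff(names(st2$data), names(st1$data)), "pp_db_ar")
  expect_identical(st2$data[names(st1$data)], st1$data)
  # steps refuse to overwrite an existing column
  st1b <- st1; st1b$current <- "pp"
  expect_error(suppressMessages(deblink(st1b)), "already exists")
})
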