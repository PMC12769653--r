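test_that("baseline outlier band matches the hand-computed example", {
  v <- c(rep(10, 9), 100)
  rep <- check_baseline_outliers(v, n = 4)
  # median 10, MAD 0: band [10, 10]; only the 100 is outside
  expect_equal(rep$thresholds$lower, 10)
  expect_equal(rep$thresholds$upper, 10)
  expect_identical(rep$flags$outlier, c(rep(FALSE, 9), TRUE))
  # inclusive bounds: identical values are never flagged
  expect_false(any(check_baseline_outliers(rep(7, 12))$flags$outlier))
})

test_that("grouped baseline outliers use per-group bands", {
  df <- data.frame(pt = rep(c("a", "b"), each = 5),
                   baseline = c(10, 10, 10, 10, 40,
                                100, 100, 100, 100, 10))
  rep <- check_baseline_outliers(df, n = 4, group_by = "pt")
  expect_identical(rep$flags$outlier,
                   c(FALSE, FALSE, FALSE, FALSE, TRUE,
                     FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_identical(nrow(rep$thresholds), 2L)
})

test_that("baseline outlier flags agree with a brute-force oracle", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(3:50, 1)
    v <- rnorm(n, 1000, sample(c(1, 20, 200), 1))
    if (runif(1) < 0.4) v[sample(n, 1)] <- 5000
    rep <- check_baseline_outliers(v, n = 4)
    med <- median(v); m <- raw_mad(v)
    expect_identical(rep$flags$outlier, v < med - 4 * m | v > med + 4 * m)
  }
})

test_that("trace outliers flag exactly the shifted trace", {
  base <- 1000 + sin(seq(0, 2 * pi, length.out = 200)) * 20
  traces <- c(replicate(9, base, simplify = FALSE), list(base + 500))
  st <- make_state(traces)
  rep <- check_trace_outliers(st, n = 4)
  # the shifted trial pulls the grand mean up by 50, so its deviation is
  # 450 and everyone else sits at exactly the 50-unit band edge (strict >)
  expect_identical(rep$flags$outlier, c(rep(FALSE, 9), TRUE))
  expect_equal(rep$flags$max_dev[10], 500 * 9 / 10)
  # all identical: zero-width band, strict exit, none flagged
  st2 <- make_state(replicate(5, base, simplify = FALSE))
  expect_false(any(check_trace_outliers(st2)$flags$outlier))
})

test_that("a sharp downward spike beyond the band is flagged", {
  set.seed(12)
  traces <- replicate(9, 1000 + rnorm(100, 0, 2), simplify = FALSE)
  spiky <- 1000 + rnorm(100, 0, 2)
  spiky[50] <- 400   # unremoved blink signature
  st <- make_state(c(traces, list(spiky)))
  rep <- check_trace_outliers(st, n = 4)
  expect_identical(which(rep$flags$outlier), 10L)
})

test_that("trace bands are translation-equivariant", {
  set.seed(41)
  traces <- replicate(6, 1000 + rnorm(150, 0, 10), simplify = FALSE)
  st <- make_state(traces)
  shifted <- make_state(lapply(traces, `+`, 250))
  a <- check_trace_outliers(st, n = 4)
  b <- check_trace_outliers(shifted, n = 4)
  expect_identical(a$flags$outlier, b$flags$outlier)
  expect_equal(b$grand_mean, a$grand_mean + 250)
  expect_equal(b$half_width, a$half_width)
})

test_that("an all-missing trial is reported as unevaluable", {
  st <- make_state(list(rep(1, 50), rep(2, 50), rep(NA_real_, 50)))
  rep <- check_trace_outliers(st)
  expect_identical(rep$unevaluable, "3")
  expect_false(rep$flags$outlier[3])
})

test_that("summary aggregates step records and outlier reports", {
  set.seed(8)
  ok_tr <- 1000 + rnorm(200, 0, 3)
  lossy <- ok_tr; lossy[1:110] <- 0       # 55% missing > 40% cap
  ev <- rep(c("fixation", "letters"), each = 100)
  st <- make_state(list(ok_tr, ok_tr + rnorm(200), ok_tr + rnorm(200),
                        lossy, ok_tr + 400),
                   event = replicate(5, ev, simplify = FALSE))
  st <- suppressMessages(chain_steps(st, list(
    "deblink", list(op = "interpolate"),
    list(op = "baseline_correct", event = "fixation", last_k = 50))))
  rep_b <- check_baseline_outliers(
    st$steps[[3]]$stats, n = 4)
  summ <- summary(st, reports = list(rep_b))
  expect_identical(nrow(summ), 5L)
  expect_identical(summ$interpolated, c(TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_false(summ$baseline_correct_ok[4])   # window all missing
  expect_identical(summ$baseline_outlier, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(summ$deblink_prop_missing[4], 110 / 200, tolerance = 0.05)
})

test_that("validate_trials marks exactly the listed trials and is idempotent", {
  st <- make_state(replicate(10, rep(1, 20), simplify = FALSE))
  st2 <- validate_trials(st, data.frame(trial = 4))
  expect_identical(sum(!st2$data$valid), 20L)
  expect_true(all(st2$data$valid[st2$data$trial != 4]))
  # proportion arithmetic
  expect_equal(mean(st2$data$valid), 1 - 20 / 200)
  # idempotent / replaceable
  st3 <- validate_trials(st2, data.frame(trial = c(4, 7)))
  expect_identical(sum(!st3$data$valid), 40L)
  st4 <- validate_trials(st3, data.frame(trial = integer(0)))
  expect_true(all(st4$data$valid))
  expect_warning(validate_trials(st, data.frame(trial = 99)), "99")
})

test_that("validate_trials commutes with row permutation", {
  st <- make_state(list(rep(1, 10), rep(2, 10), rep(3, 10)))
  perm <- sample(nrow(st$data))
  stp <- st; stp$data <- st$data[perm, ]
  a <- validate_trials(st, data.frame(trial = 2))
  b <- validate_trials(stp, data.frame(trial = 2))
  expect_identical(a$data$valid[perm], b$data$valid)
})

test_that("pupil surface conserves counts and averages sizes", {
  df <- data.frame(trial = 1, trialtime = 0:99,
                   x = c(rep(100, 50), rep(900, 50)),
                   y = c(rep(100, 50), rep(900, 50)),
                   pp = rep(7, 100))
  st <- pupil_processor(df, "trial", sampling_rate = 1000)
  surf <- pupil_surface(st, bins = c(8, 8), mode = "count",
                        xlim = c(0, 1000), ylim = c(0, 1000))
  expect_equal(sum(surf$grid), 100)
  expect_equal(surf$mean_gaze, c(500, 500))   # midpoint of equal clusters
  expect_identical(sum(surf$grid > 0), 2L)
  sz <- pupil_surface(st, bins = c(8, 8), mode = "size",
                      xlim = c(0, 1000), ylim = c(0, 1000))
  expect_true(all(sz$grid[!is.na(sz$grid)] == 7))
  # conservation holds for any binning
  for (b in list(c(3, 5), c(16, 9), c(1, 1))) {
    s <- pupil_surface(st, bins = b)
    expect_equal(sum(s$grid), 100)
  }
  st$data$x <- NA_real_
  expect_error(pupil_surface(st), "no non-missing")
})

test_that("diagnostic figures are written to disk", {
  set.seed(2)
  traces <- replicate(4, 1000 + rnorm(100, 0, 5), simplify = FALSE)
  st <- make_state(traces, event = replicate(4, rep("fixation", 100),
                                             simplify = FALSE))
  st <- suppressMessages(baseline_correct(st, event = "fixation",
                                          last_k = 20))
  rep_b <- check_baseline_outliers(st$steps[[1]]$stats)
  rep_t <- check_trace_outliers(st, column = "pp")
  surf <- pupil_surface(st, bins = c(4, 4))
  f1 <- tempfile(fileext = ".pdf"); f2 <- tempfile(fileext = ".pdf")
  f3 <- tempfile(fileext = ".pdf")
  plot_baseline_histogram(rep_b, f1)
  plot_trace_spaghetti(st, rep_t, f2)
  plot_pupil_surface(surf, f3)
  expect_true(all(file.exists(f1, f2, f3)))
  expect_true(all(file.size(c(f1, f2, f3)) > 0))
  expect_error(plot_pupil_surface(surf, tempfile(fileext = ".bmp")),
               "unsupported")
})
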