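test_that("read_asc recovers a synthetic recording exactly", {
  rec <- make_recording(n_trials = 2, blinks_for = 1)
  res <- read_asc(rec$path, rec$spec)
  s <- res$samples
  expect_identical(nrow(s), sum(vapply(rec$truth, `[[`, integer(1),
                                       "n_samples")))
  expect_setequal(unique(s$trial), c(1L, 2L))
  for (key in names(rec$truth)) {
    tr <- rec$truth[[key]]
    sub <- s[paste(s$block, s$trial, sep = "|") == key, ]
    expect_identical(nrow(sub), tr$n_samples)
    expect_identical(sub$trackertime, as.numeric(tr$trackertime))
    expect_identical(sub$pp, tr$pp)
    expect_identical(sub$x, tr$x)   # "." parsed as NA during plateaus
    expect_identical(sub$trialtime, sub$trackertime - sub$trackertime[1])
    # message pairing: most recent message at or before the sample
    msgs <- tr$messages
    expected_msg <- msgs$text[findInterval(sub$trackertime, msgs$time)]
    expect_identical(sub$msg, expected_msg)
  }
  # events recovered bit-exactly and carry trial identifiers
  ev1 <- res$events[res$events$trial == 1, ]
  tru1 <- rec$truth[["A|1"]]$events
  expect_identical(ev1$kind, tru1$kind)
  expect_identical(ev1$start_time, as.numeric(tru1$start_time))
  expect_identical(ev1$end_time, as.numeric(tru1$end_time))
  expect_true(all(ev1$duration == ev1$end_time - ev1$start_time))
})

test_that("samples outside boundary pairs are discarded", {
  rec <- make_recording(n_trials = 2)
  res <- read_asc(rec$path, rec$spec)
  raw <- readLines(rec$path)
  n_sample_rows <- sum(grepl("^[0-9]", raw))
  expect_lt(nrow(res$samples), n_sample_rows)   # junk between trials dropped
  expect_identical(nrow(res$samples),
                   sum(vapply(rec$truth, `[[`, integer(1), "n_samples")))
})

test_that("malformed rows, stray boundaries and empty files are handled", {
  spec <- default_marker_spec()
  f <- tempfile(fileext = ".asc")
  writeLines(c(
    "** header",
    "MSG\t1000 start fixation A 1",
    "1000\t960.0\t540.0\t1500.0\t...",
    "1001\t.\t.\t0.0\t...",            # track loss row: retained, NA
    "1002\t960.0\t540.0",              # malformed: too few data tokens
    "1003\t960.0\t540.0\t1501.0\t...",
    "MSG\t1003 end feedback A 1",
    "MSG\t2000 end feedback A 2",      # stop without start: ignored
    "MSG\t3000 start fixation A 3"     # unmatched start: dropped
  ), f)
  expect_warning(expect_warning(
    expect_warning(res <- read_asc(f, spec), "malformed"),
    "no open trial"), "unmatched")
  expect_identical(nrow(res$samples), 3L)
  expect_true(is.na(res$samples$x[2]) && is.na(res$samples$y[2]))
  expect_identical(res$samples$pp[2], 0)  # raw zero preserved until deblink
  # boundaries-only file: msg equals the boundary message everywhere
  expect_true(all(res$samples$msg[1:2] == "start fixation A 1"))

  f2 <- tempfile(fileext = ".asc")
  writeLines("** header only", f2)
  expect_warning(res2 <- read_asc(f2, spec), "no start/stop")
  expect_identical(nrow(res2$samples), 0L)
  expect_identical(nrow(res2$events), 0L)
})

test_that("binocular sample rows honour the eye choice", {
  spec <- default_marker_spec()
  f <- tempfile(fileext = ".asc")
  writeLines(c(
    "MSG\t10 start fixation A 1",
    "10\t100.0\t200.0\t1500.0\t700.0\t800.0\t1600.0\t.....",
    "11\t101.0\t201.0\t1501.0\t701.0\t801.0\t1601.0\t.....",
    "MSG\t11 end feedback A 1"), f)
  left <- read_asc(f, spec)$samples
  right <- read_asc(f, spec, eye = "right")$samples
  expect_identical(left$pp, c(1500, 1501))
  expect_identical(right$pp, c(1600, 1601))
  expect_identical(right$x, c(700, 701))
})

test_that("read_many concatenates with a participant column", {
  rec1 <- make_recording(n_trials = 1, seed = 1,
                         path = file.path(tempdir(), "p01.asc"))
  rec2 <- make_recording(n_trials = 1, seed = 2,
                         path = file.path(tempdir(), "p02.asc"))
  both <- read_many(c(rec1$path, rec2$path), rec1$spec)
  expect_setequal(unique(both$participant), c("p01", "p02"))
  single <- read_many(rec1$path, rec1$spec)
  alone <- read_asc(rec1$path, rec1$spec)$samples
  alone$participant <- "p01"
  expect_identical(single, alone)
  expect_error(read_many(character(0), rec1$spec), "at least one")
})

test_that("validate_generic canonicalises and validates", {
  tab <- data.frame(tr = rep(1:2, each = 3), ms = rep(c(0, 10, 20), 2),
                    gx = 1, gy = 2, dil = 5)
  out <- validate_generic(tab, list(trial = "tr", time = "ms", x = "gx",
                                    y = "gy", pupil = "dil"))
  expect_true(all(c("trackertime", "x", "y", "pp", "trialtime") %in%
                    names(out)))
  expect_identical(out$trialtime, rep(c(0, 10, 20), 2))
  expect_error(validate_generic(tab, list(trial = "tr", time = "ms",
                                          x = "gx", y = "gy")),
               "role 'pupil' unmapped")
  bad <- tab
  bad$ms[5:6] <- c(20, 10)   # backward jump inside trial 2
  expect_error(validate_generic(bad, list(trial = "tr", time = "ms",
                                          x = "gx", y = "gy", pupil = "dil")),
               "trial 2")
  dup <- tab; dup$ms[2] <- 0
  expect_error(validate_generic(dup, list(trial = "tr", time = "ms",
                                          x = "gx", y = "gy", pupil = "dil")),
               "duplicate")
})
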