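unit_square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))

test_that("point_in_polygon handles the square cases and boundaries", {
  expect_true(point_in_polygon(c(0.5, 0.5), unit_square))
  expect_false(point_in_polygon(c(2, 2), unit_square))
  # boundary inclusive: edge midpoint and vertex
  expect_true(point_in_polygon(c(1, 0.5), unit_square))
  expect_true(point_in_polygon(c(0, 0), unit_square))
  expect_error(point_in_polygon(c(0, 0), unit_square[1:4, ]), "open")
})

test_that("point_in_polygon agrees with the winding-number oracle", {
  set.seed(73)
  ang <- sort(runif(12, 0, 2 * pi))
  rad <- runif(12, 2, 6)
  poly <- cbind(5 + rad * cos(ang), 5 + rad * sin(ang))
  poly <- rbind(poly, poly[1, ])
  for (i in 1:2000) {
    pt <- runif(2, -1, 11)
    expect_identical(point_in_polygon(pt, poly),
                     oracle_point_in_polygon(pt, poly),
                     info = paste(pt, collapse = ","))
  }
})

test_that("aoi_set validates closure, simplicity and duplicates", {
  expect_error(aoi_set(list(a = rbind(c(0, 0), c(1, 0), c(1, 1)))),
               "closed|4")
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  expect_error(aoi_set(list(a = bowtie)), "self-intersects")
  expect_error(aoi_set(list(a = unit_square, a = unit_square)), "duplicate")
  # list-of-pairs input is accepted
  s <- aoi_set(list(sq = list(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))))
  expect_identical(s$sq[1, ], c(0, 0))
})

test_that("assign_aoi labels by declaration order, outside otherwise", {
  aois <- square_aois()
  fx <- data.frame(trial_id = 1,
                   x = c(300, 1300, 900), y = c(300, 300, 900))
  out <- assign_aoi(fx, aois)
  expect_identical(out$aoi, c("left", "right", "outside"))
  # overlapping AOIs: first declared wins
  ov <- aoi_set(list(first = unit_square * 10,
                     second = rbind(c(5, 5), c(15, 5), c(15, 15), c(5, 15),
                                    c(5, 5))))
  fx2 <- data.frame(x = c(7, 12), y = c(7, 7))
  expect_identical(assign_aoi(fx2, ov)$aoi, c("first", "second"))
})

test_that("nested AOI sets resolve per trial key", {
  nested <- aoi_set(list(
    "A|1" = list(box = unit_square * 100),
    "A|2" = list(box = unit_square * 100 + 500)))
  expect_true(isTRUE(attr(nested, "nested")))
  fx <- data.frame(block = "A", trial = c(1, 2), x = c(50, 50), y = c(50, 50))
  out <- assign_aoi(fx, nested, trial_identifier = c("block", "trial"))
  expect_identical(out$aoi, c("box", "outside"))
  fx_bad <- data.frame(block = "B", trial = 9, x = 1, y = 1)
  expect_error(assign_aoi(fx_bad, nested,
                          trial_identifier = c("block", "trial")), "B\\|9")
})

test_that("compute_aoi_statistics sums counts and durations with zero rows", {
  aois <- square_aois()
  fx <- data.frame(trial_id = 1,
                   x = c(300, 310, 320), y = c(300, 300, 300),
                   duration = c(100, 200, 300))
  out <- compute_aoi_statistics(fx, aois, trial_identifier = "trial_id")
  left <- out[out$aoi == "left", ]
  expect_identical(left$n_fixations, 3L)
  expect_identical(left$total_duration, 600)
  right <- out[out$aoi == "right", ]
  expect_identical(right$n_fixations, 0L)
  expect_identical(right$total_duration, 0)
  expect_setequal(out$aoi, c("left", "right", "outside"))
  # without durations only counts appear
  out2 <- compute_aoi_statistics(fx[c("trial_id", "x", "y")], aois,
                                 trial_identifier = "trial_id")
  expect_false("total_duration" %in% names(out2))
})

test_that("AOI counts and durations are conserved per trial", {
  set.seed(19)
  aois <- square_aois()
  fx <- generate_fixations(aois, list(left = 7, right = 5),
                           outside_count = 4, seed = 31, trial_id = 3)
  out <- compute_aoi_statistics(fx, aois, trial_identifier = "trial_id")
  expect_identical(sum(out$n_fixations), nrow(fx))
  expect_equal(sum(out$total_duration), sum(fx$duration))
})

test_that("assignment is invariant under joint translation", {
  aois <- square_aois()
  fx <- generate_fixations(aois, list(left = 5, right = 5),
                           outside_count = 3, seed = 11)
  shift <- c(123.5, -77.25)
  aois2 <- aoi_set(lapply(aois, function(p)
    sweep(p, 2, -shift)))
  fx2 <- fx; fx2$x <- fx$x + shift[1]; fx2$y <- fx$y + shift[2]
  expect_identical(assign_aoi(fx, aois)$aoi, assign_aoi(fx2, aois2)$aoi)
})

test_that("fixation density peaks, symmetrises and conserves mass", {
  fx <- data.frame(x = 50, y = 40)
  g <- fixation_density(fx, canvas = c(100, 80), bandwidth = 5)
  peak <- which(g == max(g), arr.ind = TRUE)
  expect_identical(as.integer(peak), c(41L, 51L))  # row = y+1, col = x+1
  # two equal fixations: symmetric about the midline
  fx2 <- data.frame(x = c(30, 70), y = c(40, 40))
  g2 <- fixation_density(fx2, canvas = c(100, 80), bandwidth = 5)
  expect_equal(g2[, 2:50], g2[, 100:52], tolerance = 1e-12)  # x and 100 - x
  # interior kernels integrate to the total duration weight
  fx3 <- data.frame(x = c(40, 60), y = c(40, 40),
                    duration = c(200, 300))
  g3 <- fixation_density(fx3, canvas = c(100, 80), bandwidth = 4)
  expect_equal(sum(g3), 500, tolerance = 0.01 * 500)
  expect_identical(sum(fixation_density(fx[0, ], c(50, 50))), 0)
})

test_that("AOI JSON round trips, nested files load, malformed files error", {
  aois <- square_aois()
  f <- tempfile(fileext = ".json")
  save_aois(aois, f)
  back <- load_aois(f)
  expect_identical(names(back), names(aois))
  expect_equal(back$left, aois$left)
  expect_equal(back$right, aois$right)
  nested <- aoi_set(list("A|1" = list(box = unit_square * 100)))
  f2 <- tempfile(fileext = ".json")
  save_aois(nested, f2)
  back2 <- load_aois(f2)
  expect_true(isTRUE(attr(back2, "nested")))
  expect_equal(back2[["A|1"]]$box, nested[["A|1"]]$box)
  f3 <- tempfile(fileext = ".json")
  writeLines('{"a": [[0,0],[1,0]', f3)
  expect_error(load_aois(f3), "malformed")
  # unclosed polygon in an otherwise valid file names the AOI
  f4 <- tempfile(fileext = ".json")
  writeLines('{"open_one": [[0,0],[1,0],[1,1],[0,1]]}', f4)
  expect_error(load_aois(f4), "open_one")
})
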