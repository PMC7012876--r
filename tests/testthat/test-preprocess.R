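test_that("temporal filter emits only fully covered windows", {
  f <- temporal_mean_filter(0:59, times = 0:59, kernel_min = 5, step_min = 1)
  expect_length(f$values, 56)
  expect_equal(f$values[1], 2)    # mean of 0..4
  expect_equal(f$values[56], 57)  # mean of 55..59
  expect_equal(f$times[1], 2.5)   # window center

  const <- temporal_mean_filter(rep(3.5, 20), times = 0:19, 5, 1)
  expect_true(all(const$values == 3.5))

  expect_error(temporal_mean_filter(1:3, times = 0:2, 5, 1), "shorter")
})

test_that("filter output length obeys the closed form", {
  for (n in c(10, 30, 60)) for (w in c(2, 5)) for (s in c(1, 2)) {
    x <- rnorm(n)
    f <- temporal_mean_filter(x, times = seq_len(n) - 1, kernel_min = w, step_min = s)
    expect_length(f$values, length(seq.int(1, n - w + 1, by = s)))
    # values agree with the direct window-mean oracle
    expect_equal(f$values, window_mean_oracle(x, w)[seq.int(1, n - w + 1, by = s)],
                 tolerance = 1e-12)
  }
})

test_that("temporal filter commutes with affine maps", {
  withr::with_seed(42, {
    for (i in 1:10) {
      x <- rnorm(40)
      a <- rnorm(1); b <- rnorm(1)
      f1 <- temporal_mean_filter(a * x + b, 0:39, 5, 1)$values
      f2 <- a * temporal_mean_filter(x, 0:39, 5, 1)$values + b
      expect_equal(f1, f2, tolerance = 1e-12)
    }
  })
})

test_that("block averaging tiles frames and preserves global means", {
  fs <- frame_stack("BV", array(2, c(100, 100, 3)), 0:2)
  g <- block_average(fs, 50)
  expect_equal(dim(g$values), c(2, 2, 3))
  expect_true(all(g$values == 2))

  fs2 <- frame_stack("BV", array(1, c(100, 150, 2)), 0:1)
  expect_equal(dim(block_average(fs2, 50))[1:2], c(2, 3))

  # pixel-scale checkerboard averages to 0.5 in every block
  cb <- outer(1:100, 1:100, function(i, j) (i + j) %% 2)
  fs3 <- frame_stack("BV", array(cb, c(100, 100, 1)), 0)
  expect_true(all(abs(block_average(fs3, 50)$values - 0.5) < 1e-12))

  withr::with_seed(7, {
    fr <- matrix(runif(120 * 130), 120, 130)
    fs4 <- frame_stack("BV", array(fr, c(120, 130, 1)), 0)
    g4 <- block_average(fs4, 50)
    expect_equal(g4$values[, , 1], block_mean_oracle(fr, 50), tolerance = 1e-12)
    # mean of cell values equals mean of the cropped frame
    expect_equal(mean(g4$values[, , 1]), mean(fr[1:100, 1:100]), tolerance = 1e-12)
  })

  expect_error(block_average(frame_stack("BV", array(1, c(30, 30, 2)), 0:1), 50),
               "exceeds")
})

test_that("blocks dominated by non-finite pixels are marked missing", {
  fr <- matrix(1, 100, 100)
  fr[1:40, 1:50] <- NA  # 80% of block (1,1) non-finite
  fs <- frame_stack("BV", array(fr, c(100, 100, 2)), 0:1)
  g <- block_average(fs, 50)
  expect_true(g$missing_mask[1, 1])
  expect_false(g$missing_mask[2, 2])
  expect_true(all(is.na(g$values[1, 1, ])))
})

test_that("block averaging and temporal filtering commute", {
  withr::with_seed(13, {
    arr <- array(runif(40 * 40 * 12, 1, 2), c(40, 40, 12))
    fs <- frame_stack("BV", arr, 0:11)
    a <- filter_grid(block_average(fs, 20), 5, 1)
    b <- block_average(filter_stack(fs, 5, 1), 20)
    expect_equal(a$values, b$values, tolerance = 1e-10)
  })
})

test_that("fractional change follows the forward-difference definition", {
  expect_equal(fractional_change_series(c(100, 110)), 0.1)
  expect_equal(fractional_change_series(c(100, 110, 99)), c(0.1, -0.1))
  expect_true(all(fractional_change_series(rep(5, 10)) == 0))
  # nonpositive denominators flag missing, not an error
  out <- fractional_change_series(c(2, 0, 3, 6))
  expect_true(is.na(out[2]))
  expect_equal(out[3], 1)
})

test_that("windowed reduction is positive for declining signals", {
  expect_equal(windowed_reduction(c(8, 8, 8, 2, 2, 2), 1:3, 4:6), 6)
  expect_equal(windowed_reduction(rep(4, 10), 1:3, 8:10), 0)
  expect_error(windowed_reduction(1:10, integer(0), 4:6), "non-empty")
  expect_error(windowed_reduction(1:10, 1:5, 5:8), "overlap")
})

test_that("preprocessing a constant trial preserves values and metadata", {
  st <- frame_stack("BV", array(7, c(100, 100, 24)), times = (0:23) * 0.5)
  grids <- preprocess_trial(trial("t", list(BV = st)))
  expect_equal(grids$BV$variable, "BV")
  expect_equal(grids$BV$block_px, 50L)
  expect_true(all(grids$BV$values == 7))
  expect_equal(dim(grids$BV$values)[3], 12 - 5 + 1)
})
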