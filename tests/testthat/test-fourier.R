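test_that("the one-sided spectrum matches closed forms", {
  expect_true(all(normalized_power_spectrum(rep(5, 56)) == 0))

  # x = m (1 + c cos(2 pi k t / N)) puts c^2/2 at bin k and nothing elsewhere
  n <- 56; c_mod <- 0.2; k0 <- 2
  t <- 0:(n - 1)
  x <- 3 * (1 + c_mod * cos(2 * pi * k0 * t / n))
  p <- normalized_power_spectrum(x)
  expect_equal(p[k0 + 1], c_mod^2 / 2, tolerance = 1e-12)
  expect_equal(10 * log10(p[k0 + 1]), -16.9897, tolerance = 1e-4)
  expect_lt(max(p[-(k0 + 1)]), 1e-25)

  expect_error(normalized_power_spectrum(rnorm(56) - 5), "positive")
  expect_error(normalized_power_spectrum(rep(1, 4)), "at least 8")
})

test_that("the FFT path equals the direct DFT-sum oracle", {
  withr::with_seed(21, {
    for (n in c(8, 13, 32, 56, 64)) {
      x <- runif(n, 1, 2)
      expect_equal(normalized_power_spectrum(x), dft_power_oracle(x),
                   tolerance = 1e-10)
    }
  })
})

test_that("Parseval holds on random series", {
  withr::with_seed(22, {
    for (i in 1:20) {
      n <- sample(c(20, 56, 57), 1)
      x <- runif(n, 5, 10)
      y <- x / mean(x) - 1
      expect_equal(sum(normalized_power_spectrum(x)), sum(y^2) / n,
                   tolerance = 1e-9)
    }
  })
})

test_that("default bands tile the spectrum at the published operating point", {
  lf <- frequency_band("LF", c(10, 56), n = 56, dt_min = 1)
  hf <- frequency_band("HF", c(2, 10), n = 56, dt_min = 1)
  expect_equal(lf$index_set, 1:5)
  expect_equal(hf$index_set, 6:28)
  expect_length(intersect(lf$index_set, hf$index_set), 0)
  expect_equal(sort(union(lf$index_set, hf$index_set)), 1:28)
})

test_that("band power maps localize planted sinusoids in the right band", {
  n <- 56
  t <- 0:(n - 1)
  mk <- function(period) 100 * (1 + 0.2 * cos(2 * pi * t / period))
  vals <- array(NA_real_, c(1, 2, n))
  vals[1, 1, ] <- mk(28)  # bin 2, LF
  vals[1, 2, ] <- mk(4)   # bin 14, HF
  g <- make_grid(vals, times = t, variable = "BF")
  lf <- frequency_band("LF", c(10, 56), n); hf <- frequency_band("HF", c(2, 10), n)
  lf_map <- band_power_map(g, lf)
  hf_map <- band_power_map(g, hf)
  expect_equal(lf_map[1, 1], 10 * log10(0.02), tolerance = 1e-6)
  expect_true(is.na(lf_map[1, 2]))   # below the -60 dB floor
  expect_equal(hf_map[1, 2], 10 * log10(0.02), tolerance = 1e-6)
  expect_true(is.na(hf_map[1, 1]))
  expect_error(band_power_map(make_grid(vals[, , 1:20, drop = FALSE]), lf), "N = 56")
})

test_that("white-noise band powers are finite and respect Parseval", {
  withr::with_seed(23, {
    x <- runif(56, 50, 100)
    g <- make_grid(array(x, c(1, 1, 56)), times = 0:55)
    bs <- band_spectra(g)
    expect_true(is.finite(bs$power_db$LF[1, 1]))
    expect_true(is.finite(bs$power_db$HF[1, 1]))
    total <- 10^(bs$power_db$LF[1, 1] / 10) + 10^(bs$power_db$HF[1, 1] / 10)
    y <- x / mean(x) - 1
    expect_equal(total, sum(y^2) / 56, tolerance = 1e-9)
  })
})

test_that("band ratios use linear powers and omit sub-floor cells", {
  n <- 56
  t <- 0:(n - 1)
  vals <- array(NA_real_, c(1, 3, n))
  # equal power planted in one LF and one HF bin -> ratio 1
  vals[1, 1, ] <- 100 * (1 + 0.1 * cos(2 * pi * t / 28) + 0.1 * cos(2 * pi * t / 4))
  # HF-only -> LF below floor -> omitted
  vals[1, 2, ] <- 100 * (1 + 0.1 * cos(2 * pi * t / 4))
  # HF power 4x LF power (amplitude 2x)
  vals[1, 3, ] <- 100 * (1 + 0.1 * cos(2 * pi * t / 28) + 0.2 * cos(2 * pi * t / 4))
  g <- make_grid(vals, times = t, variable = "BF")
  ratio <- band_ratio_map(g)
  expect_equal(ratio[1, 1], 1, tolerance = 1e-9)
  expect_true(is.na(ratio[1, 2]))
  expect_equal(ratio[1, 3], 4, tolerance = 0.05 * 4)
})

test_that("power scatter pairs variables at integer-bin periods only", {
  n <- 56
  t <- 0:(n - 1)
  mk <- function() {
    vals <- array(NA_real_, c(1, 2, n))
    both <- function(a56, a28) 100 * (1 + a56 * cos(2 * pi * t / 56) +
                                        a28 * cos(2 * pi * t / 28))
    vals[1, 1, ] <- both(0.1, 0.2)
    vals[1, 2, ] <- both(0.2, 0.1)
    band_spectra(make_grid(vals, times = t, variable = "BF"))
  }
  maps <- list(BF = mk(), BV = mk())
  tab <- power_scatter(maps, periods_min = c(56, 28))
  expect_equal(nrow(tab), 4)
  expect_equal(tab$power_db_BF, tab$power_db_BV, tolerance = 1e-12)
  expect_error(power_scatter(maps, 13), "no integer bin")
})
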