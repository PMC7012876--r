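test_that("the filtered reference shares the data's filter arithmetic", {
  ref <- build_reference(perturbation_paradigm(), cadence_min = 1,
                         kernel_min = 5, step_min = 1)
  expect_length(ref$values, 26)   # 30 - 5 + 1

  # identical code path: equals filtering the raw boxcar directly
  t_raw <- 0:29
  box <- as.numeric(t_raw >= 10 & t_raw < 20)
  manual <- temporal_mean_filter(box, t_raw, 5, 1)
  expect_identical(ref$values, manual$values)
  expect_identical(ref$times, manual$times)

  # plateaus at 0 and 1, with 4-sample linear ramps at each transition
  expect_true(all(ref$values >= 0 & ref$values <= 1))
  ramps <- which(ref$values > 0 & ref$values < 1)
  expect_length(ramps, 8)
  expect_equal(ref$values[ramps[1:4]], c(0.2, 0.4, 0.6, 0.8))

  expect_error(perturbation_paradigm("BASELINE", 30), "STIMULUS")
  expect_error(build_reference(perturbation_paradigm(durations_min = c(1, 1, 1))),
               "shorter")
})

test_that("responsiveness is a strict one-sided correlation rule", {
  ref <- build_reference(perturbation_paradigm())
  n <- length(ref$values)
  withr::with_seed(2, {
    vals <- array(NA_real_, c(1, 3, n))
    vals[1, 1, ] <- ref$values + rnorm(n, 0, 1e-3)   # follows the stimulus
    vals[1, 2, ] <- -ref$values + rnorm(n, 0, 1e-3)  # anti-correlated
    vals[1, 3, ] <- rnorm(n)                          # unrelated
    g <- make_grid(vals, times = ref$times)
    rm <- responsive_mask(g, ref, corr_threshold = 0.7)
    expect_true(rm$mask[1, 1])
    expect_false(rm$mask[1, 2])
    expect_lt(rm$r_map[1, 2], -0.9)
    expect_error(responsive_mask(g, rep(1, n)), "Constant reference")
  })
})

test_that("response magnitude excludes transition ramps and recovers levels", {
  par <- perturbation_paradigm()
  ref <- build_reference(par)
  times <- ref$times
  # noiseless boxcar response: baseline 10, stimulus 14
  series <- 10 + 4 * as.numeric(times >= 10 & times < 20)
  expect_equal(response_magnitude(series, times, par), 4)
  expect_equal(response_magnitude(rep(3, length(times)), times, par), 0)
  # invariance under constant shifts
  expect_equal(response_magnitude(series + 100, times, par), 4)
  expect_error(response_magnitude(series, times, par, kernel_min = 18),
               "clean samples")
})

test_that("planted response magnitudes are recovered within 5%", {
  par <- perturbation_paradigm()
  ref <- build_reference(par)
  times <- ref$times
  truth <- 2.5
  errs <- vapply(1:50, function(seed) {
    withr::with_seed(seed, {
      series <- 10 + truth * (times >= 10 & times < 20) +
        rnorm(length(times), 0, 0.2)
      abs(response_magnitude(series, times, par) - truth) / truth
    })
  }, numeric(1))
  expect_lte(mean(errs), 0.05)
})

test_that("cross-variable scatter pairs only doubly responsive cells", {
  mk_resp <- function(mask, delta) list(
    r_map = matrix(0.9, 2, 2), mask = mask, delta_map = delta)
  m1 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  m2 <- matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2)
  d <- matrix(1:4, 2, 2) * 1.0
  d1 <- d; d1[!m1] <- NA; d2 <- d; d2[!m2] <- NA
  resp <- structure(list(variables = list(BF = mk_resp(m1, d1),
                                          HBSAT = mk_resp(m2, d2))),
                    class = "perturbation_response")
  expect_equal(nrow(response_scatter(resp, "BF", "HBSAT")), 0)

  d3 <- d; resp$variables$HBSAT <- mk_resp(m1, d3 * NA^!m1)
  tab <- response_scatter(resp, "BF", "HBSAT")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$delta_x, tab$delta_y)
})

test_that("planted responders are detected with high sensitivity and specificity", {
  res <- t(sapply(1:5, function(s) {
    sc <- generate_scene(scene_spec("PERTURBATION", image_size = c(200, 200),
                                    cadence_min = 1, seed = s))
    m <- manifest_compare(analyze_perturbation(sc$trial), sc$manifest)
    setNames(m$value, m$metric)
  }))
  expect_gte(mean(res[, "sensitivity_HBSAT"]), 0.95)
  expect_gte(mean(res[, "sensitivity_BF"]), 0.95)
  expect_lte(mean(res[, "delta_mare_BF"]), 0.05)
})

test_that("planted independent responses stay uncorrelated across variables", {
  # deltas drawn independently per cell for the two variables
  withr::with_seed(11, {
    n_cells <- 40
    ref <- build_reference(perturbation_paradigm())
    n <- length(ref$values)
    vals_bf <- array(NA_real_, c(1, n_cells, n))
    vals_hb <- array(NA_real_, c(1, n_cells, n))
    stim <- ref$times >= 10 & ref$times < 20
    dbf <- runif(n_cells, 5, 15); dhb <- runif(n_cells, 5, 15)
    for (j in seq_len(n_cells)) {
      vals_bf[1, j, ] <- 100 + dbf[j] * stim + rnorm(n, 0, 0.5)
      vals_hb[1, j, ] <- 40 + dhb[j] * stim + rnorm(n, 0, 0.5)
    }
    grids <- list(BF = make_grid(vals_bf, ref$times, "BF"),
                  HBSAT = make_grid(vals_hb, ref$times, "HBSAT"))
    resp <- perturbation_response(grids, perturbation_paradigm(),
                                  config = run_config(temporal_step_min = 1))
    tab <- response_scatter(resp, "BF", "HBSAT")
    expect_gt(nrow(tab), 30)
    expect_lt(abs(pearson_oracle(tab$delta_x, tab$delta_y)), 0.35)
  })
})
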