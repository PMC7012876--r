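# Small planted-niche grid: K profiles assigned to cell groups plus white
# noise at a chosen fraction of the signal SD.
planted_niche_grid <- function(R = 6, C = 6, n = 40, K = 3, noise_frac = 0.25,
                               seed = 1, common_profile = FALSE) {
  withr::with_seed(seed, {
    t <- seq_len(n) - 1
    profs <- lapply(seq_len(K), function(g) {
      if (common_profile) sin(2 * pi * t / 16) else
        sin(2 * pi * t / 16 + 2 * pi * (g - 1) / K)
    })
    truth <- matrix(rep_len(seq_len(K), R * C), R, C)
    vals <- array(NA_real_, c(R, C, n))
    sig_sd <- sd(profs[[1]])
    for (i in seq_len(R)) for (j in seq_len(C)) {
      vals[i, j, ] <- profs[[truth[i, j]]] + rnorm(n, 0, noise_frac * sig_sd)
    }
    list(grid = make_grid(vals), truth = truth)
  })
}

test_that("seed correlation maps match the Pearson definition", {
  vals <- array(NA_real_, c(2, 2, 4))
  vals[1, 1, ] <- c(1, 2, 3, 4)
  vals[1, 2, ] <- c(2, 1, 4, 3)
  vals[2, 1, ] <- -c(1, 2, 3, 4)
  vals[2, 2, ] <- rep(5, 4)   # constant: no defined correlation
  g <- make_grid(vals)
  cm <- seed_correlation_map(g, seed = c(1, 1))
  expect_equal(cm$r_values[1, 1], 1)
  expect_equal(cm$r_values[1, 2], 0.6, tolerance = 1e-12)
  expect_equal(cm$r_values[2, 1], -1)
  expect_true(is.na(cm$r_values[2, 2]))

  const <- make_grid(array(1, c(2, 2, 5)))
  expect_warning(cm2 <- seed_correlation_map(const, c(1, 1)), "constant")
  expect_true(all(is.na(cm2$r_values)))
})

test_that("the master correlation matrix is symmetric with unit diagonal", {
  withr::with_seed(5, {
    vals <- array(rnorm(4 * 5 * 30), c(4, 5, 30))
    m <- master_correlation_matrix(make_grid(vals))
    expect_equal(dim(m$matrix), c(20, 20))
    expect_lt(max(abs(m$matrix - t(m$matrix))), 1e-12)
    expect_equal(unname(diag(m$matrix)), rep(1, 20))
    expect_true(all(abs(m$matrix) <= 1 + 1e-12))
  })

  # identical series correlate at exactly 1; orthogonal series at 0
  vals <- array(NA_real_, c(1, 3, 4))
  vals[1, 1, ] <- c(1, 2, 3, 4)
  vals[1, 2, ] <- c(1, 2, 3, 4)
  vals[1, 3, ] <- c(1, -1, -1, 1) + 2.5  # orthogonal to the centered ramp
  m2 <- master_correlation_matrix(make_grid(vals))
  expect_equal(m2$matrix[1, 2], 1)
  expect_lt(abs(m2$matrix[1, 3]), 1e-12)
})

test_that("SVD initialization separates planted structure", {
  # two anticorrelated blocks -> 2 preliminary groups along the sign split
  t <- 0:29
  vals <- array(NA_real_, c(2, 4, 30))
  for (j in 1:4) {
    vals[1, j, ] <- sin(t) + rnorm(30, 0, 0.05)
    vals[2, j, ] <- -sin(t) + rnorm(30, 0, 0.05)
  }
  withr::with_seed(2, {
    m <- master_correlation_matrix(make_grid(vals))
    init <- svd_initial_clusters(m)
    expect_equal(length(unique(init)), 2)
    cells <- m$cell_index
    expect_equal(length(unique(init[cells$cell_row == 1])), 1)
    expect_equal(length(unique(init[cells$cell_row == 2])), 1)
    expect_false(init[cells$cell_row == 1][1] == init[cells$cell_row == 2][1])
  })

  # identical series everywhere -> a single rank-1 group
  same <- array(rep(sin(t), each = 6), c(2, 3, 30))
  m1 <- master_correlation_matrix(make_grid(same))
  expect_equal(length(unique(svd_initial_clusters(m1))), 1)

  # three orthogonal profiles recovered exactly
  pg <- planted_niche_grid(noise_frac = 0.01, seed = 3)
  m3 <- master_correlation_matrix(pg$grid)
  init3 <- svd_initial_clusters(m3)
  ari <- mclust::adjustedRandIndex(init3, as.vector(t(pg$truth)))
  expect_equal(ari, 1)
})

test_that("refinement recovers planted niches and enforces both rules", {
  pg <- planted_niche_grid(noise_frac = 0.25, seed = 4)
  m <- master_correlation_matrix(pg$grid)
  lab <- refine_clusters(svd_initial_clusters(m), pg$grid,
                         corr_threshold = 0.7, min_cluster_frac = 0.05)
  pred <- lab$labels[cbind(lab$cell_index$cell_row, lab$cell_index$cell_col)]
  truth <- pg$truth[cbind(lab$cell_index$cell_row, lab$cell_index$cell_col)]
  expect_gte(mclust::adjustedRandIndex(pred[!is.na(pred)], truth[!is.na(pred)]), 0.9)
  expect_equal(glance(lab)$n_niches, 3)
  expect_true(lab$converged)

  # printed rules hold exactly on the returned labeling
  csm <- cell_series_matrix(pg$grid)
  for (id in unique(pred[!is.na(pred)])) {
    mem <- which(pred == id)
    expect_gte(length(mem), ceiling(0.05 * nrow(csm$cells)))
    centroid <- colMeans(csm$series[mem, , drop = FALSE])
    for (i in mem) {
      expect_gt(pearson_oracle(csm$series[i, ], centroid), 0.7)
    }
  }
})

test_that("niches sharing one profile collapse to a single cluster", {
  pg <- planted_niche_grid(noise_frac = 0.25, seed = 6, common_profile = TRUE)
  m <- master_correlation_matrix(pg$grid)
  lab <- refine_clusters(svd_initial_clusters(m), pg$grid)
  expect_equal(glance(lab)$n_niches, 1)
})

test_that("pure noise yields an empty labeling under the size rule", {
  # min_cluster_frac is scaled so the absolute size floor (5 cells) matches
  # what 5% of a realistic ~100-cell field of view implies; with a floor of
  # 1-2 cells any pair of mildly correlated noise series trivially satisfies
  # the member-to-centroid rule.
  for (seed in 1:20) {
    withr::with_seed(100 + seed, {
      vals <- array(rnorm(4 * 4 * 55), c(4, 4, 55))
      g <- make_grid(vals)
      m <- master_correlation_matrix(g)
      suppressWarnings(
        lab <- refine_clusters(svd_initial_clusters(m), g,
                               corr_threshold = 0.7, min_cluster_frac = 0.3)
      )
      expect_equal(glance(lab)$n_niches, 0)
    })
  }
})

test_that("clustering is deterministic for a fixed scene seed", {
  pg <- planted_niche_grid(seed = 8)
  run <- function() {
    m <- master_correlation_matrix(pg$grid)
    refine_clusters(svd_initial_clusters(m), pg$grid)$labels
  }
  expect_identical(run(), run())
})

test_that("the end-to-end cluster pipeline mirrors the planted merge", {
  sc <- generate_scene(scene_spec("NICHES", image_size = c(300, 500),
                                  cadence_min = 1, seed = 5))
  grids <- preprocess_trial(sc$trial)
  labs <- cluster_niches(grids$BV)
  expect_length(labs, 2)
  s1 <- manifest_compare(labs[[1]], sc$manifest, window = 1)
  expect_gte(s1$value[s1$metric == "ari"], 0.9)
  expect_equal(glance(labs[[1]])$n_niches, 3)
  expect_equal(glance(labs[[2]])$n_niches, 1)
})
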