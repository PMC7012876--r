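test_that("identical spec and seed reproduce bit-identical scenes", {
  sp <- scene_spec("NICHES", image_size = c(100, 100), duration_min = 20,
                   cadence_min = 1, seed = 17)
  a <- generate_scene(sp)
  b <- generate_scene(sp)
  expect_identical(a$trial$stacks$BV$frames, b$trial$stacks$BV$frames)
  expect_identical(a$manifest, b$manifest)

  # on-disk determinism: identical file checksums across two writes
  r1 <- withr::local_tempdir(); r2 <- withr::local_tempdir()
  generate_scene(sp, out_dir = r1)
  generate_scene(sp, out_dir = r2)
  f1 <- list.files(r1, recursive = TRUE, full.names = TRUE)
  f2 <- list.files(r2, recursive = TRUE, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(sort(f1[!grepl("provenance", f1)]))),
               unname(tools::md5sum(sort(f2[!grepl("provenance", f2)]))))

  # a different seed produces different data
  c2 <- generate_scene(scene_spec("NICHES", image_size = c(100, 100),
                                  duration_min = 20, cadence_min = 1, seed = 18))
  expect_false(identical(a$trial$stacks$BV$frames, c2$trial$stacks$BV$frames))
})

test_that("every scene kind passes trial validation", {
  kinds <- list(
    scene_spec("WAVEFRONT", image_size = c(100, 100), duration_min = 10,
               cadence_min = 1, seed = 1, initial_radius_px = 5,
               speed_um_per_min = 10),
    scene_spec("NICHES", image_size = c(100, 100), duration_min = 12,
               cadence_min = 1, seed = 1, merge_min = 6),
    scene_spec("COUPLING", image_size = c(100, 100), duration_min = 12,
               cadence_min = 1, seed = 1),
    scene_spec("PERTURBATION", image_size = c(100, 100), seed = 1,
               cadence_min = 1),
    scene_spec("SPECTRAL", image_size = c(100, 100), duration_min = 12,
               cadence_min = 1, seed = 1),
    scene_spec("COMPOSITE", image_size = c(100, 100), duration_min = 10,
               cadence_min = 1, seed = 1, initial_radius_px = 5,
               speed_um_per_min = 10)
  )
  for (sp in kinds) {
    sc <- generate_scene(sp)
    v <- validate_trial(sc$trial)
    expect_true(v$ok, label = sprintf("validate_trial ok for %s", sp$kind))
    expect_equal(sc$manifest$seed, 1)
  }
})

test_that("scene parameters are validated", {
  expect_error(scene_spec("NOPE"), "Unknown scene kind")
  expect_error(scene_spec("NICHES", bogus = 1), "Unknown parameter")
  expect_error(scene_spec("NICHES", image_size = c(20, 20)), "one block")
  expect_error(scene_spec("SPECTRAL", duration_min = 0.1, cadence_min = 1),
               "exceed")
})

test_that("block averaging recovers planted block means within noise", {
  sp <- scene_spec("SPECTRAL", image_size = c(100, 100), duration_min = 12,
                   cadence_min = 1, seed = 23, pixel_noise_sd = 0.05)
  sc <- generate_scene(sp)
  g <- block_average(sc$trial$stacks$BF, 50)
  # planted cell value at frame 1: m (1 + c cos(phase)); block mean of 2500
  # pixels has sampling error sd = pixel_noise_sd * m / 50
  se <- 0.05 * 100 / 50
  # reconstruct the planted noiseless cell series by regenerating the scene
  # without pixel noise under the same seed
  sp0 <- scene_spec("SPECTRAL", image_size = c(100, 100), duration_min = 12,
                    cadence_min = 1, seed = 23, pixel_noise_sd = 0)
  sc0 <- generate_scene(sp0)
  g0 <- block_average(sc0$trial$stacks$BF, 50)
  expect_lt(max(abs(g$values - g0$values)), 3 * se)
})

test_that("manifest comparison rejects mismatched output kinds", {
  sc <- generate_scene(scene_spec("SPECTRAL", image_size = c(100, 100),
                                  duration_min = 12, cadence_min = 1, seed = 2))
  profile_like <- structure(tibble(time_min = 1, distance_um = 1,
                                   speed_um_per_min = 1),
                            class = c("propagation_profile", "tbl_df", "tbl",
                                      "data.frame"))
  expect_error(manifest_compare(profile_like, sc$manifest), "scored against")
  expect_error(manifest_compare(profile_like, list(x = 1)), "scene_kind")
})

test_that("ARI scoring behaves at its reference points", {
  # perfect recovery scores exactly 1
  truth <- matrix(rep(1:3, each = 12), 6, 6)
  lab <- structure(
    list(labels = truth, window = 1:10, n_iter = 1, converged = TRUE,
         cell_index = tidyr::expand_grid(cell_row = 1:6, cell_col = 1:6)),
    class = "cluster_labeling")
  manifest <- list(scene_kind = "NICHES", labels_window1 = truth,
                   labels_window2 = truth)
  s <- manifest_compare(lab, manifest, window = 1)
  expect_equal(s$value[s$metric == "ari"], 1)

  # random labels against three equal niches hover near zero
  aris <- vapply(1:20, function(seed) {
    withr::with_seed(seed, {
      lab$labels <- matrix(sample(1:3, 36, replace = TRUE), 6, 6)
      s <- manifest_compare(lab, manifest, window = 1)
      s$value[s$metric == "ari"]
    })
  }, numeric(1))
  expect_lt(abs(mean(aris)), 0.1)
})

test_that("speed scoring reports plain relative error", {
  prof <- structure(
    tibble(time_min = 0:2, distance_um = c(0, 14.2, 28.4),
           speed_um_per_min = c(14.2, 14.2, NA)),
    class = c("propagation_profile", "tbl_df", "tbl", "data.frame"))
  s <- manifest_compare(prof, list(scene_kind = "WAVEFRONT",
                                   speed_um_per_min = 15))
  expect_equal(s$value[s$metric == "speed_rel_error"], 0.8 / 15,
               tolerance = 1e-12)
})

test_that("written scenes reload into an equivalent analysis input", {
  root <- withr::local_tempdir()
  sp <- scene_spec("PERTURBATION", image_size = c(100, 100), cadence_min = 1,
                   seed = 31)
  sc <- generate_scene(sp, out_dir = root)
  tr <- load_trial(root, "trial1")
  expect_setequal(names(tr$stacks), c("HBSAT", "BF"))
  expect_false(is.null(tr$paradigm))
  expect_equal(tr$paradigm$segments$state, c("BASELINE", "STIMULUS", "BASELINE"))
  # reloaded stacks support the same analysis to float32 precision
  # (compare by metric name: stack order differs on disk)
  a <- manifest_compare(analyze_perturbation(sc$trial), sc$manifest)
  b <- manifest_compare(analyze_perturbation(tr), sc$manifest)
  av <- setNames(a$value, a$metric)
  bv <- setNames(b$value, b$metric)
  expect_equal(bv[names(av)], av, tolerance = 1e-4)
  expect_true(file.exists(file.path(root, "trial1", "manifest.json")))
})
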