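SCENE_KINDS <- c("WAVEFRONT", "NICHES", "COUPLING", "PERTURBATION",
                 "SPECTRAL", "COMPOSITE")

scene_defaults <- function(kind) {
  common <- list(
    image_size = c(1000, 1400), duration_min = 60, cadence_min = 0.5,
    pixel_size = 5, block_px = 50, seed = 1, pixel_noise_sd = 0.02
  )
  kind_specific <- switch(kind,
    WAVEFRONT = list(
      origin = NA,                   # NA -> image center
      speed_um_per_min = 15, initial_radius_px = 10,
      hbsat_inside = 20, hbsat_outside = 50,
      bf_baseline = 100, bv_baseline = 100, drop_frac = 0.4,
      noise_sd = 0.1                 # fraction of the Hb_sat contrast
    ),
    NICHES = list(
      n_niches = 3, merge_min = 30, bv_baseline = 100,
      amplitude = 0.1, period_min = 20,
      noise_sd = 0.25                # fraction of the sub-region signal SD
    ),
    COUPLING = list(
      bf_baseline = 100, bv_baseline = 100, amplitude = 0.1,
      shared_periods = c(8, 13, 21),
      bf_periods = c(6, 9.5, 14), bv_periods = c(7.3, 11, 17),
      noise_sd = 0.2                 # fraction of the sub-region signal SD
    ),
    PERTURBATION = list(
      duration_min = 30,
      paradigm = perturbation_paradigm(),
      baselines = c(HBSAT = 40, BF = 100),
      deltas = c(HBSAT = 9, BF = 24),
      responder_frac = 0.5,
      snr = 3                        # planted delta over pixel noise SD
    ),
    SPECTRAL = list(
      bf_baseline = 100, modulation_depth = 0.2,
      lf_period_min = 28, hf_period_min = 4
    ),
    COMPOSITE = list(
      origin = NA, speed_um_per_min = 15, initial_radius_px = 10,
      hbsat_inside = 20, hbsat_outside = 50, noise_sd = 0.1,
      bf_baseline = 100, bv_baseline = 100, amplitude = 0.1,
      shared_periods = c(8, 13, 21)
    ),
    abort(sprintf("Unknown scene kind '%s'.", kind))
  )
  utils::modifyList(common, kind_specific)
}

#' Specify a synthetic scene
#'
#' Describes a ground-truth-bearing synthetic trial emulating the nominal
#' acquisition (frames every 30 s, 5 um pixels, 50 x 50 px sub-regions).
#' Scene kinds plant, respectively: a constant-speed expanding hypoxic disc
#' with co-localized blood-flow/volume declines (`WAVEFRONT`); spatial bands
#' of distinct vasomotion profiles that can merge mid-session (`NICHES`);
#' sub-regions with tight, poor or intermittent BF-BV coupling (`COUPLING`);
#' boxcar responders to a baseline/stimulus/baseline paradigm
#' (`PERTURBATION`); per-sub-region sinusoidal modulation at chosen periods
#' (`SPECTRAL`); and a wavefront combined with coupled BF/BV vasomotion
#' (`COMPOSITE`). All planted parameters are recorded verbatim in the
#' generated manifest.
#'
#' @param kind One of `r paste0('\x60"', SCENE_KINDS, '"\x60', collapse = ", ")`.
#' @param ... Overrides of the kind's default parameters (see
#'   [generate_scene()] for their meaning); unknown names raise an error.
#' @return A `scene_spec`.
#' @examples
#' scene_spec("WAVEFRONT", image_size = c(200, 200), seed = 7)
#' @export
scene_spec <- function(kind, ...) {
  kind <- toupper(kind)
  if (!kind %in% SCENE_KINDS) {
    abort(sprintf("Unknown scene kind '%s' (expected one of %s).",
                  kind, paste(SCENE_KINDS, collapse = ", ")))
  }
  params <- scene_defaults(kind)
  dots <- list(...)
  bad <- setdiff(names(dots), names(params))
  if (length(bad) > 0) {
    abort(sprintf("Unknown parameter(s) for %s scene: %s.",
                  kind, paste(bad, collapse = ", ")))
  }
  params[names(dots)] <- dots
  if (any(params$image_size < params$block_px)) {
    abort("Image must be at least one block in each dimension.")
  }
  if (params$duration_min <= params$cadence_min) {
    abort("Duration must exceed the cadence.")
  }
  structure(c(list(kind = kind), params), class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec %s> %d x %d px, %g min @ %g min cadence, seed %s\n",
              x$kind, x$image_size[1], x$image_size[2], x$duration_min,
              x$cadence_min, format(x$seed)))
  invisible(x)
}

# Expand an R x C grid of cell values to an H x W pixel field.
expand_blocks <- function(cell_vals, H, W, b) {
  R <- nrow(cell_vals); C <- ncol(cell_vals)
  ir <- pmin(ceiling(seq_len(H) / b), R)
  ic <- pmin(ceiling(seq_len(W) / b), C)
  cell_vals[ir, ic, drop = FALSE]
}

disc_mask <- function(H, W, center, radius) {
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
}

# Unit-SD-ish smooth latent: sum of sinusoids with given periods and random
# phases, normalized by sqrt(n/2) so the long-run SD is ~1.
smooth_latent <- function(t, periods) {
  phases <- stats::runif(length(periods), 0, 2 * pi)
  rowSums(vapply(seq_along(periods), function(i) {
    sin(2 * pi * t / periods[i] + phases[i])
  }, numeric(length(t)))) / sqrt(length(periods) / 2)
}

scene_grid_dims <- function(spec) {
  c(spec$image_size[1] %/% spec$block_px, spec$image_size[2] %/% spec$block_px)
}

scene_times <- function(spec) {
  seq(0, spec$duration_min - spec$cadence_min, by = spec$cadence_min)
}

build_wavefront <- function(spec) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  t <- scene_times(spec)
  origin <- if (length(spec$origin) != 2 || anyNA(spec$origin)) {
    c(round(H / 2), round(W / 2))
  } else spec$origin
  px_per_min <- spec$speed_um_per_min / spec$pixel_size
  contrast <- spec$hbsat_outside - spec$hbsat_inside
  radii <- spec$initial_radius_px + px_per_min * t
  final_disc <- disc_mask(H, W, origin, utils::tail(radii, 1))
  n <- length(t)
  hbsat <- array(NA_real_, c(H, W, n))
  bf <- array(NA_real_, c(H, W, n))
  bv <- array(NA_real_, c(H, W, n))
  for (k in seq_len(n)) {
    disc <- disc_mask(H, W, origin, radii[k])
    fr <- matrix(spec$hbsat_outside, H, W)
    fr[disc] <- spec$hbsat_inside
    fr <- fr + matrix(stats::rnorm(H * W, 0, spec$noise_sd * contrast), H, W)
    hbsat[, , k] <- pmin(pmax(fr, 0), 100)
    frac <- t[k] / utils::tail(t, 1)
    mk <- function(baseline) {
      f <- matrix(baseline, H, W)
      f[final_disc] <- baseline * (1 - spec$drop_frac * frac)
      f + matrix(stats::rnorm(H * W, 0, spec$noise_sd * baseline * spec$drop_frac), H, W)
    }
    bf[, , k] <- pmax(mk(spec$bf_baseline), 0)
    bv[, , k] <- pmax(mk(spec$bv_baseline), 0)
  }
  list(
    stacks = list(
      HBSAT = frame_stack("HBSAT", hbsat, t, spec$pixel_size),
      BF = frame_stack("BF", bf, t, spec$pixel_size),
      BV = frame_stack("BV", bv, t, spec$pixel_size)
    ),
    manifest = list(
      scene_kind = "WAVEFRONT",
      origin = origin, speed_um_per_min = spec$speed_um_per_min,
      initial_radius_px = spec$initial_radius_px,
      hbsat_inside = spec$hbsat_inside, hbsat_outside = spec$hbsat_outside,
      drop_frac = spec$drop_frac, radii_px = radii
    )
  )
}

build_niches <- function(spec) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  b <- spec$block_px
  gd <- scene_grid_dims(spec); R <- gd[1]; C <- gd[2]
  t <- scene_times(spec)
  K <- spec$n_niches
  # contiguous horizontal bands of cells
  labels1 <- matrix(pmin(ceiling(seq_len(R) / (R / K)), K), R, C)
  labels2 <- if (!is.null(spec$merge_min)) matrix(1L, R, C) else labels1
  phases <- 2 * pi * (seq_len(K) - 1) / K
  # phase offsets slide smoothly to zero around the merge time
  phase_weight <- if (is.null(spec$merge_min)) rep(1, length(t)) else {
    pmax(0, pmin(1, (spec$merge_min + 2 - t) / 4))
  }
  m <- spec$bv_baseline
  a <- spec$amplitude
  sig_sd <- m * a / sqrt(2)
  cell_noise_sd <- spec$noise_sd * sig_sd
  bv <- array(NA_real_, c(H, W, length(t)))
  cell_series <- array(NA_real_, c(R, C, length(t)))
  for (g in seq_len(K)) {
    prof <- m * (1 + a * sin(2 * pi * t / spec$period_min + phases[g] * phase_weight))
    for (idx in which(labels1 == g)) {
      i <- (idx - 1) %% R + 1; j <- (idx - 1) %/% R + 1
      cell_series[i, j, ] <- prof + stats::rnorm(length(t), 0, cell_noise_sd)
    }
  }
  for (k in seq_along(t)) {
    field <- expand_blocks(cell_series[, , k], H, W, b)
    bv[, , k] <- pmax(field + matrix(stats::rnorm(H * W, 0, spec$pixel_noise_sd * m), H, W), 1e-3)
  }
  list(
    stacks = list(BV = frame_stack("BV", bv, t, spec$pixel_size)),
    manifest = list(
      scene_kind = "NICHES", n_niches = K, merge_min = spec$merge_min,
      amplitude = a, period_min = spec$period_min, noise_sd = spec$noise_sd,
      labels_window1 = labels1, labels_window2 = labels2
    )
  )
}

build_coupling <- function(spec) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  b <- spec$block_px
  gd <- scene_grid_dims(spec); R <- gd[1]; C <- gd[2]
  t <- scene_times(spec)
  n <- length(t)
  M <- R * C
  # row-major thirds: TIGHT, POOR, INTERMITTENT
  cats <- c("TIGHT", "POOR", "INTERMITTENT")
  cell_cat <- matrix(cats[pmin(ceiling(seq_len(M) / (M / 3)), 3)],
                     R, C, byrow = TRUE)
  half <- t >= spec$duration_min / 2
  a <- spec$amplitude
  bf_cells <- array(NA_real_, c(R, C, n))
  bv_cells <- array(NA_real_, c(R, C, n))
  # A planted category must be true of the generated series, not just of the
  # drawing scheme: independently drawn smooth signals can correlate by
  # chance over a half-hour window. Draws are therefore rejected until the
  # two half-session correlations of the cell-level series respect the
  # category with margin around the nominal 0.7 rule (coupled halves
  # r >= 0.8, uncoupled halves |r| <= 0.4).
  half_r <- function(x, y) {
    c(suppressWarnings(cor(x[!half], y[!half])),
      suppressWarnings(cor(x[half], y[half])))
  }
  for (i in seq_len(R)) for (j in seq_len(C)) {
    for (try in seq_len(200)) {
      eta1 <- stats::rnorm(n, 0, spec$noise_sd)
      eta2 <- stats::rnorm(n, 0, spec$noise_sd)
      if (cell_cat[i, j] == "TIGHT") {
        s <- smooth_latent(t, spec$shared_periods)
        fbf <- s + eta1; fbv <- s + eta2
        ok <- all(half_r(fbf, fbv) >= 0.8)
      } else if (cell_cat[i, j] == "POOR") {
        fbf <- smooth_latent(t, spec$bf_periods) + eta1
        fbv <- smooth_latent(t, spec$bv_periods) + eta2
        ok <- all(abs(half_r(fbf, fbv)) <= 0.4)
      } else {
        s <- smooth_latent(t, spec$shared_periods)
        ind <- smooth_latent(t, spec$bf_periods)
        fbf <- s + eta1
        # decouple BF in the second half, continuously spliced at the midpoint
        k0 <- which(half)[1]
        fbf[half] <- ind[half] - ind[k0] + s[k0] + eta1[half]
        fbv <- s + eta2
        rr <- half_r(fbf, fbv)
        ok <- rr[1] >= 0.8 && abs(rr[2]) <= 0.4
      }
      if (ok) break
    }
    bf_cells[i, j, ] <- spec$bf_baseline * (1 + a * fbf)
    bv_cells[i, j, ] <- spec$bv_baseline * (1 + a * fbv)
  }
  to_stack <- function(cells, baseline, var) {
    arr <- array(NA_real_, c(H, W, n))
    for (k in seq_len(n)) {
      arr[, , k] <- pmax(expand_blocks(cells[, , k], H, W, b) +
        matrix(stats::rnorm(H * W, 0, spec$pixel_noise_sd * baseline), H, W), 1e-3)
    }
    frame_stack(var, arr, t, spec$pixel_size)
  }
  list(
    stacks = list(BF = to_stack(bf_cells, spec$bf_baseline, "BF"),
                  BV = to_stack(bv_cells, spec$bv_baseline, "BV")),
    manifest = list(
      scene_kind = "COUPLING", category = cell_cat,
      amplitude = a, noise_sd = spec$noise_sd
    )
  )
}

build_perturbation <- function(spec) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  b <- spec$block_px
  gd <- scene_grid_dims(spec); R <- gd[1]; C <- gd[2]
  t <- scene_times(spec)
  n <- length(t)
  paradigm <- spec$paradigm
  if (abs(paradigm$total_min - spec$duration_min) > 1e-9) {
    abort("Paradigm duration must equal the scene duration.")
  }
  box <- as.numeric(paradigm_state_at(paradigm, t) == "STIMULUS")
  responders <- matrix(stats::runif(R * C) < spec$responder_frac, R, C)
  vars <- names(spec$baselines)
  stacks <- list()
  for (v in vars) {
    base <- spec$baselines[[v]]
    dlt <- spec$deltas[[v]]
    noise_sd <- dlt / spec$snr
    arr <- array(NA_real_, c(H, W, n))
    resp_field <- expand_blocks(responders + 0, H, W, b)
    for (k in seq_len(n)) {
      fr <- base + resp_field * dlt * box[k] +
        matrix(stats::rnorm(H * W, 0, noise_sd), H, W)
      if (v == "HBSAT") fr <- pmin(pmax(fr, 0), 100) else fr <- pmax(fr, 0)
      arr[, , k] <- fr
    }
    stacks[[v]] <- frame_stack(v, arr, t, spec$pixel_size)
  }
  list(
    stacks = stacks,
    paradigm = paradigm,
    manifest = list(
      scene_kind = "PERTURBATION", responders = responders,
      deltas = as.list(spec$deltas), snr = spec$snr,
      paradigm = list(state = paradigm$segments$state,
                      duration_min = paradigm$segments$duration_min)
    )
  )
}

build_spectral <- function(spec) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  b <- spec$block_px
  gd <- scene_grid_dims(spec); R <- gd[1]; C <- gd[2]
  t <- scene_times(spec)
  n <- length(t)
  m <- spec$bf_baseline
  c_mod <- spec$modulation_depth
  # alternate LF/HF planting over the row-major cell scan
  is_lf <- matrix((seq_len(R * C) %% 2) == 1, R, C, byrow = TRUE)
  period <- ifelse(is_lf, spec$lf_period_min, spec$hf_period_min)
  cell_series <- array(NA_real_, c(R, C, n))
  for (i in seq_len(R)) for (j in seq_len(C)) {
    ph <- stats::runif(1, 0, 2 * pi)
    cell_series[i, j, ] <- m * (1 + c_mod * cos(2 * pi * t / period[i, j] + ph))
  }
  arr <- array(NA_real_, c(H, W, n))
  for (k in seq_len(n)) {
    arr[, , k] <- pmax(expand_blocks(cell_series[, , k], H, W, b) +
      matrix(stats::rnorm(H * W, 0, spec$pixel_noise_sd * m), H, W), 1e-3)
  }
  list(
    stacks = list(BF = frame_stack("BF", arr, t, spec$pixel_size)),
    manifest = list(
      scene_kind = "SPECTRAL", modulation_depth = c_mod,
      period_min = period, lf_cells = is_lf,
      expected_power_db = 10 * log10(c_mod^2 / 2)
    )
  )
}

build_composite <- function(spec) {
  wf_spec <- scene_spec("WAVEFRONT",
    image_size = spec$image_size, duration_min = spec$duration_min,
    cadence_min = spec$cadence_min, pixel_size = spec$pixel_size,
    block_px = spec$block_px, seed = spec$seed,
    origin = spec$origin, speed_um_per_min = spec$speed_um_per_min,
    initial_radius_px = spec$initial_radius_px,
    hbsat_inside = spec$hbsat_inside, hbsat_outside = spec$hbsat_outside,
    noise_sd = spec$noise_sd)
  cp_spec <- scene_spec("COUPLING",
    image_size = spec$image_size, duration_min = spec$duration_min,
    cadence_min = spec$cadence_min, pixel_size = spec$pixel_size,
    block_px = spec$block_px, seed = spec$seed,
    bf_baseline = spec$bf_baseline, bv_baseline = spec$bv_baseline,
    amplitude = spec$amplitude, shared_periods = spec$shared_periods)
  wf <- build_wavefront(wf_spec)
  cp <- build_coupling(cp_spec)
  list(
    stacks = list(HBSAT = wf$stacks$HBSAT, BF = cp$stacks$BF,
                  BV = cp$stacks$BV),
    manifest = list(scene_kind = "COMPOSITE",
                    wavefront = wf$manifest, coupling = cp$manifest)
  )
}

#' Generate a synthetic trial with planted ground truth
#'
#' Builds the scene described by a [scene_spec()] under its seed (identical
#' spec and seed reproduce bit-identical stacks), as a trial plus a manifest
#' recording every planted parameter. When `out_dir` is given, the trial is
#' written in the on-disk folder convention via [write_trial()] together with
#' a `manifest.json`.
#'
#' @param spec A [scene_spec()].
#' @param out_dir Optional output root directory.
#' @param trial_id Trial folder name (default `"trial1"`).
#' @return A `hemo_scene` with elements `trial`, `manifest` and `spec`.
#' @export
generate_scene <- function(spec, out_dir = NULL, trial_id = "trial1") {
  stopifnot(inherits(spec, "scene_spec"))
  built <- withr::with_seed(spec$seed, switch(spec$kind,
    WAVEFRONT = build_wavefront(spec),
    NICHES = build_niches(spec),
    COUPLING = build_coupling(spec),
    PERTURBATION = build_perturbation(spec),
    SPECTRAL = build_spectral(spec),
    COMPOSITE = build_composite(spec)
  ))
  manifest <- c(built$manifest, list(
    image_size = spec$image_size, duration_min = spec$duration_min,
    cadence_min = spec$cadence_min, pixel_size = spec$pixel_size,
    block_px = spec$block_px, seed = spec$seed
  ))
  tr <- trial(trial_id, built$stacks, paradigm = built$paradigm)
  if (!is.null(out_dir)) {
    write_trial(tr, out_dir)
    jsonlite::write_json(manifest, file.path(out_dir, trial_id, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(trial = tr, manifest = manifest, spec = spec),
            class = "hemo_scene")
}

#' @export
print.hemo_scene <- function(x, ...) {
  cat(sprintf("<hemo_scene %s>\n", x$manifest$scene_kind))
  print(x$trial)
  invisible(x)
}

#' Attenuation of a sinusoid by the temporal boxcar filter
#'
#' Amplitude gain of a `kernel_min`-long running mean (sampled every
#' `dt_min`) at a sinusoid of the given period; useful when comparing
#' measured band powers against planted modulation depths.
#'
#' @param period_min Sinusoid period in minutes.
#' @param kernel_min Boxcar length in minutes.
#' @param dt_min Sampling interval in minutes.
#' @return Amplitude gain in \[0, 1\].
#' @export
boxcar_gain <- function(period_min, kernel_min = 5, dt_min = 1) {
  w <- round(kernel_min / dt_min)
  f <- dt_min / period_min
  abs(sin(pi * f * w) / (w * sin(pi * f)))
}

confusion_tibble <- function(truth, predicted) {
  tibble(truth = truth, predicted = predicted) |>
    dplyr::count(.data$truth, .data$predicted, name = "n")
}

#' Score analysis output against a scene manifest
#'
#' Compares module output with the planted ground truth of the scene that
#' produced its input, with kind-appropriate recovery metrics: relative
#' wavefront-speed error (`WAVEFRONT` vs a [ray_speed_profile()]), adjusted
#' Rand index and niche count (`NICHES` vs a `cluster_labeling`),
#' category confusion and accuracy (`COUPLING` vs a `coupling_result`),
#' responder-mask sensitivity/specificity and response-magnitude error
#' (`PERTURBATION` vs a `perturbation_response`), and per-cell band-power
#' error in dB (`SPECTRAL` vs a `band_spectrum_map`; when `kernel_min` is
#' given, the expectation is corrected for the boxcar filter's attenuation at
#' each planted period).
#'
#' @param output The analysis result appropriate to the scene kind.
#' @param manifest A scene manifest (from a `hemo_scene` or `manifest.json`).
#' @param window For `NICHES`: which planted window labeling to compare
#'   against (1 or 2).
#' @param kernel_min For `SPECTRAL`: temporal kernel used in the analysis.
#' @return A `scene_score`: a tibble of metrics with the confusion table,
#'   where applicable, as an attribute.
#' @export
manifest_compare <- function(output, manifest, window = 1, kernel_min = NULL) {
  kind <- manifest$scene_kind
  if (is.null(kind)) abort("Manifest lacks a scene_kind.")
  score <- switch(kind,
    WAVEFRONT = {
      if (!inherits(output, "propagation_profile")) {
        abort("WAVEFRONT scenes are scored against a propagation profile.")
      }
      est <- mean_speed(output)
      truth <- manifest$speed_um_per_min
      tibble(metric = c("speed_true_um_per_min", "speed_est_um_per_min",
                        "speed_rel_error"),
             value = c(truth, est, abs(est - truth) / truth))
    },
    NICHES = {
      if (!inherits(output, "cluster_labeling")) {
        abort("NICHES scenes are scored against a cluster labeling.")
      }
      truth <- if (window == 1) manifest$labels_window1 else manifest$labels_window2
      truth <- as.vector(t(matrix(unlist(truth), nrow = nrow(output$labels), byrow = FALSE)))
      pred <- as.vector(t(output$labels))
      keep <- !is.na(truth)
      pred_f <- pred[keep]
      pred_f[is.na(pred_f)] <- 0L  # unassigned counted as its own class
      ari <- mclust::adjustedRandIndex(truth[keep], pred_f)
      tibble(metric = c("ari", "n_niches_true", "n_niches_found",
                        "frac_unassigned"),
             value = c(ari, length(unique(truth[keep])),
                       length(unique(pred[!is.na(pred)])),
                       mean(is.na(pred[keep]))))
    },
    COUPLING = {
      if (!inherits(output, "coupling_result")) {
        abort("COUPLING scenes are scored against a coupling result.")
      }
      truth <- matrix(unlist(manifest$category), nrow = nrow(output$category))
      keep <- output$category != "MISSING"
      conf <- confusion_tibble(truth[keep], output$category[keep])
      acc <- mean(truth[keep] == output$category[keep])
      res <- tibble(metric = c("accuracy", "n_cells"),
                    value = c(acc, sum(keep)))
      attr(res, "confusion") <- conf
      res
    },
    PERTURBATION = {
      if (!inherits(output, "perturbation_response")) {
        abort("PERTURBATION scenes are scored against a perturbation response.")
      }
      truth <- matrix(unlist(manifest$responders), nrow = nrow(output$variables[[1]]$mask))
      purrr::imap_dfr(output$variables, function(v, nm) {
        tp <- sum(v$mask & truth); fn <- sum(!v$mask & truth)
        tn <- sum(!v$mask & !truth); fp <- sum(v$mask & !truth)
        dlt_true <- manifest$deltas[[nm]]
        err <- abs(v$delta_map[truth & v$mask] - dlt_true) / abs(dlt_true)
        tibble(metric = paste0(c("sensitivity_", "specificity_", "delta_mare_"), nm),
               value = c(tp / (tp + fn), tn / (tn + fp),
                         mean(err)))
      })
    },
    SPECTRAL = {
      if (!inherits(output, "band_spectrum_map")) {
        abort("SPECTRAL scenes are scored against a band spectrum map.")
      }
      is_lf <- matrix(unlist(manifest$lf_cells), nrow = nrow(output$power_db[[1]]))
      period <- matrix(unlist(manifest$period_min), nrow = nrow(is_lf))
      expected <- matrix(manifest$expected_power_db, nrow(is_lf), ncol(is_lf))
      if (!is.null(kernel_min)) {
        gain <- boxcar_gain(period, kernel_min = kernel_min,
                            dt_min = output$dt_min)
        expected <- expected + 20 * log10(gain)
      }
      lf_err <- abs(output$power_db[["LF"]][is_lf] - expected[is_lf])
      hf_err <- abs(output$power_db[["HF"]][!is_lf] - expected[!is_lf])
      tibble(metric = c("lf_mean_abs_error_db", "hf_mean_abs_error_db"),
             value = c(mean(lf_err, na.rm = TRUE), mean(hf_err, na.rm = TRUE)))
    },
    abort(sprintf("No comparison defined for scene kind '%s'.", kind))
  )
  structure(score, class = c("scene_score", class(score)), scene_kind = kind)
}
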