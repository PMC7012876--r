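#' Hypoxic pixel mask
#'
#' Thresholds an oxygen-saturation frame: pixels strictly below the threshold
#' (default 30%) are hypoxic; non-finite pixels are excluded.
#'
#' @param frame 2D numeric matrix of Hb_sat in percent.
#' @param threshold_pct Threshold in percent.
#' @return Logical matrix.
#' @export
hypoxic_mask <- function(frame, threshold_pct = 30) {
  out <- is.finite(frame) & frame < threshold_pct
  out
}

shift_mat <- function(m, dr, dc) {
  R <- nrow(m); C <- ncol(m)
  out <- matrix(FALSE, R, C)
  rs <- max(1, 1 + dr):min(R, R + dr)
  cs <- max(1, 1 + dc):min(C, C + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

dilate4 <- function(m) {
  m | shift_mat(m, 1, 0) | shift_mat(m, -1, 0) |
    shift_mat(m, 0, 1) | shift_mat(m, 0, -1)
}

# 4-connected component of `mask` containing `seed` (row, col). `init`
# optionally pre-seeds the region (e.g. the previous minute's component for a
# monotonically growing front) to cut the number of growth iterations.
connected_component <- function(mask, seed, init = NULL) {
  if (!mask[seed[1], seed[2]]) return(NULL)
  comp <- matrix(FALSE, nrow(mask), ncol(mask))
  if (!is.null(init)) comp <- init & mask
  comp[seed[1], seed[2]] <- TRUE
  repeat {
    grown <- comp | (dilate4(comp) & mask)
    if (sum(grown) == sum(comp)) break
    comp <- grown
  }
  comp
}

# Inner boundary: component pixels with at least one 4-neighbor outside the
# component (the image border counts as outside).
component_boundary <- function(comp) {
  pad <- function(dr, dc) shift_mat(comp, dr, dc)
  interior <- pad(1, 0) & pad(-1, 0) & pad(0, 1) & pad(0, -1)
  # border rows/cols of the image are never interior
  interior[1, ] <- FALSE; interior[nrow(comp), ] <- FALSE
  interior[, 1] <- FALSE; interior[, ncol(comp)] <- FALSE
  comp & !interior
}

nearest_true_within <- function(mask, seed, radius) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  d2 <- (idx[, 1] - seed[1])^2 + (idx[, 2] - seed[2])^2
  j <- which.min(d2)
  if (d2[j] > radius^2) return(NULL)
  as.integer(idx[j, ])
}

#' Trace the hypoxic wavefront over time
#'
#' For each frame of a (filtered, per-minute) oxygen-saturation stack, the
#' 4-connected sub-threshold component containing the chosen origin — or the
#' component nearest the origin within `capture_radius_px` when the origin
#' pixel itself is not hypoxic — is selected, and its outer boundary stored as
#' that minute's wavefront contour. Minutes with no qualifying component are
#' marked absent.
#'
#' @param hbsat_stack A filtered [frame_stack()] of Hb_sat.
#' @param origin Length-2 integer `(row, col)`, 1-based, origin at the image
#'   top-left.
#' @param threshold_pct Hypoxia threshold in percent.
#' @param capture_radius_px Search radius when the origin is not hypoxic.
#' @return A `wavefront_set`: per-minute contour coordinate matrices, hypoxic
#'   component areas, the first/last component masks, and metadata.
#' @export
extract_wavefronts <- function(hbsat_stack, origin, threshold_pct = 30,
                               capture_radius_px = 25) {
  d <- dim(hbsat_stack$frames)
  origin <- as.integer(origin)
  if (origin[1] < 1 || origin[1] > d[1] || origin[2] < 1 || origin[2] > d[2]) {
    abort("`origin` lies outside the field of view.")
  }
  n <- d[3]
  contours <- vector("list", n)
  areas <- rep(NA_real_, n)
  comps_first <- NULL; comps_last <- NULL
  prev <- NULL
  for (k in seq_len(n)) {
    mask <- hypoxic_mask(hbsat_stack$frames[, , k], threshold_pct)
    seed <- if (mask[origin[1], origin[2]]) origin else
      nearest_true_within(mask, origin, capture_radius_px)
    # Re-seeding from the previous component is only sound while the front
    # grows monotonically (prev still sub-threshold); otherwise grow afresh.
    init <- if (!is.null(prev) && all(mask[prev])) prev else NULL
    comp <- if (is.null(seed)) NULL else connected_component(mask, seed, init = init)
    if (is.null(comp)) {
      contours[k] <- list(NULL)
      prev <- NULL
      next
    }
    bnd <- which(component_boundary(comp), arr.ind = TRUE)
    colnames(bnd) <- c("row", "col")
    contours[[k]] <- bnd
    areas[k] <- sum(comp)
    if (is.null(comps_first)) comps_first <- comp
    comps_last <- comp
    prev <- comp
  }
  structure(
    list(contours = contours, times = hbsat_stack$times, areas = areas,
         origin = origin, threshold_pct = threshold_pct,
         comp_first = comps_first, comp_last = comps_last,
         pixel_size = hbsat_stack$pixel_size, shape = d[1:2]),
    class = "wavefront_set"
  )
}

#' @export
print.wavefront_set <- function(x, ...) {
  n_present <- sum(!vapply(x$contours, is.null, TRUE))
  cat(sprintf("<wavefront_set> %d/%d minutes with a hypoxic front, origin (%d, %d), threshold %g%%\n",
              n_present, length(x$contours), x$origin[1], x$origin[2], x$threshold_pct))
  invisible(x)
}

#' @method as_tibble wavefront_set
#' @export
as_tibble.wavefront_set <- function(x, ...) {
  purrr::map_dfr(seq_along(x$contours), function(k) {
    b <- x$contours[[k]]
    if (is.null(b)) return(NULL)
    tibble(time_min = x$times[k], row = b[, "row"], col = b[, "col"])
  })
}

#' Radial expansion profile along a direction
#'
#' Measures, per minute, the farthest extent of the hypoxic wavefront along
#' the ray from the origin through a user-chosen anchor point, and converts
#' successive distances into an expansion speed by forward differencing.
#' Contour pixels within about 0.8 px of the ray line are considered
#' crossings; the leading (farthest) crossing is reported so that fingering
#' fronts yield the outer front.
#'
#' @param wavefronts A `wavefront_set`.
#' @param anchor Length-2 `(row, col)` defining the direction origin -> anchor.
#' @param direction_label Label for the profile (e.g. `"O->A"`).
#' @return A `propagation_profile` tibble with columns `time_min`,
#'   `distance_um`, `speed_um_per_min` (speed is `NA` at the final minute and
#'   around absent contours).
#' @export
ray_speed_profile <- function(wavefronts, anchor, direction_label = "ray") {
  o <- as.numeric(wavefronts$origin)
  a <- as.numeric(anchor)
  v <- a - o
  if (sqrt(sum(v^2)) < 1e-9) abort("`anchor` must differ from the origin.")
  v <- v / sqrt(sum(v^2))
  px <- wavefronts$pixel_size
  shape <- wavefronts$shape
  dist_px <- vapply(wavefronts$contours, function(b) {
    if (is.null(b)) return(NA_real_)
    dr <- b[, "row"] - o[1]
    dc <- b[, "col"] - o[2]
    t_par <- dr * v[1] + dc * v[2]          # along-ray component
    t_perp <- abs(dr * v[2] - dc * v[1])    # distance to the ray line
    hit <- t_par >= 0 & t_perp <= 0.8
    if (!any(hit)) return(NA_real_)
    k <- which(hit)[which.max(t_par[hit])]
    # a crossing on the image border means the front has left the field of
    # view along this ray: the true extent is censored, not measured
    if (b[k, "row"] <= 1 || b[k, "row"] >= shape[1] ||
        b[k, "col"] <= 1 || b[k, "col"] >= shape[2]) {
      return(NA_real_)
    }
    t_par[k]
  }, numeric(1))
  distance_um <- dist_px * px
  n <- length(distance_um)
  dt <- diff(wavefronts$times)
  speed <- c((distance_um[-1] - distance_um[-n]) / dt, NA_real_)
  structure(
    tibble(time_min = wavefronts$times, distance_um = distance_um,
           speed_um_per_min = speed),
    class = c("propagation_profile", "tbl_df", "tbl", "data.frame"),
    direction_label = direction_label,
    origin = wavefronts$origin, anchor = as.integer(anchor)
  )
}

#' Mean expansion speed of a profile
#'
#' Summary speed over the analyzed run: the mean forward-difference speed,
#' equivalent to the net radial displacement divided by elapsed time when all
#' contours are present.
#'
#' @param profile A [ray_speed_profile()] result.
#' @return Mean speed in micrometers per minute.
#' @export
mean_speed <- function(profile) {
  mean(profile$speed_um_per_min, na.rm = TRUE)
}

#' Zone-wise hemodynamic reductions around an expanding hypoxic front
#'
#' Classifies each sub-region by its center pixel against the first and last
#' wavefront contours — CHRONIC inside the first contour, ACUTE newly engulfed
#' between first and last, NORMOXIC outside the last — and reports the
#' windowed reductions -dBF and -dBV per sub-region for the acute-vs-normoxic
#' comparison.
#'
#' @param wavefronts A `wavefront_set` with first and last components present.
#' @param bf_grid,bv_grid [grid_series()] of blood flow and blood volume on
#'   the filtered base.
#' @param early_idx,late_idx Index windows passed to [windowed_reduction()];
#'   default to the first and last 5 filtered time points.
#' @return A tibble with `cell_row`, `cell_col`, `zone`, `neg_delta_bf`,
#'   `neg_delta_bv`.
#' @export
zone_scatter <- function(wavefronts, bf_grid, bv_grid,
                         early_idx = NULL, late_idx = NULL) {
  if (is.null(wavefronts$comp_first) || is.null(wavefronts$comp_last)) {
    abort("Wavefronts at the first and last analyzed minute are required.")
  }
  stopifnot(identical(dim(bf_grid$values), dim(bv_grid$values)))
  d <- dim(bf_grid$values)
  n <- d[3]
  if (is.null(early_idx)) early_idx <- seq_len(min(5, n %/% 2))
  if (is.null(late_idx)) late_idx <- seq.int(n - min(5, n %/% 2) + 1L, n)
  b <- bf_grid$block_px
  rows <- tidyr::expand_grid(cell_row = seq_len(d[1]), cell_col = seq_len(d[2]))
  ctr_r <- pmin(wavefronts$shape[1], round((rows$cell_row - 0.5) * b + 0.5))
  ctr_c <- pmin(wavefronts$shape[2], round((rows$cell_col - 0.5) * b + 0.5))
  in_first <- wavefronts$comp_first[cbind(ctr_r, ctr_c)]
  in_last <- wavefronts$comp_last[cbind(ctr_r, ctr_c)]
  zone <- dplyr::case_when(
    in_first ~ "CHRONIC",
    in_last ~ "ACUTE",
    TRUE ~ "NORMOXIC"
  )
  red <- function(grid, r, c) {
    v <- grid$values[r, c, ]
    if (any(!is.finite(v[c(early_idx, late_idx)]))) return(NA_real_)
    windowed_reduction(v, early_idx, late_idx)
  }
  rows |>
    dplyr::mutate(
      zone = factor(zone, levels = c("CHRONIC", "ACUTE", "NORMOXIC")),
      missing = bf_grid$missing_mask[cbind(.data$cell_row, .data$cell_col)] |
        bv_grid$missing_mask[cbind(.data$cell_row, .data$cell_col)],
      neg_delta_bf = purrr::map2_dbl(.data$cell_row, .data$cell_col, ~red(bf_grid, .x, .y)),
      neg_delta_bv = purrr::map2_dbl(.data$cell_row, .data$cell_col, ~red(bv_grid, .x, .y))
    ) |>
    dplyr::filter(!.data$missing) |>
    dplyr::select(-"missing")
}

#' Propagation analysis of a trial
#'
#' Convenience pipeline for the propagation module: per-minute resampling and
#' temporal filtering of the Hb_sat stack at full resolution, wavefront
#' extraction from the chosen origin, expansion-speed profiles along each
#' anchor direction, and the acute/normoxic zone scatter from the
#' block-averaged BF and BV series.
#'
#' @param trial A `hemo_trial` with an `HBSAT` stack (and `BF`/`BV` stacks for
#'   the zone scatter).
#' @param origin `(row, col)` wavefront origin.
#' @param anchors Named list of `(row, col)` direction anchors.
#' @param config A [run_config()].
#' @return List with `wavefronts`, `profiles` (one per anchor), and `zones`
#'   (`NULL` when BF/BV are absent).
#' @export
analyze_propagation <- function(trial, origin, anchors = list(),
                                config = run_config()) {
  trial <- resample_to_common_grid(trial, step_min = config$temporal_step_min)
  hb <- filter_stack(trial$stacks[["HBSAT"]],
                     kernel_min = config$temporal_kernel_min,
                     step_min = config$temporal_step_min)
  wf <- extract_wavefronts(hb, origin,
                           threshold_pct = config$hypoxia_threshold_pct,
                           capture_radius_px = config$capture_radius_px)
  profiles <- purrr::imap(anchors, function(a, nm) {
    ray_speed_profile(wf, a, direction_label = nm)
  })
  zones <- NULL
  if (all(c("BF", "BV") %in% names(trial$stacks))) {
    mk <- function(v) filter_grid(block_average(trial$stacks[[v]], config$block_px),
                                  config$temporal_kernel_min, config$temporal_step_min)
    zones <- zone_scatter(wf, mk("BF"), mk("BV"))
  }
  list(wavefronts = wf, profiles = profiles, zones = zones)
}
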