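#' Perturbation paradigm
#'
#' Ordered baseline/stimulus segments of a systemic perturbation session; the
#' default is the gas-inhalation paradigm of 10 minutes each of room air,
#' carbogen, and room air.
#'
#' @param states Character vector of `"BASELINE"` / `"STIMULUS"`.
#' @param durations_min Segment durations in minutes.
#' @return A `perturbation_paradigm`.
#' @examples
#' perturbation_paradigm()  # 10/10/10 baseline-stimulus-baseline
#' @export
perturbation_paradigm <- function(states = c("BASELINE", "STIMULUS", "BASELINE"),
                                  durations_min = c(10, 10, 10)) {
  states <- toupper(states)
  if (!all(states %in% c("BASELINE", "STIMULUS"))) {
    abort("States must be BASELINE or STIMULUS.")
  }
  if (!any(states == "STIMULUS")) abort("Paradigm needs at least one STIMULUS segment.")
  if (length(states) != length(durations_min) || any(durations_min <= 0)) {
    abort("One positive duration per segment is required.")
  }
  segments <- tibble(state = states, duration_min = as.numeric(durations_min),
                     start_min = cumsum(c(0, utils::head(durations_min, -1))))
  structure(list(segments = segments,
                 total_min = sum(durations_min)),
            class = "perturbation_paradigm")
}

#' @export
print.perturbation_paradigm <- function(x, ...) {
  cat(sprintf("<perturbation_paradigm> %g min: %s\n", x$total_min,
              paste(sprintf("%s(%g)", x$segments$state, x$segments$duration_min),
                    collapse = " -> ")))
  invisible(x)
}

paradigm_state_at <- function(paradigm, t) {
  seg_end <- paradigm$segments$start_min + paradigm$segments$duration_min
  idx <- findInterval(t, c(paradigm$segments$start_min, Inf),
                      rightmost.closed = FALSE)
  idx <- pmin(pmax(idx, 1L), nrow(paradigm$segments))
  paradigm$segments$state[idx]
}

paradigm_transitions <- function(paradigm) {
  st <- paradigm$segments
  utils::tail(st$start_min, -1)
}

#' Build the filtered stimulus reference series
#'
#' Samples the paradigm as a 0/1 boxcar at the acquisition cadence and passes
#' it through [temporal_mean_filter()] with exactly the same kernel and step
#' used for the hemodynamic series, so the reference and data share the
#' filtered time base (e.g. a 30-minute paradigm on a 1-minute base yields a
#' 26-point reference).
#'
#' @param paradigm A [perturbation_paradigm()].
#' @param cadence_min Sampling cadence of the raw base, in minutes.
#' @param kernel_min,step_min Temporal filter parameters.
#' @return List with `values` and `times` on the filtered base.
#' @export
build_reference <- function(paradigm, cadence_min = 1,
                            kernel_min = 5, step_min = 1) {
  if (paradigm$total_min < kernel_min) {
    abort("Paradigm is shorter than one filter kernel.")
  }
  t_raw <- seq(0, paradigm$total_min - cadence_min, by = cadence_min)
  box <- as.numeric(paradigm_state_at(paradigm, t_raw) == "STIMULUS")
  temporal_mean_filter(box, t_raw, kernel_min = kernel_min, step_min = step_min)
}

#' Responsive sub-region mask
#'
#' Correlates every sub-region series with the filtered stimulus reference
#' and flags cells with `r > corr_threshold` (strict, one-sided: strongly
#' anti-correlated cells are not "responsive") as responding to the
#' perturbation.
#'
#' @param grid A filtered [grid_series()].
#' @param reference Reference series from [build_reference()] (list or
#'   numeric vector on the same filtered base).
#' @param corr_threshold Threshold (default 0.7).
#' @return List with `r_map` (R x C) and `mask` (logical R x C).
#' @export
responsive_mask <- function(grid, reference, corr_threshold = 0.7) {
  ref <- if (is.list(reference)) reference$values else reference
  d <- dim(grid$values)
  if (length(ref) != d[3]) abort("Reference and grid must share the filtered time base.")
  if (sd(ref) == 0) abort("Constant reference: degenerate paradigm.")
  flat <- matrix(grid$values, nrow = d[1] * d[2])
  r <- row_cor(flat, matrix(ref, nrow = d[1] * d[2], ncol = d[3], byrow = TRUE))
  r_map <- matrix(r, d[1], d[2])
  r_map[grid$missing_mask] <- NA_real_
  mask <- !is.na(r_map) & r_map > corr_threshold
  list(r_map = r_map, mask = mask)
}

#' Response magnitude of one sub-region
#'
#' The response magnitude is the difference between mean hemodynamic levels
#' in the stimulus and baseline periods (stimulus minus baseline, so a
#' carbogen-driven increase is positive). Filtered samples whose window
#' centers lie within half a kernel of a state transition are still ramping
#' and are excluded from both means by default.
#'
#' @param series Cell series on the filtered base.
#' @param times Filtered window-center times in minutes.
#' @param paradigm A [perturbation_paradigm()].
#' @param kernel_min Temporal kernel used upstream (sets the exclusion zone).
#' @param exclude_transitions Set `FALSE` to use all samples.
#' @return The response magnitude, in the variable's units.
#' @export
response_magnitude <- function(series, times, paradigm, kernel_min = 5,
                               exclude_transitions = TRUE) {
  if (length(series) != length(times)) abort("Series and times must align.")
  state <- paradigm_state_at(paradigm, times)
  clean <- rep(TRUE, length(times))
  if (exclude_transitions) {
    for (tr in paradigm_transitions(paradigm)) {
      clean <- clean & abs(times - tr) >= kernel_min / 2
    }
  }
  stim <- series[clean & state == "STIMULUS"]
  base <- series[clean & state == "BASELINE"]
  if (length(stim) < 3 || length(base) < 3) {
    abort("Fewer than 3 clean samples in a period; relax the exclusion or lengthen the paradigm.")
  }
  mean(stim) - mean(base)
}

#' Perturbation analysis of pre-processed grids
#'
#' For each variable: the correlation map against the filtered reference, the
#' responsive mask (`r > threshold`), and the response-magnitude map, which
#' is reported only over responsive cells.
#'
#' @param grids Named list of filtered [grid_series()] (one per variable).
#' @param paradigm A [perturbation_paradigm()].
#' @param config A [run_config()].
#' @param exclude_transitions Passed to [response_magnitude()].
#' @return A `perturbation_response` holding per-variable `r_map`, `mask`
#'   and `delta_map`.
#' @export
perturbation_response <- function(grids, paradigm, config = run_config(),
                                  exclude_transitions = TRUE) {
  ref <- build_reference(paradigm,
                         cadence_min = config$temporal_step_min,
                         kernel_min = config$temporal_kernel_min,
                         step_min = config$temporal_step_min)
  per_var <- purrr::map(grids, function(g) {
    if (length(ref$values) != dim(g$values)[3]) {
      abort("Grid and reference are not on the same filtered base; check paradigm duration.")
    }
    rm <- responsive_mask(g, ref, corr_threshold = config$corr_threshold)
    d <- dim(g$values)
    delta <- matrix(NA_real_, d[1], d[2])
    for (idx in which(rm$mask)) {
      rc <- c((idx - 1) %% d[1] + 1, (idx - 1) %/% d[1] + 1)
      delta[rc[1], rc[2]] <- response_magnitude(
        g$values[rc[1], rc[2], ], g$times, paradigm,
        kernel_min = config$temporal_kernel_min,
        exclude_transitions = exclude_transitions)
    }
    list(r_map = rm$r_map, mask = rm$mask, delta_map = delta)
  })
  structure(list(variables = per_var, reference = ref, paradigm = paradigm,
                 corr_threshold = config$corr_threshold,
                 sign_convention = "stimulus_minus_baseline"),
            class = "perturbation_response")
}

#' @export
print.perturbation_response <- function(x, ...) {
  cat("<perturbation_response>\n")
  for (nm in names(x$variables)) {
    v <- x$variables[[nm]]
    cat(sprintf("  %-8s responsive %d/%d cells, median delta %.3g\n", nm,
                sum(v$mask), length(v$mask),
                stats::median(v$delta_map, na.rm = TRUE)))
  }
  invisible(x)
}

#' @method tidy perturbation_response
#' @export
tidy.perturbation_response <- function(x, ...) {
  purrr::imap_dfr(x$variables, function(v, nm) {
    d <- dim(v$r_map)
    tidyr::expand_grid(cell_row = seq_len(d[1]), cell_col = seq_len(d[2])) |>
      dplyr::mutate(
        variable = nm,
        r = v$r_map[cbind(.data$cell_row, .data$cell_col)],
        responsive = v$mask[cbind(.data$cell_row, .data$cell_col)],
        delta = v$delta_map[cbind(.data$cell_row, .data$cell_col)]
      )
  })
}

#' Cross-variable response scatter
#'
#' Pairs the response magnitudes of two variables over the cells responsive
#' in both; cells responsive in only one variable are excluded.
#'
#' @param resp A [perturbation_response()] result.
#' @param var_x,var_y Variable names (e.g. `"BF"`, `"HBSAT"`).
#' @return Tibble with `cell_row`, `cell_col`, `delta_x`, `delta_y`.
#' @export
response_scatter <- function(resp, var_x, var_y) {
  vx <- resp$variables[[var_x]]; vy <- resp$variables[[var_y]]
  if (is.null(vx) || is.null(vy)) abort("Both variables must be analyzed.")
  both <- vx$mask & vy$mask
  idx <- which(both, arr.ind = TRUE)
  tibble(
    cell_row = as.integer(idx[, 1]), cell_col = as.integer(idx[, 2]),
    delta_x = vx$delta_map[both], delta_y = vy$delta_map[both]
  )
}

#' Perturbation analysis of a trial
#'
#' Pre-processes all stacks and runs [perturbation_response()] using the
#' trial's paradigm (or a supplied one).
#'
#' @param trial A `hemo_trial`.
#' @param paradigm Optional [perturbation_paradigm()] overriding the trial's.
#' @param config A [run_config()].
#' @return A `perturbation_response`.
#' @export
analyze_perturbation <- function(trial, paradigm = NULL, config = run_config()) {
  paradigm <- paradigm %||% trial$paradigm
  if (is.null(paradigm)) abort("No perturbation paradigm available for this trial.")
  grids <- preprocess_trial(trial, config)
  grids <- grids[setdiff(names(grids), c("FL", "REFERENCE"))]
  perturbation_response(grids, paradigm, config = config)
}
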