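#' Temporal running-mean filter
#'
#' Slides a boxcar of length `kernel_min` along a uniformly sampled series in
#' steps of `step_min`, emitting only fully covered windows, so a 60-minute
#' series on a 1-minute base filtered with the default 5-minute kernel yields
#' exactly 56 points. Output timestamps sit at window centers.
#'
#' @param series Numeric vector, or a matrix with one series per row.
#' @param times Sample times in minutes, uniformly spaced.
#' @param kernel_min Kernel length in minutes; must be an integer multiple of
#'   the sampling interval.
#' @param step_min Step between windows in minutes; same divisibility rule.
#' @return A list with `values` (same shape class as the input, windows along
#'   time) and `times` (window-center minutes).
#' @examples
#' f <- temporal_mean_filter(0:59, times = 0:59, kernel_min = 5, step_min = 1)
#' length(f$values)  # 56
#' @export
temporal_mean_filter <- function(series, times, kernel_min = 5, step_min = 1) {
  mat <- if (is.matrix(series)) series else matrix(series, nrow = 1)
  n <- ncol(mat)
  if (length(times) != n) abort("`times` must match the series length.")
  dt <- diff(times)
  if (n < 2 || max(abs(dt - dt[1])) > 1e-8 * max(dt[1], 1)) {
    abort("Series must be uniformly sampled before temporal filtering.")
  }
  d <- dt[1]
  w <- kernel_min / d
  s <- step_min / d
  if (abs(w - round(w)) > 1e-8 || abs(s - round(s)) > 1e-8) {
    abort("Kernel and step must be integer multiples of the sampling interval.")
  }
  w <- as.integer(round(w)); s <- as.integer(round(s))
  if (n < w) abort(sprintf("Series of %d points is shorter than one %g-min kernel.", n, kernel_min))
  starts <- seq.int(1L, n - w + 1L, by = s)
  acc <- 0
  for (o in 0:(w - 1L)) acc <- acc + mat[, starts + o, drop = FALSE]
  out <- acc / w
  t_out <- times[starts] + kernel_min / 2
  values <- if (is.matrix(series)) out else drop(out)
  list(values = values, times = t_out)
}

#' Apply the temporal filter to a whole frame stack
#'
#' Pixelwise application of [temporal_mean_filter()], used for analyses (such
#' as wavefront tracking) that operate at full spatial resolution.
#'
#' @param stack A [frame_stack()] on a uniform time base.
#' @inheritParams temporal_mean_filter
#' @return A filtered `frame_stack` on the window-center time base.
#' @export
filter_stack <- function(stack, kernel_min = 5, step_min = 1) {
  d <- dim(stack$frames)
  flat <- stack$frames
  dim(flat) <- c(d[1] * d[2], d[3])
  f <- temporal_mean_filter(flat, stack$times, kernel_min, step_min)
  arr <- f$values
  dim(arr) <- c(d[1], d[2], length(f$times))
  frame_stack(stack$variable, arr, f$times, pixel_size = stack$pixel_size)
}

#' Construct a grid series
#'
#' Internal-facing constructor for block-averaged sub-region time-series;
#' most users obtain one from [block_average()].
#'
#' @param variable Variable label.
#' @param values R x C x N array of sub-region series.
#' @param times Minutes, length N.
#' @param block_px Pixels per block side.
#' @param missing_mask Optional R x C logical; `TRUE` marks cells excluded
#'   from analysis.
#' @return A `grid_series` object.
#' @export
grid_series <- function(variable, values, times, block_px,
                        missing_mask = NULL) {
  stopifnot(length(dim(values)) == 3, length(times) == dim(values)[3])
  d <- dim(values)
  if (is.null(missing_mask)) {
    missing_mask <- apply(values, c(1, 2), function(v) any(!is.finite(v)))
  }
  structure(
    list(variable = variable, values = values, times = as.numeric(times),
         block_px = as.integer(block_px),
         missing_mask = missing_mask),
    class = "grid_series"
  )
}

#' @export
print.grid_series <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<grid_series %s> %d x %d cells (block %d px), %d time points, %d missing cells\n",
              x$variable, d[1], d[2], x$block_px, d[3], sum(x$missing_mask)))
  invisible(x)
}

#' @export
dim.grid_series <- function(x) dim(x$values)

#' Block-average a frame stack into sub-region series
#'
#' Tiles each frame into non-overlapping `block_px` x `block_px` blocks
#' (trailing partial tiles are discarded) and takes the mean of the finite
#' pixels in each block. A block with fewer than 50% finite pixels in any
#' frame is marked missing throughout.
#'
#' @param stack A [frame_stack()].
#' @param block_px Block side length in pixels (default 50).
#' @return A [grid_series()] with `floor(H / block_px)` x `floor(W / block_px)`
#'   cells.
#' @examples
#' fs <- frame_stack("BV", array(2, c(100, 150, 3)), times = 0:2)
#' dim(block_average(fs, 50))  # 2 x 3 x 3
#' @export
block_average <- function(stack, block_px = 50) {
  d <- dim(stack$frames)
  b <- as.integer(block_px)
  if (b > min(d[1], d[2])) {
    abort(sprintf("block_px = %d exceeds the %d x %d frame.", b, d[1], d[2]))
  }
  R <- d[1] %/% b; C <- d[2] %/% b
  rg <- rep(seq_len(R), each = b)
  cg <- rep(seq_len(C), each = b)
  vals <- array(NA_real_, dim = c(R, C, d[3]))
  low_cover <- matrix(FALSE, R, C)
  for (k in seq_len(d[3])) {
    fr <- stack$frames[seq_len(R * b), seq_len(C * b), k]
    fin <- is.finite(fr)
    fr[!fin] <- 0
    sums <- t(rowsum(t(rowsum(fr, rg)), cg))        # R x C block sums
    cnts <- t(rowsum(t(rowsum(fin + 0, rg)), cg))   # finite-pixel counts
    cell <- sums / cnts
    cell[cnts == 0] <- NA_real_
    low_cover <- low_cover | (cnts < b * b / 2)
    vals[, , k] <- cell
  }
  if (any(low_cover)) {
    vals[array(rep(low_cover, d[3]), dim = dim(vals))] <- NA_real_
  }
  grid_series(stack$variable, vals, stack$times, b,
              missing_mask = low_cover | apply(vals, c(1, 2), function(v) any(!is.finite(v))))
}

#' Temporal filtering of a grid series
#'
#' @param grid A [grid_series()].
#' @inheritParams temporal_mean_filter
#' @return A filtered `grid_series`.
#' @export
filter_grid <- function(grid, kernel_min = 5, step_min = 1) {
  d <- dim(grid$values)
  flat <- grid$values
  dim(flat) <- c(d[1] * d[2], d[3])
  f <- temporal_mean_filter(flat, grid$times, kernel_min, step_min)
  arr <- f$values
  dim(arr) <- c(d[1], d[2], length(f$times))
  grid_series(grid$variable, arr, f$times, grid$block_px,
              missing_mask = grid$missing_mask)
}

#' Fractional-change series
#'
#' Forward-differenced relative change, the vasodilation/vasoconstriction
#' index used for niche clustering when applied to blood volume:
#' `out[t] = (v[t+1] - v[t]) / v[t]`. Steps whose denominator is nonpositive
#' or non-finite are flagged missing rather than raising an error.
#'
#' @param x Numeric series (strictly positive where defined).
#' @return Numeric vector of length `length(x) - 1`.
#' @examples
#' fractional_change_series(c(100, 110, 99))  # 0.10, -0.10
#' @export
fractional_change_series <- function(x) {
  n <- length(x)
  if (n < 2) abort("Need at least two points for a fractional change.")
  denom <- x[-n]
  out <- (x[-1] - denom) / denom
  out[!is.finite(denom) | denom <= 0] <- NA_real_
  out
}

#' Fractional-change grid series
#'
#' Applies [fractional_change_series()] to every sub-region of a grid; the
#' result has one fewer time point, stamped at each interval's start.
#'
#' @param grid A [grid_series()].
#' @return A `grid_series` of fractional changes.
#' @export
fractional_change_grid <- function(grid) {
  d <- dim(grid$values)
  vals <- array(NA_real_, dim = c(d[1], d[2], d[3] - 1L))
  denom <- grid$values[, , -d[3], drop = FALSE]
  vals <- (grid$values[, , -1, drop = FALSE] - denom) / denom
  vals[denom <= 0 | !is.finite(denom)] <- NA_real_
  grid_series(grid$variable, vals, grid$times[-d[3]], grid$block_px,
              missing_mask = grid$missing_mask)
}

#' Windowed signed reduction
#'
#' Mean over an early window minus mean over a late window; positive when the
#' variable declined, matching the sign convention in which a blood-flow
#' reduction is reported as -dBF.
#'
#' @param x Numeric series.
#' @param early_idx,late_idx Non-overlapping index vectors into `x`.
#' @return The signed reduction, a scalar.
#' @examples
#' windowed_reduction(c(8, 8, 8, 2, 2, 2), 1:3, 4:6)  # 6
#' @export
windowed_reduction <- function(x, early_idx, late_idx) {
  if (length(early_idx) == 0 || length(late_idx) == 0) abort("Windows must be non-empty.")
  if (length(intersect(early_idx, late_idx)) > 0) abort("Windows must not overlap.")
  if (max(early_idx, late_idx) > length(x) || min(early_idx, late_idx) < 1) {
    abort("Window indices fall outside the series.")
  }
  mean(x[early_idx]) - mean(x[late_idx])
}

#' Sub-region series as a matrix
#'
#' Flattens the non-missing cells of a grid series into an M x N matrix in
#' row-major cell order, with the cell index bookkeeping most module
#' internals share.
#'
#' @param grid A [grid_series()].
#' @return List with `series` (M x N matrix) and `cells` (tibble of
#'   `cell_row`, `cell_col`, 1-based, row-major order).
#' @export
cell_series_matrix <- function(grid) {
  d <- dim(grid$values)
  keep <- which(!t(grid$missing_mask))  # row-major scan
  cells <- tibble(
    cell_row = ((keep - 1) %/% d[2]) + 1L,
    cell_col = ((keep - 1) %% d[2]) + 1L
  )
  series <- matrix(NA_real_, nrow = nrow(cells), ncol = d[3])
  for (i in seq_len(nrow(cells))) {
    series[i, ] <- grid$values[cells$cell_row[i], cells$cell_col[i], ]
  }
  list(series = series, cells = cells)
}

#' @method as_tibble grid_series
#' @export
as_tibble.grid_series <- function(x, ...) {
  d <- dim(x$values)
  tidyr::expand_grid(cell_row = seq_len(d[1]), cell_col = seq_len(d[2])) |>
    dplyr::mutate(missing = x$missing_mask[cbind(.data$cell_row, .data$cell_col)]) |>
    tidyr::expand_grid(tibble(time_idx = seq_len(d[3]), time_min = x$times)) |>
    dplyr::mutate(value = x$values[cbind(.data$cell_row, .data$cell_col, .data$time_idx)])
}

#' End-to-end pre-processing of a trial
#'
#' Resamples all stacks onto the per-minute base, applies the temporal
#' running-mean filter, and block-averages into sub-region series — the chain
#' every analysis module expects.
#'
#' @param trial A `hemo_trial`.
#' @param config A [run_config()].
#' @return Named list of filtered [grid_series()], one per variable.
#' @export
preprocess_trial <- function(trial, config = run_config()) {
  trial <- resample_to_common_grid(trial, step_min = config$temporal_step_min)
  lapply(trial$stacks, function(st) {
    filter_grid(block_average(st, config$block_px),
                kernel_min = config$temporal_kernel_min,
                step_min = config$temporal_step_min)
  })
}
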