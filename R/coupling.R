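#' Windowed blood-flow/blood-volume coupling maps
#'
#' Coupling between two hemodynamic variables is the Pearson correlation of
#' their sub-region time-series. Correlations are computed per cell over two
#' successive windows (by default the two halves of the run) and each cell is
#' classified: TIGHT when `r > threshold` in both windows, POOR when
#' `r < threshold` in both, INTERMITTENT otherwise; cells with a constant or
#' missing series in any window are MISSING. Comparisons are strict, so a
#' correlation exactly at the threshold never counts as exceeding it.
#'
#' @param bf_grid,bv_grid [grid_series()] of blood flow and blood volume on a
#'   shared grid and time base.
#' @param windows List of two time-index windows; default [halfway_windows()].
#' @param corr_threshold Classification threshold (default 0.7).
#' @return A `coupling_result` with `r_window1`, `r_window2`, `delta_r`
#'   matrices and a `category` factor matrix.
#' @export
coupling_maps <- function(bf_grid, bv_grid, windows = NULL,
                          corr_threshold = 0.7) {
  if (!identical(dim(bf_grid$values), dim(bv_grid$values))) {
    abort("BF and BV grids must share shape and time base.")
  }
  d <- dim(bf_grid$values)
  if (is.null(windows)) windows <- halfway_windows(d[3])
  if (length(windows) != 2) abort("Exactly two windows are required.")
  if (any(lengths(windows) < 3)) abort("Each window needs at least 3 time points.")
  flatten <- function(grid, w) {
    m <- matrix(grid$values[, , w, drop = FALSE], nrow = d[1] * d[2])
    m
  }
  r_of <- function(w) {
    r <- row_cor(flatten(bf_grid, w), flatten(bv_grid, w))
    matrix(r, d[1], d[2])
  }
  r1 <- r_of(windows[[1]])
  r2 <- r_of(windows[[2]])
  missing <- bf_grid$missing_mask | bv_grid$missing_mask | is.na(r1) | is.na(r2)
  r1[missing] <- NA_real_; r2[missing] <- NA_real_
  cat_mat <- matrix(NA_character_, d[1], d[2])
  cat_mat[!missing & r1 > corr_threshold & r2 > corr_threshold] <- "TIGHT"
  cat_mat[!missing & r1 < corr_threshold & r2 < corr_threshold] <- "POOR"
  cat_mat[!missing & is.na(cat_mat)] <- "INTERMITTENT"
  cat_mat[missing] <- "MISSING"
  structure(
    list(r_window1 = r1, r_window2 = r2, delta_r = r2 - r1,
         category = cat_mat, corr_threshold = corr_threshold,
         windows = windows),
    class = "coupling_result"
  )
}

#' @export
print.coupling_result <- function(x, ...) {
  tab <- table(factor(x$category, levels = c("TIGHT", "POOR", "INTERMITTENT", "MISSING")))
  cat(sprintf("<coupling_result> threshold %g | %s\n", x$corr_threshold,
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @method tidy coupling_result
#' @export
tidy.coupling_result <- function(x, ...) {
  d <- dim(x$r_window1)
  tidyr::expand_grid(cell_row = seq_len(d[1]), cell_col = seq_len(d[2])) |>
    dplyr::mutate(
      r_window1 = x$r_window1[cbind(.data$cell_row, .data$cell_col)],
      r_window2 = x$r_window2[cbind(.data$cell_row, .data$cell_col)],
      delta_r = x$delta_r[cbind(.data$cell_row, .data$cell_col)],
      category = factor(x$category[cbind(.data$cell_row, .data$cell_col)],
                        levels = c("TIGHT", "POOR", "INTERMITTENT", "MISSING"))
    )
}

#' Coupling-change table
#'
#' One row per non-missing cell with the first-window coupling and its change
#' across windows (`r_window2 - r_window1`), the representation behind the
#' coupling-trend scatter.
#'
#' @param result A [coupling_maps()] result.
#' @return Tibble with `cell_row`, `cell_col`, `r_window1`, `delta_r`.
#' @export
coupling_change_table <- function(result) {
  tidy(result) |>
    dplyr::filter(.data$category != "MISSING") |>
    dplyr::select("cell_row", "cell_col", "r_window1", "delta_r")
}

#' Tumor-area fractions per coupling category
#'
#' @param result A [coupling_maps()] result.
#' @return Tibble with `category` and `percent` over
#'   TIGHT/POOR/INTERMITTENT, summing to 100 over non-missing cells.
#' @export
category_area_fractions <- function(result) {
  cats <- c("TIGHT", "POOR", "INTERMITTENT")
  cc <- result$category[result$category != "MISSING"]
  n <- length(cc)
  tibble(
    category = factor(cats, levels = cats),
    percent = vapply(cats, function(k) 100 * sum(cc == k) / n, numeric(1))
  )
}

#' Coupling analysis of a trial
#'
#' Pre-processes the BF and BV stacks and runs [coupling_maps()].
#'
#' @param trial A `hemo_trial` with `BF` and `BV` stacks.
#' @param config A [run_config()].
#' @param windows Optional two windows on the filtered base.
#' @return A `coupling_result`.
#' @export
analyze_coupling <- function(trial, config = run_config(), windows = NULL) {
  grids <- preprocess_trial(trial, config)
  if (!all(c("BF", "BV") %in% names(grids))) abort("Trial must contain BF and BV stacks.")
  coupling_maps(grids$BF, grids$BV, windows = windows,
                corr_threshold = config$corr_threshold)
}
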