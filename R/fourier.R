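#' Frequency band definition
#'
#' Maps a period range in minutes onto the FFT bins of an N-point series
#' sampled every `dt_min` minutes: bin `k` carries period `N * dt / k`, and a
#' bin belongs to the band when its period lies in `[period_range[1],
#' period_range[2]]` (inclusive bounds). With the default 56-point filtered
#' hour, the low-frequency band (periods 10-56 min) is bins 1-5 and the
#' high-frequency band (periods 2-10 min) is bins 6-28.
#'
#' @param label Band label, e.g. `"LF"` or `"HF"`.
#' @param period_range Two periods in minutes, `c(lower, upper)`.
#' @param n Series length N.
#' @param dt_min Sampling interval in minutes.
#' @return A `frequency_band` with the implied `index_set` of bins.
#' @examples
#' frequency_band("LF", c(10, 56), n = 56)$index_set  # 1:5
#' @export
frequency_band <- function(label, period_range, n, dt_min = 1) {
  stopifnot(length(period_range) == 2, all(period_range > 0),
            period_range[2] >= period_range[1])
  k <- seq_len(n %/% 2)
  periods <- n * dt_min / k
  idx <- k[periods >= period_range[1] & periods <= period_range[2]]
  structure(list(label = label, period_range = as.numeric(period_range),
                 n = as.integer(n), dt_min = dt_min, index_set = idx),
            class = "frequency_band")
}

#' @export
print.frequency_band <- function(x, ...) {
  cat(sprintf("<frequency_band %s> periods %g-%g min, bins {%s} of N=%d\n",
              x$label, x$period_range[1], x$period_range[2],
              paste(range(x$index_set), collapse = ".."), x$n))
  invisible(x)
}

#' One-sided power spectrum of a mean-normalized series
#'
#' The series is first expressed as fractional fluctuation about its temporal
#' mean, `y = x / mean(x) - 1`, so that powers are referenced to the mean
#' level (0 dB = fluctuation power equal to the squared mean). The one-sided
#' power at bin `k` is `2 |Y_k|^2 / N^2` for `0 < k < N/2` (the Nyquist bin,
#' when N is even, is not doubled); the DC bin is identically zero by
#' construction. A pure modulation `x = m (1 + c cos(2 pi k t / N))` lands at
#' bin `k` with power `c^2 / 2`, and the one-sided powers sum to the variance
#' of `y` (Parseval).
#'
#' @param x Numeric series of length N (N >= 8) with positive mean.
#' @return Numeric vector of length `floor(N / 2) + 1`: one-sided power at
#'   bins `0..floor(N/2)`.
#' @export
normalized_power_spectrum <- function(x) {
  n <- length(x)
  if (n < 8) abort("Need at least 8 points for a spectrum.")
  m <- mean(x)
  if (!is.finite(m) || m <= 0) abort("Series mean must be positive for mean-normalization.")
  y <- x / m - 1
  Y <- fft(y)
  half <- n %/% 2
  p <- numeric(half + 1)
  ks <- seq_len(half)
  p[ks + 1] <- 2 * Mod(Y[ks + 1])^2 / n^2
  if (n %% 2 == 0) p[half + 1] <- Mod(Y[half + 1])^2 / n^2
  p[1] <- 0
  p
}

band_power_linear <- function(p, band) {
  sum(p[band$index_set + 1])
}

#' Band power map
#'
#' Sums the one-sided spectral power of every sub-region over a band's bins
#' and reports it in dB (`10 log10`). Cells at or below the noise floor are
#' omitted (`NA`).
#'
#' @param grid A filtered [grid_series()] whose length matches `band$n`.
#' @param band A [frequency_band()].
#' @param noise_floor_db Powers at or below this level are treated as noise.
#' @return R x C matrix of dB powers.
#' @export
band_power_map <- function(grid, band, noise_floor_db = -60) {
  d <- dim(grid$values)
  if (d[3] != band$n) {
    abort(sprintf("Grid has %d time points but band expects N = %d.", d[3], band$n))
  }
  out <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (grid$missing_mask[i, j]) next
    v <- grid$values[i, j, ]
    if (any(!is.finite(v)) || mean(v) <= 0) next
    pw <- band_power_linear(normalized_power_spectrum(v), band)
    db <- if (pw > 0) 10 * log10(pw) else -Inf
    if (db > noise_floor_db) out[i, j] <- db
  }
  out
}

#' Band-wise spectral summary of a grid
#'
#' Computes per-cell one-sided spectra once, then the dB power map of each
#' band and the linear-power high/low ratio map (omitted wherever either band
#' sits at or below the noise floor).
#'
#' @param grid A filtered [grid_series()].
#' @param lf,hf [frequency_band()] objects; defaults use the configured
#'   period ranges at the grid's N and cadence.
#' @param config A [run_config()] (noise floor and default band ranges).
#' @return A `band_spectrum_map` with `power_db` (list of matrices by band
#'   label), `ratio` (linear H/L), `spectra` (M x bins matrix), `cells`,
#'   `bands` and `noise_floor_db`.
#' @export
band_spectra <- function(grid, lf = NULL, hf = NULL, config = run_config()) {
  d <- dim(grid$values)
  dt <- if (d[3] > 1) grid$times[2] - grid$times[1] else 1
  lf <- lf %||% frequency_band("LF", config$lf_period_range_min, d[3], dt)
  hf <- hf %||% frequency_band("HF", config$hf_period_range_min, d[3], dt)
  csm <- cell_series_matrix(grid)
  nb <- d[3] %/% 2 + 1
  spectra <- matrix(NA_real_, nrow(csm$cells), nb)
  for (i in seq_len(nrow(csm$cells))) {
    v <- csm$series[i, ]
    if (any(!is.finite(v)) || mean(v) <= 0) next
    spectra[i, ] <- normalized_power_spectrum(v)
  }
  floor_db <- config$noise_floor_db
  to_map <- function(band) {
    m <- matrix(NA_real_, d[1], d[2])
    for (i in seq_len(nrow(csm$cells))) {
      if (any(is.na(spectra[i, ]))) next
      pw <- band_power_linear(spectra[i, ], band)
      db <- if (pw > 0) 10 * log10(pw) else -Inf
      if (db > floor_db) m[csm$cells$cell_row[i], csm$cells$cell_col[i]] <- db
    }
    m
  }
  lf_map <- to_map(lf); hf_map <- to_map(hf)
  ratio <- 10^(hf_map / 10) / 10^(lf_map / 10)  # linear ratio; NA propagates
  structure(
    list(power_db = setNames(list(lf_map, hf_map), c(lf$label, hf$label)),
         ratio = ratio, spectra = spectra, cells = csm$cells,
         bands = list(lf = lf, hf = hf), noise_floor_db = floor_db,
         variable = grid$variable, dt_min = dt, n = d[3]),
    class = "band_spectrum_map"
  )
}

#' @export
print.band_spectrum_map <- function(x, ...) {
  cat(sprintf("<band_spectrum_map %s> N = %d, bands %s, %d cells\n",
              x$variable, x$n,
              paste(names(x$power_db), collapse = "/"), nrow(x$cells)))
  invisible(x)
}

#' @method tidy band_spectrum_map
#' @export
tidy.band_spectrum_map <- function(x, ...) {
  purrr::imap_dfr(x$power_db, function(m, lab) {
    d <- dim(m)
    tidyr::expand_grid(cell_row = seq_len(d[1]), cell_col = seq_len(d[2])) |>
      dplyr::mutate(band = lab,
                    power_db = m[cbind(.data$cell_row, .data$cell_col)])
  })
}

#' High/low band-power ratio map
#'
#' Ratio of linear band powers (high over low); a cell is omitted when either
#' band is at or below the noise floor, or when the low-frequency power is
#' zero.
#'
#' @param grid A filtered [grid_series()].
#' @inheritParams band_spectra
#' @return R x C matrix of ratios.
#' @export
band_ratio_map <- function(grid, lf = NULL, hf = NULL, config = run_config()) {
  band_spectra(grid, lf = lf, hf = hf, config = config)$ratio
}

#' Per-cell spectrum table
#'
#' @param x A [band_spectra()] result.
#' @return Tibble with `cell_row`, `cell_col`, `bin`, `period_min`,
#'   `power_db` for bins `1..floor(N/2)`.
#' @export
spectrum_table <- function(x) {
  ks <- seq_len(x$n %/% 2)
  purrr::map_dfr(seq_len(nrow(x$cells)), function(i) {
    if (any(is.na(x$spectra[i, ]))) return(NULL)
    p <- x$spectra[i, ks + 1]
    tibble(cell_row = x$cells$cell_row[i], cell_col = x$cells$cell_col[i],
           bin = ks, period_min = x$n * x$dt_min / ks,
           power_db = ifelse(p > 0, 10 * log10(p), -Inf))
  })
}

#' Cross-variable power scatter at chosen periods
#'
#' For each requested period (which must map to an integer FFT bin,
#' e.g. 56 and 28 minutes at N = 56), pairs the per-cell dB powers of several
#' variables; rows where any variable is at or below the noise floor are
#' dropped.
#'
#' @param maps Named list of [band_spectra()] results sharing grid and N.
#' @param periods_min Periods of interest in minutes.
#' @return Tibble with `period_min`, `cell_row`, `cell_col` and one
#'   `power_db_<variable>` column per map.
#' @export
power_scatter <- function(maps, periods_min) {
  stopifnot(length(maps) >= 2)
  n <- maps[[1]]$n; dt <- maps[[1]]$dt_min
  for (m in maps) {
    if (m$n != n) abort("All variables must share the FFT length.")
    if (!identical(m$cells, maps[[1]]$cells)) {
      abort("All variables must share the same non-missing grid cells.")
    }
  }
  valid <- n * dt / seq_len(n %/% 2)
  rows <- purrr::map_dfr(periods_min, function(Tm) {
    k <- n * dt / Tm
    if (abs(k - round(k)) > 1e-9 || round(k) < 1 || round(k) > n %/% 2) {
      abort(sprintf("Period %g min has no integer bin at N = %d; valid periods: %s",
                    Tm, n, paste(signif(valid, 4), collapse = ", ")))
    }
    k <- as.integer(round(k))
    base <- maps[[1]]$cells
    out <- dplyr::mutate(base, period_min = Tm, .before = 1)
    for (nm in names(maps)) {
      p <- maps[[nm]]$spectra[, k + 1]
      db <- ifelse(!is.na(p) & p > 0, 10 * log10(p), NA_real_)
      db[!is.na(db) & db <= maps[[nm]]$noise_floor_db] <- NA_real_
      out[[paste0("power_db_", nm)]] <- db
    }
    out
  })
  tidyr::drop_na(rows)
}
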