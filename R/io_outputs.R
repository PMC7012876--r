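#' Write a 2D map as a 32-bit float TIFF
#'
#' Values are affinely rescaled into \[0, 1\] for storage (the tiff format
#' used stores floats in that range); the original range is recorded in a
#' JSON sidecar next to the image so the map can be reconstructed. Missing
#' cells are stored as 0 and listed in the sidecar.
#'
#' @param m Numeric matrix.
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_map_tiff <- function(m, path) {
  fin <- is.finite(m)
  lo <- if (any(fin)) min(m[fin]) else 0
  hi <- if (any(fin)) max(m[fin]) else 1
  span <- if (hi > lo) hi - lo else 1
  scaled <- (m - lo) / span
  scaled[!fin] <- 0
  suppressWarnings(tiff::writeTIFF(scaled, path, bits.per.sample = 32L))
  jsonlite::write_json(
    list(min = lo, max = hi,
         missing = which(!fin) - 1L),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

map_to_tibble <- function(m, value_name = "value") {
  d <- dim(m)
  out <- tidyr::expand_grid(cell_row = seq_len(d[1]), cell_col = seq_len(d[2]))
  out[[value_name]] <- m[cbind(out$cell_row, out$cell_col)]
  out
}

#' Write a provenance record for a run
#'
#' Emits a JSON record of the configuration and the MD5 checksums of the
#' input files, so any output directory documents exactly what produced it.
#'
#' @param path Output JSON path.
#' @param config The [run_config()] used.
#' @param input_paths Character vector of input files to checksum.
#' @param extra Optional named list of additional fields.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, config, input_paths = character(0),
                             extra = list()) {
  files <- input_paths[file.exists(input_paths)]
  rec <- c(list(
    written_at = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = unclass(config),
    inputs = as.list(tools::md5sum(files))
  ), extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write module results to a directory
#'
#' Each result type writes its standard artifact set: contour and profile
#' CSVs for the propagation module, label maps and centroid series for the
#' cluster module, correlation/category maps and area fractions for the
#' coupling module, per-variable response maps for the perturbation module,
#' and band/ratio maps plus per-cell spectra for the spectral module. Maps
#' are written both as float TIFF (with range sidecars) and as CSV.
#'
#' @param x A module result object.
#' @param dir Output directory (created if needed).
#' @param ... Unused.
#' @return `dir`, invisibly.
#' @export
write_results <- function(x, dir, ...) UseMethod("write_results")

#' @rdname write_results
#' @export
write_results.wavefront_set <- function(x, dir, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(as_tibble(x), file.path(dir, "wavefront_contours.csv"))
  readr::write_csv(tibble(time_min = x$times, area_px = x$areas),
                   file.path(dir, "hypoxic_area.csv"))
  invisible(dir)
}

#' @rdname write_results
#' @export
write_results.propagation_profile <- function(x, dir, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lab <- attr(x, "direction_label") %||% "ray"
  out <- dplyr::mutate(as_tibble(x), direction = lab, .before = 1)
  readr::write_csv(out, file.path(dir, sprintf("profile_%s.csv", lab)))
  invisible(dir)
}

#' @rdname write_results
#' @export
write_results.cluster_labeling <- function(x, dir, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_map_tiff(x$labels, file.path(dir, "niche_labels.tif"))
  readr::write_csv(tidy(x), file.path(dir, "niche_membership.csv"))
  readr::write_csv(x$centroids, file.path(dir, "niche_centroids.csv"))
  invisible(dir)
}

#' @rdname write_results
#' @export
write_results.coupling_result <- function(x, dir, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_map_tiff(x$r_window1, file.path(dir, "r_window1.tif"))
  write_map_tiff(x$r_window2, file.path(dir, "r_window2.tif"))
  cat_codes <- matrix(match(x$category, c("TIGHT", "POOR", "INTERMITTENT")),
                      nrow(x$category))
  write_map_tiff(cat_codes, file.path(dir, "category.tif"))
  readr::write_csv(tidy(x), file.path(dir, "coupling_cells.csv"))
  readr::write_csv(category_area_fractions(x), file.path(dir, "area_fractions.csv"))
  readr::write_csv(coupling_change_table(x), file.path(dir, "coupling_change.csv"))
  invisible(dir)
}

#' @rdname write_results
#' @export
write_results.perturbation_response <- function(x, dir, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(x$variables)) {
    v <- x$variables[[nm]]
    write_map_tiff(v$r_map, file.path(dir, sprintf("r_map_%s.tif", nm)))
    write_map_tiff(v$delta_map, file.path(dir, sprintf("delta_map_%s.tif", nm)))
  }
  readr::write_csv(tidy(x), file.path(dir, "perturbation_cells.csv"))
  invisible(dir)
}

#' @rdname write_results
#' @export
write_results.band_spectrum_map <- function(x, dir, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(x$power_db)) {
    write_map_tiff(x$power_db[[nm]],
                   file.path(dir, sprintf("power_%s_db.tif", nm)))
  }
  write_map_tiff(x$ratio, file.path(dir, "band_ratio.tif"))
  readr::write_csv(spectrum_table(x), file.path(dir, "cell_spectra.csv"))
  invisible(dir)
}
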