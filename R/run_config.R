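#' Analysis run configuration
#'
#' Collects every tunable threshold and kernel used across the analysis
#' modules, with defaults matching the published operating point of the
#' toolkit: a 30% oxygen-saturation threshold for hypoxia, 50x50-pixel
#' sub-regions, a 5-minute running-mean kernel stepped by 1 minute, a
#' correlation threshold of 0.7 with a 5% minimum cluster size, a -60 dB
#' spectral noise floor, and low/high vasomotion bands covering 10-56 and
#' 2-10 minute periods.
#'
#' @param hypoxia_threshold_pct Hb_sat threshold (%) below which a pixel is
#'   called hypoxic.
#' @param block_px Side length, in pixels, of the square sub-regions used for
#'   spatial block averaging.
#' @param temporal_kernel_min Length of the temporal running-mean kernel, in
#'   minutes.
#' @param temporal_step_min Step between successive filter windows, in minutes.
#' @param corr_threshold Pearson correlation threshold shared by the cluster,
#'   coupling and perturbation modules; comparisons are strict (`r > threshold`).
#' @param min_cluster_frac Minimum niche size as a fraction of the non-missing
#'   sub-regions in the field of view.
#' @param noise_floor_db Band powers at or below this level (dB) are treated as
#'   noise and omitted from maps.
#' @param lf_period_range_min,hf_period_range_min Period ranges, in minutes,
#'   of the low- and high-frequency vasomotion bands.
#' @param cadence_min Nominal acquisition cadence in minutes, used when a trial
#'   carries no timing sidecar (one frame per variable every 30 s by default).
#' @param capture_radius_px When the wavefront origin pixel itself is not
#'   hypoxic at some time point, the nearest hypoxic pixel within this radius
#'   seeds the component search instead.
#'
#' @return An object of class `run_config` (a named list).
#' @examples
#' cfg <- run_config()
#' cfg$corr_threshold
#' @export
run_config <- function(hypoxia_threshold_pct = 30,
                       block_px = 50,
                       temporal_kernel_min = 5,
                       temporal_step_min = 1,
                       corr_threshold = 0.7,
                       min_cluster_frac = 0.05,
                       noise_floor_db = -60,
                       lf_period_range_min = c(10, 56),
                       hf_period_range_min = c(2, 10),
                       cadence_min = 0.5,
                       capture_radius_px = 25) {
  cfg <- list(
    hypoxia_threshold_pct = as.numeric(hypoxia_threshold_pct),
    block_px = as.integer(block_px),
    temporal_kernel_min = as.numeric(temporal_kernel_min),
    temporal_step_min = as.numeric(temporal_step_min),
    corr_threshold = as.numeric(corr_threshold),
    min_cluster_frac = as.numeric(min_cluster_frac),
    noise_floor_db = as.numeric(noise_floor_db),
    lf_period_range_min = as.numeric(lf_period_range_min),
    hf_period_range_min = as.numeric(hf_period_range_min),
    cadence_min = as.numeric(cadence_min),
    capture_radius_px = as.numeric(capture_radius_px)
  )
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  stopifnot(
    cfg$hypoxia_threshold_pct > 0, cfg$hypoxia_threshold_pct < 100,
    cfg$block_px >= 1,
    cfg$temporal_kernel_min > 0, cfg$temporal_step_min > 0,
    cfg$cadence_min > 0, cfg$capture_radius_px >= 0
  )
  if (!(cfg$corr_threshold > 0 && cfg$corr_threshold <= 1)) {
    abort("`corr_threshold` must lie in (0, 1].")
  }
  if (!(cfg$min_cluster_frac > 0 && cfg$min_cluster_frac < 1)) {
    abort("`min_cluster_frac` must lie in (0, 1).")
  }
  for (nm in c("lf_period_range_min", "hf_period_range_min")) {
    rng <- cfg[[nm]]
    if (length(rng) != 2 || any(rng <= 0) || rng[2] < rng[1]) {
      abort(sprintf("`%s` must be two positive minutes with upper >= lower.", nm))
    }
  }
  invisible(cfg)
}

#' Read a run configuration from YAML
#'
#' Fields in the file override the package defaults; unknown fields raise an
#' error so that typos in a config do not silently fall back to defaults.
#'
#' @param path Path to a YAML file whose keys mirror the arguments of
#'   [run_config()].
#' @return A `run_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    abort(sprintf("Unknown config field(s): %s", paste(bad, collapse = ", ")))
  }
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
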