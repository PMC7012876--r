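HEMO_VARIABLES <- c("HBSAT", "BV", "BF", "FL", "REFERENCE")

#' Construct a frame stack
#'
#' A frame stack holds one hemodynamic variable's co-registered 2D frames over
#' time, with acquisition times in minutes and the pixel size in micrometers.
#' Oxygen saturation (`HBSAT`) is expressed in percent and must lie in
#' \[0, 100\]; blood volume (`BV`) and blood flow (`BF`) are nonnegative
#' arbitrary units.
#'
#' @param variable One of `"HBSAT"`, `"BV"`, `"BF"`, `"FL"`, `"REFERENCE"`.
#' @param frames A numeric H x W x N array, or a list of H x W matrices.
#' @param times Acquisition times in minutes, strictly increasing, one per frame.
#' @param pixel_size Micrometers per pixel (nominally 5).
#' @return An object of class `frame_stack`.
#' @examples
#' fs <- frame_stack("BV", array(1, c(4, 4, 3)), times = c(0, 0.5, 1))
#' dim(fs$frames)
#' @export
frame_stack <- function(variable, frames, times, pixel_size = 5) {
  variable <- toupper(variable)
  if (!variable %in% HEMO_VARIABLES) {
    abort(sprintf("Unknown variable '%s' (expected one of %s).",
                  variable, paste(HEMO_VARIABLES, collapse = ", ")))
  }
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1) {
      bad <- which(!vapply(frames, function(f) identical(dim(f), dim(frames[[1]])), TRUE))[1]
      abort(sprintf("Frame %d has dimensions %s, expected %s.", bad,
                    paste(dim(frames[[bad]]), collapse = "x"),
                    paste(dim(frames[[1]]), collapse = "x")))
    }
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dim(frames[[1]]), length(frames)))
  }
  if (length(dim(frames)) != 3) abort("`frames` must be an H x W x N array.")
  times <- as.numeric(times)
  if (length(times) != dim(frames)[3]) {
    abort(sprintf("length(times) == %d but stack has %d frames.",
                  length(times), dim(frames)[3]))
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    abort("`times` must be strictly increasing.")
  }
  structure(
    list(variable = variable, frames = frames, times = times,
         pixel_size = as.numeric(pixel_size)),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack %s> %d x %d px, %d frames, %.3g-%.3g min, %.3g um/px\n",
              x$variable, d[1], d[2], d[3], min(x$times), max(x$times), x$pixel_size))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$frames)

stack_range_violations <- function(stack) {
  if (stack$variable == "HBSAT") {
    sum(stack$frames < 0 | stack$frames > 100, na.rm = TRUE)
  } else if (stack$variable %in% c("BV", "BF")) {
    sum(stack$frames < 0, na.rm = TRUE)
  } else {
    0L
  }
}

#' Construct a trial
#'
#' A trial bundles the co-registered frame stacks of one imaging session
#' (typically `HBSAT`, `BV` and `BF`) under a common field of view, together
#' with an optional perturbation paradigm for gas-inhalation sessions.
#'
#' @param trial_id Trial label.
#' @param stacks Named list of [frame_stack()] objects; names must match each
#'   stack's `variable`.
#' @param paradigm Optional [perturbation_paradigm()].
#' @return An object of class `hemo_trial`.
#' @export
trial <- function(trial_id, stacks, paradigm = NULL) {
  if (is.null(names(stacks)) || any(names(stacks) == "")) {
    names(stacks) <- vapply(stacks, function(s) s$variable, character(1))
  }
  for (nm in names(stacks)) {
    if (!inherits(stacks[[nm]], "frame_stack")) abort("All stacks must be frame_stack objects.")
    if (!identical(nm, stacks[[nm]]$variable)) {
      abort(sprintf("Stack named '%s' holds variable '%s'.", nm, stacks[[nm]]$variable))
    }
  }
  shapes <- unique(lapply(stacks, function(s) dim(s$frames)[1:2]))
  if (length(shapes) > 1) abort("All stacks in a trial must share H x W.")
  structure(list(trial_id = as.character(trial_id), stacks = stacks,
                 paradigm = paradigm),
            class = "hemo_trial")
}

#' @export
print.hemo_trial <- function(x, ...) {
  cat(sprintf("<trial %s> variables: %s\n", x$trial_id,
              paste(names(x$stacks), collapse = ", ")))
  for (s in x$stacks) print(s)
  invisible(x)
}

natural_order <- function(files) {
  base <- basename(files)
  num <- suppressWarnings(as.numeric(gsub("\\D", "", base)))
  prefix <- gsub("\\d.*$", "", base)
  order(prefix, num, base, na.last = TRUE)
}

read_frame_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path, all = TRUE)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) abort("PNG input needs the 'png' package.")
    list(png::readPNG(path))
  } else {
    abort(sprintf("Unsupported frame format: %s", path))
  }
  lapply(img, function(m) {
    if (length(dim(m)) == 3) m <- m[, , 1]  # collapse grayscale channels
    m
  })
}

#' Load a trial from the on-disk folder convention
#'
#' The expected layout nests data first by trial and second by variable:
#' `root/<trial_id>/<VARIABLE>/` holds either one multi-page TIFF or a set of
#' numbered single-frame TIFF/PNG files (natural number order). An optional
#' `times.csv` sidecar in the variable folder (columns `frame_index`,
#' `minutes`) supplies acquisition times; otherwise times are synthesized at
#' the configured cadence. An optional `scale.csv` at the trial level
#' (columns `variable`, `scale`) rescales stored \[0, 1\] pixel values back to
#' physical units, as written by [write_trial()].
#'
#' @param root_path Directory containing trial folders.
#' @param trial_id Trial folder name.
#' @param config A [run_config()]; supplies the default cadence and pixel size
#'   context.
#' @param pixel_size Micrometers per pixel for all loaded stacks.
#' @return A `hemo_trial`.
#' @export
load_trial <- function(root_path, trial_id, config = run_config(), pixel_size = 5) {
  tdir <- file.path(root_path, trial_id)
  if (!dir.exists(tdir)) abort(sprintf("Trial directory not found: %s", tdir))
  subdirs <- list.dirs(tdir, recursive = FALSE)
  subdirs <- subdirs[toupper(basename(subdirs)) %in% HEMO_VARIABLES]
  if (length(subdirs) == 0) abort(sprintf("No variable subfolders in %s.", tdir))

  scales <- NULL
  scale_path <- file.path(tdir, "scale.csv")
  if (file.exists(scale_path)) {
    sc <- utils::read.csv(scale_path, stringsAsFactors = FALSE)
    scales <- setNames(sc$scale, toupper(sc$variable))
  }

  stacks <- list()
  for (vd in subdirs) {
    vname <- toupper(basename(vd))
    files <- list.files(vd, pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) == 0) abort(sprintf("Variable folder is empty: %s", vd))
    files <- files[natural_order(files)]
    frames <- unlist(lapply(files, read_frame_file), recursive = FALSE)
    if (length(frames) < 2) abort(sprintf("Need >= 2 frames in %s.", vd))
    ref_dim <- dim(frames[[1]])
    for (i in seq_along(frames)) {
      if (!identical(dim(frames[[i]]), ref_dim)) {
        abort(sprintf("Frame %d of %s is %s, expected %s.", i, vname,
                      paste(dim(frames[[i]]), collapse = "x"),
                      paste(ref_dim, collapse = "x")))
      }
    }
    n <- length(frames)
    times_path <- file.path(vd, "times.csv")
    times <- if (file.exists(times_path)) {
      tt <- utils::read.csv(times_path)
      if (nrow(tt) != n) abort(sprintf("times.csv in %s lists %d frames, folder has %d.",
                                       vd, nrow(tt), n))
      tt$minutes[order(tt$frame_index)]
    } else {
      (seq_len(n) - 1) * config$cadence_min
    }
    arr <- array(unlist(frames, use.names = FALSE), dim = c(ref_dim, n))
    if (!is.null(scales) && vname %in% names(scales)) arr <- arr * scales[[vname]]
    stacks[[vname]] <- frame_stack(vname, arr, times, pixel_size = pixel_size)
  }
  paradigm <- NULL
  ppath <- file.path(tdir, "paradigm.csv")
  if (file.exists(ppath)) {
    pp <- utils::read.csv(ppath, stringsAsFactors = FALSE)
    paradigm <- perturbation_paradigm(pp$state, pp$duration_min)
  }
  trial(trial_id, stacks, paradigm = paradigm)
}

#' Write a trial in the on-disk folder convention
#'
#' Stacks are stored as one multi-page 32-bit float TIFF per variable, scaled
#' into \[0, 1\] with the per-variable scale factor recorded in `scale.csv`,
#' plus a `times.csv` timing sidecar per variable. Storage is float32, so
#' values round-trip to about 1e-7 relative precision.
#'
#' @param trial A `hemo_trial`.
#' @param root_path Output root; the trial folder is created beneath it.
#' @return The trial directory path, invisibly.
#' @export
write_trial <- function(trial, root_path) {
  tdir <- file.path(root_path, trial$trial_id)
  dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
  scale_rows <- list()
  for (vname in names(trial$stacks)) {
    st <- trial$stacks[[vname]]
    vdir <- file.path(tdir, vname)
    dir.create(vdir, showWarnings = FALSE)
    hi <- max(st$frames, na.rm = TRUE)
    scl <- if (vname == "HBSAT") 100 else if (hi > 0) hi else 1
    pages <- lapply(seq_len(dim(st$frames)[3]), function(i) st$frames[, , i] / scl)
    suppressWarnings(tiff::writeTIFF(pages, file.path(vdir, "stack.tif"),
                                     bits.per.sample = 32L))
    utils::write.csv(
      data.frame(frame_index = seq_along(st$times), minutes = st$times),
      file.path(vdir, "times.csv"), row.names = FALSE
    )
    scale_rows[[vname]] <- data.frame(variable = vname, scale = scl)
  }
  utils::write.csv(do.call(rbind, scale_rows), file.path(tdir, "scale.csv"),
                   row.names = FALSE)
  if (!is.null(trial$paradigm)) {
    utils::write.csv(
      data.frame(state = trial$paradigm$segments$state,
                 duration_min = trial$paradigm$segments$duration_min),
      file.path(tdir, "paradigm.csv"), row.names = FALSE
    )
  }
  invisible(tdir)
}

#' Validate a trial against the data-model invariants
#'
#' Report-only check of frame counts, the common time base across variables,
#' non-finite pixel fractions and physical range violations (oxygen
#' saturation outside \[0, 100\]%, negative blood volume/flow).
#'
#' @param trial A `hemo_trial`.
#' @return A `trial_validation` object with an `ok` flag, a per-variable
#'   summary tibble, and a character vector of problems.
#' @export
validate_trial <- function(trial) {
  rows <- purrr::map(trial$stacks, function(st) {
    d <- dim(st$frames)
    tibble(
      variable = st$variable,
      n_frames = d[3], height = d[1], width = d[2],
      frac_nonfinite = mean(!is.finite(st$frames)),
      range_violations = stack_range_violations(st),
      times_increasing = all(diff(st$times) > 0)
    )
  })
  summary <- dplyr::bind_rows(rows)
  problems <- character(0)
  counts <- unique(summary$n_frames)
  time_bases <- unique(lapply(trial$stacks, function(s) round(s$times, 9)))
  common_time_base <- length(counts) == 1 && length(time_bases) == 1
  if (!common_time_base) {
    problems <- c(problems, sprintf(
      "Stacks do not share a time base (frame counts: %s).",
      paste(summary$n_frames, collapse = ", ")))
  }
  if (any(summary$range_violations > 0)) {
    bad <- summary$variable[summary$range_violations > 0]
    problems <- c(problems, sprintf("Range violations in: %s.", paste(bad, collapse = ", ")))
  }
  if (any(!summary$times_increasing)) {
    problems <- c(problems, "Non-increasing acquisition times.")
  }
  structure(
    list(ok = length(problems) == 0, summary = summary,
         common_time_base = common_time_base, problems = problems),
    class = "trial_validation"
  )
}

#' @export
print.trial_validation <- function(x, ...) {
  cat(sprintf("<trial_validation> ok = %s\n", x$ok))
  print(x$summary)
  if (length(x$problems)) cat(paste0("  - ", x$problems, collapse = "\n"), "\n")
  invisible(x)
}

#' Resample every stack of a trial onto a shared time base
#'
#' Frames whose timestamps fall in each bin `[t, t + step)` are averaged, so
#' that all downstream analyses run on one regular (by default per-minute)
#' base. Bins are anchored at the latest start time common to all stacks.
#'
#' @param trial A `hemo_trial`.
#' @param step_min Bin width in minutes (default 1, the per-minute analysis base).
#' @return A `hemo_trial` whose stacks share bin-left-edge times.
#' @export
resample_to_common_grid <- function(trial, step_min = 1) {
  t_lo <- max(vapply(trial$stacks, function(s) min(s$times), numeric(1)))
  t_hi <- min(vapply(trial$stacks, function(s) max(s$times), numeric(1)))
  edges <- seq(t_lo, t_hi, by = step_min)
  n_bins <- length(edges)
  if (n_bins < 1) abort("Requested step leaves no complete bin.")
  stacks <- lapply(trial$stacks, function(st) {
    d <- dim(st$frames)
    out <- array(NA_real_, dim = c(d[1], d[2], n_bins))
    for (k in seq_len(n_bins)) {
      sel <- which(st$times >= edges[k] & st$times < edges[k] + step_min)
      if (length(sel) == 0) {
        abort(sprintf("No %s frames in bin [%g, %g) min: acquisition gap.",
                      st$variable, edges[k], edges[k] + step_min))
      }
      out[, , k] <- if (length(sel) == 1) st$frames[, , sel] else
        rowMeans(st$frames[, , sel, drop = FALSE], dims = 2)
    }
    frame_stack(st$variable, out, edges, pixel_size = st$pixel_size)
  })
  trial(trial$trial_id, stacks, paradigm = trial$paradigm)
}
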