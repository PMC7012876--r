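pearson_safe <- function(x, Y) {
  # cor of vector x against columns of Y, NA where either side is constant
  sx <- sd(x)
  sy <- apply(Y, 2, sd)
  r <- rep(NA_real_, ncol(Y))
  ok <- is.finite(sx) & sx > 0 & is.finite(sy) & sy > 0
  if (is.finite(sx) && sx > 0 && any(ok)) {
    r[ok] <- suppressWarnings(as.numeric(cor(x, Y[, ok, drop = FALSE])))
  }
  r
}

# Row-wise Pearson correlation between paired rows of A and B (M x N each).
row_cor <- function(A, B) {
  A <- A - rowMeans(A)
  B <- B - rowMeans(B)
  num <- rowSums(A * B)
  den <- sqrt(rowSums(A^2) * rowSums(B^2))
  out <- num / den
  out[den == 0 | !is.finite(den)] <- NA_real_
  out
}

window_indices <- function(n, window = NULL) {
  if (is.null(window)) seq_len(n) else {
    w <- as.integer(window)
    if (min(w) < 1 || max(w) > n) abort("Window indices outside the series.")
    w
  }
}

#' Split a series into two equal analysis windows
#'
#' The default windowing of the cluster and coupling modules: the filtered run
#' is split at its midpoint into two equal halves (e.g. 0-30 min and
#' 30-60 min of a one-hour session).
#'
#' @param n Number of time points.
#' @return List of two index vectors.
#' @export
halfway_windows <- function(n) {
  m <- n %/% 2
  list(seq_len(m), seq.int(m + 1L, n))
}

#' Seed-based correlation map
#'
#' Pearson correlation between the time-series of one seed sub-region and
#' every other sub-region over a time window — the spatial map of vasomotion
#' synchrony around the seed.
#'
#' @param grid A [grid_series()] (typically of fractional blood-volume change).
#' @param seed `(row, col)` of the seed cell.
#' @param window Optional time-index window (default: all points).
#' @return A `correlation_map` with an R x C `r_values` matrix (`NA` for
#'   missing or constant cells), the seed and window.
#' @export
seed_correlation_map <- function(grid, seed, window = NULL) {
  d <- dim(grid$values)
  w <- window_indices(d[3], window)
  if (length(w) < 3) abort("Window must contain at least 3 time points.")
  seed <- as.integer(seed)
  if (grid$missing_mask[seed[1], seed[2]]) abort("Seed cell is missing.")
  s <- grid$values[seed[1], seed[2], w]
  if (!is.finite(sd(s)) || sd(s) == 0) {
    warn("Seed series is constant; correlation map is all-missing.")
    r <- matrix(NA_real_, d[1], d[2])
  } else {
    flat <- matrix(grid$values[, , w, drop = FALSE], nrow = d[1] * d[2])
    r <- matrix(pearson_safe(s, t(flat)), d[1], d[2])
    r[grid$missing_mask] <- NA_real_
  }
  structure(list(seed = seed, r_values = r, window = w),
            class = "correlation_map")
}

#' Master correlation matrix over all sub-regions
#'
#' Stacks the linearized seed-correlation maps of every non-missing
#' sub-region into one symmetric M x M matrix of pairwise Pearson
#' correlations, in row-major cell order.
#'
#' @inheritParams seed_correlation_map
#' @return A `master_corr` with `matrix` (M x M) and `cell_index` (tibble
#'   mapping matrix rows to grid cells).
#' @export
master_correlation_matrix <- function(grid, window = NULL) {
  d <- dim(grid$values)
  w <- window_indices(d[3], window)
  csm <- cell_series_matrix(grid)
  if (nrow(csm$cells) < 2) abort("Need at least 2 non-missing cells.")
  S <- csm$series[, w, drop = FALSE]
  m <- suppressWarnings(cor(t(S)))
  diag(m) <- 1
  structure(list(matrix = m, cell_index = csm$cells, window = w),
            class = "master_corr")
}

#' SVD-based initial clustering
#'
#' Singular value decomposition of the master correlation matrix seeds the
#' niche search: the rank `K` is the smallest that captures `energy_frac` of
#' the squared singular-value energy (capped at `max_rank`), each cell joins
#' the component with its largest absolute loading, and each component is
#' split by loading sign so anticorrelated (vasodilating vs vasoconstricting)
#' dynamics start in different groups.
#'
#' @param master A [master_correlation_matrix()] result.
#' @param energy_frac Cumulative squared-singular-value fraction (default 0.8).
#' @param max_rank Cap on the retained rank (default 10).
#' @return Integer vector of preliminary group labels, one per matrix row.
#' @export
svd_initial_clusters <- function(master, energy_frac = 0.8, max_rank = 10) {
  m <- master$matrix
  m[!is.finite(m)] <- 0
  sv <- svd(m)
  energy <- cumsum(sv$d^2) / sum(sv$d^2)
  K <- min(which(energy >= energy_frac), max_rank)
  U <- sv$u[, seq_len(K), drop = FALSE]
  k_star <- max.col(abs(U), ties.method = "first")
  signs <- sign(U[cbind(seq_len(nrow(U)), k_star)])
  labels <- 2L * (k_star - 1L) + ifelse(signs >= 0, 1L, 2L)
  match(labels, sort(unique(labels)))  # consecutive ids
}

centroid_series <- function(S, labels) {
  ids <- sort(unique(labels[!is.na(labels)]))
  cent <- t(vapply(ids, function(id) {
    colMeans(S[which(labels == id), , drop = FALSE])  # which(): NA-safe
  }, numeric(ncol(S))))
  list(ids = ids, series = cent)
}

#' Iterative correlation refinement of niche clusters
#'
#' Refines a preliminary labeling into the final vasomotion niches: each
#' round recomputes niche centroids as the member-mean series, reassigns
#' every cell to its best-correlating centroid when that correlation exceeds
#' `corr_threshold` (otherwise the cell becomes unassigned; ties go to the
#' lowest niche id), dissolves niches smaller than
#' `ceiling(min_cluster_frac * M)` members, and merges niche pairs whose
#' centroids correlate above the threshold. Iteration stops when the labeling
#' is stable or after `max_iter` rounds, followed by an enforcement sweep so
#' that the returned labeling satisfies both printed rules exactly:
#' member-to-centroid `r > corr_threshold` and niche size at least 5% of the
#' field of view (at defaults).
#'
#' @param labels Integer preliminary labels (one per non-missing cell), e.g.
#'   from [svd_initial_clusters()].
#' @param grid The [grid_series()] the labels refer to.
#' @param window Optional time-index window.
#' @param corr_threshold,min_cluster_frac,max_iter Refinement controls.
#' @return A `cluster_labeling`: R x C label matrix (`NA` = unassigned),
#'   centroid series, window, iteration count and convergence flag.
#' @export
refine_clusters <- function(labels, grid, window = NULL,
                            corr_threshold = 0.7, min_cluster_frac = 0.05,
                            max_iter = 100) {
  d <- dim(grid$values)
  w <- window_indices(d[3], window)
  csm <- cell_series_matrix(grid)
  S <- csm$series[, w, drop = FALSE]
  M <- nrow(S)
  if (length(labels) != M) abort("`labels` must have one entry per non-missing cell.")
  min_size <- ceiling(min_cluster_frac * M)
  labels <- as.integer(labels)

  assign_pass <- function(labels) {
    cs <- centroid_series(S, labels)
    if (length(cs$ids) == 0) return(labels)
    R <- vapply(seq_along(cs$ids), function(j) row_cor(S, matrix(cs$series[j, ],
                nrow = M, ncol = ncol(S), byrow = TRUE)), numeric(M))
    R <- matrix(R, nrow = M)
    R[!is.finite(R)] <- -Inf
    best_j <- max.col(R, ties.method = "first")  # lowest id wins ties
    best_r <- R[cbind(seq_len(M), best_j)]
    new <- ifelse(best_r > corr_threshold, cs$ids[best_j], NA_integer_)
    as.integer(new)
  }

  dissolve_pass <- function(labels) {
    tab <- table(labels)
    small <- as.integer(names(tab)[tab < min_size])
    labels[labels %in% small] <- NA_integer_
    labels
  }

  merge_pass <- function(labels) {
    repeat {
      cs <- centroid_series(S, labels)
      if (length(cs$ids) < 2) break
      CC <- suppressWarnings(cor(t(cs$series)))
      CC[!is.finite(CC)] <- -Inf
      diag(CC) <- -Inf
      if (max(CC) <= corr_threshold) break
      ij <- which(CC == max(CC), arr.ind = TRUE)[1, ]
      keep <- min(cs$ids[ij]); drop <- max(cs$ids[ij])
      labels[which(labels == drop)] <- keep
    }
    labels
  }

  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    prev <- labels
    labels <- assign_pass(labels)
    labels <- dissolve_pass(labels)
    labels <- merge_pass(labels)
    if (identical(labels, prev)) { converged <- TRUE; break }
  }

  # Enforcement sweep: with centroids recomputed from the final members,
  # every member must satisfy r > corr_threshold and every niche the size
  # floor; repeat until both invariants hold.
  for (sweep in seq_len(50)) {
    cs <- centroid_series(S, labels)
    if (length(cs$ids) == 0) break
    viol <- FALSE
    for (j in seq_along(cs$ids)) {
      mem <- which(labels == cs$ids[j])
      r <- row_cor(S[mem, , drop = FALSE],
                   matrix(cs$series[j, ], nrow = length(mem), ncol = ncol(S), byrow = TRUE))
      bad <- mem[!(r > corr_threshold) | !is.finite(r)]
      if (length(bad) > 0) { labels[bad] <- NA_integer_; viol <- TRUE }
    }
    new_labels <- dissolve_pass(labels)
    if (!identical(new_labels, labels)) viol <- TRUE
    labels <- new_labels
    if (!viol) break
  }

  if (all(is.na(labels))) {
    warn("No niche satisfies the correlation and size rules; labeling is empty.")
  }
  # canonical ids in row-major first-appearance order
  ids <- unique(labels[!is.na(labels)])
  labels <- match(labels, ids)
  label_grid <- matrix(NA_integer_, d[1], d[2])
  label_grid[cbind(csm$cells$cell_row, csm$cells$cell_col)] <- labels
  cs <- centroid_series(S, labels)
  centroids <- if (length(cs$ids) > 0) {
    purrr::map_dfr(seq_along(cs$ids), function(j) {
      tibble(niche = cs$ids[j], time_min = grid$times[w], value = cs$series[j, ])
    })
  } else tibble(niche = integer(), time_min = numeric(), value = numeric())
  structure(
    list(labels = label_grid, centroids = centroids, window = w,
         n_iter = iter, converged = converged,
         corr_threshold = corr_threshold, min_cluster_frac = min_cluster_frac,
         cell_index = csm$cells),
    class = "cluster_labeling"
  )
}

#' @export
print.cluster_labeling <- function(x, ...) {
  k <- length(unique(x$labels[!is.na(x$labels)]))
  cat(sprintf("<cluster_labeling> %d niche(s), %d/%d cells assigned, %d iteration(s)%s\n",
              k, sum(!is.na(x$labels)), nrow(x$cell_index), x$n_iter,
              if (x$converged) "" else " (max_iter reached)"))
  invisible(x)
}

#' @method tidy cluster_labeling
#' @export
tidy.cluster_labeling <- function(x, ...) {
  d <- dim(x$labels)
  tidyr::expand_grid(cell_row = seq_len(d[1]), cell_col = seq_len(d[2])) |>
    dplyr::mutate(niche = x$labels[cbind(.data$cell_row, .data$cell_col)],
                  assigned = !is.na(.data$niche))
}

#' @method glance cluster_labeling
#' @export
glance.cluster_labeling <- function(x, ...) {
  lab <- x$labels[!is.na(x$labels)]
  tibble(
    n_niches = length(unique(lab)),
    n_assigned = length(lab),
    n_unassigned = sum(is.na(x$labels)) - (length(x$labels) - nrow(x$cell_index)),
    n_iter = x$n_iter,
    converged = x$converged
  )
}

#' Niche clustering of vasomotion dynamics
#'
#' End-to-end cluster module: from a blood-volume grid series, computes the
#' fractional-change (vasodilation/vasoconstriction) series, then per time
#' window builds the master correlation matrix, seeds groups by SVD, and
#' refines them by iterative correlation analysis.
#'
#' @param bv_grid A filtered [grid_series()] of blood volume.
#' @param windows List of time-index windows on the fractional-change base;
#'   default: two equal halves of the run.
#' @param config A [run_config()].
#' @param energy_frac SVD energy fraction for the initial rank choice.
#' @return List of `cluster_labeling`, one per window.
#' @export
cluster_niches <- function(bv_grid, windows = NULL, config = run_config(),
                           energy_frac = 0.8) {
  dv <- fractional_change_grid(bv_grid)
  n <- dim(dv$values)[3]
  if (is.null(windows)) windows <- halfway_windows(n)
  purrr::map(windows, function(w) {
    master <- master_correlation_matrix(dv, window = w)
    init <- svd_initial_clusters(master, energy_frac = energy_frac)
    refine_clusters(init, dv, window = w,
                    corr_threshold = config$corr_threshold,
                    min_cluster_frac = config$min_cluster_frac)
  })
}
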