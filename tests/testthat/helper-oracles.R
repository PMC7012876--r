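# Brute-force oracles, kept deliberately independent of the package
# implementations they check.

pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

window_mean_oracle <- function(x, w) {
  # all valid sliding means of width w by direct summation
  vapply(seq_len(length(x) - w + 1), function(i) sum(x[i:(i + w - 1)]) / w,
         numeric(1))
}

block_mean_oracle <- function(frame, b) {
  R <- nrow(frame) %/% b
  C <- ncol(frame) %/% b
  out <- matrix(NA_real_, R, C)
  for (i in seq_len(R)) for (j in seq_len(C)) {
    tile <- frame[((i - 1) * b + 1):(i * b), ((j - 1) * b + 1):(j * b)]
    out[i, j] <- sum(tile) / length(tile)
  }
  out
}

dft_power_oracle <- function(x) {
  # one-sided power of the mean-normalized series via the O(N^2) DFT sum
  n <- length(x)
  y <- x / mean(x) - 1
  half <- n %/% 2
  p <- numeric(half + 1)
  for (k in seq_len(half)) {
    re <- sum(y * cos(-2 * pi * k * (0:(n - 1)) / n))
    im <- sum(y * sin(-2 * pi * k * (0:(n - 1)) / n))
    mag2 <- (re^2 + im^2) / n^2
    p[k + 1] <- if (n %% 2 == 0 && k == half) mag2 else 2 * mag2
  }
  p
}

# Direct grid-series builder from an R x C x N array of cell series.
make_grid <- function(values, times = NULL, variable = "BV", block_px = 50) {
  if (is.null(times)) times <- seq_len(dim(values)[3]) - 1
  grid_series(variable, values, times, block_px)
}

# Noiseless frame stack with a disc of `inside` value growing at
# `speed_px_per_min` around `origin`, `outside` elsewhere.
make_disc_stack <- function(H = 80, W = 80, origin = c(40, 40), r0 = 5,
                            speed_px_per_min = 2, n_min = 10,
                            inside = 20, outside = 50) {
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  d2 <- (rr - origin[1])^2 + (cc - origin[2])^2
  frames <- array(outside, c(H, W, n_min))
  for (k in seq_len(n_min)) {
    r <- r0 + speed_px_per_min * (k - 1)
    frames[, , k][d2 <= r^2] <- inside
  }
  frame_stack("HBSAT", frames, times = seq_len(n_min) - 1)
}
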