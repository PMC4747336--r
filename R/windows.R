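# Internal machinery for evaluating bivariate-Gaussian log-densities on the
# working grid.  Probability maps are ny x nx matrices (column-major linear
# cell index = (col-1)*ny + row).  For speed, density evaluation is
# restricted to a rectangular window of +/- nsd marginal standard deviations
# around the mean; the excluded mass at the defaults (nsd >= 4) is below
# 1e-4 and cancels between numerator and denominator of every cell-mass
# ratio computed from the same window.

# Window extent (cell index ranges) for a Gaussian on the grid.
.gauss_window <- function(mu, sigma, grid, nsd) {
  sdx <- sqrt(sigma[1, 1]); sdy <- sqrt(sigma[2, 2])
  W <- grid$extent_cm[1]; H <- grid$extent_cm[2]
  c1 <- floor((mu[1] - nsd * sdx + W / 2) / W * grid$nx) + 1L
  c2 <- floor((mu[1] + nsd * sdx + W / 2) / W * grid$nx) + 1L
  r1 <- floor((H / 2 - (mu[2] + nsd * sdy)) / H * grid$ny) + 1L
  r2 <- floor((H / 2 - (mu[2] - nsd * sdy)) / H * grid$ny) + 1L
  cols <- max(1L, c1):min(grid$nx, c2)
  rows <- max(1L, r1):min(grid$ny, r2)
  list(rows = rows, cols = cols)
}

# Unnormalized Gaussian log-density (constant terms dropped) at the centers
# of the window's cells.  Returns the window plus `logd` as an
# nrow(rows) x ncol(cols) matrix and `cells`, the matching linear indices.
.gauss_logd <- function(mu, sigma, grid, nsd = 4) {
  w <- .gauss_window(mu, sigma, grid, nsd)
  dx <- grid$xs_cm[w$cols] - mu[1]
  dy <- grid$ys_cm[w$rows] - mu[2]
  A <- solve(sigma)
  logd <- -0.5 * (outer(A[2, 2] * dy^2, A[1, 1] * dx^2, `+`) +
                    2 * A[1, 2] * outer(dy, dx))
  cells <- outer(w$rows, (w$cols - 1L) * grid$ny, `+`)
  list(rows = w$rows, cols = w$cols, logd = logd, cells = cells)
}

# Same quantity at an arbitrary set of cell centers given by (row, col).
.gauss_logd_at <- function(mu, sigma, rows, cols, grid) {
  dx <- grid$xs_cm[cols] - mu[1]
  dy <- grid$ys_cm[rows] - mu[2]
  A <- solve(sigma)
  -0.5 * (A[1, 1] * dx^2 + 2 * A[1, 2] * dx * dy + A[2, 2] * dy^2)
}

# Draw one cell index (row, col) from an unnormalized weight matrix over a
# window, then jitter uniformly within the cell, returning pixel coords.
.sample_click_px <- function(wts, rows, cols, grid) {
  k <- sample.int(length(wts), 1L, prob = as.vector(wts))
  i <- (k - 1L) %% length(rows) + 1L
  j <- (k - 1L) %/% length(rows) + 1L
  px_w <- grid$frame_px[1] / grid$nx
  px_h <- grid$frame_px[2] / grid$ny
  c((cols[j] - 1L + stats::runif(1)) * px_w,
    (rows[i] - 1L + stats::runif(1)) * px_h)
}
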