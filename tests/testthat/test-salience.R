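test_that("normalize_map rescales to unit mass and rejects bad maps", {
  expect_equal(normalize_map(matrix(c(1, 3), 1))$values, matrix(c(0.25, 0.75), 1))
  expect_equal(normalize_map(matrix(1, 2, 2))$values, matrix(0.25, 2, 2))
  expect_error(normalize_map(matrix(0, 2, 2)), "all-zero")
  expect_error(salience_map(matrix(c(-1, 2), 1)), "nonnegative")
})

test_that("normalization is idempotent and scale invariant", {
  set.seed(1)
  for (i in 1:5) {
    m <- matrix(stats::runif(30), 5, 6)
    n1 <- normalize_map(m)
    expect_equal(sum(n1$values), 1, tolerance = 1e-12)
    expect_equal(normalize_map(n1)$values, n1$values)
    expect_equal(normalize_map(m * stats::runif(1, 0.1, 50))$values, n1$values)
  }
})

test_that("average_map is the pixelwise mean", {
  m1 <- salience_map(matrix(c(2, 0), 1)); m2 <- salience_map(matrix(c(0, 2), 1))
  expect_equal(average_map(list(m1, m2))$values, matrix(c(1, 1), 1))
  expect_equal(average_map(list(m1, m1))$values, m1$values)
  expect_error(average_map(list(m1)), "at least 2")
  expect_error(average_map(list(m1, salience_map(matrix(1, 2, 2)))), "shape")
})

test_that("synthetic field cohort is center biased on average", {
  avg <- fx_priors()$average$values
  ny <- nrow(avg); nx <- ncol(avg)
  central <- avg[round(ny * 0.375):round(ny * 0.625),
                 round(nx * 0.375):round(nx * 0.625)]   # central 25% of area
  border <- mean(c(avg[1:10, ], avg[(ny - 9):ny, ]))
  expect_gt(mean(central), border)
  mx <- which(avg == max(avg), arr.ind = TRUE)
  expect_true(mx[1] > ny * 0.25 && mx[1] < ny * 0.75)
  expect_true(mx[2] > nx * 0.25 && mx[2] < nx * 0.75)
})

test_that("center correction divides by the average and has unit mean", {
  m <- salience_map(matrix(c(4, 2, 1, 1), 2))
  expect_equal(center_correct(m, m)$values, matrix(1, 2, 2))
  # mirror cohort
  eps <- 1e-6
  c1 <- matrix(c(2 + eps, eps), 1); c2 <- matrix(c(eps, 2 + eps), 1)
  avg <- average_map(list(salience_map(c1), salience_map(c2)))
  cc1 <- center_correct(salience_map(c1), avg)$values
  cc2 <- center_correct(salience_map(c2), avg)$values
  expect_equal(cc1, cc2[, 2:1, drop = FALSE])
  # cohort identity: mean of corrected maps is the unit map
  pri <- fx_priors()
  mean_corr <- Reduce(`+`, lapply(pri$corrected, function(m) m$values)) /
    length(pri$corrected)
  expect_lt(max(abs(mean_corr - 1)), 1e-9)
  # zero cells in the average require the explicit floor
  z <- salience_map(matrix(c(0, 1), 1))
  expect_error(center_correct(m1 <- salience_map(matrix(c(1, 1), 1)), z), "floor_zeros")
  expect_silent(center_correct(m1, z, floor_zeros = TRUE))
})

test_that("salience_at reads the clicked cell", {
  wg <- fx_grid()
  u <- normalize_map(matrix(1, wg$ny, wg$nx))
  expect_equal(salience_at(u, c(100, 100), wg), 1 / n_cells(wg))
  blob <- make_salience_field(wg, n_blobs = 1, center_bias_strength = 0, seed = 3)
  peak <- which(blob$values == max(blob$values), arr.ind = TRUE)
  px <- c((peak[2] - 0.5) * wg$frame_px[1] / wg$nx,
          (peak[1] - 0.5) * wg$frame_px[2] / wg$ny)
  expect_equal(salience_at(blob, px, wg), max(blob$values))
  expect_error(salience_at(u, c(-1, 0), wg), "outside")
  # argmax cell of a normalized map dominates every other cell
  nb <- normalize_map(blob)
  expect_true(salience_at(nb, px, wg) >= max(nb$values))
})

test_that("contrast salience responds to local structure only", {
  flat <- contrast_salience(matrix(5, 40, 40))
  expect_equal(max(flat$values), 0)
  expect_error(normalize_map(flat), "all-zero")
  img <- matrix(0, 41, 41); img[21, 21] <- 1
  cs <- contrast_salience(img)
  expect_equal(unname(which(cs$values == max(cs$values), arr.ind = TRUE)[1, ]),
               c(21, 21))
  # step edge: ridge along the edge, near-zero far away
  step <- cbind(matrix(0, 40, 20), matrix(1, 40, 20))
  cse <- contrast_salience(step)$values
  ridge <- mean(cse[, 20:21])
  far <- mean(cse[, c(1:8, 33:40)])
  expect_gt(ridge, 10 * max(far, 1e-12))
})
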