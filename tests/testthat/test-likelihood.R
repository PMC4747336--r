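test_that("fit_ellipse returns the divide-by-n maximum-likelihood fit", {
  e <- fit_ellipse(rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2)))
  expect_equal(e$mu, c(1, 1))
  expect_equal(e$sigma, diag(1, 2))
  expect_error(fit_ellipse(rbind(c(0, 0), c(1, 1))), "at least 3")
  # collinear points are regularized into a proper ellipse
  coll <- fit_ellipse(cbind(1:5, 2 * (1:5)))
  expect_gt(min(eigen(coll$sigma, only.values = TRUE)$values), 0)
})

test_that("ellipse estimates converge on simulated clicks", {
  set.seed(21)
  mu <- c(3, -2)
  sigma <- matrix(c(4, 1.2, 1.2, 2.5), 2)
  big <- MASS::mvrnorm(1e4, mu, sigma)
  e <- fit_ellipse(big)
  expect_lt(max(abs(e$mu - mu)), 0.1)
  expect_lt(max(abs(e$sigma - sigma) / max(diag(sigma))), 0.05)
  # error shrinks roughly as 1/sqrt(n)
  errs <- vapply(c(100, 10000), function(n)
    max(abs(fit_ellipse(MASS::mvrnorm(n, mu, sigma))$mu - mu)), numeric(1))
  expect_lt(errs[2], errs[1])
})

test_that("variance inflation scales the diagonal only and preserves PD", {
  s <- matrix(c(1, 0.5, 0.5, 2), 2)
  expect_equal(inflate_variance(s, 1), s)
  expect_equal(inflate_variance(s, 2), matrix(c(2, 0.5, 0.5, 4), 2))
  expect_error(inflate_variance(s, 0.9), ">= 1")
  set.seed(4)
  for (i in 1:10) {
    a <- matrix(stats::rnorm(4), 2); sp <- crossprod(a) + diag(1e-3, 2)
    k <- stats::runif(1, 1, 5)
    expect_gt(min(eigen(inflate_variance(sp, k), only.values = TRUE)$values), 0)
  }
})

test_that("rasterized likelihood maps are normalized with correct mass", {
  wg <- fx_grid()
  e <- ellipse_params(c(0, 0), diag(9, 2), 0L)
  lm_ <- rasterize_ellipse(e, wg)
  expect_equal(sum(lm_$values), 1, tolerance = 1e-9)
  ctr <- px_to_cell(cm_to_px(c(0, 0), wg), wg)
  # the frame center sits on a cell boundary, so the peak may tie across it
  expect_true(unname(ctr[1, "cell"]) %in% which(lm_$values == max(lm_$values)))
  # mass inside the 1-sd ellipse on a fine grid ~ 1 - exp(-1/2)
  fine_geom <- scene_geometry(frame_px = c(200, 200),
                              plane_extent_cm = c(20, 20))
  fg <- working_grid(fine_geom, downsample = 1)
  sigma <- matrix(c(4, 1, 1, 3), 2)
  lf <- rasterize_ellipse(ellipse_params(c(0, 0), sigma, 0L), fg)
  A <- solve(sigma)
  q <- outer(A[2, 2] * fg$ys_cm^2, A[1, 1] * fg$xs_cm^2, `+`) +
    2 * A[1, 2] * outer(fg$ys_cm, fg$xs_cm)
  expect_equal(sum(lf$values[q <= 1]), 1 - exp(-0.5), tolerance = 0.005)
})

test_that("kappa cross-validation behaves like its simulation oracles", {
  # within-family Gaussian noise, large n: no inflation needed
  g <- make_gray_table(function(n) matrix(stats::rnorm(2 * n, 0, 2.5), n, 2),
                       reps = 40, seed = 1, dirs = seq(0, 32, by = 4))
  cv_g <- crossvalidate_kappa(g, fx_grid())
  expect_lte(cv_g$kappa, 1.2)
  # heavy-tailed noise at the experimental 5 repeats: inflation helps
  t3 <- make_gray_table(function(n) matrix(stats::rt(2 * n, df = 3) * 2, n, 2),
                        reps = 5, seed = 2, dirs = seq(0, 32, by = 4))
  cv_t <- crossvalidate_kappa(t3, fx_grid())
  expect_gt(cv_t$kappa, 1)
  expect_gt(cv_t$kappa, cv_g$kappa)
})

test_that("cross-validation is invariant to block relabeling", {
  g <- make_gray_table(function(n) matrix(stats::rnorm(2 * n, 0, 2.5), n, 2),
                       reps = 5, seed = 6, dirs = seq(0, 32, by = 8))
  cv1 <- crossvalidate_kappa(g, fx_grid())
  g2 <- g
  g2$block <- c(`2` = 5, `3` = 4, `4` = 3, `5` = 2)[as.character(g$block)]
  cv2 <- crossvalidate_kappa(g2, fx_grid())
  expect_equal(cv1$kappa, cv2$kappa)
  expect_equal(cv1$mean_heldout, cv2$mean_heldout)
  t1 <- tapply(cv1$cv$loglik, cv1$cv$kappa, sum)
  t2 <- tapply(cv2$cv$loglik, cv2$cv$kappa, sum)
  expect_equal(t1, t2)
  # a fold missing a direction is an error
  expect_error(crossvalidate_kappa(g[!(g$block == 3 & g$direction == 8), ],
                                   fx_grid()), "missing directions")
})

test_that("chance-level rule includes real observers, excludes random ones", {
  # threshold arithmetic on a 100-cell grid
  g100 <- working_grid(scene_geometry(frame_px = c(10, 10),
                                      plane_extent_cm = c(10, 10)),
                       downsample = 1)
  expect_true(validate_subject(list(mean_heldout = log(0.02)), g100))
  expect_false(validate_subject(list(mean_heldout = log(0.005)), g100))
  # well-behaved simulated observer
  m <- fx_sim()$models[["S01"]]
  expect_true(m$included)
  expect_gte(m$kappa, 1)
  expect_equal(length(m$ellipses), 33)
  # uniform-random clicker at full scale
  half <- fx_grid()$extent_cm / 2
  u <- make_gray_table(function(n) cbind(stats::runif(n, -half[1], half[1]),
                                         stats::runif(n, -half[2], half[2])),
                       reps = 5, seed = 13, centered_on_targets = FALSE)
  cv_u <- crossvalidate_kappa(u, fx_grid())
  expect_false(validate_subject(cv_u, fx_grid()))
})
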