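test_that("posterior combination follows Bayes' rule on the grid", {
  L <- matrix(c(0.6, 0.4), 1)
  p <- matrix(c(0.25, 0.75), 1)
  expect_equal(posterior_map(L, p, delta = 1)$values,
               matrix(c(1 / 3, 2 / 3), 1), tolerance = 1e-12)
  expect_error(posterior_map(L, matrix(0.5, 2, 2), 1), "shape")
  expect_error(posterior_map(L, p, -0.5), ">= 0")
  expect_error(posterior_map(L, salience_map(p, state = "raw"), 1), "normalized")
})

test_that("uniform priors and delta = 0 reduce the posterior to the likelihood", {
  wg <- fx_grid()
  L <- rasterize_ellipse(ellipse_params(c(4, -6), diag(c(7, 12)), 2L), wg)
  u <- normalize_map(matrix(1, wg$ny, wg$nx))
  pr <- fx_priors()$normalized[[1]]
  for (d in c(0, 1, 2.7))
    expect_lt(max(abs(posterior_map(L, u, d)$values - L$values)), 1e-9)
  expect_lt(max(abs(posterior_map(L, pr, 0)$values - L$values)), 1e-9)
  # every map in play is normalized
  expect_equal(sum(L$values), 1, tolerance = 1e-9)
  expect_equal(sum(pr$values), 1, tolerance = 1e-9)
  expect_equal(sum(posterior_map(L, pr, 1.5)$values), 1, tolerance = 1e-9)
  expect_true(all(posterior_map(L, pr, 1.5)$values > 0))
})

test_that("increasing delta raises posterior mass at the prior's mode", {
  wg <- fx_grid()
  L <- rasterize_ellipse(ellipse_params(c(0, 0), diag(c(20, 20)), 0L), wg)
  pr <- fx_priors()$normalized[[3]]
  k <- which.max(pr$values)
  masses <- vapply(c(0, 0.5, 1, 2, 4), function(d)
    posterior_map(L, pr, d)$values[k], numeric(1))
  expect_true(all(diff(masses) > 0))
})

test_that("click log-likelihood reads floored cell mass", {
  wg <- fx_grid()
  u <- normalize_map(matrix(1, wg$ny, wg$nx))
  expect_equal(click_loglik(u, c(10, 10), wg), log(1 / n_cells(wg)))
  m <- matrix(c(0.1, 0.5, 0.4, 0), 2, 2)
  g4 <- working_grid(scene_geometry(frame_px = c(2, 2),
                                    plane_extent_cm = c(2, 2)), 1)
  expect_equal(click_loglik(m, c(0.5, 0.5), g4), log(0.1), tolerance = 1e-9)
  # zero-mass cell is floored, never -Inf
  expect_equal(click_loglik(m, c(1.5, 1.5), g4), log(1e-12))
  expect_error(click_loglik(u, c(551, 0), wg), "outside")
})

test_that("delta fitting recovers weights and flags flat objectives", {
  sim <- fx_sim()
  wg <- fx_grid()
  pri <- fx_priors()$normalized
  tr <- sim$judgments[sim$judgments$subject == "S01" &
                        sim$judgments$block == 1, ]
  m <- sim$models[["S01"]]
  d <- fit_delta(tr, m, pri, wg)
  expect_false(attr(d, "unidentifiable"))
  expect_gt(as.numeric(d), 0.5)
  expect_lt(as.numeric(d), 2.8)
  # uniform priors carry no information about delta
  upri <- lapply(pri, function(x) normalize_map(matrix(1, wg$ny, wg$nx)))
  du <- fit_delta(tr, m, upri, wg)
  expect_equal(as.numeric(du), 0)
  expect_true(attr(du, "unidentifiable"))
  # mismatched priors fit a much smaller weight than matched ones
  mm <- mismatch_priors(pri, seed = 2)
  dmm <- fit_delta(tr, m, mm, wg)
  expect_lt(as.numeric(dmm), as.numeric(d) - 0.5)
})

test_that("model comparison is additive, order invariant and null on uniforms", {
  sim <- fx_sim()
  wg <- fx_grid()
  pri <- fx_priors()$normalized
  tr <- sim$judgments[sim$judgments$subject == "S02" &
                        sim$judgments$block == 1, ]
  m <- sim$models[["S02"]]
  cmp <- compare_models(tr, m, pri, wg, delta = 1)
  expect_equal(cmp$llr,
               sum(cmp$per_trial$loglik_full - cmp$per_trial$loglik_reduced))
  expect_gt(cmp$llr, 0)                       # matched priors help
  shuffled <- tr[sample.int(nrow(tr)), ]
  expect_equal(compare_models(shuffled, m, pri, wg, delta = 1)$llr, cmp$llr)
  upri <- lapply(pri, function(x) normalize_map(matrix(1, wg$ny, wg$nx)))
  expect_equal(compare_models(tr, m, upri, wg, delta = 1)$llr, 0)
  cmp_fit <- compare_models(tr, m, pri, wg, delta = "fit")
  expect_gte(cmp_fit$llr, cmp$llr - 1e-6)     # fitted delta can only improve
})

test_that("prior mismatching is a seeded derangement", {
  two <- mismatch_priors(c(a = "a", b = "b"), seed = 1)
  expect_equal(two[["a"]], "b")
  expect_equal(two[["b"]], "a")
  for (n in c(3, 5, 165)) {
    ids <- sprintf("i%03d", seq_len(n))
    mm <- mismatch_priors(stats::setNames(as.list(ids), ids), seed = n)
    expect_true(all(unlist(mm) != ids))        # no image keeps its own map
    expect_setequal(unlist(mm), ids)
  }
  m1 <- mismatch_priors(sprintf("x%d", 1:20), seed = 9)
  m2 <- mismatch_priors(sprintf("x%d", 1:20), seed = 9)
  expect_identical(m1, m2)
  expect_error(mismatch_priors("only", seed = 1), "at least 2")
})

test_that("group delta test matches hand-computed statistics", {
  g <- group_delta_test(c(1, 2, 3))
  expect_equal(g$mean, 2)
  expect_equal(g$t, 2 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(g$df, 2)
  g0 <- group_delta_test(c(0, 0, 0))
  expect_equal(g0$mean, 0)
  expect_true(g0$degenerate)
  expect_equal(g$ecdf$F, c(1, 2, 3) / 3)
  expect_error(group_delta_test(1), "at least 2")
})
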