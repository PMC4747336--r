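test_that("cone projection matches a Monte-Carlo ray oracle", {
  geom <- fx_geometry()
  set.seed(99)
  for (tgt in list(c(0, 0), c(20, 0), c(15, -30))) {
    P <- mc_cone_points(tgt, geom$gazer_to_plane, 0.02, 1e5)
    e <- cone_ellipse(tgt, geom, 0.02)
    expect_lt(max(abs(colMeans(P) - e$mu)), 0.2)
    scale <- max(eigen(e$sigma, only.values = TRUE)$values)
    expect_lt(max(abs(stats::cov(P) - e$sigma)), 0.05 * scale)
  }
})

test_that("oblique cone ellipses elongate along the radial direction", {
  geom <- fx_geometry()
  for (tgt in list(c(20, 0), c(0, -30), c(15, 20), c(-20, 30))) {
    e <- cone_ellipse(tgt, geom, 0.03)
    ev <- eigen(e$sigma, symmetric = TRUE)
    expect_gte(ev$values[1], ev$values[2])
    ang <- acos(min(1, abs(sum(ev$vectors[, 1] * tgt / sqrt(sum(tgt^2))))))
    expect_lt(ang, 5 * pi / 180)
  }
  # straight-ahead target: isotropic, sd = distance * sigma
  e0 <- cone_ellipse(c(0, 0), geom, 0.02)
  expect_equal(sqrt(diag(e0$sigma)), rep(115 * 0.02, 2), tolerance = 1e-6)
  # narrow-cone limit collapses onto the target
  e_small <- cone_ellipse(c(10, 10), geom, 1e-4)
  expect_lt(max(e_small$sigma), 1e-3)
  expect_equal(e_small$mu, c(10, 10))
  expect_error(cone_ellipse(c(0, 0), geom, 0.5), "0.3")
  expect_error(cone_ellipse(c(0, 0), geom, 0), "0.3")
})

test_that("salience fields are deterministic, positive and well shaped", {
  wg <- fx_grid()
  f1 <- make_salience_field(wg, seed = 11)
  f2 <- make_salience_field(wg, seed = 11)
  expect_identical(f1$values, f2$values)
  expect_true(all(f1$values > 0))
  expect_equal(dim(f1$values), c(wg$ny, wg$nx))
  flat <- make_salience_field(wg, n_blobs = 0, center_bias_strength = 0, seed = 1)
  expect_equal(max(flat$values), min(flat$values))
  expect_error(make_salience_field(wg, n_blobs = -1), ">= 0")
})

test_that("simulated image-block experiment has the five-block structure", {
  sim <- fx_sim()
  jd <- sim$judgments
  one <- jd[jd$subject == "S01", ]
  expect_equal(nrow(one), 5 * 165)
  expect_equal(sort(unique(one$block)), 1:5)
  # every direction appears five times in every block
  counts <- table(one$block, one$direction)
  expect_true(all(counts == 5))
  expect_true(all(one$image_id[one$block > 1] == "gray"))
  expect_true(all(one$image_id[one$block == 1] != "gray"))
  # all clicks inside the frame
  wg <- fx_grid()
  expect_true(all(jd$click_x_px >= 0 & jd$click_x_px < wg$frame_px[1]))
  expect_true(all(jd$click_y_px >= 0 & jd$click_y_px < wg$frame_px[2]))
})

test_that("simulation is reproducible and subject streams are independent", {
  cohort <- make_cohort(2, seed = 3)
  jd1 <- simulate_exp1(cohort, fx_fields(), fx_geometry(), fx_grid())
  jd2 <- simulate_exp1(cohort, fx_fields(), fx_geometry(), fx_grid())
  expect_identical(jd1, jd2)
  # a single subject simulated alone matches its rows in the cohort run
  jd_solo <- simulate_exp1(cohort[2], fx_fields(), fx_geometry(), fx_grid())
  expect_equal(jd_solo, jd1[jd1$subject == "S02", ], ignore_attr = TRUE)
})

test_that("with no prior weight, image-block scatter matches gray scatter", {
  subs <- lapply(1:3, function(i)
    synthetic_subject(paste0("Z", i), delta_true = 0, rng_seed = 20 + i))
  jd <- simulate_exp1(subs, fx_fields(), fx_geometry(), fx_grid(),
                      block1_likelihood = "cone")
  tg <- fx_targets()
  cm <- px_to_cm(cbind(jd$click_x_px, jd$click_y_px), fx_grid())
  rad <- sqrt((cm[, 1] - tg$x_cm[jd$direction + 1])^2 +
                (cm[, 2] - tg$y_cm[jd$direction + 1])^2)
  ks <- suppressWarnings(stats::ks.test(rad[jd$block == 1], rad[jd$block > 1]))
  expect_gt(ks$p.value, 0.01)
})

test_that("a heavily weighted prior pulls clicks onto salient locations", {
  wg <- fx_grid()
  fields <- make_field_cohort(60, wg, seed = 5, n_blobs = 12, blob_amp = 12,
                              blob_scale_cm = 4, baseline = 0.3)
  sub <- list(synthetic_subject("S", angular_sigma = 0.035, delta_true = 10,
                                rng_seed = 11))
  jd <- simulate_exp1(sub, fields, fx_geometry(), wg)
  b1 <- jd[jd$block == 1, ]
  pri <- build_priors(fields)$normalized
  v <- vapply(seq_len(nrow(b1)), function(i)
    salience_at(pri[[b1$image_id[i]]], c(b1$click_x_px[i], b1$click_y_px[i]), wg),
    numeric(1))
  # mean prior value at clicks relative to the map mean (1 / n_cells)
  expect_gt(mean(v) * n_cells(wg), 3)
})

test_that("duration experiment crosses durations with directions per block", {
  subs <- make_cohort(2, seed = 5)
  jd <- simulate_exp2(subs, fx_fields(), fx_geometry(), fx_grid())
  one <- jd[jd$subject == "S01", ]
  expect_equal(nrow(one), 2 * 168)                 # 3 practice + 33 x 5 crossing
  main <- one[one$trial > 3, ]
  counts <- table(main$block, main$direction, main$duration_ms)
  expect_true(all(counts == 1))
  expect_true(all(jd$duration_ms %in% c(150, 300, 600, 1200, 2400)))
  # without practice rows: the bare 330-row crossing
  jd0 <- simulate_exp2(subs[1], fx_fields(), fx_geometry(), fx_grid(),
                       n_practice = 0)
  expect_equal(nrow(jd0), 330)
  expect_error(simulate_exp2(subs, fx_fields(), fx_geometry(), fx_grid(),
                             durations = c(150, 999)), "unknown duration")
})
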