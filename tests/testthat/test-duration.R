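test_that("salience lookups respect definitions and practice exclusion", {
  wg <- fx_grid()
  fields <- fx_fields()
  subs <- make_cohort(2, seed = 31)
  jd <- simulate_exp2(subs, fields, fx_geometry(), wg)
  expect_equal(sum(jd$subject == "S01" & jd$block == 1), 168)
  full <- salience_of_clicks(jd, fields, "full", wg)
  expect_equal(sum(full$subject == "S01" & full$block == 1), 165)
  expect_true(all(full$trial > 3))
  # ratio x average == full at every click cell
  avg <- average_map(fields)
  ratio <- salience_of_clicks(jd, fields, "ratio", wg, average = avg)
  avgv <- salience_of_clicks(jd, fields, "average", wg, average = avg)
  expect_equal(ratio$salience * avgv$salience, full$salience,
               tolerance = 1e-12)
  # constant maps give constant values; ratio of identical maps is 1
  const <- lapply(fields, function(m)
    salience_map(matrix(2, wg$ny, wg$nx), image_id = m$image_id))
  vc <- salience_of_clicks(jd, const, "full", wg)
  expect_true(all(vc$salience == 2))
  vr <- salience_of_clicks(jd, const, "ratio", wg)
  expect_true(all(abs(vr$salience - 1) < 1e-12))
  expect_error(salience_of_clicks(jd, fields[-1], "full", wg), "missing salience map")
})

test_that("subject slopes are ordinary least squares on log2 duration", {
  dur <- rep(c(150, 300, 600, 1200, 2400), each = 4)
  expect_equal(subject_slope(rep(3, 20), dur), 0)
  expect_equal(subject_slope(log2(dur), dur), 1, tolerance = 1e-12)
  set.seed(8)
  v <- 0.3 * log2(dur) + stats::rnorm(20, 0, 0.05)
  expect_equal(subject_slope(v, dur), 0.3, tolerance = 0.1)
  # multiplicative rescaling of durations leaves the log-slope unchanged
  expect_equal(subject_slope(v, dur * 1000), subject_slope(v, dur),
               tolerance = 1e-9)
  expect_error(subject_slope(c(1, 2), c(300, 300)), "distinct duration")
  g <- group_slope_test(c(0, 0, 0))
  expect_equal(g$mean, 0)
  expect_true(g$degenerate)
})

test_that("a flat generative schedule yields null duration slopes", {
  subs <- make_cohort(6, seed = 4, delta_true = 1.5)
  flat <- exp2_schedule(width_coef = 0, mix_slope = Inf)
  jd <- simulate_exp2(subs, fx_fields(), fx_geometry(), fx_grid(),
                      schedule = flat)
  an <- duration_analysis(jd, fx_fields(), fx_grid(),
                          definitions = c("full", "average", "ratio"))
  expect_true(all(an$group$p > 0.001))
  expect_true(all(abs(an$group$mean_slope[an$group$definition != "ratio"]) < 0.2))
})

test_that("duration analysis reports per-duration means with SEM", {
  subs <- make_cohort(3, seed = 12)
  jd <- simulate_exp2(subs, fx_fields(), fx_geometry(), fx_grid())
  an <- duration_analysis(jd, fx_fields(), fx_grid(),
                          definitions = c("full", "ratio"))
  expect_equal(nrow(an$group), 2)
  expect_equal(nrow(an$by_duration), 2 * 5)
  expect_true(all(an$by_duration$sem > 0))
  expect_equal(nrow(an$slopes), 2 * 3)
  expect_equal(an$group$df, rep(2, 2))
})
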