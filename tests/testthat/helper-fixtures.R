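# Shared fixtures, built lazily once per test run.

.fx <- new.env(parent = emptyenv())

fx_geometry <- function() {
  if (is.null(.fx$geometry)) .fx$geometry <- scene_geometry()
  .fx$geometry
}

fx_grid <- function() {
  if (is.null(.fx$grid)) .fx$grid <- working_grid(fx_geometry())
  .fx$grid
}

fx_targets <- function() {
  if (is.null(.fx$targets)) .fx$targets <- make_target_grid(fx_geometry())
  .fx$targets
}

# Small cohort of salience fields shared across tests.
fx_fields <- function() {
  if (is.null(.fx$fields))
    .fx$fields <- make_field_cohort(40, fx_grid(), seed = 42)
  .fx$fields
}

fx_priors <- function() {
  if (is.null(.fx$priors)) .fx$priors <- build_priors(fx_fields())
  .fx$priors
}

# Two synthetic observers simulated end to end (model-true block 1), with
# their fitted likelihood models attached; the workhorse fixture for the
# posterior and pipeline tests.
fx_sim <- function() {
  if (is.null(.fx$sim)) {
    cohort <- make_cohort(2, seed = 7, delta_true = 1.5)
    jd <- simulate_exp1(cohort, fx_fields(), fx_geometry(), fx_grid(),
                        block1_likelihood = "measured")
    .fx$sim <- list(cohort = cohort, judgments = jd,
                    models = attr(jd, "models"))
  }
  .fx$sim
}

# Gray-block judgment table with clicks drawn around each target by a
# user-supplied noise generator (n x 2 matrix of cm offsets).
make_gray_table <- function(noise, reps, seed, dirs = 0:32,
                            centered_on_targets = TRUE) {
  grid <- fx_grid()
  tg <- fx_targets()
  set.seed(seed)
  half <- grid$extent_cm / 2
  rows <- list()
  for (b in 2:5) for (d in dirs) {
    mu <- if (centered_on_targets) c(tg$x_cm[d + 1], tg$y_cm[d + 1]) else c(0, 0)
    pts <- noise(reps) + matrix(mu, reps, 2, byrow = TRUE)
    pts[, 1] <- pmin(pmax(pts[, 1], -half[1] + 1e-6), half[1] - 1e-6)
    pts[, 2] <- pmin(pmax(pts[, 2], -half[2] + 1e-6), half[2] - 1e-6)
    px <- cm_to_px(pts, grid)
    rows[[length(rows) + 1]] <- data.frame(
      subject = "S", block = b, trial = seq_len(reps), direction = d,
      image_id = "gray", click_x_px = px[, 1], click_y_px = px[, 2],
      duration_ms = NA_real_)
  }
  do.call(rbind, rows)
}

# Monte-Carlo cone-of-gaze oracle: sample ray directions from an isotropic
# angular Gaussian around the eye-to-target axis and intersect with the
# plane.  Independent of the analytic projection it checks.
mc_cone_points <- function(target, L, sigma, n) {
  d <- c(target, L); d <- d / sqrt(sum(d^2))
  e1 <- c(-d[2], d[1], 0)
  if (sum(e1^2) < 1e-12) e1 <- c(1, 0, 0)
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  a <- stats::rnorm(n, 0, sigma); b <- stats::rnorm(n, 0, sigma)
  U <- matrix(d, n, 3, byrow = TRUE) + a %*% t(e1) + b %*% t(e2)
  s <- L / U[, 3]
  cbind(U[, 1] * s, U[, 2] * s)
}
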