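#' Elliptical gaze likelihood from a cone of gaze
#'
#' Models the gazer's directional signal as an isotropic Gaussian cone of
#' half-width `angular_sigma` emanating from the eyes, and projects it onto
#' the gazed-upon plane to first order.  The intersection of a cone with a
#' plane is an ellipse, so the projected distribution is a bivariate
#' Gaussian centered on the target and elongated radially for oblique
#' targets: with eye-to-plane distance `L`, eye-to-target distance `r` and
#' incidence cosine `L / r`, the tangential standard deviation is
#' `sigma * r` and the radial one `sigma * r^2 / L`.
#'
#' @param target Length-2 plane location of the fixated point, cm.
#' @param geometry A [scene_geometry()].
#' @param angular_sigma Cone half-width, radians; must lie in (0, 0.3).
#' @return An [ellipse_params()] centered on the target.
#' @examples
#' e <- cone_ellipse(c(0, 0), scene_geometry(), 0.02)
#' sqrt(diag(e$sigma))   # ~2.30 cm each axis
#' @export
cone_ellipse <- function(target, geometry, angular_sigma) {
  stop_if_not(inherits(geometry, "scene_geometry"), "geometry must be a scene_geometry")
  stop_if_not(is.numeric(angular_sigma) && length(angular_sigma) == 1 &&
                angular_sigma > 0 && angular_sigma < 0.3,
              "angular_sigma must lie in (0, 0.3) radians")
  target <- as.numeric(target)
  half <- geometry$plane_extent_cm / 2
  stop_if_not(abs(target[1]) <= half[1] && abs(target[2]) <= half[2],
              "target outside the plane extent")
  L <- geometry$gazer_to_plane
  r2 <- L^2 + sum(target^2)
  ecc <- sqrt(sum(target^2))
  rho <- if (ecc > 0) target / ecc else c(1, 0)   # radial direction (any, if central)
  tau <- c(-rho[2], rho[1])
  v_rad <- angular_sigma^2 * (r2 / L)^2
  v_tan <- angular_sigma^2 * r2
  sigma <- v_rad * tcrossprod(rho) + v_tan * tcrossprod(tau)
  ellipse_params(target, sigma)
}

#' Synthetic observer parameters
#'
#' A generative stand-in for a human subject: gaze-cone noise, isotropic
#' motor/click noise, and the weight `delta_true` applied to the salience
#' prior when the observer samples a click from the posterior.
#'
#' @param subject_id Token identifying the subject.
#' @param angular_sigma Gaze-cone half-width, radians (> 0).
#' @param motor_sigma Isotropic click noise, cm (>= 0).
#' @param delta_true Generative prior weight (>= 0).
#' @param rng_seed Integer seed for the subject's private RNG stream.
#' @return A `synthetic_subject` object.
#' @export
synthetic_subject <- function(subject_id, angular_sigma = 0.02,
                              motor_sigma = 1.5, delta_true = 1.5,
                              rng_seed = 1L) {
  stop_if_not(angular_sigma > 0, "angular_sigma must be > 0")
  stop_if_not(motor_sigma >= 0, "motor_sigma must be >= 0")
  stop_if_not(delta_true >= 0, "delta_true must be >= 0")
  structure(list(subject_id = as.character(subject_id),
                 angular_sigma = angular_sigma,
                 motor_sigma = motor_sigma,
                 delta_true = delta_true,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_subject")
}

#' Build a cohort of synthetic observers
#'
#' Subject-level heterogeneity follows a lognormal spread on the cone
#' width; all subjects share `delta_true`, which is the quantity the
#' recovery analyses estimate at the cohort level.  Each subject gets a
#' private RNG seed derived from the master seed, so simulation is
#' reproducible and order-independent.
#'
#' @param n_subjects Number of observers.
#' @param seed Master seed.
#' @param angular_sigma Median cone half-width, radians.
#' @param angular_sigma_cv Lognormal coefficient of variation across
#'   subjects (0 = identical subjects).
#' @param motor_sigma Click noise, cm.
#' @param delta_true Generative prior weight shared by the cohort.
#' @return A list of [synthetic_subject()]s.
#' @export
make_cohort <- function(n_subjects = 22, seed = 1, angular_sigma = 0.02,
                        angular_sigma_cv = 0.2, motor_sigma = 1.5,
                        delta_true = 1.5) {
  stop_if_not(n_subjects >= 1, "n_subjects must be >= 1")
  set.seed(derive_seed(seed, 0L))
  sdlog <- sqrt(log(1 + angular_sigma_cv^2))
  lapply(seq_len(n_subjects), function(i) {
    synthetic_subject(sprintf("S%02d", i),
                      angular_sigma = angular_sigma *
                        exp(stats::rnorm(1, -sdlog^2 / 2, sdlog)),
                      motor_sigma = motor_sigma,
                      delta_true = delta_true,
                      rng_seed = derive_seed(seed, i))
  })
}

#' Generate a synthetic salience field
#'
#' Produces a strictly positive 2-D field statistically similar to a
#' natural-image salience map: a constant baseline plus Gaussian blobs at
#' random (mildly center-concentrated) locations, all multiplied by a
#' smooth center-bias envelope.  Blob structure plays the role of
#' image-specific salient features; the multiplicative envelope plays the
#' role of the global center bias that [center_correct()] later removes.
#'
#' @param grid The [working_grid()] on which to generate the field.
#' @param n_blobs Number of Gaussian blobs (>= 0).
#' @param blob_scale_cm Blob standard deviation, cm (> 0).
#' @param blob_amp Mean blob peak amplitude relative to the baseline;
#'   individual amplitudes are jittered uniformly by +/- 50%.
#' @param center_bias_strength Peak of the multiplicative center envelope
#'   relative to the field edge (0 = no center bias).
#' @param center_sigma_frac Envelope standard deviation as a fraction of
#'   the frame extent.
#' @param baseline Constant floor, > 0 so fields are strictly positive.
#' @param seed Integer seed; fields are bit-identical on re-run.
#' @param image_id Token for the resulting map.
#' @return A raw [salience_map()].
#' @export
make_salience_field <- function(grid, n_blobs = 8, blob_scale_cm = 5,
                                blob_amp = 3, center_bias_strength = 2.5,
                                center_sigma_frac = 0.3, baseline = 1,
                                seed = 1, image_id = NULL) {
  stop_if_not(inherits(grid, "working_grid"), "grid must be a working_grid")
  stop_if_not(n_blobs >= 0, "n_blobs must be >= 0")
  stop_if_not(blob_scale_cm > 0, "blob_scale_cm must be > 0")
  stop_if_not(baseline > 0, "baseline must be > 0")
  stop_if_not(center_bias_strength >= 0, "center_bias_strength must be >= 0")
  set.seed(seed)
  W <- grid$extent_cm[1]; H <- grid$extent_cm[2]
  field <- matrix(baseline, grid$ny, grid$nx)
  if (n_blobs > 0) {
    # blob centers mildly concentrated toward the frame center, as features
    # of photographed scenes tend to be
    bx <- pmin(pmax(stats::rnorm(n_blobs, 0, 0.35 * W / 2), -W / 2), W / 2)
    by <- pmin(pmax(stats::rnorm(n_blobs, 0, 0.35 * H / 2), -H / 2), H / 2)
    amp <- baseline * blob_amp * stats::runif(n_blobs, 0.5, 1.5)
    for (k in seq_len(n_blobs)) {
      gx <- exp(-(grid$xs_cm - bx[k])^2 / (2 * blob_scale_cm^2))
      gy <- exp(-(grid$ys_cm - by[k])^2 / (2 * blob_scale_cm^2))
      field <- field + amp[k] * outer(gy, gx)
    }
  }
  if (center_bias_strength > 0) {
    sx <- center_sigma_frac * W
    sy <- center_sigma_frac * H
    cx <- exp(-grid$xs_cm^2 / (2 * sx^2))
    cy <- exp(-grid$ys_cm^2 / (2 * sy^2))
    field <- field * (1 + center_bias_strength * outer(cy, cx))
  }
  salience_map(field, state = "raw", image_id = image_id)
}

#' Generate a cohort of salience fields
#'
#' One field per image of the simulated stimulus set, ids `img001...`,
#' with per-field seeds derived from the master seed.
#'
#' @param n_images Number of fields (the experiment used 165 images).
#' @param grid The [working_grid()].
#' @param seed Master seed.
#' @param ... Passed to [make_salience_field()].
#' @return A named list of raw [salience_map()]s.
#' @export
make_field_cohort <- function(n_images = 165, grid, seed = 1, ...) {
  ids <- sprintf("img%03d", seq_len(n_images))
  fields <- lapply(seq_len(n_images), function(i)
    make_salience_field(grid, seed = derive_seed(seed, 100000L + i),
                        image_id = ids[i], ...))
  stats::setNames(fields, ids)
}

# Truncated bivariate-Gaussian click, resampled until inside the frame,
# returned in pixel coordinates.
.sample_gray_click <- function(mu, sigma, grid) {
  half <- grid$extent_cm / 2
  repeat {
    p <- MASS::mvrnorm(1, mu, sigma)
    if (abs(p[1]) < half[1] && abs(p[2]) < half[2]) {
      px <- cm_to_px(p, grid)[1, ]
      # guard against landing exactly on the right/bottom edge
      if (px[1] < grid$frame_px[1] && px[2] < grid$frame_px[2]) return(px)
    }
  }
}

# Click sampled from the delta-weighted discrete posterior
# likelihood x prior^delta over a window of the working grid.
.sample_posterior_click <- function(ellipse, prior_values, delta, grid, nsd = 5) {
  g <- .gauss_logd(ellipse$mu, ellipse$sigma, grid, nsd)
  logp <- log(pmax(prior_values[g$cells], .EPS))
  logw <- g$logd + delta * logp
  .sample_click_px(exp(logw - max(logw)), g$rows, g$cols, grid)
}

# True (generative) ellipse for one subject and direction: cone projection
# plus isotropic motor noise.
.true_ellipse <- function(subject, target, geometry, direction = NA_integer_) {
  e <- cone_ellipse(target, geometry, subject$angular_sigma)
  ellipse_params(e$mu, e$sigma + diag(subject$motor_sigma^2, 2), direction)
}

#' Simulate the block-structured gaze-judgment experiment
#'
#' Generates a judgment table with the structure of the five-block design:
#' blocks 2-5 present a uniform gray surface (`image_id = "gray"`) and
#' clicks are drawn from each subject's true elliptical likelihood (cone
#' projection plus motor noise, truncated to the frame); block 1 pairs each
#' trial with a salience field and draws clicks from the discrete posterior
#' `likelihood x prior^delta_true`, where the prior is the
#' center-corrected, normalized field, i.e. the same construction the
#' analysis pipeline applies.
#'
#' @param subjects A list of [synthetic_subject()]s (see [make_cohort()]).
#' @param fields Named list of raw salience fields (one per image); block 1
#'   assigns each field to one trial at random.
#' @param geometry A [scene_geometry()].
#' @param grid The [working_grid()].
#' @param reps_per_block Repeats of each direction per block (5 gives the
#'   165-trial blocks of the original design).
#' @param n_blocks Total number of blocks (block 1 = image block).
#' @param block1_likelihood Which eye-cue likelihood governs the block-1
#'   posterior the observer samples from: `"cone"` (default) uses the
#'   subject's true generative ellipse (cone projection plus motor noise),
#'   so block-1 scatter matches the gray blocks exactly when
#'   `delta_true = 0`; `"measured"` first fits the subject's likelihood
#'   model from the just-simulated gray blocks (with cross-validated
#'   variance inflation, exactly as the analysis pipeline will) and samples
#'   block-1 clicks from that measured likelihood.  The `"measured"` mode
#'   is the model-true setting used for parameter recovery: the fitted
#'   prior weight is then an unbiased estimate of `delta_true`, whereas
#'   under `"cone"` the variance-inflated measurement attenuates it by
#'   roughly `1 / kappa`.
#' @param kappa_grid Variance-inflation candidates for
#'   `block1_likelihood = "measured"`.
#' @return A judgment data frame with columns `subject`, `block`, `trial`,
#'   `direction`, `image_id`, `click_x_px`, `click_y_px`, `duration_ms`
#'   (all `NA` here).  In `"measured"` mode the per-subject fitted models
#'   are attached as attribute `"models"` so downstream fitting can reuse
#'   them.
#' @export
simulate_exp1 <- function(subjects, fields, geometry, grid,
                          reps_per_block = 5, n_blocks = 5,
                          block1_likelihood = c("cone", "measured"),
                          kappa_grid = seq(1, 3, by = 0.1)) {
  block1_likelihood <- match.arg(block1_likelihood)
  stop_if_not(length(fields) >= 1, "need a non-empty field set for block 1")
  stop_if_not(n_blocks >= 2, "need at least one gray block besides block 1")
  targets <- make_target_grid(geometry)
  priors <- build_priors(fields)
  out <- vector("list", length(subjects))
  models <- list()
  for (si in seq_along(subjects)) {
    sub <- subjects[[si]]
    set.seed(sub$rng_seed)
    true_ells <- lapply(seq_len(nrow(targets)), function(i)
      .true_ellipse(sub, c(targets$x_cm[i], targets$y_cm[i]), geometry,
                    targets$direction[i]))
    n_trials <- 33L * reps_per_block
    rows <- vector("list", n_blocks)
    for (b in 2:n_blocks) {                       # gray blocks first
      dirs <- sample(rep(0:32, reps_per_block))
      clicks <- t(vapply(seq_len(n_trials), function(tr) {
        e <- true_ells[[dirs[tr] + 1L]]
        .sample_gray_click(e$mu, e$sigma, grid)
      }, numeric(2)))
      rows[[b]] <- data.frame(subject = sub$subject_id, block = b,
                              trial = seq_len(n_trials), direction = dirs,
                              image_id = "gray",
                              click_x_px = clicks[, 1], click_y_px = clicks[, 2],
                              duration_ms = NA_real_)
    }
    b1_ells <- true_ells
    if (block1_likelihood == "measured") {
      gray <- do.call(rbind, rows[2:n_blocks])
      mod <- fit_subject_model(gray, grid, kappa_grid)
      models[[sub$subject_id]] <- mod
      b1_ells <- lapply(0:32, function(d) .model_ellipse(mod, d))
    }
    dirs <- sample(rep(0:32, reps_per_block))
    imgs <- sample(names(fields), n_trials, replace = n_trials > length(fields))
    clicks <- t(vapply(seq_len(n_trials), function(tr)
      .sample_posterior_click(b1_ells[[dirs[tr] + 1L]],
                              priors$normalized[[imgs[tr]]]$values,
                              sub$delta_true, grid),
      numeric(2)))
    rows[[1]] <- data.frame(subject = sub$subject_id, block = 1L,
                            trial = seq_len(n_trials), direction = dirs,
                            image_id = imgs,
                            click_x_px = clicks[, 1], click_y_px = clicks[, 2],
                            duration_ms = NA_real_)
    out[[si]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (length(models)) attr(out, "models") <- models
  out
}

#' Generative schedule for the viewing-duration experiment
#'
#' Defines how viewing duration shapes the synthetic observer's judgment:
#' the likelihood standard deviation is multiplied by
#' `1 + width_coef / sqrt(duration_ms)` (brief glimpses give wide,
#' uncertain eye-cue readings), and the prior is a mixture
#' `(1 - lambda) * center + lambda * local` with
#' `lambda = plogis((log2(d) - log2(mix_mid_ms)) / mix_slope)`, so the
#' center-bias field dominates early and image-specific (center-corrected)
#' salience takes over at long durations.
#'
#' @param width_coef Likelihood-widening coefficient (ms^0.5).
#' @param mix_mid_ms Duration at which the prior mixture is 50/50.
#' @param mix_slope Logistic slope of the mixture in log2-duration units.
#' @param delta Generative prior weight for the duration experiment.
#' @return An `exp2_schedule` list.
#' @export
exp2_schedule <- function(width_coef = 30, mix_mid_ms = 600, mix_slope = 1,
                          delta = 1.5) {
  stop_if_not(width_coef >= 0, "width_coef must be >= 0")
  stop_if_not(mix_mid_ms > 0 && mix_slope > 0, "mixture schedule must be positive")
  stop_if_not(delta >= 0, "delta must be >= 0")
  structure(list(width_coef = width_coef, mix_mid_ms = mix_mid_ms,
                 mix_slope = mix_slope, delta = delta),
            class = "exp2_schedule")
}

.EXP2_DURATIONS <- c(150, 300, 600, 1200, 2400)

#' Simulate the viewing-duration experiment
#'
#' Two blocks per subject, each a complete crossing of the candidate
#' viewing durations with the 33 gaze directions (shuffled), preceded by
#' `n_practice` practice rows that the analysis later discards.  Every
#' trial projects one image; clicks are drawn from the duration-dependent
#' posterior defined by an [exp2_schedule()].
#'
#' @param subjects List of [synthetic_subject()]s.
#' @param fields Named list of raw salience fields.
#' @param geometry A [scene_geometry()].
#' @param grid The [working_grid()].
#' @param durations Subset of the supported durations
#'   {150, 300, 600, 1200, 2400} ms.
#' @param schedule An [exp2_schedule()].
#' @param n_blocks Number of blocks (default 2).
#' @param n_practice Practice rows at the start of each block (default 3).
#' @return A judgment data frame (same columns as [simulate_exp1()]) with
#'   `duration_ms` filled in; each block has
#'   `n_practice + length(durations) * 33` rows.
#' @export
simulate_exp2 <- function(subjects, fields, geometry, grid,
                          durations = .EXP2_DURATIONS,
                          schedule = exp2_schedule(),
                          n_blocks = 2, n_practice = 3) {
  stop_if_not(all(durations %in% .EXP2_DURATIONS),
              "unknown duration value; allowed: 150, 300, 600, 1200, 2400 ms")
  stop_if_not(length(fields) >= 1, "need a non-empty field set")
  stop_if_not(inherits(schedule, "exp2_schedule"), "schedule must be an exp2_schedule")
  targets <- make_target_grid(geometry)
  priors <- build_priors(fields)
  center_vals <- normalize_map(priors$average)$values
  out <- vector("list", length(subjects))
  for (si in seq_along(subjects)) {
    sub <- subjects[[si]]
    set.seed(derive_seed(sub$rng_seed, 2L))
    true_ells <- lapply(seq_len(nrow(targets)), function(i)
      .true_ellipse(sub, c(targets$x_cm[i], targets$y_cm[i]), geometry, targets$direction[i]))
    rows <- vector("list", n_blocks)
    for (b in seq_len(n_blocks)) {
      crossing <- expand.grid(direction = 0:32, duration_ms = durations)
      crossing <- crossing[sample.int(nrow(crossing)), ]
      if (n_practice > 0) {
        practice <- data.frame(direction = sample(0:32, n_practice, replace = TRUE),
                               duration_ms = sample(durations, n_practice,
                                                    replace = TRUE))
        crossing <- rbind(practice, crossing)
      }
      n_tr <- nrow(crossing)
      imgs <- sample(names(fields), n_tr, replace = n_tr > length(fields))
      clicks <- matrix(0, n_tr, 2)
      for (tr in seq_len(n_tr)) {
        d <- crossing$duration_ms[tr]
        e <- true_ells[[crossing$direction[tr] + 1L]]
        m <- 1 + schedule$width_coef / sqrt(d)
        e_d <- ellipse_params(e$mu, m^2 * e$sigma, e$direction)
        lambda <- stats::plogis((log2(d) - log2(schedule$mix_mid_ms)) /
                                  schedule$mix_slope)
        prior_vals <- (1 - lambda) * center_vals +
          lambda * priors$normalized[[imgs[tr]]]$values
        clicks[tr, ] <- .sample_posterior_click(e_d, prior_vals,
                                                schedule$delta, grid, nsd = 4)
      }
      rows[[b]] <- data.frame(subject = sub$subject_id, block = b,
                              trial = seq_len(n_tr),
                              direction = crossing$direction,
                              image_id = imgs,
                              click_x_px = clicks[, 1], click_y_px = clicks[, 2],
                              duration_ms = crossing$duration_ms)
    }
    out[[si]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Build salience priors from raw fields
#'
#' Applies the center-bias pipeline: average the raw maps, divide each map
#' by the average, and normalize the corrected maps for use as priors.
#'
#' @param fields Named list of raw [salience_map()]s.
#' @return List with `average` (raw), `corrected` (center-corrected, same
#'   names) and `normalized` (priors summing to 1, same names).
#' @export
build_priors <- function(fields) {
  stop_if_not(length(fields) >= 2, "need at least two fields to build priors")
  avg <- average_map(fields)
  corrected <- lapply(fields, center_correct, average = avg)
  list(average = avg,
       corrected = corrected,
       normalized = lapply(corrected, normalize_map))
}
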