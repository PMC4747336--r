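#' Default run configuration
#'
#' One nested list holding every tunable of the simulation and analysis
#' pipeline: geometry, working-grid resolution, cohort and field
#' parameters, the kappa and delta search settings, and the
#' viewing-duration schedule.  All values can be overridden via `...`
#' (top-level names) and the whole object round-trips through
#' [write_config()]/[read_config()].
#'
#' @param ... Named top-level overrides, e.g. `n_subjects = 5`.
#' @return A configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_subjects = 22L,
    n_images = 165L,
    reps_per_block = 5L,
    n_blocks = 5L,
    geometry = list(gazer_to_plane = 115, camera_to_plane = 160,
                    eye_height = 125, frame_px = c(550L, 733L),
                    plane_extent_cm = c(50, 50 * 733 / 550)),
    grid_downsample = 5L,
    subject = list(angular_sigma = 0.02, angular_sigma_cv = 0.2,
                   motor_sigma = 1.5, delta_true = 1.5),
    field = list(n_blobs = 8L, blob_scale_cm = 5, blob_amp = 3,
                 center_bias_strength = 2.5, center_sigma_frac = 0.3,
                 baseline = 1),
    block1_likelihood = "measured",
    kappa_grid = seq(1, 3, by = 0.1),
    delta = list(mode = "fixed", fixed = 1, min = -2, max = 5,
                 coarse_step = 0.25, tol = 1e-4),
    exp2 = list(n_subjects = 41L, n_blocks = 2L, n_practice = 3L,
                durations = c(150, 300, 600, 1200, 2400),
                width_coef = 30, mix_mid_ms = 600, mix_slope = 1,
                delta = 1.5)
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  cfg
}

.cfg_geometry <- function(config) {
  g <- config$geometry
  scene_geometry(g$gazer_to_plane, g$camera_to_plane, g$eye_height,
                 g$frame_px, g$plane_extent_cm)
}

.cfg_fields <- function(config, grid, seed) {
  f <- config$field
  make_field_cohort(config$n_images, grid, seed = seed,
                    n_blobs = f$n_blobs, blob_scale_cm = f$blob_scale_cm,
                    blob_amp = f$blob_amp,
                    center_bias_strength = f$center_bias_strength,
                    center_sigma_frac = f$center_sigma_frac,
                    baseline = f$baseline)
}

.stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[gazeprior] %s", sprintf(fmt, ...)))
}

# Fit all subjects' likelihood models from the gray blocks of a judgment
# table; returns a named list of subject_model objects.  Simulated tables
# from simulate_exp1(block1_likelihood = "measured") carry the identical
# models (fit from the same gray rows by the same code) as an attribute,
# which is reused rather than recomputed.
.fit_cohort_models <- function(judgments, grid, kappa_grid) {
  pre <- attr(judgments, "models")
  gray <- judgments[judgments$image_id == "gray", ]
  subs <- unique(gray$subject)
  if (!is.null(pre) && all(subs %in% names(pre))) return(pre[subs])
  lapply(split(gray, gray$subject), fit_subject_model,
         grid = grid, kappa_grid = kappa_grid)
}

# Fit delta and run the delta = 1 comparison for every included subject.
.score_cohort <- function(judgments, models, priors, grid, delta_cfg) {
  block1 <- judgments[judgments$block == 1, ]
  out <- lapply(names(models), function(s) {
    m <- models[[s]]
    if (!m$included)
      return(data.frame(subject = s, included = FALSE, kappa = m$kappa,
                        delta = NA_real_, llr = NA_real_,
                        loglik_full = NA_real_, loglik_reduced = NA_real_))
    tr <- block1[block1$subject == s, ]
    terms <- .trial_terms(tr, m, priors, grid)
    dstar <- .fit_delta_terms(terms, delta_cfg$min, delta_cfg$max,
                              delta_cfg$coarse_step, delta_cfg$tol)
    dcmp <- if (identical(delta_cfg$mode, "fit")) as.numeric(dstar)
            else delta_cfg$fixed
    ll_full <- .delta_objective(terms, dcmp)
    ll_red <- .delta_objective(terms, 0)
    data.frame(subject = s, included = TRUE, kappa = m$kappa,
               delta = as.numeric(dstar), llr = ll_full - ll_red,
               loglik_full = ll_full, loglik_reduced = ll_red)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Run the full image-block experiment pipeline
#'
#' End-to-end simulation and analysis: generate salience fields and a
#' synthetic cohort, simulate the five-block judgment experiment, fit each
#' subject's elliptical likelihoods with cross-validated variance
#' inflation, build center-corrected normalized priors, fit the per-subject
#' prior weight `delta`, run the full-vs-reduced model comparison with both
#' matched and deranged (mismatched) priors, and test the cohort's deltas
#' against zero.
#'
#' @param config A configuration list from [default_config()].
#' @param judgments Optional pre-existing judgment table (e.g. loaded with
#'   [read_judgments()]); simulated from `config` when `NULL`.
#' @param fields Optional named list of raw salience maps; generated from
#'   `config` when `NULL`.
#' @param out_dir Optional directory; when given, the report (JSON), the
#'   resolved config and the judgment CSV are written there.
#' @param verbose Log stage progress via [message()].
#' @return An `exp1_report` list: `subjects` (per-subject kappa, delta,
#'   LLR, inclusion for matched priors), `subjects_mismatched`, group tests
#'   for both, cohort LLRs, and the inputs' provenance (seed, config).
#' @export
run_exp1_pipeline <- function(config = default_config(), judgments = NULL,
                              fields = NULL, out_dir = NULL, verbose = TRUE) {
  t0 <- Sys.time()
  geometry <- .cfg_geometry(config)
  grid <- working_grid(geometry, config$grid_downsample)
  if (is.null(fields)) {
    .stage(verbose, "generating %d salience fields", config$n_images)
    fields <- .cfg_fields(config, grid, config$seed)
  }
  if (is.null(judgments)) {
    .stage(verbose, "simulating %d subjects x %d blocks", config$n_subjects,
           config$n_blocks)
    cohort <- make_cohort(config$n_subjects, seed = config$seed,
                          angular_sigma = config$subject$angular_sigma,
                          angular_sigma_cv = config$subject$angular_sigma_cv,
                          motor_sigma = config$subject$motor_sigma,
                          delta_true = config$subject$delta_true)
    judgments <- simulate_exp1(cohort, fields, geometry, grid,
                               reps_per_block = config$reps_per_block,
                               n_blocks = config$n_blocks,
                               block1_likelihood = config$block1_likelihood,
                               kappa_grid = config$kappa_grid)
  }
  .stage(verbose, "building center-corrected priors")
  priors <- build_priors(fields)
  .stage(verbose, "fitting likelihood models (kappa CV)")
  models <- .fit_cohort_models(judgments, grid, config$kappa_grid)
  .stage(verbose, "fitting delta and comparing models (matched priors)")
  matched <- .score_cohort(judgments, models, priors$normalized, grid,
                           config$delta)
  .stage(verbose, "fitting delta and comparing models (mismatched priors)")
  mm <- mismatch_priors(priors$normalized, seed = derive_seed(config$seed, 999L))
  mismatched <- .score_cohort(judgments, models, mm, grid, config$delta)
  ok <- matched$included
  report <- list(
    seed = config$seed,
    n_subjects = nrow(matched),
    n_excluded = sum(!ok),
    excluded_subjects = matched$subject[!ok],
    subjects = matched,
    subjects_mismatched = mismatched,
    llr_matched = sum(matched$llr[ok]),
    llr_mismatched = sum(mismatched$llr[ok]),
    group_matched = group_delta_test(matched$delta[ok]),
    group_mismatched = group_delta_test(mismatched$delta[ok]),
    mismatch_mapping = attr(mm, "mapping"),
    config = config,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  class(report) <- "exp1_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      report[c("seed", "n_subjects", "n_excluded", "subjects",
               "subjects_mismatched", "llr_matched", "llr_mismatched")],
      file.path(out_dir, "exp1_report.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
    write_config(config, file.path(out_dir, "config.json"))
    write_judgments(judgments, file.path(out_dir, "judgments.csv"))
  }
  report
}

#' @export
print.exp1_report <- function(x, ...) {
  cat(sprintf("Image-block pipeline report (seed %d)\n", x$seed))
  cat(sprintf("  subjects: %d (%d excluded at chance)\n", x$n_subjects, x$n_excluded))
  cat(sprintf("  cohort LLR, matched priors   : %+.1f nats\n", x$llr_matched))
  cat(sprintf("  cohort LLR, mismatched priors: %+.1f nats\n", x$llr_mismatched))
  cat(sprintf("  mean delta, matched   : %.3f (t(%d) = %.2f)\n",
              x$group_matched$mean, x$group_matched$df, x$group_matched$t))
  cat(sprintf("  mean delta, mismatched: %.3f\n", x$group_mismatched$mean))
  invisible(x)
}

#' Run the viewing-duration experiment pipeline
#'
#' Simulates the duration experiment (or analyzes a supplied judgment
#' table) and computes the per-subject duration-slope analysis under all
#' salience definitions.
#'
#' @inheritParams run_exp1_pipeline
#' @param definitions Salience definitions passed to [duration_analysis()].
#' @return An `exp2_report` list: the `slope_table` (`analysis`), the
#'   judgment table dimensions, seed and config.
#' @export
run_exp2_pipeline <- function(config = default_config(), judgments = NULL,
                              fields = NULL, out_dir = NULL,
                              definitions = c("full", "average", "ratio", "lowlevel"),
                              verbose = TRUE) {
  t0 <- Sys.time()
  geometry <- .cfg_geometry(config)
  grid <- working_grid(geometry, config$grid_downsample)
  e2 <- config$exp2
  if (is.null(fields)) {
    .stage(verbose, "generating %d salience fields", config$n_images)
    fields <- .cfg_fields(config, grid, config$seed)
  }
  if (is.null(judgments)) {
    .stage(verbose, "simulating %d duration-experiment subjects", e2$n_subjects)
    cohort <- make_cohort(e2$n_subjects, seed = derive_seed(config$seed, 555L),
                          angular_sigma = config$subject$angular_sigma,
                          angular_sigma_cv = config$subject$angular_sigma_cv,
                          motor_sigma = config$subject$motor_sigma,
                          delta_true = e2$delta)
    judgments <- simulate_exp2(cohort, fields, geometry, grid,
                               durations = e2$durations,
                               schedule = exp2_schedule(e2$width_coef,
                                                        e2$mix_mid_ms,
                                                        e2$mix_slope, e2$delta),
                               n_blocks = e2$n_blocks,
                               n_practice = e2$n_practice)
  }
  .stage(verbose, "running duration analysis (%s)",
         paste(definitions, collapse = ", "))
  analysis <- duration_analysis(judgments, fields, grid,
                                definitions = definitions,
                                n_practice = e2$n_practice)
  report <- list(seed = config$seed, analysis = analysis,
                 n_rows = nrow(judgments),
                 n_subjects = length(unique(judgments$subject)),
                 config = config,
                 elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  class(report) <- "exp2_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(list(seed = config$seed, group = analysis$group,
                              by_duration = analysis$by_duration,
                              slopes = analysis$slopes),
                         file.path(out_dir, "exp2_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    write_config(config, file.path(out_dir, "config.json"))
    write_judgments(judgments, file.path(out_dir, "judgments.csv"))
  }
  report
}

#' @export
print.exp2_report <- function(x, ...) {
  cat(sprintf("Duration pipeline report (seed %d, %d subjects, %d rows)\n",
              x$seed, x$n_subjects, x$n_rows))
  print(x$analysis)
  invisible(x)
}

#' Multi-seed prior-weight recovery study
#'
#' The package's headline reproduction harness.  For each master seed it
#' simulates a fresh cohort (default 22 subjects x 165 image-block trials
#' whose clicks are drawn with generative prior weight
#' `config$subject$delta_true`), runs the full fitting pipeline, and
#' records the cohort mean fitted `delta` and the cumulative
#' log-likelihood ratio under matched priors and under a seeded
#' derangement of the image-to-map assignment.
#'
#' @param n_seeds Number of independent master seeds.
#' @param config Configuration (see [default_config()]).
#' @param base_seed First master seed; seed `base_seed + i - 1` drives
#'   run `i`.
#' @param verbose Log per-seed progress.
#' @return A `recovery_study` list: `per_seed` (data frame with one row
#'   per seed: mean deltas, LLRs, exclusions), `mean_delta_matched`,
#'   `mean_delta_mismatched`, `sign_matched` / `sign_mismatched` (number
#'   of seeds with LLR > 0 and LLR <= 0 respectively).
#' @export
exp1_recovery_study <- function(n_seeds = 20, config = default_config(),
                                base_seed = config$seed, verbose = TRUE) {
  rows <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + i - 1)
    t0 <- Sys.time()
    rep_i <- run_exp1_pipeline(cfg, verbose = FALSE)
    rows[[i]] <- data.frame(
      seed = cfg$seed,
      mean_delta_matched = rep_i$group_matched$mean,
      mean_delta_mismatched = rep_i$group_mismatched$mean,
      llr_matched = rep_i$llr_matched,
      llr_mismatched = rep_i$llr_mismatched,
      n_excluded = rep_i$n_excluded)
    .stage(verbose, "seed %d/%d: delta %.3f (mm %.3f), LLR %+.1f (mm %+.1f) [%.1fs]",
           i, n_seeds, rows[[i]]$mean_delta_matched,
           rows[[i]]$mean_delta_mismatched, rows[[i]]$llr_matched,
           rows[[i]]$llr_mismatched,
           as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  per_seed <- do.call(rbind, c(rows, make.row.names = FALSE))
  structure(list(
    per_seed = per_seed,
    mean_delta_matched = mean(per_seed$mean_delta_matched),
    mean_delta_mismatched = mean(per_seed$mean_delta_mismatched),
    sign_matched = sum(per_seed$llr_matched > 0),
    sign_mismatched = sum(per_seed$llr_mismatched <= 0),
    n_seeds = n_seeds,
    config = config), class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, ...) {
  cat(sprintf("Prior-weight recovery study over %d seeds\n", x$n_seeds))
  cat(sprintf("  mean fitted delta, matched priors   : %.3f (generative %.2f)\n",
              x$mean_delta_matched, x$config$subject$delta_true))
  cat(sprintf("  mean fitted delta, mismatched priors: %.3f\n",
              x$mean_delta_mismatched))
  cat(sprintf("  seeds with matched LLR > 0    : %d/%d\n", x$sign_matched, x$n_seeds))
  cat(sprintf("  seeds with mismatched LLR <= 0: %d/%d\n", x$sign_mismatched, x$n_seeds))
  invisible(x)
}
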