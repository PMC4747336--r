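#' Combine a likelihood with a weighted salience prior
#'
#' Bayes' rule on the working grid: the posterior over gaze targets is the
#' cellwise product of the eye-cue likelihood and the salience prior raised
#' to the weight `delta`, renormalized to sum to 1.  `delta = 0` (or a
#' uniform prior) reduces the model to the eyes-only likelihood.
#'
#' @param likelihood A `likelihood_map` from [rasterize_ellipse()] (or a
#'   bare nonnegative matrix).
#' @param prior A normalized [salience_map()] (or bare matrix) of the same
#'   shape.  The prior is epsilon-floored before exponentiation so large
#'   `delta` cannot create zeros.
#' @param delta Prior weight, >= 0.
#' @param grid Optional [working_grid()] used only to validate shapes.
#' @return A `posterior_map`: list with strictly positive `values` summing
#'   to 1.
#' @examples
#' L <- matrix(c(0.6, 0.4), 1); p <- matrix(c(0.25, 0.75), 1)
#' posterior_map(L, p, delta = 1)$values   # 1/3, 2/3
#' @export
posterior_map <- function(likelihood, prior, delta, grid = NULL) {
  stop_if_not(is.numeric(delta) && length(delta) == 1 && delta >= 0,
              "delta must be a single number >= 0")
  L <- .map_values(likelihood)
  p <- .map_values(prior)
  stop_if_not(identical(dim(L), dim(p)),
              "likelihood and prior must share a shape")
  if (!is.null(grid))
    stop_if_not(nrow(L) == grid$ny && ncol(L) == grid$nx,
                "maps do not match the working grid")
  if (inherits(prior, "salience_map"))
    stop_if_not(prior$state == "normalized",
                "prior must be a normalized salience map")
  v <- L * pmax(p, .EPS)^delta
  stop_if_not(sum(v) > 0, "posterior has no mass; check the likelihood")
  v <- pmax(v, 1e-16 * max(v))        # strictly positive after epsilon floor
  structure(list(values = v / sum(v)), class = "posterior_map")
}

#' Log-likelihood of a click under a probability map
#'
#' The natural log of the probability mass of the working-grid cell
#' containing the click.  Cells with (floored) zero mass return
#' `log(1e-12)` rather than `-Inf`.
#'
#' @param map A normalized probability map (`posterior_map`,
#'   `likelihood_map`, normalized [salience_map()] or bare matrix).
#' @param click Frame-pixel coordinates of the click (inside the frame).
#' @param grid The [working_grid()].
#' @return Log probability mass, nats.
#' @export
click_loglik <- function(map, click, grid) {
  v <- .map_values(map)
  stop_if_not(nrow(v) == grid$ny && ncol(v) == grid$nx,
              "map shape does not match the working grid")
  log(max(v[px_to_cell(click, grid)[1, "cell"]], .EPS))
}

# ---- fast per-trial scoring ------------------------------------------------
# For repeated evaluation of click log-likelihoods as a function of delta we
# cache, per trial, the unnormalized Gaussian log-density and log-prior over
# a window of the grid plus the click cell's position in that window.  All
# cell-mass ratios are computed within the window, so the (negligible)
# truncated tail cancels.

.trial_terms <- function(trials, model, priors, grid, nsd = 4) {
  lapply(seq_len(nrow(trials)), function(i) {
    e <- .model_ellipse(model, trials$direction[i])
    pr <- priors[[trials$image_id[i]]]
    stop_if_not(!is.null(pr),
                sprintf("no prior for image '%s'", trials$image_id[i]))
    g <- .gauss_logd(e$mu, e$sigma, grid, nsd)
    cell <- px_to_cell(c(trials$click_x_px[i], trials$click_y_px[i]), grid)[1, "cell"]
    k <- match(cell, g$cells)
    logL <- as.vector(g$logd)
    logp <- log(pmax(.map_values(pr)[g$cells], .EPS))
    # stored max-shifted; shifts cancel in every cell-mass ratio
    list(a = logL - max(logL), b = logp - max(logp), k = k)
  })
}

# Summed click log-likelihood at each delta.  For an equally spaced,
# sorted delta grid the per-trial partition function is computed by
# stepwise rescaling (two exp() passes per trial instead of one per
# delta), which is what makes the profile cheap.
.delta_profile <- function(terms, deltas) {
  nd <- length(deltas)
  steps <- diff(deltas)
  stepwise <- nd > 1 && max(abs(steps - steps[1])) < 1e-12
  total <- numeric(nd)
  for (tt in terms) {
    if (is.na(tt$k)) { total <- total + log(.EPS); next }
    lz <- numeric(nd)
    if (stepwise) {
      w <- exp(tt$a + deltas[1] * tt$b)
      g <- exp(steps[1] * tt$b)
      lz[1] <- log(sum(w))
      for (j in 2:nd) {
        w <- w * g
        lz[j] <- log(sum(w))
      }
    } else {
      for (j in seq_len(nd)) lz[j] <- log(sum(exp(tt$a + deltas[j] * tt$b)))
    }
    total <- total + tt$a[tt$k] + deltas * tt$b[tt$k] - lz
  }
  total
}

.delta_objective <- function(terms, delta) .delta_profile(terms, delta)

#' Fit the prior weight delta for one subject
#'
#' Maximizes the summed log-likelihood of a subject's image-block clicks
#' over the prior weight `delta` in `[delta_min, delta_max]`.  The search
#' interval extends below zero so that subjects for whom the prior is
#' useless (or misleading, as under mismatched priors) can be fit without
#' a floor that would bias the group mean upward.  The objective is
#' concave in `delta` (it is `delta * log p(click cell) - log Z(delta)`
#' summed over trials, and `log Z` is convex), so a coarse bracketing grid
#' followed by golden-section refinement ([stats::optimize]) finds the
#' global optimum; ties resolve toward smaller `delta`.  If the objective
#' is flat (e.g., uniform priors), 0 is returned with attribute
#' `unidentifiable = TRUE`.
#'
#' @param trials Image-block judgment rows for one subject (columns
#'   `direction`, `image_id`, `click_x_px`, `click_y_px`).
#' @param model A fitted `subject_model` (see [fit_subject_model()]).
#' @param priors Named list of normalized prior maps keyed by `image_id`.
#' @param grid The [working_grid()].
#' @param delta_min,delta_max Ends of the search interval.
#' @param coarse_step Bracketing grid step.
#' @param tol Refinement tolerance on delta.
#' @return The fitted `delta` (numeric scalar) with attributes `loglik`
#'   (objective at the optimum), `profile` (coarse-grid data frame) and
#'   `unidentifiable`.
#' @export
fit_delta <- function(trials, model, priors, grid, delta_min = -2,
                      delta_max = 5, coarse_step = 0.25, tol = 1e-3) {
  stop_if_not(nrow(trials) >= 1, "no trials to fit delta on")
  terms <- .trial_terms(trials, model, priors, grid)
  .fit_delta_terms(terms, delta_min, delta_max, coarse_step, tol)
}

.fit_delta_terms <- function(terms, delta_min = -2, delta_max = 5,
                             coarse_step = 0.25, tol = 1e-3) {
  deltas <- seq(delta_min, delta_max, by = coarse_step)
  prof <- .delta_profile(terms, deltas)
  if (diff(range(prof)) < 1e-9) {
    out <- 0
    attr(out, "loglik") <- prof[1]
    attr(out, "profile") <- data.frame(delta = deltas, loglik = prof)
    attr(out, "unidentifiable") <- TRUE
    return(out)
  }
  i <- which.max(prof)                     # first max: smaller delta on ties
  lo <- deltas[max(1L, i - 1L)]
  hi <- deltas[min(length(deltas), i + 1L)]
  opt <- stats::optimize(function(d) .delta_objective(terms, d),
                         interval = c(lo, hi), maximum = TRUE, tol = tol)
  best <- if (opt$objective >= prof[i]) opt$maximum else deltas[i]
  # snap results numerically indistinguishable from zero
  if (abs(best) < tol) best <- 0
  out <- best
  attr(out, "loglik") <- max(opt$objective, prof[i])
  attr(out, "profile") <- data.frame(delta = deltas, loglik = prof)
  attr(out, "unidentifiable") <- FALSE
  out
}

#' Compare the full (salience-prior) and reduced (eyes-only) models
#'
#' Scores each image-block click under the full model (likelihood times
#' prior to the power `delta`) and the reduced model (likelihood alone),
#' and accumulates the log-likelihood ratio across trials.  Positive
#' cumulative LLR favors the full model.  The primary comparison uses the
#' unweighted prior (`delta = 1`), which involves no free parameters fit to
#' the image-block data; pass `delta = "fit"` to use the subject's
#' best-fitting weight instead.
#'
#' @param trials Image-block judgment rows for one subject.
#' @param model A fitted `subject_model`.
#' @param priors Named list of normalized prior maps keyed by `image_id`.
#' @param grid The [working_grid()].
#' @param delta Either a fixed numeric weight (default 1) or `"fit"`.
#' @return A `comparison_result`: list with `per_trial` (data frame of
#'   per-trial log-likelihoods in nats), `llr` (cumulative), `delta`,
#'   `loglik_full`, `loglik_reduced`.
#' @export
compare_models <- function(trials, model, priors, grid, delta = 1) {
  stop_if_not(nrow(trials) >= 1, "no trials to compare on")
  terms <- .trial_terms(trials, model, priors, grid)
  if (identical(delta, "fit")) delta <- as.numeric(.fit_delta_terms(terms))
  stop_if_not(is.numeric(delta) && length(delta) == 1 && is.finite(delta),
              "delta must be a finite number or \"fit\"")
  ll_full <- vapply(terms, function(tt) {
    if (is.na(tt$k)) return(log(.EPS))
    w <- tt$a + delta * tt$b
    w[tt$k] - logsumexp(w)
  }, numeric(1))
  ll_red <- vapply(terms, function(tt) {
    if (is.na(tt$k)) return(log(.EPS))
    tt$a[tt$k] - logsumexp(tt$a)
  }, numeric(1))
  structure(list(
    per_trial = data.frame(trial = trials$trial, direction = trials$direction,
                           image_id = trials$image_id,
                           loglik_full = ll_full, loglik_reduced = ll_red),
    llr = sum(ll_full) - sum(ll_red),
    delta = delta,
    loglik_full = sum(ll_full),
    loglik_reduced = sum(ll_red)), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Model comparison over %d trials (delta = %.3g):\n",
              nrow(x$per_trial), x$delta))
  cat(sprintf("  full %.2f vs reduced %.2f nats; cumulative LLR = %+.2f (%s)\n",
              x$loglik_full, x$loglik_reduced, x$llr,
              if (x$llr > 0) "favors full model" else "favors eyes-only model"))
  invisible(x)
}

#' Derange the image-to-salience-map assignment
#'
#' The mismatched-prior control: every image is paired with the salience
#' map of a *different* image (a derangement, no fixed points), so the
#' prior retains the statistics of real maps but carries no image-specific
#' information.
#'
#' @param priors Named list of prior maps (>= 2 entries); alternatively a
#'   character vector of image ids.
#' @param seed Integer seed; the permutation is reproducible.
#' @return The same structure with entries deranged.  The mapping is
#'   attached as attribute `mapping` (data frame `image_id`, `donor`).
#' @export
mismatch_priors <- function(priors, seed = 1) {
  ids <- if (is.character(priors)) priors else names(priors)
  n <- length(ids)
  stop_if_not(n >= 2, "need at least 2 images to mismatch")
  set.seed(seed)
  repeat {
    perm <- sample.int(n)
    if (all(perm != seq_len(n))) break
  }
  mapping <- data.frame(image_id = ids, donor = ids[perm])
  out <- if (is.character(priors)) stats::setNames(ids[perm], ids)
         else stats::setNames(priors[perm], ids)
  attr(out, "mapping") <- mapping
  out
}

#' Group-level test of the prior weights
#'
#' Two-sided one-sample t test of the per-subject `delta` estimates
#' against zero, with the empirical CDF for reporting.  A cohort of
#' identical deltas is flagged `degenerate` (undefined variance).
#'
#' @param deltas Numeric vector of per-subject prior weights (n >= 2).
#' @return A `group_test` list: `mean`, `t`, `df`, `p`, `degenerate`,
#'   `ecdf` (data frame `delta`, `F`).
#' @examples
#' group_delta_test(c(1, 2, 3))   # t = 3.46 on 2 df
#' @export
group_delta_test <- function(deltas) {
  deltas <- as.numeric(deltas)
  res <- one_sample_t(deltas)
  s <- sort(deltas)
  res$ecdf <- data.frame(delta = s, F = seq_along(s) / length(s))
  class(res) <- "group_test"
  res
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("Group test: mean = %.3f, t(%d) = %s, p = %s\n",
              x$mean, x$df,
              if (is.na(x$t)) "NA (zero variance)" else sprintf("%.2f", x$t),
              if (is.na(x$p)) "NA" else format.pval(x$p, digits = 3)))
  invisible(x)
}
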