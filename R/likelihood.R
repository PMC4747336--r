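#' Bivariate-Gaussian ellipse parameters
#'
#' The eye-cue likelihood for one gaze direction is an ellipse: a bivariate
#' Gaussian over plane locations (cm) describing where an observer judges
#' the gaze target given that directional cue.
#'
#' @param mu Length-2 mean (cm).
#' @param sigma 2x2 symmetric positive-definite covariance (cm^2).
#' @param direction Optional direction index (0-32).
#' @return An `ellipse_params` object.
#' @export
ellipse_params <- function(mu, sigma, direction = NA_integer_) {
  mu <- unname(as.numeric(mu))
  stop_if_not(length(mu) == 2 && all(is.finite(mu)), "mu must be a finite 2-vector")
  stop_if_not(is.matrix(sigma) && all(dim(sigma) == 2), "sigma must be 2x2")
  dimnames(sigma) <- NULL
  stop_if_not(max(abs(sigma - t(sigma))) < 1e-8, "sigma must be symmetric")
  stop_if_not(min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) > 0,
              "sigma must be positive definite")
  structure(list(mu = mu, sigma = (sigma + t(sigma)) / 2,
                 direction = as.integer(direction)),
            class = "ellipse_params")
}

#' @export
print.ellipse_params <- function(x, ...) {
  ev <- eigen(x$sigma, symmetric = TRUE, only.values = TRUE)$values
  cat(sprintf("Gaze ellipse%s: mu = (%.2f, %.2f) cm, axis sd = %.2f / %.2f cm\n",
              if (is.na(x$direction)) "" else sprintf(" [direction %d]", x$direction),
              x$mu[1], x$mu[2], sqrt(ev[1]), sqrt(ev[2])))
  invisible(x)
}

#' Fit a Gaussian ellipse to gaze-judgment points
#'
#' Maximum-likelihood fit of a bivariate Gaussian to a set of click
#' locations on the plane: `mu` is the sample mean and `sigma` the
#' divide-by-n covariance.  Degenerate (collinear) point sets are
#' regularized with a small ridge (`1e-6 * I`) so the result is always
#' positive definite.
#'
#' @param points Matrix (n x 2) of plane coordinates, cm; n >= 3.
#' @param direction Optional direction index to record.
#' @return An [ellipse_params()].
#' @examples
#' fit_ellipse(rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2)))
#' @export
fit_ellipse <- function(points, direction = NA_integer_) {
  points <- as.matrix(points)
  stop_if_not(ncol(points) == 2, "points must have two columns")
  stop_if_not(nrow(points) >= 3, "need at least 3 points to fit an ellipse")
  mu <- colMeans(points)
  d <- sweep(points, 2, mu)
  sigma <- crossprod(d) / nrow(points)
  if (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) < 1e-8)
    sigma <- sigma + diag(1e-6, 2)
  ellipse_params(mu, sigma, direction)
}

#' Inflate the variances of an ellipse
#'
#' Multiplies the main diagonal of a covariance matrix by `kappa >= 1`,
#' leaving the off-diagonal untouched.  This widens the fitted ellipses to
#' prevent overfitting to the training blocks; `kappa` is tuned by
#' [crossvalidate_kappa()].  The result is always positive definite, since
#' it adds the positive semi-definite matrix `(kappa - 1) * diag(sigma)`.
#'
#' @param sigma 2x2 positive-definite covariance.
#' @param kappa Variance multiplier, `>= 1`.
#' @return The inflated covariance matrix.
#' @export
inflate_variance <- function(sigma, kappa) {
  stop_if_not(is.numeric(kappa) && length(kappa) == 1 && kappa >= 1,
              "kappa must be a single number >= 1")
  out <- sigma
  diag(out) <- diag(out) * kappa
  out
}

#' Rasterize an ellipse into a discrete likelihood map
#'
#' Evaluates the Gaussian density at every cell center of the working grid
#' and renormalizes so the map sums to 1.  This discrete map is the form in
#' which the likelihood enters the Bayesian model.
#'
#' @param ellipse An [ellipse_params()].
#' @param grid The [working_grid()].
#' @return A `likelihood_map`: list with `values` (`ny x nx`, sums to 1)
#'   and `direction`.
#' @export
rasterize_ellipse <- function(ellipse, grid) {
  stop_if_not(inherits(ellipse, "ellipse_params"), "ellipse must be ellipse_params")
  dx <- grid$xs_cm - ellipse$mu[1]
  dy <- grid$ys_cm - ellipse$mu[2]
  A <- solve(ellipse$sigma)
  logd <- -0.5 * (outer(A[2, 2] * dy^2, A[1, 1] * dx^2, `+`) +
                    2 * A[1, 2] * outer(dy, dx))
  v <- exp(logd - max(logd))
  structure(list(values = v / sum(v), direction = ellipse$direction),
            class = "likelihood_map")
}

# Fit one ellipse per direction from gray-block judgments (plane cm).
# `df` needs columns direction, x_cm, y_cm.
.fit_direction_ellipses <- function(df, directions = 0:32) {
  lapply(directions, function(d) {
    pts <- df[df$direction == d, c("x_cm", "y_cm"), drop = FALSE]
    stop_if_not(nrow(pts) >= 3,
                sprintf("direction %d has %d points; need >= 3", d, nrow(pts)))
    fit_ellipse(as.matrix(pts), direction = d)
  })
}

.add_cm <- function(judgments, grid) {
  cm <- px_to_cm(cbind(judgments$click_x_px, judgments$click_y_px), grid)
  judgments$x_cm <- cm[, 1]
  judgments$y_cm <- cm[, 2]
  judgments
}

#' Cross-validate the variance-inflation factor kappa
#'
#' Leave-one-block-out cross-validation over the gray blocks: for each held
#' -out block, ellipses are fit per direction to the remaining blocks, their
#' diagonals inflated by each candidate `kappa`, and the held-out clicks
#' scored by the log probability mass of their working-grid cell under the
#' renormalized map.  `kappa` maximizing the summed held-out log-likelihood
#' wins; ties go to the smaller value.
#'
#' @param judgments Gray-block judgment rows for one subject (columns
#'   `block`, `direction`, `click_x_px`, `click_y_px`); at least two
#'   blocks, each containing every direction.
#' @param grid The [working_grid()].
#' @param kappa_grid Candidate multipliers (default 1.0 to 3.0 by 0.1).
#' @param nsd Window half-width for density evaluation, in marginal
#'   standard deviations.
#' @return A list with `kappa` (the optimum), `cv` (a data frame of fold x
#'   kappa held-out log-likelihoods), `mean_heldout` (best mean held-out
#'   log-likelihood per trial) and `n_cells`.
#' @export
crossvalidate_kappa <- function(judgments, grid,
                                kappa_grid = seq(1, 3, by = 0.1), nsd = 4) {
  stop_if_not(all(kappa_grid >= 1), "kappa grid must be >= 1")
  blocks <- sort(unique(judgments$block))
  stop_if_not(length(blocks) >= 2, "need at least two gray blocks")
  judgments <- .add_cm(judgments, grid)
  directions <- sort(unique(judgments$direction))
  kmax <- max(kappa_grid)
  cv <- expand.grid(fold = blocks, kappa = kappa_grid)
  cv$loglik <- 0
  n_held <- 0L
  for (b in blocks) {
    train <- judgments[judgments$block != b, ]
    held <- judgments[judgments$block == b, ]
    stop_if_not(all(directions %in% unique(held$direction)) &&
                  all(directions %in% unique(train$direction)),
                sprintf("fold %d is missing directions", b))
    n_held <- n_held + nrow(held)
    ells <- .fit_direction_ellipses(train, directions)
    fold_ll <- numeric(length(kappa_grid))
    for (e in ells) {
      hd <- held[held$direction == e$direction, ]
      hc <- px_to_cell(cbind(hd$click_x_px, hd$click_y_px), grid)
      # window sized for the widest candidate, reused across the kappa scan
      win <- .gauss_window(e$mu, inflate_variance(e$sigma, kmax), grid, nsd)
      dx <- grid$xs_cm[win$cols] - e$mu[1]
      dy <- grid$ys_cm[win$rows] - e$mu[2]
      oxy <- outer(dy, dx)
      cdx <- grid$xs_cm[hc[, "col"]] - e$mu[1]
      cdy <- grid$ys_cm[hc[, "row"]] - e$mu[2]
      inside <- hc[, "row"] >= min(win$rows) & hc[, "row"] <= max(win$rows) &
        hc[, "col"] >= min(win$cols) & hc[, "col"] <= max(win$cols)
      for (ki in seq_along(kappa_grid)) {
        A <- solve(inflate_variance(e$sigma, kappa_grid[ki]))
        logd <- outer(-0.5 * A[2, 2] * dy^2, -0.5 * A[1, 1] * dx^2, `+`) -
          A[1, 2] * oxy
        lz <- log(sum(exp(logd)))                 # logd <= ~0: no shift needed
        lq <- -0.5 * (A[1, 1] * cdx^2 + 2 * A[1, 2] * cdx * cdy +
                        A[2, 2] * cdy^2)
        fold_ll[ki] <- fold_ll[ki] + sum(ifelse(inside, lq - lz, log(.EPS)))
      }
      cv$loglik[cv$fold == b] <- cv$loglik[cv$fold == b] + fold_ll
      fold_ll[] <- 0
    }
  }
  totals <- tapply(cv$loglik, cv$kappa, sum)
  best <- which.max(totals)                      # first max: smaller kappa wins ties
  list(kappa = kappa_grid[best],
       cv = cv,
       mean_heldout = max(totals) / n_held,
       n_cells = n_cells(grid))
}

#' Chance-level inclusion test for a subject's likelihood model
#'
#' A subject's likelihood model is validated if its best cross-validated
#' mean held-out log-likelihood per trial exceeds chance, defined as the
#' uniform distribution over the working grid (`log(1 / n_cells)`).
#' Subjects failing this (e.g., clicking uniformly at random) are excluded
#' from the model comparison.
#'
#' @param cv_result The result of [crossvalidate_kappa()].
#' @param grid The [working_grid()].
#' @return Logical: keep the subject?
#' @export
validate_subject <- function(cv_result, grid) {
  stop_if_not(is.list(cv_result) && !is.null(cv_result$mean_heldout),
              "cv_result must come from crossvalidate_kappa()")
  cv_result$mean_heldout > log(1 / n_cells(grid))
}

#' Fit a subject's full likelihood model
#'
#' Runs [crossvalidate_kappa()] on the subject's gray blocks, refits the 33
#' ellipses on all blocks, inflates their diagonals by the winning `kappa`,
#' and applies the chance-level inclusion rule.
#'
#' @param judgments Gray-block judgment rows for one subject.
#' @param grid The [working_grid()].
#' @param kappa_grid Candidate variance multipliers.
#' @param directions Direction indices expected in the data.
#' @return A `subject_model`: list with `subject_id`, `ellipses` (one
#'   kappa-inflated [ellipse_params()] per direction), `kappa`, `cv`,
#'   `included` and `delta` (NA until [fit_delta()] is run).
#' @export
fit_subject_model <- function(judgments, grid,
                              kappa_grid = seq(1, 3, by = 0.1),
                              directions = 0:32) {
  subj <- unique(judgments$subject)
  stop_if_not(length(subj) == 1, "judgments must belong to a single subject")
  cvres <- crossvalidate_kappa(judgments, grid, kappa_grid)
  jcm <- .add_cm(judgments, grid)
  ells <- .fit_direction_ellipses(jcm, directions)
  ells <- lapply(ells, function(e)
    ellipse_params(e$mu, inflate_variance(e$sigma, cvres$kappa), e$direction))
  structure(list(subject_id = subj,
                 ellipses = ells,
                 kappa = cvres$kappa,
                 cv = cvres,
                 included = validate_subject(cvres, grid),
                 delta = NA_real_),
            class = "subject_model")
}

#' @export
print.subject_model <- function(x, ...) {
  cat(sprintf("Subject model [%s]: %d ellipses, kappa = %.2f, %s, delta = %s\n",
              x$subject_id, length(x$ellipses), x$kappa,
              if (x$included) "included" else "EXCLUDED (at/below chance)",
              if (is.na(x$delta)) "unfit" else sprintf("%.3f", x$delta)))
  invisible(x)
}

# Ellipse lookup by direction index.
.model_ellipse <- function(model, direction) {
  for (e in model$ellipses) if (e$direction == direction) return(e)
  stop(sprintf("model has no ellipse for direction %s", direction), call. = FALSE)
}
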