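#' Salience of clicked locations under a chosen definition
#'
#' For each analyzed trial, looks up the salience of the clicked
#' working-grid cell under one of four definitions:
#' \describe{
#'   \item{`full`}{the trial image's own raw salience map (center bias
#'     included);}
#'   \item{`average`}{the cohort-average map, i.e. pure spatial/center
#'     tendency;}
#'   \item{`ratio`}{full divided by average at the same cell -- how salient
#'     the location is compared with what is typical there across images;}
#'   \item{`lowlevel`}{a low-level contrast-energy map
#'     ([contrast_salience()]) of the image, a features-only stand-in for
#'     trained salience models.}
#' }
#' The first `n_practice` trials of each block are treated as practice and
#' excluded.
#'
#' @param judgments Judgment rows (any number of subjects) with columns
#'   `subject`, `block`, `trial`, `image_id`, `click_x_px`, `click_y_px`,
#'   `duration_ms`.
#' @param maps Named list of raw salience maps keyed by `image_id`.
#' @param definition One of `"full"`, `"average"`, `"ratio"`, `"lowlevel"`.
#' @param grid The [working_grid()].
#' @param average Optional precomputed [average_map()]; computed from
#'   `maps` when `NULL`.
#' @param lowlevel Optional named list of precomputed low-level maps;
#'   computed via [contrast_salience()] from `maps` when needed.
#' @param n_practice Practice trials excluded from the start of each block.
#' @return The analyzed judgment rows with an added `salience` column.
#' @export
salience_of_clicks <- function(judgments, maps,
                               definition = c("full", "average", "ratio", "lowlevel"),
                               grid, average = NULL, lowlevel = NULL,
                               n_practice = 3) {
  definition <- match.arg(definition)
  used <- unique(judgments$image_id)
  missing_maps <- setdiff(used, names(maps))
  stop_if_not(length(missing_maps) == 0,
              paste("missing salience map(s):", paste(missing_maps, collapse = ", ")))
  keep <- judgments$trial > n_practice
  jd <- judgments[keep, , drop = FALSE]
  cells <- px_to_cell(cbind(jd$click_x_px, jd$click_y_px), grid)[, "cell"]
  if (definition %in% c("average", "ratio") && is.null(average))
    average <- average_map(maps)
  if (definition == "lowlevel" && is.null(lowlevel))
    lowlevel <- lapply(maps, function(m)
      contrast_salience(.map_values(m), image_id = m$image_id))
  lookup <- function(mp) .map_values(mp)[cells]
  jd$salience <- switch(definition,
    full = {
      v <- numeric(nrow(jd))
      for (id in unique(jd$image_id)) {
        sel <- jd$image_id == id
        v[sel] <- .map_values(maps[[id]])[cells[sel]]
      }
      v
    },
    average = lookup(average),
    ratio = {
      v <- numeric(nrow(jd))
      av <- .map_values(average)
      for (id in unique(jd$image_id)) {
        sel <- jd$image_id == id
        v[sel] <- .map_values(maps[[id]])[cells[sel]] / av[cells[sel]]
      }
      v
    },
    lowlevel = {
      v <- numeric(nrow(jd))
      for (id in unique(jd$image_id)) {
        sel <- jd$image_id == id
        v[sel] <- .map_values(lowlevel[[id]])[cells[sel]]
      }
      v
    })
  jd
}

#' Per-subject regression slope of click salience on viewing duration
#'
#' Ordinary least-squares slope of the salience values against
#' log2(duration in ms) (or raw duration with `transform = "linear"`).
#'
#' @param values Salience-at-click values for one subject's trials.
#' @param durations Matching viewing durations, ms; at least two distinct
#'   levels.
#' @param transform `"log2"` (default) or `"linear"` predictor.
#' @return The scalar OLS slope.
#' @export
subject_slope <- function(values, durations, transform = c("log2", "linear")) {
  transform <- match.arg(transform)
  stop_if_not(length(values) == length(durations),
              "values and durations must have equal length")
  stop_if_not(length(unique(durations)) >= 2,
              "need at least two distinct duration levels")
  x <- if (transform == "log2") log2(durations) else durations
  unname(coef(stats::lm(values ~ x))[2])
}

#' Group-level test of duration slopes
#'
#' Two-sided one-sample t test of per-subject regression slopes against
#' zero.
#'
#' @param slopes Numeric vector of per-subject slopes (n >= 2).
#' @return A `group_test` list (`mean`, `t`, `df`, `p`, `degenerate`).
#' @export
group_slope_test <- function(slopes) {
  res <- one_sample_t(as.numeric(slopes))
  class(res) <- "group_test"
  res
}

#' Viewing-duration analysis across salience definitions
#'
#' The complete per-definition analysis: salience of each analyzed click,
#' per-subject OLS slopes against log2 duration, group t tests of the
#' slopes, and per-duration mean salience with SEM (across subjects) for
#' plotting.
#'
#' @inheritParams salience_of_clicks
#' @param definitions Which definitions to analyze.
#' @param transform Predictor transform for the slopes.
#' @return A `slope_table`: list with `slopes` (subject x definition data
#'   frame), `group` (one row per definition: mean slope, t, df, p) and
#'   `by_duration` (definition x duration mean and SEM).
#' @export
duration_analysis <- function(judgments, maps, grid,
                              definitions = c("full", "average", "ratio", "lowlevel"),
                              n_practice = 3, transform = c("log2", "linear")) {
  transform <- match.arg(transform)
  average <- average_map(maps)
  lowlevel <- if ("lowlevel" %in% definitions)
    lapply(maps, function(m) contrast_salience(.map_values(m), image_id = m$image_id))
  slopes <- list(); group <- list(); by_dur <- list()
  for (def in definitions) {
    jd <- salience_of_clicks(judgments, maps, def, grid, average = average,
                             lowlevel = lowlevel, n_practice = n_practice)
    sl <- vapply(split(jd, jd$subject), function(d)
      subject_slope(d$salience, d$duration_ms, transform), numeric(1))
    gt <- group_slope_test(sl)
    slopes[[def]] <- data.frame(subject = names(sl), definition = def,
                                slope = unname(sl))
    group[[def]] <- data.frame(definition = def, mean_slope = gt$mean,
                               t = gt$t, df = gt$df, p = gt$p)
    submeans <- tapply(jd$salience, list(jd$subject, jd$duration_ms), mean)
    by_dur[[def]] <- data.frame(
      definition = def,
      duration_ms = as.numeric(colnames(submeans)),
      mean_salience = colMeans(submeans, na.rm = TRUE),
      sem = apply(submeans, 2, stats::sd, na.rm = TRUE) / sqrt(nrow(submeans)))
  }
  structure(list(slopes = do.call(rbind, c(slopes, make.row.names = FALSE)),
                 group = do.call(rbind, c(group, make.row.names = FALSE)),
                 by_duration = do.call(rbind, c(by_dur, make.row.names = FALSE))),
            class = "slope_table")
}

#' @export
print.slope_table <- function(x, ...) {
  cat("Viewing-duration analysis (per-subject OLS slopes vs log2 duration):\n")
  print(x$group, row.names = FALSE)
  invisible(x)
}
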