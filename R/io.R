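# File I/O: judgment tables as CSV, salience maps as plain-text matrices
# with JSON sidecars, configs as YAML or JSON.

.JUDGMENT_COLS <- c("subject", "block", "trial", "direction", "image_id",
                    "click_x_px", "click_y_px", "duration_ms")

#' Read and write judgment tables
#'
#' Judgment tables are CSV files with the fixed header
#' `subject,block,trial,direction,image_id,click_x_px,click_y_px,duration_ms`.
#' Pixel coordinates are 0-based from the top-left corner (x rightward, y
#' downward); `duration_ms` is empty for untimed trials.
#'
#' @param judgments A judgment data frame (see [simulate_exp1()]).
#' @param path File path.
#' @return `read_judgments` returns the judgment data frame;
#'   `write_judgments` returns `path` invisibly.
#' @export
write_judgments <- function(judgments, path) {
  stop_if_not(all(.JUDGMENT_COLS %in% names(judgments)),
              paste("judgments must have columns:", paste(.JUDGMENT_COLS, collapse = ", ")))
  utils::write.csv(judgments[, .JUDGMENT_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_judgments
#' @export
read_judgments <- function(path) {
  jd <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject = "character",
                                       image_id = "character"))
  stop_if_not(identical(names(jd), .JUDGMENT_COLS),
              paste("unexpected judgment CSV header; expected:",
                    paste(.JUDGMENT_COLS, collapse = ",")))
  stop_if_not(all(jd$direction >= 0 & jd$direction <= 32),
              "direction index outside 0..32")
  jd
}

#' Read and write salience maps
#'
#' Maps are stored as whitespace-separated plain-text matrices (one line
#' per pixel row, top to bottom) with a JSON sidecar (`<path>.json`)
#' recording the image id and normalization state.
#'
#' @param map A [salience_map()].
#' @param path File path for the matrix; the sidecar is `<path>.json`.
#' @return `read_map` returns the [salience_map()]; `write_map` returns
#'   `path` invisibly.
#' @export
write_map <- function(map, path) {
  stop_if_not(inherits(map, "salience_map"), "map must be a salience_map")
  utils::write.table(map$values, path, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(image_id = map$image_id, state = map$state,
                            ny = nrow(map$values), nx = ncol(map$values)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  v <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(v) <- NULL
  meta <- if (file.exists(paste0(path, ".json")))
    jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  else list(state = "raw", image_id = NULL)
  salience_map(v, state = meta$state, image_id = meta$image_id)
}

#' Read and write fitted subject models
#'
#' Serializes a list of `subject_model` objects (see
#' [fit_subject_model()]) to JSON: per subject the 33 ellipse means and
#' covariances, the cross-validated `kappa` with its CV table, the
#' inclusion flag and the fitted `delta` (if any).
#'
#' @param models Named list of `subject_model` objects.
#' @param path JSON file path.
#' @return `read_models` returns the named list of models; `write_models`
#'   returns `path` invisibly.
#' @export
write_models <- function(models, path) {
  payload <- lapply(models, function(m) {
    stop_if_not(inherits(m, "subject_model"), "models must be subject_model objects")
    list(subject_id = m$subject_id,
         kappa = m$kappa,
         included = m$included,
         delta = m$delta,
         cv = m$cv$cv,
         mean_heldout = m$cv$mean_heldout,
         ellipses = lapply(m$ellipses, function(e)
           list(direction = e$direction, mu = e$mu, sigma = as.vector(e$sigma))))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_models
#' @export
read_models <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = TRUE)
  out <- lapply(payload, function(m) {
    ells <- lapply(seq_len(nrow(m$ellipses)), function(i)
      ellipse_params(unlist(m$ellipses$mu[i]),
                     matrix(unlist(m$ellipses$sigma[i]), 2, 2),
                     m$ellipses$direction[i]))
    structure(list(subject_id = m$subject_id,
                   ellipses = ells,
                   kappa = m$kappa,
                   cv = list(cv = m$cv, mean_heldout = m$mean_heldout),
                   included = m$included,
                   delta = if (is.null(m$delta)) NA_real_ else m$delta),
              class = "subject_model")
  })
  stats::setNames(out, vapply(out, `[[`, "", "subject_id"))
}

#' Read and write run configurations
#'
#' Configurations (see [default_config()]) round-trip through YAML
#' (`.yml`/`.yaml`) or JSON (`.json`, lossless for doubles).
#'
#' @param config A configuration list.
#' @param path File path; the extension selects the format.
#' @return `read_config` returns the configuration list; `write_config`
#'   returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  if (grepl("\\.json$", path))
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}
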