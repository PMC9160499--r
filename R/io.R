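# File-format plumbing: versioned CSV/JSON artifacts. All tabular files are
# plain CSV with a comment header carrying the format version and the
# generating seed; nested state (observer configs, QUEST+ posteriors,
# study manifests) is JSON. Angles are degrees, times milliseconds,
# contrasts linear proportions throughout.

#' Artifact format version
#'
#' @return Version tag written into every file this package emits.
#' @export
saccadecs_format_version <- function() "saccadecs-v1"

#' Write / read a session trial log as CSV
#'
#' One row per trial attempt with the columns produced by [run_session()].
#' The header comment carries the format version and generating seed.
#'
#' @param session A `session_result` (or a bare log data.frame plus `seed`).
#' @param path File path.
#' @return `write_session_csv` invisibly returns `path`;
#'   `read_session_csv` returns the log data.frame with the seed as an
#'   attribute.
#' @export
write_session_csv <- function(session, path) {
  log <- if (inherits(session, "session_result")) session$log else session
  seed <- if (inherits(session, "session_result")) session$seed
          else attr(session, "seed")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s session log, seed=%s", saccadecs_format_version(),
                     seed %||% "NA"), con)
  utils::write.csv(log, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(path) {
  header <- readLines(path, n = 1L)
  df <- utils::read.csv(path, comment.char = "#")
  seed <- suppressWarnings(as.integer(sub(".*seed=", "", header)))
  need <- c("trial_id", "meridian_deg", "orientation_deg", "is_catch",
            "contrast", "saccade_correct", "keyboard_correct", "status")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("malformed session CSV: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  attr(df, "seed") <- seed
  df
}

#' Write / read an observer configuration as JSON
#'
#' @param obs An [observer_model()].
#' @param path File path.
#' @return `write_observer_json` invisibly returns `path`;
#'   `read_observer_json` returns an [observer_model()].
#' @export
write_observer_json <- function(obs, path) {
  stopifnot(inherits(obs, "observer_model"))
  obj <- unclass(obs)
  obj$csf <- lapply(obs$csf, unclass)
  if (!is.null(obs$m_fixed)) obj$m_fixed <- as.list(obs$m_fixed)
  obj$format <- saccadecs_format_version()
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_observer_json
#' @export
read_observer_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  csf <- if (!is.null(obj$csf))
    lapply(obj$csf, function(p) csf_params(p$gamma_max, p$sf_max, p$beta))
  else NULL
  m_fixed <- if (!is.null(obj$m_fixed)) unlist(obj$m_fixed) else NULL
  observer_model(csf = csf, m_fixed = m_fixed,
                 true_slope = obj$true_slope, lapse = obj$lapse,
                 guess_4afc = obj$guess_4afc,
                 latency_base_ms = obj$latency_base_ms,
                 latency_contrast_gain_ms = obj$latency_contrast_gain_ms,
                 latency_c0 = obj$latency_c0,
                 latency_sd_ms = obj$latency_sd_ms,
                 dir_noise_sd_deg = obj$dir_noise_sd_deg,
                 fp_rate = obj$fp_rate, blink_rate = obj$blink_rate)
}

#' Write a study manifest as JSON
#'
#' @param manifest Data.frame from [build_study()].
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_manifest_json <- function(manifest, path) {
  obj <- list(format = saccadecs_format_version(),
              master_seed = attr(manifest, "master_seed"),
              sessions = manifest)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write fitted sensitivity results as CSV
#'
#' @param cs_table Tidy table from [study_cs_table()].
#' @param path File path.
#' @param seed Generating seed recorded in the header comment.
#' @return Invisibly, `path`.
#' @export
write_cs_csv <- function(cs_table, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s sensitivity table, seed=%s",
                     saccadecs_format_version(), seed), con)
  utils::write.csv(cs_table, con, row.names = FALSE)
  invisible(path)
}
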