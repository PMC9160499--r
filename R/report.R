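# Method-agreement analytics: pairing of log CS values across the three
# response channels (saccade-in-saccadic, keyboard-in-saccadic,
# keyboard-in-non-saccadic), Pearson correlation and Bland-Altman limits of
# agreement, plus the per-condition summary table and the catch-trial
# false-positive rate. Omnibus tests (Friedman, ANOVA) are left to standard
# routines applied to the tidy tables this module emits.

#' Per-channel sensitivity estimates for one session
#'
#' Fits the psychometric function per meridian for every response channel
#' the session carries and converts thresholds to log10 CS.
#'
#' @param session A `session_result` from [run_session()].
#' @return Data.frame with one row per meridian x channel: `meridian_deg`,
#'   `vf_label`, `channel`, `m`, `w`, `lam`, `log_cs`, `boundary`.
#' @export
analyze_session <- function(session) {
  stopifnot(inherits(session, "session_result"))
  channels <- if (session$condition$mode == "saccadic")
    c("saccade", "keyboard") else "keyboard"
  rows <- list()
  for (mer in MERIDIANS) for (ch in channels) {
    tab <- rate_table(session$log, mer, channel = ch)
    fit <- suppressWarnings(fit_psychometric(tab, mode = ch))
    rows[[length(rows) + 1L]] <- data.frame(
      meridian_deg = mer, vf_label = meridian_label(mer), channel = ch,
      m = fit$params$m, w = fit$params$w, lam = fit$params$lam,
      log_cs = -fit$params$m / log(10), boundary = fit$boundary)
  }
  out <- do.call(rbind, rows)
  out$eccentricity_deg <- session$condition$eccentricity_deg
  out$spatial_freq_cpd <- session$condition$spatial_freq_cpd
  out$mode <- session$condition$mode
  out
}

#' Tidy sensitivity table for a whole study
#'
#' Stacks [analyze_session()] over a list of sessions and labels each row
#' with its testing method: `saccade_saccadic`, `keyboard_saccadic` or
#' `keyboard_nonsaccadic`.
#'
#' @param results List of `session_result`s (as from [run_study()]), whose
#'   manifest attribute (or the `participants` argument) supplies subject
#'   ids.
#' @param participants Optional vector of participant ids, one per session.
#' @return Tidy data.frame: `participant`, `eccentricity_deg`,
#'   `spatial_freq_cpd`, `meridian_deg`, `vf_label`, `method`, `log_cs`.
#' @export
study_cs_table <- function(results, participants = NULL) {
  manifest <- attr(results, "manifest")
  if (is.null(participants))
    participants <- if (!is.null(manifest)) manifest$participant
                    else seq_along(results)
  stopifnot(length(participants) == length(results))
  tabs <- lapply(seq_along(results), function(i) {
    a <- analyze_session(results[[i]])
    a$participant <- participants[i]
    a
  })
  tab <- do.call(rbind, tabs)
  tab$method <- ifelse(tab$mode == "non-saccadic", "keyboard_nonsaccadic",
                       ifelse(tab$channel == "saccade", "saccade_saccadic",
                              "keyboard_saccadic"))
  tab[, c("participant", "eccentricity_deg", "spatial_freq_cpd",
          "meridian_deg", "vf_label", "method", "log_cs")]
}

#' Pair log CS values across the three testing methods
#'
#' @param cs_table Tidy table from [study_cs_table()].
#' @return Wide data.frame with one row per (participant, eccentricity,
#'   spatial frequency, meridian) and one column per method; rows with any
#'   missing channel are dropped.
#' @export
method_triplets <- function(cs_table) {
  wide <- stats::reshape(
    cs_table[, c("participant", "eccentricity_deg", "spatial_freq_cpd",
                 "meridian_deg", "method", "log_cs")],
    idvar = c("participant", "eccentricity_deg", "spatial_freq_cpd",
              "meridian_deg"),
    timevar = "method", direction = "wide")
  names(wide) <- sub("^log_cs\\.", "", names(wide))
  need <- c("saccade_saccadic", "keyboard_saccadic", "keyboard_nonsaccadic")
  for (ch in setdiff(need, names(wide))) wide[[ch]] <- NA_real_
  complete <- stats::complete.cases(wide[, need])
  rownames(wide) <- NULL
  wide[complete, , drop = FALSE]
}

#' Pearson correlation of paired sensitivity values
#'
#' Thin wrapper over the product-moment correlation with the guard rails
#' the agreement analysis needs.
#'
#' @param x,y Paired numeric vectors, `n >= 3`.
#' @return List with `r` and `n`.
#' @export
pearson_r <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  list(r = stats::cor(x, y), n = length(x))
}

#' Bland-Altman agreement statistics
#'
#' Bias is the mean of the paired differences `x - y`; the limits of
#' agreement are `bias +/- 1.96 * sd(x - y)` with the sample (n-1) SD.
#'
#' @param x,y Paired numeric vectors, `n >= 2`.
#' @return List with `bias`, `sd_diff`, `loa_lower`, `loa_upper`, `n`.
#' @export
bland_altman <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  d <- x[keep] - y[keep]
  if (length(d) < 2L) stop("need >= 2 complete pairs", call. = FALSE)
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, sd_diff = s,
       loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
       n = length(d))
}

#' Full agreement report for a simulated study
#'
#' Assembles the triplet table, the three pairwise Pearson correlations and
#' Bland-Altman summaries, a per-condition median/mean +/- SD sensitivity
#' table for the saccade-based channel, and the catch-trial false-positive
#' rate. Missing channels produce a partial report with explicit `NULL`
#' gaps.
#'
#' @param results List of `session_result`s (as from [run_study()]).
#' @param participants Optional participant ids per session.
#' @return A list of class `study_report`: `cs_table`, `triplets`,
#'   `correlations`, `bland_altman`, `summary_table`, `n_catch`,
#'   `n_false_positive`, `fp_rate`.
#' @export
build_report <- function(results, participants = NULL) {
  cs_table <- study_cs_table(results, participants)
  trip <- method_triplets(cs_table)
  pairs <- list(
    saccade_vs_kb_nonsacc = c("saccade_saccadic", "keyboard_nonsaccadic"),
    saccade_vs_kb_sacc = c("saccade_saccadic", "keyboard_saccadic"),
    kb_sacc_vs_kb_nonsacc = c("keyboard_saccadic", "keyboard_nonsaccadic"))
  cors <- lapply(pairs, function(p)
    if (nrow(trip) >= 3L) pearson_r(trip[[p[1L]]], trip[[p[2L]]]) else NULL)
  bas <- lapply(pairs, function(p)
    if (nrow(trip) >= 2L) bland_altman(trip[[p[1L]]], trip[[p[2L]]])
    else NULL)
  sacc <- cs_table[cs_table$method == "saccade_saccadic", ]
  summary_table <- if (nrow(sacc)) {
    agg <- stats::aggregate(
      log_cs ~ vf_label + eccentricity_deg, data = sacc,
      FUN = function(v) c(median = stats::median(v), mean = mean(v),
                          sd = stats::sd(v)))
    data.frame(agg[c("vf_label", "eccentricity_deg")],
               median_log_cs = agg$log_cs[, "median"],
               mean_log_cs = agg$log_cs[, "mean"],
               sd_log_cs = agg$log_cs[, "sd"])
  } else NULL
  n_catch <- sum(vapply(results, function(s) s$n_catch, numeric(1)))
  n_fp <- sum(vapply(results, function(s) s$n_false_positive, numeric(1)))
  structure(list(cs_table = cs_table, triplets = trip, correlations = cors,
                 bland_altman = bas, summary_table = summary_table,
                 n_catch = n_catch, n_false_positive = n_fp,
                 fp_rate = if (n_catch > 0) n_fp / n_catch else NA_real_),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Study report: %d sensitivity estimates, %d complete triplets\n",
              nrow(x$cs_table), nrow(x$triplets)))
  for (nm in names(x$correlations)) {
    co <- x$correlations[[nm]]; ba <- x$bland_altman[[nm]]
    if (!is.null(co))
      cat(sprintf("  %s: r = %.3f (n = %d), bias = %+.4f [%.4f, %.4f]\n",
                  nm, co$r, co$n, ba$bias, ba$loa_lower, ba$loa_upper))
  }
  if (x$n_catch > 0)
    cat(sprintf("  catch trials: %d, false positives: %d (rate %.3f)\n",
                x$n_catch, x$n_false_positive, x$fp_rate))
  invisible(x)
}
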