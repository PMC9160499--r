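# Closed-loop session orchestration: fixation -> stimulus -> response ->
# QUEST+ update. One independent QUEST+ instance per meridian; catch trials
# never touch the adaptive procedure; a blink re-queues the interrupted
# trial (same stimulus parameters) and reshuffles the remaining order.

#' Run one closed-loop measurement session
#'
#' Iterates a balanced schedule for one condition against a simulated
#' observer. Per target trial, the meridian's QUEST+ instance supplies the
#' contrast, the observer produces gaze and keyboard outcomes, and only the
#' driving response type updates the procedure: the saccade verdict in
#' saccadic mode (guess rate 0), the 4AFC keyboard correctness in
#' non-saccadic mode (guess rate 0.25). Keyboard answers are still logged
#' in saccadic mode as a secondary channel.
#'
#' @param cond A [condition_spec()].
#' @param observer An [observer_model()].
#' @param seed Integer seed controlling schedule and observer randomness.
#' @param geom A [screen_geometry()].
#' @param gaze_channel `"events"` scores the observer's analytic exit events
#'   directly; `"trace"` expands each event into a 1 kHz gaze trace and
#'   scores it through [score_trial()]. The two channels implement the same
#'   behavioural model; `"trace"` additionally exercises the classifier.
#' @param grace_ms Post-stimulus grace period appended to the 500 ms
#'   presentation limit to form the response window (default 500).
#' @param lapse_grid Fixed lapse rate of the QUEST+ grids.
#' @param keep_traces If `TRUE` (with `gaze_channel = "trace"`), the gaze
#'   traces are returned alongside the log.
#' @return A list of class `session_result`: `log` (one row per trial
#'   attempt), `quest` (named list of final `quest_state`s per meridian),
#'   `condition`, `seed`, `n_false_positive`, `n_catch`, and optionally
#'   `traces`.
#' @export
run_session <- function(cond, observer, seed, geom = screen_geometry(),
                        gaze_channel = c("events", "trace"),
                        grace_ms = 500, lapse_grid = 0.02,
                        keep_traces = FALSE) {
  stopifnot(inherits(cond, "condition_spec"),
            inherits(observer, "observer_model"))
  gaze_channel <- match.arg(gaze_channel)
  window_ms <- cond$presentation_ms + grace_ms
  sched <- build_schedule(cond, seed)
  gamma_mode <- if (cond$mode == "saccadic") 0 else 0.25
  quest <- lapply(MERIDIANS, function(mer)
    quest_init(parameter_grid(gamma = gamma_mode, lam = lapse_grid),
               location_label = as.character(mer)))
  names(quest) <- as.character(MERIDIANS)

  with_seed(seed + 1L, {
    queue <- as.data.frame(sched)
    queue$contrast <- NA_real_   # filled on first attempt, kept on repeat
    rows <- list(); traces <- list(); attempt <- 0L
    while (nrow(queue) > 0L) {
      tr <- queue[1L, ]
      queue <- queue[-1L, , drop = FALSE]
      attempt <- attempt + 1L
      fix_ms <- stats::runif(1L, cond$fixation_ms_range[1L],
                             cond$fixation_ms_range[2L])
      mer <- tr$meridian_deg
      contrast <- tr$contrast
      if (!tr$is_catch && is.na(contrast))
        contrast <- quest_next_stimulus(quest[[as.character(mer)]])
      ev <- simulate_trial_outcome(observer, mer, cond$spatial_freq_cpd,
                                   contrast)
      if (gaze_channel == "trace") {
        # isolated RNG stream: trace jitter must not perturb the observer's
        # behavioural draws, so both gaze channels see identical outcomes
        trace <- with_seed((seed %% 1000000L) * 1000L + attempt,
          generate_gaze_trace(ev, geom, duration_ms = window_ms,
                              eccentricity_deg = cond$eccentricity_deg))
        if (keep_traces) traces[[attempt]] <- trace
      }
      if (ev$blink) {
        # repeat with the same stimulus parameters; reshuffle what remains
        tr$contrast <- contrast
        queue <- rbind(queue, tr)
        queue <- queue[sample.int(nrow(queue)), , drop = FALSE]
        rows[[attempt]] <- data.frame(
          attempt = attempt, trial_id = tr$trial_id, meridian_deg = mer,
          orientation_deg = tr$orientation_deg, is_catch = tr$is_catch,
          contrast = contrast, fixation_ms = fix_ms, exited = NA,
          exit_time_ms = NA_real_, beta_g = NA_real_,
          saccade_correct = NA, keyboard_correct = NA, status = "repeated")
        next
      }
      if (gaze_channel == "trace") {
        v <- score_trial(trace, if (tr$is_catch) NA_real_ else mer, geom,
                         window_ms = window_ms)
        exited <- v$exited; exit_t <- v$exit_time_ms; beta <- v$beta_g
        sacc_ok <- if (tr$is_catch) NA else v$correct
        fp <- v$false_positive
      } else {
        exited <- isTRUE(ev$exited) && ev$exit_time_ms <= window_ms
        exit_t <- if (exited) ev$exit_time_ms else NA_real_
        beta <- if (exited) ev$exit_direction_deg else NA_real_
        sacc_ok <- if (tr$is_catch) NA else
          exited && classify_saccade(beta, mer)
        fp <- tr$is_catch && exited
      }
      if (cond$mode == "non-saccadic") {
        # fixation maintained throughout: no saccade channel in this mode
        exited <- NA; exit_t <- NA_real_; beta <- NA_real_
        sacc_ok <- NA; fp <- FALSE
      }
      kb_ok <- if (cond$mode == "saccadic" || !tr$is_catch)
        ev$keyboard_correct else NA
      if (!tr$is_catch) {
        driving <- if (cond$mode == "saccadic") isTRUE(sacc_ok)
                   else isTRUE(kb_ok)
        quest[[as.character(mer)]] <-
          quest_update(quest[[as.character(mer)]], contrast, driving)
      }
      rows[[attempt]] <- data.frame(
        attempt = attempt, trial_id = tr$trial_id, meridian_deg = mer,
        orientation_deg = tr$orientation_deg, is_catch = tr$is_catch,
        contrast = contrast, fixation_ms = fix_ms, exited = exited,
        exit_time_ms = exit_t, beta_g = beta,
        saccade_correct = sacc_ok, keyboard_correct = kb_ok,
        status = "done")
    }
    log <- do.call(rbind, rows)
    rownames(log) <- NULL
    res <- list(log = log, quest = quest, condition = cond, seed = seed,
                n_catch = sum(log$is_catch & log$status == "done"),
                n_false_positive = sum(log$is_catch & log$status == "done" &
                                         log$exited, na.rm = TRUE))
    if (keep_traces) res$traces <- traces
    class(res) <- "session_result"
    res
  })
}

#' @export
print.session_result <- function(x, ...) {
  done <- x$log[x$log$status == "done", ]
  cat(sprintf(
    "Session (%s, ecc %.1f deg, %.1f cpd): %d trials done (%d targets, %d catch, %d false positives), %d repeats\n",
    x$condition$mode, x$condition$eccentricity_deg,
    x$condition$spatial_freq_cpd, nrow(done), sum(!done$is_catch),
    x$n_catch, x$n_false_positive, sum(x$log$status == "repeated")))
  invisible(x)
}

#' Simulate a cohort of sessions
#'
#' Runs [run_session()] for every row of a [build_study()]-style manifest
#' (optionally filtered), each under its derived seed, with a fresh default
#' observer per participant/eccentricity unless an observer factory is
#' supplied.
#'
#' @param manifest A data.frame as returned by [build_study()].
#' @param observer_factory Function `(participant, eccentricity_deg)`
#'   returning an [observer_model()]; default uses [default_observer()].
#' @param ... Passed to [run_session()].
#' @return A list of `session_result`s, one per manifest row, with the
#'   manifest attached as an attribute.
#' @export
run_study <- function(manifest,
                      observer_factory = function(participant, ecc)
                        default_observer(ecc),
                      ...) {
  res <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    cond <- condition_spec(row$eccentricity_deg, row$spatial_freq_cpd,
                           mode = row$mode)
    run_session(cond, observer_factory(row$participant,
                                       row$eccentricity_deg),
                seed = row$session_seed, ...)
  })
  attr(res, "manifest") <- manifest
  res
}
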