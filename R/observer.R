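# Statistical simulated observer: stands in for the human participant and
# the eye tracker so the whole closed loop is testable without human data.
# Detection follows a cumulative Weibull whose direction-specific thresholds
# derive from a log-parabola contrast sensitivity function; saccade latency
# decreases with contrast (so near-threshold saccades can overrun the 500 ms
# presentation window); fixational excursions produce catch-trial false
# positives at a configurable per-trial rate; 4AFC answers fall back on a
# 25% guess when the orientation was not perceived.

#' Simulated-observer model
#'
#' @param csf Named list of [csf_params()], one per meridian
#'   (`"0"`, `"90"`, `"180"`, `"270"` in the screen frame), giving the
#'   observer's true contrast sensitivity per direction. Ignored for a
#'   meridian listed in `m_fixed`.
#' @param m_fixed Optional named numeric vector of fixed true thresholds
#'   (natural-log contrast) per meridian, overriding the CSF; convenient for
#'   on-grid parameter-recovery studies.
#' @param true_slope Weibull slope of the observer's detection curve
#'   (width `w = c / slope`).
#' @param lapse Lapse rate.
#' @param guess_4afc Guessing probability of the 4AFC keyboard response.
#' @param latency_base_ms Asymptotic saccade latency at high contrast.
#' @param latency_contrast_gain_ms Extra latency at vanishing contrast; the
#'   latency model is `base + gain * exp(-contrast / latency_c0) + noise`.
#'   The defaults place near- and sub-threshold latencies occasionally
#'   beyond the response window, so low-contrast detections are sometimes
#'   lost to the saccade channel (but never to the keyboard channel) --
#'   the mechanism behind the saccade channel's slightly lower measured
#'   sensitivity. Set the gain to 0 for a latency-neutral observer.
#' @param latency_c0 Contrast scale of the latency decay.
#' @param latency_sd_ms SD of Gaussian latency noise.
#' @param dir_noise_sd_deg SD of Gaussian noise on saccade direction; the
#'   default 5 keeps nearly all true detections inside the 22.5-degree cone.
#' @param fp_rate Per-catch-trial probability of a fixational excursion
#'   beyond the 1-degree window (false positive), default 0.043.
#' @param blink_rate Per-trial blink probability.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(csf = NULL, m_fixed = NULL, true_slope = 3,
                           lapse = 0.02, guess_4afc = 0.25,
                           latency_base_ms = 200,
                           latency_contrast_gain_ms = 900,
                           latency_c0 = 0.1, latency_sd_ms = 150,
                           dir_noise_sd_deg = 5,
                           fp_rate = 0.043, blink_rate = 0.02) {
  probs <- c(lapse = lapse, guess_4afc = guess_4afc, fp_rate = fp_rate,
             blink_rate = blink_rate)
  if (any(probs < 0) || any(probs > 1))
    stop("rates must be probabilities in [0, 1]", call. = FALSE)
  if (latency_base_ms <= 0 || latency_contrast_gain_ms < 0 ||
      latency_c0 <= 0 || latency_sd_ms < 0)
    stop("latency parameters must be positive", call. = FALSE)
  if (true_slope <= 0) stop("`true_slope` must be positive", call. = FALSE)
  if (is.null(csf) && is.null(m_fixed))
    stop("provide `csf` (per-meridian CSFs) or `m_fixed`", call. = FALSE)
  structure(list(csf = csf, m_fixed = m_fixed, true_slope = true_slope,
                 lapse = lapse, guess_4afc = guess_4afc,
                 latency_base_ms = latency_base_ms,
                 latency_contrast_gain_ms = latency_contrast_gain_ms,
                 latency_c0 = latency_c0, latency_sd_ms = latency_sd_ms,
                 dir_noise_sd_deg = dir_noise_sd_deg,
                 fp_rate = fp_rate, blink_rate = blink_rate),
            class = "observer_model")
}

#' Default simulated observer for an eccentricity level
#'
#' Direction-specific true CSFs shaped like the qualitative visual-field
#' anisotropy of peripheral contrast sensitivity: nasal and temporal
#' directions slightly above superior, superior above inferior, and all
#' peaks decreasing (and shifting to lower spatial frequency) with
#' eccentricity.
#'
#' @param eccentricity_deg One of 2, 6.5, 11.
#' @param ... Further arguments passed to [observer_model()].
#' @return An [observer_model()].
#' @export
default_observer <- function(eccentricity_deg = 2, ...) {
  peak_log_cs <- switch(as.character(eccentricity_deg),
                        `2` = 1.55, `6.5` = 1.42, `11` = 1.35,
                        stop("eccentricity must be one of 2, 6.5, 11",
                             call. = FALSE))
  sf_peak <- switch(as.character(eccentricity_deg),
                    `2` = 2.0, `6.5` = 1.5, `11` = 1.0)
  # screen frame: 0 temporal, 90 inferior, 180 nasal, 270 superior
  offsets <- c(`0` = 0, `90` = -0.16, `180` = 0.02, `270` = -0.08)
  csf <- lapply(offsets, function(d)
    csf_params(gamma_max = 10^(peak_log_cs + d), sf_max = sf_peak,
               beta = 2.5))
  observer_model(csf = csf, ...)
}

#' True detection threshold of the observer
#'
#' For a meridian and spatial frequency, the natural-log contrast threshold
#' `m` implied by the observer's CSF (`m = -ln(10) * log10 CS`), or the
#' fixed override when one is set.
#'
#' @param obs An [observer_model()].
#' @param meridian_deg Screen-frame meridian (0, 90, 180, 270).
#' @param sf_cpd Spatial frequency, cycles per degree.
#' @return Threshold `m` in natural-log contrast units.
#' @export
observer_threshold <- function(obs, meridian_deg, sf_cpd) {
  stopifnot(inherits(obs, "observer_model"))
  key <- as.character(meridian_deg)
  if (!is.null(obs$m_fixed) && key %in% names(obs$m_fixed))
    return(unname(obs$m_fixed[key]))
  if (is.null(obs$csf[[key]]))
    stop("observer has no CSF or fixed threshold for meridian ", key,
         call. = FALSE)
  log_cs <- csf_value(sf_cpd, obs$csf[[key]])
  cs_to_threshold(10^log_cs)
}

#' Detection probability of the simulated observer
#'
#' Weibull probability that the observer detects (saccade channel, guess
#' rate 0) or correctly reports (keyboard channel, guess rate 0.25) a
#' stimulus of the given contrast.
#'
#' @param obs An [observer_model()].
#' @param meridian_deg,sf_cpd Stimulus location and spatial frequency.
#' @param contrast Contrast(s), proportion.
#' @param channel `"saccade"` (yes/no detection) or `"keyboard"` (4AFC
#'   correctness including the guessing floor).
#' @return Probability vector.
#' @export
detect_probability <- function(obs, meridian_deg, sf_cpd, contrast,
                               channel = c("saccade", "keyboard")) {
  channel <- match.arg(channel)
  m <- observer_threshold(obs, meridian_deg, sf_cpd)
  gam <- if (channel == "keyboard") obs$guess_4afc else 0
  p <- psychometric_params(m = m, w = slope_to_width(obs$true_slope),
                           gamma = gam, lam = obs$lapse)
  weibull_prob(contrast, p)
}

# Saccade latency draw for one detected stimulus (ms).
saccade_latency <- function(obs, contrast) {
  obs$latency_base_ms +
    obs$latency_contrast_gain_ms * exp(-contrast / obs$latency_c0) +
    stats::rnorm(1L, 0, obs$latency_sd_ms)
}

#' Simulate the outcome of one trial (event form)
#'
#' Draws the observer's behaviour for one trial as an analytic event record:
#' blink, perception, saccade exit time and direction, catch-trial false
#' positive, and the 4AFC keyboard answer. [generate_gaze_trace()] can
#' expand such an event into a 1 kHz gaze trace; both representations score
#' identically under [score_trial()].
#'
#' @param obs An [observer_model()].
#' @param meridian_deg Meridian of the target, or `NA` for a catch trial.
#' @param sf_cpd Spatial frequency (ignored for catch trials).
#' @param contrast Stimulus contrast (ignored for catch trials).
#' @return A list with `blink`, `perceived`, `exited`, `exit_time_ms`,
#'   `exit_direction_deg`, `keyboard_correct`.
#' @export
simulate_trial_outcome <- function(obs, meridian_deg, sf_cpd, contrast) {
  stopifnot(inherits(obs, "observer_model"))
  out <- list(blink = stats::runif(1L) < obs$blink_rate,
              perceived = FALSE, exited = FALSE,
              exit_time_ms = NA_real_, exit_direction_deg = NA_real_,
              keyboard_correct = NA)
  if (is.na(meridian_deg)) {                      # catch trial: no target
    if (stats::runif(1L) < obs$fp_rate) {
      out$exited <- TRUE
      out$exit_time_ms <- stats::runif(1L, 80, 900)
      out$exit_direction_deg <- stats::runif(1L, 0, 360)
    }
    out$keyboard_correct <- stats::runif(1L) < obs$guess_4afc
    return(out)
  }
  p_seen <- detect_probability(obs, meridian_deg, sf_cpd, contrast,
                               channel = "saccade")
  out$perceived <- stats::runif(1L) < p_seen
  if (out$perceived) {
    out$exited <- TRUE
    out$exit_time_ms <- max(saccade_latency(obs, contrast), 60)
    out$exit_direction_deg <-
      (meridian_deg + stats::rnorm(1L, 0, obs$dir_noise_sd_deg)) %% 360
  }
  out$keyboard_correct <- answer_4afc(obs, out$perceived)
  out
}

#' 4AFC keyboard answer
#'
#' If the orientation was perceived the answer is correct unless a lapse
#' occurs; otherwise the observer guesses uniformly among the four
#' orientations (correct with probability 0.25).
#'
#' @param obs An [observer_model()].
#' @param perceived Logical: did the observer perceive the orientation?
#' @return Logical: keyboard answer correct.
#' @export
answer_4afc <- function(obs, perceived) {
  stopifnot(inherits(obs, "observer_model"))
  if (isTRUE(perceived)) stats::runif(1L) >= obs$lapse
  else stats::runif(1L) < obs$guess_4afc
}

#' Expand a trial event into a synthetic 1 kHz gaze trace
#'
#' Emulates the eye-tracker stream: Gaussian fixational jitter well inside
#' the 1-degree window, then -- if the event contains an exit -- a
#' constant-velocity excursion along the event's direction starting at its
#' exit time, so that the first boundary-crossing sample lands at
#' (approximately) `exit_time_ms`. A blink becomes a 100 ms run of invalid
#' samples starting mid-window.
#'
#' @param event An event list from [simulate_trial_outcome()].
#' @param geom A [screen_geometry()].
#' @param duration_ms Trace length from stimulus onset (default 1000).
#' @param eccentricity_deg Saccade target distance, degrees (sets the
#'   excursion amplitude).
#' @param jitter_sd_deg SD of fixational jitter in degrees (kept small so
#'   jitter alone never leaves the window).
#' @return A [gaze_trace()] sampled at 1 kHz.
#' @export
generate_gaze_trace <- function(event, geom, duration_ms = 1000,
                                eccentricity_deg = 6.5,
                                jitter_sd_deg = 0.15) {
  stopifnot(inherits(geom, "screen_geometry"))
  n <- as.integer(duration_ms)
  t_ms <- seq_len(n) - 1L
  ppd <- geom$pixels_per_degree
  jit <- matrix(stats::rnorm(2L * n, 0, jitter_sd_deg * ppd), ncol = 2L)
  # clamp jitter to 0.8 deg so fixational noise never crosses the window
  r <- sqrt(rowSums(jit^2)); lim <- 0.8 * ppd
  over <- r > lim
  jit[over, ] <- jit[over, ] * lim / r[over]
  x <- geom$center_x + jit[, 1L]
  y <- geom$center_y + jit[, 2L]
  valid <- rep(TRUE, n)
  if (isTRUE(event$exited) && event$exit_time_ms < duration_ms) {
    t0 <- event$exit_time_ms
    ang <- event$exit_direction_deg * pi / 180
    # 40 ms saccade from centre to the target eccentricity
    prog <- pmin(pmax((t_ms - t0) / 40, 0), 1)
    amp <- prog * max(eccentricity_deg, 1.3) * ppd
    moving <- amp > 0
    x[moving] <- geom$center_x + amp[moving] * cos(ang)
    y[moving] <- geom$center_y + amp[moving] * sin(ang)
  }
  if (isTRUE(event$blink)) {
    b0 <- min(50L, n - 1L)
    valid[seq(b0, min(b0 + 99L, n))] <- FALSE
  }
  gaze_trace(t_ms, x, y, valid)
}
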