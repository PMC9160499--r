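# Live gaze-stream analysis: fixation-window enforcement, first-exit
# detection, saccade direction via atan2 in the screen-pixel frame, and
# scoring against a +/-22.5 degree acceptance cone around the target
# meridian. Both the computed direction and the target meridian live in the
# same screen frame (y increasing downward), so the axis convention cancels
# in the cone test; visual-field labels (nasal/temporal/...) are applied
# only at reporting time.

#' Screen geometry for gaze analysis
#'
#' @param center_x,center_y Screen centre, pixels.
#' @param pixels_per_degree Conversion factor from degrees of visual angle
#'   to pixels (must be positive). The default 52.4 corresponds to a typical
#'   1920-px-wide display viewed at 62 cm.
#' @return An object of class `screen_geometry`.
#' @export
screen_geometry <- function(center_x = 960, center_y = 540,
                            pixels_per_degree = 52.4) {
  if (pixels_per_degree <= 0)
    stop("`pixels_per_degree` must be positive", call. = FALSE)
  structure(list(center_x = center_x, center_y = center_y,
                 pixels_per_degree = pixels_per_degree,
                 y_axis_downward = TRUE),
            class = "screen_geometry")
}

#' Construct a gaze trace
#'
#' @param t_ms Sample times in ms from trial onset, non-decreasing.
#' @param x_px,y_px Gaze position in screen pixels.
#' @param valid Logical; `FALSE` marks blink/track-loss samples.
#' @return A data.frame of class `gaze_trace` with columns
#'   `t_ms, x_px, y_px, valid`.
#' @export
gaze_trace <- function(t_ms, x_px, y_px, valid = TRUE) {
  n <- length(t_ms)
  x_px <- rep_len(x_px, n)
  y_px <- rep_len(y_px, n)
  valid <- rep_len(as.logical(valid), n)
  if (n > 0L && is.unsorted(t_ms)) stop("`t_ms` must be non-decreasing",
                                        call. = FALSE)
  structure(data.frame(t_ms = t_ms, x_px = x_px, y_px = y_px, valid = valid),
            class = c("gaze_trace", "data.frame"))
}

#' Saccade direction from a gaze sample
#'
#' \eqn{\beta_g = \mathrm{atan2}(y_{eye} - y_{center}, x_{eye} - x_{center})},
#' mapped to degrees in `[0, 360)` in the screen-pixel frame. With y growing
#' downward, 90 degrees points toward the bottom of the screen.
#'
#' @param x_px,y_px Gaze position in pixels.
#' @param geom A [screen_geometry()].
#' @return Angle(s) in degrees, `[0, 360)`.
#' @export
saccade_direction <- function(x_px, y_px, geom) {
  stopifnot(inherits(geom, "screen_geometry"))
  dx <- x_px - geom$center_x
  dy <- y_px - geom$center_y
  if (any(dx == 0 & dy == 0))
    stop("gaze sample at the exact screen centre: direction undefined",
         call. = FALSE)
  (atan2(dy, dx) * 180 / pi) %% 360
}

#' Circular distance between two angles
#'
#' @param a,b Angles in degrees.
#' @return Absolute circular distance in degrees, `[0, 180]`.
#' @export
angular_distance <- function(a, b) {
  abs(((a - b + 180) %% 360) - 180)
}

#' Acceptance-cone test for a saccade direction
#'
#' A saccade is scored correct when the circular distance between its
#' direction and the target meridian is at most `cone_halfwidth`
#' (boundary inclusive).
#'
#' @param beta_g Saccade direction(s), degrees.
#' @param target_meridian Target meridian(s), degrees.
#' @param cone_halfwidth Half-width of the acceptance cone (default 22.5).
#' @return Logical vector.
#' @export
classify_saccade <- function(beta_g, target_meridian, cone_halfwidth = 22.5) {
  stopifnot(all(is.finite(beta_g)), all(is.finite(target_meridian)))
  angular_distance(beta_g, target_meridian) <= cone_halfwidth
}

#' Monitor fixation within a circular window
#'
#' Scans a trace in time order. The first invalid sample yields a `"blink"`
#' event; otherwise, the first valid sample whose distance from the screen
#' centre *strictly exceeds* `radius_deg` yields an `"exit"` event; if
#' neither occurs the fixation was `"held"`.
#'
#' @param trace A [gaze_trace()] (non-empty).
#' @param geom A [screen_geometry()].
#' @param radius_deg Fixation-window radius in degrees (default 1.0).
#' @return A list with `event` (`"held"`, `"exit"`, `"blink"`), and for
#'   non-held events `index`, `t_ms`, `x_px`, `y_px`.
#' @export
monitor_fixation <- function(trace, geom, radius_deg = 1.0) {
  stopifnot(inherits(geom, "screen_geometry"))
  if (nrow(trace) == 0L) stop("empty gaze trace", call. = FALSE)
  r_px <- radius_deg * geom$pixels_per_degree
  d <- sqrt((trace$x_px - geom$center_x)^2 + (trace$y_px - geom$center_y)^2)
  blink_i <- which(!trace$valid)
  exit_i <- which(trace$valid & d > r_px)
  first_blink <- if (length(blink_i)) blink_i[1L] else Inf
  first_exit <- if (length(exit_i)) exit_i[1L] else Inf
  if (is.infinite(first_blink) && is.infinite(first_exit))
    return(list(event = "held"))
  i <- if (first_blink < first_exit) first_blink else first_exit
  list(event = if (first_blink < first_exit) "blink" else "exit",
       index = i, t_ms = trace$t_ms[i],
       x_px = trace$x_px[i], y_px = trace$y_px[i])
}

#' Score one trial from its gaze trace
#'
#' Applies first-exit semantics within the response window: the trial is
#' scored from the first fixation-boundary crossing at or before
#' `window_ms`; later samples are ignored. A blink inside the window
#' produces a `"repeat"` status. Catch trials (no target) with an exit are
#' flagged as false positives and never feed the adaptive procedure.
#'
#' @param trace A [gaze_trace()] covering the trial from stimulus onset.
#' @param target_meridian Meridian of the target in degrees, or `NA` for a
#'   catch trial.
#' @param geom A [screen_geometry()].
#' @param window_ms Response window from stimulus onset: the 500 ms
#'   presentation limit plus a post-stimulus grace period (default
#'   500 + 500 = 1000 ms) during which a launched saccade still counts.
#' @param radius_deg Fixation-window radius in degrees.
#' @param cone_halfwidth Acceptance-cone half-width in degrees.
#' @return A list of class `saccade_verdict` with fields `exited`, `beta_g`,
#'   `angular_error`, `correct`, `exit_time_ms`, `false_positive`, `status`
#'   (`"done"` or `"repeat"`).
#' @export
score_trial <- function(trace, target_meridian, geom,
                        window_ms = 1000, radius_deg = 1.0,
                        cone_halfwidth = 22.5) {
  win <- trace[trace$t_ms <= window_ms, , drop = FALSE]
  verdict <- list(exited = FALSE, beta_g = NA_real_,
                  angular_error = NA_real_, correct = FALSE,
                  exit_time_ms = NA_real_, false_positive = FALSE,
                  status = "done")
  if (nrow(win) == 0L) {
    class(verdict) <- "saccade_verdict"
    return(verdict)
  }
  ev <- monitor_fixation(win, geom, radius_deg)
  if (ev$event == "blink") {
    verdict$status <- "repeat"
  } else if (ev$event == "exit") {
    verdict$exited <- TRUE
    verdict$exit_time_ms <- ev$t_ms
    verdict$beta_g <- saccade_direction(ev$x_px, ev$y_px, geom)
    if (is.na(target_meridian)) {
      verdict$false_positive <- TRUE
    } else {
      verdict$angular_error <- angular_distance(verdict$beta_g,
                                                target_meridian)
      verdict$correct <- verdict$angular_error <= cone_halfwidth
    }
  }
  class(verdict) <- "saccade_verdict"
  verdict
}

#' @export
print.saccade_verdict <- function(x, ...) {
  if (x$status == "repeat") {
    cat("Saccade verdict: blink detected -> repeat trial\n")
  } else if (!x$exited) {
    cat("Saccade verdict: fixation held (no saccade)\n")
  } else {
    cat(sprintf(
      "Saccade verdict: exit at %.0f ms, direction %.1f deg%s\n",
      x$exit_time_ms, x$beta_g,
      if (x$false_positive) " (catch trial: false positive)"
      else sprintf(", error %.1f deg -> %s", x$angular_error,
                   if (x$correct) "correct" else "incorrect")))
  }
  invisible(x)
}

#' Visual-field labels for screen meridians
#'
#' Reporting-only mapping from screen-frame meridians to visual-field
#' directions for a tested right eye with the screen y-axis pointing down:
#' 0 = temporal, 90 = inferior, 180 = nasal, 270 = superior.
#'
#' @param meridian_deg Meridian(s) in degrees; one of 0, 90, 180, 270.
#' @return Character vector of labels.
#' @export
meridian_label <- function(meridian_deg) {
  map <- c(`0` = "temporal", `90` = "inferior",
           `180` = "nasal", `270` = "superior")
  lab <- map[as.character(meridian_deg)]
  if (any(is.na(lab)))
    stop("meridian must be one of 0, 90, 180, 270", call. = FALSE)
  unname(lab)
}

#' Read / write gaze traces as CSV
#'
#' Long-format CSV with header `t_ms,x_px,y_px,valid` (plus `trial_id` when
#' several trials share a file). A comment header line carries the format
#' version.
#'
#' @param trace A [gaze_trace()].
#' @param path File path.
#' @return `write_gaze_csv` invisibly returns `path`; `read_gaze_csv`
#'   returns a `gaze_trace` (or a list of them keyed by `trial_id`).
#' @export
write_gaze_csv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# saccadecs gaze trace, format %s",
                     saccadecs_format_version()), con)
  utils::write.csv(as.data.frame(trace), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gaze_csv
#' @export
read_gaze_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("t_ms", "x_px", "y_px", "valid")
  if (!all(need %in% names(df)))
    stop("gaze CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if ("trial_id" %in% names(df)) {
    lapply(split(df, df$trial_id), function(g)
      gaze_trace(g$t_ms, g$x_px, g$y_px, as.logical(g$valid)))
  } else {
    gaze_trace(df$t_ms, df$x_px, df$y_px, as.logical(df$valid))
  }
}
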