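# Balanced randomized trial schedules for both measurement modes. Each
# eccentricity/spatial-frequency condition receives 120 target
# presentations with exactly 30 per meridian and 30 per orientation
# (marginal balance; joint 4x4 cell counts are free since 120/16 is not an
# integer). Saccadic-mode schedules hide 12 catch trials (no target) among
# the targets at uniformly random positions, giving 132 trials in total.

SF_SETS <- list(`2`    = c(0.8, 1.4, 2.2, 4.3, 7.2, 10.7),
                `6.5`  = c(0.8, 1.4, 2.2, 4.3, 7.2),
                `11`   = c(0.8, 1.4, 2.2, 4.3))

MERIDIANS <- c(0, 90, 180, 270)
ORIENTATIONS <- c(45, 90, 135, 180)

#' Spatial frequencies tested at an eccentricity level
#'
#' 0.8, 1.4, 2.2 and 4.3 cpd at every level, plus 7.2 cpd at the macular
#' level (6.5 deg) and 7.2 + 10.7 cpd at the central level (2 deg), where
#' high spatial frequencies remain detectable.
#'
#' @param eccentricity_deg One of 2.0, 6.5, 11.0.
#' @return Numeric vector of spatial frequencies in cycles per degree.
#' @export
spatial_frequency_set <- function(eccentricity_deg) {
  key <- as.character(eccentricity_deg)
  if (!key %in% names(SF_SETS))
    stop("eccentricity must be one of 2, 6.5, 11 (degrees)", call. = FALSE)
  SF_SETS[[key]]
}

#' Test-condition specification
#'
#' @param eccentricity_deg Target displacement from screen centre in degrees
#'   of visual angle: 2.0, 6.5 or 11.0.
#' @param spatial_freq_cpd Gabor spatial frequency; must belong to the
#'   eccentricity's set ([spatial_frequency_set()]).
#' @param mode `"saccadic"` (saccade-driven, with catch trials and a
#'   secondary keyboard response) or `"non-saccadic"` (keyboard 4AFC only).
#' @param stimulus_diameter_deg Gabor diameter (1.4 deg).
#' @param presentation_ms Stimulus presentation limit (500 ms).
#' @param fixation_ms_range Range the pre-stimulus fixation duration is
#'   drawn from, ms (500--650).
#' @return An object of class `condition_spec`.
#' @export
condition_spec <- function(eccentricity_deg, spatial_freq_cpd,
                           mode = c("saccadic", "non-saccadic"),
                           stimulus_diameter_deg = 1.4,
                           presentation_ms = 500,
                           fixation_ms_range = c(500, 650)) {
  mode <- match.arg(mode)
  sfs <- spatial_frequency_set(eccentricity_deg)
  if (!isTRUE(any(abs(spatial_freq_cpd - sfs) < 1e-9)))
    stop("spatial frequency ", spatial_freq_cpd,
         " not tested at eccentricity ", eccentricity_deg,
         " (allowed: ", paste(sfs, collapse = ", "), ")", call. = FALSE)
  structure(list(eccentricity_deg = eccentricity_deg,
                 spatial_freq_cpd = spatial_freq_cpd, mode = mode,
                 stimulus_diameter_deg = stimulus_diameter_deg,
                 presentation_ms = presentation_ms,
                 fixation_ms_range = fixation_ms_range),
            class = "condition_spec")
}

# Run `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Random 4x4 meridian x orientation table with all margins equal to 30:
# near-uniform base of 7 per cell plus two independent random permutation
# matrices (each adds exactly 1 to every row and column margin).
balanced_design_table <- function() {
  tab <- matrix(7L, 4L, 4L)
  for (k in 1:2) {
    perm <- sample.int(4L)
    tab[cbind(1:4, perm)] <- tab[cbind(1:4, perm)] + 1L
  }
  tab
}

#' Build a randomized, balanced trial schedule
#'
#' Generates the 120 target trials of one condition with exact marginal
#' balance (30 per meridian, 30 per orientation), fully shuffled. In
#' saccadic mode, 12 catch trials with no target are interleaved at
#' uniformly random positions, for 132 trials.
#'
#' @param cond A [condition_spec()].
#' @param seed Integer seed; the same seed reproduces the schedule exactly.
#' @return A data.frame of class `trial_schedule` with columns `trial_id`,
#'   `meridian_deg`, `orientation_deg`, `is_catch`, `status`, carrying the
#'   condition and seed as attributes.
#' @export
build_schedule <- function(cond, seed) {
  stopifnot(inherits(cond, "condition_spec"))
  with_seed(seed, {
    tab <- balanced_design_table()
    targets <- do.call(rbind, lapply(1:4, function(i)
      do.call(rbind, lapply(1:4, function(j)
        if (tab[i, j] > 0L)
          data.frame(meridian_deg = rep(MERIDIANS[i], tab[i, j]),
                     orientation_deg = rep(ORIENTATIONS[j], tab[i, j]))
        else NULL))))
    targets <- targets[sample.int(nrow(targets)), , drop = FALSE]
    targets$is_catch <- FALSE
    if (cond$mode == "saccadic") {
      n_total <- nrow(targets) + 12L
      catch_pos <- sort(sample.int(n_total, 12L))
      sched <- data.frame(meridian_deg = rep(NA_real_, n_total),
                          orientation_deg = NA_real_, is_catch = TRUE)
      sched[-catch_pos, ] <- targets
    } else {
      sched <- targets
    }
    sched <- cbind(trial_id = seq_len(nrow(sched)), sched)
    sched$status <- "pending"
    rownames(sched) <- NULL
    structure(sched, class = c("trial_schedule", "data.frame"),
              condition = cond, seed = seed)
  })
}

#' Study manifest for a full simulated cohort
#'
#' One session per participant x eccentricity/spatial-frequency combination
#' x measurement mode (15 conditions per mode per participant across the
#' three eccentricity levels). Per-session seeds are derived
#' deterministically from the master seed.
#'
#' @param n_participants Number of simulated participants (default 12).
#' @param seed Master integer seed.
#' @return A data.frame with one row per session: `participant`,
#'   `eccentricity_deg`, `spatial_freq_cpd`, `mode`, `session_seed`.
#' @export
build_study <- function(n_participants = 12, seed = 1) {
  conds <- do.call(rbind, lapply(names(SF_SETS), function(e)
    data.frame(eccentricity_deg = as.numeric(e),
               spatial_freq_cpd = SF_SETS[[e]])))
  grid <- expand.grid(participant = seq_len(n_participants),
                      cond_row = seq_len(nrow(conds)),
                      mode = c("saccadic", "non-saccadic"),
                      stringsAsFactors = FALSE)
  manifest <- cbind(participant = grid$participant,
                    conds[grid$cond_row, , drop = FALSE],
                    mode = grid$mode)
  rownames(manifest) <- NULL
  manifest$session_seed <- with_seed(seed,
    sample.int(.Machine$integer.max, nrow(manifest)))
  attr(manifest, "master_seed") <- seed
  manifest
}
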