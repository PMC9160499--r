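# QUEST+ adaptive Bayesian procedure over a (threshold x slope) grid with
# expected-entropy-minimising contrast placement. One independent instance
# is run per visual-field direction; asymptotes are fixed, never estimated.

#' Default 15-level contrast grid
#'
#' Fifteen contrast levels geometrically spaced (uniform in log contrast)
#' from 0.024\% to 66\% Michelson contrast. These serve both as the
#' threshold parameter space and as the testable stimulus domain.
#'
#' @return Numeric vector of 15 contrasts (proportions), increasing.
#' @export
default_contrast_levels <- function() {
  exp(seq(log(0.00024), log(0.66), length.out = 15L))
}

#' Default slope grid
#'
#' Slopes 0.5 to 5.5 in steps of 0.5.
#'
#' @return Numeric vector of 11 slopes, increasing.
#' @export
default_slope_levels <- function() {
  seq(0.5, 5.5, by = 0.5)
}

#' Parameter grid for the adaptive procedure
#'
#' Discretised (threshold, slope) space with fixed asymptotes. Thresholds
#' are natural-log contrasts; slopes are converted to widths internally via
#' `w = c / s` ([slope_to_width()]).
#'
#' @param thresholds Strictly increasing log-contrast values. Default: logs
#'   of [default_contrast_levels()].
#' @param slopes Strictly increasing slope values. Default:
#'   [default_slope_levels()].
#' @param gamma Fixed guess rate: 0 for saccade (yes/no) scoring, 0.25 for
#'   the 4AFC keyboard task.
#' @param lam Fixed lapse rate (default 0.02).
#' @return An object of class `parameter_grid`.
#' @export
parameter_grid <- function(thresholds = log(default_contrast_levels()),
                           slopes = default_slope_levels(),
                           gamma = 0, lam = 0.02) {
  stopifnot(length(thresholds) >= 1L, length(slopes) >= 1L)
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("`thresholds` must be strictly increasing", call. = FALSE)
  if (is.unsorted(slopes, strictly = TRUE))
    stop("`slopes` must be strictly increasing", call. = FALSE)
  if (gamma < 0 || gamma >= 1 - lam || lam < 0 || lam >= 1)
    stop("invalid fixed asymptotes", call. = FALSE)
  structure(list(thresholds = as.numeric(thresholds),
                 slopes = as.numeric(slopes),
                 gamma = gamma, lam = lam),
            class = "parameter_grid")
}

#' Likelihood of one outcome for every grid cell
#'
#' Evaluates \eqn{\Psi(x; m, c/s, \gamma, \lambda)} for a single stimulus
#' against all (threshold, slope) cells; for an incorrect outcome, returns
#' \eqn{1 - \Psi}.
#'
#' @param grid A [parameter_grid()].
#' @param stimulus One contrast (proportion).
#' @param correct Logical: was the response scored correct/detected?
#' @return Matrix (thresholds x slopes) of outcome probabilities.
#' @export
outcome_likelihood <- function(grid, stimulus, correct = TRUE) {
  stopifnot(inherits(grid, "parameter_grid"), length(stimulus) == 1L)
  assert_contrast(stimulus)
  cc <- weibull_c_constant()
  # widths per slope: w = c/s, so c/w = s and the exponent is s*(log x - m)
  expo <- outer(log(stimulus) - grid$thresholds, grid$slopes)
  psi <- grid$gamma + (1 - grid$lam - grid$gamma) *
    (1 - exp(log(0.5) * exp(expo)))
  if (correct) psi else 1 - psi
}

#' Initialise one QUEST+ instance
#'
#' @param grid A [parameter_grid()].
#' @param prior Optional prior mass, a matrix shaped thresholds x slopes
#'   (renormalised); default uniform.
#' @param stimulus_domain Candidate contrasts the procedure may present.
#'   Default: `exp(grid$thresholds)`, i.e. the 15 grid contrasts.
#' @param location_label Optional tag for the visual-field direction this
#'   instance controls.
#' @return An object of class `quest_state`.
#' @export
quest_init <- function(grid = parameter_grid(), prior = NULL,
                       stimulus_domain = exp(grid$thresholds),
                       location_label = NA_character_) {
  stopifnot(inherits(grid, "parameter_grid"))
  assert_contrast(stimulus_domain)
  nt <- length(grid$thresholds); ns <- length(grid$slopes)
  if (is.null(prior)) {
    posterior <- matrix(1 / (nt * ns), nt, ns)
  } else {
    prior <- as.matrix(prior)
    if (!all(dim(prior) == c(nt, ns)))
      stop("`prior` must be a ", nt, " x ", ns, " matrix", call. = FALSE)
    if (any(!is.finite(prior)) || any(prior < 0) || sum(prior) <= 0)
      stop("`prior` must be non-negative with positive total mass",
           call. = FALSE)
    posterior <- prior / sum(prior)
  }
  # precompute correct-outcome likelihoods for every candidate stimulus
  lik <- lapply(stimulus_domain, function(x)
    outcome_likelihood(grid, x, correct = TRUE))
  structure(list(grid = grid, posterior = posterior,
                 stimulus_domain = as.numeric(stimulus_domain),
                 lik_correct = lik, trial_count = 0L,
                 location_label = location_label),
            class = "quest_state")
}

#' @export
print.quest_state <- function(x, ...) {
  cat(sprintf(
    "QUEST+ state%s: %d x %d grid, %d trials, threshold estimate m = %.3f\n",
    if (is.na(x$location_label)) "" else paste0(" [", x$location_label, "]"),
    length(x$grid$thresholds), length(x$grid$slopes), x$trial_count,
    quest_estimate(x)))
  invisible(x)
}

#' Bayesian update after one trial
#'
#' Multiplies the posterior by the outcome likelihood of the observed
#' response and renormalises.
#'
#' @param state A `quest_state`.
#' @param stimulus The presented contrast (proportion).
#' @param correct Logical response outcome.
#' @return The updated `quest_state`.
#' @export
quest_update <- function(state, stimulus, correct) {
  stopifnot(inherits(state, "quest_state"), is.logical(correct),
            length(correct) == 1L, !is.na(correct))
  lik <- outcome_likelihood(state$grid, stimulus, correct = correct)
  unnorm <- state$posterior * lik
  z <- sum(unnorm)
  if (!is.finite(z) || z <= 0)
    stop("posterior degenerated to zero mass; outcome impossible under grid",
         call. = FALSE)
  state$posterior <- unnorm / z
  state$trial_count <- state$trial_count + 1L
  state
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Select the next stimulus by expected-entropy minimisation
#'
#' For each candidate contrast, computes the expected Shannon entropy of the
#' posterior after observing the trial, with the outcome probability
#' marginalised over the current posterior, and returns the candidate with
#' the smallest expected entropy. Ties are broken deterministically by the
#' lowest contrast.
#'
#' @param state A `quest_state`.
#' @param details If `TRUE`, return a list with the chosen contrast, its
#'   index and the expected-entropy vector.
#' @return The chosen contrast (or a list when `details = TRUE`).
#' @export
quest_next_stimulus <- function(state, details = FALSE) {
  stopifnot(inherits(state, "quest_state"))
  if (length(state$stimulus_domain) == 0L)
    stop("empty stimulus domain", call. = FALSE)
  post <- state$posterior
  eh <- vapply(state$lik_correct, function(lik) {
    pc_cells <- post * lik             # joint mass of (cell, correct)
    pc <- sum(pc_cells)                # marginal P(correct)
    pi_cells <- post - pc_cells        # joint mass of (cell, incorrect)
    pi <- 1 - pc
    h <- 0
    if (pc > 0) h <- h + pc * shannon_entropy(pc_cells / pc)
    if (pi > 0) h <- h + pi * shannon_entropy(pi_cells / pi)
    h
  }, numeric(1))
  idx <- which.min(eh)  # which.min takes the first minimum: lowest contrast
  if (details) list(contrast = state$stimulus_domain[idx], index = idx,
                    expected_entropy = eh)
  else state$stimulus_domain[idx]
}

#' Running threshold estimate
#'
#' Posterior mean of the threshold marginal, in natural-log contrast units.
#' The final published estimate comes from the offline psychometric fit
#' ([fit_psychometric()]); this running estimate exists for monitoring and
#' audit.
#'
#' @param state A `quest_state`.
#' @return Posterior-mean threshold `m`.
#' @export
quest_estimate <- function(state) {
  stopifnot(inherits(state, "quest_state"))
  marg <- rowSums(state$posterior)
  sum(marg * state$grid$thresholds)
}

#' Posterior-mode grid cell
#'
#' @param state A `quest_state`.
#' @return List with `threshold_index`, `slope_index`, `m`, `slope` of the
#'   cell carrying maximal posterior mass (first maximum on ties).
#' @export
quest_mode <- function(state) {
  stopifnot(inherits(state, "quest_state"))
  ij <- arrayInd(which.max(state$posterior), dim(state$posterior))
  list(threshold_index = ij[1L], slope_index = ij[2L],
       m = state$grid$thresholds[ij[1L]], slope = state$grid$slopes[ij[2L]])
}

#' Serialise / deserialise a QUEST+ state as JSON
#'
#' The posterior is written as a flat row-major list alongside the grids and
#' trial count, enabling session resume and audit.
#'
#' @param state A `quest_state`.
#' @param path File path; for `quest_from_json`, a path written by
#'   `quest_to_json`.
#' @return `quest_to_json` invisibly returns `path`; `quest_from_json`
#'   returns a reconstructed `quest_state`.
#' @export
quest_to_json <- function(state, path) {
  stopifnot(inherits(state, "quest_state"))
  obj <- list(
    format = saccadecs_format_version(),
    thresholds = state$grid$thresholds,
    slopes = state$grid$slopes,
    gamma = state$grid$gamma,
    lam = state$grid$lam,
    stimulus_domain = state$stimulus_domain,
    posterior_row_major = as.numeric(t(state$posterior)),
    trial_count = state$trial_count,
    location_label = state$location_label)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname quest_to_json
#' @export
quest_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- parameter_grid(obj$thresholds, obj$slopes, obj$gamma, obj$lam)
  nt <- length(grid$thresholds); ns <- length(grid$slopes)
  post <- matrix(obj$posterior_row_major, nt, ns, byrow = TRUE)
  st <- quest_init(grid, prior = post, stimulus_domain = obj$stimulus_domain,
                   location_label = obj$location_label %||% NA_character_)
  st$trial_count <- as.integer(obj$trial_count)
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a
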