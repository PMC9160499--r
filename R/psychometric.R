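# Cumulative-Weibull psychometric function in log-contrast space and the
# threshold -> contrast-sensitivity conversion chain used by every other
# module. Contrast is carried everywhere as a linear proportion in (0, 1];
# percent appears only at I/O boundaries. All internal logs are natural;
# only the final sensitivity report uses log10.

#' Width-normalisation constant of the cumulative Weibull
#'
#' The constant \eqn{c = \log(-\log 0.05) - \log(-\log 0.95)} (natural logs)
#' that ties the width parameter \eqn{w} -- the log-contrast span between the
#' 5\% and 95\% points of the guess- and lapse-free curve -- to the exponent
#' of the Weibull. Numerically \eqn{c \approx 4.067}.
#'
#' @return A single positive number.
#' @export
#' @examples
#' weibull_c_constant()
weibull_c_constant <- function() {
  log(-log(0.05)) - log(-log(0.95))
}

#' Psychometric function parameters
#'
#' Bundle of the four cumulative-Weibull parameters: threshold `m` and width
#' `w` in natural-log contrast units, guess rate `gamma` (lower asymptote)
#' and lapse rate `lam` (upper-asymptote deficit).
#'
#' @param m Threshold, the log contrast at which the base (`gamma = lam = 0`)
#'   curve crosses 0.5.
#' @param w Width, the log-contrast span between the 5% and 95% points of the
#'   base curve; must be positive.
#' @param gamma Guess rate in `[0, 1 - lam)`; 0.25 for a 4AFC task, 0 for
#'   yes/no saccade scoring.
#' @param lam Lapse rate in `[0, 1)`.
#' @return An object of class `psychometric_params`.
#' @export
psychometric_params <- function(m, w, gamma = 0, lam = 0) {
  stopifnot(is.numeric(m), length(m) == 1L, is.finite(m))
  if (!is.numeric(w) || length(w) != 1L || !is.finite(w) || w <= 0)
    stop("`w` must be a single positive number", call. = FALSE)
  if (lam < 0 || lam >= 1) stop("`lam` must be in [0, 1)", call. = FALSE)
  if (gamma < 0 || gamma >= 1 - lam)
    stop("`gamma` must be in [0, 1 - lam)", call. = FALSE)
  structure(list(m = m, w = w, gamma = gamma, lam = lam),
            class = "psychometric_params")
}

#' @export
print.psychometric_params <- function(x, ...) {
  cat(sprintf(
    "Weibull psychometric parameters\n  m = %.4f (CT = %.4g), w = %.4f, gamma = %.3f, lambda = %.3f\n",
    x$m, exp(x$m), x$w, x$gamma, x$lam))
  invisible(x)
}

assert_contrast <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop("contrast must be a positive finite proportion", call. = FALSE)
  if (any(x > 1))
    stop("contrast must not exceed 1 (use proportions, not percent)",
         call. = FALSE)
  invisible(x)
}

#' Evaluate the cumulative-Weibull psychometric function
#'
#' \deqn{\Psi(x) = \gamma + (1-\lambda-\gamma)\left[1 -
#'   e^{\log(0.5)\, e^{c(\log x - m)/w}}\right]}
#' with \eqn{c} from [weibull_c_constant()]. At \eqn{x = e^m} the bracketed
#' base curve equals exactly 0.5.
#'
#' @param x Contrast(s) as linear proportion(s) in (0, 1]. Vectorised.
#' @param p A [psychometric_params()] object.
#' @return Detection/correct-response probabilities in `[gamma, 1 - lam]`.
#' @export
weibull_prob <- function(x, p) {
  stopifnot(inherits(p, "psychometric_params"))
  assert_contrast(x)
  cc <- weibull_c_constant()
  base <- 1 - exp(log(0.5) * exp(cc * (log(x) - p$m) / p$w))
  p$gamma + (1 - p$lam - p$gamma) * base
}

#' Convert Weibull width to slope
#'
#' The slope `s` of the cumulative Weibull, as used by the adaptive procedure,
#' relates to the 5--95\% width `w` by `s = c / w`: a narrower (steeper)
#' curve has a larger slope.
#'
#' @param w Positive width(s) in log-contrast units.
#' @return Slope(s) `c / w`.
#' @seealso [slope_to_width()]
#' @export
width_to_slope <- function(w) {
  if (any(!is.finite(w)) || any(w <= 0))
    stop("`w` must be positive", call. = FALSE)
  weibull_c_constant() / w
}

#' Convert Weibull slope to width
#'
#' Inverse of [width_to_slope()]: `w = c / s`.
#'
#' @param s Positive slope(s).
#' @return Width(s) in log-contrast units.
#' @export
slope_to_width <- function(s) {
  if (any(!is.finite(s)) || any(s <= 0))
    stop("`s` must be positive", call. = FALSE)
  weibull_c_constant() / s
}

#' Contrast threshold to contrast sensitivity
#'
#' Converts a fitted threshold `m` (natural-log contrast) to the contrast
#' threshold `CT = exp(m)`, linear sensitivity `CS = 1/CT` and `log10(CS)`.
#' Thresholds above full contrast (`CT > 1`, sensitivity below 1) are
#' computed with a warning, since they signal an extrapolated fit.
#'
#' @param m Threshold(s) in natural-log contrast units.
#' @return A data.frame with columns `m`, `ct`, `cs`, `log_cs`.
#' @export
#' @examples
#' threshold_to_cs(log(0.01))  # CT 1%, CS 100, logCS 2
threshold_to_cs <- function(m) {
  stopifnot(is.numeric(m), all(is.finite(m)))
  ct <- exp(m)
  if (any(ct > 1))
    warning("threshold exceeds full contrast (CT > 1); sensitivity below 1",
            call. = FALSE)
  data.frame(m = m, ct = ct, cs = 1 / ct, log_cs = -m / log(10))
}

#' Contrast sensitivity back to log-contrast threshold
#'
#' Inverse of [threshold_to_cs()]: `m = -log(10) * log10(cs) = log(1/cs)`.
#'
#' @param cs Linear contrast sensitivity value(s), positive.
#' @return Threshold(s) `m` in natural-log contrast units.
#' @export
cs_to_threshold <- function(cs) {
  if (any(!is.finite(cs)) || any(cs <= 0))
    stop("`cs` must be positive", call. = FALSE)
  -log(cs)
}
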