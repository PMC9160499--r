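# Offline analysis chain: per-contrast response rates -> maximum-likelihood
# cumulative-Weibull fit (threshold m, width w, lapse; guess rate fixed by
# response mode) -> contrast threshold/sensitivity -> log-parabola CSF fit
# across spatial frequencies, per subject and as cross-subject means.

#' Tabulate response rates per contrast level
#'
#' Collapses a session log into a rate table (`contrast`, `n`, `k`) for one
#' meridian and one response channel.
#'
#' @param log Session-log data.frame from [run_session()].
#' @param meridian_deg Meridian to tabulate.
#' @param channel `"saccade"` or `"keyboard"`.
#' @return A data.frame with columns `contrast`, `n`, `k`, sorted by
#'   contrast.
#' @export
rate_table <- function(log, meridian_deg,
                       channel = c("saccade", "keyboard")) {
  channel <- match.arg(channel)
  col <- if (channel == "saccade") "saccade_correct" else "keyboard_correct"
  sel <- log$status == "done" & !log$is_catch &
    log$meridian_deg == meridian_deg & !is.na(log[[col]])
  d <- log[sel, , drop = FALSE]
  if (nrow(d) == 0L)
    return(data.frame(contrast = numeric(0), n = integer(0), k = integer(0)))
  agg <- stats::aggregate(d[[col]], by = list(contrast = d$contrast),
                          FUN = function(v) c(n = length(v), k = sum(v)))
  out <- data.frame(contrast = agg$contrast,
                    n = as.integer(agg$x[, "n"]),
                    k = as.integer(agg$x[, "k"]))
  out[order(out$contrast), , drop = FALSE]
}

weibull_nll <- function(par, tab, gamma) {
  m <- par[1L]; w <- exp(par[2L]); lam <- par[3L]
  p <- psychometric_params(m, w, gamma = gamma, lam = lam)
  pr <- weibull_prob(tab$contrast, p)
  pr <- pmin(pmax(pr, 1e-10), 1 - 1e-10)
  -sum(tab$k * log(pr) + (tab$n - tab$k) * log(1 - pr))
}

#' Maximum-likelihood cumulative-Weibull fit of a rate table
#'
#' Fits threshold `m`, width `w` and lapse rate `lam` under a binomial
#' likelihood, with the guess rate fixed by the response mode (0 for
#' saccade-based yes/no scoring, 0.25 for the 4AFC keyboard task) and the
#' lapse bounded in `[0, 0.1]`. Optimisation is L-BFGS-B from a
#' deterministic multistart over a coarse (m, w) grid. Degenerate tables
#' (all correct or all incorrect) yield a boundary fit with a warning and
#' `m` clamped to the sampled contrast range.
#'
#' @param tab A rate table (`contrast`, `n`, `k`) as from [rate_table()].
#' @param mode `"saccade"` or `"keyboard"` (sets the fixed guess rate).
#' @param lapse_max Upper bound on the lapse rate (default 0.1).
#' @return A list of class `psychometric_fit`: `params`
#'   ([psychometric_params()]), `log_lik`, `converged`, `boundary`, `n_obs`.
#' @export
fit_psychometric <- function(tab, mode = c("saccade", "keyboard"),
                             lapse_max = 0.1) {
  mode <- match.arg(mode)
  gamma <- if (mode == "keyboard") 0.25 else 0
  tab <- tab[tab$n > 0, , drop = FALSE]
  # merge duplicate contrast rows so row splitting cannot change the fit
  if (anyDuplicated(tab$contrast)) {
    agg <- stats::aggregate(cbind(n, k) ~ contrast, data = tab, FUN = sum)
    tab <- agg[order(agg$contrast), , drop = FALSE]
  }
  if (nrow(tab) < 2L)
    stop("need data at >= 2 distinct contrast levels", call. = FALSE)
  lx <- log(tab$contrast)
  rate <- tab$k / tab$n
  boundary <- all(rate >= 1 - 1e-12) || all(rate <= gamma + 1e-12)
  starts <- expand.grid(
    m = stats::quantile(lx, c(0.15, 0.35, 0.5, 0.65, 0.85), names = FALSE),
    lw = log(slope_to_width(c(1, 2.5, 4))))
  lower <- c(min(lx) - 3, log(0.05), 0)
  upper <- c(max(lx) + 3, log(30), lapse_max)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(c(starts$m[i], starts$lw[i], 0.02), weibull_nll,
                   tab = tab, gamma = gamma, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("psychometric fit failed for all starts",
                          call. = FALSE)
  m_hat <- best$par[1L]
  if (boundary) {
    warning("degenerate rate table (all correct or all at chance); ",
            "threshold clamped to the sampled contrast range",
            call. = FALSE)
    m_hat <- min(max(m_hat, min(lx)), max(lx))
  }
  structure(list(
    params = psychometric_params(m_hat, exp(best$par[2L]), gamma = gamma,
                                 lam = best$par[3L]),
    log_lik = -best$value,
    converged = best$convergence == 0,
    boundary = boundary,
    n_obs = sum(tab$n)), class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "Weibull ML fit (%d obs%s): m = %.3f (logCS %.3f), w = %.3f, lambda = %.3f, logLik %.2f\n",
    x$n_obs, if (x$boundary) ", boundary" else "", x$params$m,
    -x$params$m / log(10), x$params$w, x$params$lam, x$log_lik))
  invisible(x)
}

#' Log-parabola CSF parameters
#'
#' @param gamma_max Peak linear contrast sensitivity (> 0).
#' @param sf_max Peak spatial frequency, cycles per degree (> 0).
#' @param beta Bandwidth: full width of the parabola at half of the peak
#'   sensitivity (a log10(2) drop), in log10-cpd units (> 0).
#' @return An object of class `csf_params`.
#' @export
csf_params <- function(gamma_max, sf_max, beta) {
  if (gamma_max <= 0 || sf_max <= 0 || beta <= 0)
    stop("all log-parabola parameters must be positive", call. = FALSE)
  structure(list(gamma_max = gamma_max, sf_max = sf_max, beta = beta),
            class = "csf_params")
}

#' @export
print.csf_params <- function(x, ...) {
  cat(sprintf(
    "Log-parabola CSF: peak sensitivity %.1f (log10 %.2f) at %.2f cpd, bandwidth %.2f\n",
    x$gamma_max, log10(x$gamma_max), x$sf_max, x$beta))
  invisible(x)
}

#' Evaluate the log-parabola CSF
#'
#' \deqn{CS(SF) = \log_{10}\gamma_{max} - \log_{10}(2)
#'   \left[\frac{\log_{10} SF - \log_{10} SF_{max}}{\beta/2}\right]^2}
#' Unbounded below; no low-frequency truncation is applied.
#'
#' @param sf Spatial frequency(-ies), cpd, positive.
#' @param p A [csf_params()].
#' @return log10 contrast sensitivity value(s).
#' @export
csf_value <- function(sf, p) {
  stopifnot(inherits(p, "csf_params"))
  if (any(sf <= 0)) stop("`sf` must be positive", call. = FALSE)
  log10(p$gamma_max) -
    log10(2) * ((log10(sf) - log10(p$sf_max)) / (p$beta / 2))^2
}

#' Least-squares log-parabola fit of sensitivity points
#'
#' Fits [csf_value()] to (spatial frequency, log10 CS) points by least
#' squares in log10-SF space. A quadratic regression provides the initial
#' parameters; a bounded L-BFGS-B refinement with a deterministic multistart
#' enforces `sf_max` within `[min(sf)/2, 2*max(sf)]`, `beta` in `(0, 4]`
#' and `gamma_max` in `[1, 1e4]`.
#'
#' @param sf Spatial frequencies, cpd (>= 3 distinct values).
#' @param log_cs Matching log10 sensitivity values.
#' @return A list of class `csf_fit`: `params` ([csf_params()]), `rss`,
#'   `n`, `boundary` (any parameter at a bound).
#' @export
fit_csf <- function(sf, log_cs) {
  keep <- is.finite(sf) & is.finite(log_cs)
  sf <- sf[keep]; log_cs <- log_cs[keep]
  if (length(unique(sf)) < 3L)
    stop("need >= 3 points with distinct spatial frequencies", call. = FALSE)
  u <- log10(sf)
  lower <- c(log10_gmax = 0, log10_sfmax = log10(min(sf) / 2), beta = 1e-3)
  upper <- c(4, log10(max(sf) * 2), 4)
  sse <- function(par) {
    p <- csf_params(10^par[1L], 10^par[2L], par[3L])
    sum((csf_value(sf, p) - log_cs)^2)
  }
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  starts <- list()
  q <- stats::lm(log_cs ~ u + I(u^2))
  co <- stats::coef(q)
  if (is.finite(co[3L]) && co[3L] < 0) {
    u0 <- -co[2L] / (2 * co[3L])                  # vertex of the parabola
    beta0 <- 2 * sqrt(log10(2) / -co[3L])         # half-height width
    g0 <- co[1L] + co[2L] * u0 + co[3L] * u0^2
    starts[[1L]] <- clamp(unname(c(g0, u0, beta0)), lower, upper)
  }
  for (b in c(1, 2.5)) for (s0 in range(u))
    starts[[length(starts) + 1L]] <-
      clamp(c(max(log_cs), s0, b), lower, upper)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, sse, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("CSF fit failed for all starts", call. = FALSE)
  at_bound <- any(abs(best$par - lower) < 1e-8) ||
    any(abs(best$par - upper) < 1e-8)
  if (stats::var(log_cs) < 1e-12)
    warning("degenerate (flat) sensitivity data; CSF fit is not unique",
            call. = FALSE)
  par <- unname(best$par)
  structure(list(
    params = csf_params(10^par[1L], 10^par[2L], par[3L]),
    rss = best$value, n = length(sf), boundary = at_bound),
    class = "csf_fit")
}

#' @export
print.csf_fit <- function(x, ...) {
  cat(sprintf("CSF fit over %d points (RSS %.4g%s):\n  ", x$n, x$rss,
              if (x$boundary) ", parameter at bound" else ""))
  print(x$params)
  invisible(x)
}

#' Mean CSF across subjects
#'
#' Averages log10 CS across subjects at each spatial frequency, then fits
#' the log-parabola to the means. Subjects missing a frequency are excluded
#' from that frequency's mean with a warning.
#'
#' @param df Data.frame with columns `subject`, `sf`, `log_cs` (one row per
#'   subject x frequency).
#' @return A `csf_fit` of the per-frequency means, with the mean table in
#'   `$means`.
#' @export
mean_csf <- function(df) {
  stopifnot(all(c("subject", "sf", "log_cs") %in% names(df)))
  n_subj <- length(unique(df$subject))
  counts <- table(df$sf)
  if (any(counts < n_subj))
    warning("missing subject cells at some spatial frequencies; ",
            "means use the subjects available", call. = FALSE)
  means <- stats::aggregate(log_cs ~ sf, data = df, FUN = mean)
  fit <- fit_csf(means$sf, means$log_cs)
  fit$means <- means
  fit
}
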