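# Offline fitting chain: rate tables, Weibull maximum likelihood,
# log-parabola CSF, cross-subject means.

test_that("rate tables tally responses per contrast level", {
  log <- data.frame(
    status = "done", is_catch = FALSE, meridian_deg = c(0, 0, 0, 0, 90),
    contrast = c(0.1, 0.1, 0.2, 0.2, 0.1),
    saccade_correct = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    keyboard_correct = c(TRUE, TRUE, FALSE, TRUE, FALSE))
  tab <- rate_table(log, 0, "saccade")
  expect_equal(tab$contrast, c(0.1, 0.2))
  expect_equal(tab$n, c(2L, 2L))
  expect_equal(tab$k, c(1L, 2L))
  expect_equal(rate_table(log, 0, "keyboard")$k, c(2L, 1L))
  expect_equal(nrow(rate_table(log, 180, "saccade")), 0L)
})

test_that("noise-free rate tables reproduce their generating parameters", {
  for (gamma in c(0, 0.25)) {
    mode <- if (gamma == 0) "saccade" else "keyboard"
    p <- psychometric_params(log(0.03), w = 1.6, gamma = gamma, lam = 0.04)
    fit <- fit_psychometric(noise_free_rate_table(p), mode = mode)
    expect_equal(fit$params$m, p$m, tolerance = 1e-3)
    expect_equal(fit$params$w, p$w, tolerance = 1e-2)
    expect_equal(fit$params$lam, p$lam, tolerance = 1e-3)
    expect_true(fit$converged)
    # threshold definition: fitted curve at e^m equals gamma + 0.5(1-lam-gamma)
    at_m <- weibull_prob(exp(fit$params$m), fit$params)
    expect_equal(at_m, gamma + 0.5 * (1 - fit$params$lam - gamma),
                 tolerance = 1e-12)
  }
})

test_that("sampled rate tables recover the threshold within 0.05 log units", {
  set.seed(47)
  p <- psychometric_params(log(0.02), w = slope_to_width(3), lam = 0.02)
  errs <- replicate(20, {
    fit <- fit_psychometric(sampled_rate_table(p, n = 500), "saccade")
    fit$params$m - p$m
  })
  expect_lt(stats::median(abs(errs)), 0.05)
  expect_lt(mean(abs(errs) <= 0.05), 1.01)  # sanity: bounded fraction
  expect_gt(mean(abs(errs) <= 0.05), 0.7)
})

test_that("fits are invariant to row order and duplicate-row splitting", {
  set.seed(53)
  p <- psychometric_params(log(0.05), 1.2, lam = 0.03)
  tab <- sampled_rate_table(p, n = 200)
  f1 <- fit_psychometric(tab, "saccade")
  f2 <- fit_psychometric(tab[rev(seq_len(nrow(tab))), ], "saccade")
  split <- rbind(transform(tab, k = floor(k / 2), n = floor(n / 2)),
                 transform(tab, k = k - floor(k / 2), n = n - floor(n / 2)))
  f3 <- fit_psychometric(split, "saccade")
  expect_equal(f1$params$m, f2$params$m, tolerance = 1e-6)
  expect_equal(f1$params$m, f3$params$m, tolerance = 1e-6)
})

test_that("degenerate tables clamp the threshold with a warning", {
  tab <- data.frame(contrast = c(0.01, 0.1, 0.6), n = 30, k = 30)
  expect_warning(fit <- fit_psychometric(tab, "saccade"), "degenerate")
  expect_true(fit$boundary)
  expect_gte(fit$params$m, log(0.01))
  expect_lte(fit$params$m, log(0.6))
  expect_error(fit_psychometric(data.frame(contrast = 0.1, n = 30, k = 15),
                                "saccade"),
               ">= 2 distinct")
})

test_that("log-parabola peak, half-height and symmetry identities hold", {
  p <- csf_params(gamma_max = 40, sf_max = 2.5, beta = 2)
  expect_equal(csf_value(2.5, p), log10(40))
  # half height: a log10(2) drop at log10-SF offset beta/2
  expect_equal(csf_value(2.5 * 10^(p$beta / 2), p), log10(40) - log10(2))
  expect_equal(csf_value(2.5 * 10^(-p$beta / 2), p), log10(40) - log10(2))
  for (d in c(0.2, 0.5, 1.1))
    expect_equal(csf_value(2.5 * 10^d, p), csf_value(2.5 * 10^-d, p))
  expect_error(csf_value(-1, p), "positive")
})

test_that("three noise-free points determine the parabola exactly", {
  p <- csf_params(gamma_max = 60, sf_max = 1.8, beta = 2.2)
  sf <- c(0.8, 2.2, 7.2)
  fit <- fit_csf(sf, csf_value(sf, p))
  expect_equal(fit$params$gamma_max, p$gamma_max, tolerance = 1e-3)
  expect_equal(fit$params$sf_max, p$sf_max, tolerance = 1e-3)
  expect_equal(fit$params$beta, p$beta, tolerance = 1e-3)
  expect_lt(fit$rss, 1e-8)
  expect_error(fit_csf(c(1, 2), c(1, 1)), ">= 3 points")
})

test_that("symmetric noise leaves the fitted peak frequency unbiased", {
  set.seed(59)
  p <- csf_params(gamma_max = 35, sf_max = 2, beta = 2.5)
  sf <- c(0.8, 1.4, 2.2, 4.3, 7.2)
  peaks <- replicate(200, {
    y <- csf_value(sf, p) + rnorm(length(sf), 0, 0.05)
    log10(fit_csf(sf, y)$params$sf_max)
  })
  # the vertex estimate is a ratio of noisy quantities and is clamped to
  # its search bounds when noise flattens the parabola, so the mean has
  # heavy tails; the bulk of the distribution must be centred on the truth
  expect_lt(abs(stats::median(peaks) - log10(2)), 0.05)
})

test_that("flat sensitivity data push the bandwidth to its bound", {
  sf <- c(1, 2, 4, 8)
  expect_warning(fit <- fit_csf(sf, rep(1.3, 4)), "flat")
  expect_equal(fit$params$beta, 4, tolerance = 1e-6)   # widest allowed
  expect_equal(log10(fit$params$gamma_max), 1.3, tolerance = 0.1)
})

test_that("mean CSF averages subjects before fitting", {
  p <- csf_params(gamma_max = 30, sf_max = 2, beta = 2.5)
  sf <- c(0.8, 1.4, 2.2, 4.3, 7.2)
  base <- csf_value(sf, p)
  df_same <- rbind(data.frame(subject = 1, sf = sf, log_cs = base),
                   data.frame(subject = 2, sf = sf, log_cs = base))
  fit <- mean_csf(df_same)
  expect_equal(fit$params$sf_max, 2, tolerance = 1e-3)
  expect_equal(fit$params$gamma_max, 30, tolerance = 1e-2)
  # +/- delta subjects average to the midline
  df_pm <- rbind(data.frame(subject = 1, sf = sf, log_cs = base + 0.2),
                 data.frame(subject = 2, sf = sf, log_cs = base - 0.2))
  expect_equal(mean_csf(df_pm)$means$log_cs, base, tolerance = 1e-12)
  # missing cell warning
  expect_warning(mean_csf(df_same[-1, ]), "missing")
})

test_that("the full pipeline recovers a known CSF from noise-free cells", {
  truth <- csf_params(gamma_max = 30, sf_max = 1.8, beta = 2.5)
  sf_set <- spatial_frequency_set(6.5)
  log_cs_hat <- vapply(sf_set, function(sf) {
    m_true <- cs_to_threshold(10^csf_value(sf, truth))
    p <- psychometric_params(m_true, slope_to_width(3), 0, 0.02)
    fit <- fit_psychometric(noise_free_rate_table(p), "saccade")
    threshold_to_cs(fit$params$m)$log_cs
  }, numeric(1))
  fit <- fit_csf(sf_set, log_cs_hat)
  expect_equal(fit$params$gamma_max, truth$gamma_max, tolerance = 0.01)
  expect_equal(fit$params$sf_max, truth$sf_max, tolerance = 0.01)
  expect_equal(fit$params$beta, truth$beta, tolerance = 0.01)
})
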