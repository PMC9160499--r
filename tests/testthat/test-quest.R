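# QUEST+ engine: grid/prior handling, Bayesian updating, expected-entropy
# stimulus placement, estimates, serialization.

test_that("default grids match the published parameter spaces", {
  g <- parameter_grid()
  expect_length(g$thresholds, 15L)
  expect_equal(exp(g$thresholds)[c(1, 15)], c(0.00024, 0.66))
  expect_equal(g$slopes, seq(0.5, 5.5, by = 0.5))
  expect_equal(diff(g$thresholds), rep(diff(g$thresholds)[1], 14))  # log-even
})

test_that("initialisation yields a uniform (or renormalised) prior", {
  st <- quest_init()
  expect_equal(dim(st$posterior), c(15L, 11L))
  expect_true(all(st$posterior == 1 / 165))
  expect_equal(st$trial_count, 0L)

  g1 <- parameter_grid(thresholds = log(0.1), slopes = 2)
  expect_equal(quest_init(g1)$posterior, matrix(1, 1, 1))

  g <- parameter_grid(thresholds = log(c(0.01, 0.1)), slopes = c(1, 2))
  pr <- matrix(c(2, 1, 1, 0), 2, 2)
  st2 <- quest_init(g, prior = pr)
  expect_equal(sum(st2$posterior), 1)
  expect_equal(st2$posterior, pr / 4)
  expect_error(quest_init(g, prior = matrix(1, 3, 2)), "matrix")
  expect_error(quest_init(g, prior = matrix(-1, 2, 2)), "non-negative")
})

test_that("outcome likelihoods match direct psychometric evaluation", {
  g <- parameter_grid(gamma = 0, lam = 0)
  i <- 7L; j <- 4L
  x <- exp(g$thresholds[i])
  L <- outcome_likelihood(g, x, correct = TRUE)
  expect_equal(L[i, j], 0.5)
  expect_equal(outcome_likelihood(g, x, TRUE) +
                 outcome_likelihood(g, x, FALSE),
               matrix(1, 15, 11))
  # oracle: Eq.-style evaluation through psychometric_params for random cells
  set.seed(3)
  g2 <- parameter_grid(gamma = 0.25, lam = 0.02)
  for (k in 1:20) {
    i <- sample(15, 1); j <- sample(11, 1)
    x <- exp(runif(1, g2$thresholds[1], 0))
    p <- psychometric_params(g2$thresholds[i],
                             slope_to_width(g2$slopes[j]),
                             gamma = 0.25, lam = 0.02)
    expect_equal(outcome_likelihood(g2, x, TRUE)[i, j],
                 weibull_prob(x, p), tolerance = 1e-12)
  }
})

test_that("update performs exact Bayes on a two-cell toy grid", {
  g <- parameter_grid(thresholds = log(c(0.01, 0.2)), slopes = 2,
                      gamma = 0, lam = 0)
  st <- quest_init(g)
  x <- 0.05
  st1 <- quest_update(st, x, correct = TRUE)
  # brute-force Bayes through the psychometric core
  w <- slope_to_width(2)
  l1 <- weibull_prob(x, psychometric_params(log(0.01), w))
  l2 <- weibull_prob(x, psychometric_params(log(0.2), w))
  expect_equal(as.numeric(st1$posterior), c(l1, l2) / (l1 + l2),
               tolerance = 1e-12)
  expect_equal(st1$trial_count, 1L)
})

test_that("updates commute and keep the posterior normalised", {
  set.seed(5)
  st <- quest_init(parameter_grid(gamma = 0.25))
  a <- quest_update(quest_update(st, 0.05, TRUE), 0.3, FALSE)
  b <- quest_update(quest_update(st, 0.3, FALSE), 0.05, TRUE)
  expect_equal(a$posterior, b$posterior, tolerance = 1e-12)
  for (k in 1:30) {
    st <- quest_update(st, sample(default_contrast_levels(), 1),
                       runif(1) < 0.6)
    expect_equal(sum(st$posterior), 1, tolerance = 1e-12)
    expect_true(all(st$posterior >= 0))
  }
})

test_that("stimulus selection equals brute-force expected-entropy search", {
  g <- parameter_grid(thresholds = log(c(0.01, 0.05, 0.3)),
                      slopes = c(1, 3), gamma = 0, lam = 0.02)
  dom <- c(0.02, 0.08, 0.4)
  st <- quest_init(g, stimulus_domain = dom)
  st <- quest_update(st, 0.08, TRUE)
  st <- quest_update(st, 0.02, FALSE)
  # exhaustive enumeration over stimulus x outcome branches
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  brute <- sapply(dom, function(x) {
    psi <- outcome_likelihood(g, x, TRUE)
    eh <- 0
    for (correct in c(TRUE, FALSE)) {
      lik <- if (correct) psi else 1 - psi
      joint <- st$posterior * lik
      p_out <- sum(joint)
      if (p_out > 0) eh <- eh + p_out * H(joint / p_out)
    }
    eh
  })
  sel <- quest_next_stimulus(st, details = TRUE)
  expect_equal(sel$expected_entropy, brute, tolerance = 1e-12)
  expect_equal(sel$index, which.min(brute))
})

test_that("degenerate posterior ties break to the lowest contrast", {
  g <- parameter_grid(thresholds = log(c(0.01, 0.1)), slopes = 2)
  pr <- matrix(c(1, 0), 2, 1)
  st <- quest_init(g, prior = pr, stimulus_domain = c(0.05, 0.2, 0.6))
  expect_equal(quest_next_stimulus(st), 0.05)
})

test_that("expected entropy of the chosen stimulus never exceeds current entropy", {
  set.seed(9)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  st <- quest_init(parameter_grid(gamma = 0, lam = 0.02))
  for (k in 1:15) {
    sel <- quest_next_stimulus(st, details = TRUE)
    expect_lte(min(sel$expected_entropy), H(st$posterior) + 1e-12)
    st <- quest_update(st, sel$contrast, runif(1) < 0.5)
  }
})

test_that("threshold estimate is the posterior mean of the marginal", {
  g <- parameter_grid(thresholds = log(c(0.01, 0.1)), slopes = 2)
  st <- quest_init(g, prior = matrix(c(1, 0), 2, 1))
  expect_equal(quest_estimate(st), log(0.01))
  st2 <- quest_init(g, prior = matrix(c(1, 1), 2, 1))
  expect_equal(quest_estimate(st2), mean(log(c(0.01, 0.1))))
  set.seed(2)
  st3 <- quest_init()
  for (k in 1:10) st3 <- quest_update(st3, 0.05, runif(1) < 0.7)
  expect_equal(quest_estimate(st3),
               sum(rowSums(st3$posterior) * st3$grid$thresholds))
})

test_that("entropy of the threshold marginal shrinks on average across trials", {
  set.seed(21)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  p_true <- psychometric_params(log(default_contrast_levels())[8],
                                slope_to_width(3), 0, 0.02)
  n_rep <- 100; n_tr <- 12
  ent <- matrix(NA_real_, n_rep, n_tr + 1)
  for (r in seq_len(n_rep)) {
    st <- quest_init(parameter_grid(gamma = 0, lam = 0.02))
    ent[r, 1] <- H(rowSums(st$posterior))
    for (k in seq_len(n_tr)) {
      x <- quest_next_stimulus(st)
      st <- quest_update(st, x, runif(1) < weibull_prob(x, p_true))
      ent[r, k + 1] <- H(rowSums(st$posterior))
    }
  }
  expect_true(all(diff(colMeans(ent)) < 0))
})

test_that("4AFC engine avoids stimuli predicted below the guessing floor", {
  set.seed(13)
  p_true <- psychometric_params(log(default_contrast_levels())[10],
                                slope_to_width(2), 0.25, 0.02)
  st <- quest_init(parameter_grid(gamma = 0.25, lam = 0.02))
  for (k in 1:30) {
    x <- quest_next_stimulus(st)
    m_hat <- quest_estimate(st)
    s_hat <- sum(colSums(st$posterior) * st$grid$slopes)
    pred <- weibull_prob(x, psychometric_params(m_hat,
                                                slope_to_width(s_hat),
                                                0.25, 0.02))
    expect_gte(pred, 0.25)
    st <- quest_update(st, x, runif(1) < weibull_prob(x, p_true))
  }
})

test_that("states survive a JSON round trip", {
  set.seed(4)
  st <- quest_init(parameter_grid(gamma = 0.25),
                   location_label = "90")
  for (k in 1:5) st <- quest_update(st, 0.1, runif(1) < 0.5)
  path <- withr::local_tempfile(fileext = ".json")
  quest_to_json(st, path)
  st2 <- quest_from_json(path)
  expect_equal(st2$posterior, st$posterior, tolerance = 1e-12)
  expect_equal(st2$trial_count, st$trial_count)
  expect_equal(st2$grid$thresholds, st$grid$thresholds)
  expect_equal(st2$location_label, "90")
  expect_equal(quest_next_stimulus(st2), quest_next_stimulus(st))
})
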