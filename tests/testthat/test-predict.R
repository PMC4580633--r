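mini_fit <- function(beta, terms, vcov = NULL) {
  k <- length(beta)
  names(beta) <- c("(Intercept)", terms)
  if (is.null(vcov)) vcov <- matrix(0, k, k)
  dimnames(vcov) <- list(names(beta), names(beta))
  structure(
    list(spec = model_spec(terms), beta = beta, vcov = vcov,
         logLik = NA_real_, k = k, n = 0, aicc = NA_real_,
         converged = TRUE, terms = names(beta)),
    class = "kc_fit"
  )
}

test_that("probability prediction obeys the nuisance-mode contract", {
  d <- data.frame(SEARCH_LAG = c(10, 50), FIELDPROP = c(0.2, 0.9),
                  CENTER = c(30, 60))
  fit0 <- mini_fit(c(0, 0, 0), c("SEARCH_LAG", "FIELDPROP"))
  expect_equal(predict_probabilities(fit0, d, "observed"), c(0.5, 0.5))

  fit <- mini_fit(c(1, -0.05, 2), c("SEARCH_LAG", "FIELDPROP"))
  # corrected mode ignores whatever nuisance values the rows carry
  d2 <- d
  d2$SEARCH_LAG <- c(999, -5)
  d2$FIELDPROP <- c(0, 0)
  expect_equal(predict_probabilities(fit, d, "corrected"),
               predict_probabilities(fit, d2, "corrected"))
  expect_equal(predict_probabilities(fit, d, "corrected"),
               rep(1 / (1 + exp(-3)), 2))
  # uncorrected mode plugs in the configured means
  expect_equal(
    predict_probabilities(fit, d, "uncorrected",
                          nuisance_means = c(SEARCH_LAG = 20,
                                             FIELDPROP = 0.5)),
    rep(1 / (1 + exp(-(1 - 1 + 1))), 2)
  )
  # hand linear predictor eta = -1
  fit1 <- mini_fit(c(-1, 0), "CENTER")
  expect_equal(predict_probabilities(fit1, d, "observed")[1],
               1 / (1 + exp(1)))
})

test_that("event counting thresholds, bounds and intervals behave", {
  d <- data.frame(CENTER = rep(1, 20))
  hi <- mini_fit(c(10, 0), "CENTER")
  out <- count_events(hi, d, cutoff = 0.9, mode = "observed",
                      n_draws = 200, seed = 1)
  expect_equal(out$predicted_count, 20)
  expect_equal(out$proportion, 1)
  # degenerate vcov: zero-width intervals at the point estimate
  expect_equal(out$ci_low, 1)
  expect_equal(out$ci_high, 1)
  expect_equal(out$ci_wald_low, 1)
  expect_error(count_events(hi, d, 0.5, n_draws = 50), "at least 100")

  # monotone non-increasing in the cutoff
  sh <- shared_sim_small()
  spec <- model_spec("log(POSCOUNT)", "NIGHTPROP", "ACCXYDIFF",
                     "SEARCH_LAG", "FIELDPROP")
  fit <- fit_model(sh$visited, spec)
  cuts <- c(0.05, 0.2, 0.5, 0.8)
  counts <- vapply(cuts, function(ct) {
    count_events(fit, sh$covs, ct, mode = "corrected", n_draws = 100,
                 seed = 2)$predicted_count
  }, 0)
  expect_true(all(diff(counts) <= 0))

  # percentile interval brackets the point estimate across seeds
  for (s in 1:5) {
    pe <- count_events(fit, sh$covs, 0.3, mode = "corrected",
                       n_draws = 300, seed = s)
    expect_true(pe$ci_low <= pe$proportion + 1e-9 &&
                  pe$ci_high >= pe$proportion - 1e-9)
    expect_true(pe$ci_wald_low <= pe$proportion &&
                  pe$ci_wald_high >= pe$proportion)
  }
})

test_that("response profiles follow the model shape", {
  d <- data.frame(CENTER = runif(50, 0, 100), SEARCH_LAG = runif(50, 0, 60))
  # zero coefficient (and no interactions): flat curve
  flat <- mini_fit(c(0.4, 0, -0.02), c("CENTER", "SEARCH_LAG"))
  pr <- response_profile(flat, d, "CENTER")
  expect_equal(diff(range(pr$prob)), 0)
  # one-covariate model equals the closed-form logistic curve
  one <- mini_fit(c(-2, 0.05), "CENTER")
  g <- seq(10, 90, by = 10)
  pr1 <- response_profile(one, d, "CENTER", grid = g)
  expect_equal(pr1$prob, 1 / (1 + exp(-(-2 + 0.05 * g))))
  expect_equal(pr1$lower, pr1$prob)     # zero vcov: bands collapse
  # negative-slope covariate: monotonically decreasing profile
  neg <- mini_fit(c(1, -0.04, 0.01), c("SEARCH_LAG", "CENTER"))
  prn <- response_profile(neg, d, "SEARCH_LAG")
  expect_true(all(diff(prn$prob) < 0))
  expect_warning(response_profile(one, d, "CENTER", grid = c(-5, 50)),
                 "outside")
  expect_error(response_profile(one, d, "SEARCH_LAG"), "not in the model")
})
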