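toy_data <- function(n = 40, seed = 9) {
  set.seed(seed)
  data.frame(
    POSCOUNT = sample(2:20, n, replace = TRUE),
    NIGHTPROP = runif(n), CENTER = runif(n, 0, 150),
    ACCX = runif(n, 0, 200), ACCXYDIFF = runif(n, -50, 80),
    SEARCH_LAG = runif(n, 0, 60), FIELDPROP = runif(n),
    SEAS = sample(c("SUM", "FAL", "WIN"), n, replace = TRUE),
    FEEDING = rbinom(n, 1, 0.5)
  )
}

test_that("design matrix applies transforms in spec order", {
  d <- toy_data(10)
  dm0 <- build_design_matrix(d, model_spec(), response = "FEEDING")
  expect_equal(unname(dm0$X), matrix(1, 10, 1))   # intercept-only

  d$POSCOUNT[1] <- exp(1)
  spec <- model_spec("log(POSCOUNT)", "NIGHTPROP",
                     "log(POSCOUNT):NIGHTPROP")
  dm <- build_design_matrix(d, spec)
  expect_equal(colnames(dm$X),
               c("(Intercept)", "log(POSCOUNT)", "NIGHTPROP",
                 "log(POSCOUNT):NIGHTPROP"))
  expect_equal(unname(dm$X[1, "log(POSCOUNT)"]), 1)  # natural log
  expect_equal(dm$X[, 4], dm$X[, 2] * dm$X[, 3])  # interaction = product
  # SUM dummy indicates summer rows only
  dmS <- build_design_matrix(d, model_spec("SUM"))
  expect_equal(unname(dmS$X[, "SUM"]), as.numeric(d$SEAS == "SUM"))
})

test_that("spec hierarchy and data errors are enforced", {
  expect_error(model_spec("CENTER^2"), "requires main effect")
  expect_error(model_spec("ACCX", "ACCX:CENTER"), "both parent")
  expect_silent(model_spec("ACCX", "CENTER", "ACCX:CENTER"))
  d <- toy_data(10)
  d$POSCOUNT[3] <- 0
  expect_error(build_design_matrix(d, model_spec("log(POSCOUNT)")),
               "non-positive POSCOUNT at row")
  expect_error(build_design_matrix(d, model_spec("NOPE")),
               "missing covariate")
  d2 <- toy_data(10)
  d2$ACCX[c(2, 5)] <- NA
  expect_message(dm <- build_design_matrix(d2, model_spec("ACCX")),
                 "2 row")
  expect_equal(nrow(dm$X), 8)
})

test_that("logistic ML fit matches closed forms and the optimizer oracle", {
  # intercept-only on balanced outcomes
  y <- rep(c(0, 1), 25)
  f0 <- fit_logistic(y, matrix(1, 50, 1))
  expect_equal(unname(f0$beta), 0, tolerance = 1e-8)
  expect_equal(f0$logLik, 50 * log(0.5))

  # single binary covariate: slope = log odds ratio of the 2x2 table
  y2 <- c(rep(1, 10), rep(0, 10), rep(1, 15), rep(0, 5))
  x2 <- c(rep(0, 20), rep(1, 20))
  f2 <- fit_logistic(y2, cbind(1, x = x2))
  expect_equal(unname(f2$beta["x"]), log((15 / 5) / (10 / 10)),
               tolerance = 1e-7)

  # random instances against a generic BFGS optimizer of the likelihood
  for (s in 1:10) {
    set.seed(s)
    n <- 80
    X <- cbind(1, rnorm(n), runif(n))
    colnames(X) <- c("(Intercept)", "a", "b")
    y <- rbinom(n, 1, 1 / (1 + exp(-(0.3 - 0.8 * X[, 2] + X[, 3]))))
    if (length(unique(y)) < 2) next
    fit <- fit_logistic(y, X)
    expect_lt(max(abs(fit$beta - logistic_optim(y, X))), 1e-6)
    # score identity: fitted probabilities sum to the event count
    expect_equal(sum(fit$fitted), sum(y), tolerance = 1e-6)
  }
})

test_that("degenerate fits fail loudly", {
  set.seed(1)
  X <- cbind(1, a = rnorm(20))
  X <- cbind(X, b = X[, 2] * 2)            # collinear
  y <- rbinom(20, 1, 0.5)
  expect_error(fit_logistic(y, X), "collinear.*b")
  # complete separation
  xs <- c(rnorm(20, -5), rnorm(20, 5))
  ys <- rep(c(0, 1), each = 20)
  expect_error(fit_logistic(ys, cbind(1, x = xs)), "separation")
  expect_error(fit_logistic(ys, matrix(1, 2, 3)), "more observations")
})

test_that("AICc matches hand substitution and its small-sample limit", {
  expect_equal(aicc(0, 1, 100), 2 + 4 / 98)
  expect_equal(aicc(-10, 2, 1000), 20 + 4 + 12 / 997)
  expect_lt(abs(aicc(-5, 3, 1e9) - (10 + 6)), 1e-6)  # -> plain AIC
  expect_error(aicc(0, 5, 6), "n > k")
})

test_that("the component candidate set spans all 16 group combinations", {
  specs <- component_candidate_set()
  expect_length(specs, 16)
  expect_equal(length(specs$Null$terms), 0)
  full <- specs[["SpTemp+Acvty+GrndTru+Seas"]]
  expect_length(full$terms, 14)            # 15 params with intercept
  expect_setequal(full$terms, top_model_spec()$terms)
  # cross-group interactions only when both parent groups are on
  both <- specs[["SpTemp+Acvty"]]
  expect_true(all(c("ACCX:CENTER", "ACCXYDIFF:log(POSCOUNT)") %in%
                    both$terms))
  expect_false(any(grepl(":", specs[["SpTemp+GrndTru"]]$terms) &
                     grepl("ACCX", specs[["SpTemp+GrndTru"]]$terms)))
  expect_false("ACCX:CENTER" %in% specs[["Acvty+Seas"]]$terms)
  # parameter counts mirror the component structure
  ks <- vapply(specs, function(s) length(s$terms) + 1L, 0L)
  expect_equal(unname(ks[c("SpTemp", "Acvty", "GrndTru", "Seas", "Null")]),
               c(6L, 4L, 4L, 2L, 1L))
})

test_that("model selection table is ordered with normalized weights", {
  d <- toy_data(200, seed = 2)
  # make the response actually depend on two covariates
  set.seed(3)
  p <- 1 / (1 + exp(-(-1 + 0.02 * d$CENTER + 1.5 * d$NIGHTPROP)))
  d$FEEDING <- rbinom(nrow(d), 1, p)
  specs <- list(model_spec("CENTER", label = "C"),
                model_spec("CENTER", "NIGHTPROP", label = "CN"),
                model_spec(label = "null"))
  sel <- select_models(specs, d)
  expect_s3_class(sel, "kc_selection")
  expect_equal(sel$delta[1], 0)
  expect_equal(sum(sel$weight), 1, tolerance = 1e-12)
  expect_false(is.unsorted(sel$AICc))
  # single model: weight one
  expect_equal(select_models(specs[2], d)$weight, 1)
  # equal-AICc pair: weights half and half
  sel2 <- select_models(list(model_spec("CENTER", label = "a"),
                             model_spec("CENTER", label = "b")), d)
  expect_equal(sel2$weight, c(0.5, 0.5))
  # weights invariant to a constant logLik shift (delta-based)
  w <- exp(-sel$delta / 2)
  expect_equal(sel$weight, w / sum(w))
})
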