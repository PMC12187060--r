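# Independent naive-loop oracle for the per-site sufficient statistics.
naive_contribution <- function(X, y, beta, family) {
  p <- ncol(X); n <- nrow(X)
  info <- matrix(0, p, p); score <- numeric(p); dev <- 0
  for (i in seq_len(n)) {
    eta <- sum(X[i, ] * beta)
    if (family == "binomial_logit") {
      mu <- 1 / (1 + exp(-eta))
      w <- mu * (1 - mu)
      z <- eta + (y[i] - mu) / w
      dev <- dev - 2 * (y[i] * log(mu) + (1 - y[i]) * log(1 - mu))
    } else {
      w <- 1; z <- y[i]
      dev <- dev + (y[i] - eta)^2
    }
    info <- info + w * outer(X[i, ], X[i, ])
    score <- score + w * z * X[i, ]
  }
  list(info = info, score = score, deviance = dev, n = n)
}

random_logistic <- function(n, p, seed) {
  set.seed(seed)
  X <- cbind(1, matrix(rnorm(n * (p - 1)), n, p - 1))
  beta <- rnorm(p, 0, 0.8)
  y <- rbinom(n, 1, plogis(drop(X %*% beta)))
  list(X = X, y = y)
}

test_that("local contributions match a naive loop oracle", {
  expect_equal(unname(irls_local_contribution(matrix(1, 3, 1), c(1, 2, 3),
                                              0, "gaussian_identity")$info),
               matrix(3, 1, 1))
  expect_equal(irls_local_contribution(matrix(1, 3, 1), c(1, 2, 3), 0,
                                       "gaussian_identity")$score, 6)
  # binomial at beta = 0: mu = 1/2 everywhere, W = I/4
  X <- cbind(1, c(-1, 0, 2))
  c0 <- irls_local_contribution(X, c(0, 1, 1), c(0, 0), "binomial_logit")
  expect_equal(c0$info, 0.25 * crossprod(X))

  set.seed(41)
  for (family in c("binomial_logit", "gaussian_identity")) {
    for (rep in 1:5) {
      n <- sample(10:40, 1); p <- sample(2:4, 1)
      X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
      y <- if (family == "binomial_logit") rbinom(n, 1, 0.5) else rnorm(n)
      beta <- rnorm(p, 0, 0.3)
      got <- irls_local_contribution(X, y, beta, family)
      want <- naive_contribution(X, y, beta, family)
      expect_equal(unname(got$info), want$info, tolerance = 1e-12)
      expect_equal(unname(got$score), want$score, tolerance = 1e-12)
      expect_equal(got$deviance, want$deviance, tolerance = 1e-12)
    }
  }
  expect_error(irls_local_contribution(matrix(1, 3, 1), c(0, 1, 2), 0,
                                       "binomial_logit"), "0/1")
})

test_that("pooled fit agrees with stats::glm to 1e-8 on random instances", {
  spec <- glm_spec("y", paste0("x", 1:3), family = "binomial_logit",
                   tolerance = 1e-12)
  for (seed in 1:20) {
    d <- random_logistic(n = 300, p = 4, seed = seed)
    fit <- pooled_glm_fit(d$X, d$y, spec)
    ref <- glm.fit(d$X, d$y, family = binomial(),
                   control = glm.control(epsilon = 1e-12))
    expect_lt(max(abs(unname(fit$coefficients) - unname(ref$coefficients))),
              1e-8)
    expect_equal(fit$deviance, ref$deviance, tolerance = 1e-8)
  }
  # standard errors against the reference fit on one instance
  d <- random_logistic(400, 4, seed = 99)
  fit <- pooled_glm_fit(d$X, d$y, spec)
  ref <- summary(glm(d$y ~ d$X - 1, family = binomial(),
                     control = glm.control(epsilon = 1e-12)))
  expect_equal(unname(fit$standard_errors),
               unname(ref$coefficients[, "Std. Error"]), tolerance = 1e-6)
})

test_that("gaussian identity is solved in one step at the closed form", {
  set.seed(42)
  X <- cbind(1, matrix(rnorm(60), 30))
  y <- rnorm(30)
  fit <- pooled_glm_fit(X, y, glm_spec("y", c("a", "b"),
                                       family = "gaussian_identity"))
  expect_identical(fit$iterations, 1L)
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients),
               drop(solve(crossprod(X), crossprod(X, y))), tolerance = 1e-12)
  expect_equal(fit$deviance, sum(lm.fit(X, y)$residuals^2),
               tolerance = 1e-10)
})

test_that("intercept-only binomial recovers logit of the mean", {
  y <- c(rep(1, 30), rep(0, 70))
  fit <- pooled_glm_fit(matrix(1, 100, 1), y,
                        glm_spec("y", character(), "binomial_logit"))
  expect_equal(unname(fit$coefficients), qlogis(0.3), tolerance = 1e-10)
})

test_that("saturated one-predictor logistic equals the cross-product OR", {
  # exposed: 30 cases / 10 non-cases; unexposed: 20 cases / 40 non-cases
  x <- c(rep(1, 40), rep(0, 60))
  y <- c(rep(1, 30), rep(0, 10), rep(1, 20), rep(0, 40))
  d <- data.frame(y = y, x = x)
  fit <- pooled_glm_fit(spec = glm_spec("y", "x", "binomial_logit"),
                        data = d)
  expect_equal(unname(fit$odds_ratios["x"]), (30 * 40) / (10 * 20),
               tolerance = 1e-8)
})

test_that("Wald summaries are internally consistent", {
  d <- random_logistic(500, 3, seed = 7)
  fit <- pooled_glm_fit(d$X, d$y, glm_spec("y", c("x1", "x2")))
  expect_true(all(fit$ci_low <= fit$odds_ratios &
                    fit$odds_ratios <= fit$ci_high))
  expect_equal(unname(fit$ci_high),
               unname(exp(fit$coefficients +
                            qnorm(0.975) * fit$standard_errors)))
  expect_equal(unname(fit$p_values),
               unname(2 * pnorm(-abs(fit$coefficients /
                                       fit$standard_errors))))
  ci <- confint(fit)
  expect_equal(unname(exp(ci[, 2])), unname(fit$ci_high))
  expect_equal(coef(fit), fit$coefficients)
  expect_equal(unname(sqrt(diag(vcov(fit)))), unname(fit$standard_errors))
  pr <- predict(fit, data.frame(x1 = c(0, 1), x2 = c(0, 0)),
                type = "response")
  expect_equal(pr[1], unname(plogis(coef(fit)[1])))
})

test_that("collinear designs raise a rank-deficiency error naming columns", {
  X <- cbind(1, c(1, 2, 3, 4), c(2, 4, 6, 8))
  colnames(X) <- c("(Intercept)", "dose", "dose_double")
  y <- c(0, 1, 0, 1)
  expect_error(pooled_glm_fit(X, y, glm_spec("y", c("dose", "dose_double"))),
               "collinear.*dose")
})

test_that("complete-case handling drops rows with NA in model variables", {
  set.seed(77)
  d <- data.frame(y = rbinom(60, 1, 0.5), x = rnorm(60))
  d$y[c(3, 10)] <- NA
  d$x[c(5, 20, 31)] <- NA
  spec <- glm_spec("y", "x", tolerance = 1e-12)
  fit <- pooled_glm_fit(spec = spec, data = d)
  expect_identical(fit$n_total, 55L)
  dd <- d[complete.cases(d), ]
  ref <- glm(y ~ x, binomial(), dd, control = glm.control(epsilon = 1e-12))
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-8)
})

test_that("binomial deviance is non-increasing across IRLS iterations", {
  d <- random_logistic(400, 4, seed = 17)
  spec <- glm_spec("y", paste0("x", 1:3))
  beta <- rep(0, 4)
  devs <- numeric()
  for (it in 1:8) {
    c1 <- irls_local_contribution(d$X, d$y, beta, "binomial_logit")
    devs <- c(devs, c1$deviance)
    beta <- solve(c1$info, c1$score)
  }
  expect_true(all(diff(devs) <= 1e-12))
})

test_that("the formula mini-language parses additive terms only", {
  sp <- as_glm_spec(y ~ a + b + c, family = "binomial_logit")
  expect_identical(sp$outcome, "y")
  expect_identical(sp$predictors, c("a", "b", "c"))
  expect_error(as_glm_spec(y ~ a * b), "additive")
})
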