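test_that("weighted mean: hand example, scale invariance, degenerate replicates", {
  d <- degenerate_design(2, weight = c(1, 3))
  wm <- weighted_mean(c(1, 3), d)
  expect_equal(wm$estimate, 2.5)
  expect_equal(wm$se, 0)  # all replicate sets equal the main weights
  d10 <- degenerate_design(2, weight = 10 * c(1, 3))
  expect_equal(weighted_mean(c(1, 3), d10)$estimate, 2.5)
  deq <- degenerate_design(5)
  expect_equal(weighted_mean(c(1, 2, 3, 4, 10), deq)$estimate, 4)
})

test_that("replicate variance equals the naive-loop jackknife oracle", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    d <- dagjk_design(n, R = 12, seed = rep)
    x <- rnorm(n, 5, 2)
    wm <- weighted_mean(x, d)
    expect_equal(wm$se,
                 naive_repwt_se(x, d$weight, d$rep_weights, d$variance_factor),
                 tolerance = 1e-12)
  }
})

test_that("linear survey fit equals OLS under equal weights and degenerate replicates", {
  set.seed(30)
  n <- 20
  dat <- data.frame(x = rnorm(n), z = runif(n))
  dat$y <- 1 + 2 * dat$x - 0.5 * dat$z + rnorm(n, 0, 0.3)
  fit <- fit_survey_glm(y ~ x + z, dat, degenerate_design(n), family = "linear")
  ols <- lm(y ~ x + z, dat)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)), tolerance = 1e-10)
  expect_equal(fit$coefficients$se, rep(0, 3))
})

test_that("logistic fit with equal weights reproduces unweighted MLE to 1e-6", {
  set.seed(31)
  n <- 200
  dat <- data.frame(x = rnorm(n))
  dat$y <- rbinom(n, 1, plogis(-0.5 + 0.8 * dat$x))
  fit <- fit_survey_glm(y ~ x, dat, degenerate_design(n), family = "logistic")
  mle <- glm(y ~ x, binomial, dat)
  expect_equal(fit$coefficients$estimate, unname(coef(mle)), tolerance = 1e-6)
  # intercept-only model returns the logit of the prevalence
  f0 <- fit_survey_glm(y ~ 1, dat, degenerate_design(n), family = "logistic")
  expect_equal(f0$coefficients$estimate, qlogis(mean(dat$y)), tolerance = 1e-8)
  # odds ratio is exp(beta) and flips under outcome reversal
  expect_equal(fit_term(fit, "x")$odds_ratio, exp(fit_term(fit, "x")$estimate))
  dat$y2 <- 1 - dat$y
  f2 <- fit_survey_glm(y2 ~ x, dat, degenerate_design(n), family = "logistic")
  expect_equal(fit_term(f2, "x")$estimate, -fit_term(fit, "x")$estimate,
               tolerance = 1e-6)
})

test_that("log-outcome fits model the natural log; CI brackets the estimate", {
  set.seed(32)
  n <- 120
  dat <- data.frame(x = rnorm(n))
  dat$y <- exp(0.5 + 0.3 * dat$x + rnorm(n, 0, 0.2))
  d <- dagjk_design(n, R = 20, seed = 5)
  fit <- fit_survey_glm(y ~ x, dat, d, family = "linear", log_outcome = TRUE)
  row <- fit_term(fit, "x")
  expect_true(row$ci_low < row$estimate && row$estimate < row$ci_high)
  expect_equal(row$estimate, 0.3, tolerance = 0.15)
  dat$y[1] <- 0
  expect_error(fit_survey_glm(y ~ x, dat, d, family = "linear",
                              log_outcome = TRUE), "positive")
})

test_that("rank-deficient design matrices raise a collinearity error", {
  set.seed(33)
  dat <- data.frame(x = rnorm(10))
  dat$x2 <- 2 * dat$x
  dat$y <- rnorm(10)
  expect_error(fit_survey_glm(y ~ x + x2, dat, degenerate_design(10)),
               "rank deficient")
})

test_that("trend test: perfect trend, antisymmetry, degenerate outcome", {
  set.seed(34)
  n <- 100
  d <- dagjk_design(n, R = 20, seed = 3)
  q <- sample(1:5, n, replace = TRUE)
  y <- 2 * q + rnorm(n, 0, 0.01)
  tt <- trend_test(y, q, d)
  expect_lt(tt$p, 1e-10)
  rev <- trend_test(y, 6 - q, d)
  expect_equal(rev$estimate, -tt$estimate, tolerance = 1e-8)
  expect_equal(rev$p, tt$p, tolerance = 1e-8)
  expect_error(trend_test(rep(1, n), q, d), "constant")
})

test_that("categorical test: perfect independence and the textbook oracle", {
  d <- degenerate_design(200)
  a <- rep(c("x", "y"), each = 100)
  b <- rep(rep(c("u", "v"), each = 50), 2)
  res <- categorical_test(a, b, d)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  set.seed(35)
  a2 <- sample(c("x", "y", "z"), 200, replace = TRUE)
  b2 <- sample(c("u", "v"), 200, replace = TRUE)
  res2 <- categorical_test(a2, b2, d)
  textbook <- suppressWarnings(chisq.test(table(a2, b2), correct = FALSE))
  expect_equal(res2$statistic, unname(textbook$statistic), tolerance = 1e-10)
  expect_equal(res2$deff, 1)
})

test_that("categorical test holds its level under the null with unequal weights", {
  set.seed(36)
  n <- 300
  nonsig <- 0
  reps <- 1000
  for (r in seq_len(reps)) {
    w <- rlnorm(n, 0, 0.4)
    d <- survey_design(seq_len(n), w, matrix(w, n, 2))
    a <- sample(c("g1", "g2", "g3"), n, replace = TRUE)
    b <- sample(c("yes", "no"), n, replace = TRUE)
    if (categorical_test(a, b, d)$p >= 0.05) nonsig <- nonsig + 1
  }
  expect_gte(nonsig / reps, 0.94)
})
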