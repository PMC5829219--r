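sim_null_data <- function(n, seed) {
  set.seed(seed)
  data.frame(y = rbinom(n, 1, 0.4), x = rnorm(n), z = rnorm(n))
}

test_that("an intercept-only fit returns the logit of the case fraction", {
  d <- data.frame(y = rep(c(1, 0), c(30, 70)))
  fit <- logistic_fit(y ~ 1, d)
  expect_equal(fit$coefficients$beta[1], qlogis(0.3), tolerance = 1e-7)
  expect_equal(fit$ll_fitted, fit$ll_null, tolerance = 1e-9)
})

test_that("the score equations are satisfied at convergence", {
  set.seed(2)
  d <- data.frame(x = rnorm(300), z = rnorm(300))
  d$y <- rbinom(300, 1, plogis(-0.3 + 0.8 * d$x))
  fit <- logistic_fit(y ~ x + z, d)
  X <- model.matrix(~ x + z, d)
  resid <- d$y - fitted(fit$fit)
  expect_lt(max(abs(crossprod(X, resid))), 1e-6)
  expect_gte(fit$ll_fitted, fit$ll_null)
})

test_that("separation is flagged, aliasing is an error", {
  d <- data.frame(y = rep(c(0, 1), each = 20),
                  x = c(rnorm(20, -5), rnorm(20, 5)))
  fit <- suppressWarnings(logistic_fit(y ~ x, d))
  expect_false(fit$converged)
  d2 <- data.frame(y = rbinom(50, 1, 0.5), x = rnorm(50))
  d2$x2 <- d2$x
  expect_error(logistic_fit(y ~ x + x2, d2), "aliased")
})

test_that("Nagelkerke R2 matches the closed form and its limits", {
  # ll_fitted = ll_null gives 0
  m0 <- structure(list(ll_null = -60, ll_fitted = -60, n = 100),
                  class = "logistic_model")
  expect_equal(nagelkerke_r2(m0), 0)
  # perfect-fit limit (ll_fitted -> 0) gives 1
  m1 <- structure(list(ll_null = -60, ll_fitted = 0, n = 100),
                  class = "logistic_model")
  expect_equal(nagelkerke_r2(m1), 1)
  # hand-computed small example: n = 4, ll_null = log(1/16), ll_fitted = log(1/4)
  m2 <- structure(list(ll_null = log(1 / 16), ll_fitted = log(1 / 4),
                       n = 4), class = "logistic_model")
  cs <- 1 - exp(2 * (log(1 / 16) - log(1 / 4)) / 4)
  expect_equal(nagelkerke_r2(m2), cs / (1 - exp(2 * log(1 / 16) / 4)),
               tolerance = 1e-12)
})

test_that("Hosmer-Lemeshow grouping and degrees of freedom behave structurally", {
  set.seed(5)
  d <- data.frame(x = rnorm(2000))
  d$y <- rbinom(2000, 1, plogis(-0.5 + d$x))
  fit <- logistic_fit(y ~ x, d)
  hl <- hosmer_lemeshow(fit)
  expect_equal(hl$df, hl$groups_used - 2)
  expect_gt(hl$p.value, 0.001)  # correctly specified model
  # two groups leave no degrees of freedom: non-informative
  hl2 <- hosmer_lemeshow(fit, groups = 2)
  expect_equal(hl2$df, 0)
  expect_false(hl2$informative)
  expect_true(is.na(hl2$p.value))
  # heavily tied fitted values force group merging
  d$c <- rep(0:1, each = 1000)
  fitc <- logistic_fit(y ~ c, d)
  hlc <- hosmer_lemeshow(fitc)
  expect_true(hlc$merged)
})

test_that("forward-Wald selection stays empty under the null and finds signals", {
  # a single null candidate enters in about 5% of runs
  entered <- vapply(1:100, function(seed) {
    d <- sim_null_data(150, seed)
    length(stepwise_forward_wald(d, "y", "x")$selected) > 0
  }, logical(1))
  expect_lte(mean(entered), 0.11)
  # one strong predictor among noise is selected first
  set.seed(42)
  d <- data.frame(x1 = rnorm(800), x2 = rnorm(800), x3 = rnorm(800))
  d$y <- rbinom(800, 1, plogis(1.2 * d$x1))
  sw <- stepwise_forward_wald(d, "y", c("x2", "x3", "x1"))
  expect_equal(sw$selected[1], "x1")
  expect_equal(sw$trace$action[1], "add")
  # degenerate thresholds admit every candidate
  sw2 <- stepwise_forward_wald(d, "y", c("x1", "x2", "x3"),
                               entry_p = 1, removal_p = 1)
  expect_setequal(sw2$selected, c("x1", "x2", "x3"))
  expect_equal(sw2$selected[1], "x1")  # strongest enters first
})

test_that("bootstrap adjustment is reproducible and calibrated", {
  set.seed(3)
  d <- data.frame(x = rnorm(250))
  d$y <- rbinom(250, 1, plogis(0.9 * d$x))
  b1 <- bootstrap_adjust(y ~ x, d, B = 150, seed = 10)
  b2 <- bootstrap_adjust(y ~ x, d, B = 150, seed = 10)
  expect_identical(b1, b2)
  expect_lt(b1$p_boot[b1$term == "x"], 0.05)
  expect_true(b1$ci_low[b1$term == "x"] > 0)
  expect_error(bootstrap_adjust(y ~ x, d, B = 50), "B >= 100")
  # null calibration: bootstrap p-values spread like a uniform sample
  pvals <- vapply(1:30, function(seed) {
    dn <- sim_null_data(150, seed + 500)
    b <- bootstrap_adjust(y ~ x, dn, B = 120, seed = seed)
    b$p_boot[b$term == "x"]
  }, numeric(1))
  expect_gt(mean(pvals), 0.30)
  expect_lt(mean(pvals), 0.72)
  expect_lte(mean(pvals < 0.05), 0.2)
})

test_that("interaction tests recover signs, hold their level and reject aliasing", {
  # generative negative interaction recovered with OR < 1
  set.seed(8)
  n <- 4000
  d <- data.frame(g = rbinom(n, 1, 0.4), t = rnorm(n))
  d$y <- rbinom(n, 1, plogis(0.4 * d$g + 0.3 * d$t - 0.8 * d$g * d$t))
  r <- interaction_test(d, "y", "g", "t")
  expect_lt(r$or, 1)
  expect_lt(r$p.value, 0.01)
  # type-I error near the nominal level under no interaction
  rej <- vapply(1:100, function(seed) {
    set.seed(seed + 900)
    dn <- data.frame(g = rbinom(300, 1, 0.4), t = rnorm(300))
    dn$y <- rbinom(300, 1, plogis(0.3 * dn$g + 0.3 * dn$t))
    interaction_test(dn, "y", "g", "t")$p.value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.005)
  expect_lte(mean(rej), 0.12)
  # a binary term interacted with itself is aliased
  d$g2 <- d$g
  expect_error(interaction_test(d, "y", "g", "g2"), "rank-deficient")
})
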