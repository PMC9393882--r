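test_that("conditional log-likelihood matches closed forms and brute force", {
  # beta = 0 in n strata of size 4: n * ln(1/4)
  sim <- simulate_clr_strata(50, 1.0, seed = 1)
  expect_equal(conditional_loglik(0, sim$x, sim$y, sim$strata), 50 * log(1 / 4))
  # single stratum, case exposure 1 vs controls 0: b - ln(e^b + 3)
  for (b in c(-1, 0.3, 2))
    expect_equal(conditional_loglik(b, c(1, 0, 0, 0), c(1, 0, 0, 0), rep(1, 4)),
                 b - log(exp(b) + 3))
  # random beta / 20 random strata vs direct enumeration oracle
  set.seed(2)
  sim <- simulate_clr_strata(20, 1.4, seed = 2)
  x2 <- cbind(sim$x, rnorm(length(sim$x)))
  for (i in 1:5) {
    beta <- rnorm(2, 0, 0.5)
    expect_equal(conditional_loglik(beta, x2, sim$y, sim$strata),
                 clr_loglik_brute(beta, x2, sim$y, sim$strata),
                 tolerance = 1e-10)
  }
})

test_that("loglik input validation rejects malformed strata", {
  expect_error(conditional_loglik(0, 1:4, c(0, 0, 0, 0), rep(1, 4)),
               "exactly one case")
  expect_error(conditional_loglik(0, 1:4, c(1, 1, 0, 0), rep(1, 4)),
               "exactly one case")
  expect_error(conditional_loglik(0, 1:3, c(1, 0, 1), c(1, 1, 2)),
               "at least 2")
})

test_that("one-parameter fits match the grid-search oracle within 1e-3", {
  for (seed in 1:4) {
    sim <- simulate_clr_strata(150, c(1.0, 1.3, 1.8, 0.8)[seed], seed = seed)
    fit <- fit_clr(sim$x, sim$y, sim$strata)
    expect_true(fit$converged)
    b_grid <- grid_search_beta(sim$x, sim$y, sim$strata, -0.5, 0.5)
    expect_equal(unname(fit$coef), b_grid, tolerance = 1e-3)
    # maximality against random draws
    set.seed(seed + 100)
    lls <- vapply(rnorm(200, 0, 0.3), function(b)
      conditional_loglik(b, sim$x, sim$y, sim$strata), 0)
    expect_true(all(fit$loglik >= lls))
  }
})

test_that("fits agree with the independent survival::clogit implementation", {
  skip_if_not_installed("survival")
  library(survival)
  set.seed(9)
  sim <- simulate_clr_strata(300, 1.5, seed = 9)
  x2 <- cbind(exposure = sim$x, noise = rnorm(length(sim$x)))
  fit <- fit_clr(x2, sim$y, sim$strata)
  cl <- survival::clogit(y ~ exposure + noise + strata(s),
                         data = data.frame(exposure = x2[, 1], noise = x2[, 2],
                                           y = sim$y, s = sim$strata))
  expect_equal(unname(fit$coef), unname(coef(cl)), tolerance = 1e-7)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(cl)))), tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(cl)), tolerance = 1e-8)
})

test_that("CLR fit is invariant to stratum-constant exposure shifts", {
  sim <- simulate_clr_strata(200, 1.4, seed = 11)
  fit1 <- fit_clr(sim$x, sim$y, sim$strata)
  shift <- rep(rnorm(200, 0, 5), each = 4)
  fit2 <- fit_clr(sim$x + shift, sim$y, sim$strata)
  expect_equal(fit1$coef, fit2$coef, tolerance = 1e-7)
})

test_that("aic and CI fields satisfy their defining identities", {
  sim <- simulate_clr_strata(150, 1.3, seed = 12)
  x2 <- cbind(a = sim$x, b = rnorm(length(sim$x)))
  fit <- fit_clr(x2, sim$y, sim$strata)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * 2)
  expect_true(fit$loglik <= 0 && fit$loglik_null <= 0)
  expect_true(all(fit$ci_lo < fit$or & fit$or < fit$ci_hi))
})

test_that("degenerate designs raise explicit errors", {
  sim <- simulate_clr_strata(50, 1.0, seed = 13)
  # identical case/control exposures: flat likelihood
  expect_error(
    suppressMessages(fit_clr(rep(1, length(sim$x)), sim$y, sim$strata)),
    "flat likelihood")
  # rank-deficient design names the offending column
  x2 <- cbind(a = sim$x, b = 2 * sim$x)
  expect_error(fit_clr(x2, sim$y, sim$strata), "rank-deficient.*b")
  # complete separation: case always the within-stratum maximum
  set.seed(13)
  xs <- matrix(rnorm(200 * 4), 200, 4)
  ys <- matrix(0L, 200, 4); ys[cbind(1:200, max.col(xs))] <- 1L
  expect_error(fit_clr(as.vector(t(xs)), as.vector(t(ys)), rep(1:200, each = 4)),
               "separation")
})

test_that("or_ci rescales ORs log-linearly with exact Wald arithmetic", {
  sim <- simulate_clr_strata(200, 1.5, seed = 14)
  fit <- fit_clr(sim$x, sim$y, sim$strata)
  u1 <- or_ci(fit, 1, 1); u10 <- or_ci(fit, 1, 10)
  expect_equal(u10$or, u1$or^10)
  expect_equal(u10$lo, u1$lo^10)
  expect_equal(u10$p, u1$p)   # p is scale-invariant
  # closed-form check at beta = 0, se = 0.1
  fake <- fit; fake$coef[] <- 0; fake$se[] <- 0.1
  ci <- or_ci(fake, 1, 1)
  expect_equal(unname(c(ci$or, ci$lo, ci$hi)),
               c(1, exp(-qnorm(0.975) * 0.1), exp(qnorm(0.975) * 0.1)))
  expect_equal(round(unname(c(ci$lo, ci$hi)), 2), c(0.82, 1.22))
  expect_error(or_ci(structure(list(converged = FALSE), class = "clr_fit")),
               "converge")
})

test_that("adding signal lowers AIC; adding noise raises it on average", {
  set.seed(15)
  diffs_signal <- diffs_noise <- numeric(30)
  for (i in 1:30) {
    n <- 150
    x1 <- matrix(rnorm(n * 4), n, 4)
    x2 <- matrix(rnorm(n * 4), n, 4)
    sc <- exp(0.8 * x1 + 0.8 * x2)
    case <- vapply(seq_len(n), function(s)
      sample.int(4, 1, prob = sc[s, ]), 0L)
    y <- matrix(0L, n, 4); y[cbind(seq_len(n), case)] <- 1L
    xv1 <- as.vector(t(x1)); xv2 <- as.vector(t(x2))
    yv <- as.vector(t(y)); st <- rep(seq_len(n), each = 4)
    base <- fit_clr(xv1, yv, st)
    with_signal <- fit_clr(cbind(xv1, xv2), yv, st)
    with_noise <- fit_clr(cbind(xv1, rnorm(length(xv1))), yv, st)
    diffs_signal[i] <- with_signal$aic - base$aic
    diffs_noise[i] <- with_noise$aic - base$aic
  }
  expect_true(all(diffs_signal < 0))
  expect_gt(mean(diffs_noise), 0)
})

test_that("effect-modifier screening retains planted interactions and handles edge cases", {
  set.seed(16)
  n <- 400
  x <- matrix(rnorm(n * 4), n, 4)
  mod <- matrix(rbinom(n * 4, 1, 0.5), n, 4)        # varies within stratum
  sc <- exp(0.3 * x + 1.2 * mod)
  case <- vapply(seq_len(n), function(s) sample.int(4, 1, prob = sc[s, ]), 0L)
  y <- matrix(0L, n, 4); y[cbind(seq_len(n), case)] <- 1L
  xb <- cbind(exposure = as.vector(t(x)))
  yv <- as.vector(t(y)); st <- rep(seq_len(n), each = 4)
  groups <- list(comorbidity = data.frame(strong = as.vector(t(mod))),
                 degenerate = data.frame(flat = rep(1, n * 4)))
  res <- screen_effect_modifiers(xb, yv, st, groups)
  expect_true(res$retained[res$modifier == "strong"])
  expect_true("degenerate" %in% names(attr(res, "errors")))
  # empty modifier list leaves nothing to retain
  empty <- screen_effect_modifiers(xb, yv, st, list())
  expect_equal(nrow(empty), 0L)
  # interaction mode runs and reports the product term
  res_int <- screen_effect_modifiers(xb, yv, st,
                                     list(g = data.frame(m = as.vector(t(mod)))),
                                     mode = "interaction")
  expect_equal(nrow(res_int), 1L)
})
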