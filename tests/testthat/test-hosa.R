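test_that("OR-vs-reference-CI verdicts follow the point-outside-interval rule", {
  expect_equal(compare_or_to_reference(1.20, c(1.10, 1.30), 1.05, c(1.02, 1.10)),
               "higher")
  expect_equal(compare_or_to_reference(1.05, c(1.0, 1.12), 1.06, c(1.02, 1.10)),
               "not_significant")
  expect_equal(compare_or_to_reference(0.95, c(0.9, 1.0), 1.06, c(1.02, 1.10)),
               "lower")
  # a point exactly on the bound is not significant (strict inequality)
  expect_equal(compare_or_to_reference(1.10, c(1.05, 1.15), 1.06, c(1.02, 1.10)),
               "not_significant")
  expect_error(compare_or_to_reference(1.2, c(1.3, 1.1), 1, c(0.9, 1.1)),
               "malformed")
  # z-test mode is available and agrees on a clear-cut case
  expect_equal(compare_or_to_reference(2.0, c(1.9, 2.11), 1.0, c(0.95, 1.05),
                                       mode = "ztest"), "higher")
})

test_that("the interval rule's type-I level is anti-conservative, as measured", {
  # two independent ORs with identical truth; nominal z-test level would be 5%
  set.seed(20)
  n <- 2000
  se <- 0.05
  a <- exp(rnorm(n, 0, se)); b <- exp(rnorm(n, 0, se))
  zq <- qnorm(0.975)
  verdicts <- vapply(seq_len(n), function(i)
    compare_or_to_reference(a[i], a[i] * exp(c(-1, 1) * zq * se),
                            b[i], b[i] * exp(c(-1, 1) * zq * se)), "")
  rate <- mean(verdicts != "not_significant")
  # P(|N(0, sqrt(2) se)| > 1.96 se) = 16.6%
  expect_gt(rate, 0.10)
  expect_lt(rate, 0.25)
})

test_that("implied spans expand summary labels to individual lags", {
  expect_equal(implied_span(c("0", "1", "01", "04")), 0:4)
  expect_equal(implied_span(c("0", "1", "01")), 0:1)
  expect_equal(implied_span("24"), 2:4)
  expect_equal(implied_span(character()), integer())
  expect_error(implied_span("05"), "unknown lag")
})

test_that("HOSA width is the contiguous run containing lag 0", {
  h5 <- hosa_width(c("0", "1", "01", "04"))
  expect_equal(h5[c("hosa_grids", "hosa_km", "hosa_km2")],
               list(hosa_grids = 5L, hosa_km = 60, hosa_km2 = 720))
  h2 <- hosa_width(c("0", "1", "01"))
  expect_equal(h2[c("hosa_grids", "hosa_km", "hosa_km2")],
               list(hosa_grids = 2L, hosa_km = 24, hosa_km2 = 288))
  h0 <- hosa_width("24")
  expect_equal(h0$hosa_grids, 0L)
  expect_false(h0$contiguous)
  expect_equal(hosa_width(character())$hosa_grids, 0L)
  expect_equal(h5$n_sig_labels, 4L)
})

test_that("HOSA width is monotone under adding significant labels", {
  labels <- c("0", "1", "2", "3", "4", "01", "24", "04")
  set.seed(21)
  for (i in 1:200) {
    base <- sample(labels, sample(0:7, 1))
    extra <- sample(setdiff(labels, base), 1)
    expect_gte(hosa_width(c(base, extra))$hosa_grids,
               hosa_width(base)$hosa_grids)
  }
})

test_that("delta OR percent satisfies its exact identity and sign behaviour", {
  expect_equal(delta_or_pct(1.10, 1.00), 10)
  expect_equal(delta_or_pct(0.95, 1.00), -5)
  expect_equal(delta_or_pct(1.37, 1.37), 0)
  expect_error(delta_or_pct(1, 0), "positive")
  set.seed(22)
  a <- runif(100, 0.5, 2); b <- runif(100, 0.5, 2)
  expect_equal(delta_or_pct(a, b), 100 * (a / b - 1))
})

test_that("run_hosa_analysis assembles significant-lag sets per cell", {
  lags <- c("0", "1", "2", "3", "4", "01", "24", "04")
  mk <- function(surface, condition, or, w = 0.03) {
    data.frame(surface = surface, outcome = "ED_asthma", condition = condition,
               lag = lags, or = or, lo = or * exp(-w), hi = or * exp(w))
  }
  fits <- rbind(
    mk("PMB", "both", rep(1.00, 8)),
    mk("PMCK", "both", c(1.3, 1.3, 1, 1, 1, 1.3, 1, 1.3)),  # sig at 0,1,01,04
    mk("PMCQ", "both", rep(1.00, 8)))                        # identical: all ns
  res <- run_hosa_analysis(fits)
  pmck <- res$hosa[res$hosa$surface == "PMCK", ]
  expect_equal(pmck$hosa_grids, 5L)
  expect_equal(pmck$hosa_km2, 720)
  expect_equal(pmck$label, "4 (0, 1, 01, 04)")
  pmcq <- res$hosa[res$hosa$surface == "PMCQ", ]
  expect_equal(pmcq$hosa_grids, 0L)
  expect_equal(pmcq$label, "0")
  # missing baseline for a lag aborts
  expect_error(run_hosa_analysis(rbind(mk("PMB", "both", rep(1, 8))[-1, ],
                                       mk("PMCK", "both", rep(1.3, 8)))),
               "missing baseline")
  expect_error(run_hosa_analysis(mk("PMCK", "both", rep(1, 8))), "no baseline")
})

test_that("monitor and season contrasts emit signed delta-OR rows", {
  lags <- c("0", "1", "01", "04")
  mk <- function(surface, condition, or, season = "all") {
    data.frame(surface = surface, outcome = "IP_MI", condition = condition,
               lag = lags, or = or, lo = or * exp(-0.02), hi = or * exp(0.02),
               season = season)
  }
  fits <- rbind(mk("PMB", "both", rep(1, 4)),
                mk("PMCK", "both", rep(1.2, 4)),
                mk("PMCK", "no", rep(1.3, 4)), mk("PMB", "no", rep(1, 4)),
                mk("PMCK", "yes", rep(1.1, 4)), mk("PMB", "yes", rep(1, 4)),
                mk("PMCK", "both", rep(1.4, 4), season = "warm"),
                mk("PMCK", "both", rep(1.1, 4), season = "cold"))
  res <- run_hosa_analysis(fits)
  dm <- res$delta_or[res$delta_or$contrast == "noMonitor_vs_monitor" &
                       res$delta_or$surface == "PMCK", ]
  expect_equal(unique(round(dm$delta_or_pct, 6)),
               round(100 * (1.3 / 1.1 - 1), 6))
  expect_true(all(dm$verdict == "higher"))
  ds <- res$delta_or[res$delta_or$contrast == "warm_vs_cold", ]
  expect_equal(unique(round(ds$delta_or_pct, 6)),
               round(100 * (1.4 / 1.1 - 1), 6))
})

test_that("a planted no-monitor advantage is recovered as a monitor contrast", {
  # no-monitor strata carry a genuinely larger exposure effect
  set.seed(23)
  mkstr <- function(beta, n) {
    x <- matrix(rnorm(n * 4, 14, 3), n, 4)
    case <- vapply(seq_len(n), function(s)
      sample.int(4, 1, prob = exp(beta * (x[s, ] - 14))), 0L)
    y <- matrix(0L, n, 4); y[cbind(seq_len(n), case)] <- 1L
    list(x = as.vector(t(x)), y = as.vector(t(y)), s = rep(seq_len(n), each = 4))
  }
  fit_row <- function(d, cond) {
    f <- fit_clr(d$x, d$y, d$s); ci <- or_ci(f, 1, 10)
    data.frame(surface = "PMCK", outcome = "ED_asthma", condition = cond,
               lag = "0", or = ci$or, lo = ci$lo, hi = ci$hi)
  }
  fits <- rbind(fit_row(mkstr(log(2.2) / 10, 1500), "no"),
                fit_row(mkstr(log(1.2) / 10, 1500), "yes"))
  v <- compare_or_to_reference(fits$or[2], c(fits$lo[2], fits$hi[2]),
                               fits$or[1], c(fits$lo[1], fits$hi[1]))
  expect_equal(v, "lower")   # monitor OR significantly below no-monitor OR
  expect_gt(delta_or_pct(fits$or[1], fits$or[2]), 0)
})
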