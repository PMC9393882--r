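# Independent oracles, kept deliberately naive: plain loops and direct
# formulas, no shared code with the implementation paths they check.

# Moran's I by explicit double summation.
moran_brute <- function(x, w) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n))
    for (j in seq_len(n))
      num <- num + w[i, j] * z[i] * z[j]
  (n / sum(w)) * num / sum(z^2)
}

# Conditional log-likelihood by direct per-stratum enumeration (no
# log-sum-exp stabilization).
clr_loglik_brute <- function(beta, x, y, strata) {
  x <- as.matrix(x)
  ll <- 0
  for (s in unique(strata)) {
    idx <- which(strata == s)
    eta <- as.vector(x[idx, , drop = FALSE] %*% beta)
    ll <- ll + eta[y[idx] == 1] - log(sum(exp(eta)))
  }
  ll
}

# One-parameter maximizer by dense grid search (coarse-to-fine).
grid_search_beta <- function(x, y, strata, lo = -2, hi = 2) {
  f <- function(b) clr_loglik_brute(b, x, y, strata)
  for (pass in 1:4) {
    grid <- seq(lo, hi, length.out = 201)
    ll <- vapply(grid, f, 0)
    best <- grid[which.max(ll)]
    step <- grid[2] - grid[1]
    lo <- best - 2 * step
    hi <- best + 2 * step
  }
  best
}

# Pearson chi-square from first principles for a 2-way count table.
chisq_brute <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}

# A tiny complete exposure table: one grid, one year, monthly value = month
# index for surface "S", so referent means are knowable by hand.
month_value_exposure <- function(row = 5, col = 5, year = 2004) {
  data.frame(row = row, col = col, year = year, month = 1:12,
             S = 1:12, at_f = 50 + 1:12, pollen = 0, holiday = 0,
             snowstorm = 0)
}

# Minimal single-event table.
one_event <- function(row = 5, col = 5, date = "2004-07-15",
                      outcome = "ED_asthma") {
  data.frame(event_id = "e1", outcome = outcome, date = date,
             row = row, col = col, age = 40, gender = "F", race = "White",
             insurance = "private", zip = "Z0505",
             athero = FALSE, diabetes = FALSE, htn = FALSE,
             stringsAsFactors = FALSE)
}
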