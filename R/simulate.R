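#' Configuration for the synthetic study generator
#'
#' Bundles the generating parameters for a synthetic three-year study on the
#' lattice: five correlated exposure surfaces with a warm-season peak,
#' monitor/no-monitor level offsets, spatially smoothed fields, missingness in
#' the non-gap-filled surfaces, confounder columns, and health events whose
#' log-odds rise linearly with index-grid exposure.
#'
#' Surface cross-correlations with the baseline are controlled by the
#' surface-specific noise standard deviations (`surface_noise_sd`); the
#' defaults give the ordering r(PMCQ) > r(PMCKQ) > r(PMC) > r(PMCK) seen in
#' monitor-network evaluations. Monitor offsets follow the observed pattern:
#' all surfaces except PMCK average higher in monitor grids; PMCK sits
#' slightly higher in no-monitor grids.
#'
#' @param seed integer seed; every generator draw derives from it.
#' @param years study years (default 2004:2006).
#' @param lattice a [grid_lattice()] (default [baltimore_lattice()]).
#' @param baseline_monthly_mean overall monthly mean, ug/m3 (default 14).
#' @param seasonal_amplitude cosine amplitude peaking in July, ug/m3.
#' @param monitor_offset named ug/m3 offsets added in monitor grids.
#' @param spatial_correlation_range moving-average smoothing radius in grids.
#' @param field_sd standard deviation of the shared smoothed monthly field.
#' @param surface_noise_sd named per-surface independent noise sd (drives the
#'   cross-correlation ordering).
#' @param missingness_rate fraction of grid-months masked in PMC and PMCQ.
#' @param true_or_per_10ug named per-outcome true odds ratio per 10 ug/m3.
#' @param effect_surface surface whose index-grid value drives event risk.
#' @param effect_spatial_range_grids Chebyshev radius around the source grids
#'   within which the exposure effect applies (default covers the lattice).
#' @param source_grids optional data.frame of (row, col) effect sources;
#'   default all cells.
#' @param events_per_outcome cases generated per outcome.
#' @param outcomes outcome labels.
#' @param demographics list of category probabilities for gender/race/insurance.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       years = 2004:2006,
                       lattice = baltimore_lattice(),
                       baseline_monthly_mean = 14,
                       seasonal_amplitude = 2.5,
                       monitor_offset = c(PMB = 0.5, PMC = 0.3, PMCK = -0.12,
                                          PMCQ = 0.55, PMCKQ = 0.4),
                       spatial_correlation_range = 2L,
                       field_sd = 1.5,
                       surface_noise_sd = c(PMB = 0.4, PMC = 1.6, PMCK = 2.3,
                                            PMCQ = 0.5, PMCKQ = 1.0),
                       missingness_rate = 0.2,
                       true_or_per_10ug = c(ED_asthma = 1.5, IP_asthma = 1.5,
                                            IP_MI = 1.5, IP_HF = 1.5),
                       effect_surface = "PMB",
                       effect_spatial_range_grids = 99L,
                       source_grids = NULL,
                       events_per_outcome = 400L,
                       outcomes = c("ED_asthma", "IP_asthma", "IP_MI", "IP_HF"),
                       demographics = list(
                         gender = c(F = 0.55, M = 0.45),
                         race = c(Black = 0.35, Other = 0.05, White = 0.60),
                         insurance = c(private = 0.5, medicaid = 0.25,
                                       medicare = 0.25))) {
  stopifnot(missingness_rate >= 0, missingness_rate <= 1,
            seasonal_amplitude >= 0, all(true_or_per_10ug > 0),
            field_sd >= 0, all(surface_noise_sd >= 0))
  structure(as.list(environment()), class = "sim_config")
}

surfaces_all <- c("PMB", "PMC", "PMCK", "PMCQ", "PMCKQ")

# moving-average smoothing of a lattice field (values aligned to cells)
smooth_field <- function(values, lattice, range) {
  if (range <= 0) return(values)
  cells <- lattice$cells
  out <- numeric(length(values))
  for (i in seq_along(values)) {
    nb <- abs(cells$row - cells$row[i]) <= range &
      abs(cells$col - cells$col[i]) <= range
    out[i] <- mean(values[nb], na.rm = TRUE)
  }
  out
}

#' Simulate the monthly exposure surfaces
#'
#' Monthly grid values are baseline + seasonal cosine (warm-season peak) +
#' a spatially smoothed shared field + monitor-condition offset + surface
#' noise, truncated at zero. PMC and PMCQ are masked at the configured
#' missingness rate; PMCK and PMCKQ are their gap-filled copies (missing
#' values replaced by the neighbourhood mean of the observed ones) with extra
#' smoothing noise, and are never missing. Apparent temperature, pollen,
#' holiday and snowstorm columns are generated alongside.
#'
#' @param config a [sim_config()].
#' @return Long exposure table: `row`, `col`, `year`, `month`, the five
#'   surface columns, `at_f`, `pollen`, `holiday`, `snowstorm`.
#' @export
simulate_exposure_surfaces <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lat <- config$lattice
  cells <- lat$cells
  nc <- nrow(cells)
  grid_tab <- expand.grid(month = 1:12, year = config$years)
  n_ym <- nrow(grid_tab)
  mon <- as.numeric(cells$has_monitor)

  rows <- vector("list", n_ym)
  for (t in seq_len(n_ym)) {
    month <- grid_tab$month[t]
    seasonal <- config$seasonal_amplitude * cos(2 * pi * (month - 7) / 12)
    field <- smooth_field(stats::rnorm(nc, 0, config$field_sd * 2), lat,
                          config$spatial_correlation_range)
    field <- field * config$field_sd / max(stats::sd(field), 1e-9)
    common <- config$baseline_monthly_mean + seasonal + field

    val <- function(surf) pmax(0, common +
      config$monitor_offset[[surf]] * mon +
      stats::rnorm(nc, 0, config$surface_noise_sd[[surf]]))
    pmb <- val("PMB"); pmc <- val("PMC"); pmcq <- val("PMCQ")
    if (config$missingness_rate > 0) {
      pmc[stats::runif(nc) < config$missingness_rate] <- NA
      pmcq[stats::runif(nc) < config$missingness_rate] <- NA
    }
    gap_fill <- function(x, offset_from, offset_to, extra_sd) {
      filled <- x
      if (anyNA(x)) {
        sm <- smooth_field(x, lat, max(config$spatial_correlation_range, 1L))
        sm[is.na(sm)] <- mean(x, na.rm = TRUE)
        filled[is.na(x)] <- sm[is.na(x)]
      }
      pmax(0, filled + (offset_to - offset_from) * mon +
             stats::rnorm(nc, 0, extra_sd))
    }
    pmck <- gap_fill(pmc, config$monitor_offset[["PMC"]],
                     config$monitor_offset[["PMCK"]],
                     sqrt(max(config$surface_noise_sd[["PMCK"]]^2 -
                                config$surface_noise_sd[["PMC"]]^2, 0.01)))
    pmckq <- gap_fill(pmcq, config$monitor_offset[["PMCQ"]],
                      config$monitor_offset[["PMCKQ"]],
                      sqrt(max(config$surface_noise_sd[["PMCKQ"]]^2 -
                                 config$surface_noise_sd[["PMCQ"]]^2, 0.01)))
    # year-month weather anomaly shared across grids, plus grid-level noise,
    # so covariates do not deterministically fingerprint the referent month
    # sets (which would quasi-separate the conditional likelihood)
    at <- 56 + 14 * cos(2 * pi * (month - 7) / 12) + 1.5 * mon +
      stats::rnorm(1, 0, 2.5) + stats::rnorm(nc, 0, 2)
    pollen <- pmax(0, 40 * cos(2 * pi * (month - 5.5) / 12)) *
      exp(stats::rnorm(nc, 0, 0.6)) + stats::rpois(nc, 2)
    holiday <- c(2, 1, 0, 1, 1, 0, 1, 1, 1, 0, 2, 3)[month] / 30 *
      exp(stats::rnorm(nc, 0, 0.5))
    snow <- as.numeric(month %in% c(12, 1, 2, 3) & stats::runif(nc) < 0.15)
    rows[[t]] <- data.frame(row = cells$row, col = cells$col,
                            year = grid_tab$year[t], month = month,
                            PMB = pmb, PMC = pmc, PMCK = pmck, PMCQ = pmcq,
                            PMCKQ = pmckq, at_f = at, pollen = pollen,
                            holiday = holiday, snowstorm = snow)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate health events with a planted exposure effect
#'
#' Candidate person-days are drawn uniformly over grids with health data and
#' study months; a candidate becomes a case with probability proportional to
#' `exp(log(true OR per 10)/10 * exposure(index grid, month))`, the exposure
#' effect applying only in grids within `effect_spatial_range_grids`
#' (Chebyshev distance) of the configured source grids. Demographics follow
#' the configured mix; events carry the matching variables used downstream.
#'
#' @param config a [sim_config()].
#' @param exposure table from [simulate_exposure_surfaces()].
#' @return Health-event data.frame consumable by [build_strata()].
#' @export
simulate_health_events <- function(config, exposure) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  lat <- config$lattice
  cells <- lat$cells[lat$cells$has_health_data, , drop = FALSE]
  src <- if (is.null(config$source_grids)) lat$cells else
    as.data.frame(config$source_grids)
  in_range <- vapply(seq_len(nrow(cells)), function(i)
    any(pmax(abs(src[[1]] - cells$row[i]),
             abs(src[[2]] - cells$col[i])) <= config$effect_spatial_range_grids),
    TRUE)
  ev_list <- list()
  for (oc in config$outcomes) {
    n_target <- config$events_per_outcome
    if (n_target == 0L) next
    n_cand <- max(20L, n_target * 5L)
    ci <- sample.int(nrow(cells), n_cand, replace = TRUE)
    yr <- sample(config$years, n_cand, replace = TRUE)
    mo <- sample.int(12L, n_cand, replace = TRUE)
    day <- sample.int(28L, n_cand, replace = TRUE)
    key_e <- paste(exposure$row, exposure$col, exposure$year, exposure$month)
    pm <- exposure[[config$effect_surface]][
      match(paste(cells$row[ci], cells$col[ci], yr, mo), key_e)]
    pm[is.na(pm)] <- mean(pm, na.rm = TRUE)
    beta <- log(config$true_or_per_10ug[[oc]]) / 10
    lp <- ifelse(in_range[ci], beta * pm, 0)
    pick <- sample.int(n_cand, min(n_target, n_cand), prob = exp(lp - max(lp)))
    n <- length(pick)
    draw <- function(p) sample(names(p), n, replace = TRUE, prob = p)
    ev_list[[oc]] <- data.frame(
      event_id = sprintf("%s_%05d", oc, seq_len(n)),
      outcome = oc,
      date = as.Date(sprintf("%d-%02d-%02d", yr[pick], mo[pick], day[pick])),
      row = cells$row[ci[pick]], col = cells$col[ci[pick]],
      age = sample(5:90, n, replace = TRUE),
      gender = draw(config$demographics$gender),
      race = draw(config$demographics$race),
      insurance = draw(config$demographics$insurance),
      zip = sprintf("Z%02d%02d", cells$row[ci[pick]], cells$col[ci[pick]]),
      athero = stats::runif(n) < 0.2,
      diabetes = stats::runif(n) < 0.25,
      htn = stats::runif(n) < 0.4,
      stringsAsFactors = FALSE)
  }
  if (!length(ev_list))
    return(data.frame(event_id = character(), outcome = character(),
                      date = as.Date(character()), row = integer(),
                      col = integer(), age = integer(), gender = character(),
                      race = character(), insurance = character(),
                      zip = character(), athero = logical(),
                      diabetes = logical(), htn = logical()))
  out <- do.call(rbind, ev_list)
  rownames(out) <- NULL
  out
}

#' Simulate a complete synthetic study
#'
#' Composition of [simulate_exposure_surfaces()] and
#' [simulate_health_events()], with the generating parameters attached as the
#' `truth` record. Bit-for-bit reproducible from the config (which carries
#' the seed).
#'
#' @param config a [sim_config()].
#' @return list of class `sim_study` with `exposure`, `events`, `truth`.
#' @export
simulate_study <- function(config = sim_config()) {
  exposure <- simulate_exposure_surfaces(config)
  events <- simulate_health_events(config, exposure)
  structure(list(exposure = exposure, events = events,
                 truth = unclass(config)[setdiff(names(config), "lattice")],
                 lattice = config$lattice),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("sim_study: %d exposure grid-months, %d events (%s)\n",
              nrow(x$exposure), nrow(x$events),
              paste(unique(x$events$outcome), collapse = ", ")))
  invisible(x)
}

#' Simulate matched strata directly under the conditional model
#'
#' Generates 1:M matched strata from the exact model conditional logistic
#' regression fits: member exposures are independent normals and the case slot
#' is drawn within each stratum with probability proportional to
#' `exp(log(true OR per 10)/10 * exposure)`. This is the calibration
#' generator for coverage and parameter-recovery experiments, bypassing the
#' study-level machinery.
#'
#' @param n_strata number of strata.
#' @param true_or_per_10ug true odds ratio per 10 exposure units.
#' @param exposure_mean,exposure_sd member exposure distribution.
#' @param n_controls controls per case (default 3).
#' @param seed optional seed.
#' @return list with `x` (exposure vector), `y` (case indicator), `strata`.
#' @export
simulate_clr_strata <- function(n_strata, true_or_per_10ug = 1.5,
                                exposure_mean = 14, exposure_sd = 3,
                                n_controls = 3L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- n_controls + 1L
  beta <- log(true_or_per_10ug) / 10
  x <- matrix(stats::rnorm(n_strata * m, exposure_mean, exposure_sd),
              n_strata, m)
  w <- exp(beta * (x - x[, 1]))           # stabilized within-stratum weights
  u <- stats::runif(n_strata) * rowSums(w)
  case <- apply(t(apply(w, 1, cumsum)) >= u, 1, which.max)
  y <- matrix(0L, n_strata, m)
  y[cbind(seq_len(n_strata), case)] <- 1L
  list(x = as.vector(t(x)), y = as.vector(t(y)),
       strata = rep(seq_len(n_strata), each = m))
}

#' Simulate lag-grid strata with a planted spatial effect range
#'
#' The calibration generator for HOSA recovery. Each stratum member carries
#' exposures at lag grids 0-4 on two surfaces: a baseline surface `b` and an
#' experimental surface `e = b + u`, where `u` is an experimental-specific
#' component (e.g. satellite information absent from the baseline). The case
#' is drawn within each stratum with probability proportional to
#' `exp(beta0 * mean_k b_k + betax * sum_{k <= range} u_k)`: the shared
#' component acts at all lags (so the baseline surface shows elevated ORs
#' everywhere, as observed for real baselines), while the extra component
#' acts only within the planted range. With `betax = 0.3 * beta0` the
#' experimental-vs-baseline OR contrast is positive at exactly the lag labels
#' spanning the planted range (see the methods vignette for the algebra and
#' the power calculation behind the default effect sizes; exposure units are
#' abstract, and the planted effects are deliberately strong so that the
#' delineation logic rather than statistical power is under test).
#'
#' @param n_strata number of strata.
#' @param effect_range_grids planted range r: the extra component acts at
#'   lags 0..r (use 0, 1 or 4).
#' @param beta_common shared-component log-odds per exposure unit.
#' @param extra_ratio betax / beta0 (default 0.3; must stay in (0.2, 0.4)
#'   for the label algebra to single out the planted range).
#' @param sd_base,sd_extra standard deviations of the shared and extra
#'   components.
#' @param exposure_mean location of the baseline exposures.
#' @param n_controls controls per case.
#' @param seed optional seed.
#' @return list with arrays `baseline` and `experimental`
#'   (stratum x member x lag), `y` (stratum x member case indicator) and
#'   `truth`.
#' @export
simulate_lag_strata <- function(n_strata, effect_range_grids,
                                beta_common = 0.25, extra_ratio = 0.3,
                                sd_base = 10, sd_extra = 10,
                                exposure_mean = 14, n_controls = 3L,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(effect_range_grids %in% 0:4)
  m <- n_controls + 1L
  beta0 <- beta_common
  betax <- extra_ratio * beta0
  b <- array(stats::rnorm(n_strata * m * 5L, exposure_mean, sd_base),
             c(n_strata, m, 5L))
  u <- array(stats::rnorm(n_strata * m * 5L, 0, sd_extra), c(n_strata, m, 5L))
  e <- b + u
  score <- beta0 * rowMeans(b, dims = 2) +
    betax * rowSums(u[, , seq_len(effect_range_grids + 1L), drop = FALSE], dims = 2)
  w <- exp(score - score[, 1])
  csum <- t(apply(w, 1, cumsum))
  uu <- stats::runif(n_strata) * csum[, m]
  case <- apply(csum >= uu, 1, which.max)
  y <- matrix(0L, n_strata, m)
  y[cbind(seq_len(n_strata), case)] <- 1L
  list(baseline = b, experimental = e, y = y,
       truth = list(effect_range_grids = effect_range_grids, beta0 = beta0,
                    betax = betax))
}

#' Fit both surfaces of a planted lag-strata simulation at every lag label
#'
#' Runs [fit_clr()] on the baseline and experimental surfaces of a
#' [simulate_lag_strata()] draw at each lag label (covariate = mean member
#' exposure over the label's individual lags), returning the fit table
#' consumed by [run_hosa_analysis()].
#'
#' @param sim a [simulate_lag_strata()] result.
#' @param lags lag labels to fit.
#' @param scale OR reporting scale (default per 10 units).
#' @return data.frame with `surface`, `outcome`, `condition`, `lag`, `or`,
#'   `lo`, `hi`, `p`.
#' @export
lag_strata_fits <- function(sim, lags = lag_labels_all, scale = 10) {
  n <- dim(sim$y)[1]; m <- dim(sim$y)[2]
  strata <- rep(seq_len(n), each = m)
  y <- as.vector(t(sim$y))
  rows <- list()
  for (surf in c("baseline", "experimental")) {
    arr <- sim[[surf]]
    for (lab in lags) {
      mem <- lag_label_members(lab) + 1L
      cov <- if (length(mem) == 1L) arr[, , mem] else
        rowMeans(arr[, , mem, drop = FALSE], dims = 2)
      fit <- fit_clr(as.vector(t(cov)), y, strata)
      ci <- or_ci(fit, 1L, scale)
      rows[[paste(surf, lab)]] <- data.frame(
        surface = surf, outcome = "sim", condition = "both", lag = lab,
        or = ci$or, lo = ci$lo, hi = ci$hi, p = ci$p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
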