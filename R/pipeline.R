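#' Read and write the study input tables
#'
#' Header-first delimited text. The exposure table needs `row`, `col`,
#' `year`, `month` plus surface/covariate columns; the event table needs
#' `event_id`, `outcome`, `date` and either `row`/`col` or centroid columns.
#' Parse failures abort naming the file.
#'
#' @param file path to a delimited text file.
#' @return data.frame.
#' @export
read_exposure_table <- function(file) {
  out <- tryCatch(utils::read.csv(file, stringsAsFactors = FALSE),
                  error = function(e) stop("cannot parse exposure file '", file,
                                           "': ", conditionMessage(e)))
  check_exposure_table(out, character())
  out
}

#' @rdname read_exposure_table
#' @export
read_health_events <- function(file) {
  out <- tryCatch(utils::read.csv(file, stringsAsFactors = FALSE),
                  error = function(e) stop("cannot parse event file '", file,
                                           "': ", conditionMessage(e)))
  miss <- setdiff(c("event_id", "outcome", "date"), names(out))
  if (length(miss))
    stop("event file '", file, "' lacks columns: ", paste(miss, collapse = ", "))
  out
}

#' @rdname read_exposure_table
#' @param x table to write.
#' @export
write_study_table <- function(x, file) {
  utils::write.csv(x, file, row.names = FALSE, quote = FALSE, na = "")
  invisible(file)
}

#' Analysis settings for the end-to-end pipeline
#'
#' @param surfaces surfaces to analyse (first entry after `baseline` are the
#'   experimental surfaces).
#' @param baseline baseline surface compared against (default `"PMB"`).
#' @param outcomes outcomes to analyse (default: all present in the events).
#' @param conditions monitor conditions to fit.
#' @param lags lag labels.
#' @param or_scale exposure units per reported OR (default 10 ug/m3).
#' @param p_screen,p_final screening / final significance thresholds.
#' @param warm_months warm-season months.
#' @param moran_scheme spatial weight scheme for the autocorrelation runs.
#' @param seasonal fit warm/cold season models too (default TRUE).
#' @param include_at_sq add the squared apparent-temperature term at lags 0,
#'   1, 01, 04. Off by default: with monthly aggregation the all-season
#'   referent sets put every control at the annual AT mean, so a convex AT
#'   term can quasi-separate the conditional likelihood (see the methods
#'   vignette).
#' @return list of class `run_config`.
#' @export
run_config <- function(surfaces = surfaces_all, baseline = "PMB",
                       outcomes = NULL,
                       conditions = c("both", "yes", "no"),
                       lags = lag_labels_all, or_scale = 10,
                       p_screen = 0.09, p_final = 0.05,
                       warm_months = 4:9, moran_scheme = "rook",
                       seasonal = TRUE, include_at_sq = FALSE) {
  stopifnot(p_screen > 0, p_screen < 1, p_final > 0, p_final <= p_screen)
  structure(as.list(environment()), class = "run_config")
}

base_covariates <- function(strata, lag, include_at_sq = FALSE) {
  x <- cbind(exposure = strata$exposure, at = strata$at)
  if (include_at_sq && lag %in% c("0", "1", "01", "04"))
    x <- cbind(x, at_sq = strata$at_sq)
  for (cl in c("pollen", "holiday", "snowstorm"))
    if (!all(is.na(strata[[cl]]))) {
      x <- cbind(x, strata[[cl]])
      colnames(x)[ncol(x)] <- cl
    }
  x
}

fit_one_cell <- function(strata, lag, or_scale, include_at_sq = FALSE) {
  sl <- strata[strata$lag == lag, , drop = FALSE]
  x <- base_covariates(sl, lag, include_at_sq)
  ok_rows <- stats::complete.cases(x)
  ok_strat <- !(sl$stratum_id %in% unique(sl$stratum_id[!ok_rows]))
  sl <- sl[ok_strat, , drop = FALSE]
  x <- x[ok_strat, , drop = FALSE]
  if (nrow(sl) == 0L) return(list(error = "no complete strata"))
  fit <- tryCatch(suppressMessages(fit_clr(x, sl$y, sl$stratum_id)),
                  error = function(e) e)
  if (inherits(fit, "error")) return(list(error = conditionMessage(fit)))
  ci <- or_ci(fit, "exposure", or_scale)
  list(fit = fit, or = ci$or, lo = ci$lo, hi = ci$hi, p = ci$p,
       aic = fit$aic, n_strata = fit$n_strata)
}

# Warm/cold ORs from a season-by-exposure interaction in the all-season
# model, computed on seasonally adjusted exposures. The raw quarter-vs-
# referent contrast is dominated by the annual exposure cycle (referent sets
# average the whole year), so a season-specific slope on raw exposure is
# driven to absurd values by that deterministic component. Each member's
# exposure is therefore centred on the cross-grid mean for its month set and
# year (a seasonal climatology), leaving the spatial/meteorological anomaly,
# whose season-specific slopes are identified.
fit_seasonal_cell <- function(strata, lag, or_scale, include_at_sq = FALSE) {
  sl <- strata[strata$lag == lag, , drop = FALSE]
  month_set <- ifelse(sl$role == "case", paste0("case_", sl$quarter), sl$role)
  sl$exposure <- sl$exposure -
    stats::ave(sl$exposure, paste(month_set, sl$year))
  x <- base_covariates(sl, lag, include_at_sq)
  x <- cbind(x, exposure_warm = sl$exposure * (sl$season == "warm"))
  ok_rows <- stats::complete.cases(x)
  ok_strat <- !(sl$stratum_id %in% unique(sl$stratum_id[!ok_rows]))
  sl <- sl[ok_strat, , drop = FALSE]
  x <- x[ok_strat, , drop = FALSE]
  if (nrow(sl) == 0L || length(unique(sl$season)) < 2L)
    return(list(error = "need strata in both seasons"))
  fit <- tryCatch(suppressMessages(fit_clr(x, sl$y, sl$stratum_id)),
                  error = function(e) e)
  if (inherits(fit, "error")) return(list(error = conditionMessage(fit)))
  i1 <- match("exposure", names(fit$coef))
  i2 <- match("exposure_warm", names(fit$coef))
  zq <- stats::qnorm(0.975)
  row_of <- function(b, se) {
    list(or = exp(or_scale * b), lo = exp(or_scale * (b - zq * se)),
         hi = exp(or_scale * (b + zq * se)),
         p = 2 * stats::pnorm(-abs(b / se)), aic = fit$aic,
         n_strata = fit$n_strata)
  }
  b_cold <- fit$coef[i1]
  b_warm <- fit$coef[i1] + fit$coef[i2]
  se_warm <- sqrt(fit$vcov[i1, i1] + fit$vcov[i2, i2] + 2 * fit$vcov[i1, i2])
  list(warm = row_of(b_warm, se_warm), cold = row_of(b_cold, fit$se[i1]))
}

#' Run the full spatial lag-grid case-crossover pipeline
#'
#' Builds strata, fits the base conditional logistic model for every surface
#' x outcome x monitor condition x lag label cell (optionally also per
#' season), delineates HOSAs against the baseline surface, computes
#' delta-OR% contrasts, Moran's I per surface and season, baseline
#' correlations and Below/Within/Above categorical tables. Non-convergent
#' cells are kept as rows with a status flag; every dropped event is
#' accounted for.
#'
#' @param study a `sim_study` (or list with `exposure`, `events`, `lattice`).
#' @param config a [run_config()].
#' @param out_dir optional directory: CSV and JSON outputs are written there
#'   with fixed formatting (ORs to 3 decimals, percents to 1).
#' @return list with `fits`, `hosa`, `delta_or`, `moran`, `correlations`,
#'   `categories`, `accounting`.
#' @export
run_pipeline <- function(study, config = run_config(), out_dir = NULL) {
  exposure <- study$exposure
  events <- study$events
  lattice <- study$lattice
  outcomes <- config$outcomes
  if (is.null(outcomes)) outcomes <- unique(events$outcome)
  surfaces <- unique(c(config$baseline, config$surfaces))

  fits <- list(); acct <- list()
  for (oc in outcomes) {
    ev <- events[events$outcome == oc, , drop = FALSE]
    for (cond in config$conditions) {
      for (surf in surfaces) {
        st <- build_strata(ev, exposure, lattice, cond, surf,
                           lags = config$lags, warm_months = config$warm_months)
        dropped <- attr(st, "dropped")
        acct[[paste(oc, cond, surf)]] <- data.frame(
          outcome = oc, condition = cond, surface = surf,
          n_read = nrow(ev), n_used = length(unique(st$stratum_id)),
          n_dropped = length(unique(dropped$event_id)))
        fit_row <- function(res, lag, seas) data.frame(
          surface = surf, outcome = oc, condition = cond, lag = lag,
          season = seas,
          or = res$or %||% NA_real_, lo = res$lo %||% NA_real_,
          hi = res$hi %||% NA_real_, p = res$p %||% NA_real_,
          aic = res$aic %||% NA_real_,
          n_strata = res$n_strata %||% 0L,
          status = if (is.null(res$error)) "converged" else res$error,
          stringsAsFactors = FALSE)
        for (lag in config$lags) {
          res <- fit_one_cell(st, lag, config$or_scale,
                              config$include_at_sq %||% FALSE)
          fits[[length(fits) + 1L]] <- fit_row(res, lag, "all")
          if (isTRUE(config$seasonal) && cond == "both") {
            sres <- fit_seasonal_cell(st, lag, config$or_scale,
                                      config$include_at_sq %||% FALSE)
            for (seas in c("warm", "cold")) {
              r <- if (is.null(sres$error)) sres[[seas]] else sres
              fits[[length(fits) + 1L]] <- fit_row(r, lag, seas)
            }
          }
        }
      }
    }
  }
  fits <- do.call(rbind, fits)
  acct <- do.call(rbind, acct)
  rownames(fits) <- rownames(acct) <- NULL

  ok <- fits[fits$status == "converged", , drop = FALSE]
  hosa_res <- run_hosa_analysis(ok, baseline = config$baseline,
                                cell_width_km = lattice$cell_width_km)

  # Moran's I on seasonal grid means, plus correlations and categories
  moran <- list(); cors <- list(); cats <- list()
  seas_of <- season_label(exposure$month, config$warm_months)
  for (surf in surfaces) {
    for (seas in c("warm", "cold", "all")) {
      sel <- if (seas == "all") rep(TRUE, nrow(exposure)) else seas_of == seas
      gm <- stats::aggregate(exposure[[surf]][sel],
                             by = list(row = exposure$row[sel],
                                       col = exposure$col[sel]),
                             FUN = mean, na.rm = TRUE)
      names(gm)[3] <- "value"
      mr <- morans_i(gm, lattice, scheme = config$moran_scheme)
      moran[[paste(surf, seas)]] <- data.frame(
        surface = surf, season = seas, I = mr$I, expected = mr$expected,
        Z = mr$Z, p = mr$p, n = mr$n, stringsAsFactors = FALSE)
      if (seas == "all") {
        vals <- exposure[[surf]]
        mu <- mean(vals, na.rm = TRUE)
        se <- stats::sd(vals, na.rm = TRUE) / sqrt(sum(!is.na(vals)))
        ci <- mu + c(-1, 1) * stats::qnorm(0.975) * se
        mon <- lattice$cells$has_monitor[
          match(paste(gm$row, gm$col), paste(lattice$cells$row, lattice$cells$col))]
        ct <- categorize_grids(gm$value, ci, ifelse(mon, "yes", "no"))
        cats[[surf]] <- data.frame(
          surface = surf,
          below = sum(ct$category == "Below"),
          within = sum(ct$category == "Within"),
          above = sum(ct$category == "Above"),
          chi2 = ct$chi2, df = ct$df, p = ct$p,
          stringsAsFactors = FALSE)
      }
    }
    if (surf != config$baseline) {
      for (cond in config$conditions) {
        sub <- condition_subset(lattice, cond)
        sel <- paste(exposure$row, exposure$col) %in% paste(sub$row, sub$col)
        cs <- correlation_summary(exposure[[config$baseline]][sel],
                                  exposure[[surf]][sel])
        cors[[paste(surf, cond)]] <- data.frame(
          pair = paste0(config$baseline, "-", surf), condition = cond,
          r = cs$r, r2_pct = cs$r2_pct, n = cs$n, stringsAsFactors = FALSE)
      }
    }
  }
  moran <- do.call(rbind, moran); rownames(moran) <- NULL
  cors <- do.call(rbind, cors); rownames(cors) <- NULL
  cats <- do.call(rbind, cats); rownames(cats) <- NULL

  out <- list(fits = fits, hosa = hosa_res$hosa, delta_or = hosa_res$delta_or,
              moran = moran, correlations = cors, categories = cats,
              accounting = acct)
  if (!is.null(out_dir)) write_report_bundle(out, out_dir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_num <- function(x, digits) {
  ifelse(is.na(x), "", formatC(x, digits = digits, format = "f"))
}

write_report_bundle <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- results$fits
  for (cl in c("or", "lo", "hi", "aic")) f[[cl]] <- fmt_num(f[[cl]], 3)
  f$p <- ifelse(is.na(results$fits$p), "", formatC(results$fits$p, digits = 4, format = "g"))
  utils::write.csv(f, file.path(out_dir, "fits.csv"), row.names = FALSE)
  utils::write.csv(results$hosa, file.path(out_dir, "hosa_results.csv"),
                   row.names = FALSE)
  if (!is.null(results$delta_or)) {
    d <- results$delta_or
    d$delta_or_pct <- fmt_num(d$delta_or_pct, 1)
    utils::write.csv(d, file.path(out_dir, "delta_or.csv"), row.names = FALSE)
  }
  m <- results$moran
  m$I <- fmt_num(m$I, 4); m$Z <- fmt_num(m$Z, 2)
  m$p <- formatC(results$moran$p, digits = 4, format = "g")
  utils::write.csv(m, file.path(out_dir, "moran.csv"), row.names = FALSE)
  cr <- results$correlations
  cr$r <- fmt_num(cr$r, 3); cr$r2_pct <- fmt_num(cr$r2_pct, 1)
  utils::write.csv(cr, file.path(out_dir, "correlations.csv"), row.names = FALSE)
  utils::write.csv(results$categories, file.path(out_dir, "categories.csv"),
                   row.names = FALSE)
  utils::write.csv(results$accounting, file.path(out_dir, "accounting.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    lapply(results, function(x) if (is.data.frame(x)) x else x),
    file.path(out_dir, "report.json"), dataframe = "rows", auto_unbox = TRUE,
    digits = 6, na = "null")
  invisible(out_dir)
}
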