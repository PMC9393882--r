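#' Compare an odds ratio against a reference OR's confidence interval
#'
#' Two ORs are declared different when the comparison point estimate falls
#' outside the reference's 95% CI: `"higher"` when `or_a` exceeds the upper
#' bound, `"lower"` when it falls below the lower bound, `"not_significant"`
#' otherwise (strict inequalities; a point exactly on a bound is not
#' significant). A formal two-sample z-test on the log-OR difference is
#' available as an alternative mode; the interval rule is anti-conservative
#' relative to it (its realized type-I level is measured in the test suite,
#' not assumed).
#'
#' @param or_a comparison OR (point estimate).
#' @param ci_a its 95% CI as `c(lo, hi)` (used only in `"ztest"` mode, where
#'   the standard errors are recovered from the interval widths).
#' @param or_b reference OR.
#' @param ci_b reference 95% CI as `c(lo, hi)`.
#' @param mode `"interval"` (default) or `"ztest"`.
#' @return `"higher"`, `"lower"` or `"not_significant"`.
#' @export
compare_or_to_reference <- function(or_a, ci_a, or_b, ci_b,
                                    mode = c("interval", "ztest")) {
  mode <- match.arg(mode)
  check_ci <- function(or, ci, nm) {
    if (length(ci) != 2L || !(ci[1] < or && or < ci[2]))
      stop("malformed ", nm, " CI: need lo < point < hi")
  }
  check_ci(or_a, ci_a, "comparison")
  check_ci(or_b, ci_b, "reference")
  if (mode == "interval") {
    if (or_a > ci_b[2]) return("higher")
    if (or_a < ci_b[1]) return("lower")
    return("not_significant")
  }
  zq <- stats::qnorm(0.975)
  se_a <- (log(ci_a[2]) - log(ci_a[1])) / (2 * zq)
  se_b <- (log(ci_b[2]) - log(ci_b[1])) / (2 * zq)
  z <- (log(or_a) - log(or_b)) / sqrt(se_a^2 + se_b^2)
  if (2 * stats::pnorm(-abs(z)) > 0.05) return("not_significant")
  if (z > 0) "higher" else "lower"
}

#' Individual lag grids implied by a significant-lag set
#'
#' Summary labels stand for the individual lags they average: `01` implies
#' lags {0, 1}, `24` implies {2, 3, 4}, `04` implies {0, ..., 4}; individual
#' labels imply themselves.
#'
#' @param sig_lags character vector drawn from
#'   `c("0","1","2","3","4","01","24","04")`.
#' @return Sorted integer vector of implied individual lags.
#' @export
implied_span <- function(sig_lags) {
  sig_lags <- as.character(sig_lags)
  bad <- setdiff(sig_lags, lag_labels_all)
  if (length(bad)) stop("unknown lag label(s): ", paste(bad, collapse = ", "))
  sort(unique(as.integer(unlist(lapply(sig_lags, lag_label_members)))))
}

#' HOSA width from a significant-lag set
#'
#' The homogeneous spatial area is the maximal contiguous run of implied
#' individual lags containing lag 0 (width 0 when lag 0 is absent, flagged
#' as such since the paperless non-contiguous case is never observed in
#' practice). Width and area follow from [hosa_geometry()].
#'
#' @param sig_lags significant lag labels (see [implied_span()]).
#' @param cell_width_km cell width in km (default 12).
#' @return list with `sig_lags`, `n_sig_labels`, `implied_span`,
#'   `hosa_grids`, `hosa_km`, `hosa_km2`, and `contiguous` (FALSE when
#'   implied lags remain outside the run containing lag 0).
#' @examples
#' hosa_width(c("0", "1", "01", "04"))  # 5 grids, 60 km, 720 km^2
#' hosa_width(c("0", "1", "01"))        # 2 grids, 24 km, 288 km^2
#' @export
hosa_width <- function(sig_lags, cell_width_km = 12) {
  span <- implied_span(sig_lags)
  run <- 0L
  while ((run) %in% span) run <- run + 1L   # run = length of 0,1,2,... chain
  geom <- hosa_geometry(run, cell_width_km)
  list(sig_lags = as.character(sig_lags),
       n_sig_labels = length(unique(as.character(sig_lags))),
       implied_span = span,
       hosa_grids = run,
       hosa_km = geom$width_km,
       hosa_km2 = geom$area_km2,
       contiguous = length(setdiff(span, seq_len(run) - 1L)) == 0L)
}

#' Signed percent difference between two odds ratios
#'
#' `delta_or_pct(a, b) = 100 * (a - b) / b`, i.e. how much larger (positive)
#' or smaller (negative) OR `a` is than OR `b`, in percent of `b`. Used for
#' the no-monitor-vs-monitor and warm-vs-cold contrasts.
#'
#' @param or_a,or_b odds ratios; `or_b` must be positive.
#' @return Signed percent difference.
#' @export
delta_or_pct <- function(or_a, or_b) {
  if (any(or_b <= 0)) stop("reference OR must be positive")
  100 * (or_a - or_b) / or_b
}

#' Delineate HOSAs and OR contrasts from a table of CLR fits
#'
#' For every surface x outcome x condition cell, each experimental surface's
#' OR is compared to the baseline surface's OR at every lag label with the
#' interval rule of [compare_or_to_reference()]; the labels where the
#' experimental OR is significantly higher form the significant-lag set, from
#' which [hosa_width()] derives the HOSA size. When fits for both monitor
#' conditions (or both seasons, via an optional `season` column) are present,
#' signed delta-OR% contrasts (no-monitor minus monitor, warm minus cold) are
#' emitted per surface x outcome x lag.
#'
#' @param fits data.frame of converged fits with columns `surface`,
#'   `outcome`, `condition`, `lag`, `or`, `lo`, `hi` and optionally `season`.
#' @param baseline name of the baseline surface (default `"PMB"`).
#' @param cell_width_km cell width for the HOSA geometry.
#' @return list with `hosa` (one row per experimental surface x outcome x
#'   condition: `sig_lags`, `hosa_grids`, `hosa_km`, `hosa_km2`, and a
#'   Table-8-style `label` like `"4 (0, 1, 01, 04)"`) and `delta_or`
#'   (contrast rows with `contrast`, `surface`, `outcome`, `lag`,
#'   `delta_or_pct`, `verdict`).
#' @export
run_hosa_analysis <- function(fits, baseline = "PMB", cell_width_km = 12) {
  needed <- c("surface", "outcome", "condition", "lag", "or", "lo", "hi")
  miss <- setdiff(needed, names(fits))
  if (length(miss)) stop("fits table lacks columns: ", paste(miss, collapse = ", "))
  if (!"season" %in% names(fits)) fits$season <- "all"
  if (!baseline %in% fits$surface)
    stop("no baseline fits for surface '", baseline, "'")
  key <- function(d) paste(d$outcome, d$condition, d$lag, d$season)

  main <- fits[fits$season %in% c("all", NA), , drop = FALSE]
  base <- main[main$surface == baseline, , drop = FALSE]
  exps <- main[main$surface != baseline, , drop = FALSE]

  hosa_rows <- list()
  cells <- unique(exps[, c("surface", "outcome", "condition")])
  for (i in seq_len(nrow(cells))) {
    ce <- exps[exps$surface == cells$surface[i] &
               exps$outcome == cells$outcome[i] &
               exps$condition == cells$condition[i], , drop = FALSE]
    cb <- base[match(key(ce), key(base)), , drop = FALSE]
    if (any(is.na(cb$or)))
      stop("missing baseline fit for ", cells$outcome[i], "/",
           cells$condition[i], " at some lag")
    sig <- ce$lag[vapply(seq_len(nrow(ce)), function(j)
      compare_or_to_reference(ce$or[j], c(ce$lo[j], ce$hi[j]),
                              cb$or[j], c(cb$lo[j], cb$hi[j])) == "higher",
      TRUE)]
    hw <- hosa_width(sig, cell_width_km)
    hosa_rows[[i]] <- data.frame(
      surface = cells$surface[i], outcome = cells$outcome[i],
      condition = cells$condition[i],
      sig_lags = paste(sig, collapse = ","),
      n_sig_labels = hw$n_sig_labels, hosa_grids = hw$hosa_grids,
      hosa_km = hw$hosa_km, hosa_km2 = hw$hosa_km2,
      label = if (length(sig)) sprintf("%d (%s)", hw$n_sig_labels,
                                       paste(sig, collapse = ", ")) else "0",
      stringsAsFactors = FALSE)
  }
  hosa <- do.call(rbind, hosa_rows)

  delta <- list()
  contrast_rows <- function(a, b, nm) {
    shared <- intersect(paste(a$surface, a$outcome, a$lag),
                        paste(b$surface, b$outcome, b$lag))
    if (!length(shared)) return(NULL)
    ai <- match(shared, paste(a$surface, a$outcome, a$lag))
    bi <- match(shared, paste(b$surface, b$outcome, b$lag))
    data.frame(contrast = nm, surface = a$surface[ai], outcome = a$outcome[ai],
               lag = a$lag[ai],
               delta_or_pct = delta_or_pct(a$or[ai], b$or[bi]),
               verdict = vapply(seq_along(ai), function(j)
                 compare_or_to_reference(a$or[ai[j]], c(a$lo[ai[j]], a$hi[ai[j]]),
                                         b$or[bi[j]], c(b$lo[bi[j]], b$hi[bi[j]])),
                 ""),
               stringsAsFactors = FALSE)
  }
  delta$monitor <- contrast_rows(main[main$condition == "no", , drop = FALSE],
                                 main[main$condition == "yes", , drop = FALSE],
                                 "noMonitor_vs_monitor")
  seas <- fits[!fits$season %in% c("all", NA), , drop = FALSE]
  if (nrow(seas))
    delta$season <- contrast_rows(seas[seas$season == "warm", , drop = FALSE],
                                  seas[seas$season == "cold", , drop = FALSE],
                                  "warm_vs_cold")
  list(hosa = hosa, delta_or = do.call(rbind, delta))
}
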