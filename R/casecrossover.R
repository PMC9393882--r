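#' Calendar quarter of a month
#'
#' Quarters are calendar quarters: Q1 = Jan-Mar (winter), Q2 = Apr-Jun
#' (spring), Q3 = Jul-Sep (summer), Q4 = Oct-Dec (fall). With months ranked
#' 1-12 this fixes the case mean monthly ranks at 2.0 / 5.0 / 8.0 / 11.0.
#'
#' @param month integer month(s) in 1-12.
#' @return character vector `"Q1"`..`"Q4"`.
#' @export
quarter_of_month <- function(month) {
  month <- as.integer(month)
  if (any(is.na(month)) || any(month < 1L | month > 12L))
    stop("month must be in 1..12")
  paste0("Q", (month - 1L) %/% 3L + 1L)
}

months_of_quarter <- function(quarter) {
  q <- as.integer(sub("^Q", "", quarter))
  lapply(q, function(qi) (qi - 1L) * 3L + 1:3)
}

#' Mean monthly rank of a month set
#'
#' Months are ranked in ascending calendar order, January = 1 through
#' December = 12; the mean rank of a referent month set summarizes where the
#' set sits in the year (5.5, 6.5 and 7.5 for the three referent schemes;
#' 2.0, 5.0, 8.0, 11.0 for the four case quarters).
#'
#' @param months non-empty integer vector of distinct months in 1-12.
#' @return Arithmetic mean of the month numbers.
#' @export
mean_monthly_rank <- function(months) {
  months <- as.integer(months)
  if (length(months) == 0L) stop("month set is empty")
  if (any(months < 1L | months > 12L) || anyDuplicated(months))
    stop("months must be distinct values in 1..12")
  mean(months)
}

#' The three monthly referent schemes
#'
#' Referent exposures for the three controls are means over fixed month sets,
#' one month per season: control 1 uses January, April, July, October;
#' control 2 February, May, August, November; control 3 March, June,
#' September, December.
#'
#' @return Named list of three integer month vectors.
#' @export
referent_month_sets <- function() {
  list(control1 = c(1L, 4L, 7L, 10L),
       control2 = c(2L, 5L, 8L, 11L),
       control3 = c(3L, 6L, 9L, 12L))
}

#' Warm/cold season of a month or quarter
#'
#' The warm season defaults to April through September and the cold season to
#' October through March; the boundary is configurable.
#'
#' @param x integer months (1-12) or quarter labels `"Q1"`..`"Q4"` (a quarter
#'   is warm when the majority of its months are warm).
#' @param warm_months integer vector of warm-season months.
#' @return character vector `"warm"`/`"cold"`.
#' @export
season_label <- function(x, warm_months = 4:9) {
  if (is.character(x) && all(grepl("^Q[1-4]$", x))) {
    return(vapply(months_of_quarter(x), function(m) {
      if (sum(m %in% warm_months) >= 2L) "warm" else "cold"
    }, ""))
  }
  m <- as.integer(x)
  if (any(is.na(m)) || any(m < 1L | m > 12L))
    stop("x must be months in 1..12 or quarter labels Q1..Q4")
  ifelse(m %in% warm_months, "warm", "cold")
}

## ---- exposure table ------------------------------------------------------

exposure_required_cols <- c("row", "col", "year", "month")

check_exposure_table <- function(exposure, columns) {
  miss <- setdiff(c(exposure_required_cols, columns), names(exposure))
  if (length(miss))
    stop("exposure table lacks columns: ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

# Reshape one exposure column into a [cell, year, month] array for O(1) lookup.
exposure_array <- function(exposure, column, lattice, years) {
  arr <- array(NA_real_,
               dim = c(lattice$n_rows * lattice$n_cols, length(years), 12L))
  cell <- (exposure$row - 1L) * lattice$n_cols + exposure$col
  yi <- match(exposure$year, years)
  ok <- !is.na(yi)
  arr[cbind(cell[ok], yi[ok], exposure$month[ok])] <- exposure[[column]][ok]
  arr
}

# Mean over `months` at one grid/year, NA months skipped; n_missing recorded.
monthly_mean <- function(exposure, row, col, year, months, column) {
  check_exposure_table(exposure, column)
  sel <- exposure$row == row & exposure$col == col & exposure$year == year &
    exposure$month %in% months
  vals <- exposure[[column]][sel][match(months, exposure$month[sel])]
  n_missing <- sum(is.na(vals))
  if (n_missing == length(months))
    stop(sprintf("missing exposure: no %s values for grid (%d, %d), year %d, months %s",
                 column, row, col, year, paste(months, collapse = ",")))
  structure(mean(vals, na.rm = TRUE), n_missing = n_missing)
}

#' Quarterly case exposure in a grid
#'
#' The case exposure is the mean of the monthly surface values over the three
#' months of the event's calendar quarter, evaluated in a given grid (the
#' index grid or a lag grid). Months with missing values (possible for the
#' non-gap-filled surfaces) are skipped; the number skipped is attached as the
#' `n_missing` attribute, and an error is raised when no month is available.
#'
#' @param exposure long exposure table with columns `row`, `col`, `year`,
#'   `month` and one column per surface.
#' @param row,col grid coordinates.
#' @param year,month event year and month.
#' @param surface surface column name (e.g. `"PMB"`).
#' @return numeric scalar with attribute `n_missing`.
#' @export
case_exposure <- function(exposure, row, col, year, month, surface) {
  q <- quarter_of_month(month)
  monthly_mean(exposure, row, col, year, months_of_quarter(q)[[1]], surface)
}

#' Referent (control) exposures in a grid
#'
#' The three control exposures are means of the monthly surface values over
#' the three referent month sets of [referent_month_sets()], in the same grid
#' and year as the case assignment.
#'
#' @inheritParams case_exposure
#' @return numeric vector of length 3 (named control1..control3), each with
#'   an `n_missing` attribute retrievable via `attr(, "n_missing_by_control")`
#'   on the vector.
#' @export
control_exposures <- function(exposure, row, col, year, surface) {
  sets <- referent_month_sets()
  vals <- lapply(sets, function(m)
    monthly_mean(exposure, row, col, year, m, surface))
  out <- vapply(vals, as.numeric, 0)
  attr(out, "n_missing_by_control") <- vapply(vals, attr, 0L, "n_missing")
  out
}

## ---- strata --------------------------------------------------------------

lag_labels_all <- c("0", "1", "2", "3", "4", "01", "24", "04")

lag_label_members <- function(label) {
  switch(label,
         "0" = 0L, "1" = 1L, "2" = 2L, "3" = 3L, "4" = 4L,
         "01" = 0:1, "24" = 2:4, "04" = 0:4,
         stop("unknown lag label '", label, "'"))
}

#' Build 1:3 matched case-crossover strata with lag-grid exposures
#'
#' One stratum per health event: the case carries the quarterly mean exposure
#' of the event's calendar quarter and the three controls the three monthly
#' referent means ([referent_month_sets()]), all evaluated in the lag grids of
#' the index grid's lag sequence for the requested monitor condition. At the
#' summary lag labels `01`, `24`, `04` the exposure covariate is the mean of
#' the member's individual-lag exposures. Apparent temperature is aggregated
#' the same way in the lag grid (its square is supplied for use at lags 0, 1,
#' 01, 04); pollen, holiday and snowstorm are aggregated over the member's
#' months in the index grid. The matching key (5-year age band, gender, race,
#' insurance, ZIP, year, day of week) is copied to all four members.
#'
#' Events that cannot be resolved to a grid of the condition subset, or whose
#' exposure is entirely missing at some lag, are dropped; the dropped events
#' and reasons are attached as the `dropped` attribute.
#'
#' @param events health-event table: columns `event_id`, `outcome`, `date`
#'   (Date or yyyy-mm-dd), either `row`+`col` or `centroid_x`+`centroid_y`,
#'   `age`, `gender`, `race`, `insurance`, `zip`, and optional comorbidity
#'   flags `athero`, `diabetes`, `htn`.
#' @param exposure long monthly exposure table (see [case_exposure()]), with
#'   optional covariate columns `at_f`, `pollen`, `holiday`, `snowstorm`.
#' @param lattice a [grid_lattice()].
#' @param condition monitor condition (`"No"`, `"Yes"`, `"Both"`).
#' @param surface surface column to use as the exposure.
#' @param lags lag labels to evaluate (subset of
#'   `c("0","1","2","3","4","01","24","04")`).
#' @param warm_months warm-season months for the season label.
#' @param age_band_years width of the age matching bands (default 5).
#' @return Long data.frame, one record per stratum x member x lag label, with
#'   columns `stratum_id`, `event_id`, `outcome`, `condition`, `role`, `y`,
#'   `surface`, `lag`, `exposure`, `exposure_n_missing`, `at`, `at_sq`,
#'   `pollen`, `holiday`, `snowstorm`, `quarter`, `season`, matching-key
#'   columns, and comorbidity flags. Attribute `dropped` is a data.frame of
#'   the dropped events with reason codes.
#' @export
build_strata <- function(events, exposure, lattice, condition = "Both",
                         surface = "PMB", lags = lag_labels_all,
                         warm_months = 4:9, age_band_years = 5) {
  stopifnot(is.data.frame(events), is.data.frame(exposure))
  bad_lag <- setdiff(lags, lag_labels_all)
  if (length(bad_lag)) stop("unknown lag label(s): ", paste(bad_lag, collapse = ", "))
  check_exposure_table(exposure, surface)
  cond <- normalize_condition(condition)
  events <- as.data.frame(events)
  n0 <- nrow(events)
  if (n0 == 0L) return(empty_strata(surface, cond))
  events$date <- as.Date(events$date)
  events$year <- as.integer(format(events$date, "%Y"))
  events$month <- as.integer(format(events$date, "%m"))
  events$dow <- format(events$date, "%a")

  dropped <- data.frame(event_id = character(), reason = character())
  drop_events <- function(keep, reason) {
    if (!all(keep))
      dropped <<- rbind(dropped, data.frame(event_id = as.character(events$event_id[!keep]),
                                            reason = reason))
    events <<- events[keep, , drop = FALSE]
  }

  # resolve index grid
  if (!all(c("row", "col") %in% names(events))) {
    if (!all(c("centroid_x", "centroid_y") %in% names(events)))
      stop("events need either row/col or centroid_x/centroid_y")
    g <- assign_point_to_grid(lattice, events$centroid_x, events$centroid_y)
    events$row <- g$row; events$col <- g$col
  }
  sub <- condition_subset(lattice, cond)
  in_sub <- paste(events$row, events$col) %in% paste(sub$row, sub$col)
  drop_events(in_sub, "index grid not in condition subset")
  yrs <- sort(unique(exposure$year))
  drop_events(events$year %in% yrs, "event year not in exposure table")
  if (nrow(events) == 0L) {
    out <- empty_strata(surface, cond)
    attr(out, "dropped") <- dropped
    return(out)
  }

  # lag cells per unique index grid
  max_lag <- max(unlist(lapply(lags, lag_label_members)))
  ug <- unique(events[, c("row", "col")])
  lag_cells <- matrix(NA_integer_, nrow(ug), max_lag + 1L)  # cell index per lag 0..max
  for (i in seq_len(nrow(ug))) {
    sq <- assign_lag_grids(lattice, c(ug$row[i], ug$col[i]), cond,
                           n_lags = max(max_lag, 1L))
    cells <- rbind(c(ug$row[i], ug$col[i]),
                   as.matrix(sq$lags[, c("row", "col")]))[seq_len(max_lag + 1L), , drop = FALSE]
    lag_cells[i, ] <- (cells[, 1] - 1L) * lattice$n_cols + cells[, 2]
  }
  ev_u <- match(paste(events$row, events$col), paste(ug$row, ug$col))

  # exposure/covariate arrays
  covs <- intersect(c("at_f", "pollen", "holiday", "snowstorm"), names(exposure))
  arrs <- lapply(c(stats::setNames(surface, "exposure"),
                   stats::setNames(covs, covs)),
                 function(cl) exposure_array(exposure, cl, lattice, yrs))

  n_ev <- nrow(events)
  roles <- c("case", "control1", "control2", "control3")
  refsets <- referent_month_sets()
  month_sets <- c(list(case = NULL), refsets)  # case set filled per event

  # member x lag matrices of exposure means and missing counts
  member_means <- function(arr, lag_k, months_mat) {
    # months_mat: n_ev x m months; lag_k: lag index 0..max
    cell <- lag_cells[ev_u, lag_k + 1L]
    yi <- match(events$year, yrs)
    m <- ncol(months_mat)
    vals <- matrix(arr[cbind(rep(cell, m), rep(yi, m), as.vector(months_mat))],
                   nrow = n_ev)
    list(mean = rowMeans(vals, na.rm = TRUE), n_missing = rowSums(is.na(vals)),
         n = m)
  }
  case_months <- matrix(unlist(months_of_quarter(quarter_of_month(events$month))),
                        nrow = n_ev, byrow = TRUE)

  out <- vector("list", length(lags) * length(roles))
  oi <- 0L
  # per-role, per-individual-lag caches
  exp_cache <- array(NA_real_, c(n_ev, 4L, max_lag + 1L))
  mis_cache <- array(0L, c(n_ev, 4L, max_lag + 1L))
  at_cache <- if ("at_f" %in% covs) array(NA_real_, c(n_ev, 4L, max_lag + 1L))
  aux_cache <- lapply(intersect(c("pollen", "holiday", "snowstorm"), covs),
                      function(cl) matrix(NA_real_, n_ev, 4L))
  names(aux_cache) <- intersect(c("pollen", "holiday", "snowstorm"), covs)
  for (r in seq_along(roles)) {
    months_mat <- if (r == 1L) case_months else
      matrix(refsets[[r - 1L]], n_ev, 4L, byrow = TRUE)
    for (k in 0:max_lag) {
      mm <- member_means(arrs$exposure, k, months_mat)
      exp_cache[, r, k + 1L] <- mm$mean
      mis_cache[, r, k + 1L] <- mm$n_missing
      if (!is.null(at_cache))
        at_cache[, r, k + 1L] <- member_means(arrs$at_f, k, months_mat)$mean
    }
    for (cl in names(aux_cache))
      aux_cache[[cl]][, r] <- member_means(arrs[[cl]], 0L, months_mat)$mean
  }

  # drop events with any fully-missing member-lag exposure among needed lags
  needed <- sort(unique(unlist(lapply(lags, lag_label_members))))
  n_months <- c(3L, 4L, 4L, 4L)
  fully_missing <- rep(FALSE, n_ev)
  for (r in 1:4) for (k in needed)
    fully_missing <- fully_missing | (mis_cache[, r, k + 1L] >= n_months[r])
  keep <- !fully_missing
  if (!all(keep)) {
    dropped <- rbind(dropped,
                     data.frame(event_id = as.character(events$event_id[!keep]),
                                reason = "exposure fully missing at a lag"))
    events <- events[keep, , drop = FALSE]
    exp_cache <- exp_cache[keep, , , drop = FALSE]
    mis_cache <- mis_cache[keep, , , drop = FALSE]
    if (!is.null(at_cache)) at_cache <- at_cache[keep, , , drop = FALSE]
    aux_cache <- lapply(aux_cache, function(m) m[keep, , drop = FALSE])
    ev_u <- ev_u[keep]
    case_months <- case_months[keep, , drop = FALSE]
    n_ev <- nrow(events)
  }
  if (n_ev == 0L) {
    outdf <- empty_strata(surface, cond)
    attr(outdf, "dropped") <- dropped
    return(outdf)
  }

  opt_col <- function(nm, default) if (nm %in% names(events)) events[[nm]] else default
  key <- data.frame(
    stratum_id = paste0(events$event_id),
    event_id = events$event_id,
    outcome = opt_col("outcome", NA_character_),
    condition = cond,
    age_band = age_band_years * (opt_col("age", NA_real_) %/% age_band_years),
    gender = opt_col("gender", NA_character_),
    race = opt_col("race", NA_character_),
    insurance = opt_col("insurance", NA_character_),
    zip = opt_col("zip", NA_character_),
    year = events$year,
    dow = events$dow,
    quarter = quarter_of_month(events$month),
    season = season_label(events$month, warm_months),
    index_row = events$row,
    index_col = events$col,
    athero = opt_col("athero", NA),
    diabetes = opt_col("diabetes", NA),
    htn = opt_col("htn", NA),
    stringsAsFactors = FALSE
  )

  for (lab in lags) {
    mem <- lag_label_members(lab) + 1L
    for (r in seq_along(roles)) {
      ex <- if (length(mem) == 1L) exp_cache[, r, mem] else
        rowMeans(exp_cache[, r, mem, drop = FALSE], dims = 1)
      nm <- if (length(mem) == 1L) mis_cache[, r, mem] else
        rowSums(mis_cache[, r, mem, drop = FALSE], dims = 1)
      at <- if (is.null(at_cache)) NA_real_ else if (length(mem) == 1L)
        at_cache[, r, mem] else rowMeans(at_cache[, r, mem, drop = FALSE], dims = 1)
      oi <- oi + 1L
      out[[oi]] <- cbind(key, data.frame(
        role = roles[r], y = as.integer(r == 1L),
        surface = surface, lag = lab,
        exposure = ex, exposure_n_missing = as.integer(nm),
        at = at, at_sq = at^2,
        pollen = if ("pollen" %in% names(aux_cache)) aux_cache$pollen[, r] else NA_real_,
        holiday = if ("holiday" %in% names(aux_cache)) aux_cache$holiday[, r] else NA_real_,
        snowstorm = if ("snowstorm" %in% names(aux_cache)) aux_cache$snowstorm[, r] else NA_real_,
        stringsAsFactors = FALSE))
    }
  }
  outdf <- do.call(rbind, out[seq_len(oi)])
  outdf <- outdf[order(outdf$lag, outdf$stratum_id, -outdf$y, outdf$role), ]
  rownames(outdf) <- NULL
  attr(outdf, "dropped") <- dropped
  outdf
}

empty_strata <- function(surface, cond) {
  data.frame(stratum_id = character(), event_id = character(),
             outcome = character(), condition = character(),
             age_band = numeric(), gender = character(), race = character(),
             insurance = character(), zip = character(), year = integer(),
             dow = character(), quarter = character(), season = character(),
             index_row = integer(), index_col = integer(),
             athero = logical(), diabetes = logical(), htn = logical(),
             role = character(), y = integer(), surface = character(),
             lag = character(), exposure = numeric(),
             exposure_n_missing = integer(), at = numeric(), at_sq = numeric(),
             pollen = numeric(), holiday = numeric(), snowstorm = numeric(),
             stringsAsFactors = FALSE)
}
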