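#' Shared variance percent from a correlation
#'
#' `r2_percent(r) = 100 * r^2`, the percentage of variance two surfaces
#' share; reported to one decimal (half-up) to match printed tables.
#'
#' @param r Pearson correlation(s), in [-1, 1].
#' @param digits decimals for rounding (default 1; use `NA` for unrounded).
#' @return 100 * r^2.
#' @export
r2_percent <- function(r, digits = 1) {
  if (any(abs(r) > 1)) stop("|r| must be <= 1")
  v <- 100 * r^2
  if (is.na(digits)) v else round_half_up(v, digits)
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Difference in shared variance percent between monitor conditions
#'
#' `delta_percent(r2_yes, r2_no) = r2_yes - r2_no`, the drop in shared
#' variance from monitor grids to no-monitor grids.
#'
#' @param r2_yes,r2_no shared variance percents in [0, 100].
#' @return The difference (percentage points).
#' @export
delta_percent <- function(r2_yes, r2_no) {
  if (any(c(r2_yes, r2_no) < 0 | c(r2_yes, r2_no) > 100))
    stop("shared variance percents must be in [0, 100]")
  r2_yes - r2_no
}

#' Pearson correlation summary between two surfaces
#'
#' @param x,y paired surface values (rows with any missing value dropped).
#' @return list with `r`, `r2_pct` (one decimal) and `n`.
#' @export
correlation_summary <- function(x, y) {
  ok <- !(is.na(x) | is.na(y))
  r <- stats::cor(x[ok], y[ok])
  list(r = r, r2_pct = r2_percent(r), n = sum(ok))
}

#' Spatial weight matrix for a lattice
#'
#' Binary contiguity weights: `"rook"` joins cells sharing an edge, `"queen"`
#' additionally joins diagonal neighbours, `"distance_band"` joins cells whose
#' centre-to-centre distance is at most `d` km.
#'
#' @param lattice a [grid_lattice()].
#' @param scheme weight scheme.
#' @param d distance band in km (required for `"distance_band"`).
#' @param cells optional subset of lattice cells (data.frame with row/col)
#'   for which to build weights; defaults to all cells.
#' @return Symmetric 0/1 matrix with zero diagonal, rows ordered like `cells`.
#' @export
lattice_weights <- function(lattice, scheme = c("rook", "queen", "distance_band"),
                            d = NULL, cells = lattice$cells) {
  scheme <- match.arg(scheme)
  dr <- abs(outer(cells$row, cells$row, "-"))
  dc <- abs(outer(cells$col, cells$col, "-"))
  w <- switch(scheme,
    rook = (dr + dc) == 1L,
    queen = pmax(dr, dc) == 1L,
    distance_band = {
      if (is.null(d)) stop("distance_band weights need a band distance d")
      dist <- sqrt((dr * lattice$cell_height_km)^2 + (dc * lattice$cell_width_km)^2)
      dist <= d & dist > 0
    })
  mode(w) <- "numeric"
  diag(w) <- 0
  w
}

#' Moran's I spatial autocorrelation on a lattice
#'
#' Global Moran's I with binary contiguity weights:
#' `I = (n / W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' with `W = sum_ij w_ij`. The null expectation is `-1/(n-1)`; the variance is
#' computed under the randomization assumption by default (normality
#' selectable), giving `Z = (I - E[I]) / sd` and a two-sided normal p-value.
#'
#' @param values numeric vector of grid values, either aligned with
#'   `lattice$cells` or a data.frame with columns `row`, `col`, `value`.
#' @param lattice a [grid_lattice()].
#' @param scheme,d weight scheme passed to [lattice_weights()].
#' @param assumption `"randomization"` (default) or `"normality"` variance.
#' @return list of class `moran_result`: `I`, `expected`, `variance`, `Z`,
#'   `p`, `n`, `weight_scheme`, `assumption`.
#' @export
morans_i <- function(values, lattice, scheme = "rook", d = NULL,
                     assumption = c("randomization", "normality")) {
  assumption <- match.arg(assumption)
  cells <- lattice$cells
  if (is.data.frame(values)) {
    idx <- match(paste(cells$row, cells$col), paste(values$row, values$col))
    keep <- !is.na(idx)
    cells <- cells[keep, , drop = FALSE]
    x <- values$value[idx[keep]]
  } else {
    if (length(values) != nrow(cells))
      stop("values must align with lattice$cells or carry row/col columns")
    x <- as.numeric(values)
    keep <- !is.na(x)
    cells <- cells[keep, , drop = FALSE]
    x <- x[keep]
  }
  n <- length(x)
  if (n < 3L) stop("need at least 3 grids with values")
  z <- x - mean(x)
  m2 <- sum(z^2)
  if (m2 < .Machine$double.eps * n)
    stop("degenerate input: zero variance surface")
  w <- lattice_weights(lattice, scheme, d, cells)
  W <- sum(w)
  I <- (n / W) * drop(crossprod(z, w %*% z)) / m2
  EI <- -1 / (n - 1)
  s1 <- sum((w + t(w))^2) / 2
  s2 <- sum((rowSums(w) + colSums(w))^2)
  if (assumption == "normality") {
    varI <- (n^2 * s1 - n * s2 + 3 * W^2) / (W^2 * (n^2 - 1)) - EI^2
  } else {
    b2 <- n * sum(z^4) / m2^2
    varI <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * W^2) -
               b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * W^2)) /
      ((n - 1) * (n - 2) * (n - 3) * W^2) - EI^2
  }
  Z <- (I - EI) / sqrt(varI)
  structure(list(I = I, expected = EI, variance = varI, Z = Z,
                 p = 2 * stats::pnorm(-abs(Z)), n = n,
                 weight_scheme = scheme, assumption = assumption),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E = %.4f, %s var = %.3g), Z = %.2f, p = %.3g, n = %d, %s weights\n",
              x$I, x$expected, x$assumption, x$variance, x$Z, x$p, x$n,
              x$weight_scheme))
  invisible(x)
}

#' Compare a mean against a reference mean's 95% CI
#'
#' The rule used throughout the descriptive tables: the comparison mean is
#' significantly `"higher"`/`"lower"` (p <= 0.05) when it falls strictly
#' above/below the reference group's 95% CI, and `"not_significant"` when it
#' falls on or within the bounds.
#'
#' @param mean_a comparison mean.
#' @param ci_b reference 95% CI as `c(lo, hi)`.
#' @return `"higher"`, `"lower"` or `"not_significant"`.
#' @export
mean_ci_compare <- function(mean_a, ci_b) {
  if (length(ci_b) != 2L || !(ci_b[1] < ci_b[2]))
    stop("malformed CI: need lo < hi")
  if (mean_a > ci_b[2]) return("higher")
  if (mean_a < ci_b[1]) return("lower")
  "not_significant"
}

#' Classify grid means as Below / Within / Above a reference CI
#'
#' Each grid's multi-year mean is compared (strictly) to the lower and upper
#' bounds of the all-grids mean's 95% CI. With a grouping vector (e.g.
#' monitor condition) a Pearson chi-square test over the category x group
#' table is run; without one, the observed three-level distribution is tested
#' against uniform. Degenerate tables (a category level absent everywhere) are
#' flagged instead of tested.
#'
#' @param grid_means numeric vector of per-grid means.
#' @param ci reference 95% CI as `c(lo, hi)`.
#' @param group optional grouping vector aligned with `grid_means`.
#' @return list with `category` (per-grid factor), `counts`, `percents`,
#'   `chi2`, `df`, `p`, `degenerate`.
#' @export
categorize_grids <- function(grid_means, ci, group = NULL) {
  if (length(ci) != 2L || !(ci[1] < ci[2])) stop("malformed CI: need lo < hi")
  cat <- factor(ifelse(grid_means < ci[1], "Below",
                       ifelse(grid_means > ci[2], "Above", "Within")),
                levels = c("Below", "Within", "Above"))
  if (is.null(group)) {
    counts <- table(cat)
    observed <- as.vector(counts)
    degenerate <- sum(observed > 0) < 2L
    if (degenerate) {
      chi2 <- NA_real_; df <- NA_integer_; p <- NA_real_
    } else {
      ct <- stats::chisq.test(observed[observed >= 0])
      chi2 <- unname(ct$statistic); df <- unname(ct$parameter); p <- ct$p.value
    }
  } else {
    counts <- table(cat, group)
    degenerate <- any(rowSums(counts) == 0) || any(colSums(counts) == 0)
    if (degenerate) {
      chi2 <- NA_real_; df <- NA_integer_; p <- NA_real_
    } else {
      ct <- suppressWarnings(stats::chisq.test(counts[rowSums(counts) > 0, ,
                                                      drop = FALSE],
                                               correct = FALSE))
      chi2 <- unname(ct$statistic); df <- unname(ct$parameter); p <- ct$p.value
    }
  }
  pct <- if (is.null(group)) 100 * prop.table(table(cat)) else
    100 * prop.table(table(cat, group), margin = 2)
  list(category = cat, counts = counts,
       percents = round_half_up(pct, 1),
       chi2 = chi2, df = df, p = p, degenerate = degenerate)
}
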