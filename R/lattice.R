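#' Construct a regular grid lattice
#'
#' A lattice is the spatial template of the study area: `n_rows` x `n_cols`
#' square cells, numbered from 1 at the south-west corner (rows increase
#' south to north, columns west to east). Each cell records whether it holds
#' one or more ambient PM2.5 air monitors and whether health events are
#' available for it.
#'
#' @param cells data.frame with columns `row`, `col`, `has_monitor`,
#'   `n_monitors`, `has_health_data` and optionally `jurisdiction`. Exactly one
#'   row per (row, col) combination of the full lattice.
#' @param n_rows,n_cols lattice dimensions. Defaults are taken from the
#'   maxima of `cells$row` / `cells$col`.
#' @param cell_width_km,cell_height_km cell size in km (default 12 x 12).
#' @return An object of class `grid_lattice`: a list with elements `cells`
#'   (the validated data.frame, ordered row then column), `n_rows`, `n_cols`,
#'   `cell_width_km`, `cell_height_km`.
#' @seealso [baltimore_lattice()], [canonical_order()], [assign_lag_grids()]
#' @export
grid_lattice <- function(cells, n_rows = max(cells$row), n_cols = max(cells$col),
                         cell_width_km = 12, cell_height_km = 12) {
  stopifnot(is.data.frame(cells))
  needed <- c("row", "col", "has_monitor", "n_monitors", "has_health_data")
  missing_cols <- setdiff(needed, names(cells))
  if (length(missing_cols))
    stop("lattice cell table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!"jurisdiction" %in% names(cells)) cells$jurisdiction <- NA_character_
  cells <- cells[, c(needed, "jurisdiction")]
  cells$row <- as.integer(cells$row)
  cells$col <- as.integer(cells$col)
  cells$has_monitor <- as.logical(cells$has_monitor)
  cells$n_monitors <- as.integer(cells$n_monitors)
  cells$has_health_data <- as.logical(cells$has_health_data)
  if (cell_width_km <= 0 || cell_height_km <= 0)
    stop("cell dimensions must be positive")
  if (any(cells$row < 1L | cells$row > n_rows | cells$col < 1L | cells$col > n_cols))
    stop("cell coordinates outside the lattice")
  if (nrow(cells) != n_rows * n_cols)
    stop("expected ", n_rows * n_cols, " cells, got ", nrow(cells))
  if (anyDuplicated(cells[, c("row", "col")]))
    stop("duplicate (row, col) cells")
  if (any(cells$has_monitor & cells$n_monitors < 1L))
    stop("cells flagged has_monitor must have n_monitors >= 1")
  if (any(!cells$has_monitor & cells$n_monitors != 0L))
    stop("cells without monitors must have n_monitors = 0")
  cells <- cells[order(cells$row, cells$col), , drop = FALSE]
  rownames(cells) <- NULL
  structure(
    list(cells = cells, n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_width_km = cell_width_km, cell_height_km = cell_height_km),
    class = "grid_lattice"
  )
}

#' @export
print.grid_lattice <- function(x, ...) {
  cat(sprintf("grid_lattice: %d x %d cells (%g x %g km each)\n",
              x$n_rows, x$n_cols, x$cell_width_km, x$cell_height_km))
  cat(sprintf("  monitor cells: %d (total monitors %d); health-data cells: %d\n",
              sum(x$cells$has_monitor), sum(x$cells$n_monitors),
              sum(x$cells$has_health_data)))
  invisible(x)
}

#' The packaged Baltimore study-area lattice
#'
#' The 11 x 9 lattice of 99 CMAQ 12-km grids covering the Baltimore study
#' area, with the 15 urban monitor grids (17 federal reference method PM2.5
#' monitors in 2004-2006; the Baltimore-city grid at row 6, column 6 holds
#' three monitors, all other monitor grids one). Jurisdiction abbreviations:
#' AA = Anne Arundel, B = Baltimore county, BC = Baltimore city, H = Harford,
#' M = Montgomery, PG = Prince George's.
#'
#' Which 57 of the 84 no-monitor grids carried health data was never published,
#' so by default every cell is flagged `has_health_data = TRUE`; pass
#' `health_cells` to restrict.
#'
#' @param health_cells optional two-column matrix/data.frame of (row, col)
#'   pairs; cells not listed are flagged `has_health_data = FALSE`.
#' @return A [grid_lattice()] with 99 cells.
#' @examples
#' lat <- baltimore_lattice()
#' sum(lat$cells$has_monitor)   # 15
#' sum(lat$cells$n_monitors)    # 17
#' @export
baltimore_lattice <- function(health_cells = NULL) {
  mon <- data.frame(
    row = c(8L, 8L, 7L, 7L, 7L, 6L, 6L, 5L, 5L, 4L, 4L, 4L, 3L, 3L, 2L),
    col = c(6L, 8L, 5L, 6L, 7L, 6L, 7L, 6L, 7L, 3L, 5L, 6L, 5L, 7L, 6L),
    jurisdiction = c("B", "H", "BC", "BC", "B", "BC", "BC", "AA", "AA",
                     "M", "PG", "AA", "PG", "AA", "PG"),
    stringsAsFactors = FALSE
  )
  cells <- expand.grid(col = 1:9, row = 1:11)[, c("row", "col")]
  key <- paste(cells$row, cells$col)
  mkey <- paste(mon$row, mon$col)
  cells$has_monitor <- key %in% mkey
  cells$n_monitors <- ifelse(cells$has_monitor, 1L, 0L)
  cells$n_monitors[cells$row == 6L & cells$col == 6L] <- 3L
  cells$has_health_data <- TRUE
  cells$jurisdiction <- mon$jurisdiction[match(key, mkey)]
  if (!is.null(health_cells)) {
    health_cells <- as.data.frame(health_cells)
    hkey <- paste(health_cells[[1]], health_cells[[2]])
    cells$has_health_data <- key %in% hkey
  }
  grid_lattice(cells, n_rows = 11L, n_cols = 9L)
}

normalize_condition <- function(condition) {
  cond <- tolower(as.character(condition))
  if (!cond %in% c("no", "yes", "both"))
    stop("condition must be one of 'No', 'Yes', 'Both'")
  cond
}

condition_subset <- function(lattice, condition) {
  cond <- normalize_condition(condition)
  cells <- lattice$cells
  switch(cond,
         no = cells[!cells$has_monitor, , drop = FALSE],
         yes = cells[cells$has_monitor, , drop = FALSE],
         both = cells)
}

#' Canonical spatial ordering of a monitor-condition subset
#'
#' The lag-grid assignment walks a fixed ordering of the cells of a monitor
#' condition subset (`"No"` = cells without monitors, `"Yes"` = cells with
#' monitors, `"Both"` = all cells): row descending (north to south), then
#' column ascending (west to east). The ordering is treated as a ring, so the
#' predecessor of the first cell is the last cell.
#'
#' @param lattice a [grid_lattice()].
#' @param condition `"No"`, `"Yes"` or `"Both"` (case-insensitive).
#' @return The subset's cells data.frame in canonical order.
#' @export
canonical_order <- function(lattice, condition = "Both") {
  sub <- condition_subset(lattice, condition)
  if (nrow(sub) == 0L)
    stop("condition subset '", condition, "' is empty")
  sub <- sub[order(-sub$row, sub$col), , drop = FALSE]
  rownames(sub) <- NULL
  sub
}

#' Assign spatial lag grids to an index grid
#'
#' The index grid (the patient's grid of residence) has lag value 0; the cell
#' k positions earlier in the canonical ordering of the condition subset is
#' lag grid k. In the interior of a row this is simply the k-th cell to the
#' west; at the western edge the sequence continues from the eastern end of
#' the row above (bidirectionality), and past the north-west corner it wraps
#' around the ring (flagged via `wrapped_around_lattice`).
#'
#' @param lattice a [grid_lattice()].
#' @param index index grid as a length-2 vector `c(row, col)` (or a one-row
#'   data.frame with `row`/`col`).
#' @param condition monitor condition subset; the index grid must belong to it.
#' @param n_lags number of lag grids (default 4).
#' @return An object of class `lag_sequence`: list with `condition`, `index`
#'   (named row/col vector), `lags` (data.frame: `lag`, `row`, `col`,
#'   `wrapped`, where `wrapped` marks lag cells outside the index row),
#'   `wrapped_around_lattice` (TRUE when the ring wrapped past the start of
#'   the canonical ordering), and `summary_sets` (the lag labels `01`, `24`,
#'   `04` mapped to the individual lags they average).
#' @examples
#' lat <- baltimore_lattice()
#' assign_lag_grids(lat, c(9, 7), "No")    # lags 1-4: (9,6) (9,5) (9,4) (9,3)
#' assign_lag_grids(lat, c(6, 7), "Yes")   # lags 1-4: (6,6) (7,7) (7,6) (7,5)
#' @export
assign_lag_grids <- function(lattice, index, condition = "Both", n_lags = 4L) {
  cond <- normalize_condition(condition)
  ord <- canonical_order(lattice, cond)
  if (is.data.frame(index)) index <- c(index$row[1], index$col[1])
  index <- as.integer(index)
  pos <- which(ord$row == index[1] & ord$col == index[2])
  if (length(pos) != 1L)
    stop(sprintf("index grid (%d, %d) is not in the '%s' condition subset",
                 index[1], index[2], cond))
  n <- nrow(ord)
  if (n_lags < 1L || n_lags >= n)
    stop("n_lags must be in [1, subset size - 1]")
  lag_pos <- ((pos - 1L - seq_len(n_lags)) %% n) + 1L
  lags <- data.frame(
    lag = seq_len(n_lags),
    row = ord$row[lag_pos],
    col = ord$col[lag_pos],
    wrapped = ord$row[lag_pos] != index[1]
  )
  structure(
    list(condition = cond,
         index = c(row = index[1], col = index[2]),
         lags = lags,
         wrapped_around_lattice = any(lag_pos >= pos),
         summary_sets = list(`01` = 0:1, `24` = 2:4, `04` = 0:4)),
    class = "lag_sequence"
  )
}

#' @export
print.lag_sequence <- function(x, ...) {
  cat(sprintf("lag_sequence (condition %s): index (%d, %d)\n",
              x$condition, x$index["row"], x$index["col"]))
  lg <- apply(x$lags, 1, function(r)
    sprintf("lag %d: (%d, %d)%s", r[["lag"]], r[["row"]], r[["col"]],
            if (r[["wrapped"]]) " [row change]" else ""))
  cat(paste0("  ", lg, collapse = "\n"), "\n")
  if (x$wrapped_around_lattice) cat("  note: sequence wrapped around the lattice ring\n")
  invisible(x)
}

#' Classify lag grids as preceding or following the index grid
#'
#' Lag cells in the index grid's row lie to its west and precede it in the
#' canonical walk; lag cells pushed into another row (by the western edge)
#' follow it. An index grid in column 3 of the `"Both"` subset therefore has
#' two preceding and two following lag grids, and an index grid in column 1
#' has four following lag grids in the row above.
#'
#' @param seq a [assign_lag_grids()] result.
#' @return Character vector (`"precede"`/`"follow"`), one entry per lag grid.
#' @export
classify_precede_follow <- function(seq) {
  stopifnot(inherits(seq, "lag_sequence"))
  ifelse(seq$lags$row == seq$index["row"], "precede", "follow")
}

#' Tabulate precede/follow percentages over a condition subset
#'
#' Runs [assign_lag_grids()] for every cell of the condition subset and
#' tallies how many lag grids precede versus follow their index grid. Both
#' unweighted percentages (each index grid counted once) and optionally
#' observation-weighted percentages (weights per index grid, e.g. record
#' counts) are reported.
#'
#' @param lattice a [grid_lattice()].
#' @param condition monitor condition subset.
#' @param weights optional numeric vector of per-index-grid weights, aligned
#'   with `canonical_order(lattice, condition)`.
#' @param n_lags lags per sequence (default 4).
#' @return data.frame with columns `direction`, `n`, `pct` and, when weights
#'   are supplied, `pct_weighted`.
#' @export
precede_follow_table <- function(lattice, condition = "Both", weights = NULL,
                                 n_lags = 4L) {
  ord <- canonical_order(lattice, condition)
  if (!is.null(weights) && length(weights) != nrow(ord))
    stop("weights must align with canonical_order(lattice, condition)")
  counts <- t(vapply(seq_len(nrow(ord)), function(i) {
    cl <- classify_precede_follow(
      assign_lag_grids(lattice, c(ord$row[i], ord$col[i]), condition, n_lags))
    c(precede = sum(cl == "precede"), follow = sum(cl == "follow"))
  }, c(precede = 0, follow = 0)))
  out <- data.frame(direction = c("precede", "follow"),
                    n = c(sum(counts[, "precede"]), sum(counts[, "follow"])))
  out$pct <- 100 * out$n / sum(out$n)
  if (!is.null(weights)) {
    wp <- c(sum(counts[, "precede"] * weights), sum(counts[, "follow"] * weights))
    out$pct_weighted <- 100 * wp / sum(wp)
  }
  out
}

#' Map a point to its lattice cell
#'
#' Lattice coordinates place the origin at the south-west corner of cell
#' (1, 1); cell squares are half-open (west and south edges inclusive), so
#' every point in the lattice bounding box maps to exactly one cell. Used to
#' resolve residential-polygon centroids to grids.
#'
#' @param lattice a [grid_lattice()].
#' @param x,y point coordinates in km (vectors of equal length).
#' @return data.frame of the matched cells (one row per point).
#' @export
assign_point_to_grid <- function(lattice, x, y) {
  stopifnot(length(x) == length(y))
  w <- lattice$cell_width_km; h <- lattice$cell_height_km
  if (any(x < 0 | x >= lattice$n_cols * w | y < 0 | y >= lattice$n_rows * h))
    stop("point(s) outside the lattice bounding box")
  col <- floor(x / w) + 1L
  row <- floor(y / h) + 1L
  idx <- match(paste(row, col), paste(lattice$cells$row, lattice$cells$col))
  out <- lattice$cells[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' HOSA geometry from a grid count
#'
#' A homogeneous spatial area (HOSA) is a run of adjacent lag grids; its
#' linear width is the grid count times the cell width and its area that
#' count times the squared cell width (a multiple of 144 km^2 at the default
#' 12-km cells).
#'
#' @param n_grids non-negative number of grids in the run.
#' @param cell_width_km cell width in km (default 12).
#' @return list with `width_km` and `area_km2`.
#' @examples
#' hosa_geometry(5)  # 60 km, 720 km^2
#' hosa_geometry(2)  # 24 km, 288 km^2
#' @export
hosa_geometry <- function(n_grids, cell_width_km = 12) {
  if (any(n_grids < 0)) stop("n_grids must be non-negative")
  list(width_km = n_grids * cell_width_km,
       area_km2 = n_grids * cell_width_km^2)
}

#' Count the exposure design combinations
#'
#' Exposure values and effect modifiers vary by year, quarter, day of week
#' and grid; the design therefore spans the product of the four counts (e.g.
#' 3 years x 4 quarters x 7 days x 99 grids = 8316 combinations).
#'
#' @param n_years,n_quarters,n_days,n_grids positive integers.
#' @return The product, as a double.
#' @export
count_design_combinations <- function(n_years, n_quarters, n_days, n_grids) {
  v <- c(n_years, n_quarters, n_days, n_grids)
  if (any(v <= 0) || any(v != round(v))) stop("all counts must be positive integers")
  prod(as.numeric(v))
}

#' Export lag sequences as JSON records
#'
#' @param seqs a `lag_sequence` or list of them.
#' @param file optional path; when omitted the JSON string is returned.
#' @return JSON text (invisibly when written to file).
#' @export
lag_sequences_json <- function(seqs, file = NULL) {
  if (inherits(seqs, "lag_sequence")) seqs <- list(seqs)
  recs <- lapply(seqs, function(s) {
    list(condition = s$condition,
         index = unname(as.integer(s$index)),
         lags = lapply(seq_len(nrow(s$lags)),
                       function(i) c(s$lags$row[i], s$lags$col[i])),
         wrapped = s$lags$wrapped)
  })
  js <- jsonlite::toJSON(recs, auto_unbox = TRUE)
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(js)
}

#' Read / write a lattice definition file
#'
#' Delimited text with header
#' `row,col,has_monitor,n_monitors,has_health_data,jurisdiction`.
#'
#' @param file path to the lattice file.
#' @param cell_width_km,cell_height_km cell size passed to [grid_lattice()].
#' @return [read_lattice()] returns a `grid_lattice`.
#' @export
read_lattice <- function(file, cell_width_km = 12, cell_height_km = 12) {
  cells <- utils::read.csv(file, stringsAsFactors = FALSE)
  grid_lattice(cells, cell_width_km = cell_width_km,
               cell_height_km = cell_height_km)
}

#' @rdname read_lattice
#' @param lattice a `grid_lattice` to write.
#' @export
write_lattice <- function(lattice, file) {
  utils::write.csv(lattice$cells, file, row.names = FALSE, quote = FALSE, na = "")
  invisible(file)
}
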