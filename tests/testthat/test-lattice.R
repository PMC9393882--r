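test_that("the packaged Baltimore lattice matches the published layout", {
  lat <- baltimore_lattice()
  expect_s3_class(lat, "grid_lattice")
  expect_equal(nrow(lat$cells), 99L)
  expect_equal(sum(lat$cells$has_monitor), 15L)
  expect_equal(sum(lat$cells$n_monitors), 17L)
  expect_equal(lat$cells$n_monitors[lat$cells$row == 6 & lat$cells$col == 6], 3L)
  mon <- lat$cells[lat$cells$has_monitor, c("row", "col")]
  published <- rbind(c(8, 6), c(8, 8), c(7, 5), c(7, 6), c(7, 7), c(6, 6),
                     c(6, 7), c(5, 6), c(5, 7), c(4, 3), c(4, 5), c(4, 6),
                     c(3, 5), c(3, 7), c(2, 6))
  expect_setequal(paste(mon$row, mon$col), paste(published[, 1], published[, 2]))
})

test_that("lattice validity rules reject malformed cell tables", {
  cells <- baltimore_lattice()$cells
  expect_error(grid_lattice(cells[-1, ]), "expected 99 cells")
  dup <- cells; dup$col[1] <- dup$col[2]
  expect_error(grid_lattice(dup), "duplicate")
  bad <- cells; bad$n_monitors[bad$has_monitor][1] <- 0L
  expect_error(grid_lattice(bad), "n_monitors")
})

test_that("canonical order sorts row-descending then column-ascending as a ring", {
  lat <- baltimore_lattice()
  ord_yes <- canonical_order(lat, "Yes")
  expect_equal(ord_yes$row[1:5], c(8, 8, 7, 7, 7))
  expect_equal(ord_yes$col[1:5], c(6, 8, 5, 6, 7))
  ord_both <- canonical_order(lat, "Both")
  expect_equal(nrow(ord_both), 99L)
  i97 <- which(ord_both$row == 9 & ord_both$col == 7)
  expect_equal(unlist(ord_both[i97 - 1L, c("row", "col")], use.names = FALSE),
               c(9, 6))
  # condition subset sizes
  expect_equal(nrow(canonical_order(lat, "No")), 84L)
  expect_error(canonical_order(grid_lattice(within(lat$cells, {
    has_monitor <- FALSE; n_monitors <- 0L
  })), "Yes"), "empty")
})

test_that("lag assignment reproduces all three published worked sequences", {
  lat <- baltimore_lattice()
  no <- assign_lag_grids(lat, c(9, 7), "No")
  expect_equal(no$lags$row, rep(9L, 4))
  expect_equal(no$lags$col, c(6L, 5L, 4L, 3L))
  yes <- assign_lag_grids(lat, c(6, 7), "Yes")
  expect_equal(yes$lags$row, c(6L, 7L, 7L, 7L))
  expect_equal(yes$lags$col, c(6L, 7L, 6L, 5L))
  expect_equal(yes$lags$wrapped, c(FALSE, TRUE, TRUE, TRUE))
  both <- assign_lag_grids(lat, c(4, 7), "Both")
  expect_equal(both$lags$row, rep(4L, 4))
  expect_equal(both$lags$col, c(6L, 5L, 4L, 3L))
})

test_that("a column-4 index grid wraps its fourth lag to column 9 one row up", {
  lat <- baltimore_lattice()
  for (r in c(3, 5, 8)) {
    sq <- assign_lag_grids(lat, c(r, 4), "Both")
    expect_equal(unlist(sq$lags[4, c("row", "col")], use.names = FALSE),
                 c(r + 1, 9))
  }
  # ring wrap past the north-west corner is flagged
  top <- assign_lag_grids(lat, c(11, 3), "Both")
  expect_true(top$wrapped_around_lattice)
  expect_equal(unlist(top$lags[3, c("row", "col")], use.names = FALSE), c(1, 9))
  expect_false(assign_lag_grids(lat, c(4, 7), "Both")$wrapped_around_lattice)
})

test_that("lag assignment errors when the index grid is outside the subset", {
  lat <- baltimore_lattice()
  expect_error(assign_lag_grids(lat, c(9, 7), "Yes"), "yes")
  expect_error(assign_lag_grids(lat, c(6, 6), "No"), "no")
})

test_that("round-trip: stepping forward n_lags positions recovers the index cell", {
  lat <- baltimore_lattice()
  for (cond in c("No", "Yes", "Both")) {
    ord <- canonical_order(lat, cond)
    n <- nrow(ord)
    for (i in seq_len(n)) {
      sq <- assign_lag_grids(lat, c(ord$row[i], ord$col[i]), cond)
      lag4 <- which(ord$row == sq$lags$row[4] & ord$col == sq$lags$col[4])
      expect_equal(((lag4 - 1L + 4L) %% n) + 1L, i)
    }
  }
})

test_that("precede/follow classification follows the index column rule", {
  lat <- baltimore_lattice()
  counts <- function(r, col) {
    cl <- classify_precede_follow(assign_lag_grids(lat, c(r, col), "Both"))
    c(sum(cl == "precede"), sum(cl == "follow"))
  }
  expect_equal(counts(5, 3), c(2L, 2L))
  expect_equal(counts(5, 1), c(0L, 4L))
  expect_equal(counts(5, 2), c(1L, 3L))
  expect_equal(counts(9, 7), c(4L, 0L))
  tab <- precede_follow_table(lat, "Both", weights = rep(1, 99))
  expect_equal(sum(tab$n), 4L * 99L)
  expect_equal(sum(tab$pct), 100)
  expect_equal(tab$pct, tab$pct_weighted)
})

test_that("point-to-grid assignment partitions the lattice (half-open cells)", {
  lat <- baltimore_lattice()
  # exact centre and shared west edge
  expect_equal(unlist(assign_point_to_grid(lat, 4.5 * 12, 4.5 * 12)[, c("row", "col")],
                      use.names = FALSE), c(5, 5))
  expect_equal(unlist(assign_point_to_grid(lat, 4 * 12, 4.5 * 12)[, c("row", "col")],
                      use.names = FALSE), c(5, 5))
  expect_error(assign_point_to_grid(lat, -1, 5), "outside")
  expect_error(assign_point_to_grid(lat, 5, 11 * 12), "outside")
  # 1000 random points: each inside exactly one cell (brute-force containment)
  set.seed(42)
  x <- runif(1000, 0, 9 * 12); y <- runif(1000, 0, 11 * 12)
  got <- assign_point_to_grid(lat, x, y)
  for (i in seq_len(1000)) {
    inside <- lat$cells$row[(lat$cells$col - 1) * 12 <= x[i] &
                              x[i] < lat$cells$col * 12 &
                              (lat$cells$row - 1) * 12 <= y[i] &
                              y[i] < lat$cells$row * 12]
    expect_equal(got$row[i], inside)
  }
  expect_true(all(table(paste(got$row, got$col)) >= 1))
})

test_that("HOSA geometry is linear in the grid count", {
  expect_equal(hosa_geometry(5), list(width_km = 60, area_km2 = 720))
  expect_equal(hosa_geometry(2), list(width_km = 24, area_km2 = 288))
  expect_equal(hosa_geometry(0), list(width_km = 0, area_km2 = 0))
  expect_error(hosa_geometry(-1), "non-negative")
  for (n in 0:8) expect_equal(hosa_geometry(n)$area_km2, 144 * n)
  expect_equal(hosa_geometry(3, cell_width_km = 10),
               list(width_km = 30, area_km2 = 300))
})

test_that("design combination counts multiply the four factors", {
  expect_equal(count_design_combinations(3, 4, 7, 99), 8316)
  expect_equal(count_design_combinations(3, 4, 7, 15), 1260)
  expect_equal(count_design_combinations(1, 1, 1, 1), 1)
  expect_error(count_design_combinations(0, 4, 7, 99), "positive")
})

test_that("lattice files and lag-sequence JSON round-trip", {
  lat <- baltimore_lattice()
  f <- tempfile(fileext = ".csv")
  write_lattice(lat, f)
  lat2 <- read_lattice(f)
  expect_equal(lat2$cells[, 1:5], lat$cells[, 1:5])
  packaged <- read_lattice(system.file("extdata", "baltimore_lattice.csv",
                                       package = "splagcc"))
  expect_equal(sum(packaged$cells$n_monitors), 17L)
  js <- lag_sequences_json(assign_lag_grids(lat, c(9, 7), "No"))
  rec <- jsonlite::fromJSON(js, simplifyVector = FALSE)[[1]]
  expect_equal(rec$condition, "no")
  expect_equal(unlist(rec$index), c(9L, 7L))
  expect_equal(unlist(rec$lags[[1]]), c(9L, 6L))
})
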