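count_vec <- function(...) {
  x <- stats::setNames(rep(0L, 12), cell_classes())
  v <- c(...)
  x[names(v)] <- v
  x
}

test_that("series aggregation follows the five-series mapping", {
  rep1 <- aggregate_series(count_vec(neutrophil = 100))
  expect_equal(unname(rep1$series_pct["granulocytes"]), 100)
  expect_equal(unname(rep1$series_pct["erythroid"]), 0)
  expect_false(rep1$ge_defined)

  counts <- count_vec(neutrophil = 60, erythroblast = 20, lymphocyte = 15,
                      monocyte = 3, plasma_cell = 2)
  rep2 <- aggregate_series(counts)
  expect_equal(unname(rep2$series_pct),
               c(60, 20, 15, 3, 2))
  expect_equal(rep2$ge_ratio, 3)
  expect_true(rep2$ge_defined)
  expect_equal(sum(rep2$series_pct), 100, tolerance = 1e-9)

  # "other" is excluded from the denominator
  rep3 <- aggregate_series(counts + count_vec(other = 50))
  expect_equal(rep3$series_pct, rep2$series_pct)
  expect_equal(rep3$ge_ratio, rep2$ge_ratio)
  expect_identical(rep3$other_count, 50L)
})

test_that("all-zero counts flag every percentage undefined", {
  rep0 <- aggregate_series(count_vec())
  expect_identical(rep0$denominator, 0L)
  expect_true(all(is.na(rep0$series_pct)))
})

test_that("aggregation is additive over count vectors", {
  marrowdiff:::with_local_seed(6, {
    for (i in 1:10) {
      a <- stats::setNames(rpois(12, 20), cell_classes())
      b <- stats::setNames(rpois(12, 5), cell_classes())
      sum_rep <- aggregate_series(a + b)
      ra <- aggregate_series(a); rb <- aggregate_series(b)
      expect_equal(sum_rep$series_counts, ra$series_counts + rb$series_counts)
      expect_equal(sum_rep$series_pct,
                   100 * (ra$series_counts + rb$series_counts) /
                     (ra$denominator + rb$denominator))
    }
  })
})

test_that("every class maps to exactly one series or to other", {
  map <- series_map()
  expect_setequal(names(map), cell_classes())
  expect_true(all(map %in% c(series_names(), "other")))
})

test_that("reports round-trip through JSON and print a fixed CSV layout", {
  counts <- count_vec(neutrophil = 61, erythroblast = 17, lymphocyte = 14,
                      monocyte = 5, plasma_cell = 3, other = 7)
  rep <- aggregate_series(counts)
  jp <- tempfile(fileext = ".json"); cp <- tempfile(fileext = ".csv")
  render_report(rep, metadata = list(smear = "demo"), json_path = jp,
                csv_path = cp)
  back <- read_report(jp)
  expect_equal(back$series_pct, rep$series_pct)
  expect_equal(back$ge_ratio, rep$ge_ratio)
  expect_identical(back$denominator, rep$denominator)

  csv <- utils::read.csv(cp, colClasses = "character")
  expect_identical(names(csv), c("series", "count", "percent"))
  expect_identical(csv$series, c(series_names(), "other", "total", "ge_ratio"))
  # percentages to 1 decimal, ratio to 2 decimals
  expect_identical(csv$percent[1], sprintf("%.1f", rep$series_pct[[1]]))
  expect_identical(csv$percent[8], sprintf("%.2f", rep$ge_ratio))
})

test_that("unknown class labels are rejected at the tally step", {
  expect_error(differential_count(c("neutrophil", "blastocyte")), "unknown")
})
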