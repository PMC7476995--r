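#' Tally per-cell classifications into a differential count
#'
#' @param classes character vector of per-cell class labels (values in
#'   [cell_classes()]).
#' @return named integer vector over all 12 classes.
#' @export
differential_count <- function(classes) {
  bad <- setdiff(unique(classes), cell_classes())
  if (length(bad) > 0) stop("unknown classes: ", paste(bad, collapse = ", "))
  counts <- table(factor(classes, levels = cell_classes()))
  stats::setNames(as.integer(counts), cell_classes())
}

#' Aggregate a differential count into the five-series report
#'
#' Granulocytes = myeloblast + promyelocyte + myelocyte + metamyelocyte +
#' neutrophil + eosinophil + basophil; erythroid = erythroblast; lymphoid =
#' lymphocyte; monocytes = monocyte; plasma cells = plasma cell.  "Other"
#' is reported as a count but excluded from the percentage denominator, so
#' the five series sum to 100.  The G:E ratio uses raw counts and is
#' flagged undefined when no erythroblasts were counted.
#'
#' @param counts named nonnegative integer vector over [cell_classes()]
#'   (as from [differential_count()]).
#' @return object of class `series_report`: list with `series_counts`,
#'   `series_pct` (NA-flagged when the denominator is 0), `other_count`,
#'   `denominator`, `total`, `ge_ratio`, `ge_defined`.
#' @export
aggregate_series <- function(counts) {
  stopifnot(!is.null(names(counts)), setequal(names(counts), cell_classes()),
            all(counts >= 0))
  counts <- counts[cell_classes()]
  map <- series_map()
  sc <- vapply(series_names(), function(s) {
    as.integer(sum(counts[names(map)[map == s]]))
  }, integer(1))
  other <- as.integer(counts[["other"]])
  denom <- sum(sc)
  pct <- if (denom > 0) 100 * sc / denom else
    stats::setNames(rep(NA_real_, 5), series_names())
  ge_defined <- counts["erythroblast"] > 0
  ge <- if (ge_defined) unname(sc["granulocytes"] / counts["erythroblast"])
        else NA_real_
  structure(list(
    series_counts = sc, series_pct = pct, other_count = other,
    denominator = denom, total = as.integer(sum(counts)),
    ge_ratio = ge, ge_defined = unname(ge_defined)
  ), class = "series_report")
}

#' Write a series report as JSON and CSV
#'
#' The JSON carries full precision and round-trips through
#' [read_report()].  The CSV has the fixed column order
#' `series,count,percent` (percent to 1 decimal) followed by summary rows
#' `other`, `total`, and `ge_ratio` (2 decimals).
#'
#' @param report a [aggregate_series()] result.
#' @param metadata named list stored verbatim in the JSON.
#' @param json_path,csv_path output paths (`NULL` skips that format).
#' @return invisibly, a list of the paths written.
#' @export
render_report <- function(report, metadata = list(), json_path = NULL,
                          csv_path = NULL) {
  stopifnot(inherits(report, "series_report"))
  paths <- list()
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(series_counts = as.list(report$series_counts),
           series_pct = as.list(report$series_pct),
           other_count = report$other_count,
           denominator = report$denominator, total = report$total,
           ge_ratio = report$ge_ratio, ge_defined = report$ge_defined,
           metadata = metadata),
      json_path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
    paths$json <- json_path
  }
  if (!is.null(csv_path)) {
    df <- data.frame(
      series = c(series_names(), "other", "total", "ge_ratio"),
      count = c(report$series_counts, report$other_count, report$total, NA),
      percent = c(sprintf("%.1f", report$series_pct), "", "",
                  if (report$ge_defined) sprintf("%.2f", report$ge_ratio)
                  else "undefined"))
    utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE, na = "")
    paths$csv <- csv_path
  }
  invisible(paths)
}

#' @rdname render_report
#' @param json_path path of a report written by [render_report()].
#' @export
read_report <- function(json_path) {
  x <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  pick <- function(lst) {
    vapply(series_names(), function(s) {
      v <- lst[[s]]
      if (is.null(v) || length(v) == 0) NA_real_ else as.numeric(v)
    }, numeric(1))
  }
  structure(list(
    series_counts = pick(x$series_counts),
    series_pct = pick(x$series_pct),
    other_count = x$other_count, denominator = x$denominator,
    total = x$total,
    ge_ratio = if (is.null(x$ge_ratio)) NA_real_ else x$ge_ratio,
    ge_defined = x$ge_defined
  ), class = "series_report")
}
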