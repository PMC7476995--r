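# Pipeline orchestration: simulate -> train -> analyze -> evaluate, each a
# plain function over a config list.  The CLI in inst/scripts/marrowdiff is
# a thin wrapper around these.

#' Load a pipeline configuration
#'
#' Accepts a list (returned as-is), or a path to a YAML or JSON file with
#' per-stage blocks.  CLI flags override file values.
#'
#' @param config list or file path.
#' @return named list.
#' @export
load_config <- function(config) {
  if (is.list(config)) return(config)
  stopifnot(is.character(config), file.exists(config))
  if (grepl("\\.ya?ml$", config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configs need the 'yaml' package; use JSON instead")
    }
    yaml::read_yaml(config)
  } else {
    jsonlite::read_json(config, simplifyVector = TRUE)
  }
}

pkg_version <- function() {
  as.character(utils::packageVersion("marrowdiff"))
}

write_manifest <- function(dir, stage, timings, counts, config) {
  jsonlite::write_json(
    list(tool = "marrowdiff", version = pkg_version(), stage = stage,
         timings_sec = timings, counts = counts,
         config_digest = paste(format(config[order(names(config))]),
                               collapse = "|")),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
}

#' Generate a synthetic fixture directory
#'
#' Writes `n_fields` field PNGs with per-field ground-truth JSON, an
#' optional paired-differentials CSV, and a run manifest.  Identical
#' config and seed give byte-identical trees.
#'
#' @param config list with `out_dir`, `seed`, optional `n_fields`
#'   (default 3), `field` (arguments for [field_spec()]), and
#'   `differentials` (arguments for [paired_differential_spec()]; omit to
#'   skip the CSV).
#' @return the output directory, invisibly.
#' @export
run_simulate <- function(config) {
  config <- load_config(config)
  out <- config$out_dir %||% stop("config needs out_dir")
  seed <- config$seed %||% 1L
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  n_fields <- config$n_fields %||% 3L
  n_cells <- 0L
  for (i in seq_len(n_fields)) {
    args <- utils::modifyList(config$field %||% list(),
                              list(seed = seed + i - 1L))
    fld <- render_field(do.call(field_spec, args))
    n_cells <- n_cells + length(fld$cells)
    write_image(fld$image, file.path(out, sprintf("field_%03d.png", i)))
    write_ground_truth(fld, file.path(out, sprintf("field_%03d.json", i)))
  }
  if (!is.null(config$differentials)) {
    dargs <- utils::modifyList(config$differentials, list(seed = seed))
    pd <- simulate_paired_differentials(
      do.call(paired_differential_spec, dargs))
    write_paired_csv(pd, file.path(out, "paired_differentials.csv"))
  }
  write_manifest(out, "simulate",
                 list(total = proc.time()[["elapsed"]] - t0),
                 list(fields = n_fields, cells = n_cells), config)
  invisible(out)
}

#' Train the classifier on a synthetic corpus
#'
#' @param config list with `seed`, optional `n_per_class` (default 150),
#'   `model_path` (RDS archive to write), and `train` (config forwarded to
#'   [train_classifier()]).
#' @return the trained model, invisibly.
#' @export
run_train <- function(config) {
  config <- load_config(config)
  seed <- config$seed %||% 1L
  corpus <- synthetic_feature_corpus(
    n_per_class = config$n_per_class %||% 150, seed = seed)
  model <- train_classifier(corpus, config = config$train %||% list(),
                            seed = seed)
  if (!is.null(config$model_path)) save_model(model, config$model_path)
  invisible(model)
}

#' Analyze field images into a differential report
#'
#' For each input field (a directory of PNGs, a list of arrays, or a
#' synthetic `field` spec block): localize nucleated cells, segment each
#' crop, extract features, rank the 12 classes, and aggregate top-1 calls
#' into the five-series report.
#'
#' @param config list with `out_dir`, a model (`model` object or
#'   `model_path`), one input source (`input_dir`, `images`, or `field` +
#'   `n_fields` + `seed`), and optional `locseg` ([locseg_params()]
#'   arguments).
#' @return list with `report` (a `series_report`), `cells` (per-cell
#'   data.frame: field, box, top-5 classes and probabilities), and the
#'   output paths; also written as JSON/CSV under `out_dir`.
#' @export
run_analyze <- function(config) {
  config <- load_config(config)
  out <- config$out_dir %||% stop("config needs out_dir")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]

  model <- if (!is.null(config$model)) {
    config$model
  } else if (!is.null(config$model_path)) {
    load_model(config$model_path)
  } else {
    stop("no classifier model: set model_path (train one with run_train(),",
         " e.g. run_train(list(seed = 1, model_path = 'model.rds')))")
  }

  sources <- c(!is.null(config$input_dir), !is.null(config$images),
               !is.null(config$field))
  if (sum(sources) != 1) stop("config needs exactly one input source")
  images <- if (!is.null(config$input_dir)) {
    paths <- sort(list.files(config$input_dir, "\\.(png|tif|tiff)$",
                             full.names = TRUE, ignore.case = TRUE))
    lapply(paths, read_image)
  } else if (!is.null(config$images)) {
    config$images
  } else {
    seed <- config$seed %||% 1L
    lapply(seq_len(config$n_fields %||% 1L), function(i) {
      args <- utils::modifyList(config$field, list(seed = seed + i - 1L))
      render_field(do.call(field_spec, args))$image
    })
  }

  params <- do.call(locseg_params, config$locseg %||% list())
  cell_rows <- list()
  for (fi in seq_along(images)) {
    img <- images[[fi]]
    boxes <- localize_nucleated_cells(img, params)
    for (bi in seq_len(nrow(boxes))) {
      box <- boxes[bi, ]
      crop <- crop_box(img, box)
      mask <- segment_cell(crop, params)
      ft <- extract_features(crop, mask)
      pred <- predict_topk(model, ft, k = 5)[[1]]
      row <- data.frame(field = fi, box[, c("row0", "col0", "row1", "col1")],
                        predicted = pred$ranking$class[1])
      for (j in 1:5) {
        row[[paste0("top", j)]] <- pred$top$class[j]
        row[[paste0("prob", j)]] <- pred$top$prob[j]
      }
      cell_rows[[length(cell_rows) + 1L]] <- row
    }
  }
  cells <- if (length(cell_rows) > 0) do.call(rbind, cell_rows) else
    data.frame(field = integer(0), predicted = character(0))
  if (nrow(cells) == 0) {
    warning("no nucleated cells detected; report has denominator 0")
  }
  counts <- differential_count(cells$predicted)
  report <- aggregate_series(counts)
  render_report(report, metadata = list(n_fields = length(images)),
                json_path = file.path(out, "report.json"),
                csv_path = file.path(out, "report.csv"))
  utils::write.csv(cells, file.path(out, "cells.csv"), row.names = FALSE)
  write_manifest(out, "analyze",
                 list(total = proc.time()[["elapsed"]] - t0),
                 list(fields = length(images), cells = nrow(cells)),
                 config[setdiff(names(config), c("model", "images"))])
  invisible(list(report = report, cells = cells, out_dir = out))
}

#' Evaluate predictions and paired differential counts
#'
#' With `truth`/`predicted` (vectors or a CSV with those columns) it emits
#' confusion metrics; with a paired-differentials CSV it emits, per series,
#' the ICC, Passing-Bablok regression, and Bland-Altman limits, plus the
#' same analyses for the G:E ratio when both methods report erythroid > 0.
#'
#' @param config list with `out_dir`, and either `predictions` (CSV path or
#'   data.frame with `truth`, `predicted`) or `paired` (CSV path or
#'   data.frame from [simulate_paired_differentials()]); optional `plots`
#'   (logical; write Passing-Bablok and Bland-Altman PNGs per series).
#' @return list of results, also written as `metrics.json` under `out_dir`.
#' @export
run_evaluate <- function(config) {
  config <- load_config(config)
  out <- config$out_dir %||% stop("config needs out_dir")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  results <- list()

  if (!is.null(config$predictions)) {
    df <- if (is.character(config$predictions)) {
      utils::read.csv(config$predictions, stringsAsFactors = FALSE)
    } else {
      config$predictions
    }
    stopifnot(all(c("truth", "predicted") %in% names(df)))
    cm <- confusion_matrix(df$truth, df$predicted)
    results$classification <- class_metrics(cm)
  }

  if (!is.null(config$paired)) {
    df <- if (is.character(config$paired)) read_paired_csv(config$paired)
          else config$paired
    wide_a <- stats::reshape(df[, c("smear_id", "series", "method_a")],
                             idvar = "smear_id", timevar = "series",
                             direction = "wide")
    wide_b <- stats::reshape(df[, c("smear_id", "series", "method_b")],
                             idvar = "smear_id", timevar = "series",
                             direction = "wide")
    if (nrow(wide_a) != nrow(wide_b)) {
      stop("paired input mismatch: ", nrow(wide_a), " vs ", nrow(wide_b),
           " smears")
    }
    per_series <- list()
    for (s in intersect(series_names(), unique(df$series))) {
      a <- wide_a[[paste0("method_a.", s)]]
      b <- wide_b[[paste0("method_b.", s)]]
      pb <- passing_bablok(a, b)
      ba <- bland_altman(a, b)
      icc <- icc_consistency(cbind(a, b))
      per_series[[s]] <- list(
        icc = unclass(icc), passing_bablok = unclass(pb)[
          c("slope", "intercept", "slope_ci", "intercept_ci", "n_pairs",
            "n_slopes", "linearity_stat", "linearity_p", "linear")],
        bland_altman = unclass(ba)[
          c("bias", "sd_diff", "loa_lower", "loa_upper", "bias_ci",
            "loa_lower_ci", "loa_upper_ci", "multiplier", "n")])
      if (isTRUE(config$plots)) {
        grDevices::png(file.path(out, sprintf("pb_%s.png", s)),
                       width = 600, height = 600)
        plot_passing_bablok(a, b, pb, main = paste("Passing-Bablok:", s))
        grDevices::dev.off()
        grDevices::png(file.path(out, sprintf("ba_%s.png", s)),
                       width = 600, height = 600)
        plot_bland_altman(ba, main = paste("Bland-Altman:", s))
        grDevices::dev.off()
      }
    }
    results$paired <- per_series
  }

  jsonlite::write_json(results, file.path(out, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  invisible(results)
}
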