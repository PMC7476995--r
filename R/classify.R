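#' Render a single labelled cell crop
#'
#' Renders one cell of the requested class on a small field (with a light
#' scattering of red cells so crops carry realistic context) and crops a
#' square window around it, rebasing the ground-truth masks to the crop.
#'
#' @param cell_class one of [cell_classes()].
#' @param seed integer seed.
#' @param margin crop margin as a fraction of the cell box side.
#' @param noise_sd,rbc_density,cell_scale,phenotypes forwarded to
#'   [field_spec()].
#' @return list with `image` (RGB crop), `cell_class`, `cell_mask`,
#'   `nucleus_mask` (crop-registered logical matrices).
#' @export
render_cell_crop <- function(cell_class, seed = 1, margin = 0.35,
                             noise_sd = 4, rbc_density = 0.05,
                             cell_scale = 1,
                             phenotypes = default_phenotypes()) {
  rmax <- ceiling(max(phenotypes[[cell_class]]$cell_radius_range) *
                    cell_scale)
  side <- ceiling(2 * rmax * (1 + 2 * margin)) + 8L
  freq <- stats::setNames(rep(0, 12), cell_classes())
  freq[cell_class] <- 1
  spec <- field_spec(width = side, height = side, n_nucleated = 1,
                     rbc_density = rbc_density, class_frequencies = freq,
                     noise_sd = noise_sd, min_cell_gap = 0, seed = seed,
                     cell_scale = cell_scale, phenotypes = phenotypes)
  fld <- render_field(spec)
  cell <- fld$cells[[1]]
  b <- cell$bbox
  # frame on the nucleus box exactly as the detector does, so training
  # crops and analysis-time crops share the same framing distribution
  np <- which(cell$nucleus_mask, arr.ind = TRUE)
  nr0 <- b[["row0"]] + min(np[, 1]) - 1L; nr1 <- b[["row0"]] + max(np[, 1]) - 1L
  nc0 <- b[["col0"]] + min(np[, 2]) - 1L; nc1 <- b[["col0"]] + max(np[, 2]) - 1L
  s <- max(nr1 - nr0, nc1 - nc0) + 1
  m <- round(margin * s)
  r0 <- max(1L, nr0 - m); r1 <- min(side, nr1 + m)
  c0 <- max(1L, nc0 - m); c1 <- min(side, nc1 + m)
  cmask <- nmask <- matrix(FALSE, r1 - r0 + 1, c1 - c0 + 1)
  ro <- max(r0, b[["row0"]]):min(r1, b[["row1"]])
  co <- max(c0, b[["col0"]]):min(c1, b[["col1"]])
  cmask[ro - r0 + 1, co - c0 + 1] <-
    cell$cell_mask[ro - b[["row0"]] + 1, co - b[["col0"]] + 1]
  nmask[ro - r0 + 1, co - c0 + 1] <-
    cell$nucleus_mask[ro - b[["row0"]] + 1, co - b[["col0"]] + 1]
  list(image = fld$image[r0:r1, c0:c1, , drop = FALSE],
       cell_class = cell_class, cell_mask = cmask, nucleus_mask = nmask)
}

#' Build a labelled synthetic feature corpus
#'
#' Renders `n_per_class` crops for each class, segments each crop with
#' [segment_cell()], and extracts [feature_names()] records — the same path
#' a field crop follows at analysis time.
#'
#' @param n_per_class crops per class.
#' @param seed integer seed.
#' @param classes classes to include (default all 12).
#' @param params a [locseg_params()] for segmentation.
#' @param ... forwarded to [render_cell_crop()].
#' @return data.frame of features with a `label` factor column.
#' @export
synthetic_feature_corpus <- function(n_per_class = 150, seed = 1,
                                     classes = cell_classes(),
                                     params = locseg_params(), ...) {
  rows <- vector("list", n_per_class * length(classes))
  idx <- 0L
  for (ci in seq_along(classes)) {
    for (i in seq_len(n_per_class)) {
      idx <- idx + 1L
      crop <- render_cell_crop(classes[ci],
                               seed = seed + 7919L * ci + i, ...)
      mask <- segment_cell(crop$image, params)
      ft <- extract_features(crop$image, mask)
      ft$label <- classes[ci]
      rows[[idx]] <- ft
    }
  }
  out <- do.call(rbind, rows)
  out$label <- factor(out$label, levels = cell_classes())
  out
}

#' Train the 12-category cell classifier
#'
#' Fits the default probabilistic model — a seeded random forest
#' (\pkg{ranger}) over the interpretable feature set — on a stratified
#' 0.8/0.2 split and reports the held-out confusion matrix.  Inverse-class-
#' frequency case weights counter the strong class imbalance typical of
#' marrow differentials.  The model interface is pluggable: any
#' `fit(x, y, weights, seed)` returning an object with a
#' `predict_prob(model, x)` method can stand in.
#'
#' @param records data.frame with [feature_names()] columns and a `label`
#'   column (values in [cell_classes()]).
#' @param config list: `num_trees` (default 500), `mtry` (default NULL =
#'   ranger's default), `class_weights` (`"inverse"` or `"none"`),
#'   `train_fraction` (default 0.8).
#' @param seed integer; fixes the split and the forest.
#' @return object of class `marrow_classifier`: the fitted forest, class
#'   list, feature names, config digest, held-out confusion matrix and
#'   accuracy.
#' @export
train_classifier <- function(records, config = list(), seed = 1) {
  stopifnot(is.data.frame(records), "label" %in% names(records))
  records$label <- factor(as.character(records$label),
                          levels = cell_classes())
  if (anyNA(records$label)) stop("unknown class labels in training records")
  present <- levels(droplevels(records$label))
  if (length(present) < 2) stop("need at least 2 classes present")
  tab <- table(droplevels(records$label))
  if (any(tab < 5)) {
    stop("too few records for class(es): ",
         paste(names(tab)[tab < 5], collapse = ", "),
         " (at least 5 per present class required)")
  }
  cfg <- utils::modifyList(
    list(num_trees = 500L, mtry = NULL, class_weights = "inverse",
         train_fraction = 0.8), config)

  with_local_seed(seed, {
    # stratified split keeps every present class in both partitions
    idx_train <- unlist(lapply(split(seq_len(nrow(records)), records$label),
                               function(ix) {
      if (length(ix) == 0) return(integer(0))
      n_tr <- max(1L, round(cfg$train_fraction * length(ix)))
      sample(ix, n_tr)
    }), use.names = FALSE)
    idx_test <- setdiff(seq_len(nrow(records)), idx_train)

    xcols <- feature_names()
    train <- records[idx_train, c(xcols, "label")]
    train$label <- droplevels(train$label)
    w <- if (identical(cfg$class_weights, "inverse")) {
      freq <- table(train$label)
      as.numeric(1 / freq[train$label])
    } else {
      rep(1, nrow(train))
    }
    fit <- ranger::ranger(
      dependent.variable.name = "label", data = train,
      probability = TRUE, num.trees = cfg$num_trees, mtry = cfg$mtry,
      case.weights = w, seed = seed, num.threads = 1
    )
    model <- structure(list(
      forest = fit, classes = cell_classes(), feature_names = xcols,
      config = cfg,
      config_digest = paste(format(cfg[order(names(cfg))]), collapse = "|"),
      seed = as.integer(seed), trained = TRUE
    ), class = "marrow_classifier")

    if (length(idx_test) > 0) {
      preds <- predict_topk(model, records[idx_test, xcols], k = 1)
      top1 <- vapply(preds, function(p) p$ranking$class[1], character(1))
      model$holdout_confusion <-
        confusion_matrix(as.character(records$label[idx_test]), top1)
      model$holdout_accuracy <-
        sum(diag(model$holdout_confusion)) / sum(model$holdout_confusion)
      model$holdout_index <- idx_test
    }
    model
  })
}

#' Rank the twelve classes for one or more cells
#'
#' Returns the full probability ranking plus the top-k slice for each
#' feature record.  Probabilities over all 12 classes sum to one; classes
#' absent from training score zero; ties break by the fixed
#' [cell_classes()] order.  Records flagged `degenerate` are routed to
#' class "other" with probability one.
#'
#' @param model a trained [train_classifier()] model.
#' @param features data.frame of feature records (columns addressed by
#'   name; order is irrelevant).
#' @param k how many top entries to report (<= 12).
#' @return list of predictions, one per row: each has `ranking` (data.frame
#'   `class`, `prob`, all 12 classes, descending) and `top` (first `k`
#'   rows).  A single-row input still returns a length-1 list.
#' @export
predict_topk <- function(model, features, k = 5) {
  if (!inherits(model, "marrow_classifier") || !isTRUE(model$trained)) {
    stop("predict_topk() needs a trained marrow_classifier")
  }
  stopifnot(k >= 1, k <= 12)
  missing <- setdiff(model$feature_names, names(features))
  if (length(missing) > 0) {
    stop("missing feature columns: ", paste(missing, collapse = ", "))
  }
  x <- features[, model$feature_names, drop = FALSE]
  degen <- if ("degenerate" %in% names(features)) {
    as.logical(features$degenerate)
  } else {
    rep(FALSE, nrow(x))
  }
  pr <- stats::predict(model$forest, data = x, num.threads = 1)$predictions
  if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1)
  lapply(seq_len(nrow(x)), function(i) {
    p <- stats::setNames(rep(0, 12), model$classes)
    if (degen[i]) {
      p["other"] <- 1
    } else {
      p[colnames(pr)] <- pr[i, ]
    }
    ord <- order(-p, match(names(p), model$classes))
    ranking <- data.frame(class = names(p)[ord], prob = unname(p[ord]),
                          stringsAsFactors = FALSE)
    list(ranking = ranking, top = utils::head(ranking, k))
  })
}

#' Held-out evaluation of a classifier
#'
#' @param model a trained [train_classifier()] model.
#' @return [class_metrics()] of the model's held-out confusion matrix.
#' @export
evaluate_classifier <- function(model) {
  if (is.null(model$holdout_confusion)) {
    stop("model carries no held-out confusion matrix")
  }
  class_metrics(model$holdout_confusion)
}

#' Save / load a classifier model archive
#'
#' The archive is versioned through the training-config digest, which is
#' checked on load.
#'
#' @param model a `marrow_classifier`.
#' @param path file path.
#' @return `path` (save) or the model (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "marrow_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "marrow_classifier") ||
      is.null(model$config_digest)) {
    stop("not a marrowdiff classifier archive: ", path)
  }
  expect <- paste(format(model$config[order(names(model$config))]),
                  collapse = "|")
  if (!identical(expect, model$config_digest)) {
    stop("classifier archive failed its config-digest check: ", path)
  }
  model
}
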