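test_that("geometric features match analytic values on disc fixtures", {
  side <- 51
  ctr <- 26
  d <- outer(1:side, 1:side, function(r, c) sqrt((r - ctr)^2 + (c - ctr)^2))
  cellm <- d <= 20
  nucm <- d <= 10
  mask <- truth_to_mask(cellm, nucm)
  crop <- array(200, dim = c(side, side, 3))
  crop[, , 1][cellm] <- 170  # tint so compartments have colour structure
  crop[, , 3][nucm] <- 150; crop[, , 1][nucm] <- 80
  ft <- extract_features(crop, mask)
  expect_false(ft$degenerate)
  expect_equal(ft$nc_ratio, 0.25, tolerance = 0.03)
  expect_equal(ft$circularity, 1, tolerance = 0.1)
  expect_lt(ft$nucleus_eccentricity, 0.15)
  expect_lt(ft$nucleus_lobedness, 0.05)

  # nucleus == cell boundary case
  mask2 <- truth_to_mask(cellm, cellm)
  ft2 <- extract_features(crop, mask2)
  expect_equal(ft2$nc_ratio, 1)
})

test_that("lobed nuclei score higher lobedness than convex ones", {
  convex <- render_cell_crop("myeloblast", seed = 2)
  lobed <- render_cell_crop("neutrophil", seed = 2)
  ft_c <- extract_features(convex$image,
                           truth_to_mask(convex$cell_mask,
                                         convex$nucleus_mask))
  ft_l <- extract_features(lobed$image,
                           truth_to_mask(lobed$cell_mask,
                                         lobed$nucleus_mask))
  expect_lt(ft_c$nucleus_lobedness, 0.1)
  expect_gt(ft_l$nucleus_lobedness, ft_c$nucleus_lobedness)
})

test_that("degenerate masks produce flagged records, not NaNs", {
  crop <- array(200, dim = c(10, 10, 3))
  ft <- extract_features(crop, matrix(0L, 10, 10))
  expect_true(ft$degenerate)
  expect_false(anyNA(ft))
})

test_that("a separable two-class fixture trains to perfect held-out accuracy", {
  rec <- separable_records(200, seed = 3)
  model <- train_classifier(rec, seed = 5)
  expect_equal(model$holdout_accuracy, 1)
  # top-1 equals truth on the held-out records
  ho <- rec[model$holdout_index, ]
  preds <- predict_topk(model, ho, k = 1)
  top1 <- vapply(preds, function(p) p$ranking$class[1], character(1))
  expect_identical(top1, as.character(ho$label))
})

test_that("permuted labels collapse accuracy to chance", {
  rec <- separable_records(200, seed = 3)
  rec$label <- marrowdiff:::with_local_seed(11, sample(rec$label))
  model <- train_classifier(rec, seed = 5)
  # 2 balanced classes: chance 0.5; 99% binomial band around it
  n_ho <- sum(model$holdout_confusion)
  band <- 2.58 * sqrt(0.25 / n_ho)
  expect_lt(abs(model$holdout_accuracy - 0.5), band + 0.05)
})

test_that("training is deterministic given data, config, and seed", {
  rec <- separable_records(40, seed = 7)
  m1 <- train_classifier(rec, seed = 13)
  m2 <- train_classifier(rec, seed = 13)
  expect_identical(m1$holdout_confusion, m2$holdout_confusion)
})

test_that("prediction rankings are complete, normalized, and name-addressed", {
  rec <- separable_records(40, seed = 7)
  model <- train_classifier(rec, seed = 13)
  p <- predict_topk(model, rec[1, ], k = 12)[[1]]
  expect_setequal(p$ranking$class, cell_classes())
  expect_equal(sum(p$ranking$prob), 1, tolerance = 1e-9)
  expect_true(all(diff(p$ranking$prob) <= 1e-12))
  expect_identical(nrow(p$top), 12L)
  # feature-order permutation leaves the prediction unchanged
  shuffled <- rec[1, rev(seq_along(rec))]
  p2 <- predict_topk(model, shuffled, k = 12)[[1]]
  expect_identical(p$ranking, p2$ranking)
  # default top-5 slice
  p5 <- predict_topk(model, rec[1, ])[[1]]
  expect_identical(nrow(p5$top), 5L)
})

test_that("degenerate records route to 'other' and tie-break in class order", {
  rec <- separable_records(40, seed = 7)
  model <- train_classifier(rec, seed = 13)
  degen <- extract_features(array(200, dim = c(8, 8, 3)), matrix(0L, 8, 8))
  p <- predict_topk(model, degen, k = 12)[[1]]
  expect_identical(p$ranking$class[1], "other")
  expect_equal(p$ranking$prob[1], 1)
  # the eleven zero-probability classes keep the canonical class order
  expect_identical(p$ranking$class[-1],
                   setdiff(cell_classes(), "other"))
})

test_that("training preconditions are enforced", {
  rec <- separable_records(40, seed = 7)
  expect_error(train_classifier(rec[rec$label == "myeloblast", ], seed = 1),
               "2 classes")
  small <- rbind(rec[rec$label == "myeloblast", ][1:4, ],
                 rec[rec$label == "neutrophil", ][1:10, ])
  expect_error(train_classifier(small, seed = 1), "at least 5")
  bad <- rec; bad$label <- as.character(bad$label); bad$label[1] <- "blastoid"
  expect_error(train_classifier(bad, seed = 1), "unknown class")
  expect_error(predict_topk(list(), rec[1, ]), "trained")
})

test_that("model archives round-trip and verify their config digest", {
  rec <- separable_records(40, seed = 7)
  model <- train_classifier(rec, seed = 13)
  path <- tempfile(fileext = ".rds")
  save_model(model, path)
  re <- load_model(path)
  expect_identical(re$holdout_confusion, model$holdout_confusion)
  bad <- model; bad$config_digest <- "tampered"
  saveRDS(bad, path)
  expect_error(load_model(path), "digest")
})

test_that("classifier evaluation agrees with the confusion-metric module", {
  rec <- separable_records(100, seed = 3)
  model <- train_classifier(rec, seed = 5)
  ev <- evaluate_classifier(model)
  direct <- class_metrics(model$holdout_confusion)
  expect_identical(ev, direct)
})
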