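# Shared sharp/blurred fixture for the scorer tests
sharp_field <- render_field(field_spec(width = 160, height = 160,
                                       n_nucleated = 6, cell_scale = 0.7,
                                       seed = 21))
blurred_img <- marrowdiff:::blur_rgb(sharp_field$image, 3)

test_that("coarse score is the population variance of ROI luminance", {
  patch <- matrix(0, 3, 3)
  patch[2, 2] <- 9
  roi <- matrix(TRUE, 3, 3)
  expect_equal(coarse_score(patch, roi), 8)            # mean 1, MSD 72/9
  expect_equal(coarse_score(patch + 100, roi), 8)      # shift invariance
  expect_equal(coarse_score(matrix(7, 5, 5), matrix(TRUE, 5, 5)), 0)
  expect_error(coarse_score(patch, matrix(FALSE, 3, 3)))
})

test_that("fine score is an edge fraction: zero on flat, higher when sharp", {
  flat <- matrix(50, 32, 32)
  roi <- matrix(TRUE, 32, 32)
  expect_equal(fine_score(flat, roi), 0)
  roi_f <- find_wbc_region(sharp_field$image)
  s_sharp <- fine_score(sharp_field$image, roi_f)
  s_blur <- fine_score(blurred_img, roi_f)
  expect_gt(s_sharp, s_blur)
  expect_gte(s_sharp, 0); expect_lte(s_sharp, 1)
  rnd <- matrix(runif(1024, 0, 255), 32, 32)
  s <- fine_score(rnd, roi)
  expect_gte(s, 0); expect_lte(s, 1)
})

test_that("extra blur never increases the fine score", {
  roi <- find_wbc_region(sharp_field$image)
  for (s in c(31, 32, 33)) {
    fld <- render_field(field_spec(width = 160, height = 160,
                                   n_nucleated = 6, cell_scale = 0.7,
                                   seed = s))
    r <- find_wbc_region(fld$image)
    scores <- vapply(c(0, 1.5, 3), function(sg) {
      fine_score(marrowdiff:::blur_rgb(fld$image, sg), r)
    }, numeric(1))
    expect_true(all(diff(scores) <= 1e-12))
  }
})

test_that("the WBC ROI captures nuclei and flags fields without them", {
  roi <- find_wbc_region(sharp_field$image)
  nuc <- Reduce(`|`, lapply(sharp_field$cells, full_mask,
                            dim = dim(roi), which = "nucleus"))
  expect_gte(mean(roi[nuc]), 0.9)
  expect_false(attr(roi, "flagged"))

  rbc_only <- render_field(field_spec(width = 160, height = 160,
                                      n_nucleated = 0, seed = 3))
  roi2 <- find_wbc_region(rbc_only$image)
  expect_true(attr(roi2, "flagged"))
  expect_true(all(roi2))

  bright <- array(240, dim = c(32, 32, 3))
  expect_true(attr(find_wbc_region(bright), "flagged"))
})

test_that("autofocus picks the least-blurred slice; ties go to the lowest index", {
  base <- field_spec(width = 128, height = 128, n_nucleated = 3,
                     cell_scale = 0.5, seed = 10)
  st0 <- render_zstack(zstack_spec(base, z_positions = -2:2, focus_z = 0,
                                   blur_coefficient = 0))
  r0 <- autofocus_stack(st0$slices)
  expect_identical(r0$best_index, 1L)  # identical slices: lowest index wins

  # monotone blur: slice 1 is sharpest
  fld <- render_field(base)
  mono <- lapply(seq(0, 4, length.out = 5), function(sg) {
    marrowdiff:::blur_rgb(fld$image, sg)
  })
  expect_identical(autofocus_stack(mono)$best_index, 1L)

  expect_error(autofocus_stack(mono[1:2]))
})

test_that("stride-1 full-window search equals the global fine-score argmax", {
  st <- render_zstack(zstack_spec(
    field_spec(width = 128, height = 128, n_nucleated = 3,
               cell_scale = 0.5, seed = 14),
    z_positions = seq(-3, 3), focus_z = 0.4))
  res <- autofocus_stack(st$slices, stride = 1, window = length(st$slices))
  roi <- find_wbc_region(st$slices[[ceiling(length(st$slices) / 2)]])
  oracle <- which.max(vapply(st$slices, fine_score, numeric(1), roi = roi))
  expect_identical(res$best_index, oracle)
  expect_identical(res$best_index, st$focus_index)
})
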