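test_that("degenerate spec renders a uniform background with no cells", {
  spec <- field_spec(width = 64, height = 48, n_nucleated = 0,
                     rbc_density = 0, noise_sd = 0, seed = 1)
  fld <- render_field(spec)
  expect_length(fld$cells, 0)
  expect_equal(dim(fld$image), c(48, 64, 3))
  for (ch in 1:3) {
    expect_true(all(fld$image[, , ch] == spec$background_color[ch]))
  }
})

test_that("rendering is a pure function of spec and seed", {
  spec <- field_spec(width = 128, height = 128, n_nucleated = 4,
                     cell_scale = 0.5, seed = 77)
  f1 <- render_field(spec)
  f2 <- render_field(spec)
  expect_identical(f1$image, f2$image)
  expect_identical(f1$cells, f2$cells)
  f3 <- render_field(field_spec(width = 128, height = 128, n_nucleated = 4,
                                cell_scale = 0.5, seed = 78))
  expect_false(identical(f1$image, f3$image))
})

test_that("cell masks respect the minimum gap and are pairwise disjoint", {
  spec <- field_spec(width = 700, height = 700, n_nucleated = 20,
                     min_cell_gap = 4, seed = 5)
  fld <- render_field(spec)
  expect_length(fld$cells, 20)
  dims <- c(700, 700)
  # disjointness: no pixel belongs to two cell masks
  acc <- matrix(0L, dims[1], dims[2])
  for (cell in fld$cells) acc <- acc + full_mask(cell, dims, "cell")
  expect_lte(max(acc), 1L)
  # brute-force min distance between boundary pixels of mask pairs whose
  # inflated boxes overlap
  bounds <- lapply(fld$cells, function(cell) {
    m <- full_mask(cell, dims, "cell")
    inner <- m & !(rbind(FALSE, m[-dims[1], ]) & rbind(m[-1, ], FALSE) &
                     cbind(FALSE, m[, -dims[2]]) & cbind(m[, -1], FALSE))
    which(m & inner, arr.ind = TRUE)
  })
  for (i in 1:19) {
    for (j in (i + 1):20) {
      bi <- fld$cells[[i]]$bbox; bj <- fld$cells[[j]]$bbox
      if (bi["row0"] > bj["row1"] + 4 || bj["row0"] > bi["row1"] + 4 ||
          bi["col0"] > bj["col1"] + 4 || bj["col0"] > bi["col1"] + 4) next
      pi <- bounds[[i]]; pj <- bounds[[j]]
      d2 <- outer(pi[, 1], pj[, 1], `-`)^2 + outer(pi[, 2], pj[, 2], `-`)^2
      expect_gte(sqrt(min(d2)), 4)
    }
  }
  # nucleus inside cell, centroid inside bbox
  for (cell in fld$cells) {
    expect_true(all(cell$cell_mask[cell$nucleus_mask]))
    expect_gte(cell$centroid["row"], cell$bbox["row0"])
    expect_lte(cell$centroid["row"], cell$bbox["row1"])
  }
})

test_that("over-dense specs fail with an informative error", {
  spec <- field_spec(width = 100, height = 100, n_nucleated = 30, seed = 1)
  expect_error(render_field(spec, max_tries = 50), "over-dense")
})

test_that("class draws follow the requested frequencies", {
  freq <- c(4, 1, 1, 1, 3, 1, 1, 2, 4, 3, 1, 1)
  draws <- marrowdiff:::with_local_seed(42,
    marrowdiff:::sample_cell_classes(2000, freq))
  obs <- table(factor(draws, levels = cell_classes()))
  p <- stats::chisq.test(obs, p = freq / sum(freq))$p.value
  expect_gt(p, 0.01)
})

test_that("z-stacks blur linearly away from the focal plane", {
  base <- field_spec(width = 96, height = 96, n_nucleated = 2,
                     cell_scale = 0.5, seed = 9)
  # zero blur: all slices identical to the base field
  zs0 <- zstack_spec(base, z_positions = -2:2, focus_z = 0,
                     blur_coefficient = 0)
  st0 <- render_zstack(zs0)
  for (sl in st0$slices) expect_identical(sl, st0$field$image)
  # symmetric positions give symmetric blur radii
  zs <- zstack_spec(base, z_positions = seq(-5, 5), focus_z = 0)
  st <- render_zstack(zs)
  expect_equal(st$sigmas, rev(st$sigmas))
  expect_identical(st$focus_index, 6L)
  # 11-slice stack: strictly larger blur at the ends than at the focus
  expect_gt(st$sigmas[1], st$sigmas[6])
  expect_gt(st$sigmas[11], st$sigmas[6])
  expect_error(zstack_spec(base, z_positions = c(-1, 1), focus_z = 0))
})

test_that("paired differentials honour the noiseless and shifted contracts", {
  sp <- paired_differential_spec(n_smears = 12, method_a_noise_sd = 0,
                                 method_b_noise_sd = 0, seed = 4)
  d <- simulate_paired_differentials(sp)
  expect_equal(d$method_a, d$method_b)
  sums <- tapply(d$method_a, d$smear_id, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  # reproducibility
  expect_identical(d, simulate_paired_differentials(sp))

  sp5 <- paired_differential_spec(n_smears = 8, method_a_noise_sd = 0,
                                  method_b_noise_sd = 0,
                                  method_b_bias = c(5, 0, 0, 0, 0), seed = 4)
  d5 <- simulate_paired_differentials(sp5)
  raw <- attr(d5, "raw")
  expect_equal(unname(raw$method_b[, "granulocytes"] -
                        raw$method_a[, "granulocytes"]),
               rep(5, 8))
})
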