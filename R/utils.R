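#' @keywords internal
"_PACKAGE"

# Coordinate convention (used everywhere): images are numeric arrays
# [row, col, channel] with values in [0, 255]; masks are matrices [row, col];
# indices are 1-based; boxes are closed intervals (row0:row1, col0:col1),
# origin at the top-left.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate code under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds it with `seed`, evaluates `code`, and
#' restores the previous state on exit, so seeded internals never disturb the
#' session RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Convert an RGB raster to luminance
#'
#' Rec. 601 luma: 0.299 R + 0.587 G + 0.114 B.
#'
#' @param img numeric array `[rows, cols, 3]`, values in `[0, 255]`.
#' @return numeric matrix of the same spatial dimensions.
#' @export
to_grayscale <- function(img) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L) {
    stop("to_grayscale() expects an array [rows, cols, 3]")
  }
  y <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  matrix(y, nrow = dim(img)[1], ncol = dim(img)[2])
}

# YCbCr (Rec. 601, full range): chroma channels used by the segmentation rules
# and the colour features.  Returns Y, Cb, Cr matrices on the 0-255 scale with
# the neutral chroma point at 128.
rgb_to_ycbcr <- function(img) {
  y <- to_grayscale(img)
  cb <- 128 + 0.564 * (img[, , 3] - y)
  cr <- 128 + 0.713 * (img[, , 1] - y)
  list(Y = y, Cb = cb, Cr = cr)
}

# EBImage stores images as [x = col, y = row]; these helpers keep the
# package-wide [row, col] convention at the boundary.
as_ebi <- function(m) EBImage::Image(t(m))

from_ebi <- function(im) t(EBImage::imageData(im))

# Gaussian blur of a [row, col] matrix; sigma = 0 is the identity.
blur_gray <- function(m, sigma) {
  if (sigma <= 0) return(m)
  from_ebi(EBImage::gblur(as_ebi(m), sigma = sigma))
}

blur_rgb <- function(img, sigma) {
  if (sigma <= 0) return(img)
  out <- img
  for (ch in 1:3) out[, , ch] <- blur_gray(img[, , ch], sigma)
  out
}

# Population variance (divide by N, not N-1).
pop_var <- function(x) {
  mean((x - mean(x))^2)
}

# Binary morphology on [row, col] logical matrices with disc brushes.
# A gentle opening (speckle removal) must not sever the thin chromatin
# bridges of lobed nuclei, so it uses a smaller brush than the closing.
morph_open_close <- function(mask, open_radius = 1L, close_radius = 2L) {
  open_brush <- EBImage::makeBrush(2L * open_radius + 1L, shape = "disc")
  close_brush <- EBImage::makeBrush(2L * close_radius + 1L, shape = "disc")
  im <- as_ebi(mask * 1)
  im <- EBImage::closing(EBImage::opening(im, open_brush), close_brush)
  from_ebi(im) > 0.5
}

dilate_mask <- function(mask, radius = 2L) {
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  from_ebi(EBImage::dilate(as_ebi(mask * 1), brush)) > 0.5
}

# Connected components; returns an integer [row, col] matrix (0 = background).
label_components <- function(mask) {
  lab <- EBImage::bwlabel(as_ebi(mask * 1))
  matrix(as.integer(from_ebi(lab)), nrow = nrow(mask))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
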