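#' Find the nucleated-cell (WBC) region of a field
#'
#' Focus scoring is restricted to nucleated-cell regions so debris, red
#' cells, and empty background cannot attract the focus search.  Candidate
#' pixels are those whose luminance falls below an adaptive threshold (a
#' fraction of the field's median luminance — nuclei are far darker than
#' background and red cells), then the mask is dilated to take in the cell
#' borders.  If nothing qualifies the full-image mask is returned and
#' flagged.
#'
#' @param img RGB array `[rows, cols, 3]`.
#' @param threshold_frac luminance threshold as a fraction of the median.
#' @param dilate_radius dilation radius in pixels.
#' @return logical matrix with attribute `flagged` (`TRUE` when the fallback
#'   full-image mask was used).
#' @export
find_wbc_region <- function(img, threshold_frac = 0.7, dilate_radius = 4L) {
  lum <- to_grayscale(img)
  thr <- threshold_frac * stats::median(lum)
  mask <- lum < thr
  if (!any(mask)) {
    full <- matrix(TRUE, nrow(lum), ncol(lum))
    attr(full, "flagged") <- TRUE
    return(full)
  }
  mask <- dilate_mask(mask, dilate_radius)
  attr(mask, "flagged") <- FALSE
  mask
}

#' Coarse focus score: grayscale variance in the ROI
#'
#' The mean-square deviation of luminance inside the region of interest
#' (population variance).  Defocus flattens intensity contrast, so the score
#' peaks near the focal plane.
#'
#' @param img RGB array or grayscale matrix.
#' @param roi logical matrix; must contain at least one `TRUE` pixel.
#' @return nonnegative scalar (intensity-squared units).
#' @export
coarse_score <- function(img, roi) {
  gray <- if (is.matrix(img)) img else to_grayscale(img)
  stopifnot(is.matrix(roi), any(roi))
  pop_var(gray[roi])
}

#' Fine focus score: Canny edge-pixel fraction in the ROI
#'
#' The fraction of ROI pixels marked as edges by [canny_edges()].  Edge
#' responses sharpen as the image comes into focus, making this a finer
#' discriminator than raw variance near the focal plane.
#'
#' @param img RGB array or grayscale matrix.
#' @param roi logical matrix; must contain at least one `TRUE` pixel.
#' @param canny_params list of arguments passed to [canny_edges()]
#'   (`sigma`, `low`, `high`, `low_quantile`, `high_quantile`).
#' @return scalar in [0, 1].
#' @export
fine_score <- function(img, roi, canny_params = list()) {
  gray <- if (is.matrix(img)) img else to_grayscale(img)
  stopifnot(is.matrix(roi), any(roi))
  edges <- do.call(canny_edges, c(list(gray = gray), canny_params))
  mean(edges[roi])
}

#' Two-stage autofocus over a z-stack
#'
#' Stage 1 (coarse): [coarse_score()] on every `stride`-th slice, ROI taken
#' once from the middle slice via [find_wbc_region()] and reused so the ROI
#' cannot drift with focus.  Stage 2 (fine): [fine_score()] on every slice
#' within `window` of the coarse winner; its argmax is the result.  Ties
#' always break toward the lower index.
#'
#' @param stack list of RGB arrays (ordered slices), length >= 3.
#' @param stride coarse-stage step (>= 1).
#' @param window fine-stage half-width in slices (>= 0).
#' @param canny_params passed to [fine_score()].
#' @param scorers optional list overriding the two scoring functions:
#'   `coarse(img, roi)` and `fine(img, roi, canny_params)`.
#' @return object of class `focus_result`: list with `best_index` (1-based),
#'   `coarse_indices`, `coarse_scores`, `fine_indices`, `fine_scores`, and
#'   `roi_flagged`.
#' @export
autofocus_stack <- function(stack, stride = 1L, window = 2L,
                            canny_params = list(), scorers = NULL) {
  n <- length(stack)
  if (n < 3) stop("autofocus_stack() needs at least 3 slices")
  stopifnot(stride >= 1, window >= 0)
  coarse_fun <- scorers$coarse %||% coarse_score
  fine_fun <- scorers$fine %||% function(im, roi) {
    fine_score(im, roi, canny_params)
  }

  roi <- find_wbc_region(stack[[ceiling(n / 2)]])
  coarse_idx <- seq(1L, n, by = stride)
  coarse_sc <- vapply(coarse_idx, function(i) coarse_fun(stack[[i]], roi),
                      numeric(1))
  winner <- coarse_idx[which.max(coarse_sc)]  # which.max: lowest index on ties

  fine_idx <- seq(max(1L, winner - window), min(n, winner + window))
  fine_sc <- vapply(fine_idx, function(i) fine_fun(stack[[i]], roi),
                    numeric(1))
  best <- fine_idx[which.max(fine_sc)]

  structure(list(best_index = best,
                 coarse_indices = coarse_idx, coarse_scores = coarse_sc,
                 fine_indices = fine_idx, fine_scores = fine_sc,
                 roi_flagged = isTRUE(attr(roi, "flagged"))),
            class = "focus_result")
}
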