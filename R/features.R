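#' Names of the classifier feature set
#'
#' @return character vector of feature names, in canonical order.
#' @export
feature_names <- function() {
  c("cell_area", "nucleus_area", "nc_ratio", "circularity",
    "nucleus_eccentricity", "nucleus_lobedness",
    "nucleus_lum_mean", "nucleus_cb_mean", "nucleus_cr_mean",
    "nucleus_cb_sd", "nucleus_cr_sd",
    "cyto_lum_mean", "cyto_cb_mean", "cyto_cr_mean",
    "cyto_cb_sd", "cyto_cr_sd",
    "chromatin_granularity", "gradient_entropy")
}

# area of the convex hull of a point set (shoelace on grDevices::chull)
hull_area <- function(pts) {
  if (nrow(pts) < 3) return(0)
  h <- grDevices::chull(pts[, 2], pts[, 1])
  hp <- pts[h, , drop = FALSE]
  x <- hp[, 2]; y <- hp[, 1]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

degenerate_features <- function() {
  out <- as.list(stats::setNames(rep(0, length(feature_names())),
                                 feature_names()))
  out$degenerate <- TRUE
  as.data.frame(out)
}

#' Extract interpretable morphology features from a segmented crop
#'
#' Geometric features (areas, N:C ratio, circularity, nuclear eccentricity
#' and lobedness), per-compartment colour statistics in the YCbCr chroma
#' channels, a chromatin-granularity texture score (mean 3x3 local variance
#' of nuclear luminance), and the Shannon entropy of the gradient-magnitude
#' distribution over the cell.
#'
#' @param crop RGB array.
#' @param mask a [segment_cell()] result (or any matrix with labels 0-3).
#' @param pixel_size optional pixel edge length in micrometres; when given,
#'   area features are reported in square micrometres.
#' @return one-row data.frame with the [feature_names()] columns plus a
#'   logical `degenerate` flag; degenerate masks (no nucleus or no cell
#'   pixels) yield a flagged all-zero record, never NaNs.
#' @export
extract_features <- function(crop, mask, pixel_size = NULL) {
  nucleus <- mask == 3L
  cellm <- mask == 2L | nucleus
  if (!any(nucleus) || !any(cellm)) return(degenerate_features())

  scale2 <- if (is.null(pixel_size)) 1 else pixel_size^2
  cell_area <- sum(cellm)
  nucleus_area <- sum(nucleus)
  nc_ratio <- min(1, nucleus_area / cell_area)

  per <- contour_perimeter(cellm)
  circularity <- if (is.na(per) || per <= 0) 0 else
    min(1, 4 * pi * cell_area / per^2)

  pts <- which(nucleus, arr.ind = TRUE)
  ctr <- colMeans(pts)
  cc <- sweep(pts, 2, ctr)
  cv <- crossprod(cc) / nrow(pts)
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  eccentricity <- if (ev[1] <= 0) 0 else sqrt(max(0, 1 - ev[2] / ev[1]))

  lobedness <- {
    ha <- hull_area(pts)
    if (ha <= 0) 0 else max(0, 1 - nucleus_area / ha)
  }

  yc <- rgb_to_ycbcr(crop)
  cyto <- mask == 2L
  stat_or0 <- function(v, f) if (length(v) == 0) 0 else f(v)
  nuc_stats <- c(
    nucleus_lum_mean = mean(yc$Y[nucleus]),
    nucleus_cb_mean = mean(yc$Cb[nucleus]),
    nucleus_cr_mean = mean(yc$Cr[nucleus]),
    nucleus_cb_sd = if (sum(nucleus) > 1) stats::sd(yc$Cb[nucleus]) else 0,
    nucleus_cr_sd = if (sum(nucleus) > 1) stats::sd(yc$Cr[nucleus]) else 0)
  cyto_stats <- c(
    cyto_lum_mean = stat_or0(yc$Y[cyto], mean),
    cyto_cb_mean = stat_or0(yc$Cb[cyto], mean),
    cyto_cr_mean = stat_or0(yc$Cr[cyto], mean),
    cyto_cb_sd = if (sum(cyto) > 1) stats::sd(yc$Cb[cyto]) else 0,
    cyto_cr_sd = if (sum(cyto) > 1) stats::sd(yc$Cr[cyto]) else 0)

  # chromatin granularity: mean 3x3 local variance of nuclear luminance
  box <- matrix(1 / 9, 3, 3)
  ym <- from_ebi(EBImage::filter2(as_ebi(yc$Y), box))
  y2m <- from_ebi(EBImage::filter2(as_ebi(yc$Y^2), box))
  localvar <- pmax(0, y2m - ym^2)
  chromatin <- mean(localvar[nucleus])

  g <- sobel_gradients(yc$Y)
  mag <- sqrt(g$gx^2 + g$gy^2)[cellm]
  gradient_entropy <- {
    h <- tabulate(pmin(16L, 1L + floor(mag / (max(mag) + 1e-9) * 16)), 16L)
    p <- h / sum(h)
    p <- p[p > 0]
    -sum(p * log2(p))
  }

  out <- data.frame(
    cell_area = cell_area * scale2, nucleus_area = nucleus_area * scale2,
    nc_ratio = nc_ratio, circularity = circularity,
    nucleus_eccentricity = eccentricity, nucleus_lobedness = lobedness,
    t(nuc_stats), t(cyto_stats),
    chromatin_granularity = chromatin, gradient_entropy = gradient_entropy)
  out$degenerate <- FALSE
  rownames(out) <- NULL
  out[, c(feature_names(), "degenerate")]
}
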