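#' Localization / segmentation parameters
#'
#' @param n_intensity_clusters k for the grayscale k-means used in
#'   localization (darkest cluster = nuclear foreground).
#' @param n_color_clusters k for the colour k-means used in per-crop
#'   segmentation.
#' @param min_area,max_area connected-component area gate in pixels;
#'   components below `min_area` (red cells, debris) or above `max_area`
#'   (merged blobs) are dropped.
#' @param min_circularity minimum 4*pi*A/P^2 of a kept component; low enough
#'   to admit lobed neutrophil nuclei while rejecting stringy debris.
#' @param margin box expansion as a fraction of the box side; `NULL` uses
#'   the default 0.35 so crops of the (nuclear) detection box take in the
#'   surrounding cytoplasm.
#' @param seed seed for the k-means initializations.
#' @return object of class `locseg_params`.
#' @export
locseg_params <- function(n_intensity_clusters = 2L, n_color_clusters = 4L,
                          min_area = 350, max_area = 15000,
                          min_circularity = 0.1, margin = NULL, seed = 1L) {
  stopifnot(n_intensity_clusters >= 2, n_color_clusters >= 2,
            min_area > 0, min_area < max_area, min_circularity >= 0)
  structure(list(n_intensity_clusters = as.integer(n_intensity_clusters),
                 n_color_clusters = as.integer(n_color_clusters),
                 min_area = min_area, max_area = max_area,
                 min_circularity = min_circularity,
                 margin = margin %||% 0.35, seed = as.integer(seed)),
            class = "locseg_params")
}

# Seeded k-means over an n x p feature matrix; fits on a subsample for
# speed, then assigns every point to its nearest fitted centre.
seeded_kmeans <- function(x, k, seed, max_fit = 10000L) {
  x <- as.matrix(x)
  with_local_seed(seed, {
    idx <- if (nrow(x) > max_fit) sample.int(nrow(x), max_fit) else
      seq_len(nrow(x))
    xs <- x[idx, , drop = FALSE]
    # degrade k gracefully when the crop has fewer distinct colours
    fit <- NULL
    k_eff <- k
    while (is.null(fit) && k_eff >= 2L) {
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(xs, centers = k_eff, nstart = 3,
                                       iter.max = 30)),
        error = function(e) NULL)
      if (is.null(fit)) k_eff <- k_eff - 1L
    }
    if (is.null(fit)) {
      return(list(cluster = rep(1L, nrow(x)),
                  centers = matrix(colMeans(x), 1,
                                   dimnames = list(NULL, colnames(x)))))
    }
    d <- outer(rowSums(x^2), rep(1, k_eff)) - 2 * x %*% t(fit$centers) +
      outer(rep(1, nrow(x)), rowSums(fit$centers^2))
    list(cluster = max.col(-d), centers = fit$centers)
  })
}

# perimeter of the largest component of a mask, from its traced contour
contour_perimeter <- function(mask) {
  oc <- EBImage::ocontour(as_ebi(mask * 1))
  if (length(oc) == 0) return(NA_real_)
  pts <- oc[[which.max(vapply(oc, nrow, integer(1)))]]
  pts <- rbind(pts, pts[1, ])
  sum(sqrt(rowSums(diff(pts)^2)))
}

#' Localize nucleated cells on a field image
#'
#' Grayscale conversion, k-means on intensity, the darkest cluster taken as
#' nuclear foreground, morphological opening/closing, connected components,
#' then an area and circularity gate.  Red cells and background are paler
#' than nuclei, so the darkest intensity cluster isolates nuclei; red-cell
#' sized components fall below `min_area`.  Surviving component boxes are
#' expanded by `margin` and clipped to the field.
#'
#' @param img RGB array `[rows, cols, 3]`.
#' @param params a [locseg_params()].
#' @return data.frame of boxes sorted by (row0, col0): columns `row0`,
#'   `col0`, `row1`, `col1` (1-based, closed), `centroid_row`,
#'   `centroid_col`, `area`, `circularity`.  Attribute `n_discarded_large`
#'   counts merged blobs dropped by the `max_area` gate.
#' @export
localize_nucleated_cells <- function(img, params = locseg_params()) {
  gray <- to_grayscale(img)
  km <- seeded_kmeans(as.vector(gray), params$n_intensity_clusters,
                      params$seed, max_fit = length(gray))
  dark <- which.min(km$centers[, 1])
  fg <- matrix(km$cluster == dark, nrow(gray))
  # guard: if the "dark" cluster covers most of the field there is no dark
  # foreground (uniform-ish image split by noise)
  empty <- data.frame(row0 = integer(0), col0 = integer(0),
                      row1 = integer(0), col1 = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      area = numeric(0), circularity = numeric(0))
  attr(empty, "n_discarded_large") <- 0L
  if (mean(fg) > 0.5) return(empty)
  # the foreground cluster must actually be dark (nuclear chromatin), not
  # merely the darker of two pale clusters (red cells on background)
  if (km$centers[dark, 1] >= 0.7 * stats::median(gray)) return(empty)
  fg <- morph_open_close(fg)
  lab <- label_components(fg)
  if (max(lab) == 0) return(empty)

  boxes <- list(); discarded <- 0L
  for (id in seq_len(max(lab))) {
    sel <- lab == id
    a <- sum(sel)
    if (a > params$max_area) { discarded <- discarded + 1L; next }
    if (a < params$min_area) next
    per <- contour_perimeter(sel)
    circ <- if (is.na(per) || per <= 0) 0 else 4 * pi * a / per^2
    if (circ < params$min_circularity) next
    rc <- which(sel, arr.ind = TRUE)
    r0 <- min(rc[, 1]); r1 <- max(rc[, 1])
    c0 <- min(rc[, 2]); c1 <- max(rc[, 2])
    side <- max(r1 - r0 + 1, c1 - c0 + 1)
    m <- round(params$margin * side)
    boxes[[length(boxes) + 1L]] <- data.frame(
      row0 = max(1L, r0 - m), col0 = max(1L, c0 - m),
      row1 = min(nrow(gray), r1 + m), col1 = min(ncol(gray), c1 + m),
      centroid_row = mean(rc[, 1]), centroid_col = mean(rc[, 2]),
      area = a, circularity = circ)
  }
  if (length(boxes) == 0) return(empty)
  out <- do.call(rbind, boxes)
  out <- out[order(out$row0, out$col0), ]
  rownames(out) <- NULL
  attr(out, "n_discarded_large") <- discarded
  out
}

#' Crop a box from a field image
#'
#' @param img RGB array.
#' @param box one row of the [localize_nucleated_cells()] result (or any
#'   list with `row0`, `col0`, `row1`, `col1`).
#' @return RGB array of the crop.
#' @export
crop_box <- function(img, box) {
  img[box$row0:box$row1, box$col0:box$col1, , drop = FALSE]
}

# Reassign tiny connected components (area < min_frac of the crop) of the
# non-background labels to the dominant label around them; the largest
# nucleus component is always preserved.
prune_small_components <- function(labels, min_frac = 0.01) {
  total <- length(labels)
  out <- labels
  for (lb in 1:3) {
    sel <- out == lb
    if (!any(sel)) next
    comp <- label_components(sel)
    sizes <- tabulate(comp[comp > 0])
    keep_largest <- if (lb == 3L) which.max(sizes) else 0L
    tiny <- which(sizes < min_frac * total)
    tiny <- setdiff(tiny, keep_largest)
    if (length(tiny) == 0) next
    px <- which(matrix(comp %in% tiny, nrow(comp)), arr.ind = TRUE)
    ids <- comp[px]
    for (id in unique(ids)) {
      p <- px[ids == id, , drop = FALSE]
      r0 <- max(1L, min(p[, 1]) - 1L); r1 <- min(nrow(out), max(p[, 1]) + 1L)
      c0 <- max(1L, min(p[, 2]) - 1L); c1 <- min(ncol(out), max(p[, 2]) + 1L)
      sub_out <- out[r0:r1, c0:c1, drop = FALSE]
      sub_m <- comp[r0:r1, c0:c1, drop = FALSE] == id
      ring <- dilate_mask(sub_m, 1L) & !sub_m
      neigh <- sub_out[ring]
      neigh <- neigh[!(neigh == lb)]
      fill <- if (length(neigh) == 0) 0L else
        as.integer(names(which.max(table(neigh))))
      out[p] <- fill
    }
  }
  out
}

#' Segment a cell crop into background / RBC / cytoplasm / nucleus
#'
#' Colour k-means in (Y, Cb, Cr) followed by a fixed labelling cascade on
#' the cluster means: the brightest cluster is background; among the rest
#' the cluster scoring highest on purple-blue chroma with low luminance is
#' the nucleus; of the remainder, the cluster nearest the nucleus in chroma
#' is cytoplasm; anything left is red cells.  Tiny components (< 1% of the
#' crop) are absorbed by their surroundings.  Crops with fewer distinct
#' colours than clusters degrade gracefully (uniform crop = all background).
#'
#' @param crop RGB array.
#' @param params a [locseg_params()].
#' @return object of class `segmentation_mask`: integer matrix with values
#'   0 background, 1 RBC, 2 cytoplasm, 3 nucleus.
#' @export
segment_cell <- function(crop, params = locseg_params()) {
  yc <- rgb_to_ycbcr(crop)
  x <- cbind(Y = as.vector(yc$Y), Cb = as.vector(yc$Cb),
             Cr = as.vector(yc$Cr))
  km <- seeded_kmeans(x, params$n_color_clusters, params$seed)
  # merge near-identical clusters: k-means on a crop with fewer true colour
  # modes than k splits one mode (e.g. mottled chromatin) in two, which
  # would derail the labelling cascade below
  repeat {
    k <- nrow(km$centers)
    if (k <= 2) break
    dmat <- as.matrix(stats::dist(km$centers))
    diag(dmat) <- Inf
    if (min(dmat) >= 28) break
    pair <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
    i <- min(pair); j <- max(pair)
    ni <- sum(km$cluster == i); nj <- sum(km$cluster == j)
    km$centers[i, ] <- (ni * km$centers[i, ] + nj * km$centers[j, ]) /
      (ni + nj)
    km$cluster[km$cluster == j] <- i
    km$cluster[km$cluster > j] <- km$cluster[km$cluster > j] - 1L
    km$centers <- km$centers[-j, , drop = FALSE]
  }
  k <- nrow(km$centers)
  cl_lab <- rep(0L, k)  # default background
  if (k >= 2) {
    ord_bright <- which.max(km$centers[, "Y"])
    rest <- setdiff(seq_len(k), ord_bright)
    pb_score <- (km$centers[, "Cb"] - 128) / 128 +
      0.5 * (km$centers[, "Cr"] - 128) / 128 +
      (1 - km$centers[, "Y"] / 255)
    nuc <- rest[which.max(pb_score[rest])]
    cl_lab[nuc] <- 3L
    rest <- setdiff(rest, nuc)
    if (length(rest) > 0) {
      d_chroma <- sqrt((km$centers[rest, "Cb"] - km$centers[nuc, "Cb"])^2 +
                       (km$centers[rest, "Cr"] - km$centers[nuc, "Cr"])^2)
      cyt <- rest[which.min(d_chroma)]
      cl_lab[cyt] <- 2L
      cl_lab[setdiff(rest, cyt)] <- 1L
    }
  }
  labels <- matrix(cl_lab[km$cluster], nrow = dim(crop)[1])
  labels <- prune_small_components(labels)
  structure(labels, class = c("segmentation_mask", "matrix", "array"))
}
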