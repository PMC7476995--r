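# Canny edge detection on a grayscale matrix.
#
# No installed R imaging package exposes a Canny operator, so the classic
# pipeline is implemented here: Gaussian smoothing, Sobel gradients,
# non-maximum suppression along the quantized gradient direction, and
# two-threshold hysteresis (weak edges kept only when their connected
# component contains a strong edge).

sobel_gradients <- function(m) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- from_ebi(EBImage::filter2(as_ebi(m), t(kx)))   # d/dcol
  gy <- from_ebi(EBImage::filter2(as_ebi(m), t(t(kx))))# d/drow
  list(gx = gx, gy = gy)
}

shift_mat <- function(m, dr, dc) {
  # shift with replicate padding; out-of-range cells take the border value
  n <- nrow(m); p <- ncol(m)
  ri <- clamp(seq_len(n) + dr, 1, n)
  ci <- clamp(seq_len(p) + dc, 1, p)
  m[ri, ci, drop = FALSE]
}

#' Canny edge detector
#'
#' @param gray numeric matrix `[rows, cols]` (any intensity scale).
#' @param sigma Gaussian smoothing sigma in pixels.
#' @param low,high absolute hysteresis thresholds on the gradient magnitude;
#'   when `NULL` they are taken as quantiles (`low_quantile`,
#'   `high_quantile`) of the positive gradient magnitudes, which adapts the
#'   detector to the image contrast.
#' @param low_quantile,high_quantile quantile levels used when thresholds
#'   are not given.
#' @return logical matrix of edge pixels.
#' @export
canny_edges <- function(gray, sigma = 1.0, low = NULL, high = NULL,
                        low_quantile = 0.7, high_quantile = 0.9) {
  stopifnot(is.matrix(gray))
  sm <- blur_gray(gray, sigma)
  g <- sobel_gradients(sm)
  mag <- sqrt(g$gx^2 + g$gy^2)
  if (all(mag == 0)) return(matrix(FALSE, nrow(gray), ncol(gray)))

  # non-maximum suppression: compare against the two neighbours along the
  # gradient direction, quantized to 0/45/90/135 degrees
  ang <- atan2(g$gy, g$gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- (round(ang / (pi / 4)) %% 4)  # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  nb <- list(
    `0` = list(c(0, 1), c(0, -1)),
    `1` = list(c(1, 1), c(-1, -1)),
    `2` = list(c(1, 0), c(-1, 0)),
    `3` = list(c(1, -1), c(-1, 1))
  )
  keep <- matrix(FALSE, nrow(mag), ncol(mag))
  for (s in 0:3) {
    sel <- sector == s
    if (!any(sel)) next
    n1 <- shift_mat(mag, nb[[s + 1]][[1]][1], nb[[s + 1]][[1]][2])
    n2 <- shift_mat(mag, nb[[s + 1]][[2]][1], nb[[s + 1]][[2]][2])
    keep[sel] <- mag[sel] >= n1[sel] & mag[sel] >= n2[sel]
  }
  nms <- mag
  nms[!keep] <- 0

  pos <- nms[nms > 0]
  if (length(pos) == 0) return(matrix(FALSE, nrow(gray), ncol(gray)))
  if (is.null(high)) high <- stats::quantile(pos, high_quantile, names = FALSE)
  if (is.null(low)) low <- stats::quantile(pos, low_quantile, names = FALSE)
  strong <- nms >= high & nms > 0
  weak <- nms >= low & nms > 0
  if (!any(strong)) return(matrix(FALSE, nrow(gray), ncol(gray)))

  lab <- label_components(weak)
  keep_ids <- unique(lab[strong])
  keep_ids <- keep_ids[keep_ids > 0]
  matrix(lab %in% keep_ids, nrow(lab)) & weak
}
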