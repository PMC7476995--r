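#' Specify a synthetic smear field
#'
#' @param width,height field dimensions in pixels.
#' @param n_nucleated number of nucleated cells to place.
#' @param rbc_density target fraction of field area covered by red-cell
#'   discs, in [0, 1].
#' @param class_frequencies 12 nonnegative sampling weights, in
#'   [cell_classes()] order (or named); need not sum to 1.
#' @param background_color RGB triple of the pale inter-cell background.
#' @param noise_sd standard deviation of additive Gaussian pixel noise
#'   (intensity units on the 0-255 scale).
#' @param min_cell_gap minimum pixel gap enforced between nucleated-cell
#'   masks.
#' @param seed integer; together with the spec it fully determines the
#'   rendered field.
#' @param cell_scale multiplier applied to every phenotype radius range
#'   (1 = desk scale; ~20 restores full-magnification crop sizes).
#' @param rbc_radius_range length-2 radius range for red-cell discs.
#' @param phenotypes named list of [cell_phenotype()] per class.
#' @return object of class `field_spec`.
#' @export
field_spec <- function(width = 512, height = 512, n_nucleated = 15,
                       rbc_density = 0.15,
                       class_frequencies = rep(1, 12),
                       background_color = c(242, 238, 244),
                       noise_sd = 4, min_cell_gap = 4, seed = 1,
                       cell_scale = 1, rbc_radius_range = c(5, 9),
                       phenotypes = default_phenotypes()) {
  class_frequencies <- unlist(class_frequencies)
  if (!is.null(names(class_frequencies))) {
    stopifnot(setequal(names(class_frequencies), cell_classes()))
    class_frequencies <- class_frequencies[cell_classes()]
  }
  stopifnot(
    width > 0, height > 0, n_nucleated >= 0,
    rbc_density >= 0, rbc_density <= 1,
    length(class_frequencies) == 12, all(class_frequencies >= 0),
    n_nucleated == 0 || sum(class_frequencies) > 0,
    noise_sd >= 0, min_cell_gap >= 0, cell_scale > 0,
    length(rbc_radius_range) == 2, all(rbc_radius_range > 0)
  )
  structure(list(
    width = as.integer(width), height = as.integer(height),
    n_nucleated = as.integer(n_nucleated), rbc_density = rbc_density,
    class_frequencies = stats::setNames(as.numeric(class_frequencies),
                                        cell_classes()),
    background_color = as.numeric(background_color), noise_sd = noise_sd,
    min_cell_gap = min_cell_gap, seed = as.integer(seed),
    cell_scale = cell_scale, rbc_radius_range = as.numeric(rbc_radius_range),
    phenotypes = phenotypes
  ), class = "field_spec")
}

# Class draws for a field; must run inside the field's seeded RNG context.
sample_cell_classes <- function(n, class_frequencies) {
  sample(cell_classes(), n, replace = TRUE, prob = class_frequencies)
}

# Rasterize one cell into local bounding-box masks.  Returns cell/nucleus
# logical matrices over rows r0:r1, cols c0:c1 plus the box.
draw_cell_geometry <- function(cy, cx, r, phe, nrow_img, ncol_img,
                               angle, lobe_jitter) {
  r0 <- max(1L, floor(cy - r)); r1 <- min(nrow_img, ceiling(cy + r))
  c0 <- max(1L, floor(cx - r)); c1 <- min(ncol_img, ceiling(cx + r))
  rows <- r0:r1; cols <- c0:c1
  dy <- matrix(rows - cy, nrow = length(rows), ncol = length(cols))
  dx <- matrix(cols - cx, nrow = length(rows), ncol = length(cols),
               byrow = TRUE)
  cell <- (dx^2 + dy^2) <= r^2

  nc <- lobe_jitter$nc_ratio
  L <- phe$nucleus_lobes
  ecc <- phe$nucleus_eccentricity
  off <- phe$nucleus_offset * r
  ncy <- cy + off * sin(angle); ncx <- cx + off * cos(angle)
  ndy <- dy - (ncy - cy); ndx <- dx - (ncx - cx)
  if (L == 1L) {
    # ellipse with matched area: a*b = nc * r^2, b/a = sqrt(1 - e^2)
    ratio <- sqrt(1 - ecc^2)
    a <- r * sqrt(nc / ratio)
    b <- a * ratio
    u <- ndx * cos(angle) + ndy * sin(angle)
    v <- -ndx * sin(angle) + ndy * cos(angle)
    nucleus <- (u / a)^2 + (v / b)^2 <= 1
  } else {
    rl <- r * sqrt(nc / L)
    d <- rl * 1.35  # lobe spacing: lobes overlap slightly, staying connected
    th <- angle + 2 * pi * (seq_len(L) - 1) / L + lobe_jitter$angles
    nucleus <- matrix(FALSE, nrow(cell), ncol(cell))
    for (j in seq_len(L)) {
      ly <- d * sin(th[j]); lx <- d * cos(th[j])
      nucleus <- nucleus | ((ndx - lx)^2 + (ndy - ly)^2 <= rl^2)
    }
    # thin bridges between consecutive lobes keep the nucleus connected
    for (j in seq_len(L)) {
      jn <- if (j == L) 1L else j + 1L
      p1 <- c(d * sin(th[j]), d * cos(th[j]))
      p2 <- c(d * sin(th[jn]), d * cos(th[jn]))
      tseq <- seq(0, 1, length.out = 12)
      for (tt in tseq) {
        py <- p1[1] + tt * (p2[1] - p1[1]); px <- p1[2] + tt * (p2[2] - p1[2])
        nucleus <- nucleus | ((ndx - px)^2 + (ndy - py)^2 <= 1.6^2)
      }
    }
  }
  nucleus <- nucleus & cell
  list(cell = cell, nucleus = nucleus,
       bbox = c(r0, c0, r1, c1))
}

#' Render a synthetic smear field with ground truth
#'
#' Places `n_nucleated` cells (classes sampled from `class_frequencies`,
#' morphology from the per-class phenotypes) by rejection sampling so that
#' cell masks keep at least `min_cell_gap` pixels apart, scatters anucleate
#' red-cell discs to roughly `rbc_density` coverage, then adds Gaussian pixel
#' noise.  The result is a pure function of the spec (including its seed).
#'
#' @param spec a [field_spec()].
#' @param max_tries rejection-sampling budget per cell before the field is
#'   declared over-dense.
#' @return object of class `synthetic_field`: list with `image` (array
#'   `[rows, cols, 3]`, 0-255), `cells` (list of ground-truth records with
#'   `cell_class`, `centroid`, `bbox`, and bbox-local `cell_mask` /
#'   `nucleus_mask`), and `spec`.
#' @export
render_field <- function(spec, max_tries = 1000L) {
  stopifnot(inherits(spec, "field_spec"))
  with_local_seed(spec$seed, {
    H <- spec$height; W <- spec$width
    img <- array(0, dim = c(H, W, 3))
    for (ch in 1:3) img[, , ch] <- spec$background_color[ch]

    cells <- list()
    centers <- matrix(numeric(0), ncol = 3)  # cy, cx, r
    if (spec$n_nucleated > 0) {
      klass <- sample_cell_classes(spec$n_nucleated, spec$class_frequencies)
      for (i in seq_len(spec$n_nucleated)) {
        phe <- spec$phenotypes[[klass[i]]]
        rr <- phe$cell_radius_range * spec$cell_scale
        r <- stats::runif(1, rr[1], rr[2])
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          cy <- stats::runif(1, r + 1, H - r)
          cx <- stats::runif(1, r + 1, W - r)
          ok <- TRUE
          if (nrow(centers) > 0) {
            dd <- sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2)
            ok <- all(dd >= centers[, 3] + r + spec$min_cell_gap)
          }
          if (ok) { placed <- TRUE; break }
        }
        if (!placed) {
          stop("render_field(): could not place cell ", i, " of ",
               spec$n_nucleated, " after ", max_tries,
               " tries; the spec is over-dense for the field area")
        }
        centers <- rbind(centers, c(cy, cx, r))
        nc <- stats::runif(1, phe$nc_ratio_range[1], phe$nc_ratio_range[2])
        angle <- stats::runif(1, 0, 2 * pi)
        jit <- list(nc_ratio = nc,
                    angles = stats::runif(phe$nucleus_lobes, -0.25, 0.25))
        geom <- draw_cell_geometry(cy, cx, r, phe, H, W, angle, jit)
        b <- geom$bbox
        rows <- b[1]:b[3]; cols <- b[2]:b[4]
        # cytoplasm with mild radial shading, then granules, then nucleus
        cyto <- geom$cell & !geom$nucleus
        for (ch in 1:3) {
          plane <- img[rows, cols, ch]
          plane[cyto] <- phe$cytoplasm_color[ch]
          img[rows, cols, ch] <- plane
        }
        if (phe$granule_density > 0 && any(cyto)) {
          gr <- cyto & (matrix(stats::runif(length(cyto)), nrow(cyto))
                        < phe$granule_density)
          for (ch in 1:3) {
            plane <- img[rows, cols, ch]
            plane[gr] <- phe$granule_color[ch]
            img[rows, cols, ch] <- plane
          }
        }
        # chromatin mottling gives the nucleus a textured, clumped look
        nuc <- geom$nucleus
        mott <- matrix(stats::rnorm(length(nuc), 0, 10), nrow(nuc))
        for (ch in 1:3) {
          plane <- img[rows, cols, ch]
          plane[nuc] <- clamp(phe$nucleus_color[ch] + mott[nuc], 0, 255)
          img[rows, cols, ch] <- plane
        }
        cells[[i]] <- list(
          cell_class = klass[i],
          centroid = c(row = cy, col = cx),
          bbox = c(row0 = b[1], col0 = b[2], row1 = b[3], col1 = b[4]),
          cell_mask = geom$cell,
          nucleus_mask = geom$nucleus,
          radius = r
        )
      }
    }

    if (spec$rbc_density > 0) {
      rmean <- mean(spec$rbc_radius_range)
      n_rbc <- round(spec$rbc_density * H * W / (pi * rmean^2))
      rbc_color <- c(232, 172, 176)
      for (i in seq_len(n_rbc)) {
        r <- stats::runif(1, spec$rbc_radius_range[1],
                          spec$rbc_radius_range[2])
        cy <- stats::runif(1, 1, H); cx <- stats::runif(1, 1, W)
        if (nrow(centers) > 0) {
          dd <- sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2)
          if (any(dd < centers[, 3] + r + 1)) next  # keep nucleated masks clean
        }
        r0 <- max(1L, floor(cy - r)); r1 <- min(H, ceiling(cy + r))
        c0 <- max(1L, floor(cx - r)); c1 <- min(W, ceiling(cx + r))
        rows <- r0:r1; cols <- c0:c1
        dy <- matrix(rows - cy, length(rows), length(cols))
        dx <- matrix(cols - cx, length(rows), length(cols), byrow = TRUE)
        d2 <- dx^2 + dy^2
        disc <- d2 <= r^2
        # central pallor: blend towards background in the inner third
        w <- clamp((sqrt(d2) / r - 0.35) / 0.65, 0, 1)
        for (ch in 1:3) {
          plane <- img[rows, cols, ch]
          shade <- rbc_color[ch] * w + spec$background_color[ch] * (1 - w)
          plane[disc] <- shade[disc]
          img[rows, cols, ch] <- plane
        }
      }
    }

    if (spec$noise_sd > 0) {
      img <- clamp(img + array(stats::rnorm(length(img), 0, spec$noise_sd),
                               dim = dim(img)), 0, 255)
    }
    structure(list(image = img, cells = cells, spec = spec),
              class = "synthetic_field")
  })
}

#' Full-field ground-truth mask for one cell
#'
#' Expands a bbox-local ground-truth mask to field dimensions.
#'
#' @param cell one element of `synthetic_field$cells`.
#' @param dim `c(rows, cols)` of the field.
#' @param which `"cell"` or `"nucleus"`.
#' @return logical matrix `[rows, cols]`.
#' @export
full_mask <- function(cell, dim, which = c("cell", "nucleus")) {
  which <- match.arg(which)
  m <- matrix(FALSE, dim[1], dim[2])
  b <- cell$bbox
  m[b["row0"]:b["row1"], b["col0"]:b["col1"]] <-
    if (which == "cell") cell$cell_mask else cell$nucleus_mask
  m
}

#' Specify a defocus z-stack
#'
#' @param base a [field_spec()] for the in-focus field.
#' @param z_positions strictly increasing stage positions.
#' @param focus_z true focal position, within the z range.
#' @param blur_coefficient Gaussian blur sigma (pixels) per unit |z - focus|.
#' @return object of class `zstack_spec`.
#' @export
zstack_spec <- function(base, z_positions = seq(-5, 5), focus_z = 0,
                        blur_coefficient = 1.2) {
  stopifnot(inherits(base, "field_spec"),
            length(z_positions) >= 3,
            all(diff(z_positions) > 0),
            focus_z >= min(z_positions), focus_z <= max(z_positions),
            blur_coefficient >= 0)
  structure(list(base = base, z_positions = as.numeric(z_positions),
                 focus_z = focus_z, blur_coefficient = blur_coefficient),
            class = "zstack_spec")
}

#' Render a defocus z-stack from a field spec
#'
#' Slice i is the base field blurred with a Gaussian kernel of sigma
#' `blur_coefficient * |z_i - focus_z|` — a simple monotone surrogate for
#' optical defocus.  The slice nearest `focus_z` carries the least blur and
#' its index is returned as ground truth.
#'
#' @param spec a [zstack_spec()].
#' @return list with `slices` (list of RGB arrays), `z_positions`, `sigmas`,
#'   `focus_index` (1-based index of the slice nearest `focus_z`), and the
#'   rendered base `field`.
#' @export
render_zstack <- function(spec) {
  stopifnot(inherits(spec, "zstack_spec"))
  fld <- render_field(spec$base)
  sig <- spec$blur_coefficient * abs(spec$z_positions - spec$focus_z)
  slices <- lapply(sig, function(s) blur_rgb(fld$image, s))
  list(slices = slices, z_positions = spec$z_positions, sigmas = sig,
       focus_index = which.min(abs(spec$z_positions - spec$focus_z)),
       field = fld)
}
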