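# Serialization: PNG/TIFF images via EBImage; ground truth as JSON with
# run-length-encoded masks (column-major runs over the bbox raster).

#' Run-length encode / decode a binary mask
#'
#' @param mask logical matrix.
#' @return `rle_encode`: list with `dim`, `lengths`, `values` (0/1).
#' @export
rle_encode <- function(mask) {
  r <- rle(as.integer(as.vector(mask)))
  list(dim = dim(mask), lengths = as.integer(r$lengths),
       values = as.integer(r$values))
}

#' @rdname rle_encode
#' @param enc an `rle_encode()` list.
#' @export
rle_decode <- function(enc) {
  v <- inverse.rle(list(lengths = enc$lengths, values = enc$values))
  matrix(as.logical(v), nrow = enc$dim[1], ncol = enc$dim[2])
}

#' Write / read an RGB raster as PNG or TIFF
#'
#' @param img numeric array `[rows, cols, 3]`, 0-255.
#' @param path output path; the extension selects the format.
#' @return `path` (write) or the array (read).
#' @export
write_image <- function(img, path) {
  EBImage::writeImage(EBImage::Image(aperm(img, c(2, 1, 3)) / 255,
                                     colormode = "Color"), path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  im <- EBImage::readImage(path)
  d <- dim(im)
  if (length(d) == 2) {
    g <- t(EBImage::imageData(im)) * 255
    out <- array(0, c(nrow(g), ncol(g), 3))
    for (ch in 1:3) out[, , ch] <- g
    return(out)
  }
  aperm(EBImage::imageData(im)[, , 1:3, drop = FALSE] * 255, c(2, 1, 3))
}

#' Write / read per-field ground truth as JSON
#'
#' One JSON per field: for each cell its class, centroid, bbox, and
#' run-length-encoded bbox-local cell and nucleus masks.
#'
#' @param field a [render_field()] result.
#' @param path JSON path.
#' @return `path` (write); a list shaped like `synthetic_field$cells`
#'   (read).
#' @export
write_ground_truth <- function(field, path) {
  cells <- lapply(field$cells, function(cell) {
    list(cell_class = cell$cell_class,
         centroid = as.list(cell$centroid),
         bbox = as.list(cell$bbox),
         radius = cell$radius,
         cell_mask = rle_encode(cell$cell_mask),
         nucleus_mask = rle_encode(cell$nucleus_mask))
  })
  jsonlite::write_json(
    list(width = field$spec$width, height = field$spec$height,
         seed = field$spec$seed, cells = cells),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  cells <- lapply(x$cells, function(cell) {
    list(cell_class = cell$cell_class,
         centroid = unlist(cell$centroid),
         bbox = unlist(cell$bbox),
         radius = cell$radius,
         cell_mask = rle_decode(cell$cell_mask),
         nucleus_mask = rle_decode(cell$nucleus_mask))
  })
  list(width = x$width, height = x$height, seed = x$seed, cells = cells)
}

#' Write a focus result as JSON
#'
#' @param result a [autofocus_stack()] result.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_focus_result <- function(result, path) {
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
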