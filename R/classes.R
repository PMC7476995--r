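#' The twelve nucleated-cell categories
#'
#' Fixed, ordered label set for the WHO-aligned bone-marrow differential:
#' granulocytic precursors and mature granulocytes, monocytes, erythroblasts,
#' lymphocytes, plasma cells, and a catch-all "other" (broken/smudge cells,
#' rare hematopoietic and non-hematopoietic cells).  The order is the
#' tie-break and confusion-matrix order throughout the package.
#'
#' @return character vector of length 12.
#' @export
cell_classes <- function() {
  c("myeloblast", "promyelocyte", "myelocyte", "metamyelocyte",
    "neutrophil", "eosinophil", "basophil", "monocyte",
    "erythroblast", "lymphocyte", "plasma_cell", "other")
}

#' The five reporting series
#'
#' @return character vector of length 5, in reporting order.
#' @export
series_names <- function() {
  c("granulocytes", "erythroid", "lymphoid", "monocytes", "plasma_cells")
}

#' Map each cell class to its reporting series
#'
#' Myeloblasts through basophils form the granulocytic series (standard
#' hematology convention); "other" maps to no series and is excluded from the
#' percentage denominator.
#'
#' @return named character vector: class -> series name or `"other"`.
#' @export
series_map <- function() {
  c(myeloblast = "granulocytes", promyelocyte = "granulocytes",
    myelocyte = "granulocytes", metamyelocyte = "granulocytes",
    neutrophil = "granulocytes", eosinophil = "granulocytes",
    basophil = "granulocytes", monocyte = "monocytes",
    erythroblast = "erythroid", lymphocyte = "lymphoid",
    plasma_cell = "plasma_cells", other = "other")
}

#' Construct a cell phenotype
#'
#' A generative stand-in for the morphology of one cell category: radius and
#' nucleus-to-cell (N:C) area-ratio ranges, nuclear lobation and ellipticity,
#' Wright-Giemsa-like nucleus/cytoplasm colours, and cytoplasmic granule
#' density.
#'
#' @param cell_class one of [cell_classes()].
#' @param cell_radius_range length-2 positive pixels, ordered.
#' @param nc_ratio_range length-2 in (0, 1], ordered.
#' @param nucleus_lobes integer >= 1.
#' @param nucleus_eccentricity in [0, 1).
#' @param nucleus_color,cytoplasm_color RGB triples in [0, 255].
#' @param granule_density per-pixel probability in [0, 1].
#' @param granule_color RGB triple for granules.
#' @param nucleus_offset fraction of the cell radius by which the nucleus
#'   centre is displaced (eccentric placement, e.g. plasma cells).
#' @return an object of class `cell_phenotype`.
#' @export
cell_phenotype <- function(cell_class, cell_radius_range, nc_ratio_range,
                           nucleus_lobes = 1L, nucleus_eccentricity = 0.2,
                           nucleus_color = c(80, 55, 150),
                           cytoplasm_color = c(170, 185, 220),
                           granule_density = 0, granule_color = c(140, 60, 90),
                           nucleus_offset = 0) {
  stopifnot(
    cell_class %in% cell_classes(),
    length(cell_radius_range) == 2, all(cell_radius_range > 0),
    cell_radius_range[1] <= cell_radius_range[2],
    length(nc_ratio_range) == 2, all(nc_ratio_range > 0),
    nc_ratio_range[2] <= 1, nc_ratio_range[1] <= nc_ratio_range[2],
    nucleus_lobes >= 1,
    nucleus_eccentricity >= 0, nucleus_eccentricity < 1,
    all(nucleus_color >= 0 & nucleus_color <= 255),
    all(cytoplasm_color >= 0 & cytoplasm_color <= 255),
    granule_density >= 0, granule_density <= 1
  )
  structure(list(
    cell_class = cell_class,
    cell_radius_range = as.numeric(cell_radius_range),
    nc_ratio_range = as.numeric(nc_ratio_range),
    nucleus_lobes = as.integer(nucleus_lobes),
    nucleus_eccentricity = nucleus_eccentricity,
    nucleus_color = as.numeric(nucleus_color),
    cytoplasm_color = as.numeric(cytoplasm_color),
    granule_density = granule_density,
    granule_color = as.numeric(granule_color),
    nucleus_offset = nucleus_offset
  ), class = "cell_phenotype")
}

#' Default phenotypes for the twelve categories
#'
#' Engineering defaults chosen to echo textbook Wright-Giemsa morphology at
#' the package's desk scale (cells roughly 14-32 px radius in 512 x 512
#' fields): maturation stages of the neutrophil lineage lose N:C ratio and
#' gain nuclear lobation/indentation; eosinophils carry orange granules and
#' basophils dark violet ones; erythroblasts have small, dense, round nuclei;
#' lymphocytes a thin basophilic rim; monocytes an indented pale nucleus;
#' plasma cells an eccentric nucleus in deep-blue cytoplasm; "other" is a
#' deliberately diffuse smudge-like catch-all.
#'
#' @return named list of [cell_phenotype()] objects, one per class.
#' @export
default_phenotypes <- function() {
  list(
    myeloblast = cell_phenotype("myeloblast", c(22, 28), c(0.82, 0.92),
      nucleus_lobes = 1L, nucleus_eccentricity = 0.15,
      nucleus_color = c(90, 60, 150), cytoplasm_color = c(150, 170, 220)),
    promyelocyte = cell_phenotype("promyelocyte", c(26, 32), c(0.68, 0.78),
      nucleus_lobes = 1L, nucleus_eccentricity = 0.25,
      nucleus_color = c(85, 55, 140), cytoplasm_color = c(165, 175, 220),
      granule_density = 0.08, granule_color = c(140, 60, 90)),
    myelocyte = cell_phenotype("myelocyte", c(22, 28), c(0.55, 0.65),
      nucleus_lobes = 1L, nucleus_eccentricity = 0.35,
      nucleus_color = c(80, 50, 135), cytoplasm_color = c(195, 185, 215),
      granule_density = 0.03),
    metamyelocyte = cell_phenotype("metamyelocyte", c(20, 26), c(0.45, 0.55),
      nucleus_lobes = 1L, nucleus_eccentricity = 0.65,
      nucleus_color = c(80, 50, 135), cytoplasm_color = c(200, 190, 215),
      granule_density = 0.03),
    neutrophil = cell_phenotype("neutrophil", c(18, 24), c(0.30, 0.42),
      nucleus_lobes = 3L, nucleus_eccentricity = 0.3,
      nucleus_color = c(70, 45, 120), cytoplasm_color = c(205, 195, 215),
      granule_density = 0.02),
    eosinophil = cell_phenotype("eosinophil", c(18, 24), c(0.30, 0.42),
      nucleus_lobes = 2L, nucleus_eccentricity = 0.3,
      nucleus_color = c(75, 50, 125), cytoplasm_color = c(205, 190, 210),
      granule_density = 0.30, granule_color = c(230, 140, 90)),
    basophil = cell_phenotype("basophil", c(16, 22), c(0.40, 0.52),
      nucleus_lobes = 2L, nucleus_eccentricity = 0.3,
      nucleus_color = c(75, 50, 130), cytoplasm_color = c(195, 190, 220),
      granule_density = 0.35, granule_color = c(60, 50, 110)),
    monocyte = cell_phenotype("monocyte", c(24, 32), c(0.42, 0.55),
      nucleus_lobes = 1L, nucleus_eccentricity = 0.75,
      nucleus_color = c(100, 70, 150), cytoplasm_color = c(185, 190, 210)),
    erythroblast = cell_phenotype("erythroblast", c(14, 18), c(0.55, 0.70),
      nucleus_lobes = 1L, nucleus_eccentricity = 0.05,
      nucleus_color = c(55, 35, 90), cytoplasm_color = c(185, 170, 200)),
    lymphocyte = cell_phenotype("lymphocyte", c(14, 18), c(0.72, 0.85),
      nucleus_lobes = 1L, nucleus_eccentricity = 0.1,
      nucleus_color = c(75, 50, 120), cytoplasm_color = c(170, 185, 220)),
    plasma_cell = cell_phenotype("plasma_cell", c(20, 26), c(0.42, 0.52),
      nucleus_lobes = 1L, nucleus_eccentricity = 0.3,
      nucleus_color = c(70, 45, 115), cytoplasm_color = c(130, 155, 210),
      nucleus_offset = 0.35),
    other = cell_phenotype("other", c(16, 30), c(0.20, 0.95),
      nucleus_lobes = 1L, nucleus_eccentricity = 0.5,
      nucleus_color = c(110, 90, 140), cytoplasm_color = c(190, 185, 200))
  )
}
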