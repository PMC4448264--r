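# The 730-parameter catalog. Constructive scheme:
#   pixel level   : 4 regions x 10 channels x 10 statistics          = 400
#   object level  : 4 object classes x 11 descriptors x 7 aggregates = 308
#                   + 6 topological parameters                       = 314
#   semantic level: 16 named ratios / densities                      =  16
# Every parameter printed in the study's univariate tables has a catalog
# entry (see catalog_aliases()).

.px_regions <- c("image", "nest", "stroma", "nuclei")
.px_channels <- c("R", "G", "B", "H", "S", "V", "L", "chroma", "hem_od", "eos_od")
.px_stats <- c("mean", "sd", "min", "max", "median", "p10", "p90",
               "skew", "kurt", "entropy")
.obj_classes <- c("nest", "epithelial", "stromal_round", "stromal_nonround")
.obj_descriptors <- c("area", "perimeter", "eccentricity", "solidity",
                      "circularity", "axis_major", "axis_minor", "extent",
                      "boundary_gradient", "feret", "orientation")
.obj_aggregates <- c("count", "sum", "mean", "var", "min", "max", "median")
.topo_names <- c("tns_fractal_dimension", "tns_cell_delaunay_area_sum",
                 "delaunay_edge_mean", "delaunay_edge_var",
                 "stromal_cell_structure", "nn_mean_distance")
.semantic_names <- c(
  "tns_cell_density", "stromal_round_cell_density",
  "stromal_nonround_cell_density", "stromal_cell_density",
  "tns_nuclei_area_ratio", "tns_area_perimeter_ratio",
  "nest_stroma_area_ratio", "nest_area_fraction", "stroma_area_fraction",
  "nuclei_area_fraction", "nuclei_cytoplasm_ratio",
  "epithelial_nuclei_fraction", "stromal_round_fraction",
  "mean_nuclei_per_nest", "tns_count_density", "nuclei_count_density"
)

#' The feature catalog manifest
#'
#' Enumerates the full 730-parameter catalog: 400 pixel-level parameters
#' (region x channel x statistic), 314 object-level parameters (object class
#' x shape descriptor x aggregate, plus 6 topological parameters) and 16
#' semantic-level ratios and densities.
#'
#' @return A tibble with columns `name`, `level` (`pixel`, `object`,
#'   `semantic`) and `definition`; exactly 730 rows with unique names.
#' @export
#' @examples
#' dplyr::count(feature_catalog(), level)
feature_catalog <- function() {
  px <- tidyr::expand_grid(region = .px_regions, channel = .px_channels,
                           stat = .px_stats) |>
    dplyr::mutate(
      name = paste("px", region, channel, stat, sep = "_"),
      level = "pixel",
      definition = paste0(stat, " of channel ", channel, " over region ", region)
    )
  ob <- tidyr::expand_grid(class = .obj_classes, desc = .obj_descriptors,
                           agg = .obj_aggregates) |>
    dplyr::mutate(
      name = paste(class, desc, agg, sep = "_"),
      level = "object",
      definition = paste0(agg, " of per-object ", desc, " over class ", class)
    )
  topo <- tibble::tibble(
    name = .topo_names, level = "object",
    definition = c(
      "box-counting fractal dimension of the tumor-nest boundary",
      "sum of Delaunay triangle areas over epithelial nucleus centroids (px^2)",
      "mean Delaunay edge length over epithelial centroids (px)",
      "population variance of Delaunay edge lengths over epithelial centroids",
      "mean Delaunay edge length over stromal non-round centroids (px)",
      "mean nearest-neighbor distance over all nucleus centroids (px)"
    )
  )
  sem <- tibble::tibble(
    name = .semantic_names, level = "semantic",
    definition = c(
      "epithelial nucleus count / total nest area (px^-2)",
      "stromal round nucleus count / stroma area (px^-2)",
      "stromal non-round nucleus count / stroma area (px^-2)",
      "all stromal nucleus count / stroma area (px^-2)",
      "sum of epithelial nucleus areas / sum of nest areas",
      "sum of nest areas / sum of nest perimeters (px)",
      "nest area / stroma area",
      "nest area / image area",
      "stroma area / image area",
      "total nucleus area / image area",
      "total nucleus area / non-nucleus area",
      "epithelial nucleus count / total nucleus count",
      "stromal round count / total nucleus count",
      "epithelial nucleus count / nest count",
      "nest count / image area (px^-2)",
      "total nucleus count / image area (px^-2)"
    )
  )
  dplyr::bind_rows(
    dplyr::select(px, "name", "level", "definition"),
    dplyr::select(ob, "name", "level", "definition"),
    topo, sem
  )
}

#' Canonical names for the printed study parameters
#'
#' Maps the parameter names used in the study's univariate tables to their
#' catalog entries.
#'
#' @return A tibble with columns `parameter` and `catalog_name`.
#' @export
catalog_aliases <- function() {
  tibble::tribble(
    ~parameter, ~catalog_name,
    "TNs fractal dimension", "tns_fractal_dimension",
    "TNs number", "nest_area_count",
    "TNs perimeter sum", "nest_perimeter_sum",
    "TNs cell Delaunay area sum", "tns_cell_delaunay_area_sum",
    "Stromal cell structure feature", "stromal_cell_structure",
    "TNs area average", "nest_area_mean",
    "TNs area variance", "nest_area_var",
    "TNs cell nuclei area average", "epithelial_area_mean",
    "TNs cell nuclei area variance", "epithelial_area_var",
    "TNs cell nuclei eccentricity maximum", "epithelial_eccentricity_max",
    "TNs cell nuclei area/TNs area ratio", "tns_nuclei_area_ratio",
    "TNs cell density", "tns_cell_density",
    "TNs area/perimeter ratio", "tns_area_perimeter_ratio",
    "Stromal non round cell density", "stromal_nonround_cell_density"
  )
}

# Distribution statistics for one vector of channel values.
.px_stat_vec <- function(v) {
  if (length(v) == 0L) {
    return(stats::setNames(rep(NA_real_, 10L), .px_stats))
  }
  m <- mean(v)
  s <- stats::sd(v)
  if (length(v) == 1L) s <- 0
  q <- stats::quantile(v, c(0.1, 0.5, 0.9), names = FALSE)
  if (s > 0) {
    z <- v - m
    m2 <- mean(z^2)
    skew <- mean(z^3) / m2^1.5
    kurt <- mean(z^4) / m2^2
  } else {
    skew <- 0; kurt <- 0
  }
  h <- tabulate(pmin(floor((v - min(v)) / max(diff(range(v)), 1e-12) * 64) + 1, 64), 64)
  p <- h[h > 0] / length(v)
  ent <- -sum(p * log2(p))
  stats::setNames(
    c(m, s, min(v), max(v), q[2], q[1], q[3], skew, kurt, ent), .px_stats
  )
}

#' Pixel-level feature set (400 parameters)
#'
#' Distribution statistics of ten color/stain channels (R, G, B; HSV; Lab
#' lightness and chroma; hematoxylin and eosin OD) over four regions (whole
#' image, nest, stroma, nuclei mask).
#'
#' @param image `H x W x 3` RGB array.
#' @param tissue Integer tissue mask (1 = nest).
#' @param nuclei_labels Integer nucleus label matrix.
#' @return Named numeric vector of 400 values (NA where a region is empty).
#' @export
pixel_level_features <- function(image, tissue, nuclei_labels) {
  d <- dim(image)
  rgb01 <- matrix(image, ncol = 3L) / 255
  hsv <- t(grDevices::rgb2hsv(t(matrix(image, ncol = 3L)), maxColorValue = 255))
  lab <- grDevices::convertColor(rgb01, from = "sRGB", to = "Lab")
  ch <- color_deconvolve(image)
  channels <- list(
    R = image[, , 1], G = image[, , 2], B = image[, , 3],
    H = matrix(hsv[, 1], d[1], d[2]),
    S = matrix(hsv[, 2], d[1], d[2]),
    V = matrix(hsv[, 3], d[1], d[2]),
    L = matrix(lab[, 1], d[1], d[2]),
    chroma = matrix(sqrt(lab[, 2]^2 + lab[, 3]^2), d[1], d[2]),
    hem_od = ch$hematoxylin_od, eos_od = ch$eosin_od
  )
  regions <- list(
    image = rep(TRUE, d[1] * d[2]),
    nest = as.vector(tissue > 0),
    stroma = as.vector(tissue == 0),
    nuclei = as.vector(nuclei_labels > 0)
  )
  out <- numeric(0)
  for (rg in .px_regions) {
    sel <- regions[[rg]]
    for (cn in .px_channels) {
      v <- as.vector(channels[[cn]])[sel]
      st <- .px_stat_vec(v)
      names(st) <- paste("px", rg, cn, names(st), sep = "_")
      out <- c(out, st)
    }
  }
  out
}

# Aggregate one descriptor table into the 77-value class block.
.aggregate_class <- function(tab) {
  out <- numeric(0)
  n <- nrow(tab)
  for (dsc in .obj_descriptors) {
    v <- if (n > 0) tab[[dsc]] else numeric(0)
    v <- v[!is.na(v)]
    vals <- if (length(v) == 0L) {
      c(count = n, stats::setNames(rep(NA_real_, 6L), .obj_aggregates[-1]))
    } else {
      c(count = n, sum = sum(v), mean = mean(v),
        var = mean((v - mean(v))^2), min = min(v), max = max(v),
        median = stats::median(v))
    }
    names(vals) <- paste(dsc, .obj_aggregates, sep = "_")
    out <- c(out, vals)
  }
  out
}

#' Object-level feature set (314 parameters)
#'
#' Aggregated shape descriptors for the four object classes (tumor nests,
#' epithelial nuclei, stromal round and stromal non-round nuclei) plus six
#' topological parameters (nest-boundary fractal dimension, Delaunay
#' statistics of epithelial centroids, the stromal cell structure parameter —
#' mean Delaunay edge length over stromal non-round centroids — and the mean
#' nearest-neighbor distance of all nuclei).
#'
#' @param nests Tibble of nest measurements from [measure_objects()].
#' @param classified A `classified_nuclei` object.
#' @param tissue Integer tissue mask (used for the boundary fractal
#'   dimension).
#' @return Named numeric vector of 314 values.
#' @export
object_level_features <- function(nests, classified, tissue) {
  nuc <- classified$nuclei
  out <- numeric(0)
  for (cl in .obj_classes) {
    tab <- if (cl == "nest") nests else dplyr::filter(nuc, .data$class == cl)
    block <- .aggregate_class(tab)
    names(block) <- paste(cl, names(block), sep = "_")
    out <- c(out, block)
  }
  epi <- dplyr::filter(nuc, .data$class == "epithelial")
  nonround <- dplyr::filter(nuc, .data$class == "stromal_nonround")
  dl <- delaunay_stats(epi)
  dl_nr <- delaunay_stats(nonround)
  topo <- c(
    tns_fractal_dimension = if (any(tissue > 0)) fractal_dimension(nest_boundary(tissue)) else NA_real_,
    tns_cell_delaunay_area_sum = dl$area_sum,
    delaunay_edge_mean = dl$edge_mean,
    delaunay_edge_var = dl$edge_var,
    stromal_cell_structure = dl_nr$edge_mean,
    nn_mean_distance = .nn_mean_distance(nuc)
  )
  c(out, topo)
}

#' Semantic-level feature set (16 parameters)
#'
#' The named densities and ratios relating tissue compartments and nucleus
#' populations, including the printed prognostic parameters: TNs cell density
#' (epithelial count per px^2 of nest), stromal non-round cell density, TNs
#' cell nuclei area / TNs area ratio and TNs area / perimeter ratio.
#'
#' @inheritParams object_level_features
#' @return Named numeric vector of 16 values (NA on zero denominators).
#' @export
semantic_level_features <- function(nests, classified, tissue) {
  cnt <- classified$counts
  nuc <- classified$nuclei
  nest_area <- sum(tissue > 0)
  img_area <- length(tissue)
  stroma_area <- img_area - nest_area
  nuclei_area_total <- sum(nuc$area)
  epi_area <- sum(nuc$area[nuc$class == "epithelial"])
  n_nuc <- nrow(nuc)
  nest_perim_sum <- sum(nests$perimeter)
  rat <- function(num, den) if (is.na(den) || den == 0) NA_real_ else num / den
  stats::setNames(c(
    rat(cnt[["epithelial"]], nest_area),
    rat(cnt[["stromal_round"]], stroma_area),
    rat(cnt[["stromal_nonround"]], stroma_area),
    rat(cnt[["stromal_round"]] + cnt[["stromal_nonround"]], stroma_area),
    rat(epi_area, nest_area),
    rat(sum(nests$area), nest_perim_sum),
    rat(nest_area, stroma_area),
    nest_area / img_area,
    stroma_area / img_area,
    nuclei_area_total / img_area,
    rat(nuclei_area_total, img_area - nuclei_area_total),
    rat(cnt[["epithelial"]], n_nuc),
    rat(cnt[["stromal_round"]], n_nuc),
    rat(cnt[["epithelial"]], nrow(nests)),
    nrow(nests) / img_area,
    n_nuc / img_area
  ), .semantic_names)
}

#' Extract the full 730-parameter catalog for one image
#'
#' Runs the three feature levels on completed segmentations and returns one
#' wide row with every catalog value.
#'
#' @param image `H x W x 3` RGB array.
#' @param tissue Integer tissue mask (1 = nest).
#' @param nuclei_labels Integer nucleus label matrix.
#' @param classified A `classified_nuclei` object.
#' @param nests Nest measurement tibble; when `NULL`, nests are measured
#'   from the connected components of `tissue`.
#' @param image_id Identifier stored in the output row.
#' @return A one-row tibble: `image_id` plus 730 feature columns in catalog
#'   order.
#' @export
extract_catalog <- function(image, tissue, nuclei_labels, classified,
                            nests = NULL, image_id = "image") {
  if (is.null(nests)) nests <- measure_nests(tissue)
  vals <- c(
    pixel_level_features(image, tissue, nuclei_labels),
    object_level_features(nests, classified, tissue),
    semantic_level_features(nests, classified, tissue)
  )
  stopifnot(identical(names(vals), feature_catalog()$name))
  dplyr::bind_cols(tibble::tibble(image_id = image_id),
                   tibble::as_tibble(as.list(vals)))
}

#' Measure tumor nests from a tissue mask
#'
#' Labels the 8-connected nest components of a tissue mask and measures them
#' with [measure_objects()].
#'
#' @param tissue Integer tissue mask (1 = nest).
#' @param od Optional OD matrix for boundary saliency.
#' @return A tibble of nest objects.
#' @export
measure_nests <- function(tissue, od = NULL) {
  lab <- matrix(
    as.integer(round(.from_eb(EBImage::bwlabel(.as_eb((tissue > 0) * 1))))),
    nrow(tissue), ncol(tissue)
  )
  measure_objects(lab, od)
}

#' Aggregate per-image features to the patient level
#'
#' Averages each feature over a patient's images, ignoring missing values
#' (a feature missing on every image stays missing).
#'
#' @param features Tibble of per-image rows from [extract_catalog()], with a
#'   `patient_id` column.
#' @return Tibble with one row per patient and the per-feature means.
#' @export
aggregate_patient <- function(features) {
  stopifnot("patient_id" %in% names(features), nrow(features) >= 1)
  features |>
    dplyr::select(-dplyr::any_of("image_id")) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(dplyr::across(
      dplyr::where(is.numeric),
      ~ if (all(is.na(.x))) NA_real_ else mean(.x, na.rm = TRUE)
    ), .groups = "drop")
}
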