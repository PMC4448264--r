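#' Threshold and clean the hematoxylin channel into a nuclei mask
#'
#' Thresholds the hematoxylin optical-density map (Otsu by default), then
#' applies a morphological opening with a disk element to remove noisy
#' sub-nuclear speckles and fills holes.
#'
#' @param hematoxylin_od Nonnegative H x W optical-density matrix.
#' @param morphology_radius Disk radius (px) of the opening element.
#' @param od_threshold OD threshold; `NULL` (default) selects it by Otsu's
#'   method on the OD histogram.
#' @return Logical H x W matrix (`TRUE` = candidate nucleus pixel).
#' @export
nuclei_mask <- function(hematoxylin_od, morphology_radius = 2, od_threshold = NULL) {
  stopifnot(is.matrix(hematoxylin_od), all(hematoxylin_od >= 0))
  mx <- max(hematoxylin_od)
  if (mx == 0) return(matrix(FALSE, nrow(hematoxylin_od), ncol(hematoxylin_od)))
  if (is.null(od_threshold)) {
    od_threshold <- EBImage::otsu(.as_eb(hematoxylin_od), range = c(0, mx))
  }
  bw <- hematoxylin_od > od_threshold
  if (morphology_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(morphology_radius) + 1L, "disc")
    eb <- EBImage::opening(.as_eb(bw * 1), brush)
    bw <- .from_eb(eb) > 0.5
  }
  filled <- EBImage::fillHull(.as_eb(bw * 1))
  .from_eb(filled) > 0.5
}

#' Extract nucleus markers by depth-suppressed regional extrema
#'
#' Candidate nucleus locations are the regional maxima of the smoothed
#' hematoxylin OD inside the mask (equivalently, regional minima of the
#' inverted map) after suppressing maxima shallower than `h`. Each candidate
#' is reduced to its single peak pixel, labeled 1..k.
#'
#' @param mask Logical nuclei mask from [nuclei_mask()].
#' @param od Hematoxylin OD matrix.
#' @param h Suppression depth in OD units (> 0); `NULL` uses 10% of the
#'   robust OD range (10th to 90th percentile of the smoothed OD) inside the
#'   mask, which is insensitive to the extreme tails that contrast
#'   stretching produces.
#' @param smooth_sigma Gaussian smoothing (px) applied before peak detection.
#' @return Integer H x W marker matrix, one positive label per candidate
#'   nucleus (0 elsewhere). An empty mask yields zero markers.
#' @export
extract_markers <- function(mask, od, h = NULL, smooth_sigma = 2) {
  stopifnot(is.matrix(mask), is.matrix(od), all(dim(mask) == dim(od)))
  markers <- matrix(0L, nrow(mask), ncol(mask))
  if (!any(mask)) return(markers)
  sm <- .from_eb(EBImage::gblur(.as_eb(od), sigma = smooth_sigma))
  if (is.null(h)) {
    rng <- diff(stats::quantile(sm[mask], c(0.1, 0.9), names = FALSE))
    h <- max(0.1 * rng, 1e-6)
  }
  stopifnot(h > 0)
  x <- sm
  x[!mask] <- 0
  ws <- .from_eb(EBImage::watershed(.as_eb(x), tolerance = h, ext = 1L))
  ws[!mask] <- 0L
  labs <- sort(unique(ws[ws > 0]))
  for (i in seq_along(labs)) {
    idx <- which(ws == labs[i])
    peak <- idx[which.max(sm[idx])]
    markers[peak] <- i
  }
  markers
}

#' Grow watershed regions from markers
#'
#' Marker-controlled watershed: every mask pixel is assigned to exactly one
#' marker by seeded region growing on the OD landscape, so touching nuclei
#' are split along watershed lines between their markers. Mask components
#' containing no marker cannot be seeded; they are returned as whole-component
#' regions and their labels are recorded in the `unseeded` attribute.
#'
#' @param markers Integer marker matrix from [extract_markers()].
#' @param od Hematoxylin OD matrix.
#' @param mask Logical nuclei mask.
#' @return Integer label matrix partitioning the mask (labels contiguous from
#'   1; 0 = background), with attribute `unseeded` listing labels grown from
#'   no marker.
#' @export
watershed_segment <- function(markers, od, mask) {
  stopifnot(all(dim(markers) == dim(od)), all(dim(mask) == dim(od)))
  if (any(markers[!mask] > 0)) stop("markers must lie inside the mask")
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (!any(mask)) return(structure(out, unseeded = integer(0)))
  if (max(markers) > 0) {
    lab <- EBImage::propagate(
      x = .as_eb(od), seeds = .as_eb(markers), mask = .as_eb(mask * 1)
    )
    out <- matrix(as.integer(round(.from_eb(lab))), nrow(mask), ncol(mask))
  }
  unseeded <- integer(0)
  left <- mask & out == 0L
  if (any(left)) {
    extra <- .from_eb(EBImage::bwlabel(.as_eb(left * 1)))
    extra <- matrix(as.integer(round(extra)), nrow(mask), ncol(mask))
    off <- max(out)
    out[extra > 0L] <- extra[extra > 0L] + off
    unseeded <- off + seq_len(max(extra))
  }
  out <- .relabel(out)
  structure(out, unseeded = if (length(unseeded)) seq(max(markers) + 1L, max(out)) else integer(0))
}

# Boundary pixels of every labeled region (4-connectivity).
.label_boundary <- function(labels) {
  b <- labels != .shift_replicate(labels, 1, 0) |
    labels != .shift_replicate(labels, -1, 0) |
    labels != .shift_replicate(labels, 0, 1) |
    labels != .shift_replicate(labels, 0, -1)
  b & labels > 0
}

# Convex-hull area and Feret diameter from pixel coordinates (uses pixel
# corners so thin regions get a positive hull area).
.hull_stats <- function(rows, cols) {
  pr <- c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5)
  pc <- c(cols - 0.5, cols + 0.5, cols - 0.5, cols + 0.5)
  h <- grDevices::chull(pc, pr)
  hx <- pc[h]; hy <- pr[h]
  n <- length(h)
  area <- abs(sum(hx * hy[c(2:n, 1)] - hx[c(2:n, 1)] * hy)) / 2
  feret <- sqrt(max(outer(hx, hx, "-")^2 + outer(hy, hy, "-")^2))
  c(area = area, feret = feret)
}

#' Measure labeled objects
#'
#' Computes per-object shape and boundary descriptors for a label mask:
#' centroid, area, perimeter, eccentricity, solidity, circularity, axis
#' lengths, extent, Feret diameter, orientation and the mean intensity
#' gradient along the object boundary (in 8-bit units of the transmission
#' image implied by the OD map).
#'
#' @param labels Integer H x W label matrix (0 = background).
#' @param od Matching optical-density matrix used for boundary saliency.
#' @return A tibble with one row per object: `id`, `row`, `col`, `area`,
#'   `perimeter`, `eccentricity`, `solidity`, `circularity`, `axis_major`,
#'   `axis_minor`, `extent`, `feret`, `orientation`, `boundary_gradient`.
#' @export
measure_objects <- function(labels, od = NULL) {
  empty <- tibble::tibble(
    id = integer(), row = numeric(), col = numeric(), area = numeric(),
    perimeter = numeric(), eccentricity = numeric(), solidity = numeric(),
    circularity = numeric(), axis_major = numeric(), axis_minor = numeric(),
    extent = numeric(), feret = numeric(), orientation = numeric(),
    boundary_gradient = numeric()
  )
  if (max(labels) == 0L) return(empty)
  eb <- .as_eb(labels)
  sh <- EBImage::computeFeatures.shape(eb)
  mo <- EBImage::computeFeatures.moment(eb)
  ids <- sort(unique(labels[labels > 0]))
  idx <- split(which(labels > 0), labels[labels > 0])
  H <- nrow(labels)
  hull <- t(vapply(idx, function(i) {
    .hull_stats((i - 1L) %% H + 1L, (i - 1L) %/% H + 1L)
  }, c(area = 0, feret = 0)))
  bbox <- t(vapply(idx, function(i) {
    r <- (i - 1L) %% H + 1L; c <- (i - 1L) %/% H + 1L
    (diff(range(r)) + 1) * (diff(range(c)) + 1)
  }, 0))
  grad_mean <- rep(NA_real_, length(ids))
  if (!is.null(od)) {
    intensity <- 255 * 10^(-od)
    g <- .gradient_magnitude(intensity)
    bnd <- .label_boundary(labels)
    gm <- tapply(g[bnd], labels[bnd], mean)
    grad_mean[match(as.integer(names(gm)), ids)] <- as.numeric(gm)
  }
  area <- sh[, "s.area"]
  per <- pmax(sh[, "s.perimeter"], 1)
  ecc <- mo[, "m.eccentricity"]
  tibble::tibble(
    id = ids,
    row = as.numeric(mo[, "m.cy"]), col = as.numeric(mo[, "m.cx"]),
    area = as.numeric(area),
    perimeter = as.numeric(per),
    eccentricity = pmin(pmax(as.numeric(ecc), 0), 0.999999),
    solidity = as.numeric(pmin(as.numeric(area) / pmax(hull[, "area"], 1e-9), 1)),
    circularity = pmin(4 * pi * as.numeric(area) / per^2, 1.5),
    axis_major = as.numeric(mo[, "m.majoraxis"]),
    axis_minor = as.numeric(mo[, "m.majoraxis"]) * sqrt(1 - pmin(ecc, 1)^2),
    extent = as.numeric(area) / as.numeric(bbox),
    feret = as.numeric(hull[, "feret"]),
    orientation = as.numeric(mo[, "m.theta"]),
    boundary_gradient = grad_mean
  )
}

#' Spurious-region removal rules
#'
#' Default thresholds for [remove_spurious()]: area within
#' `[min_area, max_area]` px^2, solidity at least `s_min`, mean boundary
#' gradient at least `g_min` intensity/px. The study states the criteria
#' (shape, texture, boundary saliency) without numbers; these defaults were
#' fixed once against the synthetic generator.
#'
#' @param min_area,max_area Area gates in px^2 (`min_area < max_area`).
#' @param s_min Minimum solidity.
#' @param g_min Minimum mean boundary gradient (intensity/px).
#' @return Named list of rules.
#' @export
spurious_rules <- function(min_area = 30, max_area = 3000, s_min = 0.7, g_min = 5) {
  stopifnot(min_area < max_area)
  list(min_area = min_area, max_area = max_area, s_min = s_min, g_min = g_min)
}

#' Remove spurious watershed regions
#'
#' Drops candidate regions that fail the shape and boundary-saliency rules
#' and measures the survivors into a nucleus table.
#'
#' @param labels Label matrix from [watershed_segment()].
#' @param od Hematoxylin OD matrix.
#' @param rules A list from [spurious_rules()].
#' @return A list with `labels` (relabeled, contiguous from 1) and `nuclei`
#'   (tibble of surviving objects from [measure_objects()], ids matching the
#'   new labels).
#' @export
remove_spurious <- function(labels, od, rules = spurious_rules()) {
  meas <- measure_objects(labels, od)
  keep <- meas$area >= rules$min_area & meas$area <= rules$max_area &
    meas$solidity >= rules$s_min &
    (is.na(meas$boundary_gradient) | meas$boundary_gradient >= rules$g_min)
  drop_ids <- meas$id[!keep]
  out <- labels
  out[out %in% drop_ids] <- 0L
  out <- .relabel(out)
  nuclei <- measure_objects(out, od)
  list(labels = out, nuclei = nuclei)
}

#' Segment nuclei in an H&E image
#'
#' Full marker-controlled watershed chain: hematoxylin extraction by color
#' deconvolution, OD thresholding and morphological cleanup, depth-suppressed
#' marker extraction, seeded watershed growth, and spurious-region removal.
#'
#' @param image `H x W x 3` RGB array (ideally preprocessed).
#' @param morphology_radius,od_threshold Passed to [nuclei_mask()].
#' @param h,smooth_sigma Passed to [extract_markers()].
#' @param rules Passed to [remove_spurious()].
#' @return A list with `labels` (nucleus label matrix), `nuclei` (measurement
#'   tibble) and `hematoxylin_od`.
#' @export
segment_nuclei <- function(image, morphology_radius = 2, od_threshold = NULL,
                           h = NULL, smooth_sigma = 2, rules = spurious_rules()) {
  ch <- color_deconvolve(image)
  od <- ch$hematoxylin_od
  mask <- nuclei_mask(od, morphology_radius, od_threshold)
  markers <- extract_markers(mask, od, h = h, smooth_sigma = smooth_sigma)
  labs <- watershed_segment(markers, od, mask)
  res <- remove_spurious(labs, od, rules)
  res$hematoxylin_od <- od
  res
}
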