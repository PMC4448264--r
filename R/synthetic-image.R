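#' Synthetic H&E image scenario
#'
#' Bundles the parameters of the synthetic H&E image generator. Defaults
#' emulate a 200x invasive-ductal-carcinoma field at the pixel scale of the
#' study frames: epithelial nuclei of ~200 px^2 packed inside tumor nests at
#' ~0.0013 nuclei/px^2, nests of ~12000 px^2 covering roughly half the field,
#' and sparse round (immune) and elongated (fibroblast/vessel) nuclei in the
#' eosin-pink stroma. The default field is 544 x 416 px, a sub-field at the
#' same magnification as the acquired 1360 x 1024 frames, with the nest count
#' scaled by area.
#'
#' @param width,height Field size in pixels (>= 16).
#' @param n_nests Number of tumor nests to place.
#' @param nest_area_mean,nest_area_var Mean and variance of nest area (px^2).
#' @param nuclei_density_in_nest Epithelial nuclei per px^2 of nest.
#' @param stromal_round_density,stromal_nonround_density Stromal nuclei per
#'   px^2 of stroma.
#' @param nucleus_area_mean,nucleus_area_var Mean and variance of nucleus
#'   area (px^2).
#' @param nonround_eccentricity_min Lower eccentricity bound for stromal
#'   non-round nuclei, in `[0, 1)`.
#' @param stain_noise_sd Gaussian pixel noise, in 8-bit intensity units.
#' @param illumination_gradient Relative amplitude of a left-to-right linear
#'   illumination ramp (fraction of intensity).
#' @param seed Integer seed; identical seeds give bit-identical images.
#' @return An object of class `image_scenario` (a named list).
#' @export
image_scenario <- function(width = 544, height = 416,
                           n_nests = 11,
                           nest_area_mean = 12000, nest_area_var = 4e4,
                           nuclei_density_in_nest = 0.0013,
                           stromal_round_density = 4e-4,
                           stromal_nonround_density = 4.5e-4,
                           nucleus_area_mean = 200, nucleus_area_var = 85,
                           nonround_eccentricity_min = 0.85,
                           stain_noise_sd = 4,
                           illumination_gradient = 0.05,
                           seed = 1L) {
  sc <- list(
    width = as.integer(width), height = as.integer(height),
    n_nests = as.integer(n_nests),
    nest_area_mean = nest_area_mean, nest_area_var = nest_area_var,
    nuclei_density_in_nest = nuclei_density_in_nest,
    stromal_round_density = stromal_round_density,
    stromal_nonround_density = stromal_nonround_density,
    nucleus_area_mean = nucleus_area_mean, nucleus_area_var = nucleus_area_var,
    nonround_eccentricity_min = nonround_eccentricity_min,
    stain_noise_sd = stain_noise_sd,
    illumination_gradient = illumination_gradient,
    seed = as.integer(seed)
  )
  with(sc, {
    stopifnot(
      width >= 16, height >= 16, n_nests >= 0,
      nest_area_mean > 0, nest_area_var >= 0,
      nuclei_density_in_nest >= 0, stromal_round_density >= 0,
      stromal_nonround_density >= 0,
      nucleus_area_mean > 0, nucleus_area_var >= 0,
      nonround_eccentricity_min >= 0, nonround_eccentricity_min < 1,
      stain_noise_sd >= 0, illumination_gradient >= 0
    )
  })
  structure(sc, class = "image_scenario")
}

# Rasterize one jittered-boundary ellipse into a logical H x W matrix.
# The radius is modulated by random low-order sinusoids so nest perimeters
# are irregular rather than smooth conics.
.draw_blob <- function(H, W, cy, cx, area, ecc, theta, jitter = 0.15) {
  k <- sqrt(1 - ecc^2)
  a <- sqrt(area / (pi * k))
  b <- k * a
  n_h <- sample(2:4, 1L)
  amp <- stats::runif(n_h, 0, jitter / n_h)
  ord <- sample(2:6, n_h)
  ph <- stats::runif(n_h, 0, 2 * pi)
  r_ext <- ceiling(max(a, b) * (1 + jitter) + 1)
  rows <- max(1L, floor(cy - r_ext)):min(H, ceiling(cy + r_ext))
  cols <- max(1L, floor(cx - r_ext)):min(W, ceiling(cx + r_ext))
  if (!length(rows) || !length(cols)) return(NULL)
  dy <- matrix(rows - cy, length(rows), length(cols))
  dx <- matrix(cols - cx, length(rows), length(cols), byrow = TRUE)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  ang <- atan2(v, u)
  mod <- 1
  for (i in seq_len(n_h)) mod <- mod + amp[i] * sin(ord[i] * ang + ph[i])
  inside <- (u / a)^2 + (v / b)^2 <= mod^2
  list(rows = rows, cols = cols, inside = inside)
}

# Elliptical squared distance field for a nucleus. The rendered hematoxylin
# profile is a plateau with a sigmoid falloff crossing half-maximum exactly
# at the ground-truth ellipse boundary (d2 = 1), so OD thresholding recovers
# the true nucleus area.
.draw_nucleus <- function(H, W, cy, cx, area, ecc, theta) {
  k <- sqrt(1 - ecc^2)
  a <- sqrt(area / (pi * k))
  b <- k * a
  r_ext <- ceiling(max(a, b) * 1.3 + 1)
  rows <- max(1L, floor(cy - r_ext)):min(H, ceiling(cy + r_ext))
  cols <- max(1L, floor(cx - r_ext)):min(W, ceiling(cx + r_ext))
  dy <- matrix(rows - cy, length(rows), length(cols))
  dx <- matrix(cols - cx, length(rows), length(cols), byrow = TRUE)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  d2 <- (u / a)^2 + (v / b)^2
  list(rows = rows, cols = cols, d2 = d2)
}

#' Generate a synthetic H&E image with ground truth
#'
#' Renders an H&E-like RGB field from an [image_scenario()]: tumor nests are
#' unions of 1-4 overlapping jittered ellipses filled with densely packed
#' hematoxylin-dark epithelial nuclei; the surrounding stroma is eosin-pink
#' with sparse round and elongated nuclei. Nuclei are rendered as hematoxylin
#' optical-density blobs and the field is converted to RGB through the
#' Beer-Lambert law with [he_stain_matrix()], so color deconvolution is
#' exactly invertible up to noise. Gaussian pixel noise and a linear
#' illumination gradient are then applied.
#'
#' @param scenario An [image_scenario()].
#' @return A list with
#'   \describe{
#'     \item{image}{`H x W x 3` RGB array in `[0, 255]`.}
#'     \item{truth}{A `ground_truth` list: `nest_mask` (integer label matrix,
#'       0 = stroma), `nuclei_mask` (integer label matrix, one label per
#'       nucleus), `nucleus_classes` (character vector indexed by nucleus id,
#'       values `epithelial`, `stromal_round`, `stromal_nonround`),
#'       `centroids` (tibble of id, row, col, class) and `true_counts`
#'       (named integer vector).}
#'   }
#' @export
#' @examples
#' out <- generate_he_image(image_scenario(width = 64, height = 64,
#'   n_nests = 1, nest_area_mean = 600, seed = 3))
#' out$truth$true_counts
generate_he_image <- function(scenario) {
  stopifnot(inherits(scenario, "image_scenario"))
  withr::with_seed(scenario$seed, .render_he_image(scenario))
}

.render_he_image <- function(sc) {
  H <- sc$height; W <- sc$width
  nest_mask <- matrix(0L, H, W)

  # --- nests: union of 1-4 overlapping jittered ellipses per nest
  if (sc$n_nests > 0) {
    for (i in seq_len(sc$n_nests)) {
      area <- max(200, stats::rnorm(1, sc$nest_area_mean, sqrt(sc$nest_area_var)))
      n_ell <- sample(1:4, 1L)
      cy0 <- stats::runif(1, 0.08 * H, 0.92 * H)
      cx0 <- stats::runif(1, 0.08 * W, 0.92 * W)
      r0 <- sqrt(area / pi)
      for (j in seq_len(n_ell)) {
        bl <- .draw_blob(
          H, W,
          cy0 + stats::rnorm(1, 0, r0 / 3), cx0 + stats::rnorm(1, 0, r0 / 3),
          area / n_ell * stats::runif(1, 0.8, 1.4),
          stats::runif(1, 0.2, 0.7), stats::runif(1, 0, pi)
        )
        if (is.null(bl)) next
        sub <- nest_mask[bl$rows, bl$cols]
        sub[bl$inside] <- i
        nest_mask[bl$rows, bl$cols] <- sub
      }
    }
  }
  nest_area <- sum(nest_mask > 0)
  stroma_area <- H * W - nest_area

  # --- nucleus counts per class
  n_epi <- round(sc$nuclei_density_in_nest * nest_area)
  n_round <- round(sc$stromal_round_density * stroma_area)
  n_nonround <- round(sc$stromal_nonround_density * stroma_area)
  n_tot <- n_epi + n_round + n_nonround
  need <- n_epi * sc$nucleus_area_mean
  if (nest_area > 0 && need > 0.8 * nest_area) stop("infeasible density")
  if (stroma_area > 0 && (n_round + n_nonround) * sc$nucleus_area_mean > 0.8 * stroma_area)
    stop("infeasible density")

  hem_od <- matrix(0, H, W)
  # cytoplasm: mild hematoxylin tint inside nests adds texture contrast
  hem_od[nest_mask > 0] <- 0.10
  eos_od <- matrix(0.28, H, W)
  eos_od[nest_mask > 0] <- 0.45

  nuclei_mask <- matrix(0L, H, W)
  classes <- character(0)
  cent <- list()
  placed_r <- numeric(0)   # equivalent radii of placed nuclei
  # Nuclei are solid bodies: candidate centers are rejected while they would
  # interpenetrate an already placed nucleus (relaxed progressively so the
  # requested count is always placed).
  place <- function(n, class, idx_pool, ecc_range) {
    if (n == 0L || length(idx_pool) == 0L) return(invisible(NULL))
    for (i in seq_len(n)) {
      id <- length(classes) + 1L
      area <- max(20, stats::rnorm(1, sc$nucleus_area_mean, sqrt(sc$nucleus_area_var)))
      ecc <- stats::runif(1, ecc_range[1], ecc_range[2])
      th <- stats::runif(1, 0, pi)
      r_eq <- sqrt(area / pi)
      cy <- cx <- NA_real_
      for (attempt in 1:30) {
        j <- idx_pool[sample.int(length(idx_pool), 1L)]
        cy_try <- (j - 1L) %% H + 1L + stats::runif(1, -0.5, 0.5)
        cx_try <- (j - 1L) %/% H + 1L + stats::runif(1, -0.5, 0.5)
        spacing <- 0.95 * (1 - (attempt - 1) / 40)
        ok <- if (length(placed_r)) {
          cmat <- matrix(unlist(cent), ncol = 2L, byrow = TRUE)
          all((cmat[, 1] - cy_try)^2 + (cmat[, 2] - cx_try)^2 >=
                (spacing * (placed_r + r_eq))^2)
        } else TRUE
        if (ok) { cy <- cy_try; cx <- cx_try; break }
      }
      if (is.na(cy)) {  # last resort: accept the final candidate
        cy <- cy_try; cx <- cx_try
      }
      nd <- .draw_nucleus(H, W, cy, cx, area, ecc, th)
      peak <- stats::runif(1, 0.85, 1.1)
      sub_h <- hem_od[nd$rows, nd$cols]
      sub_l <- nuclei_mask[nd$rows, nd$cols]
      prof <- peak / (1 + exp((nd$d2 - 1) / 0.12))
      inside <- nd$d2 <= 1
      sub_h[inside] <- pmax(sub_h[inside], prof[inside])
      free <- inside & sub_l == 0L
      sub_l[free] <- id
      hem_od[nd$rows, nd$cols] <<- sub_h
      nuclei_mask[nd$rows, nd$cols] <<- sub_l
      classes[id] <<- class
      cent[[id]] <<- c(cy, cx)
      placed_r[id] <<- r_eq
    }
    invisible(NULL)
  }

  nest_idx <- which(nest_mask > 0)
  stroma_idx <- which(nest_mask == 0)
  place(n_epi, "epithelial", nest_idx, c(0.2, 0.75))
  place(n_round, "stromal_round", stroma_idx, c(0, 0.5))
  place(n_nonround, "stromal_nonround", stroma_idx,
        c(sc$nonround_eccentricity_min, 0.97))

  # --- Beer-Lambert rendering through the packaged stain matrix
  M <- he_stain_matrix()
  conc <- cbind(as.vector(hem_od), as.vector(eos_od), 0)
  od <- conc %*% M
  rgb <- 255 * 10^(-od)
  img <- array(rgb, dim = c(H, W, 3L))
  if (sc$illumination_gradient > 0) {
    ramp <- 1 + sc$illumination_gradient * ((seq_len(W) - 1) / max(W - 1, 1) - 0.5)
    img <- img * rep(ramp, each = H)
  }
  if (sc$stain_noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), 0, sc$stain_noise_sd), dim = dim(img))
  }
  img <- round(pmin(pmax(img, 0), 255))

  centroids <- if (length(cent)) {
    tibble::tibble(
      id = seq_along(cent),
      row = vapply(cent, `[`, numeric(1), 1L),
      col = vapply(cent, `[`, numeric(1), 2L),
      class = classes
    )
  } else {
    tibble::tibble(id = integer(), row = numeric(), col = numeric(),
                   class = character())
  }
  counts <- c(
    epithelial = sum(classes == "epithelial"),
    stromal_round = sum(classes == "stromal_round"),
    stromal_nonround = sum(classes == "stromal_nonround")
  )
  truth <- structure(
    list(
      nest_mask = nest_mask,
      nuclei_mask = nuclei_mask,
      nucleus_classes = classes,
      centroids = centroids,
      true_counts = counts
    ),
    class = "ground_truth"
  )
  list(image = img, truth = truth)
}

#' Sample labeled pixels from ground truth
#'
#' Draws a balanced training sample of pixel coordinates for the tissue
#' classifier: `n_per_class` pixels from the nest region and `n_per_class`
#' from the stroma, without replacement, labeled from the ground-truth nest
#' mask. This emulates expert-labeled training pixels.
#'
#' @param truth A `ground_truth` object from [generate_he_image()].
#' @param n_per_class Number of pixels to draw per tissue class (>= 1).
#' @param seed Integer seed.
#' @return A tibble with columns `row`, `col`, `label` (`nest` or `stroma`);
#'   exactly `2 * n_per_class` rows.
#' @export
generate_labeled_pixels <- function(truth, n_per_class, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"), n_per_class >= 1)
  H <- nrow(truth$nest_mask)
  nest_idx <- which(truth$nest_mask > 0)
  stroma_idx <- which(truth$nest_mask == 0)
  if (length(nest_idx) < n_per_class || length(stroma_idx) < n_per_class)
    stop("a tissue class has fewer than n_per_class pixels")
  withr::with_seed(seed, {
    pick_n <- nest_idx[sample.int(length(nest_idx), n_per_class)]
    pick_s <- stroma_idx[sample.int(length(stroma_idx), n_per_class)]
    idx <- c(pick_n, pick_s)
    tibble::tibble(
      row = (idx - 1L) %% H + 1L,
      col = (idx - 1L) %/% H + 1L,
      label = rep(c("nest", "stroma"), each = n_per_class)
    )
  })
}
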