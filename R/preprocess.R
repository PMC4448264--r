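#' Standard H&E stain matrix
#'
#' Returns the 3x3 matrix of unit-norm stain optical-density vectors used for
#' color deconvolution: rows are hematoxylin, eosin, and a residual channel
#' (the normalized cross product of the first two). These are the widely used
#' published H&E vectors.
#'
#' @return A 3x3 numeric matrix with rows `hematoxylin`, `eosin`, `residual`
#'   and columns `R`, `G`, `B`; every row has unit Euclidean norm.
#' @export
#' @examples
#' he_stain_matrix()
he_stain_matrix <- function() {
  h <- c(0.65, 0.70, 0.29)
  e <- c(0.07, 0.99, 0.11)
  r <- c(
    h[2] * e[3] - h[3] * e[2],
    h[3] * e[1] - h[1] * e[3],
    h[1] * e[2] - h[2] * e[1]
  )
  m <- rbind(
    hematoxylin = h / sqrt(sum(h^2)),
    eosin       = e / sqrt(sum(e^2)),
    residual    = r / sqrt(sum(r^2))
  )
  colnames(m) <- c("R", "G", "B")
  m
}

# Vectorized median of nine matrices via Paeth's exchange network.
.median9 <- function(p) {
  sp <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]])
    p[[j]] <<- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo
  }
  sp(2, 3); sp(5, 6); sp(8, 9)
  sp(1, 2); sp(4, 5); sp(7, 8)
  sp(2, 3); sp(5, 6); sp(8, 9)
  sp(1, 4); sp(6, 9); sp(5, 8)
  sp(4, 7); sp(2, 5); sp(3, 6)
  sp(5, 8); sp(5, 3); sp(7, 5)
  sp(5, 3)
  p[[5]]
}

#' 3x3 median filter
#'
#' De-noises an RGB image by replacing every pixel of every channel with the
#' median of its 3x3 neighborhood. Borders are handled by edge replication,
#' so the output has the same dimensions as the input.
#'
#' @param image Numeric `H x W x 3` array with intensities in `[0, 255]`.
#' @return Filtered array of the same dimensions.
#' @export
#' @examples
#' img <- array(128, dim = c(16, 16, 3))
#' identical(median_filter_3x3(img), img)
median_filter_3x3 <- function(image) {
  .assert_rgb(image)
  out <- image
  for (ch in 1:3) {
    m <- image[, , ch]
    p <- vector("list", 9L)
    k <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      k <- k + 1L
      p[[k]] <- .shift_replicate(m, dr, dc)
    }
    out[, , ch] <- .median9(p)
  }
  out
}

#' Percentile contrast stretching
#'
#' Linearly rescales each channel so that the `p_low` percentile maps to 0 and
#' the `p_high` percentile maps to 255, clipping values outside that range.
#' A constant channel cannot be stretched and is returned unchanged with a
#' warning.
#'
#' @param image Numeric `H x W x 3` array in `[0, 255]`.
#' @param p_low,p_high Percentiles in `[0, 100]` with `p_low < p_high`.
#'   Defaults `(1, 99)`.
#' @return Stretched array, rounded to whole intensity levels.
#' @export
contrast_stretch <- function(image, p_low = 1, p_high = 99) {
  .assert_rgb(image)
  stopifnot(p_low >= 0, p_high <= 100, p_low < p_high)
  out <- image
  for (ch in 1:3) {
    m <- image[, , ch]
    q <- stats::quantile(m, c(p_low, p_high) / 100, names = FALSE)
    if (q[2] <= q[1]) {
      warning(sprintf("channel %d is constant at the given percentiles; returned unchanged", ch))
      next
    }
    out[, , ch] <- round(pmin(pmax((m - q[1]) * 255 / (q[2] - q[1]), 0), 255))
  }
  out
}

#' Reinhard-style color normalization
#'
#' Removes slide-to-slide color variation by matching the per-channel mean and
#' standard deviation of the image to those of a reference image in the CIE
#' Lab color space, then converting back to RGB. Normalizing an image against
#' itself is the identity up to rounding.
#'
#' @param image,reference Numeric `H x W x 3` arrays in `[0, 255]`. The
#'   reference must have positive variance in every Lab channel.
#' @return Normalized array with the same dimensions as `image`.
#' @export
color_normalize <- function(image, reference) {
  .assert_rgb(image); .assert_rgb(reference, "reference")
  to_lab <- function(a) {
    grDevices::convertColor(matrix(a, ncol = 3L) / 255, from = "sRGB", to = "Lab")
  }
  lab <- to_lab(image)
  lab_ref <- to_lab(reference)
  mu_r <- colMeans(lab_ref)
  sd_r <- apply(lab_ref, 2L, stats::sd)
  if (any(sd_r < 1e-8)) stop("reference has a zero-variance Lab channel")
  mu <- colMeans(lab)
  sd_i <- apply(lab, 2L, stats::sd)
  for (ch in 1:3) {
    s <- if (sd_i[ch] < 1e-8) 1 else sd_r[ch] / sd_i[ch]
    lab[, ch] <- (lab[, ch] - mu[ch]) * s + mu_r[ch]
  }
  rgb <- grDevices::convertColor(lab, from = "Lab", to = "sRGB")
  out <- array(round(pmin(pmax(rgb, 0), 1) * 255), dim = dim(image))
  out
}

#' H&E color deconvolution
#'
#' Unmixes an RGB image into per-stain optical-density (OD) maps via the
#' Beer-Lambert law: `OD = -log10(I / 255)` per channel, projected onto the
#' stain basis. Negative stain densities are clipped to zero.
#'
#' @param image Numeric `H x W x 3` array in `[0, 255]`.
#' @param stain_matrix 3x3 matrix of unit-norm stain vectors (rows), default
#'   [he_stain_matrix()].
#' @return An object of class `stain_channels`: a list with `hematoxylin_od`,
#'   `eosin_od`, `residual_od` (H x W nonnegative matrices) and
#'   `stain_matrix`.
#' @export
#' @examples
#' img <- array(255, dim = c(16, 16, 3))  # pure white: no absorbance
#' ch <- color_deconvolve(img)
#' max(ch$hematoxylin_od)  # 0
color_deconvolve <- function(image, stain_matrix = he_stain_matrix()) {
  .assert_rgb(image)
  if (abs(det(stain_matrix)) < 1e-8) stop("stain matrix is singular")
  d <- dim(image)
  rgb <- matrix(image, ncol = 3L)
  od <- -log10(pmax(rgb, 1) / 255)
  conc <- od %*% solve(stain_matrix)
  conc[conc < 0] <- 0
  structure(
    list(
      hematoxylin_od = matrix(conc[, 1], d[1], d[2]),
      eosin_od       = matrix(conc[, 2], d[1], d[2]),
      residual_od    = matrix(conc[, 3], d[1], d[2]),
      stain_matrix   = stain_matrix
    ),
    class = "stain_channels"
  )
}

#' Reconstruct RGB from stain channels
#'
#' Inverse of [color_deconvolve()]: recombines per-stain optical densities
#' through the Beer-Lambert law into an 8-bit RGB image.
#'
#' @param channels A `stain_channels` object.
#' @return Numeric `H x W x 3` array in `[0, 255]`.
#' @export
reconstruct_rgb <- function(channels) {
  stopifnot(inherits(channels, "stain_channels"))
  d <- dim(channels$hematoxylin_od)
  conc <- cbind(
    as.vector(channels$hematoxylin_od),
    as.vector(channels$eosin_od),
    as.vector(channels$residual_od)
  )
  od <- conc %*% channels$stain_matrix
  rgb <- round(pmin(pmax(255 * 10^(-od), 0), 255))
  array(rgb, dim = c(d[1], d[2], 3L))
}

#' Full preprocessing chain
#'
#' Applies, in order, the 3x3 median filter, percentile contrast stretching
#' and (optionally) color normalization against a reference image. This is
#' the deterministic image-quality step that precedes segmentation.
#'
#' @inheritParams contrast_stretch
#' @param reference Optional reference image for [color_normalize()]; when
#'   `NULL` the normalization step is skipped.
#' @return Preprocessed `H x W x 3` array.
#' @export
preprocess_image <- function(image, reference = NULL, p_low = 1, p_high = 99) {
  out <- median_filter_3x3(image)
  out <- contrast_stretch(out, p_low, p_high)
  if (!is.null(reference)) out <- color_normalize(out, reference)
  out
}
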