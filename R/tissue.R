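#' Per-pixel color, homogeneity and texture features
#'
#' Computes the 15-dimensional pixel descriptor used by the tissue
#' classifier: per-channel local homogeneity `1 - sd_w / sd_max` (window
#' standard deviation normalized by the maximal possible 8-bit deviation,
#' 127.5), the raw R, G, B intensities, an 8-bin local-binary-pattern
#' histogram (fraction of window pixels whose k-th neighbor exceeds the
#' center) and the local gray-level variance. All features are deterministic
#' moving-window statistics with edge replication.
#'
#' @param image `H x W x 3` RGB array in `[0, 255]`.
#' @param window Odd window size >= 3 (default 9).
#' @return `H x W x 15` numeric array; the third dimension is named.
#' @export
pixel_features <- function(image, window = 9L) {
  .assert_rgb(image)
  window <- as.integer(window)
  stopifnot(window >= 3L, window %% 2L == 1L)
  H <- dim(image)[1]; W <- dim(image)[2]
  nm <- c("homog_R", "homog_G", "homog_B", "R", "G", "B",
          paste0("lbp", 1:8), "local_var")
  out <- array(0, dim = c(H, W, 15L), dimnames = list(NULL, NULL, nm))
  for (ch in 1:3) {
    m <- image[, , ch]
    mu <- .box_mean(m, window)
    v <- pmax(.box_mean(m^2, window) - mu^2, 0)
    out[, , ch] <- pmin(pmax(1 - sqrt(v) / 127.5, 0), 1)
    out[, , 3L + ch] <- m
  }
  gray <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
                c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  for (k in 1:8) {
    bit <- (.shift_replicate(gray, offs[k, 1], offs[k, 2]) > gray) * 1
    out[, , 6L + k] <- .box_mean(bit, window)
  }
  mu <- .box_mean(gray, window)
  out[, , 15L] <- pmax(.box_mean(gray^2, window) - mu^2, 0)
  out
}

# Flatten a feature array to an n_px x 15 matrix.
.flatten_features <- function(fa) {
  d <- dim(fa)
  matrix(fa, nrow = d[1] * d[2], ncol = d[3],
         dimnames = list(NULL, dimnames(fa)[[3]]))
}

#' Train the pixel-wise tissue SVM
#'
#' Fits an RBF-kernel support vector machine on labeled pixel feature
#' vectors. Features are z-standardized with the training statistics (stored
#' in the model and re-applied at prediction time).
#'
#' @param features Numeric matrix, one row per labeled pixel.
#' @param labels Character or factor vector of tissue classes (two or more
#'   classes, at least 10 samples each).
#' @param kernel,cost,gamma SVM hyperparameters; `gamma = NULL` uses
#'   `1 / ncol(features)`.
#' @param seed Integer seed (the SVM optimizer is deterministic given the
#'   data; the seed fixes any internal shuffling).
#' @return An object of class `pixel_classifier` with elements `model`,
#'   `center`, `scale`, `feature_names`, `window`, `train_accuracy`.
#' @export
train_classifier <- function(features, labels, kernel = "radial", cost = 1,
                             gamma = NULL, seed = 1L) {
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("need at least 2 classes")
  if (min(table(labels)) < 10L) stop("need at least 10 samples per class")
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  if (is.null(gamma)) gamma <- 1 / ncol(features)
  ctr <- colMeans(features)
  scl <- apply(features, 2L, stats::sd)
  scl[scl < 1e-9] <- 1
  x <- sweep(sweep(features, 2L, ctr), 2L, scl, "/")
  model <- withr::with_seed(seed,
    e1071::svm(x, labels, kernel = kernel, cost = cost, gamma = gamma,
               scale = FALSE)
  )
  pred <- stats::predict(model, x)
  structure(
    list(model = model, center = ctr, scale = scl,
         feature_names = colnames(features),
         train_accuracy = mean(pred == labels)),
    class = "pixel_classifier"
  )
}

#' Predict with a pixel classifier
#'
#' @param classifier A `pixel_classifier`.
#' @param features Numeric matrix with the same columns the classifier was
#'   trained on.
#' @return Factor of predicted classes.
#' @export
predict_pixels <- function(classifier, features) {
  stopifnot(inherits(classifier, "pixel_classifier"))
  if (ncol(features) != length(classifier$center))
    stop("feature length does not match the trained model")
  x <- sweep(sweep(features, 2L, classifier$center), 2L, classifier$scale, "/")
  stats::predict(classifier$model, x)
}

#' Segment tumor nests vs stroma with a trained SVM
#'
#' Computes pixel features for the whole image and labels every pixel nest
#' (1) or stroma (0) with the trained classifier.
#'
#' @param image `H x W x 3` RGB array.
#' @param classifier A `pixel_classifier` trained on [pixel_features()]
#'   output (class labels `nest` / `stroma`).
#' @param window Feature window; must match the training configuration.
#' @return Integer H x W tissue mask (1 = nest, 0 = stroma).
#' @export
classify_pixels <- function(image, classifier, window = 9L) {
  fa <- pixel_features(image, window)
  fm <- .flatten_features(fa)
  pred <- predict_pixels(classifier, fm)
  matrix(as.integer(pred == "nest"), dim(image)[1], dim(image)[2])
}

#' Morphological cleanup of a tissue mask
#'
#' Applies a morphological closing to the nest mask, then reassigns nest
#' components smaller than `min_region` to stroma and fills stroma holes
#' (enclosed within nests) smaller than `min_region`. An optional correction
#' mask, when supplied, replaces the result wherever it is not `NA` —
#' the reproducible stand-in for interactive expert editing.
#'
#' @param mask Integer H x W tissue mask (1 = nest, 0 = stroma).
#' @param min_region Minimum component size in px^2 (default 500).
#' @param closing_radius Disk radius of the closing element (default 3).
#' @param correction Optional H x W matrix of 0/1/`NA` overrides.
#' @return Cleaned integer tissue mask.
#' @export
postprocess_mask <- function(mask, min_region = 500, closing_radius = 3,
                             correction = NULL) {
  m <- mask > 0
  if (closing_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(closing_radius) + 1L, "disc")
    m <- .from_eb(EBImage::closing(.as_eb(m * 1), brush)) > 0.5
  }
  drop_small <- function(bin) {
    lab <- matrix(as.integer(round(.from_eb(EBImage::bwlabel(.as_eb(bin * 1))))),
                  nrow(bin), ncol(bin))
    if (max(lab) == 0L) return(bin)
    sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
    bin & !(lab %in% which(sizes < min_region))
  }
  m <- drop_small(m)                    # small nest specks -> stroma
  holes <- !m & !drop_small(!m)         # small stroma holes -> nest
  m <- m | holes
  out <- matrix(as.integer(m), nrow(mask), ncol(mask))
  if (!is.null(correction)) {
    ok <- !is.na(correction)
    out[ok] <- as.integer(correction[ok] > 0)
  }
  out
}

#' Train and apply the tissue classifier on one image
#'
#' Convenience wrapper: samples labeled pixels (from ground truth or a
#' supplied label mask), trains the SVM, classifies the image, and
#' post-processes the mask.
#'
#' @param image `H x W x 3` RGB array.
#' @param truth `ground_truth` (or any object with a `nest_mask` matrix)
#'   providing training labels.
#' @param n_per_class Training pixels per class (default 400).
#' @param window Feature window (default 9).
#' @param min_region,closing_radius Passed to [postprocess_mask()].
#' @param seed Integer seed for the pixel sample.
#' @return A list with `mask` (post-processed tissue mask), `raw_mask`,
#'   `classifier`.
#' @export
segment_tissue <- function(image, truth, n_per_class = 400, window = 9L,
                           min_region = 500, closing_radius = 3, seed = 1L) {
  px <- generate_labeled_pixels(truth, n_per_class, seed = seed)
  fa <- pixel_features(image, window)
  fm <- .flatten_features(fa)
  H <- dim(image)[1]
  idx <- (px$col - 1L) * H + px$row
  clf <- train_classifier(fm[idx, , drop = FALSE], px$label, seed = seed)
  pred <- predict_pixels(clf, fm)
  raw <- matrix(as.integer(pred == "nest"), H, dim(image)[2])
  list(
    mask = postprocess_mask(raw, min_region, closing_radius),
    raw_mask = raw,
    classifier = clf
  )
}

#' Dice overlap coefficient
#'
#' @param a,b Logical or 0/1 matrices of equal size.
#' @return `2|A∩B| / (|A| + |B|)`; 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  a <- a > 0; b <- b > 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Pseudo-color rendering of segmentation results
#'
#' Renders the five-class overview: nest regions yellow, stroma black,
#' epithelial nuclei red, stromal non-round nuclei green, stromal round
#' nuclei purple.
#'
#' @param tissue Integer tissue mask (1 = nest).
#' @param nuclei_labels Integer nucleus label matrix.
#' @param classes Character vector indexed by nucleus id with values
#'   `epithelial`, `stromal_round`, `stromal_nonround`.
#' @return `H x W x 3` RGB array in `[0, 255]`.
#' @export
render_pseudocolor <- function(tissue, nuclei_labels = NULL, classes = NULL) {
  H <- nrow(tissue); W <- ncol(tissue)
  img <- array(0, dim = c(H, W, 3L))
  nest <- tissue > 0
  img[, , 1][nest] <- 255
  img[, , 2][nest] <- 255
  if (!is.null(nuclei_labels) && !is.null(classes) && max(nuclei_labels) > 0) {
    pal <- rbind(
      epithelial = c(255, 0, 0),
      stromal_nonround = c(0, 255, 0),
      stromal_round = c(128, 0, 128)
    )
    pos <- which(nuclei_labels > 0)
    cls <- classes[nuclei_labels[pos]]
    ok <- !is.na(cls)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[pos[ok]] <- pal[cls[ok], ch]
      img[, , ch] <- plane
    }
  }
  img
}
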