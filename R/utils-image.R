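# Internal image helpers.
#
# Convention used throughout the package: an RGB image is a numeric array of
# dimension c(H, W, 3) with intensities in [0, 255], pixel (1,1) at the top
# left, rows indexing y. Label masks and stain maps are H x W matrices.
# EBImage stores images transposed (x, y[, c]) and scaled to [0, 1]; the two
# helpers below convert at the boundary.

.as_eb <- function(m) {
  if (length(dim(m)) == 2L) EBImage::Image(t(m)) else
    EBImage::Image(aperm(m, c(2L, 1L, 3L)), colormode = "Color")
}

.from_eb <- function(img) {
  d <- dim(img)
  a <- EBImage::imageData(img)
  if (length(d) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
}

.assert_rgb <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop(sprintf("`%s` must be an H x W x 3 array", arg), call. = FALSE)
  if (any(dim(image)[1:2] < 16L))
    stop(sprintf("`%s` must be at least 16 x 16 pixels", arg), call. = FALSE)
  invisible(image)
}

# Shift a matrix by (dr, dc) with edge replication.
.shift_replicate <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(pmax(seq_len(H) - dr, 1L), H)
  ci <- pmin(pmax(seq_len(W) - dc, 1L), W)
  m[ri, ci, drop = FALSE]
}

# Moving-window mean with edge replication (separable box filter).
.box_mean <- function(m, window) {
  r <- (window - 1L) %/% 2L
  acc <- matrix(0, nrow(m), ncol(m))
  for (d in -r:r) acc <- acc + .shift_replicate(m, d, 0L)
  acc <- acc / window
  out <- matrix(0, nrow(m), ncol(m))
  for (d in -r:r) out <- out + .shift_replicate(acc, 0L, d)
  out / window
}

# Sobel gradient magnitude of a matrix.
.gradient_magnitude <- function(m) {
  gx <- (.shift_replicate(m, 0, -1) - .shift_replicate(m, 0, 1)) * 2 +
    (.shift_replicate(m, -1, -1) - .shift_replicate(m, -1, 1)) +
    (.shift_replicate(m, 1, -1) - .shift_replicate(m, 1, 1))
  gy <- (.shift_replicate(m, -1, 0) - .shift_replicate(m, 1, 0)) * 2 +
    (.shift_replicate(m, -1, -1) - .shift_replicate(m, 1, -1)) +
    (.shift_replicate(m, -1, 1) - .shift_replicate(m, 1, 1))
  sqrt(gx^2 + gy^2) / 4
}

# Relabel a label matrix so positive labels are contiguous from 1.
.relabel <- function(labels) {
  u <- sort(unique(labels[labels > 0]))
  if (length(u) == 0L) return(labels)
  lut <- integer(max(u))
  lut[u] <- seq_along(u)
  out <- labels
  out[labels > 0] <- lut[labels[labels > 0]]
  out
}

.sample_seed <- function(seed, offset = 0L) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}
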