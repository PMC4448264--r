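#' Box-counting fractal dimension
#'
#' Estimates the fractal (box-counting) dimension of a pixel set: for each
#' box size `s` the plane is tiled with `s x s` boxes and the number `N(s)`
#' of boxes containing at least one foreground pixel is counted; the
#' dimension is the negative slope of the least-squares fit of `log N(s)`
#' against `log s`. For tumor-nest analysis the pixel set is the 8-connected
#' nest boundary (see [nest_boundary()]).
#'
#' @param mask Logical or 0/1 matrix of the pixel set.
#' @param box_sizes Integer vector of box sizes (>= 2 sizes); defaults to
#'   powers of 2 from 2 up to `min(dim(mask)) / 4`.
#' @return The estimated dimension (clamped to `[0, 2]`), or `NA` for an
#'   empty mask.
#' @export
#' @examples
#' line <- matrix(FALSE, 64, 64); line[32, ] <- TRUE
#' fractal_dimension(line)  # ~1
fractal_dimension <- function(mask, box_sizes = NULL) {
  pix <- which(mask > 0, arr.ind = TRUE)
  if (nrow(pix) == 0L) return(NA_real_)
  if (is.null(box_sizes)) {
    smax <- max(min(dim(mask)) %/% 4L, 2L)
    box_sizes <- 2^(1:floor(log2(smax)))
  }
  stopifnot(length(box_sizes) >= 2L)
  n_boxes <- vapply(box_sizes, function(s) {
    br <- (pix[, 1] - 1L) %/% s
    bc <- (pix[, 2] - 1L) %/% s
    length(unique(br * (max(bc) + 1L + 1L) + bc))
  }, 0L)
  fit <- stats::lm(log(n_boxes) ~ log(box_sizes))
  dim_est <- -unname(stats::coef(fit)[2])
  min(max(dim_est, 0), 2)
}

#' Extract the 8-connected boundary of a region mask
#'
#' Boundary pixels are foreground pixels with at least one background pixel
#' among their 8 neighbors (image edges count as interior).
#'
#' @param mask Logical or 0/1 matrix.
#' @return Logical matrix of boundary pixels.
#' @export
nest_boundary <- function(mask) {
  m <- mask > 0
  inner <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    inner <- inner & .shift_replicate(m, dr, dc)
  }
  m & !inner
}
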