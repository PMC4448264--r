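#' Delaunay triangulation statistics of a point set
#'
#' Triangulates nucleus centroids (Delaunay) and summarizes the spatial
#' arrangement: the sum of triangle areas (which equals the convex-hull area
#' of the point set), and the mean and population variance of the Delaunay
#' edge lengths.
#'
#' @param points A data frame / tibble with numeric columns `row` and `col`
#'   (pixel coordinates), or a two-column matrix.
#' @return A list with `area_sum`, `edge_mean`, `edge_var`, `n_triangles`,
#'   `n_edges`. All values are `NA` for fewer than 3 points or a degenerate
#'   (collinear) configuration.
#' @export
#' @examples
#' sq <- tibble::tibble(row = c(0, 0, 1, 1), col = c(0, 1, 0, 1))
#' delaunay_stats(sq)$area_sum  # 1
delaunay_stats <- function(points) {
  if (is.matrix(points)) points <- tibble::tibble(row = points[, 1], col = points[, 2])
  na_out <- list(area_sum = NA_real_, edge_mean = NA_real_,
                 edge_var = NA_real_, n_triangles = NA_integer_,
                 n_edges = NA_integer_)
  pts <- unique(points[, c("row", "col")])
  if (nrow(pts) < 3L) return(na_out)
  if (nrow(pts) == 3L) {  # a single triangle; deldir needs >= 4 points
    x <- unname(pts$col); y <- unname(pts$row)
    area <- abs((x[2] - x[1]) * (y[3] - y[1]) -
                  (x[3] - x[1]) * (y[2] - y[1])) / 2
    if (area < 1e-12) return(na_out)  # collinear
    el <- sqrt((x - x[c(2, 3, 1)])^2 + (y - y[c(2, 3, 1)])^2)
    return(list(area_sum = area, edge_mean = mean(el),
                edge_var = mean((el - mean(el))^2),
                n_triangles = 1L, n_edges = 3L))
  }
  tri <- tryCatch(
    suppressWarnings(deldir::deldir(pts$col, pts$row, suppressMsge = TRUE)),
    error = function(e) NULL
  )
  if (is.null(tri)) return(na_out)
  x <- pts$col; y <- pts$row
  seg <- tri$delsgs
  el <- sqrt((x[seg$ind1] - x[seg$ind2])^2 + (y[seg$ind1] - y[seg$ind2])^2)
  # areas from the triangle vertex indices and the original coordinates
  # (the coordinates deldir stores in its triangle list are rounded)
  tm <- tryCatch(deldir::triMat(tri), error = function(e) NULL)
  if (!is.matrix(tm) || nrow(tm) == 0L || ncol(tm) != 3L) {
    area_sum <- NA_real_; n_tri <- NA_integer_
  } else {
    area_sum <- sum(abs(
      (x[tm[, 2]] - x[tm[, 1]]) * (y[tm[, 3]] - y[tm[, 1]]) -
        (x[tm[, 3]] - x[tm[, 1]]) * (y[tm[, 2]] - y[tm[, 1]])) / 2)
    n_tri <- nrow(tm)
  }
  list(
    area_sum = area_sum,
    edge_mean = if (length(el)) mean(el) else NA_real_,
    edge_var = if (length(el)) mean((el - mean(el))^2) else NA_real_,
    n_triangles = n_tri,
    n_edges = length(el)
  )
}

#' Delaunay triangle-area sum
#'
#' The sum of Delaunay triangle areas over a centroid set — for epithelial
#' nuclei this is the "TNs cell Delaunay area sum" catalog parameter. Equals
#' the convex-hull area of the points.
#'
#' @inheritParams delaunay_stats
#' @return Area in px^2, or `NA` for degenerate input.
#' @export
delaunay_area_sum <- function(points) {
  delaunay_stats(points)$area_sum
}

# Mean nearest-neighbor distance of a point set (NA for < 2 points).
.nn_mean_distance <- function(points) {
  n <- nrow(points)
  if (n < 2L) return(NA_real_)
  d <- as.matrix(stats::dist(cbind(points$row, points$col)))
  diag(d) <- Inf
  mean(apply(d, 1L, min))
}
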