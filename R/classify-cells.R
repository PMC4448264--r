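#' Classify nuclei into epithelial and stromal populations
#'
#' Assigns every segmented nucleus to one of three classes by location and
#' shape: a nucleus whose centroid falls inside a tumor nest is epithelial;
#' stromal nuclei with eccentricity below `ecc_round_max` are round
#' (infiltrating immune cells), the rest are non-round (fibroblasts and
#' vascular cells, which the analysis pools).
#'
#' @param nuclei Tibble from [measure_objects()] (needs `id`, `row`, `col`,
#'   `eccentricity`).
#' @param tissue Integer H x W tissue mask (1 = nest, 0 = stroma).
#' @param ecc_round_max Eccentricity threshold for the round/non-round split,
#'   in `(0, 1)`; default 0.8.
#' @return An object of class `classified_nuclei`: list with `nuclei` (the
#'   input tibble plus a `class` column) and `counts` (named integer vector
#'   over the three classes; sums to `nrow(nuclei)`).
#' @export
#' @examples
#' tissue <- matrix(0L, 32, 32); tissue[1:16, ] <- 1L
#' nuc <- tibble::tibble(id = 1:2, row = c(8, 24), col = c(16, 16),
#'                       eccentricity = c(0.5, 0.95))
#' classify_nuclei(nuc, tissue)$counts
classify_nuclei <- function(nuclei, tissue, ecc_round_max = 0.8) {
  stopifnot(ecc_round_max > 0, ecc_round_max < 1)
  H <- nrow(tissue); W <- ncol(tissue)
  if (nrow(nuclei) > 0) {
    r <- round(nuclei$row); c <- round(nuclei$col)
    if (any(r < 1 | r > H | c < 1 | c > W))
      stop("nucleus centroid outside the image")
    in_nest <- tissue[cbind(r, c)] > 0
    cls <- ifelse(in_nest, "epithelial",
                  ifelse(nuclei$eccentricity < ecc_round_max,
                         "stromal_round", "stromal_nonround"))
  } else {
    cls <- character(0)
  }
  out <- dplyr::mutate(nuclei, class = cls)
  counts <- c(
    epithelial = sum(cls == "epithelial"),
    stromal_round = sum(cls == "stromal_round"),
    stromal_nonround = sum(cls == "stromal_nonround")
  )
  structure(list(nuclei = out, counts = counts), class = "classified_nuclei")
}
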