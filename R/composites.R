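#' Composite feature specification
#'
#' A named linear combination of catalog parameters. With
#' `standardize_inputs = TRUE` (the default) the parameters are z-scored
#' against cohort statistics before the coefficients are applied.
#'
#' @param name Composite name.
#' @param terms Tibble/data frame with columns `parameter` and `coefficient`
#'   (at least one term; parameters must be catalog names).
#' @param standardize_inputs Logical.
#' @return An object of class `composite_spec`.
#' @export
composite_spec <- function(name, terms, standardize_inputs = TRUE) {
  terms <- tibble::as_tibble(terms)
  stopifnot(nrow(terms) >= 1, all(c("parameter", "coefficient") %in% names(terms)))
  unknown <- setdiff(terms$parameter, feature_catalog()$name)
  if (length(unknown))
    stop("unknown catalog parameter(s): ", paste(unknown, collapse = ", "))
  structure(
    list(name = name, terms = terms,
         standardize_inputs = isTRUE(standardize_inputs)),
    class = "composite_spec"
  )
}

#' The printed tumor-nest composite feature
#'
#' The published linear combination quantifying tumor-nest architecture:
#' `0.260 x TNs number + 0.107 x TNs perimeter sum - 0.281 x TNs area
#' average - 0.272 x TNs area variance - 0.268 x TNs area/perimeter ratio`,
#' applied to standardized inputs.
#'
#' @return A `composite_spec`.
#' @export
tns_feature_spec <- function() {
  composite_spec("tns_feature", tibble::tribble(
    ~parameter, ~coefficient,
    "nest_area_count", 0.260,
    "nest_perimeter_sum", 0.107,
    "nest_area_mean", -0.281,
    "nest_area_var", -0.272,
    "tns_area_perimeter_ratio", -0.268
  ))
}

#' The printed tumor-nest nuclei composite feature
#'
#' The published linear combination quantifying cancer-cell nuclei:
#' `0.048 x eccentricity maximum + 0.482 x nuclei area average + 0.478 x
#' nuclei area variance + 0.246 x nuclei area/TNs area ratio`, applied to
#' standardized inputs.
#'
#' @return A `composite_spec`.
#' @export
tns_nuclei_feature_spec <- function() {
  composite_spec("tns_cell_nuclei_feature", tibble::tribble(
    ~parameter, ~coefficient,
    "epithelial_eccentricity_max", 0.048,
    "epithelial_area_mean", 0.482,
    "epithelial_area_var", 0.478,
    "tns_nuclei_area_ratio", 0.246
  ))
}

#' Evaluate a composite feature
#'
#' Computes `sum(coefficient * value)` per row of a feature table, after
#' optional z-standardization against supplied (or cohort-derived) means and
#' standard deviations.
#'
#' @param features Tibble with one row per image/patient containing the
#'   spec's parameters.
#' @param spec A [composite_spec()].
#' @param center,scale Optional named numeric vectors of cohort means and
#'   standard deviations for the standardization; when `NULL` they are taken
#'   from `features` itself.
#' @return Numeric vector, one value per row (`NA` where a term is missing).
#' @export
evaluate_composite <- function(features, spec, center = NULL, scale = NULL) {
  stopifnot(inherits(spec, "composite_spec"))
  pars <- spec$terms$parameter
  missing_par <- setdiff(pars, names(features))
  if (length(missing_par))
    stop("features lack parameter(s): ", paste(missing_par, collapse = ", "))
  x <- as.matrix(features[, pars, drop = FALSE])
  if (spec$standardize_inputs) {
    if (is.null(center)) center <- colMeans(x, na.rm = TRUE)
    if (is.null(scale)) scale <- apply(x, 2L, stats::sd, na.rm = TRUE)
    if (any(scale[pars] <= 0 | is.na(scale[pars])))
      stop("zero or undefined standard deviation for a composite term")
    x <- sweep(sweep(x, 2L, center[pars]), 2L, scale[pars], "/")
  }
  drop(x %*% spec$terms$coefficient)
}

#' Fit first-principal-component composites over parameter blocks
#'
#' For each block of parameters, z-standardizes the columns, takes the first
#' principal component, and returns its loadings as composite coefficients
#' (sign fixed so the largest-magnitude loading is positive). Constant
#' parameters are dropped with a warning.
#'
#' @param features Tibble of per-patient features (>= 3 rows).
#' @param blocks Named list of character vectors of parameter names. Default:
#'   the two published blocks (tumor-nest parameters; nuclei parameters).
#' @return A named list of `composite_spec` objects; each carries attributes
#'   `explained_variance` (fraction of block variance on PC1) and `center` /
#'   `scale` (the standardization statistics).
#' @export
fit_pca_composites <- function(features, blocks = NULL) {
  if (is.null(blocks)) {
    blocks <- list(
      tns_feature = c("nest_area_count", "nest_perimeter_sum",
                      "nest_area_mean", "nest_area_var",
                      "tns_area_perimeter_ratio"),
      tns_cell_nuclei_feature = c("epithelial_eccentricity_max",
                                  "epithelial_area_mean",
                                  "epithelial_area_var",
                                  "tns_nuclei_area_ratio")
    )
  }
  stopifnot(nrow(features) >= 3)
  purrr::imap(blocks, function(pars, nm) {
    x <- as.matrix(features[, pars, drop = FALSE])
    keep <- apply(x, 2L, function(v) stats::sd(v, na.rm = TRUE) > 0)
    if (!all(keep)) {
      warning("dropping constant parameter(s): ",
              paste(pars[!keep], collapse = ", "))
      x <- x[, keep, drop = FALSE]
      pars <- pars[keep]
    }
    cc <- stats::complete.cases(x)
    pc <- stats::prcomp(x[cc, , drop = FALSE], center = TRUE, scale. = TRUE)
    load <- pc$rotation[, 1]
    if (load[which.max(abs(load))] < 0) load <- -load
    spec <- composite_spec(nm, tibble::tibble(parameter = pars,
                                              coefficient = unname(load)))
    attr(spec, "explained_variance") <- pc$sdev[1]^2 / sum(pc$sdev^2)
    attr(spec, "center") <- pc$center
    attr(spec, "scale") <- pc$scale
    spec
  })
}

#' @export
print.composite_spec <- function(x, ...) {
  cat("<composite_spec>", x$name,
      if (x$standardize_inputs) "(standardized inputs)" else "(raw inputs)", "\n")
  print(x$terms)
  invisible(x)
}
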