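# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Cox fit into the published table layout
#'
#' One row per covariate with the coefficient, hazard ratio, Wald 95%
#' confidence interval and p-value (`hazard_ratio = exp(coefficient)`
#' exactly).
#'
#' @param x A `cox_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `coefficient`, `hazard_ratio`,
#'   `conf_low`, `conf_high`, `p_value`.
#' @export
tidy.cox_fit <- function(x, ...) {
  s <- summary(x$fit)
  co <- s$coefficients
  tibble::tibble(
    term = rownames(co),
    coefficient = co[, "coef"],
    hazard_ratio = exp(co[, "coef"]),
    conf_low = s$conf.int[, "lower .95"],
    conf_high = s$conf.int[, "upper .95"],
    p_value = co[, "Pr(>|z|)"]
  )
}

#' @rdname tidy.cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    n = x$fit$n, n_events = x$fit$nevent,
    loglik = x$fit$loglik[2],
    concordance = unname(s$concordance["C"]),
    converged = x$converged, flagged = x$flagged
  )
}

#' Tidy Kaplan-Meier curves
#'
#' @param x A `km_fit`.
#' @param ... Unused.
#' @return Tibble of curve coordinates: `group`, `time`, `n_risk`,
#'   `n_event`, `survival`, with the `S(0) = 1` anchor per group.
#' @export
tidy.km_fit <- function(x, ...) {
  f <- x$fit
  grp <- if (is.null(f$strata)) rep(x$medians$group[1], length(f$time)) else
    rep(sub("^group=", "", names(f$strata)), f$strata)
  curves <- tibble::tibble(
    group = grp, time = f$time, n_risk = f$n.risk,
    n_event = f$n.event, survival = f$surv
  )
  anchor <- tibble::tibble(
    group = unique(grp), time = 0, n_risk = NA_real_, n_event = 0,
    survival = 1
  )
  dplyr::arrange(dplyr::bind_rows(anchor, curves), .data$group, .data$time)
}

#' @rdname tidy.km_fit
#' @export
glance.km_fit <- function(x, ...) {
  tibble::tibble(n_groups = x$n_groups, chisq = x$chisq, df = x$df,
                 p_value = x$p_value)
}

#' Plot Kaplan-Meier curves
#'
#' @param object A `km_fit`.
#' @param ... Unused.
#' @return A ggplot of the per-group step curves.
#' @export
autoplot.km_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$survival,
                                  color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  color = "Group") +
    ggplot2::theme_minimal()
}

#' Display an RGB array or segmentation mask with ggplot2
#'
#' @param image `H x W x 3` RGB array in `[0, 255]`, or an H x W matrix
#'   (rendered in grayscale / as labels).
#' @return A ggplot raster plot.
#' @export
plot_image <- function(image) {
  if (length(dim(image)) == 3L) {
    H <- dim(image)[1]; W <- dim(image)[2]
    cols <- grDevices::rgb(image[, , 1], image[, , 2], image[, , 3],
                           maxColorValue = 255)
    d <- tidyr::expand_grid(row = seq_len(H), col = seq_len(W))
    d <- dplyr::arrange(d, .data$col, .data$row)
    d$fill <- as.vector(cols)
  } else {
    H <- nrow(image); W <- ncol(image)
    v <- as.vector(image) / max(max(image), 1)
    d <- tidyr::expand_grid(col = seq_len(W), row = seq_len(H))
    d$fill <- grDevices::gray(1 - v[(d$col - 1L) * H + d$row])
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$fill)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
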