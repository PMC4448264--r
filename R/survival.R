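# Survival stage: cutpoint optimization, Kaplan-Meier / log-rank, Cox,
# ROC, NPI, Spearman screening.

# k-group log-rank chi-square (the same statistic survival::survdiff
# computes). Used directly by the exhaustive cutpoint search, where calling
# survdiff tens of thousands of times would dominate the runtime; agreement
# with survdiff is asserted in the test suite.
.logrank_chisq <- function(group, time, event) {
  group <- as.integer(group)
  k <- max(group)
  if (k < 2L) return(NA_real_)
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]; g_s <- group[ord]
  n <- length(t_s)
  ut <- unique(t_s[e_s == 1])
  if (!length(ut)) return(0)
  # at-risk counts per group at each event time; events per group/time
  O <- numeric(k); E <- numeric(k)
  V <- matrix(0, k, k)
  first_idx <- match(ut, t_s)          # first subject with time >= t (sorted)
  # counts of subjects with time >= t per group via reverse cumulated tables
  cum <- apply(outer(g_s, 1:k, "=="), 2L, function(z) rev(cumsum(rev(z))))
  for (i in seq_along(ut)) {
    at <- t_s == ut[i]
    d_j <- vapply(1:k, function(j) sum(e_s[at] & g_s[at] == j), 0)
    d <- sum(d_j)
    n_j <- cum[first_idx[i], ]
    nn <- sum(n_j)
    if (nn <= 1) next
    O <- O + d_j
    E <- E + d * n_j / nn
    f <- d * (nn - d) / (nn - 1)
    V <- V + f * (diag(n_j / nn) - tcrossprod(n_j / nn))
  }
  x <- (O - E)[-k]
  Vm <- V[-k, -k, drop = FALSE]
  qr_v <- tryCatch(solve(Vm, x), error = function(e) NULL)
  if (is.null(qr_v)) return(NA_real_)
  drop(x %*% qr_v)
}

#' Optimal three-group survival cutpoints
#'
#' Converts a continuous feature into three risk categories by exhaustive
#' search over all ordered pairs of cutpoints placed at midpoints between
#' consecutive observed values, selecting the pair that maximizes the
#' three-group log-rank chi-square, subject to each group containing at
#' least `min_group_frac` of the patients. This mirrors cutpoint
#' optimization as popularized by the X-tile tool. The selected statistic is
#' optimistically biased (it is a maximum over many tests); the returned
#' `p_value` is the naive chi-square tail and `p_corrected` is a
#' Miller-Siegmund-style correction for the maximal selection (approximate
#' for the two-cutpoint case).
#'
#' @param data Data frame with the feature and survival columns.
#' @param feature Name of the continuous feature column.
#' @param time,event Names of the survival time (months) and event (0/1)
#'   columns.
#' @param min_group_frac Minimum group share in `(0, 1/3)`; default 0.10.
#' @return An object of class `cutpoint_rule`: list with `feature`,
#'   `cutpoints` (c1 < c2), `statistic`, `p_value`, `p_corrected`,
#'   `n_candidates`.
#' @export
find_cutpoints <- function(data, feature, time = "time", event = "event",
                           min_group_frac = 0.10) {
  stopifnot(min_group_frac > 0, min_group_frac < 1 / 3)
  v <- data[[feature]]; tt <- data[[time]]; ev <- data[[event]]
  ok <- stats::complete.cases(v, tt, ev)
  v <- v[ok]; tt <- tt[ok]; ev <- ev[ok]
  u <- sort(unique(v))
  if (length(u) < 3L) stop("insufficient spread: fewer than 3 distinct values")
  mids <- (u[-1] + u[-length(u)]) / 2
  n <- length(v)
  min_n <- ceiling(min_group_frac * n)
  # group sizes for each candidate cut via the empirical CDF
  below <- vapply(mids, function(m) sum(v < m), 0L)
  best <- list(stat = -Inf)
  n_cand <- 0L
  for (i in seq_along(mids)) {
    if (below[i] < min_n) next
    for (j in seq_along(mids)) {
      if (j <= i) next
      if (below[j] - below[i] < min_n) next
      if (n - below[j] < min_n) next
      g <- findInterval(v, c(mids[i], mids[j])) + 1L
      s <- .logrank_chisq(g, tt, ev)
      n_cand <- n_cand + 1L
      if (!is.na(s) && s > best$stat) best <- list(stat = s, c1 = mids[i], c2 = mids[j])
    }
  }
  if (!is.finite(best$stat)) stop("insufficient spread: no feasible cutpoint pair")
  z <- sqrt(max(best$stat, 1e-12))
  eps <- min_group_frac
  ms <- stats::dnorm(z) * (z - 1 / z) * log((1 - eps)^2 / eps^2) +
    4 * stats::dnorm(z) / z
  structure(
    list(
      feature = feature,
      cutpoints = c(best$c1, best$c2),
      statistic = best$stat,
      p_value = stats::pchisq(best$stat, df = 2, lower.tail = FALSE),
      p_corrected = min(max(ms, stats::pchisq(best$stat, 2, lower.tail = FALSE)), 1),
      n_candidates = n_cand
    ),
    class = "cutpoint_rule"
  )
}

#' Apply a categorization rule
#'
#' @param values Numeric vector.
#' @param rule A `cutpoint_rule` (or a numeric vector of two cutpoints).
#' @return Integer categories 1, 2, 3.
#' @export
categorize <- function(values, rule) {
  cp <- if (inherits(rule, "cutpoint_rule")) rule$cutpoints else rule
  stopifnot(length(cp) == 2L, cp[1] < cp[2])
  findInterval(values, cp) + 1L
}

#' Kaplan-Meier curves with log-rank test
#'
#' Product-limit survival estimates per group with the k-group log-rank
#' test and per-group median survival (the first time the curve drops to or
#' below 0.5; undefined if never reached).
#'
#' @param data Data frame.
#' @param group Name of the grouping column.
#' @param time,event Names of the survival columns.
#' @return An object of class `km_fit`: list with `fit` (a
#'   [survival::survfit] object), `chisq`, `df`, `p_value`, `medians`
#'   (tibble of group, n, events, median), `n_groups`.
#' @export
km_logrank <- function(data, group, time = "time", event = "event") {
  g <- data[[group]]
  if (!is.factor(g)) g <- factor(g)
  if (any(table(g) == 0) || nlevels(g) < 1)
    stop("every group must contain at least one subject")
  df <- data.frame(time = data[[time]], event = data[[event]], group = g)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  if (nlevels(g) >= 2) {
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
    chisq <- sd_$chisq
    dfree <- nlevels(g) - 1L
    p <- stats::pchisq(chisq, dfree, lower.tail = FALSE)
  } else {
    chisq <- NA_real_; dfree <- 0L; p <- NA_real_
  }
  tab <- summary(fit)$table
  if (is.null(dim(tab))) tab <- t(as.matrix(tab))
  medians <- tibble::tibble(
    group = levels(g),
    n = as.numeric(tab[, "records"]),
    events = as.numeric(tab[, "events"]),
    median = as.numeric(tab[, "median"])
  )
  structure(
    list(fit = fit, chisq = chisq, df = dfree, p_value = p,
         medians = medians, n_groups = nlevels(g)),
    class = "km_fit"
  )
}

#' @export
print.km_fit <- function(x, ...) {
  cat("<km_fit>", x$n_groups, "group(s); log-rank chi-square =",
      signif(x$chisq, 4), "df =", x$df, "p =", signif(x$p_value, 3), "\n")
  print(x$medians)
  invisible(x)
}

#' Multivariate Cox proportional hazards fit
#'
#' Partial-likelihood Cox regression (Efron tie handling) over the given
#' covariates, with Wald 95% confidence intervals. Requires at least 10
#' events and no constant covariate; non-convergence or separation
#' (diverging coefficients) is flagged, never silently returned.
#'
#' @param data Data frame of patient records.
#' @param covariates Character vector of covariate column names.
#' @param time,event Names of the survival columns.
#' @return An object of class `cox_fit` wrapping the
#'   [survival::coxph] fit, with `converged` and `flagged` fields.
#' @export
cox_fit <- function(data, covariates, time = "time", event = "event") {
  stopifnot(length(covariates) >= 1)
  if (sum(data[[event]]) < 10) stop("need at least 10 events")
  for (cv in covariates) {
    if (stats::sd(as.numeric(data[[cv]]), na.rm = TRUE) == 0)
      stop("constant covariate: ", cv)
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time, ", ", event, ") ~ ",
    paste(covariates, collapse = " + ")
  ))
  warn <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = "efron"),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  converged <- is.finite(fit$loglik[2]) && !any(is.na(stats::coef(fit))) &&
    !any(grepl("did not converge|infinite", warn))
  separated <- any(abs(stats::coef(fit)) > 10, na.rm = TRUE)
  structure(
    list(fit = fit, converged = converged, flagged = !converged || separated,
         warnings = warn, covariates = covariates),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  if (x$flagged) cat("NOTE: fit flagged (non-convergence or separation)\n")
  print(tidy(x))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Trapezoidal AUC (equivalently the concordance probability between a
#' positive and a negative subject) with a DeLong rank-based 95% CI.
#'
#' @param data Data frame.
#' @param score Name of the continuous score column.
#' @param outcome Name of the binary outcome column (0/1).
#' @return A tibble with `auc`, `conf_low`, `conf_high`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(data, score, outcome) {
  y <- data[[outcome]]
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  r <- pROC::roc(response = y, predictor = data[[score]],
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- suppressWarnings(pROC::ci.auc(r, conf.level = 0.95, method = "delong"))
  tibble::tibble(
    auc = as.numeric(pROC::auc(r)),
    conf_low = as.numeric(ci[1]), conf_high = as.numeric(ci[3]),
    n_pos = sum(y == 1), n_neg = sum(y == 0)
  )
}

#' Nottingham Prognostic Index
#'
#' `NPI = 0.2 x tumor size (cm) + lymph-node stage (1-3) + histologic grade
#' (1-3)`, with the conventional three risk categories (<= 2.8; 2.8-4.4;
#' > 4.4).
#'
#' @param size_cm Tumor size in centimeters (>= 0).
#' @param ln_stage Lymph-node stage, 1, 2 or 3.
#' @param grade Histologic grade, 1, 2 or 3.
#' @return Numeric NPI scores.
#' @export
#' @examples
#' npi_score(2.0, 1, 2)  # 3.4
npi_score <- function(size_cm, ln_stage, grade) {
  if (any(size_cm < 0)) stop("size_cm must be nonnegative")
  if (!all(ln_stage %in% 1:3)) stop("ln_stage must be 1, 2 or 3")
  if (!all(grade %in% 1:3)) stop("grade must be 1, 2 or 3")
  0.2 * size_cm + ln_stage + grade
}

#' @rdname npi_score
#' @param npi Numeric NPI scores.
#' @export
npi_category <- function(npi) {
  findInterval(npi, c(2.8, 4.4), left.open = TRUE) + 1L
}

#' Spearman correlation screen
#'
#' Rank correlations between each image feature and histologic grade (the
#' multicollinearity check before the Cox model), plus the feature-feature
#' rank-correlation matrix.
#'
#' @param data Data frame.
#' @param features Character vector of feature column names.
#' @param grade Name of the ordinal grade column.
#' @return List with `feature_grade` (tibble: feature, rho, p_value) and
#'   `rho_matrix` (feature-feature Spearman correlations).
#' @export
spearman_screen <- function(data, features, grade = "grade") {
  stopifnot(nrow(data) >= 3)
  fg <- purrr::map_dfr(features, function(f) {
    v <- data[[f]]
    if (stats::sd(v, na.rm = TRUE) == 0) {
      return(tibble::tibble(feature = f, rho = NA_real_, p_value = NA_real_))
    }
    ct <- suppressWarnings(
      stats::cor.test(v, as.numeric(data[[grade]]), method = "spearman",
                      exact = FALSE)
    )
    tibble::tibble(feature = f, rho = unname(ct$estimate),
                   p_value = ct$p.value)
  })
  rho <- suppressWarnings(
    stats::cor(as.matrix(data[, features, drop = FALSE]),
               method = "spearman", use = "pairwise.complete.obs")
  )
  list(feature_grade = fg, rho_matrix = rho)
}
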