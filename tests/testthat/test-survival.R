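test_that("the search statistic equals survdiff on random group assignments", {
  set.seed(8)
  for (i in 1:10) {
    n <- 40
    tt <- rexp(n); ev <- rbinom(n, 1, 0.7)
    g <- sample(1:3, n, replace = TRUE)
    if (length(unique(g)) < 2) next
    expect_equal(nestquant:::.logrank_chisq(g, tt, ev),
                 survival::survdiff(survival::Surv(tt, ev) ~ g)$chisq,
                 tolerance = 1e-10)
  }
})

test_that("log-rank matches the hand-worked toy table", {
  toy <- toy_survival()
  # hand computation: O1 = 4, E1 = 107/72, V = 0.8701775 -> chisq 7.2625
  km <- km_logrank(toy, "group")
  expect_equal(km$chisq, 7.2625, tolerance = 1e-3)
  expect_equal(km$df, 1L)
  # identical groups: statistic ~ 0
  dup <- rbind(toy, toy); dup$group <- rep(c(1, 2), each = 10)
  dup$time <- rep(toy$time, 2); dup$event <- rep(toy$event, 2)
  expect_lt(km_logrank(dup, "group")$chisq, 1e-10)
})

test_that("single-group product-limit estimate matches hand computation", {
  d <- data.frame(time = c(1, 2, 3, 4), event = 1, g = 1)
  km <- km_logrank(d, "g")
  cur <- tidy(km)
  s_at <- function(t) cur$survival[max(which(cur$time <= t))]
  expect_equal(s_at(2.5), 0.5)   # 4/4 * 3/4 * 2/3 ... at t in [2,3): 0.5
  expect_equal(s_at(0), 1)       # S(0) = 1
  expect_true(all(diff(cur$survival) <= 1e-12))  # nonincreasing
  expect_equal(km$medians$median, 2.5)
  expect_error(km_logrank(data.frame(time = 1, event = 1,
                                     g = factor("a", levels = c("a", "b"))), "g"),
               "at least one subject")
})

test_that("log-rank is invariant under monotone time transformations", {
  toy <- toy_survival()
  a <- km_logrank(toy, "group")$chisq
  toy2 <- toy; toy2$time <- exp(toy$time / 3)
  expect_equal(km_logrank(toy2, "group")$chisq, a, tolerance = 1e-10)
})

test_that("cutpoint search finds the gap and equals the exhaustive survdiff oracle", {
  set.seed(4)
  n <- 30
  x <- c(runif(15, 0, 1), runif(15, 3, 4))       # value gap at (1, 3)
  tt <- c(rexp(15, 1), rexp(15, 0.05))           # early events vs late
  d <- data.frame(x = x, time = tt, event = 1)
  cp <- find_cutpoints(d, "x", min_group_frac = 0.1)
  expect_true(any(cp$cutpoints > 1 & cp$cutpoints < 3))

  # independent oracle: brute-force over the same midpoint grid with survdiff
  oracle <- function(d, min_frac) {
    u <- sort(unique(d$x)); mids <- (u[-1] + u[-length(u)]) / 2
    best <- c(-Inf, NA, NA); n <- nrow(d); mn <- ceiling(min_frac * n)
    for (i in seq_along(mids)) for (j in seq_along(mids)) {
      if (j <= i) next
      g <- cut(d$x, c(-Inf, mids[i], mids[j], Inf), labels = FALSE)
      if (min(table(factor(g, 1:3))) < mn) next
      s <- survival::survdiff(survival::Surv(time, event) ~ g, data = d)$chisq
      if (s > best[1]) best <- c(s, mids[i], mids[j])
    }
    best
  }
  for (seed in c(1, 2)) {
    set.seed(seed)
    n <- 50
    dd <- data.frame(x = rnorm(n), time = rexp(n, 0.1), event = rbinom(n, 1, 0.8))
    got <- find_cutpoints(dd, "x", min_group_frac = 0.1)
    ref <- oracle(dd, 0.1)
    expect_equal(got$statistic, ref[1], tolerance = 1e-8)
    expect_equal(got$cutpoints, ref[2:3], tolerance = 1e-12)
  }
  expect_error(find_cutpoints(data.frame(x = rep(1, 20), time = 1:20,
                                         event = 1), "x"),
               "insufficient spread")
})

test_that("uncorrected cutpoint selection inflates the type-I error", {
  set.seed(99)
  p_raw <- p_cor <- numeric(40)
  for (i in 1:40) {
    d <- data.frame(x = rnorm(40), time = rexp(40, 0.1),
                    event = rbinom(40, 1, 0.8))
    cp <- find_cutpoints(d, "x")
    p_raw[i] <- cp$p_value
    p_cor[i] <- cp$p_corrected
  }
  # the naive p-value of the selected split rejects far too often
  expect_gt(mean(p_raw < 0.05), 0.15)
  expect_true(all(p_cor >= p_raw))
})

test_that("categorization is exhaustive and ordered", {
  v <- c(-1, 0.5, 2, 10)
  expect_equal(categorize(v, c(0, 1)), c(1L, 2L, 3L, 3L))
})

test_that("Cox recovers known effects and reports HR = exp(coef)", {
  est <- vapply(1:3, function(s) {
    coh <- generate_cohort(cohort_scenario(n_patients = 1000,
                                           betas = c(x = 0.5), seed = s))
    unname(coef(cox_fit(coh$patients, "x")$fit))
  }, 0)
  expect_true(all(est > 0.35 & est < 0.65))
  coh <- generate_cohort(cohort_scenario(n_patients = 400,
                                         betas = c(x = 0.5), seed = 5))
  fit <- cox_fit(coh$patients, c("x", "grade"))
  td <- tidy(fit)
  expect_equal(td$hazard_ratio, exp(td$coefficient))
  expect_true(all(td$conf_low <= td$conf_high))
  gl <- glance(fit)
  expect_equal(gl$n, 400L)
  expect_false(gl$flagged)
  expect_error(cox_fit(coh$patients[1:8, ], "x"), "10 events")
  expect_error(cox_fit(dplyr::mutate(coh$patients, z = 1), "z"), "constant")
})

test_that("null covariates are inside two standard errors most of the time", {
  hits <- vapply(1:60, function(s) {
    coh <- generate_cohort(cohort_scenario(n_patients = 500, betas = c(x = 0),
                                           seed = 100 + s))
    sm <- summary(cox_fit(coh$patients, "x")$fit)$coefficients
    abs(sm[1, "coef"]) < 2 * sm[1, "se(coef)"]
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("AUC equals brute-force pairwise concordance and behaves at the extremes", {
  set.seed(12)
  d <- data.frame(score = rnorm(20), outcome = rbinom(20, 1, 0.5))
  while (length(unique(d$outcome)) < 2) d$outcome <- rbinom(20, 1, 0.5)
  got <- roc_auc(d, "score", "outcome")$auc
  pos <- d$score[d$outcome == 1]; neg <- d$score[d$outcome == 0]
  conc <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  expect_equal(got, conc, tolerance = 1e-12)
  # perfect separation
  d2 <- data.frame(score = c(1:10, 21:30), outcome = rep(0:1, each = 10))
  expect_equal(roc_auc(d2, "score", "outcome")$auc, 1.0)
  # random scores, balanced n = 2000
  d3 <- data.frame(score = rnorm(2000), outcome = rep(0:1, 1000))
  expect_equal(roc_auc(d3, "score", "outcome")$auc, 0.5, tolerance = 0.03)
  expect_error(roc_auc(data.frame(score = 1:5, outcome = 1), "score", "outcome"),
               "both outcome classes")
})

test_that("NPI formula and categories match the printed convention", {
  expect_equal(npi_score(2.0, 1, 2), 3.4)
  expect_equal(npi_category(npi_score(2.0, 1, 2)), 2L)
  expect_equal(npi_score(0, 1, 1), 2.0)
  expect_equal(npi_category(2.0), 1L)
  expect_equal(npi_score(5.0, 3, 3), 7.0)
  expect_equal(npi_category(7.0), 3L)
  expect_error(npi_score(2, 4, 2), "ln_stage")
  expect_error(npi_score(2, 1, 0), "grade")
})

test_that("Spearman screening equals the rank-transform oracle", {
  d <- data.frame(grade = c(1, 1, 2, 2, 2, 2, 3, 3, 1, 2))
  d$f_same <- d$grade
  d$f_rev <- -d$grade
  set.seed(2); d$f_noise <- rnorm(10)
  out <- spearman_screen(d, c("f_same", "f_rev", "f_noise"))
  expect_equal(out$feature_grade$rho[1], 1.0)
  expect_equal(out$feature_grade$rho[2], -1.0)
  # oracle: Pearson correlation of ranks
  oracle <- cor(rank(d$f_noise), rank(d$grade))
  expect_equal(out$feature_grade$rho[3], oracle, tolerance = 1e-12)
  expect_equal(out$rho_matrix["f_same", "f_rev"], -1.0)
})
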