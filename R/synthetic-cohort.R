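#' Synthetic survival cohort scenario
#'
#' Parameters for the synthetic patient-cohort generator. Defaults follow the
#' study design this package re-implements: 230 patients with 5 images per
#' slide, 8-year disease-free survival (96-month administrative cap), a
#' constant baseline hazard of `log(2) / 50.1` per month (median survival
#' 50.1 months under the null), and a censoring share of 0.339 (66.1% events
#' at the end of follow-up).
#'
#' @param n_patients Number of patients (>= 2).
#' @param images_per_patient Images captured per slide (default 5).
#' @param betas Named numeric vector of log-hazard coefficients; names define
#'   the generated features. May be empty (null model).
#' @param feature_types Named character vector, `"normal"` (standard normal)
#'   or `"binary"` (Bernoulli 0.5) per feature; defaults to `"normal"`.
#' @param baseline_hazard Events per month under the null (> 0).
#' @param censor_rate Fraction in `[0, 1]` controlling random loss to
#'   follow-up; 0 disables random censoring (the administrative cap still
#'   applies).
#' @param follow_up_max Administrative censoring time in months; may be
#'   `Inf`.
#' @param seed Integer seed.
#' @return An object of class `cohort_scenario`.
#' @export
cohort_scenario <- function(n_patients = 230, images_per_patient = 5,
                            betas = c(tns_feature = 0.283),
                            feature_types = NULL,
                            baseline_hazard = log(2) / 50.1,
                            censor_rate = 0.339,
                            follow_up_max = 96,
                            seed = 1L) {
  stopifnot(n_patients >= 2, images_per_patient >= 1,
            baseline_hazard > 0, censor_rate >= 0, censor_rate <= 1,
            follow_up_max > 0)
  if (length(betas) && is.null(names(betas)))
    stop("betas must be a named vector")
  ft <- stats::setNames(rep("normal", length(betas)), names(betas))
  if (!is.null(feature_types)) {
    bad <- setdiff(names(feature_types), names(betas))
    if (length(bad)) stop("feature_types names must match betas")
    ft[names(feature_types)] <- feature_types
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      images_per_patient = as.integer(images_per_patient),
      betas = betas, feature_types = ft,
      baseline_hazard = baseline_hazard,
      censor_rate = censor_rate, follow_up_max = follow_up_max,
      seed = as.integer(seed)
    ),
    class = "cohort_scenario"
  )
}

#' Generate a synthetic survival cohort
#'
#' Draws a patient table with feature-dependent exponential event times:
#' each patient's hazard is `baseline_hazard * exp(sum(beta * feature))`,
#' random censoring is exponential with rate chosen so that under the null a
#' fraction `censor_rate` of subjects are censored before their event, and
#' everything is capped at `follow_up_max` months. Clinical covariates
#' (tumor size, lymph-node stage, grade, ER, HER2) are drawn from the
#' marginal frequencies of the study population and are independent of the
#' generated features.
#'
#' @param scenario A [cohort_scenario()].
#' @return An object of class `cohort`: a list with
#'   \describe{
#'     \item{patients}{Tibble with `patient_id`, one column per feature
#'       named in `betas`, `time` (months), `event` (0/1), `tumor_size_cm`,
#'       `t_stage`, `ln_stage`, `n_stage`, `grade`, `er`, `her2`.}
#'     \item{images}{Tibble of image slots: `patient_id`, `image_id`,
#'       `image_seed` (one row per captured image).}
#'     \item{scenario}{The generating scenario.}
#'   }
#' @export
#' @examples
#' coh <- generate_cohort(cohort_scenario(n_patients = 20, seed = 5))
#' nrow(coh$images)  # 100 image slots
generate_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  withr::with_seed(scenario$seed, .draw_cohort(scenario))
}

.draw_cohort <- function(sc) {
  n <- sc$n_patients
  feats <- lapply(names(sc$betas), function(f) {
    if (sc$feature_types[[f]] == "binary") stats::rbinom(n, 1L, 0.5)
    else stats::rnorm(n)
  })
  names(feats) <- names(sc$betas)
  lp <- rep(0, n)
  for (f in names(sc$betas)) lp <- lp + sc$betas[[f]] * feats[[f]]
  rate <- sc$baseline_hazard * exp(lp)
  t_event <- stats::rexp(n, rate)
  t_cens <- if (sc$censor_rate > 0) {
    cens_rate <- sc$baseline_hazard * sc$censor_rate / (1 - sc$censor_rate)
    stats::rexp(n, cens_rate)
  } else rep(Inf, n)
  t_obs <- pmin(t_event, t_cens, sc$follow_up_max)
  event <- as.integer(t_event <= pmin(t_cens, sc$follow_up_max))
  t_obs <- pmax(t_obs, 0.01)  # survival times strictly positive

  size <- round(pmin(pmax(stats::rlnorm(n, log(2.5), 0.45), 0.3), 12), 1)
  ln_stage <- sample(1:3, n, replace = TRUE, prob = c(0.46, 0.33, 0.21))
  grade <- sample(1:3, n, replace = TRUE, prob = c(0.087, 0.757, 0.156))
  patients <- tibble::tibble(patient_id = seq_len(n), !!!feats) |>
    dplyr::mutate(
      time = t_obs, event = event,
      tumor_size_cm = size,
      t_stage = cut(size, c(-Inf, 2, 5, Inf), labels = FALSE),
      ln_stage = ln_stage,
      n_stage = ln_stage,
      grade = grade,
      er = stats::rbinom(n, 1L, 0.457),
      her2 = stats::rbinom(n, 1L, 0.361)
    )
  images <- tidyr::expand_grid(
    patient_id = seq_len(n),
    image_no = seq_len(sc$images_per_patient)
  ) |>
    dplyr::mutate(
      image_id = sprintf("p%03d_img%d", patient_id, image_no),
      image_seed = .sample_seed(sc$seed, patient_id * 131L + image_no)
    ) |>
    dplyr::select("patient_id", "image_id", "image_seed")
  structure(list(patients = patients, images = images, scenario = sc),
            class = "cohort")
}
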