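#' Pipeline configuration
#'
#' Collects every tunable default of the end-to-end pipeline in one
#' validated, hashable object. Unknown keys are rejected.
#'
#' @param ... Overrides of the defaults listed below.
#' @return An object of class `pipeline_config`.
#' @details Defaults: contrast percentiles `p_low = 1`, `p_high = 99`;
#'   nuclei morphology radius 2 px, marker depth `h = NULL` (10% of OD
#'   range), smoothing sigma 2 px, spurious-region rules from
#'   [spurious_rules()]; tissue window 9 px, 400 training pixels per class,
#'   post-processing `min_region = 500` px^2 and `closing_radius = 3` px;
#'   round/non-round eccentricity threshold 0.8; composite mode `"printed"`;
#'   cutpoint minimum group share 0.10; survival features: the two composite
#'   features plus TNs cell density and the stromal cell structure
#'   parameter; Cox covariates: the categorized features plus T, N, grade,
#'   ER, HER2; `seed = 1`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    p_low = 1, p_high = 99,
    morphology_radius = 2, od_threshold = NULL, h = NULL, smooth_sigma = 2,
    rules = spurious_rules(),
    window = 9L, n_per_class = 400L, min_region = 500, closing_radius = 3,
    ecc_round_max = 0.8,
    composite_mode = "printed",
    min_group_frac = 0.10,
    survival_features = c("tns_feature", "tns_cell_nuclei_feature",
                          "tns_cell_density", "stromal_cell_structure"),
    clinical_covariates = c("t_stage", "n_stage", "grade", "er", "her2"),
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  stopifnot(defaults$composite_mode %in% c("printed", "pca"))
  structure(defaults, class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s': %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full image-to-survival pipeline
#'
#' Orchestrates the whole analysis on a synthetic study: generates (or
#' accepts) a cohort, renders each patient's images, preprocesses them,
#' segments nuclei (marker-controlled watershed) and tumor nests vs stroma
#' (pixel-wise SVM, self-trained per image from ground-truth pixel labels),
#' classifies nuclei, extracts the 730-parameter catalog per image,
#' aggregates to patients, builds composite features, categorizes them by
#' cutpoint optimization and runs Kaplan-Meier/log-rank, Cox and ROC
#' analyses. A manifest with a content hash makes reruns verifiable.
#'
#' @param image_scenario An [image_scenario()] template; each image slot is
#'   rendered from it with its own derived seed.
#' @param cohort A [cohort_scenario()], a `cohort` object, or `NULL` for an
#'   image-only run (`n_images` images are produced and the survival stage
#'   is skipped with a notice).
#' @param config A [pipeline_config()].
#' @param n_images Number of images for an image-only run (default 5).
#' @return An object of class `nestquant_result`: list with
#'   `features_image`, `features_patient`, `composite_specs`, `cutpoints`,
#'   `km`, `cox`, `roc`, `cohort`, `manifest` (including `manifest$hash`).
#' @export
run_pipeline <- function(image_scenario = nestquant::image_scenario(),
                         cohort = NULL,
                         config = pipeline_config(),
                         n_images = 5L) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(cohort, "cohort_scenario"))
    cohort <- .stage("cohort", generate_cohort(cohort))
  if (!is.null(cohort) && !inherits(cohort, "cohort"))
    stop("cohort must be a cohort_scenario, a cohort, or NULL")

  slots <- if (is.null(cohort)) {
    tibble::tibble(
      patient_id = NA_integer_,
      image_id = sprintf("img%03d", seq_len(n_images)),
      image_seed = vapply(seq_len(n_images),
                          function(i) .sample_seed(config$seed, 977L * i), 0)
    )
  } else cohort$images

  feats <- .stage("image_analysis", purrr::pmap_dfr(
    slots,
    function(patient_id, image_id, image_seed) {
      sc <- image_scenario
      sc$seed <- as.integer(image_seed)
      gen <- generate_he_image(sc)
      img <- preprocess_image(gen$image, p_low = config$p_low,
                              p_high = config$p_high)
      nuc <- segment_nuclei(img, morphology_radius = config$morphology_radius,
                            od_threshold = config$od_threshold,
                            h = config$h, smooth_sigma = config$smooth_sigma,
                            rules = config$rules)
      tis <- segment_tissue(img, gen$truth, n_per_class = config$n_per_class,
                            window = config$window,
                            min_region = config$min_region,
                            closing_radius = config$closing_radius,
                            seed = as.integer(image_seed))
      cls <- classify_nuclei(nuc$nuclei, tis$mask,
                             ecc_round_max = config$ecc_round_max)
      row <- extract_catalog(img, tis$mask, nuc$labels, cls,
                             nests = measure_nests(tis$mask, nuc$hematoxylin_od),
                             image_id = image_id)
      dplyr::bind_cols(tibble::tibble(patient_id = patient_id), row)
    }
  ))

  patient_feats <- if (is.null(cohort)) NULL else
    .stage("aggregate", aggregate_patient(feats))

  specs <- NULL; cutpoints <- NULL; km <- NULL; cox <- NULL; roc <- NULL
  survival_note <- NULL
  if (is.null(cohort)) {
    survival_note <- "no cohort supplied; survival stage skipped"
    message(survival_note)
  } else {
    specs <- .stage("composites", {
      if (config$composite_mode == "pca") {
        fit_pca_composites(patient_feats)
      } else {
        list(tns_feature = tns_feature_spec(),
             tns_cell_nuclei_feature = tns_nuclei_feature_spec())
      }
    })
    patient_feats <- .stage("composites", {
      pf <- patient_feats
      pf$tns_feature <- evaluate_composite(pf, specs$tns_feature)
      pf$tns_cell_nuclei_feature <-
        evaluate_composite(pf, specs$tns_cell_nuclei_feature)
      pf
    })
    analysis <- .stage("join", dplyr::inner_join(
      dplyr::select(cohort$patients, -dplyr::any_of(setdiff(
        names(patient_feats), "patient_id"))),
      patient_feats, by = "patient_id"
    ))
    sf <- intersect(config$survival_features, names(analysis))
    enough_spread <- vapply(sf, function(f)
      length(unique(stats::na.omit(analysis[[f]]))) >= 3, TRUE)
    if (any(!enough_spread)) {
      message("skipping feature(s) without enough spread for cutpoints: ",
              paste(sf[!enough_spread], collapse = ", "))
      sf <- sf[enough_spread]
    }
    cutpoints <- .stage("cutpoints", purrr::map(
      stats::setNames(sf, sf),
      function(f) find_cutpoints(analysis, f,
                                 min_group_frac = config$min_group_frac)
    ))
    for (f in sf) {
      analysis[[paste0(f, "_cat")]] <-
        categorize(analysis[[f]], cutpoints[[f]])
    }
    km <- .stage("km", purrr::map(
      stats::setNames(sf, sf),
      function(f) km_logrank(analysis, paste0(f, "_cat"))
    ))
    cox <- .stage("cox", {
      covs <- c(paste0(sf, "_cat"),
                intersect(config$clinical_covariates, names(analysis)))
      covs <- covs[vapply(covs, function(cv)
        stats::sd(as.numeric(analysis[[cv]]), na.rm = TRUE) > 0, TRUE)]
      if (sum(analysis$event) >= 10 && length(covs)) {
        cox_fit(analysis, covs)
      } else {
        survival_note <<- "too few events for the Cox stage"
        message(survival_note)
        NULL
      }
    })
    roc <- .stage("roc", purrr::map_dfr(
      stats::setNames(sf, sf),
      function(f) roc_auc(analysis, f, "event"), .id = "feature"
    ))
    patient_feats <- analysis
  }

  manifest <- .stage("manifest", {
    digestible <- list(
      package_version = as.character(utils::packageVersion("nestquant")),
      seed = config$seed,
      config = unclass(config),
      image_scenario = unclass(image_scenario),
      n_images = nrow(slots),
      n_patients = if (is.null(cohort)) 0L else nrow(cohort$patients),
      catalog = feature_catalog()$name,
      features_image = feats,
      features_patient = patient_feats,
      cutpoints = purrr::map(cutpoints, function(cp)
        cp[c("feature", "cutpoints", "statistic")]),
      km = purrr::map(km, function(k) list(k$chisq, k$medians)),
      cox = if (!is.null(cox)) tidy(cox) else NULL,
      roc = roc,
      note = survival_note
    )
    digestible$hash <- rlang::hash(digestible)
    digestible
  })

  structure(
    list(
      features_image = feats, features_patient = patient_feats,
      composite_specs = specs, cutpoints = cutpoints, km = km, cox = cox,
      roc = roc, cohort = cohort, manifest = manifest
    ),
    class = "nestquant_result"
  )
}

#' @export
print.nestquant_result <- function(x, ...) {
  cat("<nestquant_result>\n")
  cat("  images analyzed :", nrow(x$features_image), "\n")
  cat("  feature columns :", ncol(x$features_image) - 2L, "\n")
  if (!is.null(x$cohort))
    cat("  patients        :", nrow(x$cohort$patients), "\n")
  cat("  manifest hash   :", x$manifest$hash, "\n")
  invisible(x)
}
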