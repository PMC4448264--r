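# Shared fixtures, built in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

# A small H&E scene with a couple of nests (160 x 128): fast enough for
# per-module tests.
small_scene <- function(seed = 7) {
  key <- paste0("scene_", seed)
  if (is.null(.fixture_env[[key]])) {
    sc <- image_scenario(width = 160, height = 128, n_nests = 2,
                         nest_area_mean = 2500, nest_area_var = 1e4,
                         seed = seed)
    .fixture_env[[key]] <- generate_he_image(sc)
  }
  .fixture_env[[key]]
}

# A sparse scene guaranteeing >= 20 well-separated nuclei for detection
# metrics.
sparse_scene <- function(seed = 13) {
  key <- paste0("sparse_", seed)
  if (is.null(.fixture_env[[key]])) {
    sc <- image_scenario(width = 256, height = 192, n_nests = 2,
                         nest_area_mean = 6000, nest_area_var = 1e4,
                         nuclei_density_in_nest = 8e-4,
                         stromal_round_density = 2e-4,
                         stromal_nonround_density = 2e-4,
                         stain_noise_sd = 0, illumination_gradient = 0,
                         seed = seed)
    .fixture_env[[key]] <- generate_he_image(sc)
  }
  .fixture_env[[key]]
}

# Match segmented nuclei to ground-truth centroids (one-to-one, within tol
# pixels); returns recall/precision/F1 and the matched index pairs.
match_detections <- function(nuclei, truth, tol = 5) {
  tc <- truth$centroids
  if (nrow(nuclei) == 0 || nrow(tc) == 0) {
    return(list(recall = 0, precision = 0, f1 = 0, pairs = NULL))
  }
  d2 <- outer(nuclei$row, tc$row, "-")^2 + outer(nuclei$col, tc$col, "-")^2
  tp <- sum(apply(d2, 2, min) <= tol^2)
  tpn <- sum(apply(d2, 1, min) <= tol^2)
  keep <- apply(d2, 2, min) <= tol^2
  list(
    recall = tp / nrow(tc),
    precision = tpn / nrow(nuclei),
    f1 = 2 * tp / (nrow(tc) + nrow(nuclei)),
    pairs = data.frame(seg = apply(d2, 2, which.min)[keep],
                       truth = which(keep))
  )
}

# Deterministic toy survival table for hand-checked log-rank computations.
toy_survival <- function() {
  data.frame(
    time = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
    event = c(1, 1, 1, 0, 1, 1, 0, 1, 1, 0),
    group = c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2)
  )
}

# Random RGB test image.
random_rgb <- function(h = 16, w = 16, seed = 1) {
  withr::with_seed(seed, array(sample(0:255, h * w * 3, TRUE), dim = c(h, w, 3)))
}
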