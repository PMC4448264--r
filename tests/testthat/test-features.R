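# independent brute-force box counter used as the oracle for the fractal
# dimension (double loop over the box grid, no shared code with the package)
brute_box_count <- function(mask, s) {
  H <- nrow(mask); W <- ncol(mask)
  n <- 0L
  for (r0 in seq(1, H, by = s)) for (c0 in seq(1, W, by = s)) {
    if (any(mask[r0:min(r0 + s - 1, H), c0:min(c0 + s - 1, W)] > 0)) n <- n + 1L
  }
  n
}

test_that("fractal dimension recovers known dimensions", {
  sizes <- c(2, 4, 8, 16)
  line <- matrix(FALSE, 128, 128); line[64, ] <- TRUE
  expect_equal(fractal_dimension(line, sizes), 1.0, tolerance = 0.1)
  sq <- matrix(TRUE, 128, 128)
  expect_equal(fractal_dimension(sq, sizes), 2.0, tolerance = 0.1)
  # Sierpinski triangle, depth 6 (64 x 64): dimension log 3 / log 2
  n <- 64
  sier <- outer(0:(n - 1), 0:(n - 1), function(r, c) bitwAnd(r, c) == 0)
  expect_equal(fractal_dimension(sier, sizes), log(3) / log(2), tolerance = 0.05)
  # estimator agrees with the brute-force box-count slope
  for (mask in list(line, sier)) {
    counts <- vapply(sizes, function(s) brute_box_count(mask, s), 0L)
    d_oracle <- -unname(coef(lm(log(counts) ~ log(sizes)))[2])
    expect_equal(fractal_dimension(mask, sizes), min(max(d_oracle, 0), 2),
                 tolerance = 1e-8)
  }
  expect_true(is.na(fractal_dimension(matrix(FALSE, 32, 32))))
})

test_that("fractal dimension stays in [0, 2] on arbitrary pixel sets", {
  set.seed(31)
  for (i in 1:10) {
    m <- matrix(runif(64 * 64) < runif(1, 0.01, 0.5), 64, 64)
    if (!any(m)) next
    d <- fractal_dimension(m)
    expect_gte(d, 0); expect_lte(d, 2)
  }
})

test_that("Delaunay statistics match hand-computable configurations", {
  sq <- tibble::tibble(row = c(0, 0, 1, 1), col = c(0, 1, 0, 1))
  expect_equal(delaunay_area_sum(sq), 1.0, tolerance = 1e-9)
  tri <- tibble::tibble(row = c(0, 0, 3), col = c(0, 4, 0))
  expect_equal(delaunay_area_sum(tri), 6.0, tolerance = 1e-9)
  expect_true(is.na(delaunay_area_sum(tri[1:2, ])))
  collin <- tibble::tibble(row = c(0, 0, 0, 0), col = 1:4)
  expect_true(is.na(delaunay_area_sum(collin)))
})

test_that("Delaunay area sum equals the convex-hull area on random point sets", {
  set.seed(17)
  for (i in 1:100) {
    np <- sample(10:100, 1)
    pts <- tibble::tibble(row = runif(np), col = runif(np))
    h <- grDevices::chull(pts$col, pts$row)
    hx <- pts$col[h]; hy <- pts$row[h]
    k <- length(h)
    hull_area <- abs(sum(hx * hy[c(2:k, 1)] - hx[c(2:k, 1)] * hy)) / 2
    expect_equal(delaunay_area_sum(pts), hull_area, tolerance = 1e-6)
  }
})

test_that("the catalog counts are exactly 400 / 314 / 16", {
  fc <- feature_catalog()
  expect_equal(nrow(fc), 730L)
  expect_equal(anyDuplicated(fc$name), 0L)
  counts <- table(fc$level)
  expect_equal(as.vector(counts[c("pixel", "object", "semantic")]),
               c(400L, 314L, 16L))
  # every printed study parameter has a catalog entry
  expect_true(all(catalog_aliases()$catalog_name %in% fc$name))
})

test_that("object-level aggregates equal brute-force recomputation", {
  scene <- small_scene()
  seg <- segment_nuclei(scene$image)
  cls <- classify_nuclei(seg$nuclei, scene$truth$nest_mask)
  nests <- measure_nests(scene$truth$nest_mask, seg$hematoxylin_od)
  ob <- object_level_features(nests, cls, scene$truth$nest_mask)
  expect_length(ob, 314L)
  # oracle: recompute a few aggregates directly from the measurement tables
  expect_equal(unname(ob["nest_area_count"]), nrow(nests))
  expect_equal(unname(ob["nest_perimeter_sum"]), sum(nests$perimeter))
  expect_equal(unname(ob["nest_area_mean"]), mean(nests$area))
  expect_equal(unname(ob["nest_area_var"]),
               mean((nests$area - mean(nests$area))^2))
  epi <- dplyr::filter(cls$nuclei, class == "epithelial")
  expect_equal(unname(ob["epithelial_eccentricity_max"]), max(epi$eccentricity))
  expect_equal(unname(ob["epithelial_area_median"]), median(epi$area))
  # two-nest arithmetic example
  toy_nests <- tibble::tibble(
    id = 1:2, row = c(5, 20), col = c(5, 20), area = c(100, 300),
    perimeter = c(40, 70), eccentricity = c(0.1, 0.2), solidity = c(1, 1),
    circularity = c(0.8, 0.7), axis_major = c(12, 21), axis_minor = c(11, 19),
    extent = c(0.7, 0.7), feret = c(13, 22), orientation = c(0, 0),
    boundary_gradient = c(10, 12)
  )
  empty_cls <- classify_nuclei(measure_objects(matrix(0L, 32, 32)),
                               matrix(0L, 32, 32))
  ob2 <- object_level_features(toy_nests, empty_cls, matrix(1L, 32, 32))
  expect_equal(unname(ob2["nest_area_count"]), 2)
  expect_equal(unname(ob2["nest_area_mean"]), 200)
  expect_equal(unname(ob2["nest_area_var"]), 10000)
  # single nest: zero variance; empty classes are missing
  ob1 <- object_level_features(toy_nests[1, ], empty_cls, matrix(1L, 32, 32))
  expect_equal(unname(ob1["nest_area_var"]), 0)
  expect_true(is.na(ob1["epithelial_area_mean"]))
})

test_that("semantic features implement the printed definitions", {
  # 150 epithelial nuclei in 100000 px^2 of nest: density 0.0015 (the
  # printed middle category runs 0.0011 - 0.0016)
  tissue <- matrix(0L, 400, 500); tissue[1:200, 1:500] <- 1L  # 100000 px^2
  set.seed(9)
  nuc <- tibble::tibble(
    id = 1:160,
    row = c(runif(150, 1, 200), runif(10, 201, 400)),
    col = runif(160, 1, 500),
    area = rep(100, 160), eccentricity = c(rep(0.5, 155), rep(0.9, 5)),
    perimeter = 36, solidity = 1, circularity = 1, axis_major = 12,
    axis_minor = 10, extent = 0.7, feret = 12, orientation = 0,
    boundary_gradient = 10
  )
  cls <- classify_nuclei(nuc, tissue)
  nests <- tibble::tibble(
    id = 1L, row = 100, col = 250, area = 1000, perimeter = 100,
    eccentricity = 0.3, solidity = 1, circularity = 0.9, axis_major = 40,
    axis_minor = 30, extent = 0.7, feret = 42, orientation = 0,
    boundary_gradient = 10
  )
  sem <- semantic_level_features(nests, cls, tissue)
  expect_length(sem, 16L)
  expect_equal(unname(sem["tns_cell_density"]), 150 / 100000)
  expect_gt(unname(sem["tns_cell_density"]), 0.0011)
  expect_lt(unname(sem["tns_cell_density"]), 0.0016)
  expect_equal(unname(sem["tns_area_perimeter_ratio"]), 10)
  # oracle recomputation of every value from the inputs
  stroma_area <- sum(tissue == 0)
  expect_equal(unname(sem["stromal_round_cell_density"]),
               sum(cls$nuclei$class == "stromal_round") / stroma_area)
  expect_equal(unname(sem["nest_stroma_area_ratio"]),
               sum(tissue > 0) / stroma_area)
  expect_equal(unname(sem["nuclei_cytoplasm_ratio"]),
               sum(nuc$area) / (length(tissue) - sum(nuc$area)))
  expect_equal(unname(sem["tns_nuclei_area_ratio"]),
               sum(nuc$area[cls$nuclei$class == "epithelial"]) / sum(tissue > 0))
  expect_true(all(sem[!is.na(sem)] >= 0))
  expect_lte(unname(sem["tns_nuclei_area_ratio"]), 1)
})

test_that("extract_catalog emits all 730 values deterministically", {
  scene <- small_scene()
  seg <- segment_nuclei(scene$image)
  tis <- scene$truth$nest_mask
  cls <- classify_nuclei(seg$nuclei, tis)
  row <- extract_catalog(scene$image, tis, seg$labels, cls, image_id = "a")
  expect_equal(ncol(row) - 1L, 730L)
  expect_identical(names(row)[-1], feature_catalog()$name)
  row2 <- extract_catalog(scene$image, tis, seg$labels, cls, image_id = "a")
  expect_identical(row, row2)
})

test_that("patient aggregation is the NA-aware mean", {
  f <- tibble::tibble(
    patient_id = c(1, 1, 1, 1, 1, 2),
    image_id = c("a", "b", "c", "d", "e", "f"),
    x = c(1, 2, 3, 4, 5, 10),
    y = c(NA, 2, NA, 4, NA, NA)
  )
  agg <- aggregate_patient(f)
  expect_equal(agg$x, c(3, 10))
  expect_equal(agg$y, c(3, NA))
})
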