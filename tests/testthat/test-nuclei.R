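test_that("nuclei mask thresholds, opens and preserves real structures", {
  # all-zero OD: empty mask
  expect_false(any(nuclei_mask(matrix(0, 32, 32))))
  # a disk of radius 8 survives a radius-2 opening within a 1-px ring
  od <- matrix(0, 64, 64)
  dd <- outer(1:64, 1:64, function(r, c) sqrt((r - 32)^2 + (c - 32)^2))
  od[dd <= 8] <- 1
  m <- nuclei_mask(od, morphology_radius = 2, od_threshold = 0.5)
  expect_true(all(m[dd <= 7]))
  expect_false(any(m[dd > 9]))
  # isolated single-pixel speckles are erased
  od2 <- matrix(0, 32, 32)
  od2[cbind(c(5, 15, 25), c(5, 15, 25))] <- 1
  expect_false(any(nuclei_mask(od2, morphology_radius = 2, od_threshold = 0.5)))
})

test_that("marker extraction finds one marker per well-separated blob", {
  od <- matrix(0, 64, 64)
  for (ctr in list(c(20, 20), c(44, 44))) {
    d2 <- outer(1:64, 1:64, function(r, c) ((r - ctr[1])^2 + (c - ctr[2])^2) / 36)
    od <- pmax(od, 1 / (1 + exp((d2 - 1) / 0.12)))
  }
  mask <- od > 0.5
  mk <- extract_markers(mask, od, h = 0.1)
  expect_equal(max(mk), 2L)
  # suppression depth beyond the full range merges everything
  mk1 <- extract_markers(mask, od, h = 10)
  expect_lte(max(mk1), 2L)  # <= 1 marker per connected component
  expect_equal(max(extract_markers(matrix(FALSE, 16, 16), matrix(0, 16, 16))), 0L)
})

test_that("watershed partitions the mask and splits touching blobs evenly", {
  od <- matrix(0, 64, 96)
  for (ctr in list(c(32, 36), c(32, 60))) {  # tangent blobs, radius ~12
    d2 <- outer(1:64, 1:96, function(r, c) ((r - ctr[1])^2 + (c - ctr[2])^2) / 144)
    od <- pmax(od, 1 / (1 + exp((d2 - 1) / 0.12)))
  }
  mask <- od > 0.4
  mk <- extract_markers(mask, od, h = 0.1)
  expect_equal(max(mk), 2L)
  labs <- watershed_segment(mk, od, mask)
  # partition: every mask pixel labeled, background untouched
  expect_equal(sum(labs > 0), sum(mask))
  expect_true(all(labs[!mask] == 0))
  a <- tabulate(labs[labs > 0])
  expect_lt(abs(a[1] - a[2]) / max(a), 0.10)
  # single marker: the labeled region is exactly the mask
  mk1 <- matrix(0L, 64, 96); mk1[32, 48] <- 1L
  labs1 <- watershed_segment(mk1, od, mask)
  expect_equal(labs1 > 0, mask)
  # no markers at all: flagged unseeded regions still cover the mask
  labs0 <- watershed_segment(matrix(0L, 64, 96), od, mask)
  expect_equal(sum(labs0 > 0), sum(mask))
  expect_true(length(attr(labs0, "unseeded")) >= 1)
})

test_that("spurious-region removal applies the rules exactly", {
  scene <- sparse_scene()
  od <- color_deconvolve(scene$image)$hematoxylin_od
  mask <- nuclei_mask(od)
  mk <- extract_markers(mask, od)
  labs <- watershed_segment(mk, od, mask)
  rules <- spurious_rules(min_area = 60, max_area = 2000, s_min = 0.8,
                          g_min = 5)
  res <- remove_spurious(labs, od, rules)
  # oracle: re-filter the measured table by hand
  meas <- measure_objects(labs, od)
  keep <- meas$area >= 60 & meas$area <= 2000 & meas$solidity >= 0.8 &
    meas$boundary_gradient >= 5
  expect_equal(nrow(res$nuclei), sum(keep))
  # labels contiguous from 1
  expect_equal(sort(unique(res$labels[res$labels > 0])),
               seq_len(max(res$labels)))
  # a tiny region is removed, a perfect disk kept
  toy <- matrix(0L, 64, 64)
  dd <- outer(1:64, 1:64, function(r, c) sqrt((r - 20)^2 + (c - 20)^2))
  toy[dd <= 8] <- 1L
  toy[50, 50] <- 2L  # 1-px speck
  od_toy <- matrix(0, 64, 64); od_toy[toy > 0] <- 1
  out <- remove_spurious(toy, od_toy, spurious_rules(min_area = 30,
                                                     max_area = 3000,
                                                     s_min = 0.7, g_min = 0))
  expect_equal(max(out$labels), 1L)  # the disk is retained, the speck is not
  expect_gt(out$nuclei$solidity[1], 0.85)
  expect_lt(out$nuclei$eccentricity[1], 0.2)
})

test_that("detection recall and precision reach 0.9 on sparse synthetic images", {
  scene <- sparse_scene()
  expect_gte(sum(scene$truth$true_counts), 20)
  seg <- segment_nuclei(scene$image)
  m <- match_detections(seg$nuclei, scene$truth)
  expect_gte(m$recall, 0.9)
  expect_gte(m$precision, 0.9)
  # matched-area accuracy on the noise-free scene
  true_area <- tabulate(scene$truth$nuclei_mask[scene$truth$nuclei_mask > 0],
                        nbins = nrow(scene$truth$centroids))
  rel <- abs(seg$nuclei$area[m$pairs$seg] - true_area[m$pairs$truth]) /
    true_area[m$pairs$truth]
  expect_lte(mean(rel), 0.2)
})
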