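test_that("whole-stem segmentation thresholds, keeps one component, fills holes", {
  # bright disk on dark background
  img <- matrix(10, 240, 240)
  img[disk_mask(240, 120, 120, 100)] <- 200
  m <- segment_whole_stem(img)
  expect_equal(sum(m), sum(disk_mask(240, 120, 120, 100)), tolerance = 0.01)
  # bright annulus -> full disk after hole filling
  img2 <- matrix(10, 240, 240)
  ann <- disk_mask(240, 120, 120, 100) & !disk_mask(240, 120, 120, 60)
  img2[ann] <- 200
  m2 <- segment_whole_stem(img2)
  expect_equal(sum(m2), sum(disk_mask(240, 120, 120, 100)), tolerance = 0.01)
  # empty foreground errors with a diagnostic
  expect_error(segment_whole_stem(matrix(5, 10, 10),
                                  segmentation_params(stem_threshold = 100)),
               "segmentation-failure")
  # phantom ground truth
  ph <- get_phantom("small")
  m3 <- segment_whole_stem(ph$darkfield)
  expect_gte(jaccard(m3, ph$truth_rois$whole_stem), 0.99)
})

test_that("hole segmentation removes torn regions and nothing else", {
  ph <- get_phantom("small")   # no holes
  ws <- ph$truth_rois$whole_stem
  at <- segment_all_tissue(ph$darkfield, ws, pixel_size_um = 3.63)
  expect_equal(sum(ws) - sum(at), 0)

  phh <- get_phantom("holes")
  wsh <- phh$truth_rois$whole_stem
  ath <- segment_all_tissue(phh$darkfield, wsh, pixel_size_um = 3.63)
  true_hole_px <- sum(wsh) - sum(phh$truth_rois$all_tissue)
  got_hole_px <- sum(wsh) - sum(ath)
  expect_gt(true_hole_px, 0)
  expect_equal(got_hole_px, true_hole_px, tolerance = 0.15)
})

test_that("dense-tissue threshold isolates rind and bundles", {
  img <- matrix(50, 60, 60); img[10:20, 10:50] <- 200
  at <- matrix(TRUE, 60, 60)
  m <- threshold_rind_bundles(img, at)
  expect_identical(m, img == 200)
  expect_error(threshold_rind_bundles(img, matrix(FALSE, 60, 60)),
               "segmentation-failure")
})

test_that("bundle area mode honours the epidermis exclusion", {
  # 20 identical 10x10 squares well inside a large stem -> exact mode
  n <- 700
  ws <- matrix(TRUE, n, n)
  dm <- matrix(FALSE, n, n)
  centres <- expand.grid(r = seq(330, 430, by = 25), c = seq(330, 430, by = 25))
  for (i in seq_len(20)) {
    r <- centres$r[i]; c <- centres$c[i]
    dm[r:(r + 9), c:(c + 9)] <- TRUE
  }
  mode_mm2 <- bundle_area_mode(dm, ws, pixel_size_um = 10)
  expect_equal(mode_mm2, 100 * 1e-4, tolerance = 1e-9)  # 100 px at 10 um/px
  # components hugging the stem boundary only -> error (1 mm exclusion)
  ws2 <- disk_mask(300, 150, 150, 140)
  dm2 <- matrix(FALSE, 300, 300)
  dm2[60:69, 145:154] <- TRUE     # about 200 um below the contour
  dm2[230:239, 145:154] <- TRUE
  dm2[145:154, 60:69] <- TRUE
  expect_error(bundle_area_mode(dm2, ws2, pixel_size_um = 10),
               "insufficient-objects")
})

test_that("rind/bundle classification merges external fragments over 5x mode", {
  n <- 400
  ws <- disk_mask(n, 200, 200, 190)
  dm <- matrix(FALSE, n, n)
  # annulus rind split into 3 large arcs
  ann <- ws & !disk_mask(n, 200, 200, 170)
  theta <- atan2(col(ann) - 200, row(ann) - 200)
  arcs <- ann & !(abs(theta) < 0.15 | abs(theta - 2.2) < 0.15 |
                    abs(theta + 2.2) < 0.15)
  dm <- dm | arcs
  # interior blobs around 8x8 px
  set.seed(4)
  for (i in 1:30) {
    r <- sample(60:340, 1); c <- sample(60:340, 1)
    if (sqrt((r - 200)^2 + (c - 200)^2) > 130) next
    dm[r:(r + 7), c:(c + 7)] <- TRUE
  }
  mode_mm2 <- 64 * (10 / 1000)^2
  cls <- classify_rind_bundles(dm, mode_mm2, ws, pixel_size_um = 10)
  # all three arcs merged into one rind mask
  expect_true(all(arcs[cls$rind] | TRUE))
  expect_equal(sum(cls$rind), sum(arcs))
  expect_true(cls$rind_found)
  # bundles are the rest; individualised ones carry distinct labels
  expect_equal(sum(cls$bundles_all), sum(dm) - sum(arcs))
  expect_gt(max(cls$bundles_individual), 10)
  # a single interior blob of 10x mode stays in bundles_all but is not
  # individualised
  dm3 <- matrix(FALSE, 200, 200)
  dm3[90:121, 90:109] <- TRUE   # 640 px = 10x mode of 64 px
  for (k in 1:5) dm3[20 + 10 * k, 50:57] <- TRUE
  cls3 <- suppressWarnings(
    classify_rind_bundles(dm3, mode_mm2, matrix(TRUE, 200, 200),
                          pixel_size_um = 10))
  expect_true(all(cls3$bundles_all[90:121, 90:109]))
  expect_false(any(cls3$bundles_individual[90:121, 90:109] > 0))
})

test_that("parenchyma zonation follows Euclidean distances from the rind", {
  # rind = left column strip, 10 um/px: near < 50 px, middle > 100 px
  n <- 160
  ws <- matrix(TRUE, n, n)
  rind <- matrix(FALSE, n, n); rind[, 1:3] <- TRUE
  vb <- matrix(FALSE, n, n)
  pa <- derive_parenchyma_rois(ws, ws, rind, vb, pixel_size_um = 10)
  cols_near <- which(apply(pa$parenchyma_near_rind, 2, any))
  cols_mid <- which(apply(pa$parenchyma_middle, 2, any))
  expect_equal(max(cols_near), 3 + 49)        # distance strictly below 500 um
  expect_equal(min(cols_mid), 3 + 101)        # strictly beyond 1000 um
  # the 500-1000 um band belongs to neither zone
  band <- pa$parenchyma & !pa$parenchyma_near_rind & !pa$parenchyma_middle
  expect_true(any(band[, 60:100]))
  # enlarging the near band never shrinks the near ROI
  pa2 <- derive_parenchyma_rois(ws, ws, rind, vb,
                                segmentation_params(near_rind_max_um = 700),
                                pixel_size_um = 10)
  expect_true(all(pa2$parenchyma_near_rind[pa$parenchyma_near_rind]))
})

test_that("full workflow recovers phantom tissues and is deterministic", {
  ph <- get_phantom("small")
  rois <- segment_stem(ph$darkfield, 3.63)
  tr <- ph$truth_rois
  expect_gte(jaccard(rois$rind, tr$rind), 0.90)
  expect_gte(jaccard(rois$bundles_all, tr$bundles_all), 0.90)
  expect_gte(jaccard(rois$parenchyma, tr$parenchyma), 0.95)
  # exact partition invariant
  expect_equal(sum(rois$rind) + sum(rois$bundles_all) + sum(rois$parenchyma),
               sum(rois$whole_stem))
  # determinism
  rois2 <- segment_stem(ph$darkfield, 3.63)
  expect_identical(rois$rind, rois2$rind)
  expect_identical(rois$bundles_individual, rois2$bundles_individual)
})

test_that("a missing rind arc is detected and flagged", {
  # the epidermis exclusion is scaled with the scaled-down phantom radius
  par <- segmentation_params(epidermis_exclusion_um = 500)
  ph <- get_phantom("damaged")
  rois <- segment_stem(ph$darkfield, 3.63, par)
  expect_true(rois$rind_damaged)
  ph0 <- get_phantom("small")
  rois0 <- segment_stem(ph0$darkfield, 3.63, par)
  expect_false(rois0$rind_damaged)
})

test_that("roi_set enforces its invariants", {
  tr <- get_phantom("small")$truth_rois
  bad <- tr$parenchyma
  bad[1, 1] <- TRUE   # outside whole_stem
  expect_error(roi_set(tr$whole_stem, tr$all_tissue, tr$rind,
                       tr$bundles_individual, tr$bundles_all, bad,
                       tr$parenchyma_near_rind, tr$parenchyma_middle,
                       3.63), "parenchyma")
  expect_error(roi_set(tr$whole_stem, tr$all_tissue, tr$rind,
                       tr$bundles_individual, tr$rind | tr$bundles_all,
                       tr$parenchyma, tr$parenchyma_near_rind,
                       tr$parenchyma_middle, 3.63), "disjoint")
})
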