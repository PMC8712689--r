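test_that("background spectrum pools regions channel-wise", {
  ms <- const_ms(4, n = 30)
  r1 <- matrix(FALSE, 30, 30); r1[1:10, 1:12] <- TRUE
  bg <- background_spectrum(ms, list(r1))
  expect_equal(unname(bg$values), rep(4, 11))
  expect_identical(bg$tissue, "background")

  # two equal-size regions with channel means 2 and 4 pool to 3
  ch <- setNames(lapply(1:11, function(i) {
    m <- matrix(0, 30, 30); m[1:10, 1:10] <- 2; m[15:24, 1:10] <- 4; m
  }), channel_names())
  ms2 <- multispectral_image(ch)
  r2 <- matrix(FALSE, 30, 30); r2[15:24, 1:10] <- TRUE
  r1b <- matrix(FALSE, 30, 30); r1b[1:10, 1:10] <- TRUE
  bg2 <- background_spectrum(ms2, list(r1b, r2))
  expect_equal(unname(bg2$values), rep(3, 11))
  expect_error(background_spectrum(ms, list()), "no background region")
  expect_error(background_spectrum(ms, list(r1[1:5, 1:5, drop = FALSE] &
                                              matrix(FALSE, 5, 5))),
               "smaller")
})

test_that("tissue spectra subtract the background exactly", {
  ms <- const_ms(9, n = 20)
  roi <- matrix(FALSE, 20, 20); roi[5:15, 5:15] <- TRUE
  bgmask <- matrix(FALSE, 20, 20); bgmask[1:20, 1:5] <- TRUE
  bg <- background_spectrum(ms, bgmask)
  sp <- tissue_pseudospectrum(ms, roi, bg, "rind")
  expect_equal(unname(sp$values), rep(0, 11))
  expect_true(sp$background_corrected)
  expect_error(tissue_pseudospectrum(ms, matrix(FALSE, 20, 20), bg, "rind"),
               "empty")
})

test_that("phantom spectra recover the injected signatures and baselines", {
  ph <- get_phantom("small")
  ms <- ph$multispectral
  rois <- ph$truth_rois
  bgmask <- auto_background_mask(ms, rois$whole_stem, fraction = 0.05)
  bg <- background_spectrum(ms, bgmask, min_pixels = 50)
  # channel-dependent offsets recovered within a noise margin
  expect_equal(unname(bg$values), unname(ph$truth$background_offsets),
               tolerance = 0.15)
  sp_r <- tissue_pseudospectrum(ms, rois$rind, bg, "rind")
  tr <- ph$truth$signatures$rind
  cosang <- sum(sp_r$values * tr) / sqrt(sum(sp_r$values^2) * sum(tr^2))
  expect_gt(cosang, 0.99)
  # baseline channels carry almost nothing after subtraction
  bl <- sp_r$values[baseline_channels()]
  expect_lt(max(abs(bl)), 0.02 * max(sp_r$values))
})

test_that("density correction rescales parenchyma spectra only", {
  sp <- pseudospectrum(rep(1, 11), "parenchyma_middle",
                       background_corrected = TRUE)
  out <- density_correct(sp, 4)
  expect_equal(unname(out$values), rep(25, 11))
  expect_true(out$density_corrected)
  expect_equal(unname(density_correct(sp, 100)$values), rep(1, 11))
  spr <- pseudospectrum(rep(1, 11), "rind", background_corrected = TRUE)
  expect_error(density_correct(spr, 4), "invalid-operation")
  expect_error(density_correct(sp, 0), "invalid-input")
})

test_that("two phantoms with cell sizes d and 2d agree after density correction", {
  mk <- function(d, seed) {
    generate_phantom(phantom_params(
      stem_radius_um = 1500, rind_thickness_um = 300, n_bundles = 4,
      cell_diameter_middle_um = d, cell_diameter_near_rind_um = d * 5 / 7,
      seed = seed))
  }
  ph1 <- mk(45, 21); ph2 <- mk(90, 21)
  get_near <- function(ph) {
    ms <- ph$multispectral; rois <- ph$truth_rois
    bg <- background_spectrum(ms, auto_background_mask(ms, rois$whole_stem,
                                                       0.05), 50)
    sp <- tissue_pseudospectrum(ms, rois$parenchyma_near_rind, bg,
                                "parenchyma_near_rind")
    g <- granulometry_stats(graylevel_granulometry(
      ph$darkfield, rois$parenchyma_near_rind, "closing"))
    density_correct(sp, cell_wall_density(g$mean_size_um))
  }
  s1 <- get_near(ph1); s2 <- get_near(ph2)
  # compare on the strong channels only (weak ones are noise-dominated)
  strong <- s1$values > 0.2 * max(s1$values)
  expect_equal(unname(s1$values[strong]), unname(s2$values[strong]),
               tolerance = 0.25)
})

test_that("section normalisation implements the four-tissue mean factor", {
  mk <- function(v, tissue, dens = FALSE)
    pseudospectrum(rep(v, 11), tissue, background_corrected = TRUE,
                   density_corrected = dens)
  specs <- list(mk(1, "rind"), mk(2, "bundles"),
                mk(3, "parenchyma_near_rind", TRUE),
                mk(4, "parenchyma_middle", TRUE))
  out <- section_normalize(specs)
  expect_equal(out$Fn, 2.5)
  # mean of the four tissue means is exactly 1 after normalisation
  expect_equal(mean(vapply(out$specs, function(s) mean(s$values), numeric(1))),
               1)
  # all-equal spectra normalise to ones
  eq <- section_normalize(list(mk(7, "rind"), mk(7, "bundles"),
                               mk(7, "parenchyma_near_rind", TRUE),
                               mk(7, "parenchyma_middle", TRUE)))
  expect_equal(unname(eq$specs$rind$values), rep(1, 11))
  # refuses incomplete or uncorrected input
  expect_error(section_normalize(specs[1:3]), "four")
  bad <- specs; bad[[3]] <- mk(3, "parenchyma_near_rind", dens = FALSE)
  expect_error(section_normalize(bad), "density-corrected")
})

test_that("normalisation cancels any global gain", {
  set.seed(33)
  base <- lapply(c("rind", "bundles", "parenchyma_near_rind",
                   "parenchyma_middle"), function(t)
    pseudospectrum(runif(11, 0.5, 5), t, background_corrected = TRUE,
                   density_corrected = grepl("parenchyma", t)))
  n1 <- section_normalize(base)
  scaled <- lapply(base, function(s) { s$values <- s$values * 3.7; s })
  n2 <- section_normalize(scaled)
  for (t in names(n1$specs))
    expect_equal(n1$specs[[t]]$values, n2$specs[[t]]$values)
  expect_equal(n2$Fn, 3.7 * n1$Fn)
})

test_that("corrected parenchyma outshines rind, as in real sections", {
  ph <- get_phantom("small")
  rois <- ph$truth_rois
  g <- granulometry_stats(graylevel_granulometry(
    ph$darkfield, rois$parenchyma_middle, "closing"))
  gr <- granulometry_stats(graylevel_granulometry(
    ph$darkfield, rois$parenchyma_near_rind, "closing"))
  sp <- section_pseudospectra(ph$multispectral, rois,
                              cell_wall_density(g$mean_size_um),
                              cell_wall_density(gr$mean_size_um))
  expect_gt(mean(sp$specs$parenchyma_middle$values),
            mean(sp$specs$rind$values))
})
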