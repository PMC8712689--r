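#' Tissue regions of interest of a stem cross-section
#'
#' Holds the seven masks produced by the segmentation workflow. Invariants
#' are enforced at construction: `parenchyma` is exactly the whole stem
#' minus rind and bundles, sub-parenchyma zones are disjoint subsets of the
#' parenchyma, and rind and bundles never overlap.
#'
#' @param whole_stem,all_tissue,rind,bundles_all,parenchyma,parenchyma_near_rind,parenchyma_middle
#'   logical matrices of identical dimension.
#' @param bundles_individual integer label map (one positive label per
#'   individualised bundle), support inside `bundles_all`.
#' @param pixel_size_um pixel size in micrometres.
#' @param rind_damaged was a missing rind arc detected / declared?
#' @return object of class `roi_set`.
#' @export
roi_set <- function(whole_stem, all_tissue, rind, bundles_individual,
                    bundles_all, parenchyma, parenchyma_near_rind,
                    parenchyma_middle, pixel_size_um, rind_damaged = FALSE) {
  d <- dim(whole_stem)
  ms <- list(whole_stem = whole_stem, all_tissue = all_tissue, rind = rind,
             bundles_all = bundles_all, parenchyma = parenchyma,
             parenchyma_near_rind = parenchyma_near_rind,
             parenchyma_middle = parenchyma_middle)
  for (nm in names(ms)) {
    if (!is.logical(ms[[nm]]) || !all(dim(ms[[nm]]) == d))
      stop("mask '", nm, "' must be a logical matrix matching whole_stem")
  }
  if (!all(dim(bundles_individual) == d))
    stop("bundles_individual must match whole_stem dimensions")
  if (any(all_tissue & !whole_stem)) stop("all_tissue must be inside whole_stem")
  if (any(rind & !whole_stem)) stop("rind must be inside whole_stem")
  if (any(bundles_all & !whole_stem)) stop("bundles_all must be inside whole_stem")
  if (any(rind & bundles_all)) stop("rind and bundles_all must be disjoint")
  if (!all(parenchyma == (whole_stem & !(rind | bundles_all))))
    stop("parenchyma must equal whole_stem minus (rind | bundles_all), pixelwise")
  if (any(bundles_individual > 0 & !bundles_all))
    stop("bundles_individual support must lie inside bundles_all")
  if (any(parenchyma_near_rind & !parenchyma) ||
      any(parenchyma_middle & !parenchyma))
    stop("parenchyma sub-ROIs must lie inside parenchyma")
  if (any(parenchyma_near_rind & parenchyma_middle))
    stop("parenchyma sub-ROIs must be disjoint")
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  structure(c(ms, list(bundles_individual = bundles_individual,
                       pixel_size_um = pixel_size_um,
                       rind_damaged = rind_damaged)),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  px2mm2 <- (x$pixel_size_um / 1000)^2
  cat("roi_set (", nrow(x$whole_stem), "x", ncol(x$whole_stem), " px, ",
      x$pixel_size_um, " um/px)\n", sep = "")
  for (nm in c("whole_stem", "all_tissue", "rind", "bundles_all", "parenchyma",
               "parenchyma_near_rind", "parenchyma_middle"))
    cat(sprintf("  %-22s %8.2f mm2\n", nm, sum(x[[nm]]) * px2mm2))
  cat("  individual bundles:", max(x$bundles_individual), "\n")
  if (isTRUE(x$rind_damaged)) cat("  rind flagged as damaged\n")
  invisible(x)
}

#' Segmentation parameters
#'
#' Defaults reproduce the published workflow constants: alternating filter
#' half-widths 1-3 px at 3.63 um/px, rind fragments are external components
#' larger than 5x the bundle-area mode, bundle-mode objects are taken more
#' than 1000 um from the epidermis, and parenchyma zones are below 500 um
#' (near rind) / above 1000 um (middle) from the rind.
#'
#' @param stem_threshold `"otsu"` or a fixed numeric threshold.
#' @param hole_threshold `"median-fraction"`, `"otsu"`, or a fixed value.
#' @param hole_median_fraction holes are pixels of the hole-closed image
#'   darker than this fraction of the in-stem median (default 0.35).
#' @param hole_closing_um closing size used to brighten cell lumens before
#'   hole detection, in micrometres.
#' @param min_hole_area_um2 smallest region kept as a hole.
#' @param asf_sizes_um increasing half-widths of the alternating filter, um.
#' @param rind_mode_multiplier external fragments larger than this multiple
#'   of the bundle-area mode are merged into the rind (default 5).
#' @param epidermis_exclusion_um exclusion distance from the stem contour
#'   for the bundle-mode estimate (default 1000).
#' @param near_rind_max_um,middle_min_um distance bands defining the
#'   parenchyma sub-zones (defaults 500 and 1000).
#' @param individual_window components with area within this window times
#'   the mode, and not external, are individualised bundles.
#' @param external_margin_px a component is "external" if it comes within
#'   this many pixels of the stem contour.
#' @return list of class `segmentation_params`.
#' @export
segmentation_params <- function(stem_threshold = "otsu",
                                hole_threshold = "median-fraction",
                                hole_median_fraction = 0.35,
                                hole_closing_um = 150,
                                min_hole_area_um2 = 10000,
                                asf_sizes_um = c(3.63, 7.26, 10.89),
                                rind_mode_multiplier = 5,
                                epidermis_exclusion_um = 1000,
                                near_rind_max_um = 500,
                                middle_min_um = 1000,
                                individual_window = c(0.2, 5),
                                external_margin_px = 2) {
  if (near_rind_max_um >= middle_min_um)
    stop("near_rind_max_um must be smaller than middle_min_um")
  if (is.unsorted(asf_sizes_um, strictly = TRUE))
    stop("asf_sizes_um must be strictly increasing")
  structure(list(stem_threshold = stem_threshold,
                 hole_threshold = hole_threshold,
                 hole_median_fraction = hole_median_fraction,
                 hole_closing_um = hole_closing_um,
                 min_hole_area_um2 = min_hole_area_um2,
                 asf_sizes_um = asf_sizes_um,
                 rind_mode_multiplier = rind_mode_multiplier,
                 epidermis_exclusion_um = epidermis_exclusion_um,
                 near_rind_max_um = near_rind_max_um,
                 middle_min_um = middle_min_um,
                 individual_window = individual_window,
                 external_margin_px = external_margin_px),
            class = "segmentation_params")
}

.odd_px <- function(size_um, pixel_size_um) {
  k <- round(size_um / pixel_size_um)
  k <- 2L * floor(k / 2) + 1L   # nearest odd, at least 1
  max(1L, as.integer(k))
}

#' Segment the whole stem
#'
#' Threshold (automatic Otsu or fixed), keep the largest connected
#' component, fill interior holes.
#'
#' @param img numeric matrix, foreground brighter than background.
#' @param params [segmentation_params()].
#' @return logical mask.
#' @export
segment_whole_stem <- function(img, params = segmentation_params()) {
  thr <- if (is.numeric(params$stem_threshold)) params$stem_threshold
         else otsu_threshold(img)
  fg <- img > thr
  if (!any(fg))
    stop("segmentation-failure: empty foreground at threshold ", signif(thr, 4))
  lab <- label_components(fg, 8L)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  fill_holes(lab == keep)
}

#' Segment tissue, excluding section holes
#'
#' Detects large dark tears inside the stem. Cell lumens are first
#' brightened by a closing larger than the cell size so that only genuinely
#' missing-tissue regions stay dark; candidate holes below the hole
#' threshold and larger than `min_hole_area_um2` are removed from the stem
#' mask.
#'
#' @param img numeric matrix (same grid as `whole_stem`).
#' @param whole_stem mask from [segment_whole_stem()].
#' @param params [segmentation_params()].
#' @param pixel_size_um pixel size of `img`.
#' @return logical mask `all_tissue` (subset of `whole_stem`).
#' @export
segment_all_tissue <- function(img, whole_stem,
                               params = segmentation_params(),
                               pixel_size_um = 3.63) {
  k <- .odd_px(params$hole_closing_um, pixel_size_um)
  closed <- mm_close(img, k)
  vals <- closed[whole_stem]
  thr <- if (is.numeric(params$hole_threshold)) {
    params$hole_threshold
  } else if (identical(params$hole_threshold, "otsu")) {
    otsu_threshold(vals)
  } else {
    params$hole_median_fraction * median(vals)
  }
  cand <- whole_stem & closed < thr
  if (!any(cand)) return(whole_stem)
  lab <- label_components(cand, 8L)
  areas <- tabulate(lab[lab > 0])
  min_px <- params$min_hole_area_um2 / pixel_size_um^2
  holes <- lab > 0 & areas[pmax(lab, 1)] >= min_px
  whole_stem & !holes
}

#' Contrast rind and bundles against the parenchyma
#'
#' Alternating sequential filter (closing then opening at each size,
#' increasing sizes, square structuring elements). Thin bright parenchyma
#' walls are suppressed; dense regions keep their intensity.
#'
#' @inheritParams segment_all_tissue
#' @return filtered numeric matrix.
#' @export
enhance_rind_bundles <- function(img, params = segmentation_params(),
                                 pixel_size_um = 3.63) {
  halves <- vapply(params$asf_sizes_um,
                   function(s) max(1L, as.integer(round(s / pixel_size_um))),
                   integer(1))
  halves <- unique(halves)
  asf(img, halves)
}

#' Threshold the filtered image into a dense-tissue mask
#'
#' Automatic Otsu threshold restricted to the `all_tissue` histogram.
#'
#' @param enhanced output of [enhance_rind_bundles()].
#' @param all_tissue tissue mask.
#' @return logical mask of dense tissue (rind + bundles).
#' @export
threshold_rind_bundles <- function(enhanced, all_tissue) {
  if (!any(all_tissue)) stop("segmentation-failure: empty all_tissue mask")
  thr <- otsu_threshold(enhanced[all_tissue])
  mask <- all_tissue & enhanced > thr
  if (!any(mask) || all(mask == all_tissue))
    stop("segmentation-failure: degenerate dense-tissue threshold ",
         signif(thr, 4))
  mask
}

#' Mode of the bundle area distribution
#'
#' The typical individual-bundle area, estimated as the mode of the areas of
#' dense-mask components whose centroid lies more than
#' `epidermis_exclusion_um` inside the stem contour. The mode comes from a
#' Gaussian kernel density (Silverman bandwidth) on log-area; with fewer
#' than 10 objects a histogram mode is used instead.
#'
#' @param dense_mask mask from [threshold_rind_bundles()].
#' @param whole_stem stem mask.
#' @param params [segmentation_params()].
#' @param pixel_size_um pixel size.
#' @return mode area in mm^2.
#' @export
bundle_area_mode <- function(dense_mask, whole_stem,
                             params = segmentation_params(),
                             pixel_size_um = 3.63) {
  lab <- label_components(dense_mask, 8L)
  st <- component_stats(lab)
  if (nrow(st) == 0) stop("insufficient-objects: no dense components")
  dist_px <- distance_transform(!whole_stem)
  excl_px <- params$epidermis_exclusion_um / pixel_size_um
  ci <- pmin(pmax(round(st$centroid_row) + 1L, 1L), nrow(dense_mask))
  cj <- pmin(pmax(round(st$centroid_col) + 1L, 1L), ncol(dense_mask))
  d <- dist_px[cbind(ci, cj)]
  areas_mm2 <- st$area_px[d > excl_px] * (pixel_size_um / 1000)^2
  if (length(areas_mm2) < 3)
    stop("insufficient-objects: fewer than 3 components beyond the ",
         "epidermis exclusion distance")
  if (length(unique(areas_mm2)) == 1) return(areas_mm2[1])
  la <- log(areas_mm2)
  if (length(la) >= 10) {
    de <- density(la, bw = "nrd0")
    exp(de$x[which.max(de$y)])
  } else {
    # Freedman-Diaconis histogram mode on log-area
    h <- 2 * stats::IQR(la) / length(la)^(1 / 3)
    if (h <= 0) return(exp(median(la)))
    br <- seq(min(la) - h / 2, max(la) + h, by = h)
    cnt <- tabulate(findInterval(la, br), nbins = length(br) - 1)
    i <- which.max(cnt)
    exp((br[i] + br[i + 1]) / 2)
  }
}

#' Classify dense components into rind and vascular bundles
#'
#' External fragments (touching the stem contour zone) larger than
#' `rind_mode_multiplier` times the mode area are merged into the rind.
#' Remaining components within the individual-size window and not external
#' become individualised bundles; `bundles_all` is everything dense that is
#' not rind (connected clusters included).
#'
#' @param dense_mask mask from [threshold_rind_bundles()].
#' @param mode_area_mm2 mode from [bundle_area_mode()].
#' @param whole_stem stem mask.
#' @param params [segmentation_params()].
#' @param pixel_size_um pixel size.
#' @return list with `rind` mask, `bundles_individual` label map,
#'   `bundles_all` mask and `rind_found` flag.
#' @export
classify_rind_bundles <- function(dense_mask, mode_area_mm2, whole_stem,
                                  params = segmentation_params(),
                                  pixel_size_um = 3.63) {
  stopifnot(mode_area_mm2 > 0)
  lab <- label_components(dense_mask, 8L)
  st <- component_stats(lab)
  dist_out <- distance_transform(!whole_stem)
  # distance (px) of each component's closest pixel to the stem contour
  min_border <- rep(Inf, nrow(st))
  pos <- which(lab > 0)
  if (length(pos)) {
    l <- lab[pos]
    agg <- tapply(dist_out[pos], l, min)
    min_border[as.integer(names(agg))] <- agg
  }
  external <- min_border <= params$external_margin_px
  area_mm2 <- st$area_px * (pixel_size_um / 1000)^2
  rind_ids <- st$label[external &
                         area_mm2 > params$rind_mode_multiplier * mode_area_mm2]
  rind_found <- length(rind_ids) > 0
  if (!rind_found)
    warning("no rind fragment found: section may be a rind-free fragment")
  rind <- matrix(FALSE, nrow(dense_mask), ncol(dense_mask))
  if (rind_found) rind[lab %in% rind_ids] <- TRUE
  bundles_all <- dense_mask & !rind
  iw <- params$individual_window
  indiv_ids <- st$label[!external & !(st$label %in% rind_ids) &
                          area_mm2 >= iw[1] * mode_area_mm2 &
                          area_mm2 <= iw[2] * mode_area_mm2]
  bundles_individual <- matrix(0L, nrow(dense_mask), ncol(dense_mask))
  if (length(indiv_ids)) {
    remap <- integer(max(st$label))
    remap[indiv_ids] <- seq_along(indiv_ids)
    sel <- lab > 0 & lab %in% indiv_ids
    bundles_individual[sel] <- remap[lab[sel]]
  }
  list(rind = rind, bundles_individual = bundles_individual,
       bundles_all = bundles_all, rind_found = rind_found)
}

#' Derive parenchyma ROIs from the tissue masks
#'
#' `parenchyma` is the stem minus rind and bundles. Distance to the rind
#' (Euclidean, in micrometres) splits it into a near-rind zone
#' (< `near_rind_max_um`) and a middle zone (> `middle_min_um`); the band in
#' between belongs to neither. Sub-zones are intersected with `all_tissue`
#' so that holes never enter measurements.
#'
#' @param whole_stem,all_tissue,rind,bundles_all masks.
#' @param params [segmentation_params()].
#' @param pixel_size_um pixel size.
#' @return list with `parenchyma`, `parenchyma_near_rind`,
#'   `parenchyma_middle`.
#' @export
derive_parenchyma_rois <- function(whole_stem, all_tissue, rind, bundles_all,
                                   params = segmentation_params(),
                                   pixel_size_um = 3.63) {
  parenchyma <- whole_stem & !(rind | bundles_all)
  if (!any(parenchyma)) stop("segmentation-failure: empty parenchyma")
  ref <- if (any(rind)) rind else whole_stem & !mm_erode(whole_stem, 3L)
  d_um <- distance_transform(ref) * pixel_size_um
  near <- parenchyma & all_tissue & d_um < params$near_rind_max_um
  middle <- parenchyma & all_tissue & d_um > params$middle_min_um
  list(parenchyma = parenchyma, parenchyma_near_rind = near,
       parenchyma_middle = middle)
}

#' Full segmentation workflow
#'
#' Runs the seven-step workflow on a darkfield grey image or a fluorescence
#' sum-intensity image and returns a validated [roi_set()].
#'
#' @param img numeric matrix (darkfield grey image, or
#'   `sum_image(ms, "all")` for fluorescence stacks).
#' @param pixel_size_um pixel size of `img` in micrometres.
#' @param params [segmentation_params()].
#' @return [roi_set()].
#' @export
segment_stem <- function(img, pixel_size_um = 3.63,
                         params = segmentation_params()) {
  whole_stem <- segment_whole_stem(img, params)
  all_tissue <- segment_all_tissue(img, whole_stem, params, pixel_size_um)
  enhanced <- enhance_rind_bundles(img, params, pixel_size_um)
  dense <- threshold_rind_bundles(enhanced, all_tissue)
  mode_area <- bundle_area_mode(dense, whole_stem, params, pixel_size_um)
  cls <- classify_rind_bundles(dense, mode_area, whole_stem, params,
                               pixel_size_um)
  pa <- derive_parenchyma_rois(whole_stem, all_tissue, cls$rind,
                               cls$bundles_all, params, pixel_size_um)
  # damaged rind heuristic: rind present along < 95% of the contour
  contour <- whole_stem & !mm_erode(whole_stem, 3L)
  d_rind <- distance_transform(if (any(cls$rind)) cls$rind else whole_stem)
  rind_cover <- mean(d_rind[contour] * pixel_size_um < 2 * pixel_size_um + 20)
  roi_set(whole_stem = whole_stem, all_tissue = all_tissue, rind = cls$rind,
          bundles_individual = cls$bundles_individual,
          bundles_all = cls$bundles_all, parenchyma = pa$parenchyma,
          parenchyma_near_rind = pa$parenchyma_near_rind,
          parenchyma_middle = pa$parenchyma_middle,
          pixel_size_um = pixel_size_um,
          rind_damaged = !cls$rind_found || rind_cover < 0.95)
}
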