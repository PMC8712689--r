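#' Raw morphological descriptors from a segmentation
#'
#' Areas by pixel counting (cm^2), stem perimeter by Crofton intercepts
#' (mm).
#'
#' @param rois [roi_set()].
#' @return named list: `St_A_measured`, `St_P`, `Ri_A_measured`, `Pa_A`,
#'   `Vb_A` plus the relative areas are computed later once the estimated
#'   stem area is known.
#' @export
measure_basic <- function(rois) {
  stopifnot(inherits(rois, "roi_set"))
  if (!any(rois$whole_stem)) stop("invalid-input: empty whole_stem")
  px_cm2 <- (rois$pixel_size_um / 1e4)^2
  list(
    St_A_measured = sum(rois$whole_stem) * px_cm2,
    St_P = crofton_perimeter(rois$whole_stem, rois$pixel_size_um / 1000),
    Ri_A_measured = sum(rois$rind) * px_cm2,
    Pa_A = sum(rois$parenchyma & rois$all_tissue) * px_cm2,
    Vb_A = sum(rois$bundles_all) * px_cm2
  )
}

#' Mean rind thickness by binary opening granulometry
#'
#' Openings with square structuring elements of increasing size are applied
#' to the rind mask up to `max_size_um`; the area removed at each step gives
#' the (area-weighted) thickness distribution whose mean is the thickness.
#'
#' @param rind logical rind mask.
#' @param pixel_size_um pixel size.
#' @param max_size_um largest structuring-element size (default 1456).
#' @param step_um granulometry step (default 14.52, i.e. 4 px at 3.63
#'   um/px; the published maximum is kept, the step is an implementation
#'   choice balancing resolution and cost).
#' @return mean thickness in micrometres.
#' @export
rind_thickness <- function(rind, pixel_size_um = 3.63, max_size_um = 1456,
                           step_um = 14.52) {
  if (!any(rind)) stop("invalid-input: empty rind mask")
  sizes <- seq(step_um, max_size_um, by = step_um)
  curve <- graylevel_granulometry(matrix(as.numeric(rind), nrow(rind)),
                                  roi = matrix(TRUE, nrow(rind), ncol(rind)),
                                  transform = "opening",
                                  sizes_um = sizes,
                                  pixel_size_um = pixel_size_um,
                                  baseline_correct = FALSE)
  granulometry_stats(curve)$mean_size_um
}

#' Rind area estimated from thickness and perimeter
#'
#' `Ri_T * St_P` (unit-consistent) minus the calibration offset
#' `diffEstMeas`; negative results are clipped to zero with a warning.
#'
#' @param Ri_T rind thickness, micrometres.
#' @param St_P stem perimeter, millimetres.
#' @param diffEstMeas correction, cm^2 (see [compute_diff_est_meas()]).
#' @return estimated rind area, cm^2.
#' @export
estimate_rind_area <- function(Ri_T, St_P, diffEstMeas = 0) {
  stopifnot(Ri_T > 0, St_P > 0)
  est <- Ri_T * 1e-4 * St_P * 1e-1 - diffEstMeas   # um * mm -> cm^2
  if (est < 0) {
    warning("estimated rind area negative; clipped to 0")
    est <- 0
  }
  est
}

#' Calibration offset between estimated and measured rind areas
#'
#' Mean over undamaged sections of (Ri_T x St_P - measured rind area). The
#' square-structuring-element thickness overestimates on curved bands, so
#' the offset is normally positive.
#'
#' @param sections data.frame with columns `Ri_T` (um), `St_P` (mm),
#'   `Ri_A_measured` (cm^2), `rind_damaged` (logical).
#' @return diffEstMeas in cm^2.
#' @export
compute_diff_est_meas <- function(sections) {
  ok <- !sections$rind_damaged
  if (!any(ok))
    stop("estimation-unavailable: no undamaged section to calibrate on")
  with(sections[ok, , drop = FALSE],
       mean(Ri_T * 1e-4 * St_P * 1e-1 - Ri_A_measured))
}

#' Estimated stem area
#'
#' Measured area when the rind is preserved; otherwise measured area with
#' the measured rind replaced by the estimated rind.
#'
#' @param St_A_measured,Ri_A_measured,Ri_A_est areas in cm^2.
#' @param rind_damaged logical.
#' @return stem area, cm^2.
#' @export
estimate_stem_area <- function(St_A_measured, Ri_A_measured, Ri_A_est,
                               rind_damaged) {
  if (!rind_damaged) St_A_measured
  else St_A_measured - Ri_A_measured + Ri_A_est
}

#' Morphology of individualised vascular bundles
#'
#' Per-bundle area (mm^2) and elongation (minor/major equivalent-ellipse
#' axis, in (0, 1]), plus their means (one value per section).
#'
#' @param bundles_individual integer label map.
#' @param pixel_size_um pixel size.
#' @return list: `Vi_A` (vector, mm^2), `Vi_E` (vector), `Vi_A_mean`,
#'   `Vi_E_mean`.
#' @export
bundle_morphology <- function(bundles_individual, pixel_size_um = 3.63) {
  st <- component_stats(bundles_individual)
  st <- st[st$area_px > 0, , drop = FALSE]
  if (nrow(st) == 0) stop("invalid-input: empty bundle label map")
  vi_a <- st$area_px * (pixel_size_um / 1000)^2
  vi_e <- st$elongation
  list(Vi_A = vi_a, Vi_E = vi_e,
       Vi_A_mean = mean(vi_a), Vi_E_mean = mean(vi_e))
}

#' Bundle count and density
#'
#' The bundle count corrects for merged clusters: total bundle area divided
#' by the mean individual area. Density is count per stem area.
#'
#' @param Vb_A total bundle area, cm^2.
#' @param Vi_A_mean mean individual bundle area, mm^2.
#' @param St_A stem area, cm^2.
#' @return list `Vb_N`, `Vb_D` (per cm^2).
#' @export
bundle_count_density <- function(Vb_A, Vi_A_mean, St_A) {
  if (Vi_A_mean <= 0) stop("invalid-input: non-positive mean bundle area")
  if (St_A <= 0) stop("invalid-input: non-positive stem area")
  Vb_N <- Vb_A * 100 / Vi_A_mean   # cm^2 -> mm^2
  list(Vb_N = Vb_N, Vb_D = Vb_N / St_A)
}

#' Grey-level granulometry
#'
#' Successive closings (or openings) with square structuring elements of
#' increasing size are applied to the image; the change of the summed grey
#' level inside the ROI between consecutive sizes forms the granulometric
#' curve. For closings the sum increases as dark objects smaller than the
#' structuring element are removed ("sieving" of dark objects, here cell
#' lumens), so the curve is a grey-level size distribution of the dark
#' structures. After optional baseline correction (see Details) the curve
#' is renormalised to sum to 100.
#'
#' @details Baseline correction subtracts the smallest increment observed
#' over the largest quartile of sizes (a constant-offset model of the
#' residual variation caused by the general image background), floors at
#' zero and renormalises.
#'
#' @param img numeric matrix.
#' @param roi logical mask over which grey levels are summed.
#' @param transform `"closing"` (dark objects) or `"opening"` (bright).
#' @param sizes_um strictly increasing structuring-element sizes in
#'   micrometres (converted to the nearest odd pixel width).
#' @param pixel_size_um pixel size.
#' @param baseline_correct apply the background baseline correction?
#' @return object of class `granulometric_curve`: list with `sizes_um`,
#'   `values_pct`, `raw_increments`, `transform`, `degenerate`.
#' @export
graylevel_granulometry <- function(img, roi, transform = c("closing", "opening"),
                                   sizes_um = seq(18, 207, by = 7.26),
                                   pixel_size_um = 3.63,
                                   baseline_correct = TRUE) {
  transform <- match.arg(transform)
  stopifnot(is.matrix(img), is.matrix(roi), all(dim(img) == dim(roi)))
  if (!any(roi)) stop("invalid-input: empty ROI")
  if (is.unsorted(sizes_um, strictly = TRUE))
    stop("sizes_um must be strictly increasing")
  ks <- vapply(sizes_um, .odd_px, integer(1), pixel_size_um = pixel_size_um)
  if (max(ks) > min(dim(img)))
    stop("invalid-input: ROI/image smaller than the largest structuring element")
  v <- numeric(length(ks) + 1)
  v[1] <- sum(img[roi])
  prev_k <- 1L
  cur <- img
  lo <- min(img)
  for (i in seq_along(ks)) {
    if (ks[i] > prev_k) {
      cur <- if (transform == "closing") mm_close(img, ks[i]) else mm_open(img, ks[i])
      prev_k <- ks[i]
    }
    v[i + 1] <- sum(cur[roi])
    # openings eventually flatten the image to its minimum; once there the
    # remaining increments are all zero and can be skipped
    if (transform == "opening" && all(cur == lo)) {
      if (i < length(ks)) v[(i + 2):(length(ks) + 1)] <- v[i + 1]
      break
    }
  }
  inc <- diff(v)
  if (transform == "opening") inc <- -inc
  total <- sum(inc)
  degenerate <- total <= 0 || all(inc == 0)
  values <- inc
  if (!degenerate) {
    if (baseline_correct) {
      tail_idx <- which(sizes_um >= quantile(sizes_um, 0.75))
      base <- min(inc[tail_idx])
      values <- pmax(inc - base, 0)
      if (sum(values) <= 0) {
        degenerate <- TRUE
        values <- inc
      }
    }
    if (!degenerate) values <- values / sum(values) * 100
  }
  structure(list(sizes_um = sizes_um, values_pct = values,
                 raw_increments = inc, transform = transform,
                 degenerate = degenerate),
            class = "granulometric_curve")
}

#' @export
print.granulometric_curve <- function(x, ...) {
  cat("granulometric_curve (", x$transform, "), ",
      length(x$sizes_um), " sizes ",
      min(x$sizes_um), "-", max(x$sizes_um), " um",
      if (x$degenerate) ", DEGENERATE" else "", "\n", sep = "")
  invisible(x)
}

#' @export
plot.granulometric_curve <- function(x, ...) {
  graphics::plot(x$sizes_um, x$values_pct, type = "b",
                 xlab = "structuring element size (um)",
                 ylab = "% grey-level variation", ...)
  invisible(x)
}

#' Grey-level mean size and standard deviation of a granulometric curve
#'
#' First and second moments of the normalised size distribution.
#'
#' @param curve [graylevel_granulometry()] output (normalised, sum 100).
#' @return list `mean_size_um`, `sd_size_um`.
#' @export
granulometry_stats <- function(curve) {
  stopifnot(inherits(curve, "granulometric_curve"))
  if (curve$degenerate)
    stop("undefined-stats: degenerate granulometric curve")
  w <- curve$values_pct / 100
  m <- sum(curve$sizes_um * w)
  s <- sqrt(sum((curve$sizes_um - m)^2 * w))
  list(mean_size_um = m, sd_size_um = s)
}

#' All morphological descriptors for one section
#'
#' Convenience wrapper running [measure_basic()], [rind_thickness()],
#' bundle morphology, granulometric cell sizing and the estimation
#' formulas. `diffEstMeas` defaults to 0 (single-section use); recompute
#' descriptors after calibrating on a cohort with
#' [compute_diff_est_meas()].
#'
#' @param rois [roi_set()].
#' @param img darkfield grey image on the same grid.
#' @param diffEstMeas rind-area calibration offset, cm^2.
#' @param granulo_sizes_um sizes for the parenchyma cell granulometry.
#' @return object of class `stem_descriptors` (named list).
#' @export
stem_descriptors <- function(rois, img, diffEstMeas = 0,
                             granulo_sizes_um = seq(18, 207, by = 7.26)) {
  b <- measure_basic(rois)
  Ri_T <- if (any(rois$rind))
    rind_thickness(rois$rind, rois$pixel_size_um) else NA_real_
  Ri_A_est <- if (!is.na(Ri_T))
    estimate_rind_area(Ri_T, b$St_P, diffEstMeas) else b$Ri_A_measured
  St_A <- estimate_stem_area(b$St_A_measured, b$Ri_A_measured, Ri_A_est,
                             isTRUE(rois$rind_damaged))
  Ri_A_used <- if (isTRUE(rois$rind_damaged)) Ri_A_est else b$Ri_A_measured
  bm <- if (max(rois$bundles_individual) > 0)
    bundle_morphology(rois$bundles_individual, rois$pixel_size_um)
  else list(Vi_A = numeric(), Vi_E = numeric(),
            Vi_A_mean = NA_real_, Vi_E_mean = NA_real_)
  bc <- if (!is.na(bm$Vi_A_mean))
    bundle_count_density(b$Vb_A, bm$Vi_A_mean, St_A)
  else list(Vb_N = NA_real_, Vb_D = NA_real_)
  cell <- function(mask) {
    if (sum(mask) * rois$pixel_size_um^2 < 1e5)  # needs a workable ROI
      return(list(mean_size_um = NA_real_, sd_size_um = NA_real_))
    cv <- graylevel_granulometry(img, mask, "closing", granulo_sizes_um,
                                 rois$pixel_size_um)
    if (cv$degenerate) list(mean_size_um = NA_real_, sd_size_um = NA_real_)
    else granulometry_stats(cv)
  }
  pm <- cell(rois$parenchyma_middle)
  pr <- cell(rois$parenchyma_near_rind)
  out <- list(
    St_A = St_A, St_A_measured = b$St_A_measured, St_P = b$St_P,
    Ri_A_measured = b$Ri_A_measured, Ri_A_est = Ri_A_est, Ri_T = Ri_T,
    Pa_A = b$Pa_A, Vb_A = b$Vb_A,
    Vi_A_mean = bm$Vi_A_mean, Vi_E_mean = bm$Vi_E_mean,
    Vb_N = bc$Vb_N, Vb_D = bc$Vb_D,
    rel_Pa = b$Pa_A / St_A * 100,
    rel_Ri = Ri_A_used / St_A * 100,
    rel_Vb = b$Vb_A / St_A * 100,
    Pm_Cd = pm$mean_size_um, Pm_Cs = pm$sd_size_um,
    Pr_Cd = pr$mean_size_um, Pr_Cs = pr$sd_size_um,
    middle_area = sum(rois$parenchyma_middle) * (rois$pixel_size_um / 1e4)^2,
    rind_damaged = isTRUE(rois$rind_damaged)
  )
  structure(out, class = "stem_descriptors")
}

#' @export
print.stem_descriptors <- function(x, ...) {
  cat("stem_descriptors\n")
  cat(sprintf("  St(A) %.3f cm2   St(P) %.1f mm   Ri(T) %.0f um%s\n",
              x$St_A, x$St_P, x$Ri_T,
              if (x$rind_damaged) "  [rind damaged]" else ""))
  cat(sprintf("  relative areas: Pa %.1f%%  Ri %.1f%%  Vb %.1f%%\n",
              x$rel_Pa, x$rel_Ri, x$rel_Vb))
  cat(sprintf("  bundles: Vi(A) %.3f mm2  Vi(E) %.2f  Vb(D) %.1f /cm2\n",
              x$Vi_A_mean, x$Vi_E_mean, x$Vb_D))
  cat(sprintf("  cell sizes: Pm(Cd) %.1f um  Pr(Cd) %.1f um\n",
              x$Pm_Cd, x$Pr_Cd))
  invisible(x)
}
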