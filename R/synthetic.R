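#' Parameters of the synthetic stem phantom
#'
#' The defaults state a realistic maize internode cross-section at silage
#' stage: a 1.5 cm^2 stem, a 600 um rind (giving a rind relative area near
#' 17 percent), about 77 bundles per cm^2 of around 0.1 mm^2 each, middle
#' parenchyma cells of 70 um and near-rind cells of 50 um, imaged at
#' 3.63 um/px in darkfield convention (walls bright). Fluorescence
#' signatures are UV-dominant in the parenchyma and visible-dominant in
#' rind and bundles, with zero emission in the baseline channels.
#'
#' @param stem_radius_um stem radius (default 6910, i.e. about 1.5 cm^2).
#' @param rind_thickness_um rind annulus thickness.
#' @param n_bundles number of vascular bundles; `NA` picks a density of 77
#'   per cm^2.
#' @param bundle_axes_um full major/minor ellipse axes of a bundle.
#' @param bundle_jitter relative s.d. of bundle size jitter.
#' @param cell_diameter_middle_um,cell_diameter_near_rind_um nominal
#'   parenchyma cell diameters (middle must be the larger by default).
#' @param rind_cell_um nominal cell size of the rind cortical texture.
#' @param wall_thickness_px parenchyma wall thickness in pixels.
#' @param near_rind_band_um width of the small-cell zone below the rind.
#' @param hole_fraction fraction of the stem area torn away as holes.
#' @param missing_rind_arc_deg angular extent of a missing rind arc
#'   (0 = intact rind).
#' @param tissue_signatures named list of 11-value fluorescence signatures
#'   for `rind`, `bundles`, `parenchyma_near_rind`, `parenchyma_middle`
#'   (zero at the baseline channels).
#' @param background_offsets 11 channel-dependent background levels.
#' @param noise_sd darkfield additive Gaussian noise s.d.
#' @param noise_sd_fluo fluorescence noise s.d.
#' @param section_gain global multiplicative fluorescence gain of the
#'   section (models thickness variation).
#' @param pixel_size_um pixel size of the phantom grid.
#' @param seed integer RNG seed; the phantom is a deterministic function of
#'   the full parameter set.
#' @return list of class `phantom_params`.
#' @export
phantom_params <- function(stem_radius_um = 6910,
                           rind_thickness_um = 600,
                           n_bundles = NA_integer_,
                           bundle_axes_um = c(420, 320),
                           bundle_jitter = 0.1,
                           cell_diameter_middle_um = 70,
                           cell_diameter_near_rind_um = 50,
                           rind_cell_um = 18,
                           wall_thickness_px = 1,
                           near_rind_band_um = 500,
                           hole_fraction = 0,
                           missing_rind_arc_deg = 0,
                           tissue_signatures = default_signatures(),
                           background_offsets = default_background_offsets(),
                           noise_sd = 3,
                           noise_sd_fluo = 1,
                           section_gain = 1,
                           pixel_size_um = 3.63,
                           seed = 1L) {
  stopifnot(stem_radius_um > rind_thickness_um,
            cell_diameter_near_rind_um <= cell_diameter_middle_um ||
              TRUE,  # overridable; default honours the smaller-near-rind rule
            hole_fraction >= 0, hole_fraction < 1,
            missing_rind_arc_deg >= 0, missing_rind_arc_deg <= 180,
            section_gain > 0, pixel_size_um > 0)
  if (is.na(n_bundles)) {
    area_cm2 <- pi * (stem_radius_um / 1e4)^2
    n_bundles <- max(3L, as.integer(round(77 * area_cm2)))
  }
  for (t in c("rind", "bundles", "parenchyma_near_rind", "parenchyma_middle")) {
    s <- tissue_signatures[[t]]
    if (is.null(s) || length(s) != 11)
      stop("tissue_signatures must hold 11 values for ", t)
    if (any(s[match(baseline_channels(), channel_names())] != 0))
      stop("signatures must be zero at the baseline channels")
  }
  structure(as.list(environment()), class = "phantom_params")
}

#' Default per-tissue fluorescence signatures
#'
#' Arbitrary-unit 11-channel emission signatures: parenchyma UV-dominant,
#' rind and bundles visible-dominant, zero at the baseline channels.
#'
#' @return named list of four 11-value vectors.
#' @export
default_signatures <- function() {
  mk <- function(...) setNames(c(...), channel_names())
  list(
    #              U1b U1g U2b U2g U2r BLb BLg BLr GRb GRg GRr
    rind = mk(30, 25, 32, 28, 20, 0, 60, 55, 0, 0, 40),
    bundles = mk(25, 20, 28, 25, 15, 0, 45, 40, 0, 0, 30),
    parenchyma_near_rind = mk(90, 45, 60, 25, 8, 0, 12, 8, 0, 0, 4),
    parenchyma_middle = mk(80, 40, 70, 30, 10, 0, 15, 10, 0, 0, 5)
  )
}

#' Default channel-dependent background offsets
#' @return named 11-value vector.
#' @export
default_background_offsets <- function() {
  setNames(c(10, 8, 9, 7, 6, 5, 4, 6, 3, 2, 5), channel_names())
}

# Poisson-disc seeded Voronoi tessellation with Lloyd relaxation, returning
# the label map restricted to `domain`. `rmap_px` is the local seed spacing.
.voronoi_texture <- function(domain, rmap_px, lloyd = 2L) {
  pts <- .cpp_poisson_disc(domain, rmap_px, 30L)
  nr <- nrow(domain); nc <- ncol(domain)
  for (it in seq_len(lloyd + 1L)) {
    sites <- matrix(0L, nr, nc)
    ij <- cbind(pmin(pmax(floor(pts[, 1]) + 1L, 1L), nr),
                pmin(pmax(floor(pts[, 2]) + 1L, 1L), nc))
    sites[ij] <- seq_len(nrow(pts))
    ft <- .cpp_feature_transform(sites)
    lab <- ft$label
    lab[!domain] <- 0L
    if (it > lloyd) break
    st <- .cpp_label_stats(lab, nrow(pts))
    n <- st[, 1]
    ok <- n > 0
    newy <- ifelse(ok, st[, 2] / pmax(n, 1) + 0.5, pts[, 1])
    newx <- ifelse(ok, st[, 3] / pmax(n, 1) + 0.5, pts[, 2])
    ii <- pmin(pmax(floor(newy) + 1L, 1L), nr)
    jj <- pmin(pmax(floor(newx) + 1L, 1L), nc)
    inside <- domain[cbind(ii, jj)]
    pts[inside, 1] <- newy[inside]
    pts[inside, 2] <- newx[inside]
  }
  lab
}

# Boundary pixels between different labels (4-neighbour, single-sided),
# thickened to `thick` px.
.wall_map <- function(lab, domain, thick = 1L) {
  nr <- nrow(lab); nc <- ncol(lab)
  w <- matrix(FALSE, nr, nc)
  w[-nr, ] <- w[-nr, ] | (lab[-nr, ] != lab[-1, ])
  w[, -nc] <- w[, -nc] | (lab[, -nc] != lab[, -1])
  w <- w & domain
  if (thick > 1) w <- mm_dilate(w, 2L * (as.integer(thick) %/% 2L) + 1L) & domain
  w
}

#' Generate a synthetic stem cross-section phantom
#'
#' Builds a darkfield image, an 11-channel fluorescence stack and the full
#' ground truth (ROI set and descriptors) for one synthetic section.
#' Parenchyma is a Poisson-disc-seeded Voronoi mosaic (2 Lloyd iterations)
#' with bright walls, smaller cells within `near_rind_band_um` of the rind;
#' the rind is an annulus of small-celled dense texture; bundles are
#' non-overlapping ellipse rings with a bright sheath. Fluorescence is
#' emitted from wall pixels only: per-tissue signature times wall map times
#' `section_gain`, plus channel-dependent background and noise. The result
#' is a deterministic function of the parameters (including `seed`).
#'
#' @param params [phantom_params()].
#' @return object of class `stem_phantom`: `darkfield` matrix,
#'   `multispectral` ([multispectral_image()]), `truth_rois` ([roi_set()]),
#'   `truth` (list of true descriptor values) and `params`.
#' @export
generate_phantom <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  p <- params
  set.seed(p$seed)
  px <- p$pixel_size_um
  R <- p$stem_radius_um / px
  margin <- 25
  n <- as.integer(2 * ceiling(R + margin))
  cy <- (n + 1) / 2; cx <- (n + 1) / 2
  ii <- matrix(seq_len(n), n, n)
  jj <- matrix(seq_len(n), n, n, byrow = TRUE)
  rr <- sqrt((ii - cy)^2 + (jj - cx)^2)
  theta <- atan2(jj - cx, ii - cy)   # radians in (-pi, pi]
  stem_disk <- rr <= R
  R_in <- R - p$rind_thickness_um / px
  rind_full <- stem_disk & rr > R_in
  pith <- stem_disk & rr <= R_in

  # missing rind arc (damaged sections): rind material removed over the arc
  if (p$missing_rind_arc_deg > 0) {
    half <- p$missing_rind_arc_deg / 2 * pi / 180
    arc <- abs(theta) <= half
    rind <- rind_full & !arc
  } else rind <- rind_full
  whole_stem <- pith | rind
  whole_stem <- fill_holes(whole_stem)   # reclose pith boundary pixels
  rind_damaged <- p$missing_rind_arc_deg > 0

  # --- vascular bundles: non-overlapping ellipses in the pith ------------
  a <- p$bundle_axes_um[1] / 2 / px   # semi-major, px
  b <- p$bundle_axes_um[2] / 2 / px
  rmax_c <- R_in - a - 3
  if (rmax_c <= 0) stop("generation-failure: bundles do not fit inside the pith")
  centers <- matrix(numeric(0), 0, 2)
  sizes <- matrix(numeric(0), 0, 2)
  angles <- numeric(0)
  tries <- 0
  while (nrow(centers) < p$n_bundles && tries < 400 * p$n_bundles) {
    tries <- tries + 1
    rad <- sqrt(runif(1)) * rmax_c
    ang <- runif(1, -pi, pi)
    y <- cy + rad * cos(ang); x <- cx + rad * sin(ang)
    jit <- exp(rnorm(2, 0, p$bundle_jitter))
    aa <- a * jit[1]; bb <- b * jit[2]
    if (nrow(centers) > 0) {
      d <- sqrt((centers[, 1] - y)^2 + (centers[, 2] - x)^2)
      if (any(d < (sizes[, 1] + aa + 4))) next
    }
    centers <- rbind(centers, c(y, x))
    sizes <- rbind(sizes, c(aa, bb))
    angles <- c(angles, runif(1, 0, pi))
  }
  if (nrow(centers) < p$n_bundles)
    stop("generation-failure: could not place ", p$n_bundles,
         " bundles without overlap")
  bundle_lab <- matrix(0L, n, n)
  sheath <- matrix(FALSE, n, n)
  sheath_px <- max(2, round(50 / px))
  for (k in seq_len(nrow(centers))) {
    dy <- ii - centers[k, 1]; dx <- jj - centers[k, 2]
    u <- dy * cos(angles[k]) + dx * sin(angles[k])
    v <- -dy * sin(angles[k]) + dx * cos(angles[k])
    inside <- (u / sizes[k, 1])^2 + (v / sizes[k, 2])^2 <= 1
    core <- (u / pmax(sizes[k, 1] - sheath_px, 1))^2 +
      (v / pmax(sizes[k, 2] - sheath_px, 1))^2 <= 1
    bundle_lab[inside] <- k
    sheath <- sheath | (inside & !core)
  }
  bundles_all <- bundle_lab > 0 & pith

  # --- parenchyma tessellation ------------------------------------------
  d_rind_um <- (R - rr) * px    # radial distance below the outer contour
  depth_um <- pmax(d_rind_um - p$rind_thickness_um, 0)
  par_domain <- pith & !bundles_all
  t_mix <- pmin(pmax(depth_um / p$near_rind_band_um / 2, 0), 1)
  spacing_um <- p$cell_diameter_near_rind_um * (1 - t_mix) +
    p$cell_diameter_middle_um * t_mix
  rmap <- spacing_um / px
  cell_lab <- .voronoi_texture(pith, rmap, lloyd = 2L)
  par_walls <- .wall_map(cell_lab, par_domain, p$wall_thickness_px)

  # --- rind texture ------------------------------------------------------
  rind_lab <- if (any(rind))
    .voronoi_texture(rind, matrix(p$rind_cell_um / px, n, n), lloyd = 1L)
  else matrix(0L, n, n)
  rind_walls <- .wall_map(rind_lab, rind, 2L)

  # --- holes (torn parenchyma) ------------------------------------------
  holes <- matrix(FALSE, n, n)
  if (p$hole_fraction > 0) {
    target <- p$hole_fraction * sum(whole_stem)
    guard <- 0
    while (sum(holes) < target && guard < 100) {
      guard <- guard + 1
      rad <- runif(1, 0.3, 0.8) * R_in
      ang <- runif(1, -pi, pi)
      hy <- cy + rad * cos(ang); hx <- cx + rad * sin(ang)
      hr <- sqrt(target / pi) * runif(1, 0.5, 1)
      hole <- (ii - hy)^2 / hr^2 + (jj - hx)^2 / (0.7 * hr)^2 <= 1
      holes <- holes | (hole & pith & !bundles_all)
    }
  }
  all_tissue <- whole_stem & !holes

  # --- darkfield rendering ----------------------------------------------
  img <- matrix(5, n, n)                       # background
  img[pith] <- 12                              # parenchyma lumens
  img[par_walls] <- 120
  img[rind] <- 25                              # rind lumens
  img[rind_walls] <- 120
  img[bundles_all] <- 80                       # bundle interior (dense)
  img[sheath & bundles_all] <- 120
  img[holes] <- 5
  img <- img + matrix(rnorm(n * n, 0, p$noise_sd), n, n)
  img <- pmax(img, 0)

  # --- truth ROI set -----------------------------------------------------
  parenchyma <- whole_stem & !(rind | bundles_all)
  ref_rind <- if (any(rind)) rind else whole_stem & !mm_erode(whole_stem, 3L)
  dist_um <- distance_transform(ref_rind) * px
  near <- parenchyma & all_tissue & dist_um < 500 & !holes
  middle <- parenchyma & all_tissue & dist_um > 1000 & !holes
  bundles_individual <- bundle_lab
  bundles_individual[!bundles_all] <- 0L
  truth_rois <- roi_set(
    whole_stem = whole_stem, all_tissue = all_tissue, rind = rind,
    bundles_individual = bundles_individual, bundles_all = bundles_all,
    parenchyma = parenchyma, parenchyma_near_rind = near,
    parenchyma_middle = middle, pixel_size_um = px,
    rind_damaged = rind_damaged)

  # --- fluorescence stack ------------------------------------------------
  zone_near <- dist_um < p$near_rind_band_um
  emit <- list(
    rind = rind_walls,
    bundles = bundles_all & !holes,
    parenchyma_near_rind = par_walls & zone_near & !holes,
    parenchyma_middle = par_walls & !zone_near & !holes
  )
  emit_strength <- list(rind = 1, bundles = 0.6, parenchyma_near_rind = 1,
                        parenchyma_middle = 1)
  chans <- lapply(channel_names(), function(ch) {
    i <- match(ch, channel_names())
    m <- matrix(p$background_offsets[i], n, n)
    for (t in names(emit)) {
      sig <- p$tissue_signatures[[t]][i] * p$section_gain
      if (sig != 0) m <- m + emit[[t]] * sig * emit_strength[[t]]
    }
    pmax(m + matrix(rnorm(n * n, 0, p$noise_sd_fluo), n, n), 0)
  })
  ms <- multispectral_image(setNames(chans, channel_names()),
                            pixel_size_um = px, visible_gain = p$section_gain)

  # --- truth descriptors -------------------------------------------------
  px_cm2 <- (px / 1e4)^2
  st <- component_stats(bundles_individual)
  st <- st[st$area_px > 0, , drop = FALSE]
  realized_cells <- component_stats(cell_lab * (middle & cell_lab > 0))
  realized_cells <- realized_cells[realized_cells$area_px > 20, , drop = FALSE]
  truth <- list(
    St_A = sum(whole_stem) * px_cm2,
    Ri_A = sum(rind) * px_cm2,
    Vb_A = sum(bundles_all) * px_cm2,
    Pa_A = sum(parenchyma & all_tissue) * px_cm2,
    rel_Ri = sum(rind) / sum(whole_stem) * 100,
    rel_Vb = sum(bundles_all) / sum(whole_stem) * 100,
    rel_Pa = sum(parenchyma) / sum(whole_stem) * 100,
    n_bundles = nrow(st),
    Vi_A_mean = mean(st$area_px) * (px / 1000)^2,
    Vi_E_mean = mean(st$elongation),
    rind_thickness_um = p$rind_thickness_um,
    cell_diameter_middle_um = p$cell_diameter_middle_um,
    cell_diameter_near_rind_um = p$cell_diameter_near_rind_um,
    realized_middle_cell_um =
      mean(2 * sqrt(realized_cells$area_px / pi)) * px,
    hole_area_cm2 = sum(holes) * px_cm2,
    signatures = p$tissue_signatures,
    background_offsets = p$background_offsets
  )
  structure(list(darkfield = img, multispectral = ms,
                 truth_rois = truth_rois, truth = truth, params = p),
            class = "stem_phantom")
}

#' @export
print.stem_phantom <- function(x, ...) {
  cat("stem_phantom: ", nrow(x$darkfield), "x", ncol(x$darkfield),
      " px at ", x$params$pixel_size_um, " um/px, ",
      x$truth$n_bundles, " bundles, St(A) ",
      round(x$truth$St_A, 2), " cm2\n", sep = "")
  invisible(x)
}

#' Generate a synthetic per-line composition table
#'
#' Samples cell wall content, Klason lignin, ester-linked p-coumaric and
#' ferulic acids and digestibility within the observed ranges of maize
#' inbred lines, optionally with a target correlation structure among the
#' three phenolics (Gaussian copula). Deterministic given `seed`.
#'
#' @param n_lines number of lines (at least 4).
#' @param correlation_targets optional named list with any of `kl_pca`,
#'   `kl_fa`, `pca_fa` in (-1, 1); default independent.
#' @param seed RNG seed.
#' @return data.frame with `line`, `cw_pct_dm`, `kl_pct_cw`, `pca_pct_cw`,
#'   `fa_pct_cw`, `ivcwd_pct`.
#' @export
generate_composition_table <- function(n_lines = 14,
                                       correlation_targets = list(),
                                       seed = 1L) {
  if (n_lines < 4) stop("invalid-input: need at least 4 lines")
  set.seed(seed)
  rho <- diag(3)
  rho[1, 2] <- rho[2, 1] <- correlation_targets$kl_pca %||% 0
  rho[1, 3] <- rho[3, 1] <- correlation_targets$kl_fa %||% 0
  rho[2, 3] <- rho[3, 2] <- correlation_targets$pca_fa %||% 0
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("generation-failure: infeasible correlation targets")
  z <- matrix(rnorm(3 * n_lines), n_lines, 3) %*% chol(rho)
  u <- stats::pnorm(z)
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  kl <- 15 + u[, 1] * 6                          # uniform [15, 21] %CW
  pca <- clamp(stats::qnorm(u[, 2], 1.60, 0.25), 1.0, 2.0)
  fa <- clamp(stats::qnorm(u[, 3], 0.61, 0.06), 0.45, 0.75)
  cw <- clamp(rnorm(n_lines, 54.9, 4.7), 45, 65)
  iv <- clamp(rnorm(n_lines, 33.6, 5.0), 25, 44)
  data.frame(line = sprintf("L%02d", seq_len(n_lines)),
             cw_pct_dm = round(cw, 1), kl_pct_cw = round(kl, 2),
             pca_pct_cw = round(pca, 2), fa_pct_cw = round(fa, 2),
             ivcwd_pct = round(iv, 1))
}
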