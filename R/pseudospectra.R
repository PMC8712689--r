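#' Per-tissue autofluorescence pseudospectrum
#'
#' An 11-value vector of mean fluorescence intensities in canonical channel
#' order, with flags recording the corrections already applied. Values may
#' be slightly negative only after background subtraction.
#'
#' @param values numeric vector of length 11 (canonical channel order).
#' @param tissue one of `"rind"`, `"bundles"`, `"parenchyma_near_rind"`,
#'   `"parenchyma_middle"`, `"background"`.
#' @param background_corrected,density_corrected,section_normalized flags.
#' @param n_pixels number of pixels averaged.
#' @return object of class `pseudospectrum`.
#' @export
pseudospectrum <- function(values, tissue,
                           background_corrected = FALSE,
                           density_corrected = FALSE,
                           section_normalized = FALSE,
                           n_pixels = NA_integer_) {
  tissue <- match.arg(tissue, c("rind", "bundles", "parenchyma_near_rind",
                                "parenchyma_middle", "background"))
  if (length(values) != 11) stop("a pseudospectrum has exactly 11 values")
  values <- setNames(as.numeric(values), channel_names())
  if (!background_corrected && any(values < 0))
    stop("negative intensities are only allowed after background subtraction")
  if (background_corrected && any(values < -0.01 * max(abs(values))))
    warning("background-corrected values below -1% of the spectrum maximum")
  structure(list(values = values, tissue = tissue,
                 background_corrected = background_corrected,
                 density_corrected = density_corrected,
                 section_normalized = section_normalized,
                 n_pixels = n_pixels),
            class = "pseudospectrum")
}

#' @export
print.pseudospectrum <- function(x, ...) {
  flags <- c("bg" = x$background_corrected, "dens" = x$density_corrected,
             "norm" = x$section_normalized)
  cat("pseudospectrum [", x$tissue, "] ",
      paste(names(flags)[flags], collapse = "+"),
      if (!any(flags)) "raw", "\n", sep = "")
  print(round(x$values, 4))
  invisible(x)
}

#' @export
plot.pseudospectrum <- function(x, ...) {
  graphics::plot(seq_len(11), pmax(x$values, 0), type = "b", xaxt = "n",
                 xlab = "channel", ylab = "intensity", ...)
  graphics::axis(1, at = seq_len(11), labels = names(x$values), las = 2)
  invisible(x)
}

#' Background pseudospectrum from signal-free regions
#'
#' Channel-wise mean over the pooled pixels of one or more signal-free
#' regions. In unattended runs the regions can come from
#' [auto_background_mask()].
#'
#' @param ms [multispectral_image()].
#' @param bg_rois list of logical masks (each at least `min_pixels` px).
#' @param min_pixels minimum region size.
#' @return background-tissue [pseudospectrum()].
#' @export
background_spectrum <- function(ms, bg_rois, min_pixels = 100) {
  stopifnot(inherits(ms, "multispectral_image"))
  if (is.matrix(bg_rois)) bg_rois <- list(bg_rois)
  if (length(bg_rois) == 0) stop("invalid-input: no background region")
  pooled <- Reduce(`|`, bg_rois)
  for (r in bg_rois)
    if (sum(r) < min_pixels)
      stop("invalid-input: background region smaller than ", min_pixels, " px")
  vals <- vapply(ms$channels, function(ch) mean(ch[pooled]), numeric(1))
  pseudospectrum(vals, "background", n_pixels = sum(pooled))
}

#' Automatic background mask
#'
#' Darkest fraction of the pixels outside the whole-stem mask of the
#' summed-intensity image; a surrogate for manually selected signal-free
#' regions.
#'
#' @param ms [multispectral_image()].
#' @param whole_stem stem mask on the same grid (or `NULL` to use the whole
#'   image).
#' @param fraction darkest fraction to keep (default 0.01).
#' @return logical mask.
#' @export
auto_background_mask <- function(ms, whole_stem = NULL, fraction = 0.01) {
  s <- sum_image(ms, "all")
  outside <- if (is.null(whole_stem)) matrix(TRUE, nrow(s), ncol(s)) else !whole_stem
  thr <- quantile(s[outside], fraction)
  outside & s <= thr
}

#' Mean tissue pseudospectrum with background subtraction
#'
#' Channel-wise mean over the tissue ROI minus the background spectrum.
#'
#' @param ms [multispectral_image()].
#' @param roi logical tissue mask.
#' @param bg background [pseudospectrum()].
#' @param tissue tissue name for the result.
#' @return background-corrected [pseudospectrum()].
#' @export
tissue_pseudospectrum <- function(ms, roi, bg,
                                  tissue = c("rind", "bundles",
                                             "parenchyma_near_rind",
                                             "parenchyma_middle")) {
  stopifnot(inherits(ms, "multispectral_image"))
  tissue <- match.arg(tissue)
  if (!any(roi)) stop("invalid-input: empty tissue ROI")
  if (!inherits(bg, "pseudospectrum") || bg$tissue != "background")
    stop("bg must be a background pseudospectrum")
  vals <- vapply(ms$channels, function(ch) mean(ch[roi]), numeric(1))
  pseudospectrum(vals - bg$values, tissue,
                 background_corrected = TRUE, n_pixels = sum(roi))
}

#' Correct a parenchyma pseudospectrum for cell wall density
#'
#' Parenchyma ROIs contain mostly lumen; dividing by the cell wall density
#' estimates the fluorescence of the walls alone. Only valid for
#' parenchyma-type spectra.
#'
#' @param spec a parenchyma [pseudospectrum()].
#' @param Cw_D cell wall density, percent of volume.
#' @return density-corrected [pseudospectrum()].
#' @export
density_correct <- function(spec, Cw_D) {
  stopifnot(inherits(spec, "pseudospectrum"))
  if (!spec$tissue %in% c("parenchyma_near_rind", "parenchyma_middle"))
    stop("invalid-operation: density correction applies to parenchyma spectra only")
  if (Cw_D <= 0) stop("invalid-input: non-positive cell wall density")
  out <- spec
  out$values <- spec$values / (Cw_D / 100)
  out$density_corrected <- TRUE
  out
}

#' Section normalisation of the four tissue pseudospectra
#'
#' For each tissue the mean over the 11 channels is computed; the section
#' factor `Fn` is the mean of the four tissue means, and every spectrum is
#' divided by it. Removes the section-dependent global intensity
#' (thickness) effect: scaling all channels by a common factor leaves the
#' normalised spectra unchanged.
#'
#' @param specs list of exactly four pseudospectra (rind, bundles and the
#'   two parenchyma zones, background-corrected; parenchyma ones
#'   density-corrected).
#' @return list with `specs` (normalised) and `Fn`.
#' @export
section_normalize <- function(specs) {
  if (length(specs) != 4) stop("exactly four tissue spectra are required")
  tissues <- vapply(specs, function(s) s$tissue, character(1))
  if (!setequal(tissues, c("rind", "bundles", "parenchyma_near_rind",
                           "parenchyma_middle")))
    stop("need one spectrum per tissue: rind, bundles, parenchyma_near_rind, ",
         "parenchyma_middle")
  for (s in specs) {
    if (!s$background_corrected)
      stop("spectra must be background-corrected before normalisation")
    if (s$tissue %in% c("parenchyma_near_rind", "parenchyma_middle") &&
        !s$density_corrected)
      stop("parenchyma spectra must be density-corrected before normalisation")
  }
  tissue_means <- vapply(specs, function(s) mean(s$values), numeric(1))
  Fn <- mean(tissue_means)
  if (Fn <= 0) stop("normalization-failure: non-positive section factor")
  out <- lapply(specs, function(s) {
    s$values <- s$values / Fn
    s$section_normalized <- TRUE
    s
  })
  names(out) <- tissues
  list(specs = out, Fn = Fn)
}

#' Pseudospectra of all tissues of one section
#'
#' Measures, background-corrects, density-corrects and section-normalises
#' the four tissue pseudospectra of one multispectral image.
#'
#' @param ms [multispectral_image()].
#' @param rois [roi_set()] on the same grid.
#' @param bg background [pseudospectrum()]; when `NULL`, an automatic
#'   background mask is used.
#' @param Pm_CD,Pr_CD parenchyma cell wall densities, percent.
#' @return list with `specs`, `Fn`, `bg`.
#' @export
section_pseudospectra <- function(ms, rois, Pm_CD, Pr_CD, bg = NULL) {
  stopifnot(inherits(rois, "roi_set"))
  if (is.null(bg)) {
    bgmask <- auto_background_mask(ms, rois$whole_stem)
    bg <- background_spectrum(ms, bgmask, min_pixels = 50)
  }
  raw <- list(
    tissue_pseudospectrum(ms, rois$rind, bg, "rind"),
    tissue_pseudospectrum(ms, rois$bundles_all, bg, "bundles"),
    density_correct(
      tissue_pseudospectrum(ms, rois$parenchyma_near_rind, bg,
                            "parenchyma_near_rind"), Pr_CD),
    density_correct(
      tissue_pseudospectrum(ms, rois$parenchyma_middle, bg,
                            "parenchyma_middle"), Pm_CD)
  )
  n <- section_normalize(raw)
  c(n, list(bg = bg))
}
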