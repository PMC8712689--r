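#' Canonical fluorescence channel names
#'
#' The 11 channels of the multispectral autofluorescence image, ordered from
#' high- to low-energy excitation: blue, green (and red) channels of the RGB
#' captures taken through the U1, U2, BL (blue) and GR (green) filter cubes.
#' U1r is excluded at assembly because it carries excitation-band reflection.
#'
#' @return character vector of length 11.
#' @export
channel_names <- function() {
  c("U1b", "U1g", "U2b", "U2g", "U2r",
    "BLb", "BLg", "BLr", "GRb", "GRg", "GRr")
}

#' Baseline (no-emission) channels
#'
#' Channels where no photon can physically be emitted (emission wavelength
#' below the excitation wavelength): `BLb`, `GRb`, `GRg`. They are retained
#' in every pseudospectrum as a baseline. The set is configurable because
#' instrument configurations may differ.
#'
#' @return character vector.
#' @export
baseline_channels <- function() c("BLb", "GRb", "GRg")

#' Channels summed in the "visible fluorescence" image
#' @return character vector.
#' @export
visible_channels <- function() c("BLg", "BLr", "GRr")

#' A single filter-cube RGB capture
#'
#' @param filter one of `"U1"`, `"U2"`, `"BL"`, `"GR"`.
#' @param r,g,b numeric matrices of identical dimension, non-negative.
#' @return object of class `filter_capture`.
#' @export
filter_capture <- function(filter, r, g, b) {
  filter <- match.arg(filter, c("U1", "U2", "BL", "GR"))
  if (!all(dim(r) == dim(g)) || !all(dim(r) == dim(b)))
    stop("r, g, b grids must share identical dimensions")
  if (min(r, g, b) < 0) stop("capture intensities must be non-negative")
  structure(list(filter = filter, r = r, g = g, b = b),
            class = "filter_capture")
}

#' Multispectral 11-channel image
#'
#' Container for the named channel grids plus pixel size. Intensities are
#' stored as non-negative reals; bit depth is a reader concern.
#'
#' @param channels named list of 11 numeric matrices in canonical order.
#' @param pixel_size_um pixel size in micrometres (default 2.78).
#' @param visible_gain gain that was applied to BL/GR captures (provenance).
#' @return object of class `multispectral_image`.
#' @export
multispectral_image <- function(channels, pixel_size_um = 2.78,
                                visible_gain = NA_real_) {
  cn <- channel_names()
  if (!identical(sort(names(channels)), sort(cn)))
    stop("channels must be named exactly: ", paste(cn, collapse = ", "))
  channels <- channels[cn]
  d <- dim(channels[[1]])
  for (ch in channels) {
    if (!is.matrix(ch) || !all(dim(ch) == d))
      stop("all channel grids must be matrices of identical dimensions")
    if (min(ch) < 0) stop("channel intensities must be non-negative")
  }
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 visible_gain = visible_gain),
            class = "multispectral_image")
}

#' @export
print.multispectral_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("multispectral_image: 11 channels, ", d[1], "x", d[2],
      " px, ", x$pixel_size_um, " um/px\n", sep = "")
  invisible(x)
}

#' @export
dim.multispectral_image <- function(x) dim(x$channels[[1]])

#' Assemble a multispectral image from four filter-cube captures
#'
#' Merges the RGB images of the U1, U2, BL and GR filter cubes into the
#' 11-channel stack. The visible-excitation captures (BL, GR) are multiplied
#' by `visible_gain` (default 2) to compensate for their lower intensity;
#' the U1 red channel is dropped (excitation-band reflection).
#'
#' @param captures list of four [filter_capture()] objects, one per filter.
#' @param visible_gain positive multiplicative gain for BL and GR captures.
#' @param pixel_size_um pixel size of the assembled stack.
#' @return [multispectral_image()].
#' @export
assemble_multispectral <- function(captures, visible_gain = 2,
                                   pixel_size_um = 2.78) {
  filters <- vapply(captures, function(cp) {
    if (!inherits(cp, "filter_capture")) stop("captures must be filter_capture objects")
    cp$filter
  }, character(1))
  if (!setequal(filters, c("U1", "U2", "BL", "GR")) || anyDuplicated(filters))
    stop("exactly one capture per filter U1, U2, BL, GR is required")
  if (visible_gain <= 0) stop("visible_gain must be positive")
  caps <- setNames(captures, filters)
  d <- dim(caps$U1$r)
  for (cp in caps) if (!all(dim(cp$r) == d))
    stop("all captures must share identical dimensions")
  ch <- list(
    U1b = caps$U1$b, U1g = caps$U1$g,
    U2b = caps$U2$b, U2g = caps$U2$g, U2r = caps$U2$r,
    BLb = caps$BL$b * visible_gain, BLg = caps$BL$g * visible_gain,
    BLr = caps$BL$r * visible_gain,
    GRb = caps$GR$b * visible_gain, GRg = caps$GR$g * visible_gain,
    GRr = caps$GR$r * visible_gain
  )
  multispectral_image(ch, pixel_size_um = pixel_size_um,
                      visible_gain = visible_gain)
}

#' Composite macrofluorescence RGB representation
#'
#' Red = mean(U2r, BLr, GRr); green = mean(U1g, U2g, BLg);
#' blue = mean(U1b, U2b).
#'
#' @param ms [multispectral_image()].
#' @return list with matrices `r`, `g`, `b`.
#' @export
composite_rgb <- function(ms) {
  stopifnot(inherits(ms, "multispectral_image"))
  ch <- ms$channels
  list(
    r = (ch$U2r + ch$BLr + ch$GRr) / 3,
    g = (ch$U1g + ch$U2g + ch$BLg) / 3,
    b = (ch$U1b + ch$U2b) / 2
  )
}

#' Sum-of-intensity image over a channel subset
#'
#' Presets: `"all"` sums the 11 channels (segmentation input for
#' fluorescence stacks); `"visible"` sums BLg, BLr, GRr.
#'
#' @param ms [multispectral_image()].
#' @param subset character vector of channel names, or `"all"`/`"visible"`.
#' @return numeric matrix.
#' @export
sum_image <- function(ms, subset = "all") {
  stopifnot(inherits(ms, "multispectral_image"))
  if (identical(subset, "all")) subset <- channel_names()
  else if (identical(subset, "visible")) subset <- visible_channels()
  if (length(subset) == 0) stop("subset must be non-empty")
  unknown <- setdiff(subset, channel_names())
  if (length(unknown))
    stop("unknown channel name(s): ", paste(unknown, collapse = ", "))
  Reduce(`+`, ms$channels[subset])
}
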