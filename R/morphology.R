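#' Mathematical morphology with square structuring elements
#'
#' Grey-level erosion, dilation, opening and closing with a flat square
#' structuring element of odd pixel width `k`, using separable running
#' min/max filters (cost independent of `k`). Image borders are handled by
#' edge replication. Binary masks can be passed as logical matrices; the
#' result is then returned as logical.
#'
#' @param img numeric or logical matrix.
#' @param k odd positive integer, full width of the square structuring
#'   element in pixels. `k = 1` is the identity.
#' @return matrix of the same shape (logical in, logical out).
#' @examples
#' m <- matrix(0, 21, 21); m[11, 11] <- 1
#' sum(mm_dilate(m, 5) > 0) == 25
#' @export
mm_erode <- function(img, k) .mm_apply(img, k, do_max = FALSE)

#' @rdname mm_erode
#' @export
mm_dilate <- function(img, k) .mm_apply(img, k, do_max = TRUE)

#' @rdname mm_erode
#' @export
mm_open <- function(img, k) mm_dilate(mm_erode(img, k), k)

#' @rdname mm_erode
#' @export
mm_close <- function(img, k) mm_erode(mm_dilate(img, k), k)

.mm_apply <- function(img, k, do_max) {
  was_logical <- is.logical(img)
  m <- img
  storage.mode(m) <- "double"
  out <- .cpp_sq_filter(m, as.integer(k), do_max)
  if (was_logical) out > 0.5 else out
}

#' Alternating sequential filter
#'
#' Applies, for each structuring-element size in increasing order, a closing
#' followed by an opening. Suppresses bright structures thinner than the
#' final size (e.g. single-pixel parenchyma walls) while preserving dense
#' regions (rind, bundle sheaths), which is the contrast-enhancement step of
#' the tissue segmentation workflow.
#'
#' @param img numeric matrix.
#' @param half_widths increasing integer vector of SE half-widths in pixels;
#'   at each step the full SE width is `2 * h + 1`.
#' @return filtered numeric matrix.
#' @export
asf <- function(img, half_widths = c(1L, 2L, 3L)) {
  if (length(half_widths) == 0) return(img)
  if (is.unsorted(half_widths, strictly = TRUE))
    stop("half_widths must be strictly increasing")
  out <- img
  for (h in half_widths) {
    k <- 2L * as.integer(h) + 1L
    out <- mm_open(mm_close(out, k), k)
  }
  out
}

#' Otsu threshold
#'
#' Histogram-based automatic threshold maximising between-class variance.
#' Values are binned into 256 levels over their observed range.
#'
#' @param x numeric vector or matrix of intensities.
#' @param n_bins number of histogram bins.
#' @return threshold value; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (length(v) == 0) stop("no finite values to threshold")
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, n_bins)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * (1 - w0[valid]))
  mids[which.max(sigma_b)]
}

#' Connected-component labelling
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer matrix of labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  storage.mode(mask) <- "logical"
  .cpp_label(mask, as.integer(connectivity))
}

#' Fill interior holes of a binary mask
#'
#' Background regions not 4-connected to the image border become foreground.
#'
#' @param mask logical matrix.
#' @return logical matrix.
#' @export
fill_holes <- function(mask) {
  stopifnot(is.matrix(mask))
  storage.mode(mask) <- "logical"
  .cpp_fill_holes(mask)
}

#' Euclidean distance transform
#'
#' Exact Euclidean distance, in pixels, from every pixel to the nearest
#' `TRUE` pixel of `from` (0 inside `from`). With `labels = TRUE` the label
#' of the nearest site is also returned, which yields exact discrete Voronoi
#' tessellations.
#'
#' @param from logical matrix of sites, or an integer label matrix whose
#'   positive entries are sites.
#' @param labels return the nearest-site label map as well?
#' @return numeric distance matrix, or `list(dist, label)`.
#' @export
distance_transform <- function(from, labels = FALSE) {
  if (is.logical(from)) {
    sites <- matrix(0L, nrow(from), ncol(from))
    sites[from] <- 1L
  } else {
    sites <- from
    storage.mode(sites) <- "integer"
  }
  ft <- .cpp_feature_transform(sites)
  if (labels) ft else ft$dist
}

#' Per-component shape statistics
#'
#' Area, centroid and equivalent-ellipse axes for every label of a label
#' map. Axis lengths come from the second central moments (the same
#' convention as MATLAB's regionprops: full axis length of the ellipse with
#' identical normalised moments).
#'
#' @param lab integer label matrix (0 = background).
#' @return data.frame with one row per label: `label`, `area_px`,
#'   `centroid_row`, `centroid_col`, `major_px`, `minor_px`, `elongation`
#'   (minor/major).
#' @export
component_stats <- function(lab) {
  storage.mode(lab) <- "integer"
  nlab <- max(0L, max(lab))
  if (nlab == 0)
    return(data.frame(label = integer(), area_px = numeric(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      major_px = numeric(), minor_px = numeric(),
                      elongation = numeric()))
  s <- .cpp_label_stats(lab, nlab)
  n <- s[, 1]
  ci <- s[, 2] / n
  cj <- s[, 3] / n
  # central second moments with the 1/12 pixel-extent term
  mu_ii <- s[, 4] / n - ci^2 + 1 / 12
  mu_jj <- s[, 5] / n - cj^2 + 1 / 12
  mu_ij <- s[, 6] / n - ci * cj
  common <- sqrt((mu_ii - mu_jj)^2 + 4 * mu_ij^2)
  l1 <- (mu_ii + mu_jj + common) / 2
  l2 <- (mu_ii + mu_jj - common) / 2
  major <- 4 * sqrt(pmax(l1, 0))
  minor <- 4 * sqrt(pmax(l2, 0))
  data.frame(label = seq_len(nlab), area_px = n,
             centroid_row = ci, centroid_col = cj,
             major_px = major, minor_px = minor,
             elongation = ifelse(major > 0, minor / major, 1))
}

#' Crofton perimeter of a binary mask
#'
#' Perimeter estimate from intercept counts in four directions
#' (Cauchy-Crofton with directions 0, 45, 90, 135 degrees). Nearly unbiased
#' on smooth convex shapes such as disks.
#'
#' @param mask logical matrix.
#' @param pixel_size physical size of one pixel (result is in the same unit).
#' @return perimeter length.
#' @export
crofton_perimeter <- function(mask, pixel_size = 1) {
  stopifnot(is.matrix(mask))
  m <- mask
  storage.mode(m) <- "logical"
  nr <- nrow(m); nc <- ncol(m)
  runs <- function(mm) {
    # number of FALSE->TRUE transitions scanning along rows of mm
    started <- sum(mm[, 1])
    if (ncol(mm) > 1) started <- started + sum(mm[, -1] & !mm[, -ncol(mm)])
    started
  }
  c0 <- runs(m)                     # horizontal runs
  c90 <- runs(t(m))                 # vertical runs
  diag_runs <- function(mm, anti = FALSE) {
    if (anti) mm <- mm[, rev(seq_len(ncol(mm))), drop = FALSE]
    nr <- nrow(mm); nc <- ncol(mm)
    # transitions along direction (+1,+1)
    inner <- mm[-1, -1, drop = FALSE] & !mm[-nr, -nc, drop = FALSE]
    sum(inner) + sum(mm[1, ]) + sum(mm[-1, 1])
  }
  c45 <- diag_runs(m)
  c135 <- diag_runs(m, anti = TRUE)
  pi / 4 * (c0 + c90 + (c45 + c135) / sqrt(2)) * pixel_size
}
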