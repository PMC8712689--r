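#' @name tiff-io
#' @title Minimal TIFF reader/writer
#'
#' @description
#' Baseline little-endian uncompressed TIFF, enough to exchange greyscale
#' scientific images: 8-bit and 16-bit unsigned integer and 32-bit IEEE
#' float samples, single- or multi-page, one strip per page. No external
#' imaging package is required. Multispectral stacks are stored as
#' multi-page TIFF in canonical channel order with a JSON sidecar naming
#' channels, pixel size and the visible gain applied at assembly.
#'
#' Matrices are written row-major (TIFF convention); `read_tiff` returns
#' them back in R's usual orientation.
NULL

.tiff_sample_format <- function(type) {
  switch(type,
         uint8 = list(bits = 8L, fmt = 1L),
         uint16 = list(bits = 16L, fmt = 1L),
         float32 = list(bits = 32L, fmt = 3L),
         stop("unsupported TIFF sample type: ", type))
}

#' @rdname tiff-io
#' @param pages a numeric matrix or list of matrices (one per page).
#' @param path file path.
#' @param type `"uint8"`, `"uint16"` or `"float32"`.
#' @return `write_tiff` returns `path` invisibly.
#' @export
write_tiff <- function(pages, path, type = "float32") {
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(length(pages) >= 1)
  sf <- .tiff_sample_format(type)
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  writeChar("II", con, nchars = 2, eos = NULL)
  w(42L, 2)
  # header IFD offset placeholder, patched later
  w(8L, 4)
  offset <- 8L
  n <- length(pages)
  ifd_offsets <- integer(n)
  data_offsets <- integer(n)
  byte_counts <- integer(n)
  # first all pixel data, then all IFDs
  for (p in seq_len(n)) {
    m <- pages[[p]]
    stopifnot(is.matrix(m))
    data_offsets[p] <- offset
    v <- as.vector(t(m))      # row-major
    if (type == "float32") {
      writeBin(as.numeric(v), con, size = 4, endian = "little")
    } else {
      mx <- if (type == "uint8") 255 else 65535
      iv <- as.integer(round(pmin(pmax(v, 0), mx)))
      writeBin(iv, con, size = sf$bits / 8L, endian = "little")
    }
    byte_counts[p] <- length(v) * sf$bits / 8L
    offset <- offset + byte_counts[p]
  }
  n_entries <- 9L
  for (p in seq_len(n)) {
    ifd_offsets[p] <- offset
    offset <- offset + 2L + n_entries * 12L + 4L
  }
  entry <- function(tag, typ, count, value) {
    w(tag, 2); w(typ, 2); w(count, 4); w(value, 4)
  }
  for (p in seq_len(n)) {
    m <- pages[[p]]
    w(n_entries, 2)
    entry(256L, 4L, 1L, ncol(m))                 # ImageWidth
    entry(257L, 4L, 1L, nrow(m))                 # ImageLength
    entry(258L, 3L, 1L, sf$bits)                 # BitsPerSample
    entry(259L, 3L, 1L, 1L)                      # Compression: none
    entry(262L, 3L, 1L, 1L)                      # Photometric: BlackIsZero
    entry(273L, 4L, 1L, data_offsets[p])         # StripOffsets
    entry(278L, 4L, 1L, nrow(m))                 # RowsPerStrip
    entry(279L, 4L, 1L, byte_counts[p])          # StripByteCounts
    entry(339L, 3L, 1L, sf$fmt)                  # SampleFormat
    w(if (p < n) ifd_offsets[p + 1] else 0L, 4)  # next IFD
  }
  # patch first IFD offset in the header
  seek(con, 4, origin = "start", rw = "write")
  w(ifd_offsets[1], 4)
  invisible(path)
}

#' @rdname tiff-io
#' @return `read_tiff` returns a list of numeric matrices (one per page).
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big" else
    stop("not a TIFF file: ", path)
  u <- function(at, size) {
    # unsigned integer at 1-based byte offset `at`
    b <- raw[at:(at + size - 1)]
    if (endian == "big") b <- rev(b)
    sum(as.numeric(b) * 256^(seq_len(size) - 1))
  }
  if (u(3, 2) != 42) stop("not a TIFF file: ", path)
  ifd <- u(5, 4)
  pages <- list()
  while (ifd != 0) {
    nent <- u(ifd + 1, 2)
    tags <- list()
    for (e in seq_len(nent)) {
      at <- ifd + 3 + (e - 1) * 12
      tag <- u(at, 2); typ <- u(at + 2, 2); cnt <- u(at + 4, 4)
      tsize <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 4)[[as.character(typ)]]
      vals <- numeric(cnt)
      vat <- if (tsize * cnt <= 4) at + 8 else u(at + 8, 4) + 1
      for (i in seq_len(cnt)) vals[i] <- u(vat + (i - 1) * tsize, tsize)
      tags[[as.character(tag)]] <- vals
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stop("missing TIFF tag ", tag)
        default
      } else v
    }
    width <- need(256); height <- need(257)
    bits <- need(258, 1); comp <- need(259, 1); fmt <- need(339, 1)
    if (comp != 1) stop("only uncompressed TIFF is supported")
    offs <- need(273); counts <- need(279, width * height * bits / 8)
    buf <- raw(0)
    for (s in seq_along(offs))
      buf <- c(buf, raw[(offs[s] + 1):(offs[s] + counts[s])])
    npx <- width * height
    v <- if (fmt == 3 && bits == 32) {
      readBin(buf, "numeric", n = npx, size = 4, endian = endian)
    } else if (fmt %in% c(1, 2)) {
      readBin(buf, "integer", n = npx, size = bits / 8, endian = endian,
              signed = (fmt == 2 || bits == 32))
    } else stop("unsupported TIFF sample format")
    m <- matrix(as.numeric(v), nrow = height, ncol = width, byrow = TRUE)
    pages[[length(pages) + 1]] <- m
    ifd <- u(ifd + 3 + nent * 12, 4)
  }
  pages
}

#' Write / read a multispectral stack (multi-page TIFF + JSON sidecar)
#'
#' @param ms [multispectral_image()].
#' @param path path of the `.tif` file; the sidecar is `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_multispectral <- function(ms, path) {
  stopifnot(inherits(ms, "multispectral_image"))
  write_tiff(unname(ms$channels), path, type = "float32")
  sidecar <- list(channels = channel_names(),
                  pixel_size_um = ms$pixel_size_um,
                  visible_gain = ms$visible_gain)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_multispectral
#' @export
read_multispectral <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- read_tiff(path)
  if (length(pages) != 11) stop("expected an 11-page multispectral stack")
  multispectral_image(setNames(pages, sidecar$channels),
                      pixel_size_um = sidecar$pixel_size_um,
                      visible_gain = sidecar$visible_gain %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a segmentation result directory
#'
#' Masks go to 8-bit TIFF (0/255), the individual-bundle label map to
#' 16-bit TIFF, and a JSON manifest records files, pixel size and flags.
#'
#' @param rois [roi_set()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_roi_set <- function(rois, dir) {
  stopifnot(inherits(rois, "roi_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  masks <- c("whole_stem", "all_tissue", "rind", "bundles_all",
             "parenchyma", "parenchyma_near_rind", "parenchyma_middle")
  files <- list()
  for (m in masks) {
    f <- file.path(dir, paste0(m, ".tif"))
    write_tiff(matrix(as.numeric(rois[[m]]) * 255, nrow(rois[[m]])), f, "uint8")
    files[[m]] <- basename(f)
  }
  f <- file.path(dir, "bundles_individual.tif")
  write_tiff(matrix(as.numeric(rois$bundles_individual), nrow(rois$bundles_individual)),
             f, "uint16")
  files$bundles_individual <- basename(f)
  manifest <- list(files = files, pixel_size_um = rois$pixel_size_um,
                   rind_damaged = rois$rind_damaged %||% FALSE)
  mf <- file.path(dir, "roiset.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(mf)
}

#' @rdname write_roi_set
#' @param manifest path to `roiset.json`.
#' @export
read_roi_set <- function(manifest) {
  info <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  dir <- dirname(manifest)
  get_mask <- function(name) read_tiff(file.path(dir, info$files[[name]]))[[1]] > 0
  roi_set(
    whole_stem = get_mask("whole_stem"),
    all_tissue = get_mask("all_tissue"),
    rind = get_mask("rind"),
    bundles_individual = {
      m <- read_tiff(file.path(dir, info$files$bundles_individual))[[1]]
      storage.mode(m) <- "integer"
      m
    },
    bundles_all = get_mask("bundles_all"),
    parenchyma = get_mask("parenchyma"),
    parenchyma_near_rind = get_mask("parenchyma_near_rind"),
    parenchyma_middle = get_mask("parenchyma_middle"),
    pixel_size_um = info$pixel_size_um,
    rind_damaged = isTRUE(info$rind_damaged)
  )
}
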