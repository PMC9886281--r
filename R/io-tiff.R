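# Minimal multi-page grayscale 32-bit-float TIFF codec.
#
# No TIFF package is available in the supported environment, so the package
# carries its own reader/writer for the one flavour of TIFF the pipeline
# uses: little-endian, uncompressed, single-sample IEEE-float pages. The
# writer always emits one strip per page; the reader tolerates multiple
# strips but rejects anything it cannot represent losslessly (RGB,
# palette, compressed, integer samples) with an explicit message.

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L, StripOffsets = 273L,
               SamplesPerPixel = 277L, RowsPerStrip = 278L,
               StripByteCounts = 279L, SampleFormat = 339L)

#' Write an image stack as multi-page float32 TIFF
#'
#' Pages are written uncompressed, grayscale, 32-bit IEEE float,
#' little-endian. Physical metadata goes into a JSON sidecar next to the
#' file (same name, `.json` extension): at least `pixel_size_um`, plus
#' `z_step_um` / `frame_interval_s` when meaningful.
#'
#' @param stack Numeric matrix (single page) or 3-D array (rows x cols x
#'   pages).
#' @param path Output `.tif` path.
#' @param meta Named list written to the sidecar. Default empty.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, meta = list()) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1L))
  stopifnot(length(dim(stack)) == 3L)
  h <- dim(stack)[1]; w <- dim(stack)[2]; n <- dim(stack)[3]
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con)
  w2(42L)
  # layout per page: pixel data then IFD; first IFD offset points past page 1
  bytes_page <- 4L * w * h
  ifd_size <- 2L + 12L * length(TIFF_TAGS) + 4L
  data_off <- function(k) 8L + (k - 1L) * (bytes_page + ifd_size)
  ifd_off <- function(k) data_off(k) + bytes_page
  w4(ifd_off(1L))
  entry <- function(tag, type, value) {
    w2(tag); w2(type); w4(1L)
    if (type == 3L) { w2(value); w2(0L) } else w4(value)
  }
  for (k in seq_len(n)) {
    # TIFF stores rows sequentially; R matrices are column-major
    writeBin(as.numeric(t(stack[, , k])), con, size = 4, endian = "little")
    w2(length(TIFF_TAGS))
    entry(256L, 4L, w)
    entry(257L, 4L, h)
    entry(258L, 3L, 32L)
    entry(259L, 3L, 1L)          # no compression
    entry(262L, 3L, 1L)          # BlackIsZero
    entry(273L, 4L, data_off(k))
    entry(277L, 3L, 1L)          # one sample per pixel
    entry(278L, 4L, h)
    entry(279L, 4L, bytes_page)
    entry(339L, 3L, 3L)          # IEEE float
    w4(if (k < n) ifd_off(k + 1L) else 0L)
  }
  if (length(meta)) {
    jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Read a multi-page grayscale float32 TIFF stack
#'
#' Counterpart of [write_stack]. Refuses RGB/multi-sample, compressed,
#' and non-float-32 files with a message naming the file and the violated
#' rule. Pixel size comes from the JSON sidecar unless supplied.
#'
#' @param path `.tif` path.
#' @param pixel_size_um Overrides / replaces the sidecar value.
#' @param require_pixel_size Error when neither sidecar nor argument
#'   provides a pixel size. Default `TRUE`.
#' @return A list: `stack` (array rows x cols x pages) and `meta`
#'   (sidecar contents plus any override).
#' @export
read_stack <- function(path, pixel_size_um = NULL, require_pixel_size = TRUE) {
  if (!file.exists(path)) stop("read_stack: no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  r2 <- function() readBin(con, "integer", size = 2, endian = "little",
                           signed = FALSE)
  r4 <- function() readBin(con, "integer", size = 4, endian = "little")
  magic <- readBin(con, "raw", 2)
  if (!identical(rawToChar(magic), "II")) {
    stop("read_stack: ", path, ": only little-endian ('II') TIFF supported")
  }
  if (r2() != 42L) stop("read_stack: ", path, ": not a TIFF file")
  next_ifd <- r4()
  pages <- list()
  while (next_ifd != 0L) {
    seek(con, next_ifd)
    n_entries <- r2()
    tags <- list()
    for (i in seq_len(n_entries)) {
      tag <- r2(); type <- r2(); count <- r4()
      val_raw <- readBin(con, "raw", 4)
      value <- if (count == 1L && type == 3L) {
        as.integer(val_raw[1]) + 256L * as.integer(val_raw[2])
      } else if (count == 1L && type == 4L) {
        sum(as.integer(val_raw) * c(1, 256, 65536, 16777216))
      } else {
        # multi-value entry: 4-byte field is an offset
        off <- sum(as.integer(val_raw) * c(1, 256, 65536, 16777216))
        here <- seek(con)
        seek(con, off)
        v <- readBin(con, "integer", n = count,
                     size = if (type == 3L) 2 else 4,
                     endian = "little", signed = FALSE)
        seek(con, here)
        v
      }
      tags[[as.character(tag)]] <- value
    }
    next_ifd <- r4()
    gt <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    spp <- gt(277L, 1L)
    if (spp != 1L) {
      stop("read_stack: ", path, ": ", spp, " samples per pixel ",
           "(RGB/multi-channel TIFF unsupported; grayscale only)")
    }
    if (gt(259L, 1L) != 1L) {
      stop("read_stack: ", path, ": compressed TIFF unsupported")
    }
    if (gt(258L, 1L) != 32L || gt(339L, 1L) != 3L) {
      stop("read_stack: ", path, ": only 32-bit IEEE-float samples supported")
    }
    w <- gt(256L); h <- gt(257L)
    offs <- gt(273L); counts <- gt(279L, 4L * w * h)
    vals <- numeric(0)
    for (si in seq_along(offs)) {
      seek(con, offs[si])
      vals <- c(vals, readBin(con, "numeric", n = counts[si] / 4L, size = 4,
                              endian = "little"))
    }
    if (length(vals) != w * h) {
      stop("read_stack: ", path, ": strip data does not match ",
           h, " x ", w, " page size")
    }
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = h, byrow = TRUE)
  }
  if (!length(pages)) stop("read_stack: ", path, ": no pages found")
  stack <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  meta <- list()
  sc <- sidecar_path(path)
  if (file.exists(sc)) meta <- jsonlite::fromJSON(sc, simplifyVector = TRUE)
  if (!is.null(pixel_size_um)) meta$pixel_size_um <- pixel_size_um
  if (require_pixel_size && is.null(meta$pixel_size_um)) {
    stop("read_stack: ", path, ": no pixel_size_um in sidecar ", sc,
         " and none supplied")
  }
  list(stack = stack, meta = meta)
}
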