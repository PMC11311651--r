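# Minimal baseline-TIFF codec for uncompressed grayscale images.
# The installed R stack has no TIFF package, and the assay's image files
# are plain single-channel microscopy frames, so the package carries its
# own reader/writer restricted to what the pipeline produces and consumes:
# 8- or 16-bit unsigned grayscale, uncompressed, single sample per pixel,
# single or multiple pages. The reader accepts both byte orders and
# multi-strip files; the writer emits little-endian single-strip pages.

uint_le <- function(x, nbytes) {
  # integer (possibly > 2^31 as double) -> little-endian raw
  out <- raw(nbytes * length(x))
  for (i in seq_len(nbytes)) {
    out[seq(i, length(out), by = nbytes)] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

rd_uint <- function(bytes, pos, nbytes, big_endian) {
  b <- as.integer(bytes[pos:(pos + nbytes - 1)])
  if (big_endian) b <- rev(b)
  sum(b * 256^(seq_len(nbytes) - 1))
}

#' Write grayscale images to a TIFF file
#'
#' Writes one page per matrix as uncompressed little-endian grayscale.
#' Matrices are oriented image-style: rows are image rows (row 1 is the
#' top of the frame), columns are image columns.
#'
#' @param images a numeric matrix or a list of matrices; values must be
#'   integers in \code{[0, 2^bits_per_sample - 1]}.
#' @param path output file path.
#' @param bits_per_sample 8 or 16 (default 16).
#' @return \code{path}, invisibly.
#' @export
write_tiff <- function(images, path, bits_per_sample = 16) {
  if (is.matrix(images)) images <- list(images)
  stopifnot(length(images) >= 1, all(vapply(images, is.matrix, logical(1))))
  if (!bits_per_sample %in% c(8, 16)) stop("bits_per_sample must be 8 or 16")
  maxval <- 2^bits_per_sample - 1
  bpp <- bits_per_sample / 8
  for (img in images) {
    v <- as.vector(img)
    if (any(!is.finite(v)) || any(v < 0) || any(v > maxval) ||
        any(v != round(v)))
      stop("pixel values must be integers in [0, ", maxval, "]")
  }
  sizes <- vapply(images, function(m) length(m) * bpp, numeric(1))
  data_off <- 8 + c(0, cumsum(sizes))[seq_along(images)]
  n_tags <- 10
  ifd_size <- 2 + n_tags * 12 + 4
  ifd_off <- 8 + sum(sizes) + (seq_along(images) - 1) * ifd_size

  entry <- function(tag, type, value) {
    # type 3 = SHORT, 4 = LONG; single value, left-justified in 4 bytes
    val <- if (type == 3) c(uint_le(value, 2), raw(2)) else uint_le(value, 4)
    c(uint_le(tag, 2), uint_le(type, 2), uint_le(1, 4), val)
  }

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(uint_le(42, 2), con)
  writeBin(uint_le(ifd_off[1], 4), con)
  for (img in images) {
    v <- round(t(img))  # row-major strip
    if (bpp == 1) {
      writeBin(as.raw(as.vector(v)), con)
    } else {
      vv <- as.vector(v)
      writeBin(as.raw(rbind(vv %% 256, vv %/% 256)), con)
    }
  }
  for (i in seq_along(images)) {
    h <- nrow(images[[i]]); w <- ncol(images[[i]])
    ifd <- c(uint_le(n_tags, 2),
             entry(256, 4, w),
             entry(257, 4, h),
             entry(258, 3, bits_per_sample),
             entry(259, 3, 1),
             entry(262, 3, 1),
             entry(273, 4, data_off[i]),
             entry(277, 3, 1),
             entry(278, 4, h),
             entry(279, 4, sizes[i]),
             entry(339, 3, 1),
             uint_le(if (i < length(images)) ifd_off[i + 1] else 0, 4))
    writeBin(ifd, con)
  }
  invisible(path)
}

#' Read a grayscale TIFF file
#'
#' Supports uncompressed 8/16-bit unsigned grayscale baseline TIFF,
#' single- or multi-page, single- or multi-strip, either byte order.
#' Anything else (RGB, compressed, tiled, float samples) raises a format
#' error rather than being silently misread.
#'
#' @param path TIFF file path.
#' @return A list of numeric matrices, one per page, in page order,
#'   oriented with row 1 at the top of the frame.
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 8) stop("not a TIFF file: ", path)
  order_tag <- rawToChar(bytes[1:2])
  big <- if (order_tag == "MM") TRUE else if (order_tag == "II") FALSE else
    stop("not a TIFF file (bad byte-order mark): ", path)
  if (rd_uint(bytes, 3, 2, big) != 42) stop("not a TIFF file: ", path)

  tag_values <- function(pos, type, count) {
    nb <- if (type %in% c(1, 2)) 1 else if (type == 3) 2 else 4
    total <- nb * count
    src <- if (total <= 4) pos else rd_uint(bytes, pos, 4, big) + 1
    vapply(seq_len(count), function(j)
      rd_uint(bytes, src + (j - 1) * nb, nb, big), numeric(1))
  }

  pages <- list()
  ifd <- rd_uint(bytes, 5, 4, big)
  while (ifd != 0) {
    n <- rd_uint(bytes, ifd + 1, 2, big)
    tags <- list()
    for (k in seq_len(n)) {
      p <- ifd + 3 + (k - 1) * 12
      code <- rd_uint(bytes, p, 2, big)
      type <- rd_uint(bytes, p + 2, 2, big)
      count <- rd_uint(bytes, p + 4, 4, big)
      tags[[as.character(code)]] <- tag_values(p + 8, type, count)
    }
    need <- function(code, default = NULL) {
      v <- tags[[as.character(code)]]
      if (is.null(v)) {
        if (is.null(default)) stop("TIFF missing required tag ", code)
        default
      } else v
    }
    w <- need(256); h <- need(257)
    bits <- need(258, 8)
    if (need(259, 1) != 1) stop("unsupported TIFF: compressed data")
    if (need(277, 1) != 1) stop("unsupported TIFF: not single-channel grayscale")
    if (!need(262, 1) %in% c(0, 1)) stop("unsupported TIFF: not grayscale")
    if (need(339, 1) != 1) stop("unsupported TIFF: non-integer samples")
    if (length(bits) != 1 || !bits %in% c(8, 16))
      stop("unsupported TIFF: ", bits[1], "-bit samples")
    offs <- need(273); cnts <- need(279)
    strip <- unlist(lapply(seq_along(offs), function(j)
      bytes[(offs[j] + 1):(offs[j] + cnts[j])]), use.names = FALSE)
    if (bits == 8) {
      v <- as.numeric(strip)
    } else {
      lo <- as.numeric(strip[seq(1, length(strip), 2)])
      hi <- as.numeric(strip[seq(2, length(strip), 2)])
      v <- if (big) lo * 256 + hi else hi * 256 + lo
    }
    if (length(v) != w * h) stop("corrupt TIFF: strip size mismatch")
    pages[[length(pages) + 1]] <- t(matrix(v, nrow = w, ncol = h))
    ifd <- rd_uint(bytes, ifd + 3 + n * 12, 4, big)
  }
  if (length(pages) == 0) stop("TIFF contains no pages")
  pages
}
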