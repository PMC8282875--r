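# Minimal grayscale image I/O.
#
# No TIFF reader is available in the dependency set, so a baseline TIFF
# codec (uncompressed, single-sample grayscale, 8/16-bit, multi-page,
# little- or big-endian on read) is implemented here. Plain-text PGM (P2)
# and binary PGM (P5) are supported as well for text-only fixtures.

#' Read a grayscale image or stack
#'
#' Dispatches on file extension: `.tif`/`.tiff` (baseline uncompressed
#' grayscale TIFF) or `.pgm` (P2/P5). 16-bit data are linearly rescaled to
#' 8-bit with a warning.
#'
#' @param path file path.
#' @return a numeric matrix (single image) or a list of matrices (stack).
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  out <- switch(ext,
                "tif" = , "tiff" = read_tiff_gray(path),
                "pgm" = list(read_pgm(path)),
                stop("unsupported image format: ", ext))
  if (length(out) == 1L) out[[1L]] else out
}

#' Write a grayscale image or stack
#'
#' @param img numeric matrix in \[0, 255\], or list of matrices (stack;
#'   TIFF only).
#' @param path output path (`.tif`/`.tiff` or `.pgm`).
#' @param bits 8 or 16 (TIFF only).
#' @export
write_image <- function(img, path, bits = 8L) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         "tif" = , "tiff" = write_tiff_gray(img, path, bits = bits),
         "pgm" = write_pgm(if (is.list(img)) img[[1L]] else img, path),
         stop("unsupported image format: ", ext))
  invisible(path)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file")
  toks <- character(0)
  # header: width height maxval, comments allowed
  while (length(toks) < 3L) {
    line <- readLines(con, n = 1L)
    line <- sub("#.*$", "", line)
    toks <- c(toks, strsplit(trimws(line), "\\s+")[[1L]])
    toks <- toks[nzchar(toks)]
  }
  w <- as.integer(toks[1L]); h <- as.integer(toks[2L])
  maxv <- as.integer(toks[3L])
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  } else {
    bytes <- if (maxv > 255L) 2L else 1L
    raw <- readBin(con, "integer", n = w * h, size = bytes, signed = FALSE,
                   endian = "big")
    vals <- raw
  }
  m <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  if (maxv > 255L) {
    warning("rescaling >8-bit PGM to [0, 255]")
    m <- round(m / maxv * 255)
  }
  m * 1.0
}

write_pgm <- function(img, path) {
  m <- round(as_matrix(img))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), "255"), con)
  apply(m, 1L, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}

# ---- baseline TIFF ----

tiff_tag <- function(id, type, count, value) {
  list(id = id, type = type, count = count, value = value)
}

#' @rdname read_image
#' @param rescale rescale 16-bit data to \[0, 255\] (default TRUE; set FALSE
#'   for label maps).
#' @export
read_tiff_gray <- function(path, rescale = TRUE) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file")
  order <- rawToChar(raw[1:2])
  endian <- if (order == "II") "little" else if (order == "MM") "big" else
    stop("not a TIFF file")
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer", size = 2,
                               signed = FALSE, endian = endian)
  u32 <- function(off) readBin(raw[(off + 1):(off + 4)], "integer", size = 4,
                               signed = TRUE, endian = endian)
  if (u16(2) != 42L) stop("not a TIFF file")
  ifd_off <- u32(4)
  pages <- list()
  while (ifd_off != 0L) {
    n <- u16(ifd_off)
    tags <- list()
    for (e in seq_len(n)) {
      base <- ifd_off + 2L + (e - 1L) * 12L
      id <- u16(base); type <- u16(base + 2); count <- u32(base + 4)
      tsize <- c(1L, 1L, 2L, 4L, 8L)[type]
      nbytes <- tsize * count
      voff <- if (!is.na(nbytes) && nbytes <= 4L) base + 8L else u32(base + 8)
      vals <- if (type == 3L) {
        vapply(seq_len(count), function(i) u16(voff + (i - 1L) * 2L), 0L)
      } else if (type == 4L) {
        vapply(seq_len(count), function(i) u32(voff + (i - 1L) * 4L), 0L)
      } else NULL
      tags[[as.character(id)]] <- vals
    }
    pages[[length(pages) + 1L]] <- tags
    ifd_off <- u32(ifd_off + 2L + n * 12L)
  }
  lapply(pages, function(tags) {
    g <- function(id, default = NULL) tags[[as.character(id)]] %||% default
    w <- g(256); h <- g(257)
    bits <- g(258, 8L)[1L]
    comp <- g(259, 1L)[1L]
    spp <- g(277, 1L)[1L]
    if (comp != 1L) stop("only uncompressed TIFF is supported")
    if (spp != 1L) stop("only single-sample grayscale TIFF is supported")
    if (!bits %in% c(8L, 16L)) stop("only 8/16-bit TIFF is supported")
    offs <- g(273); cnts <- g(279)
    rps <- g(278, h)[1L]
    data <- integer(0)
    for (s in seq_along(offs)) {
      nb <- cnts[s]
      chunk <- raw[(offs[s] + 1L):(offs[s] + nb)]
      data <- c(data, readBin(chunk, "integer", n = nb %/% (bits %/% 8L),
                              size = bits %/% 8L, signed = FALSE,
                              endian = endian))
    }
    m <- matrix(data[seq_len(w * h)], nrow = h, ncol = w, byrow = TRUE)
    if (bits == 16L && rescale) {
      warning("rescaling 16-bit TIFF to [0, 255]")
      m <- round(m / 65535 * 255)
    }
    m * 1.0
  })
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  out <- read_tiff_gray(path, rescale = FALSE)
  out <- lapply(out, function(m) { storage.mode(m) <- "integer"; m })
  if (length(out) == 1L) out[[1L]] else out
}

#' @rdname write_image
#' @export
write_tiff_gray <- function(img, path, bits = 8L) {
  if (!bits %in% c(8L, 16L)) stop("bits must be 8 or 16")
  pages <- if (is.list(img)) img else list(img)
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeChar("II", con, eos = NULL)
  w16(42L)
  # layout per page: [pixel data][IFD]; first IFD offset filled in now
  offset <- 8L
  sizes <- vapply(pages, function(p) length(p) * (bits %/% 8L), 0L)
  n_entries <- 8L
  ifd_size <- 2L + n_entries * 12L + 4L
  w32(offset + sizes[1L])
  for (k in seq_along(pages)) {
    m <- round(as_matrix(pages[[k]]))
    if (min(m) < 0 || max(m) >= 2^bits) stop("pixel values out of range")
    vals <- as.integer(t(m))  # TIFF is row-major
    if (bits == 8L) {
      writeBin(as.raw(vals), con)
    } else {
      writeBin(vals, con, size = 2, endian = "little")
    }
    ifd_off <- offset + sizes[k]
    next_off <- if (k < length(pages)) ifd_off + ifd_size + sizes[k + 1L] else 0L
    w16(n_entries)
    entry <- function(id, type, count, value) {
      w16(id); w16(type); w32(count)
      if (type == 3L) { w16(value); w16(0L) } else w32(value)
    }
    entry(256L, 3L, 1L, ncol(m))          # ImageWidth
    entry(257L, 3L, 1L, nrow(m))          # ImageLength
    entry(258L, 3L, 1L, bits)             # BitsPerSample
    entry(259L, 3L, 1L, 1L)               # Compression = none
    entry(262L, 3L, 1L, 1L)               # Photometric = BlackIsZero
    entry(273L, 4L, 1L, offset)           # StripOffsets
    entry(278L, 3L, 1L, nrow(m))          # RowsPerStrip
    entry(279L, 4L, 1L, sizes[k])         # StripByteCounts
    w32(next_off)
    offset <- ifd_off + ifd_size
  }
  invisible(path)
}

#' Write a label map as TIFF
#'
#' 16-bit for up to 65535 labels; errors beyond that (32-bit label TIFF is
#' out of scope for the baseline codec).
#'
#' @param labels integer label matrix.
#' @param path output path.
#' @export
write_label_tiff <- function(labels, path) {
  if (max(labels) > 65535L) stop("more than 65535 labels")
  write_tiff_gray(labels, path, bits = 16L)
}
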