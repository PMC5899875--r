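# Minimal baseline TIFF I/O (uncompressed, little-endian), used for multipage
# volume stacks and 2D blockface/histology images. Supported: 8-bit grayscale,
# 8-bit RGB (chunky planar config), 32-bit float grayscale; one or more strips
# per page; multipage stacks map page index -> z slice. LZW/JPEG compression,
# tiled layout and palette images are out of scope.

TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L)

read_tiff_pages <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file: ", path))
  rint <- function(off, n, size) {
    readBin(raw[(off + 1):(off + n * size)], "integer", n, size,
            signed = size > 2, endian = endian)
  }
  if (rint(2, 1, 2) != 42L) stop("bad TIFF magic in ", path)
  ifd_off <- rint(4, 1, 4)
  pages <- list()
  while (ifd_off != 0L) {
    n_entries <- rint(ifd_off, 1, 2)
    tags <- list()
    for (e in seq_len(n_entries)) {
      base <- ifd_off + 2 + (e - 1) * 12
      tag <- rint(base, 1, 2)
      type <- rint(base + 2, 1, 2)
      count <- rint(base + 4, 1, 4)
      tsz <- TIFF_TYPE_SIZE[as.character(type)]
      if (is.na(tsz)) next
      nbytes <- tsz * count
      voff <- if (nbytes <= 4) base + 8 else rint(base + 8, 1, 4)
      vals <- switch(as.character(type),
        `1` = rint(voff, count, 1),
        `3` = rint(voff, count, 2),
        `4` = rint(voff, count, 4),
        `5` = { x <- rint(voff, 2 * count, 4); x[seq(1, 2 * count, 2)] / x[seq(2, 2 * count, 2)] },
        NULL)
      if (!is.null(vals)) tags[[as.character(tag)]] <- vals
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    width <- g(256); height <- g(257)
    if (is.null(width) || is.null(height)) stop("TIFF page missing dimensions")
    bps <- g(258, 1L); spp <- g(277, 1L)
    if (g(259, 1L) != 1L) stop("compressed TIFF not supported: ", path)
    if (g(284, 1L) != 1L) stop("planar TIFF not supported: ", path)
    fmt <- g(339, 1L)[1]
    offsets <- g(273); counts <- g(279)
    if (is.null(offsets)) stop("TIFF page missing strip offsets")
    if (is.null(counts)) {
      counts <- width * height * spp * bps[1] / 8
    }
    buf <- raw(sum(counts))
    pos <- 0L
    for (s in seq_along(offsets)) {
      buf[(pos + 1):(pos + counts[s])] <- raw[(offsets[s] + 1):(offsets[s] + counts[s])]
      pos <- pos + counts[s]
    }
    vals <- if (bps[1] == 8L && fmt %in% c(1L, 2L)) {
      as.double(readBin(buf, "integer", width * height * spp, 1, signed = FALSE, endian = endian))
    } else if (bps[1] == 32L && fmt == 3L) {
      readBin(buf, "double", width * height * spp, 4, endian = endian)
    } else stop("unsupported TIFF sample layout (bits=", bps[1], ", format=", fmt, ")")
    # strip order: rows (y) outer, columns (x) inner, channels fastest if RGB
    page <- if (spp == 1L) {
      matrix(vals, nrow = width, ncol = height)           # [x, y]
    } else if (spp == 3L) {
      a <- array(vals, c(3, width, height))
      aperm(a, c(2, 3, 1))                                 # [x, y, channel]
    } else stop("unsupported samples-per-pixel: ", spp)
    pages[[length(pages) + 1L]] <- page
    ifd_off <- rint(ifd_off + 2 + n_entries * 12, 1, 4)
  }
  pages
}

write_tiff_pages <- function(pages, path, float = FALSE) {
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); w2(42L)
  spp <- if (length(dim(pages[[1]])) == 3L) 3L else 1L
  bps <- if (float) 32L else 8L
  fmt <- if (float) 3L else 1L
  n_tags <- 11L
  offset <- 8L
  for (p in seq_along(pages)) {
    page <- pages[[p]]
    width <- dim(page)[1]; height <- dim(page)[2]
    nbytes <- width * height * spp * bps / 8L
    if (nbytes %% 2L == 1L) nbytes <- nbytes + 1L
    data_off <- offset
    extra_off <- data_off + nbytes
    extra_len <- if (spp == 3L) 6L else 0L
    ifd_off <- extra_off + extra_len
    if (p == 1L) w4(ifd_off) # first-IFD pointer at header bytes 4..7
    # pixel payload: rows = y, columns = x, channels interleaved
    vals <- if (spp == 1L) as.vector(page) else as.vector(aperm(page, c(3, 1, 2)))
    if (float) writeBin(as.numeric(vals), con, size = 4, endian = "little")
    else {
      v <- as.integer(pmin(pmax(round(vals), 0), 255))
      writeBin(v, con, size = 1, endian = "little")
    }
    if ((width * height * spp * bps / 8L) %% 2L == 1L) writeBin(raw(1), con)
    if (spp == 3L) w2(c(bps, bps, bps))
    w2(n_tags)
    entry <- function(tag, type, count, value) {
      w2(tag); w2(type); w4(count)
      if (type == 3L && count == 1L) { w2(value); w2(0L) } else w4(value)
    }
    entry(256L, 4L, 1L, width)
    entry(257L, 4L, 1L, height)
    if (spp == 3L) entry(258L, 3L, 3L, extra_off) else entry(258L, 3L, 1L, bps)
    entry(259L, 3L, 1L, 1L)                   # no compression
    entry(262L, 3L, 1L, if (spp == 3L) 2L else 1L)  # RGB / BlackIsZero
    entry(273L, 4L, 1L, data_off)
    entry(277L, 3L, 1L, spp)
    entry(278L, 4L, 1L, height)
    entry(279L, 4L, 1L, width * height * spp * bps / 8L)
    entry(284L, 3L, 1L, 1L)                   # chunky
    entry(339L, 3L, 1L, fmt)
    offset <- ifd_off + 2L + n_tags * 12L + 4L
    next_ifd <- 0L
    if (p < length(pages)) {
      nd <- dim(pages[[p + 1]])
      nb_next <- nd[1] * nd[2] * spp * bps / 8L
      if (nb_next %% 2L == 1L) nb_next <- nb_next + 1L
      next_ifd <- offset + nb_next + extra_len
    }
    w4(next_ifd)
  }
  invisible(path)
}
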