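# Minimal NIfTI-1 I/O.
#
# The deployment environment carries no R NIfTI package, so the package ships
# its own compact reader/writer. Scope: single-file .nii / .nii.gz,
# axis-aligned geometry (spacing from pixdim, origin from the sform/qform
# offset), datatypes uint8 / int16 / int32 / uint16 / float32 / float64,
# 3D payloads (plus 3-channel colour stored as a 4th dimension of length 3).
# Oblique orientation matrices are out of scope and rejected.

NIFTI_DT <- list(`2` = list(what = "integer", size = 1, signed = FALSE),
                 `4` = list(what = "integer", size = 2, signed = TRUE),
                 `8` = list(what = "integer", size = 4, signed = TRUE),
                 `16` = list(what = "double", size = 4, signed = TRUE),
                 `64` = list(what = "double", size = 8, signed = TRUE),
                 `512` = list(what = "integer", size = 2, signed = FALSE))

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

read_nifti <- function(path) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348)
  if (length(hdr_raw) < 348) stop("not a NIfTI-1 file (truncated header): ", path)
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", 1, 4)
  endian <- "little"
  if (sizeof_hdr != 348L) {
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", 1, 4, endian = "big")
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file: ", path)
    endian <- "big"
  }
  rd <- function(off, what, n, size) {
    readBin(hdr_raw[(off + 1):(off + n * size)], what, n, size, endian = endian)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("unsupported NIfTI magic '", magic, "'")
  dims <- rd(40, "integer", 8, 2)
  ndim <- dims[1]
  if (!(ndim %in% c(3L, 4L))) stop("only 3D (or 3D + 3 channels) NIfTI supported, got ndim=", ndim)
  shape <- dims[2:(1 + ndim)]
  if (ndim == 4L && shape[4] == 1L) { ndim <- 3L; shape <- shape[1:3] }
  if (ndim == 4L && shape[4] != 3L) stop("4D NIfTI must have exactly 3 channels")
  datatype <- rd(70, "integer", 1, 2)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)
  pixdim <- rd(76, "double", 8, 4)
  vox_offset <- rd(108, "double", 1, 4)
  scl_slope <- rd(112, "double", 1, 4)
  scl_inter <- rd(116, "double", 1, 4)
  qform_code <- rd(252, "integer", 1, 2)
  sform_code <- rd(254, "integer", 1, 2)
  qoffset <- rd(268, "double", 3, 4)
  srow <- matrix(rd(280, "double", 12, 4), nrow = 3, byrow = TRUE)
  spacing <- abs(pixdim[2:4])
  origin <- c(0, 0, 0)
  if (sform_code > 0L) {
    lin <- srow[, 1:3]
    if (max(abs(lin - diag(diag(lin)))) > 1e-4 * max(abs(diag(lin))))
      stop("oblique sform matrices are not supported")
    spacing <- abs(diag(lin))
    origin <- srow[, 4]
  } else if (qform_code > 0L) {
    origin <- qoffset
  }
  if (any(spacing <= 0)) spacing[spacing <= 0] <- 1
  n_vox <- prod(shape)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  vals <- readBin(con, dt$what, n = n_vox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) < n_vox) stop("NIfTI payload truncated: ", path)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  Volume(array(vals, dim = shape), spacing = spacing, origin = origin)
}

write_nifti <- function(v, path, datatype = c("float32", "uint8", "int16", "float64")) {
  datatype <- match.arg(datatype)
  code <- switch(datatype, uint8 = 2L, int16 = 4L, float32 = 16L, float64 = 64L)
  size <- switch(datatype, uint8 = 1L, int16 = 2L, float32 = 4L, float64 = 8L)
  d <- dim(v$data)
  ndim <- length(d)
  dims <- integer(8); dims[1] <- ndim; dims[2:(1 + ndim)] <- d
  if (ndim < 7) dims[(2 + ndim):8] <- 1L
  pixdim <- numeric(8); pixdim[2:4] <- v$spacing; pixdim[5:8] <- 1
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                        # data_type..dim_info (offset 4..39)
  wi(dims, 2)                                   # dim[8]
  wf(c(0, 0, 0))                                # intent_p1..p3
  wi(0L, 2)                                     # intent_code
  wi(code, 2)                                   # datatype
  wi(8L * size, 2)                              # bitpix
  wi(0L, 2)                                     # slice_start
  writeBin(as.numeric(pixdim), con, size = 4, endian = "little")
  wf(352)                                       # vox_offset
  wf(1); wf(0)                                  # scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(2), con)              # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0))                                # cal_max, cal_min, slice_duration
  wf(0)                                         # toffset
  wi(c(0L, 0L), 4)                              # glmax, glmin
  writeBin(raw(104), con)                       # descrip[80] + aux_file[24]
  wi(0L, 2); wi(1L, 2)                          # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0, 0, 0, 0))                       # quaternions + qoffsets
  srow <- rbind(c(v$spacing[1], 0, 0, v$origin[1]),
                c(0, v$spacing[2], 0, v$origin[2]),
                c(0, 0, v$spacing[3], v$origin[3]))
  wf(t(srow))
  writeBin(raw(16), con)                        # intent_name[16]
  writeBin(charToRaw("n+1"), con); writeBin(raw(1), con)
  writeBin(raw(4), con)                         # extension flag
  vals <- as.numeric(v$data)
  if (datatype %in% c("uint8", "int16")) {
    vals <- round(vals)
    lim <- if (datatype == "uint8") c(0, 255) else c(-32768, 32767)
    vals <- pmin(pmax(vals, lim[1]), lim[2])
    # chunked to avoid writeBin's vector length limits on big volumes
    writeBin(as.integer(vals), con, size = size, endian = "little")
  } else {
    writeBin(vals, con, size = size, endian = "little")
  }
  invisible(path)
}
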