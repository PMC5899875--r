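#' Read a 3D volume from NIfTI or multipage TIFF
#'
#' NIfTI-1 files (`.nii`, `.nii.gz`) carry spacing and origin in their header.
#' TIFF stacks carry no physical metadata, so spacing must come from
#' `spacing_override` or from a JSON sidecar `<name>.spacing.json` with keys
#' `x_mm`, `y_mm`, `z_mm` next to the file.
#'
#' @param path path to a `.nii`, `.nii.gz`, `.tif` or `.tiff` file.
#' @param spacing_override optional mm triple taking precedence over any
#'   header/sidecar spacing.
#' @return A [Volume()].
#' @export
read_volume <- function(path, spacing_override = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    v <- read_nifti(path)
    if (!is.null(spacing_override)) v$spacing <- as.numeric(spacing_override)
    return(Volume(v$data, v$spacing, v$origin))
  }
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    spacing <- spacing_override
    if (is.null(spacing)) {
      sidecar <- paste0(sub("\\.tiff?$", "", path, ignore.case = TRUE), ".spacing.json")
      if (!file.exists(sidecar))
        stop("TIFF volume needs spacing: pass spacing_override or provide ", sidecar)
      sc <- jsonlite::read_json(sidecar)
      spacing <- c(sc$x_mm, sc$y_mm, sc$z_mm)
      if (length(spacing) != 3L) stop("sidecar ", sidecar, " must define x_mm, y_mm, z_mm")
    }
    pages <- read_tiff_pages(path)
    if (length(pages) < 1L) stop("empty TIFF stack: ", path)
    d <- dim(pages[[1]])
    color <- length(d) == 3L
    arr <- if (color) array(0, c(d[1], d[2], length(pages), 3L))
           else array(0, c(d[1], d[2], length(pages)))
    for (z in seq_along(pages)) {
      if (!identical(dim(pages[[z]]), d)) stop("TIFF pages differ in shape: ", path)
      if (color) arr[, , z, ] <- pages[[z]] else arr[, , z] <- pages[[z]]
    }
    return(Volume(arr, spacing = as.numeric(spacing)))
  }
  stop("unrecognized volume format (want .nii/.nii.gz/.tif/.tiff): ", path)
}

#' Write a 3D volume
#'
#' Format chosen from the extension: NIfTI-1 for `.nii`/`.nii.gz`, multipage
#' TIFF (with a JSON spacing sidecar) for `.tif`/`.tiff`.
#'
#' @param v a [Volume()].
#' @param path output path.
#' @param datatype storage type for NIfTI output.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, datatype = "float32") {
  if (!is_volume(v)) stop("v must be a Volume")
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE))
    return(write_nifti(v, path, datatype))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    color <- vol_is_color(v)
    nz <- vol_shape(v)[3]
    pages <- lapply(seq_len(nz), function(z) {
      if (color) v$data[, , z, , drop = TRUE] else v$data[, , z, drop = TRUE]
    })
    float <- !color && (any(v$data < 0) || any(v$data > 255) ||
                        any(v$data != round(v$data)))
    write_tiff_pages(pages, path, float = float)
    sidecar <- paste0(sub("\\.tiff?$", "", path, ignore.case = TRUE), ".spacing.json")
    jsonlite::write_json(list(x_mm = v$spacing[1], y_mm = v$spacing[2],
                              z_mm = v$spacing[3]),
                         sidecar, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  stop("unrecognized output format: ", path)
}

#' Read a 2D image (TIFF)
#'
#' @param path path to a single-page `.tif`/`.tiff`.
#' @param spacing mm per pixel (TIFF carries none); default 1.
#' @return An [Image2D()].
#' @export
read_image2d <- function(path, spacing = 1) {
  pages <- read_tiff_pages(path)
  if (length(pages) != 1L) stop("expected a single-page image, got ", length(pages), " pages")
  Image2D(pages[[1]], spacing = spacing)
}

#' Write a 2D image as single-page TIFF
#'
#' @param im an [Image2D()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image2d <- function(im, path) {
  float <- !img_is_color(im) && (any(im$data < 0) || any(im$data > 255) ||
                                 any(im$data != round(im$data)))
  write_tiff_pages(list(im$data), path, float = float)
  invisible(path)
}
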