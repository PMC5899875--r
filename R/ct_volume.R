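#' Local volume ratio across freezing from CT numbers
#'
#' CT numbers are `1000 (mu - mu_w) / mu_w`, proportional to tissue density
#' for fixed composition. Since mass is unchanged by freezing, the local
#' volume ratio follows directly from the Hounsfield values:
#' `V_after / V_before = (1000 + CT_before) / (1000 + CT_after)`.
#' Works on scalars or voxelwise on two aligned HU volumes.
#'
#' @param hu_before,hu_after HU scalars or scalar [Volume()]s, rigidly
#'   aligned when voxelwise.
#' @return unitless ratio (scalar or [Volume()] map).
#' @export
volume_ratio <- function(hu_before, hu_after) {
  if (is_volume(hu_before) || is_volume(hu_after)) {
    if (!is_volume(hu_before) || !is_volume(hu_after) ||
        !identical(vol_shape(hu_before), vol_shape(hu_after)))
      stop("voxelwise ratio needs two volumes on a common grid")
    den <- 1000 + hu_after$data
    if (any(den <= 0, na.rm = TRUE))
      stop("nonphysical HU <= -1000 in the post-freezing volume")
    return(Volume((1000 + hu_before$data) / den,
                  hu_before$spacing, hu_before$origin))
  }
  den <- 1000 + hu_after
  if (any(den <= 0)) stop("nonphysical HU <= -1000 in hu_after")
  (1000 + hu_before) / den
}

#' Percent volume change over an ROI from before/after-freezing CT
#'
#' Computes the voxelwise volume ratio over the ROI and reports
#' `100 * (mean ratio - 1)` with the population standard deviation of the
#' voxelwise ratios (x100). Nonphysical voxels (HU <= -1000 on either side)
#' are excluded and counted rather than failing the whole ROI.
#'
#' @param before,after aligned HU [Volume()]s.
#' @param roi nonempty [BinaryMask()] on the same grid.
#' @return list with `percent_change`, `sd_percent`, `n_used`,
#'   `n_excluded`.
#' @export
roi_volume_change <- function(before, after, roi) {
  stopifnot_mask(roi)
  if (!identical(vol_shape(before), vol_shape(after)) ||
      !identical(vol_shape(before), vol_shape(roi)))
    stop("volumes and roi must share a grid")
  sel <- as.logical(roi$data)
  b <- before$data[sel]
  a <- after$data[sel]
  ok <- is.finite(a) & is.finite(b) & (1000 + a) > 0 & (1000 + b) > 0
  if (!any(ok)) stop("no physically valid voxels in the ROI")
  r <- (1000 + b[ok]) / (1000 + a[ok])
  list(percent_change = 100 * (mean(r) - 1),
       sd_percent = 100 * sqrt(mean((r - mean(r))^2)),
       n_used = sum(ok), n_excluded = sum(!ok))
}
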