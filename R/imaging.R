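#' Tissue thickness projection
#'
#' For one tissue, the summed path length of that tissue along a grid axis:
#' each pixel of the projection is (number of matching voxels along the
#' axis) x pitch, in mm.  Projecting along x gives the sagittal view of the
#' finger (y-z plane), along z the frontal view (x-y).
#'
#' @param vol a [label_volume()].
#' @param tissue tissue id (1..15) or name.
#' @param axis one of "x", "y", "z".
#' @param table tissue table used to resolve names.
#' @return An object of class `thickness_projection` with fields `map` (2D
#'   matrix, mm), `tissue_id`, `axis`, `pixel_mm` (pitch of the two
#'   remaining axes).
#' @export
thickness_projection <- function(vol, tissue, axis = c("x", "y", "z"),
                                 table = tissue_table()) {
  validate_label_volume(vol)
  axis <- match.arg(axis)
  id <- if (is.character(tissue)) tissue_id(tissue, table) else as.integer(tissue)
  if (id < 1L || id > 15L) stop("unknown tissue id: ", id)
  m <- vol$labels == id
  map <- switch(axis,
    x = colSums(m) * vol$pitch[1],                      # (ny, nz)
    y = colSums(aperm(m, c(2, 1, 3))) * vol$pitch[2],   # (nx, nz)
    z = rowSums(m, dims = 2) * vol$pitch[3])            # (nx, ny)
  keep <- setdiff(1:3, match(axis, c("x", "y", "z")))
  structure(list(map = map, tissue_id = id, axis = axis,
                 pixel_mm = vol$pitch[keep]),
            class = "thickness_projection")
}

#' Integrate an image stack over a spectral band
#'
#' Unweighted mean of the per-wavelength images with wavelength in
#' `[band_lo, band_hi]` (inclusive); linear in the stack.
#'
#' @param stack a `radiance_stack` from [spectral_sweep()], or a plain 3D
#'   array (n_wavelengths, nx, ny) with a `wavelengths` attribute.
#' @param band_lo,band_hi band limits in nm.
#' @param which "transmittance" (default) or "reflectance" when `stack` is
#'   a `radiance_stack`.
#' @return 2D image matrix (nx, ny).
#' @export
spectral_integrate <- function(stack, band_lo, band_hi,
                               which = c("transmittance", "reflectance")) {
  which <- match.arg(which)
  if (inherits(stack, "radiance_stack")) {
    wl <- stack$wavelengths
    arr <- stack[[which]]
  } else {
    wl <- attr(stack, "wavelengths")
    arr <- stack
    if (is.null(wl)) stop("plain arrays need a 'wavelengths' attribute")
  }
  sel <- which(wl >= band_lo & wl <= band_hi)
  if (!length(sel)) stop("empty spectral band")
  out <- arr[sel[1], , ]
  if (length(sel) > 1)
    for (i in sel[-1]) out <- out + arr[i, , ]
  out / length(sel)
}

#' Logarithmic display transform
#'
#' `log10(max(pixel, floor))`; monotone in the input, with a positive floor
#' guarding against empty pixels.
#'
#' @param image numeric matrix.
#' @param floor positive clamp value.
#' @return Matrix of log10 values.
#' @export
to_log_display <- function(image, floor = 1e-8) {
  if (floor <= 0) stop("floor must be positive")
  log10(pmax(image, floor))
}
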