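#' Write a label volume to disk
#'
#' Two formats, chosen by extension: NIfTI-1 (`.nii` / `.nii.gz`, integer
#' datatype, pitch stored in the header pixdim) and raw little-endian int32
#' (`.raw`) with a JSON sidecar (`<path>.json`) carrying dims, pitch and
#' layout.  Both round-trip labels and pitch losslessly.
#'
#' @param vol a [label_volume()].
#' @param path output path ending in .nii, .nii.gz or .raw.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  validate_label_volume(vol, max_label = max(15L, max(vol$labels)))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    a <- vol$labels
    attr(a, "pixdim") <- vol$pitch
    img <- RNifti::asNifti(a, datatype = "int32")
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.raw$", path)) {
    con <- file(path, "wb")
    writeBin(as.integer(vol$labels), con, size = 4L, endian = "little")
    close(con)
    jsonlite::write_json(
      list(dims = dim(vol$labels), pitch_mm = vol$pitch, dtype = "int32",
           byte_order = "little", layout = "column-major (x fastest)"),
      paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  } else stop("unsupported volume format: ", path)
  invisible(path)
}

#' Read a label volume from disk
#'
#' Counterpart of [write_volume()].  Float-valued NIfTI data is rejected
#' unless every value is a whole number.
#'
#' @param path a .nii/.nii.gz or .raw file written by [write_volume()].
#' @return A [label_volume()].
#' @export
read_volume <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (any(arr != round(arr)))
      stop("volume contains non-integer values; not a label volume")
    pd <- RNifti::pixdim(img)[1:3]
    if (any(!is.finite(pd)) || any(pd <= 0))
      stop("missing or invalid pitch in NIfTI header")
    label_volume(array(as.integer(arr), dim(arr)), pitch = pd)
  } else if (grepl("\\.raw$", path)) {
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    if (is.null(meta$dims) || is.null(meta$pitch_mm))
      stop("raw sidecar must carry dims and pitch_mm")
    n <- prod(meta$dims)
    con <- file(path, "rb")
    v <- readBin(con, integer(), n = n, size = 4L, endian = "little")
    close(con)
    if (length(v) != n) stop("raw file truncated")
    label_volume(array(v, meta$dims), pitch = meta$pitch_mm)
  } else stop("unsupported volume format: ", path)
}

#' Write a simulation result to image files
#'
#' Reflectance and transmittance go to 32-bit float TIFF; run metadata and
#' totals to a JSON sidecar.  Byte-identical for identical inputs.
#'
#' @param images a `radiance_images` from [run_simulation()].
#' @param prefix output path prefix; writes `<prefix>_reflectance.tif`,
#'   `<prefix>_transmittance.tif`, `<prefix>.json`.
#' @return Character vector of the files written, invisibly.
#' @export
write_images <- function(images, prefix) {
  stopifnot(inherits(images, "radiance_images"))
  fr <- paste0(prefix, "_reflectance.tif")
  ft <- paste0(prefix, "_transmittance.tif")
  fj <- paste0(prefix, ".json")
  tiff::writeTIFF(pmin(images$reflectance, 1), fr, bits.per.sample = 32L,
                  compression = "none")
  tiff::writeTIFF(pmin(images$transmittance, 1), ft, bits.per.sample = 32L,
                  compression = "none")
  jsonlite::write_json(
    list(wavelength_nm = images$wavelength, n_photons = images$n_photons,
         seed = images$seed, totals = as.list(images$totals)),
    fj, auto_unbox = TRUE, digits = NA)
  invisible(c(fr, ft, fj))
}

#' Write a spectral sweep to image files
#'
#' The transmittance and reflectance stacks become multi-image float TIFFs
#' (one directory per wavelength) with a JSON sidecar for the wavelength
#' grid and per-wavelength totals.
#'
#' @param stack a `radiance_stack` from [spectral_sweep()].
#' @param prefix output path prefix.
#' @return Character vector of the files written, invisibly.
#' @export
write_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "radiance_stack"))
  fr <- paste0(prefix, "_reflectance.tif")
  ft <- paste0(prefix, "_transmittance.tif")
  fj <- paste0(prefix, ".json")
  as_list <- function(arr) lapply(seq_len(dim(arr)[1]),
                                  function(i) pmin(arr[i, , ], 1))
  tiff::writeTIFF(as_list(stack$reflectance), fr, bits.per.sample = 32L,
                  compression = "none")
  tiff::writeTIFF(as_list(stack$transmittance), ft, bits.per.sample = 32L,
                  compression = "none")
  jsonlite::write_json(
    list(wavelengths_nm = stack$wavelengths, n_photons = stack$n_photons,
         seed = stack$seed, totals = stack$totals),
    fj, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(c(fr, ft, fj))
}
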