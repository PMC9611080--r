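#' Construct a tissue label volume
#'
#' A label volume is a 3D integer array of tissue ids (0 = ambient medium)
#' together with the physical voxel pitch in millimetres.  Axis convention:
#' x is the finger width, y the finger long axis, z the depth along which
#' light is propagated.
#'
#' @param labels 3D integer array; every value must be a non-negative
#'   integer tissue id.
#' @param pitch voxel edge lengths in mm, length 1 (isotropic) or 3.
#' @return An object of class `label_volume`.
#' @examples
#' v <- label_volume(array(0L, c(4, 4, 4)), pitch = 0.2)
#' dim(v$labels)
#' @export
label_volume <- function(labels, pitch = 0.2) {
  if (length(dim(labels)) != 3L)
    stop("labels must be a 3D array")
  if (is.double(labels)) {
    if (any(labels != round(labels)))
      stop("labels must be integer-valued")
    storage.mode(labels) <- "integer"
  }
  if (!is.integer(labels)) stop("labels must be integer")
  if (length(pitch) == 1L) pitch <- rep(pitch, 3L)
  if (length(pitch) != 3L || any(!is.finite(pitch)) || any(pitch <= 0))
    stop("pitch must be positive on all axes")
  x <- structure(list(labels = labels, pitch = as.numeric(pitch)),
                 class = "label_volume")
  validate_label_volume(x)
}

#' Validate a label volume
#'
#' Enforces the type invariants: 3D integer grid, labels in 0..15 unless
#' `max_label` says otherwise, strictly positive pitch.
#'
#' @param vol a `label_volume`.
#' @param max_label largest admissible label id.
#' @return `vol`, invisibly.
#' @export
validate_label_volume <- function(vol, max_label = 15L) {
  if (!inherits(vol, "label_volume")) stop("not a label_volume")
  rng <- range(vol$labels)
  if (rng[1] < 0L || rng[2] > max_label)
    stop("labels must lie in 0..", max_label)
  if (any(vol$pitch <= 0)) stop("pitch must be positive")
  invisible(vol)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %d x %d x %d voxels (%s mm pitch), %d voxels total\n",
              d[1], d[2], d[3],
              paste(format(x$pitch, trim = TRUE), collapse = " x "),
              prod(d)))
  tb <- label_counts(x)
  cat(sprintf("  %d non-ambient labels present: %s\n", nrow(tb),
              paste(tb$id, collapse = ", ")))
  invisible(x)
}

#' Per-label voxel counts
#'
#' @param vol a `label_volume`.
#' @return data.frame with columns `id` and `count` for every non-ambient
#'   label present in the volume.
#' @export
label_counts <- function(vol) {
  tb <- tabulate(vol$labels, nbins = max(15L, max(vol$labels)))
  present <- which(tb > 0L)
  data.frame(id = present, count = tb[present])
}
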