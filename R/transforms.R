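#' Specify a joint-inflammation transform
#'
#' Synovitis is modelled as swelling of the synovial fluid (cavity) and
#' thickening of the synovial membrane: target volume ratios relative to the
#' healthy joint, realised by in-plane radial rescaling of the transverse
#' slices around the joint, with the surrounding tissues displaced outward.
#'
#' @param joint_y y-position of the joint centre in mm; `NULL` (default)
#'   places it at the centroid of the synovial-cavity voxels nearest the
#'   proximal interphalangeal joint of the default phantom.
#' @param extent_mm axial extent of the transform (cosine-tapered), mm.
#' @param fluid_factor target synovial-cavity volume ratio (>= 1).
#' @param membrane_factor target synovial-membrane volume ratio (>= 1).
#' @return A list of class `inflammation_spec`.
#' @export
inflammation_spec <- function(joint_y = NULL, extent_mm = 8,
                              fluid_factor = 7.5, membrane_factor = 3) {
  if (extent_mm <= 0) stop("extent_mm must be positive")
  if (fluid_factor < 1 || membrane_factor < 1)
    stop("inflammation factors must be >= 1")
  structure(list(joint_y = joint_y, extent_mm = extent_mm,
                 fluid_factor = fluid_factor,
                 membrane_factor = membrane_factor),
            class = "inflammation_spec")
}

#' Named inflammation presets
#'
#' Three disease states: membrane thickening only, fluid effusion only, and
#' the combined state (fluid x 7.5, membrane x 3).
#'
#' @param name one of "inflamed-membrane", "inflamed-fluid",
#'   "inflamed-combined".
#' @param ... passed to [inflammation_spec()] (e.g. `joint_y`).
#' @return An `inflammation_spec`.
#' @export
inflammation_preset <- function(name = c("inflamed-combined", "inflamed-fluid",
                                         "inflamed-membrane"), ...) {
  name <- match.arg(name)
  switch(name,
    "inflamed-membrane" = inflammation_spec(fluid_factor = 1,
                                            membrane_factor = 3, ...),
    "inflamed-fluid" = inflammation_spec(fluid_factor = 7.5,
                                         membrane_factor = 1, ...),
    "inflamed-combined" = inflammation_spec(fluid_factor = 7.5,
                                            membrane_factor = 3, ...))
}

#' Apply joint inflammation to a label volume
#'
#' Transverse (x-z) slices within the axial extent are remapped by a
#' piecewise radial stretch about the joint centre: the region inside the
#' bone/cartilage radius is kept rigid, the cavity band is dilated to reach
#' the target fluid volume, the membrane band to reach the target membrane
#' volume, and everything beyond is displaced outward rigidly.  The stretch
#' amplitude is cosine-tapered along y and solved by bisection on the
#' achieved voxel counts, so the realised volume ratios match the requested
#' factors up to voxelization.  Outside the extent the volume is untouched.
#'
#' @param vol a [label_volume()].
#' @param spec an [inflammation_spec()].
#' @param table tissue table used to find the cavity/membrane/bone labels.
#' @return The transformed [label_volume()], with attribute
#'   `achieved_ratios` = c(fluid, membrane) counted inside the extent.
#' @export
apply_joint_inflammation <- function(vol, spec = inflammation_spec(),
                                     table = tissue_table()) {
  validate_label_volume(vol)
  stopifnot(inherits(spec, "inflammation_spec"))
  cav <- tissue_id("synovial cavity", table)
  mem <- tissue_id("synovial membrane", table)
  hard <- c(tissue_id("bone", table), tissue_id("cartilage", table))
  lab <- vol$labels
  d <- dim(lab); h <- vol$pitch
  yc <- (seq_len(d[2]) - 0.5) * h[2]

  y0 <- spec$joint_y
  if (is.null(y0)) {
    idx <- which(lab == cav, arr.ind = TRUE)
    if (!nrow(idx)) stop("no synovial cavity voxels in the volume")
    # centroid of the most proximal cavity cluster (the PIP joint)
    ys <- yc[idx[, 2]]
    y0 <- mean(ys[ys <= min(ys) + 4])
  }
  half <- spec$extent_mm / 2
  iys <- which(abs(yc - y0) <= half)
  if (!length(iys)) stop("extent selects no slices")
  if (!any(lab[, iys, ] == cav))
    stop("no synovial cavity voxels at the joint position")

  if (spec$fluid_factor == 1 && spec$membrane_factor == 1) {
    out <- vol
    attr(out, "achieved_ratios") <- c(fluid = 1, membrane = 1)
    return(out)
  }

  # in-plane joint centre from the cavity voxels inside the extent
  sub <- lab[, iys, , drop = FALSE]
  ci <- which(sub == cav, arr.ind = TRUE)
  cx <- mean((ci[, 1] - 0.5) * h[1])
  cz <- mean((ci[, 3] - 0.5) * h[3])

  xs <- (seq_len(d[1]) - 0.5) * h[1] - cx
  zs <- (seq_len(d[3]) - 0.5) * h[3] - cz
  DX <- matrix(xs, d[1], d[3])
  DZ <- matrix(zs, d[1], d[3], byrow = TRUE)
  RR <- sqrt(DX^2 + DZ^2)
  area <- h[1] * h[3]
  taper <- 0.5 * (1 + cos(pi * (yc[iys] - y0) / half))

  edge_dist <- min(cx, d[1] * h[1] - cx, cz, d[3] * h[3] - cz)

  remap <- function(Ac, Am) {
    new_slices <- vector("list", length(iys))
    for (k in seq_along(iys)) {
      sl <- lab[, iys[k], ]
      ncav <- sum(sl == cav); nmem <- sum(sl == mem)
      if (ncav + nmem == 0) { new_slices[[k]] <- sl; next }
      nhard <- sum(sl %in% hard)
      s2 <- 1 + taper[k] * (Ac - 1)
      am <- 1 + taper[k] * (Am - 1)
      r1 <- sqrt(nhard * area / pi)
      r2 <- sqrt(r1^2 + ncav * area / pi)
      r3 <- sqrt(r2^2 + nmem * area / pi)
      r2p <- sqrt(r1^2 + s2 * ncav * area / pi)
      r3p <- sqrt(r2p^2 + am * nmem * area / pi)
      delta <- r3p - r3
      rmax <- max(RR[sl != 0], 0)
      if (rmax + delta + 0.4 > edge_dist)
        stop("inflammation factors unreachable within the grid")
      rho <- RR
      b2 <- RR > r1 & RR <= r2p
      b3 <- RR > r2p & RR <= r3p
      b4 <- RR > r3p
      if (r2p > r1) rho[b2] <- r1 + (RR[b2] - r1) * (r2 - r1) / (r2p - r1)
      if (r3p > r2p) rho[b3] <- r2 + (RR[b3] - r2p) * (r3 - r2) / (r3p - r2p)
      rho[b4] <- RR[b4] - delta
      scl <- ifelse(RR > 0, rho / RR, 1)
      sx <- pmin(d[1], pmax(1, ceiling((DX * scl + cx) / h[1])))
      sz <- pmin(d[3], pmax(1, ceiling((DZ * scl + cz) / h[3])))
      new_slices[[k]] <- matrix(sl[cbind(c(sx), c(sz))], d[1], d[3])
    }
    new_slices
  }
  count_in <- function(slices, id) sum(vapply(slices, function(s) sum(s == id),
                                              numeric(1)))
  n_cav0 <- sum(lab[, iys, ] == cav)
  n_mem0 <- sum(lab[, iys, ] == mem)
  if (n_mem0 == 0 && spec$membrane_factor > 1)
    stop("no synovial membrane voxels at the joint position")

  solve_amp <- function(target, n0, id, fix_other, which) {
    if (target == 1) return(1)
    lo <- 1; hi <- 4
    val <- function(A) {
      sl <- if (which == "cav") remap(A, fix_other) else remap(fix_other, A)
      count_in(sl, id) / n0
    }
    while (val(hi) < target) {
      hi <- hi * 1.6
      if (hi > 200) stop("inflammation factors unreachable within the grid")
    }
    for (i in 1:24) {
      mid <- (lo + hi) / 2
      v <- val(mid)
      if (abs(v - target) < 0.003 * target) return(mid)
      if (v < target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  Ac <- solve_amp(spec$fluid_factor, n_cav0, cav, 1, "cav")
  Am <- solve_amp(spec$membrane_factor, n_mem0, mem, Ac, "mem")
  slices <- remap(Ac, Am)

  out <- lab
  for (k in seq_along(iys)) out[, iys[k], ] <- slices[[k]]
  res <- label_volume(out, pitch = vol$pitch)
  attr(res, "achieved_ratios") <- c(
    fluid = count_in(slices, cav) / n_cav0,
    membrane = if (n_mem0 > 0) count_in(slices, mem) / n_mem0 else NA_real_)
  res
}

#' Rupture a tendon
#'
#' Tendon voxels whose y-centre lies inside `y_range` are relabelled as the
#' surrounding filler tissue (subcutis); nothing else moves - no tendon
#' contraction or deformation is modelled.
#'
#' @param vol a [label_volume()].
#' @param tendon_id label id of the tendon (default 6).
#' @param y_range numeric length-2, half-open interval `[lo, hi)` in mm; a
#'   zero-width range is the identity.
#' @param replacement label that fills the gap (default subcutis, 1).
#' @return The transformed [label_volume()].
#' @export
apply_tendon_rupture <- function(vol, tendon_id = 6L, y_range,
                                 replacement = 1L) {
  validate_label_volume(vol)
  if (!any(vol$labels == tendon_id)) stop("tendon label ", tendon_id,
                                          " absent from volume")
  stopifnot(length(y_range) == 2, y_range[2] >= y_range[1])
  if (y_range[1] == y_range[2]) return(vol)
  yc <- (seq_len(dim(vol$labels)[2]) - 0.5) * vol$pitch[2]
  iys <- which(yc >= y_range[1] & yc < y_range[2])
  if (!length(iys)) return(vol)
  lab <- vol$labels
  sub <- lab[, iys, , drop = FALSE]
  sub[sub == tendon_id] <- as.integer(replacement)
  lab[, iys, ] <- sub
  label_volume(lab, pitch = vol$pitch)
}

#' Rescale the phantom geometry
#'
#' Nearest-neighbour resampling to `round(factor * dim)` voxels per axis;
#' the physical voxel pitch is unchanged, so the finger itself shrinks or
#' grows.  Labels are categorical, so no interpolation takes place and no
#' new label values can appear.
#'
#' @param vol a [label_volume()].
#' @param factors numeric length 3, scale factors (fx, fy, fz) > 0.
#' @return The rescaled [label_volume()].
#' @export
scale_geometry <- function(vol, factors) {
  validate_label_volume(vol)
  stopifnot(length(factors) == 3)
  if (any(factors <= 0)) stop("scale factors must be positive")
  d <- dim(vol$labels)
  nd <- as.integer(round(factors * d))
  if (any(nd < 1L)) stop("scaling would produce an empty axis")
  maps <- lapply(1:3, function(a)
    pmin(d[a], pmax(1L, as.integer(ceiling((seq_len(nd[a]) - 0.5) / factors[a])))))
  label_volume(vol$labels[maps[[1]], maps[[2]], maps[[3]], drop = FALSE],
               pitch = vol$pitch)
}
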