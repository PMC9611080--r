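#' Generate the synthetic finger label volume
#'
#' Builds per-tissue binary masks from the idealized geometry in `params`,
#' resolves overlaps with the tissue prioritization list and applies the
#' single-voxel cleanup pass.  With default parameters the result contains
#' all 15 tissue labels on the 6,809,600-voxel grid and is bit-identical
#' across calls (the only randomness, corpuscle jitter, is off by default
#' and seeded otherwise).
#'
#' @param params a [phantom_params()] list.
#' @param table a [tissue_table()]; its priority ranks drive overlap
#'   resolution.
#' @param cleanup apply [cleanup_labels()] to the assembled volume
#'   (default TRUE).
#' @return A [label_volume()].
#' @examples
#' \donttest{
#' vol <- generate_phantom()
#' nrow(label_counts(vol))  # 15
#' }
#' @export
generate_phantom <- function(params = phantom_params(), table = tissue_table(),
                             cleanup = TRUE) {
  stopifnot(inherits(params, "phantom_params"))
  validate_tissue_table(table)
  masks <- phantom_masks(params)
  vol <- resolve_overlaps(masks, table, pitch = params$pitch)
  if (cleanup) vol <- cleanup_labels(vol)
  vol
}

# Build the per-tissue logical masks (named by tissue name) on the full grid.
# Everything is vectorized over the flattened voxel-centre coordinates.
phantom_masks <- function(params) {
  p <- params
  nx <- p$dims[1]; ny <- p$dims[2]; nz <- p$dims[3]
  h <- p$pitch
  cx <- nx * h / 2; cz <- nz * h / 2
  xc <- (seq_len(nx) - 0.5) * h
  yc <- (seq_len(ny) - 0.5) * h
  zc <- (seq_len(nz) - 0.5) * h

  # radius profile along y with rounded tip
  rx_y <- approx(p$profile_y, p$profile_rx, xout = yc, rule = 2)$y
  tipf <- rep(1, ny)
  beyond <- yc > p$tip_start
  tipf[beyond] <- sqrt(pmax(0, 1 - ((yc[beyond] - p$tip_start) / p$tip_length)^2))
  rx_y <- rx_y * tipf
  rz_y <- p$rz_ratio * rx_y
  if (any(rx_y <= p$epidermis_mm + p$dermis_mm + 0.3))
    stop("grid too small: finger cross-section vanishes inside the grid")
  if (max(rx_y) + 0.4 >= cx || max(rz_y) + 0.4 >= cz)
    stop("grid too small to fit all structures (finger exceeds lateral extent)")
  if (any(p$bone_y1 >= ny * h))
    stop("grid too small to fit all structures (bones exceed long axis)")

  dx <- rep(xc - cx, times = ny * nz)
  dz <- rep(zc - cz, each = nx * ny)
  Y  <- rep(rep(yc, each = nx), times = nz)
  RX <- rep(rep(rx_y, each = nx), times = nz)
  RZ <- rep(rep(rz_y, each = nx), times = nz)
  adx <- abs(dx); adz <- abs(dz)
  pow <- p$superellipse_power

  inside_off <- function(t) {
    (adx / pmax(RX - t, 0.05))^pow + (adz / pmax(RZ - t, 0.05))^pow <= 1
  }
  finger <- inside_off(0)
  skin_t <- p$epidermis_mm + p$dermis_mm
  epi_in <- inside_off(p$epidermis_mm)
  der_in <- inside_off(skin_t)

  masks <- list()
  masks[["epidermis"]] <- finger & !epi_in
  masks[["dermis"]] <- epi_in & !der_in
  masks[["subcutis"]] <- finger   # lowest priority: takes the remainder

  dx2 <- dx^2; dz2 <- dz^2

  # phalanges: elliptical shafts, wider than deep and shifted dorsally
  # (volar flattening leaves room for the flexor tendon), with flat
  # joint-facing ends so the joint gap stays free of bone and the synovial
  # space is a clean central lens
  dzb <- dz - p$bone_dz
  bone_ell <- function(b) (dx / p$bone_rx[b])^2 + (dzb / p$bone_rz[b])^2 <= 1
  bone <- rep(FALSE, length(dx))
  for (b in seq_along(p$bone_rx)) {
    bone <- bone | (bone_ell(b) & Y >= p$bone_y0[b] & Y <= p$bone_y1[b])
  }
  masks[["bone"]] <- bone

  # cartilage: thin discs capping the bone ends that face a joint
  if (p$features$cartilage) {
    cart <- rep(FALSE, length(dx))
    ends <- list(c(1, 1), c(2, -1), c(2, 1), c(3, -1))  # (bone, side facing joint)
    for (e in ends) {
      b <- e[1]; side <- e[2]
      disc <- if (side > 0)
        Y > p$bone_y1[b] & Y <= p$bone_y1[b] + p$cartilage_mm
      else
        Y < p$bone_y0[b] & Y >= p$bone_y0[b] - p$cartilage_mm
      cart <- cart | (disc & bone_ell(b))
    }
    masks[["cartilage"]] <- cart
  }

  # synovial cavity and membrane at each joint: the cavity is an elliptical
  # fluid lens between the cartilage faces, the membrane/joint capsule a
  # thin shell wrapped around it
  if (p$features$joints) {
    dzc <- dz - p$cavity_dz
    cav <- rep(FALSE, length(dx)); mem <- rep(FALSE, length(dx))
    for (j in seq_along(p$joint_y)) {
      ady <- abs(Y - p$joint_y[j])
      cav_j <- (dx / p$cavity_rx[j])^2 + (dzc / p$cavity_rz[j])^2 <= 1 &
        ady <= p$cavity_half_y[j]
      m <- p$membrane_mm
      mem_j <- (dx / (p$cavity_rx[j] + m))^2 + (dzc / (p$cavity_rz[j] + m))^2 <= 1 &
        ady <= p$cavity_half_y[j] + m
      cav <- cav | cav_j
      mem <- mem | mem_j
    }
    masks[["synovial cavity"]] <- cav
    masks[["synovial membrane"]] <- mem
  }

  # tendons following the bone surface; z-path clamped inside the finger.
  # The flexor rides under the volar bone surface, the extensor hugs the
  # dorsal one.
  bz_prof <- approx(
    x = c(0, p$bone_y1[1], p$bone_y0[2], p$bone_y1[2], p$bone_y0[3],
          p$bone_y1[3], ny * h),
    y = c(p$bone_rz[1], p$bone_rz[1], p$bone_rz[2], p$bone_rz[2],
          p$bone_rz[3], p$bone_rz[3], p$bone_rz[3] * 0.5),
    xout = yc, rule = 2)$y
  rz_in_y <- pmax(rz_y - skin_t, 0.05)
  zoff_flex <- pmin((bz_prof - p$bone_dz) + p$flexor_clear + p$flexor_half[2],
                    rz_in_y - 0.2)
  zoff_ext  <- pmin((bz_prof + p$bone_dz) + p$extensor_clear +
                      p$extensor_half[2], rz_in_y - 0.2)
  ZF <- rep(rep(zoff_flex, each = nx), times = nz)
  ZE <- rep(rep(zoff_ext, each = nx), times = nz)
  flex_f <- (dx / p$flexor_half[1])^2 + ((dz + ZF) / p$flexor_half[2])^2
  ext_f  <- (dx / p$extensor_half[1])^2 + ((dz - ZE) / p$extensor_half[2])^2
  masks[["tendon"]] <- (flex_f <= 1 | ext_f <= 1) & der_in

  # pulley A4: annular sheath around the flexor tendon over the mid phalanx
  if (p$features$pulley) {
    t <- p$pulley_mm
    outer <- (dx / (p$flexor_half[1] + t))^2 +
             ((dz + ZF) / (p$flexor_half[2] + t))^2
    masks[["pulley A4"]] <- outer <= 1 & flex_f > 1 &
      Y >= p$pulley_y[1] & Y <= p$pulley_y[2] & der_in
  }

  # collateral ligaments: short capsules on both sides of each joint
  if (p$features$ligaments) {
    lig <- rep(FALSE, length(dx))
    for (j in seq_along(p$joint_y)) {
      xoff <- p$joint_ref_rx[j] + p$ligament_off
      dyy <- pmax(0, abs(Y - p$joint_y[j]) - p$ligament_half_y)
      for (s in c(-1, 1)) {
        lig <- lig | ((dx - s * xoff)^2 + (dz - 0.2)^2 + dyy^2 <= p$ligament_r^2)
      }
    }
    masks[["collateral ligament"]] <- lig & der_in
  }

  # volar plates: small blocks between the volar bone surface and the
  # flexor tendon at each joint
  if (p$features$volar_plates) {
    vp <- rep(FALSE, length(dx))
    for (j in seq_along(p$joint_y)) {
      zs <- p$joint_ref_rz[j] - p$bone_dz   # volar bone surface depth
      vp <- vp | (abs(dx) <= p$plate_half_x &
                  abs(Y - p$joint_y[j]) <= p$plate_half_y &
                  dz >= -(zs + 1.2) & dz <= -(zs - 0.2))
    }
    masks[["volar plate"]] <- vp & der_in
  }

  # vessels and nerves: paired tubes at fixed fractions of the inner section
  rx_in_y <- pmax(rx_y - p$vessel_margin, 0.1)
  rz_in_v <- pmax(rz_y - p$vessel_margin, 0.1)
  RXI <- rep(rep(rx_in_y, each = nx), times = nz)
  RZI <- rep(rep(rz_in_v, each = nx), times = nz)
  tube_pair <- function(frac, r) {
    m <- rep(FALSE, length(dx))
    for (s in c(-1, 1)) {
      m <- m | ((dx - s * frac[1] * RXI)^2 + (dz - frac[2] * RZI)^2 <= r^2)
    }
    m & der_in
  }
  if (p$features$vessels) {
    masks[["artery"]] <- tube_pair(p$artery_frac, p$artery_r)
    masks[["vein"]] <- tube_pair(p$vein_frac, p$vein_r)
  }
  if (p$features$nerves) masks[["nerve"]] <- tube_pair(p$nerve_frac, p$nerve_r)

  # Pacinian corpuscles: spheres in the volar subcutis
  if (p$features$corpuscles) {
    ky <- p$corpuscle_y
    kx <- cx + p$corpuscle_xsign * p$corpuscle_x
    iz <- approx(yc, rz_y, xout = ky, rule = 2)$y
    kz <- cz - p$corpuscle_zfrac * pmax(iz - skin_t, 0.1)
    if (p$jitter_mm > 0) {
      set.seed(p$seed)
      kx <- kx + rnorm(length(kx), 0, p$jitter_mm)
      ky <- ky + rnorm(length(ky), 0, p$jitter_mm)
      kz <- kz + rnorm(length(kz), 0, p$jitter_mm)
    }
    corp <- rep(FALSE, length(dx))
    X <- dx + cx; Zf <- dz + cz
    for (k in seq_along(ky)) {
      corp <- corp | ((X - kx[k])^2 + (Y - ky[k])^2 + (Zf - kz[k])^2
                      <= p$corpuscle_r^2)
    }
    masks[["Pacinian corpuscle"]] <- corp & der_in
  }

  lapply(masks, function(m) { dim(m) <- p$dims; m })
}

#' Resolve overlapping tissue masks into a label volume
#'
#' Every voxel claimed by at least one mask receives the id of the claimant
#' with the best (lowest) priority rank in `table`; unclaimed voxels stay
#' ambient (0).
#'
#' @param masks named list of logical 3D arrays, names must be tissue names
#'   from `table`; all must share one grid shape.
#' @param table a [tissue_table()].
#' @param pitch voxel pitch passed through to the result.
#' @return A [label_volume()].
#' @export
resolve_overlaps <- function(masks, table = tissue_table(), pitch = 0.2) {
  validate_tissue_table(table)
  if (!length(masks) || is.null(names(masks)))
    stop("masks must be a named list")
  shp <- dim(masks[[1]])
  for (m in masks) {
    if (!identical(dim(m), shp)) stop("all masks must share one grid shape")
    if (!is.logical(m)) stop("masks must be logical arrays")
  }
  ids <- vapply(names(masks), tissue_id, integer(1), table = table)
  ranks <- table$priority_rank[match(ids, table$id)]
  out <- array(0L, dim = shp)
  for (i in order(ranks, decreasing = TRUE)) {  # worst first, best painted last
    out[masks[[i]]] <- ids[i]
  }
  label_volume(out, pitch = pitch)
}

#' Remove stray voxels and fill single-voxel holes
#'
#' Applies a 6-neighbourhood consistency filter: any voxel with no
#' 6-neighbour of its own label (the ambient label 0 counts as a label) is
#' reassigned to the most frequent label among its in-grid 6-neighbours,
#' ties broken toward the smallest label id.  A voxel whose neighbours all
#' share one label different from its own is the special unanimous case of
#' the same rule, so isolated voxels are removed and single-voxel holes are
#' filled in one sweep.  Sweeps are repeated until the volume is a fixed
#' point, which makes the operation idempotent.
#'
#' @param vol a [label_volume()].
#' @param max_iter safety cap on the number of sweeps.
#' @return The cleaned [label_volume()].
#' @export
cleanup_labels <- function(vol, max_iter = 25L) {
  validate_label_volume(vol, max_label = max(15L, max(vol$labels)))
  lab <- vol$labels
  for (i in seq_len(max_iter)) {
    res <- cpp_cleanup_pass(lab, dim(lab))
    lab <- res$labels
    if (res$changed == 0L) break
  }
  if (i == max_iter && res$changed > 0L)
    warning("cleanup did not reach a fixed point within ", max_iter, " sweeps")
  label_volume(lab, pitch = vol$pitch)
}

#' Structural validation report for a phantom
#'
#' Computes per-label voxel counts, containment checks (the skin nests:
#' every tissue voxel 6-adjacent to ambient is epidermis, the dermis wraps
#' the interior, bone is never exposed to ambient) and per-label 6-connected
#' component counts.  Checks are reported with pass/fail flags rather than
#' raised as errors.
#'
#' @param vol a [label_volume()].
#' @param table a [tissue_table()] used to name the labels.
#' @return A list of class `phantom_report` with elements `counts`,
#'   `checks` (named logical) and `pass` (all checks combined).
#' @export
validate_phantom <- function(vol, table = tissue_table()) {
  validate_label_volume(vol)
  counts <- label_counts(vol)
  counts$name <- table$name[match(counts$id, table$id)]
  surf <- cpp_surface_labels(vol$labels, dim(vol$labels))  # labels touching ambient
  epi <- tissue_id("epidermis", table)
  bone <- tissue_id("bone", table)
  checks <- c(
    all_15_labels = nrow(counts) == 15L,
    skin_encloses = all(surf %in% c(0L, epi)),
    bone_interior = !(bone %in% surf),
    partition = sum(counts$count) == sum(vol$labels != 0L)
  )
  comps <- vapply(counts$id, function(id)
    cpp_n_components(vol$labels, dim(vol$labels), id), integer(1))
  counts$components <- comps
  structure(list(counts = counts, checks = checks, pass = all(checks)),
            class = "phantom_report")
}

#' @export
print.phantom_report <- function(x, ...) {
  cat("<phantom_report>", if (x$pass) "PASS" else "FAIL", "\n")
  for (nm in names(x$checks))
    cat(sprintf("  %-14s %s\n", nm, if (x$checks[[nm]]) "ok" else "FAIL"))
  print(x$counts, row.names = FALSE)
  invisible(x)
}
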