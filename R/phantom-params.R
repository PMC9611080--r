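#' Parameters of the procedural finger phantom
#'
#' Returns the full parameter set describing the idealized index-finger
#' geometry.  All lengths are millimetres.  The defaults reproduce the
#' reference model: a (160, 320, 133) grid at 0.2 mm isotropic pitch
#' (6,809,600 voxels), y the long axis of the finger, z the depth axis along
#' which light is propagated.  The finger cross-section is a superellipse;
#' bones are capsules (cylinders with spherical caps); the two modelled
#' joints (proximal and distal interphalangeal, PIP and DIP) carry cartilage
#' caps, a synovial cavity and a surrounding synovial membrane / joint
#' capsule shell; flexor and extensor tendons run the whole length of the
#' finger.
#'
#' @param dims integer grid dimensions (nx, ny, nz).
#' @param pitch voxel pitch in mm (scalar, isotropic).
#' @param features named logical overrides toggling structure groups:
#'   `joints` (synovial cavity + membrane), `cartilage`, `pulley`,
#'   `ligaments`, `volar_plates`, `vessels`, `nerves`, `corpuscles`.
#' @param jitter_mm standard deviation of the positional jitter applied to
#'   Pacinian corpuscle centres (0 = none, the default).
#' @param seed integer seed used only when `jitter_mm > 0`.
#' @param ... further overrides of the geometry fields (advanced use); any
#'   named element of the default list may be replaced.
#' @return A list of class `phantom_params`.
#' @examples
#' p <- phantom_params()
#' p$dims
#' @export
phantom_params <- function(dims = c(160L, 320L, 133L), pitch = 0.2,
                           features = list(), jitter_mm = 0, seed = 1L, ...) {
  p <- list(
    dims = as.integer(dims),
    pitch = pitch,
    # outer shape: superellipse half-axes rx (width) with rz = rz_ratio * rx,
    # piecewise-linear radius profile along y, rounded tip
    superellipse_power = 2.5,
    rz_ratio = 0.88,
    # radius profile with gentle waists at the joint creases (the skin is
    # anchored at the flexion creases, so soft tissue thins over the joints)
    profile_y  = c(0, 21.5, 24.5, 27.5, 33, 40, 42.5, 45, 58),
    profile_rx = c(7.8, 7.15, 6.6, 6.95, 6.6, 6.45, 6.0, 6.3, 5.8),
    tip_start = 58, tip_length = 7.5,
    # skin shells
    epidermis_mm = 0.4, dermis_mm = 1.2,
    # phalanges: elliptical shafts (wider than deep, volar-flattened via a
    # dorsal offset), flat joint-facing ends; joints between them
    bone_y0 = c(0.6, 26.5, 44.5),
    bone_y1 = c(22.5, 40.5, 56.0),
    bone_rx = c(4.4, 3.8, 2.8),
    bone_rz = c(3.0, 2.6, 2.0),
    bone_dz = 0.6,
    # joints: PIP between bones 1-2, DIP between bones 2-3
    joint_y = c(24.5, 42.5),
    joint_ref_rx = c(4.1, 3.3),
    joint_ref_rz = c(2.8, 2.3),
    cartilage_mm = 0.4,
    # synovial cavity: an elliptical fluid lens between the cartilage faces,
    # spanning the central part of the bone cross-section
    cavity_rx = c(2.6, 2.1), cavity_rz = c(2.4, 1.9),
    cavity_half_y = c(0.9, 0.8), cavity_dz = 0.3,
    membrane_mm = 0.45,
    # tendons: elliptical cross-sections tracking the bone surface
    flexor_half = c(2.2, 0.9), flexor_clear = 0.4,
    extensor_half = c(2.0, 0.55), extensor_clear = 0.25,
    pulley_y = c(33.5, 35.5), pulley_mm = 0.4,
    ligament_r = 0.6, ligament_half_y = 2.5, ligament_off = 0.4,
    plate_half_x = 2.2, plate_half_y = 1.6,
    # vessels / nerves: straight tubes at fixed fractions of the inner
    # cross-section half-axes (so they taper with the finger), tucked into
    # the subcutaneous ring beside the bone
    artery_frac = c(0.80, -0.55), artery_r = 0.45,
    vein_frac = c(0.80, 0.50), vein_r = 0.40,
    nerve_frac = c(0.88, -0.42), nerve_r = 0.40,
    vessel_margin = 2.0,
    # Pacinian corpuscles: small spheres in the volar subcutis
    corpuscle_r = 0.5,
    corpuscle_y = c(8, 15, 22, 31, 38, 48),
    corpuscle_xsign = c(1, -1, 1, -1, 1, -1),
    corpuscle_x = 3.2, corpuscle_zfrac = 0.75,
    jitter_mm = jitter_mm, seed = as.integer(seed),
    features = list(joints = TRUE, cartilage = TRUE, pulley = TRUE,
                    ligaments = TRUE, volar_plates = TRUE, vessels = TRUE,
                    nerves = TRUE, corpuscles = TRUE)
  )
  p$features <- modifyList(p$features, as.list(features))
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown)) stop("unknown phantom parameter(s): ",
                              paste(unknown, collapse = ", "))
    p <- modifyList(p, dots)
  }
  if (length(p$dims) != 3L || any(p$dims < 1L))
    stop("dims must be three positive integers")
  if (p$pitch <= 0) stop("pitch must be positive")
  lens <- c(p$profile_rx, p$bone_rx, p$bone_rz, p$cavity_rx, p$cavity_rz,
            p$epidermis_mm, p$dermis_mm,
            p$cartilage_mm, p$membrane_mm, p$flexor_half, p$extensor_half,
            p$ligament_r, p$corpuscle_r)
  if (any(lens <= 0)) stop("all lengths must be positive")
  ylim <- p$dims[2] * p$pitch
  if (any(p$joint_y <= 0 | p$joint_y >= ylim))
    stop("joint positions must lie strictly inside the grid")
  class(p) <- "phantom_params"
  p
}
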