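#' Monte Carlo simulation configuration
#'
#' @param n_photons number of photon packets to launch (>= 1).
#' @param seed master seed; every packet derives its own independent,
#'   reproducible random stream from it, so results are bit-identical for a
#'   fixed seed.
#' @param wavelength wavelength in nm at which properties are evaluated.
#' @param w_threshold Russian-roulette weight threshold (0 < w_th < 1).
#' @param roulette_m roulette survival divisor (> 1): packets below the
#'   threshold survive with probability 1/m and are reweighted by m.
#' @param record_absorption accumulate the 3D absorbed-energy grid.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_photons = 1e5, seed = 1L, wavelength = 860,
                              w_threshold = 1e-4, roulette_m = 10,
                              record_absorption = FALSE) {
  if (n_photons < 1) stop("n_photons must be >= 1")
  if (w_threshold <= 0 || w_threshold >= 1)
    stop("w_threshold must lie in (0, 1)")
  if (roulette_m <= 1) stop("roulette_m must be > 1")
  structure(list(n_photons = n_photons, seed = as.integer(seed),
                 wavelength = wavelength, w_threshold = w_threshold,
                 roulette_m = roulette_m,
                 record_absorption = isTRUE(record_absorption)),
            class = "simulation_config")
}

#' Launch positions of collimated photon packets
#'
#' Packets start with weight one and direction (0, 0, 1), uniformly
#' distributed over the z = 0 entry face of the grid.
#'
#' @param n number of packets.
#' @param width,height physical extent of the entry face in mm (nx * pitch,
#'   ny * pitch).
#' @param seed master seed.
#' @return Matrix with columns x, y (mm) and w (all exactly 1).
#' @export
launch_packets <- function(n, width, height, seed = 1L) {
  m <- cpp_launch(as.integer(n), width, height, as.double(seed))
  colnames(m) <- c("x", "y", "w")
  m
}

#' Sample an exponential free path
#'
#' `s = -log(u) / mu_t`; a vanishing attenuation coefficient yields an
#' infinite (ballistic) path.
#'
#' @param mu_t total attenuation coefficient, mm^-1.
#' @param u uniform random number in (0, 1).
#' @return Step length in mm (possibly `Inf`).
#' @export
sample_step <- function(mu_t, u) cpp_sample_step(mu_t, u)

#' Henyey-Greenstein scattering of a direction
#'
#' Draws the polar cosine from the HG inverse CDF (isotropic for g = 0) and
#' the azimuth uniformly, then rotates the incoming direction in its local
#' frame.  The mean polar cosine equals g.
#'
#' @param dir incoming unit direction (length 3).
#' @param g anisotropy factor, -1 < g < 1.
#' @param u1,u2 uniform random numbers in (0, 1).
#' @return New unit direction (length 3).
#' @export
scatter_hg <- function(dir, g, u1, u2) {
  if (g <= -1 || g >= 1) stop("g must lie in (-1, 1)")
  cpp_scatter_hg(dir, g, u1, u2)
}

#' Unpolarized Fresnel reflectance at an index step
#'
#' @param n_i,n_t refractive indices on the incident and transmitted side.
#' @param cos_theta_i cosine of the angle of incidence (0 < cos <= 1).
#' @return List with `R` (reflection probability), `cos_theta_t` and `tir`
#'   (TRUE beyond the critical angle, where R = 1).
#' @export
fresnel <- function(n_i, n_t, cos_theta_i) {
  stopifnot(n_i >= 1, n_t >= 1, cos_theta_i > 0, cos_theta_i <= 1)
  cpp_fresnel(n_i, n_t, cos_theta_i)
}

#' Russian roulette termination
#'
#' Packets at or above the threshold pass unchanged; packets below survive
#' with probability 1/m carrying m times their weight (unbiased in
#' expectation) and are terminated otherwise (weight 0).
#'
#' @param w packet weight.
#' @param w_th weight threshold.
#' @param m survival divisor (> 1).
#' @param u uniform random number in (0, 1).
#' @return The new weight (0 for a terminated packet).
#' @export
roulette <- function(w, w_th, m, u) cpp_roulette(w, w_th, m, u)

#' Geometric traversal of the voxel grid
#'
#' Walks voxel faces along `dir` from `pos`, consuming `mu_t * length` of
#' the dimensionless step per sub-segment, until the step is spent (an
#' interaction) or the packet leaves through a z face; at the lateral x/y
#' grid limits the direction is mirror-reflected.
#'
#' @param vol a [label_volume()].
#' @param mu_t_by_label numeric vector of total attenuation per label,
#'   indexed from label 0 (element 1 = ambient).
#' @param pos start position in mm.
#' @param dir unit direction.
#' @param step dimensionless step to spend.
#' @return List with `event` ("interaction", "exit_forward",
#'   "exit_backward"), final `pos`, `dir`, 0-based `voxel` index, geometric
#'   `distance` travelled (mm) and `step_left`.
#' @export
traverse <- function(vol, mu_t_by_label, pos, dir, step) {
  validate_label_volume(vol, max_label = length(mu_t_by_label) - 1L)
  if (any(!is.finite(pos))) stop("non-finite position")
  if (abs(sqrt(sum(dir^2)) - 1) > 1e-9) stop("dir must be a unit vector")
  cpp_traverse(vol$labels, dim(vol$labels), vol$pitch, mu_t_by_label,
               pos, dir, step)
}

# property matrix for the engine: one row per label id 0..max_label
prop_matrix <- function(spectra, wavelength, max_label) {
  m <- matrix(0, nrow = max_label + 1L, ncol = 4)
  colnames(m) <- c("mu_a", "mu_s", "g", "n")
  m[1, ] <- c(0, 0, 0, 1)
  for (id in seq_len(max_label)) {
    p <- properties_at(spectra, id, wavelength)
    m[id + 1L, ] <- c(p$mu_a, p$mu_s, p$g, p$n)
  }
  m
}

#' Run the Monte Carlo transport simulation
#'
#' Collimated packets of weight one enter through the z = 0 face (uniform
#' over the face), undergo Fresnel reflection/refraction at every voxel
#' face where the refractive index changes, propagate by the MCML
#' hop-drop-spin scheme (exponential free paths in mu_t, a fraction
#' mu_a/mu_t of the weight absorbed in the voxel of each interaction,
#' Henyey-Greenstein scattering), are mirror-reflected at the lateral grid
#' limits and terminated by Russian roulette.  Packets exiting backward
#' through the entry face accumulate into the reflectance image, packets
#' exiting forward into the transmittance image, each at the (x, y) pixel
#' of exit; all quantities are fractions of the launched weight.
#'
#' @param vol a [label_volume()].
#' @param spectra an `optical_spectra` table covering every label present.
#' @param config a [simulation_config()].
#' @return An object of class `radiance_images`: `reflectance` and
#'   `transmittance` (nx x ny matrices), optional `absorbed` 3D grid,
#'   `totals` (R, T, A, lost) and the run metadata.
#' @export
run_simulation <- function(vol, spectra, config = simulation_config()) {
  validate_label_volume(vol, max_label = 15L)
  stopifnot(inherits(config, "simulation_config"))
  max_lab <- max(vol$labels)
  props <- prop_matrix(spectra, config$wavelength, max_lab)
  res <- cpp_run_mc(vol$labels, dim(vol$labels), vol$pitch, props,
                    config$n_photons, config$seed, 1,
                    config$w_threshold, config$roulette_m,
                    config$record_absorption)
  structure(list(
    reflectance = res$reflectance,
    transmittance = res$transmittance,
    absorbed = if (config$record_absorption) res$absorbed else NULL,
    totals = c(R = res$R_total, T = res$T_total, A = res$A_total,
               lost = res$lost),
    wavelength = config$wavelength,
    n_photons = config$n_photons,
    seed = config$seed,
    pitch = vol$pitch), class = "radiance_images")
}

#' @export
print.radiance_images <- function(x, ...) {
  cat(sprintf("<radiance_images> %g nm, %g packets (seed %d)\n",
              x$wavelength, x$n_photons, x$seed))
  cat(sprintf("  R = %.5f  T = %.5f  A = %.5f\n",
              x$totals["R"], x$totals["T"], x$totals["A"]))
  invisible(x)
}

#' Spectral sweep of simulations
#'
#' One [run_simulation()] per wavelength with an independent seeded
#' substream each (the first wavelength reproduces `run_simulation` with
#' the same seed bit for bit).  The default grid of the shipped table,
#' 400-1100 nm in 10 nm steps, yields 71 wavelengths.
#'
#' @param vol a [label_volume()].
#' @param spectra an `optical_spectra` table.
#' @param wavelengths nm vector; all must be within the table range.
#' @param config a [simulation_config()]; its `wavelength` field is ignored.
#' @return An object of class `radiance_stack`: `wavelengths`,
#'   `transmittance` and `reflectance` arrays of dim (n_wavelengths, nx,
#'   ny), and `totals` (data.frame, one row per wavelength).
#' @export
spectral_sweep <- function(vol, spectra, wavelengths = seq(400, 1100, 10),
                           config = simulation_config()) {
  validate_label_volume(vol, max_label = 15L)
  stopifnot(length(wavelengths) >= 1)
  max_lab <- max(vol$labels)
  d <- dim(vol$labels)
  nw <- length(wavelengths)
  Tarr <- array(0, c(nw, d[1], d[2]))
  Rarr <- array(0, c(nw, d[1], d[2]))
  totals <- data.frame(wavelength = wavelengths, R = 0, T = 0, A = 0)
  for (i in seq_len(nw)) {
    props <- prop_matrix(spectra, wavelengths[i], max_lab)
    res <- cpp_run_mc(vol$labels, d, vol$pitch, props,
                      config$n_photons, config$seed, i,
                      config$w_threshold, config$roulette_m, FALSE)
    Tarr[i, , ] <- res$transmittance
    Rarr[i, , ] <- res$reflectance
    totals$R[i] <- res$R_total
    totals$T[i] <- res$T_total
    totals$A[i] <- res$A_total
  }
  structure(list(wavelengths = wavelengths, transmittance = Tarr,
                 reflectance = Rarr, totals = totals,
                 n_photons = config$n_photons, seed = config$seed),
            class = "radiance_stack")
}
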