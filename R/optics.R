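#' Default wavelength-resolved optical properties for the 15 tissues
#'
#' Builds the shipped optical-property table over 400-1100 nm (10 nm steps
#' by default) from a small chromophore model: tissue absorption is a
#' mixture of oxy-/deoxy-haemoglobin (blood volume fraction and oxygen
#' saturation), water and - for the epidermis - melanin, on top of a small
#' baseline; reduced scattering follows the usual power law
#' \eqn{\mu_s'(\lambda) = a (\lambda/500\,nm)^{-b}} and is converted to
#' \eqn{\mu_s} with the tissue anisotropy g.  All coefficients are stored in
#' mm^-1.
#'
#' These values are literature-style defaults intended to be plausible for
#' each tissue class (skin, fat, tendon, bone, cartilage, blood, synovial
#' fluid); they are explicitly replaceable via [load_spectra()] and are not
#' measurements of any specific subject.
#'
#' @param wavelengths wavelength grid in nm.
#' @return A data.frame of class `optical_spectra` with columns `tissue_id`,
#'   `tissue`, `wavelength`, `mu_a`, `mu_s`, `g`, `n` (coefficients mm^-1).
#' @export
default_spectra <- function(wavelengths = seq(400, 1100, by = 10)) {
  wl <- sort(unique(wavelengths))
  # coarse chromophore tables (interpolated linearly between knots)
  knots <- c(400, 450, 500, 550, 600, 650, 700, 750, 800, 850, 900, 950,
             1000, 1050, 1100)
  # molar extinction, cm^-1 / M
  eps_oxy <- c(266000, 63000, 21000, 43000, 3200, 368, 290, 518, 816, 1058,
               1198, 1200, 1058, 950, 900)
  eps_deoxy <- c(223300, 103000, 21000, 53000, 14700, 3750, 1794, 1405, 762,
                 691, 800, 725, 650, 600, 550)
  mua_water <- c(0.0006, 0.0003, 0.00025, 0.0005, 0.002, 0.0032, 0.006,
                 0.028, 0.020, 0.043, 0.068, 0.39, 0.36, 0.15, 0.18)  # cm^-1
  interp <- function(v) approx(knots, v, xout = wl)$y
  # whole blood: 150 g/L haemoglobin, 64500 g/mol
  mua_blood_oxy <- 2.303 * interp(eps_oxy) * 150 / 64500      # cm^-1
  mua_blood_deoxy <- 2.303 * interp(eps_deoxy) * 150 / 64500  # cm^-1
  mua_w <- interp(mua_water)
  mua_mel <- 519 * (wl / 500)^-3.5                            # cm^-1, melanosome

  #                 B      S     W     M      a(cm-1) b     g     n
  comp <- list(
    "subcutis"            = c(0.012, 0.75, 0.15, 0,    17,  0.7,  0.80, 1.44),
    "Pacinian corpuscle"  = c(0.005, 0.75, 0.70, 0,    15,  1.0,  0.90, 1.38),
    "nerve"               = c(0.010, 0.75, 0.60, 0,    22,  1.0,  0.90, 1.40),
    "vein"                = c(1.000, 0.60, 0.80, 0,    22,  0.66, 0.98, 1.37),
    "artery"              = c(1.000, 0.98, 0.80, 0,    22,  0.66, 0.98, 1.37),
    "tendon"              = c(0.015, 0.75, 0.60, 0,    40,  1.3,  0.93, 1.40),
    "collateral ligament" = c(0.010, 0.75, 0.55, 0,    35,  1.3,  0.93, 1.40),
    "volar plate"         = c(0.010, 0.75, 0.55, 0,    30,  1.2,  0.92, 1.40),
    "pulley A4"           = c(0.010, 0.75, 0.55, 0,    35,  1.3,  0.93, 1.40),
    "bone"                = c(0.050, 0.75, 0.25, 0,    32,  0.65, 0.92, 1.55),
    "cartilage"           = c(0.005, 0.75, 0.70, 0,    4,   1.2,  0.92, 1.38),
    "synovial cavity"     = c(0.0005, 0.75, 0.95, 0,   0.5, 1.0,  0.90, 1.345),
    "synovial membrane"   = c(0.040, 0.75, 0.70, 0,    15,  1.2,  0.90, 1.38),
    "epidermis"           = c(0.000, 0.75, 0.20, 0.03, 45,  1.4,  0.85, 1.42),
    "dermis"              = c(0.020, 0.75, 0.65, 0,    40,  1.35, 0.90, 1.40)
  )
  tab <- tissue_table()
  rows <- lapply(names(comp), function(nm) {
    p <- comp[[nm]]
    mua_cm <- p[1] * (p[2] * mua_blood_oxy + (1 - p[2]) * mua_blood_deoxy) +
      p[3] * mua_w + p[4] * mua_mel + 0.05
    mus_red_cm <- p[5] * (wl / 500)^-p[6]
    data.frame(tissue_id = tissue_id(nm, tab), tissue = nm, wavelength = wl,
               mu_a = mua_cm / 10, mu_s = mus_red_cm / 10 / (1 - p[7]),
               g = p[7], n = p[8], stringsAsFactors = FALSE)
  })
  spectra_table(do.call(rbind, rows))
}

#' Construct and validate an optical spectra table
#'
#' @param df data.frame with columns `tissue_id`, `wavelength`, `mu_a`,
#'   `mu_s`, `g`, `n` (and optionally `tissue`).
#' @param unit unit of `mu_a`/`mu_s` in `df`: "mm-1" (stored as is) or
#'   "cm-1" (converted to mm^-1).
#' @return The validated table, class `optical_spectra`.
#' @export
spectra_table <- function(df, unit = c("mm-1", "cm-1")) {
  unit <- match.arg(unit)
  need <- c("tissue_id", "wavelength", "mu_a", "mu_s", "g", "n")
  if (!all(need %in% names(df)))
    stop("spectra table needs columns ", paste(need, collapse = ", "))
  if (unit == "cm-1") {
    df$mu_a <- df$mu_a / 10
    df$mu_s <- df$mu_s / 10
  }
  if (any(df$mu_a < 0)) stop("mu_a must be >= 0")
  if (any(df$mu_s < 0)) stop("mu_s must be >= 0")
  if (any(df$g <= -1 | df$g >= 1)) stop("anisotropy g must lie in (-1, 1)")
  if (any(df$n < 1)) stop("refractive index n must be >= 1")
  if (any(df$tissue_id < 1)) stop("tissue_id must be >= 1 (0 is ambient)")
  dup <- duplicated(df[, c("tissue_id", "wavelength")])
  if (any(dup))
    stop("duplicate wavelength ", df$wavelength[dup][1], " nm for tissue ",
         df$tissue_id[dup][1])
  df <- df[order(df$tissue_id, df$wavelength), ]
  rownames(df) <- NULL
  class(df) <- c("optical_spectra", "data.frame")
  df
}

#' Read an optical spectra table from CSV
#'
#' The CSV must carry columns `tissue_id, wavelength, mu_a, mu_s, g, n`
#' (plus optional `tissue` names).  Validation enforces the physical
#' invariants (non-negative coefficients, |g| < 1, n >= 1, no duplicate
#' wavelengths per tissue) and - when `require_all = TRUE` - that all 15
#' tissues have a row set covering at least 400-1100 nm.
#'
#' @param path CSV file path.
#' @param unit unit of the stored coefficients ("mm-1" default or "cm-1").
#' @param require_all demand a complete 15-tissue table spanning 400-1100 nm.
#' @return An `optical_spectra` table.
#' @export
load_spectra <- function(path, unit = c("mm-1", "cm-1"), require_all = TRUE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  tab <- spectra_table(df, unit = match.arg(unit))
  if (require_all) {
    missing <- setdiff(1:15, unique(tab$tissue_id))
    if (length(missing))
      stop("missing tissue row set(s): ", paste(missing, collapse = ", "))
    for (id in 1:15) {
      r <- range(tab$wavelength[tab$tissue_id == id])
      if (r[1] > 400 || r[2] < 1100)
        stop("tissue ", id, " does not span 400-1100 nm")
    }
  }
  tab
}

#' Write an optical spectra table to CSV
#'
#' @param table an `optical_spectra` table (stored in mm^-1).
#' @param path output CSV path.
#' @export
write_spectra <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Optical properties of a tissue at a wavelength
#'
#' Exact table rows at grid wavelengths, linear interpolation in between.
#' The ambient medium (id 0) is non-absorbing, non-scattering, n = 1.
#'
#' @param table an `optical_spectra` table.
#' @param tissue_id integer label id (0 = ambient).
#' @param wavelength nm; must lie within the tissue's tabulated range.
#' @return A list with `mu_a`, `mu_s` (mm^-1), `g`, `n`.
#' @export
properties_at <- function(table, tissue_id, wavelength) {
  if (tissue_id == 0)
    return(list(mu_a = 0, mu_s = 0, g = 0, n = 1))
  rows <- table[table$tissue_id == tissue_id, ]
  if (!nrow(rows)) stop("no optical properties for tissue ", tissue_id)
  r <- range(rows$wavelength)
  if (wavelength < r[1] || wavelength > r[2])
    stop(sprintf("wavelength %g nm outside tabulated range [%g, %g] nm",
                 wavelength, r[1], r[2]))
  if (nrow(rows) == 1L)
    return(list(mu_a = rows$mu_a, mu_s = rows$mu_s, g = rows$g, n = rows$n))
  f <- function(col) approx(rows$wavelength, rows[[col]], xout = wavelength)$y
  list(mu_a = f("mu_a"), mu_s = f("mu_s"), g = f("g"), n = f("n"))
}

#' Apply disease-state property overrides
#'
#' Overrides are named per-tissue adjustments, each either a multiplicative
#' `factor` or an absolute `value` for one property column, applied across
#' all wavelengths - the mechanism by which expected arthritic changes
#' (e.g. a turbid, hypervascular joint) are layered on a base table.
#'
#' @param table an `optical_spectra` table.
#' @param overrides data.frame with columns `tissue_id`, `field` (one of
#'   mu_a, mu_s, g, n) and exactly one of `factor` / `value` per row, or a
#'   YAML file path holding a list of such records.
#' @return The adjusted `optical_spectra` table.
#' @export
apply_spectra_overrides <- function(table, overrides) {
  if (is.character(overrides) && length(overrides) == 1) {
    recs <- yaml::read_yaml(overrides)
    overrides <- do.call(rbind, lapply(recs, function(r)
      data.frame(tissue_id = r$tissue_id, field = r$field,
                 factor = if (!is.null(r$factor)) r$factor else NA_real_,
                 value = if (!is.null(r$value)) r$value else NA_real_)))
  }
  for (i in seq_len(nrow(overrides))) {
    o <- overrides[i, ]
    if (!o$field %in% c("mu_a", "mu_s", "g", "n"))
      stop("unknown property field: ", o$field)
    sel <- table$tissue_id == o$tissue_id
    if (!any(sel)) stop("no rows for tissue ", o$tissue_id)
    if (!is.null(o$factor) && !is.na(o$factor)) {
      table[[o$field]][sel] <- table[[o$field]][sel] * o$factor
    } else {
      table[[o$field]][sel] <- o$value
    }
  }
  spectra_table(as.data.frame(table))
}

#' Example arthritic override set
#'
#' Illustrative disease-state adjustments: the synovial effusion turns
#' turbid (scattering and absorption up) and the inflamed membrane becomes
#' hypervascular (absorption up).  Meant as a template for user-supplied
#' override files, not as measured pathology values.
#'
#' @return An overrides data.frame for [apply_spectra_overrides()].
#' @export
arthritic_overrides <- function() {
  data.frame(
    tissue_id = c(12L, 12L, 13L),
    field = c("mu_s", "mu_a", "mu_a"),
    factor = c(5, 2, 1.5),
    value = NA_real_
  )
}
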