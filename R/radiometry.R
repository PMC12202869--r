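#' Spectral band
#'
#' A closed wavelength interval in nanometres, the common currency of all
#' band-integrated photon fluxes.
#'
#' @param lambda_min,lambda_max Band edges in nm; `0 < lambda_min < lambda_max`,
#'   both finite.
#' @return An object of class `spectral_band` with fields `lambda_min` and
#'   `lambda_max`.
#' @examples
#' spectral_band(800, 1100)
#' @export
spectral_band <- function(lambda_min, lambda_max) {
  if (!is_scalar_number(lambda_min) || !is_scalar_number(lambda_max)) {
    stop_domain("band edges must be finite scalars")
  }
  if (lambda_min <= 0 || lambda_min >= lambda_max) {
    stop_domain("need 0 < lambda_min < lambda_max, got [",
                lambda_min, ", ", lambda_max, "]")
  }
  structure(list(lambda_min = lambda_min, lambda_max = lambda_max),
            class = "spectral_band")
}

#' Grey-body thermal source
#'
#' @param temperature Source temperature in kelvin (> 0).  Vent fluids at
#'   400 degC correspond to 673.15 K.
#' @param emissivity Scalar grey-body emissivity in (0, 1]; default 1
#'   (ideal blackbody).
#' @return An object of class `blackbody_source`.
#' @examples
#' blackbody_source(673.15)
#' @export
blackbody_source <- function(temperature, emissivity = 1) {
  if (!is_scalar_number(temperature) || temperature <= 0) {
    stop_domain("temperature must be a positive finite scalar (kelvin)")
  }
  if (!is_scalar_number(emissivity) || emissivity <= 0 || emissivity > 1) {
    stop_domain("emissivity must lie in (0, 1]")
  }
  structure(list(temperature = temperature, emissivity = emissivity),
            class = "blackbody_source")
}

#' Band-integrated photon radiance container
#'
#' @param value Photon radiance in photons cm^-2 s^-1 sr^-1 (>= 0).
#' @param band Optional [spectral_band()] provenance.
#' @param source_description Free-text provenance.
#' @return An object of class `photon_flux`.
#' @export
photon_flux <- function(value, band = NULL, source_description = "") {
  if (!is_scalar_number(value) || value < 0) {
    stop_domain("photon flux value must be a non-negative finite scalar")
  }
  if (!is.null(band) && !inherits(band, "spectral_band")) {
    stop_domain("band must be a spectral_band or NULL")
  }
  structure(list(value = value, band = band,
                 source_description = source_description),
            class = "photon_flux")
}

#' @export
print.photon_flux <- function(x, ...) {
  band <- if (is.null(x$band)) "unspecified band" else {
    sprintf("%g-%g nm", x$band$lambda_min, x$band$lambda_max)
  }
  cat(sprintf("<photon_flux> %.6g photons cm^-2 s^-1 sr^-1 (%s)%s\n",
              x$value, band,
              if (nzchar(x$source_description)) {
                paste0(" - ", x$source_description)
              } else ""))
  invisible(x)
}

#' Planck spectral photon radiance
#'
#' Spectral photon radiance of a grey body,
#' \deqn{L_p(\lambda) = \epsilon \frac{2c}{\lambda^4}
#'       \frac{1}{e^{hc/\lambda k_B T} - 1},}
#' converted to photons s^-1 cm^-2 sr^-1 nm^-1.  This is the photon-count
#' (not energy) form of Planck's law: dividing the spectral radiance by the
#' photon energy \eqn{hc/\lambda} drops one power of \eqn{\lambda} from the
#' usual \eqn{\lambda^{-5}} law.
#'
#' @param lambda_nm Wavelength(s) in nm, > 0 (vectorized).
#' @param source A [blackbody_source()].
#' @return Numeric vector of spectral photon radiance values,
#'   photons s^-1 cm^-2 sr^-1 nm^-1.
#' @examples
#' planck_photon_radiance(1000, blackbody_source(673.15))
#' @export
planck_photon_radiance <- function(lambda_nm, source) {
  stopifnot(inherits(source, "blackbody_source"))
  if (!is.numeric(lambda_nm) || !length(lambda_nm) ||
      any(!is.finite(lambda_nm)) || any(lambda_nm <= 0)) {
    stop_domain("wavelengths must be positive and finite (nm)")
  }
  lam <- lambda_nm * 1e-9                       # m
  x <- .const$h * .const$c / (lam * .const$kB * source$temperature)
  # photons s^-1 m^-2 sr^-1 m^-1  ->  cm^-2 nm^-1 is a factor 1e-13
  source$emissivity * 1e-13 * 2 * .const$c / lam^4 / expm1(x)
}

#' Band-integrated blackbody photon flux
#'
#' Integrates [planck_photon_radiance()] over a wavelength band by adaptive
#' quadrature (relative tolerance `rel_tol`).  Wide bands are split into
#' log-spaced segments before quadrature so the integrand's peak is always
#' well resolved; the result is additive over band partitions.
#'
#' @param band A [spectral_band()] in nm.
#' @param source A [blackbody_source()].
#' @param rel_tol Relative integration tolerance (default 1e-9, comfortably
#'   below the 1e-6 accuracy asserted in the tests).
#' @return A [photon_flux()] in photons cm^-2 s^-1 sr^-1 carrying the band
#'   and source provenance.
#' @examples
#' band_photon_flux(spectral_band(800, 1100), blackbody_source(673.15))
#' @export
band_photon_flux <- function(band, source, rel_tol = 1e-9) {
  stopifnot(inherits(band, "spectral_band"), inherits(source, "blackbody_source"))
  # log-spaced segmentation keeps adaptive quadrature honest on wide bands
  ratio <- band$lambda_max / band$lambda_min
  n_seg <- max(1L, ceiling(log10(ratio) * 4))
  edges <- exp(seq(log(band$lambda_min), log(band$lambda_max),
                   length.out = n_seg + 1L))
  total <- 0
  for (i in seq_len(n_seg)) {
    total <- total + integrate(planck_photon_radiance,
                               lower = edges[i], upper = edges[i + 1L],
                               source = source,
                               rel.tol = rel_tol, subdivisions = 400L)$value
  }
  photon_flux(total, band = band,
              source_description = sprintf("blackbody T=%g K, emissivity=%g",
                                           source$temperature,
                                           source$emissivity))
}

#' Total blackbody photon radiance (closed form)
#'
#' Photon radiance integrated over all wavelengths,
#' \eqn{4 \zeta(3) c (k_B T / hc)^3} per steradian per m^2, converted to
#' cm^-2.  Scales as \eqn{T^3}; used as the closed-form limit for very wide
#' band integrals.
#'
#' @param source A [blackbody_source()].
#' @return Total photon radiance, photons cm^-2 s^-1 sr^-1.
#' @export
total_photon_radiance <- function(source) {
  stopifnot(inherits(source, "blackbody_source"))
  zeta3 <- 1.2020569031595943
  source$emissivity * 4 * zeta3 * .const$c *
    (.const$kB * source$temperature / (.const$h * .const$c))^3 * 1e-4
}

#' Photon energy in electron-volts
#'
#' \eqn{E = hc/\lambda} with \eqn{hc} = 1239.841984 eV nm.
#'
#' @param lambda_nm Wavelength(s) in nm, > 0.
#' @return Photon energy in eV.
#' @examples
#' photon_energy_ev(471)  # ~2.63 eV, the chalcopyrite energy gap
#' @export
photon_energy_ev <- function(lambda_nm) {
  if (!is.numeric(lambda_nm) || any(!is.finite(lambda_nm)) ||
      any(lambda_nm <= 0)) {
    stop_domain("wavelength must be positive and finite (nm)")
  }
  .const$hc_ev_nm / lambda_nm
}

#' Wavelength of a photon of given energy
#'
#' Inverse of [photon_energy_ev()].
#'
#' @param energy_ev Photon energy in eV, > 0.
#' @return Wavelength in nm.
#' @export
ev_to_wavelength <- function(energy_ev) {
  if (!is.numeric(energy_ev) || any(!is.finite(energy_ev)) ||
      any(energy_ev <= 0)) {
    stop_domain("energy must be positive and finite (eV)")
  }
  .const$hc_ev_nm / energy_ev
}

#' Convert micromole photon irradiance to photon radiance
#'
#' Converts an irradiance quoted in umol photons m^-2 s^-1 (the unit of
#' photosynthesis photon-requirement measurements) into photon radiance in
#' photons cm^-2 s^-1 sr^-1, assuming the flux is distributed over a given
#' solid angle (hemispherical 2*pi sr by default).
#'
#' @param flux_umol Irradiance in umol photons m^-2 s^-1, >= 0.
#' @param solid_angle Solid angle in sr, in (0, 4*pi].
#' @return Photon radiance, photons cm^-2 s^-1 sr^-1.
#' @examples
#' mol_flux_to_photon_radiance(0.04)  # ~3.8e11: low-light photosynthesis limit
#' @export
mol_flux_to_photon_radiance <- function(flux_umol, solid_angle = 2 * pi) {
  if (!is.numeric(flux_umol) || any(!is.finite(flux_umol)) ||
      any(flux_umol < 0)) {
    stop_domain("flux must be non-negative and finite")
  }
  if (!is_scalar_number(solid_angle) || solid_angle <= 0 ||
      solid_angle > 4 * pi) {
    stop_domain("solid angle must lie in (0, 4*pi] sr")
  }
  flux_umol * .const$NA_mol * 1e-6 / 1e4 / solid_angle
}

#' Serialize a photon flux as a JSON record
#'
#' @param flux A [photon_flux()].
#' @param temperature_K,emissivity Optional provenance fields to embed.
#' @return A JSON string of the record
#'   `{band_nm, temperature_K, emissivity, flux_photons_cm2_s_sr}`.
#' @export
flux_to_json <- function(flux, temperature_K = NA_real_, emissivity = NA_real_) {
  stopifnot(inherits(flux, "photon_flux"))
  rec <- list(
    band_nm = if (is.null(flux$band)) NULL else
      c(flux$band$lambda_min, flux$band$lambda_max),
    temperature_K = temperature_K,
    emissivity = emissivity,
    flux_photons_cm2_s_sr = flux$value
  )
  jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null")
}
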