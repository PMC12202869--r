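#' SHG emission wavelength
#'
#' Second harmonic generation doubles the optical frequency, so the emitted
#' wavelength is half the excitation wavelength.
#'
#' @param lambda_ex Excitation wavelength(s) in nm, > 0.
#' @return Emission wavelength(s) in nm.
#' @examples
#' shg_wavelength(928)   # 464
#' shg_wavelength(1064)  # 532
#' @export
shg_wavelength <- function(lambda_ex) {
  if (!is.numeric(lambda_ex) || any(!is.finite(lambda_ex)) ||
      any(lambda_ex <= 0)) {
    stop_domain("excitation wavelength must be positive and finite (nm)")
  }
  lambda_ex / 2
}

#' Excitation-power series of SHG intensity
#'
#' @param power_mw Excitation powers in mW (all > 0, length >= 3).
#' @param intensity SHG intensities (detector counts or mW, all >= 0).
#' @param excitation_wavelength Excitation wavelength in nm.
#' @return An object of class `power_series`.
#' @export
power_series <- function(power_mw, intensity, excitation_wavelength = NA_real_) {
  if (length(power_mw) < 3L || length(power_mw) != length(intensity)) {
    stop_domain("need >= 3 (power, intensity) points of equal length")
  }
  if (any(!is.finite(power_mw)) || any(power_mw <= 0)) {
    stop_domain("all excitation powers must be positive and finite (mW)")
  }
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop_domain("all intensities must be non-negative and finite")
  }
  structure(list(power_mw = as.numeric(power_mw),
                 intensity = as.numeric(intensity),
                 excitation_wavelength = excitation_wavelength),
            class = "power_series")
}

#' Fit a power law to an SHG excitation series
#'
#' Ordinary least squares of log10(intensity) on log10(power): the slope is
#' the power-law exponent (2 for ideal SHG).  Non-positive intensities are
#' dropped with a warning; fewer than 3 usable points is an error.
#'
#' @param series A [power_series()].
#' @return An object of class `power_law_fit` with fields `exponent`,
#'   `log_prefactor` (log10 of the prefactor), `r_squared`, and `n_used`.
#' @examples
#' s <- power_series(c(0.45, 0.8, 1.5, 2.2, 3.2), 3.7 * c(0.45, 0.8, 1.5, 2.2, 3.2)^2)
#' fit_power_law(s)$exponent  # 2
#' @export
fit_power_law <- function(series) {
  stopifnot(inherits(series, "power_series"))
  ok <- series$intensity > 0
  if (any(!ok)) {
    warning(sum(!ok), " non-positive intensity point(s) excluded from the ",
            "log-log fit", call. = FALSE)
  }
  if (sum(ok) < 3L) {
    stop_domain("fewer than 3 usable (positive-intensity) points")
  }
  lp <- log10(series$power_mw[ok])
  li <- log10(series$intensity[ok])
  fit <- lm(li ~ lp)
  ss_tot <- sum((li - mean(li))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 1
  structure(list(exponent = unname(coef(fit)[2L]),
                 log_prefactor = unname(coef(fit)[1L]),
                 r_squared = min(max(r2, 0), 1),
                 n_used = sum(ok)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> exponent %.6g, prefactor 10^%.6g, R^2 %.6g (n=%d)\n",
              x$exponent, x$log_prefactor, x$r_squared, x$n_used))
  invisible(x)
}

#' Instrument loss budget
#'
#' Multiplicative detection-chain losses between the sample and the recorded
#' signal.  The defaults are the measured chain of the reference setup:
#' spectrometer+CCD quantum-harvesting efficiency 55%, fiber coupling 60%,
#' beam-splitting prism transmission 50%.
#'
#' @param detector_qe,fiber_coupling,beamsplitter_transmission Fractions in
#'   (0, 1].
#' @return An object of class `loss_budget`.
#' @export
loss_budget <- function(detector_qe = 0.55, fiber_coupling = 0.60,
                        beamsplitter_transmission = 0.50) {
  vals <- c(detector_qe = detector_qe, fiber_coupling = fiber_coupling,
            beamsplitter_transmission = beamsplitter_transmission)
  if (any(!is.finite(vals)) || any(vals <= 0) || any(vals > 1)) {
    stop_domain("all loss factors must lie in (0, 1]")
  }
  structure(as.list(vals), class = "loss_budget")
}

#' Correct a measured power for instrument losses
#'
#' Divides the measured power by the product of the loss factors to recover
#' the power originally leaving the sample.
#'
#' @param measured Measured power in mW, >= 0.
#' @param losses A [loss_budget()].
#' @return Loss-corrected power in mW.
#' @examples
#' correct_output_power(1, loss_budget())  # 1 / 0.165 = 6.06...
#' @export
correct_output_power <- function(measured, losses = loss_budget()) {
  stopifnot(inherits(losses, "loss_budget"))
  if (!is.numeric(measured) || any(!is.finite(measured)) || any(measured < 0)) {
    stop_domain("measured power must be non-negative and finite (mW)")
  }
  measured / (losses$detector_qe * losses$fiber_coupling *
                losses$beamsplitter_transmission)
}

#' SHG energy-conversion efficiency
#'
#' Ratio of the loss-corrected outgoing SHG power to the excitation power.
#' For ideal quadratic SHG the efficiency grows linearly with excitation
#' power (log-log slope 1).
#'
#' @param corrected_output Loss-corrected output power in mW, >= 0.
#' @param p_ex Excitation power in mW, > 0.
#' @return Dimensionless efficiency.
#' @export
conversion_efficiency <- function(corrected_output, p_ex) {
  if (!is.numeric(p_ex) || any(!is.finite(p_ex)) || any(p_ex <= 0)) {
    stop_domain("excitation power must be positive and finite (mW)")
  }
  if (!is.numeric(corrected_output) || any(!is.finite(corrected_output)) ||
      any(corrected_output < 0)) {
    stop_domain("corrected output must be non-negative and finite (mW)")
  }
  corrected_output / p_ex
}

#' Diamond-anvil-cell pressure series
#'
#' @param pressure_gpa Hydrostatic pressures in GPa, strictly increasing,
#'   length >= 2.
#' @param intensity Integrated SHG intensities, all > 0.
#' @param p_ex Excitation power(s) in mW (scalar or one per point).
#' @return An object of class `pressure_series`.
#' @export
pressure_series <- function(pressure_gpa, intensity, p_ex = 1) {
  n <- length(pressure_gpa)
  if (n < 2L || length(intensity) != n) {
    stop_domain("need >= 2 (pressure, intensity) points of equal length")
  }
  if (any(diff(pressure_gpa) <= 0)) {
    stop_domain("pressures must be strictly increasing")
  }
  if (any(!is.finite(intensity)) || any(intensity <= 0)) {
    stop_domain("intensities must be positive and finite")
  }
  p_ex <- rep_len(as.numeric(p_ex), n)
  if (any(!is.finite(p_ex)) || any(p_ex <= 0)) {
    stop_domain("excitation powers must be positive and finite")
  }
  structure(list(pressure_gpa = as.numeric(pressure_gpa),
                 intensity = as.numeric(intensity), p_ex = p_ex),
            class = "pressure_series")
}

#' Pressure enhancement of SHG efficiency
#'
#' Ratio of the SHG efficiency at the maximum-pressure point to that at the
#' first point.  Because SHG intensity scales with the square of excitation
#' power, each point's intensity is normalized by \eqn{P_{ex}^2} before the
#' ratio is taken, so the result reflects the change in nonlinear
#' susceptibility, not differences in excitation power.  Invariant to common
#' rescaling of all intensities.
#'
#' @param series A [pressure_series()].
#' @return Dimensionless enhancement factor (>= 1 when intensities are
#'   non-decreasing).
#' @export
pressure_enhancement <- function(series) {
  stopifnot(inherits(series, "pressure_series"))
  eff <- series$intensity / series$p_ex^2
  if (eff[1L] == 0) stop_domain("zero initial intensity")
  eff[length(eff)] / eff[1L]
}

#' Multiplicative SHG photon budget
#'
#' Output visible photon flux = IR band flux x conversion efficiency x
#' pressure enhancement x any extra named multipliers (e.g. a microcavity
#' resonance factor).  The output band defaults to the half-wavelength image
#' of the input band.
#'
#' @param ir_flux A [photon_flux()] (or bare number) for the infrared band.
#' @param efficiency SHG conversion efficiency in \[0, 1\].
#' @param enhancement Pressure-enhancement multiplier, > 0.
#' @param extra_factors Named numeric vector of additional multipliers, all
#'   > 0 (default none).
#' @return A [photon_flux()] for the up-converted visible band.
#' @examples
#' photon_budget(1e12, 1e-7, 66)$value  # 6.6e6
#' @export
photon_budget <- function(ir_flux, efficiency, enhancement = 1,
                          extra_factors = numeric()) {
  if (is.numeric(ir_flux)) ir_flux <- photon_flux(ir_flux)
  stopifnot(inherits(ir_flux, "photon_flux"))
  if (!is_scalar_number(efficiency) || efficiency < 0 || efficiency > 1) {
    stop_domain("efficiency must lie in [0, 1]")
  }
  if (!is_scalar_number(enhancement) || enhancement <= 0) {
    stop_domain("enhancement must be a positive scalar")
  }
  if (length(extra_factors) &&
      (any(!is.finite(extra_factors)) || any(extra_factors <= 0))) {
    stop_domain("all extra factors must be positive and finite")
  }
  out_band <- if (is.null(ir_flux$band)) NULL else {
    spectral_band(ir_flux$band$lambda_min / 2, ir_flux$band$lambda_max / 2)
  }
  photon_flux(ir_flux$value * efficiency * enhancement * prod(extra_factors),
              band = out_band,
              source_description = "SHG up-converted flux")
}

#' Orders of magnitude between two photon fluxes
#'
#' @param a,b [photon_flux()] objects or bare positive numbers.
#' @return log10(a / b).
#' @examples
#' orders_of_magnitude_ratio(6.6e6, 1e3)  # 3.82: "three orders of magnitude"
#' @export
orders_of_magnitude_ratio <- function(a, b) {
  va <- if (inherits(a, "photon_flux")) a$value else a
  vb <- if (inherits(b, "photon_flux")) b$value else b
  if (!is_scalar_number(va) || !is_scalar_number(vb) || va <= 0 || vb <= 0) {
    stop_domain("both fluxes must be positive")
  }
  log10(va / vb)
}
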