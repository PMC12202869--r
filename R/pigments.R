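#' Pigment absorption template
#'
#' @param name Pigment name.
#' @param absorption A [spectrum()] normalized so its maximum is 1.
#' @param nominal_peaks Nominal absorption peak wavelengths in nm.
#' @return An object of class `pigment_template`.
#' @export
pigment_template <- function(name, absorption, nominal_peaks) {
  stopifnot(inherits(absorption, "spectrum"))
  if (abs(max(absorption$intensity) - 1) > 1e-9) {
    stop_domain("absorption template must be normalized to max 1")
  }
  if (!length(nominal_peaks) || any(nominal_peaks <= 0)) {
    stop_domain("nominal peaks must be positive wavelengths (nm)")
  }
  structure(list(name = name, absorption = absorption,
                 nominal_peaks = as.numeric(nominal_peaks)),
            class = "pigment_template")
}

# Gaussian band helper on a fixed grid.
.gauss_band <- function(x, center, sigma, amp = 1) {
  amp * exp(-((x - center)^2) / (2 * sigma^2))
}

#' Packaged photosynthetic-pigment absorption templates
#'
#' Synthetic stand-in absorption spectra for the pigments relevant to
#' matching mineral SHG emission with photosynthetic light harvesting.
#' Only nominal peak positions are constrained by the literature (chlorophyll
#' a 430/662 nm, chlorophyll b 453/642 nm, a carotenoid plateau at
#' 450-500 nm, phycourobilin 495 nm, phycoerythrocyanin 575 nm,
#' allophycocyanin 650 nm); band widths (15-30 nm sigma) and relative
#' amplitudes are generic.  Each template is normalized to maximum 1 on a
#' 350-750 nm, 1 nm grid.
#'
#' @return Named list of [pigment_template()] objects.
#' @examples
#' names(pigment_templates())
#' @export
pigment_templates <- function() {
  x <- seq(350, 750, by = 1)
  mk <- function(name, bands, peaks) {
    y <- rowSums(vapply(bands,
                        function(b) .gauss_band(x, b[1L], b[2L], b[3L]),
                        numeric(length(x))))
    pigment_template(name, spectrum(x, y / max(y), label = name), peaks)
  }
  list(
    chlorophyll_a = mk("chlorophyll_a",
                       list(c(430, 18, 1.0), c(662, 15, 0.75)),
                       c(430, 662)),
    chlorophyll_b = mk("chlorophyll_b",
                       list(c(453, 18, 1.0), c(642, 15, 0.55)),
                       c(453, 642)),
    carotenoids = mk("carotenoids",
                     list(c(455, 22, 1.0), c(475, 22, 1.0), c(495, 22, 1.0)),
                     475),
    phycourobilin = mk("phycourobilin", list(c(495, 20, 1.0)), 495),
    phycoerythrocyanin = mk("phycoerythrocyanin", list(c(575, 20, 1.0)), 575),
    allophycocyanin = mk("allophycocyanin", list(c(650, 16, 1.0)), 650)
  )
}

#' Match an emission peak against pigment absorption maxima
#'
#' Ranks pigments whose nominal absorption peak lies within `tolerance` nm
#' of an emission peak, ascending by distance.
#'
#' @param peak_lambda Emission peak wavelength in nm.
#' @param pigments Named list of [pigment_template()] objects
#'   (default [pigment_templates()]).
#' @param tolerance Match tolerance in nm, > 0.
#' @return Data frame with columns `pigment`, `nominal_peak`, `distance`,
#'   sorted ascending by distance (zero rows if nothing matches).
#' @examples
#' match_pigments(575, tolerance = 10)  # phycoerythrocyanin
#' @export
match_pigments <- function(peak_lambda, pigments = pigment_templates(),
                           tolerance = 10) {
  if (!is_scalar_number(peak_lambda) || peak_lambda <= 0) {
    stop_domain("peak wavelength must be a positive scalar (nm)")
  }
  if (!is_scalar_number(tolerance) || tolerance <= 0) {
    stop_domain("tolerance must be positive (nm)")
  }
  rows <- lapply(pigments, function(p) {
    stopifnot(inherits(p, "pigment_template"))
    d <- abs(p$nominal_peaks - peak_lambda)
    i <- which.min(d)
    data.frame(pigment = p$name, nominal_peak = p$nominal_peaks[i],
               distance = d[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$distance <= tolerance, , drop = FALSE]
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}
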