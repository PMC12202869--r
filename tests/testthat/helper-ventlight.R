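# Shared fixtures and independent oracles for the test suite.

# Gaussian band on a grid (independent of the package's internal helper).
gauss <- function(x, center, sigma, amp = 1) {
  amp * exp(-((x - center)^2) / (2 * sigma^2))
}

# Independent quadrature oracle for band photon fluxes: composite
# Gauss-Legendre (80 log-spaced panels x 16 nodes via pracma), evaluating
# the Planck photon radiance written out from first principles.  A
# different scheme from the package's adaptive integrate(), and accurate to
# machine precision for this analytic integrand.
oracle_band_flux <- function(lmin, lmax, temp, emissivity = 1) {
  h <- 6.62607015e-34; cc <- 299792458; kB <- 1.380649e-23
  f <- function(lam_nm) {
    lam <- lam_nm * 1e-9
    emissivity * 1e-13 * 2 * cc / lam^4 / expm1(h * cc / (lam * kB * temp))
  }
  edges <- exp(seq(log(lmin), log(lmax), length.out = 81))
  total <- 0
  for (i in seq_len(80)) {
    gl <- pracma::gaussLegendre(16, edges[i], edges[i + 1])
    total <- total + sum(gl$w * f(gl$x))
  }
  total
}

# Brute-force positional coverage oracle: mark every covered amino acid.
oracle_covered_fraction <- function(sstart, send, len) {
  covered <- logical(len)
  for (i in seq_along(sstart)) {
    covered[seq.int(sstart[i], send[i])] <- TRUE
  }
  mean(covered)
}

# Write an outfmt-6 file from a plain record list.
write_outfmt6 <- function(rows, path) {
  writeLines(vapply(rows, paste, character(1), collapse = "\t"), path)
  path
}

# Minimal two-gene catalog for focused metagenome tests.
toy_catalog <- function() {
  gene_catalog(data.frame(
    gene_id = c("K0001", "K0002", "K0003", "FRL0001", "FRL0002", "FRL0003"),
    symbol = c("psaA", "psbA", "apcA", "apcD2", "apcD3", "apcD5"),
    category = c("PSI", "PSII", "PBS_APC", "FaRLiP", "FaRLiP", "FaRLiP"),
    length = c(100, 200, 150, 161, 161, 161),
    stringsAsFactors = FALSE
  ))
}
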