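#' Optical spectrum
#'
#' A wavelength grid with non-negative intensities, the common container of
#' all emission/absorption stages.
#'
#' @param wavelength Strictly increasing wavelength grid in nm, length >= 8.
#' @param intensity Non-negative intensities (arbitrary units), same length.
#' @param label Free-text label (condition, mineral, pigment, ...).
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(wavelength, intensity, label = "") {
  if (length(wavelength) < 8L || length(wavelength) != length(intensity)) {
    stop_domain("need equal-length wavelength/intensity vectors, length >= 8")
  }
  if (any(!is.finite(wavelength)) || any(!is.finite(intensity))) {
    stop_domain("spectrum values must be finite (no NaN/NA)")
  }
  if (any(diff(wavelength) <= 0)) {
    stop_domain("wavelengths must be strictly increasing")
  }
  if (any(intensity < 0)) {
    stop_domain("intensities must be non-negative")
  }
  structure(list(wavelength = as.numeric(wavelength),
                 intensity = as.numeric(intensity),
                 label = as.character(label)),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> '%s': %d points, %g-%g nm, max intensity %.4g\n",
              x$label, length(x$wavelength), min(x$wavelength),
              max(x$wavelength), max(x$intensity)))
  invisible(x)
}

#' Read / write a two-column spectrum TSV
#'
#' Format: two tab-separated columns `wavelength_nm` and `intensity`,
#' optional leading `#` comment lines.
#'
#' @param path File path.
#' @param label Label to attach on read (defaults to the file name).
#' @return `read_spectrum_tsv()` returns a [spectrum()];
#'   `write_spectrum_tsv()` returns `path` invisibly.
#' @export
read_spectrum_tsv <- function(path, label = basename(path)) {
  df <- read.delim(path, comment.char = "#", header = TRUE)
  if (ncol(df) < 2L) stop_domain("expected two columns in ", path)
  spectrum(df[[1L]], df[[2L]], label = label)
}

#' @rdname read_spectrum_tsv
#' @param s A [spectrum()] to write.
#' @export
write_spectrum_tsv <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  df <- data.frame(wavelength_nm = s$wavelength, intensity = s$intensity)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Detect peaks in a spectrum
#'
#' Finds local maxima and keeps those whose topographic prominence exceeds
#' `min_prominence` times the spectrum's dynamic range (max - min), which
#' makes detection invariant to intensity rescaling and to constant baseline
#' offsets.  Each peak's width is measured at half prominence by linear
#' interpolation.
#'
#' @param s A [spectrum()].
#' @param min_prominence Prominence threshold as a fraction of the dynamic
#'   range (default 0.05).
#' @return A data frame with columns `wavelength`, `height`, `prominence`
#'   and `width` (nm at half prominence), sorted by wavelength.  Zero rows
#'   if no peak qualifies.
#' @export
detect_peaks <- function(s, min_prominence = 0.05) {
  stopifnot(inherits(s, "spectrum"))
  x <- s$wavelength; y <- s$intensity; n <- length(y)
  rng <- max(y) - min(y)
  empty <- data.frame(wavelength = numeric(), height = numeric(),
                      prominence = numeric(), width = numeric())
  if (rng == 0) return(empty)
  idx <- which(y[-c(1L, n)] > y[-c(n - 1L, n)] &
                 y[-c(1L, n)] >= y[-c(1L, 2L)]) + 1L
  if (!length(idx)) return(empty)
  prom <- vapply(idx, function(i) {
    h <- y[i]
    left <- y[seq_len(i - 1L)]
    higher_l <- which(left > h)
    lmin <- min(left[seq.int(if (length(higher_l)) max(higher_l) else 1L,
                             i - 1L)])
    right <- y[seq.int(i + 1L, n)]
    higher_r <- which(right > h)
    rmin <- min(right[seq_len(if (length(higher_r)) min(higher_r) else
      length(right))])
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= min_prominence * rng
  idx <- idx[keep]; prom <- prom[keep]
  if (!length(idx)) return(empty)
  width <- mapply(function(i, p) {
    ref <- y[i] - p / 2
    li <- i
    while (li > 1L && y[li] > ref) li <- li - 1L
    xl <- if (y[li] > ref) x[li] else {
      approx(y[c(li, li + 1L)], x[c(li, li + 1L)], xout = ref)$y
    }
    ri <- i
    while (ri < n && y[ri] > ref) ri <- ri + 1L
    xr <- if (y[ri] > ref) x[ri] else {
      approx(y[c(ri - 1L, ri)], x[c(ri - 1L, ri)], xout = ref)$y
    }
    xr - xl
  }, idx, prom)
  out <- data.frame(wavelength = x[idx], height = y[idx],
                    prominence = prom, width = as.numeric(width))
  out[order(out$wavelength), , drop = FALSE]
}

# Sum-of-Gaussians + constant baseline evaluated at x for a packed parameter
# vector c(baseline, amp_1..k, center_1..k, sigma_1..k).
gauss_model <- function(par, x, k) {
  b <- par[1L]
  a <- par[1L + seq_len(k)]
  ce <- par[1L + k + seq_len(k)]
  si <- par[1L + 2L * k + seq_len(k)]
  y <- rep(b, length(x))
  for (j in seq_len(k)) {
    y <- y + a[j] * exp(-((x - ce[j])^2) / (2 * si[j]^2))
  }
  y
}

#' Multi-Gaussian decomposition of a spectrum
#'
#' Nonlinear least squares of a sum of `k` Gaussians plus a constant
#' baseline, fitted with the Levenberg-Marquardt algorithm
#' (`minpack.lm::nls.lm`) under box constraints (non-negative amplitudes,
#' centers inside the fit window, bounded widths).  Residuals are scaled by
#' intensity (relative-error objective, floored at 2% of the maximum),
#' matching the multiplicative detector-noise model of emission
#' measurements; this lets the precisely measured band tails constrain
#' strongly overlapping components.  Initial centers are the `k` most
#' prominent detected peaks; missing ones are seeded at quantiles of the
#' intensity mass (overlapping components often merge into a single broad
#' maximum).  A bounded, seeded multi-start (perturbed centers) guards
#' against local minima; the best solution by the weighted objective is
#' returned.  Deterministic for a given `seed`.
#'
#' @param s A [spectrum()].
#' @param k Number of Gaussian components, >= 1.
#' @param window Optional `c(min, max)` nm fit window (default: full grid).
#' @param n_starts Number of multi-start attempts (default 10).
#' @param seed Integer seed controlling the start perturbations.
#' @return An object of class `decomposition`: a list with `components`
#'   (data frame `center`, `sigma`, `fwhm`, `amplitude`, sorted by center),
#'   `baseline`, `residual_rms` (unweighted, intensity units), `objective`
#'   (the minimized weighted sum of squares), `window`, and `converged`.
#' @examples
#' x <- seq(600, 810, by = 1)
#' s <- spectrum(x, exp(-(x - 685)^2 / (2 * 18^2)), "one band")
#' decompose_gaussians(s, k = 1)$components
#' @export
decompose_gaussians <- function(s, k, window = NULL, n_starts = 10L,
                                seed = 1L) {
  stopifnot(inherits(s, "spectrum"))
  if (!is_scalar_number(k) || k < 1 || k != round(k)) {
    stop_domain("k must be a positive integer")
  }
  k <- as.integer(k)
  x <- s$wavelength; y <- s$intensity
  if (!is.null(window)) {
    keep <- x >= window[1L] & x <= window[2L]
    if (sum(keep) < 3L * k + 1L) {
      stop_domain("fit window covers too few grid points")
    }
    x <- x[keep]; y <- y[keep]
  }
  w_lo <- min(x); w_hi <- max(x); w_span <- w_hi - w_lo
  step <- min(diff(x))

  peaks <- detect_peaks(spectrum(x, pmax(y, 0), s$label), min_prominence = 0.02)
  centers0 <- if (nrow(peaks)) {
    head(peaks$wavelength[order(-peaks$prominence)], k)
  } else numeric()
  if (length(centers0) < k) {
    # overlapping components often merge into one broad band with a single
    # local maximum; seed the missing centers at quantiles of the intensity
    # mass so they start inside the band, not at the window edges
    mass <- cumsum(pmax(y - min(y), 0))
    if (mass[length(mass)] > 0) {
      qs <- (2 * seq_len(k) - 1) / (2 * k) * mass[length(mass)]
      cand <- x[vapply(qs, function(q) which.max(mass >= q), integer(1))]
      for (cc in cand) {
        if (length(centers0) < k &&
            (!length(centers0) || min(abs(centers0 - cc)) > w_span / (4 * k))) {
          centers0 <- c(centers0, cc)
        }
      }
    }
    if (length(centers0) < k) {
      centers0 <- c(centers0,
                    seq(w_lo + w_span / (2 * k), w_hi - w_span / (2 * k),
                        length.out = k)[seq_len(k - length(centers0))])
    }
  }
  centers0 <- sort(centers0)
  rng <- max(y) - min(y)
  b0 <- min(y)
  amps0 <- pmax(approx(x, y, xout = centers0)$y - b0, max(y) * 1e-3)
  sig0 <- rep(min(w_span / (4 * k), w_span / 8), k)

  lower <- c(min(y) - 0.1 * rng, rep(0, k), rep(w_lo, k), rep(step / 2, k))
  upper <- c(max(y), rep(1.5 * rng + .Machine$double.eps, k), rep(w_hi, k),
             rep(w_span / 3, k))

  wts <- pmax(y, 0.02 * max(y))
  best <- NULL
  best_obj <- Inf
  with_seed(seed, {
    for (i in seq_len(n_starts)) {
      ce <- if (i == 1L) centers0 else {
        pmin(pmax(centers0 + rnorm(k, 0, w_span / 15), w_lo), w_hi)
      }
      par0 <- c(b0, amps0, ce, sig0)
      fit <- tryCatch(
        minpack.lm::nls.lm(par = par0,
                           fn = function(p) (y - gauss_model(p, x, k)) / wts,
                           lower = lower, upper = upper,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 1000, ftol = 1e-12, ptol = 1e-12)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        obj <- sum(fit$fvec^2)
        if (obj < best_obj) {
          best_obj <- obj
          best <- fit
        }
        if (obj <= 1e-20 * length(y)) break
      }
    }
  })
  if (is.null(best)) {
    stop_domain("Gaussian decomposition failed to converge in ", n_starts,
                " starts (no finite fit found)")
  }
  p <- best$par
  comp <- data.frame(center = p[1L + k + seq_len(k)],
                     sigma = p[1L + 2L * k + seq_len(k)],
                     amplitude = p[1L + seq_len(k)])
  comp$fwhm <- 2.3548 * comp$sigma
  comp <- comp[order(comp$center), c("center", "sigma", "fwhm", "amplitude")]
  rownames(comp) <- NULL
  resid <- y - gauss_model(p, x, k)
  structure(list(components = comp,
                 baseline = p[1L],
                 residual_rms = sqrt(mean(resid^2)),
                 objective = best_obj,
                 window = c(w_lo, w_hi),
                 converged = best$info %in% 1:4),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("<decomposition> %d component(s), window %g-%g nm, baseline %.4g, residual RMS %.4g\n",
              nrow(x$components), x$window[1L], x$window[2L], x$baseline,
              x$residual_rms))
  print(x$components, digits = 5)
  invisible(x)
}

#' Spectral overlap score
#'
#' Normalized inner product of two spectra,
#' \eqn{\int e a \, d\lambda / \sqrt{\int e^2 d\lambda \int a^2 d\lambda}},
#' computed on the union grid restricted to the intersection of supports
#' (linear interpolation).  Lies in \[0, 1\]; equals 1 iff the shapes are
#' proportional on the common grid; symmetric; invariant to positive
#' rescaling.  Disjoint supports give 0 with a warning.
#'
#' @param emission,absorption [spectrum()] objects.
#' @return Overlap score in \[0, 1\].
#' @export
overlap_score <- function(emission, absorption) {
  stopifnot(inherits(emission, "spectrum"), inherits(absorption, "spectrum"))
  lo <- max(min(emission$wavelength), min(absorption$wavelength))
  hi <- min(max(emission$wavelength), max(absorption$wavelength))
  if (lo >= hi) {
    warning("disjoint wavelength supports; overlap score is 0", call. = FALSE)
    return(0)
  }
  grid <- sort(unique(c(emission$wavelength, absorption$wavelength)))
  grid <- grid[grid >= lo & grid <= hi]
  e <- approx(emission$wavelength, emission$intensity, xout = grid)$y
  a <- approx(absorption$wavelength, absorption$intensity, xout = grid)$y
  ee <- trapz(grid, e^2)
  aa <- trapz(grid, a^2)
  if (ee == 0 || aa == 0) {
    warning("a spectrum is identically zero on the common support",
            call. = FALSE)
    return(0)
  }
  min(1, max(0, trapz(grid, e * a) / sqrt(ee * aa)))
}

#' Classify substrate/organism control spectra
#'
#' For each labelled spectrum, decides (a) whether an SHG line is present at
#' half the excitation wavelength and (b) whether the broad cyanobacterial
#' cell fluorescence band (610-810 nm) is present.  Baseline level and noise
#' are estimated robustly (median / MAD) from the grid excluding both the
#' SHG window and the cell band; the SHG line requires the local maximum
#' within `shg_tol` nm of `lambda_ex / 2` to exceed baseline + 5 sigma, and
#' the cell band requires the mean baseline-subtracted intensity over
#' 610-810 nm to exceed 5 sigma.
#'
#' @param spectra Named list of [spectrum()] objects (names are condition
#'   labels).
#' @param lambda_ex Excitation wavelength in nm (default 1064).
#' @param shg_tol Half-width of the SHG search window in nm (default 3).
#' @param cell_band `c(min, max)` nm of the cell fluorescence band.
#' @return A data frame with columns `label`, `has_shg_line`,
#'   `has_cell_band`.
#' @export
substrate_control_classify <- function(spectra, lambda_ex = 1064,
                                       shg_tol = 3,
                                       cell_band = c(610, 810)) {
  stopifnot(is.list(spectra), length(spectra) > 0)
  if (is.null(names(spectra)) || any(!nzchar(names(spectra)))) {
    stop_domain("spectra must be a named list")
  }
  l_shg <- shg_wavelength(lambda_ex)
  rows <- lapply(names(spectra), function(lab) {
    s <- spectra[[lab]]
    stopifnot(inherits(s, "spectrum"))
    x <- s$wavelength; y <- s$intensity
    ref <- !(x >= l_shg - 10 & x <= l_shg + 10) &
      !(x >= cell_band[1L] - 10 & x <= cell_band[2L] + 10)
    if (sum(ref) < 8L) ref <- rep(TRUE, length(x))
    base <- median(y[ref])
    sigma <- max(mad(y[ref]), .Machine$double.eps)
    in_shg <- x >= l_shg - shg_tol & x <= l_shg + shg_tol
    has_shg <- any(in_shg) && max(y[in_shg]) > base + 5 * sigma
    in_band <- x >= cell_band[1L] & x <= cell_band[2L]
    has_band <- any(in_band) && mean(y[in_band]) - base > 5 * sigma
    data.frame(label = lab, has_shg_line = has_shg, has_cell_band = has_band,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
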