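# Seeded generators producing every input the pipeline consumes.  Each is a
# pure function of its arguments (including the seed): no global RNG state
# leaks in or out (see with_seed()).

#' Simulate an SHG excitation-power series
#'
#' Intensities follow `I = prefactor * P^exponent * (1 + eps)` with
#' `eps ~ Normal(0, noise_level)` (multiplicative detector-like noise).  The
#' default powers span the 0.45-3.20 mW excitation range of the reference
#' measurements.
#'
#' @param lambda_ex Excitation wavelength in nm (default 928).
#' @param powers Excitation powers in mW (default 8 points spanning
#'   0.45-3.20).
#' @param prefactor Power-law prefactor (default 1).
#' @param exponent Power-law exponent (default 2, ideal SHG).
#' @param noise_level Relative noise standard deviation (default 0.02).
#' @param seed Integer seed.
#' @return A [power_series()].
#' @examples
#' fit_power_law(gen_power_series(seed = 1, noise_level = 0))$exponent  # 2
#' @export
gen_power_series <- function(lambda_ex = 928,
                             powers = c(0.45, 0.8, 1.2, 1.6, 2.0, 2.4, 2.8, 3.2),
                             prefactor = 1, exponent = 2,
                             noise_level = 0.02, seed = 1L) {
  stopifnot(all(powers > 0), noise_level >= 0, prefactor > 0)
  intensity <- with_seed(seed, {
    prefactor * powers^exponent * (1 + rnorm(length(powers), 0, noise_level))
  })
  power_series(powers, pmax(intensity, 0), excitation_wavelength = lambda_ex)
}

#' Simulate a diamond-anvil-cell pressure series
#'
#' Builds a monotone SHG intensity profile whose last/first
#' power-normalized efficiency ratio equals `enhancement` before noise
#' (geometric ramp across `n_points`), then applies multiplicative Gaussian
#' noise.  Pressures are an arbitrary increasing GPa grid (the reference
#' experiment does not publish its pressure steps).
#'
#' @param n_points Number of pressure points, >= 2 (default 8).
#' @param enhancement Embedded efficiency enhancement factor (default 66).
#' @param noise_level Relative noise standard deviation (default 0.05).
#' @param p_ex Excitation power in mW (common to all points, default 1).
#' @param seed Integer seed.
#' @return A [pressure_series()].
#' @examples
#' pressure_enhancement(gen_pressure_series(seed = 1, noise_level = 0))  # 66
#' @export
gen_pressure_series <- function(n_points = 8L, enhancement = 66,
                                noise_level = 0.05, p_ex = 1, seed = 1L) {
  stopifnot(n_points >= 2L, enhancement > 0, noise_level >= 0, p_ex > 0)
  pressure <- seq(0.3, 9, length.out = n_points)
  eff <- enhancement^(seq(0, 1, length.out = n_points))
  base <- eff * p_ex^2
  intensity <- with_seed(seed, {
    base * (1 + rnorm(n_points, 0, noise_level))
  })
  pressure_series(pressure, pmax(intensity, min(base) * 1e-6), p_ex = p_ex)
}

#' Simulate a substrate/organism fluorescence spectrum
#'
#' Emulates the in situ fluorescence measurement of *Synechococcus* sp.
#' PCC 7002 on a mineral substrate under infrared excitation, on a
#' 400-850 nm, 1 nm grid:
#'
#' * `cpy_7002` (cells on chalcopyrite): a narrow SHG line at
#'   `lambda_ex / 2` (sigma 2 nm) plus the broad cell band modeled as three
#'   Gaussians at 656 / 685 / 713 nm (sigmas 15 / 16 / 18 nm, amplitudes
#'   0.6 / 1.0 / 0.5 — the phycobilisome, photosystem II and photosystem I
#'   signatures).
#' * `cpy_medium` (sterile A-plus medium on chalcopyrite): SHG line only.
#' * `glass_7002`, `gal_7002` (cells on glass or galena): pedestal and
#'   noise only — neither substrate up-converts.
#'
#' Multiplicative Gaussian detector noise is applied on top of a small
#' constant pedestal: `I = signal * (1 + eps)`, `eps ~ Normal(0,
#' noise_level)`, clipped at zero.
#'
#' @param condition One of `"cpy_7002"`, `"glass_7002"`, `"gal_7002"`,
#'   `"cpy_medium"`.
#' @param lambda_ex Excitation wavelength in nm (default 1064).
#' @param noise_level Noise standard deviation (default 0.01).
#' @param seed Integer seed.
#' @return A [spectrum()] labelled with the condition.
#' @export
gen_fluorescence_spectrum <- function(condition = c("cpy_7002", "glass_7002",
                                                    "gal_7002", "cpy_medium"),
                                      lambda_ex = 1064, noise_level = 0.01,
                                      seed = 1L) {
  condition <- match.arg(condition)
  x <- seq(400, 850, by = 1)
  y <- rep(0.02, length(x))  # detector pedestal
  if (condition %in% c("cpy_7002", "cpy_medium")) {
    y <- y + .gauss_band(x, shg_wavelength(lambda_ex), 2, 2.0)
  }
  if (condition == "cpy_7002") {
    y <- y + .gauss_band(x, 656, 15, 0.6) +
      .gauss_band(x, 685, 16, 1.0) +
      .gauss_band(x, 713, 18, 0.5)
  }
  y <- with_seed(seed, y * (1 + rnorm(length(x), 0, noise_level)))
  spectrum(x, pmax(y, 0), label = condition)
}

#' Mineral SHG emission templates
#'
#' Normalized (max 1) synthetic emission spectra for the five SHG-active
#' vent sulfides, on a 400-750 nm, 1 nm grid.  Peak positions follow the
#' measured emission windows: chalcopyrite 471 nm (420-540 nm band),
#' bismuthinite within 400-550 nm, molybdenite and stibnite within
#' 570-620 nm, orpiment a broad band within 420-725 nm.
#'
#' @return Named list of [spectrum()] objects.
#' @examples
#' peaks <- detect_peaks(gen_mineral_templates()$chalcopyrite)
#' peaks$wavelength  # 471
#' @export
gen_mineral_templates <- function() {
  x <- seq(400, 750, by = 1)
  mk <- function(name, bands) {
    y <- rowSums(vapply(bands,
                        function(b) .gauss_band(x, b[1L], b[2L], b[3L]),
                        numeric(length(x))))
    spectrum(x, y / max(y), label = name)
  }
  list(
    chalcopyrite = mk("chalcopyrite", list(c(471, 20, 1))),
    bismuthinite = mk("bismuthinite", list(c(490, 26, 1))),
    molybdenite = mk("molybdenite", list(c(585, 18, 1))),
    stibnite = mk("stibnite", list(c(605, 18, 1))),
    orpiment = mk("orpiment", list(c(560, 55, 1)))
  )
}

#' Default designed presence profile by vent type
#'
#' Designed per-category completeness fractions emulating the qualitative
#' structure of the vent-type comparison: high-temperature (C1) vents carry
#' near-complete photosystem and electron-transport genes with
#' phycobilisome completeness around 0.8 and no FaRLiP genes; cooler (C2)
#' vents largely lack them; shallow deposits (S) are near complete;
#' non-vent deep sea (N) lacks phycobilisomes entirely; ATPase genes are
#' intact almost everywhere.
#'
#' @return A data frame (rows = vent types, columns = categories) of class
#'   `presence_profile`.
#' @export
default_presence_profile <- function() {
  cats <- c("PSI", "PSII", "Cytb6f", "PET", "ATPase",
            "PBS_APC", "PBS_PC_PEC", "PBS_PE", "FaRLiP")
  prof <- rbind(
    C1 = c(1.0, 1.0, 1.0, 1.0, 1.0, 0.8, 0.8, 0.8, 0.0),
    C2 = c(0.1, 0.1, 0.1, 0.3, 1.0, 0.2, 0.1, 0.0, 0.0),
    S  = c(0.9, 0.9, 1.0, 0.9, 1.0, 0.9, 0.9, 0.8, 0.0),
    N  = c(0.3, 0.3, 0.2, 0.3, 1.0, 0.0, 0.0, 0.0, 0.0)
  )
  colnames(prof) <- cats
  df <- as.data.frame(prof)
  class(df) <- c("presence_profile", "data.frame")
  df
}

#' Simulate per-dataset alignment hit tables from a presence profile
#'
#' For every dataset, genes designated present receive simulated reads
#' tiling the full gene (50 aa alignments, 20 aa step, the tiling laid down
#' twice — i.e. roughly 2x redundancy, as a real library would give), so
#' that at zero dropout their breadth of coverage is exactly 1; each tiling
#' read is then removed independently with probability `dropout`, and the
#' redundancy keeps breadth above the presence threshold except under
#' coincident losses.  Genes designated absent receive at most one sparse
#' alignment covering ~30% of the gene, well under the threshold.  Which
#' genes of a category are present is drawn per dataset from the seeded
#' RNG, with the count fixed at `round(fraction * n_genes)` so the realized
#' design matrix is exact.
#'
#' @param profile Presence profile data frame (rows = vent types, columns =
#'   categories), e.g. [default_presence_profile()].
#' @param catalog A [gene_catalog()].
#' @param n_per_type Number of datasets per vent type (default 2).
#' @param library_size Library size in reads per dataset (default 1e6).
#' @param dropout Per-read Bernoulli dropout probability in \[0, 1)
#'   (default 0).
#' @param seed Integer seed.
#' @param out_dir Optional directory: if given, writes one `<dataset>.tsv`
#'   outfmt-6 file per dataset plus `library_sizes.tsv` and `metadata.tsv`.
#' @return A list with `hits` (named list of hit data frames), `meta`,
#'   `library_sizes`, and `design` (the realized completeness matrix the
#'   pipeline should recover, datasets x categories).
#' @export
gen_hit_table <- function(profile = default_presence_profile(),
                          catalog = read_gene_catalog(),
                          n_per_type = 2L, library_size = 1e6,
                          dropout = 0, seed = 1L, out_dir = NULL) {
  stopifnot(inherits(catalog, "gene_catalog"),
            dropout >= 0, dropout < 1, n_per_type >= 1L)
  cats <- colnames(profile)
  missing_cat <- setdiff(cats, catalog$category)
  if (length(missing_cat)) {
    stop_domain("profile categories absent from catalog: ",
                paste(missing_cat, collapse = ", "))
  }
  types <- rownames(profile)
  datasets <- unlist(lapply(types, function(t) {
    paste0(t, "_", seq_len(n_per_type))
  }))
  meta <- data.frame(dataset = datasets,
                     vent_type = rep(types, each = n_per_type),
                     stringsAsFactors = FALSE)
  design <- matrix(0, length(datasets), length(cats),
                   dimnames = list(datasets, cats))
  hits <- with_seed(seed, {
    res <- list()
    read_counter <- 0L
    for (d in datasets) {
      vt <- meta$vent_type[meta$dataset == d]
      rows <- list()
      for (cat in cats) {
        genes <- catalog[catalog$category == cat, , drop = FALSE]
        n_present <- round(profile[vt, cat] * nrow(genes))
        design[d, cat] <- n_present / nrow(genes)
        present <- if (n_present > 0) {
          genes$gene_id[sample.int(nrow(genes), n_present)]
        } else character()
        for (i in seq_len(nrow(genes))) {
          g <- genes$gene_id[i]
          L <- genes$length[i]
          read_len <- 50L
          if (g %in% present) {
            tile <- unique(c(seq(1L, max(1L, L - read_len + 1L), by = 20L),
                             max(1L, L - read_len + 1L)))
            starts <- rep(tile, 2L)
            if (dropout > 0) {
              starts <- starts[runif(length(starts)) >= dropout]
            }
            ends <- pmin(starts + read_len - 1L, L)
          } else if (runif(1) < 0.5) {
            # sparse sub-threshold signal on an absent gene (~30% breadth)
            len_sub <- max(1L, as.integer(floor(0.3 * L)))
            starts <- sample.int(L - len_sub + 1L, 1L)
            ends <- starts + len_sub - 1L
          } else {
            starts <- integer()
            ends <- integer()
          }
          if (!length(starts)) next
          read_counter <- read_counter + length(starts)
          ids <- sprintf("%s_read%07d", d,
                         seq.int(read_counter - length(starts) + 1L,
                                 read_counter))
          rows[[length(rows) + 1L]] <- data.frame(
            qseqid = ids, sseqid = g,
            pident = round(runif(length(starts), 85, 99), 1),
            length = ends - starts + 1L,
            mismatch = sample.int(5L, length(starts), replace = TRUE) - 1L,
            gapopen = 0L,
            qstart = 1L, qend = 3L * (ends - starts + 1L),
            sstart = starts, send = ends,
            evalue = 1e-20,
            bitscore = round(runif(length(starts), 80, 200), 1),
            stringsAsFactors = FALSE)
        }
      }
      res[[d]] <- if (length(rows)) do.call(rbind, rows) else .empty_hits()
    }
    res
  })
  # with_seed() forces its argument in this frame, so `design` is filled
  library_sizes <- setNames(rep(library_size, length(datasets)), datasets)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (d in datasets) {
      write.table(hits[[d]], file.path(out_dir, paste0(d, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
    }
    write.table(data.frame(dataset = datasets,
                           library_size = library_sizes),
                file.path(out_dir, "library_sizes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(meta, file.path(out_dir, "metadata.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(hits = hits, meta = meta, library_sizes = library_sizes,
       design = design)
}
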